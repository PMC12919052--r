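#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate -> FC -> (optional K selection) -> templates -> map ->
#' reliability -> consensus -> metrics -> stats, writing versioned text
#' artifacts and a structured log to `out_dir`. Every output embeds the
#' config hash; identical config + seeds give byte-identical metric tables.
#' A stage failure halts with the stage name and cause.
#'
#' @param config a `run_config` from [default_config()].
#' @param out_dir artifact directory (created if needed).
#' @return invisibly, a list of in-memory stage results (`cohort`,
#'   `templates`, `assignments`, `reliability`, `consensus`, `metrics`,
#'   `stats`, `summary`).
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("netmapr_run_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  log_path <- file.path(out_dir, "log.txt")
  log_line <- function(...) cat(paste0("[", hash, "] ", ...), "\n",
                                sep = "", file = log_path, append = TRUE)
  stage <- function(name, expr) {
    log_line("stage ", name, " start")
    tryCatch(expr, error = function(e) {
      log_line("stage ", name, " FAILED: ", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  write_run_config(config, file.path(out_dir, "config.json"))
  log_line("config written; seed = ", config$seed)

  cohort <- stage("simulate", simulate_cohort(
    n_subjects = config$n_subjects,
    sessions_per_subject = config$sessions_per_subject,
    n_vertices = config$n_vertices, n_parcels = config$n_parcels,
    k_true = config$k_true, r_w = config$r_w, r_b = config$r_b,
    flip_rate = config$flip_rate, boundary_bias = config$boundary_bias,
    n_frames = config$n_frames, tr = config$tr, noise_sd = config$noise_sd,
    p_high = config$p_high, age_range = config$age_range,
    age_effect = config$age_effect, seed = config$seed))
  utils::write.csv(cohort$meta, file.path(out_dir, "sessions.csv"),
                   row.names = FALSE)

  fc <- stage("fc", {
    pfc <- lapply(cohort$sessions, function(s)
      parcel_fc(parcel_timeseries(s, cohort$surface)))
    vfc <- lapply(cohort$sessions, function(s)
      vertex_parcel_fc(s, cohort$surface))
    list(parcel = pfc, vertex = vfc)
  })

  k_used <- config$k
  if (isTRUE(config$select_k)) {
    sel <- stage("select-k", stability_curve(
      fc$parcel, k_range = seq(config$k_range[1], config$k_range[2]),
      n_splits = config$n_splits, seed = config$seed + 2L,
      n_replicates = config$stability_replicates,
      policy = config$chosen_k_policy))
    utils::write.csv(sel$curve, file.path(out_dir, "stability_curve.csv"),
                     row.names = FALSE)
    k_used <- sel$chosen_k
    log_line("select-k chose K = ", k_used, " (local maxima: ",
             paste(sel$local_maxima, collapse = ", "), ")")
  }

  templates <- stage("templates", cluster_templates(
    build_profile_set(fc$parcel), k_used,
    n_replicates = config$n_replicates, seed = config$seed + 3L))
  write_matrix_txt(templates$centroids,
                   file.path(out_dir, "templates.txt"), config_hash = hash)

  assignments <- stage("map", {
    out <- lapply(names(fc$vertex), function(id) {
      a <- match_templates(fc$vertex[[id]], templates,
                           exclude_self_parcel = config$exclude_self_parcel,
                           surface = cohort$surface)
      write_label_map(a, file.path(out_dir, paste0("labels_", id, ".txt")),
                      n_left = sum(cohort$surface$hemisphere == "left"),
                      config_hash = hash)
      if (a$n_ties > 0) log_line("map ", id, ": ", a$n_ties, " tie(s)")
      a
    })
    names(out) <- names(fc$vertex)
    out
  })

  reliability <- stage("reliability", {
    halves <- lapply(names(cohort$sessions), function(id) {
      s <- cohort$sessions[[id]]
      sp <- split_session_half(s)
      lapply(sp, function(fr) match_templates(
        vertex_parcel_fc(subset_session_frames(s, fr), cohort$surface),
        templates))
    })
    names(halves) <- names(cohort$sessions)
    subj <- vapply(cohort$sessions, function(s) s$subject_id, "")
    first_sessions <- names(cohort$sessions)[!duplicated(subj)]
    a1 <- lapply(halves[first_sessions], `[[`, "first")
    a2 <- lapply(halves[first_sessions], `[[`, "second")
    names(a1) <- names(a2) <- subj[!duplicated(subj)]
    rt <- reliability_matrix(a1, a2)
    utils::write.csv(rt, file.path(out_dir, "reliability.csv"),
                     row.names = FALSE)
    rt
  })

  consensus <- stage("consensus", {
    prob <- spatial_probability(assignments, k = k_used)
    cons <- population_consensus(prob)
    v <- versatility(prob)
    thr <- threshold_consensus(prob, config$consensus_thresholds)
    write_matrix_txt(prob, file.path(out_dir, "spatial_probability.txt"),
                     config_hash = hash)
    utils::write.csv(
      data.frame(vertex = seq_along(cons$modal_label),
                 modal = cons$modal_label, agreement = cons$agreement,
                 versatility = v),
      file.path(out_dir, "consensus.csv"), row.names = FALSE)
    list(prob = prob, consensus = cons, versatility = v, thresholded = thr)
  })

  metrics <- stage("metrics", {
    wfc_ind <- t(vapply(names(assignments), function(id)
      within_network_fc(fc$vertex[[id]], assignments[[id]],
                        cohort$surface, k = k_used), numeric(k_used)))
    wfc_con <- t(vapply(names(assignments), function(id)
      within_network_fc(fc$vertex[[id]], consensus$consensus,
                        cohort$surface, k = k_used), numeric(k_used)))
    li <- lapply(assignments, laterality_index, surface = cohort$surface,
                 k = k_used)
    li_tab <- do.call(rbind, lapply(names(li), function(id)
      cbind(session_id = id, li[[id]])))
    utils::write.csv(li_tab, file.path(out_dir, "laterality.csv"),
                     row.names = FALSE)
    write_matrix_txt(wfc_ind, file.path(out_dir, "within_fc_individual.txt"),
                     config_hash = hash)
    write_matrix_txt(wfc_con, file.path(out_dir, "within_fc_consensus.txt"),
                     config_hash = hash)
    list(within_fc_individual = wfc_ind, within_fc_consensus = wfc_con,
         laterality = li_tab)
  })

  stats_out <- NULL
  if (isTRUE(config$run_stats)) {
    stats_out <- stage("stats", {
      cmp <- compare_within_fc(metrics$within_fc_individual,
                               metrics$within_fc_consensus)
      li1 <- metrics$laterality[metrics$laterality$network == 1, ]
      ord <- match(li1$session_id, cohort$meta$session_id)
      beh <- generate_behavior(
        subjects = cohort$meta$subject_id[ord],
        li_values = li1$li,
        beta_true = config$beta_true,
        noise_sd = config$behavior_noise_sd,
        age_months = cohort$meta$age[ord] * 12,
        seed = config$seed + 4L)
      model <- fit_laterality_model(beh, outcome = "li",
                                    fixed = c("age_years", "VDQ"))
      utils::write.csv(cmp, file.path(out_dir, "within_fc_tests.csv"),
                       row.names = FALSE)
      utils::write.csv(model$coefficients,
                       file.path(out_dir, "laterality_model.csv"),
                       row.names = FALSE)
      list(within_fc_tests = cmp, laterality_model = model, behavior = beh)
    })
  } else {
    log_line("stats stage skipped (run_stats = FALSE or no behavior scores)")
  }

  summary <- list(
    config_hash = hash, k = k_used,
    n_sessions = length(cohort$sessions),
    mean_within_nmi = mean(
      reliability$nmi[reliability$comparison_type == "split_within"]),
    mean_between_nmi = mean(
      reliability$nmi[reliability$comparison_type == "split_between"])
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  log_line("pipeline complete: ", out_dir)
  invisible(list(cohort = cohort, fc = fc, templates = templates,
                 assignments = assignments, reliability = reliability,
                 consensus = consensus, metrics = metrics,
                 stats = stats_out, summary = summary, out_dir = out_dir))
}
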