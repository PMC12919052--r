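#' Simulate a full synthetic cohort
#'
#' Convenience wrapper wiring the generators together: one surface, one
#' planted group partition, per-subject individual partitions (shared across
#' a subject's sessions), and per-session BOLD + motion. Optionally the
#' planted within-network correlation grows linearly with age
#' (`r_w + age_effect * (age - mean age)`), planting a developmental signal
#' in true-network FC for the age-prediction analyses.
#'
#' @param n_subjects number of subjects.
#' @param sessions_per_subject sessions per subject (timepoints Y2, Y3, ...).
#' @param n_vertices,n_parcels surface size.
#' @param k_true planted network count.
#' @param r_w,r_b planted within/between-network FC.
#' @param flip_rate,boundary_bias individual-deviation process.
#' @param n_frames,tr,noise_sd,p_high session simulation parameters.
#' @param age_range subject base ages drawn uniformly in this range (years);
#'   later timepoints add one year each.
#' @param age_effect slope of r_w on age (0 = none).
#' @param seed master seed; all per-subject/session seeds derive from it.
#' @return list: `surface`, `truth`, `partitions` (per subject),
#'   `sessions` (named `subject.timepoint`), `meta` (data.frame).
#' @export
simulate_cohort <- function(n_subjects = 10, sessions_per_subject = 1,
                            n_vertices = 600, n_parcels = 40, k_true = 6,
                            r_w = 0.4, r_b = 0.05, flip_rate = 0.1,
                            boundary_bias = 3, n_frames = 300, tr = 0.8,
                            noise_sd = 0.5, p_high = 0.05,
                            age_range = c(2, 3), age_effect = 0, seed = 1) {
  surface <- generate_surface(n_vertices, n_parcels, seed = seed)
  truth <- plant_group_networks(surface, k_true, r_w, r_b, seed = seed)
  ages <- withr_seed(seed + 1L, {
    stats::runif(n_subjects, age_range[1], age_range[2])
  })
  subjects <- sprintf("sub%02d", seq_len(n_subjects))
  partitions <- lapply(seq_len(n_subjects), function(i) {
    derive_individual_partition(truth, flip_rate, boundary_bias,
                                seed = seed + 100L + i)
  })
  names(partitions) <- subjects

  sessions <- list()
  meta <- list()
  for (i in seq_len(n_subjects)) {
    for (j in seq_len(sessions_per_subject)) {
      age <- ages[i] + (j - 1)
      truth_ij <- truth
      if (age_effect != 0) {
        rw_ij <- r_w + age_effect * (age - mean(age_range))
        truth_ij <- plant_group_networks(surface, k_true, rw_ij, r_b,
                                         seed = seed)
      }
      tp <- paste0("Y", j + 1)
      id <- paste0(subjects[i], ".", tp)
      sessions[[id]] <- simulate_session(
        truth_ij, partitions[[i]], subject_id = subjects[i], timepoint = tp,
        age = age, n_frames = n_frames, tr = tr, noise_sd = noise_sd,
        p_high = p_high, seed = seed + 1000L + i * 10L + j)
      meta[[id]] <- data.frame(
        session_id = id, subject_id = subjects[i], timepoint = tp,
        age = age, mean_fd = sessions[[id]]$mean_fd,
        n_retained = sum(sessions[[id]]$censor_mask),
        stringsAsFactors = FALSE)
    }
  }
  list(surface = surface, truth = truth, partitions = partitions,
       sessions = sessions, meta = do.call(rbind, meta))
}
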