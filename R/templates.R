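#' Concatenate parcel-wise FC profiles across sessions
#'
#' Each parcel of each session contributes one sample: its row of the
#' session's parcel-to-parcel FC matrix (self-entry = 1 retained). Parcels
#' thus serve both as samples and as features, and reproducible connectivity
#' patterns can emerge without being present in every individual.
#'
#' @param parcel_fc_list named list of P x P `parcel_fc` matrices (names =
#'   session ids).
#' @return a `profile_set`: list with `profiles` (N_sessions*P x P),
#'   `session_id`, `parcel_id` row metadata.
#' @export
build_profile_set <- function(parcel_fc_list) {
  stopifnot(length(parcel_fc_list) >= 1)
  P <- ncol(parcel_fc_list[[1]])
  if (!all(vapply(parcel_fc_list, ncol, 1L) == P)) {
    stop("all sessions must share the same parcel count P")
  }
  ids <- names(parcel_fc_list)
  if (is.null(ids)) ids <- as.character(seq_along(parcel_fc_list))
  profiles <- do.call(rbind, lapply(parcel_fc_list, unclass))
  structure(list(
    profiles = profiles,
    session_id = rep(ids, each = P),
    parcel_id = rep(seq_len(P), times = length(parcel_fc_list))
  ), class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat(sprintf("<profile_set> %d samples (%d sessions x %d parcels), %d features\n",
              nrow(x$profiles), length(unique(x$session_id)),
              ncol(x$profiles), ncol(x$profiles)))
  invisible(x)
}

# Row-standardize for correlation distance: center each row, scale to unit
# norm. Pearson r between rows == dot product of standardized rows.
.std_rows <- function(m) {
  m <- m - rowMeans(m)
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) stop("zero-variance profile row(s): ",
                          paste(utils::head(which(nrm == 0)), collapse = ", "))
  m / nrm
}

# One k-means run with correlation distance (spherical k-means on
# standardized rows): k-means++ init, Lloyd iterations with mean-direction
# centroid update. Returns labels, unit centroids, objective trace
# (sum of 1 - r; provably non-increasing).
.kmeans_corr_once <- function(z, k, max_iter = 100L) {
  n <- nrow(z)
  # k-means++ seeding on correlation distance
  centers <- matrix(0, k, ncol(z))
  i <- sample.int(n, 1L)
  centers[1, ] <- z[i, ]
  if (k > 1) {
    d2 <- (1 - drop(z %*% centers[1, ]))^2
    for (j in 2:k) {
      d2 <- pmax(d2, 0)
      i <- if (sum(d2) <= 0) sample.int(n, 1L) else
        sample.int(n, 1L, prob = d2)
      centers[j, ] <- z[i, ]
      if (j < k) d2 <- pmin(d2, (1 - drop(z %*% centers[j, ]))^2)
    }
  }
  labels <- integer(n)
  obj <- numeric(0)
  for (iter in seq_len(max_iter)) {
    sim <- z %*% t(centers)                       # n x k correlations
    new_labels <- max.col(sim, ties.method = "first")
    obj <- c(obj, sum(1 - sim[cbind(seq_len(n), new_labels)]))
    if (iter > 1 && all(new_labels == labels)) break
    labels <- new_labels
    agg <- rowsum(z, labels)
    present <- as.integer(rownames(agg))
    centers <- matrix(0, k, ncol(z))
    centers[present, ] <- agg
    missing <- setdiff(seq_len(k), present)
    if (length(missing)) {                        # re-seed empty clusters
      far <- order(sim[cbind(seq_len(n), labels)])[seq_along(missing)]
      centers[missing, ] <- z[far, , drop = FALSE]
    }
    nrm <- sqrt(rowSums(centers^2))
    nrm[nrm == 0] <- 1
    centers <- centers / nrm
  }
  list(labels = labels, centers = centers, objective = obj)
}

#' Cluster FC profiles into network templates
#'
#' K-means with correlation distance (1 - Pearson r), k-means++
#' initialization, best of `n_replicates` restarts by total within-cluster
#' correlation distance. Cluster centroids — the arithmetic mean FC profile
#' of each cluster's member rows — are the age-appropriate network
#' templates. Centroids are returned in canonical order (descending cluster
#' size).
#'
#' @param profile_set a `profile_set` (or a bare samples x features matrix).
#' @param k number of clusters (>= 1, <= number of samples).
#' @param n_replicates restarts (default 1000, the value used for final
#'   template estimation; stability sweeps use fewer).
#' @param seed integer seed.
#' @param max_iter Lloyd iteration cap per replicate.
#' @return a `template_set`: `k`, `centroids` (k x P mean profiles),
#'   `labels` (per-sample cluster in canonical order), `objective` (best
#'   total distance), `provenance` (seed, replicates, session ids).
#' @export
cluster_templates <- function(profile_set, k, n_replicates = 1000, seed = 1,
                              max_iter = 100L) {
  m <- if (inherits(profile_set, "profile_set")) profile_set$profiles
       else as.matrix(profile_set)
  n <- nrow(m)
  stopifnot(k >= 1, n_replicates >= 1)
  if (k > n) stop("k must not exceed the number of samples")
  z <- .std_rows(m)

  if (k == 1L) {
    ctr <- colSums(z)
    ctr <- ctr / sqrt(sum(ctr^2))
    best <- list(labels = rep(1L, n), centers = matrix(ctr, 1),
                 objective = sum(1 - drop(z %*% ctr)))
    best$objective <- c(best$objective)
  } else {
    best <- NULL
    withr_seed(seed, {
      for (rep_i in seq_len(n_replicates)) {
        fit <- .kmeans_corr_once(z, k, max_iter = max_iter)
        if (any(diff(fit$objective) > 1e-8)) {
          stop("internal error: k-means objective increased")
        }
        if (is.null(best) || min(fit$objective) < min(best$objective)) {
          best <- fit
        }
      }
    })
  }

  # canonical order: descending cluster size, ties by first appearance
  sizes <- tabulate(best$labels, k)
  if (any(sizes == 0L)) stop("empty cluster persisted across replicates")
  ord <- order(-sizes, seq_len(k))
  remap <- integer(k)
  remap[ord] <- seq_len(k)
  labels <- remap[best$labels]
  centroids <- rowsum(m, labels) / tabulate(labels, k)

  structure(list(
    k = as.integer(k),
    centroids = centroids,
    labels = labels,
    objective = min(best$objective),
    provenance = list(
      seed = seed, n_replicates = n_replicates,
      session_id = if (inherits(profile_set, "profile_set"))
        unique(profile_set$session_id) else NULL
    )
  ), class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set> K = %d, %d features, objective %.4f\n",
              x$k, ncol(x$centroids), x$objective))
  invisible(x)
}

# Nearest-centroid prediction under correlation distance.
predict_labels <- function(centroids, profiles) {
  z <- .std_rows(as.matrix(profiles))
  zc <- .std_rows(as.matrix(centroids))
  max.col(z %*% t(zc), ties.method = "first")
}

#' Split-half stability curve for selecting the number of networks
#'
#' Sessions are randomly divided into two halves `n_splits` times. For each
#' split and each K, the two halves are clustered independently; half-B
#' sample labels are then predicted from half-A centroids by maximum
#' correlation and compared (NMI) with half-B's own labels, and vice versa;
#' the two NMIs are averaged. The curve of mean NMI across splits is
#' reported with its local maxima (sweep endpoints are not eligible, since
#' a peak must decline on both sides). `chosen_k` is, by default, the local
#' maximum with the highest mean NMI, ties broken toward the higher K
#' (favoring sensitivity to finer-grained patterns); all local maxima are
#' retained so the choice is auditable. Alternative policies select the
#' highest-K local maximum above the curve's median, or the global maximum.
#'
#' @param parcel_fc_list named list of per-session `parcel_fc` matrices.
#' @param k_range integer vector of K values (default 1:40). K = 1 has NMI 0
#'   by the zero-entropy convention.
#' @param n_splits number of random splits (default 20).
#' @param seed integer seed.
#' @param n_replicates k-means restarts per (half, K) (default 5).
#' @param policy `"peak_nmi"` (default), `"highest_local_max"` or
#'   `"global_max"`.
#' @return a `stability_curve`: data.frame `curve` (k, mean_nmi, sd_nmi),
#'   `local_maxima`, `chosen_k`, `n_splits`.
#' @export
stability_curve <- function(parcel_fc_list, k_range = 1:40, n_splits = 20,
                            seed = 1, n_replicates = 5,
                            policy = c("peak_nmi", "highest_local_max",
                                       "global_max")) {
  policy <- match.arg(policy)
  n_sess <- length(parcel_fc_list)
  if (n_sess < 4) stop("need at least 4 sessions for split-half stability")
  n_half <- n_sess %/% 2
  max_samples <- n_half * ncol(parcel_fc_list[[1]])
  if (any(k_range > max_samples)) {
    stop("k_range exceeds the number of samples per half (", max_samples, ")")
  }
  ids <- names(parcel_fc_list)
  if (is.null(ids)) names(parcel_fc_list) <- ids <- as.character(seq_len(n_sess))

  nmi_mat <- matrix(NA_real_, n_splits, length(k_range))
  withr_seed(seed, {
    for (s in seq_len(n_splits)) {
      perm <- sample.int(n_sess)
      a_ids <- ids[perm[seq_len(n_half)]]
      b_ids <- ids[perm[(n_half + 1):(2 * n_half)]]
      if (length(a_ids) < 2 || length(b_ids) < 2) {
        stop("degenerate half (fewer than 2 sessions)")
      }
      ps_a <- build_profile_set(parcel_fc_list[a_ids])
      ps_b <- build_profile_set(parcel_fc_list[b_ids])
      for (j in seq_along(k_range)) {
        k <- k_range[j]
        if (k == 1L) { nmi_mat[s, j] <- 0; next }
        seed_a <- sample.int(.Machine$integer.max, 1L)
        seed_b <- sample.int(.Machine$integer.max, 1L)
        fit_a <- cluster_templates(ps_a, k, n_replicates, seed = seed_a)
        fit_b <- cluster_templates(ps_b, k, n_replicates, seed = seed_b)
        pred_b <- predict_labels(fit_a$centroids, ps_b$profiles)
        pred_a <- predict_labels(fit_b$centroids, ps_a$profiles)
        nmi_mat[s, j] <- (nmi(pred_b, fit_b$labels) +
                          nmi(pred_a, fit_a$labels)) / 2
      }
    }
  })

  curve <- data.frame(
    k = k_range,
    mean_nmi = colMeans(nmi_mat),
    sd_nmi = apply(nmi_mat, 2, stats::sd)
  )
  lm_idx <- local_maxima(curve$mean_nmi)
  chosen <- if (policy == "global_max" || length(lm_idx) == 0) {
    curve$k[which.max(curve$mean_nmi)]
  } else if (policy == "peak_nmi") {
    # the most prominent peak; ties toward the higher (finer-grained) K
    best <- lm_idx[curve$mean_nmi[lm_idx] == max(curve$mean_nmi[lm_idx])]
    max(curve$k[best])
  } else {
    eligible <- lm_idx[curve$mean_nmi[lm_idx] > stats::median(curve$mean_nmi)]
    if (length(eligible) == 0) eligible <- lm_idx
    max(curve$k[eligible])
  }
  structure(list(
    curve = curve,
    local_maxima = curve$k[lm_idx],
    chosen_k = chosen,
    n_splits = n_splits,
    nmi_by_split = nmi_mat
  ), class = "stability_curve")
}

# Indices of local maxima; a plateau counts once (its first index). The
# endpoints of the K sweep are not eligible: a peak must decline on both
# sides, which an endpoint cannot demonstrate.
local_maxima <- function(y) {
  n <- length(y)
  if (n == 1) return(1L)
  res <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && y[j + 1] == y[i]) j <- j + 1L
    if (i > 1L && j < n && y[i] > y[i - 1] && y[j] > y[j + 1]) {
      res <- c(res, i)
    }
    i <- j + 1L
  }
  res
}

#' @export
print.stability_curve <- function(x, ...) {
  cat(sprintf("<stability_curve> K in [%d, %d], %d splits; local maxima at %s; chosen K = %d\n",
              min(x$curve$k), max(x$curve$k), x$n_splits,
              paste(x$local_maxima, collapse = ", "), x$chosen_k))
  invisible(x)
}
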