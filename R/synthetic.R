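#' Plant a group-level network partition with block-structured FC
#'
#' Assigns each parcel to one of `k_true` networks and builds the planted
#' parcel-by-parcel correlation matrix: `r_w` within networks, `r_b` between,
#' 1 on the diagonal. If the requested matrix is not positive semidefinite it
#' is repaired by clipping eigenvalues at 1e-8 and renormalizing the diagonal
#' to 1; a matrix whose repair moves entries by more than 0.1 is rejected.
#'
#' Parcels are dealt to networks round-robin in parcel order, so each network
#' has members in both hemispheres and networks of nearly equal size.
#'
#' @param surface a `surface_model`.
#' @param k_true planted number of networks (<= number of parcels).
#' @param r_w,r_b planted within- and between-network correlations
#'   (`1 >= r_w > r_b >= -1`).
#' @param seed integer seed (used only to jitter the within-network profile of
#'   each network so that centroids are distinguishable even at equal `r_w`).
#' @return An object of class `synthetic_truth`: `group_partition` (parcel ->
#'   network), `parcel_cov` (planted P x P correlation matrix), `templates`
#'   (`k_true` x P planted network FC profiles = network-mean rows of
#'   `parcel_cov`), plus the planted levels.
#' @export
plant_group_networks <- function(surface, k_true, r_w = 0.4, r_b = 0.05,
                                 seed = 1) {
  stopifnot(inherits(surface, "surface_model"))
  P <- surface$n_parcels
  if (k_true > P) stop("k_true must not exceed the number of parcels")
  if (!(r_w > r_b)) stop("need r_w > r_b")
  if (r_w > 1 || r_b < -1) stop("correlations must lie in [-1, 1]")

  group_partition <- ((seq_len(P) - 1L) %% k_true) + 1L

  C <- matrix(r_b, P, P)
  for (k in seq_len(k_true)) {
    idx <- which(group_partition == k)
    C[idx, idx] <- r_w
  }
  diag(C) <- 1
  C <- repair_psd(C, max_shift = 0.1)

  templates <- t(vapply(seq_len(k_true), function(k) {
    idx <- which(group_partition == k)
    if (length(idx) == 1L) C[idx, ] else colMeans(C[idx, , drop = FALSE])
  }, numeric(P)))

  structure(list(
    group_partition = group_partition,
    parcel_cov = C,
    templates = templates,
    k_true = as.integer(k_true),
    r_w = r_w, r_b = r_b,
    surface = surface
  ), class = "synthetic_truth")
}

# Nearest-PSD repair: clip eigenvalues at eps, rebuild, renormalize diagonal
# to 1. Errors if the repair moves any entry by more than max_shift.
repair_psd <- function(C, eps = 1e-8, max_shift = Inf) {
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) >= eps) return(C)
  v <- pmax(e$values, eps)
  R <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(R))
  R <- R / tcrossprod(d)
  diag(R) <- 1
  if (max(abs(R - C)) > max_shift) {
    stop("requested correlation structure is too far from positive ",
         "semidefinite to repair (max entry shift ",
         format(max(abs(R - C)), digits = 3), ")")
  }
  R
}

#' Derive an individual vertex-level partition from the group partition
#'
#' Broadcasts the group (parcel-level) partition to vertices, then flips each
#' vertex independently to a uniformly chosen *other* network with probability
#' `flip_rate`, multiplied by `boundary_bias` (capped at 1) for border
#' vertices. A border vertex is one adjacent in vertex index (within its
#' hemisphere) to a vertex whose parcel belongs to a different network —
#' emulating the observation that individual deviations concentrate at
#' network borders.
#'
#' @param truth a `synthetic_truth`.
#' @param flip_rate baseline per-vertex deviation probability in \[0, 1\].
#' @param boundary_bias multiplicative odds for border vertices (>= 0);
#'   1 = no enrichment.
#' @param seed integer seed.
#' @return integer vector, vertex -> network in 1..k_true.
#' @export
derive_individual_partition <- function(truth, flip_rate = 0.1,
                                        boundary_bias = 1, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (flip_rate < 0 || flip_rate > 1) stop("flip_rate must be in [0, 1]")
  surface <- truth$surface
  k <- truth$k_true
  labels <- truth$group_partition[surface$parcel_label]
  if (k == 1L || flip_rate == 0) return(labels)

  border <- border_vertices(surface, truth$group_partition)
  p_flip <- ifelse(border, pmin(1, flip_rate * boundary_bias), flip_rate)

  withr_seed(seed, {
    do_flip <- stats::runif(surface$n_vertices) < p_flip
    # uniform over the k-1 other networks
    shift <- sample.int(k - 1L, sum(do_flip), replace = TRUE)
    labels[do_flip] <- ((labels[do_flip] - 1L + shift) %% k) + 1L
  })
  labels
}

# Vertices whose index-neighbour (same hemisphere) lies in a parcel of a
# different planted network.
border_vertices <- function(surface, group_partition) {
  net <- group_partition[surface$parcel_label]
  n <- surface$n_vertices
  hemi <- as.integer(surface$hemisphere)
  left_differs <- c(FALSE, net[-1] != net[-n] & hemi[-1] == hemi[-n])
  right_differs <- c(net[-n] != net[-1] & hemi[-n] == hemi[-1], FALSE)
  left_differs | right_differs
}

#' Simulate vertex-level BOLD realizing a planted covariance
#'
#' Draws latent per-parcel time series from the planted parcel covariance
#' (via its Cholesky factor), then gives each vertex the latent series of a
#' "source" parcel plus i.i.d. Gaussian noise. The source parcel is the
#' vertex's own parcel when the individual partition agrees with the group
#' partition there, otherwise a (seeded) random parcel of the vertex's
#' individual network — so each vertex correlates most strongly with parcels
#' of its own individual network, and parcel-mean series realize the planted
#' parcel covariance up to flip contamination and sampling error.
#'
#' @param truth a `synthetic_truth`.
#' @param individual_partition vertex -> network (from
#'   [derive_individual_partition()]).
#' @param n_frames number of frames (>= 10).
#' @param noise_sd per-vertex noise standard deviation (latent series have
#'   unit variance).
#' @param seed integer seed.
#' @return vertices x frames matrix.
#' @export
simulate_session_bold <- function(truth, individual_partition, n_frames,
                                  noise_sd = 0.5, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n_frames < 10) stop("n_frames must be at least 10")
  surface <- truth$surface
  if (length(individual_partition) != surface$n_vertices) {
    stop("individual_partition length does not match the surface")
  }
  C <- truth$parcel_cov
  e <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  if (e < -1e-10) stop("requested parcel covariance is not PSD")
  L <- chol(C + diag(1e-10, nrow(C)))

  net_of_parcel <- truth$group_partition
  withr_seed(seed, {
    latent <- matrix(stats::rnorm(n_frames * nrow(C)), n_frames) %*% L
    src <- surface$parcel_label
    flipped <- net_of_parcel[src] != individual_partition
    if (any(flipped)) {
      for (v in which(flipped)) {
        cand <- which(net_of_parcel == individual_partition[v])
        src[v] <- cand[sample.int(length(cand), 1L)]
      }
    }
    bold <- t(latent[, src, drop = FALSE])
    bold <- bold + noise_sd * matrix(stats::rnorm(length(bold)), nrow(bold))
  })
  bold
}

#' Simulate bursty head motion as realignment parameters
#'
#' A two-state Markov chain (persistence 0.8) toggles between a quiet state
#' (small white-noise increments) and a high-motion state (smooth drift whose
#' framewise displacement is well above threshold), so that FD computed
#' downstream exceeds 0.2 mm on approximately `p_high` of frames, in bursts.
#' Rotational columns are stored in radians (small-angle, 50 mm sphere).
#'
#' @param n_frames number of frames.
#' @param p_high stationary probability of the high-motion state in \[0, 1\].
#' @param seed integer seed.
#' @param persistence probability mass kept on the current state beyond the
#'   stationary mixing (0.8: bursts average ~1/(0.2*(1-p_high)) frames).
#' @param quiet_sd per-parameter white-noise increment SD (mm) in the quiet
#'   state; default keeps quiet FD near 0.03 mm.
#' @param high_step per-parameter drift increment (mm-equivalent) in the high
#'   state; default puts high-state FD near 0.5 mm.
#' @return list with `realignment` (frames x 6: 3 translations mm, 3
#'   rotations radians) and `state` (logical, TRUE = high motion).
#' @export
simulate_motion <- function(n_frames, p_high = 0.2, seed = 1,
                            persistence = 0.8, quiet_sd = 0.002,
                            high_step = 0.085) {
  if (p_high < 0 || p_high > 1) stop("p_high must be in [0, 1]")
  withr_seed(seed, {
    state <- logical(n_frames)
    state[1] <- stats::runif(1) < p_high
    p_hh <- persistence + (1 - persistence) * p_high
    p_lh <- (1 - persistence) * p_high
    if (n_frames > 1) {
      u <- stats::runif(n_frames - 1)
      for (t in 2:n_frames) {
        state[t] <- u[t - 1] < (if (state[t - 1]) p_hh else p_lh)
      }
    }
    if (p_high == 1) state[] <- TRUE
    if (p_high == 0) state[] <- FALSE

    inc <- matrix(stats::rnorm(n_frames * 6, sd = quiet_sd), n_frames, 6)
    if (any(state)) {
      # one random drift direction per burst; constant increments inside
      r <- rle(state)
      burst_id <- rep(seq_along(r$lengths), r$lengths)
      for (b in unique(burst_id[state])) {
        rows <- which(burst_id == b)
        dir <- stats::rnorm(6)
        dir <- dir / sum(abs(dir))
        inc[rows, ] <- inc[rows, ] + matrix(high_step * 6 * dir,
                                            length(rows), 6, byrow = TRUE)
      }
    }
    realignment <- apply(inc, 2, cumsum)
    if (n_frames == 1) realignment <- matrix(realignment, 1)
  })
  realignment[, 4:6] <- realignment[, 4:6] / 50  # mm -> radians on 50 mm sphere
  list(realignment = realignment, state = state)
}

#' Assemble a complete synthetic scan session
#'
#' Combines [simulate_session_bold()] and [simulate_motion()] with FD and
#' censoring into a `session` object satisfying all session invariants.
#'
#' @param truth a `synthetic_truth`.
#' @param individual_partition vertex -> network labels.
#' @param subject_id,timepoint,age metadata (age in years).
#' @param n_frames frames to simulate; `tr` repetition time in seconds.
#' @param noise_sd vertex noise SD; `p_high` high-motion probability.
#' @param seed integer seed.
#' @param fd_threshold,min_epoch,skip_frames censoring parameters, see
#'   [build_censor_mask()].
#' @param notch_band respiratory notch band in Hz for FD.
#' @return a `session` object (list): `bold`, `realignment`, `fd`,
#'   `censor_mask`, `mean_fd`, `tr`, metadata fields.
#' @export
simulate_session <- function(truth, individual_partition, subject_id,
                             timepoint = "Y2", age = 2, n_frames = 420,
                             tr = 0.8, noise_sd = 0.5, p_high = 0.1,
                             seed = 1, fd_threshold = 0.2, min_epoch = 3,
                             skip_frames = 5, notch_band = c(0.27, 0.5)) {
  bold <- simulate_session_bold(truth, individual_partition, n_frames,
                                noise_sd = noise_sd, seed = seed)
  mot <- simulate_motion(n_frames, p_high = p_high, seed = seed + 1L)
  fd <- compute_fd(mot$realignment, tr = tr, notch_band = notch_band)
  mask <- build_censor_mask(fd, threshold = fd_threshold,
                            min_epoch = min_epoch, skip_frames = skip_frames)
  structure(list(
    subject_id = subject_id, timepoint = timepoint, age = age,
    tr = tr, bold = bold, realignment = mot$realignment,
    fd = fd, censor_mask = mask, mean_fd = mean(fd)
  ), class = "session")
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf(
    "<session> %s/%s age %.2fy: %d vertices x %d frames, %d retained, mean FD %.3f mm\n",
    x$subject_id, x$timepoint, x$age, nrow(x$bold), ncol(x$bold),
    sum(x$censor_mask), x$mean_fd))
  invisible(x)
}

#' Generate behavior scores with a planted laterality effect
#'
#' Verbal developmental quotient (VDQ) is generated as
#' `intercept + beta_true * LI + age_slope * age + subject intercept + noise`;
#' the non-verbal quotient (NVDQ) is generated identically but with a zero
#' LI coefficient, serving as a built-in negative control. Age-equivalent
#' subscale scores consistent with the quotients are back-computed so that
#' [compute_dq()] round-trips.
#'
#' @param subjects character/integer vector, one entry per session.
#' @param li_values laterality index per session, in \[-1, 1\].
#' @param beta_true planted slope of VDQ on LI (quotient points per LI unit).
#' @param noise_sd residual SD of the quotients.
#' @param age_months chronological age per session, months.
#' @param seed integer seed.
#' @param intercept,age_slope,subject_sd nuisance structure of the quotients
#'   (defaults: mean 100, no age trend, subject SD 5 — DQ scores are
#'   age-normalized, so no systematic age slope is planted by default).
#' @return data.frame with subject_id, age_months, AE subscale scores (GM,
#'   FM, VR, RL, EL), VDQ, NVDQ, li.
#' @export
generate_behavior <- function(subjects, li_values, beta_true = 10,
                              noise_sd = 5, age_months, seed = 1,
                              intercept = 100, age_slope = 0,
                              subject_sd = 5) {
  n <- length(subjects)
  stopifnot(length(li_values) == n, length(age_months) == n)
  if (any(abs(li_values) > 1)) stop("li_values must be in [-1, 1]")
  withr_seed(seed, {
    subj <- as.character(subjects)
    u <- stats::rnorm(length(unique(subj)), sd = subject_sd)
    names(u) <- unique(subj)
    vdq <- intercept + beta_true * li_values + age_slope * age_months +
      u[subj] + stats::rnorm(n, sd = noise_sd)
    nvdq <- intercept + 0 * li_values + age_slope * age_months +
      u[subj] + stats::rnorm(n, sd = noise_sd)
  })
  # back out AE scores consistent with the quotients (RL = EL, VR = FM)
  rl <- vdq * age_months / 100
  vr <- nvdq * age_months / 100
  data.frame(
    subject_id = as.character(subjects),
    age_months = age_months,
    age_years = age_months / 12,
    GM = vr, FM = vr, VR = vr, RL = rl, EL = rl,
    VDQ = vdq, NVDQ = nvdq, li = li_values,
    stringsAsFactors = FALSE
  )
}
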