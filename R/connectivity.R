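#' Framewise displacement from realignment parameters
#'
#' FD is the L1 norm of the backward-differenced, notch-filtered six
#' rigid-body realignment parameters, with rotations converted to arc length
#' on a 50 mm sphere before summing and the FD of the first frame set to 0 by
#' convention. The notch (a second-order Butterworth bandstop applied
#' forward-backward, i.e. zero-phase) suppresses respiration-band artifact
#' that inflates apparent motion in fast-TR infant data.
#'
#' @param realignment frames x 6 matrix: columns 1-3 translations (mm),
#'   columns 4-6 rotations (radians).
#' @param tr repetition time, seconds.
#' @param notch_band length-2 band (low, high) in Hz with
#'   `low < high < 1/(2 tr)`; `NULL` disables filtering.
#' @param head_radius sphere radius (mm) for rotation-to-arc-length
#'   conversion.
#' @return numeric vector of per-frame FD in mm; `fd[1] == 0`.
#' @examples
#' mot <- simulate_motion(300, p_high = 0.2, seed = 1)
#' fd <- compute_fd(mot$realignment, tr = 0.8, notch_band = c(0.27, 0.5))
#' @export
compute_fd <- function(realignment, tr = 0.8, notch_band = c(0.27, 0.5),
                       head_radius = 50) {
  realignment <- as.matrix(realignment)
  if (ncol(realignment) != 6L) stop("realignment must have 6 columns")
  n <- nrow(realignment)
  if (n < 2L) stop("need at least 2 frames")
  params <- realignment
  params[, 4:6] <- params[, 4:6] * head_radius
  if (!is.null(notch_band)) {
    if (n < 12L) stop("need at least 12 frames for notch-filter warm-up")
    fs <- 1 / tr
    if (!(notch_band[1] < notch_band[2] && notch_band[2] < fs / 2)) {
      stop("notch_band must satisfy low < high < Nyquist (", fs / 2, " Hz)")
    }
    coef <- butter_bandstop2(notch_band[1], notch_band[2], fs)
    # center first: FD uses differences only, and demeaning makes the
    # filter's edge transients identical under constant parameter offsets
    params <- sweep(params, 2, colMeans(params))
    params <- apply(params, 2, filtfilt2, b = coef$b, a = coef$a)
  }
  d <- diff(params)
  c(0, rowSums(abs(d)))
}

# Second-order Butterworth bandstop (notch) via bilinear transform with
# prewarping; returns biquad coefficients b (numerator), a (denominator).
butter_bandstop2 <- function(f1, f2, fs) {
  w1 <- tan(pi * f1 / fs)
  w2 <- tan(pi * f2 / fs)
  w02 <- w1 * w2
  bw <- w2 - w1
  a0 <- 1 + bw + w02
  list(
    b = c(1 + w02, 2 * (w02 - 1), 1 + w02) / a0,
    a = c(1, 2 * (w02 - 1) / a0, (1 - bw + w02) / a0)
  )
}

# Zero-phase IIR filtering: odd reflection padding, forward pass, backward
# pass, trim. Biquad-only (length-3 b and a).
filtfilt2 <- function(x, b, a, n_pad = 9L) {
  n <- length(x)
  n_pad <- min(n_pad, n - 1L)
  pre <- 2 * x[1] - x[seq(n_pad + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - n_pad)]
  y <- c(pre, x, post)
  y <- iir2(y, b, a)
  y <- rev(iir2(rev(y), b, a))
  y[n_pad + seq_len(n)]
}

iir2 <- function(x, b, a) {
  n <- length(x)
  y <- numeric(n)
  y[1] <- b[1] * x[1]
  if (n > 1) y[2] <- b[1] * x[2] + b[2] * x[1] - a[2] * y[1]
  if (n < 3) return(y)
  for (t in 3:n) {
    y[t] <- b[1] * x[t] + b[2] * x[t - 1] + b[3] * x[t - 2] -
      a[2] * y[t - 1] - a[3] * y[t - 2]
  }
  y
}

#' Build a motion-censoring frame mask
#'
#' Retains exactly the frames that (i) come after the first `skip_frames`
#' frames, (ii) have `fd < threshold`, and (iii) belong to a run of at least
#' `min_epoch` consecutive such frames.
#'
#' @param fd per-frame framewise displacement, mm.
#' @param threshold censoring threshold, mm (default 0.2).
#' @param min_epoch minimum run length of retained frames (default 3).
#' @param skip_frames number of initial frames always dropped (default 5).
#' @return logical vector, TRUE = retained. Empty retention is valid.
#' @examples
#' build_censor_mask(c(0.1, 0.15, 0.25, 0.1, 0.1, 0.1, 0.1),
#'                   threshold = 0.2, min_epoch = 3, skip_frames = 0)
#' @export
build_censor_mask <- function(fd, threshold = 0.2, min_epoch = 3,
                              skip_frames = 5) {
  stopifnot(threshold > 0, min_epoch >= 1, skip_frames >= 0)
  ok <- fd < threshold
  if (skip_frames > 0) ok[seq_len(min(skip_frames, length(fd)))] <- FALSE
  r <- rle(ok)
  r$values <- r$values & r$lengths >= min_epoch
  inverse.rle(r)
}

#' Mean BOLD time series per parcel
#'
#' Unweighted mean over the vertices of each parcel, restricted to retained
#' (censored-in) frames.
#'
#' @param session a `session` (or any list with `bold` and `censor_mask`).
#' @param surface the matching `surface_model`.
#' @param apply_censor drop censored frames first (default TRUE).
#' @return P x retained-frames matrix.
#' @export
parcel_timeseries <- function(session, surface, apply_censor = TRUE) {
  stopifnot(nrow(session$bold) == surface$n_vertices)
  counts <- tabulate(surface$parcel_label, surface$n_parcels)
  if (any(counts == 0L)) {
    stop("parcel(s) with zero vertices: ",
         paste(which(counts == 0L), collapse = ", "))
  }
  bold <- session$bold
  if (apply_censor) bold <- bold[, session$censor_mask, drop = FALSE]
  agg <- rowsum(bold, group = surface$parcel_label, reorder = TRUE)
  agg / counts
}

#' Parcel-to-parcel functional connectivity
#'
#' Pearson correlation between parcel-mean BOLD series. No Fisher transform
#' and no thresholding are applied.
#'
#' @param pts P x frames matrix from [parcel_timeseries()].
#' @return P x P correlation matrix (class `parcel_fc`): symmetric, unit
#'   diagonal.
#' @export
parcel_fc <- function(pts) {
  if (ncol(pts) < 2L) stop("need at least 2 retained frames")
  v <- apply(pts, 1, stats::var)
  if (any(v == 0)) {
    stop("zero-variance parcel(s): ", paste(which(v == 0), collapse = ", "))
  }
  fc <- stats::cor(t(pts))
  fc <- (fc + t(fc)) / 2
  diag(fc) <- 1
  structure(fc, class = c("parcel_fc", "matrix", "array"))
}

#' Vertex-to-parcel functional connectivity
#'
#' Correlates each vertex's BOLD series with every parcel-mean series over
#' the retained frames. All connections, including weak and anticorrelated
#' values, are retained: no magnitude thresholding or distance-based
#' exclusion. A zero-variance vertex yields a row of NA (the vertex is kept
#' to preserve indexing) and is reported via the `n_undefined` attribute.
#'
#' @param session a `session`.
#' @param surface the matching `surface_model`.
#' @return V x P correlation matrix with attribute `n_undefined`.
#' @export
vertex_parcel_fc <- function(session, surface) {
  pts <- parcel_timeseries(session, surface)
  bold <- session$bold[, session$censor_mask, drop = FALSE]
  if (ncol(bold) < 2L) stop("need at least 2 retained frames")
  vv <- rowvar(bold)
  pv <- rowvar(pts)
  if (any(pv == 0)) {
    stop("zero-variance parcel(s): ", paste(which(pv == 0), collapse = ", "))
  }
  bad <- vv == 0
  fc <- matrix(NA_real_, nrow(bold), nrow(pts))
  if (any(!bad)) {
    fc[!bad, ] <- stats::cor(t(bold[!bad, , drop = FALSE]), t(pts))
  }
  if (any(bad)) {
    message(sum(bad), " zero-variance vertex row(s) set to NA")
  }
  attr(fc, "n_undefined") <- sum(bad)
  fc
}

rowvar <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  (rowSums(m^2) - n * mu^2) / (n - 1)
}
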