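test_that("FD is the L1 norm of differenced parameters", {
  # single translation column whose successive differences are known
  diffs <- c(0.1, -0.1, 0.05, 0, 0, 0.05)
  re <- matrix(0, 7, 6)
  re[, 1] <- cumsum(c(0, diffs))
  fd <- compute_fd(re, tr = 0.8, notch_band = NULL)
  expect_equal(fd, c(0, abs(diffs)))
  expect_equal(sum(fd), 0.3)

  # constant series: zero FD everywhere, filtered or not
  re2 <- matrix(rep(c(1, -2, 0.5, 0.01, -0.02, 0.03), each = 50), 50, 6)
  expect_equal(compute_fd(re2, 0.8, NULL), rep(0, 50))
  expect_equal(compute_fd(re2, 0.8, c(0.27, 0.5)), rep(0, 50), tolerance = 1e-10)
})

test_that("rotations contribute as arc length on a 50 mm sphere", {
  re <- matrix(0, 3, 6)
  re[2, 4] <- 0.002  # radians
  fd <- compute_fd(re, 0.8, notch_band = NULL)
  expect_equal(fd[2], 0.002 * 50)
})

test_that("FD is invariant to constant offsets in any parameter", {
  mot <- simulate_motion(100, p_high = 0.2, seed = 3)
  fd1 <- compute_fd(mot$realignment, 0.8, c(0.27, 0.5))
  shifted <- sweep(mot$realignment, 2, c(5, -3, 1, 0.1, -0.2, 0.05), "+")
  expect_equal(compute_fd(shifted, 0.8, c(0.27, 0.5)), fd1)
})

test_that("the notch attenuates in-band motion per its frequency response", {
  # oracle: analytic |H(f)|^2 of the order-2 Butterworth bandstop (squared
  # because the filter runs forward and backward)
  bb <- netmapr:::butter_bandstop2(0.27, 0.5, 1 / 0.8)
  gain2 <- function(f, fs = 1 / 0.8) {
    z <- exp(-2i * pi * f / fs)
    abs((bb$b[1] + bb$b[2] * z + bb$b[3] * z^2) /
          (1 + bb$a[2] * z + bb$a[3] * z^2))^2
  }
  n <- 1200
  t <- (0:(n - 1)) * 0.8
  atten <- function(f_hz) {
    re <- matrix(0, n, 6)
    re[, 1] <- 0.5 * sin(2 * pi * f_hz * t)
    fd_f <- compute_fd(re, 0.8, c(0.27, 0.5))
    fd_u <- compute_fd(re, 0.8, NULL)
    mid <- 100:1100
    mean(fd_u[mid]) / mean(fd_f[mid])
  }
  expect_fraction(atten(0.35) * gain2(0.35), 1, 0.15)
  # at the filter's transmission zero the attenuation is effectively total
  f0 <- (1 / 0.8) * 2 * atan(sqrt(tan(pi * 0.27 * 0.8) *
                                    tan(pi * 0.5 * 0.8))) / (2 * pi)
  expect_gt(atten(f0), 100)
  # out-of-band low-frequency drift passes essentially unchanged
  expect_fraction(atten(0.05), 1, 0.05)
})

test_that("compute_fd validates its inputs", {
  expect_error(compute_fd(matrix(0, 5, 6), 0.8, c(0.27, 0.5)), "12 frames")
  expect_error(compute_fd(matrix(0, 50, 6), 0.8, c(0.5, 0.27)), "Nyquist")
  expect_error(compute_fd(matrix(0, 50, 4), 0.8, NULL), "6 columns")
})

test_that("censor mask applies the epoch and skip rules", {
  expect_equal(which(build_censor_mask(
    c(0.1, 0.15, 0.25, 0.1, 0.1, 0.1, 0.1), 0.2, 3, 0)), 4:7)
  expect_equal(which(build_censor_mask(rep(0.1, 10), 0.2, 3, 5)), 6:10)
  alternating <- rep(c(0.5, 0.1), 10)
  expect_equal(sum(build_censor_mask(alternating, 0.2, 3, 0)), 0)
  # empty retention is a valid output, and censoring is idempotent
  m <- build_censor_mask(c(0.1, 0.15, 0.25, 0.1, 0.1, 0.1, 0.1), 0.2, 3, 0)
  sess <- list(bold = matrix(1:14, 2), censor_mask = m)
  once <- sess$bold[, m]
  again <- once[, rep(TRUE, ncol(once))]
  expect_identical(once, again)
})

test_that("parcel time series are per-parcel vertex means", {
  surf <- generate_surface(8, 4, seed = 5)
  x <- rnorm(10)
  bold <- matrix(0, 8, 10)
  for (v in 1:8) bold[v, ] <- if (surf$parcel_label[v] == 1) x else rnorm(10)
  sess <- list(bold = bold, censor_mask = rep(TRUE, 10))
  pts <- parcel_timeseries(sess, surf)
  expect_equal(unname(pts[1, ]), x)

  # two vertices with opposite series cancel
  bold2 <- bold
  vs <- which(surf$parcel_label == 2)
  bold2[vs[1], ] <- x
  bold2[vs[2], ] <- -x
  pts2 <- parcel_timeseries(list(bold = bold2, censor_mask = rep(TRUE, 10)),
                            surf)
  expect_equal(unname(pts2[2, ]), rep(0, 10))

  # brute-force oracle on a random session
  surf2 <- tiny_surface()
  bold3 <- matrix(rnorm(600 * 40), 600, 40)
  mask <- rep(c(TRUE, FALSE), 20)
  pts3 <- parcel_timeseries(list(bold = bold3, censor_mask = mask), surf2)
  oracle <- t(vapply(seq_len(40), function(p)
    colMeans(bold3[surf2$parcel_label == p, mask, drop = FALSE]),
    numeric(sum(mask))))
  expect_equal(unname(pts3), unname(oracle))
})

test_that("parcel FC is Pearson correlation with guarded degenerate input", {
  pts <- matrix(rnorm(5 * 200), 5, 200)
  pts[2, ] <- pts[1, ]
  fc <- parcel_fc(pts)
  expect_equal(fc[1, 2], 1)
  expect_equal(unname(diag(fc)), rep(1, 5))
  expect_equal(unclass(fc), t(unclass(fc)))
  # brute-force pairwise oracle
  oracle <- outer(1:5, 1:5, Vectorize(function(i, j) cor(pts[i, ], pts[j, ])))
  expect_equal(unclass(fc), oracle, tolerance = 1e-12, ignore_attr = TRUE)
  # independent long series: sampling error ~ 1/sqrt(T); the mean absolute
  # entry sits well inside 3/sqrt(T), and the max of all 15 pairs inside
  # 4/sqrt(T)
  pts2 <- matrix(rnorm(6 * 4000), 6, 4000)
  fc2 <- parcel_fc(pts2)
  off2 <- abs(fc2[row(fc2) != col(fc2)])
  expect_lt(mean(off2), 3 / sqrt(4000))
  expect_lt(max(off2), 4 / sqrt(4000))
  pts3 <- pts
  pts3[4, ] <- 7
  expect_error(parcel_fc(pts3), "4")
})

test_that("vertex-parcel FC matches a brute-force loop and flags NA rows", {
  surf <- generate_surface(30, 6, seed = 6)
  bold <- matrix(rnorm(30 * 80), 30, 80)
  sess <- list(bold = bold, censor_mask = rep(TRUE, 80))
  pts <- parcel_timeseries(sess, surf)
  vfc <- vertex_parcel_fc(sess, surf)
  for (v in c(1, 13, 30)) for (p in c(1, 6)) {
    expect_equal(vfc[v, p], cor(bold[v, ], pts[p, ]))
  }
  # vertex equal to a parcel mean correlates 1 / -1 with it
  bold2 <- bold
  bold2[5, ] <- pts[3, ]
  bold2[6, ] <- -pts[3, ]
  vfc2 <- vertex_parcel_fc(list(bold = bold2, censor_mask = rep(TRUE, 80)),
                           surf)
  expect_equal(vfc2[5, 3], 1)
  expect_equal(vfc2[6, 3], -1)
  # zero-variance vertex: NA row, kept in place, counted
  bold3 <- bold
  bold3[2, ] <- 3
  expect_message(
    vfc3 <- vertex_parcel_fc(list(bold = bold3, censor_mask = rep(TRUE, 80)),
                             surf), "zero-variance")
  expect_true(all(is.na(vfc3[2, ])))
  expect_equal(attr(vfc3, "n_undefined"), 1L)
  # unrelated vertices keep their correlations to parcels the constant
  # vertex does not belong to (its own parcel's mean series changed)
  other <- setdiff(1:6, surf$parcel_label[2])
  expect_equal(vfc3[3, other], vfc[3, other])
})
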