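test_that("plant_group_networks builds the requested block matrix", {
  truth <- tiny_truth()
  C <- truth$parcel_cov
  same <- outer(truth$group_partition, truth$group_partition, "==")
  off_diag <- row(C) != col(C)
  expect_equal(unique(C[same & off_diag]), 0.4)
  expect_equal(unique(C[!same]), 0.05)
  expect_equal(unname(diag(C)), rep(1, 40))
  expect_true(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) >=
                -1e-10)
})

test_that("k-means on noisy planted profiles recovers the planted centroids", {
  # oracle: block-average of many noisy copies of the planted rows
  truth <- tiny_truth()
  set.seed(42)
  reps <- 30
  noisy <- do.call(rbind, replicate(reps, {
    truth$parcel_cov + matrix(rnorm(40 * 40, sd = 0.05), 40)
  }, simplify = FALSE))
  oracle <- rowsum(noisy, rep(truth$group_partition, reps)) /
    tabulate(rep(truth$group_partition, reps))
  fit <- cluster_templates(noisy, 6, n_replicates = 10, seed = 1)
  # match fitted centroids to oracle rows by best correlation
  r <- cor(t(fit$centroids), t(oracle))
  expect_true(all(apply(r, 1, max) > 0.99))
})

test_that("single planted network is a valid degenerate case", {
  surf <- generate_surface(100, 10, seed = 2)
  truth <- plant_group_networks(surf, 1, 0.4, 0.05, seed = 2)
  expect_true(all(truth$group_partition == 1L))
  fit <- cluster_templates(truth$parcel_cov, 1, n_replicates = 1, seed = 1)
  expect_true(all(fit$labels == 1L))
})

test_that("non-repairable correlation structures are rejected", {
  surf <- generate_surface(100, 10, seed = 2)
  expect_error(plant_group_networks(surf, 3, r_w = 0.9, r_b = -0.9),
               "repair")
  expect_error(plant_group_networks(surf, 2, r_w = 0.1, r_b = 0.4), "r_w > r_b")
})

test_that("individual partitions deviate at the requested rate", {
  truth <- tiny_truth()
  surf <- tiny_surface()
  group_v <- truth$group_partition[surf$parcel_label]

  expect_identical(derive_individual_partition(truth, 0, 1, seed = 1),
                   group_v)

  # Monte Carlo over seeds: deviating fraction ~ Binomial(V, 0.1)
  fracs <- vapply(1:20, function(s) {
    p <- derive_individual_partition(truth, 0.1, 1, seed = s)
    mean(p != group_v)
  }, numeric(1))
  se <- sqrt(0.1 * 0.9 / (600 * 20))
  expect_fraction(mean(fracs), 0.1, 3 * se)
})

test_that("boundary bias enriches deviations at border vertices", {
  truth <- tiny_truth()
  surf <- tiny_surface()
  group_v <- truth$group_partition[surf$parcel_label]
  border <- netmapr:::border_vertices(surf, truth$group_partition)
  dev_border <- dev_interior <- n_border <- n_interior <- 0
  for (s in 1:10) {
    p <- derive_individual_partition(truth, 0.08, 5, seed = s)
    dev <- p != group_v
    dev_border <- dev_border + sum(dev[border])
    dev_interior <- dev_interior + sum(dev[!border])
    n_border <- n_border + sum(border)
    n_interior <- n_interior + sum(!border)
  }
  pt <- prop.test(c(dev_border, dev_interior), c(n_border, n_interior),
                  alternative = "greater")
  expect_lt(pt$p.value, 1e-6)
})

test_that("simulated BOLD realizes the planted parcel covariance", {
  truth <- tiny_truth()
  surf <- tiny_surface()
  group_v <- truth$group_partition[surf$parcel_label]
  bold <- simulate_session_bold(truth, group_v, n_frames = 5000,
                                noise_sd = 0.1, seed = 7)
  sess <- list(bold = bold, censor_mask = rep(TRUE, 5000))
  pfc <- parcel_fc(parcel_timeseries(sess, surf))
  same <- outer(truth$group_partition, truth$group_partition, "==")
  off <- row(pfc) != col(pfc)
  expect_fraction(mean(pfc[same & off]), 0.4, 0.03)
  expect_fraction(mean(pfc[!same]), 0.05, 0.03)
})

test_that("winner-take-all on simulated vertices recovers the partition", {
  truth <- tiny_truth()
  surf <- tiny_surface()
  part <- derive_individual_partition(truth, 0.1, 3, seed = 3)
  bold <- simulate_session_bold(truth, part, n_frames = 600, noise_sd = 0.3,
                                seed = 8)
  sess <- list(bold = bold, censor_mask = rep(TRUE, 600))
  vfc <- vertex_parcel_fc(sess, surf)
  a <- match_templates(vfc, truth$templates)
  expect_gt(mean(a$labels == part), 0.95)
})

test_that("doubling the frames shrinks the empirical FC error", {
  truth <- tiny_truth()
  surf <- tiny_surface()
  group_v <- truth$group_partition[surf$parcel_label]
  err <- function(n_frames, seeds) {
    mean(vapply(seeds, function(s) {
      bold <- simulate_session_bold(truth, group_v, n_frames,
                                    noise_sd = 0.1, seed = s)
      sess <- list(bold = bold, censor_mask = rep(TRUE, n_frames))
      pfc <- parcel_fc(parcel_timeseries(sess, surf))
      mean(abs(pfc - truth$parcel_cov)[row(pfc) != col(pfc)])
    }, numeric(1)))
  }
  expect_lt(err(800, 1:5), err(400, 1:5))
})

test_that("motion simulation hits the requested high-FD occupancy", {
  mot0 <- simulate_motion(200, p_high = 0, seed = 1)
  fd0 <- compute_fd(mot0$realignment, tr = 0.8, notch_band = c(0.27, 0.5))
  mask0 <- build_censor_mask(fd0, 0.2, 3, 5)
  expect_equal(sum(mask0), 200 - 5)

  mot1 <- simulate_motion(200, p_high = 1, seed = 1)
  fd1 <- compute_fd(mot1$realignment, tr = 0.8, notch_band = c(0.27, 0.5))
  mask1 <- build_censor_mask(fd1, 0.2, 3, 5)
  expect_equal(sum(mask1), 0)
  sess <- list(bold = matrix(rnorm(20 * 200), 20), censor_mask = mask1,
               tr = 0.8)
  expect_error(split_session_half(sess), "retained")

  # occupancy: Markov-chain SE inflated by (1 + rho) / (1 - rho), rho = 0.8
  mot <- simulate_motion(10000, p_high = 0.3, seed = 2)
  fd <- compute_fd(mot$realignment, tr = 0.8, notch_band = c(0.27, 0.5))
  se <- sqrt(0.3 * 0.7 / 10000) * sqrt((1 + 0.8) / (1 - 0.8))
  expect_fraction(mean(fd > 0.2), 0.3, 3 * se)
  # bursty: runs of high motion much longer than under independence
  expect_gt(mean(rle(mot$state)$lengths[rle(mot$state)$values]), 3)
})

test_that("generate_behavior plants the stated effect structure", {
  subj <- rep(sprintf("s%d", 1:5), each = 2)
  li <- rep(c(-0.2, 0.4), 5)
  age <- rep(c(24, 36), 5)
  # beta 0, no noise: VDQ constant within subject (no age term by default)
  b0 <- generate_behavior(subj, li, beta_true = 0, noise_sd = 0,
                          age_months = age, seed = 1)
  expect_true(all(tapply(b0$VDQ, b0$subject_id,
                         function(x) diff(range(x))) == 0))
  # planted beta enters VDQ, not NVDQ
  b1 <- generate_behavior(subj, li, beta_true = 10, noise_sd = 0,
                          age_months = age, seed = 1)
  expect_equal(b1$VDQ - b0$VDQ, 10 * li)
  expect_equal(b1$NVDQ, b0$NVDQ)
  # AE scores round-trip through compute_dq
  dq <- compute_dq(b1, b1$age_months)
  expect_equal(dq$VDQ, b1$VDQ)
  expect_equal(dq$NVDQ, b1$NVDQ)
})
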