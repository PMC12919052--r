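test_that("nmi matches hand-computed and degenerate values", {
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(nmi(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)  # relabeling
  # hand computation: I = 0.311278 nats-free bits, Ha = 1, Hb = 0.811278
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 2, 2, 2)), 0.3437, tolerance = 1e-4)
  # zero-entropy conventions
  expect_equal(nmi(c(1, 2, 3, 1), rep(7, 4)), 0)
  expect_equal(nmi(rep(1, 4), rep(2, 4)), 1)
  expect_error(nmi(1:3, 1:4), "length")
  expect_error(nmi(c(NA, NA), c(1, 2)), "overlap")
})

test_that("nmi is symmetric, relabel-invariant, and drops NA pairs", {
  set.seed(3)
  for (i in 1:20) {
    a <- sample(1:5, 200, replace = TRUE)
    b <- sample(1:4, 200, replace = TRUE)
    expect_equal(nmi(a, b), nmi(b, a))
    perm <- sample(5)
    expect_equal(nmi(perm[a], b), nmi(a, b))
    a_na <- a
    a_na[1:50] <- NA
    expect_equal(nmi(a_na, b), nmi(a[-(1:50)], b[-(1:50)]))
  }
})

test_that("session halves split retained frames at the midpoint", {
  mk <- function(mask) list(bold = matrix(0, 2, length(mask)),
                            censor_mask = mask, tr = 0.8)
  mask10 <- rep(FALSE, 20)
  mask10[c(2, 4:8, 11:14)] <- TRUE  # 10 retained frames
  sp <- split_session_half(mk(mask10))
  expect_length(sp$first, 5)
  expect_length(sp$second, 5)
  expect_equal(sort(c(sp$first, sp$second)), which(mask10))
  expect_length(intersect(sp$first, sp$second), 0)

  mask11 <- mask10
  mask11[20] <- TRUE
  sp11 <- split_session_half(mk(mask11))
  expect_length(sp11$first, 6)  # odd count: extra frame to the first half
  expect_length(sp11$second, 5)
  expect_true(max(sp11$first) < min(sp11$second))
})

test_that("contiguous segments honor duration, order and censoring", {
  mask <- rep(TRUE, 400)
  sess <- list(bold = matrix(0, 2, 400), censor_mask = mask, tr = 0.8)
  seg <- extract_contiguous_segment(sess, 2.5)
  expect_equal(seg, 1:188)  # ceiling(2.5 * 60 / 0.8) = 188

  # a break forces the segment past it
  mask2 <- mask
  mask2[50] <- FALSE
  sess2 <- list(bold = matrix(0, 2, 400), censor_mask = mask2, tr = 0.8)
  seg2 <- extract_contiguous_segment(sess2, 2.5)
  expect_equal(seg2, 51:238)
  expect_true(all(sess2$censor_mask[seg2]))
  expect_equal(diff(seg2), rep(1L, 187))

  expect_error(extract_contiguous_segment(sess, 20), "insufficient")
  expect_error(extract_contiguous_segment(sess, -1), "positive")
})

test_that("reliability table pairs subjects as specified", {
  ch <- small_cohort()
  halves <- lapply(ch$sessions, function(s) {
    sp <- split_session_half(s)
    lapply(sp, function(fr) match_templates(
      vertex_parcel_fc(subset_session_frames(s, fr), ch$surface),
      ch$truth$templates))
  })
  subj <- vapply(ch$sessions, function(s) s$subject_id, "")
  a1 <- lapply(halves, `[[`, "first")
  a2 <- lapply(halves, `[[`, "second")
  names(a1) <- names(a2) <- subj
  rt <- reliability_matrix(a1, a2)
  n <- length(subj)
  expect_equal(sum(rt$comparison_type == "split_within"), n)
  expect_equal(sum(rt$comparison_type == "split_between"), n * (n - 1))
  expect_true(all(rt$nmi >= 0 & rt$nmi <= 1))
  # planted individual deviations: within > between
  expect_gt(mean(rt$nmi[rt$comparison_type == "split_within"]),
            mean(rt$nmi[rt$comparison_type == "split_between"]))

  # missing pair member: skipped with a message
  expect_message(rt2 <- reliability_matrix(a1, a2[-1]), "skipping")
  expect_equal(sum(rt2$comparison_type == "split_within"), n - 1)
})

test_that("identical subjects give within approximately equal to between", {
  # flip_rate 0: all subjects share the group partition, so between-subject
  # NMI matches within-subject NMI up to sampling noise
  ch <- simulate_cohort(n_subjects = 4, n_vertices = 600, n_parcels = 40,
                        flip_rate = 0, n_frames = 400, noise_sd = 0.4,
                        p_high = 0, seed = 31)
  halves <- lapply(ch$sessions, function(s) {
    sp <- split_session_half(s)
    lapply(sp, function(fr) match_templates(
      vertex_parcel_fc(subset_session_frames(s, fr), ch$surface),
      ch$truth$templates)$labels)
  })
  subj <- vapply(ch$sessions, function(s) s$subject_id, "")
  a1 <- lapply(halves, `[[`, "first")
  a2 <- lapply(halves, `[[`, "second")
  names(a1) <- names(a2) <- subj
  rt <- reliability_matrix(a1, a2)
  w <- mean(rt$nmi[rt$comparison_type == "split_within"])
  b <- mean(rt$nmi[rt$comparison_type == "split_between"])
  expect_lt(abs(w - b), 0.05)
})

test_that("permutation null matches the analytic expectation", {
  # analytic oracle: E[MI] under random permutation ~ (Ka-1)(Kb-1)/(2N)
  # nats (hypergeometric model), normalized by the mean entropy
  set.seed(4)
  n <- 20000
  a <- sample(rep_len(1:8, n))
  b <- sample(rep_len(1:8, n))
  pn <- permutation_null(a, b, n_perm = 200, seed = 5)
  analytic <- (7 * 7) / (2 * n) / log(8)
  expect_fraction(pn$mean, analytic, 0.25 * analytic)
  expect_true(pn$interval[1] < pn$mean & pn$mean < pn$interval[2])
  # identical pair: unpermuted NMI is 1, null stays tiny
  pn2 <- permutation_null(a, a, n_perm = 100, seed = 6)
  expect_equal(nmi(a, a), 1)
  expect_lt(pn2$mean, 0.01)
  # determinism
  pn3 <- permutation_null(a, b, n_perm = 200, seed = 5)
  expect_identical(pn$nmi_null, pn3$nmi_null)
  expect_error(permutation_null(a, b, n_perm = 10), "100")
})
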