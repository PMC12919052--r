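#' Normalized mutual information between two labelings
#'
#' Mutual information normalized by the arithmetic mean of the two marginal
#' entropies, `NMI = 2 I(A;B) / (H(A) + H(B))`. Invariant to label renaming
#' and symmetric in its arguments; equals 1 iff the partitions are identical
#' up to relabeling. Zero-entropy convention: if either partition has a
#' single cluster, NMI is 0 unless both are single-cluster (identical
#' trivial partitions), in which case it is 1. Pairs where either label is
#' NA are dropped.
#'
#' @param labels_a,labels_b equal-length label vectors (any atomic type).
#' @return NMI in \[0, 1\].
#' @examples
#' nmi(c(1, 1, 2, 2), c(1, 2, 2, 2))  # 0.3437
#' @export
nmi <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("labelings differ in length")
  keep <- !is.na(labels_a) & !is.na(labels_b)
  if (!any(keep)) stop("no overlapping labeled elements")
  a <- as.integer(factor(labels_a[keep]))
  b <- as.integer(factor(labels_b[keep]))
  n <- length(a)
  ka <- max(a); kb <- max(b)
  joint <- tabulate(a + ka * (b - 1L), ka * kb) / n
  pa <- tabulate(a, ka) / n
  pb <- tabulate(b, kb) / n
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  pij <- joint[joint > 0]
  outer_p <- outer(pa, pb)[joint > 0]
  mi <- sum(pij * log(pij / outer_p))
  mi <- max(0, mi)
  min(1, 2 * mi / (ha + hb))
}

#' Split a session's retained frames into first and second halves
#'
#' Retained (censored-in) frames are split at the midpoint in acquisition
#' order; an odd count gives the extra frame to the first half.
#'
#' @param session a `session`.
#' @return list of two integer vectors of frame indices (`first`, `second`);
#'   their union is the retained set and their intersection is empty.
#' @export
split_session_half <- function(session) {
  retained <- which(session$censor_mask)
  if (length(retained) < 2) stop("need at least 2 retained frames to split")
  n1 <- ceiling(length(retained) / 2)
  list(first = retained[seq_len(n1)],
       second = retained[(n1 + 1):length(retained)])
}

#' Extract the earliest contiguous low-motion segment of a given duration
#'
#' Finds the earliest run of consecutive retained frames whose length is at
#' least `ceiling(minutes * 60 / tr)` frames (rounding up guarantees at
#' least the requested duration) and truncates it to exactly that length.
#'
#' @param session a `session`.
#' @param minutes requested duration (> 0).
#' @return integer vector of frame indices.
#' @export
extract_contiguous_segment <- function(session, minutes) {
  if (minutes <= 0) stop("minutes must be positive")
  need <- as.integer(ceiling(minutes * 60 / session$tr))
  r <- rle(session$censor_mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= need)
  if (length(ok) == 0) {
    stop("insufficient data: no contiguous low-motion segment of ",
         minutes, " minutes (", need, " frames) exists")
  }
  starts[ok[1]] + seq_len(need) - 1L
}

#' Re-map a session restricted to a frame subset
#'
#' Convenience for reliability analyses: returns a copy of the session whose
#' censor mask retains only `frames` (which must already be censored-in).
#'
#' @param session a `session`.
#' @param frames integer frame indices.
#' @return a `session`.
#' @export
subset_session_frames <- function(session, frames) {
  stopifnot(all(session$censor_mask[frames]))
  out <- session
  out$censor_mask <- rep(FALSE, length(session$censor_mask))
  out$censor_mask[frames] <- TRUE
  out
}

#' Within- and between-subject reliability table
#'
#' Pairs each subject's two designated assignments (split halves or
#' longitudinal timepoints) for the within rows, and each subject's first
#' element with every *other* subject's second element for the between rows
#' (all ordered cross pairs), computing NMI for each pair.
#'
#' @param assignments_1,assignments_2 named lists of `vertex_assignment`s
#'   (names = subject ids); element i of each list is the subject's first /
#'   second half (or Y2 / Y3 session).
#' @param comparison_type label pair such as `c("split_within",
#'   "split_between")` or `c("longitudinal_within", "longitudinal_between")`.
#' @return a data.frame (`reliability_table`): subject_i, subject_j,
#'   comparison_type, nmi. Subjects missing from either list are skipped
#'   with a message.
#' @export
reliability_matrix <- function(assignments_1, assignments_2,
                               comparison_type = c("split_within",
                                                   "split_between")) {
  subjects <- intersect(names(assignments_1), names(assignments_2))
  dropped <- setdiff(union(names(assignments_1), names(assignments_2)),
                     subjects)
  if (length(dropped)) {
    message("skipping subject(s) missing a pair member: ",
            paste(dropped, collapse = ", "))
  }
  if (length(subjects) < 2) stop("need at least 2 complete subjects")
  lab <- function(a) if (inherits(a, "vertex_assignment")) a$labels else a
  rows <- list()
  for (s in subjects) {
    rows[[length(rows) + 1L]] <- data.frame(
      subject_i = s, subject_j = s, comparison_type = comparison_type[1],
      nmi = nmi(lab(assignments_1[[s]]), lab(assignments_2[[s]])),
      stringsAsFactors = FALSE)
  }
  for (s in subjects) for (t in subjects) if (s != t) {
    rows[[length(rows) + 1L]] <- data.frame(
      subject_i = s, subject_j = t, comparison_type = comparison_type[2],
      nmi = nmi(lab(assignments_1[[s]]), lab(assignments_2[[t]])),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("reliability_table", "data.frame")
  out
}

#' Permutation null distribution of NMI
#'
#' Randomly permutes the vertex order of `labels_b` (preserving cluster
#' sizes) and recomputes NMI against `labels_a` for each draw. Under the
#' null of no spatial correspondence the expected NMI is approximately
#' `(K_a - 1)(K_b - 1) / (2 N)` nats divided by the mean entropy — tiny for
#' realistic N, which is why even modest observed NMI values are far outside
#' the null.
#'
#' @param labels_a,labels_b label vectors (NA pairs dropped, as in [nmi()]).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return list: `nmi_null` (all draws), `mean`, `interval` (2.5 and 97.5
#'   percentiles), `n_perm`.
#' @export
permutation_null <- function(labels_a, labels_b, n_perm = 1000, seed = 1) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  keep <- !is.na(labels_a) & !is.na(labels_b)
  a <- labels_a[keep]
  b <- labels_b[keep]
  draws <- numeric(n_perm)
  withr_seed(seed, {
    for (i in seq_len(n_perm)) draws[i] <- nmi(a, b[sample.int(length(b))])
  })
  list(nmi_null = draws,
       mean = mean(draws),
       interval = unname(stats::quantile(draws, c(0.025, 0.975))),
       n_perm = n_perm)
}
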