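#' Per-network spatial probability maps
#'
#' For each vertex and network, the fraction of sessions assigning that
#' vertex to that network. Rows sum to 1 for every vertex labeled in all
#' sessions (vertices excluded in some sessions are normalized over the
#' sessions that label them).
#'
#' @param assignments list of `vertex_assignment`s (or plain label vectors)
#'   on a shared surface.
#' @param k number of networks; inferred from the assignments if missing.
#' @return a `probability_maps` object: V x K matrix of frequencies.
#' @export
spatial_probability <- function(assignments, k = NULL) {
  labs <- lapply(assignments, function(a)
    if (inherits(a, "vertex_assignment")) a$labels else a)
  V <- unique(vapply(labs, length, 1L))
  if (length(V) != 1L) stop("assignments disagree on vertex count: ",
                            paste(unique(vapply(labs, length, 1L)),
                                  collapse = " vs "))
  if (is.null(k)) k <- max(unlist(labs), na.rm = TRUE)
  counts <- matrix(0, V, k)
  denom <- numeric(V)
  for (l in labs) {
    ok <- !is.na(l)
    counts[cbind(which(ok), l[ok])] <- counts[cbind(which(ok), l[ok])] + 1
    denom <- denom + ok
  }
  prob <- counts / pmax(denom, 1)
  prob[denom == 0, ] <- NA_real_
  structure(prob, class = c("probability_maps", "matrix", "array"))
}

#' Population consensus: modal network and agreement per vertex
#'
#' The most frequent network at each vertex across the population, with
#' agreement = the modal network's probability. Ties are broken toward the
#' lowest network index and counted.
#'
#' @param prob a `probability_maps` matrix (V x K).
#' @return a `consensus_map`: `modal_label`, `agreement`, `n_ties`.
#' @export
population_consensus <- function(prob) {
  prob <- unclass(prob)
  ok <- stats::complete.cases(prob)
  modal <- rep(NA_integer_, nrow(prob))
  agreement <- rep(NA_real_, nrow(prob))
  m <- prob[ok, , drop = FALSE]
  lab <- max.col(m, ties.method = "first")
  n_ties <- sum(rowSums(m == m[cbind(seq_len(nrow(m)), lab)]) > 1L)
  if (n_ties > 0) message(n_ties, " modal tie(s) broken toward lowest index")
  modal[ok] <- lab
  agreement[ok] <- m[cbind(seq_len(nrow(m)), lab)]
  structure(list(modal_label = modal, agreement = agreement,
                 n_ties = n_ties, k = ncol(prob)),
            class = "consensus_map")
}

#' Per-vertex versatility of network assignment
#'
#' Shannon entropy of the vertex's assignment frequencies normalized by
#' `log K`: 0 iff the vertex is unanimously assigned, 1 for a uniform spread
#' over all K networks, and strictly larger when frequency mass spreads over
#' more networks at a fixed modal frequency. (The cited versatility measure
#' is not restated by its source; normalized entropy satisfies every
#' qualitative property claimed for it and is adopted here.)
#'
#' @param prob a `probability_maps` matrix (V x K).
#' @return numeric vector of V values in \[0, 1\].
#' @export
versatility <- function(prob) {
  prob <- unclass(prob)
  k <- ncol(prob)
  if (k == 1) return(rep(0, nrow(prob)))
  h <- apply(prob, 1, function(p) {
    p <- p[!is.na(p) & p > 0]
    -sum(p * log(p))
  })
  h[!stats::complete.cases(prob)] <- NA_real_
  h / log(k)
}

#' Thresholded consensus maps
#'
#' At each threshold t, vertices whose agreement is at least t keep their
#' modal label; the rest are marked unassigned (NA). Assigned sets are
#' nested across increasing thresholds.
#'
#' @param prob a `probability_maps` matrix.
#' @param thresholds numeric vector in (0, 1\] (default the 35--75% ladder).
#' @return named list of per-vertex label vectors, one per threshold.
#' @export
threshold_consensus <- function(prob,
                                thresholds = c(0.35, 0.45, 0.55, 0.65, 0.75)) {
  stopifnot(all(thresholds > 0), all(thresholds <= 1))
  cons <- population_consensus(prob)
  out <- lapply(thresholds, function(t) {
    lab <- cons$modal_label
    lab[is.na(cons$agreement) | cons$agreement < t] <- NA_integer_
    lab
  })
  names(out) <- format(thresholds)
  out
}
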