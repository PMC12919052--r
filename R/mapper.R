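#' Winner-take-all template matching
#'
#' Assigns each vertex to the network template with the highest Pearson
#' correlation between the vertex's FC profile (its row of vertex-to-parcel
#' FC) and the template's parcel-wise centroid profile. No magnitude
#' thresholding or distance-based exclusion: weak and anticorrelated values
#' are retained. Ties at machine precision are broken toward the lowest
#' network index and counted; vertices with an undefined (NA) profile are
#' labeled `NA` (excluded) but kept to preserve indexing.
#'
#' @param vfc V x P vertex-to-parcel FC matrix.
#' @param template_set a `template_set` (or a bare K x P centroid matrix).
#' @param exclude_self_parcel if TRUE, drop each vertex's own-parcel column
#'   from both profile and templates before correlating (sensitivity flag;
#'   requires `surface`). Default FALSE: all-parcel profiles.
#' @param surface needed only when `exclude_self_parcel = TRUE`.
#' @return a `vertex_assignment`: `labels` (integer, 1..K or NA),
#'   `winner_r`, `k`, `n_ties`, `n_excluded`.
#' @examples
#' # a template matched against its own centroids returns identity labels
#' ctr <- diag(4) + 0.1
#' match_templates(ctr, ctr)$labels
#' @export
match_templates <- function(vfc, template_set, exclude_self_parcel = FALSE,
                            surface = NULL) {
  centroids <- if (inherits(template_set, "template_set"))
    template_set$centroids else as.matrix(template_set)
  vfc <- as.matrix(vfc)
  if (ncol(vfc) != ncol(centroids)) {
    stop("parcel count mismatch: profiles have ", ncol(vfc),
         " columns, templates ", ncol(centroids))
  }
  k <- nrow(centroids)
  V <- nrow(vfc)
  labels <- rep(NA_integer_, V)
  winner_r <- rep(NA_real_, V)
  n_ties <- 0L

  ok <- stats::complete.cases(vfc)
  if (!exclude_self_parcel) {
    r <- stats::cor(t(vfc[ok, , drop = FALSE]), t(centroids))
    lab <- max.col(r, ties.method = "first")
    n_ties <- sum(rowSums(r == r[cbind(seq_len(nrow(r)), lab)]) > 1L)
    labels[ok] <- lab
    winner_r[ok] <- r[cbind(seq_len(nrow(r)), lab)]
  } else {
    if (is.null(surface)) stop("exclude_self_parcel requires a surface")
    idx_ok <- which(ok)
    for (v in idx_ok) {
      keep <- setdiff(seq_len(ncol(vfc)), surface$parcel_label[v])
      r <- drop(stats::cor(vfc[v, keep], t(centroids[, keep, drop = FALSE])))
      lab <- which.max(r)
      if (sum(r == r[lab]) > 1L) n_ties <- n_ties + 1L
      labels[v] <- lab
      winner_r[v] <- r[lab]
    }
  }
  if (n_ties > 0) message(n_ties, " tie(s) broken toward the lowest network index")
  structure(list(
    labels = labels, winner_r = winner_r, k = as.integer(k),
    n_ties = n_ties, n_excluded = sum(!ok)
  ), class = "vertex_assignment")
}

#' @export
print.vertex_assignment <- function(x, ...) {
  cat(sprintf("<vertex_assignment> %d vertices, K = %d, %d excluded, %d tie(s)\n",
              length(x$labels), x$k, x$n_excluded, x$n_ties))
  invisible(x)
}
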