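#' Mean within-network FC per network
#'
#' Operationalized at the vertex x parcel level: for each network, the mean
#' of vertex-to-parcel FC entries between the vertices assigned to that
#' network and the parcels whose member vertices are majority-assigned to
#' it. Networks with no member vertices or no majority parcel are flagged
#' NA.
#'
#' @param vfc V x P vertex-to-parcel FC matrix for one session.
#' @param labels per-vertex network labels (a `vertex_assignment`, a
#'   `consensus_map`, or an integer vector) defining the topography —
#'   individualized or group consensus.
#' @param surface the `surface_model` (for parcel membership).
#' @param k number of networks; inferred if missing.
#' @return numeric vector of length K (NA where flagged).
#' @export
within_network_fc <- function(vfc, labels, surface, k = NULL) {
  if (inherits(labels, "vertex_assignment")) labels <- labels$labels
  if (inherits(labels, "consensus_map")) labels <- labels$modal_label
  stopifnot(length(labels) == nrow(vfc),
            surface$n_vertices == nrow(vfc))
  if (is.null(k)) k <- max(labels, na.rm = TRUE)
  # majority network of each parcel under this topography
  parcel_net <- vapply(seq_len(surface$n_parcels), function(p) {
    l <- labels[surface$parcel_label == p]
    l <- l[!is.na(l)]
    if (length(l) == 0) return(NA_integer_)
    counts <- tabulate(l, k)
    which.max(counts)
  }, integer(1))
  out <- rep(NA_real_, k)
  for (net in seq_len(k)) {
    vs <- which(!is.na(labels) & labels == net)
    ps <- which(!is.na(parcel_net) & parcel_net == net)
    if (length(vs) < 2 || length(ps) == 0) next  # no pairs: flagged
    out[net] <- mean(vfc[vs, ps], na.rm = TRUE)
  }
  if (anyNA(out)) {
    message("within-network FC flagged missing for network(s): ",
            paste(which(is.na(out)), collapse = ", "))
  }
  out
}

#' Surface-area laterality index per network
#'
#' `LI = (area_left - area_right) / (area_left + area_right)` using the sum
#' of per-vertex surface areas of the vertices assigned to each network in
#' each hemisphere. +1 means fully left-lateralized. Networks with zero
#' total area are flagged with `LI = NA`.
#'
#' @param assignment a `vertex_assignment` or label vector.
#' @param surface the `surface_model` providing hemisphere and areas.
#' @param k number of networks; inferred if missing.
#' @return data.frame: network, area_left, area_right (mm^2), li.
#' @export
laterality_index <- function(assignment, surface, k = NULL) {
  labels <- if (inherits(assignment, "vertex_assignment")) assignment$labels
            else assignment
  stopifnot(length(labels) == surface$n_vertices)
  if (is.null(k)) k <- max(labels, na.rm = TRUE)
  left <- surface$hemisphere == "left"
  al <- ar <- numeric(k)
  for (net in seq_len(k)) {
    in_net <- !is.na(labels) & labels == net
    al[net] <- sum(surface$vertex_area[in_net & left])
    ar[net] <- sum(surface$vertex_area[in_net & !left])
  }
  tot <- al + ar
  li <- ifelse(tot > 0, (al - ar) / tot, NA_real_)
  data.frame(network = seq_len(k), area_left = al, area_right = ar, li = li)
}

#' Silhouette index under correlation distance
#'
#' For each sample, `a` is the mean correlation distance (1 - r) to all
#' other samples of its assigned cluster, `b` the mean distance to the
#' samples of the best (closest) alternative cluster, and
#' `SI = (b - a) / max(a, b)` in \[-1, 1\]; positive when the sample sits
#' closer to its own cluster. Singleton clusters take `a = 0` (self
#' distance), the standard convention.
#'
#' @param profiles samples x features matrix (FC profiles).
#' @param labels per-sample cluster labels (>= 2 clusters).
#' @return data.frame with per-sample a, b, si plus attribute
#'   `cluster_means` (mean SI per cluster).
#' @export
silhouette_index <- function(profiles, labels) {
  profiles <- as.matrix(profiles)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) stop("silhouette requires at least 2 clusters")
  n <- nrow(profiles)
  d <- 1 - stats::cor(t(profiles))
  a <- b <- numeric(n)
  sizes <- tabulate(labels, k)
  for (i in seq_len(n)) {
    own <- labels[i]
    mean_d <- vapply(seq_len(k), function(c2) {
      members <- which(labels == c2)
      members <- setdiff(members, i)
      if (length(members) == 0) return(NA_real_)
      mean(d[i, members])
    }, numeric(1))
    a[i] <- if (sizes[own] == 1L) 0 else mean_d[own]
    b[i] <- min(mean_d[-own], na.rm = TRUE)
  }
  si <- ifelse(pmax(a, b) > 0, (b - a) / pmax(a, b), 0)
  out <- data.frame(sample = seq_len(n), cluster = labels, a = a, b = b,
                    si = si)
  attr(out, "cluster_means") <- tapply(si, labels, mean)
  out
}

#' Network similarity: spatial overlap times FC similarity
#'
#' Spatial overlap of a network with a prior network is the probability-
#' weighted conditional overlap `sum(p * q) / sum(p)` over vertices, where p
#' is the network's spatial probability map and q the prior's; FC similarity
#' is the Pearson correlation of the two parcel-wise FC profiles; the
#' overall similarity is their product. Zero-mass networks are flagged NA.
#'
#' @param prob_maps V x K probability maps of the networks.
#' @param prior_prob_maps V x K' probability maps of the priors (same vertex
#'   space).
#' @param network_fc K x P network FC profiles (e.g. template centroids).
#' @param prior_fc K' x P prior FC profiles (same parcel space).
#' @return list of K x K' matrices: `spatial_overlap`, `fc_similarity`,
#'   `overall`.
#' @export
network_similarity <- function(prob_maps, prior_prob_maps,
                               network_fc, prior_fc) {
  p <- unclass(prob_maps); q <- unclass(prior_prob_maps)
  if (nrow(p) != nrow(q)) stop("probability maps disagree on vertex count")
  if (ncol(network_fc) != ncol(prior_fc)) {
    stop("FC profiles disagree on parcel count")
  }
  if (ncol(p) != nrow(network_fc) || ncol(q) != nrow(prior_fc)) {
    stop("network count mismatch between maps and FC profiles")
  }
  mass <- colSums(p, na.rm = TRUE)
  overlap <- crossprod(replace(p, is.na(p), 0),
                       replace(q, is.na(q), 0)) / ifelse(mass > 0, mass, NA)
  fc_sim <- stats::cor(t(network_fc), t(prior_fc))
  list(spatial_overlap = overlap,
       fc_similarity = fc_sim,
       overall = overlap * fc_sim)
}
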