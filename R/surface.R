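#' Generate a synthetic two-hemisphere surface model
#'
#' Builds the vertex-level bookkeeping that real surface data (e.g. fs_LR-32k)
#' provides: a hemisphere label, a positive surface area and a parcel index per
#' vertex. Vertices are split evenly between hemispheres and parcels are
#' contiguous runs of vertex indices within a hemisphere, with mildly varying
#' sizes. No mesh geometry is simulated; "adjacency" downstream means
#' adjacency in vertex index within a hemisphere.
#'
#' @param n_vertices total number of vertices (even; at least `2 * n_parcels`).
#' @param n_parcels total number of parcels (even; split across hemispheres).
#' @param seed integer seed; the construction is a pure function of its
#'   arguments including the seed.
#' @param area_meanlog,area_sdlog log-normal parameters for per-vertex surface
#'   area in mm^2. Defaults give a median of about 2.7 mm^2, the order of
#'   magnitude of an fs_LR-32k vertex.
#' @return An object of class `surface_model`: a list with `n_vertices`,
#'   `n_parcels`, `hemisphere` (factor left/right per vertex), `vertex_area`
#'   (mm^2), `parcel_label` (integer in 1..P) and `parcel_hemisphere`.
#' @examples
#' surf <- generate_surface(2000, 40, seed = 1)
#' table(surf$hemisphere)
#' @export
generate_surface <- function(n_vertices, n_parcels, seed,
                             area_meanlog = 1, area_sdlog = 0.25) {
  stopifnot(n_vertices >= 2, n_parcels >= 2)
  if (n_parcels %% 2L != 0L) {
    stop("n_parcels must be even (parcels are split across hemispheres)")
  }
  if (n_vertices %% 2L != 0L) {
    stop("n_vertices must be even (vertices are split across hemispheres)")
  }
  if (n_parcels > n_vertices) stop("n_parcels must not exceed n_vertices")
  if (n_vertices < 2L * n_parcels) {
    stop("need n_vertices >= 2 * n_parcels so every parcel has a vertex")
  }

  n_hemi_v <- n_vertices %/% 2L
  n_hemi_p <- n_parcels %/% 2L

  withr_seed(seed, {
    hemisphere <- factor(rep(c("left", "right"), each = n_hemi_v),
                         levels = c("left", "right"))
    vertex_area <- stats::rlnorm(n_vertices, area_meanlog, area_sdlog)

    # contiguous parcels of mildly varying size within each hemisphere
    parcel_label <- integer(n_vertices)
    parcel_hemisphere <- factor(rep(c("left", "right"), each = n_hemi_p),
                                levels = c("left", "right"))
    for (h in 1:2) {
      sizes <- stats::rmultinom(1, size = n_hemi_v - n_hemi_p,
                                prob = rep(1, n_hemi_p))[, 1] + 1L
      labs <- rep(seq_len(n_hemi_p) + (h - 1L) * n_hemi_p, times = sizes)
      parcel_label[(h - 1L) * n_hemi_v + seq_len(n_hemi_v)] <- labs
    }
  })

  out <- structure(list(
    n_vertices = as.integer(n_vertices),
    n_parcels = as.integer(n_parcels),
    hemisphere = hemisphere,
    vertex_area = vertex_area,
    parcel_label = parcel_label,
    parcel_hemisphere = parcel_hemisphere
  ), class = "surface_model")
  validate_surface(out)
  out
}

#' Validate a surface model's invariants
#'
#' Checks that every vertex has a parcel label in 1..P, every area is
#' positive, every parcel has at least one vertex, and each parcel's vertices
#' lie in exactly one hemisphere.
#'
#' @param surface a `surface_model`.
#' @return `surface`, invisibly; errors otherwise.
#' @export
validate_surface <- function(surface) {
  stopifnot(inherits(surface, "surface_model"))
  p <- surface$parcel_label
  if (!all(p >= 1L & p <= surface$n_parcels)) {
    stop("parcel labels out of range 1..P")
  }
  if (!all(surface$vertex_area > 0)) stop("vertex areas must be positive")
  counts <- tabulate(p, surface$n_parcels)
  if (any(counts == 0L)) {
    stop("empty parcel(s): ", paste(which(counts == 0L), collapse = ", "))
  }
  n_hemi <- tapply(surface$hemisphere, p, function(h) length(unique(h)))
  if (any(n_hemi > 1L)) stop("parcel spans both hemispheres")
  invisible(surface)
}

#' @export
print.surface_model <- function(x, ...) {
  cat(sprintf("<surface_model> %d vertices (%d left / %d right), %d parcels\n",
              x$n_vertices, sum(x$hemisphere == "left"),
              sum(x$hemisphere == "right"), x$n_parcels))
  invisible(x)
}

# Run `expr` under a seed without clobbering the caller's RNG state.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}
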