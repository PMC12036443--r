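#' Specification of a synthetic ground-truth flow
#'
#' Defines an analytic flow with known trajectories so that fitting,
#' integration, and transformation can be verified against exact answers
#' without any external data.
#'
#' @param kind `"translation"`, `"rotation"`, `"radial_expansion"`, or
#'   `"sinusoidal"`.
#' @param n_points number of base points M.
#' @param times normalized times of the K >= 2 generated sets (strictly
#'   increasing, from 0 to 1).
#' @param noise_sd standard deviation of independent per-time-point
#'   coordinate jitter (models section/annotation noise); default 0.
#' @param seed RNG seed; default 1.
#' @param translation D-vector displacement per unit time (translation kind).
#' @param angular_rate radians per unit time about the domain center, in the
#'   first two axes (rotation kind).
#' @param expansion_rate relative radial growth per unit time about the
#'   domain center, e.g. 0.1 for 10%/unit-time (radial kind).
#' @param amplitude,frequency physical amplitude and spatial frequency
#'   (cycles across the domain extent) of the sinusoidal displacement.
#' @return An object of class `flow_spec`.
#' @export
flow_spec <- function(kind = c("translation", "rotation", "radial_expansion",
                               "sinusoidal"),
                      n_points, times, noise_sd = 0, seed = 1L,
                      translation = NULL, angular_rate = NULL,
                      expansion_rate = NULL, amplitude = NULL,
                      frequency = NULL) {
  kind <- match.arg(kind)
  times <- as.double(times)
  if (length(times) < 2L || any(diff(times) <= 0) ||
      times[1] != 0 || times[length(times)] != 1) {
    stop("flow_spec: 'times' must increase strictly from 0 to 1 (K >= 2)")
  }
  if (noise_sd < 0) stop("flow_spec: 'noise_sd' must be >= 0")
  if (n_points < 1L) stop("flow_spec: 'n_points' must be >= 1")
  par <- switch(kind,
    translation = {
      if (is.null(translation)) stop("flow_spec: translation kind needs 'translation'")
      list(translation = as.double(translation))
    },
    rotation = {
      if (is.null(angular_rate)) stop("flow_spec: rotation kind needs 'angular_rate'")
      list(angular_rate = as.double(angular_rate))
    },
    radial_expansion = {
      if (is.null(expansion_rate)) stop("flow_spec: radial kind needs 'expansion_rate'")
      list(expansion_rate = as.double(expansion_rate))
    },
    sinusoidal = {
      if (is.null(amplitude) || is.null(frequency)) {
        stop("flow_spec: sinusoidal kind needs 'amplitude' and 'frequency'")
      }
      list(amplitude = as.double(amplitude), frequency = as.double(frequency))
    })
  if (any(!vapply(par, function(x) all(is.finite(x)), logical(1)))) {
    stop("flow_spec: flow magnitudes must be finite")
  }
  structure(c(list(kind = kind, n_points = as.integer(n_points), times = times,
                   noise_sd = noise_sd, seed = as.integer(seed)), par),
            class = "flow_spec")
}

flow_truth_fn <- function(spec, geometry) {
  center <- domain_center(geometry)
  b <- domain_bounds(geometry)
  extent <- b$upper - b$lower
  D <- geometry$D
  switch(spec$kind,
    translation = function(coords, t) {
      sweep(coords, 2, spec$translation * t, "+")
    },
    rotation = function(coords, t) {
      th <- spec$angular_rate * t
      rel <- sweep(coords, 2, center)
      out <- rel
      out[, 1] <- cos(th) * rel[, 1] - sin(th) * rel[, 2]
      out[, 2] <- sin(th) * rel[, 1] + cos(th) * rel[, 2]
      sweep(out, 2, center, "+")
    },
    radial_expansion = function(coords, t) {
      rel <- sweep(coords, 2, center)
      sweep(rel * (1 + spec$expansion_rate * t), 2, center, "+")
    },
    sinusoidal = function(coords, t) {
      out <- coords
      for (a in seq_len(D)) {
        drv <- coords[, (a %% D) + 1]
        lo <- b$lower[(a %% D) + 1]
        ex <- extent[(a %% D) + 1]
        out[, a] <- coords[, a] +
          t * spec$amplitude * sin(2 * pi * spec$frequency * (drv - lo) / ex)
      }
      out
    })
}

#' Generate a point-set series evolving under a known analytic flow
#'
#' Base points are drawn uniformly inside the central 60% of the domain
#' (seeded); each set is the analytic flow evaluated at one of the requested
#' times, plus independent jitter when `noise_sd > 0`.  The returned `truth`
#' function gives the exact noise-free position of any coordinates at any
#' time, for recovery tests against ground truth.
#'
#' @param spec a [flow_spec()].
#' @param geometry a [grid_geometry()].
#' @return list with `series` (a [point_set_series()]), `truth`
#'   (`function(coords, t)`), and `base` (the M x D base coordinates at t=0).
#' @export
generate_flow_series <- function(spec, geometry) {
  stopifnot(inherits(spec, "flow_spec"), inherits(geometry, "grid_geometry"))
  D <- geometry$D
  b <- domain_bounds(geometry)
  center <- domain_center(geometry)
  half <- 0.3 * (b$upper - b$lower)
  truth <- flow_truth_fn(spec, geometry)
  M <- spec$n_points
  K <- length(spec$times)
  out <- withr::with_seed(spec$seed, {
    base <- sapply(seq_len(D), function(a) runif(M, center[a] - half[a],
                                                 center[a] + half[a]))
    base <- matrix(base, ncol = D)
    sets <- vector("list", K)
    for (k in seq_len(K)) {
      pos <- truth(base, spec$times[k])
      if (any(sweep(pos, 2, b$lower) < 0) || any(sweep(pos, 2, b$upper) > 0)) {
        stop("generate_flow_series: the flow carries points outside the ",
             "domain; reduce the flow magnitude or enlarge the grid")
      }
      if (spec$noise_sd > 0) {
        pos <- pos + matrix(rnorm(M * D, sd = spec$noise_sd), ncol = D)
      }
      sets[[k]] <- point_set(pos)
    }
    list(base = base, sets = sets)
  })
  list(series = point_set_series(out$sets, spec$times), truth = truth,
       base = out$base)
}

#' Rasterize labeled geometric primitives into a label volume
#'
#' Later primitives overwrite earlier ones where they overlap.  A cube of
#' edge `size` covers voxel centers within the half-open physical interval
#' `[center - size/2, center + size/2)` per axis; a sphere covers centers
#' within radius `size` of `center`.
#'
#' @param shapes list of primitives, each a list with `label` (positive
#'   integer), `type` (`"cube"` or `"sphere"`), `center` (physical D-vector),
#'   and `size` (edge length, or radius for spheres).
#' @param geometry a [grid_geometry()].
#' @return a [label_volume()].
#' @examples
#' geom <- grid_geometry(c(20, 20, 20))
#' lv <- generate_label_volume(list(list(label = 1, type = "cube",
#'                                       center = c(9, 9, 9), size = 10)), geom)
#' @export
generate_label_volume <- function(shapes, geometry) {
  stopifnot(inherits(geometry, "grid_geometry"), is.list(shapes))
  b <- domain_bounds(geometry)
  centers <- voxel_centers(geometry)
  labels <- integer(nrow(centers))
  for (s in shapes) {
    if (is.null(s$label) || s$label < 1) {
      stop("generate_label_volume: each shape needs a positive 'label'")
    }
    ctr <- as.double(s$center)
    ext <- if (identical(s$type, "cube")) rep(s$size / 2, geometry$D) else
      rep(s$size, geometry$D)
    if (any(ctr - ext < b$lower - geometry$spacing / 2) ||
        any(ctr + ext > b$upper + geometry$spacing / 2)) {
      stop("generate_label_volume: primitive with label ", s$label,
           " extends outside the domain")
    }
    inside <- switch(s$type,
      cube = {
        rel <- sweep(centers, 2, ctr)
        ok <- rep(TRUE, nrow(centers))
        for (a in seq_len(geometry$D)) {
          ok <- ok & rel[, a] >= -s$size / 2 & rel[, a] < s$size / 2
        }
        ok
      },
      sphere = {
        rowSums(sweep(centers, 2, ctr)^2) <= s$size^2
      },
      stop("generate_label_volume: unknown primitive type '", s$type, "'"))
    labels[inside] <- as.integer(s$label)
  }
  label_volume(geometry, array(labels, dim = geometry$size))
}

#' Generate an isotropic Gaussian blob image
#'
#' Peak intensity 1 at `center`; the intensity-weighted centroid of the
#' discrete image equals `center` to within a tenth of a voxel when the blob
#' is well inside the domain.
#'
#' @param center physical D-vector.
#' @param sigma isotropic standard deviation, physical units.
#' @param geometry a [grid_geometry()].
#' @return an [image_volume()].
#' @export
generate_blob_image <- function(center, sigma, geometry) {
  stopifnot(inherits(geometry, "grid_geometry"))
  center <- as.double(center)
  b <- domain_bounds(geometry)
  if (any(center < b$lower) || any(center > b$upper)) {
    stop("generate_blob_image: 'center' must lie inside the domain")
  }
  d2 <- rowSums(sweep(voxel_centers(geometry), 2, center)^2)
  image_volume(geometry, array(exp(-d2 / (2 * sigma^2)), dim = geometry$size))
}

#' Intensity-weighted centroid of an image volume
#' @param image an [image_volume()].
#' @return physical D-vector.
#' @export
image_centroid <- function(image) {
  stopifnot(inherits(image, "image_volume"))
  w <- as.vector(image$data)
  colSums(voxel_centers(image$geometry) * w) / sum(w)
}
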