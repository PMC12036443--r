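#' Physical geometry of an axis-aligned sampling lattice
#'
#' Describes the grid on which vector fields and images live: the number of
#' voxels per axis, the physical spacing between voxel centers, and the
#' physical coordinate of the center of the first voxel.  The physical
#' position of voxel index `i` (0-based) along axis `a` is
#' `origin[a] + i * spacing[a]`.  Directions other than the axis-aligned
#' identity are not supported: the model lives in a template space where one
#' fixed orientation convention prevents half-voxel bookkeeping errors.
#'
#' @param size integer vector of length 2 or 3; voxels per axis, all >= 2.
#' @param spacing positive physical length per voxel per axis (one unit, e.g.
#'   micrometres or millimetres, used consistently throughout an analysis).
#' @param origin physical coordinate of the center of the first voxel.
#' @return An object of class `grid_geometry`.
#' @examples
#' geom <- grid_geometry(c(64, 64, 64), spacing = c(50, 50, 50))
#' @export
grid_geometry <- function(size, spacing = rep(1, length(size)),
                          origin = rep(0, length(size))) {
  size <- as.integer(size)
  D <- length(size)
  if (!D %in% c(2L, 3L)) {
    stop("grid_geometry: 'size' must have 2 or 3 axes, got ", D)
  }
  if (length(spacing) == 1L) spacing <- rep(spacing, D)
  if (length(origin) == 1L) origin <- rep(origin, D)
  spacing <- as.double(spacing)
  origin <- as.double(origin)
  if (length(spacing) != D || length(origin) != D) {
    stop("grid_geometry: 'spacing' and 'origin' must match the number of axes")
  }
  if (any(is.na(size)) || any(size < 2L)) {
    stop("grid_geometry: all sizes must be >= 2")
  }
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("grid_geometry: all spacings must be positive and finite")
  }
  if (any(!is.finite(origin))) stop("grid_geometry: origin must be finite")
  structure(list(size = size, spacing = spacing, origin = origin, D = D),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %dD, size [%s], spacing [%s], origin [%s]\n",
              x$D, paste(x$size, collapse = ", "),
              paste(format(x$spacing), collapse = ", "),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

n_voxels <- function(geometry) prod(geometry$size)

#' Physical coordinates of all voxel centers
#'
#' Row order matches R's column-major array flattening (first axis fastest),
#' so row `k` corresponds to linear array index `k`.
#'
#' @param geometry a [grid_geometry()].
#' @return numeric matrix, `prod(size)` rows by `D` columns.
#' @export
voxel_centers <- function(geometry) {
  stopifnot(inherits(geometry, "grid_geometry"))
  axes <- lapply(seq_len(geometry$D), function(a) {
    geometry$origin[a] + (seq_len(geometry$size[a]) - 1) * geometry$spacing[a]
  })
  as.matrix(do.call(expand.grid, axes))
}

#' Physical bounds of the grid domain
#'
#' @param geometry a [grid_geometry()].
#' @return list with `lower` and `upper`, the physical coordinates of the
#'   first and last voxel centers per axis.
#' @export
domain_bounds <- function(geometry) {
  list(lower = geometry$origin,
       upper = geometry$origin + (geometry$size - 1) * geometry$spacing)
}

#' Physical center of the grid domain
#' @param geometry a [grid_geometry()].
#' @return numeric vector of length `D`.
#' @export
domain_center <- function(geometry) {
  b <- domain_bounds(geometry)
  (b$lower + b$upper) / 2
}

# Clamp physical coordinates (M x D matrix) to the domain, axis by axis.
clamp_to_domain <- function(coords, geometry) {
  b <- domain_bounds(geometry)
  for (a in seq_len(geometry$D)) {
    coords[, a] <- pmin(pmax(coords[, a], b$lower[a]), b$upper[a])
  }
  coords
}

same_geometry <- function(g1, g2, tol = 1e-6) {
  g1$D == g2$D && all(g1$size == g2$size) &&
    all(abs(g1$spacing - g2$spacing) <= tol * g1$spacing) &&
    all(abs(g1$origin - g2$origin) <= tol * pmax(g1$spacing, 1))
}

as_coord_matrix <- function(coords, D) {
  if (is.null(dim(coords))) {
    coords <- matrix(coords, ncol = length(coords))
  }
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (!missing(D) && ncol(coords) != D) {
    stop("coordinate matrix has ", ncol(coords), " columns; expected ", D)
  }
  coords
}
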