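#' A spatial displacement field on a grid
#'
#' One D-vector per voxel, in physical units: the field maps the position `x`
#' of each voxel center to `x + vectors(x)`.
#'
#' @param geometry a [grid_geometry()].
#' @param vectors numeric array of dimension `c(size, D)`; defaults to zeros.
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(geometry, vectors = NULL) {
  stopifnot(inherits(geometry, "grid_geometry"))
  want <- c(geometry$size, geometry$D)
  if (is.null(vectors)) vectors <- array(0, dim = want)
  if (!is.array(vectors) || !identical(dim(vectors), as.integer(want))) {
    stop("displacement_field: 'vectors' must be an array of dim [",
         paste(want, collapse = ", "), "]")
  }
  if (any(!is.finite(vectors))) {
    stop("displacement_field: all values must be finite")
  }
  structure(list(geometry = geometry, vectors = vectors),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("<displacement_field> %dD on [%s], max |u| = %.4g\n",
              x$geometry$D, paste(x$geometry$size, collapse = ", "),
              sqrt(max(rowSums(matrix(x$vectors, ncol = x$geometry$D)^2)))))
  invisible(x)
}

#' A time-parameterized velocity field
#'
#' N time-slices of a spatial vector field, slice `i` attached to integration
#' time `tau_i = (i-1)/(N-1)` on the normalized temporal domain [0, 1].  Each
#' voxel stores a D-vector in physical units per unit normalized time.
#'
#' @param geometry a [grid_geometry()].
#' @param slices numeric array of dimension `c(size, N, D)`, or `NULL` with
#'   `n_integration_points` given to create a zero field.
#' @param n_integration_points number of time slices N (>= 2) when `slices`
#'   is `NULL`.
#' @param meta optional named list of fit metadata (step size, iterations run,
#'   convergence trace, time map); written into the JSON sidecar by
#'   [write_field()].
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(geometry, slices = NULL, n_integration_points = NULL,
                           meta = list()) {
  stopifnot(inherits(geometry, "grid_geometry"))
  if (is.null(slices)) {
    if (is.null(n_integration_points)) {
      stop("velocity_field: give 'slices' or 'n_integration_points'")
    }
    N <- as.integer(n_integration_points)
    if (N < 2L) stop("velocity_field: need at least 2 integration points")
    slices <- array(0, dim = c(geometry$size, N, geometry$D))
  }
  dims <- dim(slices)
  Dp2 <- geometry$D + 2L
  if (length(dims) != Dp2 || !identical(dims[seq_len(geometry$D)], geometry$size) ||
      dims[Dp2] != geometry$D) {
    stop("velocity_field: 'slices' must be an array of dim [size..., N, D]")
  }
  N <- dims[geometry$D + 1L]
  if (N < 2L) stop("velocity_field: need at least 2 integration points")
  if (any(!is.finite(slices))) stop("velocity_field: all values must be finite")
  structure(list(geometry = geometry, slices = slices, n_slices = N,
                 meta = meta),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("<velocity_field> %dD on [%s], N = %d integration points\n",
              x$geometry$D, paste(x$geometry$size, collapse = ", "), x$n_slices))
  invisible(x)
}

#' Integration times of a velocity field's slices
#' @param v a [velocity_field()].
#' @return numeric vector of N normalized times, uniform on [0, 1].
#' @export
integration_times <- function(v) {
  stopifnot(inherits(v, "velocity_field"))
  seq(0, 1, length.out = v$n_slices)
}

#' Extract one time slice of a velocity field
#'
#' The slice is returned as a `displacement_field`-shaped vector field; note
#' its values are velocities (physical length per unit normalized time), not
#' displacements.
#'
#' @param v a [velocity_field()].
#' @param i slice index, 1..N.
#' @return a [displacement_field()] holding the slice values.
#' @export
velocity_slice <- function(v, i) {
  stopifnot(inherits(v, "velocity_field"))
  i <- as.integer(i)
  if (i < 1L || i > v$n_slices) stop("velocity_slice: index out of range")
  nv <- n_voxels(v$geometry)
  flat <- matrix(0, nv, v$geometry$D)
  for (cc in seq_len(v$geometry$D)) {
    off <- nv * (i - 1L) + nv * v$n_slices * (cc - 1L)
    flat[, cc] <- v$slices[off + seq_len(nv)]
  }
  displacement_field(v$geometry, array(flat, c(v$geometry$size, v$geometry$D)))
}

# ---- multilinear interpolation core -----------------------------------------
#
# vals: numeric vector backing an array whose first D axes are the grid;
# base_offset: 0-based offset of the first voxel of the block to interpolate
# (e.g. a velocity slice); comp_stride: linear stride between successive
# vector components; C: number of components.  Queries outside the domain are
# clamped to the boundary, giving a continuous constant extension.
interp_core <- function(vals, geometry, queries, base_offset = 0,
                        comp_stride = NULL, C = geometry$D) {
  D <- geometry$D
  n <- geometry$size
  if (is.null(comp_stride)) comp_stride <- n_voxels(geometry)
  Q <- nrow(queries)
  i0 <- matrix(0L, Q, D)
  f <- matrix(0, Q, D)
  for (a in seq_len(D)) {
    u <- (queries[, a] - geometry$origin[a]) / geometry$spacing[a]
    u <- pmin(pmax(u, 0), n[a] - 1L)
    ia <- pmin(floor(u), n[a] - 2L)
    i0[, a] <- as.integer(ia)
    f[, a] <- u - ia
  }
  strides <- cumprod(c(1, n))[seq_len(D)]
  base <- 1 + base_offset + as.vector(i0 %*% strides)
  out <- matrix(0, Q, C)
  corners <- as.matrix(do.call(expand.grid, rep(list(0:1), D)))
  for (k in seq_len(nrow(corners))) {
    cn <- corners[k, ]
    w <- rep(1, Q)
    off <- 0
    for (a in seq_len(D)) {
      w <- w * (if (cn[a] == 1L) f[, a] else 1 - f[, a])
      off <- off + cn[a] * strides[a]
    }
    idx <- base + off
    for (cc in seq_len(C)) {
      out[, cc] <- out[, cc] + w * vals[idx + (cc - 1) * comp_stride]
    }
  }
  out
}

#' Interpolate a vector field at physical coordinates
#'
#' Multilinear interpolation of each vector component over the grid.  Queries
#' outside the domain return the value at the nearest domain-boundary position
#' (clamped), avoiding the artificial velocity discontinuities zero padding
#' would introduce at the edge during integration.
#'
#' @param field a [displacement_field()] or one [velocity_slice()].
#' @param queries numeric M x D matrix of finite physical coordinates (a
#'   single coordinate vector is also accepted).
#' @return numeric M x D matrix of interpolated vectors.
#' @examples
#' geom <- grid_geometry(c(8, 8), spacing = c(1, 1))
#' d <- displacement_field(geom)
#' interpolate_vector_field(d, c(3.5, 2.25))
#' @export
interpolate_vector_field <- function(field, queries) {
  if (!inherits(field, "displacement_field")) {
    stop("interpolate_vector_field: 'field' must be a displacement_field ",
         "(use velocity_slice() to extract one slice of a velocity field)")
  }
  queries <- as_coord_matrix(queries, field$geometry$D)
  if (any(!is.finite(queries))) {
    stop("interpolate_vector_field: queries must be finite")
  }
  interp_core(field$vectors, field$geometry, queries)
}

# ---- NIfTI + sidecar I/O ----------------------------------------------------

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}

nifti_header_for <- function(geometry, dim4, ncomp, datatype = 16L,
                             intent_code = 1007L) {
  sp3 <- c(geometry$spacing, rep(1, 3 - geometry$D))[1:3]
  or3 <- c(geometry$origin, rep(0, 3 - geometry$D))[1:3]
  sz3 <- c(geometry$size, rep(1L, 3 - geometry$D))[1:3]
  ndim <- if (ncomp > 1L) 5L else 3L
  list(dim = c(ndim, sz3, dim4, ncomp, 1L, 1L),
       pixdim = c(0, sp3, 1, 1, 0, 0),
       srow_x = c(sp3[1], 0, 0, or3[1]),
       srow_y = c(0, sp3[2], 0, or3[2]),
       srow_z = c(0, 0, sp3[3], or3[3]),
       sform_code = 2L, qform_code = 0L,
       intent_code = if (ncomp > 1L) intent_code else 0L,
       datatype = datatype)
}

geometry_from_header <- function(hdr, D) {
  grid_geometry(hdr$dim[2:(1 + D)],
                spacing = hdr$pixdim[2:(1 + D)],
                origin = c(hdr$srow_x[4], hdr$srow_y[4], hdr$srow_z[4])[seq_len(D)])
}

#' Write a displacement or velocity field as NIfTI-1
#'
#' Displacement fields are written with dims `[nx, ny, nz, 1, D]`, vector
#' components along the fifth axis and intent code "vector" — the layout
#' commonly produced by ANTs-style tools.  Velocity fields use dims
#' `[nx, ny, nz, N, D]` plus a JSON sidecar (same path, `.json` extension)
#' carrying `n_integration_points`, `times_normalized`, the fit
#' configuration, and any metadata attached to the field.  Values are stored
#' as 32-bit float.
#'
#' @param field a [displacement_field()] or [velocity_field()].
#' @param path destination `.nii` (or `.nii.gz`) path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  g <- if (inherits(field, "velocity_field")) field$geometry else field$geometry
  sz3 <- c(g$size, rep(1L, 3 - g$D))[1:3]
  if (inherits(field, "displacement_field")) {
    arr <- array(field$vectors, dim = c(sz3, 1L, g$D))
    hdr <- nifti_header_for(g, 1L, g$D)
    img <- RNifti::asNifti(arr, reference = RNifti::niftiHeader(hdr),
                           datatype = "float")
    RNifti::writeNifti(img, path)
  } else if (inherits(field, "velocity_field")) {
    N <- field$n_slices
    arr <- array(field$slices, dim = c(sz3, N, g$D))
    hdr <- nifti_header_for(g, N, g$D)
    img <- RNifti::asNifti(arr, reference = RNifti::niftiHeader(hdr),
                           datatype = "float")
    RNifti::writeNifti(img, path)
    side <- c(list(n_integration_points = N,
                   times_normalized = integration_times(field),
                   geometry = list(size = g$size, spacing = g$spacing,
                                   origin = g$origin)),
              field$meta)
    jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    stop("write_field: unsupported object of class ", class(field)[1])
  }
  invisible(path)
}

#' Read a displacement or velocity field from NIfTI-1
#'
#' A file whose fourth axis has length N > 1 is a velocity field and must be
#' accompanied by its JSON sidecar (see [write_field()]); a missing sidecar or
#' a sidecar whose `n_integration_points` or geometry disagrees with the
#' header is an error.  A fourth-axis length of 1 yields a displacement field.
#'
#' @param path `.nii` (or `.nii.gz`) path.
#' @return a [displacement_field()] or [velocity_field()].
#' @export
read_field <- function(path) {
  if (!file.exists(path)) stop("read_field: no such file: ", path)
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  dims <- dim(img)
  if (length(dims) != 5L) {
    stop("read_field: expected a 5-D vector NIfTI [nx,ny,nz,N,components], got dims [",
         paste(dims, collapse = ", "), "]")
  }
  ncomp <- dims[5]
  if (!ncomp %in% c(2L, 3L)) {
    stop("read_field: component axis must have length 2 or 3, got ", ncomp)
  }
  D <- ncomp
  if (D == 2L && dims[3] != 1L) {
    stop("read_field: 2-component field must have a singleton third axis")
  }
  g <- geometry_from_header(hdr, D)
  N <- dims[4]
  sp <- sidecar_path(path)
  if (N == 1L) {
    vec <- array(as.vector(img), dim = c(g$size, D))
    return(displacement_field(g, vec))
  }
  if (!file.exists(sp)) {
    stop("read_field: velocity field ", path, " is missing its JSON sidecar ", sp)
  }
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (is.null(side$n_integration_points) || side$n_integration_points != N) {
    stop("read_field: sidecar n_integration_points (",
         side$n_integration_points, ") disagrees with 4th axis length (", N, ")")
  }
  if (!is.null(side$geometry)) {
    gs <- grid_geometry(side$geometry$size, side$geometry$spacing,
                        side$geometry$origin)
    if (!same_geometry(g, gs)) {
      stop("read_field: geometry mismatch between NIfTI header and sidecar")
    }
  }
  meta <- side[setdiff(names(side),
                       c("n_integration_points", "times_normalized", "geometry"))]
  velocity_field(g, array(as.vector(img), dim = c(g$size, N, D)), meta = meta)
}

# ---- scalar volumes ---------------------------------------------------------

#' A scalar intensity volume on a grid
#' @param geometry a [grid_geometry()].
#' @param data numeric array of dimension `size`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(geometry, data) {
  stopifnot(inherits(geometry, "grid_geometry"))
  if (!identical(dim(data), geometry$size)) {
    stop("image_volume: data dims must equal geometry size")
  }
  if (any(!is.finite(data))) stop("image_volume: data must be finite")
  structure(list(geometry = geometry, data = data), class = "image_volume")
}

#' Write a scalar volume (intensity or label) as NIfTI-1
#' @param volume an [image_volume()] or [label_volume()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  g <- volume$geometry
  data <- if (inherits(volume, "label_volume")) volume$labels else volume$data
  sz3 <- c(g$size, rep(1L, 3 - g$D))[1:3]
  dt <- if (inherits(volume, "label_volume")) 8L else 16L
  hdr <- nifti_header_for(g, 1L, 1L, datatype = dt)
  hdr$dim <- c(3L, sz3, 1L, 1L, 1L, 1L)
  img <- RNifti::asNifti(array(data, dim = sz3),
                         reference = RNifti::niftiHeader(hdr),
                         datatype = if (dt == 8L) "int" else "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a scalar volume from NIfTI-1
#' @param path file path.
#' @param type `"intensity"` for an [image_volume()], `"label"` for a
#'   [label_volume()] (values are rounded to integers).
#' @return an [image_volume()] or [label_volume()].
#' @export
read_volume <- function(path, type = c("intensity", "label")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("read_volume: no such file: ", path)
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  dims <- dim(img)
  dims <- dims[dims > 1L | seq_along(dims) <= 2L]
  D <- length(dims)
  if (!D %in% c(2L, 3L)) {
    stop("read_volume: expected a 2-D or 3-D scalar volume")
  }
  g <- geometry_from_header(hdr, D)
  arr <- array(as.vector(img), dim = g$size)
  if (type == "label") {
    label_volume(g, array(as.integer(round(arr)), dim = g$size))
  } else {
    image_volume(g, arr)
  }
}

# ---- Jacobian ---------------------------------------------------------------

#' Discrete Jacobian determinant of the mapping id + displacement
#'
#' Central differences at interior voxels, one-sided at the domain edges.
#' A strictly positive determinant everywhere indicates the discrete mapping
#' preserves orientation (no folding) — the standard sanity check for a
#' diffeomorphic transform.
#'
#' @param d a [displacement_field()].
#' @return numeric array of dimension `size` with the determinant per voxel.
#' @export
jacobian_determinant <- function(d) {
  stopifnot(inherits(d, "displacement_field"))
  g <- d$geometry
  D <- g$D
  n <- g$size
  nv <- prod(n)
  idx_all <- lapply(n, seq_len)
  # broadcast a per-axis vector along axis 'a' of an array of dim n
  bcast <- function(vals, a) {
    array(rep(rep(vals, each = prod(n[seq_len(a - 1)])),
              times = prod(n[seq(a + 1, length.out = D - a)])), dim = n)
  }
  J <- vector("list", D * D) # J[[(a-1)*D + c]] = d phi_c / d x_a
  for (cc in seq_len(D)) {
    u_c <- array(d$vectors[(cc - 1) * nv + seq_len(nv)], dim = n)
    ax <- g$origin[cc] + (seq_len(n[cc]) - 1) * g$spacing[cc]
    phi <- u_c + bcast(ax, cc)
    for (a in seq_len(D)) {
      up <- idx_all
      lo <- idx_all
      up[[a]] <- pmin(idx_all[[a]] + 1L, n[a])
      lo[[a]] <- pmax(idx_all[[a]] - 1L, 1L)
      den <- bcast((up[[a]] - lo[[a]]) * g$spacing[a], a)
      diff <- do.call(`[`, c(list(phi), up, list(drop = FALSE))) -
        do.call(`[`, c(list(phi), lo, list(drop = FALSE)))
      J[[(a - 1) * D + cc]] <- as.vector(diff) / as.vector(den)
    }
  }
  jc <- function(a, cc) J[[(a - 1) * D + cc]]
  if (D == 2L) {
    det <- jc(1, 1) * jc(2, 2) - jc(1, 2) * jc(2, 1)
  } else {
    det <- jc(1, 1) * (jc(2, 2) * jc(3, 3) - jc(2, 3) * jc(3, 2)) -
      jc(2, 1) * (jc(1, 2) * jc(3, 3) - jc(1, 3) * jc(3, 2)) +
      jc(3, 1) * (jc(1, 2) * jc(2, 3) - jc(1, 3) * jc(2, 2))
  }
  array(det, dim = n)
}
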