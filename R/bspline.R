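#' Configuration of the multilevel B-spline scattered-data approximation
#'
#' The regularizer of the velocity-field fit: scattered weighted displacement
#' samples are converted into a smooth field on the grid by the classic
#' multilevel B-spline approximation, generalized with per-sample confidence
#' weights.  At each level the control-point values are the local weighted
#' least-squares solution of the residual samples; residuals are then
#' recomputed and the control mesh is refined (doubled) for the next level.
#'
#' @param order spline order (polynomial degree); default 3 (cubic).
#' @param base_mesh control-mesh resolution (number of spans) per axis at the
#'   coarsest level; scalar or per-axis vector; default 1.
#' @param levels number of multilevel refinements; the mesh doubles per
#'   level; default 4.
#' @return An object of class `bspline_config`.
#' @export
bspline_config <- function(order = 3, base_mesh = 1, levels = 4) {
  order <- as.integer(order)
  base_mesh <- as.integer(base_mesh)
  levels <- as.integer(levels)
  if (order < 1L) stop("bspline_config: 'order' must be >= 1")
  if (any(base_mesh < 1L)) stop("bspline_config: 'base_mesh' must be >= 1")
  if (levels < 1L) stop("bspline_config: 'levels' must be >= 1")
  structure(list(order = order, base_mesh = base_mesh, levels = levels),
            class = "bspline_config")
}

# Cardinal (uniform) B-spline of degree p on [0, p+1), by Cox-de Boor.
cardinal_bspline <- function(x, p) {
  if (p == 0L) return(as.numeric(x >= 0 & x < 1))
  (x * cardinal_bspline(x, p - 1L) +
     (p + 1 - x) * cardinal_bspline(x - 1, p - 1L)) / p
}

# Basis weights of the p+1 control points supporting local parameter t in
# [0, 1]: column j+1 holds the weight of control offset j (j = 0..p).
bspline_weights <- function(t, p) {
  vapply(0:p, function(j) cardinal_bspline(t + p - j, p), numeric(length(t)))
}

# Per-axis span indices (0-based) and local parameters for physical coords.
bspline_param <- function(coords, geometry, mesh) {
  D <- geometry$D
  b <- domain_bounds(geometry)
  span <- matrix(0L, nrow(coords), D)
  t <- matrix(0, nrow(coords), D)
  for (a in seq_len(D)) {
    u <- (coords[, a] - b$lower[a]) / (b$upper[a] - b$lower[a]) * mesh[a]
    u <- pmin(pmax(u, 0), mesh[a])
    sa <- pmin(floor(u), mesh[a] - 1L)
    span[, a] <- as.integer(sa)
    t[, a] <- u - sa
  }
  list(span = span, t = t)
}

# Tensor-product basis machinery: PHI (M x ncomb) basis products and CIDX
# (M x ncomb) 1-based linear control indices, for mesh 'mesh' and order p.
bspline_tensor <- function(coords, geometry, mesh, p) {
  D <- geometry$D
  par <- bspline_param(coords, geometry, mesh)
  Ws <- lapply(seq_len(D), function(a) {
    matrix(bspline_weights(par$t[, a], p), ncol = p + 1)
  })
  ncp <- mesh + p
  cstr <- cumprod(c(1, ncp))[seq_len(D)]
  combos <- as.matrix(do.call(expand.grid, rep(list(0:p), D)))
  M <- nrow(coords)
  PHI <- matrix(0, M, nrow(combos))
  CIDX <- matrix(0L, M, nrow(combos))
  for (k in seq_len(nrow(combos))) {
    phi <- rep(1, M)
    idx <- rep(1, M)
    for (a in seq_len(D)) {
      j <- combos[k, a]
      phi <- phi * Ws[[a]][, j + 1]
      idx <- idx + (par$span[, a] + j) * cstr[a]
    }
    PHI[, k] <- phi
    CIDX[, k] <- as.integer(idx)
  }
  list(PHI = PHI, CIDX = CIDX, ncp = ncp)
}

# One level of the generalized (confidence-weighted) B-spline approximation:
# control value = sum_s w_s phi_sc^2 delta_sc / sum_s w_s phi_sc^2 with
# delta_sc = phi_sc v_s / sum_k phi_sk^2 (the local least-squares attribution
# of sample s over its support).
bspline_level_controls <- function(tensor, values, weights) {
  PHI <- tensor$PHI
  CIDX <- tensor$CIDX
  C <- ncol(values)
  ntot <- prod(tensor$ncp)
  sumsq <- rowSums(PHI^2)
  idx_flat <- as.vector(CIDX)
  phisq_w <- as.vector(weights * PHI^2)
  den <- numeric(ntot)
  acc <- rowsum(phisq_w, idx_flat)
  den[as.integer(rownames(acc))] <- acc
  ctrl <- matrix(0, ntot, C)
  base_num <- weights * PHI^3 / sumsq # delta contribution without v
  for (cc in seq_len(C)) {
    numv <- numeric(ntot)
    acc <- rowsum(as.vector(base_num * values[, cc]), idx_flat)
    numv[as.integer(rownames(acc))] <- acc
    nz <- den > 0
    ctrl[nz, cc] <- numv[nz] / den[nz]
  }
  ctrl
}

# Evaluate a control lattice at arbitrary coordinates via the tensor basis.
bspline_eval_points <- function(tensor, ctrl) {
  C <- ncol(ctrl)
  out <- matrix(0, nrow(tensor$PHI), C)
  for (cc in seq_len(C)) {
    V <- matrix(ctrl[tensor$CIDX, cc], nrow = nrow(tensor$CIDX))
    out[, cc] <- rowSums(tensor$PHI * V)
  }
  out
}

# Evaluate a control lattice at every voxel center by successive per-axis
# contractions with banded basis matrices (cheap because meshes are small).
bspline_eval_grid <- function(ctrl, geometry, mesh, p) {
  D <- geometry$D
  ncp <- mesh + p
  Bs <- lapply(seq_len(D), function(a) {
    na <- geometry$size[a]
    u <- (seq_len(na) - 1) / (na - 1) * mesh[a] # voxel centers in mesh units
    sa <- pmin(floor(u), mesh[a] - 1)
    W <- matrix(bspline_weights(u - sa, p), ncol = p + 1)
    B <- matrix(0, na, ncp[a])
    for (j in 0:p) B[cbind(seq_len(na), sa + j + 1)] <- W[, j + 1]
    B
  })
  C <- ncol(ctrl)
  A <- array(ctrl, dim = c(ncp, C))
  for (a in seq_len(D)) {
    dA <- dim(A)
    perm <- c(a, setdiff(seq_along(dA), a))
    A <- aperm(A, perm)
    dA2 <- dim(A)
    A <- Bs[[a]] %*% matrix(A, nrow = dA2[1])
    dim(A) <- c(geometry$size[a], dA2[-1])
    A <- aperm(A, order(perm))
  }
  A # dim c(size, C)
}

#' Fit a smooth vector field to weighted scattered samples
#'
#' Generalized multilevel B-spline scattered-data approximation: each vector
#' component is fitted independently; at each level the control points take
#' the confidence-weighted local least-squares value of the current residual
#' samples, residuals are recomputed at the anchors, and the control mesh is
#' doubled.  Anchors falling outside the domain are clamped to the nearest
#' boundary position before accumulation, so that correspondences whose
#' warped midpoints exit the grid still contribute.
#'
#' @param anchors numeric M x D matrix of physical sample locations.
#' @param values numeric M x D matrix of sample vectors.
#' @param weights positive numeric vector of M confidence weights; uniform
#'   rescaling of all weights leaves the fit unchanged.
#' @param geometry a [grid_geometry()] on which the field is evaluated.
#' @param config a [bspline_config()].
#' @return a [displacement_field()]: the approximant at every voxel center.
#' @examples
#' geom <- grid_geometry(c(16, 16), spacing = c(1, 1))
#' anc <- matrix(runif(40, 2, 13), ncol = 2)
#' val <- cbind(anc[, 1] * 0.05, -anc[, 2] * 0.05)
#' f <- fit_scattered_field(anc, val, rep(1, 20), geom, bspline_config())
#' @export
fit_scattered_field <- function(anchors, values, weights, geometry,
                                config = bspline_config()) {
  stopifnot(inherits(geometry, "grid_geometry"), inherits(config, "bspline_config"))
  D <- geometry$D
  anchors <- as_coord_matrix(anchors, D)
  values <- as_coord_matrix(values, D)
  if (nrow(anchors) != nrow(values)) {
    stop("fit_scattered_field: anchors and values must have equal rows")
  }
  if (nrow(anchors) < 1L) stop("fit_scattered_field: need at least one sample")
  if (any(!is.finite(anchors))) stop("fit_scattered_field: non-finite anchor")
  if (any(!is.finite(values))) stop("fit_scattered_field: non-finite value")
  weights <- as.double(weights)
  if (length(weights) != nrow(anchors) || any(!is.finite(weights)) ||
      any(weights < 0) || sum(weights) <= 0) {
    stop("fit_scattered_field: weights must be non-negative with positive sum")
  }
  if (max(abs(values)) == 0) { # zero data fits exactly to the zero field
    return(displacement_field(geometry))
  }
  anchors <- clamp_to_domain(anchors, geometry)
  mesh <- rep(config$base_mesh, length.out = D)
  p <- config$order
  residual <- values
  field <- array(0, dim = c(geometry$size, D))
  for (lev in seq_len(config$levels)) {
    tensor <- bspline_tensor(anchors, geometry, mesh, p)
    ctrl <- bspline_level_controls(tensor, residual, weights)
    residual <- residual - bspline_eval_points(tensor, ctrl)
    field <- field + bspline_eval_grid(ctrl, geometry, mesh, p)
    mesh <- mesh * 2L
  }
  displacement_field(geometry, field)
}
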