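# Shared fixtures and independent brute-force oracles.

rand_point_set <- function(M, geometry, seed = 1, margin = 0.2) {
  withr::with_seed(seed, {
    b <- velflow::domain_bounds(geometry)
    span <- b$upper - b$lower
    coords <- sapply(seq_along(b$lower), function(a) {
      runif(M, b$lower[a] + margin * span[a], b$upper[a] - margin * span[a])
    })
    velflow::point_set(matrix(coords, ncol = length(b$lower)),
                       weights = runif(M, 0.5, 2))
  })
}

# Per-axis linear interpolation oracle: recursive reduction over axes,
# independent of the package's stride-based implementation.
brute_force_interp <- function(vectors, geometry, q) {
  D <- geometry$D
  n <- geometry$size
  u <- (q - geometry$origin) / geometry$spacing
  u <- pmin(pmax(u, 0), n - 1)
  rec <- function(fixed) {
    a <- length(fixed) + 1
    if (a > D) {
      idx <- matrix(c(fixed + 1, 0), nrow = 1)
      return(sapply(seq_len(D), function(cc) {
        do.call(`[`, c(list(vectors), as.list(fixed + 1), list(cc)))
      }))
    }
    i0 <- min(floor(u[a]), n[a] - 2)
    f <- u[a] - i0
    (1 - f) * rec(c(fixed, i0)) + f * rec(c(fixed, i0 + 1))
  }
  rec(integer(0))
}

# Exhaustive 6-neighbourhood (4 in 2-D) boundary enumeration.
brute_force_boundary <- function(labels) {
  n <- dim(labels)
  D <- length(n)
  out <- array(FALSE, dim = n)
  idx <- which(labels > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    pos <- idx[r, ]
    lab <- do.call(`[`, c(list(labels), as.list(pos)))
    is_b <- FALSE
    for (a in seq_len(D)) {
      for (s in c(-1L, 1L)) {
        nb <- pos
        nb[a] <- nb[a] + s
        nb_lab <- if (nb[a] < 1 || nb[a] > n[a]) 0L else
          do.call(`[`, c(list(labels), as.list(nb)))
        if (nb_lab != lab) is_b <- TRUE
      }
    }
    if (is_b) out[matrix(pos, 1)] <- TRUE
  }
  out
}

# Naive per-control-point accumulation of the weighted multilevel B-spline
# update (single level), written directly from the local least-squares
# formula with explicit loops; independent of the vectorized implementation.
brute_force_sda_level <- function(anchors, values, weights, geometry, mesh, p) {
  D <- geometry$D
  b <- velflow::domain_bounds(geometry)
  ncp <- mesh + p
  M <- nrow(anchors)
  span <- matrix(0L, M, D)
  tloc <- matrix(0, M, D)
  for (a in seq_len(D)) {
    u <- (anchors[, a] - b$lower[a]) / (b$upper[a] - b$lower[a]) * mesh[a]
    u <- pmin(pmax(u, 0), mesh[a])
    span[, a] <- pmin(floor(u), mesh[a] - 1)
    tloc[, a] <- u - span[, a]
  }
  card <- function(x, p) {
    if (p == 0) return(as.numeric(x >= 0 & x < 1))
    (x * card(x, p - 1) + (p + 1 - x) * card(x - 1, p - 1)) / p
  }
  C <- ncol(values)
  num <- array(0, dim = c(ncp, C))
  den <- array(0, dim = ncp)
  combos <- as.matrix(do.call(expand.grid, rep(list(0:p), D)))
  for (s in seq_len(M)) {
    phis <- numeric(nrow(combos))
    for (k in seq_len(nrow(combos))) {
      phi <- 1
      for (a in seq_len(D)) {
        phi <- phi * card(tloc[s, a] + p - combos[k, a], p)
      }
      phis[k] <- phi
    }
    sumsq <- sum(phis^2)
    for (k in seq_len(nrow(combos))) {
      ci <- span[s, ] + combos[k, ] + 1
      delta <- phis[k] * values[s, ] / sumsq
      num_idx <- cbind(matrix(ci, nrow = C, ncol = D, byrow = TRUE), seq_len(C))
      num[num_idx] <- num[num_idx] + weights[s] * phis[k]^2 * delta
      den[matrix(ci, 1)] <- den[matrix(ci, 1)] + weights[s] * phis[k]^2
    }
  }
  ctrl <- array(0, dim = c(ncp, C))
  for (cc in seq_len(C)) {
    comp <- array(num[slice.index(num, D + 1) == cc], dim = ncp)
    comp[den > 0] <- comp[den > 0] / den[den > 0]
    ctrl[slice.index(ctrl, D + 1) == cc] <- comp
  }
  ctrl
}

# Weighted RMS of residual vectors at the anchors after a fit.
anchor_rms <- function(field, anchors, values, weights) {
  fit <- velflow::interpolate_vector_field(field, anchors)
  sqrt(sum(weights * rowSums((values - fit)^2)) / sum(weights))
}

# Velocity field with an analytic per-slice profile: fun(centers, tau)
# returns the Q x D slice values.
analytic_velocity_field <- function(geometry, N, fun) {
  ctr <- velflow::voxel_centers(geometry)
  slices <- array(0, dim = c(geometry$size, N, geometry$D))
  taus <- seq(0, 1, length.out = N)
  nv <- nrow(ctr)
  for (i in seq_len(N)) {
    vals <- fun(ctr, taus[i])
    for (cc in seq_len(geometry$D)) {
      off <- nv * (i - 1) + nv * N * (cc - 1)
      slices[off + seq_len(nv)] <- vals[, cc]
    }
  }
  velflow::velocity_field(geometry, slices)
}
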