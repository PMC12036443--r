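#' Configuration of the velocity-field optimization
#'
#' @param n_integration_points number N of uniformly spaced time slices at
#'   which the velocity field is stored and updated; default 11.
#' @param step_size gradient step `delta` in (0, 1] applied to each smoothed
#'   update field before it is added to the current slice; default 0.2.
#' @param max_iterations fixed iteration budget; default 200.
#' @param convergence_tolerance non-negative stop threshold on the absolute
#'   change of the 10-iteration windowed mean of the average displacement
#'   error; the default 0 never triggers, i.e. the full budget is used.
#' @param integration_substeps_per_slice_interval substeps of the midpoint
#'   (RK2) integrator per slice interval; default 4.
#' @param bspline a [bspline_config()] for the scattered-data regularizer.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(n_integration_points = 11, step_size = 0.2,
                       max_iterations = 200, convergence_tolerance = 0,
                       integration_substeps_per_slice_interval = 4,
                       bspline = bspline_config()) {
  n_integration_points <- as.integer(n_integration_points)
  if (n_integration_points < 2L) {
    stop("fit_config: 'n_integration_points' must be >= 2")
  }
  if (!is.finite(step_size) || step_size <= 0 || step_size > 1) {
    stop("fit_config: 'step_size' must be in (0, 1]")
  }
  if (max_iterations < 1L) stop("fit_config: 'max_iterations' must be >= 1")
  if (convergence_tolerance < 0) {
    stop("fit_config: 'convergence_tolerance' must be >= 0")
  }
  substeps <- as.integer(integration_substeps_per_slice_interval)
  if (substeps < 1L) stop("fit_config: substeps must be >= 1")
  stopifnot(inherits(bspline, "bspline_config"))
  structure(list(n_integration_points = n_integration_points,
                 step_size = step_size,
                 max_iterations = as.integer(max_iterations),
                 convergence_tolerance = convergence_tolerance,
                 integration_substeps_per_slice_interval = substeps,
                 bspline = bspline),
            class = "fit_config")
}

# ---- trajectory integration -------------------------------------------------

# Velocity at coords (Q x D) and normalized time t, from the raw slice array
# (dim c(size, N, D)): linear interpolation in time between the two adjacent
# slices, multilinear interpolation in space, clamped at the domain boundary.
velocity_at <- function(slices, geometry, N, coords, t) {
  nv <- n_voxels(geometry)
  s <- min(max(t, 0), 1) * (N - 1)
  i0 <- min(floor(s), N - 2)
  f <- s - i0
  cstride <- nv * N
  v0 <- interp_core(slices, geometry, coords, base_offset = nv * i0,
                    comp_stride = cstride)
  if (f == 0) return(v0)
  v1 <- interp_core(slices, geometry, coords, base_offset = nv * (i0 + 1),
                    comp_stride = cstride)
  (1 - f) * v0 + f * v1
}

# Propagate coords from t0 to t1 through the velocity slices with fixed-step
# midpoint (RK2) integration; substeps per slice interval, negative direction
# handled by a signed step.
integrate_coords <- function(slices, geometry, N, coords, t0, t1, substeps) {
  if (t1 == t0) return(coords)
  nsteps <- max(1L, as.integer(ceiling(substeps * abs(t1 - t0) * (N - 1) - 1e-9)))
  h <- (t1 - t0) / nsteps
  x <- coords
  for (k in seq_len(nsteps) - 1L) {
    t <- t0 + k * h
    k1 <- velocity_at(slices, geometry, N, x, t)
    k2 <- velocity_at(slices, geometry, N, x + 0.5 * h * k1, t + 0.5 * h)
    x <- x + h * k2
  }
  x
}

check_time_range <- function(...) {
  ts <- c(...)
  if (any(!is.finite(ts)) || any(ts < 0) || any(ts > 1)) {
    stop("normalized times must lie in [0, 1]; got ",
         paste(format(ts), collapse = ", "))
  }
}

#' Integrate a velocity field into a displacement field
#'
#' For every voxel center `x`, the position is propagated from normalized
#' time `t0` to `t1` by stepping through the velocity field (midpoint/RK2
#' scheme with a fixed number of substeps per slice interval; the velocity at
#' intermediate times is linearly interpolated between adjacent slices, and
#' spatially by [interpolate_vector_field()] semantics).  The output vector at
#' `x` is the final position minus `x`.  `t1 < t0` integrates backwards.
#'
#' @param v a [velocity_field()].
#' @param t0,t1 normalized times in `[0, 1]`, either order.
#' @param substeps substeps per slice interval; default 4.
#' @return a [displacement_field()] for the mapping from time `t0` to `t1`.
#' @export
integrate_velocity_field <- function(v, t0, t1, substeps = 4) {
  stopifnot(inherits(v, "velocity_field"))
  check_time_range(t0, t1)
  centers <- voxel_centers(v$geometry)
  final <- integrate_coords(v$slices, v$geometry, v$n_slices, centers,
                            t0, t1, substeps)
  displacement_field(v$geometry,
                     array(final - centers, c(v$geometry$size, v$geometry$D)))
}

#' Transform a point set between two time points
#'
#' Per-point trajectory integration under the velocity field (same stepping
#' scheme as [integrate_velocity_field()], but evaluated along each moving
#' point rather than on the grid).  Ids and weights are preserved.
#'
#' @param points a [point_set()].
#' @param v a [velocity_field()].
#' @param t0,t1 normalized times in `[0, 1]`, either order.
#' @param substeps substeps per slice interval; default 4.
#' @return a [point_set()] at time `t1`.
#' @export
transform_points_in_time <- function(points, v, t0, t1, substeps = 4) {
  stopifnot(inherits(points, "point_set"), inherits(v, "velocity_field"))
  check_time_range(t0, t1)
  if (ncol(points$coords) != v$geometry$D) {
    stop("transform_points_in_time: point dimensionality does not match field")
  }
  coords <- integrate_coords(v$slices, v$geometry, v$n_slices, points$coords,
                             t0, t1, substeps)
  point_set(coords, ids = points$ids, weights = points$weights)
}

#' Warp an image between two time points of a velocity field
#'
#' Resampling follows the pull-back convention: the displacement integrated
#' from the *output* time `t1` back to the *input* time `t0` is used to look
#' up source intensities, `output(x) = input(x + Phi[t1 -> t0](x) - x)`.
#'
#' @param image an [image_volume()] or [label_volume()] on `v`'s geometry.
#' @param v a [velocity_field()].
#' @param t0 normalized time of the input image.
#' @param t1 normalized time of the output image.
#' @param interpolation `"linear"` or `"nearest"` (labels should use nearest,
#'   which can introduce no label absent from the input).
#' @param substeps substeps per slice interval; default 4.
#' @return an object of the same class as `image`.
#' @export
transform_image_in_time <- function(image, v, t0, t1,
                                    interpolation = c("linear", "nearest"),
                                    substeps = 4) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(v, "velocity_field"))
  is_label <- inherits(image, "label_volume")
  if (!is_label && !inherits(image, "image_volume")) {
    stop("transform_image_in_time: 'image' must be an image_volume or label_volume")
  }
  g <- image$geometry
  if (!same_geometry(g, v$geometry)) {
    stop("transform_image_in_time: image geometry does not match the velocity ",
         "field; resample the image first")
  }
  check_time_range(t0, t1)
  data <- if (is_label) image$labels else image$data
  disp <- integrate_velocity_field(v, t1, t0, substeps = substeps)
  pos <- voxel_centers(g) + matrix(disp$vectors, ncol = g$D)
  if (interpolation == "linear") {
    vals <- interp_core(as.double(data), g, pos, comp_stride = n_voxels(g), C = 1L)
    out <- array(vals[, 1], dim = g$size)
  } else {
    idx <- matrix(0L, nrow(pos), g$D)
    for (a in seq_len(g$D)) {
      ia <- round((pos[, a] - g$origin[a]) / g$spacing[a])
      idx[, a] <- as.integer(pmin(pmax(ia, 0), g$size[a] - 1L))
    }
    strides <- cumprod(c(1, g$size))[seq_len(g$D)]
    out <- array(data[1 + as.vector(idx %*% strides)], dim = g$size)
  }
  if (is_label) label_volume(g, array(as.integer(out), g$size)) else image_volume(g, out)
}

#' Invert a displacement field by fixed-point iteration
#'
#' Iterates `u <- -d o (id + u)` until the mean update norm falls below
#' `tolerance` or the iteration budget is exhausted.  The composition
#' residual (mean norm of `u + d o (id + u)`, i.e. how far the forward and
#' inverse mappings compose from the identity) is attached as attribute
#' `composition_residual`.
#'
#' @param d a [displacement_field()].
#' @param max_iterations iteration budget; default 30.
#' @param tolerance stop threshold on the mean update norm, in physical
#'   units; default `1e-3 * min(spacing)`.
#' @return a [displacement_field()] approximating the inverse mapping.
#' @export
invert_displacement_field <- function(d, max_iterations = 30,
                                      tolerance = NULL) {
  stopifnot(inherits(d, "displacement_field"))
  g <- d$geometry
  if (is.null(tolerance)) tolerance <- 1e-3 * min(g$spacing)
  centers <- voxel_centers(g)
  u <- matrix(0, nrow(centers), g$D)
  prev_norm <- Inf
  rising <- 0L
  for (it in seq_len(max_iterations)) {
    d_at <- interp_core(d$vectors, g, centers + u)
    u_new <- -d_at
    upd <- sqrt(rowSums((u_new - u)^2))
    mean_upd <- mean(upd)
    u <- u_new
    if (mean_upd >= prev_norm) {
      rising <- rising + 1L
      if (rising >= 5L) {
        stop("invert_displacement_field: fixed-point iteration diverging ",
             "(update norm grew 5 consecutive iterations); the deformation is ",
             "too large to invert on this grid - reduce it or refine the grid")
      }
    } else {
      rising <- 0L
    }
    prev_norm <- mean_upd
    if (mean_upd < tolerance) break
  }
  res <- mean(sqrt(rowSums((u + interp_core(d$vectors, g, centers + u))^2)))
  out <- displacement_field(g, array(u, c(g$size, g$D)))
  attr(out, "composition_residual") <- res
  out
}

#' Single-shot displacement fit between two paired point sets
#'
#' The degenerate (two-set) building block of the flow fit: the vectors
#' `fixed_j - moving_j` are smoothed into a field anchored at the moving
#' points with [fit_scattered_field()].  The moving set's weights drive the
#' fit.
#'
#' @param fixed,moving [point_set()] objects with equal size and matching ids.
#' @param geometry a [grid_geometry()].
#' @param bspline a [bspline_config()].
#' @return a [displacement_field()] mapping moving towards fixed.
#' @export
fit_displacement_between_point_sets <- function(fixed, moving, geometry,
                                                bspline = bspline_config()) {
  stopifnot(inherits(fixed, "point_set"), inherits(moving, "point_set"))
  if (n_points(fixed) != n_points(moving)) {
    stop("fit_displacement_between_point_sets: point counts differ (",
         n_points(fixed), " vs ", n_points(moving), ")")
  }
  if (!identical(fixed$ids, moving$ids)) {
    bad <- utils::head(which(fixed$ids != moving$ids), 5)
    stop("fit_displacement_between_point_sets: ids differ at rows ",
         paste(bad, collapse = ", "), " (",
         paste(fixed$ids[bad], moving$ids[bad], sep = "/", collapse = ", "), ")")
  }
  fit_scattered_field(moving$coords, fixed$coords - moving$coords,
                      moving$weights, geometry, bspline)
}

# ---- the optimization loop --------------------------------------------------

# Bracketing atlas interval for integration time tau: consecutive series
# times [t_a, t_b] with t_a <= tau <= t_b.  Tie rule: tau equal to an
# interior series time t_k uses the left interval [t_{k-1}, t_k]; tau = 0 or
# 1 uses the first or last interval, so endpoint slices still receive updates.
bracket_interval <- function(times, tau) {
  K <- length(times)
  a <- if (tau <= times[1]) 1L else max(which(times < tau))
  a <- min(a, K - 1L)
  c(a, a + 1L)
}

#' Fit a time-varying velocity field to a point-set series
#'
#' The core optimization.  The field is initialized to zero over N slices at
#' `tau_i = (i-1)/(N-1)`.  Each iteration loops over the integration points;
#' at each `tau_i` the two point sets bracketing `tau_i` in time are warped to
#' `tau_i` under the current field (forward from the earlier, backward from
#' the later), their residual vectors are anchored at pair midpoints, scaled
#' by the reciprocal bracket width into velocity units, smoothed with
#' [fit_scattered_field()], and added to slice `i` scaled by the step size.
#' The per-iteration average displacement error is the mean over integration
#' points of the weighted mean residual norm; optimization stops when its
#' 10-iteration windowed mean stabilizes to within `convergence_tolerance`
#' (never, with the default tolerance 0) or at `max_iterations`.
#'
#' @param series a [point_set_series()].
#' @param geometry a [grid_geometry()] defining the field's spatial lattice;
#'   points should lie inside or near this domain (outside points are clamped
#'   for field evaluation and counted in a message).
#' @param config a [fit_config()].
#' @param verbose print the error once per 10 iterations.
#' @return a list with `field` (a [velocity_field()] carrying fit metadata)
#'   and `trace` (a `convergence_trace`: per-iteration weighted and
#'   unweighted average displacement error, and the per-integration-point
#'   median displacement error matrix).
#' @examples
#' geom <- grid_geometry(c(24, 24), spacing = c(1, 1))
#' spec <- flow_spec("translation", translation = c(2, 0), n_points = 50,
#'                   times = c(0, 1), seed = 7)
#' sim <- generate_flow_series(spec, geom)
#' fit <- fit_velocity_flow(sim$series, geom,
#'                          fit_config(n_integration_points = 3,
#'                                     max_iterations = 20))
#' @export
fit_velocity_flow <- function(series, geometry, config = fit_config(),
                              verbose = FALSE) {
  stopifnot(inherits(series, "point_set_series"),
            inherits(geometry, "grid_geometry"),
            inherits(config, "fit_config"))
  D <- geometry$D
  if (ncol(series$sets[[1]]$coords) != D) {
    stop("fit_velocity_flow: series dimensionality does not match geometry")
  }
  b <- domain_bounds(geometry)
  n_out <- sum(vapply(series$sets, function(s) {
    sum(apply(s$coords, 1, function(x) any(x < b$lower | x > b$upper)))
  }, numeric(1)))
  if (n_out > 0) {
    message("fit_velocity_flow: ", n_out, " point(s) across the series lie ",
            "outside the domain; they are clamped for field evaluation")
  }
  N <- config$n_integration_points
  tau <- seq(0, 1, length.out = N)
  delta <- config$step_size
  substeps <- config$integration_substeps_per_slice_interval
  weights <- series$sets[[1]]$weights
  wsum <- sum(weights)
  times <- series$times
  nv <- n_voxels(geometry)
  slices <- array(0, dim = c(geometry$size, N, D))
  avg_err <- numeric(0)
  avg_err_unw <- numeric(0)
  med_err <- matrix(0, 0, N)
  iterations_run <- 0L
  for (iter in seq_len(config$max_iterations)) {
    werr_i <- numeric(N)
    uerr_i <- numeric(N)
    merr_i <- numeric(N)
    for (i in seq_len(N)) {
      ab <- bracket_interval(times, tau[i])
      Pa <- integrate_coords(slices, geometry, N,
                             series$sets[[ab[1]]]$coords, times[ab[1]], tau[i],
                             substeps)
      Pb <- integrate_coords(slices, geometry, N,
                             series$sets[[ab[2]]]$coords, times[ab[2]], tau[i],
                             substeps)
      r <- Pb - Pa
      if (any(!is.finite(r))) {
        stop("fit_velocity_flow: non-finite residuals at integration point ",
             i, " (tau = ", format(tau[i]), "), iteration ", iter)
      }
      nr <- sqrt(rowSums(r^2))
      werr_i[i] <- sum(weights * nr) / wsum
      uerr_i[i] <- mean(nr)
      merr_i[i] <- stats::median(nr)
      upd <- fit_scattered_field((Pa + Pb) / 2, r / (times[ab[2]] - times[ab[1]]),
                                 weights, geometry, config$bspline)
      off <- rep(nv * (i - 1L), D) + nv * N * (seq_len(D) - 1L)
      for (cc in seq_len(D)) {
        sel <- off[cc] + seq_len(nv)
        slices[sel] <- slices[sel] + delta * upd$vectors[(cc - 1L) * nv + seq_len(nv)]
      }
    }
    avg_err <- c(avg_err, mean(werr_i))
    avg_err_unw <- c(avg_err_unw, mean(uerr_i))
    med_err <- rbind(med_err, merr_i)
    iterations_run <- iter
    if (verbose && iter %% 10 == 0) {
      message(sprintf("  iter %4d: average displacement error %.6g",
                      iter, avg_err[iter]))
    }
    if (config$convergence_tolerance > 0 && iter >= 11L) {
      cur <- mean(avg_err[(iter - 9):iter])
      prev <- mean(avg_err[(iter - 10):(iter - 1)])
      if (abs(cur - prev) < config$convergence_tolerance) break
    }
  }
  dimnames(med_err) <- NULL
  trace <- structure(list(average_error = avg_err,
                          average_error_unweighted = avg_err_unw,
                          median_error = med_err),
                     class = "convergence_trace")
  meta <- list(step_size = delta,
               iterations_run = iterations_run,
               convergence_trace = list(average_error = avg_err),
               fit_config = list(
                 n_integration_points = N,
                 step_size = delta,
                 max_iterations = config$max_iterations,
                 convergence_tolerance = config$convergence_tolerance,
                 integration_substeps_per_slice_interval = substeps,
                 bspline = unclass(config$bspline)),
               series_times = times)
  field <- velocity_field(geometry, slices, meta = meta)
  list(field = field, trace = trace)
}

#' @export
print.convergence_trace <- function(x, ...) {
  n <- length(x$average_error)
  cat(sprintf("<convergence_trace> %d iterations; average error %.6g -> %.6g\n",
              n, x$average_error[1], x$average_error[n]))
  invisible(x)
}

#' Export a convergence trace as CSV
#'
#' Columns: `iteration`, `average_error`, and one
#' `median_error_slice_<i>` column per integration point (0-based).
#'
#' @param trace a `convergence_trace` from [fit_velocity_flow()].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_convergence_trace <- function(trace, path) {
  stopifnot(inherits(trace, "convergence_trace"))
  N <- ncol(trace$median_error)
  df <- data.frame(iteration = seq_along(trace$average_error),
                   average_error = trace$average_error)
  med <- as.data.frame(trace$median_error)
  names(med) <- paste0("median_error_slice_", seq_len(N) - 1)
  utils::write.csv(cbind(df, med), path, row.names = FALSE)
  invisible(path)
}
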