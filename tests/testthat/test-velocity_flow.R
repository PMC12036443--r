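# Velocity-field optimization, integration, inversion, and warping.
# Unit tests run in 2-D on small grids; the 3-D study-scale checks live in
# test-acceptance.R.

test_that("integration of a constant field is exact for any substep count", {
  g <- grid_geometry(c(12, 12), spacing = c(1, 1))
  v <- analytic_velocity_field(g, 4, function(ctr, tau) {
    cbind(rep(0.75, nrow(ctr)), rep(-0.5, nrow(ctr)))
  })
  for (ss in c(1, 3, 8)) {
    d <- integrate_velocity_field(v, 0.2, 0.9, substeps = ss)
    expect_equal(max(abs(d$vectors[, , 1] - 0.75 * 0.7)), 0, tolerance = 1e-12)
    expect_equal(max(abs(d$vectors[, , 2] + 0.5 * 0.7)), 0, tolerance = 1e-12)
  }
  # empty interval
  d0 <- integrate_velocity_field(v, 0.4, 0.4)
  expect_true(all(d0$vectors == 0))
  expect_error(integrate_velocity_field(v, -0.1, 1), "\\[0, 1\\]")
})

test_that("a linear-in-time velocity integrates to the analytic quadratic", {
  g <- grid_geometry(c(8, 8), spacing = c(1, 1))
  v <- analytic_velocity_field(g, 11, function(ctr, tau) {
    cbind(rep(tau, nrow(ctr)), rep(0, nrow(ctr)))
  })
  d <- integrate_velocity_field(v, 0, 1)
  expect_equal(max(abs(d$vectors[, , 1] - 0.5)), 0, tolerance = 1e-3)
  # backwards: integral of t from 1 to 0 is -0.5
  db <- integrate_velocity_field(v, 1, 0)
  expect_equal(mean(db$vectors[, , 1]), -0.5, tolerance = 1e-3)
})

test_that("trajectory integration error shrinks quadratically with substeps", {
  # v(x) = x e_x is linear in space (exact under multilinear interpolation)
  # and gives the closed-form trajectory x0 * exp(t); the midpoint scheme
  # must show second-order convergence against it.
  g <- grid_geometry(c(64, 4), spacing = c(0.1, 1), origin = c(0, 0))
  v <- analytic_velocity_field(g, 2, function(ctr, tau) {
    cbind(ctr[, 1], rep(0, nrow(ctr)))
  })
  x0 <- cbind(c(1.2, 1.5, 2.0), c(1, 2, 1))
  ps <- point_set(x0)
  subs <- c(2, 4, 8, 16, 32)
  errs <- sapply(subs, function(ss) {
    out <- transform_points_in_time(ps, v, 0, 1, substeps = ss)
    mean(abs(out$coords[, 1] - x0[, 1] * exp(1)))
  })
  slope <- coef(lm(log(errs) ~ log(1 / subs)))[2]
  expect_gt(slope, 1.7)
  expect_lt(slope, 2.3)
})

test_that("point transforms preserve ids and weights and respect zero flow", {
  g <- grid_geometry(c(10, 10))
  v <- velocity_field(g, n_integration_points = 3)
  ps <- rand_point_set(20, g, seed = 7)
  out <- transform_points_in_time(ps, v, 0, 1)
  expect_identical(out$coords, ps$coords)
  expect_identical(out$ids, ps$ids)
  expect_identical(out$weights, ps$weights)
})

test_that("displacement-field inversion recovers analytic inverses", {
  g <- grid_geometry(c(24, 24), spacing = c(1, 1))
  # zero field
  z <- invert_displacement_field(displacement_field(g))
  expect_true(all(z$vectors == 0))
  # constant translation: interior values approach -c
  cvec <- c(0.8, -0.6)
  d <- displacement_field(g, array(rep(cvec, each = prod(g$size)),
                                   c(g$size, 2)))
  inv <- invert_displacement_field(d)
  interior <- matrix(inv$vectors, ncol = 2)[
    rowSums(sweep(voxel_centers(g), 2, c(11.5, 11.5))^2) < 8^2, ]
  expect_lt(max(abs(sweep(interior, 2, -cvec))), 1e-3)
  # smooth sinusoidal field under one voxel spacing: composition residual
  ctr <- voxel_centers(g)
  sine <- displacement_field(g, array(
    cbind(0.6 * sin(2 * pi * ctr[, 2] / 23), 0.6 * sin(2 * pi * ctr[, 1] / 23)),
    c(g$size, 2)))
  u <- invert_displacement_field(sine)
  # || (id + u) o (id + d) - id || on interior voxels
  pos <- ctr + matrix(sine$vectors, ncol = 2)
  comp <- pos + interpolate_vector_field(u, pos) - ctr
  inner <- rowSums(sweep(ctr, 2, c(11.5, 11.5))^2) < 8^2
  expect_lt(mean(sqrt(rowSums(comp[inner, ]^2))), 0.05)
})

test_that("inversion reports divergence for non-invertible deformations", {
  g <- grid_geometry(c(16, 16), spacing = c(1, 1))
  ctr <- voxel_centers(g)
  # expansive field: the fixed-point update is amplified by 1.05 per
  # iteration, so the update norm grows monotonically
  bad <- displacement_field(g, array(cbind(1.05 * (ctr[, 1] - 7.5),
                                           1.05 * (ctr[, 2] - 7.5)),
                                     c(g$size, 2)))
  expect_error(invert_displacement_field(bad, max_iterations = 50),
               "diverging")
})

test_that("image warping follows the pull-back convention", {
  g <- grid_geometry(c(32, 32), spacing = c(1, 1))
  blob <- generate_blob_image(c(12, 16), 3, g)
  v <- analytic_velocity_field(g, 2, function(ctr, tau) {
    cbind(rep(5, nrow(ctr)), rep(-2, nrow(ctr)))
  })
  # identity at zero flow
  v0 <- velocity_field(g, n_integration_points = 2)
  same <- transform_image_in_time(blob, v0, 0, 1)
  expect_equal(same$data, blob$data, tolerance = 1e-12)
  # constant flow moves the centroid by +c
  warped <- transform_image_in_time(blob, v, 0, 1)
  expect_lt(max(abs(image_centroid(warped) - c(12 + 5, 16 - 2))), 1)
  # nearest-neighbour warping introduces no new labels
  lv <- generate_label_volume(list(
    list(label = 3, type = "cube", center = c(10, 14), size = 6),
    list(label = 7, type = "sphere", center = c(20, 10), size = 4)), g)
  wl <- transform_image_in_time(lv, v, 0, 0.5, interpolation = "nearest")
  expect_true(all(unique(as.vector(wl$labels)) %in%
                    unique(as.vector(lv$labels))))
})

test_that("pairwise displacement fit moves moving towards fixed", {
  g <- grid_geometry(c(24, 24), spacing = c(1, 1))
  moving <- rand_point_set(80, g, seed = 11)
  # identity case
  f0 <- fit_displacement_between_point_sets(moving, moving, g)
  expect_true(all(f0$vectors == 0))
  # pure translation: field near anchors approximates d
  d <- c(1.5, -1)
  fixed <- point_set(sweep(moving$coords, 2, d, "+"), ids = moving$ids,
                     weights = moving$weights)
  fd <- fit_displacement_between_point_sets(fixed, moving, g,
                                            bspline_config(levels = 5))
  at_anchors <- interpolate_vector_field(fd, moving$coords)
  expect_lt(mean(sqrt(rowSums(sweep(at_anchors, 2, d)^2))), 0.1 * sqrt(sum(d^2)))
  # smooth synthetic warp: applying the fit halves the mean distance
  truth <- flow_spec("sinusoidal", amplitude = 1.2, frequency = 1,
                     n_points = 80, times = c(0, 1), seed = 12)
  sim <- generate_flow_series(truth, g)
  mv <- sim$series$sets[[1]]
  fx <- sim$series$sets[[2]]
  fit <- fit_displacement_between_point_sets(fx, mv, g)
  before <- mean(sqrt(rowSums((fx$coords - mv$coords)^2)))
  moved <- propagate_points(mv, list(fit))
  after <- mean(sqrt(rowSums((fx$coords - moved$coords)^2)))
  expect_lt(after, 0.5 * before)
  # id mismatch is reported
  bad <- point_set(moving$coords, ids = rev(moving$ids))
  expect_error(fit_displacement_between_point_sets(bad, moving, g),
               "ids differ")
})

test_that("bracketing follows the left-interval tie rule", {
  times <- c(0, 0.25, 0.6, 1)
  expect_equal(velflow:::bracket_interval(times, 0), c(1, 2))
  expect_equal(velflow:::bracket_interval(times, 0.1), c(1, 2))
  expect_equal(velflow:::bracket_interval(times, 0.25), c(1, 2)) # tie: left
  expect_equal(velflow:::bracket_interval(times, 0.3), c(2, 3))
  expect_equal(velflow:::bracket_interval(times, 1), c(3, 4))
})

test_that("fitting identical sets gives a zero field and zero error trace", {
  g <- grid_geometry(c(16, 16))
  ps <- rand_point_set(40, g, seed = 13)
  series <- point_set_series(list(ps, ps, ps), c(0, 0.4, 1))
  fit <- fit_velocity_flow(series, g, fit_config(n_integration_points = 4,
                                                 max_iterations = 15))
  expect_equal(max(abs(fit$field$slices)), 0)
  expect_true(all(fit$trace$average_error == 0))
  expect_true(all(fit$trace$median_error == 0))
})

test_that("a two-set translation flow is recovered end to end", {
  g <- grid_geometry(c(32, 32), spacing = c(1, 1))
  d <- c(2, 0)
  spec <- flow_spec("translation", translation = d, n_points = 100,
                    times = c(0, 1), seed = 3)
  sim <- generate_flow_series(spec, g)
  fit <- fit_velocity_flow(sim$series, g,
                           fit_config(n_integration_points = 5,
                                      max_iterations = 60))
  P0 <- sim$series$sets[[1]]
  P1 <- sim$series$sets[[2]]
  endp <- transform_points_in_time(P0, fit$field, 0, 1)
  err <- sqrt(rowSums((endp$coords - P1$coords)^2))
  expect_lt(sum(P0$weights * err) / sum(P0$weights), 0.1 * sqrt(sum(d^2)))
  # mid-trajectory close to the half-translation
  mid <- transform_points_in_time(P0, fit$field, 0, 0.5)
  mid_err <- sqrt(rowSums((sweep(mid$coords, 2, d / 2) - P0$coords)^2))
  expect_lt(mean(mid_err), 0.2 * sqrt(sum(d^2)))
  # trace: running minimum is non-increasing and everything is finite
  tr <- fit$trace$average_error
  expect_true(all(is.finite(tr)) && all(tr >= 0))
  expect_true(all(diff(cummin(tr)) <= 0))
  # round trip through the fitted field
  back <- transform_points_in_time(endp, fit$field, 1, 0)
  expect_lt(mean(sqrt(rowSums((back$coords - P0$coords)^2))), 0.1)
})

test_that("the fitted flow is inverse-consistent, semigroup, and unfolded", {
  g <- grid_geometry(c(24, 24), spacing = c(1, 1))
  spec <- flow_spec("rotation", angular_rate = pi / 8, n_points = 120,
                    times = c(0, 0.5, 1), seed = 21)
  sim <- generate_flow_series(spec, g)
  fit <- fit_velocity_flow(sim$series, g,
                           fit_config(n_integration_points = 5,
                                      max_iterations = 60))
  pts <- rand_point_set(60, g, seed = 22, margin = 0.3)
  # inverse consistency
  there <- transform_points_in_time(pts, fit$field, 0, 1)
  back <- transform_points_in_time(there, fit$field, 1, 0)
  expect_lt(mean(sqrt(rowSums((back$coords - pts$coords)^2))), 0.2)
  # semigroup: 0 -> 1 vs 0 -> 0.5 -> 1
  half <- transform_points_in_time(pts, fit$field, 0, 0.5)
  full2 <- transform_points_in_time(half, fit$field, 0.5, 1)
  expect_lt(mean(sqrt(rowSums((full2$coords - there$coords)^2))), 0.2)
  # positive Jacobian determinant of id + Phi_{0 -> 1} at interior voxels
  J <- jacobian_determinant(integrate_velocity_field(fit$field, 0, 1))
  expect_true(all(J[2:23, 2:23] > 0))
})

test_that("the convergence trace is exported in the documented CSV layout", {
  g <- grid_geometry(c(16, 16))
  spec <- flow_spec("translation", translation = c(1, 0), n_points = 30,
                    times = c(0, 1), seed = 5)
  sim <- generate_flow_series(spec, g)
  fit <- fit_velocity_flow(sim$series, g,
                           fit_config(n_integration_points = 3,
                                      max_iterations = 12))
  f <- file.path(withr::local_tempdir(), "trace.csv")
  write_convergence_trace(fit$trace, f)
  df <- read.csv(f)
  expect_named(df, c("iteration", "average_error", "median_error_slice_0",
                     "median_error_slice_1", "median_error_slice_2"))
  expect_equal(nrow(df), 12)
  expect_equal(df$average_error, fit$trace$average_error)
})

test_that("the windowed tolerance stops a stationary optimization early", {
  g <- grid_geometry(c(16, 16))
  ps <- rand_point_set(30, g, seed = 31)
  series <- point_set_series(list(ps, ps), c(0, 1))
  fit <- fit_velocity_flow(series, g,
                           fit_config(n_integration_points = 3,
                                      max_iterations = 100,
                                      convergence_tolerance = 1e-10))
  expect_lt(length(fit$trace$average_error), 100)
  expect_equal(fit$field$meta$iterations_run,
               length(fit$trace$average_error))
})
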