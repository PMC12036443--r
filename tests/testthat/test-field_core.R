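# Grid geometry, point sets, interpolation, and field/point-set I/O.

test_that("grid geometry validates its invariants", {
  g <- grid_geometry(c(8, 6, 4), spacing = c(50, 50, 50), origin = c(-10, 0, 5))
  expect_equal(g$D, 3L)
  b <- domain_bounds(g)
  expect_equal(b$lower, c(-10, 0, 5))
  expect_equal(b$upper, c(-10 + 7 * 50, 5 * 50, 5 + 3 * 50))
  expect_error(grid_geometry(c(1, 8)), "sizes")
  expect_error(grid_geometry(c(8, 8), spacing = c(1, 0)), "spacing")
  expect_error(grid_geometry(8), "axes")
})

test_that("voxel centers follow origin + i * spacing in array order", {
  g <- grid_geometry(c(3, 2), spacing = c(2, 10), origin = c(1, -5))
  ctr <- voxel_centers(g)
  expect_equal(ctr[, 1], c(1, 3, 5, 1, 3, 5))
  expect_equal(ctr[, 2], c(-5, -5, -5, 5, 5, 5))
})

test_that("point sets enforce uniqueness, positivity, and series coherence", {
  expect_error(point_set(matrix(1:4, 2), ids = c("a", "a")), "duplicate")
  expect_error(point_set(matrix(1:4, 2), weights = c(1, -1)), "positive")
  ps1 <- point_set(matrix(runif(10), 5), weights = rep(2, 5))
  ps2 <- point_set(matrix(runif(10), 5), weights = rep(2, 5))
  expect_s3_class(point_set_series(list(ps1, ps2), c(0, 1)), "point_set_series")
  expect_error(point_set_series(list(ps1, ps2), c(0, 0.5)), "end at exactly 1")
  expect_error(point_set_series(list(ps1), 0), "at least 2")
  ps3 <- point_set(matrix(runif(10), 5), weights = rep(3, 5))
  expect_error(point_set_series(list(ps1, ps3), c(0, 1)), "weights")
})

test_that("interpolation is exact at nodes, linear between, constant outside", {
  g <- grid_geometry(c(5, 4, 3), spacing = c(1, 2, 3), origin = c(0, 0, 0))
  const <- displacement_field(g, array(rep(c(1, -2, 0.5),
                                           each = prod(g$size)),
                                       c(g$size, 3)))
  expect_equal(interpolate_vector_field(const, c(1.7, 3.1, 2.2)),
               matrix(c(1, -2, 0.5), 1))
  # ramp along x: midpoint between nodes is the arithmetic mean
  ctr <- voxel_centers(g)
  ramp <- displacement_field(g, array(cbind(ctr[, 1], 0 * ctr[, 1],
                                            0 * ctr[, 1]), c(g$size, 3)))
  expect_equal(interpolate_vector_field(ramp, c(2.5, 0, 0))[1, 1], 2.5)
  # node identity
  expect_equal(interpolate_vector_field(ramp, ctr[17, , drop = FALSE]),
               matrix(c(ctr[17, 1], 0, 0), 1))
  # clamping: outside query equals its clamped version
  far <- interpolate_vector_field(ramp, c(99, -50, 100))
  clamped <- interpolate_vector_field(ramp, c(4, 0, 6))
  expect_equal(far, clamped)
  expect_error(interpolate_vector_field(ramp, c(NA, 1, 1)), "finite")
})

test_that("interpolation matches a per-axis brute-force oracle on random fields", {
  for (seed in 1:3) {
    g <- grid_geometry(c(4, 5), spacing = c(1.5, 2), origin = c(-1, 2))
    vec <- withr::with_seed(seed, array(rnorm(prod(g$size) * 2), c(g$size, 2)))
    d <- displacement_field(g, vec)
    qs <- withr::with_seed(seed + 10,
                           cbind(runif(20, -2, 5), runif(20, 1, 12)))
    got <- interpolate_vector_field(d, qs)
    want <- t(apply(qs, 1, function(q) brute_force_interp(vec, g, q)))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("point-set CSV round trip preserves values and defaults weights", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "ps.csv")
  writeLines(c("id,x,y,z", "a,1.25,2,3", "b,4,5,6", "c,7,8,9.125"), f)
  ps <- read_point_set(f)
  expect_equal(ps$weights, c(1, 1, 1))
  expect_equal(ps$coords[1, ], c(1.25, 2, 3))
  ps2 <- withr::with_seed(4, point_set(matrix(rnorm(30), 10),
                                       weights = runif(10, 0.1, 3)))
  f2 <- file.path(dir, "rt.csv")
  write_point_set(ps2, f2)
  back <- read_point_set(f2)
  expect_identical(back$coords, ps2$coords)
  expect_identical(back$weights, ps2$weights)
  expect_identical(back$ids, ps2$ids)
})

test_that("malformed point-set files are rejected with the offending row", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "bad.csv")
  writeLines(c("id,x,y,z", "a,1,2,3", "a,4,5,6"), f)
  expect_error(read_point_set(f), "duplicate id 'a' at data row 2")
  writeLines(c("id,x,y,z", "a,1,2,3", "b,oops,5,6"), f)
  expect_error(read_point_set(f), "non-numeric 'x' at data row 2")
  writeLines(c("foo,x,y", "a,1,2"), f)
  expect_error(read_point_set(f), "header")
})

test_that("displacement and velocity fields round-trip through NIfTI", {
  dir <- withr::local_tempdir()
  g <- grid_geometry(c(6, 5, 4), spacing = c(50, 50, 50), origin = c(2, -3, 0))
  vec <- withr::with_seed(5, array(rnorm(prod(g$size) * 3), c(g$size, 3)))
  d <- displacement_field(g, vec)
  f <- file.path(dir, "disp.nii")
  write_field(d, f)
  back <- read_field(f)
  expect_s3_class(back, "displacement_field")
  expect_equal(back$geometry$spacing, g$spacing)
  expect_equal(back$geometry$origin, g$origin)
  expect_equal(back$vectors, vec, tolerance = 1e-6) # 32-bit storage
  # zero velocity field with N = 2
  v <- velocity_field(g, n_integration_points = 2,
                      meta = list(step_size = 0.2, iterations_run = 0,
                                  convergence_trace = list(average_error = numeric(0))))
  fv <- file.path(dir, "vel.nii")
  write_field(v, fv)
  vb <- read_field(fv)
  expect_s3_class(vb, "velocity_field")
  expect_equal(vb$n_slices, 2L)
  expect_true(all(vb$slices == 0))
  expect_equal(vb$meta$step_size, 0.2)
})

test_that("velocity fields demand a consistent sidecar", {
  dir <- withr::local_tempdir()
  g <- grid_geometry(c(5, 4, 3))
  v <- velocity_field(g, n_integration_points = 3)
  fv <- file.path(dir, "v.nii")
  write_field(v, fv)
  side <- file.path(dir, "v.json")
  # missing sidecar
  file.remove(side)
  expect_error(read_field(fv), "sidecar")
  # inconsistent N
  write_field(v, fv)
  j <- jsonlite::read_json(side, simplifyVector = TRUE)
  j$n_integration_points <- 7
  jsonlite::write_json(j, side, auto_unbox = TRUE)
  expect_error(read_field(fv), "disagrees")
  # inconsistent geometry
  j$n_integration_points <- 3
  j$geometry$spacing <- c(2, 2, 2)
  jsonlite::write_json(j, side, auto_unbox = TRUE)
  expect_error(read_field(fv), "geometry mismatch")
})

test_that("scalar volumes round-trip and label volumes stay integer", {
  dir <- withr::local_tempdir()
  g <- grid_geometry(c(7, 6, 5), spacing = c(2, 2, 2))
  img <- image_volume(g, array(withr::with_seed(6, runif(prod(g$size))),
                               g$size))
  f <- file.path(dir, "img.nii")
  write_volume(img, f)
  back <- read_volume(f)
  expect_equal(back$data, img$data, tolerance = 1e-6)
  lv <- label_volume(g, array(sample(0:3, prod(g$size), TRUE), g$size))
  fl <- file.path(dir, "lab.nii")
  write_volume(lv, fl)
  lb <- read_volume(fl, type = "label")
  expect_identical(lb$labels, lv$labels)
})
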