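#' A multi-label volume on a grid
#'
#' @param geometry a [grid_geometry()].
#' @param labels integer array of dimension `size`; 0 is background.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(geometry, labels) {
  stopifnot(inherits(geometry, "grid_geometry"))
  if (!identical(dim(labels), geometry$size)) {
    stop("label_volume: label dims must equal geometry size")
  }
  if (any(is.na(labels)) || any(labels < 0)) {
    stop("label_volume: labels must be non-negative integers")
  }
  storage.mode(labels) <- "integer"
  structure(list(geometry = geometry, labels = labels), class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  u <- sort(unique(as.vector(x$labels)))
  cat(sprintf("<label_volume> %dD on [%s], labels: %s\n", x$geometry$D,
              paste(x$geometry$size, collapse = ", "),
              paste(utils::head(u, 10), collapse = ", ")))
  invisible(x)
}

#' Configuration of label-guided point sampling
#'
#' Defaults follow the atlas point-extraction recipe: 10% of each label's
#' boundary voxels, 1% of its interior voxels, with boundary points weighted
#' twice as heavily as interior points during optimization.
#'
#' @param contour_rate fraction of boundary voxels sampled per label, in
#'   `[0, 1]` (0 disables the stratum); default 0.10.
#' @param region_rate fraction of interior voxels sampled per label; default
#'   0.01.
#' @param boundary_weight weight of boundary points; default 2.
#' @param interior_weight weight of interior points; default 1.
#' @param seed RNG seed making the sampling reproducible; default 1.
#' @return An object of class `sampling_config`.
#' @export
sampling_config <- function(contour_rate = 0.10, region_rate = 0.01,
                            boundary_weight = 2.0, interior_weight = 1.0,
                            seed = 1L) {
  if (contour_rate < 0 || contour_rate > 1 || region_rate < 0 || region_rate > 1) {
    stop("sampling_config: rates must lie in [0, 1]")
  }
  if (boundary_weight <= 0 || interior_weight <= 0) {
    stop("sampling_config: weights must be positive")
  }
  structure(list(contour_rate = contour_rate, region_rate = region_rate,
                 boundary_weight = boundary_weight,
                 interior_weight = interior_weight, seed = as.integer(seed)),
            class = "sampling_config")
}

# Shift an array along one axis by +-1, filling vacated entries with 'fill'.
shift_array <- function(a, axis, by, fill = 0L) {
  n <- dim(a)
  idx <- lapply(n, seq_len)
  src <- idx
  src[[axis]] <- idx[[axis]] - by
  keep <- src[[axis]] >= 1L & src[[axis]] <= n[axis]
  out <- array(fill, dim = n)
  dst <- idx
  dst[[axis]] <- idx[[axis]][keep]
  src[[axis]] <- src[[axis]][keep]
  out_sub <- do.call(`[`, c(list(a), src, list(drop = FALSE)))
  out <- do.call(`[<-`, c(list(out), dst, list(value = out_sub)))
  out
}

# Face-adjacency (6-connectivity in 3-D, 4 in 2-D) boundary mask: a labeled
# voxel is boundary if any face neighbor carries a different label; positions
# outside the volume count as background.
boundary_mask <- function(labels) {
  D <- length(dim(labels))
  differs <- array(FALSE, dim = dim(labels))
  for (a in seq_len(D)) {
    for (by in c(-1L, 1L)) {
      differs <- differs | (labels != shift_array(labels, a, by, fill = 0L))
    }
  }
  differs & labels > 0L
}

sample_count <- function(n, rate) {
  if (n == 0L || rate == 0) return(0L)
  max(1L, as.integer(round(rate * n)))
}

#' Sample weighted points from a label volume
#'
#' Per label, boundary voxels (any face-adjacent neighbor carrying a
#' different label, background included) are sampled without replacement at
#' `contour_rate` and the remaining interior voxels at `region_rate`; sample
#' counts are `round(rate * count)` with a minimum of 1 whenever the stratum
#' is non-empty and its rate positive.  Point coordinates are voxel centers
#' in physical space; ids encode label, stratum, and index; the draw is
#' deterministic given `config$seed`.
#'
#' @param volume a [label_volume()] with at least one non-zero voxel.
#' @param config a [sampling_config()].
#' @return a [point_set()] with a `manifest` attribute recording per-label
#'   counts, the rates, and the seed.
#' @export
sample_label_points <- function(volume, config = sampling_config()) {
  stopifnot(inherits(volume, "label_volume"), inherits(config, "sampling_config"))
  labels <- volume$labels
  present <- sort(unique(as.vector(labels)))
  present <- present[present > 0L]
  if (length(present) == 0L) {
    stop("sample_label_points: the label map is empty (all background)")
  }
  bmask <- boundary_mask(labels)
  g <- volume$geometry
  strides <- cumprod(c(1, g$size))[seq_len(g$D)]
  pick <- withr::with_seed(config$seed, {
    lapply(present, function(l) {
      lv <- labels == l
      bidx <- which(lv & bmask)
      iidx <- which(lv & !bmask)
      nb <- sample_count(length(bidx), config$contour_rate)
      ni <- sample_count(length(iidx), config$region_rate)
      list(label = l,
           boundary = sort(bidx[sample.int(length(bidx), nb)]),
           interior = if (ni > 0L) sort(iidx[sample.int(length(iidx), ni)]) else integer(0))
    })
  })
  lin_to_phys <- function(lin) {
    sub <- arrayInd(lin, g$size)
    sweep(sweep(sub - 1, 2, g$spacing, "*"), 2, g$origin, "+")
  }
  coords <- NULL; ids <- character(0); weights <- numeric(0)
  manifest <- list(seed = config$seed,
                   contour_rate = config$contour_rate,
                   region_rate = config$region_rate,
                   labels = list())
  for (p in pick) {
    nb <- length(p$boundary); ni <- length(p$interior)
    if (nb > 0L) {
      coords <- rbind(coords, lin_to_phys(p$boundary))
      ids <- c(ids, sprintf("L%d_boundary_%d", p$label, seq_len(nb)))
      weights <- c(weights, rep(config$boundary_weight, nb))
    }
    if (ni > 0L) {
      coords <- rbind(coords, lin_to_phys(p$interior))
      ids <- c(ids, sprintf("L%d_interior_%d", p$label, seq_len(ni)))
      weights <- c(weights, rep(config$interior_weight, ni))
    }
    manifest$labels[[as.character(p$label)]] <-
      list(boundary = nb, interior = ni)
  }
  if (is.null(coords)) {
    stop("sample_label_points: both sampling rates are zero; nothing sampled")
  }
  out <- point_set(coords, ids = ids, weights = weights)
  attr(out, "manifest") <- manifest
  out
}

#' Translation aligning the shared-label centroid of one volume to another's
#'
#' The centroid-based rigid pre-normalization of atlas stages, reduced to a
#' pure translation: the difference between the physical centroids of the
#' voxels carrying labels present in both volumes.  Apply it to points living
#' in `moving`'s space (e.g. via the `pre_translation` argument of
#' [propagate_points()]) to shift them into `fixed`'s space.
#'
#' @param moving,fixed [label_volume()] objects sharing at least one label.
#' @return numeric translation vector, `centroid(fixed) - centroid(moving)`.
#' @export
label_centroid_translation <- function(moving, fixed) {
  stopifnot(inherits(moving, "label_volume"), inherits(fixed, "label_volume"))
  shared <- intersect(unique(as.vector(moving$labels)),
                      unique(as.vector(fixed$labels)))
  shared <- shared[shared > 0L]
  if (length(shared) == 0L) {
    stop("label_centroid_translation: the volumes share no labels")
  }
  centroid <- function(v) {
    lin <- which(array(v$labels %in% shared, dim = dim(v$labels)))
    sub <- arrayInd(lin, v$geometry$size)
    colMeans(sweep(sweep(sub - 1, 2, v$geometry$spacing, "*"),
                   2, v$geometry$origin, "+"))
  }
  unname(centroid(fixed) - centroid(moving))
}

#' Propagate points through an ordered chain of displacement fields
#'
#' Each displacement is interpolated at the current position and added, in
#' order — this is how a point set sampled in one atlas space is carried to
#' every other stage through externally supplied pairwise registrations,
#' constructing the cross-stage correspondence the flow fit consumes.  Ids
#' and weights are preserved.
#'
#' @param points a [point_set()].
#' @param transforms list of [displacement_field()] objects (possibly empty),
#'   applied first to last.
#' @param pre_translation optional D-vector added to all points before the
#'   chain (see [label_centroid_translation()]).
#' @return a [point_set()].
#' @export
propagate_points <- function(points, transforms, pre_translation = NULL) {
  stopifnot(inherits(points, "point_set"))
  coords <- points$coords
  if (!is.null(pre_translation)) {
    coords <- sweep(coords, 2, as.double(pre_translation), "+")
  }
  for (d in transforms) {
    stopifnot(inherits(d, "displacement_field"))
    coords <- coords + interp_core(d$vectors, d$geometry, coords)
  }
  point_set(coords, ids = points$ids, weights = points$weights)
}

#' Construct a virtual template at an intermediate time point
#'
#' Each input image is warped from its own normalized time to `target_time`
#' through the velocity field and the warped images are combined voxelwise —
#' either a uniform mean or temporal weights proportional to
#' `1 / |t_image - target_time|` (normalized to sum 1, with an exact-match
#' short-circuit returning the coinciding input).  No registration-based
#' shape refinement is performed; the output is a plain weighted average of
#' the pre-warped images.
#'
#' @param images list of [image_volume()] objects on `v`'s geometry.
#' @param times normalized time of each image, in `[0, 1]`.
#' @param target_time normalized time of the synthesized template.
#' @param v a [velocity_field()].
#' @param weighting `"temporal"` (default) or `"uniform"`.
#' @param substeps integration substeps per slice interval; default 4.
#' @return an [image_volume()] at `target_time`.
#' @export
make_virtual_template <- function(images, times, target_time, v,
                                  weighting = c("temporal", "uniform"),
                                  substeps = 4) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(v, "velocity_field"), is.list(images), length(images) >= 1L)
  times <- as.double(times)
  if (length(times) != length(images)) {
    stop("make_virtual_template: one time per image required")
  }
  check_time_range(times, target_time)
  for (img in images) {
    if (!inherits(img, "image_volume") || !same_geometry(img$geometry, v$geometry)) {
      stop("make_virtual_template: all images must be image_volume objects on ",
           "the velocity field's geometry")
    }
  }
  if (weighting == "temporal") {
    hit <- which(times == target_time)
    if (length(hit) > 0L) return(images[[hit[1]]])
    w <- 1 / abs(times - target_time)
  } else {
    w <- rep(1, length(images))
  }
  w <- w / sum(w)
  acc <- array(0, dim = v$geometry$size)
  for (k in seq_along(images)) {
    warped <- transform_image_in_time(images[[k]], v, times[k], target_time,
                                      interpolation = "linear",
                                      substeps = substeps)
    acc <- acc + w[k] * warped$data
  }
  image_volume(v$geometry, acc)
}
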