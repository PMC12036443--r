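#' A weighted point set with stable identifiers
#'
#' Points carry physical coordinates (same unit as the grid geometry they are
#' used with), a positive per-point confidence weight, and a unique id.
#' Correspondence across point sets is positional: row `j` in every set of a
#' series refers to the same anatomical sample.
#'
#' @param coords numeric M x D matrix of physical coordinates (M >= 1).
#' @param ids character vector of M unique identifiers; default `p1..pM`.
#' @param weights positive numeric vector of length M; default all 1.
#' @return An object of class `point_set` with elements `coords`, `ids`,
#'   `weights`.
#' @examples
#' ps <- point_set(matrix(runif(30), ncol = 3))
#' @export
point_set <- function(coords, ids = NULL, weights = NULL) {
  coords <- as_coord_matrix(coords)
  M <- nrow(coords)
  if (M < 1L) stop("point_set: at least one point is required")
  if (any(!is.finite(coords))) stop("point_set: coordinates must be finite")
  if (is.null(ids)) ids <- paste0("p", seq_len(M))
  ids <- as.character(ids)
  if (length(ids) != M) stop("point_set: 'ids' must have one entry per point")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("point_set: duplicate ids: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (is.null(weights)) weights <- rep(1, M)
  weights <- as.double(weights)
  if (length(weights) != M || any(!is.finite(weights)) || any(weights <= 0)) {
    stop("point_set: 'weights' must be ", M, " positive finite values")
  }
  rownames(coords) <- NULL
  structure(list(coords = coords, ids = ids, weights = weights),
            class = "point_set")
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("<point_set> %d points, %dD\n", nrow(x$coords), ncol(x$coords)))
  invisible(x)
}

n_points <- function(ps) nrow(ps$coords)

#' A chronologically ordered series of corresponding point sets
#'
#' All K >= 2 sets must share the same number of points, dimensionality, ids,
#' and weights; `times` are normalized scalars, strictly increasing from
#' exactly 0 to exactly 1 (see [normalize_time_points()] for mapping
#' chronological ages onto this domain).
#'
#' @param sets list of K [point_set()] objects in row correspondence.
#' @param times numeric vector of K normalized times.
#' @return An object of class `point_set_series`.
#' @export
point_set_series <- function(sets, times) {
  if (!is.list(sets) || length(sets) < 2L) {
    stop("point_set_series: need a list of at least 2 point sets")
  }
  if (!all(vapply(sets, inherits, logical(1), "point_set"))) {
    stop("point_set_series: all elements of 'sets' must be point_set objects")
  }
  times <- as.double(times)
  K <- length(sets)
  if (length(times) != K) stop("point_set_series: one time per set required")
  if (any(!is.finite(times)) || any(diff(times) <= 0)) {
    stop("point_set_series: times must be finite and strictly increasing")
  }
  if (times[1] != 0 || times[K] != 1) {
    stop("point_set_series: times must start at exactly 0 and end at exactly 1")
  }
  ref <- sets[[1]]
  for (k in seq_along(sets)[-1]) {
    s <- sets[[k]]
    if (nrow(s$coords) != nrow(ref$coords) || ncol(s$coords) != ncol(ref$coords)) {
      stop("point_set_series: set ", k, " has a different shape than set 1")
    }
    if (!identical(s$ids, ref$ids)) {
      stop("point_set_series: set ", k, " ids differ from set 1")
    }
    if (!isTRUE(all.equal(s$weights, ref$weights, tolerance = 1e-12))) {
      stop("point_set_series: set ", k, " weights differ from set 1")
    }
  }
  structure(list(sets = sets, times = times), class = "point_set_series")
}

#' @export
print.point_set_series <- function(x, ...) {
  cat(sprintf("<point_set_series> K = %d sets of %d points (%dD), times [%s]\n",
              length(x$sets), nrow(x$sets[[1]]$coords), ncol(x$sets[[1]]$coords),
              paste(format(x$times, digits = 3), collapse = ", ")))
  invisible(x)
}

#' Read a point set from CSV
#'
#' Expects a header `id,x,y,z` or `id,x,y` with an optional trailing `weight`
#' column; a missing weight column assigns weight 1 to every point.
#'
#' @param path file path.
#' @return a [point_set()].
#' @export
read_point_set <- function(path) {
  if (!file.exists(path)) stop("read_point_set: no such file: ", path)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  nms <- names(df)
  ok2 <- identical(nms, c("id", "x", "y")) ||
    identical(nms, c("id", "x", "y", "weight"))
  ok3 <- identical(nms, c("id", "x", "y", "z")) ||
    identical(nms, c("id", "x", "y", "z", "weight"))
  if (!ok2 && !ok3) {
    stop("read_point_set: header must be id,x,y[,z][,weight]; got: ",
         paste(nms, collapse = ","))
  }
  coord_cols <- if (ok3) c("x", "y", "z") else c("x", "y")
  ids <- df$id
  if (anyDuplicated(ids)) {
    row <- which(duplicated(ids))[1]
    stop("read_point_set: duplicate id '", ids[row], "' at data row ", row)
  }
  coords <- matrix(NA_real_, nrow(df), length(coord_cols))
  for (j in seq_along(coord_cols)) {
    v <- suppressWarnings(as.numeric(df[[coord_cols[j]]]))
    if (any(is.na(v))) {
      row <- which(is.na(v))[1]
      stop("read_point_set: non-numeric '", coord_cols[j], "' at data row ",
           row, " (value '", df[[coord_cols[j]]][row], "')")
    }
    coords[, j] <- v
  }
  weights <- NULL
  if ("weight" %in% nms) {
    weights <- suppressWarnings(as.numeric(df$weight))
    if (any(is.na(weights))) {
      row <- which(is.na(weights))[1]
      stop("read_point_set: non-numeric weight at data row ", row)
    }
  }
  point_set(coords, ids = ids, weights = weights)
}

#' Write a point set to CSV
#'
#' Coordinates and weights are printed with 17 significant digits so that a
#' read/write round trip preserves values exactly.
#'
#' @param set a [point_set()].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_point_set <- function(set, path) {
  stopifnot(inherits(set, "point_set"))
  D <- ncol(set$coords)
  header <- c("id", c("x", "y", "z")[seq_len(D)], "weight")
  num <- cbind(set$coords, set$weights)
  body <- apply(num, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(c(paste(header, collapse = ","), paste(set$ids, body, sep = ",")),
             path)
  invisible(path)
}
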