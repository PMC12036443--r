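#' Normalize chronological ages onto the [0, 1] fitting domain
#'
#' Developmental stages are unevenly spaced in chronological days, with the
#' gaps growing postnatally.  Taking the logarithm of the (adjusted) ages
#' before min-max normalization evens out the temporal sampling, so each
#' atlas interval covers a comparable share of the normalized domain.
#'
#' @param raw_days strictly increasing chronological values (days); all must
#'   be positive when `use_log` is `TRUE`.
#' @param use_log apply the log transform before normalization; default `TRUE`.
#' @return An object of class `time_map` with `raw_days`, `use_log`, and
#'   `normalized` (endpoints map to exactly 0 and 1).
#' @examples
#' tm <- normalize_time_points(devccf_default_days())
#' tm$normalized
#' @export
normalize_time_points <- function(raw_days, use_log = TRUE) {
  raw_days <- as.double(raw_days)
  if (length(raw_days) < 2L) stop("normalize_time_points: need at least 2 values")
  if (any(!is.finite(raw_days)) || any(diff(raw_days) <= 0)) {
    stop("normalize_time_points: 'raw_days' must be finite and strictly increasing")
  }
  if (use_log && any(raw_days <= 0)) {
    stop("normalize_time_points: all values must be positive when 'use_log'")
  }
  s <- if (use_log) log(raw_days) else raw_days
  normalized <- (s - s[1]) / (s[length(s)] - s[1])
  normalized[1] <- 0
  normalized[length(normalized)] <- 1
  structure(list(raw_days = raw_days, use_log = use_log,
                 normalized = normalized),
            class = "time_map")
}

#' @export
print.time_map <- function(x, ...) {
  cat(sprintf("<time_map> %d stages, %s scale\n  days: %s\n  norm: %s\n",
              length(x$raw_days), if (x$use_log) "log" else "linear",
              paste(format(x$raw_days), collapse = ", "),
              paste(format(round(x$normalized, 4)), collapse = ", ")))
  invisible(x)
}

#' Map arbitrary chronological ages through a time map
#'
#' @param days chronological values within the map's span.
#' @param map a `time_map` from [normalize_time_points()].
#' @return normalized times.
#' @export
normalize_time <- function(days, map) {
  stopifnot(inherits(map, "time_map"))
  days <- as.double(days)
  if (map$use_log && any(days <= 0)) {
    stop("normalize_time: days must be positive on a log-scale map")
  }
  s <- if (map$use_log) log(days) else days
  lo <- if (map$use_log) log(map$raw_days[1]) else map$raw_days[1]
  hi <- if (map$use_log) log(map$raw_days[length(map$raw_days)]) else
    map$raw_days[length(map$raw_days)]
  (s - lo) / (hi - lo)
}

#' Map normalized times back to chronological ages
#'
#' Exact inverse of [normalize_time()]; `denormalize_time(0, map)` is the
#' first raw day and `denormalize_time(1, map)` the last.
#'
#' @param t_normalized values in `[0, 1]`.
#' @param map a `time_map` from [normalize_time_points()].
#' @return chronological values (days).
#' @export
denormalize_time <- function(t_normalized, map) {
  stopifnot(inherits(map, "time_map"))
  t_normalized <- as.double(t_normalized)
  if (any(!is.finite(t_normalized)) || any(t_normalized < 0) ||
      any(t_normalized > 1)) {
    stop("denormalize_time: normalized times must lie in [0, 1]")
  }
  K <- length(map$raw_days)
  if (map$use_log) {
    lo <- log(map$raw_days[1]); hi <- log(map$raw_days[K])
    exp(lo + t_normalized * (hi - lo))
  } else {
    map$raw_days[1] + t_normalized * (map$raw_days[K] - map$raw_days[1])
  }
}

#' Offset (days) at which postnatal ages are placed on the embryonic scale
#'
#' Postnatal day d is placed at `18.5 + d` continuous days, i.e. birth
#' (P0) coincides with embryonic day E18.5 for the atlas strain's sampled
#' stages.  This concatenation constant is a documented package convention,
#' exposed so it can be overridden in [devccf_default_days()].
#'
#' @return 18.5
#' @export
devccf_postnatal_offset_days <- function() 18.5

#' Default chronological ages of the seven developmental atlas stages
#'
#' Embryonic stages keep their E-day values; postnatal stage Pd is placed at
#' `postnatal_offset + d` days, with P56 replaced by P28 — an adjustment that
#' reflects how little mouse brain shape changes after the fourth postnatal
#' week, and which compresses the otherwise dominant final gap.
#'
#' @param postnatal_offset days added to postnatal ages; default
#'   [devccf_postnatal_offset_days()].
#' @return named numeric vector for (E11.5, E13.5, E15.5, E18.5, P4, P14,
#'   P56): (11.5, 13.5, 15.5, 18.5, 22.5, 32.5, 46.5) under the defaults.
#' @examples
#' normalize_time_points(devccf_default_days())$normalized
#' @export
devccf_default_days <- function(postnatal_offset = devccf_postnatal_offset_days()) {
  c(E11.5 = 11.5, E13.5 = 13.5, E15.5 = 15.5, E18.5 = 18.5,
    P4 = postnatal_offset + 4, P14 = postnatal_offset + 14,
    P56 = postnatal_offset + 28) # P56 enters as 28 days
}
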