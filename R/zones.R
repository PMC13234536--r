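#' Discretization zones and calibration
#'
#' Each gesture zone is an interval on the 0-1023 device axis. A zone spans
#' from its minimum value up to (but excluding) the next zone's minimum, the
#' topmost zone extending to 1024. The peak of a detected contraction selects
#' the zone whose interval contains it; peaks below the first minimum select
#' nothing.
#'
#' @name zones
NULL

#' Construct a validated threshold set
#'
#' @param zone_minimums Strictly increasing integer vector of zone minimums,
#'   all strictly greater than `resting`, in `[0, 1024]`.
#' @param resting Resting threshold in `[0, 1023]`.
#' @param global_scale Positive calibration scale (applied to the envelope
#'   before quantization; minimums live on the post-scale axis).
#' @return A `threshold_set`.
#' @examples
#' threshold_set(c(24, 224, 424, 624, 824), resting = 23)
#' @export
threshold_set <- function(zone_minimums, resting, global_scale = 1) {
  stopifnot(is.numeric(zone_minimums), length(zone_minimums) >= 1L,
            is.numeric(resting), length(resting) == 1L,
            is.numeric(global_scale), length(global_scale) == 1L)
  zone_minimums <- as.integer(zone_minimums)
  resting <- as.integer(resting)
  if (resting < 0 || resting > 1023) stop("resting must lie in [0, 1023]")
  if (any(zone_minimums < 0) || any(zone_minimums > 1024)) {
    stop("zone minimums must lie in [0, 1024]")
  }
  if (any(diff(zone_minimums) <= 0)) {
    stop("zone minimums must be strictly increasing")
  }
  if (zone_minimums[1L] <= resting) {
    stop("the first zone minimum must exceed the resting threshold")
  }
  if (!is.finite(global_scale) || global_scale <= 0) {
    stop("global_scale must be a positive finite number")
  }
  structure(list(zone_minimums = zone_minimums, resting = resting,
                 top_bound = 1024L, global_scale = global_scale),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  b <- zone_bounds(x)
  cat(sprintf("<threshold_set: %d zone%s, resting %d, scale %.4g>\n",
              n_zones(x), if (n_zones(x) == 1L) "" else "s",
              x$resting, x$global_scale))
  for (i in seq_len(nrow(b))) {
    cat(sprintf("  zone %d: [%d, %d)\n", b$zone[i], b$lower[i], b$upper[i]))
  }
  invisible(x)
}

#' Number of zones in a threshold set
#' @param thresholds A [threshold_set()].
#' @export
n_zones <- function(thresholds) length(thresholds$zone_minimums)

#' Zone interval bounds
#'
#' @param thresholds A [threshold_set()].
#' @return Data.frame with `zone`, `lower` (inclusive), `upper` (exclusive;
#'   1024 for the top zone).
#' @export
zone_bounds <- function(thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"))
  mins <- thresholds$zone_minimums
  data.frame(zone = seq_along(mins), lower = mins,
             upper = c(mins[-1L], thresholds$top_bound))
}

#' Zone interval midpoints
#' @inheritParams zone_bounds
#' @return Numeric vector of zone centers `(lower + upper) / 2`.
#' @export
zone_centers <- function(thresholds) {
  b <- zone_bounds(thresholds)
  (b$lower + b$upper) / 2
}

#' Equal-width initial segmentation
#'
#' Zones are initially segmented equally above the resting threshold: the
#' first minimum sits just above resting (`resting + 1`), consecutive minimums
#' differ by `round((1024 - first) / n_zones)`, and the final zone extends to
#' 1024, absorbing any rounding remainder.
#'
#' @param n_zones Number of zones (>= 1).
#' @param resting Resting threshold in `[0, 1022]`.
#' @param global_scale Calibration scale carried into the result.
#' @return A [threshold_set()].
#' @examples
#' make_equal_zones(5, resting = 23)$zone_minimums # 24 224 424 624 824
#' @export
make_equal_zones <- function(n_zones, resting, global_scale = 1) {
  stopifnot(is.numeric(n_zones), length(n_zones) == 1L)
  if (n_zones < 1 || n_zones != as.integer(n_zones)) {
    stop("n_zones must be a positive integer")
  }
  if (resting >= 1023) stop("resting must be below 1023")
  first <- as.integer(resting) + 1L
  width <- as.integer(round_half_away((1024 - first) / n_zones))
  mins <- first + width * (seq_len(n_zones) - 1L)
  threshold_set(mins, resting = resting, global_scale = global_scale)
}

#' Map a contraction peak to its zone
#'
#' Returns the unique zone `i` with `minimum_i <= peak < minimum_{i+1}`
#' (taking `minimum_{K+1} = 1024`), or `NA` if the peak falls below the first
#' minimum. Boundary membership is closed at the minimum: a peak exactly equal
#' to a zone's minimum belongs to that zone.
#'
#' @param peak Integer vector of peaks in `[0, 1023]`.
#' @param thresholds A [threshold_set()].
#' @return Integer vector of zone indices (`NA` = sub-threshold).
#' @examples
#' ts <- make_equal_zones(5, resting = 23)
#' assign_zone(c(10, 224, 1023), ts)
#' @export
assign_zone <- function(peak, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"), is.numeric(peak))
  if (length(peak) && (min(peak, na.rm = TRUE) < 0 ||
                       max(peak, na.rm = TRUE) > 1023)) {
    stop("peaks must lie in [0, 1023]")
  }
  z <- findInterval(peak, thresholds$zone_minimums)
  z[z == 0L] <- NA_integer_
  as.integer(z)
}

#' Calibrate the global scale from a maximum voluntary contraction
#'
#' The calibration "zoom" rescales the envelope so that the observed MVC peak
#' lands at `target_fraction` of the top of the device scale: a repeat of the
#' same contraction, rescaled and quantized, reads
#' `round(target_fraction * 1023)`.
#'
#' @param mvc_peak Observed MVC peak on the pre-scale axis (>= 1).
#' @param target_fraction Fraction of full scale the MVC should reach,
#'   in `(0, 1]`.
#' @return A `calibration_result` list with `global_scale`, `mvc_peak`,
#'   `target_fraction`.
#' @examples
#' calibrate(512)$global_scale # ~1.998
#' @export
calibrate <- function(mvc_peak, target_fraction = 1) {
  stopifnot(is.numeric(mvc_peak), length(mvc_peak) == 1L,
            is.numeric(target_fraction), length(target_fraction) == 1L)
  if (mvc_peak < 1) stop("no measurable contraction: mvc_peak must be >= 1")
  if (target_fraction <= 0 || target_fraction > 1) {
    stop("target_fraction must lie in (0, 1]")
  }
  structure(list(global_scale = target_fraction * 1023 / mvc_peak,
                 mvc_peak = mvc_peak, target_fraction = target_fraction),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration: mvc_peak %s, target %.2f, global_scale %.4f>\n",
              format(x$mvc_peak), x$target_fraction, x$global_scale))
  invisible(x)
}

#' Serialize / load a threshold set
#'
#' YAML round-trip of `resting`, `zone_minimums`, `global_scale`; validated on
#' load via [threshold_set()].
#'
#' @param thresholds A [threshold_set()].
#' @param path File path.
#' @export
write_threshold_set <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "threshold_set"))
  yaml::write_yaml(list(resting = thresholds$resting,
                        zone_minimums = thresholds$zone_minimums,
                        global_scale = thresholds$global_scale), path)
  invisible(path)
}

#' @rdname write_threshold_set
#' @export
read_threshold_set <- function(path) {
  x <- yaml::read_yaml(path)
  for (f in c("resting", "zone_minimums", "global_scale")) {
    if (is.null(x[[f]])) stop("threshold config missing field: ", f)
  }
  threshold_set(x$zone_minimums, resting = x$resting,
                global_scale = x$global_scale)
}
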