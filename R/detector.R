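#' Flex detection: resting-baseline gated contraction segmentation
#'
#' A "flex" is one contraction episode: once the processed signal rises above
#' the resting threshold, every sample is recorded until the signal dips below
#' the threshold again, at which point the running maximum is emitted as the
#' contraction's peak. A sample exactly equal to the resting threshold neither
#' opens nor closes a contraction (opening requires strictly greater, closing
#' strictly less).
#'
#' @name flex-detection
NULL

#' Fresh detector state
#'
#' @return A `detector_state` list with `phase` (`"idle"` or `"active"`),
#'   `current_max` and `start_index` (both `NA` while idle).
#' @export
detector_state <- function() {
  structure(list(phase = "idle", current_max = NA_integer_,
                 start_index = NA_integer_, index = 0L),
            class = "detector_state")
}

#' Advance the detector by one sample
#'
#' @param state A [detector_state()].
#' @param sample Integer sample in `[0, 1023]`.
#' @param resting Resting threshold in `[0, 1023]`.
#' @return List with `state` (updated) and `event` (`NULL`, or a one-row
#'   data.frame with `start`, `end`, `peak` when a contraction closed).
#' @export
detector_step <- function(state, sample, resting) {
  stopifnot(inherits(state, "detector_state"),
            sample >= 0, sample <= 1023, resting >= 0, resting <= 1023)
  i <- state$index + 1L
  state$index <- i
  event <- NULL
  if (state$phase == "idle") {
    if (sample > resting) {
      state$phase <- "active"
      state$current_max <- as.integer(sample)
      state$start_index <- i
    }
  } else {
    if (sample < resting) {
      event <- data.frame(start = state$start_index, end = i - 1L,
                          peak = state$current_max)
      state$phase <- "idle"
      state$current_max <- NA_integer_
      state$start_index <- NA_integer_
    } else {
      state$current_max <- max(state$current_max, as.integer(sample))
    }
  }
  list(state = state, event = event)
}

#' Force-emit an open contraction
#'
#' In batch mode a contraction still open at end-of-stream emits nothing (the
#' peak is only defined once the signal has dipped below resting); interactive
#' callers may flush instead.
#'
#' @inheritParams detector_step
#' @return Same shape as [detector_step()].
#' @export
detector_flush <- function(state) {
  stopifnot(inherits(state, "detector_state"))
  event <- NULL
  if (state$phase == "active") {
    event <- data.frame(start = state$start_index, end = state$index,
                        peak = state$current_max)
    state$phase <- "idle"
    state$current_max <- NA_integer_
    state$start_index <- NA_integer_
  }
  list(state = state, event = event)
}

#' Detect all flexes in a processed stream
#'
#' @param values Integer vector in `[0, 1023]` (a processed stream).
#' @param resting Resting threshold in `[0, 1023]`.
#' @param flush If `TRUE`, a contraction still open at end-of-stream is
#'   emitted with `end` at the final sample.
#' @return A data.frame with columns `start`, `end`, `peak` (1-based sample
#'   indices; `end` is the last sample at-or-above resting), ordered by
#'   `start`. Every `peak` is strictly greater than `resting`.
#' @examples
#' detect_flexes(c(10, 50, 300, 700, 400, 20), resting = 100)
#' @export
detect_flexes <- function(values, resting, flush = FALSE) {
  stopifnot(is.numeric(values), resting >= 0, resting <= 1023)
  if (length(values) && (min(values) < 0 || max(values) > 1023)) {
    stop("processed stream values must lie in [0, 1023]")
  }
  starts <- integer(0); ends <- integer(0); peaks <- integer(0)
  phase_active <- FALSE
  cur_max <- NA_integer_; cur_start <- NA_integer_
  for (i in seq_along(values)) {
    s <- values[[i]]
    if (!phase_active) {
      if (s > resting) {
        phase_active <- TRUE
        cur_max <- s
        cur_start <- i
      }
    } else {
      if (s < resting) {
        starts <- c(starts, cur_start); ends <- c(ends, i - 1L)
        peaks <- c(peaks, cur_max)
        phase_active <- FALSE
      } else if (s > cur_max) {
        cur_max <- s
      }
    }
  }
  if (flush && phase_active) {
    starts <- c(starts, cur_start); ends <- c(ends, length(values))
    peaks <- c(peaks, cur_max)
  }
  data.frame(start = as.integer(starts), end = as.integer(ends),
             peak = as.integer(peaks))
}

#' Write a flex event log
#'
#' @param events Data.frame from [detect_flexes()].
#' @param path Output CSV path.
#' @param resting Resting threshold used, recorded per row.
#' @export
write_flex_log <- function(events, path, resting) {
  out <- data.frame(start_index = events$start, end_index = events$end,
                    peak = events$peak, resting = resting,
                    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
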