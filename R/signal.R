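#' Signal conditioning for single-channel surface EMG
#'
#' The device reports muscle activity as integers on a 0-1023 scale. The
#' conditioning chain is: full-wave rectification, a 2 Hz high-pass
#' (order-2 Butterworth, removing electrode DC offset and drift), a
#' moving-average envelope (default 50 ms), an optional global "zoom" scale
#' set during calibration, and quantization onto the device scale.
#'
#' @name signal-conditioning
NULL

#' Filter configuration for the EMG conditioning chain
#'
#' @param highpass_hz High-pass corner frequency in Hz. Must lie below the
#'   Nyquist frequency of the signal it is applied to.
#' @param smoothing_window_ms Moving-average envelope window in milliseconds;
#'   `0` disables smoothing.
#' @param filter_order Butterworth order of the high-pass stage.
#' @return A `filter_config` list.
#' @examples
#' filter_config()
#' @export
filter_config <- function(highpass_hz = 2, smoothing_window_ms = 50,
                          filter_order = 2) {
  stopifnot(
    is.numeric(highpass_hz), length(highpass_hz) == 1L, highpass_hz > 0,
    is.numeric(smoothing_window_ms), length(smoothing_window_ms) == 1L,
    smoothing_window_ms >= 0,
    is.numeric(filter_order), length(filter_order) == 1L,
    filter_order >= 1, filter_order == as.integer(filter_order)
  )
  structure(
    list(highpass_hz = highpass_hz,
         smoothing_window_ms = smoothing_window_ms,
         filter_order = as.integer(filter_order)),
    class = "filter_config"
  )
}

#' Full-wave rectification
#'
#' @param x Numeric vector of raw EMG samples (arbitrary units).
#' @return `abs(x)`, same length.
#' @examples
#' rectify(c(-3, 2, 0))
#' @export
rectify <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  abs(x)
}

# warm-up length (samples) demanded before filtering: 3 x the filter order + 1,
# the minimum signal::filter needs for stable initial conditions, with a floor.
filter_warmup_n <- function(cfg) max(3L * (cfg$filter_order + 1L), 9L)

#' High-pass filter and envelope smoothing
#'
#' Applies a causal order-`filter_order` Butterworth high-pass at
#' `highpass_hz`, then (applied after [rectify()]) a causal moving-average
#' envelope of `smoothing_window_ms`. The high-pass has zero DC gain, so any
#' constant offset decays to numerical zero after the filter transient.
#'
#' @param x Numeric vector of (typically rectified) samples.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param cfg A [filter_config()].
#' @return Numeric vector, same length as `x`.
#' @export
filter_and_smooth <- function(x, sample_rate_hz = 1000, cfg = filter_config()) {
  stopifnot(is.numeric(x), all(is.finite(x)),
            is.numeric(sample_rate_hz), sample_rate_hz > 0)
  if (cfg$highpass_hz >= sample_rate_hz / 2) {
    stop("highpass_hz must be below the Nyquist frequency (sample_rate_hz / 2)")
  }
  if (length(x) < filter_warmup_n(cfg)) {
    stop(sprintf("signal too short to filter: %d samples < warm-up length %d",
                 length(x), filter_warmup_n(cfg)))
  }
  bw <- signal::butter(cfg$filter_order, cfg$highpass_hz / (sample_rate_hz / 2),
                       type = "high")
  y <- as.numeric(signal::filter(bw, x))
  if (cfg$smoothing_window_ms > 0) {
    n_win <- max(1L, round(cfg$smoothing_window_ms * sample_rate_hz / 1000))
    # causal moving average: mean of the current and previous n_win - 1 samples
    cs <- cumsum(y)
    lagged <- c(rep(0, n_win), head(cs, -n_win))
    widths <- pmin(seq_along(y), n_win)
    y <- (cs - lagged) / widths
  }
  y
}

#' Quantize onto the 0-1023 device scale
#'
#' Multiplies by the global calibration scale, rounds half away from zero,
#' and clamps into `[0, 1023]`.
#'
#' @param x Numeric vector of envelope values.
#' @param scale Positive global scale (calibration "zoom").
#' @return Integer vector in `[0, 1023]`.
#' @examples
#' quantize(c(2000, -5, 411.6))
#' @export
quantize <- function(x, scale = 1) {
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("quantize() requires finite numeric input")
  }
  as.integer(pmin(1023L, pmax(0L, round_half_away(x * scale))))
}

#' Run the full conditioning chain
#'
#' `rectify -> filter_and_smooth -> quantize`, producing the processed stream
#' on the 0-1023 device scale that the flex detector and zones consume.
#'
#' @inheritParams filter_and_smooth
#' @param global_scale Calibration scale applied before quantization.
#' @return Integer vector in `[0, 1023]`, same length as `x`, with the frame
#'   processing interval attached as attribute `frame_interval_ms`.
#' @export
process_signal <- function(x, sample_rate_hz = 1000, cfg = filter_config(),
                           global_scale = 1) {
  env <- filter_and_smooth(rectify(x), sample_rate_hz, cfg)
  out <- quantize(env, global_scale)
  attr(out, "frame_interval_ms") <- frame_interval_ms()
  out
}

#' Frame processing interval
#'
#' Samples arrive from the controller in ~60 Hz packets but are validated and
#' processed once per rendered frame, capped at 30 Hz; the processing interval
#' is therefore `1000 / 30` = 33.3 ms.
#'
#' @param frame_rate_hz Frame cap in Hz.
#' @return Interval in milliseconds.
#' @examples
#' frame_interval_ms() # 33.33 ms at the 30 Hz cap
#' @export
frame_interval_ms <- function(frame_rate_hz = 30) {
  stopifnot(is.numeric(frame_rate_hz), frame_rate_hz > 0)
  1000 / frame_rate_hz
}

#' Buffer arrival packets into processing frames
#'
#' Packets (arbitrary-length integer vectors, arriving at ~60 Hz) are buffered
#' and consumed in arrival order at each frame tick (30 Hz cap): each frame
#' processes every sample that has arrived since the previous tick, so no
#' sample is dropped or reordered.
#'
#' @param packets List of numeric vectors in arrival order.
#' @param packets_per_frame Number of packets consumed per frame tick
#'   (2 for 60 Hz packets at a 30 Hz frame cap).
#' @return List of frames; `unlist()` of the result equals `unlist(packets)`.
#' @export
buffer_frames <- function(packets, packets_per_frame = 2) {
  stopifnot(is.list(packets), packets_per_frame >= 1)
  if (length(packets) == 0L) return(list())
  idx <- ceiling(seq_along(packets) / packets_per_frame)
  unname(lapply(split(packets, idx), function(p) unlist(p, use.names = FALSE)))
}

#' Read / write raw signal CSV
#'
#' Single-column CSV with a header row and a `# sample_rate_hz:` metadata
#' comment line.
#'
#' @param path File path.
#' @return For `read_signal_csv`, a list with `samples` and `sample_rate_hz`.
#' @export
read_signal_csv <- function(path) {
  first <- readLines(path, n = 1L)
  rate <- 1000
  skip <- 0L
  if (grepl("^#\\s*sample_rate_hz:", first)) {
    rate <- as.numeric(sub("^#\\s*sample_rate_hz:\\s*", "", first))
    skip <- 1L
  }
  df <- read.csv(path, skip = skip)
  list(samples = df[[1L]], sample_rate_hz = rate)
}

#' @rdname read_signal_csv
#' @param samples Numeric vector to write.
#' @param sample_rate_hz Sampling rate recorded in the metadata line.
#' @export
write_signal_csv <- function(samples, path, sample_rate_hz = 1000) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_rate_hz: %s", format(sample_rate_hz)), con)
  write.csv(data.frame(value = samples), con, row.names = FALSE)
  invisible(path)
}
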