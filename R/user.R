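#' Simulated participants
#'
#' Synthetic stand-ins for human participants. A simulated user produces, for
#' each cue, one contraction whose processed peak is Gaussian around the
#' center of the cued zone with participant-specific aim error (`aim_sd`,
#' counts on the 0-1023 axis), embedded between resting-noise segments. The
#' model is deliberately simple: no fatigue, no learning across trials.
#'
#' @name simulated-user
NULL

#' Construct a simulated user
#'
#' @param aim_sd Standard deviation of the peak-targeting error, in counts on
#'   the post-scale 0-1023 axis. `0` is a perfect aimer.
#' @param resting_noise_sd SD of raw resting baseline noise (pre-scale units).
#' @param resting_mean Mean raw resting baseline (pre-scale units).
#' @param burst_duration_ms Duration of one contraction burst.
#' @return A `user_model`.
#' @examples
#' user_model(aim_sd = 30)
#' @export
user_model <- function(aim_sd = 190, resting_noise_sd = 4, resting_mean = 10,
                       burst_duration_ms = 300) {
  stopifnot(aim_sd >= 0, resting_noise_sd >= 0, burst_duration_ms > 0)
  structure(list(aim_sd = aim_sd, resting_noise_sd = resting_noise_sd,
                 resting_mean = resting_mean,
                 burst_duration_ms = burst_duration_ms),
            class = "user_model")
}

#' @export
print.user_model <- function(x, ...) {
  cat(sprintf(
    "<user_model: aim_sd %.3g, resting %.3g +/- %.3g, burst %.0f ms>\n",
    x$aim_sd, x$resting_mean, x$resting_noise_sd, x$burst_duration_ms))
  invisible(x)
}

#' Draw processed contraction peaks aimed at a zone
#'
#' Fast path of the user model: samples the processed, quantized peak directly
#' from Normal(center of the target zone, `aim_sd`), rounded and clipped to
#' `[0, 1023]`. [synth_contraction()] realizes the same peak through the full
#' raw-signal path.
#'
#' @param target_zone Cued zone index.
#' @param thresholds A [threshold_set()].
#' @param user A [user_model()].
#' @param n Number of draws.
#' @return Integer vector of peaks in `[0, 1023]`.
#' @export
draw_peak <- function(target_zone, thresholds, user, n = 1) {
  stopifnot(inherits(thresholds, "threshold_set"),
            inherits(user, "user_model"),
            target_zone >= 1, target_zone <= n_zones(thresholds))
  center <- zone_centers(thresholds)[target_zone]
  quantize(rnorm(n, mean = center, sd = user$aim_sd))
}

#' Closed-form zone hit probability under Gaussian aim error
#'
#' Probability that a peak aimed at the center of `target_zone` with error SD
#' `aim_sd` lands inside `hit_zone` (default: the cued zone itself). Uses the
#' normal CDF over the zone interval `[lower, upper)`, with clipping at the
#' device rails folded into the bottom and top zones.
#'
#' @inheritParams draw_peak
#' @param aim_sd Aim error SD; overrides `user`.
#' @param hit_zone Zone whose interval is evaluated.
#' @return Probability in `[0, 1]`.
#' @export
hit_probability <- function(target_zone, thresholds, aim_sd,
                            hit_zone = target_zone) {
  stopifnot(inherits(thresholds, "threshold_set"), aim_sd >= 0)
  b <- zone_bounds(thresholds)
  center <- zone_centers(thresholds)[target_zone]
  lo <- b$lower[hit_zone]
  hi <- b$upper[hit_zone]
  if (aim_sd == 0) return(as.numeric(center >= lo - 0.5 && center < hi))
  # continuous normal with half-count shift for rounding; rail clipping maps
  # mass below -0.5 onto count 0 and above 1022.5 onto count 1023
  p_lo <- if (hit_zone == 1L && lo <= 0L) -Inf else (lo - 0.5 - center) / aim_sd
  p_hi <- if (hi >= 1024L) Inf else (hi - 0.5 - center) / aim_sd
  pnorm(p_hi) - pnorm(p_lo)
}

#' Synthetic resting-baseline signal
#'
#' Gaussian raw baseline noise; at default parameters its processed envelope
#' stays far below any study resting threshold, so no spurious flexes occur.
#'
#' @param duration_ms Duration in milliseconds.
#' @param user A [user_model()].
#' @param sample_rate_hz Sampling rate.
#' @return Numeric vector of raw samples.
#' @export
synth_resting <- function(duration_ms, user, sample_rate_hz = 1000) {
  stopifnot(duration_ms > 0, inherits(user, "user_model"))
  n <- max(1L, round(duration_ms * sample_rate_hz / 1000))
  rnorm(n, mean = user$resting_mean, sd = user$resting_noise_sd)
}

# unit raised-cosine burst envelope (max 1)
raised_cosine <- function(n) 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))

#' Synthesize one cued contraction as a raw signal
#'
#' A raised-cosine burst embedded between resting-noise segments, with its
#' amplitude solved so that the *processed* (rectified, filtered, smoothed,
#' scaled, quantized) peak equals a target drawn from
#' Normal(center of `target_zone`, `aim_sd`) — i.e. the raw-signal path
#' realizes exactly the peak distribution of [draw_peak()].
#'
#' @inheritParams draw_peak
#' @param sample_rate_hz Sampling rate of the synthetic signal.
#' @param cfg A [filter_config()].
#' @param pre_ms,post_ms Resting-noise padding around the burst.
#' @param peak_value Optional fixed target peak (device scale); when `NULL`
#'   one is drawn from the user's aim distribution.
#' @return Numeric raw-signal vector with attributes `target_peak` (the
#'   intended processed peak) and `burst_range` (sample indices).
#' @export
synth_contraction <- function(target_zone, thresholds, user,
                              sample_rate_hz = 1000, cfg = filter_config(),
                              pre_ms = 400, post_ms = 300,
                              peak_value = NULL) {
  stopifnot(inherits(thresholds, "threshold_set"), inherits(user, "user_model"))
  if (is.null(peak_value)) {
    peak_value <- draw_peak(target_zone, thresholds, user)
  }
  peak_value <- as.integer(peak_value)
  n_pre <- max(1L, round(pre_ms * sample_rate_hz / 1000))
  n_burst <- max(8L, round(user$burst_duration_ms * sample_rate_hz / 1000))
  n_post <- max(1L, round(post_ms * sample_rate_hz / 1000))
  noise <- rnorm(n_pre + n_burst + n_post,
                 mean = user$resting_mean, sd = user$resting_noise_sd)
  burst <- c(rep(0, n_pre), raised_cosine(n_burst), rep(0, n_post))
  # The chain is linear for nonnegative signals (rectification is identity),
  # so envelope(a*burst + noise) = a*envelope(burst) + envelope(noise); solve
  # for the amplitude a that puts the combined post-scale max at peak_value.
  env_burst <- filter_and_smooth(burst, sample_rate_hz, cfg)
  env_noise <- filter_and_smooth(pmax(noise, 0), sample_rate_hz, cfg)
  target_pre <- peak_value / thresholds$global_scale
  i_star <- which.max(env_burst)
  a <- (target_pre - env_noise[i_star]) / env_burst[i_star]
  for (iter in 1:4) {
    i_star <- which.max(a * env_burst + env_noise)
    a_new <- (target_pre - env_noise[i_star]) / env_burst[i_star]
    if (abs(a_new - a) < 1e-12) break
    a <- a_new
  }
  out <- a * burst + noise
  attr(out, "target_peak") <- peak_value
  attr(out, "burst_range") <- c(n_pre + 1L, n_pre + n_burst)
  out
}

#' Draw a participant population
#'
#' Per-participant aim error is drawn from a log-normal distribution; the
#' default (median 190 counts, sdlog 0.25) reproduces the qualitative score
#' gradient across 1/3/5 equal zones under the closed-form hit probability.
#'
#' @param n Number of participants.
#' @param aim_sd_meanlog,aim_sd_sdlog Log-normal parameters of `aim_sd`.
#' @param seed Optional seed.
#' @return List of [user_model()]s.
#' @export
user_population <- function(n, aim_sd_meanlog = log(190), aim_sd_sdlog = 0.25,
                            seed = NULL) {
  stopifnot(n >= 1)
  with_seed(seed, {
    sds <- exp(rnorm(n, aim_sd_meanlog, aim_sd_sdlog))
    lapply(sds, function(s) user_model(aim_sd = s))
  })
}

#' Maximum-likelihood aim error from per-cue outcomes
#'
#' Inverts the closed-form normal-CDF hit probability: given per-cue records
#' (`n_zones`, `cued_zone`, `success`) from equal-zone trials, finds the
#' `aim_sd` maximizing the Bernoulli likelihood of the observed hits.
#'
#' @param per_cue Data.frame with columns `n_zones`, `cued_zone`, `success`.
#' @param resting Resting threshold the trials used.
#' @param interval Search interval for `aim_sd` (counts).
#' @return Estimated `aim_sd`.
#' @export
estimate_aim_sd <- function(per_cue, resting = 23, interval = c(1, 1000)) {
  stopifnot(all(c("n_zones", "cued_zone", "success") %in% names(per_cue)))
  keys <- unique(per_cue[c("n_zones", "cued_zone")])
  tallies <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- per_cue$n_zones == keys$n_zones[i] &
      per_cue$cued_zone == keys$cued_zone[i]
    c(hits = sum(per_cue$success[sel]), n = sum(sel))
  })
  nll <- function(log_sd) {
    s <- exp(log_sd)
    -sum(vapply(seq_len(nrow(keys)), function(i) {
      ts <- make_equal_zones(keys$n_zones[i], resting)
      p <- min(max(hit_probability(keys$cued_zone[i], ts, s), 1e-12), 1 - 1e-12)
      tallies[[i]]["hits"] * log(p) +
        (tallies[[i]]["n"] - tallies[[i]]["hits"]) * log(1 - p)
    }, numeric(1)))
  }
  exp(optimize(nll, log(interval))$minimum)
}
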