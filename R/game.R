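#' Headless MDAT assessment engine
#'
#' One trial presents a sequence of randomized cues (default 15); the
#' participant has exactly one attempt per cue with no time limit, and an
#' attempt succeeds when the contraction's peak lands inside the cued zone.
#' Trials are scored out of the number of cues. A session is three trials per
#' arm under a cohort schedule: static cohorts play all trials at a fixed zone
#' count (A1: 1, A2: 3, A3: 5); the progressive cohort B1 advances 1 -> 3 -> 5
#' zones across trials, with a 60 s rest between trials.
#'
#' @name game-engine
NULL

#' Trial configuration
#'
#' @param n_zones Number of zones for the trial.
#' @param n_cues Number of cues (default 15).
#' @param thresholds Optional [threshold_set()]; defaults to equal segmentation
#'   above `resting`.
#' @param resting Resting threshold used when `thresholds` is `NULL`.
#' @return A `trial_config` list.
#' @export
trial_config <- function(n_zones, n_cues = 15, thresholds = NULL,
                         resting = 23) {
  stopifnot(n_zones >= 1, n_cues >= 1)
  if (is.null(thresholds)) thresholds <- make_equal_zones(n_zones, resting)
  if (n_zones(thresholds) != n_zones) {
    stop("thresholds must have exactly n_zones zones")
  }
  structure(list(n_zones = as.integer(n_zones), n_cues = as.integer(n_cues),
                 thresholds = thresholds),
            class = "trial_config")
}

#' Generate a randomized cue sequence
#'
#' Cues are i.i.d. uniform over zones by default; `balanced = TRUE` instead
#' shuffles a maximally equal allocation of zone counts.
#'
#' @param n_zones Number of zones.
#' @param n_cues Sequence length.
#' @param seed Optional seed (reproducible sequences).
#' @param balanced Use the balanced allocation instead of i.i.d. uniform.
#' @return Integer vector of zone indices of length `n_cues`.
#' @examples
#' generate_cues(3, 15, seed = 1)
#' @export
generate_cues <- function(n_zones, n_cues = 15, seed = NULL,
                          balanced = FALSE) {
  if (!is.numeric(n_zones) || n_zones < 1 || n_zones != as.integer(n_zones)) {
    stop("n_zones must be a positive integer")
  }
  if (!is.numeric(n_cues) || n_cues < 1 || n_cues != as.integer(n_cues)) {
    stop("n_cues must be a positive integer")
  }
  with_seed(seed, {
    if (balanced) {
      base <- rep(seq_len(n_zones), length.out = n_cues)
      sample(base)
    } else {
      sample.int(n_zones, n_cues, replace = TRUE)
    }
  })
}

#' Score a single attempt
#'
#' @param cued_zone The cued zone index.
#' @param peak The attempt's contraction peak (or `NA` if no flex occurred).
#' @param thresholds A [threshold_set()].
#' @return `TRUE` iff the peak's zone equals the cued zone.
#' @export
score_attempt <- function(cued_zone, peak, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"),
            cued_zone >= 1, cued_zone <= n_zones(thresholds))
  if (is.na(peak)) return(FALSE)
  z <- assign_zone(peak, thresholds)
  !is.na(z) && z == cued_zone
}

#' Run one trial
#'
#' The simulated user produces exactly one flex per cue. By default the peak
#' is drawn through the fast path ([draw_peak()]); `use_signal_path = TRUE`
#' routes each attempt through the full raw-signal chain
#' ([synth_contraction()] -> [process_signal()] -> [detect_flexes()]), which
#' realizes the same peak distribution.
#'
#' @param user A [user_model()].
#' @param cfg A [trial_config()].
#' @param seed Optional seed.
#' @param use_signal_path Route attempts through the raw-signal chain.
#' @param balanced_cues Passed to [generate_cues()].
#' @return A `trial_result`: list with `per_cue` (tibble: `cue`, `cued_zone`,
#'   `peak`, `assigned_zone`, `success`) and `score` in `[0, n_cues]`.
#' @export
run_trial <- function(user, cfg, seed = NULL, use_signal_path = FALSE,
                      balanced_cues = FALSE) {
  stopifnot(inherits(user, "user_model"), inherits(cfg, "trial_config"))
  with_seed(seed, {
    cues <- generate_cues(cfg$n_zones, cfg$n_cues, balanced = balanced_cues)
    ths <- cfg$thresholds
    targets <- vapply(cues, function(z) draw_peak(z, ths, user), integer(1))
    if (use_signal_path) {
      peaks <- integer(cfg$n_cues)
      for (i in seq_len(cfg$n_cues)) {
        raw <- synth_contraction(cues[i], ths, user, peak_value = targets[i])
        stream <- process_signal(raw, global_scale = ths$global_scale)
        ev <- detect_flexes(stream, ths$resting)
        peaks[i] <- if (nrow(ev)) max(ev$peak) else NA_integer_
      }
    } else {
      peaks <- targets
      peaks[peaks <= ths$resting] <- NA_integer_  # no flex detected
    }
    assigned <- rep(NA_integer_, cfg$n_cues)
    ok <- !is.na(peaks)
    assigned[ok] <- assign_zone(peaks[ok], ths)
    success <- !is.na(assigned) & assigned == cues
    per_cue <- tibble::tibble(cue = seq_len(cfg$n_cues), cued_zone = cues,
                              peak = peaks, assigned_zone = assigned,
                              success = success)
    structure(list(per_cue = per_cue, score = sum(success),
                   n_cues = cfg$n_cues, n_zones = cfg$n_zones),
              class = "trial_result")
  })
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("<trial_result: %d zones, score %d / %d>\n",
              x$n_zones, x$score, x$n_cues))
  invisible(x)
}

#' Cohort session schedule
#'
#' @param cohort One of `"A1"`, `"A2"`, `"A3"`, `"B1"`.
#' @return A `session_plan`: cohort label, `zones_per_trial` (length 3),
#'   `arms` (right then left), `rest_between_trials_s` (60).
#' @examples
#' session_plan("B1")$zones_per_trial # 1 3 5
#' @export
session_plan <- function(cohort = c("A1", "A2", "A3", "B1")) {
  cohort <- match.arg(cohort)
  zones <- switch(cohort,
                  A1 = c(1L, 1L, 1L), A2 = c(3L, 3L, 3L),
                  A3 = c(5L, 5L, 5L), B1 = c(1L, 3L, 5L))
  structure(list(cohort = cohort, zones_per_trial = zones,
                 arms = c("right", "left"), rest_between_trials_s = 60),
            class = "session_plan")
}

#' Run a full session (3 trials per arm under a cohort schedule)
#'
#' Arms are independent repeats of the same schedule with separate derived
#' seeds; all randomness is reproducible from `seed`.
#'
#' @param user A [user_model()].
#' @param plan A [session_plan()].
#' @param seed Seed for the whole session.
#' @param n_cues Cues per trial.
#' @param resting Resting threshold for the equal-zone thresholds.
#' @param use_signal_path Passed to [run_trial()].
#' @return Tibble with one row per arm x trial: `arm`, `trial`, `n_zones`,
#'   `score`, and a `detail` list-column of `trial_result`s.
#' @export
run_session <- function(user, plan, seed = NULL, n_cues = 15, resting = 23,
                        use_signal_path = FALSE) {
  stopifnot(inherits(plan, "session_plan"))
  combos <- expand.grid(trial = 1:3, arm = plan$arms,
                        stringsAsFactors = FALSE)[, c("arm", "trial")]
  seeds <- if (is.null(seed)) rep(list(NULL), nrow(combos)) else
    as.list(derive_seeds(seed, nrow(combos)))
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    nz <- plan$zones_per_trial[combos$trial[i]]
    res <- run_trial(user, trial_config(nz, n_cues, resting = resting),
                     seed = seeds[[i]], use_signal_path = use_signal_path)
    tibble::tibble(arm = combos$arm[i], trial = combos$trial[i],
                   n_zones = nz, score = res$score, detail = list(res))
  })
  dplyr::bind_rows(rows)
}

#' Simulate a cohort of participants
#'
#' @param cohort Cohort label (`"A1"`, `"A2"`, `"A3"`, `"B1"`).
#' @param n_participants Number of simulated participants.
#' @param population Optional list of [user_model()]s (length
#'   `n_participants`); defaults to [user_population()] draws.
#' @param seed Seed for the whole cohort.
#' @param n_cues Cues per trial.
#' @param resting Resting threshold.
#' @param keep_detail Keep per-cue records as an attribute (needed by
#'   [estimate_aim_sd()]).
#' @return Tibble: `participant_id`, `cohort`, `arm`, `trial`, `n_zones`,
#'   `score`, one row per participant x arm x trial.
#' @export
simulate_cohort <- function(cohort, n_participants, population = NULL,
                            seed = NULL, n_cues = 15, resting = 23,
                            keep_detail = FALSE) {
  stopifnot(n_participants >= 1)
  plan <- session_plan(cohort)
  seeds <- derive_seeds(if (is.null(seed)) sample.int(2^31 - 1, 1) else seed,
                        n_participants + 1L)
  if (is.null(population)) {
    population <- user_population(n_participants, seed = seeds[n_participants + 1L])
  }
  stopifnot(length(population) == n_participants)
  ids <- make_participant_ids(n_participants, seed = seeds[n_participants + 1L])
  out <- vector("list", n_participants)
  details <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    sess <- run_session(population[[p]], plan, seed = seeds[p],
                        n_cues = n_cues, resting = resting)
    if (keep_detail) {
      details[[p]] <- dplyr::bind_rows(lapply(seq_len(nrow(sess)), function(i) {
        d <- sess$detail[[i]]$per_cue
        d$n_zones <- sess$n_zones[i]
        d$participant_id <- ids[p]
        d
      }))
    }
    out[[p]] <- tibble::tibble(participant_id = ids[p], cohort = cohort,
                               arm = sess$arm, trial = sess$trial,
                               n_zones = sess$n_zones, score = sess$score)
  }
  res <- dplyr::bind_rows(out)
  if (keep_detail) attr(res, "per_cue") <- dplyr::bind_rows(details)
  res
}

#' Simulate the full study design
#'
#' All four cohorts at their study sizes (A1: 9, A2: 10, A3: 9, B1: 26).
#'
#' @param cohort_sizes Named integer vector of cohort sizes.
#' @param seed Master seed.
#' @param ... Passed to [simulate_cohort()].
#' @return Tibble of trial scores for all cohorts.
#' @export
simulate_study <- function(cohort_sizes = c(A1 = 9, A2 = 10, A3 = 9, B1 = 26),
                           seed = NULL, ...) {
  seeds <- derive_seeds(if (is.null(seed)) sample.int(2^31 - 1, 1) else seed,
                        length(cohort_sizes))
  dplyr::bind_rows(lapply(seq_along(cohort_sizes), function(i) {
    simulate_cohort(names(cohort_sizes)[i], cohort_sizes[[i]],
                    seed = seeds[i], ...)
  }))
}

#' Random 8-digit participant identifiers
#'
#' @param n Number of identifiers.
#' @param seed Optional seed.
#' @return Character vector of unique 8-digit IDs.
#' @export
make_participant_ids <- function(n, seed = NULL) {
  with_seed(seed, sprintf("%08d", sample.int(99999999L, n)))
}

#' Write per-cue session logs
#'
#' JSON-lines (one record per cue) plus a per-trial CSV summary.
#'
#' @param scores Trial-score tibble from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @export
write_session_logs <- function(scores, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(scores, file.path(dir, "trial_scores.csv"), row.names = FALSE)
  per_cue <- attr(scores, "per_cue")
  if (!is.null(per_cue)) {
    con <- file(file.path(dir, "cue_events.jsonl"), "w")
    on.exit(close(con))
    for (i in seq_len(nrow(per_cue))) {
      writeLines(jsonlite::toJSON(as.list(per_cue[i, ]), auto_unbox = TRUE,
                                  na = "null"), con)
    }
  }
  invisible(dir)
}
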