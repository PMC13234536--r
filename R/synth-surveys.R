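#' Synthetic survey and demographics generation
#'
#' Cohort-structured raw survey responses (SUS, raw NASA-TLX, EHI tallies)
#' plus gender and dominant-hand grip strength, for feeding the scoring and
#' statistics pipeline with a full simulated study. All responses are
#' integers clipped into their instrument's legal range.
#'
#' @name synthetic-surveys
NULL

#' Survey response profile for one cohort
#'
#' @param sus_item_means Length-10 vector of SUS item means in `[1, 5]`.
#' @param tlx_item_means Length-6 vector of raw TLX item means in `[1, 21]`,
#'   ordered (mental, physical, temporal, performance, effort, frustration).
#' @param sus_sd,tlx_sd Response noise SDs on the raw item scales.
#' @return A `survey_profile` list.
#' @export
survey_profile <- function(sus_item_means, tlx_item_means,
                           sus_sd = 1.2, tlx_sd = 4) {
  stopifnot(length(sus_item_means) == 10L, length(tlx_item_means) == 6L,
            all(sus_item_means >= 1 & sus_item_means <= 5),
            all(tlx_item_means >= 1 & tlx_item_means <= 21),
            sus_sd >= 0, tlx_sd >= 0)
  structure(list(sus_item_means = sus_item_means,
                 tlx_item_means = tlx_item_means,
                 sus_sd = sus_sd, tlx_sd = tlx_sd),
            class = "survey_profile")
}

# Item means that realize a target SUS score with uniform responding:
# per-item contribution c = score / 25, odd mean 1 + c, even mean 5 - c.
sus_profile_for_score <- function(score) {
  c_item <- score / 25
  means <- numeric(10)
  means[seq(1, 9, 2)] <- 1 + c_item
  means[seq(2, 10, 2)] <- 5 - c_item
  means
}

#' Default cohort survey profiles
#'
#' SUS item means are set so expected cohort scores follow the study's
#' usability pattern (A1/A2 ~75, A3 lowest ~63, B1 highest ~76); raw TLX item
#' means follow the cohort workload pattern on each subscale (A3 highest
#' demand, A1 highest perceived performance).
#'
#' @return Named list of [survey_profile()]s for cohorts A1, A2, A3, B1.
#' @export
default_survey_profiles <- function() {
  tlx_means <- list(
    # subscale targets on the 0-100 axis, mapped to raw items via x/5 + 1
    A1 = c(3.9, 31.1, 4.4, 84.4, 33.3, 6.1),
    A2 = c(11.0, 24.0, 20.0, 59.0, 33.0, 15.0),
    A3 = c(20.6, 38.9, 8.3, 30.6, 43.3, 18.3),
    B1 = c(18.3, 27.1, 21.5, 44.2, 37.7, 16.3)
  )
  sus_targets <- c(A1 = 75.0, A2 = 75.0, A3 = 63.3, B1 = 76.2)
  out <- lapply(names(sus_targets), function(ch) {
    survey_profile(sus_profile_for_score(sus_targets[[ch]]),
                   pmin(21, pmax(1, tlx_means[[ch]] / 5 + 1)))
  })
  names(out) <- names(sus_targets)
  out
}

clip_int <- function(x, lo, hi) as.integer(pmin(hi, pmax(lo, round_half_away(x))))

#' Generate raw survey responses for all cohorts
#'
#' @param n_by_cohort Named integer vector of participants per cohort
#'   (default: the study sizes).
#' @param profiles Named list of [survey_profile()]s; defaults to
#'   [default_survey_profiles()].
#' @param seed Master seed.
#' @return Tibble with one row per participant: `participant_id`, `cohort`,
#'   `gender`, `grip_kg`, `sus_01`..`sus_10` (1-5), the six raw `tlx_*`
#'   columns (1-21), `ehi_r`, `ehi_l`.
#' @export
synth_surveys <- function(n_by_cohort = c(A1 = 9, A2 = 10, A3 = 9, B1 = 26),
                          profiles = default_survey_profiles(),
                          seed = NULL) {
  stopifnot(all(names(n_by_cohort) %in% names(profiles)),
            all(n_by_cohort >= 1))
  with_seed(seed, {
    rows <- lapply(names(n_by_cohort), function(ch) {
      n <- n_by_cohort[[ch]]
      pr <- profiles[[ch]]
      sus <- sapply(seq_len(10), function(j) {
        clip_int(rnorm(n, pr$sus_item_means[j], pr$sus_sd), 1L, 5L)
      })
      tlx <- sapply(seq_len(6), function(j) {
        clip_int(rnorm(n, pr$tlx_item_means[j], pr$tlx_sd), 1L, 21L)
      })
      sus <- matrix(sus, nrow = n)
      tlx <- matrix(tlx, nrow = n)
      colnames(sus) <- sprintf("sus_%02d", 1:10)
      colnames(tlx) <- paste0("tlx_", tlx_subscales)
      # study population tested uniformly right-handed (LQ > 40)
      ehi_r <- rbinom(n, 10L, 0.92)
      ehi_r <- pmax(ehi_r, 8L)
      gender <- sample(c("men", "women", "other"), n, replace = TRUE,
                       prob = c(12, 40, 2) / 54)
      grip_mu <- c(men = 44.0, women = 27.3, other = 21.3)[gender]
      grip_sd <- c(men = 11.2, women = 4.6, other = 0.6)[gender]
      grip <- round(pmax(rnorm(n, grip_mu, grip_sd), 5), 1)
      dplyr::bind_cols(
        tibble::tibble(cohort = ch, gender = gender, grip_kg = grip),
        tibble::as_tibble(sus), tibble::as_tibble(tlx),
        tibble::tibble(ehi_r = ehi_r, ehi_l = 10L - ehi_r)
      )
    })
    out <- dplyr::bind_rows(rows)
    out <- dplyr::bind_cols(
      tibble::tibble(participant_id = make_participant_ids(nrow(out))), out)
    out
  })
}
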