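#' Study report tables
#'
#' Builds the analysis tables the study reports: cohort x trial performance
#' means (SD), matched-trial Welch comparisons of the progressive cohort
#' against its static counterparts (B1 trial 1 vs A1 trial 1, trial 2 vs A2
#' trial 2, trial 3 vs A3 trial 3), SUS by cohort plus a size-weighted
#' overall, NASA-TLX subscale means with per-subscale Kruskal-Wallis p,
#' pairwise subscale contrasts ordered by significance, and grip strength by
#' self-reported gender. No multiple-comparison adjustment is applied.
#'
#' @name report
NULL

#' Sample-size-weighted pooled mean
#'
#' @param means Group means.
#' @param n Group sizes.
#' @return `sum(n * means) / sum(n)`.
#' @examples
#' pool_cohort_means(c(75, 75, 63.3, 76.2), c(9, 10, 9, 26)) # 73.6
#' @export
pool_cohort_means <- function(means, n) {
  stopifnot(length(means) == length(n), all(n > 0))
  sum(n * means) / sum(n)
}

#' Average of trial means
#'
#' The per-cohort "average score" column: the unweighted mean of the trial
#' means (equal trial counts per participant make this identical to the mean
#' of per-participant averages).
#'
#' @param trial_means Numeric vector of per-trial means.
#' @return Their mean.
#' @export
trial_average <- function(trial_means) {
  stopifnot(is.numeric(trial_means), length(trial_means) >= 1)
  mean(trial_means)
}

round1 <- function(x) round(x, 1)

#' Cohort x trial performance table
#'
#' @param scores Trial-score tibble (`cohort`, `trial`, `score`, one row per
#'   participant x arm x trial).
#' @return Tibble with per-trial `mean` and `sd` plus an `overall` column
#'   (mean and SD of per-participant trial averages).
#' @export
trial_score_table <- function(scores) {
  stopifnot(all(c("participant_id", "cohort", "trial", "score") %in%
                  names(scores)))
  by_trial <- scores |>
    dplyr::group_by(cohort, trial) |>
    dplyr::summarise(mean = mean(score), sd = sd(score), n = dplyr::n(),
                     .groups = "drop")
  overall <- scores |>
    dplyr::group_by(cohort, participant_id) |>
    dplyr::summarise(avg = mean(score), .groups = "drop_last") |>
    dplyr::summarise(overall_mean = mean(avg), overall_sd = sd(avg),
                     .groups = "drop")
  wide <- by_trial |>
    tidyr::pivot_wider(names_from = trial,
                       values_from = c(mean, sd, n),
                       names_glue = "trial{trial}_{.value}")
  dplyr::left_join(wide, overall, by = "cohort")
}

#' Matched-trial comparisons of the progressive cohort
#'
#' Welch comparisons of B1 trial t against the static cohort playing the same
#' zone count on its t-th trial (A1/t1, A2/t2, A3/t3), isolating trials to
#' match both zone count and exposure time.
#'
#' @param scores Trial-score tibble.
#' @param exact_hedges Passed to [welch_t()].
#' @return Tibble: one row per matched pair with mean difference (B1 minus
#'   static), CI, Welch t and df, Hedges g, d_av, p.
#' @export
between_cohort_table <- function(scores, exact_hedges = FALSE) {
  pairs <- data.frame(static = c("A1", "A2", "A3"), trial = 1:3)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    b <- scores$score[scores$cohort == "B1" & scores$trial == pairs$trial[i]]
    a <- scores$score[scores$cohort == pairs$static[i] &
                        scores$trial == pairs$trial[i]]
    if (!length(b) || !length(a)) return(NULL)
    cmp <- welch_t(b, a, exact_hedges)
    tibble::tibble(comparison = sprintf("B1 vs %s, trial %d",
                                        pairs$static[i], pairs$trial[i]),
                   mean_diff = round(cmp$mean_diff, 2),
                   ci_low = round(cmp$ci95[1], 2),
                   ci_high = round(cmp$ci95[2], 2),
                   welch_t = round(cmp$statistic, 2),
                   df = round(cmp$df, 1),
                   hedges_g = round(cmp$hedges_g, 2),
                   d_av = round(cmp$d_av, 2),
                   p = cmp$p)
  })
  dplyr::bind_rows(rows)
}

#' SUS summary by cohort with size-weighted overall
#'
#' @param surveys Scored survey tibble (needs `cohort`, `sus_score`).
#' @return Tibble of cohort mean (SD) and n, with an `Overall` row whose mean
#'   is the sample-size-weighted pooled mean and whose SD is computed over all
#'   participants.
#' @export
sus_table <- function(surveys) {
  stopifnot(all(c("cohort", "sus_score") %in% names(surveys)))
  by_cohort <- surveys |>
    dplyr::group_by(cohort) |>
    dplyr::summarise(mean = round1(mean(sus_score)),
                     sd = round1(sd(sus_score)),
                     n = dplyr::n(), .groups = "drop")
  overall <- tibble::tibble(
    cohort = "Overall",
    mean = round1(pool_cohort_means(by_cohort$mean, by_cohort$n)),
    sd = round1(sd(surveys$sus_score)),
    n = nrow(surveys))
  dplyr::bind_rows(by_cohort, overall)
}

#' NASA-TLX subscale table with Kruskal-Wallis p per subscale
#'
#' @param surveys Scored survey tibble (needs `cohort` and the
#'   `tlx_*_score` columns plus `tlx_composite`).
#' @return List with `means` (cohort x subscale mean (SD) tibble, including
#'   the inverted-performance composite as `overall`) and `kruskal`
#'   (per-subscale H and p).
#' @export
tlx_table <- function(surveys) {
  score_cols <- paste0("tlx_", tlx_subscales, "_score")
  stopifnot(all(c("cohort", score_cols, "tlx_composite") %in% names(surveys)))
  long <- surveys |>
    dplyr::select(cohort, dplyr::all_of(c(score_cols, "tlx_composite"))) |>
    tidyr::pivot_longer(-cohort, names_to = "subscale", values_to = "value")
  means <- long |>
    dplyr::group_by(cohort, subscale) |>
    dplyr::summarise(mean = round1(mean(value)), sd = round1(sd(value)),
                     .groups = "drop")
  kruskal <- dplyr::bind_rows(lapply(score_cols, function(sc) {
    groups <- split(surveys[[sc]], surveys$cohort)
    groups <- groups[vapply(groups, length, integer(1)) > 0]
    if (length(groups) < 2) return(NULL)
    kw <- kruskal_wallis(groups)
    tibble::tibble(subscale = sc, H = round(kw$H, 2), df = kw$df, p = kw$p)
  }))
  list(means = means, kruskal = kruskal)
}

#' Pairwise cohort contrasts for one TLX subscale
#'
#' Welch contrasts for every cohort pair, reporting d_av (with an approximate
#' SE) and p, ordered with the most significant rows first.
#'
#' @param surveys Scored survey tibble.
#' @param subscale One of the six subscale names (e.g. `"performance"`).
#' @return Tibble: `comparison`, `d_av`, `d_av_se`, `p`, sorted by p.
#' @export
tlx_pairwise_table <- function(surveys, subscale = "performance") {
  col <- paste0("tlx_", match.arg(subscale, tlx_subscales), "_score")
  cohorts <- sort(unique(surveys$cohort))
  pairs <- utils::combn(cohorts, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- surveys[[col]][surveys$cohort == pr[1]]
    b <- surveys[[col]][surveys$cohort == pr[2]]
    if (length(a) < 2 || length(b) < 2) return(NULL)
    cmp <- welch_t(a, b)
    na <- length(a); nb <- length(b)
    # large-sample SE of a standardized mean difference
    se_d <- sqrt((na + nb) / (na * nb) + cmp$d_av^2 / (2 * (na + nb - 2)))
    tibble::tibble(comparison = paste(pr, collapse = ", "),
                   d_av = round(cmp$d_av, 2), d_av_se = round(se_d, 2),
                   p = cmp$p)
  })
  dplyr::bind_rows(rows) |> dplyr::arrange(p)
}

#' Grip strength by self-reported gender
#'
#' Summary mean (SD) and n per gender plus the men-vs-women Mann-Whitney U
#' with rank-biserial r (normality is not assumed in the smaller subsample).
#'
#' @param surveys Tibble with `gender` and `grip_kg`.
#' @return List with `summary` tibble and `test` (U, p, rank_biserial), the
#'   test `NULL` when either group has no observations.
#' @export
grip_table <- function(surveys) {
  stopifnot(all(c("gender", "grip_kg") %in% names(surveys)))
  summary <- surveys |>
    dplyr::group_by(gender) |>
    dplyr::summarise(n = dplyr::n(), mean = round1(mean(grip_kg)),
                     sd = round1(sd(grip_kg)), .groups = "drop")
  m <- surveys$grip_kg[surveys$gender == "men"]
  w <- surveys$grip_kg[surveys$gender == "women"]
  test <- if (length(m) && length(w)) mann_whitney(m, w) else NULL
  list(summary = summary, test = test)
}

#' Build the full report bundle
#'
#' @param scores Trial-score tibble from [simulate_cohort()] /
#'   [simulate_study()] or loaded from CSV.
#' @param surveys Scored survey tibble from [score_survey_table()], or `NULL`;
#'   when absent (or when a cohort is missing) the report degrades to the
#'   sections its inputs support, with a warning.
#' @return A `study_report` list of tibbles: `trial_scores`,
#'   `between_cohort`, `sus`, `tlx`, `tlx_pairwise_performance`,
#'   `tlx_pairwise_temporal`, `grip`.
#' @export
build_report <- function(scores, surveys = NULL) {
  out <- list(trial_scores = trial_score_table(scores))
  have <- unique(scores$cohort)
  missing <- setdiff(c("A1", "A2", "A3", "B1"), have)
  if (length(missing)) {
    warning("missing cohorts: ", paste(missing, collapse = ", "),
            "; emitting a partial report")
  }
  out$between_cohort <- between_cohort_table(scores)
  if (!is.null(surveys) && nrow(surveys)) {
    out$sus <- sus_table(surveys)
    out$tlx <- tlx_table(surveys)
    out$tlx_pairwise_performance <- tlx_pairwise_table(surveys, "performance")
    out$tlx_pairwise_temporal <- tlx_pairwise_table(surveys, "temporal")
    out$grip <- grip_table(surveys)
  } else {
    warning("no survey table supplied; survey sections absent")
  }
  structure(out, class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> sections:", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Write a report bundle to a directory of CSV tables plus a JSON summary
#'
#' @param report A `study_report` from [build_report()].
#' @param dir Output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  flat <- list(
    trial_scores = report$trial_scores,
    between_cohort = report$between_cohort,
    sus = report$sus,
    tlx_means = report$tlx$means,
    tlx_kruskal = report$tlx$kruskal,
    tlx_pairwise_performance = report$tlx_pairwise_performance,
    tlx_pairwise_temporal = report$tlx_pairwise_temporal,
    grip_summary = report$grip$summary
  )
  for (nm in names(flat)) {
    if (!is.null(flat[[nm]])) {
      write.csv(flat[[nm]], file.path(dir, paste0(nm, ".csv")),
                row.names = FALSE)
    }
  }
  summary <- list(sections = names(flat)[!vapply(flat, is.null, logical(1))])
  if (!is.null(report$grip$test)) summary$grip_test <- report$grip$test
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Published cohort summary statistics
#'
#' Loads the reference cohort summary tables shipped with the package:
#' per-trial performance means/SDs and SUS means/SDs by cohort, with cohort
#' sizes. These are summary statistics only (no participant-level data is
#' distributed) and back the in-arithmetic checks such as trial averages and
#' the size-weighted overall SUS mean.
#'
#' @param which `"scores"` or `"sus"`.
#' @return Tibble.
#' @export
reference_summaries <- function(which = c("scores", "sus")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   if (which == "scores") "reference_trial_scores.csv"
                   else "reference_sus.csv",
                   package = "mdatsim", mustWork = TRUE)
  tibble::as_tibble(read.csv(f))
}
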