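make_study <- function(seed = 3) {
  pop <- function(n, sd) replicate(n, user_model(aim_sd = sd),
                                   simplify = FALSE)
  dplyr::bind_rows(
    simulate_cohort("A1", 4, population = pop(4, 120), seed = seed),
    simulate_cohort("A2", 4, population = pop(4, 180), seed = seed + 1),
    simulate_cohort("A3", 4, population = pop(4, 180), seed = seed + 2),
    simulate_cohort("B1", 6, population = pop(6, 180), seed = seed + 3)
  )
}

test_that("the trial score table reports cohort x trial means with overall", {
  scores <- make_study()
  tab <- trial_score_table(scores)
  expect_setequal(tab$cohort, c("A1", "A2", "A3", "B1"))
  a1 <- tab[tab$cohort == "A1", ]
  expect_equal(a1$trial1_mean, 15)
  expect_equal(a1$trial1_sd, 0)
  expect_equal(a1$overall_mean, 15)
  expect_equal(a1$overall_sd, 0)
  # overall equals the mean of per-participant averages
  b1 <- scores[scores$cohort == "B1", ]
  per_part <- tapply(b1$score, b1$participant_id, mean)
  expect_equal(tab$overall_mean[tab$cohort == "B1"], mean(per_part))
})

test_that("matched-trial comparisons pair B1 trials with their static cohorts", {
  scores <- make_study()
  tab <- between_cohort_table(scores)
  expect_equal(tab$comparison,
               c("B1 vs A1, trial 1", "B1 vs A2, trial 2", "B1 vs A3, trial 3"))
  # cross-check one row against welch_t directly
  b <- scores$score[scores$cohort == "B1" & scores$trial == 2]
  a <- scores$score[scores$cohort == "A2" & scores$trial == 2]
  ref <- welch_t(b, a)
  expect_equal(tab$mean_diff[2], round(ref$mean_diff, 2))
  expect_equal(tab$welch_t[2], round(ref$statistic, 2))
  expect_equal(tab$p[2], ref$p)
})

test_that("SUS table pools the overall row by sample size", {
  surveys <- score_survey_table(synth_surveys(seed = 10))
  tab <- sus_table(surveys)
  expect_equal(tab$cohort, c("A1", "A2", "A3", "B1", "Overall"))
  by <- tab[tab$cohort != "Overall", ]
  expect_equal(tab$mean[tab$cohort == "Overall"],
               round(pool_cohort_means(by$mean, by$n), 1))
  expect_equal(sum(by$n), 54)
})

test_that("TLX tables carry subscale Kruskal-Wallis tests and ordered contrasts", {
  surveys <- score_survey_table(synth_surveys(seed = 11))
  tl <- tlx_table(surveys)
  expect_equal(nrow(tl$kruskal), 6)
  expect_true(all(tl$kruskal$df == 3))
  expect_true(all(tl$kruskal$p >= 0 & tl$kruskal$p <= 1))
  pw <- tlx_pairwise_table(surveys, "performance")
  expect_equal(nrow(pw), 6)              # all cohort pairs
  expect_true(!is.unsorted(pw$p))        # most significant rows first
  # the A1-vs-A3 performance gap is the largest standardized difference
  expect_equal(pw$comparison[which.max(pw$d_av)], "A1, A3")
})

test_that("grip strength summary separates genders and tests men vs women", {
  surveys <- score_survey_table(synth_surveys(seed = 12))
  g <- grip_table(surveys)
  expect_true(all(c("n", "mean", "sd") %in% names(g$summary)))
  men <- g$summary$mean[g$summary$gender == "men"]
  women <- g$summary$mean[g$summary$gender == "women"]
  expect_gt(men, women)
  expect_true(g$test$p < 0.05)
  expect_lt(g$test$rank_biserial, 0)  # men's ranks dominate
})

test_that("the report degrades gracefully and round-trips to disk", {
  scores <- make_study()
  surveys <- score_survey_table(synth_surveys(seed = 13))
  rep_full <- build_report(scores, surveys)
  expect_s3_class(rep_full, "study_report")
  expect_warning(build_report(scores[scores$cohort != "A2", ], surveys),
                 "missing cohorts: A2")
  expect_warning(rep_part <- build_report(scores, NULL), "survey")
  expect_null(rep_part$sus)
  d <- withr::local_tempdir()
  write_report(rep_full, d)
  expect_true(file.exists(file.path(d, "trial_scores.csv")))
  expect_true(file.exists(file.path(d, "sus.csv")))
  back <- read.csv(file.path(d, "sus.csv"))
  expect_equal(back$mean, rep_full$sus$mean)
  js <- jsonlite::fromJSON(file.path(d, "summary.json"))
  expect_true("sus" %in% js$sections)
})

test_that("reference cohort summaries load and reproduce printed arithmetic", {
  sc <- reference_summaries("scores")
  expect_equal(nrow(sc), 12)
  sus <- reference_summaries("sus")
  expect_equal(sum(sus$n), 54)
  expect_equal(round(pool_cohort_means(sus$mean, sus$n), 1), 73.6)
  expect_equal(round(trial_average(sc$mean[sc$cohort == "A2"]), 1), 9.1)
})

test_that("run configs validate and round-trip through YAML", {
  cfg <- run_config(seed = 7)
  expect_equal(cfg$cohort_sizes, c(A1 = 9, A2 = 10, A3 = 9, B1 = 26))
  p <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, p)
  back <- read_run_config(p)
  expect_equal(back$cohort_sizes, cfg$cohort_sizes)
  expect_equal(back$seed, 7L)
  expect_equal(back$filter$highpass_hz, 2)
  expect_error(run_config(cohort_sizes = c(Z9 = 5)), "unknown cohorts")
  expect_error(run_config(cohort_sizes = c(9, 10)), "named")
})

test_that("the CLI driver ships with the package and parses", {
  p <- system.file("cli", "mdat.R", package = "mdatsim")
  expect_true(file.exists(p))
  expect_silent(parse(p))
})
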