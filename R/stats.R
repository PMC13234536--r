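#' Cohort statistics
#'
#' The study's inferential toolkit: paired two-sided t tests with a
#' Shapiro-Wilk normality gate (Wilcoxon signed-rank attached as a
#' nonparametric sensitivity analysis when the gate fires), Welch two-sided t
#' tests between cohorts with pooled Cohen d, Hedges g and d_av, tie-corrected
#' Kruskal-Wallis omnibus tests, Spearman rank correlation, and Mann-Whitney U
#' with rank-biserial r. All tests are two-sided at alpha = .05 and no
#' multiple-comparison adjustment is applied anywhere.
#'
#' @name stats-pipeline
NULL

comparison_result <- function(mean_diff = NA_real_, ci95 = c(NA_real_, NA_real_),
                              statistic = NA_real_, df = NA_real_, p = NA_real_,
                              cohen_d = NA_real_, hedges_g = NA_real_,
                              d_av = NA_real_, rank_biserial = NA_real_,
                              method = "", flags = character(0),
                              sensitivity = NULL) {
  structure(list(mean_diff = mean_diff, ci95 = ci95, statistic = statistic,
                 df = df, p = p, cohen_d = cohen_d, hedges_g = hedges_g,
                 d_av = d_av, rank_biserial = rank_biserial, method = method,
                 flags = flags, sensitivity = sensitivity),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<%s>\n", x$method))
  cat(sprintf("  mean diff %.3f (95%% CI %.3f to %.3f)\n",
              x$mean_diff, x$ci95[1], x$ci95[2]))
  cat(sprintf("  statistic %.3f (df %.1f), p = %.4g\n", x$statistic, x$df, x$p))
  if (!is.na(x$cohen_d)) {
    cat(sprintf("  d %.3f, g %.3f, d_av %.3f\n", x$cohen_d, x$hedges_g, x$d_av))
  }
  if (!is.na(x$rank_biserial)) {
    cat(sprintf("  rank-biserial r %.3f\n", x$rank_biserial))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  if (!is.null(x$sensitivity)) {
    cat(sprintf("  Wilcoxon sensitivity: W %.1f, p = %.4g\n",
                x$sensitivity$statistic, x$sensitivity$p))
  }
  invisible(x)
}

#' Small-sample correction factor for Hedges g
#'
#' The default is the `1 - 3 / (4 df - 1)` approximation; `exact = TRUE` uses
#' the exact gamma-ratio correction `J(df) = gamma(df/2) /
#' (sqrt(df/2) gamma((df-1)/2))`.
#'
#' @param df Degrees of freedom of the standardizer.
#' @param exact Use the exact gamma-ratio correction.
#' @return Correction factor in `(0, 1)`.
#' @export
hedges_correction <- function(df, exact = FALSE) {
  stopifnot(df > 1)
  if (exact) {
    exp(lgamma(df / 2) - log(sqrt(df / 2)) - lgamma((df - 1) / 2))
  } else {
    1 - 3 / (4 * df - 1)
  }
}

#' Paired t test with Shapiro-Wilk normality gate
#'
#' Paired two-sided t test (df = n - 1) with paired Cohen
#' `d = mean(diff) / sd(diff)` and Hedges g. When Shapiro-Wilk on the paired
#' differences gives p < `gate_alpha`, a Wilcoxon signed-rank test is attached
#' as a nonparametric sensitivity analysis.
#'
#' @param x,y Paired samples of equal length (>= 3).
#' @param gate_alpha Normality-gate alpha (default .05).
#' @param exact_hedges Use the exact Hedges correction.
#' @return A `comparison_result`; `sensitivity` holds the Wilcoxon result when
#'   the gate fired, and `flags` notes degenerate inputs (all differences
#'   zero: effect size undefined).
#' @export
paired_t_gate <- function(x, y, gate_alpha = 0.05, exact_hedges = FALSE) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  d <- x - y
  n <- length(d)
  flags <- character(0)
  if (sd(d) == 0) {
    flags <- "zero-variance differences: t and effect size undefined"
    return(comparison_result(mean_diff = mean(d), ci95 = c(mean(d), mean(d)),
                             statistic = if (mean(d) == 0) 0 else NA_real_,
                             df = n - 1, p = if (mean(d) == 0) 1 else NA_real_,
                             method = "paired t", flags = flags))
  }
  tt <- t.test(x, y, paired = TRUE)
  cd <- mean(d) / sd(d)
  g <- cd * hedges_correction(n - 1, exact_hedges)
  sens <- NULL
  shap_p <- shapiro.test(d)$p.value
  if (shap_p < gate_alpha) {
    w <- suppressWarnings(wilcox.test(x, y, paired = TRUE))
    sens <- list(statistic = unname(w$statistic), p = w$p.value,
                 shapiro_p = shap_p)
  }
  comparison_result(mean_diff = unname(tt$estimate),
                    ci95 = as.numeric(tt$conf.int),
                    statistic = unname(tt$statistic),
                    df = unname(tt$parameter), p = tt$p.value,
                    cohen_d = cd, hedges_g = g,
                    method = "paired t (Shapiro-gated)",
                    sensitivity = sens)
}

#' Welch two-sided t test with pooled d, Hedges g and d_av
#'
#' Welch statistic and Welch-Satterthwaite df; 95% CI on the mean difference
#' from the t distribution at that df. Effect sizes use conventional
#' definitions: pooled Cohen d standardized by the pooled SD with
#' `df = n_a + n_b - 2`, Hedges `g = d * (1 - 3 / (4 df - 1))` on that pooled
#' df, and `d_av = mean_diff / ((sd_a + sd_b) / 2)`.
#'
#' @param a,b Independent samples, each of length >= 2.
#' @param exact_hedges Use the exact Hedges correction.
#' @return A `comparison_result`.
#' @export
welch_t <- function(a, b, exact_hedges = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2,
            all(is.finite(a)), all(is.finite(b)))
  na <- length(a); nb <- length(b)
  md <- mean(a) - mean(b)
  if (sd(a) == 0 && sd(b) == 0) {
    flags <- "zero variance in both groups: statistic undefined"
    if (md == 0) {
      return(comparison_result(mean_diff = 0, ci95 = c(0, 0), statistic = 0,
                               df = NA_real_, p = 1, cohen_d = 0,
                               hedges_g = 0, d_av = 0, method = "Welch t",
                               flags = flags))
    }
    return(comparison_result(mean_diff = md, ci95 = c(md, md),
                             method = "Welch t", flags = flags))
  }
  tt <- t.test(a, b, var.equal = FALSE)
  df_pool <- na + nb - 2
  sd_pool <- sqrt(((na - 1) * sd(a)^2 + (nb - 1) * sd(b)^2) / df_pool)
  cd <- md / sd_pool
  g <- cd * hedges_correction(df_pool, exact_hedges)
  dav <- md / ((sd(a) + sd(b)) / 2)
  comparison_result(mean_diff = md, ci95 = as.numeric(tt$conf.int),
                    statistic = unname(tt$statistic),
                    df = unname(tt$parameter), p = tt$p.value,
                    cohen_d = cd, hedges_g = g, d_av = dav,
                    method = "Welch t")
}

#' Kruskal-Wallis omnibus test
#'
#' Tie-corrected H with a chi-square p on k - 1 df (via
#' [stats::kruskal.test()]).
#'
#' @param groups List of numeric samples (>= 2 groups, none empty).
#' @return List with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, integer(1)) == 0L)) {
    stop("Kruskal-Wallis requires every group to be non-empty")
  }
  if (length(unique(unlist(groups))) == 1L) {
    # all observations tied: no rank variation, no evidence against the null
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  }
  kt <- kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; p from the t approximation.
#'
#' @param x,y Equal-length samples (>= 3).
#' @return List with `rho`, `p`, and `flags` (constant input: rho undefined).
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_,
                flags = "constant input: rho undefined"))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, flags = character(0))
}

#' Mann-Whitney U with rank-biserial r
#'
#' U counts pairs where `a` exceeds `b` (ties count one half); rank-biserial
#' `r = 1 - 2U / (n_a n_b)`. The p-value uses the exact distribution for small
#' tie-free samples (both n <= 8) and the tie-corrected normal approximation
#' otherwise.
#'
#' @param a,b Samples, each of length >= 1.
#' @return List with `U`, `p`, `rank_biserial`.
#' @export
mann_whitney <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  na <- length(a); nb <- length(b)
  has_ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- !has_ties && na <= 8 && nb <= 8
  wt <- suppressWarnings(wilcox.test(a, b, exact = use_exact, correct = TRUE))
  u <- unname(wt$statistic)  # pairs with a > b (+ half-ties)
  list(U = u, p = wt$p.value, rank_biserial = 1 - 2 * u / (na * nb))
}
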