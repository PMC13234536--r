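#' Psychometric instrument scoring
#'
#' Scoring exactly as constructed in the study pipeline: SUS (10 items, 1-5;
#' odd items contribute `x - 1`, even items `5 - x`, sum times 2.5, yielding
#' 0-100), raw NASA-TLX (6 items, 1-21, rescaled to 0-100 via `(x - 1) * 5`;
#' the performance subscale is inversely oriented: higher = better perceived
#' performance), and the Edinburgh Handedness laterality quotient
#' `(R - L) / (R + L) * 100`.
#'
#' @name survey-scoring
NULL

tlx_subscales <- c("mental", "physical", "temporal", "performance",
                   "effort", "frustration")

#' Score the System Usability Scale
#'
#' @param items Integer vector of the 10 SUS item responses, each in 1-5,
#'   in questionnaire order (item 1 first).
#' @return SUS score in `[0, 100]`.
#' @examples
#' score_sus(rep(3, 10)) # 50
#' @export
score_sus <- function(items) {
  if (length(items) != 10L) stop("SUS requires exactly 10 items")
  if (any(!is.finite(items)) || any(items < 1) || any(items > 5) ||
      any(items != as.integer(items))) {
    stop("SUS items must be integers in [1, 5]")
  }
  odd <- items[seq(1, 9, by = 2)]
  even <- items[seq(2, 10, by = 2)]
  2.5 * (sum(odd - 1) + sum(5 - even))
}

#' Score the raw NASA-TLX
#'
#' @param items Integer vector of 6 responses in 1-21, ordered (mental,
#'   physical, temporal, performance, effort, frustration); names are honored
#'   if present.
#' @return Named list: the six subscale scores in `[0, 100]` (via
#'   `(x - 1) * 5`) and `composite` — the unweighted mean of the six with the
#'   inversely-oriented performance subscale entered as `100 - performance`
#'   (labelled composite_inverted_performance in outputs).
#' @examples
#' score_tlx(rep(11, 6)) # every subscale 50
#' @export
score_tlx <- function(items) {
  if (length(items) != 6L) stop("NASA-TLX requires exactly 6 items")
  if (any(!is.finite(items)) || any(items < 1) || any(items > 21) ||
      any(items != as.integer(items))) {
    stop("NASA-TLX items must be integers in [1, 21]")
  }
  if (!is.null(names(items)) && all(tlx_subscales %in% names(items))) {
    items <- items[tlx_subscales]
  }
  sub <- (items - 1) * 5
  names(sub) <- tlx_subscales
  composite <- mean(c(sub[setdiff(tlx_subscales, "performance")],
                      100 - sub[["performance"]]))
  c(as.list(sub), list(composite = composite))
}

#' Edinburgh Handedness laterality quotient
#'
#' @param r,l Nonnegative response tallies for right- and left-hand
#'   preference; `r + l` must be positive.
#' @return LQ in `[-100, 100]`.
#' @examples
#' score_ehi(7, 3) # 40
#' @export
score_ehi <- function(r, l) {
  stopifnot(is.numeric(r), is.numeric(l), length(r) == length(l))
  if (any(r < 0 | l < 0)) stop("EHI tallies must be nonnegative")
  if (any(r + l == 0)) stop("EHI requires at least one response (R + L > 0)")
  (r - l) / (r + l) * 100
}

#' Classify handedness from the laterality quotient
#'
#' The study classified a laterality quotient above 40 as right-handed.
#'
#' @param lq Laterality quotient(s).
#' @param cutoff Classification cutoff (default 40).
#' @return Character vector: `"right"` or `"other"`.
#' @export
classify_handedness <- function(lq, cutoff = 40) {
  ifelse(lq > cutoff, "right", "other")
}

#' Score a raw survey table
#'
#' Takes one row per participant with columns `sus_01`..`sus_10`,
#' `tlx_mental`, `tlx_physical`, `tlx_temporal`, `tlx_performance`,
#' `tlx_effort`, `tlx_frustration` (raw 1-21), `ehi_r`, `ehi_l`, and appends
#' `sus_score`, the six rescaled `tlx_*_score` columns, `tlx_composite`,
#' `ehi_lq` and `handedness_class`.
#'
#' @param df Raw survey data.frame / tibble.
#' @return The input with scored columns appended.
#' @export
score_survey_table <- function(df) {
  sus_cols <- sprintf("sus_%02d", 1:10)
  tlx_cols <- paste0("tlx_", tlx_subscales)
  need <- c(sus_cols, tlx_cols, "ehi_r", "ehi_l")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("survey table is missing columns: ", paste(missing, collapse = ", "))
  }
  df <- tibble::as_tibble(df)
  df$sus_score <- apply(as.matrix(df[sus_cols]), 1L, score_sus)
  tlx_scored <- t(apply(as.matrix(df[tlx_cols]), 1L, function(x) {
    s <- score_tlx(x)
    unlist(s)
  }))
  colnames(tlx_scored) <- c(paste0("tlx_", tlx_subscales, "_score"),
                            "tlx_composite")
  df <- dplyr::bind_cols(df, tibble::as_tibble(tlx_scored))
  df$ehi_lq <- score_ehi(df$ehi_r, df$ehi_l)
  df$handedness_class <- classify_handedness(df$ehi_lq)
  df
}
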