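#' Run configuration
#'
#' One YAML config format ties the pipeline together: thresholds, filter
#' settings, cohort sizes (defaults are the study sizes), and seeds. The
#' resolved config (with seeds) is echoed into every output directory so
#' runs are reproducible from their artifacts alone; environment variables
#' are never consulted.
#'
#' @name run-config
NULL

#' Construct and validate a run configuration
#'
#' @param cohort_sizes Named integer vector; defaults to the study design
#'   (A1: 9, A2: 10, A3: 9, B1: 26).
#' @param resting Resting threshold on the device scale.
#' @param filter A [filter_config()].
#' @param seed Master seed.
#' @param n_cues Cues per trial.
#' @return A validated `run_config` list.
#' @export
run_config <- function(cohort_sizes = c(A1 = 9, A2 = 10, A3 = 9, B1 = 26),
                       resting = 23, filter = filter_config(), seed = 1,
                       n_cues = 15) {
  if (is.null(names(cohort_sizes)) || any(names(cohort_sizes) == "")) {
    stop("cohort_sizes must be a named vector")
  }
  bad <- setdiff(names(cohort_sizes), c("A1", "A2", "A3", "B1"))
  if (length(bad)) stop("unknown cohorts: ", paste(bad, collapse = ", "))
  stopifnot(all(cohort_sizes >= 1), resting >= 0, resting < 1023,
            inherits(filter, "filter_config"), n_cues >= 1)
  structure(list(cohort_sizes = cohort_sizes, resting = as.integer(resting),
                 filter = filter, seed = as.integer(seed),
                 n_cues = as.integer(n_cues)),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return For `read_run_config`, a validated `run_config`.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  filt <- if (is.null(x$filter)) filter_config() else
    filter_config(x$filter$highpass_hz %||% 2,
                  x$filter$smoothing_window_ms %||% 50,
                  x$filter$filter_order %||% 2)
  sizes <- if (is.null(x$cohort_sizes)) c(A1 = 9, A2 = 10, A3 = 9, B1 = 26)
           else unlist(x$cohort_sizes)
  run_config(cohort_sizes = sizes,
             resting = x$resting %||% 23,
             filter = filt,
             seed = x$seed %||% 1,
             n_cues = x$n_cues %||% 15)
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(list(
    cohort_sizes = as.list(config$cohort_sizes),
    resting = config$resting,
    filter = unclass(config$filter),
    seed = config$seed,
    n_cues = config$n_cues), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
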