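#' Read a ratings table from CSV
#'
#' Accepts either a wide layout (one row per subject, first column the
#' subject id, remaining columns one per rater/series) or the long layout
#' written by [write_ratings()] (`subject`, `column`, `value`, optionally
#'  `metric`), and returns a long tibble ready for [reliability_report()].
#'
#' @param path CSV file path (UTF-8, header row).
#' @return A long tibble with columns `subject`, `rater`, `value` (plus
#'   `metric` when present).
#' @export
read_ratings <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (all(c("subject", "column", "value") %in% names(df))) {
    out <- tibble::tibble(
      subject = df$subject, rater = df$column, value = as.numeric(df$value)
    )
    if ("metric" %in% names(df)) out$metric <- df$metric
    return(out)
  }
  long <- tidyr::pivot_longer(
    tibble::as_tibble(df), -1,
    names_to = "rater", values_to = "value"
  )
  names(long)[1] <- "subject"
  long$value <- as.numeric(long$value)
  long
}

#' Write a ratings table as long CSV
#'
#' Long layout: `subject`, `column`, `metric`, `value` — one measurement
#' per row.
#'
#' @param data Long ratings tibble (e.g. from [simulate_ratings()]), with a
#'   subject column, a rater/series column and a value column.
#' @param path Output CSV path.
#' @param metric Metric label to record (defaults to a `metric` column when
#'   present, else `"score"`).
#' @return `path`, invisibly.
#' @export
write_ratings <- function(data, path, metric = NULL) {
  col <- intersect(c("rater", "series", "column"), names(data))[1]
  stopifnot(!is.na(col), all(c("subject", "value") %in% names(data)))
  out <- data.frame(
    subject = data$subject,
    column = data[[col]],
    metric = metric %||%
      (if ("metric" %in% names(data)) data$metric else "score"),
    value = data$value
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' A configuration names the experiment (`exp1` or `exp2`), an integer
#' `seed`, and optional generator overrides: any field of
#' [cohort_spec()] under `cohort`, rows overriding [exp1_score_specs()]
#' under `scores`, and scalar options (`n_subjects`, `n_raters`,
#' `n_boot`). The configuration round-trips losslessly through
#' [write_config()].
#'
#' @param path YAML file path.
#' @return A named list with class `pipeline_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$experiment) ||
      !cfg$experiment %in% c("exp1", "exp2")) {
    stop("config must set `experiment: exp1` or `exp2`", call. = FALSE)
  }
  if (is.null(cfg$seed)) {
    stop("config must set an integer `seed`", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname read_config
#' @param config A `pipeline_config` (or plain list).
#' @return `write_config()` returns `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the experiment named by a configuration
#'
#' Thin driver used by the command-line interface: dispatches to
#' [run_experiment1()] or [run_experiment2()] with any overrides the
#' configuration carries.
#'
#' @param config A `pipeline_config` from [read_config()].
#' @return The report object of the dispatched pipeline.
#' @export
run_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config") || is.list(config))
  if (config$experiment == "exp1") {
    run_experiment1(
      n_subjects = config$n_subjects %||% 40,
      n_raters = config$n_raters %||% 3,
      seed = config$seed
    )
  } else {
    spec <- do.call(cohort_spec, config$cohort %||% list())
    run_experiment2(
      spec = spec,
      n_boot = config$n_boot %||% 5000,
      seed = config$seed
    )
  }
}
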