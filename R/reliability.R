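#' Coerce ratings to a complete subjects-by-columns matrix
#'
#' Accepts either a numeric matrix / all-numeric wide data frame (one row
#' per subject, one column per rater or series) or a long tibble with
#' subject, column and value variables, and returns the complete numeric
#' matrix the two-way ANOVA operates on.
#'
#' @param data Ratings in wide or long form.
#' @param subject,column,value Column names used when `data` is long. The
#'   column variable defaults to whichever of `rater` or `series` is
#'   present.
#' @return A numeric matrix with at least 2 rows and 2 columns and no
#'   missing cells.
#' @export
as_ratings_matrix <- function(data, subject = "subject", column = NULL,
                              value = "value") {
  if (is.matrix(data)) {
    m <- data
  } else if (is.data.frame(data) &&
             !(subject %in% names(data) && value %in% names(data))) {
    m <- as.matrix(data)
  } else {
    if (is.null(column)) {
      column <- intersect(c("rater", "series", "column"), names(data))[1]
      if (is.na(column)) {
        stop("cannot find a rater/series column in long ratings data",
             call. = FALSE)
      }
    }
    wide <- tidyr::pivot_wider(
      data[, c(subject, column, value)],
      names_from = dplyr::all_of(column), values_from = dplyr::all_of(value)
    )
    m <- as.matrix(wide[, -1, drop = FALSE])
    rownames(m) <- as.character(wide[[subject]])
  }
  if (!is.numeric(m)) stop("ratings must be numeric", call. = FALSE)
  if (anyNA(m)) {
    stop("ratings matrix has missing cells; a complete design is required",
         call. = FALSE)
  }
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("need at least 2 subjects and 2 measurement columns", call. = FALSE)
  }
  m
}

#' Two-way crossed ANOVA mean squares and variance components
#'
#' Decomposes a complete subjects-by-raters (or subjects-by-series) table
#' into the standard two-way crossed mean squares without replication, and
#' converts them to random-effects variance components:
#' \deqn{\hat\sigma^2_{subject} = (MS_{rows} - MS_{error})/k, \quad
#'       \hat\sigma^2_{observer} = (MS_{cols} - MS_{error})/n, \quad
#'       \hat\sigma^2_{residual} = MS_{error}.}
#' Negative component estimates are reported as-is (not truncated) and
#' flagged.
#'
#' @inheritParams as_ratings_matrix
#' @return An `anova_components` list with `ms_rows`, `ms_cols`,
#'   `ms_error`, `sigma2_subject`, `sigma2_observer`, `sigma2_residual`,
#'   `n`, `k`, `grand_mean`, `negative_components` (character vector of
#'   flagged components, possibly empty).
#' @export
anova_components <- function(data, subject = "subject", column = NULL,
                             value = "value") {
  m <- as_ratings_matrix(data, subject, column, value)
  n <- nrow(m)
  k <- ncol(m)
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)

  ms_rows <- k * sum((row_means - grand)^2) / (n - 1)
  ms_cols <- n * sum((col_means - grand)^2) / (k - 1)
  resid <- m - outer(row_means, col_means, "+") + grand
  ms_error <- sum(resid^2) / ((n - 1) * (k - 1))

  s2_subject <- (ms_rows - ms_error) / k
  s2_observer <- (ms_cols - ms_error) / n
  s2_residual <- ms_error
  flagged <- c("sigma2_subject", "sigma2_observer")[
    c(s2_subject < 0, s2_observer < 0)
  ]

  structure(
    list(
      ms_rows = ms_rows, ms_cols = ms_cols, ms_error = ms_error,
      sigma2_subject = s2_subject, sigma2_observer = s2_observer,
      sigma2_residual = s2_residual,
      n = n, k = k, grand_mean = grand,
      negative_components = flagged
    ),
    class = "anova_components"
  )
}

#' @export
print.anova_components <- function(x, ...) {
  cat(sprintf(
    "<anova_components> n=%d, k=%d | MS rows %.4g, cols %.4g, error %.4g | s2 subject %.4g, observer %.4g, residual %.4g\n",
    x$n, x$k, x$ms_rows, x$ms_cols, x$ms_error,
    x$sigma2_subject, x$sigma2_observer, x$sigma2_residual
  ))
  if (length(x$negative_components)) {
    cat("  note: negative component estimate(s):",
        paste(x$negative_components, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Intraclass correlation, two-way random effects, absolute agreement
#'
#' Single-measures form:
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E +
#'   \frac{k}{n}(MS_C - MS_E)}}
#' and its average-measures counterpart
#' \deqn{ICC(2,k) = \frac{MS_R - MS_E}{MS_R + (MS_C - MS_E)/n}.}
#' Confidence intervals use the Shrout-Fleiss F-based procedure; the
#' average-measures interval is the Spearman-Brown transform of the
#' single-measures bounds.
#'
#' @inheritParams as_ratings_matrix
#' @param form `"single"` for ICC(2,1) or `"average"` for ICC(2,k), where
#'   `k` is the number of measurement columns supplied.
#' @param conf_level Confidence level of the interval.
#' @return A one-row tibble: `form`, `n`, `k`, `estimate`, `conf_low`,
#'   `conf_high`, `conf_level`, `band` (qualitative interpretation of the
#'   estimate, see [classify_icc()]).
#' @examples
#' set.seed(1)
#' ratings <- simulate_ratings(variance_spec(50, 3, 0.5, 0.5, 200, 3))
#' icc(ratings, form = "single")
#' @export
icc <- function(data, form = c("single", "average"), conf_level = 0.95,
                subject = "subject", column = NULL, value = "value") {
  form <- match.arg(form)
  m <- as_ratings_matrix(data, subject, column, value)
  comp <- anova_components(m)
  n <- comp$n
  k <- comp$k
  msr <- comp$ms_rows
  msc <- comp$ms_cols
  mse <- comp$ms_error

  denom_single <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (abs(denom_single) < .Machine$double.eps * max(1, abs(msr))) {
    stop("ICC is undefined: the ratings matrix has no variance",
         call. = FALSE)
  }
  icc21 <- (msr - mse) / denom_single

  # Shrout-Fleiss interval for the single-measures form
  alpha <- 1 - conf_level
  fj <- msc / mse
  vn_num <- (k - 1) * (n - 1) *
    (k * icc21 * fj + n * (1 + (k - 1) * icc21) - k * icc21)^2
  vn_den <- (n - 1) * k^2 * icc21^2 * fj^2 +
    (n * (1 + (k - 1) * icc21) - k * icc21)^2
  v <- vn_num / vn_den
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)

  if (form == "average") {
    sb <- function(r) k * r / (1 + (k - 1) * r)
    est <- (msr - mse) / (msr + (msc - mse) / n)
    lower <- sb(lower)
    upper <- sb(upper)
  } else {
    est <- icc21
  }

  tibble::tibble(
    form = form, n = n, k = k,
    estimate = est, conf_low = lower, conf_high = upper,
    conf_level = conf_level, band = classify_icc(est)
  )
}

#' Standard error of measurement from variance components
#'
#' \eqn{\mathrm{SEM} = \sqrt{\sigma^2_{observer} + \sigma^2_{residual}}},
#' the agreement-type measurement error in the metric's own units. Negative
#' component estimates are floored at zero inside the radical, with a
#' warning.
#'
#' @param components An [anova_components()] object.
#' @return SEM (non-negative scalar, metric units).
#' @export
sem_measurement <- function(components) {
  stopifnot(inherits(components, "anova_components"))
  s2o <- components$sigma2_observer
  s2r <- components$sigma2_residual
  if (s2o < 0 || s2r < 0) {
    warning("negative variance component floored at 0 inside the SEM",
            call. = FALSE)
  }
  sqrt(max(s2o, 0) + max(s2r, 0))
}

#' Coefficient of variation of measurement error
#'
#' SEM expressed as a percentage of the mean score, allowing error
#' comparison across metrics with different units.
#'
#' @param sem Standard error of measurement (metric units).
#' @param mean_score Mean score in the same units; must be non-zero.
#' @return CoV in percent.
#' @export
cov_percent <- function(sem, mean_score) {
  stopifnot(sem >= 0)
  if (any(mean_score == 0)) {
    stop("CoV is undefined for a zero mean score", call. = FALSE)
  }
  100 * sem / abs(mean_score)
}

#' Smallest detectable change
#'
#' \eqn{\mathrm{SDC} = z \sqrt{2}\, \mathrm{SEM}} with the two-sided
#' standard-normal quantile for the requested confidence (1.2816, 1.4395,
#' 1.6449 and 1.9600 at 80/85/90/95%; any level in (0, 1) is accepted).
#'
#' @param sem Standard error of measurement (metric units).
#' @param confidence Confidence level(s) in (0, 1); vectorised.
#' @return SDC value(s) in metric units.
#' @examples
#' sdc(12.1, c(0.80, 0.85, 0.90, 0.95))
#' @export
sdc <- function(sem, confidence = c(0.80, 0.85, 0.90, 0.95)) {
  stopifnot(sem >= 0, all(confidence > 0), all(confidence < 1))
  z <- round(stats::qnorm(1 - (1 - confidence) / 2), 4)
  z * sqrt(2) * sem
}

#' Qualitative interpretation band of an ICC
#'
#' Poor below 0.5, moderate in 0.5-0.74, good in 0.75-0.89, excellent at
#' 0.90 and above.
#'
#' @param value ICC estimate(s), at most 1.
#' @return Character vector of bands.
#' @export
classify_icc <- function(value) {
  stopifnot(all(value <= 1 + 1e-12))
  cut(value, breaks = c(-Inf, 0.5, 0.75, 0.90, Inf), right = FALSE,
      labels = c("poor", "moderate", "good", "excellent")) |>
    as.character()
}

#' Qualitative band of a CoV percentage
#'
#' Categories `<10%`, `10-20%` and `>20%`.
#'
#' @param cov_pct CoV value(s) in percent.
#' @return Character vector of bands.
#' @export
classify_cov <- function(cov_pct) {
  stopifnot(all(cov_pct >= 0))
  cut(cov_pct, breaks = c(-Inf, 10, 20, Inf), right = TRUE,
      labels = c("<10%", "10-20%", ">20%")) |>
    as.character()
}

#' Full reliability report for one ratings table
#'
#' Chains the two-way ANOVA decomposition, both ICC forms with confidence
#' intervals, SEM, CoV and the SDC family into one report object.
#'
#' @inheritParams as_ratings_matrix
#' @param metric,units Labels carried into the report.
#' @param sdc_levels Confidence levels of the SDC family.
#' @param conf_level Confidence level of the ICC intervals.
#' @return A `reliability_report` with elements `metric`, `units`,
#'   `components` ([anova_components()]), `icc` (two-row tibble, both
#'   forms), `sem`, `cov_pct`, `cov_band`, `sdc` (tibble `confidence`,
#'   `value`), `mean_score`, `sd_score`.
#' @export
reliability_report <- function(data, metric = NULL, units = NULL,
                               sdc_levels = c(0.80, 0.85, 0.90, 0.95),
                               conf_level = 0.95,
                               subject = "subject", column = NULL,
                               value = "value") {
  m <- as_ratings_matrix(data, subject, column, value)
  if (is.null(metric) && is.data.frame(data) && "metric" %in% names(data)) {
    metric <- as.character(data$metric[1])
  }
  comp <- anova_components(m)
  icc_tbl <- dplyr::bind_rows(
    icc(m, "single", conf_level),
    icc(m, "average", conf_level)
  )
  sem_val <- sem_measurement(comp)
  cov_val <- cov_percent(sem_val, comp$grand_mean)
  structure(
    list(
      metric = metric %||% "score", units = units %||% "",
      components = comp,
      icc = icc_tbl,
      sem = sem_val,
      cov_pct = cov_val,
      cov_band = classify_cov(cov_val),
      sdc = tibble::tibble(confidence = sdc_levels,
                           value = sdc(sem_val, sdc_levels)),
      mean_score = comp$grand_mean,
      sd_score = stats::sd(as.vector(m))
    ),
    class = "reliability_report"
  )
}

#' @export
print.reliability_report <- function(x, ...) {
  single <- x$icc[x$icc$form == "single", ]
  cat(sprintf(
    "<reliability_report> %s: mean %.1f %s | ICC(2,1) %.2f (%.2f-%.2f, %s) | SEM %.1f | CoV %.1f%% (%s)\n",
    x$metric, x$mean_score, x$units,
    single$estimate, single$conf_low, single$conf_high, single$band,
    x$sem, x$cov_pct, x$cov_band
  ))
  cat("  SDC:",
      paste(sprintf("%.0f%% -> %.1f", 100 * x$sdc$confidence, x$sdc$value),
            collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn reliability_report One row per ICC form with the shared
#'   SEM/CoV columns.
#' @param x A `reliability_report`.
#' @param ... Unused.
#' @method tidy reliability_report
#' @export
tidy.reliability_report <- function(x, ...) {
  dplyr::mutate(
    x$icc,
    metric = x$metric, units = x$units,
    mean_score = x$mean_score, sem = x$sem, cov_pct = x$cov_pct,
    cov_band = x$cov_band,
    .before = 1
  )
}

#' @describeIn reliability_report One-row summary in the layout of a
#'   reliability table: mean, ICC(2,1) with CI, SEM, CoV, SDC ladder.
#' @method glance reliability_report
#' @export
glance.reliability_report <- function(x, ...) {
  single <- x$icc[x$icc$form == "single", ]
  out <- tibble::tibble(
    metric = x$metric, units = x$units,
    mean_score = x$mean_score, sd_score = x$sd_score,
    icc21 = single$estimate,
    icc21_low = single$conf_low, icc21_high = single$conf_high,
    icc_band = single$band,
    sem = x$sem, cov_pct = x$cov_pct, cov_band = x$cov_band
  )
  sdc_wide <- stats::setNames(
    as.list(x$sdc$value), sprintf("sdc%d", round(100 * x$sdc$confidence))
  )
  dplyr::bind_cols(out, tibble::as_tibble(sdc_wide))
}
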