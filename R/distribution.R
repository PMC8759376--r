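#' Skewness z-score
#'
#' Adjusted Fisher-Pearson skewness \eqn{G_1} divided by its standard error
#' \deqn{SE = \sqrt{\frac{6n(n-1)}{(n-2)(n+1)(n+3)}},}
#' with the sample-size-dependent comparison threshold used in clinimetric
#' screening: 1.96 for small samples (n < 50) and 3.29 for medium samples
#' (n >= 50).
#'
#' @param values Numeric vector, `n >= 3`, non-constant.
#' @return A one-row tibble: `n`, `skewness` (G1), `se`, `z`, `threshold`,
#'   `exceeds`.
#' @examples
#' skewness_z(rexp(100))
#' @export
skewness_z <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3) stop("skewness needs at least 3 observations", call. = FALSE)
  if (stats::sd(values) == 0) {
    stop("skewness is undefined for a constant sample", call. = FALSE)
  }
  g1 <- e1071::skewness(values, type = 2)
  se <- sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
  z <- g1 / se
  threshold <- if (n < 50) 1.96 else 3.29
  tibble::tibble(
    n = n, skewness = g1, se = se, z = z,
    threshold = threshold, exceeds = abs(z) > threshold
  )
}

#' Floor and ceiling screening by scale tails
#'
#' Applies the 15%/20% rule for bounded scales: a floor (ceiling) effect is
#' flagged when more than 15% of observations fall within the lowest
#' (highest) 20% of the scale range. Tail bins are closed intervals, so
#' boundary values count.
#'
#' @param values Numeric observations on the scale.
#' @param scale_min,scale_max Scale bounds, `scale_max > scale_min`. For
#'   one-sided metrics such as response times there is no valid bounded
#'   scale and this rule does not apply; use [skewness_z()] instead.
#' @param flag_threshold_pct Tail percentage above which an effect is
#'   flagged.
#' @return A one-row tibble: `n`, `pct_bottom20`, `pct_top20`,
#'   `floor_flag`, `ceiling_flag`.
#' @export
floor_ceiling <- function(values, scale_min, scale_max,
                          flag_threshold_pct = 15) {
  values <- values[!is.na(values)]
  if (scale_max <= scale_min) {
    stop("`scale_max` must exceed `scale_min`", call. = FALSE)
  }
  outside <- values[values < scale_min | values > scale_max]
  if (length(outside) > 0) {
    stop(sprintf(
      "values outside the scale [%g, %g]: %s",
      scale_min, scale_max,
      paste(utils::head(signif(outside, 4), 5), collapse = ", ")
    ), call. = FALSE)
  }
  range <- scale_max - scale_min
  pct_bottom <- 100 * mean(values <= scale_min + 0.2 * range)
  pct_top <- 100 * mean(values >= scale_max - 0.2 * range)
  tibble::tibble(
    n = length(values),
    pct_bottom20 = pct_bottom, pct_top20 = pct_top,
    floor_flag = pct_bottom > flag_threshold_pct,
    ceiling_flag = pct_top > flag_threshold_pct
  )
}

#' Distribution report for one score
#'
#' Combines the skewness z-score with, for bounded scales, the 15%/20%
#' tail rule. Metrics without a bounded scale (response times, rate correct
#' scores) get `NA` tail columns and rely on the skewness screen alone.
#'
#' @param values Numeric observations.
#' @param metric Label carried into the report.
#' @param scale_min,scale_max Optional scale bounds; supply both to enable
#'   the tail rule.
#' @return A one-row tibble combining [skewness_z()] and, when bounds are
#'   given, [floor_ceiling()] columns.
#' @export
distribution_report <- function(values, metric = "score",
                                scale_min = NULL, scale_max = NULL) {
  sk <- skewness_z(values)
  if (!is.null(scale_min) && !is.null(scale_max)) {
    fc <- floor_ceiling(values, scale_min, scale_max)
    fc$n <- NULL
  } else {
    fc <- tibble::tibble(
      pct_bottom20 = NA_real_, pct_top20 = NA_real_,
      floor_flag = NA, ceiling_flag = NA
    )
  }
  dplyr::bind_cols(tibble::tibble(metric = metric), sk, fc)
}
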