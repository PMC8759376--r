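# Semi-partial correlations of every non-intercept coefficient of an lm fit:
# sr_j = t_j * sqrt(1 - R^2) / sqrt(df_residual).
lm_semipartial <- function(fit) {
  s <- summary(fit)
  tvals <- s$coefficients[, "t value"][-1] # named, intercept dropped
  tvals * sqrt(1 - s$r.squared) / sqrt(fit$df.residual)
}

# Coerce a two-level factor/character/logical to 0/1 numeric (first level
# or FALSE = 0), leaving numeric columns untouched.
as_numeric_code <- function(x, name) {
  if (is.numeric(x)) return(x)
  if (is.logical(x)) return(as.numeric(x))
  f <- as.factor(x)
  if (nlevels(f) != 2) {
    stop(sprintf("column `%s` is non-numeric with %d levels; only two-level
factors can be coded 0/1", name, nlevels(f)), call. = FALSE)
  }
  as.numeric(f) - 1
}

#' Enter-model multiple linear regression with semi-partial correlations
#'
#' Fits an ordinary least squares model with all predictors entered
#' simultaneously and reports, per predictor, the unstandardized coefficient
#' `b`, its standard error, t, p, and the semi-partial correlation
#' \eqn{sr_j = t_j \sqrt{1 - R^2} / \sqrt{df_2}} (whose square is the
#' predictor's unique contribution to \eqn{R^2}).
#'
#' @param data A data frame with one row per subject.
#' @param response Name of the outcome column.
#' @param predictors Character vector of predictor columns. Two-level
#'   factors are coded 0/1 (first level = 0).
#' @return An `ols_enter` object wrapping the `lm` fit, with a `terms`
#'   tibble (`term`, `b`, `se`, `t`, `p`, `sr`) and a `model` tibble
#'   (`f_statistic`, `df1`, `df2`, `p_value`, `r_squared`, `r_squared_adj`,
#'   `n`).
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(x1 = rnorm(50), x2 = rnorm(50),
#'                     y = 2 * x1 + rnorm(50))
#' tidy(ols_enter(d, "y", c("x1", "x2")))
#' @export
ols_enter <- function(data, response, predictors) {
  stopifnot(is.data.frame(data), length(predictors) >= 1)
  cols <- c(response, predictors)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- data[stats::complete.cases(data[cols]), cols]
  d[] <- lapply(names(d), function(nm) as_numeric_code(d[[nm]], nm))
  n <- nrow(d)
  if (n <= length(predictors) + 1) {
    stop("too few complete cases for the number of predictors",
         call. = FALSE)
  }
  fml <- stats::reformulate(predictors, response)
  fit <- stats::lm(fml, data = d)
  if (fit$rank < length(predictors) + 1) {
    stop("rank-deficient design: predictors are collinear", call. = FALSE)
  }
  s <- summary(fit)
  co <- s$coefficients
  terms_tbl <- tibble::tibble(
    term = rownames(co),
    b = unname(co[, "Estimate"]), se = unname(co[, "Std. Error"]),
    t = unname(co[, "t value"]), p = unname(co[, "Pr(>|t|)"]),
    sr = unname(c(NA_real_, lm_semipartial(fit)))
  )
  fstat <- s$fstatistic
  model_tbl <- tibble::tibble(
    f_statistic = unname(fstat[1]),
    df1 = unname(fstat[2]), df2 = unname(fstat[3]),
    p_value = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
    r_squared = s$r.squared, r_squared_adj = s$adj.r.squared,
    n = n
  )
  structure(
    list(fit = fit, terms = terms_tbl, model = model_tbl,
         response = response),
    class = "ols_enter"
  )
}

#' @export
print.ols_enter <- function(x, ...) {
  m <- x$model
  cat(sprintf(
    "<ols_enter> %s ~ %s | F(%d,%d) = %.2f, p = %.3g, R2_adj = %.2f\n",
    x$response,
    paste(setdiff(x$terms$term, "(Intercept)"), collapse = " + "),
    m$df1, m$df2, m$f_statistic, m$p_value, m$r_squared_adj
  ))
  print(x$terms)
  invisible(x)
}

#' @describeIn ols_enter Per-term tibble (`b`, `se`, `t`, `p`, `sr`).
#' @param x An `ols_enter` object.
#' @param ... Unused.
#' @method tidy ols_enter
#' @export
tidy.ols_enter <- function(x, ...) x$terms

#' @describeIn ols_enter One-row model summary.
#' @method glance ols_enter
#' @export
glance.ols_enter <- function(x, ...) x$model

#' Sequential two-mediator mediation with percentile bootstrap
#'
#' Fits the serial mediation path model
#' \deqn{M_1 = i_1 + a_1 X,\quad M_2 = i_2 + a_2 X + d_{21} M_1,\quad
#'       Y = i_3 + c' X + b_1 M_1 + b_2 M_2} (each equation also containing
#' the covariates), plus the total-effect regression \eqn{Y = i_0 + c X}.
#' The three indirect effects are \eqn{a_1 b_1} (through \eqn{M_1}),
#' \eqn{a_1 d_{21} b_2} (through both mediators in sequence) and
#' \eqn{a_2 b_2} (through \eqn{M_2}); their sum is the total indirect
#' effect, which satisfies \eqn{c = c' + } total indirect exactly under OLS.
#' Indirect-effect confidence intervals come from a case-resampling
#' percentile bootstrap; direct and total effects carry t-based OLS
#' intervals. The percentage mediation is \eqn{P_m = } total indirect
#' / total effect.
#'
#' @param data One row per subject; all used columns numeric (two-level
#'   factors are coded 0/1).
#' @param x Focal predictor column name.
#' @param m1,m2 First and second mediator column names (causal order
#'   `x -> m1 -> m2 -> y`).
#' @param y Outcome column name.
#' @param covariates Optional covariate column names, entered in every
#'   equation.
#' @param n_boot Number of bootstrap resamples (>= 1000).
#' @param conf_level Confidence level of all intervals.
#' @return A `mediation_result` with `paths` (edge list: `from`, `to`,
#'   `estimate`, `se`, `p`, `sr`), `effects` (`effect`, `estimate`,
#'   `conf_low`, `conf_high`, `significant`), `p_m`, `n`, `n_boot`.
#' @examples
#' set.seed(2)
#' d <- tibble::tibble(x = rnorm(200))
#' d$m1 <- 0.5 * d$x + rnorm(200)
#' d$m2 <- 0.3 * d$m1 + rnorm(200)
#' d$y <- 0.4 * d$m1 + rnorm(200)
#' sequential_mediation(d, "x", "m1", "m2", "y", n_boot = 1000)
#' @export
sequential_mediation <- function(data, x, m1, m2, y,
                                 covariates = character(),
                                 n_boot = 5000, conf_level = 0.95) {
  stopifnot(is.data.frame(data), n_boot >= 1000)
  cols <- c(x, m1, m2, y, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- data[stats::complete.cases(data[cols]), cols]
  d[] <- lapply(names(d), function(nm) as_numeric_code(d[[nm]], nm))
  n <- nrow(d)
  if (n < length(cols) + 10) {
    stop("too few complete cases for a stable mediation fit", call. = FALSE)
  }

  # Point fits through lm for SEs, p-values and semi-partial correlations
  fml <- function(lhs, rhs) stats::reformulate(rhs, lhs)
  fit_m1 <- stats::lm(fml(m1, c(x, covariates)), data = d)
  fit_m2 <- stats::lm(fml(m2, c(x, m1, covariates)), data = d)
  fit_y <- stats::lm(fml(y, c(x, m1, m2, covariates)), data = d)
  fit_tot <- stats::lm(fml(y, c(x, covariates)), data = d)
  if (any(vapply(list(fit_m1, fit_m2, fit_y, fit_tot),
                 function(f) any(is.na(stats::coef(f))), logical(1)))) {
    stop("collinear predictors/mediators: a path regression is rank
deficient", call. = FALSE)
  }

  edge <- function(fit, term, from, to) {
    co <- summary(fit)$coefficients
    sr <- lm_semipartial(fit)
    tibble::tibble(
      from = from, to = to,
      estimate = co[term, "Estimate"], se = co[term, "Std. Error"],
      p = co[term, "Pr(>|t|)"], sr = unname(sr[term])
    )
  }
  paths <- dplyr::bind_rows(
    edge(fit_m1, x, x, m1),                    # a1
    edge(fit_m2, x, x, m2),                    # a2
    edge(fit_m2, m1, m1, m2),                  # d21
    edge(fit_y, m1, m1, y),                    # b1
    edge(fit_y, m2, m2, y),                    # b2
    edge(fit_y, x, x, paste0(y, " (direct)")), # c'
    edge(fit_tot, x, x, paste0(y, " (total)")) # c
  )
  a1 <- paths$estimate[1]; a2 <- paths$estimate[2]
  d21 <- paths$estimate[3]; b1 <- paths$estimate[4]; b2 <- paths$estimate[5]
  c_prime <- paths$estimate[6]; c_total <- paths$estimate[7]
  ind <- c(
    ind_m1 = a1 * b1,
    ind_serial = a1 * d21 * b2,
    ind_m2 = a2 * b2
  )
  total_ind <- sum(ind)

  # Case-resampling bootstrap of the three path regressions; coefficient
  # positions in the fixed design matrices: col 1 intercept, col 2 = x, then
  # mediators, then covariates.
  xv <- d[[x]]; m1v <- d[[m1]]; m2v <- d[[m2]]; yv <- d[[y]]
  covm <- if (length(covariates)) as.matrix(d[covariates]) else NULL
  bind_design <- function(...) {
    parts <- list(...)
    do.call(cbind, c(list(rep(1, n)), parts, list(covm)))
  }
  A1 <- bind_design(xv)
  A2 <- bind_design(xv, m1v)
  A3 <- bind_design(xv, m1v, m2v)

  boot <- matrix(NA_real_, n_boot, 4,
                 dimnames = list(NULL, c(names(ind), "total")))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    c1 <- stats::.lm.fit(A1[idx, , drop = FALSE], m1v[idx])$coefficients
    c2 <- stats::.lm.fit(A2[idx, , drop = FALSE], m2v[idx])$coefficients
    c3 <- stats::.lm.fit(A3[idx, , drop = FALSE], yv[idx])$coefficients
    i1 <- c1[2] * c3[3]
    i2 <- c1[2] * c2[3] * c3[4]
    i3 <- c2[2] * c3[4]
    boot[b, ] <- c(i1, i2, i3, i1 + i2 + i3)
  }
  alpha <- 1 - conf_level
  ci <- t(apply(boot, 2, stats::quantile,
                probs = c(alpha / 2, 1 - alpha / 2), na.rm = TRUE))

  tcrit <- function(fit) stats::qt(1 - alpha / 2, fit$df.residual)
  ols_ci <- function(row, fit) {
    c(row$estimate - tcrit(fit) * row$se, row$estimate + tcrit(fit) * row$se)
  }
  ci_direct <- ols_ci(paths[6, ], fit_y)
  ci_total <- ols_ci(paths[7, ], fit_tot)

  effects <- tibble::tibble(
    effect = c("ind_m1", "ind_serial", "ind_m2", "total_indirect",
               "direct", "total"),
    estimate = unname(c(ind, total_ind, c_prime, c_total)),
    conf_low = unname(c(ci[, 1], ci_direct[1], ci_total[1])),
    conf_high = unname(c(ci[, 2], ci_direct[2], ci_total[2]))
  )
  effects$significant <- effects$conf_low > 0 | effects$conf_high < 0

  structure(
    list(
      paths = paths, effects = effects,
      p_m = total_ind / c_total,
      x = x, m1 = m1, m2 = m2, y = y, covariates = covariates,
      n = n, n_boot = n_boot, conf_level = conf_level
    ),
    class = "mediation_result"
  )
}

#' @export
print.mediation_result <- function(x, ...) {
  tot <- x$effects[x$effects$effect == "total_indirect", ]
  cat(sprintf(
    "<mediation_result> %s -> (%s, %s) -> %s, n = %d, %d bootstraps\n",
    x$x, x$m1, x$m2, x$y, x$n, x$n_boot
  ))
  cat(sprintf(
    "  total indirect %.3f (%.0f%% CI %.3f to %.3f, %s), P_m = %.2f\n",
    tot$estimate, 100 * x$conf_level, tot$conf_low, tot$conf_high,
    if (tot$significant) "significant" else "n.s.", x$p_m
  ))
  print(x$effects)
  invisible(x)
}

#' @describeIn sequential_mediation Effects table (`type = "effects"`,
#'   default) or the path-coefficient edge list (`type = "paths"`).
#' @param x A `mediation_result`.
#' @param type `"effects"` or `"paths"`.
#' @param ... Unused.
#' @method tidy mediation_result
#' @export
tidy.mediation_result <- function(x, type = c("effects", "paths"), ...) {
  switch(match.arg(type), effects = x$effects, paths = x$paths)
}

#' @describeIn sequential_mediation One-row summary with the effect
#'   decomposition and percentage mediation.
#' @method glance mediation_result
#' @export
glance.mediation_result <- function(x, ...) {
  e <- x$effects
  get <- function(nm, col) e[[col]][e$effect == nm]
  tibble::tibble(
    n = x$n, n_boot = x$n_boot,
    total = get("total", "estimate"),
    direct = get("direct", "estimate"),
    total_indirect = get("total_indirect", "estimate"),
    total_indirect_low = get("total_indirect", "conf_low"),
    total_indirect_high = get("total_indirect", "conf_high"),
    indirect_significant = get("total_indirect", "significant"),
    p_m = x$p_m
  )
}

#' @describeIn sequential_mediation Point-range plot of the effect
#'   decomposition.
#' @param object A `mediation_result`.
#' @method autoplot mediation_result
#' @export
autoplot.mediation_result <- function(object, ...) {
  e <- object$effects
  e$effect <- factor(e$effect, levels = rev(e$effect))
  ggplot2::ggplot(e, ggplot2::aes(x = .data$estimate, y = .data$effect)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$conf_low, xmax = .data$conf_high,
                   colour = .data$significant)
    ) +
    ggplot2::labs(
      x = sprintf("Effect of %s on %s", object$x, object$y), y = NULL,
      colour = "CI excludes 0",
      title = sprintf("Serial mediation through %s and %s (P_m = %.2f)",
                      object$m1, object$m2, object$p_m)
    ) +
    ggplot2::theme_minimal()
}
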