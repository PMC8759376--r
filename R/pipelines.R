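#' Inter-rater reliability experiment on synthetic ratings
#'
#' Simulates, for every score metric of [exp1_score_specs()], a complete
#' subjects-by-assessors ratings table from its variance-component model and
#' runs the full reliability analysis: ICC(2,1) with 95% CI, SEM, CoV with
#' qualitative band, and the SDC family.
#'
#' @param score_specs Tibble in the shape of [exp1_score_specs()].
#' @param n_subjects,n_raters Design size (defaults: 40 participants, 3
#'   assessors).
#' @param sdc_levels Confidence levels of the SDC family.
#' @param seed Optional integer seed for the simulation.
#' @return An `exp1_report`: list with `table` (one row per metric, the
#'   [glance.reliability_report()] layout), `reports` (named list of
#'   [reliability_report()] objects) and `ratings` (named list of the
#'   simulated long tibbles).
#' @examples
#' rep1 <- run_experiment1(seed = 1)
#' rep1$table
#' @export
run_experiment1 <- function(score_specs = exp1_score_specs(),
                            n_subjects = 40, n_raters = 3,
                            sdc_levels = c(0.80, 0.85, 0.90, 0.95),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  needed <- c("metric", "units", "grand_mean", "sigma2_subject",
              "sigma2_rater", "sigma2_residual")
  stopifnot(all(needed %in% names(score_specs)))

  reports <- list()
  ratings <- list()
  for (i in seq_len(nrow(score_specs))) {
    row <- score_specs[i, ]
    spec <- variance_spec(
      row$grand_mean, row$sigma2_subject, row$sigma2_rater,
      row$sigma2_residual, n_subjects, n_raters, metric = row$metric
    )
    r <- simulate_ratings(spec)
    ratings[[row$metric]] <- r
    reports[[row$metric]] <- reliability_report(
      r, metric = row$metric, units = row$units, sdc_levels = sdc_levels
    )
  }
  structure(
    list(
      table = purrr::map_dfr(reports, glance),
      reports = reports,
      ratings = ratings
    ),
    class = "exp1_report"
  )
}

#' @export
print.exp1_report <- function(x, ...) {
  cat("<exp1_report> inter-rater reliability,", nrow(x$table), "metrics\n")
  print(x$table)
  invisible(x)
}

#' @describeIn run_experiment1 Forest plot of the ICC(2,1) estimates.
#' @param object An `exp1_report`.
#' @param ... Unused.
#' @method autoplot exp1_report
#' @export
autoplot.exp1_report <- function(object, ...) {
  tab <- object$table
  tab$metric <- factor(tab$metric, levels = rev(tab$metric))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$icc21, y = .data$metric)) +
    ggplot2::geom_vline(xintercept = c(0.5, 0.75, 0.9),
                        linetype = "dotted", colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$icc21_low, xmax = .data$icc21_high,
                   colour = .data$icc_band)
    ) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "ICC(2,1) with 95% CI", y = NULL, colour = "Band") +
    ggplot2::theme_minimal()
}

#' Cohort experiment: internal consistency, score distributions,
#' demographics
#'
#' Generates a demographically structured cohort, simulates both tests for
#' every participant (localisation spread and orientation accuracy
#' calibrated to each participant's latent accuracies), and runs the
#' second-experiment analysis battery: average-measures internal-consistency
#' ICCs over the within-session series, distribution checks for all nine
#' scores, enter-model regressions of both accuracy scores on age, sex, BMI
#' and neck surface area, and the serial mediation analyses with age and sex
#' in turn as focal predictor and BMI then neck surface area as mediators.
#'
#' @param spec A [cohort_spec()].
#' @param n_boot Bootstrap resamples per mediation analysis.
#' @param mediation_outcomes Outcome scores for the mediation battery
#'   (default: both accuracy scores).
#' @param seed Optional integer seed.
#' @return An `exp2_report`: list with `cohort` (profiles), `scores` (one
#'   row per participant with the nine scores), `series` (long per-series
#'   accuracies), `internal_consistency` (ICC(2,6) and ICC(2,4) rows),
#'   `distributions` (nine-row tibble), `regressions` and `mediations`
#'   (named lists).
#' @examples
#' \donttest{
#' rep2 <- run_experiment2(n_boot = 1000, seed = 7)
#' rep2$internal_consistency
#' }
#' @export
run_experiment2 <- function(spec = cohort_spec(), n_boot = 5000,
                            mediation_outcomes = c("loc_as", "ori_as"),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cohort <- make_cohort(spec)
  layout <- itad_layout()

  sessions <- purrr::map(seq_len(nrow(cohort)), function(i) {
    p <- cohort[i, ]
    obs_loc <- itad_observer(
      localisation_spread_mm =
        calibrate_localisation_spread(
          min(p$latent_loc_acc / 100, 0.999), layout
        ),
      orientation_accuracy = p$latent_ori_acc / 100,
      rt_location_ms = p$latent_rt_loc_ms,
      rt_scale = spec$rt_trial_scale
    )
    obs_ori <- obs_loc
    obs_ori$rt_location_ms <- p$latent_rt_ori_ms
    loc <- simulate_session(obs_loc, plan_test("localisation", layout),
                            layout)
    ori <- simulate_session(obs_ori, plan_test("orientation", layout),
                            layout)
    list(loc = loc, ori = ori)
  })

  scores <- purrr::map_dfr(seq_along(sessions), function(i) {
    s <- sessions[[i]]
    loc <- score_session(s$loc)
    ori <- score_session(s$ori)
    ov <- overall_scores(loc, ori)
    tibble::tibble(
      id = cohort$id[i],
      loc_as = loc$accuracy_pct, loc_rt = loc$mean_rt_ms,
      loc_rcs = loc$rate_correct_per_min,
      ori_as = ori$accuracy_pct, ori_rt = ori$mean_rt_ms,
      ori_rcs = ori$rate_correct_per_min,
      overall_as = ov$accuracy_pct, overall_rt = ov$mean_rt_ms,
      overall_rcs = ov$rate_correct_per_min
    )
  })

  series <- purrr::map_dfr(seq_along(sessions), function(i) {
    dplyr::bind_rows(
      dplyr::mutate(score_series(sessions[[i]]$loc),
                    id = cohort$id[i], test = "localisation"),
      dplyr::mutate(score_series(sessions[[i]]$ori),
                    id = cohort$id[i], test = "orientation")
    )
  })

  ic <- purrr::map_dfr(c("localisation", "orientation"), function(tst) {
    long <- series[series$test == tst,
                   c("id", "series", "accuracy_pct")]
    names(long) <- c("subject", "series", "value")
    dplyr::mutate(icc(long, form = "average"), test = tst, .before = 1)
  })

  bounded <- c(loc_as = TRUE, loc_rt = FALSE, loc_rcs = FALSE,
               ori_as = TRUE, ori_rt = FALSE, ori_rcs = FALSE,
               overall_as = TRUE, overall_rt = FALSE, overall_rcs = FALSE)
  dists <- purrr::map_dfr(names(bounded), function(mt) {
    if (bounded[[mt]]) {
      distribution_report(scores[[mt]], mt, scale_min = 0, scale_max = 100)
    } else {
      distribution_report(scores[[mt]], mt)
    }
  })

  analysis <- dplyr::left_join(cohort, scores, by = "id")
  predictors <- c("age", "sex_code", "bmi", "neck_surface_area_cm2")
  regressions <- list(
    loc_as = ols_enter(analysis, "loc_as", predictors),
    ori_as = ols_enter(analysis, "ori_as", predictors)
  )

  mediations <- list()
  for (outcome in mediation_outcomes) {
    for (focal in c("age", "sex_code")) {
      other <- setdiff(c("age", "sex_code"), focal)
      key <- sprintf("%s_by_%s", outcome, sub("_code$", "", focal))
      mediations[[key]] <- sequential_mediation(
        analysis, x = focal, m1 = "bmi", m2 = "neck_surface_area_cm2",
        y = outcome, covariates = other, n_boot = n_boot
      )
    }
  }

  structure(
    list(
      cohort = cohort, scores = scores, series = series,
      internal_consistency = ic, distributions = dists,
      regressions = regressions, mediations = mediations
    ),
    class = "exp2_report"
  )
}

#' @export
print.exp2_report <- function(x, ...) {
  cat("<exp2_report>", nrow(x$cohort), "participants\n")
  cat("Internal consistency (average-measures ICC):\n")
  print(x$internal_consistency[, c("test", "k", "estimate", "conf_low",
                                   "conf_high", "band")])
  cat("Distribution flags:\n")
  print(x$distributions[, c("metric", "z", "threshold", "exceeds",
                            "pct_bottom20", "pct_top20")])
  for (nm in names(x$regressions)) {
    cat("\nRegression for", nm, ":\n")
    print(x$regressions[[nm]])
  }
  invisible(x)
}
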