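#' Variance-component specification for a rater-effect score matrix
#'
#' Describes the two-way random-effects generating model
#' \deqn{y_{ij} = \mu + p_i + r_j + e_{ij}} with independent zero-mean normal
#' subject, rater and residual components. The population single-measures
#' intraclass correlation of this process is
#' \eqn{\sigma^2_{subject} / (\sigma^2_{subject} + \sigma^2_{rater} +
#' \sigma^2_{residual})}.
#'
#' @param grand_mean Overall mean \eqn{\mu} in the metric's units.
#' @param sigma2_subject,sigma2_rater,sigma2_residual Non-negative variance
#'   components.
#' @param n_subjects,n_raters Matrix dimensions (at least 2 each).
#' @param metric Optional metric label carried through to reports.
#' @return A `variance_spec` list.
#' @export
variance_spec <- function(grand_mean, sigma2_subject, sigma2_rater,
                          sigma2_residual, n_subjects = 40, n_raters = 3,
                          metric = NULL) {
  if (any(c(sigma2_subject, sigma2_rater, sigma2_residual) < 0)) {
    stop("variance components must be non-negative", call. = FALSE)
  }
  if (n_subjects < 2 || n_raters < 2) {
    stop("need at least 2 subjects and 2 raters", call. = FALSE)
  }
  structure(
    list(
      grand_mean = grand_mean, sigma2_subject = sigma2_subject,
      sigma2_rater = sigma2_rater, sigma2_residual = sigma2_residual,
      n_subjects = as.integer(n_subjects), n_raters = as.integer(n_raters),
      metric = metric
    ),
    class = "variance_spec"
  )
}

#' Simulate a subjects-by-raters score matrix
#'
#' Draws one complete ratings table from the additive variance-component
#' model of [variance_spec()].
#'
#' @param spec A [variance_spec()].
#' @return A long tibble with columns `subject`, `rater`, `value` and, when
#'   the spec carries one, `metric`; pass it directly to
#'   [reliability_report()] or [icc()].
#' @examples
#' set.seed(1)
#' simulate_ratings(variance_spec(50, 3, 0.5, 0.5, 40, 3))
#' @export
simulate_ratings <- function(spec) {
  stopifnot(inherits(spec, "variance_spec"))
  n <- spec$n_subjects
  k <- spec$n_raters
  p <- stats::rnorm(n, 0, sqrt(spec$sigma2_subject))
  r <- stats::rnorm(k, 0, sqrt(spec$sigma2_rater))
  e <- matrix(stats::rnorm(n * k, 0, sqrt(spec$sigma2_residual)), n, k)
  y <- spec$grand_mean + outer(p, r, "+") + e
  out <- tibble::tibble(
    subject = rep(seq_len(n), times = k),
    rater = rep(seq_len(k), each = n),
    value = as.vector(y)
  )
  if (!is.null(spec$metric)) out$metric <- spec$metric
  out
}

#' Published score structure of the inter-rater experiment
#'
#' The ten score metrics of the three-assessor reliability experiment (two
#' tests plus their overall score, each with accuracy, response-time and
#' rate-correct metrics, plus the caliper two-point threshold), with their
#' observed means, single-measures ICCs and SEMs. These parameterise the
#' default synthetic ratings matrices: the subject variance is backed out of
#' the ICC identity \eqn{\sigma^2_s = \mathrm{SEM}^2\,\mathrm{ICC} /
#' (1-\mathrm{ICC})} and the error variance \eqn{\mathrm{SEM}^2} is split
#' between assessor and residual components.
#'
#' @param rater_share Fraction of the error variance assigned to the
#'   assessor component (the remainder is residual).
#' @return A tibble with one row per metric: `metric`, `units`,
#'   `grand_mean`, `icc`, `sem`, `sigma2_subject`, `sigma2_rater`,
#'   `sigma2_residual`.
#' @export
exp1_score_specs <- function(rater_share = 0.25) {
  stopifnot(rater_share >= 0, rater_share <= 1)
  tab <- tibble::tribble(
    ~metric,      ~units,  ~grand_mean, ~icc, ~sem,
    "loc_as",     "%",           61.0, 0.65,   8.7,
    "loc_rt",     "ms",        1238.5, 0.82, 109.7,
    "loc_rcs",    "c/min",       30.5, 0.65,   5.0,
    "ori_as",     "%",           46.2, 0.76,   5.9,
    "ori_rt",     "ms",        1995.4, 0.80, 134.0,
    "ori_rcs",    "c/min",       14.0, 0.74,   1.9,
    "overall_as", "%",           53.6, 0.75,   5.8,
    "overall_rt", "ms",        1617.0, 0.86,  97.8,
    "overall_rcs","c/min",       20.2, 0.72,   2.3,
    "tpdt",       "mm",          47.7, 0.70,  12.1
  )
  dplyr::mutate(
    tab,
    sigma2_subject = .data$sem^2 * .data$icc / (1 - .data$icc),
    sigma2_rater = rater_share * .data$sem^2,
    sigma2_residual = (1 - rater_share) * .data$sem^2
  )
}

#' Cohort specification for the demographic experiment
#'
#' Describes the generating model of the 100-participant cohort: equal cells
#' of `n_per_cell` participants of each sex in each age bracket; latent test
#' accuracies following a linear model in age (years) and sex (female = 0,
#' male = 1) with normal residuals, clipped to the forced-choice chance
#' floor; and anthropometry (BMI, neck surface area) coupled to age and sex
#' but entering the score model with coefficient zero, so any apparent
#' anthropometry effect on scores is purely mediated structure.
#'
#' @param n_per_cell Participants per sex per age bracket.
#' @param age_brackets List of `c(lo, hi)` year ranges.
#' @param intercept_loc,intercept_ori Latent accuracy (% correct) at age 0,
#'   female.
#' @param effect_age_loc,effect_age_ori Accuracy change (% per year of age).
#' @param effect_sex_loc,effect_sex_ori Male minus female accuracy
#'   difference (%).
#' @param residual_sd_loc,residual_sd_ori Between-subject residual SD of the
#'   latent accuracies (%).
#' @param bmi_intercept,bmi_age,bmi_sex,bmi_sd Linear model of BMI
#'   (kg/m^2) on age and sex, with residual SD.
#' @param nsa_intercept,nsa_age,nsa_sex,nsa_bmi,nsa_sd Linear model of neck
#'   surface area (cm^2) on age, sex and (centred) BMI, with residual SD.
#' @param rt_loc_median_ms,rt_ori_median_ms Median response times at the
#'   cohort's mean age.
#' @param rt_age_log Per-year effect of age on log response time.
#' @param rt_sd_log Between-subject SD of log response time.
#' @param rt_trial_scale Within-session log-normal trial scale.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_cell = 10,
                        age_brackets = list(c(18, 30), c(31, 40), c(41, 50),
                                            c(51, 60), c(61, 70)),
                        intercept_loc = 65.6, effect_age_loc = -0.20,
                        effect_sex_loc = 8.04, residual_sd_loc = 11,
                        intercept_ori = 60.0, effect_age_ori = -0.39,
                        effect_sex_ori = 6.69, residual_sd_ori = 13.5,
                        bmi_intercept = 21.7, bmi_age = 0.10,
                        bmi_sex = 0.5, bmi_sd = 4.0,
                        nsa_intercept = 219, nsa_age = 0.5, nsa_sex = 40,
                        nsa_bmi = 3.0, nsa_sd = 25,
                        rt_loc_median_ms = 1240, rt_ori_median_ms = 1995,
                        rt_age_log = 0.004, rt_sd_log = 0.12,
                        rt_trial_scale = 0.25) {
  if (length(age_brackets) == 0) {
    stop("at least one age bracket is required", call. = FALSE)
  }
  if (any(c(residual_sd_loc, residual_sd_ori, bmi_sd, nsa_sd, rt_sd_log,
            rt_trial_scale) < 0)) {
    stop("spread parameters must be non-negative", call. = FALSE)
  }
  stopifnot(n_per_cell >= 1)
  structure(
    as.list(environment()),
    class = "cohort_spec"
  )
}

#' Generate a demographically structured cohort
#'
#' Draws one cohort from a [cohort_spec()]: balanced sex-by-age-bracket
#' cells, anthropometry coupled to age and sex, and latent localisation and
#' orientation accuracies from the linear age/sex model, clipped to the
#' forced-choice chance floors (100/12 % for twelve-option localisation,
#' 25 % for four-direction orientation).
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per participant: identifiers and
#'   demographics (`id`, `age`, `sex`, `sex_code`, `age_bracket`), measured
#'   and derived anthropometry (`weight_kg`, `height_m`, `bmi`,
#'   `neck_length_cm`, `neck_circumference_cm`, `neck_surface_area_cm2`),
#'   and latent performance (`latent_loc_acc`, `latent_ori_acc`,
#'   `latent_rt_loc_ms`, `latent_rt_ori_ms`).
#' @examples
#' set.seed(7)
#' cohort <- make_cohort(cohort_spec())
#' dplyr::count(cohort, age_bracket, sex)
#' @export
make_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  cells <- tidyr::expand_grid(
    bracket = seq_along(spec$age_brackets),
    sex_code = c(0L, 1L),
    rep = seq_len(spec$n_per_cell)
  )
  n <- nrow(cells)
  lo <- vapply(spec$age_brackets, `[`, numeric(1), 1)
  hi <- vapply(spec$age_brackets, `[`, numeric(1), 2)
  if (any(hi < lo)) stop("malformed age bracket", call. = FALSE)

  age <- mapply(function(b) {
    sample(seq(lo[b], hi[b]), 1)
  }, cells$bracket)
  sex_code <- cells$sex_code
  mean_age <- mean(c(min(lo), max(hi)))

  height_m <- stats::rnorm(n, ifelse(sex_code == 1, 1.77, 1.63),
                           ifelse(sex_code == 1, 0.07, 0.06))
  bmi <- spec$bmi_intercept + spec$bmi_age * age + spec$bmi_sex * sex_code +
    stats::rnorm(n, 0, spec$bmi_sd)
  bmi <- pmax(bmi, 15)
  weight_kg <- bmi * height_m^2
  nsa <- spec$nsa_intercept + spec$nsa_age * age + spec$nsa_sex * sex_code +
    spec$nsa_bmi * (bmi - 26.4) + stats::rnorm(n, 0, spec$nsa_sd)
  nsa <- pmax(nsa, 100)
  neck_length_cm <- pmax(stats::rnorm(n, 13.5, 1.2) + 0.5 * sex_code, 8)
  neck_circumference_cm <- 2 * nsa / neck_length_cm

  chance_loc <- 100 / 12
  chance_ori <- 25
  latent_loc <- spec$intercept_loc + spec$effect_age_loc * age +
    spec$effect_sex_loc * sex_code + stats::rnorm(n, 0, spec$residual_sd_loc)
  latent_ori <- spec$intercept_ori + spec$effect_age_ori * age +
    spec$effect_sex_ori * sex_code + stats::rnorm(n, 0, spec$residual_sd_ori)

  rt_loc <- exp(log(spec$rt_loc_median_ms) +
                  spec$rt_age_log * (age - mean_age) +
                  stats::rnorm(n, 0, spec$rt_sd_log))
  rt_ori <- exp(log(spec$rt_ori_median_ms) +
                  spec$rt_age_log * (age - mean_age) +
                  stats::rnorm(n, 0, spec$rt_sd_log))

  tibble::tibble(
    id = sprintf("P%03d", seq_len(n)),
    age = as.numeric(age),
    sex = factor(ifelse(sex_code == 1, "male", "female"),
                 levels = c("female", "male")),
    sex_code = sex_code,
    age_bracket = sprintf("%d-%d", lo[cells$bracket], hi[cells$bracket]),
    weight_kg = weight_kg,
    height_m = height_m,
    bmi = bmi,
    neck_length_cm = neck_length_cm,
    neck_circumference_cm = neck_circumference_cm,
    neck_surface_area_cm2 = neck_length_cm * (neck_circumference_cm / 2),
    latent_loc_acc = pmin(pmax(latent_loc, chance_loc), 100),
    latent_ori_acc = pmin(pmax(latent_ori, chance_ori), 100),
    latent_rt_loc_ms = rt_loc,
    latent_rt_ori_ms = rt_ori
  )
}
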