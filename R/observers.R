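#' Psychophysical observer for two-point discrimination
#'
#' Constructs a latent observer whose probability of reporting "two" points at
#' caliper separation `d` (mm) follows a logistic psychometric function
#' \deqn{P(\mathrm{two}\mid d) = \gamma + (1 - \gamma - \lambda)\,
#'   F\!\left(\frac{d - \theta}{\sigma}\right),}
#' where \eqn{\theta} is the threshold (separation at the midpoint of the
#' function), \eqn{\sigma} the slope scale, \eqn{\gamma} the guess rate and
#' \eqn{\lambda} the lapse rate, and \eqn{F} the standard logistic CDF.
#'
#' @param threshold_mm Separation (mm) at which the scaled function crosses
#'   its midpoint. Must be positive.
#' @param slope_mm Spread of the psychometric function in mm; smaller values
#'   give a steeper transition. Must be positive.
#' @param guess_rate Lower asymptote of P("two"), in `[0, 0.5]`.
#' @param lapse_rate Lapse probability, in `[0, 0.1]`; the upper asymptote is
#'   `1 - lapse_rate`.
#' @return An object of class `psychometric_observer`.
#' @examples
#' obs <- psychometric_observer(threshold_mm = 47.7, slope_mm = 5)
#' p_two(obs, c(30, 47.7, 65))
#' @export
psychometric_observer <- function(threshold_mm, slope_mm,
                                  guess_rate = 0, lapse_rate = 0) {
  stopifnot(
    is.numeric(threshold_mm), length(threshold_mm) == 1, threshold_mm > 0,
    is.numeric(slope_mm), length(slope_mm) == 1, slope_mm > 0,
    guess_rate >= 0, guess_rate <= 0.5,
    lapse_rate >= 0, lapse_rate <= 0.1
  )
  structure(
    list(
      threshold_mm = threshold_mm,
      slope_mm = slope_mm,
      guess_rate = guess_rate,
      lapse_rate = lapse_rate
    ),
    class = "psychometric_observer"
  )
}

#' @export
print.psychometric_observer <- function(x, ...) {
  cat(sprintf(
    "<psychometric_observer> threshold %.1f mm, slope %.1f mm, guess %.2f, lapse %.2f\n",
    x$threshold_mm, x$slope_mm, x$guess_rate, x$lapse_rate
  ))
  invisible(x)
}

#' Probability of a "two points" report
#'
#' Closed-form response probability of a [psychometric_observer()] at one or
#' more caliper separations.
#'
#' @param observer A `psychometric_observer`.
#' @param distance_mm Non-negative separations in mm (vectorised).
#' @return Numeric vector of probabilities in
#'   `[guess_rate, 1 - lapse_rate]`.
#' @export
p_two <- function(observer, distance_mm) {
  stopifnot(inherits(observer, "psychometric_observer"))
  if (any(distance_mm < 0)) {
    stop("`distance_mm` must be non-negative", call. = FALSE)
  }
  core <- stats::plogis((distance_mm - observer$threshold_mm) / observer$slope_mm)
  observer$guess_rate +
    (1 - observer$guess_rate - observer$lapse_rate) * core
}

#' Simulate a single forced-choice report
#'
#' Draws a Bernoulli "one"/"two" report from the observer's psychometric
#' function at the given separation. Randomness is taken from R's global RNG
#' stream, so call [set.seed()] beforehand for reproducibility.
#'
#' @inheritParams p_two
#' @param distance_mm A single non-negative separation in mm.
#' @return `"two"` or `"one"` (character scalar).
#' @export
tpdt_response <- function(observer, distance_mm) {
  stopifnot(length(distance_mm) == 1)
  p <- p_two(observer, distance_mm)
  if (stats::runif(1) < p) "two" else "one"
}

#' Observer model for the vibrotactile localisation/orientation tests
#'
#' Latent participant for the twelve-node array. Localisation responses are
#' drawn over nodes with probability proportional to
#' \eqn{\exp(-d^2 / (2 s^2))} of each candidate node's Euclidean distance `d`
#' (mm) from the stimulated node, where `s` is `localisation_spread_mm`;
#' orientation responses are correct with probability
#' `orientation_accuracy`, with errors uniform over the remaining available
#' directions. Response times are log-normal with log-scale location
#' `log(rt_location_ms)` and log-scale SD `rt_scale`.
#'
#' @param localisation_spread_mm Spatial confusion scale in mm (> 0). Small
#'   values give near-perfect localisation; large values approach chance
#'   (1/12) over the array.
#' @param orientation_accuracy Probability of a correct orientation response,
#'   in `[0, 1]` (chance for a four-direction response set is 0.25).
#' @param rt_location_ms Median response time in ms (> 0).
#' @param rt_scale Log-scale SD of response times (> 0).
#' @return An object of class `itad_observer`.
#' @export
itad_observer <- function(localisation_spread_mm = 20,
                          orientation_accuracy = 0.46,
                          rt_location_ms = 1200,
                          rt_scale = 0.25) {
  stopifnot(
    localisation_spread_mm > 0,
    orientation_accuracy >= 0, orientation_accuracy <= 1,
    rt_location_ms > 0, rt_scale > 0
  )
  structure(
    list(
      localisation_spread_mm = localisation_spread_mm,
      orientation_accuracy = orientation_accuracy,
      rt_location_ms = rt_location_ms,
      rt_scale = rt_scale
    ),
    class = "itad_observer"
  )
}

#' @export
print.itad_observer <- function(x, ...) {
  cat(sprintf(
    "<itad_observer> spread %.1f mm, orientation accuracy %.2f, RT median %.0f ms (log-SD %.2f)\n",
    x$localisation_spread_mm, x$orientation_accuracy, x$rt_location_ms, x$rt_scale
  ))
  invisible(x)
}

#' Expected single-trial localisation accuracy for a given spread
#'
#' Averages, over the twelve stimulus nodes, the probability that the
#' distance-weighted response kernel selects the stimulated node itself.
#'
#' @param spread_mm Confusion scale in mm (> 0).
#' @param layout Node layout, see [itad_layout()].
#' @return Expected proportion correct in `(1/12, 1)`.
#' @export
localisation_p_correct <- function(spread_mm, layout = itad_layout()) {
  stopifnot(spread_mm > 0)
  d2 <- as.matrix(stats::dist(layout[, c("x_mm", "y_mm")]))^2
  w <- exp(-d2 / (2 * spread_mm^2))
  mean(1 / rowSums(w))
}

#' Spread that yields a target localisation accuracy
#'
#' Inverts [localisation_p_correct()] by root finding, giving the confusion
#' scale at which the expected single-trial proportion correct equals `p`.
#'
#' @param p Target proportion correct, strictly between 1/12 and 1.
#' @param layout Node layout, see [itad_layout()].
#' @return Spread in mm.
#' @export
calibrate_localisation_spread <- function(p, layout = itad_layout()) {
  stopifnot(p > 1 / 12, p < 1)
  f <- function(s) localisation_p_correct(s, layout) - p
  stats::uniroot(f, lower = 1e-3, upper = 1e4, tol = 1e-8)$root
}
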