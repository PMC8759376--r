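#' Configuration of the two-point discrimination staircase
#'
#' The adaptive procedure alternates ascending and descending runs of caliper
#' separations. The first (ascending) run starts at `start_mm` and moves in
#' `coarse_step_mm` steps; all later runs use `fine_step_mm`. A run ends when
#' `consecutive_criterion` consecutive identical reports occur ("two" on
#' ascending runs, "one" on descending runs) — a reversal. Before the next,
#' oppositely directed, run begins, `jump_mm` is added in the direction of the
#' completed run. The threshold is the mean of the `n_runs` reversal
#' distances. Separations are clamped to `[floor_mm, ceiling_mm]`; because a
#' clamped boundary cannot be stepped past, three consecutive identical
#' reports at a boundary also score a reversal there, which guarantees
#' termination for any consistent responder.
#'
#' @param start_mm Starting separation of the first run (mm).
#' @param coarse_step_mm Step size of the first run (mm).
#' @param fine_step_mm Step size of subsequent runs (mm).
#' @param jump_mm Offset added in the completed run's direction before the
#'   reversed run starts (mm).
#' @param consecutive_criterion Number of consecutive identical reports that
#'   defines a reversal.
#' @param n_runs Number of runs (even; first run ascending).
#' @param max_trials Safeguard: total trials allowed before the procedure
#'   aborts with a non-convergence error.
#' @param floor_mm,ceiling_mm Bounds within which separations are clamped.
#' @param reversal_rule Which trial of the criterion streak scores the
#'   reversal: `"first"` (default; the separation at which the percept
#'   changed) or `"last"`.
#' @return A `staircase_config` list.
#' @export
staircase_config <- function(start_mm = 15, coarse_step_mm = 5,
                             fine_step_mm = 2, jump_mm = 10,
                             consecutive_criterion = 3, n_runs = 4,
                             max_trials = 400, floor_mm = 0,
                             ceiling_mm = 100,
                             reversal_rule = c("first", "last")) {
  reversal_rule <- match.arg(reversal_rule)
  stopifnot(
    start_mm >= floor_mm, start_mm <= ceiling_mm,
    coarse_step_mm > 0, fine_step_mm > 0, jump_mm >= 0,
    consecutive_criterion >= 1, n_runs >= 2, n_runs %% 2 == 0,
    max_trials >= n_runs * consecutive_criterion,
    ceiling_mm > floor_mm
  )
  structure(
    list(
      start_mm = start_mm, coarse_step_mm = coarse_step_mm,
      fine_step_mm = fine_step_mm, jump_mm = jump_mm,
      consecutive_criterion = consecutive_criterion, n_runs = n_runs,
      max_trials = max_trials, floor_mm = floor_mm,
      ceiling_mm = ceiling_mm, reversal_rule = reversal_rule
    ),
    class = "staircase_config"
  )
}

#' Run the adaptive two-point discrimination staircase
#'
#' Drives a responder through alternating ascending/descending runs and
#' estimates the discrimination threshold as the mean of the reversal
#' distances (see [staircase_config()] for the stepping rules).
#'
#' @param respond A function of one argument (separation in mm) returning
#'   `"one"` or `"two"`. Use [tpdt_response()] with a
#'   [psychometric_observer()] for stochastic simulation, or any
#'   deterministic rule.
#' @param config A [staircase_config()].
#' @return A `tpdt_result` with elements `threshold_mm`, `reversals_mm`
#'   (length `n_runs`), and `trace`, a tibble with one row per trial
#'   (`trial`, `run`, `direction`, `distance_mm`, `report`, `is_reversal`).
#' @examples
#' det <- function(d) if (d >= 40) "two" else "one"
#' res <- run_staircase(det)
#' res$threshold_mm
#' @export
run_staircase <- function(respond, config = staircase_config()) {
  stopifnot(is.function(respond), inherits(config, "staircase_config"))
  clamp <- function(d) min(max(d, config$floor_mm), config$ceiling_mm)

  trials <- vector("list", config$max_trials)
  reversals <- numeric(0)
  trial <- 0L
  d <- config$start_mm
  direction <- 1L # first run ascending

  for (run in seq_len(config$n_runs)) {
    step <- if (run == 1L) config$coarse_step_mm else config$fine_step_mm
    target <- if (direction == 1L) "two" else "one"
    streak <- 0L
    streak_start <- NA_real_
    boundary_streak <- 0L
    boundary_last <- NA_character_

    repeat {
      trial <- trial + 1L
      if (trial > config$max_trials) {
        stop(sprintf(
          "staircase did not converge: %d reversals after %d trials (need %d)",
          length(reversals), config$max_trials, config$n_runs
        ), call. = FALSE)
      }
      report <- tryCatch(
        respond(d),
        error = function(e) {
          stop(sprintf(
            "responder failed at trial %d (run %d, %.1f mm): %s",
            trial, run, d, conditionMessage(e)
          ), call. = FALSE)
        }
      )
      if (!report %in% c("one", "two")) {
        stop(sprintf(
          "responder returned %s at trial %d; expected \"one\" or \"two\"",
          deparse(report), trial
        ), call. = FALSE)
      }

      run_done <- FALSE
      rev_trial <- trial
      if (report == target) {
        streak <- streak + 1L
        if (streak == 1L) streak_start <- d
        if (streak == config$consecutive_criterion) {
          rev_d <- if (config$reversal_rule == "first") streak_start else d
          reversals <- c(reversals, rev_d)
          run_done <- TRUE
          if (config$reversal_rule == "first") {
            rev_trial <- trial - (config$consecutive_criterion - 1L)
          }
        }
      } else {
        streak <- 0L
        streak_start <- NA_real_
      }
      # a clamped boundary cannot be stepped past: three consecutive
      # identical reports there score a reversal so the run terminates
      at_boundary <- d <= config$floor_mm || d >= config$ceiling_mm
      if (at_boundary) {
        if (identical(report, boundary_last)) {
          boundary_streak <- boundary_streak + 1L
        } else {
          boundary_streak <- 1L
          boundary_last <- report
        }
        if (!run_done &&
            boundary_streak == config$consecutive_criterion) {
          reversals <- c(reversals, d)
          run_done <- TRUE
          rev_trial <- trial - (config$consecutive_criterion - 1L)
        }
      } else {
        boundary_streak <- 0L
        boundary_last <- NA_character_
      }
      trials[[trial]] <- list(
        trial = trial, run = run,
        direction = if (direction == 1L) "ascending" else "descending",
        distance_mm = d, report = report, is_reversal = FALSE
      )
      if (run_done) {
        # flag the trial whose separation scored the reversal, so that
        # re-scoring a stored trace reproduces the threshold exactly
        trials[[rev_trial]]$is_reversal <- TRUE
        break
      }
      d <- clamp(d + direction * step)
    }

    # jump in the completed run's direction, then reverse
    d <- clamp(d + direction * config$jump_mm)
    direction <- -direction
  }

  trace <- dplyr::bind_rows(trials[seq_len(trial)])
  structure(
    list(
      threshold_mm = threshold_from_reversals(reversals),
      reversals_mm = reversals,
      trace = trace,
      config = config
    ),
    class = "tpdt_result"
  )
}

#' Threshold from reversal distances
#'
#' The discrimination threshold is the arithmetic mean of the reversal
#' separations; larger values indicate poorer acuity.
#'
#' @param reversals_mm Non-empty numeric vector of reversal distances (mm).
#' @return Threshold in mm.
#' @export
threshold_from_reversals <- function(reversals_mm) {
  if (length(reversals_mm) == 0) {
    stop("no reversal distances supplied", call. = FALSE)
  }
  mean(reversals_mm)
}

#' @export
print.tpdt_result <- function(x, ...) {
  cat(sprintf(
    "<tpdt_result> threshold %.1f mm from %d reversals (%s) over %d trials\n",
    x$threshold_mm, length(x$reversals_mm),
    paste(format(x$reversals_mm), collapse = ", "), nrow(x$trace)
  ))
  invisible(x)
}

#' @describeIn run_staircase Tidy the trial-by-trial trace.
#' @param x A `tpdt_result`.
#' @param ... Unused.
#' @method tidy tpdt_result
#' @export
tidy.tpdt_result <- function(x, ...) x$trace

#' @describeIn run_staircase One-row summary (threshold, trial and reversal
#'   counts).
#' @method glance tpdt_result
#' @export
glance.tpdt_result <- function(x, ...) {
  tibble::tibble(
    threshold_mm = x$threshold_mm,
    n_reversals = length(x$reversals_mm),
    n_trials = nrow(x$trace)
  )
}

#' @describeIn run_staircase Plot the staircase trace with reversals marked.
#' @param object A `tpdt_result`.
#' @method autoplot tpdt_result
#' @export
autoplot.tpdt_result <- function(object, ...) {
  tr <- object$trace
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$trial, y = .data$distance_mm)) +
    ggplot2::geom_step(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$report), size = 2) +
    ggplot2::geom_point(
      data = tr[tr$is_reversal, ],
      colour = "red", size = 3, shape = 1, stroke = 1.2
    ) +
    ggplot2::geom_hline(
      yintercept = object$threshold_mm, linetype = "dashed"
    ) +
    ggplot2::scale_shape_manual(values = c(one = 1, two = 16)) +
    ggplot2::labs(
      x = "Trial", y = "Caliper separation (mm)", shape = "Report",
      title = sprintf("Staircase threshold %.1f mm", object$threshold_mm)
    ) +
    ggplot2::theme_minimal()
}
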