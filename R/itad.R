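#' Node layout of the vibrotactile array
#'
#' Twelve stimulator nodes arranged in three rows of four with 32.5 mm
#' centre-to-centre spacing between all rows and columns. Columns 1-2 lie on
#' the left side of the neck, columns 3-4 on the right.
#'
#' @param spacing_mm Centre-to-centre internode distance in mm.
#' @return A tibble with columns `node`, `row`, `col`, `x_mm`, `y_mm`,
#'   `side`.
#' @export
itad_layout <- function(spacing_mm = 32.5) {
  stopifnot(spacing_mm > 0)
  grid <- tidyr::expand_grid(row = 1:3, col = 1:4)
  dplyr::mutate(
    grid,
    node = dplyr::row_number(),
    x_mm = (.data$col - 1) * spacing_mm,
    y_mm = (.data$row - 1) * spacing_mm,
    side = ifelse(.data$col <= 2, "left", "right")
  ) |>
    dplyr::select("node", "row", "col", "x_mm", "y_mm", "side")
}

# Rook-adjacent neighbours of each node, as a named list of node ids.
node_neighbours <- function(layout = itad_layout()) {
  lapply(seq_len(nrow(layout)), function(i) {
    dr <- abs(layout$row - layout$row[i])
    dc <- abs(layout$col - layout$col[i])
    layout$node[(dr + dc) == 1]
  })
}

# Direction of node b relative to node a on the grid ("up" = smaller row).
relative_direction <- function(layout, a, b) {
  dr <- layout$row[b] - layout$row[a]
  dc <- layout$col[b] - layout$col[a]
  if (dr == -1 && dc == 0) "up"
  else if (dr == 1 && dc == 0) "down"
  else if (dr == 0 && dc == -1) "left"
  else if (dr == 0 && dc == 1) "right"
  else stop("nodes are not grid-adjacent", call. = FALSE)
}

# Shuffle a block of left/right stimuli into a strictly alternating order,
# relaxing only once one side is exhausted.
alternate_sides <- function(left, right, start_left) {
  out <- integer(0)
  want_left <- start_left
  while (length(left) > 0 || length(right) > 0) {
    if ((want_left && length(left) > 0) || length(right) == 0) {
      out <- c(out, left[1]); left <- left[-1]
    } else {
      out <- c(out, right[1]); right <- right[-1]
    }
    want_left <- !want_left
  }
  out
}

#' Build a trial plan for one test
#'
#' The localisation test delivers 72 trials in six series of twelve, each
#' series a block-randomised permutation of all twelve nodes; the orientation
#' test delivers 64 trials in four series of sixteen, each trial an ordered
#' pair of grid-adjacent nodes. Within every series, trials alternate between
#' the left and right side of the neck for as long as both sides have
#' stimuli remaining in the block.
#'
#' @param test `"localisation"` or `"orientation"`.
#' @param layout Node layout, see [itad_layout()].
#' @param n_series Number of series (defaults: 6 for localisation, 4 for
#'   orientation).
#' @param series_length Trials per series (defaults: 12 and 16).
#' @return A tibble with one row per trial: `trial`, `series`, `test`,
#'   `node`, `node2` (second stimulus of an orientation pair, `NA` for
#'   localisation), `side`, and for orientation trials the true `direction`
#'   and the available response `options` (list column).
#' @export
plan_test <- function(test = c("localisation", "orientation"),
                      layout = itad_layout(),
                      n_series = NULL, series_length = NULL) {
  test <- match.arg(test)
  if (is.null(n_series)) n_series <- if (test == "localisation") 6L else 4L
  if (is.null(series_length)) {
    series_length <- if (test == "localisation") 12L else 16L
  }
  stopifnot(n_series >= 1, series_length >= 2)
  nb <- node_neighbours(layout)

  series_list <- lapply(seq_len(n_series), function(s) {
    if (test == "localisation") {
      left <- sample(layout$node[layout$side == "left"])
      right <- sample(layout$node[layout$side == "right"])
      nodes <- alternate_sides(left, right, stats::runif(1) < 0.5)
      tibble::tibble(
        series = s, node = nodes,
        node2 = NA_integer_,
        side = layout$side[nodes],
        direction = NA_character_,
        options = vector("list", length(nodes))
      )
    } else {
      sides <- rep(c("left", "right"), length.out = series_length)
      if (stats::runif(1) < 0.5) sides <- rev(sides)
      first <- vapply(sides, function(sd) {
        candidates <- layout$node[layout$side == sd]
        candidates[sample.int(length(candidates), 1)]
      }, integer(1))
      second <- vapply(first, function(a) {
        nbs <- nb[[a]]
        nbs[sample.int(length(nbs), 1)]
      }, integer(1))
      tibble::tibble(
        series = s, node = first, node2 = second, side = sides,
        direction = vapply(
          seq_along(first),
          function(i) relative_direction(layout, first[i], second[i]),
          character(1)
        ),
        options = lapply(first, function(a) {
          vapply(nb[[a]], function(b) relative_direction(layout, a, b),
                 character(1))
        })
      )
    }
  })

  dplyr::bind_rows(series_list) |>
    dplyr::mutate(test = test, trial = dplyr::row_number()) |>
    dplyr::select("trial", "series", "test", "node", "node2", "side",
                  "direction", "options")
}

#' Simulate a testing session
#'
#' Plays a trial plan against an [itad_observer()]. Localisation responses
#' are drawn over the twelve nodes with probability proportional to a
#' Gaussian kernel of distance from the stimulated node; orientation
#' responses are correct with probability `orientation_accuracy`, with errors
#' uniform over the remaining available directions. Response times are
#' log-normal.
#'
#' @param observer An [itad_observer()].
#' @param plan A trial plan from [plan_test()].
#' @param layout Node layout used to build the plan.
#' @return The plan tibble with added columns `response`, `correct`,
#'   `rt_ms`.
#' @export
simulate_session <- function(observer, plan, layout = itad_layout()) {
  stopifnot(inherits(observer, "itad_observer"), nrow(plan) > 0)
  n <- nrow(plan)
  test <- plan$test[1]

  if (test == "localisation") {
    d2 <- as.matrix(stats::dist(layout[, c("x_mm", "y_mm")]))^2
    w <- exp(-d2 / (2 * observer$localisation_spread_mm^2))
    response <- vapply(plan$node, function(stim) {
      sample.int(nrow(layout), 1, prob = w[stim, ])
    }, integer(1))
    correct <- response == plan$node
    response <- as.character(response)
  } else {
    response <- character(n)
    correct <- logical(n)
    for (i in seq_len(n)) {
      opts <- plan$options[[i]]
      truth <- plan$direction[i]
      if (stats::runif(1) < observer$orientation_accuracy ||
          length(opts) == 1) {
        response[i] <- truth
      } else {
        others <- setdiff(opts, truth)
        response[i] <- others[sample.int(length(others), 1)]
      }
      correct[i] <- response[i] == truth
    }
  }

  plan$response <- response
  plan$correct <- correct
  plan$rt_ms <- stats::rlnorm(n, log(observer$rt_location_ms),
                              observer$rt_scale)
  plan
}

#' Score a session
#'
#' Computes the three summary scores of a trial record set: the accuracy
#' score (percentage correct), the mean response time, and the rate correct
#' score, the number of correct responses per minute of summed response
#' time.
#'
#' @param records Trial records with at least `correct` (logical) and
#'   `rt_ms` (positive numeric) columns, e.g. from [simulate_session()].
#' @return A one-row tibble: `test`, `n_trials`, `n_correct`,
#'   `accuracy_pct`, `mean_rt_ms`, `total_rt_ms`, `rate_correct_per_min`.
#' @examples
#' rec <- tibble::tibble(test = "localisation",
#'                       correct = rep(TRUE, 72), rt_ms = 1000)
#' score_session(rec) # 100%, 1000 ms, 60 correct/min
#' @export
score_session <- function(records) {
  if (nrow(records) == 0) stop("no trial records supplied", call. = FALSE)
  stopifnot(all(records$rt_ms > 0), !anyNA(records$correct))
  tibble::tibble(
    test = if ("test" %in% names(records)) records$test[1] else NA_character_,
    n_trials = nrow(records),
    n_correct = sum(records$correct),
    accuracy_pct = 100 * mean(records$correct),
    mean_rt_ms = mean(records$rt_ms),
    total_rt_ms = sum(records$rt_ms),
    rate_correct_per_min = sum(records$correct) / (sum(records$rt_ms) / 60000)
  )
}

#' Per-series accuracy scores
#'
#' Accuracy percentage for each series within a session, the unit of the
#' internal-consistency analysis.
#'
#' @inheritParams score_session
#' @return A tibble with one row per series: `series`, `accuracy_pct`.
#' @export
score_series <- function(records) {
  if (nrow(records) == 0) stop("no trial records supplied", call. = FALSE)
  records |>
    dplyr::group_by(.data$series) |>
    dplyr::summarise(accuracy_pct = 100 * mean(.data$correct),
                     .groups = "drop")
}

#' Overall scores across the two tests
#'
#' Overall accuracy and response time are the means of the two per-test
#' values; the overall rate correct score pools correct responses and
#' response time across both tests (total correct over total minutes), so it
#' always lies between the two per-test rates.
#'
#' @param loc,ori One-row score tibbles from [score_session()] for the
#'   localisation and orientation test.
#' @return A one-row tibble in the same shape, with `test = "overall"`.
#' @export
overall_scores <- function(loc, ori) {
  stopifnot(nrow(loc) == 1, nrow(ori) == 1)
  needed <- c("accuracy_pct", "mean_rt_ms", "n_correct", "total_rt_ms",
              "n_trials")
  if (!all(needed %in% names(loc)) || !all(needed %in% names(ori))) {
    stop("both score rows must come from score_session()", call. = FALSE)
  }
  tibble::tibble(
    test = "overall",
    n_trials = loc$n_trials + ori$n_trials,
    n_correct = loc$n_correct + ori$n_correct,
    accuracy_pct = mean(c(loc$accuracy_pct, ori$accuracy_pct)),
    mean_rt_ms = mean(c(loc$mean_rt_ms, ori$mean_rt_ms)),
    total_rt_ms = loc$total_rt_ms + ori$total_rt_ms,
    rate_correct_per_min =
      (loc$n_correct + ori$n_correct) /
      ((loc$total_rt_ms + ori$total_rt_ms) / 60000)
  )
}
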