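test_that("layout is a 3 x 4 grid with 32.5 mm nearest-neighbour spacing", {
  lay <- itad_layout()
  expect_equal(nrow(lay), 12)
  expect_equal(sort(unique(lay$row)), 1:3)
  expect_equal(sort(unique(lay$col)), 1:4)
  dmat <- as.matrix(dist(lay[, c("x_mm", "y_mm")]))
  diag(dmat) <- Inf
  expect_equal(unname(apply(dmat, 1, min)), rep(32.5, 12))
  expect_equal(sum(lay$side == "left"), 6)
})

test_that("localisation plans stimulate every node once per series", {
  set.seed(31)
  plan <- plan_test("localisation")
  expect_equal(nrow(plan), 72)
  expect_equal(unique(table(plan$series)), 12L)
  for (s in 1:6) {
    expect_setequal(plan$node[plan$series == s], 1:12)
  }
  # six left and six right stimuli per series alternate strictly
  for (s in 1:6) {
    sides <- plan$side[plan$series == s]
    expect_true(all(sides[-1] != sides[-length(sides)]))
  }
})

test_that("orientation plans use adjacent pairs and alternate sides", {
  set.seed(32)
  lay <- itad_layout()
  plan <- plan_test("orientation")
  expect_equal(nrow(plan), 64)
  expect_equal(unique(table(plan$series)), 16L)
  manhattan <- abs(lay$row[plan$node] - lay$row[plan$node2]) +
    abs(lay$col[plan$node] - lay$col[plan$node2])
  expect_true(all(manhattan == 1))
  for (s in 1:4) {
    sides <- plan$side[plan$series == s]
    expect_true(all(sides[-1] != sides[-length(sides)]))
  }
  # stated direction matches the geometry, and is among the options
  expect_true(all(mapply(function(d, o) d %in% o,
                         plan$direction, plan$options)))
})

test_that("plans are reproducible under a fixed seed", {
  set.seed(7); p1 <- plan_test("localisation")
  set.seed(7); p2 <- plan_test("localisation")
  set.seed(8); p3 <- plan_test("localisation")
  expect_identical(p1, p2)
  expect_false(identical(p1$node, p3$node))
})

test_that("localisation accuracy spans perfect to chance with spread", {
  set.seed(33)
  sharp <- itad_observer(localisation_spread_mm = 1e-3)
  rec <- simulate_session(sharp, plan_test("localisation"))
  expect_equal(score_session(rec)$accuracy_pct, 100)

  blurred <- itad_observer(localisation_spread_mm = 1e6)
  big_plan <- plan_test("localisation", n_series = 50)
  rec <- simulate_session(blurred, big_plan)
  p_hat <- mean(rec$correct)
  se <- sqrt((1 / 12) * (11 / 12) / nrow(rec))
  expect_lt(abs(p_hat - 1 / 12), 4 * se)
})

test_that("calibrated spread reproduces the target accuracy over sessions", {
  set.seed(34)
  p_target <- 0.61
  obs <- itad_observer(
    localisation_spread_mm = calibrate_localisation_spread(p_target)
  )
  as_vals <- replicate(200, {
    score_session(simulate_session(obs, plan_test("localisation")))$accuracy_pct
  })
  se_pct <- 100 * sqrt(p_target * (1 - p_target) / (72 * 200))
  expect_lt(abs(mean(as_vals) - 100 * p_target), 3 * se_pct)
})

test_that("session scores follow their defining arithmetic", {
  rec <- tibble::tibble(test = "localisation", series = rep(1:6, each = 12),
                        correct = rep(TRUE, 72), rt_ms = 1000)
  sc <- score_session(rec)
  expect_equal(sc$accuracy_pct, 100)
  expect_equal(sc$mean_rt_ms, 1000)
  expect_equal(sc$rate_correct_per_min, 60) # 72 correct / 1.2 min

  rec2 <- tibble::tibble(test = "x", correct = rep(c(TRUE, FALSE), 36),
                         rt_ms = 1238.5)
  sc2 <- score_session(rec2)
  expect_equal(sc2$accuracy_pct, 50)
  expect_equal(sc2$rate_correct_per_min, 36 / (72 * 1238.5 / 60000))
  expect_equal(round(sc2$rate_correct_per_min, 2), 24.22)

  expect_error(score_session(rec2[0, ]), "no trial records")
})

test_that("doubling response times halves the rate correct score only", {
  set.seed(35)
  rec <- simulate_session(itad_observer(20), plan_test("localisation"))
  slow <- rec
  slow$rt_ms <- 2 * slow$rt_ms
  a <- score_session(rec)
  b <- score_session(slow)
  expect_equal(b$accuracy_pct, a$accuracy_pct)
  expect_equal(b$rate_correct_per_min, a$rate_correct_per_min / 2)
})

test_that("equal response times make RCS an exact function of AS and RT", {
  rec <- tibble::tibble(test = "x",
                        correct = c(rep(TRUE, 30), rep(FALSE, 42)),
                        rt_ms = 1500)
  sc <- score_session(rec)
  expect_equal(sc$rate_correct_per_min,
               (sc$accuracy_pct / 100) * 60000 / sc$mean_rt_ms)
})

test_that("overall scores mean the test scores but pool the rate", {
  loc <- score_row("localisation", 72, 61.0, 1238.5)
  ori <- score_row("orientation", 64, 46.2, 1995.4)
  ov <- overall_scores(loc, ori)
  expect_equal(ov$accuracy_pct, 53.6)
  expect_equal(ov$mean_rt_ms, 1616.95)
  expect_equal(round(ov$mean_rt_ms), 1617)
  # pooled rate lies between the two per-test rates
  expect_gte(ov$rate_correct_per_min,
             min(loc$rate_correct_per_min, ori$rate_correct_per_min))
  expect_lte(ov$rate_correct_per_min,
             max(loc$rate_correct_per_min, ori$rate_correct_per_min))

  # identical inputs reproduce the per-test scores exactly
  same <- overall_scores(loc, loc)
  expect_equal(same$accuracy_pct, loc$accuracy_pct)
  expect_equal(same$mean_rt_ms, loc$mean_rt_ms)
  expect_equal(same$rate_correct_per_min, loc$rate_correct_per_min)
})

test_that("orientation accuracy tracks the observer parameter", {
  set.seed(36)
  obs <- itad_observer(orientation_accuracy = 0.46)
  plans <- replicate(100, simulate_session(obs, plan_test("orientation")),
                     simplify = FALSE)
  p_hat <- mean(vapply(plans, function(r) mean(r$correct), numeric(1)))
  se <- sqrt(0.46 * 0.54 / (64 * 100))
  expect_lt(abs(p_hat - 0.46), 4 * se)
  # response times strictly positive
  expect_true(all(vapply(plans, function(r) all(r$rt_ms > 0), logical(1))))
})
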