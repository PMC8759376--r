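test_that("coefficients equal an explicit normal-equations solve", {
  d <- tibble::tibble(
    x1 = c(1, 2, 3, 4, 5, 6),
    x2 = c(2, 1, 4, 3, 6, 5),
    y = c(1.2, 1.9, 3.4, 3.8, 5.6, 5.9)
  )
  fit <- ols_enter(d, "y", c("x1", "x2"))
  X <- cbind(1, d$x1, d$x2)
  beta <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(unname(fit$terms$b), as.vector(beta), tolerance = 1e-8)
})

test_that("a noiseless generating model is recovered exactly in the limit", {
  set.seed(81)
  d <- tibble::tibble(x1 = rnorm(60), x2 = rnorm(60))
  d$y <- 3 + 2 * d$x1 + 1e-8 * rnorm(60)
  fit <- ols_enter(d, "y", c("x1", "x2"))
  expect_equal(fit$terms$b[fit$terms$term == "x1"], 2, tolerance = 1e-5)
  expect_equal(fit$terms$b[fit$terms$term == "x2"], 0, tolerance = 1e-5)
  expect_gt(fit$model$r_squared, 1 - 1e-10)
})

test_that("squared semi-partials equal the unique R-squared contribution", {
  set.seed(82)
  d <- tibble::tibble(a = rnorm(40), b = rnorm(40), c = rnorm(40))
  d$y <- 0.5 * d$a - 0.3 * d$b + rnorm(40)
  full <- ols_enter(d, "y", c("a", "b", "c"))
  for (drop in c("a", "b", "c")) {
    reduced <- ols_enter(d, "y", setdiff(c("a", "b", "c"), drop))
    sr <- full$terms$sr[full$terms$term == drop]
    expect_equal(sr^2,
                 full$model$r_squared - reduced$model$r_squared,
                 tolerance = 1e-8)
  }
})

test_that("model degrees of freedom follow the enter-model layout", {
  set.seed(83)
  d <- tibble::as_tibble(matrix(rnorm(100 * 5), 100,
                                dimnames = list(NULL, letters[1:5])))
  fit <- ols_enter(d, "a", c("b", "c", "d", "e"))
  expect_equal(fit$model$df1, 4)
  expect_equal(fit$model$df2, 95)
  expect_lte(fit$model$r_squared_adj, fit$model$r_squared)
  expect_true(all(abs(fit$terms$sr) <= 1, na.rm = TRUE))
})

test_that("regression rejects collinearity and missing columns", {
  d <- tibble::tibble(x = 1:10, y = rnorm(10))
  d$z <- 2 * d$x
  expect_error(ols_enter(d, "y", c("x", "z")), "collinear")
  expect_error(ols_enter(d, "y", "nope"), "not found")
  expect_error(ols_enter(d[1:3, ], "y", c("x", "z")), "too few")
})

test_that("two-level factors are coded 0/1 in regressions", {
  set.seed(84)
  d <- tibble::tibble(g = factor(rep(c("female", "male"), 30)))
  d$y <- 2 + 5 * (as.numeric(d$g) - 1) + rnorm(60, 0, 0.1)
  fit <- ols_enter(d, "y", "g")
  expect_equal(fit$terms$b[2], 5, tolerance = 0.1)
})

test_that("mediation recovers known path products", {
  set.seed(85)
  d <- make_mediation_data(2000, a1 = 0.5, b1 = 0.4)
  res <- sequential_mediation(d, "x", "m1", "m2", "y", n_boot = 1000)
  g <- glance(res)
  expect_lt(abs(g$total_indirect - 0.2), 0.05)
  ind1 <- res$effects$estimate[res$effects$effect == "ind_m1"]
  expect_lt(abs(ind1 - 0.2), 0.05)
  expect_equal(res$p_m, g$total_indirect / g$total)
  expect_true(g$indirect_significant)
})

test_that("the OLS effect decomposition holds to numerical precision", {
  set.seed(86)
  for (rep in 1:15) {
    n <- 80
    d <- make_mediation_data(n, a1 = runif(1, -1, 1), a2 = runif(1, -1, 1),
                             d21 = runif(1, -1, 1), b1 = runif(1, -1, 1),
                             b2 = runif(1, -1, 1), c_direct = runif(1, -1, 1))
    d$cov1 <- rnorm(n)
    res <- sequential_mediation(d, "x", "m1", "m2", "y",
                                covariates = "cov1", n_boot = 1000)
    g <- glance(res)
    expect_equal(g$total, g$direct + g$total_indirect, tolerance = 1e-8)
  }
})

test_that("bootstrap intervals are reproducible and bracket the estimate", {
  d <- withr::with_seed(87, make_mediation_data(150, a1 = 0.6, b1 = 0.5,
                                                d21 = 0.3, b2 = 0.2))
  set.seed(1); r1 <- sequential_mediation(d, "x", "m1", "m2", "y",
                                          n_boot = 1000)
  set.seed(1); r2 <- sequential_mediation(d, "x", "m1", "m2", "y",
                                          n_boot = 1000)
  expect_identical(r1$effects, r2$effects)
  ind <- r1$effects[r1$effects$effect %in%
                      c("ind_m1", "ind_serial", "ind_m2", "total_indirect"), ]
  expect_true(all(ind$conf_low <= ind$estimate &
                    ind$estimate <= ind$conf_high))
})

test_that("mediation rejects collinear mediators and tiny samples", {
  set.seed(88)
  d <- make_mediation_data(100, a1 = 0.5, b1 = 0.3)
  d$m2 <- d$m1
  expect_error(sequential_mediation(d, "x", "m1", "m2", "y", n_boot = 1000),
               "rank")
  expect_error(
    sequential_mediation(make_mediation_data(8), "x", "m1", "m2", "y",
                         n_boot = 1000),
    "too few"
  )
  expect_error(
    sequential_mediation(make_mediation_data(100), "x", "m1", "m2", "y",
                         n_boot = 10),
    "n_boot"
  )
})

test_that("mediation edge list carries all seven labelled paths", {
  set.seed(89)
  d <- make_mediation_data(400, a1 = 0.4, d21 = 0.5, b2 = 0.3)
  res <- sequential_mediation(d, "x", "m1", "m2", "y", n_boot = 1000)
  paths <- tidy(res, type = "paths")
  expect_equal(nrow(paths), 7)
  expect_true(all(c("from", "to", "estimate", "se", "p", "sr") %in%
                    names(paths)))
  # a1 and d21 significant by construction, a2 null
  expect_lt(paths$p[1], 0.01)  # x -> m1
  expect_lt(paths$p[3], 0.01)  # m1 -> m2
})
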