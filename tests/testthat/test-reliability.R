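test_that("a perfectly additive 3x3 table decomposes by hand", {
  m <- rbind(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))
  comp <- anova_components(m)
  expect_equal(comp$ms_error, 0)
  expect_equal(comp$sigma2_observer, 1)
  expect_equal(comp$sigma2_subject, 1)
})

test_that("identical columns give zero error and an ICC of one", {
  m <- cbind(c(1, 5, 9, 13), c(1, 5, 9, 13), c(1, 5, 9, 13))
  comp <- anova_components(m)
  expect_equal(comp$ms_cols, 0)
  expect_equal(comp$ms_error, 0)
  expect_equal(comp$sigma2_subject, var(m[, 1]))
  expect_equal(icc(m, "single")$estimate, 1)
  expect_equal(icc(m, "average")$estimate, 1)
})

test_that("closed-form mean squares match brute-force enumeration", {
  set.seed(61)
  for (rep in 1:60) {
    n <- sample(2:6, 1)
    k <- sample(2:3, 1)
    m <- matrix(sample(0:9, n * k, replace = TRUE), n, k)
    if (sd(m) == 0) next
    comp <- anova_components(m)
    oracle <- brute_force_mean_squares(m)
    expect_equal(comp$ms_rows, oracle$ms_rows, tolerance = 1e-10)
    expect_equal(comp$ms_cols, oracle$ms_cols, tolerance = 1e-10)
    expect_equal(comp$ms_error, oracle$ms_error, tolerance = 1e-10)
  }
})

test_that("variance components recover the generating process", {
  set.seed(62)
  r <- simulate_ratings(variance_spec(100, 4, 1, 1, 2000, 3))
  comp <- anova_components(r)
  expect_equal(comp$sigma2_subject, 4, tolerance = 0.15)
  expect_equal(comp$sigma2_residual, 1, tolerance = 0.1)
  # the rater component has only k-1 = 2 df: wide tolerance
  expect_equal(comp$sigma2_observer, 1, tolerance = 3)
})

test_that("ICC point estimates and intervals match an independent implementation", {
  # 12 x 3 fixture; expected values computed with pingouin's
  # intraclass_corr (ICC(A,1)/ICC(A,k)), which reports CIs at 2 dp
  m <- matrix(c(
    37.1, 47.2, 31.3, 37.1, 56.5, 44.1, 56.2, 50.4, 44.9, 39.9, 39.6, 46.6,
    45.6, 50.2, 37.1, 36, 58.5, 38.6, 56.2, 51.2, 52.3, 35.7, 39.9, 49.2,
    46.5, 58.4, 37.4, 39.7, 54.9, 44.6, 66.2, 53.5, 55.2, 42.6, 36.6, 52.7
  ), nrow = 12)
  s <- icc(m, "single")
  a <- icc(m, "average")
  expect_equal(s$estimate, 0.8019798897, tolerance = 1e-8)
  expect_equal(a$estimate, 0.9239542362, tolerance = 1e-8)
  expect_equal(round(c(s$conf_low, s$conf_high), 2), c(0.51, 0.94))
  expect_equal(round(c(a$conf_low, a$conf_high), 2), c(0.76, 0.98))
})

test_that("average-measures ICC dominates single-measures when positive", {
  set.seed(63)
  for (rep in 1:20) {
    r <- simulate_ratings(variance_spec(0, runif(1, 0.5, 4), runif(1, 0, 1),
                                        runif(1, 0.2, 1), 30, 3))
    s <- icc(r, "single")$estimate
    a <- icc(r, "average")$estimate
    if (s > 0) expect_gte(a, s)
  }
})

test_that("ICC and SEM respect shift and scale transformations", {
  set.seed(64)
  r <- simulate_ratings(variance_spec(50, 3, 1, 1, 40, 3))
  m <- as_ratings_matrix(r)
  base_icc <- icc(m, "single")$estimate
  base_sem <- sem_measurement(anova_components(m))
  base_cov <- cov_percent(base_sem, mean(m))

  shifted <- m + 17
  expect_equal(icc(shifted, "single")$estimate, base_icc)
  expect_equal(sem_measurement(anova_components(shifted)), base_sem)

  scaled <- m * 3
  expect_equal(icc(scaled, "single")$estimate, base_icc)
  expect_equal(sem_measurement(anova_components(scaled)), 3 * base_sem)
  expect_equal(cov_percent(3 * base_sem, mean(scaled)), base_cov)
})

test_that("degenerate and malformed matrices are rejected", {
  expect_error(icc(matrix(5, 4, 3)), "no variance")
  expect_error(anova_components(matrix(1:3, 3, 1)), "at least 2")
  long <- tibble::tibble(subject = c(1, 1, 2), rater = c(1, 2, 1),
                         value = c(1, 2, 3))
  expect_error(anova_components(long), "missing cells")
})

test_that("SEM combines the error components and floors negatives", {
  comp0 <- anova_components(rbind(c(1, 1, 1), c(5, 5, 5), c(9, 9, 9)))
  expect_equal(sem_measurement(comp0), 0)

  fake <- structure(
    list(sigma2_observer = 64, sigma2_residual = 36,
         negative_components = character(0)),
    class = "anova_components"
  )
  expect_equal(sem_measurement(fake), 10)

  fake$sigma2_observer <- -2
  expect_warning(out <- sem_measurement(fake), "floored")
  expect_equal(out, 6)
})

test_that("negative variance components are preserved and flagged", {
  # anticorrelated columns: the subject component estimate goes negative
  neg <- anova_components(cbind(c(0, 1), c(1, 0), c(0.5, 0.5)))
  expect_lt(neg$sigma2_subject, 0)
  expect_true("sigma2_subject" %in% neg$negative_components)
})

test_that("CoV reproduces the published ratios and rejects a zero mean", {
  expect_equal(round(cov_percent(8.7, 61.0), 1), 14.3)
  expect_equal(round(cov_percent(134.0, 1995.4), 1), 6.7)
  expect_equal(cov_percent(0, 50), 0)
  expect_error(cov_percent(5, 0), "zero mean")
  expect_equal(classify_cov(c(5, 14.3, 25.3)),
               c("<10%", "10-20%", ">20%"))
})

test_that("the SDC ladder follows z*sqrt(2)*SEM and increases with confidence", {
  expect_equal(round(sdc(12.1, 0.95), 1), 33.5)
  expect_equal(round(sdc(8.7, 0.95), 1), 24.1)
  expect_equal(round(sdc(12.1, 0.90), 1), 28.1)
  expect_equal(sdc(0, c(0.8, 0.85, 0.9, 0.95)), rep(0, 4))
  ladder <- sdc(5.9, c(0.80, 0.85, 0.90, 0.95))
  expect_true(all(diff(ladder) > 0))
  expect_error(sdc(5, 1.2))
})

test_that("ICC interpretation bands use the published cut-offs", {
  expect_equal(classify_icc(0.70), "moderate")
  expect_equal(classify_icc(0.86), "good")
  expect_equal(classify_icc(0.49999), "poor")
  expect_equal(classify_icc(c(0.5, 0.75, 0.9)),
               c("moderate", "good", "excellent"))
})

test_that("reliability_report collects consistent pieces", {
  set.seed(65)
  r <- simulate_ratings(variance_spec(47.7, 341, 36.6, 109.8, 40, 3))
  rep_out <- reliability_report(r, metric = "tpdt", units = "mm")
  g <- glance(rep_out)
  expect_equal(g$sem, sem_measurement(rep_out$components))
  expect_equal(g$cov_pct, 100 * g$sem / g$mean_score)
  expect_equal(g$sdc95, sdc(g$sem, 0.95))
  expect_equal(g$icc_band, classify_icc(g$icc21))
  td <- tidy(rep_out)
  expect_equal(nrow(td), 2)
  expect_setequal(td$form, c("single", "average"))
})
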