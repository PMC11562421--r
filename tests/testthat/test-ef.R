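make_task_fixture <- function() {
  # five persons with hand-computable task summaries
  series <- tidyr::expand_grid(person_id = sprintf("p%d", 1:5), series = 1:50)
  series$mean_rt <- dplyr::case_when(
    series$person_id == "p1" ~ 450,                                   # SD 0
    series$person_id == "p2" ~ ifelse(series$series <= 25, 400, 500), # SD 50.51
    TRUE ~ 400 + 2 * series$series
  )
  parts <- tidyr::expand_grid(person_id = sprintf("p%d", 1:5),
                              task = c("shifting_set", "memory_search"),
                              part = 1:3)
  parts$mean_rt <- 400 + 60 * parts$part + 5 * as.integer(factor(parts$person_id))
  parts$pct_errors <- 4 + 2 * parts$part
  sad <- tibble::tibble(person_id = sprintf("p%d", 1:5), task = "sustained_attention",
                        part = 1, mean_rt = 450, pct_errors = c(5, 8, 4, 6, 7))
  list(series = series, parts = dplyr::bind_rows(parts, sad))
}

test_that("EF scores match spreadsheet-style recomputation", {
  fx <- make_task_fixture()
  ef <- derive_ef_scores(fx$series, fx$parts)
  ef <- ef[order(ef$person_id), ]
  # fluctuation in tempo: SD of the 50 per-series means (n - 1 convention)
  expect_equal(ef$fluct_tempo[1], 0)
  expect_equal(ef$fluct_tempo[2], sd(rep(c(400, 500), each = 25)))
  expect_equal(ef$fluct_tempo[2], 50.5076, tolerance = 1e-4)
  # part-difference scores: part2 - part1 = 60 ms, part3 - part1 = 120 ms
  expect_equal(ef$resinhib_rt, rep(60, 5))
  expect_equal(ef$cogflex_rt, rep(120, 5))
  expect_equal(ef$wm_rt, rep(120, 5))
  expect_equal(ef$resinhib_err, rep(2, 5))
  expect_equal(ef$wm_err, rep(4, 5))
  expect_equal(ef$fluct_errors, c(5, 8, 4, 6, 7))
  # a stated subtraction example: part1 400, part2 520 -> 120
  parts2 <- tibble::tibble(person_id = "q", task = "shifting_set", part = 1:2,
                           mean_rt = c(400, 520), pct_errors = c(3, 6))
  series2 <- tibble::tibble(person_id = "q", series = 1:50,
                            mean_rt = rnorm(50, 450, 20))
  ef2 <- derive_ef_scores(series2, parts2)
  expect_equal(ef2$resinhib_rt, 120)
  # fewer than 2 series: SD undefined
  expect_error(derive_ef_scores(series2[1, ], parts2),
               class = "panelnets_validation_error")
})

test_that("the z-score outlier filter removes exactly the planted outlier", {
  set.seed(40)
  x <- rnorm(100)
  x <- c(x, mean(x) + 6 * sd(x))
  out <- zscore_outlier_filter(x, threshold = 4)
  expect_equal(attr(out, "n_removed"), 1L)
  expect_true(is.na(out[101]))
  expect_equal(sum(is.na(out)), 1)
  # all equal: warning, nothing removed
  expect_warning(same <- zscore_outlier_filter(rep(2, 10)), "zero variance")
  expect_equal(attr(same, "n_removed"), 0L)
  # infinite threshold: identity
  id <- zscore_outlier_filter(x, threshold = Inf)
  expect_equal(as.numeric(id), x)
  expect_error(zscore_outlier_filter(c(1, 2)), class = "panelnets_validation_error")
  # single pass: borderline values that become extreme after removal stay
  y <- c(rnorm(50), 10, 100)
  once <- zscore_outlier_filter(y, threshold = 4)
  expect_lte(attr(once, "n_removed"), 1L)
})

test_that("FIML regression equals least squares on complete data", {
  set.seed(41)
  d <- tibble::tibble(x = rnorm(150))
  d$y <- 2 + 0.8 * d$x + rnorm(150)
  fr <- fit_fiml_regression(d, "y", "x", se = FALSE)
  # single predictor: slope is the closed form cov(x, y) / var(x)
  expect_equal(fr$coefficients$estimate, cov(d$x, d$y) / var(d$x),
               tolerance = 1e-8)
  expect_equal(fr$coefficients$estimate, unname(coef(lm(y ~ x, d))[2]),
               tolerance = 1e-8)
  expect_equal(fr$intercept, unname(coef(lm(y ~ x, d))[1]), tolerance = 1e-8)
  # independent outcome: negligible R^2
  set.seed(42)
  dn <- tibble::tibble(x1 = rnorm(2000), x2 = rnorm(2000), y = rnorm(2000))
  frn <- fit_fiml_regression(dn, "y", c("x1", "x2"), se = FALSE)
  expect_lt(frn$r_squared, 0.01)
  # collinear predictors error
  dc <- tibble::tibble(x1 = rnorm(100))
  dc$x2 <- 2 * dc$x1
  dc$y <- rnorm(100)
  expect_error(fit_fiml_regression(dc, "y", c("x1", "x2"), se = FALSE),
               class = "panelnets_collinearity_error")
})

test_that("FIML stays consistent under 30% MCAR missingness", {
  set.seed(43)
  n <- 2000
  X <- matrix(rnorm(n * 3), n)
  y <- X %*% c(0.5, -0.3, 0.2) + rnorm(n)
  d <- tibble::tibble(y = as.numeric(y), x1 = X[, 1], x2 = X[, 2], x3 = X[, 3])
  full <- fit_fiml_regression(d, "y", c("x1", "x2", "x3"), se = FALSE)
  dm <- d
  for (cl in c("x1", "x2", "x3")) {
    dm[[cl]][sample(n, 0.3 * n)] <- NA
  }
  part <- fit_fiml_regression(dm, "y", c("x1", "x2", "x3"), se = FALSE)
  expect_lt(max(abs(part$coefficients$estimate - full$coefficients$estimate)), 0.05)
})

test_that("FIML regression coefficients are equivariant to predictor scaling", {
  set.seed(44)
  d <- tibble::tibble(x = rnorm(300), z = rnorm(300))
  d$y <- 0.4 * d$x - 0.2 * d$z + rnorm(300)
  f1 <- fit_fiml_regression(d, "y", c("x", "z"), se = FALSE)
  d2 <- dplyr::mutate(d, x = x * 10)
  f2 <- fit_fiml_regression(d2, "y", c("x", "z"), se = FALSE)
  expect_equal(f2$coefficients$estimate[1] * 10, f1$coefficients$estimate[1],
               tolerance = 1e-8)
  expect_equal(f2$coefficients$std_estimate, f1$coefficients$std_estimate,
               tolerance = 1e-8)
})

test_that("hierarchical comparisons are nested and detect the EF regime", {
  spec <- cohort_spec(n_persons = 2000, seed = 71)
  truth <- make_ground_truth(spec, "trails_like")
  pan <- simulate_panel(truth, spec)
  ef <- simulate_ef(pan, truth, spec)
  hc <- hierarchical_compare(pan, ef, "internalizing", wave = 2, se = FALSE)
  expect_gte(hc$r2_step2, hc$r2_step1)
  expect_equal(hc$delta_r2, hc$r2_step2 - hc$r2_step1)
  # coefficient table ordered as the printed two-step specification
  expect_equal(hc$step2$coefficients$term,
               c("sex", "internalizing_w1", "externalizing_w1",
                 panelnets:::ef_model_order()))
  # weak-effect regime: every EF coefficient small, fluct_tempo positive
  efco <- hc$step2$coefficients
  efrows <- efco[efco$term %in% panelnets:::ef_model_order(), ]
  expect_true(all(abs(efrows$std_estimate) < 0.10))
  expect_gt(efrows$std_estimate[efrows$term == "fluct_tempo"], 0)

  # all-zero EF effects: no incremental variance explained
  spec0 <- cohort_spec(n_persons = 2000,
                       ef_betas = setNames(rep(0, 8), names(default_ef_betas())),
                       seed = 71)
  ef0 <- simulate_ef(pan, truth, spec0)
  hc0 <- hierarchical_compare(pan, ef0, "internalizing", wave = 2, se = FALSE)
  expect_lt(hc0$delta_r2, 0.01)
  expect_gte(hc0$delta_r2, 0)

  # wave 3 uses wave-2 symptoms as the previous wave
  hc3 <- hierarchical_compare(pan, ef, "externalizing", wave = 3, se = FALSE)
  expect_true(all(c("internalizing_w2", "externalizing_w2") %in%
                    hc3$step2$coefficients$term))
})

test_that("domain aggregates average the right communities", {
  vals <- cbind(a = c(0, 2), b = c(2, 2), c = c(1, 3))
  pd <- toy_panel(list(vals),
                  variables = tibble::tibble(
                    name = c("a", "b", "c"),
                    community = c("internalizing", "internalizing", "attention")))
  agg <- domain_aggregates(pd)
  expect_equal(agg$internalizing_w1, c(1, 2))
  expect_equal(agg$externalizing_w1, c(1, 3))  # attention counts as externalizing
})
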