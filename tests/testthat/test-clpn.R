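std <- function(m) scale(m)[, , drop = FALSE]

test_that("the unpenalized limit equals least squares", {
  set.seed(5)
  X <- std(matrix(rnorm(200 * 4), 200))
  y <- X %*% c(1, -0.5, 0, 0.2) + rnorm(200, sd = 0.3)
  fit <- fit_node_lasso(X, y, 0)
  ols <- coef(lm(y ~ X))
  expect_equal(unname(fit$coef), unname(ols[-1]), tolerance = 1e-8)
  expect_equal(fit$intercept, unname(ols[1]), tolerance = 1e-8)
  # y = x exactly with a single predictor: coefficient 1
  x1 <- std(matrix(rnorm(100), 100))
  f1 <- fit_node_lasso(x1, as.numeric(x1), 0)
  expect_equal(unname(f1$coef), 1, tolerance = 1e-10)
})

test_that("penalties above the soft-threshold bound give the null model", {
  set.seed(6)
  X <- std(matrix(rnorm(150 * 5), 150))
  y <- rnorm(150)
  lambda_max <- max(abs(crossprod(X, y - mean(y))) / length(y))
  fit <- fit_node_lasso(X, y, lambda_max * 1.0001)
  expect_true(all(fit$coef == 0))
})

test_that("orthonormal designs reproduce closed-form soft-thresholding", {
  # column-centered X with X'X = n I: the LASSO solution (with intercept)
  # is soft(b_ols, lambda) coordinatewise
  set.seed(7)
  n <- 128; p <- 6
  Z <- scale(matrix(rnorm(n * p), n), scale = FALSE)
  Q <- qr.Q(qr(Z))                 # orthonormal and mean-zero columns
  X <- Q * sqrt(n)                 # columns with x_j'x_j = n, orthogonal
  beta <- c(1.2, -0.8, 0.4, 0.15, -0.05, 0)
  y <- X %*% beta + rnorm(n, sd = 0.2)
  b_ols <- as.numeric(crossprod(X, y - mean(y))) / n
  for (lambda in c(0.05, 0.2, 0.6)) {
    fit <- fit_node_lasso(X, y, lambda)
    expected <- sign(b_ols) * pmax(abs(b_ols) - lambda, 0)
    expect_equal(unname(fit$coef), expected, tolerance = 1e-6)
    # KKT conditions at the optimum
    expect_lt(panelnets:::lasso_kkt_gap(X, y, fit, lambda), 1e-6)
  }
})

test_that("solutions satisfy the KKT conditions on correlated designs", {
  set.seed(8)
  n <- 300
  Z <- matrix(rnorm(n * 5), n)
  X <- std(Z %*% chol(0.5 + 0.5 * diag(5)))
  y <- as.numeric(scale(X %*% c(0.7, 0, -0.4, 0, 0.1) + rnorm(n)))
  for (lambda in c(0.01, 0.05, 0.15)) {
    fit <- fit_node_lasso(X, y, lambda)
    expect_lt(panelnets:::lasso_kkt_gap(X, y, fit, lambda), 1e-6)
  }
})

test_that("lasso support is monotone in the penalty", {
  set.seed(9)
  X <- std(matrix(rnorm(200 * 6), 200))
  y <- X %*% c(0.8, 0.5, 0.3, 0.1, 0, 0) + rnorm(200, sd = 0.5)
  grid <- exp(seq(log(0.5), log(0.001), length.out = 25))
  sizes <- vapply(grid, function(l) sum(fit_node_lasso(X, y, l)$coef != 0), 0L)
  expect_true(all(diff(sizes) >= 0))  # descending lambda: support grows
})

test_that("cross-validation selects sensibly and matches a LOO oracle", {
  # leave-one-out on a 10-row toy equals a hand-rolled LOO loop
  set.seed(10)
  X <- std(matrix(rnorm(10 * 2), 10))
  y <- as.numeric(X %*% c(1, 0.5) + rnorm(10, sd = 0.2))
  grid <- c(0.5, 0.2, 0.05, 0.01)
  cv <- select_lambda_cv(X, y, k = 10, grid = grid, rule = "min", seed = 123)
  folds <- panelnets:::with_seed(123, sample(rep(1:10, length.out = 10)))
  oracle <- matrix(NA_real_, length(grid), 10)
  for (f in 1:10) {
    i <- which(folds == f)
    for (g in seq_along(grid)) {
      ft <- fit_node_lasso(X[-i, , drop = FALSE], y[-i], grid[g])
      oracle[g, f] <- (y[i] - ft$intercept - sum(X[i, ] * ft$coef))^2
    }
  }
  expect_equal(cv$fold_mse, oracle, tolerance = 1e-5)
  expect_equal(cv$selected, which.min(rowMeans(oracle)))

  # pure-noise outcome: the selected model is empty (three seeds)
  set.seed(11)
  Xn <- std(matrix(rnorm(500 * 5), 500))
  yn <- rnorm(500)
  for (s in c(1, 2, 3)) {
    cvn <- select_lambda_cv(Xn, yn, seed = s)
    fitn <- fit_node_lasso(Xn, yn, cvn$lambda_selected)
    expect_true(all(fitn$coef == 0))
  }

  # strong signal: the true support is recovered in full
  ys <- as.numeric(Xn %*% c(1, -0.8, 0.6, 0, 0) + rnorm(500, sd = 0.1))
  cvs <- select_lambda_cv(Xn, ys, seed = 4)
  fits <- fit_node_lasso(Xn, ys, cvs$lambda_selected)
  expect_true(all(fits$coef[1:3] != 0))

  # the 1-SE rule never selects a denser model than the minimum rule
  cvm <- select_lambda_cv(Xn, ys, seed = 4, rule = "min")
  expect_gte(cvs$lambda_selected, cvm$lambda_selected)

  # domain errors
  expect_error(select_lambda_cv(Xn, ys, grid = numeric(0)),
               class = "panelnets_domain_error")
  expect_error(select_lambda_cv(Xn, ys, grid = c(0.1, -0.2)),
               class = "panelnets_domain_error")
  expect_error(fit_node_lasso(Xn, ys, -1), class = "panelnets_domain_error")
})

test_that("the solver agrees with an independent coordinate-descent oracle", {
  # confirmation away from the orthonormal special case
  set.seed(12)
  X <- std(matrix(rnorm(400 * 3), 400))
  y <- as.numeric(scale(X %*% c(0.5, -0.3, 0) + rnorm(400)))
  f <- fit_node_lasso(X, y, 0.07)
  cd <- coordinate_descent_lasso(X, y, 0.07)
  expect_equal(unname(f$coef), cd, tolerance = 1e-6)
})

test_that("cross-lagged networks recover planted temporal structure", {
  # null truth (diagonal B, negligible trait variance so the population
  # cross-lagged coefficients are exactly zero): off-diagonals almost all 0
  truth0 <- sparse_gvar_truth()
  truth0$B <- diag(0.3, 4)
  truth0$Sigma_B <- diag(1e-8, 4)
  dimnames(truth0$B) <- dimnames(truth0$Sigma_B) <- dimnames(truth0$K_zeta)
  spec <- cohort_spec(n_persons = 1000, p = 4, retention = c(1, 1, 1), seed = 51)
  pan0 <- simulate_panel(truth0, spec)
  net0 <- estimate_clpn(pan0, 1, 2, seed = 1)
  off0 <- net0$weights[row(net0$weights) != col(net0$weights)]
  expect_gte(mean(off0 == 0), 0.9)
  expect_true(all(abs(off0) < 0.05))
  expect_true(all(diag(net0$weights) > 0.05))  # 1-SE shrinks the 0.3 autocorrelation

  # single planted edge of standardized size 0.4 recovered within +-0.1:
  # with unit innovation variance and the lone raw edge b, the outcome SD is
  # sqrt(1 + b^2), so b = 0.4364 gives a standardized coefficient of 0.4
  truth1 <- truth0
  truth1$B <- matrix(0, 4, 4, dimnames = dimnames(truth0$B))
  truth1$B[2, 1] <- 0.4364
  truth1$K_zeta <- diag(4)
  dimnames(truth1$K_zeta) <- dimnames(truth0$K_zeta)
  pan1 <- simulate_panel(truth1, cohort_spec(n_persons = 1000, p = 4,
                                             retention = c(1, 1, 1), seed = 52))
  # magnitude recovery uses the min-MSE rule: the 1-SE rule trades a known
  # shrinkage bias (~ the selected penalty) for its sparsity guarantee
  net1 <- estimate_clpn(pan1, 1, 2, seed = 1, rule = "min")
  w <- net1$weights["V1", "V2"]
  expect_gt(abs(w), 0)
  expect_lt(abs(unname(w) - 0.4), 0.1)
  offd <- net1$weights; offd[1, 2] <- 0; diag(offd) <- 0
  expect_true(all(abs(offd) <= 0.1))  # min-rule false edges stay small
  # the default sparse rule zeroes every false edge and keeps the true one,
  # shrunk toward zero by its penalty
  net1s <- estimate_clpn(pan1, 1, 2, seed = 1)
  offs <- net1s$weights; offs[1, 2] <- 0; diag(offs) <- 0
  expect_true(all(offs == 0))
  expect_gt(net1s$weights["V1", "V2"], 0.15)
  expect_lte(abs(net1s$weights["V1", "V2"]), abs(w))
})

test_that("identical waves saturate the autoregression", {
  set.seed(13)
  m <- matrix(rnorm(300 * 3), 300, dimnames = list(NULL, c("a", "b", "c")))
  pd <- toy_panel(list(m, m))
  net <- estimate_clpn(pd, 1, 2, seed = 2)
  expect_true(all(diag(net$weights) > 0.95))
  expect_true(all(abs(net$weights[row(net$weights) != col(net$weights)]) < 0.02))
})

test_that("the estimator is equivariant to node relabeling", {
  spec <- cohort_spec(n_persons = 400, p = 4, retention = c(1, 1, 1), seed = 53)
  pan <- simulate_panel(sparse_gvar_truth(), spec)
  net <- estimate_clpn(pan, 1, 2, seed = 9)
  perm <- c(3, 1, 4, 2)
  pan_p <- pan
  pan_p$values <- pan$values[, , perm]
  pan_p$variables <- pan$variables[perm, ]
  dimnames(pan_p$values)[[3]] <- pan_p$variables$name
  net_p <- estimate_clpn(pan_p, 1, 2, seed = 9)
  expect_equal(net_p$weights, net$weights[perm, perm], tolerance = 1e-8)
})

test_that("lasso shrinkage keeps selected edges no larger than OLS", {
  spec <- cohort_spec(n_persons = 800, p = 4, retention = c(1, 1, 1), seed = 54)
  pan <- simulate_panel(sparse_gvar_truth(), spec)
  net <- estimate_clpn(pan, 1, 2, seed = 3)
  cc <- wave_pair_complete_cases(pan, 1, 2)
  X <- scale(cc$X)
  for (k in 1:4) {
    y <- as.numeric(scale(cc$Y[, k]))
    sel <- which(net$weights[, k] != 0)
    if (!length(sel)) next
    ols <- coef(lm(y ~ X[, sel, drop = FALSE] - 1))
    expect_true(all(abs(net$weights[sel, k]) <= abs(ols) + 0.02))
  }
})

test_that("tidy and glance summarise a cross-lagged network", {
  spec <- cohort_spec(n_persons = 300, p = 4, retention = c(1, 1, 1), seed = 55)
  pan <- simulate_panel(sparse_gvar_truth(), spec)
  net <- estimate_clpn(pan, 1, 2, seed = 3)
  td <- tidy(net, all_edges = TRUE)
  expect_equal(nrow(td), 16)
  expect_setequal(names(td), c("from", "to", "weight", "autoregressive",
                               "wave_from", "wave_to"))
  expect_equal(sum(td$autoregressive), 4)
  g <- glance(net)
  expect_equal(g$n_used, 300)
})
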