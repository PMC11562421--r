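scalar_params <- function() {
  gvar_params(mu = matrix(0, 3, 1), B = matrix(0.5, 1, 1),
              K_zeta = matrix(1 / 0.75, 1, 1), K_B = matrix(2, 1, 1))
}

test_that("implied moments solve the Lyapunov equation and the scalar case", {
  # B = 0.5, innovation variance 0.75, between variance 0.5:
  # within-variance 1, total variance 1.5, lag-1 covariance 1.0
  mom <- implied_moments(scalar_params(), 3)
  expect_equal(mom$Sigma_W[1, 1], 1.0)
  expect_equal(mom$cov[1, 1], 1.5)
  expect_equal(mom$cov[2, 1], 1.0)
  expect_equal(mom$cov[3, 1], 0.75)  # lag 2: 0.5 + 0.25 * 1

  # B = 0: every cross-wave block equals Sigma_B exactly
  p0 <- gvar_params(mu = matrix(0, 3, 2), B = matrix(0, 2, 2),
                    K_zeta = diag(2), K_B = diag(2, 2))
  m0 <- implied_moments(p0, 3)
  expect_equal(m0$cov[3:4, 1:2], diag(0.5, 2))
  expect_equal(m0$cov[5:6, 3:4], diag(0.5, 2))

  # random stationary parameters: PD covariance, tiny Lyapunov residual
  for (s in 1:50) {
    prm <- panelnets:::with_seed(s, {
      B <- matrix(rnorm(16, sd = 0.2), 4)
      B <- B * 0.8 / max(1e-9, panelnets:::spectral_radius(B))
      A1 <- matrix(rnorm(16), 4); A2 <- matrix(rnorm(16), 4)
      gvar_params(mu = matrix(0, 3, 4), B = B,
                  K_zeta = crossprod(A1) / 4 + diag(4),
                  K_B = crossprod(A2) / 4 + diag(4))
    })
    mm <- implied_moments(prm, 3)
    resid <- mm$Sigma_W - (prm$B %*% mm$Sigma_W %*% t(prm$B) + solve(prm$K_zeta))
    expect_lt(norm(resid, "F"), 1e-10)
    expect_gt(min(eigen(mm$cov, symmetric = TRUE, only.values = TRUE)$values), 0)
    # stationarity: all diagonal blocks identical
    expect_equal(mm$cov[1:4, 1:4], mm$cov[9:12, 9:12], tolerance = 1e-12)
  }
  # non-stationary parameters are rejected
  expect_error(
    implied_moments(structure(list(mu = matrix(0, 3, 1), B = matrix(1.2, 1, 1),
                                   K_zeta = diag(1), K_B = diag(1)),
                              class = "gvar_params"), 3),
    class = "panelnets_stationarity_error")
})

test_that("FIML equals the closed-form Gaussian likelihood without missingness", {
  # one observed standard-normal cell at zero: logL = -log(2 pi)/2
  one <- toy_panel(list(cbind(x = c(0, 0, 0, 0))))
  prm1 <- gvar_params(mu = matrix(0, 1, 1), B = matrix(0, 1, 1),
                      K_zeta = matrix(2, 1, 1), K_B = matrix(2, 1, 1))
  # total implied variance = 0.5 + 0.5 = 1
  expect_equal(fiml_loglik(prm1, one), 4 * (-0.5 * log(2 * pi)))

  # complete data: matches the saturated formula when params imply the
  # sample moments (checked through the generic pattern kernel)
  ssim <- simulate_sparse_gvar(n = 60, seed = 8)
  prm <- gvar_params(mu = matrix(0, 3, 4), B = ssim$truth$B,
                     K_zeta = ssim$truth$K_zeta, K_B = solve(ssim$truth$Sigma_B))
  Y <- panelnets:::stacked_matrix(ssim$panel)
  mom <- implied_moments(prm, 3)
  n <- nrow(Y); d <- ncol(Y)
  ctr <- sweep(Y, 2, mom$mean)
  S <- crossprod(ctr) / n
  closed <- -0.5 * n * (d * log(2 * pi) +
                          determinant(mom$cov)$modulus[1] +
                          sum(diag(solve(mom$cov, S))))
  expect_equal(fiml_loglik(prm, ssim$panel), closed, tolerance = 1e-8)
})

test_that("diagonal implied covariance factorizes into marginals", {
  vals1 <- cbind(x = c(0.3, -1, NA), y = c(1, NA, 0.5))
  vals2 <- cbind(x = c(0.1, 0.2, 0.4), y = c(NA, -0.3, 1.2))
  pd <- suppressWarnings(toy_panel(list(vals1, vals2)))
  prm <- gvar_params(mu = matrix(0.1, 2, 2), B = matrix(0, 2, 2),
                     K_zeta = diag(c(2, 4)), K_B = diag(c(10, 10)))
  mom <- implied_moments(prm, 2)
  # B = 0 with diagonal precisions still leaves cross-wave trait covariance,
  # so shrink it to nothing for a truly diagonal joint covariance
  prm2 <- gvar_params(mu = matrix(0.1, 2, 2), B = matrix(0, 2, 2),
                      K_zeta = diag(c(2, 4)), K_B = diag(1e8, 2))
  mom2 <- implied_moments(prm2, 2)
  expect_lt(max(abs(mom2$cov - diag(diag(mom2$cov)))), 1e-7)
  ll <- fiml_loglik(prm2, pd)
  Y <- panelnets:::stacked_matrix(pd)
  marg <- 0
  for (j in 1:4) {
    obs <- !is.na(Y[, j])
    marg <- marg + sum(stats::dnorm(Y[obs, j], mom2$mean[j],
                                    sqrt(mom2$cov[j, j]), log = TRUE))
  }
  expect_equal(ll, marg, tolerance = 1e-8)
})

test_that("the R reference likelihood equals the compiled kernel", {
  ssim <- simulate_sparse_gvar(n = 150, seed = 12, retention = c(1, 0.9, 0.7))
  prm <- gvar_params(mu = matrix(0.05, 3, 4), B = ssim$truth$B,
                     K_zeta = ssim$truth$K_zeta, K_B = solve(ssim$truth$Sigma_B))
  masks <- panelnets:::gvar_masks_default(4)
  th <- panelnets:::pack_theta(prm, masks)
  um <- panelnets:::masks_to_umat(masks)
  stats <- unname(panelnets:::pattern_suffstats(panelnets:::stacked_matrix(ssim$panel)))
  llC <- -panelnets:::gvar_negloglik_cpp(th, 4, 3, um$B, um$K_zeta, um$K_B, stats)
  expect_equal(fiml_loglik(prm, ssim$panel), llC, tolerance = 1e-9)
  # theta packing round-trips exactly
  back <- panelnets:::unpack_theta(th, 4, 3, masks)
  expect_equal(back$B, prm$B, ignore_attr = TRUE)
  expect_equal(back$K_zeta, prm$K_zeta, ignore_attr = TRUE)
  expect_equal(back$K_B, prm$K_B, ignore_attr = TRUE)
})

test_that("saturated estimation recovers the generating parameters", {
  ssim <- simulate_sparse_gvar(n = 2000, seed = 42)
  det <- detrend_standardize(ssim$panel)
  fit <- fit_panel_gvar(det, starts = 1, seed = 1)
  expect_true(fit$converged)
  # standardization rescales edges mildly; recovery is close elementwise
  expect_lt(max(abs(fit$params$B - ssim$truth$B)), 0.08)
  strong <- abs(ssim$truth$B) >= 0.15
  expect_true(all(sign(fit$params$B[strong]) == sign(ssim$truth$B[strong])))
  # refitting from the optimum cannot beat it by more than numerical noise
  refit <- fit_panel_gvar(det, warm_theta = fit$theta, seed = 1)
  expect_gte(refit$loglik, fit$loglik - 1e-6)
})

test_that("null temporal structure estimates to near zero", {
  truth0 <- sparse_gvar_truth()
  truth0$B <- matrix(0, 4, 4, dimnames = dimnames(truth0$B))
  spec <- cohort_spec(n_persons = 2000, p = 4, retention = c(1, 1, 1), seed = 77)
  det <- detrend_standardize(simulate_panel(truth0, spec))
  fit <- fit_panel_gvar(det, starts = 1, seed = 2)
  offB <- fit$params$B[row(fit$params$B) != col(fit$params$B)]
  expect_lt(max(abs(offB)), 0.05)
})

test_that("partial correlations from the fitted precisions are well formed", {
  ssim <- simulate_sparse_gvar(n = 800, seed = 5)
  fit <- fit_panel_gvar(detrend_standardize(ssim$panel), starts = 1, seed = 1)
  for (pc in list(contemporaneous_network(fit), between_network(fit))) {
    expect_equal(pc, t(pc))
    expect_true(all(abs(pc) <= 1))
    expect_equal(diag(pc), setNames(rep(0, 4), rownames(pc)))
  }
  # temporal network orientation: net[from, to] = t(B)
  expect_equal(temporal_network(fit), t(fit$params$B))
})

test_that("prune with alpha = 1 keeps the model unchanged", {
  ssim <- simulate_sparse_gvar(n = 600, seed = 30)
  det <- detrend_standardize(ssim$panel)
  fit <- fit_panel_gvar(det, starts = 1, seed = 1)
  pr <- prune_stepup(fit, det, alpha = 1)
  expect_equal(sum(pr$masks$B), 16)  # nothing pruned
  expect_equal(pr$loglik, fit$loglik, tolerance = 1e-6)
})

test_that("prune plus step-up keeps true structure and stays nested", {
  ssim <- simulate_sparse_gvar(n = 2000, seed = 61)
  det <- detrend_standardize(ssim$panel)
  fit <- fit_panel_gvar(det, starts = 1, seed = 1)
  pr <- prune_stepup(fit, det, alpha = 0.05)
  expect_lte(pr$loglik, fit$loglik + 1e-6)
  # all |true| >= 0.3 temporal edges retained
  strong <- which(abs(ssim$truth$B) >= 0.3, arr.ind = TRUE)
  for (r in seq_len(nrow(strong))) {
    expect_true(pr$masks$B[strong[r, 1], strong[r, 2]])
  }
  # trace records coherent decisions
  expect_true(all(pr$prune_trace$action %in% c("prune", "add")))
  expect_true(all(pr$prune_trace$p_value >= 0 & pr$prune_trace$p_value <= 1))
})

test_that("fit indices behave at their analytic anchors", {
  ssim <- simulate_sparse_gvar(n = 500, seed = 9)
  det <- detrend_standardize(ssim$panel)
  sat <- panelnets:::saturated_loglik(det)
  base <- panelnets:::independence_loglik(det)
  # a pseudo-model identical to the saturated reference: chi2 = 0, df = 0
  self <- list(loglik = sat$loglik, n_params = sat$n_params,
               n_persons = 500)
  fi <- fit_indices(self, det)
  expect_equal(fi$chi2, 0)
  expect_true(fi$rmsea_undefined)
  expect_equal(fi$rmsea, 0)
  expect_equal(fi$cfi, 1)
  # the independence model evaluated as the target model: CFI = 0
  ind <- list(loglik = base$loglik, n_params = base$n_params, n_persons = 500)
  fi0 <- fit_indices(ind, det)
  expect_equal(fi0$cfi, 0)
  expect_equal(fi0$chi2, fi0$chi2_baseline)
})

test_that("EM for the saturated moments matches complete-data moments", {
  set.seed(3)
  Y <- matrix(rnorm(300 * 4), 300)
  em <- panelnets:::em_mvnorm(Y)
  expect_equal(em$mu, colMeans(Y), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(em$Sigma, crossprod(sweep(Y, 2, colMeans(Y))) / 300,
               tolerance = 1e-8, ignore_attr = TRUE)
  # with MCAR holes, EM increases the likelihood over the start and stays PD
  Ym <- Y; Ym[sample(length(Ym), 200)] <- NA
  emm <- panelnets:::em_mvnorm(Ym)
  expect_gt(min(eigen(emm$Sigma, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_equal(emm$mu, colMeans(Y), tolerance = 0.15, ignore_attr = TRUE)
})
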