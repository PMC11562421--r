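# Shared fixtures: tiny panels and a hand-specified sparse GVAR truth used
# by the recovery and selection tests.

toy_panel <- function(values, wave_times = NULL, variables = NULL) {
  # values: list of n x p matrices, one per wave
  n <- nrow(values[[1]]); p <- ncol(values[[1]])
  arr <- array(NA_real_, dim = c(n, length(values), p))
  for (w in seq_along(values)) arr[, w, ] <- values[[w]]
  vars <- colnames(values[[1]]) %||% paste0("V", seq_len(p))
  long <- tidyr::expand_grid(person_id = sprintf("p%02d", seq_len(n)),
                             wave = seq_along(values), variable = vars)
  long$value <- arr[cbind(match(long$person_id, sprintf("p%02d", seq_len(n))),
                          long$wave, match(long$variable, vars))]
  panel_data(long, variables = variables, wave_times = wave_times)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Sparse ground truth with known zeros in all three networks: three temporal
# off-diagonal edges of |0.3|, two contemporaneous partials, two between
# partials. Everything else is a true zero, so selection error rates are
# well defined.
sparse_gvar_truth <- function() {
  p <- 4
  B <- diag(0.3, p)
  B[2, 1] <- 0.3; B[3, 2] <- 0.3; B[1, 4] <- -0.3
  K_zeta <- diag(p)
  K_zeta[1, 2] <- K_zeta[2, 1] <- -0.25
  K_zeta[3, 4] <- K_zeta[4, 3] <- -0.25
  K_B <- diag(2, p)
  K_B[1, 3] <- K_B[3, 1] <- -0.5
  K_B[2, 4] <- K_B[4, 2] <- -0.5
  labels <- paste0("V", 1:p)
  dimnames(B) <- dimnames(K_zeta) <- dimnames(K_B) <- list(labels, labels)
  structure(
    list(B = B, K_zeta = K_zeta, Sigma_B = solve(K_B),
         trend_lin = setNames(rep(0, p), labels),
         trend_quad = setNames(rep(0, p), labels),
         mu = setNames(rep(0, p), labels),
         variables = tibble::tibble(
           name = labels,
           community = rep(c("internalizing", "externalizing"), each = 2),
           instrument = NA_character_)),
    class = "ground_truth"
  )
}

simulate_sparse_gvar <- function(n = 2000, seed = 1, retention = c(1, 1, 1)) {
  truth <- sparse_gvar_truth()
  spec <- cohort_spec(n_persons = n, n_waves = 3, p = 4, retention = retention,
                      seed = seed)
  panel <- simulate_panel(truth, spec)
  if (any(retention < 1)) panel <- apply_attrition(panel, spec)
  list(truth = truth, spec = spec, panel = panel)
}

# Minimal cyclic coordinate descent for the LASSO, used only as a test
# oracle independent of the package's solver route.
coordinate_descent_lasso <- function(X, y, lambda, iters = 5000) {
  n <- nrow(X); p <- ncol(X)
  xc <- scale(X, scale = FALSE); yc <- y - mean(y)
  b <- rep(0, p)
  ss <- colSums(xc^2) / n
  for (it in seq_len(iters)) {
    b_old <- b
    for (j in seq_len(p)) {
      r <- yc - xc[, -j, drop = FALSE] %*% b[-j]
      u <- sum(xc[, j] * r) / n
      b[j] <- sign(u) * max(abs(u) - lambda, 0) / ss[j]
    }
    if (max(abs(b - b_old)) < 1e-12) break
  }
  b
}

# Exhaustive constrained-ML fit of a GGM support: maximize
# logdet K - tr(SK) over K with fixed zero pattern, via unconstrained optim
# on the free entries. Independent of the graphical-lasso code path.
fit_ggm_support_ml <- function(S, support) {
  p <- nrow(S)
  ut <- which(upper.tri(S), arr.ind = TRUE)
  free <- support  # logical over the upper-triangle pairs, in ut order
  build_K <- function(theta) {
    K <- diag(exp(theta[seq_len(p)]), p)
    off <- theta[-seq_len(p)]
    kk <- 1
    for (e in seq_len(nrow(ut))) {
      if (free[e]) {
        K[ut[e, 1], ut[e, 2]] <- K[ut[e, 2], ut[e, 1]] <- off[kk]
        kk <- kk + 1
      }
    }
    K
  }
  nll <- function(theta) {
    K <- build_K(theta)
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10) return(1e10)
    -(sum(log(ev)) - sum(S * K))
  }
  theta0 <- c(rep(0, p), rep(0, sum(free)))
  opt <- optim(theta0, nll, method = "BFGS", control = list(maxit = 2000, reltol = 1e-14))
  build_K(opt$par)
}
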