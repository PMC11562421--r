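# Panel graphical vector autoregression with random intercepts.
#
# Observed stacked-wave moments decompose as Cov(y_s, y_t) =
# Sigma_B + B^(s-t) Sigma_W (s >= t), where Sigma_B = K_B^-1 is the
# between-person (trait) covariance and Sigma_W solves the discrete Lyapunov
# equation Sigma_W = B Sigma_W B' + K_zeta^-1. Estimation is pattern-wise
# full-information maximum likelihood; the likelihood kernel lives in C++
# and a plain-R reference implementation backs the tests.

#' Construct panel GVAR parameters
#'
#' @param mu Mean per (wave, variable) cell: a `T x p` matrix.
#' @param B Temporal matrix; entry `(k, j)` is the effect of node `j` at
#'   wave `t` on node `k` at wave `t + 1`. Spectral radius must be < 1.
#' @param K_zeta Within-person contemporaneous precision (symmetric PD).
#' @param K_B Between-person precision (symmetric PD).
#' @param free_mask Optional list of logical matrices (`B`, `K_zeta`, `K_B`)
#'   marking free parameters; fixed entries must be exactly zero. Precision
#'   diagonals are always free.
#' @return A list of class `gvar_params`.
#' @export
gvar_params <- function(mu, B, K_zeta, K_B, free_mask = NULL) {
  p <- nrow(B)
  mu <- as.matrix(mu)
  if (ncol(mu) != p) abort("mu must be T x p")
  free_mask <- free_mask %||% list(
    B = matrix(TRUE, p, p),
    K_zeta = !diag(p) > 0,
    K_B = !diag(p) > 0
  )
  free_mask$K_zeta <- free_mask$K_zeta & !diag(p)
  free_mask$K_B <- free_mask$K_B & !diag(p)
  out <- structure(list(mu = mu, B = B, K_zeta = K_zeta, K_B = K_B,
                        free_mask = free_mask),
                   class = "gvar_params")
  validate_gvar_params(out)
  out
}

validate_gvar_params <- function(params) {
  if (spectral_radius(params$B) >= 1) {
    abort("temporal matrix is non-stationary (spectral radius >= 1)",
          class = "panelnets_stationarity_error")
  }
  for (nm in c("K_zeta", "K_B")) {
    K <- params[[nm]]
    if (max(abs(K - t(K))) > 1e-8) abort(sprintf("%s must be symmetric", nm))
    if (min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      abort(sprintf("%s must be positive-definite", nm))
    }
  }
  if (any(params$B[!params$free_mask$B] != 0) ||
      any(params$K_zeta[!(params$free_mask$K_zeta | diag(nrow(params$B)) > 0)] != 0) ||
      any(params$K_B[!(params$free_mask$K_B | diag(nrow(params$B)) > 0)] != 0)) {
    abort("fixed (masked) parameters must be exactly zero")
  }
  invisible(params)
}

#' Implied stacked-wave moments of a panel GVAR
#'
#' The within-process stationary covariance `Sigma_W` solves the discrete
#' Lyapunov equation `Sigma_W = B Sigma_W B' + K_zeta^-1`; the implied
#' covariance of the stacked wave-major observation vector has blocks
#' `Cov(y_{t+d}, y_t) = Sigma_B + B^d Sigma_W`.
#'
#' @param params A [gvar_params()] object.
#' @param n_waves Number of waves `T`.
#' @return A list with `mean` (length `T*p`), `cov` (`T*p x T*p`, symmetric
#'   PD), `Sigma_W` and `Sigma_B`.
#' @export
implied_moments <- function(params, n_waves) {
  if (spectral_radius(params$B) >= 1) {
    abort("spectral radius >= 1: no stationary solution",
          class = "panelnets_stationarity_error")
  }
  p <- nrow(params$B)
  Sigma_zeta <- chol2inv(chol(params$K_zeta))
  Sigma_W <- dlyap(params$B, Sigma_zeta)
  resid <- Sigma_W - (params$B %*% Sigma_W %*% t(params$B) + Sigma_zeta)
  stopifnot(norm(resid, "F") < 1e-8)
  Sigma_B <- chol2inv(chol(params$K_B))
  Bpow <- vector("list", n_waves)
  Bpow[[1]] <- diag(p)
  for (k in seq_len(n_waves - 1)) Bpow[[k + 1]] <- Bpow[[k]] %*% params$B
  cov <- matrix(0, n_waves * p, n_waves * p)
  for (t in seq_len(n_waves)) {
    for (s in t:n_waves) {
      blk <- Sigma_B + Bpow[[s - t + 1]] %*% Sigma_W
      rows <- (s - 1) * p + seq_len(p); cols <- (t - 1) * p + seq_len(p)
      cov[rows, cols] <- blk
      if (s != t) cov[cols, rows] <- t(blk)
    }
  }
  list(mean = as.vector(t(params$mu)), cov = sym_part(cov),
       Sigma_W = Sigma_W, Sigma_B = Sigma_B)
}

#' Full-information maximum likelihood log-likelihood
#'
#' Evaluates the Gaussian log-likelihood of a panel under the implied panel
#' GVAR moments, person by person on each person's observed cells only.
#' With complete data this equals the complete-data Gaussian
#' log-likelihood. This is the reference implementation; the optimizer uses
#' an equivalent compiled kernel over missingness-pattern sufficient
#' statistics.
#'
#' @param params A [gvar_params()] object.
#' @param panel A [panel_data()] object (detrended/standardized for the
#'   usual GVAR workflow, though any scale is accepted).
#' @return The log-likelihood (scalar).
#' @export
fiml_loglik <- function(params, panel) {
  mom <- implied_moments(params, n_waves(panel))
  Y <- stacked_matrix(panel)
  ll <- 0
  for (i in seq_len(nrow(Y))) {
    o <- which(!is.na(Y[i, ]))
    if (!length(o)) next
    So <- mom$cov[o, o, drop = FALSE]
    L <- tryCatch(chol(So), error = function(e) {
      abort(sprintf("singular observed submatrix for pattern of person %s", rownames(Y)[i]),
            class = "panelnets_conditioning_error")
    })
    d <- Y[i, o] - mom$mean[o]
    u <- backsolve(L, d, transpose = TRUE)
    ll <- ll - 0.5 * (length(o) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(u^2))
  }
  ll
}

# ---- parameter vector packing --------------------------------------------

gvar_masks_default <- function(p) {
  list(B = matrix(TRUE, p, p), K_zeta = !diag(p) > 0, K_B = !diag(p) > 0)
}

# Index bookkeeping for the theta vector; order must match the C++ kernel:
# mu (wave-major), B free entries (column-major), then per precision the p
# log-diagonal entries followed by free upper-triangle off-diagonals.
theta_layout <- function(p, Tn, masks, var_names = paste0("V", seq_len(p))) {
  mu_names <- paste0("mu[", rep(seq_len(Tn), each = p), ",", rep(var_names, Tn), "]")
  bidx <- which(masks$B)
  b_names <- sprintf("B[%s,%s]", var_names[row(masks$B)[bidx]], var_names[col(masks$B)[bidx]])
  prec_names <- function(mask, label) {
    ut <- which(upper.tri(mask) & mask)
    c(sprintf("%s[%s,%s]", label, var_names, var_names),
      sprintf("%s[%s,%s]", label, var_names[row(mask)[ut]], var_names[col(mask)[ut]]))
  }
  nm <- c(mu_names, b_names, prec_names(masks$K_zeta, "K_zeta"),
          prec_names(masks$K_B, "K_B"))
  n_mu <- p * Tn
  n_b <- length(bidx)
  n_kz <- p + sum(masks$K_zeta & upper.tri(masks$K_zeta))
  n_kb <- p + sum(masks$K_B & upper.tri(masks$K_B))
  list(
    names = nm,
    mu = seq_len(n_mu),
    B = n_mu + seq_len(n_b),
    K_zeta = n_mu + n_b + seq_len(n_kz),
    K_B = n_mu + n_b + n_kz + seq_len(n_kb),
    K_zeta_off = n_mu + n_b + p + seq_len(n_kz - p),
    K_B_off = n_mu + n_b + n_kz + p + seq_len(n_kb - p),
    is_network = c(rep(FALSE, n_mu), rep(TRUE, n_b),
                   rep(FALSE, p), rep(TRUE, n_kz - p),
                   rep(FALSE, p), rep(TRUE, n_kb - p)),
    n_total = n_mu + n_b + n_kz + n_kb
  )
}

pack_theta <- function(params, masks) {
  p <- nrow(params$B)
  pack_prec <- function(K, mask) {
    c(log(diag(K)), K[upper.tri(K) & mask])
  }
  c(as.vector(t(params$mu)),
    params$B[masks$B],
    pack_prec(params$K_zeta, masks$K_zeta),
    pack_prec(params$K_B, masks$K_B))
}

unpack_theta <- function(theta, p, Tn, masks, var_names = NULL) {
  var_names <- var_names %||% paste0("V", seq_len(p))
  pos <- 0L
  take <- function(k) { out <- theta[pos + seq_len(k)]; pos <<- pos + k; out }
  mu <- matrix(take(p * Tn), Tn, p, byrow = TRUE)
  B <- matrix(0, p, p)
  B[masks$B] <- take(sum(masks$B))
  rho <- spectral_radius(B)
  if (rho >= 0.99) B <- B * 0.989 / rho
  unpack_prec <- function(mask) {
    K <- diag(exp(take(p)), p)
    ut <- upper.tri(K) & mask
    K[ut] <- take(sum(ut))
    K[lower.tri(K)] <- t(K)[lower.tri(K)]
    K
  }
  K_zeta <- unpack_prec(masks$K_zeta)
  K_B <- unpack_prec(masks$K_B)
  dimnames(B) <- dimnames(K_zeta) <- dimnames(K_B) <- list(var_names, var_names)
  colnames(mu) <- var_names
  structure(list(mu = mu, B = B, K_zeta = K_zeta, K_B = K_B, free_mask = masks),
            class = "gvar_params")
}

masks_to_umat <- function(masks) {
  lapply(masks, function(m) matrix(as.integer(m), nrow(m)))
}

# ---- estimation -----------------------------------------------------------

# Moment-based starting values: between covariance from person means, B from
# pooled OLS of within deviations, residual covariance for the innovations.
moment_init <- function(panel, masks) {
  v <- panel$values
  p <- n_vars(panel); Tn <- n_waves(panel)
  mu0 <- t(apply(v, c(2, 3), mean, na.rm = TRUE))  # p x T -> transpose later
  mu0 <- t(mu0)
  bbar <- apply(v, c(1, 3), mean, na.rm = TRUE)
  SB0 <- stats::cov(bbar, use = "pairwise.complete.obs")
  SB0 <- pd_floor(SB0)
  d <- v - aperm(array(bbar, dim = c(dim(v)[1], p, Tn)), c(1, 3, 2))
  D1 <- NULL; D2 <- NULL
  for (t in seq_len(Tn - 1)) {
    D1 <- rbind(D1, d[, t, ]); D2 <- rbind(D2, d[, t + 1, ])
  }
  ok <- complete.cases(D1) & complete.cases(D2)
  B0 <- matrix(0, p, p)
  Sz0 <- diag(p)
  if (sum(ok) > p + 2) {
    A <- solve(crossprod(D1[ok, , drop = FALSE]) + 1e-6 * diag(p),
               crossprod(D1[ok, , drop = FALSE], D2[ok, , drop = FALSE]))
    B0 <- t(A)
    R <- D2[ok, , drop = FALSE] - D1[ok, , drop = FALSE] %*% A
    Sz0 <- pd_floor(stats::cov(R))
  }
  rho <- spectral_radius(B0)
  if (rho > 0.8) B0 <- B0 * 0.8 / rho
  B0[!masks$B] <- 0
  Kz0 <- chol2inv(chol(Sz0)); Kz0[!(masks$K_zeta | diag(p) > 0)] <- 0
  KB0 <- chol2inv(chol(SB0)); KB0[!(masks$K_B | diag(p) > 0)] <- 0
  list(mu = mu0, B = B0, K_zeta = pd_floor(sym_part(Kz0)),
       K_B = pd_floor(sym_part(KB0)), free_mask = masks)
}

pd_floor <- function(S, floor_frac = 0.05) {
  S <- sym_part(as.matrix(S))
  S[is.na(S)] <- 0
  e <- eigen(S, symmetric = TRUE)
  fl <- floor_frac * max(mean(abs(e$values)), 1e-3)
  vals <- pmax(e$values, fl)
  sym_part(e$vectors %*% (vals * t(e$vectors)))
}

#' Fit a panel GVAR by full-information maximum likelihood
#'
#' Maximizes the pattern-wise FIML likelihood over the free parameters
#' (means per wave-variable cell, temporal matrix, both precisions) using an
#' unconstrained parameterization: precision diagonals through their logs,
#' stationarity through spectral rescaling of the temporal matrix inside the
#' objective. A moment-based start plus `starts - 1` seeded perturbed starts
#' are run and the best optimum kept. Convergence requires the max-norm of
#' the per-person average score to fall below `grad_tol`.
#'
#' @param panel A [panel_data()] object, normally the output of
#'   [detrend_standardize()].
#' @param mask Optional free-parameter mask list (`B`, `K_zeta`, `K_B`);
#'   default saturated (all network parameters free).
#' @param starts Number of optimization starts (default 3).
#' @param seed Seed for the perturbed starts.
#' @param grad_tol Convergence tolerance on the per-person score (default
#'   `1e-5`).
#' @param max_rounds Maximum successive BFGS rounds per start.
#' @param warm_theta Optional starting parameter vector (used internally by
#'   the prune/step-up search).
#' @return An object of class `panel_gvar` with the fitted [gvar_params()],
#'   `loglik`, `n_params`, convergence diagnostics, and the theta
#'   bookkeeping reused by [prune_stepup()] and [fit_indices()].
#' @export
fit_panel_gvar <- function(panel, mask = NULL, starts = 3, seed = 1,
                           grad_tol = 1e-5, max_rounds = 6, warm_theta = NULL) {
  p <- n_vars(panel); Tn <- n_waves(panel)
  n <- n_persons(panel)
  if (n < 10 * p) warn(sprintf("n = %d is small for p = %d (fewer than 10 persons per node)", n, p))
  masks <- mask %||% gvar_masks_default(p)
  masks$K_zeta <- masks$K_zeta & !diag(p); masks$K_B <- masks$K_B & !diag(p)
  layout <- theta_layout(p, Tn, masks, panel$variables$name)
  stats_list <- unname(pattern_suffstats(stacked_matrix(panel)))
  um <- masks_to_umat(masks)
  fn <- function(th) gvar_negloglik_cpp(th, p, Tn, um$B, um$K_zeta, um$K_B, stats_list)
  gr <- function(th) gvar_negloglik_grad_cpp(th, p, Tn, um$B, um$K_zeta, um$K_B, stats_list)

  init <- moment_init(panel, masks)
  theta0 <- warm_theta %||% pack_theta(init, masks)
  best <- NULL
  n_starts <- if (!is.null(warm_theta)) 1L else starts
  for (s in seq_len(n_starts)) {
    th <- if (s == 1) theta0 else {
      with_seed(derive_seed(seed, "start", s), theta0 + rnorm(length(theta0), sd = 0.05))
    }
    val <- fn(th)
    grad_norm <- Inf
    for (round in seq_len(max_rounds)) {
      opt <- optim(th, fn, gr, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-13))
      th <- opt$par; val <- opt$value
      grad_norm <- max(abs(gr(th))) / n
      if (grad_norm < grad_tol) break
    }
    if (is.null(best) || val < best$value) {
      best <- list(par = th, value = val, grad_norm = grad_norm,
                   converged = grad_norm < grad_tol)
    }
  }
  if (!best$converged) {
    abort(sprintf(paste0("panel GVAR did not converge after %d start(s): ",
                         "best per-person score max-norm %.2e (negloglik %.4f)"),
                  n_starts, best$grad_norm, best$value),
          class = "panelnets_convergence_error")
  }
  params <- unpack_theta(best$par, p, Tn, masks, panel$variables$name)
  structure(
    list(params = params, theta = best$par, layout = layout, masks = masks,
         loglik = -best$value, n_persons = n,
         n_params = layout$n_total,
         grad_norm = best$grad_norm, converged = best$converged,
         dims = list(p = p, n_waves = Tn), variables = panel$variables,
         stats = stats_list, seed = seed),
    class = "panel_gvar"
  )
}

#' @export
print.panel_gvar <- function(x, ...) {
  cat(sprintf("<panel_gvar> p = %d nodes, %d waves, n = %d persons\n",
              x$dims$p, x$dims$n_waves, x$n_persons))
  cat(sprintf("  logLik %.3f with %d free parameters (score max-norm %.1e)\n",
              x$loglik, x$n_params, x$grad_norm))
  if (!is.null(x$prune_trace)) {
    cat(sprintf("  pruned/step-up searched: %d decisions recorded\n", nrow(x$prune_trace)))
  }
  invisible(x)
}

#' Extract the three networks of a fitted panel GVAR
#'
#' `temporal_network()` returns the lag-1 matrix in `(from, to)` orientation
#' (`net[j, k]` = effect of node `j` on node `k` at the next wave, i.e. the
#' transpose of the internal `B`); `contemporaneous_network()` and
#' `between_network()` return partial-correlation matrices derived from the
#' within and between precision matrices.
#'
#' @param fit A `panel_gvar` object.
#' @return A `p x p` matrix.
#' @export
temporal_network <- function(fit) t(fit$params$B)

#' @rdname temporal_network
#' @export
contemporaneous_network <- function(fit) precision_to_pcor(fit$params$K_zeta)

#' @rdname temporal_network
#' @export
between_network <- function(fit) precision_to_pcor(fit$params$K_B)

#' @export
tidy.panel_gvar <- function(x, network = c("temporal", "contemporaneous", "between"),
                            all_edges = FALSE, ...) {
  network <- match.arg(network)
  m <- switch(network,
              temporal = temporal_network(x),
              contemporaneous = contemporaneous_network(x),
              between = between_network(x))
  nm <- rownames(m)
  if (network == "temporal") {
    out <- tibble(from = rep(nm, times = ncol(m)), to = rep(nm, each = nrow(m)),
                  weight = as.vector(m), network = network)
  } else {
    ut <- which(upper.tri(m), arr.ind = TRUE)
    out <- tibble(from = nm[ut[, 1]], to = nm[ut[, 2]],
                  weight = m[ut], network = network)
  }
  if (!all_edges) out <- dplyr::filter(out, abs(.data$weight) > 1e-10)
  out
}

#' @export
glance.panel_gvar <- function(x, ...) {
  tibble(loglik = x$loglik, n_params = x$n_params, n_persons = x$n_persons,
         p = x$dims$p, n_waves = x$dims$n_waves,
         converged = x$converged, grad_norm = x$grad_norm,
         pruned = !is.null(x$prune_trace))
}

# ---- reference models and fit indices ------------------------------------

# EM for an unstructured multivariate normal under arbitrary missingness.
em_mvnorm <- function(Y, max_iter = 500, tol = 1e-7) {
  d <- ncol(Y)
  obs <- !is.na(Y)
  keep <- rowSums(obs) > 0
  Y <- Y[keep, , drop = FALSE]; obs <- obs[keep, , drop = FALSE]
  n <- nrow(Y)
  mu <- colMeans(Y, na.rm = TRUE); mu[is.na(mu)] <- 0
  S <- stats::cov(Y, use = "pairwise.complete.obs")
  S[is.na(S)] <- 0
  Sigma <- pd_floor(S, 0.01)
  patterns <- split(seq_len(n), apply(obs, 1, paste, collapse = ""))
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    sum_y <- numeric(d)
    sum_yy <- matrix(0, d, d)
    ll <- 0
    for (rows in patterns) {
      o <- which(obs[rows[1], ]); m <- which(!obs[rows[1], ])
      Yo <- Y[rows, o, drop = FALSE]
      So <- Sigma[o, o, drop = FALSE]
      L <- chol(So)
      dmat <- sweep(Yo, 2, mu[o])
      u <- backsolve(L, t(dmat), transpose = TRUE)
      ll <- ll - 0.5 * (length(rows) * (length(o) * log(2 * pi) + 2 * sum(log(diag(L)))) +
                          sum(u^2))
      Ey <- matrix(0, length(rows), d)
      Ey[, o] <- Yo
      C <- matrix(0, d, d)
      if (length(m)) {
        A <- Sigma[m, o, drop = FALSE] %*% chol2inv(L)  # Sigma_mo Sigma_oo^-1
        Ey[, m] <- matrix(mu[m], length(rows), length(m), byrow = TRUE) +
          dmat %*% t(A)
        C[m, m] <- Sigma[m, m, drop = FALSE] - A %*% Sigma[o, m, drop = FALSE]
      }
      sum_y <- sum_y + colSums(Ey)
      sum_yy <- sum_yy + crossprod(Ey) + length(rows) * C
    }
    mu_new <- sum_y / n
    Sigma_new <- sym_part(sum_yy / n - tcrossprod(mu_new))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      mu <- mu_new; Sigma <- Sigma_new
      break
    }
    ll_old <- ll
    mu <- mu_new; Sigma <- pd_floor(Sigma_new, 1e-8)
  }
  list(mu = mu, Sigma = Sigma, loglik = ll, n = n, iterations = iter)
}

# Saturated (unstructured mean + covariance) FIML log-likelihood.
saturated_loglik <- function(panel) {
  Y <- stacked_matrix(panel)
  em <- em_mvnorm(Y)
  stats_list <- unname(pattern_suffstats(Y))
  ll <- -mvn_negloglik_cpp(em$mu, pd_floor(em$Sigma, 1e-10), stats_list)
  d <- ncol(Y)
  list(loglik = ll, n_params = d + d * (d + 1) / 2, n = em$n)
}

# Independence model (free means, diagonal covariance): the likelihood
# factorizes over cells, so the MLE is the per-cell observed mean/variance.
independence_loglik <- function(panel) {
  Y <- stacked_matrix(panel)
  ll <- 0
  for (j in seq_len(ncol(Y))) {
    y <- Y[!is.na(Y[, j]), j]
    v <- mean((y - mean(y))^2)
    ll <- ll + sum(stats::dnorm(y, mean(y), sqrt(v), log = TRUE))
  }
  list(loglik = ll, n_params = 2 * ncol(Y))
}

#' Chi-square based fit indices for a fitted panel GVAR
#'
#' Compares the model to the saturated reference (free means and
#' unstructured covariance, fitted by FIML via EM) and the independence
#' baseline (free means, diagonal covariance):
#' `chi2 = 2 (logL_sat - logL_model)`, `RMSEA =
#' sqrt(max(0, (chi2 - df) / (df * n)))`, `CFI` and `TLI` from the baseline
#' comparison, capped at 1.
#'
#' @param fit A `panel_gvar` object.
#' @param panel The panel it was fitted to.
#' @return A list of class `gvar_fit` with `loglik`, `n_params`, `chi2`,
#'   `df`, `rmsea`, `cfi`, `tli` and a `rmsea_undefined` flag (df = 0).
#' @export
fit_indices <- function(fit, panel) {
  sat <- saturated_loglik(panel)
  base <- independence_loglik(panel)
  chi2 <- max(0, 2 * (sat$loglik - fit$loglik))
  df <- sat$n_params - fit$n_params
  if (df < 0) abort("model has more parameters than the saturated reference")
  chi2_b <- max(0, 2 * (sat$loglik - base$loglik))
  df_b <- sat$n_params - base$n_params
  n <- fit$n_persons
  rmsea_undefined <- df == 0
  rmsea <- if (rmsea_undefined) 0 else sqrt(max(0, (chi2 - df) / (df * n)))
  cfi <- 1 - max(0, chi2 - df) / max(max(0, chi2_b - df_b), .Machine$double.eps)
  cfi <- min(max(cfi, 0), 1)
  tli <- if (df > 0 && df_b > 0 && (chi2_b / df_b) > 1) {
    ((chi2_b / df_b) - (chi2 / df)) / ((chi2_b / df_b) - 1)
  } else 1
  tli <- min(tli, 1)
  structure(
    list(loglik = fit$loglik, n_params = fit$n_params, chi2 = chi2, df = df,
         rmsea = rmsea, cfi = cfi, tli = tli, rmsea_undefined = rmsea_undefined,
         chi2_baseline = chi2_b, df_baseline = df_b,
         loglik_saturated = sat$loglik, n = n),
    class = "gvar_fit"
  )
}

#' @export
print.gvar_fit <- function(x, ...) {
  cat(sprintf("chi2(%d) = %.3f, RMSEA = %.3f, CFI = %.3f, TLI = %.3f\n",
              x$df, x$chi2, x$rmsea, x$cfi, x$tli))
  invisible(x)
}

#' @export
glance.gvar_fit <- function(x, ...) {
  tibble(chi2 = x$chi2, df = x$df, rmsea = x$rmsea, cfi = x$cfi, tli = x$tli,
         loglik = x$loglik, n_params = x$n_params, n = x$n)
}

# ---- prune + step-up model search ----------------------------------------

safe_solve <- function(H) {
  out <- tryCatch(solve(H), error = function(e) NULL)
  if (!is.null(out)) return(out)
  s <- svd(H)
  pos <- s$d > max(s$d) * 1e-10
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Prune a saturated panel GVAR and search step-up
#'
#' Stage 1 fixes to zero every free network parameter (temporal entries and
#' off-diagonal precision entries) whose Wald test, using observed-information
#' standard errors, is non-significant at `alpha`, then refits. Stage 2
#' repeatedly frees the fixed parameter with the largest significant
#' score-test (modification-index) statistic and refits, until no candidate
#' reaches `alpha`; a final Wald pass then removes parameters that lost
#' significance during the search. A parameter pruned and re-added twice
#' terminates the search with a warning (oscillation guard). Every decision
#' is recorded.
#'
#' @param fit A converged saturated `panel_gvar`.
#' @param panel The panel it was fitted to.
#' @param alpha Significance level (default 0.05).
#' @param max_steps Cap on step-up iterations.
#' @return A `panel_gvar` for the pruned model, with `$prune_trace` (a
#'   tibble of decisions) and `$wald` (the stage-1 Wald table).
#' @export
prune_stepup <- function(fit, panel, alpha = 0.05, max_steps = 25) {
  if (!fit$converged) abort("prune_stepup needs a converged fit")
  p <- fit$dims$p; Tn <- fit$dims$n_waves
  um <- masks_to_umat(fit$masks)
  H <- gvar_negloglik_hess_cpp(fit$theta, p, Tn, um$B, um$K_zeta, um$K_B, fit$stats)
  V <- safe_solve(H)
  se <- sqrt(pmax(diag(V), 0))
  z <- fit$theta / pmax(se, 1e-12)
  pval <- 2 * pnorm(-abs(z))
  net <- fit$layout$is_network
  wald <- tibble(parameter = fit$layout$names, estimate = fit$theta,
                 se = se, z = z, p_value = pval, network = net)
  drop <- which(net & pval >= alpha)
  trace <- tibble(step = 0L, action = "prune",
                  parameter = fit$layout$names[drop],
                  statistic = z[drop]^2, p_value = pval[drop])
  masks <- remove_params(fit$masks, fit$layout$names[drop], fit$variables$name)
  theta_warm <- fit$theta[-drop]
  if (!length(drop)) { masks <- fit$masks; theta_warm <- fit$theta }
  cur <- fit_panel_gvar(panel, mask = masks, warm_theta = theta_warm, seed = fit$seed)

  added <- character(); pruned_names <- fit$layout$names[drop]
  add_count <- integer()
  step <- 0L
  while (step < max_steps) {
    step <- step + 1L
    mi <- modification_indices(cur, p, Tn)
    cand <- mi[mi$p_value < alpha, , drop = FALSE]
    if (!nrow(cand)) break
    cand <- cand[order(-cand$statistic, cand$parameter), , drop = FALSE]
    pick <- cand$parameter[1]
    add_count[pick] <- (if (is.na(add_count[pick])) 0L else add_count[pick]) + 1L
    if (pick %in% pruned_names && add_count[pick] >= 2L) {
      warn(sprintf("step-up oscillation on %s; terminating search", pick))
      break
    }
    trace <- dplyr::bind_rows(trace, tibble(step = step, action = "add",
                                            parameter = pick,
                                            statistic = cand$statistic[1],
                                            p_value = cand$p_value[1]))
    masks <- add_param(cur$masks, pick, cur$variables$name)
    lay_new <- theta_layout(p, Tn, masks, cur$variables$name)
    theta_new <- numeric(lay_new$n_total)
    theta_new[match(cur$layout$names, lay_new$names)] <- cur$theta
    cur <- fit_panel_gvar(panel, mask = masks, warm_theta = theta_new, seed = fit$seed)
  }
  # final re-prune: parameters that lost significance during the search are
  # removed once more (recursive pruning keeps the false-retention rate near
  # the nominal level)
  um2 <- masks_to_umat(cur$masks)
  H2 <- gvar_negloglik_hess_cpp(cur$theta, p, Tn, um2$B, um2$K_zeta, um2$K_B, cur$stats)
  V2 <- safe_solve(H2)
  se2 <- sqrt(pmax(diag(V2), 0))
  z2 <- cur$theta / pmax(se2, 1e-12)
  p2 <- 2 * pnorm(-abs(z2))
  drop2 <- which(cur$layout$is_network & p2 >= alpha)
  if (length(drop2)) {
    trace <- dplyr::bind_rows(trace, tibble(step = step + 1L, action = "prune",
                                            parameter = cur$layout$names[drop2],
                                            statistic = z2[drop2]^2,
                                            p_value = p2[drop2]))
    masks2 <- remove_params(cur$masks, cur$layout$names[drop2], cur$variables$name)
    cur <- fit_panel_gvar(panel, mask = masks2, warm_theta = cur$theta[-drop2],
                          seed = fit$seed)
  }
  cur$prune_trace <- trace
  cur$wald <- wald
  cur$alpha <- alpha
  cur
}

# Score tests (modification indices) for currently fixed network parameters,
# computed from the full-parameterization gradient and observed information
# at the restricted optimum: MI_j = g_j^2 / (H_jj - H_jF H_FF^-1 H_Fj).
modification_indices <- function(fit, p, Tn) {
  full_masks <- gvar_masks_default(p)
  lay_full <- theta_layout(p, Tn, full_masks, fit$variables$name)
  theta_full <- numeric(lay_full$n_total)
  theta_full[match(fit$layout$names, lay_full$names)] <- fit$theta
  um <- masks_to_umat(full_masks)
  g <- gvar_negloglik_grad_cpp(theta_full, p, Tn, um$B, um$K_zeta, um$K_B, fit$stats)
  H <- gvar_negloglik_hess_cpp(theta_full, p, Tn, um$B, um$K_zeta, um$K_B, fit$stats)
  free_idx <- match(fit$layout$names, lay_full$names)
  cand_idx <- setdiff(which(lay_full$is_network), free_idx)
  if (!length(cand_idx)) {
    return(tibble(parameter = character(), statistic = numeric(), p_value = numeric()))
  }
  Hff_inv_Hfc <- safe_solve(H[free_idx, free_idx, drop = FALSE]) %*%
    H[free_idx, cand_idx, drop = FALSE]
  denom <- diag(H[cand_idx, cand_idx, drop = FALSE]) -
    colSums(H[free_idx, cand_idx, drop = FALSE] * Hff_inv_Hfc)
  stat <- ifelse(denom > 1e-10, g[cand_idx]^2 / denom, 0)
  tibble(parameter = lay_full$names[cand_idx], statistic = stat,
         p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

parse_param_name <- function(name, var_names) {
  m <- regmatches(name, regexec("^(B|K_zeta|K_B)\\[([^,]+),([^]]+)\\]$", name))[[1]]
  list(what = m[2], i = match(m[3], var_names), j = match(m[4], var_names))
}

remove_params <- function(masks, names_drop, var_names) {
  for (nm in names_drop) {
    info <- parse_param_name(nm, var_names)
    if (is.na(info$i) || is.na(info$j)) abort(sprintf("cannot parse parameter '%s'", nm))
    if (info$what == "B") {
      masks$B[info$i, info$j] <- FALSE
    } else {
      masks[[info$what]][info$i, info$j] <- FALSE
      masks[[info$what]][info$j, info$i] <- FALSE
    }
  }
  masks
}

add_param <- function(masks, name, var_names) {
  info <- parse_param_name(name, var_names)
  if (is.na(info$i) || is.na(info$j)) abort(sprintf("cannot parse parameter '%s'", name))
  if (info$what == "B") {
    masks$B[info$i, info$j] <- TRUE
  } else {
    masks[[info$what]][info$i, info$j] <- TRUE
    masks[[info$what]][info$j, info$i] <- TRUE
  }
  masks
}
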