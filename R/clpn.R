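# Cross-lagged panel networks: node-wise LASSO regressions between two
# consecutive waves, penalty chosen per outcome by k-fold cross-validation.

#' Fit one LASSO node regression
#'
#' Minimizes `(1/2n) * ||y - b0 - X b||^2 + lambda * ||b||_1`. The penalized
#' solve is delegated to glmnet; the unpenalized limit (`lambda = 0`) is the
#' exact least-squares solution.
#'
#' @param X Predictor matrix (columns standardized: mean 0, SD 1).
#' @param y Outcome vector.
#' @param lambda Non-negative penalty.
#' @return A list with `coef` (named vector), `intercept` and `lambda`.
#'   Coefficients shrunk to zero are exact zeros.
#' @export
fit_node_lasso <- function(X, y, lambda) {
  X <- as.matrix(X)
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) || lambda < 0) {
    abort("lambda must be a single non-negative number", class = "panelnets_domain_error")
  }
  if (anyNA(X) || anyNA(y) || !all(is.finite(X)) || !all(is.finite(y))) {
    abort("non-finite values in X or y", class = "panelnets_validation_error")
  }
  n <- length(y)
  if (nrow(X) != n) abort("nrow(X) must equal length(y)")
  if (n <= 2) abort("need n > 2")
  cn <- colnames(X) %||% paste0("x", seq_len(ncol(X)))

  if (lambda == 0) {
    fit <- lm.fit(cbind(`(Intercept)` = 1, X), y)
    b <- fit$coefficients
    b[is.na(b)] <- 0
    return(list(coef = setNames(b[-1], cn), intercept = unname(b[1]), lambda = 0))
  }
  if (ncol(X) == 1L) {
    # glmnet needs >= 2 columns; the single-predictor solution is closed form
    xc <- X[, 1] - mean(X[, 1]); yc <- y - mean(y)
    num <- sum(xc * yc) / n
    beta <- sign(num) * max(abs(num) - lambda, 0) / (sum(xc^2) / n)
    return(list(coef = setNames(beta, cn),
                intercept = mean(y) - beta * mean(X[, 1]), lambda = lambda))
  }
  lambda_max <- max(abs(crossprod(X, y - mean(y))) / n, lambda * 1.001, 1e-4)
  path <- sort(unique(c(exp(seq(log(lambda_max), log(max(lambda, 1e-8)), length.out = 30)),
                        lambda)), decreasing = TRUE)
  g <- glmnet::glmnet(X, y, family = "gaussian", alpha = 1, lambda = path,
                      standardize = FALSE, intercept = TRUE, thresh = 1e-12)
  # read the exact path member: coef(s = ...) interpolates and would turn
  # exact zeros into numerical dust
  i <- which.min(abs(g$lambda - lambda))
  stopifnot(abs(g$lambda[i] - lambda) < 1e-10 * max(1, lambda))
  b <- as.numeric(g$beta[, i])
  b[abs(b) < 1e-12] <- 0  # shrunk-to-zero entries are stored as exact zeros
  list(coef = setNames(b, cn), intercept = unname(g$a0[i]), lambda = lambda)
}

# KKT residual of the LASSO solution; used by tests and diagnostics.
lasso_kkt_gap <- function(X, y, fit, lambda) {
  n <- length(y)
  r <- y - fit$intercept - as.matrix(X) %*% fit$coef
  grad <- as.numeric(crossprod(as.matrix(X), r)) / n
  zero <- fit$coef == 0
  gap_zero <- if (any(zero)) max(pmax(abs(grad[zero]) - lambda, 0)) else 0
  gap_act <- if (any(!zero)) max(abs(grad[!zero] - lambda * sign(fit$coef[!zero]))) else 0
  max(gap_zero, gap_act)
}

#' Select the LASSO penalty by k-fold cross-validation
#'
#' Rows are randomly partitioned into `k` near-equal folds (seeded); for each
#' penalty on the grid the out-of-fold mean squared error is averaged.
#' `rule = "1se"` (the default) picks the sparsest (largest) penalty within
#' one standard error of the minimum mean MSE — the parsimony convention
#' that keeps false-positive edges near zero under a null; `rule = "min"`
#' picks the minimizer itself.
#'
#' @param X,y Standardized predictors and outcome.
#' @param k Number of folds (default 10).
#' @param grid Descending positive penalty grid; defaults to 100 log-spaced
#'   values from the smallest all-zero penalty down to 0.1% of it.
#' @param rule `"1se"` (default) or `"min"`.
#' @param seed Fold-assignment seed (required for reproducibility).
#' @return A list of class `cv_lasso`: `lambda_grid`, `fold_mse`
#'   (grid x fold), `selected` (index), `lambda_selected`, `rule`, `seed`.
#' @export
select_lambda_cv <- function(X, y, k = 10, grid = NULL, rule = c("1se", "min"),
                             seed = 20230101) {
  rule <- match.arg(rule)
  X <- as.matrix(X)
  n <- length(y)
  if (k < 2 || k > n) abort("need n >= k >= 2", class = "panelnets_domain_error")
  if (is.null(grid)) {
    lambda_max <- max(abs(crossprod(X, y - mean(y))) / n, 1e-4)
    grid <- exp(seq(log(lambda_max), log(0.001 * lambda_max), length.out = 100))
  }
  grid <- sort(unique(as.numeric(grid)), decreasing = TRUE)
  if (!length(grid) || any(grid <= 0) || anyNA(grid)) {
    abort("penalty grid must be non-empty and strictly positive",
          class = "panelnets_domain_error")
  }
  folds <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  fold_mse <- matrix(NA_real_, length(grid), k)
  for (f in seq_len(k)) {
    tr <- folds != f
    if (ncol(X) >= 2L) {
      # one glmnet call per fold over the whole path
      g <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], family = "gaussian",
                          alpha = 1, lambda = grid, standardize = FALSE,
                          intercept = TRUE, thresh = 1e-10)
      # predict from the fitted path members directly (predict(s = ...)
      # interpolates, which both warns and blurs exact path values)
      idx <- vapply(grid, function(l) which.min(abs(g$lambda - l)), 0L)
      pred <- sweep(X[!tr, , drop = FALSE] %*% as.matrix(g$beta[, idx, drop = FALSE]),
                    2L, g$a0[idx], `+`)
    } else {
      fits <- lapply(grid, function(l) fit_node_lasso(X[tr, , drop = FALSE], y[tr], l))
      pred <- vapply(fits, function(ft) {
        as.numeric(ft$intercept + X[!tr, , drop = FALSE] %*% ft$coef)
      }, numeric(sum(!tr)))
      if (sum(!tr) == 1L) pred <- matrix(pred, nrow = 1L)
    }
    fold_mse[, f] <- colMeans((pred - y[!tr])^2)
  }
  mean_mse <- rowMeans(fold_mse)
  i_min <- which.min(mean_mse)
  selected <- if (rule == "min") {
    i_min
  } else {
    se_min <- sd(fold_mse[i_min, ]) / sqrt(k)
    min(which(mean_mse <= mean_mse[i_min] + se_min))  # grid is descending
  }
  structure(
    list(lambda_grid = grid, fold_mse = fold_mse, mean_mse = mean_mse,
         selected = selected, lambda_selected = grid[selected],
         rule = rule, seed = seed),
    class = "cv_lasso"
  )
}

#' Estimate a cross-lagged panel network between two consecutive waves
#'
#' For each of the `p` outcome nodes at wave `t`, one LASSO regression on all
#' `p` wave-`s` nodes is fitted on the complete-case wave-pair sample, each
#' with its own cross-validation-selected penalty. The diagonal of the
#' weight matrix carries the autoregressive effects; off-diagonals are the
#' cross-lagged edges, with weak coefficients shrunk exactly to zero.
#' Predictors (and, by default, outcomes) are standardized on the
#' complete-case sample so edge weights are comparable in magnitude.
#'
#' @param panel A [panel_data()] object.
#' @param s,t Consecutive wave indices (`t = s + 1`).
#' @param folds Cross-validation folds (default 10).
#' @param rule Penalty selection rule, `"1se"` (default) or `"min"`.
#' @param seed Fold-assignment seed.
#' @param standardize_outcome Standardize outcomes as well as predictors
#'   (default `TRUE`).
#' @param grid Optional shared penalty grid.
#' @return An object of class `clpn` with `weights` (entry `(j, k)` = effect
#'   of predictor node `j` at wave `s` on node `k` at wave `t`), `lambdas`,
#'   `n_used`, `wave_pair` and per-outcome CV results.
#' @export
estimate_clpn <- function(panel, s = 1, t = s + 1, folds = 10,
                          rule = c("1se", "min"), seed = 20230101,
                          standardize_outcome = TRUE, grid = NULL) {
  rule <- match.arg(rule)
  if (t != s + 1) abort("CLPN is defined for consecutive waves (t = s + 1)")
  cc <- wave_pair_complete_cases(panel, s, t)
  X <- scale(cc$X)
  p <- ncol(X)
  vars <- panel$variables$name
  weights <- matrix(0, p, p, dimnames = list(vars, vars))
  lambdas <- setNames(numeric(p), vars)
  cv_list <- vector("list", p)
  for (kk in seq_len(p)) {
    y <- cc$Y[, kk]
    if (standardize_outcome) y <- as.numeric(scale(y))
    # fold seed keyed by the outcome node's name, so relabeling nodes
    # permutes the estimate exactly (equivariance)
    cv <- select_lambda_cv(X, y, k = folds, grid = grid, rule = rule,
                           seed = derive_seed(seed, "clpn", s, t, vars[kk]))
    fit <- fit_node_lasso(X, y, cv$lambda_selected)
    weights[, kk] <- fit$coef
    lambdas[kk] <- cv$lambda_selected
    cv_list[[kk]] <- cv
  }
  structure(
    list(weights = weights, wave_pair = c(s, t), lambdas = lambdas,
         n_used = nrow(X), cv = cv_list, rule = rule, seed = seed,
         variables = panel$variables),
    class = "clpn"
  )
}

#' @export
print.clpn <- function(x, ...) {
  cat(sprintf("<clpn> waves %d -> %d, n = %d\n", x$wave_pair[1], x$wave_pair[2], x$n_used))
  nz <- sum(x$weights[row(x$weights) != col(x$weights)] != 0)
  cat(sprintf("  cross-lagged edges retained: %d of %d\n", nz, length(x$weights) - nrow(x$weights)))
  invisible(x)
}

#' Tidy a cross-lagged panel network into an edge list
#'
#' @param x A `clpn` object.
#' @param all_edges Include exact-zero edges (default `FALSE`).
#' @param ... Unused.
#' @return A tibble with `from`, `to`, `weight`, `autoregressive`,
#'   `wave_from`, `wave_to`.
#' @export
tidy.clpn <- function(x, all_edges = FALSE, ...) {
  w <- x$weights
  out <- tibble(
    from = rep(rownames(w), times = ncol(w)),
    to = rep(colnames(w), each = nrow(w)),
    weight = as.vector(w),
    autoregressive = rep(seq_len(nrow(w)), times = ncol(w)) ==
      rep(seq_len(ncol(w)), each = nrow(w)),
    wave_from = x$wave_pair[1], wave_to = x$wave_pair[2]
  )
  if (!all_edges) out <- dplyr::filter(out, .data$weight != 0)
  out
}

#' @export
glance.clpn <- function(x, ...) {
  offdiag <- x$weights[row(x$weights) != col(x$weights)]
  tibble(
    n_used = x$n_used, wave_from = x$wave_pair[1], wave_to = x$wave_pair[2],
    n_edges = sum(offdiag != 0), sparsity = mean(offdiag == 0),
    mean_autoregressive = mean(diag(x$weights)), cv_rule = x$rule
  )
}
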