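# Cross-sectional Gaussian graphical models: graphical-lasso path with
# extended-BIC model selection (hyperparameter 0.5 by default).

#' Graphical lasso for one penalty
#'
#' Maximizes `log det K - trace(S K) - lambda * ||K||_1(offdiag)` by block
#' coordinate descent over the columns of the covariance estimate, with an
#' inner soft-thresholding coordinate descent for each column's LASSO
#' subproblem. The diagonal is unpenalized. Convergence is certified by the
#' duality gap `trace(S K) + lambda * ||K||_1(offdiag) - p`.
#'
#' @param S Symmetric positive semi-definite sample covariance/correlation
#'   matrix.
#' @param lambda Non-negative penalty on off-diagonal precision entries.
#' @param max_iter Maximum outer sweeps.
#' @param gap_tol Duality-gap tolerance (default `1e-6`).
#' @param warm Optional warm-start list (`W`, `Beta`) from a neighbouring
#'   penalty on a path.
#' @return A list with `precision` (positive definite), `W` (its inverse,
#'   the dual covariance estimate), `gap` and `iterations`.
#' @export
glasso_fit <- function(S, lambda, max_iter = 500, gap_tol = 1e-6, warm = NULL) {
  S <- as.matrix(S)
  if (!is_square(S) || max(abs(S - t(S))) > 1e-8) abort("S must be symmetric")
  if (lambda < 0) abort("lambda must be >= 0", class = "panelnets_domain_error")
  p <- nrow(S)
  if (lambda == 0) {
    K <- tryCatch(chol2inv(chol(S)),
                  error = function(e) abort("S is singular and lambda = 0",
                                            class = "panelnets_degenerate_error"))
    K <- sym_part(K)
    dimnames(K) <- dimnames(S)
    return(list(precision = K, W = S, gap = 0, iterations = 0L))
  }
  W <- warm$W %||% S
  Beta <- warm$Beta %||% matrix(0, p, p)
  diag(W) <- diag(S)  # unpenalized diagonal
  K <- NULL
  gap <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      W11 <- W[idx, idx, drop = FALSE]
      s12 <- S[idx, j]
      beta <- Beta[idx, j]
      # inner lasso: min .5 b' W11 b - s12' b + lambda |b|_1
      for (inner in seq_len(200)) {
        delta <- 0
        for (k in seq_along(idx)) {
          resid <- s12[k] - sum(W11[k, ] * beta) + W11[k, k] * beta[k]
          bnew <- sign(resid) * max(abs(resid) - lambda, 0) / W11[k, k]
          delta <- max(delta, abs(bnew - beta[k]))
          beta[k] <- bnew
        }
        if (delta < 1e-10) break
      }
      Beta[idx, j] <- beta
      w12 <- as.numeric(W11 %*% beta)
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    K <- precision_from_glasso(S, W, Beta)
    gap <- glasso_gap(S, K, lambda)
    if (is.finite(gap) && gap < gap_tol) break
  }
  if (!is.finite(gap) || gap >= gap_tol) {
    abort(sprintf("graphical lasso did not converge: duality gap %.3e after %d sweeps", gap, it),
          class = "panelnets_convergence_error")
  }
  dimnames(K) <- dimnames(S)
  list(precision = K, W = W, Beta = Beta, gap = gap, iterations = it)
}

precision_from_glasso <- function(S, W, Beta) {
  p <- nrow(S)
  K <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    beta <- Beta[idx, j]
    kjj <- 1 / (W[j, j] - sum(W[idx, j] * beta))
    K[j, j] <- kjj
    K[idx, j] <- -beta * kjj
  }
  sym_part(K)
}

glasso_gap <- function(S, K, lambda) {
  offdiag <- abs(K); diag(offdiag) <- 0
  sum(S * K) + lambda * sum(offdiag) - nrow(S)
}

#' Extended Bayesian information criterion for a Gaussian graphical model
#'
#' `-n * (log det K - trace(S K)) + E * log(n) + 4 * E * gamma * log(p)`,
#' with `E` the number of nonzero upper-triangle off-diagonal precision
#' entries. Lower is better; `gamma = 0` reduces to the ordinary BIC.
#'
#' @param K Positive-definite precision matrix.
#' @param S Sample covariance/correlation.
#' @param n Sample size.
#' @param gamma Sparsity hyperparameter (0.5 is the conventional default for
#'   symptom networks).
#' @return The EBIC value (scalar).
#' @export
ebic_score <- function(K, S, n, gamma = 0.5) {
  p <- nrow(K)
  E <- sum(abs(K[upper.tri(K)]) > 1e-10)
  ll <- determinant(K, logarithm = TRUE)$modulus[1] - sum(S * K)
  -n * ll + E * log(n) + 4 * E * gamma * log(p)
}

#' Maximum-likelihood precision matrix for a fixed sparsity pattern
#'
#' Maximizes `log det K - trace(S K)` over symmetric positive-definite `K`
#' whose off-diagonal support is restricted to `support`, by BFGS on the
#' free entries with the analytic gradient `S - K^-1` (restricted to the
#' free cells).
#'
#' @param S Covariance/correlation matrix.
#' @param support Logical `p x p` symmetric matrix (or upper-triangle
#'   vector) marking allowed off-diagonal entries.
#' @return The constrained ML precision matrix.
#' @export
ml_precision_support <- function(S, support) {
  p <- nrow(S)
  if (is.matrix(support)) {
    sup <- support[upper.tri(S)]
  } else {
    sup <- as.logical(support)
  }
  ut <- which(upper.tri(S), arr.ind = TRUE)
  free <- which(sup)
  build <- function(theta) {
    K <- diag(exp(theta[seq_len(p)]), p)
    for (e in seq_along(free)) {
      i <- ut[free[e], 1]; j <- ut[free[e], 2]
      K[i, j] <- K[j, i] <- theta[p + e]
    }
    K
  }
  obj <- function(theta) {
    K <- build(theta)
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-12) return(1e10)
    -(sum(log(ev)) - sum(S * K))
  }
  grad <- function(theta) {
    K <- build(theta)
    Kinv <- tryCatch(chol2inv(chol(K)), error = function(e) NULL)
    if (is.null(Kinv)) return(rep(0, length(theta)))
    G <- S - Kinv
    c(diag(G) * diag(K),                      # chain rule through log-diagonal
      vapply(seq_along(free), function(e) {
        2 * G[ut[free[e], 1], ut[free[e], 2]]
      }, 0))
  }
  theta0 <- c(-log(pmax(diag(S), 1e-8)), rep(0, length(free)))
  opt <- optim(theta0, obj, grad, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  K <- build(opt$par)
  dimnames(K) <- dimnames(S)
  K
}

#' Estimate a cross-sectional network by EBIC-selected graphical lasso
#'
#' Fits a graphical-lasso path of `n_lambda` log-spaced penalties from the
#' smallest penalty giving an empty graph down to `lambda_min_ratio` times
#' it; the distinct sparsity patterns discovered along the path are then
#' refit by constrained maximum likelihood ([ml_precision_support()]),
#' scored with [ebic_score()], and the minimizer returned (ties broken
#' toward the sparser graph). Scoring refit patterns rather than the
#' penalized estimates makes the selection agree with exhaustive
#' enumeration of supports whenever the true pattern appears on the path;
#' `refit = FALSE` scores (and returns) the penalized path members
#' instead. Deterministic given the data.
#'
#' @param data One wave's scores: an `n x p` matrix or data frame, or a
#'   [panel_data()] with `wave` given.
#' @param wave Wave index when `data` is a `panel_data`.
#' @param gamma EBIC hyperparameter (default 0.5, the convention for
#'   removing spurious edges).
#' @param n_lambda Path length (default 100).
#' @param lambda_min_ratio Smallest penalty as a fraction of the empty-graph
#'   penalty (default 0.01).
#' @param method Correlation type: `"pearson"` (default) or `"spearman"`.
#' @param pairwise Use pairwise-complete correlations instead of complete
#'   cases.
#' @param refit Score and return constrained-ML refits of the path supports
#'   (default `TRUE`).
#' @return An object of class `ggm` with `partial_corr` (symmetric, zero
#'   diagonal, unit-bounded), `precision`, `lambda_selected`, `ebic_gamma`,
#'   the scored `path`, the moment matrix `S` and `n`.
#' @export
estimate_ggm <- function(data, wave = NULL, gamma = 0.5, n_lambda = 100,
                         lambda_min_ratio = 0.01,
                         method = c("pearson", "spearman"), pairwise = FALSE,
                         refit = TRUE) {
  method <- match.arg(method)
  if (inherits(data, "panel_data")) {
    if (is.null(wave)) abort("give a wave index for panel_data input")
    data <- wave_matrix(data, wave)
  }
  X <- as.matrix(as.data.frame(data))
  if (!pairwise) X <- X[complete.cases(X), , drop = FALSE]
  n <- nrow(X)
  p <- ncol(X)
  use <- if (pairwise) "pairwise.complete.obs" else "everything"
  # a zero-variance column makes cor() warn before we raise the degenerate
  # error ourselves; the NaN check below covers it
  S <- suppressWarnings(cor(X, method = method, use = use))
  if (anyNA(S) || min(eigen(sym_part(S), symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    abort("degenerate correlation matrix", class = "panelnets_degenerate_error")
  }
  S <- sym_part(S)
  lambda_max <- max(abs(S[upper.tri(S)]))
  if (lambda_max < 1e-12) lambda_max <- 1e-6
  path <- exp(seq(log(lambda_max), log(lambda_min_ratio * lambda_max),
                  length.out = n_lambda))
  fits <- vector("list", n_lambda)
  warm <- NULL
  scores <- edges <- numeric(n_lambda)
  sup_keys <- character(n_lambda)
  sups <- vector("list", n_lambda)
  refit_cache <- list()
  for (i in seq_len(n_lambda)) {
    fits[[i]] <- glasso_fit(S, path[i], warm = warm)
    warm <- fits[[i]]
    K <- fits[[i]]$precision
    sup <- abs(K[upper.tri(K)]) > 1e-10
    sups[[i]] <- sup
    sup_keys[i] <- paste(as.integer(sup), collapse = "")
    if (refit) {
      if (is.null(refit_cache[[sup_keys[i]]])) {
        refit_cache[[sup_keys[i]]] <- ml_precision_support(S, sup)
      }
      K <- refit_cache[[sup_keys[i]]]
    }
    scores[i] <- ebic_score(K, S, n, gamma)
    edges[i] <- sum(sup)
  }
  best <- min(scores)
  cand <- which(scores <= best + 1e-9)
  sel <- cand[which.min(edges[cand])]  # ties toward the sparser model
  K <- if (refit) refit_cache[[sup_keys[sel]]] else fits[[sel]]$precision
  structure(
    list(partial_corr = precision_to_pcor(K), precision = K,
         lambda_selected = path[sel], ebic_gamma = gamma,
         path = tibble(lambda = path, n_edges = edges, ebic = scores),
         S = S, n = n, selected = sel),
    class = "ggm"
  )
}

#' @export
print.ggm <- function(x, ...) {
  p <- nrow(x$precision)
  E <- sum(abs(x$precision[upper.tri(x$precision)]) > 1e-10)
  cat(sprintf("<ggm> %d nodes, %d edges (EBIC gamma = %g, lambda = %.4f, n = %d)\n",
              p, E, x$ebic_gamma, x$lambda_selected, x$n))
  invisible(x)
}

#' Tidy a Gaussian graphical model into an edge list
#' @param x A `ggm` object.
#' @param all_edges Include zero partial correlations.
#' @param ... Unused.
#' @return A tibble with `from`, `to`, `partial_cor` for `from < to`.
#' @export
tidy.ggm <- function(x, all_edges = FALSE, ...) {
  pc <- x$partial_corr
  nm <- rownames(pc) %||% paste0("V", seq_len(nrow(pc)))
  ut <- which(upper.tri(pc), arr.ind = TRUE)
  out <- tibble(from = nm[ut[, 1]], to = nm[ut[, 2]],
                partial_cor = pc[ut])
  if (!all_edges) out <- dplyr::filter(out, abs(.data$partial_cor) > 1e-10)
  out
}

#' @export
glance.ggm <- function(x, ...) {
  K <- x$precision
  tibble(n = x$n, p = nrow(K),
         n_edges = sum(abs(K[upper.tri(K)]) > 1e-10),
         lambda_selected = x$lambda_selected,
         ebic = x$path$ebic[x$selected],
         ebic_gamma = x$ebic_gamma)
}
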