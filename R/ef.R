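# Executive-functioning score derivation and hierarchical FIML regressions.

#' Derive executive-functioning scores from task summaries
#'
#' Computes the eight EF outcome measures from neuropsychological task
#' output: fluctuation in tempo (the within-person standard deviation of the
#' per-series mean reaction times of the sustained-attention task, sample SD
#' with `n - 1`), its overall error percentage, and the part-difference
#' scores of the set-shifting task (response inhibition: part 2 minus part
#' 1; cognitive flexibility: part 3 minus part 1) and the memory-search task
#' (working memory: part 3 minus part 1), each for mean RT (ms) and error
#' percentage. Higher values mean worse performance on every measure.
#'
#' @param series_rt Per-series records of the sustained-attention task: a
#'   data frame with `person_id`, `series`, `mean_rt` (normally 50 series
#'   per person; at least 2 are required for an SD).
#' @param part_summaries Per-part task summaries: a data frame with
#'   `person_id`, `task` (`"sustained_attention"`, `"shifting_set"`,
#'   `"memory_search"`), `part` (1--3; the sustained-attention row carries
#'   the overall error percentage), `mean_rt`, `pct_errors`.
#' @return A tibble with `person_id` and the eight measures `fluct_tempo`,
#'   `fluct_errors`, `resinhib_rt`, `resinhib_err`, `cogflex_rt`,
#'   `cogflex_err`, `wm_rt`, `wm_err`.
#' @export
derive_ef_scores <- function(series_rt, part_summaries) {
  series_rt <- as_tibble(series_rt)
  part_summaries <- as_tibble(part_summaries)
  counts <- dplyr::count(series_rt, .data$person_id)
  too_few <- counts$person_id[counts$n < 2]
  if (length(too_few)) {
    abort(sprintf("fewer than 2 series for person(s) %s: SD undefined",
                  paste(head(too_few, 5), collapse = ", ")),
          class = "panelnets_validation_error")
  }
  fluct <- series_rt |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(fluct_tempo = sd(.data$mean_rt), .groups = "drop")

  part_diff <- function(task_name, p_from, p_to, col) {
    d <- dplyr::filter(part_summaries, .data$task == task_name,
                       .data$part %in% c(p_from, p_to))
    wide <- tidyr::pivot_wider(d[, c("person_id", "part", col)],
                               names_from = "part", values_from = dplyr::all_of(col))
    tibble(person_id = wide$person_id,
           value = wide[[as.character(p_to)]] - wide[[as.character(p_from)]])
  }
  pieces <- list(
    fluct_errors = dplyr::filter(part_summaries, .data$task == "sustained_attention") |>
      dplyr::group_by(.data$person_id) |>
      dplyr::summarise(value = mean(.data$pct_errors), .groups = "drop"),
    resinhib_rt = part_diff("shifting_set", 1, 2, "mean_rt"),
    resinhib_err = part_diff("shifting_set", 1, 2, "pct_errors"),
    cogflex_rt = part_diff("shifting_set", 1, 3, "mean_rt"),
    cogflex_err = part_diff("shifting_set", 1, 3, "pct_errors"),
    wm_rt = part_diff("memory_search", 1, 3, "mean_rt"),
    wm_err = part_diff("memory_search", 1, 3, "pct_errors")
  )
  out <- fluct
  for (nm in names(pieces)) {
    piece <- setNames(pieces[[nm]], c("person_id", nm))
    out <- dplyr::full_join(out, piece, by = "person_id")
  }
  out
}

#' Screen outliers by absolute z score
#'
#' Computes z scores from the sample mean and SD of the non-missing values
#' and sets entries with `|z| >= threshold` to missing, in a single pass (no
#' re-iteration after removal). With zero variance nothing is removed and a
#' warning is raised.
#'
#' @param values Numeric vector (at least 3 non-missing values).
#' @param threshold Absolute z cutoff (default 4).
#' @return The filtered vector, with attribute `n_removed`.
#' @export
zscore_outlier_filter <- function(values, threshold = 4) {
  ok <- !is.na(values)
  if (sum(ok) < 3) abort("need at least 3 non-missing values",
                         class = "panelnets_validation_error")
  s <- sd(values[ok])
  if (!is.finite(s) || s == 0) {
    warn("zero variance: no outliers screened")
    attr(values, "n_removed") <- 0L
    return(values)
  }
  z <- (values - mean(values[ok])) / s
  out <- ifelse(!is.na(z) & abs(z) >= threshold, NA_real_, values)
  attr(out, "n_removed") <- sum(ok & is.na(out))
  out
}

#' @rdname zscore_outlier_filter
#' @param ef A tibble of EF scores (e.g. from [derive_ef_scores()]); every
#'   numeric column except `person_id` and `sex` is screened.
#' @export
filter_ef_outliers <- function(ef, threshold = 4) {
  cols <- setdiff(names(ef)[vapply(ef, is.numeric, logical(1))], c("sex"))
  removed <- integer()
  for (cl in cols) {
    f <- zscore_outlier_filter(ef[[cl]], threshold)
    removed[cl] <- attr(f, "n_removed")
    attributes(f) <- NULL
    ef[[cl]] <- f
  }
  attr(ef, "n_removed") <- removed
  ef
}

#' Regression by full-information maximum likelihood
#'
#' Fits a joint Gaussian model over the outcome and predictors by
#' pattern-wise FIML (EM for the unstructured mean/covariance), then derives
#' the regression coefficients and R-squared from the implied joint
#' covariance. On complete data this equals ordinary least squares.
#' Standard errors come from the observed information of the joint model via
#' the delta method.
#'
#' @param data A data frame containing the model variables (missingness
#'   allowed).
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of predictor columns.
#' @param se Compute standard errors (default `TRUE`; the information matrix
#'   is moderately expensive for many predictors).
#' @return A list of class `fiml_regression` with `coefficients` (a tibble:
#'   term, estimate, std_estimate, se, z, p_value), `r_squared`,
#'   `intercept`, `n` and the implied moments.
#' @export
fit_fiml_regression <- function(data, outcome, predictors, se = TRUE) {
  if (!length(predictors)) abort("need at least one predictor")
  vars <- c(outcome, predictors)
  miss <- setdiff(vars, names(data))
  if (length(miss)) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  Y <- as.matrix(as.data.frame(data)[, vars])
  storage.mode(Y) <- "double"
  Y <- Y[rowSums(!is.na(Y)) > 0, , drop = FALSE]
  em <- em_mvnorm(Y)
  beta <- beta_from_moments(em$mu, em$Sigma)
  if (is.null(beta)) {
    abort("implied predictor covariance is singular (collinearity)",
          class = "panelnets_collinearity_error")
  }
  sds <- sqrt(diag(em$Sigma))
  std <- beta$slopes * sds[-1] / sds[1]
  se_vec <- rep(NA_real_, length(predictors))
  if (se) {
    se_vec <- fiml_regression_se(Y, em)
  }
  z <- beta$slopes / se_vec
  coef_tbl <- tibble(
    term = predictors, estimate = beta$slopes, std_estimate = std,
    se = se_vec, z = z, p_value = 2 * pnorm(-abs(z))
  )
  structure(
    list(coefficients = coef_tbl, intercept = beta$intercept,
         r_squared = beta$r2, n = em$n, mu = em$mu, Sigma = em$Sigma,
         outcome = outcome),
    class = "fiml_regression"
  )
}

# Regression functionals of the joint moments (outcome first).
beta_from_moments <- function(mu, Sigma) {
  k <- nrow(Sigma) - 1
  Sxx <- Sigma[-1, -1, drop = FALSE]
  Sxy <- Sigma[-1, 1]
  slopes <- tryCatch(solve(Sxx, Sxy), error = function(e) NULL)
  if (is.null(slopes)) return(NULL)
  r2 <- sum(Sxy * slopes) / Sigma[1, 1]
  list(slopes = as.numeric(slopes), intercept = mu[1] - sum(slopes * mu[-1]),
       r2 = r2)
}

# Delta-method SEs: observed information of (mu, log-Cholesky Sigma) at the
# MLE, numerically; jacobian of beta w.r.t. the same parameterization.
fiml_regression_se <- function(Y, em) {
  d <- ncol(Y)
  pats <- unname(pattern_suffstats(Y))
  L <- t(chol(pd_floor(em$Sigma, 1e-10)))
  theta <- c(em$mu, log(diag(L)), L[lower.tri(L)])
  fn <- function(th) mvn_chol_negloglik_cpp(th, d, pats)
  H <- num_hessian(fn, theta)
  V <- safe_solve(H)
  bet <- function(th) {
    mu <- th[seq_len(d)]
    Lm <- matrix(0, d, d)
    diag(Lm) <- exp(th[d + seq_len(d)])
    Lm[lower.tri(Lm)] <- th[(2 * d + 1):length(th)]
    S <- Lm %*% t(Lm)
    beta_from_moments(mu, S)$slopes
  }
  J <- num_jacobian(bet, theta)
  Vb <- J %*% V %*% t(J)
  sqrt(pmax(diag(Vb), 0))
}

num_hessian <- function(fn, x, eps = 1e-4) {
  k <- length(x)
  h <- eps * pmax(1, abs(x))
  H <- matrix(0, k, k)
  f0 <- fn(x)
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (i == j) {
        xp <- x; xp[i] <- x[i] + h[i]
        xm <- x; xm[i] <- x[i] - h[i]
        H[i, i] <- (fn(xp) - 2 * f0 + fn(xm)) / h[i]^2
      } else {
        xpp <- x; xpp[i] <- x[i] + h[i]; xpp[j] <- x[j] + h[j]
        xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
        xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
        xmm <- x; xmm[i] <- x[i] - h[i]; xmm[j] <- x[j] - h[j]
        H[i, j] <- H[j, i] <- (fn(xpp) - fn(xpm) - fn(xmp) + fn(xmm)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

num_jacobian <- function(fn, x, eps = 1e-6) {
  f0 <- fn(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  J
}

#' @export
print.fiml_regression <- function(x, ...) {
  cat(sprintf("<fiml_regression> %s ~ %d predictors, n = %d, R^2 = %.4f\n",
              x$outcome, nrow(x$coefficients), x$n, x$r_squared))
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.fiml_regression <- function(x, ...) x$coefficients

#' @export
glance.fiml_regression <- function(x, ...) {
  tibble(r_squared = x$r_squared, n = x$n, outcome = x$outcome,
         n_predictors = nrow(x$coefficients))
}

#' Per-person broadband domain aggregates
#'
#' Mean score per person, wave and community (internalizing /
#' externalizing); variables labelled `attention` are counted with the
#' externalizing domain and `other` variables are excluded.
#'
#' @param panel A [panel_data()] object.
#' @return A wide tibble: `person_id`, then `internalizing_w<t>` and
#'   `externalizing_w<t>` columns.
#' @export
domain_aggregates <- function(panel) {
  long <- as_tibble(panel)
  meta <- panel$variables
  long$domain <- dplyr::case_when(
    meta$community[match(long$variable, meta$name)] == "internalizing" ~ "internalizing",
    meta$community[match(long$variable, meta$name)] %in% c("externalizing", "attention") ~ "externalizing",
    TRUE ~ NA_character_
  )
  long |>
    dplyr::filter(!is.na(.data$domain)) |>
    dplyr::group_by(.data$person_id, .data$wave, .data$domain) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop") |>
    dplyr::mutate(value = ifelse(is.nan(.data$value), NA_real_, .data$value)) |>
    tidyr::pivot_wider(names_from = c("domain", "wave"), values_from = "value",
                       names_sep = "_w")
}

# Step-2 predictor order follows the printed two-step model specification.
ef_model_order <- function() {
  c("wm_rt", "wm_err", "resinhib_err", "resinhib_rt",
    "fluct_tempo", "fluct_errors", "cogflex_rt", "cogflex_err")
}

#' Two-step hierarchical regression of symptoms on executive functioning
#'
#' Step 1 predicts the broadband symptom aggregate at `wave` from sex and
#' the internalizing and externalizing aggregates at the previous wave;
#' step 2 adds all eight EF measures. Both steps are fitted by
#' [fit_fiml_regression()]; the increment `delta_r2` quantifies the variance
#' the EF measures explain beyond prior symptoms and sex.
#'
#' @param panel A [panel_data()] object (raw symptom scale scores).
#' @param ef EF scores with `person_id`, the eight measures and `sex`
#'   (0/1, 1 = female by the package convention).
#' @param target `"internalizing"` or `"externalizing"`.
#' @param wave Outcome wave, 2 or 3 (predictor symptoms come from
#'   `wave - 1`).
#' @param se Compute standard errors.
#' @return A list of class `hierarchical_comparison` with `step1`, `step2`
#'   (both `fiml_regression`), `r2_step1`, `r2_step2`, `delta_r2`,
#'   `n_effective`.
#' @export
hierarchical_compare <- function(panel, ef, target = c("internalizing", "externalizing"),
                                 wave = 2, se = TRUE) {
  target <- match.arg(target)
  if (!wave %in% seq(2, n_waves(panel))) abort("wave must be a follow-up wave (>= 2)")
  ef_cols <- ef_model_order()
  miss <- setdiff(c(ef_cols, "sex"), names(ef))
  if (length(miss)) abort(paste("EF table lacks:", paste(miss, collapse = ", ")))
  agg <- domain_aggregates(panel)
  dat <- dplyr::left_join(agg, as_tibble(ef), by = "person_id")
  outcome <- sprintf("%s_w%d", target, wave)
  prev <- c(sprintf("internalizing_w%d", wave - 1), sprintf("externalizing_w%d", wave - 1))
  step1_pred <- c("sex", prev)
  step2_pred <- c(step1_pred, ef_cols)
  step1 <- fit_fiml_regression(dat, outcome, step1_pred, se = se)
  step2 <- fit_fiml_regression(dat, outcome, step2_pred, se = se)
  structure(
    list(step1 = step1, step2 = step2,
         r2_step1 = step1$r_squared, r2_step2 = step2$r_squared,
         delta_r2 = step2$r_squared - step1$r_squared,
         n_effective = step2$n, target = target, wave = wave),
    class = "hierarchical_comparison"
  )
}

#' @export
print.hierarchical_comparison <- function(x, ...) {
  cat(sprintf("<hierarchical_comparison> %s symptoms, wave %d (n = %d)\n",
              x$target, x$wave, x$n_effective))
  cat(sprintf("  R^2 step 1 = %.4f, step 2 = %.4f, delta = %.4f\n",
              x$r2_step1, x$r2_step2, x$delta_r2))
  invisible(x)
}

#' @export
tidy.hierarchical_comparison <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$step1$coefficients, step = 1L),
    dplyr::mutate(x$step2$coefficients, step = 2L)
  ) |>
    dplyr::mutate(target = x$target, wave = x$wave)
}

#' @export
glance.hierarchical_comparison <- function(x, ...) {
  tibble(target = x$target, wave = x$wave, r2_step1 = x$r2_step1,
         r2_step2 = x$r2_step2, delta_r2 = x$delta_r2, n = x$n_effective)
}
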