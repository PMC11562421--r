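# Synthetic three-wave adolescent cohort generator.
#
# The generative model mirrors the random-intercept structure the panel GVAR
# assumes: per person a trait intercept b_i ~ N(0, Sigma_B), a stationary
# within-person lag-1 process w_{t+1} = B w_t + zeta_t with zeta ~ N(0,
# K_zeta^-1), and observed scores mu + lin*t + quad*t^2 + b_i + w_it.

#' Specify a synthetic cohort design
#'
#' Collects the design knobs of the synthetic panel: sample size, waves,
#' number of symptom nodes, per-wave participation, attrition mechanism and
#' executive-functioning effect sizes. The defaults emulate a large
#' three-wave adolescent panel study: N = 2170 with participation 96% at
#' wave 2 and 76% at wave 3, dropout related to baseline symptom burden, and
#' weak (|beta| <= .07) EF-symptom associations.
#'
#' @param n_persons Number of persons (default 2170).
#' @param n_waves Number of waves (default 3).
#' @param p Number of symptom nodes (default 10).
#' @param retention Per-wave participation fractions, non-increasing with
#'   `retention[1] == 1` (default `c(1, 0.96, 0.76)`).
#' @param attrition_mechanism `"MCAR"` or `"MAR_baseline"`; under the latter,
#'   dropout odds increase with the baseline mean symptom score.
#' @param mar_strength Log-odds slope of dropout on the standardized baseline
#'   mean symptom score (default 0.5; 0 reduces to MCAR).
#' @param ef_betas Named standardized effects of the latent symptom
#'   propensity on the eight simulated EF measures.
#' @param bounded_scale If `TRUE`, clip simulated scores to the 0--2 symptom
#'   scale. Off by default: the estimators assume multivariate normality, so
#'   the unbounded Gaussian regime is primary and clipping exists to study
#'   robustness.
#' @param seed Integer seed; it fully determines every simulated output.
#' @param template Ground-truth template used when the spec is handed to
#'   [make_ground_truth()] or the pipeline: `"trails_like"` (default) or
#'   `"random_sparse"`.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_persons = 2170, n_waves = 3, p = 10,
                        retention = c(1, 0.96, 0.76),
                        attrition_mechanism = c("MAR_baseline", "MCAR"),
                        mar_strength = 0.5,
                        ef_betas = default_ef_betas(),
                        bounded_scale = FALSE,
                        seed = 20230101,
                        template = c("trails_like", "random_sparse")) {
  attrition_mechanism <- match.arg(attrition_mechanism)
  template <- match.arg(template)
  if (length(retention) != n_waves) abort("retention needs one fraction per wave")
  if (retention[1] != 1) abort("retention[1] must be 1 (everyone enters at wave 1)")
  if (any(diff(retention) > 1e-12)) abort("retention must be non-increasing across waves")
  if (any(retention <= 0 | retention > 1)) abort("retention fractions must be in (0, 1]")
  structure(
    list(n_persons = as.integer(n_persons), n_waves = as.integer(n_waves),
         p = as.integer(p), retention = retention,
         attrition_mechanism = attrition_mechanism, mar_strength = mar_strength,
         ef_betas = ef_betas, bounded_scale = isTRUE(bounded_scale),
         seed = as.integer(seed), template = template),
    class = "cohort_spec"
  )
}

#' @rdname cohort_spec
#' @export
default_ef_betas <- function() {
  c(fluct_tempo = 0.07, fluct_errors = 0.02,
    resinhib_rt = 0.05, resinhib_err = 0.01,
    cogflex_rt = 0.01, cogflex_err = 0.01,
    wm_rt = 0.02, wm_err = 0.01)
}

#' Read a cohort specification from YAML
#' @param path YAML file whose keys are [cohort_spec()] arguments.
#' @return A `cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  args <- yaml::read_yaml(path)
  do.call(cohort_spec, args)
}

# Three-wave descriptive anchors for the ten symptom scales: mean at each
# wave and the wave-1 SD, on the 0-2 (YSR) / 0-3 (RCADS) averaged-item scale.
trails_like_anchors <- function() {
  tibble::tribble(
    ~name,      ~community,      ~instrument, ~m1,  ~m2,  ~m3,  ~sd,
    "Depr",     "internalizing", "YSR",       0.29, 0.27, 0.30, 0.25,
    "Somat",    "internalizing", "YSR",       0.46, 0.32, 0.26, 0.33,
    "GenAnx",   "internalizing", "RCADS",     0.66, 0.48, 0.52, 0.45,
    "SocPhob",  "internalizing", "RCADS",     0.78, 0.68, 0.73, 0.43,
    "SepAnx",   "internalizing", "RCADS",     0.37, 0.24, 0.22, 0.35,
    "Panic",    "internalizing", "RCADS",     0.43, 0.30, 0.28, 0.36,
    "OCD",      "internalizing", "RCADS",     0.60, 0.34, 0.29, 0.44,
    "AttHyper", "externalizing", "YSR",       0.59, 0.67, 0.68, 0.36,
    "Oppos",    "externalizing", "YSR",       0.45, 0.46, 0.46, 0.35,
    "Conduct",  "externalizing", "YSR",       0.23, 0.23, 0.24, 0.20
  )
}

#' Construct ground-truth generative parameters
#'
#' Builds the three networks of the panel GVAR data-generating process:
#' a temporal matrix `B` (entry `(k, j)`: effect of node `j` at wave `t` on
#' node `k` at wave `t + 1`), a within-person contemporaneous precision
#' `K_zeta`, and a between-person covariance `Sigma_B`, plus per-variable
#' means and linear/quadratic time trends.
#'
#' The `"trails_like"` template places two symptom communities (7
#' internalizing-like and 3 externalizing-like nodes at `p = 10`) with
#' positive within-community contemporaneous partial correlations, one hub
#' node (`Depr`) whose temporal out-strength is maximal by construction, and
#' reciprocal temporal pairs (Panic--Somat, AttHyper--Oppos). Means and
#' trends follow the three-wave descriptive anchors; total variance is split
#' 40% between-person / 60% within-person. `"random_sparse"` draws a seeded
#' sparse random structure on a standardized scale.
#'
#' @param spec A [cohort_spec()].
#' @param template `"trails_like"` or `"random_sparse"`.
#' @return A list of class `ground_truth` with fields `B`, `K_zeta`,
#'   `Sigma_B`, `trend_lin`, `trend_quad`, `mu`, `variables`.
#' @export
make_ground_truth <- function(spec, template = spec$template) {
  template <- match.arg(template, c("trails_like", "random_sparse"))
  p <- spec$p
  if (p < 2) abort("need p >= 2")
  if (template == "trails_like") {
    truth <- trails_like_truth(p)
  } else {
    truth <- with_seed(derive_seed(spec$seed, "truth"), random_sparse_truth(p))
  }
  validate_ground_truth(truth)
  truth
}

trails_like_truth <- function(p) {
  n_int <- min(p, max(1L, ceiling(0.7 * p)))
  if (p == 10) {
    anchors <- trails_like_anchors()
    labels <- anchors$name
    community <- anchors$community
    instrument <- anchors$instrument
    # exact quadratic through the three wave means: mu + lin*t + quad*t^2
    A <- cbind(1, 1:3, (1:3)^2)
    coefs <- t(apply(as.matrix(anchors[, c("m1", "m2", "m3")]), 1L,
                     function(m) solve(A, m)))
    mu <- coefs[, 1]; lin <- coefs[, 2]; quad <- coefs[, 3]
    total_var <- anchors$sd^2
  } else {
    labels <- paste0("V", seq_len(p))
    community <- rep(c("internalizing", "externalizing"), c(n_int, p - n_int))
    instrument <- rep(NA_character_, p)
    mu <- rep(0, p); lin <- rep(0, p); quad <- rep(0, p)
    total_var <- rep(1, p)
  }
  int_idx <- seq_len(n_int)
  ext_idx <- setdiff(seq_len(p), int_idx)

  # temporal matrix on the standardized scale; node 1 is the hub
  B <- diag(0.25, p)
  if (n_int >= 2) B[int_idx[-1], 1] <- 0.20
  add_pair <- function(B, i, j, w) { B[j, i] <- w; B[i, j] <- w; B }
  if (p >= 7) B <- add_pair(B, 6, 2, 0.15)   # Panic <-> Somat feedback loop
  if (length(ext_idx) >= 2) B <- add_pair(B, ext_idx[1], ext_idx[2], 0.15)
  if (length(ext_idx) >= 3 && n_int >= 4) B[4, ext_idx[3]] <- -0.10
  rho <- spectral_radius(B)
  if (rho >= 0.88) B <- B * 0.88 / rho

  # contemporaneous precision from a target partial-correlation pattern
  P <- matrix(0, p, p)
  P[int_idx, int_idx] <- 0.12
  if (length(ext_idx) >= 2) P[ext_idx, ext_idx] <- 0.15
  if (length(ext_idx) >= 1) {
    P[1, ext_idx[1]] <- P[ext_idx[1], 1] <- 0.10      # hub bridges communities
    if (length(ext_idx) >= 2) P[1, ext_idx[2]] <- P[ext_idx[2], 1] <- 0.08
    if (length(ext_idx) >= 3 && n_int >= 4)
      P[4, ext_idx[3]] <- P[ext_idx[3], 4] <- -0.08   # negative cross edge
  }
  diag(P) <- 0
  K <- pcor_to_precision(P)

  Sigma_zeta <- chol2inv(chol(K))
  SW <- dlyap(B, Sigma_zeta)
  s <- sqrt(0.6 * total_var / diag(SW))
  B <- diag(s) %*% B %*% diag(1 / s)
  Sigma_zeta <- diag(s) %*% Sigma_zeta %*% diag(s)
  K_zeta <- chol2inv(chol(sym_part(Sigma_zeta)))

  Rb <- matrix(0.15, p, p)
  Rb[int_idx, int_idx] <- 0.40
  Rb[ext_idx, ext_idx] <- 0.40
  diag(Rb) <- 1
  sb <- sqrt(0.4 * total_var)
  Sigma_B <- sym_part(diag(sb) %*% Rb %*% diag(sb))

  dimnames(B) <- dimnames(K_zeta) <- dimnames(Sigma_B) <- list(labels, labels)
  structure(
    list(B = B, K_zeta = K_zeta, Sigma_B = Sigma_B,
         trend_lin = setNames(lin, labels), trend_quad = setNames(quad, labels),
         mu = setNames(mu, labels),
         variables = tibble(name = labels, community = community,
                            instrument = instrument)),
    class = "ground_truth"
  )
}

random_sparse_truth <- function(p, density = 0.2) {
  labels <- paste0("V", seq_len(p))
  B <- diag(runif(p, 0.2, 0.35))
  off <- which(upper.tri(B) | lower.tri(B))
  on <- off[runif(length(off)) < density]
  B[on] <- runif(length(on), 0.1, 0.3) * sample(c(-1, 1), length(on), replace = TRUE)
  rho <- spectral_radius(B)
  if (rho >= 0.88) B <- B * 0.88 / rho

  P <- matrix(0, p, p)
  pairs <- which(upper.tri(P), arr.ind = TRUE)
  on <- runif(nrow(pairs)) < density
  w <- ifelse(on, runif(nrow(pairs), 0.1, 0.2) * sample(c(-1, 1), nrow(pairs), replace = TRUE), 0)
  P[pairs] <- w
  P <- P + t(P)
  K_zeta <- pcor_to_precision(P)

  Ab <- matrix(rnorm(p * (p + 2)), p + 2, p)
  Rb <- stats::cov2cor(crossprod(Ab) / (p + 2))
  Sigma_B <- sym_part(0.4 * Rb)

  dimnames(B) <- dimnames(K_zeta) <- dimnames(Sigma_B) <- list(labels, labels)
  structure(
    list(B = B, K_zeta = K_zeta, Sigma_B = Sigma_B,
         trend_lin = setNames(rep(0, p), labels),
         trend_quad = setNames(rep(0, p), labels),
         mu = setNames(rep(0, p), labels),
         variables = tibble(name = labels,
                            community = rep(c("internalizing", "externalizing"),
                                            c(ceiling(0.7 * p), p - ceiling(0.7 * p))),
                            instrument = NA_character_)),
    class = "ground_truth"
  )
}

# Unit-diagonal precision with prescribed partial correlations; shrinks the
# pattern toward zero if it is not positive-definite, erroring only when even
# heavy shrinkage fails.
pcor_to_precision <- function(P) {
  for (shrink in c(1, 0.8, 0.6, 0.4)) {
    K <- -P * shrink
    diag(K) <- 1
    ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
    if (ev > 1e-6) {
      if (shrink < 1) {
        warn(sprintf("partial-correlation pattern shrunk by %.1f to stay positive-definite", shrink))
      }
      return(K)
    }
  }
  abort("requested partial correlations are incompatible with positive-definiteness; use smaller partials",
        class = "panelnets_validation_error")
}

validate_ground_truth <- function(truth) {
  if (spectral_radius(truth$B) >= 1) {
    abort("ground truth temporal matrix is non-stationary (spectral radius >= 1)")
  }
  for (nm in c("K_zeta", "Sigma_B")) {
    ev <- min(eigen(truth[[nm]], symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0) abort(sprintf("%s is not positive-definite", nm))
  }
  invisible(truth)
}

# Discrete Lyapunov equation: Sigma = B Sigma B' + Q
dlyap <- function(B, Q) {
  p <- nrow(Q)
  vecS <- solve(diag(p * p) - kronecker(B, B), as.vector(Q))
  sym_part(matrix(vecS, p, p))
}

rmvnorm_chol <- function(n, Sigma) {
  L <- chol(Sigma)
  matrix(rnorm(n * nrow(Sigma)), n) %*% L
}

#' Simulate a panel from ground-truth parameters
#'
#' Draws, per person, a trait intercept from the between-person covariance
#' and a stationary within-person lag-1 process (initialized from the
#' stationary covariance solving the discrete Lyapunov equation), then adds
#' grand means and linear/quadratic wave trends. The latent trait intercepts
#' are stored in the `intercepts` field so EF simulation and recovery tests
#' can condition on them.
#'
#' @param truth A [make_ground_truth()] result.
#' @param spec A [cohort_spec()].
#' @return A [panel_data()] object (complete; apply [apply_attrition()] for
#'   missingness).
#' @export
simulate_panel <- function(truth, spec) {
  validate_ground_truth(truth)
  n <- spec$n_persons; Tn <- spec$n_waves; p <- nrow(truth$B)
  Sigma_zeta <- chol2inv(chol(truth$K_zeta))
  SW <- dlyap(truth$B, Sigma_zeta)
  with_seed(derive_seed(spec$seed, "panel"), {
    b <- rmvnorm_chol(n, truth$Sigma_B)
    w <- array(0, dim = c(n, Tn, p))
    w[, 1, ] <- rmvnorm_chol(n, SW)
    for (t in seq_len(Tn - 1)) {
      w[, t + 1, ] <- w[, t, ] %*% t(truth$B) + rmvnorm_chol(n, Sigma_zeta)
    }
    values <- array(NA_real_, dim = c(n, Tn, p))
    for (t in seq_len(Tn)) {
      base <- matrix(truth$mu + truth$trend_lin * t + truth$trend_quad * t^2,
                     n, p, byrow = TRUE)
      values[, t, ] <- base + b + w[, t, ]
    }
    if (spec$bounded_scale) values <- pmin(pmax(values, 0), 2)
    ids <- sprintf("p%05d", seq_len(n))
    dimnames(values) <- list(ids, paste0("w", seq_len(Tn)), truth$variables$name)
    out <- structure(
      list(values = values, person_ids = ids,
           wave_times = as.numeric(seq_len(Tn)),
           variables = truth$variables,
           intercepts = `dimnames<-`(b, list(ids, truth$variables$name))),
      class = "panel_data"
    )
    validate_panel(out)
    out
  })
}

#' Apply monotone panel attrition
#'
#' Removes whole assessments (all variables of a wave) so that once a person
#' drops out they stay out, targeting the per-wave participation fractions of
#' the cohort spec. Under the `"MAR_baseline"` mechanism the per-person
#' dropout probability follows a logistic model in the standardized baseline
#' mean symptom score with slope `mar_strength`, with the intercept
#' calibrated so the expected participation matches the target; with
#' `mar_strength = 0` (or `"MCAR"`) dropout is independent of symptoms.
#'
#' @param panel A [panel_data()] object.
#' @param spec A [cohort_spec()].
#' @return The panel with wave blocks set to missing.
#' @export
apply_attrition <- function(panel, spec) {
  Tn <- n_waves(panel)
  if (all(spec$retention >= 1)) return(panel)
  baseline <- rowMeans(wave_matrix(panel, 1), na.rm = TRUE)
  z <- as.numeric(scale(baseline))
  slope <- if (spec$attrition_mechanism == "MAR_baseline") spec$mar_strength else 0
  with_seed(derive_seed(spec$seed, "attrition"), {
    present <- rep(TRUE, n_persons(panel))
    for (t in 2:Tn) {
      r_t <- spec$retention[t] / spec$retention[t - 1]
      if (r_t < 1) {
        at_risk <- which(present)
        target_drop <- 1 - r_t
        a <- calibrate_logit_intercept(z[at_risk], slope, target_drop)
        p_drop <- stats::plogis(a + slope * z[at_risk])
        dropped <- at_risk[runif(length(at_risk)) < p_drop]
        present[dropped] <- FALSE
      }
      panel$values[!present, t, ] <- NA_real_
    }
  })
  panel
}

# Solve mean(plogis(a + slope * z)) = target for the intercept a.
calibrate_logit_intercept <- function(z, slope, target) {
  if (target <= 0) return(-Inf)
  f <- function(a) mean(stats::plogis(a + slope * z)) - target
  stats::uniroot(f, c(-20, 20))$root
}

#' Simulate wave-1 executive-functioning measures and sex
#'
#' Each of the eight EF measures is generated as
#' `ef_beta * propensity + noise`, scaled to unit variance, where the latent
#' symptom propensity is the standardized mean of the person's trait
#' intercepts. Higher scores mean worse performance on every measure, so the
#' expected associations with symptoms are positive and of magnitude
#' `ef_betas` (weak by default, |beta| <= .07). Sex is Bernoulli with
#' P(female) = 0.5092.
#'
#' @param panel A synthetic [panel_data()] carrying `intercepts` (see
#'   [simulate_panel()]).
#' @param truth The [make_ground_truth()] used to simulate the panel.
#' @param spec A [cohort_spec()].
#' @return A tibble with `person_id`, the eight EF measures (standardized
#'   scale) and `sex` (1 = female).
#' @export
simulate_ef <- function(panel, truth, spec) {
  if (is.null(panel$intercepts)) {
    abort("panel carries no latent intercepts; simulate_ef needs a panel from simulate_panel()")
  }
  betas <- spec$ef_betas
  z <- as.numeric(scale(rowMeans(panel$intercepts)))
  n <- length(z)
  with_seed(derive_seed(spec$seed, "ef"), {
    ef <- purrr::map(betas, function(b) {
      b * z + sqrt(max(0, 1 - b^2)) * rnorm(n)
    })
    out <- tibble(person_id = panel$person_ids, !!!ef,
                  sex = rbinom(n, 1, 0.5092))
    out
  })
}
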