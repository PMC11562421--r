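#' Construct a panel dataset of person x wave x variable scores
#'
#' A `panel_data` object holds continuous scale scores for `n` persons
#' observed at a small number of waves on `p` variables, with missingness
#' allowed. It is the common input container for the cross-lagged panel
#' network, Gaussian graphical model and panel GVAR estimators.
#'
#' @param data A long-format data frame with columns `person_id`, `wave`
#'   (integer wave index starting at 1), `variable` and `value`.
#' @param variables Optional variable metadata: a data frame with columns
#'   `name`, `community` (one of `"internalizing"`, `"externalizing"`,
#'   `"attention"`, `"other"`) and optionally `instrument`. Defaults to
#'   community `"other"` for every variable.
#' @param wave_times Optional numeric time code per wave (strictly
#'   increasing). Defaults to the wave index `1, 2, 3, ...`; waves are the
#'   lag unit of the temporal models, but mean assessment ages can be
#'   supplied instead.
#'
#' @return An object of class `panel_data` with fields `values` (an
#'   `n x n_waves x p` array), `person_ids`, `wave_times` and `variables`.
#'
#' @details Persons must have at least one observed variable at wave 1
#'   (panel entry criterion). The stacked-vector ordering used throughout
#'   (missingness patterns, implied moments) is wave-major: wave 1's `p`
#'   variables, then wave 2's, and so on.
#'
#' @examples
#' long <- tidyr::expand_grid(person_id = c("a", "b"), wave = 1:2,
#'                            variable = c("x", "y"))
#' long$value <- rnorm(nrow(long))
#' pd <- panel_data(long)
#' dim(pd$values)
#' @export
panel_data <- function(data, variables = NULL, wave_times = NULL) {
  data <- as_tibble(data)
  needed <- c("person_id", "wave", "variable", "value")
  if (!all(needed %in% names(data))) {
    abort(paste("long panel data needs columns:", paste(needed, collapse = ", ")),
          class = "panelnets_validation_error")
  }
  persons <- unique(as.character(data$person_id))
  waves <- sort(unique(as.integer(data$wave)))
  if (!identical(waves, seq_along(waves))) {
    abort("waves must be consecutive integers starting at 1",
          class = "panelnets_validation_error")
  }
  vars <- unique(as.character(data$variable))
  if (anyDuplicated(vars)) abort("variable names must be unique")
  wave_times <- wave_times %||% as.numeric(waves)
  if (length(wave_times) != length(waves) || any(diff(wave_times) <= 0)) {
    abort("wave_times must be strictly increasing, one per wave",
          class = "panelnets_validation_error")
  }
  values <- array(NA_real_, dim = c(length(persons), length(waves), length(vars)),
                  dimnames = list(persons, paste0("w", waves), vars))
  idx <- cbind(match(as.character(data$person_id), persons),
               as.integer(data$wave),
               match(as.character(data$variable), vars))
  values[idx] <- as.numeric(data$value)

  variables <- normalize_variable_meta(variables, vars)
  out <- structure(
    list(values = values, person_ids = persons,
         wave_times = wave_times, variables = variables),
    class = "panel_data"
  )
  validate_panel(out)
  out
}

normalize_variable_meta <- function(variables, var_names) {
  if (is.null(variables)) {
    return(tibble(name = var_names, community = "other", instrument = NA_character_))
  }
  variables <- as_tibble(variables)
  if (!all(c("name", "community") %in% names(variables))) {
    abort("variable metadata needs columns name, community")
  }
  if (!"instrument" %in% names(variables)) variables$instrument <- NA_character_
  bad <- setdiff(variables$community, c("internalizing", "externalizing", "attention", "other"))
  if (length(bad)) abort(paste("unknown community:", paste(bad, collapse = ", ")))
  missing_meta <- setdiff(var_names, variables$name)
  if (length(missing_meta)) {
    variables <- dplyr::bind_rows(
      variables,
      tibble(name = missing_meta, community = "other", instrument = NA_character_)
    )
  }
  variables[match(var_names, variables$name), c("name", "community", "instrument")]
}

validate_panel <- function(panel) {
  v <- panel$values
  stopifnot(length(dim(v)) == 3L)
  if (anyDuplicated(panel$variables$name)) abort("variable names must be unique")
  all_missing_w1 <- apply(is.na(v[, 1L, , drop = FALSE]), 1L, all)
  if (any(all_missing_w1)) {
    abort(sprintf("persons with no wave-1 observations violate the entry criterion: %s",
                  paste(head(panel$person_ids[all_missing_w1], 5L), collapse = ", ")),
          class = "panelnets_validation_error")
  }
  invisible(panel)
}

#' @export
print.panel_data <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<panel_data> %d persons x %d waves x %d variables\n", d[1], d[2], d[3]))
  cat(sprintf("  wave times: %s\n", paste(x$wave_times, collapse = ", ")))
  cat(sprintf("  missing cells: %.1f%%\n", 100 * mean(is.na(x$values))))
  comm <- table(x$variables$community)
  cat("  communities:", paste(sprintf("%s=%d", names(comm), comm), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as_tibble.panel_data <- function(x, ...) {
  d <- dim(x$values)
  out <- tidyr::expand_grid(
    person_id = x$person_ids,
    wave = seq_len(d[2]),
    variable = x$variables$name
  )
  out$value <- x$values[cbind(match(out$person_id, x$person_ids),
                              out$wave,
                              match(out$variable, x$variables$name))]
  out
}

n_persons <- function(panel) dim(panel$values)[1]
n_waves <- function(panel) dim(panel$values)[2]
n_vars <- function(panel) dim(panel$values)[3]

# n x p matrix of one wave's scores
wave_matrix <- function(panel, wave) {
  m <- panel$values[, wave, , drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, ncol = n_vars(panel))
  dimnames(m) <- list(panel$person_ids, panel$variables$name)
  m
}

#' Read and write panel data as CSV
#'
#' `read_panel_long()` expects columns `person_id, wave, variable, value`;
#' `read_panel_wide()` expects `person_id` plus `<variable>_<wave>` columns
#' (e.g. `Depr_1`). Writers mirror both layouts.
#'
#' @param path File path.
#' @param variables,wave_times Passed to [panel_data()].
#' @return A [panel_data()] object (readers); the input, invisibly (writers).
#' @export
read_panel_long <- function(path, variables = NULL, wave_times = NULL) {
  panel_data(readr::read_csv(path, show_col_types = FALSE),
             variables = variables, wave_times = wave_times)
}

#' @rdname read_panel_long
#' @export
read_panel_wide <- function(path, variables = NULL, wave_times = NULL) {
  wide <- readr::read_csv(path, show_col_types = FALSE)
  long <- tidyr::pivot_longer(wide, -"person_id",
                              names_to = c("variable", "wave"),
                              names_pattern = "^(.*)_(\\d+)$",
                              values_to = "value")
  long$wave <- as.integer(long$wave)
  panel_data(long, variables = variables, wave_times = wave_times)
}

#' @rdname read_panel_long
#' @param panel A [panel_data()] object.
#' @export
write_panel_long <- function(panel, path) {
  readr::write_csv(as_tibble(panel), path)
  invisible(panel)
}

#' @rdname read_panel_long
#' @export
write_panel_wide <- function(panel, path) {
  long <- as_tibble(panel)
  wide <- tidyr::pivot_wider(long, names_from = c("variable", "wave"),
                             values_from = "value", names_sep = "_")
  readr::write_csv(wide, path)
  invisible(panel)
}

#' Score a symptom scale as the mean of its items
#'
#' Items rated on a bounded response scale (e.g. the 0--2 scale of
#' youth-report symptom checklists) are averaged into a continuous scale
#' score per person. A score is returned only when the fraction of
#' non-missing items reaches `min_coverage`; otherwise the score is `NA`.
#'
#' @param items A data frame or matrix, persons in rows and scale items in
#'   columns. Row names (or a `person_id` column) identify persons in error
#'   messages.
#' @param item_min,item_max Response-scale bounds; values outside are a
#'   validation error, not silently clipped.
#' @param min_coverage Minimum fraction of non-missing items, in (0, 1].
#'   The default 0.75 follows common checklist scoring practice.
#' @return A numeric vector of per-person scale scores within
#'   `[item_min, item_max]`.
#' @examples
#' score_scale(rbind(c(0, 1, 2), c(0, 0, 0)))
#' @export
score_scale <- function(items, item_min = 0, item_max = 2, min_coverage = 0.75) {
  if (item_min >= item_max) abort("item_min must be < item_max")
  if (min_coverage <= 0 || min_coverage > 1) abort("min_coverage must be in (0, 1]")
  items <- as.data.frame(items)
  ids <- rownames(items)
  if ("person_id" %in% names(items)) {
    ids <- as.character(items$person_id)
    items$person_id <- NULL
  }
  if (is.null(ids)) ids <- as.character(seq_len(nrow(items)))
  m <- as.matrix(items)
  bad <- which(!is.na(m) & (m < item_min | m > item_max), arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf("item value out of [%g, %g]: person %s, item %s",
                  item_min, item_max, ids[bad[1, 1]], colnames(m)[bad[1, 2]]),
          class = "panelnets_validation_error")
  }
  coverage <- rowMeans(!is.na(m))
  score <- rowMeans(m, na.rm = TRUE)
  score[coverage < min_coverage | coverage == 0] <- NA_real_
  unname(score)
}

#' Detrend for linear and quadratic time effects and standardize across waves
#'
#' For each variable, a pooled regression of the score on wave time and its
#' square (over all person-wave observations) is removed, and the residuals
#' are divided by their pooled standard deviation, so every variable has
#' pooled mean 0 and SD 1 across waves. This is the preprocessing the panel
#' GVAR model requires to make the stationarity assumption tenable.
#'
#' @param panel A [panel_data()] object.
#' @param quadratic Include the squared-time term (default `TRUE`).
#' @param per_wave Standardize within each wave separately instead of pooled
#'   across waves (off by default; the pooled transform is the conventional
#'   one for panel GVAR).
#' @return A [panel_data()] object with transformed values.
#' @export
detrend_standardize <- function(panel, quadratic = TRUE, per_wave = FALSE) {
  v <- panel$values
  tt <- panel$wave_times
  p <- n_vars(panel)
  Tn <- n_waves(panel)
  for (j in seq_len(p)) {
    yj <- v[, , j, drop = TRUE]
    if (is.null(dim(yj))) yj <- matrix(yj, ncol = Tn)
    obs <- which(!is.na(yj), arr.ind = TRUE)
    y <- yj[obs]
    tvec <- tt[obs[, 2]]
    X <- if (quadratic) cbind(1, tvec, tvec^2) else cbind(1, tvec)
    fit <- lm.fit(X, y)
    res <- fit$residuals
    s <- sqrt(mean(res^2))  # pooled (MLE) SD so the output SD is exactly 1
    if (!is.finite(s) || s < 1e-12) {
      abort(sprintf("variable '%s' has zero residual variance after detrending",
                    panel$variables$name[j]),
            class = "panelnets_degenerate_error")
    }
    yj[obs] <- res / s
    if (per_wave) {
      for (w in seq_len(Tn)) {
        col <- yj[, w]
        mu <- mean(col, na.rm = TRUE)
        sw <- sqrt(mean((col[!is.na(col)] - mu)^2))
        if (!is.finite(sw) || sw < 1e-12) {
          abort(sprintf("variable '%s' degenerate at wave %d", panel$variables$name[j], w),
                class = "panelnets_degenerate_error")
        }
        yj[, w] <- (col - mu) / sw
      }
    }
    v[, , j] <- yj
  }
  panel$values <- v
  panel
}

#' Complete-case predictor/outcome matrices for a wave pair
#'
#' Restricts to persons with no missing value at either wave and returns the
#' wave-`s` scores as predictors `X` and the wave-`t` scores as outcomes `Y`,
#' the complete-case input the cross-lagged panel network estimator uses.
#'
#' @param panel A [panel_data()] object.
#' @param s,t Wave indices with `s < t`.
#' @return A list with matrices `X` (wave `s`), `Y` (wave `t`) and the
#'   retained `person_ids`, rows in stable person order.
#' @export
wave_pair_complete_cases <- function(panel, s, t) {
  if (!(s < t)) abort("need s < t")
  Xs <- wave_matrix(panel, s)
  Yt <- wave_matrix(panel, t)
  keep <- complete.cases(Xs) & complete.cases(Yt)
  p <- n_vars(panel)
  if (sum(keep) < p + 2) {
    abort(sprintf("only %d complete cases for waves (%d, %d); need at least %d",
                  sum(keep), s, t, p + 2),
          class = "panelnets_insufficient_data_error")
  }
  list(X = Xs[keep, , drop = FALSE], Y = Yt[keep, , drop = FALSE],
       person_ids = panel$person_ids[keep])
}

#' Group persons by missingness pattern
#'
#' Partitions persons into groups sharing an identical observed-cell mask
#' over the stacked wave-by-variable vector (wave-major order), the grouping
#' that pattern-wise full-information maximum likelihood estimation uses.
#' Persons with zero observed cells are excluded with a warning.
#'
#' @param panel A [panel_data()] object.
#' @return A tibble with one row per pattern: `pattern_id`, `n_persons`,
#'   `mask` (list of logical vectors, length waves x variables) and
#'   `person_ids` (list).
#' @export
missingness_patterns <- function(panel) {
  Y <- stacked_matrix(panel)
  obs <- !is.na(Y)
  none <- rowSums(obs) == 0L
  if (any(none)) {
    warn(sprintf("%d person(s) with zero observed cells excluded from patterns", sum(none)))
    obs <- obs[!none, , drop = FALSE]
    Y <- Y[!none, , drop = FALSE]
  }
  key <- apply(obs, 1L, paste, collapse = "")
  split_idx <- unname(split(seq_len(nrow(obs)), key))
  ids <- rownames(Y)
  tibble(
    pattern_id = seq_along(split_idx),
    n_persons = lengths(split_idx),
    mask = lapply(split_idx, function(i) obs[i[1], ]),
    person_ids = lapply(split_idx, function(i) ids[i])
  )
}

# n x (T*p) stacked matrix, wave-major columns (w1:v1..vp, w2:v1..vp, ...)
stacked_matrix <- function(panel) {
  d <- dim(panel$values)
  out <- matrix(NA_real_, d[1], d[2] * d[3],
                dimnames = list(panel$person_ids,
                                paste0(rep(panel$variables$name, d[2]), "_w",
                                       rep(seq_len(d[2]), each = d[3]))))
  for (w in seq_len(d[2])) {
    out[, (w - 1) * d[3] + seq_len(d[3])] <- panel$values[, w, ]
  }
  out
}

# Pattern sufficient statistics for the C++ FIML kernels: per pattern the
# 0-based observed-cell indices, count, observed mean and MLE scatter.
pattern_suffstats <- function(Y) {
  obs <- !is.na(Y)
  keep <- rowSums(obs) > 0L
  Y <- Y[keep, , drop = FALSE]
  obs <- obs[keep, , drop = FALSE]
  key <- apply(obs, 1L, paste, collapse = "")
  groups <- split(seq_len(nrow(Y)), key)
  lapply(groups, function(rows) {
    cells <- which(obs[rows[1], ])
    Z <- Y[rows, cells, drop = FALSE]
    m <- colMeans(Z)
    Zc <- sweep(Z, 2L, m)
    list(idx = cells - 1L, n = length(rows), mean = m,
         scatter = crossprod(Zc) / length(rows))
  })
}
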