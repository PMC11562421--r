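# Config-driven orchestration of the full analysis graph: per-wave
# contemporaneous networks, per-wave-pair cross-lagged networks, the pruned
# panel GVAR, centrality and stability, and the hierarchical EF regressions.

#' Build a pipeline configuration
#'
#' @param input Either `list(synthetic = cohort_spec(...))` to simulate a
#'   cohort, or `list(file = "panel.csv")` to read a long-format panel.
#' @param stages Character vector of stages to run, in dependency order.
#'   Any subset of `c("ggm", "clpn", "gvar", "metrics", "stability",
#'   "ef_regression")`.
#' @param ggm,clpn,gvar,stability,ef_regression Per-stage parameter lists;
#'   unset entries fall back to the documented defaults of the underlying
#'   functions.
#' @param seed Global seed; every stage derives its own stream from it.
#' @param output_dir Optional directory for CSV/JSON artifacts. When `NULL`
#'   nothing is written and results are only returned.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = list(synthetic = cohort_spec()),
                            stages = c("ggm", "clpn", "gvar", "metrics",
                                       "stability", "ef_regression"),
                            ggm = list(), clpn = list(), gvar = list(),
                            stability = list(), ef_regression = list(),
                            seed = 20230101, output_dir = NULL) {
  known <- c("ggm", "clpn", "gvar", "metrics", "stability", "ef_regression")
  bad <- setdiff(stages, known)
  if (length(bad)) abort(paste("unknown stage(s):", paste(bad, collapse = ", ")),
                         class = "panelnets_config_error")
  if (is.null(input$synthetic) && is.null(input$file)) {
    abort("input must name a synthetic cohort spec or a file",
          class = "panelnets_config_error")
  }
  ggm <- modifyList(list(gamma = 0.5), ggm)
  clpn <- modifyList(list(folds = 10, rule = "1se"), clpn)
  gvar <- modifyList(list(alpha = 0.05, starts = 3, prune = TRUE), gvar)
  stability <- modifyList(
    list(analysis = "clpn", n_boot = 50, proportions = seq(0.1, 0.5, by = 0.1)),
    stability)
  structure(
    list(input = input, stages = stages, ggm = ggm, clpn = clpn, gvar = gvar,
         stability = stability, ef_regression = ef_regression,
         seed = as.integer(seed), output_dir = output_dir),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys are [pipeline_config()] arguments; a
#'   nested `input: synthetic:` block is converted to a [cohort_spec()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$input$synthetic)) {
    raw$input$synthetic <- do.call(cohort_spec, raw$input$synthetic)
  }
  do.call(pipeline_config, raw)
}

#' Run the full panel-network analysis pipeline
#'
#' Executes the configured stages on a synthetic or user-supplied panel:
#' one EBIC-glasso contemporaneous network per wave, one cross-lagged panel
#' network per consecutive wave pair, a saturated-then-pruned panel GVAR on
#' the detrended/standardized panel with fit indices, centrality and bridge
#' tables, a case-dropping stability report, and the four two-step
#' hierarchical EF regressions (both domains at waves 2 and 3). All
#' randomness derives from the config seed, so a rerun with the same config
#' reproduces every number.
#'
#' @param config A [pipeline_config()] (or path to a YAML file).
#' @return A list of class `pipeline_manifest` holding every stage's fitted
#'   objects, the seeds consumed, stage runtimes, and the paths of any
#'   written artifacts. On stage failure the error is rethrown with the
#'   partial manifest attached to the condition (`manifest` field).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  manifest <- list(config = config, seed = config$seed,
                   package_version = as.character(utils::packageVersion("panelnets")),
                   stages = list(), seeds_used = list(), runtimes = list(),
                   artifacts = character())
  run_stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(code), error = function(e) {
      if (!is.null(out_dir)) {
        jsonlite::write_json(
          list(failed_stage = name, error = conditionMessage(e),
               completed = names(manifest$stages)),
          file.path(out_dir, "manifest_partial.json"), auto_unbox = TRUE)
      }
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "panelnets_stage_error", manifest = manifest)
    })
    manifest$stages[[name]] <<- res
    manifest$runtimes[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  data <- run_stage("data", {
    if (!is.null(config$input$synthetic)) {
      spec <- config$input$synthetic
      if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
      truth <- make_ground_truth(spec, template = spec$template %||% "trails_like")
      panel <- apply_attrition(simulate_panel(truth, spec), spec)
      ef <- simulate_ef(panel, truth, spec)
      manifest$seeds_used$cohort <- spec$seed
      list(panel = panel, truth = truth, ef = ef, spec = spec)
    } else {
      list(panel = read_panel_long(config$input$file), truth = NULL, ef = NULL)
    }
  })
  panel <- data$panel
  Tn <- n_waves(panel)

  if ("ggm" %in% config$stages) {
    run_stage("ggm", {
      lapply(seq_len(Tn), function(w) {
        estimate_ggm(panel, wave = w, gamma = config$ggm$gamma)
      })
    })
  }
  if ("clpn" %in% config$stages) {
    run_stage("clpn", {
      manifest$seeds_used$clpn <- derive_seed(config$seed, "clpn")
      lapply(seq_len(Tn - 1), function(s) {
        estimate_clpn(panel, s = s, t = s + 1, folds = config$clpn$folds,
                      rule = config$clpn$rule,
                      seed = derive_seed(config$seed, "clpn"))
      })
    })
  }
  if ("gvar" %in% config$stages) {
    run_stage("gvar", {
      manifest$seeds_used$gvar <- derive_seed(config$seed, "gvar")
      det <- detrend_standardize(panel)
      fit <- fit_panel_gvar(det, starts = config$gvar$starts,
                            seed = derive_seed(config$seed, "gvar"))
      final <- if (isTRUE(config$gvar$prune)) {
        prune_stepup(fit, det, alpha = config$gvar$alpha)
      } else fit
      list(saturated = fit, model = final, indices = fit_indices(final, det),
           panel_detrended = det)
    })
  }
  if ("metrics" %in% config$stages) {
    run_stage("metrics", {
      m <- list()
      if (!is.null(manifest$stages$clpn)) {
        m$clpn_strength <- purrr::imap(manifest$stages$clpn, function(fit, i) {
          dplyr::mutate(strength_in_out(fit$weights),
                        wave_from = fit$wave_pair[1], wave_to = fit$wave_pair[2])
        })
      }
      if (!is.null(manifest$stages$ggm)) {
        comm <- setNames(panel$variables$community, panel$variables$name)
        comm[comm == "attention"] <- "externalizing"
        m$ggm_bridge <- purrr::imap(manifest$stages$ggm, function(g, w) {
          dplyr::mutate(bridge_strength(g$partial_corr, comm), wave = w)
        })
      }
      if (!is.null(manifest$stages$gvar)) {
        m$gvar_temporal_strength <- strength_in_out(temporal_network(manifest$stages$gvar$model))
      }
      m
    })
  }
  if ("stability" %in% config$stages) {
    run_stage("stability", {
      manifest$seeds_used$stability <- derive_seed(config$seed, "stability")
      st_seed <- derive_seed(config$seed, "stability", "clpn")
      statistic <- if (config$stability$analysis == "clpn") {
        function(pl) {
          fit <- estimate_clpn(pl, 1, 2, folds = config$clpn$folds, seed = st_seed)
          s <- strength_in_out(fit$weights)
          setNames(s$out_strength, s$node)
        }
      } else {
        function(pl) {
          g <- estimate_ggm(pl, wave = 1, gamma = config$ggm$gamma)
          s <- strength_in_out(g$partial_corr)
          setNames(s$in_strength, s$node)
        }
      }
      case_drop_bootstrap(panel, statistic,
                          proportions = config$stability$proportions,
                          n_boot = config$stability$n_boot,
                          seed = derive_seed(config$seed, "stability"))
    })
  }
  if ("ef_regression" %in% config$stages && !is.null(data$ef)) {
    run_stage("ef_regression", {
      grid <- tidyr::expand_grid(target = c("internalizing", "externalizing"),
                                 wave = intersect(c(2, 3), seq_len(Tn)))
      purrr::pmap(grid, function(target, wave) {
        hierarchical_compare(panel, data$ef, target = target, wave = wave)
      }) |> setNames(paste0(grid$target, "_w", grid$wave))
    })
  }

  if (!is.null(out_dir)) {
    manifest$artifacts <- write_pipeline_artifacts(manifest, out_dir)
  }
  class(manifest) <- "pipeline_manifest"
  manifest
}

write_pipeline_artifacts <- function(manifest, out_dir) {
  paths <- character()
  emit_csv <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(df, path)
    paths <<- c(paths, path)
  }
  st <- manifest$stages
  if (!is.null(st$ggm)) {
    for (w in seq_along(st$ggm)) emit_csv(tidy(st$ggm[[w]]), sprintf("ggm_w%d_edges.csv", w))
  }
  if (!is.null(st$clpn)) {
    for (i in seq_along(st$clpn)) {
      emit_csv(tidy(st$clpn[[i]]), sprintf("clpn_w%d%d_edges.csv",
                                           st$clpn[[i]]$wave_pair[1],
                                           st$clpn[[i]]$wave_pair[2]))
    }
  }
  if (!is.null(st$gvar)) {
    for (net in c("temporal", "contemporaneous", "between")) {
      emit_csv(tidy(st$gvar$model, network = net), sprintf("gvar_%s_edges.csv", net))
    }
    path <- file.path(out_dir, "gvar_fit.json")
    jsonlite::write_json(unclass(st$gvar$indices)[c("chi2", "df", "rmsea", "cfi", "tli")],
                         path, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, path)
  }
  if (!is.null(st$metrics$gvar_temporal_strength)) {
    emit_csv(st$metrics$gvar_temporal_strength, "gvar_temporal_strength.csv")
  }
  if (!is.null(st$stability)) {
    emit_csv(st$stability$summary, "stability_summary.csv")
  }
  if (!is.null(st$ef_regression)) {
    emit_csv(dplyr::bind_rows(lapply(st$ef_regression, tidy)), "ef_regressions.csv")
  }
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(seed = manifest$seed, package_version = manifest$package_version,
         stages = names(manifest$stages), runtimes = manifest$runtimes,
         seeds_used = manifest$seeds_used,
         artifacts = basename(paths)),
    path, auto_unbox = TRUE, digits = NA)
  c(paths, path)
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat("<pipeline_manifest>\n")
  for (nm in names(x$stages)) {
    cat(sprintf("  %-14s %6.2fs\n", nm, x$runtimes[[nm]] %||% NA))
  }
  if (length(x$artifacts)) cat(sprintf("  %d artifacts written\n", length(x$artifacts)))
  invisible(x)
}
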