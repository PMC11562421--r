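# Centrality and bootstrap stability for estimated networks.

#' In- and out-strength of a directed weighted network
#'
#' `out_strength(j)` is the sum of absolute outgoing edge weights
#' `|w(j -> k)|` and `in_strength(k)` the sum of absolute incoming weights;
#' in a temporal symptom network they quantify a node's influence and
#' predictability. Self-loops (autoregressive effects) are excluded unless
#' `include_self = TRUE`.
#'
#' @param net Square weight matrix, `net[j, k]` = edge `j -> k`.
#' @param include_self Count the diagonal (default `FALSE`).
#' @param signed Sum raw weights instead of absolute values (default
#'   `FALSE`; the absolute convention prevents negative edges from
#'   cancelling).
#' @return A tibble with `node`, `in_strength`, `out_strength`.
#' @export
strength_in_out <- function(net, include_self = FALSE, signed = FALSE) {
  net <- as.matrix(net)
  if (!is_square(net)) abort("network matrix must be square",
                             class = "panelnets_shape_error")
  w <- if (signed) net else abs(net)
  if (!include_self) diag(w) <- 0
  nm <- rownames(net) %||% paste0("V", seq_len(nrow(net)))
  tibble(node = nm, in_strength = unname(colSums(w)),
         out_strength = unname(rowSums(w)))
}

#' Bridge strength of nodes across symptom communities
#'
#' For each node, the sum of absolute edge weights to nodes outside its own
#' community (e.g. internalizing vs externalizing) — the degree to which a
#' symptom bridges the two domains in a contemporaneous network.
#'
#' @param net Symmetric weight matrix.
#' @param communities Community label per node: a character vector in node
#'   order, or named by node. Every node must be assigned.
#' @param signed Sum raw weights instead of absolute values.
#' @return A tibble with `node`, `community`, `bridge_strength`.
#' @export
bridge_strength <- function(net, communities, signed = FALSE) {
  net <- as.matrix(net)
  if (!is_square(net)) abort("network matrix must be square",
                             class = "panelnets_shape_error")
  p <- nrow(net)
  nm <- rownames(net) %||% paste0("V", seq_len(p))
  if (!is.null(names(communities))) communities <- communities[nm]
  if (length(communities) != p || anyNA(communities)) {
    abort("every node needs exactly one community label",
          class = "panelnets_configuration_error")
  }
  w <- if (signed) net else abs(net)
  diag(w) <- 0
  other <- outer(communities, communities, `!=`)
  tibble(node = nm, community = unname(as.character(communities)),
         bridge_strength = unname(rowSums(w * other)))
}

#' Case-dropping bootstrap stability of a network metric
#'
#' For each drop proportion `q`, `n_boot` seeded subsamples of
#' `ceiling((1 - q) * n)` persons are drawn, the estimator re-run, and the
#' correlation between the subsample metric vector and the full-sample
#' vector recorded. The correlation-stability (CS) coefficient is the
#' largest `q` at which at least 95% of bootstraps correlate at or above
#' 0.7 with the full-sample metric.
#'
#' @param panel A [panel_data()] object.
#' @param statistic A function `panel -> named numeric vector` (the
#'   estimator composed with the centrality metric); it must be
#'   deterministic given the data (fix any internal seed).
#' @param proportions Drop proportions (default 0.05 to 0.75 by 0.05).
#' @param n_boot Bootstraps per proportion (default 200).
#' @param seed Subsampling seed.
#' @param cor_threshold,prop_threshold CS convention (0.7 / 95%).
#' @return A list of class `stability_result` with `draws` (one row per
#'   bootstrap: proportion, boot, correlation), `summary`,
#'   `cs_coefficient`, `full` and `n_failures`.
#' @details Estimator failures on a subsample are skipped and counted; more
#'   than 20% failures at any proportion is an error. Correlations with a
#'   zero-variance metric vector are treated as 1 when the vectors are
#'   identical and 0 otherwise.
#' @export
case_drop_bootstrap <- function(panel, statistic,
                                proportions = seq(0.05, 0.75, by = 0.05),
                                n_boot = 200, seed = 1,
                                cor_threshold = 0.7, prop_threshold = 0.95) {
  full <- statistic(panel)
  n <- n_persons(panel)
  rows <- list()
  n_fail <- setNames(integer(length(proportions)), proportions)
  for (qi in seq_along(proportions)) {
    q <- proportions[qi]
    m <- ceiling((1 - q) * n)
    for (b in seq_len(n_boot)) {
      keep <- with_seed(derive_seed(seed, "drop", qi, b), sort(sample.int(n, m)))
      sub <- subset_panel(panel, keep)
      val <- tryCatch(statistic(sub), error = function(e) NULL)
      if (is.null(val) || length(val) != length(full)) {
        n_fail[qi] <- n_fail[qi] + 1L
        next
      }
      rows[[length(rows) + 1L]] <- tibble(proportion = q, boot = b,
                                          correlation = safe_cor(val, full))
    }
    if (n_fail[qi] > 0.2 * n_boot) {
      abort(sprintf("estimator failed on %d/%d subsamples at drop proportion %.2f",
                    n_fail[qi], n_boot, q),
            class = "panelnets_stability_error")
    }
  }
  draws <- dplyr::bind_rows(rows)
  summary <- draws |>
    dplyr::group_by(.data$proportion) |>
    dplyr::summarise(
      mean_cor = mean(.data$correlation),
      q05 = stats::quantile(.data$correlation, 0.05),
      prop_above = mean(.data$correlation >= cor_threshold),
      .groups = "drop"
    )
  res <- structure(
    list(draws = draws, summary = summary, full = full,
         proportions = proportions, n_boot = n_boot,
         cor_threshold = cor_threshold, prop_threshold = prop_threshold,
         n_failures = n_fail, seed = seed),
    class = "stability_result"
  )
  res$cs_coefficient <- cs_coefficient(res)
  res
}

#' @rdname case_drop_bootstrap
#' @param x A `stability_result`.
#' @export
cs_coefficient <- function(x, cor_threshold = NULL, prop_threshold = NULL) {
  cor_threshold <- cor_threshold %||% x$cor_threshold
  prop_threshold <- prop_threshold %||% x$prop_threshold
  ok <- x$draws |>
    dplyr::group_by(.data$proportion) |>
    dplyr::summarise(pass = mean(.data$correlation >= cor_threshold) >= prop_threshold,
                     .groups = "drop")
  passing <- ok$proportion[ok$pass]
  # CS is the largest proportion such that all smaller proportions also pass
  cs <- 0
  for (q in sort(x$proportions)) {
    if (q %in% passing) cs <- q else break
  }
  cs
}

safe_cor <- function(a, b) {
  if (sd(a) < 1e-12 || sd(b) < 1e-12) {
    return(as.numeric(max(abs(a - b)) < 1e-10))
  }
  cor(a, b)
}

subset_panel <- function(panel, keep) {
  panel$values <- panel$values[keep, , , drop = FALSE]
  panel$person_ids <- panel$person_ids[keep]
  if (!is.null(panel$intercepts)) {
    panel$intercepts <- panel$intercepts[keep, , drop = FALSE]
  }
  panel
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("<stability_result> CS(cor = %.1f) = %.2f over %d bootstraps/proportion\n",
              x$cor_threshold, x$cs_coefficient, x$n_boot))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.stability_result <- function(x, ...) x$summary

#' @export
glance.stability_result <- function(x, ...) {
  tibble(cs_coefficient = x$cs_coefficient, n_boot = x$n_boot,
         cor_threshold = x$cor_threshold,
         max_proportion = max(x$proportions),
         total_failures = sum(x$n_failures))
}

#' Convert an estimated network to an igraph object / GraphML file
#'
#' `as_igraph()` turns a `clpn` (directed), `ggm` or `panel_gvar` network
#' into an igraph graph with edge `weight` attributes and node `community`
#' attributes where available; `write_graphml()` writes it for network
#' viewers.
#'
#' @param x A `clpn`, `ggm` or `panel_gvar` object, or a weight matrix.
#' @param network Which network of a `panel_gvar` to export.
#' @param ... Unused.
#' @return An igraph object (`as_igraph`); the path, invisibly
#'   (`write_graphml`).
#' @export
as_igraph <- function(x, ...) UseMethod("as_igraph")

#' @rdname as_igraph
#' @export
as_igraph.clpn <- function(x, ...) {
  g <- igraph::graph_from_adjacency_matrix(x$weights, mode = "directed",
                                           weighted = TRUE, diag = TRUE)
  igraph::V(g)$community <- x$variables$community[match(igraph::V(g)$name,
                                                        x$variables$name)]
  g
}

#' @rdname as_igraph
#' @export
as_igraph.ggm <- function(x, ...) {
  igraph::graph_from_adjacency_matrix(x$partial_corr, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' @rdname as_igraph
#' @export
as_igraph.panel_gvar <- function(x, network = c("temporal", "contemporaneous",
                                                "between"), ...) {
  network <- match.arg(network)
  m <- switch(network, temporal = temporal_network(x),
              contemporaneous = contemporaneous_network(x),
              between = between_network(x))
  g <- igraph::graph_from_adjacency_matrix(m, weighted = TRUE,
                                           mode = if (network == "temporal") "directed" else "undirected",
                                           diag = network == "temporal")
  igraph::V(g)$community <- x$variables$community[match(igraph::V(g)$name,
                                                        x$variables$name)]
  g
}

#' @rdname as_igraph
#' @param path Output file path.
#' @export
write_graphml <- function(x, path, ...) {
  g <- if (inherits(x, "igraph")) x else as_igraph(x, ...)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
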