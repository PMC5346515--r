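#' Compare a graph metric across networks by ANOVA + Tukey HSD
#'
#' Pools per-subject metric values by network, fits a one-way ANOVA of the
#' metric on network identity, and follows with Tukey's honest significant
#' difference test for all pairwise comparisons (Tukey-Kramer for unbalanced
#' group sizes, which arise when a network is not detected in every
#' subject). Pairs are flagged at the 0.05 and 0.01 tiers.
#'
#' @param groups either a named list of numeric vectors (one per network) or
#'   a named list of lists of [metrics_record]s, in which case `metric`
#'   selects the field to compare.
#' @param metric record field name, e.g. `"n_edges"`, `"avg_degree"`,
#'   `"triangles_normalized"`, `"small_worldness"`. Ignored when `groups`
#'   already holds numeric vectors.
#' @return list of class `network_comparison`: `anova_f`, `anova_p`, and
#'   `pairs`, a data frame with columns `pair`, `diff`, `p_adj`, `tier`
#'   (`""`, `"p<=0.05"`, `"p<=0.01"`).
#' @export
compare_networks <- function(groups, metric = NULL) {
  if (length(groups) < 2L) stop("need at least two network groups")
  values <- lapply(groups, function(g) {
    if (is.numeric(g)) return(as.numeric(g))
    if (is.null(metric)) stop("metric is required for metrics-record input")
    vapply(g, function(r) as.numeric(r[[metric]]), numeric(1))
  })
  sizes <- lengths(values)
  if (any(sizes < 2L)) {
    stop("every group needs >= 2 subjects: ",
         paste(names(groups)[sizes < 2L], collapse = ", "))
  }
  df <- data.frame(
    value = unlist(values, use.names = FALSE),
    network = factor(rep(names(groups), sizes), levels = names(groups)))
  if (anyNA(df$value)) {
    df <- df[!is.na(df$value), , drop = FALSE]
    warning("dropping NA metric values before comparison")
  }
  fit <- stats::aov(value ~ network, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$network
  p_adj <- tk[, "p adj"]   # NaN when residual variance is 0: never flagged
  tier <- ifelse(!is.na(p_adj) & p_adj <= 0.01, "p<=0.01",
                 ifelse(!is.na(p_adj) & p_adj <= 0.05, "p<=0.05", ""))
  structure(
    list(anova_f = an[["F value"]][1], anova_p = an[["Pr(>F)"]][1],
         pairs = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                            p_adj = tk[, "p adj"], tier = tier,
                            row.names = NULL, stringsAsFactors = FALSE),
         metric = metric),
    class = "network_comparison"
  )
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F = %.4g, p = %.4g%s\n", x$anova_f, x$anova_p,
              if (is.null(x$metric)) "" else paste0(" (", x$metric, ")")))
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Write a network comparison report
#'
#' TSV of the pairwise table plus a JSON twin carrying the ANOVA summary.
#'
#' @param comparison a `network_comparison` (see [compare_networks]).
#' @param path output TSV path; the JSON goes to `<path>.json`.
#' @return the path, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  utils::write.table(comparison$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(anova_f = comparison$anova_f, anova_p = comparison$anova_p,
         metric = comparison$metric, pairs = comparison$pairs),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restrict the classical network to a component network's nodes
#'
#' Induced subgraph of the classical whole-brain network on the node set of
#' the network of interest (typically the non-isolated nodes of that
#' network's group graph), so that metric comparisons are not confounded by
#' network size.
#'
#' @param classical a [subject_graph] (flavor `"classical"`).
#' @param network_nodes integer vector of region ids to keep; must be a
#'   subset of the classical graph's regions.
#' @return a [subject_graph] on `network_nodes`.
#' @export
mask_classical_to_network <- function(classical, network_nodes) {
  if (length(network_nodes) == 0L) stop("empty node set")
  idx <- match(network_nodes, classical$region_ids)
  if (anyNA(idx)) stop("mask nodes missing from the classical network")
  subject_graph(classical$weights[idx, idx, drop = FALSE],
                classical$region_ids[idx],
                component_id = classical$component_id,
                flavor = classical$flavor,
                threshold_applied = classical$threshold_applied)
}

#' Non-isolated node set of a graph
#'
#' @param graph a [subject_graph] or [group_graph].
#' @return integer vector of region ids with at least one edge.
#' @export
network_node_set <- function(graph) {
  adj <- if (inherits(graph, "group_graph")) graph$adjacency else
    graph$weights > 0
  graph$region_ids[rowSums(adj) > 0]
}
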