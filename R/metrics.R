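#' Remove isolated nodes from a graph
#'
#' Nodes without edges are discarded; all graph properties are computed on
#' the remaining constellation of connected nodes.
#'
#' @param graph a [subject_graph], [group_graph], or igraph object.
#' @return an igraph object containing only nodes with degree > 0 (possibly
#'   empty), with vertex names carrying the region ids.
#' @export
connected_constellation <- function(graph) {
  g <- if (inherits(graph, "igraph")) graph else graph_to_igraph(graph)
  igraph::delete_vertices(g, which(igraph::degree(g) == 0))
}

#' Basic metric battery on the binarized thresholded graph
#'
#' On the constellation of connected nodes: number of edges E, average
#' degree k = 2E/n, number of triangles (3-cliques), average local
#' clustering coefficient C (nodes of degree < 2 contribute 0) and
#' characteristic path length L. On a disconnected graph L is averaged over
#' reachable pairs only and the unreachable fraction is reported.
#'
#' @param graph a [subject_graph], [group_graph], or igraph object; isolated
#'   nodes are removed first.
#' @return list with `n_nodes`, `n_edges`, `avg_degree`, `n_triangles`,
#'   `clustering`, `path_length`, `unreachable_fraction`.
#' @export
basic_metrics <- function(graph) {
  g <- connected_constellation(graph)
  n <- igraph::vcount(g)
  if (n == 0L) stop("empty constellation: no connected nodes")
  e <- igraph::ecount(g)
  tri <- sum(igraph::count_triangles(g)) / 3
  cc <- igraph::transitivity(g, type = "localaverage", isolates = "zero")
  dm <- igraph::distances(g, weights = NA)
  ut <- dm[upper.tri(dm)]
  reach <- is.finite(ut)
  list(n_nodes = n, n_edges = e, avg_degree = 2 * e / n,
       n_triangles = as.integer(round(tri)),
       clustering = cc,
       path_length = if (any(reach)) mean(ut[reach]) else NA_real_,
       unreachable_fraction = mean(!reach))
}

#' Erdos-Renyi null ensemble statistics
#'
#' Means of clustering coefficient, characteristic path length and triangle
#' count over `n_random` G(n, m) graphs matched on node and edge counts.
#' Seeded for reproducibility.
#'
#' @param n_nodes,n_edges size of the graphs to match.
#' @param n_random ensemble size (>= 1), default 20.
#' @param seed RNG seed.
#' @return list with `clustering`, `path_length`, `triangles`.
#' @keywords internal
er_null_stats <- function(n_nodes, n_edges, n_random = 20L, seed = 1L) {
  if (n_random < 1L) stop("n_random must be >= 1")
  stats <- withr_seed(seed, {
    vapply(seq_len(n_random), function(i) {
      g <- igraph::sample_gnm(n_nodes, n_edges)
      m <- basic_metrics_allow_isolates(g)
      c(m$clustering, m$path_length, m$n_triangles)
    }, numeric(3))
  })
  list(clustering = mean(stats[1, ]), path_length = mean(stats[2, ]),
       triangles = mean(stats[3, ]))
}

# Like basic_metrics but tolerates graphs whose constellation is empty
# (possible for sparse random null draws): returns zero clustering and
# triangles, NA path length.
basic_metrics_allow_isolates <- function(g) {
  g2 <- connected_constellation(g)
  if (igraph::vcount(g2) == 0L) {
    return(list(clustering = 0, path_length = NA_real_, n_triangles = 0L))
  }
  basic_metrics(g2)
}

# Evaluate expr with a local RNG state seeded by `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Small-worldness index
#'
#' \deqn{\sigma = (C / C_{rand}) / (L / L_{rand})}
#' where the null values are means over an Erdos-Renyi G(n, m) ensemble
#' matched on node and edge counts. \eqn{\sigma > 1} indicates a network
#' more clustered than random at comparable path length.
#'
#' @param graph a [subject_graph], [group_graph], or igraph object.
#' @param n_random null-ensemble size, default 20.
#' @param seed RNG seed for the null ensemble.
#' @return scalar sigma (`NA` if undefined, e.g. zero null clustering).
#' @export
small_worldness <- function(graph, n_random = 20L, seed = 1L) {
  m <- basic_metrics(graph)
  null <- er_null_stats(m$n_nodes, m$n_edges, n_random = n_random, seed = seed)
  if (is.na(null$clustering) || null$clustering == 0 ||
      is.na(null$path_length) || null$path_length == 0 ||
      is.na(m$path_length)) {
    return(NA_real_)
  }
  (m$clustering / null$clustering) / (m$path_length / null$path_length)
}

#' Triangle count normalized by a matched random network
#'
#' Triangle count divided by the mean triangle count of Erdos-Renyi G(n, m)
#' graphs with the same numbers of nodes and edges.
#'
#' @inheritParams small_worldness
#' @return scalar ratio (`NA` when the null expectation is zero).
#' @export
normalized_triangles <- function(graph, n_random = 20L, seed = 1L) {
  m <- basic_metrics(graph)
  null <- er_null_stats(m$n_nodes, m$n_edges, n_random = n_random, seed = seed)
  if (is.na(null$triangles) || null$triangles == 0) return(NA_real_)
  m$n_triangles / null$triangles
}

#' Compute the full metrics record for one network graph
#'
#' Runs [basic_metrics], [normalized_triangles] and [small_worldness] and
#' packs them into a [metrics_record]. An edgeless graph yields a record of
#' zeros with `NA` for the undefined averages.
#'
#' @param graph a [subject_graph] or [group_graph].
#' @param network_id identifier stored in the record.
#' @param n_random null-ensemble size for the normalized metrics.
#' @param seed RNG seed for the null ensemble.
#' @return a [metrics_record].
#' @export
compute_metrics <- function(graph, network_id, n_random = 20L, seed = 1L) {
  g <- connected_constellation(graph)
  if (igraph::vcount(g) == 0L) {
    return(metrics_record(network_id, 0L, 0L, avg_degree = NA_real_,
                          n_triangles = 0L))
  }
  m <- basic_metrics(g)
  null <- er_null_stats(m$n_nodes, m$n_edges, n_random = n_random,
                        seed = seed)
  tri_norm <- if (!is.na(null$triangles) && null$triangles > 0)
    m$n_triangles / null$triangles else NA_real_
  sigma <- if (!is.na(null$clustering) && null$clustering > 0 &&
               !is.na(null$path_length) && null$path_length > 0 &&
               !is.na(m$path_length))
    (m$clustering / null$clustering) / (m$path_length / null$path_length)
  else NA_real_
  metrics_record(network_id, m$n_nodes, m$n_edges, m$avg_degree,
                 m$n_triangles, triangles_normalized = tri_norm,
                 clustering = m$clustering, path_length = m$path_length,
                 small_worldness = sigma)
}
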