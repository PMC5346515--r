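#' Edge weight between two nodes (correlation flavor)
#'
#' \deqn{W_{a,b} = |t_a| + |t_b| - |t_a - t_b|}
#' which equals \eqn{2\min(|t_a|, |t_b|)} when the two t-values share a sign
#' and 0 when their signs are opposite, so edges are strong between regions
#' that both contribute largely, and with similar strengths, to the regional
#' signal. Vectorized over its arguments.
#'
#' @param t_a,t_b finite numeric t-values.
#' @return nonnegative weight(s).
#' @export
edge_weight <- function(t_a, t_b) {
  if (any(!is.finite(t_a)) || any(!is.finite(t_b))) {
    stop("edge_weight requires finite t-values")
  }
  abs(t_a) + abs(t_b) - abs(t_a - t_b)
}

#' Edge weight between two nodes (anti-correlation flavor)
#'
#' \deqn{W^{AC}_{a,b} = |t_a| + |t_b| - |t_a + t_b|}
#' nonzero only for t-values of opposite sign, where it equals
#' \eqn{2\min(|t_a|, |t_b|)}; the complement of [edge_weight].
#'
#' @param t_a,t_b finite numeric t-values.
#' @return nonnegative weight(s).
#' @export
edge_weight_anticorr <- function(t_a, t_b) {
  if (any(!is.finite(t_a)) || any(!is.finite(t_b))) {
    stop("edge_weight_anticorr requires finite t-values")
  }
  abs(t_a) + abs(t_b) - abs(t_a + t_b)
}

#' Build a thresholded per-component subject graph
#'
#' Takes the t-value row of one component, forms all pairwise edge weights
#' with the chosen flavor, and keeps an edge iff its weight is at least
#' `2 * t_threshold` -- equivalently, iff both node t-values reach the
#' significance threshold in magnitude and satisfy the flavor's sign
#' condition. Ties at exactly the threshold are kept. Regions flagged as
#' exact fits (infinite t) are excluded with a warning.
#'
#' @param tvalues a [tvalue_table].
#' @param component_id which component's row to use.
#' @param flavor `"correlation"` or `"anticorrelation"`.
#' @param t_threshold significance threshold on |t| (see
#'   [compute_t_threshold]).
#' @return a [subject_graph] with `threshold_applied = 2 * t_threshold`.
#' @export
build_subject_graph <- function(tvalues, component_id,
                                flavor = c("correlation", "anticorrelation"),
                                t_threshold) {
  flavor <- match.arg(flavor)
  i <- match(component_id, tvalues$component_ids)
  if (is.na(i)) stop("unknown component: ", component_id)
  tv <- tvalues$tvalues[i, ]
  bad <- !is.finite(tv)
  if (any(bad)) {
    warning(sum(bad), " region(s) with infinite t (exact fit) excluded ",
            "from graph for ", component_id)
    tv[bad] <- 0
  }
  w <- if (flavor == "correlation") {
    outer(tv, tv, edge_weight)
  } else {
    outer(tv, tv, edge_weight_anticorr)
  }
  w[w < 2 * t_threshold] <- 0
  diag(w) <- 0
  subject_graph(w, tvalues$region_ids, component_id = component_id,
                flavor = flavor, threshold_applied = 2 * t_threshold)
}

#' Aggregate thresholded subject graphs into a group graph
#'
#' Counts, per edge, the subjects whose (post-threshold) graph retains it and
#' keeps the edges whose presence fraction reaches `presence_fraction_min`
#' (default 0.25, i.e. present in at least a quarter of the subjects). Mean
#' weights over contributing subjects are stored on retained edges.
#'
#' @param graphs nonempty list of [subject_graph]s on identical region sets
#'   and of one flavor.
#' @param presence_fraction_min minimum fraction of subjects, in (0, 1].
#' @return a [group_graph].
#' @export
aggregate_group <- function(graphs, presence_fraction_min = 0.25) {
  if (length(graphs) == 0L) stop("no subject graphs to aggregate")
  ids <- graphs[[1]]$region_ids
  flav <- graphs[[1]]$flavor
  for (g in graphs) {
    if (!identical(g$region_ids, ids)) {
      stop("subject graphs have mismatched node sets")
    }
    if (!identical(g$flavor, flav)) {
      stop("subject graphs mix flavors")
    }
  }
  r <- length(ids)
  counts <- matrix(0L, r, r)
  wsum <- matrix(0, r, r)
  for (g in graphs) {
    present <- g$weights > 0
    counts <- counts + present
    wsum <- wsum + g$weights
  }
  meanw <- ifelse(counts > 0, wsum / pmax(counts, 1L), 0)
  group_graph(counts, n_subjects = length(graphs),
              presence_fraction_min = presence_fraction_min,
              mean_weights = meanw, region_ids = ids)
}

#' Build the whole-brain classical network
#'
#' Reconstructs the artifact-cleaned voxel signal as the linear combination
#' of the neuronal components weighted by their calibrated spatial maps,
#' averages it over parcellation regions, and connects regions by the
#' significance of their pairwise Pearson correlation: each r is converted
#' to a t-statistic with the same DOF as the regional GLM
#' (`t = r sqrt(DOF / (1 - r^2))`), an edge is retained iff `t >=
#' t_threshold`, and its weight is `2 t` so that it lives on the same scale
#' as the per-component edge weights. A perfect correlation yields an
#' infinite-weight edge (retained and flagged by a warning).
#'
#' @param decomposition an [ic_decomposition] with spatial maps.
#' @param neuronal_ids component ids to include in the reconstruction.
#' @param parcellation a [parcellation_volume] on the maps' voxel grid.
#' @param t_threshold significance threshold on t.
#' @param dof degrees of freedom for the r-to-t conversion; defaults to
#'   `P - N_neuronal - 1`.
#' @return a [subject_graph] with flavor `"classical"`.
#' @export
build_classical_network <- function(decomposition, neuronal_ids, parcellation,
                                    t_threshold, dof = NULL) {
  if (is.null(decomposition$spatial_maps)) {
    stop("classical-network reconstruction requires component spatial maps")
  }
  if (length(neuronal_ids) == 0L) stop("no neuronal components to combine")
  sel <- match(neuronal_ids, decomposition$component_ids)
  if (anyNA(sel)) stop("unknown component id(s)")
  maps <- decomposition$spatial_maps
  if (!identical(dim(maps)[1:3], dim(parcellation$labels))) {
    stop("spatial maps and parcellation are on different voxel grids")
  }
  X <- decomposition$timecourses[sel, , drop = FALSE]       # N x P
  nvox <- prod(dim(maps)[1:3])
  M <- matrix(maps, nrow = nvox)[, sel, drop = FALSE]       # voxels x N
  cleaned <- M %*% X                                        # voxels x P
  y <- extract_region_timecourses(
    array(cleaned, dim = c(dim(maps)[1:3], ncol(X))), parcellation,
    tr_seconds = decomposition$tr_seconds)

  if (is.null(dof)) dof <- ncol(X) - length(sel) - 1L
  rs <- y$values
  sds <- apply(rs, 1L, stats::sd)
  flat <- sds == 0
  cors <- matrix(0, nrow(rs), nrow(rs))
  if (sum(!flat) >= 2L) {
    cors[!flat, !flat] <- stats::cor(t(rs[!flat, , drop = FALSE]))
  }
  diag(cors) <- 0
  tmat <- cors * sqrt(dof / pmax(1 - cors^2, 0))
  tmat[abs(cors) >= 1 - 1e-12] <- sign(cors[abs(cors) >= 1 - 1e-12]) * Inf
  if (any(is.infinite(tmat[upper.tri(tmat)]))) {
    warning("perfectly correlated region pairs: infinite-weight edges")
  }
  w <- 2 * tmat
  w[tmat < t_threshold] <- 0
  diag(w) <- 0
  subject_graph(w, y$region_ids, component_id = "classical",
                flavor = "classical", threshold_applied = 2 * t_threshold)
}
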