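#' Domain containers
#'
#' Lightweight S3 containers shared by every pipeline stage. Each constructor
#' validates its invariants and returns a classed list; downstream functions
#' rely on those invariants instead of re-checking.
#'
#' @name icga-types
NULL

#' Construct an ICA decomposition object
#'
#' Holds the component time-courses (one row per component) and, optionally,
#' the calibrated component spatial maps needed for template matching and
#' classical-network reconstruction. Spatial maps, when present, are expected
#' in percent-signal-change units on the same voxel grid as the parcellation.
#'
#' @param timecourses numeric matrix, components x timepoints.
#' @param tr_seconds repetition time in seconds (positive).
#' @param spatial_maps optional 4D array, one volume per component.
#' @param component_ids optional character vector of component identifiers;
#'   defaults to `IC01`, `IC02`, ...
#' @return an object of class `ic_decomposition`.
#' @export
ic_decomposition <- function(timecourses, tr_seconds,
                             spatial_maps = NULL, component_ids = NULL) {
  timecourses <- as.matrix(timecourses)
  storage.mode(timecourses) <- "double"
  n <- nrow(timecourses)
  p <- ncol(timecourses)
  if (n < 1L) stop("need at least one component")
  if (p <= n + 1L) {
    stop("need more timepoints than components + 1 (otherwise DOF <= 0): ",
         "P = ", p, ", N = ", n)
  }
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0) {
    stop("tr_seconds must be a single positive number")
  }
  if (anyNA(timecourses) || any(!is.finite(timecourses))) {
    stop("timecourses contain missing or non-finite values")
  }
  if (is.null(component_ids)) {
    component_ids <- sprintf("IC%02d", seq_len(n))
  }
  if (length(component_ids) != n) {
    stop("component_ids length must equal the number of components")
  }
  if (!is.null(spatial_maps)) {
    spatial_maps <- as.array(spatial_maps)
    if (length(dim(spatial_maps)) != 4L) stop("spatial_maps must be a 4D array")
    if (dim(spatial_maps)[4] != n) {
      stop("spatial_maps must have exactly one volume per component: got ",
           dim(spatial_maps)[4], " volumes for ", n, " components")
    }
  }
  rownames(timecourses) <- component_ids
  structure(
    list(timecourses = timecourses, spatial_maps = spatial_maps,
         component_ids = component_ids, tr_seconds = as.numeric(tr_seconds)),
    class = "ic_decomposition"
  )
}

#' @export
print.ic_decomposition <- function(x, ...) {
  cat(sprintf("ic_decomposition: %d components x %d timepoints (TR = %g s)%s\n",
              nrow(x$timecourses), ncol(x$timecourses), x$tr_seconds,
              if (is.null(x$spatial_maps)) "" else ", with spatial maps"))
  invisible(x)
}

#' Construct a parcellation volume
#'
#' @param labels 3D integer array; 0 is background, positive integers are
#'   region labels. Every region id present must label at least one voxel.
#' @param region_names optional named character vector mapping label to name.
#' @return an object of class `parcellation_volume` with `region_ids` sorted
#'   ascending (background excluded).
#' @export
parcellation_volume <- function(labels, region_names = NULL) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  lv <- as.vector(labels)
  if (any(abs(lv - round(lv)) > 1e-6)) {
    stop("label volume contains non-integer values")
  }
  lv <- as.integer(round(lv))
  if (any(lv < 0L)) stop("label volume contains negative labels")
  ids <- sort(unique(lv[lv > 0L]))
  if (length(ids) == 0L) stop("empty parcellation: no nonzero labels")
  if (length(ids) < 2L) stop("need at least two regions")
  labels <- array(lv, dim = dim(labels))
  structure(
    list(labels = labels, region_ids = ids, region_names = region_names),
    class = "parcellation_volume"
  )
}

#' @export
print.parcellation_volume <- function(x, ...) {
  cat(sprintf("parcellation_volume: %d regions over a %s grid\n",
              length(x$region_ids), paste(dim(x$labels), collapse = "x")))
  invisible(x)
}

#' Construct a region-by-time matrix of averaged BOLD signal
#'
#' @param values numeric matrix, regions x timepoints; row i is the BOLD
#'   signal averaged over the voxels of region `region_ids[i]`.
#' @param region_ids integer vector aligned to rows.
#' @param tr_seconds repetition time in seconds.
#' @return an object of class `region_timeseries`.
#' @export
region_timeseries <- function(values, region_ids, tr_seconds) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(region_ids) != nrow(values)) {
    stop("region_ids must align with the rows of values")
  }
  if (anyNA(values)) stop("region time series contain missing values")
  if (!is.numeric(tr_seconds) || tr_seconds <= 0) {
    stop("tr_seconds must be positive")
  }
  region_ids <- as.integer(region_ids)
  if (anyDuplicated(region_ids)) stop("duplicate region ids")
  rownames(values) <- region_ids
  structure(
    list(values = values, region_ids = region_ids,
         tr_seconds = as.numeric(tr_seconds)),
    class = "region_timeseries"
  )
}

#' Construct a t-value table
#'
#' Stores, per component and region, the regression coefficient and its
#' t-statistic, together with the residual variance per region and the
#' degrees of freedom used for thresholding. Rows are components, columns
#' regions. t-values may be infinite where the residual variance is zero
#' (exact fits); such entries are flagged by `exact_fit`.
#'
#' @param betas,tvalues numeric matrices, components x regions.
#' @param residual_variance numeric vector, one entry per region.
#' @param dof degrees of freedom, `n_volumes - n_components - 1`.
#' @param n_volumes,n_components the counts the DOF derives from.
#' @param region_ids integer vector aligned to columns.
#' @param component_ids character vector aligned to rows.
#' @return an object of class `tvalue_table`.
#' @export
tvalue_table <- function(betas, tvalues, residual_variance, dof,
                         n_volumes, n_components, region_ids, component_ids) {
  betas <- as.matrix(betas)
  tvalues <- as.matrix(tvalues)
  stopifnot(all(dim(betas) == dim(tvalues)),
            length(residual_variance) == ncol(betas),
            length(region_ids) == ncol(betas),
            length(component_ids) == nrow(betas))
  if (dof != n_volumes - n_components - 1L) {
    stop("dof must equal n_volumes - n_components - 1")
  }
  if (dof < 1L) stop("non-positive degrees of freedom")
  exact <- residual_variance == 0
  if (any(!is.finite(tvalues[, !exact, drop = FALSE]))) {
    stop("non-finite t-values in regions with nonzero residual variance")
  }
  dimnames(betas) <- dimnames(tvalues) <- list(component_ids, region_ids)
  structure(
    list(betas = betas, tvalues = tvalues,
         residual_variance = as.numeric(residual_variance),
         dof = as.integer(dof), n_volumes = as.integer(n_volumes),
         n_components = as.integer(n_components),
         region_ids = as.integer(region_ids),
         component_ids = as.character(component_ids),
         exact_fit = exact),
    class = "tvalue_table"
  )
}

#' @export
print.tvalue_table <- function(x, ...) {
  cat(sprintf("tvalue_table: %d components x %d regions, DOF = %d\n",
              length(x$component_ids), length(x$region_ids), x$dof))
  invisible(x)
}

#' Construct a per-subject network graph
#'
#' A symmetric nonnegative weight matrix over the parcellation regions with a
#' zero diagonal. When `threshold_applied` is set, every retained (nonzero)
#' weight is at least that value.
#'
#' @param weights symmetric numeric matrix, regions x regions, zero diagonal.
#' @param region_ids integer vector aligned to rows/columns.
#' @param component_id identifier of the component (or `"classical"`).
#' @param flavor one of `"correlation"`, `"anticorrelation"`, `"classical"`.
#' @param threshold_applied optional positive number: the minimum admissible
#'   edge weight, i.e. twice the t-threshold.
#' @return an object of class `subject_graph`.
#' @export
subject_graph <- function(weights, region_ids, component_id,
                          flavor = c("correlation", "anticorrelation",
                                     "classical"),
                          threshold_applied = NULL) {
  flavor <- match.arg(flavor)
  weights <- as.matrix(weights)
  r <- nrow(weights)
  if (ncol(weights) != r) stop("weights must be square")
  if (length(region_ids) != r) stop("region_ids must align with weights")
  if (any(diag(weights) != 0)) stop("weights must have a zero diagonal")
  asym <- weights - t(weights)
  asym[is.infinite(weights) & is.infinite(t(weights))] <- 0  # Inf pairs agree
  fin <- weights[is.finite(weights)]
  if (anyNA(asym) ||
      max(abs(asym)) > 1e-12 * max(1, if (length(fin)) max(abs(fin)) else 1)) {
    stop("weights must be symmetric")
  }
  weights <- (weights + t(weights)) / 2  # exact for Inf pairs too
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (!is.null(threshold_applied)) {
    nz <- weights[weights > 0]
    if (length(nz) && min(nz) < threshold_applied - 1e-9) {
      stop("nonzero weights below the declared threshold")
    }
  }
  dimnames(weights) <- list(region_ids, region_ids)
  structure(
    list(weights = weights, region_ids = as.integer(region_ids),
         component_id = component_id, flavor = flavor,
         threshold_applied = threshold_applied),
    class = "subject_graph"
  )
}

#' @export
print.subject_graph <- function(x, ...) {
  cat(sprintf("subject_graph [%s, %s]: %d regions, %d edges\n",
              x$component_id, x$flavor, length(x$region_ids),
              sum(x$weights[upper.tri(x$weights)] > 0)))
  invisible(x)
}

#' Construct a group-level graph
#'
#' Aggregates thresholded subject graphs: `presence_counts[a, b]` is the
#' number of subjects whose graph retains edge (a, b); an edge is kept in the
#' group graph iff its presence fraction reaches `presence_fraction_min`.
#'
#' @param presence_counts symmetric integer matrix of per-edge subject counts.
#' @param n_subjects number of subjects aggregated.
#' @param presence_fraction_min minimum presence fraction in (0, 1].
#' @param mean_weights mean subject weight over contributing subjects, on
#'   retained edges (zero elsewhere).
#' @param region_ids integer vector aligned to rows/columns.
#' @return an object of class `group_graph`. `$adjacency` is the retained
#'   edge indicator.
#' @export
group_graph <- function(presence_counts, n_subjects, presence_fraction_min,
                        mean_weights, region_ids) {
  presence_counts <- as.matrix(presence_counts)
  if (any(presence_counts > n_subjects)) {
    stop("presence count exceeds number of subjects")
  }
  if (presence_fraction_min <= 0 || presence_fraction_min > 1) {
    stop("presence_fraction_min must be in (0, 1]")
  }
  retained <- (presence_counts / n_subjects) >= presence_fraction_min
  diag(retained) <- FALSE
  mean_weights <- as.matrix(mean_weights)
  mean_weights[!retained] <- 0
  dimnames(presence_counts) <- dimnames(mean_weights) <-
    list(region_ids, region_ids)
  structure(
    list(presence_counts = presence_counts, n_subjects = as.integer(n_subjects),
         presence_fraction_min = presence_fraction_min,
         mean_weights = mean_weights, adjacency = retained,
         region_ids = as.integer(region_ids)),
    class = "group_graph"
  )
}

#' @export
print.group_graph <- function(x, ...) {
  cat(sprintf(
    "group_graph: %d regions, %d edges retained (>= %.0f%% of %d subjects)\n",
    length(x$region_ids), sum(x$adjacency[upper.tri(x$adjacency)]),
    100 * x$presence_fraction_min, x$n_subjects))
  invisible(x)
}

#' Construct a metrics record
#'
#' One row of the per-subject, per-network metric battery: number of
#' connected nodes, edges, average degree, triangle count (raw and normalized
#' against an Erdos-Renyi null), average clustering coefficient,
#' characteristic path length and small-worldness. Metrics are computed after
#' isolated-node removal; an edgeless graph yields `NA` metrics.
#'
#' @param network_id network identifier.
#' @param n_connected_nodes,n_edges,avg_degree,n_triangles basic counts.
#' @param triangles_normalized,clustering,path_length,small_worldness
#'   the normalized / averaged quantities (may be `NA` when undefined).
#' @return an object of class `metrics_record` (also a plain list).
#' @export
metrics_record <- function(network_id, n_connected_nodes, n_edges, avg_degree,
                           n_triangles, triangles_normalized = NA_real_,
                           clustering = NA_real_, path_length = NA_real_,
                           small_worldness = NA_real_) {
  if (n_connected_nodes > 0) {
    stopifnot(isTRUE(all.equal(avg_degree, 2 * n_edges / n_connected_nodes)))
  }
  structure(
    list(network_id = network_id,
         n_connected_nodes = as.integer(n_connected_nodes),
         n_edges = as.integer(n_edges), avg_degree = avg_degree,
         n_triangles = as.integer(n_triangles),
         triangles_normalized = triangles_normalized,
         clustering = clustering, path_length = path_length,
         small_worldness = small_worldness),
    class = "metrics_record"
  )
}

#' Convert a list of metrics records to a data frame
#'
#' @param records list of `metrics_record` objects.
#' @return data frame with one row per record.
#' @export
metrics_to_frame <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    data.frame(network_id = r$network_id,
               n_connected_nodes = r$n_connected_nodes,
               n_edges = r$n_edges, avg_degree = r$avg_degree,
               n_triangles = r$n_triangles,
               triangles_normalized = r$triangles_normalized,
               clustering = r$clustering, path_length = r$path_length,
               small_worldness = r$small_worldness,
               stringsAsFactors = FALSE)
  }))
}
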