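#' Read a 4D BOLD image
#'
#' Reads a NIfTI-1 volume series and optionally discards the first volumes
#' (commonly done to avoid T1 saturation effects at the start of an EPI run).
#'
#' @param path path to a `.nii` / `.nii.gz` file with at least two volumes.
#' @param drop_initial number of initial volumes to discard (default 0).
#' @return 4D numeric array with attributes `pixdim` (voxel sizes incl. TR)
#'   and `n_volumes`.
#' @export
read_bold <- function(path, drop_initial = 0L) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) {
    stop("expected 4D BOLD image, got ", length(d), "D: ", path)
  }
  if (d[4] < 2L) stop("expected at least 2 volumes, got ", d[4])
  pix <- RNifti::pixdim(img)
  arr <- as.array(img)
  if (drop_initial > 0L) {
    if (drop_initial >= d[4]) stop("drop_initial leaves no volumes")
    arr <- arr[, , , (drop_initial + 1L):d[4], drop = FALSE]
  }
  attr(arr, "pixdim") <- pix
  attr(arr, "n_volumes") <- dim(arr)[4]
  arr
}

#' Write a 4D array as NIfTI
#'
#' @param arr 3D or 4D numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param pixdim optional voxel dimensions (3 or 4 values; 4th is TR).
#' @return the path, invisibly.
#' @export
write_nifti_volume <- function(arr, path, pixdim = NULL) {
  img <- RNifti::asNifti(as.array(arr))
  if (!is.null(pixdim)) RNifti::pixdim(img) <- pixdim
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a parcellation label volume
#'
#' @param path path to a 3D integer-valued NIfTI label image; 0 is background.
#' @return a [parcellation_volume] with ascending `region_ids`.
#' @export
read_parcellation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- array(as.array(img), dim = d[1:3])
  } else if (length(d) != 3L) {
    stop("expected 3D label image, got ", length(d), "D: ", path)
  }
  parcellation_volume(as.array(img))
}

#' Read a region x time matrix from TSV
#'
#' Expects a header row of region ids and one column per region, rows being
#' time points; this lets every downstream stage run without imaging data.
#'
#' @param path TSV path.
#' @param tr_seconds repetition time in seconds.
#' @return a [region_timeseries].
#' @export
read_region_matrix <- function(path, tr_seconds) {
  m <- as.matrix(utils::read.delim(path, check.names = FALSE))
  region_timeseries(t(m), region_ids = as.integer(colnames(m)),
                    tr_seconds = tr_seconds)
}

#' Write a region x time matrix to TSV
#'
#' @param y a [region_timeseries].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_region_matrix <- function(y, path) {
  m <- t(y$values)
  colnames(m) <- y$region_ids
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read ICA component time-courses from TSV
#'
#' Expects a header row of component ids and one column per component, rows
#' being time points (the transpose of the internal components x time
#' layout, matching how time series tables are usually exported).
#'
#' @param path TSV path.
#' @param tr_seconds repetition time in seconds.
#' @param spatial_maps optional path to a 4D NIfTI of component maps.
#' @return an [ic_decomposition].
#' @export
read_ic_timecourses <- function(path, tr_seconds, spatial_maps = NULL) {
  m <- as.matrix(utils::read.delim(path, check.names = FALSE))
  maps <- NULL
  if (!is.null(spatial_maps)) {
    img <- RNifti::readNifti(spatial_maps)
    if (length(dim(img)) != 4L) stop("expected 4D component maps")
    maps <- as.array(img)
  }
  ic_decomposition(t(m), tr_seconds = tr_seconds, spatial_maps = maps,
                   component_ids = colnames(m))
}

#' Write ICA component time-courses to TSV
#'
#' @param ic an [ic_decomposition].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_ic_timecourses <- function(ic, path) {
  m <- t(ic$timecourses)
  colnames(m) <- ic$component_ids
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a directory of binary network templates
#'
#' Each file `<network>.nii` or `<network>.nii.gz` is a binary mask on the
#' common voxel grid; the file stem names the network (e.g. DMN, AUD).
#'
#' @param dir directory of NIfTI masks.
#' @return named list of 3D 0/1 arrays.
#' @export
read_templates <- function(dir) {
  files <- list.files(dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
  if (length(files) == 0L) stop("no NIfTI templates found in ", dir)
  masks <- lapply(files, function(f) {
    m <- as.array(RNifti::readNifti(f))
    if (length(dim(m)) == 4L && dim(m)[4] == 1L) m <- array(m, dim(m)[1:3])
    (m != 0) * 1L
  })
  names(masks) <- sub("\\.nii(\\.gz)?$", "", basename(files))
  grids <- vapply(masks, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(grids)) > 1L) stop("templates have mismatched voxel grids")
  if (any(vapply(masks, sum, 0) == 0)) stop("empty template mask")
  masks
}

edge_table <- function(graph) {
  w <- if (inherits(graph, "group_graph")) graph$mean_weights else graph$weights
  ut <- upper.tri(w)
  keep <- if (inherits(graph, "group_graph")) graph$adjacency & ut else
    (w > 0) & ut
  idx <- which(keep, arr.ind = TRUE)
  tab <- data.frame(node_a = graph$region_ids[idx[, 1]],
                    node_b = graph$region_ids[idx[, 2]],
                    weight = w[keep])
  if (inherits(graph, "group_graph")) {
    tab$presence_count <- graph$presence_counts[keep]
  }
  tab[order(tab$node_a, tab$node_b), , drop = FALSE]
}

graph_to_igraph <- function(graph) {
  if (inherits(graph, "group_graph")) {
    w <- graph$mean_weights
    w[!graph$adjacency] <- 0
  } else {
    w <- graph$weights
  }
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  igraph::V(g)$name <- as.character(graph$region_ids)
  g
}

#' Write a graph to disk
#'
#' Emits either a TSV edge list (`node_a`, `node_b`, `weight`, and
#' `presence_count` for group graphs) or GraphML with the full vertex set.
#'
#' @param graph a [subject_graph] or [group_graph].
#' @param path output path.
#' @param format `"tsv"` or `"graphml"`.
#' @return the path, invisibly.
#' @export
write_graph <- function(graph, path, format = c("tsv", "graphml")) {
  if (!inherits(graph, c("subject_graph", "group_graph"))) {
    stop("graph must be a subject_graph or group_graph")
  }
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- edge_table(graph)
    tab$weight <- sprintf("%.12g", tab$weight)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    igraph::write_graph(graph_to_igraph(graph), path, format = "graphml")
  }
  invisible(path)
}

#' Read a graph written by [write_graph]
#'
#' @param path TSV edge list or GraphML path.
#' @param region_ids full node set (needed to restore isolated nodes from a
#'   TSV edge list; optional for GraphML, which stores all vertices).
#' @param format `"tsv"` or `"graphml"`.
#' @return a [subject_graph] (presence counts, for group graphs, are restored
#'   into the `presence_count` attribute of the returned weights table).
#' @export
read_graph <- function(path, region_ids = NULL,
                       format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- utils::read.delim(path)
    if (is.null(region_ids)) {
      region_ids <- sort(unique(c(tab$node_a, tab$node_b)))
    }
    r <- length(region_ids)
    w <- matrix(0, r, r)
    ia <- match(tab$node_a, region_ids)
    ib <- match(tab$node_b, region_ids)
    if (anyNA(ia) || anyNA(ib)) stop("edge references unknown region id")
    w[cbind(ia, ib)] <- tab$weight
    w[cbind(ib, ia)] <- tab$weight
    pc <- NULL
    if ("presence_count" %in% names(tab)) {
      pc <- matrix(0L, r, r)
      pc[cbind(ia, ib)] <- tab$presence_count
      pc[cbind(ib, ia)] <- tab$presence_count
    }
    g <- subject_graph(w, region_ids, component_id = basename(path),
                       flavor = "correlation")
    g$presence_counts <- pc
    g
  } else {
    ig <- igraph::read_graph(path, format = "graphml")
    w <- as.matrix(igraph::as_adjacency_matrix(ig, attr = "weight",
                                               sparse = FALSE))
    ids <- as.integer(igraph::V(ig)$name)
    ord <- order(ids)
    subject_graph(w[ord, ord, drop = FALSE], ids[ord],
                  component_id = basename(path), flavor = "correlation")
  }
}

#' Write a t-value table with its threshold metadata
#'
#' The t-values go to `<path>` as TSV (components x regions, header = region
#' ids); DOF, significance level and threshold go to a JSON sidecar
#' `<path>.json`.
#'
#' @param tv a [tvalue_table].
#' @param path output TSV path.
#' @param p significance level recorded in the sidecar.
#' @param t_threshold threshold recorded in the sidecar.
#' @return the path, invisibly.
#' @export
write_tvalue_table <- function(tv, path, p = NULL, t_threshold = NULL) {
  m <- tv$tvalues
  colnames(m) <- tv$region_ids
  utils::write.table(cbind(component = tv$component_ids,
                           format(m, digits = 17, trim = TRUE,
                                  scientific = TRUE)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(dof = tv$dof, n_volumes = tv$n_volumes,
               n_components = tv$n_components,
               significance_p = p, t_threshold = t_threshold)
  jsonlite::write_json(meta[!vapply(meta, is.null, TRUE)],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a list of metrics records to JSON
#'
#' @param records list of [metrics_record] objects.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_metrics_json <- function(records, path) {
  jsonlite::write_json(lapply(records, unclass), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
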