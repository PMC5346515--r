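#' Pipeline configuration
#'
#' Every numeric decision of the workflow is settable here; the defaults are
#' the method's canonical choices: significance p = 0.001 on the Student-t
#' threshold, group edge presence in at least 25% of subjects, 20 random
#' null graphs for the normalized metrics, a 0.5 in-band power cutoff for
#' the spectral neuronality heuristic, and 3 initial volumes discarded.
#'
#' @param significance_p significance level for [compute_t_threshold].
#' @param presence_fraction group edge-presence fraction for
#'   [aggregate_group].
#' @param n_random_nulls Erdos-Renyi ensemble size for normalized metrics.
#' @param seed RNG seed used for the null ensembles.
#' @param neuronal_cutoff in-band power fraction cutoff of the spectral
#'   classifier.
#' @param band_low_hz,band_high_hz neuronal frequency band, in Hz.
#' @param drop_initial_volumes initial BOLD volumes to discard.
#' @param use_all_components if `TRUE`, skip the neuronality filter and
#'   regress on every component.
#' @param tr_seconds repetition time used when the BOLD header does not
#'   carry one (and for TSV inputs).
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(significance_p = 0.001, presence_fraction = 0.25,
                            n_random_nulls = 20L, seed = 1L,
                            neuronal_cutoff = 0.5, band_low_hz = 0.01,
                            band_high_hz = 0.1, drop_initial_volumes = 3L,
                            use_all_components = FALSE, tr_seconds = 2) {
  structure(
    list(significance_p = significance_p,
         presence_fraction = presence_fraction,
         n_random_nulls = as.integer(n_random_nulls), seed = as.integer(seed),
         neuronal_cutoff = neuronal_cutoff, band_low_hz = band_low_hz,
         band_high_hz = band_high_hz,
         drop_initial_volumes = as.integer(drop_initial_volumes),
         use_all_components = isTRUE(use_all_components),
         tr_seconds = tr_seconds),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a flat YAML file
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path YAML path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

resolve_subject_inputs <- function(bold, region_matrix, parcellation,
                                   ic_timecourses, ic_maps, config) {
  if (is.character(ic_timecourses)) {
    ic <- read_ic_timecourses(ic_timecourses, tr_seconds = config$tr_seconds,
                              spatial_maps = ic_maps)
  } else {
    ic <- ic_timecourses
  }
  parc <- NULL
  if (!is.null(region_matrix)) {
    y <- if (is.character(region_matrix)) {
      read_region_matrix(region_matrix, tr_seconds = config$tr_seconds)
    } else region_matrix
  } else {
    if (is.null(bold) || is.null(parcellation)) {
      stop("need either a region matrix or a BOLD image plus parcellation")
    }
    vol <- if (is.character(bold)) {
      read_bold(bold, drop_initial = config$drop_initial_volumes)
    } else bold
    parc <- if (is.character(parcellation)) read_parcellation(parcellation)
      else parcellation
    y <- extract_region_timecourses(vol, parc, tr_seconds = config$tr_seconds)
  }
  if (ncol(y$values) != ncol(ic$timecourses)) {
    stop("timepoint mismatch between regional signal (", ncol(y$values),
         ") and component courses (", ncol(ic$timecourses), "); check ",
         "drop_initial_volumes")
  }
  list(ic = ic, y = y, parcellation = parc)
}

#' Run the full per-subject workflow
#'
#' Extract regional courses, classify neuronal components, match templates,
#' fit the regional GLM, threshold, build correlation / anti-correlation
#' graphs per detected network plus the classical network, and compute
#' subject-level metrics. All artifacts are written under
#' `out_dir/<subject_id>/`: graphs as TSV edge lists and GraphML under
#' `graphs/`, the t-value table, metrics JSON and a provenance record
#' logging every parameter (p, DOF, t-threshold, neuronal ids, assignment).
#'
#' @param subject_id subject label used for the output directory.
#' @param ic_timecourses TSV path or an [ic_decomposition].
#' @param bold,parcellation BOLD NIfTI path (or 4D array) and label volume
#'   path (or [parcellation_volume]); alternatively supply `region_matrix`.
#' @param region_matrix region x time TSV path or [region_timeseries];
#'   bypasses image handling entirely.
#' @param ic_maps optional 4D NIfTI path of component spatial maps (ignored
#'   when `ic_timecourses` is already a decomposition carrying maps).
#' @param templates optional template directory or named list of binary
#'   masks; networks are then named by template, otherwise by component.
#' @param config a [pipeline_config].
#' @param out_dir output root.
#' @param classifier neuronality classifier; default spectral heuristic with
#'   the config's band and cutoff.
#' @return invisibly, a list with the subject's `tvalues`, `graphs`,
#'   `classical`, `metrics`, `neuronal_ids`, `assignment`, `t_threshold`.
#' @export
run_subject <- function(subject_id, ic_timecourses, bold = NULL,
                        parcellation = NULL, region_matrix = NULL,
                        ic_maps = NULL, templates = NULL,
                        config = pipeline_config(), out_dir,
                        classifier = NULL) {
  inp <- resolve_subject_inputs(bold, region_matrix, parcellation,
                                ic_timecourses, ic_maps, config)
  ic <- inp$ic
  y <- inp$y

  if (is.null(classifier)) {
    classifier <- spectral_classifier(
      band_hz = c(config$band_low_hz, config$band_high_hz),
      cutoff = config$neuronal_cutoff)
  }
  neuronal <- if (config$use_all_components) ic$component_ids else
    classify_neuronal(ic, classifier)
  if (length(neuronal) == 0L) {
    stop("subject ", subject_id, ": no component passed the neuronality test")
  }

  assignment <- NULL
  if (!is.null(templates)) {
    if (is.character(templates)) templates <- read_templates(templates)
    if (is.null(ic$spatial_maps)) {
      stop("template matching requires component spatial maps")
    }
    sel <- match_templates(ic$spatial_maps, templates,
                           component_ids = ic$component_ids)
    assignment <- sel$assignment
    # a network counts as detected only if its component is neuronal
    networks <- assignment[!is.na(assignment) & assignment %in% neuronal]
  } else {
    networks <- stats::setNames(neuronal, neuronal)
  }

  keep <- match(neuronal, ic$component_ids)
  ic_n <- ic_decomposition(
    ic$timecourses[keep, , drop = FALSE], ic$tr_seconds,
    spatial_maps = if (is.null(ic$spatial_maps)) NULL else
      ic$spatial_maps[, , , keep, drop = FALSE],
    component_ids = neuronal)

  tv <- fit_glm(y, ic_n)
  t_thr <- compute_t_threshold(tv$dof, config$significance_p)

  sdir <- file.path(out_dir, subject_id)
  gdir <- file.path(sdir, "graphs")
  dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
  write_tvalue_table(tv, file.path(sdir, "tvalues.tsv"),
                     p = config$significance_p, t_threshold = t_thr)

  graphs <- list()
  metrics <- list()
  for (net in names(networks)) {
    comp <- networks[[net]]
    for (flavor in c("correlation", "anticorrelation")) {
      g <- build_subject_graph(tv, comp, flavor = flavor, t_threshold = t_thr)
      stem <- file.path(gdir, paste0(net, "_", flavor))
      write_graph(g, paste0(stem, ".tsv"), format = "tsv")
      write_graph(g, paste0(stem, ".graphml"), format = "graphml")
      graphs[[paste0(net, "_", flavor)]] <- g
    }
    metrics[[net]] <- compute_metrics(
      graphs[[paste0(net, "_correlation")]], network_id = net,
      n_random = config$n_random_nulls, seed = config$seed)
  }

  classical <- NULL
  if (!is.null(ic_n$spatial_maps) && !is.null(inp$parcellation)) {
    classical <- build_classical_network(ic_n, neuronal, inp$parcellation,
                                         t_threshold = t_thr, dof = tv$dof)
    write_graph(classical, file.path(gdir, "classical.tsv"), format = "tsv")
    write_graph(classical, file.path(gdir, "classical.graphml"),
                format = "graphml")
    metrics[["classical"]] <- compute_metrics(
      classical, network_id = "classical",
      n_random = config$n_random_nulls, seed = config$seed)
  }
  write_metrics_json(unname(metrics), file.path(sdir, "metrics.json"))

  prov <- list(subject_id = subject_id,
               region_ids = tv$region_ids,
               dof = tv$dof, n_volumes = tv$n_volumes,
               n_components = tv$n_components,
               significance_p = config$significance_p,
               t_threshold = t_thr,
               neuronal_ids = neuronal,
               assignment = as.list(assignment),
               networks = as.list(networks),
               has_classical = !is.null(classical),
               config = unclass(config))
  jsonlite::write_json(prov, file.path(sdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")

  invisible(list(tvalues = tv, graphs = graphs, classical = classical,
                 metrics = metrics, neuronal_ids = neuronal,
                 assignment = assignment, t_threshold = t_thr,
                 networks = networks, dir = sdir))
}

read_subject_outputs <- function(dir) {
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"),
                              simplifyVector = TRUE)
  prov$region_ids <- as.integer(prov$region_ids)
  prov$dir <- dir
  prov
}

#' Run the group-level workflow
#'
#' Aggregates per-subject outputs: builds group graphs per network and
#' flavor with the configured presence rule, reports the detection
#' percentage per network, recomputes per-subject metrics restricted to the
#' non-isolated node set of each network's group graph (for both the
#' network graph and the subject's classical graph masked to the same
#' nodes), writes the pooled metrics table, and compares networks against
#' their masked classical counterparts by ANOVA + Tukey HSD.
#'
#' @param subject_dirs directories written by [run_subject] (>= 2).
#' @param out_dir output directory for group artifacts.
#' @param config a [pipeline_config].
#' @return invisibly, a list with `group_graphs`, `detection`,
#'   `metrics_table`, `comparisons`.
#' @export
run_group <- function(subject_dirs, out_dir, config = pipeline_config()) {
  if (length(subject_dirs) < 2L) stop("need at least two subjects")
  subs <- lapply(subject_dirs, read_subject_outputs)
  ids <- subs[[1]]$region_ids
  for (s in subs) {
    if (!identical(s$region_ids, ids)) {
      stop("inconsistent region sets across subjects")
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n_sub <- length(subs)
  all_networks <- sort(unique(unlist(lapply(subs, function(s)
    names(s$networks)))))
  if (length(all_networks) == 0L) stop("no networks detected in any subject")

  read_sub_graph <- function(s, net, flavor) {
    g <- read_graph(file.path(s$dir, "graphs",
                              paste0(net, "_", flavor, ".tsv")),
                    region_ids = ids)
    g$flavor <- flavor
    g
  }

  group_graphs <- list()
  detection <- stats::setNames(numeric(length(all_networks)), all_networks)
  per_subject <- list()   # rows of the pooled metrics table
  groups_by_metric <- list()

  for (net in all_networks) {
    have <- vapply(subs, function(s) net %in% names(s$networks), logical(1))
    detection[net] <- 100 * sum(have) / n_sub
    contributing <- subs[have]
    for (flavor in c("correlation", "anticorrelation")) {
      gl <- lapply(contributing, read_sub_graph, net = net, flavor = flavor)
      gg <- aggregate_group(gl, presence_fraction_min =
                              config$presence_fraction)
      group_graphs[[paste0(net, "_", flavor)]] <- gg
      stem <- file.path(out_dir, paste0(net, "_group_", flavor))
      write_graph(gg, paste0(stem, ".tsv"), format = "tsv")
      write_graph(gg, paste0(stem, ".graphml"), format = "graphml")
    }
    gg <- group_graphs[[paste0(net, "_correlation")]]
    nodes <- network_node_set(gg)
    if (length(nodes) == 0L) {
      warning("network ", net, ": empty group graph, skipped in metrics")
      next
    }
    net_vals <- list()
    cn_vals <- list()
    for (s in contributing) {
      sg <- read_sub_graph(s, net, "correlation")
      msg <- mask_classical_to_network(sg, nodes)
      rec <- compute_metrics(msg, network_id = net,
                             n_random = config$n_random_nulls,
                             seed = config$seed)
      per_subject[[length(per_subject) + 1L]] <-
        cbind(data.frame(subject = s$subject_id, network = net,
                         pct = detection[net]), metrics_to_frame(list(rec)))
      net_vals[[s$subject_id]] <- rec
      if (isTRUE(s$has_classical)) {
        cg <- read_graph(file.path(s$dir, "graphs", "classical.tsv"),
                         region_ids = ids)
        mcg <- mask_classical_to_network(cg, nodes)
        crec <- compute_metrics(mcg, network_id = paste0(net, "_CN"),
                                n_random = config$n_random_nulls,
                                seed = config$seed)
        cn_vals[[s$subject_id]] <- crec
        per_subject[[length(per_subject) + 1L]] <-
          cbind(data.frame(subject = s$subject_id,
                           network = paste0(net, "_CN"),
                           pct = detection[net]),
                metrics_to_frame(list(crec)))
      }
    }
    for (metric in c("n_edges", "avg_degree", "triangles_normalized",
                     "small_worldness")) {
      if (length(net_vals) >= 2L) {
        groups_by_metric[[metric]][[net]] <- net_vals
      }
      if (length(cn_vals) >= 2L) {
        groups_by_metric[[metric]][[paste0(net, "_CN")]] <- cn_vals
      }
    }
  }

  metrics_table <- if (length(per_subject)) do.call(rbind, per_subject) else
    data.frame()
  utils::write.table(metrics_table, file.path(out_dir, "metrics_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(detection),
                       file.path(out_dir, "detection_percent.json"),
                       auto_unbox = TRUE, digits = NA)

  comparisons <- list()
  for (metric in names(groups_by_metric)) {
    gs <- groups_by_metric[[metric]]
    if (length(gs) < 2L) next
    cmp <- tryCatch(compare_networks(gs, metric = metric),
                    error = function(e) NULL)
    if (is.null(cmp)) next
    comparisons[[metric]] <- cmp
    write_comparison(cmp, file.path(out_dir,
                                    paste0("comparison_", metric, ".tsv")))
  }

  invisible(list(group_graphs = group_graphs, detection = detection,
                 metrics_table = metrics_table, comparisons = comparisons))
}
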