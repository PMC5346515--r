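#' Configuration for the synthetic resting-state generator
#'
#' The generator emulates what the graph-building method assumes about its
#' inputs: band-limited (default 0.01--0.1 Hz) component time-courses, a
#' known signed region-by-component mixing matrix, additive white noise at a
#' controlled SNR, and (optionally) a paintable label volume with matching
#' component spatial maps. Identical config + seed gives identical outputs.
#'
#' The default design is the planted-structure validation cohort: 15
#' subjects, 3 components and 60 regions in signed blocks (each component
#' loads +1 on its own block of 20 regions and -1 on the next block), 297
#' retained volumes at TR = 2 s, SNR = 10. With these settings each
#' component's true correlation graph is the union of the cliques on its two
#' loaded blocks and its anti-correlation graph is the complete bipartite
#' graph between them.
#'
#' @param n_regions,n_components,n_timepoints problem dimensions.
#' @param tr_seconds repetition time in seconds.
#' @param band_hz frequency band of the component courses, in Hz.
#' @param mixing components x regions matrix of signed loadings; default
#'   [block_mixing()] on the given dimensions.
#' @param snr per-region ratio var(signal) / var(noise) for regions with
#'   nonzero loading.
#' @param volume_shape optional 3D dims for [paint_volume].
#' @param n_subjects cohort size.
#' @param seed base RNG seed; subject s uses `seed + s`.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_regions = 60L, n_components = 3L,
                             n_timepoints = 297L, tr_seconds = 2,
                             band_hz = c(0.01, 0.1), mixing = NULL,
                             snr = 10, volume_shape = NULL,
                             n_subjects = 15L, seed = 1L) {
  if (n_timepoints <= n_components + 1L) {
    stop("n_timepoints must exceed n_components + 1")
  }
  if (band_hz[2] > 1 / (2 * tr_seconds)) {
    stop("band upper edge ", band_hz[2], " Hz exceeds the Nyquist frequency ",
         1 / (2 * tr_seconds), " Hz at TR = ", tr_seconds, " s")
  }
  if (band_hz[1] >= band_hz[2] || band_hz[1] < 0) stop("invalid band")
  if (snr <= 0) stop("snr must be positive")
  if (is.null(mixing)) mixing <- block_mixing(n_components, n_regions)
  mixing <- as.matrix(mixing)
  if (nrow(mixing) != n_components || ncol(mixing) != n_regions) {
    stop("mixing must be components x regions")
  }
  structure(
    list(n_regions = as.integer(n_regions),
         n_components = as.integer(n_components),
         n_timepoints = as.integer(n_timepoints),
         tr_seconds = tr_seconds, band_hz = band_hz, mixing = mixing,
         snr = snr, volume_shape = volume_shape,
         n_subjects = as.integer(n_subjects), seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Signed block mixing matrix
#'
#' Splits the regions into `n_components` equal blocks; component i loads +1
#' on block i and -1 on block i+1 (cyclically), other entries 0. This plants
#' both a clique structure for the correlation graphs and an opposite-sign
#' structure for the anti-correlation graphs.
#'
#' @param n_components,n_regions dimensions; `n_regions` must be divisible
#'   by `n_components`.
#' @return components x regions matrix.
#' @export
block_mixing <- function(n_components, n_regions) {
  if (n_regions %% n_components != 0L) {
    stop("n_regions must be divisible by n_components for block mixing")
  }
  bs <- n_regions %/% n_components
  if (n_components == 1L) return(matrix(1, 1L, n_regions))
  m <- matrix(0, n_components, n_regions)
  for (i in seq_len(n_components)) {
    pos <- ((i - 1L) * bs + 1L):(i * bs)
    nxt <- (i %% n_components) * bs + seq_len(bs)
    m[i, pos] <- 1
    m[i, nxt] <- -1
  }
  m
}

#' True edge set implied by a mixing matrix
#'
#' The graph the pipeline should recover for one component: an edge between
#' two regions iff both have nonzero loading on the component and the signs
#' satisfy the flavor (equal for correlation, opposite for anti-correlation).
#'
#' @param mixing components x regions matrix.
#' @param component row index.
#' @param flavor `"correlation"` or `"anticorrelation"`.
#' @return symmetric logical matrix (zero diagonal).
#' @export
planted_edges <- function(mixing, component,
                          flavor = c("correlation", "anticorrelation")) {
  flavor <- match.arg(flavor)
  l <- mixing[component, ]
  s <- sign(l)
  same <- outer(s, s) > 0
  opp <- outer(s, s) < 0
  e <- if (flavor == "correlation") same else opp
  diag(e) <- FALSE
  e
}

#' Generate band-limited, mutually decorrelated component time-courses
#'
#' Each course starts as white Gaussian noise, is Fourier-filtered to the
#' configured band (DC removed, so courses have exactly zero mean), and the
#' set is then orthogonalized over the sample (QR) and scaled to unit
#' variance, so any two courses have sample correlation exactly zero while
#' remaining band-limited.
#'
#' @param config a [synthetic_config].
#' @param seed RNG seed; default `config$seed`.
#' @return an [ic_decomposition] (no spatial maps).
#' @export
make_component_timecourses <- function(config, seed = config$seed) {
  p <- config$n_timepoints
  n <- config$n_components
  freqs <- (seq_len(p) - 1L) / (p * config$tr_seconds)
  freqs <- pmin(freqs, 1 / config$tr_seconds - freqs)  # fold negative bins
  keep <- freqs >= config$band_hz[1] & freqs <= config$band_hz[2]
  if (sum(keep) < 2L * n) {
    stop("band too narrow: only ", sum(keep), " Fourier bins for ", n,
         " components")
  }
  X <- withr_seed(seed, {
    t(vapply(seq_len(n), function(i) {
      z <- stats::fft(stats::rnorm(p))
      z[!keep] <- 0
      Re(stats::fft(z, inverse = TRUE)) / p
    }, numeric(p)))
  })
  qx <- qr(t(X))
  if (qx$rank < n) stop("degenerate draw: courses not independent")
  X <- t(qr.Q(qx))
  X <- X / apply(X, 1L, stats::sd)
  ic_decomposition(X, tr_seconds = config$tr_seconds)
}

#' Mix component courses into noisy region time courses
#'
#' `Y = t(mixing) %*% X + noise`, the noise SD per region chosen so that
#' var(signal) / var(noise) equals the configured SNR for regions with
#' nonzero loading; zero-loading regions get the mean noise SD of the loaded
#' ones (pure noise rows).
#'
#' @param config a [synthetic_config].
#' @param decomposition an [ic_decomposition] from
#'   [make_component_timecourses].
#' @param seed RNG seed for the noise; default `config$seed + 1`.
#' @return list with `series` (a [region_timeseries]) and `mixing` (the
#'   ground-truth loadings).
#' @export
make_region_timecourses <- function(config, decomposition,
                                    seed = config$seed + 1L) {
  X <- decomposition$timecourses
  if (nrow(X) != nrow(config$mixing)) {
    stop("mixing rows must match the number of components")
  }
  Y0 <- t(config$mixing) %*% X
  sigvar <- apply(Y0, 1L, stats::var)
  loaded <- rowSums(config$mixing != 0) > 0
  sds <- numeric(config$n_regions)
  sds[loaded] <- sqrt(sigvar[loaded] / config$snr)
  sds[!loaded] <- if (any(loaded)) mean(sds[loaded]) else 1
  noise <- withr_seed(seed, {
    matrix(stats::rnorm(length(Y0)), nrow(Y0), ncol(Y0)) * sds
  })
  series <- region_timeseries(Y0 + noise,
                              region_ids = seq_len(config$n_regions),
                              tr_seconds = config$tr_seconds)
  list(series = series, mixing = config$mixing)
}

#' Paint region courses into a labeled volume
#'
#' Partitions `config$volume_shape` into `n_regions` contiguous runs of
#' voxels (in array order), labels them 1..R, and fills a 4D BOLD array in
#' which every voxel carries its region's time course plus small i.i.d.
#' voxel noise. Also emits per-component spatial maps whose voxel value is
#' the region's mixing loading, for template-matching and classical-network
#' tests.
#'
#' @param config a [synthetic_config] with `volume_shape` set.
#' @param region_series a [region_timeseries] with `n_regions` rows.
#' @param voxel_noise_sd SD of the added voxel noise (default 0.05).
#' @param seed RNG seed; default `config$seed + 2`.
#' @return list with `bold` (4D array), `parcellation`
#'   (a [parcellation_volume]) and `spatial_maps` (4D array, one volume per
#'   component).
#' @export
paint_volume <- function(config, region_series, voxel_noise_sd = 0.05,
                         seed = config$seed + 2L) {
  shape <- config$volume_shape
  if (is.null(shape)) stop("volume_shape is not set in the config")
  nvox <- prod(shape)
  r <- config$n_regions
  if (nvox < r) stop("more regions than voxels")
  # contiguous runs of near-equal length in array order
  lab <- as.integer(cut(seq_len(nvox), breaks = r, labels = FALSE))
  p <- ncol(region_series$values)
  bold <- region_series$values[lab, , drop = FALSE]
  bold <- bold + withr_seed(seed, {
    matrix(stats::rnorm(nvox * p, sd = voxel_noise_sd), nvox, p)
  })
  maps <- t(config$mixing)[lab, , drop = FALSE]   # voxels x components
  list(bold = array(bold, dim = c(shape, p)),
       parcellation = parcellation_volume(array(lab, dim = shape)),
       spatial_maps = array(maps, dim = c(shape, config$n_components)))
}

#' Simulate one subject
#'
#' Draws component courses and region courses for subject `subject`; when
#' `config$volume_shape` is set, also paints the BOLD volume, parcellation
#' and spatial maps (and attaches the maps to the decomposition).
#'
#' @param config a [synthetic_config].
#' @param subject subject index (1-based); seeds are derived as
#'   `config$seed + 10 * subject + {0,1,2}` so subjects are independent.
#' @return list with `ic`, `series`, `mixing`, and (with a volume shape)
#'   `bold`, `parcellation`.
#' @export
simulate_subject <- function(config, subject = 1L) {
  base <- config$seed + 10L * subject
  ic <- make_component_timecourses(config, seed = base)
  reg <- make_region_timecourses(config, ic, seed = base + 1L)
  out <- list(ic = ic, series = reg$series, mixing = reg$mixing)
  if (!is.null(config$volume_shape)) {
    painted <- paint_volume(config, reg$series, seed = base + 2L)
    out$bold <- painted$bold
    out$parcellation <- painted$parcellation
    out$ic <- ic_decomposition(ic$timecourses, ic$tr_seconds,
                               spatial_maps = painted$spatial_maps,
                               component_ids = ic$component_ids)
  }
  out
}

#' Simulate a full cohort
#'
#' @param config a [synthetic_config].
#' @return list of [simulate_subject] results of length `config$n_subjects`.
#' @export
simulate_cohort <- function(config) {
  lapply(seq_len(config$n_subjects), function(s) simulate_subject(config, s))
}

#' Write synthetic fixtures to disk
#'
#' Emits, per subject, the component time-courses as TSV and the region
#' courses as TSV; with a volume shape also the 4D BOLD NIfTI, the label
#' volume and the component spatial maps. Ground truth (mixing matrix,
#' config) goes to `ground_truth.json`.
#'
#' @param config a [synthetic_config].
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
simulate_fixtures <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_len(config$n_subjects)) {
    sub <- simulate_subject(config, s)
    sd <- file.path(out_dir, sprintf("sub-%02d", s))
    dir.create(sd, showWarnings = FALSE)
    write_ic_timecourses(sub$ic, file.path(sd, "ic_timecourses.tsv"))
    write_region_matrix(sub$series, file.path(sd, "region_timecourses.tsv"))
    if (!is.null(config$volume_shape)) {
      write_nifti_volume(sub$bold, file.path(sd, "bold.nii.gz"),
                         pixdim = c(3, 3, 3, config$tr_seconds))
      write_nifti_volume(sub$parcellation$labels,
                         file.path(sd, "parcellation.nii.gz"))
      write_nifti_volume(sub$ic$spatial_maps, file.path(sd, "ic_maps.nii.gz"))
    }
  }
  jsonlite::write_json(
    list(mixing = config$mixing, n_regions = config$n_regions,
         n_components = config$n_components,
         n_timepoints = config$n_timepoints, tr_seconds = config$tr_seconds,
         band_hz = config$band_hz, snr = config$snr,
         n_subjects = config$n_subjects, seed = config$seed),
    file.path(out_dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(out_dir)
}
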