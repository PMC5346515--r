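#' Extract region-averaged time courses from a BOLD image
#'
#' For each parcellation region, averages the BOLD signal over the region's
#' voxels at each time point (unweighted mean).
#'
#' @param bold 4D numeric array (see [read_bold]).
#' @param parcellation a [parcellation_volume] on the same voxel grid.
#' @param tr_seconds repetition time in seconds; if `NULL`, taken from the
#'   `pixdim` attribute of `bold` when available.
#' @return a [region_timeseries], rows ordered by ascending region id.
#' @export
extract_region_timecourses <- function(bold, parcellation, tr_seconds = NULL) {
  bold <- as.array(bold)
  d <- dim(bold)
  if (length(d) != 4L) stop("bold must be a 4D array")
  if (!identical(d[1:3], dim(parcellation$labels))) {
    stop("BOLD and parcellation are on different voxel grids (",
         paste(d[1:3], collapse = "x"), " vs ",
         paste(dim(parcellation$labels), collapse = "x"),
         "); no resampling is performed")
  }
  if (is.null(tr_seconds)) {
    pix <- attr(bold, "pixdim")
    tr_seconds <- if (!is.null(pix) && length(pix) >= 4 && pix[4] > 0)
      pix[4] else 1
  }
  lab <- as.vector(parcellation$labels)
  sel <- lab > 0L
  vox <- matrix(bold, nrow = prod(d[1:3]), ncol = d[4])[sel, , drop = FALSE]
  sums <- rowsum(vox, group = lab[sel])
  counts <- as.vector(table(lab[sel]))
  ids <- as.integer(rownames(sums))
  stopifnot(identical(ids, parcellation$region_ids))
  region_timeseries(sums / counts, region_ids = ids, tr_seconds = tr_seconds)
}

#' Fit the regional GLM and transform coefficients to t-values
#'
#' Solves, for every region, the least-squares regression of the region's
#' BOLD time course on the component time-courses (design matrix = component
#' courses as columns plus an intercept), and converts each coefficient to a
#' t-statistic with contrast vector selecting that component:
#' \deqn{t_{ij} = \beta_{ij} / \sqrt{\hat\sigma^2_j \, (c_i^T (D^T D)^{-1} c_i)}}
#' with residual variance \eqn{\hat\sigma^2_j = \|\varepsilon_j\|^2 /
#' \mathrm{DOF}} and \eqn{\mathrm{DOF} = P - N - 1} (the intercept accounts
#' for the extra 1).
#'
#' Regions whose time course is constant carry no information and are dropped
#' with a warning. Regions fit exactly (zero residual variance) get infinite
#' t-values, flagged via `exact_fit`; graph construction excludes them with a
#' warning.
#'
#' @param y a [region_timeseries] (R x P).
#' @param x an [ic_decomposition] (N x P) with matching P.
#' @return a [tvalue_table].
#' @export
fit_glm <- function(y, x) {
  X <- x$timecourses
  Y <- y$values
  n <- nrow(X)
  p <- ncol(X)
  if (ncol(Y) != p) {
    stop("time dimension mismatch: Y has ", ncol(Y), " points, X has ", p)
  }
  if (p <= n + 1L) stop("too few timepoints for ", n, " components")

  const <- apply(Y, 1L, function(r) stats::sd(r) == 0)
  if (any(const)) {
    warning("dropping ", sum(const), " constant region(s): ",
            paste(y$region_ids[const], collapse = ", "))
    Y <- Y[!const, , drop = FALSE]
  }
  region_ids <- y$region_ids[!const]
  if (nrow(Y) == 0L) stop("no usable regions after dropping constants")

  D <- cbind(t(X), `(intercept)` = 1)          # P x (N + 1)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    bad <- setdiff(colnames(D), colnames(D)[qrD$pivot[seq_len(qrD$rank)]])
    bad <- sub("^$", "(unnamed)", bad)
    stop("rank-deficient design: collinear columns ",
         paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qrD, t(Y))                  # (N + 1) x R
  resid <- t(Y) - D %*% coefs
  dof <- p - n - 1L
  s2 <- colSums(resid^2) / dof
  # exact fits: residuals at numerical zero relative to the signal scale
  scale2 <- pmax(colMeans(t(Y)^2), .Machine$double.eps)
  s2[colSums(resid^2) <= 1e-20 * dof * scale2] <- 0

  XtXinv <- chol2inv(qr.R(qrD))                # (D'D)^-1 via the QR factor
  se_unit <- sqrt(diag(XtXinv)[seq_len(n)])    # per component, unit sigma
  betas <- coefs[seq_len(n), , drop = FALSE]
  tvals <- betas / outer(se_unit, sqrt(s2))
  tvals[, s2 == 0] <- sign(betas[, s2 == 0, drop = FALSE]) * Inf
  tvals[betas == 0 & !is.finite(tvals)] <- 0   # 0/0 from zero coefficients

  tvalue_table(betas = betas, tvalues = tvals, residual_variance = s2,
               dof = dof, n_volumes = p, n_components = n,
               region_ids = region_ids, component_ids = x$component_ids)
}

#' Student-t significance threshold
#'
#' The one-tailed `(1 - p)` quantile of Student's t with `dof` degrees of
#' freedom; applied to |t| during graph construction, with edge weights
#' thresholded at twice this value.
#'
#' @param dof degrees of freedom (>= 1), typically
#'   `n_volumes - n_components - 1`.
#' @param p significance level in (0, 1), default 0.001.
#' @return scalar threshold.
#' @export
compute_t_threshold <- function(dof, p = 0.001) {
  if (!is.numeric(dof) || dof < 1) stop("dof must be >= 1")
  if (!is.numeric(p) || p <= 0 || p >= 1) stop("p must be in (0, 1)")
  stats::qt(1 - p, df = dof)
}
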