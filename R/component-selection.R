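#' Goodness-of-fit of a spatial map to a binary template
#'
#' The Greicius-style score: mean map value inside the template mask minus
#' mean value outside it. Larger is better; a map unrelated to the template
#' scores near zero, and a constant map scores exactly zero.
#'
#' @param spatial_map 3D numeric array (typically a z-scored component map).
#' @param mask 3D binary array on the same voxel grid.
#' @return scalar goodness-of-fit.
#' @export
goodness_of_fit <- function(spatial_map, mask) {
  spatial_map <- as.array(spatial_map)
  mask <- as.array(mask)
  if (!identical(dim(spatial_map), dim(mask))) {
    stop("spatial map and template mask are on different voxel grids")
  }
  inside <- mask != 0
  if (!any(inside)) stop("empty template mask")
  if (all(inside)) stop("template mask covers the whole volume")
  mean(spatial_map[inside]) - mean(spatial_map[!inside])
}

#' Assign components to network templates simultaneously
#'
#' Scores every component against every template with [goodness_of_fit] and
#' then solves a maximum-weight one-to-one assignment over all pairs with
#' positive score, so that all networks are considered simultaneously rather
#' than matched greedily one template at a time. A template with no positive
#' score against any component, or left unmatched by the optimal assignment,
#' is reported as absent.
#'
#' The assignment is solved exactly by dynamic programming over subsets of
#' templates (the template count is small -- nine in typical use).
#'
#' @param maps 4D array of component spatial maps (one volume per component)
#'   or a list of 3D arrays.
#' @param templates named list of binary 3D masks (see [read_templates]).
#' @param component_ids optional identifiers aligned to maps.
#' @return a list of class `selection_result`: `assignment` (named character
#'   vector, template -> component id or `NA` for absent), `gof_matrix`
#'   (components x templates) and `total_gof`.
#' @export
match_templates <- function(maps, templates, component_ids = NULL) {
  if (is.array(maps) && length(dim(maps)) == 4L) {
    maps <- lapply(seq_len(dim(maps)[4]), function(i) maps[, , , i])
  }
  n <- length(maps)
  tn <- length(templates)
  if (n < 1L || tn < 1L) stop("need at least one component and one template")
  if (is.null(component_ids)) component_ids <- sprintf("IC%02d", seq_len(n))
  gof <- matrix(NA_real_, n, tn, dimnames = list(component_ids,
                                                 names(templates)))
  for (i in seq_len(n)) {
    for (j in seq_len(tn)) {
      gof[i, j] <- goodness_of_fit(maps[[i]], templates[[j]])
    }
  }

  # DP over template subsets: best[i, S] = max total GOF using the first i
  # components with the templates in S already served. Skipping a template
  # is free (it ends up absent); only positive-GOF pairs are eligible.
  nstates <- bitwShiftL(1L, tn)
  best <- matrix(-Inf, n + 1L, nstates)
  choice <- matrix(0L, n + 1L, nstates)  # template picked by component i (0 = none)
  best[1L, 1L] <- 0
  for (i in seq_len(n)) {
    for (s in seq_len(nstates) - 1L) {
      base <- best[i, s + 1L]
      if (!is.finite(base)) next
      # component i unassigned
      if (base > best[i + 1L, s + 1L]) {
        best[i + 1L, s + 1L] <- base
        choice[i + 1L, s + 1L] <- 0L
      }
      for (j in seq_len(tn)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(s, bit) != 0L || gof[i, j] <= 0) next
        val <- base + gof[i, j]
        if (val > best[i + 1L, bitwOr(s, bit) + 1L]) {
          best[i + 1L, bitwOr(s, bit) + 1L] <- val
          choice[i + 1L, bitwOr(s, bit) + 1L] <- j
        }
      }
    }
  }
  s <- which.max(best[n + 1L, ]) - 1L
  total <- best[n + 1L, s + 1L]
  assignment <- stats::setNames(rep(NA_character_, tn), names(templates))
  for (i in rev(seq_len(n))) {
    j <- choice[i + 1L, s + 1L]
    if (j > 0L) {
      assignment[j] <- component_ids[i]
      s <- bitwAnd(s, bitwNot(bitwShiftL(1L, j - 1L)))
    }
  }
  structure(list(assignment = assignment, gof_matrix = gof,
                 total_gof = total),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("template assignment (total GOF =", format(x$total_gof), "):\n")
  for (nm in names(x$assignment)) {
    cat(sprintf("  %-6s -> %s\n", nm,
                ifelse(is.na(x$assignment[nm]), "absent", x$assignment[nm])))
  }
  invisible(x)
}

#' Fraction of time-course spectral power inside a frequency band
#'
#' One-sided periodogram power (DC excluded) in `[band_hz[1], band_hz[2]]`
#' divided by total power up to the Nyquist frequency.
#'
#' @param x numeric time course.
#' @param tr_seconds sampling interval in seconds.
#' @param band_hz length-2 numeric, band edges in Hz.
#' @return scalar in \[0, 1\].
#' @export
band_power_fraction <- function(x, tr_seconds, band_hz = c(0.01, 0.1)) {
  p <- length(x)
  x <- x - mean(x)
  pw <- Mod(stats::fft(x))^2
  k <- seq(2L, floor(p / 2) + 1L)      # positive frequencies, DC excluded
  freqs <- (k - 1L) / (p * tr_seconds)
  inband <- freqs >= band_hz[1] & freqs <= band_hz[2]
  tot <- sum(pw[k])
  if (tot == 0) return(0)
  sum(pw[k][inband]) / tot
}

#' Built-in spectral neuronality heuristic
#'
#' Labels a component neuronal iff the fraction of its time-course power in
#' the low-frequency band exceeds `cutoff`. This is a documented stand-in
#' for classifiers trained on spatiotemporal component fingerprints (e.g.
#' SVMs); it captures only the band-limited character of resting-state
#' fluctuations, not their spatial signature.
#'
#' @param band_hz frequency band in Hz, default `c(0.01, 0.1)`.
#' @param cutoff minimum in-band power fraction, default 0.5.
#' @return a classifier function `(timecourse, tr_seconds) -> logical`.
#' @export
spectral_classifier <- function(band_hz = c(0.01, 0.1), cutoff = 0.5) {
  force(band_hz); force(cutoff)
  function(timecourse, tr_seconds) {
    band_power_fraction(timecourse, tr_seconds, band_hz) > cutoff
  }
}

#' Classify components as neuronal or non-neuronal
#'
#' Applies a classifier to each component time-course. The classifier is a
#' pluggable function `(timecourse, tr_seconds) -> logical`, defaulting to
#' the [spectral_classifier] heuristic; an empty result is allowed.
#'
#' @param decomposition an [ic_decomposition].
#' @param classifier classifier function; default [spectral_classifier()].
#' @return character vector of component ids labeled neuronal.
#' @export
classify_neuronal <- function(decomposition,
                              classifier = spectral_classifier()) {
  keep <- vapply(seq_along(decomposition$component_ids), function(i) {
    isTRUE(classifier(decomposition$timecourses[i, ],
                      decomposition$tr_seconds))
  }, logical(1))
  decomposition$component_ids[keep]
}
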