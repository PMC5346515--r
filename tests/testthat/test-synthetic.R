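test_that("component courses are band-limited, decorrelated, reproducible", {
  cfg <- synthetic_config(n_timepoints = 200, seed = 40)
  ic <- make_component_timecourses(cfg)
  X <- ic$timecourses
  cors <- cor(t(X))
  expect_lt(max(abs(cors[upper.tri(cors)])), 1e-10)
  expect_equal(unname(apply(X, 1, sd)), rep(1, nrow(X)), tolerance = 1e-12)
  for (i in seq_len(nrow(X))) {
    expect_gt(band_power_fraction(X[i, ], cfg$tr_seconds, cfg$band_hz),
              0.99)
  }
  ic2 <- make_component_timecourses(cfg)
  expect_identical(ic$timecourses, ic2$timecourses)   # bitwise determinism
  expect_error(synthetic_config(tr_seconds = 2, band_hz = c(0.01, 0.3)),
               "Nyquist")
})

test_that("mixing plus noise honors the configured SNR", {
  cfg <- synthetic_config(n_regions = 12, n_components = 3,
                          n_timepoints = 400, snr = 10, seed = 41,
                          mixing = block_mixing(3, 12))
  ic <- make_component_timecourses(cfg)
  reg <- make_region_timecourses(cfg, ic)
  Y0 <- t(cfg$mixing) %*% ic$timecourses
  noise <- reg$series$values - Y0
  snr_emp <- apply(Y0, 1, var) / apply(noise, 1, var)
  expect_equal(median(snr_emp), 10, tolerance = 0.25)
  expect_identical(reg$mixing, cfg$mixing)
})

test_that("noiseless limit recovers the mixing exactly", {
  cfg <- synthetic_config(n_regions = 6, n_components = 2,
                          n_timepoints = 100, snr = 1e12, seed = 42,
                          mixing = rbind(c(2, -1, 0, 0, 1, 0),
                                         c(0, 0, 3, 1, 0, -2)))
  ic <- make_component_timecourses(cfg)
  reg <- make_region_timecourses(cfg, ic)
  tv <- fit_glm(reg$series, ic)
  expect_equal(unname(tv$betas), unname(cfg$mixing), tolerance = 1e-4)
})

test_that("recovered coefficients cover the truth at moderate SNR", {
  cfg0 <- synthetic_config(n_regions = 12, n_components = 3,
                           n_timepoints = 150, snr = 4,
                           mixing = block_mixing(3, 12))
  n_seeds <- 30
  hits <- 0; trials <- 0; null_below <- 0; null_trials <- 0
  for (s in seq_len(n_seeds)) {
    cfg <- synthetic_config(n_regions = 12, n_components = 3,
                            n_timepoints = 150, snr = 4, seed = 1000 + s,
                            mixing = cfg0$mixing)
    ic <- make_component_timecourses(cfg)
    reg <- make_region_timecourses(cfg, ic)
    tv <- fit_glm(reg$series, ic)
    se <- abs(tv$betas / tv$tvalues)
    ok <- abs(tv$betas - cfg$mixing) <= 3 * se
    hits <- hits + sum(ok); trials <- trials + length(ok)
    # zero-loading entries should sit below the significance threshold
    thr <- compute_t_threshold(tv$dof, 0.001)
    nul <- cfg$mixing == 0
    null_below <- null_below + sum(abs(tv$tvalues[nul]) < thr)
    null_trials <- null_trials + sum(nul)
  }
  expect_gte(hits / trials, 0.99)
  expect_gte(null_below / null_trials, 0.95)
})

test_that("painted volumes partition voxels and reproduce region courses", {
  cfg <- synthetic_config(n_regions = 10, n_components = 2,
                          n_timepoints = 60, volume_shape = c(8, 6, 5),
                          mixing = block_mixing(2, 10), seed = 43)
  ic <- make_component_timecourses(cfg)
  reg <- make_region_timecourses(cfg, ic)
  painted <- paint_volume(cfg, reg$series)

  lab <- painted$parcellation$labels
  expect_true(all(lab >= 1 & lab <= 10))               # full partition
  expect_length(painted$parcellation$region_ids, 10)
  expect_equal(dim(painted$bold), c(8, 6, 5, 60))

  back <- extract_region_timecourses(painted$bold, painted$parcellation,
                                     tr_seconds = 2)
  # voxel noise (sd 0.05) averages down across ~24 voxels per region
  expect_lt(max(abs(back$values - reg$series$values)), 0.1)
  expect_gt(cor(as.vector(back$values), as.vector(reg$series$values)),
            0.999)

  # spatial map of a component is its loading painted per region
  for (comp in 1:2) {
    map <- painted$spatial_maps[, , , comp]
    for (r in 1:10) {
      expect_true(all(map[lab == r] == cfg$mixing[comp, r]))
    }
  }
})

test_that("subjects are independent but cohort-level structure is shared", {
  cfg <- synthetic_config(n_regions = 12, n_components = 3,
                          n_timepoints = 100, seed = 44,
                          mixing = block_mixing(3, 12), n_subjects = 3)
  cohort <- simulate_cohort(cfg)
  expect_length(cohort, 3)
  expect_false(identical(cohort[[1]]$ic$timecourses,
                         cohort[[2]]$ic$timecourses))
  expect_identical(cohort[[1]]$mixing, cohort[[2]]$mixing)
})

test_that("fixture writing emits readable TSV and NIfTI artifacts", {
  cfg <- synthetic_config(n_regions = 4, n_components = 2,
                          n_timepoints = 50, volume_shape = c(4, 4, 2),
                          mixing = block_mixing(2, 4), n_subjects = 2,
                          seed = 45)
  out <- tempfile("fix")
  simulate_fixtures(cfg, out)
  expect_true(file.exists(file.path(out, "ground_truth.json")))
  ic <- read_ic_timecourses(file.path(out, "sub-01", "ic_timecourses.tsv"),
                            tr_seconds = 2)
  expect_equal(dim(ic$timecourses), c(2, 50))
  bold <- read_bold(file.path(out, "sub-01", "bold.nii.gz"))
  expect_equal(dim(bold)[4], 50)
  parc <- read_parcellation(file.path(out, "sub-01", "parcellation.nii.gz"))
  expect_length(parc$region_ids, 4)
})
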