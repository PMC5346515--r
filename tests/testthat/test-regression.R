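test_that("region extraction averages voxels exactly", {
  # singleton region: the row is that voxel's course
  lab <- array(0L, c(3, 3, 2))
  lab[1, 1, 1] <- 1L
  lab[2:3, 1, 1] <- 2L
  p <- parcellation_volume(lab)
  set.seed(2)
  bold <- array(rnorm(3 * 3 * 2 * 10), c(3, 3, 2, 10))
  y <- extract_region_timecourses(bold, p, tr_seconds = 2)
  expect_equal(unname(y$values[1, ]), bold[1, 1, 1, ])

  # two-voxel region with courses v and -v cancels to zero
  v <- rnorm(10)
  bold[2, 1, 1, ] <- v
  bold[3, 1, 1, ] <- -v
  y <- extract_region_timecourses(bold, p, tr_seconds = 2)
  expect_equal(unname(y$values[2, ]), rep(0, 10))
})

test_that("region extraction matches a per-voxel loop oracle", {
  set.seed(3)
  dims <- c(6, 5, 4)
  lab <- array(sample(0:10, prod(dims), replace = TRUE), dims)
  lab[1:11] <- 0:10                       # ensure every region occupied
  p <- parcellation_volume(lab)
  bold <- array(rnorm(prod(dims) * 15), c(dims, 15))
  y <- extract_region_timecourses(bold, p, tr_seconds = 2)
  for (r in p$region_ids) {
    vox <- which(lab == r)
    acc <- rep(0, 15)
    for (v in vox) {
      idx <- arrayInd(v, dims)
      acc <- acc + bold[idx[1], idx[2], idx[3], ]
    }
    expect_lt(max(abs(y$values[as.character(r), ] - acc / length(vox))),
              1e-12)
  }
  expect_error(
    extract_region_timecourses(array(0, c(2, 2, 2, 5)), p, 2), "grids")
})

test_that("exact fits recover coefficients and flag infinite t", {
  set.seed(4)
  x <- ic_decomposition(matrix(rnorm(40), 1), tr_seconds = 2)
  y <- region_timeseries(rbind(2 * x$timecourses[1, ] + 5, rnorm(40)),
                         region_ids = 1:2, tr_seconds = 2)
  tv <- fit_glm(y, x)
  expect_equal(unname(tv$betas[1, 1]), 2, tolerance = 1e-10)
  expect_equal(tv$residual_variance[1], 0)
  expect_true(is.infinite(tv$tvalues[1, 1]) && tv$tvalues[1, 1] > 0)
  expect_true(tv$exact_fit[1])
  expect_false(tv$exact_fit[2])
})

test_that("a region orthogonal to the design has near-zero coefficients", {
  set.seed(5)
  X <- matrix(rnorm(2 * 80), 2)
  D <- cbind(t(X), 1)
  raw <- rnorm(80)
  orth <- raw - D %*% solve(crossprod(D), crossprod(D, raw))  # residualized
  y <- region_timeseries(rbind(as.vector(orth), rnorm(80)),
                         region_ids = 1:2, tr_seconds = 2)
  tv <- fit_glm(y, ic_decomposition(X, tr_seconds = 2))
  expect_lt(max(abs(tv$betas[, 1])), 1e-12)
  expect_lt(max(abs(tv$tvalues[, 1])), 1e-10)
})

test_that("betas and t-values match the normal-equations oracle", {
  set.seed(6)
  for (i in 1:10) {
    n <- sample(1:4, 1); r <- sample(3:12, 1); p <- sample(40:150, 1)
    X <- matrix(rnorm(n * p), n)
    Y <- matrix(rnorm(r * p), r)
    tv <- fit_glm(region_timeseries(Y, seq_len(r), 2),
                  ic_decomposition(X, tr_seconds = 2))
    o <- glm_oracle(Y, X)
    expect_lt(max(abs(tv$betas - o$betas)), 1e-8)
    expect_lt(max(abs(tv$tvalues - o$tvalues)), 1e-8)
    expect_equal(tv$dof, o$dof)
  }
})

test_that("collinear components are reported and constants dropped", {
  set.seed(7)
  base <- rnorm(50)
  X <- rbind(base, 2 * base)
  expect_error(fit_glm(region_timeseries(matrix(rnorm(100), 2), 1:2, 2),
                       ic_decomposition(X, tr_seconds = 2,
                                        component_ids = c("a", "b"))),
               "rank-deficient")
  Xok <- matrix(rnorm(2 * 50), 2)
  Y <- rbind(rep(3, 50), rnorm(50))
  expect_warning(tv <- fit_glm(region_timeseries(Y, 1:2, 2),
                               ic_decomposition(Xok, tr_seconds = 2)),
                 "constant")
  expect_identical(tv$region_ids, 2L)
})

test_that("t-values scale-invariant in Y magnitude, sign-flipped on negation", {
  set.seed(8)
  X <- matrix(rnorm(3 * 60), 3)
  Y <- matrix(rnorm(2 * 60), 2)
  base <- fit_glm(region_timeseries(Y, 1:2, 2),
                  ic_decomposition(X, tr_seconds = 2))
  scaled <- fit_glm(region_timeseries(Y * c(7.3, 0.002), 1:2, 2),
                    ic_decomposition(X, tr_seconds = 2))
  expect_equal(scaled$tvalues, base$tvalues, tolerance = 1e-9)
  neg <- fit_glm(region_timeseries(Y * c(-1, 1), 1:2, 2),
                 ic_decomposition(X, tr_seconds = 2))
  expect_equal(neg$tvalues[, 1], -base$tvalues[, 1], tolerance = 1e-9)
})

test_that("coefficient estimates are unbiased on synthetic signal", {
  set.seed(9)
  n <- 5; r <- 8; p <- 150
  beta_true <- matrix(rnorm(n * r), n)
  X <- matrix(rnorm(n * p), n)
  reps <- 200
  err <- array(NA_real_, c(reps, n, r))
  for (k in seq_len(reps)) {
    Y <- t(X) %*% beta_true + rnorm(r * p, sd = 1.5)
    tv <- fit_glm(region_timeseries(t(Y), seq_len(r), 2),
                  ic_decomposition(X, tr_seconds = 2))
    err[k, , ] <- tv$betas - beta_true
  }
  mean_err <- apply(err, c(2, 3), mean)
  se_mean <- apply(err, c(2, 3), sd) / sqrt(reps)
  z <- mean_err / se_mean
  # global unbiasedness: the average standardized bias over all n x r
  # coefficients is a single N(0, 1/sqrt(nr)) quantity under H0
  expect_lt(abs(mean(z)), 2 / sqrt(length(z)))
  expect_lt(max(abs(z)), 4.5)
})

test_that("the t threshold agrees with published Student-t tables", {
  expect_equal(compute_t_threshold(10, 0.05), 1.812, tolerance = 5e-4)
  expect_equal(compute_t_threshold(100, 0.001), 3.174, tolerance = 5e-4)
  expect_equal(compute_t_threshold(266, 0.001), 3.121, tolerance = 5e-4)
  expect_equal(compute_t_threshold(37, 0.5), 0)
  # large-dof limit approaches the normal quantile
  expect_equal(compute_t_threshold(1e6, 0.001), qnorm(0.999),
               tolerance = 1e-4)
  expect_error(compute_t_threshold(0, 0.001), "dof")
  expect_error(compute_t_threshold(10, 1.5), "p must")
})
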