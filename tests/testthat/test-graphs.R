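test_that("edge weighting identities hold across signs and magnitudes", {
  grid <- c(-6, -3.5, -1, -0.25, 0.25, 1, 3.5, 6)
  for (ta in grid) for (tb in grid) {
    w <- edge_weight(ta, tb)
    wa <- edge_weight_anticorr(ta, tb)
    same <- sign(ta) == sign(tb)
    expect_equal(w, if (same) 2 * min(abs(ta), abs(tb)) else 0)
    expect_equal(wa, if (same) 0 else 2 * min(abs(ta), abs(tb)))
    expect_equal(w + wa, 2 * min(abs(ta), abs(tb)))
    expect_gte(w, 0); expect_gte(wa, 0)
    expect_false(w > 0 && wa > 0)   # disjoint supports
  }
  expect_equal(edge_weight(5, 3), 6)
  expect_equal(edge_weight(5, -3), 0)
  expect_equal(edge_weight_anticorr(5, -3), 6)
  expect_equal(edge_weight_anticorr(5, 3), 0)
  set.seed(10)
  t100 <- rnorm(100, sd = 4)
  expect_equal(edge_weight(t100, t100), 2 * abs(t100))
  expect_error(edge_weight(Inf, 1), "finite")
})

make_tv_fixture <- function(tvec, ids = seq_along(tvec)) {
  n <- 1; p <- 50
  tvalue_table(betas = matrix(tvec, 1), tvalues = matrix(tvec, 1),
               residual_variance = rep(1, length(tvec)),
               dof = p - n - 1, n_volumes = p, n_components = n,
               region_ids = ids, component_ids = "IC01")
}

test_that("subject graphs keep exactly the doubly-significant same-sign pairs", {
  tv <- make_tv_fixture(c(4, 4, -4, 1))
  g <- build_subject_graph(tv, "IC01", "correlation", t_threshold = 3)
  expect_equal(sum(g$weights > 0) / 2, 1)
  expect_equal(g$weights[1, 2], 8)
  expect_equal(g$threshold_applied, 6)

  ga <- build_subject_graph(tv, "IC01", "anticorrelation", t_threshold = 3)
  expect_equal(sum(ga$weights > 0) / 2, 2)
  expect_equal(ga$weights[1, 3], 8)
  expect_equal(ga$weights[2, 3], 8)
  expect_equal(ga$weights[1, 2], 0)

  # nothing survives when every |t| is sub-threshold
  gsub <- build_subject_graph(make_tv_fixture(c(1, 2, -2.5, 0.5)), "IC01",
                              "correlation", t_threshold = 3)
  expect_equal(sum(gsub$weights), 0)
  expect_error(build_subject_graph(tv, "IC99", "correlation", 3), "unknown")
})

test_that("thresholded edge sets equal the brute-force significance rule", {
  set.seed(11)
  for (i in 1:20) {
    tvec <- rnorm(12, sd = 4)
    thr <- runif(1, 1, 5)
    tv <- make_tv_fixture(tvec)
    for (flavor in c("correlation", "anticorrelation")) {
      g <- build_subject_graph(tv, "IC01", flavor, t_threshold = thr)
      expect_identical(unname(g$weights > 0), edges_brute(tvec, thr, flavor))
    }
  }
})

test_that("raising the threshold only removes edges", {
  set.seed(12)
  tvec <- rnorm(15, sd = 4)
  tv <- make_tv_fixture(tvec)
  prev <- build_subject_graph(tv, "IC01", "correlation", 0.5)
  for (thr in c(1, 2, 3, 4, 6)) {
    cur <- build_subject_graph(tv, "IC01", "correlation", thr)
    expect_true(all(prev$weights[cur$weights > 0] > 0))
    expect_lte(sum(cur$weights > 0), sum(prev$weights > 0))
    prev <- cur
  }
})

test_that("ties at exactly the threshold are kept", {
  tv <- make_tv_fixture(c(3, 3, 5))
  g <- build_subject_graph(tv, "IC01", "correlation", t_threshold = 3)
  expect_equal(sum(g$weights > 0) / 2, 3)   # all pairs have W == 6 or more
  expect_equal(min(g$weights[g$weights > 0]), 6)
})

test_that("group aggregation applies the presence-fraction rule", {
  mk <- function(present) {
    w <- matrix(0, 2, 2)
    if (present) { w[1, 2] <- w[2, 1] <- 10 }
    subject_graph(w, 1:2, "IC01", "correlation")
  }
  # 4 of 15 subjects clears 25%, 3 of 15 does not
  g4 <- aggregate_group(c(lapply(1:4, function(i) mk(TRUE)),
                          lapply(1:11, function(i) mk(FALSE))), 0.25)
  expect_true(g4$adjacency[1, 2])
  expect_equal(g4$presence_counts[1, 2], 4L)
  expect_equal(g4$mean_weights[1, 2], 10)
  g3 <- aggregate_group(c(lapply(1:3, function(i) mk(TRUE)),
                          lapply(1:12, function(i) mk(FALSE))), 0.25)
  expect_false(g3$adjacency[1, 2])
})

test_that("presence fraction extremes give union and intersection", {
  set.seed(13)
  graphs <- lapply(1:5, function(i) random_thresholded_graph(8, thr = 5))
  supports <- lapply(graphs, function(g) g$weights > 0)
  union_o <- unname(Reduce(`|`, supports))
  inter_o <- unname(Reduce(`&`, supports))
  expect_identical(unname(aggregate_group(graphs, 1 / 5)$adjacency), union_o)
  expect_identical(unname(aggregate_group(graphs, 1.0)$adjacency), inter_o)
  # identical graphs across subjects: group support equals any subject's
  same <- lapply(1:5, function(i) graphs[[1]])
  expect_identical(unname(aggregate_group(same, 0.25)$adjacency),
                   unname(supports[[1]]))
  expect_error(aggregate_group(list(graphs[[1]],
                                    random_thresholded_graph(9)), 0.25),
               "mismatched")
})

test_that("classical network matches a direct pairwise-correlation oracle", {
  cfg <- synthetic_config(n_regions = 20, n_components = 2,
                          n_timepoints = 80, volume_shape = c(6, 6, 4),
                          mixing = rbind(seq(0.5, 2, length.out = 20),
                                         seq(2, -2, length.out = 20)),
                          seed = 14)
  sub <- simulate_subject(cfg, 1)
  dof <- 80 - 2 - 1
  cn <- build_classical_network(sub$ic, sub$ic$component_ids,
                                sub$parcellation, t_threshold = 3.2,
                                dof = dof)
  # oracle: region-average the reconstruction by hand, correlate pairwise
  maps <- matrix(sub$ic$spatial_maps, ncol = 2)
  recon <- maps %*% sub$ic$timecourses
  lab <- as.vector(sub$parcellation$labels)
  Y <- t(vapply(1:20, function(r) colMeans(recon[lab == r, , drop = FALSE]),
                numeric(80)))
  suppressWarnings({
    for (a in 1:19) for (b in (a + 1):20) {
      r_ab <- cor(Y[a, ], Y[b, ])
      t_ab <- r_ab * sqrt(dof / (1 - r_ab^2))
      if (is.finite(t_ab) && t_ab >= 3.2) {
        expect_equal(cn$weights[a, b], 2 * t_ab, tolerance = 1e-10)
      } else if (is.finite(t_ab)) {
        expect_equal(cn$weights[a, b], 0)
      }
    }
  })
})

test_that("classical network handles perfect and orthogonal regions", {
  # one component, constant map over two regions: r = 1, edge retained
  cfg <- synthetic_config(n_regions = 2, n_components = 1,
                          n_timepoints = 40, volume_shape = c(4, 4, 2),
                          mixing = matrix(1, 1, 2), seed = 15)
  sub <- simulate_subject(cfg, 1)
  expect_warning(
    cn <- build_classical_network(sub$ic, sub$ic$component_ids,
                                  sub$parcellation, t_threshold = 3),
    "perfectly correlated")
  expect_true(is.infinite(cn$weights[1, 2]))

  # two regions on orthogonal components: r ~ 0, no edge
  cfg2 <- synthetic_config(n_regions = 2, n_components = 2,
                           n_timepoints = 60, volume_shape = c(4, 4, 2),
                           mixing = rbind(c(1, 0), c(0, 1)), seed = 16)
  sub2 <- simulate_subject(cfg2, 1)
  cn2 <- build_classical_network(sub2$ic, sub2$ic$component_ids,
                                 sub2$parcellation, t_threshold = 3)
  expect_equal(cn2$weights[1, 2], 0)
  ic_nomap <- ic_decomposition(sub2$ic$timecourses, 2)
  expect_error(build_classical_network(ic_nomap, "IC01", sub2$parcellation, 3),
               "spatial maps")
})
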