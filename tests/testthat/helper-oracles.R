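# Independent oracles used across test files. These deliberately avoid the
# package's own code paths: brute-force loops, normal equations, exhaustive
# enumeration.

# OLS betas and t-values via explicit normal equations and (D'D)^-1.
glm_oracle <- function(Y, X) {
  D <- cbind(t(X), 1)
  DtD_inv <- solve(t(D) %*% D)
  B <- DtD_inv %*% t(D) %*% t(Y)            # (N+1) x R
  resid <- t(Y) - D %*% B
  dof <- ncol(Y) - nrow(X) - 1
  s2 <- colSums(resid^2) / dof
  n <- nrow(X)
  tv <- matrix(NA_real_, n, nrow(Y))
  for (i in seq_len(n)) {
    ci <- rep(0, n + 1); ci[i] <- 1
    denom <- sqrt(s2 * drop(t(ci) %*% DtD_inv %*% ci))
    tv[i, ] <- B[i, ] / denom
  }
  list(betas = B[seq_len(n), , drop = FALSE], tvalues = tv, dof = dof)
}

# Mean-inside minus mean-outside by an explicit voxel loop.
gof_oracle <- function(map, mask) {
  s_in <- 0; n_in <- 0; s_out <- 0; n_out <- 0
  for (v in seq_along(map)) {
    if (mask[v] != 0) { s_in <- s_in + map[v]; n_in <- n_in + 1 }
    else { s_out <- s_out + map[v]; n_out <- n_out + 1 }
  }
  s_in / n_in - s_out / n_out
}

# Best total GOF over all injective template -> component assignments,
# allowing any template to stay absent; only pairs with GOF > 0 count.
assignment_oracle <- function(gof) {
  tn <- ncol(gof)
  best <- -Inf
  recurse <- function(j, used, total) {
    if (j > tn) { best <<- max(best, total); return(invisible()) }
    recurse(j + 1, used, total)             # template j absent
    for (i in seq_len(nrow(gof))) {
      if (!(i %in% used) && gof[i, j] > 0) {
        recurse(j + 1, c(used, i), total + gof[i, j])
      }
    }
  }
  recurse(1, integer(0), 0)
  best
}

# Greedy assignment: repeatedly take the best remaining positive pair.
greedy_assignment_total <- function(gof) {
  total <- 0
  repeat {
    if (all(gof <= 0)) break
    ij <- which(gof == max(gof), arr.ind = TRUE)[1, ]
    total <- total + gof[ij[1], ij[2]]
    gof[ij[1], ] <- -Inf
    gof[, ij[2]] <- -Inf
  }
  total
}

# Triangle count by exhaustive 3-subset enumeration on an adjacency matrix.
triangles_enum <- function(adj) {
  n <- nrow(adj)
  cnt <- 0
  if (n < 3) return(0)
  for (a in 1:(n - 2)) for (b in (a + 1):(n - 1)) for (d in (b + 1):n) {
    if (adj[a, b] && adj[b, d] && adj[a, d]) cnt <- cnt + 1
  }
  cnt
}

# Edge set of the thresholded subject graph by the brute-force rule:
# both |t| >= thr and the flavor's sign condition, checked pair by pair.
edges_brute <- function(tv, thr, flavor) {
  r <- length(tv)
  e <- matrix(FALSE, r, r)
  for (a in seq_len(r)) for (b in seq_len(r)) {
    if (a == b) next
    ok <- abs(tv[a]) >= thr && abs(tv[b]) >= thr
    samesign <- sign(tv[a]) == sign(tv[b]) && sign(tv[a]) != 0
    e[a, b] <- ok && if (flavor == "correlation") samesign else
      (sign(tv[a]) * sign(tv[b]) < 0)
  }
  e
}

# Random symmetric nonnegative weight matrix whose nonzero entries all
# clear `thr`, zero diagonal: a valid thresholded subject graph.
random_thresholded_graph <- function(r, thr = 6, p_edge = 0.3,
                                     component_id = "ICxx") {
  w <- matrix(0, r, r)
  ut <- which(upper.tri(w))
  on <- ut[stats::runif(length(ut)) < p_edge]
  w[on] <- thr + stats::rexp(length(on))
  w <- w + t(w)
  subject_graph(w, seq_len(r), component_id = component_id,
                flavor = "correlation", threshold_applied = thr)
}

edge_set_ids <- function(weights_or_adj, ids = seq_len(nrow(weights_or_adj))) {
  idx <- which(weights_or_adj & upper.tri(weights_or_adj), arr.ind = TRUE)
  sort(paste(ids[idx[, 1]], ids[idx[, 2]], sep = "-"))
}

jaccard_edges <- function(a, b) {
  ea <- edge_set_ids(a); eb <- edge_set_ids(b)
  if (length(union(ea, eb)) == 0) return(1)
  length(intersect(ea, eb)) / length(union(ea, eb))
}
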