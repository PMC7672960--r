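# Independent oracles used across the suite. These deliberately take the
# dumbest correct route (brute force, dense triple loops, long-run plain
# proximal steps) so they share no code path with the implementation.

# All-pairs shortest paths by Floyd-Warshall on a dense length matrix.
fw_distances <- function(n, edges) {
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (e in seq_len(nrow(edges))) {
    i <- edges$from[e]; j <- edges$to[e]; w <- edges$length[e]
    d[i, j] <- min(d[i, j], w)
    d[j, i] <- min(d[j, i], w)
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      dk <- d[i, k] + d[k, ]
      d[i, ] <- pmin(d[i, ], dk)
    }
  }
  d
}

fw_nodal_spl <- function(net) {
  d <- fw_distances(net$n_nodes, net$edges)
  diag(d) <- NA
  out <- apply(d, 1, function(row) {
    reach <- row[is.finite(row)]
    if (!length(reach)) 0 else mean(reach)
  })
  unname(out)
}

# Random symmetric correlation-like matrix with unit diagonal.
random_conn <- function(n) {
  r <- matrix(runif(n * n, -1, 1), n, n)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}

# Long-run plain proximal gradient (ISTA) with a conservative step,
# used as the reference solver for the group LASSO.
ista_reference <- function(problem, lambda, iters = 20000L) {
  p <- problem$p; tt <- problem$n_tasks
  lip <- 2 * max(vapply(problem$x_list, function(x) norm(x, "2")^2,
                        numeric(1)))
  step <- 0.5 / lip
  W <- matrix(0, p, tt)
  for (it in seq_len(iters)) {
    G <- vapply(seq_len(tt), function(t) {
      x <- problem$x_list[[t]]
      drop(2 * crossprod(x, x %*% W[, t] - problem$y))
    }, numeric(p))
    V <- W - step * G
    rn <- sqrt(rowSums(V^2))
    sc <- ifelse(rn > 0, pmax(0, 1 - step * lambda / rn), 0)
    W <- V * sc
  }
  W
}

# Row-wise subgradient optimality residual for the group-LASSO solution.
glasso_kkt_residual <- function(W, problem, lambda) {
  G <- vapply(seq_len(problem$n_tasks), function(t) {
    x <- problem$x_list[[t]]
    drop(2 * crossprod(x, x %*% W[, t] - problem$y))
  }, numeric(problem$p))
  G <- as.matrix(G)
  rn <- sqrt(rowSums(W^2))
  res <- numeric(problem$p)
  for (pp in seq_len(problem$p)) {
    if (rn[pp] > 1e-10) {
      res[pp] <- sqrt(sum((G[pp, ] + lambda * W[pp, ] / rn[pp])^2))
    } else {
      res[pp] <- max(0, sqrt(sum(G[pp, ]^2)) - lambda)
    }
  }
  max(res)
}

# AUC by explicit comparison of every positive/negative score pair,
# half credit for ties.
auc_pairs_oracle <- function(scores, positive) {
  sp <- scores[positive]; sn <- scores[!positive]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# Random two-task selection problem with +/-1 labels.
random_problem <- function(seed, n = 40, p = 15, tt = 2, lambda = 0) {
  withr::with_seed(seed, {
    xs <- lapply(seq_len(tt), function(t) matrix(rnorm(n * p), n, p))
    y <- sample(c(-1, 1), n, replace = TRUE)
    selection_problem(xs, y, lambda = lambda)
  })
}

# Small planted-support multi-task instance: first `k` features carry the
# signal in both tasks, the rest are noise.
planted_instance <- function(seed, n = 400, p = 30, k = 5, snr = 10) {
  withr::with_seed(seed, {
    x1 <- matrix(rnorm(n * p), n, p)
    x2 <- matrix(rnorm(n * p), n, p)
    w <- c(rep(snr / sqrt(k), k), rep(0, p - k)) * sample(c(-1, 1), p, TRUE)
    lat <- (x1 %*% w + x2 %*% w) / 2 + rnorm(n, 0, 1)
    y <- ifelse(lat > 0, 1, -1)
    list(problem = selection_problem(list(x1, x2), y), support = seq_len(k))
  })
}

# Tiny deterministic cohort for fast end-to-end tests.
tiny_cohort <- function(seed = 1, n_per_class = 10, n_regions = 20,
                        n_timepoints = 40, d = 1.5) {
  generate_cohort(cohort_config(
    n_per_class = n_per_class, n_regions = n_regions,
    n_timepoints = n_timepoints, planted_regions = seq_len(4),
    gmv_effect_d = d, seed = seed))
}
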