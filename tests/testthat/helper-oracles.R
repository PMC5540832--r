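# Brute-force reference implementations used to validate the graph metrics.
# Deliberately naive: exhaustive enumeration, Floyd-Warshall, and direct
# definitional formulas, independent of the package's code paths.

oracle_cost <- function(W, weighted) {
  n <- nrow(W)
  cost <- matrix(Inf, n, n)
  cost[W > 0] <- if (weighted) 1 / W[W > 0] else 1
  diag(cost) <- 0
  cost
}

oracle_dists <- function(W, weighted) {
  d <- oracle_cost(W, weighted)
  n <- nrow(d)
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_path_metrics <- function(W, weighted) {
  d <- oracle_dists(W, weighted)
  off <- d[upper.tri(d)]
  fin <- is.finite(off)
  list(L = if (any(fin)) mean(off[fin]) else NaN,
       E = mean(ifelse(fin, 1 / off, 0)))
}

oracle_clustering <- function(W, weighted) {
  n <- nrow(W)
  A <- (W > 0) * 1
  k <- rowSums(A)
  Wh <- if (weighted && max(W) > 0) W / max(W) else W
  C <- numeric(n)
  for (i in seq_len(n)) {
    if (k[i] < 2) next
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == h || j == i || h == i) next
      if (A[i, j] > 0 && A[i, h] > 0 && A[j, h] > 0)
        acc <- acc + if (weighted)
          (Wh[i, j] * Wh[i, h] * Wh[j, h])^(1 / 3) else 1
    }
    C[i] <- acc / (k[i] * (k[i] - 1))
  }
  C
}

# Betweenness by shortest-path counting from the distance matrix: for each
# unordered pair {s,t}, sigma_st(v)/sigma_st summed over interior nodes v.
oracle_betweenness <- function(W, weighted) {
  n <- nrow(W)
  cost <- oracle_cost(W, weighted)
  d <- oracle_dists(W, weighted)
  tol <- 1e-10 * max(1, max(d[is.finite(d)]))
  # sigma[s, u]: number of shortest s-u paths
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    for (u in order(d[s, ])) {
      if (u == s || !is.finite(d[s, u])) next
      preds <- which(W[, u] > 0 & is.finite(d[s, ]) &
                       abs(d[s, ] + cost[, u] - d[s, u]) < tol)
      sigma[s, u] <- sum(sigma[s, preds])
    }
  }
  bc <- numeric(n)
  for (s in seq_len(n - 1L)) for (t in (s + 1L):n) {
    if (!is.finite(d[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
          abs(d[s, v] + d[v, t] - d[s, t]) < tol)
        bc[v] <- bc[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
  }
  bc
}

# All set partitions of 1..n as restricted-growth strings.
all_partitions <- function(n) {
  out <- list()
  rec <- function(a, i, mx) {
    if (i > n) {
      out[[length(out) + 1L]] <<- a
      return()
    }
    for (v in seq_len(mx + 1L)) rec(c(a, v), i + 1L, max(mx, v))
  }
  rec(integer(0), 1L, 0L)
  out
}

oracle_q_of <- function(W, memb) {
  m2 <- sum(W)
  if (m2 == 0) return(0)
  s <- rowSums(W)
  sum((W - outer(s, s) / m2)[outer(memb, memb, "==")]) / m2
}

oracle_modularity <- function(W) {
  max(vapply(all_partitions(nrow(W)), oracle_q_of, numeric(1L), W = W))
}

# Random symmetric test graph, optionally weighted.
random_graph <- function(n, density, weighted = FALSE) {
  A <- matrix(0, n, n)
  low <- lower.tri(A)
  A[low] <- as.numeric(stats::runif(sum(low)) < density)
  if (weighted) A[low] <- A[low] * stats::runif(sum(low), 0.5, 5)
  A + t(A)
}
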