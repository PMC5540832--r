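# Pull the weight matrix and mode out of either graph class.
graph_parts <- function(g) {
  if (inherits(g, "connectivity_matrix"))
    list(W = g$weights, weighted = TRUE, parc = g$parcellation)
  else if (inherits(g, "binary_adjacency"))
    list(W = g$adjacency, weighted = FALSE, parc = g$parcellation)
  else if (is.matrix(g))  # bare matrix: weighted iff non-binary entries
    list(W = g, weighted = !all(g %in% c(0, 1)), parc = NULL)
  else stop("expected a connectivity_matrix, binary_adjacency, or matrix")
}

as_igraph <- function(W) {
  igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

# Edge cost for shortest paths: unit on binary graphs, 1/weight on weighted
# (stronger connections are shorter). Returns NA for unweighted so igraph
# ignores the weight attribute.
edge_costs <- function(ig, weighted) {
  if (!weighted) return(NA)
  1 / igraph::E(ig)$weight
}

dist_matrix <- function(W, weighted) {
  ig <- as_igraph(W)
  igraph::distances(ig, weights = edge_costs(ig, weighted))
}

#' Characteristic path length and efficiency
#'
#' Shortest-path distances are computed over unit edge lengths on binary
#' graphs and over inverse weights (1/w) on weighted graphs. The
#' characteristic path length L is the mean distance over all connected
#' distinct node pairs (disconnected pairs are excluded, and their fraction
#' attached as an attribute); the global efficiency E is the mean of 1/d
#' over all distinct pairs with 1/Inf := 0, so it handles disconnected
#' networks natively.
#'
#' @param g a \code{connectivity_matrix}, \code{binary_adjacency}, or matrix.
#' @return list with \code{char_path_length} (NaN on an edgeless graph) and
#'   \code{efficiency}; the former carries attribute
#'   \code{disconnected_fraction}.
#' @export
path_metrics <- function(g) {
  p <- graph_parts(g)
  n <- nrow(p$W)
  stopifnot(n >= 2)
  d <- dist_matrix(p$W, p$weighted)
  off <- d[upper.tri(d)]
  finite <- is.finite(off)
  L <- if (any(finite)) mean(off[finite]) else NaN
  attr(L, "disconnected_fraction") <- mean(!finite)
  E <- mean(ifelse(finite, 1 / off, 0))
  list(char_path_length = L, efficiency = E)
}

#' Clustering coefficients
#'
#' Binary graphs: C_i = 2 t_i / (k_i (k_i - 1)) with t_i the number of
#' triangles through node i. Weighted graphs: the Onnela geometric-mean
#' formulation, with weights normalized by the maximum weight in the graph:
#' C_i = 2 / (k_i (k_i - 1)) * sum over neighbour pairs of
#' (w'_ij w'_ih w'_jh)^(1/3), where k_i is the binary degree. Nodes of
#' degree < 2 get C_i = 0 and are kept in the mean.
#'
#' @param g a \code{connectivity_matrix}, \code{binary_adjacency}, or matrix.
#' @return list with \code{clustering} (per-node vector) and
#'   \code{mean_clustering}.
#' @export
clustering_metrics <- function(g) {
  p <- graph_parts(g)
  W <- p$W
  A <- (W > 0) * 1
  k <- rowSums(A)
  if (p$weighted) {
    mx <- max(W)
    Wn <- if (mx > 0) (W / mx)^(1 / 3) else W
    tri <- diag(Wn %*% Wn %*% Wn)
  } else {
    tri <- diag(A %*% A %*% A)
  }
  denom <- k * (k - 1)
  C <- ifelse(denom > 0, tri / denom, 0)
  names(C) <- rownames(W)
  list(clustering = C, mean_clustering = mean(C))
}

#' Betweenness centrality
#'
#' For each node v, the sum over unordered pairs {s,t} (s, t != v) of the
#' fraction of shortest s-t paths that pass through v. Unnormalized raw
#' counts; weighted graphs use 1/w edge lengths.
#'
#' @inheritParams path_metrics
#' @return per-node numeric vector.
#' @export
betweenness_centrality <- function(g) {
  p <- graph_parts(g)
  ig <- as_igraph(p$W)
  bc <- igraph::betweenness(ig, directed = FALSE,
                            weights = edge_costs(ig, p$weighted),
                            normalized = FALSE)
  stats::setNames(as.numeric(bc), rownames(p$W))
}

#' Node strength
#'
#' Sum of the weights of the edges incident to each node; on a binary graph
#' this is the degree.
#'
#' @inheritParams path_metrics
#' @return per-node numeric vector.
#' @export
node_strength <- function(g) {
  p <- graph_parts(g)
  rowSums(p$W)
}

#' Modularity of the best community partition
#'
#' Newman-Girvan modularity Q of the best partition found by a seeded
#' multi-level (Louvain) search with \code{restarts} random restarts, taking
#' the maximum Q. Weighted graphs use their weights as affinities.
#' Deterministic given the seed. An edgeless graph has Q = 0 under the
#' singleton partition.
#'
#' @inheritParams path_metrics
#' @param seed integer seed for the restart randomization.
#' @param restarts number of restarts (default 10).
#' @return list with \code{q} and \code{partition} (integer membership).
#' @export
modularity_partition <- function(g, seed = 1L, restarts = 10L) {
  p <- graph_parts(g)
  n <- nrow(p$W)
  ig <- as_igraph(p$W)
  if (igraph::ecount(ig) == 0L)
    return(list(q = 0, partition = seq_len(n)))
  w <- igraph::E(ig)$weight
  best_q <- -Inf
  best_m <- NULL
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old))
  n <- nrow(p$W)
  for (r in seq_len(restarts)) {
    set.seed(seed + r - 1L)
    starts <- list(
      as.integer(igraph::membership(igraph::cluster_louvain(ig, weights = w))))
    if (n <= 16L) {
      # on small graphs the multi-level pass can lock in a bad coarse
      # merge; extra cheap starts let the refinement escape it
      starts <- c(starts, list(seq_len(n)),               # all singletons
                  replicate(5L, sample.int(max(2L, min(n, 8L)), n,
                                           replace = TRUE),
                            simplify = FALSE))            # random blocks
    }
    for (m0 in starts) {
      memb <- refine_partition(p$W, m0)
      q <- igraph::modularity(ig, memb, weights = w)
      if (q > best_q) {
        best_q <- q
        best_m <- memb
      }
    }
  }
  list(q = best_q, partition = relabel_partition(best_m))
}

# Greedy refinement of a flat partition: sweeps of single-node moves (to
# any existing community or a fresh singleton) alternate with pairwise
# community merges, until neither improves Q. Polishes the coarse merges a
# multi-level pass can lock in.
refine_partition <- function(W, memb, tol = 1e-12) {
  m2 <- sum(W)
  if (m2 == 0) return(memb)
  s <- rowSums(W)
  n <- nrow(W)
  repeat {
    improved <- FALSE
    # single-node moves
    repeat {
      moved <- FALSE
      for (v in seq_len(n)) {
        a <- memb[v]
        k_to <- rowsum(W[v, ], memb)[, 1L]
        S <- rowsum(s, memb)[, 1L]
        comms <- as.integer(names(k_to))
        ia <- match(a, comms)
        dq <- 2 * (k_to - k_to[[ia]]) / m2 -
          ((S[[ia]] - s[v])^2 + (S + s[v])^2 - S[[ia]]^2 - S^2) / m2^2
        dq[ia] <- 0
        dq_single <- -2 * k_to[[ia]] / m2 -
          ((S[[ia]] - s[v])^2 + s[v]^2 - S[[ia]]^2) / m2^2
        ib <- which.max(dq)
        if (dq[[ib]] > tol && dq[[ib]] >= dq_single) {
          memb[v] <- comms[ib]
          moved <- TRUE
        } else if (dq_single > tol && sum(memb == a) > 1L) {
          memb[v] <- setdiff(seq_len(n), unique(memb))[1L]
          moved <- TRUE
        }
      }
      if (!moved) break
      improved <- TRUE
    }
    # pairwise community merges
    repeat {
      comms <- unique(memb)
      if (length(comms) < 2L) break
      S <- vapply(comms, function(c) sum(s[memb == c]), numeric(1L))
      best_dq <- tol
      best_ab <- NULL
      for (i in seq_along(comms)[-length(comms)]) {
        for (j in (i + 1L):length(comms)) {
          W_ab <- sum(W[memb == comms[i], memb == comms[j]])
          dq <- 2 * W_ab / m2 - 2 * S[i] * S[j] / m2^2
          if (dq > best_dq) { best_dq <- dq; best_ab <- c(i, j) }
        }
      }
      if (is.null(best_ab)) break
      memb[memb == comms[best_ab[2L]]] <- comms[best_ab[1L]]
      improved <- TRUE
    }
    if (!improved) break
  }
  memb
}

# Renumber communities 1..k in order of first appearance.
relabel_partition <- function(memb) {
  as.integer(factor(memb, levels = unique(memb)))
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Small-world index
#'
#' sigma = (C / C_null) / (L / L_null), where C and L are the mean
#' clustering coefficient and characteristic path length of the graph, and
#' C_null, L_null their means over \code{n_null} degree-preserving rewired
#' null graphs (double edge swaps, 10 |E| attempted swaps each). On weighted
#' graphs the original edge weights are randomly reassigned to the rewired
#' edges. sigma > 1 indicates small-world organization: clustering above,
#' and path length near, the random expectation.
#'
#' @inheritParams path_metrics
#' @param n_null number of null graphs (default 100).
#' @param seed integer seed; the result is deterministic given the seed.
#' @return sigma (NaN with a warning if the null ensemble has zero mean
#'   clustering).
#' @export
small_world_index <- function(g, n_null = 100L, seed = 1L) {
  p <- graph_parts(g)
  stopifnot(n_null >= 1L)
  C <- clustering_metrics(g)$mean_clustering
  L <- as.numeric(path_metrics(g)$char_path_length)
  ig <- as_igraph(p$W)
  m <- igraph::ecount(ig)
  if (m == 0L) {
    warning("edgeless graph: small-world index undefined")
    return(NaN)
  }
  w <- igraph::E(ig)$weight
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old))
  set.seed(seed)
  Cn <- Ln <- numeric(n_null)
  for (b in seq_len(n_null)) {
    rg <- igraph::rewire(ig, igraph::keeping_degseq(niter = 10L * m))
    Wn <- igraph::as_adjacency_matrix(rg, sparse = FALSE)
    if (p$weighted) {
      # same degree sequence, original weights shuffled over the new edges
      idx <- which(lower.tri(Wn) & Wn > 0)
      Wn[idx] <- sample(w)
      Wn[upper.tri(Wn)] <- 0
      Wn <- Wn + t(Wn)
      d <- dist_matrix(Wn, weighted = TRUE)
    } else {
      d <- igraph::distances(rg, weights = NA)
    }
    Cn[b] <- clustering_metrics(Wn)$mean_clustering
    off <- d[upper.tri(d)]
    Ln[b] <- if (any(is.finite(off))) mean(off[is.finite(off)]) else NaN
  }
  Cbar <- mean(Cn)
  Lbar <- mean(Ln)
  if (Cbar == 0) {
    warning("null ensemble has zero mean clustering: sigma undefined")
    return(NaN)
  }
  (C / Cbar) / (L / Lbar)
}

#' Full graph feature vector for one subject
#'
#' The fixed-order feature vector used by the multivariate analysis:
#' 5 global measures (characteristic path length, efficiency, mean
#' clustering, modularity Q, small-world index sigma), then 3 local measures
#' for each region (betweenness centrality, clustering coefficient,
#' strength). For an 83-region parcellation this gives 5 + 3 x 83 = 254
#' features. Names are \code{global:L, global:E, global:C, global:Q,
#' global:sigma, bc:<region>, cc:<region>, str:<region>}.
#'
#' @param weighted a \code{\link{connectivity_matrix}}.
#' @param binary the matching \code{\link{binarize}} output (computed from
#'   \code{weighted} if missing).
#' @param mode \code{"weighted"} or \code{"binary"}: which graph the
#'   measures are computed on.
#' @param seed integer seed for the stochastic global measures (modularity
#'   restarts, small-world nulls).
#' @param n_null null graphs for the small-world index.
#' @return named numeric vector of length 5 + 3 n.
#' @export
graph_features <- function(weighted, binary = NULL,
                           mode = c("weighted", "binary"),
                           seed = 1L, n_null = 100L) {
  mode <- match.arg(mode)
  stopifnot(inherits(weighted, "connectivity_matrix"))
  if (is.null(binary)) binary <- binarize(weighted)
  g <- if (mode == "weighted") weighted else binary
  labels <- weighted$parcellation$labels
  pm <- path_metrics(g)
  cm <- clustering_metrics(g)
  q <- modularity_partition(g, seed = seed)$q
  sig <- small_world_index(g, n_null = n_null, seed = seed)
  v <- c(as.numeric(pm$char_path_length), pm$efficiency,
         cm$mean_clustering, q, sig,
         betweenness_centrality(g), cm$clustering, node_strength(g))
  names(v) <- c("global:L", "global:E", "global:C", "global:Q", "global:sigma",
                paste0("bc:", labels), paste0("cc:", labels),
                paste0("str:", labels))
  v
}

#' Graph feature matrix for a cohort
#'
#' Applies \code{\link{graph_features}} to every subject. Each subject gets
#' its own RNG stream, derived deterministically from the master seed and
#' the subject's position, so per-subject results do not depend on cohort
#' order or size.
#'
#' @param ch a \code{\link{cohort}}.
#' @param mode \code{"weighted"} or \code{"binary"}.
#' @param seed master seed.
#' @param n_null null graphs per subject for the small-world index.
#' @return numeric matrix, subjects x (5 + 3 n_regions).
#' @export
graph_feature_matrix <- function(ch, mode = c("weighted", "binary"),
                                 seed = 1L, n_null = 100L) {
  mode <- match.arg(mode)
  ids <- ch$subjects$id
  rows <- lapply(seq_along(ids), function(i) {
    graph_features(ch$connectomes[[ids[i]]], mode = mode,
                   seed = subject_seed(seed, i), n_null = n_null)
  })
  X <- do.call(rbind, rows)
  rownames(X) <- ids
  X
}

# Deterministic per-subject seed below 2^31.
subject_seed <- function(master, index) {
  as.integer((as.numeric(master) * 1009 + index * 7919) %% 2147483647)
}

#' Write a cohort feature matrix as delimited text
#' @param X subjects x features matrix with dimnames.
#' @param path file path.
#' @export
write_feature_matrix <- function(X, path) {
  utils::write.table(data.frame(id = rownames(X), X, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
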