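test_that("path metrics match hand-enumerated values", {
  # binary path a-b-c: distances 1, 1, 2
  pm <- path_metrics(as_ba(path3_adj()))
  expect_equal(as.numeric(pm$char_path_length), 4 / 3)
  expect_equal(pm$efficiency, (1 + 1 + 0.5) / 3)

  # weighted two-node graph: edge weight 2 -> length 1/2
  W <- matrix(c(0, 2, 2, 0), 2, 2)
  pm2 <- path_metrics(as_cm(W))
  expect_equal(as.numeric(pm2$char_path_length), 0.5)
  expect_equal(pm2$efficiency, 2)

  # two triangles joined by one edge, against the Floyd-Warshall oracle
  A <- matrix(0, 6, 6)
  for (e in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6),
                 c(3, 4))) {
    A[e[1], e[2]] <- 1
    A[e[2], e[1]] <- 1
  }
  pm3 <- path_metrics(as_ba(A))
  or <- oracle_path_metrics(A, weighted = FALSE)
  expect_equal(as.numeric(pm3$char_path_length), or$L)
  expect_equal(pm3$efficiency, or$E)

  # edgeless graph: L undefined, E = 0
  pm4 <- suppressWarnings(path_metrics(as_ba(matrix(0, 4, 4))))
  expect_true(is.nan(as.numeric(pm4$char_path_length)))
  expect_equal(pm4$efficiency, 0)

  # disconnected pair fraction is reported
  A2 <- matrix(0, 4, 4)
  A2[1, 2] <- A2[2, 1] <- 1
  pm5 <- path_metrics(as_ba(A2))
  expect_equal(attr(pm5$char_path_length, "disconnected_fraction"), 5 / 6)
})

test_that("clustering matches definitional values and the Onnela weighted form", {
  K3 <- matrix(1, 3, 3) - diag(3)
  cm <- clustering_metrics(as_ba(K3))
  expect_equal(unname(cm$clustering), rep(1, 3))
  expect_equal(cm$mean_clustering, 1)

  # star: no triangles, leaves have degree 1 -> all zero by convention
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(clustering_metrics(as_ba(star))$mean_clustering, 0)

  # weighted K3 with equal weights: normalized weights are 1 -> C = 1
  expect_equal(unname(clustering_metrics(as_cm(K3 * 3.7))$clustering),
               rep(1, 3))

  # weighted random graphs against the direct triple-loop Onnela oracle
  set.seed(42)
  for (r in 1:15) {
    W <- random_graph(7, 0.6, weighted = TRUE)
    expect_equal(unname(clustering_metrics(as_cm(W))$clustering),
                 oracle_clustering(W, weighted = TRUE))
  }
})

test_that("betweenness counts unordered pairs once, unnormalized", {
  bc <- betweenness_centrality(as_ba(path3_adj()))
  expect_equal(unname(bc), c(0, 1, 0))
  K3 <- matrix(1, 3, 3) - diag(3)
  expect_equal(unname(betweenness_centrality(as_ba(K3))), rep(0, 3))
  # star with 4 leaves: centre lies on all C(4,2) = 6 leaf pairs
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  bc2 <- betweenness_centrality(as_ba(star))
  expect_equal(unname(bc2), c(6, 0, 0, 0, 0))
  expect_equal(unname(bc2), oracle_betweenness(star, weighted = FALSE))
})

test_that("strength sums incident weights and equals degree on binary graphs", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 2.5
  W[1, 3] <- W[3, 1] <- 3.5
  expect_equal(unname(node_strength(as_cm(W))), c(6, 2.5, 3.5))
  expect_equal(unname(node_strength(as_cm(matrix(0, 3, 3)))), rep(0, 3))
  K3 <- matrix(1, 3, 3) - diag(3)
  expect_equal(unname(node_strength(as_ba(K3))), rep(2, 3))
})

test_that("modularity search finds exhaustively optimal partitions on small graphs", {
  # two triangles bridged by one edge: optimum is the two triangles
  A <- matrix(0, 6, 6)
  for (e in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6),
                 c(3, 4))) {
    A[e[1], e[2]] <- 1
    A[e[2], e[1]] <- 1
  }
  mp <- modularity_partition(as_ba(A), seed = 1)
  expect_equal(mp$q, 5 / 14)
  expect_equal(mp$partition, c(1, 1, 1, 2, 2, 2))

  # K4 has no beneficial split
  K4 <- matrix(1, 4, 4) - diag(4)
  expect_equal(modularity_partition(as_ba(K4), seed = 1)$q, 0)

  # edgeless graph: singleton partition, Q = 0
  e0 <- modularity_partition(as_ba(matrix(0, 4, 4)), seed = 1)
  expect_equal(e0$q, 0)
  expect_equal(e0$partition, 1:4)

  # deterministic given the seed
  W <- random_graph(8, 0.5, weighted = TRUE)
  expect_identical(modularity_partition(as_cm(W), seed = 9),
                   modularity_partition(as_cm(W), seed = 9))
})

test_that("small-world index behaves as defined", {
  # complete graph: rewiring cannot change it, sigma = 1
  K5 <- matrix(1, 5, 5) - diag(5)
  expect_equal(small_world_index(as_ba(K5), n_null = 20, seed = 1), 1)

  # ring lattice (n = 30, k = 4) with ~10% shortcuts is small-world
  n <- 30
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (s in 1:2) {
    j <- ((i + s - 1) %% n) + 1
    A[i, j] <- A[j, i] <- 1
  }
  set.seed(4)
  for (r in 1:6) {  # ~10% of the 60 lattice edges become shortcuts
    pick <- sample(n, 2)
    A[pick[1], pick[2]] <- A[pick[2], pick[1]] <- 1
  }
  sig <- small_world_index(as_ba(A), n_null = 50, seed = 2)
  expect_gt(sig, 1)

  # determinism contract
  expect_identical(sig, small_world_index(as_ba(A), n_null = 50, seed = 2))
})

test_that("graph feature vector has the fixed order and length 5 + 3n", {
  cfg <- tiny_config(n_pairs = 2L, n_regions = 10L, seed = 8L)
  tm <- generate_template(cfg)
  v <- graph_features(tm$counts, mode = "binary", seed = 1, n_null = 10)
  expect_length(v, 5 + 3 * 10)
  expect_equal(names(v)[1:5],
               c("global:L", "global:E", "global:C", "global:Q",
                 "global:sigma"))
  expect_equal(names(v)[6], paste0("bc:", cfg$parcellation$labels[1]))
  expect_equal(names(v)[16], paste0("cc:", cfg$parcellation$labels[1]))
  expect_equal(names(v)[26], paste0("str:", cfg$parcellation$labels[1]))
  # local blocks agree with the individual metric functions
  b <- binarize(tm$counts)
  expect_equal(unname(v[6:15]), unname(betweenness_centrality(b)))
  expect_equal(unname(v[26:35]), unname(node_strength(b)))
})

test_that("metrics are permutation-equivariant", {
  set.seed(19)
  for (r in 1:10) {
    W <- random_graph(8, 0.5, weighted = r %% 2 == 0)
    perm <- sample(8)
    Wp <- W[perm, perm]
    g <- if (r %% 2 == 0) as_cm(W) else as_ba(W)
    gp <- if (r %% 2 == 0) as_cm(Wp) else as_ba(Wp)
    expect_equal(unname(betweenness_centrality(gp)),
                 unname(betweenness_centrality(g))[perm])
    expect_equal(unname(clustering_metrics(gp)$clustering),
                 unname(clustering_metrics(g)$clustering)[perm])
    expect_equal(unname(node_strength(gp)), unname(node_strength(g))[perm])
    expect_equal(path_metrics(gp)$efficiency, path_metrics(g)$efficiency)
  }
})

test_that("weight rescaling leaves binary metrics fixed and scales weighted ones", {
  set.seed(23)
  W <- random_graph(8, 0.6, weighted = TRUE)
  c <- 3.7
  # binary view unchanged
  expect_identical(binarize(as_cm(W * c))$adjacency,
                   binarize(as_cm(W))$adjacency)
  # weighted L scales as 1/c, E as c
  expect_equal(as.numeric(path_metrics(as_cm(W * c))$char_path_length),
               as.numeric(path_metrics(as_cm(W))$char_path_length) / c)
  expect_equal(path_metrics(as_cm(W * c))$efficiency,
               path_metrics(as_cm(W))$efficiency * c)
  # betweenness values (hence ranking) are scale-invariant
  expect_equal(betweenness_centrality(as_cm(W * c)),
               betweenness_centrality(as_cm(W)))
  # Onnela clustering is scale-invariant by max-normalization
  expect_equal(clustering_metrics(as_cm(W * c))$clustering,
               clustering_metrics(as_cm(W))$clustering)
})

test_that("adding an edge never increases a shortest-path distance", {
  set.seed(31)
  for (r in 1:10) {
    W <- random_graph(7, 0.4, weighted = TRUE)
    d0 <- psyconn:::dist_matrix(W, weighted = TRUE)
    absent <- which(W == 0 & upper.tri(W), arr.ind = TRUE)
    if (nrow(absent) == 0) next
    e <- absent[sample(nrow(absent), 1), ]
    W2 <- W
    W2[e[1], e[2]] <- W2[e[2], e[1]] <- stats::runif(1, 0.5, 5)
    d1 <- psyconn:::dist_matrix(W2, weighted = TRUE)
    expect_true(all(d1 <= d0 + 1e-12))
  }
})
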