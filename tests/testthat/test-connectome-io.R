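test_that("matrix loading validates, symmetrizes and reports edge counts", {
  parc <- toy_parcellation(3)
  f <- withr::local_tempfile(fileext = ".tsv")

  writeLines(c("0 2 0", "2 0 1", "0 1 0"), f)
  m <- load_matrix(f, parc)
  expect_s3_class(m, "connectivity_matrix")
  expect_equal(sum(m$weights[upper.tri(m$weights)] > 0), 2)

  # asymmetric entry is averaged, with a warning
  writeLines(c("0 5 0", "7 0 1", "0 1 0"), f)
  expect_warning(m2 <- load_matrix(f, parc), "symmetrized")
  expect_equal(m2$weights[1, 2], 6)
  expect_equal(m2$weights[2, 1], 6)

  # dimension mismatch is fatal
  writeLines(c("0 1", "1 0"), f)
  expect_error(load_matrix(f, parc), "2 x 2")

  # negative entries are fatal
  writeLines(c("0 -1 0", "-1 0 1", "0 1 0"), f)
  expect_error(load_matrix(f, parc), "negative")

  # nonzero diagonal is zeroed with a warning
  writeLines(c("9 1 0", "1 0 1", "0 1 0"), f)
  expect_warning(m3 <- load_matrix(f, parc), "diagonal")
  expect_equal(diag(m3$weights), setNames(rep(0, 3), parc$labels))

  # comma-delimited files are accepted too
  writeLines(c("0,2,0", "2,0,1", "0,1,0"), f)
  expect_equal(load_matrix(f, parc)$weights[1, 2], 2)
})

test_that("write/load round trip reproduces entries exactly", {
  set.seed(7)
  W <- random_graph(9, 0.5, weighted = TRUE) * exp(stats::runif(1, -3, 3))
  m <- as_cm(W)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(m, f)
  m2 <- load_matrix(f, m$parcellation)
  expect_identical(m2$weights, m$weights)
})

test_that("length normalization divides counts by mean length and preserves support", {
  counts <- as_cm(matrix(c(0, 60, 0, 60, 0, 10, 0, 10, 0), 3, 3))
  lengths <- matrix(c(0, 30, 0, 30, 0, 5, 0, 5, 0), 3, 3)
  nm <- length_normalize(counts, lengths)
  expect_true(nm$normalized)
  expect_equal(unname(nm$weights),
               matrix(c(0, 2, 0, 2, 0, 2, 0, 2, 0), 3, 3))

  # zero-count entries stay zero even where a length is recorded
  lengths2 <- lengths
  lengths2[1, 3] <- lengths2[3, 1] <- 40
  expect_equal(length_normalize(counts, lengths2)$weights[1, 3], 0)

  # support must match: count without length is a fatal inconsistency
  lengths3 <- lengths
  lengths3[2, 3] <- lengths3[3, 2] <- 0
  expect_error(length_normalize(counts, lengths3), "no positive mean length")

  # property: support(normalized) == support(counts) on random matrices
  set.seed(11)
  for (r in 1:20) {
    W <- random_graph(8, 0.4, weighted = TRUE)
    L <- (W > 0) * stats::runif(64, 10, 150)
    L[lower.tri(L)] <- t(L)[lower.tri(L)]
    diag(L) <- 0
    nr <- length_normalize(as_cm(W), L)
    expect_identical(nr$weights > 0, W > 0, ignore_attr = TRUE)
  }
})

test_that("binarization keeps strictly positive weights only", {
  m <- as_cm(matrix(c(0, 2.5, 2.5, 0), 2, 2))
  expect_equal(unname(binarize(m)$adjacency), matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(sum(binarize(as_cm(matrix(0, 4, 4)))$adjacency), 0)
  # arbitrarily small positive weights count as edges (no threshold)
  tiny <- as_cm(matrix(c(0, 1e-12, 1e-12, 0), 2, 2))
  expect_equal(binarize(tiny)$adjacency[1, 2], 1)
  # binarize commutes with length normalization
  set.seed(3)
  W <- random_graph(7, 0.5, weighted = TRUE)
  L <- (W > 0) * 50
  expect_identical(binarize(length_normalize(as_cm(W), L))$adjacency,
                   binarize(as_cm(W))$adjacency)
})

test_that("edge vectorization is row-major upper triangle and invertible", {
  parc83 <- dk_parcellation()
  m83 <- connectivity_matrix(matrix(0, 83, 83), parc83)
  expect_length(vectorize_edges(m83), 83 * 82 / 2)

  m <- as_cm(matrix(c(0, 2, 0, 2, 0, 1, 0, 1, 0), 3, 3))
  v <- vectorize_edges(m)
  expect_equal(unname(v), c(2, 0, 1), ignore_attr = TRUE)
  map <- attr(v, "index_map")
  expect_equal(unlist(map[1, ]), c(i = 1, j = 2))
  expect_equal(names(v)[1], "roi001|roi002")

  set.seed(5)
  W <- random_graph(10, 0.5, weighted = TRUE)
  m10 <- as_cm(W)
  back <- devectorize_edges(vectorize_edges(m10), m10$parcellation)
  expect_equal(back$weights, m10$weights)
})

test_that("SIPS labeling follows the max-item >= 3 rule", {
  expect_equal(label_from_sips(c(3, 0, 0, 0, 0)), "psy_pos")
  expect_equal(label_from_sips(c(2, 2, 2, 2, 2)), "psy_neg")
  expect_equal(label_from_sips(c(0, 0, 0, 0, 0)), "psy_neg")
  expect_equal(label_from_sips(c(0, 0, 0, 6, 0)), "psy_pos")
  expect_error(label_from_sips(c(7, 0, 0, 0, 0)), "0..6")
  expect_error(label_from_sips(c(1, 2, 3)), "five")
  # matrix form, one label per row
  m <- rbind(c(3, 0, 0, 0, 0), c(2, 2, 2, 2, 2))
  expect_equal(label_from_sips(m), c("psy_pos", "psy_neg"))
})

test_that("diffusion tables validate ranges and load from text", {
  expect_error(diffusion_features(fa = rep(1.2, 18), ad = rep(1e-3, 18),
                                  rd = rep(5e-4, 18)), "FA")
  expect_error(diffusion_features(fa = rep(0.4, 18), ad = rep(4e-4, 18),
                                  rd = rep(5e-4, 18)), "AD >= RD")
  d <- diffusion_features(fa = rep(0.4, 18), ad = rep(1.2e-3, 18),
                          rd = rep(5e-4, 18))
  expect_equal(nrow(d), 18)
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE)
  d2 <- load_diffusion(f, tract_names = tracula_tracts())
  expect_equal(d2$fa, d$fa)
})

test_that("cohort assembly derives groups, checks pairs, and round-trips to disk", {
  cfg <- tiny_config(n_pairs = 3L, seed = 21L)
  ch <- generate_cohort(cfg)
  expect_equal(nrow(ch$subjects), 6)
  expect_equal(as.vector(table(ch$subjects$group)), c(3, 3))

  # a broken pair map is rejected
  bad <- ch$subjects
  bad$pair_id[1] <- "pair999"
  expect_error(cohort(bad, ch$parcellation, ch$connectomes), "pair")

  dir <- withr::local_tempdir()
  write_cohort(ch, dir)
  ch2 <- read_cohort(dir)
  expect_equal(ch2$subjects$group, ch$subjects$group)
  expect_equal(ch2$connectomes[[1]]$weights, ch$connectomes[[1]]$weights)
  expect_equal(ch2$diffusion[[3]]$fa, ch$diffusion[[3]]$fa)
  expect_equal(ch2$parcellation$labels, ch$parcellation$labels)
})
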