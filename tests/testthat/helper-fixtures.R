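# Small in-code fixtures shared across test files.

path3_adj <- function() {  # a - b - c
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- 1
  A[2, 3] <- A[3, 2] <- 1
  A
}

as_cm <- function(W, normalized = FALSE) {
  connectivity_matrix(W, toy_parcellation(nrow(W)), normalized = normalized)
}

as_ba <- function(A) binarize(as_cm(A))

# Two well-separated Gaussian classes: |mean difference| = 6 sd on the
# informative features.
separable_data <- function(n_per = 10L, n_feat = 6L, n_inform = 2L,
                           seed = 1L) {
  set.seed(seed)
  X <- matrix(stats::rnorm(2 * n_per * n_feat), 2 * n_per, n_feat)
  y <- factor(rep(c("psy_neg", "psy_pos"), each = n_per),
              levels = c("psy_neg", "psy_pos"))
  X[y == "psy_pos", seq_len(n_inform)] <-
    X[y == "psy_pos", seq_len(n_inform)] + 6
  list(X = X, y = y)
}

# Fast small synthetic config for pipeline-level tests: dense enough that
# every graph measure (including the small-world index) is defined.
tiny_config <- function(n_pairs = 5L, n_regions = 12L, seed = 1L, ...) {
  synth_config(n_pairs = n_pairs, n_regions = n_regions,
               within_density = 0.8, between_density = 0.3,
               seed = seed, ...)
}
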