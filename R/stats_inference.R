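#' Wilson score confidence interval for a binomial proportion
#'
#' The Wilson interval for k successes in n trials at the given confidence
#' level. Used throughout as the significance criterion for classifier
#' accuracy: a result is significant at level 1 - confidence when the
#' interval excludes the 50% chance value.
#'
#' @param k number of successes (vectorized).
#' @param n number of trials.
#' @param confidence confidence level (default 0.95).
#' @return data frame with columns \code{lower}, \code{upper}.
#' @examples
#' wilson_interval(42, 62)  # 0.554 .. 0.780
#' @export
wilson_interval <- function(k, n, confidence = 0.95) {
  if (any(n < 1)) stop("need n >= 1")
  if (any(k < 0 | k > n)) stop("need 0 <= k <= n")
  z <- stats::qnorm((1 + confidence) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  data.frame(lower = centre - half, upper = centre + half)
}

#' Is an accuracy significantly different from chance?
#'
#' @inheritParams wilson_interval
#' @param chance chance value (default 0.5).
#' @return logical: \code{TRUE} when the Wilson interval excludes
#'   \code{chance}.
#' @export
wilson_significant <- function(k, n, confidence = 0.95, chance = 0.5) {
  ci <- wilson_interval(k, n, confidence)
  ci$lower > chance | ci$upper < chance
}

#' Univariate feature screen (Mann-Whitney + FDR)
#'
#' Two-sided Mann-Whitney U test per feature between the two groups, with
#' Benjamini-Hochberg false-discovery-rate control at level \code{q}. The
#' test is exact when both groups have at most 20 subjects and the feature
#' has no ties; otherwise the tie-corrected normal approximation is used.
#' A feature constant across all subjects gets p = 1 by convention.
#'
#' @param X subjects x features numeric matrix.
#' @param y binary labels (factor or character; \code{psy_pos}/\code{psy_neg}).
#' @param q FDR level (default 0.05).
#' @return data frame with columns \code{feature}, \code{U} (statistic for
#'   the psy_pos group), \code{p}, \code{p_adj}, \code{significant}.
#' @export
univariate_screen <- function(X, y, q = 0.05) {
  X <- as.matrix(X)
  y <- as.factor(y)
  if (nlevels(droplevels(y)) != 2L) stop("need exactly two groups")
  pos <- y == "psy_pos"
  if (sum(pos) < 2L || sum(!pos) < 2L) stop("need >= 2 subjects per group")
  m <- ncol(X)
  U <- p <- numeric(m)
  for (j in seq_len(m)) {
    xj <- X[, j]
    if (stats::var(xj) == 0) {
      # no information: U at its null mean, p = 1
      U[j] <- sum(pos) * sum(!pos) / 2
      p[j] <- 1
      next
    }
    a <- xj[pos]; b <- xj[!pos]
    exact <- length(a) <= 20L && length(b) <= 20L &&
      !any(duplicated(xj))
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                         correct = !exact))
    U[j] <- unname(wt$statistic)
    p[j] <- wt$p.value
  }
  p_adj <- stats::p.adjust(p, method = "BH")
  data.frame(feature = colnames(X) %||% paste0("f", seq_len(m)),
             U = U, p = p, p_adj = p_adj, significant = p_adj <= q)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Accuracy, sensitivity and specificity from predictions
#'
#' Sensitivity is recall on the \code{psy_pos} class, specificity recall on
#' \code{psy_neg}. A class absent from the truths yields NaN for its rate,
#' with a warning.
#'
#' @param predictions,truths equal-length label vectors.
#' @return list with \code{accuracy}, \code{sensitivity}, \code{specificity}.
#' @export
confusion_summary <- function(predictions, truths) {
  predictions <- as.character(predictions)
  truths <- as.character(truths)
  stopifnot(length(predictions) == length(truths))
  acc <- mean(predictions == truths)
  rate <- function(cls) {
    sel <- truths == cls
    if (!any(sel)) {
      warning(sprintf("no %s subjects in truths: rate undefined", cls))
      return(NaN)
    }
    mean(predictions[sel] == cls)
  }
  list(accuracy = acc,
       sensitivity = rate("psy_pos"),
       specificity = rate("psy_neg"))
}

#' Matched-pair bootstrap stability of a feature-curve analysis
#'
#' Repeats the configured incremental-feature analysis while removing one
#' randomly chosen matched pair per trial (one psy_pos subject and its
#' matched psy_neg partner), and records the best accuracy and whether it
#' was Wilson-significant. Summarizes how often the discrimination survives
#' the removal.
#'
#' @param X subjects x features matrix.
#' @param y binary labels aligned with the rows of \code{X}.
#' @param pairs pair ids aligned with the rows of \code{X}.
#' @param grid feature-count grid, as for \code{\link{feature_curve}}.
#' @param n_trials number of bootstrap trials (default 100).
#' @param seed integer seed; trials are deterministic given the seed.
#' @param ... further options passed to \code{\link{feature_curve}}
#'   (covariates must then be passed as a function of the retained rows).
#' @param covariates optional covariate data frame aligned with rows of X;
#'   subset per trial.
#' @return list of class \code{bootstrap_stability}: per-trial data frame
#'   (\code{pair_removed}, \code{best_accuracy}, \code{significant}),
#'   \code{fraction_above_chance}, \code{fraction_significant}.
#' @export
matched_pair_bootstrap <- function(X, y, pairs, grid, n_trials = 100L,
                                   seed = 1L, covariates = NULL, ...) {
  stopifnot(n_trials >= 1L)
  X <- as.matrix(X)
  y <- as.factor(y)
  pairs <- as.character(pairs)
  sp <- split(seq_along(pairs), pairs)
  if (!all(lengths(sp) == 2L)) stop("incomplete matched-pair map")
  pair_ids <- names(sp)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old))
  set.seed(seed)
  removed <- sample(pair_ids, n_trials, replace = TRUE)
  best_acc <- numeric(n_trials)
  signif <- logical(n_trials)
  for (t in seq_len(n_trials)) {
    keep <- setdiff(seq_len(nrow(X)), sp[[removed[t]]])
    fc <- feature_curve(X[keep, , drop = FALSE], droplevels(y[keep]),
                        grid = grid,
                        covariates = if (is.null(covariates)) NULL else
                          covariates[keep, , drop = FALSE],
                        seed = seed + t, ...)
    best_acc[t] <- fc$best$accuracy
    signif[t] <- fc$best$significant
  }
  structure(list(
    trials = data.frame(pair_removed = removed, best_accuracy = best_acc,
                        significant = signif),
    n_trials = n_trials,
    fraction_above_chance = mean(best_acc > 0.5),
    fraction_significant = mean(signif)
  ), class = "bootstrap_stability")
}

#' @export
print.bootstrap_stability <- function(x, ...) {
  cat(sprintf(
    "matched-pair bootstrap: %d trials; accuracy > 50%% in %.0f%%, significant in %.0f%%\n",
    x$n_trials, 100 * x$fraction_above_chance, 100 * x$fraction_significant))
  invisible(x)
}
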