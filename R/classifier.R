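#' Point-biserial feature ranking
#'
#' Scores every feature by the absolute Pearson correlation between the
#' feature values and the 0/1-coded group labels (the point-biserial
#' correlation), and ranks features by decreasing score, breaking ties by
#' ascending feature index. Zero-variance features score 0 and therefore
#' rank last.
#'
#' @param X subjects x features numeric matrix.
#' @param y binary labels; \code{psy_pos} is coded 1.
#' @return list of class \code{ranked_features}: \code{order} (permutation
#'   of feature indices, best first) and \code{scores} (per feature, in the
#'   original feature order).
#' @export
rank_point_biserial <- function(X, y) {
  X <- as.matrix(X)
  y <- as.factor(y)
  if (nlevels(droplevels(y)) != 2L) stop("need both classes present")
  if (nrow(X) < 3L) stop("need at least 3 subjects to rank features")
  y01 <- as.numeric(y == "psy_pos")
  scores <- suppressWarnings(abs(as.numeric(stats::cor(X, y01))))
  scores[is.na(scores)] <- 0
  structure(list(order = order(-scores, seq_along(scores)), scores = scores),
            class = "ranked_features")
}

#' Fit a Gaussian naive Bayes model
#'
#' Models every feature within each class as an independent Gaussian.
#' Class priors are the empirical class proportions of the training data
#' (so each fold of a leave-one-out loop over a 31/31 cohort uses priors
#' 31/61 = 50.82% and 30/61 = 49.18%). Every per-class variance is floored
#' by adding 1e-9 times the largest feature variance in the training set,
#' which keeps densities proper when a feature is constant within a class.
#'
#' @param X training matrix (subjects x features).
#' @param y training labels (factor; both classes with >= 2 subjects).
#' @param var_floor optional explicit variance floor; by default derived
#'   from the columns of \code{X}. Supply the full-training-set floor when
#'   fitting on a feature subset so the model matches a fit-then-subset.
#' @return list of class \code{nb_model}: \code{classes}, \code{priors},
#'   \code{means}, \code{vars} (class x feature matrices).
#' @export
fit_nb <- function(X, y, var_floor = NULL) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stop("need exactly two classes in training data")
  counts <- table(y)
  if (any(counts < 2L)) stop("need >= 2 training subjects per class")
  classes <- levels(y)
  cls_stats <- function(cl) {
    Xc <- X[y == cl, , drop = FALSE]
    nc <- nrow(Xc)
    mu <- colMeans(Xc)
    v <- (colSums(Xc^2) - nc * mu^2) / (nc - 1)
    list(mu = mu, v = pmax(v, 0))  # clip tiny negative rounding error
  }
  s1 <- cls_stats(classes[1L])
  s2 <- cls_stats(classes[2L])
  if (is.null(var_floor)) var_floor <- nb_var_floor(X)
  structure(list(classes = classes,
                 priors = as.numeric(counts) / length(y),
                 means = rbind(s1$mu, s2$mu),
                 vars = rbind(s1$v, s2$v) + var_floor,
                 var_floor = var_floor),
            class = "nb_model")
}

# 1e-9 times the largest feature variance of the training matrix, with a
# machine-epsilon fallback when every feature is constant.
nb_var_floor <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  v <- (colSums(X^2) - n * mu^2) / (n - 1)
  fl <- 1e-9 * max(v, 0)
  if (fl == 0) fl <- .Machine$double.eps
  fl
}

#' Predict with a Gaussian naive Bayes model
#'
#' Log-posterior per class is log prior plus the sum of per-feature Gaussian
#' log densities; posteriors are normalized with log-sum-exp. An exact tie
#' goes to the class with the larger prior, then to the first class.
#'
#' @param model an \code{\link{nb_model}}.
#' @param x a feature vector, or a matrix with one row per case.
#' @return data frame with columns \code{label} and \code{posterior}
#'   (posterior probability of the predicted class).
#' @export
predict_nb <- function(model, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(X) != ncol(model$means))
    stop(sprintf("model has %d features but input has %d",
                 ncol(model$means), ncol(X)))
  out <- vapply(seq_len(nrow(X)), function(i) {
    ll <- vapply(1:2, function(c) {
      mu <- model$means[c, ]; s2 <- model$vars[c, ]
      log(model$priors[c]) -
        0.5 * sum(log(2 * pi * s2) + (X[i, ] - mu)^2 / s2)
    }, numeric(1L))
    post <- exp(ll - max(ll))
    post <- post / sum(post)
    pick <- if (ll[1L] == ll[2L]) {
      if (model$priors[1L] >= model$priors[2L]) 1L else 2L
    } else which.max(ll)
    c(pick, post[pick])
  }, numeric(2L))
  data.frame(label = model$classes[out[1L, ]], posterior = out[2L, ],
             stringsAsFactors = FALSE)
}

#' Residualize features on covariates, fitted on training rows only
#'
#' For each feature, ordinary least squares of the feature on the covariate
#' design (intercept plus one-hot-coded categoricals) is fitted on the
#' training rows; training rows get their residuals, and each test row gets
#' its observed value minus the prediction from the training coefficients.
#' This is the leakage-free, in-loop form of covariate correction: the
#' held-out subject never influences the regression.
#'
#' @param X_train,X_test feature matrices.
#' @param C_train,C_test covariate data frames (e.g. age, sex, scanner);
#'   factor levels in the test rows must have been seen in training.
#' @return list with \code{train} and \code{test} residual matrices.
#' @export
residualize_covariates <- function(X_train, C_train, X_test, C_test) {
  X_train <- as.matrix(X_train)
  X_test <- as.matrix(X_test)
  C_train <- as.data.frame(C_train)
  C_test <- as.data.frame(C_test)
  if (nrow(C_train) != nrow(X_train) || nrow(C_test) != nrow(X_test))
    stop("covariate rows must match feature rows")
  for (cl in names(C_train)) {
    if (is.character(C_train[[cl]]) || is.factor(C_train[[cl]])) {
      lev <- unique(as.character(C_train[[cl]]))
      unseen <- setdiff(unique(as.character(C_test[[cl]])), lev)
      if (length(unseen))
        stop(sprintf("test covariate '%s' has unseen level(s): %s",
                     cl, paste(unseen, collapse = ", ")))
      C_train[[cl]] <- factor(C_train[[cl]], levels = lev)
      C_test[[cl]] <- factor(C_test[[cl]], levels = lev)
    }
  }
  D_train <- stats::model.matrix(~ ., data = C_train)
  D_test <- stats::model.matrix(~ ., data = C_test)
  if (nrow(X_train) < ncol(D_train) + 1L)
    stop("too few training rows for the covariate design")
  fit <- stats::lm.fit(D_train, X_train)
  B <- fit$coefficients
  if (is.vector(B)) B <- matrix(B, ncol = ncol(X_train))
  if (anyNA(B)) {
    warning("rank-deficient covariate design: collinear columns dropped")
    B[is.na(B)] <- 0
  }
  list(train = X_train - D_train %*% B,
       test = X_test - D_test %*% B)
}

#' One fold of the leave-one-out loop
#'
#' Trains the complete fold pipeline with subject \code{i} held out:
#' optional covariate residualization (fitted on the training rows),
#' point-biserial ranking on the training rows (unless a global ranking is
#' supplied), selection of the top \code{n_features}, and a Gaussian naive
#' Bayes fit. Nothing about subject \code{i} other than its covariates (for
#' the test-side residual) enters training.
#'
#' @param X subjects x features matrix.
#' @param y binary labels.
#' @param i index of the held-out subject.
#' @param n_features number of top-ranked features to keep.
#' @param covariates optional covariate data frame aligned with rows of X.
#' @param global_order optional fixed feature order (indices) replacing the
#'   per-fold ranking.
#' @return list with \code{model} (\code{nb_model}), \code{selected}
#'   (feature indices), \code{prediction}, \code{posterior}, \code{priors}.
#' @export
loocv_fold <- function(X, y, i, n_features, covariates = NULL,
                       global_order = NULL) {
  X <- as.matrix(X)
  y <- as.factor(y)
  tr <- setdiff(seq_len(nrow(X)), i)
  Xtr <- X[tr, , drop = FALSE]
  Xte <- X[i, , drop = FALSE]
  if (!is.null(covariates)) {
    res <- residualize_covariates(Xtr, covariates[tr, , drop = FALSE],
                                  Xte, covariates[i, , drop = FALSE])
    Xtr <- res$train
    Xte <- res$test
  }
  ord <- if (is.null(global_order))
    rank_point_biserial(Xtr, y[tr])$order else global_order
  sel <- ord[seq_len(n_features)]
  model <- fit_nb(Xtr[, sel, drop = FALSE], y[tr],
                  var_floor = nb_var_floor(Xtr))
  pred <- predict_nb(model, Xte[, sel, drop = FALSE])
  list(model = model, selected = sel,
       prediction = pred$label, posterior = pred$posterior,
       priors = model$priors)
}

# Shared LOOCV engine: residualize + rank once per fold, then predict the
# held-out subject for every feature count in ks. Because the naive Bayes
# log-likelihood is a sum of independent per-feature terms and features are
# added in rank order, one cumulative sum over the top-max(ks) ranked
# features yields the prediction at every grid point exactly (the variance
# floor is shared: it is derived from the full training matrix, not the
# subset). Returns an n x length(ks) matrix of predicted labels plus
# per-fold bookkeeping.
run_loocv_grid <- function(X, y, ks, ranking_scope = c("per_fold", "global"),
                           covariates = NULL) {
  ranking_scope <- match.arg(ranking_scope)
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  n <- nrow(X)
  ks <- as.integer(ks)
  stopifnot(n >= 4L, max(ks) <= ncol(X), all(ks >= 1L))
  if (!all(is.finite(X)))
    stop("feature matrix contains non-finite values ",
         "(e.g. an undefined small-world index); drop or impute them first")
  global_order <- NULL
  if (ranking_scope == "global") {
    warning(paste("global ranking uses all subjects (including each fold's",
                  "test subject) for feature selection; accuracies are",
                  "optimistically biased"), call. = FALSE)
    global_order <- rank_point_biserial(X, y)$order
  }
  kmax <- max(ks)
  preds <- matrix(NA_character_, n, length(ks))
  priors <- matrix(NA_real_, n, 2L)
  fold_orders <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    Xtr <- X[tr, , drop = FALSE]
    Xte <- X[i, , drop = FALSE]
    if (!is.null(covariates)) {
      res <- residualize_covariates(Xtr, covariates[tr, , drop = FALSE],
                                    Xte, covariates[i, , drop = FALSE])
      Xtr <- res$train
      Xte <- res$test
    }
    ord <- if (is.null(global_order))
      rank_point_biserial(Xtr, y[tr])$order else global_order
    fold_orders[[i]] <- ord
    sel <- ord[seq_len(kmax)]
    model <- fit_nb(Xtr[, sel, drop = FALSE], y[tr],
                    var_floor = nb_var_floor(Xtr))
    priors[i, ] <- model$priors
    x <- Xte[1L, sel]
    contrib <- -0.5 * (log(2 * pi * model$vars) +
                         (rep(x, each = 2L) - model$means)^2 / model$vars)
    ll <- log(model$priors) + cbind(cumsum(contrib[1L, ]),
                                    cumsum(contrib[2L, ]))[ks, , drop = FALSE]
    pick <- ifelse(ll[, 1L] == ll[, 2L],
                   if (model$priors[1L] >= model$priors[2L]) 1L else 2L,
                   ifelse(ll[, 1L] > ll[, 2L], 1L, 2L))
    preds[i, ] <- model$classes[pick]
  }
  list(preds = preds, priors = priors, fold_orders = fold_orders, y = y)
}

#' Leave-one-subject-out cross-validated classification
#'
#' For each fold, one subject is held out; the remaining subjects are
#' (optionally) residualized on covariates, features are ranked by
#' point-biserial correlation within the fold (default) and the top
#' \code{n_features} are kept; a Gaussian naive Bayes model with empirical
#' training priors predicts the held-out subject. Accuracy is summarized
#' with its 95% Wilson score interval, and sensitivity/specificity as
#' recall on \code{psy_pos}/\code{psy_neg}.
#'
#' @param X subjects x features matrix.
#' @param y binary labels.
#' @param n_features number of top-ranked features per fold (default: all).
#' @param ranking_scope \code{"per_fold"} (leakage-free default) or
#'   \code{"global"} (rank once on all subjects; optimistic, kept for
#'   replication of analyses that selected features outside the loop).
#' @param covariates optional covariate data frame (e.g. age, sex, scanner).
#' @param confidence Wilson interval confidence level.
#' @return object of class \code{classification_result}: per-subject
#'   \code{predictions} data frame, \code{accuracy}, \code{wilson_lower},
#'   \code{wilson_upper}, \code{significant}, \code{sensitivity},
#'   \code{specificity}, \code{fold_priors}, \code{selected_features}
#'   (feature names ranked by how often folds selected them).
#' @export
loocv <- function(X, y, n_features = ncol(as.matrix(X)),
                  ranking_scope = c("per_fold", "global"),
                  covariates = NULL, confidence = 0.95) {
  X <- as.matrix(X)
  run <- run_loocv_grid(X, y, ks = n_features,
                        ranking_scope = ranking_scope,
                        covariates = covariates)
  y <- run$y
  pred <- run$preds[, 1L]
  cs <- confusion_summary(pred, as.character(y))
  k <- sum(pred == as.character(y))
  n <- length(y)
  ci <- wilson_interval(k, n, confidence)
  sel_tab <- selection_frequency(run$fold_orders, n_features,
                                 colnames(X) %||% paste0("f", seq_len(ncol(X))))
  structure(list(
    predictions = data.frame(id = rownames(X) %||% seq_len(n),
                             true = as.character(y), predicted = pred,
                             stringsAsFactors = FALSE),
    n = n, n_correct = k,
    accuracy = cs$accuracy,
    wilson_lower = ci$lower, wilson_upper = ci$upper,
    significant = ci$lower > 0.5 || ci$upper < 0.5,
    sensitivity = cs$sensitivity, specificity = cs$specificity,
    fold_priors = run$priors,
    selected_features = sel_tab
  ), class = "classification_result")
}

# How often each feature lands in the top-k across folds; returns the
# features ever selected, ordered by selection frequency.
selection_frequency <- function(fold_orders, k, feature_names) {
  counts <- integer(length(feature_names))
  for (ord in fold_orders) {
    sel <- ord[seq_len(k)]
    counts[sel] <- counts[sel] + 1L
  }
  picked <- which(counts > 0L)
  picked <- picked[order(-counts[picked], picked)]
  data.frame(feature = feature_names[picked],
             folds_selected = counts[picked],
             fraction = counts[picked] / length(fold_orders),
             stringsAsFactors = FALSE)
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf(
    "LOOCV: accuracy %.1f%% (CI: %.1f-%.1f%%)%s; sensitivity %.1f%%, specificity %.1f%%\n",
    100 * x$accuracy, 100 * x$wilson_lower, 100 * x$wilson_upper,
    if (x$significant) " *" else "",
    100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' Build a feature-count grid
#'
#' \code{seq(start, max, step)}; when \code{max} is not on the step lattice
#' it is appended as a final point, so a (5, 5, 254) grid ends
#' ..., 250, 254.
#'
#' @param start,step,max grid definition.
#' @return increasing integer vector.
#' @export
make_grid <- function(start, step, max) {
  stopifnot(start >= 1, step >= 1, max >= start)
  g <- seq.int(start, max, by = step)
  if (g[length(g)] != max) g <- c(g, max)
  g
}

#' Incremental feature curve
#'
#' Runs the leave-one-out classification at every feature count on the
#' grid, adding features in their point-biserial rank order, and flags the
#' grid points whose Wilson interval excludes 50% chance. Within each fold,
#' residualization and ranking happen once; only the number of retained
#' features varies along the grid. Note that many classifiers are evaluated
#' across the grid and per-point intervals are not corrected for that
#' selection; treat significant flags as descriptive.
#'
#' @param X subjects x features matrix.
#' @param y binary labels.
#' @param grid either a list \code{list(start=, step=, max=)} or an integer
#'   vector of feature counts. Defaults used in the study design:
#'   edges (10, 10, 1600), graph measures (5, 5, total), diffusion
#'   (1, 1, 18).
#' @param ranking_scope,covariates,confidence as in \code{\link{loocv}}.
#' @param seed recorded for provenance (the procedure itself is
#'   deterministic).
#' @return object of class \code{feature_curve}: \code{curve} data frame
#'   (\code{n_features}, \code{accuracy}, \code{lower}, \code{upper},
#'   \code{significant}), and \code{best} (accuracy-maximizing grid point,
#'   ties to the fewest features) with the ranked \code{selected} feature
#'   names at that point (full-cohort ranking, the reporting convention;
#'   per-fold rankings drive the predictions) and their per-fold selection
#'   frequencies.
#' @export
feature_curve <- function(X, y, grid, ranking_scope = c("per_fold", "global"),
                          covariates = NULL, confidence = 0.95, seed = 1L) {
  X <- as.matrix(X)
  ks <- if (is.list(grid)) make_grid(grid$start, grid$step, grid$max)
        else as.integer(grid)
  if (max(ks) > ncol(X))
    stop("grid exceeds the number of available features")
  run <- run_loocv_grid(X, y, ks, ranking_scope = ranking_scope,
                        covariates = covariates)
  y <- run$y
  truth <- as.character(y)
  n <- length(y)
  kcorr <- colSums(run$preds == truth)
  ci <- wilson_interval(kcorr, n, confidence)
  curve <- data.frame(n_features = ks, n_correct = kcorr,
                      accuracy = kcorr / n,
                      lower = ci$lower, upper = ci$upper,
                      significant = ci$lower > 0.5 | ci$upper < 0.5)
  ibest <- which.max(curve$accuracy)  # first max: fewest features wins ties
  kbest <- ks[ibest]
  fnames <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  full_order <- rank_point_biserial(X, y)$order
  structure(list(
    curve = curve,
    best = list(n_features = kbest,
                accuracy = curve$accuracy[ibest],
                n_correct = curve$n_correct[ibest],
                lower = curve$lower[ibest], upper = curve$upper[ibest],
                significant = curve$significant[ibest],
                selected = fnames[full_order[seq_len(kbest)]],
                selection_frequency = selection_frequency(
                  run$fold_orders, kbest, fnames)),
    n = n, seed = seed
  ), class = "feature_curve")
}

#' @export
print.feature_curve <- function(x, ...) {
  b <- x$best
  cat(sprintf(
    "feature curve over %d grid points; best: %d features, accuracy %.1f%% (CI: %.1f-%.1f%%)%s\n",
    nrow(x$curve), b$n_features, 100 * b$accuracy,
    100 * b$lower, 100 * b$upper, if (b$significant) " *" else ""))
  invisible(x)
}

#' Plot an accuracy curve
#'
#' Accuracy (blue) with the Wilson interval bounds (red) against the number
#' of features, with the 50% chance level dashed.
#'
#' @param x a \code{\link{feature_curve}}.
#' @param main plot title.
#' @param ... passed to \code{plot}.
#' @export
plot.feature_curve <- function(x, main = "Accuracy vs number of features",
                               ...) {
  cv <- x$curve
  graphics::plot(cv$n_features, cv$accuracy, type = "l", col = "blue",
                 ylim = c(0, 1), xlab = "Number of features",
                 ylab = "Accuracy", main = main, ...)
  graphics::lines(cv$n_features, cv$lower, col = "red")
  graphics::lines(cv$n_features, cv$upper, col = "red")
  graphics::abline(h = 0.5, lty = 2, col = "grey40")
  invisible(x)
}
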