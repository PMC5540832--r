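test_that("point-biserial ranking scores and orders features correctly", {
  y <- factor(rep(c("psy_neg", "psy_pos"), each = 3),
              levels = c("psy_neg", "psy_pos"))
  X <- cbind(perfect = c(0, 0, 0, 1, 1, 1),   # identical to the labels
             constant = rep(2, 6),
             noisy = c(0.1, -0.2, 0.05, 0.3, -0.1, 0.2))
  rk <- rank_point_biserial(X, y)
  expect_equal(rk$scores[1], 1)
  expect_equal(rk$scores[2], 0)
  expect_equal(rk$order[1], 1)
  expect_equal(rk$order[3], 2)   # constant feature ranks last
  expect_true(all(diff(rk$scores[rk$order]) <= 0))

  # hand-computed example: r = 2/sqrt(5)
  rk2 <- rank_point_biserial(cbind(x = 1:4),
                             factor(c("psy_neg", "psy_neg",
                                      "psy_pos", "psy_pos")))
  expect_equal(rk2$scores[1], 2 / sqrt(5), tolerance = 1e-12)

  # ties in score break by ascending feature index
  Xt <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  rk3 <- rank_point_biserial(Xt, factor(c("psy_neg", "psy_neg",
                                          "psy_pos", "psy_pos")))
  expect_equal(rk3$order, c(1, 2))

  expect_error(rank_point_biserial(X, factor(rep("psy_pos", 6))), "classes")
})

test_that("naive Bayes fit uses empirical priors and floors variances", {
  # balanced fold
  d <- separable_data(n_per = 5)
  m <- fit_nb(d$X, d$y)
  expect_equal(m$priors, c(0.5, 0.5))

  # leave-one-out fold of a 31/31 cohort: priors 31/61 and 30/61
  y62 <- factor(rep(c("psy_neg", "psy_pos"), 31))
  X62 <- matrix(stats::rnorm(62 * 4), 62, 4)
  m2 <- fit_nb(X62[-1, ], y62[-1])
  expect_equal(sort(m2$priors), sort(c(31, 30) / 61))
  expect_equal(round(100 * max(m2$priors), 2), 50.82)
  expect_equal(round(100 * min(m2$priors), 2), 49.18)

  # zero within-class variance is floored from the overall feature variance
  Xz <- matrix(c(0, 0, 2, 2), ncol = 1)
  yz <- factor(c("a", "a", "b", "b"))
  mz <- fit_nb(Xz, yz)
  expect_equal(unname(mz$means[, 1]), c(0, 2))
  fl <- 1e-9 * stats::var(c(0, 0, 2, 2))
  expect_equal(unname(mz$vars[, 1]), c(fl, fl))

  expect_error(fit_nb(Xz, factor(c("a", "a", "a", "b"))), ">= 2")
})

test_that("naive Bayes prediction follows the Gaussian posterior and tie rules", {
  sym <- structure(list(classes = c("psy_neg", "psy_pos"),
                        priors = c(0.5, 0.5),
                        means = matrix(c(-1, 1), 2, 1),
                        vars = matrix(c(1, 1), 2, 1)),
                   class = "nb_model")
  # midpoint: exact tie, posterior 0.5, tie goes to the first class
  p0 <- predict_nb(sym, 0)
  expect_equal(p0$posterior, 0.5)
  expect_equal(p0$label, "psy_neg")
  # x = -1 clearly favors the mean -1 class
  p1 <- predict_nb(sym, -1)
  expect_equal(p1$label, "psy_neg")
  expect_gt(p1$posterior, 0.5)

  # equal likelihoods, unequal priors: posterior equals the prior
  skew <- structure(list(classes = c("psy_neg", "psy_pos"),
                         priors = c(0.9, 0.1),
                         means = matrix(c(0, 0), 2, 1),
                         vars = matrix(c(1, 1), 2, 1)),
                    class = "nb_model")
  ps <- predict_nb(skew, 3)
  expect_equal(ps$label, "psy_neg")
  expect_equal(ps$posterior, 0.9)

  expect_error(predict_nb(sym, c(1, 2)), "features")
})

test_that("covariate residualization fits on training rows only", {
  age <- c(10, 15, 20, 25, 30)
  Xtr <- cbind(f = 2 * age)
  Ctr <- data.frame(age = age)
  Cte <- data.frame(age = 22)
  Xte <- cbind(f = 44)
  res <- residualize_covariates(Xtr, Ctr, Xte, Cte)
  expect_true(all(abs(res$train) < 1e-8))
  expect_true(all(abs(res$test) < 1e-8))

  # covariate orthogonal to the feature: residual = centered feature
  f <- c(1, 2, 2, 1)
  Co <- data.frame(c1 = c(1, -1, 1, -1))
  res2 <- residualize_covariates(cbind(f), Co, cbind(f = 1.5),
                                 data.frame(c1 = 0))
  expect_equal(unname(res2$train[, 1]), f - mean(f))

  # unseen categorical level in the test subject is a contract violation
  Ctr2 <- data.frame(scanner = c("trio", "trio", "prisma", "trio", "prisma"))
  expect_error(
    residualize_covariates(Xtr, Ctr2, Xte, data.frame(scanner = "vida")),
    "unseen")
})

test_that("LOOCV separates well-separated classes and stays near chance on noise", {
  d <- separable_data(n_per = 8, n_feat = 10, n_inform = 3, seed = 2)
  res <- loocv(d$X, d$y, n_features = 3)
  expect_equal(res$accuracy, 1)
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 1)
  expect_true(res$significant)

  # accuracy/sensitivity/specificity recomputed from stored predictions match
  cs <- confusion_summary(res$predictions$predicted, res$predictions$true)
  expect_equal(cs$accuracy, res$accuracy)
  expect_equal(cs$sensitivity, res$sensitivity)
  expect_equal(cs$specificity, res$specificity)

  # pure-noise features: mean accuracy over seeds stays in a loose chance
  # band, and Wilson flags fire rarely
  accs <- sig <- numeric(50)
  for (s in 1:50) {
    set.seed(100 + s)
    Xn <- matrix(stats::rnorm(20 * 30), 20, 30)
    yn <- factor(rep(c("psy_neg", "psy_pos"), 10))
    r <- loocv(Xn, yn, n_features = 5)
    accs[s] <- r$accuracy
    sig[s] <- r$significant
  }
  expect_gt(mean(accs), 0.35)
  expect_lt(mean(accs), 0.65)
  expect_lte(mean(sig), 0.2)
})

test_that("every LOOCV fold on a 31/31 cohort uses 31/61 and 30/61 priors", {
  set.seed(6)
  X <- matrix(stats::rnorm(62 * 8), 62, 8)
  y <- factor(rep(c("psy_neg", "psy_pos"), 31))
  res <- loocv(X, y, n_features = 4)
  for (i in 1:62)
    expect_equal(sort(res$fold_priors[i, ]), c(30, 31) / 61)
})

test_that("feature grids honor start/step and cap at the total", {
  expect_equal(make_grid(5, 5, 254), c(seq(5, 250, 5), 254))
  expect_equal(make_grid(1, 1, 18), 1:18)
  expect_equal(make_grid(10, 10, 1600), seq(10, 1600, 10))
  d <- separable_data(n_per = 6, n_feat = 18, n_inform = 2, seed = 3)
  fc <- feature_curve(d$X, d$y, grid = list(start = 1, step = 1, max = 18))
  expect_equal(fc$curve$n_features, 1:18)
  expect_error(feature_curve(d$X, d$y, grid = list(start = 5, step = 5,
                                                   max = 100)), "exceeds")
})

test_that("feature curve recovers planted features and matches pointwise LOOCV", {
  d <- separable_data(n_per = 8, n_feat = 20, n_inform = 4, seed = 4)
  fc <- feature_curve(d$X, d$y, grid = list(start = 2, step = 2, max = 20))
  expect_true(fc$best$significant)
  expect_lte(fc$best$n_features, 8)   # planted signal found early
  expect_true(all(paste0("f", 1:2) %in% fc$best$selected))
  # grid-point accuracies agree with standalone LOOCV at that feature count
  for (k in c(2, 10)) {
    r <- loocv(d$X, d$y, n_features = k)
    expect_equal(fc$curve$accuracy[fc$curve$n_features == k], r$accuracy)
  }
  # Wilson bounds are consistent with the stored correct counts
  ci <- wilson_interval(fc$curve$n_correct, fc$n)
  expect_equal(fc$curve$lower, ci$lower)
  expect_equal(fc$curve$upper, ci$upper)
})

test_that("global ranking scope is available but warns about optimism", {
  d <- separable_data(n_per = 5, n_feat = 8, seed = 5)
  expect_warning(loocv(d$X, d$y, n_features = 2, ranking_scope = "global"),
                 "optimistically")
})

test_that("training folds never see the held-out subject's features", {
  set.seed(77)
  X <- matrix(stats::rnorm(24 * 12), 24, 12)
  y <- factor(rep(c("psy_neg", "psy_pos"), 12))
  cov <- data.frame(age = stats::runif(24, 10, 30),
                    sex = sample(c("male", "female"), 24, replace = TRUE))
  for (i in sample(24, 10)) {
    ref <- loocv_fold(X, y, i, n_features = 4, covariates = cov)
    Xc <- X
    Xc[i, ] <- 1e6   # corrupt the held-out subject
    cor <- loocv_fold(Xc, y, i, n_features = 4, covariates = cov)
    expect_identical(cor$model$means, ref$model$means)
    expect_identical(cor$model$vars, ref$model$vars)
    expect_identical(cor$model$priors, ref$model$priors)
    expect_identical(cor$selected, ref$selected)
  }
})

test_that("identical inputs and seed give bitwise-identical results", {
  d <- separable_data(n_per = 6, n_feat = 10, seed = 9)
  r1 <- feature_curve(d$X, d$y, grid = list(start = 2, step = 2, max = 10),
                      seed = 3)
  r2 <- feature_curve(d$X, d$y, grid = list(start = 2, step = 2, max = 10),
                      seed = 3)
  expect_identical(r1, r2)
})
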