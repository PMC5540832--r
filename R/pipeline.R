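#' Default feature-count grids per feature family
#'
#' Edge features: start 10, step 10, up to 1600 connections. Graph-theory
#' features: start 5, step 5, up to the full vector (254 for 83 regions,
#' with the total appended when it is off the step lattice). Diffusion:
#' 1 to 18 tracts, step 1.
#'
#' @param family one of \code{edges}, \code{graph_w}, \code{graph_b},
#'   \code{fa}, \code{ad}, \code{rd}.
#' @param n_features total features available in that family.
#' @return list with \code{start}, \code{step}, \code{max}.
#' @export
default_grid <- function(family, n_features) {
  switch(family,
         edges = list(start = 10L, step = 10L,
                      max = min(1600L, as.integer(n_features))),
         graph_w = ,
         graph_b = list(start = 5L, step = 5L, max = as.integer(n_features)),
         fa = , ad = , rd = list(start = 1L, step = 1L,
                                 max = as.integer(n_features)),
         stop("unknown family: ", family))
}

study_families <- c("edges", "graph_w", "graph_b", "fa", "ad", "rd")

# Feature matrix for one family.
family_matrix <- function(ch, family, seed, n_null) {
  switch(family,
         edges = edge_feature_matrix(ch),
         graph_w = graph_feature_matrix(ch, "weighted", seed = seed,
                                        n_null = n_null),
         graph_b = graph_feature_matrix(ch, "binary", seed = seed,
                                        n_null = n_null),
         fa = diffusion_feature_matrix(ch, "fa"),
         ad = diffusion_feature_matrix(ch, "ad"),
         rd = diffusion_feature_matrix(ch, "rd"))
}

#' Run the full discrimination study on a cohort
#'
#' Reproduces the complete analysis design on one cohort: (1) a univariate
#' Mann-Whitney + FDR screen within each feature family; (2) for the
#' weighted and the binary graph, eight single-measure classifiers — the
#' five global measures entered individually, plus one classifier per local
#' measure containing that measure for every region; (3) an incremental
#' feature curve per family (edges, weighted graph, binary graph, FA, AD,
#' RD) with the family's default grid; (4) optionally, a matched-pair
#' bootstrap of the binary-graph curve. All randomness derives from
#' \code{seed}; rerunning with the same inputs and seed reproduces every
#' table byte for byte.
#'
#' @param ch a \code{\link{cohort}}, or a \code{\link{synth_config}} (a
#'   cohort is then generated from it).
#' @param families subset of \code{edges, graph_w, graph_b, fa, ad, rd}
#'   (default all available).
#' @param grids optional named list overriding \code{\link{default_grid}}.
#' @param ranking_scope \code{"per_fold"} (default) or \code{"global"}.
#' @param covariates \code{NULL} (headline analysis, no correction) or a
#'   character vector of manifest columns, e.g.
#'   \code{c("age", "sex", "scanner")}, residualized within each fold.
#' @param exclude_ids subject ids to drop before analysis (e.g. medicated
#'   subjects in a sensitivity rerun).
#' @param bootstrap number of matched-pair bootstrap trials of the
#'   binary-graph curve (0 = skip; requires an intact pair map).
#' @param seed master seed.
#' @param n_null small-world null graphs per subject.
#' @param out_dir optional output directory: writes feature tables, screen
#'   tables, single-measure summaries, curve tables, best-feature reports,
#'   accuracy-curve plots (PDF) and a JSON summary.
#' @return list of class \code{run_manifest}: \code{seed}, \code{n},
#'   \code{screen} (per family), \code{single_measure} (per graph mode),
#'   \code{curves} (per family \code{\link{feature_curve}}),
#'   \code{bootstrap}, \code{files} (when \code{out_dir} given).
#' @export
run_study <- function(ch, families = NULL, grids = NULL,
                      ranking_scope = "per_fold", covariates = NULL,
                      exclude_ids = NULL, bootstrap = 0L,
                      seed = 1L, n_null = 100L, out_dir = NULL) {
  if (inherits(ch, "synth_config")) ch <- generate_cohort(ch)
  stopifnot(inherits(ch, "cohort"))
  if (!is.null(exclude_ids)) {
    keep <- !(ch$subjects$id %in% exclude_ids)
    if (all(keep)) warning("exclude_ids matched no subjects")
    ch <- subset_cohort(ch, ch$subjects$id[keep])
  }
  if (is.null(families)) {
    families <- study_families
    if (is.null(ch$diffusion))
      families <- setdiff(families, c("fa", "ad", "rd"))
  }
  stopifnot(all(families %in% study_families))
  y <- cohort_labels(ch)
  covdf <- NULL
  if (!is.null(covariates)) {
    stopifnot(all(covariates %in% names(ch$subjects)))
    covdf <- ch$subjects[covariates]
  }

  mats <- lapply(stats::setNames(families, families), family_matrix,
                 ch = ch, seed = seed, n_null = n_null)

  screen <- lapply(mats, univariate_screen, y = y)

  single <- list()
  for (mode in intersect(c("graph_w", "graph_b"), families)) {
    X <- mats[[mode]]
    rows <- list()
    for (gm in c("global:L", "global:E", "global:C", "global:Q",
                 "global:sigma"))
      rows[[gm]] <- loocv(X[, gm, drop = FALSE], y, n_features = 1L,
                          covariates = covdf)
    for (lm in c("bc", "cc", "str")) {
      cols <- grep(paste0("^", lm, ":"), colnames(X), value = TRUE)
      rows[[lm]] <- loocv(X[, cols, drop = FALSE], y,
                          n_features = length(cols), covariates = covdf)
    }
    single[[mode]] <- rows
  }

  curves <- list()
  for (fam in families) {
    grid <- if (!is.null(grids[[fam]])) grids[[fam]]
            else default_grid(fam, ncol(mats[[fam]]))
    curves[[fam]] <- feature_curve(mats[[fam]], y, grid = grid,
                                   ranking_scope = ranking_scope,
                                   covariates = covdf, seed = seed)
  }

  boot <- NULL
  if (bootstrap > 0L && "graph_b" %in% families) {
    boot <- matched_pair_bootstrap(
      mats[["graph_b"]], y, ch$subjects$pair_id,
      grid = if (!is.null(grids[["graph_b"]])) grids[["graph_b"]]
             else default_grid("graph_b", ncol(mats[["graph_b"]])),
      n_trials = bootstrap, seed = seed, covariates = covdf)
  }

  manifest <- structure(list(
    seed = seed, n = nrow(ch$subjects),
    groups = table(ch$subjects$group),
    families = families, ranking_scope = ranking_scope,
    covariates = covariates,
    screen = screen, single_measure = single, curves = curves,
    bootstrap = boot, files = NULL
  ), class = "run_manifest")

  if (!is.null(out_dir))
    manifest$files <- write_study_outputs(manifest, mats, out_dir)
  manifest
}

#' Keep a subset of a cohort's subjects
#' @param ch a \code{\link{cohort}}.
#' @param ids subject ids to keep, in cohort order.
#' @return a \code{\link{cohort}} (pair map may become incomplete; only the
#'   bootstrap requires complete pairs).
#' @export
subset_cohort <- function(ch, ids) {
  sel <- ch$subjects$id %in% ids
  subj <- ch$subjects[sel, , drop = FALSE]
  out <- ch
  out$subjects <- subj
  out$connectomes <- ch$connectomes[subj$id]
  if (!is.null(ch$lengths)) out$lengths <- ch$lengths[subj$id]
  if (!is.null(ch$diffusion)) out$diffusion <- ch$diffusion[subj$id]
  out
}

single_measure_table <- function(rows) {
  do.call(rbind, lapply(names(rows), function(nm) {
    r <- rows[[nm]]
    data.frame(measure = nm, accuracy = r$accuracy,
               ci_lower = r$wilson_lower, ci_upper = r$wilson_upper,
               sensitivity = r$sensitivity, specificity = r$specificity,
               significant = r$significant)
  }))
}

write_study_outputs <- function(manifest, mats, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(obj, name) {
    path <- file.path(out_dir, name)
    utils::write.table(obj, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <<- c(files, path)
    path
  }
  for (fam in names(mats))
    put(data.frame(id = rownames(mats[[fam]]), mats[[fam]],
                   check.names = FALSE),
        sprintf("features_%s.tsv", fam))
  for (fam in names(manifest$screen))
    put(manifest$screen[[fam]], sprintf("screen_%s.tsv", fam))
  for (mode in names(manifest$single_measure))
    put(single_measure_table(manifest$single_measure[[mode]]),
        sprintf("single_measure_%s.tsv", mode))
  for (fam in names(manifest$curves)) {
    fc <- manifest$curves[[fam]]
    put(fc$curve, sprintf("curve_%s.tsv", fam))
    put(data.frame(rank = seq_along(fc$best$selected),
                   feature = fc$best$selected),
        sprintf("best_features_%s.tsv", fam))
    pdf_path <- file.path(out_dir, sprintf("curve_%s.pdf", fam))
    grDevices::pdf(pdf_path, width = 7, height = 5)
    plot(fc, main = sprintf("Accuracy vs number of features (%s)", fam))
    grDevices::dev.off()
    files <- c(files, pdf_path)
  }
  if (!is.null(manifest$bootstrap))
    put(manifest$bootstrap$trials, "bootstrap_trials.tsv")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    summ <- list(
      seed = manifest$seed, n = manifest$n,
      groups = as.list(manifest$groups),
      best = lapply(manifest$curves, function(fc)
        fc$best[c("n_features", "accuracy", "lower", "upper",
                  "significant")]),
      bootstrap = if (is.null(manifest$bootstrap)) NULL else
        manifest$bootstrap[c("n_trials", "fraction_above_chance",
                             "fraction_significant")]
    )
    jpath <- file.path(out_dir, "summary.json")
    jsonlite::write_json(summ, jpath, auto_unbox = TRUE, digits = NA)
    files <- c(files, jpath)
  }
  files
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("study run: n = %d (%s), seed %d\n", x$n,
              paste(sprintf("%s %d", names(x$groups), x$groups),
                    collapse = " / "), x$seed))
  for (fam in names(x$curves)) {
    b <- x$curves[[fam]]$best
    cat(sprintf("  %-8s best %.1f%% (CI %.1f-%.1f%%)%s at %d features\n",
                fam, 100 * b$accuracy, 100 * b$lower, 100 * b$upper,
                if (b$significant) " *" else "", b$n_features))
  }
  if (!is.null(x$bootstrap))
    print(x$bootstrap)
  invisible(x)
}
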