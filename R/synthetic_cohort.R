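#' Configuration for the synthetic cohort generator
#'
#' Describes a two-group matched cohort with the statistical structure the
#' analysis pipeline assumes: a shared modular connectome template;
#' subject-level multiplicative count noise and heterogeneous edge dropout;
#' a topological group effect implemented as local edge rewiring — every
#' patient carries the same amount of rewiring, concentrated at the
#' designated regions in \code{psy_pos} subjects and at per-subject random
#' regions in \code{psy_neg} subjects, so global graph measures are
#' exchangeable between groups while betweenness and clustering at the
#' designated regions discriminate; nuisance covariate effects (age, sex,
#' scanner batch); and tract-wise diffusion tables with an FA-decrease /
#' RD-increase planted in designated bundles.
#'
#' @param n_pairs matched psy_pos/psy_neg pairs (default 31, the study
#'   design).
#' @param n_regions parcellation size (default 83; 83 selects the standard
#'   \code{\link{dk_parcellation}}, anything else a
#'   \code{\link{toy_parcellation}}).
#' @param community_sizes sizes of the template's communities (default:
#'   four near-equal blocks).
#' @param within_density,between_density edge probability inside / between
#'   communities. Defaults are 0.45 / 0.08 at 83 regions and are rescaled
#'   for other parcellation sizes to keep the expected node degree fixed
#'   (capped at 0.9), because coarser parcellations yield denser
#'   connectomes in real tractography.
#' @param count_meanlog,count_sdlog log-normal parameters of streamline
#'   counts on present edges (defaults log(50), 1).
#' @param length_range range of mean streamline lengths in mm (default
#'   10-150).
#' @param count_noise subject-level multiplicative log-normal noise sigma on
#'   counts (default 0.3).
#' @param edge_dropout mean probability that any given template edge is
#'   missing from a subject's connectome (default 0.1), emulating the
#'   false-negative streamlines that make binary connectomes vary across
#'   subjects even without group effects.
#' @param dropout_spread half-width of the per-subject dropout rate range:
#'   subject rates are drawn uniformly from \code{edge_dropout} +/-
#'   \code{dropout_spread} (default 0.03, mild scan-quality
#'   heterogeneity). Large values create a strong shared density factor
#'   across all graph features, which both inflates the variance of
#'   global measures and drives leave-one-out accuracy on null data away
#'   from its nominal chance behaviour.
#' @param affected_nodes region labels carrying the group effect. Default
#'   for the 83-region parcellation: right amygdala, left posterior
#'   cingulate, left parahippocampal and right rostral anterior cingulate
#'   (the regions whose binary betweenness/clustering discriminated the
#'   groups in the motivating study); otherwise five regions evenly spaced
#'   through the parcellation.
#' @param topo_effect probability that each edge incident to a rewired node
#'   is reattached to a random non-neighbour (default 0.3). Applied at the
#'   affected regions for psy_pos subjects and at per-subject random
#'   regions for psy_neg subjects; 0 disables rewiring in both groups.
#' @param affected_tracts tract names carrying the diffusion effect
#'   (default: bilateral inferior longitudinal fasciculus and cingulum
#'   cingulate gyrus).
#' @param fa_shift additive FA shift in psy_pos affected tracts (negative;
#'   default -0.03).
#' @param rd_shift additive RD shift, mm^2/s (positive; default 3e-5).
#' @param fa_noise,diff_noise subject-level s.d. of FA and of AD/RD
#'   (defaults 0.02 and 3e-5).
#' @param age_effect,sex_effect,scanner_effect nuisance effect sizes: log
#'   multipliers on counts per age z-score / male sex / second scanner, and
#'   (scaled) additive shifts on diffusion (defaults 0.05, 0.05, 0.1).
#' @param seed master seed; everything the generator draws flows from it.
#' @return list of class \code{synth_config}.
#' @export
synth_config <- function(n_pairs = 31L, n_regions = 83L,
                         community_sizes = NULL,
                         within_density = NULL, between_density = NULL,
                         count_meanlog = log(50), count_sdlog = 1,
                         length_range = c(10, 150),
                         count_noise = 0.3,
                         edge_dropout = 0.1,
                         dropout_spread = 0.03,
                         affected_nodes = NULL,
                         topo_effect = 0.3,
                         affected_tracts = c("lh.ilf", "rh.ilf",
                                             "lh.ccg", "rh.ccg"),
                         fa_shift = -0.03, rd_shift = 3e-5,
                         fa_noise = 0.02, diff_noise = 3e-5,
                         age_effect = 0.05, sex_effect = 0.05,
                         scanner_effect = 0.1,
                         seed = 1L) {
  stopifnot(n_pairs >= 2L, n_regions >= 6L,
            topo_effect >= 0, topo_effect <= 1,
            edge_dropout >= 0, edge_dropout < 1,
            dropout_spread >= 0, dropout_spread <= edge_dropout | edge_dropout == 0,
            fa_shift <= 0, rd_shift >= 0)
  # density defaults rise for coarser parcellations (real connectome
  # density grows, sublinearly, as regions get bigger); sqrt scaling of
  # the 83-region baseline keeps node degrees away from the noisy
  # low-degree regime without saturating the graph
  dens_scale <- sqrt(82 / (n_regions - 1))
  if (is.null(within_density))
    within_density <- min(0.45 * dens_scale, 0.9)
  if (is.null(between_density))
    between_density <- min(0.08 * dens_scale, 0.45)
  stopifnot(within_density > between_density)
  parc <- if (n_regions == 83L) dk_parcellation() else
    toy_parcellation(n_regions)
  if (is.null(community_sizes)) {
    base <- n_regions %/% 4L
    community_sizes <- rep(base, 4L)
    community_sizes[seq_len(n_regions - 4L * base)] <-
      community_sizes[seq_len(n_regions - 4L * base)] + 1L
  }
  stopifnot(sum(community_sizes) == n_regions)
  if (is.null(affected_nodes)) {
    affected_nodes <- if (n_regions == 83L)
      c("rh.amygdala", "lh.posteriorcingulate", "lh.parahippocampal",
        "rh.rostralanteriorcingulate")
    else parc$labels[round(seq(1L, n_regions, length.out = 5L))]
  }
  if (!all(affected_nodes %in% parc$labels))
    stop("affected_nodes must be labels of the parcellation")
  structure(list(
    n_pairs = as.integer(n_pairs), n_regions = as.integer(n_regions),
    parcellation = parc, community_sizes = as.integer(community_sizes),
    within_density = within_density, between_density = between_density,
    count_meanlog = count_meanlog, count_sdlog = count_sdlog,
    length_range = length_range, count_noise = count_noise,
    edge_dropout = edge_dropout, dropout_spread = dropout_spread,
    affected_nodes = affected_nodes, topo_effect = topo_effect,
    affected_tracts = affected_tracts,
    fa_shift = fa_shift, rd_shift = rd_shift,
    fa_noise = fa_noise, diff_noise = diff_noise,
    age_effect = age_effect, sex_effect = sex_effect,
    scanner_effect = scanner_effect,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' Generate the cohort's template connectome
#'
#' A stochastic-block-model graph (denser within than between communities)
#' with log-normal streamline counts and uniform mean lengths on the
#' present edges. All subjects' connectomes are noisy copies of this
#' template, so it defines the cohort's shared network organization.
#'
#' @param config a \code{\link{synth_config}}.
#' @param seed seed (default: the config's).
#' @return list with \code{counts} (a \code{\link{connectivity_matrix}})
#'   and \code{lengths} (numeric matrix, mm).
#' @export
generate_template <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_regions
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old))
  set.seed(seed)
  comm <- rep(seq_along(config$community_sizes), config$community_sizes)
  P <- ifelse(outer(comm, comm, "=="), config$within_density,
              config$between_density)
  A <- matrix(0, n, n)
  low <- lower.tri(A)
  A[low] <- stats::runif(sum(low)) < P[low]
  counts <- matrix(0, n, n)
  counts[low] <- A[low] * stats::rlnorm(sum(low), config$count_meanlog,
                                        config$count_sdlog)
  counts <- counts + t(counts)
  lengths <- matrix(0, n, n)
  lengths[low] <- A[low] * stats::runif(sum(low), config$length_range[1L],
                                        config$length_range[2L])
  lengths <- lengths + t(lengths)
  dimnames(lengths) <- list(config$parcellation$labels,
                            config$parcellation$labels)
  cm <- connectivity_matrix(counts, config$parcellation)
  comp <- igraph::components(as_igraph(cm$weights))
  if (comp$no > 1L)
    warning("template graph is disconnected; consider raising the density")
  list(counts = cm, lengths = lengths)
}

#' Generate a complete synthetic cohort
#'
#' Produces \code{2 * n_pairs} subjects in matched pairs (age within one
#' year, same sex), SIPS positive-subscale scores consistent with the
#' intended groups, per-subject connectomes (template + edge dropout +
#' localized rewiring + covariate effects + multiplicative count noise)
#' with matching length matrices, and per-subject diffusion tables with
#' the planted tract effects.
#'
#' @param config a \code{\link{synth_config}}.
#' @return a \code{\link{cohort}} with connectomes, lengths and diffusion
#'   tables; the generating config is attached as attribute \code{config}.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  template <- generate_template(config)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old))
  set.seed(config$seed + 1L)
  n_pairs <- config$n_pairs
  n_sub <- 2L * n_pairs
  parc <- config$parcellation

  # matched demographics: same sex, age within a year, shared scanner mix
  base_age <- stats::runif(n_pairs, 11, 30)
  pair_sex <- sample(c("male", "female"), n_pairs, replace = TRUE)
  subjects <- data.frame(
    id = sprintf("sub%03d", seq_len(n_sub)),
    age = as.vector(rbind(base_age,
                          base_age + stats::runif(n_pairs, -1, 1))),
    sex = rep(pair_sex, each = 2L),
    scanner = sample(c("trio", "prisma"), n_sub, replace = TRUE,
                     prob = c(0.8, 0.2)),
    pair_id = rep(sprintf("pair%03d", seq_len(n_pairs)), each = 2L),
    stringsAsFactors = FALSE
  )
  group <- rep(c("psy_pos", "psy_neg"), n_pairs)

  # SIPS positive scores consistent with the intended group
  sips <- matrix(sample(0:2, n_sub * 5L, replace = TRUE), n_sub, 5L)
  for (i in which(group == "psy_pos"))
    sips[i, sample.int(5L, 1L)] <- sample(3:6, 1L)
  colnames(sips) <- paste0("P", 1:5)
  stopifnot(identical(unname(label_from_sips(sips)), group))
  subjects <- cbind(subjects, as.data.frame(sips))

  aff_idx <- match(config$affected_nodes, parc$labels)
  W0 <- template$counts$weights
  L0 <- template$lengths
  low <- lower.tri(W0)
  zage <- (subjects$age - 20.5) / 5.5
  cov_lin <- config$age_effect * zage +
    config$sex_effect * (subjects$sex == "male") +
    config$scanner_effect * (subjects$scanner == "prisma")

  connectomes <- vector("list", n_sub)
  lengths <- vector("list", n_sub)
  diffusion <- vector("list", n_sub)

  tracts <- tracula_tracts()
  fa0 <- stats::runif(18L, 0.35, 0.55)
  ad0 <- stats::runif(18L, 1.1e-3, 1.4e-3)
  rd0 <- stats::runif(18L, 4.0e-4, 6.5e-4)
  aff_tr <- match(config$affected_tracts, tracts)
  if (anyNA(aff_tr)) stop("affected_tracts must be valid tract names")

  for (i in seq_len(n_sub)) {
    W <- W0
    if (config$edge_dropout > 0) {
      # per-subject false-negative edges: every subject misses a random
      # fraction of the template's connections, and the fraction itself
      # varies across subjects (scan quality / motion heterogeneity), so
      # global connectome density fluctuates the way real cohorts do
      rate_i <- stats::runif(1, config$edge_dropout - config$dropout_spread,
                             config$edge_dropout + config$dropout_spread)
      miss <- low & W > 0 & stats::runif(length(W)) < rate_i
      W[miss | t(miss)] <- 0
    }
    if (config$topo_effect > 0) {
      # every patient carries the same amount of local rewiring; the group
      # difference is WHERE it concentrates: psy_pos at the designated
      # regions, psy_neg at regions drawn fresh per subject. Global
      # topology is therefore exchangeable between groups (global
      # classifiers sit at chance) and the signal lives in the local
      # measures of the designated regions.
      nodes_i <- if (group[i] == "psy_pos") aff_idx
                 else sample.int(config$n_regions, length(aff_idx))
      W <- rewire_affected(W, nodes_i, config$topo_effect)
    }
    noise <- matrix(0, nrow(W), ncol(W))
    noise[low] <- stats::rnorm(sum(low), 0, config$count_noise)
    noise <- noise + t(noise)
    W <- W * exp(noise) * exp(cov_lin[i])
    connectomes[[i]] <- connectivity_matrix(W, parc)
    Li <- L0 * (W > 0)
    new_edge <- low & W > 0 & Li == 0   # edges created by rewiring
    if (any(new_edge)) {
      Li[new_edge] <- stats::runif(sum(new_edge), config$length_range[1L],
                                   config$length_range[2L])
      Li[upper.tri(Li)] <- t(Li)[upper.tri(Li)]
    }
    lengths[[i]] <- Li
    fa <- fa0 + stats::rnorm(18L, 0, config$fa_noise) + 0.02 * cov_lin[i]
    ad <- ad0 + stats::rnorm(18L, 0, config$diff_noise) + 2e-5 * cov_lin[i]
    rd <- rd0 + stats::rnorm(18L, 0, config$diff_noise) + 2e-5 * cov_lin[i]
    if (group[i] == "psy_pos") {
      fa[aff_tr] <- fa[aff_tr] + config$fa_shift
      rd[aff_tr] <- rd[aff_tr] + config$rd_shift
    }
    fa <- pmin(pmax(fa, 0), 1)
    rd <- pmax(rd, 0)
    ad <- pmax(ad, rd)
    diffusion[[i]] <- diffusion_features(tracts, fa, ad, rd)
  }
  names(connectomes) <- names(lengths) <- names(diffusion) <- subjects$id
  ch <- cohort(subjects, parc, connectomes, lengths = lengths,
               diffusion = diffusion)
  stopifnot(identical(ch$subjects$group, group))
  attr(ch, "config") <- config
  ch
}

# Local rewiring: each edge incident to a selected node is, with
# probability topo_effect, detached from its current endpoint and
# reattached to a random non-neighbour. Node degree (and so strength) at
# the node is preserved, but its neighbourhood randomizes: the new
# neighbours are not interconnected, so the local clustering coefficient
# collapses and shortest-path routing through the node shifts — the group
# signal lives in the betweenness/clustering features of the regions where
# the rewiring concentrates.
rewire_affected <- function(W, aff_idx, p) {
  for (v in aff_idx) {
    for (u in which(W[v, ] > 0)) {
      if (stats::runif(1) >= p) next
      free <- which(W[v, ] == 0)
      free <- setdiff(free, c(v, u))
      if (!length(free)) next
      w <- if (length(free) == 1L) free else sample(free, 1L)
      W[v, w] <- W[w, v] <- W[v, u]
      W[v, u] <- W[u, v] <- 0
    }
  }
  W
}

#' Planted discriminative feature names of a config
#'
#' The binary-graph local features the generator's topological effect
#' targets: betweenness and clustering at each affected region.
#'
#' @param config a \code{\link{synth_config}}.
#' @return character vector of feature names (\code{bc:<region>},
#'   \code{cc:<region>}).
#' @export
planted_features <- function(config) {
  c(paste0("bc:", config$affected_nodes),
    paste0("cc:", config$affected_nodes))
}

#' Parameter-recovery experiment
#'
#' Generates a cohort from \code{config}, runs the binary-graph incremental
#' feature curve, and reports whether the analysis recovers what was
#' planted: a Wilson-significant best accuracy and the affected regions'
#' betweenness/clustering features among the best feature set.
#'
#' @param config a \code{\link{synth_config}}.
#' @param grid feature-count grid (default \code{list(start=5, step=5,
#'   max=} total features\code{)}).
#' @param n_null small-world null graphs per subject (default 100).
#' @param ranking_scope,covariates passed to \code{\link{feature_curve}}.
#' @return list of class \code{recovery_report}: the \code{feature_curve}
#'   \code{best} summary, \code{planted} feature names, \code{recovered}
#'   (planted features in the best set), \code{n_recovered},
#'   \code{significant}.
#' @export
recovery_experiment <- function(config, grid = NULL, n_null = 100L,
                                ranking_scope = "per_fold",
                                covariates = NULL) {
  ch <- generate_cohort(config)
  X <- graph_feature_matrix(ch, mode = "binary", seed = config$seed,
                            n_null = n_null)
  if (is.null(grid)) grid <- list(start = 5L, step = 5L, max = ncol(X))
  fc <- feature_curve(X, cohort_labels(ch), grid = grid,
                      ranking_scope = ranking_scope,
                      covariates = covariates, seed = config$seed)
  planted <- planted_features(config)
  recovered <- intersect(fc$best$selected, planted)
  structure(list(best = fc$best, curve = fc$curve, planted = planted,
                 recovered = recovered, n_recovered = length(recovered),
                 significant = fc$best$significant),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "recovery: best accuracy %.1f%% (CI %.1f-%.1f%%)%s with %d features; %d/%d planted features recovered\n",
    100 * x$best$accuracy, 100 * x$best$lower, 100 * x$best$upper,
    if (x$significant) " *" else "", x$best$n_features,
    x$n_recovered, length(x$planted)))
  invisible(x)
}
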