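#' Construct a connectivity matrix
#'
#' A connectivity matrix stores undirected structural connectivity between
#' every pair of regions in a parcellation: streamline counts as produced by
#' whole-brain tractography, or counts per millimetre after length
#' normalization (see \code{\link{length_normalize}}). The matrix must be
#' symmetric, nonnegative, and zero on the diagonal.
#'
#' @param weights n x n numeric matrix of nonnegative weights.
#' @param parcellation a \code{\link{parcellation}} of matching size.
#' @param normalized logical; \code{TRUE} once length-normalized.
#' @return An object of class \code{connectivity_matrix}.
#' @export
connectivity_matrix <- function(weights, parcellation, normalized = FALSE) {
  weights <- as.matrix(weights)
  n <- parcellation$n_regions
  if (!is.numeric(weights) || nrow(weights) != n || ncol(weights) != n)
    stop(sprintf("matrix must be %d x %d numeric to match the parcellation", n, n))
  if (any(weights < 0))
    stop("connectivity weights must be nonnegative")
  if (!sym_within_tol(weights))
    stop("connectivity matrix must be symmetric (tolerance 1e-9 relative)")
  weights <- (weights + t(weights)) / 2  # remove sub-tolerance asymmetry
  if (any(diag(weights) != 0))
    stop("connectivity matrix must have a zero diagonal")
  dimnames(weights) <- list(parcellation$labels, parcellation$labels)
  structure(list(weights = weights, parcellation = parcellation,
                 normalized = isTRUE(normalized)),
            class = "connectivity_matrix")
}

sym_within_tol <- function(m, tol = 1e-9) {
  scale <- max(abs(m), 1)
  max(abs(m - t(m))) <= tol * scale
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  n <- x$parcellation$n_regions
  cat(sprintf("connectivity_matrix: %d regions, %d edges%s\n", n,
              sum(x$weights[upper.tri(x$weights)] > 0),
              if (x$normalized) " (length-normalized)" else ""))
  invisible(x)
}

#' Load a connectivity or length matrix from delimited text
#'
#' Reads a dense numeric n x n matrix (whitespace- or comma-delimited, no
#' header by default). Validation mirrors what tractography exports need:
#' dimension mismatch and negative entries are fatal; a nonzero diagonal is
#' zeroed with a warning; asymmetry beyond a 1e-9 relative tolerance is
#' symmetrized by averaging with a warning (exporters differ in rounding).
#'
#' @param path file path.
#' @param parcellation a \code{\link{parcellation}} the matrix must match.
#' @param header logical; if \code{TRUE} the first row holds region names
#'   which are checked against the parcellation.
#' @return A \code{\link{connectivity_matrix}} (with \code{normalized = FALSE}).
#' @export
load_matrix <- function(path, parcellation, header = FALSE) {
  m <- read_dense_matrix(path, header = header)
  n <- parcellation$n_regions
  if (header) {
    if (!identical(colnames(m), parcellation$labels))
      stop("header region names do not match the parcellation")
  }
  if (nrow(m) != n || ncol(m) != n)
    stop(sprintf("matrix in '%s' is %d x %d but the parcellation has %d regions",
                 path, nrow(m), ncol(m), n))
  if (any(m < 0))
    stop(sprintf("matrix in '%s' has negative entries", path))
  if (!sym_within_tol(m)) {
    warning(sprintf("matrix in '%s' is asymmetric beyond tolerance; symmetrized by averaging",
                    path))
    m <- (m + t(m)) / 2
  }
  if (any(diag(m) != 0)) {
    warning(sprintf("matrix in '%s' has a nonzero diagonal; zeroed", path))
    diag(m) <- 0
  }
  connectivity_matrix(m, parcellation)
}

read_dense_matrix <- function(path, header = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- gsub(",", " ", lines, fixed = TRUE)
  cn <- NULL
  if (header) {
    cn <- strsplit(trimws(lines[1L]), "[[:space:]]+")[[1L]]
    lines <- lines[-1L]
  }
  rows <- lapply(strsplit(trimws(lines), "[[:space:]]+"), as.numeric)
  ncol <- unique(lengths(rows))
  if (length(ncol) != 1L)
    stop(sprintf("ragged matrix in '%s'", path))
  m <- do.call(rbind, rows)
  if (anyNA(m)) stop(sprintf("non-numeric entries in '%s'", path))
  colnames(m) <- cn
  m
}

#' Write a matrix as delimited text
#'
#' Full-precision (17 significant digits) tab-delimited output, so that a
#' write/load round trip reproduces every entry exactly.
#'
#' @param m a \code{connectivity_matrix}, or a plain numeric matrix.
#' @param path file path.
#' @param header write a region-name header row.
#' @export
write_matrix <- function(m, path, header = FALSE) {
  w <- if (inherits(m, "connectivity_matrix")) m$weights else as.matrix(m)
  con <- file(path, "w")
  on.exit(close(con))
  if (header && !is.null(colnames(w)))
    writeLines(paste(colnames(w), collapse = "\t"), con)
  writeLines(apply(w, 1L, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = "\t")), con)
  invisible(path)
}

#' Normalize streamline counts by mean streamline length
#'
#' Tractography streamline counts are biased toward long tracts sampled by
#' many seeds; dividing each count by the mean length (mm) of the
#' streamlines connecting that pair corrects the bias. Entries with no
#' streamlines stay zero; the matrices are never thresholded, so the support
#' is preserved exactly.
#'
#' @param counts a \code{\link{connectivity_matrix}} of raw streamline counts.
#' @param lengths a matching matrix of mean streamline lengths (mm): a plain
#'   numeric matrix or a \code{connectivity_matrix}-like object; must be
#'   positive wherever \code{counts} is positive.
#' @return A \code{\link{connectivity_matrix}} with \code{normalized = TRUE}.
#' @export
length_normalize <- function(counts, lengths) {
  stopifnot(inherits(counts, "connectivity_matrix"))
  L <- if (inherits(lengths, "connectivity_matrix")) lengths$weights else as.matrix(lengths)
  W <- counts$weights
  if (!all(dim(L) == dim(W)))
    stop("count and length matrices have different dimensions")
  bad <- W > 0 & L <= 0
  if (any(bad))
    stop(sprintf("%d connections have streamlines but no positive mean length",
                 sum(bad) / 2L))
  out <- ifelse(W > 0, W / ifelse(L > 0, L, 1), 0)
  connectivity_matrix(out, counts$parcellation, normalized = TRUE)
}

#' Binarize a connectivity matrix
#'
#' Keeps only the existence of each connection: any strictly positive weight
#' becomes an edge. No threshold other than zero is applied, matching
#' unthresholded streamline-count matrices.
#'
#' @param m a \code{\link{connectivity_matrix}}.
#' @return An object of class \code{binary_adjacency}.
#' @export
binarize <- function(m) {
  stopifnot(inherits(m, "connectivity_matrix"))
  a <- (m$weights > 0) * 1
  structure(list(adjacency = a, parcellation = m$parcellation),
            class = "binary_adjacency")
}

#' @export
print.binary_adjacency <- function(x, ...) {
  cat(sprintf("binary_adjacency: %d regions, %d edges\n",
              x$parcellation$n_regions,
              sum(x$adjacency[upper.tri(x$adjacency)])))
  invisible(x)
}

#' Flatten a connectivity matrix to an edge feature vector
#'
#' Returns the strict upper triangle flattened row-major, i.e. pairs
#' (1,2), (1,3), ..., (1,n), (2,3), ..., (n-1,n), as the classifier's
#' edge-level feature vector. The element names \code{"<region_i>|<region_j>"}
#' and the attached \code{index_map} (a data frame of i, j indices) make the
#' flattening invertible (\code{\link{devectorize_edges}}).
#'
#' @param m a \code{\link{connectivity_matrix}}.
#' @return Named numeric vector of length n(n-1)/2 with attribute
#'   \code{index_map}.
#' @export
vectorize_edges <- function(m) {
  stopifnot(inherits(m, "connectivity_matrix"))
  W <- m$weights
  # column-major lower triangle of a symmetric matrix == row-major upper triangle
  idx <- which(lower.tri(W), arr.ind = TRUE)
  map <- data.frame(i = idx[, "col"], j = idx[, "row"])
  v <- W[lower.tri(W)]
  names(v) <- paste(m$parcellation$labels[map$i],
                    m$parcellation$labels[map$j], sep = "|")
  attr(v, "index_map") <- map
  v
}

#' Rebuild a connectivity matrix from an edge vector
#' @param v edge vector as produced by \code{\link{vectorize_edges}}.
#' @param parcellation the \code{\link{parcellation}} it was built over.
#' @param normalized passed through to the constructor.
#' @return A \code{\link{connectivity_matrix}}.
#' @export
devectorize_edges <- function(v, parcellation, normalized = FALSE) {
  n <- parcellation$n_regions
  stopifnot(length(v) == n * (n - 1) / 2)
  W <- matrix(0, n, n)
  W[lower.tri(W)] <- v
  W <- W + t(W)
  connectivity_matrix(W, parcellation, normalized = normalized)
}

#' Group label from SIPS positive-subscale scores
#'
#' Subjects scoring at least 3 on any of the five positive items (P1-P5,
#' each 0-6) are labeled \code{psy_pos} (attenuated positive psychotic
#' symptoms present); all others \code{psy_neg}. Time and frequency criteria
#' are not part of the rule.
#'
#' @param sips_positive numeric vector of five integers in 0..6, or a matrix
#'   with five columns (one row per subject).
#' @return character: \code{"psy_pos"} or \code{"psy_neg"} (vector if a
#'   matrix was given).
#' @examples
#' label_from_sips(c(3, 0, 0, 0, 0))  # "psy_pos"
#' label_from_sips(c(2, 2, 2, 2, 2))  # "psy_neg"
#' @export
label_from_sips <- function(sips_positive) {
  m <- if (is.matrix(sips_positive)) sips_positive else
    matrix(sips_positive, nrow = 1L)
  if (ncol(m) != 5L)
    stop("expected five positive-subscale scores (P1-P5)")
  if (any(m < 0 | m > 6 | m != round(m)))
    stop("SIPS positive scores must be integers in 0..6")
  out <- ifelse(apply(m, 1L, max) >= 3, "psy_pos", "psy_neg")
  if (is.matrix(sips_positive)) out else out[[1L]]
}

#' Construct a per-subject diffusion feature table
#'
#' Mean diffusion-tensor scalars along each reconstructed white-matter
#' bundle: fractional anisotropy (FA, unitless in [0,1]), axial diffusivity
#' (AD) and radial diffusivity (RD) (both mm^2/s, with AD >= RD >= 0).
#'
#' @param tract_names ordered character vector of bundle names.
#' @param fa,ad,rd numeric vectors of per-tract means.
#' @return An object of class \code{diffusion_features} (a data frame).
#' @export
diffusion_features <- function(tract_names = tracula_tracts(), fa, ad, rd) {
  k <- length(tract_names)
  if (length(fa) != k || length(ad) != k || length(rd) != k)
    stop("fa, ad, rd must each have one value per tract")
  if (any(fa < 0 | fa > 1)) stop("FA must lie in [0, 1]")
  if (any(rd < 0) || any(ad < rd)) stop("need AD >= RD >= 0 for every tract")
  structure(data.frame(tract = as.character(tract_names),
                       fa = fa, ad = ad, rd = rd),
            class = c("diffusion_features", "data.frame"))
}

#' Read a diffusion feature table (columns tract, fa, ad, rd)
#' @param path delimited-text file with header.
#' @param tract_names expected tract order; defaults to the file's order.
#' @return A \code{\link{diffusion_features}} table.
#' @export
load_diffusion <- function(path, tract_names = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  need <- c("tract", "fa", "ad", "rd")
  if (!all(need %in% names(tab)))
    stop("diffusion table must have columns tract, fa, ad, rd")
  if (!is.null(tract_names)) {
    if (!setequal(tab$tract, tract_names))
      stop("diffusion table tracts do not match the expected tract list")
    tab <- tab[match(tract_names, tab$tract), ]
  }
  diffusion_features(tab$tract, tab$fa, tab$ad, tab$rd)
}

#' Assemble a cohort
#'
#' A cohort bundles the subject manifest with per-subject feature sources.
#' Groups are taken from the manifest's \code{group} column when present,
#' otherwise derived from SIPS columns \code{P1..P5} via
#' \code{\link{label_from_sips}}.
#'
#' @param subjects data frame with columns \code{id}, \code{age}, \code{sex},
#'   \code{scanner}, \code{pair_id}, and either \code{group} or
#'   \code{P1..P5}.
#' @param parcellation shared \code{\link{parcellation}}.
#' @param connectomes named list (by subject id) of
#'   \code{\link{connectivity_matrix}} objects.
#' @param lengths optional named list of length matrices (plain matrices).
#' @param diffusion optional named list of \code{\link{diffusion_features}}.
#' @return An object of class \code{cohort}.
#' @export
cohort <- function(subjects, parcellation, connectomes,
                   lengths = NULL, diffusion = NULL) {
  subjects <- as.data.frame(subjects)
  need <- c("id", "age", "sex", "scanner", "pair_id")
  if (!all(need %in% names(subjects)))
    stop("subject manifest needs columns: ", paste(need, collapse = ", "))
  subjects$id <- as.character(subjects$id)
  if (anyDuplicated(subjects$id)) stop("duplicate subject ids")
  if (!"group" %in% names(subjects)) {
    sip_cols <- paste0("P", 1:5)
    if (!all(sip_cols %in% names(subjects)))
      stop("manifest must carry either a group column or P1..P5 scores")
    subjects$group <- label_from_sips(as.matrix(subjects[sip_cols]))
  }
  if (!all(subjects$group %in% c("psy_pos", "psy_neg")))
    stop("group labels must be psy_pos or psy_neg")
  check_pairs(subjects)
  if (!all(subjects$id %in% names(connectomes)))
    stop("every subject needs a connectome")
  connectomes <- connectomes[subjects$id]
  if (!is.null(diffusion)) {
    if (!all(subjects$id %in% names(diffusion)))
      stop("diffusion tables missing for some subjects")
    diffusion <- diffusion[subjects$id]
  }
  if (!is.null(lengths)) lengths <- lengths[subjects$id]
  structure(list(subjects = subjects, parcellation = parcellation,
                 connectomes = connectomes, lengths = lengths,
                 diffusion = diffusion),
            class = "cohort")
}

check_pairs <- function(subjects) {
  sp <- split(subjects$group, subjects$pair_id)
  ok <- vapply(sp, function(g)
    length(g) == 2L && setequal(g, c("psy_pos", "psy_neg")), logical(1L))
  if (!all(ok))
    stop("each pair_id must link exactly one psy_pos to one psy_neg subject")
  invisible(TRUE)
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat(sprintf("cohort: %d subjects (%d psy_pos / %d psy_neg), %d regions%s\n",
              nrow(x$subjects), tab[["psy_pos"]], tab[["psy_neg"]],
              x$parcellation$n_regions,
              if (is.null(x$diffusion)) "" else ", with diffusion tables"))
  invisible(x)
}

#' Binary group labels of a cohort
#' @param ch a \code{\link{cohort}}.
#' @return factor with levels \code{psy_neg}, \code{psy_pos}.
#' @export
cohort_labels <- function(ch) {
  factor(ch$subjects$group, levels = c("psy_neg", "psy_pos"))
}

#' Edge feature matrix for a cohort
#'
#' One row per subject, one column per region pair, in the row-major
#' upper-triangle order of \code{\link{vectorize_edges}}.
#'
#' @param ch a \code{\link{cohort}}.
#' @return numeric matrix, subjects x n(n-1)/2, with dimnames.
#' @export
edge_feature_matrix <- function(ch) {
  rows <- lapply(ch$connectomes, vectorize_edges)
  X <- do.call(rbind, rows)
  rownames(X) <- ch$subjects$id
  X
}

#' Diffusion feature matrix for a cohort
#' @param ch a \code{\link{cohort}} with diffusion tables.
#' @param measure one of \code{"fa"}, \code{"ad"}, \code{"rd"}.
#' @return numeric matrix, subjects x tracts.
#' @export
diffusion_feature_matrix <- function(ch, measure = c("fa", "ad", "rd")) {
  measure <- match.arg(measure)
  if (is.null(ch$diffusion)) stop("cohort has no diffusion tables")
  X <- do.call(rbind, lapply(ch$diffusion, function(d) d[[measure]]))
  dimnames(X) <- list(ch$subjects$id,
                      paste(measure, ch$diffusion[[1L]]$tract, sep = ":"))
  X
}

#' Write a cohort to disk / read it back
#'
#' On-disk layout: \code{manifest.tsv} (id, group, P1..P5 when present, age,
#' sex, scanner, pair_id), \code{regions.txt} (label sidecar),
#' \code{<id>_counts.tsv} and optionally \code{<id>_lengths.tsv} per subject,
#' and \code{<id>_diffusion.tsv} when diffusion tables exist. Everything is
#' delimited text, directly consumable by the pipeline.
#'
#' @param ch a \code{\link{cohort}}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(ch, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(ch$subjects, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_parcellation(ch$parcellation, file.path(dir, "regions.txt"))
  for (id in ch$subjects$id) {
    write_matrix(ch$connectomes[[id]], file.path(dir, paste0(id, "_counts.tsv")))
    if (!is.null(ch$lengths))
      write_matrix(ch$lengths[[id]], file.path(dir, paste0(id, "_lengths.tsv")))
    if (!is.null(ch$diffusion))
      utils::write.table(ch$diffusion[[id]],
                         file.path(dir, paste0(id, "_diffusion.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  subjects <- utils::read.table(file.path(dir, "manifest.tsv"),
                                header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  parc <- read_parcellation(file.path(dir, "regions.txt"))
  ids <- as.character(subjects$id)
  conn <- lapply(ids, function(id)
    load_matrix(file.path(dir, paste0(id, "_counts.tsv")), parc))
  names(conn) <- ids
  lens <- NULL
  if (file.exists(file.path(dir, paste0(ids[1L], "_lengths.tsv")))) {
    lens <- lapply(ids, function(id)
      read_dense_matrix(file.path(dir, paste0(id, "_lengths.tsv"))))
    names(lens) <- ids
  }
  diff <- NULL
  if (file.exists(file.path(dir, paste0(ids[1L], "_diffusion.tsv")))) {
    diff <- lapply(ids, function(id)
      load_diffusion(file.path(dir, paste0(id, "_diffusion.tsv"))))
    names(diff) <- ids
  }
  cohort(subjects, parc, conn, lengths = lens, diffusion = diff)
}
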