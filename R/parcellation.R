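#' Region parcellation
#'
#' A parcellation is the fixed, ordered set of grey-matter regions over which
#' every connectivity matrix in a cohort is defined. All subjects in a cohort
#' must share one parcellation; region order defines the row/column order of
#' every matrix and the naming of every local graph feature.
#'
#' @param labels character vector of unique region names, in matrix order.
#' @param hemisphere character vector, one of \code{"left"}, \code{"right"},
#'   \code{"midline"} per region.
#' @param subcortical logical vector, \code{TRUE} for subcortical regions.
#' @return An object of class \code{parcellation}: a list with elements
#'   \code{labels}, \code{hemisphere}, \code{subcortical}, \code{n_regions}.
#' @examples
#' p <- parcellation(c("lh.a", "rh.a"), c("left", "right"), c(FALSE, FALSE))
#' p$n_regions
#' @export
parcellation <- function(labels, hemisphere, subcortical) {
  labels <- as.character(labels)
  if (anyDuplicated(labels) > 0L)
    stop("parcellation labels must be unique")
  n <- length(labels)
  hemisphere <- match.arg(as.character(hemisphere),
                          c("left", "right", "midline"), several.ok = TRUE)
  if (length(hemisphere) != n || length(subcortical) != n)
    stop("labels, hemisphere and subcortical must have equal length")
  structure(
    list(labels = labels, hemisphere = hemisphere,
         subcortical = as.logical(subcortical), n_regions = n),
    class = "parcellation"
  )
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("parcellation: %d regions (%d subcortical)\n",
              x$n_regions, sum(x$subcortical)))
  invisible(x)
}

# Desikan-Killiany cortical labels (34 per hemisphere), FreeSurfer naming.
dk_cortical <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
  "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal", "lingual",
  "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
  "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
  "postcentral", "posteriorcingulate", "precentral", "precuneus",
  "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
  "superiorparietal", "superiortemporal", "supramarginal", "frontalpole",
  "temporalpole", "transversetemporal", "insula"
)

dk_subcortical <- c("thalamus", "caudate", "putamen", "pallidum",
                    "accumbens", "hippocampus", "amygdala")

#' Default 83-region parcellation
#'
#' The standard FreeSurfer-style whole-brain parcellation used for structural
#' connectomes: 34 Desikan-Killiany cortical regions plus 7 subcortical
#' structures per hemisphere, and the brainstem (83 regions in total).
#' Labels follow the \code{lh.}/\code{rh.} prefix convention.
#'
#' @return A \code{\link{parcellation}} with 83 regions.
#' @examples
#' dk_parcellation()$n_regions  # 83
#' @export
dk_parcellation <- function() {
  labels <- c(paste0("lh.", c(dk_cortical, dk_subcortical)),
              paste0("rh.", c(dk_cortical, dk_subcortical)),
              "brainstem")
  hemi <- c(rep("left", 41L), rep("right", 41L), "midline")
  sub <- c(rep(c(rep(FALSE, 34L), rep(TRUE, 7L)), 2L), TRUE)
  parcellation(labels, hemi, sub)
}

#' Generic toy parcellation
#'
#' Small synthetic parcellation for simulation and testing: regions are named
#' \code{roi001 ...}, hemispheres alternate left/right, none subcortical.
#'
#' @param n_regions number of regions.
#' @return A \code{\link{parcellation}}.
#' @export
toy_parcellation <- function(n_regions) {
  stopifnot(n_regions >= 1)
  parcellation(
    labels = sprintf("roi%03d", seq_len(n_regions)),
    hemisphere = rep_len(c("left", "right"), n_regions),
    subcortical = rep(FALSE, n_regions)
  )
}

#' Read a parcellation sidecar file
#'
#' One region per line: \code{name hemisphere cortical|subcortical},
#' whitespace- or comma-delimited, no header.
#'
#' @param path file path.
#' @return A \code{\link{parcellation}}.
#' @export
read_parcellation <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           col.names = c("label", "hemisphere", "class"),
                           stringsAsFactors = FALSE,
                           comment.char = "#")
  parcellation(tab$label, tab$hemisphere,
               tolower(tab$class) %in% c("subcortical", "sub"))
}

#' Write a parcellation sidecar file
#' @param parc a \code{\link{parcellation}}.
#' @param path file path.
#' @export
write_parcellation <- function(parc, path) {
  stopifnot(inherits(parc, "parcellation"))
  utils::write.table(
    data.frame(parc$labels, parc$hemisphere,
               ifelse(parc$subcortical, "subcortical", "cortical")),
    path, quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Standard tract bundle names
#'
#' The 18 white-matter pathways reconstructed by the TRACULA toolbox:
#' forceps major and minor plus eight bilateral bundles (anterior thalamic
#' radiation, cingulum angular bundle, cingulum cingulate gyrus,
#' corticospinal tract, inferior longitudinal fasciculus, parietal and
#' temporal superior longitudinal fasciculus, uncinate).
#'
#' @return character vector of 18 tract names.
#' @export
tracula_tracts <- function() {
  bil <- c("atr", "cab", "ccg", "cst", "ilf", "slfp", "slft", "unc")
  c("fmajor", "fminor", paste0("lh.", bil), paste0("rh.", bil))
}
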