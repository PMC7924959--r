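#' Accessors for SumoSiteSet row metadata
#'
#' Convenience accessors for the per-site columns of a [SumoSiteSet]:
#' protein accessions, modified-lysine positions, localization
#' probabilities, sequence windows and the decoy/contaminant QC flags.
#' The intensity matrix itself is available through
#' `SummarizedExperiment::assay(x, "intensity")`.
#'
#' @param x a [SumoSiteSet].
#' @return A vector with one element per site.
#' @name site-accessors
NULL

#' @rdname site-accessors
#' @export
siteProteins <- function(x) rowData(x)$protein_id

#' @rdname site-accessors
#' @export
sitePositions <- function(x) rowData(x)$position

#' @rdname site-accessors
#' @export
locProbs <- function(x) rowData(x)$localization_prob

#' @rdname site-accessors
#' @export
sequenceWindows <- function(x) rowData(x)$sequence_window

#' @rdname site-accessors
#' @export
isReverse <- function(x) rowData(x)$reverse

#' @rdname site-accessors
#' @export
isContaminant <- function(x) rowData(x)$contaminant
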