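#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData
#'   colData rowData<- colData<-
NULL

## ---------------------------------------------------------------------------
## SumoSiteSet
## ---------------------------------------------------------------------------

#' Container for SUMO-conjugation sites and their per-sample intensities
#'
#' `SumoSiteSet` extends [SummarizedExperiment::SummarizedExperiment] with a
#' fixed schema: one row per modification site, one column per MS sample,
#' and a single `"intensity"` assay holding raw (linear-scale) label-free
#' quantification values with `NA` for missing measurements.
#'
#' Row metadata carries, per site: `protein_id`, `position` (1-based residue
#' index of the modified lysine), `localization_prob` (MaxQuant confidence
#' that the modification sits on the reported residue, in \[0,1\]),
#' `sequence_window` (odd-length window centered on the modified K, padded
#' with `_` past the protein termini), and the QC flags `reverse` (decoy
#' match) and `contaminant`. Column metadata carries the sample design:
#' `timepoint` and `replicate`.
#'
#' @param protein_id character, protein accession per site.
#' @param position integer, 1-based position of the modified lysine.
#' @param localization_prob numeric in \[0,1\].
#' @param sequence_window character, odd-length windows centered on `K`.
#' @param intensities numeric matrix, sites x samples; `NA` = missing.
#'   Column names must match `rownames(design)`.
#' @param design sample design as returned by [sampleDesign()].
#' @param reverse,contaminant logical QC flags (default all `FALSE`).
#' @param site_id character row identifiers; defaults to
#'   `"<protein_id>_K<position>"` made unique.
#'
#' @return A `SumoSiteSet`.
#' @examples
#' design <- sampleDesign(timepoints = c("t1", "t2"), n_replicates = 2)
#' m <- matrix(1e6, nrow = 1, ncol = 4, dimnames = list(NULL, rownames(design)))
#' SumoSiteSet(
#'   protein_id = "P1", position = 5L, localization_prob = 0.99,
#'   sequence_window = "AAAAKAAAA", intensities = m, design = design
#' )
#' @export
SumoSiteSet <- function(protein_id, position, localization_prob,
                        sequence_window, intensities, design,
                        reverse = FALSE, contaminant = FALSE,
                        site_id = NULL) {
  n <- length(protein_id)
  position <- as.integer(position)
  reverse <- rep_len(as.logical(reverse), n)
  contaminant <- rep_len(as.logical(contaminant), n)
  if (is.null(site_id)) {
    site_id <- make.unique(paste0(protein_id, "_K", position), sep = ".")
  }
  intensities <- as.matrix(intensities)
  if (n == 0 && ncol(intensities) == 0) {
    intensities <- matrix(numeric(0), nrow = 0, ncol = nrow(design),
                          dimnames = list(NULL, rownames(design)))
  }
  storage.mode(intensities) <- "double"
  intensities <- intensities[, rownames(design), drop = FALSE]
  rownames(intensities) <- site_id
  rd <- DataFrame(
    protein_id = as.character(protein_id),
    position = position,
    localization_prob = as.numeric(localization_prob),
    sequence_window = as.character(sequence_window),
    reverse = reverse,
    contaminant = contaminant,
    row.names = site_id
  )
  se <- SummarizedExperiment(
    assays = SimpleList(intensity = intensities),
    rowData = rd, colData = design
  )
  new("SumoSiteSet", se)
}

#' @rdname SumoSiteSet
#' @export
setClass("SumoSiteSet", contains = "SummarizedExperiment")

setValidity("SumoSiteSet", function(object) {
  rd <- rowData(object)
  need <- c("protein_id", "position", "localization_prob",
            "sequence_window", "reverse", "contaminant")
  miss <- setdiff(need, colnames(rd))
  if (length(miss) > 0) {
    return(paste("missing rowData column(s):", paste(miss, collapse = ", ")))
  }
  cd <- colData(object)
  if (!all(c("timepoint", "replicate") %in% colnames(cd))) {
    return("colData must carry 'timepoint' and 'replicate'")
  }
  if (nrow(rd) > 0) {
    if (any(rd$position < 1L, na.rm = TRUE)) {
      return("site positions must be >= 1")
    }
    lp <- rd$localization_prob
    if (any(lp < 0 | lp > 1, na.rm = TRUE)) {
      return("localization probabilities must lie in [0, 1]")
    }
    w <- rd$sequence_window
    wl <- nchar(w)
    if (any(wl %% 2L == 0L)) {
      return("sequence windows must have odd length")
    }
    ctr <- substr(w, (wl + 1L) %/% 2L, (wl + 1L) %/% 2L)
    if (any(ctr != "K")) {
      return("sequence windows must be centered on 'K'")
    }
  }
  if (!"intensity" %in% names(SummarizedExperiment::assays(object))) {
    return("an 'intensity' assay is required")
  }
  TRUE
})

setMethod("show", "SumoSiteSet", function(object) {
  cat(sprintf(
    "SumoSiteSet with %d site%s on %d protein%s across %d sample%s\n",
    nrow(object), if (nrow(object) == 1) "" else "s",
    length(unique(siteProteins(object))),
    if (length(unique(siteProteins(object))) == 1) "" else "s",
    ncol(object), if (ncol(object) == 1) "" else "s"
  ))
  if (ncol(object) > 0) {
    cd <- colData(object)
    cat("timepoints:", paste(unique(as.character(cd$timepoint)),
                             collapse = ", "), "\n")
  }
  if (nrow(object) > 0) {
    flt <- sum(!isReverse(object) & !isContaminant(object))
    cat(sprintf("QC: %d reverse, %d contaminant (%d clean)\n",
                sum(isReverse(object)), sum(isContaminant(object)), flt))
  }
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## Sample design
## ---------------------------------------------------------------------------

#' Sample design of an LFQ time course
#'
#' Builds the mapping of MS sample identifiers to `(timepoint, replicate)`
#' pairs. Sample identifiers are `"<timepoint>_<replicate>"`, the convention
#' used by MaxQuant intensity column suffixes. The default design is the
#' six-stage meiotic time course (G0, S, DSB, SI, dHJ, CO) in triplicate.
#'
#' @param timepoints ordered character vector of timepoint labels.
#' @param n_replicates integer, replicates per timepoint.
#' @return A [S4Vectors::DataFrame] with one row per sample (row names are
#'   sample ids) and columns `timepoint` (factor, levels in time order) and
#'   `replicate` (integer).
#' @examples
#' sampleDesign()
#' @export
sampleDesign <- function(timepoints = MEIOTIC_TIMEPOINTS, n_replicates = 3) {
  stopifnot(length(timepoints) >= 1, n_replicates >= 1,
            !anyDuplicated(timepoints))
  tp <- rep(timepoints, each = n_replicates)
  rep_ <- rep(seq_len(n_replicates), times = length(timepoints))
  DataFrame(
    timepoint = factor(tp, levels = timepoints),
    replicate = as.integer(rep_),
    row.names = paste(tp, rep_, sep = "_")
  )
}

## ---------------------------------------------------------------------------
## ResidueAnnotation
## ---------------------------------------------------------------------------

#' Per-residue structural annotation tracks
#'
#' Holds, for each residue of each protein, the boolean structure tracks
#' produced by upstream predictors (globular domains and long disorder in
#' the style of IUPred, solvent exposure/burial in the style of ACCpro,
#' coiled coils in the style of ncoils, transmembrane segments in the style
#' of HMMTOP) together with the continuous short-disorder score in \[0,1\].
#' The predictors themselves are never run by this package; their per-residue
#' output is consumed from a TSV (see [readAnnotationTable()]) or generated
#' synthetically (see [simulateProteome()]).
#'
#' @param table a `data.frame`/`DataFrame` with columns `protein_id`,
#'   `position`, `globular`, `long_disorder`, `short_disorder_score`,
#'   `exposed`, `buried`, `coiled_coil`, `transmembrane`.
#' @return A `ResidueAnnotation` object.
#' @export
ResidueAnnotation <- function(table) {
  new("ResidueAnnotation", table = DataFrame(as.data.frame(table)))
}

#' @rdname ResidueAnnotation
#' @export
setClass("ResidueAnnotation", representation(table = "DataFrame"))

ANNOTATION_COLUMNS <- c(
  "protein_id", "position", "globular", "long_disorder",
  "short_disorder_score", "exposed", "buried", "coiled_coil",
  "transmembrane"
)

setValidity("ResidueAnnotation", function(object) {
  tab <- object@table
  miss <- setdiff(ANNOTATION_COLUMNS, colnames(tab))
  if (length(miss) > 0) {
    return(paste("missing annotation column(s):",
                 paste(miss, collapse = ", ")))
  }
  if (nrow(tab) > 0) {
    if (any(tab$exposed & tab$buried)) {
      return("a residue cannot be both exposed and buried")
    }
    sc <- tab$short_disorder_score
    if (any(sc < 0 | sc > 1, na.rm = TRUE)) {
      return("short_disorder_score must lie in [0, 1]")
    }
    if (any(tab$position < 1L)) {
      return("positions must be >= 1")
    }
  }
  TRUE
})

setMethod("show", "ResidueAnnotation", function(object) {
  tab <- object@table
  cat(sprintf("ResidueAnnotation: %d residues in %d protein(s)\n",
              nrow(tab), length(unique(tab$protein_id))))
  invisible(NULL)
})

#' @describeIn ResidueAnnotation the underlying per-residue table.
#' @param x a `ResidueAnnotation`.
#' @export
annotationTable <- function(x) {
  stopifnot(is(x, "ResidueAnnotation"))
  x@table
}

## ---------------------------------------------------------------------------
## ProfileMatrix
## ---------------------------------------------------------------------------

PROFILE_STATES <- c("RAW", "AVERAGED", "LOG2", "IMPUTED", "ZSCORED")

#' Temporal profile matrix with an explicit processing state
#'
#' A numeric matrix (rows = proteins or sites, columns = samples or
#' timepoints) tagged with its position in the quantitative pipeline
#' `RAW -> AVERAGED -> LOG2 -> IMPUTED -> ZSCORED`. Every pipeline
#' operation validates the state of its input, so steps cannot be run out
#' of order. Rows with zero variance that could not be z-scored are listed
#' in `flaggedRows()`.
#'
#' @param values numeric matrix with row and column names; `NA` = missing.
#' @param state one of `"RAW"`, `"AVERAGED"`, `"LOG2"`, `"IMPUTED"`,
#'   `"ZSCORED"`.
#' @param flagged character vector of row names flagged as zero-variance.
#' @return A `ProfileMatrix`.
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("a", "b"), c("t1", "t2", "t3")))
#' ProfileMatrix(m, "RAW")
#' @export
ProfileMatrix <- function(values, state = "RAW", flagged = character(0)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("ProfileMatrix", values = values, state = state, flagged = flagged)
}

#' @rdname ProfileMatrix
#' @export
setClass("ProfileMatrix", representation(
  values = "matrix", state = "character", flagged = "character"
))

setValidity("ProfileMatrix", function(object) {
  if (length(object@state) != 1L || !object@state %in% PROFILE_STATES) {
    return(paste("state must be one of:", paste(PROFILE_STATES,
                                                collapse = ", ")))
  }
  if (object@state == "ZSCORED" && nrow(object@values) > 0) {
    keep <- setdiff(rownames(object@values), object@flagged)
    v <- object@values[keep, , drop = FALSE]
    if (nrow(v) > 0) {
      if (anyNA(v)) return("ZSCORED matrices cannot contain missing values")
      mu <- rowMeans(v)
      sdv <- apply(v, 1, sd)
      if (any(abs(mu) > 1e-9) || any(abs(sdv - 1) > 1e-9)) {
        return("ZSCORED rows must have mean 0 and sample SD 1 (tol 1e-9)")
      }
    }
  }
  TRUE
})

setMethod("show", "ProfileMatrix", function(object) {
  cat(sprintf("ProfileMatrix [%s]: %d x %d", object@state,
              nrow(object@values), ncol(object@values)))
  if (length(object@flagged) > 0) {
    cat(sprintf(" (%d zero-variance row(s) flagged)",
                length(object@flagged)))
  }
  cat("\n")
  invisible(NULL)
})

#' @describeIn ProfileMatrix the numeric matrix.
#' @param x a `ProfileMatrix`.
#' @export
profileValues <- function(x) {
  stopifnot(is(x, "ProfileMatrix"))
  x@values
}

#' @describeIn ProfileMatrix the processing state.
#' @export
profileState <- function(x) {
  stopifnot(is(x, "ProfileMatrix"))
  x@state
}

#' @describeIn ProfileMatrix names of rows flagged as zero-variance.
#' @export
flaggedRows <- function(x) {
  stopifnot(is(x, "ProfileMatrix"))
  x@flagged
}

## internal: assert pipeline state
assertState <- function(x, expected) {
  if (!is(x, "ProfileMatrix")) {
    stop("expected a ProfileMatrix, got ", class(x)[1])
  }
  if (!profileState(x) %in% expected) {
    stop(sprintf("expected a %s ProfileMatrix but got %s",
                 paste(expected, collapse = "/"), profileState(x)))
  }
  invisible(x)
}
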