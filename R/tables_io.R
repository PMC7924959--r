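## Reading and writing MaxQuant-dialect tables, FASTA and annotation tracks.
##
## All positions are 1-based (MaxQuant convention). Missing intensities are
## accepted on disk as empty cells or "NaN" and are always written back as
## empty cells.

#' @importFrom Biostrings readBStringSet writeXStringSet AAStringSet width
NULL

SITE_TABLE_COLUMNS <- c("Protein", "Position", "Localization prob",
                        "Sequence window", "Reverse",
                        "Potential contaminant")

## "+" marks a flagged row in MaxQuant tables; anything else is unflagged.
parseFlag <- function(x) {
  trimws(as.character(x)) == "+"
}

parseIntensityCell <- function(x) {
  x <- trimws(as.character(x))
  x[x == "" | toupper(x) == "NAN" | toupper(x) == "NA"] <- NA_character_
  as.numeric(x)
}

formatNumberCell <- function(x) {
  out <- sprintf("%.10g", x)
  out[is.na(x)] <- ""
  out
}

intensityColumns <- function(design, prefix = "Intensity") {
  paste(prefix, rownames(design))
}

#' Read a MaxQuant-style modification-site table
#'
#' Parses a tab-separated "GlyGly (K) sites"-dialect table into a
#' [SumoSiteSet]. The mandatory columns are `Protein`, `Position`,
#' `Localization prob`, `Sequence window`, `Reverse`,
#' `Potential contaminant`, plus one `Intensity <timepoint>_<replicate>`
#' column per sample in `design`. Empty or `NaN` intensity cells become
#' missing values; flag cells equal to `"+"` become `TRUE`.
#'
#' @param path path to a tab-separated file with a header row.
#' @param design sample design from [sampleDesign()], or `NULL` to parse
#'   only the site annotations (no intensity columns; the returned object
#'   has zero sample columns), e.g. for a table whose sample layout is
#'   unknown or irrelevant.
#' @return A [SumoSiteSet].
#' @seealso [writeSitesTable()], [filterSites()]
#' @export
readSitesTable <- function(path, design) {
  tab <- read.delim(path, check.names = FALSE, sep = "\t",
                    colClasses = "character")
  if (is.null(design)) {
    design <- DataFrame(timepoint = factor(), replicate = integer())
  }
  need <- c(SITE_TABLE_COLUMNS, intensityColumns(design))
  miss <- setdiff(need, colnames(tab))
  if (length(miss) > 0) {
    stop("site table schema error: missing column(s): ",
         paste(sQuote(miss), collapse = ", "))
  }
  pos_raw <- trimws(tab$Position)
  pos <- suppressWarnings(as.numeric(pos_raw))
  bad <- which(is.na(pos) | pos != floor(pos))
  if (length(bad) > 0) {
    stop(sprintf("site table parse error: non-integer Position %s in row %d",
                 sQuote(pos_raw[bad[1]]), bad[1]))
  }
  ints <- vapply(intensityColumns(design),
                 function(cn) parseIntensityCell(tab[[cn]]),
                 numeric(nrow(tab)))
  ints <- matrix(ints, nrow = nrow(tab),
                 dimnames = list(NULL, rownames(design)))
  SumoSiteSet(
    protein_id = tab$Protein,
    position = as.integer(pos),
    localization_prob = as.numeric(tab$`Localization prob`),
    sequence_window = tab$`Sequence window`,
    intensities = ints,
    design = design,
    reverse = parseFlag(tab$Reverse),
    contaminant = parseFlag(tab$`Potential contaminant`)
  )
}

#' Write a [SumoSiteSet] as a MaxQuant-style site table
#'
#' Inverse of [readSitesTable()]: numeric cells are written with 10
#' significant digits, missing intensities as empty cells, and flags as
#' `"+"`/empty.
#'
#' @param sites a [SumoSiteSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSitesTable <- function(sites, path) {
  ints <- assay(sites, "intensity")
  out <- data.frame(
    Protein = siteProteins(sites),
    Position = sitePositions(sites),
    `Localization prob` = formatNumberCell(locProbs(sites)),
    `Sequence window` = sequenceWindows(sites),
    Reverse = ifelse(isReverse(sites), "+", ""),
    `Potential contaminant` = ifelse(isContaminant(sites), "+", ""),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  for (s in colnames(ints)) {
    out[[paste("Intensity", s)]] <- formatNumberCell(ints[, s])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter decoy/contaminant sites and apply a localization cutoff
#'
#' Removes sites flagged as reverse (decoy) matches or potential
#' contaminants — the standard Perseus first step — and, when
#' `min_loc_prob` is given, additionally keeps only sites whose
#' localization probability is greater than or equal to the cutoff
#' (inclusive threshold; the conventional high-confidence cutoff for
#' "class I"-style site sets). Row order is preserved and the operation is
#' idempotent.
#'
#' @param sites a [SumoSiteSet].
#' @param min_loc_prob numeric cutoff in \[0,1\], or `NULL` for no cutoff.
#' @return The filtered [SumoSiteSet].
#' @export
filterSites <- function(sites, min_loc_prob = NULL) {
  keep <- !isReverse(sites) & !isContaminant(sites)
  if (!is.null(min_loc_prob)) {
    stopifnot(is.numeric(min_loc_prob), length(min_loc_prob) == 1L,
              min_loc_prob >= 0, min_loc_prob <= 1)
    keep <- keep & !is.na(locProbs(sites)) & locProbs(sites) >= min_loc_prob
  }
  sites[keep, ]
}

#' Read protein sequences from FASTA
#'
#' Sequence names are the first whitespace-delimited token of each FASTA
#' header; sequences are uppercased. Characters outside the 20-letter
#' amino-acid alphabet plus `*` raise an error, as do duplicated ids.
#'
#' @param path path to an (uncompressed) FASTA file.
#' @return An [Biostrings::AAStringSet] named by protein id.
#' @seealso [lysinePositions()]
#' @export
readFasta <- function(path) {
  ## read as plain strings first: AA parsing would silently drop
  ## characters outside the amino-acid code instead of failing
  seqs <- readBStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate protein id(s) in FASTA: ",
         paste(sQuote(unique(ids[duplicated(ids)])), collapse = ", "))
  }
  chars <- toupper(as.character(seqs))
  bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "*]"), chars)
  if (any(bad)) {
    stop("sequence(s) with characters outside the amino-acid alphabet: ",
         paste(sQuote(ids[bad]), collapse = ", "))
  }
  out <- AAStringSet(chars)
  names(out) <- ids
  out
}

#' Write protein sequences to FASTA
#'
#' @param proteins a named [Biostrings::AAStringSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(proteins, path) {
  writeXStringSet(proteins, path)
  invisible(path)
}

#' Lysine positions of each protein
#'
#' @param proteins a named [Biostrings::AAStringSet] (or named character
#'   vector of sequences).
#' @return A named list of sorted 1-based integer vectors, one per protein,
#'   enumerating exactly the positions carrying `K`.
#' @export
lysinePositions <- function(proteins) {
  chars <- if (is.character(proteins)) proteins else as.character(proteins)
  setNames(residuePositions(chars, "K"), names(proteins))
}

#' Read a MaxQuant-style proteinGroups table
#'
#' Parses the per-protein label-free quantification (LFQ) columns of a
#' tab-separated proteinGroups-dialect table. Mandatory columns are
#' `Protein` plus one `LFQ intensity <timepoint>_<replicate>` column per
#' sample in `design`. Missing-cell and flag conventions follow
#' [readSitesTable()].
#'
#' @inheritParams readSitesTable
#' @return A [SummarizedExperiment::SummarizedExperiment] with one row per
#'   protein group and a single `"lfq"` assay (`NA` = missing).
#' @export
readProteinTable <- function(path, design) {
  tab <- read.delim(path, check.names = FALSE, sep = "\t",
                    colClasses = "character")
  need <- c("Protein", intensityColumns(design, "LFQ intensity"))
  miss <- setdiff(need, colnames(tab))
  if (length(miss) > 0) {
    stop("protein table schema error: missing column(s): ",
         paste(sQuote(miss), collapse = ", "))
  }
  if (anyDuplicated(tab$Protein)) {
    stop("duplicate protein id(s) in protein table: ",
         paste(sQuote(unique(tab$Protein[duplicated(tab$Protein)])),
               collapse = ", "))
  }
  lfq <- vapply(intensityColumns(design, "LFQ intensity"),
                function(cn) parseIntensityCell(tab[[cn]]),
                numeric(nrow(tab)))
  lfq <- matrix(lfq, nrow = nrow(tab),
                dimnames = list(tab$Protein, rownames(design)))
  SummarizedExperiment(
    assays = SimpleList(lfq = lfq),
    rowData = DataFrame(protein_id = tab$Protein, row.names = tab$Protein),
    colData = design
  )
}

#' Write a protein LFQ table
#'
#' @param proteins a `SummarizedExperiment` with an `"lfq"` assay, as
#'   returned by [readProteinTable()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeProteinTable <- function(proteins, path) {
  lfq <- assay(proteins, "lfq")
  out <- data.frame(Protein = rownames(lfq), check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (s in colnames(lfq)) {
    out[[paste("LFQ intensity", s)]] <- formatNumberCell(lfq[, s])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-residue structural annotation tracks
#'
#' Reads the tab-separated per-residue annotation format (one row per
#' residue; columns `protein_id`, `position`, `globular`, `long_disorder`,
#' `short_disorder_score`, `exposed`, `buried`, `coiled_coil`,
#' `transmembrane`; boolean tracks encoded 0/1). This format stands in for
#' the per-residue output of IUPred, ACCpro, ncoils and HMMTOP, which are
#' run (and converted) by the user.
#'
#' @param path path to the annotation TSV.
#' @return A [ResidueAnnotation].
#' @export
readAnnotationTable <- function(path) {
  tab <- read.delim(path, check.names = FALSE, sep = "\t")
  miss <- setdiff(ANNOTATION_COLUMNS, colnames(tab))
  if (length(miss) > 0) {
    stop("annotation table schema error: missing column(s): ",
         paste(sQuote(miss), collapse = ", "))
  }
  for (cn in setdiff(ANNOTATION_COLUMNS,
                     c("protein_id", "position", "short_disorder_score"))) {
    tab[[cn]] <- as.logical(as.integer(tab[[cn]]))
  }
  tab$position <- as.integer(tab$position)
  ResidueAnnotation(tab)
}

#' Write per-residue structural annotation tracks
#'
#' @param ann a [ResidueAnnotation].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAnnotationTable <- function(ann, path) {
  tab <- as.data.frame(annotationTable(ann))
  for (cn in setdiff(ANNOTATION_COLUMNS,
                     c("protein_id", "position", "short_disorder_score"))) {
    tab[[cn]] <- as.integer(tab[[cn]])
  }
  tab$short_disorder_score <- sprintf("%.10g", tab$short_disorder_score)
  write.table(tab[, ANNOTATION_COLUMNS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read/write a sample design file
#'
#' The design is stored as a three-column TSV (`sample_id`, `timepoint`,
#' `replicate`); timepoint order follows first appearance.
#'
#' @param path path to the design TSV.
#' @return [readDesignTable()]: a design `DataFrame` as from
#'   [sampleDesign()]; [writeDesignTable()]: `path`, invisibly.
#' @export
readDesignTable <- function(path) {
  tab <- read.delim(path, check.names = FALSE, sep = "\t",
                    colClasses = "character")
  need <- c("sample_id", "timepoint", "replicate")
  miss <- setdiff(need, colnames(tab))
  if (length(miss) > 0) {
    stop("design table schema error: missing column(s): ",
         paste(sQuote(miss), collapse = ", "))
  }
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample_id in design")
  DataFrame(
    timepoint = factor(tab$timepoint, levels = unique(tab$timepoint)),
    replicate = as.integer(tab$replicate),
    row.names = tab$sample_id
  )
}

#' @rdname readDesignTable
#' @param design a design `DataFrame`.
#' @export
writeDesignTable <- function(design, path) {
  out <- data.frame(
    sample_id = rownames(design),
    timepoint = as.character(design$timepoint),
    replicate = design$replicate
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
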