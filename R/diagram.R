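## Per-protein site-map assembly: the data behind a protein diagram with
## lysine/site tracks, SUMO-interacting motifs (SIMs), domains and
## structure segments. Rendering is left to the caller; the assembled
## object is plain track data.

#' Assemble the track data for a per-protein SUMOylation site map
#'
#' Collects, for one protein, the positions of all lysines, all detected
#' SUMOylation sites (with cumulative intensities as a readout of
#' relative site usage), optional SIM and domain intervals, and the
#' structural segments (globular, coiled-coil, transmembrane) plus the
#' continuous short-disorder score series. Intervals are half-open
#' `[start, end)` in 1-based coordinates.
#'
#' @param protein_id the protein to diagram.
#' @param sequence its sequence (character or
#'   [Biostrings::AAStringSet] element).
#' @param sites a [SumoSiteSet] (rows for other proteins are ignored).
#' @param ann optional [ResidueAnnotation] covering the protein.
#' @param sims optional data.frame `start`, `end`, `tier`
#'   (`high`/`medium`/`low`, the usual SIM-prediction confidence tiers).
#' @param domains optional data.frame `start`, `end`, `name`.
#' @return A `ProteinDiagram` object.
#' @export
buildProteinDiagram <- function(protein_id, sequence, sites, ann = NULL,
                                sims = NULL, domains = NULL) {
  seq_chr <- toupper(as.character(sequence))
  len <- nchar(seq_chr)
  keep <- siteProteins(sites) == protein_id
  pos <- sitePositions(sites)[keep]
  if (any(pos < 1 | pos > len)) {
    stop("site position(s) outside [1, ", len, "] for ",
         sQuote(protein_id), ": ",
         paste(pos[pos < 1 | pos > len], collapse = ", "))
  }
  cum <- cumulativeSiteIntensity(sites)[keep]
  site_track <- data.frame(
    position = pos,
    label = paste0("K", pos),
    cumulative_intensity = as.numeric(cum)
  )
  site_track <- site_track[order(site_track$position), , drop = FALSE]
  rownames(site_track) <- NULL

  checkIntervals <- function(tab, what) {
    if (is.null(tab)) {
      return(data.frame(start = integer(0), end = integer(0)))
    }
    if (any(tab$start < 1 | tab$end > len + 1L | tab$start >= tab$end)) {
      stop(what, " interval(s) outside [1, ", len, "] for ",
           sQuote(protein_id))
    }
    tab
  }
  sims <- checkIntervals(sims, "SIM")
  domains <- checkIntervals(domains, "domain")

  structure_track <- list(
    globular = data.frame(start = integer(0), end = integer(0)),
    coiled_coil = data.frame(start = integer(0), end = integer(0)),
    transmembrane = data.frame(start = integer(0), end = integer(0)),
    disorder_score = numeric(0)
  )
  if (!is.null(ann)) {
    tab <- as.data.frame(annotationTable(ann))
    tab <- tab[tab$protein_id == protein_id, , drop = FALSE]
    tab <- tab[order(tab$position), , drop = FALSE]
    if (nrow(tab) != len) {
      stop("annotation does not cover protein ", sQuote(protein_id),
           " (", nrow(tab), " of ", len, " residues)")
    }
    runsOf <- function(v) {
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      data.frame(start = starts[r$values], end = ends[r$values] + 1L)
    }
    structure_track$globular <- runsOf(tab$globular)
    structure_track$coiled_coil <- runsOf(tab$coiled_coil)
    structure_track$transmembrane <- runsOf(tab$transmembrane)
    structure_track$disorder_score <- tab$short_disorder_score
  }

  new("ProteinDiagram",
      protein_id = protein_id,
      length = as.integer(len),
      lysines = which(strsplit(seq_chr, "")[[1]] == "K"),
      sites = site_track,
      sims = sims,
      domains = domains,
      structure = structure_track)
}

#' @rdname buildProteinDiagram
#' @export
setClass("ProteinDiagram", representation(
  protein_id = "character", length = "integer", lysines = "integer",
  sites = "data.frame", sims = "data.frame", domains = "data.frame",
  structure = "list"
))

setValidity("ProteinDiagram", function(object) {
  len <- object@length
  if (any(object@lysines < 1L | object@lysines > len)) {
    return("lysine positions outside [1, length]")
  }
  if (nrow(object@sites) > 0 &&
      any(object@sites$position < 1L | object@sites$position > len)) {
    return("site positions outside [1, length]")
  }
  if (!all(object@sites$position %in% object@lysines)) {
    return("every site must sit on a lysine")
  }
  TRUE
})

setMethod("show", "ProteinDiagram", function(object) {
  cat(sprintf(
    "ProteinDiagram %s (%d aa): %d lysines, %d SUMO sites, %d SIMs, %d domains\n",
    object@protein_id, object@length, length(object@lysines),
    nrow(object@sites), nrow(object@sims), nrow(object@domains)
  ))
  invisible(NULL)
})
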