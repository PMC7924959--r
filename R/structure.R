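## Structural context of SUMOylation sites: composite structure classes,
## per-class fold-enrichment, and disorder-score distributions.

#' @rdname constants
#' @export
STRUCTURE_CLASSES <- c(
  "GLOBULAR", "LONG_DISORDER", "SHORT_DISORDER", "DISORDERED",
  "GLOBULAR_EXPOSED", "GLOBULAR_BURIED", "COILED_COIL", "TRANSMEMBRANE",
  "DISORDERED_NOT_CC", "DISORDERED_TERMINUS", "DISORDER_NEAR_TERMINUS"
)

#' Derive composite structure classes from predictor tracks
#'
#' Combines the raw per-residue predictor tracks of a [ResidueAnnotation]
#' into the composite membership classes used for enrichment analysis:
#' \itemize{
#'   \item `SHORT_DISORDER`: short-disorder score >= `disorder_threshold`
#'     (default 0.5, the conventional IUPred decision boundary).
#'   \item `DISORDERED`: any predicted disorder (long or short) that is
#'     not inside a predicted globular domain.
#'   \item `GLOBULAR_EXPOSED` / `GLOBULAR_BURIED`: globular residues split
#'     by solvent accessibility.
#'   \item `DISORDERED_NOT_CC`: disordered and not coiled-coil.
#'   \item `DISORDERED_TERMINUS`: disordered residues belonging to a
#'     disordered region that extends to the N- or C-terminus
#'     (`terminus_mode = "region"`, the default) or disordered residues
#'     that are themselves terminal (`"residue"`).
#'   \item `DISORDER_NEAR_TERMINUS`: `DISORDERED_NOT_CC` residues strictly
#'     within `terminus_window` (default 100) residues of either terminus,
#'     i.e. `min(i - 1, length - i) < terminus_window`.
#' }
#'
#' @param ann a [ResidueAnnotation]; all tracks of a protein must cover
#'   positions 1..length contiguously.
#' @param disorder_threshold cutoff for binarizing the continuous
#'   short-disorder score.
#' @param terminus_window residue distance defining "near terminus".
#' @param terminus_mode see above.
#' @return A data.frame with `protein_id`, `position` and one logical
#'   column per class in `STRUCTURE_CLASSES`.
#' @export
deriveClasses <- function(ann, disorder_threshold = 0.5,
                          terminus_window = 100,
                          terminus_mode = c("region", "residue")) {
  terminus_mode <- match.arg(terminus_mode)
  tab <- as.data.frame(annotationTable(ann))
  ## order residues within protein and check track completeness
  tab <- tab[order(tab$protein_id, tab$position), , drop = FALSE]
  lens <- tapply(tab$position, tab$protein_id, max)
  n_res <- tapply(tab$position, tab$protein_id, length)
  if (any(lens != n_res)) {
    stop("annotation track length mismatch for protein(s): ",
         paste(sQuote(names(lens)[lens != n_res]), collapse = ", "))
  }
  protein_len <- as.integer(lens[tab$protein_id])

  out <- data.frame(protein_id = tab$protein_id, position = tab$position)
  out$GLOBULAR <- tab$globular
  out$LONG_DISORDER <- tab$long_disorder
  out$SHORT_DISORDER <- tab$short_disorder_score >= disorder_threshold
  out$DISORDERED <- (out$LONG_DISORDER | out$SHORT_DISORDER) & !out$GLOBULAR
  out$GLOBULAR_EXPOSED <- out$GLOBULAR & tab$exposed
  out$GLOBULAR_BURIED <- out$GLOBULAR & tab$buried
  out$COILED_COIL <- tab$coiled_coil
  out$TRANSMEMBRANE <- tab$transmembrane
  out$DISORDERED_NOT_CC <- out$DISORDERED & !out$COILED_COIL

  ## DISORDERED_TERMINUS: flag whole disordered runs that touch an end
  if (terminus_mode == "region") {
    term <- logical(nrow(out))
    idx <- split(seq_len(nrow(out)), out$protein_id)
    for (rows in idx) {
      dis <- out$DISORDERED[rows]
      if (!any(dis)) next
      r <- rle(dis)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      touch <- r$values & (starts == 1L | ends == length(dis))
      for (j in which(touch)) {
        term[rows[starts[j]:ends[j]]] <- TRUE
      }
    }
    out$DISORDERED_TERMINUS <- term
  } else {
    out$DISORDERED_TERMINUS <- out$DISORDERED &
      (out$position == 1L | out$position == protein_len)
  }

  dist_term <- pmin(out$position - 1L, protein_len - out$position)
  out$DISORDER_NEAR_TERMINUS <- out$DISORDERED_NOT_CC &
    dist_term < terminus_window
  out
}

## internal: row index into a class table for (protein, position) keys
classRowIndex <- function(classes, protein_id, position) {
  match(paste(protein_id, position, sep = "\r"),
        paste(classes$protein_id, classes$position, sep = "\r"))
}

#' Fold-enrichment of SUMOylation sites across structure classes
#'
#' For each structure class, the fold-enrichment is the percentage of
#' detected lysine SUMOylation sites falling within the class divided by
#' the percentage of all lysines — in proteins with at least one detected
#' site — falling within the same class. Values above 1 indicate
#' enrichment, below 1 depletion; a class holding no lysines yields `NA`.
#'
#' @param sites a filtered [SumoSiteSet].
#' @param proteins a named [Biostrings::AAStringSet] covering the site
#'   proteins.
#' @param classes a class table from [deriveClasses()].
#' @return A data.frame with one row per class: `class`, `enrichment`,
#'   `n_sumo_k` (sites in the class), `n_all_k` (lysines in the class),
#'   plus the totals as attributes `total_sumo_k` and `total_k`.
#' @seealso [classRateRatio()] for the complementary between-class rate
#'   ratio.
#' @export
foldEnrichment <- function(sites, proteins, classes) {
  site_prot <- siteProteins(sites)
  prot_ids <- intersect(names(proteins), unique(site_prot))
  lys <- lysinePositions(proteins[prot_ids])
  lys_prot <- rep(prot_ids, lengths(lys))
  lys_pos <- unlist(lys, use.names = FALSE)

  k_idx <- classRowIndex(classes, lys_prot, lys_pos)
  if (anyNA(k_idx)) {
    stop("annotation classes do not cover all lysines of the site proteins")
  }
  keep <- site_prot %in% prot_ids
  s_idx <- classRowIndex(classes, site_prot[keep], sitePositions(sites)[keep])
  if (anyNA(s_idx)) {
    stop("annotation classes do not cover all site positions")
  }

  total_k <- length(k_idx)
  total_s <- length(s_idx)
  res <- lapply(STRUCTURE_CLASSES, function(cl) {
    in_class <- classes[[cl]]
    n_all <- sum(in_class[k_idx])
    n_sumo <- sum(in_class[s_idx])
    enr <- if (n_all == 0) NA_real_ else
      (n_sumo / total_s) / (n_all / total_k)
    data.frame(class = cl, enrichment = enr,
               n_sumo_k = n_sumo, n_all_k = n_all)
  })
  out <- do.call(rbind, res)
  attr(out, "total_sumo_k") <- total_s
  attr(out, "total_k") <- total_k
  out
}

#' Between-class SUMOylation rate ratio
#'
#' The per-lysine SUMOylation rate inside a structure class divided by the
#' rate outside it, computed from a [foldEnrichment()] table. Unlike the
#' fold-enrichment statistic — which compresses toward 1 as the class
#' grows to cover most lysines — the rate ratio directly estimates the
#' relative odds that a lysine in the class is modified, and therefore
#' recovers a planted per-lysine enrichment parameter.
#'
#' @param enrichment a data.frame from [foldEnrichment()].
#' @param class a class name from `STRUCTURE_CLASSES`.
#' @return A single numeric rate ratio (`NA` if either side is empty).
#' @export
classRateRatio <- function(enrichment, class) {
  row <- enrichment[enrichment$class == class, , drop = FALSE]
  if (nrow(row) != 1) stop("unknown structure class: ", sQuote(class))
  total_s <- attr(enrichment, "total_sumo_k")
  total_k <- attr(enrichment, "total_k")
  s_in <- row$n_sumo_k
  k_in <- row$n_all_k
  s_out <- total_s - s_in
  k_out <- total_k - k_in
  if (k_in == 0 || k_out == 0 || s_out == 0) return(NA_real_)
  (s_in / k_in) / (s_out / k_out)
}

#' Short-disorder score distributions of SUMOylated vs other lysines
#'
#' Splits the continuous short-disorder scores of all lysines in
#' site-bearing proteins into those detected as SUMOylation sites and
#' those not, and summarizes both with 10/25/50/75/90% quantiles.
#'
#' @inheritParams foldEnrichment
#' @param ann a [ResidueAnnotation] covering the site proteins.
#' @return A list with numeric vectors `sumo_scores` and `other_scores`
#'   and a matrix `quantiles` (rows `sumo`, `other`).
#' @export
disorderDistributions <- function(sites, proteins, ann) {
  tab <- as.data.frame(annotationTable(ann))
  site_prot <- siteProteins(sites)
  prot_ids <- intersect(names(proteins), unique(site_prot))
  lys <- lysinePositions(proteins[prot_ids])
  lys_prot <- rep(prot_ids, lengths(lys))
  lys_pos <- unlist(lys, use.names = FALSE)

  idx <- match(paste(lys_prot, lys_pos, sep = "\r"),
               paste(tab$protein_id, tab$position, sep = "\r"))
  if (anyNA(idx)) {
    stop("annotation does not cover all lysines of the site proteins")
  }
  scores <- tab$short_disorder_score[idx]
  site_key <- paste(site_prot, sitePositions(sites), sep = "\r")
  is_sumo <- paste(lys_prot, lys_pos, sep = "\r") %in% site_key

  qs <- c(0.10, 0.25, 0.50, 0.75, 0.90)
  quantiles <- rbind(
    sumo = quantile(scores[is_sumo], qs, names = FALSE),
    other = quantile(scores[!is_sumo], qs, names = FALSE)
  )
  colnames(quantiles) <- paste0("q", qs * 100)
  list(
    sumo_scores = scores[is_sumo],
    other_scores = scores[!is_sumo],
    quantiles = quantiles
  )
}
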