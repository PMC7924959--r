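## Site topology: per-protein site counts, adjacent-site spacing, and
## distance-resolved SUMOylation probability curves.
##
## All computations are restricted to proteins carrying at least one
## detected site, and positions are 1-based residue indices.

#' Distribution of SUMOylation sites per protein
#'
#' Counts, over proteins with at least one site, how many proteins carry
#' each number of sites, together with the derived tail counts (proteins
#' with >= 2, >= 5 and >= 30 sites) that summarize the long-tailed
#' multi-site distribution typical of SUMO proteomes.
#'
#' @param sites a filtered [SumoSiteSet].
#' @return A list with `histogram` (data.frame `n_sites`, `n_proteins`),
#'   `n_proteins` (total with >= 1 site), and `ge2`, `ge5`, `ge30`.
#' @export
siteCountDistribution <- function(sites) {
  per_protein <- table(siteProteins(sites))
  counts <- table(factor(as.integer(per_protein)))
  hist <- data.frame(
    n_sites = as.integer(names(counts)),
    n_proteins = as.integer(counts)
  )
  list(
    histogram = hist[order(hist$n_sites), , drop = FALSE],
    n_proteins = length(per_protein),
    ge2 = sum(per_protein >= 2),
    ge5 = sum(per_protein >= 5),
    ge30 = sum(per_protein >= 30)
  )
}

#' Spacing between adjacent SUMOylation sites
#'
#' For every protein with two or more sites, computes the successive
#' differences of the sorted site positions and pools them across
#' proteins. [spacingFractionBelow()] reports the share of spacings
#' strictly smaller than a threshold — with the default threshold of 5
#' this is the probability that adjacent sites are less than five residues
#' apart, the headline site-clustering statistic.
#'
#' @param sites a filtered [SumoSiteSet] with at least one multi-site
#'   protein.
#' @return `adjacentSpacing()`: an integer vector of pooled spacings.
#' @export
adjacentSpacing <- function(sites) {
  pos <- split(sitePositions(sites), siteProteins(sites))
  multi <- pos[lengths(pos) >= 2]
  if (length(multi) == 0) {
    stop("no protein carries two or more sites; spacings are undefined")
  }
  unlist(lapply(multi, function(p) diff(sort(unique(p)))), use.names = FALSE)
}

#' @rdname adjacentSpacing
#' @param threshold spacings strictly below this value are counted.
#' @param pooled if `TRUE` (default) every spacing counts once across the
#'   whole data set; if `FALSE` the fraction is computed per protein and
#'   then averaged over proteins.
#' @return `spacingFractionBelow()`: a fraction in \[0,1\].
#' @export
spacingFractionBelow <- function(sites, threshold = 5, pooled = TRUE) {
  if (pooled) {
    return(mean(adjacentSpacing(sites) < threshold))
  }
  pos <- split(sitePositions(sites), siteProteins(sites))
  multi <- pos[lengths(pos) >= 2]
  if (length(multi) == 0) {
    stop("no protein carries two or more sites; spacings are undefined")
  }
  mean(vapply(multi, function(p) mean(diff(sort(unique(p))) < threshold),
              numeric(1)))
}

#' Probability of SUMOylation as a function of distance from an anchor
#'
#' For every anchor residue — each SUMOylated lysine
#' (`reference = "FROM_SUMO_K"`) or each lysine
#' (`reference = "FROM_ANY_K"`) — every *other* lysine in the same protein
#' contributes one pair. The pair distance (absolute position difference)
#' is rounded to the nearest multiple of `bin_width` (10 residues by
#' default, half-away-from-zero, so distances 1-4 fall in bin 0 and 5-14
#' in bin 10), and per bin the fraction of pairs whose other lysine is
#' itself a SUMOylation site is reported. Only proteins with at least one
#' identified site enter the computation. Under random site placement both
#' curves are flat; site clustering lifts the short-distance bins of the
#' `FROM_SUMO_K` curve above the `FROM_ANY_K` baseline.
#'
#' @param sites a filtered [SumoSiteSet].
#' @param proteins a named [Biostrings::AAStringSet] covering the site
#'   proteins (lysine positions are taken from the sequences).
#' @param reference `"FROM_SUMO_K"` or `"FROM_ANY_K"`.
#' @param bin_width distance bin width in residues.
#' @param rounding `"half-up"` (half-away-from-zero; 5 -> 10) or
#'   `"half-even"` (banker's rounding), exposed because the binning
#'   convention is not canonical.
#' @return A data.frame with one row per occupied bin: `bin` (center),
#'   `n_pairs`, `n_sumo`, `fraction` (only defined where `n_pairs > 0`),
#'   and `reference`.
#' @export
distanceCurve <- function(sites, proteins,
                          reference = c("FROM_SUMO_K", "FROM_ANY_K"),
                          bin_width = 10,
                          rounding = c("half-up", "half-even")) {
  reference <- match.arg(reference)
  rounding <- match.arg(rounding)
  site_pos <- split(sitePositions(sites), siteProteins(sites))
  prot_ids <- intersect(names(site_pos), names(proteins))
  if (length(prot_ids) < length(site_pos)) {
    stop("site protein(s) missing from the sequence set: ",
         paste(sQuote(setdiff(names(site_pos), names(proteins))),
               collapse = ", "))
  }
  lys <- lysinePositions(proteins[prot_ids])

  per_protein <- lapply(prot_ids, function(p) {
    k <- lys[[p]]
    if (length(k) < 2) return(NULL)
    is_sumo <- k %in% site_pos[[p]]
    anchors <- if (reference == "FROM_SUMO_K") which(is_sumo) else
      seq_along(k)
    if (length(anchors) == 0) return(NULL)
    d <- abs(outer(k[anchors], k, "-"))
    other_sumo <- matrix(is_sumo, nrow = length(anchors),
                         ncol = length(k), byrow = TRUE)
    self <- outer(k[anchors], k, "==")
    cbind(dist = d[!self], sumo = other_sumo[!self])
  })
  pairs <- do.call(rbind, per_protein)
  if (is.null(pairs) || nrow(pairs) == 0) {
    return(data.frame(bin = numeric(0), n_pairs = integer(0),
                      n_sumo = integer(0), fraction = numeric(0),
                      reference = character(0)))
  }
  bins <- if (rounding == "half-up") roundHalfUp(pairs[, "dist"], bin_width)
    else round(pairs[, "dist"] / bin_width) * bin_width
  agg <- rowsum(cbind(n = 1, sumo = pairs[, "sumo"]), group = bins)
  keys <- as.numeric(rownames(agg))
  ord <- order(keys)
  data.frame(
    bin = keys[ord],
    n_pairs = as.integer(agg[ord, "n"]),
    n_sumo = as.integer(agg[ord, "sumo"]),
    fraction = agg[ord, "sumo"] / agg[ord, "n"],
    reference = reference,
    row.names = NULL
  )
}
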