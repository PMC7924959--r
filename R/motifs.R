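## SUMO consensus-motif classification from sequence windows.
##
## Each modified lysine is assigned to exactly one of seven categories from
## the residues at positions -3..+2 around it (the canonical acceptor-motif
## context). Categories are tested strict-to-loose so that they are
## mutually exclusive and exhaustive:
##
##   1 HYDROPHOBIC_VARIANT  psi psi psi - K - x - E/D
##   2 CONSENSUS            psi - K - x - E/D
##   3 REVERSE_CONSENSUS    E/D - x - K - psi
##   4 ACIDIC               K - x - E/D
##   5 REVERSE_ACIDIC       E/D - x - K
##   6 DILYSINE             K directly adjacent to the modified K
##   7 NONE                 anything else
##
## psi = large hydrophobic residue (default I, L, V, M, F); the terminus
## pad character "_" never matches any class.

#' @rdname constants
#' @export
DEFAULT_HYDROPHOBIC <- c("I", "L", "V", "M", "F")

#' @rdname constants
#' @export
ACIDIC_RESIDUES <- c("E", "D")

## Characters at offsets (relative to the central K) for a vector of
## windows; "_" is returned for offsets past the window itself.
windowChar <- function(windows, offset) {
  wl <- nchar(windows)
  ctr <- (wl + 1L) %/% 2L
  idx <- ctr + offset
  out <- substr(windows, idx, idx)
  out[idx < 1L | idx > wl | out == ""] <- "_"
  out
}

#' Classify SUMO-acceptor sites into consensus-motif categories
#'
#' Assigns each sequence window (odd length, centered on the modified `K`,
#' padded with `_` beyond the protein termini) to exactly one of seven
#' motif categories, testing patterns in strict-to-loose precedence:
#' `HYDROPHOBIC_VARIANT` (\eqn{\psi\psi\psi}-K-x-E/D), `CONSENSUS`
#' (\eqn{\psi}-K-x-E/D), `REVERSE_CONSENSUS` (E/D-x-K-\eqn{\psi}),
#' `ACIDIC` (K-x-E/D), `REVERSE_ACIDIC` (E/D-x-K), `DILYSINE` (a lysine on
#' either flank of the modified K), and `NONE`. Only positions -3..+2
#' relative to the central K are consulted; the pad character never
#' matches.
#'
#' @param windows character vector of sequence windows (odd length,
#'   central character `K`).
#' @param hydrophobic character vector defining the large-hydrophobic
#'   (\eqn{\psi}) residue set. The default `I, L, V, M, F` is the standard
#'   choice in the \eqn{\psi}KxE literature; reported category fractions
#'   depend on it, so it is exposed.
#' @return `classifySite()`: a character vector of categories (factor
#'   levels in precedence order as in `MOTIF_CATEGORIES`).
#' @examples
#' classifySite("AAIKSEA")   # CONSENSUS
#' classifySite("AEAKVAA")   # REVERSE_CONSENSUS
#' classifySite("AAGKKGA")   # DILYSINE
#' @export
classifySite <- function(windows, hydrophobic = DEFAULT_HYDROPHOBIC) {
  wl <- nchar(windows)
  if (any(wl %% 2L == 0L)) stop("sequence windows must have odd length")
  ctr <- substr(windows, (wl + 1L) %/% 2L, (wl + 1L) %/% 2L)
  if (any(ctr != "K")) {
    stop("sequence window(s) not centered on 'K': ",
         paste(sQuote(windows[ctr != "K"][1]), collapse = ""))
  }
  m3 <- windowChar(windows, -3L)
  m2 <- windowChar(windows, -2L)
  m1 <- windowChar(windows, -1L)
  p1 <- windowChar(windows, 1L)
  p2 <- windowChar(windows, 2L)

  hyd <- function(x) x %in% hydrophobic
  acid <- function(x) x %in% ACIDIC_RESIDUES

  out <- rep("NONE", length(windows))
  out[p1 == "K" | m1 == "K"] <- "DILYSINE"
  out[acid(m2)] <- "REVERSE_ACIDIC"
  out[acid(p2)] <- "ACIDIC"
  out[acid(m2) & hyd(p1)] <- "REVERSE_CONSENSUS"
  out[hyd(m1) & acid(p2)] <- "CONSENSUS"
  out[hyd(m3) & hyd(m2) & hyd(m1) & acid(p2)] <- "HYDROPHOBIC_VARIANT"
  out
}

#' @rdname classifySite
#' @param sites a [SumoSiteSet] (or a character vector of windows).
#' @return `motifComposition()`: a data.frame with one row per category
#'   (`category`, `count`, `fraction`); fractions sum to 1.
#' @export
motifComposition <- function(sites, hydrophobic = DEFAULT_HYDROPHOBIC) {
  windows <- if (is.character(sites)) sites else sequenceWindows(sites)
  if (length(windows) == 0) {
    stop("cannot compute a motif composition for an empty site set")
  }
  calls <- factor(classifySite(windows, hydrophobic),
                  levels = MOTIF_CATEGORIES)
  counts <- table(calls)
  data.frame(
    category = MOTIF_CATEGORIES,
    count = as.integer(counts[MOTIF_CATEGORIES]),
    fraction = as.numeric(counts[MOTIF_CATEGORIES]) / length(windows),
    row.names = NULL
  )
}
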