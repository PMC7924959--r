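## Quantitative LFQ pipeline: replicate averaging, log2 transformation,
## column-wise downshifted-normal imputation, row z-scoring, 1 - Pearson
## hierarchical clustering, similarity matrices, normalized profiles,
## cumulative site intensities and per-timepoint identification counts.
##
## The pipeline states are strictly ordered
## RAW -> AVERAGED -> LOG2 -> IMPUTED -> ZSCORED; every operation
## validates the state of its input ProfileMatrix.

#' Build a RAW ProfileMatrix from a site or protein container
#'
#' @param x a [SumoSiteSet] (uses the `"intensity"` assay) or a
#'   `SummarizedExperiment` with an `"lfq"` assay.
#' @return A [ProfileMatrix] in state `RAW` (columns = samples).
#' @export
profileMatrix <- function(x) {
  a <- SummarizedExperiment::assays(x)
  nm <- if ("intensity" %in% names(a)) "intensity" else "lfq"
  ProfileMatrix(assay(x, nm), state = "RAW")
}

#' Average replicate columns per timepoint
#'
#' Replaces the per-sample columns of a RAW matrix by per-timepoint
#' columns holding the mean of the non-missing replicate values; a
#' timepoint with all replicates missing stays missing.
#'
#' @param x a [ProfileMatrix] in state `RAW` (columns = sample ids).
#' @param design sample design from [sampleDesign()]; every column of `x`
#'   must be a known sample.
#' @return A [ProfileMatrix] in state `AVERAGED` (columns = timepoints in
#'   design order).
#' @export
averageReplicates <- function(x, design) {
  assertState(x, "RAW")
  v <- profileValues(x)
  unknown <- setdiff(colnames(v), rownames(design))
  if (length(unknown) > 0) {
    stop("column(s) not in the sample design: ",
         paste(sQuote(unknown), collapse = ", "))
  }
  tps <- levels(design$timepoint)
  out <- vapply(tps, function(tp) {
    cols <- rownames(design)[design$timepoint == tp]
    cols <- intersect(cols, colnames(v))
    rowMeans(v[, cols, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(v)))
  out <- matrix(out, nrow = nrow(v), dimnames = list(rownames(v), tps))
  out[is.nan(out)] <- NA_real_
  ProfileMatrix(out, state = "AVERAGED")
}

#' Log2-transform an averaged intensity matrix
#'
#' @param x a [ProfileMatrix] in state `AVERAGED` (or `RAW`, when no
#'   averaging is wanted); values must be positive or missing.
#' @return A [ProfileMatrix] in state `LOG2`.
#' @export
log2Transform <- function(x) {
  assertState(x, c("RAW", "AVERAGED"))
  v <- profileValues(x)
  bad <- which(rowSums(!is.na(v) & v <= 0) > 0)
  if (length(bad) > 0) {
    stop("non-positive intensity in row(s): ",
         paste(sQuote(rownames(v)[bad]), collapse = ", "))
  }
  ProfileMatrix(log2(v), state = "LOG2")
}

#' Impute missing values from a downshifted normal distribution
#'
#' Perseus-style column-wise imputation for intensities that are missing
#' not at random: for each column with observed mean \eqn{m_c} and
#' standard deviation \eqn{s_c}, every missing cell is drawn from
#' \eqn{N(m_c - downshift \cdot s_c, (width \cdot s_c)^2)}, i.e. from a
#' narrowed distribution shifted into the low-intensity tail where
#' unobserved measurements are expected to lie. Observed cells are never
#' touched. The defaults `width = 0.3`, `downshift = 1.8` are the
#' conventional Perseus settings.
#'
#' @param x a [ProfileMatrix] in state `LOG2`.
#' @param width SD of the imputation distribution, in units of the
#'   column SD.
#' @param downshift shift of the imputation mean below the column mean,
#'   in units of the column SD.
#' @param seed integer seed making the imputation deterministic; `NULL`
#'   draws from the current RNG stream.
#' @return A [ProfileMatrix] in state `IMPUTED` with no missing values.
#' @export
imputeDownshift <- function(x, width = 0.3, downshift = 1.8, seed = NULL) {
  assertState(x, "LOG2")
  v <- profileValues(x)
  n_obs <- colSums(!is.na(v))
  if (any(n_obs < 2)) {
    stop("column(s) with fewer than 2 observed values: ",
         paste(sQuote(colnames(v)[n_obs < 2]), collapse = ", "))
  }
  out <- withSeed(seed, {
    for (j in seq_len(ncol(v))) {
      miss <- which(is.na(v[, j]))
      if (length(miss) == 0) next
      m <- mean(v[, j], na.rm = TRUE)
      s <- sd(v[, j], na.rm = TRUE)
      v[miss, j] <- rnorm(length(miss), mean = m - downshift * s,
                          sd = width * s)
    }
    v
  })
  ProfileMatrix(out, state = "IMPUTED")
}

#' Z-score rows of an imputed matrix
#'
#' Subtracts the row mean and divides by the row sample SD (n - 1
#' denominator). Rows with zero variance cannot be z-scored; they are
#' returned unscaled and listed in [flaggedRows()].
#'
#' @param x a [ProfileMatrix] in state `IMPUTED` (or `LOG2` with no
#'   missing values).
#' @return A [ProfileMatrix] in state `ZSCORED`.
#' @export
zscoreRows <- function(x) {
  assertState(x, c("LOG2", "IMPUTED"))
  v <- profileValues(x)
  if (anyNA(v)) {
    stop("missing values present; impute before z-scoring")
  }
  mu <- rowMeans(v)
  sdv <- apply(v, 1, sd)
  flagged <- rownames(v)[sdv == 0]
  scale_rows <- sdv != 0
  v[scale_rows, ] <- (v[scale_rows, , drop = FALSE] - mu[scale_rows]) /
    sdv[scale_rows]
  ProfileMatrix(v, state = "ZSCORED", flagged = flagged)
}

#' Hierarchical clustering of profiles by 1 - Pearson correlation
#'
#' Computes the pairwise distance \eqn{d(i, j) = 1 - r(row_i, row_j)}
#' (0 for identical shapes, 2 for perfect anti-correlation) and builds an
#' agglomerative merge tree. Average linkage is the default, matching the
#' common heatmap-tool convention for this distance.
#'
#' @param x a [ProfileMatrix] in state `ZSCORED` (rows with zero variance
#'   must have been removed; see [flaggedRows()]).
#' @param linkage_method linkage passed to [stats::hclust()].
#' @param k optional number of flat clusters to cut the tree into.
#' @return A list with `tree` (an `hclust`), `distance` (the `dist`),
#'   `order` (row order of the tree) and, when `k` is given, `clusters`
#'   (named integer vector).
#' @export
hierarchicalCluster <- function(x, linkage_method = "average", k = NULL) {
  assertState(x, "ZSCORED")
  v <- profileValues(x)
  if (nrow(v) < 2) stop("clustering needs at least 2 rows")
  if (length(flaggedRows(x)) > 0) {
    stop("zero-variance row(s) present (see flaggedRows()); ",
         "remove them before clustering")
  }
  d <- as.dist(1 - cor(t(v)))
  tree <- hclust(d, method = linkage_method)
  out <- list(tree = tree, distance = d, order = tree$order)
  if (!is.null(k)) {
    out$clusters <- cutree(tree, k = k)
  }
  out
}

#' Pairwise Pearson similarity matrix of profiles
#'
#' @param x a [ProfileMatrix] with at least 2 rows and no zero-variance
#'   rows.
#' @return A symmetric correlation matrix with unit diagonal; equals
#'   1 minus the clustering distance matrix.
#' @export
similarityMatrix <- function(x) {
  v <- profileValues(x)
  if (nrow(v) < 2) stop("similarity needs at least 2 rows")
  sdv <- apply(v, 1, sd)
  if (any(is.na(sdv)) || any(sdv == 0)) {
    stop("zero-variance or incomplete row(s); ",
         "impute and inspect flaggedRows() first")
  }
  s <- cor(t(v))
  diag(s) <- 1
  s
}

#' Min-max normalized temporal profile
#'
#' Scales a row of averaged intensities to \[0,1\] per timepoint:
#' `(x - min) / (max - min)`.
#'
#' @param row a numeric vector of averaged intensities (non-constant, no
#'   missing values).
#' @return A numeric vector in \[0,1\].
#' @export
normalizedProfile <- function(row) {
  if (anyNA(row)) stop("profile contains missing values")
  rng <- range(row)
  if (rng[1] == rng[2]) {
    stop("constant profile cannot be min-max normalized")
  }
  (row - rng[1]) / (rng[2] - rng[1])
}

#' Cumulative intensity of each site across all samples
#'
#' Sums the non-missing intensities of every site over all samples; the
#' cumulative intensity of a multi-site protein's sites is a readout of
#' relative site usage. Sites with no observed intensity get 0 and are
#' reported in the `all_missing` attribute.
#'
#' @param sites a [SumoSiteSet].
#' @return A named numeric vector (site ids); per-protein intensity
#'   ranking is available via [rankSitesWithin()].
#' @export
cumulativeSiteIntensity <- function(sites) {
  ints <- assay(sites, "intensity")
  out <- rowSums(ints, na.rm = TRUE)
  attr(out, "all_missing") <- rownames(ints)[rowSums(!is.na(ints)) == 0]
  out
}

#' @rdname cumulativeSiteIntensity
#' @return `rankSitesWithin()`: an integer vector ranking each site within
#'   its protein by decreasing cumulative intensity (1 = most intense).
#' @export
rankSitesWithin <- function(sites) {
  cum <- cumulativeSiteIntensity(sites)
  prot <- siteProteins(sites)
  out <- integer(length(cum))
  for (rows in split(seq_along(cum), prot)) {
    out[rows] <- rank(-cum[rows], ties.method = "min")
  }
  names(out) <- names(cum)
  out
}

#' Count identified rows per timepoint
#'
#' A row (site or protein) counts as identified at a timepoint if at
#' least one of its replicate cells at that timepoint holds a valid
#' (non-missing, positive) value; `mode = "all"` instead requires every
#' replicate to be valid.
#'
#' @param x a [ProfileMatrix] in state `RAW` (columns = sample ids).
#' @param design sample design from [sampleDesign()].
#' @param mode `"any"` (default) or `"all"`.
#' @return A named integer vector, one count per timepoint.
#' @export
countIdentified <- function(x, design, mode = c("any", "all")) {
  assertState(x, "RAW")
  mode <- match.arg(mode)
  v <- profileValues(x)
  valid <- !is.na(v) & v > 0
  tps <- levels(design$timepoint)
  out <- vapply(tps, function(tp) {
    cols <- intersect(rownames(design)[design$timepoint == tp],
                      colnames(v))
    per_row <- if (mode == "any") {
      rowSums(valid[, cols, drop = FALSE]) >= 1
    } else {
      rowSums(valid[, cols, drop = FALSE]) == length(cols)
    }
    sum(per_row)
  }, integer(1))
  setNames(as.integer(out), tps)
}
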