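## Internal helpers shared across the package.

#' @importFrom methods new is validObject setClass setGeneric setMethod show
#' @importFrom stats rnorm runif rbinom cor hclust cutree as.dist sd
#'   quantile plogis setNames rgeom
#' @importFrom utils read.delim write.table
NULL

#' Package-wide label constants
#'
#' `AA_ALPHABET`: the 20 proteinogenic amino acids (one-letter code).
#' `MEIOTIC_TIMEPOINTS`: the six stages of a synchronized meiotic time
#' course — pre-meiotic G0, S-phase, double-strand-break formation (DSB),
#' strand invasion (SI), double-Holliday junction / pachytene arrest
#' (dHJ) and crossover formation (CO). `MOTIF_CATEGORIES`: the seven
#' motif categories in classification precedence order (strict to loose;
#' `NONE` is the fall-through). `PROFILE_CLASSES`: the temporal shape
#' labels understood by the intensity simulator.
#'
#' @name constants
#' @export
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' @rdname constants
#' @export
MEIOTIC_TIMEPOINTS <- c("G0", "S", "DSB", "SI", "dHJ", "CO")

#' @rdname constants
#' @export
MOTIF_CATEGORIES <- c(
  "HYDROPHOBIC_VARIANT", "CONSENSUS", "REVERSE_CONSENSUS",
  "ACIDIC", "REVERSE_ACIDIC", "DILYSINE", "NONE"
)

#' @rdname constants
#' @export
PROFILE_CLASSES <- c("rising", "falling", "U", "peak-mid", "flat")

## Run `expr` under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is untouched. seed = NULL runs in the current stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

## Half-away-from-zero rounding to the nearest multiple of `unit`
## (base round() rounds half to even, which is not what we want for
## distance binning: 5 -> 10, 15 -> 20).
roundHalfUp <- function(x, unit = 10) {
  unit * floor(abs(x) / unit + 0.5) * sign(x + (x == 0))
}

## Positions of a residue (default lysine) in a character vector of
## sequences; returns a list of sorted 1-based integer vectors.
residuePositions <- function(sequences, residue = "K") {
  lapply(strsplit(sequences, "", fixed = TRUE), function(s) {
    which(s == residue)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
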