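mkRaw <- function(values, design) {
  ProfileMatrix(matrix(values, nrow = 1,
                       dimnames = list("r1", rownames(design))), "RAW")
}

test_that("replicate averaging ignores missing cells and respects the design", {
  design <- tinyDesign(timepoints = c("t1", "t2"), n_replicates = 3)
  x <- mkRaw(c(2, 4, NA, NA, NA, NA), design)
  av <- averageReplicates(x, design)
  expect_equal(profileState(av), "AVERAGED")
  expect_equal(unname(profileValues(av)[1, ]), c(3, NA))

  bad <- ProfileMatrix(matrix(1, 1, 1, dimnames = list("r1", "weird")),
                       "RAW")
  expect_error(averageReplicates(bad, design), "weird")
})

test_that("log2 transform preserves missingness and rejects non-positive values", {
  design <- tinyDesign(timepoints = c("t1", "t2"), n_replicates = 1)
  x <- averageReplicates(mkRaw(c(8, NA), design), design)
  lg <- log2Transform(x)
  expect_equal(unname(profileValues(lg)[1, ]), c(3, NA))
  ## round trip
  expect_equal(2^profileValues(lg)[1, 1], 8)

  y <- averageReplicates(mkRaw(c(-1, 4), design), design)
  expect_error(log2Transform(y), "r1")
})

test_that("downshifted imputation is deterministic, column-wise and leaves observed cells alone", {
  set.seed(88)
  m <- matrix(rnorm(600, mean = 25, sd = 2), ncol = 3,
              dimnames = list(sprintf("r%03d", 1:200), c("a", "b", "c")))
  holes <- matrix(runif(600) < 0.2, ncol = 3)
  m2 <- m
  m2[holes] <- NA
  x <- ProfileMatrix(m2, "LOG2")
  i1 <- imputeDownshift(x, seed = 5)
  i2 <- imputeDownshift(x, seed = 5)
  expect_identical(profileValues(i1), profileValues(i2))
  expect_false(anyNA(profileValues(i1)))
  expect_equal(profileValues(i1)[!holes], m[!holes])

  ## no missing cells: identity
  x0 <- ProfileMatrix(m, "LOG2")
  expect_equal(profileValues(imputeDownshift(x0, seed = 1)), m)

  ## a column with <2 observed values is rejected
  m3 <- m2
  m3[-1, 2] <- NA
  expect_error(imputeDownshift(ProfileMatrix(m3, "LOG2"), seed = 1),
               "fewer than 2")

  ## imputed cells follow the downshifted normal per column
  big <- matrix(rnorm(4000, 25, 2), ncol = 2,
                dimnames = list(sprintf("r%04d", 1:2000), c("a", "b")))
  bigNA <- big
  bigNA[seq(1, 2000, by = 2), 1] <- NA
  mc <- mean(bigNA[, 1], na.rm = TRUE)
  sc <- sd(bigNA[, 1], na.rm = TRUE)
  imp <- profileValues(imputeDownshift(ProfileMatrix(bigNA, "LOG2"),
                                       seed = 9))
  cells <- imp[seq(1, 2000, by = 2), 1]
  n <- length(cells)
  expect_lt(abs(mean(cells) - (mc - 1.8 * sc)), 3 * 0.3 * sc / sqrt(n))
  expect_lt(abs(sd(cells) - 0.3 * sc), 3 * 0.3 * sc / sqrt(2 * n))
})

test_that("z-scoring centers and scales rows, flagging constant ones", {
  m <- matrix(c(1, 2, 3, 4, 4, 4), nrow = 2, byrow = TRUE,
              dimnames = list(c("v", "const"), c("a", "b", "c")))
  z <- zscoreRows(ProfileMatrix(m, "IMPUTED"))
  expect_equal(unname(profileValues(z)["v", ]), c(-1, 0, 1))
  expect_equal(flaggedRows(z), "const")
  expect_equal(unname(profileValues(z)["const", ]), c(4, 4, 4))

  set.seed(41)
  r <- matrix(rnorm(500), nrow = 50,
              dimnames = list(sprintf("r%02d", 1:50), NULL))
  zz <- profileValues(zscoreRows(ProfileMatrix(r, "IMPUTED")))
  expect_true(all(abs(rowMeans(zz)) < 1e-9))
  expect_true(all(abs(apply(zz, 1, sd) - 1) < 1e-9))
})

test_that("the pipeline enforces its processing order", {
  design <- tinyDesign(timepoints = c("t1", "t2"), n_replicates = 1)
  raw <- mkRaw(c(8, 4), design)
  expect_error(zscoreRows(raw), "LOG2/IMPUTED")
  expect_error(imputeDownshift(raw), "LOG2")
  lg <- log2Transform(averageReplicates(raw, design))
  expect_error(averageReplicates(lg, design), "RAW")
})

test_that("1 - Pearson distances behave at the extremes and ignore row order", {
  m <- matrix(c(1, 2, 3, 4,
                2, 4, 6, 8,
                4, 3, 2, 1,
                1, 3, 2, 5), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("r", 1:4), paste0("t", 1:4)))
  z <- zscoreRows(ProfileMatrix(m, "IMPUTED"))
  cl <- hierarchicalCluster(z)
  d <- as.matrix(cl$distance)
  ## identical shape: distance 0; perfect anti-correlation: distance 2
  expect_equal(d["r1", "r2"], 0, tolerance = 1e-12)
  expect_equal(d["r1", "r3"], 2, tolerance = 1e-12)

  sim <- similarityMatrix(z)
  expect_equal(sim, t(sim))
  expect_true(all(diag(sim) == 1))
  expect_equal(sim["r1", "r4"], 1 - d["r1", "r4"], tolerance = 1e-12)

  ## permuting rows permutes, but does not change, the tree
  perm <- c(3, 1, 4, 2)
  z2 <- ProfileMatrix(profileValues(z)[perm, ], "ZSCORED")
  cl2 <- hierarchicalCluster(z2)
  co1 <- as.matrix(cophenetic(cl$tree))
  co2 <- as.matrix(cophenetic(cl2$tree))
  expect_equal(co2[rownames(co1), colnames(co1)], co1, tolerance = 1e-12)
})

test_that("planted profile classes are recovered by correlation clustering", {
  cfg <- simulationConfig(
    profile_classes = c(rising = 1, falling = 1, `peak-mid` = 1) / 3,
    seed = 61
  )
  classes <- sample(c("rising", "falling", "peak-mid"), 150,
                    replace = TRUE)
  sim <- simulateIntensities(classes, cfg, seed = 61)
  design <- sampleDesign(cfg$timepoints, cfg$n_replicates)
  pm <- ProfileMatrix(sim$intensities, "RAW")
  z <- zscoreRows(imputeDownshift(log2Transform(
    averageReplicates(pm, design)), seed = 61))
  keep <- setdiff(rownames(profileValues(z)), flaggedRows(z))
  cl <- hierarchicalCluster(
    ProfileMatrix(profileValues(z)[keep, ], "ZSCORED"), k = 3
  )
  ari <- mclust::adjustedRandIndex(
    cl$clusters, classes[match(keep, rownames(sim$intensities))]
  )
  expect_gte(ari, 0.95)
})

test_that("normalized profiles span [0, 1] and preserve shape", {
  expect_equal(normalizedProfile(c(2, 4, 6)), c(0, 0.5, 1))
  p <- normalizedProfile(c(0, 0.25, 1))
  expect_equal(normalizedProfile(p), p)
  mono <- normalizedProfile(c(1, 2, 4, 9))
  expect_true(all(diff(mono) > 0))
  expect_error(normalizedProfile(c(3, 3, 3)), "constant")
  expect_error(normalizedProfile(c(1, NA, 3)), "missing")
})

test_that("cumulative site intensity sums observed values and ranks sites", {
  design <- tinyDesign(timepoints = c("t1", "t2", "t3"), n_replicates = 1)
  ints <- matrix(c(1e6, NA, 3e6,
                   NA, NA, NA,
                   5e6, 5e6, NA), nrow = 3, byrow = TRUE,
                 dimnames = list(NULL, rownames(design)))
  s <- makeSites(protein_id = c("P1", "P1", "P1"),
                 position = c(5L, 9L, 13L),
                 design = design, intensities = ints)
  cum <- cumulativeSiteIntensity(s)
  expect_equal(as.numeric(cum), c(4e6, 0, 1e7))
  expect_equal(attr(cum, "all_missing"), rownames(s)[2])
  expect_equal(unname(rankSitesWithin(s)), c(2L, 3L, 1L))
})

test_that("identification counting requires one (or all) valid replicates", {
  design <- tinyDesign(timepoints = c("t1", "t2"), n_replicates = 2)
  m <- matrix(c(1e6, NA, NA, NA,
                2e6, 2e6, 3e6, NA), nrow = 2, byrow = TRUE,
              dimnames = list(c("row1", "row2"), rownames(design)))
  x <- ProfileMatrix(m, "RAW")
  expect_equal(countIdentified(x, design), c(t1 = 2L, t2 = 1L))
  expect_equal(countIdentified(x, design, mode = "all"),
               c(t1 = 1L, t2 = 0L))
})
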