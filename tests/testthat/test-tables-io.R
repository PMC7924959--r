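test_that("site table parsing handles flags and missing intensity cells", {
  design <- tinyDesign(timepoints = "t1", n_replicates = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("Protein", "Position", "Localization prob", "Sequence window",
          "Reverse", "Potential contaminant",
          "Intensity t1_1", "Intensity t1_2", "Intensity t1_3",
          sep = "\t"),
    paste("P1", "10", "0.99", paste0(strrep("A", 15), "K", strrep("A", 15)),
          "", "", "1e7", "", "2e7", sep = "\t"),
    paste("P2", "5", "0.80", paste0(strrep("_", 14), "G", "K",
                                    strrep("A", 15)),
          "+", "", "NaN", "3e6", "4e6", sep = "\t"),
    paste("P3", "7", "1", paste0(strrep("A", 15), "K", strrep("A", 15)),
          "", "+", "5e6", "6e6", "7e6", sep = "\t")
  ), path)
  s <- readSitesTable(path, design)
  expect_s4_class(s, "SumoSiteSet")
  expect_equal(nrow(s), 3L)
  expect_equal(sum(isReverse(s)), 1L)
  expect_equal(sum(isContaminant(s)), 1L)
  ints <- assay(s, "intensity")
  expect_equal(unname(ints[1, ]), c(1e7, NA, 2e7))
  expect_true(is.na(ints[2, "t1_1"]))  # "NaN" cell is missing
  expect_equal(sitePositions(s), c(10L, 5L, 7L))
})

test_that("schema and parse errors name the offending column or row", {
  design <- tinyDesign(timepoints = "t1", n_replicates = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("Protein", "Position", "Sequence window", "Reverse",
          "Potential contaminant", "Intensity t1_1", sep = "\t"),
    paste("P1", "10", "AKA", "", "", "1e7", sep = "\t")
  ), path)
  expect_error(readSitesTable(path, design), "Localization prob")

  writeLines(c(
    paste("Protein", "Position", "Localization prob", "Sequence window",
          "Reverse", "Potential contaminant", "Intensity t1_1",
          sep = "\t"),
    paste("P1", "10", "0.99", "AKA", "", "", "1e7", sep = "\t"),
    paste("P2", "ten", "0.99", "AKA", "", "", "1e7", sep = "\t")
  ), path)
  expect_error(readSitesTable(path, design), "row 2")
})

test_that("decoy/contaminant removal and localization cutoff are inclusive and idempotent", {
  s <- makeSites(
    protein_id = paste0("P", 1:10), position = rep(5L, 10),
    localization_prob = c(0.95, 0.96, 1.0, rep(0.5, 7)),
    reverse = c(rep(FALSE, 4), TRUE, TRUE, rep(FALSE, 4)),
    contaminant = c(rep(FALSE, 6), TRUE, rep(FALSE, 3))
  )
  f <- filterSites(s)
  expect_equal(nrow(f), 7L)
  ## order preserved, output a subset of input
  expect_true(all(rownames(f) %in% rownames(s)))
  expect_equal(rownames(f), rownames(s)[rownames(s) %in% rownames(f)])
  ## idempotent
  expect_equal(rownames(filterSites(f)), rownames(f))
  ## inclusive threshold: 0.96 and 1.0 survive, 0.95 does not
  f2 <- filterSites(s[1:3, ], min_loc_prob = 0.96)
  expect_equal(locProbs(f2), c(0.96, 1.0))
})

test_that("FASTA reading indexes lysines and validates input", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1 some description", "MKAK"), path)
  p <- readFasta(path)
  expect_equal(names(p), "P1")
  expect_equal(lysinePositions(p)$P1, c(2L, 4L))

  writeLines(character(0), path)
  expect_equal(length(readFasta(path)), 0L)

  writeLines(c(">P1", "MKAK", ">P1", "MAAA"), path)
  expect_error(readFasta(path), "duplicate")

  writeLines(c(">P1", "MKA2"), path)
  expect_error(readFasta(path), "alphabet")
})

test_that("a synthetic study survives a disk round trip", {
  cfg <- simulationConfig(n_proteins = 25, length_range = c(100, 200),
                          seed = 42)
  study <- simulateStudy(cfg)
  outdir <- withr::local_tempdir()
  paths <- writeStudy(study, outdir)
  expect_true(all(file.exists(paths)))

  design2 <- readDesignTable(paths["design"])
  expect_equal(rownames(design2), rownames(study$design))
  expect_equal(as.character(design2$timepoint),
               as.character(study$design$timepoint))

  s2 <- readSitesTable(paths["sites"], design2)
  expect_equal(nrow(s2), nrow(study$sites))
  expect_equal(siteProteins(s2), siteProteins(study$sites))
  expect_equal(sitePositions(s2), sitePositions(study$sites))
  expect_equal(sequenceWindows(s2), sequenceWindows(study$sites))
  expect_equal(isReverse(s2), isReverse(study$sites))
  expect_equal(locProbs(s2), locProbs(study$sites), tolerance = 1e-9)
  expect_equal(assay(s2, "intensity"), assay(study$sites, "intensity"),
               tolerance = 1e-9)

  p2 <- readFasta(paths["fasta"])
  expect_equal(as.character(p2), as.character(study$sequences))

  pg2 <- readProteinTable(paths["proteins"], design2)
  expect_equal(assay(pg2, "lfq"), assay(study$proteins, "lfq"),
               tolerance = 1e-9)

  a2 <- readAnnotationTable(paths["annotation"])
  t1 <- as.data.frame(annotationTable(study$annotation))
  t2 <- as.data.frame(annotationTable(a2))
  expect_equal(t2$globular, t1$globular)
  expect_equal(t2$short_disorder_score, t1$short_disorder_score,
               tolerance = 1e-9)

  ## ground truth re-readable and consistent with the emitted table
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(truth$sites$position,
               sitePositions(filterSites(study$sites)))
})
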