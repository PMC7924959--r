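## small helper: an annotation data.frame with all-false tracks
blankAnnotation <- function(protein_id, len) {
  data.frame(
    protein_id = protein_id, position = seq_len(len),
    globular = FALSE, long_disorder = FALSE, short_disorder_score = 0,
    exposed = TRUE, buried = FALSE, coiled_coil = FALSE,
    transmembrane = FALSE
  )
}

test_that("composite classes follow their definitions", {
  ## fully globular protein: never disordered
  a <- blankAnnotation("G1", 50)
  a$globular <- TRUE
  a$short_disorder_score <- 0.9  # inside a globular domain
  cl <- deriveClasses(ResidueAnnotation(a))
  expect_true(all(!cl$DISORDERED))
  expect_true(all(cl$SHORT_DISORDER))

  ## 100-residue terminus rule
  b <- blankAnnotation("T1", 300)
  b$long_disorder[c(50, 150)] <- TRUE
  cl <- deriveClasses(ResidueAnnotation(b))
  expect_true(cl$DISORDERED_NOT_CC[50] && cl$DISORDERED_NOT_CC[150])
  expect_true(cl$DISORDER_NEAR_TERMINUS[50])
  expect_false(cl$DISORDER_NEAR_TERMINUS[150])

  ## a disordered run touching the C-terminus is a disordered terminus
  d <- blankAnnotation("T2", 100)
  d$long_disorder[80:100] <- TRUE
  d$long_disorder[40:50] <- TRUE
  cl <- deriveClasses(ResidueAnnotation(d))
  expect_true(all(cl$DISORDERED_TERMINUS[80:100]))
  expect_false(any(cl$DISORDERED_TERMINUS[40:50]))

  ## length mismatch detected
  e <- blankAnnotation("E1", 50)[-10, ]
  expect_error(deriveClasses(ResidueAnnotation(e)), "length mismatch")
})

test_that("derived classes equal a brute-force per-residue re-derivation", {
  study <- simulateStudy(simulationConfig(n_proteins = 6,
                                          length_range = c(60, 120),
                                          seed = 31))
  ann <- as.data.frame(annotationTable(study$annotation))
  got <- deriveClasses(study$annotation)
  want <- bruteClasses(ann)
  got <- got[order(got$protein_id, got$position), ]
  want <- want[order(want$protein_id, want$position), ]
  rownames(got) <- rownames(want) <- NULL
  for (cl in STRUCTURE_CLASSES) {
    expect_equal(got[[cl]], want[[cl]], info = cl)
  }
})

test_that("fold-enrichment follows its defining ratio of percentages", {
  ## all-lysine protein: 100 K, 40 disordered; 10 sites, 8 in disorder
  a <- blankAnnotation("P1", 100)
  a$long_disorder[1:40] <- TRUE
  ann <- ResidueAnnotation(a)
  prot <- Biostrings::AAStringSet(c(P1 = strrep("K", 100)))
  s <- makeSites(protein_id = rep("P1", 10),
                 position = as.integer(c(1, 5, 10, 15, 20, 25, 30, 35,
                                         50, 90)))
  cl <- deriveClasses(ann)
  fe <- foldEnrichment(s, prot, cl)
  expect_equal(fe$enrichment[fe$class == "DISORDERED"],
               (8 / 10) / (40 / 100))
  expect_equal(fe$n_sumo_k[fe$class == "DISORDERED"], 8)
  expect_equal(fe$n_all_k[fe$class == "DISORDERED"], 40)

  ## a class covering every residue has enrichment exactly 1
  expect_equal(fe$enrichment[fe$class == "GLOBULAR_EXPOSED"], NA_real_)
  a2 <- a
  a2$long_disorder <- TRUE
  fe2 <- foldEnrichment(s, prot, deriveClasses(ResidueAnnotation(a2)))
  expect_equal(fe2$enrichment[fe2$class == "DISORDERED"], 1)
})

test_that("complementary classes bracket 1 and duplication leaves enrichment invariant", {
  study <- simulateStudy(simulationConfig(n_proteins = 30, seed = 13))
  s <- filterSites(study$sites)
  cl <- deriveClasses(study$annotation)
  fe <- foldEnrichment(s, study$sequences, cl)

  ## counts partition: DISORDERED + complement = totals (complement via
  ## a manufactured NOT_DISORDERED class)
  cl2 <- cl
  cl2$DISORDERED <- !cl$DISORDERED
  fe_c <- foldEnrichment(s, study$sequences, cl2)
  i <- which(fe$class == "DISORDERED")
  expect_equal(fe$n_sumo_k[i] + fe_c$n_sumo_k[i], attr(fe, "total_sumo_k"))
  expect_equal(fe$n_all_k[i] + fe_c$n_all_k[i], attr(fe, "total_k"))
  e1 <- fe$enrichment[i]
  e2 <- fe_c$enrichment[i]
  expect_true((e1 >= 1 && e2 <= 1) || (e1 <= 1 && e2 >= 1))

  ## duplicating every protein under new ids changes nothing
  dup_seq <- c(study$sequences, study$sequences)
  names(dup_seq) <- c(names(study$sequences),
                      paste0(names(study$sequences), "_dup"))
  ann <- as.data.frame(annotationTable(study$annotation))
  ann_dup <- ann
  ann_dup$protein_id <- paste0(ann_dup$protein_id, "_dup")
  cl_dup <- deriveClasses(ResidueAnnotation(rbind(ann, ann_dup)))
  s_dup <- makeSites(
    protein_id = c(siteProteins(s), paste0(siteProteins(s), "_dup")),
    position = c(sitePositions(s), sitePositions(s)),
    sequence_window = c(sequenceWindows(s), sequenceWindows(s)),
    design = study$design,
    intensities = rbind(assay(s, "intensity"), assay(s, "intensity"))
  )
  fe_dup <- foldEnrichment(s_dup, dup_seq, cl_dup)
  expect_equal(fe_dup$enrichment, fe$enrichment, tolerance = 1e-12)
})

test_that("disorder scores of modified lysines separate from the rest when planted", {
  study <- simulateStudy(simulationConfig(n_proteins = 60,
                                          disorder_enrichment = 4,
                                          cluster_prob = 0, seed = 23))
  s <- filterSites(study$sites)
  dd <- disorderDistributions(s, study$sequences, study$annotation)
  expect_gt(median(dd$sumo_scores), median(dd$other_scores))
  ## conservation: the two groups partition all lysines of site proteins
  lys <- lysinePositions(study$sequences[unique(siteProteins(s))])
  expect_equal(length(dd$sumo_scores) + length(dd$other_scores),
               sum(lengths(lys)))
  ## degenerate case: constant scores give equal medians
  a <- blankAnnotation("P1", 9)
  a$short_disorder_score <- 0.5
  p1 <- Biostrings::AAStringSet(c(P1 = "KAKAKAKAK"))
  s1 <- makeSites(protein_id = "P1", position = 5L)
  dd1 <- disorderDistributions(s1, p1, ResidueAnnotation(a))
  expect_equal(median(dd1$sumo_scores), 0.5)
  expect_equal(median(dd1$other_scores), 0.5)
})
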