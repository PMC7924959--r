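test_that("the generator is deterministic given its seed", {
  cfg <- simulationConfig(n_proteins = 15, length_range = c(80, 160),
                          seed = 99)
  a <- simulateStudy(cfg)
  b <- simulateStudy(cfg)
  expect_identical(as.character(a$sequences), as.character(b$sequences))
  expect_identical(a$truth$sites, b$truth$sites)
  expect_identical(assay(a$sites, "intensity"), assay(b$sites, "intensity"))
  expect_identical(annotationTable(a$annotation),
                   annotationTable(b$annotation))
})

test_that("every planted site lies on a lysine with a window centered on it", {
  study <- simulateStudy(simulationConfig(n_proteins = 30, seed = 5))
  tr <- study$truth$sites
  seqs <- as.character(study$sequences)
  centers <- substring(seqs[tr$protein_id], tr$position, tr$position)
  expect_true(all(centers == "K"))
  clean <- filterSites(study$sites)
  expect_identical(classifySite(sequenceWindows(clean)), tr$motif)
})

test_that("with no planted enrichment, sites are placed independent of disorder", {
  n_dis <- 0
  n_ord <- 0
  s_dis <- 0
  s_ord <- 0
  for (seed in 1:10) {
    cfg <- simulationConfig(n_proteins = 60, disorder_enrichment = 1,
                            cluster_prob = 0, seed = seed)
    out <- simulateProteome(cfg)
    ann <- as.data.frame(annotationTable(out$annotation))
    mask <- ann$long_disorder | ann$short_disorder_score >= 0.5
    lys <- lysinePositions(out$proteins)
    key <- paste(ann$protein_id, ann$position)
    kkey <- paste(rep(names(lys), lengths(lys)), unlist(lys))
    k_dis <- mask[match(kkey, key)]
    skey <- paste(out$truth$sites$protein_id, out$truth$sites$position)
    is_site <- kkey %in% skey
    n_dis <- n_dis + sum(k_dis)
    n_ord <- n_ord + sum(!k_dis)
    s_dis <- s_dis + sum(is_site & k_dis)
    s_ord <- s_ord + sum(is_site & !k_dis)
  }
  p_dis <- s_dis / n_dis
  p_ord <- s_ord / n_ord
  p <- (s_dis + s_ord) / (n_dis + n_ord)
  se <- sqrt(p * (1 - p) * (1 / n_dis + 1 / n_ord))
  expect_lt(abs(p_dis - p_ord), 3 * se)
})

test_that("planted clustering packs adjacent sites inside the cluster window", {
  below <- 0
  total <- 0
  for (seed in 1:10) {
    cfg <- simulationConfig(n_proteins = 40, cluster_prob = 0.6,
                            cluster_window = 5, seed = seed)
    out <- simulateProteome(cfg)
    sp <- split(out$truth$sites$position, out$truth$sites$protein_id)
    gaps <- unlist(lapply(sp[lengths(sp) >= 2],
                          function(p) diff(sort(p))))
    below <- below + sum(gaps < 5)
    total <- total + length(gaps)
  }
  expect_gte(below / total, 0.5)
})

test_that("generated motif composition follows the configured mix", {
  motifs <- character(0)
  for (seed in 16:20) {
    cfg <- simulationConfig(n_proteins = 250, seed = seed)
    motifs <- c(motifs, simulateProteome(cfg)$truth$sites$motif)
  }
  n <- length(motifs)
  expect_gte(n, 2000)
  mix <- simulationConfig()$motif_mix
  for (cat in MOTIF_CATEGORIES) {
    target <- mix[[cat]]
    got <- mean(motifs == cat)
    ci <- 2.576 * sqrt(target * (1 - target) / n)
    expect_lt(abs(got - target), max(ci, 3 / n))
  }
})

test_that("the intensity model honors its closed-form special cases", {
  ## zero steepness: every observation missing with probability 1/2
  cfg0 <- simulationConfig(mnar_steepness = 0, seed = 3)
  sim <- simulateIntensities(rep("flat", 500), cfg0, seed = 3)
  miss <- mean(is.na(sim$intensities))
  expect_lt(abs(miss - 0.5), 3 * sqrt(0.25 / length(sim$intensities)))

  ## flat class without noise: constant latent profile per row
  cfgF <- simulationConfig(noise_cv = 0, seed = 4)
  simF <- simulateIntensities(rep("flat", 20), cfgF, seed = 4)
  expect_true(all(apply(simF$latent, 1, function(r) diff(range(r)) == 0)))
})

test_that("missingness decreases with latent intensity (MNAR)", {
  cfg <- simulationConfig(seed = 12)
  sim <- simulateIntensities(
    sample(c("rising", "falling", "flat"), 5000, replace = TRUE),
    cfg, seed = 12
  )
  x <- as.vector(sim$latent)
  y <- as.integer(is.na(as.vector(sim$intensities)))
  fit <- suppressWarnings(glm(y ~ x, family = binomial()))
  slope <- coef(fit)[["x"]]
  expect_lt(slope, 0)
  ## the fitted slope is the negative of the configured steepness
  expect_lt(abs(-slope - cfg$mnar_steepness), 0.2 * cfg$mnar_steepness)
})
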