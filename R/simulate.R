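## Synthetic study generator.
##
## Emits a synthetic proteome with planted SUMOylation sites whose
## statistical structure mirrors what the downstream analyses assume:
## a controlled consensus-motif composition, enrichment of sites in
## intrinsically disordered regions, clustering of sites along the
## backbone, temporal intensity profiles drawn from shape classes, and
## intensity-dependent (missing-not-at-random) missingness.

#' Configuration of the synthetic study generator
#'
#' Returns a validated configuration list. The defaults describe a
#' triplicate six-timepoint meiotic time course with site properties in
#' the regime reported for meiotic SUMO proteomes: lysine frequency
#' 0.073, ~40% of residues in disordered segments, sites enriched
#' two-fold per-lysine in disorder, clustered sites (60% of cluster
#' extensions, members less than 5 residues apart), and a motif mix in
#' which only a minority of sites carry the \eqn{\psi}KxE consensus while
#' about half match no motif at all.
#'
#' @param n_proteins number of proteins.
#' @param length_range integer min/max protein length (uniform).
#' @param lysine_freq background lysine frequency.
#' @param site_rate expected sites per 100 lysines (after cluster
#'   extension).
#' @param disorder_enrichment relative per-lysine odds of a disordered
#'   lysine being a seed site (1 = no enrichment).
#' @param cluster_prob probability that a site cluster keeps extending by
#'   one more satellite site.
#' @param cluster_window satellites are placed strictly less than this
#'   many residues from an existing cluster member.
#' @param motif_mix named fractions over the seven motif categories; must
#'   sum to 1.
#' @param timepoints,n_replicates sample design (see [sampleDesign()]).
#' @param profile_classes named mixing weights over the temporal shape
#'   classes `rising`, `falling`, `U`, `peak-mid`, `flat`.
#' @param base_mean,base_sd mean/SD of the latent log2 base intensity.
#' @param profile_amplitude half-range of the class shape offsets (log2
#'   units).
#' @param noise_cv replicate noise SD as a fraction of the absolute base
#'   intensity.
#' @param mnar_steepness,mnar_midpoint missingness model: an observation
#'   with latent log2 intensity x is missing with probability
#'   `plogis(mnar_steepness * (mnar_midpoint - x))`.
#' @param disorder_mean_run,order_mean_run mean lengths (residues) of
#'   disordered/ordered segments.
#' @param decoy_rate,contaminant_rate fractions of extra decoy (reverse)
#'   and contaminant rows added to the emitted site table.
#' @param hydrophobic the \eqn{\psi} set used when stamping motifs.
#' @param seed integer seed; one seed governs the whole study stream.
#' @return A list of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(n_proteins = 300,
                             length_range = c(200, 800),
                             lysine_freq = 0.073,
                             site_rate = 10,
                             disorder_enrichment = 2,
                             cluster_prob = 0.6,
                             cluster_window = 5,
                             motif_mix = c(
                               HYDROPHOBIC_VARIANT = 0.0050,
                               CONSENSUS = 0.1426,
                               REVERSE_CONSENSUS = 0.0323,
                               ACIDIC = 0.1157,
                               REVERSE_ACIDIC = 0.1032,
                               DILYSINE = 0.0755,
                               NONE = 0.5257
                             ),
                             timepoints = MEIOTIC_TIMEPOINTS,
                             n_replicates = 3,
                             profile_classes = c(
                               rising = 0.2, falling = 0.2, U = 0.2,
                               `peak-mid` = 0.2, flat = 0.2
                             ),
                             base_mean = 25, base_sd = 2,
                             profile_amplitude = 2,
                             noise_cv = 0.02,
                             mnar_steepness = 1,
                             mnar_midpoint = 20,
                             disorder_mean_run = 30,
                             order_mean_run = 45,
                             decoy_rate = 0.03,
                             contaminant_rate = 0.02,
                             hydrophobic = DEFAULT_HYDROPHOBIC,
                             seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    n_proteins >= 1,
    length(length_range) == 2, length_range[1] >= 20,
    length_range[1] <= length_range[2],
    lysine_freq > 0, lysine_freq < 1,
    site_rate > 0,
    disorder_enrichment >= 0,
    cluster_prob >= 0, cluster_prob <= 1, cluster_prob < 1,
    cluster_window >= 2,
    noise_cv >= 0
  )
  if (!setequal(names(motif_mix), MOTIF_CATEGORIES)) {
    stop("motif_mix must name all seven motif categories")
  }
  if (any(motif_mix < 0) || abs(sum(motif_mix) - 1) > 1e-9) {
    stop("motif_mix fractions must be non-negative and sum to 1")
  }
  if (!all(names(profile_classes) %in% PROFILE_CLASSES) ||
      any(profile_classes < 0) || sum(profile_classes) <= 0) {
    stop("profile_classes must be non-negative weights over ",
         paste(PROFILE_CLASSES, collapse = ", "))
  }
  class(cfg) <- "SimulationConfig"
  cfg
}

## background residue frequencies: lysine at its stated frequency, the
## remaining mass uniform over the other 19 residues
backgroundFreqs <- function(lysine_freq) {
  p <- rep((1 - lysine_freq) / 19, 20)
  names(p) <- AA_ALPHABET
  p["K"] <- lysine_freq
  p
}

## alternating ordered/disordered segments with geometric lengths
sampleDisorderMask <- function(len, mean_dis, mean_ord) {
  p_start <- mean_dis / (mean_dis + mean_ord)
  state <- runif(1) < p_start
  mask <- logical(0)
  while (length(mask) < len) {
    m <- if (state) mean_dis else mean_ord
    run <- rgeom(1, 1 / m) + 1L
    mask <- c(mask, rep(state, run))
    state <- !state
  }
  mask[seq_len(len)]
}

## ---------------------------------------------------------------------------
## Motif stamping as joint constraint satisfaction
## ---------------------------------------------------------------------------

## A category is encoded as per-offset allowed residue sets chosen so
## that, by the strict-to-loose precedence of classifySite(), a window
## satisfying them is classified as exactly that category regardless of
## the unconstrained positions. Overlapping sites intersect their allowed
## sets, so nearby sites are stamped jointly instead of overwriting each
## other.
categoryConstraints <- function(category, hydrophobic) {
  H <- hydrophobic
  E <- ACIDIC_RESIDUES
  notH <- setdiff(AA_ALPHABET, H)
  notE <- setdiff(AA_ALPHABET, E)
  notK <- setdiff(AA_ALPHABET, "K")
  cons <- switch(category,
    HYDROPHOBIC_VARIANT = list(
      list(`-3` = H, `-2` = H, `-1` = H, `2` = E)
    ),
    CONSENSUS = list(
      list(`-3` = notH, `-1` = H, `2` = E)
    ),
    REVERSE_CONSENSUS = list(
      list(`-2` = E, `1` = H, `2` = notE)
    ),
    ACIDIC = list(
      list(`-2` = notE, `-1` = notH, `2` = E)
    ),
    REVERSE_ACIDIC = list(
      list(`-2` = E, `1` = notH, `2` = notE)
    ),
    DILYSINE = list(
      list(`-2` = notE, `1` = "K", `2` = notE),
      list(`-2` = notE, `-1` = "K", `2` = notE)
    ),
    NONE = list(
      list(`-2` = notE, `-1` = notK, `1` = notK, `2` = notE)
    ),
    stop("unknown motif category: ", sQuote(category))
  )
  cons
}

## Incremental constraint state for one protein. Site categories are
## drawn i.i.d. from the motif mix; a seed site is always planted at its
## chosen lysine (placement never depends on the draw), while a
## satellite takes the first offset inside the cluster window where its
## draw can be stamped. A site whose draw cannot be stamped anywhere
## keeps its natural context ("unstamped"), at a position chosen so that
## no committed neighbor stamp is broken.
newStampState <- function(seq_chars) {
  state <- new.env(parent = emptyenv())
  state$seq <- seq_chars
  state$len <- length(seq_chars)
  state$allowed <- vector("list", length(seq_chars))
  state$center <- logical(length(seq_chars))
  state
}

## first feasible constraint variant of `cat` for a new site at `pos`,
## or NULL (position must be free and able to hold the central K)
feasibleVariant <- function(state, pos, cat, hydrophobic) {
  if (pos < 4L || pos > state$len - 2L || state$center[pos]) return(NULL)
  cur0 <- state$allowed[[pos]]
  if (!is.null(cur0) && !"K" %in% cur0) return(NULL)  # K not insertable
  for (variant in categoryConstraints(cat, hydrophobic)) {
    ok <- TRUE
    for (off_chr in names(variant)) {
      p <- pos + as.integer(off_chr)
      set <- variant[[off_chr]]
      if (state$center[p]) {
        if (!"K" %in% set) { ok <- FALSE; break }
      } else {
        cur <- state$allowed[[p]] %||% AA_ALPHABET
        if (!any(cur %in% set)) { ok <- FALSE; break }
      }
    }
    if (ok) return(variant)
  }
  NULL
}

## commit a site without stamping a motif context: the site keeps
## whatever context surrounds it and is classified post hoc
plantUnstamped <- function(state, pos) {
  state$center[pos] <- TRUE
  state$seq[pos] <- "K"
  state$allowed[pos] <- list(NULL)
  invisible(state)
}

## TRUE when planting a K at `pos` leaves every committed stamp intact
kPermitted <- function(state, pos) {
  is.null(state$allowed[[pos]]) || "K" %in% state$allowed[[pos]]
}

placeSite <- function(state, pos, variant) {
  state$center[pos] <- TRUE
  state$seq[pos] <- "K"
  state$allowed[pos] <- list(NULL)
  for (off_chr in names(variant)) {
    p <- pos + as.integer(off_chr)
    if (state$center[p]) next
    cur <- state$allowed[[p]] %||% AA_ALPHABET
    state$allowed[p] <- list(intersect(cur, variant[[off_chr]]))
  }
  invisible(state)
}

## sample concrete letters for all constrained non-center positions,
## weighted by the background residue frequencies
materializeStamps <- function(state, bg) {
  for (pos in which(!vapply(state$allowed, is.null, logical(1)))) {
    if (state$center[pos]) next
    set <- state$allowed[[pos]]
    w <- bg[set]
    state$seq[pos] <- if (length(set) == 1) set else
      sample(set, 1, prob = w / sum(w))
  }
  state$seq
}

## ---------------------------------------------------------------------------
## Proteome simulation
## ---------------------------------------------------------------------------

#' Simulate a proteome with planted SUMOylation sites
#'
#' Draws i.i.d. protein sequences at the configured lysine frequency,
#' lays down alternating ordered/disordered segments, plants seed sites
#' on lysines with per-lysine odds raised by `disorder_enrichment` in
#' disordered segments, extends clusters by chained satellite placement
#' (each extension with probability `cluster_prob`, strictly less than
#' `cluster_window` residues from an existing member; a satellite
#' converts its residue to lysine when none is available), and stamps the
#' local -3..+2 context of every site to realize its assigned motif
#' category (see the package vignette for the joint stamping scheme).
#' Per-residue annotation tracks consistent with the disorder mask are
#' generated alongside. Deterministic given the seed.
#'
#' @param config a [simulationConfig()].
#' @param seed integer seed; defaults to `config$seed`. `NULL` continues
#'   the caller's RNG stream (used internally by [simulateStudy()]).
#' @return A list with `proteins` ([Biostrings::AAStringSet]),
#'   `annotation` ([ResidueAnnotation]), and `truth` — a list holding
#'   `sites` (data.frame `protein_id`, `position`, `motif`,
#'   `profile_class`, `in_disorder`), `disorder_runs` (per-protein run
#'   table) and bookkeeping counts.
#' @export
simulateProteome <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "SimulationConfig"))
  withSeed(seed, {
    bg <- backgroundFreqs(config$lysine_freq)
    lens <- sample(seq(config$length_range[1], config$length_range[2]),
                   config$n_proteins, replace = TRUE)
    prot_ids <- sprintf("SYN%04d", seq_len(config$n_proteins))

    seqs <- character(config$n_proteins)
    ann_rows <- vector("list", config$n_proteins)
    truth_sites <- vector("list", config$n_proteins)
    disorder_runs <- vector("list", config$n_proteins)

    ## seed-site rate chosen so the expected final rate (seeds plus a
    ## geometric number of satellites per seed) matches site_rate
    seed_rate <- (config$site_rate / 100) * (1 - config$cluster_prob)
    e <- config$disorder_enrichment
    ## normalize weights so the mean per-lysine seed probability is
    ## seed_rate at ~40% disordered lysines
    p_dis <- config$disorder_mean_run /
      (config$disorder_mean_run + config$order_mean_run)
    mean_w <- 1 + (e - 1) * p_dis

    for (i in seq_len(config$n_proteins)) {
      len <- lens[i]
      s <- sample(AA_ALPHABET, len, replace = TRUE, prob = bg)
      mask <- sampleDisorderMask(len, config$disorder_mean_run,
                                 config$order_mean_run)

      ## Seed sites: lysines with full -3..+2 context, Bernoulli with
      ## disorder-dependent odds. A selected seed is ALWAYS planted, so
      ## the spatial placement model never depends on the motif draw;
      ## when its drawn category cannot be stamped next to an
      ## already-committed neighbor (rare) the site keeps its natural
      ## context and its realized category is re-read below.
      cand <- which(s == "K")
      cand <- cand[cand >= 4 & cand <= len - 2]
      w <- 1 + (e - 1) * mask[cand]
      p_site <- pmin(1, seed_rate * w / mean_w)
      seeds <- cand[runif(length(cand)) < p_site]

      shuffle <- function(x) if (length(x) <= 1) x else sample(x)
      state <- newStampState(s)
      mix <- config$motif_mix
      site_pos <- integer(0)
      offs <- setdiff(seq(-(config$cluster_window - 1),
                          config$cluster_window - 1), 0)
      for (seed_pos in seeds) {
        cat_i <- sample(names(mix), 1, prob = mix)
        v <- feasibleVariant(state, seed_pos, cat_i, config$hydrophobic)
        if (is.null(v)) {
          plantUnstamped(state, seed_pos)
        } else {
          placeSite(state, seed_pos, v)
        }
        site_pos <- c(site_pos, seed_pos)
        ## chained cluster extension: keep spawning satellites with
        ## probability cluster_prob, each strictly within cluster_window
        ## of an existing member (converting a residue to K if needed);
        ## a satellite prefers an offset where its draw is stampable
        cluster <- seed_pos
        while (config$cluster_prob > 0 &&
               runif(1) < config$cluster_prob && length(cluster) < 50) {
          cat_s <- sample(names(mix), 1, prob = mix)
          cand_pos <- unique(as.vector(outer(cluster, offs, "+")))
          cand_pos <- cand_pos[cand_pos >= 4 & cand_pos <= len - 2]
          cand_pos <- cand_pos[!state$center[cand_pos]]
          if (length(cand_pos) == 0) break
          is_k <- state$seq[cand_pos] == "K"
          ordered <- c(shuffle(cand_pos[is_k]), shuffle(cand_pos[!is_k]))
          placed_pos <- NA_integer_
          for (p in ordered) {
            v <- feasibleVariant(state, p, cat_s, config$hydrophobic)
            if (!is.null(v)) {
              placeSite(state, p, v)
              placed_pos <- p
              break
            }
          }
          if (is.na(placed_pos)) {
            ## no stampable offset: plant unstamped at an offset that
            ## breaks no committed neighbor stamp
            safe <- ordered[vapply(ordered, function(p)
              kPermitted(state, p), logical(1))]
            if (length(safe) == 0) break
            placed_pos <- safe[1]
            plantUnstamped(state, placed_pos)
          }
          cluster <- c(cluster, placed_pos)
          site_pos <- c(site_pos, placed_pos)
        }
      }
      sites <- sort(site_pos)
      s <- materializeStamps(state, bg)
      ## ground truth records the REALIZED category of each emitted
      ## window; it deviates from the drawn mix only at rare stamping
      ## clashes between close neighbors
      cats <- if (length(sites) > 0) {
        vapply(sites, function(p) {
          classifySite(sequenceWindowAt(s, p, hw = 3L),
                       hydrophobic = config$hydrophobic)
        }, character(1))
      } else {
        character(0)
      }

      seqs[i] <- paste(s, collapse = "")
      r <- rle(mask)
      ends <- cumsum(r$lengths)
      disorder_runs[[i]] <- data.frame(
        protein_id = prot_ids[i],
        start = ends - r$lengths + 1L,
        end = ends,
        disordered = r$values
      )

      ## annotation tracks consistent with the planted disorder mask
      run_len <- rep(r$lengths, r$lengths)
      long_dis <- mask & run_len >= config$disorder_mean_run
      score <- ifelse(mask, 0.5 + 0.5 * runif(len), 0.5 * runif(len))
      buried <- !mask & runif(len) < 0.4
      cc <- logical(len)
      if (runif(1) < 0.15 && len > 60) {
        cc_len <- min(len, 20 + rgeom(1, 1 / 40))
        cc_start <- sample.int(len - cc_len + 1, 1)
        cc[seq(cc_start, cc_start + cc_len - 1)] <- TRUE
      }
      tm <- logical(len)
      if (runif(1) < 0.05 && len > 50) {
        for (k in seq_len(sample(1:2, 1))) {
          tm_start <- sample.int(len - 20, 1)
          tm[seq(tm_start, tm_start + 20)] <- TRUE
        }
      }
      ann_rows[[i]] <- data.frame(
        protein_id = prot_ids[i],
        position = seq_len(len),
        globular = !mask,
        long_disorder = long_dis,
        short_disorder_score = score,
        exposed = !buried,
        buried = buried,
        coiled_coil = cc,
        transmembrane = tm
      )

      if (length(sites) > 0) {
        wts <- config$profile_classes
        truth_sites[[i]] <- data.frame(
          protein_id = prot_ids[i],
          position = sites,
          motif = cats,
          profile_class = sample(names(wts), length(sites),
                                 replace = TRUE, prob = wts),
          in_disorder = mask[sites]
        )
      }
    }

    proteins <- AAStringSet(seqs)
    names(proteins) <- prot_ids
    truth <- list(
      sites = do.call(rbind, truth_sites) %||%
        data.frame(protein_id = character(0), position = integer(0),
                   motif = character(0), profile_class = character(0),
                   in_disorder = logical(0)),
      disorder_runs = do.call(rbind, disorder_runs),
      protein_lengths = setNames(as.integer(lens), prot_ids)
    )
    rownames(truth$sites) <- NULL
    list(
      proteins = proteins,
      annotation = ResidueAnnotation(do.call(rbind, ann_rows)),
      truth = truth
    )
  })
}

## ---------------------------------------------------------------------------
## Intensity simulation
## ---------------------------------------------------------------------------

## shape offset (in [-1, 1]) of each class across n timepoints
profileShape <- function(class, n_timepoints) {
  t <- seq(-1, 1, length.out = n_timepoints)
  switch(class,
    rising = t,
    falling = -t,
    U = 2 * t^2 - 1,
    `peak-mid` = 1 - 2 * t^2,
    flat = rep(0, n_timepoints),
    stop("unknown profile class: ", sQuote(class))
  )
}

#' Simulate per-sample LFQ intensities for profiled rows
#'
#' Each row gets a latent log2 intensity
#' `base + amplitude * shape(class)[timepoint] + N(0, (noise_cv * |base|)^2)`
#' per replicate, with `base ~ N(base_mean, base_sd^2)`. The observed
#' linear intensity is missing with probability
#' `plogis(mnar_steepness * (mnar_midpoint - x))` at latent log2
#' intensity `x`, so low-abundance measurements are preferentially
#' missing (MNAR). Deterministic given the seed.
#'
#' @param classes character vector of profile classes, one per row,
#'   optionally named by row id.
#' @param config a [simulationConfig()].
#' @param seed integer seed; defaults to `config$seed`; `NULL` continues
#'   the current stream.
#' @return A list with `intensities` (rows x samples linear-scale matrix,
#'   `NA` = missing), `latent` (log2 matrix before missingness) and
#'   `base` (per-row latent base).
#' @export
simulateIntensities <- function(classes, config, seed = config$seed) {
  stopifnot(inherits(config, "SimulationConfig"))
  withSeed(seed, {
    design <- sampleDesign(config$timepoints, config$n_replicates)
    n <- length(classes)
    ids <- names(classes) %||% sprintf("row%05d", seq_len(n))
    n_tp <- length(config$timepoints)
    shapes <- vapply(as.character(classes), profileShape,
                     numeric(n_tp), n_timepoints = n_tp)
    ## shapes: n_tp x n
    base <- rnorm(n, config$base_mean, config$base_sd)
    tp_idx <- as.integer(design$timepoint)
    latent <- matrix(NA_real_, n, nrow(design),
                     dimnames = list(ids, rownames(design)))
    for (j in seq_len(nrow(design))) {
      mu <- base + config$profile_amplitude * shapes[tp_idx[j], ]
      latent[, j] <- mu + rnorm(n, 0, config$noise_cv * abs(base))
    }
    p_miss <- plogis(config$mnar_steepness *
                       (config$mnar_midpoint - latent))
    obs <- 2^latent
    obs[matrix(runif(length(latent)), n) < p_miss] <- NA_real_
    list(intensities = obs, latent = latent, base = base)
  })
}

## ---------------------------------------------------------------------------
## Whole-study assembly
## ---------------------------------------------------------------------------

## sequence window of half-width hw around pos, padded with "_"
sequenceWindowAt <- function(seq_chars, pos, hw = 15) {
  padded <- c(rep("_", hw), seq_chars, rep("_", hw))
  paste(padded[seq(pos, pos + 2 * hw)], collapse = "")
}

#' Simulate a complete synthetic SUMO-proteomics study
#'
#' Runs [simulateProteome()] and [simulateIntensities()] under a single
#' RNG stream seeded once from `config$seed`, and assembles the results
#' into the package's standard containers: a [SumoSiteSet] (including a
#' small fraction of decoy and contaminant rows, as a real MaxQuant site
#' table would contain), a protein-level LFQ `SummarizedExperiment`, the
#' protein sequences, the per-residue annotation and the ground-truth
#' record.
#'
#' @param config a [simulationConfig()].
#' @return A list of class `"SumoStudy"` with elements `sites`,
#'   `proteins` (LFQ `SummarizedExperiment`), `sequences`
#'   ([Biostrings::AAStringSet]), `annotation`, `design`, `truth`,
#'   `config`.
#' @export
simulateStudy <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  withSeed(config$seed, {
    prot <- simulateProteome(config, seed = NULL)
    design <- sampleDesign(config$timepoints, config$n_replicates)
    truth <- prot$truth
    sites <- truth$sites
    n_sites <- nrow(sites)

    site_int <- simulateIntensities(
      setNames(sites$profile_class,
               paste0(sites$protein_id, "_K", sites$position)),
      config, seed = NULL
    )

    ## localization probabilities: most sites confidently localized, a
    ## minority ambiguous (typically between adjacent lysines)
    hi <- runif(n_sites) < 0.77
    loc <- ifelse(hi, runif(n_sites, 0.96, 1), runif(n_sites, 0.3, 0.96))

    seq_chars <- strsplit(as.character(prot$proteins), "")
    names(seq_chars) <- names(prot$proteins)
    windows <- vapply(seq_len(n_sites), function(i) {
      sequenceWindowAt(seq_chars[[sites$protein_id[i]]], sites$position[i])
    }, character(1))

    ## decoy and contaminant rows on top of the true sites
    n_rev <- round(config$decoy_rate * n_sites)
    n_con <- round(config$contaminant_rate * n_sites)
    n_junk <- n_rev + n_con
    junk_windows <- vapply(seq_len(n_junk), function(i) {
      paste(c(sample(AA_ALPHABET, 15, TRUE, prob = backgroundFreqs(
        config$lysine_freq)), "K",
        sample(AA_ALPHABET, 15, TRUE, prob = backgroundFreqs(
          config$lysine_freq))), collapse = "")
    }, character(1))
    junk_int <- matrix(NA_real_, n_junk, nrow(design))
    if (n_junk > 0) {
      obs <- matrix(runif(n_junk * nrow(design)) < 0.3, n_junk)
      junk_int[obs] <- 2^rnorm(sum(obs), config$base_mean, config$base_sd)
    }

    all_int <- rbind(site_int$intensities, junk_int)
    colnames(all_int) <- rownames(design)
    sset <- SumoSiteSet(
      protein_id = c(sites$protein_id,
                     if (n_rev > 0) sprintf("REV__SYN%04d", seq_len(n_rev)),
                     if (n_con > 0) sprintf("CON__%04d", seq_len(n_con))),
      position = c(sites$position, rep(16L, n_junk)),
      localization_prob = c(loc, runif(n_junk)),
      sequence_window = c(windows, junk_windows),
      intensities = all_int,
      design = design,
      reverse = c(rep(FALSE, n_sites), rep(TRUE, n_rev),
                  rep(FALSE, n_con)),
      contaminant = c(rep(FALSE, n_sites), rep(FALSE, n_rev),
                      rep(TRUE, n_con))
    )

    ## protein-level LFQ with per-protein profile classes
    prot_ids <- names(prot$proteins)
    wts <- config$profile_classes
    prot_class <- setNames(
      sample(names(wts), length(prot_ids), replace = TRUE, prob = wts),
      prot_ids
    )
    prot_int <- simulateIntensities(prot_class, config, seed = NULL)
    pset <- SummarizedExperiment(
      assays = SimpleList(lfq = prot_int$intensities),
      rowData = DataFrame(protein_id = prot_ids, row.names = prot_ids),
      colData = design
    )

    truth$localization_prob <- loc
    truth$site_latent <- site_int$latent
    truth$protein_class <- prot_class
    out <- list(
      sites = sset, proteins = pset, sequences = prot$proteins,
      annotation = prot$annotation, design = design,
      truth = truth, config = config
    )
    class(out) <- "SumoStudy"
    out
  })
}

#' Write a synthetic study to disk in the package's exchange formats
#'
#' Emits the MaxQuant-style site table, the protein LFQ table, the
#' sequences as FASTA, the per-residue annotation TSV, the sample design
#' TSV and the ground truth as JSON. All files are re-readable with the
#' corresponding `read*` functions.
#'
#' @param study a `"SumoStudy"` from [simulateStudy()].
#' @param outdir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
writeStudy <- function(study, outdir) {
  stopifnot(inherits(study, "SumoStudy"))
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(outdir)) {
      stop("cannot create output directory ", sQuote(outdir))
    }
  }
  paths <- c(
    sites = file.path(outdir, "glygly_sites.tsv"),
    proteins = file.path(outdir, "protein_groups.tsv"),
    fasta = file.path(outdir, "proteome.fasta"),
    annotation = file.path(outdir, "annotation.tsv"),
    design = file.path(outdir, "design.tsv"),
    truth = file.path(outdir, "ground_truth.json")
  )
  writeSitesTable(study$sites, paths["sites"])
  writeProteinTable(study$proteins, paths["proteins"])
  writeFasta(study$sequences, paths["fasta"])
  writeAnnotationTable(study$annotation, paths["annotation"])
  writeDesignTable(study$design, paths["design"])
  truth <- study$truth
  truth$site_latent <- NULL  # large matrix; the tables carry the data
  jsonlite::write_json(truth, paths["truth"], dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
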