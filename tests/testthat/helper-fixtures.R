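## Fixture builders and independent oracle implementations used across
## the suite. Oracles are deliberately written in a different style
## (regexes, explicit loops) from the package code they check.

suppressPackageStartupMessages({
  library(SummarizedExperiment)
  library(Biostrings)
})

tinyDesign <- function(timepoints = c("t1", "t2"), n_replicates = 3) {
  sampleDesign(timepoints = timepoints, n_replicates = n_replicates)
}

## a SumoSiteSet built directly from vectors, with sane defaults
makeSites <- function(protein_id, position,
                      localization_prob = rep(0.99, length(position)),
                      sequence_window = NULL,
                      design = tinyDesign(),
                      intensities = NULL,
                      reverse = FALSE, contaminant = FALSE) {
  n <- length(position)
  if (is.null(sequence_window)) {
    sequence_window <- rep(paste0(strrep("A", 15), "K", strrep("A", 15)), n)
  }
  if (is.null(intensities)) {
    intensities <- matrix(1e7, nrow = n, ncol = nrow(design),
                          dimnames = list(NULL, rownames(design)))
  }
  SumoSiteSet(protein_id = protein_id, position = position,
              localization_prob = localization_prob,
              sequence_window = sequence_window,
              intensities = intensities, design = design,
              reverse = reverse, contaminant = contaminant)
}

## sequences with lysines planted at given positions (elsewhere alanine)
makeProteins <- function(lys, lengths) {
  seqs <- mapply(function(k, len) {
    s <- rep("A", len)
    s[k] <- "K"
    paste(s, collapse = "")
  }, lys, lengths)
  out <- AAStringSet(unname(seqs))
  names(out) <- names(lys)
  out
}

## ---------------------------------------------------------------------
## Independent motif oracle: first-match regex over the -3..+2 context
## ---------------------------------------------------------------------
oracleClassify <- function(windows, hydrophobic = c("I", "L", "V", "M", "F")) {
  hcls <- paste0("[", paste(hydrophobic, collapse = ""), "]")
  ctx <- function(w, off) {
    wl <- nchar(w)
    i <- (wl + 1) %/% 2 + off
    ifelse(i < 1 | i > wl, "_", substr(w, i, i))
  }
  str6 <- paste0(ctx(windows, -3), ctx(windows, -2), ctx(windows, -1),
                 "K", ctx(windows, 1), ctx(windows, 2))
  pats <- c(
    HYDROPHOBIC_VARIANT = paste0("^", hcls, hcls, hcls, "K.[ED]$"),
    CONSENSUS = paste0("^..", hcls, "K.[ED]$"),
    REVERSE_CONSENSUS = paste0("^.[ED].K", hcls, ".$"),
    ACIDIC = "^...K.[ED]$",
    REVERSE_ACIDIC = "^.[ED].K..$",
    DILYSINE = "^..KK..$|^...KK.$"
  )
  out <- rep("NONE", length(windows))
  for (i in seq_along(windows)) {
    for (cat in names(pats)) {
      if (grepl(pats[[cat]], str6[i])) {
        out[i] <- cat
        break
      }
    }
  }
  out
}

randomWindows <- function(n, half_width = 3, pad_prob = 0.05) {
  chars <- c(sumoscape::AA_ALPHABET, "_")
  probs <- c(rep((1 - pad_prob) / 20, 20), pad_prob)
  vapply(seq_len(n), function(i) {
    left <- sample(chars, half_width, replace = TRUE, prob = probs)
    right <- sample(chars, half_width, replace = TRUE, prob = probs)
    paste(c(left, "K", right), collapse = "")
  }, character(1))
}

## ---------------------------------------------------------------------
## Brute-force O(n^2) distance-curve oracle
## ---------------------------------------------------------------------
bruteDistanceCurve <- function(lys_list, site_list, reference,
                               bin_width = 10) {
  rnd <- function(d) bin_width * floor(d / bin_width + 0.5)
  tal <- list()
  for (p in names(site_list)) {
    if (length(site_list[[p]]) == 0) next
    k <- lys_list[[p]]
    if (length(k) < 2) next
    anchors <- if (reference == "FROM_SUMO_K") {
      k[k %in% site_list[[p]]]
    } else {
      k
    }
    for (a in anchors) {
      for (o in k) {
        if (o == a) next
        b <- as.character(rnd(abs(o - a)))
        cur <- tal[[b]]
        if (is.null(cur)) cur <- c(0, 0)
        tal[[b]] <- cur + c(1, as.integer(o %in% site_list[[p]]))
      }
    }
  }
  bins <- sort(as.numeric(names(tal)))
  data.frame(
    bin = bins,
    n_pairs = vapply(as.character(bins), function(b) tal[[b]][1], 0),
    n_sumo = vapply(as.character(bins), function(b) tal[[b]][2], 0),
    row.names = NULL
  )
}

## ---------------------------------------------------------------------
## Brute-force per-residue structure-class re-derivation
## ---------------------------------------------------------------------
bruteClasses <- function(ann_df, threshold = 0.5, window = 100) {
  out <- list()
  for (p in unique(ann_df$protein_id)) {
    a <- ann_df[ann_df$protein_id == p, ]
    a <- a[order(a$position), ]
    len <- nrow(a)
    for (i in seq_len(len)) {
      short <- a$short_disorder_score[i] >= threshold
      dis <- (a$long_disorder[i] || short) && !a$globular[i]
      dnc <- dis && !a$coiled_coil[i]
      ## does the disordered run containing i touch a terminus?
      dterm <- FALSE
      if (dis) {
        disv <- (a$long_disorder | a$short_disorder_score >= threshold) &
          !a$globular
        lo <- i
        while (lo > 1 && disv[lo - 1]) lo <- lo - 1
        hi <- i
        while (hi < len && disv[hi + 1]) hi <- hi + 1
        dterm <- lo == 1 || hi == len
      }
      out[[length(out) + 1]] <- data.frame(
        protein_id = p, position = a$position[i],
        GLOBULAR = a$globular[i], LONG_DISORDER = a$long_disorder[i],
        SHORT_DISORDER = short, DISORDERED = dis,
        GLOBULAR_EXPOSED = a$globular[i] && a$exposed[i],
        GLOBULAR_BURIED = a$globular[i] && a$buried[i],
        COILED_COIL = a$coiled_coil[i],
        TRANSMEMBRANE = a$transmembrane[i],
        DISORDERED_NOT_CC = dnc,
        DISORDERED_TERMINUS = dterm,
        DISORDER_NEAR_TERMINUS = dnc && min(i - 1, len - i) < window
      )
    }
  }
  do.call(rbind, out)
}
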