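---
title: "Analysing SUMO-modified proteomes with sumoscape"
author: "sumoscape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing SUMO-modified proteomes with sumoscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sumoscape)
```

# The problem

SUMO (Small Ubiquitin-like MOdifier) is conjugated to lysine side chains
of target proteins. Di-glycine (K-&epsilon;-GG) remnant proteomics maps
the conjugated lysines at residue resolution: after protease digestion,
each formerly modified lysine carries a Gly-Gly stub whose mass signature
MaxQuant-class search engines localize to a specific residue with a
*localization probability*. Combined with label-free quantification (LFQ)
over a synchronized time course — here the six meiotic stages G0 (pre-meiotic),
S (S-phase), DSB (double-strand-break formation), SI (strand invasion),
dHJ (double-Holliday junction / pachytene) and CO (crossover formation),
each in triplicate — this yields a site-by-sample intensity table whose
downstream analysis this package implements:

* filtering decoy and contaminant matches, and applying a localization
  cutoff;
* classifying each site into SUMO consensus-motif categories;
* quantifying how sites cluster along the protein backbone;
* measuring enrichment or depletion of sites across structural contexts
  (intrinsic disorder, solvent accessibility, coiled coils,
  transmembrane segments);
* the quantitative pipeline from raw per-sample intensities to
  hierarchically clustered temporal profiles;
* a synthetic-data generator that emulates the statistical structure of
  such an experiment with known ground truth, used throughout the test
  suite to validate every analysis by parameter recovery.

# Data model

`SumoSiteSet` extends `SummarizedExperiment`: one row per site, one
column per MS sample, a single `"intensity"` assay (linear scale, `NA`
for missing), per-site metadata (`protein_id`, 1-based `position`,
`localization_prob`, `sequence_window` centered on the modified K and
padded with `_` past termini, decoy/contaminant flags) and the sample
design (`timepoint`, `replicate`) as column metadata. Sequences travel
as a `Biostrings::AAStringSet`; per-residue predictor tracks as a
`ResidueAnnotation`; matrices moving through the quantitative pipeline
as `ProfileMatrix` objects tagged with an explicit processing state.
All coordinates are 1-based (the MaxQuant convention).

# Filtering

`filterSites()` drops rows flagged as reverse (decoy) or potential
contaminant — the standard first step of Perseus-style processing — and
optionally applies an inclusive localization-probability cutoff. The
conventional high-confidence cutoff for this kind of data is 0.96;
it is a parameter, not a constant, because lower-confidence sites
frequently reflect ambiguity between adjacent lysines and remain useful
for coarser analyses.

# Motif classification

Each site is assigned to exactly one of seven categories from the
residues at positions $-3..+2$ around the modified K, tested
strict-to-loose so the categories are mutually exclusive and exhaustive:

| order | category | pattern |
|---|---|---|
| 1 | `HYDROPHOBIC_VARIANT` | $\psi\psi\psi$-K-x-E/D |
| 2 | `CONSENSUS` | $\psi$-K-x-E/D |
| 3 | `REVERSE_CONSENSUS` | E/D-x-K-$\psi$ |
| 4 | `ACIDIC` | K-x-E/D |
| 5 | `REVERSE_ACIDIC` | E/D-x-K |
| 6 | `DILYSINE` | K adjacent to the modified K (either flank) |
| 7 | `NONE` | anything else |

Design choices worth stating explicitly:

* The large-hydrophobic set $\psi$ defaults to I, L, V, M, F — the
  standard reading in the $\psi$KxE literature — and is exposed as a
  parameter because reported category percentages depend on it.
* Precedence makes the stricter pattern win: a window matching
  $\psi\psi\psi$-K-x-E/D is *not* also counted as consensus, and the
  partial-acidic categories exclude full-consensus windows.
* Only positions $-3..+2$ are consulted; the pad character `_` never
  matches any class, so windows truncated by a terminus can only fall
  into looser categories.
* `DILYSINE` checks both flanks; adjacency is read symmetrically.

The classifier is validated against an independently written first-match
regular-expression oracle on random windows (exact agreement required).

# Site topology

`adjacentSpacing()` pools, across proteins, the successive differences
of sorted site positions; `spacingFractionBelow(sites, 5)` is the
probability that adjacent sites lie less than five residues apart. The
pooled (pair-weighted) form is the default; a per-protein-averaged
variant is available (`pooled = FALSE`) because the two conventions
differ on skewed site counts.

`distanceCurve()` computes, for every anchor (each SUMOylated lysine, or
each lysine), the distance to every *other* lysine of the same protein,
bins distances to the nearest 10 residues, and reports per bin the
fraction of partner lysines that are themselves sites. Conventions:

* Rounding is half-away-from-zero (distance 5 &rarr; bin 10), so bin 0
  holds distances 1-4 and bin 10 distances 5-14; a half-even mode is
  available since the convention is not canonical.
* Anchors never pair with themselves; pairs are pooled pair-weighted.
* Only proteins with at least one identified site participate. This
  restriction makes the any-lysine baseline sit slightly *above* the
  site-anchored curve under random placement (excluding zero-site
  proteins inflates the apparent per-lysine rate), which is why
  clustering is judged against the `FROM_ANY_K` baseline, not against a
  naive global rate.
* When the site-anchored curve is tested for flatness under a null
  simulation, the binomial standard error of a bin is computed on the
  number of *distinct unordered* pairs (half the ordered count): a
  site-site pair enters the curve from both anchors, and treating the
  doubled count as binomial would understate the standard error by
  about $\sqrt{2}$ and fail the null systematically.

A brute-force $O(n^2)$ re-computation on small proteins serves as the
oracle for the optimized implementation.

# Structural context

Upstream predictors are *not* run by this package. Per-residue tracks in
the style of IUPred (globular domains, long disorder, continuous short-
disorder score), ACCpro (exposed/buried), ncoils and HMMTOP arrive via a
defined TSV and are combined by `deriveClasses()`:

* `SHORT_DISORDER` binarizes the continuous score at 0.5 (IUPred's
  conventional decision boundary; configurable).
* `DISORDERED` = (long or short disorder) and not globular.
* `DISORDERED_TERMINUS` flags disordered *regions* that extend to a
  terminus (the region-touches-terminus reading; a residue-is-terminal
  mode exists because the definition is ambiguous).
* `DISORDER_NEAR_TERMINUS` requires `DISORDERED_NOT_CC` and strict
  distance < 100 residues from the nearest terminus.

`foldEnrichment()` implements the descriptive statistic: the percentage
of sites in a class divided by the percentage of all lysines (in
site-bearing proteins) in that class. Note that this statistic
*compresses toward 1 as the class grows*: if lysines in disorder are
twice as likely to be modified and 40% of lysines are disordered, the
fold-enrichment is $\frac{2p}{2p + (1-p)} / p \approx 1.43$, not 2.
`classRateRatio()` therefore complements it with the between-class rate
ratio (sites-per-lysine inside / outside the class), which directly
estimates the relative modification odds and is the estimator used when
recovering the generator's planted `disorder_enrichment` parameter.
`disorderDistributions()` returns the short-disorder scores of modified
versus unmodified lysines with summary quantiles.

# The quantitative pipeline

States are strictly ordered `RAW` &rarr; `AVERAGED` &rarr; `LOG2` &rarr;
`IMPUTED` &rarr; `ZSCORED`; each operation validates its input state.

* `averageReplicates()`: mean of non-missing replicates per timepoint;
  a timepoint with all replicates missing stays missing.
* `log2Transform()`: elementwise; zero or negative intensities are an
  error (they indicate an upstream problem, not data).
* `imputeDownshift()`: per column with observed mean $m_c$ and SD
  $s_c$, missing cells are drawn from
  $N(m_c - 1.8\,s_c,\ (0.3\,s_c)^2)$. Width 0.3 and downshift 1.8 are
  the Perseus conventions for left-censored LFQ missingness and are
  exposed as parameters. The draw is seeded and deterministic.
* `zscoreRows()`: row mean 0, sample ($n-1$) SD 1; zero-variance rows
  cannot be z-scored and are flagged rather than silently mangled.
* `hierarchicalCluster()`: distance $d(i,j) = 1 - r(i,j)$ (0 identical
  shape, 2 perfect anti-correlation), agglomerative with average
  linkage by default — the common default of matrix-visualization
  tools for correlation distances; the linkage is a parameter.
* `similarityMatrix()` is the complementary correlation matrix
  (symmetric, unit diagonal, equal to one minus the distance matrix).
* `normalizedProfile()` min-max scales an averaged profile to [0,1]
  for display; constant profiles are an error.
* `cumulativeSiteIntensity()` sums observed intensities per site across
  all samples — a readout of relative site usage within a protein —
  with `rankSitesWithin()` for the per-protein ranking.
* `countIdentified()` counts a row at a timepoint when at least one
  replicate holds a valid (positive, non-missing) value; a strict
  all-replicates mode exists because the counting convention is
  ambiguous in the field.

# The synthetic-data generator

`simulateStudy()` produces a complete study — site table with decoy and
contaminant rows, protein LFQ table, FASTA, annotation tracks, design,
and ground truth — under a single seeded RNG stream. What it emulates,
and the defaults chosen (all are `simulationConfig()` parameters, fixed
once as the package's study conditions):

* **Sequences**: i.i.d. residues with lysine frequency 0.073 (the
  budding-yeast proteome average), other residues uniform.
* **Disorder**: alternating ordered/disordered segments with geometric
  lengths (means 45 and 30 residues), giving ~40% disordered residues;
  the continuous short-disorder score is drawn above 0.5 inside
  disordered segments and below outside, so the IUPred-style threshold
  reproduces the mask exactly.
* **Site placement**: each eligible lysine becomes a seed site by an
  independent Bernoulli draw with odds multiplied by
  `disorder_enrichment` (default 2) in disordered segments; each seed
  then extends a cluster by chained satellites, each appearing with
  probability `cluster_prob` (default 0.6) strictly less than
  `cluster_window` (default 5) residues from an existing member,
  converting the residue to lysine when none is available. The defaults
  reproduce the regime reported for meiotic SUMO proteomes, where
  roughly half of adjacent site pairs lie within five residues and
  multi-site clusters span tens of residues. The overall rate is
  `site_rate` sites per 100 lysines (default 10).
* **Motifs**: each site draws its category i.i.d. from `motif_mix`
  (defaults mirror the published proportions: 14.26% consensus, 52.57%
  no motif, etc.). A category is stamped as per-position *allowed
  residue sets* on $-3..+2$; overlapping sites intersect their sets,
  so nearby stamps are satisfied jointly instead of overwriting each
  other, and letters are then sampled from the intersected sets
  weighted by background frequencies. Seeds are always planted
  regardless of the draw (so spatial structure never depends on
  categories); a satellite prefers an offset where its draw is
  stampable and otherwise takes an offset that breaks no committed
  stamp. Ground truth records the category *realized* in the emitted
  window, which deviates from the drawn mix only at rare clashes
  between close neighbors; empirically the realized composition tracks
  the mix within binomial noise.
* **Intensities**: latent log2 intensity = base
  ($N(25, 2^2)$) + class shape ($\pm 2$ log2 units across the six
  timepoints; shapes `rising`, `falling`, `U`, `peak-mid`, `flat`) +
  replicate noise ($SD = 0.02\,|base|$). An observation is missing with
  probability $\mathrm{logit}^{-1}(1 \cdot (20 - x))$ at latent
  intensity $x$: missingness is confined to the low-abundance tail
  (single-digit percent overall), the missing-not-at-random behavior
  that motivates downshifted imputation. The MNAR parameters are a
  stand-in, not calibrated to any particular data set.
* **Localization**: 77% of sites draw a probability in [0.96, 1], the
  rest in [0.3, 0.96), imitating adjacent-lysine ambiguity.

What it deliberately does **not** emulate: real yeast sequence
composition beyond lysine frequency, peptide-level effects (digestion,
missed cleavages, FDR), correlated replicate structure, batch effects,
or the true missingness mechanism of any real experiment. Passing the
recovery tests therefore shows the analyses are correct and well
calibrated on data obeying their assumptions — not that those
assumptions hold in any particular real data set.

# Validation by parameter recovery

The test suite regenerates data and recovers the planted parameters:

* motif mix recovered within binomial 99% confidence at ~5,000 sites;
* planted disorder rate ratio of 2 recovered within 10% at ~50,000
  lysines — with clustering disabled, because satellites are placed by
  *proximity*, not disorder, and so dilute the per-lysine effect (a
  deliberate property of the model, matching locality-driven cluster
  growth);
* distance curves flat within 3 SE of the pooled rate under the null
  and lifted at least two-fold above the any-lysine baseline in bins 0
  and 10 when clustering is planted;
* three planted temporal classes recovered by 1-Pearson average-linkage
  clustering with adjusted Rand index &ge; 0.95 at 300 rows;
* imputation reproduces its downshifted-normal parameters within 3 SE
  at 10,000 imputed cells.

Problem sizes (300-1,400 proteins, lengths 150-800) were chosen so each
experiment carries enough statistical power for the stated tolerances
while the whole suite runs in about a minute on a single CPU.

# Numerical and degenerate-input conventions

One integer seed drives each generator run through a single stream;
identical seeds give byte-identical studies. Imputation takes its own
seed and restores the caller's RNG state. Distance rounding and the
terminus conventions are parameters, documented above. Degenerate
inputs fail loudly and early: empty site sets, proteins without a
second site for spacing, constant rows for normalization, zero-variance
rows for clustering, and out-of-order pipeline states all raise errors
that name the offending object.

# Known limitations

* The published headline counts of a given study can only be reproduced
  with that study's deposited site table, which the user must supply;
  the packaged validation is synthetic.
* The fold-enrichment statistic is descriptive; no significance testing
  of structural enrichment or clustering is provided, mirroring its
  descriptive use in the field.
* The motif stamping scheme guarantees the realized category of almost
  every site, but under very dense clustering a small fraction of sites
  keep their natural context; ground truth always records the realized
  category, so the data and its truth never disagree.
* GPS-SUMO-style SIM prediction, HMMER domain detection and GO
  enrichment are out of scope; their outputs are consumed as interval
  annotations for diagrams when provided.
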