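# sumoscape

Site-level analysis of SUMO-modified proteomes from label-free
quantification (LFQ) time courses.

Di-glycine (K-ε-GG) remnant proteomics maps SUMO-conjugation sites at
residue resolution: MaxQuant-class searches report, per site, the target
protein, the modified lysine's position, a localization probability, a
sequence window and per-sample intensities. `sumoscape` implements the
downstream analysis of such tables for time-resolved experiments — the
package's reference design is a six-stage meiotic time course (G0, S,
DSB, SI, dHJ, CO) in triplicate — for proteomics researchers who want
the standard site-level characterization as tested, reusable functions
rather than spreadsheet steps:

- **Filtering** — decoy (reverse) and contaminant removal, inclusive
  localization-probability cutoff (`filterSites`).
- **Motif classification** — each site is assigned to exactly one of
  seven categories, tested strict-to-loose: ΨΨΨ-K-x-E/D, Ψ-K-x-E/D
  (consensus), E/D-x-K-Ψ (reverse consensus), K-x-E/D (acidic),
  E/D-x-K (reverse acidic), di-lysine, none (Ψ = large hydrophobic,
  default {I,L,V,M,F}) (`classifySite`, `motifComposition`).
- **Site topology** — sites-per-protein distribution, adjacent-site
  spacings (fraction under 5 residues), and distance-resolved
  SUMOylation probability curves: for each anchor (SUMO-K or any K) and
  every other lysine of the protein, the fraction of partners that are
  sites per 10-residue distance bin (`siteCountDistribution`,
  `adjacentSpacing`, `distanceCurve`).
- **Structural context** — composite classes from per-residue predictor
  tracks (IUPred/ACCpro/ncoils/HMMTOP-style input), per-class
  fold-enrichment *(% sites in class) / (% lysines in class)*, the
  complementary between-class rate ratio, and disorder-score
  distributions of modified vs unmodified lysines (`deriveClasses`,
  `foldEnrichment`, `classRateRatio`, `disorderDistributions`).
- **LFQ dynamics** — the pipeline RAW → replicate averaging → log2 →
  per-column downshifted-normal imputation (Perseus-style, width 0.3,
  downshift 1.8) → row z-scoring → hierarchical clustering by
  1 − Pearson correlation with average linkage, plus similarity
  matrices, min-max profiles, cumulative site intensities and
  per-timepoint identification counts.
- **Synthetic studies** — `simulateStudy()` generates a proteome with
  planted motif composition, disorder enrichment, site clusters,
  temporal profile classes and intensity-dependent missingness, plus
  ground truth; every analysis above is validated by recovering the
  planted parameters.
- **Orchestration** — `runPipeline()` executes
  filter → motifs → topology → structure → dynamics from a config list
  or file and writes all result tables, a run log and a JSON summary;
  `buildProteinDiagram()` assembles per-protein site-map track data.

## Worked example

```r
library(sumoscape)

study <- simulateStudy(simulationConfig(n_proteins = 100, seed = 7))
sites <- filterSites(study$sites, min_loc_prob = 0.96)
sites
#> SumoSiteSet with 315 sites on 72 proteins across 18 samples
#> timepoints: G0, S, DSB, SI, dHJ, CO
#> QC: 0 reverse, 0 contaminant (315 clean)

motifComposition(sites)
#>              category count fraction
#> 1 HYDROPHOBIC_VARIANT     1  0.00317
#> 2           CONSENSUS    58  0.18413
#> 3   REVERSE_CONSENSUS    12  0.03810
#> 4              ACIDIC    31  0.09841
#> 5      REVERSE_ACIDIC    37  0.11746
#> 6            DILYSINE    17  0.05397
#> 7                NONE   159  0.50476

spacingFractionBelow(sites, 5)
#> [1] 0.6910112

fe <- foldEnrichment(filterSites(study$sites), study$sequences,
                     deriveClasses(study$annotation))
fe[fe$class %in% c("GLOBULAR", "DISORDERED"), ]
#>        class enrichment n_sumo_k n_all_k
#> 1   GLOBULAR       0.75      176    1825
#> 4 DISORDERED       1.35      224    1286
```

Half of the filtered sites carry no recognizable motif, adjacent sites
sit within five residues of each other about 69% of the time, and sites
are enriched in disordered regions (fold-enrichment 1.35) while depleted
from globular domains (0.75) — the planted structure of the synthetic
study, recovered by the analyses. The intensity matrix flows through the
quantitative pipeline as:

```r
design <- study$design
z <- zscoreRows(imputeDownshift(log2Transform(averageReplicates(
  profileMatrix(sites), design)), seed = 1))
cl <- hierarchicalCluster(z, k = 3)
```

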