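## End-to-end orchestration: filter -> motifs -> topology -> structure ->
## dynamics, with a run log and a machine-readable summary.

## minimal hclust -> Newick serialization (leaf labels, merge heights)
hclustToNewick <- function(tree) {
  lab <- tree$labels %||% as.character(seq_len(nrow(tree$merge) + 1))
  node <- function(i, parent_h) {
    if (i < 0) {
      sprintf("%s:%.6g", lab[-i], parent_h)
    } else {
      h <- tree$height[i]
      sprintf("(%s,%s):%.6g", node(tree$merge[i, 1], h),
              node(tree$merge[i, 2], h), parent_h - h)
    }
  }
  n <- nrow(tree$merge)
  h <- tree$height[n]
  paste0("(", node(tree$merge[n, 1], h), ",",
         node(tree$merge[n, 2], h), ");")
}

## read a flat key<TAB>value configuration file into a named list
readPipelineConfig <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2
  if (any(bad)) {
    stop("config parse error: expected 'key<TAB>value' but got ",
         sQuote(lines[bad][1]))
  }
  setNames(lapply(parts, function(p) paste(p[-1], collapse = "\t")),
           vapply(parts, `[[`, character(1), 1))
}

#' Run the full site-analysis pipeline
#'
#' Executes filtering, motif classification, site topology, structural
#' context (when an annotation file is given) and the quantitative LFQ
#' pipeline on a set of input tables, writing every result table, a run
#' log (package version, seed, parameters) and a JSON summary of the
#' headline statistics into `outdir`. Any stage failure is re-raised with
#' the stage name. Given identical inputs, seed and parameters, the
#' output files are byte-identical across runs.
#'
#' @param config either a named list or the path of a flat
#'   `key<TAB>value` config file. Recognized keys: `sites`,
#'   `protein_groups`, `fasta`, `annotation` (optional), `design`,
#'   `outdir`, and the parameters `min_loc_prob` (default none),
#'   `hydrophobic` (string such as `"ILVMF"`), `disorder_threshold`
#'   (0.5), `impute_width` (0.3), `impute_downshift` (1.8), `linkage`
#'   (`"average"`), `rounding` (`"half-up"`), `spacing_threshold` (5),
#'   `seed` (1).
#' @return Invisibly, a list with the computed objects (`sites`,
#'   `composition`, `site_counts`, `spacings`, `curves`, `enrichment`,
#'   `dynamics`, `summary`) and the written file paths.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- readPipelineConfig(config)
  }
  stopifnot(is.list(config))
  get_num <- function(key, default) {
    if (is.null(config[[key]])) default else as.numeric(config[[key]])
  }
  get_chr <- function(key, default) {
    if (is.null(config[[key]])) default else as.character(config[[key]])
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  outdir <- config$outdir %||% stop("config must name an 'outdir'")
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  seed <- as.integer(get_num("seed", 1))
  hydrophobic <- strsplit(get_chr("hydrophobic", "ILVMF"), "")[[1]]
  min_loc_prob <- if (is.null(config$min_loc_prob)) NULL else
    as.numeric(config$min_loc_prob)

  design <- stage("input", readDesignTable(config$design))
  sites_raw <- stage("input", readSitesTable(config$sites, design))
  proteins <- stage("input", readFasta(config$fasta))
  pgroups <- if (!is.null(config$protein_groups)) {
    stage("input", readProteinTable(config$protein_groups, design))
  }

  sites <- stage("filter", {
    s <- filterSites(sites_raw, min_loc_prob)
    if (nrow(s) == 0) stop("no sites left after filtering")
    s
  })

  composition <- stage("motifs", motifComposition(sites, hydrophobic))
  site_counts <- stage("topology", siteCountDistribution(sites))
  spacing_threshold <- get_num("spacing_threshold", 5)
  spacings <- stage("topology", adjacentSpacing(sites))
  rounding <- get_chr("rounding", "half-up")
  curves <- stage("topology", list(
    from_sumo = distanceCurve(sites, proteins, "FROM_SUMO_K",
                              rounding = rounding),
    from_any = distanceCurve(sites, proteins, "FROM_ANY_K",
                             rounding = rounding)
  ))

  enrichment <- NULL
  if (!is.null(config$annotation)) {
    enrichment <- stage("structure", {
      ann <- readAnnotationTable(config$annotation)
      classes <- deriveClasses(
        ann, disorder_threshold = get_num("disorder_threshold", 0.5)
      )
      foldEnrichment(sites, proteins, classes)
    })
  }

  dynamics <- stage("dynamics", {
    raw <- profileMatrix(sites)
    averaged <- averageReplicates(raw, design)
    counted <- countIdentified(raw, design)
    ## cluster rows quantifiable at >= 1 timepoint, imputing the rest
    quantifiable <- profileValues(averaged)
    keep1 <- rowSums(!is.na(quantifiable)) >= 1
    pm <- ProfileMatrix(quantifiable[keep1, , drop = FALSE], "AVERAGED")
    lg <- log2Transform(pm)
    im <- imputeDownshift(lg, width = get_num("impute_width", 0.3),
                          downshift = get_num("impute_downshift", 1.8),
                          seed = seed)
    zs <- zscoreRows(im)
    ok <- setdiff(rownames(profileValues(zs)), flaggedRows(zs))
    zs_ok <- ProfileMatrix(profileValues(zs)[ok, , drop = FALSE],
                           "ZSCORED")
    clust <- if (length(ok) >= 2) {
      hierarchicalCluster(zs_ok, linkage_method = get_chr("linkage",
                                                          "average"))
    }
    sim <- if (length(ok) >= 2) similarityMatrix(zs_ok)
    list(averaged = averaged, identified = counted, zscored = zs,
         cluster = clust, similarity = sim,
         cumulative = cumulativeSiteIntensity(sites))
  })

  ## ---- write outputs ------------------------------------------------
  writeMatrix <- function(m, path) {
    df <- data.frame(id = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  paths <- c(
    filtered_sites = file.path(outdir, "filtered_sites.tsv"),
    composition = file.path(outdir, "motif_composition.tsv"),
    site_counts = file.path(outdir, "site_count_histogram.tsv"),
    spacings = file.path(outdir, "adjacent_spacings.tsv"),
    curve_sumo = file.path(outdir, "distance_curve_from_sumo_k.tsv"),
    curve_any = file.path(outdir, "distance_curve_from_any_k.tsv"),
    averaged = file.path(outdir, "averaged_matrix.tsv"),
    zscored = file.path(outdir, "zscored_matrix.tsv"),
    similarity = file.path(outdir, "similarity_matrix.tsv"),
    tree = file.path(outdir, "cluster_tree.nwk"),
    summary = file.path(outdir, "summary.json"),
    log = file.path(outdir, "run_log.txt")
  )
  writeSitesTable(sites, paths["filtered_sites"])
  write.table(composition, paths["composition"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(site_counts$histogram, paths["site_counts"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(spacing = spacings), paths["spacings"],
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(curves$from_sumo, paths["curve_sumo"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(curves$from_any, paths["curve_any"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeMatrix(profileValues(dynamics$averaged), paths["averaged"])
  writeMatrix(profileValues(dynamics$zscored), paths["zscored"])
  if (!is.null(dynamics$similarity)) {
    writeMatrix(dynamics$similarity, paths["similarity"])
  }
  if (!is.null(dynamics$cluster)) {
    writeLines(hclustToNewick(dynamics$cluster$tree), paths["tree"])
  }
  if (!is.null(enrichment)) {
    paths["enrichment"] <- file.path(outdir, "structure_enrichment.tsv")
    write.table(enrichment, paths["enrichment"], sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  summary <- list(
    n_sites_raw = nrow(sites_raw),
    n_sites = nrow(sites),
    n_proteins = site_counts$n_proteins,
    proteins_ge2_sites = site_counts$ge2,
    proteins_ge5_sites = site_counts$ge5,
    motif_fractions = setNames(as.list(composition$fraction),
                               composition$category),
    spacing_fraction_below = setNames(
      mean(spacings < spacing_threshold),
      paste0("lt", spacing_threshold)
    ),
    identified_per_timepoint = as.list(dynamics$identified),
    enrichment = if (!is.null(enrichment)) {
      setNames(as.list(enrichment$enrichment), enrichment$class)
    }
  )
  jsonlite::write_json(summary, paths["summary"], auto_unbox = TRUE,
                       digits = NA, null = "null")
  writeLines(c(
    paste("sumoscape version:",
          as.character(utils::packageVersion("sumoscape"))),
    paste("seed:", seed),
    paste("min_loc_prob:", min_loc_prob %||% "none"),
    paste("hydrophobic:", paste(hydrophobic, collapse = "")),
    paste("linkage:", get_chr("linkage", "average")),
    paste("impute:", get_num("impute_width", 0.3), "/",
          get_num("impute_downshift", 1.8)),
    paste("inputs:", config$sites, config$fasta, config$design)
  ), paths["log"])

  invisible(list(
    sites = sites, composition = composition, site_counts = site_counts,
    spacings = spacings, curves = curves, enrichment = enrichment,
    dynamics = dynamics, summary = summary, paths = paths
  ))
}
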