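## End-to-end orchestration: a structured configuration drives the four
## analysis stages in dependency order (proteome -> de -> gsea ->
## integrate), with uniform TSV outputs and a run manifest carrying
## checksums for provenance.  makeDemo() emits a complete synthetic input
## bundle with planted ground truth.

#' Stage parameter defaults
#'
#' One place holding every tunable threshold with its published default:
#' EV-enrichment rule (log2FC > 0.7 at BH FDR < 0.01), differential
#' abundance rule (p < 0.05, |log2FC| > 0.1), DEG threshold (padj <= 0.1),
#' GSEA parameters (1000 permutations, set sizes 5-500, weight 1), miRNA
#' selection (top 50 above 2000 RPM), integration DEG gate (padj < 0.05),
#' multiplicity floor (2), and the Fisher sweep grid (3.0 down to 0 in 0.1
#' steps at alpha 0.05).
#'
#' @return Named list of defaults.
#' @export
pipelineDefaults <- function() {
  list(
    enrichLfcCutoff = NULL,   # NULL = derive by Fisher sweep
    enrichFdr = 0.01,
    dapP = 0.05,
    dapLfc = 0.1,
    degPadj = 0.1,
    gseaNperm = 1000L,
    gseaSetMin = 5L,
    gseaSetMax = 500L,
    gseaWeight = 1,
    topN = 50L,
    minRpm = 2000,
    integratePadj = 0.05,
    minMirnas = 2L,
    sweepAlpha = 0.05,
    sweepGridStart = 3,
    sweepGridStep = 0.1,
    sweepGridFloor = 0
  )
}

.knownInputs <- c("proteome", "channel_groups", "markers", "counts",
                  "conditions", "biotypes", "mirna_counts", "targets",
                  "gene_sets", "de_table")
.knownStages <- c("proteome", "de", "gsea", "integrate")

.validateConfig <- function(config) {
  known <- c("seed", "out_dir", "stages", "inputs", "params")
  extra <- setdiff(names(config), known)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  for (k in c("seed", "out_dir"))
    if (is.null(config[[k]])) stop("config key '", k, "' is required")
  st <- config$stages
  if (is.null(st)) st <- stats::setNames(as.list(rep(TRUE, 4)), .knownStages)
  extra <- setdiff(names(st), .knownStages)
  if (length(extra))
    stop("unknown stage(s): ", paste(extra, collapse = ", "))
  for (s in .knownStages) if (is.null(st[[s]])) st[[s]] <- FALSE
  config$stages <- st
  extra <- setdiff(names(config$inputs), .knownInputs)
  if (length(extra))
    stop("unknown input key(s): ", paste(extra, collapse = ", "))
  par <- pipelineDefaults()
  extra <- setdiff(names(config$params), names(par))
  if (length(extra))
    stop("unknown parameter(s): ", paste(extra, collapse = ", "))
  par[names(config$params)] <- config$params
  if (par$enrichFdr < 0 || par$enrichFdr > 1 || par$degPadj < 0 ||
      par$degPadj > 1 || par$integratePadj < 0 || par$integratePadj > 1 ||
      par$sweepAlpha < 0 || par$sweepAlpha > 1)
    stop("threshold parameter outside [0, 1]")
  config$params <- par
  enabled <- unlist(st[.knownStages])
  if ((st$gsea || st$integrate) && !st$de &&
      is.null(config$inputs$de_table))
    stop("stage '", if (st$gsea) "gsea" else "integrate",
         "' requires the 'de' stage or an inputs$de_table file")
  needs <- list(
    proteome = c("proteome", "channel_groups", "markers"),
    de = c("counts", "conditions"),
    gsea = "gene_sets",
    integrate = c("mirna_counts", "targets"))
  for (s in .knownStages[enabled]) {
    miss <- setdiff(needs[[s]], names(config$inputs))
    if (length(miss))
      stop("stage '", s, "' is missing input(s): ",
           paste(miss, collapse = ", "))
    for (f in needs[[s]])
      if (!file.exists(config$inputs[[f]]))
        stop("input file not found: ", config$inputs[[f]])
  }
  config
}

#' Run the full EV-cargo pipeline from a configuration
#'
#' Executes the enabled stages in dependency order, writing every result as
#' a TSV under \code{out_dir} and a \code{manifest.yaml} with the config
#' hash, seed and an md5 checksum per output.  Re-running with an identical
#' configuration and inputs reproduces identical checksums.  Schema
#' violations (unknown keys, missing dependency inputs) fail before any
#' computation.
#'
#' @param config path to a YAML configuration or an equivalent named list;
#'   keys: \code{seed}, \code{out_dir}, \code{stages} (logical toggles
#'   \code{proteome}, \code{de}, \code{gsea}, \code{integrate}),
#'   \code{inputs} (file paths), \code{params} (overrides of
#'   \code{\link{pipelineDefaults}}).
#' @return The manifest, invisibly.
#' @seealso \code{\link{makeDemo}} for a ready-to-run bundle.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- .validateConfig(config)
  par <- config$params
  seed <- as.integer(config$seed)
  outDir <- config$out_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  outputs <- character(0)
  emit <- function(obj, name) {
    p <- file.path(outDir, name)
    .writeTsv(obj, p)
    outputs <<- c(outputs, p)
    p
  }

  degTable <- NULL
  if (config$stages$proteome) {
    message("[proteome] differential abundance + Fisher sweep")
    rs <- readReportersTsv(config$inputs$proteome,
                           config$inputs$channel_groups)
    markers <- readMarkerIds(config$inputs$markers)
    norm <- normalizeReporters(rs)
    diff <- differentialAbundance(norm)
    lfc <- stats::setNames(diff$log2fc, diff$id)
    sw <- sweepCutoff(lfc, markers,
                         gridStart = par$sweepGridStart,
                         gridStep = par$sweepGridStep,
                         gridFloor = par$sweepGridFloor,
                         alpha = par$sweepAlpha)
    cutoff <- par$enrichLfcCutoff
    if (is.null(cutoff)) cutoff <- sw@chosenCutoff
    if (is.na(cutoff))
      stop("Fisher sweep found no significant cutoff; supply ",
           "params$enrichLfcCutoff explicitly")
    diff <- classifyEnriched(diff, cutoff, par$enrichFdr)$table
    diff <- classifyDap(diff, par$dapP, par$dapLfc)$table
    emit(diff, "proteome_diff.tsv")
    emit(data.frame(cutoff = sw@grid, p = sw@p,
                    chosen = sw@grid == cutoff), "sweep.tsv")
  }

  if (config$stages$de) {
    message("[de] negative-binomial differential expression")
    cs <- readCountsTsv(config$inputs$counts, config$inputs$conditions)
    res <- nbWaldTest(cs)
    called <- callDegs(res, par$degPadj)
    degTable <- called$table
    emit(degTable, "de_results.tsv")
    sim <- sampleSimilarity(cs,
                            sizeFactors = metadata(res)$sizeFactors)
    emit(data.frame(sample = rownames(sim$euclidean), sim$euclidean,
                    check.names = FALSE), "similarity_euclidean.tsv")
    emit(data.frame(sample = rownames(sim$pearson), sim$pearson,
                    check.names = FALSE), "similarity_pearson.tsv")
    if (!is.null(config$inputs$biotypes)) {
      bt <- .readTsv(config$inputs$biotypes)
      comp <- biotypeComposition(degTable,
                                 stats::setNames(bt$biotype, bt$id))
      emit(data.frame(biotype = names(comp), percent = as.integer(comp)),
           "biotype_composition.tsv")
    }
  }
  if (is.null(degTable) && !is.null(config$inputs$de_table)) {
    degTable <- .readTsv(config$inputs$de_table)
  }

  if (config$stages$gsea) {
    message("[gsea] preranked gene set enrichment")
    if (is.null(degTable)) stop("stage 'gsea' has no DE table")
    ranked <- rankFromDE(degTable)
    sets <- readGeneSets(config$inputs$gene_sets)
    gres <- runGsea(ranked, sets, nperm = par$gseaNperm,
                    setMin = par$gseaSetMin, setMax = par$gseaSetMax,
                    weight = par$gseaWeight, seed = seed)
    emit(gres, "gsea_results.tsv")
  }

  if (config$stages$integrate) {
    message("[integrate] miRNA profiling and target integration")
    if (is.null(degTable)) stop("stage 'integrate' has no DE table")
    ev <- readCountsTsv(config$inputs$mirna_counts)
    prof <- rpmProfile(ev)
    sel <- selectTopMirnas(prof, topN = par$topN, minRpm = par$minRpm)
    emit(sel$profile, "mirna_profile.tsv")
    db <- readTargetTsv(config$inputs$targets)
    edges <- integrateTargets(sel$ids, db, degTable,
                              padjThreshold = par$integratePadj)
    filt <- multiplicityFilter(edges, par$minMirnas)
    emit(filt$edges, "edges.tsv")
    emit(rankCandidates(filt$edges), "ranking.tsv")
    ch <- chordTable(filt$edges)
    emit(ch$links, "chord.tsv")
  }

  cfgYaml <- yaml::as.yaml(config[order(names(config))])
  cfgHashFile <- tempfile()
  writeLines(cfgYaml, cfgHashFile)
  manifest <- list(
    tool = "exoCargo",
    version = as.character(utils::packageVersion("exoCargo")),
    configHash = unname(tools::md5sum(cfgHashFile)),
    seed = seed,
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    outputs = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                      basename(outputs))))
  unlink(cfgHashFile)
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  invisible(manifest)
}

#' Write a complete synthetic demo bundle
#'
#' Generates every pipeline input with planted ground truth and a matching
#' configuration, sized to run end-to-end in well under a minute: a
#' 1000-protein TMT proteome with 100 planted EV markers (the marker list
#' doubles as the enrichment reference); a 4000-gene RNA-seq experiment
#' (5 replicates per arm, 10 percent of genes differentially expressed at
#' |log2FC| = 2, NB dispersion 0.1); a 58-set gene-set collection including
#' two sets planted inside the up- and down-regulated genes; a 600-miRNA EV
#' library with a Zipf abundance profile; and a validated-target table with
#' background density 0.005 plus five planted regulator miRNAs, each wired
#' to 12 genes from a shared pool of 20 planted DE genes (so every pool
#' gene is hit by multiple regulators, as the multiplicity filter expects).
#' All identities and effect sizes are written to \code{truth_*} files.
#'
#' @param seed integer seed driving every generator.
#' @param outDir writable output directory (created if needed).
#' @return Invisibly, a list with \code{config} (path), \code{truth}
#'   (planted regulator ids, marker ids, DE gene ids, planted set names)
#'   and \code{files}.
#' @examples
#' \donttest{
#' demo <- makeDemo(seed = 1, outDir = tempfile())
#' manifest <- runPipeline(demo$config)
#' }
#' @export
makeDemo <- function(seed, outDir) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  seed <- as.integer(seed)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(outDir, 2) != 0) stop("directory not writable: ", outDir)
  fp <- function(x) file.path(outDir, x)

  ## proteome arm; noise sd 0.15 log2 units reflects typical TMT
  ## reporter-ion precision after median centring
  prot <- simulateTmtProteome(nProteins = 1000L, nMarkers = 100L,
                              markerLfc = 2, noiseSd = 0.15,
                              nPerGroup = 3L, seed = seed)
  writeMatrixTsv(prot, fp("proteome.tsv"))
  .writeTsv(data.frame(channel = colnames(prot),
                       group = channelGroups(prot)),
            fp("channel_groups.tsv"))
  markerIds <- rownames(prot)[rowData(prot)$isMarker]
  writeMarkerIds(markerIds, fp("markers.txt"))
  .writeTsv(as.data.frame(truthTable(prot)), fp("truth_proteins.tsv"))

  ## transcriptome arm
  rna <- simulateRnaSeqCounts(nGenes = 4000L, nPerGroup = 5L,
                              fracDe = 0.1, deLfc = 2, dispersion = 0.1,
                              seed = seed + 1L)
  writeMatrixTsv(rna, fp("counts.tsv"))
  .writeTsv(data.frame(sample = colnames(rna),
                       condition = sampleConditions(rna)),
            fp("conditions.tsv"))
  .writeTsv(data.frame(id = rownames(rna), biotype = biotypes(rna)),
            fp("biotypes.tsv"))
  .writeTsv(as.data.frame(truthTable(rna)), fp("truth_genes.tsv"))

  ## gene sets: 56 background + 2 planted in the shifted genes
  truthRna <- truthTable(rna)
  upGenes <- truthRna$id[truthRna$isDe & truthRna$truthLfc > 0]
  downGenes <- truthRna$id[truthRna$isDe & truthRna$truthLfc < 0]
  planted <- .withSeed(seed + 2L, list(
    PLANTED_UP = sample(upGenes, min(40L, length(upGenes))),
    PLANTED_DOWN = sample(downGenes, min(40L, length(downGenes)))))
  sets <- simulateGeneSets(rownames(rna), nSets = 56L,
                           sizeRange = c(15L, 200L), planted = planted,
                           seed = seed + 3L)
  writeGmt(sets, fp("gene_sets.gmt"))

  ## miRNA arm: 600 miRNAs, regulators planted among the top-50 ranks
  ev <- simulateMirnaCounts(nMirnas = 600L, librarySize = 5e6,
                            abundanceShape = 1, seed = seed + 4L)
  writeMatrixTsv(ev, fp("mirna_counts.tsv"))
  regulators <- rownames(ev)[c(3L, 8L, 15L, 27L, 42L)]
  pool <- .withSeed(seed + 5L,
                    sample(c(upGenes, downGenes), 20L))
  regTargets <- .withSeed(seed + 6L, {
    stats::setNames(lapply(regulators, function(m) sample(pool, 12L)),
                    regulators)
  })
  db <- simulateTargetDb(rownames(ev), rownames(rna), density = 0.005,
                         planted = regTargets, seed = seed + 7L)
  writeTargetTsv(db$edges, fp("targets.tsv"))
  writeMarkerIds(regulators, fp("truth_regulators.txt"))

  config <- list(
    seed = seed,
    out_dir = fp("results"),
    stages = list(proteome = TRUE, de = TRUE, gsea = TRUE,
                  integrate = TRUE),
    inputs = list(proteome = fp("proteome.tsv"),
                  channel_groups = fp("channel_groups.tsv"),
                  markers = fp("markers.txt"),
                  counts = fp("counts.tsv"),
                  conditions = fp("conditions.tsv"),
                  biotypes = fp("biotypes.tsv"),
                  mirna_counts = fp("mirna_counts.tsv"),
                  targets = fp("targets.tsv"),
                  gene_sets = fp("gene_sets.gmt")),
    params = list())
  cfgPath <- fp("config.yaml")
  yaml::write_yaml(config, cfgPath)

  invisible(list(
    config = cfgPath,
    truth = list(markers = markerIds,
                 deGenes = truthRna$id[truthRna$isDe],
                 upGenes = upGenes, downGenes = downGenes,
                 regulators = regulators, pool = pool,
                 plantedSets = names(planted)),
    files = config$inputs))
}
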