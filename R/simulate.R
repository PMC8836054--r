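## Synthetic multi-omics generators with planted ground truth.  Every
## generator takes one explicit integer seed and restores the caller's RNG
## state; identical arguments + seed give identical output.

#' Simulate a TMT reporter-ion proteome with planted EV markers
#'
#' Generates a proteins x channels intensity matrix for a two-group design
#' (CELL vs EV).  Per protein, log2 intensity = baseline + group effect +
#' Normal(0, \code{noiseSd}); planted marker proteins carry a group effect of
#' \code{markerLfc} in the EV channels, all other proteins 0.  Intensities
#' are returned on the raw (2^log2) scale, strictly positive, ready for
#' \code{\link{normalizeReporters}}.
#'
#' @param nProteins number of proteins.
#' @param nMarkers number of planted EV-enriched marker proteins
#'   (\code{<= nProteins}); the marker identities are a seeded random subset.
#' @param markerLfc planted log2 fold change (EV vs CELL) of the markers.
#' @param noiseSd standard deviation of the per-channel log2 noise
#'   (log2 units, >= 0).
#' @param nPerGroup channels per group (>= 2 so group variances exist).
#' @param baselineLog2 range of the per-protein baseline log2 intensity,
#'   drawn uniformly.
#' @param groups the two channel-group labels, reference first; the
#'   planted effect applies to the second group (e.g. EV, or TREATED).
#' @param seed integer seed.
#' @return A \code{\link{ReporterSet}} with \code{rowData} columns
#'   \code{truthLfc} and \code{isMarker} (the planted ground truth).
#' @examples
#' sim <- simulateTmtProteome(nProteins = 100, nMarkers = 10, seed = 1)
#' table(truthTable(sim)$isMarker)
#' @export
simulateTmtProteome <- function(nProteins = 500L, nMarkers = 50L,
                                markerLfc = 2, noiseSd = 0.3,
                                nPerGroup = 3L, baselineLog2 = c(10, 20),
                                groups = c("CELL", "EV"), seed) {
  nProteins <- .assertCount(nProteins, "nProteins")
  nMarkers <- .assertCount(nMarkers, "nMarkers", min = 0L)
  if (nMarkers > nProteins) stop("'nMarkers' must be <= 'nProteins'")
  .assertScalar(markerLfc, "markerLfc")
  .assertScalar(noiseSd, "noiseSd", nonneg = TRUE)
  nPerGroup <- .assertCount(nPerGroup, "nPerGroup", min = 2L)
  stopifnot(length(groups) == 2L)
  .withSeed(seed, {
    ids <- sprintf("P%04d", seq_len(nProteins))
    markers <- sort(sample.int(nProteins, nMarkers))
    truthLfc <- numeric(nProteins)
    truthLfc[markers] <- markerLfc
    baseline <- stats::runif(nProteins, baselineLog2[1], baselineLog2[2])
    nch <- 2L * nPerGroup
    group <- rep(as.character(groups), each = nPerGroup)
    eff <- outer(truthLfc, as.numeric(group == groups[2]))
    lg <- baseline + eff +
      matrix(stats::rnorm(nProteins * nch, 0, noiseSd), nProteins, nch)
    m <- 2^lg
    dimnames(m) <- list(ids, paste0(group, "_", rep(seq_len(nPerGroup), 2)))
    ReporterSet(m, group,
                rowData = DataFrame(truthLfc = truthLfc,
                                    isMarker = seq_len(nProteins) %in% markers,
                                    row.names = ids))
  })
}

#' Simulate an RNA-seq count matrix with planted differential expression
#'
#' Counts are drawn from a negative binomial with mean
#' \eqn{s_j q_i 2^{lfc_i x_j}} and variance \eqn{\mu + \alpha \mu^2}
#' (\eqn{\alpha} = \code{dispersion}; \eqn{x_j} is 0 for the reference group
#' and 1 for the treated group).  \code{round(fracDe * nGenes)} genes are
#' flagged differentially expressed with |planted lfc| = \code{deLfc} and a
#' random sign.  Per-sample size factors are drawn log-uniform in
#' \eqn{\pm}\code{sizeFactorLog2} log2 units so normalization stages are
#' non-trivially exercised.  Biotype labels are sampled from
#' \code{biotypeProbs}.
#'
#' @param nGenes number of genes.
#' @param nPerGroup samples per condition.
#' @param fracDe fraction of genes planted as differentially expressed.
#' @param deLfc absolute planted log2 fold change of DE genes.
#' @param dispersion NB dispersion alpha (>= 0; 0 gives the Poisson limit).
#' @param meanRange range of the per-gene base mean, drawn log-uniform.
#' @param biotypeProbs named sampling probabilities over the six transcript
#'   biotype categories; must sum to 1 within 1e-9.
#' @param sizeFactorLog2 half-width of the log2-uniform size-factor draw.
#' @param conditions labels of the two groups (reference first).
#' @param seed integer seed.
#' @return A \code{\link{CountSet}} with \code{colData$condition} and
#'   \code{rowData} columns \code{isDe}, \code{truthLfc}, \code{dispersion},
#'   \code{biotype}; \code{metadata(x)$trueSizeFactors} holds the planted
#'   per-sample scaling.
#' @examples
#' sim <- simulateRnaSeqCounts(nGenes = 200, seed = 1)
#' sum(truthTable(sim)$isDe)
#' @export
simulateRnaSeqCounts <- function(nGenes = 2000L, nPerGroup = 3L,
                                 fracDe = 0.1, deLfc = 2, dispersion = 0.1,
                                 meanRange = c(10, 1000),
                                 biotypeProbs = c(protein_coding = 0.71,
                                                  pseudogene = 0.17,
                                                  lncRNA = 0.06,
                                                  TEC = 0.03,
                                                  processed_transcript = 0.02,
                                                  ncRNA = 0.01),
                                 sizeFactorLog2 = 0.3,
                                 conditions = c("untreated", "treated"),
                                 seed) {
  nGenes <- .assertCount(nGenes, "nGenes")
  nPerGroup <- .assertCount(nPerGroup, "nPerGroup", min = 2L)
  .assertProb(fracDe, "fracDe")
  .assertScalar(deLfc, "deLfc")
  .assertScalar(dispersion, "dispersion", nonneg = TRUE)
  if (abs(sum(biotypeProbs) - 1) > 1e-9)
    stop("'biotypeProbs' must sum to 1 (tolerance 1e-9)")
  stopifnot(length(conditions) == 2L)
  .withSeed(seed, {
    ids <- sprintf("g%05d", seq_len(nGenes))
    nDe <- as.integer(round(fracDe * nGenes))
    isDe <- logical(nGenes)
    truthLfc <- numeric(nGenes)
    if (nDe > 0L) {
      deIdx <- sample.int(nGenes, nDe)
      isDe[deIdx] <- TRUE
      truthLfc[deIdx] <- deLfc * sample(c(-1, 1), nDe, replace = TRUE)
    }
    q <- exp(stats::runif(nGenes, log(meanRange[1]), log(meanRange[2])))
    ns <- 2L * nPerGroup
    sf <- 2^stats::runif(ns, -sizeFactorLog2, sizeFactorLog2)
    x <- rep(c(0, 1), each = nPerGroup)
    mu <- outer(q, sf) * 2^(truthLfc %o% x)
    k <- if (dispersion == 0) {
      matrix(stats::rpois(length(mu), mu), nGenes, ns)
    } else {
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
             nGenes, ns)
    }
    biotype <- sample(names(biotypeProbs), nGenes, replace = TRUE,
                      prob = biotypeProbs)
    dimnames(k) <- list(ids, paste0(rep(conditions, each = nPerGroup), "_",
                                    rep(seq_len(nPerGroup), 2)))
    out <- CountSet(k, condition = rep(conditions, each = nPerGroup),
                    rowData = DataFrame(isDe = isDe, truthLfc = truthLfc,
                                        dispersion = rep(dispersion, nGenes),
                                        biotype = biotype, row.names = ids))
    metadata(out)$trueSizeFactors <- stats::setNames(sf, colnames(k))
    out
  })
}

#' Simulate a small-RNA (miRNA) count library with a power-law profile
#'
#' Abundances follow a Zipf profile (rank^-\code{abundanceShape}); counts per
#' sample are a single multinomial draw, so each library sums exactly to
#' \code{librarySize}.  With the defaults (600 miRNAs, shape 1, 5e6 reads)
#' roughly 75 miRNAs exceed 2000 reads per million, mirroring an EV library
#' in which far more than 50 miRNAs pass the selection threshold.
#'
#' @param nMirnas number of miRNAs (>= 1); id rank 1 is the most abundant.
#' @param librarySize total reads per sample.
#' @param abundanceShape Zipf exponent of the abundance profile.
#' @param nSamples number of libraries (columns).
#' @param seed integer seed.
#' @return A \code{\link{CountSet}} (no condition labels) whose rowData
#'   carries the abundance rank.
#' @examples
#' ev <- simulateMirnaCounts(nMirnas = 50, librarySize = 1e5, seed = 1)
#' colSums(SummarizedExperiment::assay(ev))
#' @export
simulateMirnaCounts <- function(nMirnas = 600L, librarySize = 5e6,
                                abundanceShape = 1, nSamples = 1L, seed) {
  nMirnas <- .assertCount(nMirnas, "nMirnas")
  librarySize <- .assertCount(librarySize, "librarySize")
  .assertScalar(abundanceShape, "abundanceShape", nonneg = TRUE)
  nSamples <- .assertCount(nSamples, "nSamples")
  .withSeed(seed, {
    ids <- sprintf("miR-%04d", seq_len(nMirnas))
    p <- seq_len(nMirnas)^(-abundanceShape)
    p <- p / sum(p)
    k <- stats::rmultinom(nSamples, size = librarySize, prob = p)
    dimnames(k) <- list(ids, sprintf("EV%d", seq_len(nSamples)))
    out <- CountSet(k, rowData = DataFrame(rank = seq_len(nMirnas),
                                           row.names = ids))
    out
  })
}

#' Simulate a validated miRNA-target interaction table
#'
#' Background edges between every (miRNA, gene) pair are sampled i.i.d. with
#' probability \code{density}; planted edges (e.g. regulator miRNAs wired to
#' known differentially expressed genes) are always present.  The edge set
#' is deduplicated.
#'
#' @param mirnaIds,geneIds the two id universes.
#' @param density background edge probability in [0, 1].
#' @param planted named list: names are miRNA ids, elements are character
#'   vectors of target gene ids; every id must belong to the universes.
#' @param seed integer seed.
#' @return A list with \code{edges} (data.frame with columns \code{mirna},
#'   \code{gene}) and \code{plantedRegulators} (names of \code{planted}).
#' @examples
#' db <- simulateTargetDb(paste0("m", 1:5), paste0("g", 1:20),
#'                        density = 0.2, seed = 1)
#' nrow(db$edges)
#' @export
simulateTargetDb <- function(mirnaIds, geneIds, density = 0.005,
                             planted = list(), seed) {
  .assertProb(density, "density")
  mirnaIds <- as.character(mirnaIds)
  geneIds <- as.character(geneIds)
  if (length(planted)) {
    if (is.null(names(planted)) || any(!nzchar(names(planted))))
      stop("'planted' must be a named list (miRNA id -> gene ids)")
    if (!all(names(planted) %in% mirnaIds))
      stop("planted miRNA id not in 'mirnaIds'")
    if (!all(unlist(planted) %in% geneIds))
      stop("planted gene id not in 'geneIds'")
  }
  .withSeed(seed, {
    nm <- length(mirnaIds); ng <- length(geneIds)
    edges <- if (density > 0) {
      hit <- which(stats::runif(nm * ng) < density)
      data.frame(mirna = mirnaIds[((hit - 1L) %% nm) + 1L],
                 gene = geneIds[((hit - 1L) %/% nm) + 1L],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(mirna = character(0), gene = character(0),
                 stringsAsFactors = FALSE)
    }
    if (length(planted)) {
      pl <- data.frame(
        mirna = rep(names(planted), lengths(planted)),
        gene = unlist(planted, use.names = FALSE),
        stringsAsFactors = FALSE)
      edges <- rbind(edges, pl)
    }
    edges <- edges[!duplicated(edges[c("mirna", "gene")]), , drop = FALSE]
    edges <- edges[order(edges$mirna, edges$gene), , drop = FALSE]
    rownames(edges) <- NULL
    list(edges = edges, plantedRegulators = names(planted))
  })
}

#' Simulate a gene-set collection
#'
#' Draws \code{nSets} sets of sizes uniform in \code{sizeRange}, each sampled
#' without replacement from \code{geneIds}.  Entries of \code{planted}
#' override the sampled membership of the set of the same name (used by the
#' demo bundle to plant sets concentrated in up- or down-regulated genes,
#' whose metric signs are then correlated by construction).
#'
#' @param geneIds gene universe.
#' @param nSets number of sets (0 gives an empty collection).
#' @param sizeRange integer range of set sizes, within \code{[1,
#'   length(geneIds)]}.
#' @param planted named list of forced member vectors.
#' @param seed integer seed.
#' @return Named list of character vectors; planted set names are recorded
#'   in \code{attr(x, "planted")}.
#' @examples
#' gs <- simulateGeneSets(paste0("g", 1:100), nSets = 5,
#'                        sizeRange = c(5, 10), seed = 1)
#' lengths(gs)
#' @export
simulateGeneSets <- function(geneIds, nSets = 58L, sizeRange = c(15L, 200L),
                             planted = list(), seed) {
  nSets <- .assertCount(nSets, "nSets", min = 0L)
  geneIds <- as.character(geneIds)
  sizeRange <- as.integer(sizeRange)
  if (sizeRange[1] < 1L || sizeRange[2] > length(geneIds) ||
      sizeRange[1] > sizeRange[2])
    stop("'sizeRange' must lie within [1, length(geneIds)]")
  if (length(planted) && !all(unlist(planted) %in% geneIds))
    stop("planted member not in 'geneIds'")
  .withSeed(seed, {
    out <- vector("list", nSets)
    names(out) <- sprintf("SET_%03d", seq_len(nSets))
    for (i in seq_len(nSets)) {
      sz <- if (sizeRange[1] == sizeRange[2]) sizeRange[1] else
        sample(seq(sizeRange[1], sizeRange[2]), 1L)
      out[[i]] <- sort(sample(geneIds, sz))
    }
    for (nm in names(planted)) {
      out[[nm]] <- sort(unique(as.character(planted[[nm]])))
    }
    attr(out, "planted") <- names(planted)
    out
  })
}
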