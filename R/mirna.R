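## miRNA cargo profiling and integration with the recipient-cell DEGs:
## reads-per-million normalization, top-expressed selection, merge with a
## validated miRNA-target table, DEG gating, multiplicity filtering,
## candidate ranking and the chord-diagram export.

#' Reads-per-million normalization
#'
#' \code{rpm = count * 1e6 / column sum}; every library sums to 1e6 within
#' 1e-6 relative tolerance and the scaling is exactly invariant to
#' multiplying a library by a positive constant.
#'
#' @param x a \code{\link{CountSet}} or counts matrix.
#' @return Matrix of RPM values, same dimensions and order as the input.
#' @export
rpmNormalize <- function(x) {
  k <- .countsMatrix(x)
  depth <- colSums(k)
  if (any(depth <= 0)) stop("zero-depth sample: ",
                            paste(colnames(k)[depth <= 0], collapse = ", "))
  sweep(k, 2, depth, "/") * 1e6
}

#' Per-miRNA abundance profile
#'
#' Summarises raw counts and RPM per miRNA (RPM averaged across libraries
#' when several are present) with a \code{selected} placeholder filled by
#' \code{\link{selectTopMirnas}}.
#'
#' @param x a \code{\link{CountSet}} or counts matrix.
#' @return A \code{DataFrame} with columns \code{id}, \code{rawCount},
#'   \code{rpm}, \code{selected}; input order preserved.
#' @export
rpmProfile <- function(x) {
  k <- .countsMatrix(x)
  rpm <- rpmNormalize(k)
  DataFrame(id = rownames(k), rawCount = rowSums(k),
            rpm = rowMeans(rpm), selected = NA)
}

#' Select the top-expressed miRNAs
#'
#' Sorts the profile by RPM descending (stable order on ties) and keeps the
#' first \code{topN} entries that also exceed \code{minRpm}.  Both knobs are
#' exposed because "top 50" and "RPM > 2000" coincide on some libraries but
#' not in general; boundary ties are reported via a message.
#'
#' @param profile a \code{DataFrame} from \code{\link{rpmProfile}}.
#' @param topN maximal number of selected miRNAs.
#' @param minRpm RPM floor (strictly greater than).
#' @return A list with \code{ids} (selected, in descending RPM order) and
#'   \code{profile} (the input with \code{selected} filled).
#' @export
selectTopMirnas <- function(profile, topN = 50L, minRpm = 2000) {
  stopifnot(all(c("id", "rpm") %in% colnames(profile)))
  topN <- .assertCount(topN, "topN", min = 0L)
  .assertScalar(minRpm, "minRpm", nonneg = TRUE)
  o <- order(-profile$rpm, method = "radix")   # stable on ties
  eligible <- o[profile$rpm[o] > minRpm]
  sel <- utils::head(eligible, topN)
  if (length(eligible) > topN &&
      length(sel) > 0 &&
      profile$rpm[eligible[topN + 1L]] == profile$rpm[sel[length(sel)]])
    message("RPM tie at the top-", topN, " boundary; kept stable input order")
  profile$selected <- seq_len(nrow(profile)) %in% sel
  list(ids = as.character(profile$id[sel]), profile = profile)
}

.normId <- function(x) tolower(trimws(as.character(x)))

#' Merge selected miRNAs, validated targets and DEGs
#'
#' Keeps target edges whose miRNA is among the selected ids and whose gene
#' is differentially expressed at \code{padj < padjThreshold}, annotating
#' each edge with the gene's log2 fold change, adjusted p and direction.
#' Id matching is exact-string after case normalization.  An empty result
#' is allowed and returned empty.
#'
#' @param selected character vector of selected miRNA ids.
#' @param targetDb data.frame with columns \code{mirna}, \code{gene}
#'   (validated interactions); duplicate pairs are removed.
#' @param degs a DEG table (from \code{\link{callDegs}}; needs \code{id},
#'   \code{log2fc}, \code{padj}).
#' @param padjThreshold DEG gate for the integration (the figure-level 0.05,
#'   intentionally stricter than the 0.1 DE-calling default).
#' @return A \code{DataFrame} with columns \code{mirna}, \code{gene},
#'   \code{geneLog2fc}, \code{genePadj}, \code{degDirection},
#'   \code{geneMultiplicity} (distinct miRNAs per gene) and per-miRNA
#'   DEG-target counts in \code{metadata(x)$mirnaTargets}.
#' @export
integrateTargets <- function(selected, targetDb, degs,
                             padjThreshold = 0.05) {
  stopifnot(all(c("mirna", "gene") %in% colnames(targetDb)),
            all(c("id", "log2fc", "padj") %in% colnames(degs)))
  db <- unique(data.frame(mirna = as.character(targetDb$mirna),
                          gene = as.character(targetDb$gene),
                          stringsAsFactors = FALSE))
  degKeep <- degs[degs$padj < padjThreshold, , drop = FALSE]
  degKey <- .normId(degKeep$id)
  selKey <- .normId(selected)
  hit <- .normId(db$mirna) %in% selKey & .normId(db$gene) %in% degKey
  db <- db[hit, , drop = FALSE]
  idx <- match(.normId(db$gene), degKey)
  dir <- if ("direction" %in% colnames(degKeep))
    as.character(degKeep$direction[idx])
  else ifelse(degKeep$log2fc[idx] >= 0, "up", "down")
  out <- DataFrame(mirna = db$mirna, gene = db$gene,
                   geneLog2fc = degKeep$log2fc[idx],
                   genePadj = degKeep$padj[idx],
                   degDirection = dir)
  mult <- if (nrow(out)) table(out$gene) else table(character(0))
  out$geneMultiplicity <- if (nrow(out))
    as.integer(mult[out$gene]) else integer(0)
  metadata(out) <- list(
    mirnaTargets = if (nrow(out)) table(out$mirna) else table(character(0)),
    padjThreshold = padjThreshold)
  out
}

#' Keep genes targeted by multiple miRNAs
#'
#' Restricts the edge table to genes whose distinct-miRNA multiplicity is
#' at least \code{minMirnas} ("multiple" = 2 by default).
#'
#' @param edges a \code{DataFrame} from \code{\link{integrateTargets}}.
#' @param minMirnas minimal number of distinct targeting miRNAs per gene.
#' @return A list with \code{genes} (retained gene ids) and \code{edges}
#'   (the restricted table, multiplicities recomputed).
#' @export
multiplicityFilter <- function(edges, minMirnas = 2L) {
  stopifnot(all(c("mirna", "gene") %in% colnames(edges)))
  minMirnas <- .assertCount(minMirnas, "minMirnas", min = 0L)
  mult <- if (nrow(edges))
    tapply(edges$mirna, edges$gene, function(m) length(unique(m)))
  else integer(0)
  genes <- names(mult)[mult >= minMirnas]
  out <- edges[edges$gene %in% genes, , drop = FALSE]
  out$geneMultiplicity <- if (nrow(out))
    as.integer(table(out$gene)[out$gene]) else integer(0)
  list(genes = genes, edges = out)
}

#' Rank candidate miRNAs by number of filtered DEG targets
#'
#' miRNAs are ordered by the count of distinct target genes in the filtered
#' edge table, descending; ties are broken alphabetically and flagged.
#'
#' @param edges a filtered edge table (see \code{\link{multiplicityFilter}}).
#' @return A \code{DataFrame} with \code{mirna}, \code{nTargets},
#'   \code{tied}, sorted by rank.
#' @export
rankCandidates <- function(edges) {
  stopifnot(all(c("mirna", "gene") %in% colnames(edges)))
  if (nrow(edges) == 0L)
    return(DataFrame(mirna = character(0), nTargets = integer(0),
                     tied = logical(0)))
  cnt <- tapply(edges$gene, edges$mirna, function(g) length(unique(g)))
  o <- order(-cnt, names(cnt), method = "radix")
  cnt <- cnt[o]
  tied <- as.vector(duplicated(cnt) | duplicated(cnt, fromLast = TRUE))
  DataFrame(mirna = names(cnt), nTargets = as.integer(cnt), tied = tied)
}

#' Long-format chord-diagram export
#'
#' One row per (miRNA, gene) link with the gene's regulation direction,
#' plus per-miRNA and per-gene degrees so segment sizes are reproducible.
#' The degree sums on both sides equal the number of links (handshake
#' identity).
#'
#' @param edges a filtered edge table with \code{degDirection}.
#' @return A list with \code{links} (\code{DataFrame}: mirna, gene,
#'   direction), \code{mirnaDegree} and \code{geneDegree} (named integer
#'   vectors).
#' @export
chordTable <- function(edges) {
  stopifnot(all(c("mirna", "gene", "degDirection") %in% colnames(edges)))
  links <- DataFrame(mirna = edges$mirna, gene = edges$gene,
                     direction = edges$degDirection)
  md <- if (nrow(links)) table(links$mirna) else table(character(0))
  gd <- if (nrow(links)) table(links$gene) else table(character(0))
  list(links = links,
       mirnaDegree = stats::setNames(as.integer(md), names(md)),
       geneDegree = stats::setNames(as.integer(gd), names(gd)))
}
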