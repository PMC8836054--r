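## TMT proteome stage: normalization, EV-vs-cell differential abundance,
## Fisher-sweep cutoff selection against a marker reference, and the two
## classification rules (EV-enriched; differentially abundant).

#' Log2-transform and median-centre reporter intensities
#'
#' Each channel is log2-transformed and its median subtracted, so every
#' channel's median is exactly zero afterwards.  Protein order is preserved.
#' For inputs that are already on the log2 scale set
#' \code{alreadyLog2 = TRUE} to skip the transform (re-normalizing
#' median-centred log2 data is then a no-op up to tolerance).
#'
#' @param x a raw \code{\link{ReporterSet}}.
#' @param alreadyLog2 logical; input assay already log2-transformed.
#' @return A normalized \code{ReporterSet} (\code{isNormalized(x)} is
#'   \code{TRUE}).
#' @examples
#' sim <- simulateTmtProteome(nProteins = 50, nMarkers = 5, seed = 1)
#' norm <- normalizeReporters(sim)
#' apply(SummarizedExperiment::assay(norm), 2, median)  # all zero
#' @export
normalizeReporters <- function(x, alreadyLog2 = FALSE) {
  stopifnot(methods::is(x, "ReporterSet"))
  if (isNormalized(x) && !alreadyLog2)
    stop("'x' is already normalized; pass alreadyLog2 = TRUE to re-centre")
  v <- assay(x, "intensity")
  if (!alreadyLog2) {
    bad <- which(v <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop("non-positive intensity for protein '", rownames(v)[bad[1, 1]],
           "', channel '", colnames(v)[bad[1, 2]], "'")
    v <- log2(v)
  }
  med <- apply(v, 2, stats::median)
  v <- sweep(v, 2, med, "-")
  out <- ReporterSet(v, channelGroups(x), normalized = TRUE,
                     rowData = rowData(x))
  out
}

#' EV-vs-cell differential reporter abundance
#'
#' Per protein, the log2 fold change is the difference of channel-group
#' means on the normalized log2 scale (\code{groupB} minus \code{groupA})
#' and the p-value comes from an unpaired two-sided t-test -- classic
#' pooled-variance Student by default, Welch behind \code{welch = TRUE}.
#' P-values are Benjamini-Hochberg adjusted into \code{fdr}.
#'
#' @param x a normalized \code{\link{ReporterSet}}.
#' @param groupA,groupB the two channel-group labels (defaults: the first
#'   level as reference and the second as comparison, e.g. CELL vs EV).
#' @param welch use Welch's unequal-variance t-test instead of pooled.
#' @return A \code{DataFrame} with columns \code{id}, \code{log2fc},
#'   \code{p}, \code{fdr} and placeholder flags \code{enriched}, \code{dap}
#'   (filled by \code{\link{classifyEnriched}} / \code{\link{classifyDap}}).
#' @examples
#' sim <- simulateTmtProteome(nProteins = 50, nMarkers = 5, seed = 1)
#' diff <- differentialAbundance(normalizeReporters(sim))
#' head(diff)
#' @export
differentialAbundance <- function(x, groupA = NULL, groupB = NULL,
                                  welch = FALSE) {
  stopifnot(methods::is(x, "ReporterSet"))
  if (!isNormalized(x))
    stop("'x' must be normalized first (see normalizeReporters)")
  g <- channelGroups(x)
  lev <- unique(g)
  if (is.null(groupA)) groupA <- lev[1]
  if (is.null(groupB)) groupB <- lev[2]
  if (!all(c(groupA, groupB) %in% lev))
    stop("unknown channel group label")
  a <- which(g == groupA); b <- which(g == groupB)
  nA <- length(a); nB <- length(b)
  if (nA < 2L || nB < 2L)
    stop("each group needs >= 2 channels (variance undefined)")
  v <- assay(x, "intensity")
  mA <- rowMeans(v[, a, drop = FALSE])
  mB <- rowMeans(v[, b, drop = FALSE])
  vA <- rowSums((v[, a, drop = FALSE] - mA)^2) / (nA - 1L)
  vB <- rowSums((v[, b, drop = FALSE] - mB)^2) / (nB - 1L)
  if (welch) {
    se <- sqrt(vA / nA + vB / nB)
    df <- (vA / nA + vB / nB)^2 /
      ((vA / nA)^2 / (nA - 1L) + (vB / nB)^2 / (nB - 1L))
  } else {
    sp2 <- ((nA - 1L) * vA + (nB - 1L) * vB) / (nA + nB - 2L)
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
    df <- rep(nA + nB - 2L, nrow(v))
  }
  tstat <- (mB - mA) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  p[se == 0 & mB == mA] <- 1       # identical groups: t = 0/0, no evidence
  out <- DataFrame(id = rownames(v), log2fc = mB - mA, p = p,
                   fdr = bhAdjust(p), enriched = NA, dap = NA)
  metadata(out) <- list(groupA = groupA, groupB = groupB, welch = welch)
  out
}

#' One-sided Fisher (hypergeometric) enrichment p-value
#'
#' For a 2x2 table with \code{k} reference proteins among the \code{K}
#' proteins above a cutoff, \code{n} reference proteins in a universe of
#' \code{N}, returns \eqn{P[X \ge k]} with
#' \eqn{X \sim Hypergeometric(N, n, K)} -- the one-sided (enrichment
#' direction) Fisher exact test.
#'
#' @param k reference proteins above the cutoff.
#' @param K all proteins above the cutoff.
#' @param n reference proteins in the universe.
#' @param N universe size.
#' @return The enrichment p-value in (0, 1].
#' @examples
#' fisherEnrichment(5, 5, 5, 10)  # 1 / choose(10, 5)
#' @export
fisherEnrichment <- function(k, K, n, N) {
  k <- .assertCount(k, "k", min = 0L); K <- .assertCount(K, "K", min = 0L)
  n <- .assertCount(n, "n", min = 0L); N <- .assertCount(N, "N", min = 1L)
  if (K > N || n > N || k > min(K, n))
    stop("inconsistent margins: need k <= min(K, n), K <= N, n <= N")
  stats::phyper(k - 1L, n, N - n, K, lower.tail = FALSE)
}

#' Empirical fold-change cutoff by Fisher sweep against a marker reference
#'
#' Walks a descending grid of candidate log2 fold-change cutoffs and, at
#' each cutoff c, tests whether the reference proteins are over-represented
#' among the proteins with \code{log2fc > c} (one-sided Fisher test over
#' the full quantified universe).  The cutoff is reduced until the
#' enrichment p-value exceeds \code{alpha} for the first time after having
#' been significant; the chosen cutoff is the last significant grid point
#' before that exit (when the p-value stays significant down to the grid
#' floor, the floor itself).  The entry point -- the first grid point at
#' which the sweep reached significance while descending -- is reported
#' alongside so both stopping semantics can be audited.  If no grid point
#' is significant both endpoints are \code{NA} ("undefined"), never
#' silently zero.
#'
#' @param log2fc named numeric vector of per-protein log2 fold changes; the
#'   names define the universe.
#' @param referenceIds marker reference ids (intersected with the universe
#'   before testing; the intersection must be non-empty).
#' @param gridStart,gridStep,gridFloor sweep grid: \code{gridStart} down to
#'   \code{gridFloor} in steps of \code{gridStep} (> 0).
#' @param alpha significance level of the sweep.
#' @return A \code{\linkS4class{SweepResult}}.
#' @examples
#' lfc <- c(setNames(rnorm(90, 0, 0.1), paste0("bg", 1:90)),
#'          setNames(rnorm(10, 2, 0.1), paste0("mk", 1:10)))
#' sweepCutoff(lfc, paste0("mk", 1:10))
#' @export
sweepCutoff <- function(log2fc, referenceIds, gridStart = 3,
                        gridStep = 0.1, gridFloor = 0, alpha = 0.05) {
  if (is.null(names(log2fc)))
    stop("'log2fc' must be named by protein id")
  .assertScalar(gridStep, "gridStep", positive = TRUE)
  .assertProb(alpha, "alpha")
  if (gridStart < gridFloor) stop("empty grid: gridStart < gridFloor")
  universe <- names(log2fc)
  ref <- intersect(unique(as.character(referenceIds)), universe)
  if (length(ref) == 0L)
    stop("reference ids do not intersect the protein universe")
  grid <- seq(gridStart, gridFloor, by = -gridStep)
  N <- length(universe)
  n <- length(ref)
  isRef <- universe %in% ref
  p <- vapply(grid, function(cc) {
    above <- log2fc > cc
    fisherEnrichment(sum(above & isRef), sum(above), n, N)
  }, numeric(1))
  sig <- p <= alpha
  chosen <- NA_real_
  first <- NA_real_
  if (any(sig)) {
    entry <- which(sig)[1]           # significance entry, descending
    first <- grid[entry]
    exit <- which(!sig & seq_along(sig) > entry)
    chosen <- if (length(exit)) grid[exit[1] - 1L] else grid[length(grid)]
  }
  methods::new("SweepResult", grid = grid, p = p, chosenCutoff = chosen,
               firstSignificant = first, alpha = alpha)
}

#' Call EV-enriched proteins
#'
#' A protein is enriched when \code{log2fc > cutoff} and
#' \code{fdr < fdrThreshold} (BH-adjusted p).
#'
#' @param diff a \code{DataFrame} from \code{\link{differentialAbundance}}.
#' @param cutoff log2 fold-change cutoff (default the published 0.7; in a
#'   full run use \code{\link{sweepCutoff}} to derive it empirically).
#' @param fdrThreshold BH FDR threshold.
#' @return A list with \code{ids} (character vector of enriched proteins)
#'   and \code{table} (the input with the \code{enriched} flag set).
#' @export
classifyEnriched <- function(diff, cutoff = 0.7, fdrThreshold = 0.01) {
  stopifnot(all(c("id", "log2fc", "fdr") %in% colnames(diff)))
  flag <- diff$log2fc > cutoff & diff$fdr < fdrThreshold
  diff$enriched <- flag
  list(ids = as.character(diff$id[flag]), table = diff)
}

#' Call differentially abundant proteins (DAPs)
#'
#' A protein is differentially abundant when its raw p-value (not the FDR)
#' is below \code{pThreshold} and \code{|log2fc| > lfcThreshold}.
#'
#' @param diff a \code{DataFrame} from \code{\link{differentialAbundance}}.
#' @param pThreshold raw p-value threshold.
#' @param lfcThreshold absolute log2 fold-change threshold.
#' @return A list with \code{ids} and the flagged \code{table} (column
#'   \code{dap}).
#' @export
classifyDap <- function(diff, pThreshold = 0.05, lfcThreshold = 0.1) {
  stopifnot(all(c("id", "log2fc", "p") %in% colnames(diff)))
  flag <- diff$p < pThreshold & abs(diff$log2fc) > lfcThreshold
  diff$dap <- flag
  list(ids = as.character(diff$id[flag]), table = diff)
}
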