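## Preranked gene set enrichment analysis written from scratch: weighted
## Kolmogorov-Smirnov-like running-sum enrichment score, size-matched
## random-set permutation null, side-wise normalized enrichment score,
## add-one nominal p, and a ratio-estimator FDR q.

#' Build a ranked list from a differential-expression table
#'
#' Orders genes by log2 fold change, descending, with ties kept in stable
#' input order.  Duplicate gene ids or non-finite metrics are errors.
#'
#' @param de a \code{DataFrame}/data.frame with columns \code{id} and
#'   \code{log2fc} (e.g. from \code{\link{nbWaldTest}}), or a named numeric
#'   metric vector.
#' @return Named numeric vector, sorted by metric descending.
#' @export
rankFromDE <- function(de) {
  if (is.numeric(de)) {
    metric <- de
    if (is.null(names(metric))) stop("metric vector must be named")
  } else {
    stopifnot(all(c("id", "log2fc") %in% colnames(de)))
    metric <- stats::setNames(as.numeric(de$log2fc), as.character(de$id))
  }
  if (anyDuplicated(names(metric))) stop("duplicate gene ids in ranking")
  if (any(!is.finite(metric))) stop("non-finite ranking metric")
  metric[order(-metric)]            # order() is stable: ties keep input order
}

## core ES walk; `ranked` must already be sorted descending
.esCore <- function(ranked, hits, weight) {
  N <- length(ranked)
  NH <- length(hits)
  aw <- abs(ranked)^weight
  NR <- sum(aw[hits])
  inc <- rep(-1 / (N - NH), N)
  unweighted <- NR == 0
  inc[hits] <- if (unweighted) 1 / NH else aw[hits] / NR
  run <- cumsum(inc)
  iMax <- which.max(run); iMin <- which.min(run)
  ## signed maximal deviation; exact |max| = |min| ties resolve to the
  ## positive peak, with a small tolerance so the choice is stable under
  ## floating-point accumulation order
  takePos <- run[iMax] >= -run[iMin] - 1e-12
  es <- if (takePos) run[iMax] else run[iMin]
  peak <- if (takePos) iMax else iMin
  list(es = es, runningSum = run, peakIndex = peak, unweighted = unweighted)
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list; members of the set increment the running sum by
#' \eqn{|metric_i|^w / N_R} (with \eqn{N_R} the summed member weight) and
#' non-members decrement it by \eqn{1/(N - N_H)}.  The enrichment score is
#' the running-sum value of maximal absolute deviation from zero, signed
#' (ties prefer the positive peak).  If every member metric is exactly zero
#' (\eqn{N_R = 0}) the hit increments fall back to \eqn{1/N_H} and the
#' result is flagged \code{unweighted}.
#'
#' @param ranked named metric vector sorted descending (see
#'   \code{\link{rankFromDE}}).
#' @param setMembers character vector of member ids; the intersection with
#'   the ranked universe must be non-empty and strictly smaller than it.
#' @param weight metric weight exponent w (1 = the "weighted" scheme).
#' @return A list: \code{es} in [-1, 1], \code{runningSum} (length N),
#'   \code{peakIndex}, \code{unweighted}.
#' @examples
#' r <- rankFromDE(setNames(c(3, 1, -1, -3), paste0("g", 1:4)))
#' enrichmentScore(r, "g1")$es   # +1: the single hit leads the list
#' @export
enrichmentScore <- function(ranked, setMembers, weight = 1) {
  if (is.null(names(ranked))) stop("'ranked' must be named")
  if (is.unsorted(rev(ranked))) stop("'ranked' must be sorted descending")
  hits <- which(names(ranked) %in% setMembers)
  N <- length(ranked)
  if (length(hits) == 0L) stop("set does not intersect the ranked universe")
  if (length(hits) == N) stop("set covers the whole universe")
  .esCore(ranked, hits, weight)
}

#' Permutation null of the enrichment score
#'
#' Draws \code{nperm} uniformly random gene sets of the given size from the
#' ranked universe and returns their enrichment scores -- the preranked
#' null model.
#'
#' @param ranked named metric vector sorted descending.
#' @param setSize size of the random sets (1 <= setSize < N).
#' @param nperm number of permutations.
#' @param weight metric weight exponent.
#' @param seed integer seed (same seed, same sample).
#' @return Numeric vector of \code{nperm} null enrichment scores.
#' @export
permutationNull <- function(ranked, setSize, nperm = 1000L, weight = 1,
                            seed) {
  nperm <- .assertCount(nperm, "nperm")
  setSize <- .assertCount(setSize, "setSize")
  N <- length(ranked)
  if (setSize >= N) stop("setSize must be < length(ranked)")
  .withSeed(seed, {
    vapply(seq_len(nperm), function(i) {
      hits <- sort(sample.int(N, setSize))
      .esCore(ranked, hits, weight)$es
    }, numeric(1))
  })
}

#' Normalized enrichment score and nominal p from a permutation null
#'
#' The NES divides the observed score by the absolute mean of the null
#' scores sharing its sign (side-wise normalization); the nominal p uses
#' the add-one estimator over the same-sign null values with
#' \eqn{|null| \ge |es|}.  When no null value shares the sign, the NES is
#' undefined (\code{NA}) and flagged.
#'
#' @param es observed enrichment score.
#' @param null numeric vector of null enrichment scores.
#' @return A list: \code{nes}, \code{pNominal}, \code{nSameSign},
#'   \code{degenerate}.
#' @export
nesSignificance <- function(es, null) {
  if (length(null) == 0L) stop("empty null sample")
  side <- if (es >= 0) null[null >= 0] else null[null < 0]
  if (length(side) == 0L || mean(abs(side)) == 0) {
    return(list(nes = NA_real_, pNominal = 1 / (1 + length(side)),
                nSameSign = length(side), degenerate = TRUE))
  }
  nes <- es / abs(mean(side))
  p <- (1 + sum(abs(side) >= abs(es))) / (1 + length(side))
  list(nes = nes, pNominal = p, nSameSign = length(side),
       degenerate = FALSE)
}

#' Ratio-estimator FDR q-values for normalized enrichment scores
#'
#' For each observed NES, q is the fraction of pooled same-sign null NES at
#' least as extreme divided by the fraction of observed same-sign NES at
#' least as extreme, clipped to [0, 1] and made monotone within each sign
#' (each set receives the minimum q over sets with smaller-or-equal |NES|,
#' step-up style).
#'
#' @param nes numeric vector of observed NES (NA allowed; returned as NA).
#' @param nullNes pooled vector of normalized null enrichment scores.
#' @return Numeric q-values aligned with \code{nes}.
#' @export
gseaFdr <- function(nes, nullNes) {
  q <- rep(NA_real_, length(nes))
  for (sgn in c(1, -1)) {
    obsIdx <- which(!is.na(nes) & sign(nes) == sgn)
    if (!length(obsIdx)) next
    nullSide <- nullNes[!is.na(nullNes) & sign(nullNes) == sgn]
    obsSide <- nes[obsIdx]
    qi <- vapply(obsSide, function(v) {
      num <- if (length(nullSide)) mean(abs(nullSide) >= abs(v)) else 0
      den <- mean(abs(obsSide) >= abs(v))
      min(1, max(0, num / den))
    }, numeric(1))
    ## step-up monotone within sign: each set takes the minimum q over
    ## sets of smaller-or-equal |NES|, so q never decreases as |NES| drops
    o <- order(abs(obsSide))                 # ascending extremeness
    qi[o] <- cummin(qi[o])
    q[obsIdx] <- qi
  }
  q
}

#' Run preranked GSEA over a gene-set collection
#'
#' Restricts every set to the ranked universe, drops sets outside
#' \code{[setMin, setMax]} (reported in \code{metadata(result)$dropped}),
#' and for each retained set computes the enrichment score, a size-matched
#' permutation null (\code{nperm} draws; nulls are shared between sets of
#' identical restricted size for efficiency), the side-wise NES, the
#' add-one nominal p and the ratio-estimator FDR q.  Deterministic for a
#' fixed seed.
#'
#' @param ranked named metric vector sorted descending (see
#'   \code{\link{rankFromDE}}).
#' @param sets named list of character vectors (e.g. read with
#'   \code{\link{readGeneSets}}).
#' @param nperm permutations per set.
#' @param setMin,setMax retained set-size range after restriction to the
#'   universe.
#' @param weight metric weight exponent (1 = "weighted").
#' @param seed integer seed.
#' @return A \code{DataFrame} with columns \code{name}, \code{size},
#'   \code{es}, \code{nes}, \code{pNominal}, \code{fdrQ}, sorted by
#'   \code{nes} descending; dropped set names in
#'   \code{metadata(result)$dropped}.
#' @examples
#' r <- rankFromDE(setNames(rnorm(100), paste0("g", 1:100)))
#' gs <- simulateGeneSets(names(r), nSets = 5, sizeRange = c(10, 20),
#'                        seed = 2)
#' runGsea(r, gs, nperm = 100, seed = 3)
#' @export
runGsea <- function(ranked, sets, nperm = 1000L, setMin = 5L,
                    setMax = 500L, weight = 1, seed) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("'sets' must be a uniquely named list")
  nperm <- .assertCount(nperm, "nperm")
  setMin <- .assertCount(setMin, "setMin")
  setMax <- .assertCount(setMax, "setMax", min = setMin)
  restricted <- lapply(sets, function(s)
    unique(s[s %in% names(ranked)]))
  size <- lengths(restricted)
  keep <- size >= setMin & size <= setMax
  dropped <- names(sets)[!keep]
  if (!any(keep)) stop("no gene set retained after size filtering")
  restricted <- restricted[keep]
  size <- size[keep]

  es <- vapply(restricted, function(s)
    enrichmentScore(ranked, s, weight)$es, numeric(1))

  ## one null per distinct restricted size, seeded reproducibly
  uSize <- sort(unique(size))
  nulls <- .withSeed(seed, {
    lapply(stats::setNames(uSize, uSize), function(sz) {
      N <- length(ranked)
      vapply(seq_len(nperm), function(i) {
        .esCore(ranked, sort(sample.int(N, sz)), weight)$es
      }, numeric(1))
    })
  })

  nes <- numeric(length(es)); pNom <- numeric(length(es))
  nullNesPool <- vector("list", length(uSize))
  for (j in seq_along(uSize)) {
    nv <- nulls[[j]]
    posMean <- mean(abs(nv[nv >= 0])); negMean <- mean(abs(nv[nv < 0]))
    nn <- ifelse(nv >= 0,
                 if (is.nan(posMean) || posMean == 0) NA_real_
                 else nv / posMean,
                 if (is.nan(negMean) || negMean == 0) NA_real_
                 else nv / negMean)
    nullNesPool[[j]] <- nn
  }
  for (i in seq_along(es)) {
    r <- nesSignificance(es[i], nulls[[as.character(size[i])]])
    nes[i] <- r$nes; pNom[i] <- r$pNominal
  }
  q <- gseaFdr(nes, unlist(nullNesPool))
  out <- DataFrame(name = names(restricted), size = as.integer(size),
                   es = es, nes = nes, pNominal = pNom, fdrQ = q)
  out <- out[order(-out$nes, method = "radix"), ]
  metadata(out) <- list(dropped = dropped, nperm = nperm, setMin = setMin,
                        setMax = setMax, weight = weight, seed = seed)
  out
}
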