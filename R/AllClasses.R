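#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData colData<- rowData<-
NULL

#' ReporterSet: TMT reporter-ion intensities with channel groups
#'
#' A thin \linkS4class{SummarizedExperiment} subclass holding a proteins x
#' channels reporter-ion matrix (assay \code{"intensity"}) together with a
#' two-level channel grouping (e.g. EV vs CELL, or TREATED vs UNTREATED) in
#' \code{colData(x)$group}.  Raw objects carry strictly positive intensities;
#' after \code{\link{normalizeReporters}} the assay holds log2, per-channel
#' median-centred values and \code{isNormalized(x)} is \code{TRUE}.
#'
#' @slot .. inherited from SummarizedExperiment.
#' @seealso \code{\link{ReporterSet}}, \code{\link{normalizeReporters}},
#'   \code{\link{differentialAbundance}}
#' @export
setClass("ReporterSet", contains = "SummarizedExperiment")

setValidity("ReporterSet", function(object) {
  msg <- NULL
  if (!"intensity" %in% names(assays(object)))
    msg <- c(msg, "assay 'intensity' is required")
  if (!"group" %in% names(colData(object)))
    msg <- c(msg, "colData column 'group' is required")
  else {
    g <- colData(object)$group
    if (length(unique(g)) != 2L)
      msg <- c(msg, "channel groups must have exactly two levels")
  }
  if ("intensity" %in% names(assays(object))) {
    v <- assay(object, "intensity")
    if (anyNA(v) || any(!is.finite(v)))
      msg <- c(msg, "intensities must be finite")
    else if (!isTRUE(metadata(object)$normalized) && any(v <= 0))
      msg <- c(msg, "raw intensities must be strictly positive")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a ReporterSet
#'
#' @param intensities numeric matrix, proteins x channels; strictly positive
#'   unless \code{normalized = TRUE} (then interpreted as log2,
#'   median-centred values).
#' @param channelGroups character/factor of length \code{ncol(intensities)}
#'   with exactly two levels.
#' @param normalized logical flag; \code{FALSE} for raw reporter intensities.
#' @param rowData optional \code{DataFrame} of per-protein annotation.
#' @return A \linkS4class{ReporterSet}.
#' @examples
#' m <- matrix(2^rnorm(60, 15), 10, 6,
#'             dimnames = list(paste0("P", 1:10), paste0("ch", 1:6)))
#' rs <- ReporterSet(m, rep(c("CELL", "EV"), each = 3))
#' @export
ReporterSet <- function(intensities, channelGroups, normalized = FALSE,
                        rowData = NULL) {
  intensities <- as.matrix(intensities)
  if (is.null(rownames(intensities)))
    rownames(intensities) <- sprintf("P%04d", seq_len(nrow(intensities)))
  if (is.null(colnames(intensities)))
    colnames(intensities) <- sprintf("ch%02d", seq_len(ncol(intensities)))
  if (length(channelGroups) != ncol(intensities))
    stop("'channelGroups' must label every channel")
  se <- SummarizedExperiment(
    assays = list(intensity = intensities),
    colData = DataFrame(group = as.character(channelGroups),
                        row.names = colnames(intensities)))
  if (!is.null(rowData)) rowData(se) <- rowData
  metadata(se)$normalized <- isTRUE(normalized)
  out <- methods::new("ReporterSet", se)
  methods::validObject(out)
  out
}

#' CountSet: non-negative integer counts with optional condition labels
#'
#' \linkS4class{SummarizedExperiment} subclass for gene- or miRNA-level read
#' counts (assay \code{"counts"}).  When a two-group comparison is intended,
#' \code{colData(x)$condition} carries exactly two levels; per-feature
#' annotation (biotype, planted truth from the simulators) lives in
#' \code{rowData}.
#'
#' @seealso \code{\link{CountSet}}, \code{\link{nbWaldTest}}
#' @export
setClass("CountSet", contains = "SummarizedExperiment")

setValidity("CountSet", function(object) {
  msg <- NULL
  if (!"counts" %in% names(assays(object)))
    msg <- c(msg, "assay 'counts' is required")
  else {
    k <- assay(object, "counts")
    if (anyNA(k) || any(!is.finite(k)) || any(k < 0))
      msg <- c(msg, "counts must be finite and non-negative")
    else if (any(abs(k - round(k)) > 1e-8))
      msg <- c(msg, "counts must be integers")
  }
  if ("condition" %in% names(colData(object))) {
    if (length(unique(colData(object)$condition)) != 2L)
      msg <- c(msg, "'condition' must have exactly two levels")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a CountSet
#'
#' @param counts integer matrix, features x samples, non-negative.
#' @param condition optional sample condition labels (exactly two levels).
#' @param rowData optional per-feature annotation \code{DataFrame} (e.g. a
#'   \code{biotype} column).
#' @return A \linkS4class{CountSet}.
#' @examples
#' k <- matrix(rpois(60, 20), 10, 6,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
#' cs <- CountSet(k, condition = rep(c("untreated", "treated"), each = 3))
#' @export
CountSet <- function(counts, condition = NULL, rowData = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%05d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  cd <- DataFrame(row.names = colnames(counts))
  if (!is.null(condition)) {
    if (length(condition) != ncol(counts))
      stop("'condition' must label every sample")
    cd$condition <- as.character(condition)
  }
  se <- SummarizedExperiment(assays = list(counts = counts), colData = cd)
  if (!is.null(rowData)) rowData(se) <- rowData
  out <- methods::new("CountSet", se)
  methods::validObject(out)
  out
}

#' SweepResult: Fisher-sweep choice of an enrichment fold-change cutoff
#'
#' Result of \code{\link{sweepCutoff}}: the descending cutoff grid, the
#' one-sided Fisher enrichment p-value at each cutoff, and two audit points
#' of the significant run -- \code{chosenCutoff}, the cutoff at which the
#' descending sweep stops: the last significant grid point before the
#' p-value exceeds \code{alpha} (the "reduced until exceeding" stopping
#' rule), and \code{firstSignificant}, the entry point where the sweep
#' first reached significance while descending.  \code{NA} marks an
#' undefined endpoint (never silently zero).
#'
#' @slot grid numeric, strictly decreasing candidate cutoffs.
#' @slot p numeric, Fisher enrichment p per cutoff.
#' @slot chosenCutoff numeric(1), possibly NA.
#' @slot firstSignificant numeric(1), possibly NA.
#' @slot alpha numeric(1), significance level of the sweep.
#' @export
setClass("SweepResult", representation(
  grid = "numeric", p = "numeric",
  chosenCutoff = "numeric", firstSignificant = "numeric", alpha = "numeric"))

setValidity("SweepResult", function(object) {
  msg <- NULL
  if (length(object@grid) == 0L) msg <- c(msg, "empty grid")
  if (length(object@grid) > 1L && any(diff(object@grid) >= 0))
    msg <- c(msg, "grid must be strictly decreasing")
  if (length(object@p) != length(object@grid))
    msg <- c(msg, "p must align with grid")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn SweepResult-class compact display
#' @param object a \code{SweepResult}
#' @export
setMethod("show", "SweepResult", function(object) {
  cat("Fisher-sweep over", length(object@grid), "cutoffs [",
      max(object@grid), "..", min(object@grid), "], alpha =",
      object@alpha, "\n")
  cat("  chosen cutoff (last significant before exceeding alpha):",
      if (is.na(object@chosenCutoff)) "undefined" else object@chosenCutoff,
      "\n")
  cat("  first significant while descending:",
      if (is.na(object@firstSignificant)) "undefined"
      else object@firstSignificant, "\n")
  invisible(object)
})

#' @describeIn ReporterSet-class display with normalization state
#' @param object a \code{ReporterSet}
#' @export
setMethod("show", "ReporterSet", function(object) {
  methods::callNextMethod()
  cat("normalized:", isTRUE(metadata(object)$normalized), "\n")
  invisible(object)
})
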