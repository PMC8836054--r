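#' Accessors for ReporterSet and CountSet
#'
#' Small accessor layer so user code never touches slots directly:
#' \code{channelGroups} returns the two-level channel labels of a
#' \code{ReporterSet}; \code{isNormalized} its normalization flag;
#' \code{sampleConditions} the condition labels of a \code{CountSet} (or
#' \code{NULL}); \code{biotypes} the per-feature biotype labels (or
#' \code{NULL}); \code{truthTable} the planted ground truth emitted by the
#' simulators as a \code{DataFrame}.
#'
#' @param x a \code{ReporterSet} or \code{CountSet}
#' @return See each generic's description.
#' @name accessors
#' @examples
#' sim <- simulateTmtProteome(nProteins = 20, nMarkers = 4, seed = 1)
#' channelGroups(sim)
#' head(truthTable(sim))
NULL

#' @rdname accessors
#' @export
setGeneric("channelGroups", function(x) standardGeneric("channelGroups"))

#' @rdname accessors
#' @export
setMethod("channelGroups", "ReporterSet", function(x)
  stats::setNames(colData(x)$group, colnames(x)))

#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname accessors
#' @export
setMethod("isNormalized", "ReporterSet", function(x)
  isTRUE(metadata(x)$normalized))

#' @rdname accessors
#' @export
setGeneric("sampleConditions", function(x) standardGeneric("sampleConditions"))

#' @rdname accessors
#' @export
setMethod("sampleConditions", "CountSet", function(x) {
  if (!"condition" %in% names(colData(x))) return(NULL)
  stats::setNames(colData(x)$condition, colnames(x))
})

#' @rdname accessors
#' @export
setGeneric("biotypes", function(x) standardGeneric("biotypes"))

#' @rdname accessors
#' @export
setMethod("biotypes", "CountSet", function(x) {
  if (!"biotype" %in% names(rowData(x))) return(NULL)
  stats::setNames(rowData(x)$biotype, rownames(x))
})

#' @rdname accessors
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @rdname accessors
#' @export
setMethod("truthTable", "SummarizedExperiment", function(x) {
  rd <- rowData(x)
  keep <- intersect(c("truthLfc", "isMarker", "isDe", "dispersion",
                      "biotype"), names(rd))
  out <- rd[, keep, drop = FALSE]
  out$id <- rownames(x)
  out[, c("id", keep), drop = FALSE]
})
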