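## Plain-text readers/writers for every pipeline input and output: TSV
## matrices (feature id in the first column, sample/channel headers), GMT
## gene sets, two-column target tables, one-id-per-line marker lists.

.writeTsv <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.readTsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read / write feature-by-sample matrices as TSV
#'
#' The first column holds the feature id; remaining columns are samples or
#' channels.  \code{readCountsTsv} optionally attaches condition labels
#' from a two-column (sample, condition) TSV; \code{readReportersTsv}
#' requires a channel-group TSV (channel, group).
#'
#' @param x matrix-like object or \code{SummarizedExperiment} to write.
#' @param path file path.
#' @param idCol name of the id column written first.
#' @return The readers return a \code{\link{CountSet}} /
#'   \code{\link{ReporterSet}}; the writers return the path invisibly.
#' @name matrix-io
NULL

#' @rdname matrix-io
#' @export
writeMatrixTsv <- function(x, path, idCol = "id") {
  m <- if (methods::is(x, "SummarizedExperiment")) assay(x) else as.matrix(x)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  colnames(df)[1] <- idCol
  .writeTsv(df, path)
}

#' @rdname matrix-io
#' @param conditionFile optional TSV with columns \code{sample},
#'   \code{condition}.
#' @export
readCountsTsv <- function(path, conditionFile = NULL) {
  df <- .readTsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  cond <- NULL
  if (!is.null(conditionFile)) {
    cf <- .readTsv(conditionFile)
    stopifnot(all(c("sample", "condition") %in% colnames(cf)))
    cond <- cf$condition[match(colnames(m), cf$sample)]
    if (anyNA(cond)) stop("condition file does not cover every sample")
  }
  CountSet(m, condition = cond)
}

#' @rdname matrix-io
#' @param groupFile TSV with columns \code{channel}, \code{group}.
#' @param normalized logical; values already log2 median-centred.
#' @export
readReportersTsv <- function(path, groupFile, normalized = FALSE) {
  df <- .readTsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  gf <- .readTsv(groupFile)
  stopifnot(all(c("channel", "group") %in% colnames(gf)))
  grp <- gf$group[match(colnames(m), gf$channel)]
  if (anyNA(grp)) stop("group file does not cover every channel")
  ReporterSet(m, grp, normalized = normalized)
}

#' Read / write gene-set collections (GMT)
#'
#' Reading goes through the standard GMT parser
#' (\code{fgsea::gmtPathways}); writing emits the usual
#' name / description / members layout, one set per line.
#'
#' @param path GMT file path.
#' @param sets named list of character vectors.
#' @param description description field written for every set.
#' @return \code{readGeneSets}: named list; \code{writeGmt}: the path,
#'   invisibly.
#' @name gmt-io
NULL

#' @rdname gmt-io
#' @export
readGeneSets <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname gmt-io
#' @export
writeGmt <- function(sets, path, description = "na") {
  stopifnot(!is.null(names(sets)))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write miRNA-target edge tables and marker lists
#'
#' Target tables are two-column TSVs (\code{mirna}, \code{gene}); marker
#' references are one protein id per line.
#'
#' @param path file path.
#' @param edges data.frame with columns \code{mirna}, \code{gene}.
#' @param ids character vector of marker ids.
#' @return Readers return the parsed object; writers the path, invisibly.
#' @name list-io
NULL

#' @rdname list-io
#' @export
readTargetTsv <- function(path) {
  df <- .readTsv(path)
  stopifnot(all(c("mirna", "gene") %in% colnames(df)))
  df[, c("mirna", "gene")]
}

#' @rdname list-io
#' @export
writeTargetTsv <- function(edges, path) {
  stopifnot(all(c("mirna", "gene") %in% colnames(edges)))
  .writeTsv(edges[, c("mirna", "gene")], path)
}

#' @rdname list-io
#' @export
readMarkerIds <- function(path) {
  ids <- trimws(readLines(path))
  ids[nzchar(ids)]
}

#' @rdname list-io
#' @export
writeMarkerIds <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}
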