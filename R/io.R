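#' Read and write feature-by-sample matrices as TSV
#'
#' The on-disk format has the feature id in the first column and sample
#' ids in the header.
#'
#' @param mat a matrix with rownames (features) and colnames (samples).
#' @param path file path.
#' @param featureCol name of the first (feature id) column on disk.
#' @return \code{readMatrixTSV} returns a numeric matrix with the feature
#'   ids as rownames; \code{writeMatrixTSV} returns the path invisibly.
#' @export
writeMatrixTSV <- function(mat, path, featureCol = "feature") {
  df <- data.frame(rownames(mat), as.data.frame(mat), check.names = FALSE)
  colnames(df)[1] <- featureCol
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMatrixTSV
#' @export
readMatrixTSV <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read a two-column sample-to-group map
#'
#' @param path TSV with columns sample and group/condition (header
#'   optional contentwise; the first two columns are used).
#' @return Named character vector (names = samples).
#' @export
readGroupsTSV <- function(path) {
  df <- read.delim(path)
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Write a DFrame result table as TSV
#'
#' @param df a DFrame or data.frame.
#' @param path file path.
#' @return The path, invisibly.
#' @export
writeTableTSV <- function(df, path) {
  write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
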