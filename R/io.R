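# Plain-text readers/writers for the tab-separated interchange formats.

#' Read a tab-separated count matrix (features x samples)
#'
#' First column = feature ids, remaining columns = samples.
#'
#' @param path File path.
#' @return Integer matrix with feature rownames.
#' @export
readCountMatrix <- function(path) {
    df <- read.delim(path, row.names = 1L, check.names = FALSE)
    as.matrix(df)
}

#' Write a matrix as tab-separated text with a feature id column
#'
#' @param m Matrix with rownames.
#' @param path Output path.
#' @param idColumn Name of the leading id column (default
#'   \code{"feature"}).
#' @return Invisibly, \code{path}.
#' @export
writeCountMatrix <- function(m, path, idColumn = "feature") {
    df <- data.frame(id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1] <- idColumn
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
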