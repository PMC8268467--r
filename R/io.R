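#' Read an OTU count table
#'
#' Reads a sample-by-feature count table from TSV or CSV (first row =
#' feature ids, first column = sample ids, samples in rows) or from a BIOM
#' file (JSON or HDF5 dialect, via the `biomformat` package).  BIOM stores
#' observations (features) in rows, so BIOM input is transposed to the
#' sample-major orientation used throughout this package.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tsv"`, `"csv"` or `"biom"`.
#' @param counts logical; validate entries as counts (non-negative).  Set
#'   `FALSE` to read general real-valued sample tables (e.g. simulated
#'   Gaussian data) with the same layout.
#' @return numeric matrix with sample row names and feature column names.
#' @seealso [write_otu_table()]
#' @export
read_otu_table <- function(path, format = c("auto", "tsv", "csv", "biom"),
                           counts = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", biom = "biom", "tsv")
  }
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM files requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    x <- t(as(biomformat::biom_data(b), "matrix"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            row.names = NULL, check.names = FALSE,
                            stringsAsFactors = FALSE)
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids))
      stop("duplicate sample ids: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    feat <- names(df)[-1L]  # before subsetting, which uniquifies names
    x <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(x))
      stop("non-numeric entries in count table ", path)
    dimnames(x) <- list(ids, feat)
  }
  storage.mode(x) <- "double"
  if (anyDuplicated(colnames(x)))
    stop("duplicate feature ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (counts) {
    neg <- which(x < 0, arr.ind = TRUE)
    if (nrow(neg) > 0L)
      stop("negative count at row '", rownames(x)[neg[1L, 1L]],
           "', column '", colnames(x)[neg[1L, 2L]], "'")
  }
  x
}

#' Write a sample-by-feature table to TSV/CSV
#'
#' Inverse of [read_otu_table()] for the text formats: first row = feature
#' ids, first column (named `sample_id`) = sample ids.
#'
#' @param x numeric matrix with sample row names and feature column names.
#' @param path output file path.
#' @param format `"tsv"` or `"csv"`.
#' @return invisibly, `path`.
#' @export
write_otu_table <- function(x, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  x <- as.matrix(x)
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = if (format == "csv") "," else "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
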