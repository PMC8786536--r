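#' Read a feature x sample matrix from a tab-separated file
#'
#' Expects a header row of sample ids and a first column of row (gene or
#' probe) ids. Plain or gzip files are accepted; CRLF line endings are
#' tolerated.
#'
#' @param path matrix file.
#' @param samples data.frame with columns `sample_id`, `group` (and
#'   optionally `pair`), or NULL to infer groups from `_tumor` / `_normal`
#'   sample-id suffixes.
#' @param type `"expression"` or `"methylation"`.
#' @return an [omics_matrix()].
#' @export
read_omics_matrix <- function(path, samples = NULL,
                              type = c("expression", "methylation")) {
  type <- match.arg(type)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  if (is.null(samples)) {
    group <- ifelse(grepl("_tumor$", colnames(m)), "tumor",
                    ifelse(grepl("_normal$", colnames(m)), "normal", NA))
    if (anyNA(group))
      stop("cannot infer tumor/normal groups from sample ids; ",
           "provide a samples table")
    pair <- sub("_(tumor|normal)$", "", colnames(m))
  } else {
    idx <- match(colnames(m), samples$sample_id)
    if (anyNA(idx)) stop("sample(s) missing from the samples table")
    group <- samples$group[idx]
    pair <- if ("pair" %in% names(samples)) samples$pair[idx] else NULL
  }
  omics_matrix(m, group = group, pair = pair, type = type)
}

#' Write an omics matrix as a tab-separated file
#' @param x an `omics_matrix` (or plain matrix).
#' @param path output file.
#' @param id_col name for the row-id column (default `"id"`).
#' @export
write_matrix_tsv <- function(x, path, id_col = "id") {
  df <- data.frame(rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
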