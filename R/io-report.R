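#' Write a pipeline report table
#'
#' All result tables are emitted as TSV with a header and a stable column and
#' row order; a JSON mirror of the same records is available for downstream
#' tooling.  TSV round-trips losslessly through [read_report()].
#'
#' @param records A data.frame.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @param sort_by Optional character vector of columns used to order rows;
#'   defaults to all of `chrom`, `start`, `transcript_id`, `gene_id`,
#'   `sample_id` that are present.
#' @return `path`, invisibly.
#' @export
write_report <- function(records, path, format = c("tsv", "json"),
                         sort_by = NULL) {
  format <- match.arg(format)
  records <- as.data.frame(records)
  if (is.null(sort_by))
    sort_by <- intersect(c("chrom", "start", "transcript_id", "gene_id",
                           "sample_id"), names(records))
  if (length(sort_by) && nrow(records) > 0L)
    records <- records[do.call(order, records[sort_by]), , drop = FALSE]
  rownames(records) <- NULL
  if (format == "json") {
    jsonlite::write_json(records, path, auto_unbox = FALSE, digits = NA,
                         na = "null")
  } else {
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "NA",
                       fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read back a report written by [write_report()]
#' @param path File path.
#' @param format `"tsv"` or `"json"`.
#' @return data.frame.
#' @export
read_report <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                      comment.char = "", stringsAsFactors = FALSE,
                      colClasses = NA, encoding = "UTF-8")
  }
}
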