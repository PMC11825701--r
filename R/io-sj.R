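#' Read a STAR SJ.out.tab splice-junction table
#'
#' The 9-column STAR dialect: chrom, intron start, intron end (both 1-based
#' inclusive, first/last intronic base), strand code (0 undetermined, 1 `+`,
#' 2 `-`), intron motif code, annotated flag, unique-mapping read count,
#' multi-mapping read count, maximum spliced overhang.  Intron coordinates are
#' stored unchanged (the internal junction convention is the same interval).
#'
#' @param path Path to an SJ.out.tab file (whitespace-separated).
#' @param sample_id Sample label attached to the table; defaults to the file
#'   name without the `.SJ.out.tab`/`.tab` suffix.
#' @return A `junction_count_table`: data.frame with columns `chrom`, `start`,
#'   `end`, `strand` (`+`, `-` or `*` for undetermined), `motif`, `annotated`,
#'   `unique_reads`, `multi_reads`, `max_overhang`, and a `sample_id`
#'   attribute.  An empty file yields a zero-row table.
#' @export
read_sj_table <- function(path, sample_id = NULL) {
  if (is.null(sample_id))
    sample_id <- sub("\\.SJ\\.out\\.tab$|\\.tab$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(junction_count_table(empty_sj_df(), sample_id))
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 9L))
    stop("SJ table ", path, ": expected 9 columns, got ", nf[nf != 9L][1L],
         " at line ", which(nf != 9L)[1L])
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  df <- data.frame(chrom = m[, 1L],
                   start = as.integer(m[, 2L]),
                   end = as.integer(m[, 3L]),
                   strand = c("*", "+", "-")[as.integer(m[, 4L]) + 1L],
                   motif = as.integer(m[, 5L]),
                   annotated = as.integer(m[, 6L]),
                   unique_reads = as.integer(m[, 7L]),
                   multi_reads = as.integer(m[, 8L]),
                   max_overhang = as.integer(m[, 9L]))
  if (anyNA(df$start) || anyNA(df$end) || anyNA(df$strand))
    stop("SJ table ", path, ": unparseable coordinate or strand code")
  if (any(df$start > df$end))
    stop("SJ table ", path, ": intron start > end")
  if (any(df$unique_reads < 0) || any(df$multi_reads < 0))
    stop("SJ table ", path, ": negative read count")
  junction_count_table(df, sample_id)
}

empty_sj_df <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), motif = integer(0), annotated = integer(0),
             unique_reads = integer(0), multi_reads = integer(0),
             max_overhang = integer(0))
}

#' @rdname read_sj_table
#' @param df A data.frame with the columns listed above.
#' @export
junction_count_table <- function(df, sample_id) {
  stopifnot(all(c("chrom", "start", "end", "strand", "unique_reads") %in% names(df)))
  for (col in c("motif", "annotated", "multi_reads", "max_overhang"))
    if (is.null(df[[col]])) df[[col]] <- integer(nrow(df))
  if (any(df$unique_reads < 0) || any(df$multi_reads < 0))
    stop("negative read count in junction table for sample ", sample_id)
  structure(df[, names(empty_sj_df())], sample_id = sample_id,
            class = c("junction_count_table", "data.frame"))
}

#' Write a junction table in the STAR SJ.out.tab dialect
#' @param table A `junction_count_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sj_table <- function(table, path) {
  code <- match(table$strand, c("*", "+", "-")) - 1L
  ord <- order(table$chrom, table$start, table$end)
  lines <- sprintf("%s\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%d",
                   table$chrom[ord], table$start[ord], table$end[ord],
                   code[ord], table$motif[ord], table$annotated[ord],
                   table$unique_reads[ord], table$multi_reads[ord],
                   table$max_overhang[ord])
  writeLines(lines, path)
  invisible(path)
}
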