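#' Read a GTF annotation into transcript models
#'
#' Parses `exon` features (via [rtracklayer::import]); each transcript's exon
#' rows must carry `gene_id` and `transcript_id` attributes.  GTF coordinates
#' are 1-based inclusive, matching the internal convention.
#'
#' @param path Path to a GTF file.
#' @return Named list of [transcript_model()] objects.
#' @export
read_transcripts_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[!is.na(gr$type) & gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon features in ", path)
  gid <- as.character(gr$gene_id)
  tid <- as.character(gr$transcript_id)
  bad <- which(is.na(gid) | is.na(tid) | gid == "" | tid == "")
  if (length(bad))
    stop("exon feature without gene_id/transcript_id in ", path,
         " (exon record ", bad[1L], ")")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   gene_id = gid, transcript_id = tid)
  # one transcript_id must map to a single gene/chrom/strand
  chk <- unique(df[, c("transcript_id", "gene_id", "chrom", "strand")])
  dup <- chk$transcript_id[duplicated(chk$transcript_id)]
  if (length(dup))
    stop("duplicate transcript_id with conflicting attributes: ",
         paste(unique(dup), collapse = ", "))
  rows <- split(df, df$transcript_id)
  models <- lapply(rows, function(d)
    transcript_model(d$transcript_id[1L], d$gene_id[1L], d$chrom[1L],
                     d$strand[1L], d[, c("start", "end")]))
  models[order(names(models))]
}

#' Read a GTF annotation and build the reference index
#' @inheritParams read_transcripts_gtf
#' @return A [reference_index()].
#' @export
read_annotation_gtf <- function(path) reference_index(read_transcripts_gtf(path))

#' Write transcript models as GTF
#'
#' Emits gene, transcript and exon features with deterministic row order
#' (chrom, start, gene, transcript) and attribute order (`gene_id` then
#' `transcript_id`), so fixed inputs give byte-identical files.
#'
#' @param models List of [transcript_model()] objects.
#' @param path Output path.
#' @param source Second GTF column.
#' @return `path`, invisibly.
#' @export
write_annotation_gtf <- function(models, path, source = "isoforge") {
  ids <- vapply(models, `[[`, character(1), "transcript_id")
  names(models) <- ids
  ord <- order(vapply(models, `[[`, character(1), "chrom"),
               vapply(models, function(m) min(m$exons$start), integer(1)),
               vapply(models, `[[`, character(1), "gene_id"),
               ids)
  lines <- character(0)
  seen_gene <- character(0)
  for (m in models[ord]) {
    gs <- min(m$exons$start); ge <- max(m$exons$end)
    if (!m$gene_id %in% seen_gene) {
      lines <- c(lines, sprintf(
        "%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
        m$chrom, source, gs, ge, m$strand, m$gene_id))
      seen_gene <- c(seen_gene, m$gene_id)
    }
    attr_str <- sprintf("gene_id \"%s\"; transcript_id \"%s\";",
                        m$gene_id, m$transcript_id)
    lines <- c(lines, sprintf("%s\t%s\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                              m$chrom, source, gs, ge, m$strand, attr_str))
    lines <- c(lines, sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                              m$chrom, source, m$exons$start, m$exons$end,
                              m$strand, attr_str))
  }
  writeLines(lines, path)
  invisible(path)
}
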