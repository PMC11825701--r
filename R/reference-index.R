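#' Build a reference index from transcript models
#'
#' The index is the novelty oracle used by the structural classifier: it
#' catalogues every reference junction, donor/acceptor splice site, intron,
#' TSS/TES and per-gene merged exon union.
#'
#' Donor/acceptor roles are strand-aware: for a `+`-strand intron the donor is
#' the first intronic base and the acceptor the last; roles swap on `-`.
#'
#' @param models A list of [transcript_model()] objects (names ignored;
#'   `transcript_id`s must be unique).
#' @return An object of class `reference_index` with components
#'   `transcripts` (named list of models), `genes` (gene_id -> transcript ids),
#'   `chains` (per-transcript junction keys), `chain_map` (collapsed chain ->
#'   transcript ids, multi-exon only), `junction_set`, `donor_set`,
#'   `acceptor_set`, `introns` (per-transcript intron data.frames in genomic
#'   order), `tss`/`tes` (per-transcript positions), `exon_union` (per-gene
#'   merged exon intervals) and `gene_span`.
#' @export
reference_index <- function(models) {
  ids <- vapply(models, `[[`, character(1), "transcript_id")
  if (anyDuplicated(ids))
    stop("duplicate transcript_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(models) <- ids

  gene_ids <- vapply(models, `[[`, character(1), "gene_id")
  genes <- split(ids, gene_ids)

  chains <- lapply(models, chain_keys)
  multi <- ids[vapply(chains, length, integer(1)) > 0L]
  chain_map <- split(multi, vapply(chains[multi], paste, character(1), collapse = "|"))

  introns <- lapply(models, splice_chain)
  donor <- character(0); acceptor <- character(0)
  for (id in ids) {
    sc <- introns[[id]]
    if (nrow(sc) == 0L) next
    m <- models[[id]]
    if (m$strand == "+") {
      donor    <- c(donor,    site_key(m$chrom, sc$start, m$strand))
      acceptor <- c(acceptor, site_key(m$chrom, sc$end,   m$strand))
    } else {
      donor    <- c(donor,    site_key(m$chrom, sc$end,   m$strand))
      acceptor <- c(acceptor, site_key(m$chrom, sc$start, m$strand))
    }
  }

  junction_set <- unique(unlist(chains, use.names = FALSE))
  if (is.null(junction_set)) junction_set <- character(0)

  tss <- vapply(models, five_prime_end, integer(1))
  tes <- vapply(models, three_prime_end, integer(1))

  exon_union <- lapply(genes, function(txs) {
    ex <- do.call(rbind, lapply(models[txs], `[[`, "exons"))
    ir <- IRanges::reduce(IRanges::IRanges(ex$start, ex$end))
    data.frame(start = IRanges::start(ir), end = IRanges::end(ir))
  })
  gene_span <- data.frame(
    gene_id = names(genes),
    chrom  = vapply(genes, function(t) models[[t[1L]]]$chrom, character(1)),
    strand = vapply(genes, function(t) models[[t[1L]]]$strand, character(1)),
    start  = vapply(exon_union, function(u) min(u$start), integer(1)),
    end    = vapply(exon_union, function(u) max(u$end), integer(1)),
    row.names = NULL)

  structure(
    list(transcripts = models, genes = genes, chains = chains,
         chain_map = chain_map, junction_set = junction_set,
         donor_set = unique(donor), acceptor_set = unique(acceptor),
         introns = introns, tss = tss, tes = tes,
         exon_union = exon_union, gene_span = gene_span),
    class = "reference_index")
}

#' @export
print.reference_index <- function(x, ...) {
  cat(sprintf("<reference_index> %d transcripts, %d genes, %d junctions\n",
              length(x$transcripts), length(x$genes), length(x$junction_set)))
  invisible(x)
}

#' Introns of a reference transcript in transcript (5'->3') orientation
#'
#' Intron 1 is the intron following exon 1 in transcript orientation, so on
#' the minus strand it is the genomically rightmost intron.
#'
#' @param index A `reference_index`.
#' @param transcript_id Reference transcript id.
#' @return data.frame of intron `start`/`end` (genomic coordinates) in
#'   transcript order.
#' @export
introns_tx_order <- function(index, transcript_id) {
  sc <- index$introns[[transcript_id]]
  if (is.null(sc)) stop("unknown transcript ", transcript_id)
  m <- index$transcripts[[transcript_id]]
  if (m$strand == "-" && nrow(sc) > 1L) sc <- sc[rev(seq_len(nrow(sc))), , drop = FALSE]
  rownames(sc) <- NULL
  sc
}
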