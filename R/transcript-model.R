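#' Construct a transcript model
#'
#' A `transcript_model` is the unit that gets classified and quantified: one
#' transcript's strand-aware exon chain on a single chromosome, plus optional
#' per-sample read support.  All coordinates are 1-based inclusive (the
#' Bioconductor convention); exons are stored sorted by genomic start.
#'
#' @param transcript_id,gene_id Character scalars.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons A data.frame (or 2-column matrix) with columns `start`, `end`,
#'   1-based inclusive.  Exons must be pairwise non-overlapping and separated
#'   by at least one intronic base.
#' @param support Optional named numeric vector of per-sample read counts.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             support = NULL) {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L,
            is.character(gene_id), length(gene_id) == 1L,
            length(chrom) == 1L, length(strand) == 1L)
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-' for transcript ", transcript_id)
  if (is.matrix(exons)) exons <- as.data.frame(exons)
  if (!all(c("start", "end") %in% names(exons)))
    stop("exons must have 'start' and 'end' columns")
  exons <- data.frame(start = as.integer(exons$start),
                      end   = as.integer(exons$end))
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (nrow(exons) < 1L)
    stop("transcript ", transcript_id, " has no exons")
  if (any(exons$start < 1L) || any(exons$end < exons$start))
    stop("invalid exon coordinates in transcript ", transcript_id)
  if (nrow(exons) > 1L) {
    gap <- exons$start[-1L] - exons$end[-nrow(exons)]
    if (any(gap < 2L))
      stop("overlapping or adjacent exons in transcript ", transcript_id)
  }
  if (!is.null(support)) {
    support <- unlist(support)
    if (any(support < 0)) stop("negative support for transcript ", transcript_id)
  }
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id,
         chrom = as.character(chrom), strand = strand,
         exons = exons, support = support),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%d-%d(%s), %d exon(s)\n",
              x$transcript_id, x$gene_id, x$chrom,
              min(x$exons$start), max(x$exons$end), x$strand,
              nrow(x$exons)))
  invisible(x)
}

n_exons <- function(model) nrow(model$exons)

exon_lengths <- function(model) model$exons$end - model$exons$start + 1L

#' Total spliced length of a transcript model
#' @param model A `transcript_model`.
#' @return Integer, summed exon lengths in nt.
#' @export
transcript_length <- function(model) sum(exon_lengths(model))

#' Splice chain of a transcript model
#'
#' The ordered list of introns (donor-acceptor pairs) of a multi-exon
#' transcript, as intron intervals: first intronic base to last intronic base,
#' 1-based inclusive, in genomic order.  Mono-exon transcripts yield zero rows.
#'
#' @param model A `transcript_model`.
#' @return data.frame with columns `start`, `end`; `nrow == n_exons - 1`.
#' @export
splice_chain <- function(model) {
  n <- n_exons(model)
  if (n < 2L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = model$exons$end[-n] + 1L,
             end   = model$exons$start[-1L] - 1L)
}

junction_key <- function(chrom, start, end, strand)
  sprintf("%s:%d-%d:%s", chrom, start, end, strand)

site_key <- function(chrom, pos, strand) sprintf("%s:%d:%s", chrom, pos, strand)

chain_keys <- function(model) {
  sc <- splice_chain(model)
  if (nrow(sc) == 0L) return(character(0))
  junction_key(model$chrom, sc$start, sc$end, model$strand)
}

#' 5' and 3' genomic end of a transcript model
#'
#' Strand-aware: on the minus strand the 5' end is the rightmost genomic
#' coordinate.
#' @param model A `transcript_model`.
#' @return Integer genomic position.
#' @export
five_prime_end <- function(model) {
  if (model$strand == "+") model$exons$start[1L] else model$exons$end[n_exons(model)]
}

#' @rdname five_prime_end
#' @export
three_prime_end <- function(model) {
  if (model$strand == "+") model$exons$end[n_exons(model)] else model$exons$start[1L]
}

# Exons in transcript (5'->3') order.
exons_tx_order <- function(model) {
  if (model$strand == "+") model$exons else model$exons[rev(seq_len(n_exons(model))), , drop = FALSE]
}

#' Map a transcript-coordinate interval to genomic intervals
#'
#' Positions are 1-based inclusive in transcript (spliced, 5'->3') space.
#' The result is a set of genomic exonic intervals, sorted by genomic start.
#'
#' @param model A `transcript_model`.
#' @param from,to Transcript coordinates, `1 <= from <= to <= transcript_length`.
#' @return data.frame with columns `start`, `end` (genomic, 1-based inclusive).
#' @export
tx_to_genomic <- function(model, from, to) {
  L <- transcript_length(model)
  stopifnot(from >= 1L, to >= from, to <= L)
  ex <- exons_tx_order(model)
  lens <- ex$end - ex$start + 1L
  offs <- cumsum(c(0L, lens[-length(lens)]))  # tx pos of base before each exon
  out <- vector("list", nrow(ex))
  for (i in seq_len(nrow(ex))) {
    a <- max(from, offs[i] + 1L)
    b <- min(to, offs[i] + lens[i])
    if (a > b) next
    if (model$strand == "+") {
      gs <- ex$start[i] + (a - offs[i] - 1L)
      ge <- ex$start[i] + (b - offs[i] - 1L)
    } else {
      ge <- ex$end[i] - (a - offs[i] - 1L)
      gs <- ex$end[i] - (b - offs[i] - 1L)
    }
    out[[i]] <- c(gs, ge)
  }
  out <- do.call(rbind, out)
  out <- data.frame(start = out[, 1L], end = out[, 2L])
  out[order(out$start), , drop = FALSE]
}

#' Spliced transcript sequence from a genome
#'
#' Concatenates exon sequences in genomic order and reverse-complements for
#' minus-strand models, so the result reads 5'->3' in transcript orientation.
#'
#' @param model A `transcript_model`.
#' @param genome A [Biostrings::DNAStringSet] keyed by chromosome name.
#' @return Character scalar DNA sequence.
#' @export
transcript_sequence <- function(model, genome) {
  if (!model$chrom %in% names(genome))
    stop("chromosome ", model$chrom, " not in genome")
  chr <- genome[[model$chrom]]
  parts <- Biostrings::DNAStringSet(chr,
                                    start = model$exons$start,
                                    end = model$exons$end)
  seq <- Biostrings::DNAString(paste(as.character(parts), collapse = ""))
  if (model$strand == "-") seq <- Biostrings::reverseComplement(seq)
  as.character(seq)
}
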