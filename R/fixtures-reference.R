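#' Simulation configuration for the synthetic transcriptome generator
#'
#' The generator emulates the inputs of a long-read isoform pipeline: a small
#' genome, a reference annotation of multi-exon coding genes, derived novel
#' isoforms carrying labelled splicing events, per-sample read support, CAGE
#' peaks and splice-junction count tables at known inclusion levels.
#'
#' Gene architecture (transcript orientation): exon 1 is pure 5'UTR; exon 2 is
#' a UTR tail ending in the annotated ATG; exons 3..k-1 are coding with
#' lengths divisible by 3 (codon-aligned boundaries); exon k starts with the
#' TAA stop followed by the 3'UTR.  All sequence outside the annotated ORF is
#' kept free of ATG trigrams, and coding sequence carries periodic codon pairs
#' that force stop codons in both shifted reading frames, so the annotated ORF
#' (or its event-truncated form) is always the unique ORF an ATG-scanning
#' predictor can report.  This is what makes generated truth labels exactly
#' recoverable.
#'
#' @param seed Integer RNG seed; fixing it fixes every emitted byte.
#' @param n_genes Number of genes.
#' @param exons_per_gene Integer range `c(min, max)` of exons per gene
#'   (minimum 6 so every event kind has a feasible host).
#' @param exon_len,intron_len,utr5_exon_len,utr_tail_len,utr3_len,spacer_len
#'   Integer ranges (nt) for coding-exon, intron, first-exon, pre-ATG tail,
#'   3'UTR and intergenic spacer lengths.  Coding-exon lengths are rounded
#'   down to multiples of 3; 3'UTRs stay under the long-3'UTR NMD threshold.
#' @param chrom Chromosome name for the simulated genome.
#' @param samples Number of cohort samples for junction-count simulation.
#' @param depth Expected junction-spanning reads per event per sample (Poisson
#'   mean `D`).
#' @param psi Per-sample inclusion fraction in `[0, 1]` (recycled across
#'   samples).
#' @param strand_mix If `TRUE`, genes alternate between `+` and `-` strands.
#' @param min_flank Minimum intronic flank (nt) retained on each side of a
#'   planted cassette exon.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 20L, exons_per_gene = c(6L, 9L),
                       exon_len = c(90L, 210L), intron_len = c(150L, 400L),
                       utr5_exon_len = c(80L, 160L), utr_tail_len = c(30L, 60L),
                       utr3_len = c(80L, 250L), spacer_len = c(400L, 800L),
                       chrom = "chrT", samples = 6L, depth = 10000,
                       psi = 0.3, strand_mix = TRUE, min_flank = 20L) {
  rng <- function(r, nm) {
    r <- as.integer(r)
    if (length(r) == 1L) r <- c(r, r)
    if (any(r <= 0L) || r[2L] < r[1L]) stop("invalid range for ", nm)
    r
  }
  if (any(psi < 0) || any(psi > 1)) stop("psi must lie in [0, 1]")
  if (depth <= 0) stop("depth must be positive")
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              exons_per_gene = rng(exons_per_gene, "exons_per_gene"),
              exon_len = rng(exon_len, "exon_len"),
              intron_len = rng(intron_len, "intron_len"),
              utr5_exon_len = rng(utr5_exon_len, "utr5_exon_len"),
              utr_tail_len = rng(utr_tail_len, "utr_tail_len"),
              utr3_len = rng(utr3_len, "utr3_len"),
              spacer_len = rng(spacer_len, "spacer_len"),
              chrom = chrom, samples = as.integer(samples), depth = depth,
              psi = psi, strand_mix = isTRUE(strand_mix),
              min_flank = as.integer(min_flank))
  if (cfg$exons_per_gene[1L] < 6L) stop("exons_per_gene minimum is 6")
  if (cfg$exon_len[1L] < 30L) stop("exon_len minimum is 30")
  if (cfg$intron_len[1L] < 60L) stop("intron_len minimum is 60")
  if (cfg$utr_tail_len[1L] < 10L) stop("utr_tail_len minimum is 10")
  if (cfg$utr3_len[2L] > 340L) stop("utr3_len maximum is 340")
  class(cfg) <- "sim_config"
  cfg
}

rand_int <- function(r) if (r[1L] == r[2L]) r[1L] else sample(r[1L]:r[2L], 1L)

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# Replace every ATG trigram (middle T -> C); cannot create new ATGs.
scrub_atg <- function(s) gsub("ATG", "ACG", s, fixed = TRUE)

# ATG- and stop-free random UTR / spacer sequence.
utr_seq <- function(n) scrub_atg(rand_dna(n))

STOP_CODONS <- c("TAA", "TAG", "TGA")
# codon alphabet: no stops, no ATG
SAFE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all3, c(STOP_CODONS, "ATG"))
}
# pair forcing a stop in frame +1 (cTA|Aac) and +2 (gcT|AAc)
PUNCT_CODONS <- c("CTA", "AAC", "GCT", "AAC")

# n coding codons: stop-free in frame 0, no ATG across codon boundaries,
# stops forced in both shifted frames every 8 codons, final codon GCC.
rand_codons <- function(n) {
  out <- character(n)
  prev <- "GG"  # upstream context always safe at exon starts
  for (i in seq_len(n)) {
    slot <- (i - 1L) %% 8L
    if (i == n) {
      cod <- "GCC"
    } else if (slot >= 4L) {
      cod <- PUNCT_CODONS[slot - 3L]
    } else {
      repeat {
        cod <- sample(SAFE_CODONS, 1L)
        tri <- paste0(prev, cod)
        if (!grepl("ATG", tri, fixed = TRUE)) break
      }
    }
    out[i] <- cod
    prev <- substr(cod, 2L, 3L)
  }
  out
}

intron_seq <- function(n) {
  stopifnot(n >= 8L)
  paste0("GT", utr_seq(n - 4L), "AG")
}

# Reverse-translate a peptide, greedily avoiding ATG trigrams across codon
# boundaries.  Used for planted cassette exons.
codons_for_peptide <- function(peptide) {
  tab <- list(
    A = c("GCC", "GCA", "GCG"), C = c("TGC", "TGT"), D = c("GAC", "GAT"),
    E = c("GAA", "GAG"), F = c("TTC", "TTT"), G = c("GGC", "GGA", "GGG"),
    H = c("CAC", "CAT"), I = c("ATC", "ATA", "ATT"), K = c("AAA", "AAG"),
    L = c("CTG", "CTC", "TTA"), M = "ATG", N = c("AAC", "AAT"),
    P = c("CCC", "CCA", "CCG"), Q = c("CAA", "CAG"), R = c("CGC", "AGA", "CGG"),
    S = c("AGC", "TCC", "TCA"), T = c("ACC", "ACA"), V = c("GTC", "GTA"),
    W = "TGG", Y = c("TAC", "TAT"))
  aas <- strsplit(peptide, "")[[1L]]
  out <- character(length(aas))
  prev <- "GG"
  for (i in seq_along(aas)) {
    opts <- tab[[aas[i]]]
    if (is.null(opts)) stop("unknown residue ", aas[i])
    ok <- opts[!vapply(opts, function(c) grepl("ATG", paste0(prev, c),
                                               fixed = TRUE), logical(1))]
    if (length(ok) == 0L)
      stop("cannot encode residue ", aas[i], " without creating an ATG")
    out[i] <- ok[1L]
    prev <- substr(out[i], 2L, 3L)
  }
  out
}

# Build one gene in transcript orientation.  Returns locus sequence plus
# exon intervals (locus coordinates, transcript order) and CDS bookkeeping.
make_gene_locus <- function(cfg) {
  k <- rand_int(cfg$exons_per_gene)
  coding_len <- function() {
    l <- rand_int(cfg$exon_len)
    max(9L, l - l %% 3L)
  }
  lens <- integer(k)
  lens[1L] <- rand_int(cfg$utr5_exon_len)
  lens[2L] <- rand_int(cfg$utr_tail_len) + 3L
  for (j in 3:(k - 1L)) lens[j] <- coding_len()
  lens[k] <- 3L + rand_int(cfg$utr3_len)
  exon_seqs <- character(k)
  exon_seqs[1L] <- utr_seq(lens[1L])
  exon_seqs[2L] <- paste0(utr_seq(lens[2L] - 3L), "ATG")
  for (j in 3:(k - 1L))
    exon_seqs[j] <- paste(rand_codons(lens[j] / 3L), collapse = "")
  exon_seqs[k] <- paste0("TAA", utr_seq(lens[k] - 3L))
  intron_lens <- vapply(seq_len(k - 1L), function(i) rand_int(cfg$intron_len),
                        integer(1))
  intron_seqs <- vapply(intron_lens, intron_seq, character(1))

  pieces <- character(2L * k - 1L)
  pieces[seq(1L, 2L * k - 1L, by = 2L)] <- exon_seqs
  pieces[seq(2L, 2L * k - 2L, by = 2L)] <- intron_seqs
  locus <- paste(pieces, collapse = "")

  starts <- integer(k)
  pos <- 1L
  for (j in seq_len(k)) {
    starts[j] <- pos
    pos <- pos + lens[j] + if (j < k) intron_lens[j] else 0L
  }
  cds_start_tx <- lens[1L] + lens[2L] - 2L
  cds_len <- 3L + sum(lens[3:(k - 1L)]) + 3L
  list(seq = locus, k = k, exon_start = starts, exon_len = lens,
       intron_len = intron_lens,
       cds_tx = c(cds_start_tx, cds_start_tx + cds_len - 1L))
}

#' Generate a synthetic genome and reference annotation
#'
#' Deterministic for a fixed seed: the same `sim_config` always yields the
#' same genome and annotation, byte for byte.  Every gene has one multi-exon
#' coding transcript with an annotated ATG..TAA ORF and canonical GT/AG
#' dinucleotides at every junction on the coding strand.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `sim_reference`: list with `genome`
#'   ([Biostrings::DNAStringSet]), `index` ([reference_index()]), `models`
#'   (reference transcript models), `cds` (per-transcript CDS interval in
#'   transcript coordinates, stop included), `meta` (per-transcript exon
#'   layout) and `config`.
#' @export
make_reference <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  parts <- character(0)
  pos <- 1L
  models <- list()
  cds <- list()
  meta <- list()
  for (g in seq_len(cfg$n_genes)) {
    sp <- utr_seq(rand_int(cfg$spacer_len))
    parts <- c(parts, sp)
    pos <- pos + nchar(sp)
    strand <- if (cfg$strand_mix && g %% 2L == 0L) "-" else "+"
    locus <- make_gene_locus(cfg)
    M <- nchar(locus$seq)
    gseq <- if (strand == "+") locus$seq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(locus$seq)))
    parts <- c(parts, gseq)
    # exon locus interval [a, b] (tx orientation) -> genomic
    a <- locus$exon_start
    b <- a + locus$exon_len - 1L
    if (strand == "+") {
      gs <- pos + a - 1L; ge <- pos + b - 1L
    } else {
      gs <- pos + M - b; ge <- pos + M - a
    }
    gene_id <- sprintf("G%03d", g)
    tx_id <- paste0(gene_id, ".t1")
    models[[tx_id]] <- transcript_model(tx_id, gene_id, cfg$chrom, strand,
                                        data.frame(start = gs, end = ge))
    cds[[tx_id]] <- locus$cds_tx
    meta[[tx_id]] <- list(k = locus$k, exon_len = locus$exon_len,
                          intron_len = locus$intron_len, strand = strand)
    pos <- pos + M
  }
  tail_sp <- utr_seq(200L)
  parts <- c(parts, tail_sp)
  genome <- Biostrings::DNAStringSet(paste(parts, collapse = ""))
  names(genome) <- cfg$chrom
  structure(list(genome = genome, index = reference_index(models),
                 models = models, cds = cds, meta = meta, config = cfg),
            class = "sim_reference")
}

#' @export
print.sim_reference <- function(x, ...) {
  cat(sprintf("<sim_reference> %d genes on %s (%d nt), seed %d\n",
              length(x$index$genes), x$config$chrom,
              sum(Biostrings::width(x$genome)), x$config$seed))
  invisible(x)
}

#' Write a simulated genome as FASTA
#' @param ref A `sim_reference` (or any object with a `genome` DNAStringSet).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(ref, path) {
  genome <- if (inherits(ref, "DNAStringSet")) ref else ref$genome
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Simulate CAGE peaks around reference TSSs
#'
#' A configurable fraction of transcripts receive a peak covering their TSS;
#' the rest receive a decoy peak displaced well beyond the validation window,
#' so end-support rates on the fixture are known exactly.
#'
#' @param index A [reference_index()].
#' @param supported_frac Fraction of transcripts with an on-TSS peak.
#' @param peak_halfwidth Peak half-width in nt.
#' @param miss_offset Displacement (nt, downstream) of decoy peaks.
#' @param seed RNG seed.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (1-based inclusive coordinates) plus a logical `on_tss` truth
#'   column.
#' @export
make_cage_peaks <- function(index, supported_frac = 0.7, peak_halfwidth = 10L,
                            miss_offset = 120L, seed = 1L) {
  set.seed(seed)
  ids <- names(index$transcripts)
  on_tss <- rep(FALSE, length(ids))
  n_on <- round(supported_frac * length(ids))
  if (n_on > 0L) on_tss[sample(seq_along(ids), n_on)] <- TRUE
  rows <- lapply(seq_along(ids), function(i) {
    m <- index$transcripts[[ids[i]]]
    tss <- five_prime_end(m)
    centre <- if (on_tss[i]) tss else
      tss + (if (m$strand == "+") miss_offset else -miss_offset)
    data.frame(chrom = m$chrom, start = max(1L, centre - peak_halfwidth),
               end = centre + peak_halfwidth,
               name = paste0("peak_", ids[i]), score = 1L,
               strand = m$strand, on_tss = on_tss[i])
  })
  do.call(rbind, rows)
}

#' Write CAGE peaks as BED6
#'
#' Converts internal 1-based inclusive intervals to BED's 0-based half-open.
#' @param peaks data.frame from [make_cage_peaks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cage_bed <- function(peaks, path) {
  ord <- order(peaks$chrom, peaks$start)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   peaks$chrom[ord], peaks$start[ord] - 1L, peaks$end[ord],
                   peaks$name[ord], peaks$score[ord], peaks$strand[ord])
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED6 file of CAGE peaks
#' @param path BED path.
#' @return data.frame with 1-based inclusive `start`/`end`.
#' @export
read_cage_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) gr$name else NA_character_,
             score = if (!is.null(gr$score)) as.integer(gr$score) else 0L,
             strand = as.character(GenomicRanges::strand(gr)))
}
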