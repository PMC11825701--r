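#' The ERBB2-like worked-example fixture
#'
#' A deterministic single-gene fixture emulating the ERBB2 i14e pattern: a
#' 22-exon coding gene plus a derived isoform carrying a 102-nt in-frame
#' cassette exon strictly inside intron 14 (between exons 14 and 15).  The
#' cassette encodes 34 residues whose central 19-mer is
#' `SLPRIKLGGGPRGRGHRDW`; the flanking 15 residues are synthetic (the fixture
#' is a stand-in, not the real locus, and documents this split).  A UGG-rich
#' window is planted at 1-based offsets 47..60 downstream of the cassette's
#' 3' end, the remainder of that intronic region being kept UGG-poor so the
#' planted window is the unique top-scoring one.
#'
#' @param seed RNG seed for the synthetic filler sequence.
#' @return List with `genome`, `index` (reference of the parent transcript),
#'   `models` (parent + i14e isoform), `parent_id`, `i14e_id`, `cassette`
#'   (genomic start/end), `host_intron` (genomic start/end),
#'   `host_intron_index` (14), `downstream_seq` (intron sequence 3' of the
#'   cassette, transcript orientation, offset 1 = first intronic base),
#'   `ugg_window` (c(47, 60)), `peptide19`, `cassette_peptide` (34 aa) and
#'   `cds_tx` (parent CDS in transcript coordinates).
#' @export
make_erbb2_like_fixture <- function(seed = 42L) {
  set.seed(seed)
  chrom <- "chrE"
  peptide19 <- "SLPRIKLGGGPRGRGHRDW"
  flank_l <- "GSGSGSG"   # synthetic, not paper-derived
  flank_r <- "GSGSGSGA"  # synthetic, not paper-derived
  cassette_pep <- paste0(flank_l, peptide19, flank_r)  # 34 aa
  cassette <- paste(codons_for_peptide(cassette_pep), collapse = "")  # 102 nt

  k <- 22L
  exon_seqs <- character(k)
  exon_seqs[1L] <- paste0(utr_seq(48L), "ATG",
                          paste(rand_codons(3L), collapse = ""))
  for (j in 2:(k - 1L)) exon_seqs[j] <- paste(rand_codons(40L), collapse = "")
  exon_seqs[k] <- paste0("TAA", utr_seq(150L))

  # intron 14 carries the cassette context:
  # GT | 25 nt filler | AG | cassette (102) | GT | downstream | AG
  up_fill <- utr_seq(25L)
  down_interior <- gsub("TGG", "TCG", utr_seq(265L), fixed = TRUE)
  intron14 <- paste0("GT", up_fill, "AG", cassette, "GT", down_interior, "AG")
  stopifnot(nchar(intron14) == 400L)
  # plant the UGG-rich window at downstream offsets 47..60 (offset 1 = the G
  # of the new donor GT); motif phases chosen so offset 47 is the unique
  # maximal-score window of width 14
  ugg <- "TGGTGGTGGCATGG"
  down_seq <- paste0("GT", down_interior, "AG")  # offsets 1..269
  substr(down_seq, 47L, 60L) <- ugg
  substr(intron14, 132L, 400L) <- down_seq

  intron_seqs <- vapply(rep(200L, k - 1L), intron_seq, character(1))
  intron_seqs[14L] <- intron14
  intron_lens <- nchar(intron_seqs)

  pieces <- character(2L * k - 1L)
  pieces[seq(1L, 2L * k - 1L, by = 2L)] <- exon_seqs
  pieces[seq(2L, 2L * k - 2L, by = 2L)] <- intron_seqs
  locus <- paste(pieces, collapse = "")

  lens <- nchar(exon_seqs)
  starts <- integer(k); pos <- 1L
  for (j in seq_len(k)) {
    starts[j] <- pos
    pos <- pos + lens[j] + if (j < k) intron_lens[j] else 0L
  }
  offset <- 300L
  genome <- Biostrings::DNAStringSet(paste0(utr_seq(offset), locus,
                                            utr_seq(offset)))
  names(genome) <- chrom
  gs <- offset + starts
  ge <- gs + lens - 1L

  parent <- transcript_model("ERBB2L.t1", "ERBB2L", chrom, "+",
                             data.frame(start = gs, end = ge))
  host <- c(ge[14L] + 1L, gs[15L] - 1L)  # genomic intron 14
  cass_gs <- host[1L] + 29L              # intron offsets 30..131
  cass_ge <- cass_gs + 101L
  i14e <- transcript_model("ERBB2L.i14e", "ERBB2L", chrom, "+",
                           rbind(data.frame(start = gs, end = ge),
                                 data.frame(start = cass_gs, end = cass_ge)))

  cds_start <- 49L
  cds_len <- 12L + 20L * 120L + 3L
  list(genome = genome, index = reference_index(list(parent)),
       models = list(parent = parent, i14e = i14e),
       parent_id = "ERBB2L.t1", i14e_id = "ERBB2L.i14e",
       cassette = c(cass_gs, cass_ge), host_intron = host,
       host_intron_index = 14L, downstream_seq = down_seq,
       ugg_window = c(47L, 60L), peptide19 = peptide19,
       cassette_peptide = cassette_pep,
       cds_tx = c(cds_start, cds_start + cds_len - 1L))
}
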