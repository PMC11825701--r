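#' NMD and ORF-classification thresholds
#'
#' Defaults follow common practice for NMD feature calling; the thresholds
#' are deliberately explicit and configurable.
#'
#' @param ptc_rule_nt The 50-nt rule: a stop more than this many nt upstream
#'   of the final exon-exon junction flags the transcript as a PTC/NMD
#'   candidate (strict `>`).
#' @param short_orf_aa ORFs shorter than this (in aa) are `short_ORF`.
#' @param long_utr3_nt 3'UTRs longer than this are an NMD feature.
#' @param min_orf_aa Minimum protein length for [find_orf()] to report an ORF.
#' @param uorf_min_aa Minimum protein length of a counted upstream ORF.
#' @return List of class `nmd_config`.
#' @export
nmd_config <- function(ptc_rule_nt = 50L, short_orf_aa = 100L,
                       long_utr3_nt = 350L, min_orf_aa = 30L,
                       uorf_min_aa = 10L) {
  v <- c(ptc_rule_nt, short_orf_aa, long_utr3_nt, min_orf_aa, uorf_min_aa)
  if (any(v <= 0)) stop("all nmd_config thresholds must be positive")
  list(ptc_rule_nt = as.integer(ptc_rule_nt),
       short_orf_aa = as.integer(short_orf_aa),
       long_utr3_nt = as.integer(long_utr3_nt),
       min_orf_aa = as.integer(min_orf_aa),
       uorf_min_aa = as.integer(uorf_min_aa))
}

# start positions (1-based) of stop codons per frame, as a list frame -> pos
stop_positions <- function(seq) {
  pos <- sort(unlist(lapply(c("TAA", "TAG", "TGA"), function(s)
    as.integer(gregexpr(s, seq, fixed = TRUE)[[1L]]))))
  pos <- pos[pos > 0L]
  split(pos, (pos - 1L) %% 3L)
}

#' Find the ORF of a transcript sequence
#'
#' Longest ATG-initiated open reading frame with an in-frame stop codon;
#' equal lengths break to the 5'-most start.  Nothing is reported when the
#' protein would be shorter than `min_orf_aa`.
#'
#' @param seq DNA sequence in transcript orientation (character or
#'   [Biostrings::DNAString]).
#' @param cfg An [nmd_config()].
#' @return `NULL`, or a list of class `orf_record`: `cds_start`, `cds_end`
#'   (1-based inclusive transcript coordinates, stop codon included),
#'   `protein`, `length_aa`.
#' @export
find_orf <- function(seq, cfg = nmd_config()) {
  seq <- toupper(as.character(seq))
  if (grepl("[^ACGT]", seq)) stop("sequence contains non-ACGT characters")
  atg <- as.integer(gregexpr("ATG", seq, fixed = TRUE)[[1L]])
  if (atg[1L] == -1L) return(NULL)
  stops <- stop_positions(seq)
  best <- NULL
  for (p in atg) {
    fr <- as.character((p - 1L) %% 3L)
    st <- stops[[fr]]
    st <- st[st >= p + 3L]
    if (length(st) == 0L) next
    q <- st[1L]
    aa <- (q - p) / 3L
    if (aa < cfg$min_orf_aa) next
    if (is.null(best) || aa > best$length_aa)
      best <- list(cds_start = p, cds_end = q + 2L, length_aa = aa)
  }
  if (is.null(best)) return(NULL)
  best$protein <- translate_cds(substr(seq, best$cds_start, best$cds_end))
  structure(best[c("cds_start", "cds_end", "protein", "length_aa")],
            class = "orf_record")
}

#' Translate a CDS with the standard genetic code
#'
#' @param cds In-frame DNA (length divisible by 3); a single terminal stop
#'   codon is allowed and excluded from the protein.  An internal stop is an
#'   error (it violates the ORF invariant).
#' @return Character protein sequence.
#' @export
translate_cds <- function(cds) {
  cds <- toupper(as.character(cds))
  if (nchar(cds) %% 3L != 0L) stop("CDS length not divisible by 3")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           no.init.codon = TRUE))
  has_stop <- substr(aa, nchar(aa), nchar(aa)) == "*"
  prot <- if (has_stop) substr(aa, 1L, nchar(aa) - 1L) else aa
  if (grepl("*", prot, fixed = TRUE)) stop("internal stop codon in CDS")
  prot
}

#' NMD features of an ORF on its transcript model
#'
#' `stop_to_last_junction` is the transcript-space distance from the base
#' following the stop codon to the final exon-exon junction; the PTC flag is
#' `stop_to_last_junction > ptc_rule_nt` (strict, so a stop exactly at the
#' threshold is not flagged).  Mono-exon transcripts are never flagged.
#'
#' @param orf An `orf_record` from [find_orf()] (or `NULL`).
#' @param model The corresponding [transcript_model()].
#' @param cfg An [nmd_config()].
#' @return One-row data.frame: `stop_to_last_junction`, `ptc_flag`,
#'   `utr3_len`, `long_utr3_flag`, `uorf_count`.
#' @param seq Optional transcript sequence (recomputed uORF scan needs it;
#'   pass the same sequence given to [find_orf()]).
#' @export
nmd_features <- function(orf, model, cfg = nmd_config(), seq = NULL) {
  L <- transcript_length(model)
  if (is.null(orf))
    return(data.frame(stop_to_last_junction = NA_integer_, ptc_flag = FALSE,
                      utr3_len = NA_integer_, long_utr3_flag = FALSE,
                      uorf_count = 0L))
  if (orf$cds_end > L)
    stop("ORF extends past transcript end for ", model$transcript_id)
  n <- n_exons(model)
  if (n == 1L) {
    d <- NA_integer_; ptc <- FALSE
  } else {
    last_junction <- L - exon_lengths(model)[if (model$strand == "+") n else 1L]
    d <- last_junction - orf$cds_end
    ptc <- d > cfg$ptc_rule_nt
  }
  utr3 <- L - orf$cds_end
  uorf <- 0L
  if (!is.null(seq)) uorf <- count_uorfs(seq, orf$cds_start, cfg)
  data.frame(stop_to_last_junction = d, ptc_flag = ptc, utr3_len = utr3,
             long_utr3_flag = utr3 > cfg$long_utr3_nt, uorf_count = uorf)
}

# ATG-initiated ORFs (>= uorf_min_aa) lying entirely within the 5'UTR
count_uorfs <- function(seq, cds_start, cfg) {
  if (cds_start <= 1L) return(0L)
  seq <- toupper(as.character(seq))
  atg <- as.integer(gregexpr("ATG", seq, fixed = TRUE)[[1L]])
  atg <- atg[atg > 0L & atg < cds_start]
  if (length(atg) == 0L) return(0L)
  stops <- stop_positions(seq)
  n <- 0L
  for (p in atg) {
    st <- stops[[as.character((p - 1L) %% 3L)]]
    st <- st[st >= p + 3L]
    if (length(st) == 0L) next
    q <- st[1L]
    if (q + 2L >= cds_start) next        # not entirely within the 5'UTR
    if ((q - p) / 3L >= cfg$uorf_min_aa) n <- n + 1L
  }
  n
}

# genomic interval set of an ORF, for CDS identity comparison
orf_genomic_cds <- function(orf, model) {
  if (is.null(orf)) return(NULL)
  tx_to_genomic(model, orf$cds_start, orf$cds_end)
}

genomic_stop_key <- function(orf, model) {
  if (is.null(orf)) return(NA_character_)
  g <- tx_to_genomic(model, orf$cds_end - 2L, orf$cds_end)
  paste(model$chrom, min(g$start), max(g$end), sep = ":")
}

# do two proteins differ by exactly one codon indel (identical remainder)?
single_codon_indel <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  if (abs(la - lb) != 1L) return(FALSE)
  if (la < lb) { tmp <- a; a <- b; b <- tmp; la <- nchar(a); lb <- nchar(b) }
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  pre <- 0L
  while (pre < lb && av[pre + 1L] == bv[pre + 1L]) pre <- pre + 1L
  suf <- 0L
  while (suf < lb - pre && av[la - suf] == bv[lb - suf]) suf <- suf + 1L
  pre + suf >= lb
}

#' Assign the five-class ORF consequence of a novel transcript
#'
#' Priority cascade relative to the resolved reference ORF:
#' \enumerate{
#'   \item genomic CDS intervals identical to the reference -> `unchanged_ORF`
#'     (only UTRs changed);
#'   \item NAGNAG: a single acceptor shifted by exactly 3 nt between the two
#'     splice chains, same genomic stop codon, and proteins identical up to
#'     one codon at the shift -> `NAGNAG`;
#'   \item no ORF, or protein shorter than `short_orf_aa` -> `short_ORF`;
#'   \item any NMD feature (PTC by the 50-nt rule, long 3'UTR, upstream ORFs)
#'     -> `PTC_NMD`;
#'   \item otherwise -> `protein_coding_novel`.
#' }
#' Unproductive transcripts often satisfy several criteria; short ORFs are
#' prioritised and the remaining NMD-feature carriers collapse into the PTC
#' class.
#'
#' @param novel_model,novel_orf,novel_nmd The novel transcript, its
#'   [find_orf()] record (may be `NULL`) and [nmd_features()] row.
#' @param ref_model,ref_orf The reference transcript and its ORF.
#' @param cfg An [nmd_config()].
#' @return One-row data.frame: `transcript_id`, `orf_class`, `reference_orf`,
#'   `evidence`.
#' @export
classify_consequence <- function(novel_model, novel_orf, novel_nmd,
                                 ref_model, ref_orf, cfg = nmd_config()) {
  if (is.null(ref_orf))
    stop("no reference ORF resolvable for gene ", novel_model$gene_id)
  res <- function(class, evidence)
    data.frame(transcript_id = novel_model$transcript_id, orf_class = class,
               reference_orf = ref_model$transcript_id, evidence = evidence)

  if (!is.null(novel_orf)) {
    g_new <- orf_genomic_cds(novel_orf, novel_model)
    g_ref <- orf_genomic_cds(ref_orf, ref_model)
    if (isTRUE(all.equal(g_new, g_ref, check.attributes = FALSE)))
      return(res("unchanged_ORF", "identical genomic CDS"))
    if (is_nagnag_pair(novel_model, ref_model) &&
        identical(genomic_stop_key(novel_orf, novel_model),
                  genomic_stop_key(ref_orf, ref_model)) &&
        single_codon_indel(novel_orf$protein, ref_orf$protein))
      return(res("NAGNAG", "3-nt acceptor shift, one-codon indel"))
  }
  if (is.null(novel_orf))
    return(res("short_ORF", "no ORF found"))
  if (novel_orf$length_aa < cfg$short_orf_aa)
    return(res("short_ORF", sprintf("ORF %d aa < %d", novel_orf$length_aa,
                                    cfg$short_orf_aa)))
  ev <- c(if (novel_nmd$ptc_flag) "PTC(50nt)",
          if (novel_nmd$long_utr3_flag) "long_3UTR",
          if (novel_nmd$uorf_count > 0L) "uORF")
  if (length(ev) > 0L)
    return(res("PTC_NMD", paste(ev, collapse = "+")))
  res("protein_coding_novel", "intact novel ORF")
}

# chains differ by exactly one acceptor shifted +/- 3 nt
is_nagnag_pair <- function(novel, ref) {
  a <- splice_chain(novel); b <- splice_chain(ref)
  if (nrow(a) != nrow(b) || nrow(a) == 0L) return(FALSE)
  if (novel$chrom != ref$chrom || novel$strand != ref$strand) return(FALSE)
  # acceptor side: intron end on '+', intron start on '-'
  if (novel$strand == "+") {
    same_d <- a$start == b$start
    diff_a <- a$end - b$end
  } else {
    same_d <- a$end == b$end
    diff_a <- a$start - b$start
  }
  if (!all(same_d)) return(FALSE)
  shifted <- which(diff_a != 0L)
  length(shifted) == 1L && abs(diff_a[shifted]) == 3L
}

#' Resolve reference ORFs and classify ORF consequences for a set of calls
#'
#' The reference ORF is taken from the matched reference transcript for
#' FSM/ISM calls and from the assigned gene's longest-CDS transcript
#' otherwise.
#'
#' @param models Named list of novel [transcript_model()]s.
#' @param calls Their structural calls ([classify_transcripts()]).
#' @param index A [reference_index()].
#' @param genome A [Biostrings::DNAStringSet].
#' @param cfg An [nmd_config()].
#' @return data.frame with one row per classified model: ORF coordinates,
#'   NMD features and `orf_class`.
#' @export
classify_consequences <- function(models, calls, index, genome,
                                  cfg = nmd_config()) {
  ref_orf_cache <- new.env(parent = emptyenv())
  ref_orf_of <- function(tx) {
    if (!exists(tx, ref_orf_cache)) {
      m <- index$transcripts[[tx]]
      assign(tx, find_orf(transcript_sequence(m, genome), cfg), ref_orf_cache)
    }
    get(tx, ref_orf_cache)
  }
  rows <- lapply(names(models), function(id) {
    m <- models[[id]]
    call <- calls[calls$transcript_id == id, , drop = FALSE]
    if (nrow(call) == 0L) stop("no structural call for ", id)
    if (call$category %in% c("FSM", "ISM") && !is.na(call$matched_transcript)) {
      ref_tx <- call$matched_transcript
    } else {
      gene <- call$assigned_gene
      if (is.na(gene) || !gene %in% names(index$genes))
        stop("no reference ORF resolvable for gene ",
             if (is.na(gene)) "<unassigned>" else gene)
      cand <- index$genes[[gene]]
      cds_len <- vapply(cand, function(tx) {
        o <- ref_orf_of(tx)
        if (is.null(o)) 0L else as.integer(o$cds_end - o$cds_start + 1L)
      }, integer(1))
      ref_tx <- cand[order(-cds_len, cand)][1L]
    }
    seq <- transcript_sequence(m, genome)
    orf <- find_orf(seq, cfg)
    nmd <- nmd_features(orf, m, cfg, seq = seq)
    cls <- classify_consequence(m, orf, nmd, index$transcripts[[ref_tx]],
                                ref_orf_of(ref_tx), cfg)
    cbind(data.frame(transcript_id = id,
                     cds_start = if (is.null(orf)) NA_integer_ else orf$cds_start,
                     cds_end = if (is.null(orf)) NA_integer_ else orf$cds_end,
                     length_aa = if (is.null(orf)) NA_integer_ else orf$length_aa),
          nmd, cls[, c("orf_class", "reference_orf", "evidence")])
  })
  do.call(rbind, rows)
}
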