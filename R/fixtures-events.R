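#' Specify a splicing event to plant on a reference gene
#'
#' @param kind One of `exon_skip`, `cryptic_exon`, `intron_retention`,
#'   `alt_tss`, `alt_tes`, `nagnag_shift`, `utr_only`, `ptc_insertion`.
#' @param ... Kind-specific parameters:
#'   \describe{
#'     \item{exon_skip}{`exon`: transcript-order index of the coding exon to
#'       skip (default: random feasible).}
#'     \item{cryptic_exon}{`host_intron`: transcript-order intron index;
#'       `len`: cassette length in nt, `>= 6` and divisible by 3 (in-frame;
#'       use `ptc_insertion` for a stop-bearing cassette); `offset`: cassette
#'       start within the intron (default: centred).}
#'     \item{intron_retention}{`intron`: internal intron to retain (a stop
#'       codon is planted near its 5' end so the ORF consequence is exact).}
#'     \item{alt_tss}{drops the purely untranslated first exon.}
#'     \item{alt_tes}{`trim`: nt trimmed from the 3'UTR end (default 30).}
#'     \item{nagnag_shift}{3-nt acceptor shift at the intron downstream of the
#'       start codon (NAGNAG tandem acceptor).}
#'     \item{utr_only}{`extend`: nt added upstream of the first exon
#'       (default 50).}
#'     \item{ptc_insertion}{`host_intron`, `len`, `offset` as for
#'       `cryptic_exon`, plus `stop_codon`: 1-based codon index inside the
#'       cassette replaced by TAA (default 2).}
#'   }
#' @return A list of class `event_spec`.
#' @export
event_spec <- function(kind = c("exon_skip", "cryptic_exon",
                                "intron_retention", "alt_tss", "alt_tes",
                                "nagnag_shift", "utr_only", "ptc_insertion"),
                       ...) {
  kind <- match.arg(kind)
  params <- list(...)
  if (kind %in% c("cryptic_exon", "ptc_insertion")) {
    len <- params$len %||% if (kind == "cryptic_exon") 102L else 60L
    if (len < 6L) stop("cassette length must be >= 6 nt")
    if (kind == "cryptic_exon" && len %% 3L != 0L)
      stop("cryptic_exon length must be divisible by 3 (in-frame); ",
           "use ptc_insertion for frame-disrupting cassettes")
    params$len <- as.integer(len)
  }
  structure(list(kind = kind, params = params), class = "event_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tx-orientation offset within an intron -> genomic start of a patch of
# length len (sequence must be reverse-complemented on '-').
intron_patch_start <- function(intron_gs, intron_ge, strand, offset, len) {
  if (strand == "+") intron_gs + offset - 1L
  else intron_ge - offset - len + 2L
}

patch_genome <- function(genome, chrom, gstart, seq_tx, strand) {
  if (strand == "-")
    seq_tx <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_tx)))
  x <- genome[[chrom]]
  Biostrings::subseq(x, gstart, gstart + nchar(seq_tx) - 1L) <- Biostrings::DNAString(seq_tx)
  genome[[chrom]] <- x
  genome
}

ref_protein_aa <- function(ref, tx) (diff(ref$cds[[tx]]) + 1L) / 3L - 1L

# arithmetic ORF-consequence truth for a truncating event, mirroring the
# five-class cascade thresholds (short-ORF 100 aa, minimum ORF 30 aa)
truncated_class <- function(protein_aa, short_orf_aa = 100L, min_orf_aa = 30L) {
  if (protein_aa < short_orf_aa) "short_ORF" else "PTC_NMD"
}

#' Plant a splicing event, returning the novel isoform and its truth record
#'
#' The returned isoform differs from its parent transcript only by the
#' specified event.  Cassette-bearing events patch the genome inside the host
#' intron (canonical AG/GT written at the new junctions; cassette content
#' ATG-free except planted signals), which never alters any reference
#' transcript's sequence.  Infeasible events raise an error rather than being
#' silently truncated.
#'
#' @param ref A `sim_reference` from [make_reference()].
#' @param gene_id Gene to derive the isoform from.
#' @param event An [event_spec()].
#' @param seed Optional RNG seed for the event's random choices.
#' @return List with `model` (the novel [transcript_model()]), `truth`
#'   (one-row data.frame: expected structural category, expected ORF class,
#'   planted coordinates) and `ref` (the reference with any genome patches
#'   applied).
#' @export
apply_event <- function(ref, gene_id, event, seed = NULL) {
  stopifnot(inherits(ref, "sim_reference"), inherits(event, "event_spec"))
  if (!is.null(seed)) set.seed(seed)
  txs <- ref$index$genes[[gene_id]]
  if (is.null(txs)) stop("unknown gene ", gene_id)
  tx <- txs[1L]
  m <- ref$models[[tx]]
  meta <- ref$meta[[tx]]
  k <- meta$k
  lens <- meta$exon_len
  ex_tx <- exons_tx_order(m)          # genomic exon intervals, tx order
  intr_tx <- introns_tx_order(ref$index, tx)
  p <- event$params
  strand <- m$strand
  P <- ref_protein_aa(ref, tx)
  cum_cds_aa <- function(upto) (3L + if (upto >= 3L) sum(lens[3:upto]) else 0L) / 3L

  new_id <- NULL; exons <- NULL
  truth <- data.frame(transcript_id = NA_character_, gene_id = gene_id,
                      kind = event$kind, category = NA_character_,
                      orf_class = NA_character_, host_intron = NA_integer_,
                      cassette_start = NA_integer_, cassette_end = NA_integer_,
                      protein_aa = NA_real_, parent = tx,
                      stringsAsFactors = FALSE)

  if (event$kind == "exon_skip") {
    feas <- 3:(k - 1L)
    j <- p$exon %||% if (length(feas) == 1L) feas else sample(feas, 1L)
    if (!j %in% feas) stop("exon ", j, " of ", tx, " is not a skippable coding exon")
    exons <- ex_tx[-j, , drop = FALSE]
    new_id <- sprintf("%s.skip%d", tx, j)
    aa <- P - lens[j] / 3L
    truth$category <- "NIC"
    truth$orf_class <- if (aa < 30L) "short_ORF"
      else if (aa < 100L) "short_ORF" else "protein_coding_novel"
    truth$protein_aa <- aa
  } else if (event$kind == "intron_retention") {
    feas <- 3:(k - 2L)
    if (length(feas) == 0L) stop("no internal coding intron in ", tx)
    j <- p$intron %||% if (length(feas) == 1L) feas else sample(feas, 1L)
    if (!j %in% feas) stop("intron ", j, " of ", tx, " is not internal coding")
    # plant GTC TAA at intron tx-offsets 3..6
    gs <- intron_patch_start(intr_tx$start[j], intr_tx$end[j], strand, 3L, 4L)
    ref$genome <- patch_genome(ref$genome, m$chrom, gs, "CTAA", strand)
    merged <- c(min(ex_tx$start[j], ex_tx$start[j + 1L], intr_tx$start[j]),
                max(ex_tx$end[j], ex_tx$end[j + 1L], intr_tx$end[j]))
    exons <- ex_tx[-(j + 1L), , drop = FALSE]
    exons$start[j] <- merged[1L]; exons$end[j] <- merged[2L]
    new_id <- sprintf("%s.ir%d", tx, j)
    aa <- cum_cds_aa(j) + 1L
    truth$category <- "NIC"
    truth$orf_class <- truncated_class(aa)
    truth$host_intron <- j
    truth$protein_aa <- aa
  } else if (event$kind %in% c("cryptic_exon", "ptc_insertion")) {
    L <- p$len
    flank <- ref$config$min_flank
    need <- L + 2L * flank + 6L
    feas <- which(meta$intron_len >= need & seq_len(k - 1L) >= 2L)
    feas <- feas[feas <= k - 1L & feas >= 2L]
    if (length(feas) == 0L)
      stop("no intron of ", tx, " can host a ", L, " nt cassette (need >= ",
           need, " nt)")
    j <- p$host_intron %||% if (length(feas) == 1L) feas else sample(feas, 1L)
    if (!j %in% feas)
      stop("intron ", j, " of ", tx, " cannot host a ", L, " nt cassette")
    n_int <- meta$intron_len[j]
    o <- p$offset %||% max(flank + 3L, floor((n_int - L) / 2L))
    if (o < flank + 3L || o + L - 1L > n_int - flank - 2L)
      stop("cassette offset ", o, " leaves insufficient intronic flank")
    n_cod <- ceiling(L / 3L)
    cass <- rand_codons(n_cod)
    cass <- substr(paste(cass, collapse = ""), 1L, L)
    stop_idx <- NA_integer_
    if (event$kind == "ptc_insertion") {
      stop_idx <- as.integer(p$stop_codon %||% 2L)
      if (stop_idx < 1L || stop_idx * 3L > L)
        stop("stop_codon index outside cassette")
      substr(cass, stop_idx * 3L - 2L, stop_idx * 3L) <- "TAA"
    }
    gs <- intron_patch_start(intr_tx$start[j], intr_tx$end[j], strand,
                             o - 2L, L + 4L)
    ref$genome <- patch_genome(ref$genome, m$chrom, gs,
                               paste0("AG", cass, "GT"), strand)
    if (strand == "+") {
      cs <- intr_tx$start[j] + o - 1L
    } else {
      cs <- intr_tx$end[j] - o - L + 2L
    }
    ce <- cs + L - 1L
    exons <- rbind(ex_tx, data.frame(start = cs, end = ce))
    new_id <- sprintf("%s.%s%d", tx,
                      if (event$kind == "cryptic_exon") "ce" else "ptc", j)
    truth$category <- "NNC"
    truth$host_intron <- j
    truth$cassette_start <- cs
    truth$cassette_end <- ce
    if (event$kind == "cryptic_exon") {
      aa <- P + L / 3L
      truth$orf_class <- if (aa < 100L) "short_ORF" else "protein_coding_novel"
      truth$protein_aa <- aa
    } else {
      aa <- cum_cds_aa(j) + (stop_idx - 1L)
      truth$orf_class <- truncated_class(aa)
      truth$protein_aa <- aa
    }
  } else if (event$kind == "nagnag_shift") {
    j <- 2L  # intron downstream of the start codon
    n_int <- meta$intron_len[j]
    gs <- intron_patch_start(intr_tx$start[j], intr_tx$end[j], strand,
                             n_int - 5L, 6L)
    ref$genome <- patch_genome(ref$genome, m$chrom, gs, "CAGCAG", strand)
    exons <- ex_tx
    if (strand == "+") exons$start[3L] <- exons$start[3L] - 3L
    else exons$end[3L] <- exons$end[3L] + 3L
    new_id <- paste0(tx, ".nagnag")
    truth$category <- "NNC"
    truth$orf_class <- "NAGNAG"
    truth$protein_aa <- P + 1L
  } else if (event$kind == "alt_tss") {
    exons <- ex_tx[-1L, , drop = FALSE]
    new_id <- paste0(tx, ".tss")
    truth$category <- "ISM"
    truth$orf_class <- "unchanged_ORF"
    truth$protein_aa <- P
  } else if (event$kind == "alt_tes") {
    d <- as.integer(p$trim %||% 30L)
    if (lens[k] - d < 13L) stop("alt_tes trim ", d, " would reach the stop codon")
    exons <- ex_tx
    if (strand == "+") exons$end[k] <- exons$end[k] - d
    else exons$start[k] <- exons$start[k] + d
    new_id <- paste0(tx, ".tes")
    truth$category <- "FSM"
    truth$orf_class <- "unchanged_ORF"
    truth$protein_aa <- P
  } else if (event$kind == "utr_only") {
    d <- as.integer(p$extend %||% 50L)
    exons <- ex_tx
    if (strand == "+") exons$start[1L] <- exons$start[1L] - d
    else exons$end[1L] <- exons$end[1L] + d
    if (any(exons$start < 1L)) stop("utr_only extension runs off the chromosome")
    # rescrub the extension window (plus the 2 boundary bases of exon 1) in
    # transcript orientation: intergenic sequence is only ATG-free as plus
    # text, and ATGs could otherwise appear in the extended 5'UTR
    win_start <- if (strand == "+") exons$start[1L] else exons$end[1L] - d - 1L
    win <- Biostrings::DNAString(as.character(
      Biostrings::subseq(ref$genome[[m$chrom]], win_start, win_start + d + 1L)))
    if (strand == "-") win <- Biostrings::reverseComplement(win)
    ref$genome <- patch_genome(ref$genome, m$chrom, win_start,
                               scrub_atg(as.character(win)), strand)
    new_id <- paste0(tx, ".utr")
    truth$category <- "FSM"
    truth$orf_class <- "unchanged_ORF"
    truth$protein_aa <- P
  }

  model <- transcript_model(new_id, gene_id, m$chrom, strand, exons)
  truth$transcript_id <- new_id
  list(model = model, truth = truth, ref = ref)
}

#' Simulate a labelled isoform atlas
#'
#' Builds a reference with [make_reference()] and plants one event per gene,
#' cycling deterministically through the eight event kinds, then draws
#' per-sample read support for every isoform.  The result feeds every
#' downstream stage and carries full truth labels.
#'
#' @param cfg A [sim_config()].
#' @param kinds Event kinds to cycle through (default: all eight).
#' @param support_mean Range of per-sample Poisson means for read support.
#' @param low_support_frac Fraction of novel isoforms forced to near-zero
#'   support so the read-support filter has work to do.
#' @return List with `ref` (patched `sim_reference`), `models` (parents +
#'   novel isoforms, with support attached), `truth` (data.frame of truth
#'   records for the novel isoforms) and `support` (matrix isoform x sample).
#' @export
simulate_atlas <- function(cfg, kinds = c("exon_skip", "cryptic_exon",
                                          "intron_retention", "nagnag_shift",
                                          "utr_only", "alt_tss", "alt_tes",
                                          "ptc_insertion"),
                           support_mean = c(5, 50), low_support_frac = 0.1) {
  ref <- make_reference(cfg)
  genes <- names(ref$index$genes)
  truths <- list()
  novel <- list()
  for (i in seq_along(genes)) {
    ev <- event_spec(kinds[(i - 1L) %% length(kinds) + 1L])
    res <- apply_event(ref, genes[i], ev)
    ref <- res$ref
    novel[[res$model$transcript_id]] <- res$model
    truths[[i]] <- res$truth
  }
  models <- c(ref$models, novel)
  n <- length(models); s <- cfg$samples
  lam <- stats::runif(n, support_mean[1L], support_mean[2L])
  low <- stats::runif(n) < low_support_frac &
    names(models) %in% names(novel)
  lam[low] <- 0.3
  support <- matrix(stats::rpois(n * s, rep(lam, s)), nrow = n,
                    dimnames = list(names(models), sprintf("S%02d", seq_len(s))))
  for (id in names(models)) models[[id]]$support <- support[id, ]
  list(ref = ref, models = models, truth = do.call(rbind, truths),
       support = support)
}
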