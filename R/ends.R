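#' Configuration for transcript-end validation
#'
#' @param window Distance window (nt) for calling a 5' end CAGE-supported or
#'   a TSS/TES close to annotation; inclusive (`distance <= window`).
#' @param polya_motifs Hexamers scanned near the 3' end (uppercase DNA).
#' @param search_span Number of terminal transcript nt scanned for polyA
#'   motifs.
#' @param cage_same_strand Restrict CAGE peaks to the transcript's strand
#'   (peaks with undefined strand always match).
#' @return List of class `end_config`.
#' @export
end_config <- function(window = 50L, polya_motifs = c("AATAAA", "ATTAAA"),
                       search_span = 50L, cage_same_strand = TRUE) {
  if (window <= 0L) stop("window must be positive")
  if (!all(grepl("^[ACGT]+$", polya_motifs)))
    stop("polya motifs must be uppercase DNA")
  list(window = as.integer(window), polya_motifs = polya_motifs,
       search_span = as.integer(search_span),
       cage_same_strand = isTRUE(cage_same_strand))
}

interval_distance <- function(pos, start, end) pmax(start - pos, pos - end, 0L)

#' 5' end support from CAGE peaks and annotated TSSs
#'
#' The transcript's strand-aware 5' end is compared with CAGE peak intervals
#' (distance 0 when inside a peak) and with annotated reference TSSs; the
#' closest distance is kept.  TSS distance is signed, positive when the query
#' end lies downstream of the annotated site.
#'
#' @param model A [transcript_model()].
#' @param cage_peaks data.frame from [read_cage_bed()]/[make_cage_peaks()]
#'   (may be `NULL`).
#' @param index A [reference_index()].
#' @param cfg An [end_config()].
#' @return One-row data.frame: `transcript_id`, `cage_distance`,
#'   `cage_within_window`, `tss_distance`.
#' @export
tss_support <- function(model, cage_peaks, index, cfg = end_config()) {
  p5 <- five_prime_end(model)
  cage_d <- NA_integer_
  if (!is.null(cage_peaks) && nrow(cage_peaks) > 0L) {
    pk <- cage_peaks[cage_peaks$chrom == model$chrom, , drop = FALSE]
    if (cfg$cage_same_strand && nrow(pk) > 0L)
      pk <- pk[pk$strand %in% c(model$strand, "*", "."), , drop = FALSE]
    if (nrow(pk) > 0L)
      cage_d <- min(interval_distance(p5, pk$start, pk$end))
  }
  tss_d <- NA_integer_
  ids <- names(index$transcripts)
  same <- vapply(index$transcripts, function(r)
    r$chrom == model$chrom && r$strand == model$strand, logical(1))
  if (any(same)) {
    ref_tss <- index$tss[ids[same]]
    signed <- if (model$strand == "+") p5 - ref_tss else ref_tss - p5
    tss_d <- signed[order(abs(signed), signed)][1L]
  }
  data.frame(transcript_id = model$transcript_id,
             cage_distance = cage_d,
             cage_within_window = !is.na(cage_d) & cage_d <= cfg$window,
             tss_distance = tss_d)
}

#' 3' end support from polyA motifs and annotated TESs
#'
#' Scans the final `search_span` nt of the spliced transcript sequence
#' (strand-corrected) for any configured polyA hexamer and reports the
#' 3'-most hit; the offset is the number of nt between the motif's last base
#' and the transcript 3' end.  TES distance is signed as in [tss_support()].
#'
#' @param model A [transcript_model()].
#' @param genome A [Biostrings::DNAStringSet].
#' @param index A [reference_index()] (for TES distances; may be `NULL`).
#' @param cfg An [end_config()].
#' @return One-row data.frame: `transcript_id`, `polya_motif_found`,
#'   `polya_motif`, `polya_offset`, `tes_distance`.
#' @export
polya_support <- function(model, genome, index = NULL, cfg = end_config()) {
  seq <- transcript_sequence(model, genome)
  L <- nchar(seq)
  span <- min(cfg$search_span, L)
  tail_seq <- substr(seq, L - span + 1L, L)
  best_end <- -1L; best_motif <- NA_character_
  for (motif in cfg$polya_motifs) {
    m <- gregexpr(motif, tail_seq, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) next
    ends <- m + nchar(motif) - 1L
    if (max(ends) > best_end) {
      best_end <- max(ends)
      best_motif <- motif
    }
  }
  found <- best_end > 0L
  offset <- if (found) span - best_end else NA_integer_
  tes_d <- NA_integer_
  if (!is.null(index)) {
    p3 <- three_prime_end(model)
    ids <- names(index$transcripts)
    same <- vapply(index$transcripts, function(r)
      r$chrom == model$chrom && r$strand == model$strand, logical(1))
    if (any(same)) {
      ref_tes <- index$tes[ids[same]]
      signed <- if (model$strand == "+") p3 - ref_tes else ref_tes - p3
      tes_d <- signed[order(abs(signed), signed)][1L]
    }
  }
  data.frame(transcript_id = model$transcript_id,
             polya_motif_found = found, polya_motif = best_motif,
             polya_offset = offset, tes_distance = tes_d)
}

#' End support for a set of transcript models
#'
#' Joins [tss_support()] and [polya_support()] per transcript.
#'
#' @param models List of [transcript_model()] objects.
#' @inheritParams tss_support
#' @inheritParams polya_support
#' @return data.frame with one row per transcript.
#' @export
end_supports <- function(models, cage_peaks, genome, index,
                         cfg = end_config()) {
  rows <- lapply(models, function(m) {
    cbind(tss_support(m, cage_peaks, index, cfg),
          polya_support(m, genome, index, cfg)[, -1L, drop = FALSE])
  })
  do.call(rbind, rows)
}

#' Per-category end-support rates and distance histogram
#'
#' For each structural category, the fraction of transcripts whose 5' end is
#' CAGE-supported within the window and whose 3' end carries a polyA motif,
#' plus a binned table of signed TSS/TES distances for density plotting.
#'
#' @param supports data.frame from [end_supports()].
#' @param calls data.frame of structural calls (joined on `transcript_id`).
#' @param breaks Histogram breaks (nt) for the signed distances.
#' @return List with `rates` (per-category data.frame: `n`, `cage_rate`,
#'   `polya_rate`) and `distance_hist` (long data.frame: `end`, `bin`, `n`).
#' @export
end_summary <- function(supports, calls,
                        breaks = c(-Inf, -200, -100, -50, -10, 0, 10, 50,
                                   100, 200, Inf)) {
  df <- merge(supports, calls[, c("transcript_id", "category")],
              by = "transcript_id")
  cats <- intersect(c("FSM", "ISM", "NIC", "NNC"), unique(df$category))
  rates <- do.call(rbind, lapply(cats, function(cc) {
    d <- df[df$category == cc, , drop = FALSE]
    data.frame(category = cc, n = nrow(d),
               cage_rate = mean(d$cage_within_window, na.rm = TRUE),
               polya_rate = mean(d$polya_motif_found, na.rm = TRUE))
  }))
  hist_one <- function(x, label) {
    x <- x[!is.na(x)]
    b <- cut(x, breaks = breaks)
    data.frame(end = label, bin = levels(b), n = as.integer(table(b)))
  }
  list(rates = rates,
       distance_hist = rbind(hist_one(df$tss_distance, "tss"),
                             hist_one(df$tes_distance, "tes")))
}
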