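#' Define a cassette-exon inclusion event
#'
#' Junctions are intron intervals (first..last intronic base, 1-based
#' inclusive — the SJ.out.tab convention): two inclusion junctions (host
#' donor -> cassette acceptor; cassette donor -> host acceptor) and one
#' exclusion junction (the intact host intron), which must span both.
#'
#' @param name Event name.
#' @param chrom,strand Location.
#' @param inclusion data.frame of 2 rows (`start`, `end`), genomic order.
#' @param exclusion Length-2 vector or 1-row data.frame (`start`, `end`).
#' @return List of class `event_def`.
#' @export
event_def <- function(name, chrom, strand, inclusion, exclusion) {
  if (is.numeric(exclusion)) exclusion <- data.frame(start = exclusion[1L],
                                                     end = exclusion[2L])
  inclusion <- inclusion[order(inclusion$start), , drop = FALSE]
  if (nrow(inclusion) != 2L) stop("exactly 2 inclusion junctions required")
  if (exclusion$start > inclusion$start[1L] ||
      exclusion$end < inclusion$end[2L])
    stop("exclusion junction must span both inclusion junctions")
  structure(list(name = name, chrom = chrom, strand = strand,
                 inclusion = inclusion, exclusion = exclusion),
            class = "event_def")
}

#' Derive an event definition from a strict cryptic-exon call
#'
#' The exclusion junction is the host reference intron; the inclusion
#' junctions run from the host donor to the cassette acceptor and from the
#' cassette donor to the host acceptor.
#'
#' @param call One row from [detect_intron_derived_exons()] (strict mode).
#' @param index A [reference_index()].
#' @param name Event name (defaults to the call's transcript id).
#' @return An [event_def()].
#' @export
event_from_cryptic_call <- function(call, index, name = NULL) {
  if (call$mode != "strict")
    stop("event definitions require a strict-mode call ",
         "(relaxed calls need not match the host intron's flanks)")
  host <- index$transcripts[[call$host_transcript_id]]
  ri <- index$introns[[call$host_transcript_id]]
  n_int <- nrow(ri)
  ii <- if (host$strand == "+") call$host_intron_index
        else n_int - call$host_intron_index + 1L
  hs <- ri$start[ii]; he <- ri$end[ii]
  event_def(name %||% paste0(call$transcript_id, ".event"),
            host$chrom, host$strand,
            inclusion = data.frame(start = c(hs, call$exon_end + 1L),
                                   end = c(call$exon_start - 1L, he)),
            exclusion = c(hs, he))
}

lookup_junction <- function(table, chrom, start, end, strand) {
  hit <- table$chrom == chrom & table$start == start & table$end == end &
    (table$strand == strand | table$strand == "*")
  if (!any(hit)) return(0L)
  sum(table$unique_reads[hit])
}

#' Quantify a cassette event in one junction table
#'
#' The supporting-read ratio is
#' `mean(inc_up, inc_down) / (mean(inc_up, inc_down) + exc)` (a sum-based
#' alternative is available); junctions absent from the table count as zero
#' and an all-zero event yields an undefined (NA) ratio.  Presence requires
#' at least `min_reads_each_inclusion` unique reads on *each* inclusion
#' junction.  Only unique-mapping reads are counted.
#'
#' @param event An [event_def()].
#' @param table A `junction_count_table`.
#' @param min_reads_each_inclusion Presence threshold (default 2).
#' @param ratio_method `"mean"` (default) or `"sum"`.
#' @return One-row data.frame: `sample_id`, `inc_up`, `inc_down`, `exc`,
#'   `ratio`, `present`.
#' @export
quantify_event <- function(event, table, min_reads_each_inclusion = 2L,
                           ratio_method = c("mean", "sum")) {
  ratio_method <- match.arg(ratio_method)
  if (min_reads_each_inclusion < 1L)
    stop("min_reads_each_inclusion must be >= 1")
  inc_up <- lookup_junction(table, event$chrom, event$inclusion$start[1L],
                            event$inclusion$end[1L], event$strand)
  inc_down <- lookup_junction(table, event$chrom, event$inclusion$start[2L],
                              event$inclusion$end[2L], event$strand)
  exc <- lookup_junction(table, event$chrom, event$exclusion$start,
                         event$exclusion$end, event$strand)
  inc <- if (ratio_method == "mean") mean(c(inc_up, inc_down))
         else inc_up + inc_down
  denom <- inc + exc
  ratio <- if (denom > 0) inc / denom else NA_real_
  data.frame(sample_id = attr(table, "sample_id") %||% NA_character_,
             inc_up = inc_up, inc_down = inc_down, exc = exc, ratio = ratio,
             present = inc_up >= min_reads_each_inclusion &
               inc_down >= min_reads_each_inclusion)
}

#' Cohort prevalence of a cassette event
#'
#' Applies [quantify_event()] to every sample and reports the fraction of
#' samples in which the event is present.  The presence threshold is
#' reported alongside (it is an assumption, so prevalence should be read as
#' a function of it).
#'
#' @param event An [event_def()].
#' @param tables List of `junction_count_table`s (unique sample ids).
#' @param min_reads_each_inclusion Presence threshold.
#' @param ratio_method Passed to [quantify_event()].
#' @return List with `quants` (per-sample data.frame), `prevalence`
#'   (fraction present) and `threshold`.
#' @export
cohort_prevalence <- function(event, tables, min_reads_each_inclusion = 2L,
                              ratio_method = "mean") {
  quants <- do.call(rbind, lapply(tables, quantify_event, event = event,
                                  min_reads_each_inclusion = min_reads_each_inclusion,
                                  ratio_method = ratio_method))
  if (anyDuplicated(quants$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(quants$sample_id[duplicated(quants$sample_id)]),
               collapse = ", "))
  list(quants = quants, prevalence = mean(quants$present),
       threshold = min_reads_each_inclusion)
}

#' Relative supporting-read ratios and group comparison
#'
#' Each sample's ratio is normalised by the baseline group's mean ratio, so
#' the baseline group has mean relative ratio 1 by construction.  With
#' exactly two groups a two-sided Welch t test on the relative ratios is
#' reported.
#'
#' @param quants data.frame from [quantify_event()]/[cohort_prevalence()].
#' @param groups Named character vector or factor of group labels per
#'   sample_id (or a vector aligned with `quants` rows).
#' @param baseline Baseline group label.
#' @return List with `per_sample` (sample, group, ratio, relative_ratio),
#'   `group_means`, and for two groups `t_statistic`, `p_value`.
#' @export
relative_support_ratio <- function(quants, groups, baseline) {
  g <- if (!is.null(names(groups))) unname(groups[quants$sample_id])
       else as.character(groups)
  if (length(g) != nrow(quants)) stop("group labels do not match samples")
  if (!baseline %in% g) stop("baseline group ", baseline, " not present")
  base_mean <- mean(quants$ratio[g == baseline], na.rm = TRUE)
  if (!is.finite(base_mean) || base_mean <= 0)
    stop("baseline group mean ratio is zero or undefined")
  per_sample <- data.frame(sample_id = quants$sample_id, group = g,
                           ratio = quants$ratio,
                           relative_ratio = quants$ratio / base_mean)
  gm <- stats::aggregate(relative_ratio ~ group, per_sample, mean)
  out <- list(per_sample = per_sample, group_means = gm)
  if (length(unique(g)) == 2L) {
    other <- setdiff(unique(g), baseline)
    a <- per_sample$relative_ratio[g == other]
    b <- per_sample$relative_ratio[g == baseline]
    if (stats::var(a) + stats::var(b) > 0) {
      tt <- stats::t.test(a, b, alternative = "two.sided")
      out$t_statistic <- unname(tt$statistic)
      out$p_value <- tt$p.value
    } else {
      out$t_statistic <- 0
      out$p_value <- 1
    }
  }
  out
}

#' Scan for UGG-rich windows downstream of a cassette exon
#'
#' Slides a fixed-width window along the given intronic sequence (sense
#' orientation, position 1 = first intronic base after the exon's 3' end)
#' counting possibly-overlapping motif occurrences; windows whose motif
#' fraction reaches `min_motif_fraction` are reported ranked by motif count,
#' ties going to the 5'-most window.  The motif defaults to TGG on sense DNA
#' (UGG in the transcript), the ESRP binding element.
#'
#' @param intron_seq Character DNA sequence.
#' @param motif Motif (default `"TGG"`).
#' @param window_len Window width in nt (default 14).
#' @param min_motif_fraction Minimum fraction of window bases covered by
#'   motif hits for a window to be reported (default 0.5).
#' @param search_range Optional cap: scan only the first `search_range` nt.
#' @return data.frame ranked as described: `start`, `end` (1-based offsets
#'   downstream of the exon), `count`, `fraction`.  Zero rows when the
#'   sequence is shorter than the window or no window qualifies.
#' @export
scan_ugg_rich <- function(intron_seq, motif = "TGG", window_len = 14L,
                          min_motif_fraction = 0.5, search_range = NULL) {
  if (window_len < 3L) stop("window_len must be >= 3")
  seq <- toupper(as.character(intron_seq))
  if (!is.null(search_range)) seq <- substr(seq, 1L, search_range)
  L <- nchar(seq)
  empty <- data.frame(start = integer(0), end = integer(0),
                      count = integer(0), fraction = numeric(0))
  if (L < window_len) return(empty)
  hits <- as.integer(gregexpr(paste0("(?=", motif, ")"), seq,
                              perl = TRUE)[[1L]])
  hits <- hits[hits > 0L]
  starts <- seq_len(L - window_len + 1L)
  count <- vapply(starts, function(w)
    sum(hits >= w & hits + nchar(motif) - 1L <= w + window_len - 1L),
    integer(1))
  fraction <- count * nchar(motif) / window_len
  keep <- fraction >= min_motif_fraction
  if (!any(keep)) return(empty)
  out <- data.frame(start = starts[keep], end = starts[keep] + window_len - 1L,
                    count = count[keep], fraction = fraction[keep])
  out[order(-out$count, out$start), , drop = FALSE]
}
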