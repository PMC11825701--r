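#' Classify a transcript model against the reference annotation
#'
#' SQANTI-style structural categories.  Multi-exon rules, applied to the
#' splice chain (the ordered set of introns):
#' \itemize{
#'   \item FSM (full splice match): the chain equals a same-strand reference
#'     chain.  When several references share the chain, the match with the
#'     smallest total end distance is reported (ties broken by transcript id).
#'   \item ISM (incomplete splice match): the chain is a contiguous proper
#'     sub-chain of a reference chain (5'- or 3'-truncation).
#'   \item NIC: neither, but every splice site is a known donor or acceptor.
#'   \item NNC: at least one splice site is novel.
#' }
#' Mono-exon: FSM if contained within a same-strand reference mono-exon
#' transcript; otherwise `genic` when overlapping a same-strand gene,
#' `antisense` when overlapping only the opposite strand, `intergenic`
#' otherwise.  A transcript whose exons overlap two non-overlapping
#' same-strand genes is labelled `fusion_like` and excluded downstream.
#'
#' @param model A [transcript_model()].
#' @param index A [reference_index()].
#' @param mono_tolerance Mono-exon containment slack in nt (default 0, exact
#'   containment).
#' @return A one-row data.frame (`structural_call`): `transcript_id`,
#'   `gene_id` (as given), `category`, `novelty` (known/novel, see
#'   [reannotate()]), `assigned_gene`, `matched_transcript`,
#'   `n_novel_junctions`, `n_novel_sites`, plus list-columns
#'   `novel_junctions` and `novel_sites`.
#' @export
classify_transcript <- function(model, index, mono_tolerance = 0L) {
  out <- data.frame(transcript_id = model$transcript_id,
                    gene_id = model$gene_id,
                    category = NA_character_, novelty = NA_character_,
                    assigned_gene = NA_character_,
                    matched_transcript = NA_character_,
                    n_novel_junctions = 0L, n_novel_sites = 0L,
                    stringsAsFactors = FALSE)
  out$novel_junctions <- list(character(0))
  out$novel_sites <- list(character(0))

  if (n_exons(model) == 1L) {
    res <- classify_mono_exon(model, index, mono_tolerance)
    out$category <- res$category
    out$assigned_gene <- res$assigned_gene
    out$matched_transcript <- res$matched_transcript
    return(out)
  }

  keys <- chain_keys(model)
  chain_str <- paste(keys, collapse = "|")

  # FSM: exact chain match
  hit <- index$chain_map[[chain_str]]
  if (!is.null(hit)) {
    best <- fsm_tie_break(model, hit, index)
    out$category <- "FSM"
    out$matched_transcript <- best
    out$assigned_gene <- index$transcripts[[best]]$gene_id
    return(out)
  }

  # ISM: contiguous proper sub-chain of one reference chain
  for (rid in names(index$chains)) {
    rc <- index$chains[[rid]]
    if (index$transcripts[[rid]]$strand != model$strand) next
    if (length(rc) <= length(keys)) next
    pos <- match(keys[1L], rc)
    if (is.na(pos)) next
    if (pos + length(keys) - 1L <= length(rc) &&
        identical(rc[pos:(pos + length(keys) - 1L)], keys)) {
      out$category <- "ISM"
      out$matched_transcript <- rid
      out$assigned_gene <- index$transcripts[[rid]]$gene_id
      return(out)
    }
  }

  ov <- gene_overlaps(model, index)
  same <- ov[ov$strand == model$strand & ov$exonic > 0L, , drop = FALSE]
  if (nrow(same) >= 2L && !genes_overlap_each_other(same$gene_id, index)) {
    out$category <- "fusion_like"
    out$assigned_gene <- same$gene_id[which.max(same$exonic)]
    return(out)
  }
  if (nrow(same) >= 1L) {
    out$assigned_gene <- same$gene_id[which.max(same$exonic)]
  } else if (any(ov$strand != model$strand)) {
    out$category <- "antisense"
    return(out)
  } else {
    out$category <- "intergenic"
    return(out)
  }

  # NIC vs NNC by splice-site novelty (union of donor and acceptor sets)
  sc <- splice_chain(model)
  known <- c(index$donor_set, index$acceptor_set)
  sites <- c(site_key(model$chrom, sc$start, model$strand),
             site_key(model$chrom, sc$end, model$strand))
  novel_sites <- setdiff(sites, known)
  novel_junctions <- setdiff(keys, index$junction_set)
  out$n_novel_sites <- length(novel_sites)
  out$n_novel_junctions <- length(novel_junctions)
  out$novel_sites <- list(novel_sites)
  out$novel_junctions <- list(novel_junctions)
  out$category <- if (length(novel_sites) > 0L) "NNC" else "NIC"
  out
}

fsm_tie_break <- function(model, candidates, index) {
  if (length(candidates) == 1L) return(candidates)
  d <- vapply(candidates, function(id) {
    r <- index$transcripts[[id]]
    abs(five_prime_end(model) - five_prime_end(r)) +
      abs(three_prime_end(model) - three_prime_end(r))
  }, numeric(1))
  candidates[order(d, candidates)][1L]
}

classify_mono_exon <- function(model, index, tol) {
  s <- model$exons$start[1L]; e <- model$exons$end[1L]
  res <- list(category = NA_character_, assigned_gene = NA_character_,
              matched_transcript = NA_character_)
  for (rid in names(index$transcripts)) {
    r <- index$transcripts[[rid]]
    if (n_exons(r) != 1L || r$strand != model$strand || r$chrom != model$chrom) next
    if (s >= r$exons$start[1L] - tol && e <= r$exons$end[1L] + tol) {
      res$category <- "FSM"
      res$matched_transcript <- rid
      res$assigned_gene <- r$gene_id
      return(res)
    }
  }
  ov <- gene_overlaps(model, index)
  same <- ov[ov$strand == model$strand, , drop = FALSE]
  if (nrow(same) >= 1L) {
    res$category <- "genic"
    res$assigned_gene <- same$gene_id[which.max(same$exonic + same$span)]
  } else if (nrow(ov) >= 1L) {
    res$category <- "antisense"
  } else {
    res$category <- "intergenic"
  }
  res
}

# per-gene exonic and span overlap (bp) of a model, both strands
gene_overlaps <- function(model, index) {
  gs <- index$gene_span
  gs <- gs[gs$chrom == model$chrom, , drop = FALSE]
  if (nrow(gs) == 0L)
    return(data.frame(gene_id = character(0), strand = character(0),
                      exonic = integer(0), span = integer(0)))
  q <- IRanges::IRanges(model$exons$start, model$exons$end)
  span_ov <- vapply(seq_len(nrow(gs)), function(i) {
    g <- IRanges::IRanges(gs$start[i], gs$end[i])
    sum(IRanges::width(IRanges::intersect(q, g)))
  }, integer(1))
  keep <- span_ov > 0L
  gs <- gs[keep, , drop = FALSE]
  exonic <- vapply(gs$gene_id, function(g) {
    u <- index$exon_union[[g]]
    r <- IRanges::IRanges(u$start, u$end)
    sum(IRanges::width(IRanges::intersect(q, r)))
  }, integer(1))
  data.frame(gene_id = gs$gene_id, strand = gs$strand,
             exonic = exonic, span = span_ov[keep], row.names = NULL)
}

genes_overlap_each_other <- function(gene_ids, index) {
  gs <- index$gene_span
  gs <- gs[match(gene_ids, gs$gene_id), , drop = FALSE]
  for (i in seq_len(nrow(gs) - 1L))
    for (j in (i + 1L):nrow(gs))
      if (gs$start[i] <= gs$end[j] && gs$start[j] <= gs$end[i]) return(TRUE)
  FALSE
}

#' Classify a list of transcript models
#' @param models List of [transcript_model()] objects.
#' @inheritParams classify_transcript
#' @return data.frame with one `structural_call` row per model.
#' @export
classify_transcripts <- function(models, index, mono_tolerance = 0L) {
  rows <- lapply(models, classify_transcript, index = index,
                 mono_tolerance = mono_tolerance)
  do.call(rbind, rows)
}

#' Detect intron-derived (cryptic) cassette exons
#'
#' Reports internal exons lying strictly inside a reference intron of the
#' assigned gene.  In `strict` mode the query junctions flanking the exon
#' must reuse the host intron's donor and acceptor (the i14e pattern: the
#' cassette is spliced into an otherwise intact intron); `relaxed` mode drops
#' the flank-matching conditions.  Exons overlapping any reference exon of
#' the assigned gene are never reported.
#'
#' @param model A [transcript_model()].
#' @param call Its `structural_call` row (needs `assigned_gene`).
#' @param index A [reference_index()].
#' @param mode `"strict"` or `"relaxed"`.
#' @return data.frame (possibly empty): `transcript_id`, `exon_start`,
#'   `exon_end`, `host_transcript_id`, `host_intron_index` (1-based,
#'   transcript orientation), `mode`.
#' @export
detect_intron_derived_exons <- function(model, call, index,
                                        mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  empty <- data.frame(transcript_id = character(0), exon_start = integer(0),
                      exon_end = integer(0), host_transcript_id = character(0),
                      host_intron_index = integer(0), mode = character(0))
  gene <- call$assigned_gene
  if (is.na(gene) || n_exons(model) < 3L) return(empty)
  u <- index$exon_union[[gene]]
  uref <- IRanges::IRanges(u$start, u$end)
  sc <- splice_chain(model)
  out <- list()
  for (i in 2:(n_exons(model) - 1L)) {
    es <- model$exons$start[i]; ee <- model$exons$end[i]
    if (length(IRanges::findOverlaps(IRanges::IRanges(es, ee), uref)) > 0L)
      next
    for (rid in index$genes[[gene]]) {
      ri <- index$introns[[rid]]
      if (nrow(ri) == 0L) next
      if (index$transcripts[[rid]]$strand != model$strand) next
      inside <- which(ri$start < es & ee < ri$end)
      if (length(inside) == 0L) next
      for (ii in inside) {
        if (mode == "strict") {
          # flanking query introns must reuse the host intron's boundaries
          up_ok <- any(sc$start == ri$start[ii] & sc$end == es - 1L)
          down_ok <- any(sc$start == ee + 1L & sc$end == ri$end[ii])
          if (!(up_ok && down_ok)) next
        }
        n_int <- nrow(ri)
        idx_tx <- if (model$strand == "+") ii else n_int - ii + 1L
        out[[length(out) + 1L]] <- data.frame(
          transcript_id = model$transcript_id, exon_start = es, exon_end = ee,
          host_transcript_id = rid, host_intron_index = idx_tx, mode = mode)
      }
    }
  }
  if (length(out) == 0L) return(empty)
  unique(do.call(rbind, out))
}

#' Filter transcript models on total read support
#'
#' Retains models whose summed support across samples reaches `min_support`
#' (default 3: models with fewer than 3 supporting reads are dropped).
#'
#' @param models List of [transcript_model()] objects with `support` set.
#' @param min_support Minimum total read count (default 3).
#' @return List with `retained` (models) and `dropped` (data.frame drop log:
#'   `transcript_id`, `total_support`, `reason`).
#' @export
filter_models <- function(models, min_support = 3L) {
  if (min_support < 1L) stop("min_support must be >= 1")
  totals <- vapply(models, function(m) {
    if (is.null(m$support))
      stop("no support counts for transcript ", m$transcript_id)
    sum(m$support)
  }, numeric(1))
  keep <- totals >= min_support
  dropped <- data.frame(
    transcript_id = vapply(models[!keep], `[[`, character(1), "transcript_id"),
    total_support = unname(totals[!keep]),
    reason = sprintf("support %d < %d", as.integer(totals[!keep]),
                     as.integer(min_support)))
  list(retained = models[keep], dropped = dropped)
}

#' Re-annotate structural calls into known and novel, with a subtype tally
#'
#' FSM transcripts are `known`; every other category is `novel` by default
#' (the treatment of ISM is configurable since truncated matches are
#' sometimes counted as known).
#'
#' @param calls data.frame of `structural_call` rows.
#' @param ism_known Count ISM as known (default `FALSE`).
#' @return List with `calls` (input plus `novelty` column) and `tally`
#'   (data.frame of per-category counts; sums to `nrow(calls)`).
#' @export
reannotate <- function(calls, ism_known = FALSE) {
  known_cats <- c("FSM", if (ism_known) "ISM")
  calls$novelty <- ifelse(calls$category %in% known_cats, "known", "novel")
  lv <- c("FSM", "ISM", "NIC", "NNC", "genic", "antisense", "intergenic",
          "fusion_like")
  tally <- as.data.frame(table(category = factor(calls$category, levels = lv)),
                         responseName = "n")
  list(calls = calls, tally = tally)
}
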