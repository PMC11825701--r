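# Brute-force structural-classification oracle: exhaustive enumeration over
# raw exon tables, written independently of the package's indexed classifier.

oracle_introns <- function(exons) {
  exons <- exons[order(exons$start), , drop = FALSE]
  n <- nrow(exons)
  if (n < 2) return(NULL)
  data.frame(start = exons$end[-n] + 1L, end = exons$start[-1L] - 1L)
}

oracle_classify <- function(model, ref_models) {
  ex <- model$exons[order(model$exons$start), , drop = FALSE]
  same <- Filter(function(r) r$chrom == model$chrom &&
                   r$strand == model$strand, ref_models)
  anti <- Filter(function(r) r$chrom == model$chrom &&
                   r$strand != model$strand, ref_models)
  ov_bp <- function(a, b)  # overlap bp between two exon tables
    sum(outer(seq_len(nrow(a)), seq_len(nrow(b)), Vectorize(function(i, j)
      max(0L, min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]) + 1L))))

  if (nrow(ex) == 1L) {
    for (r in same) {
      re <- r$exons
      if (nrow(re) == 1L && ex$start >= re$start && ex$end <= re$end)
        return("FSM")
    }
    genes_s <- split(same, vapply(same, `[[`, "", "gene_id"))
    for (g in genes_s) {
      span <- range(unlist(lapply(g, function(r) c(r$exons$start, r$exons$end))))
      if (ex$start <= span[2] && ex$end >= span[1]) return("genic")
    }
    for (r in anti)
      if (ex$start <= max(r$exons$end) && ex$end >= min(r$exons$start))
        return("antisense")
    return("intergenic")
  }

  qi <- oracle_introns(ex)
  qkey <- paste(qi$start, qi$end)
  for (r in same) {
    ri <- oracle_introns(r$exons)
    if (!is.null(ri) && identical(paste(ri$start, ri$end), qkey)) return("FSM")
  }
  for (r in same) {
    ri <- oracle_introns(r$exons)
    if (is.null(ri) || nrow(ri) <= nrow(qi)) next
    rkey <- paste(ri$start, ri$end)
    for (i in seq_len(length(rkey) - length(qkey) + 1L))
      if (identical(rkey[i:(i + length(qkey) - 1L)], qkey)) return("ISM")
  }
  genes_s <- split(same, vapply(same, `[[`, "", "gene_id"))
  hit_genes <- names(genes_s)[vapply(genes_s, function(g)
    sum(vapply(g, function(r) ov_bp(ex, r$exons), numeric(1))) > 0,
    logical(1))]
  if (length(hit_genes) >= 2L) {
    spans <- lapply(genes_s[hit_genes], function(g)
      range(unlist(lapply(g, function(r) c(r$exons$start, r$exons$end)))))
    disjoint <- TRUE
    for (i in seq_along(spans)[-1]) for (j in seq_len(i - 1L))
      if (spans[[i]][1] <= spans[[j]][2] && spans[[j]][1] <= spans[[i]][2])
        disjoint <- FALSE
    if (disjoint) return("fusion_like")
  }
  if (length(hit_genes) == 0L) {
    for (r in anti)
      if (min(ex$start) <= max(r$exons$end) && max(ex$end) >= min(r$exons$start))
        return("antisense")
    return("intergenic")
  }
  sites <- unlist(lapply(same, function(r) {
    ri <- oracle_introns(r$exons)
    if (is.null(ri)) NULL else c(ri$start, ri$end)
  }))
  qsites <- c(qi$start, qi$end)
  if (all(qsites %in% sites)) "NIC" else "NNC"
}

# random query transcripts of every flavour, built from a reference
random_query <- function(ref, i) {
  models <- ref$models
  tx <- models[[sample(length(models), 1L)]]
  ex <- tx$exons
  n <- nrow(ex)
  mode <- sample(c("copy", "trim", "subchain", "skip", "shift", "mono",
                   "anti", "inter"), 1L)
  id <- sprintf("q%04d", i)
  mk <- function(exons, strand = tx$strand)
    transcript_model(id, "query", tx$chrom, strand, exons)
  jitter_ends <- function(e) {
    e$start[1L] <- max(1L, e$start[1L] + sample(-40:40, 1L))
    e$end[nrow(e)] <- e$end[nrow(e)] + sample(-40:40, 1L)
    if (e$end[nrow(e)] < e$start[nrow(e)]) e$end[nrow(e)] <- e$start[nrow(e)] + 5L
    e
  }
  if (mode == "copy") return(mk(ex))
  if (mode == "trim") return(mk(jitter_ends(ex)))
  if (mode == "subchain" && n >= 4L) {
    a <- sample(1:(n - 2L), 1L); b <- sample((a + 1L):(n - 1L), 1L)
    return(mk(jitter_ends(ex[a:b, , drop = FALSE])))
  }
  if (mode == "skip" && n >= 4L)
    return(mk(ex[-sample(2:(n - 1L), 1L), , drop = FALSE]))
  if (mode == "shift" && n >= 3L) {
    j <- sample(2:(n - 1L), 1L)
    d <- sample(c(-15:-5, 5:15), 1L)
    ex$start[j] <- ex$start[j] + d
    if (ex$start[j] <= ex$end[j - 1L] + 1L || ex$start[j] >= ex$end[j])
      return(mk(tx$exons))
    return(mk(ex))
  }
  if (mode == "mono") {
    w <- sample(30:80, 1L)
    s <- sample(ex$start[1L]:(ex$end[n] - w), 1L)
    return(mk(data.frame(start = s, end = s + w)))
  }
  if (mode == "anti")
    return(mk(data.frame(start = ex$start[1L] + 5L, end = ex$start[1L] + 80L),
              strand = if (tx$strand == "+") "-" else "+"))
  if (mode == "inter") {
    s <- sum(Biostrings::width(ref$genome)) + sample(100:200, 1L)
    return(transcript_model(id, "query", tx$chrom, "+",
                            data.frame(start = s, end = s + 60L)))
  }
  mk(ex)
}
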