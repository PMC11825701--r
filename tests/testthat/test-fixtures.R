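test_that("fixed seeds fix every emitted byte", {
  r1 <- make_reference(sim_config(seed = 7, n_genes = 4))
  r2 <- make_reference(sim_config(seed = 7, n_genes = 4))
  expect_identical(as.character(r1$genome), as.character(r2$genome))
  g1 <- tempfile(); g2 <- tempfile()
  write_annotation_gtf(r1$models, g1)
  write_annotation_gtf(r2$models, g2)
  expect_identical(readLines(g1), readLines(g2))
  r3 <- make_reference(sim_config(seed = 8, n_genes = 4))
  expect_false(identical(as.character(r1$genome), as.character(r3$genome)))
})

test_that("generated references honour the configured architecture", {
  cfg <- sim_config(seed = 3, n_genes = 3, exons_per_gene = c(7, 7))
  ref <- make_reference(cfg)
  expect_length(ref$index$genes, 3)
  for (m in ref$models) expect_equal(n_exons(m), 7)
})

test_that("every generated intron is GT..AG on the coding strand", {
  ref <- make_reference(sim_config(seed = 21, n_genes = 8))
  for (id in names(ref$models)) {
    m <- ref$models[[id]]
    introns <- introns_tx_order(ref$index, id)
    for (i in seq_len(nrow(introns))) {
      s <- Biostrings::subseq(ref$genome[[m$chrom]], introns$start[i],
                              introns$end[i])
      if (m$strand == "-") s <- Biostrings::reverseComplement(s)
      s <- as.character(s)
      expect_equal(substr(s, 1, 2), "GT")
      expect_equal(substr(s, nchar(s) - 1, nchar(s)), "AG")
    }
  }
})

test_that("annotated ORFs are recoverable from the generated genome", {
  ref <- make_reference(sim_config(seed = 31, n_genes = 6))
  for (id in names(ref$models)) {
    seq <- transcript_sequence(ref$models[[id]], ref$genome)
    orf <- find_orf(seq)
    expect_false(is.null(orf))
    expect_equal(c(orf$cds_start, orf$cds_end), ref$cds[[id]])
  }
})

test_that("cryptic cassette lies inside the host intron with novel flanks", {
  ref <- make_reference(sim_config(seed = 41, n_genes = 3, strand_mix = TRUE))
  for (g in c("G001", "G002")) {  # one gene per strand
    res <- apply_event(ref, g, event_spec("cryptic_exon", len = 102))
    tr <- res$truth
    tx <- tr$parent
    introns <- introns_tx_order(ref$index, tx)
    host <- introns[tr$host_intron, ]
    expect_true(host$start < tr$cassette_start && tr$cassette_end < host$end)
    # both flanking junctions are absent from the reference junction set
    m <- res$model
    keys <- chain_keys(m)
    cass_keys <- setdiff(keys, ref$index$junction_set)
    expect_length(cass_keys, 2)
    # cassette is in frame: protein grows by len/3
    seq <- transcript_sequence(m, res$ref$genome)
    expect_equal(find_orf(seq)$length_aa,
                 ref_len <- find_orf(transcript_sequence(
                   ref$models[[tx]], ref$genome))$length_aa + 34)
  }
})

test_that("utr_only keeps the genomic CDS identical to the parent", {
  ref <- make_reference(sim_config(seed = 43, n_genes = 2))
  res <- apply_event(ref, "G002", event_spec("utr_only", extend = 50))
  parent <- ref$models[[res$truth$parent]]
  orf_p <- find_orf(transcript_sequence(parent, res$ref$genome))
  orf_n <- find_orf(transcript_sequence(res$model, res$ref$genome))
  expect_equal(tx_to_genomic(res$model, orf_n$cds_start, orf_n$cds_end),
               tx_to_genomic(parent, orf_p$cds_start, orf_p$cds_end),
               ignore_attr = TRUE)
  expect_equal(transcript_length(res$model), transcript_length(parent) + 50)
})

test_that("ptc_insertion plants the stop at a hand-computable distance", {
  ref <- make_reference(sim_config(seed = 44, n_genes = 1, strand_mix = FALSE))
  tx <- "G001.t1"
  k <- ref$meta[[tx]]$k
  j <- k - 2L  # host intron well upstream of the last junction
  res <- apply_event(ref, "G001", event_spec("ptc_insertion", host_intron = j,
                                             len = 60, stop_codon = 2))
  m <- res$model
  seq <- transcript_sequence(m, res$ref$genome)
  orf <- find_orf(seq)
  lens <- ref$meta[[tx]]$exon_len
  # hand-computed: stop ends 54 nt into the cassette exon's transcript span
  expected_stop_end <- sum(lens[1:j]) + 6L
  expect_equal(orf$cds_end, expected_stop_end)
  nmd <- nmd_features(orf, m, seq = seq)
  # distance to the last junction: rest of cassette + remaining internal exons
  expect_equal(nmd$stop_to_last_junction, 54L + sum(lens[(j + 1):(k - 1)]))
  expect_true(nmd$ptc_flag)
})

test_that("infeasible events fail loudly", {
  ref <- make_reference(sim_config(seed = 45, n_genes = 1))
  expect_error(apply_event(ref, "G001", event_spec("cryptic_exon", len = 3000)),
               "cannot host|no intron")
  expect_error(apply_event(ref, "G001", event_spec("cryptic_exon", len = 100)),
               "divisible by 3")
  expect_error(apply_event(ref, "nope", event_spec("exon_skip")), "unknown gene")
})

test_that("junction-count simulation matches its sampling model at the edges", {
  ref <- make_reference(sim_config(seed = 51, n_genes = 1))
  res <- apply_event(ref, "G001", event_spec("cryptic_exon", len = 90))
  call <- classify_transcript(res$model, ref$index)
  ce <- detect_intron_derived_exons(res$model, call, ref$index, "strict")
  ev <- event_from_cryptic_call(ce[1, ], ref$index)

  t0 <- simulate_junction_counts(ev, 10, 500, psi = 0, seed = 1)
  expect_true(all(vapply(t0, function(tb)
    all(tb$unique_reads[tb$annotated == 0] == 0), logical(1))))
  t1 <- simulate_junction_counts(ev, 10, 500, psi = 1, seed = 1)
  expect_true(all(vapply(t1, function(tb)
    all(tb$unique_reads[tb$annotated == 1] == 0), logical(1))))

  # mean estimated ratio within 3 binomial SE of the generating psi
  tabs <- simulate_junction_counts(ev, 50, 10000, psi = 0.3, seed = 2)
  q <- do.call(rbind, lapply(tabs, quantify_event, event = ev))
  se <- sqrt(0.3 * 0.7 / 10000) / sqrt(50)
  expect_lt(abs(mean(q$ratio) - 0.3), 3 * se)
})

test_that("the ERBB2-like fixture carries its documented signals", {
  fx <- make_erbb2_like_fixture()
  # cassette contributes exactly 34 residues
  expect_equal(nchar(fx$cassette_peptide), 34)
  expect_equal(fx$cassette[2] - fx$cassette[1] + 1, 102)
  # strictly inside reference intron 14
  expect_true(fx$host_intron[1] < fx$cassette[1] &&
                fx$cassette[2] < fx$host_intron[2])
  # planted UGG window occupies downstream offsets 47..60
  win <- substr(fx$downstream_seq, 47, 60)
  expect_equal(nchar(win), 14)
  expect_equal(win, "TGGTGGTGGCATGG")
  # determinism
  fx2 <- make_erbb2_like_fixture()
  expect_identical(as.character(fx$genome), as.character(fx2$genome))
})

test_that("truth labels are recoverable across seeds and event kinds", {
  for (s in c(101, 102)) {
    atlas <- simulate_atlas(sim_config(seed = s, n_genes = 8))
    calls <- classify_transcripts(atlas$models, atlas$ref$index)
    tr <- atlas$truth
    got <- calls$category[match(tr$transcript_id, calls$transcript_id)]
    expect_identical(got, tr$category)
    orf <- classify_consequences(atlas$models[tr$transcript_id], calls,
                                 atlas$ref$index, atlas$ref$genome)
    expect_identical(orf$orf_class[match(tr$transcript_id, orf$transcript_id)],
                     tr$orf_class)
  }
})
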