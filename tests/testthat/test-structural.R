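# small hand-built reference: one 5-exon gene (+), one 2-exon gene (-),
# one mono-exon gene (+), plus a distant gene for fusion tests
tiny_reference <- function() {
  ex5 <- data.frame(start = c(100, 300, 500, 700, 900),
                    end = c(200, 400, 600, 800, 1000))
  models <- list(
    transcript_model("A.t1", "A", "chr1", "+", ex5),
    transcript_model("B.t1", "B", "chr1", "-",
                     data.frame(start = c(2000, 2400), end = c(2100, 2500))),
    transcript_model("M.t1", "M", "chr1", "+",
                     data.frame(start = 3000, end = 3400)),
    transcript_model("C.t1", "C", "chr1", "+",
                     data.frame(start = c(5000, 5300), end = c(5100, 5400))))
  list(models = models, index = reference_index(models))
}

test_that("multi-exon categories follow the chain rules", {
  tr <- tiny_reference()
  idx <- tr$index
  q <- function(exons, strand = "+")
    classify_transcript(transcript_model("q", "q", "chr1", strand, exons), idx)

  full <- q(data.frame(start = c(100, 300, 500, 700, 900),
                       end = c(200, 400, 600, 800, 1000)))
  expect_equal(full$category, "FSM")
  expect_equal(full$matched_transcript, "A.t1")

  # last 2 of 4 reference junctions -> contiguous sub-chain -> ISM
  ism <- q(data.frame(start = c(520, 700, 900), end = c(600, 800, 1000)))
  expect_equal(ism$category, "ISM")

  # known sites in a novel combination (skipped exon) -> NIC
  nic <- q(data.frame(start = c(100, 300, 700, 900),
                      end = c(200, 400, 800, 1000)))
  expect_equal(nic$category, "NIC")
  expect_equal(nic$n_novel_sites, 0)
  expect_equal(nic$n_novel_junctions, 1)

  # one shifted donor -> novel splice site -> NNC
  nnc <- q(data.frame(start = c(100, 300, 500, 700, 900),
                      end = c(200, 400, 590, 800, 1000)))
  expect_equal(nnc$category, "NNC")
  expect_equal(nnc$n_novel_sites, 1)
})

test_that("FSM is invariant to end changes that do not cross a splice site", {
  tr <- tiny_reference()
  for (d in c(-60, -10, 15, 80)) {
    m <- transcript_model("q", "q", "chr1", "+",
                          data.frame(start = c(100 + d, 300, 500, 700, 900),
                                     end = c(200, 400, 600, 800, 1000 + d)))
    expect_equal(classify_transcript(m, tr$index)$category, "FSM")
  }
})

test_that("mono-exon transcripts use containment and overlap rules", {
  tr <- tiny_reference()
  idx <- tr$index
  q <- function(s, e, strand = "+")
    classify_transcript(transcript_model("q", "q", "chr1", strand,
                                         data.frame(start = s, end = e)), idx)
  expect_equal(q(3050, 3300)$category, "FSM")      # inside mono-exon reference
  expect_equal(q(2999, 3300)$category, "genic")    # 1 nt outside: tolerance 0
  expect_equal(q(150, 350)$category, "genic")
  expect_equal(q(2010, 2080)$category, "antisense")
  expect_equal(q(2010, 2080, "-")$category, "genic")
  expect_equal(q(9000, 9100)$category, "intergenic")
})

test_that("transcripts spanning two disjoint genes are fusion_like", {
  tr <- tiny_reference()
  m <- transcript_model("q", "q", "chr1", "+",
                        data.frame(start = c(900, 5000), end = c(1000, 5100)))
  expect_equal(classify_transcript(m, tr$index)$category, "fusion_like")
})

test_that("classifier agrees with the brute-force oracle on random models", {
  ref <- make_reference(sim_config(seed = 61, n_genes = 10))
  set.seed(62)
  n_bad <- 0
  for (i in 1:300) {
    m <- random_query(ref, i)
    got <- classify_transcript(m, ref$index)$category
    want <- oracle_classify(m, ref$models)
    if (!identical(got, want)) n_bad <- n_bad + 1
  }
  expect_equal(n_bad, 0)
})

test_that("strict cryptic-exon calls are a subset of relaxed calls", {
  atlas <- simulate_atlas(sim_config(seed = 71, n_genes = 8))
  calls <- classify_transcripts(atlas$models, atlas$ref$index)
  for (id in atlas$truth$transcript_id) {
    m <- atlas$models[[id]]
    call <- calls[calls$transcript_id == id, ]
    strict <- detect_intron_derived_exons(m, call, atlas$ref$index, "strict")
    relaxed <- detect_intron_derived_exons(m, call, atlas$ref$index, "relaxed")
    key <- function(d) paste(d$exon_start, d$exon_end, d$host_transcript_id)
    expect_true(all(key(strict) %in% key(relaxed)))
  }
  # the planted cassettes are found in strict mode with the right host intron
  planted <- atlas$truth[atlas$truth$kind %in% c("cryptic_exon",
                                                 "ptc_insertion"), ]
  for (r in seq_len(nrow(planted))) {
    id <- planted$transcript_id[r]
    m <- atlas$models[[id]]
    strict <- detect_intron_derived_exons(m, calls[calls$transcript_id == id, ],
                                          atlas$ref$index, "strict")
    expect_equal(nrow(strict), 1)
    expect_equal(strict$host_intron_index, planted$host_intron[r])
  }
  # an exon-skip isoform yields no cryptic-exon calls
  skip_id <- atlas$truth$transcript_id[atlas$truth$kind == "exon_skip"][1]
  expect_equal(nrow(detect_intron_derived_exons(
    atlas$models[[skip_id]], calls[calls$transcript_id == skip_id, ],
    atlas$ref$index, "strict")), 0)
})

test_that("exons straddling an intron boundary are excluded in both modes", {
  tr <- tiny_reference()
  idx <- tr$index
  # internal exon overlapping reference exon 3's boundary
  m <- transcript_model("q", "q", "chr1", "+",
                        data.frame(start = c(100, 550, 900),
                                   end = c(200, 650, 1000)))
  call <- classify_transcript(m, idx)
  for (mode in c("strict", "relaxed"))
    expect_equal(nrow(detect_intron_derived_exons(m, call, idx, mode)), 0)
})

test_that("the read-support filter applies the < 3 rule", {
  mk <- function(id, support) {
    m <- transcript_model(id, "g", "chr1", "+", data.frame(start = 1, end = 50))
    m$support <- support
    m
  }
  models <- list(mk("keep3", c(1, 2)), mk("drop2", c(1, 1)), mk("keep9", 9))
  flt <- filter_models(models, 3)
  expect_setequal(vapply(flt$retained, `[[`, "", "transcript_id"),
                  c("keep3", "keep9"))
  expect_equal(flt$dropped$transcript_id, "drop2")
  # min_support = 1 is the identity filter for supported models
  expect_length(filter_models(models, 1)$retained, 3)
  expect_error(filter_models(list(transcript_model("x", "g", "chr1", "+",
                                                   data.frame(start = 1, end = 9))),
                             3), "no support")

  set.seed(63)
  for (i in 1:200) {
    sup <- matrix(rpois(12, 1.2), nrow = 4)
    models <- lapply(1:4, function(j) mk(paste0("t", j), sup[j, ]))
    flt <- filter_models(models, 3)
    oracle <- paste0("t", 1:4)[rowSums(sup) >= 3]  # one-line oracle
    expect_setequal(vapply(flt$retained, `[[`, "", "transcript_id"), oracle)
  }
})

test_that("reannotation partitions transcripts and tallies sum to the input", {
  atlas <- simulate_atlas(sim_config(seed = 72, n_genes = 8))
  calls <- classify_transcripts(atlas$models, atlas$ref$index)
  ra <- reannotate(calls)
  expect_equal(sum(ra$tally$n), nrow(calls))
  expect_true(all(ra$calls$novelty[ra$calls$category == "FSM"] == "known"))
  # parents are FSM/known; the 8 planted events include FSM-category ones
  # (UTR-level changes), so novel count equals the non-FSM events
  expect_equal(sum(ra$calls$novelty == "novel"),
               sum(atlas$truth$category != "FSM"))
  ra2 <- reannotate(calls, ism_known = TRUE)
  expect_true(all(ra2$calls$novelty[ra2$calls$category == "ISM"] == "known"))
  # all-FSM input has zero novel
  fsm_only <- calls[calls$category == "FSM", ]
  expect_equal(sum(reannotate(fsm_only)$calls$novelty == "novel"), 0)
})
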