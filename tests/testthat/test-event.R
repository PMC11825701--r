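mk_table <- function(df, id = "s1") junction_count_table(df, id)

simple_event <- function() {
  event_def("ev", "chr1", "+",
            inclusion = data.frame(start = c(1000, 1200), end = c(1100, 1300)),
            exclusion = c(1000, 1300))
}

test_that("event definitions validate their junction geometry", {
  expect_error(event_def("x", "chr1", "+",
                         data.frame(start = 1000, end = 1100),
                         c(1000, 1300)), "exactly 2")
  expect_error(event_def("x", "chr1", "+",
                         data.frame(start = c(1000, 1200),
                                    end = c(1100, 1300)),
                         c(1050, 1300)), "span")
})

test_that("events derived from strict cryptic calls mirror the host intron", {
  fx <- make_erbb2_like_fixture()
  call <- classify_transcript(fx$models$i14e, fx$index)
  ce <- detect_intron_derived_exons(fx$models$i14e, call, fx$index, "strict")
  ev <- event_from_cryptic_call(ce[1, ], fx$index)
  # exclusion junction equals reference intron 14
  expect_equal(c(ev$exclusion$start, ev$exclusion$end), fx$host_intron)
  # inclusion junctions' outer ends equal the exclusion ends
  expect_equal(ev$inclusion$start[1], ev$exclusion$start)
  expect_equal(ev$inclusion$end[2], ev$exclusion$end)
  # and their inner ends flank the cassette
  expect_equal(ev$inclusion$end[1], fx$cassette[1] - 1)
  expect_equal(ev$inclusion$start[2], fx$cassette[2] + 1)
  # relaxed-mode calls are rejected
  rel <- ce[1, ]; rel$mode <- "relaxed"
  expect_error(event_from_cryptic_call(rel, fx$index), "strict")
})

test_that("quantify_event computes the supporting-read ratio", {
  ev <- simple_event()
  tab <- mk_table(data.frame(
    chrom = "chr1", start = c(1000, 1200, 1000), end = c(1100, 1300, 1300),
    strand = "+", unique_reads = c(10, 10, 30)))
  q <- quantify_event(ev, tab)
  expect_equal(q$ratio, 0.25)
  expect_true(q$present)
  # all-zero counts: undefined ratio, absent
  q0 <- quantify_event(ev, mk_table(data.frame(
    chrom = "chr1", start = 1, end = 2, strand = "+", unique_reads = 0)))
  expect_true(is.na(q0$ratio))
  expect_false(q0$present)
  # row order and unrelated junctions do not matter
  tab2 <- mk_table(data.frame(
    chrom = c("chr1", "chr2", "chr1", "chr1", "chr1"),
    start = c(1000, 1000, 1200, 7777, 1000),
    end = c(1300, 1100, 1300, 8888, 1100),
    strand = "+", unique_reads = c(30, 99, 10, 55, 10)))
  expect_equal(quantify_event(ev, tab2)$ratio, 0.25)
  # undetermined-strand rows match events on either strand
  tab3 <- mk_table(data.frame(
    chrom = "chr1", start = c(1000, 1200, 1000), end = c(1100, 1300, 1300),
    strand = "*", unique_reads = c(5, 5, 15)))
  expect_equal(quantify_event(ev, tab3)$ratio, 0.25)
  # sum-based alternative
  expect_equal(quantify_event(ev, tab, ratio_method = "sum")$ratio, 0.4)
})

test_that("cohort prevalence counts samples above the presence rule", {
  ev <- simple_event()
  mk <- function(inc, id) mk_table(data.frame(
    chrom = "chr1", start = c(1000, 1200, 1000), end = c(1100, 1300, 1300),
    strand = "+", unique_reads = c(inc, inc, 50)), id)
  tables <- c(lapply(1:5, function(i) mk(3, paste0("pos", i))),
              lapply(1:15, function(i) mk(1, paste0("neg", i))))
  coh <- cohort_prevalence(ev, tables, min_reads_each_inclusion = 2)
  expect_equal(coh$prevalence, 0.25)
  # raising the threshold never raises prevalence
  for (t in c(3, 4, 10))
    expect_lte(cohort_prevalence(ev, tables, t)$prevalence, coh$prevalence)
  # psi = 0 cohort -> prevalence 0
  zero <- simulate_junction_counts(ev, 10, 100, psi = 0, seed = 1)
  expect_equal(cohort_prevalence(ev, zero)$prevalence, 0)
  expect_error(cohort_prevalence(ev, c(tables, tables[1])), "duplicate")
})

test_that("psi-hat is unbiased at high depth", {
  ev <- simple_event()
  for (psi in c(0.05, 0.5)) {
    tabs <- simulate_junction_counts(ev, 200, 10000, psi, seed = 300 + psi * 100)
    r <- vapply(tabs, function(tb) quantify_event(ev, tb)$ratio, numeric(1))
    se <- sqrt(psi * (1 - psi) / 10000) / sqrt(200)
    expect_lt(abs(mean(r) - psi), 4 * se)
  }
})

test_that("relative support ratios normalise to the baseline group", {
  ev <- simple_event()
  mk <- function(inc, exc, id) mk_table(data.frame(
    chrom = "chr1", start = c(1000, 1200, 1000), end = c(1100, 1300, 1300),
    strand = "+", unique_reads = c(inc, inc, exc)), id)
  tables <- c(lapply(1:5, function(i) mk(10 + i, 90, paste0("c", i))),
              lapply(1:5, function(i) mk(40 + i, 60, paste0("r", i))))
  q <- do.call(rbind, lapply(tables, quantify_event, event = ev))
  groups <- setNames(rep(c("control", "resistant"), each = 5), q$sample_id)
  rel <- relative_support_ratio(q, groups, baseline = "control")
  expect_equal(rel$group_means$relative_ratio[
    rel$group_means$group == "control"], 1)  # exact by construction
  expect_gt(rel$group_means$relative_ratio[
    rel$group_means$group == "resistant"], 1)
  expect_true(is.finite(rel$t_statistic))

  # all-identical samples: every relative ratio 1 and t = 0
  same <- do.call(rbind, lapply(1:6, function(i)
    quantify_event(ev, mk(10, 30, paste0("s", i)))))
  rel0 <- relative_support_ratio(same, setNames(rep(c("a", "b"), 3),
                                                same$sample_id), "a")
  expect_true(all(rel0$per_sample$relative_ratio == 1))
  expect_equal(rel0$t_statistic, 0)
})

test_that("group-mean ordering follows the generating psi", {
  ev <- simple_event()
  wrong <- 0
  for (s in 1:50) {
    t_lo <- simulate_junction_counts(ev, 5, 5000, 0.05, seed = s,
                                     sample_ids = paste0("lo", 1:5))
    t_hi <- simulate_junction_counts(ev, 5, 5000, 0.30, seed = 1000 + s,
                                     sample_ids = paste0("hi", 1:5))
    q <- do.call(rbind, lapply(c(t_lo, t_hi), quantify_event, event = ev))
    rel <- relative_support_ratio(q, setNames(rep(c("lo", "hi"), each = 5),
                                              q$sample_id), "lo")
    gm <- setNames(rel$group_means$relative_ratio, rel$group_means$group)
    if (gm["hi"] <= gm["lo"]) wrong <- wrong + 1
  }
  expect_equal(wrong, 0)
})

test_that("UGG scanning ranks windows and honours deletions", {
  fx <- make_erbb2_like_fixture()
  sw <- scan_ugg_rich(fx$downstream_seq)
  expect_equal(sw$start[1], 47)
  expect_equal(sw$end[1], 60)
  expect_equal(sw$end[1] - sw$start[1] + 1, 14)
  # motif-free sequence: nothing reported
  expect_equal(nrow(scan_ugg_rich(strrep("CA", 40))), 0)
  # sequence shorter than the window: empty result
  expect_equal(nrow(scan_ugg_rich("TGGTGG")), 0)
  # deleting the top window removes it from the scan (the 14R-del logic)
  deleted <- paste0(substr(fx$downstream_seq, 1, 46),
                    substr(fx$downstream_seq, 61,
                           nchar(fx$downstream_seq)))
  expect_equal(nrow(scan_ugg_rich(deleted)), 0)
})

test_that("window ranking agrees with exhaustive enumeration", {
  set.seed(115)
  for (i in 1:50) {
    seq <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE,
                        prob = c(0.2, 0.2, 0.35, 0.25)), collapse = "")
    got <- scan_ugg_rich(seq, min_motif_fraction = 0)
    # oracle: count TGG occurrences in every window by direct substring scan
    L <- nchar(seq); wl <- 14
    cnt <- vapply(seq_len(L - wl + 1), function(w) {
      win <- substr(seq, w, w + wl - 1)
      sum(vapply(seq_len(wl - 2), function(p)
        substr(win, p, p + 2) == "TGG", logical(1)))
    }, integer(1))
    expect_equal(got$count[order(got$start)], unname(cnt))
    expect_equal(got$start[1], order(-cnt, seq_along(cnt))[1])
  }
})
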