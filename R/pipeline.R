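#' Configuration for a full pipeline run
#'
#' One seed governs every stochastic stage; re-running with the same
#' configuration reproduces byte-identical outputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed propagated to every stochastic stage.
#' @param sim A [sim_config()]; defaults to `sim_config(seed = seed)`.
#' @param stages Named logical list toggling `simulate`, `classify`, `ends`,
#'   `orf`, `quantify`, `event`.
#' @param min_support Read-support filter threshold (default 3).
#' @param abundant_threshold Abundance-flag threshold (default 0.40).
#' @param end_cfg An [end_config()].
#' @param nmd An [nmd_config()].
#' @param sat A [saturation_config()].
#' @param presence_threshold Event presence rule (reads on each inclusion
#'   junction).
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, sim = NULL, stages = list(),
                       min_support = 3L, abundant_threshold = 0.40,
                       end_cfg = end_config(), nmd = nmd_config(),
                       sat = NULL, presence_threshold = 2L) {
  defaults <- list(simulate = TRUE, classify = TRUE, ends = TRUE, orf = TRUE,
                   quantify = TRUE, event = TRUE)
  defaults[names(stages)] <- stages
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 sim = sim %||% sim_config(seed = seed),
                 stages = defaults, min_support = as.integer(min_support),
                 abundant_threshold = abundant_threshold, end_cfg = end_cfg,
                 nmd = nmd, sat = sat %||% saturation_config(seed = seed),
                 presence_threshold = as.integer(presence_threshold)),
            class = "run_config")
}

config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL  # hash the scientific configuration, not the paths
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

write_stage_table <- function(df, path, hash, sort_by = NULL) {
  df <- as.data.frame(df)
  if (is.null(sort_by))
    sort_by <- intersect(c("chrom", "start", "transcript_id", "gene_id",
                           "sample_id"), names(df))
  if (length(sort_by) && nrow(df) > 0L)
    df <- df[do.call(order, df[sort_by]), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash=", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full simulate -> classify -> ends -> orf -> quantify -> event
#' pipeline
#'
#' Stages run in dependency order; each output table carries the run's
#' configuration hash in a header comment and the run manifest records the
#' hash, seed, package version and per-stage record counts.  Disabling a
#' stage that a later stage depends on raises an explicit error.  Timing is
#' logged to stderr and never written to outputs, so fixed seeds give
#' byte-identical results.
#'
#' @param cfg A [run_config()].
#' @return The manifest (also written to `manifest.json`), invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  st <- cfg$stages
  need <- function(stage, dep) {
    if (!isTRUE(st[[dep]]))
      stop("stage '", stage, "' requires stage '", dep, "' to be enabled")
  }
  if (isTRUE(st$classify)) need("classify", "simulate")
  for (s in c("ends", "orf", "quantify", "event"))
    if (isTRUE(st[[s]])) need(s, "classify")

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  manifest <- list(config_hash = hash, seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("isoforge")),
                   counts = list())
  tick <- function(stage, t0)
    message(sprintf("[isoforge] %-9s %.2fs", stage,
                    as.numeric(Sys.time()) - t0))
  path <- function(f) file.path(cfg$out_dir, f)

  if (!isTRUE(st$simulate)) {
    jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE)
    return(invisible(manifest))
  }
  t0 <- as.numeric(Sys.time())
  atlas <- simulate_atlas(cfg$sim)
  write_genome_fasta(atlas$ref, path("genome.fa"))
  write_annotation_gtf(atlas$ref$models, path("reference.gtf"))
  write_annotation_gtf(atlas$models, path("isoforms.gtf"))
  support_df <- data.frame(transcript_id = rownames(atlas$support),
                           atlas$support, check.names = FALSE)
  write_stage_table(support_df, path("support.tsv"), hash)
  write_stage_table(atlas$truth, path("truth.tsv"), hash)
  cage <- make_cage_peaks(atlas$ref$index, seed = cfg$seed)
  write_cage_bed(cage, path("cage.bed"))
  manifest$counts$n_reference <- length(atlas$ref$models)
  manifest$counts$n_models <- length(atlas$models)
  tick("simulate", t0)

  t0 <- as.numeric(Sys.time())
  flt <- filter_models(atlas$models, cfg$min_support)
  calls <- classify_transcripts(flt$retained, atlas$ref$index)
  calls <- reannotate(calls)$calls
  tally <- reannotate(calls)$tally
  cryptic <- do.call(rbind, lapply(flt$retained, function(m)
    detect_intron_derived_exons(m, calls[calls$transcript_id ==
                                           m$transcript_id, ],
                                atlas$ref$index, mode = "strict")))
  flat_calls <- calls[, setdiff(names(calls),
                                c("novel_junctions", "novel_sites"))]
  write_stage_table(flat_calls, path("calls.tsv"), hash)
  write_stage_table(flt$dropped, path("dropped.tsv"), hash)
  write_stage_table(tally, path("category_tally.tsv"), hash, sort_by = character(0))
  write_stage_table(cryptic, path("cryptic_exons.tsv"), hash)
  manifest$counts$n_retained <- length(flt$retained)
  manifest$counts$n_dropped <- nrow(flt$dropped)
  manifest$counts$n_novel <- sum(calls$novelty == "novel")
  manifest$counts$n_cryptic <- nrow(cryptic)
  tick("classify", t0)

  if (isTRUE(st$ends)) {
    t0 <- as.numeric(Sys.time())
    supports <- end_supports(flt$retained, cage, atlas$ref$genome,
                             atlas$ref$index, cfg$end_cfg)
    write_stage_table(supports, path("ends.tsv"), hash)
    summ <- end_summary(supports, calls)
    write_stage_table(summ$rates, path("end_rates.tsv"), hash,
                      sort_by = character(0))
    manifest$counts$n_end_supported <- sum(supports$cage_within_window)
    tick("ends", t0)
  }

  if (isTRUE(st$orf)) {
    t0 <- as.numeric(Sys.time())
    novel_ids <- setdiff(names(flt$retained), names(atlas$ref$models))
    orf_calls <- classify_consequences(flt$retained[novel_ids], calls,
                                       atlas$ref$index, atlas$ref$genome,
                                       cfg$nmd)
    write_stage_table(orf_calls, path("orf_calls.tsv"), hash)
    manifest$counts$orf_classes <- as.list(table(orf_calls$orf_class))
    tick("orf", t0)
  }

  if (isTRUE(st$quantify)) {
    t0 <- as.numeric(Sys.time())
    tx2gene <- vapply(atlas$models, `[[`, character(1), "gene_id")
    props <- isoform_proportions(atlas$support, tx2gene)
    flags <- abundant_flags(props, cfg$abundant_threshold)
    div <- gene_diversity(calls, rowSums(atlas$support))
    sat <- saturation_curve(
      data.frame(transcript_id = rownames(atlas$support),
                 reads = rowSums(atlas$support)), cfg$sat)
    write_stage_table(flags, path("abundant_flags.tsv"), hash)
    write_stage_table(div, path("gene_diversity.tsv"), hash)
    write_stage_table(sat$means, path("saturation_means.tsv"), hash,
                      sort_by = character(0))
    write_stage_table(sat$fit, path("saturation_fit.tsv"), hash,
                      sort_by = character(0))
    manifest$counts$n_abundant <- sum(flags$abundant)
    manifest$counts$saturation_Nmax <- sat$fit$Nmax[1L]
    tick("quantify", t0)
  }

  if (isTRUE(st$event)) {
    t0 <- as.numeric(Sys.time())
    if (is.null(cryptic) || nrow(cryptic) == 0L) {
      manifest$counts$event <- "no strict cryptic-exon call"
    } else {
      ev <- event_from_cryptic_call(cryptic[1L, ], atlas$ref$index)
      tables <- simulate_junction_counts(ev, cfg$sim$samples, cfg$sim$depth,
                                         cfg$sim$psi, seed = cfg$seed)
      coh <- cohort_prevalence(ev, tables, cfg$presence_threshold)
      write_stage_table(coh$quants, path("event_quant.tsv"), hash)
      for (tb in tables)
        write_sj_table(tb, path(sprintf("%s.SJ.out.tab",
                                        attr(tb, "sample_id"))))
      manifest$counts$event_prevalence <- coh$prevalence
      manifest$counts$event_mean_ratio <- mean(coh$quants$ratio, na.rm = TRUE)
    }
    tick("event", t0)
  }

  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
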