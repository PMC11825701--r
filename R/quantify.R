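#' Per-gene isoform proportions from a count matrix
#'
#' For every gene and sample, each transcript's share of the gene's total
#' counts.  Gene-sample pairs with zero total are flagged and excluded from
#' downstream abundance filters rather than producing NaNs silently.
#'
#' @param counts Numeric matrix (transcripts x samples) with rownames, or a
#'   data.frame with a `transcript_id` column.
#' @param tx2gene Named character vector mapping transcript_id -> gene_id.
#' @return Long data.frame: `transcript_id`, `gene_id`, `sample`, `count`,
#'   `fraction`, `zero_gene` (flag for undefined fractions).
#' @export
isoform_proportions <- function(counts, tx2gene) {
  if (is.data.frame(counts)) {
    rn <- counts$transcript_id
    counts <- as.matrix(counts[, setdiff(names(counts), "transcript_id")])
    rownames(counts) <- rn
  }
  if (any(counts < 0)) stop("counts must be nonnegative")
  missing <- setdiff(rownames(counts), names(tx2gene))
  if (length(missing))
    stop("transcript without gene assignment: ",
         paste(missing, collapse = ", "))
  genes <- tx2gene[rownames(counts)]
  long <- data.frame(
    transcript_id = rep(rownames(counts), ncol(counts)),
    gene_id = rep(unname(genes), ncol(counts)),
    sample = rep(colnames(counts), each = nrow(counts)),
    count = as.vector(counts))
  totals <- stats::aggregate(count ~ gene_id + sample, long, sum)
  names(totals)[3L] <- "gene_total"
  long <- merge(long, totals, by = c("gene_id", "sample"), sort = FALSE)
  long$zero_gene <- long$gene_total == 0
  long$fraction <- ifelse(long$zero_gene, NA_real_, long$count / long$gene_total)
  long[order(long$transcript_id, long$sample),
       c("transcript_id", "gene_id", "sample", "count", "fraction",
         "zero_gene")]
}

#' Flag abundant transcripts
#'
#' A transcript is abundant when it reaches the threshold proportion of its
#' gene's counts in at least one sample ("40% or more": the comparison is
#' inclusive).
#'
#' @param proportions Output of [isoform_proportions()].
#' @param threshold Proportion threshold in (0, 1]; default 0.40.
#' @return data.frame: `transcript_id`, `max_fraction`, `abundant`.
#' @export
abundant_flags <- function(proportions, threshold = 0.40) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  ok <- proportions[!proportions$zero_gene, , drop = FALSE]
  mx <- tapply(ok$fraction, ok$transcript_id, max)
  ids <- unique(proportions$transcript_id)
  mf <- as.numeric(mx[ids])
  data.frame(transcript_id = ids, max_fraction = mf,
             abundant = !is.na(mf) & mf >= threshold, row.names = NULL)
}

#' Per-gene isoform diversity
#'
#' Isoform number, novel isoform count and novel ratio per gene, optionally
#' with summed expression, mirroring atlas-style diversity summaries.
#'
#' @param calls Structural calls with `novelty` (see [reannotate()]).
#' @param expression Optional named numeric vector of per-transcript
#'   expression.
#' @return data.frame: `gene_id`, `n_isoforms`, `n_novel`, `novel_ratio`,
#'   `expression`.
#' @export
gene_diversity <- function(calls, expression = NULL) {
  if (!"novelty" %in% names(calls)) calls <- reannotate(calls)$calls
  grp <- split(calls, calls$assigned_gene)
  rows <- lapply(names(grp), function(g) {
    d <- grp[[g]]
    expr <- if (is.null(expression)) NA_real_ else
      sum(expression[d$transcript_id], na.rm = TRUE)
    data.frame(gene_id = g, n_isoforms = nrow(d),
               n_novel = sum(d$novelty == "novel"),
               novel_ratio = mean(d$novelty == "novel"),
               expression = expr)
  })
  out <- do.call(rbind, rows)
  out[order(out$gene_id), , drop = FALSE]
}

#' Saturation configuration
#' @param fractions Subsampling fractions in (0, 1], sorted.
#' @param replicates Thinning replicates per fraction.
#' @param min_support Reads needed to call a transcript detected.
#' @param seed RNG seed.
#' @param model Curve model: saturating exponential
#'   `N(f) = Nmax (1 - exp(-lambda f))` or Michaelis-Menten
#'   `N(f) = Nmax f / (K + f)`.
#' @return List of class `saturation_config`.
#' @export
saturation_config <- function(fractions = c(0.1, 0.3, 0.5, 0.7, 0.9, 1.0),
                              replicates = 20L, min_support = 3L, seed = 1L,
                              model = c("exponential", "michaelis")) {
  if (any(fractions <= 0) || any(fractions > 1)) stop("fractions must be in (0, 1]")
  if (is.unsorted(fractions)) stop("fractions must be sorted")
  list(fractions = fractions, replicates = as.integer(replicates),
       min_support = as.integer(min_support), seed = as.integer(seed),
       model = match.arg(model))
}

#' Depth-saturation analysis by read subsampling
#'
#' Reads assigned to each transcript are binomially thinned at each fraction;
#' a transcript counts as detected when it retains at least `min_support`
#' reads.  Mean detected counts are fitted with the configured saturating
#' curve and the saturation point is the smallest fraction at which the
#' fitted curve reaches 95% of its asymptote.  When a `class` column is
#' present (e.g. known/novel), separate curves are fitted per class.
#'
#' @param assignments data.frame with `transcript_id` and `reads` columns
#'   (full-depth read counts), optionally `class`.
#' @param cfg A [saturation_config()].
#' @return List with `points` (fraction x replicate detected counts),
#'   `means`, and `fit` (per class: `Nmax`, `rate`, `saturation_point`,
#'   `converged`).
#' @export
saturation_curve <- function(assignments, cfg = saturation_config()) {
  stopifnot(all(c("transcript_id", "reads") %in% names(assignments)))
  if (!"class" %in% names(assignments)) assignments$class <- "all"
  set.seed(cfg$seed)
  pts <- list()
  for (f in cfg$fractions) for (r in seq_len(cfg$replicates)) {
    thin <- if (f >= 1) assignments$reads else
      stats::rbinom(nrow(assignments), assignments$reads, f)
    det <- tapply(thin >= cfg$min_support, assignments$class, sum)
    pts[[length(pts) + 1L]] <- data.frame(
      fraction = f, replicate = r, class = names(det),
      n_detected = as.integer(det))
  }
  points <- do.call(rbind, pts)
  means <- stats::aggregate(n_detected ~ fraction + class, points, mean)
  fits <- lapply(split(means, means$class), function(d) {
    fit_saturation(d$fraction, d$n_detected, cfg$model)
  })
  fit <- do.call(rbind, Map(function(cl, f)
    data.frame(class = cl, Nmax = f$Nmax, rate = f$rate,
               saturation_point = f$saturation_point,
               converged = f$converged),
    names(fits), fits))
  list(points = points, means = means, fit = fit)
}

fit_saturation <- function(f, n, model) {
  out <- list(Nmax = NA_real_, rate = NA_real_,
              saturation_point = NA_real_, converged = FALSE)
  n0 <- max(n)
  if (n0 <= 0) return(out)
  if (diff(range(n)) == 0)  # already saturated at the smallest fraction
    return(list(Nmax = n[1], rate = NA_real_, saturation_point = f[1],
                converged = TRUE))
  res <- tryCatch({
    if (model == "exponential") {
      fit <- minpack.lm::nlsLM(n ~ Nmax * (1 - exp(-lambda * f)),
                               start = list(Nmax = n0, lambda = 2),
                               lower = c(Nmax = 0, lambda = 1e-6),
                               data = data.frame(f = f, n = n))
      cf <- stats::coef(fit)
      list(Nmax = unname(cf["Nmax"]), rate = unname(cf["lambda"]),
           saturation_point = -log(0.05) / unname(cf["lambda"]),
           converged = TRUE)
    } else {
      fit <- minpack.lm::nlsLM(n ~ Nmax * f / (K + f),
                               start = list(Nmax = n0, K = 0.2),
                               lower = c(Nmax = 0, K = 1e-9),
                               data = data.frame(f = f, n = n))
      cf <- stats::coef(fit)
      list(Nmax = unname(cf["Nmax"]), rate = unname(cf["K"]),
           saturation_point = 19 * unname(cf["K"]), converged = TRUE)
    }
  }, error = function(e) NULL)
  if (is.null(res)) return(out)
  res
}
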