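#' Simulate per-sample splice-junction count tables for a cassette event
#'
#' Sampling model: per sample, the number of event-informative junction reads
#' is `N ~ Poisson(depth)`; of these, `I ~ Binomial(N, psi)` support
#' inclusion.  Both inclusion junctions receive the identical count `I` (a
#' read pair spanning the cassette supports both); the exclusion junction
#' receives `N - I`.  With `jitter = TRUE` the two inclusion junctions are
#' drawn independently instead.
#'
#' @param event An `event_def` (see [event_from_cryptic_call()]).
#' @param n_samples Number of samples.
#' @param depth Expected informative reads per sample (`D`).
#' @param psi Inclusion fraction in `[0, 1]`; scalar or per-sample vector.
#' @param seed Optional RNG seed.
#' @param jitter Draw the two inclusion junctions independently.
#' @param sample_ids Optional sample labels.
#' @return List of `junction_count_table`, one per sample.
#' @export
simulate_junction_counts <- function(event, n_samples, depth, psi,
                                     seed = NULL, jitter = FALSE,
                                     sample_ids = NULL) {
  stopifnot(inherits(event, "event_def"))
  if (any(psi < 0) || any(psi > 1)) stop("psi must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  psi <- rep_len(psi, n_samples)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(n_samples))
  lapply(seq_len(n_samples), function(i) {
    n <- stats::rpois(1L, depth)
    inc <- stats::rbinom(1L, n, psi[i])
    inc2 <- if (jitter) stats::rbinom(1L, n, psi[i]) else inc
    df <- data.frame(
      chrom = event$chrom,
      start = c(event$inclusion$start, event$exclusion$start),
      end = c(event$inclusion$end, event$exclusion$end),
      strand = event$strand,
      motif = 1L,
      annotated = c(0L, 0L, 1L),
      unique_reads = c(inc, inc2, n - inc),
      multi_reads = 0L,
      max_overhang = 50L)
    junction_count_table(df, sample_ids[i])
  })
}
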