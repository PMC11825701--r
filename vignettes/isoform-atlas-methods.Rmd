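---
title: "Methods: isoform classification, ORF consequences and event quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isoform classification, ORF consequences and event quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoforge)
```

This vignette documents the models, conventions and design choices behind
`isoforge`: what each stage computes, which thresholds matter and why, what
the synthetic-data generator does and does not emulate, and where the design
was genuinely open.

## Coordinates and junctions

All internal coordinates are 1-based inclusive, the Bioconductor convention.
A junction is represented as its intron interval — first to last intronic
base — which makes the STAR `SJ.out.tab` dialect (columns 2 and 3 are
exactly those bases) a verbatim mapping, and GTF exon rows a ±1 conversion
at intron boundaries. Donor and acceptor roles are strand-aware: on `+` the
donor is the intron's first base, on `-` its last. Writers emit
deterministic row and column order so that fixed inputs give byte-identical
files.

## Structural classification

The classifier operates on the *splice chain*, the ordered junction list of
a multi-exon model, against an index of reference chains, junctions, splice
sites, ends and per-gene exon unions:

* **FSM** — the chain equals a same-strand reference chain. Transcript ends
  play no role, so FSM is invariant to end extension or truncation that does
  not cross a splice site. When several references share a chain, the match
  minimising total end distance wins, ties broken by transcript id.
* **ISM** — the chain is a *contiguous* proper sub-chain of one reference
  chain. Contiguity reflects the degraded/truncated-isoform interpretation
  of partial matches; non-contiguous subsets (e.g. an exon skip) are genuine
  novel combinations and fall through to NIC/NNC.
* **NIC / NNC** — neither of the above: NIC when every query splice site is
  found in the union of known donor and acceptor positions, NNC when at
  least one site is novel. Using the union is deliberate: a donor landing on
  a known acceptor coordinate is treated as a known position.
* Mono-exon models: FSM when contained (tolerance 0 nt, configurable) in a
  same-strand mono-exon reference; otherwise `genic` when overlapping a
  same-strand gene (exonically or intronically — the intron-only case is
  folded into `genic` rather than given its own label), `antisense` when
  overlapping only the opposite strand, else `intergenic`.
* A model with exonic overlap on two same-strand genes whose spans are
  disjoint is `fusion_like`; it is labelled and excluded from downstream
  stages, since fusion calling proper is out of scope.

Re-annotation maps FSM → known and everything else → novel. Whether ISM
should count as known is genuinely ambiguous (a truncated copy of a known
transcript is not a new structure, but it is not a catalogued one either);
the default is novel, switchable via `ism_known`.

## Intron-derived exons

A cassette exon "derived from an intron" is an internal exon strictly
contained in a reference intron of the assigned gene, overlapping no
reference exon. Strict mode additionally requires the two query junctions
flanking the exon to reuse the host intron's donor and acceptor — the
pattern of a cassette spliced into an otherwise intact intron, which is what
the downstream event definition (two inclusion junctions, one exclusion
junction) needs. Relaxed mode drops the flank conditions and is a superset
of strict by construction. The host intron index is reported in transcript
orientation (intron 1 follows exon 1).

## Transcript ends

5′ ends are compared with CAGE peak intervals; the distance is zero inside a
peak and the "within 50 bp" call is inclusive (`distance <= 50`), a reading
documented here because the boundary case matters for rate summaries. 3′
ends are scanned for polyA hexamers (AATAAA, ATTAAA by default) in the final
50 nt of *transcript-space* sequence — annotated-polyA semantics — rather
than the genomic 3′ flank; the 3′-most hit is reported. Distances to
annotated TSS/TES are signed, positive downstream, and the closest distance
is kept.

## ORF and NMD consequence classes

`find_orf` reports the longest ATG-initiated ORF with an in-frame stop,
5′-most on ties, and nothing below 30 aa. NMD features are computed in
transcript space: the 50-nt rule flags a stop more than 50 nt upstream of
the final junction (strictly greater, so a stop exactly at 50 nt is not
flagged; mono-exon transcripts are never flagged), a 3′UTR longer than
350 nt is a feature, and uORFs are ATG-initiated ORFs of ≥ 10 aa lying
entirely within the 5′UTR. None of these thresholds is canonical in the
literature beyond the 50-nt rule; they are explicit in `nmd_config` and
configurable.

The consequence cascade, applied against the matched reference transcript
(FSM/ISM) or the gene's longest-CDS transcript otherwise:

1. identical genomic CDS → `unchanged_ORF`;
2. `NAGNAG`: exactly one acceptor shifted ±3 nt between the chains, same
   genomic stop, proteins identical up to a one-codon indel. Tandem
   acceptors alter the residue adjacent to the initiator in the fixture
   design, but the detector accepts the indel anywhere the flanks match,
   since the 3-nt acceptor-shift signature is the defining feature;
3. no ORF or < 100 aa → `short_ORF`;
4. any NMD feature → `PTC_NMD`. Unproductive transcripts usually satisfy
   several criteria at once; short ORFs are prioritised and the remaining
   feature carriers (PTC, long 3′UTR, uORF — including downstream-ORF-like
   signals) collapse into this one class, with the fired evidence recorded;
5. otherwise → `protein_coding_novel`.

Classes 1, 2 and 5 form the coding major class, 3 and 4 the unproductive
one.

## Abundance, diversity and saturation

Per-gene isoform proportions are computed per sample; gene-samples with zero
total are flagged rather than silently NaN. A transcript is *abundant* when
it reaches 40% of its gene's counts in at least one sample (inclusive).
Saturation analysis thins each transcript's read count binomially at
fractions 0.1, 0.3, 0.5, 0.7, 0.9, 1.0 (20 replicates), calls a transcript
detected at ≥ 3 reads (the same support threshold as structural filtering,
for consistency), and fits N(f) = N~max~(1 − e^−λf^). The functional form is
a choice — nothing in the subsampling model dictates it — so a
Michaelis–Menten alternative is available; the saturation point is the
smallest fraction at which the fitted curve reaches 95% of N~max~
(closed-form: −ln 0.05 / λ). Exactly flat curves (already saturated at the
smallest fraction) short-circuit the fit. Saturation counts transcripts,
not genes.

## Event quantification

A cassette event is two inclusion junctions and one exclusion junction. The
supporting-read ratio is

ψ̂ = mean(inc₁, inc₂) / (mean(inc₁, inc₂) + exc),

with a sum-based variant behind `ratio_method = "sum"`; the mean-based form
is the package's definition of the otherwise loosely-specified "relative
supporting reads ratio" family of measures, and under the simulator's
sampling model (N ~ Poisson(D), I ~ Binomial(N, ψ), both inclusion
junctions receiving I) it is exactly I/N, an unbiased estimator of ψ.
Presence requires ≥ 2 unique reads on *each* inclusion junction — an
assumption, so cohort prevalence is reported together with the threshold
and is monotone non-increasing in it. Only unique-mapping reads are
counted; undetermined-strand junction rows match events on coordinates
alone. Group comparisons normalise each sample's ratio by the baseline
group mean (making the baseline mean exactly 1) and report a two-sided
Welch t statistic for two groups.

## UGG scanning

`scan_ugg_rich` slides a 14-nt window along the intronic sequence downstream
of a cassette exon (offset 1 = first intronic base), counts possibly
overlapping TGG occurrences, keeps windows whose motif fraction reaches 0.5,
and ranks by count, ties to the 5′-most window. Fourteen nt matches the
deletion-scale at which such elements are experimentally probed; a window
that would tie under a pure repeat is avoided in the fixture by phase
(see below).

## The synthetic-data generator

The generator's job is exact truth recovery, and its gene architecture is
built for it: exon 1 is pure 5′UTR; exon 2 a UTR tail ending in the
annotated ATG; exons 3..k−1 coding with lengths divisible by 3 (codon-
aligned boundaries); exon k the TAA stop plus a 3′UTR kept under the
long-3′UTR threshold. Three sequence-level constraints make ORF truth
deterministic rather than merely probable:

* every UTR, intron and intergenic region is ATG-free (the trigram is
  recoded), and coding codons are drawn from a stop- and ATG-free alphabet
  with boundary-crossing ATGs rejected — so the annotated start is the only
  ORF start a scanner can use;
* coding sequence carries a periodic codon quartet that forces stop codons
  in both shifted reading frames, bounding any out-of-frame reading well
  below the 30-aa ORF minimum;
* all junctions are written GT..AG on the coding strand.

Eight event kinds are planted with hand-computable consequences: exon skips
and in-frame cassettes change protein length by exactly the event length / 3;
intron retentions and PTC cassettes carry a planted in-frame stop whose
transcript-space position (hence PTC distance and truncated length) follows
from the exon lengths; NAGNAG writes a tandem `CAGCAG` acceptor at the
intron downstream of the start codon; UTR-level events (5′ extension, 3′
trim, first-exon drop) leave the genomic CDS untouched. Cassette genome
patches are confined to intron interiors, so the parent transcript's
sequence is never altered. Cryptic-exon events are restricted to in-frame
lengths; frame-disrupting cassettes are expressed as the PTC event kind,
where the stop is planted explicitly instead of arising from uncontrolled
downstream sequence. Junction counts follow N ~ Poisson(D),
I ~ Binomial(N, ψ), with both inclusion junctions receiving the identical
count (a cassette-spanning read pair supports both); independent draws are
available behind a `jitter` switch.

The worked-example fixture is a 22-exon gene whose derived isoform carries a
102-nt cassette strictly inside intron 14. Its translation contributes 34
residues: a documented 19-mer core (`SLPRIKLGGGPRGRGHRDW`) flanked by 15
synthetic residues — the flanks are a labelled stand-in, not a claim about
any real locus. The UGG-rich window is planted at downstream offsets 47–60
as TGG·TGG·TGG·CA·TGG: a pure 14-nt TGG repeat would tie (4 motifs) with
windows shifted 1–2 nt left and the 5′-most tie-break would report offset
45; phasing the fourth motif to end exactly at offset 60 makes 47–60 the
unique top-scoring window. The surrounding intronic region is kept TGG-free
so the ranking cannot be confounded by chance motifs.

What the generator does *not* emulate — and hence what green tests do not
show about real data: sequencing error and alignment ambiguity, degraded
5′ ends beyond clean truncations, expression dispersion beyond Poisson
support counts, overlapping gene architectures, non-canonical splice sites
(a switch exists but defaults off), and internal-methionine ORF starts.
Real atlases need the upstream long-read processing stack; this package
starts where collapsed transcript models end.

## Problem sizes and numerical notes

The test suite runs the classifier-versus-oracle comparison on 1000 randomly
perturbed transcripts over a 12-gene reference, truth-label recovery on 208
planted events across 13 seeds, ψ̂ recovery on 500 simulated samples at
depth 10⁴ for each ψ ∈ {0.05, 0.3, 0.7}, and saturation recovery on 400
transcripts at mean depth 10× the support threshold — sizes chosen so the
whole suite completes in about two minutes while keeping binomial standard
errors far below the tolerances being asserted. Curve fitting uses
Levenberg–Marquardt least squares with non-negativity bounds; degenerate
flat inputs bypass the optimiser. All randomness flows from explicit seeds;
re-running any generator or the full pipeline with the same configuration
reproduces byte-identical outputs (the run manifest records a configuration
hash and per-stage counts, never timestamps).

## Known limitations

Classification is exhaustive rather than indexed for ISM lookup (linear in
reference transcripts per query), which is ample at fixture scale but would
want interval-tree support for a genome-wide reference. The NAGNAG detector
requires the acceptor-shift signature and will not catch donor-side tandem
shifts. Fusion-like models are only labelled. The prevalence presence rule
and the NMD thresholds other than the 50-nt rule are documented assumptions,
not estimated quantities.
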