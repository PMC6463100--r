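---
title: "Filtering and merging amplicon variant calls: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filtering and merging amplicon variant calls: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varscreen)
```

## Scope and model

varscreen post-processes variant callsets from targeted amplicon panels
sequenced on flow-based instruments. Its inputs are the outputs of an
upstream alignment/calling stack — one VCF per (aligner, caller)
combination, one SAM/BAM per aligner, and the panel BED — and its job is
the downstream decision logic: which calls to trust, how to reconcile the
combinations, and how to summarise the result. It never recomputes
caller-internal annotations (QD, FS, MQ0, ReadPosRankSum, DP, QUAL are
consumed, not derived), and it does no alignment, realignment or
annotation-database lookup of its own.

Two empirical observations drive the design. First, flow-based chemistry
mis-measures homopolymer run lengths, so indel calls inside homopolymer
runs are enriched for artifacts. Second, aligner/caller combinations
disagree enough that agreement *count* is informative: a call supported by
all combinations is much more likely real than one supported by a single
combination.

## Variant identity

All cross-callset logic keys on the normalized `(chrom, pos, ref, alt)`
tuple. Normalization trims shared trailing then leading bases (keeping one
anchor base for indels) and, when reference sequence is available, shifts
indels to their leftmost equivalent placement by the standard
extend-left-and-trim walk. Callers differ in where they place indels
inside repeats; without left-alignment, identical biological events would
fail to match during merging and the confidence score would be
systematically deflated for exactly the repeat-associated indels the
homopolymer filter cares about. Normalization is idempotent, and
multi-allelic records are split per alternate allele before it, so
per-combination support counting is well defined.

Coordinates follow the formats: VCF positions are 1-based, BED intervals
0-based half-open, and conversions happen only at I/O boundaries. All
inputs are reference-stranded; no strand flipping occurs anywhere.

## The filter cascade

**Stage 1 — region filter.** A call is on-target when its anchor position
(0-based `pos − 1`) lies in some BED interval. Membership is tested on the
anchor only, not the full deletion span: the simplest rule consistent with
removing "calls outside the targeted regions", and the only one that needs
no per-type casing.

**Stage 2 — quality expressions.** GATK-style callsets are filtered per
variant class with the fixed panel-calibrated expressions given in
`snp_filter_config()` / `indel_filter_config()`; SAMtools-style callsets
get the depth-range rule in `depth_filter_config()`. Three points deserve
comment:

* *Missing fails.* Any sub-expression referencing an absent annotation
  counts as matched, labeling the call with `MISSING_<FIELD>`. This
  follows the upstream filtering engines' missing-values-fail switch. It
  is deliberately harsh — calls lacking ReadPosRankSum (e.g. homozygous
  sites) are labeled — but the union-retention rule below absorbs most of
  the collateral damage, and absent-vs-zero is kept distinct throughout
  (`NA`, never sentinel values).
* *bwa-specific FS.* The Fisher-strand threshold is 590 for bwa-aligned
  callsets and 60 otherwise: bwa's FS statistic runs far higher on this
  kind of amplicon data, and a shared threshold of 60 would discard nearly
  everything bwa calls. The override is a fixed configuration default
  (`max_fs_bwa`), adjustable per run.
* *SNP clusters.* A SNP is flagged when it belongs to ≥ `cluster_size`
  SNPs spanning ≤ `cluster_window` bp (defaults 3 in 10 bp). Only the
  window size is inherited from the calibrated configuration; the
  companion cluster size is not stated there, so the upstream tool's
  default of 3 is adopted and exposed as a parameter.

After labeling, the **union-retention rule** applies per caller group: a
key survives the group when at least one aligner combination left it
unlabeled. The rule is stated for the GATK group; we apply it to the
SAMtools group symmetrically as the least-surprising extension. Merging
then counts only combinations whose own call passed — a variant rescued by
the union rule is supported by the combinations that passed it, not by
those that labeled it.

**Stage 3 — homopolymer indel filter.** For a candidate indel site and one
aligner's reads, let the event lengths be the signed lengths (+insertion,
−deletion) of the I/D CIGAR events matched to the site, one per
indel-bearing covering read. Two statistics summarise the distribution:

* `var` — population variance of the lengths (bp²). We divide by *n*, not
  *n − 1*: the lengths are the complete population of observed events at
  the site, and the divide-by-*n* form keeps `var = 0` well-defined at a
  single event. The choice is configurable in effect because thresholds
  calibrated and applied with the same estimator are internally
  consistent.
* `frmode` — the fraction of indel-bearing reads carrying the modal
  length, in (0, 1]. The denominator excludes event-free covering reads:
  `frmode` asks "do the reads that see an event agree on it?", which is
  robust to the allele fraction. Tied modes share the same count, so the
  statistic is well defined under ties.

Signed lengths are pooled in a single distribution so that an
insertion/deletion mixture at one site registers as maximal dispersion
(`var({+1, −1}) = 1`), which is precisely the inconsistency the filter
exists to catch.

A site is rejected when `var > maxVar` **and** `frmode < minFrmode` for at
least one aligner — both strict, both for the same aligner. Thresholds on
the boundary retain. The any-aligner rule is deliberately conservative: an
artifact may be visible in only one aligner's pileup (a documented case of
this motivates the rule), and a real indel produces consistent events in
every aligner. Aligners with no events at the site are skipped rather than
treated as violations, since both statistics are undefined on an empty
distribution (`NO_EVENTS`).

*Calibration.* `calibrate_thresholds()` sets `maxVar` to the maximum `var`
and `minFrmode` to the minimum `frmode` over the TP-labeled entries of a
training table; FP entries only quantify achieved filtering. The package
defaults (`maxVar = 0.055`, `minFrmode = 0.9790`) are the values this
formula yields on a cohort of 108 Sanger-inspected homopolymer indel calls
(18 TP, 90 FP). The formula guarantees zero TP loss on the training set:
every TP has `var ≤ maxVar`, so the rejecting conjunction cannot hold.

*Event matching.* The default `mode = "exact"` matches events whose
anchor equals the site's normalized position; it needs no reference.
`mode = "homopolymer_run"` accepts any event anchored inside the
homopolymer run containing the site, which is closer to the biological
intent (slipped events land anywhere in the run) but requires reference
sequence. The run is taken as the maximal identical-base run containing
the first affected base.

## Merging and confidence

Merging is an exact-key union over post-filter callsets: one merged
variant per distinct normalized key, supported by exactly the combinations
whose filtered callset contains it. The confidence score is the size of
that support set — never stored independently, always recomputed from it.
Merging is invariant under permutation of the input callsets, and
duplicate (aligner, caller) declarations are an error. Conflicting
annotations across combinations are aggregated as max QUAL and median
depth; this aggregation is a presentation choice for the report and feeds
no filtering decision.

## Reporting and benchmark metrics

The final report ranks variants by descending confidence, then genomic
order. Gene and database annotations come from an optional user-supplied
table joined on the variant key — a deliberate replacement for live
annotation-service queries, which are out of scope; the report schema is
unchanged by their absence. Summary tables (per gene, per score, per type)
each conserve the total variant count.

Benchmark metrics are sensitivity `TP/(TP+FN)` and specificity
`TN/(TN+FP)` as percentages with two decimals, rounded
half-away-from-zero (base R's round-half-even would mis-print boundary
values relative to the conventional reporting of these quantities). A zero
denominator yields `NA`, never 0 or 100. For benchmark evaluation against
an orthogonal method with limited sensitivity, calls below a 10% alternate
allele fraction should be excluded from the *evaluation* (not from the
report); the metrics functions take whatever confusion counts the caller
assembles under that convention.

## Synthetic data: what it emulates, and what it does not

The generators exist so every stage is testable end-to-end with no
external data:

* `simulate_reference()` embeds homopolymer runs at known positions in an
  otherwise run-free random sequence.
* `simulate_pileup()` draws reads covering a site; each read shows the
  true indel with its length perturbed by ±1 with probability
  `slippage_prob`, emulating the over/under-call of a homopolymer run that
  dominates flow-based error. A perturbed length is never 0 — a 0-length
  event would silently vanish from the pileup rather than appear as a
  wrong-length event — so when a ±1 draw would cancel the event the
  magnitude is pushed one further. This keeps the modal fraction near
  `1 − slippage_prob`, the binomial expectation the tests check.
  Magnitude-2 slips arise through that same rule.
* `simulate_callsets()` drops each true variant from each combination
  independently with probability `dropout_prob` and fills healthy
  annotation values, so merged confidence follows a truncated binomial.
* `simulate_training_set()` builds a labeled cohort shaped like the
  historical calibration set (defaults 18 TP / 90 FP): TP entries from
  low-slippage pileups (default 0.02), FP entries from high-slippage
  pileups (default 0.35), 40 reads per site. The noise defaults were
  chosen once as plausible for flow-based amplicon data: true indels
  produce nearly perfectly consistent events, while slippage artifacts
  show wrong-length events in roughly a third of reads. Under these
  settings the two classes separate almost completely in the
  (`var`, `frmode`) plane, so calibrated thresholds remove close to all
  FPs — cleaner than a real cohort, where removal rates are lower.

What the simulations do **not** model: base-substitution sequencing error,
quality-score distributions, allele-fraction structure, multi-site
interactions, mapping ambiguity, or strand bias. Passing tests on
synthetic data therefore demonstrate the correctness of the decision
logic under its stated assumptions, not field performance on clinical
samples.

All generators take an explicit seed, restore the caller's RNG state, and
are bit-reproducible; the pipeline itself contains no randomness at all,
and repeated runs on identical inputs are byte-identical.

## Numerical and degenerate-input choices

* Threshold comparisons in every filter are exactly as printed in the
  configurations: strict where strict (`var > maxVar`, `DP < 5`), so
  boundary values retain/pass.
* `compute_var`/`compute_frmode` error on empty distributions
  (`NO_EVENTS`) instead of returning 0/1, because an absent distribution
  means "no evidence", not "perfect consistency"; `decide_homopolymer()`
  skips such aligners and errors only when no aligner has evidence.
* Percentage rounding is half-away-from-zero at two decimals, applied at
  the reporting boundary only; internal arithmetic is double precision.
* Empty inputs flow through: empty BED means everything is off-target,
  empty callsets merge to an empty table, empty reports carry headers and
  zero-count summaries.
* Problem sizes in the test suite are chosen for tight oracles: pileup
  oracle equivalence runs 500 random pileups of ≤ 100 reads against an
  independent CIGAR walk; the calibration guarantee runs 200 random
  training tables; the end-to-end checks use a 600 bp two-amplicon toy
  panel with 5 true variants across 6 callsets.

## Known limitations

* Exact-key merging cannot match calls that normalize differently because
  one caller emitted a complex representation (e.g. an MNP bundling a SNP
  with an indel); no fuzzy or windowed matching is attempted, by design —
  determinism and auditability outweigh the rare missed match on amplicon
  panels.
* The homopolymer filter judges candidate sites only; it does not discover
  candidates, and a site whose reads show no events anywhere is left to
  the upstream caller's judgment.
* The depth filter implements the zero-window configuration of its
  upstream counterpart; gap-adjacency testing at nonzero windows is
  parameterised but intentionally not applied at the defaults.
* CRAM input, contig-name liftover and reference download are out of
  scope.
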