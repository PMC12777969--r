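---
title: "svstream: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{svstream: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the model behind `svstream`, the parameters that
matter, the design decisions that were genuinely open, and what the
synthetic fixtures do and do not demonstrate about real data.

## The streaming model

`svstream` treats an in-progress sequencing run as a growing multiset of
alignment records delivered in batches. Three properties make real-time
calling exact rather than approximate:

1. **Additive extraction.** Signature extraction is a per-read function: a
   read's intra-alignment (CIGAR) and inter-alignment (split-read) evidence
   depends only on that read's records. For any partition of the records
   into batches that keeps each read's records together, the union of
   per-batch extractions equals the extraction of the whole. Batches
   therefore only ever *append* to the signature store.
2. **Pure clustering.** `call_variants()` is a deterministic function of
   (store, depth track, parameters). It holds no state between invocations,
   so an interim callset can be recomputed at any time and two engines with
   equal stores emit byte-identical VCFs.
3. **Atomic state transitions.** A batch is applied as a single value
   update (store + depth + ledger) and becomes durable only when the JSON
   checkpoint is atomically renamed into place. Any crash therefore lands
   on a state that equals "first k batches processed", from which resuming
   is indistinguishable from never having crashed.

Streaming/offline equivalence and crash-recovery equivalence in the test
suite are exact byte comparisons of whole VCF files, which is why the VCF
writer fixes its `##fileDate`/`##source` strings (configurable) instead of
stamping wall-clock time.

## Signature extraction

Intra-alignment: each CIGAR `D` is a deletion candidate at its reference
interval, each `I` an insertion candidate anchored where it interrupts the
reference walk. Same-type candidates of one read whose anchors lie within
`merge_dist` are merged *before* the size filter, so an SV fragmented by
the aligner into several nearby operations (e.g. `40D 10M 40D`) is
recovered as one 80 bp deletion. The merged insertion anchor is the
length-weighted mean of member anchors rounded half-up — deterministic,
symmetric, and stable under permutation of the merged operations. Deletion
merges keep the first start and sum the deleted lengths (the span would
also count the spacers, which are not deleted sequence).

Inter-alignment: only *consecutive* segment pairs in forward-read order are
examined. This bounds work per read, matches how split alignments tile a
read, and avoids quadratic pairings that would double-count nested events.
Reverse-strand segments have their query intervals flipped onto the forward
read before sorting, so gap arithmetic is orientation-free. The inversion
signature spans the union of the discordant pair's reference intervals; see
"fixture geometry" below for a consequence.

Parameters (all config-exposed via `extraction_params()`):

| parameter         | default | units | role |
|-------------------|---------|-------|------|
| `min_size`        | 30      | bp    | smallest reportable SV; below this, indels are treated as alignment noise |
| `merge_dist`      | 500     | bp    | intra-read merge radius for fragmented CIGAR evidence |
| `min_mapq`        | 20      | —     | single mapping-quality gate, applied when the batch is read; a read whose primary fails it contributes nothing |
| `min_segment_len` | 300     | bp    | minimum reference span for an SA segment to be a usable split anchor |

These defaults mirror the conventions of widely used long-read SV callers;
the contribution of this package is the streaming framework, not new
thresholds.

## Clustering, support, genotypes

Per (contig, type), sorted signatures are split by a greedy linear scan
wherever the start-to-start gap exceeds a per-type bias (DEL 200, INS 100,
INV 500, DUP 500, BND 50 bp — looser where breakpoint estimates are
noisier). Gaps chain, so dense evidence can form clusters wider than the
bias; with well-separated SVs this does not occur, and it keeps the scan
O(n).

Cluster summaries use the *lower* median (the lower of the two central
order statistics for even counts): coordinates stay integral, and the
result is invariant under permutation of the store. Support `DV` counts
*distinct* read ids, so a chimeric read contributing two signatures to one
cluster cannot inflate support.

The support threshold is depth-adaptive:
`clamp(round_half_up(0.1 × mean_depth), 2, 10)`. The depth driving it is
the *run-level mean* (total aligned bases / genome length), not the local
depth: the threshold models sequencing progress, and a run-level statistic
steps identically for every locus, which is what produces the
characteristic transient dips of the detection-rate curve exactly at
threshold increments. `DR` at a call locus is estimated from a 1 kb-binned
depth track (`max(0, round_half_up(local_depth) − DV)`) rather than by
re-querying alignments: spent batches are never touched again, at the cost
of a bias bounded by bin granularity (a read's bases land in the correct
bins exactly; only the within-bin position is smoothed).

Genotypes come from binomial likelihoods of `DV` alt reads among
`DV + DR`, with alt-read probability `eps = 0.1` (0/0), `0.5` (0/1),
`1 − eps` (1/1) and a uniform prior. Ties break toward the lower-alt
genotype (conservative); `DV + DR = 0` yields `./.` with quality 0; quality
is `−10·log10(1 − max posterior)` rounded and capped at 100 (the cap also
absorbs the degenerate `posterior = 1` case).

## The engine

File readiness is defined purely by the two-poll rule — size and mtime
unchanged across `stability_window` — because it is portable and testable;
OS event hooks could accelerate discovery but would not change the
contract. The window defaults to 5 s in the CLI and is dialled down to tens
of milliseconds in tests.

Checkpoints are written after every batch and every cycle, bounding
recovery rework to a single batch. The ledger stores a content checksum
(file length + MD5 of the first and last 64 KiB) per processed batch;
recovery verifies these and refuses to continue if an input mutated
mid-run, since the equivalence guarantee would then be void. Interim VCFs
at or beyond the checkpointed cycle index are deleted and regenerated on
recovery because they may be partial. One engine instance owns an output
directory (lock file); multi-instrument setups run one engine per watch
directory.

Degenerate inputs: header-only batches are valid (empty extraction);
unreadable batches are retried up to 3 times and then quarantined without
touching state; an empty store yields a header-only VCF; an empty truth
set makes the detection rate undefined (error) rather than silently 0/0.

## Feedback and early stopping

The detection rate is *truth-side* coverage — the fraction of the
AF-filtered truth set matched by at least one call — matching its role as
"how much of what we expect to find have we found". Call-side precision
and F1 against a same-sample truth are available offline via
`sv_benchmark()` but deliberately kept out of the feedback loop, where a
population truth set is the realistic reference. The AF filter is strict
(`af > af_min`, default 0.1) and treats a missing AF as failing. Matching
uses community-conventional defaults (breakpoints within 1000 bp, min/max
length ratio ≥ 0.7, types equal; BNDs matched on contig and position
only). The stop signal is a recommendation in the report — the engine
never terminates an external sequencing process.

## The synthetic fixture

`simulate_run()` emulates what reaches the caller from a sequencer +
aligner: equal-size read batches of alignment records, materialized
atomically one file at a time. Alignments are *constructed*, not produced
by a real aligner: a variant-allele read gets exactly the CIGAR or
primary/supplementary split geometry that the corresponding SV would
induce, with three noise knobs — breakpoint/length jitter (sd 10 bp),
per-read evidence dropout (0.1), and background indels (0.2/kb, 1–10 bp,
all below `min_size` so the size filter must remove them). Heterozygous
SVs (fraction 0.5) are carried per-read with probability 1/2. Truth AFs
are drawn uniformly on [0.02, 0.6] so the AF filter has real work.

Default study conditions: 2 × 500 kb contigs, 40 implanted SVs
(12 DEL, 12 INS, 5 INV, 6 DUP, 5 BND), 20× coverage with 8 ± 2 kb reads,
10 batches, seed 42. These sizes keep the full equivalence tests within a
couple of minutes on one core while leaving every mechanism (merging,
clustering, depth steps, split geometry) non-trivially exercised; the
depth-step behaviour is additionally probed on a smaller 45× fixture where
the support threshold actually increments.

**Fixture geometry for inversions.** The inter-alignment inversion rule
reports the union span of the strand-discordant segment pair, so an INV
call's length exceeds the inverted interval by one flanking segment — and
flanks must be ≥ `min_segment_len` (300 bp) to be alignable anchors at
all. A 50–500 bp inversion therefore cannot pass a 0.7 size-ratio match
against its own truth record under any geometry. The generator
consequently implants inversions of 1000–2500 bp with 300–400 bp flank
segments (worst-case ratio 1000/1400 ≈ 0.71), while the other types keep
the 50–500 bp default.

What the fixture does **not** model: base-level sequencing error and its
alignment artifacts, soft-clip-only evidence, nested/complex SVs, reads
carrying both a split-type SV and CIGAR SVs, reference-strand sampling
(all primaries are forward), chimeric mapping noise, and non-uniform
coverage. Passing the fixture demonstrates the framework's bookkeeping
properties (additivity, purity, recovery) and the correctness of the
extraction/clustering arithmetic — not calling accuracy on real nanopore
data, which depends on aligner behaviour the fixture idealizes.

## Known limitations

- Signature extraction assumes the upstream aligner's conventions (SA tags
  per the SAM spec, hard-clipped supplementaries); CRAM, phased genotypes
  and multi-sample VCFs are out of scope.
- The `DR` estimate inherits bin-granularity smoothing; loci at depth
  discontinuities can be off by a few reads, which perturbs genotype
  quality but not the callset itself.
- Breakpoints are cluster medians; no consensus refinement or insertion
  sequence assembly is attempted.
- The detection-rate statistic inherits the representativeness of the
  population truth set it is given.
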