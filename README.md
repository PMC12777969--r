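# svstream

Real-time, batch-incremental structural variant (SV) detection from
long-read alignments.

Long-read sequencers (nanopore in particular) emit reads continuously while
a run is in progress, but conventional SV callers wait for the complete
dataset before doing any work. `svstream` closes that gap: it watches a
directory into which alignment batches arrive, converts each batch into
read-level SV signatures as soon as the file stabilizes, and maintains a
cumulative signature store and depth track from which it clusters and
genotypes a full callset after every processing cycle. Because signature
extraction is additive over batches and clustering is a pure function of the
accumulated state, the streaming callset is *identical* — byte for byte —
to a one-shot offline callset over the same reads. Atomic checkpoints make
that identity survive crashes: kill the engine after any batch, resume, and
the final VCF is unchanged.

A detection-rate feedback statistic — the fraction of a frequency-filtered
population truth set covered by the current callset — is recomputed every
cycle, so a run can be terminated early once detection has plateaued above a
user-defined threshold, saving sequencing time and cost.

The package is aimed at method developers and pipeline engineers working on
real-time long-read analysis; everything (including a sequencer-emulating
fixture generator) runs from plain SAM/VCF text with no external aligner.

## The method

**Signatures.** Each retained alignment record (primary or supplementary,
`MAPQ >= 20`) yields *intra-alignment* evidence: every CIGAR `D`/`I`
operation is a DEL/INS candidate at its reference anchor; same-type
candidates of one read with anchors within 500 bp are merged (DEL: first
start, summed length; INS: length-weighted mean anchor, summed length) and
kept if the merged length is >= 30 bp. Each primary record plus its SA-tag
supplementaries yields *inter-alignment* evidence from consecutive segment
pairs in read order: with reference gap `dr` and read gap `dq`,
`dr - dq >= 30` is a DEL and `dq - dr >= 30` an INS; a strand flip on one
contig is an INV over the united span; a reference rewind on one strand is a
tandem DUP; a contig change is a BND.

**Clustering and genotyping.** Per contig and type, signatures sorted by
start are split wherever the start gap exceeds a per-type bias (DEL 200,
INS 100, INV/DUP 500, BND 50 bp). A cluster becomes a call at the lower
median of member starts/lengths with support `DV` = distinct read count,
kept when

    DV >= clamp(round(0.1 * mean_depth), 2, 10),

the depth-adaptive support threshold that steps upward as coverage
accumulates. Reference support is `DR = max(0, round(local_depth) - DV)`
from a 1 kb-binned depth track, and the genotype maximizes the binomial
likelihood of `DV` alt reads among `DV + DR` under allele fractions
`{eps, 0.5, 1 - eps}` (`eps = 0.1`) with a uniform prior.

**Feedback.** A call matches a truth record when types agree, breakpoints
are within 1000 bp, and min/max length ratio is >= 0.7 (BNDs: contig and
position only). The detection rate is the truth-side coverage of records
with allele frequency > 0.1; stopping is recommended once the last
`patience` cycles all reach the threshold.

## Worked example

Simulate a sequencer run (2 × 500 kb contigs, 40 implanted SVs, 20×
coverage split into 10 read batches), then stream it with early stopping:

```r
library(svstream)

fx <- simulate_run("demo", seed = 42)
res <- run_engine(fx$batch_dir, "demo/out", fx$contigs,
                  truth = fx$truth_vcf, stop_threshold = 0.9,
                  cycle_every_batch = TRUE)
for (r in res$reports)
  cat(sprintf("cycle %d: depth %.1f, rate %.3f, stop %s\n",
              r$cycle_index, r$mean_depth, r$detection_rate,
              r$stop_recommended))
```

```
cycle 0: depth 1.8, rate 0.485, stop FALSE
cycle 1: depth 3.6, rate 0.606, stop FALSE
cycle 2: depth 5.3, rate 0.636, stop FALSE
cycle 3: depth 7.2, rate 0.636, stop FALSE
cycle 4: depth 9.0, rate 0.636, stop FALSE
cycle 5: depth 11.0, rate 0.879, stop FALSE
cycle 6: depth 12.9, rate 0.970, stop FALSE
cycle 7: depth 14.8, rate 0.970, stop TRUE
```

The rate climbs steeply at low depth and plateaus; after cycle 7 (~15× of
the 20× run) the last two rates exceed 0.9 and the engine recommends
stopping. Benchmarking the early-stopped callset against *all* implanted
SVs:

```r
calls <- read_truth_vcf(res$final_vcf)
bm <- sv_benchmark(calls, read_truth_vcf(fx$truth_vcf))
cat(sprintf("precision %.3f recall %.3f f1 %.3f\n",
            bm$precision, bm$recall, bm$f1))
#> precision 1.000 recall 0.975 f1 0.987
```

`final.vcf` records look like:

```
ctg1  37669  svstream.DEL.1  N  <DEL>  35  PASS  SVTYPE=DEL;SVLEN=-271;END=37939;SUPPORT=19  GT:DR:DV  1/1:2:19
```

Run to completion instead (`stop_threshold = NULL`) and the final VCF is
byte-identical to `call_offline(fx$batch_paths, fx$contigs, ...)` on the
same batches — and to a run that was killed after any batch and resumed
with another `run_engine()` call on the same output directory.

A thin CLI mirrors the R interface
(`exec/svstream simulate|run|resume|call|evaluate`).

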