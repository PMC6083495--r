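---
title: "Detecting readthrough (DoG) transcripts: model, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting readthrough (DoG) transcripts: model, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dogscan)
```

## The model

Transcriptional readthrough leaves a characteristic footprint in RNA-seq:
a run of *continuous* read coverage beginning at a gene's 3′ end and
extending into intergenic space. `dogscan` formalizes a DoG
(Downstream-of-Gene transcript) as the maximal such run:

* the **initial criterion**: coverage breadth — the fraction of positions
  covered by at least one aligned block — over the first `min_dog_len`
  bases downstream of the 3′ end must reach `min_dog_cov`;
* the **elongation rule**: overlapping windows of `window_len` bp,
  advanced by `window_step` bp, extend the DoG while each window's breadth
  stays at or above `min_dog_cov`; the first failing window ends the DoG;
* the **neighbor constraint**: a DoG may not extend past the nearest gene
  lying 3′ of the anchor (same-strand genes for stranded libraries, genes
  of either strand for unstranded ones), and a gene whose 3′ neighbor
  leaves less than `min_dog_len` of room is not considered at all.

Only **non-genic reads** feed the coverage signal: any read with ≥ 1 bp of
block overlap with any gene locus is removed first, so alternative
isoforms, overlapping ncRNAs and ambient genic signal cannot masquerade as
readthrough. Gene loci themselves are built to be as inclusive as
possible: within each annotation source a gene spans its outermost
transcript coordinates, and across sources same-strand loci that overlap
by ≥ 1 bp are merged (different overlapping genes too — read density
inside another gene can never be attributed to readthrough unambiguously).

## Parameters

| parameter    | default | units | meaning |
|--------------|---------|-------|---------|
| `min_dog_len` | 4000   | bp    | initial downstream length that must pass the breadth test; also the minimum reported DoG length |
| `min_dog_cov` | 0.60   | fraction | breadth threshold for the initial interval and every window |
| `window_len`  | 200    | bp    | elongation window width |
| `window_step` | 100    | bp    | window advance; endpoint resolution is ± one step |

The 4000 bp / 60% defaults suit polyA-selected libraries. Non-polyA,
nuclear-enriched libraries see far more (and longer) readthrough signal;
stricter settings such as 4500 bp / 80% are then appropriate. The window
geometry is this package's own choice — the detection model only requires
"overlapping running windows" — sized so that endpoints resolve to
~100 bp, and overlapping so a single short gap cannot split an otherwise
continuous run; both knobs are exposed.

Thresholds compare inclusively (`>=`): a window at exactly 60% breadth
passes. Some convention must be fixed; inclusive matches the reading of
the thresholds as *minimal* coverage/length.

## Strandedness

Library protocol is inferred natively: among loci with no opposite-strand
overlapping locus, the fraction `f` of alignments consistent with the
forward model (single/mate-1 read on the transcript strand, mate-2
opposite) is measured over up to 200 000 alignments; `f >= 0.8` calls
forward, `1 - f >= 0.8` reverse, anything else unstranded. After
inference, every read's strand is normalized to the *transcript* strand,
so downstream logic never needs protocol awareness. For stranded
libraries, genic filtering, coverage, neighbor limits and read counting
are all strand-matched; for unstranded libraries coverage is strand-blind
and neighbor limits apply regardless of strand, which makes unstranded
calls conservative by construction (a convergent opposite-strand neighbor
truncates the DoG even though its reads look identical).

## Depth equalization

Because the criterion is continuous coverage, the number of detectable
DoGs grows with library depth (deeper libraries fill in coverage gaps).
Comparing DoG sets across samples therefore requires equal depth:
`preprocess_samples()` downsamples every sample, without replacement, to a
common target (default: the minimum mapped-read count across the set; a
numeric target is accepted). Sampling is seeded — per-sample seed = base
seed + sample index — and pair-atomic for paired layouts, so a mate pair
is never split and reruns are bit-identical. Both the strand-normalized
and the downsampled read sets are kept so discovery can be re-run with
different parameters cheaply.

## Combining samples and quantifying

Replicate DoG sets are combined by gene identifier (every DoG is anchored
to exactly one gene, so replicate overlap is a gene-level notion):
`common_dogs()` keeps genes present in all sets, `union_dogs()` genes
present in any, both taking the most downstream end per gene (maximum end
on `+`, minimum start on `-`) with the 3′-end anchor preserved. The
intersection's end-combination rule was genuinely open; the most
downstream rule is the default for symmetry with the union, and the
minimal common extent is available via `combine = "min"`.

Expression is a plain RPKM over any DoG annotation. The denominator is
the mapped-read count of the downsampled sample, so cross-sample RPKMs
share the normalization the preprocessing step established. Genic reads
are *not* excluded during quantification (genic removal belongs to
discovery); a read overlapping both a locus and a DoG counts for the DoG.
An `exclude_genic` toggle exists for users who want the stricter
behavior. A read may count toward several DoGs only in unstranded mode
with convergent genes; no fractional assignment is attempted.

## Numerical choices and edge cases

* Internally all intervals live in Bioconductor `GRanges` (1-based
  closed), the native convention of the GenomicRanges/rtracklayer stack
  this package is built on; BED files are converted at the I/O boundary,
  and inter-base boundary coordinates (3′ ends, neighbor limits) are
  reported in BED-style numbers, which coincide in both conventions.
* Chromosome-boundary clipping is silent: the downstream interval is
  truncated, and a gene whose clipped room falls below `min_dog_len` is
  discarded by the same rule as a neighbor-limited gene (the chromosome
  end is the degenerate neighbor).
* A neighbor that overlaps the query gene and extends past its 3′ end
  clamps the available room to zero — the gene is discarded.
* The final elongation window may be truncated by the neighbor limit; a
  truncated window that still passes ends the DoG exactly at the limit.
* Elongation never re-anchors after a failing window: "until coverage
  drops below the threshold" is read literally, so an interior
  sub-threshold stretch ends the DoG even if coverage resumes later.
  (Released readthrough callers differ here; this is the stricter and
  more predictable choice.)
* "Coverage" is breadth (fraction of positions with depth ≥ 1), not mean
  depth: continuity is the phenomenon of interest, and breadth is
  depth-robust at the cost of being the harder criterion at low depth.
* Ties/duplicates: duplicate-flagged alignments are retained by default
  (`drop_duplicates` exposed); merged multi-gene loci take the longest
  contributor's identifier, with the others kept as aliases.

## The synthetic-data generator

`generate_fixture()` emulates the data regimes the pipeline must handle:
a multi-gene genome with configurable intergenic gaps, per-gene expression
depth, planted readthrough of known length and breadth on chosen genes,
single/paired layout under forward/reverse/unstranded protocols, and
uniform intergenic noise. Gene-body reads have uniform start positions;
readthrough coverage is planted with **periodic breadth masking**: each
`window_len`-sized segment of the readthrough interval is covered over its
leading `breadth` fraction and left bare over the remainder, so *every*
discovery window of that size sees exactly the configured breadth.

Why periodic rather than random masking? With i.i.d. masking at read-tile
scale, a single masked 100 bp tile drops any 200 bp window that contains
it to ≤ 50% breadth — below the 60% threshold — so a nominal breadth of
0.8 would be unrecoverable by any windowed detector and "planted breadth"
would not mean what it says. Periodic masking makes the planted truth
exact: a fixture with breadth b is callable iff `b >= min_dog_cov` (and
the length and room conditions hold), which the truth table records.
Randomness across replicate fixtures enters through read sampling, seeds
and downsampling.

`readthrough_depth` (default: the gene-body depth) sets the coverage
depth over the unmasked readthrough positions separately from the body
depth, since real libraries are dominated by genic reads while
readthrough regions sit near the detection limit.

What the generator does **not** model: sequencing errors, GC and positional
bias, isoform structure, spliced reads (the reader supports them; the
generator doesn't produce them), fragment-length variation beyond a fixed
insert, and chimeric/multimapping artifacts. Passing tests on these
fixtures therefore demonstrate the correctness of the detection geometry,
strand logic, depth behavior and bookkeeping — not robustness to mapper
noise on real data.

## Validation strategy and problem sizes

The test suite validates discovery against an independent brute-force
oracle (per-base boolean coverage arrays plus an exhaustive window scan)
on 100+ randomized genomes of ≤ 80 kb and ≤ 12 genes; recovery of planted
readthrough (4–20 kb, breadth 0.80, depth 5×) across 50 seeded fixtures
with endpoint error ≤ one window step; rejection of sub-threshold breadth
(0.45) fixtures; zero calls when every 3′ gap is below `min_dog_len`;
monotonicity of DoG counts in depth (20-seed depth series) and
anti-monotonicity in `min_dog_cov`; gene-keyed set-algebra equivalence;
closed-form RPKM values; bit-identical pipeline reruns; and mirror
symmetry of stranded calls under coordinate reflection. These sizes keep
the full suite in the minutes range while exercising every code path; the
detection arithmetic is size-independent.

## Limitations

* Loci are flat intervals: no isoform-aware 3′ ends, no splice-aware DoG
  model, no antisense-DoG pairing, no 5′ (upstream) readthrough.
* Gene-level set operations assume the input DoG files came from the same
  loci annotation; combining calls made against different annotations is
  undefined.
* The pipeline is single-threaded; determinism is guaranteed by
  construction rather than by careful parallel reduction. For the data
  sizes the coverage-index design targets (tens of millions of reads),
  preprocessing is the only stage where parallelism would pay.
* Poorly annotated genomes: discovery quality is bounded by annotation
  quality; adapting the locus builder to CDS-only annotations (calling
  3′ UTR + readthrough jointly) is possible future work.
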