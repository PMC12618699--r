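---
title: "Methods: split-pool single-cell ATAC processing for FFPE tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: split-pool single-cell ATAC processing for FFPE tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scSplitPool)
```

# Background

Formalin-fixed paraffin-embedded (FFPE) tissue is the dominant archival
format in pathology, but fixation crosslinks and fragments DNA, which
defeats standard single-cell ATAC-seq: inserts are short, many templates
are nicked, and library complexity collapses. One assay design that works
around this combines three ingredients:

1. **Split-pool combinatorial indexing.** Nuclei are tagmented with one of
   64 indexed Tn5 adaptors, then passed through three rounds of
   split-pool ligation with 96 barcodes per round. Each nucleus
   accumulates a (Tn5, round-1, round-2, round-3) combination — a space of
   $64 \times 96^3 = 56{,}623{,}104$ barcodes per run.
2. **T7-driven linear amplification (IVT).** A T7 promoter on the final
   ligation product lets damaged templates be transcribed into RNA copies
   before PCR. This rescues broken molecules but produces a second class
   of duplicates: copies that share the Tn5 insertion coordinate while
   ending at different positions (transcripts stop at variable points).
3. **Damage-tolerant decoding.** Reads from heavily degraded inserts are
   short; the decoder must locate a staggered barcode frame, tolerate
   sequencing errors in barcodes and linkers, and retain very short
   genomic mates.

scSplitPool implements the computational side of this design as a tested
library and CLI: collision modelling, demultiplexing, duplicate
collapsing, per-cell QC and filtering, pseudo-bulk differential
accessibility, and a bootstrap robustness layer for pseudotime — together
with a synthetic-data generator so that every stage can be exercised, with
full ground truth, on a laptop and offline.

# Barcode collisions

When $N$ nuclei draw uniformly from $D$ barcode combinations, the expected
number of distinct combinations in use is $D\,(1 - ((D-1)/D)^N)$, and the
collision rate is defined as the expected fraction of cells that do not
hold a unique combination:

$$\mathrm{collision\ rate}\ (\%) \;=\; 100 \times
\frac{N - D + D\left(\frac{D-1}{D}\right)^{N}}{N}.$$

Two points are worth stating explicitly. First, this is an **expectation
over cells** (how many cells lose uniqueness on average), not the
probability of observing at least one collision — the latter is far larger
for any realistic $N$. Second, the natural unit is the **sub-library**:
cells that received different Tn5 indexes can never collide, so $D$
defaults to $96^3 = 884{,}736$ per sub-library. Whether $N$ should be the
cells of one sub-library or the whole run depends on how the reactions
were pooled; the implementation computes the formula for user-supplied
$(N, D)$ and the CLI exposes both readings. At $N = 50{,}000$ and
$D = 96^3$ the rate is 2.77%.

```{r}
round(collision_rate(50000, 96^3), 2)
```

The power $((D-1)/D)^N$ is evaluated as `exp(N * log1p(-1/D))`, which is
stable for large $N$ and $D$; the naive power underflows long before the
quantities of interest do.

# Read anatomy and the demultiplexer

Read 2 opens with the barcode frame: the round-1 barcode at offset 0, a
staggered spacer, the round-2 barcode, a fixed 17-nt linker, the round-3
barcode, a second spacer, the 3-nt Tn5 index and the 19-nt mosaic end
(ME), followed by 50 genomic bases. Read 1 is 91 nt of genomic sequence
from the opposite end of the molecule.

The printed absolute positions of the segments (round-2 barcode starting
at 1-based 22–26, round-3 at 43–47, Tn5 index at 66–68) cannot all hold
simultaneously with a fixed 17-nt linker, and the published frame length
spans 88–91 nt, which admits only four stagger values. We therefore anchor
everything **relative to the linker** and fix the geometry as: round-2
barcode start drawn from 0-based {22..25}, second spacer 13 nt. This
yields frame lengths of exactly 88–91 nt and a Tn5 index starting at
0-based 66 at minimal stagger — inside all the printed windows that can be
satisfied jointly. Since decoding is anchor-relative, only the anchor
search window matters; it defaults to linker offsets 20–40 (0-based),
generous on both sides, and is configurable.

Decoding proceeds per pair:

* **Anchor.** The linker is slid over the window; the offset minimising
  Hamming distance wins (leftmost on ties) provided the distance is at
  most 3 mismatches. Reads with no acceptable offset are rejected
  (`no_anchor`).
* **Barcodes.** Round-2 and round-3 barcodes are the 7-mers flanking the
  anchor; round-1 is the first 7 nt; the Tn5 index sits 37 nt right of
  the anchor start. Matching is exact-7 first, then exact match of the
  last five bases against the whitelist suffixes (distinct by
  construction, validated at load). There is deliberately **no Hamming-1
  rescue**: the last-5 mechanism is the only error tolerance the design
  specifies, and adding more would change the published behaviour. The
  Tn5 index (all 64 3-mers in the default set) is matched exactly; with a
  saturated 3-mer space no error detection is possible there.
* **Genomic mates.** The last 50 nt of Read 2 are taken as the genomic
  mate; Read 1 is truncated to 75 nt. The reverse-complemented ME is then
  searched in each mate — full-length only, up to 1 mismatch, rightmost
  occurrence — and everything from it onward is removed. Requiring the
  full 19-mer keeps chance trimming at the $10^{-10}$ level, at the price
  of leaving partial (<19 nt) adaptor tails in place; aligners soft-clip
  those. Pairs whose shorter trimmed mate falls below `ml` are rejected.

The retention parameter `ml` (minimum retained read length, default 17
bp) is the lever that trades decoding yield against mapping quality in
degraded material; `ml_sweep()` reproduces the sweep used to choose it,
decoding once and re-applying the gate per threshold.

Decoded pairs are written per Tn5 index with the cell barcode in the
header as `@<orig_id>|<bc1>-<bc2>-<bc3>-<tn5>` (1-based whitelist
indices) — one paired FASTQ set per index. The published description of a
"single merged file" is ambiguous between interleaving and pairing; we
emit pairs, which every aligner accepts.

The linker, spacer and adaptor sequences of the default architecture are
documented placeholders (the original oligo tables are not reproduced
here); every sequence is overridable via `barcode_architecture()` or a
plain-text config directory (`load_architecture()`). The default round
whitelists are generated deterministically with distinct last-5 suffixes,
mirroring the structural property the real whitelists are stated to have.

# Duplicate collapsing

Alignment-level records are collapsed per cell. PCR duplicates are
identical on (cell, chrom, start, end, strand). Linear-amplification
duplicates require a weaker key: IVT copies of one tagmentation event
share the insertion-proximal 5' coordinate but end wherever transcription
stopped. `dedup_fragments(mode = "pcr_and_linear")` therefore groups on
**(cell, chrom, strand, 5' insertion coordinate)** and keeps the maximal
extent as the representative. The exact rule used by the original
in-house script is unpublished; this key is our recorded choice, and
`mode = "pcr_only"` gives the conventional behaviour for comparison. No
Tn5 +4/−5 coordinate shift is applied by default, as none is specified
for this assay. The per-cell duplication rate is
$100\,(1 - \mathrm{unique}/\mathrm{total})$.

# Per-cell QC and filtering

* **FRiT** — the fraction of a cell's unique fragments overlapping an
  oriented TSS window, −1000..+200 bp. Intervals are 0-based half-open
  throughout, so a fragment starting exactly at TSS+200 is outside. A
  fragment overlapping two windows counts once (whether the original
  implementation counted fragments or read ends is unstated; counting
  fragments avoids double counting).
* **FRiP** — the same with peak intervals.
* **TSS profile** — strand-oriented coverage ±3000 bp in 10-bp bins (600
  bins); fold enrichment normalises each bin by the mean of the outermost
  100 bp on each side, the convention of the standard enrichment-score
  tools, since profile plotting was delegated to external software in the
  original workflow. The enrichment score is the central bin's fold.
* **Fragment-length bands** — fractions of fragments at 0–100, 0–200 and
  0–300 bp, the shorthand used to describe FFPE degradation.

Filtering presets are strict inequalities as published: `mouse` keeps
FRiT > 10 and > 1500 unique fragments; `human` FRiT > 7 and > 1000; the
`tss_score` variant (TSS enrichment score ≥ 4 and ≥ 1500 fragments) is
the non-strict form used when benchmarking against standard single-cell
ATAC. FRiT thresholds of 10 and 7 are only meaningful on a percent scale,
so FRiT is reported in percent.

# Pseudo-bulk differential accessibility

Single-cell accessibility counts are too sparse for per-cell tests, so
replicates are manufactured by resampling: per group, each of $R$
replicates averages the depth-normalised profiles (counts scaled to
10,000 per cell) of 500 randomly sampled cells — without replacement
within a replicate, with replacement (flagged) when the group is smaller
than 500. $R$ defaults to 5 (the mouse setting; 10 was used for human
clinical samples). Per peak, the R-vs-R replicate means are compared with
a two-sided t-test; we use the Welch form, as the published description
says only "t-test" and unequal variances cost little when they are in
fact equal. BH correction is applied over peaks, and a peak passes at
q < 0.05 with a fold change ≥ 2. Fold changes are computed on
$\varepsilon$-padded means ($\varepsilon = 10^{-6}$ on the normalised
scale) symmetrically in both directions, so zero-mean peaks neither crash
nor pass spuriously. Peaks constant across all replicates are assigned
p = 1.

Cell-type-specific peaks run the same machinery one-vs-rest per type,
keep peaks enriched **toward** the target type, and then apply the
exclusivity rule: any peak passing in more than one type is removed from
every final set, making the sets pairwise disjoint by construction. The
replicate count for one-vs-rest is not separately published; it defaults
to the same $R = 5$. One figure legend of the source workflow mentions a
one-sided Fisher test for a related comparison; the procedure implemented
here is the pseudo-bulk t-test described in its methods.

# Bootstrap robustness for pseudotime

The lineage engine is pluggable. The default is intentionally minimal —
a minimum spanning tree over cluster centroids, lineages as root-to-leaf
cluster paths from a designated start cluster, and per-cell pseudotime as
the arc length of the cell's orthogonal projection onto the
piecewise-linear centroid path. It is not a principal-curve method and is
not meant to replace one; it exists so the bootstrap layer has a fast,
deterministic engine to drive and test.

The bootstrap layer resamples cells with replacement $B$ times (1000 in
the published analysis; tests here use 200), reruns the engine, and maps
each bootstrap lineage back to a reference lineage. The default match is
**exact ordered cluster-sequence equality** — the conservative reading of
a branch being "recovered" — with a relaxed terminal-cluster mode
available. Branch support is the fraction of valid replicates recovering
the lineage; replicates whose resample lost the start cluster are invalid
and excluded from the denominator (and counted). Pseudotimes are stored
in a cells × lineages × bootstraps array with missingness: a cell drawn
multiple times contributes its single engine value; a cell absent from a
resample is missing in that slice. Per (cell, lineage), the summary is
the median and the 2.5th/97.5th percentiles of the non-missing values —
a 95% percentile interval — with cells observed in fewer than 20
replicates flagged low-confidence.

# The synthetic-data generator

The generator exists to make every claim above testable with known truth.
It emulates, deterministically per seed:

* a random genome with well-separated TSS and peak annotations (features
  on a 7-kb grid so that TSS windows, profile flanks and peaks never
  collide);
* cells with barcode tuples sampled without replacement (or with
  replacement from a restricted space, to reproduce the birthday-paradox
  setting);
* FFPE-length fragments — the `ffpe` preset is a truncated lognormal with
  mode ≈ 60 bp and a hard floor of 20 bp, chosen to reproduce the
  published dominance of sub-100/sub-300 bp fragments without claiming to
  be the real length law; `fresh` is a nucleosomal mixture. Per cell, an
  exact share of fragments is planted inside TSS windows and peaks, and
  background placement rejects those regions, so FRiT/FRiP truth is exact
  by construction;
* duplicate structure — IVT copies per fragment and PCR copies per
  molecule are both 1 + geometric (means 2 and 1.5 by default; the real
  copy-number laws are unpublished, and geometric gives the heavy tail
  such processes show). IVT copies share the 5' insertion coordinate and
  shorten at the 3' end; the transcript-length model (uniform fraction of
  the insert) is an assumption of the generator, not a published fact;
* reads — the full staggered frame with configurable substitution rates
  for barcode and genomic bases, adaptor read-through for short inserts,
  and a truth table mapping every read to its cell and fragment.

What the generator does **not** emulate: indels, quality-score structure,
GC and sequence-composition bias, chimeric molecules, doublets, and real
chromatin co-accessibility structure. Green tests therefore demonstrate
algorithmic correctness against the stated model, not performance on any
particular tissue.

# Numerical and scale choices

Whitelist validation, anchor ties, half-open interval arithmetic and the
degenerate cases (empty inputs, all-zero cells, constant peaks,
single-lineage data, cells lost from resamples) are all handled
explicitly and covered by tests. The test and acceptance workloads use
deliberately modest sizes — $10^4$ read pairs for the decoder round trip,
$10^4$ aligned pairs for deduplication, 550 peaks × 4000 cells with 200
permutation replicates for the differential layer, and $B = 200$
bootstraps on a 400-cell bifurcation — sizes at which the stochastic
checks are already stable. The acceptance script recomputes the headline
collision figure analytically; everything else it relies on is covered by
the test suite.

# Limitations

* Alignment, peak calling, embedding, clustering and motif analysis are
  out of scope; the package starts from FASTQ and hands off to the
  standard tools at the conventional boundaries (per-index FASTQ,
  fragments files, peak × cell matrices).
* The dedup key for linear amplification and the IVT transcript-length
  model are recorded assumptions (see above), not published facts.
* The default lineage engine is a stand-in adequate for well-separated
  clusters; real analyses should plug in a curve-fitting engine and keep
  the bootstrap layer.
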