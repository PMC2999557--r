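---
title: "Calling broad heterochromatin domains at zinc-finger gene clusters: methods and design notes"
author: "znfdomains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Broad-domain methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(znfdomains)
```

This vignette records the models behind each stage of the package, the
parameters that matter, the numerical conventions, and the design choices
that were genuinely open — in the spirit of a methods supplement a
maintainer can argue with.

## The biological setting

Clustered C2H2 zinc-finger (ZNF) genes carry broad H3K9me3 heterochromatin
domains over their 3′ (final) exons, where the tandem finger/linker coding
repeats live. A KRAB-ZNF factor binds there and recruits KAP1 and the
H3K9 methyltransferase SETDB1, so a site-specific factor signal (sharp
peaks) sits at the centre of broad repressive domains. The package's job is
to make every computational claim in that chain testable: call the broad
domains on two platforms, show replicates agree, show the sharp and broad
signals co-localize, assign sites to the right genes, and recover the
sequence motif in the finger/linker repeats that distinguishes bound from
unbound ZNF genes.

## Coordinate conventions

Every file the package reads or writes uses BED-style 0-based half-open
coordinates. In memory, ranges are `GRanges` (1-based closed — the
Bioconductor convention); conversion happens once at the I/O boundary.
Interval centers are `floor((start0 + end0)/2)` in 0-based terms, a
convention shared by the callers, the distance profiles and the sequence
extraction, so all midpoint arithmetic agrees to the base pair.

## Tiling-array caller

The array model is a probe every `tile_interval_bp` (100 bp, the HD2-style
tiling density) carrying a log2(ChIP/input) ratio. Four parameters define a
peak, all exposed in `mayacamas_config()`:

| parameter | default | role |
|---|---|---|
| `smooth_halfwidth_oligos` | 5 | sliding-average halfwidth, in probes |
| `percentile_level` | 0.01 | top fraction of smoothed probes called "above" |
| `min_span_bp` | 800 | minimum first-probe-start to last-probe-end span |
| `max_missing_oligos` | 6 | missing grid positions bridged per region |
| `min_expected_fraction` | 0.5 | occupancy floor relative to expected probes |

Smoothing is done in probe-index space, not bp space: where probes are
missing (repetitive sequence has no unique oligos) the window widens in bp
rather than shrinking in sample count, which is what keeps broad domains
intact across probe gaps. The 5% level suits spreading histone marks; 1%
suits site-specific factors; 0.5% suits sparse factors.

Two readings of the missing-probe rule were possible: at most 6 missing
positions *in total* per region, or at most 6 *consecutive*. We read it as
total-per-region, implemented as a greedy run builder that bridges grid
gaps while the cumulative missing budget holds; a *present* probe below
threshold always terminates a run, because bridging exists for absent
probes, not weak signal. The expected probe count of a region is
`floor(span / tile_interval) + 1`. The percentile threshold is the k-th
largest smoothed value with `k = ceiling(level · N)`; "above threshold"
means `value ≥ cutoff` everywhere, so with tied values the above set can
exceed k.

## ChIP-seq broad caller

Tags (5′ positions of uniquely mapped reads) are extended
`fragment_length_bp` (150 bp, the approximate minimal chromatin fragment)
3′-ward, strand-aware. Per-bp fragment coverage is averaged in 30 bp bins
anchored at multiples of 30 from coordinate 0, and each bin is smoothed by
the mean of raw bin values whose starts lie within ±600 bp (a 41-bin
window, truncated at chromosome edges). We smooth *fragment coverage*
rather than raw tag counts; either reading is defensible, and coverage is
the quantity the minimum-length filter is phrased in.

The height cutoff is empirical-FDR based: over the ascending grid of
observed ChIP bin values,

$$\mathrm{FDR}(h) = \frac{s \cdot \#\{\text{input bins} \ge h\}}{\#\{\text{ChIP bins} \ge h\}},
\qquad s = \frac{\text{depth}_{\text{ChIP}}}{\text{depth}_{\text{input}}},$$

and h\* is the lowest h with FDR(h) ≤ 0.01, found by exhaustive scan so the
"lowest qualifying value" semantics are exact. The scale factor is applied
to the input *exceedance count*; when no h qualifies the caller returns a
"no signal" marker and emits nothing. Runs of qualifying bins shorter than
150 bp are dropped. Depth scaling replaces the original caller's
CNV-aware input normalisation (duplication/deletion detection in the input
library), a deliberate simplification: the synthetic inputs are
copy-neutral, and CNV modelling is out of scope. The original caller's
third step — significance over background — is deliberately absent in
broad-domain mode, since small input peaks do not affect calls over broad
domains.

## Replicate QC and peak-set operations

The replicate rule truncates both ranked lists to n = min(|A|, |B|)
top-ranked peaks and compares `ceiling(0.4 · n)` top peaks of one against
the whole truncated other list, both directions; overlap means ≥ 1 bp.
When the two replicates differ in size, both are truncated to the minimum
— the rule never says which list the original procedure truncated, and
truncating both is the symmetric choice. qPCR fold enrichment is
`2^(ct_input − ct_chip)`.

Distance profiles use signed center-to-center distances (query − subject),
nearest by absolute value, ties to the smaller subject coordinate; query
peaks on subject-free chromosomes are reported `NA` rather than silently
dropped. `top_fraction` keeps `ceiling(frac·N)` peaks with ties resolved by
(chromosome, start), so boundary ties are deterministic.

## Two-pass gene assignment

Standard nearest-TSS annotation fails in ZNF clusters: a site in gene A's
final exon can be closer to neighbour B's promoter than to A's own TSS.
Pass 1 therefore assigns every peak that intersects a gene body
(`[tx start, tx end)`) to that gene; pass 2 sends only the remaining peaks
to the nearest strand-aware TSS (transcript start on +, transcript end on
−), measured from the peak center. When a peak overlaps two gene bodies,
the greater overlap wins, then the smaller gene start — the tie rule is our
choice; nothing in the procedure being reproduced specifies it. Context is
classified from the peak center against the assigned gene's exons, with
the final exon defined in transcription order (genomically first for −
genes).

Expression quintiles use the 20/40/60/80th percentiles (R's default
type-7 quantiles) of the full expression table, boundaries belonging to
the lower quintile.

## Motif discovery with a coding background

All ZNF final exons — bound or not — share finger/linker coding sequence,
so the informative background is unbound-ZNF final exons, not promoters.
Discovery is a fully specified k-mer-seed procedure:

1. Count each k-mer's sites (k = 6…12, either orientation, palindromes
   once) in foreground and background.
2. Score enrichment with a one-sided *conditional* binomial: given the
   pooled fg+bg site count, the probability of at least the observed
   foreground share under p₀ = W_fg / (W_fg + W_bg) (window totals). This
   two-pool form stays calibrated when background counts are 0 — a naive
   test against an estimated background *rate* declares any k-mer with
   zero background count infinitely significant. Window totals are frozen
   at their pre-masking values so masking one motif cannot inflate the
   apparent enrichment of everything else.
3. Accept the longest k with any k-mer passing Bonferroni (over 4^k) at
   10⁻⁶, take its best k-mer, align its occurrences ±3 bp, build a
   pseudocount-0.25 PWM on background base composition, mask the
   occurrences, repeat (≤ 30 rounds). Preferring the longest passing seed
   makes rounds produce overlapping, specific fragments of long motifs
   rather than a blur of 6-mers.
4. Merge PWMs whose best ungapped alignment (either orientation) reaches a
   mean per-column Pearson correlation of 0.8, summing aligned counts;
   merged length is capped at the foreground sequence length (a motif
   longer than the sequences it came from cannot be scored); low-information
   edge columns (< 0.3 bits) are trimmed. This is how fragments of one
   long motif — including a pair discovered in opposite orientations —
   reassemble.
5. Classify foreground sequences as motif-positive with a deterministic
   1-D two-means split of best-hit scores, and fit the stringency pair as
   the mean 5th-percentile core and PWM scores of the positive class over
   100 bootstrap resamples. The occurrence count reported per motif is the
   number of motif-positive sequences.

Match scores follow the matrix-library convention: the summed
log-probability of a window, min–max normalised by the worst/best
attainable sums, for the full matrix (PWM score) and for the core — the 5
consecutive columns maximising summed information content (core score).
Consensus windows score exactly 1, per-position-worst windows exactly 0.
Windows containing non-ACGT symbols are skipped. Scans report all windows
(both strands, overlaps allowed) meeting a `(core_cut, pwm_cut)` pair;
hit sets are nested across stringencies by construction. A 10⁻⁹ tolerance
guards the `cut = 1.00` comparison against float round-off.

`merge_reverse_oriented` handles the composite-motif analysis directly on
consensi: the consensus of one motif is slid against the reverse
complement of the other over all offsets with ≥ 4 aligned columns; ≥ 90%
identity in the overlap merges them into a consensus of length
L_B + L_A − overlap.

## What the synthetic generator emulates — and what it does not

`sim_config()` defaults define the study conditions: two chromosomes with
~85% of C2H2 genes clustered on the first (mirroring the concentration of
human ZNF genes on chromosome 19); 400 genes, 55% C2H2, 60% of C2H2 genes
bound — giving ~132 bound genes versus ~88 unbound background exons,
tracking the scale of the experiment being emulated (a few hundred peak
sequences against ~90 background exons); four exons per gene with the
final exon carrying 4–15 tandem 84 bp finger/linker repeats; a fixed
canonical 29 bp linker motif planted per repeat in bound genes at 10%
per-position mutation, and a divergent linker (9 fixed mismatches) in
unbound genes; 2 kb domains at 5-fold enrichment over bound final exons
with 150 bp sharp sites at 10-fold at domain centers; array noise SD 0.25
with 5% missing probes; 200k tags per channel. Array values are
`log2(fold)` plus Gaussian noise; tag fragment centers are multinomial
over a piecewise-constant intensity, with uniform input.

Deliberately *not* modelled: read sequences and qualities, mappability,
GC bias, copy-number variation, fragment-length variation, isoform
structure, and overdispersion beyond multinomial sampling. Passing tests
therefore demonstrate algorithmic correctness and calibration under the
stated noise model, not robustness to every artefact of real libraries —
in particular the empirical-FDR cutoff inherits whatever biases a real
input library carries.

One synthetic-data subtlety worth knowing: because foreground windows sit
inside tandem coding repeats, naive discovery tends to walk along the
repeat unit (linker → junction → finger core). The frozen window totals in
step 2 and the merged-length cap in step 4 are what keep the discovered
motif anchored on the linker, which is the only part that differs between
bound and unbound genes.

## Problem sizes and determinism

The test suite and acceptance script run at desk scale, chosen to exercise
each property with comfortable margins: 200 random tracks for the
array-caller oracle; 5 Mb genomes with 100k–500k tags per channel for the
sequencing caller's null calibration (20 seeds), planted-domain recovery
(5 seeds) and replicate QC (10 seeds); 337 × 100 nt sequences with 200
planted motif copies for discovery (5 seeds). Every random stream derives
from one master seed via fixed sub-seed labels (`derive_seed`), so a run
is reproducible bit for bit; the generators use R's default RNG.

## Known limitations

- The empirical FDR is a count ratio, not a p-value; with very shallow
  libraries the observed-value grid is coarse and h\* jumps discretely.
- The greedy missing-probe budget can split one true region into two when
  a wide probe desert sits mid-domain; the alternative (bridge-then-reject)
  would instead drop the region entirely.
- Two-pass assignment is transcript-model-free: one interval per gene, no
  isoforms, and a peak spanning two genes is assigned to exactly one.
- Discovery assumes the motif is ungapped and well covered by exact
  k-mer seeds at the planted mutation rate; above ~20% per-position
  divergence the seed counts fall below the Bonferroni bar and the
  procedure (correctly, but unhelpfully) returns nothing.
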