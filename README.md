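# znfdomains

Broad heterochromatin-domain peak calling and binding-site analysis for
C2H2 zinc-finger (ZNF) gene clusters.

## The problem

The 3′ ends of clustered C2H2 zinc-finger genes are covered by broad
H3K9me3 heterochromatin domains, nucleated where a KRAB-ZNF factor recruits
the KAP1/SETDB1 corepressor–methyltransferase complex. Analysing this system
computationally is awkward on four fronts, and each gets a dedicated module
here:

1. **Broad domains break point-source peak callers.** Spreading marks such
   as H3K9me3 need callers that tolerate kilobase-scale enrichment and, on
   tiling arrays, gaps where repetitive sequence has no unique probes.
2. **Replicate agreement needs a rank-aware rule**, because small peak sets
   from factors with few binding sites make naive overlap fractions
   unstable.
3. **Nearest-TSS annotation misassigns 3′-exon binding sites.** In dense
   ZNF clusters a site in one gene's final exon is often closer to the
   *neighbouring* gene's promoter.
4. **Motif discovery in coding repeats needs a coding background.** Final
   exons of all ZNF genes share finger/linker coding motifs, so promoters
   are the wrong null model; the informative comparison is bound versus
   unbound ZNF 3′ exons.

Everything runs against synthetic genomes with planted truth (domains,
sharp sites, a 29 bp motif in the finger/linker repeats of "bound" genes),
so every stage is scored against known answers without any external data.

## Methods at a glance

**Tiling-array caller** (`smooth_track`, `percentile_cutoff`,
`call_chipchip_peaks`). Probe log2 ratios are smoothed with a sliding
average over five probes on either side; the threshold is the top 5% / 1% /
0.5% of smoothed probes; a peak is a run of above-threshold probes spanning
≥ 800 bp, bridging at most 6 missing grid positions, and containing at
least half of the expected probes.

**ChIP-seq broad caller** (`bin_and_smooth`, `fdr_height_cutoff`,
`call_broad_peaks`). Tags are extended to 150 bp fragments; coverage is
averaged in 30 bp bins and smoothed over ±600 bp. The height cutoff h\* is
the lowest observed bin value whose empirical FDR

    FDR(h) = scale · #{input bins ≥ h} / #{ChIP bins ≥ h},
    scale = depth(ChIP) / depth(input)

does not exceed 0.01; runs of qualifying bins ≥ 150 bp become peaks.

**Replicate QC** (`encode_overlap`). Both ranked peak lists are truncated
to the same length n; the top 40% of one list is intersected (≥ 1 bp) with
the full truncated other list, in both directions.

**Location analysis** (`assign_targets`). Pass 1 assigns peaks inside a
gene body to that gene (greatest overlap wins); only the remainder go to
the nearest strand-aware TSS in pass 2. Context is classified against the
assigned gene's exons (final exon = 3′-most in transcription order).

**Motif pipeline** (`discover_motifs`, `scan_sequences`,
`merge_reverse_oriented`). 100 nt windows around peak midpoints are tested
against unbound-ZNF final exons: k-mer seeds (k = 6–12) are scored by a
one-sided conditional binomial on pooled foreground/background site counts
with Bonferroni correction over 4^k, grown into PWMs (pseudocount 0.25),
masked, and re-seeded for up to 30 rounds; overlapping fragments merge by
per-column correlation (≥ 0.8), reassembling long composite motifs.
Matches are scored with min–max-normalised PWM and core scores (core = the
5 consecutive most-informative columns) at stringency pairs such as
(1.00/0.99) and (1.00/0.95), and two motifs whose consensi overlap in
reverse orientation are merged into one long motif.

## Worked example

```r
library(znfdomains)

cfg <- sim_config(seed = 4, chrom_lengths = c(chrZ = 1.2e6, chrO = 8e5),
                  n_genes = 150, n_chip_tags = 100000, n_input_tags = 100000)
gen <- make_genome(cfg)
cat("C2H2 genes:", sum(gen$genes$is_c2h2),
    "| bound:", length(gen$truth$bound_gene_ids), "\n")

chip  <- simulate_tags(gen$truth, cfg, "chip")
input <- simulate_tags(gen$truth, cfg, "input")
peaks <- call_chipseq_peaks(chip, input, cfg$chrom_lengths, verbose = TRUE)

sc <- score_recovery(peaks, gen$truth$domains)
cat(sprintf("domain recall %.2f, precision %.2f\n", sc$recall, sc$precision))

reps <- make_replicates(gen$truth, cfg, n = 2)
pks  <- lapply(reps, call_chipseq_peaks, input = input,
               chrom_lengths = cfg$chrom_lengths)
qc <- encode_overlap(pks[[1]], pks[[2]])
cat(sprintf("replicate overlap: %.2f / %.2f (n = %d)\n",
            qc$frac_a_in_b, qc$frac_b_in_a, qc$truncated_n))

asg <- assign_targets(peaks, gen$genes)
table(asg$context)
```

Output:

```
C2H2 genes: 82 | bound: 49
scale=1.0000 cutoff=10.92846 peaks=49
domain recall 1.00, precision 1.00
replicate overlap: 1.00 / 1.00 (n = 49)

final_exon
        49
```

Reading it: 49 of the 82 simulated C2H2 genes carry a planted 2 kb, 5-fold
domain over their final exon. With 100k ChIP and 100k input tags the
empirical-FDR cutoff lands at a smoothed coverage of 10.93, all 49 domains
are recovered with no false calls, two same-truth replicates agree
perfectly under the top-40% rule, and every called peak is assigned to the
final exon of its gene — the signature the pipeline is built to detect.

`run_pipeline(pipeline_config(seed = 1), "out/")` chains all stages —
array and sequencing callers, replicate QC, peak-set and location analyses,
motif discovery/scan/merge — and writes BED/TSV tables, a run log and a
truth-versus-called scoring table under `out/`.

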