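#' Pipeline configuration
#'
#' Bundles the nested stage configurations and a master seed. The master
#' seed overrides the simulation seed so one integer reproduces the whole
#' run.
#'
#' @param seed master seed.
#' @param sim a [sim_config()].
#' @param mayacamas a [mayacamas_config()].
#' @param broadcall a [broadcall_config()].
#' @param stringencies list of `c(core_cut, pwm_cut)` pairs for the genome
#'   motif scan.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, sim = sim_config(),
                            mayacamas = mayacamas_config(),
                            broadcall = broadcall_config(),
                            stringencies = list(c(1.00, 0.99), c(1.00, 0.95))) {
  sim$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), sim = sim, mayacamas = mayacamas,
                 broadcall = broadcall, stringencies = stringencies),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Truth variant whose only enriched features are the sharp sites: used to
# simulate a site-specific factor's library over the same genome.
sharp_channel_truth <- function(truth) {
  truth$domains <- truth$domains[integer(0)]
  truth
}

#' Run the end-to-end synthetic experiment
#'
#' Generates a synthetic genome with planted truth; simulates and calls
#' tiling-array peaks at the three percentile levels; simulates ChIP/input
#' tag libraries for a broad (domain-spreading) channel and a sharp
#' (site-specific) channel and calls peaks on both; simulates two broad
#' replicates and scores their top-40% overlap; computes peak-set overlaps,
#' per-chromosome counts and the top-10% distance-to-nearest profile;
#' assigns peaks to genes and builds the finger-count histogram; extracts
#' peak sequences, discovers motifs against the unbound-ZNF-exon
#' background, scans the genome at each stringency pair, classifies hits by
#' ZNF-gene proximity and attempts the reverse-orientation merge of the two
#' most frequent motifs. All tables are written under `out_dir` along with
#' a run log and a truth-versus-called scoring table.
#'
#' @param config a [pipeline_config()].
#' @param out_dir writable output directory (created if needed).
#' @return (invisibly) a report list with every computed object.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempdir()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  emit <- function(obj, file, writer) {
    path <- file.path(out_dir, file)
    writer(obj, path)
    manifest <<- c(manifest, file)
    path
  }
  log_lines <- c(sprintf("master_seed\t%d", config$seed),
                 sprintf("sim.%s\t%s", names(config$sim),
                         vapply(config$sim, function(x)
                           paste(format(x), collapse = ","), "")))

  gen <- make_genome(config$sim)
  emit(gen$genome, "genome.fa", function(x, p)
    Biostrings::writeXStringSet(x, p))
  emit(gen$genes, "genes.tsv", write_gene_table)
  truth_df <- rbind(
    data.frame(type = "domain",
               chrom = as.character(GenomicRanges::seqnames(gen$truth$domains)),
               start = bed0_start(gen$truth$domains),
               end = bed0_end(gen$truth$domains),
               fold = gen$truth$domains$fold, id = "", strand = "."),
    data.frame(type = "sharp_site",
               chrom = as.character(GenomicRanges::seqnames(gen$truth$sharp_sites)),
               start = bed0_start(gen$truth$sharp_sites),
               end = bed0_end(gen$truth$sharp_sites),
               fold = gen$truth$sharp_sites$fold, id = "", strand = "."),
    if (nrow(gen$truth$motif_insertions) > 0)
      data.frame(type = "motif",
                 chrom = "", start = gen$truth$motif_insertions$offset,
                 end = gen$truth$motif_insertions$offset + 29L, fold = 1,
                 id = gen$truth$motif_insertions$gene_id,
                 strand = gen$truth$motif_insertions$strand))
  emit(truth_df, "truth.tsv", write_tsv)

  # tiling-array channel
  arr <- simulate_array(gen$truth, config$sim)
  sm <- smooth_track(arr, config$mayacamas$smooth_halfwidth_oligos)
  array_peaks <- list()
  for (lev in c(0.05, 0.01, 0.005)) {
    cfg <- config$mayacamas
    cfg$percentile_level <- lev
    pk <- call_chipchip_peaks(sm, cfg)
    array_peaks[[sprintf("level_%g", lev)]] <- pk
    emit(pk, sprintf("array_peaks_%g.bed", lev), write_bed)
  }

  # sequencing channels: broad (domains + sites) and sharp (sites only)
  cl <- config$sim$chrom_lengths
  chip <- simulate_tags(gen$truth, config$sim, "chip")
  input <- simulate_tags(gen$truth, config$sim, "input")
  emit(chip, "chip.tags", write_tags)
  emit(input, "input.tags", write_tags)
  broad_peaks <- call_chipseq_peaks(chip, input, cl, config$broadcall)
  emit(broad_peaks, "broad_peaks.bed", write_bed)

  sharp_truth <- sharp_channel_truth(gen$truth)
  sharp_chip <- simulate_tags(sharp_truth, config$sim, "chip",
                              seed = derive_seed(config$seed, "sharp_chip"))
  sharp_peaks <- call_chipseq_peaks(sharp_chip, input, cl, config$broadcall)
  emit(sharp_peaks, "sharp_peaks.bed", write_bed)

  # replicate QC on the broad channel
  reps <- make_replicates(gen$truth, config$sim, n = 2L)
  rep_peaks <- lapply(reps, call_chipseq_peaks, input = input,
                      chrom_lengths = cl, config = config$broadcall)
  qc <- encode_overlap(rep_peaks[[1]], rep_peaks[[2]])
  emit(data.frame(frac_a_in_b = qc$frac_a_in_b,
                  frac_b_in_a = qc$frac_b_in_a,
                  truncated_n = qc$truncated_n),
       "replicate_overlap.tsv", write_tsv)

  # peak-set analyses
  oc <- overlap_counts(broad_peaks, sharp_peaks)
  emit(data.frame(n_broad_overlapping_sharp = oc$n_a_overlapping_b,
                  n_sharp_overlapping_broad = oc$n_b_overlapping_a),
       "overlap_counts.tsv", write_tsv)
  emit(per_chromosome_counts(sharp_peaks, gen$genes),
       "per_chromosome.tsv", write_tsv)
  dprof <- distance_to_nearest(top_fraction(broad_peaks, 0.10), sharp_peaks)
  emit(dprof, "distance_profile.tsv", write_tsv)
  emit(distance_histogram(dprof), "distance_histogram.tsv", write_tsv)

  # location analysis
  assignments <- assign_targets(sharp_peaks, gen$genes)
  emit(assignments, "assignments.tsv", write_tsv)
  emit(finger_count_histogram(assignments, gen$genes),
       "finger_histogram.tsv", write_tsv)

  # motif pipeline on the sharp channel
  fg <- extract_peak_sequences(sharp_peaks, gen$genome)
  bgset <- build_background_set(gen$genes, sharp_peaks, gen$genome)
  motifs <- discover_motifs(fg, bgset, seed = config$seed)
  scan_results <- list()
  hit_class <- list()
  if (length(motifs) > 0) {
    emit(motifs[[1]], "motif_top.transfac", write_pwm)
    for (sp in config$stringencies) {
      key <- sprintf("%.2f_%.2f", sp[1], sp[2])
      hits <- scan_sequences(gen$genome, motifs[[1]],
                             core_cut = sp[1], pwm_cut = sp[2])
      scan_results[[key]] <- hits
      hit_class[[key]] <- classify_hits(hits, gen$genes)
      emit(hits, sprintf("genome_hits_%s.tsv", key), write_tsv)
    }
  }
  motif_merge <- if (length(motifs) >= 2) {
    merge_reverse_oriented(motifs[[1]], motifs[[2]])
  } else NULL

  # truth-versus-called scoring
  broad_score <- score_recovery(broad_peaks, gen$truth$domains)
  sharp_score <- score_recovery(sharp_peaks, gen$truth$sharp_sites,
                                min_jaccard = 0.05)
  emit(data.frame(channel = c("broad", "sharp"),
                  recall = c(broad_score$recall, sharp_score$recall),
                  precision = c(broad_score$precision, sharp_score$precision),
                  n_truth = c(broad_score$n_truth, sharp_score$n_truth),
                  n_called = c(broad_score$n_called, sharp_score$n_called)),
       "scoring.tsv", write_tsv)

  writeLines(log_lines, file.path(out_dir, "run_log.tsv"))
  writeLines(sort(manifest), file.path(out_dir, "MANIFEST"))
  invisible(list(genes = gen$genes, truth = gen$truth,
                 array_peaks = array_peaks, broad_peaks = broad_peaks,
                 sharp_peaks = sharp_peaks, replicate_qc = qc,
                 overlap_counts = oc, distance_profile = dprof,
                 assignments = assignments, motifs = motifs,
                 scan_results = scan_results, hit_class = hit_class,
                 motif_merge = motif_merge, broad_score = broad_score,
                 sharp_score = sharp_score, manifest = manifest))
}
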