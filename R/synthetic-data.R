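# Canonical planted 29 bp motif: stands in for the composite linker/H2-helix
# coding motif carried by the tandem finger repeats of bound ZNF genes. Any
# fixed 29 bp string works because all scoring compares against the planted
# truth; this one is a zinc-finger-linker-like coding sequence.
CANONICAL_29MER <- "TGAGAAGCCCTACGAATGTAAGGAATGTG"

# Divergent linker used in unbound C2H2 genes: the canonical 29mer with every
# third position substituted (9 mismatches), so unbound finger repeats still
# look like finger/linker coding but do not carry the motif.
divergent_29mer <- function() {
  x <- strsplit(CANONICAL_29MER, "")[[1]]
  pos <- seq(3, 29, by = 3)
  x[pos] <- DNA_BASES4[(match(x[pos], DNA_BASES4) %% 4) + 1]
  paste(x, collapse = "")
}

# Fixed 55 bp finger-core coding unit; one finger repeat = core + 29 bp linker
# (84 bp total).
FINGER_CORE_55 <- "TTCAGTTGTGGGATCTGTGGAAAATCCTTTACTCAAAGCTCAAGTCTGATCCGAC"

#' Simulation configuration
#'
#' Defines the synthetic study conditions: a designated ZNF chromosome
#' carrying clustered multi-exon C2H2 zinc-finger genes whose final exons
#' hold tandem finger/linker repeats, a bound subset whose repeats carry a
#' plantable 29 bp motif, broad enriched domains over those 3' exons with
#' sharp sites at domain centers, tiling-array noise with missing probes,
#' and multinomial tag sampling for ChIP versus input channels.
#'
#' @param seed master seed; every random stream is derived from it.
#' @param chrom_lengths named chromosome lengths (bp); the first chromosome
#'   is the designated ZNF-cluster chromosome.
#' @param n_genes total genes to place.
#' @param frac_c2h2 fraction of genes that are C2H2 zinc-finger genes.
#' @param finger_count_distribution integer vector of finger-domain counts
#'   sampled uniformly for C2H2 genes.
#' @param frac_bound fraction of C2H2 genes that are bound (planted motif,
#'   domain and sharp site over the final exon).
#' @param domain_width_bp width of each planted broad domain.
#' @param domain_fold,sharp_fold enrichment folds of domains and sharp sites.
#' @param sharp_width_bp width of each planted sharp site.
#' @param array_noise_sd Gaussian noise SD of array log2 ratios.
#' @param probe_missing_prob probability that a probe is dropped.
#' @param n_chip_tags,n_input_tags library sizes.
#' @param fragment_length_bp chromatin fragment length for the tag model.
#' @param motif_mutation_rate per-position mutation rate of planted 29mers.
#' @param tile_interval_bp array probe spacing; probes are 50 bp long.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr19s = 2.5e6, chr2s = 1.5e6),
                       n_genes = 400L,
                       frac_c2h2 = 0.55,
                       finger_count_distribution = 4:15,
                       frac_bound = 0.6,
                       domain_width_bp = 2000L,
                       domain_fold = 5,
                       sharp_fold = 10,
                       sharp_width_bp = 150L,
                       array_noise_sd = 0.25,
                       probe_missing_prob = 0.05,
                       n_chip_tags = 200000L,
                       n_input_tags = 200000L,
                       fragment_length_bp = 150L,
                       motif_mutation_rate = 0.1,
                       tile_interval_bp = 100L) {
  cfg <- list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
              n_genes = as.integer(n_genes), frac_c2h2 = frac_c2h2,
              finger_count_distribution = as.integer(finger_count_distribution),
              frac_bound = frac_bound,
              domain_width_bp = as.integer(domain_width_bp),
              domain_fold = domain_fold, sharp_fold = sharp_fold,
              sharp_width_bp = as.integer(sharp_width_bp),
              array_noise_sd = array_noise_sd,
              probe_missing_prob = probe_missing_prob,
              n_chip_tags = as.integer(n_chip_tags),
              n_input_tags = as.integer(n_input_tags),
              fragment_length_bp = as.integer(fragment_length_bp),
              motif_mutation_rate = motif_mutation_rate,
              tile_interval_bp = as.integer(tile_interval_bp))
  with(cfg, {
    stop_if_not(all(c(frac_c2h2, frac_bound, probe_missing_prob,
                      motif_mutation_rate) >= 0) &&
                  all(c(frac_c2h2, frac_bound, probe_missing_prob,
                        motif_mutation_rate) <= 1),
                "probabilities must lie in [0, 1]")
    stop_if_not(all(c(domain_fold, sharp_fold) >= 1), "folds must be >= 1")
    stop_if_not(all(chrom_lengths > 0) && !is.null(names(chrom_lengths)),
                "chrom_lengths must be named and positive")
    stop_if_not(array_noise_sd >= 0, "array_noise_sd must be >= 0")
  })
  class(cfg) <- "sim_config"
  cfg
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  x <- strsplit(seq, "")[[1]]
  hit <- runif(length(x)) < rate
  if (any(hit)) {
    x[hit] <- vapply(x[hit], function(b)
      sample(setdiff(DNA_BASES4, b), 1L), "")
  }
  paste(x, collapse = "")
}

random_dna <- function(n) {
  paste(sample(DNA_BASES4, n, replace = TRUE), collapse = "")
}

#' Generate a synthetic genome, gene annotation and planted truth
#'
#' Genes are laid out in clusters; C2H2 genes are concentrated on the first
#' (designated ZNF) chromosome, mirroring the clustering of zinc-finger genes
#' on human chromosome 19. Every gene has three 150 bp upstream exons and a
#' final exon; C2H2 final exons carry `finger_count` tandem 84 bp
#' finger/linker repeats flanked by 60 bp pads. In bound genes each repeat's
#' linker is the canonical 29mer mutated per position at
#' `motif_mutation_rate`; unbound C2H2 genes carry a divergent linker with 9
#' mismatches to the canonical sequence. Broad domains (width
#' `domain_width_bp`, fold `domain_fold`) are planted over bound final exons
#' with sharp sites (fold `sharp_fold`) at the domain centers, so sharp-site
#' centers always lie inside a domain (co-localized truth).
#'
#' @param config a [sim_config()].
#' @return a list with `genome` (named `DNAStringSet`), `genes` (a
#'   [gene_table()]) and `truth` (a `truth_set`: `domains` and `sharp_sites`
#'   as `GRanges` with a `fold` column, `motif_insertions` data.frame with
#'   0-based genomic offsets, `bound_gene_ids`, `chrom_lengths`).
#' @export
make_genome <- function(config = sim_config()) {
  set.seed(derive_seed(config$seed, "genome"))
  cl <- config$chrom_lengths
  n_c2h2 <- round(config$n_genes * config$frac_c2h2)
  n_other <- config$n_genes - n_c2h2
  # ~85% of C2H2 genes on the designated chromosome, the rest (and all
  # non-C2H2 genes) spread over the remaining chromosomes
  znf_chrom <- names(cl)[1]
  if (length(cl) > 1) {
    n_c2h2_main <- ceiling(0.85 * n_c2h2)
    gene_chrom <- c(rep(znf_chrom, n_c2h2_main),
                    rep(names(cl)[-1], length.out = n_c2h2 - n_c2h2_main),
                    rep(names(cl)[-1], length.out = n_other))
  } else {
    gene_chrom <- rep(znf_chrom, config$n_genes)
  }
  is_c2h2 <- c(rep(TRUE, n_c2h2), rep(FALSE, n_other))
  fc <- ifelse(is_c2h2,
               sample(config$finger_count_distribution, config$n_genes,
                      replace = TRUE), 0L)
  n_bound <- round(n_c2h2 * config$frac_bound)
  bound <- rep(FALSE, config$n_genes)
  if (n_bound > 0) bound[sample(seq_len(n_c2h2), n_bound)] <- TRUE
  strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)

  # final exon: 60 bp pad + finger repeats + 60 bp pad (300 bp if no fingers)
  fexon_len <- ifelse(is_c2h2, 120L + 84L * fc, 300L)
  rows <- vector("list", config$n_genes)
  cursor <- setNames(rep(10000L, length(cl)), names(cl))
  placed_in_cluster <- setNames(rep(0L, length(cl)), names(cl))
  for (i in seq_len(config$n_genes)) {
    chr <- gene_chrom[i]
    es <- cursor[[chr]] + c(0L, 550L, 1100L, 1650L)
    ee <- es + c(150L, 150L, 150L, fexon_len[i])
    if (strand[i] == "-") {  # mirror exon sizes so the final exon is 5'-most
      sizes <- rev(ee - es)
      es <- cursor[[chr]] + cumsum(c(0L, sizes[-4] + 400L))
      ee <- es + sizes
    }
    gend <- ee[4]
    if (gend > cl[[chr]] - 10000L) {
      stop(sprintf("genes do not fit in chromosome %s (need > %d bp)",
                   chr, gend + 10000L), call. = FALSE)
    }
    rows[[i]] <- data.frame(gene_id = sprintf("G%04d", i), chrom = chr,
                            start = es[1], end = gend, strand = strand[i],
                            is_c2h2 = is_c2h2[i], finger_count = fc[i],
                            has_krab = is_c2h2[i] & (runif(1) < 0.8),
                            stringsAsFactors = FALSE)
    rows[[i]]$exon_starts <- list(es)
    rows[[i]]$exon_ends <- list(ee)
    placed_in_cluster[[chr]] <- placed_in_cluster[[chr]] + 1L
    gap <- if (placed_in_cluster[[chr]] %% 8L == 0L) 20000L else 2500L
    cursor[[chr]] <- gend + gap
  }
  genes <- gene_table(do.call(rbind, rows))

  # random genome, then overwrite final exons with finger/linker coding
  genome_chr <- lapply(names(cl), function(chr) {
    strsplit(random_dna(cl[[chr]]), "")[[1]]
  })
  names(genome_chr) <- names(cl)
  div29 <- divergent_29mer()
  bound_lookup <- setNames(bound, sprintf("G%04d", seq_len(config$n_genes)))
  mi_gene <- character(0); mi_off <- integer(0); mi_strand <- character(0)
  fe <- final_exon0(genes)
  for (i in seq_len(nrow(genes))) {
    if (!genes$is_c2h2[i]) next
    fcnt <- genes$finger_count[i]
    gene_bound <- bound_lookup[[genes$gene_id[i]]]
    linkers <- vapply(seq_len(fcnt), function(r) {
      if (gene_bound) mutate_seq(CANONICAL_29MER, config$motif_mutation_rate)
      else div29
    }, "")
    coding <- paste0(random_dna(60),
                     paste0(FINGER_CORE_55, linkers, collapse = ""),
                     random_dna(60))
    es0 <- fe[i, 1]; ee0 <- fe[i, 2]
    insert <- if (genes$strand[i] == "+") coding else revcomp_chr(coding)
    genome_chr[[genes$chrom[i]]][(es0 + 1):ee0] <- strsplit(insert, "")[[1]]
    if (gene_bound) {
      for (r in seq_len(fcnt)) {
        p <- 60L + (r - 1L) * 84L + 55L  # 0-based offset of linker in coding
        off <- if (genes$strand[i] == "+") es0 + p else ee0 - p - 29L
        mi_gene <- c(mi_gene, genes$gene_id[i])
        mi_off <- c(mi_off, off)
        mi_strand <- c(mi_strand, genes$strand[i])
      }
    }
  }
  genome <- Biostrings::DNAStringSet(vapply(genome_chr, paste,
                                            "", collapse = ""))
  names(genome) <- names(cl)

  bound_ids <- sprintf("G%04d", which(bound))
  bidx <- match(bound_ids, genes$gene_id)
  dom_center <- (fe[bidx, 1] + fe[bidx, 2]) %/% 2L
  dstart <- pmax(dom_center - config$domain_width_bp %/% 2L, 0L)
  dend <- pmin(dstart + config$domain_width_bp,
               cl[genes$chrom[bidx]])
  sstart <- pmax(dom_center - config$sharp_width_bp %/% 2L, 0L)
  send <- sstart + config$sharp_width_bp
  domains <- gr_from_bed0(genes$chrom[bidx], dstart, dend)
  domains$fold <- rep(config$domain_fold, length(domains))
  sharp <- gr_from_bed0(genes$chrom[bidx], sstart, send)
  sharp$fold <- rep(config$sharp_fold, length(sharp))
  truth <- structure(list(domains = domains, sharp_sites = sharp,
                          motif_insertions = data.frame(
                            gene_id = mi_gene, offset = mi_off,
                            strand = mi_strand, stringsAsFactors = FALSE),
                          bound_gene_ids = bound_ids,
                          chrom_lengths = cl),
                     class = "truth_set")
  list(genome = genome, genes = genes, truth = truth)
}

#' Simulate a tiling-array log2-ratio track
#'
#' Probes of 50 bp are placed every `tile_interval_bp` along each chromosome.
#' A probe whose midpoint lies inside a planted domain gets value
#' `log2(domain fold)`, others 0; Gaussian noise of SD `array_noise_sd` is
#' added and each probe is dropped independently with `probe_missing_prob`.
#'
#' @param truth a `truth_set` from [make_genome()].
#' @param config the [sim_config()] used to generate it.
#' @return an [array_track()].
#' @export
simulate_array <- function(truth, config) {
  set.seed(derive_seed(config$seed, "array"))
  cl <- truth$chrom_lengths
  out <- vector("list", length(cl))
  for (ci in seq_along(cl)) {
    chr <- names(cl)[ci]
    starts <- seq.int(0L, cl[[ci]] - 50L, by = config$tile_interval_bp)
    mid <- starts + 25L
    val <- numeric(length(starts))
    dom <- truth$domains[as.character(GenomicRanges::seqnames(truth$domains)) == chr]
    if (length(dom) > 0) {
      hit <- IRanges::findOverlaps(IRanges::IRanges(mid + 1L, mid + 1L),
                                   IRanges::ranges(dom), select = "first")
      inside <- !is.na(hit)
      val[inside] <- log2(dom$fold[hit[inside]])
    }
    if (config$array_noise_sd > 0) {
      val <- val + rnorm(length(val), 0, config$array_noise_sd)
    }
    keep <- runif(length(starts)) >= config$probe_missing_prob
    out[[ci]] <- data.frame(chrom = chr, probe_start = starts[keep],
                            probe_end = starts[keep] + 50L,
                            value = val[keep], stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  array_track(df$chrom, df$probe_start, df$probe_end, df$value,
              config$tile_interval_bp)
}

# Piecewise-constant per-bp intensity segments for one chromosome:
# baseline 1, multiplied by the fold of every overlapping planted feature.
intensity_segments <- function(truth, chr, channel) {
  len <- truth$chrom_lengths[[chr]]
  feats <- suppressWarnings(c(truth$domains, truth$sharp_sites))
  feats <- feats[as.character(GenomicRanges::seqnames(feats)) == chr]
  if (channel == "input" || length(feats) == 0) {
    return(data.frame(start = 0, end = len, w = 1))
  }
  brk <- sort(unique(c(0L, len, pmax(GenomicRanges::start(feats) - 1L, 0L),
                       pmin(GenomicRanges::end(feats), len))))
  seg_s <- brk[-length(brk)]; seg_e <- brk[-1]
  segq <- IRanges::IRanges(seg_s + 1L, seg_e)
  mult <- rep(1, length(seg_s))
  ov <- IRanges::findOverlaps(segq, IRanges::ranges(feats))
  if (length(ov) > 0) {
    f <- tapply(feats$fold[S4Vectors::subjectHits(ov)],
                S4Vectors::queryHits(ov), prod)
    mult[as.integer(names(f))] <- f
  }
  data.frame(start = seg_s, end = seg_e, w = mult)
}

#' Simulate a ChIP or input tag library
#'
#' Fragment centers are drawn from a piecewise-constant intensity: uniform
#' over the genome for the input channel; multiplied by the enrichment fold
#' over planted domains and sharp sites for the ChIP channel. Each fragment
#' of `fragment_length_bp` gets a random strand; the emitted tag is the
#' fragment's 5' start, so plus-strand tags sit upstream and minus-strand
#' tags downstream of site centers. Exactly `n_chip_tags` (or
#' `n_input_tags`) tags are emitted.
#'
#' @param truth a `truth_set`.
#' @param config a [sim_config()].
#' @param channel `"chip"` or `"input"`.
#' @param seed random seed; defaults to a channel-specific stream derived
#'   from `config$seed`.
#' @return a [tag_library()].
#' @export
simulate_tags <- function(truth, config, channel = c("chip", "input"),
                          seed = NULL) {
  channel <- match.arg(channel)
  if (is.null(seed)) seed <- derive_seed(config$seed, paste0("tags_", channel))
  set.seed(seed)
  n <- if (channel == "chip") config$n_chip_tags else config$n_input_tags
  cl <- truth$chrom_lengths
  segs <- do.call(rbind, lapply(names(cl), function(chr) {
    s <- intensity_segments(truth, chr, channel)
    s$chrom <- chr
    s
  }))
  wts <- (segs$end - segs$start) * segs$w
  stop_if_not(sum(wts) > 0, "total intensity is zero")
  pick <- sample.int(nrow(segs), n, replace = TRUE, prob = wts)
  center <- segs$start[pick] +
    floor(runif(n) * (segs$end[pick] - segs$start[pick]))
  strand <- ifelse(runif(n) < 0.5, "+", "-")
  fl <- config$fragment_length_bp
  pos <- ifelse(strand == "+", center - fl %/% 2L, center + fl - 1L - fl %/% 2L)
  maxpos <- cl[segs$chrom[pick]] - 1L
  pos <- pmin(pmax(pos, 0L), maxpos)
  tag_library(segs$chrom[pick], as.integer(pos), strand)
}

#' Simulate replicate ChIP libraries from one truth
#'
#' Independent tag draws from the same planted intensity with distinct
#' derived sub-seeds, emulating ChIP assays performed on cells grown on
#' separate days.
#'
#' @param truth a `truth_set`.
#' @param config a [sim_config()].
#' @param n number of replicates (at least 2).
#' @param channel `"chip"` or `"input"`.
#' @return a list of `n` tag libraries.
#' @export
make_replicates <- function(truth, config, n = 2L, channel = "chip") {
  stop_if_not(n >= 2, "n must be >= 2")
  lapply(seq_len(n), function(k) {
    simulate_tags(truth, config, channel,
                  seed = derive_seed(config$seed, paste0("tags_", channel,
                                                         "_rep", k)))
  })
}
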