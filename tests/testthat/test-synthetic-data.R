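small_cfg <- function(...) {
  sim_config(seed = 42L, chrom_lengths = c(chrZ = 6e5, chrO = 3e5),
             n_genes = 40L, n_chip_tags = 20000L, n_input_tags = 20000L, ...)
}

test_that("genome generation is deterministic and respects composition", {
  cfg <- small_cfg()
  g1 <- make_genome(cfg)
  g2 <- make_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$genes, g2$genes)
  expect_identical(g1$truth$motif_insertions, g2$truth$motif_insertions)

  # counting oracle: n_genes * frac_c2h2 genes are C2H2
  cfg2 <- sim_config(seed = 5, chrom_lengths = c(a = 1.5e6, b = 1.5e6),
                     n_genes = 200L, frac_c2h2 = 0.5)
  g3 <- make_genome(cfg2)
  expect_equal(sum(g3$genes$is_c2h2), 100L)
  expect_true(all(g3$genes$finger_count[!g3$genes$is_c2h2] == 0))

  # no bound genes -> no planted motifs, no domains
  g4 <- make_genome(small_cfg(frac_bound = 0))
  expect_equal(nrow(g4$truth$motif_insertions), 0L)
  expect_equal(length(g4$truth$domains), 0L)
})

test_that("planted truth is internally consistent", {
  cfg <- small_cfg(motif_mutation_rate = 0.05)
  gen <- make_genome(cfg)
  truth <- gen$truth
  genes <- gen$genes

  # sharp-site centers lie inside a domain (co-localized construction)
  ctr <- (GenomicRanges::start(truth$sharp_sites) +
            GenomicRanges::end(truth$sharp_sites)) %/% 2
  ctr_gr <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(truth$sharp_sites), IRanges::IRanges(ctr, ctr))
  expect_true(all(IRanges::overlapsAny(ctr_gr, truth$domains)))

  # every motif insertion falls within its gene's final exon
  canon <- znfdomains:::CANONICAL_29MER
  mm_per_ins <- integer(0)
  for (r in seq_len(nrow(truth$motif_insertions))) {
    mi <- truth$motif_insertions[r, ]
    g <- genes[genes$gene_id == mi$gene_id, ]
    k <- if (g$strand == "+") length(g$exon_starts[[1]]) else 1L
    fe_s <- g$exon_starts[[1]][k]; fe_e <- g$exon_ends[[1]][k]
    expect_true(mi$offset >= fe_s && mi$offset + 29 <= fe_e)
    s <- substr(as.character(gen$genome[[g$chrom]]), mi$offset + 1,
                mi$offset + 29)
    if (mi$strand == "-") {
      s <- paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                 collapse = "")
    }
    mm_per_ins <- c(mm_per_ins,
                    sum(strsplit(s, "")[[1]] != strsplit(canon, "")[[1]]))
  }
  # at 5% per-position mutation the mean mismatch count stays small
  expect_lt(mean(mm_per_ins), 29 * 0.15)

  # unbound C2H2 genes carry the divergent linker (>= 8 mismatches)
  div <- znfdomains:::divergent_29mer()
  expect_gte(sum(strsplit(div, "")[[1]] != strsplit(canon, "")[[1]]), 8)
  unbound <- genes[genes$is_c2h2 &
                     !(genes$gene_id %in% truth$bound_gene_ids), ]
  g <- unbound[1, ]
  fe <- if (g$strand == "+") {
    c(g$exon_starts[[1]][length(g$exon_starts[[1]])],
      g$exon_ends[[1]][length(g$exon_ends[[1]])])
  } else c(g$exon_starts[[1]][1], g$exon_ends[[1]][1])
  exon_seq <- substr(as.character(gen$genome[[g$chrom]]), fe[1] + 1, fe[2])
  if (g$strand == "-") {
    exon_seq <- paste(rev(strsplit(chartr("ACGT", "TGCA", exon_seq),
                                   "")[[1]]), collapse = "")
  }
  expect_true(grepl(div, exon_seq, fixed = TRUE))
  expect_false(grepl(canon, exon_seq, fixed = TRUE))
})

test_that("array simulation is exact without noise and drops probes as configured", {
  # no noise, no domains -> all zero
  cfg0 <- small_cfg(frac_bound = 0, array_noise_sd = 0, probe_missing_prob = 0)
  gen0 <- make_genome(cfg0)
  arr0 <- simulate_array(gen0$truth, cfg0)
  expect_true(all(arr0$value == 0))

  # no noise, domains of fold 4 -> in-domain probes exactly 2
  cfg4 <- small_cfg(domain_fold = 4, array_noise_sd = 0,
                    probe_missing_prob = 0)
  gen4 <- make_genome(cfg4)
  arr4 <- simulate_array(gen4$truth, cfg4)
  mid_gr <- GenomicRanges::GRanges(arr4$chrom,
                                   IRanges::IRanges(arr4$probe_start + 26,
                                                    arr4$probe_start + 26))
  inside <- IRanges::overlapsAny(mid_gr, gen4$truth$domains)
  expect_true(all(arr4$value[inside] == 2))
  expect_true(all(arr4$value[!inside] == 0))

  # dropped probe count within the binomial 99% interval
  cfg_m <- small_cfg(probe_missing_prob = 0.1)
  gen_m <- make_genome(cfg_m)
  arr_m <- simulate_array(gen_m$truth, cfg_m)
  n_expected <- sum(vapply(cfg_m$chrom_lengths, function(l)
    length(seq.int(0L, l - 50L, by = 100L)), 0))
  dropped <- n_expected - nrow(arr_m)
  ci <- qbinom(c(0.005, 0.995), n_expected, 0.1)
  expect_gte(dropped, ci[1])
  expect_lte(dropped, ci[2])
})

test_that("tag simulation hits requested depth and null distributions", {
  cl <- c(u = 2e6)
  truth <- bare_truth(cl)
  cfg <- sim_config(seed = 9, chrom_lengths = cl, n_chip_tags = 50000L,
                    n_input_tags = 50000L)
  inp <- simulate_tags(truth, cfg, "input")
  expect_equal(tag_depth(inp), 50000L)
  # input positions are uniform (KS at alpha = 0.01)
  ks <- suppressWarnings(stats::ks.test(inp$start / cl[["u"]], "punif"))
  expect_gt(ks$p.value, 0.01)

  # domains of fold 1 leave chip indistinguishable from input
  d <- GenomicRanges::GRanges("u", IRanges::IRanges(500001, 510000))
  d$fold <- 1
  truth1 <- bare_truth(cl, domains = d)
  chip1 <- simulate_tags(truth1, cfg, "chip")
  ks2 <- suppressWarnings(stats::ks.test(chip1$start, inp$start))
  expect_gt(ks2$p.value, 0.01)

  # fold > 1 concentrates chip tags over the domain
  d5 <- d; d5$fold <- 20
  chip5 <- simulate_tags(bare_truth(cl, domains = d5), cfg, "chip")
  in_dom <- function(t) mean(t$start >= 5e5 & t$start < 5.1e5)
  expect_gt(in_dom(chip5), 5 * in_dom(inp))
})

test_that("replicates are independent draws from one truth", {
  cl <- c(u = 1e6)
  d <- GenomicRanges::GRanges("u", IRanges::IRanges(1e5, 1.02e5))
  d$fold <- 5
  truth <- bare_truth(cl, domains = d)
  cfg <- sim_config(seed = 3, chrom_lengths = cl, n_chip_tags = 5000L)
  reps <- make_replicates(truth, cfg, n = 3)
  expect_length(reps, 3L)
  expect_false(identical(reps[[1]]$start, reps[[2]]$start))
  expect_false(identical(reps[[2]]$start, reps[[3]]$start))
  expect_error(make_replicates(truth, cfg, n = 1), ">= 2")
})
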