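# Small hand-built annotation: gene A (+) with a final exon at its 3' end,
# gene B (+) just downstream so that B's TSS is closer to A's final exon
# than A's own TSS - the adversarial case for nearest-TSS assignment.
adversarial_genes <- function() {
  df <- data.frame(gene_id = c("A", "B"), chrom = "chr1",
                   start = c(0L, 6000L), end = c(5500L, 9000L),
                   strand = "+", is_c2h2 = c(TRUE, FALSE),
                   finger_count = c(6L, 0L), has_krab = c(TRUE, FALSE))
  df$exon_starts <- list(c(0L, 2000L, 4500L), c(6000L, 8000L))
  df$exon_ends <- list(c(200L, 2200L, 5500L), c(6300L, 9000L))
  gene_table(df)
}

test_that("peaks inside a gene are assigned to it, never the closer neighbouring TSS", {
  genes <- adversarial_genes()
  # peak in A's final exon, 200 bp short of B's TSS (6000), 5.2 kb from A's
  pk <- peak_set(GenomicRanges::GRanges("chr1", IRanges::IRanges(5201, 5400)),
                 3)
  asg <- assign_targets(pk, genes)
  expect_equal(asg$gene_id, "A")
  expect_equal(asg$mode, "within_gene")
  expect_equal(asg$context, "final_exon")
  expect_equal(asg$distance_bp, 0)

  # adding distant genes cannot change a within-gene assignment
  far <- genes
  far[3, ] <- far[1, ]
  far$gene_id[3] <- "Z"; far$start[3] <- 50000L; far$end[3] <- 55500L
  far$exon_starts[[3]] <- far$exon_starts[[1]] + 50000L
  far$exon_ends[[3]] <- far$exon_ends[[1]] + 50000L
  asg2 <- assign_targets(pk, gene_table(as.data.frame(far)))
  expect_equal(asg2$gene_id, "A")
  expect_equal(asg2$mode, "within_gene")
})

test_that("intergenic peaks go to the nearest strand-aware TSS", {
  genes <- adversarial_genes()
  # peak at 5600-5800 (between A end 5500 and B start 6000): nearest TSS is
  # B's start (6000) at 300 bp from the center 5700; A's TSS is 5700 away
  pk <- peak_set(GenomicRanges::GRanges("chr1", IRanges::IRanges(5601, 5800)),
                 1)
  asg <- assign_targets(pk, genes)
  expect_equal(asg$gene_id, "B")
  expect_equal(asg$mode, "nearest_tss")
  expect_equal(asg$context, "upstream")
  expect_equal(asg$distance_bp, 300)

  # minus-strand gene: TSS at tx end
  dfm <- data.frame(gene_id = "M", chrom = "chr1", start = 20000L,
                    end = 25000L, strand = "-", is_c2h2 = FALSE,
                    finger_count = 0L, has_krab = FALSE)
  dfm$exon_starts <- list(c(20000L, 24000L))
  dfm$exon_ends <- list(c(21000L, 25000L))
  gm <- gene_table(rbind(as.data.frame(adversarial_genes()), dfm))
  pk2 <- peak_set(GenomicRanges::GRanges("chr1",
                                         IRanges::IRanges(25501, 25700)), 1)
  asg2 <- assign_targets(pk2, gm)
  expect_equal(asg2$gene_id, "M")
  expect_equal(asg2$distance_bp, abs(25600 - 24999))
  expect_equal(asg2$context, "upstream")  # 3' of a minus gene = upstream

  # nearest-TSS equals the all-genes scan oracle on random fixtures
  set.seed(23)
  gen <- make_genome(sim_config(seed = 6, chrom_lengths = c(chr1 = 8e5),
                                n_genes = 25))
  genes_r <- gen$genes
  tss <- ifelse(genes_r$strand == "+", genes_r$start, genes_r$end - 1L)
  for (rep in 1:20) {
    pos <- sample(0:799000, 1)
    pkr <- peak_set(GenomicRanges::GRanges("chr1",
                                           IRanges::IRanges(pos + 1,
                                                            pos + 100)), 1)
    asgr <- assign_targets(pkr, genes_r)
    if (asgr$mode == "nearest_tss") {
      center <- pos + 50
      expect_equal(asgr$distance_bp, min(abs(center - tss)))
    }
  }
})

test_that("greatest overlap wins when a peak spans two genes", {
  df <- data.frame(gene_id = c("A", "B"), chrom = "chr1",
                   start = c(0L, 1300L), end = c(1300L, 3000L),
                   strand = "+", is_c2h2 = FALSE, finger_count = 0L,
                   has_krab = FALSE)
  df$exon_starts <- list(0L, 1300L)
  df$exon_ends <- list(1300L, 3000L)
  genes <- gene_table(df)
  # peak 1000-1350: 300 bp in A, 50 bp in B -> A
  pk <- peak_set(GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1350)),
                 1)
  expect_equal(assign_targets(pk, genes)$gene_id, "A")
  expect_error(assign_targets(pk, genes[0, ]), "empty")
})

test_that("exon context is classified in transcription order", {
  genes <- adversarial_genes()
  # center in A's first exon (internal in transcription order on +)
  pk1 <- peak_set(GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150)), 1)
  expect_equal(assign_targets(pk1, genes)$context, "internal_exon")
  # center in an intron
  pk2 <- peak_set(GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1100)),
                  1)
  expect_equal(assign_targets(pk2, genes)$context, "intron")

  # minus-strand gene: the genomically FIRST exon is the final exon
  dfm <- data.frame(gene_id = "M", chrom = "chr1", start = 0L, end = 5000L,
                    strand = "-", is_c2h2 = TRUE, finger_count = 3L,
                    has_krab = TRUE)
  dfm$exon_starts <- list(c(0L, 4000L))
  dfm$exon_ends <- list(c(1000L, 5000L))
  gm <- gene_table(dfm)
  pk3 <- peak_set(GenomicRanges::GRanges("chr1", IRanges::IRanges(501, 600)), 1)
  expect_equal(assign_targets(pk3, gm)$context, "final_exon")
  pk4 <- peak_set(GenomicRanges::GRanges("chr1", IRanges::IRanges(4501, 4600)),
                  1)
  expect_equal(assign_targets(pk4, gm)$context, "internal_exon")
})

test_that("finger-count histogram conserves gene totals", {
  gen <- make_genome(sim_config(seed = 12, chrom_lengths = c(z = 1e6, o = 5e5),
                                n_genes = 60))
  genes <- gen$genes

  # no assignments -> zero bound everywhere, n_all = per-bin census
  empty_asg <- data.frame(gene_id = character(0))
  h0 <- finger_count_histogram(empty_asg, genes)
  expect_true(all(h0$n_bound_c2h2 == 0))
  expect_equal(sum(h0$n_all_c2h2), sum(genes$is_c2h2))

  # every C2H2 gene bound -> the two columns are equal
  all_asg <- data.frame(gene_id = genes$gene_id[genes$is_c2h2])
  h1 <- finger_count_histogram(all_asg, genes)
  expect_equal(h1$n_bound_c2h2, h1$n_all_c2h2)

  # random subset equals a group-by oracle
  set.seed(9)
  sub <- sample(genes$gene_id[genes$is_c2h2], 10)
  h2 <- finger_count_histogram(data.frame(gene_id = sub), genes)
  c2 <- genes[genes$is_c2h2, ]
  for (b in h2$finger_count_bin) {
    expect_equal(h2$n_bound_c2h2[h2$finger_count_bin == b],
                 sum(c2$finger_count == b & c2$gene_id %in% sub))
  }
  expect_equal(sum(h2$n_bound_c2h2), 10L)
})

test_that("expression quintile profile matches a percentile oracle", {
  set.seed(33)
  expr <- data.frame(gene_id = sprintf("g%03d", 1:200),
                     level = stats::runif(200))
  bound <- sample(expr$gene_id, 40)
  got <- expression_quintile_profile(data.frame(gene_id = bound), expr)
  q <- stats::quantile(expr$level, c(0.2, 0.4, 0.6, 0.8))
  want <- vapply(1:5, function(k) {
    lv <- expr$level[expr$gene_id %in% bound]
    lo <- if (k == 1) -Inf else q[k - 1]
    hi <- if (k == 5) Inf else q[k]
    sum(lv > lo & lv <= hi)
  }, 0L)
  expect_equal(got, want)
  expect_equal(sum(got), 40L)

  # all bound genes at the minimum -> quintile 1
  expr2 <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                      level = c(1, 1, 2, 3, 4))
  got2 <- expression_quintile_profile(data.frame(gene_id = c("a", "b")), expr2)
  expect_equal(got2[1], 2L)
  expect_equal(sum(got2), 2L)

  # empty bound set -> all zeros; empty expression table -> error
  expect_equal(sum(expression_quintile_profile(
    data.frame(gene_id = character(0)), expr)), 0L)
  expect_error(expression_quintile_profile(data.frame(gene_id = "a"),
                                           expr[0, ]), "empty")
})
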