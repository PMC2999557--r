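test_that("PWM construction normalises columns and finds the core", {
  counts <- matrix(c(10, 0, 0, 0,
                     0, 10, 0, 0,
                     2, 3, 3, 2,
                     0, 0, 0, 10,
                     0, 0, 10, 0,
                     3, 2, 2, 3,
                     10, 0, 0, 0), nrow = 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  p <- pwm_from_counts(counts)
  expect_equal(colSums(p$probs), rep(1, 7), tolerance = 1e-12)
  expect_true(all(p$probs > 0 & p$probs < 1))
  expect_equal(p$consensus, "ACCTGAA")  # flat columns tie to the first max
  # the 5 consecutive most informative columns avoid one flat column
  expect_true(p$core_start %in% c(1L, 3L))
  expect_equal(p$core_width, 5L)
})

test_that("min-max scores hit 1 on the consensus and 0 on the worst word", {
  p <- toy_pwm("ACGTAGGCAT")
  bh <- best_hit("ACGTAGGCAT", p)
  expect_equal(bh$pwm_score, 1.0)
  expect_equal(bh$core_score, 1.0)
  expect_equal(bh$offset, 0L)

  # per-position worst letter scores exactly 0
  worst <- paste(apply(p$probs, 2, function(col)
    rownames(p$probs)[which.min(col)]), collapse = "")
  sc <- znfdomains:::score_both_strands(worst, p)
  expect_equal(min(sc$pwm_score, na.rm = TRUE), 0.0)

  # windows containing non-ACGT symbols are skipped
  bh2 <- best_hit("NNNNNNNNNNACGTAGGCAT", p)
  expect_equal(bh2$offset, 10L)
})

test_that("best_hit equals the exhaustive both-strand oracle", {
  set.seed(41)
  p <- toy_pwm("TGAGAAGCCCTA", weight = 6)
  for (rep in 1:3) {
    seq <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
                 collapse = "")
    got <- best_hit(seq, p)
    want <- oracle_best_hit(seq, p)
    expect_equal(got$pwm_score, want$score, tolerance = 1e-12)
    expect_equal(got$offset, want$offset)
    expect_equal(got$strand, want$strand)
  }
})

test_that("scanning a sequence and its reverse complement mirrors hits", {
  set.seed(43)
  p <- toy_pwm("ACGTAGGC", weight = 5)
  seq <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
               collapse = "")
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]),
              collapse = "")
  h1 <- scan_sequences(c(s = seq), p, core_cut = 0, pwm_cut = 0.8)
  h2 <- scan_sequences(c(s = rc), p, core_cut = 0, pwm_cut = 0.8)
  expect_equal(nrow(h1), nrow(h2))
  # a + hit at offset o maps to a - hit at n - L - o on the reverse strand
  remap <- sort(nchar(seq) - 8 - h2$offset)
  expect_equal(sort(h1$offset), remap)
  expect_equal(sort(h1$pwm_score), sort(h2$pwm_score), tolerance = 1e-12)
})

test_that("hits are monotone in the stringency pair and planted copies are found", {
  set.seed(44)
  p <- toy_pwm("TGAGAAGCCCTACGAAT", weight = 8)
  base <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                collapse = "")
  for (off in c(100, 900, 1500)) {
    substr(base, off + 1, off + 17) <- "TGAGAAGCCCTACGAAT"
  }
  strict <- scan_sequences(c(x = base), p, 1.00, 0.99)
  loose <- scan_sequences(c(x = base), p, 1.00, 0.95)
  key <- function(h) paste(h$offset, h$strand)
  expect_true(all(key(strict) %in% key(loose)))
  expect_gte(nrow(strict), 3L)
  expect_true(all(c(100, 900, 1500) %in% strict$offset))
  expect_equal(nrow(scan_sequences(character(0), p)), 0L)
})

test_that("peak sequence extraction slices the genome around midpoints", {
  genome <- c(gA = paste(rep("ACGT", 500), collapse = ""))  # 2 kb
  pk <- peak_set(GenomicRanges::GRanges(c("gA", "gA"),
                                        IRanges::IRanges(c(901, 31),
                                                         c(1100, 50))),
                 c(2, 1))
  expect_warning(seqs <- extract_peak_sequences(pk, genome, 50),
                 "skipped")
  expect_length(seqs, 1L)
  expect_equal(nchar(seqs[[1]]), 100L)
  # direct substring oracle: center0 = 1000, window [950, 1050)
  expect_equal(unname(seqs[1]), substr(genome[["gA"]], 951, 1050))
  bad <- peak_set(GenomicRanges::GRanges("zz", IRanges::IRanges(1, 10)), 1)
  expect_error(extract_peak_sequences(bad, genome), "absent")
})

test_that("background set is the final exons of unbound C2H2 genes", {
  gen <- make_genome(sim_config(seed = 31, chrom_lengths = c(z = 8e5, o = 4e5),
                                n_genes = 40))
  genes <- gen$genes
  # peaks over the final exons of the truly bound genes
  pk <- peak_set(gen$truth$domains, rep(1, length(gen$truth$domains)))
  bgset <- build_background_set(genes, pk, gen$genome)
  expect_true(all(names(bgset) %in% genes$gene_id[genes$is_c2h2]))
  expect_false(any(names(bgset) %in% gen$truth$bound_gene_ids))
  # every unbound C2H2 gene whose body misses the peaks is present
  gb <- znfdomains:::genes_as_granges(genes)
  unpeaked <- genes$gene_id[genes$is_c2h2 & !IRanges::overlapsAny(gb, pk)]
  expect_setequal(names(bgset), unpeaked)
  # all-bound corner: no eligible gene -> error
  allpk <- peak_set(gb[genes$is_c2h2], rep(1, sum(genes$is_c2h2)))
  expect_error(build_background_set(genes, allpk, gen$genome), "unbound")
})

test_that("discovery recovers a planted motif and returns nothing under the null", {
  fx <- planted_motif_fixture(seed = 71)
  mot <- discover_motifs(fx$fg, fx$bg, seed = 71)
  expect_gte(length(mot), 1L)
  top <- mot[[1]]
  expect_gte(consensus_identity(top$consensus, fx$canon), 24)
  expect_lte(abs(top$n_occurrences - fx$n_planted), 0.1 * fx$n_planted)
  expect_true(top$stringency$pwm_cut > 0 && top$stringency$pwm_cut <= 1)

  # determinism: same seed, same result
  mot2 <- discover_motifs(fx$fg, fx$bg, seed = 71)
  expect_identical(lapply(mot, `[[`, "consensus"),
                   lapply(mot2, `[[`, "consensus"))
  expect_identical(lapply(mot, `[[`, "stringency"),
                   lapply(mot2, `[[`, "stringency"))

  # null foreground drawn from the background model -> empty list
  set.seed(72)
  null_fg <- vapply(1:200, function(i)
    paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = ""),
    "")
  expect_length(discover_motifs(null_fg, fx$bg, seed = 72), 0L)
})

test_that("hit classification by ZNF-gene proximity matches direct membership", {
  df <- data.frame(gene_id = c("z1", "n1"), chrom = "c",
                   start = c(10000L, 50000L), end = c(12000L, 52000L),
                   strand = "+", is_c2h2 = c(TRUE, FALSE),
                   finger_count = c(5L, 0L), has_krab = c(TRUE, FALSE))
  df$exon_starts <- list(10000L, 50000L)
  df$exon_ends <- list(12000L, 52000L)
  genes <- gene_table(df)
  hits <- data.frame(seq_id = "c",
                     offset = c(10500L, 12500L, 13500L, 50500L),
                     strand = "+", core_score = 1, pwm_score = 1,
                     width = 29L)
  # inside znf; within 1 kb window; outside window; inside non-znf gene
  r <- classify_hits(hits, genes, window = 1000L)
  expect_equal(r$n_total, 4L)
  expect_equal(r$n_at_znf, 2L)
  expect_equal(r$fraction, 0.5)
  expect_true(is.na(classify_hits(hits[0, ], genes)$fraction))
  expect_equal(classify_hits(hits, genes[!genes$is_c2h2, ])$fraction, 0)
})

test_that("reverse-orientation merge reconstructs the long composite motif", {
  # 29mer split into a 17mer (reverse orientation) and an 18mer sharing a
  # 6-column overlap, mirroring the two-fragment structure of a long motif
  long <- "TGAGAAGCCCTACGAATGTAAGGAATGTG"
  revcomp1 <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s),
                                             "")[[1]]), collapse = "")
  partB <- substr(long, 1, 18)               # 5' fragment, forward
  partA <- revcomp1(substr(long, 13, 29))    # 3' fragment, reversed (17 nt)
  m <- merge_reverse_oriented(toy_pwm(partA), toy_pwm(partB))
  expect_false(is.null(m))
  expect_equal(m$overlap, 6L)
  expect_equal(nchar(m$consensus), 29L)
  expect_equal(m$consensus, long)

  # self-identity: B against the reverse complement of B merges to length LB
  pB <- toy_pwm(partB)
  pA_rc <- toy_pwm(revcomp1(partB))
  m2 <- merge_reverse_oriented(pA_rc, pB)
  expect_equal(nchar(m2$consensus), nchar(partB))
  expect_equal(m2$identity, 1.0)

  # unrelated random consensi do not merge
  set.seed(91)
  hits <- 0
  for (rep in 1:20) {
    a <- paste(sample(c("A", "C", "G", "T"), 17, replace = TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 18, replace = TRUE),
               collapse = "")
    res <- merge_reverse_oriented(toy_pwm(a), toy_pwm(b), min_overlap = 8)
    if (!is.null(res)) hits <- hits + 1
  }
  expect_lte(hits, 1)
})

test_that("PWM text files round-trip through the TRANSFAC-like format", {
  p <- toy_pwm("ACGTAGGCAT")
  f <- withr::local_tempfile()
  write_pwm(p, f)
  back <- read_pwm(f)
  expect_equal(back$counts, p$counts, tolerance = 1e-6)
  expect_equal(back$consensus, p$consensus)
  expect_equal(back$core_start, p$core_start)
})
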