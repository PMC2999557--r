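# Independent brute-force oracles and fixture builders. Each oracle is a
# direct, unoptimised restatement of the definition it checks, sharing no
# code with the implementation.

# --- fixtures ---------------------------------------------------------------

random_peak_gr <- function(n, chroms = c("chrA", "chrB"), max_pos = 1e6,
                           width_range = c(50, 2000)) {
  # non-overlapping random intervals per chromosome
  per <- split(seq_len(n), sample(chroms, n, replace = TRUE))
  parts <- lapply(names(per), function(chr) {
    k <- length(per[[chr]])
    if (k == 0) return(NULL)
    w <- sample(width_range[1]:width_range[2], k, replace = TRUE)
    gaps <- sample(1:500, k, replace = TRUE)
    s <- cumsum(gaps + w) - w + sample(0:1000, 1)
    GenomicRanges::GRanges(chr, IRanges::IRanges(start = s, width = w))
  })
  gr <- suppressWarnings(do.call(c, parts[!vapply(parts, is.null, TRUE)]))
  peak_set(gr, height = stats::rnorm(length(gr)))
}

dense_track <- function(n_probes, chrom = "chrT", tile = 100L,
                        probe_len = 50L, values = NULL) {
  if (is.null(values)) values <- stats::rnorm(n_probes)
  starts <- seq(0L, by = tile, length.out = n_probes)
  array_track(rep(chrom, n_probes), starts, starts + probe_len, values, tile)
}

# a bare truth object for the tag simulator (no genome/genes needed)
bare_truth <- function(chrom_lengths, domains = NULL, sharp = NULL) {
  mk <- function(x) {
    if (is.null(x)) {
      g <- GenomicRanges::GRanges()
      g$fold <- numeric(0)
      g
    } else x
  }
  structure(list(domains = mk(domains), sharp_sites = mk(sharp),
                 motif_insertions = data.frame(), bound_gene_ids = character(0),
                 chrom_lengths = chrom_lengths),
            class = "truth_set")
}

planted_motif_fixture <- function(n_fg = 337, n_planted = 200, n_bg = 90,
                                  mutation = 0.1, seed = 1) {
  set.seed(seed)
  canon <- znfdomains:::CANONICAL_29MER
  rand1 <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")
  fg <- vapply(seq_len(n_fg), function(i) rand1(100), "")
  for (i in seq_len(n_planted)) {
    m <- znfdomains:::mutate_seq(canon, mutation)
    off <- sample(0:(100 - 29), 1)
    substr(fg[i], off + 1, off + 29) <- m
  }
  bg <- vapply(seq_len(n_bg), function(i) rand1(500), "")
  list(fg = fg, bg = bg, canon = canon, n_planted = n_planted)
}

# --- oracles ----------------------------------------------------------------

# maximal above-threshold runs on a dense (gap-free) track, with the span /
# occupancy filters applied afterwards
oracle_chipchip_dense <- function(track, cutoff, min_span = 800,
                                  tile = 100, min_frac = 0.5) {
  out <- NULL
  for (chr in unique(track$chrom)) {
    sub <- track[track$chrom == chr, ]
    above <- sub$value >= cutoff
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      i <- starts[k]; j <- ends[k]
      span <- sub$probe_end[j] - sub$probe_start[i]
      expected <- span %/% tile + 1
      if (span >= min_span && (j - i + 1) >= min_frac * expected) {
        out <- rbind(out, data.frame(chrom = chr, start = sub$probe_start[i],
                                     end = sub$probe_end[j],
                                     height = max(sub$value[i:j])))
      }
    }
  }
  out
}

# per-bp fragment coverage -> bin means -> window means, all by direct loops
oracle_bin_smooth <- function(tags, chrom_len, step = 30, flank = 600,
                              frag = 150) {
  cov <- numeric(chrom_len)
  for (r in seq_len(nrow(tags))) {
    if (tags$strand[r] == "+") {
      a <- tags$start[r]; b <- tags$start[r] + frag - 1
    } else {
      a <- tags$start[r] - frag + 1; b <- tags$start[r]
    }
    a <- max(a, 0); b <- min(b, chrom_len - 1)
    if (a <= b) cov[(a + 1):(b + 1)] <- cov[(a + 1):(b + 1)] + 1
  }
  bin_starts <- seq(0, chrom_len - 1, by = step)
  raw <- vapply(bin_starts, function(b)
    mean(cov[(b + 1):min(b + step, chrom_len)]), 0)
  smoothed <- vapply(seq_along(bin_starts), function(i) {
    sel <- abs(bin_starts - bin_starts[i]) <= flank
    mean(raw[sel])
  }, 0)
  data.frame(bin_start = bin_starts, raw = raw, smoothed = smoothed)
}

# exhaustive scan for the lowest chip height with empirical FDR <= fdr
oracle_fdr_cutoff <- function(chip_vals, input_vals, scale = 1, fdr = 0.01) {
  for (h in sort(unique(chip_vals))) {
    f <- scale * sum(input_vals >= h) / sum(chip_vals >= h)
    if (f <= fdr) return(h)
  }
  NA_real_
}

gr_df <- function(ps) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(ps)),
             start = GenomicRanges::start(ps), end = GenomicRanges::end(ps),
             height = ps$height)
}

# all-pairs >=1 bp overlap counts (1-based closed intervals)
oracle_overlap_counts <- function(a, b) {
  da <- gr_df(a); db <- gr_df(b)
  hit_a <- vapply(seq_len(nrow(da)), function(i)
    any(db$chrom == da$chrom[i] & db$start <= da$end[i] &
          db$end >= da$start[i]), TRUE)
  hit_b <- vapply(seq_len(nrow(db)), function(i)
    any(da$chrom == db$chrom[i] & da$start <= db$end[i] &
          da$end >= db$start[i]), TRUE)
  c(sum(hit_a), sum(hit_b))
}

# signed distance to nearest subject center, all-pairs
oracle_distance <- function(query, subject) {
  dq <- gr_df(query); ds <- gr_df(subject)
  # 0-based half-open centers
  qc <- (dq$start - 1 + dq$end) %/% 2
  sc <- (ds$start - 1 + ds$end) %/% 2
  vapply(seq_len(nrow(dq)), function(i) {
    j <- which(ds$chrom == dq$chrom[i])
    if (length(j) == 0) return(NA_real_)
    d <- qc[i] - sc[j]
    cand <- j[abs(d) == min(abs(d))]
    d[match(cand[which.min(sc[cand])], j)]
  }, 0)
}

# best-scoring window by exhaustive enumeration over both strands
oracle_best_hit <- function(seq, pwm) {
  revcomp1 <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s),
                                             "")[[1]]), collapse = "")
  L <- ncol(pwm$probs)
  lp <- log(pwm$probs)
  smin <- sum(apply(lp, 2, min)); smax <- sum(apply(lp, 2, max))
  best <- list(score = -Inf)
  n <- nchar(seq)
  for (off in 0:(n - L)) {
    w <- substr(seq, off + 1, off + L)
    if (grepl("[^ACGT]", w)) next
    for (strand in c("+", "-")) {
      ww <- if (strand == "+") w else revcomp1(w)
      s <- sum(vapply(seq_len(L), function(j)
        lp[ww_base <- substr(ww, j, j), j], 0))
      score <- (s - smin) / (smax - smin)
      if (score > best$score + 1e-12) {
        best <- list(score = score, offset = off, strand = strand)
      }
    }
  }
  best
}

# best ungapped identity between a consensus and a reference string,
# either orientation, any offset
consensus_identity <- function(consensus, ref) {
  revcomp1 <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s),
                                             "")[[1]]), collapse = "")
  best <- 0
  for (str in c(consensus, revcomp1(consensus))) {
    a <- strsplit(str, "")[[1]]; b <- strsplit(ref, "")[[1]]
    for (off in (-length(a) + 1):(length(b) - 1)) {
      bi <- max(1, off + 1):min(length(b), off + length(a))
      ai <- bi - off
      best <- max(best, sum(a[ai] == b[bi]))
    }
  }
  best
}

# uniform-ish PWM with a dominant consensus letter per column
toy_pwm <- function(consensus, weight = 10) {
  b <- strsplit(consensus, "")[[1]]
  counts <- matrix(0.5, 4, length(b),
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(b)) counts[b[j], j] <- weight
  pwm_from_counts(counts)
}
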