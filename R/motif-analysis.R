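#' Position weight matrix with background and core columns
#'
#' Builds a PWM from a 4 x L count matrix (rows A, C, G, T) with a
#' pseudocount added to every cell. The per-position probabilities, the
#' consensus (highest-probability base per column) and the core — the 5
#' consecutive columns maximising summed information content, the
#' matrix-library convention for match scoring — are stored together with
#' the background nucleotide frequencies.
#'
#' @param counts 4 x L numeric matrix with rownames A, C, G, T.
#' @param bg background frequencies (length 4, summing to 1); uniform by
#'   default.
#' @param pseudocount added to every cell before normalising (0.25).
#' @return a `pwm` object: list with `probs`, `counts`, `bg`, `consensus`,
#'   `core_start`, `core_width`.
#' @export
pwm_from_counts <- function(counts, bg = rep(0.25, 4), pseudocount = 0.25) {
  stop_if_not(is.matrix(counts) && nrow(counts) == 4, "counts must be 4 x L")
  if (is.null(rownames(counts))) rownames(counts) <- DNA_BASES4
  counts <- counts[DNA_BASES4, , drop = FALSE]
  bg <- bg / sum(bg)
  probs <- sweep(counts + pseudocount, 2, colSums(counts) + 4 * pseudocount, "/")
  L <- ncol(probs)
  ic_terms <- probs * log2(probs / bg)
  ic_terms[probs == 0] <- 0
  ic <- colSums(ic_terms)
  core_width <- min(5L, L)
  core_start <- if (L <= core_width) 1L else {
    ic_run <- vapply(seq_len(L - core_width + 1L), function(s)
      sum(ic[s:(s + core_width - 1L)]), 0)
    which.max(ic_run)
  }
  consensus <- paste(DNA_BASES4[apply(probs, 2, which.max)], collapse = "")
  structure(list(probs = probs, counts = counts, bg = bg,
                 consensus = consensus, core_start = as.integer(core_start),
                 core_width = as.integer(core_width)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM length %d, consensus %s, core columns %d-%d\n",
              ncol(x$probs), x$consensus, x$core_start,
              x$core_start + x$core_width - 1L))
  invisible(x)
}

pwm_length <- function(pwm) ncol(pwm$probs)

# Reverse complement of a PWM: reverse columns, complement rows.
pwm_revcomp <- function(pwm) {
  rc <- pwm$counts[c("T", "G", "C", "A"), rev(seq_len(ncol(pwm$counts))),
                   drop = FALSE]
  rownames(rc) <- DNA_BASES4
  pwm_from_counts(rc, bg = pwm$bg[4:1], pseudocount = 0)
}

#' Write / read a PWM as a TRANSFAC-like count matrix
#'
#' Plain-text format: a `DE` line with the consensus, numbered rows of
#' A/C/G/T counts, and `XX`/`//` terminators.
#'
#' @param pwm a `pwm` object.
#' @param path file path.
#' @export
write_pwm <- function(pwm, path) {
  lines <- c(paste0("DE\t", pwm$consensus),
             paste0("P0\tA\tC\tG\tT"),
             vapply(seq_len(ncol(pwm$counts)), function(j)
               paste(c(sprintf("%02d", j),
                       formatC(pwm$counts[, j], format = "g", digits = 8)),
                     collapse = "\t"), ""),
             "XX", "//")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pwm
#' @param bg background frequencies to attach on read.
#' @export
read_pwm <- function(path, bg = rep(0.25, 4)) {
  lines <- readLines(path)
  rows <- grep("^[0-9][0-9]\t", lines, value = TRUE)
  counts <- t(vapply(strsplit(rows, "\t"), function(f)
    as.numeric(f[2:5]), numeric(4)))
  counts <- t(counts)
  rownames(counts) <- DNA_BASES4
  pwm_from_counts(counts, bg = bg)
}

seq_to_codes <- function(seq) {
  codes <- match(strsplit(toupper(seq), "")[[1]], DNA_BASES4)
  codes
}

# Min-max normalised PWM and core scores for every window of one strand.
# Windows containing a non-ACGT symbol score NA.
score_strand <- function(codes, pwm) {
  lp <- log(pwm$probs)
  L <- ncol(lp)
  n <- length(codes)
  if (n < L) return(list(pwm = numeric(0), core = numeric(0)))
  nw <- n - L + 1L
  S <- numeric(nw); C <- numeric(nw)
  core_cols <- pwm$core_start:(pwm$core_start + pwm$core_width - 1L)
  for (j in seq_len(L)) {
    v <- lp[, j][codes[j:(j + nw - 1L)]]
    S <- S + v
    if (j %in% core_cols) C <- C + v
  }
  smin <- sum(apply(lp, 2, min)); smax <- sum(apply(lp, 2, max))
  cmin <- sum(apply(lp[, core_cols, drop = FALSE], 2, min))
  cmax <- sum(apply(lp[, core_cols, drop = FALSE], 2, max))
  list(pwm = (S - smin) / (smax - smin), core = (C - cmin) / (cmax - cmin))
}

# All-window scores on both strands. Offsets are 0-based on the forward
# sequence; a minus-strand window at offset o covers the same forward
# positions [o, o+L).
score_both_strands <- function(seq, pwm) {
  codes <- seq_to_codes(seq)
  L <- pwm_length(pwm)
  fwd <- score_strand(codes, pwm)
  rcodes <- rev(5L - codes)  # reverse complement in code space (A<->T, C<->G)
  rcodes[is.na(rcodes)] <- NA_integer_
  rev_ <- score_strand(rcodes, pwm)
  nw <- length(fwd$pwm)
  # minus-strand window at revcomp offset o' maps to forward offset nw-1-o'
  list(offset = c(seq_len(nw) - 1L, rev(seq_len(nw) - 1L)),
       strand = rep(c("+", "-"), each = nw),
       pwm_score = c(fwd$pwm, rev_$pwm),
       core_score = c(fwd$core, rev_$core))
}

#' Best PWM match in a sequence
#'
#' Maximises the min-max normalised PWM score over both strands and all
#' offsets; ties go to the smallest offset, plus strand first. Windows with
#' non-ACGT symbols are skipped.
#'
#' @param seq a character string (length >= PWM length).
#' @param pwm a `pwm` object.
#' @return a one-row data.frame (offset, strand, core_score, pwm_score), or
#'   zero rows when no window is scorable.
#' @export
best_hit <- function(seq, pwm) {
  sc <- score_both_strands(seq, pwm)
  ok <- which(!is.na(sc$pwm_score))
  if (length(ok) == 0) {
    return(data.frame(offset = integer(0), strand = character(0),
                      core_score = numeric(0), pwm_score = numeric(0)))
  }
  o <- ok[order(-sc$pwm_score[ok], sc$offset[ok],
                match(sc$strand[ok], c("+", "-")))]
  b <- o[1]
  data.frame(offset = sc$offset[b], strand = sc$strand[b],
             core_score = sc$core_score[b], pwm_score = sc$pwm_score[b],
             stringsAsFactors = FALSE)
}

#' Scan sequences for PWM matches above a core/PWM stringency
#'
#' Reports every window (both strands, overlaps allowed) whose core score
#' and PWM score meet the stringency pair — e.g. (1.00/0.99) for the highest
#' stringency, (1.00/0.95) for a lower one.
#'
#' @param seqs named character vector or `DNAStringSet`.
#' @param pwm a `pwm` object.
#' @param core_cut,pwm_cut stringency thresholds in `[0, 1]`.
#' @return data.frame (seq_id, offset, strand, core_score, pwm_score, width).
#' @export
scan_sequences <- function(seqs, pwm, core_cut = 1.0, pwm_cut = 0.95) {
  stop_if_not(core_cut >= 0 && core_cut <= 1 && pwm_cut >= 0 && pwm_cut <= 1,
              "stringency cutoffs must be in [0, 1]")
  ids <- names(seqs)
  if (!is.character(seqs)) seqs <- as.character(seqs)
  if (is.null(ids)) ids <- names(seqs)
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  out <- lapply(seq_along(seqs), function(i) {
    sc <- score_both_strands(seqs[[i]], pwm)
    # tolerance guards against float round-off at cut = 1.0
    keep <- which(!is.na(sc$pwm_score) &
                    sc$core_score >= core_cut - 1e-9 &
                    sc$pwm_score >= pwm_cut - 1e-9)
    if (length(keep) == 0) return(NULL)
    data.frame(seq_id = ids[i], offset = sc$offset[keep],
               strand = sc$strand[keep], core_score = sc$core_score[keep],
               pwm_score = sc$pwm_score[keep], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(seq_id = character(0), offset = integer(0),
                      strand = character(0), core_score = numeric(0),
                      pwm_score = numeric(0), stringsAsFactors = FALSE)
  }
  res$width <- rep(pwm_length(pwm), nrow(res))
  res
}

#' Extract fixed-width sequences around peak midpoints
#'
#' Retrieves `2 * halfwidth` nt of forward-strand genome sequence centred on
#' each peak's midpoint (100 nt by default, the window in which consensus
#' motifs for a factor are typically recoverable). Peaks too close to a
#' contig edge are skipped with a warning.
#'
#' @param peaks a peak set.
#' @param genome named `DNAStringSet` (or named character vector).
#' @param halfwidth half-window in bp (50).
#' @return named character vector of sequences (`chrom:mid` names).
#' @export
extract_peak_sequences <- function(peaks, genome, halfwidth = 50L) {
  if (!is.character(genome)) genome <- as.character(genome)
  chr <- as.character(GenomicRanges::seqnames(peaks))
  stop_if_not(all(chr %in% names(genome)),
              "peak chromosome absent from genome")
  mid <- interval_center0(peaks)
  lo0 <- mid - halfwidth
  hi0 <- mid + halfwidth  # half-open end
  lens <- nchar(genome)[match(chr, names(genome))]
  ok <- lo0 >= 0 & hi0 <= lens
  if (any(!ok)) {
    warning(sprintf("%d peaks too close to a contig edge were skipped",
                    sum(!ok)))
  }
  out <- substring(genome[match(chr[ok], names(genome))],
                   lo0[ok] + 1L, hi0[ok])
  names(out) <- paste0(chr[ok], ":", mid[ok])
  out
}

#' Background sequence set from unbound ZNF final exons
#'
#' Final-exon coding regions share finger/linker motifs regardless of
#' binding, so promoter backgrounds would flag coding sequence as "motif".
#' The background set used here is the final exons of C2H2 zinc-finger
#' genes whose gene body intersects no peak; non-C2H2 genes are excluded.
#'
#' @param genes a [gene_table()].
#' @param peaks a peak set.
#' @param genome named `DNAStringSet` or character vector.
#' @return named character vector of final-exon sequences (forward strand).
#' @export
build_background_set <- function(genes, peaks, genome) {
  if (!is.character(genome)) genome <- as.character(genome)
  gb <- genes_as_granges(genes)
  hit <- suppressWarnings(IRanges::overlapsAny(gb, peaks))
  keep <- which(genes$is_c2h2 & !hit)
  if (length(keep) == 0) {
    stop("no unbound C2H2 genes available; supply a larger annotation",
         call. = FALSE)
  }
  fe <- final_exon0(genes)
  out <- substring(genome[match(genes$chrom[keep], names(genome))],
                   fe[keep, 1] + 1L, fe[keep, 2])
  names(out) <- genes$gene_id[keep]
  out
}

# Count forward-strand k-mer windows of a sequence set. Returns a named
# count vector and the number of scorable (ACGT-only) windows.
count_kmers <- function(seqs, k) {
  all <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  }), use.names = FALSE)
  all <- all[!grepl("[^ACGT]", all)]
  list(counts = table(all), total = length(all))
}

# Strand-collapsed site counts: occurrences of each k-mer OR its reverse
# complement among forward windows, indexed by the lexicographically smaller
# of the pair (palindromes counted once).
kmer_site_counts <- function(counts) {
  kmers <- names(counts)
  if (length(kmers) == 0) return(numeric(0))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(kmers)))
  cnt <- as.numeric(counts)
  rc_cnt <- cnt[match(rc, kmers)]
  rc_cnt[is.na(rc_cnt)] <- 0
  site <- ifelse(rc == kmers, cnt, cnt + rc_cnt)
  keep <- kmers <= rc
  setNames(site[keep], kmers[keep])
}

# Find 0-based offsets of exact matches of kmer or its reverse complement on
# the forward text of each sequence. Returns data.frame(seq, offset, strand).
find_kmer_occurrences <- function(seqs, kmer) {
  rc <- revcomp_chr(kmer)
  out <- lapply(seq_along(seqs), function(i) {
    res <- NULL
    for (pat in unique(c(kmer, rc))) {
      st <- if (pat == kmer) "+" else "-"
      m <- gregexpr(pat, seqs[[i]], fixed = TRUE)[[1]]
      if (m[1] != -1) {
        res <- rbind(res, data.frame(seq = i, offset = as.integer(m) - 1L,
                                     strand = st))
      }
    }
    res
  })
  res <- do.call(rbind, out)
  if (is.null(res)) data.frame(seq = integer(0), offset = integer(0),
                               strand = character(0)) else res
}

# Aligned count matrix from occurrences: each occurrence is extended by
# `flank` on each side and oriented so the seed reads forward; positions
# falling outside the sequence contribute nothing.
counts_from_occurrences <- function(seqs, occ, k, flank) {
  L <- k + 2L * flank
  counts <- matrix(0, 4, L, dimnames = list(DNA_BASES4, NULL))
  for (r in seq_len(nrow(occ))) {
    s <- seqs[[occ$seq[r]]]
    n <- nchar(s)
    lo <- occ$offset[r] - flank  # 0-based
    win <- vapply(0:(L - 1L), function(p) {
      q <- lo + p
      if (q < 0 || q >= n) "N" else substr(s, q + 1L, q + 1L)
    }, "")
    if (occ$strand[r] == "-") {
      win <- rev(c(A = "T", C = "G", G = "C", T = "A", N = "N")[win])
    }
    for (p in seq_len(L)) {
      b <- win[p]
      if (b %in% DNA_BASES4) counts[b, p] <- counts[b, p] + 1
    }
  }
  counts
}

# Best ungapped alignment (either orientation) between two PWMs: mean
# per-column Pearson correlation of probability columns over the overlap.
pwm_best_alignment <- function(a, b, min_overlap = 5L) {
  la <- pwm_length(a)
  col_stats <- function(m) list(mu = colMeans(m), ss = colSums(m^2))
  sa <- col_stats(a$probs)
  best <- list(cor = -Inf)
  for (orient in c("fwd", "rev")) {
    bb <- if (orient == "fwd") b else pwm_revcomp(b)
    sb <- col_stats(bb$probs)
    lb <- pwm_length(bb)
    for (off in (-(lb - min_overlap)):(la - min_overlap)) {
      ai <- max(1L, off + 1L):min(la, off + lb)
      bi <- ai - off
      if (length(ai) < min_overlap) next
      num <- colSums(a$probs[, ai, drop = FALSE] *
                       bb$probs[, bi, drop = FALSE]) -
        4 * sa$mu[ai] * sb$mu[bi]
      den <- sqrt((sa$ss[ai] - 4 * sa$mu[ai]^2) * (sb$ss[bi] - 4 * sb$mu[bi]^2))
      cors <- ifelse(den > 0, num / den, 0)
      m <- mean(cors)
      if (m > best$cor) best <- list(cor = m, orient = orient, offset = off)
    }
  }
  best
}

# Merge b into a at the given alignment: summed counts over the union span.
pwm_merge_at <- function(a, b, orient, offset, bg) {
  bb <- if (orient == "fwd") b else pwm_revcomp(b)
  la <- pwm_length(a); lb <- pwm_length(bb)
  lo <- min(1L, offset + 1L); hi <- max(la, offset + lb)
  L <- hi - lo + 1L
  counts <- matrix(0, 4, L, dimnames = list(DNA_BASES4, NULL))
  counts[, (1L:la) - lo + 1L] <- a$counts
  bcols <- (offset + 1L):(offset + lb) - lo + 1L
  counts[, bcols] <- counts[, bcols] + bb$counts
  pwm_from_counts(counts, bg = bg)
}

#' De novo motif discovery by k-mer enrichment against a custom background
#'
#' A self-contained discovery procedure: (1) count every k-mer's sites
#' (either orientation, k in `k_range`) in the foreground and background
#' sets; (2) score enrichment with a one-sided conditional binomial test —
#' of the pooled foreground + background sites, the probability of seeing
#' at least the observed foreground share given the window totals — which
#' stays calibrated when background counts are small; (3) take the
#' top k-mer passing `p_limit` after Bonferroni correction over `4^k`, align
#' its foreground occurrences with `flank` bp on each side, build a
#' pseudocount-0.25 PWM on the background nucleotide composition, mask the
#' occurrences, and repeat for up to `max_rounds`; (4) merge PWMs whose best
#' ungapped alignment in either orientation reaches a mean per-column
#' Pearson correlation of `merge_cor` (overlapping fragments of one long
#' motif reassemble here); (5) classify foreground sequences as
#' motif-positive by a deterministic two-class split of their best-hit
#' scores, then fit each motif's stringency pair as the mean 5th-percentile
#' core and PWM scores of the positive sequences' best hits over `n_boot`
#' bootstrap resamples. A motif's occurrence count is the number of
#' motif-positive foreground sequences.
#'
#' @param fg,bg non-empty character vectors (or `DNAStringSet`) of
#'   foreground and background sequences.
#' @param k_range seed k-mer lengths tried each round.
#' @param seed seed for the bootstrap resampling.
#' @param max_rounds maximum seed-and-mask rounds.
#' @param p_limit Bonferroni-corrected p-value bound for a seed k-mer.
#' @param flank bp added on each side of a seed occurrence.
#' @param merge_cor correlation needed to merge two PWMs.
#' @param n_boot bootstrap resamples for the stringency fit.
#' @return list of `pwm` objects, each with elements `stringency`
#'   (`core_cut`, `pwm_cut`), `n_occurrences` and `seed_kmers`; ordered by
#'   decreasing occurrence count. Empty list when nothing is enriched.
#' @export
discover_motifs <- function(fg, bg, k_range = 6:12, seed = 1L,
                            max_rounds = 30L, p_limit = 1e-6, flank = 3L,
                            merge_cor = 0.8, n_boot = 100L) {
  fg <- as.character(fg); bg <- as.character(bg)
  stop_if_not(length(fg) > 0 && length(bg) > 0,
              "fg and bg must be non-empty")
  set.seed(derive_seed(seed, "discover"))
  bg_freq <- nucleotide_frequencies(bg)
  bg_k <- lapply(k_range, function(k) {
    x <- count_kmers(bg, k)
    list(sites = kmer_site_counts(x$counts), total = x$total)
  })
  names(bg_k) <- as.character(k_range)
  work <- fg
  motifs <- list()
  # window totals are frozen at their pre-masking values so that masking a
  # found motif cannot inflate the apparent enrichment of the rest
  fg_total0 <- vapply(k_range, function(k) count_kmers(fg, k)$total, 0)
  names(fg_total0) <- as.character(k_range)
  for (round in seq_len(max_rounds)) {
    # prefer the longest (most specific) seed length with any passing k-mer
    best <- list(logp = Inf)
    for (k in sort(k_range, decreasing = TRUE)) {
      fgk <- count_kmers(work, k)
      if (fgk$total == 0) next
      fg_sites <- kmer_site_counts(fgk$counts)
      bgk <- bg_k[[as.character(k)]]
      kmers <- names(fg_sites)
      bg_n <- as.numeric(bgk$sites[kmers])
      bg_n[is.na(bg_n)] <- 0
      cnt <- as.numeric(fg_sites)
      # conditional binomial: of the cnt + bg_n pooled sites, how surprising
      # is seeing cnt in the foreground pool of windows?
      p0 <- fg_total0[[as.character(k)]] /
        (fg_total0[[as.character(k)]] + bgk$total)
      logp <- pbinom(cnt - 1, cnt + bg_n, p0, lower.tail = FALSE,
                     log.p = TRUE) + k * log(4)
      ok <- which(logp <= log(p_limit) & cnt >= 3)
      if (length(ok) == 0) next
      o <- ok[order(logp[ok], -cnt[ok], kmers[ok])][1]
      best <- list(logp = logp[o], kmer = kmers[o], k = k)
      break
    }
    if (!is.finite(best$logp)) break
    occ <- find_kmer_occurrences(work, best$kmer)
    counts <- counts_from_occurrences(work, occ, best$k, flank)
    m <- pwm_from_counts(counts, bg = bg_freq)
    m$seed_kmers <- best$kmer
    motifs[[length(motifs) + 1L]] <- m
    # mask the seed occurrences so later rounds find different signals
    for (r in seq_len(nrow(occ))) {
      i <- occ$seq[r]
      substr(work[[i]], occ$offset[r] + 1L, occ$offset[r] + best$k) <-
        paste(rep("N", best$k), collapse = "")
    }
  }
  if (length(motifs) == 0) return(list())
  # merge highly similar / overlapping PWMs (either orientation); a merged
  # motif must stay scoreable within the foreground sequences
  max_len <- max(nchar(fg))
  repeat {
    if (length(motifs) < 2) break
    bestpair <- NULL; bestal <- list(cor = -Inf)
    for (i in seq_len(length(motifs) - 1L)) {
      for (j in (i + 1L):length(motifs)) {
        al <- pwm_best_alignment(motifs[[i]], motifs[[j]])
        li <- pwm_length(motifs[[i]]); lj <- pwm_length(motifs[[j]])
        span <- max(li, al$offset + lj) - min(1L, al$offset + 1L) + 1L
        if (span > max_len) next
        if (al$cor > bestal$cor) { bestal <- al; bestpair <- c(i, j) }
      }
    }
    if (bestal$cor < merge_cor) break
    i <- bestpair[1]; j <- bestpair[2]
    merged <- pwm_merge_at(motifs[[i]], motifs[[j]], bestal$orient,
                           bestal$offset, bg_freq)
    merged$seed_kmers <- c(motifs[[i]]$seed_kmers, motifs[[j]]$seed_kmers)
    motifs[[i]] <- merged
    motifs[[j]] <- NULL
  }
  # fit stringency cutoffs and count occurrences on the original foreground
  for (i in seq_along(motifs)) {
    motifs[[i]] <- pwm_trim_edges(motifs[[i]])
    m <- motifs[[i]]
    all_best <- do.call(rbind, lapply(fg, best_hit, pwm = m))
    if (is.null(all_best) || nrow(all_best) < 3) {
      motifs[[i]]$stringency <- list(core_cut = 1, pwm_cut = 1)
      motifs[[i]]$n_occurrences <- 0L
      next
    }
    # motif-positive sequences: upper class of the bimodal best-hit score
    # distribution (sequences carrying the motif versus background-like)
    thr <- two_class_threshold(all_best$pwm_score)
    pos <- which(all_best$pwm_score > thr)
    if (length(pos) < 3) {
      motifs[[i]]$stringency <- list(core_cut = 1, pwm_cut = 1)
      motifs[[i]]$n_occurrences <- 0L
      next
    }
    q_pwm <- numeric(n_boot); q_core <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      take <- pos[sample.int(length(pos), length(pos), replace = TRUE)]
      q_pwm[b] <- quantile(all_best$pwm_score[take], 0.05, names = FALSE)
      q_core[b] <- quantile(all_best$core_score[take], 0.05, names = FALSE)
    }
    cuts <- list(core_cut = min(mean(q_core), 1), pwm_cut = min(mean(q_pwm), 1))
    motifs[[i]]$stringency <- cuts
    motifs[[i]]$n_occurrences <- length(pos)
  }
  motifs[order(-vapply(motifs, function(m) m$n_occurrences, 0L))]
}

# Deterministic 1-D two-means threshold: splits a score vector at the
# midpoint of two cluster centers (Lloyd iterations from the extremes).
two_class_threshold <- function(x) {
  c1 <- min(x); c2 <- max(x)
  for (it in 1:100) {
    t <- (c1 + c2) / 2
    lo <- x[x <= t]; hi <- x[x > t]
    if (length(lo) == 0 || length(hi) == 0) return(t)
    n1 <- mean(lo); n2 <- mean(hi)
    if (abs(n1 - c1) < 1e-12 && abs(n2 - c2) < 1e-12) break
    c1 <- n1; c2 <- n2
  }
  (c1 + c2) / 2
}

# Trim uninformative edge columns (information content below `min_ic`
# bits) from both ends of a PWM; at least `min_len` columns are kept.
pwm_trim_edges <- function(pwm, min_ic = 0.3, min_len = 6L) {
  probs <- pwm$probs
  ic_terms <- probs * log2(probs / pwm$bg)
  ic_terms[probs == 0] <- 0
  ic <- colSums(ic_terms)
  L <- length(ic)
  lo <- 1L; hi <- L
  while (lo < hi - min_len + 2L && ic[lo] < min_ic) lo <- lo + 1L
  while (hi > lo + min_len - 2L && ic[hi] < min_ic) hi <- hi - 1L
  if (lo == 1L && hi == L) return(pwm)
  out <- pwm_from_counts(pwm$counts[, lo:hi, drop = FALSE], bg = pwm$bg)
  out$seed_kmers <- pwm$seed_kmers
  out
}

nucleotide_frequencies <- function(seqs) {
  tab <- table(factor(unlist(strsplit(toupper(paste(seqs, collapse = "")),
                                      "")), levels = DNA_BASES4))
  f <- as.numeric(tab)
  if (sum(f) == 0) return(rep(0.25, 4))
  f / sum(f)
}

#' Classify motif hits by proximity to ZNF genes
#'
#' A hit is "at" a ZNF gene when its interval intersects the body of a C2H2
#' gene extended by `window` bp on each side.
#'
#' @param hits data.frame from [scan_sequences()] where `seq_id` is a
#'   chromosome name and `offset` a 0-based genomic position.
#' @param genes a [gene_table()].
#' @param window extension of gene bodies in bp (1000).
#' @return list (`n_at_znf`, `n_total`, `fraction`); `fraction` is `NA`
#'   when there are no hits and 0 when there are no C2H2 genes.
#' @export
classify_hits <- function(hits, genes, window = 1000L) {
  n_total <- nrow(hits)
  if (n_total == 0) return(list(n_at_znf = 0L, n_total = 0L, fraction = NA_real_))
  c2 <- genes[genes$is_c2h2, , drop = FALSE]
  if (nrow(c2) == 0) {
    return(list(n_at_znf = 0L, n_total = n_total, fraction = 0))
  }
  ext <- gr_from_bed0(c2$chrom, pmax(c2$start - window, 0L), c2$end + window)
  hr <- gr_from_bed0(hits$seq_id, hits$offset, hits$offset + hits$width)
  n_at <- sum(suppressWarnings(IRanges::overlapsAny(hr, ext)))
  list(n_at_znf = n_at, n_total = n_total, fraction = n_at / n_total)
}

#' Merge two motifs whose consensi overlap in reverse orientation
#'
#' Slides the consensus of `pwmB` against the reverse complement of the
#' consensus of `pwmA` over every offset with at least `min_overlap`
#' aligned columns. If some offset reaches `min_identity` column identity
#' in the overlap, the two motifs are fragments of one longer motif and the
#' merged consensus (length `LB + LA - overlap`) is returned.
#'
#' @param pwmA,pwmB `pwm` objects.
#' @param min_overlap minimum aligned columns (4).
#' @param min_identity identity required in the overlap (0.9).
#' @return list (`consensus`, `overlap`, `identity`, `offset`), or `NULL`
#'   when no qualifying overlap exists.
#' @export
merge_reverse_oriented <- function(pwmA, pwmB, min_overlap = 4L,
                                   min_identity = 0.9) {
  rcA <- strsplit(revcomp_chr(pwmA$consensus), "")[[1]]
  b <- strsplit(pwmB$consensus, "")[[1]]
  la <- length(rcA); lb <- length(b)
  best <- NULL
  for (off in (-(la - min_overlap)):(lb - min_overlap)) {
    bi <- max(1L, off + 1L):min(lb, off + la)
    ai <- bi - off
    if (length(bi) < min_overlap) next
    ident <- mean(b[bi] == rcA[ai])
    if (ident >= min_identity && (is.null(best) || ident > best$identity)) {
      lo <- min(1L, off + 1L); hi <- max(lb, off + la)
      merged <- character(hi - lo + 1L)
      merged[(off + 1L):(off + la) - lo + 1L] <- rcA
      merged[(1L:lb) - lo + 1L] <- b  # B's letters win in the overlap
      best <- list(consensus = paste(merged, collapse = ""),
                   overlap = length(bi), identity = ident, offset = off)
    }
  }
  best
}
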