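#' Mutual overlap counts between two peak sets
#'
#' Counts, for each set, how many of its peaks intersect (at least 1 bp) any
#' peak of the other set — the numbers behind peak-set Venn diagrams.
#'
#' @param a,b peak sets.
#' @return a list with `n_a_overlapping_b` and `n_b_overlapping_a`.
#' @export
overlap_counts <- function(a, b) {
  list(n_a_overlapping_b = sum(suppressWarnings(IRanges::overlapsAny(a, b))),
       n_b_overlapping_a = sum(suppressWarnings(IRanges::overlapsAny(b, a))))
}

#' Per-chromosome peak and C2H2 gene counts
#'
#' One row per chromosome present in either input, with the number of peaks
#' and the number of C2H2 zinc-finger genes encoded on that chromosome —
#' the table behind binding-distribution figures that contrast binding-site
#' counts with the ZNF gene census per chromosome.
#'
#' @param a a peak set.
#' @param genes a [gene_table()].
#' @return data.frame (chrom, n_peaks, n_c2h2_genes); columns sum to
#'   `length(a)` and the number of C2H2 genes.
#' @export
per_chromosome_counts <- function(a, genes) {
  pk <- table(as.character(GenomicRanges::seqnames(a)))
  gn <- table(genes$chrom[genes$is_c2h2])
  chroms <- sort(unique(c(names(pk), names(gn))))
  data.frame(chrom = chroms,
             n_peaks = as.integer(ifelse(chroms %in% names(pk),
                                         pk[chroms], 0L)),
             n_c2h2_genes = as.integer(ifelse(chroms %in% names(gn),
                                              gn[chroms], 0L)),
             stringsAsFactors = FALSE)
}

#' Top fraction of a peak set by height
#'
#' Keeps the `ceiling(frac * N)` highest peaks (ties resolved
#' deterministically by chromosome then start, i.e. by rank) and re-ranks
#' the result.
#'
#' @param a a non-empty peak set.
#' @param frac fraction in (0, 1].
#' @return a peak set.
#' @export
top_fraction <- function(a, frac) {
  stop_if_not(length(a) > 0, "peak set is empty")
  stop_if_not(frac > 0 && frac <= 1, "frac must be in (0, 1]")
  k <- ceiling(frac * length(a))
  peak_set(a[a$rank <= k], name = S4Vectors::metadata(a)$name,
           source = sprintf("top %g of %s", frac,
                            S4Vectors::metadata(a)$source))
}

#' Signed distances from query peaks to nearest subject peak centers
#'
#' For every query peak, the signed distance (bp) from its center to the
#' center of the nearest subject peak on the same chromosome: distance =
#' query center - subject center, nearest by absolute distance, ties going
#' to the subject with the smaller coordinate. Centers are
#' `floor((start + end) / 2)` under 0-based half-open coordinates. Query
#' peaks on chromosomes without any subject peak get `NA`.
#'
#' @param query,subject non-empty peak sets.
#' @return data.frame (chrom, query_start, query_center, distance).
#' @export
distance_to_nearest <- function(query, subject) {
  stop_if_not(length(query) > 0 && length(subject) > 0,
              "query and subject must be non-empty")
  qc <- interval_center0(query)
  sc <- interval_center0(subject)
  qchr <- as.character(GenomicRanges::seqnames(query))
  schr <- as.character(GenomicRanges::seqnames(subject))
  dist <- rep(NA_real_, length(query))
  for (chr in unique(qchr)) {
    qi <- which(qchr == chr)
    si <- which(schr == chr)
    if (length(si) == 0) next
    s <- sort(sc[si])
    for (j in qi) {
      d <- qc[j] - s
      best <- which.min(abs(d))  # ties: smaller subject coordinate wins
      dist[j] <- d[best]
    }
  }
  data.frame(chrom = qchr, query_start = bed0_start(query),
             query_center = qc, distance = dist, stringsAsFactors = FALSE)
}

#' Histogram of a distance profile
#'
#' Bins the signed distances from [distance_to_nearest()] for export and
#' plotting.
#'
#' @param profile output of [distance_to_nearest()].
#' @param bin_width bin width in bp (100 by default).
#' @return data.frame (bin_start, bin_end, count); `NA` distances excluded.
#' @export
distance_histogram <- function(profile, bin_width = 100L) {
  d <- profile$distance[!is.na(profile$distance)]
  if (length(d) == 0) {
    return(data.frame(bin_start = integer(0), bin_end = integer(0),
                      count = integer(0)))
  }
  b <- floor(d / bin_width)
  tb <- table(b)
  data.frame(bin_start = as.integer(names(tb)) * bin_width,
             bin_end = (as.integer(names(tb)) + 1L) * bin_width,
             count = as.integer(tb), stringsAsFactors = FALSE)
}
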