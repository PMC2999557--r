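#' Two-pass assignment of peaks to genes
#'
#' Standard location-analysis tools link a binding site with the nearest
#' transcription start site, which misassigns sites lying in 3' exons of
#' gene-dense clusters to the neighbouring gene's promoter. This two-pass
#' rule first assigns every peak overlapping a gene body to that gene
#' (`within_gene`), and only then assigns the remaining peaks to the gene
#' with the nearest strand-aware TSS (`nearest_tss`). When a peak overlaps
#' several gene bodies, the gene with the greatest overlap wins, then the
#' gene with the smaller start. The peak's context is classified against the
#' assigned gene's exon structure using the peak center: `final_exon` (the
#' 3'-most exon in transcription order), `internal_exon`, `intron`, or —
#' for `nearest_tss` assignments — `upstream`/`downstream` of the gene in
#' its transcription orientation.
#'
#' @param peaks a peak set.
#' @param genes a non-empty [gene_table()].
#' @return data.frame with one row per peak: `chrom`, `peak_start`,
#'   `peak_end` (0-based half-open), `height`, `gene_id`, `mode`, `context`,
#'   `distance_bp` (0 for `within_gene`, else center-to-TSS distance).
#' @export
assign_targets <- function(peaks, genes) {
  stop_if_not(nrow(genes) > 0, "gene table is empty")
  gb <- genes_as_granges(genes)
  n <- length(peaks)
  gene_id <- character(n); mode <- character(n)
  context <- character(n); distance <- numeric(n)
  tss0 <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  fe <- final_exon0(genes)
  centers0 <- interval_center0(peaks)
  pchr <- as.character(GenomicRanges::seqnames(peaks))
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(peaks, gb, ignore.strand = TRUE))
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  widths <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(peaks)[qh], IRanges::ranges(gb)[sh]))
  for (i in seq_len(n)) {
    hits <- which(qh == i)
    if (length(hits) > 0) {
      # pass 1: greatest overlap, then smaller gene start
      o <- hits[order(-widths[hits], genes$start[sh[hits]])]
      g <- sh[o[1]]
      gene_id[i] <- genes$gene_id[g]
      mode[i] <- "within_gene"
      distance[i] <- 0
      context[i] <- classify_context(centers0[i], genes, g, fe)
    } else {
      # pass 2: nearest strand-aware TSS on the same chromosome
      cand <- which(genes$chrom == pchr[i])
      if (length(cand) == 0) cand <- seq_len(nrow(genes))
      d <- abs(centers0[i] - tss0[cand])
      g <- cand[order(d, genes$start[cand])[1]]
      gene_id[i] <- genes$gene_id[g]
      mode[i] <- "nearest_tss"
      distance[i] <- abs(centers0[i] - tss0[g])
      ups <- if (genes$strand[g] == "+") centers0[i] < genes$start[g]
             else centers0[i] >= genes$end[g]
      context[i] <- if (ups) "upstream" else "downstream"
    }
  }
  data.frame(chrom = pchr, peak_start = bed0_start(peaks),
             peak_end = bed0_end(peaks), height = peaks$height,
             gene_id = gene_id, mode = mode, context = context,
             distance_bp = distance, stringsAsFactors = FALSE)
}

# Exon context of a 0-based position within gene g (row index into genes).
classify_context <- function(center0, genes, g, fe) {
  es <- genes$exon_starts[[g]]; ee <- genes$exon_ends[[g]]
  inx <- which(center0 >= es & center0 < ee)
  if (length(inx) == 0) return("intron")
  if (es[inx[1]] == fe[g, 1] && ee[inx[1]] == fe[g, 2]) "final_exon"
  else "internal_exon"
}

#' Finger-domain histogram of bound versus all C2H2 genes
#'
#' For each finger-count bin, the number of C2H2 genes with at least one
#' assigned peak (`n_bound_c2h2`) next to the total number of C2H2 genes in
#' the annotation (`n_all_c2h2`). Each gene is counted once.
#'
#' @param assignments output of [assign_targets()].
#' @param genes a [gene_table()] carrying `finger_count`.
#' @param bin_width finger-count bin width (1 by default).
#' @return data.frame (finger_count_bin, n_bound_c2h2, n_all_c2h2).
#' @export
finger_count_histogram <- function(assignments, genes, bin_width = 1L) {
  c2 <- genes[genes$is_c2h2, , drop = FALSE]
  bound_ids <- unique(assignments$gene_id)
  bin <- (c2$finger_count %/% bin_width) * bin_width
  bins <- sort(unique(bin))
  data.frame(finger_count_bin = bins,
             n_bound_c2h2 = vapply(bins, function(b)
               sum(bin == b & c2$gene_id %in% bound_ids), 0L),
             n_all_c2h2 = vapply(bins, function(b) sum(bin == b), 0L))
}

#' Bound-gene counts per expression quintile
#'
#' Quintile boundaries are the 20/40/60/80th percentiles of the full
#' expression table (each gene's value being its mean expression level
#' across replicates, computed upstream); the function returns how many
#' bound genes fall in each quintile (1 = lowest expression).
#'
#' @param assignments output of [assign_targets()] (bound genes are the
#'   distinct assigned gene ids present in the expression table).
#' @param expression data.frame with columns `gene_id` and `level`.
#' @return integer vector of length 5, counts per quintile.
#' @export
expression_quintile_profile <- function(assignments, expression) {
  stop_if_not(nrow(expression) > 0, "expression table is empty")
  q <- quantile(expression$level, probs = c(0.2, 0.4, 0.6, 0.8))
  quint <- findInterval(expression$level, q, left.open = TRUE) + 1L
  bound <- unique(assignments$gene_id)
  idx <- expression$gene_id %in% bound
  as.integer(table(factor(quint[idx], levels = 1:5)))
}
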