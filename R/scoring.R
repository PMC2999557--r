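#' Score called peaks against planted truth regions
#'
#' A truth region counts as recovered when some called peak matches it with
#' interval Jaccard (intersection / union) at or above `min_jaccard`;
#' a called peak counts as a true call when it matches some truth region
#' the same way. Recall is the recovered fraction of truth regions,
#' precision the true fraction of called peaks.
#'
#' @param peaks a peak set.
#' @param truth_regions `GRanges` of planted regions.
#' @param min_jaccard Jaccard threshold (0.5).
#' @return list (`recall`, `precision`, `n_truth`, `n_called`).
#' @export
score_recovery <- function(peaks, truth_regions, min_jaccard = 0.5) {
  n_truth <- length(truth_regions)
  n_called <- length(peaks)
  if (n_truth == 0 || n_called == 0) {
    return(list(recall = if (n_truth == 0) NA_real_ else 0,
                precision = if (n_called == 0) NA_real_ else 0,
                n_truth = n_truth, n_called = n_called))
  }
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(peaks, truth_regions, ignore.strand = TRUE))
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  inter <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(peaks)[qh], IRanges::ranges(truth_regions)[sh]))
  uni <- IRanges::width(IRanges::ranges(peaks))[qh] +
    IRanges::width(IRanges::ranges(truth_regions))[sh] - inter
  jac <- inter / uni
  good <- jac >= min_jaccard
  list(recall = length(unique(sh[good])) / n_truth,
       precision = length(unique(qh[good])) / n_called,
       n_truth = n_truth, n_called = n_called)
}
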