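#' Replicate consistency by top-ranked peak overlap
#'
#' The ENCODE-style replicate check: both peak lists are truncated to the
#' same length n = min(|A|, |B|), keeping the top-ranked peaks by height;
#' the top `top_frac` (ceiling) of one truncated list is then compared to
#' the entire truncated list of the other replicate, and the fraction with
#' at least 1 bp of overlap is reported, in both directions.
#'
#' @param repA,repB ranked peak sets (non-empty).
#' @param top_frac fraction of the truncated list compared (0.40 by default).
#' @return a list with `frac_a_in_b`, `frac_b_in_a` and `truncated_n`.
#' @export
encode_overlap <- function(repA, repB, top_frac = 0.40) {
  stop_if_not(length(repA) > 0 && length(repB) > 0,
              "both peak sets must be non-empty")
  stop_if_not(top_frac > 0 && top_frac <= 1, "top_frac must be in (0, 1]")
  n <- min(length(repA), length(repB))
  truncA <- repA[repA$rank <= n]
  truncB <- repB[repB$rank <= n]
  k <- ceiling(top_frac * n)
  topA <- truncA[truncA$rank <= k]
  topB <- truncB[truncB$rank <= k]
  frac_a <- mean(suppressWarnings(IRanges::overlapsAny(topA, truncB)))
  frac_b <- mean(suppressWarnings(IRanges::overlapsAny(topB, truncA)))
  list(frac_a_in_b = frac_a, frac_b_in_a = frac_b, truncated_n = n)
}

#' qPCR fold enrichment from cycle thresholds
#'
#' Fold enrichment of a ChIP target is 2 to the power of the cycle-threshold
#' difference between the input chromatin and the ChIP sample:
#' `2^(ct_input - ct_chip)`.
#'
#' @param ct_input,ct_chip finite cycle-threshold values (vectorised).
#' @return fold enrichment.
#' @export
qpcr_fold_enrichment <- function(ct_input, ct_chip) {
  stop_if_not(all(is.finite(ct_input)) && all(is.finite(ct_chip)),
              "cycle thresholds must be finite")
  2^(ct_input - ct_chip)
}
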