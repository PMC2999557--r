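#' Configuration for the tiling-array broad-peak caller
#'
#' Defaults follow the caller's published settings: a sliding average over
#' five probes on either side of the center probe, candidate thresholds at
#' the top 5%, 1% or 0.5% of smoothed probes, a minimum peak span of 800 bp,
#' at most 6 missing probe positions bridged inside one peak region, and an
#' occupancy requirement of at least half the expected probe count. The 5%
#' level suits spreading histone marks (H3K9me3); 1% suits site-specific
#' factors (KAP1, SETDB1); 0.5% suits sparse factors (G9a).
#'
#' @param smooth_halfwidth_oligos probes averaged on each side when smoothing.
#' @param percentile_level fraction of probes called "top" (0.05, 0.01, 0.005).
#' @param min_span_bp minimum peak span in bp.
#' @param max_missing_oligos maximum missing expected probe positions bridged
#'   within one peak region.
#' @param min_expected_fraction minimum fraction of expected probes that must
#'   be present in a peak region.
#' @param tile_interval_bp expected probe spacing.
#' @return a `mayacamas_config` list.
#' @export
mayacamas_config <- function(smooth_halfwidth_oligos = 5L,
                             percentile_level = 0.01,
                             min_span_bp = 800L,
                             max_missing_oligos = 6L,
                             min_expected_fraction = 0.5,
                             tile_interval_bp = 100L) {
  stop_if_not(tile_interval_bp > 0, "tile_interval_bp must be positive")
  stop_if_not(percentile_level > 0 && percentile_level <= 1,
              "percentile_level must be in (0, 1]")
  stop_if_not(smooth_halfwidth_oligos >= 0 && min_span_bp >= 0 &&
                max_missing_oligos >= 0, "counts must be >= 0")
  structure(list(smooth_halfwidth_oligos = as.integer(smooth_halfwidth_oligos),
                 percentile_level = percentile_level,
                 min_span_bp = as.integer(min_span_bp),
                 max_missing_oligos = as.integer(max_missing_oligos),
                 min_expected_fraction = min_expected_fraction,
                 tile_interval_bp = as.integer(tile_interval_bp)),
            class = "mayacamas_config")
}

#' Smooth an array track with a sliding average
#'
#' Each probe's value is replaced by the mean of the probe values in a window
#' of up to `halfwidth` probes on either side of it, in probe-index space
#' (missing probes widen the bp footprint of the window rather than shrinking
#' the number of values averaged). At chromosome edges the window is
#' truncated to the available probes; chromosomes are never mixed.
#'
#' @param track an [array_track()].
#' @param halfwidth probes averaged on each side (5 by default).
#' @return the smoothed array track.
#' @export
smooth_track <- function(track, halfwidth = 5L) {
  if (nrow(track) == 0) return(track)
  halfwidth <- as.integer(halfwidth)
  out <- track
  for (chr in unique(track$chrom)) {
    idx <- which(track$chrom == chr)
    v <- track$value[idx]
    n <- length(v)
    cs <- cumsum(c(0, v))
    lo <- pmax(seq_len(n) - halfwidth, 1L)
    hi <- pmin(seq_len(n) + halfwidth, n)
    out$value[idx] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  out
}

#' Percentile height threshold over smoothed probes
#'
#' Returns the k-th largest smoothed value, k = `ceiling(level * N)`, so that
#' the top `level` fraction of probes is at or above the threshold.
#' Downstream, "above threshold" means `value >= cutoff`; with tied values
#' the above-threshold set can exceed k.
#'
#' @param track a smoothed array track with at least one probe.
#' @param level top fraction of probes, in (0, 1].
#' @return the threshold value.
#' @export
percentile_cutoff <- function(track, level) {
  stop_if_not(is.numeric(level) && level > 0 && level <= 1,
              "level must be in (0, 1]")
  stop_if_not(nrow(track) >= 1, "track must contain at least one probe")
  k <- ceiling(level * nrow(track))
  sort(track$value, decreasing = TRUE)[k]
}

#' Call broad peaks on a smoothed tiling-array track
#'
#' A peak is a run of above-threshold probes (`value >= cutoff`). A present
#' probe below threshold always terminates a run; gaps in the tiling grid
#' (expected probe positions with no probe, the hallmark of repetitive
#' regions on these arrays) are bridged as long as the total number of
#' missing positions within the region stays at or below
#' `max_missing_oligos`. An emitted peak must span at least `min_span_bp`
#' (first probe start to last probe end) and contain at least
#' `min_expected_fraction` of the expected probe count, where expected =
#' `floor(span / tile_interval) + 1`. Peak height is the maximum smoothed
#' value in the run.
#'
#' @param track a smoothed array track.
#' @param config a [mayacamas_config()].
#' @param cutoff height threshold; computed from
#'   `config$percentile_level` via [percentile_cutoff()] when `NULL`.
#' @return a peak set ranked by height.
#' @export
call_chipchip_peaks <- function(track, config = mayacamas_config(),
                                cutoff = NULL) {
  stop_if_not(inherits(config, "mayacamas_config"), "config must be a mayacamas_config")
  if (nrow(track) == 0) {
    return(peak_set(GenomicRanges::GRanges(), numeric(0), "chipchip_peaks"))
  }
  if (is.null(cutoff)) cutoff <- percentile_cutoff(track, config$percentile_level)
  tile <- config$tile_interval_bp
  res_chrom <- character(0); res_s <- integer(0); res_e <- integer(0)
  res_h <- numeric(0)
  for (chr in unique(track$chrom)) {
    sub <- track[track$chrom == chr, , drop = FALSE]
    above <- sub$value >= cutoff
    i <- 1L; n <- nrow(sub)
    while (i <= n) {
      if (!above[i]) { i <- i + 1L; next }
      # grow a run: below-threshold probes terminate it; grid gaps are
      # bridged while cumulative missing positions stay within budget
      j <- i; missing <- 0L
      while (j < n && above[j + 1L]) {
        gap <- (sub$probe_start[j + 1L] - sub$probe_start[j]) %/% tile - 1L
        if (gap < 0L) gap <- 0L
        if (missing + gap > config$max_missing_oligos) break
        missing <- missing + gap
        j <- j + 1L
      }
      span <- sub$probe_end[j] - sub$probe_start[i]
      n_probes <- j - i + 1L
      expected <- span %/% tile + 1L
      if (span >= config$min_span_bp &&
          n_probes >= config$min_expected_fraction * expected) {
        res_chrom <- c(res_chrom, chr)
        res_s <- c(res_s, sub$probe_start[i])
        res_e <- c(res_e, sub$probe_end[j])
        res_h <- c(res_h, max(sub$value[i:j]))
      }
      i <- j + 1L
    }
  }
  peak_set(gr_from_bed0(res_chrom, res_s, res_e), res_h, "chipchip_peaks",
           sprintf("mayacamas level=%g cutoff=%g", config$percentile_level, cutoff))
}
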