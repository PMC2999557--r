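#' Configuration for the broad-domain ChIP-seq caller
#'
#' Defaults follow the modified broad-domain settings: 30 bp bins smoothed
#' over 600 bp on either side, an empirical false discovery rate of 0.01 for
#' the height cutoff, and a 150 bp minimum peak length approximating the
#' minimal chromatin fragment size. Tags are extended to
#' `fragment_length_bp` before computing coverage.
#'
#' @param bin_step_bp bin width/step in bp (bins anchored at multiples of it).
#' @param smooth_flank_bp smoothing flank: a bin's smoothed value is the mean
#'   of raw bin values whose bin start lies within this distance.
#' @param fdr empirical FDR bound for the height cutoff.
#' @param min_length_bp minimum emitted peak length.
#' @param fragment_length_bp 3'-ward extension applied to each tag.
#' @return a `broadcall_config` list.
#' @export
broadcall_config <- function(bin_step_bp = 30L, smooth_flank_bp = 600L,
                             fdr = 0.01, min_length_bp = 150L,
                             fragment_length_bp = 150L) {
  stop_if_not(smooth_flank_bp %% bin_step_bp == 0,
              "bin_step_bp must divide smooth_flank_bp")
  stop_if_not(fdr > 0 && fdr < 1, "fdr must be in (0, 1)")
  stop_if_not(min_length_bp >= bin_step_bp, "min_length_bp must be >= bin_step_bp")
  structure(list(bin_step_bp = as.integer(bin_step_bp),
                 smooth_flank_bp = as.integer(smooth_flank_bp),
                 fdr = fdr, min_length_bp = as.integer(min_length_bp),
                 fragment_length_bp = as.integer(fragment_length_bp)),
            class = "broadcall_config")
}

#' Depth-normalisation factor between ChIP and input libraries
#'
#' Returns `depth(chip) / depth(input)`; the input exceedance counts are
#' scaled by this factor before the empirical FDR is computed, so libraries
#' of unequal sequencing depth are comparable.
#'
#' @param chip,input tag libraries with positive depth.
#' @return the scale factor.
#' @export
normalize_background <- function(chip, input) {
  stop_if_not(tag_depth(chip) > 0, "chip library has zero depth")
  stop_if_not(tag_depth(input) > 0, "input library has zero depth")
  tag_depth(chip) / tag_depth(input)
}

#' Binned, smoothed fragment coverage
#'
#' Each tag is extended `fragment_length_bp` 3'-ward from its 5' start
#' (strand-aware) and per-bp fragment coverage is computed. The raw value of
#' a bin (bins of `bin_step_bp`, anchored at multiples of it from coordinate
#' 0) is the mean coverage over the bin; the smoothed value is the mean of
#' the raw values of all bins whose start lies within `smooth_flank_bp` of
#' the bin's start (window truncated at chromosome edges). Tags whose
#' fragment extends past a chromosome end are clipped with a warning.
#'
#' @param tags a tag library.
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param config a [broadcall_config()].
#' @param smooth if `FALSE`, return raw bin means without smoothing.
#' @return a `binned_track` data.frame with columns `chrom`, `bin_start`
#'   (0-based) and `value`, ordered, with attribute `bin_step`.
#' @export
bin_and_smooth <- function(tags, chrom_lengths, config = broadcall_config(),
                           smooth = TRUE) {
  stop_if_not(!is.null(names(chrom_lengths)) && all(nzchar(names(chrom_lengths))),
              "chrom_lengths must be a named vector")
  step <- config$bin_step_bp
  flank_bins <- config$smooth_flank_bp %/% step
  fl <- config$fragment_length_bp
  out <- vector("list", length(chrom_lengths))
  for (ci in seq_along(chrom_lengths)) {
    chr <- names(chrom_lengths)[ci]
    len <- as.integer(chrom_lengths[[ci]])
    sub <- tags[tags$chrom == chr, , drop = FALSE]
    if (any(sub$start >= len)) {
      warning(sprintf("%d tags beyond end of %s clipped",
                      sum(sub$start >= len), chr))
      sub <- sub[sub$start < len, , drop = FALSE]
    }
    # fragment intervals, 1-based closed for IRanges
    s1 <- ifelse(sub$strand == "+", sub$start + 1L, sub$start - fl + 2L)
    e1 <- ifelse(sub$strand == "+", sub$start + fl, sub$start + 1L)
    s1 <- pmax(s1, 1L); e1 <- pmin(e1, len)
    keep <- e1 >= s1
    cov <- IRanges::coverage(IRanges::IRanges(s1[keep], e1[keep]), width = len)
    bin_start <- seq.int(0L, len - 1L, by = step)
    bin_end <- pmin(bin_start + step, len)
    raw <- IRanges::viewMeans(IRanges::Views(cov, bin_start + 1L, bin_end))
    value <- if (smooth && length(raw) > 0) {
      cs <- cumsum(c(0, raw))
      n <- length(raw)
      lo <- pmax(seq_len(n) - flank_bins, 1L)
      hi <- pmin(seq_len(n) + flank_bins, n)
      (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    } else as.numeric(raw)
    out[[ci]] <- data.frame(chrom = chr, bin_start = bin_start, value = value,
                            stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  attr(df, "bin_step") <- step
  class(df) <- c("binned_track", "data.frame")
  df
}

#' Empirical-FDR height cutoff
#'
#' Over the ascending grid of observed ChIP bin values h, the empirical FDR
#' is `FDR(h) = scale * #(input bins >= h) / #(ChIP bins >= h)`. The cutoff
#' is the lowest observed h whose FDR does not surpass `fdr`. When no height
#' qualifies the function returns `NA` (the "no signal" marker) and the
#' caller emits zero peaks.
#'
#' @param chip,input binned tracks on identical bin grids.
#' @param scale depth-normalisation factor from [normalize_background()].
#' @param fdr the FDR bound.
#' @return the cutoff height, or `NA_real_` when no height qualifies.
#' @export
fdr_height_cutoff <- function(chip, input, scale = 1, fdr = 0.01) {
  stop_if_not(nrow(chip) == nrow(input) &&
                all(chip$chrom == input$chrom) &&
                all(chip$bin_start == input$bin_start),
              "chip and input must share one bin grid")
  h_grid <- sort(unique(chip$value))
  chip_sorted <- sort(chip$value)
  input_sorted <- sort(input$value)
  n_chip <- length(chip_sorted) - findInterval(h_grid, chip_sorted,
                                              left.open = TRUE)
  n_input <- length(input_sorted) - findInterval(h_grid, input_sorted,
                                                 left.open = TRUE)
  ok <- (scale * n_input / n_chip) <= fdr
  if (!any(ok)) return(NA_real_)
  h_grid[which(ok)[1]]
}

#' Call broad peaks from a smoothed binned track
#'
#' Peaks are maximal runs of consecutive bins (adjacent bin starts) with
#' smoothed value at or above the height cutoff. Run length in bp is
#' `(last bin start - first bin start) + bin_step`; runs shorter than
#' `min_length_bp` are dropped. Peak height is the maximum bin value in the
#' run; peaks are ranked by height, ties by (chromosome, start).
#'
#' @param chip a smoothed binned track.
#' @param cutoff height cutoff from [fdr_height_cutoff()]; `NA` means "no
#'   signal" and yields an empty peak set.
#' @param config a [broadcall_config()].
#' @return a peak set.
#' @export
call_broad_peaks <- function(chip, cutoff, config = broadcall_config()) {
  step <- attr(chip, "bin_step")
  if (is.null(step)) step <- config$bin_step_bp
  empty <- peak_set(GenomicRanges::GRanges(), numeric(0), "broad_peaks")
  if (is.na(cutoff) || nrow(chip) == 0) return(empty)
  above <- chip$value >= cutoff
  if (!any(above)) return(empty)
  idx <- which(above)
  brk <- c(TRUE, diff(chip$bin_start[idx]) != step |
             chip$chrom[idx][-1] != chip$chrom[idx][-length(idx)])
  run_id <- cumsum(brk)
  first <- idx[!duplicated(run_id)]
  last <- idx[!duplicated(run_id, fromLast = TRUE)]
  len_bp <- chip$bin_start[last] - chip$bin_start[first] + step
  keep <- len_bp >= config$min_length_bp
  first <- first[keep]; last <- last[keep]
  if (length(first) == 0) return(empty)
  h <- vapply(seq_along(first), function(k)
    max(chip$value[first[k]:last[k]]), 0)
  peak_set(gr_from_bed0(chip$chrom[first], chip$bin_start[first],
                        chip$bin_start[last] + step),
           h, "broad_peaks", sprintf("broadcall cutoff=%g", cutoff))
}

#' End-to-end broad-domain ChIP-seq peak calling
#'
#' Runs depth normalisation, binning and smoothing of both libraries, the
#' empirical-FDR height cutoff, and run/length filtering. The original
#' sharp-peak caller's third step (significance over background) is
#' deliberately absent from this broad-domain mode: small peaks in input
#' data do not affect calling over broad chromatin domains.
#'
#' @param chip,input tag libraries.
#' @param chrom_lengths named chromosome lengths.
#' @param config a [broadcall_config()].
#' @param verbose log the scale factor, cutoff and peak count.
#' @return a peak set.
#' @export
call_chipseq_peaks <- function(chip, input, chrom_lengths,
                               config = broadcall_config(), verbose = FALSE) {
  scale <- normalize_background(chip, input)
  chip_b <- bin_and_smooth(chip, chrom_lengths, config)
  input_b <- bin_and_smooth(input, chrom_lengths, config)
  hstar <- fdr_height_cutoff(chip_b, input_b, scale, config$fdr)
  peaks <- call_broad_peaks(chip_b, hstar, config)
  if (verbose) {
    message(sprintf("scale=%.4f cutoff=%s peaks=%d", scale,
                    format(hstar), length(peaks)))
  }
  peaks
}
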