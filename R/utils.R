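#' @import methods
#' @importFrom stats quantile rnorm runif rbinom pbinom setNames
#' @importFrom utils read.table write.table head
NULL

# All files exchanged by this package use BED-style 0-based half-open
# coordinates. In memory, ranges live in GRanges (1-based closed, the
# Bioconductor convention); conversion happens only at the I/O boundary.

gr_from_bed0 <- function(chrom, start0, end0) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start0 + 1L, end = end0))
}

bed0_start <- function(gr) GenomicRanges::start(gr) - 1L
bed0_end <- function(gr) GenomicRanges::end(gr)

# Interval center under the 0-based half-open convention:
# floor((start0 + end0) / 2), reported as a 0-based position.
interval_center0 <- function(gr) {
  (bed0_start(gr) + bed0_end(gr)) %/% 2L
}

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Derive a reproducible 32-bit sub-seed from a master seed and a stream label.
# Streams keep the generator stages independent without a global RNG walk.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

DNA_BASES4 <- c("A", "C", "G", "T")

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
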