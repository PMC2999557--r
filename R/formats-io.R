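#' Construct a peak set
#'
#' A peak set is a `GRanges` holding ranked, non-overlapping enriched regions.
#' Each peak carries a `height` (the caller's enrichment statistic: maximum
#' smoothed log2 ratio for tiling arrays, maximum smoothed tag coverage for
#' sequencing) and a 1-based `rank` by descending height. Peaks are stored
#' sorted by (chromosome, start); ranks are recomputed on construction, with
#' ties broken by (chromosome, start).
#'
#' @param gr `GRanges` of peak intervals (1-based closed, as usual for
#'   `GRanges`); any existing `rank` column is discarded.
#' @param height numeric enrichment values, one per range. Defaults to an
#'   existing `height` metadata column, else 0.
#' @param name label for the set.
#' @param source free-text provenance note.
#' @return `GRanges` with metadata columns `height` and `rank`, and
#'   `metadata()` entries `name` and `source`.
#' @export
peak_set <- function(gr, height = NULL, name = "peaks", source = "") {
  stop_if_not(methods::is(gr, "GRanges"), "gr must be a GRanges")
  if (is.null(height)) {
    height <- if (!is.null(gr$height)) gr$height else rep(0, length(gr))
  }
  stop_if_not(length(height) == length(gr), "height length must match gr")
  stop_if_not(all(is.finite(height)), "peak heights must be finite")
  S4Vectors::mcols(gr) <- NULL
  gr$height <- as.numeric(height)
  o <- order(as.character(GenomicRanges::seqnames(gr)), GenomicRanges::start(gr))
  gr <- gr[o]
  if (length(gr) > 1) {
    same <- as.character(GenomicRanges::seqnames(gr))[-1] ==
      as.character(GenomicRanges::seqnames(gr))[-length(gr)]
    ov <- same & GenomicRanges::start(gr)[-1] <= GenomicRanges::end(gr)[-length(gr)]
    stop_if_not(!any(ov), "peaks within a set must not overlap on a chromosome")
  }
  gr$rank <- peak_ranks(gr)
  S4Vectors::metadata(gr)$name <- name
  S4Vectors::metadata(gr)$source <- source
  gr
}

# Ranks 1..N by descending height, ties by (chrom, start).
peak_ranks <- function(gr) {
  o <- order(-gr$height, as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr))
  r <- integer(length(gr))
  r[o] <- seq_along(o)
  r
}

#' Read a BED file as a peak set
#'
#' Accepts 3 to 5+ tab-separated columns (chrom, start, end, name, score);
#' the 5th column, when present, is taken as the peak height. BED 0-based
#' half-open coordinates are preserved. The returned set is sorted by
#' (chromosome, start) and ranks are recomputed from heights.
#'
#' @param path file path.
#' @param name,source labels stored on the returned set.
#' @return a peak set (see [peak_set()]).
#' @export
read_bed <- function(path, name = basename(path), source = path) {
  stop_if_not(file.exists(path), paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(peak_set(GenomicRanges::GRanges(), numeric(0), name, source))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop(sprintf("malformed BED line %d: fewer than 3 fields",
                 which(nf < 3)[1]), call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad)) {
    stop(sprintf("malformed BED line %d: non-numeric coordinates", bad[1]),
         call. = FALSE)
  }
  if (any(start0 >= end0)) {
    stop(sprintf("invalid interval on line %d: start >= end",
                 which(start0 >= end0)[1]), call. = FALSE)
  }
  if (any(start0 < 0)) {
    stop(sprintf("invalid interval on line %d: negative start",
                 which(start0 < 0)[1]), call. = FALSE)
  }
  height <- ifelse(nf >= 5,
                   suppressWarnings(as.numeric(vapply(fields, function(f)
                     if (length(f) >= 5) f[[5]] else "0", ""))),
                   0)
  height[is.na(height)] <- 0
  peak_set(gr_from_bed0(chrom, start0, end0), height, name, source)
}

#' Write a peak set as BED5
#'
#' Emits chrom, 0-based start, half-open end, name (`<set>_<rank>`), height.
#' `read_bed(write_bed(x))` reproduces intervals and heights (heights to the
#' printed precision: up to 10 significant digits).
#'
#' @param peaks a peak set.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  nm <- S4Vectors::metadata(peaks)$name
  if (is.null(nm)) nm <- "peak"
  lines <- if (length(peaks) == 0) character(0) else {
    paste(as.character(GenomicRanges::seqnames(peaks)),
          bed0_start(peaks), bed0_end(peaks),
          paste0(nm, "_", peaks$rank),
          formatC(peaks$height, digits = 10, format = "g"),
          sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Array track: ordered tiling-array probe measurements
#'
#' An array track is a data.frame with columns `chrom`, `probe_start`,
#' `probe_end` (0-based half-open) and `value` (log2 ChIP/input ratio), with
#' probe starts strictly increasing within each chromosome, plus an attribute
#' `tile_interval` giving the expected probe spacing in bp (100 for the HD2
#' style tiling used here).
#'
#' @param chrom,probe_start,probe_end,value probe columns.
#' @param tile_interval expected probe spacing in bp.
#' @return an `array_track` data.frame.
#' @export
array_track <- function(chrom, probe_start, probe_end, value,
                        tile_interval = 100L) {
  df <- data.frame(chrom = as.character(chrom),
                   probe_start = as.integer(probe_start),
                   probe_end = as.integer(probe_end),
                   value = as.numeric(value),
                   stringsAsFactors = FALSE)
  stop_if_not(all(is.finite(df$value)), "array values must be finite")
  stop_if_not(all(df$probe_end > df$probe_start), "probe_end must exceed probe_start")
  df <- df[order(df$chrom, df$probe_start), , drop = FALSE]
  rownames(df) <- NULL
  dup <- stats::ave(df$probe_start, df$chrom,
                    FUN = function(x) c(FALSE, diff(x) <= 0))
  stop_if_not(!any(dup > 0), "probe starts must be strictly increasing per chromosome")
  attr(df, "tile_interval") <- as.integer(tile_interval)
  class(df) <- c("array_track", "data.frame")
  df
}

#' @rdname array_track
#' @param path tab-separated file with 4 columns (chrom, probe_start,
#'   probe_end, log2 ratio), 0-based half-open; rows in any order.
#' @export
read_array_track <- function(path, tile_interval = 100L) {
  stop_if_not(file.exists(path), paste0("no such file: ", path))
  df <- read.table(path, sep = "\t", header = FALSE, col.names =
                     c("chrom", "probe_start", "probe_end", "value"),
                   colClasses = c("character", "integer", "integer", "numeric"))
  array_track(df$chrom, df$probe_start, df$probe_end, df$value, tile_interval)
}

#' @rdname array_track
#' @param track an array track.
#' @export
write_array_track <- function(track, path) {
  write.table(data.frame(track$chrom, track$probe_start, track$probe_end,
                         track$value),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Tag library: uniquely-mapped read 5' positions
#'
#' A tag library is a data.frame with columns `chrom`, `start` (0-based 5'
#' position of the uniquely aligned tag) and `strand` (`+`/`-`). Its depth
#' is the number of tags.
#'
#' @param chrom,start,strand tag columns.
#' @return a `tag_library` data.frame.
#' @export
tag_library <- function(chrom, start, strand) {
  stop_if_not(all(strand %in% c("+", "-")), "strand must be '+' or '-'")
  stop_if_not(all(start >= 0), "tag positions must be >= 0")
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   strand = as.character(strand), stringsAsFactors = FALSE)
  class(df) <- c("tag_library", "data.frame")
  df
}

#' @rdname tag_library
#' @param tags a tag library.
#' @export
tag_depth <- function(tags) nrow(tags)

#' @rdname tag_library
#' @param path tab-separated file (chrom, start, strand), one tag per line.
#' @export
read_tags <- function(path) {
  stop_if_not(file.exists(path), paste0("no such file: ", path))
  n <- length(readLines(path))
  if (n == 0) return(tag_library(character(0), integer(0), character(0)))
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "strand"),
                   colClasses = c("character", "integer", "character"))
  if (!all(df$strand %in% c("+", "-"))) {
    stop(sprintf("unknown strand symbol on line %d",
                 which(!(df$strand %in% c("+", "-")))[1]), call. = FALSE)
  }
  tag_library(df$chrom, df$start, df$strand)
}

#' @rdname tag_library
#' @export
write_tags <- function(tags, path) {
  write.table(data.frame(tags$chrom, tags$start, tags$strand),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Gene table: annotated gene models with zinc-finger attributes
#'
#' A gene table is a data.frame with one row per gene: `gene_id`, `chrom`,
#' `start`, `end` (transcript bounds, 0-based half-open), `strand`,
#' list-columns `exon_starts`/`exon_ends` (0-based half-open, ordered by
#' genomic coordinate, non-overlapping, within the transcript bounds), and
#' the attributes `is_c2h2` (C2H2 zinc-finger gene), `finger_count`
#' (number of finger domains; 0 for non-C2H2 genes) and `has_krab`
#' (carries a KRAB repression domain).
#'
#' @param df data.frame with the columns above.
#' @return a validated `gene_table` data.frame.
#' @export
gene_table <- function(df) {
  need <- c("gene_id", "chrom", "start", "end", "strand",
            "exon_starts", "exon_ends")
  stop_if_not(all(need %in% names(df)),
              paste("gene table needs columns:", paste(need, collapse = ", ")))
  if (is.null(df$is_c2h2)) { warning("no is_c2h2 column; defaulting to FALSE"); df$is_c2h2 <- FALSE }
  if (is.null(df$finger_count)) { warning("no finger_count column; defaulting to 0"); df$finger_count <- 0L }
  if (is.null(df$has_krab)) { warning("no has_krab column; defaulting to FALSE"); df$has_krab <- FALSE }
  stop_if_not(all(df$strand %in% c("+", "-")), "gene strand must be '+' or '-'")
  stop_if_not(all(df$finger_count[!df$is_c2h2] == 0),
              "finger_count must be 0 for non-C2H2 genes")
  for (i in seq_len(nrow(df))) {
    es <- df$exon_starts[[i]]; ee <- df$exon_ends[[i]]
    stop_if_not(length(es) == length(ee) && length(es) >= 1,
                sprintf("gene %s: exon start/end mismatch", df$gene_id[i]))
    stop_if_not(all(ee > es), sprintf("gene %s: empty exon", df$gene_id[i]))
    o <- order(es)
    es <- es[o]; ee <- ee[o]
    stop_if_not(all(es[-1] >= ee[-length(ee)]),
                sprintf("gene %s: overlapping exons", df$gene_id[i]))
    stop_if_not(es[1] >= df$start[i] && ee[length(ee)] <= df$end[i],
                sprintf("gene %s: exons outside transcript bounds", df$gene_id[i]))
    df$exon_starts[[i]] <- as.integer(es); df$exon_ends[[i]] <- as.integer(ee)
  }
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_table", "data.frame")
  df
}

#' @rdname gene_table
#' @param path refFlat-style tab-separated file: gene_id, chrom, strand,
#'   tx_start, tx_end, exon_count, comma-joined exon_starts, comma-joined
#'   exon_ends, then optional attribute columns is_c2h2 (0/1), finger_count,
#'   has_krab (0/1). Absent attribute columns default to FALSE/0 with a
#'   warning.
#' @export
read_gene_table <- function(path) {
  stop_if_not(file.exists(path), paste0("no such file: ", path))
  raw <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  stop_if_not(ncol(raw) >= 8, "gene table needs >= 8 columns")
  parse_ints <- function(s) as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
  df <- data.frame(gene_id = as.character(raw[[1]]), chrom = as.character(raw[[2]]),
                   strand = as.character(raw[[3]]),
                   start = as.integer(raw[[4]]), end = as.integer(raw[[5]]),
                   stringsAsFactors = FALSE)
  df$exon_starts <- lapply(raw[[7]], parse_ints)
  df$exon_ends <- lapply(raw[[8]], parse_ints)
  stop_if_not(all(lengths(df$exon_starts) == as.integer(raw[[6]])),
              "exon_count column disagrees with exon list")
  if (ncol(raw) >= 11) {
    df$is_c2h2 <- as.logical(as.integer(raw[[9]]))
    df$finger_count <- as.integer(raw[[10]])
    df$has_krab <- as.logical(as.integer(raw[[11]]))
  }
  gene_table(df)
}

#' @rdname gene_table
#' @param genes a gene table.
#' @export
write_gene_table <- function(genes, path) {
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    paste(genes$gene_id[i], genes$chrom[i], genes$strand[i],
          genes$start[i], genes$end[i], length(genes$exon_starts[[i]]),
          paste(genes$exon_starts[[i]], collapse = ","),
          paste(genes$exon_ends[[i]], collapse = ","),
          as.integer(genes$is_c2h2[i]), genes$finger_count[i],
          as.integer(genes$has_krab[i]), sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# Gene bodies as GRanges (1-based closed), named by gene_id.
genes_as_granges <- function(genes) {
  gr <- gr_from_bed0(genes$chrom, genes$start, genes$end)
  GenomicRanges::strand(gr) <- genes$strand
  names(gr) <- genes$gene_id
  gr
}

# The final (3'-most in transcription order) exon of each gene, 0-based
# half-open [start, end). For '+' genes this is the last genomic exon, for
# '-' genes the first.
final_exon0 <- function(genes) {
  t(vapply(seq_len(nrow(genes)), function(i) {
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    k <- if (genes$strand[i] == "+") length(es) else 1L
    c(es[k], ee[k])
  }, integer(2)))
}
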