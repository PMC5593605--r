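# Internal helpers shared across modules. All internal coordinates are
# 0-based half-open; file readers/writers convert to each format's dialect.

# Unique key for a genomic interval or tile.
tile_key <- function(chrom, start) paste0(chrom, ":", start)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Convert an internal 0-based half-open interval data.frame (chrom,start,end)
# to a GRanges (1-based inclusive).
as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# Overlap hits between two interval data.frames; returns the findOverlaps
# Hits object (queries with >= 1 bp overlap under half-open semantics).
interval_overlaps <- function(query, subject) {
  GenomicRanges::findOverlaps(as_granges(query), as_granges(subject))
}

stop_premeth <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
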