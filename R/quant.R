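# Methylation quantification: per-CpG levels, 100-bp tile pooling, local CpG
# density, stage averaging, and methylation-status summaries.

#' Load a Bismark coverage file
#'
#' Reads a 6-column Bismark coverage file (chrom, start, end, percent
#' methylation, count methylated, count unmethylated; 1-based inclusive
#' coordinates) into per-CpG counts with 0-based positions.
#'
#' @param path Path to the coverage file.
#' @param sample_id Sample identifier stored with the result; defaults to the
#'   file name without extension.
#' @return A `data.frame` with columns `chrom`, `pos` (0-based cytosine
#'   position), `meth`, `unmeth`, sorted by `(chrom, pos)`, with attribute
#'   `sample_id`.
#' @export
load_coverage <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop_premeth("coverage file not found: %s", path)
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  raw <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      colClasses = c("character", "numeric", "numeric",
                                     "numeric", "numeric", "numeric"),
                      quote = "", comment.char = ""),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) NULL else
        stop_premeth("cannot parse %s: %s", path, conditionMessage(e))
    })
  if (is.null(raw) || nrow(raw) == 0) {
    warning(sprintf("coverage file %s is empty", path), call. = FALSE)
    out <- data.frame(chrom = character(), pos = integer(),
                      meth = integer(), unmeth = integer())
    attr(out, "sample_id") <- sample_id
    class(out) <- c("cpg_counts", "data.frame")
    return(out)
  }
  if (ncol(raw) != 6) {
    stop_premeth("%s: expected 6 columns in Bismark coverage format, got %d",
                 path, ncol(raw))
  }
  counts <- raw[, c(5, 6)]
  bad <- which(counts[[1]] < 0 | counts[[2]] < 0 |
               counts[[1]] != round(counts[[1]]) |
               counts[[2]] != round(counts[[2]]))
  if (length(bad)) {
    stop_premeth("%s: negative or non-integer counts at line(s) %s", path,
                 paste(utils::head(bad, 10), collapse = ", "))
  }
  out <- data.frame(chrom = raw[[1]],
                    pos = as.integer(raw[[2]]) - 1L,
                    meth = as.integer(raw[[5]]),
                    unmeth = as.integer(raw[[6]]))
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  dup <- duplicated(out[c("chrom", "pos")])
  if (any(dup)) {
    d <- out[dup, ][1, ]
    stop_premeth("%s: duplicated CpG position %s:%d", path, d$chrom, d$pos + 1L)
  }
  rownames(out) <- NULL
  attr(out, "sample_id") <- sample_id
  class(out) <- c("cpg_counts", "data.frame")
  out
}

#' Per-CpG methylation levels
#'
#' The level of a CpG is the number of reads reporting C divided by the reads
#' reporting C or T; CpGs below the coverage cutoff are dropped.
#'
#' @param counts A `cpg_counts` data.frame (see [load_coverage()]).
#' @param min_cov Minimum total coverage for a CpG to be reported (inclusive).
#' @return `data.frame` with `chrom`, `pos`, `meth`, `unmeth`, `coverage`,
#'   `level`.
#' @export
cpg_methylation <- function(counts, min_cov = 5) {
  stopifnot(min_cov >= 1)
  cov <- counts$meth + counts$unmeth
  keep <- cov >= min_cov
  out <- data.frame(chrom = counts$chrom[keep], pos = counts$pos[keep],
                    meth = counts$meth[keep], unmeth = counts$unmeth[keep],
                    coverage = cov[keep])
  out$level <- ifelse(out$coverage > 0, out$meth / out$coverage, NA_real_)
  rownames(out) <- NULL
  out
}

#' Local CpG density
#'
#' Density of a CpG site is the number of CpG sites (including itself) within
#' `window` bp up- and downstream of it.
#'
#' @param positions Sorted vector of all CpG positions on one chromosome.
#' @param query_pos Positions at which to evaluate the density; must be a
#'   subset of `positions`. Defaults to all of them.
#' @param window Flank size in bp (default 50).
#' @return Integer vector of densities, parallel to `query_pos`.
#' @export
cpg_density <- function(positions, query_pos = positions, window = 50) {
  if (is.unsorted(positions)) positions <- sort(positions)
  if (!all(query_pos %in% positions)) {
    stop_premeth("query position(s) not in the CpG set: %s",
                 paste(utils::head(setdiff(query_pos, positions), 5),
                       collapse = ", "))
  }
  hi <- findInterval(query_pos + window, positions)
  lo <- findInterval(query_pos - window - 1, positions)
  as.integer(hi - lo)
}

#' Tile methylation by pooled counts
#'
#' Partitions each chromosome into fixed non-overlapping tiles anchored at
#' position 0 and pools the reads of all CpGs passing the coverage cutoff
#' within each tile; the tile level is pooled methylated reads over pooled
#' total reads. A tile is reported iff at least one CpG contributes. The tile
#' CpG density is the mean local density of its contributing CpGs, computed
#' against all CpG positions known for the sample (or against
#' `cpg_positions`, e.g. the full genomic CpG set, when supplied).
#'
#' @param counts A `cpg_counts` data.frame.
#' @param tile_size Tile width in bp (default 100).
#' @param min_cov Minimum per-CpG coverage for a CpG to contribute.
#' @param density_window Flank used for the local CpG density (default 50).
#' @param cpg_positions Optional data.frame `(chrom, pos)` of the full CpG
#'   site set used for density; defaults to the positions present in `counts`.
#' @return `data.frame` with `chrom`, `start`, `end` (0-based half-open),
#'   `level`, `pooled_meth`, `pooled_total`, `n_cpgs`, `cpg_density`;
#'   attribute `sample_id`.
#' @export
tile_methylation <- function(counts, tile_size = 100, min_cov = 5,
                             density_window = 50, cpg_positions = NULL) {
  stopifnot(tile_size >= 1, min_cov >= 1)
  cov <- counts$meth + counts$unmeth
  keep <- cov >= min_cov
  used <- counts[keep, , drop = FALSE]
  if (nrow(used) == 0) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      level = double(), pooled_meth = integer(),
                      pooled_total = integer(), n_cpgs = integer(),
                      cpg_density = double())
    attr(out, "sample_id") <- attr(counts, "sample_id")
    return(out)
  }
  ref <- if (is.null(cpg_positions)) {
    counts[c("chrom", "pos")]
  } else cpg_positions
  dens <- numeric(nrow(used))
  for (ch in unique(used$chrom)) {
    sel <- used$chrom == ch
    dens[sel] <- cpg_density(sort(ref$pos[ref$chrom == ch]),
                             used$pos[sel], window = density_window)
  }
  tile_start <- (used$pos %/% tile_size) * tile_size
  key <- tile_key(used$chrom, tile_start)
  grp <- factor(key, levels = unique(key))
  pooled_meth <- as.integer(rowsum(used$meth, grp))
  pooled_total <- as.integer(rowsum(used$meth + used$unmeth, grp))
  out <- data.frame(
    chrom = used$chrom[!duplicated(grp)],
    start = tile_start[!duplicated(grp)],
    pooled_meth = pooled_meth,
    pooled_total = pooled_total,
    n_cpgs = as.integer(tabulate(grp)),
    cpg_density = as.numeric(rowsum(dens, grp)) / tabulate(grp)
  )
  out$end <- out$start + as.integer(tile_size)
  out$level <- out$pooled_meth / out$pooled_total
  out <- out[order(out$chrom, out$start),
             c("chrom", "start", "end", "level", "pooled_meth",
               "pooled_total", "n_cpgs", "cpg_density")]
  rownames(out) <- NULL
  attr(out, "sample_id") <- attr(counts, "sample_id")
  out
}

#' Average replicate methylomes into a stage methylome
#'
#' Stage level of a tile is the unweighted arithmetic mean of the replicate
#' levels; only tiles covered in every replicate are retained.
#'
#' @param replicates List of tile methylomes (see [tile_methylation()]).
#' @param stage Optional stage label stored as an attribute.
#' @return `data.frame` `chrom`, `start`, `end`, `level`, `cpg_density`
#'   (mean over replicates), `n_replicates`.
#' @export
stage_average <- function(replicates, stage = NULL) {
  if (length(replicates) < 1) stop_premeth("stage_average needs >= 1 replicate")
  keys <- lapply(replicates, function(m) tile_key(m$chrom, m$start))
  common <- Reduce(intersect, keys)
  base <- replicates[[1]]
  idx1 <- match(common, keys[[1]])
  lev <- sapply(replicates, function(m) {
    m$level[match(common, tile_key(m$chrom, m$start))]
  })
  den <- sapply(replicates, function(m) {
    m$cpg_density[match(common, tile_key(m$chrom, m$start))]
  })
  if (length(common) == 1) { lev <- t(lev); den <- t(den) }
  out <- data.frame(chrom = base$chrom[idx1], start = base$start[idx1],
                    end = base$end[idx1],
                    level = if (length(common)) rowMeans(lev) else double(),
                    cpg_density = if (length(common)) rowMeans(den) else double(),
                    n_replicates = length(replicates))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "stage") <- stage
  out
}

#' Mean methylation level of a methylome
#'
#' The sample- (or stage-) wide methylation level: the unweighted average of
#' its retained 100-bp tile levels.
#'
#' @param methylome A tile or stage methylome.
#' @return Scalar mean level.
#' @export
sample_mean_level <- function(methylome) {
  if (nrow(methylome) == 0) stop_premeth("methylome has no tiles")
  mean(methylome$level)
}

#' Methylation status fractions
#'
#' Fractions of levels that are low (< `low`), intermediate (in
#' `[low, high]`, boundaries inclusive) and high (> `high`).
#'
#' @param levels Numeric vector of methylation levels in \[0, 1\].
#' @param low,high Status boundaries (defaults 0.20 and 0.80).
#' @return Named numeric vector `(low, intermediate, high)` summing to 1.
#' @export
status_fractions <- function(levels, low = 0.20, high = 0.80) {
  levels <- levels[!is.na(levels)]
  if (length(levels) == 0) stop_premeth("status_fractions: no levels supplied")
  if (low >= high) stop_premeth("status_fractions: low must be < high")
  c(low = mean(levels < low),
    intermediate = mean(levels >= low & levels <= high),
    high = mean(levels > high))
}
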