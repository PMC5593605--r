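# Gene models, promoters, feature assignment of tiles, TSS meta-profiles and
# distribution comparisons between the lncRNA and protein-coding classes.

#' Load gene models from GTF or BED12
#'
#' Reads gene annotations and collapses transcripts to one model per gene,
#' keeping the TSS of the longest isoform. The TSS is the 5' end respecting
#' strand and the promoter is the 2-kb window centred on it
#' (`[TSS - flank, TSS + flank)`).
#'
#' @param path GTF (attributes `gene_id`, `transcript_id`, optionally
#'   `gene_class`) or BED12 file (name column = gene id).
#' @param class_label Gene class (`"lncRNA"` or `"coding"`) applied to all
#'   genes in the file; may be omitted for GTFs carrying a `gene_class`
#'   attribute.
#' @param promoter_flank Promoter half-width in bp (default 1000).
#' @return A `gene_models` object: list with `genes` (`gene_id`, `gene_class`,
#'   `chrom`, `strand`, `start`, `end`, `tss`, `promoter_start`,
#'   `promoter_end`; 0-based half-open) and `exons` (`gene_id`, `chrom`,
#'   `start`, `end`).
#' @export
load_genes <- function(path, class_label = NULL, promoter_flank = 1000) {
  if (!file.exists(path)) stop_premeth("annotation file not found: %s", path)
  is_gtf <- grepl("\\.(gtf|gff[23]?)$", path, ignore.case = TRUE)
  gr <- rtracklayer::import(path)
  if (is_gtf) {
    tx <- gr[tolower(as.character(gr$type)) == "transcript"]
    ex <- gr[tolower(as.character(gr$type)) == "exon"]
    if (length(tx) == 0) stop_premeth("%s: no transcript records", path)
    tx_df <- data.frame(
      gene_id = as.character(tx$gene_id),
      tx_id = as.character(tx$transcript_id),
      chrom = as.character(GenomicRanges::seqnames(tx)),
      strand = as.character(GenomicRanges::strand(tx)),
      start = GenomicRanges::start(tx) - 1L,
      end = GenomicRanges::end(tx))
    if (!is.null(tx$gene_class)) tx_df$gene_class <- as.character(tx$gene_class)
    ex_df <- data.frame(
      tx_id = as.character(ex$transcript_id),
      chrom = as.character(GenomicRanges::seqnames(ex)),
      start = GenomicRanges::start(ex) - 1L,
      end = GenomicRanges::end(ex))
  } else {
    # BED12: one row per transcript; blocks are the exons
    tx_df <- data.frame(
      gene_id = as.character(gr$name),
      tx_id = as.character(gr$name),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr))
    blocks <- gr$blocks
    ex_df <- do.call(rbind, lapply(seq_along(gr), function(i) {
      b <- blocks[[i]]
      data.frame(tx_id = tx_df$tx_id[i], chrom = tx_df$chrom[i],
                 start = tx_df$start[i] + (IRanges::start(b) - 1L),
                 end = tx_df$start[i] + IRanges::end(b))
    }))
  }
  bad <- !tx_df$strand %in% c("+", "-")
  if (any(bad)) {
    stop_premeth("unknown strand for gene(s): %s",
                 paste(unique(tx_df$gene_id[bad]), collapse = ", "))
  }
  # collapse transcripts: keep the longest isoform per gene
  tx_df$width <- tx_df$end - tx_df$start
  ord <- order(tx_df$gene_id, -tx_df$width)
  tx_df <- tx_df[ord, ]
  genes <- tx_df[!duplicated(tx_df$gene_id), , drop = FALSE]
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes$promoter_start <- genes$tss - as.integer(promoter_flank)
  genes$promoter_end <- genes$tss + as.integer(promoter_flank)
  if (is.null(genes$gene_class)) {
    if (is.null(class_label)) {
      stop_premeth("class_label required: %s carries no gene_class attribute",
                   path)
    }
    genes$gene_class <- class_label
  } else if (!is.null(class_label)) {
    genes$gene_class <- class_label
  }
  exons <- merge(ex_df, genes[c("tx_id", "gene_id")], by = "tx_id")
  exons <- exons[order(exons$gene_id, exons$start),
                 c("gene_id", "chrom", "start", "end")]
  genes <- genes[order(genes$chrom, genes$start),
                 c("gene_id", "gene_class", "chrom", "strand", "start", "end",
                   "tss", "promoter_start", "promoter_end")]
  rownames(genes) <- rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes (%s), %d exons\n", nrow(x$genes),
              paste(sprintf("%s=%d", names(table(x$genes$gene_class)),
                            table(x$genes$gene_class)), collapse = ", "),
              nrow(x$exons)))
  invisible(x)
}

#' Promoter / gene-body regions of gene models
#'
#' @param models A `gene_models` object.
#' @return `data.frame` `(gene_id, gene_class, chrom, start, end)`.
#' @export
promoters_of <- function(models) {
  g <- models$genes
  data.frame(gene_id = g$gene_id, gene_class = g$gene_class, chrom = g$chrom,
             start = g$promoter_start, end = g$promoter_end)
}

#' @rdname promoters_of
#' @export
gene_bodies_of <- function(models) {
  g <- models$genes
  data.frame(gene_id = g$gene_id, gene_class = g$gene_class, chrom = g$chrom,
             start = g$start, end = g$end)
}

#' Filter lncRNA genes distal to protein-coding genes
#'
#' Retains lncRNA genes whose gene body lies at least `min_dist` bp away from
#' every protein-coding gene body on the same chromosome (overlapping genes
#' have distance 0 and are dropped).
#'
#' @param lncrnas,codings `gene_models` objects.
#' @param min_dist Minimum gap in bp (default 1000).
#' @return A `gene_models` object containing the retained lncRNA genes.
#' @export
filter_distal_lncrna <- function(lncrnas, codings, min_dist = 1000) {
  lg <- lncrnas$genes
  cg <- codings$genes
  if (nrow(cg) == 0 || nrow(lg) == 0) return(lncrnas)
  # a chromosome with no coding gene yields no hit (its lncRNAs are kept);
  # the disjoint-seqlevels warning that raises is expected
  hits <- suppressWarnings(GenomicRanges::distanceToNearest(
    as_granges(data.frame(chrom = lg$chrom, start = lg$start, end = lg$end)),
    as_granges(data.frame(chrom = cg$chrom, start = cg$start, end = cg$end))))
  dist <- rep(Inf, nrow(lg))  # no coding gene on the chromosome -> kept
  dist[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  keep_ids <- lg$gene_id[dist >= min_dist]
  structure(list(genes = lg[lg$gene_id %in% keep_ids, , drop = FALSE],
                 exons = lncrnas$exons[lncrnas$exons$gene_id %in% keep_ids, ,
                                       drop = FALSE]),
            class = "gene_models")
}

#' Assign genomic feature labels to tiles
#'
#' A tile carries a feature label iff it overlaps the feature by at least one
#' bp (half-open coordinates); multiple labels are allowed. A tile is
#' `intergenic` when it overlaps none of the gene-derived features (all
#' supplied sets except `cgi`).
#'
#' @param tiles `data.frame` with `chrom`, `start`, `end`.
#' @param features Named list of interval `data.frame`s
#'   (`chrom`, `start`, `end`), e.g. `promoter`, `exon`, `intron`, `cgi`.
#' @return `tiles` with one logical column per feature plus `intergenic`.
#' @export
assign_tiles <- function(tiles, features) {
  stopifnot(is.list(features), length(features) > 0, !is.null(names(features)))
  out <- tiles
  for (nm in names(features)) {
    f <- features[[nm]]
    lab <- rep(FALSE, nrow(tiles))
    if (!is.null(f) && nrow(f) > 0) {
      hits <- interval_overlaps(tiles, f)
      lab[unique(S4Vectors::queryHits(hits))] <- TRUE
    }
    out[[nm]] <- lab
  }
  genic <- setdiff(names(features), "cgi")
  out$intergenic <- !Reduce(`|`, out[genic], init = rep(FALSE, nrow(tiles)))
  out
}

#' Mean methylation of regions
#'
#' The level of a region is the unweighted mean of the levels of the retained
#' tiles it overlaps; regions with no covered tile are reported as `NA`.
#'
#' @param methylome Tile or stage methylome.
#' @param regions `data.frame` with `chrom`, `start`, `end` (and optionally
#'   `gene_id`, carried through).
#' @return `regions` plus `level` and `n_tiles` columns.
#' @export
region_methylation <- function(methylome, regions) {
  out <- regions
  out$level <- NA_real_
  out$n_tiles <- 0L
  if (nrow(methylome) > 0 && nrow(regions) > 0) {
    hits <- interval_overlaps(regions, methylome)
    if (length(hits) > 0) {
      q <- S4Vectors::queryHits(hits)
      lev <- methylome$level[S4Vectors::subjectHits(hits)]
      agg <- rowsum(lev, q)
      n <- tabulate(factor(q, levels = sort(unique(q))))
      idx <- as.integer(rownames(agg))
      out$level[idx] <- agg[, 1] / n
      out$n_tiles[idx] <- n
    }
  }
  out
}

#' Strand-aware TSS meta-profile
#'
#' Averages a per-tile quantity (methylation level or CpG density) in
#' contiguous 100-bp bins around the TSS of each gene, 5 kb up- and
#' downstream, orienting minus-strand genes so that positive offsets are
#' downstream of the TSS. Each tile contributes to the bin containing its
#' midpoint.
#'
#' @param methylome Tile or stage methylome.
#' @param models `gene_models` object.
#' @param flank Distance from the TSS covered on each side (default 5000).
#' @param window Bin width in bp (default 100).
#' @param value Column of `methylome` to average (default `"level"`).
#' @return `data.frame` with `offset` (bin left edge relative to the TSS,
#'   downstream positive), `mean`, `n` (tiles contributing).
#' @export
tss_profile <- function(methylome, models, flank = 5000, window = 100,
                        value = "level") {
  genes <- models$genes
  if (nrow(genes) == 0) stop_premeth("tss_profile: no genes")
  offsets <- seq(-flank, flank - window, by = window)
  acc_sum <- acc_n <- numeric(length(offsets))
  mids <- methylome$start + (methylome$end - methylome$start) / 2
  vals <- methylome[[value]]
  for (i in seq_len(nrow(genes))) {
    sel <- methylome$chrom == genes$chrom[i]
    if (!any(sel)) next
    rel <- if (genes$strand[i] == "+") {
      mids[sel] - genes$tss[i]
    } else genes$tss[i] - mids[sel]
    bin <- floor(rel / window) * window
    ok <- bin >= -flank & bin <= flank - window
    if (!any(ok)) next
    idx <- match(bin[ok], offsets)
    rs <- rowsum(vals[sel][ok], idx)
    at <- as.integer(rownames(rs))
    acc_sum[at] <- acc_sum[at] + rs[, 1]
    acc_n[at] <- acc_n[at] + tabulate(idx, nbins = length(offsets))[at]
  }
  data.frame(offset = offsets,
             mean = ifelse(acc_n > 0, acc_sum / acc_n, NA_real_),
             n = as.integer(acc_n))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Two-sided two-sample K-S test with asymptotic p-value, used to compare TSS
#' methylation or CpG-density distributions between gene classes.
#'
#' @param values_a,values_b Numeric samples (each of length >= 2).
#' @return List with `statistic` (D) and `p.value`.
#' @export
ks_compare <- function(values_a, values_b) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop_premeth("ks_compare: both samples need n >= 2")
  }
  kt <- suppressWarnings(stats::ks.test(values_a, values_b, exact = FALSE))
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}
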