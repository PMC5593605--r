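# Gamete-specific DMR calling: threshold rule + per-tile replicate t-test
# with Benjamini-Hochberg correction, k-means clustering of developmental
# dynamics, annotation enrichment and parental-bias summaries.

#' Call gamete-specific DMRs
#'
#' Tests every 100-bp tile covered in all sperm and all oocyte replicates
#' with a two-sample pooled-variance Student's t-test on the replicate tile
#' levels, adjusts p-values across all tested tiles with Benjamini-Hochberg,
#' and calls a tile a G-DMR iff its mean level exceeds `hi` in one gamete,
#' falls below `lo` in the other, and its FDR q-value is below `fdr`.
#'
#' @param sperm_reps,oocyte_reps Lists (length >= 2) of replicate tile
#'   methylomes (see [tile_methylation()]).
#' @param hi Hypermethylation threshold in the specific gamete (default 0.75,
#'   exclusive).
#' @param lo Hypomethylation threshold in the other gamete (default 0.25,
#'   exclusive).
#' @param fdr BH q-value cutoff (default 0.05).
#' @return `data.frame` of called G-DMRs: `chrom`, `start`, `end`, `gamete`
#'   (`sperm`/`oocyte`), `mean_sperm`, `mean_oocyte`, `t`, `p`, `q`.
#'   Attribute `tested` holds the full per-tile test table.
#' @export
call_gdmrs <- function(sperm_reps, oocyte_reps, hi = 0.75, lo = 0.25,
                       fdr = 0.05) {
  if (length(sperm_reps) < 2 || length(oocyte_reps) < 2) {
    stop_premeth("call_gdmrs needs >= 2 replicates per gamete")
  }
  if (hi <= lo) stop_premeth("call_gdmrs: hi (%.2f) must exceed lo (%.2f)",
                             hi, lo)
  keys <- lapply(c(sperm_reps, oocyte_reps),
                 function(m) tile_key(m$chrom, m$start))
  common <- Reduce(intersect, keys)
  if (length(common) == 0) {
    stop_premeth("call_gdmrs: no tile covered in every replicate")
  }
  lev <- function(reps) {
    sapply(reps, function(m) m$level[match(common, tile_key(m$chrom, m$start))])
  }
  S <- lev(sperm_reps); O <- lev(oocyte_reps)
  if (length(common) == 1) { S <- t(S); O <- t(O) }
  n1 <- ncol(S); n2 <- ncol(O)
  m1 <- rowMeans(S); m2 <- rowMeans(O)
  v1 <- apply(S, 1, stats::var); v2 <- apply(O, 1, stats::var)
  df <- n1 + n2 - 2
  s2p <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(s2p * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df)
  # zero pooled variance: identical means are uninformative, distinct means
  # are a degenerate perfect separation
  zero <- se == 0
  p[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
  t[zero & p == 0] <- sign(m1[zero & p == 0] - m2[zero & p == 0]) * Inf
  q <- stats::p.adjust(p, method = "BH")
  base <- sperm_reps[[1]]
  idx <- match(common, keys[[1]])
  tested <- data.frame(chrom = base$chrom[idx], start = base$start[idx],
                       end = base$end[idx], mean_sperm = m1, mean_oocyte = m2,
                       t = t, p = p, q = q)
  tested$gamete <- ifelse(m1 > hi & m2 < lo, "sperm",
                          ifelse(m2 > hi & m1 < lo, "oocyte", NA_character_))
  tested <- tested[order(tested$chrom, tested$start), , drop = FALSE]
  rownames(tested) <- NULL
  calls <- tested[!is.na(tested$gamete) & tested$q < fdr,
                  c("chrom", "start", "end", "gamete", "mean_sperm",
                    "mean_oocyte", "t", "p", "q"), drop = FALSE]
  rownames(calls) <- NULL
  attr(calls, "tested") <- tested
  calls
}

#' Cluster DMR developmental dynamics with k-means
#'
#' Clusters per-DMR stage-trajectory vectors (Euclidean distance on raw
#' levels) into `k` dynamics. Missing stage values are imputed by the stage
#' mean over all DMRs. Clusters are relabelled in decreasing size order so
#' cluster 1 is always the largest.
#'
#' @param traj Numeric matrix, DMRs x stages.
#' @param k Number of clusters (default 6).
#' @param seed RNG seed making the assignment deterministic.
#' @param nstart Random restarts passed to [stats::kmeans()].
#' @return List with `cluster` (assignments), `centers` (k x stages),
#'   `sizes`, `tot_withinss`.
#' @export
cluster_dynamics <- function(traj, k = 6, seed = 1, nstart = 10) {
  traj <- as.matrix(traj)
  if (k < 2) stop_premeth("cluster_dynamics: k must be >= 2")
  if (nrow(traj) < k) {
    stop_premeth("cluster_dynamics: %d DMRs < k = %d", nrow(traj), k)
  }
  for (j in seq_len(ncol(traj))) {
    miss <- is.na(traj[, j])
    if (any(miss)) traj[miss, j] <- mean(traj[, j], na.rm = TRUE)
  }
  set.seed(seed)
  km <- stats::kmeans(traj, centers = k, nstart = nstart, iter.max = 100)
  ord <- order(-km$size, seq_len(k))
  relabel <- match(seq_len(k), ord)
  list(cluster = relabel[km$cluster],
       centers = km$centers[ord, , drop = FALSE],
       sizes = km$size[ord],
       tot_withinss = km$tot.withinss)
}

# Upper-tail hypergeometric probability P(X >= k) for overlap k out of a
# query of size n against K labelled elements in a universe of N.
hyper_upper_p <- function(k, K, n, N) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Annotation enrichment of a DMR set
#'
#' For each feature label, tests whether the DMR tiles overlap the label more
#' often than expected from the universe of tested tiles, with an upper-tail
#' hypergeometric test; BH correction across labels.
#'
#' @param dmrs `data.frame` of DMR tiles (`chrom`, `start`); must be a subset
#'   of the universe.
#' @param universe_labels Output of [assign_tiles()] on the universe tiles:
#'   `chrom`, `start`, `end` plus one logical column per label.
#' @param labels Label columns to test; defaults to all logical columns.
#' @return `data.frame` with `label`, `overlap`, `expected`, `p`, `q`.
#' @export
annotation_enrichment <- function(dmrs, universe_labels, labels = NULL) {
  if (nrow(universe_labels) == 0) stop_premeth("empty tile universe")
  if (is.null(labels)) {
    labels <- names(universe_labels)[vapply(universe_labels, is.logical,
                                            TRUE)]
  }
  ukey <- tile_key(universe_labels$chrom, universe_labels$start)
  dkey <- tile_key(dmrs$chrom, dmrs$start)
  if (!all(dkey %in% ukey)) {
    stop_premeth("annotation_enrichment: DMR set is not a subset of the universe")
  }
  N <- nrow(universe_labels)
  n <- length(dkey)
  in_dmr <- ukey %in% dkey
  res <- do.call(rbind, lapply(labels, function(lb) {
    K <- sum(universe_labels[[lb]])
    k <- sum(universe_labels[[lb]] & in_dmr)
    data.frame(label = lb, overlap = k, expected = n * K / N,
               p = hyper_upper_p(k, K, n, N))
  }))
  res$q <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Parental bias of DMRs by gene class
#'
#' Assigns DMRs to host genes by >= 1 bp overlap with the gene body or the
#' promoter, tabulates gamete of origin by gene class, and compares the two
#' classes with a Pearson chi-square test (no continuity correction). DMRs
#' overlapping genes of both classes are counted in both and flagged
#' ambiguous.
#'
#' @param dmrs Called G-DMRs (see [call_gdmrs()]), with a `gamete` column.
#' @param models `gene_models` object containing both gene classes.
#' @param region `"body"` or `"promoter"`: which gene region defines hosting.
#' @return List with `counts` (class x gamete table), `sperm_fraction` (per
#'   class), `chisq` (`statistic`, `p.value`), `n_ambiguous`.
#' @export
parental_bias <- function(dmrs, models, region = c("body", "promoter")) {
  region <- match.arg(region)
  regions <- if (region == "body") gene_bodies_of(models) else
    promoters_of(models)
  hits <- interval_overlaps(dmrs[c("chrom", "start", "end")], regions)
  q <- S4Vectors::queryHits(hits)
  cls <- regions$gene_class[S4Vectors::subjectHits(hits)]
  pairs <- unique(data.frame(dmr = q, class = cls,
                             gamete = dmrs$gamete[q]))
  n_amb <- length(unique(pairs$dmr[duplicated(pairs[c("dmr")]) |
                                   duplicated(pairs[c("dmr")],
                                              fromLast = TRUE)]))
  classes <- sort(unique(regions$gene_class))
  if (nrow(pairs) == 0 || length(unique(pairs$class)) < 2) {
    stop_premeth("parental_bias: need DMRs hosted in both gene classes")
  }
  counts <- table(factor(pairs$class, levels = classes),
                  factor(pairs$gamete, levels = c("sperm", "oocyte")))
  chis <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(counts = counts,
       sperm_fraction = counts[, "sperm"] / rowSums(counts),
       chisq = list(statistic = unname(chis$statistic),
                    p.value = chis$p.value),
       n_ambiguous = n_amb)
}
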