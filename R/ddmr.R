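# Developmental-specific DMRs: Shannon-entropy specificity of stage
# methylation profiles. A tile whose methylation is concentrated in few
# stages has low entropy; tiles below the entropy threshold are called.

#' Shannon-entropy methylation specificity
#'
#' Normalises a stage methylation vector to pseudo-probabilities
#' `p_s = (m_s + epsilon) / sum(m_t + epsilon)` and computes
#' `H = -sum(p_s * log2(p_s))` in bits. Hypomethylation specificity (low in
#' few stages, high elsewhere) is captured by also scoring the reflected
#' vector `m' = (max(m) + min(m)) - m` and taking the minimum of the two
#' entropies; the orientation achieving the minimum is recorded as the
#' direction (`hyper` when the raw orientation wins).
#'
#' @param m Numeric vector of stage methylation levels in \[0, 1\] (length
#'   >= 2), or a matrix with one tile per row.
#' @param epsilon Pseudo-level avoiding log(0) (default 1e-3). All-zero
#'   vectors therefore score maximum entropy and are never called.
#' @return For a vector: list with `H`, `H_raw`, `H_reflected`, `direction`.
#'   For a matrix: `data.frame` with those columns, one row per tile.
#' @export
methylation_entropy <- function(m, epsilon = 1e-3) {
  vec <- is.null(dim(m))
  M <- if (vec) matrix(m, nrow = 1) else as.matrix(m)
  if (ncol(M) < 2) stop_premeth("methylation_entropy: need >= 2 stages")
  if (anyNA(M) || any(M < 0) || any(M > 1)) {
    stop_premeth("methylation_entropy: levels must be in [0, 1] and non-missing")
  }
  ent <- function(X) {
    P <- (X + epsilon) / rowSums(X + epsilon)
    -rowSums(P * log2(P))
  }
  h_raw <- ent(M)
  refl <- (apply(M, 1, max) + apply(M, 1, min)) - M
  h_ref <- ent(refl)
  h <- pmin(h_raw, h_ref)
  dir <- ifelse(h_raw <= h_ref, "hyper", "hypo")
  if (vec) {
    list(H = h[1], H_raw = h_raw[1], H_reflected = h_ref[1],
         direction = dir[1])
  } else {
    data.frame(H = h, H_raw = h_raw, H_reflected = h_ref, direction = dir)
  }
}

#' Call developmental-specific DMRs
#'
#' Scores every tile covered in all stages with [methylation_entropy()] and
#' calls tiles whose entropy falls below the threshold. The default
#' threshold 4.22 bits is defined for profiles over `reference_n = 32`
#' samples (maximum entropy log2(32) = 5 bits); for other profile widths it
#' is rescaled proportionally to the attainable maximum, with a message.
#'
#' @param stage_levels `data.frame` with `chrom`, `start`, `end` and one
#'   numeric column per stage (see [stage_level_matrix()]), or a plain
#'   numeric matrix of stage levels.
#' @param threshold Entropy threshold in bits at the reference width
#'   (default 4.22).
#' @param reference_n Profile width at which `threshold` is defined
#'   (default 32).
#' @param epsilon Pseudo-level passed to [methylation_entropy()].
#' @return `data.frame` of called tiles with the stage columns plus `H` and
#'   `direction`. Attributes: `threshold_used`, `n_excluded` (tiles dropped
#'   for missing stages), `tested` (full scored table).
#' @export
call_ddmrs <- function(stage_levels, threshold = 4.22, reference_n = 32,
                       epsilon = 1e-3) {
  df <- as.data.frame(stage_levels)
  coord_cols <- intersect(c("chrom", "start", "end"), names(df))
  stage_cols <- setdiff(names(df), coord_cols)
  M <- as.matrix(df[stage_cols])
  S <- ncol(M)
  thr <- threshold
  if (S != reference_n) {
    thr <- threshold * log2(S) / log2(reference_n)
    message(sprintf(
      "call_ddmrs: %d stages differ from the reference width %d; threshold rescaled to %.3f bits",
      S, reference_n, thr))
  }
  if (thr >= log2(S)) {
    warning(sprintf(
      "entropy threshold %.3f >= attainable maximum log2(%d) = %.3f; every tile would be called",
      thr, S, log2(S)), call. = FALSE)
  }
  complete <- stats::complete.cases(M)
  n_excl <- sum(!complete)
  if (n_excl > 0) {
    message(sprintf("call_ddmrs: %d tile(s) excluded for missing stage values",
                    n_excl))
  }
  df <- df[complete, , drop = FALSE]
  ent <- methylation_entropy(M[complete, , drop = FALSE], epsilon = epsilon)
  tested <- cbind(df, ent[c("H", "direction")])
  rownames(tested) <- NULL
  calls <- tested[tested$H < thr, , drop = FALSE]
  rownames(calls) <- NULL
  attr(calls, "threshold_used") <- thr
  attr(calls, "n_excluded") <- n_excl
  attr(calls, "tested") <- tested
  calls
}

#' Stage-level tile matrix
#'
#' Joins stage methylomes on the tiles covered in every stage into one table
#' suitable for [call_ddmrs()] and [cluster_dynamics()].
#'
#' @param stage_methylomes Named list of stage methylomes
#'   (see [stage_average()]); names are the stage labels.
#' @param all_stages If `FALSE`, keep tiles missing in some stages (filled
#'   with `NA`) instead of intersecting.
#' @return `data.frame` `chrom`, `start`, `end` plus one level column per
#'   stage.
#' @export
stage_level_matrix <- function(stage_methylomes, all_stages = TRUE) {
  stopifnot(length(stage_methylomes) >= 1, !is.null(names(stage_methylomes)))
  keys <- lapply(stage_methylomes, function(m) tile_key(m$chrom, m$start))
  all_keys <- if (all_stages) Reduce(intersect, keys) else
    Reduce(union, keys)
  pool <- do.call(rbind, lapply(stage_methylomes,
                                function(m) m[c("chrom", "start", "end")]))
  pool <- pool[!duplicated(tile_key(pool$chrom, pool$start)), , drop = FALSE]
  out <- pool[match(all_keys, tile_key(pool$chrom, pool$start)), ,
              drop = FALSE]
  for (i in seq_along(stage_methylomes)) {
    m <- stage_methylomes[[i]]
    out[[names(stage_methylomes)[i]]] <- m$level[match(all_keys, keys[[i]])]
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene-class summary of D-DMRs
#'
#' For the gene-body and promoter regions separately, counts the genes of
#' each class hosting at least one D-DMR (>= 1 bp overlap), reports each
#' class's share of the DMR-hosting genes, and compares hosting rates between
#' classes with a Pearson chi-square test.
#'
#' @param ddmrs Called D-DMRs (`chrom`, `start`, `end`).
#' @param models `gene_models` with both classes.
#' @return List with `summary` (`data.frame`: region, class, n_genes,
#'   n_host, host_fraction, share_of_hosts) and `chisq` (per region). Both
#'   empty when no D-DMRs are supplied.
#' @export
ddmr_class_summary <- function(ddmrs, models) {
  if (is.null(ddmrs) || nrow(ddmrs) == 0) {
    return(list(summary = data.frame(), chisq = list()))
  }
  out <- list(); tests <- list()
  for (region in c("body", "promoter")) {
    regions <- if (region == "body") gene_bodies_of(models) else
      promoters_of(models)
    hits <- interval_overlaps(ddmrs[c("chrom", "start", "end")], regions)
    host <- unique(S4Vectors::subjectHits(hits))
    regions$hosts <- seq_len(nrow(regions)) %in% host
    tab <- table(regions$gene_class, regions$hosts)
    n_host <- tapply(regions$hosts, regions$gene_class, sum)
    n_gene <- tapply(regions$hosts, regions$gene_class, length)
    out[[region]] <- data.frame(
      region = region, class = names(n_host),
      n_genes = as.integer(n_gene), n_host = as.integer(n_host),
      host_fraction = as.numeric(n_host / n_gene),
      share_of_hosts = as.numeric(n_host / sum(n_host)))
    tests[[region]] <- if (ncol(tab) == 2 && all(rowSums(tab) > 0)) {
      # small desk-scale counts: the asymptotic-approximation warning is expected
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      list(statistic = unname(ct$statistic), p.value = ct$p.value)
    } else NULL
  }
  list(summary = do.call(rbind, out), chisq = tests)
}
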