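# Coding-noncoding co-expression network: expression filtering, all-pairs
# Pearson correlation with Fisher-asymptotic p-values, seeding by promoter
# D-DMR genes, topology, and generic hypergeometric gene-set enrichment.

#' Filter genes by expression level and variance
#'
#' Keeps genes whose maximal FPKM over samples exceeds `min_max_expr` and
#' whose expression variance (on the `log2(FPKM + 1)` scale) ranks in the
#' retained top fraction. The default keeps the 75% most-variable genes; set
#' `var_keep_fraction = 0.25` for the stricter top-quartile reading.
#'
#' @param exprset An `expression_set` or plain FPKM matrix.
#' @param min_max_expr Minimum of the per-gene maximum FPKM (default 5,
#'   exclusive).
#' @param var_keep_fraction Fraction of most-variable genes retained
#'   (default 0.75).
#' @return Character vector of retained gene ids.
#' @export
filter_expressed_genes <- function(exprset, min_max_expr = 5,
                                   var_keep_fraction = 0.75) {
  expr <- if (inherits(exprset, "expression_set")) exprset$expr else exprset
  if (nrow(expr) == 0) stop_premeth("empty expression matrix")
  v <- apply(log2(expr + 1), 1, stats::var)
  keep <- apply(expr, 1, max) > min_max_expr &
    v >= stats::quantile(v, 1 - var_keep_fraction)
  out <- rownames(expr)[keep]
  if (length(out) == 0) {
    stop_premeth("no gene survives min_max_expr = %g / var_keep_fraction = %g; lower the thresholds",
                 min_max_expr, var_keep_fraction)
  }
  out
}

#' All-pairs Pearson correlation with Fisher-asymptotic p-values
#'
#' Computes the Pearson correlation for every gene pair across samples (on
#' the `log2(FPKM + 1)` scale) and its two-sided p-value from Fisher's
#' asymptotic test: `t = r * sqrt(n - 2) / sqrt(1 - r^2)` referred to a t
#' distribution with `n - 2` degrees of freedom. Pairs involving a constant
#' gene are reported with missing `r` and `p`.
#'
#' @param exprset An `expression_set` or FPKM matrix.
#' @param genes Optional subset of gene ids (e.g. from
#'   [filter_expressed_genes()]).
#' @param log_transform Apply `log2(x + 1)` before correlating
#'   (default `TRUE`).
#' @return `data.frame` with `gene_a`, `gene_b` (`gene_a < gene_b`), `r`,
#'   `p`; attribute `n_samples`.
#' @export
pair_correlations <- function(exprset, genes = NULL, log_transform = TRUE) {
  expr <- if (inherits(exprset, "expression_set")) exprset$expr else exprset
  if (!is.null(genes)) expr <- expr[rownames(expr) %in% genes, , drop = FALSE]
  n <- ncol(expr)
  if (n < 4) stop_premeth("pair_correlations: need >= 4 samples, got %d", n)
  if (nrow(expr) < 2) stop_premeth("pair_correlations: need >= 2 genes")
  x <- if (log_transform) log2(expr + 1) else expr
  cm <- suppressWarnings(stats::cor(t(x)))
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  r <- cm[idx]
  t <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(t), n - 2)
  p[abs(r) >= 1] <- 0  # perfect correlation: limit of the t tail
  out <- data.frame(gene_a = rownames(x)[idx[, 1]],
                    gene_b = rownames(x)[idx[, 2]], r = r, p = p)
  swap <- out$gene_a > out$gene_b
  tmp <- out$gene_a[swap]
  out$gene_a[swap] <- out$gene_b[swap]
  out$gene_b[swap] <- tmp
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_samples") <- n
  out
}

#' Build the coding-noncoding co-expression network
#'
#' Retains the gene pairs with `|r| > r_min` and `p < p_max` in which at
#' least one endpoint belongs to the seed set (genes whose promoter hosts a
#' developmental-specific DMR).
#'
#' @param pairs Pair table from [pair_correlations()].
#' @param seed_genes Non-empty character vector of seed gene ids.
#' @param r_min Correlation gate (default 0.8, exclusive).
#' @param p_max p-value gate (default 0.05, exclusive).
#' @param models Optional `gene_models` used to type the nodes.
#' @return A `cnc_network`: list with `edges` (`gene_a`, `gene_b`, `r`, `p`,
#'   `seeded_a`, `seeded_b`) and `nodes` (`gene`, `seeded`, optionally
#'   `gene_class`).
#' @export
build_network <- function(pairs, seed_genes, r_min = 0.8, p_max = 0.05,
                          models = NULL) {
  if (length(seed_genes) == 0) stop_premeth("build_network: empty seed set")
  keep <- !is.na(pairs$r) & abs(pairs$r) > r_min & pairs$p < p_max &
    (pairs$gene_a %in% seed_genes | pairs$gene_b %in% seed_genes)
  edges <- pairs[keep, , drop = FALSE]
  if (nrow(edges) == 0) {
    warning("no gene pair passes the correlation, p-value and seed gates",
            call. = FALSE)
  }
  edges$seeded_a <- edges$gene_a %in% seed_genes
  edges$seeded_b <- edges$gene_b %in% seed_genes
  rownames(edges) <- NULL
  nodes <- data.frame(gene = unique(c(edges$gene_a, edges$gene_b)))
  nodes$seeded <- nodes$gene %in% seed_genes
  if (!is.null(models)) {
    nodes$gene_class <- models$genes$gene_class[match(nodes$gene,
                                                      models$genes$gene_id)]
  }
  structure(list(edges = edges, nodes = nodes,
                 r_min = r_min, p_max = p_max), class = "cnc_network")
}

#' @export
print.cnc_network <- function(x, ...) {
  cat(sprintf("cnc_network: %d nodes, %d edges (|r| > %g, p < %g)\n",
              nrow(x$nodes), nrow(x$edges), x$r_min, x$p_max))
  invisible(x)
}

#' Topology of a co-expression network
#'
#' @param network A `cnc_network`.
#' @param hub_quantile Degree quantile above which a node is a hub
#'   (default 0.95, i.e. top 5%).
#' @return List with `degrees` (`gene`, `degree`, sorted decreasing),
#'   `hubs` (gene ids), `component_sizes` (decreasing).
#' @export
network_topology <- function(network, hub_quantile = 0.95) {
  if (nrow(network$edges) == 0) {
    return(list(degrees = data.frame(gene = character(), degree = integer()),
                hubs = character(), component_sizes = integer()))
  }
  g <- igraph::graph_from_data_frame(network$edges[c("gene_a", "gene_b")],
                                     directed = FALSE,
                                     vertices = network$nodes$gene)
  deg <- igraph::degree(g)
  degrees <- data.frame(gene = names(deg), degree = as.integer(deg))
  degrees <- degrees[order(-degrees$degree, degrees$gene), , drop = FALSE]
  rownames(degrees) <- NULL
  cut <- max(stats::quantile(degrees$degree, hub_quantile), 1)
  hubs <- degrees$gene[degrees$degree >= cut]
  comp <- igraph::components(g)
  list(degrees = degrees, hubs = hubs,
       component_sizes = sort(as.integer(comp$csize), decreasing = TRUE))
}

#' Hypergeometric gene-set enrichment
#'
#' For every annotation term, tests over-representation of the query genes
#' with an upper-tail hypergeometric test against the universe, applies BH
#' correction across terms, and reports fold enrichment
#' `(k / n) / (K / N)`.
#'
#' @param query_genes Character vector, a subset of `universe`.
#' @param term_table `data.frame` with columns `term` and `gene`.
#' @param universe Character vector of background gene ids.
#' @return `data.frame` with `term`, `k` (overlap), `K` (term size in
#'   universe), `n` (query size), `N` (universe size), `fold`, `p`, `q`,
#'   sorted by `p`. Terms with no gene in the universe are skipped with a
#'   message.
#' @export
geneset_enrichment <- function(query_genes, term_table, universe) {
  if (nrow(term_table) == 0) stop_premeth("empty term table")
  if (!all(query_genes %in% universe)) {
    stop_premeth("query genes outside the universe: %s",
                 paste(utils::head(setdiff(query_genes, universe), 5),
                       collapse = ", "))
  }
  N <- length(unique(universe))
  n <- length(unique(query_genes))
  terms <- split(term_table$gene, term_table$term)
  res <- lapply(names(terms), function(tm) {
    tg <- intersect(unique(terms[[tm]]), universe)
    K <- length(tg)
    if (K == 0) return(NULL)
    k <- length(intersect(tg, query_genes))
    data.frame(term = tm, k = k, K = K, n = n, N = N,
               fold = if (n > 0) (k / n) / (K / N) else NA_real_,
               p = hyper_upper_p(k, K, n, N))
  })
  skipped <- sum(vapply(res, is.null, TRUE))
  if (skipped > 0) {
    message(sprintf("geneset_enrichment: %d term(s) with no universe gene skipped",
                    skipped))
  }
  out <- do.call(rbind, res)
  if (is.null(out)) stop_premeth("no term overlaps the universe")
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
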