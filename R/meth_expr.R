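# Per-stage correlation of promoter / gene-body methylation with expression.

#' Load a gene x sample expression matrix
#'
#' @param path TSV with a header row of sample ids; first column = gene ids.
#' @param sample_map Named character vector or `data.frame(sample, stage)`
#'   mapping every sample to its developmental stage.
#' @return An `expression_set`: list with `expr` (numeric matrix, genes x
#'   samples, FPKM) and `stages` (named by sample).
#' @export
load_expression <- function(path, sample_map) {
  if (!file.exists(path)) stop_premeth("expression file not found: %s", path)
  tab <- utils::read.delim(path, check.names = FALSE)
  genes <- as.character(tab[[1]])
  if (anyDuplicated(genes)) {
    stop_premeth("duplicated gene id(s): %s",
                 paste(utils::head(unique(genes[duplicated(genes)]), 5),
                       collapse = ", "))
  }
  expr <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(expr)) stop_premeth("%s: non-numeric expression values", path)
  if (any(expr < 0, na.rm = TRUE)) {
    stop_premeth("%s: negative expression values", path)
  }
  rownames(expr) <- genes
  if (is.data.frame(sample_map)) {
    sample_map <- stats::setNames(as.character(sample_map$stage),
                                  sample_map$sample)
  }
  missing <- setdiff(colnames(expr), names(sample_map))
  if (length(missing)) {
    stop_premeth("sample(s) missing from the stage map: %s",
                 paste(missing, collapse = ", "))
  }
  structure(list(expr = expr, stages = sample_map[colnames(expr)]),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("expression_set: %d genes x %d samples, %d stages\n",
              nrow(x$expr), ncol(x$expr), length(unique(x$stages))))
  invisible(x)
}

#' Per-gene region methylation across stages
#'
#' Convenience wrapper: applies [region_methylation()] per stage methylome
#' and returns a gene x stage level table.
#'
#' @param stage_methylomes Named list of stage methylomes.
#' @param regions `data.frame` with `gene_id`, `chrom`, `start`, `end`
#'   (see [promoters_of()] / [gene_bodies_of()]).
#' @return `data.frame`: `gene_id` plus one level column per stage
#'   (`NA` where the region has no covered tile).
#' @export
region_level_matrix <- function(stage_methylomes, regions) {
  out <- data.frame(gene_id = regions$gene_id)
  for (st in names(stage_methylomes)) {
    out[[st]] <- region_methylation(stage_methylomes[[st]], regions)$level
  }
  out
}

#' Per-stage methylation-expression correlation
#'
#' For every stage, computes the Pearson correlation across genes between
#' the region methylation level and expression, where stage expression is
#' the mean of `log2(FPKM + 1)` over that stage's samples. Stages with fewer
#' than `min_genes` complete gene pairs, or with a constant vector on either
#' side, are reported with an `NA` correlation and a reason.
#'
#' @param region_levels Gene x stage methylation table
#'   (see [region_level_matrix()]).
#' @param exprset An `expression_set` (see [load_expression()]).
#' @param min_genes Minimum complete pairs per stage (default 3).
#' @return `data.frame` with `stage`, `n`, `r`, `p`, `note`.
#' @export
meth_expr_correlation <- function(region_levels, exprset, min_genes = 3) {
  logx <- log2(exprset$expr + 1)
  stages <- intersect(setdiff(names(region_levels), "gene_id"),
                      unique(exprset$stages))
  shared <- intersect(region_levels$gene_id, rownames(logx))
  res <- lapply(stages, function(st) {
    x <- region_levels[[st]][match(shared, region_levels$gene_id)]
    y <- rowMeans(logx[shared, exprset$stages == st, drop = FALSE])
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_genes) {
      return(data.frame(stage = st, n = sum(ok), r = NA_real_, p = NA_real_,
                        note = sprintf("fewer than %d genes", min_genes)))
    }
    x <- x[ok]; y <- y[ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(stage = st, n = length(x), r = NA_real_,
                        p = NA_real_, note = "constant vector"))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(stage = st, n = length(x), r = unname(ct$estimate),
               p = ct$p.value, note = "")
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
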