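# Shared fixtures, built once per test session and reused across files.

.fixture_env <- new.env()

# Default synthetic dataset (the study conditions, seed 1).
demo_dataset <- function() {
  if (is.null(.fixture_env$ds)) {
    .fixture_env$ds <- simulate_dataset(sim_config(seed = 1))
  }
  .fixture_env$ds
}

# Full pipeline run on the default dataset.
demo_run <- function() {
  if (is.null(.fixture_env$run)) {
    dir <- file.path(tempdir(), "premeth-demo-run")
    .fixture_env$run <- suppressMessages(suppressWarnings(
      run_pipeline(pipeline_config(out_dir = dir, seed = 1))))
  }
  .fixture_env$run
}

# Build a cpg_counts object in code.
make_counts <- function(chrom, pos, meth, unmeth, sample_id = "s1") {
  df <- data.frame(chrom = chrom, pos = as.integer(pos),
                   meth = as.integer(meth), unmeth = as.integer(unmeth))
  df <- df[order(df$chrom, df$pos), ]
  rownames(df) <- NULL
  attr(df, "sample_id") <- sample_id
  class(df) <- c("cpg_counts", "data.frame")
  df
}

# Minimal tile methylome from vectors.
make_tiles <- function(chrom, start, level, cpg_density = 1) {
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start + 100L), level = level,
             pooled_meth = NA_integer_, pooled_total = NA_integer_,
             n_cpgs = 1L, cpg_density = cpg_density)
}

# Hand-built gene_models object.
make_models <- function(gene_id, gene_class, chrom, strand, start, end) {
  genes <- data.frame(gene_id = gene_id, gene_class = gene_class,
                      chrom = chrom, strand = strand,
                      start = as.integer(start), end = as.integer(end))
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes$promoter_start <- genes$tss - 1000L
  genes$promoter_end <- genes$tss + 1000L
  exons <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                      start = genes$start, end = genes$end)
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

# Exhaustive upper-tail hypergeometric probability by enumeration.
enum_hyper_upper <- function(k, K, n, N) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}
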