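# Fixture serialization: writes a simulated dataset to the standard file
# formats the pipeline consumes (Bismark coverage, GTF2.2, BED12, BED3,
# expression TSV, ground-truth TSVs, JSON manifest) and reads them back.

write_tsv <- function(df, path, col.names = TRUE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = col.names)
}

# Bismark coverage dialect: 1-based inclusive, percent = 100 * M / (M + U).
write_bismark_cov <- function(counts, path) {
  pct <- round(100 * counts$meth / (counts$meth + counts$unmeth), 6)
  write_tsv(data.frame(counts$chrom, counts$pos + 1L, counts$pos + 1L, pct,
                       counts$meth, counts$unmeth),
            path, col.names = FALSE)
}

write_gtf <- function(models, path) {
  g <- models$genes
  ex <- models$exons
  lines <- character()
  for (i in seq_len(nrow(g))) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s.t1"; gene_class "%s";',
                     g$gene_id[i], g$gene_id[i], g$gene_class[i])
    lines <- c(lines, paste(g$chrom[i], "premeth", "transcript",
                            g$start[i] + 1L, g$end[i], ".", g$strand[i], ".",
                            attrs, sep = "\t"))
    e <- ex[ex$gene_id == g$gene_id[i], , drop = FALSE]
    for (j in seq_len(nrow(e))) {
      lines <- c(lines, paste(e$chrom[j], "premeth", "exon", e$start[j] + 1L,
                              e$end[j], ".", g$strand[i], ".", attrs,
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
}

write_bed12 <- function(models, path) {
  g <- models$genes
  rows <- vapply(seq_len(nrow(g)), function(i) {
    e <- models$exons[models$exons$gene_id == g$gene_id[i], , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    paste(g$chrom[i], g$start[i], g$end[i], g$gene_id[i], 0, g$strand[i],
          g$start[i], g$end[i], "0", nrow(e),
          paste0(paste(e$end - e$start, collapse = ","), ","),
          paste0(paste(e$start - g$start[i], collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(rows, path)
}

#' Write a simulated dataset to disk
#'
#' Serializes a [simulate_dataset()] result: one Bismark coverage file per
#' RRBS sample, the gene annotation as GTF and per-class BED12, feature BED3
#' files (CGIs, exons, introns), the expression TSV, the sample table, the
#' ground-truth tables and a JSON manifest holding the full configuration
#' (seed included).
#'
#' @param dataset A `sim_dataset`.
#' @param out_dir Output directory (created, recursively).
#' @return Invisibly, the directory path.
#' @export
write_fixture <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  for (d in file.path(out_dir, c("coverage", "annotation", "expression",
                                 "truth"))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  if (!dir.exists(out_dir)) stop_premeth("cannot create directory %s", out_dir)
  for (nm in names(dataset$methylomes$counts)) {
    write_bismark_cov(dataset$methylomes$counts[[nm]],
                      file.path(out_dir, "coverage", paste0(nm, ".cov")))
  }
  ann <- dataset$annotation
  write_gtf(ann$models, file.path(out_dir, "annotation", "genes.gtf"))
  for (cl in unique(ann$models$genes$gene_class)) {
    sub <- structure(list(
      genes = ann$models$genes[ann$models$genes$gene_class == cl, ],
      exons = ann$models$exons[ann$models$exons$gene_id %in%
        ann$models$genes$gene_id[ann$models$genes$gene_class == cl], ]),
      class = "gene_models")
    write_bed12(sub, file.path(out_dir, "annotation",
                               paste0(tolower(cl), ".bed")))
  }
  write_tsv(ann$cgis[c("chrom", "start", "end")],
            file.path(out_dir, "annotation", "cgi.bed"), col.names = FALSE)
  write_tsv(ann$models$exons[c("chrom", "start", "end")],
            file.path(out_dir, "annotation", "exons.bed"), col.names = FALSE)
  write_tsv(ann$introns[c("chrom", "start", "end")],
            file.path(out_dir, "annotation", "introns.bed"), col.names = FALSE)
  expr <- as.data.frame(dataset$expression$expr)
  expr <- cbind(gene_id = rownames(expr), expr)
  write_tsv(expr, file.path(out_dir, "expression", "expression.tsv"))
  samples <- rbind(
    cbind(dataset$methylomes$samples[c("sample", "stage")], assay = "rrbs"),
    cbind(dataset$expression$samples[c("sample", "stage")], assay = "rna"))
  write_tsv(samples, file.path(out_dir, "samples.tsv"))
  tr <- dataset$truth
  write_tsv(tr$gdmrs, file.path(out_dir, "truth", "gdmrs.tsv"))
  write_tsv(tr$ddmrs, file.path(out_dir, "truth", "ddmrs.tsv"))
  if (!is.null(tr$modules)) {
    write_tsv(tr$modules, file.path(out_dir, "truth", "modules.tsv"))
  }
  write_tsv(tr$coupling, file.path(out_dir, "truth", "coupling.tsv"))
  cfg <- unclass(dataset$config)
  cfg$chrom_sizes <- as.list(cfg$chrom_sizes)
  cfg$stage_trajectory <- as.list(cfg$stage_trajectory)
  jsonlite::write_json(list(format = "premeth-fixture", version = 1L,
                            seed = dataset$config$seed, config = cfg),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

read_bed3 <- function(path) {
  if (!file.exists(path) || file.size(path) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  }
  df <- utils::read.table(path, sep = "\t",
                          col.names = c("chrom", "start", "end"),
                          colClasses = c("character", "integer", "integer"))
  df
}

#' Load a fixture directory
#'
#' Reads back everything [write_fixture()] wrote, through the same readers
#' the pipeline uses on real data ([load_coverage()], [load_genes()],
#' [load_expression()]).
#'
#' @param dir Fixture directory.
#' @return List with `manifest`, `samples`, `counts` (named list of
#'   `cpg_counts`), `models` (`gene_models`), `features` (named list of
#'   interval `data.frame`s), `exprset` (`expression_set`) and `truth`
#'   (list of ground-truth tables, or `NULL` when absent).
#' @export
load_fixture <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop_premeth("no manifest.json in %s", dir)
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  samples <- utils::read.delim(file.path(dir, "samples.tsv"))
  rrbs <- samples[samples$assay == "rrbs", , drop = FALSE]
  counts <- lapply(rrbs$sample, function(nm) {
    load_coverage(file.path(dir, "coverage", paste0(nm, ".cov")),
                  sample_id = nm)
  })
  names(counts) <- rrbs$sample
  models <- load_genes(file.path(dir, "annotation", "genes.gtf"))
  features <- list(
    promoter = promoters_of(models)[c("chrom", "start", "end")],
    exon = read_bed3(file.path(dir, "annotation", "exons.bed")),
    intron = read_bed3(file.path(dir, "annotation", "introns.bed")),
    cgi = read_bed3(file.path(dir, "annotation", "cgi.bed")))
  rna <- samples[samples$assay == "rna", , drop = FALSE]
  exprset <- load_expression(file.path(dir, "expression", "expression.tsv"),
                             stats::setNames(rna$stage, rna$sample))
  truth_dir <- file.path(dir, "truth")
  truth <- NULL
  if (dir.exists(truth_dir)) {
    read_truth <- function(nm) {
      p <- file.path(truth_dir, nm)
      if (file.exists(p)) utils::read.delim(p) else NULL
    }
    truth <- list(gdmrs = read_truth("gdmrs.tsv"),
                  ddmrs = read_truth("ddmrs.tsv"),
                  modules = read_truth("modules.tsv"),
                  coupling = read_truth("coupling.tsv"))
  }
  list(manifest = manifest, samples = samples, counts = counts,
       models = models, features = features, exprset = exprset,
       truth = truth)
}
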