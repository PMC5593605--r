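# Gene models, promoters, tile feature assignment, TSS profiles, K-S.

test_that("TSS and promoter respect strand; GTF and BED12 readers agree", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "src", "transcript", 1001, 3000, ".", "-", ".",
          'gene_id "gA"; transcript_id "gA.t1";', sep = "\t"),
    paste("chr1", "src", "exon", 1001, 3000, ".", "-", ".",
          'gene_id "gA"; transcript_id "gA.t1";', sep = "\t"),
    paste("chr1", "src", "transcript", 5001, 7000, ".", "+", ".",
          'gene_id "gB"; transcript_id "gB.t1";', sep = "\t"),
    paste("chr1", "src", "exon", 5001, 7000, ".", "+", ".",
          'gene_id "gB"; transcript_id "gB.t1";', sep = "\t")), gtf)
  m <- load_genes(gtf, class_label = "coding")
  gA <- m$genes[m$genes$gene_id == "gA", ]
  expect_equal(gA$tss, 3000L)                     # minus strand: 5' = end
  expect_equal(c(gA$promoter_start, gA$promoter_end), c(2000L, 4000L))
  gB <- m$genes[m$genes$gene_id == "gB", ]
  expect_equal(gB$tss, 5000L)
  expect_equal(c(gB$promoter_start, gB$promoter_end), c(4000L, 6000L))
  expect_true(all(m$genes$promoter_end - m$genes$promoter_start == 2000L))

  # reader equivalence on the generated fixture
  ds <- demo_dataset()
  d <- tempfile()
  write_fixture(ds, d)
  from_gtf <- load_genes(file.path(d, "annotation", "genes.gtf"))
  from_bed <- load_genes(file.path(d, "annotation", "coding.bed"),
                         class_label = "coding")
  cod <- from_gtf$genes[from_gtf$genes$gene_class == "coding", ]
  rownames(cod) <- NULL
  expect_equal(from_bed$genes, cod[names(from_bed$genes)])

  bad <- tempfile(fileext = ".gtf")
  writeLines(paste("chr1", "src", "transcript", 1, 10, ".", "*", ".",
                   'gene_id "gX"; transcript_id "gX.t1";', sep = "\t"), bad)
  expect_error(load_genes(bad, "coding"), "unknown strand.*gX")
})

test_that("distal lncRNA filter matches an all-pairs brute force", {
  lnc <- make_models(paste0("l", 1:3), "lncRNA", "chr1", "+",
                     c(100, 5000, 20000), c(600, 5400, 21000))
  cod <- make_models(paste0("c", 1:2), "coding", "chr1", "+",
                     c(1000, 30000), c(2000, 31000))
  kept <- filter_distal_lncrna(lnc, cod, min_dist = 1000)
  # l1 ends 600, coding starts 1000 -> gap 400 < 1kb: dropped
  expect_setequal(kept$genes$gene_id, c("l2", "l3"))
  solo <- make_models("l9", "lncRNA", "chr9", "+", 100, 500)
  expect_equal(filter_distal_lncrna(solo, cod)$genes$gene_id, "l9")

  # oracle on the generated annotation
  ds <- demo_dataset()
  g <- ds$annotation$models$genes
  sub <- function(cl) {
    ids <- g$gene_id[g$gene_class == cl]
    structure(list(genes = g[g$gene_id %in% ids, ],
                   exons = ds$annotation$models$exons[
                     ds$annotation$models$exons$gene_id %in% ids, ]),
              class = "gene_models")
  }
  got <- filter_distal_lncrna(sub("lncRNA"), sub("coding"))$genes$gene_id
  lg <- g[g$gene_class == "lncRNA", ]
  cg <- g[g$gene_class == "coding", ]
  oracle <- lg$gene_id[sapply(seq_len(nrow(lg)), function(i) {
    same <- cg$chrom == lg$chrom[i]
    if (!any(same)) return(TRUE)
    gaps <- pmax(cg$start[same] - lg$end[i], lg$start[i] - cg$end[same])
    all(gaps >= 1000)
  })]
  expect_setequal(got, oracle)
})

test_that("tile feature assignment uses half-open >=1bp overlap, multi-label", {
  tiles <- data.frame(chrom = "chr1", start = c(100L, 100L),
                      end = c(200L, 200L))[1, , drop = FALSE]
  lab <- assign_tiles(tiles, list(promoter = data.frame(chrom = "chr1",
                                                        start = 150L,
                                                        end = 400L)))
  expect_true(lab$promoter)
  lab2 <- assign_tiles(tiles, list(feat = data.frame(chrom = "chr1",
                                                     start = 200L,
                                                     end = 300L)))
  expect_false(lab2$feat)  # half-open: [100,200) does not touch [200,300)
  expect_true(lab2$intergenic)

  # brute-force oracle on fixture tiles
  run <- demo_run()
  tested <- attr(run$gdmr$calls, "tested")
  tiles <- tested[sample(nrow(tested), 1500), c("chrom", "start", "end")]
  labs <- assign_tiles(tiles, run$fixture$features)
  for (nm in names(run$fixture$features)) {
    f <- run$fixture$features[[nm]]
    oracle <- vapply(seq_len(nrow(tiles)), function(i) {
      any(f$chrom == tiles$chrom[i] & f$start < tiles$end[i] &
            f$end > tiles$start[i])
    }, logical(1))
    expect_equal(labs[[nm]], oracle, info = nm)
  }
  # label counts stable under permutation of input tiles
  perm <- sample(nrow(tiles))
  labs_p <- assign_tiles(tiles[perm, ], run$fixture$features)
  expect_equal(colSums(labs_p[names(run$fixture$features)]),
               colSums(labs[names(run$fixture$features)]))
})

test_that("region methylation averages overlapping tiles, missing stays NA", {
  meth <- make_tiles("chr1", c(0, 100, 300), c(0.2, 0.6, 0.9))
  reg <- data.frame(chrom = "chr1", start = c(0L, 1000L), end = c(200L, 1100L))
  rm <- region_methylation(meth, reg)
  expect_equal(rm$level, c(0.4, NA))
  expect_equal(rm$n_tiles, c(2L, 0L))
})

test_that("lncRNA promoters run hotter than coding promoters in the fixture", {
  run <- demo_run()
  proms <- promoters_of(run$annotation$models)
  lev <- region_methylation(run$quant$stage_meth$sperm, proms)
  by_class <- tapply(lev$level, proms$gene_class, mean, na.rm = TRUE)
  expect_gt(by_class[["lncRNA"]], by_class[["coding"]])
})

test_that("TSS profiles are flat on uniform input and mirror under strand flip", {
  meth <- make_tiles("chr1", seq(0, 19900, by = 100), 0.5)
  gene_p <- make_models("g1", "coding", "chr1", "+", 10000, 12000)
  prof <- tss_profile(meth, gene_p)
  expect_equal(nrow(prof), 100)
  expect_true(all(prof$mean == 0.5))

  set.seed(5)
  meth$level <- runif(nrow(meth))
  gene_m <- make_models("g1", "coding", "chr1", "-", 8000, 10000)  # tss 10000
  pp <- tss_profile(meth, gene_p)
  pm <- tss_profile(meth, gene_m)
  expect_equal(pm$mean, rev(pp$mean))
})

test_that("K-S comparison matches the max ECDF gap and handles edge cases", {
  x <- c(1, 2, 3); y <- c(1, 2, 3)
  expect_equal(ks_compare(x, y)$statistic, 0)
  expect_equal(ks_compare(1:5, 11:15)$statistic, 1)  # disjoint supports
  expect_error(ks_compare(1, 1:5), "n >= 2")

  set.seed(9)
  a <- rnorm(50); b <- rnorm(60, 0.5)
  d <- ks_compare(a, b)$statistic
  grid <- sort(c(a, b))
  oracle <- max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
  expect_equal(d, oracle, tolerance = 1e-12)
})
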