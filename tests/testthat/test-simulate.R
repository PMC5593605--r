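# Synthetic-data generator: determinism, planted structure, serialization.

test_that("annotation honours the configuration and is deterministic", {
  cfg <- sim_config(n_coding = 50, n_lncrna = 50,
                    chrom_sizes = c(chrA = 1e6), seed = 1)
  ann <- generate_annotation(cfg)
  g <- ann$models$genes
  expect_equal(nrow(g), 100)
  expect_true(all(g$promoter_end - g$promoter_start == 2000L))
  expect_true(all(g$promoter_start + 1000L == g$tss))
  expect_setequal(unique(g$strand), c("+", "-"))
  # non-overlapping gene bodies per chromosome
  ord <- g[order(g$chrom, g$start), ]
  expect_true(all(diff(ord$start) >= (ord$end - ord$start)[-nrow(ord)] |
                  ord$chrom[-1] != ord$chrom[-nrow(ord)]))
  ann2 <- generate_annotation(cfg)
  expect_identical(ann, ann2)

  # coding promoters carry more CpGs than lncRNA promoters
  cpg <- ann$cpg_sites
  prom_counts <- sapply(seq_len(nrow(g)), function(i) {
    sum(cpg$chrom == g$chrom[i] & cpg$pos >= g$promoter_start[i] &
          cpg$pos < g$promoter_end[i])
  })
  expect_gt(mean(prom_counts[g$gene_class == "coding"]),
            mean(prom_counts[g$gene_class == "lncRNA"]))

  expect_error(generate_annotation(sim_config(chrom_sizes = c(tiny = 5e4))),
               "chromosome tiny.*too short")
  expect_error(sim_config(stages = c("a", "b")), "gamete")
})

test_that("methylomes carry the planted truth and the stated noise model", {
  ds <- demo_dataset()
  truth <- ds$truth
  expect_equal(sum(truth$gdmrs$gamete == "sperm"), 20)
  expect_equal(sum(truth$gdmrs$gamete == "oocyte"), 20)
  expect_equal(nrow(truth$ddmrs), 30)
  # planted regions are pairwise disjoint
  planted <- rbind(truth$gdmrs[c("chrom", "start", "end")],
                   truth$ddmrs[c("chrom", "start", "end")])
  planted <- planted[order(planted$chrom, planted$start), ]
  expect_true(all(planted$start[-1] >= planted$end[-nrow(planted)] |
                  planted$chrom[-1] != planted$chrom[-nrow(planted)]))
  # Poisson coverage close to its mean over >= 10,000 CpGs
  cc <- ds$methylomes$counts[[1]]
  expect_gt(nrow(cc), 10000)
  expect_lt(abs(mean(cc$meth + cc$unmeth) - 30) / 30, 0.2)
  expect_true(all(cc$meth >= 0 & cc$unmeth >= 0))
  expect_error(simulate_methylomes(ds$annotation,
                                   sim_config(replicates_per_stage = 1)),
               "replicates")
})

test_that("planted gamete DMRs clear the threshold margins in every replicate", {
  run <- demo_run()
  tiles <- run$quant$tiles
  rrbs <- run$fixture$samples[run$fixture$samples$assay == "rrbs", ]
  truth <- run$fixture$truth$gdmrs
  level_at <- function(tile_df, chrom, start) {
    tile_df$level[tile_df$chrom == chrom & tile_df$start == start]
  }
  for (i in which(truth$gamete == "sperm")) {
    for (s0 in seq(truth$start[i], truth$end[i] - 100, by = 100)) {
      for (smp in rrbs$sample[rrbs$stage == "sperm"]) {
        expect_gt(level_at(tiles[[smp]], truth$chrom[i], s0), 0.75)
      }
      for (smp in rrbs$sample[rrbs$stage == "oocyte"]) {
        expect_lt(level_at(tiles[[smp]], truth$chrom[i], s0), 0.25)
      }
    }
  }
  # planted-truth completeness: every planted tile is covered in every sample
  planted <- rbind(truth[c("chrom", "start", "end")],
                   run$fixture$truth$ddmrs[c("chrom", "start", "end")])
  for (smp in rrbs$sample) {
    keys <- tile_key(tiles[[smp]]$chrom, tiles[[smp]]$start)
    for (i in seq_len(nrow(planted))) {
      want <- tile_key(planted$chrom[i],
                       seq(planted$start[i], planted$end[i] - 100, 100))
      expect_true(all(want %in% keys))
    }
  }
})

test_that("expression follows the planted coupling and module structure", {
  ds <- demo_dataset()
  # degenerate configuration: no coupling, no noise, no modules
  cfg0 <- sim_config(coupling_slope = 0, coupling_slope_body = 0,
                     n_coexpr_modules = 0, expr_noise_sd = 0, seed = 2)
  ann0 <- generate_annotation(cfg0)
  meth0 <- simulate_methylomes(ann0, cfg0)
  ex0 <- simulate_expression(ann0, meth0, cfg0)
  expect_true(all(apply(ex0$expr, 1, function(x) diff(range(x))) < 1e-9))
  expect_true(all(ds$expression$expr >= 0))
  # module genes are promoter-D-DMR hosts
  seeds <- ds$truth$ddmrs$host_gene[ds$truth$ddmrs$placement == "promoter"]
  expect_true(all(ds$truth$modules$gene %in% seeds))
  expect_equal(nrow(ds$truth$modules), 18)
})

test_that("fixtures serialize faithfully and deterministically", {
  cfg <- sim_config(n_coding = 20, n_lncrna = 15, chrom_sizes = c(chr1 = 4e5),
                    n_gdmr_sperm = 4, n_gdmr_oocyte = 4, n_ddmr = 10,
                    n_coexpr_modules = 2, module_size = 3, seed = 5)
  ds <- simulate_dataset(cfg)
  d1 <- tempfile(); d2 <- tempfile()
  write_fixture(ds, d1)
  write_fixture(simulate_dataset(cfg), d2)
  files <- list.files(d1, recursive = TRUE)
  expect_setequal(files, list.files(d2, recursive = TRUE))
  for (f in files) {  # same config + seed -> byte-identical files
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # coverage round-trip through the Bismark reader
  smp <- ds$methylomes$samples$sample[1]
  back <- load_coverage(file.path(d1, "coverage", paste0(smp, ".cov")))
  orig <- ds$methylomes$counts[[smp]]
  expect_equal(back$pos, orig$pos)
  expect_equal(back$meth, orig$meth)
  expect_equal(back$unmeth, orig$unmeth)
  # percent column = 100 * M / (M + U) to 6 decimals
  raw <- read.table(file.path(d1, "coverage", paste0(smp, ".cov")),
                    sep = "\t")
  expect_equal(raw$V4, round(100 * raw$V5 / (raw$V5 + raw$V6), 6))
  expect_true(all(raw$V2 == raw$V3))  # 1-based point intervals
  # manifest records the seed
  man <- jsonlite::read_json(file.path(d1, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$seed, 5)
  expect_equal(man$config$n_coding, 20)
})
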