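# Gamete-specific DMR calling, dynamics clustering, enrichment, bias.

test_that("the threshold rule gates G-DMR calls", {
  sperm <- list(make_tiles("chr1", c(0, 100), c(0.88, 0.60)),
                make_tiles("chr1", c(0, 100), c(0.92, 0.60)))
  ooc <- list(make_tiles("chr1", c(0, 100), c(0.08, 0.10)),
              make_tiles("chr1", c(0, 100), c(0.12, 0.10)))
  calls <- call_gdmrs(sperm, ooc)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$start, 0L)       # 0.60 fails the > 0.75 rule
  expect_equal(calls$gamete, "sperm")
  expect_lt(calls$q, 0.05)

  expect_error(call_gdmrs(sperm[1], ooc), ">= 2 replicates")
  expect_error(call_gdmrs(sperm, ooc, hi = 0.2, lo = 0.25), "must exceed")
})

test_that("BH q-values are monotone in p and no call exceeds the FDR gate", {
  run <- demo_run()
  tested <- attr(run$gdmr$calls, "tested")
  ord <- order(tested$p)
  expect_true(all(diff(tested$q[ord]) >= -1e-12))
  expect_true(all(run$gdmr$calls$q < 0.05))
  # direction labels consistent with the threshold rule
  with(run$gdmr$calls, {
    expect_true(all(ifelse(gamete == "sperm",
                           mean_sperm > 0.75 & mean_oocyte < 0.25,
                           mean_oocyte > 0.75 & mean_sperm < 0.25)))
  })
})

test_that("planted G-DMRs are recovered with high sensitivity and precision", {
  run <- demo_run()
  expect_gte(run$recovery$gdmr_sensitivity, 0.95)
  expect_gte(run$recovery$gdmr_precision, 0.95)
})

test_that("k-means dynamics clustering is deterministic and separates groups", {
  set.seed(2)
  centers <- matrix(runif(6 * 9), 6)
  traj <- centers[rep(1:6, each = 10), ] + matrix(rnorm(540, 0, 0.01), 60)
  cl <- cluster_dynamics(traj, k = 6, seed = 3)
  expect_equal(length(unique(cl$cluster)), 6)
  # each planted group lands in exactly one cluster
  expect_true(all(tapply(cl$cluster, rep(1:6, each = 10),
                         function(x) length(unique(x))) == 1))
  cl2 <- cluster_dynamics(traj, k = 6, seed = 3)
  expect_identical(cl$cluster, cl2$cluster)
  expect_true(all(diff(cl$sizes) <= 0))  # size-ordered labels
  expect_error(cluster_dynamics(traj[1:4, ], k = 6), "< k")

  # fitted SSE beats 100 random assignments
  sse <- function(assign) {
    sum(sapply(split(seq_len(nrow(traj)), assign), function(i) {
      ctr <- colMeans(traj[i, , drop = FALSE])
      sum(sweep(traj[i, , drop = FALSE], 2, ctr)^2)
    }))
  }
  set.seed(4)
  rand <- replicate(100, sse(sample(1:6, nrow(traj), replace = TRUE)))
  expect_true(all(cl$tot_withinss <= rand))
})

test_that("hypergeometric enrichment equals exhaustive tail enumeration", {
  universe <- data.frame(chrom = "chr1", start = seq(0, 1900, 100),
                         end = seq(100, 2000, 100),
                         lab = rep(c(TRUE, FALSE), c(5, 15)))
  dmrs <- universe[c(1:4, 6:11), ]  # 10 DMRs, 4 labelled
  res <- annotation_enrichment(dmrs, universe, labels = "lab")
  expect_equal(res$p, 28028 / 184756, tolerance = 1e-12)
  expect_equal(res$p, enum_hyper_upper(4, 5, 10, 20), tolerance = 1e-12)
  expect_equal(res$overlap, 4)
  expect_equal(res$expected, 10 * 5 / 20)

  all_lab <- transform(universe, lab = TRUE)
  expect_equal(annotation_enrichment(dmrs, all_lab, labels = "lab")$p, 1)
  none <- universe[6:15, ]  # 0 labelled DMRs, K > 0, n > 0
  expect_equal(annotation_enrichment(none, universe, labels = "lab")$p, 1)
  expect_error(annotation_enrichment(dmrs, universe[0, ]), "empty")
  expect_error(annotation_enrichment(transform(universe, start = start + 5),
                                     universe), "subset")
})

test_that("parental bias uses the plain Pearson chi-square and flags ambiguity", {
  # 67/33 lncRNA vs 51/49 coding sperm/oocyte split
  n_l <- 100; n_c <- 100
  models <- make_models(
    c(sprintf("l%03d", 1:n_l), sprintf("c%03d", 1:n_c)),
    rep(c("lncRNA", "coding"), c(n_l, n_c)), "chr1", "+",
    seq(0, by = 5000, length.out = n_l + n_c),
    seq(0, by = 5000, length.out = n_l + n_c) + 3000)
  g <- models$genes
  dmrs <- data.frame(chrom = "chr1", start = g$start + 100L,
                     end = g$start + 200L,
                     gamete = c(rep(c("sperm", "oocyte"), c(67, 33)),
                                rep(c("sperm", "oocyte"), c(51, 49))))
  pb <- parental_bias(dmrs, models, "body")
  obs <- matrix(c(51, 49, 67, 33), 2, byrow = TRUE,
                dimnames = list(c("coding", "lncRNA"), c("sperm", "oocyte")))
  expect_equal(unclass(pb$counts), unclass(as.table(obs)),
               ignore_attr = TRUE)
  exp_counts <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  expect_equal(pb$chisq$statistic, sum((obs - exp_counts)^2 / exp_counts),
               tolerance = 1e-12)
  expect_equal(unname(pb$sperm_fraction), c(0.51, 0.67))

  # identical distributions: statistic ~ 0, p ~ 1
  dmrs2 <- transform(dmrs, gamete = rep(c("sperm", "oocyte"), 100))
  pb2 <- suppressWarnings(parental_bias(dmrs2, models, "body"))
  expect_lt(pb2$chisq$statistic, 1e-12)
  expect_equal(pb2$chisq$p.value, 1, tolerance = 1e-6)

  # a DMR spanning genes of both classes counts in both and is flagged
  models3 <- make_models(c("l1", "c1"), c("lncRNA", "coding"), "chr1", "+",
                         c(2000, 2500), c(3000, 3500))
  dmrs3 <- data.frame(chrom = "chr1",
                      start = c(2600L, 2100L, 3200L),
                      end = c(2700L, 2200L, 3300L),
                      gamete = c("sperm", "oocyte", "oocyte"))
  pb3 <- suppressWarnings(parental_bias(dmrs3, models3, "body"))
  expect_equal(pb3$n_ambiguous, 1)
  expect_equal(sum(pb3$counts), 4)  # the ambiguous DMR counted twice
})
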