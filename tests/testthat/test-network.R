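# Coding-noncoding co-expression network and gene-set enrichment.

test_that("the expression filter applies both gates", {
  set.seed(17)
  expr <- matrix(runif(100 * 10, 0, 20), 100,
                 dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:10)))
  expr["g001", ] <- 4.9          # max below the FPKM gate
  expr["g002", ] <- 10           # constant: zero variance
  kept <- filter_expressed_genes(expr)
  expect_false("g001" %in% kept)
  expect_false("g002" %in% kept)
  # brute-force recount
  v <- apply(log2(expr + 1), 1, var)
  oracle <- rownames(expr)[apply(expr, 1, max) > 5 & v >= quantile(v, 0.25)]
  expect_setequal(kept, oracle)
  expect_error(filter_expressed_genes(expr, min_max_expr = 1e9),
               "no gene survives")
})

test_that("pair correlation p-values follow Fisher's asymptotic test", {
  # r = 0.8, n = 10: t = 0.8 * sqrt(8) / sqrt(0.36)
  t_exp <- 0.8 * sqrt(8) / sqrt(1 - 0.64)
  expect_equal(t_exp, 3.771236, tolerance = 1e-6)
  p_exp <- 2 * pt(-t_exp, 8)
  # construct two genes with exactly r = 0.8 on the analysed scale
  set.seed(19)
  x <- rnorm(10)
  e <- rnorm(10); e <- residuals(lm(e ~ x)); e <- e / sd(e) * sd(x)
  y <- 0.8 * x + sqrt(1 - 0.8^2) * e
  pc_raw <- pair_correlations(rbind(g1 = x, g2 = y), log_transform = FALSE)
  expect_equal(pc_raw$r, 0.8, tolerance = 1e-9)
  expect_equal(pc_raw$p, p_exp, tolerance = 1e-9)

  # perfect correlation: p = 0 without numerical blow-up
  pc1 <- pair_correlations(rbind(g1 = x, g2 = 2 * x), log_transform = FALSE)
  expect_equal(pc1$r, 1, tolerance = 1e-12)
  expect_equal(pc1$p, 0)

  # p monotone decreasing in |r| at fixed n
  rs <- seq(0.1, 0.9, 0.1)
  ps <- 2 * pt(-abs(rs * sqrt(8) / sqrt(1 - rs^2)), 8)
  expect_true(all(diff(ps) < 0))

  # constant gene: its pairs are missing
  pc2 <- pair_correlations(rbind(g1 = x, g2 = rep(1, 10)),
                           log_transform = FALSE)
  expect_true(is.na(pc2$r) && is.na(pc2$p))
  expect_error(pair_correlations(rbind(g1 = x[1:3], g2 = y[1:3])),
               ">= 4 samples")
})

test_that("network edges obey the r, p and seed gates", {
  pairs <- data.frame(gene_a = c("a", "a", "b", "c"),
                      gene_b = c("b", "c", "d", "d"),
                      r = c(0.85, 0.79, -0.9, 0.95),
                      p = c(0.001, 0.001, 0.01, 0.2))
  net <- build_network(pairs, seed_genes = "a")
  expect_equal(nrow(net$edges), 1)  # a-b passes; a-c fails |r|; others unseeded/p
  expect_equal(net$edges$gene_a, "a")
  expect_equal(net$edges$gene_b, "b")
  net2 <- build_network(pairs, seed_genes = "b")
  expect_setequal(paste(net2$edges$gene_a, net2$edges$gene_b),
                  c("a b", "b d"))
  expect_error(build_network(pairs, character()), "empty seed")
  expect_warning(build_network(pairs, "z"), "no gene pair")

  # invariance to gene order in the expression matrix
  set.seed(23)
  expr <- matrix(2^rnorm(8 * 20, 3), 8,
                 dimnames = list(paste0("g", 1:8), paste0("s", 1:20)))
  p1 <- pair_correlations(expr)
  p2 <- pair_correlations(expr[sample(8), ])
  p2 <- p2[order(p2$gene_a, p2$gene_b), ]
  rownames(p2) <- NULL
  expect_equal(p1, p2, ignore_attr = TRUE)
})

test_that("topology: degrees, hubs and components", {
  star <- data.frame(gene_a = "hub", gene_b = paste0("leaf", 1:5),
                     r = 0.9, p = 0.001)
  net <- build_network(star, seed_genes = "hub")
  topo <- network_topology(net)
  expect_equal(topo$degrees$degree[topo$degrees$gene == "hub"], 5L)
  expect_true(all(topo$degrees$degree[topo$degrees$gene != "hub"] == 1L))
  expect_equal(topo$hubs, "hub")

  tri2 <- data.frame(gene_a = c("a", "b", "a", "x", "y", "x"),
                     gene_b = c("b", "c", "c", "y", "z", "z"),
                     r = 0.9, p = 0.001)
  net2 <- build_network(tri2, seed_genes = c("a", "b", "c", "x", "y", "z"))
  topo2 <- network_topology(net2)
  expect_equal(topo2$component_sizes, c(3L, 3L))
  # handshake lemma
  expect_equal(sum(topo2$degrees$degree), 2 * nrow(net2$edges))
})

test_that("planted modules dominate the fixture network edges", {
  run <- demo_run()
  expect_gte(run$recovery$network_edge_precision, 0.9)
  edges <- run$network$network$edges
  expect_true(all(abs(edges$r) > 0.8 & edges$p < 0.05))
  expect_true(all(edges$seeded_a | edges$seeded_b))
  expect_true(all(edges$gene_a != edges$gene_b))
  expect_false(any(duplicated(edges[c("gene_a", "gene_b")])))
  # planted module pairs reach |r| >= 0.8 empirically
  mods <- split(run$fixture$truth$modules$gene, run$fixture$truth$modules$module)
  lx <- log2(run$fixture$exprset$expr + 1)
  for (m in mods) {
    cm <- cor(t(lx[m, ]))
    expect_gte(min(abs(cm[upper.tri(cm)])), 0.8)
  }
})

test_that("gene-set enrichment: exact-match query, fold, enumeration oracle", {
  universe <- sprintf("g%02d", 1:20)
  terms <- data.frame(term = rep(c("T1", "T2", "T3"), each = 5),
                      gene = c(universe[1:5], universe[6:10], universe[8:12]))
  res <- geneset_enrichment(universe[1:5], terms, universe)
  r1 <- res[res$term == "T1", ]
  expect_equal(r1$k, 5)
  expect_equal(r1$fold, 20 / 5)  # N / K for an exact match
  expect_equal(r1$p, min(res$p))
  # p equals exhaustive enumeration for every term
  for (i in seq_len(nrow(res))) {
    expect_equal(res$p[i], enum_hyper_upper(res$k[i], res$K[i], res$n[i],
                                            res$N[i]), tolerance = 1e-12)
  }
  expect_true(all(res$q >= res$p))
  expect_true(all(res$k <= pmin(res$n, res$K)))
  expect_error(geneset_enrichment("zz", terms, universe), "outside")
  expect_message(
    geneset_enrichment(universe[1:3],
                       rbind(terms, data.frame(term = "T4", gene = "nope")),
                       universe), "skipped")
})
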