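# End-to-end orchestration: simulate (or load) inputs, quantify, call DMRs,
# correlate methylation with expression, build the co-expression network,
# and score recovery against planted ground truth when available.

#' Pipeline configuration
#'
#' Collects every stage parameter with the study defaults: 100-bp tiles with
#' a five-fold coverage filter, 1-kb promoter flanks, the 0.75/0.25 G-DMR
#' threshold rule at FDR 0.05, the 4.22-bit entropy threshold (defined at 32
#' profiles, rescaled to the actual stage count), k-means with k = 6, and
#' the |r| > 0.8, p < 0.05 network gates with the max-FPKM > 5 / top-75%
#' variance expression filter.
#'
#' @param out_dir Run directory for all outputs.
#' @param seed Seed governing every stochastic step (simulation, k-means).
#' @param simulate Generate the inputs with the synthetic-data module
#'   (default `TRUE`); otherwise `input_dir` must point to a fixture-layout
#'   directory.
#' @param sim A [sim_config()] used when `simulate = TRUE`.
#' @param input_dir Existing fixture directory used when `simulate = FALSE`.
#' @param min_cov,tile_size Tile quantification parameters.
#' @param gdmr_hi,gdmr_lo,gdmr_fdr G-DMR caller parameters.
#' @param h_threshold,h_reference_n D-DMR entropy threshold and its
#'   reference profile width.
#' @param kmeans_k G-DMR dynamics clusters.
#' @param r_min,p_max,min_max_expr,var_keep_fraction Network gates and
#'   expression filter.
#' @param hub_quantile Degree quantile defining hubs.
#' @param resume Reuse cached stage results found in `out_dir` (default
#'   `FALSE`).
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("premeth_run_"),
                            seed = 1,
                            simulate = TRUE,
                            sim = sim_config(seed = seed),
                            input_dir = NULL,
                            min_cov = 5, tile_size = 100,
                            gdmr_hi = 0.75, gdmr_lo = 0.25, gdmr_fdr = 0.05,
                            h_threshold = 4.22, h_reference_n = 32,
                            kmeans_k = 6,
                            r_min = 0.8, p_max = 0.05,
                            min_max_expr = 5, var_keep_fraction = 0.75,
                            hub_quantile = 0.95,
                            resume = FALSE) {
  cfg <- as.list(environment())
  if (gdmr_hi <= gdmr_lo) {
    stop_premeth("config error: gdmr_hi (%.2f) must exceed gdmr_lo (%.2f)",
                 gdmr_hi, gdmr_lo)
  }
  for (nm in c("gdmr_hi", "gdmr_lo", "gdmr_fdr", "p_max",
               "var_keep_fraction", "hub_quantile")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      stop_premeth("config error: %s = %g outside [0, 1]", nm, cfg[[nm]])
    }
  }
  if (min_cov < 1 || tile_size < 1 || kmeans_k < 2 || h_threshold <= 0) {
    stop_premeth("config error: threshold outside its valid range")
  }
  if (!simulate && is.null(input_dir)) {
    stop_premeth("config error: input_dir required when simulate = FALSE")
  }
  structure(cfg, class = "pipeline_config")
}

# Stage cache: recompute unless resuming and a cached result exists.
# Dependent stages are grouped into one cache unit so deleting a unit
# triggers recomputation of everything in it.
.stage <- function(state, name, fun) {
  path <- file.path(state$cache_dir, paste0(name, ".rds"))
  if (state$resume && file.exists(path)) {
    message(sprintf("[%s] reusing cached result", name))
    return(readRDS(path))
  }
  t0 <- proc.time()[["elapsed"]]
  res <- fun()
  saveRDS(res, path)
  state$timings[[name]] <- round(proc.time()[["elapsed"]] - t0, 2)
  message(sprintf("[%s] done in %.1fs", name, state$timings[[name]]))
  res
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order: data (simulate or load) ->
#' tile quantification -> annotation summaries -> G-DMR and D-DMR calling ->
#' methylation-expression correlation -> co-expression network and
#' enrichment -> recovery report (when ground truth is available). Every
#' stage writes its tables under `out_dir` and a `run_report.json` records
#' all thresholds actually used.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a `premeth_run` list with all stage results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- new.env()
  state$cache_dir <- file.path(out_dir, "cache")
  dir.create(state$cache_dir, showWarnings = FALSE)
  state$resume <- isTRUE(config$resume)
  state$timings <- list()
  set.seed(config$seed)

  fx <- .stage(state, "data", function() {
    input_dir <- config$input_dir
    if (config$simulate) {
      ds <- simulate_dataset(config$sim)
      input_dir <- file.path(out_dir, "fixture")
      write_fixture(ds, input_dir)
    }
    load_fixture(input_dir)
  })

  quant <- .stage(state, "quant", function() {
    cpg_sites <- unique(do.call(rbind, lapply(fx$counts,
                                              function(x) x[c("chrom", "pos")])))
    cpg_sites <- cpg_sites[order(cpg_sites$chrom, cpg_sites$pos), ]
    tiles <- lapply(fx$counts, tile_methylation, tile_size = config$tile_size,
                    min_cov = config$min_cov, cpg_positions = cpg_sites)
    rrbs <- fx$samples[fx$samples$assay == "rrbs", ]
    stage_meth <- lapply(split(rrbs$sample, rrbs$stage)[unique(rrbs$stage)],
                         function(s) stage_average(tiles[s]))
    tile_dir <- file.path(out_dir, "tiles")
    dir.create(tile_dir, showWarnings = FALSE)
    for (nm in names(tiles)) {
      write_tsv(tiles[[nm]][c("chrom", "start", "end", "level",
                              "pooled_total", "cpg_density")],
                file.path(tile_dir, paste0(nm, ".tiles.tsv")))
    }
    for (nm in names(stage_meth)) {
      write_tsv(stage_meth[[nm]],
                file.path(tile_dir, paste0("stage_", nm, ".tsv")))
    }
    list(tiles = tiles, stage_meth = stage_meth, cpg_sites = cpg_sites)
  })

  annot <- .stage(state, "annotation", function() {
    models <- fx$models
    cls <- split(models$genes$gene_id, models$genes$gene_class)
    subset_models <- function(ids) {
      structure(list(genes = models$genes[models$genes$gene_id %in% ids, ],
                     exons = models$exons[models$exons$gene_id %in% ids, ]),
                class = "gene_models")
    }
    lnc <- subset_models(cls$lncRNA)
    cod <- subset_models(cls$coding)
    lnc_distal <- filter_distal_lncrna(lnc, cod)
    sperm <- quant$stage_meth[["sperm"]]
    profiles <- list(
      meth_coding = tss_profile(sperm, cod),
      meth_lncrna = tss_profile(sperm, lnc_distal),
      density_coding = tss_profile(sperm, cod, value = "cpg_density"),
      density_lncrna = tss_profile(sperm, lnc_distal, value = "cpg_density"))
    prom_ks <- ks_compare(
      region_methylation(sperm, promoters_of(cod))$level,
      region_methylation(sperm, promoters_of(lnc_distal))$level)
    status <- t(sapply(quant$stage_meth, function(m) status_fractions(m$level)))
    for (nm in names(profiles)) {
      write_tsv(profiles[[nm]],
                file.path(out_dir, paste0("tss_profile_", nm, ".tsv")))
    }
    write_tsv(cbind(stage = rownames(status), as.data.frame(status)),
              file.path(out_dir, "status_fractions.tsv"))
    list(models = models, lnc = lnc, cod = cod, lnc_distal = lnc_distal,
         profiles = profiles, prom_ks = prom_ks, status = status)
  })

  gdmr <- .stage(state, "gdmr", function() {
    rrbs <- fx$samples[fx$samples$assay == "rrbs", ]
    reps <- function(st) quant$tiles[rrbs$sample[rrbs$stage == st]]
    calls <- call_gdmrs(reps("sperm"), reps("oocyte"), hi = config$gdmr_hi,
                        lo = config$gdmr_lo, fdr = config$gdmr_fdr)
    stage_mat <- stage_level_matrix(quant$stage_meth, all_stages = FALSE)
    key <- tile_key(stage_mat$chrom, stage_mat$start)
    traj <- as.matrix(stage_mat[match(tile_key(calls$chrom, calls$start), key),
                                names(quant$stage_meth), drop = FALSE])
    clusters <- if (nrow(calls) >= config$kmeans_k) {
      cluster_dynamics(traj, k = config$kmeans_k, seed = config$seed)
    } else NULL
    tested <- attr(calls, "tested")
    universe <- assign_tiles(tested[c("chrom", "start", "end")], fx$features)
    enrich <- lapply(split(seq_len(nrow(calls)), calls$gamete), function(i) {
      annotation_enrichment(calls[i, ], universe)
    })
    bias <- tryCatch(parental_bias(calls, annot$models, "body"),
                     error = function(e) NULL)
    bias_prom <- tryCatch(parental_bias(calls, annot$models, "promoter"),
                          error = function(e) NULL)
    out <- calls
    if (!is.null(clusters)) out$cluster <- clusters$cluster
    write_tsv(out, file.path(out_dir, "gdmrs.tsv"))
    list(calls = calls, clusters = clusters, enrichment = enrich,
         bias_body = bias, bias_promoter = bias_prom)
  })

  ddmr <- .stage(state, "ddmr", function() {
    stage_mat <- stage_level_matrix(quant$stage_meth, all_stages = TRUE)
    calls <- call_ddmrs(stage_mat, threshold = config$h_threshold,
                        reference_n = config$h_reference_n)
    summary <- ddmr_class_summary(calls, annot$models)
    write_tsv(calls, file.path(out_dir, "ddmrs.tsv"))
    if (nrow(summary$summary)) {
      write_tsv(summary$summary, file.path(out_dir, "ddmr_class_summary.tsv"))
    }
    list(calls = calls, summary = summary,
         threshold_used = attr(calls, "threshold_used"))
  })

  methexpr <- .stage(state, "methexpr", function() {
    proms <- promoters_of(annot$models)
    bodies <- gene_bodies_of(annot$models)
    prom_levels <- region_level_matrix(quant$stage_meth, proms)
    body_levels <- region_level_matrix(quant$stage_meth, bodies)
    res <- list(
      promoter = meth_expr_correlation(prom_levels, fx$exprset),
      body = meth_expr_correlation(body_levels, fx$exprset))
    write_tsv(res$promoter, file.path(out_dir, "correlation_promoter.tsv"))
    write_tsv(res$body, file.path(out_dir, "correlation_body.tsv"))
    list(correlations = res, prom_levels = prom_levels,
         body_levels = body_levels)
  })

  network <- .stage(state, "network", function() {
    kept <- filter_expressed_genes(fx$exprset,
                                   min_max_expr = config$min_max_expr,
                                   var_keep_fraction = config$var_keep_fraction)
    pairs <- pair_correlations(fx$exprset, genes = kept)
    # seed genes: promoters hosting a called D-DMR (pipeline-derived)
    proms <- promoters_of(annot$models)
    hits <- interval_overlaps(ddmr$calls[c("chrom", "start", "end")], proms)
    seeds <- unique(proms$gene_id[S4Vectors::subjectHits(hits)])
    net <- if (length(seeds)) {
      build_network(pairs, seeds, r_min = config$r_min,
                    p_max = config$p_max, models = annot$models)
    } else NULL
    topo <- if (!is.null(net)) network_topology(net, config$hub_quantile)
      else NULL
    enrich <- NULL
    if (!is.null(net) && nrow(net$edges) && !is.null(fx$truth$modules)) {
      enrich <- tryCatch(
        geneset_enrichment(intersect(net$nodes$gene, kept),
                           stats::setNames(fx$truth$modules[c("module", "gene")],
                                           c("term", "gene")),
                           universe = kept),
        error = function(e) NULL)
    }
    if (!is.null(net)) {
      write_tsv(net$edges, file.path(out_dir, "network_edges.tsv"))
      write_tsv(topo$degrees, file.path(out_dir, "network_degrees.tsv"))
    }
    if (!is.null(enrich)) {
      write_tsv(enrich, file.path(out_dir, "network_enrichment.tsv"))
    }
    list(kept = kept, pairs = pairs, seeds = seeds, network = net,
         topology = topo, enrichment = enrich)
  })

  run <- structure(list(config = config, fixture = fx, quant = quant,
                        annotation = annot, gdmr = gdmr, ddmr = ddmr,
                        methexpr = methexpr, network = network),
                   class = "premeth_run")
  recovery <- NULL
  if (!is.null(fx$truth) && !is.null(fx$truth$gdmrs)) {
    recovery <- evaluate_recovery(run, fx$truth)
    jsonlite::write_json(recovery, file.path(out_dir, "recovery.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run$recovery <- recovery
  report <- list(
    seed = config$seed,
    thresholds = config[c("min_cov", "tile_size", "gdmr_hi", "gdmr_lo",
                          "gdmr_fdr", "h_threshold", "h_reference_n",
                          "kmeans_k", "r_min", "p_max", "min_max_expr",
                          "var_keep_fraction", "hub_quantile")],
    entropy_threshold_used = ddmr$threshold_used,
    counts = list(n_tiles_tested_gdmr = nrow(attr(gdmr$calls, "tested")),
                  n_gdmrs = nrow(gdmr$calls),
                  n_ddmrs = nrow(ddmr$calls),
                  n_network_edges = if (!is.null(network$network))
                    nrow(network$network$edges) else 0L),
    timings_s = state$timings)
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(run)
}

#' @export
print.premeth_run <- function(x, ...) {
  cat(sprintf("premeth_run: %d G-DMR tiles, %d D-DMR tiles, %d network edges\n",
              nrow(x$gdmr$calls), nrow(x$ddmr$calls),
              if (!is.null(x$network$network)) nrow(x$network$network$edges)
              else 0L))
  if (!is.null(x$recovery)) {
    cat(sprintf("  recovery: G-DMR sens %.3f / prec %.3f; D-DMR sens %.3f / bg FPR %.4f\n",
                x$recovery$gdmr_sensitivity, x$recovery$gdmr_precision,
                x$recovery$ddmr_sensitivity,
                x$recovery$ddmr_background_false_call_rate))
  }
  invisible(x)
}

# Fraction of planted regions with >= 1 overlapping called tile (optionally
# label-matched), and per-call precision.
.region_hit <- function(planted, calls, match_col = NULL) {
  if (is.null(planted) || nrow(planted) == 0) return(NA_real_)
  if (nrow(calls) == 0) return(0)
  hits <- interval_overlaps(planted, calls)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  if (!is.null(match_col)) {
    keep <- planted[[match_col]][q] == calls[[match_col]][s]
    q <- q[keep]
  }
  length(unique(q)) / nrow(planted)
}

#' Score a run against planted ground truth
#'
#' @param run A `premeth_run`.
#' @param truth Ground-truth tables from the fixture.
#' @return List of recovery metrics: planted G-DMR sensitivity/precision
#'   (gamete-matched), planted D-DMR sensitivity, background false-call rate
#'   (called tiles among tiles overlapping no planted region of any kind),
#'   fraction of stages with negative promoter methylation-expression
#'   correlation (and positive gene-body correlation), and network edge
#'   precision against the planted modules.
#' @export
evaluate_recovery <- function(run, truth) {
  gcalls <- run$gdmr$calls
  planted_g <- truth$gdmrs
  gdmr_sens <- .region_hit(planted_g, gcalls, "gamete")
  gdmr_prec <- if (nrow(gcalls) == 0) NA_real_ else {
    hits <- interval_overlaps(gcalls, planted_g)
    ok <- gcalls$gamete[S4Vectors::queryHits(hits)] ==
      planted_g$gamete[S4Vectors::subjectHits(hits)]
    length(unique(S4Vectors::queryHits(hits)[ok])) / nrow(gcalls)
  }
  dcalls <- run$ddmr$calls
  ddmr_sens <- .region_hit(truth$ddmrs, dcalls)
  tested <- attr(run$ddmr$calls, "tested")
  planted_all <- rbind(planted_g[c("chrom", "start", "end")],
                       truth$ddmrs[c("chrom", "start", "end")])
  bg <- rep(TRUE, nrow(tested))
  bg[S4Vectors::queryHits(interval_overlaps(
    tested[c("chrom", "start", "end")], planted_all))] <- FALSE
  called_key <- tile_key(dcalls$chrom, dcalls$start)
  bg_called <- tile_key(tested$chrom, tested$start) %in% called_key & bg
  ddmr_fpr <- if (sum(bg) > 0) sum(bg_called) / sum(bg) else NA_real_
  corr <- run$methexpr$correlations
  prom_r <- corr$promoter$r[!is.na(corr$promoter$r)]
  body_r <- corr$body$r[!is.na(corr$body$r)]
  edges <- if (!is.null(run$network$network)) run$network$network$edges
    else NULL
  edge_prec <- NA_real_
  if (!is.null(edges) && nrow(edges) > 0 && !is.null(truth$modules)) {
    mod <- stats::setNames(truth$modules$module, truth$modules$gene)
    same <- !is.na(mod[edges$gene_a]) & !is.na(mod[edges$gene_b]) &
      mod[edges$gene_a] == mod[edges$gene_b]
    edge_prec <- mean(same)
  }
  list(
    gdmr_sensitivity = gdmr_sens,
    gdmr_precision = gdmr_prec,
    n_gdmr_calls = nrow(gcalls),
    ddmr_sensitivity = ddmr_sens,
    ddmr_background_false_call_rate = ddmr_fpr,
    n_ddmr_calls = nrow(dcalls),
    frac_stages_promoter_r_negative = mean(prom_r < 0),
    frac_stages_body_r_positive = mean(body_r > 0),
    network_edge_precision = edge_prec,
    n_network_edges = if (is.null(edges)) 0L else nrow(edges))
}

#' One-command synthetic demo
#'
#' Simulates a dataset, runs the whole pipeline on it and reports recovery
#' against the planted ground truth.
#'
#' @param out_dir Run directory.
#' @param seed Seed for simulation and clustering.
#' @param ... Overrides passed to [pipeline_config()].
#' @return Invisibly, the `premeth_run`.
#' @export
run_demo <- function(out_dir = tempfile("premeth_demo_"), seed = 1, ...) {
  cfg <- pipeline_config(out_dir = out_dir, seed = seed,
                         sim = sim_config(seed = seed), ...)
  run <- run_pipeline(cfg)
  print(run)
  invisible(run)
}
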