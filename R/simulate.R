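# Synthetic-data generator: annotation, per-sample bisulfite counts with
# planted gamete- and developmental-specific DMRs, and an expression matrix
# with promoter-methylation coupling and planted co-expression modules.
# Defaults emulate the structure of the study system: nine stages from the
# gametes through post-implantation, a demethylation wave bottoming at the
# 2-cell stage, and CpG-poorer lncRNA promoters.

# Default stage-level background methylation trajectory: high in sperm,
# intermediate in oocyte, minimum at the 2-cell stage, remethylated after
# implantation.
.default_stages <- c("sperm", "oocyte", "zygote", "2cell", "4cell", "8cell",
                     "morula", "blastocyst", "postimplantation")
.default_trajectory <- c(sperm = 0.85, oocyte = 0.55, zygote = 0.45,
                         "2cell" = 0.25, "4cell" = 0.30, "8cell" = 0.35,
                         morula = 0.40, blastocyst = 0.45,
                         postimplantation = 0.75)

#' Simulation configuration
#'
#' Defines the study conditions emulated by the generator. Defaults: nine
#' developmental stages with two RRBS replicates each on a single 1-Mb
#' chromosome, 120 protein-coding and 80 lncRNA genes, mean 30x CpG
#' coverage, planted sperm-/oocyte-specific and developmental-specific DMRs,
#' negative promoter-methylation-expression coupling and three planted
#' co-expression modules.
#'
#' @param stages Ordered stage labels; must contain `"sperm"` and
#'   `"oocyte"`.
#' @param replicates_per_stage RRBS replicates per stage (>= 2; the G-DMR
#'   t-test needs replication).
#' @param n_coding,n_lncrna Gene counts per class.
#' @param chrom_sizes Named vector of chromosome lengths in bp.
#' @param coverage_mean Expected per-CpG read depth (Poisson).
#' @param beta_dispersion Overdispersion of per-CpG methylation around the
#'   regional mean: the per-CpG level is Beta(mu/d, (1-mu)/d), so larger `d`
#'   means noisier levels (default 0.02).
#' @param stage_trajectory Named background methylation level per stage;
#'   defaults to the built-in demethylation wave for the default stages.
#' @param n_gdmr_sperm,n_gdmr_oocyte Planted gamete-specific DMR counts.
#' @param n_ddmr Planted developmental-specific DMR count.
#' @param ddmr_promoter_fraction Fraction of planted D-DMRs placed in
#'   promoters (the rest go to gene bodies); promoter placements are biased
#'   towards lncRNA genes.
#' @param coupling_slope Effect of promoter methylation on log2 expression
#'   (negative by default).
#' @param coupling_slope_body Effect of distal gene-body methylation
#'   (promoter window excluded) on log2 expression (positive by default).
#' @param n_coexpr_modules,module_size Planted co-expression modules; module
#'   genes are drawn from the promoter-D-DMR host genes so that the module
#'   edges are recoverable through the seeded network.
#' @param module_strength Loading of the shared latent factor on module
#'   genes (log2 scale).
#' @param expr_noise_sd,expr_baseline_mean,expr_baseline_sd Log2-scale
#'   expression noise and per-gene baseline.
#' @param expr_cells_per_stage Expression samples (cells) per stage.
#' @param gene_length_range,gene_gap_range Gene body lengths and intergenic
#'   gaps (bp, uniform).
#' @param promoter_offset_sd_range Half-width of the per-gene promoter
#'   methylation offset (uniform on +/- this value).
#' @param lncrna_promoter_shift Additive promoter methylation shift for
#'   lncRNA genes (their promoters run hotter).
#' @param cpg_rate_background,cpg_rate_gene_body,cpg_rate_promoter_coding,
#'   cpg_rate_promoter_lncrna,cpg_rate_cgi Per-bp CpG placement rates
#'   (additive on top of the background); the lower lncRNA promoter rate
#'   reproduces their lower CpG density.
#' @param seed RNG seed; the whole generator is deterministic given the
#'   configuration.
#' @return A validated `sim_config` object (list).
#' @export
sim_config <- function(stages = .default_stages,
                       replicates_per_stage = 2,
                       n_coding = 120, n_lncrna = 80,
                       chrom_sizes = c(chr1 = 1e6),
                       coverage_mean = 30,
                       beta_dispersion = 0.02,
                       stage_trajectory = NULL,
                       n_gdmr_sperm = 20, n_gdmr_oocyte = 20,
                       n_ddmr = 30, ddmr_promoter_fraction = 0.7,
                       coupling_slope = -2, coupling_slope_body = 3,
                       n_coexpr_modules = 3, module_size = 6,
                       module_strength = 2.5,
                       expr_noise_sd = 0.6, expr_baseline_mean = 3,
                       expr_baseline_sd = 0.8,
                       expr_cells_per_stage = 4,
                       gene_length_range = c(1500, 4000),
                       gene_gap_range = c(500, 2500),
                       promoter_offset_sd_range = 0.18,
                       lncrna_promoter_shift = 0.08,
                       cpg_rate_background = 0.01,
                       cpg_rate_gene_body = 0.03,
                       cpg_rate_promoter_coding = 0.07,
                       cpg_rate_promoter_lncrna = 0.02,
                       cpg_rate_cgi = 0.05,
                       seed = 1) {
  cfg <- as.list(environment())
  if (!all(c("sperm", "oocyte") %in% stages)) {
    stop_premeth("stages must contain both gamete labels 'sperm' and 'oocyte'")
  }
  if (anyDuplicated(stages)) stop_premeth("duplicated stage labels")
  if (is.null(stage_trajectory)) {
    if (!all(stages %in% names(.default_trajectory))) {
      stop_premeth("stage_trajectory required for non-default stage labels")
    }
    cfg$stage_trajectory <- .default_trajectory[stages]
  } else {
    if (!setequal(names(stage_trajectory), stages)) {
      stop_premeth("stage_trajectory names must match stages")
    }
    cfg$stage_trajectory <- stage_trajectory[stages]
  }
  counts <- c(replicates_per_stage = replicates_per_stage,
              n_coding = n_coding, n_lncrna = n_lncrna,
              n_gdmr_sperm = n_gdmr_sperm, n_gdmr_oocyte = n_gdmr_oocyte,
              n_ddmr = n_ddmr, n_coexpr_modules = n_coexpr_modules,
              module_size = module_size,
              expr_cells_per_stage = expr_cells_per_stage)
  if (any(counts < 0)) stop_premeth("all counts must be >= 0")
  if (n_coding + n_lncrna < 1) stop_premeth("need at least one gene")
  if (length(chrom_sizes) == 0 || is.null(names(chrom_sizes))) {
    stop_premeth("chrom_sizes must be a non-empty named vector")
  }
  if (coverage_mean <= 0 || beta_dispersion <= 0) {
    stop_premeth("coverage_mean and beta_dispersion must be positive")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d stages x %d reps, %d coding + %d lncRNA genes, %.0f bp genome, seed %d\n",
    length(x$stages), x$replicates_per_stage, x$n_coding, x$n_lncrna,
    sum(x$chrom_sizes), x$seed))
  invisible(x)
}

# Sample CpG positions on [0, len) at a per-bp rate, restricted to an
# interval, 0-based.
.sample_positions <- function(start, end, rate) {
  w <- end - start
  if (w <= 0 || rate <= 0) return(integer())
  start + which(stats::runif(w) < rate) - 1L
}

#' Generate a synthetic gene annotation
#'
#' Places non-overlapping gene bodies (both strands, classes interleaved at
#' random) along each chromosome, derives exon/intron structure, promoters
#' (TSS +/- 1 kb) and CpG islands, and lays down CpG sites at class-specific
#' rates -- lncRNA promoters receive a lower CpG-placement rate than
#' protein-coding promoters.
#'
#' @param config A [sim_config()].
#' @return A `sim_annotation`: list with `models` (a `gene_models` object),
#'   `introns`, `cgis` (interval `data.frame`s), `cpg_sites`
#'   (`chrom`, `pos`), `chrom_sizes`, `config`.
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_genes <- config$n_coding + config$n_lncrna
  chroms <- names(config$chrom_sizes)
  # genes per chromosome, proportional to length
  alloc <- floor(n_genes * config$chrom_sizes / sum(config$chrom_sizes))
  rem <- n_genes - sum(alloc)
  if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1
  classes <- sample(c(rep("coding", config$n_coding),
                      rep("lncRNA", config$n_lncrna)))
  margin <- 3000  # room for promoters and TSS flanks at the chromosome ends
  genes <- list(); gi <- 0
  for (ch in chroms) {
    L <- config$chrom_sizes[[ch]]
    cursor <- margin
    for (k in seq_len(alloc[[ch]])) {
      len <- round(stats::runif(1, config$gene_length_range[1],
                                config$gene_length_range[2]))
      if (cursor + len > L - margin) {
        stop_premeth("chromosome %s (%d bp) too short to place %d genes",
                     ch, L, alloc[[ch]])
      }
      gi <- gi + 1
      genes[[gi]] <- data.frame(
        gene_id = sprintf("g%03d", gi), gene_class = classes[gi],
        chrom = ch, strand = sample(c("+", "-"), 1),
        start = as.integer(cursor), end = as.integer(cursor + len))
      cursor <- cursor + len + round(stats::runif(1, config$gene_gap_range[1],
                                                  config$gene_gap_range[2]))
    }
  }
  genes <- do.call(rbind, genes)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes$promoter_start <- genes$tss - 1000L
  genes$promoter_end <- genes$tss + 1000L
  # exon/intron structure: 2-4 exons, gene bodies begin and end with an exon
  exons <- list(); introns <- list()
  for (i in seq_len(nrow(genes))) {
    k <- sample(2:4, 1)
    grid <- seq(genes$start[i] + 100, genes$end[i] - 100, by = 20)
    cuts <- sort(sample(grid, 2 * (k - 1)))
    bounds <- c(genes$start[i], cuts, genes$end[i])
    seg <- data.frame(gene_id = genes$gene_id[i], chrom = genes$chrom[i],
                      start = as.integer(bounds[-length(bounds)]),
                      end = as.integer(bounds[-1]))
    exons[[i]] <- seg[seq(1, nrow(seg), by = 2), ]
    if (nrow(seg) > 1) introns[[i]] <- seg[seq(2, nrow(seg) - 1, by = 2), ]
  }
  exons <- do.call(rbind, exons)
  introns <- do.call(rbind, introns)
  # CpG islands over a subset of promoters (coding more often than lncRNA)
  has_cgi <- stats::runif(nrow(genes)) <
    ifelse(genes$gene_class == "coding", 0.5, 0.2)
  cgis <- data.frame(chrom = genes$chrom[has_cgi],
                     start = as.integer(genes$tss[has_cgi] - 300L),
                     end = as.integer(genes$tss[has_cgi] + 300L))
  # CpG sites: background everywhere, boosted in gene bodies, promoters
  # (class-specific) and CGIs
  sites <- list()
  for (ch in chroms) {
    L <- config$chrom_sizes[[ch]]
    pos <- .sample_positions(0L, L, config$cpg_rate_background)
    sel <- genes$chrom == ch
    for (i in which(sel)) {
      pos <- c(pos, .sample_positions(genes$start[i], genes$end[i],
                                      config$cpg_rate_gene_body))
      prate <- if (genes$gene_class[i] == "coding") {
        config$cpg_rate_promoter_coding
      } else config$cpg_rate_promoter_lncrna
      pos <- c(pos, .sample_positions(genes$promoter_start[i],
                                      genes$promoter_end[i], prate))
    }
    for (i in which(cgis$chrom == ch)) {
      pos <- c(pos, .sample_positions(cgis$start[i], cgis$end[i],
                                      config$cpg_rate_cgi))
    }
    pos <- sort(unique(pos))
    pos <- pos[pos >= 0 & pos < L]
    sites[[ch]] <- data.frame(chrom = ch, pos = as.integer(pos))
  }
  models <- structure(
    list(genes = genes[c("gene_id", "gene_class", "chrom", "strand", "start",
                         "end", "tss", "promoter_start", "promoter_end")],
         exons = exons[c("gene_id", "chrom", "start", "end")]),
    class = "gene_models")
  rownames(models$genes) <- rownames(models$exons) <- NULL
  structure(list(models = models,
                 introns = introns[c("gene_id", "chrom", "start", "end")],
                 cgis = cgis,
                 cpg_sites = do.call(rbind, sites),
                 chrom_sizes = config$chrom_sizes,
                 config = config),
            class = "sim_annotation")
}

# Planted-pattern stage means, all on [0, 1].
.planted_pattern <- function(kind, stages, on_stage = NULL) {
  S <- length(stages)
  p <- switch(kind,
    gdmr_sperm = {
      v <- stats::setNames(rep(0.10, S), stages)
      v["sperm"] <- 0.92; v["oocyte"] <- 0.08
      post <- which(stages == "sperm" | stages == "oocyte")
      first_embryo <- setdiff(seq_len(S), post)[1]
      v[first_embryo] <- 0.40  # paternal DMRs demethylate fast but not instantly
      v[S] <- 0.80             # remethylated by the last (post-implantation) stage
      v
    },
    gdmr_oocyte = {
      v <- stats::setNames(rep(0.50, S), stages)  # imprint-like maternal pattern
      v["sperm"] <- 0.08; v["oocyte"] <- 0.92
      v[S] <- 0.80
      v
    },
    ddmr = {
      v <- stats::setNames(rep(0.05, S), stages)
      v[on_stage] <- 0.90
      v
    })
  p
}

# Select `n` planted regions of `tiles_per_region` consecutive 100-bp tiles,
# each tile holding >= min_cpgs CpG sites, inside the given per-gene target
# intervals; regions are disjoint across calls via the shared `used`
# environment (a set of tile keys).
.pick_planted <- function(targets, n, cpg_tab, used, tiles_per_region = 2,
                          min_cpgs = 3, what = "DMR") {
  if (n == 0) return(targets[0, ])
  picked <- list()
  for (i in sample(seq_len(nrow(targets)))) {
    if (length(picked) >= n) break
    ch <- targets$chrom[i]
    lo <- ceiling(targets$start[i] / 100) * 100
    hi <- floor(targets$end[i] / 100) * 100 - tiles_per_region * 100
    if (hi < lo) next
    starts <- seq(lo, hi, by = 100)
    ok <- vapply(starts, function(s) {
      keys <- tile_key(ch, s + 100 * (seq_len(tiles_per_region) - 1))
      cnt <- cpg_tab[keys]
      all(!is.na(cnt) & cnt >= min_cpgs) && !any(keys %in% used$keys)
    }, TRUE)
    if (!any(ok)) next
    s <- sample(starts[ok], 1)
    keys <- tile_key(ch, s + 100 * (seq_len(tiles_per_region) - 1))
    used$keys <- c(used$keys, keys)
    picked[[length(picked) + 1]] <-
      data.frame(chrom = ch, start = s,
                 end = s + tiles_per_region * 100L,
                 host_gene = targets$gene_id[i],
                 host_class = targets$gene_class[i])
  }
  if (length(picked) < n) {
    stop_premeth("could only place %d of %d planted %ss; enlarge the genome or CpG rates",
                 length(picked), n, what)
  }
  do.call(rbind, picked)
}

#' Simulate per-sample bisulfite CpG counts with planted DMRs
#'
#' Assigns every CpG a regional stage-mean methylation (the background
#' demethylation wave, shifted per gene promoter/body, overridden inside
#' planted regions), then draws per-CpG per-sample counts: coverage is
#' Poisson (`coverage_mean`; zero-coverage CpGs are absent from that
#' sample), the per-CpG level is Beta-distributed around the regional mean
#' (`beta_dispersion`), and methylated reads are Binomial. Planted
#' sperm-specific DMRs have stage means 0.92 in sperm and 0.08 in oocyte
#' (and symmetrically); planted D-DMRs are methylated (0.90) in exactly one
#' embryonic stage and 0.05 elsewhere.
#'
#' @param annotation A `sim_annotation` from [generate_annotation()].
#' @param config The same [sim_config()].
#' @return A `sim_methylomes`: list with `samples`
#'   (`sample`, `stage`, `replicate`), `counts` (named list of `cpg_counts`),
#'   `truth` (`gdmrs`, `ddmrs` tables), and `regional_means` (per-gene
#'   promoter and gene-body stage-mean matrices, used by
#'   [simulate_expression()]).
#' @export
simulate_methylomes <- function(annotation, config) {
  stopifnot(inherits(annotation, "sim_annotation"),
            inherits(config, "sim_config"))
  if (config$replicates_per_stage < 2) {
    stop_premeth("replicates_per_stage must be >= 2 (the G-DMR t-test needs replicates)")
  }
  set.seed(config$seed + 1L)
  genes <- annotation$models$genes
  cpg <- annotation$cpg_sites
  stages <- config$stages
  S <- length(stages)
  wave <- config$stage_trajectory

  # per-gene persistent methylation offsets; lncRNA promoters run hotter
  off <- config$promoter_offset_sd_range
  prom_offset <- stats::runif(nrow(genes), -off, off) +
    ifelse(genes$gene_class == "lncRNA", config$lncrna_promoter_shift, 0)
  body_offset <- stats::runif(nrow(genes), -off, off)

  # regional stage means per CpG: background wave + promoter/body offset
  mu <- matrix(rep(wave, each = nrow(cpg)), nrow = nrow(cpg),
               dimnames = list(NULL, stages))
  cpg_iv <- data.frame(chrom = cpg$chrom, start = cpg$pos, end = cpg$pos + 1L)
  bhits <- interval_overlaps(cpg_iv, gene_bodies_of(annotation$models))
  phits <- interval_overlaps(cpg_iv, promoters_of(annotation$models))
  # body first, then promoter overrides (promoter takes precedence)
  offvec <- rep(0, nrow(cpg))
  offvec[S4Vectors::queryHits(bhits)] <-
    body_offset[S4Vectors::subjectHits(bhits)]
  offvec[S4Vectors::queryHits(phits)] <-
    prom_offset[S4Vectors::subjectHits(phits)]
  mu <- clamp(mu + offvec, 0.03, 0.97)

  # planted regions: disjoint runs of 2 tiles with enough CpGs
  tile_of <- tile_key(cpg$chrom, (cpg$pos %/% 100) * 100)
  cpg_tab <- table(tile_of)
  cpg_tab <- stats::setNames(as.integer(cpg_tab), names(cpg_tab))
  used <- new.env(); used$keys <- character()
  bodies <- gene_bodies_of(annotation$models)
  proms <- promoters_of(annotation$models)
  split_classes <- function(n, lnc_frac) {
    n_lnc <- round(n * lnc_frac); c(lncRNA = n_lnc, coding = n - n_lnc)
  }
  pick_by_class <- function(targets, n_by_class, what) {
    do.call(rbind, lapply(names(n_by_class), function(cl) {
      .pick_planted(targets[targets$gene_class == cl, , drop = FALSE],
                    n_by_class[[cl]], cpg_tab, used, what = what)
    }))
  }
  # paternal bias: sperm-specific DMRs favour lncRNA hosts, oocyte-specific
  # favour coding hosts
  gdmr_s <- pick_by_class(bodies, split_classes(config$n_gdmr_sperm, 0.67),
                          "sperm G-DMR")
  gdmr_o <- pick_by_class(bodies, split_classes(config$n_gdmr_oocyte, 0.33),
                          "oocyte G-DMR")
  gdmrs <- rbind(
    if (nrow(gdmr_s)) cbind(gdmr_s, gamete = "sperm"),
    if (nrow(gdmr_o)) cbind(gdmr_o, gamete = "oocyte"))
  n_prom_ddmr <- round(config$n_ddmr * config$ddmr_promoter_fraction)
  # distinct host genes for promoter D-DMRs (they seed the network)
  prom_targets <- proms[!duplicated(proms$gene_id), , drop = FALSE]
  ddmr_p <- pick_by_class(prom_targets, split_classes(n_prom_ddmr, 0.64),
                          "promoter D-DMR")
  if (!is.null(ddmr_p) && anyDuplicated(ddmr_p$host_gene)) {
    ddmr_p <- ddmr_p[!duplicated(ddmr_p$host_gene), , drop = FALSE]
  }
  ddmr_b <- pick_by_class(bodies,
                          split_classes(config$n_ddmr - n_prom_ddmr, 0.5),
                          "gene-body D-DMR")
  embryo_stages <- setdiff(stages, c("sperm", "oocyte"))
  ddmrs <- rbind(
    if (!is.null(ddmr_p) && nrow(ddmr_p)) cbind(ddmr_p, placement = "promoter"),
    if (!is.null(ddmr_b) && nrow(ddmr_b)) cbind(ddmr_b, placement = "body"))
  if (!is.null(ddmrs) && nrow(ddmrs)) {
    ddmrs$on_stage <- sample(embryo_stages, nrow(ddmrs), replace = TRUE)
  }

  # apply planted patterns to the CpGs inside each region
  apply_pattern <- function(region_df, kind) {
    for (i in seq_len(NROW(region_df))) {
      sel <- cpg$chrom == region_df$chrom[i] &
        cpg$pos >= region_df$start[i] & cpg$pos < region_df$end[i]
      mu[sel, ] <<- matrix(
        .planted_pattern(kind, stages, region_df$on_stage[i]),
        nrow = sum(sel), ncol = S, byrow = TRUE)
    }
  }
  if (!is.null(gdmrs) && nrow(gdmrs)) {
    apply_pattern(gdmrs[gdmrs$gamete == "sperm", ], "gdmr_sperm")
    apply_pattern(gdmrs[gdmrs$gamete == "oocyte", ], "gdmr_oocyte")
  }
  if (!is.null(ddmrs) && nrow(ddmrs)) apply_pattern(ddmrs, "ddmr")

  # regional per-gene stage means (for the expression generator and truth);
  # the gene-body mean excludes CpGs inside any promoter window so that the
  # planted body coupling is a distal-body signal, not a promoter echo
  region_mean <- function(regions, exclude = NULL) {
    hits <- interval_overlaps(cpg_iv, regions)
    if (!is.null(exclude)) {
      drop_cpg <- unique(S4Vectors::queryHits(interval_overlaps(cpg_iv,
                                                                exclude)))
      hits <- hits[!S4Vectors::queryHits(hits) %in% drop_cpg]
    }
    out <- matrix(NA_real_, nrow(genes), S,
                  dimnames = list(genes$gene_id, stages))
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    tab <- tabulate(s, nbins = nrow(genes))
    for (j in seq_len(S)) {
      acc <- rowsum(mu[q, j], s)
      idx <- as.integer(rownames(acc))
      out[idx, j] <- acc[, 1] / tab[idx]
    }
    out
  }
  regional_means <- list(promoter = region_mean(proms),
                         body = region_mean(bodies, exclude = proms))

  # draw the counts, one sample per stage x replicate
  d <- config$beta_dispersion
  samples <- expand.grid(replicate = seq_len(config$replicates_per_stage),
                         stage = stages, stringsAsFactors = FALSE)
  samples <- samples[order(match(samples$stage, stages), samples$replicate), ]
  samples$sample <- sprintf("%s_rep%d", samples$stage, samples$replicate)
  rownames(samples) <- NULL
  counts <- list()
  for (i in seq_len(nrow(samples))) {
    st <- samples$stage[i]
    cov <- stats::rpois(nrow(cpg), config$coverage_mean)
    keep <- cov > 0
    m <- mu[keep, st]
    p <- stats::rbeta(sum(keep), m / d, (1 - m) / d)
    meth <- stats::rbinom(sum(keep), cov[keep], p)
    df <- data.frame(chrom = cpg$chrom[keep], pos = cpg$pos[keep],
                     meth = as.integer(meth),
                     unmeth = as.integer(cov[keep] - meth))
    attr(df, "sample_id") <- samples$sample[i]
    class(df) <- c("cpg_counts", "data.frame")
    counts[[samples$sample[i]]] <- df
  }
  structure(list(samples = samples[c("sample", "stage", "replicate")],
                 counts = counts,
                 truth = list(gdmrs = gdmrs, ddmrs = ddmrs),
                 regional_means = regional_means),
            class = "sim_methylomes")
}

#' Simulate an expression matrix coupled to promoter methylation
#'
#' Log2 expression of gene g in cell c of stage s is
#' `baseline_g + coupling_slope * promoter_meth(g, s) +
#' coupling_slope_body * body_meth(g, s) + module loading * z(module(g), c)
#' + noise`, exponentiated to FPKM (`2^x`, hence nonnegative). Module genes
#' are drawn from the promoter-D-DMR host genes and share a latent factor
#' per cell.
#'
#' @param annotation A `sim_annotation`.
#' @param methylomes The matching `sim_methylomes`.
#' @param config The same [sim_config()].
#' @return A `sim_expression`: list with `expr` (FPKM matrix, genes x
#'   cells), `samples` (`sample`, `stage`) and `truth`
#'   (`modules`, `coupling`).
#' @export
simulate_expression <- function(annotation, methylomes, config) {
  stopifnot(inherits(annotation, "sim_annotation"),
            inherits(methylomes, "sim_methylomes"))
  set.seed(config$seed + 2L)
  genes <- annotation$models$genes
  stages <- config$stages
  samples <- expand.grid(cell = seq_len(config$expr_cells_per_stage),
                         stage = stages, stringsAsFactors = FALSE)
  samples <- samples[order(match(samples$stage, stages), samples$cell), ]
  samples$sample <- sprintf("%s_cell%d", samples$stage, samples$cell)
  rownames(samples) <- NULL
  n_g <- nrow(genes); n_s <- nrow(samples)

  need <- config$n_coexpr_modules * config$module_size
  pool <- unique(methylomes$truth$ddmrs$host_gene[
    methylomes$truth$ddmrs$placement == "promoter"])
  modules <- NULL
  if (config$n_coexpr_modules > 0) {
    if (length(pool) < need) {
      stop_premeth("only %d promoter-D-DMR host genes for %d module slots; raise n_ddmr or ddmr_promoter_fraction",
                   length(pool), need)
    }
    mg <- sample(pool, need)
    modules <- data.frame(module = rep(sprintf("M%d",
                                               seq_len(config$n_coexpr_modules)),
                                       each = config$module_size),
                          gene = mg)
  }
  module_of <- stats::setNames(rep(NA_character_, n_g), genes$gene_id)
  if (!is.null(modules)) module_of[modules$gene] <- modules$module

  prom_mu <- methylomes$regional_means$promoter[genes$gene_id, , drop = FALSE]
  body_mu <- methylomes$regional_means$body[genes$gene_id, , drop = FALSE]
  prom_mu[is.na(prom_mu)] <- 0.5
  body_mu[is.na(body_mu)] <- 0.5
  baseline <- stats::rnorm(n_g, config$expr_baseline_mean,
                           config$expr_baseline_sd)
  z <- matrix(stats::rnorm(max(config$n_coexpr_modules, 1) * n_s),
              nrow = max(config$n_coexpr_modules, 1),
              dimnames = list(sprintf("M%d", seq_len(max(config$n_coexpr_modules, 1))),
                              samples$sample))
  stage_idx <- match(samples$stage, stages)
  logx <- matrix(baseline, n_g, n_s) +
    config$coupling_slope * prom_mu[, stage_idx, drop = FALSE] +
    config$coupling_slope_body * body_mu[, stage_idx, drop = FALSE]
  has_mod <- !is.na(module_of)
  if (any(has_mod)) {
    logx[has_mod, ] <- logx[has_mod, ] +
      config$module_strength * z[module_of[has_mod], , drop = FALSE]
  }
  logx <- logx + matrix(stats::rnorm(n_g * n_s, 0, config$expr_noise_sd),
                        n_g, n_s)
  expr <- 2^logx
  dimnames(expr) <- list(genes$gene_id, samples$sample)
  coupling <- data.frame(gene = genes$gene_id,
                         slope_promoter = config$coupling_slope,
                         slope_body = config$coupling_slope_body)
  structure(list(expr = expr,
                 samples = samples[c("sample", "stage")],
                 truth = list(modules = modules, coupling = coupling)),
            class = "sim_expression")
}

#' Simulate a complete dataset
#'
#' Runs [generate_annotation()], [simulate_methylomes()] and
#' [simulate_expression()] with one configuration.
#'
#' @param config A [sim_config()].
#' @return A `sim_dataset`: list with `config`, `annotation`, `methylomes`,
#'   `expression` and the combined `truth` tables (`gdmrs`, `ddmrs`,
#'   `modules`, `coupling`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  annotation <- generate_annotation(config)
  methylomes <- simulate_methylomes(annotation, config)
  expression <- simulate_expression(annotation, methylomes, config)
  structure(list(config = config, annotation = annotation,
                 methylomes = methylomes, expression = expression,
                 truth = c(methylomes$truth, expression$truth)),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "sim_dataset: %d CpGs, %d RRBS samples, %d cells, %d planted G-DMRs, %d D-DMRs\n",
    nrow(x$annotation$cpg_sites), length(x$methylomes$counts),
    ncol(x$expression$expr), NROW(x$truth$gdmrs), NROW(x$truth$ddmrs)))
  invisible(x)
}
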