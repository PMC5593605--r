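# premeth

DNA methylation is erased and re-established around fertilization: the
sperm genome arrives highly methylated, the oocyte intermediately so, a
genome-wide demethylation wave bottoms out around the 2-cell stage, and
remethylation follows implantation. `premeth` is an R toolkit for asking
how long noncoding RNA (lncRNA) genes ride this wave compared with
protein-coding genes, from reduced-representation bisulfite sequencing
(RRBS) counts and single-cell expression, for epigenomics analysts who
want every step of that comparison reproducible and testable.

## What it computes

* **Tile methylation** — per-CpG levels `M/(M+U)` with a ≥5× coverage
  filter, pooled into fixed 100-bp tiles; local CpG density (±50 bp);
  stage methylomes as arithmetic replicate means; methylation-status
  fractions (low <20%, intermediate 20–80%, high >80%).
* **G-DMRs** (gamete-specific DMRs) — tiles with mean level >0.75 in one
  gamete and <0.25 in the other, supported by a per-tile two-sample
  Student's t-test across replicates with Benjamini–Hochberg FDR <0.05;
  k-means (k=6) clustering of their developmental dynamics; hypergeometric
  feature enrichment; parental-bias chi-square between gene classes.
* **D-DMRs** (developmental-specific DMRs) — Shannon-entropy specificity
  of the stage profile, `H = −Σ p_s log2 p_s` with
  `p_s = (m_s+ε)/Σ(m_t+ε)`, reflected for hypomethylation specificity;
  tiles with `H` below the threshold (4.22 bits at 32 profiles, rescaled
  by `log2(S)/5` for other widths) are called.
* **TSS meta-profiles** — strand-aware 100-bp binning of methylation and
  CpG density ±5 kb around the TSS, with two-sample Kolmogorov–Smirnov
  comparisons between gene classes.
* **Methylation–expression coupling** — per-stage Pearson correlation
  across genes between promoter (or gene-body) methylation and mean
  `log2(FPKM+1)` expression.
* **CNC network** — coding–noncoding co-expression network: genes filtered
  by max FPKM >5 and top-75% variance, all-pairs Pearson `r` with
  Fisher-asymptotic p (`t = r√(n−2)/√(1−r²)`), edges gated at |r| >0.8 and
  p <0.05 and seeded by promoter-D-DMR genes; topology (degrees, hubs,
  components) and generic hypergeometric gene-set enrichment.
* **Synthetic data** — a fully configurable generator planting all of the
  above (demethylation wave, gamete- and stage-specific DMRs, CpG-poor
  lncRNA promoters, negative promoter-methylation→expression coupling,
  co-expression modules) with ground-truth tables, so recovery is
  measurable.

See `vignettes/premeth-methods.Rmd` for the model details and design
choices.

## Worked example

```r
library(premeth)

# entropy of a tile methylated in one of four stages: highly specific
str(methylation_entropy(c(0.9, 0.05, 0.05, 0.05)))
#> List of 4
#>  $ H          : num 0.828
#>  $ H_raw      : num 0.828
#>  $ H_reflected: num 1.69
#>  $ direction  : chr "hyper"

# simulate the default study conditions and run the whole pipeline
run <- run_pipeline(pipeline_config(out_dir = "premeth_demo", seed = 1))
#> premeth_run: 81 G-DMR tiles, 100 D-DMR tiles, 45 network edges
#>   recovery: G-DMR sens 1.000 / prec 0.988; D-DMR sens 1.000 / bg FPR 0.0000

head(run$gdmr$calls[c("chrom", "start", "end", "gamete",
                      "mean_sperm", "mean_oocyte", "q")], 3)
#>   chrom start   end gamete mean_sperm mean_oocyte          q
#> 1  chr1 20300 20400 oocyte 0.05401228   0.9118693 0.01551644
#> 2  chr1 20400 20500 oocyte 0.07304397   0.9234296 0.01624568
#> 3  chr1 28000 28100 oocyte 0.07549858   0.9178150 0.01875977

run$methexpr$correlations$promoter[1:4, c("stage", "n", "r")]
#>    stage   n          r
#> 1  sperm 200 -0.2589409
#> 2 oocyte 200 -0.3082816
#> 3 zygote 200 -0.2587389
#> 4  2cell 200 -0.2688553
```

The 81 called G-DMR tiles cover all 40 planted gamete-specific regions
(sensitivity 1.00) with one borderline background tile (precision 0.988);
all 30 planted developmental-specific regions are recovered with no
background false call; promoter methylation correlates negatively with
expression in every stage, as planted; and all 45 network edges connect
genes of the same planted co-expression module. `run$config$out_dir`
holds the per-stage TSV tables, `run_report.json` (every threshold used)
and `recovery.json`.

`run_pipeline` also consumes real data: point
`pipeline_config(simulate = FALSE, input_dir = ...)` at a directory with
Bismark coverage files, a GTF/BED12 annotation, feature BEDs, an
expression TSV and a sample table (see `load_fixture()` for the layout).
A thin command-line wrapper with `demo` / `simulate` / `run` subcommands
is installed at `inst/scripts/premeth.R`.

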