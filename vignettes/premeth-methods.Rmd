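---
title: "Methods: tile-based methylation dynamics and the coding-noncoding network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tile-based methylation dynamics and the coding-noncoding network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`premeth` analyses DNA methylation dynamics across pre-implantation
development, contrasting long noncoding RNA (lncRNA) and protein-coding
genes. It takes per-CpG bisulfite counts (Bismark coverage files), gene
annotations (GTF or BED12), feature intervals (CpG islands, exons,
introns) and a gene-by-sample FPKM matrix, and produces: tile and stage
methylomes, gamete-specific DMRs (G-DMRs), developmental-specific DMRs
(D-DMRs), TSS meta-profiles, per-stage methylation-expression
correlations, and a coding-noncoding (CNC) co-expression network seeded by
promoter-D-DMR genes. A synthetic-data generator with planted signal makes
the whole chain testable against ground truth; `run_demo()` exercises it
end to end.

# Quantification model

The level of a CpG is the fraction of reads reporting C among reads
reporting C or T; CpGs with coverage below five are discarded. Tiles are
fixed, non-overlapping 100-bp windows anchored at position 0 of each
chromosome; a tile's level pools the reads of its retained CpGs, which
equals the coverage-weighted mean of their levels (an invariant the test
suite checks against a brute-force oracle). Local CpG density is the count
of CpG sites within 50 bp of a site (self included); a tile's density
averages its contributing CpGs.

Two readings of the coverage filter are possible ("at least" versus "more
than" five-fold); we adopt the inclusive `>= 5` reading uniformly for CpGs
and tile contributions, exposed as `min_cov`. Stage methylomes average
replicate tile levels arithmetically (no coverage weighting), keeping only
tiles covered in every replicate. Region levels average overlapping
retained tile levels, unweighted, mirroring the tile-as-unit
summarization; regions with no covered tile are missing, never zero.

# G-DMR calling

Tiles covered in all sperm and all oocyte replicates are tested with a
two-sample pooled-variance Student's t-test on replicate tile levels, and
Benjamini-Hochberg correction is applied across all tested tiles. A tile
is a G-DMR iff its mean exceeds 0.75 in one gamete, falls below 0.25 in
the other, and q < 0.05. With two replicates per gamete the t-test has two
degrees of freedom and little power on its own; the threshold rule does
most of the selection, which we document rather than "fix". The test
could alternatively be computed across CpGs within a tile; we test across
replicates (the replication structure is what the averaging operates on)
and keep the replicate matrices exposed so either reading is computable.

Dynamics of the called tiles across stages are clustered with k-means
(k = 6 by default, Euclidean distance on raw levels, seeded and restarted
ten times, clusters relabelled in decreasing size order). Stage values
missing for a DMR are imputed by the stage mean over all DMRs - the
simplest defensible completion for a distance-based method. Feature
enrichment of a DMR set against the tested-tile universe uses an
upper-tail hypergeometric test per label with BH across labels. Parental
bias tabulates DMR-hosting genes by class and gamete (gene-body and
promoter assignment reported separately; a DMR overlapping both classes
counts in both and is flagged) and compares classes with the plain Pearson
chi-square statistic (no continuity correction), so the statistic matches
the textbook expected-counts formula exactly.

# D-DMR calling by Shannon entropy

A stage methylation vector `m` is converted to pseudo-probabilities
`p_s = (m_s + eps) / sum(m_t + eps)` (eps = 1e-3 avoids log 0; an all-zero
vector scores maximum entropy and is never called) and scored with
`H = -sum(p_s log2 p_s)` in bits. Low entropy means methylation
concentrated in few stages. Because hypomethylation in few stages is
equally specific, the reflected vector `(max m + min m) - m` is scored too
and the minimum taken; the winning orientation is reported as the
direction. This makes reflection symmetry exact, and H is invariant to
stage permutation and (in the eps -> 0 limit) to positive scaling.

The calling threshold is 4.22 bits, defined for 32-sample profiles
(maximum entropy log2 32 = 5). We treat 4.22 as an opaque configured
constant; because the attainable range depends on the profile width S, the
threshold is rescaled as `4.22 * log2(S) / 5` when S differs from 32, with
a message. On the default nine-stage fixture this gives 2.675 bits. Only
tiles covered in every stage are scored; excluded tiles are counted and
reported.

# Methylation-expression correlation

Per stage, the Pearson correlation is computed across genes between the
region methylation level (promoter, and separately gene body) and stage
expression, where stage expression is the mean of `log2(FPKM + 1)` over
that stage's samples. The pseudocount of 1 is a convention choice (only
the log2 transform itself is essential); correlating on the log scale
matches the generative model of the simulator. Stages with
fewer than three complete gene pairs, or a constant vector on either side,
are reported as missing with a reason rather than as zero.

# CNC network

Construction follows five steps: (1) keep genes with maximal FPKM above 5
and expression variance in the retained top fraction - "variance ranked in
the top 75 percentile" is ambiguous, so the default keeps the top 75% most
variable genes and `var_keep_fraction = 0.25` gives the stricter
top-quartile reading; (2) Pearson correlation for all gene pairs across
all expression samples (cells, not stage means - the sample count enters
the test); (3) a two-sided p-value from Fisher's asymptotic test,
`t = r sqrt(n-2) / sqrt(1-r^2)` on n-2 degrees of freedom; (4) retain
pairs with |r| > 0.8 and raw p < 0.05 (the gate uses raw p-values; a BH
variant would only be stricter); (5) keep pairs with at
least one endpoint in the seed set - genes whose promoter hosts a called
D-DMR ("pairs including" such genes reads as one endpoint sufficing, not
both). Topology reports degrees, connected components and hubs (top 5% of
the degree distribution). Gene-set enrichment is a generic upper-tail
hypergeometric engine over user-supplied term tables with BH within each
table; callers mirroring separate ontology namespaces should pass one
table per namespace so correction stays per family.

# What the generator emulates

The generator's defaults define the study conditions used throughout the
tests: nine stages (sperm, oocyte, zygote, 2-cell, 4-cell, 8-cell,
morula, blastocyst, post-implantation) with two RRBS replicates each, one
1-Mb chromosome carrying 120 coding and 80 lncRNA genes, mean 30x Poisson
coverage per CpG, and four expression cells per stage. These sizes keep a
full demo run in the low minutes on one CPU while leaving roughly 9,000
testable tiles and 48,000 CpGs - large enough for the rate estimates the
recovery report makes.

Structure planted by the generator:

* A background demethylation wave (stage means 0.85, 0.55, 0.45, 0.25,
  0.30, 0.35, 0.40, 0.45, 0.75) - high in sperm, intermediate in oocyte,
  bottoming at the 2-cell stage, remethylated post-implantation. The wave
  is qualitative - the stage means were chosen once to give that shape with
  realistic spacing - and must not be read as reproducing published
  measurements.
* Per-gene promoter and gene-body offsets, uniform on +/-0.18, with a
  +0.08 shift for lncRNA promoters (lncRNA promoters run hotter). Offsets
  of this size cannot satisfy both G-DMR thresholds (sperm > 0.75 needs an
  offset above -0.10, oocyte < 0.25 needs one below -0.30), so background
  tiles are excluded from G-DMR calls by construction, and their stage
  vectors stay comfortably above the rescaled entropy threshold.
* 20 sperm-specific and 20 oocyte-specific G-DMRs (two consecutive tiles
  each, at least three CpGs per tile), gamete means 0.92/0.08. Sperm DMRs
  favour lncRNA hosts and oocyte DMRs coding hosts (67/33 versus 33/67),
  echoing the paternal bias the analysis measures. Margins are set so the
  threshold rule is met deterministically at the default dispersion.
* 30 D-DMRs methylated (0.90) in exactly one embryonic stage and 0.05
  elsewhere; 70% sit in promoters (lncRNA-biased 64/36), the rest in gene
  bodies. Promoter D-DMR host genes are the seed pool for the network.
* Expression: `log2 FPKM = baseline + slope_promoter * promoter_meth +
  slope_body * distal_body_meth + module loading * factor + noise`, with
  slope_promoter = -2 and slope_body = +3. The body coupling acts on the
  promoter-excluded gene-body mean: gene bodies overlap their promoters,
  so a coupling on the full-body mean would be dominated by the (CpG-dense,
  negatively coupled) promoter window and the planted positive body signal
  would not be observable in the measured full-body correlation. Three
  six-gene modules drawn from the promoter-D-DMR hosts share a per-cell
  latent factor with loading 2.5 against noise sd 0.6, putting expected
  pairwise |r| well above the 0.8 edge gate.

Per-CpG counts are beta-binomial: coverage is Poisson(30) (zero-coverage
CpGs are simply absent from that sample's file, as in real coverage
output), the per-CpG level is Beta(mu/d, (1-mu)/d) with d = 0.02 around
the regional stage mean, and methylated reads are binomial. CpG placement
rates (background 0.01/bp, gene bodies +0.03, coding promoters +0.07,
lncRNA promoters +0.02, CGIs +0.05) give lncRNA promoters visibly lower
CpG density.

What the generator does not emulate: reads or bisulfite conversion
chemistry, allele-resolved (parent-of-origin) methylation, non-CpG
methylation, RRBS fragment-selection bias, isoform complexity (one
transcript per gene) or hg19-scale genomes. Passing recovery tests
therefore demonstrates that the pipeline's rules and statistics are
implemented correctly under their stated assumptions, not that the
pipeline would reproduce published genome-scale counts on real
accessions; the published headline figures depend on the real data and
full annotation and are out of reach at desk scale by design.

# Numerical choices and degenerate inputs

Zero pooled variance in the G-DMR t-test (possible with two replicates)
is resolved by p = 1 for identical means and p = 0 for distinct means (a
degenerate perfect separation). Perfect correlation in the network test is
assigned p = 0 without dividing by zero. Hypergeometric p-values are
computed with the stable `phyper` tail, which the tests verify against
exhaustive enumeration for universes up to 25. K-S comparisons use the
asymptotic two-sample test (tile-level samples are large and tied values
are tolerated). All internal coordinates are 0-based half-open, converted
at each reader/writer to the native dialect of the format (Bismark
coverage and GTF are 1-based inclusive; BED is 0-based half-open);
overlap anywhere means at least one shared base. TSS profiles use
contiguous 100-bp bins (step = width): a sliding variant would need an
arbitrary step choice, and contiguous bins keep bins independent;
tiles contribute to the bin holding their midpoint, with minus-strand
genes mirrored so positive offsets are downstream. Gene models collapse
transcripts to the longest isoform's TSS - one TSS per gene is required
and the choice is otherwise unconstrained.

One calibration caveat: with small discrete universes, hypergeometric
p-values are conservative, so under a global null the BH procedure
rejects well below the nominal 5% of terms. The calibration test asserts
the attainable property - a rejection rate bounded by the nominal level
(with binomial slack), q monotone in p and never below p, and null
p-values that are not anti-conservative - rather than equality with 5%,
which discreteness rules out.

# Problem sizes used by the checks

The shipped tests and the acceptance script run the default conditions
above: ~48,000 CpGs by 18 RRBS samples, ~9,000 tested tiles, 200 genes by
36 cells, 1,000-repeat null calibration. The recovery report computes
planted G-DMR sensitivity and precision, planted D-DMR sensitivity, the
background false-call rate (over tiles overlapping no planted region of
any kind - planted G-DMR tiles are genuinely stage-dynamic and are
legitimately picked up by the entropy rule, so they are excluded from the
false-call denominator), per-stage correlation signs, and network edge
precision against the planted modules.

# Known limitations

The G-DMR caller assumes replicate-level variation is informative despite
tiny replicate numbers; the entropy threshold rescaling is a proportional
heuristic, not a data-driven recalibration of the threshold;
promoter definitions ignore alternative TSSs; and the network's Fisher
test assumes approximately bivariate-normal log expression, which planted
modules satisfy but real single-cell data often will not.

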