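---
title: "TAD-aware analysis of grade-specific gene regulation: models and methods"
author: "gliotad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TAD-aware analysis of grade-specific gene regulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliotad)
```

# Scope

`gliotad` implements a statistical pipeline for studying how gene regulation
changes across glioma malignancy grades — pilocytic astrocytoma (PA, WHO I),
diffuse astrocytoma (DA, WHO II/III) and glioblastoma (GBM/pGBM, WHO IV,
adult and pediatric pooled) — organised around topologically associating
domains (TADs). The pipeline consumes per-sample count matrices (RNA-seq and
promoter-level H3K4me3, H3K27ac, H3K27me3, ATAC, DNase signal), per-cytosine
methylation beta values, a TAD segmentation, chromatin contact pairs and a
sample sheet, and produces differential calls, TAD-level enrichment and
homogeneity statistics, bivalent-chromatin gene sets, gene–enhancer links
with grade-specific activity tests, and envelope-filtered TF–target
correlations. A synthetic-cohort generator with ground truth makes every
stage testable end to end without any external download.

# Statistical models and procedures

## Differential calling

The built-in caller is rank-based: per feature, a two-sided
Mann–Whitney–Wilcoxon test between two grade groups on library-size
normalised values (counts per million), followed by Bonferroni or
Benjamini–Hochberg correction, with significance at corrected $p < \alpha$
(default $\alpha = 0.01$). Results from an external negative-binomial GLM
caller can be injected verbatim through the same five-column table schema
(`read_differential()`), so the rest of the pipeline is agnostic to the
caller. Log2 fold changes are
$\log_2\left(\frac{\bar{x}_2 + c}{\bar{x}_1 + c}\right)$ with pseudocount
$c = 1$ by default; the pseudocount guards all-zero features and is
configurable because no canonical value exists.

The Mann–Whitney p-value uses the exact distribution when both groups have
at most 8 observations and the pooled values are tie-free, and the normal
approximation with tie and continuity correction otherwise. The exact
branch makes small-sample results reproducible against enumeration of all
rank assignments; the approximation is what cohort-scale group sizes
(7–15 samples) require. A fully tied feature carries no ordering
information and is reported at $p = 1$.

## Promoters, TADs and enrichment

Promoters are symmetric windows of TSS ± 2 kb (strand-agnostic by
construction), clipped at the chromosome start. A gene belongs to a TAD iff
its canonical TSS lies inside the TAD interval under half-open semantics;
genes outside all TADs are excluded from TAD statistics. Membership is by
TSS point rather than gene-body overlap because genes can straddle TAD
borders and the promoter is the regulatory anchor of the analysis.

TAD enrichment for differential genes uses the binomial upper tail
$P(X \ge k)$, $X \sim \mathrm{Bin}(n_\mathrm{genes}, p_0)$, where $p_0$ is
the global share of flagged genes among all TAD-assigned genes, computed
once. TADs with fewer than 3 genes are excluded before BH correction;
enrichment requires corrected $p < 0.05$. The background is computed over
TAD-assigned genes (not all annotated genes) so the test is self-consistent
within its own universe.

## Fold-change homogeneity within TADs

Whether genes in the same TAD shift together between grades is tested with
a Kruskal–Wallis statistic on log2 fold changes grouped by TAD, with
tie correction, plus a permutation null: fold-change values are shuffled
among TADs preserving each TAD's gene count, and
$p = (1 + \#\{H_\mathrm{perm} \ge H_\mathrm{obs}\})/(B + 1)$. The
permutation loop recomputes $H$ from the pooled ranks, which are invariant
under label permutation, so only group sums change per replicate; a unit
test pins this fast statistic to `kruskal.test`. All permutation and
bootstrap p-values in the package use the $(k+1)/(n+1)$ estimator and are
therefore never exactly zero.

## Expression–mark correlation with matched backgrounds

Per differential gene, the Spearman correlation across patients between
expression and promoter mark signal. Constant vectors have undefined rank
correlation; such records are `NA` and excluded from medians rather than
coerced to zero, which would bias summaries toward the null. Gene sets with
high correlation use a strict $\rho > 0.7$ cutoff.

Random background sets are drawn from active genes (mean raw count ≥ 10
across all samples) under the constraint that the background set's overall
mean expression is at least that of the differential set — a set-level
constraint, which is what the procedure states, not per-gene matching,
which would be stricter. Implementation: rejection sampling of whole sets
(cap 100), then a decile-stratified draw repaired upward by swapping in
high-expression genes; genuine infeasibility (even the top-$k$ pool genes
cannot reach the target mean) is an error. The DEG/DEM overlap bootstrap
replaces the expression set by matched backgrounds and reports the
probability of matching or exceeding the observed overlap.

## Bivalent chromatin and TAD overlap

Genes are ranked by summarised promoter H3K4me3 and H3K27me3 signal (mean
across the group's samples by default, median switchable — the summary
statistic is not canonical); the top 1000 of each ranking are intersected
with each other and with the differential set. Ties at the top-$n$ boundary
break lexicographically by gene id so runs are deterministic. The overlap
between enriched TADs and TADs carrying bivalent differential genes is
tested with the hypergeometric upper tail over the universe of TADs that
passed the ≥ 3 gene filter (the universe is configurable; the tested set is
the natural default because both margins are defined only there).

## Enhancers, contacts and grade-specific activity

Enhancers are H3K27ac peaks lying outside all promoter windows; a single
shared base with any promoter excludes a peak. A contact pair supports a
(gene, enhancer) link iff one anchor overlaps the gene's promoter and the
other overlaps the enhancer, in either orientation, with the
promoter–enhancer midpoint distance ≤ 2 Mb. Each contact counts once per
pair even if both orientations match; contact scores are ignored when
counting (score weighting is a possible extension). Genes are classed by
total supporting contacts: none (0), few (1–5), multi (≥ 6), and per-gene
mean expression is compared between multi and few classes with the same
rank test.

Grade-specific enhancer activity (acetylation, and mean CpG methylation
within the enhancer) is tested per region with a two-sided Mann–Whitney
test at raw $p < 0.01$ — deliberately uncorrected, mirroring the stated
procedure; a BH option exists but is off by default. Samples without
covered CpGs in an enhancer get an undefined mean beta and drop out of
correlations. The correlation permutation null randomly re-pairs gene
expression vectors with enhancer acetylation vectors (not within-sample
labels — the pairing itself is what the null breaks) and records the mean
correlation per replicate, 100 replicates by default.

## TF–target envelope filter

For externally supplied candidate (TF, target) pairs, the Spearman
correlation between the TF-coding gene's expression and the target's
expression is compared against an envelope built per TF from 100 random
active genes (real targets excluded): a pair is retained iff its
correlation exceeds the envelope maximum or falls below the envelope
minimum (the negative branch retains repressors). The envelope is per TF,
not global, because each TF's expression profile sets its own chance
correlation scale. Both per-pair decisions and per-TF median correlations
are reported, since the retention rule can reasonably be read either way.

# The synthetic cohort generator

`simulation_config()` / `simulate_cohort()` emulate the joint structure the
analysis assumes:

- **Genome**: `n_tads` TADs tile `n_chrom` chromosomes without gaps; each
  TAD carries exactly `genes_per_tad` genes with uniformly placed,
  strand-labelled TSSs, so gene–TAD membership is unambiguous by
  construction.
- **Cohort**: group sizes default to PA 11, DA 7, GBM 15 — the study design
  this package targets, with the single pediatric GBM pooled into GBM.
- **Expression**: negative binomial with per-gene log-normal baseline means
  (meanlog $= \log 100$, sdlog 1) and variance $\mu + \mu^2\phi$. A
  fraction `frac_deg` of genes (default 0.1) carries a grade effect of
  magnitude `lfc_effect` (default 2 in log2 units) applied progressively
  along the grade axis and centred, so the extreme-grade ratio is
  $2^{\mathrm{lfc}}$ while the gene's overall mean stays pool-comparable —
  uncentred effects would make expression-matched backgrounds infeasible by
  construction. A fraction `tad_coupling` of true differential genes is
  concentrated in `n_enriched_tads` spiked TADs; the rest scatter.
- **Dispersion calibration**: $\phi = 0.1$. At the cohort's group sizes
  (11 vs 15) and a 2-fold effect, the Mann–Whitney power at raw
  $p < 0.01$ is analytically ≈ 0.86 at $\phi = 0.1$ and ≈ 0.68 at
  $\phi = 0.2$; the generator is calibrated so that a 2-fold shift is
  recoverable at ≥ 80% sensitivity, which is the operating regime the
  pipeline's validation assumes.
- **Promoter marks**: a Gaussian rank copula against realised expression
  with target Spearman `mark_coupling_rho` (default 0.7; H3K27me3 coupled
  at the negative of that value, as a repressive mark), using the latent
  correlation $r = 2\sin(\pi\rho_s/6)$. The copula controls the rank
  correlation directly, which matters because the pipeline's correlation
  claims are rank-based.
- **Enhancers**: `n_enhancers` peaks placed outside promoter windows; a
  fraction `frac_diff_enhancers` receives a centred grade shift in
  acetylation. Contacts link each gene's promoter to Poisson-many eligible
  enhancers (same chromosome, within 2 Mb). Enhancer CpG betas come from a
  Beta(5, 5) quantile transform of a latent negatively coupled to the
  enhancer's acetylation ranks at strength `methyl_anticorr`.
- **Reproducibility**: one seed per cohort; each data type draws from its
  own sub-stream at a fixed offset of $10^6$ per type, so adding a data
  type never perturbs the others and cohorts with nearby seeds share no
  stream.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: library-size heterogeneity between samples,
batch effects, copy-number alterations, IDH-status substructure within DA,
overdispersion heterogeneity across genes, peak-calling noise, bisulfite
coverage variation, and any sequence-level signal. Results on synthetic
cohorts validate the statistics' calibration and power under the assumed
model, not biological conclusions.

# Numerical choices and degenerate inputs

- Coordinates are uniformly 0-based half-open internally; published
  1-based inclusive coordinates convert at the I/O boundary only.
  Chromosome names match as exact strings, with an optional `chr`-prefix
  normalisation at load.
- Overlapping TADs are a load-time error (every TAD statistic assumes a
  partition); inter-chromosomal contact pairs are dropped with a count.
- Peaks spanning several regions contribute their full value to each
  region (no proportional split) — the simplest defensible rule given no
  stated splitting convention.
- All-tied rank tests report $p = 1$; all-equal fold-change vectors report
  $H = 0$, $p = 1$; constant correlation vectors report `NA` and are
  excluded from medians.
- Permutation comparisons use `H_perm >= H_obs - 1e-12` so floating-point
  ties count toward the null, keeping p-values conservative.
- Top-$n$ selections break ties by gene id; every pipeline stage is
  deterministic given the configuration seed.

# Problem sizes used in validation

The package's own validation runs at desk scale: calibration on 200 null
cohorts of 50 TADs × 10 genes (permutation null at $B = 499$, script at
$B = 299$ over 100 cohorts), enrichment recovery on 300-TAD genomes with
20 genes per TAD over 20 seeds, correlation recovery at 33 samples and 500
genes, and envelope-filter operating characteristics over 20 simulations of
160 genes. At 10 genes per TAD the binomial enrichment test has analytic
per-TAD power 0.63 under the recovery scenario's flag probabilities (0.6
inside vs 0.1 outside), so recovery analyses use 20 genes per TAD, where
the power is 0.979; this is a property of the binomial tail at the BH
threshold, not of the implementation.

# Known limitations

- The rank-based caller is a deliberate simplification of NB-GLM callers;
  no dispersion shrinkage, no covariates (a subgroup analysis is expressed
  as the same comparison on a sample subset).
- `normalized counts` is implemented as counts per million (switchable
  off); other normalisations affect rank tests only through ties but do
  shift fold-change magnitudes.
- Motif discovery, survival screens, GO enrichment, Hi-C loop calling and
  CNA analysis are out of scope; their outputs enter as plain input tables
  where the pipeline needs them.
- The hypergeometric TAD-overlap universe and the per-assay scope of BH
  correction are configurable because neither has a single canonical
  definition.
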