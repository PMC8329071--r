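# gliotad

TAD-aware statistical analysis of grade-specific gene regulation in glioma.

Gliomas of increasing WHO grade — pilocytic astrocytoma (PA), diffuse
astrocytoma (DA), glioblastoma (GBM/pGBM) — differ not only in which genes
they express but in how that expression is organised along the genome.
`gliotad` asks where regulation changes *spatially*: are differentially
expressed genes (DEGs) and differential promoter marks (H3K4me3, H3K27ac,
H3K27me3, ATAC, DNase, CpG hypermethylation) clustered into particular
topologically associating domains (TADs), do genes within a TAD shift
together between grades, which enhancers contact which DEGs through
chromatin loops, and which of those enhancers change activity with grade?

It is written for computational biologists who have grade-labelled count
matrices, a TAD segmentation, and chromatin contact pairs, and want the
domain-level statistics — plus a fully synthetic cohort generator with
ground truth so every stage can be validated without any external data.

## The statistics at the core

- **Differential calling** — per feature, a two-sided Mann–Whitney test
  between grade groups on CPM-normalised counts, Bonferroni or
  Benjamini–Hochberg corrected, significant at corrected *p* < 0.01; log2
  fold changes log2((x̄₂+c)/(x̄₁+c)). External (e.g. NB-GLM) calls can be
  injected through the same table schema.
- **TAD enrichment** — for each TAD with ≥ 3 genes, P(X ≥ k) with
  X ~ Binomial(n_genes, p₀), p₀ the global share of flagged genes among
  TAD-assigned genes; BH across TADs, enriched at adjusted *p* < 0.05.
- **Fold-change homogeneity** — Kruskal–Wallis on log2 fold changes grouped
  by TAD, with a permutation null that shuffles values among TADs
  preserving TAD sizes; p = (1 + #{H_perm ≥ H_obs}) / (B + 1).
- **Expression–mark correlation** — Spearman ρ across patients at DEG
  promoters, compared against expression-matched random gene sets and a
  bootstrap overlap test; high-correlation selection at ρ > 0.7.
- **Bivalent chromatin** — intersection of the top-1000 genes by promoter
  H3K4me3 and by H3K27me3 with the DEG set; hypergeometric overlap of the
  resulting TADs with the enriched "glioma TADs".
- **Enhancer analysis** — enhancers are H3K27ac peaks outside TSS ± 2 kb
  promoter windows; contact pairs link them to DEG promoters within 2 Mb;
  genes are classed by contact multiplicity (none / 1–5 / ≥ 6);
  grade-specific acetylation and enhancer CpG methylation are tested at raw
  Mann–Whitney *p* < 0.01; linked expression–acetylation correlations are
  compared to a 100-replicate random re-pairing null.
- **TF–target filter** — a candidate TF–target correlation is retained only
  if it escapes the envelope (min, max) of that TF's correlations with 100
  random active genes.

## Worked example

```r
library(gliotad)

cfg    <- simulation_config(seed = 1)   # 100 TADs x 5 genes, PA 11 / DA 7 / GBM 15
cohort <- simulate_cohort(cfg)

deg <- rank_test_differential(cohort$expression, cohort$samples,
                              "PA", "GBM", correction = "bh", alpha = 0.01)
sum(deg$significant)
#> [1] 50

asg <- assign_genes_to_tads(cohort$genes, cohort$tads)
enr <- tad_enrichment(asg, deg$feature_id[deg$significant])
subset(enr, enriched)
#>      tad_id n_genes n_flagged background_prob p_raw p_adj enriched
#> 29 tad_0029       5         5             0.1 1e-05 2e-04     TRUE
#> 38 tad_0038       5         5             0.1 1e-05 2e-04     TRUE
#> 40 tad_0040       5         5             0.1 1e-05 2e-04     TRUE
#> 79 tad_0079       5         5             0.1 1e-05 2e-04     TRUE
#> 87 tad_0087       5         5             0.1 1e-05 2e-04     TRUE
```

The cohort was simulated with 5 spiked TADs and 80% of its 50 true DEGs
concentrated there; the enrichment test recovers exactly those five
(`cohort$truth$tads` confirms), each with all 5 genes flagged against a 10%
background, at binomial p = 1e-05 and BH-adjusted p = 2e-04.

```r
rec <- gene_mark_correlations(cohort$expression, cohort$marks$H3K27ac,
                              deg$feature_id[deg$significant])
median(rec$rho, na.rm = TRUE)
#> [1] 0.68
```

The generator couples promoter H3K27ac to expression at Spearman ρ = 0.7
through a rank copula; the recovered median across the 50 DEGs is 0.68.

```r
set.seed(1)
fc  <- log2_fold_changes(cohort$expression, cohort$samples, "PA", "GBM")
hom <- permutation_homogeneity(fc, asg, n_perm = 1000)
c(H = hom$statistic, p = hom$p_permutation)
#>         H         p
#> 113.94409   0.10789
```

With only 5 of 100 TADs carrying concerted shifts, the genome-wide
homogeneity permutation test stays non-significant (p ≈ 0.11) — it detects
broad within-TAD co-regulation, not a handful of spiked domains, which is
precisely what the enrichment test is for.

The whole pipeline (differential → correlation → TAD statistics → bivalent
→ enhancers → TF filter) runs from one call, writing per-stage TSVs and a
manifest with checksums:

```r
run_pipeline(cohort, pipeline_config(rng_seed = 1), outdir = "run1")
```

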