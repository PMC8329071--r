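make_assignment <- function(tad_sizes) {
  genes <- data.frame(
    gene_id = paste0("g", seq_len(sum(tad_sizes))),
    chrom = "chr1", strand = "+",
    tss = seq_len(sum(tad_sizes)) * 10, stringsAsFactors = FALSE)
  ends <- cumsum(tad_sizes) * 10 + 5
  starts <- c(0, ends[-length(ends)])
  tads <- genomic_intervals(names(tad_sizes), "chr1", starts, ends)
  assign_genes_to_tads(genes, tads)
}

test_that("TAD enrichment reproduces the binomial upper tail", {
  asg <- make_assignment(c(t1 = 5, t2 = 5, t3 = 2, t4 = 38))
  # flag 3/5 genes in t1, background 5/50 = 0.1
  flagged <- c(asg$tad2genes$t1[1:3], asg$tad2genes$t4[1:2])
  enr <- tad_enrichment(asg, flagged, alpha = 0.05, min_genes = 3)
  r1 <- enr[enr$tad_id == "t1", ]
  expect_equal(r1$background_prob, 0.1)
  expect_equal(r1$p_raw, 0.00856, tolerance = 1e-8)
  expect_equal(enr$p_raw[enr$tad_id == "t2"], 1)     # zero flagged
  expect_true(is.na(enr$p_raw[enr$tad_id == "t3"]))  # < 3 genes excluded
  expect_true(is.na(enr$p_adj[enr$tad_id == "t3"]))
  expect_false(enr$enriched[enr$tad_id == "t3"])
})

test_that("enrichment p-values equal brute-force pmf summation", {
  set.seed(17)
  g <- generate_genome(simulation_config(n_tads = 40, genes_per_tad = 8,
                                         seed = 17))
  asg <- assign_genes_to_tads(g$genes, g$tads)
  flagged <- sample(g$genes$gene_id, 60)
  enr <- tad_enrichment(asg, flagged)
  for (i in which(!is.na(enr$p_raw))) {
    expect_equal(enr$p_raw[i],
                 binom_upper_tail(enr$n_flagged[i], enr$n_genes[i],
                                  enr$background_prob[i]),
                 tolerance = 1e-12)
  }
})

test_that("flagged genes outside all TADs are dropped with a message", {
  asg <- make_assignment(c(t1 = 4, t2 = 4))
  expect_message(tad_enrichment(asg, c("g1", "stranger")), "outside all TADs")
})

test_that("KW homogeneity handles signal, degeneracy and the rank formula", {
  asg <- make_assignment(c(t1 = 2, t2 = 2))
  fc <- setNames(c(1, 2, 3, 4), paste0("g", 1:4))
  res <- kw_homogeneity(fc, asg)
  expect_equal(res$statistic, 2.4)  # 12/20*(9/2 + 49/2) - 15
  expect_equal(res$statistic,
               unname(kruskal.test(unname(fc),
                                   factor(c(1, 1, 2, 2)))$statistic))
  # all values identical: degenerate, reported as no heterogeneity
  res0 <- kw_homogeneity(setNames(rep(1, 4), paste0("g", 1:4)), asg)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_asymptotic, 1)
  expect_error(kw_homogeneity(fc[1:2], asg), ">= 2 TADs")
})

test_that("fast permutation statistic agrees with kruskal.test", {
  set.seed(23)
  asg <- make_assignment(c(a = 6, b = 9, c = 5))
  for (i in 1:20) {
    fc <- setNames(round(rnorm(20), 1), paste0("g", 1:20))  # forces ties
    obs <- kw_homogeneity(fc, asg)
    d <- gliotad:::prepare_homogeneity(fc, asg)
    h <- gliotad:::kw_stat_from_ranks(rank(d$values), d$groups,
                                      gliotad:::kw_tie_correction(d$values),
                                      length(d$values))
    expect_equal(h, obs$statistic, tolerance = 1e-10)
  }
})

test_that("permutation homogeneity is rank-based and detects TAD structure", {
  set.seed(29)
  asg <- make_assignment(setNames(rep(5, 10), paste0("t", 1:10)))
  # strong within-TAD homogeneity: each TAD has its own fold-change level
  fc <- setNames(rep(rnorm(10, sd = 3), each = 5) + rnorm(50, sd = 0.1),
                 paste0("g", 1:50))
  res <- suppressWarnings(permutation_homogeneity(fc, asg, n_perm = 999))
  expect_lte(res$p_permutation, 0.01)
  # invariance under monotone transformation of the fold changes
  set.seed(101); r1 <- permutation_homogeneity(fc, asg, n_perm = 200)
  set.seed(101); r2 <- permutation_homogeneity(exp(fc), asg, n_perm = 200)
  expect_equal(r1$p_permutation, r2$p_permutation)
  expect_equal(r1$statistic, r2$statistic)
  expect_error(permutation_homogeneity(fc, asg, n_perm = 0), ">= 1")
})

test_that("TAD-level fold-change correlation hits the deterministic poles", {
  asg <- make_assignment(setNames(rep(3, 5), paste0("t", 1:5)))
  expr_fc <- setNames(rnorm(15), paste0("g", 1:15))
  res <- tad_fc_correlation(expr_fc, expr_fc, asg)
  expect_equal(res$rho, 1)
  expect_equal(tad_fc_correlation(expr_fc, -expr_fc, asg)$rho, -1)
  expect_error(tad_fc_correlation(expr_fc[1:3], expr_fc[1:3],
                                  make_assignment(c(t1 = 3, t2 = 3))),
               "fewer than 3")
})

test_that("coupled cohorts give positive TAD-level correlation", {
  co <- simulate_cohort(simulation_config(n_tads = 300, genes_per_tad = 3,
                                          chrom_length = 2e8,
                                          mark_coupling_rho = 0.7, seed = 41))
  asg <- assign_genes_to_tads(co$genes, co$tads)
  fc <- log2_fold_changes(co$expression, co$samples, "PA", "GBM")
  mfc <- log2_fold_changes(co$marks$H3K27ac, co$samples, "PA", "GBM")
  res <- tad_fc_correlation(fc, mfc, asg)
  expect_gt(res$rho, 0.3)
})

test_that("bivalent selection intersects top mark ranks with DEGs", {
  n <- 2000
  ids <- sprintf("g%04d", seq_len(n))
  # genes 1..1000 top in both marks; of those, 54 are DEGs
  k4 <- matrix(rep(n:1, 2), n, 2, dimnames = list(ids, c("s1", "s2")))
  k27 <- matrix(rep(c(rep(2, 1000), rep(1, 1000)), 2), n, 2,
                dimnames = list(ids, c("s1", "s2")))
  degs <- ids[c(1:54, 1500:1600)]
  out <- bivalent_genes(signal_matrix(k4, "H3K4me3"),
                        signal_matrix(k27, "H3K27me3"), degs, top_n = 1000)
  expect_length(out, 54)
  expect_setequal(out, ids[1:54])
  # top in one mark only is excluded
  k27_flipped <- k27[rev(seq_len(n)), , drop = FALSE]
  rownames(k27_flipped) <- ids
  out2 <- bivalent_genes(signal_matrix(k4, "H3K4me3"),
                         signal_matrix(k27_flipped, "H3K27me3"),
                         degs, top_n = 1000)
  expect_length(out2, 0)
  expect_message(bivalent_genes(signal_matrix(k4, "H3K4me3"),
                                signal_matrix(k27, "H3K27me3"), degs,
                                top_n = 5000), "all")
})

test_that("hypergeometric TAD overlap matches subset enumeration", {
  u <- paste0("t", 1:10)
  p <- tad_overlap_hypergeom(u[1:4], c(u[1], u[2], u[9]), u)
  expect_equal(p, 1 / 3)  # (C(4,2)C(6,1)+C(4,3))/C(10,3) = 40/120
  expect_equal(tad_overlap_hypergeom(u[1:4], u[9:10], u), 1)
  set.seed(13)
  for (i in 1:20) {
    n <- sample(6:12, 1)
    uni <- paste0("t", seq_len(n))
    enriched <- sample(uni, sample(1:(n - 1), 1))
    marked <- sample(uni, sample(1:(n - 1), 1))
    k <- length(intersect(enriched, marked))
    expect_equal(tad_overlap_hypergeom(enriched, marked, uni),
                 enumerate_hyper_p(uni, enriched, length(marked), k),
                 tolerance = 1e-12)
  }
  expect_error(tad_overlap_hypergeom("t1", "t1", character()), "empty")
  expect_error(tad_overlap_hypergeom("zz", "t1", u), "subsets")
})
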