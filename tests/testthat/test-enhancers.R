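peak_fixture <- function() {
  promoters <- genomic_intervals(c("gA", "gB"), "chr1",
                                 c(8000, 50000), c(12000, 54000))
  peaks <- genomic_intervals(
    c("inside", "far", "edge"), "chr1",
    c(9000, 30000, 11999), c(9500, 30500, 13000))
  sig <- signal_matrix(
    matrix(1, 3, 4, dimnames = list(peaks$id, paste0("s", 1:4))), "H3K27ac")
  list(promoters = promoters, peaks = peaks, sig = sig)
}

test_that("enhancer calling excludes any promoter-overlapping peak", {
  fx <- peak_fixture()
  enh <- call_enhancers(fx$peaks, fx$sig, fx$promoters)
  # a single shared base (11999 in [8000,12000)) is enough to exclude
  expect_equal(enh$intervals$id, "far")
  expect_equal(rownames(enh$acetylation), "far")
  # invariant: no retained enhancer overlaps any promoter
  for (i in seq_len(nrow(enh$intervals))) {
    expect_length(overlap_query(fx$promoters, enh$intervals$chrom[i],
                                enh$intervals$start[i], enh$intervals$end[i]),
                  0)
  }
})

test_that("gene-enhancer linking counts supporting contacts within 2 Mb", {
  promoters <- genomic_intervals("gA", "chr1", 8000, 12000)
  enhancers <- genomic_intervals(c("e_near", "e_far"), "chr1",
                                 c(1000000, 2600000), c(1001500, 2601500))
  contacts <- data.frame(
    chrom = "chr1",
    start_a = c(9000, 9000, 1000100, 9000),
    end_a = c(9100, 9200, 1000200, 9100),
    start_b = c(1000000, 1000500, 9500, 2600000),
    end_b = c(1000100, 1000600, 9600, 2600100),
    score = NA_real_)
  links <- link_genes_to_enhancers(promoters, enhancers, contacts, 2e6)
  expect_equal(nrow(links), 1)
  expect_equal(links$gene_id, "gA")
  expect_equal(links$enhancer_id, "e_near")  # e_far ~2.59 Mb away, filtered
  expect_equal(links$n_contacts, 3L)  # both orientations + duplicate support
  expect_lte(links$distance, 2e6)
})

test_that("linking agrees with the brute-force matcher on small cohorts", {
  cfg <- simulation_config(n_tads = 10, genes_per_tad = 5, n_enhancers = 25,
                           contacts_per_gene = 2, seed = 33)
  co <- generate_cohort(generate_genome(cfg), cfg)
  promoters <- make_promoters(co$genes, 2000)
  enh <- co$enhancers$intervals
  links <- link_genes_to_enhancers(promoters, enh, co$contacts, 2e6)
  oracle <- brute_links(promoters, enh, co$contacts, 2e6)
  expect_equal(links[, c("gene_id", "enhancer_id", "n_contacts")],
               oracle[, c("gene_id", "enhancer_id", "n_contacts")],
               ignore_attr = TRUE)
  # every link satisfies chromosome and distance constraints
  expect_true(all(links$distance <= 2e6))
  expect_true(all(links$chrom ==
                    promoters$chrom[match(links$gene_id, promoters$id)]))
})

test_that("contact classes follow the published multiplicity bounds", {
  links <- data.frame(
    gene_id = c("g6", "g6", "g5", "g1"),
    enhancer_id = c("e1", "e2", "e3", "e4"),
    chrom = "chr1", n_contacts = c(3L, 3L, 5L, 1L), distance = 1e5)
  cls <- contact_classes(links, genes = c("g6", "g5", "g1", "g0"))
  expect_equal(cls$class[cls$gene_id == "g6"], "multi")  # 3 + 3 = 6
  expect_equal(cls$class[cls$gene_id == "g5"], "few")    # 5
  expect_equal(cls$class[cls$gene_id == "g1"], "few")
  expect_equal(cls$class[cls$gene_id == "g0"], "none")
})

test_that("expression comparison between classes uses the exact rank test", {
  expr <- matrix(rep(c(1, 2, 3, 10, 11, 12), 2), 6, 2,
                 dimnames = list(paste0("g", 1:6), c("s1", "s2")))
  cls <- data.frame(gene_id = paste0("g", 1:6),
                    total_contacts = c(1, 1, 1, 9, 9, 9),
                    class = rep(c("few", "multi"), each = 3))
  res <- compare_expression_by_class(expr, cls)
  expect_equal(res$p, 0.1)  # 3 vs 3 complete separation
  expect_gt(res$median_multi, res$median_few)
  expect_error(compare_expression_by_class(expr, cls[cls$class == "few", ]),
               ">= 2 genes")
})

test_that("differential region significance uses a strict raw-p cutoff", {
  samples <- tiny_samples(3, 3)
  flat <- matrix(5, 2, 6, dimnames = list(c("r1", "r2"), samples$sample_id))
  res <- differential_region_signal(flat, samples, "PA", "GBM", alpha = 0.01)
  expect_false(any(res$significant))
  # complete separation at 3v3 gives exactly p = 0.1: strict < excludes it
  sep <- matrix(c(1, 2, 3, 10, 11, 12), 1, 6,
                dimnames = list("r1", samples$sample_id))
  res <- differential_region_signal(sep, samples, "PA", "GBM", alpha = 0.1)
  expect_equal(res$p_raw, 0.1)
  expect_false(res$significant)
  expect_true(differential_region_signal(sep, samples, "PA", "GBM",
                                         alpha = 0.11)$significant)
})

test_that("spiked differential enhancers are recovered with high sensitivity", {
  # 2-fold grade effect, PA n=11 vs GBM/pGBM n=15, raw p < 0.01
  cfg <- simulation_config(n_tads = 10, genes_per_tad = 3, n_enhancers = 150,
                           frac_diff_enhancers = 0.4, lfc_effect = 1,
                           seed = 44)
  co <- generate_cohort(generate_genome(cfg), cfg)
  res <- differential_region_signal(co$enhancers$acetylation, co$samples,
                                    "PA", "GBM", alpha = 0.01)
  truth <- co$truth$enhancers
  sens <- mean(res$significant[truth$is_diff])
  fpr <- mean(res$significant[!truth$is_diff])
  expect_gte(sens, 0.8)
  expect_lte(fpr, 0.05)
})

test_that("enhancer methylation means honour coverage holes", {
  enh <- genomic_intervals("e1", "chr1", 100, 200)
  meth <- data.frame(chrom = "chr1", pos = c(110, 150, 300),
                     sample_id = c("s1", "s1", "s2"),
                     beta = c(0.2, 0.4, 0.9))
  expect_message(mb <- enhancer_methylation(meth, enh,
                                            sample_ids = c("s1", "s2")),
                 "without covered CpGs")
  expect_equal(mb["e1", "s1"], 0.3)
  expect_true(is.na(mb["e1", "s2"]))  # its only CpG lies outside e1
})

test_that("link correlations hit deterministic poles and skip short strata", {
  samples <- sample_sheet(paste0("s", 1:6), rep(c("PA", "GBM"), each = 3))
  expr <- matrix(c(1:6, 6:1), 2, 6, byrow = TRUE,
                 dimnames = list(c("gUp", "gDown"), samples$sample_id))
  acet <- matrix(1:6, 1, 6, dimnames = list("e1", samples$sample_id))
  links <- data.frame(gene_id = c("gUp", "gDown"), enhancer_id = "e1",
                      chrom = "chr1", n_contacts = 1L, distance = 1)
  lc <- link_correlations(links, expr, acet, samples)
  expect_equal(lc$rho, c(1, -1))
  expect_equal(lc$rho_PA, c(1, -1))
  # constant acetylation -> undefined
  acet["e1", ] <- 2
  lc <- link_correlations(links, expr, acet, samples)
  expect_true(all(is.na(lc$rho)))
})

test_that("the correlation permutation null behaves at its edge cases", {
  m <- matrix(rep(1:5, 4), 4, 5, byrow = TRUE,
              dimnames = list(paste0("l", 1:4), paste0("s", 1:5)))
  # identical vectors everywhere: every pairing correlates perfectly
  res <- correlation_permutation_null(m, m, reps = 10)
  expect_equal(res$means, rep(1, 10))
  expect_equal(res$median, 1)
  expect_length(correlation_permutation_null(m, m, reps = 1)$means, 1)
})
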