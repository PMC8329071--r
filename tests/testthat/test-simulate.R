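test_that("genome generation honours the construction contract", {
  cfg <- simulation_config(n_chrom = 1, n_tads = 10, genes_per_tad = 5,
                           seed = 1)
  g <- generate_genome(cfg)
  expect_equal(nrow(g$tads), 10)
  expect_equal(nrow(g$genes), 50)
  validate_tads <- asNamespace("gliotad")$validate_tads
  expect_silent(validate_tads(g$tads))
  # every TSS in exactly one TAD
  hits <- vapply(seq_len(50), function(i) {
    length(overlap_query(g$tads, g$genes$chrom[i], g$genes$tss[i],
                         g$genes$tss[i] + 1))
  }, integer(1))
  expect_true(all(hits == 1))
  # determinism
  expect_identical(g, generate_genome(cfg))
})

test_that("full TAD coupling places every true DEG in a spiked TAD", {
  cfg <- simulation_config(n_tads = 20, genes_per_tad = 10,
                           n_enriched_tads = 2, tad_coupling = 1,
                           frac_deg = 0.1, seed = 5)
  g <- generate_genome(cfg)
  spiked <- g$truth$tads$tad_id[g$truth$tads$enriched]
  expect_length(spiked, 2)
  deg_tads <- g$truth$genes$tad_id[g$truth$genes$is_deg]
  expect_length(deg_tads, 20)  # 10% of 200 genes
  expect_true(all(deg_tads %in% spiked))
})

test_that("cohorts are byte-identical under the same configuration", {
  cfg <- simulation_config(n_tads = 10, genes_per_tad = 4, n_enhancers = 20,
                           seed = 9)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(generate_cohort(generate_genome(cfg), cfg), d1)
  write_cohort(generate_cohort(generate_genome(cfg), cfg), d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_setequal(f1, f2)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})

test_that("a written cohort round-trips through the package readers", {
  cfg <- simulation_config(n_tads = 10, genes_per_tad = 4, n_enhancers = 20,
                           seed = 9)
  co <- generate_cohort(generate_genome(cfg), cfg)
  d <- withr::local_tempdir()
  write_cohort(co, d)
  back <- read_cohort(d)
  expect_equal(back$expression, co$expression, ignore_attr = TRUE)
  expect_equal(sort(names(back$marks)), sort(names(co$marks)))
  expect_equal(back$tads, co$tads, ignore_attr = TRUE)
  expect_equal(back$genes, co$genes, ignore_attr = TRUE)
  expect_equal(nrow(back$contacts), nrow(co$contacts))
  expect_equal(back$samples$group, co$samples$group)
  expect_equal(back$truth$genes$is_deg, co$truth$genes$is_deg)
})

test_that("cohort structure matches the configured study design", {
  co <- simulate_cohort(simulation_config(n_tads = 10, genes_per_tad = 4,
                                          n_enhancers = 30, seed = 2))
  expect_equal(nrow(co$samples), 33)
  expect_equal(table(co$samples$group)[c("PA", "DA", "GBM")],
               table(factor(rep(c("PA", "DA", "GBM"), c(11, 7, 15)),
                            levels = c("PA", "DA", "GBM"))))
  expect_true(all(co$expression >= 0))
  # no simulated enhancer overlaps a promoter window
  pr <- make_promoters(co$genes, 2000)
  enh <- co$enhancers$intervals
  for (i in seq_len(nrow(enh))) {
    expect_length(overlap_query(pr, enh$chrom[i], enh$start[i], enh$end[i]), 0)
  }
  # contacts respect the simulated distance bound
  mid_b <- (co$contacts$start_b + co$contacts$end_b) / 2
  mid_a <- (co$contacts$start_a + co$contacts$end_a) / 2
  expect_true(all(abs(mid_b - mid_a) <= 2e6 + 2000 + 750))
})

test_that("uncoupled marks show no expression correlation", {
  co <- simulate_cohort(simulation_config(n_tads = 20, genes_per_tad = 10,
                                          mark_coupling_rho = 0, seed = 6))
  rec <- gene_mark_correlations(co$expression, co$marks$H3K27ac,
                                rownames(co$expression))
  expect_lt(abs(median(rec$rho, na.rm = TRUE)), 0.15)
})

test_that("full methylation anticorrelation yields negative coupling", {
  cfg <- simulation_config(n_tads = 4, genes_per_tad = 2, n_enhancers = 1,
                           methyl_anticorr = 1, n_enriched_tads = 1,
                           n_samples_per_group = c(PA = 6, GBM = 6), seed = 8)
  co <- generate_cohort(generate_genome(cfg), cfg)
  enh <- co$enhancers$intervals
  mb <- suppressMessages(enhancer_methylation(
    co$methylation, enh, sample_ids = colnames(co$enhancers$acetylation)))
  rho <- spearman_rho(mb[1, ], co$enhancers$acetylation[1, ])
  expect_lt(rho, 0)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(simulation_config(frac_deg = 1.5), "\\[0, 1\\]")
  expect_error(simulation_config(n_tads = 0), "positive")
  expect_error(simulation_config(n_enriched_tads = 11, n_tads = 10))
  expect_error(
    generate_genome(simulation_config(n_tads = 10, genes_per_tad = 200,
                                      chrom_length = 500)),
    "exceeds TAD width")
})
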