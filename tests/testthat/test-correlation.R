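test_that("spearman matches the closed form in the tie-free case", {
  expect_equal(spearman_rho(1:3, c(10, 20, 30)), 1)
  expect_equal(spearman_rho(1:3, c(30, 20, 10)), -1)
  expect_equal(spearman_rho(1:4, c(2, 1, 4, 3)), 0.6)  # 1 - 6*4/(4*15)
  set.seed(9)
  for (i in 1:50) {
    n <- sample(4:20, 1)
    x <- rnorm(n); y <- rnorm(n)
    d <- rank(x) - rank(y)
    expect_equal(spearman_rho(x, y), 1 - 6 * sum(d^2) / (n * (n^2 - 1)),
                 tolerance = 1e-12)
  }
  expect_true(is.na(spearman_rho(c(1, 1, 1), c(1, 2, 3))))
  expect_error(spearman_rho(1:3, 1:4), "length mismatch")
})

test_that("gene-mark correlations recover coupling and skip short strata", {
  set.seed(21)
  n <- 30
  expr <- matrix(rpois(200 * n, 60), 200, n,
                 dimnames = list(paste0("g", 1:200), paste0("s", 1:n)))
  # independent marks: median rho centred at 0
  marks <- signal_matrix(matrix(rpois(200 * n, 60), 200, n,
                                dimnames = dimnames(expr)), "H3K4me3")
  rec <- gene_mark_correlations(expr, marks, rownames(expr))
  expect_lt(abs(median(rec$rho, na.rm = TRUE)), 0.15)
  expect_equal(unique(rec$mark_kind), "H3K4me3")
  # perfectly coupled gene
  marks["g1", ] <- expr["g1", ] * 2 + 1
  rec <- gene_mark_correlations(expr, marks, "g1")
  expect_equal(rec$rho, 1)
  # fewer than 3 shared samples -> skipped
  expect_message(
    rec <- gene_mark_correlations(expr[, 1:2], marks[, 1:2, drop = FALSE],
                                  c("g1", "missing")),
    "skipped")
  expect_equal(nrow(rec), 0)
})

test_that("matched backgrounds satisfy the set-mean constraint", {
  set.seed(14)
  expr <- matrix(rpois(300 * 10, 100), 300, 10,
                 dimnames = list(paste0("g", 1:300), paste0("s", 1:10)))
  pool <- rownames(expr)
  degs <- sample(pool, 30)
  target <- mean(rowMeans(expr)[degs])
  for (i in 1:100) {
    bg <- matched_background(degs, pool, expr)
    expect_length(bg, 30)
    expect_length(intersect(bg, degs), 0)
    expect_gte(mean(rowMeans(expr)[bg]), target)
  }
})

test_that("an infeasible background constraint errors with the target mean", {
  expr <- matrix(rep(c(1000, 1), each = 5), 10, 3,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:3)))
  degs <- paste0("g", 1:5)  # the top-expressed genes; pool cannot match
  expect_error(matched_background(degs, rownames(expr), expr),
               "cannot draw a background")
  expect_error(matched_background(paste0("g", 1:8), paste0("g", 1:9), expr),
               "smaller than")
})

test_that("bootstrap overlap p saturates and detects constructed coincidence", {
  set.seed(31)
  expr <- matrix(rpois(200 * 12, 80), 200, 12,
                 dimnames = list(paste0("g", 1:200), paste0("s", 1:12)))
  pool <- rownames(expr)
  degs <- sample(pool, 25)
  # dem covers the whole pool: every replicate ties the observed overlap
  expect_equal(bootstrap_overlap_p(degs, pool, pool, expr, reps = 100), 1)
  # empty observed overlap: nothing can fall below it
  expect_equal(bootstrap_overlap_p(degs, character(), pool, expr, reps = 100), 1)
  # DEGs and DEMs coincide by construction: overlap unbeatable by chance
  p <- bootstrap_overlap_p(degs, degs, pool, expr, reps = 300)
  expect_lte(p, 0.01)
  expect_error(bootstrap_overlap_p(degs, degs, pool, expr, reps = 10), ">= 100")
})

test_that("prognostic overlap ratios and their comparison are computed", {
  sets <- list(a = paste0("g", 1:10), b = paste0("x", 1:5))
  prog <- c("g1", "z9")
  props <- prognostic_overlap_ratio(sets, prog, paste0("d", 1:100))
  expect_equal(unname(props), c(0.01, 0))
  expect_error(prognostic_overlap_ratio(sets, prog, character()), "denominator")
  # exact 3v3 Mann-Whitney on separated proportion vectors
  expect_equal(
    compare_overlap_proportions(c(0.02, 0.01, 0.011), c(0.004, 0.003, 0.0031)),
    0.1)
})

test_that("high-correlation selection is strictly greater than the cutoff", {
  rec <- data.frame(gene_id = c("a", "b", "c", "d"),
                    mark_kind = "H3K27ac",
                    rho = c(0.7, 0.71, NA, 0.9), n = 10)
  expect_setequal(select_high_rho(rec, 0.7), c("b", "d"))
  expect_equal(select_high_rho(rec[0, ], 0.7), character())
})
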