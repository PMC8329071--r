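#' Two-sided Mann-Whitney p-value for two sample groups
#'
#' The workhorse of all rank-based comparisons. The exact distribution is
#' used when both groups have at most 8 observations and the pooled values
#' are tie-free; otherwise the normal approximation with tie correction and
#' continuity correction. A fully tied input (every value identical) carries
#' no ordering information and returns p = 1.
#'
#' @param x,y numeric vectors, one per group, each of length >= 2.
#' @return two-sided p-value.
#' @export
mann_whitney_p <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 values")
  pooled <- c(x, y)
  if (all(pooled == pooled[1])) return(1)
  exact <- length(x) <= 8 && length(y) <= 8 && !anyDuplicated(pooled)
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
  )
}

#' Library-size normalisation to counts per million
#'
#' @param mat signal matrix of raw counts.
#' @return matrix of the same shape scaled so each column sums to 1e6.
#' @export
cpm <- function(mat) {
  libsize <- colSums(mat)
  if (any(libsize == 0)) stop("zero library size for sample(s): ",
                              paste(colnames(mat)[libsize == 0], collapse = ", "))
  t(t(mat) / libsize) * 1e6
}

check_two_groups <- function(mat, samples, group1, group2) {
  ids1 <- group_samples(samples, group1)
  ids2 <- group_samples(samples, group2)
  if (length(ids1) < 2 || length(ids2) < 2) {
    stop("both groups need >= 2 samples")
  }
  missing <- setdiff(c(ids1, ids2), colnames(mat))
  if (length(missing)) {
    stop("samples absent from matrix: ", paste(missing, collapse = ", "))
  }
  list(ids1 = ids1, ids2 = ids2)
}

#' Rank-based differential feature calling between two grade groups
#'
#' Per feature, a two-sided Mann-Whitney test comparing the two sample
#' groups on library-size normalised values (counts per million; switch off
#' with `normalize = FALSE`), followed by multiple-testing correction over
#' all tested features. Log2 fold changes are
#' `log2((mean2 + c) / (mean1 + c))` with pseudocount `c`.
#'
#' @param mat signal matrix covering all samples of both groups.
#' @param samples sample sheet.
#' @param group1,group2 group labels; fold changes are group2 vs group1.
#' @param correction `"bonferroni"` or `"bh"`.
#' @param alpha significance threshold on the corrected p-value (strict <).
#' @param normalize scale columns to counts per million first.
#' @param pseudocount added to both group means in the fold change.
#' @return data frame with one row per feature: `feature_id`, `log2fc`,
#'   `p_raw`, `p_adj`, `significant`.
#' @export
rank_test_differential <- function(mat, samples, group1, group2,
                                   correction = c("bonferroni", "bh"),
                                   alpha = 0.01, normalize = TRUE,
                                   pseudocount = 1) {
  correction <- match.arg(correction)
  g <- check_two_groups(mat, samples, group1, group2)
  if (normalize) mat <- cpm(mat)
  m1 <- mat[, g$ids1, drop = FALSE]
  m2 <- mat[, g$ids2, drop = FALSE]
  p_raw <- vapply(seq_len(nrow(mat)),
                  function(i) mann_whitney_p(m1[i, ], m2[i, ]), numeric(1))
  p_adj <- if (correction == "bonferroni") {
    pmin(1, p_raw * length(p_raw))
  } else {
    bh_adjust(p_raw)
  }
  data.frame(
    feature_id = rownames(mat),
    log2fc = log2((rowMeans(m2) + pseudocount) / (rowMeans(m1) + pseudocount)),
    p_raw = p_raw, p_adj = p_adj,
    significant = p_adj < alpha,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up FDR control: with p-values sorted ascending,
#' `q_i = min_{j >= i} (m p_(j) / j)`, clipped at 1 and reported in input
#' order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) stop("empty p-value vector")
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Log2 fold changes of group means
#'
#' @inheritParams rank_test_differential
#' @return named numeric vector, one log2 fold change (group2 vs group1) per
#'   feature.
#' @export
log2_fold_changes <- function(mat, samples, group1, group2, pseudocount = 1,
                              normalize = TRUE) {
  g <- check_two_groups(mat, samples, group1, group2)
  if (normalize) mat <- cpm(mat)
  fc <- log2((rowMeans(mat[, g$ids2, drop = FALSE]) + pseudocount) /
               (rowMeans(mat[, g$ids1, drop = FALSE]) + pseudocount))
  stats::setNames(as.numeric(fc), rownames(mat))
}

#' Active genes by mean expression
#'
#' A gene is active when its mean raw count across all samples reaches
#' `min_mean` (inclusive; the published rule is >= 10 reads on average).
#'
#' @param expression expression signal matrix.
#' @param min_mean threshold on the row mean.
#' @return character vector of active gene ids.
#' @export
active_genes <- function(expression, min_mean = 10) {
  stopifnot(nrow(expression) > 0)
  rownames(expression)[rowMeans(expression) >= min_mean]
}

#' Count hypermethylated CpGs per region and sample
#'
#' For each (region, sample), counts cytosines with beta at or above the
#' threshold (the published rule is beta >= 0.8). Regions with no covered
#' CpGs for a sample count 0.
#'
#' @param meth methylation data frame (see [read_methylation()]).
#' @param regions interval data frame (e.g. promoters).
#' @param threshold hypermethylation beta cutoff, inclusive.
#' @param sample_ids sample universe for the output columns; defaults to the
#'   samples present in `meth`.
#' @return signal matrix (kind `"methyl_count"`), regions x samples.
#' @export
count_hypermethylated <- function(meth, regions, threshold = 0.8,
                                  sample_ids = NULL) {
  validate_methylation(meth)
  validate_intervals(regions)
  if (threshold < 0 || threshold > 1) stop("beta threshold outside [0, 1]")
  if (is.null(sample_ids)) sample_ids <- sort(unique(meth$sample_id))
  out <- matrix(0, nrow = nrow(regions), ncol = length(sample_ids),
                dimnames = list(regions$id, sample_ids))
  hyper <- meth[meth$beta >= threshold, , drop = FALSE]
  if (nrow(hyper)) {
    cpg <- data.frame(chrom = hyper$chrom, start = hyper$pos,
                      end = hyper$pos + 1)
    hits <- overlap_join(cpg, regions)
    if (nrow(hits)) {
      tab <- table(factor(regions$id[hits$target_idx], levels = regions$id),
                   factor(hyper$sample_id[hits$query_idx], levels = sample_ids))
      out <- out + unclass(tab)[rownames(out), colnames(out), drop = FALSE]
    }
  }
  signal_matrix(out, "methyl_count")
}

#' Read or write a differential-result table
#'
#' External differential flag tables (for instance produced by a
#' negative-binomial GLM caller) are accepted in the same five-column schema
#' the built-in rank test writes, so they can be injected verbatim.
#'
#' @param path TSV with header `feature_id`, `log2fc`, `p_raw`, `p_adj`,
#'   `significant`.
#' @export
read_differential <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("feature_id", "log2fc", "p_raw", "p_adj", "significant")
  if (!all(need %in% names(dt))) {
    stop("differential table must have columns: ", paste(need, collapse = ", "))
  }
  out <- as.data.frame(dt[, need, with = FALSE])
  out$feature_id <- as.character(out$feature_id)
  out$significant <- as.logical(out$significant)
  out
}

#' @rdname read_differential
#' @param x differential result data frame.
#' @export
write_differential <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE)
  invisible(path)
}
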