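#' Correlate TF expression with candidate target genes
#'
#' Candidate (TF, target) pairs come from an external motif/binding-site
#' analysis; this stage only computes, per pair, the Spearman correlation
#' between the TF-coding gene's expression and the target's expression
#' across samples. Pairs with a missing gene are skipped (counted in the
#' `"n_skipped"` attribute); per-TF median rho is also reported.
#'
#' @param candidates data frame with columns `tf_gene_id`,
#'   `target_gene_id`.
#' @param expression expression signal matrix with >= 3 samples.
#' @return data frame `tf_gene_id`, `target_gene_id`, `rho`; the per-TF
#'   medians are in the `"tf_median_rho"` attribute (named numeric).
#' @export
tf_target_correlations <- function(candidates, expression) {
  stopifnot(all(c("tf_gene_id", "target_gene_id") %in% names(candidates)))
  if (ncol(expression) < 3) stop("need >= 3 samples")
  ok <- candidates$tf_gene_id %in% rownames(expression) &
    candidates$target_gene_id %in% rownames(expression)
  n_skipped <- sum(!ok)
  if (n_skipped > 0) message(n_skipped, " candidate pair(s) skipped")
  kept <- candidates[ok, , drop = FALSE]
  rho <- vapply(seq_len(nrow(kept)), function(i) {
    spearman_rho(expression[kept$tf_gene_id[i], ],
                 expression[kept$target_gene_id[i], ])
  }, numeric(1))
  out <- data.frame(tf_gene_id = kept$tf_gene_id,
                    target_gene_id = kept$target_gene_id, rho = rho,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "tf_median_rho") <-
    tapply(out$rho, out$tf_gene_id, stats::median, na.rm = TRUE)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Random-target correlation envelope for a TF
#'
#' Correlates the TF with `n_draws` active genes drawn at random (its real
#' targets excluded) and records the minimum, maximum and median of those
#' correlations. The envelope is the TF-specific band a real target must
#' escape to be retained.
#'
#' @param tf TF gene id.
#' @param pool character vector of active gene ids.
#' @param expression expression signal matrix.
#' @param n_draws number of random genes (without replacement).
#' @param exclude gene ids never drawn (the TF itself and its real
#'   targets).
#' @return list `min_rho`, `max_rho`, `median_rho`, `n_draws`.
#' @export
random_target_envelope <- function(tf, pool, expression, n_draws = 100,
                                   exclude = character()) {
  pool <- setdiff(pool, c(tf, exclude))
  if (length(pool) < n_draws) stop("active-gene pool smaller than n_draws")
  drawn <- sample(pool, n_draws)
  rho <- vapply(drawn, function(g) {
    spearman_rho(expression[tf, ], expression[g, ])
  }, numeric(1))
  rho <- rho[!is.na(rho)]
  if (!length(rho)) stop("all random-target correlations undefined")
  list(min_rho = min(rho), max_rho = max(rho),
       median_rho = stats::median(rho), n_draws = n_draws)
}

#' Filter TF-target correlations by the random envelope
#'
#' A pair is retained iff its correlation exceeds the maximum of the TF's
#' random-target correlations (positive branch) or falls below their
#' minimum (negative branch, for repressors).
#'
#' @param records data frame from [tf_target_correlations()].
#' @param envelopes named list, one [random_target_envelope()] result per
#'   TF appearing in `records`.
#' @return `records` with an added logical `passes_envelope` column.
#' @export
filter_by_envelope <- function(records, envelopes) {
  missing <- setdiff(unique(records$tf_gene_id), names(envelopes))
  if (length(missing)) {
    stop("no envelope for TF(s): ", paste(missing, collapse = ", "))
  }
  records$passes_envelope <- vapply(seq_len(nrow(records)), function(i) {
    env <- envelopes[[records$tf_gene_id[i]]]
    r <- records$rho[i]
    !is.na(r) && (r > env$max_rho || r < env$min_rho)
  }, logical(1))
  records
}
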