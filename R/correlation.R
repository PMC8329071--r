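#' Spearman rank correlation
#'
#' Average ranks for ties. A constant vector has no rank ordering, so the
#' correlation is undefined and `NA` is returned; callers exclude such
#' records from summaries rather than coercing them to 0.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Spearman rho, or `NA` when either vector is constant.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("need >= 3 paired observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Gene-mark correlation records
#'
#' Spearman correlation, across patients, between a gene's expression and
#' the mark signal at its promoter, for each requested gene. Genes absent
#' from either matrix, or with fewer than 3 shared samples, are skipped and
#' counted in the `"n_skipped"` attribute.
#'
#' @param expression expression signal matrix (genes x samples).
#' @param marks promoter-level mark signal matrix (genes x samples) with a
#'   `kind` attribute.
#' @param genes character vector of gene ids to evaluate.
#' @return data frame `gene_id`, `mark_kind`, `rho`, `n`; rho is `NA` for
#'   constant vectors (logged, excluded from medians downstream).
#' @export
gene_mark_correlations <- function(expression, marks, genes) {
  shared <- intersect(colnames(expression), colnames(marks))
  kind <- attr(marks, "kind")
  if (is.null(kind)) kind <- "mark"
  usable <- genes[genes %in% rownames(expression) & genes %in% rownames(marks)]
  n_skipped <- length(genes) - length(usable)
  if (length(shared) < 3) usable <- character()
  out <- data.frame(
    gene_id = usable,
    mark_kind = rep(kind, length(usable)),
    rho = vapply(usable, function(g) {
      spearman_rho(expression[g, shared], marks[g, shared])
    }, numeric(1)),
    n = rep(length(shared), length(usable)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (n_skipped > 0) message(n_skipped, " gene(s) skipped in correlation")
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Expression-matched random background gene sets
#'
#' Draws `|deg_set|` genes from the active pool (excluding the differential
#' genes themselves) under the constraint that the drawn set's overall mean
#' expression is at least that of the differential set. Whole sets are
#' redrawn up to `max_retry` times; if rejection sampling fails, a fallback
#' draw stratified by expression decile (matching the differential set's
#' decile profile) is attempted once before erroring.
#'
#' @param deg_set character vector of differential gene ids.
#' @param pool character vector of active gene ids (the sampling universe).
#' @param expression expression signal matrix covering both sets.
#' @param max_retry rejection-sampling cap.
#' @return character vector of background gene ids, same size as `deg_set`.
#' @export
matched_background <- function(deg_set, pool, expression, max_retry = 100) {
  pool <- setdiff(pool, deg_set)
  if (length(pool) < length(deg_set)) {
    stop("background pool smaller than the differential set")
  }
  gm <- rowMeans(expression)
  target <- mean(gm[deg_set])
  for (i in seq_len(max_retry)) {
    cand <- sample(pool, length(deg_set))
    if (mean(gm[cand]) >= target) return(cand)
  }
  if (mean(sort(gm[pool], decreasing = TRUE)[seq_along(deg_set)]) < target) {
    stop(sprintf(
      "cannot draw a background with mean expression >= %.3f (pool mean %.3f)",
      target, mean(gm[pool])))
  }
  # decile-stratified fallback: mirror the differential set's expression
  # profile, then repair upwards until the set-mean constraint holds
  br <- unique(stats::quantile(gm[pool], probs = seq(0, 1, 0.1)))
  cand <- if (length(br) > 2) {
    dd <- cut(gm[deg_set], br, include.lowest = TRUE)
    pd <- cut(gm[pool], br, include.lowest = TRUE)
    drawn <- unlist(lapply(levels(dd), function(lv) {
      need <- sum(dd == lv, na.rm = TRUE)
      have <- pool[which(pd == lv)]
      if (need == 0) return(character())
      sample(have, min(need, length(have)))
    }), use.names = FALSE)
    short <- length(deg_set) - length(drawn)
    if (short > 0) {
      extra <- setdiff(pool, drawn)
      drawn <- c(drawn, extra[order(gm[extra],
                                    decreasing = TRUE)][seq_len(short)])
    }
    drawn
  } else {
    sample(pool, length(deg_set))
  }
  unused <- setdiff(pool, cand)
  unused <- unused[order(gm[unused], decreasing = TRUE)]
  cand <- cand[order(gm[cand])]
  i <- 1L
  while (mean(gm[cand]) < target && i <= length(unused)) {
    if (gm[unused[i]] > gm[cand[i]]) cand[i] <- unused[i]
    i <- i + 1L
  }
  if (mean(gm[cand]) >= target) return(cand)
  stop(sprintf(
    "cannot draw a background with mean expression >= %.3f (pool mean %.3f)",
    target, mean(gm[pool])))
}

#' Bootstrap significance of the DEG/DEM overlap
#'
#' Probability of observing at least the original number of genes shared
#' between the differential-expression and differential-mark sets when the
#' expression set is replaced by expression-matched random sets. Uses the
#' (k + 1) / (n + 1) permutation estimator, never exactly 0.
#'
#' @param deg_set,dem_set character vectors of gene ids.
#' @param pool active-gene sampling universe for [matched_background()].
#' @param expression expression signal matrix.
#' @param reps bootstrap replicates (>= 100).
#' @return p-value in (0, 1\].
#' @export
bootstrap_overlap_p <- function(deg_set, dem_set, pool, expression,
                                reps = 1000) {
  if (reps < 100) stop("use >= 100 bootstrap replicates")
  observed <- length(intersect(deg_set, dem_set))
  hits <- 0L
  for (i in seq_len(reps)) {
    bg <- matched_background(deg_set, pool, expression)
    if (length(intersect(bg, dem_set)) >= observed) hits <- hits + 1L
  }
  (1 + hits) / (reps + 1)
}

#' Overlap proportions with a prognostic gene set
#'
#' For each named gene set, `|set intersect prognostic| / |denominator|`.
#' Prognostic status is an externally supplied flag table (e.g. a published
#' survival-screen result).
#'
#' @param gene_sets named list of character vectors.
#' @param prognostic character vector of prognostic gene ids.
#' @param denominators either one character vector used for every set, or a
#'   named list parallel to `gene_sets`.
#' @return named numeric vector of proportions.
#' @export
prognostic_overlap_ratio <- function(gene_sets, prognostic, denominators) {
  stopifnot(length(gene_sets) > 0, !is.null(names(gene_sets)))
  if (!is.list(denominators)) {
    denominators <- stats::setNames(
      rep(list(denominators), length(gene_sets)), names(gene_sets))
  }
  vapply(names(gene_sets), function(nm) {
    den <- denominators[[nm]]
    if (!length(den)) stop("empty denominator set for ", nm)
    length(intersect(gene_sets[[nm]], prognostic)) / length(den)
  }, numeric(1))
}

#' Compare two groups of overlap proportions
#'
#' Two-sided Mann-Whitney test on per-comparison proportions, e.g.
#' high-correlation differential genes vs all differential genes across the
#' three grade comparisons.
#'
#' @param props1,props2 numeric vectors of proportions (one per comparison).
#' @return two-sided p-value.
#' @export
compare_overlap_proportions <- function(props1, props2) {
  mann_whitney_p(props1, props2)
}

#' Select genes with high mark correlation
#'
#' Strictly greater than the threshold (the published rule is
#' Spearman rho > 0.7); undefined correlations never pass.
#'
#' @param records data frame from [gene_mark_correlations()].
#' @param threshold rho cutoff (strict).
#' @return character vector of gene ids.
#' @export
select_high_rho <- function(records, threshold = 0.7) {
  if (!nrow(records)) return(character())
  unique(records$gene_id[!is.na(records$rho) & records$rho > threshold])
}
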