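#' Binomial TAD enrichment for differential genes
#'
#' For each TAD, the probability of observing at least the observed number
#' of flagged (differentially expressed / differentially marked) genes under
#' a binomial model: `P(X >= k)` with `X ~ Binomial(n_genes, p0)` where `p0`
#' is the global share of flagged genes among all TAD-assigned genes,
#' computed once. TADs with fewer than `min_genes` genes are excluded before
#' Benjamini-Hochberg correction over the remaining TADs; a TAD is enriched
#' when its corrected p falls below `alpha` (and it passed the size filter).
#' Flagged genes not assigned to any TAD are dropped (counted in a message).
#'
#' @param assignment gene-to-TAD assignment from [assign_genes_to_tads()].
#' @param flagged character vector of flagged gene ids.
#' @param alpha BH threshold for enrichment.
#' @param min_genes minimum TAD gene count to be tested.
#' @return data frame `tad_id`, `n_genes`, `n_flagged`, `background_prob`,
#'   `p_raw`, `p_adj`, `enriched`; `p_raw`/`p_adj` are `NA` for excluded
#'   TADs.
#' @export
tad_enrichment <- function(assignment, flagged, alpha = 0.05, min_genes = 3) {
  tad2genes <- assignment$tad2genes
  assigned <- unlist(tad2genes, use.names = FALSE)
  if (!length(assigned)) stop("no genes assigned to any TAD")
  n_unassigned <- length(setdiff(flagged, assigned))
  if (n_unassigned > 0) {
    message(n_unassigned, " flagged gene(s) outside all TADs dropped")
  }
  flagged <- intersect(flagged, assigned)
  p0 <- length(flagged) / length(assigned)
  n_genes <- lengths(tad2genes)
  n_flagged <- vapply(tad2genes, function(g) length(intersect(g, flagged)),
                      integer(1))
  tested <- n_genes >= min_genes
  p_raw <- rep(NA_real_, length(tad2genes))
  # upper tail P(X >= k): the k = 0 case is identically 1
  p_raw[tested] <- stats::pbinom(n_flagged[tested] - 1, n_genes[tested], p0,
                                 lower.tail = FALSE)
  p_adj <- rep(NA_real_, length(tad2genes))
  if (any(tested)) p_adj[tested] <- bh_adjust(p_raw[tested])
  data.frame(
    tad_id = names(tad2genes), n_genes = as.integer(n_genes),
    n_flagged = n_flagged, background_prob = p0,
    p_raw = p_raw, p_adj = p_adj,
    enriched = tested & !is.na(p_adj) & p_adj < alpha,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

# Tie-corrected Kruskal-Wallis H from pre-computed pooled ranks. The rank
# vector (and hence the tie correction) is invariant under permutation of
# group labels, which makes the permutation null loop cheap.
kw_stat_from_ranks <- function(r, g, tie_correction, N) {
  Rj <- rowsum(r, g)
  nj <- as.vector(rowsum(rep(1, N), g))
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  H / tie_correction
}

kw_tie_correction <- function(values) {
  t <- table(values)
  1 - sum(t^3 - t) / (length(values)^3 - length(values))
}

prepare_homogeneity <- function(fold_changes, assignment) {
  gene2tad <- assignment$gene2tad
  genes <- intersect(names(fold_changes), names(gene2tad)[!is.na(gene2tad)])
  values <- fold_changes[genes]
  groups <- gene2tad[genes]
  keep <- !is.na(values)
  values <- values[keep]; groups <- groups[keep]
  if (length(unique(groups)) < 2) {
    stop("need >= 2 TADs carrying fold changes")
  }
  list(values = as.numeric(values), groups = as.character(groups))
}

#' Kruskal-Wallis homogeneity of fold changes across TADs
#'
#' Tests whether log2 fold changes are exchangeable across TADs: fold
#' changes are the values, TAD membership the grouping. A significant
#' result means fold changes are more homogeneous within TADs (genes in the
#' same domain shift together) than across them. TADs without any
#' fold-change-bearing gene are dropped. With all values identical the
#' statistic is degenerate; the result reports H = 0, p = 1.
#'
#' @param fold_changes named numeric vector, gene -> log2 fold change.
#' @param assignment gene-to-TAD assignment.
#' @return list `statistic` (tie-corrected H), `p_asymptotic` (chi-square
#'   tail, `#groups - 1` df), `df`, `n_genes`, `n_tads`.
#' @export
kw_homogeneity <- function(fold_changes, assignment) {
  d <- prepare_homogeneity(fold_changes, assignment)
  n_tads <- length(unique(d$groups))
  if (all(d$values == d$values[1])) {
    return(list(statistic = 0, p_asymptotic = 1, df = n_tads - 1,
                n_genes = length(d$values), n_tads = n_tads))
  }
  kt <- stats::kruskal.test(d$values, factor(d$groups))
  list(statistic = unname(kt$statistic), p_asymptotic = kt$p.value,
       df = unname(kt$parameter), n_genes = length(d$values),
       n_tads = n_tads)
}

#' Permutation null for the TAD homogeneity statistic
#'
#' Shuffles fold-change values among TADs while keeping each TAD's gene
#' count, recomputes the Kruskal-Wallis statistic each time, and reports
#' `p = (1 + #{H_perm >= H_obs}) / (n_perm + 1)`.
#'
#' @inheritParams kw_homogeneity
#' @param n_perm number of permutations (values below 100 trigger a
#'   warning; 0 is an error).
#' @return the [kw_homogeneity()] list plus `p_permutation` and `n_perm`.
#' @export
permutation_homogeneity <- function(fold_changes, assignment, n_perm = 1000) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (n_perm < 100) warning("n_perm < 100 gives a coarse permutation p")
  obs <- kw_homogeneity(fold_changes, assignment)
  d <- prepare_homogeneity(fold_changes, assignment)
  r <- rank(d$values)
  N <- length(r)
  tc <- kw_tie_correction(d$values)
  g <- d$groups
  h_obs <- if (tc == 0) 0 else kw_stat_from_ranks(r, g, tc, N)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    h <- if (tc == 0) 0 else kw_stat_from_ranks(r, sample(g), tc, N)
    if (h >= h_obs - 1e-12) hits <- hits + 1L
  }
  obs$p_permutation <- (1 + hits) / (n_perm + 1)
  obs$n_perm <- n_perm
  obs
}

#' Per-TAD mean fold-change correlation
#'
#' For each TAD, the mean expression log2 fold change of its genes and the
#' mean mark log2 fold change, then one Spearman correlation across TADs.
#' TADs missing either quantity are excluded; fewer than 3 usable TADs is
#' an error.
#'
#' @param expr_fc named numeric vector, gene -> expression log2 fold change
#'   (typically restricted to differential genes).
#' @param mark_fc named numeric vector, gene/promoter feature -> mark log2
#'   fold change.
#' @param assignment gene-to-TAD assignment.
#' @return list with `per_tad` (data frame `tad_id`, `mean_expr_fc`,
#'   `mean_mark_fc`, `n_expr`, `n_mark`) and `rho`.
#' @export
tad_fc_correlation <- function(expr_fc, mark_fc, assignment) {
  tad2genes <- assignment$tad2genes
  per_tad <- do.call(rbind, lapply(names(tad2genes), function(tid) {
    g <- tad2genes[[tid]]
    ge <- intersect(g, names(expr_fc))
    gm <- intersect(g, names(mark_fc))
    data.frame(
      tad_id = tid,
      mean_expr_fc = if (length(ge)) mean(expr_fc[ge]) else NA_real_,
      mean_mark_fc = if (length(gm)) mean(mark_fc[gm]) else NA_real_,
      n_expr = length(ge), n_mark = length(gm),
      stringsAsFactors = FALSE
    )
  }))
  usable <- stats::complete.cases(per_tad[, c("mean_expr_fc", "mean_mark_fc")])
  if (sum(usable) < 3) stop("fewer than 3 TADs with both mean fold changes")
  rho <- spearman_rho(per_tad$mean_expr_fc[usable],
                      per_tad$mean_mark_fc[usable])
  list(per_tad = per_tad, rho = rho, n_tads = sum(usable))
}

#' Differential genes with bivalent chromatin
#'
#' Ranks genes by their summarised promoter H3K4me3 and H3K27me3 signals
#' (mean or median across the selected samples), takes the `top_n` of each
#' ranking, and intersects both top sets with the differential gene set.
#' Ties at the top-n boundary are broken by gene id, so runs are
#' deterministic.
#'
#' @param h3k4me3,h3k27me3 promoter-level signal matrices over the same
#'   genes.
#' @param degs character vector of differential gene ids.
#' @param top_n genes kept from the top of each ranking; if larger than the
#'   number of genes, all genes are kept (with a message).
#' @param sample_ids samples to summarise over (e.g. the GBM group);
#'   defaults to all columns.
#' @param summary `"mean"` (default) or `"median"`.
#' @return character vector of bivalent differential gene ids (sorted).
#' @export
bivalent_genes <- function(h3k4me3, h3k27me3, degs, top_n = 1000,
                           sample_ids = NULL, summary = c("mean", "median")) {
  summary <- match.arg(summary)
  genes <- rownames(h3k4me3)
  stopifnot(setequal(genes, rownames(h3k27me3)))
  h3k27me3 <- h3k27me3[genes, , drop = FALSE]
  if (is.null(sample_ids)) sample_ids <- colnames(h3k4me3)
  summarise <- function(m) {
    m <- m[, sample_ids, drop = FALSE]
    if (summary == "mean") rowMeans(m) else apply(m, 1, stats::median)
  }
  if (top_n > length(genes)) {
    message("top_n exceeds gene count; using all ", length(genes), " genes")
    top_n <- length(genes)
  }
  top_set <- function(score) {
    o <- order(-score, genes)  # descending signal, gene id breaks ties
    genes[o][seq_len(top_n)]
  }
  sort(intersect(intersect(top_set(summarise(h3k4me3)),
                           top_set(summarise(h3k27me3))), degs))
}

#' Hypergeometric overlap of two TAD sets
#'
#' Upper-tail probability of drawing at least the observed overlap between
#' the enriched ("glioma") TADs and the marked (e.g. bivalent-gene-bearing)
#' TADs from the tested TAD universe: `P(X >= k)` with
#' `X ~ Hypergeometric(|universe|, |enriched|, |marked|)`.
#'
#' @param enriched_tads,marked_tads character vectors, subsets of
#'   `universe`.
#' @param universe character vector of tested TAD ids.
#' @return upper-tail p-value.
#' @export
tad_overlap_hypergeom <- function(enriched_tads, marked_tads, universe) {
  if (!length(universe)) stop("empty TAD universe")
  enriched_tads <- unique(enriched_tads)
  marked_tads <- unique(marked_tads)
  if (!all(enriched_tads %in% universe) || !all(marked_tads %in% universe)) {
    stop("enriched/marked TADs must be subsets of the universe")
  }
  k <- length(intersect(enriched_tads, marked_tads))
  stats::phyper(k - 1, length(enriched_tads),
                length(universe) - length(enriched_tads),
                length(marked_tads), lower.tail = FALSE)
}
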