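#' Call enhancers from H3K27ac peaks
#'
#' An enhancer is an H3K27ac peak lying entirely outside all promoter
#' windows: any overlap with a promoter, even a single base, excludes the
#' peak. Retained peaks keep their ids and per-sample acetylation signal.
#'
#' @param peaks interval data frame of H3K27ac peaks.
#' @param peak_signal signal matrix (peaks x samples) of H3K27ac values.
#' @param promoters promoter interval data frame (see [make_promoters()]).
#' @return list with `intervals` (enhancer interval data frame) and
#'   `acetylation` (signal matrix restricted to the retained peaks).
#' @export
call_enhancers <- function(peaks, peak_signal, promoters) {
  validate_intervals(peaks, "peak")
  validate_intervals(promoters, "promoter")
  stopifnot(all(peaks$id %in% rownames(peak_signal)))
  hits <- overlap_join(peaks, promoters)
  keep <- setdiff(seq_len(nrow(peaks)), unique(hits$query_idx))
  intervals <- peaks[keep, , drop = FALSE]
  rownames(intervals) <- NULL
  list(intervals = intervals,
       acetylation = signal_matrix(
         peak_signal[intervals$id, , drop = FALSE], "H3K27ac"))
}

interval_mid <- function(x) (x$start + x$end) / 2

#' Link genes to enhancers through chromatin contact pairs
#'
#' A contact pair supports a (gene, enhancer) link iff one anchor overlaps
#' the gene's promoter and the other anchor overlaps the enhancer (either
#' orientation), and the distance between promoter and enhancer midpoints is
#' at most `max_dist` (the published window is 2 Mb). Each contact counts
#' once per (gene, enhancer) pair even if both orientations match;
#' `n_contacts` is the number of distinct supporting contacts.
#'
#' @param promoters promoter interval data frame (ids are gene ids).
#' @param enhancers enhancer interval data frame.
#' @param contacts contact data frame from [read_contacts()].
#' @param max_dist maximum promoter-enhancer midpoint distance in bp.
#' @return data frame `gene_id`, `enhancer_id`, `chrom`, `n_contacts`,
#'   `distance`, sorted by gene then enhancer.
#' @export
link_genes_to_enhancers <- function(promoters, enhancers, contacts,
                                    max_dist = 2e6) {
  validate_intervals(promoters, "promoter")
  validate_intervals(enhancers, "enhancer")
  empty <- data.frame(gene_id = character(), enhancer_id = character(),
                      chrom = character(), n_contacts = integer(),
                      distance = numeric(), stringsAsFactors = FALSE)
  if (!nrow(contacts) || !nrow(promoters) || !nrow(enhancers)) return(empty)
  anchor <- function(side) {
    data.frame(chrom = contacts$chrom,
               start = contacts[[paste0("start_", side)]],
               end = contacts[[paste0("end_", side)]])
  }
  hits_for <- function(x, targets) {
    h <- overlap_join(x, targets)
    data.frame(contact = h$query_idx, target = h$target_idx)
  }
  pa <- hits_for(anchor("a"), promoters); pb <- hits_for(anchor("b"), promoters)
  ea <- hits_for(anchor("a"), enhancers); eb <- hits_for(anchor("b"), enhancers)
  pair_up <- function(p, e) {
    if (!nrow(p) || !nrow(e)) {
      return(data.frame(contact = integer(), prom = integer(),
                        enh = integer()))
    }
    m <- merge(p, e, by = "contact", suffixes = c("_p", "_e"))
    data.frame(contact = m$contact, prom = m$target_p, enh = m$target_e)
  }
  cand <- rbind(pair_up(pa, eb), pair_up(pb, ea))
  if (!nrow(cand)) return(empty)
  cand <- unique(cand)  # one count per contact per (gene, enhancer)
  dist <- abs(interval_mid(promoters)[cand$prom] -
                interval_mid(enhancers)[cand$enh])
  same_chrom <- promoters$chrom[cand$prom] == enhancers$chrom[cand$enh]
  cand <- cand[same_chrom & dist <= max_dist, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  key <- paste(cand$prom, cand$enh)
  agg <- cand[!duplicated(key), , drop = FALSE]
  agg$n_contacts <- as.integer(table(key)[paste(agg$prom, agg$enh)])
  out <- data.frame(
    gene_id = promoters$id[agg$prom],
    enhancer_id = enhancers$id[agg$enh],
    chrom = promoters$chrom[agg$prom],
    n_contacts = agg$n_contacts,
    distance = abs(interval_mid(promoters)[agg$prom] -
                     interval_mid(enhancers)[agg$enh]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$gene_id, out$enhancer_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify genes by enhancer contact multiplicity
#'
#' Total contacts per gene = sum of `n_contacts` over its links; classes
#' follow the published bounds: `none` (0), `few` (1-5), `multi` (>= 6).
#'
#' @param links link data frame from [link_genes_to_enhancers()].
#' @param genes optional gene universe; genes without links are reported in
#'   class `none`.
#' @param multi_min contact count at which the `multi` class starts.
#' @return data frame `gene_id`, `total_contacts`, `class`.
#' @export
contact_classes <- function(links, genes = NULL, multi_min = 6) {
  totals <- if (nrow(links)) {
    tapply(links$n_contacts, links$gene_id, sum)
  } else {
    stats::setNames(integer(), character())
  }
  if (is.null(genes)) genes <- names(totals)
  tot <- stats::setNames(rep(0L, length(genes)), genes)
  shared <- intersect(genes, names(totals))
  tot[shared] <- as.integer(totals[shared])
  data.frame(
    gene_id = genes, total_contacts = as.integer(tot),
    class = ifelse(tot == 0, "none", ifelse(tot >= multi_min, "multi", "few")),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Compare expression between contact-multiplicity classes
#'
#' Two-sided Mann-Whitney test on per-gene mean expression, multi-contact
#' class vs few-contact class.
#'
#' @param expression expression signal matrix.
#' @param classes data frame from [contact_classes()].
#' @param sample_ids samples over which gene means are taken (default all).
#' @return list `p`, `median_multi`, `median_few`, `n_multi`, `n_few`.
#' @export
compare_expression_by_class <- function(expression, classes,
                                        sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- colnames(expression)
  gm <- rowMeans(expression[, sample_ids, drop = FALSE])
  multi <- intersect(classes$gene_id[classes$class == "multi"], names(gm))
  few <- intersect(classes$gene_id[classes$class == "few"], names(gm))
  if (length(multi) < 2 || length(few) < 2) {
    stop("both contact classes need >= 2 genes with expression")
  }
  list(p = mann_whitney_p(gm[multi], gm[few]),
       median_multi = stats::median(gm[multi]),
       median_few = stats::median(gm[few]),
       n_multi = length(multi), n_few = length(few))
}

#' Grade-specific differential signal at regions
#'
#' Per region (enhancer acetylation, enhancer CpG methylation, ...), a
#' two-sided Mann-Whitney test between two grade groups on per-sample
#' values. Significance uses the raw p-value with a strict cutoff
#' (published rule: p < 0.01, uncorrected); optional BH correction is
#' available but off by default.
#'
#' @param region_signal signal-like matrix regions x samples (NA allowed
#'   for methylation means; regions with < 2 usable values per group are
#'   skipped with `NA` p).
#' @param samples sample sheet.
#' @param group1,group2 group labels.
#' @param alpha cutoff on the deciding p-value (strict <).
#' @param correction `"none"` (default, as published) or `"bh"`.
#' @return data frame `region_id`, `p_raw`, `p_adj`, `significant`.
#' @export
differential_region_signal <- function(region_signal, samples, group1, group2,
                                       alpha = 0.01,
                                       correction = c("none", "bh")) {
  correction <- match.arg(correction)
  ids1 <- group_samples(samples, group1)
  ids2 <- group_samples(samples, group2)
  if (length(ids1) < 2 || length(ids2) < 2) stop("both groups need >= 2 samples")
  p_raw <- vapply(seq_len(nrow(region_signal)), function(i) {
    x <- region_signal[i, ids1]; y <- region_signal[i, ids2]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    mann_whitney_p(x, y)
  }, numeric(1))
  p_adj <- if (correction == "bh") {
    out <- rep(NA_real_, length(p_raw))
    out[!is.na(p_raw)] <- bh_adjust(p_raw[!is.na(p_raw)])
    out
  } else {
    p_raw
  }
  data.frame(region_id = rownames(region_signal), p_raw = p_raw,
             p_adj = p_adj, significant = !is.na(p_adj) & p_adj < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Mean CpG methylation per enhancer and sample
#'
#' Arithmetic mean of beta values at CpGs inside each enhancer interval,
#' per sample. Samples with no covered CpG in an enhancer get `NA` (such
#' cells are excluded from downstream correlations; their count is
#' reported in a message).
#'
#' @param meth methylation data frame.
#' @param enhancers enhancer interval data frame.
#' @param sample_ids sample universe for the columns (default: samples seen
#'   in `meth`).
#' @return numeric matrix enhancers x samples of mean betas (with `NA`
#'   holes).
#' @export
enhancer_methylation <- function(meth, enhancers, sample_ids = NULL) {
  validate_methylation(meth)
  validate_intervals(enhancers, "enhancer")
  if (is.null(sample_ids)) sample_ids <- sort(unique(meth$sample_id))
  out <- matrix(NA_real_, nrow(enhancers), length(sample_ids),
                dimnames = list(enhancers$id, sample_ids))
  cpg <- data.frame(chrom = meth$chrom, start = meth$pos, end = meth$pos + 1)
  hits <- overlap_join(cpg, enhancers)
  if (nrow(hits)) {
    key <- paste(enhancers$id[hits$target_idx], meth$sample_id[hits$query_idx],
                 sep = "\r")
    means <- tapply(meth$beta[hits$query_idx], key, mean)
    parts <- strsplit(names(means), "\r", fixed = TRUE)
    eid <- vapply(parts, `[`, character(1), 1)
    sid <- vapply(parts, `[`, character(1), 2)
    ok <- sid %in% sample_ids
    out[cbind(eid[ok], sid[ok])] <- as.numeric(means)[ok]
  }
  n_missing <- sum(is.na(out))
  if (n_missing > 0) {
    message(n_missing, " (enhancer, sample) cell(s) without covered CpGs")
  }
  out
}

#' Correlation between linked gene expression and enhancer acetylation
#'
#' Per (gene, enhancer) link, the Spearman correlation between the gene's
#' expression and the enhancer's acetylation across samples, overall and
#' (optionally) within each grade group. Strata with fewer than 3 samples
#' are skipped (`NA`); constant vectors give `NA` and are excluded from
#' medians.
#'
#' @param links link data frame.
#' @param expression expression signal matrix.
#' @param acetylation enhancer acetylation signal matrix.
#' @param samples sample sheet.
#' @param per_group also compute per-grade correlations.
#' @return data frame with `gene_id`, `enhancer_id`, `rho`, and one
#'   `rho_<group>` column per grade when `per_group`.
#' @export
link_correlations <- function(links, expression, acetylation, samples,
                              per_group = TRUE) {
  shared <- intersect(colnames(expression), colnames(acetylation))
  shared <- intersect(shared, samples$sample_id)
  rho_for <- function(ids) {
    if (length(ids) < 3) return(rep(NA_real_, nrow(links)))
    vapply(seq_len(nrow(links)), function(i) {
      g <- links$gene_id[i]; e <- links$enhancer_id[i]
      if (!g %in% rownames(expression) || !e %in% rownames(acetylation)) {
        return(NA_real_)
      }
      spearman_rho(expression[g, ids], acetylation[e, ids])
    }, numeric(1))
  }
  out <- data.frame(gene_id = links$gene_id, enhancer_id = links$enhancer_id,
                    rho = rho_for(shared), stringsAsFactors = FALSE)
  if (per_group) {
    for (grp in attr(samples, "groups") %||% unique(samples$group)) {
      ids <- intersect(shared, samples$sample_id[samples$group == grp])
      out[[paste0("rho_", grp)]] <- rho_for(ids)
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Permutation null for linked expression-acetylation correlation
#'
#' Randomly re-pairs gene expression vectors with enhancer acetylation
#' vectors (breaking the observed gene-enhancer assignment), computes the
#' mean Spearman correlation over pairs in each replicate, and returns the
#' replicate means. On real coupled data the observed mean correlation is
#' high while the null medians sit near zero.
#'
#' @param link_expression matrix links x samples of gene expression, one
#'   row per link.
#' @param link_acetylation matrix links x samples of enhancer acetylation,
#'   rows parallel to `link_expression`.
#' @param reps number of random re-pairings (published procedure: 100).
#' @return list `means` (numeric vector of per-replicate mean rho, NA
#'   correlations excluded from each mean) and `median` of the means.
#' @export
correlation_permutation_null <- function(link_expression, link_acetylation,
                                         reps = 100) {
  stopifnot(nrow(link_expression) == nrow(link_acetylation),
            nrow(link_expression) >= 2, reps >= 1)
  n <- nrow(link_expression)
  means <- vapply(seq_len(reps), function(r) {
    perm <- sample.int(n)
    rho <- vapply(seq_len(n), function(i) {
      spearman_rho(link_expression[i, ], link_acetylation[perm[i], ])
    }, numeric(1))
    mean(rho, na.rm = TRUE)
  }, numeric(1))
  list(means = means, median = stats::median(means))
}
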