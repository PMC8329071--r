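#' Build promoter windows around canonical TSSs
#'
#' Promoters are symmetric windows `[tss - flank, tss + flank)` regardless of
#' strand (the published definition, TSS +/- 2 kb, is symmetric by
#' construction), clipped at the chromosome start.
#'
#' @param genes gene annotation data frame.
#' @param flank half-width in bp (> 0).
#' @return interval data frame with one promoter per gene, `id` = gene id.
#' @export
make_promoters <- function(genes, flank = 2000) {
  stopifnot(flank > 0)
  validate_genes(genes)
  genomic_intervals(genes$gene_id, genes$chrom,
                    pmax(0, genes$tss - flank), genes$tss + flank)
}

#' Aggregate per-peak signal into regions
#'
#' Sums, per (region, sample), the signal of all peaks overlapping the
#' region by at least one base. A peak spanning several regions contributes
#' its full value to each (no proportional splitting).
#'
#' @param peaks interval data frame of signal-carrying features.
#' @param peak_signal signal matrix with one row per peak (rownames matching
#'   `peaks$id`).
#' @param regions interval data frame (e.g. promoters from
#'   [make_promoters()]).
#' @param samples optional sample sheet; when given, `peak_signal` columns
#'   must all be known sample ids.
#' @return matrix regions x samples of summed signal (0 where nothing
#'   overlaps) with the `kind` of `peak_signal`.
#' @export
aggregate_signal <- function(peaks, peak_signal, regions, samples = NULL) {
  validate_intervals(peaks, "peak")
  validate_intervals(regions, "region")
  stopifnot(setequal(rownames(peak_signal), peaks$id))
  if (!is.null(samples)) {
    unknown <- setdiff(colnames(peak_signal), samples$sample_id)
    if (length(unknown)) {
      stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
    }
  }
  peak_signal <- peak_signal[peaks$id, , drop = FALSE]
  out <- matrix(0, nrow = nrow(regions), ncol = ncol(peak_signal),
                dimnames = list(regions$id, colnames(peak_signal)))
  hits <- overlap_join(peaks, regions)
  if (nrow(hits)) {
    agg <- rowsum(peak_signal[hits$query_idx, , drop = FALSE],
                  group = regions$id[hits$target_idx], reorder = FALSE)
    out[rownames(agg), ] <- agg
  }
  k <- attr(peak_signal, "kind")
  if (!is.null(k)) attr(out, "kind") <- k
  out
}

#' Assign genes to TADs by TSS position
#'
#' A gene belongs to a TAD iff its TSS lies inside the TAD interval
#' (half-open: a TSS exactly at a TAD end coordinate falls outside). Genes
#' outside every TAD are unassigned and excluded from TAD-level statistics.
#'
#' @param genes gene annotation data frame.
#' @param tads TAD interval data frame (non-overlapping; validated).
#' @return list with `gene2tad` (named character vector gene -> TAD, `NA`
#'   for unassigned genes) and `tad2genes` (named list TAD -> gene ids, in
#'   TSS order).
#' @export
assign_genes_to_tads <- function(genes, tads) {
  validate_genes(genes)
  validate_tads(tads)
  tss <- data.frame(chrom = genes$chrom, start = genes$tss,
                    end = genes$tss + 1)
  hits <- overlap_join(tss, tads)
  gene2tad <- stats::setNames(rep(NA_character_, nrow(genes)), genes$gene_id)
  gene2tad[hits$query_idx] <- tads$id[hits$target_idx]
  tad2genes <- stats::setNames(vector("list", nrow(tads)), tads$id)
  if (nrow(hits)) {
    o <- order(genes$tss[hits$query_idx])
    sp <- split(genes$gene_id[hits$query_idx][o],
                tads$id[hits$target_idx][o])
    tad2genes[names(sp)] <- sp
  }
  tad2genes[vapply(tad2genes, is.null, logical(1))] <- list(character())
  list(gene2tad = gene2tad, tad2genes = tad2genes)
}
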