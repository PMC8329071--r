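#' Read a gene annotation table
#'
#' Tab-separated with header: `gene_id`, `chrom`, `strand`, `tss`. Each gene
#' carries one canonical, strand-aware TSS as a 0-based position.
#'
#' @param path path to the TSV.
#' @return data frame with columns `gene_id`, `chrom`, `strand`, `tss`.
#' @export
read_genes <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = "chrom"))
  need <- c("gene_id", "chrom", "strand", "tss")
  if (!all(need %in% names(dt))) {
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  }
  genes <- as.data.frame(dt[, need, with = FALSE])
  genes$gene_id <- as.character(genes$gene_id)
  genes$tss <- as.numeric(genes$tss)
  validate_genes(genes)
  genes
}

validate_genes <- function(genes) {
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id in annotation")
  if (any(genes$tss < 0)) stop("negative TSS position")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  invisible(genes)
}

#' @rdname read_genes
#' @param genes gene annotation data frame.
#' @export
write_genes <- function(genes, path) {
  data.table::fwrite(genes, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Signal matrices
#'
#' A signal matrix holds non-negative feature-by-sample values (read counts
#' or mark coverage): a numeric matrix with feature ids as rownames, sample
#' ids as colnames, and a `kind` attribute naming the assay.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#' @param kind one of `"expression"`, `"H3K4me3"`, `"H3K27ac"`,
#'   `"H3K27me3"`, `"ATAC"`, `"DNase"`, `"methyl_count"`.
#' @return the validated matrix with its `kind` attribute set.
#' @export
signal_matrix <- function(values, kind) {
  kind <- match.arg(kind, signal_kinds())
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (anyDuplicated(rownames(values))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (any(is.na(values))) stop("signal matrix contains missing cells")
  if (any(values < 0)) stop("signal matrix contains negative values")
  attr(values, "kind") <- kind
  values
}

signal_kinds <- function() {
  c("expression", "H3K4me3", "H3K27ac", "H3K27me3", "ATAC", "DNase",
    "methyl_count")
}

#' @rdname signal_matrix
#' @param path path to a TSV whose first column (`feature_id`) holds feature
#'   ids and whose remaining column names are sample ids.
#' @export
read_signal_matrix <- function(path, kind) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- as.character(dt[[1]])
  storage.mode(m) <- "double"
  signal_matrix(m, kind)
}

#' @rdname signal_matrix
#' @param x signal matrix.
#' @export
write_signal_matrix <- function(x, path) {
  dt <- data.table::data.table(feature_id = rownames(x))
  dt <- cbind(dt, data.table::as.data.table(unclass(x)))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Sample sheets
#'
#' Maps sample ids to grade groups. The default group set, in malignancy
#' order, is PA (pilocytic astrocytoma, WHO I), DA (diffuse astrocytoma,
#' WHO II/III) and GBM (glioblastoma, WHO IV; adult and pediatric pooled).
#'
#' @param sample_id character vector of unique sample ids.
#' @param group group label per sample.
#' @param groups ordered set of allowed group labels.
#' @return data frame with columns `sample_id`, `group`; the ordered group
#'   set is kept in the `"groups"` attribute.
#' @export
sample_sheet <- function(sample_id, group, groups = c("PA", "DA", "GBM")) {
  if (anyDuplicated(sample_id)) stop("duplicate sample ids")
  if (!all(group %in% groups)) {
    stop("unknown group label(s): ",
         paste(setdiff(unique(group), groups), collapse = ", "))
  }
  out <- data.frame(sample_id = as.character(sample_id),
                    group = as.character(group), stringsAsFactors = FALSE)
  attr(out, "groups") <- groups
  out
}

#' @rdname sample_sheet
#' @param path TSV with header columns `sample_id`, `group`.
#' @export
read_sample_sheet <- function(path, groups = c("PA", "DA", "GBM")) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  sample_sheet(dt$sample_id, dt$group, groups)
}

#' @rdname sample_sheet
#' @param samples sample sheet.
#' @export
write_sample_sheet <- function(samples, path) {
  data.table::fwrite(samples, path, sep = "\t", quote = FALSE)
  invisible(path)
}

group_samples <- function(samples, group) {
  ids <- samples$sample_id[samples$group == group]
  if (!length(ids)) stop("unknown or empty group: ", group)
  ids
}

#' Read per-cytosine methylation beta values
#'
#' Long-format TSV with header `chrom`, `pos`, `sample_id`, `beta`; one row
#' per covered CpG per sample. Positions are 0-based; betas are methylated
#' read fractions in \[0, 1\].
#'
#' @param path path to the TSV.
#' @return data frame with those four columns.
#' @export
read_methylation <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("chrom", "sample_id")))
  meth <- as.data.frame(dt[, c("chrom", "pos", "sample_id", "beta"), with = FALSE])
  validate_methylation(meth)
  meth
}

validate_methylation <- function(meth) {
  if (any(meth$beta < 0 | meth$beta > 1)) stop("beta outside [0, 1]")
  if (any(meth$pos < 0)) stop("negative CpG position")
  invisible(meth)
}

#' @rdname read_methylation
#' @param meth methylation data frame.
#' @export
write_methylation <- function(meth, path) {
  data.table::fwrite(meth, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis, with the published
#' value of each as its default: promoters as TSS +/- 2 kb, differential
#' calls at corrected p < 0.01, active genes at mean count >= 10,
#' high-correlation selection at Spearman rho > 0.7, hypermethylation at
#' beta >= 0.8, TAD enrichment at BH p < 0.05 with TADs under 3 genes
#' excluded, gene-enhancer contacts within 2 Mb, the >= 6 contact
#' multiplicity class, top-1000 bivalent selection, and raw Mann-Whitney
#' p < 0.01 for grade-specific enhancers.
#'
#' @param promoter_flank promoter half-width in bp.
#' @param deg_alpha corrected-p threshold for differential calls.
#' @param active_min_mean mean-count threshold defining active genes.
#' @param rho_select Spearman rho threshold (strict >) for high-correlation
#'   gene selection.
#' @param beta_hyper beta threshold (inclusive >=) for hypermethylated CpGs.
#' @param enrich_alpha BH threshold for TAD enrichment.
#' @param min_tad_genes TADs with fewer genes are excluded from enrichment
#'   testing.
#' @param contact_max_dist maximum promoter-enhancer distance in bp.
#' @param multi_contact_min contact count from which a gene counts as
#'   multi-contact.
#' @param bivalent_top_n genes taken from the top of each mark ranking.
#' @param enhancer_diff_alpha raw-p cutoff (strict <) for differential
#'   enhancer acetylation/methylation.
#' @param n_perm permutations for the TAD homogeneity null.
#' @param n_boot bootstrap replicates for the DEG/DEM overlap test.
#' @param n_corr_perm replicates for the enhancer-gene correlation null.
#' @param rng_seed integer seed used by [run_pipeline()].
#' @return a validated list of class `gliotad_config`.
#' @export
pipeline_config <- function(promoter_flank = 2000, deg_alpha = 0.01,
                            active_min_mean = 10, rho_select = 0.7,
                            beta_hyper = 0.8, enrich_alpha = 0.05,
                            min_tad_genes = 3, contact_max_dist = 2e6,
                            multi_contact_min = 6, bivalent_top_n = 1000,
                            enhancer_diff_alpha = 0.01, n_perm = 1000,
                            n_boot = 1000, n_corr_perm = 100, rng_seed = 1L) {
  cfg <- list(promoter_flank = promoter_flank, deg_alpha = deg_alpha,
              active_min_mean = active_min_mean, rho_select = rho_select,
              beta_hyper = beta_hyper, enrich_alpha = enrich_alpha,
              min_tad_genes = min_tad_genes,
              contact_max_dist = contact_max_dist,
              multi_contact_min = multi_contact_min,
              bivalent_top_n = bivalent_top_n,
              enhancer_diff_alpha = enhancer_diff_alpha,
              n_perm = n_perm, n_boot = n_boot, n_corr_perm = n_corr_perm,
              rng_seed = as.integer(rng_seed))
  pos <- c("promoter_flank", "active_min_mean", "enrich_alpha", "deg_alpha",
           "min_tad_genes", "contact_max_dist", "multi_contact_min",
           "bivalent_top_n", "enhancer_diff_alpha", "n_perm", "n_boot",
           "n_corr_perm", "rho_select", "beta_hyper")
  for (nm in pos) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] <= 0) {
      stop("config field must be a positive scalar: ", nm)
    }
  }
  for (nm in c("deg_alpha", "enrich_alpha", "enhancer_diff_alpha",
               "beta_hyper", "rho_select")) {
    if (cfg[[nm]] >= 1) stop("config probability must be in (0, 1): ", nm)
  }
  structure(cfg, class = "gliotad_config")
}
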