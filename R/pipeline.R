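#' Run the TAD-aware regulation pipeline end-to-end
#'
#' Executes the analysis stages in dependency order on a cohort (either a
#' cohort list from [simulate_cohort()]/[read_cohort()] or a directory
#' written by [write_cohort()]): differential expression between all grade
#' pairs, promoter/TAD assignment, expression-mark correlation with
#' high-correlation selection, TAD enrichment and fold-change homogeneity,
#' bivalent-chromatin detection with the hypergeometric TAD overlap,
#' enhancer calling/linking/differential activity/methylation with the
#' correlation permutation null, and (when candidate pairs are supplied)
#' TF-target envelope filtering. Stage outputs are written as TSV under
#' `outdir`; a manifest records the configuration, seed, per-stage outputs
#' and their checksums.
#'
#' @param cohort cohort list or cohort directory path.
#' @param config analysis configuration from [pipeline_config()].
#' @param outdir output directory.
#' @param stages subset of stages to run, in any order; dependencies
#'   (differential calls, promoters, assignments) are computed on demand.
#' @param tf_candidates optional data frame of candidate TF-target pairs
#'   (`tf_gene_id`, `target_gene_id`).
#' @param prognostic optional character vector of prognostic gene ids.
#' @return the manifest, invisibly; also written as `manifest.json` when
#'   the jsonlite package is available.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), outdir,
                         stages = c("differential", "correlation",
                                    "tad_stats", "bivalent", "enhancers",
                                    "tf"),
                         tf_candidates = NULL, prognostic = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$rng_seed)
  p <- function(f) file.path(outdir, f)
  outputs <- character()
  log <- list()
  groups <- attr(cohort$samples, "groups") %||% unique(cohort$samples$group)
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  pair_name <- function(pr) paste(pr[1], pr[2], sep = "_vs_")

  # shared prerequisites (cheap; always computed)
  promoters <- make_promoters(cohort$genes, config$promoter_flank)
  assignment <- assign_genes_to_tads(cohort$genes, cohort$tads)
  active <- active_genes(cohort$expression, config$active_min_mean)
  diff_res <- lapply(pairs, function(pr) {
    rank_test_differential(cohort$expression, cohort$samples, pr[1], pr[2],
                           correction = "bh", alpha = config$deg_alpha)
  })
  names(diff_res) <- vapply(pairs, pair_name, character(1))
  deg_sets <- lapply(diff_res, function(d) d$feature_id[d$significant])
  log$n_active <- length(active)
  log$n_deg <- lengths(deg_sets)
  # the extreme-grade comparison (first vs last group) anchors the
  # promoter-mark, bivalent and enhancer stages
  main_pair <- c(groups[1], groups[length(groups)])
  main_key <- pair_name(main_pair)

  if ("differential" %in% stages) {
    for (nm in names(diff_res)) {
      f <- p(sprintf("differential_expression_%s.tsv", nm))
      write_differential(diff_res[[nm]], f)
      outputs <- c(outputs, f)
    }
  }

  if ("correlation" %in% stages) {
    corr <- do.call(rbind, lapply(names(cohort$marks), function(kind) {
      gene_mark_correlations(cohort$expression, cohort$marks[[kind]],
                             deg_sets[[main_key]])
    }))
    f <- p("gene_mark_correlations.tsv")
    data.table::fwrite(corr, f, sep = "\t"); outputs <- c(outputs, f)
    high <- select_high_rho(corr[corr$mark_kind == "H3K27ac", , drop = FALSE],
                            config$rho_select)
    log$n_high_rho <- length(high)
    dem <- rank_test_differential(cohort$marks$H3K27ac, cohort$samples,
                                  main_pair[1], main_pair[2],
                                  correction = "bh", alpha = config$deg_alpha)
    dem_set <- dem$feature_id[dem$significant]
    log$n_dem <- length(dem_set)
    boot_p <- if (length(deg_sets[[main_key]]) &&
                    length(setdiff(active, deg_sets[[main_key]])) >
                      length(deg_sets[[main_key]])) {
      bootstrap_overlap_p(deg_sets[[main_key]], dem_set, active,
                          cohort$expression, reps = config$n_boot)
    } else {
      NA_real_
    }
    summ <- data.frame(
      comparison = main_key, n_deg = length(deg_sets[[main_key]]),
      n_dem = length(dem_set),
      n_overlap = length(intersect(deg_sets[[main_key]], dem_set)),
      bootstrap_overlap_p = boot_p)
    if (!is.null(prognostic)) {
      props <- prognostic_overlap_ratio(
        list(high_rho = high, all_deg = deg_sets[[main_key]]),
        prognostic, list(high_rho = deg_sets[[main_key]],
                         all_deg = deg_sets[[main_key]]))
      summ$prognostic_share_high_rho <- props[["high_rho"]]
      summ$prognostic_share_all_deg <- props[["all_deg"]]
    }
    f <- p("correlation_summary.tsv")
    data.table::fwrite(summ, f, sep = "\t"); outputs <- c(outputs, f)
  }

  if ("tad_stats" %in% stages) {
    for (nm in names(diff_res)) {
      enr <- tad_enrichment(assignment, deg_sets[[nm]],
                            alpha = config$enrich_alpha,
                            min_genes = config$min_tad_genes)
      f <- p(sprintf("tad_enrichment_%s.tsv", nm))
      data.table::fwrite(enr, f, sep = "\t"); outputs <- c(outputs, f)
    }
    fc <- log2_fold_changes(cohort$expression, cohort$samples,
                            main_pair[1], main_pair[2])
    hom <- permutation_homogeneity(fc, assignment, n_perm = config$n_perm)
    f <- p("homogeneity_expression.tsv")
    data.table::fwrite(data.frame(
      comparison = main_key, statistic = hom$statistic,
      p_asymptotic = hom$p_asymptotic, p_permutation = hom$p_permutation,
      n_perm = hom$n_perm, n_genes = hom$n_genes, n_tads = hom$n_tads),
      f, sep = "\t")
    outputs <- c(outputs, f)
    mark_fc <- log2_fold_changes(cohort$marks$H3K27ac, cohort$samples,
                                 main_pair[1], main_pair[2])
    deg_fc <- fc[intersect(names(fc), deg_sets[[main_key]])]
    tfc <- tryCatch(tad_fc_correlation(deg_fc, mark_fc, assignment),
                    error = function(e) NULL)
    if (!is.null(tfc)) {
      f <- p("tad_fc_correlation.tsv")
      data.table::fwrite(tfc$per_tad, f, sep = "\t"); outputs <- c(outputs, f)
      log$tad_fc_rho <- tfc$rho
    }
  }

  if ("bivalent" %in% stages) {
    gbm <- group_samples(cohort$samples, groups[length(groups)])
    biv <- bivalent_genes(cohort$marks$H3K4me3, cohort$marks$H3K27me3,
                          deg_sets[[main_key]],
                          top_n = min(config$bivalent_top_n,
                                      nrow(cohort$marks$H3K4me3)),
                          sample_ids = gbm)
    f <- p("bivalent_genes.tsv")
    data.table::fwrite(data.frame(gene_id = biv), f, sep = "\t")
    outputs <- c(outputs, f)
    enr <- tad_enrichment(assignment, deg_sets[[main_key]],
                          alpha = config$enrich_alpha,
                          min_genes = config$min_tad_genes)
    universe <- enr$tad_id[!is.na(enr$p_raw)]
    marked <- unique(stats::na.omit(assignment$gene2tad[biv]))
    hyp <- tad_overlap_hypergeom(
      intersect(enr$tad_id[enr$enriched], universe),
      intersect(marked, universe), universe)
    f <- p("bivalent_tad_overlap.tsv")
    data.table::fwrite(data.frame(
      n_bivalent = length(biv), n_marked_tads = length(marked),
      n_enriched_tads = sum(enr$enriched), hypergeom_p = hyp),
      f, sep = "\t")
    outputs <- c(outputs, f)
  }

  if ("enhancers" %in% stages) {
    enh <- call_enhancers(cohort$enhancers$intervals,
                          cohort$enhancers$acetylation, promoters)
    links <- link_genes_to_enhancers(
      promoters[promoters$id %in% deg_sets[[main_key]], , drop = FALSE],
      enh$intervals, cohort$contacts, config$contact_max_dist)
    f <- p("gene_enhancer_links.tsv")
    data.table::fwrite(links, f, sep = "\t"); outputs <- c(outputs, f)
    classes <- contact_classes(links, genes = deg_sets[[main_key]],
                               multi_min = config$multi_contact_min)
    f <- p("contact_classes.tsv")
    data.table::fwrite(classes, f, sep = "\t"); outputs <- c(outputs, f)
    cmp <- tryCatch(
      compare_expression_by_class(cohort$expression, classes),
      error = function(e) NULL)
    if (!is.null(cmp)) log$class_expression_p <- cmp$p
    diff_enh <- differential_region_signal(
      enh$acetylation, cohort$samples, main_pair[1], main_pair[2],
      alpha = config$enhancer_diff_alpha)
    f <- p(sprintf("differential_enhancers_%s.tsv", main_key))
    data.table::fwrite(diff_enh, f, sep = "\t"); outputs <- c(outputs, f)
    log$n_diff_enhancers <- sum(diff_enh$significant)
    meth <- enhancer_methylation(cohort$methylation, enh$intervals,
                                 sample_ids = cohort$samples$sample_id)
    diff_meth <- differential_region_signal(
      meth, cohort$samples, main_pair[1], main_pair[2],
      alpha = config$enhancer_diff_alpha)
    f <- p(sprintf("differential_enhancer_methylation_%s.tsv", main_key))
    data.table::fwrite(diff_meth, f, sep = "\t"); outputs <- c(outputs, f)
    sig_links <- links[links$enhancer_id %in%
                         diff_enh$region_id[diff_enh$significant], ,
                       drop = FALSE]
    if (nrow(sig_links)) {
      lc <- link_correlations(sig_links, cohort$expression,
                              enh$acetylation, cohort$samples)
      f <- p("link_correlations.tsv")
      data.table::fwrite(lc, f, sep = "\t"); outputs <- c(outputs, f)
      if (nrow(sig_links) >= 2) {
        shared <- intersect(colnames(cohort$expression),
                            colnames(enh$acetylation))
        null <- correlation_permutation_null(
          cohort$expression[sig_links$gene_id, shared, drop = FALSE],
          enh$acetylation[sig_links$enhancer_id, shared, drop = FALSE],
          reps = config$n_corr_perm)
        f <- p("link_correlation_null.tsv")
        data.table::fwrite(
          data.frame(replicate = seq_along(null$means),
                     mean_rho = null$means), f, sep = "\t")
        outputs <- c(outputs, f)
        log$link_null_median <- null$median
        log$link_observed_median <-
          stats::median(lc$rho, na.rm = TRUE)
      }
    }
  }

  if ("tf" %in% stages && !is.null(tf_candidates)) {
    rec <- tf_target_correlations(tf_candidates, cohort$expression)
    envs <- lapply(unique(rec$tf_gene_id), function(tf) {
      excl <- rec$target_gene_id[rec$tf_gene_id == tf]
      random_target_envelope(
        tf, active, cohort$expression,
        n_draws = min(100L, length(setdiff(active, c(tf, excl)))),
        exclude = excl)
    })
    names(envs) <- unique(rec$tf_gene_id)
    rec <- filter_by_envelope(rec, envs)
    f <- p("tf_target_filtered.tsv")
    data.table::fwrite(rec, f, sep = "\t"); outputs <- c(outputs, f)
    log$n_tf_retained <- sum(rec$passes_envelope)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("gliotad")),
    rng_seed = config$rng_seed,
    config = unclass(config),
    stages = stages,
    outputs = basename(outputs),
    checksums = as.list(stats::setNames(tools::md5sum(outputs),
                                        basename(outputs))),
    log = log)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  invisible(manifest)
}
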