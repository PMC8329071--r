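#' Simulation configuration
#'
#' Defines a synthetic glioma cohort with the joint structure the analysis
#' assumes: a small genome tiled by TADs, genes with strand-aware TSSs,
#' negative-binomial expression counts with grade effects partly
#' concentrated in designated "enriched" TADs, promoter mark signals coupled
#' to expression through a Gaussian copula, enhancers with grade-specific
#' acetylation, contact pairs linking promoters to nearby enhancers, and
#' enhancer CpG methylation anticorrelated with acetylation. Group sizes
#' default to the glioma cohort structure (PA 11, DA 7, GBM 15 with the
#' single pediatric GBM pooled into GBM).
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_tads total number of TADs, tiled across chromosomes.
#' @param genes_per_tad genes placed in each TAD.
#' @param n_samples_per_group named integer vector, group -> sample count.
#' @param nb_mean baseline negative-binomial mean for counts.
#' @param nb_dispersion NB dispersion (variance = mu + mu^2 * dispersion).
#' @param frac_deg fraction of genes given a true grade effect.
#' @param lfc_effect log2 fold-change magnitude of the effect (applied
#'   progressively along the grade order: none in the first group, full in
#'   the last).
#' @param tad_coupling fraction of true differential genes concentrated in
#'   the enriched TADs.
#' @param n_enriched_tads number of TADs spiked with differential genes.
#' @param mark_coupling_rho target Spearman correlation between expression
#'   and promoter mark signal (H3K27me3 is coupled at minus this value, as
#'   a repressive mark).
#' @param n_enhancers number of enhancer peaks.
#' @param frac_diff_enhancers fraction of enhancers with a grade-specific
#'   acetylation shift.
#' @param contacts_per_gene mean contacts drawn per gene (Poisson).
#' @param methyl_anticorr strength in \[0, 1\] of the anticorrelation
#'   between enhancer mean methylation and acetylation.
#' @param cpgs_per_enhancer CpGs simulated inside each enhancer.
#' @param promoter_flank promoter half-width used for contact anchors.
#' @param contact_max_dist maximum promoter-enhancer distance for simulated
#'   contacts.
#' @param enhancer_width enhancer width in bp.
#' @param seed integer seed; identical configs give byte-identical cohorts.
#' @return validated list of class `gliotad_sim_config`.
#' @export
simulation_config <- function(n_chrom = 2, chrom_length = 5e7, n_tads = 100,
                              genes_per_tad = 5,
                              n_samples_per_group = c(PA = 11, DA = 7, GBM = 15),
                              nb_mean = 100, nb_dispersion = 0.1,
                              frac_deg = 0.1, lfc_effect = 2,
                              tad_coupling = 0.8, n_enriched_tads = 5,
                              mark_coupling_rho = 0.7, n_enhancers = 200,
                              frac_diff_enhancers = 0.2,
                              contacts_per_gene = 3, methyl_anticorr = 0.8,
                              cpgs_per_enhancer = 10, promoter_flank = 2000,
                              contact_max_dist = 2e6, enhancer_width = 1500,
                              seed = 1L) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  for (nm in c("frac_deg", "tad_coupling", "frac_diff_enhancers",
               "methyl_anticorr")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) stop(nm, " must lie in [0, 1]")
  }
  if (abs(cfg$mark_coupling_rho) > 1) stop("mark_coupling_rho outside [-1, 1]")
  for (nm in c("n_chrom", "chrom_length", "n_tads", "genes_per_tad",
               "n_enhancers", "cpgs_per_enhancer", "promoter_flank",
               "contact_max_dist", "enhancer_width")) {
    if (cfg[[nm]] <= 0) stop(nm, " must be positive")
  }
  if (is.null(names(cfg$n_samples_per_group)) ||
      any(cfg$n_samples_per_group < 2)) {
    stop("n_samples_per_group must be named with >= 2 samples per group")
  }
  if (cfg$n_enriched_tads > cfg$n_tads) stop("n_enriched_tads > n_tads")
  structure(cfg, class = "gliotad_sim_config")
}

# progressive grade effect: 0 in the first group, 1 in the last
grade_fractions <- function(groups) {
  n <- length(groups)
  stats::setNames(if (n == 1) 1 else (seq_len(n) - 1) / (n - 1), groups)
}

nb_size <- function(dispersion) if (dispersion > 0) 1 / dispersion else 1e8

# latent Pearson correlation giving Spearman rho under a Gaussian copula
copula_latent_r <- function(rho_s) 2 * sin(pi * rho_s / 6)

#' Generate the synthetic genome: TADs, genes, ground truth
#'
#' TADs tile each chromosome without gaps or overlap; every TAD carries
#' exactly `genes_per_tad` genes, so each TSS lies in exactly one TAD. The
#' truth tables record which genes carry a real grade effect and which TADs
#' were spiked as enriched.
#'
#' @param config simulation configuration from [simulation_config()].
#' @return list `genes` (annotation data frame), `tads` (interval data
#'   frame), `truth` (list of data frames `genes`, `tads`).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "gliotad_sim_config"))
  set.seed(config$seed)
  per_chrom <- diff(round(seq(0, config$n_tads, length.out = config$n_chrom + 1)))
  tad_rows <- list(); gene_rows <- list()
  tad_i <- 0L
  for (ci in seq_len(config$n_chrom)) {
    ch <- paste0("chr", ci)
    n <- per_chrom[ci]
    if (n == 0) next
    w <- floor(config$chrom_length / n)
    if (config$genes_per_tad > w) {
      stop("genes_per_tad exceeds TAD width; enlarge chrom_length")
    }
    for (k in seq_len(n)) {
      tad_i <- tad_i + 1L
      s <- (k - 1) * w; e <- k * w
      tid <- sprintf("tad_%04d", tad_i)
      tad_rows[[tad_i]] <- data.frame(id = tid, chrom = ch, start = s, end = e,
                                      stringsAsFactors = FALSE)
      tss <- s + sort(sample.int(e - s, config$genes_per_tad)) - 1
      gene_rows[[tad_i]] <- data.frame(
        gene_id = NA_character_, chrom = ch,
        strand = sample(c("+", "-"), config$genes_per_tad, replace = TRUE),
        tss = tss, tad_id = tid, stringsAsFactors = FALSE)
    }
  }
  tads <- do.call(rbind, tad_rows)
  genes <- do.call(rbind, gene_rows)
  genes$gene_id <- sprintf("gene_%05d", seq_len(nrow(genes)))
  enriched <- sample(tads$id, config$n_enriched_tads)
  n_deg <- round(config$frac_deg * nrow(genes))
  in_pool <- genes$gene_id[genes$tad_id %in% enriched]
  out_pool <- setdiff(genes$gene_id, in_pool)
  n_in <- min(round(config$tad_coupling * n_deg), length(in_pool))
  n_out <- min(n_deg - n_in, length(out_pool))
  degs <- c(if (n_in > 0) sample(in_pool, n_in),
            if (n_out > 0) sample(out_pool, n_out))
  direction <- stats::setNames(rep(0L, nrow(genes)), genes$gene_id)
  direction[degs] <- sample(c(-1L, 1L), length(degs), replace = TRUE)
  truth_genes <- data.frame(
    gene_id = genes$gene_id, tad_id = genes$tad_id,
    is_deg = genes$gene_id %in% degs,
    direction = as.integer(direction[genes$gene_id]),
    stringsAsFactors = FALSE)
  truth_tads <- data.frame(tad_id = tads$id, enriched = tads$id %in% enriched,
                           stringsAsFactors = FALSE)
  list(genes = genes[, c("gene_id", "chrom", "strand", "tss")],
       tads = tads,
       truth = list(genes = truth_genes, tads = truth_tads))
}

copula_coupled_matrix <- function(expression, rho_s, base_mean, size) {
  n <- ncol(expression)
  rl <- copula_latent_r(rho_s)
  z_e <- qnorm(t(apply(expression, 1, rank)) / (n + 1))
  z_m <- rl * z_e + sqrt(max(0, 1 - rl^2)) *
    matrix(stats::rnorm(length(z_e)), nrow(z_e), n)
  out <- stats::qnbinom(stats::pnorm(z_m), mu = base_mean, size = size)
  dimnames(out) <- dimnames(expression)
  storage.mode(out) <- "double"
  out
}

#' Generate a full synthetic cohort
#'
#' Draws every assay of the cohort from the genome and truth produced by
#' [generate_genome()]. See [simulation_config()] for the noise model.
#'
#' @param genome result of [generate_genome()].
#' @param config the same simulation configuration.
#' @return list with `samples` (sample sheet), `expression` (signal
#'   matrix), `marks` (named list of promoter-level signal matrices for
#'   H3K4me3, H3K27ac, H3K27me3, ATAC, DNase), `enhancers` (list
#'   `intervals`, `acetylation`), `contacts` (BEDPE-style data frame),
#'   `methylation` (long data frame), `genes`, `tads`, and `truth` (with an
#'   added `enhancers` table).
#' @export
generate_cohort <- function(genome, config) {
  stopifnot(inherits(config, "gliotad_sim_config"))
  genes <- genome$genes; tads <- genome$tads; truth <- genome$truth
  groups <- names(config$n_samples_per_group)
  samples <- sample_sheet(
    unlist(lapply(groups, function(g) {
      sprintf("%s_%02d", g, seq_len(config$n_samples_per_group[[g]]))
    })),
    rep(groups, config$n_samples_per_group), groups = groups)
  gfrac <- grade_fractions(groups)
  sfrac <- gfrac[samples$group]
  n_s <- nrow(samples); n_g <- nrow(genes)
  size <- nb_size(config$nb_dispersion)

  # expression: NB counts with progressive grade shifts for true DEGs
  set.seed(config$seed + 1000000L)
  base_mean <- stats::rlnorm(n_g, log(config$nb_mean), 1)
  # the effect is centred on the grade axis so a true DEG's baseline mean
  # stays comparable to the pool (the extreme-grade ratio is still
  # 2^lfc_effect)
  dir <- truth$genes$direction
  mu <- outer(base_mean, rep(1, n_s)) *
    2^(outer(dir * config$lfc_effect, sfrac - 0.5))
  expression <- matrix(stats::rnbinom(n_g * n_s, mu = mu, size = size),
                       n_g, n_s, dimnames = list(genes$gene_id,
                                                 samples$sample_id))
  storage.mode(expression) <- "double"
  expression <- signal_matrix(expression, "expression")

  # promoter marks: rank copula against realised expression
  set.seed(config$seed + 2000000L)
  mark_rho <- c(H3K4me3 = config$mark_coupling_rho,
                H3K27ac = config$mark_coupling_rho,
                H3K27me3 = -config$mark_coupling_rho,
                ATAC = config$mark_coupling_rho,
                DNase = config$mark_coupling_rho)
  marks <- lapply(names(mark_rho), function(kind) {
    base <- stats::rlnorm(n_g, log(config$nb_mean), 0.5)
    signal_matrix(copula_coupled_matrix(expression, mark_rho[[kind]],
                                        base, size), kind)
  })
  names(marks) <- names(mark_rho)

  # enhancers: peaks placed outside promoter windows, a fraction with
  # grade-shifted acetylation
  set.seed(config$seed + 3000000L)
  promoters <- make_promoters(genes, config$promoter_flank)
  chroms <- unique(tads$chrom)
  enh_rows <- vector("list", config$n_enhancers)
  for (i in seq_len(config$n_enhancers)) {
    for (try in 1:1000) {
      ch <- sample(chroms, 1)
      s <- sample.int(config$chrom_length - config$enhancer_width, 1) - 1
      e <- s + config$enhancer_width
      if (!length(overlap_query(promoters, ch, s, e))) break
      if (try == 1000) stop("cannot place enhancer outside promoters")
    }
    enh_rows[[i]] <- data.frame(id = sprintf("enh_%04d", i), chrom = ch,
                                start = s, end = e, stringsAsFactors = FALSE)
  }
  enh <- do.call(rbind, enh_rows)
  n_diff <- round(config$frac_diff_enhancers * config$n_enhancers)
  diff_ids <- if (n_diff > 0) sample(enh$id, n_diff) else character()
  enh_dir <- stats::setNames(rep(0L, config$n_enhancers), enh$id)
  enh_dir[diff_ids] <- sample(c(-1L, 1L), n_diff, replace = TRUE)
  enh_base <- stats::rlnorm(config$n_enhancers, log(config$nb_mean), 0.5)
  enh_mu <- outer(enh_base, rep(1, n_s)) *
    2^(outer(enh_dir * config$lfc_effect, sfrac))
  acetylation <- matrix(
    stats::rnbinom(config$n_enhancers * n_s, mu = enh_mu, size = size),
    config$n_enhancers, n_s,
    dimnames = list(enh$id, samples$sample_id))
  storage.mode(acetylation) <- "double"
  acetylation <- signal_matrix(acetylation, "H3K27ac")
  truth$enhancers <- data.frame(enhancer_id = enh$id,
                                is_diff = enh$id %in% diff_ids,
                                direction = as.integer(enh_dir),
                                stringsAsFactors = FALSE)

  # contacts: promoter anchor paired with an eligible enhancer anchor on
  # the same chromosome within the contact window
  set.seed(config$seed + 4000000L)
  enh_mid <- (enh$start + enh$end) / 2
  contact_rows <- list()
  for (gi in seq_len(n_g)) {
    k <- stats::rpois(1, config$contacts_per_gene)
    if (k == 0) next
    eligible <- which(enh$chrom == genes$chrom[gi] &
                        abs(enh_mid - genes$tss[gi]) <= config$contact_max_dist)
    if (!length(eligible)) next
    pick <- eligible[sample.int(length(eligible), k, replace = TRUE)]
    contact_rows[[length(contact_rows) + 1L]] <- data.frame(
      chrom = genes$chrom[gi],
      start_a = promoters$start[gi], end_a = promoters$end[gi],
      start_b = enh$start[pick], end_b = enh$end[pick],
      score = 1, stringsAsFactors = FALSE)
  }
  contacts <- if (length(contact_rows)) {
    do.call(rbind, contact_rows)
  } else {
    data.frame(chrom = character(), start_a = numeric(), end_a = numeric(),
               start_b = numeric(), end_b = numeric(), score = numeric())
  }
  rownames(contacts) <- NULL

  # methylation: enhancer CpG betas whose per-sample mean anticorrelates
  # with that enhancer's acetylation
  set.seed(config$seed + 5000000L)
  rl <- copula_latent_r(config$methyl_anticorr)
  meth_rows <- vector("list", config$n_enhancers)
  for (i in seq_len(config$n_enhancers)) {
    pos <- enh$start[i] +
      sort(sample.int(enh$end[i] - enh$start[i], config$cpgs_per_enhancer)) - 1
    z_a <- qnorm(rank(acetylation[i, ]) / (n_s + 1))
    z_b <- -rl * z_a + sqrt(max(0, 1 - rl^2)) * stats::rnorm(n_s)
    z_cs <- rep(z_b, each = config$cpgs_per_enhancer) +
      0.3 * stats::rnorm(config$cpgs_per_enhancer * n_s)
    beta <- stats::qbeta(stats::pnorm(z_cs / sqrt(1.09)), 5, 5)
    meth_rows[[i]] <- data.frame(
      chrom = enh$chrom[i],
      pos = rep(pos, times = n_s),
      sample_id = rep(samples$sample_id, each = config$cpgs_per_enhancer),
      beta = beta, stringsAsFactors = FALSE)
  }
  methylation <- do.call(rbind, meth_rows)
  rownames(methylation) <- NULL

  list(samples = samples, expression = expression, marks = marks,
       enhancers = list(intervals = enh, acetylation = acetylation),
       contacts = contacts, methylation = methylation,
       genes = genes, tads = tads, truth = truth)
}

#' Simulate a complete cohort in one call
#'
#' @inheritParams generate_genome
#' @return see [generate_cohort()].
#' @export
simulate_cohort <- function(config = simulation_config()) {
  genome <- generate_genome(config)
  generate_cohort(genome, config)
}

#' Write / read a cohort directory
#'
#' Writes every component of a simulated cohort in the exact plain-text
#' formats the package readers consume (BED for TADs and enhancers, BEDPE
#' for contacts, TSV for matrices, sample sheet, methylation and truth
#' tables), so a cohort round-trips through the I/O layer.
#'
#' @param cohort cohort list from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_genes(cohort$genes, p("genes.tsv"))
  write_intervals(cohort$tads, p("tads.bed"))
  write_sample_sheet(cohort$samples, p("samples.tsv"))
  write_signal_matrix(cohort$expression, p("expression.tsv"))
  for (kind in names(cohort$marks)) {
    write_signal_matrix(cohort$marks[[kind]],
                        p(sprintf("mark_%s.tsv", kind)))
  }
  write_intervals(cohort$enhancers$intervals, p("enhancers.bed"))
  write_signal_matrix(cohort$enhancers$acetylation,
                      p("enhancer_H3K27ac.tsv"))
  write_contacts(cohort$contacts, p("contacts.bedpe"))
  write_methylation(cohort$methylation, p("methylation.tsv"))
  data.table::fwrite(cohort$truth$genes, p("truth_genes.tsv"), sep = "\t")
  data.table::fwrite(cohort$truth$tads, p("truth_tads.tsv"), sep = "\t")
  data.table::fwrite(cohort$truth$enhancers, p("truth_enhancers.tsv"),
                     sep = "\t")
  invisible(dir)
}

#' @rdname write_cohort
#' @param groups ordered group labels for the sample sheet.
#' @export
read_cohort <- function(dir, groups = c("PA", "DA", "GBM")) {
  p <- function(f) file.path(dir, f)
  mark_files <- list.files(dir, pattern = "^mark_.*\\.tsv$")
  kinds <- sub("^mark_(.*)\\.tsv$", "\\1", mark_files)
  marks <- stats::setNames(lapply(kinds, function(k) {
    read_signal_matrix(p(sprintf("mark_%s.tsv", k)), k)
  }), kinds)
  truth <- list(
    genes = as.data.frame(data.table::fread(p("truth_genes.tsv"))),
    tads = as.data.frame(data.table::fread(p("truth_tads.tsv"))),
    enhancers = as.data.frame(data.table::fread(p("truth_enhancers.tsv"))))
  list(
    samples = read_sample_sheet(p("samples.tsv"), groups),
    expression = read_signal_matrix(p("expression.tsv"), "expression"),
    marks = marks,
    enhancers = list(
      intervals = read_intervals(p("enhancers.bed")),
      acetylation = read_signal_matrix(p("enhancer_H3K27ac.tsv"), "H3K27ac")),
    contacts = read_contacts(p("contacts.bedpe")),
    methylation = read_methylation(p("methylation.tsv")),
    genes = read_genes(p("genes.tsv")),
    tads = read_tads(p("tads.bed")),
    truth = truth)
}
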