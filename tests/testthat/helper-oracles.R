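# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they validate.

# exact two-sided Mann-Whitney p by enumerating all rank assignments
enumerate_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  centre <- n1 * n2 / 2
  mean(abs(u_all - centre) >= abs(u_obs - centre) - 1e-9)
}

# BH step-up written from the definition
stepup_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(1, q)
  out
}

# binomial upper tail by direct pmf summation
binom_upper_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(choose(n, k:n) * p^(k:n) * (1 - p)^(n - (k:n)))
}

# hypergeometric upper tail by exhaustive subset enumeration
enumerate_hyper_p <- function(universe, enriched, n_marked, k_obs) {
  subsets <- utils::combn(length(universe), n_marked)
  hits <- apply(subsets, 2, function(idx) {
    length(intersect(universe[idx], enriched)) >= k_obs
  })
  mean(hits)
}

# O(n) scan oracle for overlap_query
brute_overlaps <- function(targets, chrom, start, end) {
  hit <- targets$chrom == chrom & targets$start < end & targets$end > start
  targets$id[hit]
}

# O(genes x enhancers x contacts) oracle for gene-enhancer linking
brute_links <- function(promoters, enhancers, contacts, max_dist) {
  ov <- function(s1, e1, s2, e2) s1 < e2 && e1 > s2
  rows <- list()
  for (gi in seq_len(nrow(promoters))) {
    for (ei in seq_len(nrow(enhancers))) {
      if (promoters$chrom[gi] != enhancers$chrom[ei]) next
      d <- abs((promoters$start[gi] + promoters$end[gi]) / 2 -
                 (enhancers$start[ei] + enhancers$end[ei]) / 2)
      if (d > max_dist) next
      n <- 0L
      for (ci in seq_len(nrow(contacts))) {
        if (contacts$chrom[ci] != promoters$chrom[gi]) next
        pa <- ov(contacts$start_a[ci], contacts$end_a[ci],
                 promoters$start[gi], promoters$end[gi])
        pb <- ov(contacts$start_b[ci], contacts$end_b[ci],
                 promoters$start[gi], promoters$end[gi])
        ea <- ov(contacts$start_a[ci], contacts$end_a[ci],
                 enhancers$start[ei], enhancers$end[ei])
        eb <- ov(contacts$start_b[ci], contacts$end_b[ci],
                 enhancers$start[ei], enhancers$end[ei])
        if ((pa && eb) || (pb && ea)) n <- n + 1L
      }
      if (n > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = promoters$id[gi], enhancer_id = enhancers$id[ei],
          n_contacts = n, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(gene_id = character(), enhancer_id = character(),
                      n_contacts = integer()))
  }
  out <- do.call(rbind, rows)
  out[order(out$gene_id, out$enhancer_id), , drop = FALSE]
}

# draw two vectors with a target Spearman rho through a Gaussian copula
copula_pair <- function(n, rho) {
  rl <- 2 * sin(pi * rho / 6)
  z1 <- rnorm(n)
  z2 <- rl * z1 + sqrt(1 - rl^2) * rnorm(n)
  list(x = z1, y = z2)
}

tiny_samples <- function(n1 = 3, n2 = 3, groups = c("PA", "GBM")) {
  sample_sheet(c(sprintf("a%d", seq_len(n1)), sprintf("b%d", seq_len(n2))),
               rep(groups, c(n1, n2)), groups = groups)
}
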