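#' Per-cluster genetic diversity summaries
#'
#' For each genetic cluster (or the whole table) computes observed
#' heterozygosity (Ho, fraction heterozygous among non-missing calls),
#' unbiased expected heterozygosity (He = 2p(1-p) * 2n/(2n-1)), nucleotide
#' diversity per site (pi, the mean pairwise allele-difference fraction, which
#' for biallelic SNPs equals the unbiased He computed from allele counts), the
#' method-of-moments inbreeding coefficient F per sample
#' ((observed hom - expected hom) / (n_loci - expected hom), as in the
#' standard per-individual heterozygosity test), and Tajima's D. 95%
#' confidence intervals come from a nonparametric bootstrap over loci.
#'
#' @param gt a `genotype_table`.
#' @param by_cluster if `TRUE` (default when a `cluster` column is present),
#'   summaries are computed per cluster; clusters of size 1 are an error.
#' @param n_boot bootstrap draws over loci for the confidence intervals.
#' @param seed integer seed for the bootstrap.
#' @return A data frame, one row per cluster, with columns `cluster`, `n`,
#'   and `<metric>`, `<metric>_lo`, `<metric>_hi` for ho, he, f, pi and
#'   tajima_d.
#' @export
diversity_metrics <- function(gt, by_cluster = !is.null(gt$samples$cluster),
                              n_boot = 1000, seed = 1L) {
  stopifnot(inherits(gt, "genotype_table"))
  groups <- if (by_cluster) {
    if (is.null(gt$samples$cluster)) stop("no cluster assignments; run assign_clusters()")
    split(seq_len(nrow(gt$dosages)), gt$samples$cluster)
  } else list(all = seq_len(nrow(gt$dosages)))
  out <- lapply(names(groups), function(cl) {
    idx <- groups[[cl]]
    if (length(idx) < 2)
      stop("cluster '", cl, "' has fewer than 2 samples")
    sub <- gt_subset(gt, samples = idx)
    one_cluster_diversity(sub, cl, n_boot, seed)
  })
  do.call(rbind, out)
}

one_cluster_diversity <- function(gt, cluster_label, n_boot, seed) {
  d <- gt$dosages
  m <- ncol(d)
  het <- d == 1
  ho_loc <- colMeans(het, na.rm = TRUE)
  n_nm <- colSums(!is.na(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  nh <- 2 * n_nm
  he_loc <- ifelse(nh > 1, 2 * p * (1 - p) * nh / (nh - 1), 0)
  pi_loc <- he_loc  # per-site mean pairwise difference fraction, biallelic

  # per-sample F: expected homozygote count from per-locus frequencies
  e_hom <- 1 - he_loc
  f_sample <- vapply(seq_len(nrow(d)), function(i) {
    ok <- !is.na(d[i, ])
    o <- sum(d[i, ok] != 1)
    e <- sum(e_hom[ok])
    n <- sum(ok)
    if (n - e == 0) return(NA_real_)
    (o - e) / (n - e)
  }, numeric(1))

  td <- tajimas_d(gt)

  est <- c(ho = mean(ho_loc, na.rm = TRUE), he = mean(he_loc, na.rm = TRUE),
           pi = mean(pi_loc, na.rm = TRUE))
  # site counts rescaled to the full haplotype count, for bootstrap D
  n_hap <- 2L * nrow(d)
  n_nm2 <- 2 * colSums(!is.na(d))
  site_cnt <- colSums(d, na.rm = TRUE)
  site_cnt <- ifelse(n_nm2 > 0, round(site_cnt * n_hap / n_nm2), 0)
  set.seed(seed)
  boot <- replicate(n_boot, {
    li <- sample.int(m, m, replace = TRUE)
    ok <- !is.na(d[, li, drop = FALSE])
    o <- rowSums(d[, li, drop = FALSE] != 1, na.rm = TRUE)
    e <- as.vector(ok %*% e_hom[li])
    nn <- rowSums(ok)
    c(ho = mean(ho_loc[li], na.rm = TRUE),
      he = mean(he_loc[li], na.rm = TRUE),
      pi = mean(pi_loc[li], na.rm = TRUE),
      f = mean(ifelse(nn - e == 0, NA_real_, (o - e) / (nn - e)), na.rm = TRUE),
      td = suppressWarnings(tajima_d_from_counts(site_cnt[li], n_hap)))
  })
  ci <- function(v) stats::quantile(v, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  ho_ci <- ci(boot["ho", ]); he_ci <- ci(boot["he", ]); pi_ci <- ci(boot["pi", ])
  td_ci <- ci(boot["td", ]); f_ci <- ci(boot["f", ])
  data.frame(cluster = cluster_label, n = nrow(d),
             ho = est["ho"], ho_lo = ho_ci[1], ho_hi = ho_ci[2],
             he = est["he"], he_lo = he_ci[1], he_hi = he_ci[2],
             f = mean(f_sample, na.rm = TRUE), f_lo = f_ci[1], f_hi = f_ci[2],
             pi = est["pi"], pi_lo = pi_ci[1], pi_hi = pi_ci[2],
             tajima_d = td, tajima_d_lo = td_ci[1], tajima_d_hi = td_ci[2],
             row.names = NULL, stringsAsFactors = FALSE)
}

tajima_constants <- function(n) {
  # Tajima (1989) a1,a2,b1,b2,c1,c2,e1,e2 for n sequences
  stopifnot(n >= 4)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Tajima's D from derived-allele counts
#'
#' Computes D = (pi_total - S/a1) / sqrt(e1 S + e2 S (S-1)) from the site
#' frequency spectrum: `counts` holds the derived (or alternate) allele count
#' of each segregating site among `n_hap` haplotypes.
#'
#' @param counts integer vector of per-site allele counts in 1..(n_hap-1);
#'   sites at 0 or n_hap (monomorphic) are dropped.
#' @param n_hap number of haplotypes.
#' @return Tajima's D, or `NA` (with a warning) when no site segregates.
#' @export
tajima_d_from_counts <- function(counts, n_hap) {
  counts <- counts[counts > 0 & counts < n_hap]
  s <- length(counts)
  if (s == 0L) {
    warning("no segregating sites; Tajima's D undefined")
    return(NA_real_)
  }
  k <- tajima_constants(n_hap)
  pi_tot <- sum(counts * (n_hap - counts)) / choose(n_hap, 2)
  (pi_tot - s / k$a1) / sqrt(k$e1 * s + k$e2 * s * (s - 1))
}

#' Tajima's D for a genotype table
#'
#' Unphased diploid genotypes are treated as 2n haplotypes via allele counts
#' (sufficient under the infinite-sites model). Constants use the full
#' haplotype count 2 * n_samples; per-site pairwise differences use the
#' non-missing allele counts scaled to the full count.
#'
#' @param gt a `genotype_table` with >= 2 samples.
#' @return Tajima's D.
#' @export
tajimas_d <- function(gt) {
  stopifnot(inherits(gt, "genotype_table"))
  n_hap <- 2L * nrow(gt$dosages)
  if (n_hap < 4) stop("Tajima's D needs at least 4 haplotypes (2 diploids)")
  d <- gt$dosages
  n_nm <- 2 * colSums(!is.na(d))
  cnt <- colSums(d, na.rm = TRUE)
  # rescale counts at partially-missing sites to the full haplotype count
  cnt <- ifelse(n_nm > 0, round(cnt * n_hap / n_nm), 0)
  tajima_d_from_counts(cnt, n_hap)
}
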