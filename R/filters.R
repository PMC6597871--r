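#' Locus filter specification
#'
#' Thresholds for the standard RAD-seq locus filter chain: site quality
#' (Phred), per-site mean read depth, minor-allele frequency, a Hardy-Weinberg
#' exact test, and a cap on per-locus missingness. Defaults mirror a typical
#' reduced-representation workflow: Phred 30-80, mean depth 20-50, HWE exact
#' p < 1e-4, and a 25% missing-data cap; the LD threshold (r^2 < 0.4) is
#' applied separately by [ld_prune()].
#'
#' @param phred_min,phred_max site quality bounds (Phred scale).
#' @param depth_min,depth_max per-site mean read depth bounds.
#' @param maf_min minor-allele-frequency threshold, or `NULL` to skip.
#' @param hwe_alpha Hardy-Weinberg exact-test p-value threshold; loci with
#'   p < `hwe_alpha` are removed. Use 0 to skip.
#' @param max_missing maximum tolerated fraction of missing genotypes per locus.
#' @param ld_r2_max squared dosage-correlation threshold used by [ld_prune()].
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(phred_min = 30, phred_max = 80,
                        depth_min = 20, depth_max = 50,
                        maf_min = NULL, hwe_alpha = 1e-4,
                        max_missing = 0.25, ld_r2_max = 0.4) {
  stopifnot(!is.na(phred_min), !is.na(phred_max),
            !is.na(depth_min), !is.na(depth_max),
            ld_r2_max >= 0, ld_r2_max <= 1,
            hwe_alpha >= 0, hwe_alpha < 1)
  structure(list(phred_min = phred_min, phred_max = phred_max,
                 depth_min = depth_min, depth_max = depth_max,
                 maf_min = maf_min, hwe_alpha = hwe_alpha,
                 max_missing = max_missing, ld_r2_max = ld_r2_max),
            class = "filter_spec")
}

#' Apply the locus filter chain to a genotype table
#'
#' Filters are applied in a fixed order — missingness, quality, depth, minor
#' allele frequency, Hardy-Weinberg — cheap scalar criteria first, each acting
#' on the survivors of the previous step. LD pruning and outlier removal are
#' separate steps ([ld_prune()], [fst_outlier_scan()]) because they depend on
#' the surviving locus set as a whole. The chain is idempotent.
#'
#' @param gt a `genotype_table`.
#' @param spec a [filter_spec()].
#' @return A list with elements `gt` (the filtered table) and `report` (a
#'   `filter_report`: per-step removal counts in application order, ids of
#'   retained loci).
#' @export
apply_locus_filters <- function(gt, spec = filter_spec()) {
  stopifnot(inherits(gt, "genotype_table"))
  n0 <- ncol(gt$dosages)
  steps <- character(0)
  removed <- integer(0)
  keep_tab <- gt

  drop_step <- function(tab, keep, name) {
    keep[is.na(keep)] <- FALSE
    steps <<- c(steps, name)
    removed <<- c(removed, sum(!keep))
    if (!any(keep))
      stop("all loci removed at step '", name,
           "'; relax the corresponding thresholds")
    gt_subset(tab, loci = which(keep))
  }

  miss <- colMeans(is.na(keep_tab$dosages))
  keep_tab <- drop_step(keep_tab, miss <= spec$max_missing, "missingness")

  q <- keep_tab$loci$phred_quality
  keep <- is.na(q) | (q >= spec$phred_min & q <= spec$phred_max)
  keep[is.na(keep)] <- TRUE
  keep_tab <- drop_step(keep_tab, keep, "quality")

  d <- keep_tab$loci$mean_depth
  keep <- is.na(d) | (d >= spec$depth_min & d <= spec$depth_max)
  keep[is.na(keep)] <- TRUE
  keep_tab <- drop_step(keep_tab, keep, "depth")

  if (!is.null(spec$maf_min)) {
    maf <- minor_allele_freq(keep_tab)
    keep_tab <- drop_step(keep_tab, maf >= spec$maf_min, "maf")
  }

  if (spec$hwe_alpha > 0) {
    p <- apply(keep_tab$dosages, 2, hwe_exact_test)
    keep_tab <- drop_step(keep_tab, p >= spec$hwe_alpha, "hwe")
  }

  report <- structure(list(steps = steps, removed = removed,
                           n_input = n0, n_retained = ncol(keep_tab$dosages),
                           retained = keep_tab$loci$id),
                      class = "filter_report")
  list(gt = keep_tab, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("locus filter report:", x$n_input, "loci in,", x$n_retained, "retained\n")
  for (i in seq_along(x$steps))
    cat(sprintf("  %-12s removed %d\n", x$steps[i], x$removed[i]))
  invisible(x)
}

#' Write a filter report as JSON
#' @param report a `filter_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Hardy-Weinberg conditional exact test for one biallelic locus
#'
#' Two-sided exact test on the heterozygote count conditional on the observed
#' allele counts: all heterozygote configurations compatible with the allele
#' counts are enumerated, and the p-value sums the probabilities of
#' configurations no more probable than the observed one (the standard SNP
#' exact test). Monomorphic loci return p = 1.
#'
#' @param dosages vector of genotypes coded 0/1/2 (`NA` ignored).
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(dosages) {
  g <- dosages[!is.na(dosages)]
  n <- length(g)
  if (n < 1L) return(1)
  n_het <- sum(g == 1)
  n_alt <- sum(g)              # alt allele count
  n_all <- 2L * n
  n_minor <- min(n_alt, n_all - n_alt)
  if (n_minor == 0L) return(1)  # monomorphic
  # possible heterozygote counts share the parity of the minor allele count
  h <- seq(n_minor %% 2L, n_minor, by = 2L)
  # log P(het = h | allele counts): n! 2^h / (n_AA! h! n_aa!) * nA! na! / (2n)!
  n_hom_min <- (n_minor - h) / 2
  n_hom_maj <- n - h - n_hom_min
  logp <- lfactorial(n) + h * log(2) - lfactorial(n_hom_min) -
    lfactorial(h) - lfactorial(n_hom_maj) +
    lfactorial(n_minor) + lfactorial(n_all - n_minor) - lfactorial(n_all)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- which(h == n_het)
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' Greedy LD pruning by squared dosage correlation
#'
#' Loci are visited in map order (chromosome, then position); a locus is kept
#' unless its squared Pearson correlation of dosages with an already-kept
#' locus exceeds `r2_max`. All kept-locus pairs are compared genome-wide
#' (reduced-representation loci carry no meaningful physical windows);
#' correlations use pairwise-complete observations. Deterministic.
#'
#' @param gt a `genotype_table` with at least 2 loci.
#' @param r2_max maximum tolerated squared correlation (pairs with r^2
#'   strictly greater are pruned).
#' @return The pruned `genotype_table`.
#' @export
ld_prune <- function(gt, r2_max = 0.4) {
  stopifnot(inherits(gt, "genotype_table"), ncol(gt$dosages) >= 2L)
  ord <- order(gt$loci$chrom, gt$loci$pos)
  d <- gt$dosages[, ord, drop = FALSE]
  m <- ncol(d)
  r2 <- suppressWarnings(stats::cor(d, use = "pairwise.complete.obs"))^2
  r2[is.na(r2)] <- 0
  kept <- logical(m)
  for (j in seq_len(m)) {
    kept[j] <- !any(r2[j, kept] > r2_max)
  }
  keep_ids <- colnames(d)[kept]
  gt_subset(gt, loci = match(keep_ids, gt$loci$id))
}
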