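#' Specification for neutral coalescent simulations
#'
#' Standard constant-size coalescent under the infinite-sites model. Mutations
#' are either dropped at rate theta/2 along branches, or a fixed number of
#' segregating sites `s_fixed` is placed multinomially by branch length
#' (conditioning on S, the default mode when `s_fixed` is given).
#'
#' @param n_haplotypes number of sampled haplotypes (>= 4).
#' @param theta population mutation rate (ignored when `s_fixed` is set).
#' @param s_fixed fixed number of segregating sites, or `NULL`.
#' @param replicates number of independent genealogies.
#' @param seed integer seed.
#' @return A `neutral_sim_spec` list.
#' @export
neutral_sim_spec <- function(n_haplotypes, theta = NULL, s_fixed = NULL,
                             replicates = 1000L, seed = 1L) {
  stopifnot(n_haplotypes >= 4, replicates >= 1)
  if (is.null(theta) && is.null(s_fixed))
    stop("one of theta or s_fixed must be given")
  structure(list(n_haplotypes = as.integer(n_haplotypes), theta = theta,
                 s_fixed = s_fixed, replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "neutral_sim_spec")
}

# one coalescent genealogy: returns per-lineage-interval branch lengths and
# the number of tips subtended by each (the sizes determine derived counts)
coalescent_tree_intervals <- function(n) {
  sizes <- rep(1L, n)          # tips subtended per active lineage
  len <- numeric(0)            # exposure time of each (lineage, interval)
  sub <- integer(0)            # subtended tips of each exposure
  tmrca <- 0
  k <- n
  while (k > 1L) {
    t_k <- stats::rexp(1, rate = k * (k - 1) / 2)
    tmrca <- tmrca + t_k
    len <- c(len, rep(t_k, k))
    sub <- c(sub, sizes)
    pick <- sample.int(k, 2L)
    sizes[pick[1]] <- sizes[pick[1]] + sizes[pick[2]]
    sizes <- sizes[-pick[2]]
    k <- k - 1L
  }
  list(len = len, sub = sub, tmrca = tmrca)
}

#' Simulate neutral coalescent samples
#'
#' Simulates `spec$replicates` independent constant-size coalescent
#' genealogies for `spec$n_haplotypes` samples and drops infinite-sites
#' mutations on the branches. Each replicate is summarised by its site
#' frequency spectrum (derived allele count per segregating site), which is
#' sufficient for Tajima's D and frequency filters; full haplotype matrices
#' can be reconstructed from it under infinite sites but are not stored.
#'
#' @param spec a [neutral_sim_spec()].
#' @return A list with one element per replicate: integer vector of derived
#'   allele counts (possibly length 0); attribute `tmrca` holds the per-
#'   replicate times to the most recent common ancestor (coalescent units).
#' @export
simulate_neutral_sample <- function(spec) {
  stopifnot(inherits(spec, "neutral_sim_spec"))
  set.seed(spec$seed)
  tmrca <- numeric(spec$replicates)
  out <- vector("list", spec$replicates)
  for (r in seq_len(spec$replicates)) {
    tr <- coalescent_tree_intervals(spec$n_haplotypes)
    tmrca[r] <- tr$tmrca
    total <- sum(tr$len)
    s <- if (!is.null(spec$s_fixed)) spec$s_fixed
         else stats::rpois(1, spec$theta / 2 * total)
    if (s > 0) {
      branch <- sample.int(length(tr$len), s, replace = TRUE, prob = tr$len)
      out[[r]] <- tr$sub[branch]
    } else out[[r]] <- integer(0)
  }
  attr(out, "tmrca") <- tmrca
  attr(out, "n_haplotypes") <- spec$n_haplotypes
  out
}

#' Neutral-model bias correction of Tajima's D under a MAF filter
#'
#' A minor-allele-frequency filter removes rare variants and biases Tajima's D
#' upward. The correction simulates neutral coalescent replicates matched to
#' the observed data (same haplotype count, conditioned on the observed S by
#' default), applies the same MAF filter, and subtracts the mean filtered D of
#' the replicates (the neutral expectation is zero, so the filtered null mean
#' is the bias).
#'
#' @param d_obs observed Tajima's D (computed after the MAF filter).
#' @param maf_min the minor-allele-frequency threshold that was applied.
#' @param spec a [neutral_sim_spec()] matched to the observed sample size and
#'   (via `s_fixed` or `theta`) to the observed number of segregating sites.
#' @return A list: `corrected` D, the estimated `bias`, its Monte Carlo
#'   standard error `bias_se`, `replicates` used, and the `seed`.
#' @export
debias_tajimas_d <- function(d_obs, maf_min, spec) {
  sims <- simulate_neutral_sample(spec)
  n <- attr(sims, "n_haplotypes")
  d_null <- vapply(sims, function(cnt) {
    maf <- pmin(cnt, n - cnt) / n
    cnt <- cnt[maf >= maf_min]
    if (length(cnt) == 0L) NA_real_
    else suppressWarnings(tajima_d_from_counts(cnt, n))
  }, numeric(1))
  if (all(is.na(d_null)))
    stop("MAF filter removed every site in all neutral replicates")
  bias <- mean(d_null, na.rm = TRUE)
  se <- stats::sd(d_null, na.rm = TRUE) / sqrt(sum(!is.na(d_null)))
  list(corrected = d_obs - bias, bias = bias, bias_se = se,
       replicates = spec$replicates, seed = spec$seed)
}

#' Effective population size from linkage disequilibrium
#'
#' Implements the bias-corrected LD method: the mean squared dosage
#' correlation across locus pairs (loci below the allele-frequency threshold
#' excluded) is corrected for the finite sample of individuals, and the drift
#' component is inverted to Ne. Constants follow the published LD-Ne method
#' for samples of S >= 30 individuals (r2_sample approx 1/S + 3.19/S^2;
#' random mating: Ne = (1/3 + sqrt(1/9 - 2.76 r2'))/(2 r2'); monogamy:
#' Ne = (2/3 + sqrt(4/9 - 7.2 r2'))/(2 r2')), with the small-sample (S < 30)
#' variants (1/S + 0.69/S^2, 0.308/0.618 and their monogamy analogues)
#' switched automatically. A non-positive corrected r2 is reported as
#' infinite Ne. Confidence intervals by delete-one-locus jackknife.
#'
#' @param gt a `genotype_table` with >= 8 samples.
#' @param allele_freq_min loci with minor-allele frequency below this are
#'   excluded (default 0.05).
#' @param mating `"monogamy"` (default) or `"random"`.
#' @return A list: `ne`, `ci` (95% jackknife), `r2_drift`, `n_pairs`,
#'   `n_loci`.
#' @export
ld_ne <- function(gt, allele_freq_min = 0.05, mating = c("monogamy", "random")) {
  mating <- match.arg(mating)
  stopifnot(inherits(gt, "genotype_table"))
  S <- nrow(gt$dosages)
  if (S < 8) stop("LD-Ne needs at least 8 samples")
  keep <- which(minor_allele_freq(gt) >= allele_freq_min)
  if (length(keep) < 2) stop("fewer than 2 loci pass the allele-frequency threshold")
  d <- gt$dosages[, keep, drop = FALSE]
  m <- ncol(d)
  r2 <- suppressWarnings(stats::cor(d, use = "pairwise.complete.obs"))^2
  ut <- upper.tri(r2)
  # sample-size expectation of r^2 under no drift LD (Waples 2006)
  e_r2 <- if (S >= 30) 1 / S + 3.19 / S^2 else 0.0018 + 0.907 / S + 4.44 / S^2
  invert <- function(r2d) {
    if (is.na(r2d) || r2d <= 0) return(Inf)
    if (mating == "random") {
      if (S >= 30) (1 / 3 + sqrt(max(0, 1 / 9 - 2.76 * r2d))) / (2 * r2d)
      else (0.308 + sqrt(max(0, 0.308^2 - 2.08 * r2d))) / (2 * r2d)
    } else {
      if (S >= 30) (2 / 3 + sqrt(max(0, 4 / 9 - 7.2 * r2d))) / (2 * r2d)
      else (0.618 + sqrt(max(0, 0.618^2 - 5.24 * r2d))) / (2 * r2d)
    }
  }
  r2_mean <- mean(r2[ut], na.rm = TRUE)
  r2_drift <- r2_mean - e_r2
  ne <- invert(r2_drift)
  # delete-one-locus jackknife (block jackknife over the pairs sharing a locus)
  loo <- vapply(seq_len(m), function(j) {
    sub <- r2[-j, -j, drop = FALSE]
    mean(sub[upper.tri(sub)], na.rm = TRUE)
  }, numeric(1))
  ne_loo <- vapply(loo - e_r2, invert, numeric(1))
  fin <- is.finite(ne_loo)
  if (sum(fin) >= 3 && is.finite(ne)) {
    # jackknife on 1/Ne (the estimable scale; Ne is a reciprocal of a mean)
    inv <- 1 / ne_loo[fin]
    nj <- length(inv)
    inv_bar <- mean(inv)
    se_inv <- sqrt((nj - 1) / nj * sum((inv - inv_bar)^2))
    lo_inv <- 1 / ne + stats::qnorm(0.975) * se_inv
    hi_inv <- 1 / ne - stats::qnorm(0.975) * se_inv
    ci <- c(if (lo_inv > 0) 1 / lo_inv else Inf,
            if (hi_inv > 0) 1 / hi_inv else Inf)
  } else ci <- c(NA_real_, Inf)
  list(ne = ne, ci = ci, r2_drift = r2_drift,
       n_pairs = sum(ut & !is.na(r2)), n_loci = m)
}
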