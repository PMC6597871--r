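#' Select environmental variables from principal components
#'
#' Runs a PCA on the scaled environmental matrix and, for each of the first
#' `n_axes` components, picks the variable most strongly correlated (in
#' absolute value) with the component scores. A variable already selected by
#' an earlier axis is skipped in favour of the next-best one (reported via a
#' message), so exactly `n_axes` distinct variables come back.
#'
#' @param env numeric matrix or data frame, observations x environmental
#'   variables (e.g. 19 bioclimatic variables plus altitude and forest cover).
#' @param n_axes number of leading components to represent (default 4).
#' @return A list: `selected` variable names (one per axis), `variance`
#'   (proportion of variance per component) and `cumulative_variance` of the
#'   first `n_axes`.
#' @export
env_variable_select <- function(env, n_axes = 4) {
  env <- as.matrix(env)
  if (ncol(env) < n_axes) stop("fewer variables than axes")
  if (nrow(env) < n_axes + 1) stop("fewer observations than axes + 1")
  if (any(apply(env, 2, stats::sd) == 0)) stop("constant environmental column")
  pc <- stats::prcomp(env, center = TRUE, scale. = TRUE)
  varprop <- pc$sdev^2 / sum(pc$sdev^2)
  selected <- character(0)
  for (a in seq_len(n_axes)) {
    cors <- abs(stats::cor(env, pc$x[, a]))
    ord <- order(cors, decreasing = TRUE)
    pick <- colnames(env)[ord][!(colnames(env)[ord] %in% selected)][1]
    if (!colnames(env)[ord][1] %in% c(pick))
      message("axis ", a, ": top variable already selected; using '", pick, "'")
    selected <- c(selected, pick)
  }
  list(selected = selected, variance = varprop,
       cumulative_variance = sum(varprop[seq_len(n_axes)]))
}

#' Genomic inflation factor adjustment of p-values
#'
#' Converts p-values to one-degree chi-square quantiles, estimates the
#' inflation factor as the ratio of their median to the null median
#' (qchisq(0.5, 1) = 0.4549), and rescales: adjusted p = upper tail of
#' chi-square(1) at z^2 / lambda.
#'
#' @param pvals vector of p-values in (0, 1].
#' @return A list: `lambda` and `p_adj`.
#' @export
genomic_inflation_adjust <- function(pvals) {
  if (length(pvals) < 10) stop("need at least 10 p-values")
  if (any(pvals <= 0 | pvals > 1, na.rm = TRUE)) stop("p-values must be in (0, 1]")
  z2 <- stats::qchisq(pvals, df = 1, lower.tail = FALSE)
  lambda <- stats::median(z2, na.rm = TRUE) / stats::qchisq(0.5, 1)
  p_adj <- stats::pchisq(z2 / lambda, df = 1, lower.tail = FALSE)
  list(lambda = lambda, p_adj = p_adj)
}

#' Benjamini-Hochberg step-up false discovery control
#'
#' Standard step-up rule: sort the m p-values ascending and flag every test
#' up to the largest i with p_(i) <= i * q / m.
#'
#' @param pvals p-value vector.
#' @param q target false discovery rate in (0, 1).
#' @return Logical vector of flags aligned with `pvals` (`NA` p-values are
#'   never flagged).
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  stopifnot(q > 0, q < 1)
  ok <- !is.na(pvals)
  m <- sum(ok)
  flags <- logical(length(pvals))
  if (m == 0) return(flags)
  ord <- order(pvals[ok])
  ps <- pvals[ok][ord]
  below <- which(ps <= seq_len(m) * q / m)
  if (length(below) > 0) {
    k <- max(below)
    idx <- which(ok)[ord[seq_len(k)]]
    flags[idx] <- TRUE
  }
  flags
}

# per-locus association regression on a fixed design; returns stat + p
locus_regressions <- function(dosages, design) {
  Y <- dosages
  mu <- colMeans(Y, na.rm = TRUE)
  miss <- is.na(Y)
  if (any(miss)) Y[miss] <- rep(mu, each = nrow(Y))[miss]
  keep <- apply(Y, 2, stats::sd) > 0
  n <- nrow(design); p <- ncol(design)
  H <- solve(crossprod(design))
  B <- H %*% crossprod(design, Y)
  res <- Y - design %*% B
  s2 <- colSums(res^2) / (n - p)
  se <- sqrt(s2 * H[2, 2])
  tt <- B[2, ] / se
  pr <- 2 * stats::pt(-abs(tt), df = n - p)
  tt[!keep] <- NA; pr[!keep] <- NA
  list(stat = tt, p = pr, monomorphic = !keep)
}

#' Latent-factor environmental-association genome scan
#'
#' Regresses each locus's allele dosage on an environmental variable while
#' conditioning on `k` latent factors (the leading principal components of
#' the centered dosage matrix) that absorb background population structure —
#' a least-squares latent-factor approximation of the latent factor mixed
#' model workflow. The per-locus association statistics are converted to
#' p-values, recalibrated by the genomic inflation factor, and flagged by
#' Benjamini-Hochberg FDR at rate `q`.
#'
#' @param gt a `genotype_table`.
#' @param env_values numeric vector, one value per sample (non-constant).
#' @param k number of latent factors (0 <= k <= n_samples - 3).
#' @param q FDR rate (default 0.05).
#' @param lambda_adjust apply genomic-inflation calibration (default TRUE).
#' @return A `scan_result` data frame (`locus`, `stat`, `p_raw`, `p_adj`,
#'   `flagged`) with attributes `lambda`, `k`, `mode`.
#' @export
latent_factor_scan <- function(gt, env_values, k, q = 0.05,
                               lambda_adjust = TRUE) {
  stopifnot(inherits(gt, "genotype_table"), k >= 0)
  n <- nrow(gt$dosages)
  if (k >= n - 2) stop("k must be below n_samples - 2")
  if (stats::sd(env_values) == 0) stop("environmental variable is constant")
  Y <- gt$dosages
  mu <- colMeans(Y, na.rm = TRUE)
  miss <- is.na(Y)
  if (any(miss)) Y[miss] <- rep(mu, each = n)[miss]
  Yc <- sweep(Y, 2, colMeans(Y))
  factors <- if (k > 0) {
    sv <- svd(Yc, nu = k, nv = 0)
    sv$u[, seq_len(k), drop = FALSE] * rep(sv$d[seq_len(k)], each = n)
  } else NULL
  design <- cbind(1, as.numeric(scale(env_values)), factors)
  reg <- locus_regressions(gt$dosages, design)
  if (any(reg$monomorphic))
    warning(sum(reg$monomorphic), " monomorphic locus/loci excluded from the scan")
  p_raw <- reg$p
  if (lambda_adjust) {
    adj <- genomic_inflation_adjust(p_raw[!is.na(p_raw)])
    lambda <- adj$lambda
    p_adj <- p_raw
    p_adj[!is.na(p_raw)] <- adj$p_adj
  } else {
    lambda <- 1
    p_adj <- p_raw
  }
  out <- data.frame(locus = gt$loci$id, stat = reg$stat, p_raw = p_raw,
                    p_adj = p_adj, flagged = bh_fdr(p_adj, q),
                    stringsAsFactors = FALSE)
  structure(out, lambda = lambda, k = k, q = q, mode = "latent_factor",
            class = c("scan_result", "data.frame"))
}

# per-locus Weir & Cockerham variance-component Fst (biallelic)
wc_fst_per_locus <- function(dosages, cluster) {
  cl <- split(seq_len(nrow(dosages)), cluster)
  r <- length(cl)
  stats_one <- function(y) {
    ni <- vapply(cl, function(idx) sum(!is.na(y[idx])), 0)
    use <- ni > 0
    ni <- ni[use]
    pi_ <- vapply(cl[use], function(idx) mean(y[idx], na.rm = TRUE) / 2, 0)
    hi <- vapply(cl[use], function(idx) mean(y[idx] == 1, na.rm = TRUE), 0)
    ri <- length(ni)
    if (ri < 2) return(c(a = NA, bc = NA))
    nbar <- mean(ni)
    nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (ri - 1)
    pbar <- sum(ni * pi_) / sum(ni)
    s2 <- sum(ni * (pi_ - pbar)^2) / ((ri - 1) * nbar)
    hbar <- sum(ni * hi) / sum(ni)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (ri - 1) / ri * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (ri - 1) / ri * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    c_ <- hbar / 2
    c(a = a, bc = b + c_)
  }
  comp <- apply(dosages, 2, stats_one)
  fst <- comp["a", ] / (comp["a", ] + comp["bc", ])
  fst[!is.finite(fst)] <- NA
  fst
}

#' Fst-outlier genome scan across genetic clusters
#'
#' Per-locus Weir-Cockerham variance-component Fst is converted to a
#' Lewontin-Krakauer-style chi-square statistic, (k - 1) * Fst / mean(Fst),
#' with k - 1 degrees of freedom, recalibrated by the genomic inflation
#' factor, and flagged by Benjamini-Hochberg FDR. Flagged loci are the
#' putative selection outliers to remove before neutral analyses.
#'
#' @param gt a `genotype_table`.
#' @param clusters optional cluster vector (defaults to `gt$samples$cluster`).
#' @param q FDR rate.
#' @return A `scan_result` data frame as in [latent_factor_scan()], with mode
#'   `"fst_outlier"`.
#' @export
fst_outlier_scan <- function(gt, clusters = gt$samples$cluster, q = 0.05) {
  if (is.null(clusters)) stop("no cluster assignments")
  tab <- table(clusters)
  if (length(tab) < 2 || any(tab < 2))
    stop("need at least 2 clusters with at least 2 samples each")
  fst <- wc_fst_per_locus(gt$dosages, clusters)
  if (any(is.na(fst)))
    warning(sum(is.na(fst)), " monomorphic or unusable locus/loci excluded")
  k <- length(tab)
  fbar <- mean(pmax(fst, 0), na.rm = TRUE)
  stat <- (k - 1) * pmax(fst, 0) / fbar
  p_raw <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  p_raw[p_raw == 0] <- .Machine$double.xmin
  adj <- genomic_inflation_adjust(p_raw[!is.na(p_raw)])
  p_adj <- p_raw
  if (adj$lambda > 1) {
    p_adj[!is.na(p_raw)] <- adj$p_adj
  }
  # lambda < 1 reflects the right-skew of the ratio statistic, not test
  # deflation; genomic control only ever corrects inflation
  out <- data.frame(locus = gt$loci$id, stat = stat, p_raw = p_raw,
                    p_adj = p_adj, flagged = bh_fdr(p_adj, q),
                    stringsAsFactors = FALSE)
  structure(out, lambda = adj$lambda, k = k, q = q, mode = "fst_outlier",
            class = c("scan_result", "data.frame"))
}

#' Intersect candidate loci across scans
#'
#' Robustness filter over the latent-factor dimension: candidates are the
#' loci flagged in every scan (e.g. runs at k - 1, k and k + 1 factors).
#'
#' @param scans list of >= 2 `scan_result` objects over the same loci.
#' @return Character vector of locus ids flagged in all scans.
#' @export
intersect_candidates <- function(scans) {
  stopifnot(length(scans) >= 2)
  loci <- scans[[1]]$locus
  for (s in scans[-1])
    if (!identical(s$locus, loci)) stop("scans cover different locus sets")
  sets <- lapply(scans, function(s) s$locus[s$flagged])
  Reduce(intersect, sets)
}
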