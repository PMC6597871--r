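#' Yang genomic relatedness matrix
#'
#' The allele-frequency-standardized genomic relationship estimator used in
#' GCTA-style analyses. For individuals j != k,
#' A_jk = (1/m_jk) * sum_i (g_ij - 2 p_i)(g_ik - 2 p_i) / (2 p_i (1 - p_i)),
#' and on the diagonal
#' A_jj = 1 + (1/m_j) * sum_i (g_ij^2 - (1 + 2 p_i) g_ij + 2 p_i^2) / (2 p_i (1 - p_i)),
#' where g is the allele dosage, p_i the sample allele frequency, and m the
#' number of loci usable for that entry (missing genotypes are excluded
#' pairwise; monomorphic loci are excluded throughout). Unrelated pairs score
#' near 0, parent-offspring near 0.5.
#'
#' @param gt a `genotype_table` with >= 2 samples and >= 1 polymorphic locus.
#' @return A `relatedness_matrix`: symmetric numeric matrix with sample-id
#'   dimnames and attribute `loci_used` (matrix of per-pair usable locus
#'   counts).
#' @export
yang_relatedness <- function(gt) {
  stopifnot(inherits(gt, "genotype_table"), nrow(gt$dosages) >= 2)
  p <- allele_freq(gt)
  poly <- which(p > 0 & p < 1 & !is.na(p))
  if (length(poly) == 0L) stop("no polymorphic loci")
  g <- gt$dosages[, poly, drop = FALSE]
  p <- p[poly]
  n <- nrow(g)
  w <- 2 * p * (1 - p)
  obs <- !is.na(g)
  gz <- g
  gz[!obs] <- 0

  # off-diagonal: cross-products of standardized dosages, pairwise-complete
  z <- sweep(gz, 2, 2 * p) * obs          # (g - 2p) with missing zeroed
  zs <- sweep(z, 2, sqrt(w), "/")
  num <- tcrossprod(zs)                    # sum over usable loci of products
  m_pair <- tcrossprod(obs * 1)            # usable locus counts per pair
  if (any(m_pair[upper.tri(m_pair)] < 1)) {
    bad <- which(m_pair < 1 & upper.tri(m_pair), arr.ind = TRUE)[1, ]
    stop("pair (", gt$samples$id[bad[1]], ", ", gt$samples$id[bad[2]],
         ") has no usable loci")
  }
  A <- num / m_pair

  # diagonal uses its own estimator
  num_d <- (gz^2 - sweep(gz, 2, 1 + 2 * p, "*") + rep(2 * p^2, each = n) * obs)
  num_d <- sweep(num_d, 2, w, "/") * obs
  diag(A) <- 1 + rowSums(num_d) / rowSums(obs)

  dimnames(A) <- list(gt$samples$id, gt$samples$id)
  structure(A, loci_used = m_pair, class = c("relatedness_matrix", "matrix"))
}

#' @export
print.relatedness_matrix <- function(x, ...) {
  n <- nrow(x)
  off <- x[upper.tri(x)]
  cat(sprintf("relatedness_matrix: %d individuals; off-diagonal mean %.4f (range %.3f..%.3f)\n",
              n, mean(off), min(off), max(off)))
  invisible(x)
}

#' Great-circle distance matrix between samples
#'
#' Haversine distances (Earth radius 6371 km) between sample coordinates in
#' WGS84 decimal degrees. Samples at the same location are 0 km apart.
#'
#' @param samples data frame with `lon` and `lat` columns in degrees, or a
#'   `genotype_table`.
#' @return Symmetric matrix of distances in km.
#' @export
geographic_distance_matrix <- function(samples) {
  if (inherits(samples, "genotype_table")) samples <- samples$samples
  lon <- samples$lon; lat <- samples$lat
  if (any(abs(lat) > 90)) stop("latitude outside [-90, 90]")
  if (any(abs(lon) > 180)) stop("longitude outside [-180, 180]")
  n <- length(lon)
  la <- lat * pi / 180; lo <- lon * pi / 180
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    dlat <- la - la[i]
    dlon <- lo - lo[i]
    h <- sin(dlat / 2)^2 + cos(la[i]) * cos(la) * sin(dlon / 2)^2
    d[i, ] <- 2 * 6371 * asin(pmin(1, sqrt(h)))
  }
  d <- (d + t(d)) / 2
  diag(d) <- 0
  if (!is.null(samples$id)) dimnames(d) <- list(samples$id, samples$id)
  d
}

#' LOESS spatial autocorrelogram of pairwise relatedness
#'
#' Fits a local-linear LOESS curve of pairwise relatedness against pairwise
#' geographic distance, and builds a pointwise 95% null envelope by randomly
#' permuting sample locations (coordinates are relabelled across individuals,
#' distances recomputed, and the curve refitted) `n_perm` times. The
#' location permutation preserves the clustered sampling geometry, which a
#' naive permutation of relatedness values would destroy.
#'
#' @param rel a `relatedness_matrix` (or symmetric numeric matrix).
#' @param dist matrix of pairwise distances (km), conformable with `rel`.
#' @param span LOESS span (local-linear, tricube weights).
#' @param n_perm number of location permutations (>= 99).
#' @param n_grid evaluation grid size (equally spaced, 0 to max distance).
#' @param seed integer seed.
#' @return An `autocorrelogram`: data frame with columns `distance`, `fit`,
#'   `lo`, `hi`, plus attributes `span`, `n_perm`.
#' @export
spatial_autocorrelogram <- function(rel, dist, span = 0.5, n_perm = 199L,
                                    n_grid = 100L, seed = 1L) {
  stopifnot(all(dim(rel) == dim(dist)), n_perm >= 99)
  n <- nrow(rel)
  ut <- upper.tri(rel)
  if (max(dist) - min(dist[ut]) <= 0) stop("all pairwise distances identical")
  grid <- seq(0, max(dist), length.out = n_grid)
  fit_curve <- function(dvec) {
    df <- data.frame(y = rel[ut], x = dvec)
    fit <- stats::loess(y ~ x, data = df, span = span, degree = 1,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    stats::predict(fit, newdata = data.frame(x = grid))
  }
  obs <- fit_curve(dist[ut])
  set.seed(seed)
  perms <- matrix(NA_real_, n_perm, length(grid))
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    dp <- dist[idx, idx]
    perms[b, ] <- fit_curve(dp[ut])
  }
  # exact Monte-Carlo envelope: k-th order statistics rather than
  # interpolated quantiles, so the pointwise level is 2k/(n_perm + 1)
  k <- max(1L, floor(0.025 * (n_perm + 1)))
  srt <- apply(perms, 2, sort)
  out <- data.frame(distance = grid, fit = obs, lo = srt[k, ],
                    hi = srt[n_perm + 1L - k, ])
  structure(out, span = span, n_perm = n_perm, seed = seed,
            class = c("autocorrelogram", "data.frame"))
}

#' Plot an autocorrelogram with its null envelope
#' @param x an `autocorrelogram`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.autocorrelogram <- function(x, ...) {
  graphics::plot(x$distance, x$fit, type = "n",
                 ylim = range(c(x$fit, x$lo, x$hi), na.rm = TRUE),
                 xlab = "distance (km)", ylab = "relatedness", ...)
  graphics::polygon(c(x$distance, rev(x$distance)), c(x$lo, rev(x$hi)),
                    col = "grey85", border = NA)
  graphics::abline(h = 0, lty = 3)
  graphics::lines(x$distance, x$fit, lwd = 2)
  invisible(x)
}
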