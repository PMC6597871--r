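#' Spatial correlation kernels
#'
#' Conventional geostatistical correlation functions of distance, all equal
#' to 1 at d = 0:
#' `none` (0 for d > 0), `linear` (1 - d/range inside the range, else 0),
#' `exponential` (exp(-d/range)), `gaussian` (exp(-(d/range)^2)),
#' `spherical` (1 - 1.5 (d/range) + 0.5 (d/range)^3 inside the range, else 0),
#' `rational_quadratic` (1 / (1 + (d/range)^2)).
#'
#' @param structure kernel name.
#' @param d non-negative distance (vector or matrix).
#' @param range range parameter (> 0; ignored for `none`).
#' @return Correlations with the same shape as `d`.
#' @export
correlation_kernel <- function(structure = c("none", "linear", "exponential",
                                             "gaussian", "spherical",
                                             "rational_quadratic"),
                               d, range = 1) {
  structure <- match.arg(structure)
  stopifnot(all(d >= 0), range > 0)
  r <- d / range
  out <- switch(structure,
    none = ifelse(d == 0, 1, 0),
    linear = ifelse(r < 1, 1 - r, 0),
    exponential = exp(-r),
    gaussian = exp(-r^2),
    spherical = ifelse(r < 1, 1 - 1.5 * r + 0.5 * r^3, 0),
    rational_quadratic = 1 / (1 + r^2))
  out[d == 0] <- 1
  out
}

#' Location-level table of habitat amount and mean genetic diversity
#'
#' Aggregates a genotype table to one row per sampling location: mean habitat
#' fraction within a buffer (when a land-cover raster is supplied), and the
#' across-colony means of per-individual observed heterozygosity, expected
#' heterozygosity (from table-wide allele frequencies over the individual's
#' non-missing loci) and inbreeding F.
#'
#' @param gt a `genotype_table`.
#' @param landcover optional `raster_grid` for [habitat_fraction()].
#' @param radius_km buffer radius (default 2 km).
#' @param habitat_values raster values counted as habitat.
#' @return A `location_table` data frame: `location_id`, `lon`, `lat`, `n`,
#'   `habitat` (or NA), `ho`, `he`, `f`.
#' @export
location_table <- function(gt, landcover = NULL, radius_km = 2,
                           habitat_values = 1) {
  d <- gt$dosages
  p <- allele_freq(gt)
  nh <- 2 * colSums(!is.na(d))
  he_loc <- ifelse(nh > 1, 2 * p * (1 - p) * nh / (nh - 1), 0)
  e_hom <- 1 - he_loc
  per_sample <- t(vapply(seq_len(nrow(d)), function(i) {
    ok <- !is.na(d[i, ])
    o_hom <- sum(d[i, ok] != 1)
    e <- sum(e_hom[ok]); n <- sum(ok)
    c(ho = mean(d[i, ok] == 1),
      he = mean(he_loc[ok]),
      f = if (n - e == 0) NA_real_ else (o_hom - e) / (n - e))
  }, numeric(3)))
  agg <- split(seq_len(nrow(d)), gt$samples$location_id)
  out <- do.call(rbind, lapply(names(agg), function(L) {
    idx <- agg[[L]]
    lon <- gt$samples$lon[idx[1]]; lat <- gt$samples$lat[idx[1]]
    hab <- if (is.null(landcover)) NA_real_ else
      habitat_fraction(landcover, lon, lat, radius_km, habitat_values)
    data.frame(location_id = L, lon = lon, lat = lat, n = length(idx),
               habitat = hab,
               ho = mean(per_sample[idx, "ho"], na.rm = TRUE),
               he = mean(per_sample[idx, "he"], na.rm = TRUE),
               f = mean(per_sample[idx, "f"], na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("location_table", "data.frame")
  out
}

logit_eps <- function(x, eps) {
  if (any(x <= 0 | x >= 1)) {
    warning("logit of values at 0/1: epsilon-adjusted by ", eps)
    x <- pmin(pmax(x, eps), 1 - eps)
  }
  log(x / (1 - x))
}

#' Generalized least squares with a spatial correlation structure
#'
#' Fits `y = b0 + b1 * predictor + e` with `cov(e_a, e_b) = sigma^2 *
#' kernel(d_ab; range)` over location distances (great-circle km). The
#' coefficients and sigma^2 are profiled analytically; the range is estimated
#' by (restricted) maximum likelihood with a one-dimensional bounded search.
#' Heterozygosity-type responses can be logit-transformed first.
#'
#' @param table a [location_table()] (or any data frame with `lon`, `lat`).
#' @param response,predictor column names.
#' @param structure a [correlation_kernel()] name.
#' @param transform `"identity"` or `"logit"`.
#' @param method `"REML"` (default) or `"ML"`.
#' @param nugget optional nugget proportion in \[0, 1); 0 disables (default).
#' @param logit_epsilon epsilon used when logit-transforming exact 0/1.
#' @return A `spatial_gls` object: `coefficients`, `se`, `sigma2`, `range`,
#'   `structure`, `loglik`, `aic`, `aicc`, `n`, `method`.
#' @export
fit_gls <- function(table, response, predictor, structure = "exponential",
                    transform = c("identity", "logit"), method = c("REML", "ML"),
                    nugget = 0, logit_epsilon = 1e-3) {
  transform <- match.arg(transform); method <- match.arg(method)
  y <- table[[response]]
  if (transform == "logit") y <- logit_eps(y, logit_epsilon)
  if (any(!is.finite(y))) stop("response not finite after transform")
  X <- cbind(`(Intercept)` = 1, table[[predictor]])
  colnames(X)[2] <- predictor
  n <- length(y); p <- ncol(X)
  if (n < 5) stop("need at least 5 locations")
  D <- geographic_distance_matrix(table)

  profile_fit <- function(range) {
    C <- correlation_kernel(structure, D, max(range, 1e-9))
    if (nugget > 0) C <- (1 - nugget) * C + nugget * diag(n)
    diag(C) <- 1
    cC <- tryCatch(chol(C + 1e-10 * diag(n)), error = function(e) NULL)
    if (is.null(cC)) return(list(obj = 1e10))
    Wx <- forwardsolve(t(cC), X); Wy <- forwardsolve(t(cC), y)
    XtX <- crossprod(Wx); Xty <- crossprod(Wx, Wy)
    beta <- solve(XtX, Xty)
    r <- Wy - Wx %*% beta
    rss <- sum(r^2)
    logdet <- 2 * sum(log(diag(cC)))
    if (method == "ML") {
      s2 <- rss / n
      ll <- -0.5 * (n * log(2 * pi * s2) + logdet + n)
    } else {
      s2 <- rss / (n - p)
      ll <- -0.5 * ((n - p) * log(2 * pi * s2) + logdet +
                    determinant(XtX, logarithm = TRUE)$modulus - p * log(s2) +
                    (n - p))
    }
    list(obj = -ll, loglik = as.numeric(ll), beta = as.numeric(beta), sigma2 = s2,
         vcov = s2 * solve(XtX))
  }

  if (structure == "none") {
    best_range <- NA_real_
    fit <- profile_fit(1)
    k_range <- 0L
  } else {
    dmax <- max(D)
    opt <- stats::optimize(function(lr) profile_fit(exp(lr))$obj,
                           interval = log(c(dmax / 500, dmax * 10)))
    best_range <- exp(opt$minimum)
    fit <- profile_fit(best_range)
    k_range <- 1L
  }
  k <- p + 1L + k_range
  aic <- -2 * fit$loglik + 2 * k
  aicc <- aic + 2 * k * (k + 1) / max(n - k - 1, 1e-9)
  beta <- fit$beta; names(beta) <- colnames(X)
  se <- sqrt(diag(fit$vcov)); names(se) <- colnames(X)
  structure(list(coefficients = beta, se = se, sigma2 = fit$sigma2,
                 range = best_range, structure = structure, loglik = fit$loglik,
                 aic = aic, aicc = aicc, n = n, k = k, method = method,
                 response = response, predictor = predictor,
                 transform = transform, nugget = nugget),
            class = "spatial_gls")
}

#' @export
print.spatial_gls <- function(x, ...) {
  cat(sprintf("spatial GLS (%s, %s correlation), n = %d\n",
              x$method, x$structure, x$n))
  print(round(rbind(estimate = x$coefficients, se = x$se), 5))
  cat(sprintf("  sigma2 = %.4g  range = %s  logLik = %.3f  AICc = %.3f\n",
              x$sigma2, if (is.na(x$range)) "-" else sprintf("%.1f km", x$range),
              x$loglik, x$aicc))
  invisible(x)
}

#' @export
coef.spatial_gls <- function(object, ...) object$coefficients

#' @export
logLik.spatial_gls <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' Compare spatial correlation structures and test the predictor
#'
#' Fits the model under each candidate correlation structure by REML, ranks
#' them by AICc, refits the best structure by maximum likelihood and compares
#' it against the intercept-only ML model with the same structure by a
#' likelihood ratio test.
#'
#' @param table a [location_table()].
#' @param response,predictor column names.
#' @param structures character vector of [correlation_kernel()] names.
#' @param transform `"identity"` or `"logit"`.
#' @param method ranking method (default REML).
#' @param ... passed to [fit_gls()].
#' @return A list: `ranking` (data frame of structure, loglik, aicc,
#'   delta_aicc), `best` (ML refit), `lrt` (list chi2, df, p), `fits`.
#' @export
compare_gls_structures <- function(table, response, predictor,
                                   structures = c("none", "linear", "exponential",
                                                  "gaussian", "spherical",
                                                  "rational_quadratic"),
                                   transform = "identity", method = "REML", ...) {
  stopifnot(length(structures) >= 2)
  fits <- lapply(structures, function(s)
    fit_gls(table, response, predictor, s, transform, method, ...))
  aicc <- vapply(fits, `[[`, 0, "aicc")
  ord <- order(aicc)
  ranking <- data.frame(structure = structures[ord],
                        loglik = vapply(fits, `[[`, 0, "loglik")[ord],
                        aicc = aicc[ord], delta_aicc = aicc[ord] - min(aicc))
  best_s <- structures[ord[1]]
  best_ml <- fit_gls(table, response, predictor, best_s, transform, "ML", ...)
  null_ml <- fit_gls_null(table, response, best_s, transform, ...)
  chi2 <- max(0, 2 * (best_ml$loglik - null_ml$loglik))
  lrt <- list(chi2 = chi2, df = 1, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
  list(ranking = ranking, best = best_ml, null = null_ml, lrt = lrt,
       fits = stats::setNames(fits, structures))
}

# intercept-only ML spatial GLS (internal; same profiling as fit_gls)
fit_gls_null <- function(table, response, structure, transform = "identity",
                         nugget = 0, logit_epsilon = 1e-3) {
  y <- table[[response]]
  if (transform == "logit") y <- logit_eps(y, logit_epsilon)
  n <- length(y)
  D <- geographic_distance_matrix(table)
  prof <- function(range) {
    C <- correlation_kernel(structure, D, max(range, 1e-9))
    if (nugget > 0) C <- (1 - nugget) * C + nugget * diag(n)
    diag(C) <- 1
    cC <- tryCatch(chol(C + 1e-10 * diag(n)), error = function(e) NULL)
    if (is.null(cC)) return(list(obj = 1e10))
    Wx <- forwardsolve(t(cC), rep(1, n)); Wy <- forwardsolve(t(cC), y)
    beta <- sum(Wx * Wy) / sum(Wx^2)
    rss <- sum((Wy - Wx * beta)^2)
    s2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * s2) + 2 * sum(log(diag(cC))) + n)
    list(obj = -ll, loglik = ll, beta = beta, sigma2 = s2)
  }
  if (structure == "none") {
    fit <- prof(1); rng <- NA_real_; k <- 2L
  } else {
    dmax <- max(D)
    opt <- stats::optimize(function(lr) prof(exp(lr))$obj,
                           interval = log(c(dmax / 500, dmax * 10)))
    rng <- exp(opt$minimum); fit <- prof(rng); k <- 3L
  }
  aic <- -2 * fit$loglik + 2 * k
  structure(list(coefficients = c(`(Intercept)` = fit$beta), se = NA,
                 sigma2 = fit$sigma2, range = rng, structure = structure,
                 loglik = fit$loglik, aic = aic,
                 aicc = aic + 2 * k * (k + 1) / max(n - k - 1, 1e-9),
                 n = n, k = k, method = "ML", response = response,
                 predictor = NULL, transform = transform, nugget = nugget),
            class = "spatial_gls")
}
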