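#' All-subsets AIC model selection over noncollinear predictor sets
#'
#' Enumerates every subset of the predictors in which all included pairs have
#' absolute Pearson correlation below `collinearity_rmax` (including the
#' intercept-only model), fits each by maximum likelihood, and ranks by AIC
#' with Akaike weights. Deterministic: subsets are generated in a fixed
#' order and ties keep that order.
#'
#' @param pairs a `pair_table`.
#' @param predictors character vector of predictor column names (defaults to
#'   the table's recorded predictors).
#' @param collinearity_rmax exclusion threshold on |r| between predictors
#'   (default 0.6: pairs at or above never co-occur).
#' @param nested fit NMLPE (default) or plain MLPE.
#' @param response response column name.
#' @return A `selection_table`: data frame with one row per candidate model
#'   (`model`, `k_predictors`, `loglik`, `aic`, `delta_aic`, `weight`, `rho`),
#'   sorted by AIC, with the fitted models in attribute `fits`.
#' @export
all_subsets_selection <- function(pairs, predictors = attr(pairs, "predictors"),
                                  collinearity_rmax = 0.6, nested = TRUE,
                                  response = "relatedness") {
  stopifnot(length(predictors) >= 1)
  cm <- abs(stats::cor(as.matrix(pairs[predictors])))
  subsets <- list(character(0))
  for (k in seq_along(predictors)) {
    cmb <- utils::combn(predictors, k, simplify = FALSE)
    ok <- vapply(cmb, function(s) {
      if (length(s) < 2) return(TRUE)
      sub <- cm[s, s]
      all(sub[upper.tri(sub)] < collinearity_rmax)
    }, logical(1))
    subsets <- c(subsets, cmb[ok])
  }
  fits <- lapply(subsets, function(s) {
    f <- stats::reformulate(if (length(s)) s else "1", response = response)
    suppressWarnings(mlpe(f, pairs, nested = nested, method = "ML"))
  })
  tab <- data.frame(
    model = vapply(subsets, function(s)
      if (length(s)) paste(s, collapse = " + ") else "(intercept)", ""),
    k_predictors = lengths(subsets),
    loglik = vapply(fits, `[[`, 0, "loglik"),
    aic = vapply(fits, `[[`, 0, "aic"),
    rho = vapply(fits, `[[`, 0, "rho"),
    stringsAsFactors = FALSE)
  ord <- order(tab$aic)
  tab <- tab[ord, , drop = FALSE]
  fits <- fits[ord]
  tab$delta_aic <- tab$aic - tab$aic[1]
  w <- exp(-0.5 * tab$delta_aic)
  tab$weight <- w / sum(w)
  rownames(tab) <- NULL
  structure(tab[, c("model", "k_predictors", "loglik", "aic", "delta_aic",
                    "weight", "rho")],
            fits = fits, class = c("selection_table", "data.frame"))
}

#' Likelihood ratio test between nested MLPE fits
#'
#' @param full,reduced `mlpe` fits by maximum likelihood, `reduced` nested in
#'   `full` (REML fits are rejected: fixed-effect LRTs require ML).
#' @return A list: `chi2`, `df` (parameter difference), `p` (chi-square upper
#'   tail).
#' @export
likelihood_ratio_test <- function(full, reduced) {
  stopifnot(inherits(full, "mlpe"), inherits(reduced, "mlpe"))
  if (full$method != "ML" || reduced$method != "ML")
    stop("LRT on fixed effects requires ML fits, not REML")
  chi2 <- max(0, 2 * (full$loglik - reduced$loglik))
  df <- full$n_params - reduced$n_params
  if (df < 0) stop("'reduced' has more parameters than 'full'")
  p <- if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p)
}

#' @export
anova.mlpe <- function(object, ..., test = TRUE) {
  others <- list(...)
  if (length(others) != 1L || !inherits(others[[1]], "mlpe"))
    stop("anova.mlpe compares exactly two mlpe fits")
  a <- object; b <- others[[1]]
  if (a$n_params < b$n_params) { tmp <- a; a <- b; b <- tmp }
  lrt <- likelihood_ratio_test(a, b)
  data.frame(model = c(deparse(b$formula), deparse(a$formula)),
             df = c(b$n_params, a$n_params),
             logLik = c(b$loglik, a$loglik),
             AIC = c(b$aic, a$aic),
             chi2 = c(NA, lrt$chi2), p = c(NA, lrt$p))
}

#' Lag-1 serial autocorrelation of normalized residuals
#'
#' The model-misspecification diagnostic for clustered pairwise data: the
#' fit's residuals are whitened by the Cholesky factor of the fitted marginal
#' correlation after sorting rows by the unordered location-pair key, and the
#' lag-1 Pearson autocorrelation of the whitened series is returned. Values
#' materially above 0 indicate location-level dependence the correlation
#' structure did not absorb (the symptom that motivates the nested model).
#'
#' @param fit a converged `mlpe` fit.
#' @param pairs optional `pair_table` (defaults to the fit's data).
#' @return Lag-1 autocorrelation (numeric scalar).
#' @export
residual_serial_autocorrelation <- function(fit, pairs = fit$data) {
  stopifnot(inherits(fit, "mlpe"))
  n <- nrow(pairs)
  if (n < 3) stop("need at least 3 residuals")
  ord <- order(pairs$locpair, pairs$id1, pairs$id2)
  W <- mlpe_marginal_w(fit, order_idx = ord)
  L <- t(chol(W))
  r <- as.numeric(solve(L, fit$residuals_raw[ord])) / sqrt(fit$sigma2_e)
  stats::cor(r[-1], r[-length(r)])
}

#' Sensitivity of model selection to sample exclusion
#'
#' Repeats the all-subsets selection on random data subsets: for each
#' exclusion size, `n_subsets` random draws of individuals are removed (with
#' all their pairs), the selection is rerun, and each predictor's inclusion
#' in the near-best models (delta AIC <= `delta_max`) is recorded. Seeded and
#' reproducible.
#'
#' @param pairs a `pair_table`.
#' @param predictors predictor column names.
#' @param n_subsets subsets per exclusion size (default 100).
#' @param exclusion_sizes integer vector of how many individuals to drop.
#' @param seed integer seed.
#' @param nested fit NMLPE (default) or MLPE.
#' @param collinearity_rmax passed to [all_subsets_selection()].
#' @param delta_max delta-AIC cutoff defining the best-model set.
#' @return Data frame: `exclusion_size`, `predictor`, `frequency` (fraction
#'   of subsets whose best-model set included the predictor).
#' @export
subset_sensitivity <- function(pairs, predictors = attr(pairs, "predictors"),
                               n_subsets = 100L, exclusion_sizes = c(0L, 2L, 4L),
                               seed = 1L, nested = TRUE,
                               collinearity_rmax = 0.6, delta_max = 2) {
  ids <- unique(c(pairs$id1, pairs$id2))
  if (any(exclusion_sizes >= length(ids) - 3))
    stop("exclusion sizes must leave at least 4 individuals")
  set.seed(seed)
  rows <- list()
  for (ex in exclusion_sizes) {
    inc <- matrix(0, n_subsets, length(predictors),
                  dimnames = list(NULL, predictors))
    for (b in seq_len(n_subsets)) {
      drop_ids <- if (ex > 0) sample(ids, ex) else character(0)
      keep <- !(pairs$id1 %in% drop_ids | pairs$id2 %in% drop_ids)
      sub <- pairs[keep, , drop = FALSE]
      attr(sub, "predictors") <- predictors
      sel <- all_subsets_selection(sub, predictors, collinearity_rmax, nested)
      best <- sel$model[sel$delta_aic <= delta_max]
      terms <- unique(unlist(strsplit(best[best != "(intercept)"], " \\+ ")))
      inc[b, predictors %in% terms] <- 1
    }
    rows[[as.character(ex)]] <- data.frame(exclusion_size = ex,
                                           predictor = predictors,
                                           frequency = colMeans(inc),
                                           row.names = NULL)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
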