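#' Assemble a pairwise table for MLPE/NMLPE regression
#'
#' Flattens the upper triangle of a relatedness matrix and one or more
#' resistance-distance matrices into one row per unordered pair of
#' individuals, carrying the individual ids, location ids and the unordered
#' location-pair key used by the nested model. Each predictor is
#' z-standardized (mean and sd stored in the `scaling` attribute so effects
#' can be back-transformed); rows with non-finite predictor values (e.g.
#' disconnected pairs with infinite resistance) are dropped with a warning.
#'
#' @param rel symmetric relatedness matrix (response).
#' @param distances named list of symmetric predictor matrices, conformable
#'   with `rel` and aligned to the same samples.
#' @param samples data frame with `id` and `location_id` (a `genotype_table`
#'   is also accepted).
#' @param standardize z-standardize predictors (default `TRUE`).
#' @return A `pair_table`: data frame with columns `id1`, `id2`, `loc1`,
#'   `loc2`, `locpair`, `relatedness`, and one column per predictor.
#' @export
build_pair_table <- function(rel, distances, samples, standardize = TRUE) {
  if (inherits(samples, "genotype_table")) samples <- samples$samples
  n <- nrow(rel)
  stopifnot(n == nrow(samples))
  if (is.null(names(distances)) || any(names(distances) == ""))
    stop("distances must be a named list")
  for (nm in names(distances)) {
    if (!all(dim(distances[[nm]]) == n))
      stop("distance matrix '", nm, "' is not conformable with the relatedness matrix")
    dn <- rownames(distances[[nm]])
    if (!is.null(dn) && !is.null(rownames(rel)) && !identical(dn, rownames(rel)))
      stop("sample ids of distance matrix '", nm, "' are misaligned")
  }
  if (!is.null(rownames(rel)) && !identical(rownames(rel), samples$id))
    stop("sample ids of the relatedness matrix do not match the sample table")
  ut <- which(upper.tri(rel), arr.ind = TRUE)
  i <- ut[, 1]; j <- ut[, 2]
  loc1 <- as.character(samples$location_id[i])
  loc2 <- as.character(samples$location_id[j])
  key <- ifelse(loc1 <= loc2, paste(loc1, loc2, sep = "||"),
                paste(loc2, loc1, sep = "||"))
  out <- data.frame(id1 = samples$id[i], id2 = samples$id[j],
                    loc1 = loc1, loc2 = loc2, locpair = key,
                    relatedness = rel[ut], stringsAsFactors = FALSE)
  scaling <- list()
  for (nm in names(distances)) out[[nm]] <- distances[[nm]][ut]
  pred_cols <- names(distances)
  finite <- rowSums(!is.finite(as.matrix(out[pred_cols]))) == 0
  if (!all(finite)) {
    warning(sum(!finite), " pair(s) with non-finite predictor values dropped")
    out <- out[finite, , drop = FALSE]
  }
  if (standardize) {
    for (nm in pred_cols) {
      mu <- mean(out[[nm]]); sd_ <- stats::sd(out[[nm]])
      if (sd_ == 0) stop("predictor '", nm, "' is constant")
      out[[nm]] <- (out[[nm]] - mu) / sd_
      scaling[[nm]] <- c(mean = mu, sd = sd_)
    }
  }
  structure(out, predictors = pred_cols, scaling = scaling,
            class = c("pair_table", "data.frame"))
}

# sparse random-effect incidence matrices for a pair table
pair_design <- function(data) {
  ids <- sort(unique(c(data$id1, data$id2)))
  qu <- length(ids)
  n <- nrow(data)
  Zu <- Matrix::sparseMatrix(i = rep(seq_len(n), 2),
                             j = c(match(data$id1, ids), match(data$id2, ids)),
                             x = 1, dims = c(n, qu))
  lp <- sort(unique(data$locpair))
  Zv <- Matrix::sparseMatrix(i = seq_len(n), j = match(data$locpair, lp),
                             x = 1, dims = c(n, length(lp)))
  list(Zu = Zu, Zv = Zv, ids = ids, locpairs = lp)
}

# profiled (RE)ML deviance machinery; gammas are variance ratios sigma^2_x / sigma^2_e
mlpe_profile <- function(y, X, Z, blocks, method) {
  n <- length(y); p <- ncol(X)
  ZtZ <- as.matrix(Matrix::crossprod(Z))
  ZtX <- as.matrix(Matrix::crossprod(Z, X))
  Zty <- as.numeric(Matrix::crossprod(Z, y))
  XtX <- crossprod(X); Xty <- crossprod(X, y); yty <- sum(y^2)
  q <- ncol(Z)
  function(log_gamma) {
    g <- exp(log_gamma)[blocks]          # per-column ratio
    A <- ZtZ + diag(1 / g, q)
    cA <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(cA)) return(list(obj = 1e10))
    logdetW <- 2 * sum(log(diag(cA))) + sum(log(g))
    Ai_ZtX <- backsolve(cA, forwardsolve(t(cA), ZtX))
    Ai_Zty <- backsolve(cA, forwardsolve(t(cA), Zty))
    XtWX <- XtX - crossprod(ZtX, Ai_ZtX)
    XtWy <- Xty - crossprod(ZtX, Ai_Zty)
    yWy <- yty - sum(Zty * Ai_Zty)
    cX <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(cX)) return(list(obj = 1e10))
    beta <- backsolve(cX, forwardsolve(t(cX), XtWy))
    rss <- max(yWy - sum(beta * XtWy), 1e-300)
    if (method == "ML") {
      s2 <- rss / n
      ll <- -0.5 * (n * log(2 * pi * s2) + logdetW + n)
    } else {
      s2 <- rss / (n - p)
      ll <- -0.5 * ((n - p) * log(2 * pi * s2) + logdetW +
                    2 * sum(log(diag(cX))) - p * log(s2) + (n - p))
    }
    list(obj = -ll, loglik = ll, beta = as.numeric(beta), sigma2 = s2,
         vcov_beta = s2 * chol2inv(cX), rss = rss)
  }
}

#' Fit an MLPE or nested-MLPE mixed model to pairwise data
#'
#' Regression for pairwise distance/similarity data:
#' \deqn{y_{ij} = x_{ij}'\beta + u_i + u_j + [v_{L(i)L(j)}] + \epsilon_{ij}}
#' with iid Normal random effects `u` per individual (the maximum-likelihood
#' population effects, MLPE, structure: observations sharing an individual
#' are correlated) and — in the nested model (NMLPE) — an additional iid
#' Normal effect `v` per unordered pair of sampling locations, absorbing the
#' dependence induced by sampling several individuals (e.g. colonies) per
#' location. Estimation profiles the fixed effects and the residual variance
#' analytically and optimizes the variance ratios numerically ((restricted)
#' maximum likelihood, multi-start bounded quasi-Newton). The shared-
#' individual correlation is reported as
#' \eqn{\rho = \sigma_u^2 / (2\sigma_u^2 + \sigma_v^2 + \sigma_e^2) \le 0.5}.
#'
#' When every location pair occurs only once the nested effect is confounded
#' with the residual; the fit detects this, constrains \eqn{\sigma_v^2} out of
#' the model and flags `identifiable = FALSE` instead of returning an
#' arbitrary split.
#'
#' @param formula model formula, e.g. `relatedness ~ tempRange + forest`.
#' @param data a [build_pair_table()] result (any data frame with `id1`,
#'   `id2`, `locpair` columns works).
#' @param nested include the location-pair random effect (NMLPE) or not
#'   (plain MLPE).
#' @param method `"ML"` (default; required for AIC comparison across fixed
#'   effects and for likelihood-ratio tests) or `"REML"`.
#' @param n_starts number of optimizer starts.
#' @return An object of class `mlpe`; see [summary.mlpe()]. Key elements:
#'   `beta`, `se`, `ci`, `rho`, `sigma2_u`, `sigma2_v`, `sigma2_e`, `loglik`,
#'   `aic`, `n_params`, `converged`, `identifiable`.
#' @seealso [likelihood_ratio_test()], [all_subsets_selection()],
#'   [residual_serial_autocorrelation()]
#' @export
mlpe <- function(formula, data, nested = TRUE, method = c("ML", "REML"),
                 n_starts = 3L) {
  method <- match.arg(method)
  stopifnot(all(c("id1", "id2", "locpair") %in% names(data)))
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  if (length(unique(c(data$id1, data$id2))) < 3)
    stop("need at least 3 individuals")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular fixed-effect design; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  des <- pair_design(data)
  identifiable <- TRUE
  use_nested <- nested
  if (nested && max(table(data$locpair)) == 1L) {
    identifiable <- FALSE
    use_nested <- FALSE
    warning(paste("every location pair occurs once: sigma2_v and sigma2_e are",
                  "not separately identifiable; the location-pair effect was",
                  "dropped from the fit"))
  }
  Z <- if (use_nested) cbind(des$Zu, des$Zv) else des$Zu
  blocks <- if (use_nested) rep(1:2, c(ncol(des$Zu), ncol(des$Zv))) else
    rep(1L, ncol(des$Zu))
  nll <- mlpe_profile(y, X, Z, blocks, method)
  k <- max(blocks)
  starts <- list(rep(-2, k), rep(0, k), rep(2, k), c(0, rep(-4, k - 1)))[seq_len(n_starts)]
  best <- NULL
  converged <- FALSE
  for (s in starts) {
    opt <- tryCatch(
      stats::optim(s, function(th) nll(th)$obj, method = "L-BFGS-B",
                   lower = rep(-18, k), upper = rep(15, k),
                   control = list(factr = 1e4)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value - 1e-10) {
      best <- opt
      converged <- opt$convergence == 0
    }
  }
  if (is.null(best)) stop("variance-ratio optimization failed from all starts")
  fitv <- nll(best$par)
  gam <- exp(best$par)
  s2e <- fitv$sigma2
  s2u <- gam[1] * s2e
  s2v <- if (use_nested) gam[2] * s2e else if (nested) NA_real_ else 0
  rho <- s2u / (2 * s2u + ifelse(is.na(s2v), 0, s2v) + s2e)
  beta <- fitv$beta; names(beta) <- colnames(X)
  se <- sqrt(diag(fitv$vcov_beta)); names(se) <- colnames(X)
  ci <- cbind(lower = beta - stats::qnorm(0.975) * se,
              upper = beta + stats::qnorm(0.975) * se)
  n_params <- ncol(X) + 1L + k   # fixed effects + residual variance + ratios
  aic <- -2 * fitv$loglik + 2 * n_params
  fitted_fix <- as.numeric(X %*% beta)
  out <- list(beta = beta, se = se, ci = ci, vcov = fitv$vcov_beta,
              rho = rho, sigma2_u = s2u, sigma2_v = s2v, sigma2_e = s2e,
              loglik = fitv$loglik, n_params = n_params, aic = aic,
              method = method, nested = nested, identifiable = identifiable,
              converged = converged, formula = formula, n = length(y),
              n_individuals = length(des$ids), n_locpairs = length(des$locpairs),
              gamma = gam, fitted = fitted_fix, residuals_raw = y - fitted_fix,
              data = data, design = des, call = match.call())
  class(out) <- "mlpe"
  out
}

#' @export
print.mlpe <- function(x, ...) {
  cat(sprintf("%s regression (%s), %d pairs, %d individuals, %d location pairs\n",
              if (x$nested) "NMLPE" else "MLPE", x$method, x$n,
              x$n_individuals, x$n_locpairs))
  cat("  formula:", deparse(x$formula), "\n")
  print(round(x$beta, 5))
  cat(sprintf("  rho = %.3f; sigma2_u = %.3g, sigma2_v = %.3g, sigma2_e = %.3g\n",
              x$rho, x$sigma2_u, x$sigma2_v, x$sigma2_e))
  cat(sprintf("  logLik = %.3f, AIC = %.3f%s%s\n", x$loglik, x$aic,
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (!x$identifiable) " [sigma2_v not identifiable]" else ""))
  invisible(x)
}

#' Summarize an MLPE/NMLPE fit
#' @param object an `mlpe` fit.
#' @param ... unused.
#' @return A `summary.mlpe`: coefficient table (estimate, SE, z, p, 95% CI),
#'   variance components and fit statistics.
#' @export
summary.mlpe <- function(object, ...) {
  z <- object$beta / object$se
  tab <- cbind(Estimate = object$beta, `Std. Error` = object$se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)),
               object$ci)
  out <- list(coefficients = tab, rho = object$rho,
              variances = c(individual = object$sigma2_u,
                            location_pair = object$sigma2_v,
                            residual = object$sigma2_e),
              loglik = object$loglik, aic = object$aic, n = object$n,
              method = object$method, nested = object$nested,
              converged = object$converged, identifiable = object$identifiable,
              formula = object$formula)
  class(out) <- "summary.mlpe"
  out
}

#' @export
print.summary.mlpe <- function(x, ...) {
  cat(sprintf("%s regression (%s), %d pairs\n",
              if (x$nested) "NMLPE" else "MLPE", x$method, x$n))
  cat("formula:", deparse(x$formula), "\n\nFixed effects:\n")
  stats::printCoefmat(x$coefficients[, 1:4, drop = FALSE], P.values = TRUE,
                      has.Pvalue = TRUE)
  cat("\n95% CI:\n")
  print(round(x$coefficients[, 5:6, drop = FALSE], 5))
  cat("\nVariance components:\n")
  print(round(x$variances, 6))
  cat(sprintf("rho = %.4f   logLik = %.4f   AIC = %.4f\n", x$rho, x$loglik, x$aic))
  if (!x$converged) cat("WARNING: optimizer did not converge\n")
  if (!x$identifiable)
    cat("NOTE: sigma2_v not identifiable (every location pair unique); dropped\n")
  invisible(x)
}

#' @export
coef.mlpe <- function(object, ...) object$beta

#' @export
vcov.mlpe <- function(object, ...) object$vcov

#' @export
confint.mlpe <- function(object, parm, level = 0.95, ...) {
  se <- object$se
  q <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$beta - q * se, object$beta + q * se)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2)), "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
logLik.mlpe <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n,
            class = "logLik")
}

#' Predict from an MLPE fit (fixed effects)
#' @param object an `mlpe` fit.
#' @param newdata optional data frame with the predictor columns; the fit's
#'   own data when omitted.
#' @param ... unused.
#' @return Numeric vector of population-level predictions.
#' @export
predict.mlpe <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  tt <- stats::delete.response(stats::terms(object$formula))
  X <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
  as.numeric(X %*% object$beta)
}

#' Residuals of an MLPE fit
#' @param object an `mlpe` fit.
#' @param type `"response"` (raw, y minus fixed-effect fit) or `"normalized"`
#'   (whitened by the Cholesky factor of the fitted marginal correlation, in
#'   the current row order, and scaled by the residual SD).
#' @param ... unused.
#' @return Numeric vector of residuals.
#' @export
residuals.mlpe <- function(object, type = c("response", "normalized"), ...) {
  type <- match.arg(type)
  r <- object$residuals_raw
  if (type == "response") return(r)
  W <- mlpe_marginal_w(object)
  L <- t(chol(W))
  as.numeric(solve(L, r)) / sqrt(object$sigma2_e)
}

# dense marginal W = I + gamma_u Zu Zu' + gamma_v Zv Zv' in the data row order
mlpe_marginal_w <- function(object, order_idx = NULL) {
  des <- object$design
  Zu <- des$Zu; Zv <- des$Zv
  if (!is.null(order_idx)) { Zu <- Zu[order_idx, ]; Zv <- Zv[order_idx, ] }
  W <- Matrix::Diagonal(nrow(Zu)) + object$gamma[1] * Matrix::tcrossprod(Zu)
  if (object$nested && object$identifiable)
    W <- W + object$gamma[2] * Matrix::tcrossprod(Zv)
  as.matrix(W)
}

#' Simulate responses from a fitted MLPE/NMLPE model
#' @param object an `mlpe` fit.
#' @param nsim number of simulated response vectors.
#' @param seed integer seed, or `NULL` to leave the RNG state alone.
#' @param ... unused.
#' @return Data frame with `nsim` columns, one simulated response per column.
#' @export
simulate.mlpe <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  des <- object$design
  n <- object$n
  s2v <- if (object$nested && object$identifiable) object$sigma2_v else 0
  out <- replicate(nsim, {
    u <- stats::rnorm(ncol(des$Zu), 0, sqrt(object$sigma2_u))
    v <- stats::rnorm(ncol(des$Zv), 0, sqrt(s2v))
    as.numeric(object$fitted + des$Zu %*% u + des$Zv %*% v +
               stats::rnorm(n, 0, sqrt(object$sigma2_e)))
  })
  as.data.frame(out)
}

#' Plot an MLPE fit
#'
#' Scatter of the response against the first predictor with the fixed-effect
#' line, plus a normalized-residual series sorted by location pair.
#' @param x an `mlpe` fit.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.mlpe <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  pred <- attr(stats::terms(x$formula), "term.labels")
  y <- x$fitted + x$residuals_raw
  if (length(pred) >= 1) {
    xv <- x$data[[pred[1]]]
    graphics::plot(xv, y, xlab = pred[1], ylab = "response", pch = 16,
                   cex = 0.4, col = "grey40", ...)
    o <- order(xv)
    graphics::lines(xv[o], x$fitted[o], col = "red3", lwd = 2)
  }
  rn <- residuals(x, "normalized")[order(x$data$locpair)]
  graphics::plot(rn, type = "h", xlab = "pair (sorted by location pair)",
                 ylab = "normalized residual")
  invisible(x)
}
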