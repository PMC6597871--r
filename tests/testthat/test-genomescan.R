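test_that("environmental variable selection recovers a planted factor structure", {
  set.seed(21)
  n <- 60
  base <- matrix(rnorm(n * 4), n, 4)
  colnames(base) <- paste0("orig", 1:4)
  # give the four factors decreasing variance so each owns one component
  base <- sweep(base, 2, c(4, 3, 2, 1.5), "*")
  noise_copies <- base[, rep(1:4, each = 2)] +
    matrix(rnorm(n * 8, 0, 0.5), n, 8)
  colnames(noise_copies) <- paste0("copy", 1:8)
  env <- cbind(base, noise_copies, pure_noise = rnorm(n))
  sel <- env_variable_select(env, n_axes = 4)
  expect_equal(length(sel$selected), 4L)
  expect_equal(sum(sel$variance), 1)
  expect_gt(sel$cumulative_variance, 0.8)
  # each axis should be represented by an original or its direct copy
  for (a in 1:4)
    expect_true(any(grepl(paste0("orig", a, "$|copy", 2 * a - 1, "|copy", 2 * a),
                          sel$selected)))
  expect_error(env_variable_select(env[1:3, ], n_axes = 4), "observations")
})

test_that("duplicate axis winners fall back to the next-best variable", {
  set.seed(5)
  n <- 50
  f <- rnorm(n)
  env <- cbind(a = 3 * f + rnorm(n, 0, 0.01), b = 3 * f + rnorm(n, 0, 0.01),
               c = rnorm(n), d = rnorm(n))
  sel <- env_variable_select(env, n_axes = 2)
  expect_equal(length(unique(sel$selected)), 2L)
})

test_that("genomic inflation adjustment calibrates and is the identity at lambda 1", {
  set.seed(9)
  p <- runif(5000)
  adj <- genomic_inflation_adjust(p)
  expect_lt(abs(adj$lambda - 1), 0.1)
  # construct exactly lambda = 1: adjusted equals raw
  z2 <- qchisq(p, 1, lower.tail = FALSE)
  z2_cal <- z2 * qchisq(0.5, 1) / median(z2)
  p_cal <- pchisq(z2_cal, 1, lower.tail = FALSE)
  adj_cal <- genomic_inflation_adjust(p_cal)
  expect_equal(adj_cal$lambda, 1, tolerance = 1e-12)
  expect_equal(adj_cal$p_adj, p_cal, tolerance = 1e-12)
  # doubling every chi-square doubles lambda and restores uniformity
  p_infl <- pchisq(2 * z2, 1, lower.tail = FALSE)
  adj2 <- genomic_inflation_adjust(p_infl)
  expect_equal(adj2$lambda, 2 * adj$lambda, tolerance = 0.05)
  expect_gt(ks.test(adj2$p_adj, "punif")$p.value, 0.01)
  expect_error(genomic_inflation_adjust(c(0, p)), "0, 1")
})

test_that("Benjamini-Hochberg step-up rule matches hand computation and controls FDR", {
  expect_equal(bh_fdr(c(0.001, 0.2, 0.9), 0.05), c(TRUE, FALSE, FALSE))
  expect_equal(bh_fdr(rep(1, 5), 0.05), rep(FALSE, 5))
  # agrees with p.adjust on random input
  set.seed(2)
  p <- c(runif(400), runif(100, 0, 1e-3))
  expect_equal(bh_fdr(p, 0.05), p.adjust(p, "BH") <= 0.05)
  # empirical FDR control on pure-null simulations
  set.seed(3)
  fdp <- replicate(400, {
    flags <- bh_fdr(runif(300), 0.05)
    mean(any(flags))
  })
  expect_lte(mean(fdp), 0.05 + 0.03)
})

test_that("latent-factor scans are calibrated under the null", {
  land <- simulate_landscape(20, 20, autocorr_range = 1, seed = 61)
  des <- simulate_sampling_design(30, 4, land$habitat, seed = 61)
  surf <- build_resistance_surface(land$habitat, "habitat")
  sim <- simulate_genotypes_ibr(des, surf, n_loci = 5000, fst_scale = 0.05,
                                seed = 61)
  set.seed(62)
  env <- rnorm(nrow(sim$gt$dosages))
  sc <- latent_factor_scan(sim$gt, env, k = 0)
  expect_lt(abs(attr(sc, "lambda") - 1), 0.1)
  expect_gt(ks.test(sc$p_raw[!is.na(sc$p_raw)], "punif")$p.value, 0.01)
  expect_lte(sum(sc$flagged), 5)
  expect_error(latent_factor_scan(sim$gt, rep(1, nrow(sim$gt$dosages)), 0),
               "constant")
})

test_that("latent factors absorb structure confounding", {
  land <- simulate_landscape(20, 20, autocorr_range = 2, seed = 63)
  des <- simulate_sampling_design(20, 4, land$habitat, seed = 63)
  surf <- build_resistance_surface(land$habitat, "habitat")
  sim <- simulate_genotypes_ibr(des, surf, n_loci = 3000, fst_scale = 0.4,
                                seed = 63)
  # environment correlated with a geography axis -> confounded at k = 0
  env <- sim$gt$samples$lon + rnorm(nrow(sim$gt$dosages), 0, 0.1)
  l0 <- attr(latent_factor_scan(sim$gt, env, k = 0), "lambda")
  l2 <- attr(latent_factor_scan(sim$gt, env, k = 2), "lambda")
  expect_lt(abs(l2 - 1), abs(l0 - 1))
})

test_that("spiked environmental clines are recovered with controlled FDR", {
  land <- simulate_landscape(20, 20, autocorr_range = 1, seed = 65)
  des <- simulate_sampling_design(30, 4, land$habitat, seed = 65)
  surf <- build_resistance_surface(land$habitat, "habitat")
  sim <- simulate_genotypes_ibr(des, surf, n_loci = 4000, fst_scale = 0.05,
                                seed = 65)
  set.seed(66)
  env_loc <- rnorm(length(unique(des$location_id)))
  env <- env_loc[match(des$location_id, unique(des$location_id))]
  sp <- spike_adaptive_loci(sim$gt, env, fraction = 0.05, slope = 2, seed = 66)
  sc <- latent_factor_scan(sp$gt, env, k = 0)
  hits <- which(sc$flagged)
  expect_gt(length(hits), 10)
  fdr <- mean(!(hits %in% sp$truth$spiked))
  expect_lte(fdr, 0.10)
  # spiked loci rank at the top of the statistic
  ranks <- rank(-abs(sc$stat))[sp$truth$spiked]
  expect_lt(median(ranks) / ncol(sp$gt$dosages), 0.1)
  # power grows with slope
  sp_weak <- spike_adaptive_loci(sim$gt, env, fraction = 0.05, slope = 0.5,
                                 seed = 66)
  sc_weak <- latent_factor_scan(sp_weak$gt, env, k = 0)
  expect_lte(sum(sc_weak$flagged), length(hits))
})

test_that("Fst outlier scans flag differentiated loci and only those", {
  set.seed(71)
  n_per <- 25; m <- 2000
  p0 <- runif(m, 0.2, 0.8)
  # island model: three demes with modest shared drift
  mk_deme <- function() {
    pd <- plogis(qlogis(p0) + rnorm(m, 0, 0.3))
    vapply(seq_len(m), function(j) rbinom(n_per, 2, pd[j]), numeric(n_per))
  }
  dos <- rbind(mk_deme(), mk_deme(), mk_deme())
  # spike 10 loci with extreme between-deme differentiation
  spiked <- sample(m, 10)
  for (j in spiked) {
    dos[1:n_per, j] <- rbinom(n_per, 2, 0.02)
    dos[(n_per + 1):(3 * n_per), j] <- rbinom(2 * n_per, 2, 0.95)
  }
  gt <- make_gt(dos)
  cl <- rep(1:3, each = n_per)
  sc <- fst_outlier_scan(gt, cl, q = 0.05)
  expect_gte(mean(spiked %in% which(sc$flagged)), 0.8)
  expect_lte(sum(sc$flagged[-spiked]), 0.05 * m)
  expect_error(fst_outlier_scan(gt, rep(1, nrow(dos))), "2 clusters")
  # monomorphic loci excluded with a warning
  gt$dosages[, 1] <- 0
  expect_warning(fst_outlier_scan(gt, cl), "monomorphic|unusable")
})

test_that("candidate intersection across latent-factor settings", {
  mk_scan <- function(flagged, loci = sprintf("l%02d", 1:10)) {
    structure(data.frame(locus = loci, stat = 1, p_raw = 0.5, p_adj = 0.5,
                         flagged = loci %in% flagged),
              class = c("scan_result", "data.frame"))
  }
  s1 <- mk_scan(c("l01", "l02", "l03"))
  s2 <- mk_scan(c("l02", "l03", "l04"))
  expect_equal(intersect_candidates(list(s1, s2)), c("l02", "l03"))
  s3 <- mk_scan(character(0))
  expect_equal(length(intersect_candidates(list(s1, s2, s3))), 0L)
  out <- intersect_candidates(list(s1, s2))
  expect_true(all(out %in% s1$locus[s1$flagged]))
  s4 <- mk_scan("l01", loci = sprintf("x%02d", 1:10))
  expect_error(intersect_candidates(list(s1, s4)), "different locus sets")
})
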