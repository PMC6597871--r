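test_that("diversity metrics match direct counts and a brute-force pi oracle", {
  # single locus, genotypes (0, 1, 2): Ho = 1/3, p = 0.5
  gt <- make_gt(matrix(c(0, 1, 2), 3, 1))
  d <- diversity_metrics(gt, by_cluster = FALSE, n_boot = 50)
  expect_equal(d$ho, 1 / 3)
  expect_equal(d$he, 2 * 0.5 * 0.5 * 6 / 5)
  # all homozygous reference
  gt0 <- make_gt(matrix(0, 4, 3))
  d0 <- suppressWarnings(diversity_metrics(gt0, by_cluster = FALSE, n_boot = 50))
  expect_equal(c(d0$ho, d0$he, d0$pi), c(0, 0, 0))
  # pi equals mean pairwise allele-difference fraction (brute force over
  # haplotype pairs per site)
  gt2 <- sim_hwe_gt(20, 50, seed = 2)
  d2 <- diversity_metrics(gt2, by_cluster = FALSE, n_boot = 50)
  brute_pi <- mean(apply(gt2$dosages, 2, function(g) {
    n_alt <- sum(g); n_all <- 2 * length(g)
    n_alt * (n_all - n_alt) / choose(n_all, 2)
  }))
  expect_equal(d2$pi, brute_pi, tolerance = 1e-12)
  expect_true(all(d2$ho >= d2$ho_lo & d2$ho <= d2$ho_hi))
})

test_that("inbreeding F is near zero for Hardy-Weinberg genotypes", {
  gt <- sim_hwe_gt(100, 800, seed = 9)
  d <- diversity_metrics(gt, by_cluster = FALSE, n_boot = 200)
  expect_lt(abs(d$f), 0.02)
  expect_true(d$f_lo <= d$f & d$f <= d$f_hi)
  # He >= Ho on the same data implies F >= 0 (algebraic sign link)
  gt_inbred <- gt
  gt_inbred$dosages[gt_inbred$dosages == 1] <-
    2 * rbinom(sum(gt_inbred$dosages == 1, na.rm = TRUE), 1, 0.5)
  di <- diversity_metrics(gt_inbred, by_cluster = FALSE, n_boot = 50)
  expect_gt(di$he, di$ho)
  expect_gt(di$f, 0)
})

test_that("clusters are summarised separately and singleton clusters error", {
  gt <- sim_hwe_gt(12, 40, seed = 4)
  gt$samples$cluster <- rep(1:2, each = 6)
  d <- diversity_metrics(gt, n_boot = 50)
  expect_equal(nrow(d), 2L)
  gt$samples$cluster <- c(rep(1, 11), 2)
  expect_error(diversity_metrics(gt, n_boot = 50), "fewer than 2")
})

test_that("Tajima's D evaluates the closed-form constants correctly", {
  # independent spreadsheet-style evaluation for S = 1, 10 haplotypes,
  # derived count 5
  n <- 10
  i <- 1:(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  pi_tot <- 5 * 5 / choose(10, 2)
  d_expected <- (pi_tot - 1 / a1) / sqrt(e1 * 1 + e2 * 0)
  expect_equal(tajima_d_from_counts(5L, 10L), d_expected, tolerance = 1e-12)
  # all singletons -> negative D
  expect_lt(tajima_d_from_counts(rep(1L, 20), 10L), 0)
  # no segregating sites -> NA with warning
  expect_warning(out <- tajima_d_from_counts(integer(0), 10L), "undefined")
  expect_true(is.na(out))
  # genotype-table interface agrees with the count interface
  gt <- sim_hwe_gt(10, 30, seed = 3)
  expect_equal(tajimas_d(gt),
               tajima_d_from_counts(colSums(gt$dosages), 20L))
})

test_that("coalescent simulator reproduces closed-form neutral expectations", {
  # E[TMRCA] for n=2 is 1 coalescent unit
  s2 <- neutral_sim_spec(4, theta = 1, replicates = 4000, seed = 21)
  s2$n_haplotypes <- 2L
  sims <- simulate_neutral_sample(s2)
  expect_equal(mean(attr(sims, "tmrca")), 1, tolerance = 0.05)
  # Watterson: E[S] = theta * a1 at n=10
  th <- 10
  sp <- neutral_sim_spec(10, theta = th, replicates = 4000, seed = 22)
  sims <- simulate_neutral_sample(sp)
  a1 <- sum(1 / (1:9))
  expect_equal(mean(lengths(sims)), th * a1, tolerance = 0.03)
  # site-frequency spectrum proportional to 1/i
  cnt <- table(factor(unlist(sims), levels = 1:9))
  expect_equal(as.numeric(cnt / cnt[1]), 1 / (1:9), tolerance = 0.1)
  # determinism
  sp2 <- neutral_sim_spec(10, s_fixed = 20, replicates = 10, seed = 5)
  expect_identical(simulate_neutral_sample(sp2), simulate_neutral_sample(sp2))
})

test_that("neutral Tajima's D is near zero with the statistic's small negative bias", {
  spec <- neutral_sim_spec(50, s_fixed = 100, replicates = 2000, seed = 31)
  sims <- simulate_neutral_sample(spec)
  d <- vapply(sims, tajima_d_from_counts, numeric(1), n_hap = 50)
  # the normalized statistic has a small negative expectation in finite
  # samples; it must be near zero but not exactly zero
  expect_lt(abs(mean(d)), 0.15)
  expect_lt(mean(d), 0)
})

test_that("MAF-filter bias correction restores the neutral expectation", {
  spec <- neutral_sim_spec(50, s_fixed = 100, replicates = 2000, seed = 41)
  sims <- simulate_neutral_sample(spec)
  d_raw <- vapply(sims, tajima_d_from_counts, numeric(1), n_hap = 50)
  d_filt <- vapply(sims, function(cnt) {
    maf <- pmin(cnt, 50 - cnt) / 50
    tajima_d_from_counts(cnt[maf >= 0.05], 50)
  }, numeric(1))
  expect_gt(mean(d_filt), mean(d_raw) + 0.5)  # filter biases D upward
  corr <- debias_tajimas_d(mean(d_filt), 0.05,
                           neutral_sim_spec(50, s_fixed = 100,
                                            replicates = 2000, seed = 42))
  expect_lt(abs(corr$corrected), 0.1)  # back to the neutral expectation
  # maf_min = 0 leaves the estimate unchanged up to the simulated null mean
  corr0 <- debias_tajimas_d(mean(d_raw), 0,
                            neutral_sim_spec(50, s_fixed = 100,
                                             replicates = 2000, seed = 43))
  expect_lt(abs(corr0$corrected), 3 * corr0$bias_se + 0.05)
  # doubling replicates moves the correction by less than ~2 MC SE
  corr2 <- debias_tajimas_d(mean(d_filt), 0.05,
                            neutral_sim_spec(50, s_fixed = 100,
                                             replicates = 4000, seed = 44))
  expect_lt(abs(corr2$corrected - corr$corrected),
            3 * sqrt(corr$bias_se^2 + corr2$bias_se^2))
})

test_that("LD-based Ne recovers a known Wright-Fisher population size", {
  ne_true <- 100
  hits <- 0; n_rep <- 20
  for (r in seq_len(n_rep)) {
    gt <- wf_sample_gt(ne = ne_true, s = 50, m = 150, gens = 50, seed = 400 + r)
    est <- ld_ne(gt, mating = "random")
    covered <- !is.na(est$ci[1]) && est$ci[1] <= ne_true && ne_true <= est$ci[2]
    if (covered) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.6)
  # monogamy estimate is the published constant rescaling of the same r2
  gt <- wf_sample_gt(ne = ne_true, s = 50, m = 150, gens = 50, seed = 499)
  em <- ld_ne(gt, mating = "monogamy")
  er <- ld_ne(gt, mating = "random")
  expect_gt(em$ne, er$ne)
  expect_equal(em$r2_drift, er$r2_drift)
  # boundary: non-positive corrected r2 reports infinite Ne
  big <- sim_hwe_gt(60, 80, seed = 7)   # panmictic, huge Ne
  est_inf <- ld_ne(big, mating = "random")
  expect_true(is.infinite(est_inf$ne) || est_inf$ne > 500)
})
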