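test_that("VCF round-trip preserves dosages, metadata and missingness", {
  set.seed(1)
  dos <- matrix(sample(c(0, 1, 2, NA), 60, replace = TRUE,
                       prob = c(0.4, 0.3, 0.2, 0.1)), nrow = 5)
  gt <- make_gt(dos, phred = runif(12, 30, 80), depth = runif(12, 20, 50),
                location = rep(c("A", "B"), c(2, 3)))
  vcf <- tempfile(fileext = ".vcf"); meta <- tempfile(fileext = ".csv")
  write_vcf(gt, vcf, meta)
  back <- read_vcf(vcf, meta)
  expect_equal(unname(back$dosages), unname(gt$dosages))
  expect_equal(back$samples$id, gt$samples$id)
  expect_equal(back$samples$location_id, gt$samples$location_id)
  expect_equal(back$loci$phred_quality, gt$loci$phred_quality, tolerance = 1e-6)
  # DP is written rounded per site
  expect_equal(back$loci$mean_depth, round(gt$loci$mean_depth), tolerance = 1e-6)
})

test_that("multiallelic records are dropped and unmatched samples are named", {
  gt <- make_gt(matrix(c(0, 1, 2, 0, 1, 2), nrow = 3))
  vcf <- tempfile(fileext = ".vcf"); meta <- tempfile(fileext = ".csv")
  write_vcf(gt, vcf, meta)
  # inject a triallelic record
  lines <- readLines(vcf)
  tri <- sub("\tA\tT\t", "\tA\tT,G\t", lines[length(lines)])
  tri <- sub("l002", "l_tri", tri)
  writeLines(c(lines, tri), vcf)
  expect_message(back <- read_vcf(vcf, meta), "multiallelic")
  expect_equal(ncol(back$dosages), 2L)

  meta2 <- tempfile(fileext = ".csv")
  md <- read.csv(meta)
  write.csv(md[-2, ], meta2, row.names = FALSE)
  expect_error(read_vcf(vcf, meta2), "s002")
})

test_that("locus filter chain removes by quality/depth/MAF/HWE in order and is idempotent", {
  set.seed(7)
  n <- 60
  dos <- vapply(1:100, function(j) rbinom(n, 2, 0.5), numeric(n))
  phred <- rep(50, 100); phred[1] <- 25            # below quality window
  depth <- rep(30, 100); depth[11:20] <- 60        # above depth window
  dos[, 30] <- rep(1, n)                           # extreme HWE deviation
  dos[, 31] <- c(2, rep(0, n - 1))                 # MAF = 1/(2n)
  gt <- make_gt(dos, phred = phred, depth = depth)
  spec <- filter_spec(maf_min = 0.05)
  res <- apply_locus_filters(gt, spec)
  expect_equal(res$report$steps,
               c("missingness", "quality", "depth", "maf", "hwe"))
  expect_equal(res$report$removed[res$report$steps == "quality"], 1L)
  expect_equal(res$report$removed[res$report$steps == "depth"], 10L)
  expect_true(res$report$removed[res$report$steps == "maf"] >= 1)
  expect_true(res$report$removed[res$report$steps == "hwe"] >= 1)
  expect_false("l001" %in% res$gt$loci$id)
  expect_false("l030" %in% res$gt$loci$id)
  expect_equal(sum(res$report$removed) + res$report$n_retained,
               res$report$n_input)
  # idempotence
  res2 <- apply_locus_filters(res$gt, spec)
  expect_equal(sum(res2$report$removed), 0L)
  expect_equal(res2$gt$loci$id, res$gt$loci$id)
  # a no-op spec removes nothing
  noop <- filter_spec(phred_min = -Inf, phred_max = Inf, depth_min = -Inf,
                      depth_max = Inf, hwe_alpha = 0, max_missing = 1)
  expect_equal(sum(apply_locus_filters(gt, noop)$report$removed), 0L)
  # report JSON is written
  path <- tempfile(fileext = ".json")
  write_filter_report(res$report, path)
  expect_equal(jsonlite::read_json(path)$n_retained, res$report$n_retained)
})

test_that("HWE exact test matches a permutation-enumeration oracle", {
  # oracle: shuffle the 2n alleles into pairs, tabulate heterozygote counts
  hwe_oracle <- function(g, nrep = 40000, seed = 1) {
    set.seed(seed)
    n <- length(g); n_alt <- sum(g); n_het_obs <- sum(g == 1)
    alleles <- rep(c(1, 0), c(n_alt, 2 * n - n_alt))
    hets <- replicate(nrep, {
      a <- sample(alleles)
      sum(a[seq(1, 2 * n, 2)] != a[seq(2, 2 * n, 2)])
    })
    tab <- table(hets) / nrep
    p_obs <- tab[as.character(n_het_obs)]
    if (is.na(p_obs)) p_obs <- 0
    sum(tab[tab <= as.numeric(p_obs) * (1 + 1e-9)])
  }
  cases <- list(rep(c(0, 1, 2), c(5, 20, 5)),    # het excess
                rep(c(0, 1, 2), c(12, 4, 14)),   # het deficit
                rep(c(0, 1, 2), c(12, 25, 13)))  # near equilibrium
  for (g in cases) {
    expect_lt(abs(hwe_exact_test(g) - hwe_oracle(g)), 0.02)
  }
  expect_lt(hwe_exact_test(rep(c(0, 1, 2), c(0, 100, 0))), 1e-10)
  expect_equal(hwe_exact_test(rep(c(0, 1, 2), c(25, 50, 25))), 1,
               tolerance = 0.05)
  expect_equal(hwe_exact_test(rep(0, 100)), 1)
})

test_that("LD pruning is greedy by position and verified against brute force", {
  set.seed(3)
  n <- 200
  a <- rbinom(n, 2, 0.5)
  c_ <- rbinom(n, 2, 0.5)
  b <- ifelse(rbinom(n, 1, 0.95) == 1, a, c_)   # b~a strong, b~c weak
  gt <- make_gt(cbind(a, b, c_))
  pruned <- ld_prune(gt, 0.4)
  expect_equal(pruned$loci$id, c("l001", "l003"))
  # duplicated locus: first kept
  gt2 <- make_gt(cbind(a, a))
  expect_equal(ld_prune(gt2, 0.4)$loci$id, "l001")
  # independent loci all kept
  gt3 <- sim_hwe_gt(300, 10, seed = 5)
  expect_equal(ncol(ld_prune(gt3, 0.4)$dosages), 10L)
  # brute-force invariant on random tables up to 50 loci
  for (seed in 1:3) {
    gt4 <- sim_hwe_gt(80, 50, seed = seed)
    # plant some duplicates to exercise pruning
    gt4$dosages[, 5] <- gt4$dosages[, 4]
    gt4$dosages[, 20] <- gt4$dosages[, 19]
    out <- ld_prune(gt4, 0.4)
    r2 <- cor(out$dosages)^2
    expect_true(all(r2[upper.tri(r2)] <= 0.4 + 1e-12))
  }
})

test_that("cluster assignment takes the ancestry argmax with deterministic ties", {
  gt <- make_gt(matrix(c(0, 1, 2), 3, 2))
  q <- rbind(c(0.1, 0.7, 0.2), c(0.5, 0.5, 0.0), c(1, 0, 0))
  expect_message(out <- assign_clusters(gt, q), "tied")
  expect_equal(out$samples$cluster, c(2L, 1L, 1L))
  expect_equal(assign_clusters(gt, matrix(1, 3, 1))$samples$cluster, rep(1L, 3))
  expect_error(assign_clusters(gt, q * 1.01), "sum to 1")
})
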