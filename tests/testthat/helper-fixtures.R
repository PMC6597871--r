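# quick genotype-table builder with default metadata
make_gt <- function(dosages, phred = NULL, depth = NULL, chrom = "chr1",
                    location = NULL, lon = NULL, lat = NULL) {
  dosages <- as.matrix(dosages)
  n <- nrow(dosages); m <- ncol(dosages)
  loci <- data.frame(id = sprintf("l%03d", seq_len(m)), chrom = chrom,
                     pos = seq_len(m) * 10L,
                     phred_quality = if (is.null(phred)) rep(50, m) else phred,
                     mean_depth = if (is.null(depth)) rep(30, m) else depth)
  samples <- data.frame(id = sprintf("s%03d", seq_len(n)),
                        lon = if (is.null(lon)) seq_len(n) * 0.01 else lon,
                        lat = if (is.null(lat)) seq_len(n) * 0.01 else lat,
                        location_id = if (is.null(location))
                          sprintf("s%03d", seq_len(n)) else location)
  genotype_table(dosages, loci, samples)
}

# Hardy-Weinberg-equilibrium genotypes: n samples x m loci, freqs p
sim_hwe_gt <- function(n, m, p = runif(m, 0.1, 0.9), seed = 1) {
  set.seed(seed)
  dos <- vapply(seq_len(m), function(j) stats::rbinom(n, 2, p[j]), numeric(n))
  make_gt(dos)
}

# genotype-level discrete-generation Wright-Fisher population of diploid
# size ne (random mating), followed for `gens` generations at `m` unlinked
# loci; the finite parent pool generates genuine drift LD between unlinked
# loci. Returns a genotype table of `s` sampled individuals (segregating
# loci only).
wf_sample_gt <- function(ne, s, m, gens = 60, seed = 1) {
  set.seed(seed)
  p <- runif(m, 0.2, 0.8)
  A1 <- vapply(p, function(pp) rbinom(ne, 1, pp), numeric(ne))
  A2 <- vapply(p, function(pp) rbinom(ne, 1, pp), numeric(ne))
  for (g in seq_len(gens)) {
    mi <- sample.int(ne, ne, replace = TRUE)
    fi <- sample.int(ne, ne, replace = TRUE)
    pick1 <- matrix(runif(ne * m) < 0.5, ne, m)
    pick2 <- matrix(runif(ne * m) < 0.5, ne, m)
    A1n <- ifelse(pick1, A1[mi, ], A2[mi, ])
    A2n <- ifelse(pick2, A1[fi, ], A2[fi, ])
    A1 <- A1n; A2 <- A2n
  }
  idx <- sample.int(ne, s)
  dos <- A1[idx, ] + A2[idx, ]
  keep <- apply(dos, 2, function(x) var(x) > 0)
  make_gt(dos[, keep, drop = FALSE])
}
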