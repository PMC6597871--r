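# Gaussian random field on a grid by circulant embedding (exponential
# covariance, range in map units); returned standardized to mean 0, sd 1.
gaussian_random_field <- function(nr, nc, range, cellsize = 1) {
  NR <- 2 * nr; NC <- 2 * nc
  dy <- pmin(0:(NR - 1), NR - (0:(NR - 1))) * cellsize
  dx <- pmin(0:(NC - 1), NC - (0:(NC - 1))) * cellsize
  d <- sqrt(outer(dy^2, dx^2, "+"))
  lam <- Re(stats::fft(exp(-d / range)))
  lam[lam < 0] <- 0
  xi <- matrix(stats::rnorm(NR * NC), NR, NC) +
    1i * matrix(stats::rnorm(NR * NC), NR, NC)
  f <- Re(stats::fft(sqrt(lam) * xi))[seq_len(nr), seq_len(nc)] / sqrt(NR * NC)
  (f - mean(f)) / stats::sd(f)
}

# local standard deviation in a 3x3 moving window (edge cells use the
# available neighbors)
local_sd <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ri <- max(1, i - 1):min(nr, i + 1)
    cj <- max(1, j - 1):min(nc, j + 1)
    out[i, j] <- stats::sd(m[ri, cj])
  }
  out
}

#' Simulate a synthetic landscape raster set
#'
#' Generates spatially autocorrelated Gaussian-random-field surfaces (via
#' circulant embedding with exponential covariance) standing in for the GIS
#' layers of a landscape-genetic study: continuous `elevation` (scaled to
#' 0-1000 m), a `climate` layer, a continuous `forest` cover layer (0-100),
#' a binary `habitat` layer (its own field thresholded so that a fraction
#' `habitat_prob` of cells is habitat), and `roughness` (local standard
#' deviation of elevation). All layers share the grid geometry and the seed
#' makes them reproducible.
#'
#' @param nrows,ncols grid dimensions (>= 10 each).
#' @param autocorr_range correlation range in map units.
#' @param habitat_prob fraction of habitat cells in \[0, 1\].
#' @param seed integer seed.
#' @param cellsize,xll,yll grid geometry (decimal degrees by default).
#' @return Named list of `raster_grid`s: `elevation`, `climate`, `forest`,
#'   `habitat`, `roughness`.
#' @export
simulate_landscape <- function(nrows, ncols, autocorr_range = 2,
                               habitat_prob = 0.5, seed = 1L,
                               cellsize = 0.1, xll = -45, yll = -10) {
  stopifnot(nrows >= 10, ncols >= 10, habitat_prob >= 0, habitat_prob <= 1)
  set.seed(seed)
  mk <- function(v) raster_grid(v, cellsize = cellsize, xll = xll, yll = yll)
  elev_f <- gaussian_random_field(nrows, ncols, autocorr_range, cellsize)
  clim_f <- gaussian_random_field(nrows, ncols, autocorr_range, cellsize)
  forest_f <- gaussian_random_field(nrows, ncols, autocorr_range, cellsize)
  hab_f <- gaussian_random_field(nrows, ncols, autocorr_range, cellsize)
  elev <- pmax(500 + 250 * elev_f, 0)  # sea level floor
  habitat <- if (habitat_prob >= 1) matrix(1, nrows, ncols)
    else if (habitat_prob <= 0) matrix(0, nrows, ncols)
    else (hab_f >= stats::quantile(hab_f, 1 - habitat_prob)) * 1
  forest <- 50 + 20 * forest_f
  forest <- pmin(pmax(forest, 0), 100)
  list(elevation = mk(elev), climate = mk(clim_f), forest = mk(forest),
       habitat = mk(habitat), roughness = mk(local_sd(elev)))
}

#' Simulate a clustered sampling design on a raster
#'
#' Places `n_locations` sampling locations uniformly on distinct non-nodata
#' cells and draws the number of colonies per location from a zero-truncated
#' Poisson. Colonies share their location's cell-center coordinates, so
#' within-location pairs are 0 km apart, mirroring designs where several
#' colonies are sampled from one beekeeper.
#'
#' @param n_locations number of locations (>= 2).
#' @param colonies_per_location_mean Poisson mean before zero-truncation.
#' @param raster a `raster_grid` supplying valid cells and geometry.
#' @param seed integer seed.
#' @return Data frame: `id`, `lon`, `lat`, `location_id`.
#' @export
simulate_sampling_design <- function(n_locations, colonies_per_location_mean = 3,
                                     raster, seed = 1L) {
  stopifnot(n_locations >= 2)
  set.seed(seed)
  ok <- which(!is.na(raster$values))
  if (length(ok) < n_locations)
    stop("raster too small: ", length(ok), " valid cells for ",
         n_locations, " locations")
  cells <- sample(ok, n_locations)
  cc <- raster_cell_centers(raster)
  nr <- nrow(raster$values)
  row <- ((cells - 1) %% nr) + 1
  col <- ((cells - 1) %/% nr) + 1
  n_col <- vapply(seq_len(n_locations), function(i) {
    repeat {
      k <- stats::rpois(1, colonies_per_location_mean)
      if (k >= 1) return(k)
    }
  }, integer(1))
  out <- do.call(rbind, lapply(seq_len(n_locations), function(i) {
    data.frame(id = sprintf("L%02dC%02d", i, seq_len(n_col[i])),
               lon = cc$x[col[i]], lat = cc$y[row[i]],
               location_id = sprintf("L%02d", i), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate genotypes whose relatedness decays with circuit resistance
#'
#' Instantiates the isolation-by-resistance generative assumption directly:
#' per locus, an ancestral frequency p0 ~ Uniform(0.1, 0.9) is drawn and the
#' per-location logit frequencies come from a multivariate Normal with mean
#' logit(p0) and covariance `fst_scale * exp(-R_ab / phi)`, where `R_ab` is
#' the circuit-theory resistance between locations on `surface`. Individual
#' dosages are Binomial(2, p_location). Optional iid location noise
#' (`location_noise_sd`, per locus and location) adds shared within-location
#' drift with no spatial structure — the dependence that the nested MLPE
#' model absorbs. Frequencies are clipped to \[0.001, 0.999\].
#'
#' @param design a [simulate_sampling_design()] data frame.
#' @param surface a `resistance_surface`.
#' @param n_loci number of loci (>= 100 for stable relatedness estimates).
#' @param fst_scale variance of the logit-frequency field (drives Fst).
#' @param phi resistance-decay scale; `NULL` uses the median pairwise
#'   resistance; `Inf` removes the decay (no isolation signal).
#' @param location_noise_sd sd of the unstructured location noise.
#' @param seed integer seed.
#' @return A list: `gt` (a `genotype_table`) and `truth` (generating
#'   parameters: surface provenance, `phi`, `fst_scale`, `location_noise_sd`,
#'   `seed`, per-locus `p0`, and the location resistance matrix `R`).
#' @export
simulate_genotypes_ibr <- function(design, surface, n_loci = 1000,
                                   fst_scale = 0.3, phi = NULL,
                                   location_noise_sd = 0, seed = 1L) {
  locs <- design[!duplicated(design$location_id), , drop = FALSE]
  R <- pairwise_circuit_resistance(surface, locs)
  if (any(!is.finite(R))) stop("disconnected locations on the resistance surface")
  set.seed(seed)
  L <- nrow(locs)
  if (is.null(phi)) phi <- stats::median(R[upper.tri(R)])
  S <- fst_scale * exp(-R / phi)
  ch <- chol(S + 1e-8 * diag(L))
  p0 <- stats::runif(n_loci, 0.1, 0.9)
  Zs <- matrix(stats::rnorm(n_loci * L), n_loci, L) %*% ch
  if (location_noise_sd > 0)
    Zs <- Zs + matrix(stats::rnorm(n_loci * L, 0, location_noise_sd), n_loci, L)
  pf <- stats::plogis(sweep(Zs, 1, stats::qlogis(p0), "+"))
  pf <- pmin(pmax(pf, 0.001), 0.999)
  loc_idx <- match(design$location_id, locs$location_id)
  n <- nrow(design)
  P <- t(pf)[loc_idx, , drop = FALSE]    # samples x loci success probabilities
  dos <- matrix(stats::rbinom(length(P), 2, P), nrow = n)
  loci <- data.frame(id = sprintf("snp%05d", seq_len(n_loci)), chrom = "chr1",
                     pos = seq_len(n_loci) * 100L,
                     phred_quality = round(stats::runif(n_loci, 35, 75), 1),
                     mean_depth = round(stats::runif(n_loci, 22, 48), 1),
                     stringsAsFactors = FALSE)
  gt <- genotype_table(dos, loci, design)
  truth <- list(surface = attr(surface, "provenance"), phi = phi,
                fst_scale = fst_scale, location_noise_sd = location_noise_sd,
                seed = seed, p0 = p0, R = R)
  list(gt = gt, truth = truth)
}

#' Spike environmentally-associated loci into a genotype table
#'
#' Replaces the per-location allele frequencies of a random fraction of loci
#' with a logistic cline in an environmental variable,
#' `p_loc = plogis(logit(p0) + slope * env_loc)`, and redraws those dosages.
#' The modified locus indices and slope are recorded so scans can be scored.
#'
#' @param gt a `genotype_table`.
#' @param env_values numeric vector, one value per sample (location-constant
#'   values recommended); standardized internally.
#' @param fraction fraction of loci to spike, in (0, 0.5].
#' @param slope logistic slope per sd of the environmental variable.
#' @param seed integer seed.
#' @return A list: `gt` (modified table) and `truth` (`spiked` indices,
#'   `slope`, `seed`).
#' @export
spike_adaptive_loci <- function(gt, env_values, fraction = 0.05, slope = 1,
                                seed = 1L) {
  stopifnot(fraction > 0, fraction <= 0.5,
            length(env_values) == nrow(gt$dosages))
  set.seed(seed)
  m <- ncol(gt$dosages)
  idx <- sort(sample.int(m, max(1, round(fraction * m))))
  env_s <- as.numeric(scale(env_values))
  p0 <- pmin(pmax(allele_freq(gt)[idx], 0.1), 0.9)
  for (k in seq_along(idx)) {
    p <- stats::plogis(stats::qlogis(p0[k]) + slope * env_s)
    p <- pmin(pmax(p, 0.001), 0.999)
    gt$dosages[, idx[k]] <- stats::rbinom(length(p), 2, p)
  }
  list(gt = gt, truth = list(spiked = idx, slope = slope, seed = seed))
}

#' Simulate pairwise data from the MLPE/NMLPE generative model
#'
#' Draws a clustered design (locations uniform in a box, a fixed number of
#' colonies each), builds the pair table with one standardized
#' distance-derived predictor `x`, and simulates the response
#' `y = beta * x + u_i + u_j + v_locpair + e` with the variance components
#' implied by `rho` and `sigma2_v` at unit total pair variance
#' (`sigma2_u = rho * total_var`; `sigma2_e` absorbs the rest). With
#' `null_predictor = TRUE` the response is simulated with `beta = 0` while
#' the structured predictor is kept — the type-I-error scenario for
#' pairwise regression.
#'
#' @param n_locations,colonies_per_location design size.
#' @param beta true slope on the standardized predictor.
#' @param rho shared-individual correlation (sigma2_u at unit total variance).
#' @param sigma2_v location-pair variance component.
#' @param total_var total pair variance (2 sigma2_u + sigma2_v + sigma2_e).
#' @param null_predictor simulate under beta = 0.
#' @param seed integer seed.
#' @return A `pair_table` with attribute `truth` (list of the generating
#'   parameters) and predictor column `x`.
#' @export
simulate_mlpe_data <- function(n_locations = 20, colonies_per_location = 3,
                               beta = -0.5, rho = 0.3, sigma2_v = 0,
                               total_var = 1, null_predictor = FALSE,
                               seed = 1L) {
  set.seed(seed)
  s2u <- rho * total_var
  s2e <- total_var - 2 * s2u - sigma2_v
  if (s2e <= 0) stop("rho and sigma2_v leave no residual variance")
  lon <- stats::runif(n_locations, -45, -37)
  lat <- stats::runif(n_locations, -12, -4)
  samples <- do.call(rbind, lapply(seq_len(n_locations), function(i)
    data.frame(id = sprintf("L%02dC%02d", i, seq_len(colonies_per_location)),
               lon = lon[i], lat = lat[i],
               location_id = sprintf("L%02d", i), stringsAsFactors = FALSE)))
  D <- geographic_distance_matrix(samples)
  n <- nrow(samples)
  pt <- build_pair_table(matrix(0, n, n, dimnames = list(samples$id, samples$id)),
                         list(x = D), samples)
  des <- pair_design(pt)
  b <- if (null_predictor) 0 else beta
  u <- stats::rnorm(ncol(des$Zu), 0, sqrt(s2u))
  v <- stats::rnorm(ncol(des$Zv), 0, sqrt(sigma2_v))
  e <- stats::rnorm(nrow(pt), 0, sqrt(s2e))
  pt$relatedness <- as.numeric(b * pt$x + des$Zu %*% u + des$Zv %*% v + e)
  attr(pt, "truth") <- list(beta = b, rho = rho, sigma2_u = s2u,
                            sigma2_v = sigma2_v, sigma2_e = s2e, seed = seed)
  pt
}

#' Write a genotype table as a VCF plus metadata CSV
#'
#' Emits a minimal VCF v4.2 (GT:DP fields, site QUAL from the locus Phred
#' quality) and a `sample_id, lon, lat, location_id` CSV, so synthetic
#' datasets can exercise the package's file interfaces end to end.
#'
#' @param gt a `genotype_table`.
#' @param vcf_path,metadata_path output paths.
#' @return Invisibly, a list with both paths.
#' @export
write_vcf <- function(gt, vcf_path, metadata_path) {
  n <- nrow(gt$dosages); m <- ncol(gt$dosages)
  con <- file(vcf_path, "w")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gt$samples$id), collapse = "\t")), con)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  dp <- round(ifelse(is.na(gt$loci$mean_depth), 30, gt$loci$mean_depth))
  for (j in seq_len(m)) {
    g <- gt$dosages[, j]
    cells <- ifelse(is.na(g), "./.",
                    paste0(gt_code[as.character(g)], ":", dp[j]))
    qual <- gt$loci$phred_quality[j]
    writeLines(paste(c(gt$loci$chrom[j], gt$loci$pos[j], gt$loci$id[j], "A",
                       "T", ifelse(is.na(qual), ".", qual), "PASS", ".",
                       "GT:DP", cells), collapse = "\t"), con)
  }
  close(con)
  meta <- data.frame(sample_id = gt$samples$id, lon = gt$samples$lon,
                     lat = gt$samples$lat, location_id = gt$samples$location_id)
  utils::write.csv(meta, metadata_path, row.names = FALSE, quote = FALSE)
  invisible(list(vcf = vcf_path, metadata = metadata_path))
}

#' Raster values at point coordinates
#' @param raster a `raster_grid`.
#' @param lon,lat coordinate vectors.
#' @return Numeric vector of cell values at the points.
#' @export
extract_raster_values <- function(raster, lon, lat) {
  vapply(seq_along(lon), function(i) {
    rc <- raster_cell_at(raster, lon[i], lat[i])
    raster$values[rc[1], rc[2]]
  }, numeric(1))
}
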