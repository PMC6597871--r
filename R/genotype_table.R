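#' Genotype tables
#'
#' A `genotype_table` holds a samples x loci allele-dosage matrix (values 0,
#' 1, 2 or `NA` for missing) together with per-locus metadata (id, chromosome,
#' 1-based position, site Phred quality, mean read depth) and per-sample
#' metadata (id, longitude, latitude, location id, optional genetic cluster).
#' It is the substrate of every genetic computation in the package.
#'
#' @param dosages numeric matrix, samples in rows, loci in columns; entries
#'   must be 0, 1, 2 or `NA`. Row and column names are taken from `samples$id`
#'   and `loci$id` if absent.
#' @param loci data frame with columns `id`, `chrom`, `pos`, `phred_quality`,
#'   `mean_depth` (missing metadata columns are filled with `NA`).
#' @param samples data frame with columns `id`, `lon`, `lat`, `location_id`
#'   and optionally `cluster`.
#'
#' @return An object of class `genotype_table`: a list with elements
#'   `dosages`, `loci`, `samples`.
#' @export
genotype_table <- function(dosages, loci, samples) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (ncol(dosages) < 1L) stop("genotype_table needs at least one locus")
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  for (col in c("chrom", "pos", "phred_quality", "mean_depth"))
    if (is.null(loci[[col]])) loci[[col]] <- NA
  if (is.null(loci$id)) stop("loci must have an 'id' column")
  if (is.null(samples$id)) stop("samples must have an 'id' column")
  loci$id <- as.character(loci$id)
  samples$id <- as.character(samples$id)
  if (anyDuplicated(loci$id)) stop("locus ids must be unique")
  if (anyDuplicated(samples$id)) stop("sample ids must be unique")
  if (nrow(loci) != ncol(dosages)) stop("loci rows must match dosage columns")
  if (nrow(samples) != nrow(dosages)) stop("samples rows must match dosage rows")
  if (!all(c("lon", "lat") %in% names(samples)) ||
      any(!is.finite(samples$lon)) || any(!is.finite(samples$lat)))
    stop("every sample needs finite lon/lat coordinates")
  if (is.null(samples$location_id)) samples$location_id <- samples$id
  rownames(dosages) <- samples$id
  colnames(dosages) <- loci$id
  structure(list(dosages = dosages, loci = loci, samples = samples),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  miss <- mean(is.na(x$dosages))
  cat(sprintf("genotype_table: %d samples x %d loci (%.1f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages), 100 * miss))
  cat(sprintf("  locations: %d", length(unique(x$samples$location_id))))
  if (!is.null(x$samples$cluster))
    cat(sprintf(", clusters: %d", length(unique(x$samples$cluster))))
  cat("\n")
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$dosages)

#' Subset a genotype table by samples and/or loci
#'
#' @param gt a `genotype_table`.
#' @param samples,loci index vectors (logical, integer or character ids);
#'   `NULL` keeps everything.
#' @return A `genotype_table`.
#' @export
gt_subset <- function(gt, samples = NULL, loci = NULL) {
  si <- if (is.null(samples)) seq_len(nrow(gt$dosages)) else samples
  li <- if (is.null(loci)) seq_len(ncol(gt$dosages)) else loci
  if (is.character(si)) si <- match(si, gt$samples$id)
  if (is.character(li)) li <- match(li, gt$loci$id)
  genotype_table(gt$dosages[si, li, drop = FALSE],
                 gt$loci[li, , drop = FALSE],
                 gt$samples[si, , drop = FALSE])
}

#' Per-locus alternate allele frequency
#'
#' @param gt a `genotype_table`.
#' @return Numeric vector: alternate-allele frequency per locus from
#'   non-missing genotypes (NaN for loci with no calls).
#' @export
allele_freq <- function(gt) {
  colMeans(gt$dosages, na.rm = TRUE) / 2
}

#' Per-locus minor allele frequency
#' @param gt a `genotype_table`.
#' @return Numeric vector of minor-allele frequencies.
#' @export
minor_allele_freq <- function(gt) {
  p <- allele_freq(gt)
  pmin(p, 1 - p)
}

#' Read a multi-sample VCF and sample metadata into a genotype table
#'
#' Biallelic SNP records are kept; multiallelic records are dropped with a
#' message. Missing genotypes become `NA` dosages. Site quality (QUAL) and
#' per-site mean depth (INFO/DP divided by the sample count, or the mean of
#' per-genotype FORMAT/DP when present) populate the locus metadata.
#'
#' @param path path to a VCF (v4.x, plain text or gzipped).
#' @param metadata path to a CSV with columns `sample_id`, `lon`, `lat`,
#'   `location_id` (extra columns retained); `sample_id` must cover every VCF
#'   sample.
#' @return A `genotype_table`.
#' @export
read_vcf <- function(path, metadata) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@gt) == 0L) stop("empty VCF: no variant records in ", path)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  biallelic <- !grepl(",", alt) & nchar(ref) == 1L & nchar(alt) == 1L & alt != "."
  n_drop <- sum(!biallelic)
  if (n_drop > 0)
    message(n_drop, " multiallelic/non-SNP record(s) dropped")
  if (!any(biallelic)) stop("no biallelic SNP records in ", path)
  vcf <- vcf[biallelic, ]
  fix <- fix[biallelic, , drop = FALSE]

  gtmat <- vcfR::extract.gt(vcf, element = "GT")
  alleles <- function(g) {
    g <- sub(":.*", "", g)
    a <- strsplit(g, "[/|]")
    vapply(a, function(x) {
      x <- suppressWarnings(as.numeric(x))
      if (any(is.na(x))) NA_real_ else sum(x)
    }, numeric(1))
  }
  dos <- apply(gtmat, 2, alleles)
  if (is.null(dim(dos)))
    dos <- matrix(dos, nrow = 1, dimnames = list(NULL, colnames(gtmat)))
  dos <- t(dos)  # samples x loci

  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  dp <- tryCatch({
    dpm <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
    rowMeans(dpm, na.rm = TRUE)
  }, error = function(e) rep(NA_real_, nrow(fix)))
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  loci <- data.frame(id = make.unique(ids), chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     phred_quality = qual, mean_depth = dp,
                     stringsAsFactors = FALSE)

  meta <- utils::read.csv(metadata, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "lon", "lat", "location_id") %in% names(meta)))
    stop("metadata CSV needs columns sample_id, lon, lat, location_id")
  vcf_samples <- rownames(dos)
  missing_meta <- setdiff(vcf_samples, meta$sample_id)
  if (length(missing_meta) > 0)
    stop("metadata missing sample id(s): ", paste(missing_meta, collapse = ", "))
  meta <- meta[match(vcf_samples, meta$sample_id), , drop = FALSE]
  samples <- data.frame(id = meta$sample_id, lon = meta$lon, lat = meta$lat,
                        location_id = as.character(meta$location_id),
                        stringsAsFactors = FALSE)
  if (!is.null(meta$cluster)) samples$cluster <- meta$cluster
  genotype_table(dos, loci, samples)
}

#' Assign samples to genetic clusters from an ancestry (Q) matrix
#'
#' Each sample is assigned to the cluster with its highest ancestry fraction,
#' as when hard-assigning individuals from sNMF/Admixture output. Ties are
#' broken toward the lowest cluster index and reported via a message.
#'
#' @param gt a `genotype_table`.
#' @param qmatrix numeric matrix or data frame, samples x K, rows summing to 1
#'   (tolerance 1e-6); rownames (or a `sample_id` column) must match the
#'   table's sample ids when present, otherwise row order is used.
#' @return The `genotype_table` with a `cluster` column (1-based integer).
#' @export
assign_clusters <- function(gt, qmatrix) {
  q <- qmatrix
  if (is.data.frame(q) && "sample_id" %in% names(q)) {
    rn <- q$sample_id
    q <- as.matrix(q[, setdiff(names(q), "sample_id"), drop = FALSE])
    rownames(q) <- rn
  } else q <- as.matrix(q)
  if (!is.null(rownames(q)) && all(gt$samples$id %in% rownames(q)))
    q <- q[gt$samples$id, , drop = FALSE]
  if (nrow(q) != nrow(gt$dosages))
    stop("Q-matrix rows must match samples")
  rs <- rowSums(q)
  if (any(abs(rs - 1) > 1e-6))
    stop("Q-matrix rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  cl <- apply(q, 1, which.max)  # which.max takes the first maximum: lowest index on ties
  ties <- apply(q, 1, function(r) sum(r == max(r)) > 1)
  if (any(ties))
    message(sum(ties), " sample(s) with tied ancestry assigned to the lowest cluster index")
  gt$samples$cluster <- as.integer(cl)
  gt
}
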