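pipeline_known_keys <- c("vcf", "metadata", "qmatrix", "rasters", "out_dir",
                         "filters", "resistance", "ibr", "scan", "seed")

validate_pipeline_config <- function(config) {
  unknown <- setdiff(names(config), pipeline_known_keys)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (key in c("vcf", "metadata", "out_dir"))
    if (is.null(config[[key]])) stop("config key '", key, "' is required")
  for (key in c("vcf", "metadata", "qmatrix"))
    if (!is.null(config[[key]]) && !file.exists(config[[key]]))
      stop("config path for '", key, "' does not exist: ", config[[key]])
  for (nm in names(config$rasters))
    if (!file.exists(config$rasters[[nm]]))
      stop("raster path '", nm, "' does not exist: ", config$rasters[[nm]])
  invisible(config)
}

#' Run the landscape-genomics pipeline end to end
#'
#' Executes the stages in dependency order — locus filtering, per-cluster
#' diversity, relatedness + autocorrelogram, resistance surfaces and circuit
#' distances, MLPE/NMLPE model selection, environmental-association and
#' Fst-outlier scans — writing each stage's tables as CSV/JSON into the
#' output directory together with a JSON log of seeds and settings.
#'
#' @param config a named list (or path to a YAML/JSON file) with keys:
#'   `vcf`, `metadata` (paths, required), `out_dir` (required), optional
#'   `qmatrix` (ancestry CSV), `rasters` (named list of ESRI ASCII paths with
#'   a `mode` convention: names `habitat`, `forest`, `elevation`, `roughness`,
#'   `climate` are mapped to surface modes), `filters` (arguments to
#'   [filter_spec()]), `ibr` (list: `nested`, `collinearity_rmax`), `scan`
#'   (list: `env`, `k`, `q`), `seed`. Unknown keys are rejected before any
#'   computation.
#' @return The output directory path, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("yaml package needed for YAML configs")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  validate_pipeline_config(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log <- list(seed = seed, started = format(Sys.time()), stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    log$stages[[name]] <<- list(done = TRUE)
    res
  }

  gt <- stage("read", read_vcf(config$vcf, config$metadata))
  if (!is.null(config$qmatrix))
    gt <- stage("clusters",
                assign_clusters(gt, utils::read.csv(config$qmatrix)))

  filt <- stage("filter", {
    spec <- do.call(filter_spec, as.list(config$filters))
    res <- apply_locus_filters(gt, spec)
    res$gt <- ld_prune(res$gt, spec$ld_r2_max)
    write_filter_report(res$report, file.path(out, "filter_report.json"))
    res
  })
  gt_f <- filt$gt

  stage("diversity", {
    div <- diversity_metrics(gt_f, by_cluster = !is.null(gt_f$samples$cluster),
                             n_boot = 200, seed = seed)
    utils::write.csv(div, file.path(out, "diversity.csv"), row.names = FALSE)
  })

  rel <- stage("relatedness", {
    A <- yang_relatedness(gt_f)
    utils::write.csv(as.data.frame(unclass(A)),
                     file.path(out, "relatedness.csv"))
    D <- geographic_distance_matrix(gt_f)
    ac <- spatial_autocorrelogram(A, D, n_perm = 99, seed = seed)
    utils::write.csv(as.data.frame(ac), file.path(out, "autocorrelogram.csv"),
                     row.names = FALSE)
    A
  })

  dist_list <- NULL
  if (!is.null(config$rasters)) {
    dist_list <- stage("resistance", {
      modes <- c(habitat = "habitat", forest = "invert", elevation = "raw",
                 roughness = "raw", climate = "raw")
      dl <- list()
      for (nm in names(config$rasters)) {
        r <- read_ascii_grid(config$rasters[[nm]])
        mode <- if (nm %in% names(modes)) modes[[nm]] else "raw"
        surf <- build_resistance_surface(r, mode, points = gt_f$samples,
                                         provenance = nm)
        dl[[nm]] <- pairwise_circuit_resistance(surf, gt_f$samples)
      }
      null_surf <- build_resistance_surface(read_ascii_grid(config$rasters[[1]]),
                                            "null", points = gt_f$samples,
                                            provenance = "geographic_null")
      dl$geographic_null <- pairwise_circuit_resistance(null_surf, gt_f$samples)
      dl
    })
    stage("ibr", {
      pt <- build_pair_table(rel, dist_list, gt_f$samples)
      nested <- !isFALSE(config$ibr$nested)
      rmax <- if (is.null(config$ibr$collinearity_rmax)) 0.6
              else config$ibr$collinearity_rmax
      # selection on the plain MLPE structure; the best model is refitted
      # with the nested structure for final estimates
      sel <- all_subsets_selection(pt, collinearity_rmax = rmax,
                                   nested = FALSE)
      utils::write.csv(as.data.frame(sel), file.path(out, "model_selection.csv"),
                       row.names = FALSE)
      best <- if (nested && sel$model[1] != "(intercept)")
        mlpe(stats::reformulate(strsplit(sel$model[1], " \\+ ")[[1]],
                                response = "relatedness"),
             pt, nested = TRUE)
      else attr(sel, "fits")[[1]]
      est <- summary(best)$coefficients
      utils::write.csv(cbind(term = rownames(est), as.data.frame(est)),
                       file.path(out, "best_model_estimates.csv"),
                       row.names = FALSE)
    })
  }

  if (!is.null(config$scan)) {
    stage("scan", {
      k <- if (is.null(config$scan$k)) 2L else as.integer(config$scan$k)
      q <- if (is.null(config$scan$q)) 0.05 else config$scan$q
      env <- config$scan$env
      stopifnot(length(env) == nrow(gt$dosages))
      ks <- unique(pmax(0, c(k - 1, k, k + 1)))
      scans <- lapply(ks, function(kk)
        latent_factor_scan(gt, env, k = kk, q = q))
      cand <- intersect_candidates(scans)
      utils::write.csv(as.data.frame(scans[[which(ks == k)]]),
                       file.path(out, "scan_k.csv"), row.names = FALSE)
      jsonlite::write_json(
        list(k_values = ks,
             flagged_per_k = vapply(scans, function(s) sum(s$flagged), 0),
             shared_candidates = cand),
        file.path(out, "scan_candidates.json"), auto_unbox = TRUE, digits = NA)
    })
  }

  log$finished <- format(Sys.time())
  jsonlite::write_json(log, file.path(out, "pipeline_log.json"),
                       auto_unbox = TRUE)
  invisible(out)
}
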