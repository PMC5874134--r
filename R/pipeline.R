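## Configuration-driven orchestration of the full analysis, from NIfTI
## files or a synthetic spec to TSV/JSON outputs plus a run manifest.

#' Validate a pipeline configuration
#'
#' @param mode "synthetic" (generate from \code{spec}) or "files" (read
#'   \code{boldPath}/\code{labelPath}).
#' @param spec a \linkS4class{SyntheticSpec} (synthetic mode).
#' @param boldPath,labelPath,maskPath NIfTI paths (files mode).
#' @param detrend apply linear detrending (default TRUE).
#' @param powerFilterFraction low-power exclusion fraction in (0, 1), or
#'   NULL to skip the filter; applied after detrending.
#' @param smoothingFwhmMm numeric vector of smoothing kernels in mm; 0
#'   means unsmoothed. The first entry is the variant carried through the
#'   pair-table and network stages; every entry gets its own consistency
#'   table.
#' @param densities link-density grid for the network stage.
#' @param nBins bin count for size/relation binning.
#' @param nPermutations permutations for the within/between test.
#' @param pairCap between-ROI pair budget for the pooled distributions.
#' @param seed master seed for every random draw in the run.
#' @param outputDir directory for all outputs (created if needed).
#' @return A validated config (class \code{PipelineConfig}).
#' @export
pipelineConfig <- function(mode = c("synthetic", "files"), spec = NULL,
                           boldPath = NULL, labelPath = NULL,
                           maskPath = NULL, detrend = TRUE,
                           powerFilterFraction = 0.02,
                           smoothingFwhmMm = 0,
                           densities = defaultDensityGrid(), nBins = 10,
                           nPermutations = 10000, pairCap = 1e7,
                           seed = 1L, outputDir) {
  mode <- match.arg(mode)
  if (mode == "synthetic") {
    if (!is(spec, "SyntheticSpec"))
      stop("synthetic mode requires a SyntheticSpec")
    validObject(spec)
  } else {
    if (is.null(boldPath) || is.null(labelPath))
      stop("files mode requires boldPath and labelPath")
    if (!file.exists(boldPath)) stop("boldPath does not exist")
    if (!file.exists(labelPath)) stop("labelPath does not exist")
  }
  if (!is.null(powerFilterFraction) &&
      (powerFilterFraction <= 0 || powerFilterFraction >= 1))
    stop("powerFilterFraction must be in (0, 1) or NULL")
  if (any(smoothingFwhmMm < 0)) stop("smoothing FWHM must be nonnegative")
  if (any(densities <= 0 | densities > 1))
    stop("densities must lie in (0, 1]")
  if (missing(outputDir)) stop("outputDir is required")
  cfg <- list(mode = mode, spec = spec, boldPath = boldPath,
              labelPath = labelPath, maskPath = maskPath,
              detrend = isTRUE(detrend),
              powerFilterFraction = powerFilterFraction,
              smoothingFwhmMm = as.numeric(smoothingFwhmMm),
              densities = as.numeric(densities), nBins = as.integer(nBins),
              nPermutations = as.integer(nPermutations),
              pairCap = as.numeric(pairCap), seed = as.integer(seed),
              outputDir = outputDir)
  class(cfg) <- "PipelineConfig"
  cfg
}

.writeTsv <- function(df, dir, name) {
  path <- file.path(dir, name)
  write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages: read or generate -> detrend -> low-power filter -> (per-FWHM
#' smoothing variants) -> ROI averaging -> consistency, within/between
#' distributions with the permutation test, size binning -> pair table
#' with identity-bound check -> adjacency, thresholding, and the
#' consistency-centrality relation. All tabular outputs are written as
#' TSV, summaries as JSON, and a run manifest (configuration, seed,
#' package version, warnings, per-stage timings) as manifest.json.
#'
#' The pair-table and network stages run on the first smoothing variant
#' (FWHM \code{smoothingFwhmMm[1]}, default unsmoothed); additional FWHM
#' values yield parallel consistency tables.
#'
#' @param config a config from \code{\link{pipelineConfig}}.
#' @return Invisibly, a report list with every in-memory result and the
#'   paths of all files written.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  out <- config$outputDir
  warningsLog <- character()
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)),
      warning = function(w) {
        warningsLog <<- c(warningsLog,
                          sprintf("[%s] %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  files <- list()

  ## --- input -------------------------------------------------------------
  if (config$mode == "synthetic") {
    parc <- stage("generate", generateParcellation(config$spec))
    vts <- stage("generate", generateVoxelTimeSeries(config$spec, parc))
  } else {
    vts <- stage("read", readVoxelTimeSeries(config$boldPath,
                                             config$maskPath))
    parc <- stage("read", readParcellation(config$labelPath, image = vts))
  }

  ## --- preprocessing ------------------------------------------------------
  if (config$detrend) vts <- stage("detrend", detrendLinear(vts))
  if (!is.null(config$powerFilterFraction)) {
    flt <- stage("power_filter",
                 filterLowPowerVoxels(vts, config$powerFilterFraction))
    vts <- flt$vts
    files$removed_voxels <- .writeTsv(flt$report, out, "removed_voxels.tsv")
    parc <- stage("power_filter", {
      lab <- parc@labels
      if (nrow(flt$report))
        lab[as.matrix(flt$report[, c("x", "y", "z")]) + 1L] <- 0L
      Parcellation(lab, roiNames = parc@roiNames)
    })
  }

  ## --- per-FWHM consistency variants --------------------------------------
  fwhms <- config$smoothingFwhmMm
  variants <- lapply(fwhms, function(f)
    stage(sprintf("smooth_fwhm%g", f),
          smoothSpatial(vts, smoothingKernel(f))))
  consistencyTables <- list()
  for (k in seq_along(fwhms)) {
    ct <- stage(sprintf("consistency_fwhm%g", fwhms[k]),
                roiConsistency(variants[[k]], parc))
    consistencyTables[[k]] <- ct
    files[[sprintf("consistency_fwhm%g", fwhms[k])]] <-
      .writeTsv(ct, out, sprintf("consistency_fwhm%g.tsv", fwhms[k]))
  }
  vts1 <- variants[[1L]]
  cons <- consistencyTables[[1L]]

  ## --- distributions and size binning -------------------------------------
  dist <- stage("distributions",
                withinBetweenDistributions(
                  vts1, parc, pairCap = config$pairCap,
                  nPermutations = config$nPermutations,
                  seed = config$seed))
  jsonlite::write_json(
    dist[c("within_mean", "between_mean", "t_statistic", "p_value",
           "n_permutations")],
    file.path(out, "distribution_summary.json"), auto_unbox = TRUE,
    digits = NA)
  files$distribution_summary <- file.path(out, "distribution_summary.json")
  sizeBin <- stage("size_binning", consistencyVsSize(cons, config$nBins))
  files$consistency_vs_size <-
    .writeTsv(sizeBin$binned, out, "consistency_vs_size.tsv")

  ## --- pair table and bound check ------------------------------------------
  rts <- stage("roi_average", roiAverage(vts1, parc))
  files$roi_timeseries <- writeRoiTimeSeries(
    rts, file.path(out, "roi_timeseries.tsv"))
  pairs <- stage("pair_table", buildPairTable(vts1, rts, parc, cons))
  files$pair_table <- .writeTsv(pairs, out, "pair_table.tsv")
  jsonlite::write_json(
    attr(pairs, "correlations"),
    file.path(out, "pair_summary.json"), auto_unbox = TRUE, digits = NA)
  files$pair_summary <- file.path(out, "pair_summary.json")
  violations <- stage("bound_check", identityBoundCheck(pairs))
  files$bound_violations <- .writeTsv(violations, out,
                                      "bound_violations.tsv")

  ## --- network stage -------------------------------------------------------
  A <- stage("adjacency", buildAdjacency(rts))
  rel <- stage("centrality",
               consistencyCentralityRelation(cons, A, config$densities,
                                             config$nBins))
  files$centrality_correlations <-
    .writeTsv(rel$correlations, out, "centrality_correlations.tsv")
  files$centrality_binned <-
    .writeTsv(rel$binned, out, "centrality_binned.tsv")
  nodeMetrics <- do.call(rbind, lapply(config$densities, function(d) {
    ds <- degreeAndStrength(thresholdToDensity(A, d))
    cbind(density = d, ds)
  }))
  files$node_metrics <- .writeTsv(nodeMetrics, out, "node_metrics.tsv")
  files$edges <- writeEdgeList(
    thresholdToDensity(A, max(config$densities)),
    file.path(out, "edges_max_density.tsv"))

  ## --- manifest -------------------------------------------------------------
  cfgSer <- config
  cfgSer$spec <- if (is.null(config$spec)) NULL else
    list(roi_sizes = config$spec@roiSizes,
         n_timepoints = config$spec@nTimepoints,
         shared_fraction = config$spec@sharedFraction,
         global_fraction = config$spec@globalFraction,
         latent_correlation = config$spec@latentCorrelation,
         seed = config$spec@seed, grid_shape = config$spec@gridShape,
         ar = config$spec@ar, voxel_size_mm = config$spec@voxelSizeMm)
  manifest <- list(config = unclass(cfgSer), seed = config$seed,
                   package_version = as.character(packageVersion(
                     "ROIconsistency")),
                   r_version = R.version.string,
                   warnings = warningsLog, timings = timings)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  files$manifest <- file.path(out, "manifest.json")

  invisible(list(vts = vts1, parcellation = parc, rts = rts,
                 consistency = consistencyTables, distributions = dist,
                 size_binning = sizeBin, pair_table = pairs,
                 bound_violations = violations, adjacency = A,
                 centrality = rel, node_metrics = nodeMetrics,
                 warnings = warningsLog, files = files))
}

#' Pool per-subject consistency tables
#'
#' Concatenates per-subject records (for pooled distributions and size
#' binning) and also reports the per-ROI mean and standard deviation of
#' phi across subjects (for maps and tables).
#'
#' @param tables list of data frames from \code{\link{roiConsistency}},
#'   one per subject; names are used as subject ids when present.
#' @return A list: records (concatenated rows with subject_id) and
#'   perRoi (data frame roi_id, size, mean_phi, sd_phi, n_subjects).
#' @export
poolConsistency <- function(tables) {
  if (!length(tables)) stop("no tables to pool")
  ids <- names(tables)
  if (is.null(ids)) ids <- as.character(seq_along(tables))
  records <- do.call(rbind, lapply(seq_along(tables), function(k) {
    df <- tables[[k]]
    df$subject_id <- ids[k]
    df
  }))
  sp <- split(records, records$roi_id)
  perRoi <- do.call(rbind, lapply(sp, function(df) {
    ph <- df$phi[!is.na(df$phi)]
    data.frame(roi_id = df$roi_id[1L], size = df$size[1L],
               mean_phi = if (length(ph)) mean(ph) else NA_real_,
               sd_phi = if (length(ph) > 1) sd(ph) else NA_real_,
               n_subjects = length(ph))
  }))
  perRoi <- perRoi[order(perRoi$roi_id), ]
  rownames(perRoi) <- NULL
  list(records = records, perRoi = perRoi)
}
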