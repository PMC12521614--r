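#' Default pipeline configuration
#'
#' @param scan_table Path to the scan measurement table (or NULL when
#'   \code{scans} objects are passed to [runPipeline()] directly).
#' @param conservation_table,prediction_table,property_scales Optional
#'   paths (the last a named character vector of scale files).
#' @param n_bins Primary histogram bin count.
#' @param bin_range Length-2 integer vector, the bin-sweep range.
#' @param exclusion_threshold Undetectable-expression cutoff, percent of
#'   wild type (strict less-than).
#' @param neutral_threshold,toggle_threshold,rheostat_threshold Class
#'   cutoffs.
#' @param z_equiv z quantile for the neutral equivalence window.
#' @param seed Seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @param output_dir Where [runPipeline()] writes its tables.
#' @return A named list, the \code{config} argument of [runPipeline()].
#' @export
runConfig <- function(scan_table = NULL, conservation_table = NULL,
                      prediction_table = NULL, property_scales = NULL,
                      n_bins = 10, bin_range = c(5L, 11L),
                      exclusion_threshold = 1,
                      neutral_threshold = 0.70, toggle_threshold = 2 / 3,
                      rheostat_threshold = 0.5, z_equiv = 1.96,
                      seed = 1L, output_dir = tempfile("rheoscan_run_")) {
  stopifnot(n_bins >= 3, length(bin_range) == 2L,
            bin_range[[1]] <= bin_range[[2]],
            exclusion_threshold >= 0,
            neutral_threshold > 0, neutral_threshold <= 1,
            toggle_threshold > 0, toggle_threshold <= 1,
            rheostat_threshold > 0, rheostat_threshold <= 1)
  list(scan_table = scan_table, conservation_table = conservation_table,
       prediction_table = prediction_table,
       property_scales = property_scales, n_bins = n_bins,
       bin_range = bin_range, exclusion_threshold = exclusion_threshold,
       neutral_threshold = neutral_threshold,
       toggle_threshold = toggle_threshold,
       rheostat_threshold = rheostat_threshold, z_equiv = z_equiv,
       seed = seed, output_dir = output_dir)
}

#' Read a pipeline configuration file
#'
#' YAML file whose keys mirror the arguments of [runConfig()]; unknown
#' keys are rejected, missing keys take the defaults, and referenced input
#' files must exist.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated config list.
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(runConfig))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- do.call(runConfig, raw)
  for (f in c("scan_table", "conservation_table", "prediction_table")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("config references missing file: ", cfg[[f]], call. = FALSE)
  }
  for (f in cfg$property_scales) {
    if (!file.exists(f))
      stop("config references missing file: ", f, call. = FALSE)
  }
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full scan-analysis pipeline
#'
#' Orchestrates the stages end to end -- read, expression filter,
#' expression correction, RheoScale scoring with bin sweep, correlation
#' analyses -- and writes tidy CSV outputs plus a plain-text run manifest.
#' Rerunning with an identical configuration and inputs reproduces every
#' output bit for bit; any stage failure aborts with the stage name.
#'
#' Outputs written to \code{config$output_dir}:
#' \describe{
#'   \item{results.csv}{per-(variant, assay) measurements including
#'     corrected transport and exclusion flags, plus per-(position, assay)
#'     summary rows with scores and labels}
#'   \item{scores.csv}{the per-(position, assay) RheoScale table}
#'   \item{bin_sweep.csv}{scores and labels at every bin count in the
#'     sweep range}
#'   \item{correlations.csv}{conservation, concordance, trade-off and
#'     property-scale correlations (one row each)}
#'   \item{predictor_comparison.csv}{measured-vs-predicted band calls, if
#'     a prediction table was supplied}
#'   \item{manifest.txt}{configuration, package/R versions, record counts}
#' }
#'
#' @param config List from [runConfig()]/[readRunConfig()], or the path
#'   of a YAML config file.
#' @param scans Optional named list of \linkS4class{PositionScan} objects,
#'   bypassing \code{config$scan_table}.
#' @return Invisibly, a list with the in-memory results: \code{scans}
#'   (corrected), \code{scores}, \code{binSweep}, \code{correlations},
#'   \code{sensitivity}, \code{predictorComparison}, \code{outputDir}.
#' @export
runPipeline <- function(config, scans = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  scans <- .stage("read", {
    if (is.null(scans)) {
      if (is.null(config$scan_table))
        stop("no scan table configured and no scans supplied")
      readScanTable(config$scan_table)
    } else scans
  })
  message("read: ", length(scans), " position scan(s)")

  scans <- .stage("normalize", {
    lapply(scans, function(s) {
      hasS <- length(.keysOfKind(s, "surface_expression")) > 0L
      hasU <- length(.keysOfKind(s, "cellular_uptake")) > 0L
      if (hasS && hasU)
        correctForExpression(s, threshold = config$exclusion_threshold)
      else if (hasS)
        expressionFilter(s, threshold = config$exclusion_threshold)
      else s
    })
  })
  nExcluded <- vapply(scans, function(s)
    length(excludedSubstitutions(s)), integer(1))
  message("normalize: excluded ", sum(nExcluded),
          " substitution(s) with undetectable expression")

  binRange <- seq(config$bin_range[[1]], config$bin_range[[2]])
  scoreArgs <- list(nBins = config$n_bins, binRange = binRange,
                    zEquiv = config$z_equiv,
                    neutralThreshold = config$neutral_threshold,
                    toggleThreshold = config$toggle_threshold,
                    rheostatThreshold = config$rheostat_threshold)
  scores <- .stage("score", {
    do.call(rbind, lapply(scans, function(s)
      do.call(scoreScan, c(list(s), scoreArgs))))
  })
  rownames(scores) <- NULL
  sweep <- .stage("score", {
    do.call(rbind, lapply(scans, function(s)
      do.call(scanBinSweep, c(list(s), scoreArgs[-1L]))))
  })
  rownames(sweep) <- NULL
  message("score: ", nrow(scores), " (position, assay) result(s)")

  conservation <- NULL
  if (!is.null(config$conservation_table))
    conservation <- .stage("correlate",
                           readConservationTable(config$conservation_table))

  corrRows <- list()
  sensitivity <- NULL
  .stage("correlate", {
    if (!is.null(conservation) && length(scans) >= 3L) {
      averages <- do.call(rbind, lapply(scans, averageOutcomes))
      useScores <- scores[scores$kind %in%
        c("surface_expression", "corrected_transport"), , drop = FALSE]
      useAvg <- averages[averages$kind %in%
        c("surface_expression", "corrected_transport"), , drop = FALSE]
      sensitivity <- sensitivitySummary(useScores, useAvg, conservation)
      for (measure in c("summed_rheostat", "summed_average")) {
        r <- sensitivityVsConservation(sensitivity, measure)
        corrRows[[length(corrRows) + 1L]] <- data.frame(
          analysis = "sensitivity_vs_conservation", position = NA,
          detail = measure, method = "pearson",
          coefficient = r$coefficient, p_value = r$p_value, n = r$n)
      }
    }
    for (nm in names(scans)) {
      s <- scans[[nm]]
      cKeys <- .keysOfKind(s, "corrected_transport")
      if (length(cKeys) >= 2L) {
        cc <- substrateConcordance(s)
        corrRows[[length(corrRows) + 1L]] <- data.frame(
          analysis = "substrate_concordance", position = scanPosition(s),
          detail = paste(cc$substrate_a, "vs", cc$substrate_b),
          method = "spearman", coefficient = cc$coefficient,
          p_value = cc$p_value, n = cc$n)
      }
      if (length(cKeys) >= 1L &&
          length(.keysOfKind(s, "surface_expression")) >= 1L) {
        tr <- stabilityFunctionTradeoff(s)
        corrRows[[length(corrRows) + 1L]] <- data.frame(
          analysis = "stability_function_tradeoff",
          position = scanPosition(s), detail = tr$substrate,
          method = "spearman", coefficient = tr$coefficient,
          p_value = tr$p_value, n = tr$n)
      }
      for (scaleName in names(config$property_scales)) {
        scale <- readPropertyScale(config$property_scales[[scaleName]],
                                   name = scaleName)
        for (key in c(.keysOfKind(s, "surface_expression"), cKeys)) {
          keep <- !rowData(s)$is_wt & !rowData(s)$excluded
          outcomes <- setNames(assay(s, "mean")[keep, key],
                               rownames(s)[keep])
          pc <- propertyCorrelation(outcomes, scale)
          corrRows[[length(corrRows) + 1L]] <- data.frame(
            analysis = "property_correlation",
            position = scanPosition(s),
            detail = paste(scaleName, "vs", key), method = "spearman",
            coefficient = pc$coefficient, p_value = pc$p_value, n = pc$n)
        }
      }
    }
  })
  correlations <- if (length(corrRows)) do.call(rbind, corrRows) else NULL

  predCmp <- NULL
  if (!is.null(config$prediction_table)) {
    predCmp <- .stage("predictor_comparison", {
      predicted <- readPredictionTable(config$prediction_table)
      measured <- do.call(rbind, lapply(scans, function(s) {
        uk <- .keysOfKind(s, "cellular_uptake")
        if (!length(uk)) return(NULL)
        keep <- !rowData(s)$is_wt
        data.frame(position = scanPosition(s),
                   sub = rownames(s)[keep],
                   value = assay(s, "mean")[keep, uk[[1]]],
                   wt_sd = assay(s, "sd")[.wtRow(s), uk[[1]]])
      }))
      predictorBandComparison(measured, predicted,
                              wtSd = mean(measured$wt_sd))
    })
  }

  .stage("write", {
    out <- function(f) file.path(config$output_dir, f)
    writeResultsTable(scans, scores, out("results.csv"))
    write.csv(scores, out("scores.csv"), row.names = FALSE)
    write.csv(sweep, out("bin_sweep.csv"), row.names = FALSE)
    if (!is.null(correlations))
      write.csv(correlations, out("correlations.csv"), row.names = FALSE)
    if (!is.null(predCmp))
      write.csv(predCmp$calls, out("predictor_comparison.csv"),
                row.names = FALSE)
    manifest <- c(
      "rheoscan pipeline manifest",
      paste0("package_version: ", as.character(packageVersion("rheoscan"))),
      paste0("r_version: ", R.version.string),
      paste0("seed: ", config$seed),
      paste0("n_bins: ", config$n_bins),
      paste0("bin_range: ", paste(config$bin_range, collapse = "-")),
      paste0("exclusion_threshold: ", config$exclusion_threshold),
      paste0("thresholds: neutral ", config$neutral_threshold,
             ", toggle ", config$toggle_threshold,
             ", rheostat ", config$rheostat_threshold),
      paste0("positions: ", paste(vapply(scans, scanPosition, integer(1)),
                                  collapse = ", ")),
      paste0("excluded_substitutions: ", sum(nExcluded)),
      paste0("score_rows: ", nrow(scores)))
    writeLines(manifest, out("manifest.txt"))
  })
  message("write: outputs in ", config$output_dir)

  invisible(list(scans = scans, scores = scores, binSweep = sweep,
                 correlations = correlations, sensitivity = sensitivity,
                 predictorComparison = predCmp,
                 outputDir = config$output_dir))
}
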