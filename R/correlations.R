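#' Correlation between substitution outcomes and a residue property scale
#'
#' Spearman rank correlation between per-substitution outcome values and a
#' physicochemical property of the substituted side chain (hydrophobicity,
#' solvent-exposed surface area, helical propensity, ...).  Pairs are
#' dropped listwise when the variant is excluded/missing or the scale does
#' not cover the residue, and the number dropped is reported.  Ties are
#' handled by average ranks; the p-value is the asymptotic two-sided
#' approximation, adequate at the n of about 19 typical for a full scan
#' (use \code{exact = TRUE} for tiny n).
#'
#' @param outcomes Named numeric vector of per-substitution values (names
#'   are residue codes).
#' @param scale Named numeric vector from [readPropertyScale()], or any
#'   residue-named numeric vector.
#' @param method \code{"spearman"} (default) or \code{"pearson"}.
#' @param exact Compute the exact permutation p-value (Spearman only,
#'   no ties).
#' @return One-row data.frame: \code{scale}, \code{method},
#'   \code{coefficient}, \code{p_value}, \code{n}, \code{n_dropped},
#'   \code{computable}.  With fewer than 3 complete pairs or a
#'   zero-variance vector the result is flagged not computable.
#' @export
propertyCorrelation <- function(outcomes, scale, method = "spearman",
                                exact = FALSE) {
  method <- match.arg(method, c("spearman", "pearson"))
  scaleName <- attr(scale, "name", exact = TRUE)
  if (is.null(scaleName)) scaleName <- NA_character_
  common <- intersect(names(outcomes), names(scale))
  x <- outcomes[common]; y <- scale[common]
  ok <- !is.na(x) & !is.na(y)
  nDropped <- length(outcomes) - sum(ok)
  x <- x[ok]; y <- y[ok]
  notComputable <- function() data.frame(
    scale = scaleName, method = method, coefficient = NA_real_,
    p_value = NA_real_, n = length(x), n_dropped = nDropped,
    computable = FALSE)
  if (length(x) < 3L || sd(x) == 0 || sd(y) == 0) return(notComputable())
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = exact))
  data.frame(scale = scaleName, method = method,
             coefficient = unname(ct$estimate), p_value = ct$p.value,
             n = length(x), n_dropped = nDropped, computable = TRUE)
}

#' Rank concordance of corrected transport across substrates
#'
#' If a position's substitutions keep the same rank order for two
#' substrates, substrate specificity is unchanged; a scrambled rank order
#' means specificity is altered.  Computes the Spearman correlation for
#' every unordered substrate pair over the shared, non-excluded
#' substitutions.
#'
#' @param scan A \linkS4class{PositionScan} with at least two channels of
#'   \code{kind}.
#' @param kind Assay kind to compare (default corrected transport).
#' @param exact Passed to [propertyCorrelation()]'s correlation machinery.
#' @return data.frame with one row per pair: \code{substrate_a},
#'   \code{substrate_b}, \code{coefficient}, \code{p_value}, \code{n},
#'   \code{computable}.
#' @export
substrateConcordance <- function(scan, kind = "corrected_transport",
                                 exact = FALSE) {
  keys <- .keysOfKind(scan, kind)
  if (length(keys) < 2L)
    stop("need at least two '", kind, "' channels for concordance",
         call. = FALSE)
  subsOnly <- !rowData(scan)$is_wt & !rowData(scan)$excluded
  pairs <- combn(keys, 2L, simplify = FALSE)
  rows <- lapply(pairs, function(p) {
    a <- assay(scan, "mean")[subsOnly, p[[1]]]
    b <- assay(scan, "mean")[subsOnly, p[[2]]]
    ok <- !is.na(a) & !is.na(b)
    res <- if (sum(ok) >= 3L && sd(a[ok]) > 0 && sd(b[ok]) > 0) {
      ct <- suppressWarnings(cor.test(a[ok], b[ok], method = "spearman",
                                      exact = exact))
      data.frame(coefficient = unname(ct$estimate), p_value = ct$p.value,
                 computable = TRUE)
    } else {
      data.frame(coefficient = NA_real_, p_value = NA_real_,
                 computable = FALSE)
    }
    cbind(data.frame(substrate_a = colData(scan)[p[[1]], "substrate"],
                     substrate_b = colData(scan)[p[[2]], "substrate"],
                     n = sum(ok)), res)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-position substitution-sensitivity summary
#'
#' Sums each position's per-parameter rheostat scores and per-parameter
#' average outcomes (see [averageOutcomes()]) and attaches the
#' conservation score, producing the per-position table that
#' [sensitivityVsConservation()] consumes.
#'
#' @param scores data.frame from [scoreScan()] (rows for several positions
#'   can be concatenated), typically restricted to the parameters of
#'   interest before calling.
#' @param averages data.frame from [averageOutcomes()], same positions.
#' @param conservation data.frame from [readConservationTable()].
#' @return data.frame with one row per position: \code{position},
#'   \code{summed_rheostat}, \code{summed_average}, \code{conservation},
#'   \code{n_parameters}.
#' @export
sensitivitySummary <- function(scores, averages, conservation) {
  pos <- sort(unique(scores$position))
  out <- do.call(rbind, lapply(pos, function(p) {
    sc <- scores[scores$position == p & scores$scorable, , drop = FALSE]
    av <- averages[averages$position == p, , drop = FALSE]
    data.frame(position = p,
               summed_rheostat = sum(sc$rheostat_score),
               summed_average = sum(av$average, na.rm = TRUE),
               conservation = conservation$score[
                 match(p, conservation$position)],
               n_parameters = nrow(sc))
  }))
  rownames(out) <- NULL
  out
}

#' Correlate summed substitution sensitivity with conservation
#'
#' Pearson correlation (with two-sided p-value) between a per-position
#' sensitivity summary -- summed rheostat scores, or summed average
#' outcomes -- and the positions' evolutionary conservation grades.
#'
#' @param summary data.frame from [sensitivitySummary()].
#' @param measure \code{"summed_rheostat"} (default) or
#'   \code{"summed_average"}.
#' @return One-row data.frame: \code{measure}, \code{coefficient},
#'   \code{p_value}, \code{n}, \code{computable}.
#' @export
sensitivityVsConservation <- function(summary,
                                      measure = c("summed_rheostat",
                                                  "summed_average")) {
  measure <- match.arg(measure)
  x <- summary[[measure]]
  y <- summary$conservation
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L || sd(x[ok]) == 0 || sd(y[ok]) == 0)
    return(data.frame(measure = measure, coefficient = NA_real_,
                      p_value = NA_real_, n = sum(ok), computable = FALSE))
  ct <- cor.test(x[ok], y[ok], method = "pearson")
  data.frame(measure = measure, coefficient = unname(ct$estimate),
             p_value = ct$p.value, n = sum(ok), computable = TRUE)
}

#' Stability/function trade-off check for one position
#'
#' Spearman correlation between surface expression and expression-corrected
#' transport across a position's non-excluded substitutions.  A strong
#' negative correlation is the classic stability/function trade-off;
#' absence of correlation indicates that expression and transport are
#' modulated by different biophysical parameters.
#'
#' @param scan A \linkS4class{PositionScan} with surface-expression and
#'   corrected-transport channels (run [correctForExpression()] first).
#' @param substrate Substrate of the corrected-transport channel to use;
#'   default: the first corrected channel.
#' @param exact Exact permutation p-value.
#' @return One-row data.frame as for [propertyCorrelation()].
#' @export
stabilityFunctionTradeoff <- function(scan, substrate = NULL,
                                      exact = FALSE) {
  sKey <- .keysOfKind(scan, "surface_expression")
  cKeys <- .keysOfKind(scan, "corrected_transport", substrate)
  if (!length(sKey) || !length(cKeys))
    stop("need surface-expression and corrected-transport channels ",
         "(run correctForExpression() first)", call. = FALSE)
  keep <- !rowData(scan)$is_wt & !rowData(scan)$excluded
  expr <- setNames(assay(scan, "mean")[keep, sKey[[1]]],
                   rownames(scan)[keep])
  trans <- setNames(assay(scan, "mean")[keep, cKeys[[1]]],
                    rownames(scan)[keep])
  out <- propertyCorrelation(expr, trans, method = "spearman",
                             exact = exact)
  out$scale <- colData(scan)[cKeys[[1]], "substrate"]
  names(out)[names(out) == "scale"] <- "substrate"
  out
}

#' Compare measured phenotypes with predictor pathogenicity bands
#'
#' Assigns each shared variant a measured band -- \emph{benign-consistent}
#' when the measured value lies inside the wild-type range,
#' \emph{pathogenic-consistent} when below it -- and a predicted band from
#' the predictor score (likely benign at or below \code{benign_max},
#' likely pathogenic at or above \code{pathogenic_min}, ambiguous in
#' between; ambiguous predictions attempt no call and are excluded from
#' the discordance denominator).  A likely-benign prediction is concordant
#' only when the measurement falls inside the wild-type range; a
#' likely-pathogenic prediction only when the measurement falls below it.
#'
#' @param measured data.frame with columns \code{position}, \code{sub},
#'   \code{value} (cellular uptake, percent of wild type).
#' @param predicted data.frame from [readPredictionTable()].
#' @param wtRange Length-2 numeric, the measured wild-type range (the
#'   "gray box"); defaults to WT mean +/- SD, i.e. \code{c(100 - wtSd,
#'   100 + wtSd)}.
#' @param wtSd Wild-type measurement SD used for the default range.
#' @return A list with \code{calls} (per-variant data.frame with measured
#'   and predicted bands and concordance) and \code{summary} (counts of
#'   concordant, discordant and ambiguous calls, and the discordance rate
#'   over non-ambiguous calls).
#' @export
predictorBandComparison <- function(measured, predicted, wtRange = NULL,
                                    wtSd = 10) {
  if (is.null(wtRange)) wtRange <- c(100 - wtSd, 100 + wtSd)
  stopifnot(length(wtRange) == 2L, wtRange[[1]] < wtRange[[2]])
  bmax <- attr(predicted, "benign_max")
  pmin_ <- attr(predicted, "pathogenic_min")
  if (is.null(bmax) || is.null(pmin_))
    stop("prediction table lacks band cutoffs; read it with ",
         "readPredictionTable()", call. = FALSE)
  m <- merge(measured, predicted, by = c("position", "sub"))
  if (!nrow(m))
    stop("measured and predicted variant sets do not overlap",
         call. = FALSE)
  m$measured_band <- ifelse(m$value < wtRange[[1]], "pathogenic_consistent",
                     ifelse(m$value <= wtRange[[2]], "benign_consistent",
                            "above_wt_range"))
  m$predicted_band <- ifelse(m$score <= bmax, "likely_benign",
                      ifelse(m$score >= pmin_, "likely_pathogenic",
                             "ambiguous"))
  m$concordant <- ifelse(m$predicted_band == "ambiguous", NA,
    (m$predicted_band == "likely_benign" &
       m$measured_band == "benign_consistent") |
    (m$predicted_band == "likely_pathogenic" &
       m$measured_band == "pathogenic_consistent"))
  nAmb <- sum(is.na(m$concordant))
  nCon <- sum(m$concordant, na.rm = TRUE)
  nDis <- sum(!m$concordant, na.rm = TRUE)
  list(calls = m,
       summary = data.frame(
         n = nrow(m), concordant = nCon, discordant = nDis,
         ambiguous = nAmb,
         discordance_rate = if (nCon + nDis) nDis / (nCon + nDis)
                            else NA_real_))
}
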