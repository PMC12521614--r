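#' Build the outcome histogram for one set of substitution values
#'
#' The functional range runs from the dead value (no detectable activity,
#' default 0) to the larger of the observed maximum and the wild-type
#' value, so that enhanced (>WT) substitutions populate bins beyond wild
#' type.  The range is partitioned into \code{nBins} half-open intervals
#' \code{[a, b)}, the last bin closed.  Values below the dead value
#' (background over-subtraction) are clamped to it before binning.  One bin
#' contains the wild-type value, one the dead value.
#'
#' @param values Numeric substitution means (percent of wild type).
#' @param nBins Number of bins (>= 3); scores in the source analyses are
#'   conventionally computed at 10 bins.
#' @param wtValue Wild-type reference value (100 on the percent scale).
#' @param deadValue Value representing no activity/expression.
#' @return A list with elements \code{nBins}, \code{edges}, \code{width},
#'   \code{domain}, \code{assignments} (bin index per value),
#'   \code{counts}, \code{wtBin} and \code{deadBin}.
#' @examples
#' h <- buildHistogram(seq(5, 95, by = 10), nBins = 10)
#' h$edges    # multiples of 10 up to 100
#' @export
buildHistogram <- function(values, nBins = 10, wtValue = 100,
                           deadValue = 0) {
  if (length(values) < 1L || all(is.na(values)))
    stop("no scorable values (all substitutions excluded or missing)",
         call. = FALSE)
  if (nBins < 3L) stop("nBins must be at least 3", call. = FALSE)
  values <- values[!is.na(values)]
  v <- pmax(values, deadValue)
  lo <- deadValue
  hi <- max(v, wtValue)
  if (hi <= lo)
    stop("degenerate histogram domain: all values at the dead value and ",
         "wtValue <= deadValue", call. = FALSE)
  width <- (hi - lo) / nBins
  binOf <- function(x) as.integer(pmin(floor((x - lo) / width) + 1, nBins))
  list(nBins = as.integer(nBins),
       edges = seq(lo, hi, length.out = nBins + 1L),
       width = width,
       domain = c(lo, hi),
       assignments = binOf(v),
       counts = tabulate(binOf(v), nbins = nBins),
       wtBin = binOf(wtValue),
       deadBin = binOf(deadValue))
}

#' Rheostat score: fraction of histogram bins populated
#'
#' The number of distinct bins sampled by a position's substitutions,
#' divided by the total bin count.  The wild-type and dead bins count in
#' both numerator (when populated) and denominator, so a position whose
#' substitutions sample every possible outcome scores exactly 1.
#'
#' @param x A histogram from [buildHistogram()], or a
#'   \linkS4class{RheoScaleResult} (accessor).
#' @param ... Unused.
#' @return Fraction in (0, 1].
#' @rdname RheoScaleResult-accessors
#' @export
setMethod("rheostatScore", "list", function(x, ...) {
  length(unique(x$assignments)) / x$nBins
})

# substitutions indistinguishable from wild type: in the WT bin, or (when
# replicate SDs are available) within a two-sample z window of the WT mean
.neutralMask <- function(values, hist, wtValue, sds = NULL, ns = NULL,
                         wtSd = 0, wtN = NA_real_, zEquiv = 1.96) {
  mask <- hist$assignments == hist$wtBin
  if (!is.null(sds) && !all(is.na(sds))) {
    ns <- if (is.null(ns)) rep(1, length(sds)) else ns
    wtVar <- if (is.na(wtSd) || is.na(wtN) || wtN < 1) 0 else wtSd^2 / wtN
    win <- zEquiv * sqrt(sds^2 / ns + wtVar)
    equiv <- !is.na(win) & abs(values - wtValue) <= win
    mask <- mask | equiv
  }
  mask
}

#' Classify a position from its fractions and rheostat score
#'
#' Deterministic precedence: \emph{neutral} when at least
#' \code{neutralThreshold} (default 70\%) of the substitutions are
#' indistinguishable from wild type; else \emph{toggle} when at least
#' \code{toggleThreshold} (default two thirds) fall in the dead bin; else
#' \emph{rheostat} when at least half of the accessible range is sampled
#' (rheostat score >= \code{rheostatThreshold}); everything else is a
#' \emph{moderate rheostat} -- mostly non-neutral substitutions confined to
#' less than half the range.
#'
#' @param neutralFraction,toggleFraction,rheostatScore Scores for one
#'   (position, assay).
#' @param neutralThreshold,toggleThreshold,rheostatThreshold Class cutoffs.
#' @return One of \code{"neutral"}, \code{"toggle"}, \code{"rheostat"},
#'   \code{"moderate_rheostat"}.
#' @examples
#' classifyPosition(14/19, 0, 0.3)   # neutral
#' classifyPosition(0, 13/19, 0.1)   # toggle
#' @export
classifyPosition <- function(neutralFraction, toggleFraction, rheostatScore,
                             neutralThreshold = 0.70,
                             toggleThreshold = 2 / 3,
                             rheostatThreshold = 0.5) {
  if (neutralFraction >= neutralThreshold) "neutral"
  else if (toggleFraction >= toggleThreshold) "toggle"
  else if (rheostatScore >= rheostatThreshold) "rheostat"
  else "moderate_rheostat"
}

.scoreAt <- function(values, nBins, wtValue, deadValue, sds, ns, wtSd, wtN,
                     zEquiv, neutralThreshold, toggleThreshold,
                     rheostatThreshold) {
  h <- buildHistogram(values, nBins = nBins, wtValue = wtValue,
                      deadValue = deadValue)
  rs <- rheostatScore(h)
  nf <- mean(.neutralMask(values, h, wtValue, sds, ns, wtSd, wtN, zEquiv))
  tf <- mean(h$assignments == h$deadBin & !.neutralMask(values, h, wtValue,
             sds, ns, wtSd, wtN, zEquiv))
  list(histogram = h, rheostat_score = rs, neutral_fraction = nf,
       toggle_fraction = tf,
       label = classifyPosition(nf, tf, rs, neutralThreshold,
                                toggleThreshold, rheostatThreshold))
}

#' Sweep the histogram bin count and report label stability
#'
#' Recomputes scores and the class label at every bin count in
#' \code{binRange} (default 5 to 11).  A classification that does not
#' depend on the bin count is evidence that the label reflects the data
#' rather than the histogram discretization.
#'
#' @inheritParams rheoScale
#' @return data.frame with one row per bin count: \code{n_bins},
#'   \code{rheostat_score}, \code{neutral_fraction},
#'   \code{toggle_fraction}, \code{label}, plus attribute \code{stable}.
#' @export
binSweep <- function(values, sds = NULL, ns = NULL, wtValue = 100,
                     deadValue = 0, wtSd = 0, wtN = NA_real_,
                     binRange = 5:11, zEquiv = 1.96,
                     neutralThreshold = 0.70, toggleThreshold = 2 / 3,
                     rheostatThreshold = 0.5) {
  keep <- !is.na(values)
  values <- values[keep]
  if (!is.null(sds)) sds <- sds[keep]
  if (!is.null(ns)) ns <- ns[keep]
  rows <- lapply(binRange, function(nb) {
    s <- .scoreAt(values, nb, wtValue, deadValue, sds, ns, wtSd, wtN,
                  zEquiv, neutralThreshold, toggleThreshold,
                  rheostatThreshold)
    data.frame(n_bins = nb, rheostat_score = s$rheostat_score,
               neutral_fraction = s$neutral_fraction,
               toggle_fraction = s$toggle_fraction, label = s$label)
  })
  out <- do.call(rbind, rows)
  attr(out, "stable") <- length(unique(out$label)) == 1L
  out
}

#' Score one set of substitution outcomes
#'
#' Builds the outcome histogram, computes the rheostat score and the
#' neutral and toggle fractions, assigns the class label and runs the
#' bin-count sweep.  Means are binned; replicate SDs, when supplied, only
#' refine the neutral test (a substitution whose mean is statistically
#' indistinguishable from the wild-type mean by a two-sample z criterion
#' counts as neutral even when batch-to-batch drift pushes it out of the
#' bin containing the wild-type value).
#'
#' @param values Substitution means for one assay, percent-of-WT scale.
#'   Excluded substitutions must already be removed (transport assays) or
#'   set to the dead value (surface expression).
#' @param sds,ns Optional replicate SDs and counts matching \code{values}.
#' @param wtValue,deadValue Histogram anchors (defaults 100 and 0).
#' @param wtSd,wtN Wild-type measurement SD and replicate count, used by
#'   the neutral equivalence test.
#' @param nBins Primary bin count for the reported scores.
#' @param binRange Bin counts for the stability sweep.
#' @param zEquiv z quantile of the neutral equivalence window (1.96 for a
#'   95\% two-sided criterion).
#' @param neutralThreshold,toggleThreshold,rheostatThreshold Class cutoffs,
#'   see [classifyPosition()].
#' @return A \linkS4class{RheoScaleResult}.
#' @examples
#' res <- rheoScale(seq(2.5, 132.5, length.out = 19))
#' rheostatScore(res); classLabel(res)
#' @export
rheoScale <- function(values, sds = NULL, ns = NULL, wtValue = 100,
                      deadValue = 0, wtSd = 0, wtN = NA_real_, nBins = 10,
                      binRange = 5:11, zEquiv = 1.96,
                      neutralThreshold = 0.70, toggleThreshold = 2 / 3,
                      rheostatThreshold = 0.5) {
  keep <- !is.na(values)
  values <- values[keep]
  if (!is.null(sds)) sds <- sds[keep]
  if (!is.null(ns)) ns <- ns[keep]
  if (length(values) == 0L) {
    return(new("RheoScaleResult", values = numeric(), nBins = as.integer(nBins),
               histogram = list(), rheostatScore = NA_real_,
               neutralFraction = NA_real_, toggleFraction = NA_real_,
               nUsed = 0L, label = NA_character_,
               binSweep = data.frame(), binSweepStable = NA,
               scorable = FALSE))
  }
  s <- .scoreAt(values, nBins, wtValue, deadValue, sds, ns, wtSd, wtN,
                zEquiv, neutralThreshold, toggleThreshold,
                rheostatThreshold)
  sweep <- binSweep(values, sds, ns, wtValue, deadValue, wtSd, wtN,
                    binRange, zEquiv, neutralThreshold, toggleThreshold,
                    rheostatThreshold)
  new("RheoScaleResult", values = values, nBins = as.integer(nBins),
      histogram = s$histogram, rheostatScore = s$rheostat_score,
      neutralFraction = s$neutral_fraction,
      toggleFraction = s$toggle_fraction, nUsed = length(values),
      label = s$label, binSweep = sweep,
      binSweepStable = attr(sweep, "stable"), scorable = TRUE)
}

#' @rdname RheoScaleResult-accessors
#' @export
setMethod("rheostatScore", "RheoScaleResult", function(x, ...) x@rheostatScore)

#' Accessors for RheoScaleResult objects
#'
#' @param x A \linkS4class{RheoScaleResult} (for \code{rheostatScore},
#'   alternatively a histogram list from [buildHistogram()], for which the
#'   score is computed).
#' @param ... Unused.
#' @name RheoScaleResult-accessors
NULL

#' @rdname RheoScaleResult-accessors
#' @export
setMethod("neutralFraction", "RheoScaleResult", function(x) x@neutralFraction)

#' @rdname RheoScaleResult-accessors
#' @export
setMethod("toggleFraction", "RheoScaleResult", function(x) x@toggleFraction)

#' @rdname RheoScaleResult-accessors
#' @export
setMethod("classLabel", "RheoScaleResult", function(x) x@label)

#' @rdname RheoScaleResult-accessors
#' @export
setMethod("binSweepStable", "RheoScaleResult", function(x) x@binSweepStable)

#' @rdname RheoScaleResult-accessors
#' @export
setMethod("nUsed", "RheoScaleResult", function(x) x@nUsed)

# channel values ready for scoring: excluded substitutions are omitted
# from transport channels but scored as dead for surface expression
.scoringInput <- function(x, key) {
  parsed <- parseAssayKey(key)
  ch <- .channelValues(x, key)
  vals <- ch$mean; sds <- ch$sd; ns <- ch$n
  if (parsed$kind == "surface_expression") {
    vals[ch$excluded & is.na(vals)] <- 0  # undetectable: dead
  } else {
    keep <- !ch$excluded
    vals <- vals[keep]; sds <- sds[keep]; ns <- ns[keep]
  }
  wtRow <- .wtRow(x)
  list(kind = parsed$kind, substrate = parsed$substrate, values = vals,
       sds = sds, ns = ns, wtSd = assay(x, "sd")[wtRow, key],
       wtN = assay(x, "n")[wtRow, key])
}

#' Score every assay channel of a scan
#'
#' Applies [rheoScale()] to each assay channel of a
#' \linkS4class{PositionScan}.  The wild-type self-record is displayed in
#' plots but never counted among the substitutions.  Substitutions flagged
#' by [expressionFilter()] are omitted from cellular-uptake and
#' corrected-transport channels (their transport cannot be determined) but
#' scored as dead for the surface-expression channel.
#'
#' @param x A \linkS4class{PositionScan}.
#' @param nBins,binRange,zEquiv,neutralThreshold,toggleThreshold,rheostatThreshold
#'   Passed to [rheoScale()].
#' @param ... Unused.
#' @return data.frame with one row per assay channel: \code{position},
#'   \code{wt}, \code{kind}, \code{substrate}, \code{n_used},
#'   \code{rheostat_score}, \code{neutral_fraction},
#'   \code{toggle_fraction}, \code{label}, \code{bin_sweep_stable},
#'   \code{scorable}.
#' @rdname scoreScan
#' @export
setMethod("scoreScan", "PositionScan",
          function(x, nBins = 10, binRange = 5:11, zEquiv = 1.96,
                   neutralThreshold = 0.70, toggleThreshold = 2 / 3,
                   rheostatThreshold = 0.5, ...) {
  rows <- lapply(colnames(x), function(key) {
    inp <- .scoringInput(x, key)
    res <- rheoScale(inp$values, sds = inp$sds, ns = inp$ns,
                     wtSd = inp$wtSd, wtN = inp$wtN,
                     nBins = nBins, binRange = binRange, zEquiv = zEquiv,
                     neutralThreshold = neutralThreshold,
                     toggleThreshold = toggleThreshold,
                     rheostatThreshold = rheostatThreshold)
    data.frame(position = scanPosition(x), wt = wtResidue(x),
               kind = inp$kind, substrate = inp$substrate,
               n_used = nUsed(res), rheostat_score = rheostatScore(res),
               neutral_fraction = neutralFraction(res),
               toggle_fraction = toggleFraction(res),
               label = classLabel(res),
               bin_sweep_stable = binSweepStable(res),
               scorable = res@scorable)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
})

#' Bin-count sweep for every assay channel of a scan
#'
#' Long-format version of the per-channel [binSweep()]: one row per
#' (assay channel, bin count), the control used to verify that class
#' assignments do not depend on the histogram discretization.
#'
#' @inheritParams scoreScan
#' @param x A \linkS4class{PositionScan}.
#' @return data.frame with columns \code{position}, \code{kind},
#'   \code{substrate}, \code{n_bins}, \code{rheostat_score},
#'   \code{neutral_fraction}, \code{toggle_fraction}, \code{label}.
#' @export
scanBinSweep <- function(x, binRange = 5:11, zEquiv = 1.96,
                         neutralThreshold = 0.70, toggleThreshold = 2 / 3,
                         rheostatThreshold = 0.5) {
  rows <- lapply(colnames(x), function(key) {
    inp <- .scoringInput(x, key)
    if (all(is.na(inp$values))) return(NULL)
    sw <- binSweep(inp$values[!is.na(inp$values)],
                   sds = inp$sds[!is.na(inp$values)],
                   ns = inp$ns[!is.na(inp$values)],
                   wtSd = inp$wtSd, wtN = inp$wtN, binRange = binRange,
                   zEquiv = zEquiv, neutralThreshold = neutralThreshold,
                   toggleThreshold = toggleThreshold,
                   rheostatThreshold = rheostatThreshold)
    cbind(data.frame(position = scanPosition(x), kind = inp$kind,
                     substrate = inp$substrate), sw)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Average substitution outcome per assay channel
#'
#' The arithmetic mean of a position's substitution means for each
#' parameter, the most common summary in site-saturation studies.
#' Substitutions with undetectable expression count as 0 for the
#' surface-expression channel and are omitted from transport channels,
#' mirroring the scoring rules.
#'
#' @param x A \linkS4class{PositionScan}.
#' @param ... Unused.
#' @return data.frame with columns \code{position}, \code{kind},
#'   \code{substrate}, \code{average}, \code{n_used}.
#' @rdname averageOutcomes
#' @export
setMethod("averageOutcomes", "PositionScan", function(x, ...) {
  rows <- lapply(colnames(x), function(key) {
    parsed <- parseAssayKey(key)
    ch <- .channelValues(x, key)
    vals <- ch$mean
    if (parsed$kind == "surface_expression") {
      vals[ch$excluded & is.na(vals)] <- 0
    } else {
      vals <- vals[!ch$excluded]
    }
    vals <- vals[!is.na(vals)]
    data.frame(position = scanPosition(x), kind = parsed$kind,
               substrate = parsed$substrate,
               average = if (length(vals)) mean(vals) else NA_real_,
               n_used = length(vals))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
})
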