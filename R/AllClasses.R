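#' PositionScan: one position's site-saturation scan
#'
#' A \code{PositionScan} holds the measurements for a single scanned protein
#' position: the wild-type self-record plus up to 19 substitution variants,
#' each measured in one or more assay channels.  It extends
#' \link[SummarizedExperiment]{SummarizedExperiment}: rows are variants
#' (named by substituted residue), columns are assay channels (named by
#' [assayKey()] strings), and the \code{mean}, \code{sd} and \code{n} assay
#' matrices carry percent-of-wild-type means, standard deviations and
#' replicate counts.
#'
#' Invariants enforced by the validity method:
#' \itemize{
#'   \item the position is a 1-based residue index and the wild-type residue
#'     is one of the 20 standard amino acids;
#'   \item row names are unique residue codes and exactly one row is the
#'     wild-type self-record, whose mean is 100 in every assay by
#'     construction;
#'   \item \code{sd >= 0} and \code{n >= 1} wherever defined.
#' }
#'
#' Negative means are allowed for substitution records (background
#' over-subtraction); they are flagged by the normalization path and clamped
#' to the dead value only when binned by [rheoScale()].
#'
#' @slot .. see \link[SummarizedExperiment]{SummarizedExperiment}; scan-level
#'   information (\code{position}, \code{wt}) lives in \code{metadata()}.
#'
#' @seealso [PositionScan()] for construction from a long measurement table,
#'   [readScanTable()] for file input.
#' @aliases PositionScan-class
#' @export
setClass("PositionScan", contains = "SummarizedExperiment")

setValidity("PositionScan", function(object) {
  msg <- character()
  md <- metadata(object)
  pos <- md$position
  wt <- md$wt
  if (is.null(pos) || length(pos) != 1L || is.na(pos) || pos < 1 ||
      pos != as.integer(pos))
    msg <- c(msg, "metadata()$position must be a single 1-based residue index")
  if (is.null(wt) || length(wt) != 1L || !.isResidue(wt))
    msg <- c(msg, "metadata()$wt must be one of the 20 standard residues")
  need <- c("mean", "sd", "n")
  if (!all(need %in% assayNames(object))) {
    msg <- c(msg, "assays 'mean', 'sd' and 'n' are required")
    return(if (length(msg)) msg else TRUE)
  }
  rn <- rownames(object)
  if (is.null(rn) || anyDuplicated(rn) || !all(.isResidue(rn)))
    msg <- c(msg, "row names must be unique standard residue codes")
  if (!is.null(wt) && length(wt) == 1L && !is.na(wt) && !is.null(rn)) {
    if (sum(rn == wt) != 1L) {
      msg <- c(msg, "exactly one wild-type self-record row is required")
    } else {
      wtMeans <- assay(object, "mean")[rn == wt, , drop = TRUE]
      off <- abs(wtMeans - 100) > 1e-6 & !is.na(wtMeans)
      if (any(off))
        msg <- c(msg, "the wild-type self-record must have mean 100 in every assay")
    }
    if (nrow(object) > 20L)
      msg <- c(msg, "at most 19 substitutions plus the wild-type record allowed")
  }
  for (key in colnames(object)) {
    parsed <- try(parseAssayKey(key), silent = TRUE)
    if (inherits(parsed, "try-error"))
      msg <- c(msg, sprintf("invalid assay key '%s'", key))
  }
  sds <- assay(object, "sd")
  if (any(sds < 0, na.rm = TRUE))
    msg <- c(msg, "standard deviations must be >= 0")
  ns <- assay(object, "n")
  if (any(ns < 1, na.rm = TRUE))
    msg <- c(msg, "replicate counts must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a PositionScan from a long measurement table
#'
#' @param measurements A data.frame with one row per (variant, assay):
#'   columns \code{sub} (substituted residue; equal to \code{wt} for the
#'   wild-type self-record), \code{kind}, \code{substrate} (NA for surface
#'   expression), \code{mean}, \code{sd}, \code{n}.
#' @param position 1-based residue index on the protein sequence.
#' @param wt Wild-type residue one-letter code.
#' @param replicates Optional named list of raw replicate vectors, kept in
#'   \code{metadata()} for provenance.
#' @return A \linkS4class{PositionScan}.
#' @examples
#' m <- data.frame(sub = c("G", "A"), kind = "cellular_uptake",
#'                 substrate = "TCA", mean = c(100, 55), sd = c(8, 6), n = 3)
#' PositionScan(m, position = 102, wt = "G")
#' @export
PositionScan <- function(measurements, position, wt, replicates = NULL) {
  stopifnot(is.data.frame(measurements))
  need <- c("sub", "kind", "substrate", "mean", "sd", "n")
  miss <- setdiff(need, names(measurements))
  if (length(miss))
    stop("measurement table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  keys <- mapply(assayKey, measurements$kind,
                 ifelse(is.na(measurements$substrate), NA_character_,
                        as.character(measurements$substrate)))
  subs <- as.character(measurements$sub)
  usubs <- unique(subs)
  ukeys <- unique(unname(keys))
  if (anyDuplicated(paste(subs, keys)))
    stop("duplicate (sub, assay) measurement rows", call. = FALSE)
  shape <- function(field) {
    m <- matrix(NA_real_, length(usubs), length(ukeys),
                dimnames = list(usubs, ukeys))
    m[cbind(match(subs, usubs), match(keys, ukeys))] <- measurements[[field]]
    m
  }
  cd <- DataFrame(do.call(rbind.data.frame, lapply(ukeys, parseAssayKey)),
                  row.names = ukeys)
  rd <- DataFrame(sub = usubs, is_wt = usubs == wt,
                  excluded = FALSE, exclude_reason = NA_character_,
                  row.names = usubs)
  se <- SummarizedExperiment(
    assays = list(mean = shape("mean"), sd = shape("sd"), n = shape("n")),
    rowData = rd, colData = cd)
  metadata(se) <- list(position = as.integer(position), wt = wt,
                       replicates = replicates)
  new("PositionScan", se)
}

setMethod("show", "PositionScan", function(object) {
  md <- metadata(object)
  nsub <- sum(!rowData(object)$is_wt)
  nexc <- sum(rowData(object)$excluded)
  cat(sprintf("PositionScan: position %d (wild type %s)\n",
              md$position, md$wt))
  cat(sprintf("  %d substitution(s)%s, %d assay channel(s):\n", nsub,
              if (nexc) sprintf(" [%d excluded]", nexc) else "",
              ncol(object)))
  for (key in colnames(object)) cat("   -", key, "\n")
})

#' RheoScaleResult: histogram-based substitution-sensitivity scores
#'
#' Result of scoring one set of substitution outcomes with [rheoScale()]:
#' the histogram specification, the rheostat score (fraction of histogram
#' bins populated), the neutral and toggle fractions, the class label and
#' the bin-count sweep used to check the label's stability.
#'
#' @slot values Numeric; the substitution means that were binned.
#' @slot nBins Integer; number of histogram bins at the primary bin count.
#' @slot histogram List with the bin edges, assignments, counts and the
#'   indices of the wild-type and dead bins.
#' @slot rheostatScore Fraction of bins populated, in (0, 1].
#' @slot neutralFraction Fraction of substitutions indistinguishable from
#'   wild type (in the WT bin, or within the equivalence window when
#'   replicate SDs are available).
#' @slot toggleFraction Fraction of substitutions in the dead bin.
#' @slot nUsed Number of substitutions scored after exclusions.
#' @slot label One of \code{"neutral"}, \code{"toggle"}, \code{"rheostat"},
#'   \code{"moderate_rheostat"} (or \code{NA} when not scorable).
#' @slot binSweep data.frame with one row per bin count in the sweep range.
#' @slot binSweepStable TRUE when the label is identical at every bin count.
#' @slot scorable FALSE when no usable values remained.
#' @aliases RheoScaleResult-class
#' @export
setClass("RheoScaleResult",
  representation(values = "numeric", nBins = "integer", histogram = "list",
                 rheostatScore = "numeric", neutralFraction = "numeric",
                 toggleFraction = "numeric", nUsed = "integer",
                 label = "character", binSweep = "data.frame",
                 binSweepStable = "logical", scorable = "logical"))

setValidity("RheoScaleResult", function(object) {
  msg <- character()
  if (object@scorable) {
    if (!is.na(object@rheostatScore) &&
        (object@rheostatScore <= 0 || object@rheostatScore > 1))
      msg <- c(msg, "rheostatScore must lie in (0, 1] when scorable")
    nf <- object@neutralFraction
    tf <- object@toggleFraction
    if (!is.na(nf) && !is.na(tf) && nf + tf > 1 + 1e-12)
      msg <- c(msg, "neutralFraction + toggleFraction must not exceed 1")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "RheoScaleResult", function(object) {
  if (!object@scorable) {
    cat("RheoScaleResult: not scorable (no usable substitution values)\n")
    return(invisible(NULL))
  }
  cat(sprintf("RheoScaleResult (%d bins, %d substitutions)\n",
              object@nBins, object@nUsed))
  cat(sprintf("  rheostat score:   %.3f\n", object@rheostatScore))
  cat(sprintf("  neutral fraction: %.3f\n", object@neutralFraction))
  cat(sprintf("  toggle fraction:  %.3f\n", object@toggleFraction))
  cat(sprintf("  class: %s (stable across %d-%d bins: %s)\n", object@label,
              min(object@binSweep$n_bins), max(object@binSweep$n_bins),
              ifelse(object@binSweepStable, "yes", "no")))
})
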