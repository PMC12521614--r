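#' Background-subtract raw uptake wells
#'
#' Subtracts each batch's empty-vector mean from every well in that batch.
#' Signals must already be normalized per well to total protein; background
#' subtraction happens after that per-well normalization.  Net values may be
#' negative (background over-subtraction); they are retained and flagged,
#' not clamped.
#'
#' @param wells data.frame with columns \code{batch}, \code{group} (one of
#'   \code{"empty_vector"}, \code{"wildtype"}, \code{"variant"}), \code{sub}
#'   (substituted residue for variant wells, NA otherwise) and
#'   \code{signal} (assay counts per total protein, >= 0).
#' @return The input with columns \code{net} (background-subtracted signal)
#'   and \code{below_background} (logical) appended.
#' @examples
#' w <- data.frame(batch = 1, group = c("empty_vector", "variant"),
#'                 sub = c(NA, "A"), signal = c(10, 50))
#' netUptake(w)$net   # EV mean 10: net 0 and 40
#' @export
netUptake <- function(wells) {
  stopifnot(all(c("batch", "group", "signal") %in% names(wells)))
  if (any(wells$signal < 0, na.rm = TRUE))
    stop("raw signals must be >= 0", call. = FALSE)
  bad <- !wells$group %in% c("empty_vector", "wildtype", "variant")
  if (any(bad))
    stop("unknown well group: ", paste(unique(wells$group[bad]),
         collapse = ", "), call. = FALSE)
  out <- do.call(rbind, lapply(split(wells, wells$batch), function(b) {
    ev <- b$signal[b$group == "empty_vector"]
    if (!length(ev))
      stop("batch '", b$batch[[1]], "' has no empty-vector wells",
           call. = FALSE)
    b$net <- b$signal - mean(ev)
    b$below_background <- b$net < 0
    b
  }))
  rownames(out) <- NULL
  out
}

#' Scale net values to percent of wild type
#'
#' The batch wild-type reference maps to exactly 100; SDs scale by the same
#' factor.  Negative net values yield negative percentages, retained with
#' their below-background flag.
#'
#' @param net Numeric net (background-subtracted) values.
#' @param wtReference The batch's wild-type net mean; must be positive, a
#'   non-positive reference signals an unusable batch.
#' @return Numeric percent-of-WT values.
#' @examples
#' percentOfWT(c(40, 20, -2), wtReference = 40)  # 100, 50, -5
#' @export
percentOfWT <- function(net, wtReference) {
  if (length(wtReference) != 1L || is.na(wtReference) || wtReference <= 0)
    stop("wild-type reference must be a single positive value ",
         "(unusable batch)", call. = FALSE)
  100 * net / wtReference
}

#' Scale surface-expression band intensities to percent of wild type
#'
#' The reference is the mean of the wild-type lanes run on the same blot
#' (batch), set to 100.  A zero intensity maps to 0 and is a candidate for
#' the undetectable-expression filter.
#'
#' @param intensities Numeric band intensities for one blot.
#' @param wtLanes Intensities of that blot's wild-type lanes (typically
#'   two); at least one is required.
#' @return Numeric percent-of-WT values.
#' @examples
#' percentOfWTSurface(30, wtLanes = c(40, 60))  # 60
#' @export
percentOfWTSurface <- function(intensities, wtLanes) {
  if (length(wtLanes) < 1L || all(is.na(wtLanes)))
    stop("at least one wild-type lane is required on the blot",
         call. = FALSE)
  ref <- mean(wtLanes, na.rm = TRUE)
  if (ref <= 0)
    stop("wild-type lane mean must be positive (unusable blot)",
         call. = FALSE)
  100 * intensities / ref
}

#' Pool raw uptake wells into percent-of-WT measurements
#'
#' Full uptake normalization path: per batch, the empty-vector mean is
#' subtracted from every protein-normalized well and each well is scaled to
#' percent of the batch's wild-type net mean; the per-well percentages are
#' then pooled across batches into one measurement (mean, SD, n) per
#' variant.  Cross-batch pooling only ever happens after percent-of-WT
#' scaling, so batches of different absolute sensitivity combine cleanly.
#'
#' @param wells As for [netUptake()].
#' @return data.frame with columns \code{sub} (NA for the wild-type
#'   record), \code{is_wt}, \code{mean}, \code{sd}, \code{n},
#'   \code{below_background} (any pooled well below background).
#' @export
normalizeUptakeWells <- function(wells) {
  wells <- netUptake(wells)
  perc <- do.call(rbind, lapply(split(wells, wells$batch), function(b) {
    wtNet <- mean(b$net[b$group == "wildtype"])
    if (!is.finite(wtNet))
      stop("batch '", b$batch[[1]], "' has no wild-type wells", call. = FALSE)
    b$percent <- percentOfWT(b$net, wtNet)
    b
  }))
  perc <- perc[perc$group != "empty_vector", , drop = FALSE]
  id <- ifelse(perc$group == "wildtype", ".wt", perc$sub)
  out <- do.call(rbind, lapply(split(perc, id), function(g) {
    data.frame(sub = if (g$group[[1]] == "wildtype") NA_character_
               else g$sub[[1]],
               is_wt = g$group[[1]] == "wildtype",
               mean = mean(g$percent),
               sd = if (nrow(g) > 1L) sd(g$percent) else 0,
               n = nrow(g),
               below_background = any(g$below_background))
  }))
  rownames(out) <- NULL
  out
}

#' Pool surface-expression lanes into percent-of-WT measurements
#'
#' Per blot, every lane is scaled to percent of the mean of that blot's
#' wild-type lanes; per-blot percentages are then pooled across blots into
#' one measurement per variant, with \code{n} the number of blots.  A
#' variant with no detectable band on any blot comes out as mean 0, sd 0
#' (the encoding the expression filter expects).
#'
#' @param lanes data.frame with columns \code{blot}, \code{group}
#'   (\code{"wildtype"} or \code{"variant"}), \code{sub}, \code{intensity}.
#' @return data.frame as for [normalizeUptakeWells()], plus
#'   \code{detected} (any nonzero band).
#' @export
normalizeSurfaceLanes <- function(lanes) {
  stopifnot(all(c("blot", "group", "intensity") %in% names(lanes)))
  perc <- do.call(rbind, lapply(split(lanes, lanes$blot), function(b) {
    wt <- b$intensity[b$group == "wildtype"]
    b$percent <- percentOfWTSurface(b$intensity, wt)
    b
  }))
  id <- ifelse(perc$group == "wildtype", ".wt", perc$sub)
  out <- do.call(rbind, lapply(split(perc, id), function(g) {
    data.frame(sub = if (g$group[[1]] == "wildtype") NA_character_
               else g$sub[[1]],
               is_wt = g$group[[1]] == "wildtype",
               mean = mean(g$percent),
               sd = if (nrow(g) > 1L) sd(g$percent) else 0,
               n = nrow(g),
               detected = any(g$percent > 0))
  }))
  rownames(out) <- NULL
  out
}

#' Flag substitutions with undetectable surface expression
#'
#' Substitutions whose surface-expression mean falls strictly below
#' \code{threshold} (default 1 percent of wild type) are flagged as
#' excluded: their transport phenotypes cannot be determined, so they are
#' omitted from uptake and corrected-transport scoring.  They still count
#' in the surface-expression histogram, where they populate the dead bin.
#' The filter is idempotent and order-independent.
#'
#' @param x A \linkS4class{PositionScan} with a surface-expression channel.
#' @param threshold Exclusion threshold in percent of wild type; strict
#'   less-than.
#' @param ... Unused.
#' @return The scan with \code{rowData()$excluded} and
#'   \code{$exclude_reason} updated.  Use [excludedSubstitutions()] to
#'   retrieve the excluded set.
#' @rdname expressionFilter
#' @export
setMethod("expressionFilter", "PositionScan", function(x, threshold = 1, ...) {
  keys <- .keysOfKind(x, "surface_expression")
  if (!length(keys)) {
    warning("no surface-expression channel; nothing to filter",
            call. = FALSE)
    return(x)
  }
  surf <- assay(x, "mean")[, keys[[1]]]
  hit <- !is.na(surf) & surf < threshold & !rowData(x)$is_wt
  rd <- rowData(x)
  rd$excluded <- hit
  rd$exclude_reason <- ifelse(hit,
    sprintf("surface expression < %g%% of wild type", threshold),
    NA_character_)
  rowData(x) <- rd
  x
})

#' Correct a measurement pair for surface expression
#'
#' Expression-corrected transport isolates per-molecule transport function:
#' \code{mean = 100 * uptake / surface}, both on the percent-of-WT scale.
#' The SD is propagated to first order treating the two assays as
#' independent (they come from separate experiments):
#' \deqn{sd = \frac{100}{s}\sqrt{sd_u^2 + (u/s)^2 sd_s^2}}
#' which equals \code{mean * sqrt((sd_u/u)^2 + (sd_s/s)^2)} for nonzero
#' uptake but remains defined at \code{u = 0}.  Wild type corrects to
#' 100 by construction.  Negative uptake yields a negative corrected mean,
#' carried through with its flag.
#'
#' @param uptake,surface Lists or data.frames with numeric elements
#'   \code{mean} and \code{sd} (vectors allowed), percent-of-WT scale.
#' @return data.frame with columns \code{mean} and \code{sd}.
#' @examples
#' correctMeasurement(list(mean = 50, sd = 10), list(mean = 50, sd = 5))
#' # corrected 100 +/- 22.36
#' @export
correctMeasurement <- function(uptake, surface) {
  u <- uptake$mean; su <- uptake$sd
  s <- surface$mean; ss <- surface$sd
  if (any(s <= 0, na.rm = TRUE))
    stop("surface expression must be positive to correct transport ",
         "(run the expression filter first)", call. = FALSE)
  m <- 100 * u / s
  data.frame(mean = m, sd = (100 / s) * sqrt(su^2 + (u / s)^2 * ss^2))
}

#' Add expression-corrected transport channels to a scan
#'
#' For every cellular-uptake channel, divides uptake by the
#' surface-expression measurement and appends a \code{corrected_transport}
#' channel with the propagated SD (see [correctMeasurement()]).  The
#' expression filter is applied first (if it has not been already):
#' excluded substitutions get \code{NA} corrected values, so the division
#' by a (near-)zero surface mean is unreachable.
#'
#' @param x A \linkS4class{PositionScan} with surface-expression and
#'   cellular-uptake channels.
#' @param threshold Passed to [expressionFilter()].
#' @param ... Unused.
#' @return The scan with one \code{corrected_transport:<substrate>} channel
#'   per uptake substrate appended.
#' @rdname correctForExpression
#' @export
setMethod("correctForExpression", "PositionScan",
          function(x, threshold = 1, ...) {
  sKey <- .keysOfKind(x, "surface_expression")
  uKeys <- .keysOfKind(x, "cellular_uptake")
  if (!length(sKey) || !length(uKeys))
    stop("need both surface-expression and cellular-uptake channels",
         call. = FALSE)
  x <- expressionFilter(x, threshold = threshold)
  usable <- !rowData(x)$excluded
  sMean <- assay(x, "mean")[, sKey[[1]]]
  sSd <- assay(x, "sd")[, sKey[[1]]]
  sN <- assay(x, "n")[, sKey[[1]]]
  m <- assay(x, "mean"); s <- assay(x, "sd"); n <- assay(x, "n")
  cd <- as.data.frame(colData(x))
  for (uk in uKeys) {
    substrate <- colData(x)[uk, "substrate"]
    ck <- assayKey("corrected_transport", substrate)
    if (ck %in% colnames(m)) next  # already corrected
    newM <- newS <- rep(NA_real_, nrow(x))
    ok <- usable & !is.na(m[, uk]) & !is.na(sMean)
    corr <- correctMeasurement(
      list(mean = m[ok, uk], sd = s[ok, uk]),
      list(mean = sMean[ok], sd = sSd[ok]))
    newM[ok] <- corr$mean
    newS[ok] <- corr$sd
    m <- cbind(m, setNames(data.frame(newM), ck))
    s <- cbind(s, setNames(data.frame(newS), ck))
    n <- cbind(n, setNames(data.frame(pmin(n[, uk], sN)), ck))
    cd <- rbind(cd, data.frame(kind = "corrected_transport",
                               substrate = substrate, row.names = ck))
  }
  se <- SummarizedExperiment(
    assays = list(mean = as.matrix(m), sd = as.matrix(s), n = as.matrix(n)),
    rowData = rowData(x), colData = DataFrame(cd))
  metadata(se) <- metadata(x)
  new("PositionScan", se)
})
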