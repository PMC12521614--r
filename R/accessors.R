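#' Accessors for PositionScan objects
#'
#' \code{scanPosition} returns the 1-based residue index, \code{wtResidue}
#' the wild-type residue code, \code{substitutions} the substituted residues
#' present (excluding the wild-type self-record), and
#' \code{excludedSubstitutions} the substitutions flagged by
#' [expressionFilter()].  \code{scanMeasurements} flattens the scan back
#' into a long data.frame with one row per (variant, assay).
#'
#' @param x A \linkS4class{PositionScan}.
#' @param ... Unused.
#' @return See each description.
#' @name PositionScan-accessors
NULL

#' @rdname PositionScan-accessors
#' @export
setMethod("scanPosition", "PositionScan", function(x) metadata(x)$position)

#' @rdname PositionScan-accessors
#' @export
setMethod("wtResidue", "PositionScan", function(x) metadata(x)$wt)

#' @rdname PositionScan-accessors
#' @export
setMethod("substitutions", "PositionScan", function(x) {
  rownames(x)[!rowData(x)$is_wt]
})

#' @rdname PositionScan-accessors
#' @export
setMethod("excludedSubstitutions", "PositionScan", function(x) {
  rownames(x)[rowData(x)$excluded]
})

#' @rdname PositionScan-accessors
#' @export
setMethod("scanMeasurements", "PositionScan", function(x, ...) {
  keys <- colnames(x)
  out <- do.call(rbind, lapply(keys, function(key) {
    parsed <- parseAssayKey(key)
    data.frame(position = scanPosition(x), wt = wtResidue(x),
               sub = rownames(x), kind = parsed$kind,
               substrate = parsed$substrate,
               mean = assay(x, "mean")[, key],
               sd = assay(x, "sd")[, key],
               n = assay(x, "n")[, key],
               excluded = rowData(x)$excluded,
               row.names = NULL)
  }))
  out[!is.na(out$mean), , drop = FALSE]
})

# mean/sd/n vectors for one channel, substitutions only
.channelValues <- function(scan, key, includeWT = FALSE) {
  keep <- if (includeWT) rep(TRUE, nrow(scan)) else !rowData(scan)$is_wt
  list(sub = rownames(scan)[keep],
       mean = assay(scan, "mean")[keep, key],
       sd = assay(scan, "sd")[keep, key],
       n = assay(scan, "n")[keep, key],
       excluded = rowData(scan)$excluded[keep])
}

.wtRow <- function(scan) which(rowData(scan)$is_wt)

# channel keys of one kind (optionally one substrate, case-insensitive)
.keysOfKind <- function(scan, kind, substrate = NULL) {
  cd <- colData(scan)
  keep <- cd$kind == kind
  if (!is.null(substrate))
    keep <- keep & .sameSubstrate(cd$substrate, substrate)
  colnames(scan)[keep]
}
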