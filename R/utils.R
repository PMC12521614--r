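#' The twenty standard amino acids
#'
#' One-letter codes of the canonical amino-acid alphabet.  Residue codes in
#' scan tables are validated against this set; anything else is rejected at
#' parse time.
#'
#' @format A character vector of length 20.
#' @export
AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "W", "Y", "V")

ASSAY_KINDS <- c("surface_expression", "cellular_uptake", "corrected_transport")

.isResidue <- function(x) {
  is.character(x) & x %in% AA_CODES
}

#' Build an assay key
#'
#' Assay channels are identified by a kind (\code{surface_expression},
#' \code{cellular_uptake} or \code{corrected_transport}) plus, for the two
#' transport kinds, a substrate label.  Substrate labels are free-form and
#' compared case-insensitively.  \code{corrected_transport} keys are only
#' produced by [correctForExpression()], never read from raw input.
#'
#' @param kind Assay kind, one of the three values above.
#' @param substrate Substrate label; required unless
#'   \code{kind == "surface_expression"}.
#' @return A single key string, e.g. \code{"cellular_uptake:TCA"}.
#' @seealso [parseAssayKey()]
#' @examples
#' assayKey("cellular_uptake", "TCA")
#' assayKey("surface_expression")
#' @export
assayKey <- function(kind, substrate = NA_character_) {
  kind <- match.arg(kind, ASSAY_KINDS, several.ok = FALSE)
  if (kind == "surface_expression") {
    if (!is.na(substrate) && nzchar(substrate))
      stop("surface_expression takes no substrate label", call. = FALSE)
    return(kind)
  }
  if (is.na(substrate) || !nzchar(substrate))
    stop("assay kind '", kind, "' requires a substrate label", call. = FALSE)
  paste0(kind, ":", substrate)
}

#' Split an assay key into kind and substrate
#'
#' @param key Key string as produced by [assayKey()].
#' @return A list with elements \code{kind} and \code{substrate}
#'   (\code{NA} for surface expression).
#' @export
parseAssayKey <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)[[1]]
  kind <- parts[[1]]
  if (!kind %in% ASSAY_KINDS)
    stop("unknown assay kind '", kind, "'", call. = FALSE)
  substrate <- if (length(parts) > 1L) paste(parts[-1L], collapse = ":")
               else NA_character_
  if (kind != "surface_expression" &&
      (is.na(substrate) || !nzchar(substrate)))
    stop("assay kind '", kind, "' requires a substrate label", call. = FALSE)
  list(kind = kind, substrate = substrate)
}

# case-insensitive substrate match
.sameSubstrate <- function(a, b) {
  (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & toupper(a) == toupper(b))
}

#' Summarize replicate values into a measurement
#'
#' @param replicates Numeric vector of per-replicate percent-of-WT values.
#' @return A list with \code{mean}, \code{sd} (0 for a single replicate) and
#'   \code{n}.
#' @examples
#' measurementFromReplicates(c(110, 120, 130))  # mean 120, sd 10, n 3
#' @export
measurementFromReplicates <- function(replicates) {
  replicates <- as.numeric(replicates)
  replicates <- replicates[!is.na(replicates)]
  if (length(replicates) == 0L)
    stop("no replicate values supplied", call. = FALSE)
  list(mean = mean(replicates),
       sd = if (length(replicates) > 1L) sd(replicates) else 0,
       n = length(replicates))
}

# full-precision numeric formatting so CSV round-trips are bit exact
.fmtNum <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}
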