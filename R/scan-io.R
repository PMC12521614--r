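#' Read a site-saturation scan table
#'
#' Reads a delimited table of per-variant assay measurements and groups the
#' rows into one \linkS4class{PositionScan} per scanned position.  The table
#' must provide the columns \code{position}, \code{wt}, \code{sub},
#' \code{assay} and \code{substrate}, plus either replicate-level values
#' (columns \code{rep1}, \code{rep2}, ...) or summary columns \code{mean},
#' \code{sd}, \code{n}.  All values are on the percent-of-wild-type scale
#' (wild type = 100).  When a row carries both replicates and summary
#' values, the replicate-level values win and a warning is issued.
#'
#' Rows violating the type invariants (unknown residue codes, duplicate
#' (position, sub, assay) combinations, a missing wild-type row for a
#' scanned position, \code{corrected_transport} rows, which are only ever
#' produced by [correctForExpression()]) produce itemized parse errors with
#' line numbers.
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator; \code{","} (default) or \code{"\t"}.
#' @param columns Optional named character vector remapping the canonical
#'   column names to the names used in the file, e.g.
#'   \code{c(position = "pos", sub = "mutant")}.
#' @return A named list of \linkS4class{PositionScan} objects, one per
#'   position, names \code{"<wt><position>"} (e.g. \code{"G102"}).
#' @seealso [writeScanTable()], [writeResultsTable()]
#' @export
readScanTable <- function(path, sep = ",", columns = character()) {
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE)
  canon <- c("position", "wt", "sub", "assay", "substrate",
             "mean", "sd", "n")
  for (nm in names(columns)) {
    if (columns[[nm]] %in% names(raw))
      names(raw)[names(raw) == columns[[nm]]] <- nm
  }
  miss <- setdiff(c("position", "wt", "sub", "assay"), names(raw))
  if (length(miss))
    stop("scan table lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"substrate" %in% names(raw)) raw$substrate <- NA_character_
  raw$substrate[!is.na(raw$substrate) & !nzchar(raw$substrate)] <- NA_character_

  repCols <- grep("^rep[0-9]+$", names(raw), value = TRUE)
  hasSummary <- all(c("mean", "sd", "n") %in% names(raw))
  if (!length(repCols) && !hasSummary)
    stop("scan table needs either rep1..repK columns or mean/sd/n columns",
         call. = FALSE)

  line <- seq_len(nrow(raw)) + 1L  # header is line 1
  errs <- character()
  addErr <- function(rows, what)
    sprintf("line %d: %s", line[rows], what)

  bad <- !.isResidue(raw$wt)
  if (any(bad)) errs <- c(errs, addErr(which(bad), paste0(
    "unknown wild-type residue code '", raw$wt[bad], "'")))
  bad <- !.isResidue(raw$sub)
  if (any(bad)) errs <- c(errs, addErr(which(bad), paste0(
    "unknown substituted residue code '", raw$sub[bad], "'")))
  bad <- is.na(suppressWarnings(as.integer(raw$position))) |
    raw$position < 1
  if (any(bad)) errs <- c(errs, addErr(which(bad), "invalid position index"))
  bad <- raw$assay == "corrected_transport"
  if (any(bad)) errs <- c(errs, addErr(which(bad),
    "corrected_transport is derived, never read from raw input"))
  bad <- !raw$assay %in% c("surface_expression", "cellular_uptake")
  bad <- bad & raw$assay != "corrected_transport"
  if (any(bad)) errs <- c(errs, addErr(which(bad), paste0(
    "unknown assay kind '", raw$assay[bad], "'")))
  bad <- raw$assay == "cellular_uptake" & is.na(raw$substrate)
  if (any(bad)) errs <- c(errs, addErr(which(bad),
    "cellular_uptake rows require a substrate label"))

  keyOf <- paste(raw$position, raw$sub, raw$assay,
                 toupper(ifelse(is.na(raw$substrate), "", raw$substrate)))
  dup <- duplicated(keyOf)
  if (any(dup)) errs <- c(errs, addErr(which(dup),
    "duplicate (position, sub, assay) row"))

  for (p in unique(raw$position)) {
    rows <- raw$position == p
    if (!any(raw$sub[rows] == raw$wt[rows]))
      errs <- c(errs, sprintf("position %s: missing wild-type row", p))
    if (length(unique(raw$wt[rows])) > 1L)
      errs <- c(errs, sprintf("position %s: conflicting wild-type residues", p))
  }
  if (length(errs))
    stop("scan table parse errors:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)

  # replicate-level values win over summary columns
  useReps <- rep(FALSE, nrow(raw))
  if (length(repCols)) {
    repMat <- as.matrix(raw[repCols])
    mode(repMat) <- "numeric"
    useReps <- rowSums(!is.na(repMat)) > 0L
    if (hasSummary && any(useReps & !is.na(raw$mean)))
      warning("rows with both replicate and summary values: ",
              "replicate-level values used", call. = FALSE)
    summ <- lapply(which(useReps), function(i)
      measurementFromReplicates(repMat[i, ]))
    raw$mean[useReps] <- vapply(summ, `[[`, numeric(1), "mean")
    raw$sd[useReps] <- vapply(summ, `[[`, numeric(1), "sd")
    raw$n[useReps] <- vapply(summ, `[[`, numeric(1), "n")
  }

  scans <- lapply(split(raw, raw$position), function(df) {
    reps <- NULL
    if (length(repCols)) {
      keep <- rowSums(!is.na(as.matrix(df[repCols]))) > 0L
      if (any(keep)) {
        reps <- lapply(which(keep), function(i) {
          v <- as.numeric(df[i, repCols])
          v[!is.na(v)]
        })
        names(reps) <- paste(df$sub, df$assay,
                             ifelse(is.na(df$substrate), "", df$substrate))[keep]
      }
    }
    PositionScan(
      data.frame(sub = df$sub, kind = df$assay, substrate = df$substrate,
                 mean = as.numeric(df$mean), sd = as.numeric(df$sd),
                 n = as.numeric(df$n)),
      position = df$position[[1]], wt = df$wt[[1]], replicates = reps)
  })
  names(scans) <- vapply(scans, function(s)
    paste0(wtResidue(s), scanPosition(s)), character(1))
  scans[order(vapply(scans, scanPosition, integer(1)))]
}

#' Write scans back to a delimited table
#'
#' Writes the mean/sd/n measurement rows of one or more scans in the format
#' [readScanTable()] consumes.  Numeric fields are written at full precision
#' so that a write-then-read round trip reproduces means and SDs bit for
#' bit.
#'
#' @param scans A \linkS4class{PositionScan} or list of them.
#' @param path Output file path.
#' @param sep Field separator.
#' @return \code{path}, invisibly.
#' @export
writeScanTable <- function(scans, path, sep = ",") {
  if (is(scans, "PositionScan")) scans <- list(scans)
  rows <- do.call(rbind, lapply(scans, scanMeasurements))
  rows <- rows[rows$kind != "corrected_transport", , drop = FALSE]
  out <- data.frame(position = rows$position, wt = rows$wt, sub = rows$sub,
                    assay = rows$kind, substrate = rows$substrate,
                    mean = .fmtNum(rows$mean), sd = .fmtNum(rows$sd),
                    n = .fmtNum(rows$n))
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write per-variant and per-position results
#'
#' Emits a long table with one \code{measurement} row per (variant, assay)
#' -- including derived \code{corrected_transport} channels and exclusion
#' flags -- plus one \code{position_summary} row per (position, assay) with
#' the RheoScale scores.  An empty result set yields a header-only file.
#'
#' @param scans List of \linkS4class{PositionScan} (possibly empty).
#' @param scores Optional data.frame from [scoreScan()] (rows are appended
#'   as position summaries).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeResultsTable <- function(scans, scores = NULL, path) {
  cols <- c("row_type", "position", "wt", "sub", "assay", "substrate",
            "mean", "sd", "n", "excluded", "n_used", "rheostat_score",
            "neutral_fraction", "toggle_fraction", "label",
            "bin_sweep_stable")
  if (is(scans, "PositionScan")) scans <- list(scans)
  blocks <- list()
  if (length(scans)) {
    m <- do.call(rbind, lapply(scans, scanMeasurements))
    blocks$m <- data.frame(row_type = "measurement", position = m$position,
      wt = m$wt, sub = m$sub, assay = m$kind, substrate = m$substrate,
      mean = .fmtNum(m$mean), sd = .fmtNum(m$sd), n = .fmtNum(m$n),
      excluded = m$excluded, n_used = NA, rheostat_score = NA,
      neutral_fraction = NA, toggle_fraction = NA, label = NA,
      bin_sweep_stable = NA)
  }
  if (!is.null(scores) && nrow(scores)) {
    blocks$s <- data.frame(row_type = "position_summary",
      position = scores$position, wt = scores$wt, sub = NA,
      assay = scores$kind, substrate = scores$substrate, mean = NA, sd = NA,
      n = NA, excluded = NA, n_used = scores$n_used,
      rheostat_score = .fmtNum(scores$rheostat_score),
      neutral_fraction = .fmtNum(scores$neutral_fraction),
      toggle_fraction = .fmtNum(scores$toggle_fraction),
      label = scores$label, bin_sweep_stable = scores$bin_sweep_stable)
  }
  out <- if (length(blocks)) do.call(rbind, blocks)
         else as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                     cols))
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a position-to-conservation-score table
#'
#' Two-column delimited table mapping positions to ConSurf-style
#' conservation grades; grades must be integers between 1 (least conserved)
#' and 9 (most conserved).
#'
#' @param path Path to a CSV with columns \code{position}, \code{score}.
#' @return data.frame with integer columns \code{position} and \code{score}.
#' @export
readConservationTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("position", "score") %in% names(df)))
    stop("conservation table needs columns 'position' and 'score'",
         call. = FALSE)
  bad <- is.na(df$score) | df$score < 1 | df$score > 9 |
    df$score != as.integer(df$score)
  if (any(bad))
    stop("conservation scores must be integers in 1..9 (rows: ",
         paste(which(bad), collapse = ", "), ")", call. = FALSE)
  data.frame(position = as.integer(df$position),
             score = as.integer(df$score))
}

#' Read a variant-effect prediction table
#'
#' Three-column table of predictor scores in [0, 1] per (position,
#' substitution), as distributed for AlphaMissense-style predictors, plus
#' the predictor's published category cutoffs: scores at or below
#' \code{benignMax} are called likely benign, scores at or above
#' \code{pathogenicMin} likely pathogenic, and scores in between are
#' ambiguous (no prediction attempted).
#'
#' @param path CSV with columns \code{position}, \code{sub}, \code{score}.
#' @param benignMax,pathogenicMin Band cutoffs; defaults are the published
#'   AlphaMissense class boundaries (0.34 and 0.564).
#' @return data.frame with attributes \code{benign_max} and
#'   \code{pathogenic_min}.
#' @export
readPredictionTable <- function(path, benignMax = 0.34,
                                pathogenicMin = 0.564) {
  stopifnot(benignMax < pathogenicMin)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("position", "sub", "score") %in% names(df)))
    stop("prediction table needs columns 'position', 'sub', 'score'",
         call. = FALSE)
  if (any(!.isResidue(df$sub)))
    stop("prediction table contains non-standard residue codes",
         call. = FALSE)
  if (any(is.na(df$score) | df$score < 0 | df$score > 1))
    stop("predictor scores must lie in [0, 1]", call. = FALSE)
  out <- data.frame(position = as.integer(df$position), sub = df$sub,
                    score = as.numeric(df$score))
  attr(out, "benign_max") <- benignMax
  attr(out, "pathogenic_min") <- pathogenicMin
  out
}

#' Read a residue property scale
#'
#' Two-column table mapping one-letter residue codes to a numeric
#' physicochemical property (hydrophobicity, side-chain surface area,
#' helical propensity, ...).  A scale may omit residues; pairs with missing
#' values are dropped listwise by [propertyCorrelation()] and counted.
#'
#' @param path CSV with columns \code{residue}, \code{value}.
#' @param name Scale name; defaults to the file name.
#' @return Named numeric vector over the residues present, with a
#'   \code{name} attribute.
#' @export
readPropertyScale <- function(path, name = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("residue", "value") %in% names(df)))
    stop("property scale needs columns 'residue' and 'value'", call. = FALSE)
  if (any(!.isResidue(df$residue)))
    stop("property scale contains non-standard residue codes", call. = FALSE)
  if (anyDuplicated(df$residue))
    stop("property scale lists a residue twice", call. = FALSE)
  out <- setNames(as.numeric(df$value), df$residue)
  attr(out, "name") <- if (is.null(name))
    sub("\\.[^.]*$", "", basename(path)) else name
  out
}
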