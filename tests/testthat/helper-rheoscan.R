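# shared fixtures and independent oracles (kept deliberately naive)

assay <- SummarizedExperiment::assay
rowData <- SummarizedExperiment::rowData
colData <- SummarizedExperiment::colData

# quick PositionScan: one uptake channel (+ optional surface channel)
simpleScan <- function(subMeans, surface = NULL, wt = "G", position = 1,
                       substrate = "TCA", sdFrac = 0, n = 3,
                       wtSd = 0, surfaceSd = 0) {
  subs <- setdiff(AA_CODES, wt)[seq_along(subMeans)]
  df <- rbind(
    data.frame(sub = wt, kind = "cellular_uptake", substrate = substrate,
               mean = 100, sd = wtSd, n = n),
    data.frame(sub = subs, kind = "cellular_uptake", substrate = substrate,
               mean = subMeans, sd = sdFrac * abs(subMeans), n = n))
  if (!is.null(surface)) {
    df <- rbind(df,
      data.frame(sub = wt, kind = "surface_expression",
                 substrate = NA_character_, mean = 100, sd = wtSd, n = n),
      data.frame(sub = subs, kind = "surface_expression",
                 substrate = NA_character_, mean = surface,
                 sd = surfaceSd * abs(surface), n = n))
  }
  PositionScan(df, position = position, wt = wt)
}

# enumeration oracle: count populated bins by checking every bin directly
oraclePopulatedBins <- function(values, nBins, wtValue = 100,
                                deadValue = 0) {
  v <- pmax(values, deadValue)
  edges <- seq(deadValue, max(v, wtValue), length.out = nBins + 1)
  populated <- 0L
  for (k in seq_len(nBins)) {
    inBin <- if (k < nBins) v >= edges[k] & v < edges[k + 1]
             else v >= edges[k] & v <= edges[k + 1]
    if (any(inBin)) populated <- populated + 1L
  }
  populated
}

# rank-then-Pearson oracle for Spearman's rho (average ranks for ties)
oracleSpearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  oraclePearson(rx, ry)
}

# direct covariance-formula oracle for Pearson's r
oraclePearson <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}
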