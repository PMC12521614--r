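#' Synthetic four-position transporter study (worked example)
#'
#' A deterministic, fully synthetic stand-in for a four-position bile-acid
#' transporter scan study: one highly conserved channel-buried rheostat
#' position (G102, conservation grade 9) whose substitutions spread both
#' surface expression and transport over the full accessible range and
#' whose I/K/L/R/V substitutions lack detectable surface expression; a
#' transport rheostat position with unchanged expression (S267, grade 8);
#' a moderate rheostat position (N271, grade 5) whose substitutions sample
#' less than half the range; and a nearly neutral surface-loop position
#' (Y146, grade 4) with two expression-abolishing substitutions (N, S).
#' Three uptake substrates (TCA, E3S, rosuvastatin) plus surface
#' expression are included per position.
#'
#' The numbers are constructed, not measured: they encode the qualitative
#' behavior above so that every pipeline stage (exclusion filter,
#' expression correction, RheoScale scoring, bin sweep, concordance and
#' conservation correlations) can be exercised and regression-tested on a
#' dataset with known structure.  Do not use them as experimental values.
#'
#' @return A list with \code{scans} (named list of
#'   \linkS4class{PositionScan}, uncorrected) and \code{conservation}
#'   (data.frame of ConSurf-style grades).
#' @examples
#' study <- syntheticStudy()
#' scoreScan(correctForExpression(study$scans$G102))
#' @export
syntheticStudy <- function() {
  mkRows <- function(sub, kind, substrate, mean, sd, n) {
    data.frame(sub = sub, kind = kind, substrate = substrate, mean = mean,
               sd = sd, n = n)
  }
  uptakeRows <- function(sub, substrate, mean, sdFloor = 1) {
    mkRows(sub, "cellular_uptake", substrate, mean,
           pmax(0.10 * abs(mean), sdFloor), 9)
  }
  surfaceRows <- function(sub, mean) {
    mkRows(sub, "surface_expression", NA_character_, mean,
           ifelse(mean == 0, 0, 0.10 * mean), 3)
  }
  wtRows <- function(wt) {
    rbind(
      uptakeRows(wt, "TCA", 100), uptakeRows(wt, "E3S", 100),
      uptakeRows(wt, "rosuvastatin", 100),
      mkRows(wt, "surface_expression", NA_character_, 100, 10, 3))
  }
  buildScan <- function(position, wt, sub, uTCA, uE3S, uRos, surf) {
    PositionScan(rbind(
      wtRows(wt),
      uptakeRows(sub, "TCA", uTCA), uptakeRows(sub, "E3S", uE3S),
      uptakeRows(sub, "rosuvastatin", uRos), surfaceRows(sub, surf)),
      position = position, wt = wt)
  }

  # G102: rheostatic in expression and all transports; five substitutions
  # with long aliphatic side chains are not expressed at the surface
  g102Sub <- c("P", "E", "D", "Q", "F", "M", "C", "Y", "W", "H", "T", "N",
               "S", "A", "I", "K", "L", "R", "V")
  g102U <- c(6.05, 14, 25.05, 30, 37, 48, 55, 65, 75, 83.3, 89.8, 95,
             97.5, 117.8, 0.4, 0.6, 0.5, 0.7, 0.3)
  g102S <- c(55, 31.1, 15, 33, 92.5, 40, 110, 78.3, 53.6, 70, 102, 63.3,
             125, 95, 0, 0, 0, 0, 0)
  g102 <- buildScan(102, "G", g102Sub, g102U, 0.8 * g102U, 0.7 * g102U,
                    g102S)

  # Y146: nearly neutral; N and S abolish surface expression
  y146Sub <- setdiff(AA_CODES, c("Y", "N", "S"))
  y146 <- buildScan(146, "Y",
    c(y146Sub, "N", "S"),
    c(seq(88, 110, length.out = 17), 0.5, 0.4),
    c(seq(91, 109, length.out = 17), 0.6, 0.5),
    c(seq(90, 107, length.out = 17), 0.4, 0.6),
    c(seq(90, 112, length.out = 17), 0, 0))

  # S267: transport rheostat with scrambled substrate rank order and
  # unchanged expression
  s267Sub <- setdiff(AA_CODES, "S")
  ord <- c(10, 3, 17, 6, 1, 14, 8, 19, 12, 5, 16, 2, 11, 7, 18, 4, 13, 9,
           15)
  s267 <- buildScan(267, "S", s267Sub,
                    seq(2, 155, length.out = 19),
                    rev(seq(5, 150, length.out = 19)),
                    seq(4, 152, length.out = 19)[ord],
                    seq(96, 106, length.out = 19))

  # N271: moderate rheostat -- non-neutral transport confined to well
  # under half the accessible range, expression unchanged
  n271Sub <- setdiff(AA_CODES, "N")
  n271 <- buildScan(271, "N", n271Sub,
                    seq(40.5, 66.2, length.out = 19),
                    seq(42, 65, length.out = 19),
                    seq(43, 64.5, length.out = 19),
                    seq(93, 107, length.out = 19))

  list(scans = list(G102 = g102, Y146 = y146, S267 = s267, N271 = n271),
       conservation = data.frame(position = c(102L, 146L, 267L, 271L),
                                 score = c(9L, 4L, 8L, 5L)))
}
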