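test_that("property correlation recovers monotone and degenerate cases", {
  subs <- setdiff(AA_CODES, "G")
  scale <- setNames(seq_along(subs), subs)
  attr(scale, "name") <- "synthetic-monotone"
  outcomes <- setNames(seq_along(subs)^2, subs)  # monotone in the scale
  r <- propertyCorrelation(outcomes, scale)
  expect_equal(r$coefficient, 1)
  expect_identical(r$n, 19L)

  flat <- setNames(rep(1, 19), subs)             # zero-variance scale
  expect_false(propertyCorrelation(outcomes, flat)$computable)
  expect_false(propertyCorrelation(outcomes[1:2], scale)$computable)

  # listwise deletion over scale gaps is counted
  gappy <- scale[1:10]
  r2 <- propertyCorrelation(outcomes, gappy)
  expect_identical(r2$n, 10L)
  expect_identical(r2$n_dropped, 9L)
})

test_that("Spearman and Pearson match brute-force oracles", {
  set.seed(303)
  for (i in 1:200) {
    n <- sample(4:19, 1)
    x <- setNames(runif(n, -50, 150), AA_CODES[seq_len(n)])
    y <- setNames(runif(n, 0, 10), AA_CODES[seq_len(n)])
    rs <- propertyCorrelation(x, y, method = "spearman")
    expect_equal(rs$coefficient, oracleSpearman(x, y))
    rp <- propertyCorrelation(x, y, method = "pearson")
    expect_equal(rp$coefficient, oraclePearson(x, y))
  }
  # average-rank tie handling
  xt <- setNames(c(1, 2, 2, 2, 5, 6), AA_CODES[1:6])
  yt <- setNames(c(3, 3, 9, 1, 4, 8), AA_CODES[1:6])
  expect_equal(propertyCorrelation(xt, yt)$coefficient,
               oracleSpearman(xt, yt))
})

test_that("Spearman is invariant under monotone transforms, Pearson affine", {
  set.seed(11)
  x <- setNames(runif(19, 1, 100), setdiff(AA_CODES, "G"))
  y <- setNames(runif(19, 1, 100), setdiff(AA_CODES, "G"))
  base <- propertyCorrelation(x, y)$coefficient
  expect_equal(propertyCorrelation(exp(x / 50), y)$coefficient, base)
  expect_equal(propertyCorrelation(x, log(y))$coefficient, base)
  pb <- propertyCorrelation(x, y, method = "pearson")$coefficient
  expect_equal(propertyCorrelation(3 * x + 7, y,
                                   method = "pearson")$coefficient, pb)
  expect_equal(propertyCorrelation(-2 * x, y,
                                   method = "pearson")$coefficient, -pb)
  expect_lte(abs(base), 1)
  expect_lte(abs(pb), 1)
})

test_that("substrate concordance detects identical and reversed rank orders", {
  subs <- setdiff(AA_CODES, "G")
  vals <- seq(5, 140, length.out = 19)
  mk <- function(e3s) {
    df <- rbind(
      data.frame(sub = "G", kind = "cellular_uptake",
                 substrate = c("TCA", "E3S"), mean = 100, sd = 5, n = 3),
      data.frame(sub = subs, kind = "cellular_uptake", substrate = "TCA",
                 mean = vals, sd = 5, n = 3),
      data.frame(sub = subs, kind = "cellular_uptake", substrate = "E3S",
                 mean = e3s, sd = 5, n = 3),
      data.frame(sub = c("G", subs), kind = "surface_expression",
                 substrate = NA, mean = 100, sd = 5, n = 3))
    correctForExpression(PositionScan(df, position = 1, wt = "G"))
  }
  same <- substrateConcordance(mk(vals))
  expect_equal(same$coefficient, 1)
  rev_ <- substrateConcordance(mk(rev(vals)))
  expect_equal(rev_$coefficient, -1)
})

test_that("summed sensitivity correlates with conservation as constructed", {
  scores <- data.frame(position = rep(1:4, each = 2),
                       rheostat_score = c(0.9, 0.9, 0.7, 0.7, 0.5, 0.5,
                                          0.3, 0.3),
                       scorable = TRUE, kind = "corrected_transport")
  averages <- data.frame(position = rep(1:4, each = 2),
                         kind = "corrected_transport",
                         average = c(20, 20, 40, 40, 60, 60, 80, 80))
  cons <- data.frame(position = 1:4, score = c(9L, 7L, 5L, 3L))
  sens <- sensitivitySummary(scores, averages, cons)
  expect_equal(sens$summed_rheostat, c(1.8, 1.4, 1.0, 0.6))
  r <- sensitivityVsConservation(sens, "summed_rheostat")
  expect_equal(r$coefficient, 1)       # exactly proportional
  ra <- sensitivityVsConservation(sens, "summed_average")
  expect_equal(ra$coefficient, -1)
  # zero variance is flagged not computable
  sens0 <- sens
  sens0$summed_rheostat <- 1
  expect_false(sensitivityVsConservation(sens0)$computable)
})

test_that("stability/function trade-off has the constructed sign", {
  subs <- setdiff(AA_CODES, "G")[1:10]
  surface <- seq(20, 150, length.out = 10)
  mkScan <- function(uptake) {
    df <- rbind(
      data.frame(sub = "G", kind = "cellular_uptake", substrate = "TCA",
                 mean = 100, sd = 0, n = 3),
      data.frame(sub = subs, kind = "cellular_uptake", substrate = "TCA",
                 mean = uptake, sd = 0, n = 3),
      data.frame(sub = "G", kind = "surface_expression", substrate = NA,
                 mean = 100, sd = 0, n = 3),
      data.frame(sub = subs, kind = "surface_expression", substrate = NA,
                 mean = surface, sd = 0, n = 3))
    correctForExpression(PositionScan(df, position = 1, wt = "G"))
  }
  # corrected transport equal to expression itself: rho = 1
  rho1 <- stabilityFunctionTradeoff(mkScan(surface^2 / 100))
  expect_equal(rho1$coefficient, 1)
  # trade-off archetype: corrected transport decreasing in expression
  anti <- mkScan(surface * (200 - surface) / 100)
  expect_lt(stabilityFunctionTradeoff(anti)$coefficient, 0)
})

test_that("predictor band comparison applies the stated call logic", {
  pred <- data.frame(position = 1, sub = c("A", "C", "D", "E"),
                     score = c(0.1, 0.9, 0.5, 0.9))
  attr(pred, "benign_max") <- 0.34
  attr(pred, "pathogenic_min") <- 0.564
  measured <- data.frame(position = 1, sub = c("A", "C", "D", "E"),
                         value = c(95, 98, 50, 20))
  out <- predictorBandComparison(measured, pred, wtRange = c(90, 110))
  calls <- out$calls[match(c("A", "C", "D", "E"), out$calls$sub), ]
  expect_identical(calls$concordant, c(TRUE, FALSE, NA, TRUE))
  expect_identical(out$summary$ambiguous, 1L)
  expect_identical(out$summary$concordant, 2L)
  expect_identical(out$summary$discordant, 1L)
  expect_equal(out$summary$discordance_rate, 1 / 3)
  expect_error(predictorBandComparison(
    data.frame(position = 9, sub = "A", value = 50), pred,
    wtRange = c(90, 110)), "overlap")
})
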