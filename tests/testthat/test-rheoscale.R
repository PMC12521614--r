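test_that("histogram partitions [dead, max(values, wt)] with closed last bin", {
  h <- buildHistogram(seq(5, 95, by = 10), nBins = 10)
  expect_equal(h$edges, seq(0, 100, by = 10))
  expect_equal(h$assignments, 1:10)
  expect_identical(buildHistogram(c(50, 100), nBins = 10)$assignments[2], 10L)
  expect_identical(h$wtBin, 10L)   # wt = 100 lands in the closed last bin
  expect_identical(h$deadBin, 1L)
  # enhanced values extend the domain beyond the wild type
  h2 <- buildHistogram(c(10, 150), nBins = 10)
  expect_equal(h2$domain, c(0, 150))
  # below-dead values are clamped into the dead bin
  expect_identical(buildHistogram(c(-5, 50), nBins = 10)$assignments[1], 1L)
  expect_error(buildHistogram(numeric()), "no scorable values")
})

test_that("a single wild-type-like value populates only the WT bin", {
  h <- buildHistogram(100, nBins = 10)
  expect_identical(unique(h$assignments), h$wtBin)
  expect_equal(rheostatScore(h), 0.1)
})

test_that("rheostat score is populated bins over total bins", {
  # 19 values covering all 10 bins of [0, 133]
  vals <- seq(2.5, 132.5, length.out = 19)
  expect_equal(rheostatScore(buildHistogram(vals, nBins = 10)), 1)
  # all substitutions dead: only the dead bin is sampled
  expect_equal(rheostatScore(buildHistogram(rep(0, 19), nBins = 10)), 0.1)
})

test_that("populated-bin counting matches a brute-force enumeration oracle", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(3:19, 1)
    vals <- runif(n, -5, 160)
    nb <- sample(5:11, 1)
    h <- buildHistogram(vals, nBins = nb)
    expect_equal(rheostatScore(h),
                 oraclePopulatedBins(vals, nb) / nb)
  }
})

test_that("classification precedence is neutral, toggle, rheostat, moderate", {
  expect_identical(classifyPosition(14 / 19, 0, 0.3), "neutral")
  expect_identical(classifyPosition(0, 13 / 19, 0.1), "toggle")
  expect_identical(classifyPosition(0.1, 0.1, 0.62), "rheostat")
  expect_identical(classifyPosition(0.1, 0.1, 0.45), "moderate_rheostat")
  # pathological overlap resolves deterministically by precedence
  expect_identical(classifyPosition(0.75, 0.70, 0.9), "neutral")
  expect_identical(classifyPosition(0.2, 0.68, 0.9), "toggle")
  # thresholds are inclusive
  expect_identical(classifyPosition(0.70, 0, 0.1), "neutral")
  expect_identical(classifyPosition(0, 2 / 3, 0.1), "toggle")
  expect_identical(classifyPosition(0, 0, 0.5), "rheostat")
})

test_that("scores and labels survive positive rescaling of values and WT", {
  set.seed(77)
  for (i in 1:25) {
    vals <- runif(19, 0, 140)
    base <- rheoScale(vals)
    for (k in c(0.2, 3, 250)) {
      scaled <- rheoScale(vals * k, wtValue = 100 * k)
      expect_equal(rheostatScore(scaled), rheostatScore(base))
      expect_equal(neutralFraction(scaled), neutralFraction(base))
      expect_equal(toggleFraction(scaled), toggleFraction(base))
      expect_identical(classLabel(scaled), classLabel(base))
    }
  }
})

test_that("adding a value inside the domain never depopulates bins", {
  set.seed(5)
  for (i in 1:50) {
    vals <- runif(sample(3:18, 1), 0, 120)
    before <- length(unique(buildHistogram(vals, nBins = 10)$assignments))
    extra <- runif(1, 0, max(vals, 100))
    after <- length(unique(buildHistogram(c(vals, extra),
                                          nBins = 10)$assignments))
    expect_gte(after, before)
  }
})

test_that("bin sweep flags archetypal patterns as stable", {
  sw <- binSweep(seq(2.5, 132.5, length.out = 19))
  expect_true(attr(sw, "stable"))
  expect_true(all(sw$label == "rheostat"))
  swDead <- binSweep(rep(0, 19))
  expect_true(attr(swDead, "stable"))
  expect_true(all(swDead$label == "toggle"))
  expect_identical(nrow(sw), 7L)   # bin counts 5 through 11
})

test_that("the neutral test accepts means statistically equal to wild type", {
  # whole cloud drifted to ~105 by a shared reference shift, with one
  # enhanced value stretching the domain: the bin containing 100 no longer
  # contains the cloud, but the replicate-error equivalence window does
  vals <- c(rep(105, 18), 115)
  sds <- rep(9, 19)
  ns <- rep(9, 19)
  h <- buildHistogram(vals, nBins = 10)
  expect_true(all(h$assignments != h$wtBin))     # positionally non-neutral
  res <- rheoScale(vals, sds = sds, ns = ns, wtSd = 9, wtN = 9)
  expect_equal(neutralFraction(res), 18 / 19)
  expect_identical(classLabel(res), "neutral")
  # without error information the pure bin rule applies
  expect_equal(neutralFraction(rheoScale(vals)), 0)
  # a clearly distinct cloud is not swallowed by the window
  far <- rheoScale(rep(40, 19), sds = sds, ns = ns, wtSd = 9, wtN = 9)
  expect_equal(neutralFraction(far), 0)
})

test_that("neutral and toggle fractions never sum above one", {
  set.seed(12)
  for (i in 1:50) {
    vals <- runif(19, -5, 150)
    res <- rheoScale(vals, sds = runif(19, 0, 30), ns = rep(3, 19),
                     wtSd = runif(1, 0, 30), wtN = 3)
    expect_lte(neutralFraction(res) + toggleFraction(res), 1)
  }
})

test_that("scan scoring omits excluded variants except for surface expression", {
  scan <- simpleScan(subMeans = c(1, 40, 80, 120),
                     surface = c(0.2, 50, 100, 150))
  scan <- expressionFilter(scan)   # first substitution undetectable
  sc <- scoreScan(scan)
  up <- sc[sc$kind == "cellular_uptake", ]
  surf <- sc[sc$kind == "surface_expression", ]
  expect_identical(up$n_used, 3L)    # excluded omitted from transport
  expect_identical(surf$n_used, 4L)  # but binned (dead) for surface
  # all substitutions excluded: transport channel is not scorable
  allOut <- expressionFilter(simpleScan(c(10, 20), surface = c(0, 0.3)))
  scAll <- scoreScan(allOut)
  expect_false(scAll$scorable[scAll$kind == "cellular_uptake"])
  expect_true(is.na(scAll$label[scAll$kind == "cellular_uptake"]))
})

test_that("average outcomes follow the exclusion rules", {
  scan <- expressionFilter(simpleScan(subMeans = c(10, 50, 90),
                                      surface = c(0, 60, 140)))
  av <- averageOutcomes(scan)
  expect_equal(av$average[av$kind == "cellular_uptake"], mean(c(50, 90)))
  expect_equal(av$average[av$kind == "surface_expression"],
               mean(c(0, 60, 140)))
})
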