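test_that("background subtraction uses the batch empty-vector mean", {
  w <- data.frame(batch = 1,
                  group = c("empty_vector", "empty_vector", "variant",
                            "variant", "variant"),
                  sub = c(NA, NA, "A", "C", "D"),
                  signal = c(8, 12, 50, 10, 8))
  out <- netUptake(w)
  net <- out$net[match(c("A", "C", "D"), out$sub)]
  expect_equal(net, c(40, 0, -2))
  expect_identical(out$below_background[match(c("A", "C", "D"), out$sub)],
                   c(FALSE, FALSE, TRUE))
  expect_error(netUptake(data.frame(batch = 1, group = "variant", sub = "A",
                                    signal = 5)),
               "no empty-vector")
})

test_that("percent-of-WT maps the reference to exactly 100", {
  expect_equal(percentOfWT(40, 40), 100)
  expect_equal(percentOfWT(20, 40), 50)
  expect_equal(percentOfWT(-2, 40), -5)   # retained, not clamped
  expect_error(percentOfWT(10, 0), "positive")
  expect_error(percentOfWT(10, -3), "positive")
})

test_that("surface percent uses the same-blot wild-type lane pair", {
  expect_equal(percentOfWTSurface(30, c(40, 60)), 60)
  expect_equal(mean(percentOfWTSurface(c(40, 60), c(40, 60))), 100)
  expect_equal(percentOfWTSurface(0, c(40, 60)), 0)
  expect_error(percentOfWTSurface(10, numeric()), "wild-type lane")
})

test_that("percent-of-WT normalization is invariant to raw signal rescaling", {
  set.seed(42)
  w <- do.call(rbind, lapply(1:3, function(b) {
    data.frame(batch = b,
               group = c(rep("empty_vector", 3), rep("wildtype", 3),
                         rep("variant", 6)),
               sub = c(rep(NA, 6), rep(c("A", "C"), each = 3)),
               signal = c(runif(3, 40, 60), runif(3, 900, 1100),
                          runif(6, 100, 800)))
  }))
  base <- normalizeUptakeWells(w)
  for (k in c(0.1, 7, 1000)) {
    w2 <- w
    w2$signal <- w2$signal * k
    scaled <- normalizeUptakeWells(w2)
    expect_equal(scaled$mean, base$mean)
    expect_equal(scaled$sd, base$sd)
  }
  expect_equal(base$mean[base$is_wt], 100)  # WT pins to 100 by construction
})

test_that("expression filter excludes strictly below threshold, idempotently", {
  scan <- simpleScan(subMeans = c(50, 60, 70, 80, 90),
                     surface = c(0, 0.5, 1.0, 1.2, 40))
  scan <- expressionFilter(scan)
  subs <- setdiff(AA_CODES, "G")[1:5]
  expect_identical(excludedSubstitutions(scan), subs[1:2])
  # exactly 1.0 is retained (strict less-than); idempotent reapplication
  scan2 <- expressionFilter(expressionFilter(scan))
  expect_identical(excludedSubstitutions(scan2), subs[1:2])
  # all expressed: empty exclusion set
  ok <- expressionFilter(simpleScan(c(50, 60), surface = c(10, 20)))
  expect_length(excludedSubstitutions(ok), 0L)
})

test_that("expression correction follows first-order ratio propagation", {
  r <- correctMeasurement(list(mean = 50, sd = 10), list(mean = 50, sd = 5))
  expect_equal(r$mean, 100)
  expect_equal(r$sd, 100 * sqrt((10 / 50)^2 + (5 / 50)^2))
  expect_equal(r$sd, 22.360679774997898)
  r0 <- correctMeasurement(list(mean = 100, sd = 0), list(mean = 100, sd = 0))
  expect_equal(r0$mean, 100)
  expect_equal(r0$sd, 0)
  # negative uptake is carried through with sign
  rn <- correctMeasurement(list(mean = -2, sd = 1), list(mean = 40, sd = 0))
  expect_equal(rn$mean, -5)
  expect_error(correctMeasurement(list(mean = 10, sd = 1),
                                  list(mean = 0, sd = 0)),
               "positive")
})

test_that("correcting a measurement by itself gives exactly 100", {
  set.seed(7)
  for (x in runif(25, 0.01, 500)) {
    r <- correctMeasurement(list(mean = x, sd = 0), list(mean = x, sd = 0))
    expect_equal(r$mean, 100)
    expect_equal(r$sd, 0)
  }
})

test_that("propagated SD is monotone in each input's relative error", {
  sds <- seq(0, 30, by = 5)
  up <- vapply(sds, function(s)
    correctMeasurement(list(mean = 80, sd = s),
                       list(mean = 90, sd = 9))$sd, numeric(1))
  expect_true(all(diff(up) > 0))
  sf <- vapply(sds, function(s)
    correctMeasurement(list(mean = 80, sd = 8),
                       list(mean = 90, sd = s))$sd, numeric(1))
  expect_true(all(diff(sf) > 0))
  # never below the SD implied by either input alone
  both <- correctMeasurement(list(mean = 80, sd = 8),
                             list(mean = 90, sd = 9))$sd
  onlyU <- correctMeasurement(list(mean = 80, sd = 8),
                              list(mean = 90, sd = 0))$sd
  onlyS <- correctMeasurement(list(mean = 80, sd = 0),
                              list(mean = 90, sd = 9))$sd
  expect_gte(both, onlyU)
  expect_gte(both, onlyS)
})

test_that("scan-level correction adds corrected channels and skips excluded", {
  scan <- simpleScan(subMeans = c(50, 60, 70), surface = c(0, 50, 200))
  corr <- correctForExpression(scan)
  ck <- "corrected_transport:TCA"
  expect_true(ck %in% colnames(corr))
  subs <- setdiff(AA_CODES, "G")[1:3]
  m <- assay(corr, "mean")[subs, ck]
  expect_true(is.na(m[[1]]))                    # excluded: no corrected value
  expect_equal(unname(m[[2]]), 100 * 60 / 50)
  expect_equal(unname(m[[3]]), 100 * 70 / 200)
  expect_equal(unname(assay(corr, "mean")["G", ck]), 100)  # WT corrects to 100
  # applying twice does not duplicate channels
  expect_identical(colnames(correctForExpression(corr)), colnames(corr))
})
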