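test_that("replicate-level rows are summarized into mean/sd/n", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("position,wt,sub,assay,substrate,rep1,rep2,rep3",
               "102,G,G,cellular_uptake,TCA,100,100,100",
               "102,G,A,cellular_uptake,TCA,110,120,130"), f)
  scans <- readScanTable(f)
  expect_length(scans, 1L)
  scan <- scans$G102
  expect_equal(unname(assay(scan, "mean")["A", "cellular_uptake:TCA"]), 120)
  expect_equal(unname(assay(scan, "sd")["A", "cellular_uptake:TCA"]), 10)
  expect_equal(unname(assay(scan, "n")["A", "cellular_uptake:TCA"]), 3)
  expect_equal(measurementFromReplicates(c(110, 120, 130)),
               list(mean = 120, sd = 10, n = 3L))
})

test_that("parse errors are itemized with line numbers", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("position,wt,sub,assay,substrate,mean,sd,n",
               "102,G,G,cellular_uptake,TCA,100,5,3",
               "102,G,B,cellular_uptake,TCA,50,5,3"), f)
  expect_error(readScanTable(f), "line 3.*'B'")

  writeLines(c("position,wt,sub,assay,substrate,mean,sd,n",
               "102,G,A,cellular_uptake,TCA,50,5,3"), f)
  expect_error(readScanTable(f), "missing wild-type row")

  writeLines(c("position,wt,sub,assay,substrate,mean,sd,n",
               "102,G,G,cellular_uptake,TCA,100,5,3",
               "102,G,A,cellular_uptake,TCA,50,5,3",
               "102,G,A,cellular_uptake,tca,60,5,3"), f)
  expect_error(readScanTable(f), "duplicate")

  writeLines(c("position,wt,sub,assay,substrate,mean,sd,n",
               "102,G,G,corrected_transport,TCA,100,5,3"), f)
  expect_error(readScanTable(f), "never read from raw input")
})

test_that("a well-formed 20-row table groups into one full scan", {
  subs <- setdiff(AA_CODES, "G")
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(position = 102, wt = "G", sub = c("G", subs),
                   assay = "cellular_uptake", substrate = "TCA",
                   mean = c(100, seq_along(subs)), sd = 1, n = 3)
  write.csv(df, f, row.names = FALSE)
  scans <- readScanTable(f)
  expect_length(scans, 1L)
  expect_identical(sort(substitutions(scans$G102)), sort(subs))
  expect_identical(scanPosition(scans$G102), 102L)
  expect_identical(wtResidue(scans$G102), "G")
})

test_that("write-then-read round trip reproduces means and SDs bit for bit", {
  gen <- generatePositionScan(archetypeSpec("rheostat", seed = 11,
                                            noiseCV = 0.1))
  f <- withr::local_tempfile(fileext = ".csv")
  writeScanTable(gen$scan, f)
  back <- readScanTable(f)[[1]]
  for (field in c("mean", "sd", "n")) {
    expect_identical(assay(back, field)[rownames(gen$scan),
                                        colnames(gen$scan)],
                     assay(gen$scan, field),
                     info = field)
  }
})

test_that("results writer emits measurement plus summary rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeResultsTable(list(), NULL, f)
  empty <- read.csv(f)
  expect_identical(nrow(empty), 0L)   # header-only file
  expect_true("rheostat_score" %in% names(empty))

  gen <- generatePositionScan(archetypeSpec("toggle", seed = 3,
                                            noiseCV = 0))
  scores <- scoreScan(gen$scan)
  writeResultsTable(list(gen$scan), scores, f)
  out <- read.csv(f)
  nMeas <- nrow(scanMeasurements(gen$scan))
  expect_identical(sum(out$row_type == "measurement"), nMeas)
  expect_identical(sum(out$row_type == "position_summary"), nrow(scores))
})

test_that("PositionScan enforces its construction invariants", {
  base <- data.frame(sub = c("G", "A"), kind = "cellular_uptake",
                     substrate = "TCA", mean = c(100, 55), sd = 0, n = 3)
  expect_s4_class(PositionScan(base, position = 102, wt = "G"),
                  "PositionScan")
  noWT <- base[base$sub != "G", ]
  expect_error(PositionScan(noWT, position = 102, wt = "G"),
               "wild-type self-record")
  badWT <- base
  badWT$mean[badWT$sub == "G"] <- 95
  expect_error(PositionScan(badWT, position = 102, wt = "G"), "mean 100")
  dup <- rbind(base, base[2, ])
  expect_error(PositionScan(dup, position = 102, wt = "G"), "duplicate")
  negSD <- base
  negSD$sd <- -1
  expect_error(PositionScan(negSD, position = 102, wt = "G"), ">= 0")
})

test_that("conservation, prediction and property-scale readers validate", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(position = c(102, 146), score = c(9, 4)), f,
            row.names = FALSE)
  cons <- readConservationTable(f)
  expect_identical(cons$score, c(9L, 4L))
  write.csv(data.frame(position = 1, score = 12), f, row.names = FALSE)
  expect_error(readConservationTable(f), "1\\.\\.9")

  write.csv(data.frame(position = 102, sub = "A", score = 0.9), f,
            row.names = FALSE)
  pred <- readPredictionTable(f)
  expect_identical(attr(pred, "benign_max"), 0.34)
  write.csv(data.frame(position = 102, sub = "A", score = 1.4), f,
            row.names = FALSE)
  expect_error(readPredictionTable(f), "\\[0, 1\\]")

  write.csv(data.frame(residue = c("A", "C"), value = c(1.2, -0.3)), f,
            row.names = FALSE)
  sc <- readPropertyScale(f, name = "demo")
  expect_identical(attr(sc, "name", exact = TRUE), "demo")
  expect_identical(unname(sc["C"]), -0.3)
  write.csv(data.frame(residue = c("A", "A"), value = 1:2), f,
            row.names = FALSE)
  expect_error(readPropertyScale(f), "twice")
})
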