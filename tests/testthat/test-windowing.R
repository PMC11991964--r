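## Small hand-built feature container: values encode (record, minute) so
## window rows can be checked against brute-force construction.
toyFeatures <- function(nMinutes = 5, records = "r1") {
  cols <- length(records) * nMinutes
  rid <- rep(records, each = nMinutes)
  mins <- rep(seq_len(nMinutes) - 1L, length(records))
  m <- matrix(0, 18, cols)
  for (j in seq_len(cols)) m[, j] <- mins[j] * 100 + seq_len(18)
  SegmentFeatures(m, recordId = rid, minuteIndex = mins,
                  label = rep(c(FALSE, TRUE), length.out = cols),
                  valid = rep(TRUE, cols))
}

test_that("window (0, 0) reproduces the unwindowed matrix bit-for-bit", {
  sf <- toyFeatures()
  wm <- assembleWindowedFeatures(sf, windowSpec(0, 0))
  expect_identical(unname(designMatrix(wm)),
                   unname(t(SummarizedExperiment::assay(sf, "features"))))
  expect_identical(segmentLabels(wm),
                   SummarizedExperiment::colData(sf)$label)
})

test_that("row length is 18 * (past + future + 1) across the grid", {
  sf <- toyFeatures(nMinutes = 3)
  for (p in c(0L, 1L, 3L, 15L)) {
    for (f in c(0L, 2L, 13L, 15L)) {
      wm <- assembleWindowedFeatures(sf, windowSpec(p, f))
      expect_identical(ncol(designMatrix(wm)), 18L * (p + f + 1L))
      expect_identical(nrow(designMatrix(wm)), 3L)  # all targets kept
    }
  }
  # the published MLP optimum (future 13, past 3) gives 306 columns
  wm <- assembleWindowedFeatures(toyFeatures(), windowSpec(3, 13))
  expect_identical(ncol(designMatrix(wm)), 306L)
})

test_that("edge replication matches brute-force row construction", {
  sf <- toyFeatures(nMinutes = 5)
  fm <- SummarizedExperiment::assay(sf, "features")
  wm <- assembleWindowedFeatures(sf, windowSpec(2, 2))
  # minute 0: out-of-range past minutes replicate the minute-0 vector
  expect_identical(unname(designMatrix(wm)[1, ]),
                   unname(c(fm[, 1], fm[, 1], fm[, 1], fm[, 2], fm[, 3])))
  # interior minute 2: plain concatenation of minutes 0..4
  expect_identical(unname(designMatrix(wm)[3, ]),
                   unname(c(fm[, 1], fm[, 2], fm[, 3], fm[, 4], fm[, 5])))
  # last minute: future context replicates the final vector
  expect_identical(unname(designMatrix(wm)[5, ]),
                   unname(c(fm[, 3], fm[, 4], fm[, 5], fm[, 5], fm[, 5])))
})

test_that("zero and drop edge policies behave as documented", {
  sf <- toyFeatures(nMinutes = 4)
  wmZ <- assembleWindowedFeatures(sf, windowSpec(1, 1), edgePolicy = "zero")
  expect_identical(unname(designMatrix(wmZ)[1, 1:18]), rep(0, 18))
  wmD <- assembleWindowedFeatures(sf, windowSpec(1, 1), edgePolicy = "drop")
  expect_identical(nrow(designMatrix(wmD)), 2L)  # edge targets dropped
  expect_identical(wmD@minuteIndex, 1:2)
})

test_that("context never crosses recording boundaries", {
  sf <- toyFeatures(nMinutes = 3, records = c("a", "b"))
  fm <- SummarizedExperiment::assay(sf, "features")
  wm <- assembleWindowedFeatures(sf, windowSpec(1, 1))
  # record b starts at column 4; its first row must replicate b's own
  # minute 0, not borrow record a's last minute
  rowB0 <- which(segmentGroups(wm) == "b")[1]
  expect_identical(unname(designMatrix(wm)[rowB0, 1:18]), unname(fm[, 4]))
})

test_that("assembly is invariant to record order and rejects disorder", {
  sf <- toyFeatures(nMinutes = 4, records = c("a", "b"))
  wm1 <- assembleWindowedFeatures(sf, windowSpec(1, 1))
  # permute records (b first), reassemble, then re-sort rows
  cd <- SummarizedExperiment::colData(sf)
  ord <- order(cd$record_id == "a", cd$minute_index)
  sf2 <- SegmentFeatures(
    SummarizedExperiment::assay(sf, "features")[, ord],
    recordId = cd$record_id[ord], minuteIndex = cd$minute_index[ord],
    label = cd$label[ord], valid = cd$valid[ord])
  wm2 <- assembleWindowedFeatures(sf2, windowSpec(1, 1))
  key1 <- order(segmentGroups(wm1), wm1@minuteIndex)
  key2 <- order(segmentGroups(wm2), wm2@minuteIndex)
  expect_identical(designMatrix(wm1)[key1, ], designMatrix(wm2)[key2, ])

  # unsorted minutes within a record are an error
  bad <- SegmentFeatures(matrix(0, 18, 2), recordId = c("x", "x"),
                         minuteIndex = c(1L, 0L), label = c(FALSE, TRUE),
                         valid = c(TRUE, TRUE))
  expect_error(assembleWindowedFeatures(bad, windowSpec(0, 1)),
               "not strictly increasing")
})

test_that("window spec bounds are validated", {
  expect_error(windowSpec(-1, 0))
  expect_error(windowSpec(0, 16))
  expect_silent(windowSpec(15, 15))
})

test_that("grid search returns the surface and applies the tie-break", {
  sf <- toyFeatures()
  # single-cell grid
  res1 <- gridSearchWindows(sf, grid = list(windowSpec(0, 0)),
                            evaluator = function(f, s) 0.5)
  expect_identical(nrow(res1$surface), 1L)
  expect_identical(windowPast(res1$best), 0L)

  # stubbed surface with a tie: (1,1) and (2,2) at 0.9 -> smallest wins
  stub <- function(f, s) {
    key <- paste(windowPast(s), windowFuture(s))
    c("0 0" = 0.8, "1 1" = 0.9, "2 2" = 0.9)[[key]]
  }
  res2 <- gridSearchWindows(
    sf, grid = list(windowSpec(0, 0), windowSpec(1, 1), windowSpec(2, 2)),
    evaluator = stub)
  expect_identical(windowPast(res2$best), 1L)
  expect_identical(windowFuture(res2$best), 1L)

  # tie at equal size: smallest future wins
  stub2 <- function(f, s) if (windowFuture(s) == 2) 0.9 else 0.9
  res3 <- gridSearchWindows(
    sf, grid = list(windowSpec(0, 2), windowSpec(2, 0)), evaluator = stub2)
  expect_identical(windowFuture(res3$best), 0L)
  expect_error(gridSearchWindows(sf, grid = list()), "non-empty")
})

test_that("grid search over real evaluations is deterministic and complete", {
  feats <- smallFeatures()
  grid <- list(windowSpec(0, 0), windowSpec(1, 1))
  res1 <- gridSearchWindows(feats, grid = grid,
                            config = classifierConfig("RF"),
                            nFolds = 3, seed = 1)
  res2 <- gridSearchWindows(feats, grid = grid,
                            config = classifierConfig("RF"),
                            nFolds = 3, seed = 1)
  expect_identical(res1$surface, res2$surface)
  expect_identical(nrow(res1$surface), 2L)
  expect_true(all(res1$surface$mean_accuracy >= 0 &
                    res1$surface$mean_accuracy <= 1))
})
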