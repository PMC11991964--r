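test_that("grouped k-fold splits partition records with the 28/7 shape", {
  ids <- sprintf("x%02d", 1:35)
  folds <- groupKFoldSplit(ids, nFolds = 5, seed = 4)
  expect_length(folds, 5)
  for (f in folds) {
    expect_length(f$valid, 7)
    expect_length(f$train, 28)
    expect_length(intersect(f$train, f$valid), 0)
  }
  # every id in exactly one validation fold
  allValid <- unlist(lapply(folds, `[[`, "valid"))
  expect_setequal(allValid, ids)
  expect_identical(anyDuplicated(allValid), 0L)

  # 10 ids -> validation folds of 2
  folds10 <- groupKFoldSplit(sprintf("y%d", 1:10), nFolds = 5, seed = 1)
  expect_true(all(vapply(folds10, function(f) length(f$valid), 0L) == 2L))
  expect_error(groupKFoldSplit(c("a", "b"), nFolds = 5), "at least 5")
})

test_that("segment metrics reproduce the printed equations", {
  # TP = 84, FN = 16, TN = 90, FP = 10
  truth <- c(rep(TRUE, 100), rep(FALSE, 100))
  pred <- c(rep(TRUE, 84), rep(FALSE, 16), rep(FALSE, 90), rep(TRUE, 10))
  m <- segmentMetrics(truth, pred)
  expect_identical(unname(m$counts),
                   c(84L, 90L, 10L, 16L))
  expect_equal(m$ACC, 0.87)
  expect_equal(m$SEN, 0.84)
  expect_equal(m$SPE, 0.90)
  expect_equal(m$PRE, 84 / 94, tolerance = 1e-12)
  expect_equal(m$F1, 2 * (84 / 94) * 0.84 / (84 / 94 + 0.84),
               tolerance = 1e-12)
  # F1 identity: 2 * PRE * SEN / (PRE + SEN)
  expect_equal(m$F1, 2 * m$PRE * m$SEN / (m$PRE + m$SEN))

  perfect <- segmentMetrics(truth, truth, scores = as.numeric(truth))
  for (k in c("ACC", "SEN", "SPE", "PRE", "F1", "AUC"))
    expect_equal(perfect[[k]], 1)
})

test_that("AUC is the midrank rank statistic, matching the pairwise oracle", {
  truth <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(segmentMetrics(truth, truth, scores = c(1, 1, 0, 0))$AUC, 1)
  expect_equal(segmentMetrics(truth, truth, scores = c(0, 0, 1, 1))$AUC, 0)
  set.seed(21)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    tr <- runif(n) < 0.4
    if (length(unique(tr)) < 2) next
    sc <- round(runif(n), 2)  # rounding forces ties
    expect_equal(segmentMetrics(tr, tr, scores = sc)$AUC, oracleAUC(tr, sc),
                 tolerance = 1e-12)
  }
  # independent cross-check against pROC on one draw
  set.seed(22)
  tr <- runif(100) < 0.5
  sc <- round(runif(100), 2)
  expect_equal(segmentMetrics(tr, tr, scores = sc)$AUC,
               as.numeric(pROC::auc(pROC::roc(
                 tr, sc, quiet = TRUE, direction = "<",
                 levels = c(FALSE, TRUE)))),
               tolerance = 1e-12)
  expect_error(segmentMetrics(rep(TRUE, 3), rep(TRUE, 3), scores = 1:3),
               "single class")
})

test_that("AHI formula and SAS threshold are exact", {
  expect_identical(computeAHI(40, 480), 5)
  expect_identical(computeAHI(0, 400), 0)
  expect_equal(computeAHI(70, 420), 10)
  expect_error(computeAHI(10, 0), "positive")
  # linearity: doubling both counts and minutes leaves AHI unchanged
  expect_equal(computeAHI(34, 412), computeAHI(68, 824))
  expect_true(diagnoseSAS(5.0))     # boundary inclusive
  expect_false(diagnoseSAS(4.99))
  expect_false(diagnoseSAS(0))
})

test_that("recording metrics compute SAS classification and Pearson r", {
  tab <- data.frame(
    record_id = c("a", "b", "c", "d"), T = rep(60, 4),
    n_sa_pred = c(10, 2, 8, 1), n_sa_true = c(12, 1, 9, 0),
    predicted_ahi = c(10, 2, 8, 1), actual_ahi = c(12, 1, 9, 0),
    predicted_sas = c(TRUE, FALSE, TRUE, FALSE),
    actual_sas = c(TRUE, FALSE, TRUE, FALSE))
  m <- recordingMetrics(tab)
  expect_equal(m$ACC, 1)
  # hand-computed Pearson r on the AHI pairs
  x <- c(10, 2, 8, 1); y <- c(12, 1, 9, 0)
  rHand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(m$r, rHand, tolerance = 1e-12)

  # identity case: perfect AHI prediction -> r = 1
  tab2 <- tab
  tab2$predicted_ahi <- tab2$actual_ahi
  tab2$n_sa_pred <- tab2$n_sa_true
  tab2$predicted_sas <- tab2$actual_sas
  expect_equal(recordingMetrics(tab2)$r, 1)

  # all-positive predictions: SEN 1, SPE 0
  tab3 <- tab
  tab3$predicted_sas <- TRUE
  tab3$predicted_ahi <- c(10, 6, 8, 7)
  m3 <- recordingMetrics(tab3)
  expect_equal(m3$SEN, 1)
  expect_equal(m3$SPE, 0)

  expect_error(recordingMetrics(tab[1, , drop = FALSE]), "at least 2")
  tabZ <- tab; tabZ$predicted_ahi <- rep(3, 4)
  expect_error(recordingMetrics(tabZ), "zero variance")
})

test_that("experiments keep train and test records disjoint", {
  feats <- smallFeatures()
  ids <- unique(SummarizedExperiment::colData(feats)$record_id)
  expect_error(
    runExperiment(feats, classifierConfig("LR"), windowSpec(0, 0),
                  split = "train_test", trainIds = ids[1:4],
                  testIds = ids[3:6], seed = 1),
    "both train and test")
})

test_that("a full cross-validated experiment produces coherent artifacts", {
  feats <- smallFeatures()
  res <- runExperiment(feats, classifierConfig("RF"), windowSpec(1, 1),
                       split = "cv", nFolds = 3, seed = 2)
  # every annotated segment is scored exactly once
  expect_identical(nrow(res$predictions), ncol(feats))
  # recording table invariants: ahi = 60/T * n_sa, sas = (ahi >= 5)
  tab <- res$recordingTable
  expect_equal(tab$predicted_ahi, 60 / tab$T * tab$n_sa_pred)
  expect_equal(tab$actual_ahi, 60 / tab$T * tab$n_sa_true)
  expect_identical(tab$predicted_sas, tab$predicted_ahi >= 5)
  # run log records the configuration actually used
  expect_identical(res$runLog$classifier, "RF")
  expect_identical(res$runLog$hyperparameters$n_estimators, 148)
  expect_identical(unname(res$runLog$window), c(1L, 1L))
  # metrics bounded
  for (k in c("ACC", "SEN", "SPE", "PRE", "F1", "AUC")) {
    expect_gte(res$segmentMetrics[[k]], 0)
    expect_lte(res$segmentMetrics[[k]], 1)
  }
})

test_that("experiment reports serialize and rerun byte-identically", {
  feats <- smallFeatures()
  ids <- unique(SummarizedExperiment::colData(feats)$record_id)
  run <- function() {
    res <- runExperiment(feats, classifierConfig("RF"), windowSpec(1, 1),
                         split = "train_test", trainIds = ids[1:4],
                         testIds = ids[5:6], seed = 3)
    path <- tempfile(fileext = ".json")
    writeExperimentReport(res, path)
    path
  }
  p1 <- run(); p2 <- run()
  expect_identical(readLines(p1), readLines(p2))
  report <- jsonlite::read_json(p1)
  expect_named(report, c("segment_metrics", "confusion", "fold_accuracy",
                         "recording_metrics", "recordings", "run_log"),
               ignore.order = TRUE)
})
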