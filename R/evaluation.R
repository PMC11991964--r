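#' Grouped k-fold split of record ids
#'
#' Shuffles the unique record ids with a seeded RNG and deals them
#' round-robin into `nFolds` validation folds, so every record appears in
#' exactly one validation fold and all segments of a record stay together.
#' With 35 records and 5 folds, each validation fold holds exactly 7
#' records (the 28/7 protocol).
#'
#' @param recordIds character vector of record ids (duplicates allowed; the
#'   split is over unique ids).
#' @param nFolds number of folds (default 5).
#' @param seed RNG seed for the shuffle.
#' @return A list of `nFolds` lists, each with `train` and `valid` id sets.
#' @export
groupKFoldSplit <- function(recordIds, nFolds = 5, seed = 1) {
  ids <- unique(as.character(recordIds))
  if (length(ids) < nFolds)
    stop("need at least ", nFolds, " records, got ", length(ids))
  shuffled <- withSeed(seed, sample(ids))
  foldOf <- rep(seq_len(nFolds), length.out = length(shuffled))
  lapply(seq_len(nFolds), function(k) {
    list(train = shuffled[foldOf != k], valid = shuffled[foldOf == k])
  })
}

## Midrank (Mann-Whitney) AUC.
aucMidrank <- function(truth, scores) {
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: truth contains a single class")
  r <- rank(scores)           # midranks for ties
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.confusion <- function(truth, pred) {
  c(TP = sum(truth & pred), TN = sum(!truth & !pred),
    FP = sum(!truth & pred), FN = sum(truth & !pred))
}

.classMetrics <- function(truth, pred) {
  cm <- .confusion(truth, pred)
  tp <- cm[["TP"]]; tn <- cm[["TN"]]; fp <- cm[["FP"]]; fn <- cm[["FN"]]
  acc <- (tp + tn) / sum(cm)
  sen <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spe <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  pre <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(pre) && !is.na(sen) && pre + sen > 0)
    2 * pre * sen / (pre + sen) else NA_real_
  list(counts = cm, ACC = acc, SEN = sen, SPE = spe, PRE = pre, F1 = f1)
}

#' Per-segment classification metrics
#'
#' Accuracy, sensitivity (recall), specificity, precision and F1 from the
#' confusion counts, plus AUC computed as the midrank Mann-Whitney statistic
#' over the continuous scores.
#'
#' @param truth logical vector of actual per-minute labels.
#' @param pred logical vector of predicted labels.
#' @param scores optional numeric scores for AUC (omit to skip AUC).
#' @return A list with `counts` (TP/TN/FP/FN) and `ACC`, `SEN`, `SPE`,
#'   `PRE`, `F1`, `AUC`.
#' @examples
#' segmentMetrics(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE),
#'                scores = c(0.9, 0.4, 0.1))
#' @export
segmentMetrics <- function(truth, pred, scores = NULL) {
  truth <- as.logical(truth); pred <- as.logical(pred)
  if (length(truth) != length(pred))
    stop("truth and pred must have equal length")
  out <- .classMetrics(truth, pred)
  out$AUC <- if (!is.null(scores)) aucMidrank(truth, scores) else NA_real_
  out
}

#' Apnea-hypopnea index from per-minute detections
#'
#' `AHI = 60 / T * nSA`, where `T` is the recording time in annotated
#' minutes and `nSA` the number of minutes classified as containing
#' apnea/hypopnea.
#'
#' @param nSA number of SA minutes.
#' @param T recording time in minutes (> 0).
#' @return AHI in events per hour.
#' @examples
#' computeAHI(40, 480)  # 5
#' @export
computeAHI <- function(nSA, T) {
  if (T <= 0) stop("T must be positive")
  60 / T * nSA
}

#' Sleep-apnea-syndrome screening decision
#'
#' Positive when AHI is at or above the threshold (default 5 events/hour,
#' the clinical screening cutoff; the boundary itself is positive).
#'
#' @param ahi AHI in events per hour.
#' @param threshold diagnostic threshold (default 5).
#' @return Logical.
#' @export
diagnoseSAS <- function(ahi, threshold = 5) {
  ahi >= threshold
}

#' Per-recording SAS metrics
#'
#' Classification metrics on the predicted vs actual SAS status across
#' recordings, plus the Pearson correlation between predicted and actual
#' AHI.
#'
#' @param results data.frame with columns `record_id`, `T`, `n_sa_pred`,
#'   `n_sa_true`, `predicted_ahi`, `actual_ahi`, `predicted_sas`,
#'   `actual_sas` (as produced by [runExperiment()]).
#' @return A list with `counts`, `ACC`, `SEN`, `SPE`, `PRE`, `F1` and `r`.
#' @export
recordingMetrics <- function(results) {
  if (nrow(results) < 2) stop("need at least 2 recordings")
  out <- .classMetrics(results$actual_sas, results$predicted_sas)
  if (popSD(results$predicted_ahi) == 0 || popSD(results$actual_ahi) == 0)
    stop("Pearson r undefined: zero variance in an AHI vector")
  out$r <- cor(results$predicted_ahi, results$actual_ahi)
  out
}

.recordingTable <- function(groups, truth, pred, sasThreshold = 5) {
  ids <- unique(groups)
  do.call(rbind, lapply(ids, function(rid) {
    sel <- groups == rid
    T <- sum(sel)
    nPred <- sum(pred[sel]); nTrue <- sum(truth[sel])
    pAHI <- computeAHI(nPred, T); aAHI <- computeAHI(nTrue, T)
    data.frame(record_id = rid, T = T, n_sa_pred = nPred, n_sa_true = nTrue,
               predicted_ahi = pAHI, actual_ahi = aAHI,
               predicted_sas = diagnoseSAS(pAHI, sasThreshold),
               actual_sas = diagnoseSAS(aAHI, sasThreshold))
  }))
}

#' Run the full detection/diagnosis experiment
#'
#' Executes the complete pipeline on extracted per-minute features: for each
#' train/validation partition, fit the z-score normalization on training
#' rows only, assemble past/future windowed matrices, train the classifier,
#' predict validation segments, then aggregate per-minute detections into
#' per-recording AHI and SAS calls.
#'
#' In `"cv"` mode the partitions are grouped k-fold splits of the record
#' ids; every record is scored exactly once (when in its validation fold).
#' In `"train_test"` mode `trainIds`/`testIds` give one explicit partition;
#' overlapping sets are rejected.
#'
#' @param features a [SegmentFeatures-class] spanning all records.
#' @param config a [ClassifierConfig-class].
#' @param window a [WindowSpec-class].
#' @param split `"cv"` or `"train_test"`.
#' @param nFolds folds for `"cv"` (default 5).
#' @param trainIds,testIds record id sets for `"train_test"`.
#' @param seed seed for fold assignment and training.
#' @param sasThreshold AHI threshold for SAS (default 5).
#' @param edgePolicy edge policy for [assembleWindowedFeatures()].
#' @return A list with `segmentMetrics`, `foldAccuracy`, `recordingTable`,
#'   `recordingMetrics`, per-segment `predictions`, and a `runLog` recording
#'   every configuration value used.
#' @export
runExperiment <- function(features, config = classifierConfig("MLP"),
                          window = windowSpec(0, 0),
                          split = c("cv", "train_test"), nFolds = 5,
                          trainIds = NULL, testIds = NULL, seed = 1,
                          sasThreshold = 5, edgePolicy = "replicate") {
  split <- match.arg(split)
  stopifnot(is(features, "SegmentFeatures"))
  cd <- SummarizedExperiment::colData(features)
  allIds <- unique(cd$record_id)

  partitions <- if (split == "cv") {
    groupKFoldSplit(allIds, nFolds = nFolds, seed = seed)
  } else {
    if (is.null(trainIds) || is.null(testIds))
      stop("train_test mode requires trainIds and testIds")
    overlap <- intersect(trainIds, testIds)
    if (length(overlap))
      stop("records in both train and test: ",
           paste(overlap, collapse = ", "))
    list(list(train = trainIds, valid = testIds))
  }

  predAll <- rep(NA, ncol(features))
  scoreAll <- rep(NA_real_, ncol(features))
  foldAcc <- numeric(length(partitions))

  for (k in seq_along(partitions)) {
    part <- partitions[[k]]
    if (length(intersect(part$train, part$valid)))
      stop("fold ", k, ": train and validation records overlap")
    trainCols <- which(cd$record_id %in% part$train)
    validCols <- which(cd$record_id %in% part$valid)
    raw <- t(SummarizedExperiment::assay(features, "features"))
    norm <- normalizeFeatures(raw[trainCols, , drop = FALSE],
                              raw[validCols, , drop = FALSE])
    normed <- matrix(NA_real_, nrow = nrow(raw), ncol = ncol(raw))
    normed[trainCols, ] <- norm$train
    normed[validCols, ] <- norm$applyTo
    sub <- c(trainCols, validCols)
    fsub <- SegmentFeatures(t(normed[sub, , drop = FALSE]),
                            recordId = cd$record_id[sub],
                            minuteIndex = cd$minute_index[sub],
                            label = cd$label[sub], valid = cd$valid[sub])
    wm <- assembleWindowedFeatures(fsub, spec = window,
                                   edgePolicy = edgePolicy)
    isTrain <- wm@groups %in% part$train
    wmTrain <- new("WindowedMatrix", x = wm@x[isTrain, , drop = FALSE],
                   labels = wm@labels[isTrain], groups = wm@groups[isTrain],
                   minuteIndex = wm@minuteIndex[isTrain], spec = window)
    wmValid <- new("WindowedMatrix", x = wm@x[!isTrain, , drop = FALSE],
                   labels = wm@labels[!isTrain], groups = wm@groups[!isTrain],
                   minuteIndex = wm@minuteIndex[!isTrain], spec = window)
    if (length(unique(wmTrain@labels)) < 2 ||
        length(unique(wmValid@labels)) < 2)
      stop("fold ", k, " is missing a class")
    model <- trainClassifier(wmTrain, config)
    pr <- predictSegments(model, wmValid)
    foldAcc[[k]] <- mean(pr$labels == wmValid@labels)
    ## map predictions back to the global segment grid
    key <- paste(wmValid@groups, wmValid@minuteIndex)
    gkey <- paste(cd$record_id, cd$minute_index)
    at <- match(key, gkey)
    predAll[at] <- pr$labels
    scoreAll[at] <- pr$scores
  }

  scored <- !is.na(predAll)
  segM <- segmentMetrics(cd$label[scored], predAll[scored] == 1,
                         scores = scoreAll[scored])
  recTab <- .recordingTable(cd$record_id[scored], cd$label[scored],
                            predAll[scored] == 1, sasThreshold)
  recM <- if (nrow(recTab) >= 2 && popSD(recTab$predicted_ahi) > 0 &&
              popSD(recTab$actual_ahi) > 0)
    recordingMetrics(recTab) else NULL
  runLog <- list(
    classifier = config@kind, hyperparameters = config@params,
    classifier_seed = config@seed, window = c(past = window@past,
                                              future = window@future),
    split = split, n_folds = if (split == "cv") nFolds else NA,
    seed = seed, sas_threshold = sasThreshold, edge_policy = edgePolicy,
    n_records = length(allIds), n_segments = ncol(features))
  list(segmentMetrics = segM, foldAccuracy = foldAcc,
       recordingTable = recTab, recordingMetrics = recM,
       predictions = data.frame(record_id = cd$record_id[scored],
                                minute_index = cd$minute_index[scored],
                                label = cd$label[scored],
                                predicted = predAll[scored] == 1,
                                score = scoreAll[scored]),
       runLog = runLog)
}

#' Write an experiment report as JSON
#'
#' Serializes the metric blocks, confusion counts, per-record AHI pairs and
#' the run log of a [runExperiment()] result to a JSON file with full
#' numeric precision.
#'
#' @param result a [runExperiment()] result.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeExperimentReport <- function(result, path) {
  payload <- list(
    segment_metrics = result$segmentMetrics[c("ACC", "SEN", "SPE", "PRE",
                                              "F1", "AUC")],
    confusion = as.list(result$segmentMetrics$counts),
    fold_accuracy = result$foldAccuracy,
    recording_metrics = if (!is.null(result$recordingMetrics))
      result$recordingMetrics[c("ACC", "SEN", "SPE", "PRE", "F1", "r")],
    recordings = result$recordingTable,
    run_log = result$runLog)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
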