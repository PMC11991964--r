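#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats median sd fft spline approx quantile rnorm runif rbinom
#'   predict glm.fit binomial cor setNames
#' @importFrom utils read.table write.table head tail
NULL

## Canonical per-minute feature layout: 6 time-domain + 6 RR-spectral +
## 6 amplitude-spectral names, in the exact column order used by feature tables.
.FEATURE_NAMES <- c(
  "MRR", "MHR", "RMSSD", "SDNN", "NN50", "pNN50",
  "rr_VLF", "rr_LF", "rr_HF", "rr_LF_HF", "rr_LF_norm", "rr_HF_norm",
  "amp_VLF", "amp_LF", "amp_HF", "amp_LF_HF", "amp_LF_norm", "amp_HF_norm"
)

#' ECGRecord: a single-lead ECG recording
#'
#' Holds one continuous single-lead ECG signal together with its sampling
#' rate and identifier. Values are in millivolts or any consistent
#' dimensionless scale.
#'
#' @slot recordId character(1) identifier.
#' @slot samplingRate sampling rate in Hz (must be > 0).
#' @slot samples numeric vector of signal samples.
#' @export
setClass("ECGRecord",
  representation(
    recordId = "character",
    samplingRate = "numeric",
    samples = "numeric"
  )
)

setValidity("ECGRecord", function(object) {
  msg <- character()
  if (length(object@recordId) != 1L || is.na(object@recordId))
    msg <- c(msg, "recordId must be a single non-NA string")
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (anyNA(object@samples))
    msg <- c(msg, "samples must not contain NA")
  if (length(msg)) msg else TRUE
})

#' Construct an ECGRecord
#'
#' @param samples numeric vector of signal samples.
#' @param samplingRate sampling rate in Hz (default 100, the Apnea-ECG rate).
#' @param recordId identifier string.
#' @return An [ECGRecord-class] object.
#' @examples
#' rec <- ECGRecord(sin(seq(0, 2 * pi, length.out = 6000)), 100, "toy")
#' durationMinutes(rec)
#' @export
ECGRecord <- function(samples, samplingRate = 100, recordId = "record") {
  new("ECGRecord",
      recordId = as.character(recordId),
      samplingRate = as.numeric(samplingRate),
      samples = as.numeric(samples))
}

#' MinuteLabels: per-minute apnea annotations
#'
#' One logical per 1-minute segment; `TRUE` means the expert annotation marks
#' apnea/hypopnea present in that minute.
#'
#' @slot recordId character(1) identifier.
#' @slot labels logical vector, index 1 = first minute.
#' @export
setClass("MinuteLabels",
  representation(recordId = "character", labels = "logical")
)

setValidity("MinuteLabels", function(object) {
  msg <- character()
  if (length(object@recordId) != 1L)
    msg <- c(msg, "recordId must be a single string")
  if (anyNA(object@labels))
    msg <- c(msg, "labels must not contain NA")
  if (length(msg)) msg else TRUE
})

#' Construct MinuteLabels
#'
#' @param labels logical vector (TRUE = apnea/hypopnea in that minute).
#' @param recordId identifier string.
#' @return A [MinuteLabels-class] object.
#' @export
MinuteLabels <- function(labels, recordId = "record") {
  new("MinuteLabels", recordId = as.character(recordId),
      labels = as.logical(labels))
}

#' RPeakSeries: detected R peaks and RR intervals
#'
#' Detected R-peak times (seconds from record start, strictly increasing),
#' the filtered-signal amplitude at each peak, the raw RR intervals in ms,
#' and (after [medianCorrectRR()]) the cleaned RR series.
#'
#' @slot recordId character(1).
#' @slot peakTimes numeric, seconds, strictly increasing.
#' @slot peakAmplitudes numeric, one per peak.
#' @slot rrIntervals numeric, ms; `rrIntervals[i] = 1000 * (peakTimes[i+1] -
#'   peakTimes[i])`.
#' @slot correctedRR numeric, ms; length 0 until median correction is applied,
#'   then same length as `rrIntervals`.
#' @export
setClass("RPeakSeries",
  representation(
    recordId = "character",
    peakTimes = "numeric",
    peakAmplitudes = "numeric",
    rrIntervals = "numeric",
    correctedRR = "numeric"
  )
)

setValidity("RPeakSeries", function(object) {
  msg <- character()
  n <- length(object@peakTimes)
  if (n >= 2 && any(diff(object@peakTimes) <= 0))
    msg <- c(msg, "peakTimes must be strictly increasing")
  if (length(object@peakAmplitudes) != n)
    msg <- c(msg, "peakAmplitudes must match peakTimes in length")
  if (length(object@rrIntervals) != max(0L, n - 1L))
    msg <- c(msg, "rrIntervals must have length(peakTimes) - 1")
  if (length(object@rrIntervals) && any(object@rrIntervals <= 0))
    msg <- c(msg, "all rrIntervals must be positive")
  if (length(object@correctedRR) &&
      length(object@correctedRR) != length(object@rrIntervals))
    msg <- c(msg, "correctedRR must be empty or match rrIntervals in length")
  if (length(msg)) msg else TRUE
})

#' Construct an RPeakSeries
#'
#' @param peakTimes numeric, peak times in seconds, strictly increasing.
#' @param peakAmplitudes numeric, signal value at each peak.
#' @param recordId identifier string.
#' @param correctedRR optional cleaned RR series (ms).
#' @return An [RPeakSeries-class] object; RR intervals are derived from
#'   `peakTimes`.
#' @export
RPeakSeries <- function(peakTimes, peakAmplitudes, recordId = "record",
                        correctedRR = numeric()) {
  rr <- if (length(peakTimes) >= 2) diff(peakTimes) * 1000 else numeric()
  new("RPeakSeries",
      recordId = as.character(recordId),
      peakTimes = as.numeric(peakTimes),
      peakAmplitudes = as.numeric(peakAmplitudes),
      rrIntervals = rr,
      correctedRR = as.numeric(correctedRR))
}

#' SegmentFeatures: per-minute feature matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] with the 18 per-minute
#' features in rows (assay `"features"`) and one column per annotated 1-minute
#' segment. `colData` carries `record_id`, `minute_index` (0-based), `label`
#' and `valid`.
#'
#' @export
setClass("SegmentFeatures", contains = "SummarizedExperiment")

setValidity("SegmentFeatures", function(object) {
  msg <- character()
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'features' is required")
  need <- c("record_id", "minute_index", "label", "valid")
  miss <- setdiff(need, colnames(SummarizedExperiment::colData(object)))
  if (length(miss))
    msg <- c(msg, paste0("colData missing: ", paste(miss, collapse = ", ")))
  if (!identical(rownames(object), .FEATURE_NAMES))
    msg <- c(msg, "rownames must be the canonical 18 feature names")
  if (length(msg)) msg else TRUE
})

#' Construct a SegmentFeatures container
#'
#' @param features numeric matrix, 18 rows (canonical feature order), one
#'   column per segment.
#' @param recordId character vector, one per segment.
#' @param minuteIndex integer vector, 0-based minute index per segment.
#' @param label logical vector, apnea annotation per segment.
#' @param valid logical vector, whether the segment supported feature
#'   extraction.
#' @return A [SegmentFeatures-class] object.
#' @export
SegmentFeatures <- function(features, recordId, minuteIndex, label, valid) {
  stopifnot(nrow(features) == length(.FEATURE_NAMES))
  rownames(features) <- .FEATURE_NAMES
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = features),
    colData = S4Vectors::DataFrame(
      record_id = as.character(recordId),
      minute_index = as.integer(minuteIndex),
      label = as.logical(label),
      valid = as.logical(valid)
    )
  )
  new("SegmentFeatures", se)
}

#' WindowSpec: past/future time-window sizes
#'
#' @slot past integer minutes of past context, in \[0, 15\].
#' @slot future integer minutes of future context, in \[0, 15\].
#' @export
setClass("WindowSpec",
  representation(past = "integer", future = "integer")
)

setValidity("WindowSpec", function(object) {
  msg <- character()
  for (s in c("past", "future")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 0L || v > 15L)
      msg <- c(msg, paste0(s, " must be a single integer in [0, 15]"))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a WindowSpec
#'
#' `windowSpec(0, 0)` denotes the non-time window (no context).
#'
#' @param past minutes of past context (integer, 0-15).
#' @param future minutes of future context (integer, 0-15).
#' @return A [WindowSpec-class] object.
#' @export
windowSpec <- function(past = 0, future = 0) {
  new("WindowSpec", past = as.integer(past), future = as.integer(future))
}

#' WindowedMatrix: per-segment design matrix with time-window context
#'
#' One row per target segment; columns are the concatenated feature vectors
#' for minutes `t - past ... t ... t + future` (18 x (past + future + 1)
#' columns). Rows never mix features from different recordings.
#'
#' @slot x numeric design matrix.
#' @slot labels logical target-minute labels.
#' @slot groups character record id per row.
#' @slot minuteIndex integer 0-based target minute per row.
#' @slot spec the [WindowSpec-class] used.
#' @export
setClass("WindowedMatrix",
  representation(
    x = "matrix",
    labels = "logical",
    groups = "character",
    minuteIndex = "integer",
    spec = "WindowSpec"
  )
)

setValidity("WindowedMatrix", function(object) {
  msg <- character()
  n <- nrow(object@x)
  if (length(object@labels) != n || length(object@groups) != n ||
      length(object@minuteIndex) != n)
    msg <- c(msg, "labels, groups and minuteIndex must match nrow(x)")
  w <- object@spec
  if (ncol(object@x) !=
      length(.FEATURE_NAMES) * (w@past + w@future + 1L))
    msg <- c(msg, "ncol(x) must equal 18 * (past + future + 1)")
  if (length(msg)) msg else TRUE
})

#' ClassifierConfig: one of the five reference classifiers
#'
#' @slot kind one of "MLP", "SVM", "RF", "XGBoost", "LR".
#' @slot params named list of hyperparameters.
#' @slot seed integer RNG seed used for training.
#' @export
setClass("ClassifierConfig",
  representation(kind = "character", params = "list", seed = "integer")
)

setValidity("ClassifierConfig", function(object) {
  if (!object@kind %in% c("MLP", "SVM", "RF", "XGBoost", "LR"))
    return("kind must be one of MLP, SVM, RF, XGBoost, LR")
  TRUE
})

#' ApneaModel: a trained per-segment classifier
#'
#' @slot config the [ClassifierConfig-class] used to train.
#' @slot fit the fitted model object (opaque).
#' @slot nFeatures expected feature count at prediction time.
#' @export
setClass("ApneaModel",
  representation(config = "ClassifierConfig", fit = "ANY",
                 nFeatures = "integer")
)
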