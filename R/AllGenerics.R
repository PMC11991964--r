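#' @describeIn ECGRecord-class record identifier
#' @param object an object of the documented class.
#' @export
setGeneric("recordId", function(object) standardGeneric("recordId"))

#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @export
setGeneric("samples", function(object) standardGeneric("samples"))

#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @export
setGeneric("durationMinutes", function(object) standardGeneric("durationMinutes"))

#' @export
setGeneric("minuteLabels", function(object) standardGeneric("minuteLabels"))

#' @export
setGeneric("peakTimes", function(object) standardGeneric("peakTimes"))

#' @export
setGeneric("peakAmplitudes", function(object) standardGeneric("peakAmplitudes"))

#' @export
setGeneric("rrIntervals", function(object) standardGeneric("rrIntervals"))

#' @export
setGeneric("correctedRR", function(object) standardGeneric("correctedRR"))

#' @export
setGeneric("windowPast", function(object) standardGeneric("windowPast"))

#' @export
setGeneric("windowFuture", function(object) standardGeneric("windowFuture"))

#' @export
setGeneric("designMatrix", function(object) standardGeneric("designMatrix"))

#' @export
setGeneric("segmentLabels", function(object) standardGeneric("segmentLabels"))

#' @export
setGeneric("segmentGroups", function(object) standardGeneric("segmentGroups"))

setMethod("recordId", "ECGRecord", function(object) object@recordId)
setMethod("samplingRate", "ECGRecord", function(object) object@samplingRate)
setMethod("samples", "ECGRecord", function(object) object@samples)
setMethod("nSamples", "ECGRecord", function(object) length(object@samples))
setMethod("durationMinutes", "ECGRecord", function(object)
  length(object@samples) / (object@samplingRate * 60))

setMethod("recordId", "MinuteLabels", function(object) object@recordId)
setMethod("minuteLabels", "MinuteLabels", function(object) object@labels)
setMethod("length", "MinuteLabels", function(x) length(x@labels))

setMethod("recordId", "RPeakSeries", function(object) object@recordId)
setMethod("peakTimes", "RPeakSeries", function(object) object@peakTimes)
setMethod("peakAmplitudes", "RPeakSeries", function(object) object@peakAmplitudes)
setMethod("rrIntervals", "RPeakSeries", function(object) object@rrIntervals)
setMethod("correctedRR", "RPeakSeries", function(object) object@correctedRR)

setMethod("windowPast", "WindowSpec", function(object) object@past)
setMethod("windowFuture", "WindowSpec", function(object) object@future)

setMethod("designMatrix", "WindowedMatrix", function(object) object@x)
setMethod("segmentLabels", "WindowedMatrix", function(object) object@labels)
setMethod("segmentGroups", "WindowedMatrix", function(object) object@groups)

setMethod("show", "ECGRecord", function(object) {
  cat(sprintf("ECGRecord '%s': %d samples @ %g Hz (%.2f min)\n",
              object@recordId, length(object@samples), object@samplingRate,
              durationMinutes(object)))
})

setMethod("show", "MinuteLabels", function(object) {
  cat(sprintf("MinuteLabels '%s': %d minutes, %d apneic (%.1f%%)\n",
              object@recordId, length(object@labels), sum(object@labels),
              100 * mean(object@labels)))
})

setMethod("show", "RPeakSeries", function(object) {
  corr <- if (length(object@correctedRR)) "corrected" else "raw"
  cat(sprintf("RPeakSeries '%s': %d peaks, %d RR intervals (%s)\n",
              object@recordId, length(object@peakTimes),
              length(object@rrIntervals), corr))
  if (length(object@rrIntervals))
    cat(sprintf("  median RR %.1f ms\n", median(object@rrIntervals)))
})

setMethod("show", "WindowSpec", function(object) {
  cat(sprintf("WindowSpec(past = %d, future = %d)\n",
              object@past, object@future))
})

setMethod("show", "WindowedMatrix", function(object) {
  cat(sprintf(
    "WindowedMatrix: %d segments x %d features (past %d, future %d), %d records\n",
    nrow(object@x), ncol(object@x), object@spec@past, object@spec@future,
    length(unique(object@groups))))
})

setMethod("show", "ClassifierConfig", function(object) {
  cat(sprintf("ClassifierConfig '%s' (seed %d)\n", object@kind, object@seed))
  p <- object@params
  if (length(p))
    cat(paste0("  ", names(p), " = ", vapply(p, format, ""), "\n"), sep = "")
})

setMethod("show", "ApneaModel", function(object) {
  cat(sprintf("ApneaModel: %s trained on %d features\n",
              object@config@kind, object@nFeatures))
})
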