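#' FilterSpec: FIR bandpass design parameters
#'
#' @slot lowCut low cutoff in Hz (default 3).
#' @slot highCut high cutoff in Hz (default 45).
#' @slot nTaps number of taps; odd, so the group delay is an integer and the
#'   linear-phase filter can be made exactly zero-phase. `NA` means
#'   "next odd >= sampling rate" (about a 1 s impulse response).
#' @export
setClass("FilterSpec",
  representation(lowCut = "numeric", highCut = "numeric", nTaps = "integer")
)

#' Construct a FilterSpec
#'
#' Defaults are the 3-45 Hz QRS passband; baseline wander (< 0.5 Hz) and
#' 50/60 Hz mains hum fall in the stopbands.
#'
#' @param lowCut low cutoff, Hz.
#' @param highCut high cutoff, Hz.
#' @param nTaps odd tap count, or `NA` to derive from the sampling rate.
#' @return A [FilterSpec-class].
#' @export
filterSpec <- function(lowCut = 3, highCut = 45, nTaps = NA) {
  new("FilterSpec", lowCut = as.numeric(lowCut), highCut = as.numeric(highCut),
      nTaps = as.integer(nTaps))
}

.resolveTaps <- function(spec, fs) {
  n <- spec@nTaps
  if (is.na(n)) {
    n <- as.integer(ceiling(fs))
    if (n %% 2L == 0L) n <- n + 1L
  }
  if (n %% 2L == 0L) stop("nTaps must be odd")
  n
}

#' Zero-phase FIR bandpass filter
#'
#' Windowed-sinc (Hamming) linear-phase FIR bandpass, applied forward with
#' exact group-delay compensation, so the output has zero net phase shift
#' and the same length as the input. Edges are handled by signal reflection.
#'
#' @param record an [ECGRecord-class].
#' @param spec a [FilterSpec-class]; cutoffs must satisfy
#'   `0 < lowCut < highCut < samplingRate / 2`.
#' @return The filtered [ECGRecord-class].
#' @examples
#' fs <- 100
#' t <- seq(0, 10, by = 1 / fs)
#' rec <- ECGRecord(sin(2 * pi * 10 * t), fs)
#' filt <- bandpassFIR(rec)
#' @export
bandpassFIR <- function(record, spec = filterSpec()) {
  stopifnot(is(record, "ECGRecord"), is(spec, "FilterSpec"))
  fs <- samplingRate(record)
  if (!(0 < spec@lowCut && spec@lowCut < spec@highCut &&
        spec@highCut < fs / 2))
    stop("require 0 < lowCut < highCut < samplingRate/2")
  n <- .resolveTaps(spec, fs)
  x <- samples(record)
  if (length(x) < n)
    stop("record shorter than the filter (", length(x), " < ", n, " samples)")
  b <- as.numeric(signal::fir1(n - 1L, c(spec@lowCut, spec@highCut) / (fs / 2),
                               type = "pass", window = signal::hamming(n)))
  d <- (n - 1L) %/% 2L
  # reflect d samples at each edge, filter causally, then undo the delay
  xpad <- c(rev(x[2:(d + 1L)]), x, rev(x[(length(x) - d):(length(x) - 1L)]))
  y <- as.numeric(signal::filter(b, 1, xpad))
  ECGRecord(y[(2L * d + 1L):(2L * d + length(x))],
            samplingRate = fs, recordId = recordId(record))
}

#' Hamilton-style R-peak detection
#'
#' Detects QRS complexes on a bandpass-filtered single-lead ECG using the
#' Hamilton scheme: differentiate, rectify, integrate over a short moving
#' window, then accept integrated-signal peaks against an adaptive threshold
#' between running averages of recent QRS and noise peaks, with a refractory
#' period and a search-back pass that rescues beats missed in long gaps.
#' Each detection is then localized to the filtered-signal maximum in a
#' small neighbourhood, where the R amplitude is read.
#'
#' @param filtered a bandpass-filtered [ECGRecord-class].
#' @param integrationMs moving-integration window, ms (default 80).
#' @param refractoryMs minimum separation between beats, ms (default 200).
#'   Setting this to 0 disables the refractory rule (duplicates may appear).
#' @param thresholdCoef detection threshold position between the noise and
#'   QRS running averages (default 0.3125).
#' @param searchBackFactor gaps longer than this multiple of the running
#'   mean RR trigger search-back at half threshold (default 1.5).
#' @param tWaveMs candidates closer than this to the previous beat whose
#'   peak slope is below half the previous QRS slope are classified as
#'   T waves and rejected (default 360).
#' @param localizeMs half-width of the R-peak localization window, ms
#'   (default 100).
#' @return An [RPeakSeries-class] with peak times, amplitudes from the
#'   filtered signal, and raw RR intervals.
#' @export
detectRPeaks <- function(filtered, integrationMs = 80, refractoryMs = 200,
                         thresholdCoef = 0.3125, searchBackFactor = 1.5,
                         tWaveMs = 360, localizeMs = 100) {
  stopifnot(is(filtered, "ECGRecord"))
  fs <- samplingRate(filtered)
  x <- samples(filtered)
  if (length(x) < fs) stop("insufficient beats: record too short")

  ## feature signal: |derivative| integrated over ~integrationMs
  dx <- abs(diff(x))
  w <- max(1L, as.integer(round(integrationMs / 1000 * fs)))
  ma <- as.numeric(stats::filter(dx, rep(1 / w, w), sides = 1))
  ma[is.na(ma)] <- 0

  ## candidate peaks: strict local maxima of the integrated signal
  n <- length(ma)
  cand <- which(ma[2:(n - 1)] > ma[1:(n - 2)] & ma[2:(n - 1)] >= ma[3:n]) + 1L
  if (length(cand) < 2) stop("insufficient beats: fewer than 2 candidates")

  refr <- refractoryMs / 1000 * fs
  tRefr <- tWaveMs / 1000 * fs
  slopeW <- max(1L, as.integer(round(0.04 * fs)))  # slope window ~40 ms
  peakSlope <- function(i) max(dx[max(1L, i - slopeW):min(length(dx), i)])
  ## QRS-related maxima are a small top fraction of all candidates, so the
  ## running signal estimate starts at a high quantile of candidate heights
  spk <- as.numeric(quantile(ma[cand], 0.98))
  npk <- as.numeric(quantile(ma[cand], 0.5))
  qrs <- integer()
  lastQrs <- -Inf
  lastSlope <- Inf
  rrHist <- numeric()

  acceptPeak <- function(i) {
    qrs[[length(qrs) + 1L]] <<- i
    if (is.finite(lastQrs)) {
      rrHist[[length(rrHist) + 1L]] <<- i - lastQrs
      if (length(rrHist) > 8L) rrHist <<- tail(rrHist, 8L)
    }
    lastQrs <<- i
    lastSlope <<- peakSlope(i)
    spk <<- 0.875 * spk + 0.125 * ma[i]
  }

  for (k in seq_along(cand)) {
    i <- cand[[k]]
    if (i - lastQrs < refr) next
    ## T-wave rule: low-slope candidate shortly after a beat is repolarization
    if (i - lastQrs < tRefr && peakSlope(i) < 0.5 * lastSlope) {
      npk <- 0.875 * npk + 0.125 * ma[i]
      next
    }
    thr <- npk + thresholdCoef * (spk - npk)
    if (ma[i] >= thr) {
      ## search-back: long gap since the last beat -> rescue the best
      ## sub-threshold candidate inside the gap at half threshold
      if (length(rrHist) >= 2 && is.finite(lastQrs) &&
          (i - lastQrs) > searchBackFactor * mean(rrHist)) {
        gap <- cand[cand > lastQrs + refr & cand < i - refr]
        if (length(gap)) {
          j <- gap[[which.max(ma[gap])]]
          if (ma[j] >= 0.5 * thr) acceptPeak(j)
        }
      }
      acceptPeak(i)
    } else {
      npk <- 0.875 * npk + 0.125 * ma[i]
    }
  }
  if (length(qrs) < 2) stop("insufficient beats: fewer than 2 peaks detected")

  ## localize each detection to the filtered-signal maximum nearby
  half <- as.integer(round(localizeMs / 1000 * fs))
  loc <- vapply(qrs, function(i) {
    lo <- max(1L, i - half); hi <- min(length(x), i + half)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  loc <- sort(unique(loc))
  ## enforce the refractory rule on localized peaks, keeping the larger one
  if (refr > 0 && length(loc) > 1) {
    keep <- loc[[1]]
    for (i in loc[-1]) {
      if (i - tail(keep, 1) < refr) {
        if (x[i] > x[tail(keep, 1)]) keep[length(keep)] <- i
      } else keep <- c(keep, i)
    }
    loc <- keep
  }
  if (length(loc) < 2) stop("insufficient beats: fewer than 2 peaks detected")
  RPeakSeries(peakTimes = (loc - 1L) / fs, peakAmplitudes = x[loc],
              recordId = recordId(filtered))
}

#' Conditional median correction of RR intervals
#'
#' Replaces physiologically uninterpretable RR intervals (outside
#' `[rrMin, rrMax]`) by the median of a window of beats centered on the
#' suspect interval; in-band intervals pass through unchanged. Edge windows
#' shrink symmetrically. If a window median still falls outside the band it
#' is clamped to the nearest bound, which makes the operation idempotent.
#'
#' @param series an [RPeakSeries-class].
#' @param windowBeats odd window length in beats (default 5).
#' @param rrMin,rrMax physiological band in ms (defaults 300 and 2000).
#' @return The series with the `correctedRR` slot filled.
#' @examples
#' s <- RPeakSeries(cumsum(c(0, 800, 810, 2500, 805, 795)) / 1000, rep(1, 6))
#' correctedRR(medianCorrectRR(s))
#' @export
medianCorrectRR <- function(series, windowBeats = 5, rrMin = 300,
                            rrMax = 2000) {
  stopifnot(is(series, "RPeakSeries"))
  rr <- rrIntervals(series)
  if (length(rr) < 3) stop("need at least 3 RR intervals")
  if (windowBeats %% 2 != 1) stop("windowBeats must be odd")
  inBand <- rr >= rrMin & rr <= rrMax
  if (!any(inBand))
    stop("all RR intervals are outside [", rrMin, ", ", rrMax, "] ms")
  out <- rr
  half <- (windowBeats - 1) / 2
  n <- length(rr)
  for (i in which(!inBand)) {
    r <- min(half, i - 1, n - i)   # shrink symmetrically at the edges
    m <- median(rr[(i - r):(i + r)])
    out[[i]] <- min(max(m, rrMin), rrMax)
  }
  initialize(series, correctedRR = out)
}
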