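#' BandDefinition: HRV frequency bands
#'
#' Contiguous, non-overlapping half-open bands `[lo, hi)` in Hz:
#' VLF 0-0.04, LF 0.04-0.15, HF 0.15-0.4 by default.
#'
#' @slot vlf,lf,hf numeric length-2 `(lo, hi)` in Hz.
#' @export
setClass("BandDefinition",
  representation(vlf = "numeric", lf = "numeric", hf = "numeric")
)

setValidity("BandDefinition", function(object) {
  b <- rbind(object@vlf, object@lf, object@hf)
  if (ncol(b) != 2 || any(b[, 1] >= b[, 2]))
    return("each band must be (lo, hi) with lo < hi")
  if (object@vlf[2] != object@lf[1] || object@lf[2] != object@hf[1])
    return("bands must be contiguous: vlf hi == lf lo, lf hi == hf lo")
  TRUE
})

#' Construct a BandDefinition
#' @param vlf,lf,hf numeric `(lo, hi)` pairs in Hz.
#' @return A [BandDefinition-class].
#' @export
bandDefinition <- function(vlf = c(0, 0.04), lf = c(0.04, 0.15),
                           hf = c(0.15, 0.4)) {
  new("BandDefinition", vlf = vlf, lf = lf, hf = hf)
}

#' SpectralEstimatorSpec: Welch PSD settings for beat-series spectra
#'
#' The irregular beat-indexed series is cubic-interpolated onto a uniform
#' grid at `resampleRate`, mean-removed, Hamming-windowed and transformed
#' with an FFT of length `fftLength`. A 1-minute segment at 3 Hz yields
#' fewer samples than the FFT length, so the estimate is a single
#' zero-padded (modified) periodogram — deterministic by construction.
#' Longer inputs are split into 50%-overlapping segments and averaged.
#'
#' @slot resampleRate uniform resampling rate, Hz (default 3).
#' @slot fftLength FFT length (default 256).
#' @slot windowFunction window name, `"hamming"` or `"hann"`.
#' @slot detrend if `TRUE`, the series mean is removed before windowing.
#' @export
setClass("SpectralEstimatorSpec",
  representation(resampleRate = "numeric", fftLength = "integer",
                 windowFunction = "character", detrend = "logical")
)

#' Construct a SpectralEstimatorSpec
#' @param resampleRate resampling rate in Hz.
#' @param fftLength FFT length.
#' @param windowFunction `"hamming"` or `"hann"`.
#' @param detrend remove the mean before windowing.
#' @return A [SpectralEstimatorSpec-class].
#' @export
spectralEstimatorSpec <- function(resampleRate = 3, fftLength = 256,
                                  windowFunction = "hamming",
                                  detrend = TRUE) {
  new("SpectralEstimatorSpec", resampleRate = as.numeric(resampleRate),
      fftLength = as.integer(fftLength),
      windowFunction = match.arg(windowFunction, c("hamming", "hann")),
      detrend = as.logical(detrend))
}

#' Beats belonging to one 1-minute segment
#'
#' RR intervals are assigned to the minute containing their terminating R
#' peak; amplitudes to the minute containing the peak. Both use the
#' half-open window `[60 m, 60 (m + 1))` seconds.
#'
#' @param series an [RPeakSeries-class].
#' @param minuteIndex 0-based minute index.
#' @param useCorrected use `correctedRR` when available (default `TRUE`).
#' @return A list with `rr` (ms), `amp`, and `times` (peak seconds) for the
#'   segment; components may be empty.
#' @export
segmentBeats <- function(series, minuteIndex, useCorrected = TRUE) {
  stopifnot(is(series, "RPeakSeries"))
  t0 <- 60 * minuteIndex
  t1 <- 60 * (minuteIndex + 1)
  pt <- peakTimes(series)
  inWin <- pt >= t0 & pt < t1
  rr <- if (useCorrected && length(correctedRR(series)))
    correctedRR(series) else rrIntervals(series)
  ## rr[i] terminates at peak i + 1
  termIn <- if (length(rr)) inWin[-1] else logical()
  list(rr = rr[termIn], amp = peakAmplitudes(series)[inWin],
       times = pt[inWin])
}

#' Time-domain HRV features of one segment
#'
#' Computes MRR (mean RR, ms), MHR (mean of the per-beat instantaneous heart
#' rate, bpm), RMSSD (ms), SDNN (ms), NN50 (count of successive differences
#' exceeding 50 ms) and pNN50 (NN50 divided by the number of RR intervals).
#'
#' @param rr numeric RR intervals in ms (at least 2).
#' @param sdnnSample if `TRUE` use the sample (n-1) standard deviation for
#'   SDNN instead of the population form (default `FALSE`).
#' @return Named numeric vector `MRR, MHR, RMSSD, SDNN, NN50, pNN50`.
#' @examples
#' timeDomainFeatures(c(800, 850, 790))
#' @export
timeDomainFeatures <- function(rr, sdnnSample = FALSE) {
  if (length(rr) < 2) stop("need at least 2 RR intervals")
  d <- diff(rr)
  nn50 <- sum(abs(d) > 50)
  c(MRR = mean(rr),
    MHR = mean(60000 / rr),
    RMSSD = sqrt(mean(d^2)),
    SDNN = if (sdnnSample) sd(rr) else popSD(rr),
    NN50 = as.numeric(nn50),
    pNN50 = nn50 / length(rr))
}

## One-sided Welch PSD of a numeric vector sampled at rate fs.
## Returns list(freq, psd) with psd in value^2 / Hz.
welchPSD <- function(x, fs, fftLength = 256L, window = "hamming",
                     detrend = TRUE) {
  n <- length(x)
  if (detrend) x <- x - mean(x)
  segLen <- min(n, fftLength)
  step <- max(1L, segLen %/% 2L)
  starts <- seq(1L, max(1L, n - segLen + 1L), by = step)
  w <- if (window == "hamming")
    0.54 - 0.46 * cos(2 * pi * (0:(segLen - 1)) / (segLen - 1))
  else
    0.5 - 0.5 * cos(2 * pi * (0:(segLen - 1)) / (segLen - 1))
  scale <- 1 / (fs * sum(w^2))
  nf <- fftLength %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + segLen - 1L)] * w
    seg <- c(seg, numeric(fftLength - segLen))   # zero-pad to fftLength
    X <- fft(seg)[seq_len(nf)]
    acc <- acc + scale * (Mod(X)^2)
  }
  psd <- acc / length(starts)
  psd[2:(nf - 1L)] <- 2 * psd[2:(nf - 1L)]       # one-sided
  list(freq = (seq_len(nf) - 1L) * fs / fftLength, psd = psd)
}

.bandIntegral <- function(freq, psd, lo, hi) {
  df <- freq[2] - freq[1]
  sum(psd[freq >= lo & freq < hi]) * df
}

#' Band powers of a beat-indexed series
#'
#' Cubic-interpolates an irregular series (values at beat times) onto a
#' uniform grid, removes the mean and estimates the PSD by the Welch method
#' (see [spectralEstimatorSpec()]). Band power is the PSD integral over each
#' half-open band; ratios are LF/HF, LF/(LF+HF), HF/(LF+HF). If LF + HF is
#' zero, all three ratios are defined as 0 (degenerate-segment rule).
#'
#' @param times numeric, seconds at which `values` are observed.
#' @param values numeric series (e.g. RR in ms, or R amplitudes).
#' @param estimator a [SpectralEstimatorSpec-class].
#' @param bands a [BandDefinition-class].
#' @param ratioConvention `"sum"` for LF/(LF+HF) and HF/(LF+HF) (default) or
#'   `"literal"` for LF/(LF/HF) and HF/(LF/HF).
#' @return Named numeric `VLF, LF, HF, LF_HF, LF_norm, HF_norm`, or all-`NA`
#'   when the series has fewer than 4 points or spans less than 30 s.
#' @export
bandPowers <- function(times, values, estimator = spectralEstimatorSpec(),
                       bands = bandDefinition(),
                       ratioConvention = c("sum", "literal")) {
  ratioConvention <- match.arg(ratioConvention)
  empty <- c(VLF = NA_real_, LF = NA_real_, HF = NA_real_,
             LF_HF = NA_real_, LF_norm = NA_real_, HF_norm = NA_real_)
  if (length(times) < 4 || (max(times) - min(times)) < 30) return(empty)
  grid <- seq(min(times), max(times), by = 1 / estimator@resampleRate)
  if (length(grid) < 8) return(empty)
  y <- spline(times, values, xout = grid, method = "fmm")$y
  sp <- welchPSD(y, fs = estimator@resampleRate,
                 fftLength = estimator@fftLength,
                 window = estimator@windowFunction,
                 detrend = estimator@detrend)
  vlf <- .bandIntegral(sp$freq, sp$psd, bands@vlf[1], bands@vlf[2])
  lf <- .bandIntegral(sp$freq, sp$psd, bands@lf[1], bands@lf[2])
  hf <- .bandIntegral(sp$freq, sp$psd, bands@hf[1], bands@hf[2])
  tot <- lf + hf
  if (tot > 0) {
    lfhf <- if (hf > 0) lf / hf else 0
    if (ratioConvention == "sum") {
      lfn <- lf / tot; hfn <- hf / tot
    } else {
      lfn <- if (lfhf > 0) lf / lfhf else 0
      hfn <- if (lfhf > 0) hf / lfhf else 0
    }
  } else {
    lfhf <- 0; lfn <- 0; hfn <- 0
  }
  c(VLF = vlf, LF = lf, HF = hf, LF_HF = lfhf, LF_norm = lfn, HF_norm = hfn)
}

#' Extract the 18 per-minute features of a recording
#'
#' For every annotated minute, computes the 6 time-domain RR features, the 6
#' RR spectral features, and the 6 R-amplitude spectral features. Segments
#' with fewer than `minBeats` beats, or whose beat series cannot support
#' spectral estimation, are marked `valid = FALSE` with `NA` features (the
#' classification pipeline later imputes them with training-set means so the
#' per-minute grid stays intact for AHI).
#'
#' @param series an [RPeakSeries-class] (median-corrected RR recommended).
#' @param labels the matching [MinuteLabels-class].
#' @param estimator a [SpectralEstimatorSpec-class].
#' @param bands a [BandDefinition-class].
#' @param minBeats minimum beats per minute for a valid segment (default 10).
#' @param sdnnSample see [timeDomainFeatures()].
#' @param ampRatioConvention ratio convention for the amplitude family;
#'   see [bandPowers()].
#' @return A [SegmentFeatures-class] with one column per annotated minute.
#' @export
extractRecordingFeatures <- function(series, labels,
                                     estimator = spectralEstimatorSpec(),
                                     bands = bandDefinition(),
                                     minBeats = 10, sdnnSample = FALSE,
                                     ampRatioConvention = "sum") {
  stopifnot(is(series, "RPeakSeries"), is(labels, "MinuteLabels"))
  if (recordId(series) != recordId(labels))
    stop("record id mismatch: '", recordId(series), "' vs '",
         recordId(labels), "'")
  nSeg <- length(minuteLabels(labels))
  feat <- matrix(NA_real_, nrow = length(.FEATURE_NAMES), ncol = nSeg,
                 dimnames = list(.FEATURE_NAMES, NULL))
  valid <- logical(nSeg)
  for (m in seq_len(nSeg) - 1L) {
    seg <- segmentBeats(series, m)
    if (length(seg$amp) < minBeats || length(seg$rr) < 2) next
    rrTimes <- seg$times[seq.int(length(seg$times) - length(seg$rr) + 1L,
                                 length(seg$times))]
    rrF <- bandPowers(rrTimes, seg$rr, estimator, bands)
    ampF <- bandPowers(seg$times, seg$amp, estimator, bands,
                       ratioConvention = ampRatioConvention)
    if (anyNA(rrF) || anyNA(ampF)) next
    feat[, m + 1L] <- c(timeDomainFeatures(seg$rr, sdnnSample), rrF, ampF)
    valid[[m + 1L]] <- TRUE
  }
  SegmentFeatures(feat, recordId = rep(recordId(labels), nSeg),
                  minuteIndex = seq_len(nSeg) - 1L,
                  label = minuteLabels(labels), valid = valid)
}

#' Z-score normalization fit on a training partition
#'
#' Centers and scales every feature with the training-set mean and
#' population standard deviation, then applies the same transform to an
#' optional second matrix (no leakage from validation/test rows). Constant
#' features get scale 1. `NA` entries (invalid segments) are excluded from
#' the statistics and imputed with the training mean, i.e. 0 after scaling.
#'
#' @param train numeric matrix, rows = segments.
#' @param applyTo optional matrix with the same columns.
#' @return A list with `train`, `applyTo` (or `NULL`), `center`, `scale`.
#' @export
normalizeFeatures <- function(train, applyTo = NULL) {
  train <- as.matrix(train)
  if (nrow(train) < 2) stop("need at least 2 training rows")
  center <- apply(train, 2, function(v) mean(v[!is.na(v)]))
  center[is.na(center)] <- 0
  scale <- apply(train, 2, popSD)
  scale[is.na(scale) | scale == 0] <- 1
  tf <- function(m) {
    m <- sweep(m, 2, center, "-")
    m <- sweep(m, 2, scale, "/")
    m[is.na(m)] <- 0
    m
  }
  list(train = tf(train),
       applyTo = if (!is.null(applyTo)) tf(as.matrix(applyTo)),
       center = center, scale = scale)
}
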