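#' SynthConfig: synthetic recording generator settings
#'
#' Study conditions for the synthetic single-lead ECG generator. Apneic
#' minutes carry a slow cyclical RR oscillation (cyclic bradycardia-
#' tachycardia at `cvhrFreq`, inside the VLF band the spectral features
#' sense) plus R-amplitude modulation at the same frequency; normal minutes
#' carry respiratory sinus arrhythmia at `rsaFreq` (HF band). The rendered
#' signal adds baseline wander, powerline hum and broadband noise.
#'
#' @slot nRecords number of recordings.
#' @slot minutesPerRecord annotated minutes per recording (default 60).
#' @slot normalLenRange,apneaLenRange integer `(min, max)` episode lengths
#'   in minutes for normal and apneic runs.
#' @slot baselineRR mean RR in ms (default 850).
#' @slot baselineJitter between-record SD of the baseline RR, ms.
#' @slot rsaAmplitude,rsaFreq RSA oscillation: ms and Hz (30 ms at 0.25 Hz).
#'   RSA is present in every minute with per-minute amplitude variability;
#'   apneic minutes retain a reduced RSA (obstructive events keep
#'   respiratory effort), normal minutes a fuller one.
#' @slot lfAmplitude,lfFreq Mayer-wave-like LF oscillation present in all
#'   minutes: ms and Hz (25 ms at 0.095 Hz); overlaps the band the apneic
#'   signature leaks into, so single minutes are not trivially separable.
#' @slot cvhrAmplitude,cvhrFreq apneic RR oscillation: ms and Hz
#'   (70 ms at 0.025 Hz).
#' @slot cvhrVar per-minute relative jitter of the apneic oscillation
#'   strength (0-1); some apneic minutes express the signature weakly.
#' @slot postEpisodeDecay numeric vector of carry-over factors: the cyclic
#'   heart-rate response persists after an episode ends, so the k-th minute
#'   after an apneic minute still expresses the oscillation at this
#'   fraction of its strength. This puts apnea-like power into normal
#'   minutes bordering episodes; resolving them requires temporal context.
#' @slot onsetRamp expression fraction of the first minute of each apneic
#'   episode (default 0.5): the cyclic response builds up after onset, so
#'   episode-start minutes are weakly expressed and future context is
#'   needed to classify them.
#' @slot normalVlfSd scale (ms) of non-apneic VLF activity: each normal
#'   minute gets a slow oscillation at `normalVlfFreq` with amplitude drawn
#'   half-normal with this SD (sleep-stage drifts and arousals put VLF power
#'   into normal minutes too, so the bands overlap between classes).
#' @slot normalVlfFreq frequency of the non-apneic VLF activity, Hz.
#' @slot ampModDepth fractional R-amplitude modulation in apneic minutes.
#' @slot respAmpDepth fractional R-amplitude modulation at `rsaFreq` in
#'   normal minutes (respiration modulates R amplitude in everyone).
#' @slot ampDriftSd scale of slow non-apneic amplitude drift: each normal
#'   minute gets an amplitude oscillation at `normalVlfFreq` with depth
#'   drawn half-normal with this SD (posture and electrode-impedance
#'   drifts put slow amplitude power into normal minutes too).
#' @slot ampJitterSd per-beat white jitter of the R-amplitude factor.
#' @slot rrJitterSd per-beat white RR jitter, ms.
#' @slot noiseSd broadband noise SD, signal units.
#' @slot wanderAmplitude,wanderFreq baseline wander: units and Hz (0.3 Hz).
#' @slot humAmplitude,humFreq powerline hum: units and Hz (50 Hz).
#' @slot ectopicRate per-beat probability of an ectopic-like RR spike
#'   (default 0; used to exercise the median filter).
#' @slot healthyFraction fraction of recordings drawn as non-SAS controls
#'   (default 0: every default recording is apneic-type, with its
#'   apneic-minute fraction in 0.1-0.7). Set to e.g. 1/3 to emulate a
#'   screening cohort: a control record carries at most `healthyMaxEvents`
#'   isolated apneic minutes, so its AHI stays below the screening
#'   threshold, and controls are interleaved deterministically across the
#'   record sequence so any contiguous train/test split contains both
#'   recording classes (needed for per-recording SAS specificity).
#' @slot healthyMaxEvents maximum apneic minutes in a control recording
#'   (default 4; with 60 annotated minutes the AHI is then at most 4).
#' @slot seed master seed.
#' @export
setClass("SynthConfig",
  representation(
    nRecords = "integer", minutesPerRecord = "integer",
    normalLenRange = "integer", apneaLenRange = "integer",
    baselineRR = "numeric", baselineJitter = "numeric",
    rsaAmplitude = "numeric", rsaFreq = "numeric",
    lfAmplitude = "numeric", lfFreq = "numeric",
    cvhrAmplitude = "numeric", cvhrFreq = "numeric", cvhrVar = "numeric",
    postEpisodeDecay = "numeric", onsetRamp = "numeric",
    normalVlfSd = "numeric", normalVlfFreq = "numeric",
    ampModDepth = "numeric", respAmpDepth = "numeric",
    ampDriftSd = "numeric", ampJitterSd = "numeric",
    rrJitterSd = "numeric",
    noiseSd = "numeric", wanderAmplitude = "numeric", wanderFreq = "numeric",
    humAmplitude = "numeric", humFreq = "numeric",
    ectopicRate = "numeric", healthyFraction = "numeric",
    healthyMaxEvents = "integer", seed = "integer"
  )
)

#' Construct a SynthConfig
#'
#' @param nRecords,minutesPerRecord,normalLenRange,apneaLenRange,baselineRR
#'   see [SynthConfig-class].
#' @param baselineJitter,rsaAmplitude,rsaFreq,lfAmplitude,lfFreq
#'   see [SynthConfig-class].
#' @param cvhrAmplitude,cvhrFreq,cvhrVar,postEpisodeDecay,onsetRamp
#'   see [SynthConfig-class].
#' @param normalVlfSd,normalVlfFreq,ampModDepth,respAmpDepth,ampDriftSd
#'   see [SynthConfig-class].
#' @param ampJitterSd,rrJitterSd,noiseSd,wanderAmplitude,wanderFreq
#'   see [SynthConfig-class].
#' @param humAmplitude,humFreq,ectopicRate,seed see [SynthConfig-class].
#' @param healthyFraction,healthyMaxEvents see [SynthConfig-class].
#' @return A [SynthConfig-class].
#' @export
synthConfig <- function(nRecords = 20, minutesPerRecord = 60,
                        normalLenRange = c(3, 10), apneaLenRange = c(2, 6),
                        baselineRR = 850, baselineJitter = 40,
                        rsaAmplitude = 30, rsaFreq = 0.25,
                        lfAmplitude = 25, lfFreq = 0.095,
                        cvhrAmplitude = 70, cvhrFreq = 0.025, cvhrVar = 0.9,
                        postEpisodeDecay = c(0.6, 0.35, 0.15),
                        onsetRamp = 0.5,
                        normalVlfSd = 50, normalVlfFreq = 0.02,
                        ampModDepth = 0.15, respAmpDepth = 0.08,
                        ampDriftSd = 0.18, ampJitterSd = 0.05,
                        rrJitterSd = 30,
                        noiseSd = 0.02, wanderAmplitude = 0.1,
                        wanderFreq = 0.3, humAmplitude = 0.02, humFreq = 50,
                        ectopicRate = 0, healthyFraction = 0,
                        healthyMaxEvents = 4, seed = 1) {
  new("SynthConfig",
      nRecords = as.integer(nRecords),
      minutesPerRecord = as.integer(minutesPerRecord),
      normalLenRange = as.integer(normalLenRange),
      apneaLenRange = as.integer(apneaLenRange),
      baselineRR = baselineRR, baselineJitter = baselineJitter,
      rsaAmplitude = rsaAmplitude, rsaFreq = rsaFreq,
      lfAmplitude = lfAmplitude, lfFreq = lfFreq,
      cvhrAmplitude = cvhrAmplitude, cvhrFreq = cvhrFreq, cvhrVar = cvhrVar,
      postEpisodeDecay = postEpisodeDecay, onsetRamp = onsetRamp,
      normalVlfSd = normalVlfSd, normalVlfFreq = normalVlfFreq,
      ampModDepth = ampModDepth, respAmpDepth = respAmpDepth,
      ampDriftSd = ampDriftSd, ampJitterSd = ampJitterSd,
      rrJitterSd = rrJitterSd,
      noiseSd = noiseSd, wanderAmplitude = wanderAmplitude,
      wanderFreq = wanderFreq, humAmplitude = humAmplitude,
      humFreq = humFreq, ectopicRate = ectopicRate,
      healthyFraction = healthyFraction,
      healthyMaxEvents = as.integer(healthyMaxEvents),
      seed = as.integer(seed))
}

#' SynthRecord: one synthetic recording with ground truth
#'
#' @slot ecg the rendered [ECGRecord-class].
#' @slot labels the [MinuteLabels-class].
#' @slot rTimes ground-truth R-peak times, seconds.
#' @slot rrSeries ground-truth RR intervals, ms (`diff(rTimes) * 1000`).
#' @slot ampFactors per-beat R-amplitude scale factors.
#' @export
setClass("SynthRecord",
  representation(ecg = "ECGRecord", labels = "MinuteLabels",
                 rTimes = "numeric", rrSeries = "numeric",
                 ampFactors = "numeric")
)

setMethod("show", "SynthRecord", function(object) {
  cat(sprintf("SynthRecord '%s': %d beats, %d minutes (%d apneic)\n",
              recordId(object@ecg), length(object@rTimes),
              length(minuteLabels(object@labels)),
              sum(minuteLabels(object@labels))))
})

#' Simulate per-minute apnea labels
#'
#' For an apneic recording (the default): alternating normal/apneic
#' episodes with integer lengths drawn uniformly from the configured
#' ranges, starting with a normal run; draws are rejected until the
#' apneic-minute fraction lies in `[0.1, 0.7]`, so every apneic recording
#' has both classes in realistic proportion. For a control recording
#' (`healthy = TRUE`): at most `healthyMaxEvents` isolated apneic minutes
#' at random positions, so the recording's AHI stays below the screening
#' threshold.
#'
#' @param config a [SynthConfig-class].
#' @param seed RNG seed (defaults to the config seed).
#' @param healthy draw a non-SAS control recording instead.
#' @return A [MinuteLabels-class] of length `minutesPerRecord`.
#' @export
simulateLabels <- function(config, seed = config@seed, healthy = FALSE) {
  stopifnot(is(config, "SynthConfig"))
  nMin <- config@minutesPerRecord
  if (nMin < 1) stop("minutesPerRecord must be >= 1")
  if (healthy) {
    return(withSeed(seed, {
      lab <- logical(nMin)
      nEvents <- sample.int(config@healthyMaxEvents + 1L, 1L) - 1L
      if (nEvents > 0)
        lab[sample.int(nMin, min(nEvents, nMin))] <- TRUE
      MinuteLabels(lab, recordId = "synth")
    }))
  }
  drawLen <- function(range) {
    if (range[1] == range[2]) range[1]
    else sample(seq.int(range[1], range[2]), 1)
  }
  withSeed(seed, {
    for (attempt in 1:200) {
      lab <- logical(0)
      apneic <- FALSE
      while (length(lab) < nMin) {
        len <- drawLen(if (apneic) config@apneaLenRange
                       else config@normalLenRange)
        lab <- c(lab, rep(apneic, len))
        apneic <- !apneic
      }
      lab <- lab[seq_len(nMin)]
      f <- mean(lab)
      if (f >= 0.1 && f <= 0.7) break
      if (attempt == 200)
        stop("cannot reach an apneic fraction in [0.1, 0.7] with ",
             nMin, " minutes and the configured episode lengths")
    }
    MinuteLabels(lab, recordId = "synth")
  })
}

#' Simulate beat times, RR intervals and amplitude factors
#'
#' Beats are placed by cumulative summation of the instantaneous RR:
#' baseline plus RSA (normal minutes) or the cyclic apneic oscillation
#' (apneic minutes, with per-minute strength jitter) plus white jitter, all
#' clipped to 400-1800 ms. The per-beat R-amplitude factor is modulated by
#' `ampModDepth` at `cvhrFreq` during apneic minutes and is 1 otherwise.
#' With `ectopicRate > 0`, occasional beats get an out-of-band RR spike.
#'
#' @param labels a [MinuteLabels-class].
#' @param config a [SynthConfig-class].
#' @param seed RNG seed.
#' @return A list with `times` (s), `rr` (ms, `diff(times) * 1000` exactly)
#'   and `ampFactors`.
#' @export
simulateRR <- function(labels, config, seed = config@seed) {
  stopifnot(is(labels, "MinuteLabels"), is(config, "SynthConfig"))
  lab <- minuteLabels(labels)
  Tend <- length(lab) * 60
  withSeed(seed, {
    strength <- 1 + config@cvhrVar * runif(length(lab), -1, 1)
    ## carry-over: minutes after an episode retain a decaying fraction of
    ## the cyclic response (the response outlasts the event)
    influence <- as.numeric(lab)
    ## onset ramp: the first minute of each apneic run expresses weakly
    isStart <- lab & !c(FALSE, head(lab, -1))
    influence[isStart] <- config@onsetRamp
    for (k in seq_along(config@postEpisodeDecay)) {
      if (k >= length(influence)) break
      shifted <- c(numeric(k), head(influence, -k))
      influence <- pmax(influence, config@postEpisodeDecay[[k]] * shifted)
    }
    vlfAmp <- abs(rnorm(length(lab), 0, config@normalVlfSd))
    driftAmp <- abs(rnorm(length(lab), 0, config@ampDriftSd))
    ## RSA never vanishes: reduced during apneic minutes, variable in normal
    rsaScale <- ifelse(lab, runif(length(lab), 0.2, 0.8),
                       runif(length(lab), 0.5, 1.5))
    t <- 0.4
    times <- numeric(0)
    while (t < Tend) {
      times[[length(times) + 1L]] <- t
      m <- min(length(lab), floor(t / 60) + 1)
      rr <- config@baselineRR +
        config@lfAmplitude * sin(2 * pi * config@lfFreq * t) +
        rsaScale[[m]] * config@rsaAmplitude *
          sin(2 * pi * config@rsaFreq * t) +
        influence[[m]] * strength[[m]] * config@cvhrAmplitude *
          sin(2 * pi * config@cvhrFreq * t) +
        (if (lab[[m]]) 0
         else vlfAmp[[m]] * sin(2 * pi * config@normalVlfFreq * t)) +
        (if (config@rrJitterSd > 0) rnorm(1, 0, config@rrJitterSd) else 0)
      rr <- min(max(rr, 400), 1800)
      if (config@ectopicRate > 0 && runif(1) < config@ectopicRate)
        rr <- rr * sample(c(0.3, 3), 1)
      t <- t + rr / 1000
    }
    amp <- vapply(seq_along(times), function(i) {
      ti <- times[[i]]
      m <- min(length(lab), floor(ti / 60) + 1)
      1 + influence[[m]] * strength[[m]] * config@ampModDepth *
            sin(2 * pi * config@cvhrFreq * ti) +
        (if (lab[[m]]) 0
         else driftAmp[[m]] * sin(2 * pi * config@normalVlfFreq * ti) +
           config@respAmpDepth * sin(2 * pi * config@rsaFreq * ti))
    }, numeric(1))
    if (config@ampJitterSd > 0)
      amp <- amp + rnorm(length(amp), 0, config@ampJitterSd)
    list(times = times, rr = diff(times) * 1000, ampFactors = amp)
  })
}

## PQRST template: Gaussian bumps (offset s, amplitude, sigma s).
.PQRST <- cbind(offset = c(-0.180, -0.025, 0, 0.030, 0.250),
                amp = c(0.12, -0.15, 1.0, -0.20, 0.30),
                sigma = c(0.025, 0.010, 0.008, 0.010, 0.060))

#' Render a synthetic single-lead ECG
#'
#' Places a fixed PQRST-like template (sum of Gaussian bumps, dominant R
#' bump ~20 ms wide) at each beat time, scaled by the beat's amplitude
#' factor, then adds a baseline-wander sinusoid, powerline hum and white
#' noise, sampled at 100 Hz.
#'
#' @param times beat times in seconds (>= 2 beats).
#' @param ampFactors per-beat amplitude scale factors.
#' @param config a [SynthConfig-class].
#' @param seed RNG seed (noise and phases).
#' @param recordId identifier for the output record.
#' @return An [ECGRecord-class] of exactly
#'   `minutesPerRecord * 60 * 100` samples.
#' @export
renderECG <- function(times, ampFactors, config, seed = config@seed,
                      recordId = "synth") {
  stopifnot(length(times) >= 2, length(ampFactors) == length(times))
  fs <- 100
  n <- config@minutesPerRecord * 60 * fs
  x <- numeric(n)
  for (i in seq_along(times)) {
    lo <- max(1L, as.integer(floor((times[[i]] - 0.32) * fs)) + 1L)
    hi <- min(n, as.integer(ceiling((times[[i]] + 0.48) * fs)) + 1L)
    if (lo > hi) next
    tr <- (seq.int(lo, hi) - 1) / fs - times[[i]]
    bump <- numeric(length(tr))
    for (b in seq_len(nrow(.PQRST)))
      bump <- bump + .PQRST[b, "amp"] *
        exp(-((tr - .PQRST[b, "offset"])^2) / (2 * .PQRST[b, "sigma"]^2))
    x[lo:hi] <- x[lo:hi] + ampFactors[[i]] * bump
  }
  tg <- (seq_len(n) - 1) / fs
  withSeed(seed, {
    ph <- runif(2, 0, 2 * pi)
    if (config@wanderAmplitude > 0)
      x <- x + config@wanderAmplitude *
        sin(2 * pi * config@wanderFreq * tg + ph[[1]])
    if (config@humAmplitude > 0)
      x <- x + config@humAmplitude *
        sin(2 * pi * config@humFreq * tg + ph[[2]])
    if (config@noiseSd > 0)
      x <- x + rnorm(n, 0, config@noiseSd)
  })
  ECGRecord(x, samplingRate = fs, recordId = recordId)
}

#' Generate a labeled synthetic dataset
#'
#' Draws `nRecords` independent recordings, each from a per-record seed
#' derived from the master seed (reproducible regardless of order). The
#' between-record baseline-RR jitter is applied here. When `dir` is given,
#' each record is serialized as a WFDB header/signal pair plus a plain-text
#' annotation file, together with a manifest JSON listing all configuration
#' values and file paths.
#'
#' @param config a [SynthConfig-class].
#' @param dir optional output directory.
#' @return A list of [SynthRecord-class] objects (invisibly also written to
#'   `dir` when given).
#' @examples
#' ds <- generateDataset(synthConfig(nRecords = 1, minutesPerRecord = 5,
#'                                   seed = 7))
#' ds[[1]]
#' @export
generateDataset <- function(config = synthConfig(), dir = NULL) {
  stopifnot(is(config, "SynthConfig"))
  if (config@nRecords < 1) stop("nRecords must be >= 1")
  nRec <- config@nRecords
  isControl <- rep(FALSE, nRec)
  if (config@healthyFraction > 0) {
    step <- max(1L, as.integer(round(1 / config@healthyFraction)))
    if (step <= nRec) isControl[seq.int(step, nRec, by = step)] <- TRUE
  }
  records <- lapply(seq_len(nRec), function(idx) {
    rid <- sprintf("s%03d", idx)
    seedR <- deriveSeed(config@seed, idx)
    base <- withSeed(deriveSeed(seedR, 1),
                     config@baselineRR +
                       (if (config@baselineJitter > 0)
                          rnorm(1, 0, config@baselineJitter) else 0))
    cfgR <- initialize(config, baselineRR = base)
    labels <- simulateLabels(cfgR, seed = deriveSeed(seedR, 2),
                             healthy = isControl[[idx]])
    labels <- initialize(labels, recordId = rid)
    rr <- simulateRR(labels, cfgR, seed = deriveSeed(seedR, 3))
    ecg <- renderECG(rr$times, rr$ampFactors, cfgR,
                     seed = deriveSeed(seedR, 4), recordId = rid)
    new("SynthRecord", ecg = ecg, labels = labels, rTimes = rr$times,
        rrSeries = rr$rr, ampFactors = rr$ampFactors)
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    manifest <- list(config = .synthConfigList(config), records = list())
    for (rec in records) {
      rid <- recordId(rec@ecg)
      writeWFDBRecord(rec@ecg, dir)
      writeMinuteAnnotations(rec@labels, file.path(dir, paste0(rid, ".apn")))
      writeLines(fmtNum(rec@rTimes), file.path(dir, paste0(rid, ".rtimes")))
      manifest$records[[rid]] <- list(
        header = paste0(rid, ".hea"), signal = paste0(rid, ".dat"),
        annotations = paste0(rid, ".apn"),
        r_times = paste0(rid, ".rtimes"))
    }
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  records
}

.synthConfigList <- function(config) {
  slots <- slotNames(config)
  out <- lapply(slots, function(s) slot(config, s))
  names(out) <- slots
  out
}

#' Extract features for a set of synthetic records
#'
#' Convenience wrapper running the full preprocessing and feature pipeline
#' (bandpass filter, R-peak detection, median RR correction, per-minute
#' feature extraction) over the output of [generateDataset()] and binding
#' the per-record [SegmentFeatures-class] containers into one.
#'
#' @param records list of [SynthRecord-class] objects.
#' @param ... passed to [extractRecordingFeatures()].
#' @return A combined [SegmentFeatures-class].
#' @export
pipelineFeatures <- function(records, ...) {
  parts <- lapply(records, function(rec) {
    filt <- bandpassFIR(rec@ecg)
    peaks <- detectRPeaks(filt)
    peaks <- medianCorrectRR(peaks)
    extractRecordingFeatures(peaks, rec@labels, ...)
  })
  feat <- do.call(cbind, lapply(parts, SummarizedExperiment::assay,
                                "features"))
  cd <- do.call(rbind, lapply(parts, function(p)
    as.data.frame(SummarizedExperiment::colData(p))))
  SegmentFeatures(feat, recordId = cd$record_id,
                  minuteIndex = cd$minute_index, label = cd$label,
                  valid = cd$valid)
}
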