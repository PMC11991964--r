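test_that("time-domain features match their definitions on worked examples", {
  f <- timeDomainFeatures(c(800, 800, 800))
  expect_equal(f[["MRR"]], 800)
  expect_equal(f[["MHR"]], 75)
  expect_equal(f[["RMSSD"]], 0)
  expect_equal(f[["SDNN"]], 0)
  expect_equal(f[["NN50"]], 0)
  expect_equal(f[["pNN50"]], 0)

  f2 <- timeDomainFeatures(c(800, 850, 790))
  expect_equal(f2[["RMSSD"]], sqrt((50^2 + 60^2) / 2))      # 55.227 ms
  expect_equal(f2[["SDNN"]], sqrt(mean((c(800, 850, 790) -
                                          mean(c(800, 850, 790)))^2)))
  # diffs 60, 40, 20 -> one exceeds 50 ms; divisor is the interval count
  f3 <- timeDomainFeatures(c(800, 860, 900, 920))
  expect_equal(f3[["NN50"]], 1)
  expect_equal(f3[["pNN50"]], 0.25)

  expect_error(timeDomainFeatures(c(800)), "at least 2")
})

test_that("time-domain features agree with a brute-force oracle", {
  set.seed(7)
  for (i in 1:100) {
    rr <- runif(sample(5:80, 1), 400, 1500)
    got <- timeDomainFeatures(rr)
    want <- oracleTimeDomain(rr)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("pure tachogram sinusoids land in the right bands", {
  times <- seq(0, 60, by = 0.5)
  lfSig <- sin(2 * pi * 0.10 * times)
  hfSig <- sin(2 * pi * 0.25 * times)
  pLF <- bandPowers(times, lfSig)
  pHF <- bandPowers(times, hfSig)
  expect_gte(pLF[["LF"]] / (pLF[["VLF"]] + pLF[["LF"]] + pLF[["HF"]]), 0.9)
  expect_gte(pHF[["HF_norm"]], 0.9)
  expect_lte(pHF[["LF_norm"]], 0.1)
})

test_that("band powers: normalized ratios, zero-power rule, preconditions", {
  times <- seq(0, 59.5, by = 0.4)
  set.seed(8)
  vals <- 850 + 40 * sin(2 * pi * 0.1 * times) + rnorm(length(times), 0, 15)
  p <- bandPowers(times, vals)
  expect_equal(p[["LF_norm"]] + p[["HF_norm"]], 1, tolerance = 1e-9)
  expect_equal(p[["LF_HF"]], p[["LF"]] / p[["HF"]], tolerance = 1e-12)

  # constant series: mean removal annihilates everything
  pc <- bandPowers(times, rep(5, length(times)))
  expect_equal(pc[["VLF"]], 0)
  expect_equal(pc[["LF"]], 0)
  expect_equal(pc[["HF"]], 0)
  expect_identical(pc[["LF_norm"]], 0)   # zero-power rule
  expect_identical(pc[["HF_norm"]], 0)
  expect_identical(pc[["LF_HF"]], 0)

  # too few points or too short a span -> NA (invalid segment)
  expect_true(all(is.na(bandPowers(c(1, 2, 3), c(1, 2, 3)))))
  expect_true(all(is.na(bandPowers(seq(0, 20, 2), rnorm(11)))))
})

test_that("band energy never exceeds the total PSD integral", {
  set.seed(9)
  for (i in 1:10) {
    times <- sort(runif(80, 0, 60))
    vals <- rnorm(80, 850, 50)
    p <- bandPowers(times, vals)
    est <- spectralEstimatorSpec()
    grid <- seq(min(times), max(times), by = 1 / est@resampleRate)
    y <- spline(times, vals, xout = grid)$y
    sp <- ApneaScreenR:::welchPSD(y, 3)
    total <- sum(sp$psd) * (sp$freq[2] - sp$freq[1])
    expect_lte(p[["VLF"]] + p[["LF"]] + p[["HF"]], total + 1e-9)
  }
})

test_that("segment assignment follows the terminating-peak rule", {
  # peaks at 0.5, 1.5, ..., 59.5, 60.5 s
  pt <- seq(0.5, 60.5, by = 1)
  s <- RPeakSeries(pt, seq_along(pt))
  m0 <- segmentBeats(s, 0)
  expect_length(m0$amp, 60)   # peaks in [0, 60)
  expect_length(m0$rr, 59)    # the 60.5 s peak's RR belongs to minute 1
  m1 <- segmentBeats(s, 1)
  expect_length(m1$amp, 1)
  expect_length(m1$rr, 1)
  # partition property: per-minute amplitude subsets tile the full list
  allAmp <- c(segmentBeats(s, 0)$amp, segmentBeats(s, 1)$amp)
  expect_identical(allAmp, peakAmplitudes(s))
  # empty minute
  expect_length(segmentBeats(s, 5)$rr, 0)
})

test_that("per-recording extraction yields 18 finite features per valid minute", {
  ds <- generateDataset(synthConfig(nRecords = 1, minutesPerRecord = 10,
                                    seed = 12))
  pk <- medianCorrectRR(detectRPeaks(bandpassFIR(ds[[1]]@ecg)))
  sf <- extractRecordingFeatures(pk, ds[[1]]@labels)
  expect_identical(dim(sf), c(18L, 10L))
  cd <- SummarizedExperiment::colData(sf)
  m <- SummarizedExperiment::assay(sf, "features")
  expect_true(all(is.finite(m[, cd$valid])))
  expect_identical(rownames(sf),
                   c("MRR", "MHR", "RMSSD", "SDNN", "NN50", "pNN50",
                     "rr_VLF", "rr_LF", "rr_HF", "rr_LF_HF", "rr_LF_norm",
                     "rr_HF_norm", "amp_VLF", "amp_LF", "amp_HF",
                     "amp_LF_HF", "amp_LF_norm", "amp_HF_norm"))
  # normalized-ratio invariant holds for every valid segment, both families
  expect_equal(unname(m["rr_LF_norm", cd$valid] + m["rr_HF_norm", cd$valid]),
               rep(1, sum(cd$valid)), tolerance = 1e-9)
  expect_equal(unname(m["amp_LF_norm", cd$valid] + m["amp_HF_norm", cd$valid]),
               rep(1, sum(cd$valid)), tolerance = 1e-9)
  # id mismatch is rejected
  expect_error(extractRecordingFeatures(pk, MinuteLabels(logical(10), "zz")),
               "mismatch")
})

test_that("segments with too few beats are marked invalid", {
  # 10-minute grid but beats only in the first 3 minutes
  pt <- seq(0.5, 179.5, by = 0.8)
  s <- RPeakSeries(pt, rep(1, length(pt)), recordId = "r")
  sf <- extractRecordingFeatures(s, MinuteLabels(logical(10), "r"))
  cd <- SummarizedExperiment::colData(sf)
  expect_true(all(cd$valid[1:2]))
  expect_false(any(cd$valid[4:10]))
})

test_that("normalization is train-fitted, leak-free and handles degeneracy", {
  expect_equal(normalizeFeatures(cbind(c(1, 3)))$train[, 1], c(-1, 1))
  # constant column -> zeros with scale 1
  nz <- normalizeFeatures(cbind(a = c(2, 2, 2), b = c(1, 2, 3)))
  expect_identical(unname(nz$train[, 1]), c(0, 0, 0))
  expect_identical(unname(nz$scale[[1]]), 1)
  # a test value equal to the train mean maps to 0
  nz2 <- normalizeFeatures(cbind(c(1, 3)), applyTo = cbind(2))
  expect_identical(unname(nz2$applyTo[1, 1]), 0)
  # train stats: mean 0, population SD 1 per non-constant column
  set.seed(10)
  m <- matrix(rnorm(200, 5, 3), 50, 4)
  nz3 <- normalizeFeatures(m)
  expect_equal(unname(colMeans(nz3$train)), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(apply(nz3$train, 2, ApneaScreenR:::popSD)), rep(1, 4),
               tolerance = 1e-9)
  expect_error(normalizeFeatures(m[0, , drop = FALSE]), "at least 2")
  # NA entries excluded from stats and imputed to the train mean (0)
  m[3, 2] <- NA
  nz4 <- normalizeFeatures(m)
  expect_identical(unname(nz4$train[3, 2]), 0)
})
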