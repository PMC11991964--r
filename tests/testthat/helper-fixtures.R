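## Shared fixtures, generated once per test run and cached in this
## environment so independent test files can reuse them cheaply.
.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache)) {
    assign(name, builder(), envir = .fixtureCache)
  }
  get(name, envir = .fixtureCache)
}

## A small synthetic dataset: 6 records x 12 minutes.
smallDataset <- function() {
  cachedFixture("smallDataset", function() {
    generateDataset(synthConfig(nRecords = 6, minutesPerRecord = 12,
                                seed = 11))
  })
}

## Per-minute features of the small dataset, full pipeline.
smallFeatures <- function() {
  cachedFixture("smallFeatures", function() {
    pipelineFeatures(smallDataset())
  })
}

## Match detected peaks against ground truth within a tolerance (seconds).
peakMatchRates <- function(truth, detected, tol = 0.05) {
  recall <- mean(vapply(truth, function(t) any(abs(detected - t) <= tol),
                        logical(1)))
  precision <- mean(vapply(detected, function(t) any(abs(truth - t) <= tol),
                           logical(1)))
  c(recall = recall, precision = precision)
}

## Independent brute-force oracles for the time-domain HRV features.
oracleTimeDomain <- function(rr) {
  n <- length(rr)
  mrr <- sum(rr) / n
  mhr <- sum(60000 / rr) / n
  ssq <- 0
  for (i in seq_len(n - 1)) ssq <- ssq + (rr[i + 1] - rr[i])^2
  rmssd <- sqrt(ssq / (n - 1))
  sdnn <- sqrt(sum((rr - mrr)^2) / n)
  nn50 <- 0
  for (i in seq_len(n - 1)) if (abs(rr[i + 1] - rr[i]) > 50) nn50 <- nn50 + 1
  c(MRR = mrr, MHR = mhr, RMSSD = rmssd, SDNN = sdnn, NN50 = nn50,
    pNN50 = nn50 / n)
}

## Brute-force pairwise AUC (probability a random positive outranks a
## random negative, ties counting one half).
oracleAUC <- function(truth, scores) {
  pos <- scores[truth]
  neg <- scores[!truth]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
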