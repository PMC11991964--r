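#' Read a WFDB record (Apnea-ECG dialect)
#'
#' Parses a WFDB header/signal pair (format 16: 16-bit little-endian
#' two's-complement samples) and returns channel 0 as an [ECGRecord-class].
#' This covers the dialect used by the PhysioNet Apnea-ECG database
#' (100 Hz, 16-bit, gain 200 adu/mV).
#'
#' @param path path to the record, with or without the `.hea` extension.
#' @return An [ECGRecord-class] with the header's sampling rate; sample
#'   values are converted to physical units via `(adc - baseline) / gain`.
#' @seealso [writeWFDBRecord()], [readCSVSignal()]
#' @export
readWFDBRecord <- function(path) {
  base <- sub("\\.hea$", "", path)
  hea <- paste0(base, ".hea")
  if (!file.exists(hea))
    stop("WFDB header not found: ", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty WFDB header: ", hea)
  rec <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  if (length(rec) < 3) stop("malformed WFDB record line in ", hea)
  recName <- rec[[1]]
  nsig <- as.integer(rec[[2]])
  fs <- as.numeric(rec[[3]])
  nsamp <- if (length(rec) >= 4) as.numeric(rec[[4]]) else NA_real_
  if (is.na(nsig) || nsig < 1)
    stop("WFDB record declares zero signal channels: ", hea)
  if (length(lines) < 2) stop("WFDB header has no signal line: ", hea)
  sig <- strsplit(trimws(lines[[2]]), "\\s+")[[1]]
  datFile <- file.path(dirname(hea), sig[[1]])
  fmt <- sub(":.*$", "", sub("x.*$", "", sig[[2]]))
  if (fmt != "16")
    stop("unsupported WFDB signal format '", fmt, "' (only format 16)")
  gainTok <- if (length(sig) >= 3) sig[[3]] else "200"
  gainTok <- sub("/.*$", "", gainTok)
  baseline <- NA_real_
  if (grepl("\\(", gainTok)) {
    baseline <- as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gainTok))
    gainTok <- sub("\\(.*$", "", gainTok)
  }
  gain <- as.numeric(gainTok)
  if (is.na(gain) || gain == 0) gain <- 200
  adcZero <- if (length(sig) >= 5) as.numeric(sig[[5]]) else 0
  if (is.na(baseline)) baseline <- if (is.na(adcZero)) 0 else adcZero
  if (!file.exists(datFile))
    stop("WFDB signal file not found: ", datFile)
  con <- file(datFile, "rb")
  on.exit(close(con))
  total <- file.info(datFile)$size / 2
  adc <- readBin(con, "integer", n = total, size = 2, signed = TRUE,
                 endian = "little")
  if (nsig > 1) adc <- adc[seq(1, length(adc), by = nsig)]
  if (!is.na(nsamp) && nsamp > 0) adc <- adc[seq_len(min(length(adc), nsamp))]
  ECGRecord((adc - baseline) / gain, samplingRate = fs, recordId = recName)
}

#' Write a WFDB record (Apnea-ECG dialect)
#'
#' Serializes an [ECGRecord-class] as a WFDB header plus a format-16 signal
#' file. Samples are quantized to integers with the given gain; the
#' quantization step is `1 / gain` physical units.
#'
#' @param record an [ECGRecord-class].
#' @param dir output directory (created if missing).
#' @param gain adu per physical unit (default 200, the Apnea-ECG value).
#' @return Invisibly, the path to the header file.
#' @export
writeWFDBRecord <- function(record, dir, gain = 200) {
  stopifnot(is(record, "ECGRecord"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- recordId(record)
  hea <- file.path(dir, paste0(id, ".hea"))
  dat <- file.path(dir, paste0(id, ".dat"))
  adc <- as.integer(pmax(-32768, pmin(32767, round(samples(record) * gain))))
  writeLines(c(
    sprintf("%s 1 %s %d", id, format(samplingRate(record)), length(adc)),
    sprintf("%s.dat 16 %d(0)/mV 16 0 %d 0 0 ECG", id, as.integer(gain),
            if (length(adc)) adc[[1]] else 0L)
  ), hea)
  con <- file(dat, "wb")
  on.exit(close(con))
  writeBin(adc, con, size = 2, endian = "little")
  invisible(hea)
}

#' Read a plain-text signal file
#'
#' One numeric sample per line; an optional single header line is skipped.
#'
#' @param path file path.
#' @param samplingRate sampling rate in Hz to attach to the record.
#' @param recordId identifier; defaults to the file's base name.
#' @return An [ECGRecord-class].
#' @export
readCSVSignal <- function(path, samplingRate,
                          recordId = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop("signal file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty signal file: ", path)
  vals <- suppressWarnings(as.numeric(lines))
  start <- 1L
  if (is.na(vals[[1]]) && length(lines) > 1) start <- 2L  # header line
  bad <- which(is.na(vals[start:length(vals)])) + start - 1L
  if (length(bad))
    stop("non-numeric value at line ", bad[[1]], " of ", path, ": '",
         lines[[bad[[1]]]], "'")
  if (start > length(vals)) stop("signal file has no numeric samples: ", path)
  ECGRecord(vals[start:length(vals)], samplingRate = samplingRate,
            recordId = recordId)
}

#' Write a plain-text signal file
#'
#' @param record an [ECGRecord-class].
#' @param path output path; one sample per line at full double precision.
#' @return Invisibly, `path`.
#' @export
writeCSVSignal <- function(record, path) {
  stopifnot(is(record, "ECGRecord"))
  writeLines(fmtNum(samples(record)), path)
  invisible(path)
}

#' Read per-minute apnea annotations
#'
#' Accepts one symbol per line: `A` or `1` marks an apneic minute, `N` or `0`
#' a normal one (the per-minute annotation dialect of the Apnea-ECG
#' database, in text form). Index 0 is the first minute of the recording.
#'
#' @param path file path.
#' @param recordId identifier; defaults to the file's base name.
#' @return A [MinuteLabels-class].
#' @export
readMinuteAnnotations <- function(path,
                                  recordId = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty annotation file: ", path)
  lab <- rep(NA, length(lines))
  lab[lines %in% c("A", "1")] <- TRUE
  lab[lines %in% c("N", "0")] <- FALSE
  if (anyNA(lab)) {
    i <- which(is.na(lab))[[1]]
    stop("unknown annotation symbol '", lines[[i]], "' at line ", i,
         " of ", path)
  }
  MinuteLabels(lab, recordId = recordId)
}

#' Write per-minute apnea annotations
#'
#' @param labels a [MinuteLabels-class].
#' @param path output path; one `A`/`N` symbol per line.
#' @return Invisibly, `path`.
#' @export
writeMinuteAnnotations <- function(labels, path) {
  stopifnot(is(labels, "MinuteLabels"))
  writeLines(ifelse(minuteLabels(labels), "A", "N"), path)
  invisible(path)
}

.windowColnames <- function(past, future) {
  pref <- vapply(seq.int(-past, future), function(o) {
    if (o < 0) paste0("m", -o) else if (o > 0) paste0("p", o) else "c"
  }, "")
  as.vector(vapply(pref, function(p) paste0(p, "_", .FEATURE_NAMES),
                   character(length(.FEATURE_NAMES))))
}

#' Write a feature table
#'
#' Serializes a [SegmentFeatures-class] or [WindowedMatrix-class] as a
#' tab-separated table with a header row. Numeric values are written with
#' 17 significant digits so the round-trip through text is lossless.
#'
#' The per-segment layout is `record_id`, `minute_index`, `label`, the 18
#' feature columns in canonical order, then `valid`. The windowed layout is
#' `record_id`, `minute_index`, `label`, then `18 * (past + future + 1)`
#' columns named `m<k>_*` (past), `c_*` (current), `p<k>_*` (future).
#'
#' @param x a [SegmentFeatures-class] or [WindowedMatrix-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeFeatureTable <- function(x, path) {
  if (is(x, "SegmentFeatures")) {
    cd <- SummarizedExperiment::colData(x)
    m <- t(SummarizedExperiment::assay(x, "features"))
    header <- c("record_id", "minute_index", "label", .FEATURE_NAMES, "valid")
    body <- cbind(
      cd$record_id, cd$minute_index, ifelse(cd$label, "1", "0"),
      apply(m, 2, fmtNum), ifelse(cd$valid, "1", "0"))
  } else if (is(x, "WindowedMatrix")) {
    header <- c("record_id", "minute_index", "label", colnames(x@x))
    body <- cbind(x@groups, x@minuteIndex, ifelse(x@labels, "1", "0"),
                  apply(x@x, 2, fmtNum))
  } else {
    stop("x must be a SegmentFeatures or WindowedMatrix")
  }
  con <- file(path, "wb")  # binary mode: byte-identical across platforms
  on.exit(close(con))
  writeLines(c(paste(header, collapse = "\t"),
               apply(body, 1, paste, collapse = "\t")), con)
  invisible(path)
}

#' Read a feature table
#'
#' Reads a table written by [writeFeatureTable()] and reconstructs the
#' original container; the layout is recognized from the header row.
#'
#' @param path file path.
#' @return A [SegmentFeatures-class] or [WindowedMatrix-class].
#' @export
readFeatureTable <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  header <- colnames(df)
  segHeader <- c("record_id", "minute_index", "label", .FEATURE_NAMES, "valid")
  if (!all(c("record_id", "minute_index", "label") %in% header))
    stop("feature table header must contain record_id, minute_index, label")
  if (identical(header, segHeader)) {
    m <- t(vapply(seq_len(nrow(df)),
                  function(i) as.numeric(df[i, .FEATURE_NAMES]),
                  numeric(length(.FEATURE_NAMES))))
    if (nrow(df) == 0) m <- matrix(numeric(), 0, length(.FEATURE_NAMES))
    return(SegmentFeatures(t(m),
                           recordId = df$record_id,
                           minuteIndex = as.integer(df$minute_index),
                           label = df$label == "1",
                           valid = df$valid == "1"))
  }
  featCols <- setdiff(header, c("record_id", "minute_index", "label"))
  mPast <- grep("^m([0-9]+)_", featCols, value = TRUE)
  pFut <- grep("^p([0-9]+)_", featCols, value = TRUE)
  past <- if (length(mPast)) max(as.integer(sub("^m([0-9]+)_.*$", "\\1", mPast))) else 0L
  future <- if (length(pFut)) max(as.integer(sub("^p([0-9]+)_.*$", "\\1", pFut))) else 0L
  expected <- .windowColnames(past, future)
  if (!identical(featCols, expected))
    stop("feature table header does not match any known layout")
  m <- as.matrix(df[, featCols, drop = FALSE])
  storage.mode(m) <- "double"
  new("WindowedMatrix", x = m, labels = df$label == "1",
      groups = df$record_id, minuteIndex = as.integer(df$minute_index),
      spec = windowSpec(past, future))
}

#' Check annotation/signal length consistency
#'
#' The number of annotated minutes must match the floor of the recording
#' duration to within one minute (datasets may omit a trailing partial
#' minute). Larger discrepancies are rejected rather than silently truncated.
#'
#' @param record an [ECGRecord-class].
#' @param labels a [MinuteLabels-class] for the same record.
#' @return Invisibly `TRUE`; errors on inconsistency.
#' @export
checkAnnotationConsistency <- function(record, labels) {
  nMin <- floor(durationMinutes(record))
  nSeg <- length(minuteLabels(labels))
  if (abs(nSeg - nMin) > 1)
    stop(sprintf(
      "record '%s': %d annotated minutes but signal spans %d full minutes",
      recordId(record), nSeg, nMin))
  invisible(TRUE)
}
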