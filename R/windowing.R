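#' Assemble a past/future windowed design matrix
#'
#' For every target minute `t` of every recording, concatenates the
#' per-minute feature vectors for minutes `t - past ... t ... t + future`
#' in temporal order. Context never crosses recording boundaries;
#' out-of-range minutes are handled by `edgePolicy`:
#' `"replicate"` (default) repeats the nearest existing minute's vector so
#' every annotated minute stays a classifiable row, `"zero"` fills with
#' zeros, `"drop"` removes targets lacking full context.
#'
#' @param features a [SegmentFeatures-class] (one or more recordings; minutes
#'   must be sorted increasing within each recording).
#' @param spec a [WindowSpec-class].
#' @param edgePolicy `"replicate"`, `"zero"` or `"drop"`.
#' @return A [WindowedMatrix-class] with `18 * (past + future + 1)` columns.
#' @examples
#' \dontrun{
#' wm <- assembleWindowedFeatures(feats, windowSpec(past = 3, future = 13))
#' ncol(designMatrix(wm))  # 18 * 17 = 306
#' }
#' @export
assembleWindowedFeatures <- function(features, spec = windowSpec(0, 0),
                                     edgePolicy = c("replicate", "zero",
                                                    "drop")) {
  stopifnot(is(features, "SegmentFeatures"), is(spec, "WindowSpec"))
  edgePolicy <- match.arg(edgePolicy)
  cd <- SummarizedExperiment::colData(features)
  fm <- SummarizedExperiment::assay(features, "features")  # 18 x nseg
  past <- spec@past; future <- spec@future
  offsets <- seq.int(-past, future)
  p <- length(.FEATURE_NAMES)

  rowsList <- list(); labList <- list(); grpList <- list(); minList <- list()
  for (rid in unique(cd$record_id)) {
    idx <- which(cd$record_id == rid)
    mins <- cd$minute_index[idx]
    if (is.unsorted(mins, strictly = TRUE))
      stop("minutes of record '", rid, "' are not strictly increasing")
    nm <- length(idx)
    block <- fm[, idx, drop = FALSE]
    keep <- rep(TRUE, nm)
    out <- matrix(NA_real_, nrow = nm, ncol = p * length(offsets))
    for (j in seq_along(offsets)) {
      src <- seq_len(nm) + offsets[[j]]
      cols <- ((j - 1L) * p + 1L):(j * p)
      if (edgePolicy == "replicate") {
        src <- pmin(pmax(src, 1L), nm)
        out[, cols] <- t(block[, src, drop = FALSE])
      } else if (edgePolicy == "zero") {
        ok <- src >= 1L & src <= nm
        out[ok, cols] <- t(block[, src[ok], drop = FALSE])
        out[!ok, cols] <- 0
      } else {
        ok <- src >= 1L & src <= nm
        keep <- keep & ok
        src <- pmin(pmax(src, 1L), nm)
        out[, cols] <- t(block[, src, drop = FALSE])
      }
    }
    rowsList[[rid]] <- out[keep, , drop = FALSE]
    labList[[rid]] <- cd$label[idx][keep]
    grpList[[rid]] <- rep(rid, sum(keep))
    minList[[rid]] <- mins[keep]
  }
  x <- do.call(rbind, rowsList)
  colnames(x) <- .windowColnames(past, future)
  new("WindowedMatrix", x = x,
      labels = as.logical(unlist(labList, use.names = FALSE)),
      groups = as.character(unlist(grpList, use.names = FALSE)),
      minuteIndex = as.integer(unlist(minList, use.names = FALSE)),
      spec = spec)
}

#' Grid search over past/future window sizes
#'
#' Evaluates mean group-5-fold cross-validated per-segment accuracy for each
#' candidate window and returns the full accuracy surface plus the best
#' window. Ties are broken toward the smallest `past + future`, then the
#' smallest `future` (cheapest context wins). Deterministic for a fixed
#' seed: every cell uses the same folds.
#'
#' @param features a [SegmentFeatures-class] spanning all records.
#' @param grid a list of [WindowSpec-class] objects, or `NULL` for the full
#'   16 x 16 grid (past and future 0-15).
#' @param config a [ClassifierConfig-class].
#' @param nFolds folds for grouped cross-validation (default 5).
#' @param seed seed for fold assignment and training.
#' @param evaluator optional function `(features, spec) -> accuracy`
#'   replacing the cross-validation evaluation (used for testing).
#' @return A list with `surface` (data.frame `past`, `future`,
#'   `mean_accuracy`) and `best` (a [WindowSpec-class]).
#' @export
gridSearchWindows <- function(features, grid = NULL, config = classifierConfig("MLP"),
                              nFolds = 5, seed = 1, evaluator = NULL) {
  if (is.null(grid))
    grid <- unlist(lapply(0:15, function(p)
      lapply(0:15, function(f) windowSpec(p, f))))
  if (!length(grid)) stop("grid must be non-empty")
  acc <- vapply(grid, function(spec) {
    if (!is.null(evaluator)) return(evaluator(features, spec))
    res <- runExperiment(features, config = config, window = spec,
                         split = "cv", nFolds = nFolds, seed = seed)
    mean(res$foldAccuracy)
  }, numeric(1))
  surface <- data.frame(
    past = vapply(grid, windowPast, integer(1)),
    future = vapply(grid, windowFuture, integer(1)),
    mean_accuracy = acc)
  ## argmax with ties toward smallest past+future, then smallest future
  ord <- order(-surface$mean_accuracy,
               surface$past + surface$future, surface$future)
  best <- surface[ord[[1]], ]
  list(surface = surface, best = windowSpec(best$past, best$future))
}
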