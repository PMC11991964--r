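## Printed default hyperparameters for the five reference classifiers.
.CLASSIFIER_DEFAULTS <- list(
  MLP = list(hidden_layer_sizes = NA, alpha = 1, max_iter = 1000),
  SVM = list(C = 9.9, tol = 5e-4, kernel = "radial"),
  RF = list(n_estimators = 148, max_depth = 185, max_features = 15,
            random_state = 42),
  XGBoost = list(eta = 0.1, num_round = 10000, early_stopping_rounds = 50,
                 max_depth = 9, min_child_weight = 0.121, gamma = 6.45e-7,
                 colsample_bytree = 0.876, subsample = 0.872,
                 eval_fraction = 0.1),
  LR = list(random_state = 42)
)

#' Construct a ClassifierConfig
#'
#' Returns one of the five reference classifier configurations with its
#' published default hyperparameters; any named argument overrides the
#' default of the same name.
#'
#' Defaults: MLP hidden layer size `n_features * 2 + 1` (computed from the
#' actual windowed feature count at training time), `alpha = 1`,
#' `max_iter = 1000`; SVM `C = 9.9`, `tol = 5e-4`, RBF kernel; RF
#' `n_estimators = 148`, `max_depth = 185`, `max_features = 15` (capped at
#' the feature count), `random_state = 42`; XGBoost `eta = 0.1`,
#' `num_round = 10000`, `early_stopping_rounds = 50`, `max_depth = 9`,
#' `min_child_weight = 0.121`, `gamma = 6.45e-7`,
#' `colsample_bytree = 0.876`, `subsample = 0.872`; LR `random_state = 42`.
#'
#' @param kind one of `"MLP"`, `"SVM"`, `"RF"`, `"XGBoost"`, `"LR"`.
#' @param ... hyperparameter overrides (must name existing defaults).
#' @param seed RNG seed used at training time (default 42).
#' @return A [ClassifierConfig-class].
#' @examples
#' classifierConfig("RF")
#' classifierConfig("SVM", C = 1)
#' @export
classifierConfig <- function(kind = c("MLP", "SVM", "RF", "XGBoost", "LR"),
                             ..., seed = 42) {
  kind <- match.arg(kind)
  params <- .CLASSIFIER_DEFAULTS[[kind]]
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(params))
    if (length(bad))
      stop("unknown hyperparameter(s) for ", kind, ": ",
           paste(bad, collapse = ", "))
    params[names(dots)] <- dots
  }
  new("ClassifierConfig", kind = kind, params = params,
      seed = as.integer(seed))
}

## Grouped holdout of ~fraction of training rows for XGBoost early stopping:
## whole records go to the eval slice when more than one record is present.
.xgbEvalRows <- function(groups, fraction, seed) {
  n <- length(groups)
  ids <- unique(groups)
  withSeed(seed, {
    if (length(ids) > 1) {
      k <- max(1L, round(fraction * length(ids)))
      evalIds <- sample(ids, k)
      which(groups %in% evalIds)
    } else {
      sample.int(n, max(1L, round(fraction * n)))
    }
  })
}

#' Train a per-segment apnea classifier
#'
#' Fits the configured classifier on the rows of a windowed design matrix.
#' Features are expected to be normalized already (see
#' [normalizeFeatures()]). The MLP hidden-layer size is computed from the
#' actual feature count (`n * 2 + 1`); XGBoost early stopping monitors a
#' seed-fixed grouped holdout of the training rows.
#'
#' @param wm a [WindowedMatrix-class] of training rows.
#' @param config a [ClassifierConfig-class].
#' @return An [ApneaModel-class].
#' @export
trainClassifier <- function(wm, config = classifierConfig("MLP")) {
  stopifnot(is(wm, "WindowedMatrix"), is(config, "ClassifierConfig"))
  x <- wm@x
  y <- wm@labels
  if (length(unique(y)) < 2)
    stop("training data contain a single class")
  p <- ncol(x)
  prm <- config@params
  seed <- config@seed
  fit <- switch(config@kind,
    MLP = {
      hidden <- if (is.na(prm$hidden_layer_sizes)) p * 2 + 1
                else prm$hidden_layer_sizes
      withSeed(seed,
        mlpFit(x, as.numeric(y), hidden = hidden, alpha = prm$alpha,
               maxIter = prm$max_iter))
    },
    SVM = withSeed(seed,
      e1071::svm(x = x, y = factor(y, levels = c(FALSE, TRUE)),
                 kernel = prm$kernel, cost = prm$C, tolerance = prm$tol,
                 probability = TRUE, scale = FALSE)),
    RF = ranger::ranger(
      x = x, y = factor(y, levels = c(FALSE, TRUE)),
      num.trees = prm$n_estimators, max.depth = prm$max_depth,
      mtry = min(prm$max_features, p), probability = TRUE,
      seed = prm$random_state, num.threads = 1),
    XGBoost = {
      evalRows <- .xgbEvalRows(wm@groups, prm$eval_fraction, seed)
      dtrain <- xgboost::xgb.DMatrix(x[-evalRows, , drop = FALSE],
                                     label = as.numeric(y[-evalRows]))
      deval <- xgboost::xgb.DMatrix(x[evalRows, , drop = FALSE],
                                    label = as.numeric(y[evalRows]))
      withSeed(seed,
        xgboost::xgb.train(
          params = list(objective = "binary:logistic", eta = prm$eta,
                        max_depth = prm$max_depth,
                        min_child_weight = prm$min_child_weight,
                        gamma = prm$gamma,
                        colsample_bytree = prm$colsample_bytree,
                        subsample = prm$subsample, nthread = 1,
                        eval_metric = "logloss"),
          data = dtrain, nrounds = prm$num_round,
          early_stopping_rounds = prm$early_stopping_rounds,
          evals = list(eval = deval), verbose = 0))
    },
    LR = suppressWarnings(
      glm.fit(cbind(1, x), as.numeric(y), family = binomial()))
  )
  new("ApneaModel", config = config, fit = fit, nFeatures = as.integer(p))
}

#' Predict per-segment apnea labels and scores
#'
#' Scores are monotone class-probability surrogates in `[0, 1]` (predicted
#' probability for MLP, LR and RF; calibrated probability for SVM; logistic
#' output for XGBoost). Labels are `score >= 0.5`.
#'
#' @param model an [ApneaModel-class].
#' @param wm a [WindowedMatrix-class] with the same feature count.
#' @return A list with `labels` (logical) and `scores` (numeric in `[0, 1]`).
#' @export
predictSegments <- function(model, wm) {
  stopifnot(is(model, "ApneaModel"), is(wm, "WindowedMatrix"))
  x <- wm@x
  if (nrow(x) == 0)
    return(list(labels = logical(), scores = numeric()))
  if (ncol(x) != model@nFeatures)
    stop("feature count mismatch: model expects ", model@nFeatures,
         ", got ", ncol(x))
  scores <- switch(model@config@kind,
    MLP = mlpPredict(model@fit, x),
    SVM = {
      pr <- predict(model@fit, x, probability = TRUE)
      attr(pr, "probabilities")[, "TRUE"]
    },
    RF = predict(model@fit, data = x, num.threads = 1)$predictions[, "TRUE"],
    XGBoost = as.numeric(predict(model@fit, xgboost::xgb.DMatrix(x))),
    LR = {
      beta <- model@fit$coefficients
      beta[is.na(beta)] <- 0  # aliased (collinear) columns drop out
      eta <- drop(cbind(1, x) %*% beta)
      1 / (1 + exp(-eta))
    })
  scores <- pmin(pmax(as.numeric(scores), 0), 1)
  list(labels = scores >= 0.5, scores = scores)
}
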