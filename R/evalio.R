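#' Load a UCI-style leaf signature CSV
#'
#' Expects headerless rows of a class label followed by 64 numeric values --
#' the normalized contour signature samples distributed over the full turn.
#'
#' @param path CSV path.
#' @return list with `features` (`n x 64` matrix) and `labels`.
#' @export
loadUciLeafCsv <- function(path) {
  nf <- count.fields(path, sep = ",")
  bad <- which(nf != 65)
  if (length(bad))
    stop("malformed row ", bad[1], ": expected a label plus 64 values, got ",
         nf[bad[1]] - 1)
  df <- read.csv(path, header = FALSE, stringsAsFactors = FALSE)
  features <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(features) || anyNA(features))
    stop("non-numeric feature value in ", path)
  colnames(features) <- paste0("f", 0:63)
  list(features = features, labels = as.character(df[[1]]))
}

#' Stratified train/test split
#'
#' Splits per class in proportion `testFraction`, seeded; train and test
#' sets are disjoint and cover the data.
#'
#' @param features feature matrix.
#' @param labels labels.
#' @param testFraction fraction per class put in the test set.
#' @param seed integer seed.
#' @return list with `trainX`, `trainY`, `testX`, `testY`, `testIdx`.
#' @export
stratifiedSplit <- function(features, labels, testFraction = 0.2,
                            seed = NULL) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(testFraction > 0, testFraction < 1)
  if (min(table(labels)) < 2)
    stop("every class needs at least 2 samples to split")
  withSeed(seed, {
    testIdx <- sort(unlist(lapply(split(seq_along(labels), labels),
      function(ix) sample(ix, max(1, round(testFraction * length(ix)))))))
    list(trainX = features[-testIdx, , drop = FALSE],
         trainY = labels[-testIdx],
         testX = features[testIdx, , drop = FALSE],
         testY = labels[testIdx],
         testIdx = testIdx)
  })
}

#' Stratified k-fold cross-validation
#'
#' Partitions the data into `k` stratified folds, trains the classifier on
#' `k - 1` and scores accuracy on the held-out fold, rotating through all
#' folds.
#'
#' @param features feature matrix.
#' @param labels labels.
#' @param k number of folds (default 10).
#' @param factory function `(trainX, trainY)` returning an object accepted
#'   by [errorRate()].
#' @param seed integer seed for the fold assignment.
#' @return list with `meanAccuracy`, `sdAccuracy` and `foldAccuracies`.
#' @export
kfoldCv <- function(features, labels, k = 10, factory, seed = NULL) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  n <- length(labels)
  if (k < 2 || k > n) stop("k must be between 2 and the number of samples")
  withSeed(seed, {
    fold <- integer(n)
    for (ix in split(seq_len(n), labels))
      fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
    acc <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      if (length(unique(labels[tr])) < 2) return(NA_real_)
      m <- factory(features[tr, , drop = FALSE], labels[tr])
      1 - errorRate(m, features[!tr, , drop = FALSE], labels[!tr])
    }, 0)
    acc <- acc[!is.na(acc)]
    list(meanAccuracy = mean(acc), sdAccuracy = sd(acc),
         foldAccuracies = acc)
  })
}

#' Grid-search baseline for SVM hyperparameters
#'
#' Evaluates a log-spaced `gridSize x gridSize` grid of `(C, sigma)` pairs
#' over the same search box as the salp-swarm tuner, scoring each on the
#' same kind of inner validation split, and retrains on all training data
#' at the best point.
#'
#' @param features training feature matrix.
#' @param labels training labels.
#' @param gridSize points per axis.
#' @param bounds search box, default [svmTuneBounds()].
#' @param innerFraction inner validation fraction.
#' @param seed integer seed for the inner split.
#' @return list with `C`, `sigma`, `model`, `value` (best validation error).
#' @export
gridSvmTune <- function(features, labels, gridSize = 20,
                        bounds = svmTuneBounds(), innerFraction = 0.2,
                        seed = NULL) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  split <- stratifiedSplit(features, labels, testFraction = innerFraction,
                           seed = seed)
  Cs <- exp(seq(log(bounds[1, 1]), log(bounds[1, 2]), length.out = gridSize))
  sigmas <- exp(seq(log(bounds[2, 1]), log(bounds[2, 2]),
                    length.out = gridSize))
  best <- list(value = Inf)
  for (C in Cs) for (sg in sigmas) {
    m <- tryCatch(svmTrain(split$trainX, split$trainY, C = C, sigma = sg),
                  error = function(e) NULL)
    if (is.null(m)) next
    err <- errorRate(m, split$testX, split$testY)
    if (err < best$value) best <- list(C = C, sigma = sg, value = err)
  }
  best$model <- svmTrain(features, labels, C = best$C, sigma = best$sigma)
  best
}

#' Experiment configuration
#'
#' @param angleSteps angular steps (degrees) to sweep; defaults to
#'   `c(30, 20, 10, 8)`, i.e. 12, 18, 36 and 45 features.
#' @param testFraction held-out test fraction (default 0.2; the remaining
#'   80% is used for training and cross-validation).
#' @param nFolds cross-validation folds (default 10).
#' @param classifiers subset of `c("rbfnn", "svm", "ssa_svm")`.
#' @param gaCfg [gaConfig()] used for curve fitting and the RBFNN spread
#'   search.
#' @param ssaCfg [ssaConfig()] used by the SSA-SVM tuner.
#' @param gridSize grid size for the plain-SVM baseline tuner.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return object of class `experimentConfig`.
#' @export
experimentConfig <- function(angleSteps = c(30, 20, 10, 8),
                             testFraction = 0.2, nFolds = 10,
                             classifiers = c("rbfnn", "svm", "ssa_svm"),
                             gaCfg = gaConfig(), ssaCfg = NULL,
                             gridSize = 20, seed = 1) {
  stopifnot(testFraction > 0, testFraction < 1, nFolds >= 2)
  classifiers <- match.arg(classifiers, c("rbfnn", "svm", "ssa_svm"),
                           several.ok = TRUE)
  if (is.null(ssaCfg))
    ssaCfg <- ssaConfig(bounds = svmTuneBounds(), targetObjective = 0.025,
                        seed = seed)
  structure(list(angleSteps = angleSteps, testFraction = testFraction,
                 nFolds = nFolds, classifiers = classifiers, gaCfg = gaCfg,
                 ssaCfg = ssaCfg, gridSize = gridSize, seed = seed),
            class = "experimentConfig")
}

#' Run the full classification experiment
#'
#' For each angular step: fit one periodic RBF curve per shape (done once,
#' shared across steps), resample feature vectors, split 80/20 stratified,
#' run each configured classifier with k-fold cross-validation on the
#' training part and a final evaluation on the held-out test part.
#' Hyperparameter tuning (SSA or grid) only ever sees training rows.
#'
#' @param input either a list with `masks` and `labels` (e.g. from
#'   [makeDataset()]), a path to a UCI-style CSV (see [loadUciLeafCsv()];
#'   rows are treated as signatures sampled uniformly over the turn and
#'   refitted), or a list with `models` and `labels` of pre-fitted curves.
#' @param cfg an [experimentConfig()].
#' @return data frame with one row per classifier and angular step:
#'   `classifier`, `angle_step`, `n_features`, `cv_mean_accuracy`, `cv_sd`,
#'   `test_accuracy`; run metadata in `attr(, "metadata")`.
#' @export
runExperiment <- function(input, cfg = experimentConfig()) {
  gaCfg <- cfg$gaCfg
  if (is.null(gaCfg$seed)) gaCfg$seed <- cfg$seed
  if (is.character(input)) {
    uci <- loadUciLeafCsv(input)
    k <- ncol(uci$features)
    sigs <- lapply(seq_len(nrow(uci$features)), function(i) {
      v <- uci$features[i, ]
      list(angles = seq(0, 360 - 360 / k, by = 360 / k),
           normDistances = v / max(v))
    })
    models <- fitCurves(sigs, gaCfg)
    labels <- uci$labels
  } else if (!is.null(input$models)) {
    models <- input$models
    labels <- as.character(input$labels)
  } else {
    models <- fitCurves(input$masks, gaCfg)
    labels <- as.character(input$labels)
  }
  rows <- list()
  for (step in cfg$angleSteps) {
    features <- featuresFromModels(models, step)
    split <- stratifiedSplit(features, labels,
                             testFraction = cfg$testFraction,
                             seed = cfg$seed + step)
    for (clf in cfg$classifiers) {
      r <- evalClassifier(clf, split, cfg)
      rows[[length(rows) + 1]] <-
        data.frame(classifier = clf, angle_step = step,
                   n_features = ncol(features),
                   cv_mean_accuracy = r$cv$meanAccuracy,
                   cv_sd = r$cv$sdAccuracy,
                   test_accuracy = r$testAccuracy)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "metadata") <- list(seed = cfg$seed, angleSteps = cfg$angleSteps,
                                classifiers = cfg$classifiers,
                                nFolds = cfg$nFolds,
                                testFraction = cfg$testFraction,
                                package = as.character(utils::packageVersion("leafccd")))
  out
}

# Train/tune one classifier on the training part, cross-validate it there,
# and score the held-out test part.
evalClassifier <- function(clf, split, cfg) {
  seed <- cfg$seed
  if (clf == "rbfnn") {
    gaCfg <- cfg$gaCfg; gaCfg$seed <- seed + 1
    factory <- function(x, y) rbfnnTrain(x, y, gaCfg)
    final <- factory(split$trainX, split$trainY)
  } else if (clf == "svm") {
    tuned <- gridSvmTune(split$trainX, split$trainY, gridSize = cfg$gridSize,
                         seed = seed + 2)
    factory <- function(x, y) svmTrain(x, y, C = tuned$C, sigma = tuned$sigma)
    final <- tuned$model
  } else {
    ssaCfg <- cfg$ssaCfg
    if (is.null(ssaCfg$seed)) ssaCfg$seed <- seed + 3
    tuned <- ssaSvmTune(split$trainX, split$trainY, ssaCfg)
    factory <- function(x, y) svmTrain(x, y, C = tuned$C, sigma = tuned$sigma)
    final <- tuned$model
  }
  cv <- kfoldCv(split$trainX, split$trainY, k = cfg$nFolds, factory,
                seed = seed + 4)
  list(cv = cv, testAccuracy = 1 - errorRate(final, split$testX, split$testY))
}
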