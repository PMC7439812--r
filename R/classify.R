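#' Train a prototype RBF-network classifier
#'
#' Every training vector is stored as one hidden-unit prototype; an input is
#' compared against each prototype through the Gaussian activation
#' `exp(-beta_k ||x - mu_k||^2)`, and one output unit per class combines the
#' activations linearly.  By construction a prototype's own activation is
#' exactly 1, so the output for its class is close to 1 when the input
#' matches a stored example.  The per-neuron spreads `beta_k` are tuned by a
#' genetic algorithm that minimizes the RMSE between the output scores and
#' one-hot class targets on an inner validation split; for each candidate
#' spread vector the output weights are re-solved by damped least squares on
#' the training part, so the GA effectively co-tunes spreads and weights.
#'
#' @param features numeric matrix, one row per training vector.
#' @param labels class labels (any atomic type; compared as character).
#' @param cfg a [gaConfig()] controlling the spread search; defaults to a
#'   population of 20 with early stopping.
#' @return object of class `rbfnnClassifier`.
#' @export
rbfnnTrain <- function(features, labels, cfg = gaConfig()) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes")
  if (min(table(labels)) < 2) stop("need at least 2 samples per class")
  if (!all(is.finite(features))) stop("features must be finite")
  n <- nrow(features)
  Y <- outer(labels, classes, `==`) * 1  # one-hot targets
  # squared distances between all training vectors
  sq <- rowSums(features^2)
  D2 <- pmax(outer(sq, sq, `+`) - 2 * tcrossprod(features), 0)
  medD2 <- stats::median(D2[D2 > 0])
  if (!is.finite(medD2) || medD2 <= 0) medD2 <- 1
  withSeed(cfg$seed, {
    idxVal <- unlist(lapply(split(seq_len(n), labels), function(ix)
      sample(ix, max(1, round(cfg$testFraction * length(ix))))))
    idxTr <- setdiff(seq_len(n), idxVal)
    solveW <- function(logb) {
      beta <- exp(logb)
      Phi <- cbind(1, exp(-sweep(D2[idxTr, , drop = FALSE], 2, beta, "*")))
      qr.coef(qr(rbind(Phi, 1e-6 * diag(ncol(Phi)))),
              rbind(Y[idxTr, , drop = FALSE],
                    matrix(0, ncol(Phi), ncol(Y))))
    }
    fitness <- function(logb) {
      W <- tryCatch(solveW(logb), error = function(e) NULL)
      if (is.null(W) || anyNA(W)) return(Inf)
      Phi <- cbind(1, exp(-sweep(D2[idxVal, , drop = FALSE], 2, exp(logb), "*")))
      sqrt(mean((Phi %*% W - Y[idxVal, , drop = FALSE])^2))
    }
    # GA over per-neuron log-spreads, seeded around the median pairwise
    # squared distance
    b0 <- log(1 / medD2)
    pop <- replicate(cfg$populationSize,
                     rnorm(n, b0, 1), simplify = FALSE)
    fit <- vapply(pop, fitness, 0)
    best <- list(logb = pop[[which.min(fit)]], val = min(fit))
    gen <- 0L; since <- 0L
    while (gen < cfg$maxGenerations && since < cfg$patience &&
           best$val > cfg$targetRmse) {
      gen <- gen + 1L
      newPop <- vector("list", cfg$populationSize)
      newPop[[1]] <- best$logb
      for (i in 2:cfg$populationSize) {
        p1 <- pop[[gaTournament(fit)]]
        p2 <- pop[[gaTournament(fit)]]
        ch <- ifelse(runif(n) < 0.5, p1, p2)
        hit <- runif(n) < cfg$mutationRate
        ch[hit] <- ch[hit] + rnorm(sum(hit), 0, 0.3)
        newPop[[i]] <- ch
      }
      pop <- newPop
      fit <- vapply(pop, fitness, 0)
      if (min(fit) < best$val - 1e-12) {
        best <- list(logb = pop[[which.min(fit)]], val = min(fit))
        since <- 0L
      } else since <- since + 1L
    }
    beta <- exp(best$logb)
    # final output weights on all training data with tuned spreads
    Phi <- cbind(1, exp(-sweep(D2, 2, beta, "*")))
    W <- qr.coef(qr(rbind(Phi, 1e-6 * diag(ncol(Phi)))),
                 rbind(Y, matrix(0, ncol(Phi), ncol(Y))))
    structure(list(prototypes = features, betas = beta,
                   bias = W[1, ], outputWeights = W[-1, , drop = FALSE],
                   classes = classes, valRmse = best$val,
                   generations = gen, seed = cfg$seed),
              class = "rbfnnClassifier")
  })
}

#' @export
print.rbfnnClassifier <- function(x, ...) {
  cat("RBFNN classifier:", nrow(x$prototypes), "prototypes,",
      length(x$classes), "classes, validation RMSE",
      signif(x$valRmse, 3), "\n")
  invisible(x)
}

#' Class scores and labels from a prototype RBF-network classifier
#'
#' Scores are the linear combination of prototype activations per class;
#' the predicted label is the argmax, ties broken toward the
#' lexicographically smallest label.
#'
#' @param clf an `rbfnnClassifier`.
#' @param features vector or matrix of inputs (training dimension).
#' @return list with `labels` and a `scores` matrix (one column per class).
#' @export
rbfnnPredict <- function(clf, features) {
  features <- rbind(features)
  if (ncol(features) != ncol(clf$prototypes))
    stop("feature dimension mismatch: expected ", ncol(clf$prototypes))
  sqX <- rowSums(features^2); sqP <- rowSums(clf$prototypes^2)
  D2 <- pmax(outer(sqX, sqP, `+`) - 2 * tcrossprod(features, clf$prototypes), 0)
  Phi <- exp(-sweep(D2, 2, clf$betas, "*"))
  scores <- sweep(Phi %*% clf$outputWeights, 2, clf$bias, `+`)
  colnames(scores) <- clf$classes
  labels <- clf$classes[apply(scores, 1, argmaxTol)]
  list(labels = labels, scores = scores)
}

#' @export
predict.rbfnnClassifier <- function(object, newdata, ...) {
  rbfnnPredict(object, newdata)$labels
}

#' Train a soft-margin Gaussian-kernel SVM
#'
#' Trains a one-vs-one multiclass SVM with the Gaussian kernel
#' `K(x, x') = exp(-||x - x'||^2 / (2 sigma^2))`, penalty `C`, and dual
#' variables bounded by `0 <= alpha_i <= C`.  The quadratic dual is solved
#' by libsvm (through \pkg{e1071}) at tolerance `1e-6`; the exposed
#' parameters are exactly the penalty `C` and the kernel width `sigma`
#' (libsvm's `gamma` is derived as `1 / (2 sigma^2)`), and the alpha bound
#' is verified after training.
#'
#' @param features numeric matrix of training vectors.
#' @param labels class labels.
#' @param C penalty parameter (> 0).
#' @param sigma Gaussian kernel width (> 0).
#' @return object of class `ccdSvm` wrapping the fitted model together with
#'   `C`, `sigma`, support vectors and dual coefficients.
#' @export
svmTrain <- function(features, labels, C = 1, sigma = 1) {
  features <- as.matrix(features)
  if (!all(is.finite(features))) stop("features must be finite")
  if (C <= 0 || sigma <= 0) stop("C and sigma must be positive")
  y <- factor(as.character(labels))
  fit <- e1071::svm(features, y, scale = FALSE, kernel = "radial",
                    gamma = 1 / (2 * sigma^2), cost = C, tolerance = 1e-6)
  if (any(abs(fit$coefs) > C + 1e-6))
    stop("dual feasibility violated: |alpha| exceeds C")
  structure(list(fit = fit, C = C, sigma = sigma,
                 supportVectors = fit$SV, dualCoefs = fit$coefs,
                 bias = fit$rho, classes = levels(y),
                 multiclassScheme = "one-vs-one"),
            class = "ccdSvm")
}

#' @export
print.ccdSvm <- function(x, ...) {
  cat("Gaussian-kernel SVM: C =", signif(x$C, 4), ", sigma =",
      signif(x$sigma, 4), ",", nrow(x$supportVectors),
      "support vectors,", length(x$classes), "classes\n")
  invisible(x)
}

#' @export
predict.ccdSvm <- function(object, newdata, decisionValues = FALSE, ...) {
  p <- predict(object$fit, rbind(newdata), decision.values = decisionValues)
  labels <- as.character(p)
  if (decisionValues)
    list(labels = labels, decisionValues = attr(p, "decision.values"))
  else labels
}

#' Misclassification rate of a fitted classifier
#'
#' The fraction of misclassified samples, `Nerr / Ntotal` -- the quantity
#' the SSA hyperparameter search minimizes.
#'
#' @param model anything with a `predict` method returning labels (a
#'   `ccdSvm`, an `rbfnnClassifier`, or a prediction function).
#' @param features evaluation feature matrix.
#' @param labels true labels.
#' @return misclassified fraction in `[0, 1]`.
#' @export
errorRate <- function(model, features, labels) {
  if (length(labels) == 0) stop("empty evaluation set")
  pred <- if (is.function(model)) model(rbind(features))
    else predict(model, rbind(features))
  mean(as.character(pred) != as.character(labels))
}

#' Serialize a classifier to JSON
#'
#' SVMs are stored as support vectors, dual coefficients, bias terms, `C`
#' and `sigma`; RBFNN classifiers as prototypes, spreads and output
#' weights.
#'
#' @param model a `ccdSvm` or `rbfnnClassifier`.
#' @param path JSON path.
#' @export
writeModelJson <- function(model, path) {
  if (inherits(model, "ccdSvm")) {
    out <- list(type = "svm", C = model$C, sigma = model$sigma,
                supportVectors = model$supportVectors,
                dualCoefs = model$dualCoefs, bias = model$bias,
                classes = model$classes,
                multiclassScheme = model$multiclassScheme)
  } else if (inherits(model, "rbfnnClassifier")) {
    out <- list(type = "rbfnn", prototypes = model$prototypes,
                betas = model$betas, bias = model$bias,
                outputWeights = model$outputWeights, classes = model$classes)
  } else stop("unsupported model type")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
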