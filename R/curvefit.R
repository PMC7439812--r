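#' Genetic algorithm configuration for RBF curve fitting
#'
#' Controls the real-coded GA that selects the number of hidden units, the
#' basis centers and the spreads of the periodic RBF regressor.  Defaults
#' follow the fitting protocol used throughout the package: a population of
#' 20 candidate networks, up to 1000 generations, and early stopping once
#' the held-out RMSE of the signature fit drops to 1%.
#'
#' @param populationSize number of chromosomes (>= 2).
#' @param maxGenerations generation cap.
#' @param targetRmse early-stopping target for the held-out RMSE, as a
#'   fraction of the normalized distance range.
#' @param crossoverRate probability that a child mixes genes of two parents.
#' @param mutationRate per-gene probability of Gaussian mutation.
#' @param nCentersRange allowed range for the number of basis centers.
#' @param patience generations without improvement before giving up.
#' @param testFraction fraction of signature points held out for fitness.
#' @param seed integer seed; the whole fit is deterministic under it.
#' @return object of class `gaConfig`.
#' @export
gaConfig <- function(populationSize = 20, maxGenerations = 1000,
                     targetRmse = 0.01, crossoverRate = 0.9,
                     mutationRate = 0.2, nCentersRange = c(3, 25),
                     patience = 30, testFraction = 0.2, seed = NULL) {
  stopifnot(populationSize >= 2, targetRmse > 0, targetRmse < 1,
            nCentersRange[1] >= 1, nCentersRange[2] >= nCentersRange[1],
            testFraction > 0, testFraction < 1)
  structure(list(populationSize = populationSize,
                 maxGenerations = maxGenerations, targetRmse = targetRmse,
                 crossoverRate = crossoverRate, mutationRate = mutationRate,
                 nCentersRange = as.integer(nCentersRange),
                 patience = patience, testFraction = testFraction,
                 seed = seed),
            class = "gaConfig")
}

# Gaussian RBF design matrix on the circle: exp(-beta_k * d(angle, mu_k)^2)
# with d the circular angular difference in degrees.
rbfDesign <- function(angles, centers, spreads) {
  D <- outer(angles, centers, circDiff)
  exp(-sweep(D * D, 2, spreads, "*"))
}

#' Evaluate a periodic RBF curve model
#'
#' The prediction is `bias + sum_k w_k exp(-beta_k d(angle, mu_k)^2)` where
#' `d` is the circular angular difference in degrees wrapped to
#' `[-180, 180)`, so the fitted curve is 360-degree periodic by
#' construction.
#'
#' @param model an `rbfCurveModel`.
#' @param angles angles in degrees (wrapped modulo 360).
#' @return predicted normalized distances.
#' @export
rbfPredict <- function(model, angles) {
  drop(rbfDesign(wrapAngle(angles), model$centers, model$spreads) %*%
         model$weights) + model$bias
}

#' Fit RBF output weights by damped linear least squares
#'
#' With centers and spreads fixed, the output layer is linear; the weights
#' and bias minimizing the sum of squared residuals are found by QR on the
#' ridge-augmented system (damping `lambda` for conditioning).
#'
#' @param centers basis center angles in degrees.
#' @param spreads positive spreads `beta_k`.
#' @param angles,values training pairs (angle in degrees, normalized
#'   distance).
#' @param lambda ridge damping.
#' @return list with `weights` and `bias`.
#' @export
fitWeights <- function(centers, spreads, angles, values, lambda = 1e-8) {
  k <- length(centers)
  if (length(values) < k + 1)
    stop("need at least nCenters + 1 data points")
  if (any(spreads <= 0)) stop("spreads must be positive")
  A <- cbind(1, rbfDesign(angles, centers, spreads))
  Aaug <- rbind(A, sqrt(lambda) * diag(k + 1))
  qrA <- qr(Aaug)
  if (qrA$rank < k + 1)
    stop("rank-deficient RBF design even after damping")
  coef <- qr.coef(qrA, c(values, numeric(k + 1)))
  list(weights = coef[-1], bias = coef[1])
}

# ---- GA internals ------------------------------------------------------

# chromosome: list(centers = angles, logb = log-spreads)
gaRandomChrom <- function(cfg) {
  nc <- sample(seq(cfg$nCentersRange[1], cfg$nCentersRange[2]), 1)
  list(centers = runif(nc, 0, 360), logb = runif(nc, log(1e-4), log(0.02)))
}

gaMutate <- function(ch, cfg) {
  nc <- length(ch$centers)
  hit <- runif(nc) < cfg$mutationRate
  ch$centers[hit] <- wrapAngle(ch$centers[hit] + rnorm(sum(hit), 0, 5))
  hit <- runif(nc) < cfg$mutationRate
  ch$logb[hit] <- ch$logb[hit] + rnorm(sum(hit), 0, 0.1)
  if (runif(1) < 0.1) {  # structural: add or drop a basis unit
    if (runif(1) < 0.5 && nc < cfg$nCentersRange[2]) {
      ch$centers <- c(ch$centers, runif(1, 0, 360))
      ch$logb <- c(ch$logb, runif(1, log(1e-4), log(0.02)))
    } else if (nc > cfg$nCentersRange[1]) {
      drop <- sample.int(nc, 1)
      ch$centers <- ch$centers[-drop]
      ch$logb <- ch$logb[-drop]
    }
  }
  ch
}

gaCross <- function(p1, p2, cfg) {
  if (runif(1) >= cfg$crossoverRate) return(p1)
  pool <- list(centers = c(p1$centers, p2$centers),
               logb = c(p1$logb, p2$logb))
  nc <- length(if (runif(1) < 0.5) p1$centers else p2$centers)
  pick <- sample.int(length(pool$centers), nc)
  list(centers = pool$centers[pick], logb = pool$logb[pick])
}

gaTournament <- function(fitness, k = 3) {
  cand <- sample.int(length(fitness), k, replace = TRUE)
  cand[which.min(fitness[cand])]
}

#' Fit a periodic RBF curve to a CCD signature with a genetic algorithm
#'
#' The GA searches over the number of hidden units, the center angles and
#' the (log-)spreads; for every candidate the linear output weights are
#' solved exactly by [fitWeights()] on a training subset of the signature
#' points, and fitness is the RMSE on the held-out remainder.  The search
#' stops early when the held-out RMSE reaches `cfg$targetRmse` (1% by
#' default), when no improvement is seen for `cfg$patience` generations, or
#' at the generation cap; the best model so far is always returned, with
#' `targetMet` recording whether the target was reached.
#'
#' @param signature a `contourSignature`, or any list with `angles` and
#'   `normDistances`.
#' @param cfg a [gaConfig()].
#' @return object of class `rbfCurveModel` with centers, spreads, weights,
#'   bias, train/test RMSE, generations used and `targetMet`.
#' @export
gaFitCurve <- function(signature, cfg = gaConfig()) {
  angles <- signature$angles
  values <- signature$normDistances
  n <- length(angles)
  if (n < 16) stop("need at least 16 signature points to fit")
  withSeed(cfg$seed, {
    idxTest <- sample.int(n, max(1, round(cfg$testFraction * n)))
    trainA <- angles[-idxTest]; trainV <- values[-idxTest]
    testA <- angles[idxTest]; testV <- values[idxTest]
    maxNc <- min(cfg$nCentersRange[2], length(trainA) - 1)
    cfgLoc <- cfg
    cfgLoc$nCentersRange <- c(min(cfg$nCentersRange[1], maxNc), maxNc)
    fitOne <- function(ch) {
      fw <- tryCatch(
        fitWeights(ch$centers, exp(ch$logb), trainA, trainV),
        error = function(e) NULL)
      if (is.null(fw)) return(list(rmse = Inf, fw = NULL))
      pred <- drop(rbfDesign(testA, ch$centers, exp(ch$logb)) %*% fw$weights) +
        fw$bias
      list(rmse = sqrt(mean((pred - testV)^2)), fw = fw)
    }
    pop <- replicate(cfg$populationSize, gaRandomChrom(cfgLoc),
                     simplify = FALSE)
    fits <- lapply(pop, fitOne)
    fitness <- vapply(fits, `[[`, 0, "rmse")
    bestIdx <- which.min(fitness)
    best <- list(chrom = pop[[bestIdx]], fit = fits[[bestIdx]],
                 rmse = fitness[bestIdx])
    history <- best$rmse
    gen <- 0L; sinceImprove <- 0L
    while (gen < cfg$maxGenerations && best$rmse > cfg$targetRmse &&
           sinceImprove < cfg$patience) {
      gen <- gen + 1L
      newPop <- vector("list", cfg$populationSize)
      newPop[[1]] <- best$chrom  # elite
      for (i in 2:cfg$populationSize) {
        p1 <- pop[[gaTournament(fitness)]]
        p2 <- pop[[gaTournament(fitness)]]
        newPop[[i]] <- gaMutate(gaCross(p1, p2, cfgLoc), cfgLoc)
      }
      pop <- newPop
      fits <- lapply(pop, fitOne)
      fitness <- vapply(fits, `[[`, 0, "rmse")
      bestIdx <- which.min(fitness)
      if (fitness[bestIdx] < best$rmse - 1e-12) {
        best <- list(chrom = pop[[bestIdx]], fit = fits[[bestIdx]],
                     rmse = fitness[bestIdx])
        sinceImprove <- 0L
      } else sinceImprove <- sinceImprove + 1L
      history <- c(history, best$rmse)
    }
    ch <- best$chrom; fw <- best$fit$fw
    trainPred <- drop(rbfDesign(trainA, ch$centers, exp(ch$logb)) %*%
                        fw$weights) + fw$bias
    structure(list(nCenters = length(ch$centers), centers = ch$centers,
                   spreads = exp(ch$logb), weights = fw$weights,
                   bias = fw$bias,
                   rmseTrain = sqrt(mean((trainPred - trainV)^2)),
                   rmseTest = best$rmse,
                   targetMet = best$rmse <= cfg$targetRmse,
                   generations = gen, history = history, seed = cfg$seed),
              class = "rbfCurveModel")
  })
}

#' @export
print.rbfCurveModel <- function(x, ...) {
  cat("Periodic RBF curve model:", x$nCenters, "centers,",
      "held-out RMSE", signif(x$rmseTest, 3),
      if (x$targetMet) "(target met)" else "(target not met)", "\n")
  invisible(x)
}

#' Sample a fitted curve at uniform angles to build a feature vector
#'
#' Features are the fitted normalized distances at angles
#' `0, step, 2*step, ...` measured from the reference axis, giving
#' `360 / step` values; e.g. a step of 30 degrees gives 12 features, and
#' steps of 20, 10 and 8 degrees give 18, 36 and 45.
#'
#' @param model an `rbfCurveModel`.
#' @param angleStep angular step in degrees; must divide 360.
#' @return numeric feature vector of length `360 / angleStep` with attribute
#'   `angleStep`.
#' @export
sampleFeatures <- function(model, angleStep) {
  if (angleStep <= 0 || 360 %% angleStep != 0)
    stop("angleStep must be a positive divisor of 360")
  k <- 360 %/% angleStep
  v <- rbfPredict(model, seq(0, 360 - angleStep, by = angleStep))
  names(v) <- paste0("f", seq_len(k) - 1)
  attr(v, "angleStep") <- angleStep
  v
}

#' Mask-to-features pipeline for one shape
#'
#' Convenience wrapper: contour extraction, CCD signature, GA curve fit,
#' uniform resampling.
#'
#' @param mask binary mask matrix.
#' @param angleStep angular step in degrees.
#' @param cfg a [gaConfig()].
#' @return feature vector (see [sampleFeatures()]).
#' @export
extractFeatures <- function(mask, angleStep = 10, cfg = gaConfig()) {
  sampleFeatures(gaFitCurve(ccdSignature(mask), cfg), angleStep)
}

#' Fit curve models for a list of masks
#'
#' One GA fit per shape; per-shape seeds are derived from `cfg$seed` plus
#' the shape index so runs are reproducible shape by shape.
#'
#' @param masks list of binary masks, or list of signature-like lists.
#' @param cfg a [gaConfig()].
#' @return list of `rbfCurveModel` objects.
#' @export
fitCurves <- function(masks, cfg = gaConfig()) {
  lapply(seq_along(masks), function(i) {
    cfgi <- cfg
    if (!is.null(cfg$seed)) cfgi$seed <- cfg$seed + i
    sig <- if (is.matrix(masks[[i]])) ccdSignature(masks[[i]]) else masks[[i]]
    gaFitCurve(sig, cfgi)
  })
}

#' Feature matrix from fitted curve models
#'
#' @param models list of `rbfCurveModel` objects.
#' @param angleStep angular step in degrees.
#' @return numeric matrix, one row per shape, columns `f0 ... f{K-1}`.
#' @export
featuresFromModels <- function(models, angleStep) {
  t(vapply(models, function(m) as.numeric(sampleFeatures(m, angleStep)),
           numeric(360 %/% angleStep))) |>
    `colnames<-`(paste0("f", seq_len(360 %/% angleStep) - 1))
}

#' Write / read a feature matrix with labels as CSV
#'
#' One row per shape: feature columns `f0 ... f{K-1}` plus a `label`
#' column.
#'
#' @param features numeric matrix.
#' @param labels label vector.
#' @param path CSV path.
#' @export
writeFeatures <- function(features, labels, path) {
  df <- as.data.frame(features)
  df$label <- labels
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatures
#' @export
readFeatures <- function(path) {
  df <- read.csv(path)
  if (!"label" %in% names(df)) stop("feature CSV must have a 'label' column")
  list(features = as.matrix(df[, setdiff(names(df), "label"), drop = FALSE]),
       labels = as.character(df$label))
}

#' Serialize / deserialize a curve model as JSON
#'
#' @param model an `rbfCurveModel`.
#' @param path JSON path.
#' @export
writeCurveModel <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCurveModel
#' @export
readCurveModel <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(m, class = "rbfCurveModel")
}
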