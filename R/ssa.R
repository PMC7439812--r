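#' Salp Swarm Algorithm configuration
#'
#' @param nAgents number of search agents (salps), default 20.
#' @param maxIterations maximum number of iterations `L_M`.
#' @param bounds `d x 2` matrix (or 2-vector for `d = 1`) of per-dimension
#'   lower and upper bounds.
#' @param targetObjective stop as soon as the best objective value reaches
#'   this level, or `NULL` to disable.
#' @param stagnationPatience stop after this many iterations without any
#'   improvement of the best value; `Inf` to disable.
#' @param seed integer seed.
#' @return object of class `ssaConfig`.
#' @export
ssaConfig <- function(nAgents = 20, maxIterations = 100, bounds,
                      targetObjective = NULL, stagnationPatience = 30,
                      seed = NULL) {
  bounds <- rbind(bounds)
  if (ncol(bounds) != 2 || any(bounds[, 1] >= bounds[, 2]))
    stop("bounds must be a d x 2 matrix with lower < upper")
  if (nAgents < 2) stop("need at least 2 agents")
  structure(list(nAgents = nAgents, maxIterations = maxIterations,
                 bounds = bounds, targetObjective = targetObjective,
                 stagnationPatience = stagnationPatience, seed = seed),
            class = "ssaConfig")
}

#' Exploration/exploitation coefficient of the salp chain
#'
#' `s1 = 2 exp(-(4 Lc / LM)^2)`: close to 2 early (wide exploration around
#' the food source) and decaying to nearly 0 at the final iteration
#' (intensification).
#'
#' @param Lc current iteration (0-based within `[0, LM]`).
#' @param LM maximum number of iterations (> 0).
#' @return value in `(0, 2]`.
#' @export
coefficientS1 <- function(Lc, LM) {
  if (LM <= 0) stop("LM must be positive")
  2 * exp(-(4 * Lc / LM)^2)
}

#' One leader update around the food source
#'
#' Per dimension `j`, with `s2, s3` drawn uniformly on `[0, 1]`:
#' `p_j = F_j + s1 * ((uppb_j - lowb_j) s2 + lowb_j)` when `s3 >= 0.5` and
#' with a minus sign otherwise, clamped to the bounds afterwards.
#'
#' @param food current food source position (best-ever solution).
#' @param bounds `d x 2` bounds matrix.
#' @param s1 exploration coefficient from [coefficientS1()].
#' @param s2,s3 optional fixed random draws (vectors of length `d`),
#'   mainly for testing; drawn uniformly when `NULL`.
#' @return new leader position.
#' @export
updateLeader <- function(food, bounds, s1, s2 = NULL, s3 = NULL) {
  bounds <- rbind(bounds)
  d <- length(food)
  if (is.null(s2)) s2 <- runif(d)
  if (is.null(s3)) s3 <- runif(d)
  step <- s1 * ((bounds[, 2] - bounds[, 1]) * s2 + bounds[, 1])
  p <- ifelse(s3 >= 0.5, food + step, food - step)
  pmin(pmax(p, bounds[, 1]), bounds[, 2])
}

#' Follower chain update
#'
#' Each follower moves to the midpoint of itself and its (already updated)
#' predecessor in the chain: `p_i = (p_i + p_{i-1}) / 2` for `i >= 2`,
#' applied sequentially and clamped to the bounds.
#'
#' @param positions `n x d` matrix of agent positions (row 1 = leader).
#' @param bounds `d x 2` bounds matrix, or `NULL` to skip clamping.
#' @return updated positions matrix.
#' @export
updateFollowers <- function(positions, bounds = NULL) {
  n <- nrow(positions)
  if (n < 2) stop("need at least 2 agents")
  for (i in 2:n)
    positions[i, ] <- (positions[i, ] + positions[i - 1, ]) / 2
  if (!is.null(bounds)) {
    bounds <- rbind(bounds)
    for (i in 2:n)
      positions[i, ] <- pmin(pmax(positions[i, ], bounds[, 1]), bounds[, 2])
  }
  positions
}

#' Minimize a bound-constrained objective with the Salp Swarm Algorithm
#'
#' Agents are initialized uniformly in the box; each iteration evaluates
#' all agents, updates the food source `F` to the best-ever position,
#' recomputes `s1`, moves the leader around `F` and chains the followers
#' through midpoints, clamping everything to the bounds.  Termination: the
#' iteration cap, reaching `targetObjective`, or `stagnationPatience`
#' iterations without improvement.  Non-finite objective values are treated
#' as `+Inf` so such agents can never become the food source.
#'
#' @param objective function of a numeric position vector returning a
#'   scalar to minimize.
#' @param cfg an [ssaConfig()].
#' @return list with `par` (best position), `value`, `trace` (best value
#'   after each iteration, non-increasing), `iterations` and `converged`.
#' @export
ssaMinimize <- function(objective, cfg) {
  stopifnot(inherits(cfg, "ssaConfig"))
  bounds <- cfg$bounds
  d <- nrow(bounds)
  withSeed(cfg$seed, {
    pos <- sapply(seq_len(d), function(j)
      runif(cfg$nAgents, bounds[j, 1], bounds[j, 2]))
    pos <- matrix(pos, cfg$nAgents, d)
    evalAgent <- function(p) {
      v <- objective(p)
      if (!is.finite(v)) Inf else v
    }
    vals <- apply(pos, 1, evalAgent)
    bestI <- which.min(vals)
    food <- pos[bestI, ]; bestVal <- vals[bestI]
    trace <- numeric(0)
    since <- 0L; iter <- 0L
    converged <- !is.null(cfg$targetObjective) &&
      bestVal <= cfg$targetObjective
    while (iter < cfg$maxIterations && !converged &&
           since <= cfg$stagnationPatience) {
      iter <- iter + 1L
      s1 <- coefficientS1(iter, cfg$maxIterations)
      pos[1, ] <- updateLeader(food, bounds, s1)
      pos <- updateFollowers(pos, bounds)
      vals <- apply(pos, 1, evalAgent)
      bestI <- which.min(vals)
      if (vals[bestI] < bestVal) {
        bestVal <- vals[bestI]; food <- pos[bestI, ]
        since <- 0L
      } else since <- since + 1L
      trace <- c(trace, bestVal)
      if (!is.null(cfg$targetObjective) && bestVal <= cfg$targetObjective)
        converged <- TRUE
    }
    list(par = food, value = bestVal, trace = trace, iterations = iter,
         converged = converged)
  })
}

#' Tune SVM hyperparameters with the Salp Swarm Algorithm
#'
#' Each salp position encodes a `(C, sigma)` pair in the two-dimensional
#' box `[0.01, 1000] x [0.01, 100]`.  The objective is the
#' misclassification rate of an SVM trained on an inner 80% of the
#' training data and evaluated on the remaining 20% validation split
#' (stratified and fixed for the whole run, so tuning never sees test
#' data).  The search stops when the objective reaches
#' `targetObjective` (0.025 by default), stagnates, or hits the iteration
#' cap; the returned model is retrained on all training data at the tuned
#' parameters.
#'
#' @param features training feature matrix.
#' @param labels training labels.
#' @param cfg an [ssaConfig()]; if `bounds`/`targetObjective` are missing
#'   the defaults above are used.
#' @param innerFraction fraction of the training data held out as the inner
#'   validation split.
#' @return list with `C`, `sigma`, `model` (final `ccdSvm`), `value` (best
#'   objective reached), `trace`, `iterations`, `converged`.
#' @export
ssaSvmTune <- function(features, labels,
                       cfg = ssaConfig(bounds = svmTuneBounds(),
                                       targetObjective = 0.025),
                       innerFraction = 0.2) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("need at least 2 classes")
  split <- stratifiedSplit(features, labels, testFraction = innerFraction,
                           seed = cfg$seed)
  objective <- function(p) {
    m <- tryCatch(svmTrain(split$trainX, split$trainY, C = p[1], sigma = p[2]),
                  error = function(e) NULL)
    if (is.null(m)) return(Inf)
    errorRate(m, split$testX, split$testY)
  }
  res <- ssaMinimize(objective, cfg)
  model <- svmTrain(features, labels, C = res$par[1], sigma = res$par[2])
  list(C = res$par[1], sigma = res$par[2], model = model,
       value = res$value, trace = res$trace, iterations = res$iterations,
       converged = res$converged)
}

#' Default SVM hyperparameter search box
#'
#' Penalty `C` in `[0.01, 1000]`, kernel width `sigma` in `[0.01, 100]`.
#'
#' @return `2 x 2` bounds matrix with rownames `C` and `sigma`.
#' @export
svmTuneBounds <- function() {
  matrix(c(0.01, 1000, 0.01, 100), 2, 2, byrow = TRUE,
         dimnames = list(c("C", "sigma"), c("lower", "upper")))
}

#' Write an SSA tuning trace as CSV
#'
#' @param tune result of [ssaSvmTune()].
#' @param path CSV path.
#' @export
writeTuneTrace <- function(tune, path) {
  # an empty trace means the initial population already met the target
  tr <- if (length(tune$trace)) tune$trace else tune$value
  write.csv(data.frame(iteration = seq_along(tr) - !length(tune$trace),
                       best_objective = tr,
                       C = tune$C, sigma = tune$sigma),
            path, row.names = FALSE)
  invisible(path)
}
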