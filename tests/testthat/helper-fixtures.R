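# Shared fixtures (cached across tests) and independent oracles.

.fixtures <- new.env(parent = emptyenv())

fixtureCached <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# A moderately lobed test shape and its signature / curve fit.
fixtureShape <- function() fixtureCached("shape", {
  spec <- radialShapeSpec(100, list(c(2, 0.15, 0), c(5, 0.08, 1.0)),
                          noiseSd = 0.005, seed = 7)
  mask <- makeShape(spec)
  sig <- ccdSignature(mask)
  list(spec = spec, mask = mask, sig = sig,
       model = gaFitCurve(sig, gaConfig(seed = 7)))
})

# Shape with one dominant radial lobe, so the farthest-point reference
# axis is stable under rotation/scale perturbations (unlike shapes with
# nearly tied lobes, where the reference can flip).
fixtureStableShape <- function() fixtureCached("stableShape", {
  spec <- radialShapeSpec(100, list(c(2, 0.15, 0), c(3, 0.10, 0.5)),
                          noiseSd = 0.005, seed = 7)
  mask <- makeShape(spec)
  list(spec = spec, mask = mask, sig = ccdSignature(mask))
})

# Small 3-class dataset with fitted curves and 36-point features.
fixtureDataset <- function() fixtureCached("dataset", {
  spec <- synthDatasetSpec(nClasses = 3, samplesPerClass = 6,
                           scaleRange = c(0.8, 1.25), seed = 5)
  ds <- makeDataset(spec)
  models <- fitCurves(ds$masks, gaConfig(seed = 5))
  list(ds = ds, models = models,
       features = featuresFromModels(models, 10), labels = ds$labels)
})

# Easily separable Gaussian-blob feature sets for classifier tests.
blobData <- function(nPerClass = 20, nClasses = 3, dim = 5, sdWithin = 0.3,
                     seed = 1) {
  set.seed(seed)
  # class centers on distinct axes, >= 6 within-class sd apart
  centers <- matrix(0, nClasses, dim)
  for (k in seq_len(nClasses))
    centers[k, (k - 1) %% dim + 1] <- 6 * sdWithin * ceiling(k / dim) * k
  x <- do.call(rbind, lapply(seq_len(nClasses), function(k)
    sweep(matrix(rnorm(nPerClass * dim, sd = sdWithin), nPerClass, dim),
          2, centers[k, ], `+`)))
  list(x = x, y = rep(paste0("c", seq_len(nClasses)), each = nPerClass))
}

# Oracle: foreground pixels of the largest component that touch the
# exterior background (flood-filled from the border) through a 4-neighbor
# side.  Independent of the tracing code path.
boundaryScanOracle <- function(mask) {
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask)))))
  tab <- tabulate(lab[lab > 0])
  comp <- matrix(as.integer(lab == which.max(tab)), nrow(mask), ncol(mask))
  bg <- 1L - comp
  bgl <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(bg)))))
  H <- nrow(bgl); W <- ncol(bgl)
  ext <- bgl %in% unique(c(bgl[1, ], bgl[H, ], bgl[, 1], bgl[, W])) & bg == 1L
  ext <- matrix(ext, H, W)
  out <- matrix(0L, 0, 2)
  for (y in seq_len(H)) for (x in seq_len(W)) {
    if (comp[y, x] == 1L) {
      nb <- rbind(c(y + 1, x), c(y - 1, x), c(y, x + 1), c(y, x - 1))
      touch <- FALSE
      for (r in seq_len(4)) {
        yy <- nb[r, 1]; xx <- nb[r, 2]
        if (yy < 1 || yy > H || xx < 1 || xx > W || ext[yy, xx]) touch <- TRUE
      }
      if (touch) out <- rbind(out, c(x, y))
    }
  }
  out
}

ptsKey <- function(p) paste(p[, 1], p[, 2])

# Oracle: exact soft-margin SVM dual by active-set enumeration, for binary
# problems with n <= 8.  Maximizes sum(a) - a' Q a / 2 subject to
# 0 <= a <= C, sum(a * y) = 0, with Q = (y y') * K.  Each variable is at
# its lower bound, upper bound, or free; every assignment is enumerated and
# the KKT system solved for the free set.
svmDualOracle <- function(K, y, C) {
  n <- length(y)
  stopifnot(n <= 8, all(y %in% c(-1, 1)))
  Q <- (y %o% y) * K
  bestObj <- -Inf; best <- NULL
  states <- expand.grid(rep(list(0:2), n))  # 0 = at 0, 1 = at C, 2 = free
  for (r in seq_len(nrow(states))) {
    st <- as.integer(states[r, ])
    free <- which(st == 2); up <- which(st == 1)
    a <- numeric(n); a[up] <- C
    if (length(free) > 0) {
      # KKT: Q[f, ] a + y_f * b = 1 for free f; sum(a y) = 0
      A <- rbind(cbind(Q[free, free, drop = FALSE], y[free]),
                 c(y[free], 0))
      rhs <- c(1 - (if (length(up)) Q[free, up, drop = FALSE] %*% a[up]
                    else numeric(length(free))),
               -sum(a[up] * y[up]))
      sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      a[free] <- sol[seq_along(free)]
      b <- sol[length(sol)]
      if (any(a[free] < -1e-9) || any(a[free] > C + 1e-9)) next
    } else {
      if (abs(sum(a * y)) > 1e-9) next
      b <- NA  # bias undetermined; only accept if some free var exists
      next
    }
    # KKT sign conditions for bound variables: grad_i = (Q a)_i + y_i b - 1
    g <- drop(Q %*% a) + y * b - 1
    if (any(g[st == 0] < -1e-7)) next   # at 0 requires grad >= 0
    if (any(g[st == 1] > 1e-7)) next    # at C requires grad <= 0
    obj <- sum(a) - drop(crossprod(a, Q %*% a)) / 2
    if (obj > bestObj) {
      bestObj <- obj
      best <- list(alpha = a, b = b, objective = obj)
    }
  }
  best
}

# Gaussian kernel with the package's width convention.
gaussK <- function(X, sigma) {
  d2 <- as.matrix(dist(X))^2
  exp(-d2 / (2 * sigma^2))
}

# Linear interpolation of a raw signature on the circle at given angles.
resampleSignature <- function(sig, at) {
  ord <- order(sig$angles)
  a <- sig$angles[ord]; v <- sig$normDistances[ord]
  a <- c(a, a[1] + 360); v <- c(v, v[1])
  approx(a, v, xout = ifelse(at < a[1], at + 360, at), ties = mean)$y
}
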