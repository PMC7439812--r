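test_that("rbfPredict evaluates the periodic Gaussian basis", {
  m1 <- structure(list(centers = 90, spreads = 1, weights = 1, bias = 0),
                  class = "rbfCurveModel")
  expect_equal(rbfPredict(m1, 90), 1)               # exp(0)
  m2 <- structure(list(centers = 90, spreads = 0.5, weights = 1, bias = 0),
                  class = "rbfCurveModel")
  expect_equal(rbfPredict(m2, 91), exp(-0.5))
  expect_equal(rbfPredict(m1, 10), rbfPredict(m1, 370))  # periodicity
  # distance is circular: 350 vs 10 degrees are 20 degrees apart
  m3 <- structure(list(centers = 350, spreads = 0.01, weights = 1, bias = 0),
                  class = "rbfCurveModel")
  expect_equal(rbfPredict(m3, 10), exp(-0.01 * 400))
})

test_that("fitWeights solves the damped linear least-squares problem", {
  set.seed(11)
  centers <- c(20, 150, 280); spreads <- c(0.002, 0.001, 0.003)
  truth <- structure(list(centers = centers, spreads = spreads,
                          weights = c(0.5, -0.3, 0.8), bias = 0.7),
                     class = "rbfCurveModel")
  ang <- seq(0, 355, by = 5)
  y <- rbfPredict(truth, ang)
  fw <- fitWeights(centers, spreads, ang, y)
  fit <- structure(list(centers = centers, spreads = spreads,
                        weights = fw$weights, bias = fw$bias),
                   class = "rbfCurveModel")
  expect_lt(sqrt(mean((rbfPredict(fit, ang) - y)^2)), 1e-6)

  # constant data with one center is reproduced at the center
  fwc <- fitWeights(180, 0.001, ang, rep(0.42, length(ang)))
  cm <- structure(list(centers = 180, spreads = 0.001,
                       weights = fwc$weights, bias = fwc$bias),
                  class = "rbfCurveModel")
  expect_equal(rbfPredict(cm, 180), 0.42, tolerance = 1e-6)

  expect_error(fitWeights(c(10, 20, 30), rep(0.01, 3), c(1, 2, 3), c(1, 2, 3)),
               "at least")
})

test_that("fitWeights agrees with a normal-equations oracle", {
  set.seed(12)
  for (rep in 1:3) {
    centers <- runif(5, 0, 360); spreads <- exp(runif(5, log(1e-3), log(1e-2)))
    ang <- runif(40, 0, 360); y <- runif(40)
    fw <- fitWeights(centers, spreads, ang, y, lambda = 1e-8)
    # independent route: explicit normal equations
    D <- outer(ang, centers, function(a, b) {
      d <- (a - b) %% 360; ifelse(d >= 180, d - 360, d)
    })
    A <- cbind(1, exp(-sweep(D^2, 2, spreads, "*")))
    coef <- solve(t(A) %*% A + 1e-8 * diag(6), t(A) %*% y)
    rImpl <- sqrt(sum((A %*% c(fw$bias, fw$weights) - y)^2))
    rOracle <- sqrt(sum((A %*% coef - y)^2))
    expect_lt(abs(rImpl - rOracle), 1e-8)
  }
})

test_that("the GA fit reaches 1% held-out RMSE on analytic signatures", {
  # constant target: a circle
  circ <- gaFitCurve(ccdSignature(makeShape(radialShapeSpec(50, seed = 2))),
                     gaConfig(maxGenerations = 50, seed = 2))
  expect_lte(circ$rmseTest, 0.01)

  # lobed radial-harmonic shape (the curve-fitting quality target)
  sh <- fixtureShape()
  expect_lte(sh$model$rmseTest, 0.01)
  expect_true(sh$model$targetMet)

  # determinism under seed
  again <- gaFitCurve(sh$sig, gaConfig(seed = 7))
  expect_identical(again$centers, sh$model$centers)
  expect_identical(again$weights, sh$model$weights)

  expect_error(gaFitCurve(list(angles = 1:10, normDistances = runif(10))),
               "at least 16")
})

test_that("GA best fitness never increases across generations", {
  sig <- ccdSignature(makeShape(radialShapeSpec(40, list(c(4, 0.2, 0)),
                                                noiseSd = 0.02, seed = 3)))
  m <- gaFitCurve(sig, gaConfig(targetRmse = 0.001, maxGenerations = 40,
                                patience = 40, seed = 3))
  expect_true(all(diff(m$history) <= 0))
})

test_that("enlarging a fixed center grid never hurts training RMSE", {
  sh <- fixtureShape()
  ang <- sh$sig$angles; val <- sh$sig$normDistances
  grid <- seq(0, 359, length.out = 24)
  rmse <- vapply(c(4, 8, 16, 24), function(k) {
    ctr <- grid[seq_len(k)]
    fw <- fitWeights(ctr, rep(5e-3, k), ang, val)
    mm <- structure(list(centers = ctr, spreads = rep(5e-3, k),
                         weights = fw$weights, bias = fw$bias),
                    class = "rbfCurveModel")
    sqrt(mean((rbfPredict(mm, ang) - val)^2))
  }, 0)
  expect_true(all(diff(rmse) <= 1e-10))
})

test_that("feature sampling maps angular steps to feature counts", {
  sh <- fixtureShape()
  expect_length(sampleFeatures(sh$model, 30), 12)
  expect_length(sampleFeatures(sh$model, 20), 18)
  expect_length(sampleFeatures(sh$model, 10), 36)
  expect_length(sampleFeatures(sh$model, 8), 45)
  expect_error(sampleFeatures(sh$model, 7), "divisor")

  # first feature sits on the reference axis
  expect_equal(unname(sampleFeatures(sh$model, 30)[1]),
               rbfPredict(sh$model, 0))

  const <- structure(list(centers = 10, spreads = 1e-9, weights = 0,
                          bias = 0.6), class = "rbfCurveModel")
  expect_true(all(abs(sampleFeatures(const, 30) - 0.6) < 1e-9))
})

test_that("curve models and feature matrices round-trip through files", {
  sh <- fixtureShape()
  mp <- withr::local_tempfile(fileext = ".json")
  writeCurveModel(sh$model, mp)
  back <- readCurveModel(mp)
  expect_equal(rbfPredict(back, c(0, 45, 123)),
               rbfPredict(sh$model, c(0, 45, 123)))

  fx <- fixtureDataset()
  fp <- withr::local_tempfile(fileext = ".csv")
  writeFeatures(fx$features, fx$labels, fp)
  rf <- readFeatures(fp)
  expect_equal(rf$features, fx$features, ignore_attr = TRUE)
  expect_identical(rf$labels, fx$labels)
  # a CSV without labels is rejected
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(f0 = 1:3), bad, row.names = FALSE)
  expect_error(readFeatures(bad), "label")
})
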