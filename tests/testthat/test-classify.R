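test_that("the prototype RBF network recalls and generalizes", {
  blobs <- blobData(nPerClass = 50, nClasses = 2, dim = 2, sdWithin = 0.4,
                    seed = 31)
  split <- stratifiedSplit(blobs$x, blobs$y, testFraction = 0.2, seed = 31)
  clf <- rbfnnTrain(split$trainX, split$trainY,
                    gaConfig(maxGenerations = 30, patience = 10, seed = 31))

  # a stored training vector activates its own class with a score near 1
  p <- rbfnnPredict(clf, split$trainX[1, ])
  expect_equal(p$labels, split$trainY[1])
  expect_gt(p$scores[1, split$trainY[1]], 0.7)

  # held-out accuracy on well-separated blobs
  expect_gte(1 - errorRate(clf, split$testX, split$testY), 0.95)
})

test_that("RBFNN scores decay to the bias far from all prototypes", {
  protos <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)
  clf <- structure(list(prototypes = protos, betas = c(1, 1),
                        bias = c(a = 0.2, b = 0.1),
                        outputWeights = matrix(c(1, 0, 0, 1), 2, 2),
                        classes = c("a", "b")),
                   class = "rbfnnClassifier")
  far <- c(50, 50)
  sc <- rbfnnPredict(clf, far)$scores
  expect_lt(max(abs(sc - rbind(clf$bias))), 1e-3)
})

test_that("RBFNN prediction is deterministic and validates input", {
  clf <- structure(list(prototypes = matrix(0, 1, 3), betas = 1,
                        bias = c(a = 0.5, b = 0.5),
                        outputWeights = matrix(0, 1, 2),
                        classes = c("b", "a")),
                   class = "rbfnnClassifier")
  # both classes score identically -> smallest label wins
  expect_equal(rbfnnPredict(clf, c(0, 0, 0))$labels, "b")
  clf$classes <- sort(clf$classes)
  expect_equal(rbfnnPredict(clf, c(0, 0, 0))$labels, "a")
  expect_error(rbfnnPredict(clf, c(0, 0)), "dimension mismatch")
  expect_error(rbfnnTrain(matrix(1:4, 2), c("a", "a")), "2 classes")
})

test_that("the SVM separates simple and kernel-separable patterns", {
  x <- rbind(c(0, 0), c(2, 2))
  y <- c("neg", "pos")
  m <- svmTrain(x, y, C = 1000, sigma = 1)
  expect_equal(predict(m, x), y)
  expect_equal(errorRate(m, x, y), 0)

  # XOR needs the kernel trick
  xor <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  yx <- c("a", "a", "b", "b")
  mx <- svmTrain(xor, yx, C = 100, sigma = 0.5)
  expect_equal(errorRate(mx, xor, yx), 0)
  expect_true(all(abs(mx$dualCoefs) <= 100 + 1e-6))
})

test_that("the SVM dual matches an exhaustive active-set QP oracle", {
  cases <- list(
    list(x = rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0)),
         y = c(1, 1, -1, -1), C = 100, sigma = 0.5),
    list(x = rbind(c(0, 0), c(2, 2)), y = c(1, -1), C = 10, sigma = 1)
  )
  set.seed(41)
  for (s in 1:3) {
    n <- 6
    cases[[length(cases) + 1]] <-
      list(x = matrix(rnorm(2 * n), n, 2),
           y = rep(c(1, -1), length.out = n), C = 5, sigma = 1.2)
  }
  for (cs in cases) {
    lbl <- ifelse(cs$y > 0, "p", "n")
    m <- svmTrain(cs$x, lbl, C = cs$C, sigma = cs$sigma)
    K <- gaussK(cs$x, cs$sigma)
    oracle <- svmDualOracle(K, cs$y, cs$C)
    expect_false(is.null(oracle))
    # compare decision values f(x_i) = sum_j a_j y_j K(i, j) + b
    fOracle <- drop(K %*% (oracle$alpha * cs$y)) + oracle$b
    dv <- predict(m, cs$x, decisionValues = TRUE)$decisionValues
    # e1071 names the column "A/B" with positive values meaning class A
    sgn <- if (strsplit(colnames(dv)[1], "/")[[1]][1] == "p") 1 else -1
    expect_lt(max(abs(sgn * drop(dv) - fOracle)), 1e-4)
  }
})

test_that("raising C never increases SVM training error", {
  blobs <- blobData(nPerClass = 15, nClasses = 2, dim = 2, sdWithin = 1.5,
                    seed = 32)
  errs <- vapply(c(0.1, 1, 10, 100), function(C)
    errorRate(svmTrain(blobs$x, blobs$y, C = C, sigma = 1),
              blobs$x, blobs$y), 0)
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("svmTrain validates inputs and enforces dual feasibility", {
  expect_error(svmTrain(matrix(c(1, NA, 2, 3), 2), c("a", "b")), "finite")
  expect_error(svmTrain(matrix(1:4, 2), c("a", "b"), C = -1), "positive")
  blobs <- blobData(nPerClass = 10, nClasses = 3, dim = 3, seed = 33)
  m <- svmTrain(blobs$x, blobs$y, C = 2, sigma = 1)
  expect_true(all(abs(m$dualCoefs) <= 2 + 1e-6))
  expect_equal(m$multiclassScheme, "one-vs-one")
})

test_that("errorRate is the misclassified fraction", {
  truth <- rep(c("a", "b"), each = 4)
  pred6 <- function(x) c("a", "a", "b", "a", "b", "b", "a", "b")
  expect_equal(errorRate(pred6, matrix(0, 8, 1), truth), 0.25)
  expect_equal(errorRate(function(x) truth, matrix(0, 8, 1), truth), 0)
  # majority-class predictor on a balanced 4-class set
  y4 <- rep(c("a", "b", "c", "d"), each = 25)
  expect_equal(errorRate(function(x) rep("a", 100), matrix(0, 100, 1), y4),
               0.75)
  expect_error(errorRate(pred6, matrix(0, 0, 1), character(0)), "empty")
})

test_that("classifier models serialize to JSON", {
  blobs <- blobData(nPerClass = 5, nClasses = 2, dim = 2, seed = 34)
  m <- svmTrain(blobs$x, blobs$y, C = 3, sigma = 2)
  p <- withr::local_tempfile(fileext = ".json")
  writeModelJson(m, p)
  j <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(j$type, "svm")
  expect_equal(j$C, 3)
  expect_equal(j$sigma, 2)
  expect_equal(length(j$dualCoefs), nrow(m$supportVectors))

  clf <- rbfnnTrain(blobs$x, blobs$y,
                    gaConfig(maxGenerations = 5, patience = 3, seed = 34))
  writeModelJson(clf, p)
  j2 <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(j2$type, "rbfnn")
  expect_equal(dim(j2$prototypes), dim(blobs$x))
})
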