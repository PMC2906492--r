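# Learners: down-sampled RF, weighted SVM, RFR, SVR, RI, persistence.

# small linearly separable 58-dim problem: two Gaussian blobs 10 sigma apart
makeBlobs <- function(n = 120, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * 58), n, 58)
  y <- rep(c(1L, 0L), length.out = n)
  X[y == 1, 1:4] <- X[y == 1, 1:4] + 10
  list(X = X, y = y)
}

test_that("down-sampled RF draws equal class counts for every tree", {
  set.seed(2)
  X <- matrix(rnorm(400 * 58), 400, 58)
  y <- c(rep(1L, 100), rep(0L, 300))
  m <- trainClassifier(X, y, thermoParams("rf", n_trees = 25, seed = 3))
  inbag <- m@fitted$state$inbag
  expect_identical(nrow(inbag), 25L)
  expect_true(all(inbag[, "pos"] == 100))
  expect_true(all(inbag[, "neg"] == 100))
})

test_that("both classifiers separate 10-sigma blobs perfectly in training", {
  b <- makeBlobs()
  for (algo in c("rf", "svm")) {
    params <- thermoParams(algo, n_trees = 100, seed = 4)
    m <- trainClassifier(b$X, b$y, params)
    pr <- predict(m, b$X)
    cc <- ThermoShift:::.confusion(pr$sign, ifelse(b$y == 1, 1, -1))
    expect_equal(confusionMetrics(cc)$MCC, 1.0, info = algo)
  }
})

test_that("classifier training validates its inputs", {
  b <- makeBlobs(40)
  expect_error(trainClassifier(b$X, rep(1L, 40), thermoParams("rf")),
               "both classes")
  expect_error(trainClassifier(b$X, b$y[-1], thermoParams("rf")), "length")
  Xbad <- b$X; Xbad[1, 1] <- NA
  expect_error(trainClassifier(Xbad, b$y, thermoParams("rf")), "finite")
  expect_error(trainClassifier(b$X[, 1:10], b$y, thermoParams("rf")), "58")
})

test_that("SVM applies the 3-fold penalty weight to the stabilizing class", {
  b <- makeBlobs(60, seed = 9)
  m <- trainClassifier(b$X, b$y, thermoParams("svm"))
  ub <- m@fitted$state$upper_bounds
  expect_equal(unique(ub[b$y == 1]) / unique(ub[b$y == 0]), 3.0)
  expect_equal(m@params$svm_pos_class_weight, 3.0)
})

test_that("RF score O equals the fraction of trees voting stabilizing", {
  b <- makeBlobs(80, seed = 5)
  m <- trainClassifier(b$X, b$y, thermoParams("rf", n_trees = 10, seed = 6))
  set.seed(7)
  Xnew <- matrix(rnorm(15 * 58), 15, 58)
  Xnew[1:7, 1:4] <- Xnew[1:7, 1:4] + 5  # near the positive blob
  pr <- predict(m, Xnew, return_votes = TRUE)
  votes <- attr(pr, "votes")
  expect_identical(dim(votes), c(15L, 10L))
  expect_equal(pr$O, rowMeans(votes))
  expect_identical(pr$sign, ifelse(pr$O > 0.5, 1L, -1L))
})

test_that("regressors recover structure and validate inputs", {
  set.seed(8)
  X <- matrix(rnorm(500 * 58), 500, 58)
  target <- 2 * X[, 3] - X[, 10] + 0.5 * X[, 44]
  m <- trainRegressor(X, target, thermoParams("rfr", n_trees = 300, seed = 9))
  rTrain <- pearsonR(target, predict(m, X)$ddg_pred)
  expect_gte(rTrain, 0.99)

  # identical-zero targets -> zero predictions
  m0 <- trainRegressor(X[1:50, ], rep(0, 50), thermoParams("rfr", n_trees = 20))
  expect_equal(predict(m0, X[1:50, ])$ddg_pred, rep(0, 50), tolerance = 1e-6)
  m0s <- trainRegressor(X[1:50, ], rep(0, 50), thermoParams("svr"))
  expect_equal(predict(m0s, X[1:50, ])$ddg_pred, rep(0, 50), tolerance = 0.11)

  expect_error(trainRegressor(X[1:9, ], target[1:9], thermoParams("rfr")),
               "10 rows")
  # determinism
  m2 <- trainRegressor(X, target, thermoParams("rfr", n_trees = 300, seed = 9))
  expect_equal(predict(m2, X)$ddg_pred, predict(m, X)$ddg_pred)
})

test_that("prediction fills task-appropriate fields and checks dimensions", {
  b <- makeBlobs(60, seed = 10)
  cls <- trainClassifier(b$X, b$y, thermoParams("rf", n_trees = 50, seed = 1))
  pc <- predict(cls, b$X[1:5, ])
  expect_true(all(pc$O >= 0 & pc$O <= 1))
  expect_true(all(pc$RI == reliabilityIndex(pc$O)))
  expect_true(all(is.na(pc$ddg_pred)))

  reg <- trainRegressor(b$X, rnorm(60), thermoParams("svr"))
  pg <- predict(reg, b$X[1:5, ])
  expect_true(all(is.na(pg$O)))
  expect_identical(pg$sign, ifelse(pg$ddg_pred > 0, 1L, -1L))
  expect_error(predict(cls, b$X[, 1:20]), "58")
})

test_that("reliability index follows floor(20 |O - 0.5|), clipped to 0..10", {
  expect_identical(reliabilityIndex(0.5), 0L)
  expect_identical(reliabilityIndex(1.0), 10L)
  expect_identical(reliabilityIndex(0.0), 10L)
  expect_identical(reliabilityIndex(0.87), 7L)  # floor(7.4)
  expect_error(reliabilityIndex(1.2), "\\[0, 1\\]")
  # non-decreasing in |O - 0.5| over a dense grid
  O <- seq(0.5, 1, length.out = 501)
  expect_true(all(diff(reliabilityIndex(O)) >= 0))
})

test_that("both classifiers beat chance on the noisy synthetic world", {
  # true sign is a threshold on a noisy monotone score (snr 1, ~1:3 classes)
  d <- generateDataset(syntheticConfig(n_mutants = 2000, seed = 21))$data
  X <- ThermoShift:::encodedMatrix(d)
  y <- as.integer(d$ddg > 0)
  tr <- 1:1300; te <- 1301:2000

  rf <- trainClassifier(X[tr, ], y[tr],
                        thermoParams("rf", n_trees = 150, seed = 1))
  ccRf <- ThermoShift:::.confusion(predict(rf, X[te, ])$sign,
                                   ifelse(y[te] == 1, 1, -1))
  expect_gt(confusionMetrics(ccRf)$MCC, 0.3)

  # SVM on a 600-row subsample (the exact QP solver is O(n^3)); kernel width
  # 1/58 - the standard 1/p heuristic - since the published gamma = 2 was
  # tuned for a different feature distribution and is degenerate here
  set.seed(1)
  sub <- sample(tr, 600)
  svm <- trainClassifier(X[sub, ], y[sub],
                         thermoParams("svm", svr_gamma = 1 / 58, seed = 1))
  ccSvm <- ThermoShift:::.confusion(predict(svm, X[te, ])$sign,
                                    ifelse(y[te] == 1, 1, -1))
  expect_gt(confusionMetrics(ccSvm)$MCC, 0.3)
})

test_that("model save/load round-trips predictions and validates versions", {
  b <- makeBlobs(60, seed = 11)
  m <- trainClassifier(b$X, b$y, thermoParams("rf", n_trees = 30, seed = 2))
  p <- tempfile(fileext = ".rds")
  saveModel(m, p)
  m2 <- loadModel(p)
  set.seed(12)
  Xnew <- matrix(rnorm(20 * 58), 20, 58)
  expect_identical(predict(m2, Xnew), predict(m, Xnew))
  expect_equal(modelParams(m2), modelParams(m))

  corrupt <- tempfile(fileext = ".rds")
  writeLines("not a model", corrupt)
  expect_error(loadModel(corrupt))

  wrongVer <- readRDS(p)
  wrongVer$header$schema_version <- "0.0"
  p2 <- tempfile(fileext = ".rds")
  saveRDS(wrongVer, p2)
  expect_error(loadModel(p2), "0\\.0.*1\\.0|version")
})
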