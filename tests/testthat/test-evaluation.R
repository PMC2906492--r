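# Evaluation harness: folds, metrics, ROC, CV, RI curve, importance.

test_that("k-fold splits partition indices with near-equal sizes", {
  sp <- kfoldSplit(100, 10, seed = 1)
  tests <- lapply(sp, `[[`, "test")
  expect_identical(sort(unlist(tests)), 1:100)
  expect_true(all(lengths(tests) == 10L))
  for (f in sp) expect_identical(sort(c(f$train, f$test)), 1:100)

  sp2 <- kfoldSplit(103, 10, seed = 2)
  expect_lte(diff(range(lengths(lapply(sp2, `[[`, "test")))), 1L)

  expect_identical(kfoldSplit(50, 5, seed = 3), kfoldSplit(50, 5, seed = 3))
  expect_error(kfoldSplit(5, 10), "folds")
})

test_that("stratified and grouped splits respect their constraints", {
  labels <- rep(c(1, 0), c(20, 80))
  sp <- kfoldSplit(100, 10, labels = labels, seed = 4)
  posPerFold <- vapply(sp, function(f) sum(labels[f$test] == 1), numeric(1))
  expect_true(all(posPerFold == 2))

  groups <- rep(paste0("p", 1:10), each = 10)
  spg <- kfoldSplit(100, 5, groups = groups, seed = 5)
  for (f in spg) {
    inTest <- unique(groups[f$test])
    expect_length(intersect(inTest, unique(groups[f$train])), 0L)
  }
})

test_that("confusion metrics match the defining formulas", {
  m <- confusionMetrics(TP = 50, TN = 50, FP = 0, FN = 0)
  expect_equal(m$Q2, 100)
  expect_equal(m$MCC, 1)
  expect_equal(m$sensitivity, 100)
  expect_equal(m$specificity, 100)

  degenerate <- confusionMetrics(TP = 0, TN = 90, FP = 0, FN = 10)
  expect_equal(degenerate$sensitivity, 0)
  expect_equal(degenerate$MCC, 0)  # zero-factor guard

  # spreadsheet-style recomputation
  TP <- 600; FN <- 236; TN <- 2100; FP <- 430
  m2 <- confusionMetrics(TP = TP, TN = TN, FP = FP, FN = FN)
  expect_equal(m2$Q2, 100 * (TP + TN) / (TP + TN + FP + FN))
  expect_equal(m2$MCC, (TP * TN - FP * FN) /
                 sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)))
  expect_equal(m2$sensitivity, 100 * TP / (TP + FN))
  expect_equal(m2$specificity, 100 * TN / (TN + FP))

  expect_error(confusionMetrics(TP = 0, TN = 0, FP = 0, FN = 0), "zero")
})

test_that("MCC equals the Pearson correlation of the binary vectors", {
  set.seed(6)
  for (i in 1:200) {
    cc <- as.list(rmultinom(1, sample(20:200, 1), rep(0.25, 4))[, 1])
    names(cc) <- c("TP", "TN", "FP", "FN")
    pred <- c(rep(1, cc$TP), rep(0, cc$TN), rep(1, cc$FP), rep(0, cc$FN))
    truth <- c(rep(1, cc$TP), rep(0, cc$TN), rep(0, cc$FP), rep(1, cc$FN))
    mcc <- confusionMetrics(cc)$MCC
    if (sd(pred) > 0 && sd(truth) > 0) {
      expect_equal(mcc, cor(pred, truth), tolerance = 1e-12)
    } else {
      expect_equal(mcc, 0)
    }
  }
})

test_that("pearsonR matches the brute-force product-moment formula", {
  expect_equal(pearsonR(1:10, 1:10), 1)
  expect_equal(pearsonR(1:10, -(1:10)), -1)
  x <- c(1, 2, 3, 4); y <- c(1.1, 1.9, 3.2, 3.8)
  brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearsonR(x, y), brute)
  expect_error(pearsonR(1:3, rep(2, 3)), "variance")
  expect_error(pearsonR(1:3, 1:4), "length")
})

test_that("ROC/AUC matches the concordant-pair rank statistic", {
  perfect <- rocAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1)

  set.seed(7)
  scores <- round(rnorm(20), 1)  # ties likely
  labels <- rbinom(20, 1, 0.5)
  if (length(unique(labels)) == 1L) labels[1] <- 1 - labels[1]
  got <- rocAuc(scores, labels)$auc
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  expect_equal(got, mean(pairs), tolerance = 1e-12)

  # null: scores independent of labels
  set.seed(8)
  s0 <- rnorm(10000); l0 <- rbinom(10000, 1, 0.3)
  expect_equal(rocAuc(s0, l0)$auc, 0.5, tolerance = 0.02)
  expect_error(rocAuc(1:5, rep(1, 5)), "both classes")
})

test_that("cross-validation scores each mutant once and reports strata", {
  d <- generateDataset(syntheticConfig(n_mutants = 300, seed = 13))$data
  cv <- crossValidate(d, thermoParams("rf", n_trees = 60, seed = 3),
                      folds = 5, seed = 3)
  expect_false(anyNA(cv$predictions$O))
  expect_identical(sort(unique(cv$predictions$fold)), 1:5)
  expect_true(all(table(cv$predictions$fold) >= 1))

  bc <- cv$stratified$by_mutation_count
  expect_identical(bc$stratum, c("1", "2", "3", ">=4", ">=1"))
  expect_identical(sum(bc$n[1:4]), bc$n[5])
  expect_identical(bc$n[5], nrow(d))

  bd <- cv$stratified$by_abs_ddg
  expect_identical(bd$stratum, c("[0,1)", "[1,2)", "[2,3)", "[3,14)"))
  expect_identical(sum(bd$n), nrow(d))

  expect_error(crossValidate(transform(d, ddg = NA), thermoParams("rf")),
               "ddg")
})

test_that("grouped cross-validation keeps proteins within folds", {
  d <- generateDataset(syntheticConfig(n_mutants = 200, n_proteins = 10,
                                       seed = 14))$data
  cv <- crossValidate(d, thermoParams("rf", n_trees = 40, seed = 4),
                      folds = 5, seed = 4, group_by_protein = TRUE,
                      regression = FALSE)
  byFold <- split(d$protein_id, cv$predictions$fold)
  all <- unlist(lapply(byFold, unique))
  expect_identical(anyDuplicated(all), 0L)
})

test_that("RI accuracy curve matches brute-force filtering", {
  set.seed(9)
  O <- runif(50)
  pred <- data.frame(O = O, sign = ifelse(O > 0.5, 1L, -1L),
                     RI = reliabilityIndex(O))
  truth <- rbinom(50, 1, 0.5)
  curve <- riAccuracyCurve(pred, truth)
  expect_identical(nrow(curve), 11L)
  expect_true(all(diff(curve$fraction) <= 0))
  for (t in 0:10) {
    sel <- pred$RI >= t
    expect_equal(curve$fraction[t + 1], mean(sel))
    if (any(sel))
      expect_equal(curve$accuracy[t + 1],
                   100 * mean((pred$sign[sel] > 0) == (truth[sel] == 1)))
  }

  allGood <- data.frame(O = rep(1, 10), sign = rep(1L, 10), RI = rep(10L, 10))
  cg <- riAccuracyCurve(allGood, rep(1, 10))
  expect_true(all(cg$fraction == 1))
  expect_true(all(cg$accuracy == 100))
})

test_that("permutation importance finds the signal feature", {
  set.seed(10)
  n <- 400
  X <- matrix(rnorm(n * 58), n, 58)
  X[, 12] <- 0       # constant column -> importance exactly 0
  score <- X[, 1]
  y <- as.integer(score + rnorm(n, 0, 0.3) > 0)
  X[, 1] <- score
  m <- trainClassifier(X, y, thermoParams("rf", n_trees = 80, seed = 5))
  imp <- permutationImportance(m, X, y, n_perm = 5, seed = 6)
  expect_length(imp, 58L)
  expect_identical(unname(which.max(imp)), 1L)
  expect_identical(unname(imp[12]), 0)
  imp2 <- permutationImportance(m, X, y, n_perm = 5, seed = 6)
  expect_identical(imp, imp2)
})
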