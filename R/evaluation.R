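# Assessment protocol: k-fold CV, Q2 / MCC / sensitivity / specificity,
# Pearson r, ROC/AUC, stratified reports, RI cumulative accuracy,
# permutation variable importance.

#' k-fold cross-validation splits
#'
#' Partitions `1..n` into `folds` test sets of near-equal size (difference
#' at most 1). With `labels`, assignment is class-stratified; with `groups`,
#' all members of a group (e.g. all mutants of one protein) land in the same
#' fold. Deterministic for a fixed seed.
#'
#' @param n number of rows.
#' @param folds number of folds (>= 2, <= n).
#' @param labels optional class labels for stratification.
#' @param groups optional grouping vector (overrides stratification).
#' @param seed integer RNG seed.
#' @return list of `folds` elements, each `list(train =, test =)`.
#' @export
kfoldSplit <- function(n, folds = 10L, labels = NULL, groups = NULL,
                       seed = 1L) {
  folds <- as.integer(folds)
  if (folds < 2L) stop("folds must be >= 2")
  if (folds > n) stop("folds must not exceed n")
  assign <- integer(n)
  withSeed(seed, {
    if (!is.null(groups)) {
      g <- unique(groups)
      gf <- sample(rep_len(seq_len(folds), length(g)))
      assign <- gf[match(groups, g)]
    } else if (!is.null(labels)) {
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        assign[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
    } else {
      assign <- sample(rep_len(seq_len(folds), n))
    }
  })
  lapply(seq_len(folds), function(f)
    list(train = which(assign != f), test = which(assign == f)))
}

#' Classification metrics from confusion counts
#'
#' Overall accuracy `Q2 = 100 (TP + TN) / n`, Matthews correlation
#' coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`
#' (0 when any factor is 0), sensitivity `TP/(TP+FN)` and specificity
#' `TN/(TN+FP)` as percentages.
#'
#' @param TP,TN,FP,FN non-negative integer counts; alternatively pass a
#'   named vector/list as `TP`.
#' @return list: `Q2`, `MCC`, `sensitivity`, `specificity`, `n`.
#' @examples
#' confusionMetrics(TP = 50, TN = 50, FP = 0, FN = 0)$MCC  # 1
#' @export
confusionMetrics <- function(TP, TN = NULL, FP = NULL, FN = NULL) {
  if (is.null(TN) && (is.list(TP) || length(TP) == 4L)) {
    cc <- as.list(TP)
    TP <- cc$TP; TN <- cc$TN; FP <- cc$FP; FN <- cc$FN
  }
  cnt <- c(TP, TN, FP, FN)
  if (any(cnt < 0) || anyNA(cnt)) stop("counts must be non-negative")
  total <- TP + TN + FP + FN
  if (total == 0) stop("all-zero confusion counts")
  q2 <- 100 * (TP + TN) / total
  fac <- as.numeric(c(TP + FP, TP + FN, TN + FP, TN + FN))
  mcc <- if (any(fac == 0)) 0 else
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(prod(fac))
  sens <- if (TP + FN == 0) NA_real_ else 100 * TP / (TP + FN)
  spec <- if (TN + FP == 0) NA_real_ else 100 * TN / (TN + FP)
  list(Q2 = q2, MCC = mcc, sensitivity = sens, specificity = spec, n = total)
}

# Confusion counts from predicted and true signs (+1 stabilizing).
.confusion <- function(pred_sign, true_sign) {
  p <- pred_sign > 0
  t <- true_sign > 0
  list(TP = sum(p & t), TN = sum(!p & !t), FP = sum(p & !t), FN = sum(!p & t))
}

#' Pearson product-moment correlation
#'
#' Validates the inputs (equal length >= 2, non-zero variance) and returns
#' the standard product-moment correlation between experimental and
#' predicted ddG.
#'
#' @param x,y numeric vectors.
#' @return correlation in `[-1, 1]`.
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: Pearson r undefined")
  stats::cor(x, y)
}

#' ROC curve and AUC
#'
#' Sweeps all score thresholds, returns the (FPR, TPR) step curve and its
#' trapezoid-rule area. Grouping tied scores into single steps makes the
#' trapezoid area identical to the midrank (concordant-pair) statistic.
#'
#' @param scores classifier scores, larger = more stabilizing.
#' @param labels true classes (logical / 0-1 / sign).
#' @return list: `curve` (data.frame threshold, fpr, tpr) and `auc`.
#' @export
rocAuc <- function(scores, labels) {
  y <- .as01(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  np <- sum(y == 1); nn <- sum(y == 0)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; yo <- y[o]
  # collapse ties so each distinct score is one threshold step
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(yo); fp <- cumsum(1 - yo)
  last <- which(!duplicated(grp, fromLast = TRUE))
  curve <- data.frame(threshold = s[last],
                      fpr = fp[last] / nn, tpr = tp[last] / np)
  curve <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0), curve)
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                utils::tail(curve$tpr, -1)) / 2)
  list(curve = curve, auc = auc)
}

.ddgBreaks <- c(0, 1, 2, 3, 14)
.ddgLabels <- c("[0,1)", "[1,2)", "[2,3)", "[3,14)")

.metricsRow <- function(label, pred, truth, ddg, ddg_pred) {
  cc <- .confusion(pred, truth)
  m <- if (sum(unlist(cc)) > 0) confusionMetrics(cc) else
    list(Q2 = NA, MCC = NA, sensitivity = NA, specificity = NA, n = 0)
  r <- if (!is.null(ddg_pred) && length(ddg) >= 2 &&
           !anyNA(ddg_pred) && stats::sd(ddg) > 0 && stats::sd(ddg_pred) > 0)
    pearsonR(ddg, ddg_pred) else NA_real_
  data.frame(stratum = label, n = m$n, MCC = m$MCC, Q2 = m$Q2,
             sensitivity = m$sensitivity, specificity = m$specificity, r = r,
             stringsAsFactors = FALSE)
}

# Stratified report over mutation counts {1,2,3,>=4,>=1} and |ddG| bins.
stratifiedReport <- function(pred_sign, true_sign, ddg, n_sites,
                             ddg_pred = NULL) {
  pick <- function(sel, lab) .metricsRow(lab, pred_sign[sel], true_sign[sel],
                                         ddg[sel], ddg_pred[sel])
  byCount <- rbind(pick(n_sites == 1, "1"), pick(n_sites == 2, "2"),
                   pick(n_sites == 3, "3"), pick(n_sites >= 4, ">=4"),
                   pick(rep(TRUE, length(ddg)), ">=1"))
  absd <- abs(ddg)
  byDdg <- do.call(rbind, lapply(seq_len(4), function(b)
    pick(absd >= .ddgBreaks[b] & absd < .ddgBreaks[b + 1], .ddgLabels[b])))
  list(by_mutation_count = byCount, by_abs_ddg = byDdg)
}

#' Cross-validated assessment of the thermostability predictors
#'
#' 10-fold (by default) cross-validation on an encoded dataset: in each
#' split, a sign classifier and a ddG regressor of the requested family
#' (`rf` pairs with `rfr`, `svm` with `svr`) are trained on the training
#' folds and applied to the held-out fold, so every mutant is scored exactly
#' once by a model not trained on it. Reports overall metrics plus strata by
#' mutation count (1, 2, 3, >=4, >=1) and by experimental |ddG| bin
#' ([0,1), [1,2), [2,3), [3,14)).
#'
#' Folds are class-stratified by default; `group_by_protein = TRUE` instead
#' keeps all mutants of a protein in one fold, guarding against cross-fold
#' leakage of protein identity.
#'
#' @param data encoded data.frame (`ddg`, `n_sites`, `z1..z58`, optionally
#'   `protein_id`).
#' @param params classifier hyperparameters ([thermoParams()]); the paired
#'   regressor inherits the forest/kernel settings.
#' @param folds number of folds.
#' @param seed integer RNG seed.
#' @param group_by_protein keep each protein's mutants in a single fold.
#' @param regression also fit the paired regressor (default TRUE).
#' @return list: `predictions` (per-mutant out-of-fold O, sign, ddg_pred,
#'   RI, fold), `metrics` (overall), `stratified` (the two stratum tables),
#'   `roc` (curve + AUC).
#' @export
crossValidate <- function(data, params = thermoParams("rf"), folds = 10L,
                          seed = 1L, group_by_protein = FALSE,
                          regression = TRUE) {
  if (!"ddg" %in% names(data) || anyNA(data$ddg))
    stop("every mutant needs an experimental ddg value")
  X <- encodedMatrix(data)
  n <- nrow(X)
  y <- as.integer(data$ddg > 0)
  if (n < folds) stop("fewer rows than folds")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  n_sites <- if ("n_sites" %in% names(data)) data$n_sites else rep(1L, n)

  groups <- if (group_by_protein) {
    if (!"protein_id" %in% names(data))
      stop("group_by_protein needs a protein_id column")
    data$protein_id
  } else NULL
  splits <- kfoldSplit(n, folds, labels = if (is.null(groups)) y,
                       groups = groups, seed = seed)

  regAlgo <- c(rf = "rfr", svm = "svr", rfr = "rfr", svr = "svr")[[
    params$algorithm]]
  clsAlgo <- c(rf = "rf", svm = "svm", rfr = "rf", svr = "svm")[[
    params$algorithm]]

  O <- rep(NA_real_, n); ddg_pred <- rep(NA_real_, n)
  foldId <- rep(NA_integer_, n)
  for (f in seq_along(splits)) {
    tr <- splits[[f]]$train; te <- splits[[f]]$test
    pc <- params; pc$algorithm <- clsAlgo
    pc$seed <- childSeed(seed, paste0("cls", f))
    cls <- trainClassifier(X[tr, , drop = FALSE], y[tr], pc)
    O[te] <- predict(cls, X[te, , drop = FALSE])$O
    if (regression) {
      pr <- params; pr$algorithm <- regAlgo
      pr$min_node <- if (regAlgo == "rfr") 5L else pr$min_node
      pr$seed <- childSeed(seed, paste0("reg", f))
      reg <- trainRegressor(X[tr, , drop = FALSE], data$ddg[tr], pr)
      ddg_pred[te] <- predict(reg, X[te, , drop = FALSE])$ddg_pred
    }
    foldId[te] <- f
  }

  sign_pred <- ifelse(O > 0.5, 1L, -1L)
  sign_true <- ifelse(y == 1, 1L, -1L)
  predictions <- data.frame(O = O, sign = sign_pred, ddg_pred = ddg_pred,
                            RI = reliabilityIndex(O), fold = foldId,
                            ddg = data$ddg, n_sites = n_sites)
  metrics <- .metricsRow(">=1", sign_pred, sign_true, data$ddg,
                         if (regression) ddg_pred)
  strat <- stratifiedReport(sign_pred, sign_true, data$ddg, n_sites,
                            if (regression) ddg_pred)
  list(predictions = predictions, metrics = metrics, stratified = strat,
       roc = rocAuc(O, y))
}

#' Cumulative accuracy by reliability index
#'
#' For each RI threshold t in 0..10, the fraction of predictions with
#' `RI >= t` and the accuracy among them. The fraction column is
#' non-increasing in t.
#'
#' @param predictions data.frame with columns `RI` and `sign` (as returned
#'   by [predict()][predict,ThermoModel-method]).
#' @param true_sign true signs (+1 / -1, or logical stabilizing).
#' @return data.frame: `threshold`, `fraction`, `accuracy` (percent; NA when
#'   no prediction reaches the threshold).
#' @export
riAccuracyCurve <- function(predictions, true_sign) {
  ri <- predictions$RI
  correct <- (predictions$sign > 0) == (.as01(true_sign) == 1)
  do.call(rbind, lapply(0:10, function(t) {
    sel <- ri >= t
    data.frame(threshold = t, fraction = mean(sel),
               accuracy = if (any(sel)) 100 * mean(correct[sel]) else NA_real_)
  }))
}

#' Permutation variable importance
#'
#' Importance of feature j = baseline out-of-sample accuracy minus the
#' accuracy after permuting column j (mean over `n_perm` seeded
#' permutations). A constant column has importance exactly 0.
#'
#' @param model fitted classifier ([ThermoModel-class]).
#' @param data held-out encoded table or 58-column matrix.
#' @param labels true classes.
#' @param n_perm permutations per feature (default 10).
#' @param seed integer RNG seed.
#' @return named numeric(58) of accuracy drops, in `z1..z58` order.
#' @export
permutationImportance <- function(model, data, labels, n_perm = 10L,
                                  seed = 1L) {
  X <- .asEncodedMatrix(data)
  y <- .as01(labels)
  base <- mean((predict(model, X)$sign > 0) == (y == 1))
  withSeed(seed, {
    imp <- vapply(seq_len(ncol(X)), function(j) {
      if (length(unique(X[, j])) == 1L) return(0)
      drops <- vapply(seq_len(n_perm), function(p) {
        Xp <- X
        Xp[, j] <- X[sample.int(nrow(X)), j]
        base - mean((predict(model, Xp)$sign > 0) == (y == 1))
      }, numeric(1))
      mean(drops)
    }, numeric(1))
    stats::setNames(imp, paste0("z", seq_len(ncol(X))))
  })
}
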