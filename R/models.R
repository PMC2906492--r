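# The four learners (RF / SVM classification, RFR / SVR regression),
# prediction, reliability index, model persistence.

#' Hyperparameters for the thermostability learners
#'
#' Defaults follow the published configuration: forests of 1000 trees
#' (performance is stable above 500), an RBF kernel with gamma = 2 and
#' cost = 8, and a 3-fold misclassification weight on the (minority)
#' stabilizing class for the SVM. The forest classifier instead counters
#' imbalance by down-sampling: every tree trains on equal-size class draws.
#'
#' @param algorithm one of `"rf"`, `"svm"` (sign classifiers), `"rfr"`,
#'   `"svr"` (ddG regressors).
#' @param n_trees trees per forest (>= 1).
#' @param mtry features tried per split; default `round(sqrt(58))`.
#' @param min_node minimal node size (1 classification, 5 regression).
#' @param svm_pos_class_weight weight on the stabilizing class (SVM only).
#' @param svr_gamma,svr_cost RBF kernel width and box penalty.
#' @param svr_epsilon epsilon-insensitive tube half-width (SVR only).
#' @param seed integer RNG seed threaded through every stochastic step.
#' @return named list of validated hyperparameters.
#' @export
thermoParams <- function(algorithm = c("rf", "svm", "rfr", "svr"),
                         n_trees = 1000L,
                         mtry = round(sqrt(ENCODED_DIM)),
                         min_node = NULL,
                         svm_pos_class_weight = 3.0,
                         svr_gamma = 2, svr_cost = 8, svr_epsilon = 0.1,
                         seed = 1L) {
  algorithm <- match.arg(algorithm)
  n_trees <- as.integer(n_trees)
  if (n_trees < 1L) stop("n_trees must be >= 1")
  if (svm_pos_class_weight <= 0 || svr_cost <= 0 || svr_gamma <= 0)
    stop("weights, costs and gamma must be > 0")
  if (is.null(min_node))
    min_node <- if (algorithm %in% c("rf", "svm")) 1L else 5L
  list(algorithm = algorithm, n_trees = n_trees, mtry = as.integer(mtry),
       min_node = as.integer(min_node),
       svm_pos_class_weight = svm_pos_class_weight,
       svr_gamma = svr_gamma, svr_cost = svr_cost,
       svr_epsilon = svr_epsilon, seed = as.integer(seed))
}

.asEncodedMatrix <- function(X) {
  if (is.data.frame(X)) X <- encodedMatrix(X)
  if (!is.matrix(X)) X <- matrix(X, ncol = ENCODED_DIM)
  if (ncol(X) != ENCODED_DIM)
    stop("encoded vectors must have 58 elements, got ", ncol(X))
  if (!all(is.finite(X))) stop("non-finite feature value in input")
  X
}

# labels: logical, 0/1, or +/-1 -> integer 0/1 (1 = stabilizing)
.as01 <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  u <- sort(unique(labels))
  if (all(u %in% c(0, 1))) return(as.integer(labels))
  if (all(u %in% c(-1, 1))) return(as.integer(labels > 0))
  stop("labels must be logical, 0/1, or -1/+1")
}

#' Train a stabilizing/destabilizing sign classifier
#'
#' `rf`: a forest of `n_trees` CART trees, each grown on a bootstrap with
#' equal draws from both classes (down-sampled to the minority size); the
#' score O is the fraction of trees voting stabilizing. `svm`: a weighted
#' RBF soft-margin machine with misclassification weight
#' `svm_pos_class_weight` (default 3) on the stabilizing class; O is a
#' sigmoid calibration of the decision value. Deterministic for a fixed
#' `params$seed`.
#'
#' @param X encoded table (data.frame with `z1..z58`) or numeric matrix with
#'   58 columns.
#' @param labels class labels: logical, 0/1 or -1/+1; 1/TRUE = stabilizing
#'   (ddG > 0).
#' @param params see [thermoParams()].
#' @return A [ThermoModel-class].
#' @export
trainClassifier <- function(X, labels, params = thermoParams("rf")) {
  X <- .asEncodedMatrix(X)
  y <- .as01(labels)
  if (length(y) != nrow(X)) stop("labels length must match rows of X")
  if (length(unique(y)) < 2L)
    stop("both classes must be present in the training labels")
  if (!params$algorithm %in% c("rf", "svm"))
    stop("classifier algorithm must be rf or svm")

  fitted <- if (params$algorithm == "rf") {
    growForest(X, y, ntree = params$n_trees, mtry = params$mtry,
               minnode = params$min_node, classification = TRUE,
               seed = params$seed)
  } else {
    svmFit(X, ifelse(y == 1, 1, -1), cost = params$svr_cost,
           gamma = params$svr_gamma,
           weights = c(pos = params$svm_pos_class_weight, neg = 1))
  }
  new("ThermoModel", params = params, task = "classification",
      fitted = list(state = fitted), feature_dim = ENCODED_DIM,
      training_summary = list(n = nrow(X),
                              class_counts = list(stabilizing = sum(y == 1),
                                                  destabilizing = sum(y == 0))))
}

#' Train a ddG regressor
#'
#' `rfr`: forest regression (bootstrap per tree, leaf-mean averaging).
#' `svr`: epsilon-insensitive RBF support vector regression with the
#' published defaults gamma = 2, cost = 8.
#'
#' @param X encoded table or 58-column matrix (>= 10 rows).
#' @param ddg_values experimental ddG targets in kcal/mol, finite.
#' @param params see [thermoParams()].
#' @return A [ThermoModel-class].
#' @export
trainRegressor <- function(X, ddg_values, params = thermoParams("rfr")) {
  X <- .asEncodedMatrix(X)
  if (nrow(X) < 10L) stop("regression needs at least 10 rows")
  if (length(ddg_values) != nrow(X) || !all(is.finite(ddg_values)))
    stop("ddg_values must be finite and match rows of X")
  if (!params$algorithm %in% c("rfr", "svr"))
    stop("regressor algorithm must be rfr or svr")

  fitted <- if (params$algorithm == "rfr") {
    growForest(X, as.numeric(ddg_values), ntree = params$n_trees,
               mtry = params$mtry, minnode = params$min_node,
               classification = FALSE, seed = params$seed)
  } else {
    svrFit(X, as.numeric(ddg_values), cost = params$svr_cost,
           gamma = params$svr_gamma, epsilon = params$svr_epsilon)
  }
  new("ThermoModel", params = params, task = "regression",
      fitted = list(state = fitted), feature_dim = ENCODED_DIM,
      training_summary = list(n = nrow(X),
                              ddg_range = list(min = min(ddg_values),
                                               max = max(ddg_values))))
}

#' Reliability index of a classifier score
#'
#' `RI = floor(20 * |O - 0.5|)`, an integer confidence on a 0--10 scale:
#' 0 at O = 0.5 (coin toss), 10 at O = 0 or 1.
#'
#' @param O classifier score(s) in `[0, 1]`.
#' @return integer vector in `0..10`.
#' @examples
#' reliabilityIndex(c(0.5, 0.87, 1))  # 0 7 10
#' @export
reliabilityIndex <- function(O) {
  if (any(!is.finite(O)) || any(O < 0 | O > 1))
    stop("O must lie in [0, 1]")
  pmin(as.integer(floor(20 * abs(O - 0.5))), 10L)
}

#' Predict stability change for encoded mutants
#'
#' Classifier models fill the stabilizing-class score `O`, the predicted
#' `sign` (+1 if O > 0.5 else -1) and the reliability index `RI`.
#' Regression models fill `ddg_pred` (kcal/mol) and derive `sign` from it.
#'
#' @param object a [ThermoModel-class].
#' @param newdata encoded table or 58-column matrix.
#' @param return_votes logical; for `rf` models also return the per-tree
#'   vote matrix (attribute `"votes"`).
#' @param ... ignored.
#' @return data.frame with columns `O`, `sign`, `ddg_pred`, `RI` (NA where
#'   not applicable).
#' @export
setMethod("predict", "ThermoModel",
  function(object, newdata, return_votes = FALSE, ...) {
    X <- .asEncodedMatrix(newdata)
    algo <- object@params$algorithm
    st <- object@fitted$state
    if (object@task == "classification") {
      if (algo == "rf") {
        pr <- forestPredict(st, X, return_votes = TRUE)
        O <- pr$O
      } else {
        O <- svmProb(st, X)
      }
      O <- pmin(pmax(O, 0), 1)
      res <- data.frame(O = O, sign = ifelse(O > 0.5, 1L, -1L),
                        ddg_pred = NA_real_, RI = reliabilityIndex(O))
      if (return_votes && algo == "rf") attr(res, "votes") <- pr$votes
      res
    } else {
      ddg <- if (algo == "rfr") forestPredict(st, X) else svrPredict(st, X)
      data.frame(O = NA_real_, sign = ifelse(ddg > 0, 1L, -1L),
                 ddg_pred = ddg, RI = NA_integer_)
    }
  })

#' Save / load a fitted model
#'
#' The model file is an RDS archive holding a header (schema version,
#' hyperparameters, task, training summary) plus the serialized learner
#' state. Loading a file with a different schema version fails, naming both
#' versions. `loadModel(saveModel(m))` is the identity on predictions.
#'
#' @param model a [ThermoModel-class].
#' @param path file path.
#' @return `saveModel`: `path`, invisibly. `loadModel`: the model.
#' @name modelIO
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "ThermoModel"))
  obj <- list(header = list(schema_version = MODEL_SCHEMA_VERSION,
                            params = model@params, task = model@task,
                            training_summary = model@training_summary),
              state = model@fitted)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname modelIO
#' @export
loadModel <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read model file ", path, ": ", conditionMessage(e)))
  if (!is.list(obj) || is.null(obj$header$schema_version))
    stop("not a ThermoShift model file: ", path)
  if (!identical(obj$header$schema_version, MODEL_SCHEMA_VERSION))
    stop("model schema version mismatch: file has ",
         obj$header$schema_version, ", package expects ",
         MODEL_SCHEMA_VERSION)
  new("ThermoModel", params = obj$header$params, task = obj$header$task,
      fitted = obj$state, feature_dim = ENCODED_DIM,
      training_summary = obj$header$training_summary)
}
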