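# RBF-kernel SVM / SVR solved as quadratic programs (quadprog).
#
# Dual soft-margin SVM with per-class box constraints implements the
# "3-fold greater weight on the stabilizing class" scheme: the upper bound
# for sample i is cost * class_weight(y_i). The probability output O is a
# Platt-style sigmoid (logistic fit of the training labels on the decision
# values). The active-set QP solver is exact but O(n^3); fine for the
# datasets this package targets, large inputs should prefer the forests.

rbfKernel <- function(A, B, gamma) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

# y in {-1, +1}; weights named c(pos=, neg=)
svmFit <- function(X, y, cost, gamma, weights = c(pos = 3, neg = 1)) {
  n <- nrow(X)
  K <- rbfKernel(X, X, gamma)
  Q <- (y %o% y) * K
  D <- Q + diag(1e-8, n)
  Cup <- ifelse(y > 0, cost * weights[["pos"]], cost * weights[["neg"]])
  A <- cbind(y, diag(n), -diag(n))
  b0 <- c(0, rep(0, n), -Cup)
  sol <- quadprog::solve.QP(D, rep(1, n), A, b0, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), Cup)
  sv <- alpha > 1e-8
  f0 <- as.numeric(K %*% (alpha * y))
  margin <- which(sv & alpha < Cup - 1e-6)
  if (length(margin) == 0L) margin <- which(sv)
  b <- mean(y[margin] - f0[margin])
  decision <- f0 + b
  # Platt-style sigmoid calibration on training decision values
  lab01 <- as.integer(y > 0)
  platt <- tryCatch(
    stats::glm(lab01 ~ decision, family = stats::binomial())$coefficients,
    warning = function(w)
      suppressWarnings(stats::glm(lab01 ~ decision,
                                  family = stats::binomial())$coefficients))
  list(X = X[sv, , drop = FALSE], coef = (alpha * y)[sv], b = b,
       gamma = gamma, cost = cost, weights = weights,
       upper_bounds = Cup, alpha = alpha, platt = platt)
}

svmDecision <- function(fit, Xnew) {
  K <- rbfKernel(Xnew, fit$X, fit$gamma)
  as.numeric(K %*% fit$coef) + fit$b
}

svmProb <- function(fit, Xnew) {
  d <- svmDecision(fit, Xnew)
  eta <- fit$platt[[1]] + fit$platt[[2]] * d
  1 / (1 + exp(-eta))
}

# epsilon-insensitive SVR: variables (alpha, alpha*), standard 2n-dim dual.
svrFit <- function(X, y, cost = 8, gamma = 2, epsilon = 0.1) {
  n <- nrow(X)
  K <- rbfKernel(X, X, gamma)
  D <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-6, 2 * n)
  d <- c(y - epsilon, -y - epsilon)
  A <- cbind(c(rep(1, n), rep(-1, n)), diag(2 * n), -diag(2 * n))
  b0 <- c(0, rep(0, 2 * n), rep(-cost, 2 * n))
  sol <- quadprog::solve.QP(D, d, A, b0, meq = 1)
  a <- pmin(pmax(sol$solution, 0), cost)
  beta <- a[1:n] - a[(n + 1):(2 * n)]
  f0 <- as.numeric(K %*% beta)
  # intercept from margin points (0 < alpha < C); fallback: median residual
  up <- which(a[1:n] > 1e-6 & a[1:n] < cost - 1e-6)
  dn <- which(a[(n + 1):(2 * n)] > 1e-6 & a[(n + 1):(2 * n)] < cost - 1e-6)
  b <- if (length(up) + length(dn) > 0) {
    mean(c(y[up] - f0[up] - epsilon, y[dn] - f0[dn] + epsilon))
  } else {
    stats::median(y - f0)
  }
  sv <- abs(beta) > 1e-8
  if (!any(sv)) sv <- rep(TRUE, n)
  list(X = X[sv, , drop = FALSE], coef = beta[sv], b = b,
       gamma = gamma, cost = cost, epsilon = epsilon)
}

svrPredict <- function(fit, Xnew) {
  K <- rbfKernel(Xnew, fit$X, fit$gamma)
  as.numeric(K %*% fit$coef) + fit$b
}
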