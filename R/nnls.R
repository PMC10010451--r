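#' Nonnegative ridge regression on RDM vectors
#'
#' Minimises `||y - Xw - b||^2 + lambda * ||w||^2` subject to
#' `w >= 0`, with an unpenalised intercept. Callers supply predictor
#' columns already standardized on the training pairs (zero mean, unit
#' sd), so the intercept profile reduces to `b = mean(y)` and the
#' problem is solved exactly by active-set NNLS on the ridge-augmented
#' normal equations.
#'
#' @param y numeric vector of training-pair dissimilarities.
#' @param X pairs x p matrix of standardized predictor columns.
#' @param lambda ridge penalty, `>= 0`.
#' @param standardization optional list with `center` and `scale`
#'   recording the training-pair standardization (carried through to
#'   the result for later prediction).
#' @return A `fit_result`: list with nonnegative `weights`,
#'   `intercept`, `lambda`, `standardization`.
#' @examples
#' X <- scale(matrix(rnorm(60), 20, 3))
#' y <- X %*% c(1, 0.5, 0) + 2
#' fit_nn_ridge(y, X, lambda = 1e-6)$weights
#' @export
fit_nn_ridge <- function(y, X, lambda, standardization = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("y and X must have matching rows")
  if (lambda < 0) stop("lambda must be nonnegative")
  b <- mean(y)
  yc <- y - b
  p <- ncol(X)
  if (stats::var(y) == 0) {
    w <- rep(0, p)
  } else {
    G <- crossprod(X) + diag(lambda, p)
    w <- drop(.nnls_gram(G, cbind(crossprod(X, yc))))
  }
  names(w) <- colnames(X)
  structure(list(weights = w, intercept = b, lambda = lambda,
                 standardization = standardization),
            class = "fit_result")
}

#' Nonnegative GLM on RDM vectors with explained variance
#'
#' Minimises `||y - Xw - b||^2` with `w >= 0` and a free intercept
#' (profiled out by centering), and reports
#' `r2 = 1 - SS_res / SS_tot`, with `SS_tot` about the mean of `y`.
#' Predictors are used as given (no re-standardization): at the second
#' level they are calibrated cross-validated predictions and the
#' intercept absorbs homogeneous offsets. `r2` may be negative for a
#' forced bad fit; nothing is clipped.
#'
#' @param y numeric data vector (vectorised RDM at one time point).
#' @param X pairs x p matrix of prediction vectors.
#' @return A `glm_result`: list with nonnegative `weights`,
#'   `intercept`, `r2`, `fitted`.
#' @export
nnls_glm <- function(y, X) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("y and X must have matching rows")
  if (ncol(X) < 1) stop("need at least one predictor")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("zero-variance data vector: r2 undefined")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  yc <- y - mean(y)
  keep <- colSums(Xc^2) > 0
  w <- rep(0, ncol(X))
  if (any(keep)) {
    Xk <- Xc[, keep, drop = FALSE]
    w[keep] <- drop(.nnls_gram(crossprod(Xk), cbind(crossprod(Xk, yc))))
  }
  names(w) <- colnames(X)
  b <- mean(y) - sum(ctr * w)
  fitted <- drop(X %*% w) + b
  r2 <- 1 - sum((y - fitted)^2) / ss_tot
  structure(list(weights = w, intercept = b, r2 = r2, fitted = fitted),
            class = "glm_result")
}
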