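# Learner contract: a learner is a list with
#   $id       label,
#   $fit      function(X, y) -> model   (X predictor matrix, y logical),
#   $predict  function(model, X) -> scores in [0, 1].
# Any object honoring this contract can enter the ensemble.

#' Regularized logistic learner
#'
#' Ridge-penalized logistic regression (glmnet, fixed small lambda) scoring
#' presence probability. The workhorse reference learner: on synthetic
#' species whose truth is itself a logistic response it should recover the
#' surface nearly exactly.
#'
#' @param lambda ridge penalty (default 1e-3; mild, mostly for stability).
#' @return a learner list.
#' @export
makeLogisticLearner <- function(lambda = 1e-3) {
  list(
    id = "logistic",
    fit = function(X, y) {
      glmnet::glmnet(X, as.numeric(y), family = "binomial", alpha = 0,
                     lambda = lambda)
    },
    predict = function(model, X) {
      as.numeric(stats::predict(model, X, type = "response"))
    })
}

#' Nearest-environmental-neighbor learner
#'
#' Scores a location by the presence fraction among its `k` nearest
#' training points in z-scored predictor space. A deliberately different
#' model family from the logistic learner, exercising the ensemble's
#' weighting across heterogeneous members.
#'
#' @param k number of neighbors (default 7).
#' @return a learner list.
#' @export
makeNearestEnvLearner <- function(k = 7) {
  list(
    id = "nearest_env",
    fit = function(X, y) {
      mu <- colMeans(X); sd <- apply(X, 2, stats::sd)
      sd[sd == 0 | !is.finite(sd)] <- 1
      list(Z = sweep(sweep(X, 2, mu), 2, sd, "/"), y = as.numeric(y),
           mu = mu, sd = sd, k = min(k, nrow(X)))
    },
    predict = function(model, X) {
      Zq <- sweep(sweep(X, 2, model$mu), 2, model$sd, "/")
      tr <- model$Z
      trSq <- rowSums(tr^2)
      out <- numeric(nrow(Zq))
      chunk <- 512L
      for (s in seq(1L, nrow(Zq), by = chunk)) {
        e <- min(s + chunk - 1L, nrow(Zq))
        q <- Zq[s:e, , drop = FALSE]
        d2 <- outer(rowSums(q^2), trSq, "+") - 2 * q %*% t(tr)
        out[s:e] <- apply(d2, 1, function(d)
          mean(model$y[order(d)[seq_len(model$k)]]))
      }
      pmin(pmax(out, 0), 1)
    })
}

#' Project a fitted learner onto the predictor grid
#'
#' Predicts the learner's score for every non-missing cell of the stack.
#'
#' @param learner a learner list.
#' @param model the fitted model from `learner$fit`.
#' @param env an [EnvStack-class] (already reduced to the modeling
#'   variables).
#' @return numeric matrix on the stack's grid, `NA` on missing cells.
#' @export
projectLearner <- function(learner, model, env) {
  ny <- nRows(env@grid); nx <- nCols(env@grid)
  X <- vapply(env@layers, as.vector, numeric(ny * nx))
  ok <- stats::complete.cases(X)
  out <- rep(NA_real_, ny * nx)
  if (any(ok))
    out[ok] <- learner$predict(model, X[ok, , drop = FALSE])
  matrix(out, ny, nx)
}
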