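#' Linear soft-margin SVM (C-classification)
#'
#' Exact sequential-minimal-optimisation solver for the binary linear C-SVC
#' dual, trained on a precomputed Gram matrix so that the recursive
#' feature-elimination loop can re-train thousands of small models cheaply.
#' The decision function is `f(z) = w . z + b`; `predict` returns decision
#' values or class labels. `cost` defaults to 1.
#'
#' @param x subjects x features numeric matrix.
#' @param y two-level factor (or coercible); `positive` names the class mapped
#'   to +1 (defaults to the second factor level).
#' @param cost soft-margin parameter C.
#' @param positive label of the positive class.
#' @return A `linear_svm` object with `weights`, `bias`, `levels`,
#'   `positive`, and the training `alpha`.
#' @export
linear_svm <- function(x, y, cost = 1, positive = NULL) {
  x <- as.matrix(x)
  y <- as.factor(y)
  if (nlevels(y) != 2L) stop("linear_svm needs exactly two classes")
  if (nrow(x) != length(y)) stop("x rows must match length of y")
  if (any(!is.finite(x))) stop("features must be finite")
  positive <- positive %||% levels(y)[2]
  if (!positive %in% levels(y)) stop("positive label not among classes")
  ys <- ifelse(y == positive, 1, -1)
  fit <- cpp_svm_train(tcrossprod(x), as.numeric(ys), cost)
  coefs <- fit$alpha * ys
  structure(list(weights = as.numeric(crossprod(x, coefs)), bias = fit$b,
                 alpha = fit$alpha, levels = levels(y), positive = positive,
                 cost = cost, converged = fit$converged),
            class = "linear_svm")
}

#' @rdname linear_svm
#' @param object a `linear_svm` fit.
#' @param newdata matrix of observations to score.
#' @param type `"decision"` for decision values, `"class"` for labels.
#' @param ... unused.
#' @export
predict.linear_svm <- function(object, newdata,
                               type = c("decision", "class"), ...) {
  type <- match.arg(type)
  d <- as.numeric(as.matrix(newdata) %*% object$weights + object$bias)
  if (type == "decision") return(d)
  neg <- setdiff(object$levels, object$positive)
  factor(ifelse(d > 0, object$positive, neg), levels = object$levels)
}
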