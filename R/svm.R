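# Linear SVM archetype classifier and its decision-value score (the EM score),
# with Platt sigmoid calibration of posterior probabilities.

# class coding used throughout: epithelial "E" = -1, mesenchymal "M" = +1
em_label <- function(y) {
  if (is.logical(y)) y <- ifelse(y, "M", "E")
  if (is.numeric(y)) y <- ifelse(y > 0, "M", "E")
  factor(as.character(y), levels = c("E", "M"))
}

em_sign <- function(y) ifelse(em_label(y) == "M", 1, -1)

#' Train the linear epithelial/mesenchymal SVM
#'
#' Soft-margin linear SVM (box constraint `C`) on predictors divided by the
#' kernel scale `s_k`. The stored coefficient vector `beta` and intercept `b`
#' reproduce the decision values exactly, oriented so mesenchymal cells score
#' positive.
#'
#' @param x matrix of PC scores.
#' @param y labels (`"E"`/`"M"`, or numeric sign with M = +1).
#' @param C box constraint (default 1).
#' @param kernel_scale positive kernel scale `s_k`; predictors are divided by
#'   it before fitting (default 1).
#' @param tolerance optimizer termination tolerance.
#' @return object of class `em_svm`: `beta`, `b`, `kernel_scale`, `C`.
#' @export
train_linear_svm <- function(x, y, C = 1, kernel_scale = 1, tolerance = 1e-6) {
  x <- as.matrix(x)
  y <- em_label(y)
  if (nlevels(droplevels(y)) < 2) stop("both classes must be present")
  if (kernel_scale <= 0) stop("kernel_scale must be > 0")
  fit <- e1071::svm(x / kernel_scale, y, kernel = "linear", cost = C,
                    scale = FALSE, tolerance = tolerance)
  beta <- as.vector(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  s <- (x / kernel_scale) %*% beta + b
  if (mean(s[y == "M"]) < mean(s[y == "E"])) {  # orient: M positive
    beta <- -beta; b <- -b
  }
  structure(list(beta = beta, b = b, kernel_scale = kernel_scale, C = C,
                 k = ncol(x)),
            class = "em_svm")
}

#' SVM decision-value score
#'
#' `s_j = (x_j / s_k)' beta + b`: the signed distance (up to the margin
#' scaling convention) of cell j from the separating hyperplane. Negative
#' scores are epithelial-like, positive mesenchymal-like.
#'
#' @param model an `em_svm`.
#' @param x matrix (or vector) of PC scores.
#' @return numeric vector of scores.
#' @export
svm_score <- function(model, x) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(x) != length(model$beta)) {
    stop(sprintf("dimension mismatch: model has %d predictors, x has %d",
                 length(model$beta), ncol(x)))
  }
  as.vector((x / model$kernel_scale) %*% model$beta + model$b)
}

#' @export
predict.em_svm <- function(object, newdata, ...) {
  em_label(svm_score(object, newdata) > 0)
}

#' @export
print.em_svm <- function(x, ...) {
  cat(sprintf("<em_svm> %d predictors, |beta| = %.3f, b = %.3f, s_k = %.4g, C = %g\n",
              x$k, sqrt(sum(x$beta^2)), x$b, x$kernel_scale, x$C))
  invisible(x)
}

#' Fit Platt sigmoid calibration
#'
#' Maximum-likelihood fit of `P(s) = 1 / (1 + exp(A s + B))` to scores and
#' binary labels, with Platt's regularized target coding
#' (`t+ = (N+ + 1)/(N+ + 2)`, `t- = 1/(N- + 2)`). `A` is negative when larger
#' scores imply higher mesenchymal probability.
#'
#' @param scores numeric decision values.
#' @param labels class labels (`"E"`/`"M"`).
#' @return object of class `platt_model` with `A` and `B`.
#' @export
platt_fit <- function(scores, labels) {
  y <- em_label(labels)
  if (nlevels(droplevels(y)) < 2) stop("both classes must be present")
  if (stats::sd(scores) == 0) stop("degenerate scores: all values equal")
  np <- sum(y == "M"); nn <- sum(y == "E")
  t <- ifelse(y == "M", (np + 1) / (np + 2), 1 / (nn + 2))
  # with p = 1/(1+exp(eta)):  NLL = sum[ log(1+exp(eta)) - (1-t)*eta ]
  log1pexp <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))
  nll <- function(par) {
    eta <- par[1] * scores + par[2]
    sum(log1pexp(eta) - (1 - t) * eta)
  }
  grad <- function(par) {
    eta <- par[1] * scores + par[2]
    d <- 1 / (1 + exp(-eta)) - (1 - t)  # (1-p) - (1-t)
    c(sum(d * scores), sum(d))
  }
  fit <- stats::optim(c(A = -1, B = 0), nll, gr = grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  structure(list(A = unname(fit$par[1]), B = unname(fit$par[2])),
            class = "platt_model")
}

#' Platt posterior probability
#'
#' @param model a `platt_model`.
#' @param s numeric score(s).
#' @return posterior probability of the mesenchymal class,
#'   `1 / (1 + exp(A s + B))`.
#' @export
platt_posterior <- function(model, s) {
  1 / (1 + exp(model$A * s + model$B))
}

#' @export
print.platt_model <- function(x, ...) {
  cat(sprintf("<platt_model> A = %.4f, B = %.4f\n", x$A, x$B))
  invisible(x)
}
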