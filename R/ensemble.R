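# Tree ensembles: AdaBoost (sequential reweighting, closed-form learner
# weights) and bagged trees (bootstrap aggregation of per-learner posteriors).

#' Train an AdaBoost ensemble of depth-limited trees
#'
#' Classic discrete AdaBoost on PC predictors with class coding E = -1,
#' M = +1. Each retained learner t stores the exact closed-form weight
#' `a_t = 0.5 log[(1 - eps_t) / eps_t]`, where `eps_t` is its weighted
#' classification error; the learning rate shrinks only the sample-weight
#' update, so the stored weights keep the closed form. A perfect learner
#' (`eps_t = 0`) gets its weight capped and training stops (nothing is left
#' to reweight); a learner with `eps_t >= 0.5` is rejected and training
#' stops with a warning.
#'
#' @param x matrix of PC scores.
#' @param y labels (`"E"`/`"M"`).
#' @param n_learners total learners T (default 200).
#' @param learn_rate shrinkage of the weight update (default 0.1).
#' @param maxdepth depth limit of each tree (default 1: decision stumps).
#' @param a_max cap on a learner weight when `eps_t = 0`.
#' @return object of class `em_boost`: `trees`, `a` (weights), `eps`
#'   (weighted errors), `learn_rate`.
#' @export
train_boost <- function(x, y, n_learners = 200, learn_rate = 0.1,
                        maxdepth = 1, a_max = 10) {
  x <- as.matrix(x)
  y <- em_label(y)
  if (nlevels(droplevels(y)) < 2) stop("both classes must be present")
  n <- nrow(x)
  ysgn <- em_sign(y)
  w <- rep(1 / n, n)
  trees <- list(); a <- numeric(0); eps <- numeric(0)
  for (t in seq_len(n_learners)) {
    tree <- fit_class_tree(x, y, weights = w * n, maxdepth = maxdepth,
                           minsplit = 4, minbucket = 2)
    hsgn <- ifelse(tree_predict_class(tree, x) == "M", 1, -1)
    e_t <- sum(w[hsgn != ysgn])
    if (e_t >= 0.5) {
      if (t == 1) stop("first learner no better than chance; cannot boost")
      warning(sprintf("learner %d has weighted error %.3f >= 0.5; stopping", t, e_t))
      break
    }
    if (e_t <= 0) {
      warning(sprintf("learner %d is perfect; weight capped at %g", t, a_max))
      trees[[length(trees) + 1L]] <- tree
      a <- c(a, a_max); eps <- c(eps, 0)
      break
    }
    a_t <- 0.5 * log((1 - e_t) / e_t)
    trees[[length(trees) + 1L]] <- tree
    a <- c(a, a_t); eps <- c(eps, e_t)
    w <- w * exp(-learn_rate * a_t * ysgn * hsgn)
    w <- w / sum(w)
  }
  structure(list(trees = trees, a = a, eps = eps, learn_rate = learn_rate,
                 maxdepth = maxdepth, k = ncol(x)),
            class = "em_boost")
}

#' AdaBoost prediction score
#'
#' `f(x) = sum_t a_t h_t(x)` with `h_t(x)` in \{-1, +1\}; the sign is the
#' predicted class (positive = mesenchymal), the magnitude the ensemble's
#' confidence. Range is unbounded.
#'
#' @param model an `em_boost`.
#' @param x matrix (or vector) of PC scores.
#' @return numeric vector of scores.
#' @export
boost_score <- function(model, x) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  s <- numeric(nrow(x))
  for (t in seq_along(model$trees)) {
    h <- ifelse(tree_predict_class(model$trees[[t]], x) == "M", 1, -1)
    s <- s + model$a[t] * h
  }
  s
}

#' @export
predict.em_boost <- function(object, newdata, ...) {
  em_label(boost_score(object, newdata) > 0)
}

#' @export
print.em_boost <- function(x, ...) {
  cat(sprintf("<em_boost> %d learners (depth <= %d), learn_rate %g\n",
              length(x$trees), x$maxdepth, x$learn_rate))
  invisible(x)
}

#' Train a bagged-tree ensemble
#'
#' Fully grown classification trees on bootstrap resamples of the training
#' set. Learner weights `a_t` default to 1 (uniform) but are kept in the
#' model so the weighted-posterior aggregation stays general.
#'
#' @param x matrix of PC scores.
#' @param y labels (`"E"`/`"M"`).
#' @param n_learners number of bootstrap trees (default 200).
#' @param seed RNG seed for the bootstrap draws.
#' @param a optional learner weights (recycled to `n_learners`).
#' @return object of class `em_bag`: `trees`, `a`.
#' @export
train_bag <- function(x, y, n_learners = 200, seed = 1, a = 1) {
  x <- as.matrix(x)
  y <- em_label(y)
  if (nlevels(droplevels(y)) < 2) stop("both classes must be present")
  n <- nrow(x)
  a <- rep_len(a, n_learners)
  trees <- with_seed(seed, lapply(seq_len(n_learners), function(t) {
    idx <- sample.int(n, n, replace = TRUE)
    fit_class_tree(x[idx, , drop = FALSE], y[idx], maxdepth = 30,
                   minsplit = 2, minbucket = 1)
  }))
  structure(list(trees = trees, a = a, k = ncol(x)), class = "em_bag")
}

#' Bagged-tree posterior probability
#'
#' Weighted average of the included learners' leaf class frequencies:
#' `P_bag(c|x) = sum_t a_t P_t(c|x) I(t in S) / sum_t a_t I(t in S)`.
#' The two class posteriors sum to 1.
#'
#' @param model an `em_bag`.
#' @param x matrix (or vector) of PC scores.
#' @param class `"M"` (default) or `"E"`.
#' @param S indices of learners included in the prediction (default: all).
#' @return numeric vector of posterior probabilities in \[0,1\].
#' @export
bag_posterior <- function(model, x, class = "M", S = NULL) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  S <- S %||% seq_along(model$trees)
  if (!length(S)) stop("S is empty: no learners included in the prediction")
  num <- numeric(nrow(x)); den <- 0
  for (t in S) {
    num <- num + model$a[t] * tree_posterior(model$trees[[t]], x)
    den <- den + model$a[t]
  }
  pM <- num / den
  if (identical(class, "M")) pM else 1 - pM
}

#' @export
predict.em_bag <- function(object, newdata, ...) {
  em_label(bag_posterior(object, newdata) > 0.5)
}

#' @export
print.em_bag <- function(x, ...) {
  cat(sprintf("<em_bag> %d bootstrap trees\n", length(x$trees)))
  invisible(x)
}
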