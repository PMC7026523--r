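# Repeated stratified cross-validation and ANOVA/Dunnett PC-count selection.

stratified_folds <- function(y, folds) {
  f <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    f[idx] <- rep_len(seq_len(folds), length(idx))
  }
  f
}

#' Repeated stratified k-fold cross-validation
#'
#' Shuffles and stratifies the data `repeats` times; within each repeat every
#' cell is scored exactly once by a model trained on the other folds, and the
#' repeat's accuracy is the pooled fraction correct.
#'
#' @param x predictor matrix.
#' @param y labels (`"E"`/`"M"`).
#' @param trainer function `(x, y) -> model` whose `predict` method returns
#'   class labels; defaults to the linear SVM.
#' @param folds number of folds (>= 2, default 5).
#' @param repeats number of repeats (default 5).
#' @param seed RNG seed.
#' @return list with `accuracy` (per repeat), `mean`, `sd`.
#' @export
crossvalidate <- function(x, y, trainer = function(x, y) train_linear_svm(x, y),
                          folds = 5, repeats = 5, seed = 1) {
  if (folds < 2) stop("folds must be >= 2")
  x <- as.matrix(x)
  y <- em_label(y)
  acc <- vapply(seq_len(repeats), function(r) {
    with_seed(derive_seed(seed, r), {
      fa <- stratified_folds(y, folds)
      correct <- 0L
      for (f in seq_len(folds)) {
        tr <- fa != f
        m <- trainer(x[tr, , drop = FALSE], y[tr])
        pred <- predict(m, x[!tr, , drop = FALSE])
        correct <- correct + sum(pred == y[!tr])
      }
      correct / length(y)
    })
  }, numeric(1))
  list(accuracy = acc, mean = mean(acc), sd = stats::sd(acc),
       folds = folds, repeats = repeats)
}

# one-factor repeated-measures ANOVA (subjects = rows, treatments = cols);
# degenerate zero-variance tables return F = 0, p = 1
rm_anova <- function(acc) {
  if (stats::sd(acc) == 0) return(list(F = 0, p = 1))
  long <- data.frame(acc = as.vector(acc),
                     treat = factor(rep(seq_len(ncol(acc)), each = nrow(acc))),
                     subj = factor(rep(seq_len(nrow(acc)), ncol(acc))))
  fit <- stats::aov(acc ~ treat + Error(subj), data = long)
  tab <- summary(fit)[["Error: Within"]][[1]]
  i <- which(trimws(rownames(tab)) == "treat")
  list(F = tab[i, "F value"], p = tab[i, "Pr(>F)"])
}

#' Select the number of principal components
#'
#' Runs repeated stratified CV of the linear SVM for each candidate PC count,
#' then a one-factor repeated-measures ANOVA (repeats as subjects) on the
#' per-repeat accuracies, with Dunnett many-to-one comparisons against the
#' smallest candidate (1 PC). Selection policy: among candidates whose
#' improvement over 1 PC is significant (and positive), the smallest k whose
#' mean accuracy is within one pooled standard error of the best mean; if no
#' candidate is significant the baseline is kept.
#'
#' @param x feature matrix or table (the PCA is fitted on it once).
#' @param y labels.
#' @param ks candidate PC counts (default 1:17).
#' @param folds,repeats CV settings.
#' @param seed RNG seed.
#' @param alpha significance level for the Dunnett comparisons.
#' @return list with `k` (selected count), `anova` (`F`, `p`), `dunnett`
#'   (data.frame of estimates and adjusted p-values), `accuracy` (repeats x k
#'   matrix) and `policy`.
#' @export
select_pc_count <- function(x, y, ks = 1:17, folds = 5, repeats = 5,
                            seed = 1, alpha = 0.05) {
  if (length(ks) < 2) stop("need at least 2 candidate PC counts")
  if (repeats < 2) stop("repeats must be >= 2")
  ks <- sort(unique(as.integer(ks)))
  if (is.data.frame(x)) x <- feature_matrix(x)
  y <- em_label(y)
  pca <- pca_fit(x, k = max(ks))
  scores <- pca_transform(pca, x, k = max(ks))
  acc <- matrix(NA_real_, repeats, length(ks),
                dimnames = list(NULL, paste0("k", ks)))
  for (r in seq_len(repeats)) {
    fa <- with_seed(derive_seed(seed, r), stratified_folds(y, folds))
    for (j in seq_along(ks)) {
      xk <- scores[, seq_len(ks[j]), drop = FALSE]
      correct <- 0L
      for (f in seq_len(folds)) {
        tr <- fa != f
        m <- train_linear_svm(xk[tr, , drop = FALSE], y[tr])
        correct <- correct + sum(predict(m, xk[!tr, , drop = FALSE]) == y[!tr])
      }
      acc[r, j] <- correct / length(y)
    }
  }
  rm <- rm_anova(acc)
  Fval <- rm$F; pval <- rm$p
  long <- data.frame(acc = as.vector(acc),
                     kf = factor(rep(ks, each = repeats), levels = ks),
                     repf = factor(rep(seq_len(repeats), length(ks))))
  dun <- tryCatch({
    fit2 <- stats::aov(acc ~ kf + repf, data = long)
    gl <- summary(multcomp::glht(fit2, linfct = multcomp::mcp(kf = "Dunnett")))
    data.frame(k = ks[-1], estimate = unname(gl$test$coefficients),
               p = unname(gl$test$pvalues))
  }, error = function(e) data.frame(k = ks[-1], estimate = NA_real_, p = NA_real_))
  means <- colMeans(acc)
  sig <- dun$k[!is.na(dun$p) & dun$p < alpha & dun$estimate > 0]
  if (!length(sig)) {
    k_star <- ks[1]
  } else {
    se <- mean(apply(acc, 2, stats::sd)) / sqrt(repeats)
    good <- ks[means >= max(means) - se]
    cand <- intersect(sig, good)
    k_star <- if (length(cand)) min(cand) else min(sig)
  }
  list(k = k_star, anova = list(F = unname(Fval), p = unname(pval)),
       dunnett = dun, accuracy = acc,
       policy = "smallest Dunnett-significant k within one pooled SE of the best mean; none significant -> baseline")
}
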