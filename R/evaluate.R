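# Evaluation and reporting: ROC/AUC, outlier screening, score correlations,
# quartile-representative cells, model comparison, and the assembled report.

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores with trapezoidal AUC (equal to the
#' Mann-Whitney U statistic divided by n1*n2). Mesenchymal is the positive
#' class.
#'
#' @param scores numeric scores (higher = more mesenchymal).
#' @param labels class labels (`"E"`/`"M"`).
#' @return list with `points` (data.frame `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- em_label(labels)
  if (nlevels(droplevels(y)) < 2) stop("both classes must be present")
  r <- pROC::roc(response = y, predictor = scores, levels = c("E", "M"),
                 direction = "<", quiet = TRUE)
  pts <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
  pts <- pts[order(pts$fpr, pts$tpr), ]
  rownames(pts) <- NULL
  list(points = pts, auc = as.numeric(r$auc))
}

#' Exclude extreme scores
#'
#' Single-pass rule: scores more than `sd_threshold` standard deviations from
#' the population mean (both computed on the full sample) are excluded. A
#' zero-variance sample excludes nothing.
#'
#' @param scores numeric vector (n >= 3).
#' @param sd_threshold threshold in SD units (default 5.6).
#' @param ids identifiers parallel to `scores` (default indices).
#' @return list with `retained`, `retained_ids`, `excluded_ids`.
#' @export
exclude_outliers <- function(scores, sd_threshold = 5.6,
                             ids = seq_along(scores)) {
  stopifnot(length(scores) >= 3, length(ids) == length(scores))
  s <- stats::sd(scores)
  ex <- if (!is.finite(s) || s == 0) rep(FALSE, length(scores)) else
    abs(scores - mean(scores)) > sd_threshold * s
  list(retained = scores[!ex], retained_ids = ids[!ex],
       excluded_ids = ids[ex])
}

#' Pairwise correlations between score types
#'
#' Pearson and Spearman coefficients for every pair of numeric score columns;
#' a constant column yields `NA` with a note rather than an error.
#'
#' @param scores data.frame of score columns (e.g. a `score_set`), or any
#'   data.frame whose numeric columns should be compared.
#' @return data.frame: `a`, `b`, `pearson`, `spearman`, `note`.
#' @export
score_correlations <- function(scores) {
  num <- scores[vapply(scores, is.numeric, logical(1))]
  num <- num[, setdiff(names(num), "blend"), drop = FALSE]
  if (ncol(num) < 2 || nrow(num) < 3) stop("need >= 3 cells and >= 2 numeric columns")
  prs <- utils::combn(names(num), 2)
  do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
    a <- num[[prs[1, i]]]; b <- num[[prs[2, i]]]
    const <- stats::sd(a) == 0 || stats::sd(b) == 0
    data.frame(a = prs[1, i], b = prs[2, i],
               pearson = if (const) NA_real_ else stats::cor(a, b),
               spearman = if (const) NA_real_ else
                 stats::cor(a, b, method = "spearman"),
               note = if (const) "constant column: correlation undefined" else "")
  }))
}

#' Representative cells at the score order statistics
#'
#' Returns the cells whose scores are closest to the minimum, first quartile,
#' median, third quartile and maximum (quartiles by linear interpolation);
#' ties go to the lower id.
#'
#' @param scores numeric scores of one line.
#' @param ids cell identifiers parallel to `scores`.
#' @return data.frame: `stat`, `target` (the order statistic), `id`, `score`.
#'   When fewer than 5 cells are available the result carries attribute
#'   `partial = TRUE`.
#' @export
representative_cells <- function(scores, ids = seq_along(scores)) {
  stopifnot(length(scores) >= 1, length(ids) == length(scores))
  targets <- stats::quantile(scores, c(0, 0.25, 0.5, 0.75, 1), type = 7,
                             names = FALSE)
  ord <- order(as.character(ids))
  pick <- vapply(targets, function(tv) {
    d <- abs(scores - tv)
    cand <- which(d == min(d))
    cand[order(as.character(ids[cand]))][1]  # tie -> lower id
  }, integer(1))
  out <- data.frame(stat = c("min", "q1", "median", "q3", "max"),
                    target = targets, id = ids[pick], score = scores[pick])
  if (length(scores) < 5) attr(out, "partial") <- TRUE
  out
}

#' Compare two models' accuracy vectors
#'
#' Two-sample two-tailed Student's t-test on per-repeat accuracies
#' (equal-variance by default; Welch optional).
#'
#' @param a,b numeric accuracy vectors (>= 2 repeats each).
#' @param welch use the Welch correction.
#' @return list with `t`, `df`, `p`.
#' @export
compare_models <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 repeats per model")
  tt <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

# Freedman-Diaconis breaks over the pooled range
fd_breaks <- function(x) {
  h <- 2 * stats::IQR(x) / length(x)^(1 / 3)
  if (h <= 0) h <- diff(range(x)) / 30
  if (h <= 0) return(c(x[1] - 0.5, x[1] + 0.5))
  lo <- min(x); hi <- max(x)
  seq(lo - h / 2, hi + h, by = h)
}

#' Assemble the evaluation report for a scored dataset
#'
#' Bundles, per score type: confusion matrix and accuracy on cells with a
#' known class, ROC/AUC, pooled-bin (Freedman-Diaconis) histogram counts per
#' line, the SVM-score outlier exclusions (per line), pairwise score
#' correlations, and the quartile-representative cells of every line for the
#' SVM and AdaBoost scores.
#'
#' @param scores a `score_set` from [transfer_score()].
#' @param true_class optional vector of known classes (`"E"`/`"M"`, `NA` for
#'   unknown cells) parallel to `scores`.
#' @param outlier_sd SD threshold of the SVM-score outlier rule (default 5.6).
#' @return object of class `em_report`.
#' @export
evaluation_report <- function(scores, true_class = NULL, outlier_sd = 5.6) {
  stopifnot(is.data.frame(scores))
  score_cols <- c("svm_score", "platt_posterior", "boost_score", "bag_posterior")
  cutoffs <- c(svm_score = 0, platt_posterior = 0.5, boost_score = 0,
               bag_posterior = 0.5)
  lines <- unique(scores$line)

  labelled <- if (is.null(true_class)) rep(FALSE, nrow(scores)) else
    !is.na(true_class)
  perf <- lapply(stats::setNames(nm = score_cols), function(sc) {
    if (!any(labelled)) return(NULL)
    y <- em_label(true_class[labelled])
    pred <- em_label(scores[[sc]][labelled] > cutoffs[[sc]])
    cm <- table(truth = y, predicted = pred)
    list(confusion = cm, accuracy = sum(diag(cm)) / sum(cm),
         error_rate = 1 - sum(diag(cm)) / sum(cm),
         roc = if (nlevels(droplevels(y)) == 2)
           roc_auc(scores[[sc]][labelled], y) else NULL)
  })

  outliers <- lapply(stats::setNames(nm = lines), function(ln) {
    idx <- scores$line == ln
    if (sum(idx) < 3) return(list(retained_ids = scores$cell_id[idx],
                                  excluded_ids = character(0)))
    exclude_outliers(scores$svm_score[idx], outlier_sd,
                     ids = scores$cell_id[idx])
  })
  excluded_ids <- unlist(lapply(outliers, `[[`, "excluded_ids"), use.names = FALSE)

  hists <- lapply(stats::setNames(nm = score_cols), function(sc) {
    keep <- !(scores$cell_id %in% excluded_ids) | sc != "svm_score"
    v <- scores[[sc]][keep]
    br <- fd_breaks(v)
    lapply(stats::setNames(nm = lines), function(ln) {
      graphics::hist(scores[[sc]][keep & scores$line == ln],
                     breaks = br, plot = FALSE)$counts
    })
  })

  reps <- lapply(stats::setNames(nm = c("svm_score", "boost_score")), function(sc) {
    lapply(stats::setNames(nm = lines), function(ln) {
      idx <- scores$line == ln
      representative_cells(scores[[sc]][idx], ids = scores$cell_id[idx])
    })
  })

  structure(list(performance = perf, outliers = outliers,
                 excluded_ids = excluded_ids, histograms = hists,
                 correlations = score_correlations(
                   scores[, score_cols, drop = FALSE]),
                 representatives = reps, n_scored = nrow(scores),
                 outlier_sd = outlier_sd),
            class = "em_report")
}

#' @export
print.em_report <- function(x, ...) {
  cat(sprintf("<em_report> %d cells scored, %d SVM-score outliers excluded\n",
              x$n_scored, length(x$excluded_ids)))
  for (sc in names(x$performance)) {
    p <- x$performance[[sc]]
    if (!is.null(p)) {
      cat(sprintf("  %-16s accuracy %.3f%s\n", sc, p$accuracy,
                  if (!is.null(p$roc)) sprintf(", AUC %.3f", p$roc$auc) else ""))
    }
  }
  invisible(x)
}
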