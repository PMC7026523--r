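# Figure helpers (base graphics): score histograms, ROC curves, score-score
# scatter, and a representative-cell gallery.

line_palette <- function(lines) {
  stats::setNames(grDevices::hcl.colors(max(length(lines), 3), "Dark 3")[seq_along(lines)],
                  lines)
}

#' Plot per-line score histograms
#'
#' One panel per line on identical pooled Freedman-Diaconis bins, so the four
#' distributions are directly comparable.
#'
#' @param scores a `score_set`.
#' @param score_col score column to plot (default `"svm_score"`).
#' @export
plot_score_histograms <- function(scores, score_col = "svm_score") {
  lines <- unique(scores$line)
  br <- fd_breaks(scores[[score_col]])
  pal <- line_palette(lines)
  op <- graphics::par(mfrow = c(length(lines), 1), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(op))
  for (ln in lines) {
    graphics::hist(scores[[score_col]][scores$line == ln], breaks = br,
                   col = pal[[ln]], border = "white", main = ln,
                   xlab = score_col, ylab = "cells")
  }
  invisible(NULL)
}

#' Plot a ROC curve
#'
#' @param roc result of [roc_auc()].
#' @param ... passed to [graphics::plot()].
#' @export
plot_roc <- function(roc, ...) {
  graphics::plot(roc$points$fpr, roc$points$tpr, type = "s", lwd = 2,
                 xlab = "false positive rate", ylab = "true positive rate",
                 main = sprintf("AUC = %.3f", roc$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(NULL)
}

#' Scatter plots of one score against the others
#'
#' @param scores a `score_set`.
#' @param x score column on the x axis (default `"svm_score"`).
#' @export
plot_score_correlations <- function(scores, x = "svm_score") {
  others <- setdiff(c("svm_score", "platt_posterior", "boost_score",
                      "bag_posterior"), x)
  pal <- line_palette(unique(scores$line))
  op <- graphics::par(mfrow = c(1, length(others)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (sc in others) {
    graphics::plot(scores[[x]], scores[[sc]], col = pal[scores$line],
                   pch = 16, cex = 0.6, xlab = x, ylab = sc)
  }
  invisible(NULL)
}

#' Gallery of representative cells
#'
#' Crops and displays the height map of each listed cell (e.g. the
#' min/Q1/median/Q3/max cells of [representative_cells()]).
#'
#' @param fields list of `phase_field`s the cells came from.
#' @param cell_ids cell ids as produced by [build_feature_table()]
#'   (`<field_id>_cNNN`).
#' @param margin crop margin in pixels.
#' @export
plot_cell_gallery <- function(fields, cell_ids, margin = 5) {
  names(fields) <- vapply(fields, `[[`, character(1), "field_id")
  op <- graphics::par(mfrow = c(1, length(cell_ids)), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  for (cid in cell_ids) {
    fid <- sub("_c[0-9]+$", "", cid)
    lab <- as.integer(sub(".*_c", "", cid))
    f <- fields[[fid]]
    if (is.null(f)) stop(sprintf("field for cell '%s' not found", cid))
    idx <- which(f$labels == lab, arr.ind = TRUE)
    r <- range(idx[, 1]); cl <- range(idx[, 2])
    r <- clamp(c(r[1] - margin, r[2] + margin), 1, nrow(f$labels))
    cl <- clamp(c(cl[1] - margin, cl[2] + margin), 1, ncol(f$labels))
    h <- phase_to_height(f)[r[1]:r[2], cl[1]:cl[2]]
    graphics::image(h, axes = FALSE, main = cid, useRaster = TRUE,
                    col = grDevices::hcl.colors(64, "Viridis"))
  }
  invisible(NULL)
}
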