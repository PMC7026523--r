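# Feature standardization + PCA predictor transform, and the train/test split.

#' Partition a feature table into training and test sets
#'
#' Per-line random holdout of exactly `test_n` cells; the remainder goes to
#' training. With the default populations (332 and 309 archetype cells) and
#' `test_n = 80` this yields a 481-cell training set (252 + 229), the 4:1
#' regime used for classifier development.
#'
#' @param table feature table from [build_feature_table()].
#' @param test_n held-out cells per line.
#' @param seed RNG seed for the split.
#' @return list with `train` and `test` data.frames.
#' @export
partition_data <- function(table, test_n = 80, seed = 1) {
  stopifnot(is.data.frame(table), "line" %in% names(table))
  lines <- unique(table$line)
  cnt <- table(table$line)
  if (test_n > 0 && any(cnt <= test_n)) {
    stop(sprintf("insufficient cells: every line needs more than %d cells", test_n))
  }
  with_seed(seed, {
    test_idx <- unlist(lapply(lines, function(ln) {
      idx <- which(table$line == ln)
      if (test_n == 0) integer(0) else sample(idx, test_n)
    }))
    list(train = table[setdiff(seq_len(nrow(table)), test_idx), , drop = FALSE],
         test = table[sort(test_idx), , drop = FALSE])
  })
}

feature_matrix <- function(table) {
  as.matrix(table[, em_feature_names(), drop = FALSE])
}

#' Fit the standardize-then-PCA predictor transform
#'
#' Features are centred and scaled to unit variance (they carry incommensurate
#' units), then rotated onto principal components ordered by explained
#' variance. A constant feature gets scale 1 with a warning rather than
#' failing.
#'
#' @param x numeric matrix or feature table (rows = cells).
#' @param k number of PCs to retain (default 6).
#' @return object of class `pca_model`: `center`, `scale`, `rotation`,
#'   `sdev`, `k`.
#' @export
pca_fit <- function(x, k = 6) {
  if (is.data.frame(x)) x <- feature_matrix(x)
  stopifnot(is.matrix(x), nrow(x) >= 2)
  if (k < 1 || k > ncol(x)) stop("k must lie in [1, ncol(x)]")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  if (any(scl == 0)) {
    warning("constant feature(s): scale set to 1 for ",
            paste(colnames(x)[scl == 0], collapse = ", "))
    scl[scl == 0] <- 1
  }
  z <- sweep(sweep(x, 2, ctr), 2, scl, `/`)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  structure(list(center = ctr, scale = scl, rotation = pc$rotation,
                 sdev = pc$sdev, k = as.integer(k)),
            class = "pca_model")
}

#' Project data with a fitted PCA model
#'
#' Applies the training-fitted centring, scaling and rotation (no refit).
#'
#' @param model a `pca_model`.
#' @param x matrix or feature table with the training schema.
#' @param k number of PCs (defaults to the model's `k`).
#' @return matrix of PC scores (rows = cells, cols = PC1..PCk).
#' @export
pca_transform <- function(model, x, k = model$k) {
  if (is.data.frame(x)) x <- feature_matrix(x)
  if (ncol(x) != length(model$center)) {
    stop("schema mismatch: feature count differs from the fitted model")
  }
  z <- sweep(sweep(x, 2, model$center), 2, model$scale, `/`)
  z %*% model$rotation[, seq_len(k), drop = FALSE]
}

#' @export
print.pca_model <- function(x, ...) {
  ve <- x$sdev^2 / sum(x$sdev^2)
  cat(sprintf("<pca_model> %d features -> %d PCs (%.1f%% variance)\n",
              length(x$center), x$k, 100 * sum(ve[seq_len(x$k)])))
  invisible(x)
}
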