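# The trained EM model bundle and transfer scoring of unknown cells.

#' Train the full EM model bundle on archetype cells
#'
#' Fits the standardize+PCA transform on the training features only, then the
#' linear SVM (with Platt calibration of its decision values), the AdaBoost
#' ensemble and the bagged-tree ensemble on the PC scores.
#'
#' @param train training feature table (archetype cells).
#' @param labels class labels; by default derived from the generator's blend
#'   metadata (`blend >= 0.5` is mesenchymal).
#' @param k number of PCs (default 6).
#' @param C SVM box constraint.
#' @param kernel_scale SVM kernel scale `s_k`.
#' @param n_trees ensemble size (default 200).
#' @param learn_rate AdaBoost learning rate (default 0.1).
#' @param seed RNG seed (bootstrap draws).
#' @return object of class `em_model`: `pca`, `svm`, `platt`, `boost`, `bag`.
#' @export
em_train <- function(train, labels = NULL, k = 6, C = 1, kernel_scale = 1,
                     n_trees = 200, learn_rate = 0.1, seed = 1) {
  y <- if (!is.null(labels)) em_label(labels) else {
    if (!"blend" %in% names(train) || anyNA(train$blend)) {
      stop("labels not given and no blend metadata to derive them from")
    }
    em_label(train$blend >= 0.5)
  }
  pca <- pca_fit(train, k = k)
  pc <- pca_transform(pca, train)
  svm <- train_linear_svm(pc, y, C = C, kernel_scale = kernel_scale)
  platt <- platt_fit(svm_score(svm, pc), y)
  boost <- train_boost(pc, y, n_learners = n_trees, learn_rate = learn_rate)
  bag <- train_bag(pc, y, n_learners = n_trees, seed = derive_seed(seed, 77))
  structure(list(pca = pca, svm = svm, platt = platt, boost = boost,
                 bag = bag, k = as.integer(k)),
            class = "em_model")
}

#' @export
print.em_model <- function(x, ...) {
  cat(sprintf("<em_model> %d PCs; SVM + Platt + AdaBoost(%d) + Bag(%d)\n",
              x$k, length(x$boost$trees), length(x$bag$trees)))
  invisible(x)
}

#' Transfer the trained models to unknown cells
#'
#' Applies the training-fitted standardization and PCA (no refit) to a feature
#' table, then computes all four EM scores per cell: the SVM decision value
#' `s_j`, its Platt posterior, the AdaBoost score `f(x)` and the bagged-tree
#' posterior. The predicted class follows the SVM sign convention
#' (`s_j > 0` = mesenchymal; ties go to epithelial).
#'
#' @param model an `em_model`.
#' @param table feature table with the training schema.
#' @return `score_set` data.frame: per-cell metadata, the four scores, and
#'   `predicted_class`.
#' @export
transfer_score <- function(model, table) {
  stopifnot(inherits(model, "em_model"))
  pc <- pca_transform(model$pca, table)
  s <- svm_score(model$svm, pc)
  out <- data.frame(
    cell_id = table$cell_id %||% sprintf("cell%04d", seq_len(nrow(pc))),
    line = table$line %||% NA_character_,
    blend = table$blend %||% NA_real_,
    svm_score = s,
    platt_posterior = platt_posterior(model$platt, s),
    boost_score = boost_score(model$boost, pc),
    bag_posterior = bag_posterior(model$bag, pc),
    predicted_class = em_label(s > 0))
  class(out) <- c("score_set", "data.frame")
  out
}

model_schema_version <- "1.0"

#' Serialize an EM model bundle to JSON
#'
#' Everything needed to score new cells (PCA transform, SVM hyperplane, Platt
#' sigmoid, exported tree node tables and learner weights) is written to a
#' single schema-versioned JSON file.
#'
#' @param model an `em_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
em_model_save <- function(model, path) {
  stopifnot(inherits(model, "em_model"))
  payload <- list(
    schema = model_schema_version,
    k = model$k,
    pca = list(center = model$pca$center, scale = model$pca$scale,
               rotation = model$pca$rotation, sdev = model$pca$sdev,
               k = model$pca$k),
    svm = model$svm[c("beta", "b", "kernel_scale", "C", "k")],
    platt = model$platt[c("A", "B")],
    boost = list(a = model$boost$a, eps = model$boost$eps,
                 learn_rate = model$boost$learn_rate,
                 maxdepth = model$boost$maxdepth, k = model$boost$k,
                 trees = model$boost$trees),
    bag = list(a = model$bag$a, k = model$bag$k, trees = model$bag$trees))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' Load an EM model bundle from JSON
#'
#' @param path file written by [em_model_save()].
#' @return an `em_model`.
#' @export
em_model_load <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE)
  if (!identical(p$schema, model_schema_version)) {
    stop(sprintf("unsupported model schema '%s'", p$schema))
  }
  fix_tree <- function(tr) {
    n <- length(unlist(tr$node))
    col <- function(v, cast) {
      v <- unlist(v)
      if (is.null(v)) rep(cast(NA), n) else suppressWarnings(cast(v))
    }
    data.frame(node = col(tr$node, as.integer),
               var = col(tr$var, as.character),
               index = col(tr$index, as.numeric),
               ncat = col(tr$ncat, as.integer),
               p_E = col(tr$p_E, as.numeric),
               p_M = col(tr$p_M, as.numeric))
  }
  rot <- p$pca$rotation
  structure(list(
    pca = structure(list(center = unlist(p$pca$center),
                         scale = unlist(p$pca$scale),
                         rotation = matrix(unlist(rot), nrow = length(p$pca$center),
                                           dimnames = list(names(p$pca$center),
                                                           paste0("PC", seq_len(length(unlist(rot)) / length(p$pca$center))))),
                         sdev = unlist(p$pca$sdev), k = as.integer(p$pca$k)),
                    class = "pca_model"),
    svm = structure(list(beta = unlist(p$svm$beta), b = p$svm$b,
                         kernel_scale = p$svm$kernel_scale, C = p$svm$C,
                         k = as.integer(p$svm$k)), class = "em_svm"),
    platt = structure(list(A = p$platt$A, B = p$platt$B), class = "platt_model"),
    boost = structure(list(trees = lapply(p$boost$trees, fix_tree),
                           a = unlist(p$boost$a), eps = unlist(p$boost$eps),
                           learn_rate = p$boost$learn_rate,
                           maxdepth = as.integer(p$boost$maxdepth),
                           k = as.integer(p$boost$k)), class = "em_boost"),
    bag = structure(list(trees = lapply(p$bag$trees, fix_tree),
                         a = unlist(p$bag$a), k = as.integer(p$bag$k)),
                    class = "em_bag"),
    k = as.integer(p$k)), class = "em_model")
}
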