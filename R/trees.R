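# Portable decision-tree representation. Base learners for the ensembles are
# fitted with rpart and immediately exported to a flat node table, which is
# what prediction (and JSON serialization) operates on. Trees are fitted with
# no competitor or surrogate splits so the split rows map 1:1 onto the
# internal nodes of the frame.

tree_control <- function(maxdepth = 30, minsplit = 2, minbucket = 1, cp = 0) {
  rpart::rpart.control(maxdepth = maxdepth, minsplit = minsplit,
                       minbucket = minbucket, cp = cp, xval = 0,
                       maxcompete = 0, maxsurrogate = 0, usesurrogate = 0)
}

# fit a classification tree on PC predictors; y is an "E"/"M" factor
fit_class_tree <- function(x, y, weights = NULL, maxdepth = 30,
                           minsplit = 2, minbucket = 1) {
  x <- as.matrix(x)
  colnames(x) <- paste0("V", seq_len(ncol(x)))  # canonical predictor names
  d <- as.data.frame(x)
  d$.y <- y
  fit <- rpart::rpart(.y ~ ., data = d, weights = weights, method = "class",
                      control = tree_control(maxdepth, minsplit, minbucket))
  export_tree(fit, levels(y))
}

# flatten an rpart fit into a node table:
#   node (heap index), var (predictor name, NA at leaves), index (threshold),
#   ncat (-1: left if x < index; +1: left if x >= index), p_E, p_M
export_tree <- function(fit, class_levels) {
  fr <- fit$frame
  node <- as.integer(rownames(fr))
  is_leaf <- fr$var == "<leaf>"
  nsplit <- sum(!is_leaf)
  var <- rep(NA_character_, nrow(fr))
  index <- rep(NA_real_, nrow(fr))
  ncat <- rep(NA_integer_, nrow(fr))
  if (nsplit > 0) {
    sp <- fit$splits
    var[!is_leaf] <- as.character(fr$var[!is_leaf])
    index[!is_leaf] <- sp[seq_len(nsplit), "index"]
    ncat[!is_leaf] <- as.integer(sp[seq_len(nsplit), "ncat"])
  }
  yv2 <- fr$yval2
  # class method: columns are [class, n_1..n_K, p_1..p_K, nodeprob]
  K <- length(class_levels)
  probs <- yv2[, (1 + K + 1):(1 + 2 * K), drop = FALSE]
  data.frame(node = node, var = var, index = index, ncat = ncat,
             p_E = probs[, 1], p_M = probs[, 2])
}

# posterior P(M | x) for each row of x under an exported tree
tree_posterior <- function(tree, x) {
  x <- as.matrix(x)
  colnames(x) <- paste0("V", seq_len(ncol(x)))
  lookup <- match(tree$var, colnames(x))
  out <- numeric(nrow(x))
  node_row <- stats::setNames(seq_len(nrow(tree)), tree$node)
  for (i in seq_len(nrow(x))) {
    r <- node_row[["1"]]
    while (!is.na(tree$var[r])) {
      v <- x[i, lookup[r]]
      left <- if (tree$ncat[r] == -1L) v < tree$index[r] else v >= tree$index[r]
      child <- 2L * tree$node[r] + if (left) 0L else 1L
      r <- node_row[[as.character(child)]]
    }
    out[i] <- tree$p_M[r]
  }
  out
}

tree_predict_class <- function(tree, x) {
  em_label(tree_posterior(tree, x) > 0.5)
}
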