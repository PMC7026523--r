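test_that("AUC equals the pair-counting oracle and handles degenerate input", {
  # perfectly separated
  r <- roc_auc(c(-3, -2, -1, 1, 2, 3), c(-1, -1, -1, 1, 1, 1))
  expect_equal(r$auc, 1)
  # identical scores: chance
  expect_equal(roc_auc(rep(2, 6), c(-1, -1, -1, 1, 1, 1))$auc, 0.5)
  # 6-point toy with a tie: exact pair-counting agreement
  s <- c(0.1, 0.4, 0.35, 0.8, 0.35, 0.9)
  y <- c(-1, -1, 1, 1, -1, 1)
  expect_equal(roc_auc(s, y)$auc, auc_pair_oracle(s, y))
  # random small sets
  set.seed(41)
  for (i in 1:10) {
    s <- round(rnorm(20), 1)
    y <- rep(c(-1, 1), 10)
    expect_equal(roc_auc(s, y)$auc, auc_pair_oracle(s, y))
  }
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
  # ROC endpoints
  expect_equal(range(r$points$fpr), c(0, 1))
  expect_equal(range(r$points$tpr), c(0, 1))
})

test_that("the SD-threshold outlier rule excludes exactly the planted value", {
  set.seed(43)
  s <- c(rnorm(99), 10)
  ids <- sprintf("c%03d", 1:100)
  out <- exclude_outliers(s, sd_threshold = 5.6, ids = ids)
  expect_equal(out$excluded_ids, "c100")
  expect_length(out$retained, 99)
  # infinite threshold keeps everything
  expect_length(exclude_outliers(s, Inf, ids)$excluded_ids, 0)
  # zero-variance sample: nothing excluded
  expect_length(exclude_outliers(rep(1, 10))$excluded_ids, 0)
})

test_that("score correlations match manual rank computation", {
  d <- data.frame(a = c(1, 2, 3, 4, 5), b = c(2, 1, 4, 3, 5))
  cc <- score_correlations(d)
  expect_equal(cc$spearman, spearman_oracle(d$a, d$b), tolerance = 1e-12)
  # score against itself
  d2 <- data.frame(a = rnorm(10))
  d2$b <- d2$a
  cc2 <- score_correlations(d2)
  expect_equal(cc2$pearson, 1)
  expect_equal(cc2$spearman, 1)
  # strictly monotone sigmoid: Spearman 1, Pearson < 1
  d3 <- data.frame(s = seq(-4, 4, length.out = 20))
  d3$p <- 1 / (1 + exp(-2 * d3$s))
  cc3 <- score_correlations(d3)
  expect_equal(cc3$spearman, 1)
  expect_lt(cc3$pearson, 1)
  # constant column reported as undefined, not an error
  d4 <- data.frame(a = rnorm(5), b = rep(2, 5))
  cc4 <- score_correlations(d4)
  expect_true(is.na(cc4$pearson))
  expect_match(cc4$note, "constant")
})

test_that("representative cells hit the order statistics with lower-id ties", {
  r <- representative_cells(c(1, 2, 3, 4, 5), ids = letters[1:5])
  expect_equal(r$score, c(1, 2, 3, 4, 5))
  expect_equal(r$id, letters[1:5])
  # duplicate scores at the median: lowest id wins
  r2 <- representative_cells(c(1, 2, 3, 3, 5), ids = c("e", "d", "c", "b", "a"))
  expect_equal(r2$id[r2$stat == "median"], "b")
  # brute-force sort oracle on a larger sample
  set.seed(47)
  s <- rnorm(101); ids <- sprintf("c%03d", 1:101)
  r3 <- representative_cells(s, ids)
  qs <- quantile(s, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
  for (i in 1:5) {
    d <- abs(s - qs[i])
    expect_equal(r3$id[i], ids[which(d == min(d))[1]])
  }
  r4 <- representative_cells(c(1, 2, 3))
  expect_true(isTRUE(attr(r4, "partial")))
})

test_that("model comparison reproduces the textbook t-test", {
  eq <- compare_models(c(0.9, 0.91, 0.92), c(0.9, 0.91, 0.92))
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  a <- c(0.95, 0.96, 0.955); b <- c(0.93, 0.94, 0.945)
  got <- compare_models(a, b)
  want <- t_oracle(a, b)
  expect_equal(got$t, want$t, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)
  swapped <- compare_models(b, a)
  expect_equal(swapped$t, -got$t)
  expect_equal(swapped$p, got$p)
  expect_error(compare_models(1, c(1, 2)), "repeats")
})

test_that("the evaluation report reconciles counts and accuracy", {
  set.seed(51)
  n <- 60
  sc <- data.frame(
    cell_id = sprintf("c%03d", 1:n),
    line = rep(c("E_line", "M_line"), each = n / 2),
    blend = rep(c(0, 1), each = n / 2),
    svm_score = c(rnorm(n / 2, -2), rnorm(n / 2, 2)),
    stringsAsFactors = FALSE)
  sc$platt_posterior <- 1 / (1 + exp(-sc$svm_score))
  sc$boost_score <- sc$svm_score / 2
  sc$bag_posterior <- sc$platt_posterior
  sc$predicted_class <- factor(ifelse(sc$svm_score > 0, "M", "E"),
                               levels = c("E", "M"))
  truth <- rep(c("E", "M"), each = n / 2)
  rep <- evaluation_report(sc, truth)
  perf <- rep$performance$svm_score
  # accuracy from the confusion matrix equals mean per-cell correctness
  expect_equal(perf$accuracy,
               mean((sc$svm_score > 0) == (truth == "M")))
  expect_equal(sum(perf$confusion), n)
  # histogram counts + exclusions reconcile with the scored cells
  for (ln in unique(sc$line)) {
    counts <- sum(rep$histograms$svm_score[[ln]])
    expect_equal(counts + length(rep$outliers[[ln]]$excluded_ids),
                 sum(sc$line == ln))
  }
  expect_equal(rep$n_scored, n)
})
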