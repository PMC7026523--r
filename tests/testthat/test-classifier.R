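test_that("partition holds out exactly test_n cells per line", {
  tab <- data.frame(line = rep(c("A", "B"), c(100, 90)), v = rnorm(190))
  p <- partition_data(tab, test_n = 20, seed = 3)
  expect_equal(nrow(p$train), 150)
  expect_equal(nrow(p$test), 40)
  expect_equal(unname(table(p$test$line)), c(20L, 20L), ignore_attr = TRUE)
  # reproducible under the same seed
  p2 <- partition_data(tab, test_n = 20, seed = 3)
  expect_identical(p$test, p2$test)
  # zero holdout puts everything in training
  p0 <- partition_data(tab, test_n = 0, seed = 1)
  expect_equal(nrow(p0$train), 190)
  expect_equal(nrow(p0$test), 0)
  expect_error(partition_data(tab, test_n = 95), "insufficient")
})

test_that("PCA transform centres training data and orders variance", {
  set.seed(7)
  x <- matrix(rnorm(60 * 17), 60, 17,
              dimnames = list(NULL, em_feature_names()))
  m <- pca_fit(x, k = 6)
  sc <- pca_transform(m, x)
  expect_lt(max(abs(colMeans(sc))), 1e-10)
  expect_true(all(diff(m$sdev) <= 1e-12))
  expect_error(pca_transform(m, x[, 1:5]), "schema mismatch")

  # 2-D correlated Gaussian: PC1 matches the analytic covariance eigenvector
  set.seed(8)
  z <- matrix(rnorm(4000), ncol = 2) %*% chol(matrix(c(1, 0.8, 0.8, 1), 2))
  ctr <- scale(z, scale = apply(z, 2, sd))
  ev <- eigen(stats::cov(ctr))$vectors[, 1]
  m2 <- pca_fit(z, k = 2)
  ang <- acos(min(1, abs(sum(m2$rotation[, 1] * ev)))) * 180 / pi
  expect_lt(ang, 1)

  # constant feature: scale guard with warning, not failure
  xc <- cbind(x, const = 1)
  expect_warning(mc <- pca_fit(xc, k = 3), "constant")
  expect_true(all(is.finite(pca_transform(mc, xc))))
})

test_that("linear SVM reproduces the analytic max-margin solution", {
  x <- matrix(c(-1, 1), ncol = 1)
  y <- c("E", "M")
  m <- train_linear_svm(x, y, C = 1, kernel_scale = 1)
  expect_equal(unname(m$beta), 1, tolerance = 1e-4)
  expect_equal(m$b, 0, tolerance = 1e-4)
  # label swap negates the hyperplane
  m2 <- train_linear_svm(x, rev(y), C = 1)
  expect_equal(m2$beta, -m$beta, tolerance = 1e-6)
  expect_equal(m2$b, -m$b, tolerance = 1e-6)
  # duplicating the data leaves the separable solution unchanged
  m3 <- train_linear_svm(rbind(x, x), c(y, y), C = 1)
  expect_equal(m3$beta, m$beta, tolerance = 1e-4)
  expect_error(train_linear_svm(x, c("E", "E")), "both classes")
})

test_that("SVM solution matches the exhaustive KKT enumeration oracle", {
  set.seed(13)
  x <- matrix(c(-1.2, -0.8, -1.5, -0.4, 0.6, 1.1, 0.9, 1.6,
                -0.3, 0.2, -1.0, -1.4, 0.8, 0.1, 1.2, 0.7), ncol = 2)
  y <- rep(c(-1, 1), each = 4)
  m <- train_linear_svm(x, y, C = 1)
  oracle <- svm_qp_oracle(x, y, C = 1)
  expect_equal(unname(m$beta), oracle$beta, tolerance = 1e-4)
  expect_equal(m$b, oracle$b, tolerance = 1e-4)
})

test_that("the SVM score follows s = (x/s_k)'beta + b", {
  m <- structure(list(beta = c(1, 0), b = 0, kernel_scale = 1, C = 1, k = 2),
                 class = "em_svm")
  expect_equal(svm_score(m, c(2, 0)), 2)
  expect_equal(svm_score(m, c(0, 5)), 0)  # on the hyperplane
  m2 <- m; m2$kernel_scale <- 2
  expect_equal(svm_score(m2, c(2, 0)), 1)  # s_k = 2 halves the score
  expect_error(svm_score(m, c(1, 2, 3)), "dimension mismatch")
})

test_that("Platt calibration matches the likelihood grid-search oracle", {
  expect_equal(platt_posterior(structure(list(A = -1, B = 0),
                                         class = "platt_model"), 0), 0.5)
  set.seed(17)
  s <- c(rnorm(10, -1.2, 0.8), rnorm(10, 1.2, 0.8))
  y <- rep(c(-1, 1), each = 10)
  fit <- platt_fit(s, y)
  oracle <- platt_grid_oracle(s, y)
  expect_equal(fit$A, oracle$A, tolerance = 1e-3)
  expect_equal(fit$B, oracle$B, tolerance = 1e-3)
  expect_lt(fit$A, 0)  # higher score -> higher mesenchymal probability
  # symmetric scores give B ~ 0
  ssym <- c(-2, -1, -0.5, 0.5, 1, 2)
  fsym <- platt_fit(ssym, c(-1, -1, -1, 1, 1, 1))
  expect_equal(fsym$B, 0, tolerance = 1e-4)
  # posterior strictly monotone in the score
  ss <- seq(-5, 5, length.out = 50)
  expect_true(all(diff(platt_posterior(fit, ss)) > 0))
  expect_error(platt_fit(rep(1, 6), c(-1, -1, -1, 1, 1, 1)), "degenerate")
})

test_that("AdaBoost weights follow the closed form on a hand-checked toy", {
  # 0.5*log((1-eps)/eps) closed-form values
  expect_equal(0.5 * log((1 - 0.1) / 0.1), 0.5 * log(9))
  x <- matrix(1:8, ncol = 1)
  y <- c("E", "E", "E", "E", "M", "E", "M", "M")
  m <- train_boost(x, y, n_learners = 1, learn_rate = 0.1)
  # best stump splits at 4.5, misclassifying only the E at x = 6: eps = 1/8
  expect_equal(m$eps[1], 1 / 8)
  expect_equal(m$a[1], 0.5 * log(7))
  expect_equal(boost_score(m, matrix(c(2, 7), ncol = 1)),
               0.5 * log(7) * c(-1, 1))
  # invariant: every retained learner weight equals the closed form
  tab <- small_archetypes()
  pc <- pca_transform(pca_fit(tab, 6), tab)
  mb <- suppressWarnings(train_boost(pc, tab$blend >= 0.5, n_learners = 30))
  keep <- mb$eps > 0
  expect_equal(mb$a[keep], 0.5 * log((1 - mb$eps[keep]) / mb$eps[keep]))
  expect_true(all(mb$eps[keep] > 0 & mb$eps[keep] < 0.5))
  # score sign equals predicted class
  pred <- predict(mb, pc)
  expect_equal(pred, emscore:::em_label(boost_score(mb, pc) > 0))
})

test_that("bagged posterior implements the weighted aggregation formula", {
  # two single-leaf learners with posteriors 0.2 and 0.6, weights 1 and 3
  leaf <- function(pM) data.frame(node = 1L, var = NA_character_,
                                  index = NA_real_, ncat = NA_integer_,
                                  p_E = 1 - pM, p_M = pM)
  m <- structure(list(trees = list(leaf(0.2), leaf(0.6)), a = c(1, 3), k = 1),
                 class = "em_bag")
  expect_equal(bag_posterior(m, matrix(0), "M"), (0.2 + 3 * 0.6) / 4)
  expect_equal(bag_posterior(m, matrix(0), "M", S = 1), 0.2)
  expect_error(bag_posterior(m, matrix(0), S = integer(0)), "S is empty")
  # unanimous learners give posterior 1; complements always sum to 1
  m1 <- structure(list(trees = list(leaf(1), leaf(1)), a = c(1, 1), k = 1),
                  class = "em_bag")
  expect_equal(bag_posterior(m1, matrix(0)), 1)
  tab <- small_archetypes()
  pc <- pca_transform(pca_fit(tab, 6), tab)
  mb <- train_bag(pc, tab$blend >= 0.5, n_learners = 25, seed = 5)
  pM <- bag_posterior(mb, pc, "M"); pE <- bag_posterior(mb, pc, "E")
  expect_equal(pM + pE, rep(1, nrow(pc)))
  expect_true(all(pM >= 0 & pM <= 1))
})

test_that("cross-validation behaves correctly on separable and null data", {
  set.seed(23)
  x <- cbind(c(rnorm(20, -4), rnorm(20, 4)), c(rnorm(20, 4), rnorm(20, -4)))
  y <- rep(c("E", "M"), each = 20)
  cv <- crossvalidate(x, y, folds = 5, repeats = 3, seed = 1)
  expect_equal(cv$accuracy, rep(1, 3))
  # label permutation: chance-level accuracy
  yperm <- sample(y)
  cvp <- crossvalidate(x, yperm, folds = 5, repeats = 5, seed = 2)
  expect_lt(abs(cvp$mean - 0.5), 0.18)
  expect_error(crossvalidate(x, y, folds = 1), "folds")
})

test_that("repeated-measures ANOVA matches explicit sums of squares", {
  acc <- matrix(c(0.90, 0.91, 0.89, 0.92,
                  0.93, 0.95, 0.94, 0.96,
                  0.95, 0.96, 0.94, 0.97), nrow = 4)
  got <- emscore:::rm_anova(acc)
  want <- rm_anova_oracle(acc)
  expect_equal(got$F, want$F, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)
})

test_that("PC-count selection keeps the baseline when nothing improves", {
  set.seed(29)
  x <- cbind(f1 = c(rnorm(15, -4), rnorm(15, 4)),
             f2 = c(rnorm(15, 4), rnorm(15, -4)))
  y <- rep(c("E", "M"), each = 15)
  # perfectly separable at every k: accuracies identical, F = 0, k* = baseline
  sel <- suppressWarnings(  # degenerate zero-variance table warns in glht
    select_pc_count(x, y, ks = 1:2, folds = 3, repeats = 3, seed = 1))
  expect_equal(sel$anova$F, 0)
  expect_equal(sel$k, 1)
  expect_error(select_pc_count(x, y, ks = 2, folds = 3, repeats = 3), "2 candidate")
})

test_that("PC-count selection finds the informative dimension", {
  # PC1 is noise, adding PC2 brings the signal: selection must move past 1
  set.seed(31)
  n <- 60
  sig <- c(rnorm(n / 2, -1.2), rnorm(n / 2, 1.2))
  x <- cbind(rnorm(n, sd = 9), sig)
  y <- rep(c("E", "M"), each = n / 2)
  sel <- select_pc_count(x, y, ks = 1:2, folds = 5, repeats = 4, seed = 3)
  expect_equal(sel$k, 2)
  expect_true(sel$dunnett$p[sel$dunnett$k == 2] < 0.05)
})

test_that("transfer scoring is self-consistent and serializes losslessly", {
  tab <- small_archetypes()
  part <- partition_data(tab, test_n = 15, seed = 9)
  model <- suppressWarnings(em_train(part$train, k = 6, n_trees = 40, seed = 9))
  sc_tr <- transfer_score(model, part$train)
  truth <- emscore:::em_label(part$train$blend >= 0.5)
  expect_gt(mean(sc_tr$predicted_class == truth), 0.9)
  # epithelial centroid scores negative
  centroid <- part$train[1, ]
  centroid[em_feature_names()] <-
    as.list(colMeans(part$train[part$train$blend == 0, em_feature_names()]))
  expect_lt(transfer_score(model, centroid)$svm_score, 0)
  # sign convention: class = M iff s > 0
  sc_te <- transfer_score(model, part$test)
  expect_equal(sc_te$predicted_class, emscore:::em_label(sc_te$svm_score > 0))
  expect_error(transfer_score(model, part$test[, 1:8]),
               "schema|undefined|subscript")

  path <- tempfile(fileext = ".json")
  em_model_save(model, path)
  back <- em_model_load(path)
  sc2 <- transfer_score(back, part$test)
  expect_equal(sc2$svm_score, sc_te$svm_score, tolerance = 1e-12)
  expect_equal(sc2$boost_score, sc_te$boost_score, tolerance = 1e-12)
  expect_equal(sc2$bag_posterior, sc_te$bag_posterior, tolerance = 1e-12)
})
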