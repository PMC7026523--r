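# Independent oracles used to cross-check the implementation on tiny inputs.
# These deliberately share no code with the package internals.

# exact soft-margin linear SVM by exhaustive enumeration of the dual
# active-set configurations (each alpha_i is 0, C, or interior); every
# candidate is solved from the KKT equalities and checked against the KKT
# inequalities. Feasible only for tiny n (3^n configurations).
svm_qp_oracle <- function(x, y, C = 1) {
  x <- as.matrix(x)
  ysgn <- ifelse(y > 0, 1, -1)
  n <- nrow(x)
  K <- tcrossprod(x)
  best <- NULL; best_obj <- Inf
  primal <- function(beta, b) {
    0.5 * sum(beta^2) + C * sum(pmax(1 - ysgn * (x %*% beta + b), 0))
  }
  for (code in 0:(3^n - 1)) {
    cfg <- (code %/% 3^(0:(n - 1))) %% 3  # 0: alpha=0, 1: alpha=C, 2: interior
    I <- which(cfg == 2); U <- which(cfg == 1)
    alpha <- numeric(n); alpha[U] <- C
    if (length(I)) {
      A <- rbind(cbind(K[I, I, drop = FALSE] *
                         outer(rep(1, length(I)), ysgn[I]), 1),
                 c(ysgn[I], 0))
      rhs <- c(ysgn[I] - C * (if (length(U))
        K[I, U, drop = FALSE] %*% ysgn[U] else 0),
        -C * sum(ysgn[U]))
      sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      aI <- sol[seq_along(I)]; b <- sol[length(sol)]
      if (any(aI <= 1e-9 | aI >= C - 1e-9)) next
      alpha[I] <- aI
    } else {
      # configurations with no margin (interior) support vector leave b
      # undetermined; the generic optima used in the tests always have one
      next
    }
    beta <- colSums(x * (alpha * ysgn))
    f <- as.vector(x %*% beta + b)
    m <- ysgn * f
    ok <- all(m[cfg == 0] >= 1 - 1e-7) && all(m[U] <= 1 + 1e-7)
    if (!ok) next
    o <- primal(beta, b)
    if (o < best_obj - 1e-12) {
      best_obj <- o
      best <- list(beta = unname(beta), b = unname(b))
    }
  }
  best
}

# Platt sigmoid fit by pure grid search with refinement
platt_grid_oracle <- function(scores, y, iters = 7, grid_n = 41) {
  yb <- y > 0
  np <- sum(yb); nn <- sum(!yb)
  t <- ifelse(yb, (np + 1) / (np + 2), 1 / (nn + 2))
  nll <- function(A, B) {
    p <- 1 / (1 + exp(A * scores + B))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(t * log(p) + (1 - t) * log(1 - p))
  }
  ctr <- c(-1, 0); width <- c(6, 6)
  for (it in seq_len(iters)) {
    As <- seq(ctr[1] - width[1], ctr[1] + width[1], length.out = grid_n)
    Bs <- seq(ctr[2] - width[2], ctr[2] + width[2], length.out = grid_n)
    vals <- outer(As, Bs, Vectorize(nll))
    ij <- arrayInd(which.min(vals), dim(vals))
    ctr <- c(As[ij[1]], Bs[ij[2]])
    width <- width * 2.5 / (grid_n - 1)
  }
  list(A = ctr[1], B = ctr[2])
}

# AUC by exhaustive concordant-pair counting (ties count 1/2)
auc_pair_oracle <- function(scores, y) {
  pos <- scores[y > 0]; neg <- scores[y <= 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# one-factor repeated-measures ANOVA F by explicit sums of squares
# acc: matrix, rows = subjects (repeats), cols = treatments
rm_anova_oracle <- function(acc) {
  n <- nrow(acc); k <- ncol(acc)
  gm <- mean(acc)
  ss_treat <- n * sum((colMeans(acc) - gm)^2)
  ss_subj <- k * sum((rowMeans(acc) - gm)^2)
  ss_tot <- sum((acc - gm)^2)
  ss_err <- ss_tot - ss_treat - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  F <- (ss_treat / df1) / (ss_err / df2)
  list(F = F, p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

# two-sample pooled-variance t statistic from the textbook formula
t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = na + nb - 2,
       p = 2 * stats::pt(abs(t), na + nb - 2, lower.tail = FALSE))
}

# Spearman correlation from explicitly constructed average ranks
spearman_oracle <- function(a, b) {
  avrank <- function(v) {
    s <- sort(v)
    vapply(v, function(x) mean(which(s == x)), numeric(1))
  }
  ra <- avrank(a); rb <- avrank(b)
  da <- ra - mean(ra); db <- rb - mean(rb)
  sum(da * db) / sqrt(sum(da^2) * sum(db^2))
}

# measured eccentricity of a logical mask from coordinate moments
mask_ecc_oracle <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  cv <- stats::cov(idx) * (nrow(idx) - 1) / nrow(idx)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  sqrt(max(0, 1 - ev[2] / ev[1]))
}
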