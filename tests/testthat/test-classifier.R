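# Logistic classifier, ROC machinery, repeated cross-validation.

sim_logistic <- function(n, theta, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- length(theta) - 1L
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  y <- rbinom(n, 1, sigmoid(drop(cbind(1, X) %*% theta)))
  list(X = X, y = y)
}

test_that("sigmoid is symmetric and numerically stable", {
  expect_equal(sigmoid(0), 0.5)
  y <- c(rnorm(20, 0, 5), 50, -50, 700, -700)
  expect_equal(sigmoid(y) + sigmoid(-y), rep(1, length(y)))
  expect_lt(abs(sigmoid(50) - 1), 1e-15)
  expect_false(any(is.nan(sigmoid(c(-750, 750)))))
})

test_that("cost matches a per-sample oracle and known closed forms", {
  set.seed(3)
  X <- matrix(rnorm(40), 20, 2)
  y <- rbinom(20, 1, 0.5)
  theta <- rnorm(3)
  naive <- 0
  for (i in 1:20) {
    p <- 1 / (1 + exp(-(theta[1] + sum(theta[2:3] * X[i, ]))))
    naive <- naive - (y[i] * log(p) + (1 - y[i]) * log(1 - p)) / 20
  }
  expect_equal(logistic_cost(theta, X, y), naive, tolerance = 1e-12)

  # theta = 0 on balanced classes: exactly ln 2
  yb <- rep(c(0, 1), 10)
  expect_equal(logistic_cost(c(0, 0, 0), X, yb), log(2))

  # perfectly confident predictions cost no more than the clipping floor
  Xs <- matrix(c(-1e4, 1e4), 2, 1)
  expect_lte(logistic_cost(c(0, 1), Xs, c(0, 1)), -log(1 - 1e-15) + 1e-16)

  expect_error(logistic_cost(theta, X, c(y[-1], 2)), "labels")
})

test_that("cost is convex along random segments", {
  set.seed(4)
  X <- matrix(rnorm(100), 50, 2)
  y <- rbinom(50, 1, 0.5)
  for (i in 1:25) {
    t1 <- rnorm(3, sd = 2); t2 <- rnorm(3, sd = 2); a <- runif(1)
    lhs <- logistic_cost(a * t1 + (1 - a) * t2, X, y)
    rhs <- a * logistic_cost(t1, X, y) + (1 - a) * logistic_cost(t2, X, y)
    expect_lte(lhs, rhs + 1e-9)
  }
})

test_that("fit_logistic matches glm and is permutation invariant", {
  d <- sim_logistic(800, c(-0.5, 1, -0.7), seed = 5)
  m <- fit_logistic(d$X, d$y)
  g <- stats::glm(d$y ~ d$X, family = stats::binomial())
  expect_true(m$converged)
  expect_lt(max(abs(coef(m) - unname(coef(g)))), 1e-5)
  expect_lt(max(abs(sqrt(diag(vcov(m))) - unname(sqrt(diag(vcov(g)))))), 1e-5)

  perm <- sample(nrow(d$X))
  m2 <- fit_logistic(d$X[perm, ], d$y[perm])
  expect_lt(max(abs(coef(m) - coef(m2))), 1e-8)

  expect_error(fit_logistic(d$X, rep(1, 800)), "each class")
})

test_that("fit_logistic recovers simulation parameters within 3 SE", {
  theta <- c(-1, 0.8, -0.5, 0.3)
  d <- sim_logistic(5000, theta, seed = 6)
  m <- fit_logistic(d$X, d$y)
  se <- sqrt(diag(vcov(m)))
  expect_true(all(abs(coef(m) - theta) < 3 * se))
})

test_that("predictions are probabilities consistent with hand arithmetic", {
  d <- sim_logistic(200, c(0.2, 1, -1), seed = 7)
  m <- fit_logistic(d$X, d$y)
  x_new <- data.frame(x1 = 0.5, x2 = -1)
  manual <- 1 / (1 + exp(-(coef(m)[1] + coef(m)[2] * 0.5 - coef(m)[3])))
  expect_equal(unname(predict(m, x_new)), unname(manual), tolerance = 1e-12)

  # monotone in a positive-coefficient feature
  stopifnot(coef(m)["x1"] > 0)
  grid <- data.frame(x1 = seq(-3, 3, length.out = 11), x2 = 0)
  expect_true(all(diff(predict(m, grid)) >= 0))
  expect_true(all(predict(m, d$X) > 0 & predict(m, d$X) < 1))
  expect_error(predict(m, data.frame(bad = 1)), "x1")
})

test_that("roc_curve handles separation, ties, and matches pair counting", {
  perf <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perf$auc, 1)
  expect_true(any(perf$fpr == 0 & perf$tpr == 1))

  tied <- roc_curve(rep(0.5, 10), rep(c(0, 1), 5))
  expect_equal(tied$auc, 0.5)

  pair_auc <- function(s, l) {
    pos <- s[l == 1]; neg <- s[l == 0]
    g <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
    mean(g)
  }
  set.seed(8)
  for (i in 1:50) {
    n <- sample(20:60, 1)
    s <- sample(round(rnorm(n), 1))  # rounded: plenty of ties
    l <- rbinom(n, 1, 0.4)
    if (length(unique(l)) < 2) next
    expect_equal(roc_curve(s, l)$auc, pair_auc(s, l), tolerance = 1e-12)
  }
  expect_error(roc_curve(1:5, rep(1, 5)), "both classes")

  # independent cross-check against pROC on a tied, unbalanced instance
  s <- round(rnorm(150), 1)
  l <- rbinom(150, 1, 0.3)
  expect_equal(roc_curve(s, l)$auc,
               as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(9)
  s <- rnorm(100); l <- rbinom(100, 1, 0.5)
  a1 <- roc_curve(s, l)$auc
  expect_equal(roc_curve(exp(s), l)$auc, a1, tolerance = 1e-12)
  expect_equal(roc_curve(qlogis(plogis(s)), l)$auc, a1, tolerance = 1e-9)
})

test_that("cross-validation is seeded, enveloped, and near the analytic AUC", {
  set.seed(10)
  n <- 600
  x <- c(rnorm(n / 2, 0), rnorm(n / 2, 1.5))
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(x = x)
  cv1 <- crossvalidate(X, y, k = 10, reps = 15, seed = 99)
  cv2 <- crossvalidate(X, y, k = 10, reps = 15, seed = 99)
  expect_identical(cv1$auc_reps, cv2$auc_reps)
  expect_identical(cv1$mean_tpr, cv2$mean_tpr)

  # mean curve lies inside its own percentile envelope
  expect_true(all(cv1$mean_tpr >= cv1$tpr_lo - 1e-12))
  expect_true(all(cv1$mean_tpr <= cv1$tpr_hi + 1e-12))
  expect_true(all(diff(cv1$mean_tpr) >= -1e-12))

  # gaussian classes: AUC should approach Phi(delta / sqrt(2))
  expect_lt(abs(cv1$auc - pnorm(1.5 / sqrt(2))), 0.03)
})

test_that("grouped folds never split a patient across train and test", {
  d <- sim_logistic(120, c(0, 1, -1), seed = 11)
  group <- rep(sprintf("P%02d", 1:30), each = 4)
  # with 30 groups of 4 in 10 folds each fold holds whole groups, so pooled
  # out-of-fold scores exist for every sample and the run must succeed
  cv <- crossvalidate(d$X, d$y, k = 10, reps = 3, seed = 12, group = group)
  expect_length(cv$auc_reps, 3)
  expect_true(all(cv$auc_reps > 0 & cv$auc_reps < 1))
})

test_that("specificity is read off the mean ROC curve", {
  perfect <- structure(list(fpr_grid = seq(0, 1, 0.01),
                            mean_tpr = c(0, rep(1, 100))),
                       class = "roc_summary")
  expect_equal(unname(specificity_at_sensitivity(perfect, c(0.6, 0.8))),
               c(0.99, 0.99))
  diag <- structure(list(fpr_grid = seq(0, 1, 0.01),
                         mean_tpr = seq(0, 1, 0.01)),
                    class = "roc_summary")
  expect_equal(unname(specificity_at_sensitivity(diag, c(0.6, 0.8))),
               c(0.4, 0.2))
  flatline <- structure(list(fpr_grid = seq(0, 1, 0.01),
                             mean_tpr = rep(0.5, 101)),
                        class = "roc_summary")
  expect_true(is.na(specificity_at_sensitivity(flatline, 0.8)))
})

test_that("feature-set comparison validates subsets and dedupes", {
  set.seed(13)
  ds <- data.frame(label = rep(c(0, 1), each = 40),
                   pr_mean = rnorm(80), pr_grad = rnorm(80),
                   spo2_mean = rnorm(80) - rep(c(0, 1), each = 40),
                   spo2_grad = rnorm(80), rr_mean = rnorm(80),
                   rr_grad = rnorm(80))
  expect_error(compare_feature_sets(ds, subsets = list("HRV")), "unknown")
  expect_warning(
    out <- compare_feature_sets(ds, subsets = list("PR", "PR"), reps = 2),
    "duplicate")
  expect_equal(nrow(out$table), 1)
  out2 <- compare_feature_sets(ds, subsets = list("SpO2", c("RR", "PR")),
                               reps = 3, seed = 5)
  expect_equal(out2$table$features, c("SpO2", "RR+PR"))
  expect_true(all(out2$table$mean_auc > 0 & out2$table$mean_auc < 1))
})
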