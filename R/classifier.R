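# Logistic classification of stable vs prodromal periods, with repeated
# 10-fold cross-validation, per-repeat ROC curves, vertically averaged mean
# ROC with percentile confidence bands, and AUC summaries.

#' Numerically stable sigmoid
#'
#' @param y numeric vector.
#' @return `1 / (1 + exp(-y))`, computed without overflow for large `|y|`.
#' @export
sigmoid <- function(y) {
  out <- numeric(length(y))
  pos <- !is.na(y) & y >= 0
  out[pos] <- 1 / (1 + exp(-y[pos]))
  ey <- exp(y[!pos])
  out[!pos] <- ey / (1 + ey)
  out[is.na(y)] <- NA_real_
  out
}

#' Mean cross-entropy cost for logistic regression
#'
#' Probabilities are clipped to `[eps, 1 - eps]` so numerically saturated
#' predictions cannot produce infinite cost.
#'
#' @param theta parameter vector (intercept first).
#' @param X design matrix *without* the intercept column.
#' @param y labels in \{0, 1\}.
#' @param eps clipping floor (default 1e-15).
#' @return Scalar mean cost.
#' @export
logistic_cost <- function(theta, X, y, eps = 1e-15) {
  if (!all(y %in% c(0, 1))) stopf("labels must be 0 or 1")
  p <- sigmoid(drop(cbind(1, as.matrix(X)) %*% theta))
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Fit a logistic classifier by Newton iteration on the convex cost
#'
#' Features are z-scored internally using the training data; the convex mean
#' cross-entropy cost is minimised from a zero start by damped Newton steps
#' until the gradient norm falls below `tol`. Coefficients (and their
#' covariance) are mapped back to the original feature scale, so predictions
#' and inference are expressed in the units of the input features.
#'
#' @param X numeric matrix or data.frame of features (no intercept column).
#' @param y labels in \{0, 1\}, at least 2 samples per class.
#' @param tol gradient-norm convergence tolerance (default 1e-6).
#' @param max_iter iteration cap (default 1e5).
#' @param lambda optional ridge penalty on the standardised non-intercept
#'   coefficients (default 0, plain logistic regression).
#' @return An object of class `copd_logit` with `coefficients` (original
#'   scale, intercept first), `vcov`, `feature_names`, `standardization`,
#'   `converged`, `iterations`, `final_gradient_norm`, `cost`.
#' @export
fit_logistic <- function(X, y, tol = 1e-6, max_iter = 1e5, lambda = 0) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stopf("labels must be 0 or 1")
  if (min(table(factor(y, levels = c(0, 1)))) < 2L)
    stopf("need at least 2 samples in each class")
  fn <- colnames(X)
  if (is.null(fn)) fn <- paste0("x", seq_len(ncol(X)))

  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Z <- cbind(1, sweep(sweep(X, 2, ctr), 2, scl, "/"))
  n <- nrow(Z); p <- ncol(Z)
  pen <- c(0, rep(lambda, p - 1L))

  theta <- numeric(p)
  grad_norm <- Inf
  iter <- 0L
  while (iter < max_iter) {
    eta <- drop(Z %*% theta)
    mu <- sigmoid(eta)
    grad <- drop(crossprod(Z, mu - y)) / n + pen * theta
    grad_norm <- sqrt(sum(grad^2))
    if (grad_norm < tol) break
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Z * w, Z) / n + diag(pen, p)
    step <- tryCatch(solve(H, grad), error = function(e) grad)
    # damped Newton: halve until the convex cost decreases
    cost0 <- logistic_cost(theta, Z[, -1, drop = FALSE], y) +
      sum(pen * theta^2) / 2
    alpha <- 1
    repeat {
      cand <- theta - alpha * step
      cost1 <- logistic_cost(cand, Z[, -1, drop = FALSE], y) +
        sum(pen * cand^2) / 2
      if (cost1 <= cost0 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    theta <- cand
    iter <- iter + 1L
  }
  converged <- grad_norm < tol
  if (!converged)
    warning(sprintf("logistic fit did not converge: gradient norm %.3g after %d iterations",
                    grad_norm, iter), call. = FALSE)

  # map standardised coefficients (and covariance) to the original scale:
  # theta_orig = A %*% theta_std with a fixed linear map A
  A <- diag(c(1, 1 / scl))
  A[1, -1] <- -ctr / scl
  coef_orig <- drop(A %*% theta)
  names(coef_orig) <- c("(Intercept)", fn)
  mu <- sigmoid(drop(Z %*% theta))
  w <- mu * (1 - mu)
  info <- crossprod(Z * w, Z)  # observed Fisher information (unpenalised)
  vc <- tryCatch(A %*% solve(info) %*% t(A), error = function(e) {
    matrix(NA_real_, p, p)
  })
  dimnames(vc) <- list(names(coef_orig), names(coef_orig))

  structure(list(coefficients = coef_orig, vcov = vc,
                 feature_names = fn,
                 standardization = list(center = ctr, scale = scl),
                 theta_std = theta, converged = converged, iterations = iter,
                 final_gradient_norm = grad_norm,
                 cost = logistic_cost(theta, Z[, -1, drop = FALSE], y),
                 n = n, lambda = lambda),
            class = "copd_logit")
}

#' @export
print.copd_logit <- function(x, digits = 4, ...) {
  cat(sprintf("Logistic classifier (%d samples, %s)\n", x$n,
              if (x$converged) sprintf("converged in %d Newton steps", x$iterations)
              else sprintf("NOT converged, gradient norm %.3g", x$final_gradient_norm)))
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
coef.copd_logit <- function(object, ...) object$coefficients

#' @export
vcov.copd_logit <- function(object, ...) object$vcov

#' @export
summary.copd_logit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab, cost = object$cost, n = object$n,
                 converged = object$converged), class = "summary.copd_logit")
}

#' @export
print.summary.copd_logit <- function(x, ...) {
  cat(sprintf("Logistic classifier: n = %d, mean cross-entropy %.4f\n\n",
              x$n, x$cost))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' Predicted probability of the prodromal class
#'
#' @param object a `copd_logit`.
#' @param newdata matrix or data.frame with the model's feature columns.
#' @param type `"response"` (probability, default) or `"link"`.
#' @param ... unused.
#' @return Numeric vector of probabilities in (0, 1) (or linear predictors).
#' @export
predict.copd_logit <- function(object, newdata, type = c("response", "link"),
                               ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  missing <- setdiff(object$feature_names, names(newdata))
  if (length(missing) > 0L)
    stopf("newdata is missing feature column(s): %s",
          paste(missing, collapse = ", "))
  newdata <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  eta <- drop(cbind(1, newdata) %*% object$coefficients)
  if (type == "link") eta else sigmoid(eta)
}

#' ROC curve over all score thresholds
#'
#' Thresholds are the sorted unique scores (ties grouped); the curve is
#' anchored at (0,0) and (1,1). A correctly classified prodromal period
#' (label 1) is a true positive; a correctly classified stable period
#' (label 0) is a true negative.
#'
#' @param scores classifier scores, higher = more prodromal.
#' @param labels labels in \{0, 1\}; both classes must be present.
#' @return List with `fpr`, `tpr` (non-decreasing, in \[0,1\]) and `auc`
#'   (trapezoidal).
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stopf("labels must be 0 or 1")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stopf("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # group tied scores: cumulative counts at the last index of each tie group
  last <- rev(!duplicated(rev(s)))
  tp <- cumsum(l)[last]; fp <- cumsum(1 - l)[last]
  fpr <- c(0, fp / n_neg, 1)
  tpr <- c(0, tp / n_pos, 1)
  keep <- !duplicated(cbind(fpr, tpr))
  fpr <- fpr[keep]; tpr <- tpr[keep]
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

interp_tpr <- function(curve, grid) {
  stats::approx(curve$fpr, curve$tpr, xout = grid, ties = max,
                yleft = 0, yright = 1)$y
}

#' Repeated k-fold cross-validation with mean ROC summary
#'
#' For each repeat the data are randomly partitioned into `k` folds
#' (unstratified; a partition leaving a training split single-class is
#' resampled); out-of-fold predicted probabilities are pooled over the folds
#' so every sample is scored once per repeat, giving one ROC curve per
#' repeat. Each curve is interpolated onto a fixed false-positive-rate grid
#' and averaged vertically; 95% bands are the 2.5/97.5 percentiles of the
#' true-positive rate per grid point. The headline AUC is the mean of the
#' per-repeat trapezoidal AUCs, with a percentile interval.
#'
#' @param X feature matrix or data.frame.
#' @param y labels in \{0, 1\}.
#' @param k number of folds (default 10).
#' @param reps number of repeats (default 1000).
#' @param seed integer seed for the fold partitions.
#' @param fpr_grid grid for vertical averaging (default `seq(0, 1, 0.01)`).
#' @param group optional grouping vector (e.g. patient id); when supplied,
#'   folds are drawn over groups so one group never spans train and test.
#' @param lambda ridge penalty passed to [fit_logistic()].
#' @return An object of class `roc_summary`: `fpr_grid`, `mean_tpr`,
#'   `tpr_lo`, `tpr_hi`, `auc` (mean), `auc_ci`, `auc_reps`,
#'   `auc_of_mean_curve`, `k`, `reps`, `n`, `class_counts`.
#' @export
crossvalidate <- function(X, y, k = 10, reps = 1000, seed = 1L,
                          fpr_grid = seq(0, 1, by = 0.01), group = NULL,
                          lambda = 0) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (k < 2) stopf("k must be >= 2")
  if (reps < 1) stopf("reps must be >= 1")
  if (length(unique(y)) < 2L) stopf("both classes must be present")
  units <- if (is.null(group)) seq_len(n) else unique(group)
  n_units <- length(units)
  if (n_units < k) stopf("fewer units (%d) than folds (%d)", n_units, k)

  with_seed(seed, {
    tpr_mat <- matrix(NA_real_, reps, length(fpr_grid))
    aucs <- numeric(reps)
    for (r in seq_len(reps)) {
      repeat {
        fold_of_unit <- sample(rep_len(seq_len(k), n_units))
        fold <- if (is.null(group)) fold_of_unit
                else fold_of_unit[match(group, units)]
        ok <- all(vapply(seq_len(k), function(f) {
          length(unique(y[fold != f])) == 2L && any(fold == f)
        }, logical(1)))
        if (ok) break
        message("degenerate fold partition resampled")
      }
      prob <- numeric(n)
      for (f in seq_len(k)) {
        test <- fold == f
        model <- fit_logistic(X[!test, , drop = FALSE], y[!test],
                              lambda = lambda)
        prob[test] <- predict(model, X[test, , drop = FALSE])
      }
      curve <- roc_curve(prob, y)
      aucs[r] <- curve$auc
      tpr_mat[r, ] <- interp_tpr(curve, fpr_grid)
    }
    structure(list(
      fpr_grid = fpr_grid,
      mean_tpr = colMeans(tpr_mat),
      tpr_lo = apply(tpr_mat, 2, stats::quantile, 0.025),
      tpr_hi = apply(tpr_mat, 2, stats::quantile, 0.975),
      auc = mean(aucs),
      auc_ci = unname(stats::quantile(aucs, c(0.025, 0.975))),
      auc_reps = aucs,
      auc_of_mean_curve = sum(diff(fpr_grid) *
        (utils::head(colMeans(tpr_mat), -1) + utils::tail(colMeans(tpr_mat), -1)) / 2),
      k = k, reps = reps, n = n,
      class_counts = table(factor(y, levels = c(0, 1)))),
      class = "roc_summary")
  })
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("Repeated %d-fold cross-validation, %d repeats, n = %d (%s stable / %s prodromal)\n",
              x$k, x$reps, x$n, x$class_counts[1], x$class_counts[2]))
  cat(sprintf("  mean AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$auc, x$auc_ci[1], x$auc_ci[2]))
  sp <- specificity_at_sensitivity(x, c(0.6, 0.8))
  cat(sprintf("  specificity %.0f%%-%.0f%% for 60%%-80%% sensitivity (mean ROC curve)\n",
              100 * sp[1], 100 * sp[2]))
  invisible(x)
}

#' @export
plot.roc_summary <- function(x, main = "Mean ROC curve (95% band)", ...) {
  graphics::plot(x$fpr_grid, x$mean_tpr, type = "l", lwd = 2,
                 xlab = "1 - specificity (false positive rate)",
                 ylab = "Sensitivity (true positive rate)", main = main, ...)
  graphics::polygon(c(x$fpr_grid, rev(x$fpr_grid)),
                    c(x$tpr_lo, rev(x$tpr_hi)),
                    border = NA, col = grDevices::adjustcolor("steelblue", 0.3))
  graphics::lines(x$fpr_grid, x$mean_tpr, lwd = 2)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}

#' Specificity at requested sensitivity levels on the mean ROC curve
#'
#' For each sensitivity, returns `1 - fpr` at the smallest grid
#' false-positive rate whose mean true-positive rate reaches the level;
#' unreachable levels give `NA`.
#'
#' @param summary a `roc_summary`.
#' @param sens_levels sensitivities in \[0, 1\] (default `c(0.6, 0.8)`).
#' @return Named numeric vector of specificities in \[0, 1\].
#' @export
specificity_at_sensitivity <- function(summary, sens_levels = c(0.6, 0.8)) {
  stopifnot(inherits(summary, "roc_summary"))
  out <- vapply(sens_levels, function(s) {
    hit <- which(summary$mean_tpr >= s)
    if (length(hit) == 0L) NA_real_ else 1 - summary$fpr_grid[min(hit)]
  }, numeric(1))
  names(out) <- sprintf("sens_%g", sens_levels)
  out
}

VITAL_FEATURES <- list(PR = c("pr_mean", "pr_grad"),
                       SpO2 = c("spo2_mean", "spo2_grad"),
                       RR = c("rr_mean", "rr_grad"))

#' Compare feature subsets of the three vital signs by cross-validated AUC
#'
#' Runs [crossvalidate()] for each named subset of \{PR, SpO2, RR\} with a
#' shared per-subset seed schedule and tabulates mean AUC, its percentile
#' interval, and the specificity range at 60%-80% sensitivity.
#'
#' @param dataset data.frame from [build_dataset()] (needs the feature
#'   columns and `label`).
#' @param subsets list of character vectors naming vitals; default all 7
#'   combinations.
#' @param k,reps,seed,group passed to [crossvalidate()].
#' @return List with `table` (data.frame, one row per subset) and
#'   `summaries` (named list of `roc_summary`).
#' @export
compare_feature_sets <- function(dataset,
                                 subsets = list("PR", "SpO2", "RR",
                                                c("PR", "SpO2"), c("RR", "PR"),
                                                c("RR", "SpO2"),
                                                c("RR", "PR", "SpO2")),
                                 k = 10, reps = 1000, seed = 1L,
                                 group = NULL) {
  names(subsets) <- vapply(subsets, paste, character(1), collapse = "+")
  if (anyDuplicated(names(subsets))) {
    warning("duplicate feature subsets removed", call. = FALSE)
    subsets <- subsets[!duplicated(names(subsets))]
  }
  bad <- setdiff(unique(unlist(subsets)), names(VITAL_FEATURES))
  if (length(bad) > 0L)
    stopf("unknown vital name(s): %s", paste(bad, collapse = ", "))
  summaries <- lapply(names(subsets), function(nm) {
    cols <- unlist(VITAL_FEATURES[subsets[[nm]]], use.names = FALSE)
    # same seed for every subset: identical fold partitions per repeat, so
    # subset comparisons are paired
    crossvalidate(dataset[, cols, drop = FALSE], dataset$label, k = k,
                  reps = reps, seed = seed, group = group)
  })
  names(summaries) <- names(subsets)
  tab <- do.call(rbind, lapply(names(subsets), function(nm) {
    s <- summaries[[nm]]
    sp <- specificity_at_sensitivity(s, c(0.6, 0.8))
    data.frame(features = nm, mean_auc = s$auc,
               auc_lo = s$auc_ci[1], auc_hi = s$auc_ci[2],
               spec_at_sens60 = 100 * sp[1], spec_at_sens80 = 100 * sp[2],
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  list(table = tab, summaries = summaries)
}
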