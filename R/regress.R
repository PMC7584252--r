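#' Probit transform of splicing ratios
#'
#' Maps ratios in \[0,1\] to the real line via `qnorm` after clipping into
#' `[eps, 1 - eps]` so boundary values stay finite. `NA` propagates.
#'
#' @param psi numeric vector in \[0,1\].
#' @param eps clipping bound in (0, 0.5).
#' @return numeric vector `y = qnorm(clip(psi))`.
#' @export
#' @examples
#' probit_transform(c(0.5, 0.841344746))  # ~ c(0, 1)
probit_transform <- function(psi, eps = 1e-6) {
  ok <- is.na(psi) | (psi >= 0 & psi <= 1)
  sf_assert(all(ok), "invalid_input", "psi values must lie in [0,1]")
  qnorm(clip_unit(psi, eps))
}

#' Differential splicing ratio on the probit scale
#'
#' `delta_y = qnorm(clip(psi_t)) - qnorm(clip(psi_c))`, elementwise with a
#' shared clipping bound; missing in either condition gives missing.
#'
#' @param psi_t,psi_c treatment and control splicing ratios, paired by
#'   position (equal length).
#' @param eps clipping bound.
#' @return numeric vector of probit differences.
#' @export
delta_response <- function(psi_t, psi_c, eps = 1e-6) {
  sf_assert(length(psi_t) == length(psi_c), "invalid_input",
            "psi_t and psi_c must be paired vectors of equal length")
  probit_transform(psi_t, eps) - probit_transform(psi_c, eps)
}

#' Fraction of variance explained on held-out data
#'
#' `FVE(y, yhat) = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`, the
#' coefficient of determination computed against the evaluation set's own
#' mean. Unlike in-sample R-squared it can be negative when the model
#' predicts worse than the test mean.
#'
#' @param y observed responses (length >= 2, non-constant).
#' @param y_hat predictions.
#' @return a single number <= 1.
#' @export
#' @examples
#' fve(c(0, 1, 2, 3), c(0.5, 1.5, 1.5, 2.5))  # 0.8
fve <- function(y, y_hat) {
  sf_assert(length(y) == length(y_hat) && length(y) >= 2, "invalid_input",
            "y and y_hat must have equal length >= 2")
  sf_assert(all(is.finite(y)) && all(is.finite(y_hat)), "invalid_input",
            "y and y_hat must be finite")
  ss_tot <- sum((y - mean(y))^2)
  sf_assert(ss_tot > 0, "undefined_fve", "FVE undefined for constant y")
  1 - sum((y - y_hat)^2) / ss_tot
}

#' Ridge regression with evidence-maximized regularization
#'
#' Fits `y = X w + e` under a Gaussian weight prior, estimating both the
#' weight precision (`lambda`) and noise precision (`alpha`) by iterative
#' maximization of the marginal likelihood (MacKay's fixed-point updates
#' on the SVD of the centred design). The effective ridge penalty is thus
#' chosen from the training data alone; the fit is deterministic.
#'
#' @param X numeric feature matrix (no missing values).
#' @param y numeric response (non-constant).
#' @param max_iter,tol fixed-point iteration controls.
#' @return object of class `ridge_evidence` with `coef`, `intercept`,
#'   `lambda`, `alpha`, `n_iter`; use `predict()` on new data.
#' @export
fit_linear <- function(X, y, max_iter = 300L, tol = 1e-8) {
  X <- as.matrix(X)
  sf_assert(nrow(X) == length(y), "invalid_input",
            "X and y must have matching rows")
  sf_assert(!anyNA(X) && !anyNA(y), "invalid_input",
            "fit_linear requires complete data (impute first)")
  sf_assert(stats::var(y) > 0, "degenerate_fit",
            "response has zero variance")
  x_center <- colMeans(X)
  Xc <- sweep(X, 2, x_center)
  y_mean <- mean(y)
  yc <- y - y_mean
  sv <- svd(Xc)
  d2 <- sv$d^2
  uty <- drop(crossprod(sv$u, yc))
  n <- length(y)

  alpha <- 1 / stats::var(yc)     # noise precision
  lambda <- 1                     # weight precision
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    k <- lambda / alpha
    shrink <- sv$d / (d2 + k)
    w_rot <- shrink * uty                      # coefficients in V basis
    gamma <- sum(d2 / (d2 + k))                # effective dof
    wtw <- sum(w_rot^2)
    fitted_rot <- sv$u %*% (sv$d * w_rot)
    rss <- sum((yc - fitted_rot)^2)
    lambda_new <- if (wtw > 0) gamma / wtw else lambda
    alpha_new <- max(n - gamma, 1e-12) / max(rss, 1e-300)
    moved <- abs(log(lambda_new / lambda)) + abs(log(alpha_new / alpha))
    lambda <- lambda_new
    alpha <- alpha_new
    if (moved < tol) break
  }
  k <- lambda / alpha
  w <- drop(sv$v %*% ((sv$d / (d2 + k)) * uty))
  structure(list(coef = stats::setNames(w, colnames(X)),
                 intercept = y_mean - sum(w * x_center),
                 lambda = lambda, alpha = alpha, n_iter = n_iter),
            class = "ridge_evidence")
}

#' @export
predict.ridge_evidence <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  drop(X %*% object$coef) + object$intercept
}

#' @export
print.ridge_evidence <- function(x, ...) {
  cat(sprintf(
    "evidence-maximized ridge: %d coefficients, penalty %.4g, %d iterations\n",
    length(x$coef), x$lambda / x$alpha, x$n_iter))
  invisible(x)
}

#' Random-forest regression
#'
#' Ensemble of regression trees on bootstrap samples with random feature
#' subsets (`mtry = max(1, floor(p / 3))`, the common regression default),
#' predictions averaged over trees. Thin deterministic wrapper around
#' `ranger` with a fixed seed and one thread.
#'
#' @param X numeric feature matrix (no missing values).
#' @param y numeric response.
#' @param n_trees number of trees (>= 1).
#' @param seed integer seed making the forest reproducible.
#' @return object of class `rf_model`; use `predict()` on new data.
#' @export
fit_random_forest <- function(X, y, n_trees = 100L, seed = 1L) {
  sf_assert(length(n_trees) == 1 && is.finite(n_trees) && n_trees >= 1,
            "invalid_config", "n_trees must be a positive integer")
  X <- as.matrix(X)
  sf_assert(!anyNA(X) && !anyNA(y), "invalid_input",
            "fit_random_forest requires complete data (impute first)")
  df <- as.data.frame(X)
  names(df) <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  df$.response <- y
  fit <- ranger::ranger(
    dependent.variable.name = ".response", data = df,
    num.trees = as.integer(n_trees),
    mtry = max(1L, floor(ncol(X) / 3)),
    seed = as.integer(seed), num.threads = 1L, verbose = FALSE)
  structure(list(fit = fit, feature_names = names(df)[-ncol(df)]),
            class = "rf_model")
}

#' @export
predict.rf_model <- function(object, newdata, ...) {
  df <- as.data.frame(as.matrix(newdata))
  names(df) <- object$feature_names
  predict(object$fit, data = df, num.threads = 1L)$predictions
}

#' Repeated-split FVE evaluation
#'
#' The core evaluation loop: `n_splits` independent random train/test
#' partitions (default 75/25). Per split, feature columns are imputed by
#' the training-split median and standardized by training-split mean/SD
#' (leakage-free), the model is fitted on the training part, and FVE is
#' computed on the held-out part. Events with missing response are dropped
#' up front; all-missing feature columns are dropped with a warning.
#'
#' @param X event x feature matrix or data.frame (may contain NAs).
#' @param y numeric response (probit-transformed splicing ratios or their
#'   differences).
#' @param model `"linear_reg"` (evidence-maximized ridge) or
#'   `"random_forest"`.
#' @param n_splits number of repeated splits (default 5).
#' @param test_fraction held-out fraction per split (default 0.25).
#' @param seed integer seed; split assignments and forests derive from it.
#' @param feature_set label stored in the result.
#' @param n_trees forest size when `model = "random_forest"`.
#' @return object of class `fve_result`: list with `model`, `feature_set`,
#'   `per_split_fve`, `mean_fve`, `n_events_used`, `seed`.
#' @export
evaluate_fve <- function(X, y, model = c("linear_reg", "random_forest"),
                         n_splits = 5L, test_fraction = 0.25, seed = 1L,
                         feature_set = "features", n_trees = 100L) {
  model <- match.arg(model)
  X <- as.matrix(X)
  sf_assert(nrow(X) == length(y), "invalid_input",
            "X rows and y length must match")
  sf_assert(test_fraction > 0 && test_fraction < 1, "invalid_input",
            "test_fraction must be in (0,1)")
  keep <- !is.na(y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  all_na <- apply(X, 2, function(cl) all(is.na(cl)))
  if (any(all_na)) {
    warning(sprintf("dropping %d all-missing feature column(s)",
                    sum(all_na)), call. = FALSE)
    X <- X[, !all_na, drop = FALSE]
  }
  n <- length(y)
  sf_assert(n >= 20, "insufficient_data",
            "need at least 20 events with non-missing response, got %d", n)
  sf_assert(ncol(X) >= 1, "invalid_input", "no usable feature columns")

  set.seed(derive_seed(seed, "splits"))
  split_seeds <- sample.int(2147483646L, n_splits)
  per_split <- rep(NA_real_, n_splits)
  for (s in seq_len(n_splits)) {
    set.seed(split_seeds[s])
    n_test <- max(1L, round(n * test_fraction))
    test_idx <- sample.int(n, n_test)
    tr_X <- X[-test_idx, , drop = FALSE]
    te_X <- X[test_idx, , drop = FALSE]
    tr_y <- y[-test_idx]
    te_y <- y[test_idx]
    if (stats::var(te_y) == 0) {
      warning(sprintf("split %d has constant test response; FVE recorded missing", s),
              call. = FALSE)
      next
    }
    # training-only imputation and standardization
    med <- apply(tr_X, 2, stats::median, na.rm = TRUE)
    med[!is.finite(med)] <- 0
    for (j in seq_len(ncol(tr_X))) {
      tr_X[is.na(tr_X[, j]), j] <- med[j]
      te_X[is.na(te_X[, j]), j] <- med[j]
    }
    mu <- colMeans(tr_X)
    sg <- apply(tr_X, 2, stats::sd)
    sg[sg == 0 | !is.finite(sg)] <- 1
    tr_X <- sweep(sweep(tr_X, 2, mu), 2, sg, "/")
    te_X <- sweep(sweep(te_X, 2, mu), 2, sg, "/")
    fit <- if (model == "linear_reg") fit_linear(tr_X, tr_y)
           else fit_random_forest(tr_X, tr_y, n_trees = n_trees,
                                  seed = split_seeds[s])
    per_split[s] <- fve(te_y, predict(fit, te_X))
  }
  structure(list(model = model, feature_set = feature_set,
                 per_split_fve = per_split,
                 mean_fve = mean(per_split, na.rm = TRUE),
                 n_events_used = n, n_splits = n_splits,
                 seed = as.integer(seed)),
            class = "fve_result")
}

#' @export
print.fve_result <- function(x, ...) {
  cat(sprintf("FVE [%s | %s]: mean %.3f over %d splits (n = %d)\n  splits: %s\n",
              x$model, x$feature_set, x$mean_fve, x$n_splits,
              x$n_events_used,
              paste(sprintf("%.3f", x$per_split_fve), collapse = " ")))
  invisible(x)
}

#' @export
as.data.frame.fve_result <- function(x, ...) {
  data.frame(model = x$model, feature_set = x$feature_set,
             split = seq_len(x$n_splits), fve = x$per_split_fve,
             mean_fve = x$mean_fve, n = x$n_events_used, seed = x$seed)
}

#' Pearson correlation between splicing and methylation changes
#'
#' Pearson r with a two-sided p-value from the t distribution on n - 2
#' degrees of freedom; pairs with a missing value in either vector are
#' dropped and the number used is reported.
#'
#' @param delta_psi per-event change in splicing ratio (or its probit
#'   transform).
#' @param delta_meth per-event change in a methylation feature.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_delta_correlation <- function(delta_psi, delta_meth) {
  sf_assert(length(delta_psi) == length(delta_meth), "invalid_input",
            "delta_psi and delta_meth must be paired vectors")
  ok <- stats::complete.cases(delta_psi, delta_meth)
  sf_assert(sum(ok) >= 3, "insufficient_data",
            "need at least 3 complete pairs, got %d", sum(ok))
  ct <- stats::cor.test(delta_psi[ok], delta_meth[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
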