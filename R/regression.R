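#' Configuration of the regression refinement
#'
#' Defaults follow the refinement procedure the package implements: a
#' ten-fold outer Monte Carlo cross-validation holding out 20% of samples,
#' a six-fold inner cross-validation for the penalty strength, a mixing
#' grid from 0 to 1 in steps of 0.01, a pseudo-count of 1 before the log
#' transform, and a model q-value gate of 0.05.
#'
#' @param outer_folds Number of outer Monte Carlo repetitions.
#' @param test_fraction Held-out fraction per outer repetition.
#' @param inner_folds Inner cross-validation folds for the penalty.
#' @param alpha_grid Grid of mixing values (printed-convention alpha: the
#'   weight of the ridge term; see [fit_elastic_net_mc_cv()]).
#' @param pseudo_count Added before the log transform.
#' @param q_threshold Model-level q-value gate.
#' @param seed Master seed for all splits.
#' @return An object of class \code{reg_config}.
#' @export
reg_config <- function(outer_folds = 10, test_fraction = 0.2,
                       inner_folds = 6, alpha_grid = seq(0, 1, by = 0.01),
                       pseudo_count = 1, q_threshold = 0.05, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1,
            all(alpha_grid >= 0), all(alpha_grid <= 1))
  structure(list(outer_folds = outer_folds, test_fraction = test_fraction,
                 inner_folds = inner_folds, alpha_grid = alpha_grid,
                 pseudo_count = pseudo_count, q_threshold = q_threshold,
                 seed = as.integer(seed)),
            class = "reg_config")
}

#' Log-transform, centre and scale features
#'
#' Applies \code{log(v + pseudo_count)} elementwise, then standardises each
#' column to mean 0 and unit standard deviation. Columns with zero standard
#' deviation are dropped with a warning (their indices are recorded).
#' Centre/scale parameters may be supplied, e.g. estimated on training
#' samples and applied to held-out samples.
#'
#' @param X Non-negative matrix (or vector, treated as one column).
#' @param pseudo_count Pseudo-count (default 1).
#' @param center,scale Optional precomputed column parameters.
#' @return List with \code{X} (transformed), \code{center}, \code{scale},
#'   \code{kept} (column indices retained).
#' @export
transform_features <- function(X, pseudo_count = 1, center = NULL,
                               scale = NULL) {
  vec <- is.null(dim(X))
  X <- as.matrix(X)
  if (any(X < 0)) stop("negative values: expected non-negative signal/expression")
  L <- log(X + pseudo_count)
  if (is.null(center)) {
    center <- colMeans(L)
    scale <- apply(L, 2, stats::sd)
    kept <- which(scale > 1e-12)
    if (length(kept) < ncol(L))
      warning(sprintf("dropping %d constant column(s) after log transform",
                      ncol(L) - length(kept)))
  } else {
    kept <- which(scale > 1e-12)
  }
  Xs <- sweep(sweep(L[, kept, drop = FALSE], 2, center[kept], "-"),
              2, scale[kept], "/")
  if (vec) Xs <- drop(Xs)
  list(X = Xs, center = center, scale = scale, kept = kept)
}

# The penalty is written internally in the printed convention
#   lambda * (alpha * ||b||^2 + (1 - alpha) * ||b||_1),
# i.e. alpha weights the ridge (squared) term. glmnet's mixing parameter
# weights the L1 term, so the bridge is alpha_glmnet = 1 - alpha (the 1/2
# on glmnet's ridge term is absorbed by the lambda grid).
alpha_to_glmnet <- function(alpha) 1 - alpha

cv_pick_alpha <- function(Xtr, ytr, cfg, foldid) {
  best <- NULL
  pad <- ncol(Xtr) == 1
  Xfit <- if (pad) cbind(Xtr, 0) else Xtr
  for (a in cfg$alpha_grid) {
    # tiny inner folds make cv.glmnet fall back to ungrouped error curves;
    # that fallback is fine here and its warning would swamp small runs
    cvfit <- withCallingHandlers(
      glmnet::cv.glmnet(Xfit, ytr, alpha = alpha_to_glmnet(a),
                        foldid = foldid, standardize = FALSE,
                        type.measure = "mse"),
      warning = function(w) {
        if (grepl("grouped=FALSE enforced", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    cvm <- min(cvfit$cvm)
    if (is.null(best) || cvm < best$cvm) {
      best <- list(cvm = cvm, alpha = a, fit = cvfit)
    }
  }
  best$pad <- pad
  best
}

#' Elastic-net refinement by Monte Carlo cross-validation
#'
#' Fits, for each of \code{outer_folds} seeded random 80/20 splits, an
#' elastic net predicting (transformed) expression from (transformed)
#' candidate signals. On each training part the mixing parameter alpha and
#' the penalty strength lambda are selected by an inner
#' \code{inner_folds}-fold cross-validation minimising mean squared error
#' (the lambda.min rule); performance is then evaluated on the held-out 20%
#' as Pearson and Spearman correlation and MSE between predicted and
#' measured expression.
#'
#' The mixing parameter follows the convention in which alpha weights the
#' squared (ridge) penalty and \eqn{1 - \alpha} the lasso penalty — the
#' reverse of glmnet's parameterisation; the mapping is applied internally
#' (see the methods vignette). Centring and scaling parameters are
#' estimated on the training samples only and applied to the held-out
#' samples.
#'
#' The model p-value fed into the across-gene correction is the p-value of
#' the Pearson correlation between held-out predictions and observations
#' pooled (concatenated) over the outer folds.
#'
#' @param X m x k matrix of raw (untransformed) candidate signals.
#' @param y Raw expression values.
#' @param cfg A [reg_config()].
#' @return Object of class \code{elastic_net_model}: per-fold table
#'   (alpha, lambda, test r, test rho, test MSE), coefficient matrix
#'   (folds x candidates), per-candidate median coefficients, mean test
#'   performance, pooled-correlation model p-value.
#' @export
fit_elastic_net_mc_cv <- function(X, y, cfg = reg_config()) {
  X <- as.matrix(X)
  m <- nrow(X)
  if (ncol(X) < 1) stop("no candidate features to refine")
  n_test <- max(1, round(cfg$test_fraction * m))
  if (m - n_test < cfg$inner_folds + 2)
    stop(sprintf(paste0("too few samples (%d) for %d inner folds on the ",
                        "training part; reduce inner_folds or provide more ",
                        "paired samples"), m, cfg$inner_folds))
  set.seed(cfg$seed)
  folds <- data.frame(alpha = numeric(0), lambda = numeric(0),
                      test_r = numeric(0), test_rho = numeric(0),
                      test_mse = numeric(0))
  coefs <- matrix(NA_real_, cfg$outer_folds, ncol(X))
  colnames(coefs) <- colnames(X)
  pooled_pred <- pooled_obs <- numeric(0)

  for (f in seq_len(cfg$outer_folds)) {
    test_idx <- sample(m, n_test)
    train_idx <- setdiff(seq_len(m), test_idx)
    tx <- transform_features(X[train_idx, , drop = FALSE], cfg$pseudo_count)
    ty <- transform_features(y[train_idx], cfg$pseudo_count)
    Xtr <- as.matrix(tx$X); ytr <- as.numeric(ty$X)
    beta_full <- numeric(ncol(X))
    if (ncol(Xtr) >= 1 && stats::sd(ytr) > 0) {
      foldid <- sample(rep(seq_len(cfg$inner_folds),
                           length.out = length(train_idx)))
      pick <- cv_pick_alpha(Xtr, ytr, cfg, foldid)
      b <- as.numeric(stats::coef(pick$fit, s = "lambda.min"))[-1]
      if (pick$pad) b <- b[1]
      beta_full[tx$kept] <- b
      Xte <- transform_features(X[test_idx, , drop = FALSE], cfg$pseudo_count,
                                center = tx$center, scale = tx$scale)$X
      yte <- transform_features(y[test_idx], cfg$pseudo_count,
                                center = ty$center, scale = ty$scale)$X
      Xte_fit <- if (pick$pad) cbind(as.matrix(Xte), 0) else as.matrix(Xte)
      pred <- as.numeric(stats::predict(pick$fit, newx = Xte_fit,
                                        s = "lambda.min"))
      r <- if (stats::sd(pred) > 0) stats::cor(pred, yte) else NA_real_
      rho <- if (stats::sd(pred) > 0)
        suppressWarnings(stats::cor(pred, yte, method = "spearman")) else NA_real_
      mse <- mean((pred - yte)^2)
      folds[f, ] <- c(pick$alpha, pick$fit$lambda.min, r, rho, mse)
      pooled_pred <- c(pooled_pred, pred)
      pooled_obs <- c(pooled_obs, as.numeric(yte))
    } else {
      folds[f, ] <- c(NA, NA, NA, NA, NA)
    }
    coefs[f, ] <- beta_full
  }

  model_p <- if (length(pooled_pred) > 3 && stats::sd(pooled_pred) > 0)
    stats::cor.test(pooled_pred, pooled_obs)$p.value else 1
  structure(list(
    folds = folds,
    coefficients = coefs,
    median_coefficients = apply(coefs, 2, stats::median, na.rm = TRUE),
    mean_test_r = mean(folds$test_r, na.rm = TRUE),
    mean_test_rho = mean(folds$test_rho, na.rm = TRUE),
    mean_test_mse = mean(folds$test_mse, na.rm = TRUE),
    model_p = model_p,
    n_train = m - n_test),
    class = "elastic_net_model")
}

#' Candidates with non-zero median coefficient
#'
#' A candidate enters the refined set when the median of its coefficients
#' across the outer folds is non-zero (absolute value above \code{tol}).
#' The number of retained features is capped at the number of training
#' samples (by decreasing absolute median coefficient), matching the
#' feature-count bound inherent to the regression.
#'
#' @param model An \code{elastic_net_model}.
#' @param tol Numerical zero (default 1e-12).
#' @return Integer indices into the candidate columns.
#' @export
median_nonzero <- function(model, tol = 1e-12) {
  med <- model$median_coefficients
  idx <- which(abs(med) > tol)
  if (length(idx) > model$n_train) {
    idx <- idx[order(abs(med[idx]), decreasing = TRUE)][seq_len(model$n_train)]
    idx <- sort(idx)
  }
  idx
}

#' Benjamini-Yekutieli correction
#'
#' Adjusts p-values controlling the false discovery rate under arbitrary
#' dependence between tests (the harmonic-sum-inflated step-up procedure).
#'
#' @param p Vector of p-values.
#' @return Vector of q-values.
#' @export
by_correction <- function(p) {
  stats::p.adjust(p, method = "BY")
}

#' Ordinary least squares on the refined candidates
#'
#' Fits an unpenalised linear model of transformed expression on the
#' transformed refined candidate signals (with intercept) and reports per
#' feature the coefficient and its two-sided t-test p-value. Regularisation
#' bias is absent, so these coefficients are comparable across genes; they
#' are the quantities attached to the final element records. The OLS fit is
#' never used to judge model performance — that is the role of the held-out
#' Monte Carlo evaluation. Collinear columns are pruned (reported in
#' \code{dropped}).
#'
#' @param X_nz m x q matrix of raw signals of the refined candidates.
#' @param y Raw expression.
#' @param pseudo_count Pseudo-count for the log transform.
#' @return List with \code{coefficients}, \code{pvalues} (both named by
#'   column, intercept excluded), \code{dropped} (indices pruned as
#'   collinear or constant).
#' @export
fit_ols <- function(X_nz, y, pseudo_count = 1) {
  X_nz <- as.matrix(X_nz)
  if (is.null(colnames(X_nz)))
    colnames(X_nz) <- paste0("f", seq_len(ncol(X_nz)))
  if (ncol(X_nz) >= nrow(X_nz))
    stop("more features than samples: OLS is not identifiable")
  tx <- transform_features(X_nz, pseudo_count)
  ty <- transform_features(y, pseudo_count)
  Xs <- as.matrix(tx$X)
  fit <- stats::lm(ty$X ~ Xs)
  cf <- summary(fit)$coefficients
  beta <- stats::coef(fit)[-1]
  aliased <- which(is.na(beta))
  out_coef <- setNames(rep(NA_real_, ncol(X_nz)), colnames(X_nz))
  out_p <- out_coef
  est <- setNames(cf[-1, "Estimate"], sub("^Xs", "", rownames(cf)[-1]))
  pv <- setNames(cf[-1, "Pr(>|t|)"], sub("^Xs", "", rownames(cf)[-1]))
  kept_names <- colnames(Xs)[!is.na(beta)]
  out_coef[kept_names] <- est[kept_names]
  out_p[kept_names] <- pv[kept_names]
  dropped <- setdiff(seq_len(ncol(X_nz)),
                     tx$kept[!is.na(beta)])
  list(coefficients = out_coef, pvalues = out_p, dropped = dropped)
}
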