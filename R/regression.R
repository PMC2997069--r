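#' Ordinary least squares fit of methylation on a CM profile
#'
#' Fits the multiple linear regression
#' \deqn{M_i = \beta_0 + \sum_j \beta_j CM_{ij} + \epsilon_i}
#' of the methylation column on all feature columns of the profile, with an
#' intercept.  Per-coefficient standard errors and two-sided t-test p-values
#' against \eqn{\beta_j = 0} use the full-model residual degrees of freedom
#' `N - f - 1`.
#'
#' @param profile A [cm_profile()].
#' @param features Optional character vector of features to regress on
#'   (default: all).
#' @return An object of class `cm_regression` with fields `intercept`,
#'   `coefficients`, `std_errors`, `t_stats`, `p_values` (all named by
#'   feature), `df`, `sigma`, `in_sample_pcc`, and placeholders `cv_pcc` /
#'   `fold_pccs` filled by [cross_validate()].
#' @export
fit_ols <- function(profile, features = NULL) {
  validate_profile(profile)
  X <- profile_matrix(profile, features)
  y <- profile$methylation
  n <- nrow(X)
  f <- ncol(X)
  if (n <= f + 1L) stop("need N > f + 1 loci (N = ", n, ", f = ", f, ")")
  const <- colnames(X)[apply(X, 2L, function(v) max(v) - min(v) == 0)]
  if (length(const)) {
    stop("rank-deficient design: constant column(s) ",
         paste(const, collapse = ", "))
  }
  fit <- lm(y ~ X)
  if (anyNA(coef(fit))) {
    alias <- sub("^X", "", names(coef(fit))[is.na(coef(fit))])
    stop("rank-deficient design: aliased column(s) ",
         paste(alias, collapse = ", "))
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  feats <- colnames(X)
  rownames(ct) <- c("(Intercept)", feats)  # coefficient order = column order
  structure(list(
    intercept = unname(ct["(Intercept)", 1L]),
    coefficients = setNames(ct[feats, 1L], feats),
    std_errors = setNames(ct[feats, 2L], feats),
    t_stats = setNames(ct[feats, 3L], feats),
    p_values = setNames(ct[feats, 4L], feats),
    df = fit$df.residual,
    sigma = sm$sigma,
    in_sample_pcc = if (sd(fit$fitted.values) > 0 && sd(y) > 0) {
      cor(fit$fitted.values, y)
    } else NA_real_,
    feature_names = feats,
    cv_pcc = NA_real_,
    fold_pccs = NULL
  ), class = "cm_regression")
}

#' @export
print.cm_regression <- function(x, ...) {
  cat(sprintf("cm_regression: %d feature(s), residual df %d\n",
              length(x$coefficients), x$df))
  df <- regression_report(x)
  print(format(df, digits = 4), row.names = FALSE)
  if (!is.na(x$cv_pcc)) cat(sprintf("cross-validated Pcc: %.4f\n", x$cv_pcc))
  invisible(x)
}

#' Tabular model report
#'
#' @param r A `cm_regression`.
#' @return Data frame with columns feature, coefficient, std_error, t, p.
#' @export
regression_report <- function(r) {
  data.frame(feature = r$feature_names,
             coefficient = unname(r$coefficients),
             std_error = unname(r$std_errors),
             t = unname(r$t_stats),
             p = unname(r$p_values))
}

# Fast OLS coefficients for CV/permutation loops (no inference needed).
ols_coef <- function(X, y) {
  fit <- .lm.fit(cbind(1, X), y)
  fit$coefficients
}

#' 10-fold cross-validated Pearson correlation
#'
#' Loci are partitioned into `folds` disjoint subsets by a seeded shuffle.
#' For each fold the model is trained on the remaining folds and the Pearson
#' correlation between predicted and measured methylation is computed on the
#' held-out fold.  The summary `cv_pcc` is the arithmetic mean of the
#' per-fold correlations (not a pooled-prediction correlation).
#'
#' @param profile A [cm_profile()].
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param features Optional feature subset.
#' @return List with `cv_pcc` and `fold_pccs`.
#' @export
cross_validate <- function(profile, folds = 10L, seed = 1L, features = NULL) {
  validate_profile(profile)
  X <- profile_matrix(profile, features)
  y <- profile$methylation
  n <- nrow(X)
  if (n < folds) stop("need at least as many loci as folds")
  assign <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  if (min(tabulate(assign, folds)) < 3L) {
    stop("a fold has fewer than 3 loci; correlation undefined")
  }
  fold_pccs <- vapply(seq_len(folds), function(k) {
    test <- assign == k
    b <- ols_coef(X[!test, , drop = FALSE], y[!test])
    pred <- drop(cbind(1, X[test, , drop = FALSE]) %*% b)
    if (sd(pred) == 0 || sd(y[test]) == 0) return(0)
    cor(pred, y[test])
  }, numeric(1))
  list(cv_pcc = mean(fold_pccs), fold_pccs = fold_pccs)
}

#' Select informative features by t-test
#'
#' Keeps features whose two-sided regression t-test p-value is strictly
#' below `alpha` (default 0.001).
#'
#' @param r A `cm_regression` from [fit_ols()].
#' @param alpha Significance threshold.
#' @return List of class `cm_selection` with `selected` (feature names) and
#'   `alpha`.
#' @export
select_features <- function(r, alpha = 0.001) {
  stopifnot(inherits(r, "cm_regression"))
  structure(list(selected = names(r$p_values)[r$p_values < alpha],
                 alpha = alpha),
            class = "cm_selection")
}

#' @export
print.cm_selection <- function(x, ...) {
  cat(sprintf("cm_selection: %d feature(s) at p < %g\n",
              length(x$selected), x$alpha))
  if (length(x$selected)) cat(" ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Permutation empirical p-value for the cross-validated model
#'
#' Permutes the methylation column `n_perm` times (seeded), recomputes the
#' cross-validated Pearson correlation for each permutation, and returns
#' the add-one empirical p-value
#' `(1 + #\{cv_pcc_perm >= cv_pcc_obs\}) / (1 + n_perm)`.
#'
#' @param profile A [cm_profile()].
#' @param n_perm Number of permutations (>= 1).  The default of 10000 is a
#'   desk-scale compromise; larger counts sharpen the attainable minimum
#'   p-value `1 / (n_perm + 1)`.
#' @param seed Integer seed driving both the fold split and the
#'   permutations.
#' @param folds CV folds (default 10).
#' @param features Optional feature subset.
#' @return List with `p_value`, `observed` (cv_pcc) and `perm_pccs`.
#' @export
permutation_pvalue <- function(profile, n_perm = 10000L, seed = 1L,
                               folds = 10L, features = NULL) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  validate_profile(profile)
  obs <- cross_validate(profile, folds = folds, seed = seed,
                        features = features)$cv_pcc
  n <- length(profile$methylation)
  perm_pccs <- with_seed(derive_seed(seed, 1L), vapply(seq_len(n_perm),
    function(i) {
      pp <- profile
      pp$methylation <- profile$methylation[sample.int(n)]
      cross_validate(pp, folds = folds, seed = seed,
                     features = features)$cv_pcc
    }, numeric(1)))
  list(p_value = (1 + sum(perm_pccs >= obs)) / (1 + n_perm),
       observed = obs, perm_pccs = perm_pccs)
}

#' Predict methylation from a fitted model
#'
#' Linear predictor `beta_0 + sum_j b_j x_j` per locus.  Predictions are
#' deliberately not clamped to \[0,1\]; clamp explicitly if a methylation
#' scale is required.
#'
#' @param object A `cm_regression`.
#' @param profile A [cm_profile()] whose features include the model's.
#' @param ... Unused.
#' @return Numeric vector of predictions, one per locus.
#' @export
predict.cm_regression <- function(object, profile, ...) {
  validate_profile(profile)
  miss <- setdiff(object$feature_names, profile$feature_names)
  if (length(miss)) {
    stop("profile is missing model feature(s): ", paste(miss, collapse = ", "))
  }
  X <- profile_matrix(profile, object$feature_names)
  drop(object$intercept + X %*% object$coefficients)
}

#' Fit, select, and refit: the feature-reduced model
#'
#' Convenience wrapper for the standard sequence: fit the full model,
#' select features at `alpha`, refit on the selected features only (the
#' feature-reduced model), and cross-validate the reduced fit.
#'
#' @param profile A [cm_profile()].
#' @param alpha Selection threshold (default 0.001).
#' @param folds CV folds.
#' @param seed Integer seed for the CV fold split.
#' @return List with `full` (full-model `cm_regression`), `selection`,
#'   `reduced` (`cm_regression` on selected features, with `cv_pcc` and
#'   `fold_pccs` filled in), or `reduced = NULL` when nothing is selected.
#' @export
feature_reduced_model <- function(profile, alpha = 0.001, folds = 10L,
                                  seed = 1L) {
  full <- fit_ols(profile)
  sel <- select_features(full, alpha = alpha)
  reduced <- NULL
  if (length(sel$selected)) {
    reduced <- fit_ols(profile, features = sel$selected)
    cv <- cross_validate(profile, folds = folds, seed = seed,
                         features = sel$selected)
    reduced$cv_pcc <- cv$cv_pcc
    reduced$fold_pccs <- cv$fold_pccs
  }
  list(full = full, selection = sel, reduced = reduced)
}
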