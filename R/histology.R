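# Histology-predictive validation: rank-based AUC, an L1-penalized
# multi-gene classifier with cross-validated AUC, Monte-Carlo significance
# against random signatures/genes, and the regional-amplification test
# used for external-cohort style validation.

#' Rank-based AUC (Mann-Whitney)
#'
#' Probability that a randomly chosen positive outscores a randomly chosen
#' negative, with ties counted 0.5: `U / (n1 * n0)` from midranks.
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1, logical, or a two-level factor whose
#'   second level is the positive class).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("undefined AUC: both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) {
    if (nlevels(droplevels(labels)) > 2) stop("labels must be binary")
    return(as.integer(labels == levels(droplevels(labels))[2]))
  }
  u <- sort(unique(labels))
  if (length(u) > 2) stop("labels must be binary")
  as.integer(labels == u[length(u)])
}

# Stratified fold assignment, seeded; returns integer folds per subject.
stratified_folds <- function(labels, k, seed = NULL) {
  y <- as_binary_labels(labels)
  with_seed(seed, {
    folds <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
    folds
  })
}

# Pick the lambda index on a glmnet path whose active set matches `size`;
# among exact matches take the largest lambda, otherwise the nearest
# attainable set size. Returns list(index, size, exact).
lambda_index_for_size <- function(fit, size) {
  df <- fit$df
  hit <- which(df == size)
  if (length(hit) > 0) return(list(index = hit[1], size = size, exact = TRUE))
  best <- which.min(abs(df - size))
  list(index = best, size = df[best], exact = FALSE)
}

# Out-of-fold linear predictor from fold-wise L1 logistic fits at the
# signature size, pooled over folds. Scores are standardized within each
# held-out fold (a monotone within-fold transform) so that fold-specific
# scale and offset of the fitted models do not leak rank structure into
# the pooled AUC.
cv_l1_scores <- function(x, y, folds, size) {
  scores <- numeric(length(y))
  exact <- TRUE
  for (f in sort(unique(folds))) {
    tr <- folds != f
    fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr], family = "binomial",
                          nlambda = 50, lambda.min.ratio = 0.01)
    sel <- lambda_index_for_size(fit, min(size, ncol(x)))
    exact <- exact && sel$exact
    s <- as.numeric(
      stats::predict(fit, x[!tr, , drop = FALSE],
                     s = fit$lambda[sel$index], type = "link"))
    if (stats::sd(s) > 0) s <- (s - mean(s)) / stats::sd(s)
    scores[!tr] <- s
  }
  list(scores = scores, exact = exact)
}

#' L1-penalized expression signature with cross-validated AUC
#'
#' Per training fold an L1-penalized logistic regression path is fit and
#' the regularization chosen so the active set has `signature_size`
#' features; the reported AUC pools out-of-fold linear predictors across
#' stratified folds. The returned signature is the active set of the
#' full-data fit at the matched size (nearest attainable size, flagged,
#' when the path never visits the exact size).
#'
#' @param expr feature x subject matrix.
#' @param labels binary histology labels (named or aligned with columns).
#' @param signature_size requested number of signature genes.
#' @param cv_folds number of stratified folds.
#' @param seed integer seed (fold assignment).
#' @return list with `signature`, `cv_auc`, `fold_assignments`,
#'   `size_exact`, `seed`.
#' @export
l1_signature <- function(expr, labels, signature_size = 15L, cv_folds = 10L,
                         seed = 1L) {
  x <- t(expr)
  y <- as_binary_labels(labels)
  if (min(table(y)) < cv_folds * 2)
    cv_folds <- max(2L, min(cv_folds, floor(min(table(y)) / 2)))
  folds <- stratified_folds(y, cv_folds, seed = derive_seed(seed, "folds"))
  cv <- cv_l1_scores(x, y, folds, signature_size)
  fit <- glmnet::glmnet(x, y, family = "binomial", nlambda = 50)
  sel <- lambda_index_for_size(fit, min(signature_size, ncol(x)))
  beta <- stats::coef(fit, s = fit$lambda[sel$index])[-1, 1]
  sig <- names(beta)[beta != 0]
  list(signature = sig, cv_auc = auc(cv$scores, y),
       fold_assignments = stats::setNames(folds, colnames(expr)),
       size_exact = cv$exact && sel$exact, seed = seed)
}

#' Monte-Carlo significance of a signature's AUC against random signatures
#'
#' Draws `n_draws` random feature sets of the same size, scores each with
#' the same cross-validated classifier protocol as [l1_signature()]
#' restricted to the drawn features, and reports the add-one permutation
#' p-value `(1 + #\{null >= observed\}) / (n_draws + 1)` together with the
#' null AUC distribution.
#'
#' @param expr feature x subject matrix (must have more features than
#'   `signature_size`).
#' @param labels binary labels.
#' @param signature_size features per random signature.
#' @param n_draws number of random signatures (>= 1).
#' @param seed integer seed.
#' @param observed_auc the observed signature's cross-validated AUC.
#' @param cv_folds folds for the per-draw classifier.
#' @return list with `observed_auc`, `null_aucs`, `null_median`,
#'   `p_value`, `n_draws`.
#' @export
monte_carlo_signature_pvalue <- function(expr, labels, signature_size = 15L,
                                         n_draws = 1000L, seed = 1L,
                                         observed_auc, cv_folds = 10L) {
  if (n_draws < 1) stop("configuration error: n_draws must be >= 1")
  if (nrow(expr) <= signature_size)
    stop("expr must have more features than signature_size")
  x <- t(expr)
  y <- as_binary_labels(labels)
  if (min(table(y)) < cv_folds * 2)
    cv_folds <- max(2L, min(cv_folds, floor(min(table(y)) / 2)))
  folds <- stratified_folds(y, cv_folds, seed = derive_seed(seed, "mc_folds"))
  null_aucs <- with_seed(derive_seed(seed, "mc_draws"), {
    vapply(seq_len(n_draws), function(b) {
      feat <- sample(nrow(expr), signature_size)
      cv <- cv_l1_scores(x[, feat, drop = FALSE], y, folds, signature_size)
      auc(cv$scores, y)
    }, 0)
  })
  p <- (1 + sum(null_aucs >= observed_auc)) / (n_draws + 1)
  list(observed_auc = observed_auc, null_aucs = null_aucs,
       null_median = stats::median(null_aucs), p_value = p,
       n_draws = n_draws)
}

#' Monte-Carlo AUC test for a single feature against random features
#'
#' Compares the feature's AUC with the AUCs of randomly drawn features
#' from the same matrix. By default departures are folded
#' (`max(a, 1 - a)`) so an AUC of 0.1 is as extreme as 0.9; set
#' `folded = FALSE` for the one-sided (greater) version.
#'
#' @param expr feature x subject matrix serving as the null pool.
#' @param feature row id (or index) of the feature under test.
#' @param labels binary labels.
#' @param n_draws number of random features.
#' @param seed integer seed.
#' @param folded fold AUC departures around 0.5.
#' @return list with `auc`, `p_value`, `n_draws`.
#' @export
single_feature_auc_test <- function(expr, feature, labels, n_draws = 1000L,
                                    seed = 1L, folded = TRUE) {
  x <- expr[feature, ]
  if (stats::sd(x) == 0)
    stop("undefined AUC: constant feature")
  y <- as_binary_labels(labels)
  stat <- function(a) if (folded) max(a, 1 - a) else a
  obs <- auc(x, y)
  null <- with_seed(derive_seed(seed, "single_feature"), {
    rows <- sample(nrow(expr), n_draws, replace = TRUE)
    vapply(rows, function(r) {
      xr <- expr[r, ]
      if (stats::sd(xr) == 0) return(0.5)
      stat(auc(xr, y))
    }, 0)
  })
  p <- (1 + sum(null >= stat(obs))) / (n_draws + 1)
  list(auc = obs, p_value = p, n_draws = n_draws)
}

#' Regional amplification test on probe intensities
#'
#' One-sided one-sample t-test of the probes in a window (e.g. the 500 kb
#' region around a driver) against the standardized global mean 0; the
#' region is amplified when the p-value falls below `p_threshold`.
#'
#' @param probe_intensities standardized log-ratio intensities in the
#'   window (>= 2 probes).
#' @param global_mean reference mean (0 after standardization).
#' @param p_threshold significance threshold.
#' @return list with `mean`, `p_value`, `amplified`.
#' @export
regional_amplification_test <- function(probe_intensities, global_mean = 0,
                                        p_threshold = 0.001) {
  x <- probe_intensities
  if (length(x) < 2) stop("insufficient data: need at least 2 probes")
  if (stats::sd(x) < 1e-15) {
    m <- mean(x)
    p <- if (abs(m - global_mean) < 1e-15) 0.5 else if (m > global_mean) 0 else 1
  } else {
    tt <- stats::t.test(x, mu = global_mean, alternative = "greater")
    p <- tt$p.value
  }
  list(mean = mean(x), p_value = p, amplified = p < p_threshold)
}
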