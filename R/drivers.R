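# Driver-gene search: candidate filters, correlation modules, sparse CCA
# refinement and final ranking.
#
# The search proceeds in three steps. Step 1 (elsewhere): recurrent CNA
# regions; features inside pure regions are candidate drivers. Step 2:
# candidates are filtered on expression variability, a one-sided Welch test
# against copy-neutral subjects, fold change and sign consistency; each
# remaining gene becomes a candidate target grouped with its most
# correlated driver at p < 0.001. Step 3: each module is refined by sparse
# canonical correlation, dropping targets with zero canonical weight, and
# drivers are ranked by refined module size.

#' Keep features whose expression varies across subjects
#'
#' @param expr feature x subject matrix of log2 ratios.
#' @param sd_threshold minimum sample standard deviation; features strictly
#'   below it are removed.
#' @return character vector of retained feature ids.
#' @export
filter_variable_features <- function(expr, sd_threshold = 0.25) {
  rownames(expr)[row_sds(expr) >= sd_threshold]
}

#' Copy-number / expression consistency filter for one candidate driver
#'
#' One-sided Welch t-test of altered vs copy-neutral subjects in the
#' direction of the region polarity, a linear-scale fold-change condition
#' (`2^(mean log2 difference)`, > `min_fold_change` for amplifications and
#' < `1/min_fold_change` for deletions; skipped when `min_fold_change` is
#' `NULL`, the miRNA regime), and a sign-consistency rule: at least
#' `consistency_min` of altered subjects must have log2 expression of the
#' polarity's sign.
#'
#' @param expr_row named expression vector for the candidate.
#' @param altered_subjects ids of subjects altered in the candidate's
#'   region (with matching polarity).
#' @param polarity `"amplification"`/`"amp_only"` or
#'   `"deletion"`/`"del_only"`.
#' @param p_max Welch p-value threshold (0.05 genes, 0.01 miRNAs).
#' @param min_fold_change linear fold-change threshold, or NULL to skip.
#' @param consistency_min required concordant fraction of altered subjects.
#' @return list with `retained` plus the candidate statistics
#'   (`fold_change`, `welch_p`, `consistency_fraction`) or a `reason` code.
#' @export
cna_expression_filter <- function(expr_row, altered_subjects,
                                  polarity = c("amplification", "deletion",
                                               "amp_only", "del_only"),
                                  p_max = 0.05, min_fold_change = 2,
                                  consistency_min = 0.9) {
  polarity <- match.arg(polarity)
  amp <- polarity %in% c("amplification", "amp_only")
  altered_subjects <- intersect(altered_subjects, names(expr_row))
  neutral <- setdiff(names(expr_row), altered_subjects)
  if (length(altered_subjects) < 2 || length(neutral) < 2)
    return(list(retained = FALSE, reason = "insufficient_data"))
  xa <- expr_row[altered_subjects]
  xn <- expr_row[neutral]
  diff <- mean(xa) - mean(xn)
  fold_change <- 2^diff
  welch_p <- tryCatch(
    stats::t.test(xa, xn, alternative = if (amp) "greater" else "less",
                  var.equal = FALSE)$p.value,
    error = function(e) NA_real_)
  consistency <- if (amp) mean(xa > 0) else mean(xa < 0)
  fc_ok <- if (is.null(min_fold_change)) TRUE
  else if (amp) fold_change > min_fold_change
  else fold_change < 1 / min_fold_change
  retained <- !is.na(welch_p) && welch_p < p_max && fc_ok &&
    consistency >= consistency_min
  reason <- if (retained) NA_character_
  else if (is.na(welch_p) || welch_p >= p_max) "welch_p"
  else if (!fc_ok) "fold_change"
  else "consistency"
  list(retained = retained, fold_change = unname(fold_change),
       welch_p = unname(welch_p), consistency_fraction = unname(consistency),
       n_altered = length(altered_subjects), reason = reason)
}

#' Pairwise driver-target correlations with t-based p-values
#'
#' Pearson (default) or Spearman correlation of every (driver, target)
#' pair, with two-sided p-values from the t transform on n - 2 degrees of
#' freedom. Zero-variance features yield NA.
#'
#' @param expr feature x subject matrix.
#' @param drivers,targets feature id vectors (rows of `expr`).
#' @param method `"pearson"` or `"spearman"`.
#' @return list with matrices `r` and `p` (drivers x targets).
#' @export
pairwise_driver_correlation <- function(expr, drivers, targets,
                                        method = c("pearson", "spearman")) {
  method <- match.arg(method)
  n <- ncol(expr)
  if (n < 4) stop("need at least 4 subjects")
  r <- suppressWarnings(
    stats::cor(t(expr[drivers, , drop = FALSE]),
               t(expr[targets, , drop = FALSE]), method = method))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1 - 1e-15] <- 0
  dimnames(r) <- dimnames(p) <- list(drivers, targets)
  list(r = r, p = p)
}

#' Initial target-to-driver module assignment
#'
#' Each target with at least one significantly correlated driver
#' (p < `p_threshold`, raw) is assigned to the driver with the largest
#' absolute correlation among the significant ones; exact ties go to the
#' lexicographically first driver id. Targets with no significant driver
#' stay unassigned. The assignment partitions the assigned targets.
#'
#' @param corr,pmat drivers x targets matrices from
#'   [pairwise_driver_correlation()].
#' @param p_threshold raw p-value threshold.
#' @return named character vector, target -> driver.
#' @export
initial_modules <- function(corr, pmat, p_threshold = 0.001) {
  drivers <- rownames(corr)[order(rownames(corr))]
  corr <- corr[drivers, , drop = FALSE]
  pmat <- pmat[drivers, , drop = FALSE]
  out <- vapply(seq_len(ncol(corr)), function(j) {
    sig <- which(!is.na(pmat[, j]) & pmat[, j] < p_threshold)
    if (length(sig) == 0) return(NA_character_)
    best <- sig[which.max(abs(corr[sig, j]))]  # ties: first in sorted order
    drivers[best]
  }, "")
  names(out) <- colnames(corr)
  out[!is.na(out)]
}

# Soft-threshold `a` so that after L2 normalization its L1 norm is <= c;
# binary search over the threshold (penalized-matrix-decomposition style).
soft_l1_project <- function(a, c) {
  norm2 <- sqrt(sum(a^2))
  if (norm2 < .Machine$double.eps) return(a)
  u <- a / norm2
  if (sum(abs(u)) <= c + 1e-12) return(u)
  soft <- function(x, d) sign(x) * pmax(abs(x) - d, 0)
  lo <- 0; hi <- max(abs(a))
  for (iter in 1:60) {
    mid <- (lo + hi) / 2
    s <- soft(a, mid)
    n2 <- sqrt(sum(s^2))
    l1 <- if (n2 > 0) sum(abs(s)) / n2 else 0
    if (l1 > c) lo <- mid else hi <- mid
  }
  s <- soft(a, hi)
  s / sqrt(sum(s^2))
}

#' Sparse canonical correlation refinement of a module
#'
#' Rank-1 sparse CCA between a module's driver block and target block by
#' alternating soft-thresholded power iterations on the cross-covariance.
#' With both penalties zero and more subjects than features the blocks are
#' whitened by their inverse covariance square roots, so the leading
#' canonical correlation equals classical CCA; with nonzero penalties the
#' within-block covariances are treated as identity (the
#' penalized-matrix-decomposition formulation, appropriate when features
#' outnumber subjects) and weights are L1-constrained. Targets with zero
#' canonical weight are dropped from the module.
#'
#' @param X subjects x drivers matrix (module driver expression).
#' @param Y subjects x targets matrix.
#' @param penalty_x,penalty_y sparsity in `[0, 1]`: 0 = no penalty (all
#'   features retained), 1 = maximal sparsity. The L1 bound on a weight
#'   vector of length p is `sqrt(p) - penalty * (sqrt(p) - 1)`.
#' @param max_iter,tol iteration control; non-convergence raises an error
#'   of class `scca_no_convergence` carrying the last iterate and delta.
#' @return list with `xweights`, `yweights` (unit norm), `cor` (canonical
#'   correlation), `retained` (targets with nonzero weight), `iterations`,
#'   `converged`.
#' @export
refine_module_scca <- function(X, Y, penalty_x = 0, penalty_y = 0,
                               max_iter = 200L, tol = 1e-10) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (n != nrow(Y)) stop("X and Y need the same subjects")
  if (n < 3) stop("need more than 2 subjects")
  if (ncol(X) < 1 || ncol(Y) < 1) stop("module is empty")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)

  if (penalty_x == 0 && penalty_y == 0 && n > ncol(X) + ncol(Y)) {
    # whitened (classical CCA) route
    isqrt <- function(S) {
      e <- eigen(S, symmetric = TRUE)
      if (min(e$values) < 1e-12 * max(e$values))
        stop("singular within-block covariance; use a nonzero penalty")
      e$vectors %*% diag(1 / sqrt(e$values), length(e$values)) %*% t(e$vectors)
    }
    Sx <- crossprod(Xc) / (n - 1)
    Sy <- crossprod(Yc) / (n - 1)
    Sxy <- crossprod(Xc, Yc) / (n - 1)
    Wx <- isqrt(Sx); Wy <- isqrt(Sy)
    sv <- svd(Wx %*% Sxy %*% Wy)
    a <- drop(Wx %*% sv$u[, 1]); b <- drop(Wy %*% sv$v[, 1])
    a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
    rho <- stats::cor(drop(Xc %*% a), drop(Yc %*% b))
    if (rho < 0) { a <- -a; rho <- -rho }
    names(a) <- colnames(X); names(b) <- colnames(Y)
    return(list(xweights = a, yweights = b, cor = rho,
                retained = colnames(Y)[abs(b) > 0],
                iterations = 0L, converged = TRUE))
  }

  # penalized route on standardized blocks
  zscale <- function(M) {
    s <- apply(M, 2, stats::sd)
    s[s < 1e-12] <- 1
    sweep(M, 2, s, "/")
  }
  Xs <- zscale(Xc); Ys <- zscale(Yc)
  Z <- crossprod(Xs, Ys) / (n - 1)
  c1 <- sqrt(ncol(X)) - penalty_x * (sqrt(ncol(X)) - 1)
  c2 <- sqrt(ncol(Y)) - penalty_y * (sqrt(ncol(Y)) - 1)
  sv <- svd(Z)
  v <- sv$v[, 1]
  u <- sv$u[, 1]
  delta <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    u_new <- soft_l1_project(drop(Z %*% v), c1)
    v_new <- soft_l1_project(drop(crossprod(Z, u_new)), c2)
    delta <- max(max(abs(u_new - u)), max(abs(v_new - v)))
    u <- u_new; v <- v_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    cond <- structure(
      class = c("scca_no_convergence", "error", "condition"),
      list(message = sprintf(
        "sparse CCA did not converge after %d iterations (delta = %.3g)",
        max_iter, delta),
        call = sys.call(-1), xweights = u, yweights = v, delta = delta))
    stop(cond)
  }
  xs <- drop(Xs %*% u); ys <- drop(Ys %*% v)
  rho <- if (stats::sd(xs) > 0 && stats::sd(ys) > 0) stats::cor(xs, ys) else 0
  if (rho < 0) { u <- -u; rho <- -rho }
  names(u) <- colnames(X); names(v) <- colnames(Y)
  list(xweights = u, yweights = v, cor = rho,
       retained = colnames(Y)[abs(v) > 1e-12],
       iterations = it, converged = TRUE)
}

#' Choose the target-side sparsity by a permutation gap criterion
#'
#' Over a small penalty grid, compares the canonical correlation on the
#' real data with its mean over subject-permuted target blocks and keeps
#' the penalty maximizing the gap. Fixed seed for the permutation stream.
#'
#' @param X,Y as in [refine_module_scca()].
#' @param grid candidate `penalty_y` values.
#' @param n_perm permutations per grid point.
#' @param seed integer seed.
#' @return the selected penalty (scalar).
#' @export
select_scca_penalty <- function(X, Y, grid = c(0.2, 0.4, 0.6, 0.8),
                                n_perm = 10L, seed = 1L) {
  with_seed(seed, {
    n <- nrow(as.matrix(X))
    gaps <- vapply(grid, function(pen) {
      real <- refine_module_scca(X, Y, penalty_x = 0, penalty_y = pen)$cor
      perm <- vapply(seq_len(n_perm), function(b) {
        refine_module_scca(X, Y[sample(n), , drop = FALSE],
                           penalty_x = 0, penalty_y = pen)$cor
      }, 0)
      real - mean(perm)
    }, 0)
    grid[which.max(gaps)]
  })
}

#' Rank and select final drivers
#'
#' Keeps candidates whose fold-change magnitude exceeds `fc_final` and
#' whose Welch p-value is below `p_final`, ordered by descending refined
#' module size with ties broken by descending fold-change magnitude.
#'
#' @param candidates data frame with columns `feature`, `fold_change`,
#'   `welch_p` (one row per retained candidate driver).
#' @param modules named list, driver id -> character vector of (refined)
#'   targets.
#' @param fc_final final fold-change threshold (strict, on the magnitude
#'   `max(fc, 1/fc)`).
#' @param p_final final p-value threshold (strict).
#' @return data frame of selected drivers with `n_targets` and `rank`.
#' @export
rank_and_select_drivers <- function(candidates, modules, fc_final = 4,
                                    p_final = 0.001) {
  if (nrow(candidates) == 0)
    return(data.frame(feature = character(0), fold_change = numeric(0),
                      welch_p = numeric(0), n_targets = integer(0),
                      rank = integer(0)))
  fc_mag <- pmax(candidates$fold_change, 1 / candidates$fold_change)
  keep <- fc_mag > fc_final & candidates$welch_p < p_final
  out <- candidates[keep, , drop = FALSE]
  fc_mag <- fc_mag[keep]
  out$n_targets <- vapply(out$feature, function(d)
    length(modules[[d]]), 0L)
  o <- order(-out$n_targets, -fc_mag)
  out <- out[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Module size as a function of the correlation cutoff
#'
#' @param target_corr named vector of per-target correlations with the
#'   driver.
#' @param thresholds increasing correlation cutoffs.
#' @return data frame with `threshold` and `n_targets` (the number of
#'   targets with `|r| >= threshold`; non-increasing in the cutoff).
#' @export
target_count_curve <- function(target_corr, thresholds) {
  data.frame(threshold = thresholds,
             n_targets = vapply(thresholds, function(th)
               sum(abs(target_corr) >= th), 0L))
}
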