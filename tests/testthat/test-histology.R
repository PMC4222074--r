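test_that("rank-based AUC handles separation, ties and reversals", {
  expect_identical(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_identical(auc(rep(2, 6), c(0, 0, 0, 1, 1, 1)), 0.5)
  expect_identical(auc(c(3, 1, 2, 4), c(0, 0, 1, 1)), 0.75)
  expect_error(auc(1:4, c(1, 1, 1, 1)), "both classes")
  # complement identity for tie-free scores
  set.seed(2)
  for (i in 1:50) {
    s <- sample(100, 8)
    l <- c(0, 1, sample(0:1, 6, replace = TRUE))
    expect_equal(auc(s, l) + auc(-s, l), 1)
  }
})

test_that("AUC equals exhaustive pair counting on small instances", {
  set.seed(9)
  for (i in 1:300) {
    n <- sample(2:8, 1)
    scores <- sample(1:4, n, replace = TRUE)  # small alphabet forces ties
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_identical(auc(scores, labels), oracle_auc(scores, labels),
                     info = paste("case", i))
  }
})

test_that("the L1 signature recovers planted informative genes", {
  recovered <- numeric(10)
  aucs <- numeric(10)
  for (s in 1:10) {
    dat <- with_seed_test(100 + s, {
      n <- 100
      y <- rep(c(0, 1), each = n / 2)
      expr <- matrix(rnorm(200 * n, 0, 0.5), 200, n,
                     dimnames = list(sprintf("g%03d", 1:200),
                                     paste0("s", 1:n)))
      expr[1:15, y == 1] <- expr[1:15, y == 1] + 2
      list(expr = expr, y = y)
    })
    res <- l1_signature(dat$expr, dat$y, signature_size = 15, seed = s)
    recovered[s] <- sum(res$signature %in% sprintf("g%03d", 1:15))
    aucs[s] <- res$cv_auc
  }
  expect_true(all(aucs >= 0.95))
  expect_gte(mean(recovered), 12)
})

test_that("the signature AUC is at chance under permuted labels", {
  aucs <- vapply(1:20, function(s) {
    dat <- with_seed_test(300 + s, {
      n <- 200
      expr <- matrix(rnorm(100 * n, 0, 0.5), 100, n,
                     dimnames = list(paste0("g", 1:100), paste0("s", 1:n)))
      list(expr = expr, y = sample(rep(c(0, 1), each = n / 2)))
    })
    l1_signature(dat$expr, dat$y, signature_size = 15, cv_folds = 10,
                 seed = s)$cv_auc
  }, 0)
  # forcing the active set to the signature size keeps substantial
  # selection noise in any single null CV-AUC (sd ~ 0.08-0.1); the
  # calibration property is that the distribution is centred at chance,
  # which is also what makes the matching Monte-Carlo null exact
  expect_lt(abs(mean(aucs) - 0.5), 0.07)
  expect_true(all(abs(aucs - 0.5) <= 0.3))
})

test_that("a single perfectly separating gene is found at size 1", {
  with_seed_test(77, {
    n <- 60
    y <- rep(c(0, 1), each = n / 2)
    expr <- matrix(rnorm(50 * n, 0, 0.5), 50, n,
                   dimnames = list(paste0("g", 1:50), paste0("s", 1:n)))
    expr["g7", ] <- y * 4 + rnorm(n, 0, 0.01)
    res <- l1_signature(expr, y, signature_size = 1, seed = 1)
    expect_identical(res$signature, "g7")
    expect_identical(res$cv_auc, 1)
  })
})

test_that("the Monte-Carlo signature p-value follows the add-one rule", {
  dat <- with_seed_test(55, {
    n <- 60
    expr <- matrix(rnorm(80 * n, 0, 0.5), 80, n,
                   dimnames = list(paste0("g", 1:80), paste0("s", 1:n)))
    list(expr = expr, y = rep(c(0, 1), each = n / 2))
  })
  mc <- monte_carlo_signature_pvalue(dat$expr, dat$y, signature_size = 10,
                                     n_draws = 50, seed = 3, cv_folds = 3,
                                     observed_auc = 1)
  expect_identical(mc$p_value, 1 / 51)      # observed beats every null
  expect_length(mc$null_aucs, 50)
  low <- monte_carlo_signature_pvalue(dat$expr, dat$y, signature_size = 10,
                                      n_draws = 50, seed = 3, cv_folds = 3,
                                      observed_auc = mc$null_median - 0.01)
  expect_gt(low$p_value, 0.5)
  again <- monte_carlo_signature_pvalue(dat$expr, dat$y, signature_size = 10,
                                        n_draws = 50, seed = 3, cv_folds = 3,
                                        observed_auc = 1)
  expect_identical(again$null_aucs, mc$null_aucs)
  expect_error(monte_carlo_signature_pvalue(dat$expr, dat$y, n_draws = 0,
                                            observed_auc = 1),
               "configuration")
})

test_that("histology-biased planted drivers test as predictive", {
  hits <- 0
  for (s in 1:10) {
    # informative background genes are kept at the default cohort's ~1.5%
    # share so the random-gene null is comparable
    co <- generate_cohort(tiny_config(seed = 400 + s, planted_regions = list(
      planted_region(1, 150000, 300000, "amplification", 0.9, 0.3,
                     histology_bias = c(AC = 0, SCC = 0.8, LCC = 0),
                     driver_gene = "DRV1", n_targets = 10L)),
      n_histology_genes = 3L))
    acscc <- names(co$labels)[co$labels %in% c("AC", "SCC")]
    res <- single_feature_auc_test(co$expr[, acscc], "DRV1",
                                   factor(co$labels[acscc]),
                                   n_draws = 200, seed = s)
    if (res$auc >= 0.8 && res$p_value <= 0.05) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("single-feature Monte-Carlo p-values are calibrated on noise", {
  pvals <- with_seed_test(999, {
    n <- 60
    y <- rep(c(0, 1), each = n / 2)
    expr <- matrix(rnorm(250 * n), 250, n,
                   dimnames = list(paste0("g", 1:250), paste0("s", 1:n)))
    vapply(1:200, function(i)
      single_feature_auc_test(expr, paste0("g", i), y, n_draws = 99,
                              seed = i)$p_value, 0)
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_error(
    single_feature_auc_test(rbind(flat = rep(1, 6), x = rnorm(6)), "flat",
                            c(0, 0, 0, 1, 1, 1)),
    "constant")
})

test_that("the regional amplification test behaves like a one-sided t-test", {
  res0 <- regional_amplification_test(rep(0, 20))
  expect_identical(res0$p_value, 0.5)
  expect_false(res0$amplified)
  x <- with_seed_test(5, rnorm(20, 0.5, 0.1))
  res <- regional_amplification_test(x)
  expect_lt(res$p_value, 1e-3)
  expect_true(res$amplified)
  expect_equal(res$p_value, t.test(x, mu = 0, alternative = "greater")$p.value)
  expect_error(regional_amplification_test(0.4), "insufficient")
  # the amplified set at 0.001 is a subset of that at 0.05
  set.seed(6)
  for (i in 1:50) {
    w <- rnorm(10, runif(1, -0.2, 0.6), 0.2)
    strict <- regional_amplification_test(w, p_threshold = 0.001)$amplified
    loose <- regional_amplification_test(w, p_threshold = 0.05)$amplified
    expect_true(!strict || loose)
  }
})
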