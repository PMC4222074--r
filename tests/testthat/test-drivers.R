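test_that("the variability filter keeps features with SD >= 0.25", {
  expr <- rbind(const = rep(1, 4), spread = c(-0.5, 0.5, -0.5, 0.5),
                mid = c(0, 0.1, 0, 0.1))
  colnames(expr) <- paste0("s", 1:4)
  expect_identical(filter_variable_features(expr), "spread")
  expect_identical(filter_variable_features(expr, 0),
                   c("const", "spread", "mid"))
  # sd of (-0.5, 0.5) over two subjects is ~0.707, above the cutoff
  expect_identical(filter_variable_features(expr[2, 1:2, drop = FALSE]),
                   "spread")
})

test_that("the CNA-expression filter combines Welch test, fold change and consistency", {
  subj <- paste0("s", 1:50)
  x <- setNames(rep(0, 50), subj)
  alt <- subj[1:10]
  x[alt] <- 2
  x[11:50] <- rnorm(40, 0, 1e-3)
  res <- cna_expression_filter(x, alt, "amplification")
  expect_true(res$retained)
  expect_gt(res$fold_change, 2)
  expect_lt(res$welch_p, 1e-10)
  expect_identical(res$consistency_fraction, 1)
  # identical group means: one-sided p = 0.5, rejected
  y <- setNames(c(rep(c(0, 1e-6), 25)), subj)
  res2 <- cna_expression_filter(y + 1, alt, "amplification")
  expect_false(res2$retained)
  expect_equal(res2$welch_p, 0.5, tolerance = 0.2)
  # log2 difference 0.8 -> FC 1.74: rejected for genes, eligible for the
  # miRNA regime (no fold-change rule)
  z <- setNames(c(rep(0.8, 10), rnorm(40, 0, 0.05)), subj)
  gene <- cna_expression_filter(z, alt, "amplification",
                                p_max = 0.05, min_fold_change = 2)
  expect_false(gene$retained)
  expect_identical(gene$reason, "fold_change")
  expect_equal(gene$fold_change, 2^0.8, tolerance = 0.05)
  mir <- cna_expression_filter(z, alt, "amplification",
                               p_max = 0.01, min_fold_change = NULL)
  expect_true(mir$retained)
  # deletions work in the mirrored direction
  del <- cna_expression_filter(-z, alt, "deletion")
  expect_false(del$retained)  # FC rule: 2^-0.8 not < 1/2
  del2 <- cna_expression_filter(setNames(c(rep(-1.5, 10), rnorm(40, 0, 0.05)),
                                         subj), alt, "deletion")
  expect_true(del2$retained)
  # too few altered subjects
  ins <- cna_expression_filter(x, alt[1], "amplification")
  expect_false(ins$retained)
  expect_identical(ins$reason, "insufficient_data")
})

test_that("pairwise correlations and p-values match cor.test", {
  set.seed(8)
  expr <- rbind(d1 = rnorm(20), t1 = NA, t2 = NA, flat = rep(1, 20))
  expr["t1", ] <- expr["d1", ]
  expr["t2", ] <- -expr["d1", ]
  colnames(expr) <- paste0("s", 1:20)
  pc <- pairwise_driver_correlation(expr, "d1", c("t1", "t2", "flat"))
  expect_equal(pc$r["d1", "t1"], 1)
  expect_equal(pc$r["d1", "t2"], -1)
  expect_identical(pc$p["d1", "t1"], 0)
  expect_true(is.na(pc$r["d1", "flat"]))
  # r = 0.8 at n = 20: t ~ 5.66, agrees with cor.test
  x <- rnorm(20); y <- 0.8 * x + rnorm(20)
  e2 <- rbind(a = x, b = y); colnames(e2) <- paste0("s", 1:20)
  pc2 <- pairwise_driver_correlation(e2, "a", "b")
  ct <- cor.test(x, y)
  expect_equal(pc2$r["a", "b"], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pc2$p["a", "b"], ct$p.value, tolerance = 1e-10)
  expect_error(pairwise_driver_correlation(e2[, 1:3], "a", "b"), "4 subjects")
})

test_that("targets join their most correlated significant driver", {
  corr <- matrix(c(0.9, 0.5, 0.3, 0.7, 0.6, 0.6), 2, 3, byrow = TRUE,
                 dimnames = list(c("B", "A"), c("t1", "t2", "t3")))
  pmat <- matrix(c(1e-5, 1e-4, 0.01, 1e-6, 1e-4, 0.01), 2, 3, byrow = TRUE,
                 dimnames = dimnames(corr))
  mm <- initial_modules(corr, pmat)
  expect_identical(unname(mm["t1"]), "B")    # 0.9 beats 0.7
  expect_identical(unname(mm["t2"]), "A")    # t2: only A significant? both are
  expect_false("t3" %in% names(mm))          # best p = 0.01 > 0.001
  # exact tie on |r| goes to the lexicographically first driver id
  corr2 <- matrix(c(0.6, 0.6), 2, 1, dimnames = list(c("B", "A"), "t"))
  pmat2 <- matrix(c(1e-5, 1e-5), 2, 1, dimnames = dimnames(corr2))
  expect_identical(unname(initial_modules(corr2, pmat2)["t"]), "A")
  # partition: each assigned target appears exactly once
  expect_false(any(duplicated(names(mm))))
})

test_that("sparse CCA reduces to classical CCA at zero penalty", {
  x <- matrix(rnorm(60), 30, 2)
  y <- matrix(rnorm(90), 30, 3)
  colnames(x) <- c("d1", "d2"); colnames(y) <- c("t1", "t2", "t3")
  sc <- refine_module_scca(x, y)
  cc <- cancor(x, y)
  expect_equal(sc$cor, cc$cor[1], tolerance = 1e-8)
  expect_setequal(sc$retained, colnames(y))
  # single identical feature on both sides: canonical correlation 1
  v <- matrix(rnorm(20), 20, 1, dimnames = list(NULL, "f"))
  one <- refine_module_scca(v, v)
  expect_equal(one$cor, 1, tolerance = 1e-10)
})

test_that("strong target penalties recover a planted support", {
  ok <- 0
  for (s in 1:20) {
    hit <- with_seed_test(s, {
      n <- 40
      d <- rnorm(n)
      x <- matrix(d, n, 1, dimnames = list(NULL, "drv"))
      sig <- sapply(1:5, function(i) d + rnorm(n, 0, 0.2))
      noise <- matrix(rnorm(n * 50), n, 50)
      y <- cbind(sig, noise)
      colnames(y) <- c(paste0("hit", 1:5), paste0("nse", 1:50))
      sc <- refine_module_scca(x, y, penalty_x = 0, penalty_y = 0.85)
      length(sc$retained) > 0 && all(grepl("^hit", sc$retained))
    })
    if (isTRUE(hit)) ok <- ok + 1
  }
  expect_gte(ok, 18)
})

test_that("zero target-side penalty keeps the whole module", {
  with_seed_test(3, {
    x <- matrix(rnorm(25), 25, 1, dimnames = list(NULL, "d"))
    y <- matrix(rnorm(25 * 40), 25, 40,
                dimnames = list(NULL, paste0("t", 1:40)))
    sc <- refine_module_scca(x, y, penalty_x = 0, penalty_y = 0)
    expect_setequal(sc$retained, colnames(y))
  })
})

test_that("non-convergence raises a condition carrying the last iterate", {
  with_seed_test(4, {
    x <- matrix(rnorm(200), 20, 10)
    y <- matrix(rnorm(200), 20, 10)
    colnames(x) <- paste0("d", 1:10); colnames(y) <- paste0("t", 1:10)
    err <- tryCatch(
      refine_module_scca(x, y, penalty_x = 0.5, penalty_y = 0.5,
                         max_iter = 1L, tol = 1e-16),
      scca_no_convergence = function(e) e)
    expect_s3_class(err, "scca_no_convergence")
    expect_true(is.numeric(err$delta))
    expect_length(err$yweights, 10)
  })
})

test_that("final ranking applies the strict thresholds and tie-breaks", {
  cand <- data.frame(feature = c("a", "b", "c", "d"),
                     fold_change = c(5, 3.5, 6, 4.5),
                     welch_p = c(1e-4, 1e-6, 1e-4, 1e-4))
  modules <- list(a = paste0("t", 1:800), c = paste0("u", 1:800),
                  d = paste0("v", 1:10))
  sel <- rank_and_select_drivers(cand, modules)
  # b excluded (FC <= 4); a and c tie on size, c has larger fold change
  expect_identical(sel$feature, c("c", "a", "d"))
  expect_identical(sel$n_targets[1:2], c(800L, 800L))
  none <- rank_and_select_drivers(cand, modules, fc_final = 1e6)
  expect_identical(nrow(none), 0L)
})

test_that("target counts are non-increasing in the correlation cutoff", {
  r <- setNames(runif(200, -1, 1), paste0("t", 1:200))
  curve <- target_count_curve(r, seq(0, 1, by = 0.05))
  expect_identical(curve$n_targets[1], 200L)
  expect_true(all(diff(curve$n_targets) <= 0))
  expect_identical(curve$n_targets[curve$threshold == 1],
                   sum(abs(r) >= 1))
  set.seed(12)
  for (i in 1:100) {
    rr <- runif(sample(5:50, 1), -1, 1)
    names(rr) <- seq_along(rr)
    cc <- target_count_curve(rr, sort(runif(6)))
    expect_true(all(diff(cc$n_targets) <= 0))
  }
})
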