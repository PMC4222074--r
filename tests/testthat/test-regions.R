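test_that("the 10% recurrence threshold keeps 12/121 and drops 11/121", {
  build_calls <- function(n_shared) {
    subj <- paste0("s", seq_len(121))
    # every subject has one private call somewhere so all 121 count in the
    # denominator; n_shared of them also share one identical region
    private <- data.frame(
      subject = subj, chrom = "chr9",
      start = (seq_len(121) - 1) * 10000,
      end_open = (seq_len(121) - 1) * 10000 + 2000,
      state = "dup")
    shared <- data.frame(
      subject = subj[seq_len(n_shared)], chrom = "chr1",
      start = 100, end_open = 900, state = "dup")
    rbind(private, shared)
  }
  r12 <- find_recurrent_regions(build_calls(12))
  expect_true(any(r12$chrom == "chr1" & r12$n_altered == 12))
  r11 <- find_recurrent_regions(build_calls(11))
  expect_false(any(r11$chrom == "chr1"))
  # one identical call in all subjects -> recurrence 1
  all_shared <- data.frame(subject = paste0("s", 1:8), chrom = "chr2",
                           start = 0, end_open = 500, state = "del")
  r <- find_recurrent_regions(all_shared)
  expect_identical(nrow(r), 1L)
  expect_identical(r$recurrence, 1)
  expect_identical(nrow(find_recurrent_regions(all_shared[0, ])), 0L)
})

test_that("recurrent regions match the per-base brute-force oracle", {
  for (i in 1:100) {
    calls <- with_seed_test(i, random_call_set())
    got <- find_recurrent_regions(calls, min_recurrence = 0.10)
    want <- oracle_recurrent_regions(calls, min_recurrence = 0.10)
    expect_identical(nrow(got), nrow(want), info = paste("case", i))
    if (nrow(want) > 0) {
      expect_identical(got$chrom, want$chrom, info = paste("case", i))
      expect_identical(as.integer(got$start), as.integer(want$start))
      expect_identical(as.integer(got$end), as.integer(want$end))
      expect_identical(got$n_altered, want$n_altered)
    }
  }
})

test_that("recurrence is invariant to subject order and call splitting", {
  calls <- with_seed_test(5, random_call_set(n_calls = 12))
  base <- find_recurrent_regions(calls)
  shuffled <- calls[rev(seq_len(nrow(calls))), ]
  expect_equal(find_recurrent_regions(shuffled)[, 1:7], base[, 1:7])
  # split the first call into two abutting calls of the same state
  k <- 1
  mid <- floor((calls$start[k] + calls$end_open[k]) / 2)
  split_calls <- rbind(
    transform(calls[k, ], end_open = mid),
    transform(calls[k, ], start = mid),
    calls[-k, ])
  expect_equal(find_recurrent_regions(split_calls)[, 1:7], base[, 1:7])
})

test_that("polarity classification applies the mixture tolerance", {
  expect_identical(classify_polarity(10, 0, 0)$polarity, "amp_only")
  expect_identical(classify_polarity(19, 1, 0.10)$polarity, "amp_only")
  expect_equal(classify_polarity(19, 1, 0.10)$mixture_fraction, 0.05)
  expect_identical(classify_polarity(19, 1, 0)$polarity, "mixed")
  expect_identical(classify_polarity(0, 7, 0)$polarity, "del_only")
  expect_identical(classify_polarity(5, 5, 0.49)$polarity, "mixed")
  expect_error(classify_polarity(1, 1, 0.6), "configuration")
  expect_error(classify_polarity(0, 0, 0), "no altered")
})

test_that("the per-region ANOVA matches aov and handles degeneracies", {
  # identical values across all groups -> F = 0
  m <- matrix(0.3, 1, 9)
  colnames(m) <- paste0("s", 1:9)
  labs <- setNames(rep(c("AC", "SCC", "LCC"), each = 3), colnames(m))
  res <- anova_differential_regions(m, labs)
  expect_identical(res$F, 0)
  # well-separated groups with tiny jitter -> essentially zero p
  m2 <- matrix(rep(c(0, 1, 2), each = 3) + seq(-1e-6, 1e-6, length.out = 9),
               1, 9, dimnames = list(NULL, colnames(m)))
  expect_lt(anova_differential_regions(m2, labs)$p, 1e-10)
  # random regions agree with stats::aov
  set.seed(31)
  m3 <- matrix(rnorm(20 * 30), 20, 30,
               dimnames = list(NULL, paste0("s", 1:30)))
  labs3 <- setNames(sample(c("AC", "SCC", "LCC"), 30, replace = TRUE),
                    colnames(m3))
  res3 <- anova_differential_regions(m3, labs3)
  for (r in c(1, 7, 20)) {
    fit <- summary(aov(m3[r, ] ~ factor(labs3)))[[1]]
    expect_equal(res3$F[r], fit$`F value`[1], tolerance = 1e-10)
    expect_equal(res3$p[r], fit$`Pr(>F)`[1], tolerance = 1e-10)
  }
  expect_equal(res3$fdr, p.adjust(res3$p, "BH"))
  # a group with < 2 subjects is dropped; with only one group left -> NA
  m4 <- matrix(rnorm(3), 1, 3, dimnames = list(NULL, paste0("s", 1:3)))
  labs4 <- setNames(c("AC", "AC", "SCC"), colnames(m4))
  expect_true(is.na(anova_differential_regions(m4, labs4)$p))
})

test_that("cluster merging respects the 1-point tolerance and chromosomes", {
  regions <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                        start = c(0, 100, 200, 0),
                        end = c(100, 200, 300, 100))
  f0 <- matrix(c(10, 5, 10, 5, 10, 5, 10, 5), 4, 2, byrow = TRUE,
               dimnames = list(NULL, c("dup.AC", "dup.SCC")))
  # identical tables on chr1 merge; chr2 never joins
  cl <- merge_into_clusters(regions, f0)
  expect_identical(cl$n_regions, c(3L, 1L))
  # a 2-point jump in one frequency starts a new cluster
  f1 <- f0; f1[2, "dup.SCC"] <- 7
  cl1 <- merge_into_clusters(regions, f1)
  expect_identical(cl1$n_regions, c(1L, 1L, 1L, 1L))
  # drift guard: deviations are measured against the cluster anchor
  f2 <- f0; f2[2, 1] <- 10.9; f2[3, 1] <- 11.8
  cl2 <- merge_into_clusters(regions, f2, tolerance = 1)
  expect_identical(cl2$n_regions[1:2], c(2L, 1L))
})

test_that("features map to regions by half-open overlap", {
  regions <- data.frame(chrom = "chr1", start = 150, end = 300)
  ann <- data.frame(feature = c("a", "b", "c"), chrom = "chr1",
                    start = c(100, 300, 140), end = c(200, 400, 400))
  got <- map_features_to_regions(regions, ann)
  expect_setequal(got[[1]], c("a", "c"))  # "b" abuts half-open, no overlap
  two <- data.frame(chrom = "chr1", start = c(0, 200), end = c(200, 500))
  spans <- data.frame(feature = "wide", chrom = "chr1", start = 150, end = 250)
  expect_identical(map_features_to_regions(two, spans),
                   list("wide", "wide"))
  odd <- data.frame(feature = "x", chrom = "chrUn", start = 0, end = 10)
  expect_warning(res <- map_features_to_regions(regions, odd,
                                                known_chromosomes = "chr1"),
                 "unknown")
  expect_identical(res[[1]], character(0))
})

test_that("region frequencies count each state within each histology group", {
  labels <- setNames(rep(c("AC", "SCC"), each = 4), paste0("s", 1:8))
  regions <- data.frame(chrom = "chr1", start = 0, end = 10)
  regions$states <- list(setNames(c("dup", "dup", "del"),
                                  c("s1", "s5", "s6")))
  f <- region_state_frequencies(regions, labels)
  expect_equal(unname(f[1, "dup.AC"]), 25)
  expect_equal(unname(f[1, "dup.SCC"]), 25)
  expect_equal(unname(f[1, "del.SCC"]), 25)
  expect_equal(unname(f[1, "del.AC"]), 0)
})
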