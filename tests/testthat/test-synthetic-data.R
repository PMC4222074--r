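test_that("zero-noise carriers get exactly the planted amplitude in-region", {
  co <- generate_cohort(noiseless_config(seed = 3))
  reg <- co$config$planted_regions[[1]]
  carriers <- co$truth$carriers[, 1]
  for (s in c(which(carriers)[1], which(!carriers)[1])) {
    pr <- co$profiles[[s]]$probes
    inside <- pr$chrom == "chr1" & pr$pos >= reg$start & pr$pos < reg$end
    expected <- if (carriers[s]) reg$mean_amplitude else 0
    expect_identical(unique(pr$log2ratio[inside]), expected)
    expect_identical(unique(pr$log2ratio[!inside]), 0)
  }
})

test_that("driver-target sample correlation matches the generative value", {
  # Monte-Carlo check of the latent-factor construction: at n = 200 and
  # module_corr = 0.9 the mean sample correlation over 50 targets should
  # sit within 0.05 of 0.9 across replicate seeds.
  cfg_for <- function(s)
    sim_config(n_subjects = 200L, n_chromosomes = 2L,
               probes_per_chromosome = 40L, n_genes = 100L, n_mirnas = 10L,
               planted_regions = list(
                 planted_region(1, 100000, 250000, "amplification", 0.9, 0.4,
                                driver_gene = "DRV1", n_targets = 50L)),
               module_corr = 0.9, n_histology_genes = 4L, seed = s)
  mean_r <- vapply(1:20, function(s) {
    co <- generate_cohort(cfg_for(s))
    tg <- names(co$truth$module_membership)
    mean(cor(t(co$expr[tg, ]), co$expr["DRV1", ]))
  }, 0)
  expect_lt(abs(mean(mean_r) - 0.9), 0.05)
})

test_that("identical seeds give identical cohorts", {
  a <- generate_cohort(tiny_config(seed = 11))
  b <- generate_cohort(tiny_config(seed = 11))
  expect_identical(a$expr, b$expr)
  expect_identical(a$mirna_expr, b$mirna_expr)
  expect_identical(a$labels, b$labels)
  expect_identical(lapply(a$profiles, `[[`, "probes"),
                   lapply(b$profiles, `[[`, "probes"))
  c2 <- generate_cohort(tiny_config(seed = 12))
  expect_false(identical(a$expr, c2$expr))
})

test_that("carrier counts and histology-biased fractions are honored", {
  co <- generate_cohort(sim_config(seed = 5))
  n <- co$config$n_subjects
  for (k in seq_along(co$config$planted_regions)) {
    r <- co$config$planted_regions[[k]]
    if (is.null(r$histology_bias)) {
      expect_lte(abs(sum(co$truth$carriers[, k]) -
                       round(r$carrier_fraction * n)), 1)
    } else {
      for (g in names(r$histology_bias)) {
        idx <- names(co$labels)[co$labels == g]
        frac <- mean(co$truth$carriers[idx, k])
        expect_lte(abs(frac - r$histology_bias[[g]]), 1 / length(idx) + 1e-9)
      }
    }
  }
  # label composition follows the configured simplex
  expect_equal(unname(table(co$labels)[c("AC", "SCC", "LCC")]),
               c(55L, 49L, 16L), ignore_attr = TRUE)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(histology_proportions = c(AC = 0.5, SCC = 0.5, LCC = 0.1)),
               "sum to 1")
  expect_error(sim_config(probes_per_chromosome = 20), ">= 30")
  expect_error(sim_config(module_corr = 1.2), "module_corr")
  expect_error(
    sim_config(planted_regions = list(
      planted_region(1, 0, 9e9, "amplification", 1, 0.5))),
    "coordinate")
  expect_error(
    sim_config(planted_regions = list(
      planted_region(1, 0, 100000, "amplification", 1, 0.5),
      planted_region(1, 50000, 150000, "deletion", -1, 0.5))),
    "overlapping")
  expect_error(planted_region(1, 0, 100, "amplification", -0.5, 0.5),
               "positive mean_amplitude")
  expect_error(planted_region(1, 0, 100, "deletion", 0.5, 0.5),
               "negative mean_amplitude")
})

test_that("a written cohort round-trips losslessly", {
  co <- generate_cohort(tiny_config(seed = 2))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$expr, co$expr, tolerance = 1e-12)
  expect_equal(back$mirna_expr, co$mirna_expr, tolerance = 1e-12)
  expect_identical(back$labels, co$labels)
  expect_equal(back$annotation$feature, co$annotation$feature)
  expect_equal(back$annotation$start, co$annotation$start)
  # probe profiles survive the SEG round trip
  s1 <- co$profiles[[1]]
  b1 <- back$profiles[[s1$subject]]
  expect_equal(b1$probes$pos, s1$probes$pos)
  expect_equal(b1$probes$log2ratio, s1$probes$log2ratio, tolerance = 1e-12)
  # SEG rows sorted by (sample, chrom, start)
  seg <- read_seg(file.path(dir, "probes.seg"))
  o <- order(seg$sample, seg$chrom, seg$loc.start)
  expect_identical(o, seq_len(nrow(seg)))
  # truth reloads to the same content
  tr <- back$truth
  expect_identical(tr$carriers, co$truth$carriers)
  expect_identical(tr$planted_drivers, co$truth$planted_drivers)
  expect_identical(tr$module_membership, co$truth$module_membership)
  expect_identical(tr$histology, co$truth$histology)
  expect_identical(tr$seed, co$truth$seed)
})

test_that("every target maps to exactly one planted driver", {
  co <- generate_cohort(tiny_config(seed = 9))
  mm <- co$truth$module_membership
  expect_false(any(duplicated(names(mm))))
  expect_true(all(mm %in% co$truth$planted_drivers))
  sizes <- table(mm)
  planted <- vapply(co$config$planted_regions, `[[`, 0L, "n_targets")
  expect_setequal(as.integer(sizes), planted[planted > 0])
})
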