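# Synthetic-cohort generator with planted ground truth.
#
# The generator emulates a paired tumor/normal NSCLC-style cohort: probe-level
# aCGH log2(T/N) profiles with recurrent amplified/deleted regions carried by
# a configurable fraction of subjects, driver genes whose expression tracks
# their copy state, correlated target-gene modules induced by a shared latent
# factor, histology labels (AC/SCC/LCC) with optional histology-biased
# carrier fractions, and independent background genes/miRNAs.

#' Describe one planted copy-number region
#'
#' @param chromosome chromosome index (1-based integer).
#' @param start,end region bounds in bases, 0-based half-open.
#' @param polarity `"amplification"` or `"deletion"`.
#' @param mean_amplitude mean probe log2 ratio inside the region for carriers;
#'   its sign must match the polarity.
#' @param carrier_fraction fraction of subjects carrying the alteration, in
#'   (0, 1].
#' @param histology_bias optional named vector of per-histology carrier
#'   fractions (names among `AC`, `SCC`, `LCC`); overrides `carrier_fraction`
#'   within each group.
#' @param driver_gene optional id of a driver feature placed inside the
#'   region whose expression responds to the copy state.
#' @param driver_type `"gene"` or `"mirna"`; which expression matrix the
#'   driver lives in.
#' @param n_targets number of target features correlated with the driver.
#' @param target_effect expression effect (log2 units) of carrying the
#'   alteration on the driver's own expression.
#' @return a `planted_region` list.
#' @export
planted_region <- function(chromosome, start, end,
                           polarity = c("amplification", "deletion"),
                           mean_amplitude, carrier_fraction,
                           histology_bias = NULL, driver_gene = NULL,
                           driver_type = c("gene", "mirna"),
                           n_targets = 0L, target_effect = 2.5) {
  polarity <- match.arg(polarity)
  driver_type <- match.arg(driver_type)
  if (start >= end) stop("planted region must have start < end")
  if (carrier_fraction <= 0 || carrier_fraction > 1)
    stop("carrier_fraction must be in (0, 1]")
  if (polarity == "amplification" && mean_amplitude <= 0)
    stop("amplification requires a positive mean_amplitude")
  if (polarity == "deletion" && mean_amplitude >= 0)
    stop("deletion requires a negative mean_amplitude")
  if (!is.null(histology_bias) &&
      !all(names(histology_bias) %in% c("AC", "SCC", "LCC")))
    stop("histology_bias names must be among AC, SCC, LCC")
  structure(list(
    chromosome = as.integer(chromosome), start = as.numeric(start),
    end = as.numeric(end), polarity = polarity,
    mean_amplitude = mean_amplitude, carrier_fraction = carrier_fraction,
    histology_bias = histology_bias, driver_gene = driver_gene,
    driver_type = driver_type, n_targets = as.integer(n_targets),
    target_effect = target_effect
  ), class = "planted_region")
}

#' Default planted regions for the reference synthetic cohort
#'
#' Three amplified regions carrying expression-coupled driver genes with
#' 120-150-gene target modules (one histology-biased towards SCC), one
#' amplified region carrying a driver miRNA, and one deletion region with
#' bystander genes only.
#'
#' @return list of [planted_region()] objects.
#' @export
default_planted_regions <- function() {
  list(
    planted_region(1, 150000, 300000, "amplification", 0.9, 0.35,
                   histology_bias = c(AC = 0.15, SCC = 0.65, LCC = 0.15),
                   driver_gene = "DRV1", n_targets = 150L),
    planted_region(2, 100000, 260000, "amplification", 1.1, 0.30,
                   driver_gene = "DRV2", n_targets = 150L),
    planted_region(3, 200000, 350000, "amplification", 0.8, 0.25,
                   driver_gene = "DRV3", n_targets = 120L),
    planted_region(4, 100000, 220000, "amplification", 0.9, 0.30,
                   driver_gene = "hsa-mir-sim-1", driver_type = "mirna",
                   n_targets = 0L, target_effect = 1.5),
    planted_region(5, 150000, 250000, "deletion", -0.7, 0.20)
  )
}

#' Configuration of a synthetic cohort
#'
#' Defaults describe the reference study conditions used throughout the
#' package's tests: 120 subjects, 5 chromosomes of 50 probes at 10 kb
#' spacing, 2000 genes, 80 miRNAs, histology proportions matching a
#' surgical NSCLC cohort (46% AC, 41% SCC, 13% LCC), probe noise sd 0.1,
#' expression noise sd 0.3 and driver-target module correlation 0.6.
#'
#' @param n_subjects number of subjects.
#' @param n_chromosomes number of simulated chromosomes.
#' @param probes_per_chromosome probes per chromosome (>= 30).
#' @param probe_spacing distance between consecutive probes, bases.
#' @param n_genes total number of genes in the expression matrix.
#' @param n_mirnas total number of miRNAs.
#' @param histology_proportions named simplex over `AC`, `SCC`, `LCC`.
#' @param planted_regions list of [planted_region()] objects.
#' @param noise_sd_probe sd of i.i.d. Gaussian noise on probe log2 ratios
#'   (>= 0; 0 gives noiseless profiles).
#' @param noise_sd_expr sd of expression noise (log2 units).
#' @param module_corr population Pearson correlation between a driver's
#'   expression and each of its targets, in (0, 1).
#' @param n_histology_genes background genes given a histology main effect
#'   (split between AC-high and SCC-high) so histology classification is
#'   non-degenerate.
#' @param histology_effect size of that main effect, log2 units. The
#'   default 0.6 at expression noise 0.3 puts single informative genes at
#'   an AUC of ~0.9 — strong markers, but no single gene separates the
#'   classes perfectly, so multi-gene signatures genuinely beat random
#'   ones.
#' @param bystanders_per_region non-driver genes placed inside each planted
#'   region; their expression responds only weakly to copy state.
#' @param bystander_effect expression effect of copy state on bystanders.
#' @param seed master integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_subjects = 120L, n_chromosomes = 5L,
                       probes_per_chromosome = 50L, probe_spacing = 10000,
                       n_genes = 2000L, n_mirnas = 80L,
                       histology_proportions = c(AC = 0.46, SCC = 0.41, LCC = 0.13),
                       planted_regions = default_planted_regions(),
                       noise_sd_probe = 0.1, noise_sd_expr = 0.3,
                       module_corr = 0.6, n_histology_genes = 30L,
                       histology_effect = 0.6, bystanders_per_region = 3L,
                       bystander_effect = 0.5, seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    n_chromosomes = as.integer(n_chromosomes),
    probes_per_chromosome = as.integer(probes_per_chromosome),
    probe_spacing = as.numeric(probe_spacing),
    n_genes = as.integer(n_genes), n_mirnas = as.integer(n_mirnas),
    histology_proportions = histology_proportions,
    planted_regions = planted_regions,
    noise_sd_probe = noise_sd_probe, noise_sd_expr = noise_sd_expr,
    module_corr = module_corr,
    n_histology_genes = as.integer(n_histology_genes),
    histology_effect = histology_effect,
    bystanders_per_region = as.integer(bystanders_per_region),
    bystander_effect = bystander_effect, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (abs(sum(cfg$histology_proportions) - 1) > 1e-9)
    stop("histology_proportions must sum to 1")
  if (!all(sort(names(cfg$histology_proportions)) == c("AC", "LCC", "SCC")))
    stop("histology_proportions must be named AC, SCC, LCC")
  if (cfg$probes_per_chromosome < 30L)
    stop("probes_per_chromosome must be >= 30")
  if (cfg$module_corr <= 0 || cfg$module_corr >= 1)
    stop("module_corr must be in (0, 1)")
  if (cfg$noise_sd_probe < 0 || cfg$noise_sd_expr <= 0)
    stop("noise sds must be non-negative (probe) / positive (expression)")
  chrom_len <- cfg$probes_per_chromosome * cfg$probe_spacing
  for (r in cfg$planted_regions) {
    if (r$chromosome < 1L || r$chromosome > cfg$n_chromosomes ||
        r$start < 0 || r$end > chrom_len)
      stop("coordinate error: planted region outside the simulated genome")
  }
  by_chrom <- split(cfg$planted_regions,
                    vapply(cfg$planted_regions, `[[`, 1L, "chromosome"))
  for (rs in by_chrom) {
    if (length(rs) < 2L) next
    o <- order(vapply(rs, `[[`, 0, "start"))
    rs <- rs[o]
    for (k in seq_len(length(rs) - 1L))
      if (rs[[k]]$end > rs[[k + 1L]]$start)
        stop("configuration error: overlapping planted regions on one chromosome")
  }
  invisible(cfg)
}

# Integer group sizes from proportions by largest remainder, summing to n.
proportion_counts <- function(p, n) {
  raw <- p * n
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(short)]] <- base[o[seq_len(short)]] + 1
  }
  as.integer(base)
}

#' Generate a seeded synthetic cohort with planted truth
#'
#' @param config a [sim_config()] object.
#' @return a list with elements `profiles` (list of [genomic_profile()]),
#'   `expr` (gene x subject log2 T/N matrix), `mirna_expr` (miRNA x subject
#'   matrix), `annotation` (feature interval table, 0-based half-open),
#'   `labels` (named histology vector), `truth` (planted ground truth:
#'   carrier matrix, driver ids, target-to-driver map, region table, seed)
#'   and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_subjects
  P <- cfg$probes_per_chromosome
  spacing <- cfg$probe_spacing
  chrom_len <- P * spacing
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  subjects <- sprintf("S%03d", seq_len(n))
  regions <- cfg$planted_regions
  n_reg <- length(regions)
  region_ids <- paste0("region_", seq_len(n_reg))

  ## histology labels: exact composition by largest remainder, shuffled
  counts <- proportion_counts(cfg$histology_proportions, n)
  labels <- sample(rep(names(cfg$histology_proportions), counts))
  names(labels) <- subjects

  ## carriers per region
  carriers <- matrix(FALSE, n, n_reg, dimnames = list(subjects, region_ids))
  for (k in seq_len(n_reg)) {
    r <- regions[[k]]
    if (is.null(r$histology_bias)) {
      n_carr <- round_half_up(r$carrier_fraction * n)
      carriers[sample(n, n_carr), k] <- TRUE
    } else {
      for (g in names(r$histology_bias)) {
        idx <- which(labels == g)
        n_g <- round_half_up(r$histology_bias[[g]] * length(idx))
        if (n_g > 0) carriers[sample(idx, n_g), k] <- TRUE
      }
    }
  }

  ## probe-level profiles: signal + iid Gaussian noise
  pos <- (seq_len(P) - 1) * spacing
  probe_chrom <- rep(chroms, each = P)
  probe_pos <- rep(pos, cfg$n_chromosomes)
  signal <- matrix(0, length(probe_pos), n)
  for (k in seq_len(n_reg)) {
    r <- regions[[k]]
    in_reg <- probe_chrom == chroms[r$chromosome] &
      probe_pos >= r$start & probe_pos < r$end
    signal[in_reg, carriers[, k]] <- signal[in_reg, carriers[, k]] +
      r$mean_amplitude
  }
  noise <- if (cfg$noise_sd_probe > 0)
    matrix(stats::rnorm(length(signal), 0, cfg$noise_sd_probe), nrow(signal))
  else 0
  values <- signal + noise
  profiles <- lapply(seq_len(n), function(s) {
    genomic_profile(subjects[s],
                    data.frame(chrom = probe_chrom, pos = probe_pos,
                               log2ratio = values[, s]))
  })
  names(profiles) <- subjects

  ## feature layout
  gene_regions <- which(vapply(regions, function(r)
    !is.null(r$driver_gene) && r$driver_type == "gene", TRUE))
  mirna_regions <- which(vapply(regions, function(r)
    !is.null(r$driver_gene) && r$driver_type == "mirna", TRUE))
  drivers <- vapply(regions[gene_regions], `[[`, "", "driver_gene")
  driver_mirnas <- vapply(regions[mirna_regions], `[[`, "", "driver_gene")

  target_ids <- list()
  for (k in gene_regions) {
    nt <- regions[[k]]$n_targets
    if (nt > 0)
      target_ids[[regions[[k]]$driver_gene]] <-
        sprintf("%s_TGT%03d", regions[[k]]$driver_gene, seq_len(nt))
  }
  bystander_ids <- unlist(lapply(seq_len(n_reg), function(k)
    sprintf("BYS%d_%d", k, seq_len(cfg$bystanders_per_region))))
  hst_ids <- if (cfg$n_histology_genes > 0)
    sprintf("HST%03d", seq_len(cfg$n_histology_genes)) else character(0)
  n_used <- length(drivers) + length(unlist(target_ids)) +
    length(bystander_ids) + length(hst_ids)
  if (cfg$n_genes < n_used)
    stop("n_genes too small for the planted features")
  bgd_ids <- sprintf("BGD%04d", seq_len(cfg$n_genes - n_used))
  gene_ids <- c(drivers, unlist(target_ids, use.names = FALSE),
                bystander_ids, hst_ids, bgd_ids)

  mirna_ids <- c(driver_mirnas,
                 sprintf("mir-bg-%03d", seq_len(cfg$n_mirnas - length(driver_mirnas))))

  ## annotation: drivers/bystanders inside their regions, everything else
  ## on evenly spaced slots outside all planted regions
  feat_w <- 2000
  region_tbl <- data.frame(
    region = region_ids,
    chrom = chroms[vapply(regions, `[[`, 1L, "chromosome")],
    start = vapply(regions, `[[`, 0, "start"),
    end = vapply(regions, `[[`, 0, "end"),
    polarity = vapply(regions, `[[`, "", "polarity"),
    mean_amplitude = vapply(regions, `[[`, 0, "mean_amplitude"),
    carrier_fraction = vapply(regions, `[[`, 0, "carrier_fraction"),
    driver = vapply(regions, function(r)
      if (is.null(r$driver_gene)) NA_character_ else r$driver_gene, ""),
    stringsAsFactors = FALSE
  )
  slot_starts <- seq(0, chrom_len - feat_w, by = 500)
  free_slots <- do.call(rbind, lapply(seq_len(cfg$n_chromosomes), function(c) {
    s <- slot_starts
    for (r in regions) {
      if (r$chromosome != c) next
      s <- s[s + feat_w <= r$start | s >= r$end]
    }
    if (length(s) == 0) return(NULL)
    data.frame(chrom = chroms[c], start = s)
  }))
  place_inside <- function(r, m) {
    # m feature starts spread inside region r
    s <- seq(r$start, r$end - feat_w, length.out = m + 2L)[-c(1L, m + 2L)]
    floor(s)
  }
  ann <- list()
  for (k in seq_along(gene_regions)) {
    r <- regions[[gene_regions[k]]]
    ann[[drivers[k]]] <- c(r$chromosome, floor((r$start + r$end) / 2) - feat_w / 2)
  }
  for (k in seq_along(mirna_regions)) {
    r <- regions[[mirna_regions[k]]]
    ann[[driver_mirnas[k]]] <- c(r$chromosome, floor((r$start + r$end) / 2) - feat_w / 2)
  }
  bys_i <- 0L
  for (k in seq_len(n_reg)) {
    st <- place_inside(regions[[k]], cfg$bystanders_per_region)
    for (b in seq_len(cfg$bystanders_per_region)) {
      bys_i <- bys_i + 1L
      ann[[bystander_ids[bys_i]]] <- c(regions[[k]]$chromosome, st[b])
    }
  }
  placed <- names(ann)
  outside <- setdiff(c(gene_ids, mirna_ids), placed)
  if (length(outside) > nrow(free_slots))
    stop("not enough genome outside planted regions to place features")
  slot_idx <- floor(seq(1, nrow(free_slots), length.out = length(outside)))
  annotation <- data.frame(
    feature = c(placed, outside),
    chrom = c(chroms[vapply(ann, `[`, 0, 1)], free_slots$chrom[slot_idx]),
    start = c(vapply(ann, `[`, 0, 2), free_slots$start[slot_idx]),
    stringsAsFactors = FALSE
  )
  annotation$end <- annotation$start + feat_w
  annotation$type <- ifelse(annotation$feature %in% mirna_ids, "mirna", "gene")
  annotation <- annotation[match(c(gene_ids, mirna_ids), annotation$feature), ]
  rownames(annotation) <- NULL

  ## expression: driver = copy-state effect + noise; targets share a scaled
  ## latent copy of the driver signal so the population driver-target
  ## correlation equals module_corr exactly
  sd_e <- cfg$noise_sd_expr
  rho <- cfg$module_corr
  expr <- matrix(0, cfg$n_genes, n, dimnames = list(gene_ids, subjects))
  module_membership <- character(0)
  for (k in seq_along(gene_regions)) {
    r <- regions[[gene_regions[k]]]
    cc <- as.numeric(carriers[, gene_regions[k]])
    d <- r$target_effect * cc + stats::rnorm(n, 0, sd_e)
    expr[drivers[k], ] <- d
    if (r$n_targets > 0) {
      pi_c <- r$carrier_fraction
      mu <- r$target_effect * pi_c
      sd_pop <- sqrt(r$target_effect^2 * pi_c * (1 - pi_c) + sd_e^2)
      z <- (d - mu) / sd_pop
      tg <- target_ids[[drivers[k]]]
      lat <- matrix(rep(z, each = r$n_targets), r$n_targets, n)
      eps <- matrix(stats::rnorm(r$n_targets * n), r$n_targets, n)
      expr[tg, ] <- sd_e * (rho * lat + sqrt(1 - rho^2) * eps)
      mm <- rep(drivers[k], r$n_targets)
      names(mm) <- tg
      module_membership <- c(module_membership, mm)
    }
  }
  bys_i <- 0L
  for (k in seq_len(n_reg)) {
    cc <- as.numeric(carriers[, k])
    eff <- sign(regions[[k]]$mean_amplitude) * cfg$bystander_effect
    for (b in seq_len(cfg$bystanders_per_region)) {
      bys_i <- bys_i + 1L
      expr[bystander_ids[bys_i], ] <- eff * cc + stats::rnorm(n, 0, sd_e)
    }
  }
  if (length(hst_ids) > 0) {
    half <- ceiling(length(hst_ids) / 2)
    for (i in seq_along(hst_ids)) {
      grp <- if (i <= half) "SCC" else "AC"
      expr[hst_ids[i], ] <- cfg$histology_effect * (labels == grp) +
        stats::rnorm(n, 0, sd_e)
    }
  }
  if (length(bgd_ids) > 0)
    expr[bgd_ids, ] <- matrix(stats::rnorm(length(bgd_ids) * n, 0, sd_e),
                              length(bgd_ids), n)

  mirna_expr <- matrix(stats::rnorm(cfg$n_mirnas * n, 0, sd_e),
                       cfg$n_mirnas, n, dimnames = list(mirna_ids, subjects))
  for (k in seq_along(mirna_regions)) {
    r <- regions[[mirna_regions[k]]]
    cc <- as.numeric(carriers[, mirna_regions[k]])
    mirna_expr[driver_mirnas[k], ] <- r$target_effect * cc +
      stats::rnorm(n, 0, sd_e)
  }

  truth <- list(
    carriers = carriers,
    planted_drivers = unname(drivers),
    planted_driver_mirnas = unname(driver_mirnas),
    module_membership = module_membership,
    histology = labels,
    regions = region_tbl,
    seed = cfg$seed
  )
  class(truth) <- "synthetic_truth"
  list(profiles = profiles, expr = expr, mirna_expr = mirna_expr,
       annotation = annotation, labels = labels, truth = truth,
       config = cfg)
}

#' Simulate a functional gene network and pathway sets with planted
#' enrichment
#'
#' Builds an Erdos-Renyi background network over the supplied genes, draws
#' pathway gene sets from the background genes, and wires extra edges
#' between each driver's target set and its matched pathway so the
#' enrichment is real and detectable.
#'
#' @param target_sets named list, driver id -> character vector of targets.
#' @param background_genes genes eligible as pathway members / noise nodes.
#' @param n_pathways total number of pathway sets (>= number of drivers).
#' @param pathway_size genes per pathway.
#' @param avg_degree mean background degree.
#' @param extra_edges planted target-pathway edges per enriched pathway.
#' @param seed integer seed.
#' @return list with `network` (igraph), `pathways` (named list of gene
#'   sets) and `planted` (driver -> enriched pathway name).
#' @export
simulate_network <- function(target_sets, background_genes, n_pathways = 8L,
                             pathway_size = 25L, avg_degree = 4,
                             extra_edges = 60L, seed = 1L) {
  stopifnot(n_pathways >= length(target_sets))
  with_seed(seed, {
    nodes <- unique(c(unlist(target_sets, use.names = FALSE), background_genes))
    n <- length(nodes)
    m <- round(avg_degree * n / 2)
    e1 <- matrix(nodes[sample.int(n, 2 * m, replace = TRUE)], ncol = 2)
    pathways <- lapply(seq_len(n_pathways), function(i)
      sample(background_genes, pathway_size))
    names(pathways) <- paste0("PW", seq_len(n_pathways))
    planted <- character(0)
    extra <- NULL
    for (i in seq_along(target_sets)) {
      d <- names(target_sets)[i]
      names(pathways)[i] <- paste0("PW_", d)
      planted[d] <- names(pathways)[i]
      extra <- rbind(extra, cbind(sample(target_sets[[i]], extra_edges, replace = TRUE),
                                  sample(pathways[[i]], extra_edges, replace = TRUE)))
    }
    g <- igraph::graph_from_edgelist(rbind(e1, extra), directed = FALSE)
    g <- igraph::simplify(g)
    list(network = g, pathways = pathways, planted = planted)
  })
}
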