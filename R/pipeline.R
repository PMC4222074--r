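# End-to-end driver-search pipeline: segmentation -> fixed-threshold
# calls -> recurrent regions -> polarity -> candidate filters -> initial
# correlation modules -> sparse CCA refinement -> final ranking ->
# histology-predictive validation -> optional network enrichment.

#' Pipeline configuration with the standard thresholds
#'
#' Defaults are the printed constants of the method: segmentation alpha
#' 0.01; fixed calling thresholds (|mean| 0.15, FDR 1e-5, 10 probes,
#' 1 kb); 10% recurrence; expression SD 0.25; Welch p 0.05 with
#' fold-change > 2 for genes (p 0.01, no fold-change rule, 10% polarity
#' mixture for miRNAs); module correlation p 0.001; final fold-change > 4
#' at p < 0.001; signature size 15; 1000 Monte-Carlo draws.
#'
#' @param seed master seed; every stage draws a named substream from it.
#' @param mode `"gene"` or `"mirna"` filtering regime.
#' @param ... override any default listed above.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, mode = c("gene", "mirna"), ...) {
  mode <- match.arg(mode)
  cfg <- list(
    seed = as.integer(seed), mode = mode,
    seg_alpha = 0.01, seg_n_perm = 1000L, seg_min_width = 2L,
    dgs_mean_threshold = 0.15, dgs_fdr_max = 1e-5,
    dgs_min_probes = 10L, dgs_min_length = 1000,
    min_recurrence = 0.10,
    mixture_tolerance = if (mode == "gene") 0 else 0.10,
    sd_threshold = 0.25,
    welch_p_max = if (mode == "gene") 0.05 else 0.01,
    min_fold_change = if (mode == "gene") 2 else NULL,
    consistency_min = 0.9,
    module_p_threshold = 0.001,
    scca_penalty = NULL,
    # the final fold-change/p thresholds belong to the gene regime; the
    # miRNA list is already final after the candidate filters and is only
    # ranked, so the miRNA defaults are vacuous bounds
    fc_final = if (mode == "gene") 4 else 1,
    p_final = if (mode == "gene") 0.001 else 1,
    signature_size = 15L, n_mc_draws = 1000L,
    nea_n_perm = 1000L, nea_desired_size = 100L)
  override <- list(...)
  bad <- setdiff(names(override), names(cfg))
  if (length(bad) > 0) stop("unknown config field(s): ",
                            paste(bad, collapse = ", "))
  cfg[names(override)] <- override
  for (f in c("seg_alpha", "dgs_mean_threshold", "dgs_fdr_max",
              "min_recurrence", "sd_threshold", "welch_p_max",
              "module_p_threshold", "fc_final", "p_final"))
    if (!is.null(cfg[[f]]) && cfg[[f]] <= 0)
      stop("configuration error: ", f, " must be positive")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full driver-search pipeline on a cohort
#'
#' @param cohort a cohort list as produced by [generate_cohort()] or
#'   [read_cohort()] (`profiles`, `expr`, `mirna_expr`, `annotation`,
#'   `labels`).
#' @param config a [pipeline_config()].
#' @param network optional `igraph` functional network for the enrichment
#'   stage.
#' @param pathways optional named list of pathway gene sets.
#' @param output_dir optional directory; when given, per-stage tables and
#'   a JSON report are written there.
#' @return a report list: survivor counts per filter (monotone), the
#'   recurrent-region table, the candidate table, module sizes before and
#'   after sparse-CCA refinement, the final driver ranking, per-driver
#'   AUC validation, and enrichment tables when a network is supplied.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         network = NULL, pathways = NULL,
                         output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  mode <- config$mode
  cand_expr <- if (mode == "gene") cohort$expr else cohort$mirna_expr
  cand_type <- if (mode == "gene") "gene" else "mirna"

  ## stage: segmentation + fixed-threshold calls
  calls <- segment_and_call_cohort(
    cohort$profiles, alpha = config$seg_alpha, n_perm = config$seg_n_perm,
    min_width = config$seg_min_width, seed = derive_seed(seed, "segmentation"),
    mean_threshold = config$dgs_mean_threshold, fdr_max = config$dgs_fdr_max,
    min_probes = config$dgs_min_probes, min_length = config$dgs_min_length)

  ## stage: recurrent regions + polarity
  regions <- find_recurrent_regions(calls, config$min_recurrence)
  if (nrow(regions) > 0) {
    pol <- classify_polarity(regions$n_dup, regions$n_del,
                             config$mixture_tolerance)
    regions$polarity <- pol$polarity
    regions$mixture_fraction <- pol$mixture_fraction
  } else {
    regions$polarity <- character(0)
    regions$mixture_fraction <- numeric(0)
  }
  pure <- regions[regions$polarity != "mixed", , drop = FALSE]

  ## stage: candidate drivers = features in pure recurrent regions
  ann <- cohort$annotation[cohort$annotation$type == cand_type, , drop = FALSE]
  region_feats <- map_features_to_regions(pure, ann)
  region_genes <- unique(unlist(region_feats))
  variable <- filter_variable_features(cand_expr, config$sd_threshold)
  candidates <- list()
  for (r in seq_len(nrow(pure))) {
    polarity <- if (pure$polarity[r] == "amp_only") "amplification" else "deletion"
    want <- if (polarity == "amplification") "dup" else "del"
    st <- pure$states[[r]]
    altered <- names(st)[st == want]
    for (f in intersect(region_feats[[r]], variable)) {
      res <- cna_expression_filter(
        cand_expr[f, ], altered, polarity,
        p_max = config$welch_p_max,
        min_fold_change = config$min_fold_change,
        consistency_min = config$consistency_min)
      candidates[[length(candidates) + 1L]] <- data.frame(
        feature = f, region = r, polarity = polarity,
        fold_change = if (is.null(res$fold_change)) NA_real_ else res$fold_change,
        welch_p = if (is.null(res$welch_p)) NA_real_ else res$welch_p,
        consistency = if (is.null(res$consistency_fraction)) NA_real_
        else res$consistency_fraction,
        retained = res$retained,
        reason = if (is.na(res$retained) || res$retained) NA_character_
        else res$reason)
    }
  }
  candidates <- if (length(candidates) > 0) do.call(rbind, candidates)
  else data.frame(feature = character(0), region = integer(0),
                  polarity = character(0), fold_change = numeric(0),
                  welch_p = numeric(0), consistency = numeric(0),
                  retained = logical(0), reason = character(0))
  retained <- candidates[candidates$retained, , drop = FALSE]
  retained <- retained[order(retained$welch_p), , drop = FALSE]
  retained <- retained[!duplicated(retained$feature), , drop = FALSE]
  drivers <- retained$feature

  ## stage: initial correlation modules (targets are the remaining
  ## variable genes; drivers never appear in another driver's target set)
  target_pool <- setdiff(filter_variable_features(cohort$expr,
                                                  config$sd_threshold),
                         if (mode == "gene") drivers else character(0))
  modules <- list()
  module_corr <- list()
  assignment <- character(0)
  if (length(drivers) > 0 && length(target_pool) > 0) {
    driver_expr <- if (mode == "gene") cohort$expr else cohort$mirna_expr
    joint <- rbind(driver_expr[drivers, , drop = FALSE],
                   cohort$expr[target_pool, , drop = FALSE])
    pc <- pairwise_driver_correlation(joint, drivers, target_pool)
    assignment <- initial_modules(pc$r, pc$p, config$module_p_threshold)
    for (d in drivers) {
      tg <- names(assignment)[assignment == d]
      if (length(tg) > 0) {
        modules[[d]] <- tg
        module_corr[[d]] <- pc$r[d, tg]
      }
    }
  }
  initial_sizes <- vapply(drivers, function(d)
    length(modules[[d]]), 0L)

  ## stage: sparse CCA refinement
  refined <- list()
  refined_corr <- list()
  scca_stats <- list()
  for (d in names(modules)) {
    X <- t((if (mode == "gene") cohort$expr else cohort$mirna_expr)[d, , drop = FALSE])
    Y <- t(cohort$expr[modules[[d]], , drop = FALSE])
    pen <- config$scca_penalty
    if (is.null(pen))
      pen <- select_scca_penalty(X, Y, seed = derive_seed(seed, paste0("scca_", d)))
    sc <- refine_module_scca(X, Y, penalty_x = 0, penalty_y = pen)
    refined[[d]] <- sc$retained
    refined_corr[[d]] <- module_corr[[d]][sc$retained]
    scca_stats[[d]] <- list(penalty = pen, cor = sc$cor,
                            n_before = length(modules[[d]]),
                            n_after = length(sc$retained))
  }

  ## stage: final ranking
  final <- rank_and_select_drivers(retained, refined,
                                   fc_final = config$fc_final,
                                   p_final = config$p_final)

  ## stage: histology-predictive validation (AC vs SCC)
  validation <- data.frame(feature = character(0), auc = numeric(0),
                           p_value = numeric(0))
  acscc <- names(cohort$labels)[cohort$labels %in% c("AC", "SCC")]
  if (nrow(final) > 0 && length(acscc) > 3) {
    vexpr <- cand_expr[, acscc, drop = FALSE]
    vlab <- factor(cohort$labels[acscc], levels = c("AC", "SCC"))
    validation <- do.call(rbind, lapply(seq_len(nrow(final)), function(i) {
      f <- final$feature[i]
      res <- single_feature_auc_test(
        vexpr, f, vlab, n_draws = config$n_mc_draws,
        seed = derive_seed(seed, paste0("val_", f)))
      data.frame(feature = f, auc = res$auc, p_value = res$p_value)
    }))
  }

  ## stage: network enrichment of final drivers' target sets
  nea <- NULL
  if (!is.null(network) && !is.null(pathways) && nrow(final) > 0) {
    nea <- lapply(final$feature, function(d) {
      if (is.null(refined_corr[[d]]) || length(refined_corr[[d]]) == 0)
        return(NULL)
      sel <- select_targets_for_nea(refined_corr[[d]],
                                    desired_size = config$nea_desired_size,
                                    mirna = (mode == "mirna"))
      res <- nea_test(sel$targets, pathways, network,
                      n_perm = config$nea_n_perm,
                      seed = derive_seed(seed, paste0("nea_", d)))
      res$driver <- d
      res$cutoff <- sel$cutoff
      res
    })
    names(nea) <- final$feature
    nea <- nea[!vapply(nea, is.null, TRUE)]
  }

  report <- list(
    seed = seed, mode = mode,
    counts = list(
      n_subjects = length(cohort$profiles),
      n_calls = nrow(calls),
      n_subjects_with_calls = length(unique(calls$subject)),
      n_recurrent_regions = nrow(regions),
      n_pure_regions = nrow(pure),
      n_region_features = length(region_genes),
      n_after_variability = length(intersect(region_genes, variable)),
      n_retained_candidates = length(drivers),
      n_final_drivers = nrow(final)),
    regions = regions[, setdiff(names(regions), "states")],
    candidates = candidates,
    module_sizes = data.frame(
      driver = drivers,
      initial = unname(initial_sizes),
      refined = vapply(drivers, function(d)
        length(refined[[d]]), 0L)),
    modules = refined,
    module_corr = refined_corr,
    scca = scca_stats,
    final_drivers = final,
    validation = validation,
    nea = nea,
    config = unclass(config))

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      report[c("seed", "mode", "counts", "final_drivers", "validation")],
      file.path(output_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    utils::write.table(candidates, file.path(output_dir, "candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(report$regions, file.path(output_dir, "regions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}
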