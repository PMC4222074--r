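# Cohort-level recurrent-region discovery, polarity classification,
# histology-differential ANOVA and 1%-tolerance cluster merging.

#' Find recurrent CNA regions across a cohort
#'
#' The genome is partitioned at the union of all call breakpoints; maximal
#' runs of contiguous atoms over which the per-subject state assignment
#' (which subjects are altered, and how) stays constant are merged into
#' regions. A region is recurrent when its altered-subject count reaches
#' `min_recurrence` of the eligible denominator: subjects with at least one
#' call anywhere. The count threshold is `round(min_recurrence * n)` with
#' conventional half-up rounding, so e.g. 12 of 121 subjects qualifies at
#' 10%.
#'
#' @param calls data frame with columns `subject`, `chrom`, `start`,
#'   `end_open` (0-based half-open interval bounds) and `state` (any of
#'   `dup`/`gain`/`amplification` count as duplication, `del`/`loss` as
#'   deletion).
#' @param min_recurrence minimum recurrence fraction (default 0.10).
#' @return data frame with one row per recurrent region: `chrom`, `start`,
#'   `end` (half-open), `n_altered`, `n_dup`, `n_del`, `recurrence`, and a
#'   list-column `states` (named per-subject state vectors).
#' @export
find_recurrent_regions <- function(calls, min_recurrence = 0.10) {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_altered = integer(0),
                      n_dup = integer(0), n_del = integer(0),
                      recurrence = numeric(0))
  empty$states <- list()
  if (is.null(calls) || nrow(calls) == 0) return(empty)
  stopifnot(all(c("subject", "chrom", "start", "end_open", "state") %in%
                  names(calls)))
  calls$polarity <- state_polarity(calls$state)
  denom <- length(unique(calls$subject))
  threshold <- max(1, round_half_up(min_recurrence * denom))
  out <- list()
  for (ch in unique(calls$chrom)) {
    cc <- calls[calls$chrom == ch, ]
    bks <- sort(unique(c(cc$start, cc$end_open)))
    if (length(bks) < 2) next
    n_atom <- length(bks) - 1L
    keys <- character(n_atom)
    states_by_atom <- vector("list", n_atom)
    for (a in seq_len(n_atom)) {
      lo <- bks[a]; hi <- bks[a + 1L]
      hit <- cc$start <= lo & cc$end_open >= hi
      if (!any(hit)) { keys[a] <- ""; next }
      sub <- cc[hit, ]
      sub <- sub[!duplicated(sub$subject), ]
      o <- order(sub$subject)
      st <- sub$polarity[o]
      names(st) <- sub$subject[o]
      states_by_atom[[a]] <- st
      keys[a] <- paste(names(st), st, sep = ":", collapse = ";")
    }
    run_id <- cumsum(c(TRUE, keys[-1] != keys[-n_atom]))
    for (r in unique(run_id)) {
      idx <- which(run_id == r)
      if (keys[idx[1]] == "") next
      st <- states_by_atom[[idx[1]]]
      n_alt <- length(st)
      if (n_alt < threshold) next
      out[[length(out) + 1L]] <- list(
        chrom = ch, start = bks[idx[1]], end = bks[idx[length(idx)] + 1L],
        n_altered = n_alt, n_dup = sum(st == "dup"), n_del = sum(st == "del"),
        recurrence = n_alt / denom, states = st)
    }
  }
  if (length(out) == 0) return(empty)
  res <- data.frame(
    chrom = vapply(out, `[[`, "", "chrom"),
    start = vapply(out, `[[`, 0, "start"),
    end = vapply(out, `[[`, 0, "end"),
    n_altered = vapply(out, `[[`, 0L, "n_altered"),
    n_dup = vapply(out, `[[`, 0L, "n_dup"),
    n_del = vapply(out, `[[`, 0L, "n_del"),
    recurrence = vapply(out, `[[`, 0, "recurrence"),
    stringsAsFactors = FALSE
  )
  res$states <- lapply(out, `[[`, "states")
  res <- res[order(res$chrom, res$start), ]
  rownames(res) <- NULL
  res
}

# Map call states onto the dup/del polarity vocabulary.
state_polarity <- function(state) {
  out <- ifelse(state %in% c("dup", "gain", "amplification"), "dup",
                ifelse(state %in% c("del", "loss"), "del", NA_character_))
  if (any(is.na(out))) stop("unknown call state(s): ",
                            paste(unique(state[is.na(out)]), collapse = ", "))
  out
}

#' Classify the polarity of a recurrent region
#'
#' A region is pure (`amp_only`/`del_only`) when the minority-polarity
#' fraction among its altered subjects is zero or strictly below
#' `mixture_tolerance`; otherwise `mixed`. Tolerance 0 is the strict rule
#' used for genes; 0.10 is the relaxed rule used for miRNAs.
#'
#' @param n_dup,n_del counts of duplicated/deleted subjects (vectorized).
#' @param mixture_tolerance allowed minority fraction, in `[0, 0.5)`.
#' @return data frame with `polarity` and `mixture_fraction`.
#' @export
classify_polarity <- function(n_dup, n_del, mixture_tolerance = 0) {
  if (mixture_tolerance < 0 || mixture_tolerance >= 0.5)
    stop("configuration error: mixture_tolerance must be in [0, 0.5)")
  n_alt <- n_dup + n_del
  if (any(n_alt == 0)) stop("region with no altered subjects")
  minority <- pmin(n_dup, n_del) / n_alt
  pure <- minority == 0 | minority < mixture_tolerance
  polarity <- ifelse(!pure, "mixed",
                     ifelse(n_dup >= n_del, "amp_only", "del_only"))
  data.frame(polarity = polarity, mixture_fraction = minority)
}

#' Segmented per-subject mean log2 ratio inside regions
#'
#' Assigns each probe its segment mean (the segmented dataset) and averages
#' those values over the probes falling inside each region, giving the
#' region x subject matrix the differential ANOVA runs on.
#'
#' @param profiles named list of [genomic_profile()] objects.
#' @param segments_list matching named list of [segment_profile()] outputs.
#' @param regions data frame with `chrom`, `start`, `end` (half-open).
#' @return numeric matrix, regions x subjects (NA where a subject has no
#'   probe in a region).
#' @export
region_mean_matrix <- function(profiles, segments_list, regions) {
  stopifnot(length(profiles) == length(segments_list))
  subjects <- vapply(profiles, `[[`, "", "subject")
  mat <- matrix(NA_real_, nrow(regions), length(profiles),
                dimnames = list(NULL, subjects))
  for (s in seq_along(profiles)) {
    pr <- profiles[[s]]$probes
    seg <- segments_list[[s]]
    segval <- rep(NA_real_, nrow(pr))
    for (k in seq_len(nrow(seg))) {
      sel <- pr$chrom == seg$chrom[k] & pr$pos >= seg$start[k] &
        pr$pos <= seg$end[k]
      segval[sel] <- seg$mean[k]
    }
    for (r in seq_len(nrow(regions))) {
      sel <- pr$chrom == regions$chrom[r] & pr$pos >= regions$start[r] &
        pr$pos < regions$end[r]
      if (any(sel)) mat[r, s] <- mean(segval[sel], na.rm = TRUE)
    }
  }
  mat
}

#' One-way ANOVA for histology-differential regions
#'
#' Per region, a one-way F test of the segmented mean log2 ratio across
#' histology groups, BH-adjusted across regions. Regions without at least
#' two groups of two or more subjects get NA.
#'
#' @param region_means regions x subjects matrix (see
#'   [region_mean_matrix()]).
#' @param labels named histology vector aligned with the columns.
#' @param fdr_threshold significance cutoff on the BH-adjusted p-value.
#' @return data frame with `F`, `p`, `fdr`, `significant` per region.
#' @export
anova_differential_regions <- function(region_means, labels,
                                       fdr_threshold = 1e-5) {
  labels <- labels[colnames(region_means)]
  res <- t(vapply(seq_len(nrow(region_means)), function(r) {
    y <- region_means[r, ]
    ok <- is.finite(y)
    y <- y[ok]; g <- factor(labels[ok])
    tab <- table(g)
    tab <- tab[tab >= 2]
    if (length(tab) < 2) return(c(NA_real_, NA_real_))
    keep <- g %in% names(tab)
    y <- y[keep]; g <- droplevels(g[keep])
    n <- length(y); k <- nlevels(g)
    gm <- tapply(y, g, mean)
    ssb <- sum(tapply(y, g, length) * (gm - mean(y))^2)
    ssw <- sum((y - gm[g])^2)
    if (ssw < 1e-24) {
      if (ssb < 1e-24) return(c(0, 1))
      return(c(Inf, 0))
    }
    f <- (ssb / (k - 1)) / (ssw / (n - k))
    c(f, stats::pf(f, k - 1, n - k, lower.tail = FALSE))
  }, numeric(2)))
  out <- data.frame(F = res[, 1], p = res[, 2])
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$fdr) & out$fdr < fdr_threshold
  out
}

#' Per-region aberration frequencies by state and histology group
#'
#' @param regions output of [find_recurrent_regions()] (needs the `states`
#'   list-column).
#' @param labels named histology vector for all cohort subjects.
#' @return matrix regions x (state, group) of percentages of each group's
#'   subjects altered with that state.
#' @export
region_state_frequencies <- function(regions, labels) {
  groups <- sort(unique(labels))
  cols <- as.vector(outer(c("dup", "del"), groups, paste, sep = "."))
  mat <- matrix(0, nrow(regions), length(cols),
                dimnames = list(NULL, cols))
  for (r in seq_len(nrow(regions))) {
    st <- regions$states[[r]]
    for (g in groups) {
      members <- names(labels)[labels == g]
      n_g <- length(members)
      mat[r, paste0("dup.", g)] <-
        100 * sum(names(st) %in% members & st == "dup") / n_g
      mat[r, paste0("del.", g)] <-
        100 * sum(names(st) %in% members & st == "del") / n_g
    }
  }
  mat
}

#' Merge adjacent differential regions into clusters
#'
#' Greedy left-to-right merge of genomically ordered regions: a region
#' joins the running cluster while every (state, histology) aberration
#' frequency stays within `tolerance` percentage points of the cluster's
#' first (anchor) region. Clusters never span chromosomes.
#'
#' @param regions data frame ordered by (chrom, start) with `chrom`,
#'   `start`, `end`.
#' @param freqs matching frequency matrix in percent (see
#'   [region_state_frequencies()]).
#' @param tolerance maximum allowed deviation, percentage points.
#' @return data frame of clusters: `chrom`, `start`, `end`, `n_regions`,
#'   `members` (list-column of row indices).
#' @export
merge_into_clusters <- function(regions, freqs, tolerance = 1) {
  n <- nrow(regions)
  if (n == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_regions = integer(0)))
  cluster <- integer(n)
  cluster[1] <- 1L
  anchor <- 1L
  for (r in seq_len(n)[-1]) {
    same_chrom <- regions$chrom[r] == regions$chrom[anchor]
    within <- all(abs(freqs[r, ] - freqs[anchor, ]) <= tolerance)
    if (same_chrom && within) {
      cluster[r] <- cluster[r - 1L]
    } else {
      cluster[r] <- cluster[r - 1L] + 1L
      anchor <- r
    }
  }
  cl <- factor(cluster, levels = unique(cluster))
  out <- do.call(rbind, lapply(split(seq_len(n), cl), function(idx) {
    data.frame(chrom = regions$chrom[idx[1]],
               start = min(regions$start[idx]),
               end = max(regions$end[idx]),
               n_regions = length(idx))
  }))
  out$members <- split(seq_len(n), cl)
  rownames(out) <- NULL
  out
}

#' Assign annotated features to regions by interval overlap
#'
#' Half-open arithmetic: feature `[fs, fe)` overlaps region `[rs, re)` iff
#' they share at least one base on the same chromosome.
#'
#' @param regions data frame with `chrom`, `start`, `end` (half-open).
#' @param annotation data frame with `feature`, `chrom`, `start`, `end`.
#' @param known_chromosomes optional vector of valid chromosome names;
#'   annotation rows on other chromosomes are skipped with a warning.
#' @return list of length `nrow(regions)`; each element the character
#'   vector of overlapping feature ids.
#' @export
map_features_to_regions <- function(regions, annotation,
                                    known_chromosomes = NULL) {
  if (!is.null(known_chromosomes)) {
    bad <- !(annotation$chrom %in% known_chromosomes)
    if (any(bad)) {
      warning("skipping ", sum(bad),
              " feature(s) on unknown chromosome(s): ",
              paste(unique(annotation$chrom[bad]), collapse = ", "))
      annotation <- annotation[!bad, ]
    }
  }
  lapply(seq_len(nrow(regions)), function(r) {
    hit <- annotation$chrom == regions$chrom[r] &
      annotation$start < regions$end[r] &
      regions$start[r] < annotation$end
    annotation$feature[hit]
  })
}
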