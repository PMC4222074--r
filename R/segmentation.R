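# Per-subject segmentation of log2-ratio profiles and CNA calling.
#
# Two calling regimes are supported, matching the two uses downstream:
#  * call_aberrations(): noise-adaptive calls (per-profile amplitude
#    threshold = the profile's internal noise; >= 3 consecutive probes),
#    used for frequency/ANOVA summaries, with amplification flagged at
#    log2 ratio > 1.0;
#  * call_cna_dgs(): fixed-threshold filtered calls (|mean| >= 0.15,
#    per-segment FDR < 1e-5, >= 10 probes, >= 1 kb), the input to
#    recurrent-region detection in the driver search.

#' Construct a per-subject genomic profile
#'
#' @param subject subject id.
#' @param probes data frame with columns `chrom`, `pos` (bases, strictly
#'   increasing within chromosome) and `log2ratio` (finite).
#' @return an object of class `genomic_profile`.
#' @export
genomic_profile <- function(subject, probes) {
  stopifnot(is.data.frame(probes),
            all(c("chrom", "pos", "log2ratio") %in% names(probes)))
  if (!all(is.finite(probes$log2ratio)))
    stop("log2ratio values must be finite")
  for (ch in unique(probes$chrom)) {
    p <- probes$pos[probes$chrom == ch]
    if (any(diff(p) <= 0))
      stop("probe positions must be strictly increasing within chromosome ", ch)
  }
  structure(list(subject = subject, probes = probes),
            class = "genomic_profile")
}

#' @export
print.genomic_profile <- function(x, ...) {
  cat("<genomic_profile>", x$subject, ":", nrow(x$probes), "probes on",
      length(unique(x$probes$chrom)), "chromosomes\n")
  invisible(x)
}

#' Internal noise of a profile
#'
#' One-fourth of the median absolute difference between consecutive probe
#' log2 ratios, with differences taken within chromosomes only and pooled
#' across chromosomes. Used as the per-profile amplitude threshold for
#' noise-adaptive calling.
#'
#' @param profile a [genomic_profile()].
#' @return noise estimate in log2 units.
#' @export
profile_noise <- function(profile) {
  stopifnot(inherits(profile, "genomic_profile"))
  d <- unlist(lapply(split(profile$probes$log2ratio, profile$probes$chrom),
                     diff), use.names = FALSE)
  if (length(d) == 0)
    stop("undefined noise: need at least 2 probes on some chromosome")
  stats::median(abs(d)) / 4
}

# Recursive CBS on one chromosome's values; returns sorted breakpoints
# (index after which a boundary falls, within 1..n-1).
cbs_breakpoints <- function(x, alpha, n_perm, min_width) {
  n <- length(x)
  if (n < 2L * min_width) return(integer(0))
  if (max(x) - min(x) < 1e-12) return(integer(0))
  res <- .cbs_scan(x, n_perm, min_width)
  if (is.na(res$i) || res$p >= alpha) return(integer(0))
  i <- res$i; j <- res$j  # arc is (i, j], 0-based boundaries
  bks <- integer(0)
  if (i > 0L) bks <- c(bks, i)
  if (j < n) bks <- c(bks, j)
  pieces <- list()
  lo <- 1L
  for (b in c(bks, n)) {
    pieces[[length(pieces) + 1L]] <- c(lo, b)
    lo <- b + 1L
  }
  out <- bks
  for (p in pieces) {
    sub <- cbs_breakpoints(x[p[1]:p[2]], alpha, n_perm, min_width)
    out <- c(out, sub + p[1] - 1L)
  }
  sort(unique(out))
}

#' Segment a profile with circular binary segmentation
#'
#' Recursive binary splitting per chromosome. Each candidate split is the
#' circular arc maximizing a mean-shift t-like statistic and is accepted
#' when its permutation p-value falls below `alpha`. Segment means are
#' arithmetic means of member probes. Deterministic given `seed`.
#'
#' @param profile a [genomic_profile()].
#' @param alpha permutation significance level for accepting a split.
#' @param n_perm permutations per scan.
#' @param min_width minimum segment width in probes.
#' @param seed integer seed for the permutation stream (NULL = current RNG).
#' @return data frame with columns `chrom`, `start`, `end` (positions of
#'   the first/last member probe), `end_open` (half-open right bound: the
#'   next segment's first probe position, or last position + median
#'   spacing), `n_probes`, `mean`.
#' @export
segment_profile <- function(profile, alpha = 0.01, n_perm = 1000L,
                            min_width = 2L, seed = NULL) {
  stopifnot(inherits(profile, "genomic_profile"))
  with_seed(seed, {
    out <- lapply(split(profile$probes, profile$probes$chrom), function(pr) {
      pr <- pr[order(pr$pos), ]
      x <- pr$log2ratio
      n <- length(x)
      bks <- cbs_breakpoints(x, alpha, n_perm, min_width)
      starts <- c(1L, bks + 1L)
      ends <- c(bks, n)
      spacing <- if (n > 1) stats::median(diff(pr$pos)) else 1
      data.frame(
        chrom = pr$chrom[1],
        start = pr$pos[starts],
        end = pr$pos[ends],
        end_open = c(pr$pos[starts[-1]], pr$pos[n] + spacing),
        n_probes = ends - starts + 1L,
        mean = vapply(seq_along(starts), function(k)
          mean(x[starts[k]:ends[k]]), 0)
      )
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}

#' Per-segment p-values and FDR against zero
#'
#' Two-sided one-sample t-test of each segment's member probe log2 ratios
#' against 0, BH-adjusted across all segments of the profile. Degenerate
#' segments (zero within-segment variance) get p = 0 when their mean is
#' nonzero and p = 1 otherwise; single-probe segments get NA.
#'
#' @param profile the [genomic_profile()] the segments came from.
#' @param segments output of [segment_profile()].
#' @return `segments` with columns `p` and `fdr` appended.
#' @export
segment_fdr <- function(profile, segments) {
  pr <- profile$probes
  p <- vapply(seq_len(nrow(segments)), function(k) {
    sel <- pr$chrom == segments$chrom[k] &
      pr$pos >= segments$start[k] & pr$pos <= segments$end[k]
    x <- pr$log2ratio[sel]
    if (length(x) < 2) return(NA_real_)
    if (stats::sd(x) < 1e-12) return(if (abs(mean(x)) > 1e-12) 0 else 1)
    stats::t.test(x, mu = 0)$p.value
  }, 0)
  segments$p <- p
  segments$fdr <- stats::p.adjust(p, method = "BH")
  segments
}

#' Noise-adaptive aberration calls
#'
#' Keeps segments with at least `min_probes` probes and |mean| strictly
#' above the profile noise; state is `gain`/`loss` by sign, upgraded to
#' `amplification` when the mean exceeds 1.0 log2 units.
#'
#' @param segments output of [segment_profile()] (optionally with FDR).
#' @param noise per-profile amplitude threshold, typically
#'   [profile_noise()]; must be >= 0.
#' @param min_probes minimum consecutive probes.
#' @return the called subset of `segments` with a `state` column.
#' @export
call_aberrations <- function(segments, noise, min_probes = 3L) {
  stopifnot(noise >= 0)
  keep <- segments$n_probes >= min_probes & abs(segments$mean) > noise
  out <- segments[keep, , drop = FALSE]
  out$state <- ifelse(out$mean > 1.0, "amplification",
                      ifelse(out$mean > 0, "gain", "loss"))
  rownames(out) <- NULL
  out
}

#' Fixed-threshold filtered calls for the driver search
#'
#' Retains segments satisfying all four conditions: |mean| >= the
#' amplitude threshold (0.15 by default, duplications positive, deletions
#' negative), per-segment FDR strictly below `fdr_max`, at least
#' `min_probes` probes, and length (end - start in bases) of at least
#' `min_length`. State is `dup`/`del` by sign.
#'
#' @param segments segments with an `fdr` column (see [segment_fdr()]).
#' @param mean_threshold amplitude threshold (> 0).
#' @param fdr_max FDR cutoff (strict).
#' @param min_probes minimum probe count.
#' @param min_length minimum segment length in bases.
#' @return the retained calls with a `state` column.
#' @export
call_cna_dgs <- function(segments, mean_threshold = 0.15, fdr_max = 1e-5,
                         min_probes = 10L, min_length = 1000) {
  if (mean_threshold <= 0 || min_length <= 0 || min_probes <= 0 || fdr_max <= 0)
    stop("configuration error: thresholds must be positive")
  if (is.null(segments$fdr))
    stop("segments need an 'fdr' column; run segment_fdr() first")
  keep <- abs(segments$mean) >= mean_threshold &
    !is.na(segments$fdr) & segments$fdr < fdr_max &
    segments$n_probes >= min_probes &
    (segments$end - segments$start) >= min_length
  out <- segments[keep, , drop = FALSE]
  out$state <- ifelse(out$mean > 0, "dup", "del")
  rownames(out) <- NULL
  out
}

#' Segment and call one cohort of profiles under the driver-search regime
#'
#' Convenience wrapper: segments every profile (seeded substream per
#' subject), computes per-segment FDRs, applies [call_cna_dgs()], and
#' stacks the calls with a `subject` column.
#'
#' @param profiles named list of [genomic_profile()] objects.
#' @param alpha,n_perm,min_width passed to [segment_profile()].
#' @param seed master seed; per-subject streams are derived from it.
#' @param ... passed to [call_cna_dgs()].
#' @return data frame of calls across subjects.
#' @export
segment_and_call_cohort <- function(profiles, alpha = 0.01, n_perm = 1000L,
                                    min_width = 2L, seed = 1L, ...) {
  calls <- lapply(profiles, function(pf) {
    seg <- segment_profile(pf, alpha = alpha, n_perm = n_perm,
                           min_width = min_width,
                           seed = derive_seed(seed, paste0("seg_", pf$subject)))
    seg <- segment_fdr(pf, seg)
    cl <- call_cna_dgs(seg, ...)
    if (nrow(cl) > 0) cl$subject <- pf$subject
    cl
  })
  calls <- calls[vapply(calls, nrow, 0L) > 0]
  if (length(calls) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), end_open = numeric(0),
                      n_probes = integer(0), mean = numeric(0),
                      p = numeric(0), fdr = numeric(0),
                      state = character(0), subject = character(0)))
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}
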