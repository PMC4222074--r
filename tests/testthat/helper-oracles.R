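# Independent brute-force oracles used by the unit and acceptance tests.
# They deliberately share no code with the implementation they check.

# AUC by exhaustive positive-negative pair counting (ties score 0.5).
oracle_auc <- function(scores, labels) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  total <- 0
  for (i in pos) for (j in neg) {
    total <- total + if (scores[i] > scores[j]) 1
    else if (scores[i] == scores[j]) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Fixed-threshold call filter applied one condition at a time.
oracle_dgs_filter <- function(seg) {
  keep <- logical(nrow(seg))
  for (k in seq_len(nrow(seg))) {
    ok <- abs(seg$mean[k]) >= 0.15
    ok <- ok && !is.na(seg$fdr[k]) && seg$fdr[k] < 1e-5
    ok <- ok && seg$n_probes[k] >= 10
    ok <- ok && (seg$end[k] - seg$start[k]) >= 1000
    keep[k] <- ok
  }
  keep
}

# Recurrent regions by a per-base scan: for every base of a small genome,
# record the (subject -> polarity) assignment; maximal runs of a constant
# non-empty assignment are regions, kept at the count threshold.
oracle_recurrent_regions <- function(calls, min_recurrence = 0.10,
                                     genome_length = 500) {
  denom <- length(unique(calls$subject))
  thr <- max(1, floor(min_recurrence * denom + 0.5))
  out <- NULL
  for (ch in unique(calls$chrom)) {
    cc <- calls[calls$chrom == ch, ]
    pol <- ifelse(cc$state %in% c("dup", "gain", "amplification"),
                  "dup", "del")
    keys <- character(genome_length)
    for (b in seq_len(genome_length)) {
      pos <- b - 1
      hit <- which(cc$start <= pos & pos < cc$end_open)
      hit <- hit[!duplicated(cc$subject[hit])]
      if (length(hit) == 0) next
      o <- order(cc$subject[hit])
      keys[b] <- paste(cc$subject[hit][o], pol[hit][o],
                       sep = ":", collapse = ";")
    }
    b <- 1
    while (b <= genome_length) {
      if (keys[b] == "") { b <- b + 1; next }
      e <- b
      while (e < genome_length && keys[e + 1] == keys[b]) e <- e + 1
      n_alt <- length(strsplit(keys[b], ";")[[1]])
      if (n_alt >= thr)
        out <- rbind(out, data.frame(chrom = ch, start = b - 1, end = e,
                                     n_altered = n_alt))
      b <- e + 1
    }
  }
  if (is.null(out)) return(data.frame(chrom = character(0),
                                      start = numeric(0), end = numeric(0),
                                      n_altered = integer(0)))
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

# Random call set on a tiny integer-coordinate genome for the oracle test.
random_call_set <- function(n_subjects = 6, n_calls = 10,
                            genome_length = 500, chroms = c("cA", "cB")) {
  starts <- sample(0:(genome_length - 20), n_calls, replace = TRUE)
  width <- sample(5:120, n_calls, replace = TRUE)
  data.frame(
    subject = sample(paste0("s", seq_len(n_subjects)), n_calls, replace = TRUE),
    chrom = sample(chroms, n_calls, replace = TRUE),
    start = starts,
    end_open = pmin(starts + width, genome_length),
    state = sample(c("dup", "del"), n_calls, replace = TRUE))
}

# Edge count between two sets by exhaustive edge enumeration.
oracle_count_links <- function(setA, setB, edge_mat) {
  n <- 0
  for (k in seq_len(nrow(edge_mat))) {
    a <- edge_mat[k, 1]; b <- edge_mat[k, 2]
    if ((a %in% setA && b %in% setB) || (a %in% setB && b %in% setA))
      n <- n + 1
  }
  n
}
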