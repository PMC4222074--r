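# Network enrichment analysis of driver target sets against pathway gene
# sets on a functional-coupling network, with a degree-preserving
# permutation null.

#' Build a gene network from an edge table
#'
#' Undirected simple graph: self-loops and duplicate edges are removed.
#'
#' @param edges two-column matrix or data frame of gene pairs.
#' @return an `igraph` object.
#' @export
gene_network <- function(edges) {
  el <- as.matrix(edges)[, 1:2, drop = FALSE]
  mode(el) <- "character"
  igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))
}

#' Count network links between two gene sets
#'
#' Number of edges with one endpoint in `setA` and the other in `setB`;
#' an edge lying inside the intersection of the two sets is counted once
#' (set `double_count_overlap = TRUE` to count such edges twice).
#'
#' @param setA,setB character gene sets.
#' @param network an `igraph` network.
#' @param double_count_overlap count edges internal to the intersection
#'   twice.
#' @return integer edge count.
#' @export
count_links <- function(setA, setB, network,
                        double_count_overlap = FALSE) {
  nodes <- igraph::V(network)$name
  setA <- intersect(setA, nodes)
  setB <- intersect(setB, nodes)
  if (length(setA) == 0 && length(setB) == 0)
    stop("both sets are empty on the network")
  el <- igraph::as_edgelist(network)
  a1 <- el[, 1] %in% setA; b1 <- el[, 1] %in% setB
  a2 <- el[, 2] %in% setA; b2 <- el[, 2] %in% setB
  cross <- (a1 & b2) | (b1 & a2)
  n <- sum(cross)
  if (double_count_overlap) n <- n + sum(a1 & b1 & a2 & b2)
  as.integer(n)
}

# Vectorized cross-set edge counts for a list of pathway sets against one
# target set, given an edge list (character matrix).
count_links_el <- function(el, target_set, pathway_sets) {
  inA1 <- el[, 1] %in% target_set
  inA2 <- el[, 2] %in% target_set
  vapply(pathway_sets, function(pw) {
    b1 <- el[, 1] %in% pw
    b2 <- el[, 2] %in% pw
    sum((inA1 & b2) | (b1 & inA2))
  }, 0)
}

#' Network enrichment test with a degree-preserving permutation null
#'
#' For each pathway set, the observed number of network links to the
#' target set is compared with its distribution over degree-preserving
#' rewirings of the network (double-edge swaps, `rewire_factor x |edges|`
#' swap attempts per permutation). Reports the permutation z-score, the
#' one-sided upper add-one p-value and BH-adjusted FDR across testable
#' pathways. A closed-form `"binomial"` mode approximates the null with a
#' configuration-model expectation and a Poisson upper tail; it is faster
#' but cruder and is cross-checked against the permutation mode in the
#' test-suite.
#'
#' @param target_set character vector of target genes.
#' @param pathway_sets named list of pathway gene sets.
#' @param network `igraph` network.
#' @param n_perm permutations (permutation mode).
#' @param seed integer seed.
#' @param method `"permutation"` or `"binomial"`.
#' @param rewire_factor swap attempts per edge per permutation.
#' @return data frame with `pathway`, `n_genes` (on network),
#'   `observed_links`, `expected_links`, `z`, `p`, `fdr`, `testable`.
#' @export
nea_test <- function(target_set, pathway_sets, network, n_perm = 1000L,
                     seed = 1L, method = c("permutation", "binomial"),
                     rewire_factor = 10) {
  method <- match.arg(method)
  nodes <- igraph::V(network)$name
  target_set <- intersect(unique(target_set), nodes)
  if (length(target_set) == 0) stop("target set is empty on the network")
  pw_on <- lapply(pathway_sets, function(pw) intersect(unique(pw), nodes))
  testable <- vapply(pw_on, length, 0L) > 0
  el <- igraph::as_edgelist(network)
  obs <- count_links_el(el, target_set, pw_on)
  n_pw <- length(pw_on)

  if (method == "permutation") {
    m <- igraph::ecount(network)
    null <- with_seed(derive_seed(seed, "nea_perm"), {
      vapply(seq_len(n_perm), function(b) {
        g2 <- igraph::rewire(
          network, igraph::keeping_degseq(niter = ceiling(rewire_factor * m)))
        count_links_el(igraph::as_edgelist(g2), target_set, pw_on)
      }, numeric(n_pw))
    })
    null <- if (n_pw == 1L) matrix(null, ncol = 1L) else t(null)
    mu <- colMeans(null)
    sdev <- apply(null, 2, stats::sd)
    z <- ifelse(sdev > 0, (obs - mu) / sdev,
                ifelse(obs == mu, 0, sign(obs - mu) * Inf))
    p <- (1 + colSums(sweep(null, 2, obs, ">="))) / (n_perm + 1)
    expected <- mu
  } else {
    deg <- igraph::degree(network)
    m <- igraph::ecount(network)
    expected <- vapply(pw_on, function(pw) {
      if (length(pw) == 0) return(NA_real_)
      DA <- sum(deg[target_set]); DB <- sum(deg[pw])
      I <- intersect(target_set, pw)
      O <- DA * DB - sum(deg[I]^2)
      S_II <- (sum(deg[I])^2 - sum(deg[I]^2)) / 2
      (O - S_II) / (2 * m)
    }, 0)
    z <- (obs - expected) / sqrt(pmax(expected, .Machine$double.eps))
    p <- stats::ppois(obs - 1, lambda = expected, lower.tail = FALSE)
  }
  p[!testable] <- NA_real_
  z[!testable] <- NA_real_
  fdr <- rep(NA_real_, n_pw)
  fdr[testable] <- stats::p.adjust(p[testable], method = "BH")
  data.frame(pathway = names(pathway_sets),
             n_genes = vapply(pw_on, length, 0L),
             observed_links = as.integer(obs),
             expected_links = unname(expected),
             z = unname(z), p = unname(p), fdr = fdr,
             testable = testable, row.names = NULL)
}

#' Select a driver's targets for network enrichment
#'
#' Picks the smallest correlation cutoff on the grid whose target count is
#' at most `desired_size` (around 100 by convention) and returns that
#' target set with the cutoff used. If the whole module already fits, the
#' grid minimum is reported and the full module returned. miRNA modules
#' bypass correlation filtering (miRNA-target expression need not be
#' correlated) and are returned unchanged.
#'
#' @param target_corr named per-target correlations with the driver.
#' @param desired_size target set size aimed for.
#' @param grid increasing correlation cutoffs to try.
#' @param mirna bypass the correlation filter.
#' @return list with `targets` and `cutoff` (NA in miRNA mode).
#' @export
select_targets_for_nea <- function(target_corr, desired_size = 100L,
                                   grid = seq(0.3, 0.9, by = 0.05),
                                   mirna = FALSE) {
  if (length(target_corr) == 0) stop("empty module")
  if (mirna)
    return(list(targets = names(target_corr), cutoff = NA_real_))
  if (length(target_corr) <= desired_size)
    return(list(targets = names(target_corr), cutoff = min(grid)))
  counts <- vapply(grid, function(th) sum(abs(target_corr) >= th), 0L)
  ok <- which(counts <= desired_size)
  cutoff <- if (length(ok) > 0) grid[ok[1]] else grid[length(grid)]
  list(targets = names(target_corr)[abs(target_corr) >= cutoff],
       cutoff = cutoff)
}
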