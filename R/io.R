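# Readers and writers for the standard text formats the pipeline speaks:
# SEG tables, feature-by-subject TSV matrices, BED annotation, GMT gene
# sets, edge lists, and the JSON ground-truth file. Coordinates are
# normalized to 0-based half-open internally; SEG keeps its native
# closed-on-probe convention on disk.

read_table_checked <- function(path, n_cols, what) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) == 0) stop(path, ": empty ", what, " file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 0L) < n_cols)
  if (length(bad) > 0)
    stop(path, ": malformed ", what, " line ", bad[1],
         " (expected >= ", n_cols, " tab-separated fields)")
  lines
}

#' Read / write SEG files
#'
#' Tab-separated segmented copy-number tables with the conventional
#' columns `sample`, `chrom`, `loc.start`, `loc.end`, `num.mark`,
#' `seg.mean`; extra columns (e.g. `state`, `fdr`) are preserved.
#'
#' @param path file path.
#' @return data frame of segments.
#' @export
read_seg <- function(path) {
  read_table_checked(path, 6L, "SEG")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "loc.start", "loc.end", "num.mark", "seg.mean")
  if (!all(need %in% names(df)))
    stop(path, ": SEG header must contain ", paste(need, collapse = ", "))
  for (col in c("loc.start", "loc.end", "num.mark", "seg.mean")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(is.na(v) & !is.na(df[[col]])))
      stop(path, ": non-numeric value in column ", col, " at line ",
           which(is.na(v) & !is.na(df[[col]]))[1] + 1L)
    df[[col]] <- v
  }
  df
}

#' @rdname read_seg
#' @param seg data frame of segments.
#' @export
write_seg <- function(seg, path) {
  seg <- seg[order(seg$sample, seg$chrom, seg$loc.start), ]
  utils::write.table(seg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write feature-by-subject TSV matrices
#'
#' First column `feature`, remaining columns one per subject. Missing
#' cells read as NA.
#'
#' @param path file path.
#' @return numeric matrix with feature rownames.
#' @export
read_matrix <- function(path) {
  read_table_checked(path, 2L, "matrix")
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_matrix
#' @param mat numeric matrix, features in rows.
#' @export
write_matrix <- function(mat, path) {
  df <- data.frame(feature = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write BED-like annotation (0-based half-open)
#'
#' Columns: chrom, start, end, name, and optionally a fifth `type`
#' column. Empty intervals (start >= end) are rejected.
#'
#' @param path file path.
#' @return data frame with `feature`, `chrom`, `start`, `end`, `type`.
#' @export
read_bed <- function(path) {
  lines <- read_table_checked(path, 4L, "BED")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0)
    stop(path, ": non-numeric BED coordinates at line ", bad[1])
  empty <- which(start >= end)
  if (length(empty) > 0)
    stop(path, ": empty interval (start >= end) at line ", empty[1])
  data.frame(
    feature = vapply(fields, `[`, "", 4L),
    chrom = vapply(fields, `[`, "", 1L),
    start = start, end = end,
    type = vapply(fields, function(f)
      if (length(f) >= 5L) f[5L] else "gene", ""),
    stringsAsFactors = FALSE)
}

#' @rdname read_bed
#' @param annotation data frame with `feature`, `chrom`, `start`, `end`
#'   and optionally `type`.
#' @export
write_bed <- function(annotation, path) {
  if (any(annotation$start >= annotation$end))
    stop("empty interval (start >= end) in annotation")
  type <- if ("type" %in% names(annotation)) annotation$type else "gene"
  out <- data.frame(annotation$chrom, annotation$start, annotation$end,
                    annotation$feature, type)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write GMT gene-set files
#'
#' @param path file path.
#' @return named list of character gene sets.
#' @export
read_gmt <- function(path) {
  lines <- read_table_checked(path, 3L, "GMT")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[`, "", 1L)
  sets
}

#' @rdname read_gmt
#' @param sets named list of gene sets.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write two-column network edge lists
#'
#' @param path file path.
#' @return two-column character matrix of edges.
#' @export
read_edges <- function(path) {
  lines <- read_table_checked(path, 2L, "edge")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  cbind(vapply(fields, `[`, "", 1L), vapply(fields, `[`, "", 2L))
}

#' @rdname read_edges
#' @param edges two-column matrix/data frame.
#' @export
write_edges <- function(edges, path) {
  utils::write.table(as.data.frame(edges), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a generated cohort to a directory
#'
#' Writes a probe-level SEG file (`probes.seg`; one row per probe,
#' `num.mark` 1, rows sorted by sample, chromosome, start), the gene and
#' miRNA expression matrices (`expr.tsv`, `mirna.tsv`), the BED
#' annotation (`annotation.bed`), the histology labels (`labels.tsv`) and
#' the ground truth (`truth.json`). [read_cohort()] round-trips the set
#' losslessly.
#'
#' @param cohort output of [generate_cohort()].
#' @param directory output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  seg <- do.call(rbind, lapply(cohort$profiles, function(pf) {
    data.frame(sample = pf$subject, chrom = pf$probes$chrom,
               loc.start = pf$probes$pos, loc.end = pf$probes$pos,
               num.mark = 1L, seg.mean = pf$probes$log2ratio)
  }))
  write_seg(seg, file.path(directory, "probes.seg"))
  write_matrix(cohort$expr, file.path(directory, "expr.tsv"))
  write_matrix(cohort$mirna_expr, file.path(directory, "mirna.tsv"))
  write_bed(cohort$annotation, file.path(directory, "annotation.bed"))
  utils::write.table(
    data.frame(subject = names(cohort$labels), histology = cohort$labels),
    file.path(directory, "labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_truth(cohort$truth, file.path(directory, "truth.json"))
  invisible(directory)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(directory) {
  seg <- read_seg(file.path(directory, "probes.seg"))
  profiles <- lapply(split(seg, seg$sample), function(s) {
    s <- s[order(s$chrom, s$loc.start), ]
    genomic_profile(s$sample[1],
                    data.frame(chrom = s$chrom, pos = s$loc.start,
                               log2ratio = s$seg.mean))
  })
  labels_df <- utils::read.delim(file.path(directory, "labels.tsv"),
                                 stringsAsFactors = FALSE)
  labels <- stats::setNames(labels_df$histology, labels_df$subject)
  profiles <- profiles[names(labels)]
  list(profiles = profiles,
       expr = read_matrix(file.path(directory, "expr.tsv")),
       mirna_expr = read_matrix(file.path(directory, "mirna.tsv")),
       annotation = read_bed(file.path(directory, "annotation.bed")),
       labels = labels,
       truth = read_truth(file.path(directory, "truth.json")))
}

#' Write / read planted ground truth as JSON
#'
#' @param truth a `synthetic_truth` object.
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  payload <- list(
    subjects = rownames(truth$carriers),
    carriers = apply(truth$carriers, 2, function(cc)
      rownames(truth$carriers)[cc], simplify = FALSE),
    planted_drivers = truth$planted_drivers,
    planted_driver_mirnas = truth$planted_driver_mirnas,
    module_membership = as.list(truth$module_membership),
    histology = as.list(truth$histology),
    regions = truth$regions,
    seed = truth$seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  subjects <- x$subjects
  carriers <- matrix(FALSE, length(subjects), length(x$carriers),
                     dimnames = list(subjects, names(x$carriers)))
  for (r in names(x$carriers))
    carriers[unlist(x$carriers[[r]]), r] <- TRUE
  truth <- list(
    carriers = carriers,
    planted_drivers = as.character(x$planted_drivers),
    planted_driver_mirnas = as.character(x$planted_driver_mirnas),
    module_membership = unlist(x$module_membership),
    histology = unlist(x$histology),
    regions = as.data.frame(x$regions),
    seed = as.integer(x$seed))
  class(truth) <- "synthetic_truth"
  truth
}
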