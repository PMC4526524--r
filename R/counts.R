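#' Count read-pair inserts onto probes
#'
#' The counted unit is the insert (fragment) interval of each pair, not the
#' individual reads. Two overlap rules are provided: `midpoint` (default for
#' disjoint genome tiles) increments the probe containing the insert
#' midpoint, which conserves the total pair count over a tiling;
#' `any_overlap` (default for promoter probes) increments every probe the
#' insert overlaps by at least 1 bp, so any-overlap counts dominate midpoint
#' counts probe-wise. Counts are independent of input pair order.
#'
#' @param pairs filtered read-pair data.frame (concordant pairs; any
#'   cross-chromosome pairs are dropped with a warning).
#' @param probes probe data.frame.
#' @param samples sample sheet data.frame (sample_id, strain, treatment); the
#'   column order of the matrix follows it. Defaults to the samples present
#'   in `pairs`.
#' @param mode `"midpoint"` or `"any_overlap"`.
#' @param library_size optional named per-sample totals; defaults to the
#'   number of pairs per sample in `pairs`.
#' @return an `mbd_counts` object: list(counts = integer matrix probes x
#'   samples, samples, library_size).
#' @export
count_overlaps <- function(pairs, probes, samples = NULL,
                           mode = c("midpoint", "any_overlap"),
                           library_size = NULL) {
  mode <- match.arg(mode)
  if (is.null(samples)) {
    samples <- data.frame(sample_id = unique(pairs$sample_id),
                          stringsAsFactors = FALSE)
  }
  if (any(pairs$chrom1 != pairs$chrom2)) {
    warning("dropping ", sum(pairs$chrom1 != pairs$chrom2),
            " cross-chromosome pair(s) with undefined insert")
    pairs <- pairs[pairs$chrom1 == pairs$chrom2, , drop = FALSE]
  }
  sample_ids <- samples$sample_id
  mat <- matrix(0L, nrow = nrow(probes), ncol = length(sample_ids),
                dimnames = list(probes$probe_id, sample_ids))
  ins_lo <- pmin(pairs$start1, pairs$start2)
  ins_hi <- pmax(pairs$end1, pairs$end2)
  s_idx <- match(pairs$sample_id, sample_ids)
  if (anyNA(s_idx)) .stopf("pairs contain sample ids absent from the sample sheet")
  for (cn in unique(probes$chrom)) {
    pi <- which(probes$chrom == cn)
    ri <- which(pairs$chrom1 == cn)
    if (length(ri) == 0L) next
    if (mode == "midpoint") {
      q <- .ir_point(as.integer((ins_lo[ri] + ins_hi[ri]) %/% 2L))
    } else {
      q <- .ir(ins_lo[ri], ins_hi[ri])
    }
    hits <- IRanges::findOverlaps(q, .ir(probes$start[pi], probes$end[pi]))
    if (length(hits) == 0L) next
    tab <- table(probe = pi[S4Vectors::subjectHits(hits)],
                 sample = s_idx[ri][S4Vectors::queryHits(hits)])
    mat[as.integer(rownames(tab)), as.integer(colnames(tab))] <-
      mat[as.integer(rownames(tab)), as.integer(colnames(tab))] + as.integer(tab)
  }
  if (is.null(library_size)) {
    library_size <- stats::setNames(
      as.integer(table(factor(pairs$sample_id, levels = sample_ids))), sample_ids)
  } else {
    library_size <- library_size[sample_ids]
  }
  structure(list(counts = mat, samples = samples, library_size = library_size),
            class = "mbd_counts")
}

#' @export
print.mbd_counts <- function(x, ...) {
  cat(sprintf("mbd_counts: %d probes x %d samples (median library %s pairs)\n",
              nrow(x$counts), ncol(x$counts),
              format(stats::median(x$library_size), big.mark = ",")))
  invisible(x)
}

#' Subset an mbd_counts object by samples and/or probes
#'
#' @param counts an `mbd_counts` object.
#' @param sample_ids,probe_ids identifiers to retain (NULL keeps all).
#' @export
subset_counts <- function(counts, sample_ids = NULL, probe_ids = NULL) {
  m <- counts$counts
  ss <- counts$samples
  if (!is.null(probe_ids)) m <- m[probe_ids, , drop = FALSE]
  if (!is.null(sample_ids)) {
    m <- m[, sample_ids, drop = FALSE]
    ss <- ss[match(sample_ids, ss$sample_id), , drop = FALSE]
  }
  structure(list(counts = m, samples = ss,
                 library_size = counts$library_size[colnames(m)]),
            class = "mbd_counts")
}
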