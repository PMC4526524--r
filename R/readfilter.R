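#' Filter aligned read pairs before counting
#'
#' Applies the three filtration rules in fixed order, attributing each
#' rejected pair to the first rule it fails:
#' 1. concordance — both reads on the same chromosome with an inner gap
#'    (distance between the facing ends of the two reads) of at most
#'    `max_gap` bp; overlapping or dovetailing reads (negative gap) are
#'    concordant;
#' 2. uniqueness — the pair maps to a single genomic position;
#' 3. CpG content — the insert (leftmost read start to rightmost read end)
#'    contains at least one CpG site of the sample's strain, SNP-created
#'    sites included.
#'
#' @param pairs read-pair data.frame (see [read_bedpe()]).
#' @param cpg_sites `cpg_sites` for the sample's strain (see
#'   [enumerate_cpg_sites()]).
#' @param max_gap maximum inner gap in bp (default 600).
#' @return list with `kept` (subset of `pairs`) and `tally` (named counts:
#'   input, kept, non_concordant, multi_mapped, no_cpg). The tally conserves
#'   the input: kept + rejections = input.
#' @export
filter_read_pairs <- function(pairs, cpg_sites, max_gap = 600L) {
  known <- attr(cpg_sites, "chroms")
  if (is.null(known)) known <- unique(cpg_sites$chrom)
  bad <- setdiff(unique(c(pairs$chrom1, pairs$chrom2)), known)
  if (length(bad))
    .stopf("pair references unknown chromosome: %s", bad[1])
  n <- nrow(pairs)
  if (n == 0L) {
    return(list(kept = pairs,
                tally = c(input = 0L, kept = 0L, non_concordant = 0L,
                          multi_mapped = 0L, no_cpg = 0L)))
  }
  gap <- pmax(pairs$start1, pairs$start2) - pmin(pairs$end1, pairs$end2)
  concordant <- (pairs$chrom1 == pairs$chrom2) & (gap <= max_gap)
  uniq <- as.logical(pairs$unique)

  ins_lo <- pmin(pairs$start1, pairs$start2)
  ins_hi <- pmax(pairs$end1, pairs$end2)
  has_cpg <- logical(n)
  for (cn in unique(pairs$chrom1)) {
    pi <- which(pairs$chrom1 == cn & concordant)
    if (length(pi) == 0L) next
    sp <- cpg_sites$pos[cpg_sites$chrom == cn]
    if (length(sp) == 0L) next
    has_cpg[pi] <- IRanges::countOverlaps(.ir(ins_lo[pi], ins_hi[pi]),
                                          .ir_point(sp)) > 0L
  }

  fail_conc <- !concordant
  fail_uniq <- concordant & !uniq
  fail_cpg <- concordant & uniq & !has_cpg
  keep <- concordant & uniq & has_cpg
  list(
    kept = pairs[keep, , drop = FALSE],
    tally = c(input = n, kept = sum(keep), non_concordant = sum(fail_conc),
              multi_mapped = sum(fail_uniq), no_cpg = sum(fail_cpg))
  )
}
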