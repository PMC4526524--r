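# Aggregation of DMR results into the study's reporting structures:
# gene-class volcano quadrants, trend fractions and genomic-feature
# distributions.

#' Classify a gene symbol into the aggregated gene classes
#'
#' Case-insensitive substring match with precedence Vmn > Olfr > Mir:
#' vomeronasal receptors ("Vmn"), olfactory receptors ("Olfr"), microRNAs
#' ("Mir"), otherwise "other".
#'
#' @param symbol character vector of gene symbols.
#' @return character vector of classes.
#' @export
classify_gene_symbol <- function(symbol) {
  if (any(!nzchar(symbol))) .stopf("empty gene symbol")
  out <- rep("other", length(symbol))
  out[grepl("mir", symbol, ignore.case = TRUE)] <- "microrna"
  out[grepl("olfr", symbol, ignore.case = TRUE)] <- "olfactory"
  out[grepl("vmn", symbol, ignore.case = TRUE)] <- "vomeronasal"
  out
}

#' Volcano quadrant counts for a gene class
#'
#' Splits promoter results into significant hyper/hypo calls (p below the
#' promoter Bonferroni threshold AND |log2fc| above the fold-change
#' threshold) and non-significant two-fold trends per direction. Direction is
#' in control-over-dehp orientation: `hyper` here means higher methylation in
#' controls (log2fc > threshold), which the study describes as
#' hypo-methylated in DEHP; the complementary DEHP-oriented labels are
#' reported alongside to avoid sign confusion. Probes with |log2fc| at or
#' below the threshold fall in no quadrant. The summary is invariant to
#' result row order.
#'
#' @param results data.frame from [test_dmr()] carrying a `gene_class`
#'   column (or pass `gene_class` separately).
#' @param class_filter one of "vomeronasal", "olfactory", "microrna",
#'   "other", or "all".
#' @param policy a [call_policy()] with `promoter_m` set.
#' @param gene_class optional vector overriding `results$gene_class`.
#' @return list of class `class_summary` with the quadrant counts.
#' @export
volcano_quadrants <- function(results, class_filter, policy,
                              gene_class = NULL) {
  if (is.null(gene_class)) gene_class <- results$gene_class
  if (is.null(gene_class)) .stopf("results carry no gene_class")
  valid <- c("vomeronasal", "olfactory", "microrna", "other", "all")
  if (!class_filter %in% valid) .stopf("unknown gene class: %s", class_filter)
  keep <- if (class_filter == "all") rep(TRUE, nrow(results))
          else gene_class == class_filter
  r <- results[keep, , drop = FALSE]
  thr <- bonferroni_threshold(policy$promoter_alpha, policy$promoter_m)
  fc <- r$log2fc
  sig <- r$p < thr
  up <- fc > policy$fc_threshold
  dn <- fc < -policy$fc_threshold
  structure(list(
    class = class_filter,
    n_total = nrow(r),
    n_sig_hyper_control = sum(sig & up),
    n_sig_hypo_control = sum(sig & dn),
    n_trend_hyper = sum(!sig & up),
    n_trend_hypo = sum(!sig & dn),
    # same quadrants in the DEHP-oriented vocabulary
    n_sig_hyper_dehp = sum(sig & dn),
    n_sig_hypo_dehp = sum(sig & up),
    p_threshold = thr
  ), class = "class_summary")
}

#' Trend fraction of a gene class
#'
#' Percentage of the class's promoters whose methylation moved more than
#' two-fold in the given direction, significant or not:
#' `100 * (n_trend + n_sig) / n_total`, with a display value rounded to the
#' nearest integer.
#'
#' @param summary a `class_summary` from [volcano_quadrants()].
#' @param direction `"hyper"` or `"hypo"` (control orientation).
#' @return list(fraction, display).
#' @export
class_trend_fraction <- function(summary, direction = c("hyper", "hypo")) {
  direction <- match.arg(direction)
  if (summary$n_total == 0L) .stopf("empty gene class")
  num <- if (direction == "hyper")
    summary$n_trend_hyper + summary$n_sig_hyper_control
  else summary$n_trend_hypo + summary$n_sig_hypo_control
  f <- 100 * num / summary$n_total
  list(fraction = f, display = round(f))
}

#' Genomic-feature distribution of a probe subset
#'
#' Counts and percentages per feature (promoter, exon, intron, enhancer,
#' intergenic) over a probe subset, e.g. all tiles, hyper-methylated DMR
#' tiles, or hypo-methylated DMR tiles. Integer display percentages sum to
#' 100 up to rounding.
#'
#' @param features character vector of feature assignments (see
#'   [assign_feature()]), or a probe data.frame with a `feature` column.
#' @return data.frame: feature, n, percent, percent_display.
#' @export
feature_distribution <- function(features) {
  if (is.data.frame(features)) features <- features$feature
  if (length(features) == 0L) .stopf("empty probe subset")
  lev <- c("promoter", "exon", "intron", "enhancer", "intergenic")
  tab <- table(factor(features, levels = lev))
  data.frame(feature = lev, n = as.integer(tab),
             percent = 100 * as.integer(tab) / length(features),
             percent_display = round(100 * as.integer(tab) / length(features)),
             stringsAsFactors = FALSE)
}
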