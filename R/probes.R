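#' Cut a genome into fixed-length tile probes
#'
#' Each chromosome is partitioned into consecutive non-overlapping tiles
#' `[0, tile_length), [tile_length, 2*tile_length), ...`; the final partial
#' tile is kept when at least 1 bp remains, so the tiles exactly cover the
#' chromosome.
#'
#' @param genome a `genome_model` (or named character vector of sequences).
#' @param tile_length tile size in bp (default 2200).
#' @return data.frame of probes with kind `"genome_tile"`.
#' @export
tile_genome <- function(genome, tile_length = 2200L) {
  if (!.is_count(tile_length)) .stopf("tile_length must be a positive integer")
  seqs <- if (inherits(genome, "genome_model")) genome$sequences else genome
  if (length(seqs) == 0L) .stopf("genome is empty")
  lens <- nchar(seqs)
  out <- lapply(names(seqs), function(cn) {
    L <- lens[[cn]]
    starts <- seq.int(0L, L - 1L, by = tile_length)
    data.frame(chrom = cn, start = starts,
               end = pmin(starts + as.integer(tile_length), L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  data.frame(
    probe_id = sprintf("tile_%s_%06d", out$chrom,
                       as.integer(out$start / tile_length) + 1L),
    chrom = out$chrom, start = out$start, end = out$end,
    kind = "genome_tile", gene_symbol = NA_character_,
    gene_class = NA_character_, stringsAsFactors = FALSE
  )
}

#' Promoter window probes
#'
#' One probe per gene spanning 2 kb transcriptionally upstream of the
#' transcription start site (first transcribed base) to 200 bp downstream of
#' it, inclusive of the TSS: for a + strand gene with TSS `t` the window is
#' `[t-2000, t+200)`; for a - strand gene it is the mirrored
#' `[t-199, t+2001)`. Windows are truncated at chromosome bounds.
#'
#' @param genome a `genome_model` with a `genes` table (symbol, class, chrom,
#'   strand, tss).
#' @param upstream,downstream window extents in bp (defaults 2000 and 200).
#' @return data.frame of probes with kind `"promoter"`.
#' @export
promoter_probes <- function(genome, upstream = 2000L, downstream = 200L) {
  g <- genome$genes
  if (is.null(g) || nrow(g) == 0L) .stopf("genome has no gene models")
  if (any(is.na(g$strand)) || !all(g$strand %in% c("+", "-")))
    .stopf("every gene needs a '+' or '-' strand")
  lens <- nchar(genome$sequences)[g$chrom]
  plus <- g$strand == "+"
  start <- ifelse(plus, g$tss - upstream, g$tss - downstream + 1L)
  end <- ifelse(plus, g$tss + downstream, g$tss + upstream + 1L)
  start <- pmax(0L, as.integer(start))
  end <- pmin(as.integer(lens), as.integer(end))
  data.frame(
    probe_id = paste0("prom_", g$symbol),
    chrom = g$chrom, start = start, end = end, kind = "promoter",
    gene_symbol = g$symbol,
    gene_class = if (!is.null(g$class)) g$class else classify_gene_symbol(g$symbol),
    stringsAsFactors = FALSE
  )
}

#' Classify a variant's effect on the CpG census
#'
#' Compares the number of CG dinucleotides in the window `[pos-1, pos+1]` of
#' the reference sequence against the same window with the alternate allele
#' substituted. A net gain is CpG-creating, a net loss CpG-destroying,
#' otherwise neutral. Only single-nucleotide variants are classified; indels
#' return `"neutral"` (they are excluded from CpG logic).
#'
#' @param sequences named character vector of chromosome sequences (or a
#'   `genome_model`).
#' @param chrom,pos,ref,alt vectors describing the variants (`pos` 0-based).
#' @return character vector: "creating", "destroying" or "neutral".
#' @export
classify_cpg_effect <- function(sequences, chrom, pos, ref, alt) {
  if (inherits(sequences, "genome_model")) sequences <- sequences$sequences
  n <- length(pos)
  out <- character(n)
  for (i in seq_len(n)) {
    if (nchar(ref[i]) != 1L || nchar(alt[i]) != 1L) { out[i] <- "neutral"; next }
    s <- sequences[[chrom[i]]]
    L <- nchar(s)
    p <- pos[i]
    if (substr(s, p + 1L, p + 1L) != ref[i])
      .stopf("reference allele mismatch at %s:%d (expected %s, genome has %s)",
             chrom[i], p, ref[i], substr(s, p + 1L, p + 1L))
    lo <- max(0L, p - 1L); hi <- min(L - 1L, p + 1L)
    win_ref <- substr(s, lo + 1L, hi + 1L)
    win_alt <- win_ref
    substr(win_alt, p - lo + 1L, p - lo + 1L) <- alt[i]
    n_ref <- .count_cg(win_ref); n_alt <- .count_cg(win_alt)
    out[i] <- if (n_alt > n_ref) "creating" else if (n_alt < n_ref) "destroying" else "neutral"
  }
  out
}

.count_cg <- function(x) {
  m <- gregexpr("(?=CG)", x, perl = TRUE)[[1]]
  sum(m > 0)
}

#' Enumerate CpG dinucleotide sites for a strain
#'
#' Scans the strain-substituted genome sequence (reference sequence with the
#' strain's alternate alleles applied) and returns the 0-based position of the
#' C of every CG dinucleotide. Sites absent from the reference sequence but
#' present under the alternate alleles are marked `snp_created`.
#'
#' @param genome a `genome_model` (or named character vector of sequences).
#' @param variants strain variant data.frame (`NULL` for the reference
#'   strain). Only single-nucleotide variants are substituted.
#' @return data.frame (chrom, pos, provenance) of class `cpg_sites`, sorted by
#'   chromosome and position.
#' @export
enumerate_cpg_sites <- function(genome, variants = NULL) {
  seqs <- if (inherits(genome, "genome_model")) genome$sequences else genome
  subs <- seqs
  if (!is.null(variants) && nrow(variants) > 0L) {
    v <- variants[nchar(variants$ref) == 1L & nchar(variants$alt) == 1L, , drop = FALSE]
    if (anyDuplicated(v[, c("chrom", "pos")]))
      .stopf("overlapping variants at a single position")
    for (cn in unique(v$chrom)) {
      vi <- v[v$chrom == cn, , drop = FALSE]
      s <- subs[[cn]]
      have <- substring(s, vi$pos + 1L, vi$pos + 1L)
      bad <- which(have != vi$ref)
      if (length(bad))
        .stopf("reference allele mismatch at %s:%d", cn, vi$pos[bad[1]])
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      ch[vi$pos + 1L] <- vi$alt
      subs[[cn]] <- paste(ch, collapse = "")
    }
  }
  sites <- .scan_cg(subs)
  if (!is.null(variants)) {
    ref_sites <- .scan_cg(seqs)
    key <- paste(sites$chrom, sites$pos)
    sites$provenance <- ifelse(key %in% paste(ref_sites$chrom, ref_sites$pos),
                               "reference", "snp_created")
  } else {
    sites$provenance <- rep("reference", nrow(sites))
  }
  class(sites) <- c("cpg_sites", "data.frame")
  attr(sites, "chroms") <- names(seqs)
  sites
}

.scan_cg <- function(seqs) {
  out <- lapply(names(seqs), function(cn) {
    m <- gregexpr("(?=CG)", seqs[[cn]], perl = TRUE)[[1]]
    pos <- m[m > 0] - 1L
    data.frame(chrom = rep(cn, length(pos)), pos = as.integer(pos),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Count CpG sites falling inside probes
#'
#' Adds `n_cpg_ref` (reference-strain CpGs) and `n_cpg_snp_dependent`
#' (SNP-created CpGs of the alternate strain) columns to a probe table. A CpG
#' is counted when the position of its C lies inside the probe interval.
#'
#' @param probes probe data.frame.
#' @param ref_sites `cpg_sites` of the reference strain.
#' @param alt_sites optional `cpg_sites` of the alternate strain (for the
#'   SNP-dependent census).
#' @export
count_probe_cpgs <- function(probes, ref_sites, alt_sites = NULL) {
  probes$n_cpg_ref <- .count_sites_in(probes, ref_sites)
  if (!is.null(alt_sites)) {
    created <- alt_sites[alt_sites$provenance == "snp_created", , drop = FALSE]
    probes$n_cpg_snp_dependent <- .count_sites_in(probes, created)
  } else {
    probes$n_cpg_snp_dependent <- 0L
  }
  probes
}

.count_sites_in <- function(probes, sites) {
  n <- integer(nrow(probes))
  for (cn in unique(probes$chrom)) {
    pi <- which(probes$chrom == cn)
    si <- sites$pos[sites$chrom == cn]
    if (length(si) == 0L) next
    hits <- IRanges::countOverlaps(.ir(probes$start[pi], probes$end[pi]), .ir_point(si))
    n[pi] <- hits
  }
  n
}

#' Assign a genomic feature to each probe
#'
#' Overlap-based assignment with fixed priority promoter > exon > intron >
#' enhancer > intergenic: a probe gets the highest-priority category with at
#' least 1 bp of overlap, and `intergenic` when it overlaps nothing. The
#' result does not depend on annotation record order.
#'
#' @param probes probe data.frame.
#' @param annotation list with elements `promoters`, `exons`, `introns`,
#'   `enhancers` — each a data.frame with chrom/start/end — as built by
#'   [build_feature_annotation()].
#' @return character vector of features, one per probe.
#' @export
assign_feature <- function(probes, annotation) {
  hit <- function(set) {
    res <- logical(nrow(probes))
    if (is.null(set) || nrow(set) == 0L) return(res)
    for (cn in unique(probes$chrom)) {
      pi <- which(probes$chrom == cn)
      si <- set[set$chrom == cn, , drop = FALSE]
      if (nrow(si) == 0L) next
      res[pi] <- IRanges::countOverlaps(.ir(probes$start[pi], probes$end[pi]),
                                        .ir(si$start, si$end)) > 0L
    }
    res
  }
  feature <- rep("intergenic", nrow(probes))
  feature[hit(annotation$enhancers)] <- "enhancer"
  feature[hit(annotation$introns)] <- "intron"
  feature[hit(annotation$exons)] <- "exon"
  feature[hit(annotation$promoters)] <- "promoter"
  feature
}

#' Derive the feature annotation used by [assign_feature()]
#'
#' Promoter windows use the same definition as [promoter_probes()]; introns
#' are gene bodies minus exons; enhancers come from the genome model (a
#' user-supplied BED in a real analysis).
#'
#' @param genome a `genome_model`.
#' @inheritParams promoter_probes
#' @export
build_feature_annotation <- function(genome, upstream = 2000L, downstream = 200L) {
  prom <- promoter_probes(genome, upstream, downstream)
  introns <- do.call(rbind, lapply(seq_len(nrow(genome$genes)), function(i) {
    g <- genome$genes[i, ]
    e <- genome$exons[genome$exons$gene_id == g$gene_id, , drop = FALSE]
    if (nrow(e) == 0L) return(NULL)
    body <- .ir(g$start, g$end)
    gaps <- IRanges::setdiff(body, .ir(e$start, e$end))
    if (length(gaps) == 0L) return(NULL)
    data.frame(chrom = g$chrom, start = IRanges::start(gaps) - 1L,
               end = IRanges::end(gaps), stringsAsFactors = FALSE)
  }))
  list(
    promoters = prom[, c("chrom", "start", "end")],
    exons = genome$exons[, c("chrom", "start", "end")],
    introns = if (is.null(introns)) data.frame(chrom = character(0), start = integer(0), end = integer(0)) else introns,
    enhancers = if (is.null(genome$enhancers)) data.frame(chrom = character(0), start = integer(0), end = integer(0))
                else genome$enhancers[, c("chrom", "start", "end")]
  )
}

#' Apply the probe selection filter
#'
#' A probe is retained when (a) it contains at least one CpG site or one
#' SNP-dependent CpG site in either strain, and (b) more than `min_count`
#' read pairs align to it in more than `min_samples` samples (literal strict
#' reading: at least `min_count + 1` pairs in at least `min_samples + 1`
#' samples, pooled across all arms).
#'
#' @param probes probe data.frame with CpG census columns (see
#'   [count_probe_cpgs()]).
#' @param counts an `mbd_counts` object covering every probe.
#' @param min_count count that must be exceeded (default 3).
#' @param min_samples number of samples that must be exceeded (default 2).
#' @return the retained subset of `probes`.
#' @export
select_probes <- function(probes, counts, min_count = 3L, min_samples = 2L) {
  miss <- setdiff(probes$probe_id, rownames(counts$counts))
  if (length(miss)) .stopf("counts missing %d probe(s), e.g. %s", length(miss), miss[1])
  m <- counts$counts[probes$probe_id, , drop = FALSE]
  has_cpg <- (probes$n_cpg_ref + probes$n_cpg_snp_dependent) >= 1L
  enough <- rowSums(m > min_count) > min_samples
  probes[has_cpg & enough, , drop = FALSE]
}

#' Annotate probes with nearby strain variants
#'
#' Lists the variants falling within each probe interval extended by `window`
#' bp on both sides, propagating the per-variant CpG and protein flags.
#'
#' @param probes probe data.frame.
#' @param variants variant data.frame.
#' @param window extension in bp (default 0).
#' @return data.frame with one row per (probe, variant) pair.
#' @export
annotate_probe_variants <- function(probes, variants, window = 0L) {
  if (window < 0) .stopf("window must be non-negative")
  out <- NULL
  for (cn in unique(probes$chrom)) {
    pi <- which(probes$chrom == cn)
    vi <- which(variants$chrom == cn)
    if (length(vi) == 0L) next
    hits <- IRanges::findOverlaps(
      .ir(pmax(0L, probes$start[pi] - as.integer(window)),
          probes$end[pi] + as.integer(window)),
      .ir_point(variants$pos[vi]))
    if (length(hits) == 0L) next
    block <- cbind(
      data.frame(probe_id = probes$probe_id[pi][S4Vectors::queryHits(hits)],
                 stringsAsFactors = FALSE),
      variants[vi[S4Vectors::subjectHits(hits)], , drop = FALSE])
    out <- rbind(out, block)
  }
  if (is.null(out))
    out <- cbind(data.frame(probe_id = character(0), stringsAsFactors = FALSE),
                 .empty_variants())
  rownames(out) <- NULL
  out
}
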