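#' Read genome sequences from FASTA
#'
#' Sequences are normalized to uppercase. Chromosome names are taken from the
#' first whitespace-delimited token of each header.
#'
#' @param path FASTA file (gzip-transparent).
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta_sequences <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) {
    warning("empty FASTA file: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) .stopf("duplicate chromosome names in %s", path)
  stats::setNames(toupper(as.character(seqs)), nm)
}

#' Write genome sequences to FASTA
#'
#' @param sequences named character vector (or a `genome_model`, whose
#'   `$sequences` element is used).
#' @param path output file.
#' @export
write_fasta_sequences <- function(sequences, path) {
  if (inherits(sequences, "genome_model")) sequences <- sequences$sequences
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Read strain variants from a VCF file
#'
#' Applies the study's variant filtration: homozygous-alternate genotype and a
#' minimum read-depth evidence (default: at least 3 reads, boundary
#' inclusive). Positions are converted from VCF 1-based to the package's
#' internal 0-based convention. CpG-effect flags are parsed from an INFO
#' `CPG=` tag when present (as written by [write_variants_vcf()]); otherwise
#' they are left `NA` and can be recomputed with [classify_cpg_effect()].
#'
#' @param path VCF v4.x file (gzip-transparent).
#' @param min_depth minimum DP to retain a record (default 3).
#' @param require_homozygous drop records that are not homozygous-alternate.
#' @return data.frame with columns chrom, pos (0-based), ref, alt, genotype,
#'   depth, cpg_creating, cpg_destroying, protein_modifying.
#' @export
read_vcf_variants <- function(path, min_depth = 3L, require_homozygous = TRUE) {
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "#"))
  for (i in body_idx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L || is.na(suppressWarnings(as.integer(f[2]))))
      .stopf("malformed VCF record at line %d of %s", i, path)
  }
  if (length(body_idx) == 0L) return(.empty_variants())
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(as.integer(vcfR::extract.gt(v, element = "DP")))
  geno <- if (is.null(gt)) rep(NA_character_, nrow(fix)) else gt[, 1]
  depth <- if (all(is.na(dp))) rep(NA_integer_, nrow(fix)) else dp
  info <- vcfR::getINFO(v)
  eff <- ifelse(grepl("CPG=creating", info), "creating",
         ifelse(grepl("CPG=destroying", info), "destroying",
         ifelse(grepl("CPG=neutral", info), "neutral", NA_character_)))
  prot <- grepl("PROTMOD", info)
  out <- data.frame(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS) - 1L,
    ref = fix$REF,
    alt = fix$ALT,
    genotype = geno,
    depth = depth,
    cpg_creating = eff == "creating",
    cpg_destroying = eff == "destroying",
    protein_modifying = ifelse(is.na(info), NA, prot),
    stringsAsFactors = FALSE
  )
  keep <- rep(TRUE, nrow(out))
  if (require_homozygous) {
    hom <- !is.na(out$genotype) & out$genotype %in% c("1/1", "1|1")
    keep <- keep & hom
  }
  keep <- keep & !is.na(out$depth) & out$depth >= min_depth
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_variants <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), genotype = character(0), depth = integer(0),
             cpg_creating = logical(0), cpg_destroying = logical(0),
             protein_modifying = logical(0), stringsAsFactors = FALSE)
}

#' Write strain variants as VCF v4.2
#'
#' Emits GT and DP per record plus an INFO `CPG=` tag carrying the CpG-effect
#' flag so that the flags round-trip through [read_vcf_variants()].
#'
#' @param variants variant data.frame (0-based `pos`).
#' @param path output file.
#' @param sample_name column header for the single genotype column.
#' @export
write_variants_vcf <- function(variants, path, sample_name = "FVB_N") {
  con <- .out_con(path)
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CPG,Number=1,Type=String,Description=\"Effect on CpG census: creating, destroying or neutral\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_name)
  ), con)
  if (nrow(variants) > 0L) {
    eff <- ifelse(isTRUE_v(variants$cpg_creating), "creating",
           ifelse(isTRUE_v(variants$cpg_destroying), "destroying", "neutral"))
    rec <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tCPG=%s\tGT:DP\t%s:%d",
                   variants$chrom, variants$pos + 1L, variants$ref,
                   variants$alt, eff, variants$genotype, variants$depth)
    writeLines(rec, con)
  }
  invisible(path)
}

# Vectorized isTRUE tolerating NA.
isTRUE_v <- function(x) !is.na(x) & x

#' Read aligned read pairs from BEDPE
#'
#' Requires the standard 10 columns (chrom1, start1, end1, chrom2, start2,
#' end2, name, score, strand1, strand2). Coordinates are 0-based half-open and
#' preserved as-is. The score column encodes pair mapping uniqueness (1 =
#' unique, 0 = multi-mapped). Pairs whose two reads map to different
#' chromosomes are loaded but flagged `discordant`.
#'
#' @param path BEDPE file (gzip-transparent).
#' @param sample_id sample identifier attached to every pair.
#' @return data.frame of read-pair alignments.
#' @export
read_bedpe <- function(path, sample_id) {
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
            "name", "score", "strand1", "strand2")
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = c(1, 4, 7, 9, 10)))
  if (nrow(dt) == 0L) {
    out <- stats::setNames(data.frame(character(0), integer(0), integer(0),
                                      character(0), integer(0), integer(0),
                                      character(0), numeric(0), character(0),
                                      character(0), stringsAsFactors = FALSE), cols)
    out$unique <- logical(0); out$discordant <- logical(0)
    out$sample_id <- character(0)
    return(out)
  }
  if (ncol(dt) != 10L) .stopf("BEDPE %s must have 10 columns, found %d", path, ncol(dt))
  out <- stats::setNames(as.data.frame(dt), cols)
  if (any(out$start1 > out$end1) || any(out$start2 > out$end2))
    .stopf("BEDPE %s has records with start > end", path)
  out$unique <- out$score > 0
  out$discordant <- out$chrom1 != out$chrom2
  out$sample_id <- sample_id
  out
}

#' Write read pairs as BEDPE
#'
#' @param pairs read-pair data.frame as returned by [read_bedpe()] or the
#'   simulator.
#' @param path output file.
#' @export
write_bedpe <- function(pairs, path) {
  con <- .out_con(path)
  on.exit(close(con))
  if (nrow(pairs) > 0L) {
    rec <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s\t%d\t%s\t%s",
                   pairs$chrom1, pairs$start1, pairs$end1,
                   pairs$chrom2, pairs$start2, pairs$end2,
                   pairs$name, as.integer(pairs$score),
                   pairs$strand1, pairs$strand2)
    writeLines(rec, con)
  }
  invisible(path)
}

#' Write DMR test results as TSV
#'
#' Coordinates are emitted 1-based inclusive for human readability (internal
#' coordinates are 0-based half-open); p-values are printed in scientific
#' notation with 3 significant digits. Rows are ordered by chromosome then
#' start. An empty result set produces a header-only file.
#'
#' @param results data.frame with probe_id, chrom, start, end, feature,
#'   gene_symbol, gene_class, per-arm mean columns, log2fc, p, p_adjusted,
#'   call.
#' @param path output file.
#' @export
write_results_tsv <- function(results, path) {
  res <- results
  num3 <- function(x) ifelse(is.na(x), NA, formatC(x, format = "e", digits = 2))
  if (nrow(res) > 0L) {
    res <- res[order(res$chrom, res$start), , drop = FALSE]
    res$start <- res$start + 1L   # 1-based inclusive for display
    for (cn in intersect(c("p", "p_adjusted", "fdr"), names(res)))
      res[[cn]] <- num3(res[[cn]])
  } else {
    res$start <- integer(0)
  }
  data.table::fwrite(res, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a sample sheet
#'
#' Expects columns sample_id, strain, treatment, path. Validates uniqueness of
#' sample ids and, when `require_full_design` is set, the presence of both
#' strains under both treatments with at least 2 samples per arm.
#'
#' @param path TSV file.
#' @param require_full_design check the full 2x2 design.
#' @export
read_sample_sheet <- function(path, require_full_design = FALSE) {
  ss <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  validate_sample_sheet(ss, require_full_design = require_full_design)
  ss
}

#' @rdname read_sample_sheet
#' @param samples sample sheet data.frame.
#' @export
validate_sample_sheet <- function(samples, require_full_design = FALSE) {
  need <- c("sample_id", "strain", "treatment")
  miss <- setdiff(need, names(samples))
  if (length(miss)) .stopf("sample sheet missing columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id)) .stopf("duplicate sample ids in sample sheet")
  if (!all(samples$treatment %in% c("control", "dehp")))
    .stopf("treatment must be 'control' or 'dehp'")
  if (require_full_design) {
    tab <- table(samples$strain, samples$treatment)
    if (!all(dim(tab) == c(2L, 2L)) || any(tab < 2L)) {
      missing_cells <- character(0)
      strains <- unique(samples$strain)
      for (s in strains) for (tr in c("control", "dehp"))
        if (sum(samples$strain == s & samples$treatment == tr) < 2L)
          missing_cells <- c(missing_cells, paste(s, tr, sep = ":"))
      .stopf("full 2x2 design with >=2 samples per arm required; deficient cell(s): %s",
             paste(missing_cells, collapse = ", "))
    }
  }
  invisible(samples)
}

#' Write probes as BED6
#'
#' name = probe id, score = total CpG count (reference + SNP-dependent).
#'
#' @param probes probe data.frame.
#' @param path output file.
#' @export
write_probes_bed <- function(probes, path) {
  con <- .out_con(path)
  on.exit(close(con))
  score <- probes$n_cpg_ref
  if (!is.null(probes$n_cpg_snp_dependent)) score <- score + probes$n_cpg_snp_dependent
  if (is.null(score)) score <- rep(0L, nrow(probes))
  if (nrow(probes) > 0L)
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", probes$chrom, probes$start,
                       probes$end, probes$probe_id, as.integer(score),
                       if (is.null(probes$strand)) "." else probes$strand), con)
  invisible(path)
}

#' Write gene models as BED12 and enhancers as BED6
#'
#' @param genome a `genome_model`.
#' @param gene_path,enhancer_path output files.
#' @export
write_annotation_bed <- function(genome, gene_path, enhancer_path = NULL) {
  g <- genome$genes
  ex <- genome$exons
  con <- .out_con(gene_path)
  lines <- vapply(seq_len(nrow(g)), function(i) {
    e <- ex[ex$gene_id == g$gene_id[i], , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            g$chrom[i], g$start[i], g$end[i], g$symbol[i], g$strand[i],
            g$start[i], g$end[i], nrow(e),
            paste0(paste(e$end - e$start, collapse = ","), ","),
            paste0(paste(e$start - g$start[i], collapse = ","), ","))
  }, character(1))
  writeLines(lines, con)
  close(con)
  if (!is.null(enhancer_path)) {
    con2 <- .out_con(enhancer_path)
    en <- genome$enhancers
    if (!is.null(en) && nrow(en) > 0L)
      writeLines(sprintf("%s\t%d\t%d\t%s\t0\t.", en$chrom, en$start, en$end, en$name), con2)
    close(con2)
  }
  invisible(gene_path)
}

#' Read gene models (BED12) and enhancers (BED6) back into annotation tables
#'
#' Inverse of [write_annotation_bed()]: reconstructs the genes and exons
#' tables (TSS derived from the strand: first transcribed base) and the
#' enhancer intervals. Gene classes are re-derived from the symbols.
#'
#' @param gene_path BED12 file of gene models.
#' @param enhancer_path optional BED6 file of enhancers.
#' @return list(genes, exons, enhancers) in the `genome_model` layout.
#' @export
read_annotation_bed <- function(gene_path, enhancer_path = NULL) {
  b <- as.data.frame(data.table::fread(gene_path, header = FALSE, sep = "\t"))
  if (ncol(b) < 12L) .stopf("%s is not BED12", gene_path)
  genes <- data.frame(
    gene_id = seq_len(nrow(b)), chrom = b$V1, strand = b$V6,
    tss = ifelse(b$V6 == "+", b$V2, b$V3 - 1L),
    start = b$V2, end = b$V3, symbol = b$V4,
    class = classify_gene_symbol(b$V4), stringsAsFactors = FALSE)
  exons <- do.call(rbind, lapply(seq_len(nrow(b)), function(i) {
    sizes <- as.integer(strsplit(b$V11[i], ",")[[1]])
    offs <- as.integer(strsplit(b$V12[i], ",")[[1]])
    data.frame(gene_id = i, chrom = b$V1[i], start = b$V2[i] + offs,
               end = b$V2[i] + offs + sizes, stringsAsFactors = FALSE)
  }))
  enh <- NULL
  if (!is.null(enhancer_path) && file.exists(enhancer_path)) {
    e <- as.data.frame(data.table::fread(enhancer_path, header = FALSE, sep = "\t"))
    if (nrow(e) > 0L)
      enh <- data.frame(chrom = e$V1, start = e$V2, end = e$V3, name = e$V4,
                        stringsAsFactors = FALSE)
  }
  list(genes = genes, exons = exons, enhancers = enh)
}

#' Write a count matrix as TSV
#'
#' Emits a probes x samples matrix plus a companion column-metadata TSV with
#' strain, treatment and library size.
#'
#' @param counts an `mbd_counts` object.
#' @param path matrix output file.
#' @param meta_path metadata output file (default `<path>.samples.tsv`).
#' @export
write_counts_tsv <- function(counts, path, meta_path = paste0(path, ".samples.tsv")) {
  m <- data.frame(probe_id = rownames(counts$counts), counts$counts,
                  check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(m, path, sep = "\t", quote = FALSE)
  meta <- counts$samples
  meta$library_size <- counts$library_size[meta$sample_id]
  data.table::fwrite(meta, meta_path, sep = "\t", quote = FALSE)
  invisible(path)
}
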