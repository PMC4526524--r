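# Fixtures are built in code; nothing is stored on disk.

# A small handcrafted genome: one 12 kb chromosome, two genes on opposite
# strands, one enhancer.
tiny_genome <- function() {
  set.seed(99)
  L <- 12000L
  base <- sample(c("A", "C", "T"), L, replace = TRUE)  # CpG-free background
  cpg_at <- seq(10L, L - 10L, by = 100L)
  base[cpg_at] <- "C"; base[cpg_at + 1L] <- "G"
  genes <- data.frame(
    gene_id = 1:2, chrom = "chr1", strand = c("+", "-"),
    tss = c(5000L, 9000L), start = c(5000L, 6001L), end = c(8000L, 9001L),
    symbol = c("Vmn2r1", "Gene2"), class = c("vomeronasal", "other"),
    stringsAsFactors = FALSE
  )
  exons <- data.frame(
    gene_id = c(1L, 1L, 2L, 2L), chrom = "chr1",
    start = c(5000L, 7000L, 6001L, 8500L),
    end = c(5500L, 8000L, 6500L, 9001L), stringsAsFactors = FALSE
  )
  enh <- data.frame(chrom = "chr1", start = 1000L, end = 1400L,
                    name = "enh1", stringsAsFactors = FALSE)
  structure(list(sequences = c(chr1 = paste(base, collapse = "")),
                 genes = genes, exons = exons, enhancers = enh),
            class = "genome_model")
}

# Wrap a count matrix into mbd_counts with an optional sample sheet.
make_counts <- function(Y, samples = NULL, library_size = NULL) {
  if (is.null(colnames(Y))) colnames(Y) <- paste0("s", seq_len(ncol(Y)))
  if (is.null(rownames(Y))) rownames(Y) <- paste0("p", seq_len(nrow(Y)))
  if (is.null(samples))
    samples <- data.frame(sample_id = colnames(Y), stringsAsFactors = FALSE)
  if (is.null(library_size))
    library_size <- stats::setNames(pmax(colSums(Y), 1L), colnames(Y))
  structure(list(counts = Y, samples = samples, library_size = library_size),
            class = "mbd_counts")
}

# Equal-offset normalization (unit factors) for controlled experiments.
unit_norm <- function(sample_ids, libsize = 1e5) {
  structure(list(factors = stats::setNames(rep(1, length(sample_ids)), sample_ids),
                 effective_libsize = stats::setNames(rep(libsize, length(sample_ids)), sample_ids),
                 offsets = stats::setNames(rep(log(libsize), length(sample_ids)), sample_ids)),
            class = "tmm_norm")
}

# 2x2 sample sheet: 5 C57 + 5 FVB per treatment.
design_2x2 <- function(n = 5L) {
  data.frame(sample_id = paste0("s", seq_len(4L * n)),
             strain = rep(c("C57BL/6J", "FVB/N"), each = 2L * n),
             treatment = rep(rep(c("control", "dehp"), each = n), 2L),
             stringsAsFactors = FALSE)
}

# One concordant unique read pair with the given insert.
make_pair <- function(chrom, lo, hi, sample_id = "s1", name = "pair",
                      unique = TRUE, rl = 50L) {
  data.frame(chrom1 = chrom, start1 = lo, end1 = min(lo + rl, hi),
             chrom2 = chrom, start2 = max(hi - rl, lo), end2 = hi,
             name = name, score = as.integer(unique), strand1 = "+",
             strand2 = "-", unique = unique, discordant = FALSE,
             sample_id = sample_id, stringsAsFactors = FALSE)
}

cpg_set <- function(chrom, pos, provenance = "reference") {
  df <- data.frame(chrom = rep(chrom, length.out = length(pos)),
                   pos = as.integer(pos),
                   provenance = rep(provenance, length.out = length(pos)),
                   stringsAsFactors = FALSE)
  structure(df, class = c("cpg_sites", "data.frame"),
            chroms = unique(chrom))
}

# A fast small simulation configuration for smoke tests.
small_sim_config <- function(seed = 7L) {
  sim_config(seed = seed, n_chroms = 1L, chrom_length = 80000L, n_genes = 12L,
             target_pairs_per_sample = 4000L,
             class_fracs = c(vomeronasal = 0.25, olfactory = 0.25,
                             microrna = 0.25))
}
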