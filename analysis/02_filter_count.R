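#!/usr/bin/env Rscript
# Start from the on-disk files written by 01_simulate.R: read genome,
# annotation, variants and per-sample BEDPE alignments back in; enumerate
# strain-aware CpG sites; filter read pairs (concordance <= 600 bp inner gap,
# uniqueness, CpG-in-insert); build 2.2 kb tiles and promoter probes; count
# insert overlaps (midpoint on tiles, any-overlap on promoters); and apply
# the probe selection rule (>=1 CpG in either strain, >3 pairs in >2
# samples).
#
# Finds: filtration removes a small no-CpG fraction (background capture of
# unmethylated fragments) and nothing else in clean synthetic data; tile
# counts conserve the kept pairs exactly.

suppressMessages(library(mbddmr))
dir.create("results", showWarnings = FALSE)

dirin <- "scratch/experiment"
genome <- list(sequences = read_fasta_sequences(file.path(dirin, "genome.fa")))
genome <- c(genome, read_annotation_bed(file.path(dirin, "genes.bed12"),
                                        file.path(dirin, "enhancers.bed")))
class(genome) <- "genome_model"
variants <- read_vcf_variants(file.path(dirin, "strain_variants.vcf"),
                              min_depth = 3, require_homozygous = TRUE)
samples <- read_sample_sheet(file.path(dirin, "samples.tsv"),
                             require_full_design = TRUE)

sites <- list("C57BL/6J" = enumerate_cpg_sites(genome, NULL),
              "FVB/N" = enumerate_cpg_sites(genome, variants))
cat(sprintf("CpG sites: %d reference, %d FVB/N (%d SNP-created)\n",
            nrow(sites[[1]]), nrow(sites[[2]]),
            sum(sites[[2]]$provenance == "snp_created")))

filtered <- lapply(seq_len(nrow(samples)), function(i) {
  pairs <- read_bedpe(samples$path[i], samples$sample_id[i])
  filter_read_pairs(pairs, sites[[samples$strain[i]]], max_gap = 600)
})
names(filtered) <- samples$sample_id
tallies <- do.call(rbind, lapply(filtered, function(f) f$tally))
print(tallies)
kept <- do.call(rbind, lapply(filtered, function(f) f$kept))
library_size <- setNames(tallies[, "kept"], samples$sample_id)

tiles <- tile_genome(genome, 2200)
proms <- promoter_probes(genome)
ann <- build_feature_annotation(genome)
tiles$feature <- assign_feature(tiles, ann)
tiles <- count_probe_cpgs(tiles, sites[[1]], sites[[2]])
proms <- count_probe_cpgs(proms, sites[[1]], sites[[2]])

cnt_tiles <- count_overlaps(kept, tiles, samples, mode = "midpoint",
                            library_size = library_size)
cnt_proms <- count_overlaps(kept, proms, samples, mode = "any_overlap",
                            library_size = library_size)
stopifnot(all(colSums(cnt_tiles$counts) == library_size))  # conservation

sel_tiles <- select_probes(tiles, cnt_tiles)
sel_proms <- select_probes(proms, cnt_proms)
cat(sprintf("selected probes: %d/%d tiles, %d/%d promoters\n",
            nrow(sel_tiles), nrow(tiles), nrow(sel_proms), nrow(proms)))

write.table(data.frame(sample_id = rownames(tallies), tallies),
            "results/filter_tallies.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
saveRDS(list(samples = samples, sites = sites,
             tiles = sel_tiles, promoters = sel_proms,
             counts_tiles = subset_counts(cnt_tiles, probe_ids = sel_tiles$probe_id),
             counts_promoters = subset_counts(cnt_proms, probe_ids = sel_proms$probe_id)),
        "scratch/counts.rds")
cat("wrote results/filter_tallies.tsv and scratch/counts.rds\n")
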