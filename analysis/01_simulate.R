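#!/usr/bin/env Rscript
# Simulate the MBD-Seq experiment: two strains (reference plus a SNP-bearing
# strain) in quintuplicate per arm, with known-truth differentially
# methylated promoters injected — including strain-opposite interaction
# regions. All on-disk interchange formats (FASTA, BED12/BED6, VCF, BEDPE,
# TSV) are written under scratch/ so the later stages can start from files.
#
# Finds (seed 4242): ~1,050 homozygous strain SNPs of which ~10% affect the
# CpG census, and 18 truth regions over 60 promoters; each library captures
# roughly a quarter of its 30k sampled fragments.

suppressMessages(library(mbddmr))
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = 4242)
exp <- simulate_mbd_experiment(cfg)

cat(sprintf("genome: %d chromosomes x %s bp, %d genes\n", cfg$n_chroms,
            format(cfg$chrom_length, big.mark = ","), cfg$n_genes))
cat(sprintf("strain variants: %d (creating %d, destroying %d CpGs)\n",
            nrow(exp$variants), sum(exp$variants$cpg_creating),
            sum(exp$variants$cpg_destroying)))
cat(sprintf("truth regions: %d (%d interaction)\n", nrow(exp$truth),
            sum(exp$truth$interaction)))
cat(sprintf("captured pairs per library: %s\n",
            paste(range(vapply(exp$pairs, nrow, integer(1))), collapse = "-")))

write_experiment(exp, "scratch/experiment")
saveRDS(exp, "scratch/experiment.rds")
write.table(exp$truth, "results/known_truth.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote scratch/experiment/ and results/known_truth.tsv\n")
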