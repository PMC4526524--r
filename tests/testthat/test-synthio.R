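test_that("configuration validation rejects invalid rates and counts", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(seed = 1, snp_rate = 1.5), "rates")
  expect_error(sim_config(seed = 1, n_genes = 0), "positive")
  expect_error(capture_model(p_background = 0.99), "p_background")
  expect_error(capture_model(fragment_min = 300), "fragment_min")
})

test_that("identical configuration and seed give byte-identical output", {
  cfg <- small_sim_config(seed = 5L)
  e1 <- simulate_mbd_experiment(cfg)
  e2 <- simulate_mbd_experiment(small_sim_config(seed = 5L))
  expect_identical(e1$genome$sequences, e2$genome$sequences)
  expect_identical(e1$variants, e2$variants)
  expect_identical(e1$pairs, e2$pairs)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_experiment(e1, d1); write_experiment(e2, d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_identical(f1, f2)
  for (f in setdiff(f1, "samples.tsv"))  # sample sheet embeds the out dir path
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
})

test_that("promoters are CpG-enriched, and degenerate rates flatten the enrichment", {
  cfg <- sim_config(seed = 3, n_chroms = 1L, chrom_length = 150000L,
                    n_genes = 30L, target_pairs_per_sample = 100L)
  gm <- simulate_genome(cfg)
  sites <- enumerate_cpg_sites(gm)
  dens <- function(start, end) {
    sum(sites$pos >= start & sites$pos < end) / (end - start)
  }
  prom <- promoter_probes(gm)
  prom_d <- mapply(dens, prom$start, prom$end)
  in_prom <- rep(FALSE, nchar(gm$sequences))
  for (i in seq_len(nrow(prom))) in_prom[(prom$start[i] + 1):prom$end[i]] <- TRUE
  bg_d <- sum(!in_prom[sites$pos + 1L]) / sum(!in_prom)
  expect_gt(mean(prom_d), 4 * bg_d)   # 0.08 island vs 0.01 background

  cfg2 <- sim_config(seed = 3, n_chroms = 1L, chrom_length = 150000L,
                     n_genes = 30L, cpg_island_rate = 0.02,
                     background_cpg_rate = 0.02,
                     target_pairs_per_sample = 100L)
  gm2 <- simulate_genome(cfg2)
  sites2 <- enumerate_cpg_sites(gm2)
  prom2 <- promoter_probes(gm2)
  pd <- mapply(function(s, e) sum(sites2$pos >= s & sites2$pos < e) / (e - s),
               prom2$start, prom2$end)
  gd <- nrow(sites2) / nchar(gm2$sequences)
  expect_lt(abs(mean(pd) - gd), 2 * stats::sd(pd) / sqrt(length(pd)))
})

test_that("gene class census follows the configured fractions", {
  cfg <- sim_config(seed = 2, n_chroms = 1L, chrom_length = 100000L,
                    n_genes = 10L, target_pairs_per_sample = 100L,
                    class_fracs = c(vomeronasal = 0.3, olfactory = 0.3,
                                    microrna = 0.3))
  gm <- simulate_genome(cfg)
  census <- table(classify_gene_symbol(gm$genes$symbol))
  expect_equal(unname(census[c("vomeronasal", "olfactory", "microrna", "other")]),
               as.table(c(3L, 3L, 3L, 1L)), ignore_attr = TRUE)
})

test_that("strain variants are homozygous, flagged, and hit the affecting fraction", {
  cfg <- sim_config(seed = 8, n_chroms = 1L, chrom_length = 200000L,
                    n_genes = 20L, snp_rate = 5e-3,
                    frac_cpg_affecting_snps = 0.3,
                    target_pairs_per_sample = 100L)
  gm <- simulate_genome(cfg)
  v <- simulate_strain_variants(gm, cfg)
  expect_true(all(v$genotype == "1/1"))
  expect_true(all(v$depth >= 3))
  expect_gt(nrow(v), 800)
  phat <- mean(v$cpg_creating | v$cpg_destroying)
  ci <- 2.576 * sqrt(0.3 * 0.7 / nrow(v))
  expect_lt(abs(phat - 0.3), ci + 0.01)
  # flags agree with an independent reclassification
  expect_equal(classify_cpg_effect(gm, v$chrom, v$pos, v$ref, v$alt) == "creating",
               v$cpg_creating)
  # a vanishing SNP rate warns and returns an empty set
  cfg0 <- sim_config(seed = 8, n_chroms = 1L, chrom_length = 1000L,
                     n_genes = 1L, snp_rate = 1e-6,
                     target_pairs_per_sample = 100L)
  gm0 <- simulate_genome(cfg0)
  expect_warning(v0 <- simulate_strain_variants(gm0, cfg0), "below 1")
  expect_equal(nrow(v0), 0L)
})

test_that("capture probability follows the saturating model", {
  cap <- capture_model(p_background = 0)
  expect_equal(capture_probability(cap$k_half, cap), cap$p_max / 2)
  expect_equal(capture_probability(0, cap), 0)
  cap2 <- capture_model()
  expect_equal(capture_probability(0, cap2), cap2$p_background)
  k <- 0:50
  expect_true(all(diff(capture_probability(k, cap2)) > 0))
  expect_true(all(capture_probability(k, cap2) < cap2$p_max))
})

# single-chromosome genome with evenly spaced CpGs and no gene models
flat_genome <- function(L = 6000L, spacing = 25L) {
  base <- rep("A", L)
  pos <- seq(10L, L - 10L, by = spacing)
  base[pos + 1L] <- "C"; base[pos + 2L] <- "G"
  structure(list(sequences = c(chr1 = paste(base, collapse = "")),
                 genes = NULL, exons = NULL, enhancers = NULL),
            class = "genome_model")
}

flat_profile <- function(gm, p_ctl, p_dehp, strain = "C57BL/6J") {
  sites <- enumerate_cpg_sites(gm)
  structure(list(strains = stats::setNames(list(list(
    sites = sites,
    probs = cbind(control = rep(p_ctl, nrow(sites)),
                  dehp = rep(p_dehp, nrow(sites))))), strain),
    strain_names = strain), class = "meth_profile")
}

test_that("zero methylation with zero background capture emits no pairs", {
  gm <- flat_genome()
  cap <- capture_model(p_background = 0)
  prof <- flat_profile(gm, 0, 0)
  cfg <- sim_config(seed = 4, n_chroms = 1L, chrom_length = 6000L,
                    n_genes = 1L, target_pairs_per_sample = 2000L,
                    libsize_cv = 0)
  samples <- data.frame(sample_id = "s1", strain = "C57BL/6J",
                        treatment = "control", stringsAsFactors = FALSE)
  pr <- simulate_mbd_readpairs(gm, prof, cap, cfg, samples)
  expect_equal(nrow(pr$s1), 0L)
})

test_that("zero injected effect leaves all arm profiles identical", {
  cfg <- small_sim_config()
  gm <- simulate_genome(cfg)
  v <- simulate_strain_variants(gm, cfg)
  prom <- promoter_probes(gm)
  truth0 <- data.frame(chrom = prom$chrom[1:2], start = prom$start[1:2],
                       end = prom$end[1:2], strain = "both", log2fc = 0,
                       interaction = FALSE, stringsAsFactors = FALSE)
  m <- simulate_methylation(gm, v, truth0, seed = 1)
  for (st in m$profile$strain_names) {
    pf <- m$profile$strains[[st]]
    expect_identical(pf$probs[, "control"], pf$probs[, "dehp"])
  }
  expect_error(simulate_methylation(gm, v, data.frame(
    chrom = "chr1", start = 0L, end = 10 * cfg$chrom_length, strain = "both",
    log2fc = 1, interaction = FALSE), seed = 1), "outside genome")
})

test_that("interaction regions shift the two strains in opposite directions", {
  cfg <- small_sim_config()
  gm <- simulate_genome(cfg)
  v <- simulate_strain_variants(gm, cfg)
  prom <- promoter_probes(gm)
  truth <- data.frame(chrom = prom$chrom[1], start = prom$start[1],
                      end = prom$end[1], strain = "both", log2fc = 2,
                      interaction = TRUE, stringsAsFactors = FALSE)
  m <- simulate_methylation(gm, v, truth, seed = 1)
  shift_sign <- vapply(m$profile$strain_names, function(st) {
    pf <- m$profile$strains[[st]]
    inr <- pf$sites$chrom == truth$chrom & pf$sites$pos >= truth$start &
      pf$sites$pos < truth$end
    sign(mean(pf$probs[inr, "control"]) - mean(pf$probs[inr, "dehp"]))
  }, numeric(1))
  expect_equal(unname(shift_sign), c(1, -1))
})

test_that("an injected four-fold effect is realized in expected captured counts", {
  gm <- flat_genome(L = 6000L, spacing = 30L)
  cap <- capture_model()
  region <- data.frame(chrom = "chr1", start = 1400L, end = 3600L,
                       strain = "both", log2fc = 2, interaction = FALSE,
                       stringsAsFactors = FALSE)
  m <- simulate_methylation(gm, variants = NULL, truth_spec = region,
                            capture = cap, seed = 6)
  expect_lt(abs(m$truth$realized_log2fc - 2), 0.05)  # calibration residual
  # Monte-Carlo check with 1e5 fragments per arm
  cfg <- sim_config(seed = 10, n_chroms = 1L, chrom_length = 6000L,
                    n_genes = 1L, target_pairs_per_sample = 100000L,
                    libsize_cv = 0)
  samples <- data.frame(sample_id = c("ctl", "dehp"), strain = "C57BL/6J",
                        treatment = c("control", "dehp"),
                        stringsAsFactors = FALSE)
  pr <- simulate_mbd_readpairs(gm, m$profile, cap, cfg, samples)
  in_region <- function(p) {
    mid <- (pmin(p$start1, p$start2) + pmax(p$end1, p$end2)) %/% 2
    sum(mid >= region$start & mid < region$end)
  }
  ratio <- in_region(pr$ctl) / in_region(pr$dehp)
  expect_lt(abs(ratio / 4 - 1), 0.10)
})

test_that("capture counts match the closed-form model prediction and are monotone", {
  # two chromosomes, uniform methylation 0.1 vs 0.9, identical CpG density
  spacing <- 25L; L <- 6000L
  g1 <- flat_genome(L, spacing); g2 <- flat_genome(L, spacing)
  gm <- structure(list(sequences = c(chrA = g1$sequences[[1]],
                                     chrB = g2$sequences[[1]]),
                       genes = NULL, exons = NULL, enhancers = NULL),
                  class = "genome_model")
  sites <- enumerate_cpg_sites(gm)
  probs <- ifelse(sites$chrom == "chrA", 0.1, 0.9)
  prof <- structure(list(strains = list("C57BL/6J" = list(
    sites = sites, probs = cbind(control = probs, dehp = probs))),
    strain_names = "C57BL/6J"), class = "meth_profile")
  cap <- capture_model()
  cfg <- sim_config(seed = 12, n_chroms = 2L, chrom_length = L, n_genes = 1L,
                    target_pairs_per_sample = 10000L, libsize_cv = 0)
  samples <- data.frame(sample_id = "s1", strain = "C57BL/6J",
                        treatment = "control", stringsAsFactors = FALSE)
  pr <- simulate_mbd_readpairs(gm, prof, cap, cfg, samples)$s1
  nA <- sum(pr$chrom1 == "chrA"); nB <- sum(pr$chrom1 == "chrB")
  expect_gt(nB, nA)   # capture monotone in methylation level
  # closed-form expectation: k ~ Binomial(sites in fragment, p), averaged
  # over the truncated-normal length distribution
  lens <- cap$fragment_min:cap$fragment_max
  wl <- stats::dnorm(lens, cap$fragment_mean, cap$fragment_sd)
  wl <- wl / sum(wl)
  e_cap <- function(p) {
    sum(vapply(seq_along(lens), function(i) {
      msites <- floor(lens[i] / spacing)
      k <- 0:msites
      wl[i] * sum(stats::dbinom(k, msites, p) * capture_probability(k, cap))
    }, numeric(1)))
  }
  pred <- log(e_cap(0.9) / e_cap(0.1))
  obs <- log(nB / nA)
  ci99 <- 2.576 * sqrt(1 / nA + 1 / nB)
  expect_lt(abs(obs - pred), ci99 + 0.05)  # margin for chromosome-edge effects
})

test_that("library sizes vary log-normally around the target", {
  cfg <- sim_config(seed = 13, n_chroms = 1L, chrom_length = 6000L,
                    n_genes = 1L, target_pairs_per_sample = 3000L,
                    libsize_cv = 0.3)
  gm <- flat_genome()
  prof <- flat_profile(gm, 0.5, 0.5)
  samples <- data.frame(sample_id = paste0("s", 1:8), strain = "C57BL/6J",
                        treatment = "control", stringsAsFactors = FALSE)
  pr <- simulate_mbd_readpairs(gm, prof, capture_model(), cfg, samples)
  n <- vapply(pr, nrow, integer(1))
  expect_gt(stats::sd(n) / mean(n), 0.05)   # variation present
  expect_true(all(n > 0))
})
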