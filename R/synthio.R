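# Synthetic MBD-capture experiment generator.
#
# Emulates the study design at desk scale: two mouse strains differing by
# homozygous SNPs (some creating or destroying CpG dinucleotides), CpG-dense
# promoters, per-arm methylation landscapes with injected log2 fold-change
# effects (including strain-opposite interaction effects), MBD capture of
# ~200 bp fragments with saturating capture probability in methylated-CpG
# content, paired-end read emission and log-normal library-size variation.
# Every downstream stage can thus be validated against known truth.

#' Simulation configuration
#'
#' Defaults are the study conditions at desk scale: two strains in
#' quintuplicate per arm, CpG-enriched promoters over a low genomic
#' background, a SNP rate matching the strain-difference density of the
#' mouse strains compared, and library sizes scaled from the study's
#' millions of read pairs down to tens of thousands of fragments.
#'
#' @param seed mandatory RNG seed; the generator has no implicit randomness.
#' @param n_chroms,chrom_length genome shape (default 2 x 300 kb).
#' @param n_genes number of gene models (default 60).
#' @param cpg_island_rate per-bp probability that a promoter position starts
#'   a CpG (default 0.08).
#' @param background_cpg_rate per-bp CpG start probability elsewhere
#'   (default 0.01, about one CpG per 100 bp).
#' @param snp_rate per-bp probability of a strain-distinguishing SNP
#'   (default 1.8e-3, the genome-wide density implied by ~4.9 M SNPs).
#' @param frac_cpg_affecting_snps proportion of SNPs that create or destroy
#'   a CpG (default 0.1, split evenly between the two).
#' @param n_samples_per_arm biological replicates per strain x treatment arm
#'   (default 5, quintuplicate).
#' @param target_pairs_per_sample fragments sampled per library before
#'   capture (default 30000); the emitted pair count is the captured subset.
#' @param libsize_cv coefficient of variation of the log-normal library-size
#'   multiplier (default 0.2).
#' @param class_fracs named fractions of gene symbols drawn from the
#'   vomeronasal/olfactory/microRNA classes (defaults proportional to the
#'   238/1074/996 promoters of 22480 in the study).
#' @export
sim_config <- function(seed,
                       n_chroms = 2L, chrom_length = 300000L, n_genes = 60L,
                       cpg_island_rate = 0.08, background_cpg_rate = 0.01,
                       snp_rate = 1.8e-3, frac_cpg_affecting_snps = 0.1,
                       n_samples_per_arm = 5L,
                       target_pairs_per_sample = 30000L, libsize_cv = 0.2,
                       class_fracs = c(vomeronasal = 238, olfactory = 1074,
                                       microrna = 996) / 22480) {
  if (missing(seed) || !.is_count(seed + 1)) .stopf("an integer seed is mandatory")
  for (r in list(cpg_island_rate, background_cpg_rate, snp_rate,
                 frac_cpg_affecting_snps))
    if (!.is_prob(r)) .stopf("rates must lie in [0, 1]")
  if (any(class_fracs < 0) || sum(class_fracs) > 1)
    .stopf("class fractions must be non-negative and sum to at most 1")
  for (k in list(n_chroms, chrom_length, n_genes, n_samples_per_arm,
                 target_pairs_per_sample))
    if (!.is_count(k)) .stopf("lengths and counts must be positive integers")
  if (libsize_cv < 0) .stopf("libsize_cv must be non-negative")
  structure(list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
                 chrom_length = as.integer(chrom_length),
                 n_genes = as.integer(n_genes),
                 cpg_island_rate = cpg_island_rate,
                 background_cpg_rate = background_cpg_rate,
                 snp_rate = snp_rate,
                 frac_cpg_affecting_snps = frac_cpg_affecting_snps,
                 n_samples_per_arm = as.integer(n_samples_per_arm),
                 target_pairs_per_sample = as.integer(target_pairs_per_sample),
                 libsize_cv = libsize_cv, class_fracs = class_fracs),
            class = "sim_config")
}

#' MBD capture model
#'
#' Fragmentation at ~200 bp and a saturating (Michaelis-Menten) capture
#' probability in the number of methylated CpGs of the fragment:
#' `p(k) = p_background + (p_max - p_background) * k / (k + k_half)`.
#' The saturating form reflects the MBD protein binding a ~12 bp footprint:
#' a handful of methylated CpGs suffices for efficient capture. The study
#' states only that capture is methyl-CpG dependent; this functional form is
#' the generator's own modeling assumption and every parameter is
#' configurable.
#'
#' @param fragment_mean,fragment_sd,fragment_min,fragment_max truncated
#'   normal fragment length distribution in bp (defaults 200, 30, 80, 400).
#' @param p_max capture probability ceiling (default 0.95).
#' @param k_half methylated-CpG count at half-maximal capture (default 2).
#' @param p_background capture probability of a fully unmethylated fragment
#'   (default 0.01).
#' @param read_length emitted read length in bp (default 50).
#' @export
capture_model <- function(fragment_mean = 200, fragment_sd = 30,
                          fragment_min = 80, fragment_max = 400,
                          p_max = 0.95, k_half = 2, p_background = 0.01,
                          read_length = 50L) {
  if (!(fragment_min < fragment_mean && fragment_mean < fragment_max))
    .stopf("need fragment_min < fragment_mean < fragment_max")
  if (!(0 <= p_background && p_background < p_max && p_max <= 1))
    .stopf("need 0 <= p_background < p_max <= 1")
  structure(list(fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 fragment_min = fragment_min, fragment_max = fragment_max,
                 p_max = p_max, k_half = k_half, p_background = p_background,
                 read_length = as.integer(read_length)),
            class = "capture_model")
}

#' Capture probability of a fragment with k methylated CpGs
#'
#' @param k methylated CpG count (vectorized).
#' @param capture a [capture_model()].
#' @export
capture_probability <- function(k, capture) {
  capture$p_background +
    (capture$p_max - capture$p_background) * k / (k + capture$k_half)
}

#' Simulate a genome with gene models
#'
#' Chromosome sequences are uniform random DNA with CpG dinucleotides seeded
#' at `background_cpg_rate` per bp, raised to `cpg_island_rate` inside
#' promoter windows (2 kb upstream to 200 bp downstream of each TSS,
#' strand-aware) so promoters are CpG-enriched relative to background. Genes
#' get a strand, a TSS, 2-4 exons, and symbols drawn from the vomeronasal /
#' olfactory / microRNA / other classes at the configured fractions.
#' Identical configurations produce byte-identical genomes.
#'
#' @param config a [sim_config()].
#' @return list of class `genome_model`: sequences, genes, exons, enhancers.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.child_seed(config$seed, 0L))
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  L <- config$chrom_length

  # gene placement: round-robin over chromosomes, jittered regular spacing
  gi <- seq_len(config$n_genes)
  g_chrom <- chroms[(gi - 1L) %% config$n_chroms + 1L]
  genes <- do.call(rbind, lapply(chroms, function(cn) {
    idx <- which(g_chrom == cn)
    k <- length(idx)
    if (k == 0L) return(NULL)
    margin <- min(3000L, L %/% 10L)
    slot <- (L - 2L * margin) / k
    tss <- as.integer(margin + (seq_len(k) - 1L) * slot +
                        floor(stats::runif(k, 0.2, 0.8) * slot * 0.5))
    tss <- pmin(pmax(tss, 1L), L - 2L)
    strand <- sample(c("+", "-"), k, replace = TRUE)
    len <- pmin(as.integer(stats::runif(k, 2000, 8000)), L %/% 2L)
    start <- ifelse(strand == "+", tss, pmax(0L, tss + 1L - len))
    end <- ifelse(strand == "+", pmin(L, tss + len), tss + 1L)
    data.frame(gene_id = idx, chrom = cn, strand = strand, tss = tss,
               start = as.integer(start), end = as.integer(end),
               stringsAsFactors = FALSE)
  }))
  genes <- genes[order(genes$gene_id), , drop = FALSE]

  # gene symbols by class
  n <- config$n_genes
  n_cls <- round(config$class_fracs * n)
  cls <- rep("other", n)
  pool <- sample.int(n)
  off <- 0L
  for (cname in names(n_cls)) {
    k <- n_cls[[cname]]
    if (k > 0L) cls[pool[(off + 1L):(off + k)]] <- cname
    off <- off + k
  }
  prefix <- c(vomeronasal = "Vmn2r", olfactory = "Olfr", microrna = "Mir",
              other = "Gene")
  genes$symbol <- paste0(prefix[cls], genes$gene_id)
  genes$class <- cls

  # exons: 2-4 blocks inside the gene body
  exons <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    ne <- sample(2:4, 1L)
    width <- g$end - g$start
    bnd <- sort(sample.int(width - 2L, 2L * (ne - 1L))) + g$start
    st <- c(g$start, bnd[seq(2L, length(bnd), by = 2L)])
    en <- c(bnd[seq(1L, length(bnd), by = 2L)], g$end)
    data.frame(gene_id = g$gene_id, chrom = g$chrom, start = as.integer(st),
               end = as.integer(en), stringsAsFactors = FALSE)
  }))

  # a few enhancer intervals in intergenic space
  enh <- do.call(rbind, lapply(chroms, function(cn) {
    k <- max(1L, config$n_genes %/% (10L * config$n_chroms))
    w <- min(1000L, L %/% 6L)
    st <- as.integer(stats::runif(k, 0, L - 1.5 * w))
    data.frame(chrom = cn, start = st, end = st + w,
               name = sprintf("enh_%s_%d", cn, seq_len(k)),
               stringsAsFactors = FALSE)
  }))

  # sequences: uniform bases, then CpG seeds at position-dependent rates
  rate_tracks <- lapply(chroms, function(cn) {
    r <- rep(config$background_cpg_rate, L)
    gg <- genes[genes$chrom == cn, , drop = FALSE]
    for (i in seq_len(nrow(gg))) {
      w <- .promoter_window(gg$tss[i], gg$strand[i], L)
      r[(w[1] + 1L):w[2]] <- config$cpg_island_rate
    }
    r
  })
  names(rate_tracks) <- chroms
  sequences <- vapply(chroms, function(cn) {
    base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    # break accidental CG dinucleotides so the CpG density is exactly the
    # configured rate, not rate + 1/16 from uniform base composition
    repeat {
      cg <- which(base[-L] == "C" & base[-1L] == "G")
      if (length(cg) == 0L) break
      base[cg + 1L] <- sample(c("A", "C", "T"), length(cg), replace = TRUE)
    }
    sel <- stats::runif(L) < rate_tracks[[cn]]
    sel[L] <- FALSE
    sel <- sel & !c(FALSE, sel[-L])   # no overlapping seeds
    pos <- which(sel)
    base[pos] <- "C"; base[pos + 1L] <- "G"
    paste(base, collapse = "")
  }, character(1))

  structure(list(sequences = sequences, genes = genes, exons = exons,
                 enhancers = enh, config = config),
            class = "genome_model")
}

# promoter window [start, end) 0-based for a TSS (shared with probe design)
.promoter_window <- function(tss, strand, L, upstream = 2000L, downstream = 200L) {
  if (strand == "+") c(max(0L, tss - upstream), min(L, tss + downstream))
  else c(max(0L, tss - downstream + 1L), min(L, tss + upstream + 1L))
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosome(s), %s bp, %d genes\n",
              length(x$sequences), format(sum(nchar(x$sequences)), big.mark = ","),
              nrow(x$genes)))
  invisible(x)
}

#' Simulate homozygous strain-distinguishing variants
#'
#' Emits homozygous SNPs with simulated read-depth evidence. A configured
#' fraction affects the CpG census, split evenly between CpG-creating
#' (an existing C gains a following G) and CpG-destroying (the C of an
#' existing CpG mutates) substitutions; the remainder is CpG-neutral. Flags
#' are assigned by [classify_cpg_effect()] against the reference sequence.
#' SNP positions are kept at least 3 bp apart so each flag changes the
#' strain's CpG census independently.
#'
#' @param genome a `genome_model`.
#' @param config a [sim_config()].
#' @return variant data.frame (see [read_vcf_variants()] for columns).
#' @export
simulate_strain_variants <- function(genome, config) {
  stopifnot(inherits(genome, "genome_model"), inherits(config, "sim_config"))
  set.seed(.child_seed(config$seed, 1L))
  total_len <- sum(nchar(genome$sequences))
  n_snp <- stats::rbinom(1L, total_len, config$snp_rate)
  if (config$snp_rate * total_len < 1) {
    warning("expected SNP count below 1; returning empty variant set")
    return(.empty_variants())
  }
  n_aff <- stats::rbinom(1L, n_snp, config$frac_cpg_affecting_snps)
  n_create <- n_aff %/% 2L
  n_destroy <- n_aff - n_create
  n_neutral <- n_snp - n_aff

  chars <- lapply(genome$sequences, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  taken <- lapply(chars, function(x) logical(length(x)))
  free <- function(cn, p) {
    lo <- max(1L, p - 2L); hi <- min(length(taken[[cn]]), p + 4L)
    !any(taken[[cn]][lo:hi])
  }
  claim <- function(cn, p) taken[[cn]][max(1L, p - 2L):min(length(taken[[cn]]), p + 4L)] <<- TRUE

  pick <- function(n_want, candidates_fn, alt_fn) {
    out <- NULL
    guard <- 0L
    while (n_want > 0L && guard < 60L) {
      guard <- guard + 1L
      cand <- candidates_fn(min(n_want * 4L, 20000L))
      if (nrow(cand) == 0L) break
      for (i in seq_len(nrow(cand))) {
        if (n_want == 0L) break
        cn <- cand$chrom[i]; p <- cand$pos[i]
        if (!free(cn, p + 1L)) next
        a <- alt_fn(cn, p)
        if (is.na(a)) next
        claim(cn, p + 1L)
        out <- rbind(out, data.frame(chrom = cn, pos = p,
                                     ref = chars[[cn]][p + 1L], alt = a,
                                     stringsAsFactors = FALSE))
        n_want <- n_want - 1L
      }
    }
    out
  }
  rnd_pos <- function(k) {
    cn <- sample(names(chars), k, replace = TRUE,
                 prob = nchar(genome$sequences))
    pos <- vapply(cn, function(x) sample.int(length(chars[[x]]) - 2L, 1L),
                  integer(1))
    data.frame(chrom = cn, pos = pos, stringsAsFactors = FALSE)
  }

  # CpG-destroying: C of an existing CpG -> T (verified against the census)
  cg <- .scan_cg(genome$sequences)
  destroy <- pick(n_destroy,
    function(k) cg[sample.int(nrow(cg), min(k, nrow(cg))), , drop = FALSE],
    function(cn, p) {
      if (classify_cpg_effect(genome$sequences, cn, p, chars[[cn]][p + 1L],
                              "T") == "destroying") "T" else NA_character_
    })

  # CpG-creating: base right of a lone C mutates to G
  create <- pick(n_create, rnd_pos, function(cn, p) {
    x <- chars[[cn]]
    if (p < 1L || p + 2L > length(x)) return(NA_character_)
    if (x[p] != "C") return(NA_character_)      # needs a C immediately left
    ref <- x[p + 1L]
    if (ref == "G") return(NA_character_)       # CpG already present
    if (classify_cpg_effect(genome$sequences, cn, p, ref, "G") == "creating")
      "G" else NA_character_
  })

  # CpG-neutral: random substitution verified to leave the census unchanged
  neutral <- pick(n_neutral, rnd_pos, function(cn, p) {
    ref <- chars[[cn]][p + 1L]
    for (a in sample(setdiff(c("A", "C", "G", "T"), ref))) {
      eff <- classify_cpg_effect(genome$sequences, cn, p, ref, a)
      if (eff == "neutral") return(a)
    }
    NA_character_
  })

  v <- rbind(destroy, create, neutral)
  if (is.null(v) || nrow(v) == 0L) return(.empty_variants())
  v <- v[order(v$chrom, v$pos), , drop = FALSE]
  eff <- classify_cpg_effect(genome$sequences, v$chrom, v$pos, v$ref, v$alt)
  v$genotype <- "1/1"
  v$depth <- stats::rpois(nrow(v), 25) + 3L
  v$cpg_creating <- eff == "creating"
  v$cpg_destroying <- eff == "destroying"
  v$protein_modifying <- NA
  rownames(v) <- NULL
  v
}

#' Default truth specification
#'
#' Picks promoter regions to carry injected effects: regions affected in both
#' strains, in a single strain, and strain-opposite interaction regions. The
#' injected |log2fc| defaults to 2 (four-fold), comfortably beyond the
#' study's two-fold calling threshold.
#'
#' @param genome a `genome_model`.
#' @param n_both,n_single,n_interaction region counts (defaults 6, 4 per
#'   strain, 4).
#' @param log2fc injected effect magnitude (control-over-dehp, default 2).
#' @param seed RNG seed for region choice.
#' @export
default_truth_spec <- function(genome, n_both = 6L, n_single = 4L,
                               n_interaction = 4L, log2fc = 2, seed = 1L) {
  set.seed(.child_seed(seed, 7L))
  prom <- promoter_probes(genome)
  need <- n_both + 2L * n_single + n_interaction
  if (nrow(prom) < need) {
    # scale the allocation down proportionally for small genomes
    f <- nrow(prom) / need
    n_both <- max(1L, as.integer(n_both * f))
    n_single <- max(1L, as.integer(n_single * f))
    n_interaction <- max(1L, as.integer(n_interaction * f))
    need <- n_both + 2L * n_single + n_interaction
  }
  if (nrow(prom) < need) .stopf("not enough promoters for the truth spec")
  idx <- sample.int(nrow(prom), need)
  take <- function(k) {
    out <- prom[idx[seq_len(k)], c("chrom", "start", "end", "probe_id")]
    idx <<- idx[-seq_len(k)]
    out
  }
  sgn <- function(k) rep_len(c(1, -1), k)
  rows <- list(
    cbind(take(n_both), strain = "both", log2fc = sgn(n_both) * log2fc,
          interaction = FALSE),
    cbind(take(n_single), strain = "C57BL/6J", log2fc = sgn(n_single) * log2fc,
          interaction = FALSE),
    cbind(take(n_single), strain = "FVB/N", log2fc = sgn(n_single) * log2fc,
          interaction = FALSE),
    cbind(take(n_interaction), strain = "both", log2fc = log2fc,
          interaction = TRUE)
  )
  out <- do.call(rbind, rows)
  names(out)[names(out) == "probe_id"] <- "region_id"
  rownames(out) <- NULL
  out
}

#' Simulate per-arm methylation profiles with known-truth effects
#'
#' Draws baseline per-CpG methylation probabilities (shared between arms and,
#' for sites common to both strains, between strains), then shifts the DEHP
#' arm inside each truth region on the logit scale, with the shift calibrated
#' numerically so the expected captured-fragment count of the region differs
#' from control by the injected log2 fold-change under the given capture
#' model. Interaction regions get opposite-sign shifts in the two strains.
#' Truth records report the realized expected-count log-ratio.
#'
#' @param genome a `genome_model`.
#' @param variants strain variants of the alternate strain (FVB/N).
#' @param truth_spec data.frame(chrom, start, end, strain, log2fc,
#'   interaction) — see [default_truth_spec()].
#' @param capture a [capture_model()] (used for calibration).
#' @param base_shape1,base_shape2 Beta parameters of the baseline per-CpG
#'   methylation probability (defaults 1.5, 4.5: mean 0.25).
#' @param strains names of the reference and variant-carrying strain.
#' @param seed RNG seed for the baseline draw.
#' @return list(profile = `meth_profile`, truth = truth records with
#'   realized_log2fc).
#' @export
simulate_methylation <- function(genome, variants, truth_spec,
                                 capture = capture_model(),
                                 base_shape1 = 1.5, base_shape2 = 4.5,
                                 strains = c("C57BL/6J", "FVB/N"),
                                 seed = 1L) {
  set.seed(.child_seed(seed, 11L))
  lens <- nchar(genome$sequences)
  if (nrow(truth_spec) > 0) {
    bad <- truth_spec$chrom %in% names(lens) == FALSE |
      truth_spec$start < 0 | truth_spec$end > lens[truth_spec$chrom]
    if (any(bad)) .stopf("truth region outside genome bounds")
  }
  site_sets <- list(enumerate_cpg_sites(genome, NULL),
                    enumerate_cpg_sites(genome, variants))
  names(site_sets) <- strains

  # baseline probabilities keyed by position so shared sites agree
  all_keys <- unique(c(paste(site_sets[[1]]$chrom, site_sets[[1]]$pos),
                       paste(site_sets[[2]]$chrom, site_sets[[2]]$pos)))
  base <- stats::setNames(stats::rbeta(length(all_keys), base_shape1, base_shape2),
                          all_keys)

  profile <- list()
  truth <- truth_spec
  truth$realized_log2fc <- NA_real_
  for (si in seq_along(strains)) {
    st <- strains[si]
    sites <- site_sets[[st]]
    p0 <- unname(base[paste(sites$chrom, sites$pos)])
    probs <- cbind(control = p0, dehp = p0)
    for (ri in seq_len(nrow(truth_spec))) {
      tr <- truth_spec[ri, ]
      applies <- tr$strain == "both" || tr$strain == st
      if (!applies) next
      eff <- tr$log2fc
      if (isTRUE(tr$interaction) && si == 2L) eff <- -eff
      if (abs(eff) < 1e-12) { truth$realized_log2fc[ri] <- 0; next }
      in_region <- sites$chrom == tr$chrom & sites$pos >= tr$start &
        sites$pos < tr$end
      if (!any(in_region)) next
      cal <- .calibrate_logit_shift(sites, probs[, "control"], in_region,
                                    tr$chrom, tr$start, tr$end, eff, capture)
      probs[in_region, "control"] <- cal$control
      probs[in_region, "dehp"] <- cal$dehp
      realized <- cal$realized
      if (isTRUE(tr$interaction) && si == 2L) realized <- -realized
      # realized ratio is strain-specific; keep the first strain's for
      # non-interaction rows, record per-strain mean otherwise
      if (is.na(truth$realized_log2fc[ri])) truth$realized_log2fc[ri] <- realized
      else truth$realized_log2fc[ri] <- mean(c(truth$realized_log2fc[ri], realized))
    }
    profile[[st]] <- list(sites = sites, probs = probs)
  }
  list(profile = structure(list(strains = profile, strain_names = strains),
                           class = "meth_profile"),
       truth = truth)
}

# Expected capture probability of a fragment whose midpoint falls in the
# region, for per-site methylation probabilities `pr` over `sites`.
# Fragment length is fixed at the model mean (documented approximation);
# the Poisson-binomial distribution of the methylated-CpG count is evaluated
# exactly by dynamic programming on a grid of fragment positions.
.region_capture_expectation <- function(sites, pr, chrom, start, end,
                                        capture, step = 20L) {
  flen <- round(capture$fragment_mean)
  mids <- seq.int(start, end - 1L, by = step)
  fr_start <- mids - flen %/% 2L
  on_chrom <- sites$chrom == chrom
  sp <- sites$pos[on_chrom]
  pp <- pr[on_chrom]
  mean(vapply(fr_start, function(fs) {
    j <- which(sp >= fs & sp < fs + flen)
    if (length(j) == 0L) return(capture$p_background)
    dp <- 1
    for (p in pp[j]) dp <- c(dp * (1 - p), 0) + c(0, dp * p)
    sum(dp * capture_probability(0:(length(dp) - 1L), capture))
  }, numeric(1)))
}

# Solve for the logit shift achieving the requested expected-count log2
# ratio (control over dehp) in a region. The lower arm is always the one
# shifted downward — the baseline can sit near the capture ceiling, so the
# higher arm stays at baseline: for log2fc > 0 the DEHP arm is lowered, for
# log2fc < 0 the control arm is.
.calibrate_logit_shift <- function(sites, base_pr, in_region, chrom,
                                   start, end, log2fc, capture) {
  e_base <- .region_capture_expectation(sites, base_pr, chrom, start, end,
                                        capture)
  shifted_at <- function(s) {
    pr <- base_pr
    pr[in_region] <- stats::plogis(stats::qlogis(pr[in_region]) - s)
    pr
  }
  f <- function(s) {
    e_lo <- .region_capture_expectation(sites, shifted_at(s), chrom, start,
                                        end, capture)
    log2(e_base / e_lo) - abs(log2fc)
  }
  r <- stats::uniroot(f, c(0, 30), tol = 1e-4, extendInt = "upX")
  pr_lo <- shifted_at(r$root)
  e_lo <- .region_capture_expectation(sites, pr_lo, chrom, start, end, capture)
  if (log2fc >= 0) {
    list(control = base_pr[in_region], dehp = pr_lo[in_region],
         realized = log2(e_base / e_lo))
  } else {
    list(control = pr_lo[in_region], dehp = base_pr[in_region],
         realized = -log2(e_base / e_lo))
  }
}

#' Build the experiment sample sheet
#'
#' @param config a [sim_config()].
#' @param strains the two strain names.
#' @export
make_sample_sheet <- function(config, strains = c("C57BL/6J", "FVB/N")) {
  short <- c("C57", "FVB")
  grid <- expand.grid(rep = seq_len(config$n_samples_per_arm),
                      treatment = c("control", "dehp"),
                      strain_i = 1:2, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  data.frame(
    sample_id = sprintf("%s_%s_%d", short[grid$strain_i],
                        ifelse(grid$treatment == "control", "ctl", "dehp"),
                        grid$rep),
    strain = strains[grid$strain_i],
    treatment = grid$treatment,
    stringsAsFactors = FALSE
  )
}

#' Simulate MBD-captured read pairs for every sample
#'
#' Fragments are drawn uniformly along the genome with truncated-normal
#' lengths; each fragment's methylated-CpG count k is drawn per CpG from the
#' sample arm's profile; the fragment is retained with probability
#' `p_background + (p_max - p_background) * k / (k + k_half)`; retained
#' fragments emit a read pair covering `read_length` bp at each fragment
#' end. Library sizes vary log-normally with the configured CV. Fully
#' deterministic given the configuration seed.
#'
#' @param genome a `genome_model`.
#' @param profile a `meth_profile` from [simulate_methylation()].
#' @param capture a [capture_model()].
#' @param config a [sim_config()].
#' @param samples sample sheet (default [make_sample_sheet()]).
#' @return named list of read-pair data.frames, one per sample.
#' @export
simulate_mbd_readpairs <- function(genome, profile, capture, config,
                                   samples = make_sample_sheet(config)) {
  stopifnot(inherits(profile, "meth_profile"), inherits(capture, "capture_model"))
  if (capture$read_length > capture$fragment_min)
    .stopf("read_length exceeds fragment_min: a read cannot be longer than its fragment")
  lens <- nchar(genome$sequences)
  chroms <- names(lens)
  sdlog <- sqrt(log(1 + config$libsize_cv^2))
  out <- vector("list", nrow(samples))
  names(out) <- samples$sample_id
  for (i in seq_len(nrow(samples))) {
    set.seed(.child_seed(config$seed, 1000L + i))
    st <- samples$strain[i]
    arm <- samples$treatment[i]
    pf <- profile$strains[[st]]
    if (is.null(pf)) .stopf("profile not defined for strain %s", st)
    mult <- if (config$libsize_cv > 0)
      stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog) else 1
    n_frag <- max(0L, round(config$target_pairs_per_sample * mult))
    if (n_frag == 0L) { out[[i]] <- .empty_pairs(samples$sample_id[i]); next }
    fchrom <- sample(chroms, n_frag, replace = TRUE, prob = lens)
    flen <- round(stats::rnorm(n_frag, capture$fragment_mean, capture$fragment_sd))
    redo <- which(flen < capture$fragment_min | flen > capture$fragment_max)
    while (length(redo)) {
      flen[redo] <- round(stats::rnorm(length(redo), capture$fragment_mean,
                                       capture$fragment_sd))
      redo <- redo[flen[redo] < capture$fragment_min |
                     flen[redo] > capture$fragment_max]
    }
    fstart <- as.integer(floor(stats::runif(n_frag) * (lens[fchrom] - flen)))
    k <- integer(n_frag)
    for (cn in chroms) {
      fi <- which(fchrom == cn)
      if (length(fi) == 0L) next
      sel <- pf$sites$chrom == cn
      sp <- pf$sites$pos[sel]
      if (length(sp) == 0L) next
      prb <- pf$probs[sel, arm]
      hits <- IRanges::findOverlaps(.ir_point(sp),
                                    .ir(fstart[fi], fstart[fi] + flen[fi]))
      if (length(hits) == 0L) next
      meth <- stats::rbinom(length(hits), 1L, prb[S4Vectors::queryHits(hits)])
      k[fi] <- k[fi] + tabulate(S4Vectors::subjectHits(hits)[meth == 1L],
                                nbins = length(fi))
    }
    keep <- stats::runif(n_frag) < capture_probability(k, capture)
    fi <- which(keep)
    if (length(fi) == 0L) { out[[i]] <- .empty_pairs(samples$sample_id[i]); next }
    rl <- capture$read_length
    out[[i]] <- data.frame(
      chrom1 = fchrom[fi], start1 = fstart[fi], end1 = fstart[fi] + rl,
      chrom2 = fchrom[fi], start2 = fstart[fi] + flen[fi] - rl,
      end2 = fstart[fi] + flen[fi],
      name = sprintf("%s_frag%07d", samples$sample_id[i], fi),
      score = 1L, strand1 = "+", strand2 = "-",
      unique = TRUE, discordant = FALSE,
      sample_id = samples$sample_id[i], stringsAsFactors = FALSE
    )
  }
  out
}

.empty_pairs <- function(sample_id) {
  data.frame(chrom1 = character(0), start1 = integer(0), end1 = integer(0),
             chrom2 = character(0), start2 = integer(0), end2 = integer(0),
             name = character(0), score = integer(0), strand1 = character(0),
             strand2 = character(0), unique = logical(0),
             discordant = logical(0), sample_id = character(0),
             stringsAsFactors = FALSE)
}

#' Simulate a complete MBD-Seq experiment
#'
#' Convenience wrapper chaining [simulate_genome()],
#' [simulate_strain_variants()], [default_truth_spec()],
#' [simulate_methylation()] and [simulate_mbd_readpairs()].
#'
#' @param config a [sim_config()].
#' @param capture a [capture_model()].
#' @param truth_spec optional truth specification (default
#'   [default_truth_spec()] seeded from the config).
#' @return list: config, capture, genome, variants, truth, profile, samples,
#'   pairs.
#' @export
simulate_mbd_experiment <- function(config, capture = capture_model(),
                                    truth_spec = NULL) {
  genome <- simulate_genome(config)
  variants <- simulate_strain_variants(genome, config)
  if (is.null(truth_spec)) truth_spec <- default_truth_spec(genome, seed = config$seed)
  meth <- simulate_methylation(genome, variants, truth_spec, capture,
                               seed = config$seed)
  samples <- make_sample_sheet(config)
  pairs <- simulate_mbd_readpairs(genome, meth$profile, capture, config, samples)
  list(config = config, capture = capture, genome = genome,
       variants = variants, truth = meth$truth, profile = meth$profile,
       samples = samples, pairs = pairs)
}

#' Write a simulated experiment to disk
#'
#' Emits genome FASTA, gene BED12 + enhancer BED6, variants VCF, one BEDPE
#' per sample, the sample sheet and the truth table, plus a resolved
#' key-value configuration file.
#'
#' @param experiment result of [simulate_mbd_experiment()].
#' @param dir output directory (created if needed).
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta_sequences(experiment$genome, file.path(dir, "genome.fa"))
  write_annotation_bed(experiment$genome, file.path(dir, "genes.bed12"),
                       file.path(dir, "enhancers.bed"))
  write_variants_vcf(experiment$variants, file.path(dir, "strain_variants.vcf"))
  ss <- experiment$samples
  ss$path <- file.path(dir, paste0(ss$sample_id, ".bedpe"))
  for (i in seq_len(nrow(ss)))
    write_bedpe(experiment$pairs[[ss$sample_id[i]]], ss$path[i])
  data.table::fwrite(ss, file.path(dir, "samples.tsv"), sep = "\t")
  data.table::fwrite(experiment$truth, file.path(dir, "truth.tsv"), sep = "\t")
  cfg <- experiment$config
  kv <- vapply(names(cfg), function(k) paste0(k, " = ",
        paste(signif(unlist(cfg[[k]]), 8), collapse = ",")), character(1))
  writeLines(kv, file.path(dir, "config.txt"))
  invisible(dir)
}
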