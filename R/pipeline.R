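# End-to-end orchestration: simulate (optional) -> filter -> probes/select ->
# count -> DMR tests (genome-wide and promoter, per strain) -> interaction ->
# summaries. Intermediate objects are the module interchange structures, so
# every stage is independently re-runnable; the analysis/ scripts of the
# repository drive these stages one at a time.

#' Pipeline parameters
#'
#' All defaults match the study's printed values: 2.2 kb tiles, -2000/+200 bp
#' promoter windows, 600 bp concordance gap, the >3-pairs-in->2-samples probe
#' selection, |log2FC| > 1 with p < 0.01 genome-wide and Bonferroni
#' alpha = 0.05 at the promoter level.
#'
#' @param tile_length genome tile size (bp).
#' @param promoter_upstream,promoter_downstream promoter window extents (bp).
#' @param max_gap concordance inner-gap threshold (bp).
#' @param select_min_count,select_min_samples probe selection thresholds
#'   (strict: counts above `select_min_count` in more than
#'   `select_min_samples` samples).
#' @param fc_threshold,genome_wide_p,promoter_alpha calling thresholds.
#' @param dmr_method per-probe test for the two-group comparisons.
#' @export
pipeline_params <- function(tile_length = 2200L, promoter_upstream = 2000L,
                            promoter_downstream = 200L, max_gap = 600L,
                            select_min_count = 3L, select_min_samples = 2L,
                            fc_threshold = 1.0, genome_wide_p = 1e-2,
                            promoter_alpha = 0.05,
                            dmr_method = c("lrt", "exact")) {
  structure(list(tile_length = tile_length,
                 promoter_upstream = promoter_upstream,
                 promoter_downstream = promoter_downstream,
                 max_gap = max_gap, select_min_count = select_min_count,
                 select_min_samples = select_min_samples,
                 fc_threshold = fc_threshold, genome_wide_p = genome_wide_p,
                 promoter_alpha = promoter_alpha,
                 dmr_method = match.arg(dmr_method)),
            class = "pipeline_params")
}

#' Run the full DMR pipeline on an experiment
#'
#' Takes a simulated experiment (or an equivalent list built from files:
#' genome, variants, samples with per-sample read pairs) and executes
#' filtration, probe construction and selection, counting, normalization,
#' dispersion estimation, per-strain control-vs-DEHP tests on genome tiles
#' and promoter probes, the strain-by-treatment interaction contrast, and
#' the reporting summaries. Per-stage record counts are accumulated in a
#' log.
#'
#' @param experiment list with genome, variants, samples, pairs (see
#'   [simulate_mbd_experiment()]).
#' @param params a [pipeline_params()].
#' @param strains length-2 character vector; the first strain is the
#'   reference (variant-free) genome.
#' @return a results bundle (list) with per-stage outputs and a `log` of
#'   record counts.
#' @export
run_mbd_pipeline <- function(experiment, params = pipeline_params(),
                             strains = c("C57BL/6J", "FVB/N")) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  genome <- experiment$genome
  samples <- experiment$samples
  validate_sample_sheet(samples, require_full_design = TRUE)
  log <- list()

  sites <- stage("cpg_sites", {
    s <- list(enumerate_cpg_sites(genome, NULL),
              enumerate_cpg_sites(genome, experiment$variants))
    names(s) <- strains
    s
  })
  log$cpg_sites <- vapply(sites, nrow, integer(1))

  filtered <- stage("filter", {
    lapply(seq_len(nrow(samples)), function(i) {
      filter_read_pairs(experiment$pairs[[samples$sample_id[i]]],
                        sites[[samples$strain[i]]], max_gap = params$max_gap)
    })
  })
  names(filtered) <- samples$sample_id
  tallies <- do.call(rbind, lapply(filtered, function(f) f$tally))
  log$filter <- tallies
  kept <- do.call(rbind, lapply(filtered, function(f) f$kept))
  library_size <- stats::setNames(tallies[, "kept"], samples$sample_id)

  probes <- stage("probes", {
    tiles <- tile_genome(genome, params$tile_length)
    proms <- promoter_probes(genome, params$promoter_upstream,
                             params$promoter_downstream)
    ann <- build_feature_annotation(genome, params$promoter_upstream,
                                    params$promoter_downstream)
    tiles$feature <- assign_feature(tiles, ann)
    tiles <- count_probe_cpgs(tiles, sites[[1]], sites[[2]])
    proms <- count_probe_cpgs(proms, sites[[1]], sites[[2]])
    list(tiles = tiles, promoters = proms)
  })
  log$probes <- c(tiles = nrow(probes$tiles), promoters = nrow(probes$promoters))

  counts <- stage("count", {
    list(tiles = count_overlaps(kept, probes$tiles, samples,
                                mode = "midpoint", library_size = library_size),
         promoters = count_overlaps(kept, probes$promoters, samples,
                                    mode = "any_overlap",
                                    library_size = library_size))
  })

  selected <- stage("select", {
    list(tiles = select_probes(probes$tiles, counts$tiles,
                               params$select_min_count, params$select_min_samples),
         promoters = select_probes(probes$promoters, counts$promoters,
                                   params$select_min_count,
                                   params$select_min_samples))
  })
  log$selected <- c(tiles = nrow(selected$tiles),
                    promoters = nrow(selected$promoters))
  cnt_t <- subset_counts(counts$tiles, probe_ids = selected$tiles$probe_id)
  cnt_p <- subset_counts(counts$promoters, probe_ids = selected$promoters$probe_id)

  promoter_m <- nrow(selected$promoters)
  policy <- call_policy(fc_threshold = params$fc_threshold,
                        genome_wide_p = params$genome_wide_p,
                        promoter_alpha = params$promoter_alpha,
                        promoter_m = promoter_m)

  per_strain <- stage("dmr", {
    out <- list()
    for (st in strains) {
      ids <- samples$sample_id[samples$strain == st]
      ctl <- samples$sample_id[samples$strain == st & samples$treatment == "control"]
      dehp <- samples$sample_id[samples$strain == st & samples$treatment == "dehp"]
      for (level in c("tiles", "promoters")) {
        cnt <- if (level == "tiles") cnt_t else cnt_p
        sub <- subset_counts(cnt, sample_ids = ids)
        norm <- tmm_normalize(sub)
        disp <- estimate_dispersion(sub, design = factor(
          samples$treatment[match(ids, samples$sample_id)]),
          offsets = norm$offsets)
        res <- test_dmr(sub, arm_a = ctl, arm_b = dehp, dispersion = disp,
                        norm = norm, method = params$dmr_method)
        res <- call_dmrs(res, policy,
                         mode = if (level == "tiles") "genome_wide" else "promoter")
        pr <- if (level == "tiles") selected$tiles else selected$promoters
        res <- cbind(res, pr[match(res$probe_id, pr$probe_id),
                             setdiff(names(pr), "probe_id"), drop = FALSE])
        out[[paste(st, level, sep = ".")]] <- res
      }
    }
    out
  })

  interaction <- stage("interaction", {
    norm <- tmm_normalize(cnt_p)
    cellf <- interaction(factor(samples$strain, levels = strains),
                         factor(samples$treatment))
    disp <- estimate_dispersion(cnt_p, design = cellf, offsets = norm$offsets)
    test_interaction(cnt_p, dispersion = disp, norm = norm, m = promoter_m,
                     strain_levels = strains)
  })

  summaries <- stage("summarize", {
    feat_all <- feature_distribution(selected$tiles)
    feat_dmr <- list()
    for (st in strains) {
      r <- per_strain[[paste(st, "tiles", sep = ".")]]
      for (dir in c("hyper_in_control", "hypo_in_control")) {
        sub <- r[r$call == dir, , drop = FALSE]
        if (nrow(sub) > 0)
          feat_dmr[[paste(st, dir, sep = ".")]] <- feature_distribution(sub)
      }
    }
    classes <- list()
    for (st in strains) {
      r <- per_strain[[paste(st, "promoters", sep = ".")]]
      for (cl in c("vomeronasal", "olfactory", "microrna", "other"))
        classes[[paste(st, cl, sep = ".")]] <-
          volcano_quadrants(r, cl, policy, gene_class = r$gene_class)
    }
    list(feature_all = feat_all, feature_dmr = feat_dmr, classes = classes)
  })

  list(params = params, policy = policy, samples = samples, sites = sites,
       filter_tallies = tallies, probes = probes, selected = selected,
       counts = list(tiles = cnt_t, promoters = cnt_p),
       dmr = per_strain, interaction = interaction, summaries = summaries,
       truth = experiment$truth, log = log)
}

#' Write the pipeline results bundle to disk
#'
#' Emits per-contrast DMR TSVs, the interaction TSV, filter tallies, probe
#' BEDs and a run manifest (package version, seed if known, parameter
#' fingerprint).
#'
#' @param bundle result of [run_mbd_pipeline()].
#' @param dir output directory.
#' @param seed seed to record in the manifest.
#' @export
write_pipeline_outputs <- function(bundle, dir, seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(bundle$dmr)) {
    r <- bundle$dmr[[nm]]
    out <- data.frame(probe_id = r$probe_id, chrom = r$chrom, start = r$start,
                      end = r$end,
                      feature = if (!is.null(r$feature)) r$feature else NA,
                      gene_symbol = if (!is.null(r$gene_symbol)) r$gene_symbol else NA,
                      gene_class = if (!is.null(r$gene_class)) r$gene_class else NA,
                      mean_control = r$mean_a, mean_dehp = r$mean_b,
                      log2fc = r$log2fc, p = r$p, p_adjusted = r$p_adjusted,
                      call = r$call, stringsAsFactors = FALSE)
    write_results_tsv(out, file.path(dir, paste0("dmr_", gsub("[ /]", "_", nm), ".tsv")))
  }
  data.table::fwrite(bundle$interaction, file.path(dir, "interaction.tsv"),
                     sep = "\t")
  data.table::fwrite(data.frame(sample_id = rownames(bundle$filter_tallies),
                                bundle$filter_tallies),
                     file.path(dir, "filter_tallies.tsv"), sep = "\t")
  write_probes_bed(bundle$selected$tiles, file.path(dir, "tiles_selected.bed"))
  write_probes_bed(bundle$selected$promoters,
                   file.path(dir, "promoters_selected.bed"))
  param_fp <- paste(vapply(bundle$params, function(x) paste0(x, collapse = ","),
                           character(1)), collapse = ";")
  manifest <- c(
    sprintf("package_version\t%s", as.character(utils::packageVersion("mbddmr"))),
    sprintf("seed\t%s", seed),
    sprintf("params\t%s", param_fp),
    sprintf("n_samples\t%d", nrow(bundle$samples)),
    sprintf("promoter_m\t%d", bundle$policy$promoter_m)
  )
  writeLines(manifest, file.path(dir, "manifest.tsv"))
  invisible(dir)
}
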