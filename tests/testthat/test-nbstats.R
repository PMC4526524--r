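test_that("TMM factors are 1 for identical columns and compensate scaling", {
  set.seed(41)
  y <- rnbinom(500, mu = 50, size = 5)
  Y <- cbind(s1 = y, s2 = y, s3 = y)
  nf <- tmm_normalize(make_counts(Y))
  expect_equal(unname(nf$factors), rep(1, 3), tolerance = 1e-12)
  expect_equal(unname(exp(mean(log(nf$factors)))), 1)

  # one column doubled: effective library about 2x the others
  Y2 <- cbind(s1 = y, s2 = y, s3 = 2L * y)
  nf2 <- tmm_normalize(make_counts(Y2))
  r <- nf2$effective_libsize["s3"] / nf2$effective_libsize["s1"]
  expect_lt(abs(r / 2 - 1), 0.01)
  expect_error(tmm_normalize(make_counts(Y), library_size = c(0, 1, 1)),
               "zero library")
})

test_that("TMM trimming is robust to a 5% inflated minority of probes", {
  set.seed(42)
  G <- 2000
  mu <- exp(rnorm(G, log(80), 0.5))
  Y <- matrix(rnbinom(G * 4, mu = rep(mu, 4), size = 10), G, 4)
  lib <- stats::setNames(colSums(Y), paste0("s", 1:4))
  nf_null <- tmm_normalize(make_counts(Y), library_size = lib)
  Yd <- Y
  idx <- sample.int(G, G * 0.05)
  Yd[idx, 1] <- Yd[idx, 1] * 8L
  # the inflated minority sits entirely in the trimmed M tail, so the factor
  # is essentially unmoved
  nf_de <- tmm_normalize(make_counts(Yd), library_size = lib)
  expect_lt(abs(nf_de$factors[1] / nf_null$factors[1] - 1), 0.03)
  # an untrimmed mean of M would have been pulled by ~log2(8)*5% (~11%)
  M <- log2((Yd[, 1] / lib[1]) / (Yd[, 2] / lib[2]))
  expect_gt(abs(2^mean(M[is.finite(M)]) - 1), 0.06)
})

test_that("TMM agrees with the established reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(43)
  G <- 1000
  Y <- matrix(rnbinom(G * 6, mu = rep(exp(rnorm(G, 4, 0.8)), 6), size = 3),
              G, 6, dimnames = list(NULL, paste0("s", 1:6)))
  Y[sample.int(G, 50), 2] <- Y[sample.int(G, 50), 2] * 4L
  nf <- tmm_normalize(make_counts(Y))
  ref <- edgeR::calcNormFactors(edgeR::DGEList(counts = Y))$samples$norm.factors
  expect_equal(unname(nf$factors), ref, tolerance = 0.01)
})

test_that("dispersion estimation recovers the Poisson limit and phi = 0.2", {
  set.seed(44)
  G <- 2000; S <- 10
  grp <- factor(rep(c("a", "b"), each = 5))
  mu <- exp(rnorm(G, log(100), 0.7))
  Yp <- matrix(rpois(G * S, rep(mu, S)), G, S,
               dimnames = list(paste0("p", 1:G), paste0("s", 1:S)))
  cm <- make_counts(Yp)
  dp <- estimate_dispersion(cm, design = grp,
                            offsets = tmm_normalize(cm)$offsets)
  expect_lt(dp$common, 0.02)

  Yn <- matrix(rnbinom(G * S, mu = rep(mu, S), size = 1 / 0.2), G, S,
               dimnames = dimnames(Yp))
  cn <- make_counts(Yn)
  dn <- estimate_dispersion(cn, design = grp,
                            offsets = tmm_normalize(cn)$offsets)
  expect_gt(dn$common, 0.15)
  expect_lt(dn$common, 0.25)
  expect_error(estimate_dispersion(make_counts(matrix(0L, 5, 4))), "all-zero")
})

test_that("constant-count probes shrink by the prior-weight pull toward common", {
  set.seed(45)
  G <- 200; S <- 6
  Y <- matrix(rnbinom(G * S, mu = 50, size = 1 / 0.15), G, S,
              dimnames = list(paste0("p", 1:G), paste0("s", 1:S)))
  Y[1, ] <- 40L   # constant across samples: probe-wise estimate 0
  cm <- make_counts(Y, library_size = stats::setNames(rep(1e4, S), colnames(Y)))
  d <- estimate_dispersion(cm, offsets = stats::setNames(rep(log(1e4), S), colnames(Y)),
                           prior_weight = 10)
  expect_equal(unname(d$probe["p1"]), 0)
  df_res <- S - 1L
  expect_equal(unname(d$shrunk["p1"]),
               10 * d$common / (df_res + 10), tolerance = 1e-12)
})

test_that("identical arms give log2fc 0 and p near 1; labels flip the sign only", {
  set.seed(46)
  y <- rnbinom(100, mu = 60, size = 8)
  Y <- matrix(rep(y, 10), ncol = 10,
              dimnames = list(paste0("p", 1:100), paste0("s", 1:10)))
  cm <- make_counts(Y, library_size = stats::setNames(rep(1e4, 10), colnames(Y)))
  nf <- unit_norm(colnames(Y), 1e4)
  res <- test_dmr(cm, paste0("s", 1:5), paste0("s", 6:10), dispersion = 0.1,
                  norm = nf)
  expect_equal(res$log2fc, rep(0, 100))
  expect_true(all(res$p > 0.999))

  set.seed(47)
  Y2 <- matrix(rnbinom(1000, mu = 60, size = 8), 100, 10,
               dimnames = dimnames(Y))
  cm2 <- make_counts(Y2, library_size = stats::setNames(rep(1e4, 10), colnames(Y)))
  a <- test_dmr(cm2, paste0("s", 1:5), paste0("s", 6:10), dispersion = 0.1, norm = nf)
  b <- test_dmr(cm2, paste0("s", 6:10), paste0("s", 1:5), dispersion = 0.1, norm = nf)
  expect_equal(a$log2fc, -b$log2fc)
  expect_equal(a$p, b$p, tolerance = 1e-8)
  expect_error(test_dmr(cm2, paste0("s", 1:5), paste0("s", 5:10)), "overlap")
})

test_that("the NB GLM fit matches an established GLM on random cases", {
  skip_if_not_installed("MASS")
  set.seed(48)
  for (i in 1:5) {
    y <- rnbinom(12, mu = exp(rnorm(1, 4, 1)), size = 5)
    x <- rep(c(0, 1), each = 6)
    off <- log(runif(12, 8e3, 1.2e4))
    phi <- 0.2
    X <- cbind(1, x)
    fit <- mbddmr:::.nb_fit_glm(y, X, off, phi)
    ref <- suppressWarnings(stats::glm(y ~ x + offset(off),
                                       family = MASS::negative.binomial(theta = 1 / phi)))
    expect_equal(unname(fit$beta), unname(stats::coef(ref)), tolerance = 1e-5)
  }
})

test_that("Poisson-limit exact test equals the enumerated conditional binomial", {
  # independent oracle: direct enumeration of the conditional split
  oracle_p <- function(ya, yb, na, nb) {
    s <- ya + yb
    pr <- stats::dbinom(0:s, s, na / (na + nb))
    sum(pr[pr <= pr[ya + 1] * (1 + 1e-8)])
  }
  sample_ids <- paste0("s", 1:10)
  nf <- unit_norm(sample_ids, 1000)
  split5 <- function(tot) c(rep(tot %/% 5, 4), tot - 4 * (tot %/% 5))
  worst <- 0
  for (tot in c(20L, 50L, 120L, 200L)) {
    for (ya in unique(round(seq(0, tot, length.out = 15)))) {
      yb <- tot - ya
      Y <- matrix(c(split5(ya), split5(yb)), 1, 10,
                  dimnames = list("p1", sample_ids))
      cm <- make_counts(Y, library_size = stats::setNames(rep(1000L, 10), sample_ids))
      p_impl <- test_dmr(cm, sample_ids[1:5], sample_ids[6:10],
                         dispersion = 1e-12, norm = nf, method = "exact")$p
      p_orc <- oracle_p(ya, yb, 5, 5)
      if (p_orc >= 1e-6 && p_orc <= 0.5)
        worst <- max(worst, abs(p_impl / p_orc - 1))
    }
  }
  expect_lt(worst, 0.10)
})

test_that("type-I error is nominal on null simulations", {
  set.seed(49)
  G <- 2000; S <- 10
  mu <- exp(rnorm(G, log(100), 0.7))
  Y <- matrix(rnbinom(G * S, mu = rep(mu, S), size = 1 / 0.2), G, S,
              dimnames = list(paste0("p", 1:G), paste0("s", 1:S)))
  cm <- make_counts(Y)
  nf <- tmm_normalize(cm)
  grp <- factor(rep(c("a", "b"), each = 5))
  d <- estimate_dispersion(cm, design = grp, offsets = nf$offsets)
  res <- test_dmr(cm, colnames(Y)[1:5], colnames(Y)[6:10], dispersion = d,
                  norm = nf)
  frac <- mean(res$p < 0.01)
  ci <- 2.576 * sqrt(0.01 * 0.99 / G)
  expect_lt(abs(frac - 0.01), ci)
})

test_that("injected four-fold effects are recovered in the estimated log2fc", {
  set.seed(50)
  G <- 500
  Y <- cbind(matrix(rnbinom(G * 5, mu = 200, size = 1 / 0.05), G, 5),
             matrix(rnbinom(G * 5, mu = 50, size = 1 / 0.05), G, 5))
  dimnames(Y) <- list(paste0("p", 1:G), paste0("s", 1:10))
  cm <- make_counts(Y, library_size = stats::setNames(rep(125000L, 10), colnames(Y)))
  res <- test_dmr(cm, paste0("s", 1:5), paste0("s", 6:10), dispersion = 0.05,
                  norm = unit_norm(colnames(Y), 125000))
  expect_lt(abs(stats::median(res$log2fc) - 2), 0.15)
  expect_true(all(res$p[res$log2fc > 1.5] < 1e-4))
})

test_that("normalization keeps inference stable when a sample is rescaled", {
  set.seed(51)
  G <- 400
  Y <- matrix(rnbinom(G * 10, mu = 150, size = 1 / 0.1), G, 10,
              dimnames = list(paste0("p", 1:G), paste0("s", 1:10)))
  cm <- make_counts(Y)
  nf <- tmm_normalize(cm)
  Y2 <- Y; Y2[, 1] <- 3L * Y2[, 1]
  cm2 <- make_counts(Y2)
  nf2 <- tmm_normalize(cm2)
  # the factor absorbs the scaling: effective library ratio tracks 3x
  r <- (nf2$effective_libsize[1] / nf2$effective_libsize[2]) /
    (nf$effective_libsize[1] / nf$effective_libsize[2])
  expect_lt(abs(r / 3 - 1), 0.01)
  # normalized means are unchanged
  q1 <- Y[, 1] / nf$effective_libsize[1]
  q2 <- Y2[, 1] / nf2$effective_libsize[1]
  expect_equal(q1 / mean(q1), q2 / mean(q2), tolerance = 0.01)
  # and p-values stay close after re-normalization
  a <- test_dmr(cm, paste0("s", 1:5), paste0("s", 6:10), dispersion = 0.1, norm = nf)
  b <- test_dmr(cm2, paste0("s", 1:5), paste0("s", 6:10), dispersion = 0.1, norm = nf2)
  expect_gt(stats::cor(log10(a$p), log10(b$p)), 0.98)
})

test_that("Bonferroni threshold and DMR calling apply the printed rules", {
  expect_equal(signif(bonferroni_threshold(0.05, 22480), 2), 2.2e-6)
  expect_equal(bonferroni_threshold(0.05, 22480), 0.05 / 22480)
  expect_equal(bonferroni_threshold(0.3, 1), 0.3)
  expect_equal(bonferroni_threshold(0.05, 20), 2.5e-3)
  expect_error(bonferroni_threshold(0.05, 0), "m must be")

  res <- data.frame(probe_id = c("a", "b", "c", "d"),
                    log2fc = c(1.2, 0.9, -1.5, 1.1),
                    p = c(1e-3, 1e-8, 1e-3, 0.5),
                    stringsAsFactors = FALSE)
  gw <- call_dmrs(res, call_policy(), mode = "genome_wide")
  expect_equal(gw$call, c("hyper_in_control", "none", "hypo_in_control", "none"))
  pol <- call_policy(promoter_m = 22480)
  pr <- call_dmrs(data.frame(probe_id = "x", log2fc = 1.5, p = 1e-5),
                  pol, mode = "promoter")
  expect_equal(pr$call, "none")   # 1e-5 > 0.05 / 22480
  pr2 <- call_dmrs(data.frame(probe_id = "x", log2fc = 1.5, p = 1e-7),
                   pol, mode = "promoter")
  expect_equal(pr2$call, "hyper_in_control")
  expect_error(call_dmrs(res, call_policy(), mode = "promoter"), "promoter_m")
})

test_that("interaction Z equals the stratified log2fc difference on noiseless counts", {
  ss <- design_2x2(n = 2L)
  # expected counts with a clean interaction: effects 2 and -1 in log2
  mu <- c(C57_ctl = 400, C57_dehp = 100, FVB_ctl = 100, FVB_dehp = 200)
  Y <- matrix(rep(c(rep(mu["C57_ctl"], 2), rep(mu["C57_dehp"], 2),
                    rep(mu["FVB_ctl"], 2), rep(mu["FVB_dehp"], 2)), 3),
              nrow = 3, byrow = TRUE,
              dimnames = list(paste0("p", 1:3), ss$sample_id))
  cm <- make_counts(Y, ss, stats::setNames(rep(1e5, 8), ss$sample_id))
  it <- test_interaction(cm, dispersion = 0.05, norm = unit_norm(ss$sample_id),
                         m = 10)
  expect_equal(it$Z, it[["log2fc_C57BL/6J"]] - it[["log2fc_FVB/N"]],
               tolerance = 1e-6)
  expect_equal(it[["log2fc_C57BL/6J"]], rep(2, 3), tolerance = 1e-6)
  expect_equal(it[["log2fc_FVB/N"]], rep(-1, 3), tolerance = 1e-6)
  # missing design cell errors cleanly
  broken <- subset_counts(cm, sample_ids = ss$sample_id[ss$sample_id != "s7"])
  expect_error(test_interaction(broken), "deficient cell")
})

test_that("interaction p-values are uniform when both strains respond alike", {
  set.seed(52)
  G <- 2000
  ss <- design_2x2()
  mu <- matrix(100, G, 20)
  mu[, c(6:10, 16:20)] <- 25   # same +2 treatment effect in both strains
  Y <- matrix(rnbinom(G * 20, mu = mu, size = 1 / 0.05), G, 20,
              dimnames = list(paste0("p", 1:G), ss$sample_id))
  cm <- make_counts(Y, ss, stats::setNames(rep(1e5, 20), ss$sample_id))
  it <- test_interaction(cm, dispersion = 0.05,
                         norm = unit_norm(ss$sample_id), m = 10000)
  expect_lt(abs(mean(it$Z)), 0.05)
  expect_gt(stats::ks.test(it$p, "punif")$p.value, 0.01)
})

test_that("opposite strain effects are flagged and permutation destroys them", {
  set.seed(53)
  G <- 100
  ss <- design_2x2()
  mu <- matrix(100, G, 20)
  mu[, 6:10] <- 25    # C57: control - dehp = +2
  mu[, 16:20] <- 400  # FVB: control - dehp = -2
  Y <- matrix(rnbinom(G * 20, mu = mu, size = 1 / 0.05), G, 20,
              dimnames = list(paste0("p", 1:G), ss$sample_id))
  cm <- make_counts(Y, ss, stats::setNames(rep(1e5, 20), ss$sample_id))
  nf <- unit_norm(ss$sample_id)
  it <- test_interaction(cm, dispersion = 0.05, norm = nf, m = 10000)
  expect_gt(mean(it$genome_wide_significant), 0.90)
  # permute strain labels within treatment (balanced interleave: a maximally
  # mixed permutation; near-identity draws would retain genuine signal) and
  # re-estimate dispersion as a real permutation analysis would
  perm <- ss
  for (tr in c("control", "dehp")) {
    i <- which(ss$treatment == tr)
    perm$strain[i] <- rep(c("C57BL/6J", "FVB/N"), length.out = length(i))
  }
  cmp <- cm; cmp$samples <- perm
  dperm <- estimate_dispersion(cmp, design = interaction(perm$strain, perm$treatment),
                               offsets = nf$offsets)
  itp <- test_interaction(cmp, dispersion = dperm, norm = nf, m = 10000)
  expect_lte(mean(itp$p < 0.05), 0.05)
})
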