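# Negative-binomial count statistics for MBD-Seq probes.
#
# The NB log-linear machinery (TMM offsets, adjusted-profile-likelihood
# dispersion estimation, likelihood-ratio and exact two-group tests, the
# strain x treatment interaction contrast) is implemented here; established
# packages serve only as independent cross-checks in the test suite.

#' Trimmed-mean-of-M-values (TMM) normalization
#'
#' Computes per-sample scaling factors robust to a minority of differential
#' probes: pairwise log-ratios (M) against a reference sample are doubly
#' trimmed (30% of each M tail, 5% of each A tail) and averaged with
#' asymptotic precision weights. The reference is the sample whose
#' upper-quartile count fraction is closest to the mean. Factors are rescaled
#' so their geometric mean is 1; effective library size is library size times
#' factor, and `offsets` are its natural logarithm, ready for the GLM.
#'
#' @param counts an `mbd_counts` object (>= 2 samples) or a count matrix.
#' @param library_size per-sample totals (taken from the object if omitted).
#' @param logratio_trim,abs_trim trim fractions for M and A (defaults 0.30
#'   and 0.05, per tail).
#' @return list of class `tmm_norm`: factors, effective_libsize, offsets.
#' @export
tmm_normalize <- function(counts, library_size = NULL,
                          logratio_trim = 0.30, abs_trim = 0.05) {
  if (inherits(counts, "mbd_counts")) {
    m <- counts$counts
    if (is.null(library_size)) library_size <- counts$library_size
  } else m <- counts
  if (is.null(library_size)) library_size <- colSums(m)
  if (ncol(m) < 2L) .stopf("TMM needs at least 2 samples")
  if (any(library_size <= 0)) .stopf("sample with zero library size")
  N <- as.numeric(library_size)
  f75 <- apply(m, 2L, function(y) stats::quantile(y / sum(y), 0.75))
  # upper-quartile fraction uses each sample's own total so that externally
  # supplied library sizes cannot skew reference choice
  ref <- which.min(abs(f75 - mean(f75)))
  fac <- vapply(seq_len(ncol(m)), function(j) {
    .tmm_pair_factor(m[, j], m[, ref], N[j], N[ref], logratio_trim, abs_trim)
  }, numeric(1))
  fac <- fac / exp(mean(log(fac)))
  eff <- N * fac
  structure(list(factors = stats::setNames(fac, colnames(m)),
                 effective_libsize = stats::setNames(eff, colnames(m)),
                 offsets = stats::setNames(log(eff), colnames(m)),
                 reference = colnames(m)[ref]),
            class = "tmm_norm")
}

.tmm_pair_factor <- function(y, yr, N, Nr, logratio_trim, abs_trim) {
  ok <- y > 0 & yr > 0
  if (sum(ok) == 0L) return(1)
  y <- y[ok]; yr <- yr[ok]
  M <- log2((y / N) / (yr / Nr))
  A <- 0.5 * (log2(y / N) + log2(yr / Nr))
  w <- (N - y) / (N * y) + (Nr - yr) / (Nr * yr)
  fin <- is.finite(M) & is.finite(A)
  M <- M[fin]; A <- A[fin]; w <- w[fin]
  n <- length(M)
  if (n == 0L) return(1)
  if (max(abs(M)) < 1e-6) return(1)
  loM <- floor(n * logratio_trim) + 1L; hiM <- n + 1L - loM
  loA <- floor(n * abs_trim) + 1L; hiA <- n + 1L - loA
  rM <- rank(M, ties.method = "first"); rA <- rank(A, ties.method = "first")
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep)) return(1)
  f <- sum(M[keep] / w[keep]) / sum(1 / w[keep])
  if (!is.finite(f)) f <- 0
  2^f
}

# ---------------------------------------------------------------------------
# NB GLM fitting
# ---------------------------------------------------------------------------

# Log-likelihood of NB counts at fitted means (phi = 0 is the Poisson limit).
.nb_loglik <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-10)
  if (phi < 1e-10) sum(stats::dpois(y, mu, log = TRUE))
  else sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
}

# One-way (cell-means) NB fit, vectorized across probes.
# Y: G x S count matrix; groups: factor of length S; offsets: length S;
# phi: scalar or length-G vector. Returns fitted means, per-probe loglik and
# the Cox-Reid adjustment term 0.5*log det(X'WX) (diagonal for cell means).
.nb_fit_oneway <- function(Y, groups, offsets, phi) {
  G <- nrow(Y); S <- ncol(Y)
  groups <- as.factor(groups)
  phi <- rep_len(phi, G)
  mu <- matrix(0, G, S, dimnames = dimnames(Y))
  logdet <- numeric(G)
  eoff <- exp(offsets)
  for (lev in levels(groups)) {
    js <- which(groups == lev)
    Yg <- Y[, js, drop = FALSE]
    eo <- eoff[js]
    tot <- rowSums(Yg)
    gamma <- tot / sum(eo)                  # Poisson MLE as start
    zero <- tot == 0
    theta <- log(pmax(gamma, 1e-12))
    off_m <- matrix(log(eo), G, length(js), byrow = TRUE)
    for (it in 1:50) {
      MU <- exp(theta + off_m)
      W <- MU / (1 + phi * MU)
      score <- rowSums((Yg - MU) / (1 + phi * MU))
      info <- rowSums(W)
      step <- ifelse(info > 0, score / info, 0)
      step <- pmin(pmax(step, -5), 5)
      step[zero] <- 0
      theta <- theta + step
      if (max(abs(step)) < 1e-10) break
    }
    MU <- exp(theta + off_m)
    MU[zero, ] <- 1e-12
    mu[, js] <- MU
    W <- MU / (1 + phi * MU)
    logdet <- logdet + log(pmax(rowSums(W), 1e-300))
  }
  ll <- vapply(seq_len(G), function(g) .nb_loglik(Y[g, ], mu[g, ], phi[g]), numeric(1))
  list(mu = mu, loglik = ll, cr_adj = 0.5 * logdet)
}

# General NB IRLS fit for one probe with an arbitrary design matrix.
.nb_fit_glm <- function(y, X, offsets, phi, max_iter = 100L) {
  mu <- pmax(y, 0.5)
  eta <- log(mu)
  for (it in seq_len(max_iter)) {
    W <- mu / (1 + phi * mu)
    z <- (eta - offsets) + (y - mu) / pmax(mu, 1e-10)
    XtW <- t(X * W)
    beta <- tryCatch(solve(XtW %*% X, XtW %*% z),
                     error = function(e) qr.coef(qr(sqrt(W) * X), sqrt(W) * z))
    beta[!is.finite(beta)] <- 0
    eta_new <- pmin(pmax(drop(X %*% beta) + offsets, -30), 30)
    if (max(abs(eta_new - eta)) < 1e-10) { eta <- eta_new; break }
    eta <- eta_new
    mu <- exp(eta)
  }
  mu <- exp(eta)
  W <- mu / (1 + phi * mu)
  list(beta = drop(beta), mu = mu, loglik = .nb_loglik(y, mu, phi),
       cr_adj = 0.5 * determinant(t(X * W) %*% X, logarithm = TRUE)$modulus[1])
}

# Per-probe adjusted profile log-likelihood at a given dispersion.
.apl <- function(Y, groups, offsets, phi) {
  fit <- .nb_fit_oneway(Y, groups, offsets, phi)
  fit$loglik - fit$cr_adj
}

#' Estimate negative-binomial dispersion
#'
#' The common dispersion maximizes the Cox-Reid adjusted profile likelihood
#' pooled over probes under a cell-means design. Per-probe dispersions are
#' maximized on a log-spaced grid (with parabolic refinement) and shrunk
#' toward the common value with a prior weight:
#' `phi_g = (df_res * phi_hat_g + prior_weight * phi_common) / (df_res +
#' prior_weight)`. A probe with constant counts has probe-wise estimate 0 and
#' its shrunk value is the prior-weighted pull toward the common value.
#'
#' @param counts `mbd_counts` object or count matrix.
#' @param design factor (or sample-sheet columns) defining the cell-means
#'   design; defaults to a single group.
#' @param offsets log effective library sizes from [tmm_normalize()].
#' @param prior_weight shrinkage prior weight in residual-df units
#'   (default 10).
#' @param grid dispersion grid for the per-probe maximization.
#' @return list of class `nb_dispersion`: common, probe (raw per-probe),
#'   shrunk, prior_weight.
#' @export
estimate_dispersion <- function(counts, design = NULL, offsets = NULL,
                                prior_weight = 10,
                                grid = 10^seq(-6, 1, length.out = 36)) {
  Y <- if (inherits(counts, "mbd_counts")) counts$counts else counts
  if (all(Y == 0)) .stopf("all-zero count matrix")
  S <- ncol(Y)
  groups <- if (is.null(design)) factor(rep("all", S)) else as.factor(design)
  if (is.null(offsets)) offsets <- log(pmax(colSums(Y), 1))
  df_res <- S - nlevels(groups)
  if (df_res < 1L) .stopf("no residual degrees of freedom for dispersion estimation")

  pooled <- function(log_phi) sum(.apl(Y, groups, offsets, exp(log_phi)))
  opt <- stats::optimize(pooled, interval = log(c(1e-7, 10)), maximum = TRUE,
                         tol = 1e-4)
  common <- exp(opt$maximum)
  if (common < 1.5e-7) common <- 0

  apl_grid <- vapply(grid, function(p) .apl(Y, groups, offsets, p),
                     numeric(nrow(Y)))
  apl_grid <- matrix(apl_grid, nrow = nrow(Y))
  phi_hat <- .grid_argmax(grid, apl_grid)
  # constant-count probes (no residual variation) sit at the boundary
  phi_hat[phi_hat <= grid[1] * 1.5] <- 0

  shrunk <- (df_res * phi_hat + prior_weight * common) / (df_res + prior_weight)
  structure(list(common = common,
                 probe = stats::setNames(phi_hat, rownames(Y)),
                 shrunk = stats::setNames(shrunk, rownames(Y)),
                 prior_weight = prior_weight, df_residual = df_res),
            class = "nb_dispersion")
}

# Row-wise argmax on a log-spaced grid with parabolic refinement.
.grid_argmax <- function(grid, val) {
  idx <- max.col(val, ties.method = "first")
  lg <- log(grid)
  out <- numeric(nrow(val))
  for (g in seq_len(nrow(val))) {
    i <- idx[g]
    if (i == 1L || i == length(grid)) { out[g] <- grid[i]; next }
    y0 <- val[g, i - 1L]; y1 <- val[g, i]; y2 <- val[g, i + 1L]
    denom <- y0 - 2 * y1 + y2
    delta <- if (abs(denom) < 1e-12) 0 else 0.5 * (y0 - y2) / denom
    delta <- pmin(pmax(delta, -1), 1)
    out[g] <- exp(lg[i] + delta * (lg[2] - lg[1]))
  }
  out
}

# ---------------------------------------------------------------------------
# Two-group DMR test
# ---------------------------------------------------------------------------

#' Per-probe two-group differential-methylation test
#'
#' Fits a negative-binomial log-linear model with an arm effect per probe and
#' reports a two-sided p-value, either from the likelihood-ratio test
#' (chi-square, 1 df; the default) or from the exact conditional test on the
#' arm totals (`method = "exact"`, the classic two-group variant; reduces to
#' the conditional binomial split in the Poisson limit). The reported log2
#' fold-change is oriented control-over-dehp — `log2(mean_a) - log2(mean_b)`
#' on normalized means with a display-only count offset of 0.125 (never used
#' in the likelihood). Probes with zero counts everywhere get p = 1 and
#' log2fc = 0.
#'
#' @param counts `mbd_counts` object.
#' @param arm_a,arm_b sample ids of the two arms (arm A is conventionally the
#'   control arm). Must not overlap.
#' @param dispersion `nb_dispersion` object (its `shrunk` values are used), a
#'   numeric vector, or a scalar.
#' @param norm `tmm_norm` object for the samples involved (computed on the
#'   fly if omitted).
#' @param method `"lrt"` or `"exact"`.
#' @return data.frame: probe_id, mean_a, mean_b (normalized), log2fc, p,
#'   p_adjusted (Benjamini-Hochberg), call (filled by [call_dmrs()]).
#' @export
test_dmr <- function(counts, arm_a, arm_b, dispersion = NULL, norm = NULL,
                     method = c("lrt", "exact")) {
  method <- match.arg(method)
  if (length(intersect(arm_a, arm_b))) .stopf("arms overlap")
  if (length(arm_a) == 0L || length(arm_b) == 0L) .stopf("both arms must be non-empty")
  sub <- subset_counts(counts, sample_ids = c(arm_a, arm_b))
  if (is.null(norm)) norm <- tmm_normalize(sub)
  offsets <- norm$offsets[colnames(sub$counts)]
  phi <- .phi_vector(dispersion, sub$counts)
  Y <- sub$counts
  grp <- factor(ifelse(colnames(Y) %in% arm_a, "a", "b"), levels = c("a", "b"))

  eff <- exp(offsets)
  qn <- sweep(Y, 2L, eff / mean(eff), "/")   # normalized counts, common scale
  mean_a <- rowMeans(qn[, grp == "a", drop = FALSE])
  mean_b <- rowMeans(qn[, grp == "b", drop = FALSE])
  log2fc <- log2(mean_a + 0.125) - log2(mean_b + 0.125)

  if (method == "lrt") {
    full <- .nb_fit_oneway(Y, grp, offsets, phi)
    null <- .nb_fit_oneway(Y, factor(rep("all", ncol(Y))), offsets, phi)
    dev <- pmax(2 * (full$loglik - null$loglik), 0)
    p <- stats::pchisq(dev, df = 1, lower.tail = FALSE)
  } else {
    p <- vapply(seq_len(nrow(Y)), function(g) {
      .nb_exact_p(Y[g, grp == "a"], Y[g, grp == "b"],
                  eff[grp == "a"], eff[grp == "b"], phi[g])
    }, numeric(1))
  }
  zero <- rowSums(Y) == 0
  p[zero] <- 1; log2fc[zero] <- 0
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  data.frame(probe_id = rownames(Y), mean_a = mean_a, mean_b = mean_b,
             log2fc = log2fc, p = p, p_adjusted = stats::p.adjust(p, "BH"),
             call = NA_character_, stringsAsFactors = FALSE, row.names = NULL)
}

.phi_vector <- function(dispersion, Y) {
  if (is.null(dispersion)) return(rep(0, nrow(Y)))
  if (inherits(dispersion, "nb_dispersion")) {
    phi <- dispersion$shrunk[rownames(Y)]
    phi[is.na(phi)] <- dispersion$common
    return(unname(phi))
  }
  rep_len(as.numeric(dispersion), nrow(Y))
}

# Exact conditional two-group NB test. Counts are rescaled to a common
# library size, group sums are conditioned on their total, and the two-sided
# p-value sums the probabilities of all splits at most as likely as the one
# observed. The split distribution is the NB convolution (binomial in the
# Poisson limit).
.nb_exact_p <- function(ya, yb, eff_a, eff_b, phi) {
  Nbar <- mean(c(eff_a, eff_b))
  sa <- round(sum(ya * Nbar / eff_a))
  sb <- round(sum(yb * Nbar / eff_b))
  s <- sa + sb
  if (s == 0) return(1)
  na <- length(ya); nb <- length(yb)
  m <- s / (na + nb)
  a <- 0:s
  if (phi < 1e-8) {
    lp <- stats::dbinom(a, s, na / (na + nb), log = TRUE)
  } else {
    lp <- stats::dnbinom(a, size = na / phi, mu = na * m, log = TRUE) +
      stats::dnbinom(s - a, size = nb / phi, mu = nb * m, log = TRUE)
    lp <- lp - .logsumexp(lp)
  }
  obs <- lp[sa + 1L]
  sum(exp(lp[lp <= obs + 1e-8]))
}

.logsumexp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

# ---------------------------------------------------------------------------
# Calling and multiple testing
# ---------------------------------------------------------------------------

#' DMR calling policy
#'
#' Thresholds used by [call_dmrs()]: absolute log2 fold-change above
#' `fc_threshold` (default 1.0, i.e. two-fold) plus either an unadjusted
#' p-value below `genome_wide_p` (default 1e-2) for genome-wide tiles, or a
#' Bonferroni-corrected threshold `promoter_alpha / promoter_m` for promoter
#' probes.
#'
#' @param fc_threshold log2 fold-change threshold (default 1.0).
#' @param genome_wide_p unadjusted p threshold for genome tiles (default
#'   1e-2).
#' @param promoter_alpha family-wise alpha for promoter probes (default
#'   0.05).
#' @param promoter_m number of tested promoter probes (Bonferroni divisor).
#' @export
call_policy <- function(fc_threshold = 1.0, genome_wide_p = 1e-2,
                        promoter_alpha = 0.05, promoter_m = NULL) {
  stopifnot(fc_threshold > 0, genome_wide_p > 0, promoter_alpha > 0)
  if (!is.null(promoter_m) && promoter_m < 1) .stopf("promoter_m must be >= 1")
  structure(list(fc_threshold = fc_threshold, genome_wide_p = genome_wide_p,
                 promoter_alpha = promoter_alpha, promoter_m = promoter_m),
            class = "call_policy")
}

#' Bonferroni family-wise threshold
#'
#' @param alpha family-wise error rate.
#' @param m number of tests.
#' @return alpha / m.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (length(m) != 1L || !is.finite(m) || m < 1) .stopf("m must be >= 1")
  alpha / m
}

#' Call DMRs from per-probe test results
#'
#' Genome-wide mode: call when p < `genome_wide_p` and |log2fc| >
#' `fc_threshold`. Promoter mode: call when p < `promoter_alpha / promoter_m`
#' and |log2fc| > `fc_threshold`. Direction comes from the sign of the
#' control-over-dehp log2fc: positive is `hyper_in_control` (hypo-methylated
#' in DEHP), negative `hypo_in_control`.
#'
#' @param results data.frame from [test_dmr()].
#' @param policy a [call_policy()].
#' @param mode `"genome_wide"` or `"promoter"`.
#' @export
call_dmrs <- function(results, policy = call_policy(),
                      mode = c("genome_wide", "promoter")) {
  mode <- match.arg(mode)
  p_thr <- if (mode == "genome_wide") policy$genome_wide_p else {
    if (is.null(policy$promoter_m)) .stopf("promoter mode requires promoter_m in the policy")
    bonferroni_threshold(policy$promoter_alpha, policy$promoter_m)
  }
  sig <- results$p < p_thr & abs(results$log2fc) > policy$fc_threshold
  results$call <- ifelse(!sig, "none",
                         ifelse(results$log2fc > 0, "hyper_in_control",
                                "hypo_in_control"))
  results
}

# ---------------------------------------------------------------------------
# Strain x treatment interaction
# ---------------------------------------------------------------------------

#' Test the strain-by-treatment interaction contrast
#'
#' Per probe, fits the full negative-binomial GLM with strain, treatment and
#' their interaction against the additive null, and tests the interaction
#' coefficient by likelihood ratio (chi-square, 1 df). The interaction
#' estimate Z is the difference between the two strains' control-minus-dehp
#' log2 fold-changes, computed from the fitted cell means of the saturated
#' model; it captures regions responding to treatment in opposite directions
#' in the two strains. Reports per-strain log2fc, Z, p, Benjamini-Hochberg
#' FDR and a genome-wide Bonferroni flag at `alpha / m`.
#'
#' @param counts `mbd_counts` whose sample sheet has `strain` and `treatment`
#'   columns forming a full 2x2 design with >= 2 samples per cell.
#' @param dispersion `nb_dispersion`, numeric vector or scalar.
#' @param norm `tmm_norm` (computed on the fly if omitted).
#' @param m Bonferroni divisor for the genome-wide flag (default: number of
#'   probes tested).
#' @param alpha family-wise alpha (default 0.05).
#' @param strain_levels optional length-2 character vector fixing which
#'   strain is reported first (defaults to sorted unique strains, so
#'   C57BL/6J precedes FVB/N).
#' @return data.frame: probe_id, log2fc per strain, Z, p, fdr,
#'   genome_wide_significant.
#' @export
test_interaction <- function(counts, dispersion = NULL, norm = NULL,
                             m = NULL, alpha = 0.05, strain_levels = NULL) {
  ss <- counts$samples
  validate_sample_sheet(ss, require_full_design = TRUE)
  if (is.null(strain_levels)) strain_levels <- sort(unique(ss$strain))
  strain <- factor(ss$strain, levels = strain_levels)
  treat <- factor(ss$treatment, levels = c("control", "dehp"))
  cell <- interaction(strain, treat, drop = FALSE)
  Y <- counts$counts
  if (is.null(norm)) norm <- tmm_normalize(counts)
  offsets <- norm$offsets[colnames(Y)]
  phi <- .phi_vector(dispersion, Y)
  if (is.null(m)) m <- nrow(Y)

  full <- .nb_fit_oneway(Y, cell, offsets, phi)
  X0 <- stats::model.matrix(~ strain + treat)
  ll0 <- vapply(seq_len(nrow(Y)), function(g) {
    .nb_fit_glm(Y[g, ], X0, offsets, phi[g])$loglik
  }, numeric(1))
  dev <- pmax(2 * (full$loglik - ll0), 0)
  p <- stats::pchisq(dev, df = 1, lower.tail = FALSE)
  zero <- rowSums(Y) == 0
  p[zero] <- 1

  # cell means of the saturated fit on the normalized scale
  gmean <- function(lev) {
    js <- which(cell == lev)
    full$mu[, js[1]] / exp(offsets[js[1]]) * mean(exp(offsets))
  }
  lv <- levels(cell)  # strain1.control, strain2.control, strain1.dehp, strain2.dehp
  mu_c1 <- gmean(lv[1]); mu_c2 <- gmean(lv[2])
  mu_d1 <- gmean(lv[3]); mu_d2 <- gmean(lv[4])
  fc1 <- log2(pmax(mu_c1, 1e-8)) - log2(pmax(mu_d1, 1e-8))
  fc2 <- log2(pmax(mu_c2, 1e-8)) - log2(pmax(mu_d2, 1e-8))
  out <- data.frame(probe_id = rownames(Y), stringsAsFactors = FALSE,
                    row.names = NULL)
  out[[paste0("log2fc_", strain_levels[1])]] <- fc1
  out[[paste0("log2fc_", strain_levels[2])]] <- fc2
  out$Z <- fc1 - fc2
  out$p <- p
  out$fdr <- stats::p.adjust(p, "BH")
  out$genome_wide_significant <- p < bonferroni_threshold(alpha, m)
  out
}
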