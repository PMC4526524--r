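---
title: "Methods: MBD-Seq differential methylation with mbddmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MBD-Seq differential methylation with mbddmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mbddmr` analyses methyl-CpG-binding-domain capture sequencing (MBD-Seq) of
two mouse strains under a 2×2 strain × treatment design. This vignette is
the package's account of the statistical model, the synthetic data
generator, the numerical choices, and the design decisions that were
genuinely open.

## The measurement model

MBD-Seq reads out methylation indirectly: sheared ~200 bp fragments are
captured with probability increasing in their methylated-CpG content, and
captured fragments are paired-end sequenced. The number of read pairs whose
insert overlaps a probe — a 2.2 kb genome tile or a −2000/+200 bp promoter
window — is therefore a count proportional to the region's methylation
level, library depth, and capture efficiency.

Counts are modeled per probe as negative binomial,

$$y_{gs} \sim \mathrm{NB}(\mu_{gs}, \phi_g), \qquad
\log \mu_{gs} = x_s^\top \beta_g + \log(N_s f_s),$$

where $N_s$ is the sample's kept-pair total and $f_s$ its TMM scaling
factor. The NB variance $\mu + \phi\mu^2$ reduces to Poisson at $\phi = 0$;
$\phi$ absorbs biological replicate-to-replicate variability in capture and
methylation.

Assumptions worth stating: capture efficiency is treated as a
probe-constant multiplier absorbed into $\beta$ (so only *differences*
between arms are interpretable, not absolute methylation); hydroxymethylation
is indistinguishable from methylation in MBD capture and is not modeled;
and the 2×2 design has no further covariates.

## Normalization

TMM factors are computed exactly in the trimmed, precision-weighted form:
pairwise log2 ratios $M$ against a reference sample (the one whose
upper-quartile count fraction is closest to the mean) are doubly trimmed —
30% of each $M$ tail and 5% of each abundance tail — and averaged with
asymptotic binomial weights; factors are rescaled to geometric mean 1. The
trimming makes the factors robust to a minority of genuinely differential
probes; the test suite verifies this on a matrix with 5% of probes inflated
8-fold, and checks agreement with the reference implementation in `edgeR`
to within 1%.

## Dispersion estimation

A common $\phi$ maximizes the Cox–Reid adjusted profile likelihood (APL)
pooled over probes under the cell-means design,
$\sum_g [\ell_g(\hat\beta_g(\phi), \phi) - \tfrac12 \log\det X^\top W X]$,
via golden-section search on the log scale. Per-probe estimates maximize
each probe's APL on a 36-point log-spaced grid in $[10^{-6}, 10]$ with
parabolic refinement, and are shrunk toward the common value with prior
weight $w_0 = 10$ (in residual-df units):
$\phi_g = (d\,\hat\phi_g + w_0\,\hat\phi_{\text{common}})/(d + w_0)$,
where $d$ is the residual degrees of freedom. A probe with no residual
variation has $\hat\phi_g = 0$ and is pulled toward the common value by
exactly the prior weight — the simplest scheme with the qualitative
behavior of moderated-dispersion frameworks. Calibration is validated by
simulation: Poisson data recover $\phi < 0.02$ and $\phi = 0.2$ data
recover a common estimate inside $[0.15, 0.25]$ at 2,000 probes × 10
samples.

## Testing and calling

The control-vs-DEHP contrast is tested per probe by likelihood ratio
(deviance difference, $\chi^2_1$), fitting group means by Newton iterations
vectorized across probes. For the two-group case an exact conditional
variant is provided: counts are rescaled to a common library size, the two
arm totals are conditioned on their sum, and the two-sided p-value sums the
probabilities of all splits at most as likely as the observed one under the
NB convolution — which reduces to the conditional binomial split in the
Poisson limit. The suite checks this variant against an independent
brute-force enumeration on totals up to 200 (agreement within 10% relative
for p in $[10^{-6}, 0.5]$); the asymptotic LRT p-value is the default for
model-based testing, mirroring the common split between exact pairwise
tests and GLM-based tests in count-model packages. Null calibration of the
LRT (fraction of p < 0.01 within the binomial 99% CI at 2,000 null probes)
is part of the acceptance tests.

Calling applies the study's printed thresholds: $|\log_2 FC| > 1$ plus
unadjusted $p < 10^{-2}$ for genome tiles (a global survey, not a
target-identification screen), or a Bonferroni threshold $\alpha/m$ for
promoter probes ($0.05/22{,}480 = 2.2\times10^{-6}$ at study scale). The
genome-wide p was taken as unadjusted, since no correction is stated
alongside it. Fold-changes are oriented control-over-DEHP; positive log2FC
means hyper-methylated in controls, equivalently hypo-methylated under
DEHP, and summaries report both vocabularies to avoid sign confusion.

Reported log2 fold-changes use normalized arm means with a display-only
count offset of 0.125 (never entering the likelihood), so zero-count arms
yield finite values; zero-total probes are reported with $p = 1$ and
log2FC 0 rather than dropped.

## The strain × treatment interaction

Strain-specific DMRs are detected by testing
$Z = (\text{C57BL/6J.control} - \text{C57BL/6J.dehp}) -
(\text{FVB/N.control} - \text{FVB/N.dehp})$
as the interaction coefficient of the NB GLM (saturated cell-means fit vs
additive null, LRT with 1 df). $Z$ is computed from the fitted cell means
and equals the difference of the stratified per-strain log2 fold-changes
exactly on noiseless data (verified to $10^{-6}$). Both BH FDR and a
genome-wide Bonferroni flag are reported, since the study quotes both an
FDR and a genome-wide threshold for its interaction hits. Note the single
test deliberately captures both opposite-direction responses and
one-strain-only responses — both are strain-specific effects.

A permutation sanity property is part of the tests: permuting strain labels
within treatment and re-estimating the dispersion under the permuted labels
destroys the significance of injected opposite-effect regions. Dispersion
re-estimation is essential — holding the unpermuted dispersion fixed makes
the permuted model misspecified (within-cell heterogeneity inflates the
LRT). The test uses a balanced interleaved permutation; a random
permutation that happens to nearly reproduce the original labels retains
genuine signal, so "the" permutation property only holds for well-mixed
draws.

## The synthetic generator

The generator emulates, at desk scale, the features of the study design
that the pipeline must be sensitive to:

* **Genome and genes** — uniform random sequence whose accidental CG
  dinucleotides are removed, then CpGs seeded at 0.01/bp genome-wide
  (about one per 100 bp) and 0.08/bp inside promoter windows, giving
  CpG-dense promoters over a sparse background; gene symbols drawn from
  the Vmn/Olfr/Mir classes at the study's promoter-census proportions.
* **Strain variants** — homozygous SNPs at 1.8×10⁻³/bp (the density
  implied by ~4.9 M SNPs between the strains), a configurable fraction
  CpG-creating or CpG-destroying, flagged by reclassifying the local
  census; depth evidence is Poisson around 25 reads. SNP positions are
  kept ≥3 bp apart so each flag changes the strain census independently.
  (A CpG-neutral SNP may still *relocate* a CpG — destroy one and create
  an adjacent one — so site provenance counts can exceed flag counts while
  the census identity holds exactly.)
* **Methylation and truth** — baseline per-CpG methylation probabilities
  are Beta(1.5, 4.5) (mean 0.25), shared between arms and, for common
  sites, between strains. Inside each truth region the lower arm is
  shifted on the logit scale, with the shift calibrated by root-finding so
  the *expected captured-fragment count* differs by the injected log2
  fold-change under the capture model (expectations computed by exact
  Poisson-binomial dynamic programming on a 20 bp grid of fragment
  placements with the fragment length fixed at its mean — the documented
  approximation behind the recorded "realized" effect). The lower arm is
  shifted rather than the higher one because baselines can sit near the
  capture ceiling. Interaction regions receive opposite-sign shifts in the
  two strains.
* **Capture and reads** — fragment lengths are truncated normal
  (200 ± 30 bp, clamped to 80–400); each fragment's methylated-CpG count
  k is drawn per CpG; capture follows the saturating form
  $p(k) = p_{bg} + (p_{max} - p_{bg})\,k/(k + k_{1/2})$ with defaults
  $p_{bg} = 0.01$, $p_{max} = 0.95$, $k_{1/2} = 2$. The study states only
  that capture is methyl-CpG dependent; the Michaelis–Menten form is this
  package's modeling assumption (motivated by the MBD protein's ~12 bp
  binding footprint — a few methylated CpGs suffice), not an inference
  about the capture kit. Captured fragments emit 2×50 bp read pairs;
  dovetailing pairs from short fragments are legitimate and concordant.
  `target_pairs_per_sample` is the number of fragments sampled per library
  *before* capture; per-library totals vary log-normally (CV 0.2). The
  default scale — 2 chromosomes × 300 kb, 60 genes, 30k fragments per
  library, quintuplicates — is the study design scaled from ~13 M pairs
  and a 2.7 Gb genome down to what property tests can exercise in seconds.

What the generator does **not** emulate, hence what passing tests do not
show about real data: sequencing errors and quality (no FASTQ), aligner
behavior and mapping ambiguity structure (uniqueness is a supplied flag),
PCR duplicates, batch effects, CpG-island spatial autocorrelation of
methylation, and — importantly — extra-Poisson biological variability:
methylation is sampled per fragment per CpG, so replicates within an arm
differ only by sampling noise and estimated dispersions on default
synthetic data are near zero. Dispersion estimation is therefore validated
on directly simulated NB matrices with known $\phi$, not on the generator's
output.

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open everywhere; conversions occur
  only at I/O boundaries (VCF is 1-based; results TSVs print 1-based
  inclusive coordinates for readability). Overlap queries delegate to
  IRanges behind two conversion helpers.
* The concordance criterion uses the *inner* gap (facing read ends), not
  the outer span: with 2×50 reads the two differ by 100 bp and "space
  between the reads" reads most naturally as the inner distance. The
  threshold (600 bp) is inclusive and configurable.
* The probe selection rule takes "more than 3 pairs in more than 2
  samples" literally (≥4 pairs in ≥3 samples), pooled across all arms;
  both thresholds are exposed as parameters.
* Promoter windows for − strand genes mirror the +2000/−200 arithmetic
  around the first transcribed base: TSS $t$ gives $[t-199, t+2001)$.
* Newton steps in the one-way NB fit are clamped to ±5 on the log scale;
  all-zero groups stay at the boundary ($\mu = 10^{-12}$) and zero-total
  probes get $p = 1$ directly. Deviances are floored at 0.
* The power solve uses the equal-variance noncentral-t with $2n-2$ df
  (the conventional power t-test), solved by `uniroot` to $10^{-6}$
  relative tolerance; the Welch df is used only for data tests. At the
  study's parameters (n = 8, sd = 3) the solve gives 4.52, displayed as
  4.5 — the methods-level figure; a results-level mention of 4.4 in the
  source material is the same quantity printed once with a different
  rounding and is not reproduced.
* Bonferroni thresholds print at 2 significant figures (0.05/22,480 →
  2.2×10⁻⁶); trend fractions and feature percentages display as nearest
  integers with raw fractions retained.

## Problem sizes in the test suite

Property tests run at sizes chosen to make their statistical claims sharp
yet quick: 2,000 probes × 10 samples for null calibration and dispersion
recovery, 500 probes for effect-size recovery, 100 truth probes for
interaction recovery, totals ≤ 200 for exact-test enumeration, and a
1 × 120 kb genome with 24 genes and 12k fragments per library for the
end-to-end determinism and recovery checks. These are the package's own
choices of scale for the properties being demonstrated.

## Known limitations

The pipeline starts from aligned pairs (BEDPE; SAM/BAM can be adapted to
it) — alignment itself is out of scope, as are GO/imprinting annotation,
external enhancer retrieval (enhancers enter as a user BED), bisulfite
validation chemistry, and expression integration. The exact normalization
and dispersion settings of the original analysis are not recoverable from
its description, so agreement with it is established behaviorally (by
simulation calibration and printed-value checks), not by numerical
identity on the archived data.
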