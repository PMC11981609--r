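---
title: "Methods: barcode-resolved DMS analysis with NB mixed models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcode-resolved DMS analysis with NB mixed models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Overview

`bardms` analyses deep mutational scans in which each protein variant
is linked to many independent 21-nt DNA barcodes and read out as
barcode expression counts over treatment conditions and replicates. The
pipeline has three layers: (1) construction of the variant–barcode map
from tagged mapping reads; (2) per-position mixed-effects negative
binomial modelling of raw counts; (3) cross-condition analytics
(treatment-response contrasts, signaling-bias PCA, ligand-specificity
meta-regression). A generative simulator with recorded ground truth
makes every stage testable without sequencing data.

## The count model and its assumptions

For condition $i$, variant $j$, barcode $k$, sample $m$:

$$\mathrm{count}_{ijkm} \sim \mathrm{NB}(\mu_{ij}, \theta), \qquad
\log \mu_{ij} = \beta^{cond}_i + \beta^{var}_{ij} + \alpha_k +
\mathrm{offset}(\gamma_m), \qquad \alpha_k \sim N(0, \sigma^2).$$

We use the mean/dispersion NB convention
$\mathrm{Var} = \mu + \mu^2/\theta$ (stated explicitly to avoid the
rate/size ambiguity). Assumptions worth spelling out:

- **Reference coding.** Wild-type deviations are fixed at 0, so
  $\beta^{var}_{ij}$ is the variant's natural-log shift from wild-type
  within condition $i$; condition intercepts are free. Estimates are
  converted to log2 only at reporting boundaries (divide by $\ln 2$).
- **One $\theta$ and one $\sigma^2$ per positional fit**, shared across
  conditions, and one $\alpha_k$ per barcode shared across *all* its
  samples — this sharing is what lets barcodes act as internal
  replicates across replicates and conditions.
- **Positional independence.** The model is fitted per residue
  position, pooling all variants at the position with every wild-type
  barcode of the same cloning subregion. Subregion identity is a
  required design column; its boundaries come from the library design,
  not from the model.
- **Explicit zeros.** A mapped barcode absent from a sample is a 0
  count, not missing data: the assay reads out expression, so absence
  is evidence of low activity. Barcodes are never deleted for
  missingness. (The alternative — dropping unobserved cells — would
  bias strong loss-of-function variants toward wild-type.)
- **Offsets from stop codons.** $\gamma_m$ is the natural log of the
  library-wide sum of stop-variant barcode counts in sample $m$. A stop
  variant's receptor is dead, so its reporter output does not respond
  to stimulation; the summed stop counts therefore track sequencing
  depth and composition but not treatment. One offset per sample, not
  per position. Forskolin-style variant-independent normalisation can
  be supplied by writing offsets into the sample sheet directly.

A variant–condition cell whose counts are all zero has a divergent ML
deviation; such cells are flagged non-estimable, excluded from the
likelihood and from the BH denominator, and reported as `NA`.

## Estimation and numerical choices

The barcode random intercepts are integrated out by a **Laplace
approximation**: the inner problem is a one-dimensional, strictly
concave maximisation per barcode, solved by damped Newton in compiled
code; the log-determinant correction is computed as
$\tfrac12\log(1+\sigma^2 W_k)$, which is continuous and exact as
$\sigma \to 0$, so the $\sigma = 0$ boundary needs no special casing.
The outer optimisation over (fixed effects, $\log\sigma$,
$\log\theta$) uses L-BFGS-B with an analytic gradient for the fixed
effects (envelope theorem plus the mode-shift term of the
log-determinant) and central differences for the two variance
parameters. Box bounds ($\log\sigma \in [-10, 2]$,
$\log\theta \in [-5, 14]$) keep overflow away without binding in
practice. Starting values are offset-weighted log mean ratios; up to 3
jittered restarts run before a fit is flagged non-converged (flagged,
never silently dropped). Standard errors come from the inverse observed
information of the Laplace objective (central differences of the
analytic gradient), with the variance parameters included so their
uncertainty propagates into the fixed-effect covariance; a
pseudo-inverse fallback handles near-singular information.

The test suite keeps an independent 64-node adaptive Gauss–Hermite
oracle (written against `dnbinom` and Golub–Welsch quadrature, sharing
no code with the main path) and checks the Laplace fit against it on
fixtures of ≤10 barcodes, plus `MASS::glm.nb` as the fixed-effect
oracle in the $\sigma = 0$ reduction.

One caveat discovered in testing: "multiply all counts and offsets'
antilogs by a constant" is *not* an exact invariance of an NB fit with
estimated dispersion — a deterministically scaled NB draw is itself
overdispersed, so $\hat\theta$ changes and samples are reweighted
within cells. The identity holds to well under 1% at realistic depth
and exactly in the fixed-$\theta$ Poisson limit; it is tested at the 1%
tolerance.

## Inference

Wald statistics ($z$ = estimate/SE) are referred to the standard
normal (no t correction, matching the analysis being reproduced);
Benjamini–Hochberg adjustment is applied per condition across variants
by default (scope configurable and logged). Classification uses strict
thresholds: LoF/GoF at q below the stated FDR with the corresponding
sign. The residue-level sensitivity score is the mean missense log2FC
divided by $\sqrt{\sum SE^2}$, nonsense excluded; as any SE grows
without bound the denominator dominates and the score tends to 0.

**Marginal means and corrector contrasts.** The marginal mean of
variant $v$ under treatment $t$ is
$\beta^{cond}_t + \beta^{var}_{vt}$ at random-effect mean 0 and the
fit's average offset, in log2. *Defect* = variant minus wild-type under
DMSO; *rescue* = variant under corrector minus variant under DMSO. Both
arms are fitted in one positional model so the full fixed-effect
covariance is available for SE propagation; the average-offset constant
cancels in both contrasts. `defect-rescued` requires both a
significantly negative defect and a significantly positive rescue at
the configured FDR (default 5%) — our operationalisation of "partially
or fully rescued"; the dual-significance rule and level are
configuration, and we do not claim to reproduce any particular
published count of rescued variants.

**Bias PCA.** The variant-by-condition matrix of $z$ statistics
(complete cases only, drops counted) is analysed by column-centered,
unscaled SVD — the `prcomp` default. SVD signs are arbitrary, so a
deterministic orientation is imposed: PC1 is flipped so nonsense
variants score positive on it (loss of function to the right); without
nonsense variants, and for every other component, the
largest-magnitude loading is made positive. The |PC2| cutoff (default
7.5, strict) flags biased variants, but which *pathway* a PC2 sign
means is an empirical property of each dataset: direction labels are
arguments, validated against planted truth in tests, never assumed.

**Errors-in-variables meta-regression.** Ligand-specific effects are
found by regressing one ligand's per-variant statistics on another's
with measurement error in both:
$x_i \sim N(t_i, sx_i^2)$, $y_i \sim N(a + b t_i, s^2 + sy_i^2)$,
$t_i \sim N(\mu_t, \tau^2)$, with priors $a, b \sim N(0, 10^2)$,
$s \sim$ half-N(0, 5), $\mu_t \sim N(0, 10^2)$, $\tau \sim$
half-N(0, 10). The sampler is a self-contained Gibbs scheme (conjugate
updates for $t_i$, $(a,b)$, $\mu_t$) with adaptive random-walk steps on
$\log s$ and $\log\tau$; 4 chains, split-$\hat R$ < 1.01 required for
$a$, $b$, $s$ (error by default on failure). $s$ is floored at $10^{-3}$
so exactly-collinear data keep a proper posterior. `sx = 0` pins the
latent predictor to the observation, recovering ordinary regression.

Two design decisions here deserve emphasis:

1. *Residual p-values.* The raw posterior sign probability
   $2\min(P(r>0), P(r<0))$ declares nearly every variant's residual
   "non-zero": under a scatter scale $s$, points legitimately sit off
   the line, and the posterior is certain about which side. It is kept
   as `p_sign`, but inference uses the posterior-predictive tail of the
   standardized residual, $E_{post}[2\Phi(-|r_i|/\sqrt{s^2+sy_i^2})]$,
   which is approximately uniform for on-line variants and small only
   for genuine outliers — the property FDR control actually needs.
2. *Robust scatter.* A Gaussian $s$ absorbs the very outliers the
   residual test is meant to find, inflating the scale and erasing
   sensitivity. `nu` switches the scatter to a Student-t
   (scale-mixture Gibbs step); `nu = 3` keeps the fitted scale at the
   on-line value in contaminated data and is used for outlier
   discovery. The Gaussian model (`nu = Inf`) remains the default and
   is what the line-recovery checks use.

## The simulator: what it emulates, and what it does not

`simulate_counts()` inverts the fitted model exactly: NB draws around
$\exp(\log \mathrm{baseline} + c_i + e_{ji} + \alpha_k + \gamma_m)$.
Defaults describe a realistic screen: baseline mean 10 counts/barcode
(the order of observed median reads per barcode per sample), 30
barcodes/variant, 4 replicates/condition, $\sigma = 0.5$ (barcode
clone-to-clone variability), $\theta = 5$, offset jitter 0.3
(±35% depth variation), stimulation raising wild-type output 4-fold.
The true effect distribution of a library is *not* assumed — it is a
user-supplied table; by default missense effects are 0 and stop
variants exactly cancel the stimulation term, which is precisely the
condition that justifies stop-derived offsets. Dropout removes
barcodes from the map entirely; per-sample zeros arise from the NB.
Read simulation (`simulate_reads()`) emits 21-nt barcode + insert
fragments with configurable chimera and substitution-error rates on an
RNG stream independent of the count stream, so enabling it never
perturbs count fixtures.

Not emulated: PCR chemistry, UMI collisions, index hopping, alignment
ambiguity beyond exact matching, position-dependent error profiles, or
correlated barcode effects. A green test therefore establishes that the
*statistical machinery* behaves as specified under the model's own
generative assumptions — not that any particular biological dataset
meets those assumptions.

Wild-type pools: each cloning subregion in a real library carries
several wild-type oligos, each with its own barcode set, so the WT pool
is several-fold larger than a single variant's ~30 barcodes. The
acceptance simulations use 90 WT barcodes per subregion for this
reason; with a WT pool as small as one variant's barcode set, all
deviations at a position share one noisy WT reference and
position-level errors become strongly correlated, which makes
small-scale coverage estimates unstable even when marginal calibration
is correct.

## Mapping filters

Exact-match insert lookup stands in for strictly-unique alignment
against the designed library (a closed dictionary at desk scale); an
edit-distance-1 rescue exists but is off by default. The filter chain
retains an oligo–barcode pair only if, in *both* mapping replicates,
the barcode has the correct length (21), total read depth strictly
greater than 10, purity (pair reads / total barcode reads) strictly
greater than 0.75, and the same majority oligo; removals are counted
per rule. The three threshold rules commute (pure intersection), and
thresholds are configurable.

## Known limitations

- Wald/normal inference is slightly anticonservative at small barcode
  counts (a null z-sd near 1.07 was observed at 8 barcodes and 2
  replicates); the design target of ~30 barcodes and 4 replicates is
  where calibration holds. No t correction or moderation is applied.
- The Laplace approximation degrades for barcodes with very few, very
  small counts; the quadrature oracle bounds this on small fixtures
  but no runtime switch to quadrature is provided.
- BH control of the *realised* false discovery proportion in a single
  dataset fluctuates around the FDR level; detection of outliers at 4
  standard deviations among hundreds of tests is intrinsically near
  the power boundary of FDR-controlled testing, whatever the model.
- Dose–response modelling (EC50s), shrinkage of effect estimates, and
  UMI-level deduplication are out of scope; doses are categorical
  condition levels.
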