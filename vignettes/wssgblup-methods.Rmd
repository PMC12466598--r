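---
title: "Weighted single-step GBLUP and window-based GWAS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted single-step GBLUP and window-based GWAS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of the statistical machinery it
implements: the single-step animal model and its H matrix, REML
estimation of variance components, the back-solving and iterative
weighting of SNP effects, the sliding-window decomposition of additive
genetic variance, and the herd simulator that every test and
calibration run is built on. It also records the numerical and design
choices that were genuinely open, and what the calibration results do
and do not show about real data.

## The model

Fertility traits of beef cows kept under extensive management — age at
first calving (AFC), the first-to-second and average calving intervals
(IC12, ACI), and reproductive efficiency (RE, the percentage deviation
of a cow's realized parity count from the optimum at her age) — are
lowly heritable and strongly structured by contemporary groups. The
univariate animal model is

$$ y = \mu + Xb + Za + Wc + e $$

with $a \sim N(0,\, K\sigma^2_a)$ the additive genetic effects of *all*
pedigree animals, $c \sim N(0,\, I\sigma^2_{hys})$ the herd–year–season
(HYS) contemporary-group effect, and $e \sim N(0,\, I\sigma^2_e)$.
Heritability is $h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_{hys} +
\sigma^2_e)$. The fixed-effect layout is trait-specific
(`trait_model_spec()`): AFC is fitted with the mean only; IC12 and ACI
add the inbreeding covariate $F$ and a three-class age-at-first-calving
factor (< 30, [30, 36), >= 36 months, first class dropped); RE
additionally carries age at last calving as a covariate.

$K$ is the pedigree relationship matrix $A$ for a conventional
evaluation, or the single-step matrix $H$ combining $A$ with the
genomic relationships $G$ of the genotyped subset. Only $H^{-1}$ is
ever formed:

$$ H^{-1} = A^{-1} + \begin{bmatrix} 0 & 0 \\ 0 & G^{-1} - A_{22}^{-1}
\end{bmatrix}, \qquad G = \frac{Z_m Z_m'}{\sum_i 2 p_i (1 - p_i)} $$

where $Z_m$ holds centered SNP dosages ($x_{ij} - 2p_j$, missing calls
mean-imputed to zero), $p_i$ the observed counted-allele frequency in
the genotyped set, and $A_{22}$ the pedigree relationships among
genotyped animals. $A^{-1}$ is assembled sparsely by Henderson's rules
with the inbreeding-adjusted Mendelian sampling variances $d_i = 0.5 -
0.25(F_s + F_d)$ (one-parent and founder cases: $0.75 - 0.25F$, $1$);
inbreeding itself comes from the Meuwissen–Luo recursion (compiled);
$A_{22}$ and arbitrary column blocks of $A$ come from the indirect
triangular-solve identity $A = (I - P)^{-1} D (I - P)^{-T}$, so the
dense $A$ is never formed outside the small tabular test oracle.

### Frequency convention

The centering frequency and the VanRaden divisor use the observed
counted-allele frequency $p$, not the folded minor-allele frequency:
folding would flip centering signs inconsistently across SNPs. A
`fold = TRUE` switch exists in `allele_frequencies()` for sensitivity
analysis only. Frequencies are computed from the observed genotyped
animals, matching the $G$ formula as used in routine evaluations.

### Compatibility of G with the pedigree base

$G$ centered at the observed frequencies of a *related* genotyped
sample is expressed relative to that sample's own mean relatedness (its
mean off-diagonal is ~0), while $A_{22}$'s is positive. Before
inversion, $G$ is therefore rescaled so that its mean diagonal and mean
off-diagonal match those of $A_{22}$ (`tune_G()`, an affine adjustment
$a + bG$), which is what routine genomic-evaluation programs do
silently; then a 5% pedigree admixture is blended in
(`blend_G()`, $0.95\,G + 0.05\,A_{22}$) to guarantee positive
definiteness when animals outnumber effectively independent markers.
Both steps are defaults and both can be switched off.

## REML

Two independent routes are implemented, and their agreement is part of
the test suite:

* **`algorithm = "ai"`** (default) maximizes the restricted likelihood
  on the observation scale, $V = \sigma^2_a M + \sigma^2_{hys} WW' +
  \sigma^2_e I$ with $M = Z K Z'$ the relationship block of the
  recorded animals (obtained from $K^{-1}$ by one sparse Cholesky
  solve). Average-information updates use exact first derivatives
  (traces via the dense $V^{-1}$ at the size of the record count, not
  the equation count — the reason this route is fast at a few thousand
  records). A proposed step that would drive a component non-positive
  is halved until admissible, with a floor of $10^{-8}$ of the
  phenotypic variance; a component sitting on the floor whose score
  still points downward is pinned there and the AI system is solved
  over the free components only, so a boundary estimate (e.g. a herd
  with no detectable HYS variance) cannot stall the others.
  Convergence is declared on the maximum relative component change, or
  when the restricted log-likelihood stalls to within $10^{-9}$ —
  which is where boundary cases end up. This step-halving-with-pinning
  plays the safeguard role that an EM fallback step plays elsewhere,
  and away from the boundary it is never the active path.
* **`algorithm = "em"`** is the classical EM on Henderson's equations:
  $\sigma^{2\prime}_a = (\hat u' K^{-1} \hat u + \sigma^2_e\,
  \mathrm{tr}(K^{-1} C^{uu}))/q$, the analogous HYS update, and the
  residual from $y'y - \hat\theta'\,\mathrm{rhs}$ over $n -
  \mathrm{rank}(X)$. It needs the dense inverse of the coefficient
  matrix per iteration and converges slowly, so it serves as the
  independent cross-check on small fixtures rather than the production
  path.

Convergence is declared when the largest relative component change
falls below `tol` (default $10^{-8}$; the replicated calibration runs
use $10^{-6}$, which is far below the Monte-Carlo noise of a single
replicate). Standard errors come from the inverse average-information
matrix, with a delta-method SE for $h^2$; they are reported but no
calibration claim depends on them. Non-convergence raises a condition
object carrying the iterate trajectory.

GEBVs and fixed-effect solutions come from the sparse mixed-model
equations at the converged components, solved by sparse Cholesky
(`method = "direct"`) or Jacobi-preconditioned conjugate gradients
(`method = "pcg"`); the direct solution satisfies the system to
$10^{-8}$ relative residual and the two methods agree to $10^{-6}$ on
test fixtures.

## Back-solving, weighting, windows

SNP effects are back-solved from the GEBVs of the genotyped animals
only:

$$ \hat a = D Z_m' (Z_m D Z_m')^{-1} \hat u_g $$

with $D = I$ in the first (unweighted) iteration. $Z_m D Z_m'$ is
singular whenever animals outnumber independent markers, so the scaled
blended matrix $G^* \sum 2pq$ stands in for it — the same regularization
the evaluation itself uses. Per-SNP variances $\sigma^2_{u,i} = 2 \hat
a_i^2 p_i (1 - p_i)$ become the next iteration's weights, normalized to
mean 1 so the weighted $G^*$ keeps the unweighted scale. Variance
components are estimated once, in the unweighted iteration, and held
fixed afterwards; the weighted iterations re-estimate GEBVs only. The
default is 2 iterations (one re-weighted analysis, configurable 1–10):
the squared-effect weighting is known to overfit beyond 2–3 iterations,
and the null-calibration results below show why.

Windows slide one SNP at a time: the window anchored at SNP $j$
contains all consecutive SNPs $k \ge j$ on the same chromosome with
$\mathrm{pos}_k - \mathrm{pos}_j < 1\,\mathrm{Mb}$ (half-open, strict;
reported coordinates $[\mathrm{pos}_j, \mathrm{pos}_j + 1\,\mathrm{Mb})$),
so there are exactly as many windows as SNPs and windows never cross
chromosomes. Each window's share is

$$ \frac{\mathrm{Var}\left(\sum_{j \in \mathrm{window}} Z_{mj} \hat a_j\right)}
        {\sigma^2_a} \times 100\% $$

with the empirical variance over genotyped animals using denominator
$n$ (population variance, for determinism; a `n-1` switch exists) and
the REML $\sigma^2_a$ in the denominator (so percentages need not sum
to 100; `denominator = "realized"` divides by $\mathrm{Var}(Z_m\hat a)$
instead). Selection keeps windows strictly above 1%, ranked by share;
overlapping selected windows can optionally be merged into regions for
reporting. Annotation against a BED track is a plain >= 1 bp interval
intersection.

## The herd simulator

`sim_config()` + `simulate_herd()` generate the study conditions every
calibration runs on. The default herd emulates the structure of an
extensively managed beef population with performance recording:

* ~3,000 animals: 600 founders (90% female) plus 5 discrete
  generations of 480 offspring (25 sires and 240 dams per generation, 2
  offspring per dam, sires reused across dams — paternal half-sib
  families; random mating, so inbreeding accumulates only by drift
  through the finite sire pool);
* 1,200 SNPs on 10 chromosomes of 100 Mb, founder frequencies uniform
  in MAF [0.05, 0.5], descendants by Mendelian gene dropping with free
  segregation between loci (no linkage model — see limitations);
* records for the ~1,200 non-founder females ("cows"; a
  `recorded_fraction` below 1 emulates partial enrollment in
  performance recording, stratified by generation); the genotyped
  animals are drawn from the *recorded* cows — two thirds by default,
  giving the 800 genotyped animals of the calibration design;
* 300 HYS classes assigned at random (~4 records per class, matching
  the few-records-per-contemporary-group regime of extensive systems);
* trait profiles carrying the four variance regimes
  (AFC 6.29/15.90/21.01, IC12 3.65/2.49/8.90, ACI 2.91/1.45/6.26,
  RE 53.38/73.79/133.94; trait means ~35, 15, 16 months and 70%)
  and their fixed-effect layouts, with modest true coefficients for
  the covariates the profile includes.

### Trait architecture: why the markers carry the variance

The generator builds breeding values as a marker part plus a residual
pedigree-polygenic part (recursion $a_i = (a_s + a_d)/2 + m_i$ with
inbreeding-adjusted Mendelian variance). The *default* puts all of
$\sigma^2_a$ on the marker part — every SNP carries a small effect,
jointly scaled so the founder-population variance equals $\sigma^2_a$ —
because that is the covariance structure the single-step model itself
asserts: for genotyped animals, $\mathrm{cov}(a) \propto$ their
realized genomic relationships. This choice was settled by a
design-phase simulation analysis worth recording:

* with a purely pedigree-polygenic truth, single-step REML on the same
  herds under-estimates $h^2$ by ~25% relative (mean 0.104 vs true
  0.146 in the AFC regime): the deviations of $G$ from $A_{22}$ are
  then pure noise with respect to the trait, and act like errors in
  the covariance ("G-noise attenuation"). Pedigree-only REML on the
  same data is unbiased (0.144), so this is a property of the
  truth/model mismatch, not of the estimator code;
* a mixed architecture (90% marker, 10% pedigree) still attenuates
  noticeably through whichever channel is mismatched — records of
  ungenotyped cows under a marker truth, genotyped animals under a
  pedigree truth (13–18% relative in the configurations measured);
* with the whole-panel marker architecture both channels agree with
  the model, and recovery at the default design (~1,200 records, 800
  genotyped) is near-unbiased in all four regimes: on 20 fresh seeded
  replicates per trait, means 0.148/0.251/0.273/0.205 against true
  values 0.146/0.243/0.274/0.204, with per-replicate SDs 0.033–0.051.

At a real 45k-SNP panel these mismatches are far smaller (the
effective number of independent segments is much larger than this
desk-scale panel's 1,200); the attenuation numbers are left here as
the package's own characterization of architecture/model mismatch at
desk scale. Power and null studies use explicit architectures instead:
a single planted common QTL at 8% of $\sigma^2_a$ over a
pedigree-polygenic background, and a purely pedigree-polygenic null
(`qtl_variance_fraction = 0`).

### Determinism

The configuration seed fixes all randomness end-to-end (R's default
integer-state generator; stage-specific seeds are derived from it), so
a herd, its fixture files, and every downstream result are reproducible
bit-for-bit under a fixed seed; this is asserted by md5 comparisons in
the tests.

## Calibration studies and problem sizes

* **Heritability recovery** (`h2_recovery_study()`): 10 seeded
  replicates per trait regime of the default herd; mean estimated
  $h^2$ is compared with the regime's reference value at tolerance
  0.03. A replicate runs in a few seconds (observation-scale AI-REML at
  ~1,200 records), so the full 40-replicate study takes a few minutes.
  One statistical fact about this check deserves stating: the
  per-replicate AI-REML standard error of $\hat h^2$ at ~1,200 records
  is 0.035–0.055 (and the observed replicate SD matches it), so the
  mean of 10 replicates has a Monte-Carlo SE of roughly 0.01–0.016 and
  the 0.03 tolerance is a ~2–3 SE band — an occasional miss on an
  unlucky seed set is expected behaviour of the check itself, not
  evidence of miscalibration.
* **Power** (`power_study()`): 20 seeded replicates of a deeper herd
  (~4,680 animals, ~2,100 recorded-and-genotyped cows, $h^2 = 0.3$,
  1,000 SNPs) with one common QTL (founder MAF >= 0.2) at 8% of
  $\sigma^2_a$. The design depth follows shrinkage arithmetic — the
  back-solved share of a QTL scales like $n\,2pq/(n\,2pq + \lambda)$
  with $\lambda \approx 700$ here, so records are the power lever — and
  is sized so the QTL window is already at or near the 1% selection
  threshold in the unweighted pass; the weighted iteration then
  amplifies a signal that is top-ranked to begin with. Two design facts found on
  the way are worth keeping: a planted QTL on a rare founder allele
  (MAF ~0.1, drifting lower) is undetectable *by construction* (its
  back-solved share is a fraction of a percent), which is why sparse
  QTLs are drawn from common variants; and at half this record depth
  the weighted iteration's noise amplification (below) occasionally
  out-ranks a genuinely detected QTL.
* **Null calibration** (`null_study()`): 20 seeded replicates at the
  500-animal/1,000-SNP scale with no planted effect. The *unweighted*
  scan selects nothing at the 1% threshold and the chromosome of the
  top window is uniform (chi-square rank-uniformity p > 0.01).

### The weighting loop sharpens noise too

A finding worth stating plainly: under the null, the unweighted scan is
clean (max window share ~0.2%), but the second, weighted iteration
inflates a handful of windows to several percent — squared-effect
weights are chi-square-like with a heavy right tail (max weight 12–22
across all 20 null replicates at the 500-animal scale), and re-building
$G^*$ from them amplifies whatever the first pass found, noise
included. This is the known overfitting of the iterative weighting
scheme, and it is why (a) the default stops at 2 iterations, (b) the
null calibration is read from the unweighted scan, and (c) a window
that clears 1% only after weighting, without a large unweighted rank,
deserves skepticism in real analyses.

## Numerical choices and degenerate inputs

* Dense tabular $A$ is a test oracle capped at 2,000 animals; above
  that the sparse/indirect paths are the only ones offered.
* External ids are mapped once to integer codes in topological order;
  duplicate ids, pedigree cycles (including self-parenthood) and
  unknown ids are hard errors naming the offender; referenced-but-
  absent parents are silently added as founders; an animal may have
  exactly one known parent (the $d_i$ rules above cover it).
* QC stages run in a fixed order (autosomes, individual call rate,
  MAF recomputed on survivors); monomorphic SNPs fall to the MAF stage
  (MAF 0 < threshold); removing every SNP or every animal is an error,
  not an empty result.
* Phenotype records are canonically sorted on ingestion, so file row
  order cannot change any result; REML itself is order-invariant and
  this is tested.
* Weights of an all-zero first pass (no signal at all) degrade to unit
  weights rather than 0/0; weight collapse (>99% of mass on <= 5 SNPs)
  logs a warning and continues.
* Ties in window ranking are broken by the sort's stable order (by
  descending share, then genomic position); the power criterion uses
  rank 1 strictly.

## Limitations

* No linkage: loci segregate freely, so there is no LD decay along a
  chromosome and a "window" catches a QTL only by containing it. This
  keeps the generator desk-scale and the power criterion sharp, but it
  understates the multi-window signal spreading seen with real LD.
* The HYS assignment is random rather than nested within herd and
  season; the identity covariance of the HYS term makes this
  immaterial for variance-component behaviour, but real confounding
  between herd and genetics is not emulated.
* The simulator produces already-clean records; the record filtering of
  a real recording scheme is not modeled.
* Passing calibration on these synthetic herds shows the estimator
  machinery is correct and well-calibrated *under the stated
  conditions*; it does not certify behaviour under real LD, selection,
  or pedigree error.
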