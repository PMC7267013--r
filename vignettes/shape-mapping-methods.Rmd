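---
title: "Methods: elliptic Fourier shape mapping of leaf outlines"
author: "leafscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: elliptic Fourier shape mapping of leaf outlines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafscan)
```

## The problem

`leafscan` maps quantitative trait loci (QTLs) that control whole-leaf shape
in clonally replicated tree populations sampled from two contrasting
environments (here called *demes*, e.g. high- and low-altitude provenances).
The phenotype is not a scalar but the entire leaf margin; the package
carries it as a fixed-length landmark configuration, models its mean with
elliptic Fourier descriptors, and tests each SNP by a likelihood ratio under
a structured multivariate normal model. Around this core sit the standard
population-genetic companions of such a study: SNP quality filtering,
testcross/intercross segregation typing, Weir--Cockerham $F_{ST}$ on neutral
SNPs, the island-model migrant number $N_m$, $Q_{ST}$ from deme variance
components, and a fixed-effects ANOVA of scalar leaf traits.

## From images to phenotypes

1. **Outlines.** A leaf enters as a closed, ordered point sequence (landmark
   CSV) or a binary silhouette image (white leaf on black background, traced
   with `outline_from_image()`). Traversal is normalized to clockwise; the
   first point is treated as the blade base (petiole junction).
2. **Landmarks.** `resample_contour()` casts `K` rays from the area centroid
   at equal angular increments, landmark 0 on the ray through the blade
   base. This requires the margin to be star-shaped about its centroid,
   which holds for unlobed leaves; the function reports the offending angle
   otherwise. Equal-angle sampling was chosen over equal spacing of radii:
   the two coincide only for circles, and rays from the centroid give every
   landmark an unambiguous anatomical direction.
3. **Alignment.** `procrustes_align()` is a generalized Procrustes analysis:
   translation to the origin, centroid size (root-mean-square landmark
   distance) scaled to 1, and the optimal no-reflection rotation against a
   running consensus, iterated to convergence (tolerance $10^{-8}$, at most
   100 iterations, consensus initialized from the first shape). Reflections
   are never applied: leaves have chirality from imaging, and allowing them
   would merge mirror forms.
4. **Averaging.** Leaves are averaged landmark-wise per clonal line
   (`average_shape()`), which cancels heterophylly (crown position) and
   nursery-block effects; the per-line averages are aligned again and
   stacked into the phenotype matrices (`shape_phenotypes()`).

The landmark count is selected by AIC (`select_landmark_count()`): for each
candidate `K`, shapes are resampled, aligned, fitted with the elliptic
Fourier model and scored against the true margin on a fixed 360-point
equal-angle grid, so likelihoods are comparable across `K`; the parameter
count is $4N + 2$ coefficients per shape. Because any curved margin is
approximated strictly better by more landmarks at the same parameter count,
the AIC curve typically flattens rather than turning; ties within $10^{-6}$
go to the smaller count. The harmonic order is selected from the cumulative
explained-variance profile (`select_order()`), the smallest order whose
reconstruction $R^2$, $1 - \mathrm{SSE}(N)/\mathrm{SST}$ averaged over
shapes, exceeds 95%; a normalized-power variant is available via
`method = "power"`.

## Elliptic Fourier descriptors

`efd_decompose()` implements the classical closed-contour formulas with
chord-length parameterization (the polygon perimeter is the period). A
`"uniform"` parameterization (equal parameter increment per vertex) is also
provided: it is the parameterization in which a contour sampled at equal
increments of its generating parameter — an ellipse sampled at equal angles
of its circular parameter, for instance — is represented exactly by its
generating harmonics. The distinction matters: under arc length a 2:1
ellipse acquires genuine odd harmonics ($a_3 \approx 0.13$), which is a
property of the parameterization, not an error. No first-ellipse
normalization is applied to the coefficients; orientation and scale are
already handled by the Procrustes step.

## The association model

For one SNP with genotype classes $j = 1..J$, the phenotype of line $i$ is
the $2K$-vector $z_i = (x_1..x_K, y_1..y_K)$ of aligned landmark
coordinates. Under $H_1$ each genotype class has its own mean curve; under
$H_0$ all lines share one. A class mean curve is the least-squares fit of
the truncated Fourier basis (order $N$, default 4, so $4N + 2 = 18$
coefficients) to the class's coordinate-wise mean. Residuals are modeled as
two independent AR(1) blocks,
$\Sigma_{ij} = \sigma^2 \rho^{|i-j|}$, one for $x$ and one for $y$, shared
across genotype classes and re-estimated under each hypothesis by profile
maximum likelihood (closed-form $\hat\sigma^2$ given $\rho$, bounded 1-D
search for $\rho \in (-0.99, 0.99)$). The statistic is
$LR = 2(\ln L_1 - \ln L_0)$, clamped at zero.

Numerical design choices that matter:

* The AR(1) log-density uses the closed-form determinant
  $K\ln\sigma^2 + (K-1)\ln(1-\rho^2)$ and the tridiagonal inverse quadratic
  form, so each evaluation is $O(K)$ (`ar1_loglik()` exposes it directly).
* Inside the scan, the Fourier basis uses the uniform (landmark-index)
  parameterization. Landmarks are equal-angle samples, so this is the
  natural parameter, and it makes the design matrix — and hence the hat
  matrix — identical for every group, marker and permutation; it is computed
  once per scan. This is what keeps 1000-replicate permutation thresholds
  tractable on one CPU.
* Profile likelihood reduces each covariance fit to a 1-D optimization over
  three residual cross-products, so a single LR test costs a few matrix
  operations regardless of the number of optimizer iterations.
* Genotype classes below `min_group_size` (default 5) are dropped per
  marker; markers with fewer than two usable classes are recorded as
  skipped, never errored. Missing genotypes are handled by per-marker case
  deletion.

Significance uses the study design's empirical approach: one shared
permutation of line phenotypes against genotype rows per replicate, the
maximum LR over all markers of a segregation type recorded, and the
$(1-\alpha)$ type-7 quantile of the maxima taken as that type's genome-wide
threshold (`permutation_threshold()`, default 1000 replicates in the
pipeline). Testcross ($J = 2$) and intercross ($J = 3$) markers get separate
thresholds because their LR statistics live on different scales. Note the
arithmetic consequence: two families controlled at 5% each give a combined
family-wise rate near 9.75% by construction; the package's calibration
checks therefore measure the 5% property on a single threshold family.

Per-SNP heritability of a scalar trait is the between-genotype variance
ratio $h^2 = 1 - \mathrm{SS}_\mathrm{within}/\mathrm{SS}_\mathrm{total}$;
summing it over a marker set ("cumulative heritability") double-counts
whatever the markers share, so treat such sums as an upper bound under
collinearity.

## QTL shape-pattern classes

`classify_pattern()` sorts a significant QTL into one of four classes from
its genotype mean contours: `LENGTH` (long-narrow vs short-broad: relative
ranges of both length and width exceed `tau_rel`), `BASE` and `TIP` (equal
axis; divergence concentrated at least `tau_ratio`-fold in the basal or
apical third of the pooled mean's axis), and `WIDTH` (equal axis, width
moved, divergence spread along the blade). Regional divergence is the mean
pairwise landmark distance between genotype means within each axial third.

The default `tau_rel = 0.045` deserves explanation, because it was a
genuinely open design point. In Procrustes shape space absolute size is
gone; only proportions remain. Uniformly widening a leaf therefore reads as
width-up *and* length-down, in a fixed ratio set by the share of landmark
variance carried by the transverse coordinate (about 0.27 under equal-angle
sampling of an elongated ovate, hence measured
$\Delta L \approx 0.5\,\Delta W$). A threshold of 0.02 on relative length
would classify every realistic width change as `LENGTH`; 0.045 cleanly
separates aspect-ratio changes (planted `LENGTH` effects, where
$\Delta L \approx \Delta W$) from blade-body widening across the 8--15%
effect range, while leaving `TIP`/`BASE` (whose $\Delta L$ is below 2%)
untouched. Both thresholds are exposed in the configuration.

Genotype effect tables (`effect_table()`) report per-deme genotype means of
area, width and length with cross-deme percent differences computed as
$100\,|a - b| / \min(a, b)$ — the smaller mean is the baseline — and flag
markers significant in exactly one deme as deme-specific.

## The synthetic-data generator

`sim_config()` + `generate_dataset()` produce complete studies with known
truth. Defaults emulate the targeted field design: 119 high- and 141
low-altitude clonal lines, six leaves per line (two per crown section,
alternating two nursery blocks), 70 landmarks, order-4 base shape,
Balding--Nichols SNP divergence at $F = 0.0075$, AR(1) landmark noise with
sd 0.02 and lag-1 autocorrelation 0.7, a 3% deme width offset (high-altitude
leaves slender), ±3% crown-position and ±0.5% block width effects, Poisson
read depths with mean 20, and neutrality classes assigned in the proportions
typical of a resequencing panel (intergenic : intron : synonymous roughly
53 : 16 : 0.2). The base leaf is an elongated ovate (axis 3, width 1,
broadest chord 30% from the base, the band reported for poplar leaves).

Planted QTL classes are constructed so that each lands on its own
measurable signature after alignment:

* `LENGTH`: axis $\times (1+e)$, width $\times (1-e)$ — long-narrow vs
  short-broad.
* `WIDTH`: a raised-cosine widening of the blade body (centre 40% of the
  axis, half-width 30%), amplitude calibrated ($1.19e$) so the measured
  maximum-width change between extreme genotypes equals the nominal effect
  $e$. A uniform width scaling would be indistinguishable from an
  aspect-ratio change in shape space (see above), so the generator plants
  what a width QTL means there: blade-body widening at equal axis.
* `TIP` / `BASE`: raised-cosine margin bulges confined to the middle-upper
  (centre 78%) or basal (centre 22%) sections, applied in landmark space so
  the planted locality is exact. The basal bulge also moves maximum width —
  the broadest chord is basal — making `BASE` a width-moving class, while
  `TIP` leaves the width descriptor almost unchanged.

Noise is generated at the `K` landmark knots and interpolated around the
emitted dense margin, so the noise lives at the landmark scale while the
margin stays locally smooth; each leaf additionally receives a random
similarity jitter (rotation, scale, translation) that the alignment step
must remove. Leaves that violate the star-shape precondition are redrawn
(and counted); after ten rejections the noise is progressively damped
rather than looping forever. All randomness flows from the single config
seed through named per-stage streams, so identical configs give
byte-identical bundles.

Two honest caveats about what the generator does and does not emulate.
First, real leaf margins carry serration, lobing and measurement artifacts
that the smooth ovate base cannot show; passing tests demonstrate the
pipeline's statistical behavior under its own model class, not robustness
to arbitrary real margins. Second, phenotypes built through the full
geometric path (resample, align, average) carry *mean-model lack of fit*:
the order-4 Fourier curve cannot represent the ovate exactly, and that
shared misfit inflates the fitted residual variance and autocorrelation
(estimates of $\rho$ drift toward 0.8 regardless of the planted value). The
likelihood-ratio contrast is unaffected — both hypotheses share the misfit —
but parameter-recovery checks use `simulate_shape_phenotypes()`, which
draws phenotypes with the mean exactly in the fitted basis span and AR(1)
noise at the landmarks; under that model-consistent generator the planted
$\rho$ and $\sigma$ are recovered to well within ±0.1.

## Population-genetic summaries

* `filter_markers()` applies the strict-inequality retention rules: site
  mean depth > 12 reads, exact Hardy--Weinberg p-value > 0.05 (conditional
  exact test, `hwe_exact_pvalue()`), minor allele frequency > 0.05, missing
  fraction < 0.10, heterozygote excess < 0.10. Heterozygosity is filtered
  as the *excess* of the observed heterozygote frequency over its
  Hardy--Weinberg expectation: a literal observed-heterozygosity cap of
  0.10 would discard essentially every intercross marker, contradicting
  their retention. The literal rule and a per-genotype depth rule are
  available as configuration flags.
* `weir_cockerham_fst()` is the Weir & Cockerham (1984) moment estimator
  $\theta$, combining loci by ratio of averages (sum of per-locus
  numerators over sum of denominators), monomorphic loci skipped.
* `nm_from_fst()` is the island-model $N_m = (1 - F_{ST})/(4 F_{ST})$.
* `deme_variance_components()` + `qst()` give
  $Q_{ST} = \sigma^2_{GB} / (\sigma^2_{GB} + 2\sigma^2_{GW})$ from one-way
  method-of-moments components with the unbalanced-design effective group
  size; a negative between-deme component is truncated to zero with a
  warning. (The denominator uses $2\sigma^2_{GW}$; a doubled *between*
  component sometimes seen in print is a typo of the standard formula.)
* `shape_anova()` fits the fixed-effects trait model — altitude, genotype
  nested in altitude, crown position, block, genotype-by-position,
  altitude-by-position — by least squares with sequential (type-I) sums of
  squares in that order, F against the residual mean square. With genotype
  labels unique per altitude the altitude-by-position span is contained in
  genotype-by-position, so that last term can legitimately carry zero
  degrees of freedom in a complete design; it is reported as fitted.

## Problem sizes used by the checks

The packaged tests and the acceptance script run complete simulated studies
at sizes a workstation handles comfortably: null calibration on 60--100
datasets of 100 lines x 50 markers with 200-replicate thresholds; power and
classification on 12--20 studies per class of 150 lines x 6 leaves;
$F_{ST}$ recovery on 2000 loci; $Q_{ST}$--$F_{ST}$ contrasts on 25--50
studies of 120 lines x 500 loci. The pipeline default of 1000 permutation
replicates matches the study design; the calibration suites use 200, which
is ample for a 5% genome-wide quantile.

## Known limitations

* Equal-angle landmarks require star-shaped margins; deeply lobed leaves
  need a different correspondence scheme.
* The AR(1)-by-block covariance ignores x--y cross-covariance at a
  landmark; it is a deliberate $O(K)$ modeling choice, stated, not a claim
  about leaves.
* Cumulative heritabilities over linked markers overlap (no joint model).
* The sampler's AIC landmark selection flattens rather than turning for
  smooth margins; it is a guard against under-sampling, not a sharp
  optimum.
* No linkage disequilibrium in the simulator: markers are independent,
  sufficient for calibration and power work but not for fine-mapping
  studies.
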