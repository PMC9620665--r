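---
title: "NFT burden, spatial clustering, and the clinicopathologic battery: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NFT burden, spatial clustering, and the clinicopathologic battery: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nftburden)
```

This vignette records how `nftburden` defines its quantities, which
conventions it fixes where several were defensible, how the synthetic
cohort is calibrated, and what the test suite does and does not establish
about real data.

## The data model

A slide is a set of segmented neurofibrillary tangles (NFTs), each reduced
to a centroid in continuous level-0 pixel coordinates (origin top-left, x
rightward, y downward) and a pixel area, together with two manually traced
region polygons: the hippocampus proper and the adjacent entorhinal
cortex. The default pixel pitch is 0.5066 µm/px (100 px = 50.66 µm at the
40x scan resolution); it can be overridden per slide, and every derived
unit follows from it by dimensional analysis.

When the upstream model supplies per-pixel NFT probabilities rather than
discrete objects, `extract_instances()` binarizes at a threshold
(inclusive, default 0.5), labels connected components (8-connectivity by
default, 4 available), drops components below 20 px², and takes the
unweighted mean of member pixel centers as the centroid. No canonical
reduction from probabilities to instances exists for these maps; all three
parameters are explicit knobs, and the defaults are conservative stand-ins
rather than measured optima: 0.5 is the symmetric cut of a calibrated
probability, 8-connectivity is the more inclusive choice for blob-like
structures, and 20 px² (≈ 5 µm² at default pitch) is well below any
plausible tangle cross-section, so it removes only speckle.

Containment is inclusive: a centroid exactly on a region boundary belongs
to that region. This is the deterministic tie rule; without it, a centroid
on an edge would be assigned or dropped depending on floating-point noise.
Tangles in neither polygon are labeled `unassigned`, excluded from
regional metrics, and counted in the pipeline log.

Cognitive status is dichotomized as: CDR ≥ 0.5 or MMSE < 26 ⇒ impaired
(CI); CDR 0 or MMSE ≥ 26 ⇒ unimpaired (NCI). With both scores present the
more recently dated decides; same-date ties and unresolvable dates go to
CDR (the latter with a warning, since the tie is then an assumption rather
than a fact); with neither score, a chart-review flag decides. Dates are
compared at day resolution.

## Burden metrics

Three scalar measures per region, plus the pooled "combined" region:

- count density = NFT count / region area (NFTs/mm²);
- NFT positive-pixel density = Σ NFT pixel areas / region pixel area
  (dimensionless, invariant to pixel pitch);
- positive-pixel burden = positive pixels / total pixels, a 0–1 scale
  consuming externally computed immunoreactivity counts. The proprietary
  positive-pixel algorithm behind such counts (hue/intensity windows,
  batch-control calibration) is out of scope; the function accepts counts
  from any source and tags their provenance (`external` vs `threshold`).

The combined region pools objects and sums areas — it is *not* the average
of the two densities, which would weight a small region as much as a large
one. Densities are reported in NFTs/mm²; since every downstream model
standardizes its predictor, the unit choice affects reporting only.

## The clustering metric

The spatial summary of a slide is the mean local clustering coefficient of
the geometric graph on NFT centroids: nodes are tangles; an edge joins two
tangles at Euclidean distance strictly less than a threshold r; the local
coefficient of a node with degree k ≥ 2 is the fraction of its neighbor
pairs that are themselves connected, and the slide value is the arithmetic
mean over all nodes. Conventions fixed here, with the reasoning:

- **Strict `<` at the boundary.** A pair at distance exactly r is a
  non-edge. For continuous centroids ties are measure-zero, so the choice
  is about determinism, not substance; distances are compared on squared
  values so the rule is exact in floating point.
- **Degree < 2 contributes 0.** Isolated and pendant tangles have no
  neighbor pair; counting them as 0 (the dominant convention in network
  analysis) makes the mean sensitive to the dispersed fraction of the
  pattern. The alternative — excluding them from the mean — is available
  as `low_degree = "exclude"` because the choice is not forced.
- **Fewer than 3 tangles ⇒ undefined.** The statistic is returned as `NA`,
  never 0: a dispersed pattern legitimately scores 0, and conflating the
  two would bias group comparisons. Such slides are excluded from
  clustering regressions, with a logged count.
- **Whole-slide pooling.** The metric is computed on all of a slide's
  tangles across both regions; it is a per-slide, not per-region, summary.

No canonical inter-tangle distance exists, so the metric is swept over
r = 100, 200, …, 5000 px (50 values; 50.66–2533 µm at default pitch). The
total tangle count travels with the sweep as a mandatory nuisance
covariate: at fixed r, denser patterns have higher coefficients regardless
of arrangement, so any regression on the coefficient without the count
would measure density twice.

The sweep kernel is compiled (packed-bitset adjacency with popcount
triangle counting, O(n²·n/64) per radius after an O(n²) distance matrix).
Exactness — not approximation — is the contract: the suite checks the
kernel against an independent O(n³) brute-force evaluation to 1e-12 across
the full grid, and against closed forms (complete triangle 1, square
4-cycle 0, sub-minimum radius 0, supra-diameter radius 1).

## The statistical battery

Odds ratios come from maximum-likelihood logistic regression with the
predictor (and continuous covariates) z-scored, so every reported OR is
per standard deviation. The measures span counts/mm², dimensionless
fractions, an ordinal stage and a graph coefficient; per-unit ORs would be
incomparable across rows, and per-SD scaling is the only scale on which a
single table makes sense. Intervals and p-values are Wald-based, matching
the OR-with-95%-CI reporting style; fits that fail to converge or show
quasi-separation (|log-OR| > 15 or SE > 100 on the standardized scale) are
errors, not numbers.

Multiplicity is controlled by Benjamini–Hochberg FDR within two separate
families: (a) the battery of measures, separately within the unadjusted
and age-adjusted conditions; (b) the radius grid within an OR curve. The
battery and the curve answer different questions (which measures predict
impairment; over which spatial scales the clustering signal lives), so
their tests are not pooled.

Other conventions: 2×2 chi-squares use the Yates continuity correction,
r×c tables none (both verified against published-count p-values);
two-sample comparisons default to Welch's t (the pooled-variance Student
test is a switch) because equal group variances are an assumption the data
need not honor; the CMH age adjustment stratifies at the median age by
default, with the cut exposed; missing covariates are handled by listwise
deletion with logged exclusion counts; age-corrected group displays use
residuals from a linear fit of the measure on age. The CMH statistic is
computed from its hypergeometric-moments formula (continuity correction
optional, default off) so a single stratum degrades gracefully to the
plain 2×2 association.

## The synthetic cohort

The generator exists to exercise the estimators under known truth, not to
claim biological realism. It encodes the cohort structure the analysis
assumes:

- **Ages**: truncated normal, mean 85, SD 10, bounds 55–110.
- **Counts**: whole-slide expected count λ = m·exp(b·z_age − b²/2) with
  m = 120 at the mean age. The slope b is solved by moment matching so
  that corr(count, age) = 0.3: with over-dispersion 1 + w·µ from the
  clustered mixture, Cov(N, z) = m·b and
  Var(N) = m(1 + wµ) + m²(e^{b²} − 1), and b is the root of the resulting
  correlation equation on its rising branch. The mean count of 120 over
  ~82 mm² of tissue (≈ 1.5 tangles/mm²) is a plausible medial-temporal
  tangle load for the Braak II–III range that dominates such cohorts.
- **Patterns**: with probability 0.5 a slide is a Thomas process (Poisson
  parents, Poisson(µ = 10) offspring per parent, isotropic Gaussian
  dispersion σ = 400 px ≈ 203 µm) and otherwise homogeneous Poisson, both
  at the same expected count. σ = 400 px is a choice, not a measurement:
  it places the cluster scale inside the radius band where the clustering
  metric is expected to be informative (roughly 2σ = 800 px). Parents are
  simulated in the bounding box dilated by 4σ so edge effects on the
  retained-count mean are negligible.
- **Outcome**: logit P(CI) = β₀ + β_burden·z(count) + β_age·z(age) with
  β_burden = ln(1.40) per SD and β₀ = ln(344/362) (≈ 49% impaired).
  β_age is solved numerically so the marginal CI−NCI age gap is ≈ 4.5
  years: under a bivariate-normal approximation of (z_age, z_count) — with
  the age z carrying its truncated-normal variance — the group gap of any
  covariate equals its covariance with the linear predictor times the
  logistic selection gap of that predictor, and the latter is evaluated by
  numerical integration rather than by the linear-discriminant shortcut,
  which overstates the gap by ~15% at these effect sizes.
- **Clinical instruments**: CDR (present with p = 0.75), MMSE (p = 0.6), a
  chart flag (always present if neither score is), with values encoding
  the subject's label after a symmetric flip with probability 0.1 — the
  default emulates the noise of retrospective clinical classification.
  Braak stage is generated from a latent variable tracking burden and cut
  at the marginal stage frequencies of a ~700-subject autopsy series;
  ARTAG prevalence rises with age (for exercising the CMH adjustment);
  positive-pixel counts are the slide's tangle pixels plus multiplicative
  thread/background noise.

Reproducibility is exact: each subject's seed derives deterministically
from the master seed (kept below 2³¹), so (seed, params) fixes every file
byte. Empirically (and asserted in the suite): the count–age correlation
lands within ±0.08 of 0.3, the age gap within ~0.1 year of 4.5, and the
age-adjusted per-SD OR of combined count density recovers 1.40 with ~95%
Wald coverage.

Three estimator experiments deserve their caveats stated plainly:

- *Parameter recovery* runs with label noise 0. With the default 10%
  symmetric noise, the logistic slope attenuates by roughly (1 − 2ε) and
  the recovered OR drops to ≈ 1.31 — that is a property of misclassified
  outcomes, not an estimator defect, and recovery of a generating
  parameter requires observing the generating labels. Recovery also uses
  the age-adjusted fit, matching the generating model: the crude OR is
  confounded upward (≈ 1.55) because burden and outcome share age as a
  cause.
- *Null calibration* sets both β_burden and β_age to zero. With only
  β_burden = 0, burden still correlates with the (age-driven) outcome
  through the count–age link, so burden measures are not null; a
  false-positive experiment needs the outcome independent of everything
  the battery tests.
- *Problem sizes*: recovery uses 100 cohorts of n = 700; null calibration
  20 cohorts of n = 300 (about 150 per class keeps all 18 battery fits
  estimable); brute-force equivalence uses 20 point sets of 30–300 points.
  These sizes are the package's own choices balancing Monte-Carlo error
  against runtime.

## What the tests do and do not show

The synthetic cohort has uniform region geometry across subjects, a single
pixel pitch, independent subjects, no staining batch effects, no
segmentation error model (false merges/splits near the instance-extraction
threshold), and spatial patterns drawn from exactly two stationary
processes. Passing tests therefore establish that the estimators are
implemented correctly and behave nominally under the assumed data model —
they do not validate the biological claim that tangle clustering predicts
impairment in any particular cohort, nor the robustness of the metrics to
segmentation-model failure modes. The published-count checks (Yates 2×2,
Braak r×c, unit conversions) tie the arithmetic, not the cohort inference,
to external numbers.

Known limitations: region polygons must be simple (no holes — an annulus
would need a boundary-touching cut); the dense distance matrix caps
practical slides at a few tens of thousands of tangles; the OR curve
refits per radius without sharing information across radii (no smoothing);
and the CERAD association printed in the cohort literature is not
reproducible from its published marginal counts under either correction
convention, so it is deliberately not among the checked values.
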