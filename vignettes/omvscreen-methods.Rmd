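---
title: "Methods: scoring, filtering and calling vesiculation phenotypes"
author: "OMVscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, filtering and calling vesiculation phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OMVscreen)
```

# The measurement model

A high-throughput vesiculation screen grows each knockout strain of an
arrayed library in a 96-well plate, filters the culture supernatant onto a
nitrocellulose membrane, and quantifies the trapped outer-membrane material
by immunoblot densitometry. The package models the raw intensity of strain
*g* on membrane *m* as

$$ I_{gm} = S_m \, \theta_g \, (1 + \varepsilon), $$

where $S_m$ is a membrane-wide scale factor (blotting and imaging differ
between days, i.e. between membranes), $\theta_g$ is the strain's true
relative vesiculation level, and $\varepsilon$ is well-level multiplicative
noise. Two consequences drive the whole analysis:

* dividing every well by the membrane mean removes $S_m$ exactly — this is
  `normalizeMembrane()`, and its scale invariance (tested property) is
  precisely the day-to-day correction the design needs;
* after normalization, replicate values of the same strain from different
  membranes are comparable, so the strain score is the arithmetic mean of
  its normalized replicates, reported on the log10 scale
  (`scoreStrains()`).

Averaging is done on the linear scale first and log10 is applied to the
mean; this keeps the score's expectation centred on $\theta_g$ under
multiplicative noise. The alternative (mean of logs, i.e. geometric
averaging) is available via `average = "log"` but is not the default,
since it shifts the null score down by half the log-scale variance.

The replicate coefficient of variation is the sample standard deviation
divided by the mean of the **unlogged** normalized replicate values. (Some
reports print the CV as "mean/standard deviation"; that inverts the
standard definition, and the standard sd/mean is what is computed here.)
Note that with two replicates the sample-sd CV is a noticeably downward
biased estimate of the generative CV (expectation ≈ 0.80 of it), so a
collection run mostly in duplicate will report a mean CV below the
per-well noise CV. The `collectionCV()` summary is an average over
strains, dominated by the duplicate majority.

Wells with non-positive intensity (possible after background subtraction)
are excluded from the membrane mean and treated as missing replicates; a
strain needs at least two usable replicates to be scored, otherwise it is
diverted to a rejects list with a reason.

# Growth quality control

Low blot signal can reflect poor growth and high signal can reflect lysis,
so growth is a mandatory gate before phenotype calling. OD600 time courses
(18 h, 30-minute reads, three trials by default) are fit with the
modified Gompertz model in the Zwietering parameterization,

$$ od(t) = y_0 + A\,\exp\!\big(-\exp\big(\tfrac{\mu_{max} e}{A}(\lambda - t) + 1\big)\big), $$

whose $\mu_{max}$ is the slope of the tangent at the inflection (OD600/h)
and $\lambda$ the lag time (h). Fitting uses bounded Levenberg–Marquardt
least squares on the raw OD values with data-driven starting values
(baseline = min OD, amplitude = range, rate = steepest finite-difference
slope, lag from the tangent construction, clipped at 0) and one
deterministic restart from perturbed starting values; optimizer failure is
recorded as `converged = FALSE` and treated downstream as a poor fit, not
raised as an error. Raw-OD fitting is the default because plate-reader
curves in rich medium rarely have the dynamic range that justifies log-OD
fitting; `logOd = TRUE` switches the scale.

Filtering is two-stage (`classifyGrowth()`):

* trials with R² ≤ 0.7 (the boundary value itself is filtered) or without
  convergence are unusable; a strain with no usable trial is excluded as
  `poor_fit_all_trials`;
* per-strain mean rates are compared with the population of per-strain
  means; strains strictly farther than `nSd` (default 1) population
  standard deviations from the population mean are excluded as
  `rate_outlier`, two-sided — both abnormally slow and abnormally fast
  growers are suspect. A pooled mode (statistics over all per-trial rates)
  is available, since "across all trials" is ambiguous between the two;
  the per-strain mean is the default because it weights strains equally.

A degenerate population (zero rate spread) excludes no one, because the
comparisons are strict. R² is undefined on a flat curve (zero total sum of
squares) and reported as NA.

# The two-standard-deviation call

On the growth-passing collection the log10 scores are approximately
normal, and a strain is called *over* (*under*) when its score is strictly
above (below) the collection mean ± 2 sample standard deviations
(`computeCutoffs()`, `callPhenotypes()`). Scores exactly at a cutoff are
normal. The mean and sd are computed on the growth-passing set (the set
actually being called); no per-gene variance weighting and no
multiple-testing correction are applied at this stage — the rule is a pure
z-cutoff, and under normality it calls ≈ 4.6% of a null collection. The
cutoffs are location/scale equivariant, so calls are invariant to affine
changes of the score scale (tested property).

# Enrichment and validation statistics

Functional enrichment uses flat category sets over an explicit universe
(`AnnotationSet`), with the exact upper-tail hypergeometric probability
$P(X \ge k)$ for observing $k$ of $n$ significant genes in a category of
$K$ within a universe of $N$. The package surfaces raw p-values flagged at
α = 0.05; Bonferroni and Benjamini–Hochberg adjustments are explicit
options and never applied silently, and an optional Jaccard-overlap filter
can suppress near-duplicate categories. In `runPipeline()` the universe is
the set of called (scored, growth-passing) strains — the population the
significant set was actually drawn from; genome-wide annotation universes
from web services are generally larger and not reconstructable offline, so
externally printed enrichment p-values should not be expected to match
numerically.

FCOP (flask-grown culture OMV preparation) measurements are normalized by
`fcopVesiculation()`: per-replicate FM4-64/CFU ratios, averaged per strain,
divided by the wild-type mean, making the wild type exactly 1 and the
result invariant to rescaling all fluorescence values. Concordance between
the screen and FCOP (`methodConcordance()`) is Pearson correlation between
the screen log10 score and log10 of the normalized FCOP value, with a
one-sided p-value (positive association is the only direction that
validates), Spearman optional. Sign agreement counts pairs whose effect
directions match, an exact zero on either side agreeing with anything
(measured zeros are vanishingly unlikely; the convention only matters for
constructed data).

# The synthetic generator and what it does (not) emulate

`generateLibrary()` + the three simulators generate complete screens with
known truth. Default conditions mirror a genome-scale screen: 3,905
strains; planted log10 effects of ±0.6 on 2% (over) and 2.5% (under) of
genes; well noise CV 27.8%; membrane scale lognormal with σ = 0.3 (the
day-to-day magnitude is not something a published screen reports, so this
is a free parameter chosen to be visibly larger than well noise, not an
estimate); every strain in duplicate with random subsets of 272/138/76
strains run 3/4/5 times; three growth trials at 0.01 OD noise; a 2.69%
growth-defective subpopulation.

Two generator choices deserve justification:

* **Growth-rate spread.** A screen that excludes only ~2.7% of strains
  with a ±1 sd filter cannot have normally distributed rates (that would
  exclude 31.7%); the observed rate distribution must be tightly
  concentrated with a displaced defective subpopulation. The generator
  therefore gives normal strains a small true rate sd (0.015 OD600/h
  around 0.5) and displaces defective strains by 20 of those sd (slow by
  default; a `fast` option exists because the filter is two-sided). The
  resulting population sd is dominated by the defectives, and the 1-sd
  filter recovers approximately the planted subpopulation plus a small
  normal tail.
* **Planted categories.** Enriched categories are filled by weighted
  sampling with odds 60:1 in favour of effect genes, giving roughly
  three-quarters effect genes per planted category at genome scale —
  strong but not degenerate enrichment.

The generator emulates plate/membrane structure, replicate design,
multiplicative noise and ground-truth effects. It does **not** emulate:
image formation or densitometry artefacts, spatial within-plate effects
(edge evaporation, row/column gradients), correlated biological covariance
between vesiculation and growth (defects are planted independently), or
annotation redundancy across categories. Passing recovery tests on this
generator therefore demonstrates the statistical machinery under the
stated noise model, not robustness to spatial artefacts or confounded
biology.

# Numerical choices

* Sample standard deviations (n−1) throughout; at collection scale the
  choice is numerically irrelevant but it is fixed.
* Strict inequalities at every cutoff (score cutoffs, rate filter), so
  boundary values and degenerate spreads behave predictably.
* Hypergeometric tails go through the numerically stable distribution
  function; the test suite checks them exhaustively against direct
  binomial-coefficient enumeration for all universes up to N = 60 at
  1e−12 relative tolerance.
* Noise factors are normal around 1, redrawn until positive; at the
  default CV this truncation is a < 2 × 10⁻⁴ tail event.
* All randomness enters through explicit `seed` arguments; generators
  restore the caller's RNG state.
* Result tables are written at 15 significant digits (lossless round trip
  at the documented 12).

# Problem sizes in the test suite

Unit tests run on 96–500-gene libraries. The end-to-end recovery and null
calibration tests use the full default conditions (3,905-strain libraries,
and 3,800-strain null collections, 10 seeds each), which keeps the whole
suite under a minute; the Gompertz recovery test uses 100 noisy curves.
The acceptance script regenerates one complete default screen including
all ~11,700 growth-curve fits.

# Known limitations

* The per-strain CV is reported but not propagated into calling; a
  variance-weighted or empirical-Bayes caller would use it.
* Flat annotation only: no ontology graph, no term propagation, no
  "most specific term" collapsing beyond the optional Jaccard filter.
* The Gompertz model assumes a single growth phase; diauxic or lysing
  curves are typically caught by the R² filter rather than modelled.
* Growth-rate units are OD600/h (amplitude-scale); comparing against
  rates in 1/h requires knowing the source's convention.
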