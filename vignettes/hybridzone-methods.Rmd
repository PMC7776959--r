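---
title: "Models and methods for ecotone hybrid-zone analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for ecotone hybrid-zone analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybzone)
```

# The scientific setting

Pairs of plant taxa that hybridize freely yet remain distinct are often
separated by sharp habitat transitions — an ecotone only tens of meters
wide between, say, a desert plain and a coastal dune. `hybzone` provides
the full computational chain such a study needs: from biallelic SNP
genotypes and transect coordinates to admixture proportions, hybrid-class
assignments, geographic cline widths, morphological hybrid indices, and
reciprocal-transplant selection coefficients, plus a seeded synthetic-data
generator so the entire chain can be exercised and validated without field
data.

Positions are signed meters from the ecotone midline (desert side
negative, dune side positive). Genotypes are ALT/pool-1 allele dosages in
{0, 1, 2}; all internal indexing is 0-based only at file boundaries (VCF
stays 1-based on disk).

# Supervised admixture proportions

For an individual with dosages $g_l$ and parental pool frequencies
$f_{1l}, f_{2l}$, the admixture proportion $q$ toward pool 1 maximizes

$$\ell(q) = \sum_l \log \mathrm{Binom}(g_l;\, 2,\, \pi_l), \qquad
\pi_l = q f_{1l} + (1 - q) f_{2l}.$$

Because $\pi_l$ is affine in $q$, $\ell$ is concave and a single bounded
1-D optimization (tolerance $10^{-6}$) suffices — no multistart. The
standard error uses the observed Fisher information at the optimum and is
reported `NA` on the boundary, where the quadratic approximation fails.
This is a *supervised* analogue of the usual unsupervised two-population
admixture model: reference panels exist on both transect ends, so the
parental frequencies are estimated once from the panels (with Agresti
shrinkage, below) and held fixed. The trade-off is honest: uncertainty in
the panel frequencies is not propagated into $q$.

**Frequency shrinkage.** Each pool's frequency estimator adds 0.5
pseudo-alleles of each type: $f = (c + 0.5)/(d + 1)$ for allele count $c$
and denominator $d$. Finite panels otherwise produce exact 0/1
frequencies, which make class likelihoods $-\infty$ the moment a query
individual carries the "impossible" allele. Loci with fewer than 2
scorable alleles in either pool are dropped and reported.

**Missing data.** Loci missing in an individual are simply excluded from
that individual's sums; individuals with fewer than 50 usable loci
(configurable) are flagged and excluded rather than estimated — sparse
ddRAD individuals otherwise produce degenerate likelihoods. The threshold
is our declared default, not a value inherited from any particular study.

# Hybrid-category classification

Each category $c \in \{P1, P2, F1, F2, BC1, BC2\}$ has an allele-origin
distribution $w(c)$ over (both alleles from pool 1, one from each, both
from pool 2):

| class | both-P1 | one-each | both-P2 |
|-------|--------:|---------:|--------:|
| P1    | 1       | 0        | 0       |
| P2    | 0       | 0        | 1       |
| F1    | 0       | 1        | 0       |
| F2    | 1/4     | 1/2      | 1/4     |
| BC1   | 1/2     | 1/2      | 0       |
| BC2   | 0       | 1/2      | 1/2     |

and $P(g \mid c) = \sum_z w_z(c) P(g \mid z)$ with the one-each state
giving $P(2) = f_1 f_2$, $P(1) = f_1(1-f_2) + (1-f_1)f_2$,
$P(0) = (1-f_1)(1-f_2)$. Log-likelihoods are summed over usable loci and
combined with a prior (uniform by default — the source analyses state
maximum-likelihood categorization without a prior) via log-sum-exp.

Exact ties (within $10^{-9}$ on the log scale) are broken by the fixed
order P1, P2, F1, F2, BC1, BC2 with a warning; a tie means the loci carry
no information for the choice, so determinism matters more than the label.
Only first/second-generation categories are modeled; deeper backcrosses
fold into the nearest category — a documented limitation shared with the
standard category classifiers in this field.

# Geographic clines

Individuals are binned into fixed-width bands (default 10 m) anchored on
the ecotone midline; band means of ancestry are the fitted "populations".
The cline model is

$$p(x) = p_{min} + (p_{max} - p_{min}) \,
\frac{1 + \tanh\!\big(2 (x - c)/w\big)}{2},$$

where the width $w$ is the inverse of the maximum slope of the scaled
cline. Tails are free parameters in $[0,1]$, not pinned to 0/1 — observed
transects show non-extreme tail ancestries.

**Error model.** Band means are Normal with variance $\sigma^2/n_b$ and
$\sigma^2$ profiled, making maximum likelihood a weighted least squares.
A binomial pseudo-count option ($2n$ trials, $2n \bar q$ successes) is
also provided; which likelihood the classic cline tools used is not
always stated, and both are defensible, so the choice is exposed.

**Numerics.** For fixed $(c, w)$ the tails enter linearly, so the inner
problem is a 2x2 weighted regression; the outer search over
$(c, \log w)$ uses Nelder-Mead from 8 starts (centres at the position
quintiles crossed with widths span/10 and span/3 — tanh fits have flat
ridges), followed by a boxed quasi-Newton polish with tails constrained
to $[0, 1]$. The bootstrap CI for $w$ resamples individuals within bands
(default B = 500) and refits from the point estimate. In the acceptance
suite B = 199 is used purely to respect the stated time budget over 200
simulated zones; percentile-interval coverage is insensitive to B at this
scale.

# Morphological hybrid index

All leaves enter one scaled, centred PCA; axis-1 scores are averaged per
individual, then mapped affinely so the parental reference centroids sit
exactly at $-2$ (pool 1) and $+2$ (pool 2). Averaging raw scores before
the affine map is provably equivalent to mapping first (the map is
affine); a test asserts it. The $\pm 2$ anchor makes the conventional
seedling-scoring rule — "hybrid" if the index falls in $(-1, 1)$ —
operational on a reproducible scale; the anchor constant is configurable
because the original scaling of such indices is typically unstated.
Progeny hybridization rates carry Wilson score intervals.

# Reciprocal-transplant selection

Composite fitness per plant is survival (0/1) times $\ln(1 + \text{biomass})$;
dead plants contribute 0, not missing (their biomass at death is recorded
but survival zeroes the product). Within each habitat, cell means are
standardized by the fittest phenotype; the selection coefficient is
$s = 1 - w_{rel}$, so exactly one phenotype per habitat has $s = 0$ and
all $s \in [0, 1]$. Percentile bootstrap CIs (plants resampled within
cells by default; within habitats optionally — the original resampling
scope is unstated) are truncated to $[0, 1]$.

**A caveat on accuracy at field scale.** With ~31 plants per cell, the
sampling error of a cell-mean ratio is of order 0.1–0.2, so no single
experiment pins $s$ to 0.05. The recovery test therefore checks that the
*mean* estimate over hundreds of simulated experiments is within 0.05 of
truth for every cell — a bias bound. Even the bias is not exactly zero:
standardizing by the observed best cell inflates $\hat s$ for a
runner-up whose true fitness nearly ties the winner (a winner's-curse
effect of order the cell-mean standard error). At this design scale the
measured worst-case bias is ~0.04.

**The GLM.** The interaction test fits a negative binomial GLM with log
link on the $\ln(1+x)$-scale response — replicating the source analysis's
(unusual) use of an NB model on transformed continuous data. Responses
are accepted in the quasi-likelihood sense rather than rounded; a Gamma
GLM with log link is exposed as the conventional alternative for positive
responses. When the NB dispersion profile diverges (sparse all-zero
cells), the fit falls back to a moment-estimated fixed dispersion with a
warning. Nested models are compared with $LR = 2\Delta\ell$ against
$\chi^2$ on the difference in mean-model parameters.

# Cause-specific mortality: hierarchical log-linear models

Three-way tables (habitat x phenotype x died-of-cause) are fitted by
iterative proportional fitting to the margins of a generating class, with
$G^2 = 2\sum o \log(o/e)$ and degrees of freedom from the standard
hierarchical parameter count. Sampling zeros get no additive constant —
IPF tolerates them, and flat +0.5-type corrections distort $G^2$;
structural problems surface as non-convergence and flag the affected term
instead of removing it silently.

Backward stepwise selection starts from the saturated model and
repeatedly removes the maximal term with the largest removal p-value
above $\alpha = 0.05$ (main effects are never removed); the first
candidate from a 3-way table is always the three-way interaction, so the
first trail row is the habitat-by-phenotype test. The default two-model
LR comparison is saturated vs. all-two-way.

One calibration fact worth knowing: under full mutual independence the
chance that stepwise ends at main-effects-only is about
$0.95^4 \approx 0.81$, because four sequential null removals must all
pass at $\alpha = 0.05$. Folklore expectations of 85–95% "clean"
selections overstate what any correct implementation can deliver; our
property test asserts 75%.

# The synthetic world

The generator's defaults describe one coherent, field-realistic scenario
and are fixed independently of any test outcome:

* **Gene pools.** $f_1 \sim \mathrm{Beta}(8,2)$,
  $f_2 \sim \mathrm{Beta}(2,8)$ per locus: strongly divergent pools with
  mean frequency differential 0.6. Query genotypes are drawn through the
  class origin distributions above, so simulated F1 heterozygosity is
  $f_1(1-f_2) + f_2(1-f_1)$ in expectation by construction.
* **Transect.** A 300-m span, cline centre 0, width 100 m, tails
  0.02/0.98; individual ancestry is Beta around the cline expectation
  with concentration 50 (keeps draws in $[0,1]$, dispersion tunable).
* **Transplant.** 3 habitats x 3 phenotypes, ~30 plants per cell (the
  published design scale of 276 plants over 9 cells). Cell survival
  matches the qualitative record (parental survival < 10% in the
  nonnative habitat); lognormal biomass location is *solved numerically*
  (by integrating $E[\ln(1+B)]$) so each cell's expected composite
  fitness reproduces the published selection coefficients
  ($s$ = 0.983, 0.755, 0.702, 0.097, 0.582, 0.460). Burial mortality is
  absent in the desert and never hits the dune-native phenotype;
  herbivory occurs everywhere. Biomass dispersion (sdlog = 0.5) is a
  realism judgement, made once.
* **Determinism.** Every generator consumes the `sim_config` seed, so
  runs are bit-reproducible; pipeline reports embed a config hash and the
  package version.

What a green test does *not* establish: the generator is a
single-generation sampling model (no dispersal, no multi-generation
selection), loci are unlinked and exchangeable, morphology has one
dominant axis by construction, and transplant cells are homogeneous. Real
ddRAD data adds linkage, allele-frequency misestimation from small
panels, and spatially structured missingness that these tests do not
probe.

# Known limitations

* Supervised $q$ ignores panel-frequency uncertainty; with very small
  reference panels the reported SE is optimistic.
* Classification folds deeper backcrosses into BC1/BC2.
* Only the single sigmoid cline is implemented (no stepped or
  exponential-tail variants, no model selection).
* The NB-on-transformed-data GLM is a replication choice, not a
  statistical recommendation; prefer the Gamma alternative for new work.
* Log-linear inference is asymptotic ($G^2$); sparse tables get warnings,
  not exact tests.
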