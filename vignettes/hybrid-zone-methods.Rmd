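---
title: "Models and methods for two-species contact-zone admixture analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for two-species contact-zone admixture analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hzadmix)
```

# The scientific setting

Reinforcement contact zones are secondary contact zones in which
selection against hybridization strengthens prezygotic isolation,
typically leaving a signature of reproductive character displacement
(RCD): mating signals more divergent in sympatry than in allopatry.
Testing whether reinforcement explains RCD requires demonstrating that
hybridization actually occurs, measuring how its frequency varies
across the zone, asking whether it is directionally asymmetric, and
relating signal displacement to admixture. `hzadmix` implements that
chain of analyses for two species genotyped at codominant,
multi-allelic (microsatellite-style) loci, together with a synthetic
zone generator that makes the whole chain testable with known truth.

# The hybrid-index model

## Likelihood

Let $p_A(l, a)$ and $p_B(l, a)$ be the allele frequencies of allele
$a$ at locus $l$ in the two parental reference pools, and let $h \in
[0, 1]$ be the proportion of an individual's genome derived from
species A ($h = 1$ pure A, $h = 0$ pure B; the orientation can be
flipped by exchanging reference roles, which maps $\hat h \mapsto
1 - \hat h$ exactly — a tested invariant). Each non-missing allele copy
contributes independently:

$$\log L(h) \;=\; \sum_{\text{copies } (l,a)}
  \log\!\big[\, h\, p_A(l, a) + (1 - h)\, p_B(l, a) \,\big].$$

The model treats allele copies as exchangeable draws from the
$h$-mixture of the two pools. That is exact for individuals produced
by random mating among admixed ancestors; for pedigree classes with
constrained genotypes (an F1 carries exactly one copy per species at
every locus) the model *overstates* genotype variance, which matters
for interval calibration (below).

Missing loci are simply skipped for that individual — the likelihood
is over typed loci only.

## Reference frequencies and smoothing

References are formed by pooling all allopatric localities of each
species (`pool_references()`; the default selector is species x
allopatric, with explicit locality or per-individual overrides
available for edge cases such as single-individual counties pooled
with a neighbour). Frequencies use add-$\alpha$ smoothing over the
union allele set of the whole dataset,

$$\hat p = \frac{\text{count} + \alpha}{\text{copies} + \alpha K},$$

with $\alpha = 0.5$ (a Jeffreys-style pseudocount) and $K$ the size of
the locus's allele universe. Without smoothing, an allele present in a
focal individual but unobserved in one reference would force $\hat h$
to a boundary regardless of the other 11 loci; with it, the likelihood
stays finite and the penalty is proportionate. $\alpha = 0$ recovers
raw proportions when exact arithmetic is wanted (several tests use it).

## Estimation and intervals

$\hat h$ is found by a grid scan at step $10^{-3}$ followed by bounded
golden-section refinement (tolerance $10^{-9}$), with explicit
comparison against both boundaries since the likelihood is often
monotone for pure individuals. On $L$ fully diagnostic loci the MLE
has a closed form — the species-A fraction of the $2L$ allele copies —
which the estimator reproduces to $10^{-6}$ (tested for every count
$k = 0, \dots, 24$ at $L = 12$).

The 95% confidence interval is the profile-likelihood set
$\{h : \log L(h) \ge \log L(\hat h) - 1.92\}$, endpoints by bisection,
*clamped to [0, 1]*. Clamping is what gives the phrase "the interval
extends to 0 or 1" operational meaning, and hence drives the second
classification rule. Calibration, measured on synthetic individuals
drawn from the mixture model itself (500 per $h \in \{0, 0.25, 0.5,
0.75, 1\}$, references of 200 individuals per species, loci at
divergence 0.2): interior classes cover at roughly 0.93–0.96. At the
boundary values the clamped interval is one-sided and covers with
probability near 0.99 — asymptotically $1 - \frac{1}{2}P(\chi^2_1 >
3.84) \approx 0.975$, higher at 12 loci — so boundary coverage sits at
the top of, and sometimes above, the nominal band. Pedigree-constrained
classes (true F1s and backcrosses) over-cover further because their
genotype variance is below the model's; the test suite therefore checks
them as parameter-recovery properties (mean $\hat h$, detection rates)
rather than as interval calibration.

## Classification

* **F1 window rule** — $\hat h \in [0.25, 0.75]$, inclusive at both
  ends (the bounds calibrated from laboratory-bred F1 hybrids, whose
  indices ranged up to 0.75). The window knowingly also captures
  advanced-generation genotypes; no disambiguation is attempted, and
  the realized flagged proportion runs above the true F1 fraction in
  the synthetic zone for exactly this reason.
* **CI rule** — hybrid of undetermined class if the interval excludes
  both 0 and 1 (tolerance $10^{-9}$).

Region summaries report the proportion flagged by each rule and the
derived advanced-generation proportion (CI minus F1, clipped at zero
with a warning if the rules disagree in the unexpected direction).

# Randomization and exact tests

**Difference in hybrid proportions.** The statistic is
$\bar f_1 - \bar f_2$ over the two regions' indicator vectors; null
replicates permute the pooled vector without replacement, preserving
group sizes. The p-value uses the add-one convention $(1 + b)/(R + 1)$
so it is never zero and is valid for any $R$. The default is 100,000
replicates and a two-sided criterion on $|{\rm difference}|$; a signed
one-sided mode is first-class because published tables are ambiguous
about sidedness. Two properties are worth stating plainly: (i) against
exhaustive hypergeometric enumeration the Monte-Carlo p agrees within
sampling error across every group configuration with $n_1 + n_2 \le
12$; (ii) for binary data the two-sided permutation test is
intrinsically conservative — under two Binomial(100, 0.2) groups the
*ideal* test's exact rejection rate at $\alpha = 0.05$ is 0.0329, not
0.05, because the observed arrangement's own probability mass sits in
the tail. The package reports the honest p-value rather than applying
any continuity adjustment.

**Sequential Bonferroni.** Holm's step-down procedure, via
`stats::p.adjust(method = "holm")`, with flags returned in input
order; it is order-invariant and never more permissive than plain
Bonferroni (both tested). Censored published entries such as
`"<.00001"` parse to a small stand-in ($10^{-6}$) adequate for Holm
ordering, with a censoring flag preserved.

**Maternal asymmetry.** With $X \sim {\rm Bin}(k_A + k_B, 1/2)$,
$p = \min\{1,\ 2\min[P(X \le \min), P(X \ge \max)]\}$. At null
proportion ½ tail-doubling coincides with the minimum-likelihood
convention of `binom.test` (cross-checked over a random grid), which
is why published values are exactly reproducible from printed counts.
The conventional $n > 15$ reporting threshold is a flag, not a
computational gate — all regions are computed.

**Delta-K.** $\Delta K = |{\rm mean}\,L(K{+}1) - 2\,{\rm mean}\,L(K) +
{\rm mean}\,L(K{-}1)| / {\rm sd}\,L(K)$ on a contiguous K grid with
sample-SD denominator; undefined at grid ends, flagged infinite when
the replicate SD is zero. Cluster inference itself is out of scope —
the statistic consumes any replicate log-probability table, and the
generator plants a recoverable kink for testing.

# Population structure

**Fst.** Weir–Cockerham $\theta$, the estimator the field's software
actually computes (as opposed to Wright's island-model parameter):
per-allele variance components $a, b, c$ summed over alleles and loci,
$\theta = \sum a / \sum (a + b + c)$, negative estimates retained and
meaningful as sampling noise around zero. Localities need $n \ge 5$ by
default.

**Rst.** Slatkin's allele-size analogue:
$R_{ST} = \sum_l (\bar S - S_W) / \sum_l \bar S$, with $\bar S$ the
mean squared size difference over all copy pairs pooled across the two
localities and $S_W$ the within-locality mean pooled over within-pair
counts; computed via the variance identity (mean pairwise squared
difference = twice the sample variance) and verified against brute-
force double loops. Allele identifiers are bin midpoints, so sizes are
integers by construction.

**PCoA.** Gower double-centering $-\frac12 J D^2 J$ and an
eigendecomposition; coordinates for positive eigenvalues; percent
variance relative to the sum of the *positive* eigenvalues (negative
eigenvalues, routine for non-Euclidean Fst/Rst input, are excluded
from the denominator — matching common practice in the spreadsheet
tools used for such analyses). On Euclidean input the configuration
reproduces all pairwise distances to $10^{-9}$.

**Geographic distance.** Haversine great-circle distance with mean
Earth radius 6371.0088 km for GPS input; a planar flag covers
synthetic transect coordinates. Although field descriptions often say
"Euclidean" distance between GPS points, the cited distance generators
produce geodesics, so haversine is the default for lon/lat.

**Mantel.** Pearson correlation of upper triangles, null by jointly
permuting rows and columns of the second matrix, one-tailed for
positive association, add-one p. Whether raw Fst or the
$F_{ST}/(1-F_{ST})$ linearization enters the regression is a flag
(`linearize`), raw by default.

**IBD residual randomization.** The reinforcement-specific test: fit
pairwise genetic distance on geographic distance by OLS, take the
residuals, and compare the mean residual of pairs *involving* a
sympatric locality with the mean residual of allopatric–allopatric
pairs. The null permutes the sympatry labels across localities
(preserving counts); the regression is fixed under the null, so only
the pair classification changes. One-tailed, add-one. Hybrids flagged
by *either* classification rule are removed before any IBD analysis,
from all localities. The default 200 randomizations follow convention
but give p-value granularity 1/201; several thousand is advisable when
the result is near a threshold. Under label-exchangeable null zones
the measured size at $\alpha = 0.05$ is 0.046 (500 zones), and power
at a planted effect of twice the residual SD is 1.0 (100 zones, 999
reps) — both recomputed by the acceptance script.

# Acoustic analyses

Calls are corrected to a common 14 °C by subtracting the estimated
linear temperature effect, ${\rm corr} = {\rm obs} - b\,(T - 14)$ —
algebraically the only correction consistent with a linear model —
with slopes per population and variable, falling back on the pooled
within-species slope below 3 recordings. The correction is exactly
idempotent (re-estimated slopes of corrected values are zero).
Corrected values that fall non-positive (possible when a tiny
population's slope is wildly estimated) are dropped with a message
before log-transforms.

Hybrid index is regressed on the natural log of each corrected call
variable (log base is a convention choice; natural log throughout,
applied to call variables only). Model choice fits {PR}, {PN},
{PR+PN} and ranks by AIC and BIC, with a collinearity guard. The RCD
metric is the Euclidean distance between a sympatric region's mean
corrected (pulse rate, pulse number) and the species' pooled
allopatric baseline; the two variables have different units
(pulses/s vs pulses/call), so a z-standardized variant is available,
but the default is raw corrected means. Regional RCD means use all
recorded males, not only genotyped ones. Admixture-on-RCD regressions
are reported per species for all three admixture metrics; with 6–10
regions per species the null $r^2$ distribution is wide (a tested
property), so these fits are descriptive, not confirmatory.

# The synthetic zone generator

The generator emulates the statistical structure the analyses assume:

* **Parental pools** — per locus, an ancestral frequency vector from a
  symmetric Dirichlet(1), then species pools from
  Dirichlet$(\frac{1-F}{F}\,{\rm ancestral})$ (Balding–Nichols), so
  the single knob `f_div` sets expected Fst. Default 0.2, a realistic
  microsatellite-scale differentiation for congeners in secondary
  contact; 12 loci with 6–32 alleles on a tetranucleotide ladder.
* **Layout** — a planar transect: ten sympatric regions on the contact
  line with sample sizes matching the reference design (five large:
  386, 45, 87, 99, 119; five small: 10, 24, 7, 29, 26), allopatric
  localities north (species A, total 188) and south (species B, total
  80).
* **Classes** — per-region mixtures of pureA/pureB/F1/F2/BxA/BxB with
  F1 fractions 0.05–0.31 and advanced-generation fractions 0.06–0.47,
  spanning the range reported for real contact-zone regions.
  Genotypes are built from gametes: a pure parent contributes one
  allele per locus from its pool; an F1 gamete is species A or B with
  probability ½ per locus. Consequently a backcross's realized
  ancestry fraction is $(L + {\rm Bin}(L, \frac12))/2L$ — SD
  $1/(4\sqrt L)$ — which the tests assert in closed form.
* **Drift/IBD** — locality pools drift along the transect as a
  Dirichlet chain whose step concentration scales with inter-locality
  distance (`drift_scale`, per km; default $2 \times 10^{-4}$), so
  pairwise divergence accumulates with distance and Mantel r²
  increases in `drift_scale` (a tested monotonicity).
* **Maternal labels** — F1 mothers are species B with probability
  0.74, the pooled fraction in the reference design; pure individuals
  carry their own species; later generations are unknown.
* **Calls** — `call = intercept + slope·h + b_T (T − 14) + noise`,
  temperatures N(14, 3) °C, with additive displacement applied to
  sympatric males of the displaced species (species A in the six
  southern regions, species B weakly in the north). Noise SDs (4.3
  pulses/s, 1.1 pulses/call) are calibrated so the 75-male two-region
  benchmark regression of index on log pulse number lands near
  $r^2 \approx 0.77$ under the default class mixture.

What the generator does *not* emulate — and hence what green tests do
not establish about real data: genotyping artefacts (null alleles,
allelic dropout, stutter), linkage and departures from Hardy–Weinberg
within pools, mutation (no stepwise-mutation process behind the allele
sizes, so Rst's mutational rationale is exercised only structurally),
spatially continuous clines (classes are drawn per locality, not from
a mating model), and observation-level call structure (each simulated
male contributes exactly one recording). Locus-exclusion sensitivity
analyses (e.g. dropping high-null-frequency loci) are supported as a
configuration option (`subset_dataset()`), not as a null-allele
estimator.

# Reproducibility and numerical choices

Every stochastic function takes an integer seed, saves and restores
the caller's RNG state, and the pipeline derives per-stage streams
from one master seed (`derive_seed()`, kept below $2^{31}$), recorded
in the run log — identical master seeds give identical outputs, an
acceptance-tested property. Fragment binning uses left-closed
right-open intervals (a length exactly on an edge goes right); missing
data are GENEPOP zeros externally and `NA` internally; GENEPOP output
encodes `locality:individual` in the id field so write-then-read is
the identity; alleles above 999 are rejected rather than truncated.
Degenerate inputs fail loudly: all-missing individuals, empty
reference selectors, non-symmetric distance matrices, zero-variance
Mantel triangles, single-class sympatry labellings.

Test problem sizes are deliberately moderate — 500 replicates per
coverage class, 1,000 null pairs for test size, 500 null zones and 100
power zones for the IBD test, 1,000–20,000 Monte-Carlo replicates
where enumeration oracles exist — chosen so the full suite completes
in about a minute while leaving Monte-Carlo error well inside the
asserted bands.

# Interfaces

The package is organised as a library plus a numbered analysis
narrative (`analysis/01_simulate.R` … `06_acoustics.R`), each script a
thin driver over exported functions that prints what it found and
writes its tables under `results/`. There is deliberately no shell
wrapper binary: `run_pipeline()` (JSON-configurable, one master seed)
plays that role programmatically, and the numbered scripts are the
command-line surface. File formats: GENEPOP (2/3-digit), STRUCTURE
two-row, CSV metadata/maternal/call tables, labelled CSV distance
matrices.

# Known limitations

The hybrid-index model ignores linkage and genotyping error; the F1
window rule cannot distinguish F1s from some backcross genotypes (by
design, following the calibration-window practice); boundary CI
coverage is conservative (see above); the two-sided binary permutation
test is conservative at small effective information (exact analysis
above); Rst uses a pooled-pair weighting of within-locality variance,
one of several defensible conventions; and the acoustic module assumes
linear temperature dependence over the observed range.
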