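# hzadmix

Analysis toolkit for **reinforcement contact zones** between two
hybridizing species genotyped at codominant multi-allelic
(microsatellite-style) loci — the setting of the chorus frog
(*Pseudacris feriarum* × *P. nigrita*) contact zone along the
southeastern U.S. Fall Line, where selection against hybridization has
driven reproductive character displacement (RCD) in male advertisement
calls. The package is aimed at population geneticists and behavioral
ecologists who need to quantify how much hybridization occurs across a
contact zone, in which direction, and whether it relates to signal
displacement.

## What it computes

**Hybrid index.** Each diploid individual's ancestry proportion
*h* ∈ [0, 1] (1 = pure species A, 0 = pure species B) is estimated by
maximum likelihood from the allele-frequency distributions of two pooled
parental reference groups. Writing *p_A(l, a)* and *p_B(l, a)* for the
reference frequencies of allele *a* at locus *l*, the log-likelihood of
a genotype is

    logL(h) = Σ_copies log[ h · p_A(l, a) + (1 − h) · p_B(l, a) ]

maximized by a grid scan plus bounded refinement. A 95%
profile-likelihood interval is the set of *h* within
χ²₁(0.95)/2 = 1.92 log-units of the maximum, clamped to [0, 1].
Reference frequencies use add-α smoothing (α = 0.5 by default) over the
dataset's allele universe so private alleles cannot force *h* to a
boundary. Two classification rules follow the field's practice: an
individual is a **putative F1** if *h* falls in the window [0.25, 0.75]
calibrated from laboratory-bred F1s, and a **hybrid of undetermined
class** if its interval excludes both 0 and 1.

**Hypothesis tests.** Differences in hybrid proportion between region
pairs use a 100,000-replicate permutation test (individuals reassigned
between the pair without replacement) with a sequential Bonferroni
(Holm) correction; maternal-parent asymmetry among F1s uses the exact
two-sided binomial at null proportion ½; optimal cluster number from
replicate model log-probabilities uses the delta-K second-difference
statistic.

**Population structure.** Pairwise Weir–Cockerham θ (Fst) and Slatkin
Rst (allele-size variance) matrices, principal coordinates analysis by
Gower double-centering, Mantel tests of isolation by distance, and a
randomization test asking whether residual genetic divergence (after
regressing Fst on geographic distance) is elevated for locality pairs
involving sympatric (reinforced) localities.

**Acoustics.** Temperature correction of pulse rate and pulse number to
14 °C with population-specific slopes, regressions of hybrid index on
the log call variables with AIC/BIC model choice, a Euclidean RCD
displacement metric per sympatric region against the pooled allopatric
baseline, and regressions of regional admixture on RCD.

**Synthetic zone.** A seeded generator (`sim_zone()`) builds complete
contact-zone datasets — Balding–Nichols diverged parental pools,
per-region mixtures of pure/F1/F2/backcross individuals, transect drift
producing isolation by distance, asymmetric maternal parentage, and a
temperature-dependent call model with sympatric displacement — so every
stage of the pipeline is testable end to end with known truth.

## Worked example

```r
library(hzadmix)

zone <- sim_zone(sim_config(), seed = 1)      # 1,100 individuals, 12 loci
refs <- pool_references(zone$dataset)          # 188 A + 80 B allopatric
freqs <- estimate_frequencies(zone$dataset, refs)
hidx <- estimate_hybrid_index(zone$dataset, freqs)
summarize_region(hidx, dataset = zone$dataset)
```

yields (abridged):

```
   region   N prop_F1 prop_undetermined prop_advanced
       R2 386   0.611             0.723        0.1114
       R6  87   0.126             0.138        0.0115
       R8  99   0.576             0.667        0.0909
```

with accuracy against the generator's truth of
`mean |h_hat − h_true| = 0.0072` for pure individuals and mean
`h_hat = 0.512` among true F1s. The maternal tally of the same run
recovers the planted asymmetry (pooled fraction of species-B mothers
0.732 vs 0.74 planted), and the exact binomial on the published
maternal-parent counts for the Florida focal region gives
`exact_binomial_asymmetry(35, 74) = 2.37e-04`.

The full analysis narrative lives in `analysis/01_simulate.R` …
`analysis/06_acoustics.R`; each stage reads the previous stage's files
from `results/` and prints what it found. Run them in order:

```sh
Rscript analysis/01_simulate.R 1   # the argument is the master seed
Rscript analysis/02_hybrid_index.R
...
```

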