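---
title: "Estimating larval dispersal spread from isolation-by-distance genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating larval dispersal spread from isolation-by-distance genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibdkernel)
```

## The inference problem

Coastal reef organisms often live in habitat that is hundreds of
kilometres long but only a few kilometres wide. When sites are sampled
along such a quasi-one-dimensional habitat, drift–migration balance
produces isolation by distance (IBD): pairwise genetic differentiation
grows with alongshore separation. Rousset's result for a 1-D habitat is
that linearized differentiation, $F_{ST}/(1-F_{ST})$, increases
approximately linearly with distance, with slope

$$m = \frac{1}{4\,D_e\,\sigma^2},$$

where $D_e$ is the linear effective density (effective individuals per
km of coast) and $\sigma$ the standard deviation of the dispersal
kernel. Inverting gives the package's target quantity,
$\sigma = (4 D_e m)^{-1/2}$ (`sigma_point()`).

Two measured inputs therefore drive everything:

1. **the IBD slope $m$** — OLS regression of pairwise linearized
   $F_{ST}$ on pairwise alongshore distance, each unordered site pair
   one observation (`ibd_regression()`). Pairs are not independent; the
   slope standard error is the conventional OLS one and is interpreted
   accordingly.
2. **the linear effective density $D_e = N_e/L$** — from a
   single-sample estimate of the effective number of breeders $N_b$,
   adjusted to $N_e$ for overlapping generations, divided by the region
   length $L$ (km).

The assumptions inherited from IBD theory are a roughly constant $D_e$
along the region, several generations of stable dispersal, negligible
selection and mutation at the markers, and an approximately 1-D habitat
(site spacing greater than habitat width).

## Genetic statistics

**Pairwise $F_{ST}$.** `pairwise_fst()` implements the Weir–Cockerham
(1984) variance-component estimator $\theta$: for each locus and allele
the among-population (a), among-individual (b) and within-individual (c)
components are computed for the two-site comparison, and the multilocus
estimate is the ratio of sums $\sum a / \sum(a+b+c)$ over alleles and
loci. The ratio-of-sums convention keeps weakly polymorphic loci from
destabilising the estimate. Negative values are legitimate sampling
outcomes and are not truncated. Loci monomorphic across a pair carry no
information and are skipped; a pair with no usable locus is an error,
not a silent `NA`.

**Hardy–Weinberg screening.** `hwe_exact_test()` is a Monte-Carlo exact
probability test. The chain state is the genotype table with allele
counts fixed; one step swaps an allele copy between two random
individuals. Because the null conditional distribution of tables is
exactly that induced by uniformly random pairing of the $2n$ allele
copies, the swap chain is stationary for it and every proposal is
accepted. The p-value is the visited-mass of tables whose conditional
probability does not exceed the observed table's (probability-test
statistic, two-sided by construction). Defaults (20 batches × 5000
iterations after 10000 burn-in) mirror common practice for
microsatellite data; a between-batch standard error is attached.
Monomorphic locus×site combinations return `NA` ("not applicable"), not
an error.

## Effective number of breeders from linkage disequilibrium

`ld_nb()` is a single-sample LD estimator. For every locus pair, over
the individuals typed at both loci (pairwise-complete; their count is
$S$), and for every pair of retained alleles:

* Burrows' composite disequilibrium
  $\hat\Delta = \mathrm{cov}(X,Y)/2$, the sample covariance (with its
  built-in $S/(S-1)$) of the two allele-dosage vectors;
* $\hat r^2 = \hat\Delta^2/(\pi_A \pi_B)$ with
  $\pi_A = p_A(1-p_A) + D_A$, where $D_A$ is the within-locus
  homozygote excess. The $D_A$ term means no random-mating assumption is
  made *within* the sample — important when the sample pools sites.

Comparisons are averaged with weights $S$; the sampling expectation
$E[\hat r^2_S]$ ($1/S + 3.19/S^2$ for $S \ge 30$, else
$0.0018 + 0.907/S + 4.44/S^2$) is subtracted to leave the drift signal
$r^2{}'$, which the mating-model formula inverts to $\hat N_b$
(monogamy: $(2/3 + \sqrt{4/9 - 7.2 r^2{}'})/(2 r^2{}')$; random:
$(1/3 + \sqrt{1/9 - 2.76 r^2{}'})/(2 r^2{}')$). A non-positive
$r^2{}'$ means the drift signal is below sampling noise; the estimate
is then infinite — a real outcome at large $N_b$, not a failure. The
package's null calibration (inter-locus associations destroyed by
per-locus permutation of simulated data) reproduces the tabulated
$E[\hat r^2_S]$ to about $10^{-5}$, so the subtraction is unbiased for
this implementation.

Alleles with pooled frequency below `pcrit` (default 0.02, the standard
rule of thumb for samples above ~25) are screened out first; rare
alleles otherwise inflate $\hat r^2$.

The confidence interval is a delete-one-locus-pair jackknife on
$r^2{}'$ with normal-theory percentiles, pushed through the monotone
inversion. When the jackknife lower bound of $r^2{}'$ is non-positive
the upper $N_b$ bound is infinite; one-sided intervals of the form
$[N_{b,\mathrm{low}}, \infty)$ are the expected behaviour whenever true
$N_b$ is large relative to what $S$ and the locus count can resolve.
(Jackknifing over locus pairs rather than individuals was chosen
because the locus-pair contributions are the independent-ish units of
the estimator.)

## From $N_b$ to $\sigma$: the deterministic chain

`nb_ne_ratio()` evaluates the two-trait life-history regression
$N_b/N_e = 0.485 + 0.758\log_{10}(AL/\alpha)$ (adult lifespan and age
at maturity, years). `ne_from_nb()` applies the paired bias adjustment
$\hat N_b^{adj} = \hat N_b/(1.26 - 0.323\,N_b/N_e)$ and divides by the
ratio to get $N_e$; `linear_effective_density()` divides by $L$. At the
reference inputs ($AL = 7.05$, $\alpha = 1.68$) the ratio evaluates to
0.9572 — note that rounding to three decimals gives 0.957, and any
source quoting 0.958 for the same inputs has rounded upstream. The
default `ratio_sd = 0.186` is the prediction uncertainty used with that
regression; it is caller-overridable because it originates outside the
regression itself.

## Monte-Carlo uncertainty propagation

`propagate_sigma()` resamples each input and pushes every draw through
the same deterministic chain as the point estimate:

* $N_b/N_e \sim \mathcal N(\text{ratio SD as configured})$;
* $m \sim \mathcal N(\hat m, SE_m)$;
* $N_b$ from a chi-squared construction (below);
* draws with $m \le 0$, ratio $\le 0$, or adjustment denominator
  $\le 0$ are rejected and redrawn, preserving the draw count (at the
  reference configuration the rejection rate is ~0.06%, dominated by
  the slope's small negative tail); a rejection rate above 10% aborts,
  since it signals inconsistent inputs.

The interval is the 2.5th/97.5th percentile of the draws;
`sigma_point` is reported from the deterministic point parameters, not
the draw mean. `exceedance_fraction()` gives the mass of draws at or
above a threshold (≥ semantics; the choice is immaterial for continuous
draws).

**The chi-squared $N_b$ sampler.** An LD-based $N_b$ estimate with an
infinite upper bound carries strongly asymmetric uncertainty, and a
chi-squared family is the natural carrier. Two parameterizations share
one fitted degrees-of-freedom $\nu$:

* *reciprocal* (default): the estimated drift signal, which scales as
  $1/N_b$, is resampled as a mean-preserving scaled chi-squared, so
  $N_b^* = \hat N_b\,\nu/X$, $X \sim \chi^2_\nu$. This places the error
  on the quantity that is actually measured (a squared correlation) and
  yields the heavy upper $N_b$ tail an infinite upper bound implies.
* *scale*: $N_b^* = \hat N_b X/\nu$, chi-squared on the $N_b$ scale
  itself; kept as a sensitivity flag (`chi2_form = "scale"`).

`fit_chi2_nb_sampler()` solves $\chi^2_p(\nu)/\nu = N_{b,low}/\hat N_b$
for $\nu$ by monotone root-finding (tolerance $10^{-11}$). By default
the reported interval is treated as one-sided ($p = 0.05$), because an
interval whose upper endpoint is infinite is effectively a one-sided
bound; `ci_one_sided = FALSE` gives the two-sided (2.5%) reading. We
compared the four combinations against the downstream interval and
exceedance fractions published for the reference configuration: the
reciprocal/one-sided combination reproduces all four within a few
percent, while the scale form misses them severely (its upper $N_b$
tail is far too light, which both widens the upper $\sigma$ bound and
inflates the exceedance fractions). The default follows that
comparison; both flags remain available for sensitivity analysis.
Degenerate limit: as $N_{b,low} \to \hat N_b$, $\nu \to \infty$; above
$\nu = 10^6$ a point-mass sampler is used, so a zero-uncertainty
configuration returns an interval of width zero.

## Census density

`linear_census_density()` converts per-transect areal densities
(fish/km²) to fish per km of coastline: mean density × reef area ÷
region length. The 95% interval resamples whole transects (the survey
is the sampling unit, not the fish) with the BCa bootstrap
(`bca_interval()`): bias correction $z_0$ from the bootstrap
distribution, acceleration $a$ from the delete-one jackknife skewness,
adjusted percentiles via the standard formula, quantile type 6.
Constant data give a degenerate interval with a warning rather than an
error.

## Isolation by oceanography

Connectivity matrices are directed source→sink transport probabilities;
Mantel machinery needs symmetry, so `symmetrize_connectivity()` reduces
each unordered pair by the arithmetic mean of the two directions
(default; the least-assumption choice), with `max` and `forward`
variants flagged for sensitivity. `assign_release_sites()` maps each
sampling site to its nearest release cell by great-circle distance and
reports merge groups — sampling sites sharing a release cell should be
pooled with `merge_sites()` before comparison, since the ocean model
cannot tell them apart. `connectivity_vs_genetics()` runs the Mantel or
partial-Mantel test, or an OLS regression of linearized $F_{ST}$ on
connectivity over the pairs containing one focal site (used for a site
that visibly departs from the IBD trend; the designation is a
configuration choice, not an automated outlier detection).

Sign conventions: higher connectivity should mean lower genetic
distance, so the expected association is negative. With the one-tailed
"greater" default a genuine negative association appears as $r < 0$
with $p$ near 1; test `tail = "less"` for its complement.

## Permutation tests

`mantel()` correlates lower-triangle vectors and permutes rows and
columns of the first matrix simultaneously. When $n! - 1$ does not
exceed the requested permutation count, all relabelings are enumerated
and the p-value is exact: $p = \#\{r_{perm} \ge r_{obs}\}/n!$ over all
$n!$ relabelings (identity included), with $n! - 1$ reported as the
permutation count — this matches the minimum-permutation correction of
standard implementations (5039 for 7 sites, 719 for 6, 23 for 4). In
sampled mode $p = (\#\{r_{perm} \ge r_{obs}\} + 1)/(n_{perm}+1)$. Ties
are counted with a $10^{-12}$ tolerance so exact duplicates of the
observed statistic count as at least as extreme. Permutations are drawn
with R's Mersenne-Twister under the caller's seed, so results are
reproducible bit-for-bit per seed.

## The stepping-stone simulator

`simulate_stepping_stone()` is the package's ground-truth generator: a
compiled forward-time Wright–Fisher model of `n_demes` demes on a line,
`deme_size` diploids each, non-overlapping generations. Each
offspring's parent deme is drawn from a discretized Gaussian kernel of
spread `sigma` renormalized at the habitat edges (no offshore loss, so
density stays spatially constant — the IBD assumption); two distinct
parents are drawn uniformly within that deme (optional monogamous
pairing); each transmitted allele mutates ±1 repeat with probability
`mu`, reflecting at the repeat-code bounds (stepwise mutation, and
bounded so 3-digit Genepop coding cannot overflow). Allele states start
uniformly random within the bounds: high standing diversity that decays
toward drift–mutation balance keeps loci polymorphic after a practical
burn-in, whereas a monomorphic start would need on the order of $1/\mu$
generations to diversify.

Defaults describe the study conditions the package is tested against:
40 demes 5 km apart, 250 diploids per deme ($D_e = 50$/km), $\sigma=8$
km, 16 loci, $\mu = 5\times10^{-4}$, 2000 burn-in generations, seven
sampled sites of 20 fish spaced 25 km apart. An optional corridor
(`corridor_demes`, `corridor_strength`) short-circuits two demes with
extra migration, mimicking a jet-like current; `make_fixture_suite()`
writes a matching connectivity matrix with the same anomalous pair, so
the qualitative outlier-site pattern (excluding the corridor site
strengthens the IBD correlation) can be produced end to end.

What the simulator does *not* emulate: overlapping generations (hence
recovery tests use ratio = 1 and the life-history adjustment is
exercised on analytic examples), selection, uneven sampling effort,
genotyping error and null alleles, and 2-D habitat structure. Passing
recovery tests therefore show the chain is consistent under its own
assumptions — not that those assumptions hold for any particular reef.

## Parameter recovery and what it shows

The recovery test runs the full chain on ten simulated replicates at
the default conditions: pairwise $\theta$ → linearized regression →
`ld_nb` on the pooled **mid-region** sites → ratio-1 adjustment →
$D_e = N_e/L$ with $L$ the pooled span plus one deme spacing →
`sigma_point`. The $N_b$ pool is the three central sampled sites. This
is a deliberate choice: pooling the whole transect raises $S$ but also
raises the true $N$ of the pooled region (~7800 diploids), pushing the
drift signal $\approx 1/(3N)$ below the $\hat r^2$ sampling noise — in
our measurements the wide-pool estimate came back infinite in roughly
40% of replicates, which is the same phenomenon as a real study
obtaining an unbounded upper $N_b$. The local pool keeps the target
$N$ small enough to resolve. The acceptance thresholds are a factor of
two on $\sigma$ in at least 8 of 10 replicates and a factor of two on
the median slope; simulation problem sizes throughout the test suite
(deme counts, burn-ins, replicate counts) were chosen to keep the whole
suite in the few-minute range while leaving the tested invariants
well-resolved.

## Numerical details and edge cases

* Half-missing genotype calls `(0, x)` are rejected at construction;
  only `(0, 0)` is missing. Allele pairs are stored sorted, making
  datasets comparable as multisets (`gt_equal()` ignores individual
  labels, which are free text in Genepop files).
* $F_{ST} = 1$ linearizes to infinity and errors; $\theta$ of a pair
  with no shared polymorphic locus errors (`ibd_undefined_pair`).
* `uniroot` tolerances: chi-squared fit $10^{-11}$; jackknife CI uses
  $z_{0.975}$ normal percentiles.
* BCa with constant data returns a degenerate interval and warns;
  bootstrap quantiles use type 6 throughout.
* All stochastic functions take a `seed` and are bit-reproducible; the
  pipeline echoes its fully materialized configuration into the report
  so no default is silent.

## Limitations

The OLS slope SE underestimates uncertainty because site pairs share
sites; the Monte-Carlo interval inherits that optimism. The $N_b$
chi-squared construction is a modelling choice over an under-determined
object (only a point estimate and one finite bound are available); both
parameterizations are shipped, and conclusions that depend on the
difference should be treated with caution. Mantel tests have known low
power with few sites — with 4 sites only 23 distinct relabelings
exist, so the smallest attainable p-value is 1/24. None of the genetic
machinery models null alleles or scoring error; loci failing
Hardy–Weinberg screening should be inspected before trusting
downstream estimates.
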