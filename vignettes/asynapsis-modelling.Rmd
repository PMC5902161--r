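---
title: "Modelling meiotic asynapsis from symmetric DSB hotspots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling meiotic asynapsis from symmetric DSB hotspots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synapsim)
```

## The biological problem

Male hybrids between the house-mouse subspecies *Mus musculus musculus* (PWD)
and *M. m. domesticus* (C57BL/6) are sterile: at the pachytene stage of
meiosis many autosome pairs fail to form a synaptonemal complex. A leading
mechanistic account ties this failure to PRDM9-determined recombination
hotspots. In the hybrid, most hotspots are *asymmetric* — active on only one
homolog — and double-strand breaks (DSBs) in asymmetric hotspots repair poorly
against the other homolog. Synapsis of a chromosome pair then depends on it
receiving enough DSBs in *symmetric* hotspots. Two experimental dials probe
this model: per-chromosome asynapsis rates in F1 hybrids, and crosses that
introduce random stretches of *consubspecific* (PWD/PWD homozygous) sequence —
which by construction cannot carry asymmetric hotspots — onto otherwise
heterosubspecific chromosome pairs.

synapsim implements the full quantitative chain: a per-chromosome simulator of
symmetric-DSB counts, inference of how many symmetric DSBs suffice for
synapsis, a change-point regression for the minimal rescuing length of
consubspecific sequence, random-intercept logistic models of scored asynapsis
counts, multiplicative full-synapsis expectations with fertility summaries,
and a synthetic-data generator that emulates the scoring tables such studies
produce.

## The symmetric-DSB model

For one meiotic cell the simulator draws

1. a total autosomal DSB count `T` from a normal distribution with mean 250
   and standard deviation 20, rounded to the nearest integer and redrawn if
   negative (the truncation probability is negligible at these values);
2. a multinomial allocation of the `T` breaks across autosomes with
   probabilities equal to each autosome's share of SPO11-oligo counts, the
   standard proxy for relative DSB density (a deterministic proportional
   allocation is available as an option);
3. for each break on a chromosome, a uniform position; breaks inside
   consubspecific intervals are always symmetric, breaks elsewhere are
   symmetric with probability `p_sym = 0.28`, the estimated fraction of
   symmetric hotspots in the hybrid.

Because positions only matter through interval membership, the default code
path collapses the uniform draw to a Bernoulli membership test with
probability `f_homo`, the consubspecific fraction of the chromosome; the
explicit-position path is retained behind `explicit_positions = TRUE` for
future position-dependent extensions, and the two paths are checked against
each other in the test suite.

The same model admits a closed form, which the package uses as an independent
oracle: given the total `T`, a chromosome with allocation share `q` receives a
`Binomial(T, q)` number of breaks, each symmetric with probability
`pi = f_homo + (1 - f_homo) * p_sym`; by binomial thinning the symmetric count
is `Binomial(T, q * pi)`, and the pmf is the exact finite mixture over the
rounded truncated-normal distribution of `T`. Monte-Carlo and analytic
cumulative probabilities agree within Monte-Carlo error across a grid of
`(f_homo, p_sym)` values — this is the package's first acceptance property.

```{r simulator, eval = FALSE}
K <- generate_karyotype(19, seed = 1)
params <- dsb_sim_params(n_sims = 100000, seed = 1)
dists <- simulate_symmetric_pmf(K, NULL, params)
prob_fewer_than_k(dists[["19"]], 2)  # P(< 2 symmetric DSBs) on Chr 19
```

## How many symmetric DSBs suffice?

If asynapsis strikes exactly those chromosomes that receive fewer than `k*`
symmetric DSBs, then regressing per-chromosome asynapsis rates on the
simulated `P(< k)` gives slope 1 at `k = k*`, slopes above 1 for smaller `k`
(the predictor underestimates asynapsis) and below 1 for larger `k`.
`infer_threshold_k()` runs one through-origin regression per candidate `k`
and selects the slope nearest 1 on the log scale, ties toward smaller `k`.
The regression passes through the origin because the mechanistic reading
forces it — a chromosome with ample symmetric DSBs has no model-implied
asynapsis — and because the published analysis reports slopes only; an
intercept can be switched on for sensitivity checks.

## The change-point model for consubspecific length

In crosses carrying recombinant chromosomes, the asynapsis rate of a
chromosome declines roughly linearly with the length of its consubspecific
interval until a change point `psi`, beyond which it stays at a low floor.
`fit_segmented()` fits the continuous two-part model

```
rate = b0_g + b1_g * x + b2_g * (x - psi)+
```

by weighted least squares, with the breakpoint `psi` shared across
chromosomes and profiled on a grid (default 0.25 Mb) over the central 90% of
the predictor range, then refined by iterative linearization: the design is
augmented with a gap column `-I(x > psi) * b2_g`, whose fitted coefficient
estimates the shift to the optimal `psi` and vanishes at convergence. A
non-convergent refinement falls back to the best grid point with a warning.

Three design choices deserve comment.

* **Per-chromosome hinge coefficients.** When chromosomes have their own
  below-breakpoint slopes, they must also have their own slope changes: all
  chromosomes flatten to the same floor, so a steeper decline implies a larger
  slope change at `psi`. Forcing a single shared slope-change coefficient is
  misspecified and, in simulation, biased the breakpoint estimate about 2 Mb
  low even on noiseless data; the per-group hinge removes the bias. Only
  `psi` itself is shared.
* **Weights.** The response is the per-male, per-chromosome proportion on the
  natural scale (the published analysis plots and models rates, not logits),
  weighted by the number of pachynemas scored (default), reflecting binomial
  heteroscedasticity. Unweighted fitting is available.
* **Confidence interval.** The bootstrap resamples *males*, not observations,
  because observations within a male share a random intercept. The default
  interval is the symmetric bootstrap-standard-error interval. We initially
  used percentile intervals, but the breakpoint estimator carries a small
  downward bias under realistic per-animal noise and the percentile interval
  inherits that bias twice over: in coverage simulations at the study's scale
  it covered the true change point in only ~88% of replicates, versus ~92-95%
  for the symmetric interval. Percentile and delta-method intervals remain
  available through `segmented_options()`.

Chromosome-specific slope heterogeneity is tested by the extra-sum-of-squares
F test between the per-chromosome and pooled fits (`slope_equality_test()`),
with one degree of freedom subtracted for the estimated breakpoint. A rate is
classified as rescued when it falls strictly below the 5% baseline
(`classify_synapsis_rescue()`).

## Mixed-effects logistic models

Asynapsis counts are grouped binomials per male and chromosome (equivalent
to, and far cheaper than, per-pachynema binary coding). `fit_mixed_logit()`
maximises the exact marginal likelihood of a logit model with a normal random
intercept per animal. Because the random structure is intercept-only, the
marginal likelihood factors into one-dimensional integrals per animal, which
are evaluated by adaptive Gauss-Hermite quadrature: the integrand's mode is
found by Newton steps (it is strictly concave), the quadrature is centred and
scaled there, and 15 nodes are used by default (`n_quad = 1` gives the
Laplace approximation). Estimation is plain maximum likelihood — not a
REML-like variant — so likelihood-ratio comparisons between nested
fixed-effect designs (`lrt_compare()`) are valid. The test suite validates
the quadrature against dense numeric integration (agreement to 1e-6 on a
small fixture), against ordinary logistic regression when the intercept
standard deviation is held at zero, and against an independent GLMM
implementation. Random slopes and crossed random effects are out of scope.

## Likelihood-ratio binomial intervals

Per-male, per-chromosome asynapsis rates are often exactly zero, where Wald
intervals collapse. `lr_ci_binomial()` inverts the likelihood-ratio test
instead: the interval is the set of proportions whose deviance against the
maximum-likelihood estimate stays below the chi-square cutoff, giving a zero
lower bound and a positive upper bound at zero counts. Coverage of such
intervals oscillates with the binomial's discreteness: at `n = 50` the exact
coverage is 94.2% at `p = 0.1` and 95.7% at `p = 0.3`, but 98.2% at
`p = 0.02`, because the interval happens to cover 0.02 for every `x <= 3`.
Pooled across these three proportions the coverage is ~96%, within the
93-97% band the package asserts; per-proportion bands would be unattainable
at small `np` for any interval construction.

## Trans effects and multiplicative expectations

If chromosomes synapsed independently, the fraction of pachynemas with all
autosomes synapsed would be the product of per-chromosome synapsis rates
(`expected_full_synapsis()`), and a male's expected fully synapsed fraction
combines his own scored chromosomes with F1 baselines for the rest
(`expected_full_synapsis_per_male()`). Departures from these products — and
the drop in asynapsis of *nonrecombinant* chromosomes when other chromosomes
in the same nucleus are rescued — indicate a trans effect.
`trans_effect_loglog()` quantifies it as an elasticity: ordinary least
squares of log focal asynapsis rate on log predicted synapsis of the other
scored chromosomes (their per-male product, consistent with the
multiplication convention). Zero focal rates are replaced by
`(x + 0.5) / (n + 1)` (an Anscombe-type correction; exclusion is available —
the choice is the package's, as the source analyses do not state one).
Per-chromosome slopes are pooled by inverse-variance weighting, and the
summary `100 * (1 - 1.1^slope)` is the percent change in focal asynapsis per
10% rise in the others' predicted synapsis. `predict_rescue_fraction()`
projects the fully synapsed fraction if a chosen chromosome set were fully
rescued, and `sperm_presence_vs_synapsis()` compares the per-male probability
that all scored chromosomes synapse between sperm-positive and aspermic males
(Mann-Whitney), around the 0.7 rule-of-thumb threshold.

## The synthetic-data generator

No raw scoring tables ship with the package; `generate_cross_dataset()`
produces datasets with the statistical structure the analyses assume, at the
scale of the motivating study, and a truth record of every latent quantity.
Defaults (all overridable in `generator_config()`):

* a 19-autosome karyotype, lengths declining ~195 to ~61 Mb, SPO11 shares
  proportional to length with ±20% lognormal perturbation;
* 40 F1 males scored on all autosomes; three 2-chromosome crosses (pairs
  5+12, 7+15, 17+18; 61 males, 122 scored chromosomes); a 4-chromosome cross
  (15, 16, 18, 19) with 87 males carrying fertility records, 18 of them
  scored cytologically — sample sizes mirroring the study design;
* F1 asynapsis rates rising from 2.6% (Chr 1) to 42.2% (Chr 19), the observed
  range;
* a true change point at 27 Mb with per-chromosome slopes reaching a 2% floor
  exactly at the change point (at the steep end, -1.2% per Mb);
* per-animal logit-scale intercepts with standard deviation 0.3 and a
  trans-effect coupling `gamma = 1` (a logit shift proportional to how far
  the mean true asynapsis of the other scored chromosomes falls below its F1
  value) — moderate values chosen once as realistic for cytological scoring
  data, since the source analyses do not report them;
* ~100 pachynemas scored per male and chromosome (Poisson, floored at 20),
  matching ~12,000 pachynemas per cross arm;
* transmitted consomic chromosomes that are whole consubspecific (20%),
  nonrecombinant heterosubspecific (20%), double-crossover interstitial
  (10%), or single-crossover proximal/distal segments, with marker
  uncertainty simulated by widening each true breakpoint outward by up to
  1.5 Mb per side into (min, max) bound columns;
* aspermia exactly when the probability that all scored chromosomes synapse
  falls below 0.7, with positive counts lognormal and scaled by that
  probability.

The generator reproduces the features the analyses rely on — binomial
scoring noise, animal-level overdispersion, marker-bounded interval
coordinates, the piecewise-linear length effect, coupling between
chromosomes, and a fertility readout tied to full synapsis. It does not
emulate position-dependent rescue efficiency, chromosome-specific deviations
from the SPO11 length trend beyond lognormal noise, apoptosis dynamics, or
scoring misclassification; passing tests therefore validate the estimators
under the stated stochastic structure, not those additional features of real
cytological data.

## Validation scale and pre-registered tolerances

The test suite fixes its problem sizes as package choices: simulator checks
run at 100,000 cells against the analytic oracle (3 Monte-Carlo standard
errors, cumulative probabilities up to k = 5); threshold self-consistency
requires the selected k to equal the generating k with slope within 5% of 1;
change-point recovery runs 200 replicate datasets at the 2-chromosome-cross
scale (122 observations) and requires 95% CI coverage of the true 27 Mb in at
least 90% of replicates with a median absolute error of at most 4 Mb;
quadrature must match dense numeric integration to 1e-6; LR-interval coverage
pooled across p in {0.02, 0.1, 0.3} must fall in 93-97% over 2000 draws; and
the multiplicative identities must hold exactly. Latent-parameter recovery
(sigma_u, gamma) is asserted within 30-40% relative error at the study's
sample sizes.

## Numerical notes and limitations

Breakpoint profiling excludes the outer 5% of predictor values so both
segments stay identifiable; ties in the threshold scan resolve to the
smaller k; the Spearman p-value uses exact permutation enumeration up to
n = 9 and the t approximation above; Mann-Whitney switches from exact
enumeration to the tie-corrected normal approximation when the smaller sample
exceeds 8 or ties occur; separation in the mixed logit is flagged when
coefficients exceed 12 on the log-odds scale. The segmented model is linear
on the rate scale — no logit-link segmented variant is provided — and only
single-breakpoint models are supported. The mixed logit hard-codes the
random-intercept-only structure. No multiple-testing correction is applied
anywhere, matching the analyses the package mirrors.
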