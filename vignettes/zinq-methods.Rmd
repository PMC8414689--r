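---
title: "Zero-inflated quantile rank-score testing: model, algorithm, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zero-inflated quantile rank-score testing: model, algorithm, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zinq)
```

## The problem

Microbiome count data are zero-inflated (a taxon is absent, or present but
unsequenced), over-dispersed, compositional, and frequently heavy-tailed.
Parametric differential-abundance models (zero-inflated Poisson or negative
binomial, zero-inflated beta or log-normal, tobit) buy power by assuming a
distributional family that real taxa routinely violate, which shows up as
inflated type I error. Classical nonparametric tests (Wilcoxon,
Kolmogorov-Smirnov) control size but cannot adjust for covariates and only
see location or gross distributional differences.

This package tests, taxon by taxon, whether the normalized abundance `Y` of
a taxon is associated with a clinical variable `C` (binary or
quantitative), adjusting for covariates `Z` (intercept included), without
assuming a distributional family for the non-zero part.

## The two-part quantile model

Presence/absence and the positive part are modeled separately:

* **Zero part.** `logit P(Y > 0 | X) = Z' zeta + gamma C`.
* **Positive part.** For each quantile level `tau` in (0,1),
  `Q_Y(tau | X, Y > 0) = Z' alpha(tau) + beta(tau) C`.

The global null is `gamma = 0` and `beta(tau) = 0` for all `tau`: the
variable affects neither the chance the taxon is present nor any quantile
of its abundance when present. Quantile coefficients are estimated by
minimizing the check loss `rho_tau(u) = u (tau - I(u < 0))` over the
non-zero observations. For discrete outcomes (raw or rarefied counts) a
uniform `U(0,1)` perturbation `W = Y + U` breaks ties; this is the standard
device for quantile regression on counts. The zero/non-zero status is
always taken from the raw outcome, never from the perturbed one.

## The testing procedure

1. **Zero part.** Any valid test of `gamma = 0` in the logistic model. The
   default is the likelihood-ratio test; if the IRLS fit fails to converge
   or separates, the code falls back to Rao's score test, which needs only
   the null-model fit and is defined under separation.
2. **Quantile part.** At each grid level `tau`, a rank-score test of
   `beta(tau) = 0` built for zero inflation. With `C~ = C I(Y > 0)` and
   `Z~ = Z I(Y > 0)`, the residualized variable
   `C* = (I - Z~ (Z~'Z~)^{-1} Z~') C~` carries the variable's information
   net of the covariates. The score is
   `S_tau = n^{-1/2} sum_i psi_tau(W_i - Z_i' alpha_hat(tau)) I(Y_i > 0) C*_i`,
   `psi_tau(u) = tau - I(u < 0)`, with `alpha_hat(tau)` the null
   (covariate-only) quantile fit on the non-zero subset. The statistic
   `T_tau = S_tau / sqrt(n^{-1} tau (1 - tau) C*'C*)` is asymptotically
   standard normal. Crucially the variance uses the *zero-truncated*
   `C*`: since `E(C~^2) = E(C^2 P(Y > 0 | X))`, it absorbs the sampling
   uncertainty of which observations land in the non-zero subset —
   the correction a standard rank-score test applied to the truncated data
   would miss.
3. **Combination.** The logistic p-value and the `K` quantile p-values are
   combined either by
   * the **weighted Cauchy test**:
     `T = r tan((0.5 - p_L) pi) + sum_k w_k tan((0.5 - p_k) pi)`, with `r`
     the observed zero proportion and
     `w_k = (1 - r) g_k / sum(g)`, `g_k = tau_k` for `tau_k <= 0.5` and
     `1 - tau_k` above the median, so central quantiles weigh more and all
     weights total one; `T` is standard Cauchy under the null; or
   * the **MinP procedure**: the statistic is the smallest marginal
     p-value; its own p-value is
     `1 - (1 - T_minP) P(all quantile p's > T_minP | H0)`, using the
     asymptotic independence of the zero and quantile parts. The joint
     probability is estimated by drawing score vectors from the mean-zero
     multivariate normal with covariance
     `Sigma_kl = n^{-1} (min(tau_k, tau_l) - tau_k tau_l) C*'C*` (a
     Brownian-bridge kernel, hence positive semidefinite by construction).

## Tunable parameters

* **Quantile grid** — default `0.1, 0.25, 0.5, 0.75, 0.9` for continuous
  outcomes with at least 30 non-zero observations; `0.25, 0.5, 0.75` for
  discrete outcomes (the perturbation adds noise at extreme quantiles) or
  fewer non-zeros. Below 15 non-zero observations (or fewer than `p + 2`)
  the quantile part is refused and the taxon flagged `low_prevalence`: fits
  at quantiles far from the median are unstable there, and the combined
  test would inherit that instability. A user grid is honored whenever it
  has fewer levels than the number of non-zero measurements — more levels
  than observations makes the marginal results so dependent that false
  positives are uncontrolled.
* **MinP draws** — `B = 10000` by default; the Monte-Carlo standard error
  of the combined p-value is reported alongside it.
* **Normalization parameters** — rarefaction depth (default: the minimum
  library size); CSS quantile (0.5) and scale (1000); CLR pseudocount
  (0.5). The CSS definition used here is the fixed-quantile one: the
  scaling factor is the sum of a sample's counts at or below the
  empirical `quantile`-level of its positive counts, where the empirical
  quantile is the order statistic `ceiling(level * n_positive)` (no
  interpolation). An adaptive data-driven quantile choice is out of scope.

## Sidedness and degeneracy conventions

* Marginal quantile p-values are **two-sided** normal p-values: the
  alternative of interest is association in either direction. The MinP
  resampling therefore counts draws whose two-sided p-values all exceed
  the observed minimum; this p-value-scale reading is the one consistent
  with using "the smallest p-value" as the statistic.
* `psi_tau(0) = tau`: the indicator in `psi_tau(u) = tau - I(u < 0)` is
  taken as 0 at `u = 0`. Exact zero residuals do occur — the quantile fit
  interpolates `p` observations — so the convention is pinned by tests.
* **All-zero taxa** are flagged and not tested. **Zero-free taxa** drop
  the logistic part; its Cauchy weight is `r = 0` anyway, and MinP runs
  over the quantile p-values alone. A variable constant on the non-zero
  subset leaves the quantile part undefined (`constant_covariate` flag).
* Unavailable components in the Cauchy combination are dropped and the
  remaining weights renormalized to sum to one, which preserves the
  standard-Cauchy null law of the statistic.
* For p-values below `1e-15` the tangent is replaced by its asymptote
  `1/(p pi)` to avoid overflow; p-values are capped at `1 - 1e-15`.

## The quantile fit

The null coefficient `alpha_hat(tau)` minimizes the check loss on the
non-zero subset. The fit is an exact linear program solved by an
exterior-point simplex over bases of `p` interpolated observations: dual
multipliers `lambda_j` must lie in `[-tau, 1-tau]` at an optimum; a
violated multiplier yields an edge direction, and a weighted-quantile line
search over residual breakpoints pivots one observation into the basis.
Determinism conventions, all pinned by tests:

* intercept-only designs use the closed form — the lower-vertex sample
  quantile (when the minimizing set is an interval `[w_(k), w_(k+1)]`, its
  lower endpoint is returned). The rank score can depend on this choice,
  so determinism was preferred over convention-neutrality;
* the initial basis is the first `p` linearly independent rows; the line
  search stops at the first breakpoint where the directional derivative
  turns non-negative;
* tied responses create degenerate vertices where the multiplier test is
  unreliable; they are resolved by re-solving with a fixed infinitesimal
  general-position jitter (a deterministic Park-Miller sequence, far above
  the residual tolerance, negligible against the data scale) and refitting
  the resulting basis on the original data. Inside the testing pipeline
  ties never arise — discrete outcomes are perturbed — but normalized
  values (e.g. equal proportions under TSS) can tie.

The solver is validated against brute-force enumeration of all
`choose(m, p)` interpolating bases on small problems, including heavily
tied ones.

## What the generators emulate

* **Empirical-distribution mixtures** re-create the two-group,
  single-taxon design: each group draws from its own empirical
  distribution, and signal strength is diluted by mixing the two
  distributions (`mix = 1` full effect, `0.5` null). The packaged
  reference pair is fully synthetic: a zero-inflated log-normal taxon
  whose "affected" group is both more prevalent (0.75 vs 0.60) and
  right-shifted (0.5 on the log scale) — a realistic moderate effect for a
  common taxon.
* **Two-part generators** simulate a whole count table from fitted (or
  designed) logistic and quantile-coefficient functions on the fine grid
  `tau = 0.01, ..., 0.99`: presence from the logistic part; a positive
  count by inverse-CDF sampling — evaluate the conditional quantile
  function at the sample's covariates, draw `U ~ U(0,1)`, interpolate
  linearly between grid levels, round to the nearest integer. Two choices
  the procedure needs but plain coefficient fits do not give:
  * *monotone rearrangement*: raw per-`tau` fits can cross, making the
    inverse CDF ill-defined; the 99 evaluated quantiles are sorted per
    sample before sampling, which preserves every marginal quantile;
  * *a floor of one*: rounding can produce a non-positive count for a
    sample the logistic part declared present, which would contradict the
    fitted zero model; such draws are clamped to 1 and counted
    (`clamp_count` attribute).
* **Dirichlet-multinomial generators** favor mean-based analyses: a
  composition per sample from `Dirichlet(alpha)`, counts multinomially at
  the sample's library size. Fitting is by the Weir-Hill method of
  moments — stable and closed-form, which is all a generator needs.
* **Covariate resampling and joint permutation** build null populations:
  resampling each covariate independently preserves marginals and breaks
  everything else; permuting all covariate rows jointly preserves the
  covariate dependence structure while severing the covariate-outcome
  link.
* The **benchmark catalogue** (`synthetic_benchmark_params`) replaces
  restricted cohort-fitted parameters with a deterministic library
  spanning prevalence 10-95%, log-normal and heavy-tailed positive parts,
  and four effect shapes: pure location shift, crossing (the effect
  changes sign across quantiles), spindle (effect concentrated in upper
  quantiles), and null.

What passing tests on these generators do **not** show: robustness to the
taxon-taxon correlation of real tables (taxa are generated independently
given the covariates, except for the compositional coupling in the
Dirichlet-multinomial design), to library-size confounding with the
variable of interest, or to batch structure. The generators match the
marginal, zero-inflation, and covariate-effect structure of real data, not
its full joint law.

## Simulation sizes in the shipped suites

The acceptance suite uses 5000 replicates for the size studies (binomial
Monte-Carlo standard error 0.003 at the 0.05 level), 1000 replicates per
mixture setting for the power ordering, and 500 replicates for the
heterogeneity comparison; rejection-rate reports always carry their
Monte-Carlo standard errors so results are judged against sampling error.
These sizes were chosen so the whole suite runs in minutes on one core
while keeping the standard errors an order of magnitude below the effects
being checked.

## Known limitations

* No estimation or confidence intervals for `beta(tau)` under the
  alternative; the package tests.
* When library size is confounded with the variable of interest, no
  zero-aware method can say whether zero-proportion differences are
  biological or depth artifacts; treating abundance quantitatively (or
  adding library size as a covariate) is then more honest.
* No omnibus combination across normalizations; the per-taxon p-values
  from different normalizations could be combined with the same Cauchy or
  MinP machinery, but that is left out of scope.
* The heterogeneity coefficient of variation mixes the logistic
  coefficient (log-odds units) with quantile coefficients (abundance
  units); it is a diagnostic for ranking taxa, not a calibrated effect
  size.
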