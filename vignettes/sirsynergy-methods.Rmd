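---
title: "Shape-constrained synergy testing: model, inference and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-constrained synergy testing: model, inference and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(sirsynergy)
```

## The problem

A drug-combination experiment measures cell viability $Y_{ij} \in [0,1]$ on
an $I \times J$ grid of increasing concentrations of two drugs. Classical
synergy scores (Bliss, HSA, Loewe, ZIP) each posit a different pointwise
"no interaction" reference and summarize the excess over it, but they provide
no matrix-level hypothesis test, can disagree with each other on the same
data, and the parametric ones fail outright when marginal dose-response
curves do not converge. This package instead asks a single statistical
question per matrix: *does the dose-response surface deviate from a
monotone-additive null anywhere on the grid?* — and answers it with a
calibrated-by-construction resampling test plus interpretable effect-size
surfaces.

## Model

Responses are mapped to an unconstrained scale, by default
$Z_{ij} = \mathrm{logit}\,Y_{ij}$ after clamping $Y$ to
$[\varepsilon, 1-\varepsilon]$, $\varepsilon = 10^{-6}$. The logit is the
principled default for bounded viability: it stabilizes variance near 0 and
1 and makes additivity mean equal log-odds increments. Identity, asinh and
log transforms are available as sensitivity checks
(`transform_spec()`); note the null hypothesis itself is defined on the
chosen scale, so results legitimately depend on it.

Two nested shape-constrained classes are fitted by weighted least squares:

* the **monotone cone** $\mathcal{M}$: surfaces non-increasing along every
  row and column (more drug never increases viability) — the flexible
  alternative $\hat\theta^{\mathrm{iso}}$, a 2D isotonic regression;
* the **monotone-additive class**
  $\mathcal{A} \subset \mathcal{M}$:
  $\theta_{ij} = \alpha + u_i + v_j$ with $u, v$ non-increasing and
  $u_1 = v_1 = 0$ for identifiability — the "no interaction" null
  $\hat\theta^{\mathrm{add}}$, in which each drug contributes its own
  monotone main effect.

Their difference $\delta_{ij} = \hat\theta^{\mathrm{iso}}_{ij} -
\hat\theta^{\mathrm{add}}_{ij}$ is the **interaction surface**; $\delta < 0$
means the combination lowers viability below the additive expectation
(synergy). On the viability scale the effect size is
$S_{ij} = \mathrm{logit}^{-1}\hat\theta^{\mathrm{add}}_{ij} -
\mathrm{logit}^{-1}\hat\theta^{\mathrm{iso}}_{ij}$ (positive = synergy).
Because $\mathcal{A}$ is nested in $\mathcal{M}$, $\delta$ reflects genuine
departure from additivity, not a structural mismatch between reference
models. The global strength is the interaction energy
$S^2 = \sum_{ij} w_{ij}\delta_{ij}^2$, and the test statistic is its
grid-normalized form $T = S^2 / \sum_{ij} w_{ij}$.

## Weights

With within-well replicates, $w_{ij} = m_{ij} / \max(s^2_{ij}, \tau)$
(inverse-variance with floor $\tau = 10^{-6}$ against degenerate sample
variances). Wells with one replicate, or whole matrices without replicate
variance, fall back to the uniform floor weight $1/\tau$. Positive weights
are Winsorized at the 99th percentile within the matrix so a few
near-zero-variance wells cannot dominate; Winsorization is per matrix and
uses all positive weights (the alternative — capping only replicate-derived
weights — changes nothing in the uniform case and needlessly special-cases
the mixed one). $T$ is invariant to rescaling all weights, so the floor's
absolute magnitude is immaterial.

## Solvers and numerical choices

Both projections are convex quadratic programs with monotonicity
constraints; both are solved by compiled exact-block methods rather than a
generic QP solver:

* `fit_isotonic_2d()` uses **Dykstra's alternating projections** between the
  row-monotone and column-monotone half-cones, each half-projection an exact
  weighted pool-adjacent-violators (PAVA) pass in the same weighted inner
  product. The iterates converge to the unique projection onto the
  intersection; iteration stops when successive surfaces differ by less than
  `tol/100` in sup norm (default `tol = 1e-8`), and non-convergence raises
  an error rather than returning an infeasible surface.
* `fit_monotone_additive()` uses **block coordinate descent** on $(u, v)$
  with exact weighted PAVA block updates; with two blocks and a smooth
  convex objective over a product of closed convex cones this converges to
  the global minimum. The free additive constant rides along in $u$ during
  iteration and is normalized out ($u_1 = v_1 = 0$) afterwards.

The test suite verifies both solvers against independent oracles: the
max–min formula for 1D isotonic regression on random slices, and exhaustive
active-set (KKT) enumeration of the full QP on random $3\times3$ grids, to
$10^{-6}$.

Missing wells enter the isotonic projection as effectively free variables
(vanishing weight, $10^{-10}\times$ the mean observed weight, keeping the
projection single-valued); their fitted values are then resolved
deterministically to the midpoint of the tightest monotone envelope implied
by the observed fitted values, computed by two monotone sweeps. On a
noiseless additive surface with uniform dose steps this midpoint rule
recovers a removed interior well exactly, which the tests assert. Wells
whose envelope is one-sided (missing edge rows/columns beyond them) use the
available bound and trigger a warning. Grids smaller than $2\times2$ are
rejected: interaction is undefined without two varying doses.

## Effective degrees of freedom and residual inflation

Monotone regression pools adjacent dose levels that violate monotonicity,
so its effective parameter count is data-dependent. The null fit's df is
approximated by counting distinct fitted levels:
$\mathrm{df} = \#\mathrm{levels}(\hat u) + \#\mathrm{levels}(\hat v) - 1$,
merging levels closer than $10^{-6}$ on the logit scale (numerical solvers
return near-ties, not exact ties) and subtracting the shared intercept
level; a $5\times5$ grid with fully distinct marginals gives
$\mathrm{df} = 9$ on $n = 25$ cells. Residuals of the null fit are shrunk
because the fit absorbed noise, so before resampling they are inflated by
$\sqrt{n_{\mathrm{eff}} / (n_{\mathrm{eff}} - \mathrm{df})}$ — the error
*variance* is inflated by $n_{\mathrm{eff}}/(n_{\mathrm{eff}} -
\mathrm{df})$, the analogue of the $n/(n-p)$ correction in linear
regression ($25/16 = 1.5625$ in the example above). The printed ratio is
read as a variance ratio, hence the square-root multiplier on residuals.
The test aborts with a clear error when
$n_{\mathrm{eff}} \le \mathrm{df}$ (grid too small or too sparse).

## The wild bootstrap test

`wild_bootstrap_test()` fits the null, inflates its residuals, and builds
$B$ pseudo-datasets $Z^\star = \hat\theta^{\mathrm{add}} + \xi \odot
\tilde r$ with independent Rademacher signs $\xi_{ij} \in \{-1, +1\}$ per
well per resample, preserving the residuals' heteroscedastic magnitudes
without parametric error assumptions. Both models are refitted on every
$Z^\star$ with the original weights, df is *not* recomputed per resample
(it enters only the inflation factor), and

$$p = \frac{1 + \#\{T^\star_b \ge T_{\mathrm{obs}}\}}{B + 1},$$

so $p \ge 1/(B+1)$ — at the default $B = 200$ the resolution is
$\approx 0.005$, adequate for exploratory screens; confirmatory analyses
should raise $B$ to 1000–5000. A solver failure inside a resample is
retried once and then scored $T^\star = +\infty$, which can only increase
$p$ (never silently dropped). Everything is reproducible bit-for-bit for a
fixed seed. Screens (`run_screen()`) derive a per-matrix substream seed
from the master seed and block index, so batch results are independent of
processing order, and apply Benjamini–Hochberg FDR, optionally within
strata such as cell line or plate.

## Synthetic data and the simulation design

`generate_null_surface()` draws exact members of $\mathcal{A}$:
$\alpha \sim U(0.5, 2)$ logit units and cumulative non-positive increments
$-|N(0.4, 0.2^2)|$ for $u$ and $v$ — after back-transformation these span
realistic viability, near 1 at the lowest doses falling towards 0 at the
highest. Alternatives are built by `inject_interaction()`: a Gaussian bump
of amplitude $s$ (towards synergy) with width $I/4$ at the grid midpoint is
subtracted and the result is projected back onto $\mathcal{M}$, so
alternatives stay model-consistent. Observation noise is i.i.d. Gaussian,
$\sigma = 0.1$ on the logit scale. The calibration study runs 200 null
simulations and the power study 30 per strength, both on $8\times8$ grids
with $B = 200$.

Two quantitative design choices deserve explanation:

* **Bump amplitudes** default to $\{2, 4, 6, 8, 10\}$ logit units, fixed
  once by the design requirement that the five equally spaced strengths
  carry the power curve from near the null to above 95% rejection at this
  noise level. The nominal amplitude greatly overstates the effective
  departure: the bump's rising flank violates monotonicity, so the cone
  projection pools away most of it, and the surviving perturbation is a
  fraction of the amplitude.
* **What the generator does not emulate**: real screens have discrete
  replicate structure, heteroscedastic and occasionally non-Gaussian noise,
  plate effects that correlate errors across wells (the bootstrap assumes
  independence), and marginal dose-response curves with flat plateaus at
  sub-threshold and saturating doses. The generator's steep, always-distinct
  marginal steps are deliberately simple; passing tests on it demonstrate
  correctness of the machinery, not performance on any particular real
  screen.

## Known limitations

* **Conservatism of the test in steep-marginal regimes.** The statistic
  $T$ is a pure quadratic functional of the noise: under the null it is
  driven almost entirely by the realized residual energy whenever the
  monotone fits never pool levels (marginal steps much larger than the
  noise, as in this generator). A Rademacher bootstrap holds residual
  magnitudes fixed, and after df inflation the resampled statistics centre
  on each dataset's own observed value, so null p-values concentrate around
  0.5 instead of spreading uniformly: the test is then *conservative* —
  it under-rejects at small $\alpha$ and never inflates false positives
  (without the df correction the same resampler is strongly
  anti-conservative, which is exactly the failure the correction targets).
  When marginals have plateaus comparable to the noise, level pooling makes
  the fitted df — and hence the resampled statistic — genuinely random and
  the tail calibration improves markedly. The package's calibration study
  (`run_calibration_study()`) computes the rejection rate and the
  Dvoretzky–Kiefer–Wolfowitz check so users can quantify this on designs
  that resemble their own screens; power at realistic effect sizes is
  unaffected in the saturated regime (see the acceptance checks).
* Hormetic (non-monotone) dose responses violate the cone assumption; the
  fits will flatten them rather than flag them. Diagnostics, not alternative
  constraints, are the intended remedy.
* The test is global; per-well confidence intervals for $\delta$ are not
  provided. Directional energies (`directional_energy()`) summarize the
  split between synergy and antagonism after a global rejection.
* Loewe and ZIP references are out of scope by design: they require the
  parametric marginal fits this framework exists to avoid.

## Worked example

```{r example}
g <- simulate_grid(I = 8, J = 8, strength = 10, sigma = 0.1, seed = 3)
res <- sir_test(g, B = 200, seed = 1)
res

# pointwise baselines on the same grid, viability-scale excess
s <- baseline_surfaces(g)
round(c(bliss = s$summary_bliss, hsa = s$summary_hsa), 3)

# missing-well prediction
g$Y[4, 4] <- NA; g$m[4, 4] <- 0L
g <- dose_grid(g$Y, g$conc_row, g$conc_col, m = g$m,
               drug_row = g$drug_row, drug_col = g$drug_col)
predict_missing(g)$predicted
```

## Problem sizes used in the test suite

Unit tests run on grids between $2\times2$ and $8\times8$ with bootstrap
sizes 25–200; the acceptance checks use the full study design (200
calibration simulations and 30 power simulations at $8\times8$, $B = 200$)
and 1000 random grids for the nesting property — a few minutes on one core
in total.
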