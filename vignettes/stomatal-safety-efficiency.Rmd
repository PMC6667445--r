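---
title: "Methods: quantifying the stomatal safety-efficiency trade-off"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the stomatal safety-efficiency trade-off}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stomsafe)
```

## The problem

Stomata set both the ceiling on leaf gas exchange and the first line of
defense against drought. Across species, a high maximum stomatal conductance
($g_{max}$, mmol m$^{-2}$ s$^{-1}$) tends to come bundled with stomata that
close at milder dehydration, i.e. a less negative leaf water potential at
50% closure ($\Psi_{gs50}$, MPa). `stomsafe` implements the full
computational chain needed to quantify that safety-efficiency trade-off
from dehydration experiments: response-curve fitting with model selection,
anatomical maximum conductance, a steady-state whole-plant simulation of
the trade-off's consequences, and trait-correlation statistics that account
for shared ancestry. A seeded synthetic-data generator reproduces the
statistical structure of such experiments so every stage is testable
without measurements.

## Fitting $g_s(\Psi_{leaf})$ responses

Each species contributes paired points (leaf water potential $\Psi_{leaf}
\le 0$ MPa, stomatal conductance $g_s \ge 0$). The species mean minimum
epidermal conductance $g_{min}$ is subtracted first so the fitted decline is
relative to residual (cuticular) conductance; negative adjusted values are
retained, since clamping would bias the error model. The
literature-compilation path skips the subtraction (published point clouds
rarely report $g_{min}$).

Four candidate families are fitted:

| family | form | parameters |
|---|---|---|
| linear | $g_0 + a\Psi$ | $a, g_0$ |
| sigmoidal | $a / (1 + e^{-(\Psi - x_0)/b})$ | $a, b, x_0$ |
| logistic | $a / (1 + (\Psi/x_0)^b)$ | $a, b, x_0$ |
| exponential | $g_0 + a e^{-b\Psi}$ | $g_0, a, b$ |

**Error model.** We assume i.i.d. Gaussian noise on $g_s$ with unknown
$\sigma$, under which maximum likelihood reduces to least squares with
$\hat\sigma^2 = RSS/n$ and
$$\mathrm{AICc} = n\ln(RSS/n) + 2k + \frac{2k(k+1)}{n-k-1},$$
with $k$ = number of curve parameters + 1 (for $\sigma$). This is the
standard ML-for-curve-selection convention; nothing in the fitted data
motivates a heteroscedastic alternative, and the synthetic generator uses
the same noise model so that the fitting assumption is exactly met in the
tested world.

**Optimization.** Every family is linear in its amplitude parameter(s)
given the nonlinear ones, so the amplitudes are concentrated out by a
linear solve and the optimizer works in one or two dimensions only
(exponential: Brent refinement of a 40-point log-spaced scan of $b$;
sigmoidal/logistic: Nelder-Mead from a deterministic grid of 20 data-driven
starts -- $x_0$ from quantiles of the observed potentials, shape from
log-spaced spans). The fit is a pure function of the data: no random
numbers, hence bitwise reproducibility.

**Selection.** Lowest AICc wins; AICc differences below 2 are not treated
as meaningful, so among candidates within 2 units of the best, the fewest
parameters win, with exact/equal-parameter ties broken by the fixed order
linear, exponential, sigmoidal, logistic. A consequence worth knowing: when
sigmoidal and logistic describe the data equally well (they often do), the
tie rule deterministically prefers sigmoidal.

**Refinement filters.** Dehydration experiments show two artifact classes:
*squeeze points* (closed stomata in turgid leaves, from the mechanical
advantage of epidermal cells) and *re-opening points* (stomata open in
flaccid, strongly dehydrated leaves that lost stomatal control). The
refined mode removes points with $g_s^{adj} < 50$ mmol m$^{-2}$ s$^{-1}$ at
$\Psi_{leaf} > -0.5$ MPa, and points with $g_s^{adj} > 50$ mmol m$^{-2}$
s$^{-1}$ at $\Psi_{leaf} < -2.0$ MPa. Two notes on these thresholds. First,
they are interpreted in mmol m$^{-2}$ s$^{-1}$: porometer conductances are
hundreds of mmol, so a literal mol-scale threshold would be inert. Second,
the re-opening rule is sometimes printed with the inequality pointing the
wrong way ($\Psi > -2$ MPa), which contradicts its own definition --
re-opening is by definition a deep-dehydration phenomenon -- so it is
implemented as $\Psi < -2$ MPa. Both thresholds are arguments, not
constants. The filter is idempotent, and both "all data" and "refined"
modes are first-class.

**Derived quantities.** $g_{max}$ is the selected curve evaluated at a
reference potential (0 MPa by default; $-0.1$ MPa as a sensitivity
re-analysis, since extrapolation to full hydration is a theoretical
construct). $\Psi_{gs20/50/80}$ are the most-hydrated roots of
$g(\Psi) = (1 - X/100)\,g_{max}$, found by scanning for a sign change on a
bracket extending 1.5$\times$ beyond the most negative observation and
bisecting to $10^{-6}$ MPa. Extrapolation is thus explicit: a threshold the
curve never reaches inside the bracket is reported missing with a warning
flag, never invented. For the logistic family with reference 0,
$\Psi_{gs50} = x_0$ is returned exactly.

**Significance.** Each selected fit is tested against the constant-$g_s$
null with a likelihood-ratio statistic $n\ln(RSS_0/RSS_1)$ on
$\chi^2_{k-1}$ degrees of freedom (curve parameters minus one). Whether the
original per-species P values came from an LRT is not documented anywhere
we could verify; the LRT is our design choice, stated here rather than
presented as a reconstruction.

## Anatomical maximum conductance

From stomatal density $d$, areal size $s$, width $W$, guard-cell length
$L$, and pore length $p$:
$$g_{max,anatomy} = \frac{b\, m\, d\, s}{\sqrt{s}}, \qquad
m = \frac{\pi c^2}{\sqrt{j}\,(4hj + \pi)}, \quad c = p/L, \; j = W/L,$$
with $b = D/v$, $D = 2.82\times10^{-5}$ m$^2$ s$^{-1}$ (diffusivity of
water vapor in air) and $v = 2.24\times10^{-2}$ m$^3$ mol$^{-1}$ (molar
volume of air). The pore-depth-to-width ratio $h$ defaults to 0.5 because
pore depth is rarely measured. Unit confusion is the classic failure mode
of this formula, so inputs carry an explicit unit tag: `"field"` (d in
mm$^{-2}$, s in um$^2$, lengths in um) or `"SI"`; evaluation is always in
SI and the result is in mol m$^{-2}$ s$^{-1}$. $s$ is treated as the area
of a single stoma (abaxial surface), $d$ as the density summed over both
surfaces. The opening ratio $g_{max}/g_{max,anatomy}$ converts units
explicitly (fitted $g_{max}$ arrives in mmol).

## The steady-state plant model

The whole-plant simulation asks what a given $(g_{max}, \Psi_{gs50})$ pair
*costs*: assimilation foregone under wet soil, and water-potential stress
under drought. Water moves through root, stem and leaf in series; at steady
state the net volumetric flux into each organ is zero, i.e. each segment's
Kirchhoff flux capacity equals transpiration:
$$\int_{\Psi_{leaf}}^{\Psi_{stem}} K_{leaf}(\Psi)\,d\Psi =
  \int_{\Psi_{stem}}^{\Psi_{root}} K_{stem}(\Psi)\,d\Psi =
  \int_{\Psi_{root}}^{\Psi_{soil}} K_{root}(\Psi)\,d\Psi =
  E = g_s(\Psi_{leaf})\cdot VPD.$$

Organ conductance follows the sigmoid $K(\Psi) = K_{max}/(1 +
e^{\alpha(\Psi - \Psi_{50})})$ with $K(\Psi_{50}) = K_{max}/2$. Two
documented choices here:

* **Shape $\alpha$** is never reported per organ; all organs default to
  $\alpha = 3$ MPa$^{-1}$, override per curve. Simulated surfaces are
  therefore quantitatively sensitive to $\alpha$ and should be read
  qualitatively.
* **Direction.** With $\alpha > 0$ this literal form *saturates* at
  $K_{max}$ for strongly negative $\Psi$ and gives $K(0) < K_{max}/2$
  (e.g. 0.474 for $K_{max}=10$, $\Psi_{50}=-1$, $\alpha=3$). That is the
  form the model is defined with, and all qualitative grid conclusions are
  insensitive to it, but users porting embolism-style vulnerability curves
  (which lose conductance when dehydrated) should negate $\alpha$.

The Kirchhoff integral has the closed form $K_{max}[\Psi -
\tfrac{1}{\alpha}\ln(1+e^{\alpha(\Psi-\Psi_{50})})]$ evaluated with an
overflow-safe log-sum-exp; tests verify agreement with adaptive quadrature
to 1e-8 of the integral's natural scale.

**Stomatal closure** is exponential in $\Psi_{leaf}$, anchored so that both
grid coordinates are exact by construction:
$g_s(\Psi) = g_{max} 2^{\Psi/|\Psi_{gs50}|}$, giving $g_s(0) = g_{max}$ and
$g_s(\Psi_{gs50}) = g_{max}/2$. The exponential family is used because it
is the most frequently selected family in real dehydration datasets; the
half-point anchoring is our choice (any anchoring consistent with the two
constraints is equivalent up to reparameterization).

**Photosynthesis** is light-saturated and carboxylation-limited. Combining
Fick's law $A = u(c_a - c_i)$ (with $u = g_s/1600$: mmol$\to$mol conversion
times the 1.6 H$_2$O/CO$_2$ diffusivity ratio) with net assimilation $A =
V_{cmax}(c_i - \Gamma^*)/(c_i + K_m) - R$ yields the closed form
$$A = a + bu - \sqrt{b^2u^2 + cu + a^2},$$
$a = 0.5(V_{cmax} - R)$, $b = 0.5(c_a + K_m)$, $c = 0.5[R(c_a + K_m) +
V_{cmax}(K_m - c_a + 2\Gamma^*)]$. Two dimensional readings are forced by
the algebra: $\Gamma^* = 40$ must be a mole fraction (ppm), and the
Farquhar expression must include $-R$ (the coefficient $c$ contains $R$;
without $-R$ the closed form would not solve the stated pair). Defaults
($V_{cmax} = 29.1$ umol m$^{-2}$ s$^{-1}$, $K_m = 550$ ppm, $R = 1$ umol
m$^{-2}$ s$^{-1}$, $c_a = 400$ ppm) describe a typical Mediterranean
evergreen oak. $A(0) = 0$ exactly and $A$ is increasing and concave in
$g_s$.

**Solver.** A damped Newton iteration on $(\Psi_{leaf}, \Psi_{stem},
\Psi_{root})$ (finite-difference Jacobian, step halving, iterates capped at
$\Psi_{soil}$) is tried first; on failure a nested-bisection fallback uses
series continuity -- given $\Psi_{leaf}$, $E$ is known and the upstream
potentials follow from monotone 1-D root finding, leaving a single
1-D residual in $\Psi_{leaf}$. Residual tolerance is $10^{-10}$ mmol
m$^{-2}$ s$^{-1}$; non-convergence is flagged, never silently returned. The
default grid spans $g_{max} \in [100, 400]$ by 10 and $\Psi_{gs50} \in
[-3, -0.2]$ by 0.2 under $\Psi_{soil} \in \{0, -1.2\}$ MPa at VPD 0.01 mol
mol$^{-1}$ (930 cells), and the tested invariants are: flux residuals
below 1e-8 everywhere, the ordering $\Psi_{soil} \ge \Psi_{root} \ge
\Psi_{stem} \ge \Psi_{leaf}$, $A$ non-decreasing in $g_{max}$, $A$
non-increasing as $\Psi_{gs50} \to 0$, and $\Psi_{stem}$ non-increasing in
$g_{max}$ under drought.

## Comparative statistics

**Ahistorical.** Pearson correlations are computed on raw and
log-transformed data (linear vs approximately power-law reading), the
stronger $|r|$ marked as selected. Traits that are negative by convention
($\Psi_{gs50}$, $\pi_o$, $\pi_{tlp}$) are multiplied by $-1$ before
logging. Structural relationships are summarized by standard major axes:
slope $= \mathrm{sign}(r)\,sd(y)/sd(x)$, line through the means, exactly.

**Cross-study heterogeneity.** Whether the trade-off's SMA slope differs
across studies is tested with a likelihood-ratio common-slope test built on
the residual-versus-fitted-axis correlation: at a candidate common slope
$b$, group $i$ contributes $-n_i \ln(1 - r^2_{uv,i}(b))$ where $u = y -
bx$, $v = y + bx$; the statistic minimized over $b$ is $\chi^2_{g-1}$. We
use $n_i$ rather than small-sample-corrected weights, which is mildly
liberal at very small $n$; the power and null behavior are verified by
simulation in the test suite. If the common slope is not rejected, a Wald
test compares elevations at the common slope.

**Evolutionary.** PGLS is a GLS regression whose residual covariance comes
from shared branch lengths: Brownian motion uses the tree covariance
directly; Pagel's lambda multiplies off-diagonals by $\lambda \in [0,1]$
($\hat\lambda$ by ML, with explicit boundary checks at 0 and 1); OU uses
the root-conditioned covariance $e^{-2\alpha T}(e^{2\alpha s_{ij}} -
1)/(2\alpha)$, which recovers BM as $\alpha \to 0$ ($\hat\alpha$ by ML on a
log grid plus bounded refinement). OU is well-posed here only for
ultrametric trees; non-ultrametric input is height-normalized with a
warning. AIC counts regression coefficients + $\sigma^2$ + the transform
parameter ($k = 3$ for BM, 4 otherwise); the lowest AIC wins, with lambda
preferred over OU when the two differ by less than 2. Exact identities hold
by construction and are tested to machine precision: $\lambda = 0$
$\equiv$ OLS and $\lambda = 1 \equiv$ BM; a star phylogeny $\equiv$ OLS.

The reported PGLS "r" is a convention, not a sample statistic:
$\mathrm{sign}(slope)\sqrt{R^2_{GLS}}$ with $R^2$ about the
phylogenetically weighted mean. Because conventions differ between
implementations, the raw slope and its SE are always reported alongside,
and the convention is recorded in the output metadata.

## The synthetic world

The generator emulates the statistical structure the analysis assumes --
it is a stated world, not a tuning dial, and its defaults were chosen once:

* **15 species, 40 points per species** -- a typical common-garden
  dehydration experiment (real campaigns span roughly 14-77 points).
* **Noise SD 10 mmol m$^{-2}$ s$^{-1}$**, additive, homoscedastic, floored
  at zero -- matching the fitting error model by design.
* **Artifact rates 4% + 4%** -- squeeze and re-opening points together
  averaging ~8% of points, the magnitude reported for refined datasets.
  Squeeze points get $\Psi \sim U(-0.45, -0.05)$ and adjusted $g_s \sim
  U(0, 40)$; re-opening points sit below both the species' deep-closure
  potential and $-2$ MPa with adjusted $g_s \sim U(60, 150)$ -- magnitudes
  chosen to straddle the 50 mmol threshold so the filters are exercised on
  both sides.
* **$g_{max} \in [150, 450]$, $\Psi_{gs50} \in [-1.2, -0.4]$** -- hydrated
  conductances typical of porometry on woody species, and closure on the
  sensitive side. The sensitive $\Psi_{gs50}$ default keeps the world
  internally consistent with the fixed $-2$ MPa re-opening threshold: that
  filter presupposes bulk closure before $-2$ MPa, and a world full of
  drought-tolerant closers would see the filter discard legitimate points.
* **Trade-off correlation 0.7** between $\log g_{max}$ and $\Psi_{gs50}$,
  implemented as correlated bivariate Brownian evolution on a unit-height
  Yule tree (matrix-normal construction; affine range-mapping preserves the
  correlation). Auxiliary traits carry the expected sign structure:
  stomatal size decreasing with $g_{max}$, $\pi_{tlp} \le \pi_o < 0$
  tracking $\Psi_{gs50}$, LMA decreasing with $g_{max}$.
* **Sub-streamed RNG**: each species' dataset is drawn from a seed derived
  by a stable hash of its id, so adding a species never perturbs the
  others.
* **$\Psi$ sampling design**: stratified-uniform over $[1.5\Psi_{gs80},
  0]$ (one draw per equal-width stratum), representing the aim of covering
  maximum opening through full closure. The true per-leaf sampling
  distribution of real campaigns is unknown; this design is a stand-in,
  not a reconstruction.

What a green test establishes: the estimation chain recovers known truth
under its own assumptions (95% of 200 synthetic species within 5% on
$g_{max}$ and 0.1 MPa on $\Psi_{gs50}$ in the shipped checks). What it does
not establish: robustness to porometer drift, leaf-temperature artifacts,
within-leaf patchiness, heteroscedastic or autocorrelated noise, or
plasticity of the response -- none of which the generator simulates.

## Degenerate inputs and edge behavior

Fewer than 6 points (or fewer than parameters + 2), or all-identical
$\Psi$, is a fit error with a diagnostic, not a silent skip; species
failing inside the pipeline are collected in `failures` and the run
continues. Empty post-refinement datasets error. Zero variance makes SMA
degenerate (error). Fewer than 3 complete pairs blocks any correlation.
The logistic family's power is only evaluated on $\Psi \le 0$, $x_0 < 0$,
where its base is non-negative.

## Known limitations

* The optional qualitative clause of the re-opening rule ("after the bulk
  of leaves closed") is implemented as a disabled-by-default percentile
  second pass; the quantitative $-2$ MPa rule is the default behavior.
* The steady-state model has no capacitance, soil resistance, energy
  balance, or RuBP-regeneration/TPU limitation; it is a design argument,
  not a gas-exchange simulator.
* PGLS r-value conventions vary across implementations; compare slopes,
  not r, across software.
* The SMA elevation test uses a first-order Wald approximation; for
  borderline elevation p-values prefer the slope test plus inspection.
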