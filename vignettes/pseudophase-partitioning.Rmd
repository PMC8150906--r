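---
title: "Pseudophase kinetic modelling of antioxidant partitioning in emulsions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudophase kinetic modelling of antioxidant partitioning in emulsions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasekin)
```

## The model

An oil-in-water emulsion stabilised by a nonionic surfactant is treated as
three thermodynamic regions — oil (O), water (W) and the surfactant
interfacial film (I) — among which an antioxidant (AO) exchanges rapidly
relative to every reaction timescale of interest. Concentrations are
expressed per litre *of the region*, so the stoichiometric concentration
$[AO_T]$ (moles per litre of whole emulsion) obeys the mass balance

$$ c_O \Phi_O + c_W \Phi_W + c_I \Phi_I = [AO_T], $$

where $\Phi_O$, $\Phi_W$, $\Phi_I$ are the region volume fractions and
$\Phi_I$ is the surfactant volume over the emulsion volume. Two partition
constants describe the equilibrium:

$$ P_{OI} = c_I / c_O, \qquad P_{WI} = c_I / c_W . $$

For a compound confined to two regions (the usual case: hydrophilic
parents occupy water + interface, esterified phenolipids oil + interface)
the interfacial mole fraction has the closed form

$$ f_I = \frac{P_{WI}\,\Phi_I}{\Phi_W + P_{WI}\,\Phi_I} $$

(and symmetrically with $\Phi_O$, $P_{OI}$), giving
$c_I = f_I [AO_T]/\Phi_I$. The general three-region form combines both
ratio definitions with the mass balance:

$$ f_I = \frac{P_{OI} P_{WI} \Phi_I}
  {P_{OI} P_{WI} \Phi_I + P_{WI}\Phi_O + P_{OI}\Phi_W}. $$

Two structural consequences matter scientifically and are enforced as
package invariants: as $\Phi_I$ grows, $f_I$ increases strictly while
$c_I$ decreases strictly — more emulsifier recruits a larger *share* of
antioxidant into a disproportionately larger interfacial volume, diluting
it. This "dilution paradox" is why antioxidant efficiency falls at higher
emulsifier loads even though the interfacial percentage rises.

### Kinetic determination of the constants

The partition constants of reactive phenols are measured *in situ* with a
chemical probe, a long-chain arenediazonium ion that is both surface
active and insoluble in oil and water, hence confined to the interfacial
region. Under pseudo-first-order conditions ($[AO] \gg$ probe) the
observed decay constant of the probe reports the effective interfacial
antioxidant concentration:

$$ k_{obs} = k_I\, c_I
   = \frac{k_I [AO_T] P_{WI}}{\Phi_W + P_{WI}\Phi_I}, $$

with $k_I$ the intrinsic second-order rate constant in the interfacial
region. Varying $\Phi_I$ across the experimental span (0.005–0.04) traces
a curve whose scale fixes $k_I$ and whose curvature fixes $P$. The
reciprocal $1/k_{obs}$ is exactly affine in $\Phi_I$, which supplies
starting values; the fit itself is nonlinear least squares on the
$k_{obs}$ scale (Levenberg–Marquardt via `minpack.lm`), because the
measurement error is a roughly constant *relative* 7–9 % on $k_{obs}$,
not on its reciprocal. Replicates enter pointwise rather than
pre-averaged, preserving degrees of freedom for the Jacobian-based
covariance; an optional $1/k_{obs}^2$ weighting flag implements the
constant-relative-error assumption exactly. Uncertainty on derived
quantities ($c_I$, enhancement ratios) is propagated to first order from
the fitted covariance.

Identifiability deserves a caveat that the package surfaces rather than
hides: the sensitivity of $\ln k_{obs}$ to $\ln P$ is
$P\Phi_I/(\Phi_{bulk}+P\Phi_I)$, which saturates for large $P$, so
partition constants in the several-hundred range carry substantially
larger relative errors than constants near 50 at the same design — with
12 points and ~8 % rate noise, the achievable relative standard error on
$P$ is on the order of 13 % regardless of the truth. Precise constants at
realistic noise need more $\Phi_I$ levels or replicates.

## Trace reduction

Raw data are absorbance–time pairs at 572 nm from a derivatization assay
(unreacted probe coupled to an azo dye). `fit_first_order()` fits
$A(t) = A_\infty + (A_0 - A_\infty) e^{-k_{obs} t}$, auto-detecting decay
versus growth from the overall trend. The asymptote is fitted by default;
whether to fit or pin $A_\infty$ is genuinely open in this assay family,
so a `fix_a_inf` toggle is provided. Starting values come from the
trailing extreme and a log-linear regression — robust without user input.
Guards: a trace whose range is below three times the noise level
(median absolute deviation of first differences, scaled to a per-point
SD) is rejected as "no reaction detected"; a window shorter than two
half-lives of the fitted constant triggers a coverage warning, the
conventional design rule being 2–3 half-lives. Replicate fits are pooled
by `aggregate_kobs()`, which flags groups with replicate CV above 9 % or
any $r^2$ below 0.995 — the assay's usual quality bounds.

## Assay reductions

* **FRAP**: the Fe(II)-equivalent concentration giving the sample's
  593 nm absorbance change, `(dA_sample/dA_standard) * conc_standard`.
* **DPPH EC50**: the AO/DPPH mole ratio halving the radical
  concentration, located by linear interpolation between the bracketing
  observations; no functional form is imposed because none is standard.
  Weak scavengers (monophenols) that never reach the 0.5 crossing return
  a "not reached" sentinel carrying the maximum ratio tested —
  extrapolation would manufacture a number the data do not support.
* **Oxidative stability**: emulsions in an accelerated 60 °C oven test
  are tracked by conjugated-diene (CD) content; the induction time is the
  first upward crossing of the sample's own baseline + 0.5 *percentage
  points* CD, linearly interpolated. The threshold is absolute, not
  relative: a relative reading (0.5 % of the ~0.075 % baseline, i.e.
  0.0004 points) would sit far below measurement noise and is not a
  plausible reading of the convention. The efficiency figure of merit is
  the relative increase $(t_{AO} - t_C)/t_C$ against the
  antioxidant-free control, which is invariant to common time rescaling.

## Predictor analysis

`pearson_matrix()` screens candidate predictors against the stability
response with two-tailed p-values from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df, starred at 0.05/0.01.
`stepwise_regression()` implements the classical
probability-of-F stepwise procedure: forward entry of the smallest
partial-F p-value below `p_enter` (default 0.150), then backward removal
of any included predictor whose removal p-value exceeds `p_remove`
(default 0.200), iterated to a fixed point. The partial F for one term is
$(RSS_{red} - RSS_{full})/(RSS_{full}/(n-k-1))$ on $(1, n-k-1)$ df.
Defaults keep `p_enter < p_remove`, which precludes entry/removal
cycling. Ties on entry are broken by larger partial F, then predictor
name (the convention had to be fixed somewhere; nothing downstream is
sensitive to it). Missing values are removed listwise — rows without
distribution data simply cannot enter a model whose central predictor is
the interfacial concentration. Standardized betas are the coefficients
after z-scoring response and predictors (sample SD, $n-1$); VIFs are
$1/(1-R_j^2)$ with an infinite-VIF collinearity flag. Per-step cumulative,
adjusted and partial $R^2$ are reported; partial $R^2$ values sum to the
final cumulative $R^2$.

Forward selection has a known blind spot that the test suite documents
rather than papers over: jointly decisive but individually weak
predictors (suppressor structure) can stall entry. On a small 10-row
design (five compounds at two emulsifier fractions) an exactly linear
planted response can yield a single-predictor model even though the
three-predictor fit is perfect; the 20-row four-fraction design separates
the contributions cleanly. This is a property of the procedure itself —
faithfully reproduced — not of the implementation.

## The synthetic scenario generator

`scenario_spec()` defines a fully reproducible simulated study; every
generator consumes only the spec and the seed, and identical specs give
byte-identical outputs. What it emulates, and the defaults:

* 4:6 oil/water emulsion ($\Phi_O = 0.4$, $\Phi_W = 0.6$ held fixed as
  $\Phi_I$ varies — see numerical choices), $[AO_T] = 0.24$ mM,
  $\Phi_I \in \{0.005, 0.01, 0.02, 0.04\}$, triplicate kinetics.
* **Traces**: exponential decays with the true $k_{obs}$ from the
  forward model, 25 points over 3 half-lives, additive Gaussian
  photometric noise (SD 0.005 AU) plus replicate-level lognormal
  perturbation of the rate. The CV parameter (default 8 %) is the target
  *observed* replicate CV: the lognormal scale is inflated by the
  Gaussian $c_4(n)$ small-sample correction ($c_4(3)=0.886$) so that
  triplicate sample CVs average inside the assay's 7–9 % band.
* **Oxidation curves**: flat baseline 0.075 % CD plus a logistic rise
  whose +0.5-point crossing lands on the planted induction time; noise is
  additive Gaussian. By default induction times encode the scenario's
  planted linear stability model evaluated on the true distributions, so
  the kinetic, distributional and statistical layers share one coherent
  truth; a verbatim `t_induction` mode supports planting specific
  fold-changes (e.g. a 16-fold compound against a 10 h control).
* **Compound table**: predictors from the true distributions
  (concentrations in mM), response
  $\beta_0 + \beta_1 c_I + \beta_2 E_{pa} + \beta_3 c_W + \varepsilon$.
  The default coefficients $(\beta_1, \beta_2, \beta_3) = (0.45, -12,
  -25)$ with $\beta_0 = 6$, $\sigma = 0.5$ were chosen once, at design
  time, so the noiseless partial-$R^2$ pattern is dominated by the
  interfacial concentration with secondary anodic-potential and
  water-concentration contributions — the qualitative structure such
  panels show — and were not revisited.

What the generator does **not** emulate: droplet-size and curvature
effects, temperature dependence of the constants, radical chain
mechanism detail, probe-coupling chemistry (treated as instantaneous),
creaming, or between-day instrument drift. Passing tests therefore show
that the estimators recover the model's own truth under realistic noise
— not that the model is complete for any particular real emulsion.

## Numerical choices

* Volume-fraction convention: $\Phi_O$ and $\Phi_W$ are the nominal 4:6
  values and are *not* renormalised as $\Phi_I$ varies (sums may slightly
  exceed 1). This additive convention is the one under which the bundled
  panel's constants reproduce the panel's published enhancement figures;
  the alternative renormalised convention would change third-digit
  results only.
* Partition constants at or above $10^9$ are treated as "exclusively
  interfacial" to avoid overflow; the three-region form reduces exactly
  to the matching two-region limit there.
* Optimiser tolerances $10^{-10}$ (ftol/ptol), 200 iterations; fits
  failing to converge raise errors with the underlying diagnostic rather
  than returning silently bad parameters. A rate series whose $k_{obs}$
  spans less than 2 % of its median is rejected as not determinable —
  the partition constant is at the zero boundary, mirroring compounds
  whose probe reactivity is too low to measure.
* Interpolations (EC50, induction time) are linear between adjacent
  observations; first crossing wins.
* Degenerate inputs error early and specifically: zero interfacial
  volume, both-or-neither partition constants, flat traces, responses
  with zero variance, collinear candidate predictors (skipped and
  logged).

## Problem sizes in the test suite

The suite regenerates all fixtures in code: conservation and
monotonicity on a $10^4$-point randomised $(P_{OI}, P_{WI}, \Phi_I)$
grid; partition-fit Monte Carlo at 500 seeds (2 % replicate CV for the
coverage claim, plus a 500-seed run at the full 8 % band); stepwise
versus an exhaustive subset-enumeration oracle on 500 seeded scenario
tables and 40 random designs; end-to-end noiseless pipeline round trips.
These sizes give Monte-Carlo standard errors comfortably below the
asserted margins while keeping the default run under a minute of compute
for the deterministic parts and a few tens of seconds for the simulation
parts.

## Known limitations

* Large partition constants are weakly identified by design, not by
  implementation (see above); standard errors say so honestly.
* The stepwise procedure inherits forward selection's suppressor blind
  spot and the usual caveats of data-driven selection (post-selection
  p-values are optimistic); it is provided because it is the field's
  reporting convention, with the exhaustive oracle available in the test
  helpers for small candidate sets.
* The absorbance→CD conversion from raw 233 nm readings and the
  peroxide-value assay are out of scope; oxidation curves enter already
  expressed as CD %.
* EC50 is interpolation-based and says nothing below the smallest or
  above the largest tested ratio.
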