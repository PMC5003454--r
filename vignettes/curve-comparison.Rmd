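---
title: "Comparing biologically relevant response curves across two scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing biologically relevant response curves across two scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curvecomp)
```

## The problem

Serial gene expression experiments measure each gene's response along an
ordered condition — developmental time, dose, temperature — and often do so
under two scenarios (two species, two drugs, two stimuli). `curvecomp` fits a
small set of biologically interpretable curve shapes to each gene in each
scenario, decides which shape (if any) describes the gene well, and then
compares the two scenarios' reported curves per gene in terms of

* **heteromorphy** — the two reported shapes differ;
* **heterochrony (HC)** — the transition happens at a different condition
  value, quantified as the transition-point gap as a percentage of the
  condition range;
* **heterometry (HM)** — the response magnitude differs, quantified as the
  mean vertical gap at the curves' characteristic points as a percentage of
  the vertical response range.

## The model cascade

Five nested-complexity families are fit per gene, all by least squares on
the *fitted points* only (see below):

| family | parameters | shapes it yields |
|---|---|---|
| flat | `alpha` (1) | flat |
| linear | `alpha, beta` (2) | lineU / lineD |
| sigmoid | `alpha, beta, gamma, delta` (4) | sigmoid, hockey, transition (U/D) |
| double sigmoid | `alpha, beta, gamma, delta, epsilon, phi` (6) | impulse, step (U/D) |
| generalized double sigmoid | + `lambda` (7) | impulse+, step+ (U/D) |

The sigmoid is parameterized as
`f(x) = alpha + (gamma - alpha) * expit(s (x - delta))` with internal rate
`s = 4 beta / (gamma - alpha)`, so that `alpha` and `gamma` are the two
steady-state levels and `beta` is the maximum slope, attained at `delta`.
The double sigmoid is the product of two logistic factors,

```
f(x) = (1/beta) * [alpha + (beta - alpha) expit( epsilon (x - delta))]
               * [gamma + (beta  - gamma) expit(-epsilon (x - phi))]
```

which runs (for `epsilon > 0`) from level `alpha` through an intermediate
level governed by `beta` to level `gamma`: an impulse (interior peak or
trough) when `beta` lies outside the two outer levels, a step (interior
plateau) when between them. The generalized form multiplies the second
factor's rate by `lambda`, allowing unequal slopes on the two transitions.
Degree-3/5/7 polynomials can be added as an *overfitting control*: they have
no biological rationale, so a selection procedure that resists overfitting
should not let them displace the shapes above.

### Gauge symmetries of the double sigmoid

Two exact reparameterizations leave the double-sigmoid curve unchanged:
swapping the two factors (`(gamma, beta, alpha, phi, -epsilon, delta)`), and
swapping the transition locations with the conjugate intermediate level
`alpha*gamma/beta`. Parameter estimates are therefore only comparable modulo
this group; `canonical_dbs()` and `dbs_orbit()` expose the canonical
representative and the full orbit, and all parameter-recovery checks in the
test suite measure the distance to the closest orbit member.

## Held-out scoring: the Relative Prediction Error

To resist overfitting without pooling information across genes, each model
is fit to every other observation (the odd-indexed *fitted points*) and
scored on the remaining even-indexed *evaluation points*:

```
RPE = 100 * sqrt(mean((y - f)^2)) / (max(f) - min(f))
```

with the max/min over the evaluation-point predictions. Dividing by the
predicted range makes the score comparable across genes regardless of
absolute expression level. A fit is *good* when RPE <= 10% (`good_fit_rpe`).

**Degenerate denominators.** A flat curve predicts a single value, so its
own range is zero; any near-constant fit has a vanishing range that would
inflate its RPE arbitrarily (we observed values above 1000% for near-flat
linear fits on impulse-shaped genes, driven entirely by the denominator).
Whenever the predicted range falls below 10% of the observed evaluation
range, the observed range is substituted and the value is flagged
(`range_fallback`). This keeps scores of uninformative fits finite and
mutually comparable; good fits (predicted range comparable to observed) are
never affected. A consequence worth knowing: a truly flat gene can never be
*reported*, because every candidate's RPE is then roughly
`100 * sd(noise) / range(noise)` ≈ 35–40% regardless of the noise level.
Flat curves enter the results only via the parsimony step below.

An AIC-style diagnostic on the same evaluation points,
`m log(SSE/m) + 2k`, is carried alongside (`aic_eval`); it plays no role in
selection but lets one check that the leeway rule and a held-out
information criterion usually agree.

## Selection: best fit, then parsimony leeway

Per gene and scenario, each converged fit is classified into a shape label
and the labelled candidates enter a two-step rule (`select_curves`):

1. **Curve A** is the candidate with the smallest RPE (ties: fewer
   parameters, then a fixed label order that places biological shapes before
   polynomial controls). If `RPE_A > 10%`, no curve is reported.
2. Among candidates with *fewer* parameters than Curve A, those with
   `RPE <= RPE_A + 5%` (the `leeway_rpe`) are eligible; the
   fewest-parameter one is reported as **Curve B**. If none is eligible,
   Curve A is reported and the most complex fewer-parameter candidate is
   kept as the comparison curve for plots.

### Classification details

* The sigmoid family's shape depends on how many *steady states* fall inside
  the observed range: a boundary derivative magnitude at or below
  `steady_slope = 0.10` (response units per condition unit, evaluated at the
  first and last observed condition values — the only data-anchored choice)
  counts as a steady state; two give a sigmoid, one a hockey stick, none a
  transition. The threshold is in the data's native units and is a control
  knob.
* Double-sigmoid shapes are classified on a 1001-point grid
  (`grid_points`) over the observed range: a strict interior global extremum
  (tolerance `1e-8` of the curve's own range; within one grid step of an
  endpoint counts as "at the endpoint") makes an impulse, otherwise a step.
  If both an interior peak and trough exist, the larger excursion wins.
* Direction (U/D) comes from comparing the curve's first and last values;
  impulses are U for a peak and D for a trough.

### The double-sigmoid fitting guard

The double sigmoid is fit only when the sigmoid model is *not* already an
adequate description: when the sigmoid's RPE exceeds the linear model's, or
exceeds the good-fit threshold. The first clause skips the expensive and
numerically fragile 6-parameter fit when a near-perfect sigmoid exists; the
second keeps the impulse/step pathway open for genes where both simple
models fail. (Requiring only `RPE_sig > RPE_lin` would block the double
sigmoid for essentially every impulse-shaped gene, since the 4-parameter
sigmoid almost always beats the 2-parameter line on held-out error even
when both are poor.) The generalized double sigmoid is fit only when the
double sigmoid was, seeded from its estimates, and only with at least 14
observations (`max_model = "gen_double_sigmoid"`); with 12–13 observations
set `max_model = "double_sigmoid"`.

### Optimizer choices

Nonlinear families are minimized by Levenberg–Marquardt
(`minpack.lm::nls.lm`, `ftol = ptol = 1e-10`, up to 2000 function
evaluations) with deterministic multi-starts: the sigmoid from
level-anchored starts over a 3-point `delta` grid; the double sigmoid from
the sigmoid-seeded start (`alpha = a_sig`, `beta = (a_sig + g_sig)/2`,
`gamma = g_sig`, `delta = d_sig`, `epsilon = phi = 0`) plus perturbed
variants (`epsilon` in ±{0.5, 2} per 1/14th of the range, impulse-shaped
`beta` seeds), because the printed start makes one factor locally constant
and can stall a gradient method; the generalized double sigmoid from the
double-sigmoid estimates with `lambda` in {0, 0.5, 1, 2}. Near-exact ties
in fitted SSE (interpolants of the saturated 7-parameter fit on 7 points)
are broken by evaluation SSE, so the returned interpolant is the one that
generalizes. All starts are deterministic: a fixed series always yields a
bit-identical fit. A series with all responses identical gets only the flat
fit. Optimizer failures are flagged (`converged = FALSE`), never raised;
per-gene failures in the batch driver are logged and skipped.

## Comparing the two scenarios

HM is evaluated at the union of both curves' characteristic points — any
point for flat (the left endpoint is used), the two endpoints for
monotone-family shapes, endpoints plus the peak/trough for impulses — and
normalized by the range of both curves' values over that same union.
Evaluating *both* curves at the *union* keeps the statistic symmetric when
the two shapes differ. Two flat curves at distinct levels give HM = 100 by
this convention (the difference is the whole range). HC is the gap between
the two transition points (maximum-|slope| location for sigmoid-family and
step shapes, the extremum for impulses) as a percentage of the condition
range; it is undefined for flat and linear curves, which have no
transition. Flags are set when a statistic *exceeds* 10%
(`hm_threshold`, `hc_threshold`): frequent-pair summary tables count
heterochrony-only, heterometry-only and both.

Pairs are formed only for genes whose reported curve exists in *both*
scenarios. Cross-tabulations are stratified by trend direction
(up/down in each scenario); a flat-reported curve is stratified by its own
underlying trend (the sign of that scenario's linear-fit slope), so flat
pairs can land in either stratum; a pair with no direction information at
all goes to the U/U stratum by convention.

## The synthetic-data generator

`synth_expression()` plants a known truth so every pipeline stage is
testable without external data: a shape per gene from a mixture, true
parameters sampled in documented ranges, a scenario-2 copy with planted HC
(transition locations shifted by a fraction of the condition range) and HM
(a vertical offset `c = p*R/(1-p)` chosen so the measured HM statistic
equals `100p` at zero noise), plus i.i.d. Gaussian noise. Default
conditions: a 14-point axis (`1:14`); levels on a log2-expression-like
scale in [0, 12]; transitions in the central part of the range; maximum
slopes in a band resolvable from 7 fitted points (hockey slopes capped at
1.1 response units per condition unit — a steeper jump falling between two
fitted points is unrecoverable by *any* method that sees only every other
observation); noise SD 0.25 response units by default (a typical
replicate-mean residual scale for such levels; the test suite mostly uses
0.12, i.e. 1% of the level scale). The default mixture emulates the
relative prevalence of reported families in comparative developmental
expression data — sigmoid 0.35, hockey 0.20, line 0.15, impulse 0.10, step
0.07, flat 0.05, transition 0.03, impulse+ 0.03, step+ 0.02. Draws whose
true label would not classify as the requested shape in both scenarios, or
whose boundary slopes sit within a factor of two of the steady-state
threshold (labels that would flip under infinitesimal noise), are redrawn;
the returned truth table is therefore exact at zero noise.

What the generator does *not* emulate: probe-level effects, replicate
structure (inputs are replicate means), heteroskedastic or correlated
noise, and cross-gene correlation. Passing recovery tests on this generator
shows the algorithm recovers identifiable planted shapes under i.i.d.
Gaussian noise; it does not certify performance on real data with
structured noise.

## What the test suite establishes (and problem sizes)

The package's own checks run at deliberately modest sizes: label recovery
on 500 synthetic genes at noise SD 0.12 (≥ 90% of genes report the planted
label or a more parsimonious one; flat-truth genes, 5% of the mixture, can
never be reported — see above — and are the main structural miss);
parameter recovery per family on 50 noiseless and 50 noisy (2%-of-range)
series, measured as l2 relative error against the closest gauge-orbit
member (a max-over-components metric is dominated by intrinsically noisy
rate parameters); AIC concordance and the polynomial control on the same
500-gene fixture; selection equivalence against a brute-force oracle on
thousands of random candidate tables.

On the AIC concordance: when Curve A is reported, the held-out AIC prefers
Curve A essentially always; when Curve B is reported, the AIC prefers B in
a clear majority of cases but not all — the +5-percentage-point leeway
admits RPE ratios up to `(RPE_A + 5)/RPE_A`, while AIC concordance needs
roughly `RPE_B/RPE_A <= exp((k_A - k_B)/m)`. The two rules agree most
often when the simpler curve is the true model (near-tied errors), which is
the regime the leeway was designed for.

## Known limitations

* Truly flat genes cannot be reported (RPE's denominator convention); flat
  appears in results only as a parsimony-leeway winner.
* Hockey vs sigmoid and step/impulse vs sigmoid distinctions are genuinely
  ambiguous near the thresholds; inspect the per-gene plots.
* HC compares one transition point per curve; curves with two comparable
  transitions (steps) use the global maximum-slope point only.
* No uncertainty quantification on the selected label or on HC/HM.
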