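---
title: "Methods: evolutionary maximum-likelihood estimation of moisture-ratio models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evolutionary maximum-likelihood estimation of moisture-ratio models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrfit)
```

## The model and its assumptions

A drying run is recorded as pairs $\{S(k), MR(k)\}_{k=1}^{k_{\max}}$:
the area shrinkage $S = A(t)/A(0)$ measured from images, and the
moisture ratio $MR = MC(t)/MC(0)$ measured from mass. The model is an
$n$-order polynomial in the shrinkage with additive noise,

$$MR(k) = \tau^T(k)\,\gamma + w(k), \qquad
\tau(k) = (1, S(k), S^2(k), \dots, S^n(k))^T,$$

with $\gamma \in \mathbb{R}^{Q}$, $Q = n + 1$, and $w$ white Gaussian
with unknown variance $\sigma^2$. The assumptions that matter:

* **independent, homoscedastic Gaussian noise** on MR. The likelihood
  factorises over samples; profiling $\sigma^2$ at its ML value
  $\hat\sigma^2 = \lambda(\gamma)$ collapses the log-likelihood to
  $\mathrm{const} - (k_{\max}/2)\ln\lambda(\gamma)$, where
  $$\lambda(\gamma) = \frac{1}{k_{\max}}\sum_k
  \left[MR(k) - \tau^T(k)\gamma\right]^2$$
  is the *maximum-likelihood fitness*. Maximising the likelihood is
  exactly minimising $\lambda$; the package therefore treats $\lambda$
  (equal to RMSE$^2$) as the single objective. The additive constant of
  the profiled log-likelihood is fixed to
  $-(k_{\max}/2)(\ln 2\pi + 1)$ so `log_likelihood_profile()` is fully
  defined; only differences matter for estimation.
* **shrinkage treated as an exact regressor.** Pixelisation and
  segmentation errors in $S$ are ignored by the estimator (no
  errors-in-variables correction); the imaging tests quantify how small
  those errors are on synthetic stacks.
* **no monotonicity requirement.** The records are an unordered
  regression sample — the fitness is permutation-invariant — so datasets
  with non-monotone S (e.g. from case-hardening artefacts) are accepted.

Because $\lambda$ is a convex quadratic in $\gamma$, its global minimum
has a closed form: the least-squares solution of the Vandermonde system.
`ols_fit()` computes it by QR decomposition and serves as the
independent oracle throughout the test suite. The evolutionary
estimators never call it; they must *find* it.

## The two estimators

Both are differential-evolution loops over a population of $P$ candidate
coefficient vectors, run for exactly `generations` sweeps (no early
stopping — the loop structure has a single exit at the final
generation). Each sweep builds one trial per individual via mutation and
binomial crossover, and applies greedy selection: the trial replaces its
parent only when its fitness is *strictly* smaller, ties keeping the
parent. Survivors replace parents synchronously at the end of the sweep,
and the partner fitnesses used by the sorted mutation are evaluated
against that frozen parent generation (cached once per sweep). Ties in
the final best-individual scan break toward the lowest index.

* **`mlp-ie`** mutates with DE/rand/1 — base vector plus
  $F \cdot$ (difference of two other random partners), all three drawn
  without replacement excluding the target — at a fixed scaling factor
  $F$ and crossover rate $CR$. Neither constant is canonical for this
  problem; the defaults $F = 0.5$, $CR = 0.9$ are standard
  DE/rand/1/bin practice and both are configurable.
* **`mlp-i-ie`** sorts the three drawn partners by fitness and searches
  from the best along the worst-to-suboptimal direction, with schedules
  $$F_{g} = f_1 e^{-f_2\,g/g_{\max}^{f_3}}, \qquad
  CR_{g} = \frac{1 + \sin g}{c_1} + c_2$$
  ($g$ the 1-based generation index, sine in radians on the bare
  integer; $CR$ recomputed at generation 1 and every even generation,
  each odd generation above 1 holding the previous value, so the rate
  updates once while the generation advances twice). Validity requires
  $2/c_1 + c_2 \le 1$ so $CR$ stays a probability.

Binomial crossover draws one forced position uniformly from
$\{1,\dots,Q\}$ so at least one mutant element always survives; the
per-element uniform draws are independent across positions and
individuals. All randomness flows from a single stream seeded by
`de_control(seed = )`, which makes every fit bitwise reproducible.

## Choice of the schedule constants

The schedule *shapes* are part of the method; the five constants are
free tunables. The package's defaults are

| constant | default | effect |
|---|---|---|
| $f_1$ | 0.9 | initial scaling-factor scale |
| $f_2$ | 0.5 | decay rate: $F$ falls from $0.9e^{-f_2/g_{\max}} \approx 0.88$ to $0.9e^{-0.5} \approx 0.55$ |
| $f_3$ | 1.0 | makes the decay shape invariant to $g_{\max}$ |
| $c_1$ | 2.5 | oscillation amplitude: $CR \in (c_2, 2/c_1 + c_2]$ |
| $c_2$ | 0.2 | oscillation floor |

These were selected, once, by a design study on the generator's default
conditions (cubic truth, $\sigma = 0.02$, $k_{\max} = 100$): the
improved variant should do what it exists to do, namely beat the classic
variant at small budgets ($P = 30$, $g_{\max} = 20$) while still
converging to the least-squares optimum at large ones. A gentle decay
and a crossover rate that periodically approaches 1 achieve both —
across 8 independent datasets and two disjoint 20-seed blocks the
improved variant's median final fitness was 0.36–0.69 of the classic
one's, and at $P = 50$, $g_{\max} = 500$ it reaches the convex optimum
to $\sim 10^{-19}$. Steeper decays (e.g. $f_2 = 2$) freeze the
population before it can cross the distance from the unit
initialisation box to coefficients of magnitude 4–13, and a lower $CR$
ceiling ($c_1 = 4$) mixes mutants too timidly; both reverse the
ranking of the two algorithms at small budgets. All five constants
remain user-settable.

Initialisation defaults to the unit box $[0, 1)$ — the estimators'
definition — even though realistic cubic coefficients lie far outside
it; mutation is unbounded, so the population escapes the box, but
recovery at small generation budgets is faster from a wider box, which
is why `init_low`/`init_high` are exposed and the deep-convergence
checks use $[-15, 15]$.

## The synthetic-data generator

`simulate_drying()` emulates the study conditions the package is tested
under:

* shrinkage trajectory $S(k) = 1 - (1 - s_{\min})(k/k_{\max})^\beta$,
  strictly decreasing; defaults $s_{\min} = 0.55$, $\beta = 1$ (linear
  decline). The floor 0.55 is deliberate: the default ground-truth
  cubic $(-4.0180, 12.5609, -11.1670, 3.5632)$ — a published
  best-fitting cubic for cantaloupe-slice microwave drying — turns
  negative below $S \approx 0.52$, so the generator only uses it where
  it yields physically sensible MR values in $[0, 1]$.
* $MR(k) = \tau^T(k)\gamma^* + w(k)$ with $w \sim N(0, \sigma^2)$,
  default $\sigma = 0.02$ — the same magnitude as the best published
  fit RMSE for this system (0.0239), so synthetic difficulty matches
  the real problem. Noise is *not* clipped: clipping would break the
  Gaussian assumption the likelihood derivation relies on, so MR may
  stray slightly outside $[0, 1]$.
* default $k_{\max} = 100$: a plausible camera-sampled drying run
  (every 30 s over ~50 min); the real study's count is not public, so
  this is a declared choice, not an inference.
* the ground truth and realised noise ride along as attributes — a
  sidecar deliberately separate from the CSV that
  `write_fixture_bundle()` emits, so estimation code cannot read it
  even by accident.

`generate_image_stack()` renders each sample as a bright disk of radius
$r_0\sqrt{S(k)}$ on a dark background (area ratio equals commanded
shrinkage by construction), decorated with bright specks outside the
slice and dark holes inside it, plus optional Gaussian pixel noise.
Because the trajectory starts at $S(1) = 1 - (1 - s_{\min})/k_{\max}$,
slightly below 1, the quantity the pipeline can actually be tested
against is the commanded area *ratio to the first frame*, which the
truth table exposes as `area_ratio`.

What passing on this generator does **not** show: robustness to uneven
illumination, shadows, specular highlights, translucent edges during
late drying, slice drift, or correlated (non-white) measurement noise.
Real deployments should spot-check masks with `binarize()` +
`fill_holes()` on their own frames.

## Imaging pipeline choices

* **Thresholding:** Otsu's criterion by default (256-level histogram),
  with a fixed `threshold` override; foreground is *strictly above* the
  threshold, `invert` flips polarity. A constant image has no Otsu
  threshold and degenerates to an empty mask with a warning.
* **Connectivity:** hole filling treats the *background* as
  4-connected (a hole is background not 4-connected to the border);
  particle filtering treats *foreground* components as 8-connected.
  The two differ exactly at diagonal contacts, which is why both are
  stated. 4-connected labelling comes from `EBImage::bwlabel`;
  8-connectivity is obtained by merging labels that touch diagonally
  (an `igraph` components pass over the label-adjacency graph).
* **Keep-largest tie-break:** among equal-sized largest components, the
  one containing the earliest pixel in column-major order wins — an
  arbitrary but documented and deterministic rule.
* **Grayscale weights** are fixed (ITU-R 601) so masks are
  bit-reproducible across platforms.
* The first frame defines $A(0)$; an empty mask mid-series records
  $S = 0$ with a warning rather than aborting a long measurement run.

## Numerical and degenerate-input conventions

* Greedy selection uses strict `<`; equal-fitness trials are discarded,
  which keeps the best-fitness trajectory non-increasing by
  construction.
* A dataset whose shrinkage values cannot support the requested order
  (fewer than $n + 1$ distinct values) raises a *warning* from the
  evolutionary fits — DE needs no matrix inversion and still runs — but
  an *error* from `ols_fit()`, whose QR factorisation is genuinely
  rank-deficient.
* A zero-variance observed series makes $R^2$ undefined and raises an
  error rather than returning $\pm\infty$; `fit_moisture_model()`
  reports `NA` metrics in that case instead of failing the whole fit.
* An exact fit ($\lambda = 0$) flags the profiled log-likelihood as
  `Inf` rather than throwing.
* Order-selection ties break toward the smaller order (parsimony);
  validation applies the adjusted-$R^2$ penalty with the fitted model's
  order even though no parameters are re-estimated on the validation
  batch.
* CSV and JSON output is written with 9 significant digits: enough for
  lossless round-tripping at double precision of the quantities
  involved, and stable under re-runs for byte-level diffing.

## Problem sizes in the tests

The suite exercises deep convergence at $P = 50$, $g_{\max} = 500$ on
$k_{\max} \in \{60, 100\}$ (about a second per fit), the paired-seed
comparison at the small-budget settings $P = 30$, $g_{\max} = 20$ over
20 seeds, and imaging on 128–192 px rasters with disk radii of 30–70 px
— sizes chosen so the whole suite completes in well under a minute
while still leaving the deep runs 12+ orders of magnitude of fitness
descent to demonstrate.

## Known limitations

* No standard errors or confidence intervals for the coefficients; the
  likelihood machinery could provide them, but they are out of scope.
* No physics-based drying models and no errors-in-variables treatment
  of the shrinkage regressor.
* The improved estimator's advantage is demonstrated on the generator's
  conditions; on very different noise levels or coefficient scales the
  schedule constants may need re-tuning (they are all exposed).
* The imaging pipeline assumes one slice per frame; multi-slice scenes
  need a crop to the slice of interest (the `roi` argument of
  `process_frames()`), not in-package tracking.
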