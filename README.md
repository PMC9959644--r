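# mrfit

Drying a slice of plant tissue (a cantaloupe disc, an apple ring) shrinks
it, and the shrinkage visible to a camera turns out to be an excellent
proxy for how much water is left. `mrfit` estimates the relationship
between the two: it fits a polynomial model of the **moisture ratio** MR
as a function of the **area shrinkage** S,

```
MR(k) = r0 + r1 S(k) + r2 S(k)^2 + ... + rn S(k)^n + w(k),
```

where `S(k) = A(k)/A(0)` is the slice's pixel area relative to its first
image, `MR(k) = MC(k)/MC(0)` is the dry-basis moisture content relative
to its initial value, and `w` is white Gaussian noise with unknown
variance. The Weierstrass approximation theorem motivates the polynomial
form: it can track the MR–S relationship of any product and drying regime
given enough terms.

The package is aimed at postharvest / food-engineering researchers who
record drying runs with a camera and a balance and want a calibrated,
reproducible MR(S) model.

## What is inside

**Two evolutionary maximum-likelihood estimators.** For Gaussian noise,
profiling the variance out of the likelihood leaves a single objective,
the *maximum-likelihood fitness*

```
lambda(gamma) = (1/kmax) * sum_k [ MR(k) - tau(k)' gamma ]^2,
```

(`tau(k) = (1, S(k), ..., S(k)^n)'`), whose minimiser is the ML estimate
of the coefficients `gamma`. Two differential-evolution searches descend
it:

* `mlp-ie` — classic DE/rand/1/bin: random-partner difference mutation,
  binomial crossover at a fixed rate, greedy survivor selection;
* `mlp-i-ie` — an improved variant in which the three mutation partners
  are sorted by fitness (the best becomes the base vector, the difference
  points from worst to suboptimal), the scaling factor decays
  exponentially across generations, `F(g) = f1 exp(-f2 g / gmax^f3)`, and
  the crossover rate follows a sinusoid updated every second generation,
  `CR(g) = (1 + sin g)/c1 + c2`.

A closed-form least-squares fit (`ols_fit()`) is included as the
independent oracle: the fitness is convex quadratic in `gamma`, so the
evolutionary estimators must land on the same optimum, and the tests hold
them to it.

**Goodness of fit and order selection.** `r_squared()`,
`adjusted_r_squared()`, `rmse()`, `select_order()` (largest adjusted R²
wins; ties go to the smaller order) and `validate_model()` for scoring a
frozen model on an independent batch.

**Image-based shrinkage measurement.** `process_frames()` runs the
camera-side pipeline: grayscale conversion (fixed ITU-R 601 weights),
Otsu or fixed thresholding, filling of enclosed background holes
(4-connectivity), removal of small spurious components (8-connectivity,
keep-largest), pixel counting, and division by the first frame's area.

**A synthetic-data generator.** `simulate_drying()` produces datasets
with a known ground truth (by default the cubic
`gamma = (-4.0180, 12.5609, -11.1670, 3.5632)` over S in [0.55, 1] with
sigma = 0.02 noise), and `generate_image_stack()` renders matching
shrinking-disk image stacks with specks and holes, so every stage of the
toolchain is testable without laboratory data.

## Worked example

```r
library(mrfit)

d <- simulate_drying(kmax = 100, sigma = 0.02, seed = 7)
fit <- fit_moisture_model(
  d, order = 3,
  control = de_control(pop_size = 50, generations = 500,
                       init_low = -15, init_high = 15, seed = 1)
)
fit
#> Moisture-ratio model fit (mlp-i-ie, order 3)
#>        r0        r1        r2        r3
#>  -3.97773  12.35780 -10.86550   3.43200
#> R2 0.9939  adjR2 0.9937  RMSE 0.01883  (kmax 100, 500 generations)
```

The estimated coefficients sit close to the generator's hidden truth
`(-4.0180, 12.5609, -11.1670, 3.5632)`; the residual RMSE 0.0188 is at
the level of the injected noise (sigma = 0.02), which is as good as any
estimator can do. `tidy(fit)`, `glance(fit)`, `augment(fit)`,
`autoplot(fit)`, `plot_trajectory(fit)` and `plot_schedules(fit)` give
the broom/ggplot2 views of the same object.

Order selection over n = 1..3 reproduces the expected choice of the
cubic:

```r
select_order(d, orders = 1:3,
             control = de_control(pop_size = 50, generations = 500,
                                  init_low = -15, init_high = 15, seed = 1))
#>   order    r2 adj_r2   rmse best
#> 1     1 0.960  0.960 0.0481 FALSE
#> 2     2 0.993  0.993 0.0197 FALSE
#> 3     3 0.994  0.994 0.0188 TRUE
```

And the imaging side, on a generated five-frame shrinking-disk stack:

```r
stack <- generate_image_stack(kmax = 5, size = 192, r0 = 70, seed = 2)
process_frames(stack$frames)
#>       k area_px shrinkage
#> 1     1   14028     1
#> 2     2   12620     0.900
#> 3     3   11248     0.802
#> 4     4    9856     0.703
#> 5     5    8484     0.605
```

The measured ratios track the commanded area schedule to a few tenths of
a percent (pixelisation is the only error source here).

A command-line interface wraps the same functions; after installation:

```sh
MRFIT=$(Rscript -e 'cat(system.file("exec", "mrfit", package = "mrfit"))')
Rscript $MRFIT simulate --kmax 100 --sigma 0.02 --seed 7 --images --outdir run/
Rscript $MRFIT shrinkage --frames run/frames --manifest run/manifest.csv --output run/shrinkage.csv
Rscript $MRFIT fit --input run/data.csv --order 1 --order 2 --order 3 --seed 1 --output run/fit.json
Rscript $MRFIT validate --model run/fit.json --order 3 --input run/data.csv --output run/metrics.json
```

## Scope

The package models MR as a function of S only. It does not implement
physics-based drying models (Page, Lewis, heat/mass-transfer ODEs),
confidence intervals for the coefficients, camera calibration, or
hardware control of a drying rig. See `vignettes/mrfit-methods.Rmd` for
the modelling assumptions, parameter choices and known limitations.
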