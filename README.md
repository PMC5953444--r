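# eccfit

Ellipse fitting with eccentricity-weighted data augmentation.

Least-squares ellipse fitters systematically mis-estimate the parts of an
ellipse where the data are most *eccentric* — far out along the major
axis.  This bites hardest in applications like plant-root phenotyping,
where a root tip tracked on a turntable traces a highly eccentric,
often partially occluded ellipse in the image plane and the fit feeds a
camera self-calibration.  `eccfit` implements a fitter-agnostic remedy:
score every data point by its eccentricity, then resample the point set
so that high-eccentricity neighbourhoods are densified before the fit.

For a candidate ellipse with semi-axes `a >= b` and eccentricity
`eps = sqrt(a^2 - b^2)/a`, a point `X_s` gets

    xi_s = eps * d_a / (d_a + d_b)

where `d_a`, `d_b` are its orthogonal distances to the minor- and
major-axis lines, so `xi` runs from 0 on the minor axis to `eps` on the
major axis.  Weights `w_s = exp(xi_s)` are normalised and fed to a
systematic resampler: the cumulative weight distribution is traversed
with fixed step `1/T`, `T = floor(1/min W_s)`, and each interval emits
its original point plus one linearly interpolated point per extra
traversal step it received — every original point is retained and the
per-interval output counts match `T * W_s` within 1.

The package also provides:

* five classical fitting families behind one interface
  (`fit_ellipse()`): basic algebraic least squares, direct
  ellipse-specific fitting, its numerically stable variant,
  gradient-weighted fitting, and iterative Sampson-distance
  minimisation with a degeneracy barrier;
* orthogonal-distance error evaluation (`orthogonal_distance()`,
  `rmse_ellipse()`) via vectorised Newton projection;
* a synthetic generator for sector-restricted noisy samples and
  occluded trajectory arcs (`sample_sector()`, `occluded_arc()`);
* the closed-form theory of when a supplementary point improves the
  axis-aligned restricted fit (`on_axis_interval()`,
  `off_axis_conditions()`, `delta_curve()`);
* a reproducible Monte-Carlo benchmarking harness
  (`run_sector_experiment()`, `run_noise_sweep()`).

## Worked example

Fit a noisy, sector-restricted sample of an eccentric ellipse
(semi-axes 100 and 32, noise 20% of the semi-major axis, points confined
to ±60° around the two major vertices), with and without the
augmentation pre-pass:

```r
library(eccfit)

e0 <- ellipse(0, 0, a = 100, b = 32, theta = 0)
p  <- add_noise(sample_sector(e0, benchmark_sectors()$range1, 200, seed = 11),
                e0, 0.2, seed = 12)

summary(fit_ellipse(p, method = "direct"))
#> Ellipse fit, method 'direct'
#> Points: 200
#> Parameters:
#>         cx         cy          a          b      theta
#>  -1.493412  -1.727452 103.746169  48.345341   0.028913
#> Eccentricity: 0.884787
#> Mean point eccentricity of data: 0.710767
#> RMSE (orthogonal distance, original points): 17.3839

summary(fit_ellipse(p, method = "direct", augment = TRUE,
                    axis_strategy = "two_pass"))
#> Ellipse fit, method 'direct' (eccentricity-augmented pre-processing)
#> Points: 200 (284 after augmentation)
#> Parameters:
#>         cx         cy          a          b      theta
#>  -1.882237  -1.506235 102.726276  48.382290   0.029093
#> Eccentricity: 0.882142
#> Mean point eccentricity of data: 0.708545
#> RMSE (orthogonal distance, original points): 17.4385
```

At this noise level the raw fit overestimates the minor axis badly
(48.3 versus the true 32).  The augmented fit moves the recovered shape
toward the truth: scoring each fit against the noiseless generating
positions gives an RMSE of 9.24 for the raw fit and 8.84 after
augmentation.  Run over 250 seeded repeats
(`run_sector_experiment(experiment_config(sigma = 0.2))`), the
truth-referenced mean RMSE drops for every fitter family, and grows
strictly with the sector's mean point eccentricity for the four
algebraic-family fitters.

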