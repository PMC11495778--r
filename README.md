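# tempmort

Two-stage temperature–mortality analysis with excess-mortality attribution
and climate-scenario projection.

`tempmort` is for environmental epidemiologists and climate–health impact
modellers who work with multi-location daily mortality panels. It
implements the full analysis chain used in multi-country temperature–health
studies:

1. **First stage** — per-location distributed lag nonlinear models (DLNM):
   quasi-Poisson regression of daily deaths on a temperature × lag
   cross-basis (natural cubic splines, 21-day lag window), with seasonal
   spline and day-of-week confounder control, reduced to the overall
   cumulative exposure–response curve `θ, V(θ)`.
2. **Second stage** — multivariate random-effects meta-regression
   `θ̂ᵢ ~ N(B xᵢ, Sᵢ + Ψ)` fitted by REML over meta-predictors (location
   mean temperature, temperature range, log GDP, climate zone), with
   per-location best linear unbiased predictions (BLUPs).
3. **Attribution** — minimum mortality temperature (MMT) search on the
   percentile grid; backward attributable fractions `AF = 1 − e^{−η}`
   split into cold (below MMT) and heat (above); empirical confidence
   intervals from 1000 Monte-Carlo draws of the curve coefficients.
4. **Projection** — trend-preserving bias calibration of scenario
   temperature series (monthly offsets + residual variance scaling),
   constant day-of-year baseline mortality over 1980–2099, decadal
   excess-mortality fractions, scenario differencing in percentage points,
   member → model → multimodel averaging, and death-weighted regional
   aggregation.

Because the mortality archives and earth-system-model output such analyses
rely on are restricted, the package ships a first-class **synthetic-data
module** (`make_study()`, `make_scenario_series()`) generating
multi-location panels with a known U-shaped exposure–lag–response surface,
known meta-level structure and pseudo-ESM scenario series — every stage is
validated against ground truth.

## Worked example

The numbered scripts under `analysis/` run the demo study (6 locations × 5
years, 3 pseudo-ESMs × 3 scenarios × 2 members) end to end, writing all
tables under `results/pipeline/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_first_stage.R
Rscript analysis/03_pool.R
Rscript analysis/04_attribution.R
Rscript analysis/05_projection.R
```

Stage 4 prints, for the default seed:

```
MMT percentiles across locations: 61, 65, 57, 32, 26, 84 (boundary flags: 0)
  cold  EM fraction: mean 3.63% (per-location range 1.19% to 6.61%)
  heat  EM fraction: mean 6.79% (per-location range 0.54% to 16.37%)
  total EM fraction: mean 10.42% (per-location range 5.00% to 17.55%)
```

i.e. about one death in ten in this (warm-leaning) synthetic panel is
attributable to non-optimal temperature. Stage 5 prints the multimodel-mean
decadal changes by 2090–2099, in percentage points of excess mortality:

```
  noLULCC         cold  mean -0.56 pp   heat  mean +1.48 pp   total mean +0.92 pp
  sustainability  cold  mean -0.06 pp   heat  mean -0.49 pp   total mean -0.55 pp
  inequality      cold  mean -0.13 pp   heat  mean +0.71 pp   total mean +0.58 pp
```

Under the warming control scenario, cold-related excess mortality falls and
heat-related rises; the cooler *sustainability* perturbation lowers the
total burden relative to control while the warmer *inequality* perturbation
raises it — each by a few tenths of a percentage point, the same order as
the decade-scale land-use signals such frameworks are built to resolve.
(The sustainability and inequality rows are differences from the control
scenario in the same decade; the control row is the difference from its own
1980–1989.)

The same pipeline is available as one call:

```r
library(tempmort)
cfg <- default_config(out_dir = "results/pipeline")  # or read_config("my.yaml")
run_pipeline(cfg)
```

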