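# casekin

Kinetics of micelle rearrangement during tryptic proteolysis of
β-casein.

When trypsin digests micellar β-casein, the original micelles do not
simply dissolve: micelles with hydrolyzed bonds reassemble into new,
denser nanoparticles, which the same enzyme then degrades to soluble
peptides. `casekin` is for researchers studying such
proteolysis-driven particle rearrangement — by light scattering, FTIR
spectroscopy or AFM — who want a quantitative, testable model of the
process.

## The model

The rearrangement is a linear chain of first-order steps,

```
S --k1*E0--> X --k2--> Y --k3*E0--> N        (optional Y --ka--> Z)
```

with `S` intact micelles, `X` hydrolyzed micelles, `Y` new
nanoparticles, `N` peptide products (all fractions of the initial
substrate, S0 = 1), and `E0` the trypsin concentration in mg/L. The
first and third stages are enzymatic and scale with `E0`; the second —
self-assembly of fragments into new particles — does not. With
effective rates `a = k1*E0`, `b = k2`, `c = k3*E0` the nanoparticle
fraction has the closed form

```
Y(t) = a*b * [ exp(-a*t)/((b-a)(c-a)) + exp(-b*t)/((b-c)(b-a))
             + exp(-c*t)/((c-a)(c-b)) ]
```

and peaks at the root `t_max` of `dY/dt = 0`, a transcendental
equation that also lets `k2` be fitted from measured peak times at
several enzyme concentrations. Because `k2` does not scale with
enzyme, `t_max` versus `1/E0` is *not* a hyperbola — the model's
signature prediction. The package also predicts secondary-structure
time courses (`S+Y`, or `S+X/2+Y` when half the structure survives in
hydrolyzed micelles), implements the FTIR difference-spectrum
processing chain used to monitor digestion (enzyme subtraction,
1725/1375 cm⁻¹ baseline anchors, equal-area normalization, band
traces at 1633/1650/1593 cm⁻¹), and summarizes AFM nanoparticle
ensembles (height/diameter distributions, volume models,
sphere-equivalent radii). Synthetic-data generators with recorded
ground truth make every stage testable end to end.

## Worked example

```r
library(casekin)

# rate constants calibrated at E0 = 0.25 mg/L
rc <- rate_constants(k1E0 = 0.0066, k2 = 0.0015, k3E0 = 2e-4, E0 = 0.25)
m  <- proteolysis_model(rc, E0 = 0.25)
m
#> Three-stage proteolysis model (S -> X -> Y -> N)
#>   E0 = 0.25 mg/L (S0 = 1, fractions of initial micelles)
#>   effective rates: k1*E0 = 0.0066, k2 = 0.0015, k3*E0 = 0.0002 s^-1
#>   nanoparticle peak: t_max = 1724 s (28.7 min)
```

The nanoparticle population peaks 29 minutes into the reaction. The
full species trajectories:

```r
tr <- trajectory(m, seq(0, 10000, by = 50))
head(as.data.frame(tr), 3)
#>   t_s         S         X          Y            N Z
#> 1   0 1.0000000 0.0000000 0.00000000 0.000000e+00 0
#> 2  50 0.7189237 0.2702373 0.01080169 3.725044e-05 0
#> 3 100 0.5168513 0.4449909 0.03788769 2.700309e-04 0

product_lag_time(tr)     # products appear only after a lag phase
#> [1] 835.2925
```

Fitting `k2` from (noisy, synthetic) peak-time observations at four
enzyme levels:

```r
obs <- gen_tmax_dataset(rc, E0 = c(0.125, 0.25, 0.5, 1),
                        sigma = 0.1, seed = 42)
fit <- fit_k2(obs, k1 = rc$k1, k3 = rc$k3)
summary(fit)
#> Rearrangement rate constant fitted from nanoparticle peak times
#>   k2 = 0.00133419 s^-1  (k1 = 0.0264, k3 = 0.0008 s^-1 per mg/L, fixed)
#>   4 observation(s), residual sum of squares 8.4e+04 s^2
#>   RMSE = 144.9 s
#>
#> Per-observation residuals:
#>  E0_mg_per_L tmax_obs_s tmax_fit_s  residual_s
#>        0.125  2678.0334  2488.2460  189.787385
#>        0.250  1629.7982  1845.1712 -215.373035
#>        0.500  1330.7397  1370.5996  -39.859921
#>        1.000   998.8752   996.9412    1.933922
```

With 10 % timing noise the estimate (0.00133 s⁻¹) lands within ~11 %
of the generating value 0.0015 s⁻¹ for this single draw; across 200
replicates the median recovery is within a few percent (see the test
suite). AFM volumes convert to sphere-equivalent radii with
`sphere_equivalent_radius(3500)` → 9.42 nm and
`sphere_equivalent_radius(2200)` → 8.07 nm.

A YAML-configured end-to-end run (`run_pipeline()`, or the thin
wrapper `inst/cli/casekin.R`) writes trajectories, synthetic FTIR
band traces and AFM summaries plus a reproducibility manifest.

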