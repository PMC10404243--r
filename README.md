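# dynlgcp

Dynamic log-Gaussian Cox process models for spatio-temporal point patterns.

Point patterns such as satellite fire detections — an event is a location
and a date — often need to be read on two axes at once: *when* is activity
changing (permanently? seasonally? in multi-year swings?) and *where* is it
concentrated beyond what observed covariates explain. `dynlgcp` addresses
both with a single model: a Poisson point process whose log-intensity is

```
lambda(s, t) = beta0 + z(s,t)' beta + mu_t + s_t + c_t + xi(s, t)
```

- `mu_t` — long-term trend, second-order random-walk (RW2) prior;
- `s_t` — seasonal component, lag-m autoregression (m = 4 quarterly, 12
  monthly);
- `c_t` — stationary AR(2) cycle parameterised by its partial
  autocorrelations, so complex roots capture genuine multi-year swings;
- `z(s,t)' beta` — fixed effects (climate class, temperature, rainfall,
  distance to roads, ...);
- `xi(s, t)` — a Matérn Gaussian field (smoothness 1, marginal sd `sigma`,
  range `rho`) evolving over periods as an AR(1) with dependence `Phi`.

The Matérn field is made computationally tractable by the SPDE approach:
a finite-element discretisation over a triangulated mesh yields a Gaussian
Markov random field with sparse precision
`Q = tau^2 (kappa^2 C + G)' C^-1 (kappa^2 C + G)` (lumped mass `C`,
stiffness `G`). The intractable Cox likelihood over the window is replaced
by `(n + n_t) T` independent Poisson pseudo-observations via a dual-mesh
quadrature rule, and inference runs a Laplace (Gaussian) approximation of
the latent field nested in an empirical-Bayes (or small-grid) exploration
of the hyperparameter posterior. A full simulator draws patterns from
exactly this generative model, so every stage is testable against known
ground truth without any external data.

## Worked example

Simulate an Amazon-like scenario (irregular ~100 × 70 km window, eight
quarters, V-shaped trend, dry-season seasonality peaking in quarters 3–4,
covariate effects, spatio-temporal field) and fit the temporal
decomposition:

```r
library(dynlgcp)

scn <- amazon_scenario(seed = 1)
sim <- simulate_pattern(scn)
sim$pattern
#> lgcp_pattern: 3991 events over 8 periods, window area 4893

spec <- lgcp_spec(seasonal = list(period = 4, estimate_phi = FALSE),
                  field = FALSE)
mod  <- lgcp_model(sim$pattern, sim$mesh, spec)
fit  <- fit_lgcp(mod, seed = 1)
fit
#> lgcp_fit (eb): 5 hyperparameters, latent dim 25, seed 1
#> hyperparameters (natural scale):
#>       parameter       mean        sd    q0.025       q0.5     q0.975
#> 1    prec_trend 20281.9094 1.997e+04 2943.4268 20281.9094  1.398e+05
#> 2 prec_seasonal 19077.2813 1.960e+04 2547.4707 19077.2813  1.429e+05
#> 3    prec_cycle   566.8005 9.951e+02   18.1562   566.8005  1.769e+04
#> 4            p1     0.2932 3.046e-02    0.2324     0.2932  3.517e-01
#> 5            p2    -0.9824 3.009e-02   -0.9994    -0.9824 -5.862e-01
#> fixed effects:
#>   parameter   mean      sd q0.025   q0.5 q0.975
#> 1 intercept -2.424 0.02257 -2.468 -2.424  -2.38
```

The hyperparameter table follows the usual posterior-summary layout (mean,
sd, 2.5/50/97.5% quantiles, mode). High precisions mean low component
variability; `p1`, `p2` are the cycle's partial autocorrelations — here
`p2` near −1 says the periodic signal was absorbed by the cycle rather
than the seasonal block, an aliasing between the two that is possible at
quarterly resolution (their sum is identified; see the methods vignette).
The intercept −2.42 is the baseline log-intensity per km² per quarter:
`exp(-2.42) * 4893 km² ≈ 437` baseline events per quarter.

Per-period predicted totals against the observed counts:

```r
dec <- extract_components(fit)
head(dec$totals, 4)
#>   period observed predicted      lwr      upr pred_lwr pred_upr
#> 1      1      476  468.4914 428.0818 509.9539  405.950  523.075
#> 2      2      680  686.5680 641.9192 727.3953  626.975  760.100
#> 3      3      522  522.4797 484.2880 558.8438  460.975  582.025
#> 4      4      309  298.0294 275.7102 322.8012  254.975  335.100
```

`lwr`/`upr` bound the integrated intensity, `pred_lwr`/`pred_upr` the
realised counts (Poisson predictive); observed counts fall inside the
predictive intervals.

A configuration-file pipeline covers the same flow from the shell
(`inst/cli/dynlgcp.R <simulate|fit|decompose> config.yaml`); every run is
reproducible byte-for-byte from config plus seed.

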