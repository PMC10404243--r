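---
title: "Dynamic log-Gaussian Cox processes: model, discretisation and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic log-Gaussian Cox processes: model, discretisation and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynlgcp)
```

## The model

`dynlgcp` fits spatio-temporal point patterns — the motivating application
is satellite fire detections over a large region, aggregated to quarters or
months — as a log-Gaussian Cox process (LGCP): a Poisson process whose
log-intensity is itself a Gaussian random field. The log-intensity at
location $s$ and period $t$ decomposes additively,

$$
\lambda(s,t) = \beta_0 + z(s,t)^\top\beta + \mu_t + s_t + c_t + \xi(s,t),
$$

with

* $\mu_t$: a long-term trend with a second-order random-walk (RW2) prior.
  The RW2 penalises second differences, so its null space (level and slope)
  carries smooth permanent change — the component that answers "has the
  baseline rate durably shifted?".
* $s_t$: a seasonal component following the lag-$m$ autoregression
  $s_t = \phi_s\, s_{t-m} + \eta_s$ with $m = 4$ (quarterly) or $12$
  (monthly). With $\phi_s = 1$ this is a seasonal random walk whose null
  space is every period-$m$ pattern; the package estimates $\phi_s$ by
  default and can fix it at 1.
* $c_t$: a stationary AR(2) cycle, parameterised by its first two partial
  autocorrelations $(p_1, p_2)$ so that the open box $|p_k| < 1$ maps
  exactly onto the stationarity triangle. Complex characteristic roots
  ($\theta_1^2 + 4\theta_2 < 0$) give genuinely oscillatory behaviour —
  multi-year swings that are neither trend nor fixed-period seasonality.
* $z(s,t)^\top\beta$: fixed effects of covariates (climate class indicators,
  temperature, rainfall, distance to roads, ...), continuous ones
  standardised, categorical ones one-hot encoded against a reference level.
* $\xi(s,t)$: a Matérn Gaussian field (smoothness $\nu = 1$) in space with
  AR(1) dependence across periods,
  $\xi(\cdot,t) = \Phi\,\xi(\cdot,t-1) + \omega(\cdot,t)$, innovations
  independent across periods and scaled so the per-period marginal
  covariance is constant in $t$ (a separable space–time covariance).

The field uses the standard SPDE parameterisation: internal scales
$(\log\tau, \log\kappa)$ map to the interpretable marginal standard
deviation $\sigma$ and range $\rho$ (the distance, in the same km units as
the coordinates, at which correlation falls to about 0.14) through
$\sigma^2 = \Gamma(\nu)/(4\pi\kappa^{2\nu}\tau^2\Gamma(\nu + d/2))$ and
$\kappa = \sqrt{8\nu}/\rho$. A frequently reproduced variant of the
$\log\tau$ identity omits a $(8\nu)^{\nu/2}$ factor and is inconsistent
with the marginal-variance formula; this package treats the
marginal-variance identity as defining and derives $\log\tau$ from it.

## Discretisation

**Mesh.** The window polygon is covered by a structured grid of right
triangles whose every edge (including cell diagonals) is at most
`max_edge_inner`, surrounded by an extension ring of width
`extension_fraction` × window diameter (default 0.2). The ring pushes the
artificial Neumann boundary of the SPDE discretisation away from the
window, where it would otherwise inflate variances. A structured grid was
chosen over constrained Delaunay triangulation: it satisfies the same
coverage and refinement guarantees with far less machinery, produces
well-shaped elements by construction, and keeps vertex lookup trivial. The
`max_edge_outer` argument is accepted for interface stability but the ring
is not coarsened — a conforming two-resolution structured grid adds
complexity disproportionate to the node savings at the problem sizes the
package targets.

**Finite elements.** Piecewise-linear (P1) basis functions give the mass
matrix $C$ and stiffness matrix $G$; the lumped (row-sum diagonal) mass
$\tilde C$ replaces $C$ in both factors of the precision
$Q = \tau^2(\kappa^2\tilde C + G)^\top \tilde C^{-1}(\kappa^2\tilde C + G)$,
the standard Markov construction that keeps $Q$ sparse.

**Quadrature.** Each vertex receives the area of its barycentric dual cell
(vertex–edge-midpoint–centroid quadrilaterals, clipped to the window).
These weights are non-negative, sum exactly to the window area at any mesh
resolution, and integrate constants exactly; on meshes whose triangles tile
the window exactly they also integrate linear fields exactly.

**Augmented likelihood.** The intractable LGCP likelihood is replaced by
independent Poisson pseudo-observations: per period, one zero-count row per
vertex with exposure `dual weight × offset`, plus one unit-count row with
zero exposure per event — $(n + n_t)T$ rows in total. The entire linear
predictor of an event row (covariates *and* field) is evaluated at the
event's dual-cell vertex, i.e. the dominant barycentric vertex of its
containing triangle. Evaluating different parts of the predictor at
different locations (e.g. field interpolated, covariates nearest-node) is
not an option: along directions where the covariate design and the field
are nearly collinear, the mismatch leaves the event-row reward without any
exposure penalty and the pseudo-likelihood mode degenerates (coefficients
of order $10^4$ cancelling node-wise). With the dual-cell convention the
augmented log-likelihood is exact for intensities piecewise constant per
dual cell, and the pseudo-likelihood is bounded by the saturated model.

## Inference

Inference is nested: a Gaussian (Laplace) approximation of the latent
field inside an exploration of the hyperparameter posterior.

* **Latent level.** Newton optimisation with step halving of the latent
  log-posterior; convergence when the largest gradient entry falls below
  $10^{-6}$ or the relative mode change below $10^{-8}$, at most 50
  iterations. The posterior precision is the prior plus the curvature
  $A^\top W A$ of the Poisson rows.
* **Constraints.** The trend always carries a sum-to-zero constraint (to
  separate it from the intercept); a $\phi_s = 1$ seasonal carries one
  sum-to-zero constraint per phase. Constraints are imposed by conditioning
  by kriging on the unconstrained Gaussian approximation. Intrinsic prior
  blocks additionally receive a relative diagonal jitter of $10^{-6}$ times
  their precision scalar: when two intrinsic null spaces overlap (the
  constant is in both the RW2 and the $\phi_s=1$ seasonal null space) the
  joint posterior precision is otherwise exactly singular; the jitter makes
  it factorisable and the constraints remove the affected directions from
  all summaries.
* **Hyperparameter level.** The log marginal posterior of the transformed
  hyperparameters (log precisions; Fisher-z of $\phi_s, p_1, p_2, \Phi$;
  $\log\tau, \log\kappa$) is the Laplace evidence plus the hyperprior,
  with generalised (rank-based) prior log-determinants for intrinsic
  blocks. The default strategy `eb` maximises it by BFGS and reads spread
  from the inverse Hessian at the mode — a 9-dimensional hyperparameter
  space makes dense integration grids unattractive; the `grid` strategy
  adds a star design of $2k+1$ points around the mode with
  evidence-weighted mixture summaries as a cheap check on the
  mode-only approximation.
* **Priors** (all configurable): log-gamma(1, 5e-5) on log precisions,
  standard normal on Fisher-z transforms, normal with sd 1 on
  $(\log\tau, \log\kappa)$ centred at the values implying $\sigma = 1$ and
  $\rho$ = 20% of the window diameter — weakly-informative defaults in the
  spirit of the usual SPDE defaults, which are not published as numbers.
* **Summaries.** Hyperparameters are summarised on their natural scale
  (mean and sd by the delta method, quantiles by monotone transformation of
  Gaussian quantiles). Latent quantities use Gaussian marginals
  (mean ± z·sd) without skewness correction — a simplification relative to
  full INLA, stated as a limitation below. Per-period predicted totals and
  their intervals come from Monte Carlo draws of the latent Gaussian
  (reproducible under the fit seed), with a Poisson predictive interval for
  realised counts.

If the hyperparameter Hessian is not positive definite, the fit falls back
to its diagonal with a warning. A non-positive-definite factorisation
anywhere in the evidence computation is treated as an error for that
hyperparameter value (never as a silent partial factorisation — a partial
factor would return a wrong log-determinant and create spurious evidence
ridges).

## The simulator

`simulate_pattern()` draws from exactly the generative model above: RW2
recursion (or a fixed path) for the trend, lag-$m$ recursion for the
seasonal, stationary AR(2) for the cycle, the stationary AR(1)-Matérn
field on the mesh, and covariates as (i) a nearest-centroid partition into
$k$ classes standing in for a climate classification, (ii) smooth low-order
spatial polynomials with seasonal modulation standing in for temperature
and rainfall surfaces, and (iii) distance to a polyline standing in for a
road network. Events are placed per period and triangle by thinning: a
homogeneous Poisson draw at the triangle's maximum vertex intensity,
uniform placement, acceptance with probability intensity/bound. Because the
exponential of a linear interpolant attains its maximum at a vertex, the
bound is exact and the sampler is unbiased for the piecewise log-linear
intensity — no grid discretisation is involved.

The `amazon_scenario()` preset mirrors the shape of a fire-occurrence
analysis: an irregular pentagon of roughly 100 × 70 km-units, eight
quarters, a V-shaped trend (decline then rise), dry-season seasonality
peaking in the third and fourth quarters, a mild cycle with PACFs
$(0.308, -0.366)$, a field with $\Phi = 0.842$, and positive-temperature /
negative-rainfall / negative-distance-to-road effects. Component magnitudes
are the package's own choices; only the signs and the dependence structure
mirror the motivating application.

What the simulator does **not** emulate: sensor artefacts of real fire
detections (swath gaps, detection confidence, duplicate detections),
irregular real geography, non-stationary fields, or covariate measurement
error. Passing recovery tests therefore demonstrates the correctness of
the estimation machinery under the model's own assumptions, not robustness
to their violation.

## Numerical choices

* Coordinates are planar km; lon/lat input is converted by a sinusoidal
  equal-area projection before any core computation.
* Point-in-triangle tests snap at $10^{-9}$ × window diameter; points on
  shared edges resolve to the lowest triangle index.
* Event-count guard: simulation aborts if the vertex-quadrature estimate of
  the expected count exceeds a cap (default $10^6$).
* Degenerate triangles (area below $10^{-12}$) abort assembly naming the
  triangle.
* All randomness flows through explicit integer seeds; identical
  configuration plus seed reproduces every artefact byte-for-byte (CSV
  output at 6 significant digits).

The correctness checks run at deliberate desk scale: the discretisation
oracle uses a 41 × 41 grid on a 10 × 10 window with range 2; parameter
recovery uses ~200 mesh vertices, 8 periods and a few thousand events per
replicate; decomposition recovery uses 16 periods. These sizes were chosen
so that each check isolates one property at comfortably sufficient
information content.

## Known limitations

* Latent marginals are Gaussian at the hyperparameter mode (or a small
  mixture); no skewness correction, so extreme-tail latent quantiles are
  approximate.
* Empirical-Bayes hyperparameter treatment understates hyperparameter
  uncertainty relative to full integration; the star-design `grid`
  strategy is a partial remedy, not a full CCD.
* The event-row predictor is resolved at dual-cell scale; sub-cell
  positional information is not exploited (refine the mesh to recover it).
* Separable space–time covariance only; no non-stationary $\kappa(s)$,
  $\tau(s)$, fractional operator orders, or meshes on the sphere.
* With quarterly data the seasonal and cycle components can alias: an AR(2)
  with complex roots near period 4 represents the same oscillation as the
  lag-4 seasonal, and the evidence may attribute the pattern to either. The
  trend, the fitted intensity and their sum are identified; the split
  between the two periodic components is not always.
* Windows with holes are not supported.
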