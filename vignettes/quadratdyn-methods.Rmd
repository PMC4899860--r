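---
title: "Models and methods in quadratdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in quadratdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

quadratdyn turns yearly maps of perennial plants in permanent 1-m²
("chart") quadrats into multispecies population models, and uses those
models to ask how communities respond to climate perturbations: how much of
a species' response is *direct* (its own vital rates react to climate) and
how much is *indirect* (its competitors' abundances change, and competition
changes with them). This vignette explains each stage of the pipeline, the
assumptions behind it, and the choices we made where the methodology left
them open.

## From maps to demography

Chart quadrats record every perennial plant as a basal-cover polygon (or a
point, for very small plants) in quadrat-local centimetre coordinates.
Demography requires individual identities through time, which maps alone do
not carry. The tracking algorithm assigns them geometrically:

1. every polygon of year *t−1* is dilated by a 5-cm buffer, absorbing
   mapping error and short-distance clonal movement;
2. each conspecific year-*t* polygon inherits the identity of the buffered
   antecedent with which it shares the greatest overlap area, or is labelled
   a recruit if it overlaps none;
3. genets may fragment (several year-*t* polygons inheriting one identity)
   and coalesce.

Overlap areas are integrated on a fine raster (default 0.25 cm), which
handles non-convex outlines without polygon-clipping machinery; the raster
resolution only has to rank overlaps correctly, not measure them to high
precision. **Tie-breaking.** A small year-*t* polygon is frequently
contained entirely within several buffered antecedent regions, making the
"greatest overlap" criterion a tie. We break ties by nearest antecedent
centroid, then larger antecedent area, then lexicographically smallest
genet id. The distance-first rule matters: breaking by area first
systematically reassigns small stationary plants to large neighbours, and
in validation against archives with known identities it pushed survivor
identity recovery from ~87% down from the ~100% the distance rule achieves.
A consequence of the buffering rule that no tie-break can remove: a genuine
new recruit that germinates within the buffered canopy of an established
conspecific is indistinguishable from a surviving fragment and will be
classified a survivor. Tests therefore score identity recovery on true
survivors (≥99% required) and only require that a majority of true recruits
be flagged.

For modelling, each genet-year is collapsed to a circle: area = the summed
area of its polygons, location = their area-weighted centroid; point plants
get a fixed 0.25 cm². Distances between genets are distances between
centroids; interspersed genets with coincident centroids simply get
distance zero, which every kernel below tolerates.

## Crowding

Plant–plant interactions enter the vital-rate models through a
neighbourhood crowding index with a Gaussian kernel,

$$w_{jm} = \sum_k u_k \, e^{-\alpha_{jm} d_k^2},$$

summing over all same-quadrat neighbours *k* of species *m*, with $u_k$
their areas (cm²) and $d_k$ the centroid distances (cm). The spatial-scale
parameters $\alpha_{jm}$ are inputs (per species pair), not fitted jointly
with the regressions; `estimate_alpha()` provides a likelihood grid search
for synthetic work, but the surface is informative only when crowding
effects are strong. No distance truncation is applied; the kernel decays
fast enough that none is needed. Crowding never crosses quadrat boundaries.

## Vital-rate models

Survival is a binomial GLMM on log size $u$,

$$\mathrm{logit}\, S = \gamma_t + \phi_g + (\beta + \beta_t) u
  + \boldsymbol\omega \cdot \mathbf w + \boldsymbol\eta \cdot \mathbf C
  (+\ \text{crowding} \times u,\ \text{climate} \times u),$$

with random year intercepts $\gamma_t$, random per-year size slopes
$\beta_t$, and random group intercepts $\phi_g$ (a group is a set of nearby
quadrats within one pasture). Growth models next log size with the same
structure; the residual variance about the growth curve is size-dependent,
$\sigma^2(\bar v) = a e^{b \bar v}$, fitted to the squared conditional
residuals by a Gamma GLM with log link. This exponential form follows the
standard usage in size-structured plant IPMs; it is stored as two
parameters and can be swapped.

Recruitment is modelled at the quadrat level (parentage is unobservable):
counts $y$ arriving in year $t+1$ are negative binomial with size $\theta$
and mean

$$\lambda_j = N'_j \exp\!\big(\gamma_t + \phi_g
  + \boldsymbol\omega \cdot \sqrt{\mathbf N'} + \boldsymbol\eta \cdot
  \mathbf C\big),$$

a Ricker-type form with the square root of cover in the exponent and
proportionality to the focal species' *effective cover*
$N' = p N_q + (1-p)\bar N_g$, a mixture of focal-quadrat cover and the
group mean acknowledging seed input from outside the quadrat
($p$ defaults to 0.5 and can be profiled by maximum likelihood over a
grid). Fitting uses glmmTMB's negative-binomial family with an offset on
$\log N'_j$; quadrat-years with zero focal effective cover are dropped
because the intensity is structurally zero there.

All fits are maximum likelihood (lme4, glmmTMB). Climate covariates are
standardised internally for optimizer stability — raw precipitation
(hundreds of mm) next to log sizes (a few units) produces extreme Hessian
eigenvalue ratios and spurious convergence warnings — and every coefficient
is transformed back to the raw scale before storage, so the parameter
containers and `tidy()` always speak raw units. Non-convergence is never
silent: fits carry a `converged` flag and the optimizer messages.

**Climate covariates.** Five per transition: prior water-year
precipitation, and critical-season precipitation and temperature in each of
the two transition years, plus optional within-year precipitation ×
temperature interactions (survival and growth only; excluded from
recruitment, where they hinder convergence). Stepwise AIC selection is
bidirectional and deterministic. The search objective includes a random
year intercept: climate covariates explain *between-year* variation, and
scoring them with plain fixed-effects regressions lets thousands of
pseudo-replicated transitions make spurious covariates look significant.
With the year term, the per-candidate false-inclusion rate is the AIC
asymptotic ~0.16, so null data select more than two of the five covariates
only rarely (~4%); the null-calibration test is stated in those terms. An
interaction becomes eligible only when both its parent terms are in the
model. Year replication — not genet count — is what identifies climate
coefficients; recovery harnesses therefore use archives with ~20 years
rather than piling transitions into few years, where Wald standard errors
for between-year terms are anticonservative.

**Variance explained by climate.** For each vital rate we compare a
*constant* model (no temporal terms), a *climate* model, and a *full* model
(climate plus year effects) and report
$(X_\mathrm{constant} - X_\mathrm{climate}) /
 (X_\mathrm{constant} - X_\mathrm{full})$,
with $X$ the residual sum of squares (growth) or residual deviance
(survival, recruitment). Sampling noise can push the ratio slightly outside
[0, 1]; it is clipped with a warning, and an exactly degenerate triplet
returns `NA`.

## Two simulation engines

**The IBM** is spatially explicit and demographically stochastic: Bernoulli
survival, Normal growth with the fitted variance function, negative
binomial recruits placed uniformly at random at the point-plant size
(0.25 cm², the mapped minimum — recruit size is otherwise unobserved).
Boundaries are absorbing by default (neighbours outside the quadrat do not
exist), matching the historical hindcast protocol: initialise with the
plants observed in a quadrat's first census, step forward with
year-specific parameters in chronological order, re-initialise after census
gaps, and average cover over replicate runs. A "climate only" mode zeroes
the year deviations to isolate what the climate covariates explain. A
periodic-boundary mode exists for comparisons against the spatially
implicit IPM, whose mean-field crowding assumes an edge-free plane.

**The IPM** is environmentally stochastic but demographically
deterministic: each species is a density $n(u, t)$ over log size on a
shared midpoint-rule mesh (default 100 nodes from $\log 0.2$ to
$\log 400 + 1$; the mesh must extend past the sizes the community reaches,
and a convergence test doubles the mesh to confirm one-step cover changes
by less than 0.1%). The kernel combines fitted survival and growth;
recruitment, being a quadrat-level function of total cover, is applied as
an inflow of $\lambda_j$ recruits at the recruit-size node rather than as a
per-capita kernel column — equivalent to per-capita fecundity proportional
to $e^u$, so that total recruitment tracks total cover.

Crowding in the IPM is spatially implicit. For heterospecifics, random
spatial arrangement gives the closed-form expectation
$\pi/\alpha_{jm} \times$ cover density — the Gaussian kernel integrated
over a homogeneous plane — which a Monte-Carlo placement oracle confirms.
Conspecifics are not random in real quadrats: large genets segregate
without overlapping. The "no overlap" rule excludes neighbour centres
within the sum of the two circle radii $r(u) + r(u')$, and for the Gaussian
kernel this exclusion integrates in closed form to a factor
$e^{-\alpha (r(u)+r(u'))^2}$, cached as a mesh × mesh matrix per species.
The rule earns its keep empirically: in the cross-engine validation the IPM
tracks the 200-replicate IBM ensemble mean within Monte-Carlo error with
the rule on, and sits visibly above the band with it off, because
density-dependent mortality thins crowded neighbourhoods in the IBM exactly
as the exclusion approximates. Since per-step z-scores along a trajectory
are strongly autocorrelated, the cross-engine test uses trajectory-level
statistics (RMS standardised deviation, and mean absolute deviation against
the mean Monte-Carlo standard error) rather than per-step bands.

At each stochastic step one observed climate year and, independently, one
set of random year effects are drawn. The drawn *indices* do not depend on
the table contents — this is the common-random-numbers contract that makes
paired perturbation runs exactly comparable.

## Coexistence measures

Equilibrium cover comes from initialising all species at very low cover and
averaging over a post-burn-in window (defaults 500 + 2,000 steps; a
no-trend diagnostic — OLS slope of cover on step with CI covering zero —
certifies the window). A species' *equilibrium frequency* is its share of
total community cover.

The *invasion growth rate* runs the residents to stochastic equilibrium
without the focal species, introduces the focal as a recruit-sized point
mass at cover $10^{-6}$ cm², and then repeatedly: advances one step,
records $\log(C_{t+1}/C_t)$, and rescales the focal's density back to
$10^{-6}$. Rescaling (rather than resetting to the recruit point mass)
lets the invader's size structure converge to the invasion structure while
keeping it demographically invisible; the IGR is the mean of the step log
ratios over 1,000 steps by default, i.e. the log of the geometric mean
growth factor. Residents evolve freely between repeats; only the focal is
reset.

*Negative frequency dependence* (NFD) is the slope of the line through
(frequency ≈ 0, IGR) and (equilibrium frequency, 0): $-\mathrm{IGR}/f_{eq}$,
negative exactly when the species can invade. It is the community-level
proxy for niche differences: in the shipped scenarios the slope orders
correctly with the interspecific-to-intraspecific interaction ratio (0.2 →
0.6 → 0.9 gives slopes of roughly −0.39 → −0.15 → −0.03 per unit
frequency).

## Perturbation experiments

Three perturbation kinds: precipitation means × 1.01 (multiplicative, 1%);
temperature means + 1% of the site mean (additive by default — multiplying
°C is origin-dependent, though a multiplicative mode exists); and a
variability perturbation that scales every covariate's anomalies by
$\sqrt{1.10}$, multiplying each sample variance by exactly 1.10 with means
untouched. Interaction covariates are recomputed from the perturbed bases,
never perturbed independently. Interaction *coefficients* are held
constant throughout, so indirect effects arise only through abundance
changes.

The *full effect* is the equilibrium-cover change when all species see the
perturbed climate; the *direct effect* perturbs only the focal species'
climate inputs while competitors see observed climate, with both runs
sharing the baseline's seed; the *indirect effect* is full − direct,
exact under common random numbers. Effects are also reported proportionally
(divided by baseline cover) and as the log ratio
$\log(|\text{prop indirect}| / |\text{prop direct}|)$, positive when
indirect effects dominate. The community-level variance of raw direct
effects (shared by every species of a site × perturbation) and the NFD
slope are the two fixed effects of the synthesis model: a linear
mixed-effects model for the absolute magnitude of raw indirect effects,
with random intercepts for site and perturbation nested in site, fitted by
maximum likelihood (nlme), degrading gracefully to simpler structures when
the grouping is singular.

The "pure-indirect" scenario demonstrates that the framework can express
the qualitative reversal: a climate-insensitive focal species whose
competitor is strongly climate-sensitive shows a direct effect of exactly
zero and a substantial indirect effect.

## The synthetic-data generator

Every stage is testable without field data because the generator runs the
IBM from known ("ground truth") parameters and emits the same artefacts a
digitised archive would: polygon maps (circles rendered as exact-area
regular 16-gons, vertices clamped to the quadrat, points for plants at the
0.25-cm² floor), plus the hidden true identities and recruit flags.

Scenario parameters were chosen once to represent a semi-arid grassland
community at a realistic scale and validated only for persistence:
per-species cover of a few hundred cm² (2–6% of the quadrat, basal cover
being sparse in these systems), ~50–150 genets per quadrat, survival ~0.9
for established plants, mean genet area ~10 cm², negative-binomial
recruitment with $\theta = 2$, Gaussian interaction scale
$\alpha = 0.01\ \mathrm{cm^{-2}}$ (~10 cm interaction range), year-effect
standard deviations of 0.25 (survival), 0.12 (growth) and 0.3
(recruitment) on the linear predictor, and climate drawn independently per
year (no autocorrelation, matching the simulation protocol) with means and
standard deviations typical of the region (e.g. water-year precipitation
300 ± 60 mm). Climate effect sizes are set so that recovery is possible at
roughly 5,000 transitions spread over ~20 years — about one eighth of a
standard deviation of the linear predictor per climate standard deviation.
Scenarios differ in the interspecific-to-intraspecific interaction ratio
and in the climate terms, as described above; a `climate_effects = FALSE`
variant of the template scenarios zeroes every climate coefficient for
false-positive calibration.

What the generator does *not* emulate: mapping error and digitisation
noise (polygons are exact), observer-missed plants, spatially
autocorrelated recruitment, temporal climate autocorrelation, and
movement of genets (circles stay put, which is why tracking accuracy on
synthetic archives is an upper bound on field performance). Passing tests
on synthetic data therefore certify the machinery — estimators recover the
parameters that generated the data, the two engines agree, the
decomposition identities hold — not the field realism of any particular
parameter value.

## Numerical choices and problem sizes

Raster resolution 0.25 cm for overlap ranking (0.1 cm where areas
themselves are asserted); mesh 100 nodes with the doubling check; midpoint
rule throughout; growth kernels need their Normal sd resolvable on the mesh
(sd > one cell) and mass away from the mesh edges, which the mesh limits
guarantee for all shipped parameter sets; negative densities (impossible
analytically, possible numerically) are clipped at zero. Equilibrium runs
in the test-suite and the acceptance script use burn-ins of 250–300 steps
and windows of 500–700 steps with 100-node meshes, archives of 6 × 20
quadrat-years for transition-level fits and 25 × 21 for quadrat-level
recruitment, 200 IBM replicates for the cross-engine ensemble, and 400–600
invasion steps; these sizes hold every Monte-Carlo standard error well
below the effects being measured while keeping the whole pipeline
runnable on a laptop in minutes. Defaults in `default_config()` (500 +
2,000 equilibrium steps, 1,000 invasion steps, 50 hindcast replicates)
are the sizes a production analysis would use.

## Known limitations

- Identity tracking cannot separate a recruit germinating under an
  established conspecific canopy from a fragment; recruitment rates near
  large adults are biased low by construction of the algorithm.
- The IPM's mean-field crowding ignores edge effects and any spatial
  pattern beyond the conspecific exclusion rule; communities with strong
  heterospecific aggregation would violate its assumptions.
- $\alpha$ values are treated as known inputs; the grid-search utility is
  honest about the flatness of the likelihood surface when crowding effects
  are weak.
- The synthesis model treats NFD and direct-effect variance as measured
  without error, as in the original formulation.
- Single-quadrat simulations make the effective-cover mixture inert
  (group mean = own cover); $p$ matters only when groups of quadrats are
  simulated or fitted jointly.
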