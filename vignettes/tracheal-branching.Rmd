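---
title: "Models and methods: tracheal branching geometry and CO2 transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: tracheal branching geometry and CO2 transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracheoflux)
```

This vignette is the package's own account of the models it implements,
the choices made where the design was genuinely open, and what the tests
do and do not establish.

## The branching exponent

A branching event is one parent branch of radius $r_i$ and its $2$--$4$
children $r_j$ (radii in $\mu$m throughout the measurement layer; SI
units appear only inside the gas-exchange module). The exponent
$\alpha$ in

$$r_i^{\alpha} = \sum_j r_j^{\alpha}$$

summarises the local geometry: $\alpha = 2$ preserves summed
cross-sectional area across the event (Da Vinci's rule), $\alpha = 3$
increases it (Murray's law, the optimum for laminar liquid flow), and
$\alpha = 1$ conserves the summed *radius*, so area shrinks with each
branching. Dividing by $r_i^{\alpha}$,

$$g(\alpha) = \sum_j (r_j/r_i)^{\alpha} - 1,$$

and when every child is strictly smaller than its parent each term is a
decaying exponential in $\alpha$, so $g$ is strictly decreasing,
$g(0^+) = n_{\text{children}} - 1 > 0$, $g(\infty) = -1$: the root
exists and is unique. `solve_branching_exponent()` brackets it in
$(10^{-6}, 64)$ — doubling the upper bound as needed, since siblings
nearly as large as their parent push the root arbitrarily high — refines
with `uniroot`, and polishes with a Newton step or two until
$|g| \le 10^{-10}$ (the `tolerance` argument). Events with
$\max_j r_j \ge r_i$ admit no root; they are excluded and counted, never
imputed. The estimate is scale-invariant by construction ($g$ depends
only on ratios), which the tests verify to $10^{-10}$.

Summaries follow the classical pipeline (`summarize_exponents()`):
median and skewness of raw $\alpha$, then a $\log_{10}$ transform (the
raw distribution is right-skewed) and two-sided one-sample t-tests of
the mean $\log_{10}\alpha$ against $\log_{10} 2 \approx 0.30$ and
$\log_{10} 3 \approx 0.48$. Skewness is the moment estimator
$m_3/m_2^{3/2}$ — the common default, and the quantity is only used
descriptively. A constant sample tested against a different reference
has no defined t statistic; it is flagged, not thrown.

`pooled_individual_alpha()` fits one exponent across all of an
individual's events by minimising $\sum_e g_e(\alpha)^2$ with each event
normalised by its own parent radius (so events at different scales weigh
equally). Least squares is a reconstruction — a single shared root
rarely exists exactly — and with one event it reduces to the exact root.

## The regression test

For each candidate $\alpha \in \{1,2,3\}$, `transform_power()` forms
$x = r_i^{\alpha}$, $y = \sum_j r_j^{\alpha}$; the candidate under which
the fitted slope is closest to 1 wins (`compare_alphas()`). Two fits are
reported:

* **Origin-forced OLS** (`ols_through_origin()`): slope
  $\sum xy / \sum x^2$, SE
  $\sqrt{\sum(y-bx)^2/(n-1)/\sum x^2}$, t-based CI with $n-1$ df.
  Forcing the origin expresses the physical constraint that a vanishing
  parent has vanishing children.
* **Major Axis (Model II)** (`major_axis()`): appropriate because both
  axes are powers of radii measured the same way, so carry equal error.
  Slope and free intercept come from the first principal axis of the
  covariance matrix. The default CI inverts the exact rotation F test:
  rotating the data by angle $\theta$, the covariance between residual
  and axis scores is sinusoidal in $2\theta$ while the covariance
  determinant is rotation-invariant, so the acceptance region is
  $\tan(\hat\theta \pm \tfrac12 \arcsin\sqrt{q})$ with
  $q = F_{1-\gamma;1,n-2}\,\det S / ((n-2) R^2)$. Perfectly collinear
  data collapse the interval to a point; $q \ge 1$ means the axis
  orientation is unresolved and the CI is reported unbounded. A
  percentile bootstrap (`ci = "bootstrap"`) is provided as the
  alternative; the two agree on simulated data and the F interval's
  empirical coverage sits at its nominal level.
* **Species random intercept** (`random_intercept_fit()`): $y \sim x$
  with a per-species intercept (REML, via `nlme`) guards against the
  slope being an artefact of between-species size differences. One
  species, or a degenerate fit, falls back to OLS with a warning.

Outliers — events "clearly outside the size range" of the rest — have no
canonical definition, so `exclude_outliers()` uses a conservative
interquartile fence on parent radius per event class
($k = 3$ by default, configurable); flags are recorded and counted,
never silently dropped, and every result reports
`n_used + n_excluded = n`.

## The gas-exchange model

`build_geometry(alpha)` constructs the model ant: behind each spiracle a
symmetric tree of five bifurcating levels, level 1 at the spiracle and
level 5 at the tissue, $n_l = 2^{l-1}$ branches of length $L_l$
(1569, 976, 586, 352, 211 $\mu$m; 3694 $\mu$m total path) and radii
grown outward from $r_5 = 3\,\mu$m by the branching rule
$r_l = 2^{(5-l)/\alpha} r_5$. Symmetry reduces the tree to a 1-D serial
chain with effective cross-section $a_l = n_l \pi r_l^2$.

**Steady-state diffusion with distributed influx.** Within each level,
Fick diffusion (Krogh's constant $K$) with a uniform wall source on the
influx levels (3--5, where tissue exchange occurs):

$$\frac{d}{dx}\!\left(K a_l \frac{dp}{dx}\right) = -\varphi\, w_l,
\qquad w_l = n_l\, 2\pi r_l,$$

with $\varphi$ the influx density (m$^3$ CO$_2$ m$^{-2}$ s$^{-1}$) and
outward flux $J(x) = K a_l\, dp/dx$. Three boundary conditions close the
system: $J = 0$ at the blind level-5 tips, $p = 0$ at the open end (all
pressures are CO$_2$ partial pressures above the external air), and
$p = \Delta pp$ (default 6 kPa; 4 and 8 kPa scenarios) at the tips.
Because everything is linear in $\varphi$, the solution is closed-form:
$J(x) = \varphi W(x)$ with $W$ the influx wall area distal to $x$, and

$$\varphi = \frac{K\,\Delta pp}{\displaystyle\int_0^{X}
\frac{W(x)}{a(x)}\,dx},$$

giving a piecewise-quadratic pressure profile and the exact spiracle
identity $J(0) = \varphi \times$ total influx wall area. With no influx
levels the tip condition is dropped and the model degenerates to the
series-resistance flux $\Delta pp / \sum_l L_l/(K a_l)$
(`series_flux_no_influx()`), which doubles as an independent check of
the resistance assembly. An air sac at level 3 or 4 is a pressure
release: the domain truncates to the levels from the sac inward, and
efflux proximal to the sac is *projected* (carried unchanged), since the
sac removes the proximal resistance. The analytic solution is verified
against an independent $10^4$-node quadrature oracle to better than
$10^{-4}$ relative error in all 27 sweep scenarios.

Whether the wall source should scale with wall *area* or with branch
*length* is not determined by the physics alone; both are implemented
(`influx_mode`), defaulting to wall area since the influx is a flux per
unit area. Whole-organism fluxes multiply the per-spiracle value by
$2 \times 6$ abdominal spiracle pairs and are compared against mean
literature CO$_2$ production of resting (10.63 $\mu$l h$^{-1}$) and
walking (115 $\mu$l h$^{-1}$) ants; `convert_metabolic_rate()` maps
O$_2$-consumption (respiratory quotient 0.84 by default) and
metabolic-power records (oxyjoule equivalent 20.1 J ml$^{-1}$ O$_2$)
onto that scale, and `tissue_level_flux()` divides by the 70% of body
mass treated as metabolically active.

**Periodic convection.** `convective_flux()` models discontinuous
ventilation: each compression expels a fraction (default 66%) of the
whole airway at frequency $f$ (default 0.26 Hz, both from empirical
observations of tracheal compression), carrying CO$_2$ at the local
steady-state partial pressures, so the per-breath CO$_2$ volume is
$\text{fraction} \times V_{\text{airway}} \times \bar p / P_{\text{atm}}$.
Two conventions for $\bar p$ are implemented: the mean of $p(x)$ along
the airway path (`pp_averaging = "length"`, default) and the
volume-weighted mean (`"volume"`). The length-averaged reading is the
default because, over the area-reducing steady state at 6 kPa, it yields
$\approx 0.24\,\mu$l h$^{-1}$ per spiracle — matching published
estimates of the convective gain for a model ant — where the
volume-weighted form gives $\approx 0.14$. Flux is exactly linear in
frequency and evacuation fraction, so gains scale directly with activity.
$P_{\text{atm}} = 101.325$ kPa is configurable; external CO$_2$ is the
zero of the pressure coordinate.

## The synthetic-data generator

`generate_dataset()` emulates the *structure* of the empirical design so
the pipeline can be tested with known truth: 165 individuals from 20
species by default; level-1 radii lognormal around a 25 $\mu$m median
(log-sd 0.25, bracketing printed example radii of 29.15 and 32.83
$\mu$m) with a per-species multiplicative intercept (log-sd 0.1,
moderate interspecific variation); 2--4 level-2 children with
probabilities 100:61:4 over 165; level-2 branches a and b each
bifurcating into level-3 children. Child radii invert the branching
relation exactly — symmetric-Dirichlet partition weights $w_j$ (sum 1,
concentration 8, resembling a 17.67/14.44 sibling split) with
$r_j = r_i w_j^{1/\alpha}$ — then receive multiplicative lognormal
measurement noise (log-sd 0.05 by default, a few-percent error
consistent with pixel-limited imaging; additive noise is an option, and
radii can be quantised to a 7.6 $\mu$m measurement grid). Individuals
with 3--4 children are assigned to a designated species group (10% of
species), mirroring the restriction of multi-furcations to a single
genus while keeping the marginal child-count mix exact.

The generator is for pipeline testing and parameter recovery only. It
does **not** model real interspecific allometry (no radius--body-size
relation), branch lengths, within-individual correlation beyond the
shared parent radius, or any systematic asymmetry between the a and b
branches. Passing recovery tests therefore show that the estimators
invert the assumed generative model at realistic noise — not that real
tracheal data satisfy that model.

## Numerical choices and degenerate inputs

* Root bracket $(10^{-6}, 64)$ with doubling expansion to $10^6$;
  solver tolerance $10^{-10}$ on $|g|$.
* The pooled fit uses `optimize` on $(10^{-3}, 64)$ with a local
  refinement pass around the minimum.
* Child order within an event follows the input's `branch_path` labels;
  nothing is reordered, so the "a" and "b" designations are the data's.
* A diameter-valued input column is halved on read
  (`values = "diameter"`).
* Validation reports *all* problems with row numbers rather than
  stopping at the first; empty tables are valid and propagate to empty
  (reported) results.
* All randomness funnels through configuration seeds; pipeline outputs
  embed the seed and a config digest, and identical configurations
  reproduce outputs byte-identically.

Test problem sizes: recovery tests use 200 individuals at noise log-sd
0.05 (and 40 replicates of 60 individuals at log-sd 0.1 for the
winner-stability property); the solver--closed-form comparison runs
1000 random symmetric events; the diffusion oracle uses $10^4$ nodes
per scenario. The whole suite runs in well under a minute.

## Known limitations

* The diffusion model is steady-state and CO$_2$-only: no O$_2$
  co-transport, no unsteady dynamics, no inter-spiracle connectivity,
  and no liquid-phase transport in the finest tracheoles.
* The air-sac treatment assigns the sac no resistance and projects
  (rather than models) efflux proximal to it.
* The influx-convention and pressure-averaging switches are genuine
  model degrees of freedom; defaults are stated above with their
  rationale, and both alternatives remain available.
* The mixed-model check estimates a single variance component
  (species intercepts); it is a guard, not a comparative phylogenetic
  analysis.
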