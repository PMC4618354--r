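---
title: "Modelling the shape of an auxin pulse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the shape of an auxin pulse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(auxinpulse)
```

## The problem

In the classic pulse-labelling assay, radio-labelled auxin (IAA) is
applied at the apical end of a stem or coleoptile segment, transported
basipetally for some time, and the segment is then cut into (typically
2 mm) pieces whose label is counted. The resulting amount-vs-position
profiles move at a roughly constant velocity $v$ (mm/hr) and broaden at
a roughly constant *spreading rate* $\rho = d\,\mathrm{Var}/dt$
(mm²/hr). `auxinpulse` implements a family of compartmental
advection–diffusion models of this process, the estimators used to
measure $(v, \rho)$ from noisy segment counts, and the closed-form
relations connecting the two.

## Flux laws

All movement is described by fluxes per unit membrane area
(concentration × cm/s), positive from the first-named compartment to
the second (basipetal for axial faces). Concentrations are in arbitrary
model units; under saturation only the ratio to $K_m$ matters.

* **Linear polar + diffusion-like** (`linear_flux()`):
  $\phi = p\,a_{up} + q\,(a_{up} - a_{down})$, with polar permeability
  $p$ and symmetric permeability $q$ (cm/s).
* **Carrier algebra** (`transporter_flux()`, `derive_pq()`): with
  exporter permeabilities $\alpha_1$ (basal face of the upper cell) and
  $\alpha_2$ (apical face of the lower cell), equal importer+passive
  permeability $\beta$ on both faces, and an apoplastic gap of width
  $L_0$ and diffusivity $D_0$, eliminating the wall concentrations
  gives $\phi = (\alpha_1 a_1 - \alpha_2 a_2)/(2 + r)$,
  $r = \beta L_0/D_0$, i.e. $p = (\alpha_1-\alpha_2)/(2+r)$,
  $q = \alpha_2/(2+r)$ and $q/p = \alpha_2/(\alpha_1-\alpha_2)$. A
  large $q/p$ therefore requires nearly apolar export.
* **Michaelis–Menten saturation** (`saturating_flux()`):
  $\phi = \kappa_1 a_1/(K_m+a_1) - \kappa_2 a_2/(K_m+a_2)$. A coupling
  that is linear with permeability $s$ at low concentration is obtained
  with $\kappa_1 = \kappa_2 = K_m s$.
* **Asymmetric lateral exchange** (`asymmetric_lateral_flux()`):
  $\phi = s_{fwd} a_1 - s_{rev} a_2$, used for the tonoplast, where the
  pH difference between cytosol (7.2) and vacuole (5.5) biases passive
  movement. Passive permeabilities follow the chemiosmotic rule
  $P_{IAAH} \cdot 1/(1+10^{pH-pK})$ with $pK = 4.7$
  (`passive_permeability()`); with $P_{IAAH} = 4\times10^{-5}$ cm/s
  this evaluates to $1.26\times10^{-7}$ (cytosol) and
  $5.47\times10^{-6}$ cm/s (vacuole). (Published roundings of these two
  numbers, $1.2\times10^{-7}$ and $5.6\times10^{-6}$, differ in the
  last digit from the direct computation; the package reports the
  computed values.)

## Closed-form kinetics

For a file of well-mixed cells of length $L$ the pulse obeys $v = p$
and $\rho = L(p + 2q)$, and is asymptotically gaussian with mean $vt$
and variance $\rho t$ — the justification for gaussian profile fits.
With finite intracellular diffusion $D$,

$$\frac 1 v = \frac 1 p + \frac{L}{2D}\Bigl(1 + \frac{2q}{p}\Bigr),
\qquad \rho \le L v \Bigl(1 + \frac{2q}{p}\Bigr),$$

the bound approached as $D \to \infty$. Inverting the first pair gives
`infer_qp()` ($q/p = (\rho/(Lv) - 1)/2$), and the $p \to \infty$ limit
of the second pair gives the smallest diffusion constant compatible
with an observed spreading rate, $D_{min} = \rho/2$ (`min_diffusion()`;
the derivation is in the function's documentation). Lateral movement
through a tissue combines intracellular diffusion and membrane
crossing in series: $1/D_{eff} = 1/D + 1/(ws)$
(`effective_diffusion()`).

Internally everything is computed in CGS units (cm, s); the
presentation layer converts to mm/hr and mm²/hr with the `units`
helpers, which are exact inverses of each other.

## The simulator

Cells are bricks $L = 100\,\mu m$ long, $20\,\mu m$ wide and deep,
split lengthwise into $N = 5$ axial compartments; a channel is a file
of such cells, and a tissue an ordered set of channels coupled
laterally. The update is an explicit forward-Euler step of length
$\Delta = 1/20$ s on compartment amounts:

* within a cell, adjacent compartments exchange diffusively with
  permeability $D(N-1)/L$, the discretization under which the
  computational velocity relation
  $1/v' = 1/p' + (N-1)/(2D')(1+2q'/p')$ maps exactly onto the
  continuous one via $p = p'L/(N\Delta)$ and
  $D = D'L^2/(N(N-1)\Delta)$ (`convert_computational_*()`);
* cell boundaries use the channel's axial law (linear or saturating);
* adjacent channels exchange laterally through their coupling law over
  the shared face of each compartment.

Every transfer is antisymmetric, so closed-system mass is conserved to
rounding error (tested to $10^{-9}$ relative over $10^5$ steps).

**Stability guard.** Before running, the worst-case fractional outflow
per compartment per step is computed from the permeabilities; if it
reaches 0.5 the constructor aborts and names the offending face. This
turns silent blow-up into a diagnostic; the guard also implies
nonnegativity of all amounts under linear laws. The classic parameter
sets satisfy the guard at $\Delta = 1/20$ s; the strongly coupled 21-
and 30-channel presets use $\Delta = 1/25$ and $1/80$ s respectively.

**Lateral sub-split.** When a lateral coupling is strong
($w s > 0.1\,D$ for an adjacent channel, a threshold chosen so that
membrane crossing faster than a tenth of cytoplasmic diffusion is
resolved rather than lumped), each compartment of that channel is
split width-wise into two sub-columns coupled by intracellular lateral
diffusion ($2D/d$ between sub-column centers).

**Boundaries and loading.** Both stem ends are no-flux; the default
stem is 300 cells (30 mm) so pulses never reach the basal end within
simulated times, and the simulator warns if more than 1% of the mass
does. Loading deposits into the apical-most cell of the target
channels, either at a constant rate (the classic protocol: 15 min of
uptake, 15 min wait, so experimental "zero time" is 30 min of
simulated time and the "30 min" profile is at 60 min) or
instantaneously in the first computational cycle. After loading,
recorded distributions are normalised to total 1. Whether loading in
multi-channel models targets all channels or a subset is configurable;
the scaled-model presets load all channels, the saturating
(`fig10`-style) presets load channels 2–6 only.

**Subnormal flush.** Amounts below $10^{-250}$ are flushed to zero
during the update: the far tail of a pulse otherwise decays into
subnormal floating-point numbers, which slows the arithmetic by orders
of magnitude without affecting any measurable quantity.

**Randomization experiments.** `perturb_model()` scales each
cell-boundary flux by an independent factor $1 \pm 20\%$ and each
cell's internal diffusive exchange by $1/f$ with $f \sim 1 \pm 20\%$ —
the permeability-equivalent of randomizing cell length. The
accompanying shift of compartment positions is neglected (second-order
for length variations of this size). Both perturbations leave the
single-channel spreading deficit intact, which is the point of the
experiment.

## Measuring $v$ and $\rho$

`bin_profile()` reproduces the experimental observable (2 mm segment
sums). Three estimators of pulse shape are provided:

* `profile_moments()` — amount-weighted mean and variance; sensitive
  to trailing components far from the peak;
* `gaussian_least_squares()` — Levenberg–Marquardt fit of
  $A e^{-(x-\mu)^2/2\sigma^2}$ over bin midpoints, initialized from the
  moments, with $\sigma$ bounded below by half the bin width, and
  unweighted by default (a counting-error weighting is available);
* `maximal_fit()` — the peak-region fit: start from the 5 bins centered
  on the global maximum and greedily extend one bin at a time on the
  side that least increases the normalized RMS residual of a re-fit
  gaussian, stopping when no extension keeps the residual within 5% of
  the fitted amplitude (ties toward the apical side). This realizes
  "select the peak region and ignore the flanks"; the specific greedy
  rule is this package's interpretation of that idea, chosen because
  it is deterministic and needs no tuning per data set.

`estimate_kinetics()` regresses fitted means and variances on time
(ordinary least squares, standard errors from the regression). Because
any loading history only adds a constant to the variance, the slope
$\rho$ is invariant to it — which the tests verify. For simulated
trajectories, `trajectory_kinetics(..., method = "field")` uses the
exact (unbinned) field moments: binning into 2 mm segments causes a
small aliasing wobble of the variance as the pulse shifts within bins,
which is part of the experimental estimator but should be excluded
when comparing against closed forms. `empirical_spreading_rate()`
implements the two-time variance procedure (variance at 30 and 60 min
of a pulse started in a single compartment), and
`surrogate_spreading_rate()` the fallback $|Var(t)-Var(0)|/t$ used
where weak coupling makes the variance grow superlinearly. The
surrogate is implemented with an absolute value: written literally,
$(\mathrm{Var}(0)-\mathrm{Var}(t))/t$ is negative for a spreading
pulse, so the magnitude is clearly what is meant.

## The synthetic-data generator

`generate_profiles()` emulates the structure of the historical data
sets: 2 mm segment bins, one profile per transport time, and Poisson
counting noise (radioactivity counting; a Gaussian option is
deliberately omitted). Expected profiles come either from a generating
tissue model or from the parametric gaussian
$N(\mu_0 + vt,\ \sigma_0^2 + \rho t)$. A trailing component — the
slow-moving or immobile label observed behind real pulses — is mixed
in as an exponential decaying from the apical end
(`add_trailing_component()`); its true shape in the historical data is
unknown, exponential is an assumption. The default experiment
(`goldsmith_like_fixture()`) uses $v = 10.7$ mm/hr, $\rho = 26$ mm²/hr
(the least-squares estimates for the classic coleoptile data), six
times spanning 0–2 hr, $10^4$ expected counts per profile, and 10%
trailing contamination with a 4 mm decay length; $\mu_0 = 3$ mm and
$\sigma_0^2 = 2$ mm² give the zero-time pulse a realistic width. What
passing recovery tests show is that the estimators are unbiased and
reasonably precise *under this noise model*; real profiles contain
additional structure (fast components, segment-to-segment calibration
drift) that the generator does not emulate.

## Scenario presets and their parameters

The named scenarios collect the parameter sets of the model family
(all D = 5×10⁻⁶ cm²/s unless noted):

| scenario | channels | key parameters |
|---|---|---|
| `fig3_single_channel` | 1 polar | $p = 4\times10^{-4}$, $q/p = 0.052$ |
| `fig5_minimal(s)` | polar + apolar | $p = 1.4\times10^{-3}$, $q = 0$; coupling $s$ |
| `fig6_scaled(n)` | $n \in \{2,6,21,30\}$, 1/3 polar | $s$ = 7.1e-6, 8e-5, 1.4e-3, 1.2e-2 |
| `fig7_polarity_ratio(a)` | two polar | $p_{left} = \alpha p$, $p_{right} = (1-\alpha)p$ |
| `vacuole(passive)` | cytosol (1 µm) + vacuole (9 µm) | $s_{cyt}, s_{vac}$ passive or width-rescaled |
| `fig4_saturation(u)` | 1 saturating | $\kappa_1 = 10^{-6}$, $K_m = 10^{-3}$, uptakes 0.3/1/2 |
| `fig10_brewer(site, u)` | 6 channels | lateral $K_m s$ couplings, weak 5–6 link |
| `s6_four_channel(u)` | 4 channels | D = 3×10⁻⁶, saturating laterals |

Channel counts for the scaled models follow the sketches (7 polar of
21); the 30-channel split (10 polar) is not stated anywhere and is set
by analogy. For the saturating presets the uptake-to-concentration
calibration is a single constant (default $10^{-3}$ model units per
ng) chosen once so that the classic uptake series 0.45–95.9 ng spans
the linear-to-saturated transition of $K_m = 10^{-4}$; only the
qualitative ordering of the curves is meaningful, since no absolute
mapping between nanograms and model concentration exists. The Brewer
presets run on a 60 mm stem so that 4 hr of transport stays clear of
the basal boundary.

Scenario configurations round-trip through YAML
(`write_scenario_config()` / `read_scenario_config()`), and a thin
command-line wrapper over the exported functions is installed at
`inst/scripts/auxinpulse.R` (subcommands `analyze`, `fit`, `scenario`,
`synth`, `list-scenarios`).

## Numerical choices and degenerate inputs

* Nonlinear fits are initialized from profile moments and bounded
  ($A \ge 0$, $\sigma \ge$ half bin width); all-zero or single-bin
  profiles raise fit-failure errors rather than returning garbage.
* `infer_qp()` warns (rather than errors) when $\rho < Lv$, because
  measured spreading rates carry error bars; the negative value is
  returned flagged.
* `derive_pq()` with $\alpha_1 = \alpha_2$ reports $p = 0$ and an
  infinite $q/p$ with a warning.
* Kinetics regressions with exactly two time points report zero
  standard error (the slope is exact, its uncertainty undefined).
* Tie-breaks in `maximal_fit()` go toward the apical side, matching
  the convention that trailing contamination sits apically.

## Problem sizes

The test suite and the acceptance script use 200–300-cell stems
(20–30 mm) and 1–2 hr of simulated transport for the linear models,
and a scaled-down two-uptake contrast for the saturating six-channel
model; these sizes leave the measured quantities within a few percent
of longer runs (the grid-refinement and boundary-warning tests bound
the error) while keeping a full run of everything in minutes on one
core.

## Known limitations

* The vacuole preset with passive tonoplast permeabilities yields a
  spreading contribution of ~4 mm²/hr with the minimal-model polar
  channel; published discussion of this configuration suggests a
  smaller value (~2.6) but does not print the polar permeability used,
  and exchange-dispersion theory
  ($2 f(1-f)v_1^2/(k_1+k_2)$ with $k_1 = s_{cyt}/d_{cyt}$,
  $k_2 = s_{vac}/d_{vac}$) confirms the package's number for the
  stated parameters.
* 1-D channels only: no 2-D/3-D tissue geometry, no growth, no auxin
  metabolism or decay, no receiver-block export.
* The correction function relating the single-channel $\rho$ to
  $pL/D$ and $q/p$ has no closed form here; only its empirical
  two-time estimation procedure is provided.
* Randomized cell length enters through permeability scaling, not
  through actual geometry changes (see above).
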