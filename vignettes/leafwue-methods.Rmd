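---
title: "Model and methods behind leafwue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind leafwue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`leafwue` simulates one day of gas exchange of a single, fully expanded,
well-watered C3 leaf (the default parameterisation is for cucumber) and
asks how daily water use efficiency — integrated net assimilation divided
by integrated transpiration, in mmol CO2 per mol H2O — responds to the
dynamic properties of stomata and to mesophyll CO2 conductance. This
vignette is the package's own account of the model, its numerical
treatment, and the design decisions taken where the model description left
room for interpretation.

## The coupled model

Four sub-models are advanced together on a fixed time grid.

**Steady-state photosynthesis and the stomatal target.** The biochemical
demand for CO2 follows the Farquhar–von Caemmerer–Berry scheme: a
Rubisco-limited rate $A_c = V_{cmax}(C_c-\Gamma^*)/(C_c+K_m)$ and an
RuBP-regeneration-limited rate $A_j = J(C_c-\Gamma^*)/(4C_c+8\Gamma^*)$,
with the electron transport rate $J$ the smaller root of a
non-rectangular hyperbola in incident light. Supply comes through the
stomatal and mesophyll conductances in series,
$C_c = C_a - A\,(1/G + 1/g_m)$, and the steady-state stomatal target is
the unified optimal-conductance (Medlyn-type) form gated by leaf water
status,
$$G = g_0 + \underbrace{\left(1+\frac{g_1}{\sqrt{\delta e}}\right)
\frac{f_{\psi_m}}{C_a}}_{g_{scb}} \, A ,$$
where $f_{\psi_m}$ is a sigmoid in mesophyll water potential (Tuzet-type
gating) applied to the assimilation-coupled slope only, not to the
intercept $g_0$. Eliminating $C_c$ and $G$ turns each branch into a cubic
in $A$ whose coefficients are formed exactly
(`cubic_rubisco()`, `cubic_rubp()`); the admissible root (non-negative
rate, chloroplastic CO2 in $(0, C_a]$, conductance at least $g_0$;
smallest such root on ties) is selected, and the net target rate is the
branch minimum. The cubic route is cross-checked in the test suite
against an independent bisection solve of the implicit system; the two
agree to well below $10^{-6}$ µmol m$^{-2}$ s$^{-1}$, and the tie-break
has never disagreed with the bisection solution on any tested draw — if
it ever does, the solver raises rather than silently picking.

**Stomatal kinetics.** The conductance to water vapour relaxes towards
$1.6\,G$ (the CO2/H2O diffusivity ratio) by
$$\frac{dg_{sw}}{dt} = \alpha_g \,
\ln\!\frac{1.6\,G - r_0}{g_{sw} - r_0}\,(g_{sw} - r_0),$$
where $\alpha_g$ (s$^{-1}$) sets the speed and $r_0$ the initial-lag
conductance. Both the state and the target are floored at $r_0 +
10^{-6}$ before the logarithm; this is what realises the "initial lag"
encoded by $r_0$, and floor events are counted in the run metadata. Under
a constant target the substitution $u=\ln\frac{g_{sw}-r_0}{1.6G-r_0}$
linearises the equation ($\dot u = -\alpha_g u$), so
`simulate_induction()` steps with the exact exponential propagator —
still a forward integration, but independent of step size — which makes
the parameter-recovery tests an exact inverse problem.
`fit_induction()` estimates $(\alpha_g, r_0)$ from an observed opening
curve by Levenberg–Marquardt least squares over that closed-form
trajectory, fitting the plateau and starting conductance jointly under
box constraints.

**Energy balance and transpiration.** The leaf temperature is the
closed-form root of the linearised single-leaf energy balance
$R_n - G_i = H + \lambda E$, with sensible heat through the
boundary-layer heat conductance $g_{aH}=g_{bw}/1.15$, and transpiration
$$E = g_{tw}\,\rho_a c_p\,\frac{\delta e + s\,(T_l-T_a)}{\lambda\gamma},
\qquad g_{tw}=\frac{g_{bw}g_{sw}}{g_{sw}+g_{bw}}.$$
All constants are molar: $\rho_a c_p \approx 29.3$ J mol$^{-1}$
K$^{-1}$ is the molar heat capacity of air and $\lambda = 44172$ J
mol$^{-1}$ the molar latent heat. This choice makes both equations
dimensionally consistent with molar conductances (a volumetric constant
set would not be), and is tested against a bisection root of the raw
balance over a thousand random atmospheres.

**Leaf water relations.** Mesophyll water content obeys
$dW_m/dt = F_i - F_O$ with influx $F_i = k_x(\psi_x - \psi_m)$ from a
xylem at constant potential $\psi_x$, and efflux equal to transpiration.
The hydraulic conductance has an irradiance-dependent part saturating at
PPFD$_{lim}$ and a circadian oscillation term (120-min cycle in the
default time unit; see below), converted to molar units and floored at
zero. The mesophyll potential is the sum of a van 't Hoff osmotic term
in the solute amount $N_m$ and an exponential pressure–volume turgor
term; solutes accumulate with the influx, $dN_m/dt = c_i N_{xy} F_i$.

## Numerical scheme

The coupled system is advanced by explicit Euler at `dt = 1` s by
default, deliberately without adaptive stepping so that identical inputs
give bit-identical traces. Within a step the order is: air-state
quantities, water potentials (with the leaf temperature lagged one step
to avoid an implicit loop; the lag error is below the discretisation
error at 1-s steps), the steady-state target, the stomatal Euler update,
instantaneous assimilation at the updated conductance (per-branch
quadratics, smaller roots), the energy balance and transpiration, the
hydraulic influx, and the water/solute update. The trace row at $t_n$
records the state at $t_n$ together with the conductances and fluxes
acting over $[t_n, t_n+dt)$; with that convention the integrator
conserves the rectangle sum of the recorded fluxes *exactly*, which is
what `closure_balance()` checks (relative errors at machine precision
whenever no state clipping occurred). Output integrals in `daily_wue()`
use the trapezoid. A step-halving comparison (dt = 5 vs 2.5 s) in the
test suite bounds the trajectory change below 0.1 %, which is the guard
used when sensitivity scans are run at 5-s steps for speed; the shipped
analyses use 1-s steps for single days and 5-s steps inside scans.

Water content is clipped into $(0, W_{m,max}]$ after each update with a
counter; under the default scenarios no clipping occurs. The vapour
pressure deficit entering the stomatal target is floored at `de_min =
0.01` kPa against the $1/\sqrt{\delta e}$ singularity at saturation.
Cubic roots come from the companion-matrix solver (`polyroot`), declared
real below an imaginary tolerance of $10^{-8}$ and polished by three
Newton iterations, so returned rates satisfy their defining implicit
equations to residuals below $10^{-9}$; the degenerate $g_{scb}=0$ case
falls back to the closed-form quadratic.

## Forcing: the ideal day

Because recorded greenhouse climate is not distributable, analyses run
on reproducible "ideal days": light
$I(t) = I_m + I_a\cos(\pi (t-t_0)/p - \pi)$ within a 15-h photoperiod
(06:00–21:00), zero outside, with the phase origin at the photoperiod
start so the day begins at the minimum $I_m - I_a$; `p` is the
half-cycle, so light runs minimum–maximum–minimum in $2p$ seconds.
Daytime means and amplitudes are 237/137.02 (sunny) and 139/133.435
(cloudy) µmol photon m$^{-2}$ s$^{-1}$, chosen so the daily light
integral matches a representative recorded day of each type; whenever
$p$ divides the photoperiod, the daytime mean is exactly $I_m$.
Temperature follows the same waveform, delayed 30 min behind the light.
The model description does not fix the temperature mean and amplitude of
ideal days; the package uses `Tm = 295.15` K and `Ta_amp = 4` K for
*both* kinds as explicit, documented defaults, and relative humidity is
derived from temperature by the hyperbolic decay
$h_r = 1173.613/((T_a-273.16)-6.3458)$, clamped at 100 % (the relation
exceeds 100 % below 18.08 °C and is undefined below 6.35 °C). Climate
CSVs are linearly interpolated to the integration grid — appropriate
because the 1-s step is much finer than typical 1-min logging.

What the ideal day does *not* emulate: cloud-driven irregular flicker,
weather-scale humidity excursions decoupled from temperature, and the
day-specific temperature contrast between sunny and cloudy conditions.
Consequences of the last point are discussed below.

## Design decisions in ambiguous places

* **Target model reading.** The printed steady-state target is typeset
  ambiguously; it is resolved to the Medlyn form
  $(1+g_1/\sqrt{\delta e})(A/C_a) f_{\psi_m}$, which is the model the
  formulation cites, matches the factorisation into $g_0 + g_{scb}A$,
  and makes $g_1$ dimensionless against $\sqrt{\text{kPa}}$. A
  multiplicative $(1+g_1\delta e)$ literal reading is deliberately not
  shipped.
* **$\Gamma^*$ units.** The parameter table prints flux units for
  $\Gamma^*$, but every equation uses it as a mole fraction; 43.02
  µmol mol$^{-1}$ is adopted.
* **Day respiration.** $R_d$ is tabulated but subtracted in no printed
  equation; the default reports the un-subtracted rate, and
  `subtract_rd = TRUE` switches to the conventional net form. The flag
  is part of the parameter set serialised with every run.
* **Vapour-pressure slope.** The printed slope is proportional to the
  *deficit* ($s = a_2 a_3 \delta e/(a_3+T_c)^2$), which differs from the
  thermodynamic convention of using the saturation pressure. The literal
  form is the default; `slope_mode = "saturation"` provides the
  conventional alternative. Neither is asserted to be the original
  authors' intent.
* **Circadian time unit.** The oscillation argument
  $\cos(-\pi t/60 + 5\pi/2)$ is read with $t$ in minutes since midnight
  (a 120-minute cycle); because the cited motivation is a morning peak
  of hydraulic conductance, `osc_time_unit = "hours"` is available and
  both are tested. The oscillation uses the constant reference potential
  $\psi_{m,r}$, not the instantaneous one, as printed.
* **Net radiation.** No PPFD-to-radiation conversion is stated for the
  energy balance; the default `k_rad = 0.4376` J µmol$^{-1}$ maps PPFD
  to PAR energy (4.57 µmol J$^{-1}$) doubled to approximate the total
  shortwave load, and is an explicit parameter.
* **Initial potentials.** The tabulated initial osmotic (−1.28 MPa) and
  turgor (1.2 MPa) values are inconsistent with the potential functions
  evaluated at the tabulated initial state ($W_m = 16 = W_{m,max}$,
  $N_m = 0.121$), which give about −1.03 and 2.4 MPa. The simulator
  initialises from $(W_m, N_m)$ and derives the potentials; the
  resulting early-morning efflux relaxes the relative water content to
  about 92 %, consistent with the reported night-time plateau.
* **Unused parameter.** The Na$^+$ exclusion coefficient $c_e = 0.2$ is
  parsed into the parameter set for completeness but appears in no model
  equation; the ion exchange factor $c_i = 2$ is the one entering the
  solute balance.

## What the sensitivity analyses show

Run at the defaults, the package reproduces the qualitative sensitivity
structure of daily WUE: it falls monotonically as the target slope $g_1$
grows (a +20 % slope costs about 8 % of daily WUE on both ideal days);
it rises with mesophyll conductance with strongly diminishing returns
(the absolute gain beyond $g_m = 0.8$ mol m$^{-2}$ s$^{-1}$ is a few
tenths of a percent — in this formulation the gain is nearly linear in
the mesophyll *resistance* $1/g_m$, so the marginal benefit ratio
between successive doublings is set by resistance differences); a +60 %
stomatal speed-up changes daily WUE by under 1 % on slow 2-h-period
days even though instantaneous WUE during light transients differs by
tens of percent between slow and fast stomata; and WUE against the
fluctuation period has an interior maximum (around 30 min at the
defaults), with a dynamic range of several tens of percent.

Two caveats follow from the equal-temperature ideal-day construction.
First, with both kinds sharing the default temperature course, the
sunny day can out-perform the cloudy day at slow fluctuation periods:
the cloudy scenario's light minima are deep (5.6 µmol m$^{-2}$
s$^{-1}$) and slowly closing stomata keep transpiring through them,
which outweighs the sunny day's larger radiative load; at 30-min
periods the cloudy day wins. A cloudy-over-sunny WUE advantage at all
periods requires the cooler, moister cloudy-day atmosphere that the
shared default removes — users with day-specific temperature estimates
should set `Tm`/`Ta_amp` per scenario. Second, the gm-saturation and
speed results above are statements about this model's structure, not
measurements; the induction-fitting module is the only part calibrated
against (synthetic) observations, where it recovers known kinetics to
well under 1 % (noise-free) and a few percent under 2 % multiplicative
noise.

## Known limitations

No TPU limitation branch and no temperature dependence of
$V_{cmax}$, $J_{max}$, $K_m$ or $\Gamma^*$ (photosynthetic parameters
are held constant over the day); no Rubisco activation kinetics; a
single mesophyll compartment with constant xylem potential (no
cavitation, no root/stem hydraulics); one kinetic time constant for
stomatal opening and closing; no canopy scaling or multi-day carry-over.
These match the single-leaf, single-day scope of the design.
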