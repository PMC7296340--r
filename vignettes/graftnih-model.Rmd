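---
title: "The graftnih model: shear-driven intimal growth in vein bypass grafts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The graftnih model: shear-driven intimal growth in vein bypass grafts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graftnih)
```

## The problem

Peripheral vein bypass grafts fail predominantly through neointimal
hyperplasia (NIH): smooth muscle cells migrate into the intima, proliferate
and lay down collagen, thickening the inner wall until the lumen narrows to a
hemodynamically significant stenosis (conventionally, more than 50% loss of
cross-sectional area). NIH localizes preferentially at the anastomoses, where
the graft caliber changes and wall shear stress is low and oscillatory.
`graftnih` implements a reduced-order multiscale pipeline that connects the
second-scale pulsatile hemodynamics to the month-scale biology:

1. a periodic inflow waveform drives quasi-steady wall shear along the graft;
2. cycle-averaged shear indices — TAWSS, OSI and HOLMES — summarize the
   mechanical environment per axial station;
3. a per-station system of ordinary differential equations for nitric oxide,
   growth factor, smooth muscle cells and collagen converts the local index
   into intimal area growth;
4. the growing intima narrows the lumen, and the final geometry is compared
   with baseline as percent area stenosis per station and region.

The package is a desk-scale research tool: every input can be generated
synthetically, and wall shear fields computed by an external 3D CFD solver
can be injected through a CSV contract (`import_wss_field()`) to replace the
reduced-order hemodynamics while keeping the rest of the pipeline.

## Hemodynamics

**Waveforms.** A `waveform` is one cardiac cycle on the half-open grid
`[0, T)`. Duplex-derived traces are read from CSV with declared clinical
units and converted to SI (1 mmHg = 133.322 Pa, 1 dyn/cm² = 0.1 Pa).
Measured velocity is converted to volumetric flow under one of two
conventions: the *flat* profile treats the measurement as the
cross-sectional mean (`Q = v·πr²`), the *parabolic* profile treats it as the
centerline peak of a Poiseuille profile, whose mean is half the peak
(`Q = v/2·πr²`). The literature does not fix which convention a given duplex
trace follows, so both are exposed and differ by exactly the factor 2.
Resampling onto uniform grids is trigonometric (Fourier) when the input grid
is uniform with an even sample count — exact for band-limited signals and
mean-preserving by construction — and falls back to a periodic cubic spline
otherwise.

**Rheology.** Blood is shear-thinning; the Carreau-Yasuda law
$$\mu(\dot\gamma) = \mu_\infty + (\mu_0-\mu_\infty)\,
\bigl[1 + (\lambda\dot\gamma)^a\bigr]^{(n-1)/a}$$
is the default with standard whole-blood literature constants
(μ₀ = 0.16 Pa·s, μ∞ = 0.0035 Pa·s, λ = 8.2 s, a = 0.64, n = 0.2128), all
config-overridable. A Newtonian model (default 0.0035 Pa·s, the conventional
0.035 dyn·s/cm²) is available for comparison runs.

**Wall shear.** The 3D finite-volume CFD step of a patient-specific workflow
is replaced by quasi-steady Poiseuille shear per station: with current lumen
radius $r$, the nominal wall shear rate is $\dot\gamma_w(t) = 4Q(t)/(\pi r^3)$
and $\tau(t)=\mu(|\dot\gamma_w|)\dot\gamma_w$. This preserves what drives the
growth model — the spatial pattern of low shear at caliber changes — at a
cost of ignoring entrance effects, secondary flow and unsteadiness
(Womersley corrections are deliberately out of scope). The `iterative` mode
sharpens the generalized-Newtonian consistency with the
Weissenberg–Rabinowitsch–Mooney wall correction,
$\dot\gamma_w \leftarrow \dot\gamma_{nom}\,(3 + 1/n_{loc})/4$ with
$n_{loc} = d\ln\tau/d\ln\dot\gamma$, iterated to a relative tolerance of
1e-8; for a Newtonian fluid $n_{loc}\equiv 1$ and the two modes coincide
exactly.

**Windkessel outlets.** The downstream vasculature is a two-element
Windkessel, $C\,dP/dt = Q(t) - P/R$. The integrator treats the linear decay
exactly (exponential integrator with φ-functions) and reconstructs the flow
linearly on a fixed grid of 1024 substeps per cycle, so zero-inflow decay
and the constant-inflow steady state are exact and periodic forcing is
second-order accurate; intermediate cycles are advanced through the exact
affine cycle map, making long settling times free. `tune_windkessel()`
reproduces the zero-dimensional tuning step: $R$ from the target mean
pressure, $C$ by bracketed root finding on the periodic steady-state pulse
pressure (0.5% tolerance). Outlet pressure is reported but does not feed
back on the shear stimulus — the growth mechanisms modeled here are
shear-mediated.

## Shear indices

Per station over one cycle of signed wall shear $\tau(t)$:
$$\mathrm{TAWSS} = \frac{1}{T}\int_0^T |\tau|\,dt,\qquad
\mathrm{OSI} = \frac12\Bigl(1 - \frac{|\int_0^T \tau\,dt|}{\int_0^T |\tau|\,dt}\Bigr),\qquad
\mathrm{HOLMES} = \mathrm{TAWSS}\,(0.5 - \mathrm{OSI}).$$
HOLMES (highly oscillatory, low magnitude shear) jointly penalizes low and
oscillating shear: it equals TAWSS/2 for unidirectional shear and collapses
to zero for purely oscillatory shear. OSI is defined as 0 for identically
zero shear (avoiding 0/0; such stations are flagged). Integrals are
trapezoidal on the cycle grid including the periodic wrap-around segment.
Stations are classified *low-shear* where the chosen index falls strictly
below 0.5 Pa, the conventional cutoff. In this axisymmetric reduced model
$\tau$ is a signed scalar; imported 3D fields must be pre-projected onto a
consistent direction (OSI from vector-valued WSS is out of scope).

## The growth model

The biology is represented by four coupled mechanisms per station, with
dimensionless state densities (in vivo values of SMC and collagen
composition are not standardized in the literature) and day-scale rates.
With stimulus $x$ (the local HOLMES or TAWSS value, Pa):

* low-shear activation $\;Act(x) = \theta^h/(\theta^h + x^h)$ — a Hill
  switch centered on the 0.5 Pa threshold ($\theta$), steepness $h$;
* shear sensing $\;\sigma(x) = x/(x + \tau_{ref})$;
* nitric oxide $N' = k_N\,\sigma(x) - d_N N$ — produced with shear,
  inhibiting proliferation;
* growth factor $G' = k_G\,Act(x) - d_G G$ — released at low shear;
* smooth muscle cells
  $S' = p_S\,G\,S\,(1-S/S_{max})/(1+\alpha_N N) - d_S S$ — logistic
  turnover, growth-factor driven, NO-inhibited;
* collagen $C' = k_C S - d_C C$ — secreted by SMCs;
* intimal area $A' = \max(0,\ \beta_S S' + \beta_C C')$ — the intima
  integrates the volume gain and never regresses, consistent with the
  monotone clinical course over the simulated horizon.

The system is positivity-preserving from any nonnegative state (every loss
term vanishes with its own component), so the integrator — deSolve's
`lsoda`, adaptive and stiff-capable, relative/absolute tolerances 1e-6/1e-8
by default and 1e-8/1e-10 in tests — needs no clipping. All stations are
integrated jointly as one flattened system. The $S=C=0$ state is absorbing:
no tissue appears spontaneously, so initial conditions carry a small SMC
seed ($S_0 = 10^{-3}$, sparse medial cells activated by surgical injury).

**The `demo-2020` preset.** The functional forms above are one concrete
realization of the four mechanisms; every constant is exposed so alternative
parameterizations can be substituted. The shipped preset
(`nih_params("demo-2020")`) is calibrated at order-of-magnitude level, not
fitted to a patient: a sustained low-shear stimulus of 0.1 Pa at an
anastomotic caliber (radius 3.5 mm) produces 50–70% area stenosis within
8–24 months (the run lands at 63%), while stimuli an order of magnitude
above the threshold produce under 1% of the low-shear growth over two
years. The time scales stack as: NO equilibrates in about a day, growth
factor in days, the SMC population over 2–4 months, collagen follows with a
10-day lag.

| parameter | value | units | role |
|---|---|---|---|
| `k_N`, `d_N` | 2, 2 | 1/day | NO production/decay |
| `k_G`, `d_G` | 0.5, 0.5 | 1/day | growth-factor production/decay |
| `p_S`, `d_S` | 0.1, 0.01 | 1/day | SMC proliferation/apoptosis |
| `S_max` | 1 | — | SMC carrying capacity |
| `alpha_N` | 2 | — | NO inhibition strength |
| `k_C`, `d_C` | 0.05, 0.1 | 1/day | collagen secretion/degradation |
| `beta_S`, `beta_C` | 1e-5, 3.5e-5 | m² | volume per unit S, C |
| `tau_ref` | 1 | Pa | NO shear half-saturation |
| `theta` | 0.5 | Pa | low-shear activation threshold |
| `h` | 8 | — | Hill steepness |

The steep Hill switch ($h = 8$) is what separates the anastomoses from the
graft body in the demonstration scenario: at the demo geometry the caliber
ratio 3.5/2.5 mm maps to a shear ratio of only $(3.5/2.5)^3 \approx 2.7$
between body and anastomosis, so a shallow threshold would let the mid-graft
grow as well.

## The coupling loop and the recoupling policy

`run_simulation()` advances the growth ODEs in quasi-static steps (default
7 days — the cardiac and growth time scales differ by six orders of
magnitude, so the stimulus is frozen within a step), updates intimal areas
and lumen radii, and holds the media constant. A station whose lumen would
fall below 1% of baseline is frozen and flagged `near_occluded`; the run
completes with the flag in the report, keeping stenosis strictly below 100%.

How often the hemodynamics should be recomputed on the remodeled lumen is a
genuinely open design choice, so it is a config knob (`recoupling`). The
default is `"baseline"`: the stimulus is computed once on the baseline
(post-implantation) configuration and held for the whole run. The rationale
is specific to the reduced-order solver: in a straight-tube Poiseuille
model, shear depends on the lumen only through $r^{-3}$, so as a station
narrows, its shear index rises and the Hill switch shuts growth down as soon
as the local stimulus reaches the level of the (non-growing) graft body —
capping stenosis around 35% at the demo caliber ratio regardless of the
biology. Real anastomotic hemodynamics do not behave this way: the
low/oscillatory-shear recirculation zone at a caliber change persists as the
lumen narrows. Freezing the baseline stimulus preserves the realistic
regime; `recoupling = "every_step"` is fully implemented and tested, and
demonstrates the self-limiting behavior (the per-step run never exceeds the
baseline-policy run). Quasi-static convergence is verified by step halving:
the final worst-station stenosis changes by well under 2% absolute.

## Geometry metrics

Centerlines are ordered 3D point sets with chordal arc length. Curvature
$\kappa = |\gamma'\times\gamma''|/|\gamma'|^3$ and torsion
$\tau = (\gamma'\times\gamma'')\cdot\gamma'''/|\gamma'\times\gamma''|^2$ are
evaluated from sliding-window polynomial fits (degree 5 over 9 points,
scaled for conditioning) of the coordinates against arc length — third
derivatives amplify noise, and local least-squares fits keep them stable
where spline differentiation of raw points would not; an optional
`smoothing` parameter pre-smooths each coordinate with a smoothing spline
first. Where $|\gamma'\times\gamma''| < 10^{-10}$ the torsion is undefined
(locally straight or planar); it is reported as 0 with `planar_flag` set so
such points cannot poison summaries. Tortuosity follows the common toolkit
convention $L/D - 1$ (arc length over endpoint chord). Oracle accuracy on
closed forms (circle $\kappa = 1/R$; helix $\kappa = R/(R^2+c^2)$,
$\tau = c/(R^2+c^2)$) is within 1e-3 relative at 200+ samples, and all
metrics are invariant under rigid-body motion.

## Synthetic data

`build_synthetic_graft()` constructs an axisymmetric bypass: cosine tapers
from the anastomotic caliber (3.5 mm radius) at both ends to the body
caliber (2.5 mm) over 30 mm, a constant-thickness media annulus (0.5 mm),
zero initial intima, and a gently bowed planar centerline (20 mm bow over
0.4 m) so the tortuosity metrics have something nontrivial to measure.
`make_waveform("femoral_triphasic")` produces a fixed truncated-Fourier
template with a systolic peak, an early-diastolic reverse phase and a small
late-diastolic forward phase, scaled to an exact requested cycle mean; the
reverse phase matters because HOLMES only differs from TAWSS/2 when the
shear oscillates. The demonstration conditions — period 1 s, mean flow
5 mL/s (300 mL/min, a physiologic common femoral inflow), pulsatility 3 —
were chosen once on physiological grounds. In this reduced model OSI is
spatially uniform (the same waveform shape drives every station), so the
spatial contrast between anastomosis and body comes entirely from the
caliber profile; real grafts add geometric oscillation sources the reduced
model does not represent. Passing tests on these fixtures therefore
demonstrate internal correctness of the pipeline and the qualitative
anastomotic localization, not patient-level predictive accuracy.

`make_observation_set()` generates noisy intimal-area time series with known
ground truth for parameter-recovery exercises; with 5% multiplicative noise,
three stimuli and twenty time points, `fit_growth_params()` (log-scale
Levenberg–Marquardt) recovers the generating proliferation, apoptosis and
collagen-secretion rates to within a few percent.

## Numerical choices, degenerate inputs, limitations

* Waveform periodicity is enforced at 1e-9 relative on duplicated
  endpoints; at least 16 samples per cycle are required.
* The Windkessel substep is fixed at T/1024; the compliance search bracket
  is [1e-12, 1e-6] m³/Pa with a clear error (reporting the achievable pulse
  range) when the target lies outside.
* Identically zero shear gives OSI = 0 by definition; constant inflow with
  a zero pulse target returns the exact resistance with an arbitrary valid
  compliance.
* The WRM fixed point caps at 100 iterations and names the failing station.
* The near-occlusion guard freezes a station at 99% area loss rather than
  erroring; the flag is carried in the stenosis report.
* Problem sizes: the demonstration scenario uses 81 stations, 256 time
  samples per cycle and 83 growth steps, and runs in under a second; the
  full test suite regenerates all of its fixtures in code.

Not modeled (by design): image segmentation and baseline reconstruction from
CT; 3D Navier–Stokes, turbulence, fluid–structure interaction (walls are
rigid); flow splits at branch points (the graft is a single conduit);
endothelial, extracellular-matrix and inflammatory-biomarker extensions;
pressure-mediated growth; regression of established intima.
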