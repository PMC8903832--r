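---
title: "Modelling chemotactic smoothing of bacterial fronts in porous media"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling chemotactic smoothing of bacterial fronts in porous media}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(chemosmooth)
```

## The model

Dense populations of *E. coli* 3D-printed inside a jammed hydrogel
packing consume the surrounding nutrient (L-serine, doubling as the
chemoattractant), create a self-generated gradient, and migrate outward
as a coherent front.  When the initial population carries a large-scale
sinusoidal undulation (wavelength $\lambda$ in the millimetre range,
amplitude $A_0 \approx 300\ \mu$m), the migrating front autonomously
flattens: the undulation amplitude decays exponentially with a
smoothing time $\tau$ of order an hour.  This package implements the
continuum (Keller–Segel) description of that process and the complete
analysis pipeline around it.

The model couples the nutrient concentration $c(\mathbf r, t)$ and the
bacterial number density $b(\mathbf r, t)$ on a 2D domain:

$$\partial_t c = D_c \nabla^2 c - b\,\kappa\, g(c), \qquad
  g(c) = \frac{c}{c + c_{1/2}},$$

$$\partial_t b = -\nabla \cdot \mathbf J_b + b\,\gamma\, g(c), \qquad
  \mathbf J_b = -D_b(b)\, \nabla b + b\, \chi(b)\, \nabla f(c).$$

Chemotaxis enters through the logarithmic sensing function

$$f(c) = \log\!\frac{1 + c/c_-}{1 + c/c_+},$$

which is linear in $c$ below the lower receptor dissociation constant
$c_-$ and saturates at $\log(c_+/c_-)$ above the upper one, $c_+$.  The
chemotactic velocity can be read as a driving force modulated by a
response function,

$$\mathbf v_c = \underbrace{\chi f'(c)}_{\text{response}}
  \underbrace{\nabla c}_{\text{forcing}}, \qquad
  f'(c) = \frac{1}{c + c_-} - \frac{1}{c + c_+},$$

and the strict decrease of $f'$ with $c$ — receptor saturation — is the
mechanism of interest: convex regions of an undulated front protrude
into richer nutrient, where the response is weaker, so concave regions
outrun them and the undulation heals.  A strictly linear variant
$f(c) = c/c_{\rm lin}$ with $c_{\rm lin} = (1/c_- - 1/c_+)^{-1}$
(matching the logarithmic form at small $c$) removes the saturation and
with it the smoothing; it is available via
`model_params(sensing_mode = "linear")`.

### Parameters and units

All quantities are carried internally in $\mu$m, s, $\mu$M and
cells/$\mu$m$^3$; printed literature values (mM, cells/mL, min, hr) are
converted once at construction and round-trip exactly
(`kappa_to_internal()` / `kappa_to_printed()`).  Defaults:

| parameter | value | units | meaning |
|---|---|---|---|
| $D_c$ | 800 | $\mu$m$^2$/s | nutrient diffusivity |
| $\kappa$ | $1.6\times10^{-11}$ | mM (cell/mL)$^{-1}$ s$^{-1}$ | maximal per-cell consumption |
| $c_{1/2}$ | 1 | $\mu$M | Monod constant |
| $\gamma$ | $\ln 2$/hr | — | maximal division rate |
| $c_-$, $c_+$ | 1, 30 | $\mu$M | receptor dissociation constants |
| $c_0$ | $10^4$ | $\mu$M | initial nutrient (10 mM) |
| $b_{\rm pack}$ | 0.95 | cells/$\mu$m$^3$ | packed inoculum density |

The motility coefficients are measured per porous medium and shipped as
presets selectable by mean pore size $\xi$ (`porous_medium(1.7)` etc.):

| $\xi$ ($\mu$m) | $D_b$ ($\mu$m$^2$/s) | $\chi$ ($\mu$m$^2$/s) | $f$ | $l_c$ ($\mu$m) |
|---|---|---|---|---|
| 2.2 | 2.32 | 145 | 0.36 | 4.6 |
| 1.7 | 0.93 | 9   | 0.17 | 3.1 |
| 1.2 | 0.42 | 5   | 0.04 | 2.4 |

Crowding is handled by a mean-field collision model: the mean cell
separation $l_{\rm cell} = (3f/4\pi b)^{1/3} - d$ truncates the random
walk once it falls below the mean chord length $l_c$ of the pore space,
multiplying both $D_b$ and $\chi$ by $(l_{\rm cell}/l_c)^2$, and both
vanish where $l_{\rm cell} \le 0$ (jamming).  We read the jamming
clause as $l_{\rm cell} \le 0$ — a squared factor cannot itself be
negative — which is the only reading consistent with jammed cells being
immobile.  The base of the logarithm in $f(c)$ is taken as natural,
the convention of the sensing literature from which the dissociation
constants $c_\pm$ are drawn.  The choice is not innocuous when the
chemotactic coefficients are imported rather than refitted: holding
the shipped $\chi$ values fixed, switching the base to 10 would scale
every chemotactic velocity — and with it the front speed and all
smoothing time scales — by $1/\ln 10 \approx 0.43$.  Because $\chi$ is
in practice calibrated against measured front speeds (see
`calibrate_chi()`), the base and $\chi$ form a pair: only their
product is observable.  All orderings, signs and mechanism signatures
are independent of the base.

## Numerics

### Discretization

Space is a uniform node-centred grid; the Laplacian and all flux
gradients are standard central differences.  The bacterial transport
term is discretized in conservative (flux) form on cell faces with
arithmetic-mean face coefficients, so that with growth switched off the
discrete total cell number is constant to round-off — cell number
should change only by proliferation, and the tests assert conservation
to $10^{-6}$ relative over full runs.  Zero normal flux is imposed on
all boundaries by ghost-node reflection.  The y domain spans exactly
one undulation wavelength; we place valleys on the two y boundaries
(phase `valley_at_0`), so a single symmetric repeat unit is simulated
and mirror symmetry about $y = \lambda/2$ is preserved to round-off.

### Time integration and the stiff consumption term

Time stepping is an Adams–Bashforth–Moulton predictor–corrector in
PECE mode: order-3 Adams–Bashforth predictor, one evaluation, order-2
Adams–Moulton (trapezoidal) corrector, one trailing evaluation that
becomes the newest history entry.  The two starting values are built
with a classical RK4 starter — any single-step method of order $\ge 3$
is sufficient for an order-3 predictor, and RK4's coefficients are
unambiguous.

One term cannot be advanced explicitly: at packed density the
consumption sink $-b\kappa g(c)$ relaxes $c$ on the time scale
$c_{1/2}/(b\kappa) \approx 7\times10^{-5}$ s, five orders of magnitude
below any affordable time step, and an explicit step of the Monod
kinetics is violently unstable once $c$ falls below a few tens of
$\mu$M (the iteration overshoots through the pole of $g$ at
$c = -c_{1/2}$).  The package therefore integrates consumption by a
Lie split: each ABM step advances transport + growth, then a pointwise
backward-Euler step advances consumption exactly, via the positive root
of the quadratic $c_{\rm new}(c_{\rm new} + c_{1/2}) =
(c_{\rm old} - S)\,c_{\rm new} + c_{1/2} c_{\rm old}$ with
$S = \Delta t\, b\, \kappa$ — unconditionally stable, strictly
positivity-preserving, and exact in both the dilute and the
instantaneous-depletion limits.  The trailing PECE evaluation is taken
at the post-split state so the multistep history remains consistent.
The split is first-order in the consumption coupling, but the splitting
error acts on a term whose own physics (near-instantaneous local
depletion) is far below the hour time scales being measured; the
discretization-robustness check below bounds its practical effect.

The density field is never clipped: small negative undershoot is
intrinsic to non-monotone central schemes near steep fronts, and
silently zeroing it would break mass conservation.  Instead the
integrator aborts when undershoot exceeds a per-field tolerance of
$10^{-3}$ of the packed density for $b$ and $10^{-3}$ of the 10 mM
nutrient scale for $c$.  The undershoot of the scheme itself is a
bounded oscillation that saturates below these guards for every
shipped preset (it grows with the cell Peclet number, so the
strongest-chemotaxis medium on the coarse grid comes closest), while
genuine instability grows without bound and trips them within a few
hundred steps.

The strictly linear (non-saturating) sensing variant deserves a
special note.  With $f = c/c_{\rm lin}$ the sensed gradient does not
saturate at high nutrient, so chemotactic velocities near the
depletion boundary reach $\sim$100 $\mu$m/s — two orders of magnitude
above the logarithmic case — and the cell Peclet number
$v\,dx/D_b$ is $O(10^3)$ at any affordable resolution.  Central
differencing of such advection is violently unstable (densities
diverge within simulated minutes), so the full linear-sensing PDE is
not integrable with this discretization.  The package instead
evaluates the variant where it is scientifically used: in the velocity
decomposition, the response function $f'$ is swapped to its linear
form and evaluated along the leading edge of the self-generated
nutrient field, which shows the velocity-gap inversion (peaks outrun
valleys) and, through the catch-up bookkeeping, the absence of
smoothing.

### Resolution presets and problem sizes

Three presets are shipped (`case_config(preset = ...)`):

* `desk` — $dx = 20\ \mu$m, $\Delta t = 0.05$ s, $L_x = 6$ mm.  The
  workhorse used for the knockout and base-case analyses in the tests
  and the acceptance script.
* `coarse` — $dx = 40\ \mu$m, $\Delta t = 0.2$ s, $L_x = 6$ mm.  Used
  for the wavelength/pore-size sweeps and variant comparisons, where
  orderings rather than absolute values are at stake.
* `paper` — $dx = 10\ \mu$m, $\Delta t = 0.01$ s, $L_x = 3.5$ cm with a
  centred inoculum: the full-chamber geometry.  Selectable but
  expensive; the package's analyses do not require it because the
  smoothing observables are grid-converged well above this resolution
  (see below).

Both desk presets keep the diffusion stability number
$D_c \Delta t/dx^2 = 0.1$, well inside the PECE stability interval.
In the desk/coarse presets the inoculum centreline sits at
$x = 0.2 L_x$ rather than the centre: the physics is symmetric in
$\pm x$ and all analysis is performed on the $+x$ front, so shifting
the inoculum gives that front ~4.8 mm of fetch at no extra cost, while
the $-x$ front stalls harmlessly against the near wall in an already
nutrient-depleted region.  The undulated ridge is a Gaussian of FWHM
100 $\mu$m whose centreline oscillates with amplitude $A_0$; the
amplitude convention is that the centreline spans
$[x_c - A_0,\ x_c + A_0]$, i.e. the measured edge amplitude $A$ (half
the peak-to-valley excursion) equals $A_0$ at $t = 0$.

The discretization-robustness test integrates the same physical case at
(`coarse`) and at ($dx/2$, $\Delta t/4$) (`desk`) and asserts the
fitted $\tau$ moves by less than 15% (observed: ~1%).

One finite-domain effect sets the analysis windows.  Nutrient diffuses
toward the consuming population from ever farther away; once the
depletion halo $\sqrt{2 D_c t}$ reaches the $+x$ wall, the reduced
domain's finite nutrient reservoir (unlike the centimetres-wide
physical chamber) begins to starve the front, which thins and
eventually drops below the edge-detection threshold.  Runs are
therefore analysed within $t \lesssim L_{\rm fetch}^2/(2 D_c)$ — about
4 hr for the 6 mm domains and 7 hr for the 8 mm domains used at the
longest undulation wavelengths.  All smoothing observables ($t_0$,
$\tau$, $\tau'$) converge well inside these windows.

## Front analysis

The leading edge at time $t$ is the locus where $b$ falls below a
threshold, scanned row-by-row from the $+x$ boundary inward with linear
sub-grid interpolation.  Migration traces use the threshold
$10^{-4}\times$ the peak initial density; the velocity-decomposition
analysis uses fixed per-condition thresholds (0.003 cells/$\mu$m$^3$
for the prototypical $\xi = 1.7\ \mu$m, $\lambda = 0.8$ mm case and all
$\xi = 2.2\ \mu$m cases; 0.002 for $\xi = 1.7\ \mu$m at
$\lambda = 2.0$–3.2 mm; 0.001 for $\xi = 1.2\ \mu$m).  The undulation
amplitude is $A = (\max_y x_{\rm edge} - \min_y x_{\rm edge})/2$ and
the front position $R_f$ is the leading-most point relative to the
inoculum centreline.

The smoothing time is extracted exactly as for the experimental traces:
for every candidate initiation time $t_0$ on the sampling grid, fit
$A = A(t_0)\,e^{-(t - t_0)/\tau}$ by least squares over $\tau$ alone
(with $A_0$ pinned to the observed $A(t_0)$), and report the earliest
$t_0$ whose fit error is within 5% of the global minimum; the spread of
acceptable $t_0$ becomes the uncertainty band.  Two documented choices
make this well-posed on clean simulated traces: the error metric is the
RMSE normalized by $A(t_0)$ (the unnormalized RMSE shrinks trivially as
the amplitude decays, which would drag $t_0$ late), and fits better
than $10^{-4}$ relative are treated as equally perfect.  The fit is
performed on untransformed $A$, not $\log A$, matching a plain
exponential-decay fit without reweighting small amplitudes.  A series
whose amplitude never decays (or whose best-fit $\tau$ exceeds 50
run durations) is reported as non-smoothing rather than given a
meaningless $\tau$.

The mechanism analysis evaluates, along the edge, the nutrient gradient
$\partial_x c$ (bilinear interpolation of the node-centred central
difference), the response $f'(c)$, and their product
$v_{c,x} = \chi f' \partial_x c$ with $\chi$ at its constant per-medium
value.  Edge thresholds sit orders of magnitude below the jamming
density — though not below the onset of the crowding correction, whose
local value is returned for inspection — and the peak/valley rows are
identified from the edge geometry each frame rather than pinned to
$y = \lambda/2$ and $0$, to tolerate drift.  The catch-up time $\tau'$
is the first time the running (trapezoidal) integral of the
valley-minus-peak velocity gap $\Delta v_{c,x}$ reaches $A_0$.

The observable "cellular signal" used for rendering mimics
fluorescence loss of starved cells: wherever $c$ first dropped below
$c_\ast$ at time $t'$, the density at $t > t' + \tau_{\rm delay}$ is
multiplied by $e^{-(t - t')/\tau_{\rm starve}}$
($\tau_{\rm delay} = 2$ hr, $\tau_{\rm starve} = 29.7$ min).  The
depletion threshold $c_\ast$ is not fixed by any printed value; we
default it to $c_{1/2} = 1\ \mu$M, the natural kinetic scale at which
consumption and growth have halved, and expose it as a parameter.

## What the synthetic inputs emulate — and what they do not

`make_undulated_inoculum()` reproduces the geometry of the 3D-printed
inocula: Gaussian cross-section (FWHM 100 $\mu$m), peak density
0.95 cells/$\mu$m$^3$, sinusoidal centreline.  `synth_amplitude_series()`
generates exponential-decay amplitude fixtures (optionally with seeded
Gaussian noise) so the $\tau$-fitter can be validated in isolation, and
`render_image_stack()` converts snapshots to log-scaled 16-bit TIFF
frames resembling maximum-intensity projections.  None of these emulate
pore-scale granularity, imaging noise physics, or the 3D structure of
the real experiments; agreement of the pipeline on these inputs
validates the computational chain, not the biology.  The continuum
model itself is 2D by construction and mean-field in its treatment of
cell-cell collisions; hydrodynamic or alignment interactions are
excluded on the grounds that tight pores only permit end-on encounters.

## Experiment drivers

`run_case()` composes generator → solver → edge analysis →
decomposition and returns a summary (τ, τ′, t₀, A₀, front-formation
flag, flat-front speed where applicable).  `run_knockout()` zeroes
exactly one of $D_b$, $\gamma$, $\chi$; `run_sweep()` tabulates τ and
τ′ over $\lambda \times \xi$ grids; `run_low_nutrient()` runs the
robustness variant with $c_0$ between $c_-$ and $c_+$ (10 $\mu$M),
where consumption is too weak to build a gradient and no travelling
front forms.  "No front" is judged quantitatively: a population that merely
"spreads via diffusion and proliferation" advances its
threshold-crossing by the analytic creep scale of a growing, diffusing
Gaussian fringe (`creep_scale()`), and a run counts as front-forming
only when the measured leading-edge advance exceeds twice that scale.
A pure $\sqrt{D_b t}$ bound is not usable here: proliferation lifts the
whole density profile exponentially, which moves the fixed-threshold
crossing outward much faster than diffusion alone even when nothing
migrates.  `calibrate_chi()` recovers the chemotactic
coefficient from a target flat-front speed by geometric bisection,
measuring the long-time speed as the slope of $R_f(t)$ over the final
third of the run; it is validated by self-consistency (planting a χ*,
measuring its speed, and recovering χ* within 5%) because no
independent speed values are available in machine-readable form.

## Known limitations

* The coarse presets under-resolve the initial 100 $\mu$m ridge
  (5 nodes per FWHM at `desk`); the robustness check shows the
  smoothing observables are insensitive to this, but early-transient
  details (first ~minutes) are not quantitative.
* The Lie split renders the consumption term first-order in time;
  profiles of $c$ inside the depletion zone inherit an
  $O(\Delta t)$ error that is irrelevant to edge observables but would
  matter for any analysis of the deep interior.
* Literal reproduction of the full-chamber geometry
  (`preset = "paper"`) is supported but takes orders of magnitude
  longer; all shipped analyses use the reduced domains described above.
* Amplitudes below roughly one grid spacing cannot be measured
  meaningfully; late-time $A(t)$ plateaus at the discretization floor
  rather than reaching zero.
* Absolute smoothing times inherit the ambiguity of the
  $(\chi, \text{log base})$ pairing noted above: with the shipped
  $\chi$ presets and natural-log sensing, all chemotactic time scales
  are a fixed factor faster than they would be under a base-10
  reading.  Wavelength/pore-size orderings, knockout outcomes, the
  velocity-gap sign structure and the $\tau' \approx \tau$
  correspondence are unaffected; for quantitative matching to a
  particular experiment, $\chi$ should be recalibrated against that
  experiment's measured front speed with `calibrate_chi()`.
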