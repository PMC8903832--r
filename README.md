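# chemosmooth

Simulation and analysis of **chemotactic smoothing**: how collectively
migrating bacterial populations in porous media autonomously flatten
large-scale undulations in their front morphology.

Dense *E. coli* populations printed into jammed hydrogel packings
consume the surrounding nutrient (L-serine, which doubles as the
chemoattractant), build a self-generated gradient, and migrate outward
as a coherent front. A front whose shape carries a sinusoidal
perturbation of wavelength λ and amplitude A₀ flattens as it runs: the
amplitude decays exponentially, `A = A₀ exp(−Δt/τ)`. The package
implements the continuum model of this process and everything needed to
measure and explain τ in silico. It is aimed at quantitative
microbiologists and active-matter physicists who want to simulate,
fit, or perturb this smoothing process.

## The model

Nutrient concentration c and cell density b evolve on a 2D domain as

    ∂t c = Dc ∇²c − b κ g(c),                 g(c) = c/(c + c½)
    ∂t b = −∇·Jb + b γ g(c),                  Jb = −Db(b) ∇b + b χ(b) ∇f(c)

with logarithmic nutrient sensing

    f(c) = log[(1 + c/c₋)/(1 + c/c₊)],        v_c = χ f′(c) ∇c.

`f′(c)` decreases with c (receptor saturation): convex regions of an
undulated front poke into richer nutrient where the chemotactic
*response* is weaker, so concave regions catch up and the front heals —
even though the nutrient *gradient* (the forcing) is stronger at the
convex peaks and by itself would do the opposite. Density-dependent
motility with jamming, cell proliferation, the three porous-medium
parameter presets (mean pore size ξ = 1.2, 1.7, 2.2 μm), a
non-saturating linear sensing variant, and knockouts (Db = 0, γ = 0,
χ = 0) are all included.

The solver is a conservative central-difference scheme with an
Adams–Bashforth–Moulton (order 3/2) predictor–corrector in a compiled
core; the stiff Monod consumption term is advanced by an exact
pointwise backward-Euler split step. See the methods vignette
(`vignettes/chemotactic-smoothing.Rmd`) for the numerics and every
default.

## Worked example

Simulate the prototypical case — λ = 0.8 mm, A₀ = 300 μm, ξ = 1.7 μm
medium, 10 mM nutrient — for four simulated hours on the desk-scale
grid (dx = 20 μm, dt = 0.05 s; about three minutes of wall time), then
extract the leading edge, fit the smoothing law, and decompose the
chemotactic velocity:

```r
library(chemosmooth)
res <- run_case(case_config(lambda_mm = 0.8, xi = 1.7, t_max_hr = 4))
print(res)
#> ks_case: lambda = 0.8 mm, xi = 1.7 um, log sensing
#>   front formed: TRUE (Rf advance 1468 um vs passive creep scale 645 um)
#>   smoothing: t0 = 0.00 hr, tau = 0.53 hr, tau' = 0.72 hr
```

The population organizes into a migrating front (its leading edge
advances 1.5 mm, more than twice what diffusion plus proliferation
alone could produce) while its 300 μm undulation decays with
τ ≈ 0.5 h; the catch-up time τ′ (computed independently by integrating
the valley-minus-peak chemotactic velocity gap until it covers A₀)
agrees with τ within a factor of two — the mechanistic signature that
spatial variation in the chemotactic response drives the smoothing.

Knockouts isolate the mechanism:

```r
run_knockout(case_config(t_max_hr = 4), "diffusion")   # still smooths
run_knockout(case_config(t_max_hr = 4), "growth")      # still smooths
run_knockout(case_config(t_max_hr = 3), "chemotaxis")  # no front at all
```

`run_sweep()` tabulates τ over λ × ξ grids, `run_low_nutrient()` runs
the 10 μM robustness variant (no front forms),
`model_params(sensing_mode = "linear")` switches to non-saturating
sensing (smoothing is abolished), and `calibrate_chi()` recovers χ from
a measured flat-front speed. A thin command-line front end is provided
at `inst/cli/chemosmooth.R`.

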