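# huecancel

Simulated hue-cancellation psychophysics for trivial observer networks, and
an analytic change-of-basis model of the same experiment.

## The problem

Hue cancellation is the classical procedure behind opponent color theory:
an observer adds narrow-band "cancelling" lights — blue (475 nm), green
(500 nm), yellow (580 nm), red (700 nm) — to a monochromatic test until it
matches a grey, and the signed energies define the red–green and
yellow–blue valence functions, traditionally read as the sensitivities of
post-receptoral opponent mechanisms.

`huecancel` is for vision scientists who want to probe that interpretation.
It runs the experiment on *observer networks* with no opponent machinery —
an identity (or any fixed linear) transform on top of a tristimulus front
end in cone LMS, opponent ATD, linear RGB or nonlinear display RGB — by
solving, at each test wavelength λ, the matching problem

    w*(λ) = argmin_w || R'(W ⊕ Σ_{w<0}|w_i|E_ci) − R'(E_λ ⊕ Σ_{w>0}w_i E_ci) ||

(physical superposition is additive, so negative weights add light to the
reference side). Human-like opponent valence curves emerge from every such
observer, which means the curves measure the front-end tristimulus geometry
and the choice of cancellation lights, not the network.

The package also implements the equivalent change-of-basis description:
with cancellation lights complementary in pairs, the valence curves are two
rows of the inverse primary matrix `M = [R(P1*) R(P2*) R(P3*)]^-1` applied
to the color matching functions. That analytic form makes it cheap to scan
*alternative* cancellation-light choices `(λ1, λ2 = λ1 + Δλ, complements)`
and score each against reference opponent curves — the resulting error
surface has its global minimum at the classical 475/500 nm choice.

## Worked example

Cancellation sweep for an identity network living in cone LMS space:

```r
library(huecancel)

cfg    <- hc_config()                       # grid, white, observer, defaults
lights <- cancellation_lights(cfg$grid)     # classical 475/500/580/700 nm
net    <- identity_network(cfg$cmfs, "lms", cfg$params)
curves <- run_cancellation_curves(cfg$grid, lights, net, cfg$white)

as.data.frame(curves)[16:21, ]
#>    wavelength_nm        w_blue       w_green      w_yellow         w_red            rg            yb     residual converged
#> 16           475 -9.999781e-01 -8.167737e-05  4.737843e-05 -4.679023e-03  0.004597345 -1.000025e+00 9.638271e-14      TRUE
#> 17           480 -7.371214e-01 -1.955762e-01  9.590445e-03  6.061569e-05 -0.195636850 -7.467119e-01 1.063443e-13      TRUE
#> 18           485 -5.037905e-01 -3.856840e-01  1.439085e-02  4.519987e-03 -0.390203965 -5.181814e-01 2.842171e-14      TRUE
#> 19           490 -3.068498e-01 -5.755125e-01  1.434371e-02  8.755057e-03 -0.584267585 -3.211936e-01 8.526513e-14      TRUE
#> 20           495 -1.422200e-01 -7.765582e-01  9.630512e-03  1.298744e-02 -0.789545608 -1.518505e-01 4.922784e-14      TRUE
#> 21           500 -8.167737e-05 -9.996954e-01 -1.766793e-04  1.744859e-02 -1.017144004  9.500198e-05 3.177644e-14      TRUE
```

Reading it: residuals of ~1e-13 mean every match is essentially perfect. At
a 475 nm test the solution is a weight of −1 on the blue light (the test's
own narrow component, superposed to the reference side) and the yellow–blue
valence `yb = w_yellow − w_blue` crosses zero at exactly 500 nm — the
opponent signature. Gain-fitting to the packaged reference valence model
(`RG = x̄ − ȳ`, `YB = 0.4(ȳ − z̄)`):

```r
fit <- scale_to_reference(curves, cfg$ref)
fit$gains
#>    rg    yb
#> 0.336 0.378
cor(fit$rg, cfg$ref$rg); cor(fit$yb, cfg$ref$yb)
#> 0.9987
#> 0.9965
```

The same curves arrive from identity networks in ATD, linear RGB and
γ = 2.2 display RGB (`run_classical_experiments(cfg)`), and from the
analytic route (`predicted_valences()`); the error-surface scan over
alternative cancellation lights finds the classical setting:

```r
scan_surface(cfg, method = "analytic", option = 2)
#> <error_surface> analytic (option 2, space lms): 21x12 cells;
#>   global min at lambda1=475, lambda2=500 (mse 0.004446)
```

`run_full_study(outdir, cfg)` writes the resolved configuration, the
classical curves, the surface and its minima as CSV/JSON artifacts;
outputs are byte-reproducible for a given configuration and seed.

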