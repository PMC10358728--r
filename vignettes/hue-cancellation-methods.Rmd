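---
title: "Simulated hue cancellation and the change-of-basis view: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated hue cancellation and the change-of-basis view: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question and the simulated task

Hue cancellation is the classical psychophysical procedure behind opponent
color theory: an observer views a monochromatic test light and adds
"cancelling" lights — classically narrow-band blue (475 nm), green (500 nm),
yellow (580 nm) and red (700 nm) — until the mixture is indistinguishable
from a grey. The signed energies needed at each test wavelength define the
red–green and yellow–blue *valence functions*, historically read as the
spectral sensitivities of post-receptoral opponent mechanisms.

`huecancel` simulates this task with *observer networks* that have no
opponent machinery at all. An observer is a front end (standard-observer
color matching functions plus a color-space map) followed by an arbitrary
transform on 3-vectors; the shipped transforms are the identity and fixed
linear maps. The observer "answers" by direct minimization: for a test
stimulus $E_\lambda$, grey reference $W$, and cancellation lights $E_{c_i}$,
it finds the weights $w_i$ minimizing the Euclidean distance between its
responses to the two sides of the match,

$$ w^\star(\lambda) \;=\; \arg\min_w \; \bigl\| \, R'(W \oplus \textstyle\sum_{w_i<0}|w_i|E_{c_i})
   \;-\; R'(E_\lambda \oplus \textstyle\sum_{w_i>0} w_i E_{c_i}) \, \bigr\| , $$

where $\oplus$ is physical (always additive) superposition: a negative
weight means the light is added to the reference side, the standard
color-matching convention. The package's central observation is that the
opponent shape of the resulting valence curves is fixed by the front-end
tristimulus representation and by the choice of cancellation wavelengths —
not by the transform — so the curves cannot identify the post-retinal
architecture.

## Stimuli and the grey reference

All stimuli live on a regular wavelength grid, by default 400–700 nm in
5 nm steps — the grid on which the packaged CIE 1931 2° table is tabulated
exactly, so no resampling is involved. Quasi-monochromatic lights are
narrow Gaussians (default $\sigma = 5$ nm, narrow relative to the ~100 nm
scale of the color matching functions) riding on a low-radiance
equienergetic background. Truly monochromatic lines cannot be represented
on a sampled grid, and the Gaussian changes a light's chromaticity only
marginally.

The grey reference defaults to the stimulus background itself: an
equienergetic spectrum of radiance 1, with test and cancellation Gaussians
of height 5 (all cancellation lights share this "equal initial energy").
This identification matters. If the grey were much brighter than the
background, a full-tristimulus match would force a large
wavelength-independent achromatic component into every weight function
(the minimum-norm solution of $\sum_i w_i R(E_{c_i}) = R(W) - R(E_\lambda)$
acquires the constant term $A^{+}R(W)$), burying the opponent zero
crossings. With reference = background, the right-hand side reduces to the
test Gaussian's tristimulus alone and the valence geometry is clean. The
5:1 peak-to-background ratio also keeps monochromatic greens inside the
device-RGB gamut, so the nonlinear digital observer optimizes over a smooth
region rather than against the clipping boundary.

## Color representations

Conversions all start from CIE XYZ:

* **lms** — the Hunt–Pointer–Estévez cone transform (equal-energy
  normalization). The package deliberately derives its cone space linearly
  from the packaged CIE observer rather than shipping a separate
  cone-fundamental tabulation; externally tabulated fundamentals (e.g.
  Stockman–Sharpe) can be loaded from CSV with `read_observer_csv()`. For
  the claims tested here only the existence of *some* tristimulus front end
  matters.
* **atd** — an achromatic/opponent model with rows normalized at the
  working white: $A = Y/Y_w$, $T = X/X_w - Y/Y_w$, $D = 0.4\,(Y/Y_w -
  Z/Z_w)$. The normalization guarantees $T = D = 0$ for the equienergetic
  white *as computed on the working grid*, so spectral truncation cannot
  break the opponency of the chromatic channels. Tests rely only on these
  structural properties (A all-positive, T and D opponent, white
  annihilated), not on particular matrix entries.
* **rgb_linear / rgb_digital** — the sRGB primaries matrix, and on top of
  it a display model: rescaling into $[0,1]$ (the white maps to
  $1/\mathrm{headroom}$ of full scale, default headroom 4, leaving room for
  superposed lights), clipping, and a $1/\gamma$ power law with
  $\gamma = 2.2$. This is the "arbitrary device-dependent digital count"
  representation: all-positive broadband sensitivities with a mild
  pointwise nonlinearity.

## Solving the match

With four lights and a three-dimensional response the match condition is a
3-equation, 4-unknown system; for end-to-end linear observers it is exactly
solvable and underdetermined along one null direction (jointly raising the
energies of opposing lights in the null combination changes nothing — both
sides receive the same extra light). Three ingredients make the solution
well-defined and comparable across observers:

1. **Preconditioning.** Descent runs in a variable scaled by the
   tristimulus norms of the lights. The classical 700 nm light is almost
   invisible per unit energy (its tristimulus norm is ~300 times smaller
   than the 580 nm light's), which makes the raw quadratic hopeless for
   first-order methods. The scaling changes neither the solution set nor
   the reported canonical weights.
2. **Conjugate-gradient descent from zero.** Linear observers use CG with
   exact steps; nonlinear observers (digital RGB) use Polak–Ribière CG
   with finite-difference gradients (relative step $10^{-6}$) and Armijo
   backtracking. Conjugate directions are not a luxury: configurations
   whose cancellation lights are nearly parallel in tristimulus space
   (e.g. two complements a couple of nm apart) have condition numbers that
   defeat plain steepest descent within any reasonable iteration budget,
   while CG solves the 4-weight quadratic in a handful of steps. Starting
   from zero keeps linear iterates in the row space, so descent converges
   to the *minimum-norm* solution — the same one the closed-form
   pseudo-inverse oracle computes.
3. **Canonicalization.** Any solution is projected onto the orthogonal
   complement of the null direction of the 3×4 light matrix (computed in
   the front-end tristimulus space; the direction is invariant under
   invertible linear changes of space). Every observer that achieves a
   perfect match therefore reports the *same* canonical weights, which is
   the precise sense in which the curves carry no information about the
   transform.

Wavelengths that fail to converge are flagged, never fatal; they are
excluded from gain fitting and error scoring downstream.

## From weights to valence curves

The four lights form two opponent axes; sorting the classical peaks gives
the blue/yellow pair (475, 580) and the green/red pair (500, 700). Each
axis contributes the difference `w_partner - w_primary`, and one overall
sign is fixed so the red–green curve is positive at the long-wavelength
end. For generalized light sets built from a pair $(\lambda_1, \lambda_2)$
and their complements, the red–green label goes to the axis whose
complement is purple (the green–magenta axis); if neither or both
complements are purple, the axis with the longer primary wavelength takes
the label. The purple-flag rule is what keeps role-swapped configurations
(e.g. $\lambda_1 = 500$, $\lambda_2 = 580$ — the classical set with axis
roles exchanged) correctly labeled.

Valence scales are free: curves are compared to a reference only after a
closed-form per-curve least-squares gain.

The packaged reference is the classical linear valence model
$RG = \bar{x} - \bar{y}$, $YB = 0.4(\bar{y} - \bar{z})$, not digitized
human data: measured human valences exist only as published figures, which
this package will not digitize into ground truth. The loader accepts an
externally digitized CSV for users who have one. Consequences: agreements
with "the human curves" reported by the tests are agreements with this
analytic stand-in, whose zero crossings (~477, ~578, ~498 nm) sit within a
few nm of the classical unique-hue loci.

## The change-of-basis model

When the cancellation lights are pairwise complementary, solving the match
is equivalent to expressing each monochromatic light in a new color basis:
two primaries along the chromatic axes (each cancellation wavelength
through the white to its complement) and a third along the white. The
valence curves are then the two chromatic rows of
$M = [R(P_1^\star)\, R(P_2^\star)\, R(P_3^\star)]^{-1}$ applied to the
color matching functions — an analytic prediction requiring no
optimization, which is what makes dense error-surface scans cheap.

Construction choices:

* Each chromatic primary is the cancellation light's *own chromaticity*
  lifted to the unit-coordinate-sum 3-vector. Any vector in the plane
  spanned by the axis and the white yields the same channel up to scale;
  this representative keeps coordinate sums positive so the
  chromaticity/γ factorization $R(P^\star) = \gamma\, r(P^\star)$ stays
  well-defined, and it preserves the defining geometry: channel $i$
  vanishes exactly where a light's chromaticity falls on the *other* axis,
  so predicted curves cross zero at the cancellation wavelengths.
* **Option 1** uses these lifted chromaticities directly; **option 2**
  orthogonalizes the chromatic primaries against the white primary
  (Euclidean inner product in tristimulus space), so they carry no
  brightness component. A short calculation shows the two options' chromatic
  channels are *identical after per-channel gain fitting* — changing
  $P_{1,2}$ by multiples of $P_3$ leaves the first two rows of the inverse
  unchanged — so their error surfaces coincide up to rounding. Both are
  kept because they are distinct, documented constructions whose
  equivalence is itself a property worth testing; headline results use
  option 2.
* Complements are found by intersecting the ray from a light's
  chromaticity through the white with the diagram boundary: the spectral
  locus treated as a polyline (ties broken toward the longer-wavelength
  segment), or the purple line, in which case the complement is the
  "auxiliary magenta". For network simulations a purple complement becomes
  a physical instrumental light: the energy-matched mixture of narrow
  lights at the two spectral extremes closest in chromaticity to the
  required purple point; its weight is bookkept back onto the partner
  cancelling light by `assign_instrumental_to_cancelling()`, which leaves
  curve values untouched.

## Error surfaces and their minima

`error_of_config()` scores a configuration $(\lambda_1, \Delta\lambda)$ by
the mean squared difference between its gain-fitted valence curves and the
reference, averaged over both curves and normalized by the reference's mean
square — the normalization makes the score invariant to joint rescaling of
the reference. The analytic scan covers $\lambda_1 \in [420, 520]$ nm and
$\Delta\lambda \in [5, 60]$ nm at 5 nm (252 cells, containing the classical
cell $(475, 25)$; under a second on one CPU). Network scans simulate full
cancellation sweeps per cell and default to a 15 nm grid
($\lambda_1 \in \{420, \dots, 495\}$, $\Delta\lambda \in \{15, \dots, 60\}$)
with a 10 nm test-wavelength sweep — sizes chosen so the whole suite runs
comfortably on a laptop while still bracketing the classical region.
Minima are cells no worse than all valid 8-neighbors; on a plateau every
cell qualifies, which is the documented degenerate behavior.

The global minimum of the option-2 analytic surface falls at
$\lambda_1 = 475$, $\lambda_2 = 500$ — the classical blue and green
cancellation wavelengths — and on an extended scan
($\Delta\lambda \le 110$ nm) the second-deepest minimum is the role-swapped
twin $(\lambda_1 = 500, \lambda_2 = 580)$, the *same* four lights with the
axes exchanged.

## Known limitations

* **Representative dependence far from the classical setting.** With four
  lights the per-light weights are defined only up to the null direction;
  the package reports the minimum-norm representative (what descent from
  zero produces), while the analytic model implicitly uses the dual-basis
  representative. Near the classical configuration the two agree to
  correlation > 0.99, but for configurations where *both* complements are
  purple (λ₁ ≳ 495 nm) the two instrumental magentas are nearly parallel
  and visually weak, the null direction is dominated by that pair, and
  simulated curves degrade much faster than analytic ones. Network and
  analytic error surfaces then agree in broad structure but not cell-by-cell
  rank near that edge of the scan — simulated errors grow faster away from
  the good region than the analytic ones do.
* The generator emulates idealized uniform fields: no spatial structure,
  no photon or neural noise, no observer variability, no chromatic
  adaptation. Passing tests show what the *geometry* of tristimulus
  mixture implies for this task; they say nothing about mechanisms a noisy
  or adaptive observer might reveal.
* The reference valence curves are an analytic stand-in (above); error
  magnitudes against genuinely measured human data would differ, though
  the location of the minimum is a geometric property expected to survive.
* Only the CIE 1931 2° observer ships; the cone space is a fixed linear
  transform of it. Conclusions are invariant under any such linear change
  of front end — that invariance is itself part of the test suite.
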