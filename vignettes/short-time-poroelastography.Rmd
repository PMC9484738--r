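---
title: "Short-time poroelastography: models, estimators and numerical choices"
author: "stpe package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Short-time poroelastography: models, estimators and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stpe)
```

## The problem

Poroelastography images the mechanical and transport properties of soft
tissue by holding a small constant stress on it (creep compression) while
ultrasound frames are collected. A fluid-saturated tissue responds in two
stages: immediately after loading it behaves as an incompressible solid
(effective Poisson's ratio near 0.5), and as fluid leaves the loaded region
the strains relax towards the drained steady state. Three quantities of
clinical interest can be read off this process for a tumor embedded in
normal tissue: the Young's modulus $E_i$ and Poisson's ratio $\nu_i$ of the
inclusion (from the steady-state strains) and its vascular permeability
$L_p$ (from the *rate* of the relaxation).

The practical obstacle is acquisition time: reaching steady state takes
several strain time constants, often more than a minute of motionless
scanning. This package implements and evaluates the *short-time* variant:
fit the transient model to a truncated window of observation (WoO), predict
the steady state, and quantify how the estimates degrade as the window
shrinks to a small multiple of the underlying time constant.

## The creep model

Each pixel's axial and lateral strain is modelled as a first-order
relaxation

$$ s(t) = \eta + (\alpha - \eta)\, e^{-t/\tau}, $$

where $\alpha$ is the strain immediately after loading, $\eta$ the
steady-state strain and $\tau$ the strain time constant. Truncating the
record at $t = k\tau$ leaves a fraction $e^{-k}$ of the transient
unobserved (0.368 at one time constant, 0.135 at two), which is why moduli
— which depend only on $\eta$ — tolerate much shorter windows than the
permeability, which also needs $\tau$ itself.

When vascular filtration dominates interstitial flow
($\chi = L_p S/V \gg k/a^2$), the time constant satisfies

$$ \tau = \frac{1}{H_A\, \chi}, \qquad
   H_A = \frac{E(1-\nu)}{(1-2\nu)(1+\nu)}, $$

with $H_A$ the aggregate modulus and $S/V$ the capillary surface-to-volume
ratio, so $L_p = 1/(\tau H_A \cdot S/V)$ once $E$, $\nu$ and $\tau$ are
known. The package warns when $\chi < 10\,k/a^2$; the assumption is
routinely valid inside tumors but questionable in normal background tissue,
which is why permeability maps are restricted to the inclusion mask by
default.

## The forward model (synthetic phantoms)

Ground truth is generated analytically rather than by finite elements. For
an ellipsoidal inhomogeneity under remote uniaxial stress, Eshelby's result
gives a spatially uniform interior strain via the equivalent-inclusion
method: $\varepsilon_{in} = \varepsilon^0 + S\varepsilon^*$ with
$[(C_i - C_b)S + C_b]\,\varepsilon^* = (C_b - C_i)\varepsilon^0$, where $S$
is the Eshelby tensor (closed forms for the sphere; elliptic I-integral
forms for oblate/prolate spheroids, verified in the tests against
quadrature of the defining integrals). The steady state $\eta$ uses the
drained Poisson's ratios; the instantaneous response $\alpha$ re-solves the
same problem with both media at an effective undrained $\nu = 0.499$ (kept
just below 0.5 so the stiffnesses stay finite) and unchanged Young's
moduli; each region then relaxes exponentially with its own
$\tau = 1/(H_A L_p S/V)$. Two consequences worth knowing:

* the background axial strain has no transient under this model (uniaxial
  stress with free lateral boundaries makes $\varepsilon_{zz} = \sigma_0/E$
  independent of $\nu$), so background axial fits are flagged degenerate —
  by design, not by accident;
* interior fields are piecewise uniform, so phantom strain movies contain
  exactly two distinct curves. The fitting code detects duplicate pixel
  curves and fits each distinct curve once, which keeps the noise-free
  experiments near-instant at any grid.

The built-in scenario library (`stpe_scenarios()`) uses a 20 x 40 mm plane,
a 7.5 mm spherical or 7.5 x 5 mm elliptical inclusion, 1 kPa creep stress,
$S/V = 20\,000\ \mathrm{m^{-1}}$, 60 s records at 0.1 s (120 s at 0.2 s for
the 30.25 s time-constant sample), background 30 kPa at $\nu_b = 0.3$
(3.3% far-field strain, inside the 1-5% regime where speckle tracking
stays correlated), stiffness contrasts 2-4x and inclusion time constants
10-30 s. These values are the package's fixed study conditions; where the
published description of comparable experiments is not machine-readable,
they were chosen once from the stated constraints and are not tuning knobs.

## Ultrasound simulation and tracking

The RF simulator is a convolution speckle model: uniformly random
scatterers (default 10 per resolution cell, enough for fully developed
Rayleigh speckle) carry standard-normal reflectivities; each contributes
the separable point spread function — axially a cosine at 6.6 MHz under a
Gaussian whose amplitude spectrum has a 50% fractional -6 dB bandwidth,
laterally a Gaussian with 1 mm -6 dB beamwidth — evaluated at its exact
continuous position (no gridding error), sampled at 40 MHz; Gaussian noise
sets the per-frame SNR. Displacement movies are obtained from the phantom
strain movies by midpoint integration (axial from the transducer face,
lateral outward from the centerline).

Tracking follows the two-step scheme: per-A-line dynamic programming over
integer (axial, lateral) offsets with an L1 continuity penalty along the
line and against the previous line's solution, then Horn-Schunck optical
flow on the motion-compensated pair for the sub-sample part. Around this
core the tracker applies standard practice that matters at realistic SNR:

* matched axial filtering of the frames (correlation with the pulse) for
  the optical-flow stage only — the integer dynamic program keeps the raw
  broadband frames, whose wide envelope spectrum protects it from
  wavelength-hopping ambiguity;
* $\sin(\omega)/\omega$ corrections of the central-difference gradient
  bias in the optical flow — axially at the carrier frequency (otherwise
  axial flow inflates by about 20% at 6 samples per wavelength), laterally
  as the gradient-energy-weighted average over the beam's lateral spectrum
  (otherwise lateral flow inflates by about 15% at the default pitch);
* a 3-line median on the integer fields (isolated peak-hopping);
* consecutive-frame tracking with accumulated displacement; the *lateral*
  accumulation is re-anchored every 10 frames by tracking directly against
  the last keyframe — without re-anchoring the lateral error random-walks
  over the record and masquerades as a slow strain transient. The axial
  path stays purely consecutive: its per-pair noise is an order of
  magnitude smaller, and keyframe decorrelation would do more harm to the
  time-constant fits than the walk it removes;
* heavy spatial smoothing of the accumulated lateral displacement before
  its slope is taken (lateral speckle tracking is far noisier than axial;
  the lateral motion field is smooth at the tissue scale).

Strain is the moving least-squares slope of displacement (81 samples
axially, 15 lines laterally by default) followed by a scalar random-walk
Kalman filter along depth.

## Fitting and inversion

Per pixel, the creep model is fitted by variable projection: for each
candidate $\tau$ the linear pair $(\eta, \alpha-\eta)$ has a closed-form
least-squares solution, so the search is one-dimensional. Candidates are
log-spaced (200 points) from half the sampling interval to ten times the
window length — wide enough that no admissible time constant sits outside
the bracket — then refined by Brent minimisation on $\log\tau$ to a
$10^{-10}$ tolerance. Curves with dynamic range below `1e-12` are flagged
degenerate ($\eta$ = mean, $\tau$ = NaN). Before per-pixel fitting the
strain stacks can be denoised by truncated SVD of the pixels x time matrix
(EOF analysis, default 3 modes — a constant, the background lateral
transient and the inclusion transient).

Inversion proceeds in two stages. Background moduli come directly from the
far-field steady state: $E_b = \sigma_0/|\eta_{zz}|$,
$\nu_b = |\eta_{rr}/\eta_{zz}|$, averaged over a region well outside the
(1.6x enlarged) inclusion ellipse and away from image borders. The
inclusion moduli minimise the squared difference between two expressions of
the interior eigenstrain — geometric, $S^{-1}(\varepsilon_{in} -
\varepsilon^0)$, versus material, from the equivalency at candidate
$(E_i, \nu_i)$ — over the box $E_i \in [0.05, 50]E_b$,
$\nu_i \in [0.01, 0.499]$, with a closed-form linear start (the equivalency
is linear in the Lamé pair once the eigenstrain is fixed) plus
deterministic multi-starts; only the axial and lateral strain components
enter, with the elevational equal to the lateral by axisymmetry. For
irregular masks the Eshelby tensor uses the aspect ratio of the best-fit
ellipse from the mask's second moments.

Near the incompressible limit the problem degenerates: above
$\nu_i \approx 0.45$ the eigenstrain mismatch becomes nearly flat in
$\nu_i$ while the aggregate modulus $H_A$ diverges. Three safeguards keep
the estimators continuous there, all exactly inert in the identifiable
region: a one-sided quadratic barrier on $\nu_i$ above 0.45 in the
inversion cost (without it, estimates snap discontinuously to the box
edge under noise); a refit of $E_i$ from the axial eigenstrain component
alone when $\nu_i$ does saturate (the lateral mismatch carries no
information there); and evaluation of $H_A$ at $\min(\hat\nu_i, 0.45)$
when converting the time constant to vascular permeability, since beyond
that point the permeability scale is not identifiable at realistic noise.

Two aggregation levels are reported. *Maps* apply the inversion per pixel,
replace time constants above 100 s (or degenerate) by the in-mask median,
and median-filter the time-constant map in a 5x5 in-mask neighborhood — the
transport model holds the time constant spatially uniform inside a tumor,
so this pooling removes only noise. *Scalars* fit the region-mean strain
curves and invert those: spatial averaging before the nonlinear fit avoids
the heavy-tailed errors of per-pixel exponential fits on short, noisy
records. The inclusion curves are averaged over an eroded core of the mask
(ellipse scaled to 0.65) so that boundary pixels blurred by the strain
kernels do not bias the steady states; the background curves over the
border-cropped far-field region. This scalar path is the configuration
used for the headline window-of-observation numbers.

## The window-of-observation experiment

`run_stpe_experiment()` generates a scenario, optionally corrupts it
(strain-domain noise, or the full RF chain at 20/40 dB), fits the full
record to obtain the reference estimates and the pilot time constant, then
refits truncated copies at the requested multiples of that pilot value
(window lengths are clamped to at least 10 samples). Errors are percent
relative errors (PRE) of the short-window estimate against the
*full-record* estimate — the quantity that isolates the cost of the
shorter window — with the full-record-versus-truth error reported
separately as an audit. PRE is computed both over in-mask pixels (`pre`)
and for the region-scalar estimates (`pre_scalar`).

Problem sizes are chosen so the whole evaluation runs comfortably on one
CPU: noise-free suites use a 0.5 mm grid (the piecewise-uniform fields make
finer grids informationless), and the RF experiments use a 20 x 20 mm
field, 64 lines, 61 frames at 1 s spacing. On noise-free data the
window-of-observation errors are numerically tiny (the model is exact and
variable projection recovers it to optimizer precision); the noisy
conditions are where the window dependence becomes visible and monotone.

## What the synthetic tests do and do not show

The generator reproduces the geometry, timing, contrast range and noise
levels of a controlled creep experiment, and the RF chain adds the
dominant ultrasonic limitations (speckle decorrelation, pitch-limited
lateral tracking, additive noise). It does not emulate spatially varying
transients inside each region (the first-order model is exact per region by
construction), pore-pressure diffusion gradients near the
inclusion-background boundary, transducer diffraction or depth-dependent
focusing, physiological motion, or irregular tumor shapes. Passing the
acceptance suite therefore demonstrates correctness of the estimators and
their window-of-observation behavior under the stated model, not clinical
performance.

## Known limitations

* Lateral strain — and hence Poisson's ratio — is biased low by several
  percent through the RF chain (beam-width smoothing and heavy lateral
  regularisation); the window-of-observation comparison is unaffected
  because the bias is common to all windows, but absolute $\nu_i$ from
  tracked data should be read with that in mind.
* Per-pixel parameter maps at 20 dB SNR and 60-frame records are dominated
  by pixel noise; the region-scalar estimates remain far more stable.
* At the half-size, 60-frame simulation scale, the Poisson's-ratio channel
  has a realization tail: roughly one speckle realization in several
  yields a lateral strain field whose window-to-window consistency is an
  order of magnitude worse than typical, and the relative error of
  `nu_i` (and, through the aggregate modulus, of the permeability) then
  exceeds its usual percent-level value. Larger fields and denser frame
  sampling shrink this tail.
* The background time constant is not identifiable from axial strain in
  this forward model (no axial transient) and its vascular-dominance
  assumption is dubious anyway; background permeability is opt-in and
  flagged.
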