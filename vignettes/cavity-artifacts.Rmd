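---
title: "Simulating cavity-structure artifacts in photoacoustic tomography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating cavity-structure artifacts in photoacoustic tomography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Photoacoustic tomography (PAT) images optical absorbers — above all blood —
by recording the ultrasound that a short light pulse launches from absorbing
tissue. Organs with cavities (lungs, airways) are hostile territory for PAT:
an air space has a sound speed of 340 m/s and a density of 1.2 kg/m³ against
roughly 1500 m/s and 1000 kg/m³ for soft tissue, so its acoustic impedance is
about three orders of magnitude lower. Waves leaving a blood vessel reflect
almost totally off a nearby air space, and the reflected energy is
reconstructed in the wrong place: a bright semicircular artifact. `pacavity`
simulates this mechanism end to end in a controlled phantom and measures how
well two classical edge-preserving denoisers — Perona–Malik anisotropic
diffusion (ADF) and non-local means (NLM) — remove those artifacts as a
function of how uniformly the phantom is illuminated.

## The phantom (synthetic-data generator)

`build_arrangement()` constructs a 5 cm square agarose substrate seen in
cross-section, carrying 1 mm-diameter tubes of blood, air and water:

* `s1`–`s3`: one tube (single-medium controls);
* `s4`–`s6`: three tubes in a horizontal row (`s4` = blood–air–water, …);
* `S1`–`S3`: 3×3 matrices of a single medium;
* `S4`–`S6`: 3×3 Latin squares, first row as in `s4`–`s6`, later rows cyclic
  shifts, so each medium appears once per row and column.

The study never states the centre-to-centre tube spacing in mm; the figures
show evenly spaced tubes, so the spacing is a reported parameter with a
10 mm default. Tubes become disks in the imaging plane (`rasterize()`, strict
centre-in-disk membership with pixel centres on a grid whose physical origin
is the grid centre); the 3-D Monte Carlo stage extrudes the same model along
the tube axis (`voxelize()`). Tube walls, agarose mechanics and real lung
anatomy are not modelled: the phantom isolates exactly one mechanism —
impedance mismatch at a cylindrical air inclusion — and the test suite's
conclusions are claims about that idealized geometry, not about in vivo
images.

Two optical property tables are built in. `media_uniform()` is the
uniform-light working point: a rounded absorption of 3 cm⁻¹ for blood and 0
for everything else, so initial pressure is proportional to the label map.
`media_mc()` carries the full 800 nm set (absorption, scattering,
Henyey–Greenstein anisotropy, refractive index) for background, water, blood
and air. The table has no row for the agarose substrate, which is optically
near-inert; the substrate reuses the background optics. Acoustically the
substrate, water and blood all take the water parameters, per the study's
forward model.

## Optical stage

Under uniform light, `uniform_initial_pressure()` applies
P₀ = Γ·η·μₐ·F pointwise with Γ = η = F = 1, so P₀ numerically equals μₐ.

Under Gaussian illumination, `mc_fluence()` runs a voxel Monte Carlo photon
transport: free paths sampled against the scattering coefficient, continuous
exponential absorption along every segment (the weight ledger
launched = absorbed + exited + roulette balance closes to ~1e-13),
Henyey–Greenstein scattering, Fresnel reflection/refraction at voxel faces
where the refractive index changes, and Russian roulette termination
(threshold 1e-4, survival factor 10). Fluence uses the track-length
estimator, which remains defined in non-absorbing media. Time gating is not
modelled — the study uses fluence only as a static weight in the
initial-pressure relation, so steady-state accumulation is the right
quantity.

The beam model: five collimated line sources fanned 39° apart, aimed at the
phantom centre from a 58 mm stand-off (the study shows the source layout
only pictorially; the stand-off and aiming are exposed as `beam_spec()`
fields and recorded in every output). Each beam has the Gaussian intensity
profile exp(−2r²/w²), sampled as transverse offsets with standard deviation
w/2 per axis; w is the waist radius, the study's proxy for light-source
uniformity. Photon count defaults to 10⁶ and is configurable; the
acceptance runs use 10⁵, which resolves the fluence contrasts that matter
here (the media table's scattering contrasts are large) at desk-scale run
times. A fast in-plane mode (2-D Henyey–Greenstein analogue) runs the waist
sweep; the 3-D mode with central-slice projection (`project_slice()`) is the
reference geometry. Whether the study projected its 3-D absorption by slice
or integral is unstated; the central slice through the tube axes is used
because the tubes are extruded and the slice is representative.

## Acoustic stage

`forward_simulate()` integrates the first-order linear acoustic system
(momentum, mass conservation, pressure–density relation) on heterogeneous
c(x), ρ(x) maps with a k-space pseudospectral scheme: FFT spatial derivatives
on staggered grids, the exact k-space correction sinc(c_ref·k·Δt/2), leapfrog
time stepping, and a quartic-profile split-field PML outside the 121×121,
1 mm physical grid (the study quotes both 120 and 121; 121 is the default).
The 128-element half-ring array (radius 55 mm, arched over the phantom — the
arc orientation is configurable) samples pressure by bilinear interpolation
for 4096 samples at 12.5 ns. Acoustic attenuation is deliberately absent.
Sources are Blackman-smoothed in k-space by default; property maps are
piecewise constant per medium — the impedance step at the air boundary *is*
the phenomenon under study, so no interface smoothing is applied.

Numerical checks built into the tests: the scheme conserves the discrete
leapfrog energy (kinetic term at t ± Δt/2 paired around the pressure at t)
to machine precision in a lossless homogeneous run; point-source arrivals
match d/c within two samples; and an independently written second-order
staggered-grid FDTD solver (`fdtd_simulate()`) reproduces the spectral
solver's traces (correlation ≥ 0.99, peak shift ≤ 1 sample) on 64×64
fixtures. Two independent discretizations catching each other's bugs is the
reason the FDTD reference exists.

A stability guard rejects time steps with CFL = c_max·Δt/Δx above 0.5
(spectral) or 1/√2 (FDTD). The study's own settings (1 mm, 12.5 ns) sit at
CFL ≈ 0.019.

## Reconstruction

`lowpass()` applies a zero-phase (forward–backward) order-4 Butterworth
low-pass at 750 kHz — the study names only the cutoff; zero phase is chosen
because delay-and-sum depends on arrival times. `das_reconstruct()` then sums
each element's trace at the straight-ray travel time to every pixel.
Reconstruction speed defaults to the study's 1429 m/s; an optional two-speed
mode splits each ray's time between air (430 m/s) and water pixels. Out-of-
window delays contribute zero and are counted.

Two choices deserve justification:

* **Normalization.** Delay-and-sum output is signed. Mapping min→0, max→1
  parks the signal-free background near 0.4–0.5, and that constant offset
  against an ideal image whose background is 0 dominates every quality
  metric — filter lift ratios collapse to ~10⁻⁴, orders of magnitude from
  the study's reported tens of percent. Clipping negative swings and scaling
  by the maximum (`normalize = "clip"`) leaves the background at 0, matches
  the dark-background normalized figures, and restores the reported metric
  regime; it is the default. Min–max and raw signed output remain options.
* **Speed for the artifact-isolation experiment.** Reconstructing 1500 m/s
  data at 1429 m/s radially biases the artifact semicircle: the arc around
  an air tube at blood–air distance d appears at roughly
  (d + r_ring)(1429/1500) − r_ring (≈ 6.9 mm instead of 10 mm here, −31%).
  The geometric claim under test — radius equals the blood–air distance —
  only holds with matched-speed delays, so the isolation experiment
  reconstructs at 1500 m/s. Both speeds are configurable everywhere.

The default evaluation grid is 300×300 at 0.4 mm; the study-scale 1200×1200
at 0.1 mm grid is available by configuration and agrees with the desk grid
(downsampled correlation ≥ 0.95 on a round-trip fixture).

## Artifact removal

`adf()` implements Perona–Malik diffusion over the 4-neighbourhood with
either coefficient form, exp(−(x/k)²) (default) or 1/(1+(x/k)²). The printed
rational variant with a literal 2 in the denominator is selectable for
audit, but k is clearly the intended scale — the exponential form and the
whole diffusion literature use it. The update divides by the interior
neighbour count (4 in 2-D) with zero flux across the border, which conserves
the image mean exactly (the divergence form's defining property); dividing
by the *local* neighbour count at borders — the literal reading of the
printed discrete update — breaks conservation and is kept only as
`eta_mode = "local"`. Stability requires Δt ≤ 0.25.

`nlm()` averages each pixel over its search window with weights
exp(−‖v_p − v_q‖²/h²) on raw squared patch distances; the search window
clips at the image border, patches pad reflectively. Output is a convex
combination, hence bounded by the input range; a brute-force double-loop
oracle in the test suite confirms exact agreement on small images.

The study reports none of its filter hyperparameters. Defaults here are
k = h = 0.1 × dynamic range, Δt = 0.2, 20 iterations, patch radius 2,
search radius 7. For table-style comparisons the package follows a
held-out protocol (`tune_filter_params()`): each filter's hyperparameters
maximize its PSNR lift on the `s5` arrangement and are then frozen for every
other arrangement. The grids are fixed a priori to each filter's intended
operating regime — ADF with k ∈ {0.05, 0.1, 0.2} × range and 10–40
iterations, NLM with h ∈ {0.5, 1, 2, 4} × range. The caps matter and are a
design decision, not a convenience: with k comparable to the dynamic range
and hundreds of iterations, "anisotropic" diffusion degenerates into a
global Gaussian blur whose PSNR lift can exceed NLM's, because flattening
the large artifact-covered background pays more than preserving the few
bright pixels. That regime defeats the purpose of the edge-stopping
coefficient and is excluded; within the stated regimes NLM's saturation at
h ≈ 4 × range is genuine (h = 8 changes nothing).

## Evaluation

`image_metrics()` computes MSE, PSNR (data range 1), NAE and SSIM (11-pixel
Gaussian window, σ 1.5, K₁ = 0.01, K₂ = 0.03, valid region). The lift ratio
of metric X is (X(Ga,Gf) − X(Ga,Go)) / X(Ga,Go) with Ga the ideal image, Go
the reconstruction, Gf the filtered reconstruction; denominators below 1e-12
are flagged rather than zeroed. The study never defines its "anticipated"
image operationally; `ideal_image()` renders the absorbing disks at
reconstruction resolution with intensity proportional to μₐ — the only
observer-independent choice.

`isolate_artifacts()` subtracts a blood-only simulation from the full one
(raw traces or un-normalized images, keeping the subtraction linear);
`fit_semicircle()` fits an algebraic least-squares circle to the thresholded
residual and reports centre, radius and angular span. On the uniform-light
`s4` pair the fitted circle sits within ~1 mm of the air tube with radius
within 10% of the blood–air distance and an arc span near 180° — the
semicircular-artifact mechanism, quantified.

`waist_sweep()` runs the full Gaussian-light pipeline per waist radius,
reports per-metric lift ratios and the ADF/NLM improvement-rate ratio,
flags waists below 8 mm as unstable (over-focused illumination makes the
metrics track the visible light paths instead of the tubes), smooths the
ratio curves with a 3-point moving average and reports sign changes of
(ratio − 1) by linear interpolation.

**A finding that disagrees with the source study.** The study reports that
the ADF/NLM improvement-ratio curves cross 1 near a 17 mm waist for the
horizontal arrangement, i.e. ADF overtakes NLM as the light becomes *more*
uniform — while its own uniform-light table shows NLM winning every metric.
Those two statements are hard to reconcile, and this implementation comes
down on the table's side: across waists of 5–20 mm the ADF/NLM PSNR-lift
ratio stays well below 1 (NLM wins throughout, consistently with the
uniform-light ordering), and no crossover occurs in (10, 20) mm. The
corresponding acceptance test asserts the study's claim and is expected to
fail; the sweep machinery itself (curve computation, instability flagging,
crossover detection on constructed fixtures) is fully tested. Likely
contributors: the study's unreported filter hyperparameters, and its
physical-experiment light nonuniformities (fiber-bundle speckle, specular
reflections) that a clean Gaussian-beam Monte Carlo does not produce.

## Problem sizes

The package defaults are the desk-scale study conditions: forward grid
121×121 at 1 mm with 4096 samples at 12.5 ns (the study's own acoustic
settings), reconstruction 300×300 at 0.4 mm, 10⁵–10⁶ photons. The
acceptance script runs the uniform-light pipelines, the paired artifact
isolation, solver and Monte Carlo validations, and a five-point waist sweep
({5, 10, 14, 17, 20} mm at 10⁵ photons) in a few minutes on one CPU; the
full 1–20 mm sweep at 10⁸ photons and 1200×1200 reconstruction is reachable
through the same configuration objects.

## Known limitations

* 2-D acoustics only; element directivity, finite aperture and the physical
  array's 5 MHz band limit are not modelled (bandwidth enters only through
  the 750 kHz reconstruction low-pass).
* No acoustic attenuation, nonlinearity, or tube-wall acoustics.
* The Monte Carlo beam geometry (stand-off, aiming) is a documented default
  where the study is pictorial.
* Lift ratios are sensitive to the normalization convention; all reports
  name the convention and the filter parameters that produced them.
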