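# pacavity

Simulation and artifact-removal evaluation for photoacoustic tomography of
cavity-structure phantoms.

Photoacoustic tomography (PAT) maps optical absorbers — chiefly hemoglobin —
by recording the ultrasound launched when pulsed light heats absorbing
tissue. Organs containing air cavities (lungs, airways) defeat naive PAT:
the acoustic impedance of air (Z = ρc ≈ 340 m/s × 1.2 kg/m³) is ~3 orders of
magnitude below soft tissue's (1500 m/s × 1000 kg/m³), so the wave leaving a
blood vessel reflects almost totally off a nearby air space. Delay-and-sum
reconstruction places that reflected energy on a bright **semicircular
artifact** centred on the air inclusion with radius equal to the blood–air
distance. `pacavity` reproduces this mechanism in silico and quantifies how
well two classical denoisers remove it.

The package is aimed at researchers studying PAT artifact physics and
artifact-removal selection. It provides, as composable R functions:

* **phantom** — a 5 cm agarose substrate with 1 mm blood/air/water tubes in
  horizontal rows (`s4`–`s6`), 3×3 Latin squares (`S4`–`S6`) and controls;
  rasterization and 3-D voxelization (`build_arrangement`, `rasterize`,
  `voxelize`);
* **optics** — uniform-light initial pressure P₀ = Γ·η·μₐ·F and a seeded
  voxel Monte Carlo photon transport (Henyey–Greenstein scattering, Fresnel
  boundaries, Russian roulette) for Gaussian beams of waist 1–20 mm
  (`uniform_initial_pressure`, `mc_fluence`, `absorption_map`);
* **acoustics** — a k-space pseudospectral solver for the first-order
  acoustic equations on heterogeneous media with PML, a 128-element half-ring
  array (radius 55 mm), plus an independent FDTD cross-check and the
  grid-design formulas f_max = c/2Δx, Δx ≤ c/2f_max, depth = N_s·c/f_max
  (`forward_simulate`, `fdtd_simulate`, `max_supported_frequency`,
  `max_spatial_step`, `max_depth`);
* **recon** — zero-phase 750 kHz Butterworth low-pass and delay-and-sum
  beamforming at 1429 m/s (optional air-aware two-speed delays)
  (`lowpass`, `das_reconstruct`);
* **filters** — Perona–Malik anisotropic diffusion (ADF) with both published
  coefficient forms, and non-local means (NLM), C-accelerated
  (`adf`, `nlm`);
* **evaluate** — PSNR/SSIM/MSE/NAE, the lift ratio
  (X(Ga,Gf) − X(Ga,Go)) / X(Ga,Go), ideal-image rendering, paired-simulation
  artifact isolation with semicircle fitting, and the beam-waist uniformity
  sweep with ADF/NLM crossover detection (`image_metrics`, `lift_ratio`,
  `ideal_image`, `isolate_artifacts`, `fit_semicircle`, `waist_sweep`);
* **pipeline** — YAML-configurable end-to-end runs with reproducible,
  hash-manifested outputs (`experiment_config`, `run_pipeline`).

## Worked example

Blood–air–water phantom under uniform light, the study's acoustic settings
(121×121 grid at 1 mm, 4096 samples at 12.5 ns), desk-scale reconstruction:

```r
library(pacavity)

max_spatial_step(340, 750e3) * 1e3   # largest grid step resolving 750 kHz in air
#> [1] 0.2266667                      # mm; the study quotes 0.226 mm
max_depth(4096, 340, 750e3)
#> [1] 1.856853                       # m; the study quotes 1.857 m

model  <- build_arrangement("s4", tube_radius = 0.5, spacing = 10)
grid   <- acoustic_grid_spec()
labels <- rasterize(model, grid$shape, grid$pitch)
p0     <- uniform_initial_pressure(labels)   # P0 = mu_a: blood 3, rest 0
sd     <- forward_simulate(p0, labels, grid = grid)   # ~15 s
rs     <- recon_spec()                       # 300 x 300 at 0.4 mm
go     <- das_reconstruct(lowpass(sd), rs)   # normalized [0, 1] image
ga     <- ideal_image(model, rs)             # ground-truth blood disk

gf  <- nlm(go, nlm_params(h = 2 * diff(range(go$values))))
rep <- metric_report(ga, go, gf)
sprintf("PSNR %.2f -> %.2f dB (lift %+.1f%%)",
        rep$baseline$psnr, rep$filtered$psnr, 100 * rep$lift_ratios$psnr)
#> [1] "PSNR 28.84 -> 30.60 dB (lift +6.1%)"
sprintf("MSE %.5f -> %.5f (lift %+.1f%%)",
        rep$baseline$mse, rep$filtered$mse, 100 * rep$lift_ratios$mse)
#> [1] "MSE 0.00130 -> 0.00087 (lift -33.3%)"
```

The reconstruction shows the blood tube plus the semicircular air artifact;
NLM raises PSNR by ~6% and cuts MSE by a third against the ideal image —
the uniform-light ordering (NLM over ADF, error metrics falling) that the
evaluation suite checks. Subtracting a blood-only twin simulation isolates
the artifact itself:

```r
model_b <- model
model_b$inclusions <- subset(model$inclusions, medium == "blood")
sd_b  <- forward_simulate(uniform_initial_pressure(rasterize(model_b, grid$shape, grid$pitch)),
                          rasterize(model_b, grid$shape, grid$pitch), grid = grid)
rs_m  <- recon_spec(sound_speed_water = 1500)  # matched-speed delays
art   <- isolate_artifacts(das_reconstruct(lowpass(sd), rs_m, normalize = "none"),
                           das_reconstruct(lowpass(sd_b), rs_m, normalize = "none"))
fit_semicircle(art, threshold = 0.5)
#> centre within ~1 mm of the air tube, radius ~9 mm (blood-air distance 10 mm),
#> arc span ~185 degrees
```

A full pipeline run with manifested outputs:

```r
res <- run_pipeline(experiment_config(arrangement_id = "s4", seed = 1))
res$manifest   # labels, p0, sensor data, recon, both filtered images, metrics + MD5s
```

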