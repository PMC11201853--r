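---
title: "Neural reflectivity fields for phase-less echolocation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural reflectivity fields for phase-less echolocation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the echo-formation model behind the simulator, the reflectivity field and
its rendering equation, the training procedure, the reconstruction step,
the parameters that matter, and the numerical choices made where the design
was genuinely open. Every empirical number quoted here is computed by the
package's test suite or by `scripts/acceptance.R`; nothing is asserted that
those runs do not measure.

## 1. Why phase-less

A gleaning bat's auditory periphery behaves like band-pass filters followed
by envelope detection, so the phase of the incoming pressure wave is lost.
The sensory input is therefore modeled as the *magnitude* of a short-time
Fourier transform of the binaural echoes — a `2·N_f × N_t` matrix per
ensonification (left-ear rows stacked over right-ear rows), dechirped so a
point reflector's energy collects in one range column, and compressed
logarithmically to a `[0, 1]` scale. Discarding phase makes classic
phase-coherent tomography inapplicable and is the entire reason a learned,
render-and-compare approach is interesting: 3D structure emerges from
solving a prediction task ("what would this scene sound like from a pose I
have not visited?") rather than from inverting a wave equation.

## 2. The echo simulator (training-data generator)

Scenes are collections of point-like reflectors — the Huygens approximation
of surfaces. Each scatterer has a nonnegative gain, optionally a complex
per-frequency reflection spectrum over the call band, and optionally a
cosine-power directional lobe. Echoes are synthesized in the frequency
domain: per scatterer and ear, the emitted spectrum is multiplied by the
ERTF (the product of the emitter's and that ear's piston directivities,
evaluated at the scatterer's body-frame direction), the scatterer's
reflection filter at its incidence direction, and a pure delay
`exp(-j 2π f r / v_s)` at the full emitter→scatterer→ear path length `r`;
contributions sum linearly over scatterers.

Deliberate modeling choices:

* **Spreading loss.** The idealized filter product contains no amplitude
  decay; the simulator applies round-trip geometric spreading
  `1/(d_out · d_back)` by default, with `sim_config(spreading = FALSE)` for
  the strictly lossless mode. Both paths are tested.
* **Directivity stand-in.** Measured bat ERTFs are not shipped; the default
  is a parametric stand-in — a 4 mm circular-piston emitter and two 6 mm
  piston ears at (±7 mm lateral, +5 mm up), tilted ±15° in azimuth — with
  each ear's combined ERTF normalized to unit gain on the forward axis. The
  bare baffled-piston pattern has no rear rolloff (it is ≈0.1 in magnitude
  at 90° for these apertures), so it is multiplied by a cardioid-style
  `(1 + cos θ)/2` taper: rear directions become near-zero while the Bessel
  null positions are unchanged (verified against a brute-force aperture
  integral). With tilted ears, on-axis normalization implies |E| can exceed
  1 toward an ear's own axis; we keep on-axis normalization because a unit
  forward gain is the natural reference for a forward-looking sonar.
  Tabulated ERTFs over (azimuth, elevation, frequency) are accepted via
  `ertf_from_table()`.
* **What is not modeled.** No multi-path, no occlusion or shadowing between
  scatterers, no atmospheric absorption, no Doppler, single-harmonic FM
  call. These are exactly the effects the rendering equation cannot express
  either, so the generator matches the model class; consequences for
  realism are discussed in §7.
* **Noise.** Optional additive white noise at a configurable level relative
  to the peak signal, off by default, seeded when on.

The call is a descending FM sweep (default 100→40 kHz, 1 ms, linear law;
hyperbolic available) with a mild Tukey amplitude taper (fraction 0.1) to
confine spectral leakage; out-of-band energy is under 5% by an independent
DFT check. Its closed-form delay law `Δt(f)` (0 at the top frequency, the
full duration at the bottom) drives dechirping.

## 3. From echoes to observations

`make_observation()` composes: Hann-windowed STFT magnitude per ear
(window 64 samples, zero-padded FFT, magnitudes linearly interpolated onto
47 uniform band bins), binaural concatenation (94 rows), dechirp (each row
shifted left by `round(Δt(f)/column_dt)` columns, both ear blocks
identically, vacated columns zero-filled), and logarithmic compression

```
C(x) = clip( (20·log10(x/ref + ε) − floor) / (ceiling − floor), 0, 1 )
```

with floor −60 dB, ceiling 0 dB and ε = 1e−6. The range axis uses the
round-trip convention `r = v_s·t/2` with column times at window centers.

Numerical notes:

* **Columns.** The default overlap is 93.75% (hop 4 samples at 400 kHz),
  which yields on the order of 450–500 range columns for the default 0.6 m
  maximum range — the intended full-scale observation size. Reduced runs in
  the tests use 75% overlap (~87 columns) to keep training sets small.
* **Dechirp quantization.** Shifts are by nearest column; no sub-column
  interpolation, since magnitude-only data has no meaningful sub-sample
  phase. A single reflector's per-row peaks then align to within one column
  — except in two well-understood situations: when the target's delay falls
  within half a column of a column boundary, rounding parity can split rows
  across two columns; and at the extreme band edges the finite window
  truncated against the sweep's onset/offset biases the peak by up to half
  a window length. At fine hops this bias becomes visible as a few columns
  of spread in the outermost rows; it is part of why phase-less range
  processing "thickens" reconstructions.
* **Compression reference.** One reference amplitude — the maximum
  pre-compression magnitude across the whole training ensemble — is shared
  by all observations of an ensemble (stored in its metadata). Paired
  scenes meant for energy differencing must share a single reference across
  both ensembles (`simulate_ensemble(..., ref = )`), otherwise their energy
  volumes are not on a common scale.

## 4. The reflectivity field

`F_Θ` is an MLP taking six inputs — the queried position (normalized, see
below) and the unit ensonification direction — lifted by a Fourier
embedding: per input scalar `v`, the features `sin(2^l π v), cos(2^l π v)`
for 15 octaves, i.e. 30 features per input, 180 in total. Hidden layers use
leaky-ReLU (slope 0.01); chosen layers receive a depth-concatenated copy of
the embedding (skip connections); the linear output layer has 94 units
decoded as 47 real + 47 imaginary parts of the complex band spectrum.

* **Default profile.** Hidden widths (256, 256, 256, 256, 280, 256) with
  the skip concat before layer 5 give 462,166 learnable parameters — the
  ~5×10^5 scale of the full model. All reduced experiments use two hidden
  layers of 64 with the skip at layer 2 (33,374 parameters).
* **Position normalization.** Octave embeddings assume O(1) inputs. We
  normalize positions not by the tight scene box but by the *ensonified
  volume* — the bounding box of all training pose positions dilated by the
  maximum range — because the renderer queries the field over entire
  hemispheres spanning that volume. Normalizing by the (much smaller) scene
  box would push most queries far outside [−1, 1], where the high octaves
  alias into incoherent features, and training then fails to fit at all.
  The normalization box is stored with the trained field and reused
  verbatim at prediction and reconstruction time.
* **Direction convention.** The direction input points from the sensor
  toward the queried point (the direction from which the point is being
  ensonified); direction dependence is what lets the field express
  non-isotropic reflectivity.

## 5. Rendering and training

One rendered range slice integrates the field over a discretized
constant-range forward hemisphere: a deterministic Fibonacci lattice of 600
points (first point exactly on the forward axis, equal weights summing to
2π), each point contributing `F_Θ(p, v) · E_ear(ψ, ω)`; the magnitude of
the weighted sum, times an inert unimodular round-trip delay factor, is
compressed with the ensemble's reference. The ERTF over the lattice depends
only on body-frame directions, so it is computed once per training run.

Training treats every (pose, range column) pair as one sample. Each epoch
shuffles all slices (seeded), renders minibatches, and takes Adam steps on
the mean squared error between rendered and measured compressed spectra;
the learning rate starts at 0.01 and is multiplied by 0.97 after each
epoch. Empty slices (no echo energy) are kept: they supervise free space
toward zero reflectivity. All slices are used for fitting — no validation
split, as is usual for radiance-field models — and evaluation poses are
generated separately.

Two training-procedure details matter in practice:

* **Output-scale calibration.** The compression clips at 0 below the floor,
  and the clip's gradient is exactly zero. A freshly initialized network
  whose rendered magnitudes start below the floor therefore receives no
  gradient anywhere and never learns. At initialization the output layer is
  deterministically rescaled (from a probe of 64 fixed slices) so the
  median rendered magnitude sits about −20 dB below the ensemble reference,
  inside the active region of the compression.
* **Batch size at reduced scale.** The full-scale default batch of 512 is
  about 0.25% of a 200,000-slice training set. The desk-scale experiments
  have ~2,000 slices, where a 512 batch would leave five updates per epoch;
  they therefore use batch 128, keeping the per-epoch update count
  meaningful. The package default remains 512.

Gradients are computed by hand-derived analytic backpropagation through the
entire pipeline — compression, magnitude, the complex hemisphere sum with
ERTF weights, and the MLP — and are verified against central finite
differences (relative agreement better than 1e−4, measured ~1e−6) both at
the MLP level and through the full render-plus-loss composition. The
magnitude's derivative is guarded at zero; clipped compression regions
propagate zero gradient by construction. Training aborts with a diagnostic
message if the loss goes non-finite. Checkpoints (parameters, Adam state,
RNG state) can be written every *k* epochs; resuming reproduces the
uninterrupted run's loss to well below 1e−6.

## 6. Reconstruction

`query_grid()` evaluates the trained field at every voxel center of a cubic
grid for 100 ensonification directions on a deterministic full-sphere
lattice, storing per (voxel, direction) the band energy Σ_ω |F_Θ|²; the
"energy" reading of the reflectivity value matches the energy-difference
use downstream. `integrate_directions()` sums over the direction axis
exactly (verified against a brute-force four-loop sum to 1e−12).
`isosurface()` extracts the level set at a configurable fraction (default
0.5) of the volume maximum by marching tetrahedra: each grid cube is split
into six tetrahedra around a fixed diagonal, consistently across cubes, so
shared faces agree and smooth closed level sets come out watertight (the
Euler characteristic of the Gaussian-blob test surface is 2). Maximum
intensity projections and signed volume differences complete the toolkit;
for paired-scene comparisons both projections are normalized to the joint
maximum of the two volumes.

The reference voxel size for the full model is 0.5 mm; a desk default of
5 mm keeps grid sizes tractable, and `query_grid()` refuses grids beyond a
configurable cell budget with a size estimate rather than exhausting
memory.

## 7. Reduced study conditions, and what the tests do and do not show

The full-scale setup — 100–400 ensonifications, ~500 columns, the ~5×10^5
parameter field, 100 epochs — is a GPU-days workload. The package's test
suite and acceptance script run two reduced experiments chosen to preserve
the phenomena rather than the scale:

* **One-sphere experiment.** A 3 cm sphere sampled as 48 surface
  scatterers, 24 poses at 0.3 m, maximum range 0.45 m, 75% overlap (~87
  columns), the 2×64 field, 20 epochs, 192 hemisphere points, batch 128.
  Measured at seed 1: final epoch mean loss ≈ 0.05× the first epoch's;
  Pearson correlation ≈ 0.81 between predicted and simulated compressed
  spectrograms pooled over 4 held-out poses; energy-volume argmax ≈ 0.4 cm
  from the true center; isosurface bounding radius ≈ 3.3 cm against the
  true 1.5 cm radius — the inflation expected from semi-coherent range
  processing.
* **Prey-localization experiment.** A 10 cm leaf disc with and without a
  compact higher-gain insect cluster perched at its center (insect gain 4,
  ~6 mm cluster, offset 8 mm off the leaf plane — the mid-leaf perch of the
  gleaning scenario), 24 poses, two fields trained under a shared
  compression reference, 16 epochs, 128 hemisphere points; energy volumes
  on a common grid at 5 mm voxels, 64 directions. Measured at seed 1: the
  difference-volume peak lies ≈ 1.1 cm from the insect centroid.

Because generator and model share the same physics class (point scatterers,
no multi-path, no occlusion), these results demonstrate internal
consistency of the render-and-learn loop, the geometry conventions, and
the reconstruction pipeline — not robustness to effects real foliage
produces (multi-path returns, occlusion, clutter, atmospheric absorption,
measurement noise). The known thickening of reconstructions and the
band-edge dechirp bias (§3) are real properties of phase-less processing
that do carry over.

## 8. Parameter reference

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `f_hi`, `f_lo` | 100e3, 40e3 | Hz | FM sweep band (descending) |
| `duration` | 1e-3 | s | sweep duration |
| `sample_rate` | 400e3 | Hz | simulation rate (> 2·f_hi) |
| `band_bins` | 47 | — | frequency bins spanning the band |
| `v_s` | 343 | m/s | speed of sound |
| `max_range` | 0.6 | m | one-way range covered by the signal |
| `window_len` / `overlap` | 64 / 0.9375 | samples / — | STFT analysis |
| `floor_db` / `ceiling_db` | −60 / 0 | dB | compression span |
| `embed_features` | 30 | — | sin/cos features per field input |
| `hidden` | 256,256,256,256,280,256 | — | MLP widths (~4.6e5 params) |
| `batch_size` / `lr` / `lr_drop` / `epochs` | 512 / 0.01 / 0.97 / 100 | — | optimizer schedule |
| `n_hemisphere` | 600 | — | hemisphere points per rendered slice |
| `voxel_size` | 0.005 (reference 0.0005) | m | reconstruction grid |
| `n_directions` | 100 | — | directions per voxel |
| `threshold_frac` | 0.5 | — | isosurface level, fraction of max |

All lattices (pose spheres, sphere surfaces, hemispheres, direction sets)
are deterministic Fibonacci constructions; seeds only rotate their phase,
so every experiment is exactly reproducible from its seed set.
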