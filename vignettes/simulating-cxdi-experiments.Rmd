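---
title: "Simulating coherent diffractive imaging experiments with cxdisim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating coherent diffractive imaging experiments with cxdisim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cxdisim)
```

## The physical model

Coherent X-ray diffractive imaging (CXDI) at free-electron laser sources
records far-field diffraction from individual, noncrystalline particles —
one ultrashort pulse, one pattern, one unknown orientation. `cxdisim`
generates such data with ground truth attached, for developing and stress
testing classification, background-subtraction and reconstruction
algorithms before (or instead of) beam time.

The elastic scattering amplitude of a particle with scatterers $j$ at
positions $\mathbf r_j$ and continuum-solvent sample points $k$ with
amplitudes $A_k$ is the direct sum

$$F(\mathbf q) \;=\; \sum_j \mathrm{occ}_j\, f_j(|\mathbf q|)\,
  e^{i \mathbf q \cdot \mathbf r_j}
  \;+\; \sum_k A_k\, e^{i \mathbf q \cdot \mathbf r_k},$$

with atomic form factors $f_j$ parameterized as the standard four-Gaussian
sum $f(s) = \sum_i a_i e^{-b_i s^2} + c$, $s = |\mathbf q|/(4\pi)$, so that
$f(0)$ equals the electron count. Throughout the package $\mathbf q =
\mathbf k_\mathrm{out} - \mathbf k_\mathrm{in}$ with $|\mathbf k| =
2\pi/\lambda$ and resolution $d = 2\pi/|\mathbf q|$.

A detector pixel at lab position $\mathbf p$ (interaction point at the
origin, beam along $+z$) sees momentum transfer $\mathbf q =
\tfrac{2\pi}{\lambda}(\hat{\mathbf p} - \hat{\mathbf z})$ — the Ewald-sphere
construction, bounding $|\mathbf q| \le 4\pi/\lambda$. The expected photon
count of pixel $p$ is

$$\lambda_p \;=\; \Phi\, r_e^2\, \Delta\Omega_p\, P_p\, |F(\mathbf q_p)|^2,$$

with fluence $\Phi$ (photons m$^{-2}$), classical electron radius $r_e$,
pixel solid angle $\Delta\Omega_p$ and Thomson polarization factor $P_p$
($1 - \hat u_x^2$ for horizontal polarization, the XFEL default). Measured
counts are independent Poisson draws from $\lambda_p$; both the ideal
$\lambda_p$ and the quantized photons can be saved.

## One-time volumes, per-shot slices

Because direct summation scales with the atom count, `build_volume()`
evaluates $|F|^2$ once per particle state on a cubic grid
$[-q_\mathrm{max}, q_\mathrm{max}]^3$; each shot then rotates the pixel
momentum transfers by the orientation quaternion and interpolates the
volume trilinearly (`slice_pattern()`), at a per-shot cost independent of
particle size. Orientations are drawn uniformly over SO(3) (unit
quaternions via the subgroup algorithm); $q$ and $-q$ act identically.

Numerical choices:

* **Grid extent**: `q_max` defaults to 1.02 x the detector's maximum
  recorded momentum transfer, so every pixel stays inside the volume at any
  orientation.
* **Grid density**: the intensity speckle (Shannon) spacing of a particle
  of diameter $D$ is $\pi/D$; `default_n_grid()` places `oversampling`
  grid points per Shannon spacing. The default of 8 keeps the trilinear
  interpolation error of the full pipeline below 1% relative RMS against
  exact direct summation even for worst-case, high-contrast speckle
  (hollow-shell test particles); 4-fold oversampling suffices for globular
  particles. Out-of-volume pixels are masked, never extrapolated.
* **Multi-particle shots** (aggregates, FXS, FTH) need inter-particle
  interference, which a stored $|F|^2$ volume cannot supply; those patterns
  are computed by exact per-particle direct summation at the pixel
  momentum transfers: $|\sum_k e^{i\mathbf q\cdot\mathbf d_k}
  F_k(R_k\mathbf q)|^2$.
* **Polychromatic patterns** are incoherent weighted sums over spectrum
  samples, each with its own Ewald mapping — SASE spikes are mutually
  incoherent. A monochromatic spectrum reproduces the single-wavelength
  path exactly.

## Noise model

Each source is independently switchable and seeded; the per-shot order is
fixed: spectrum → slice/sum → static background → Poisson → digitize →
dark noise.

| Source | Model | Key parameter (default) |
|---|---|---|
| Photon counting | Poisson($\lambda_p$) | — |
| SASE spectrum | Gaussian KDE over spike trains | `bandwidth_fraction` (1e-3) |
| Fluence jitter | $N \cdot \max(0, 1+\varepsilon)$, $\varepsilon \sim \mathcal N(0,\sigma^2)$ | `jitter_fraction` (0) |
| Beam miscentering | per-axis Gaussian center offset, remapped to reciprocal space | `miscenter_sigma_m` (0) |
| Dark noise | supplied pedestal-subtracted frames, or Gaussian ADU | `dark_sigma_adu` (0) |
| Static background | expected photons added before Poisson sampling | `static_background` |
| Auto-ranging gain | pixel-wise gain switching at 80% full well | 1 : 6.7 : 100 relative gains |
| Heterogeneity | normal-mode conformer libraries | mode amplitudes (Å RMSD) |
| Hydration layer | continuum shell on the particle contour | thickness; 0.334 e Å$^{-3}$ |
| Aggregation | ballistic hit-and-stick clusters | `particles_per_shot` |

Decisions the underlying physics leaves open, fixed here:

* **SASE**: spike center energies $\sim \mathcal N(E_0, (\mathrm{bw}\cdot
  E_0)^2)$, heights $\sim U(0.5, 1.5)$, KDE bandwidth by Scott's rule over
  the spike centers, evaluated on an energy grid spanning $\pm 4\sigma$.
  Spike energies and per-spike fluences are independent.
* **Static background** is added to the *expected* intensities, so it is
  Poisson-sampled together with the signal; dark noise is detector-side
  and is added after digitization, in ADU.
* **Auto-ranging** keeps ADU continuous (no integer rounding), so decoding
  ADU / gain recovers the deposited energy exactly in noise-free mode;
  energy past the coarsest range is clamped at full well and flagged.
* **Hydration**: the particle envelope is the union of spheres of radius
  1.7 Å (a generic heavy-atom van der Waals radius, configurable) around
  the scatterers; solvent points sit on a cubic lattice (2 Å default)
  restricted to the shell, each carrying `density * voxel^3` electrons at
  bulk-water density 0.334 e Å$^{-3}$. Points are q-independent
  amplitudes; keep the lattice spacing below the inverse of the recorded
  `q_max` (times the oversampling) to avoid aliasing. Cavity filling
  identifies interior voids by flood fill from the bounding box, so only
  voxels disconnected from the exterior are filled.
* **Normal modes**: a uniform-spring anisotropic network (15 Å cutoff,
  unit spring constant — eigenvalues are scale-free) over C-alpha nodes
  when present, otherwise a spatial subsample capped at 500 nodes.
  Conformers draw zero-mean Gaussian coefficients per selected internal
  mode, scaled so the signed per-state RMSD contribution of mode $m$ has
  standard deviation `amplitudes[m]`; an absolute-valued RMSD cannot have
  that standard deviation for a symmetric draw, so the signed convention
  is the one the scale parameter refers to. Non-node scatterers ride with
  their nearest node.
* **Aggregation**: collision detection is at bounding-sphere level (the
  hit-and-stick idealization: no re-orientation, compression or
  fragmentation after contact). Incoming members launch from a uniform
  random direction with a transverse impact offset uniform in the
  cluster's projected disk, and translate toward the cluster center of
  mass until first sphere contact. Partial aggregation (several clusters
  per shot) is not modeled — sticking is all-or-nothing.
* **Interaction volume**: a box (extents configurable, 1 micron default),
  uniform particle positions. For single-particle shots the displacement
  is recorded as ground truth but does not alter the recorded intensity
  (the transverse phase ramp is invisible in $|F|^2$ and the
  distance-dependent solid-angle change is negligible over micron-scale
  jitter); for FXS/FTH the positions enter the coherent sum as phase
  factors.
* **FTH**: the reference (a gold FCC nanosphere by default) sits at a
  fixed configurable separation from the target, default 2.5 x the summed
  diameters along x.

## Reproducibility

One root seed per experiment; every shot derives independent child streams
per noise stage via exact integer mixing (Lehmer steps modulo $2^{31}-1$),
so shot $i$ is bit-reproducible regardless of execution order — verified
by the determinism tests. Datasets are CXI-flavored HDF5 with complete
ground truth (orientations, positions, particle counts, per-shot fluence,
miscenter offsets, seeds).

## Validation utilities

`fsc()` computes the Fourier shell correlation
$\mathrm{FSC}(k) = \mathrm{Re}\sum F_1 F_2^* / \sqrt{\sum|F_1|^2
\sum|F_2|^2}$ per spherical shell (the real part, since the raw ratio can
be complex for finite shells), and `resolution_at_threshold()` reports the
first crossing below a threshold (0.5 by convention) by linear
interpolation, as $d = 1/k$ in the map's cycles-per-Angstrom convention
(the angular-frequency equivalent $2\pi/q$ is stated in the attributes to
avoid the $2\pi$ ambiguity). No mask or shell apodization is applied.

## What the synthetic fixtures do and do not show

The test suite and the acceptance script run on generated toy particles —
two-atom pairs (closed-form fringes), hollow shells and uniform balls
(analytic sphere scattering, first intensity zero at $qR = 4.4934$),
random coils (generic globular speckle) — plus Monte Carlo checks of every
noise source at its configured parameter. Problem sizes are kept modest
(detectors up to 256 x 256, particles up to a few hundred scatterers,
runs of ~100 shots) so the whole validation executes in minutes on one
CPU; the same code paths scale to megapixel detectors and full proteins
linearly in pixels and atoms. Passing these checks demonstrates correct
physics, statistics and bookkeeping on ideal particles; it does not
demonstrate realism of any particular biological target, detector
calibration, or facility-specific dark noise — those enter through
user-supplied PDB/HDF5 structures, geometry files and dark-frame stacks.

## Known limitations

No radiation-damage dynamics (the pattern is computed from a static
structure per shot), no incoherent/Compton scattering, no detector
point-spread function or charge sharing, no wavefront propagation or
transverse-coherence modeling, no protonation or alternate-location
handling, and no facility calibration-constant ingestion. Reconstruction
(phase retrieval) is deliberately out of scope: this package produces the
data such algorithms consume.
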