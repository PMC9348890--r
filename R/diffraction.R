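# Diffraction engine. The elastic scattering amplitude of a particle is the
# direct sum F(q) = sum_j occ_j f_j(|q|) exp(i q.r_j) + sum_k A_k exp(i q.r_k)
# over scatterers j and continuum-solvent points k. |F|^2 is evaluated once on
# a 3D reciprocal-space grid per particle state (cost linear in the atom
# count); each shot then slices the Ewald sphere through this volume by
# trilinear interpolation at a cost independent of the atom count.

#' Structure factors by direct summation
#'
#' Exact direct summation of atomic form factors and solvent amplitudes; this
#' is the reference for everything downstream (volumes, slices).
#'
#' @param p A [particle].
#' @param q_points n x 3 matrix of scattering vectors in Angstrom^-1.
#' @param chunk Internal chunk size bounding the phase-matrix memory.
#' @return Complex amplitudes in electrons, length n.
#' @export
structure_factor_direct <- function(p, q_points, chunk = 4e6) {
  stopifnot(inherits(p, "particle"))
  q_points <- if (is.matrix(q_points)) q_points else matrix(q_points, ncol = 3)
  stopifnot(ncol(q_points) == 3, all(is.finite(q_points)))
  m <- nrow(q_points)
  qmag <- sqrt(rowSums(q_points^2))
  Fq <- complex(m)
  groups <- .ff_groups(p)
  n_pts <- nrow(p$positions) + nrow(p$solvent_points)
  csize <- max(1L, as.integer(chunk %/% max(1L, n_pts)))
  for (s in seq(1L, m, by = csize)) {
    e <- min(m, s + csize - 1L)
    Q <- q_points[s:e, , drop = FALSE]
    for (g in groups) {
      R <- p$positions[g$indices, , drop = FALSE]
      occ <- p$occupancy[g$indices]
      ph <- Q %*% t(R)                       # (chunk x n_group) phases
      S <- (cos(ph) + 1i * sin(ph)) %*% occ  # coherent sum over the group
      Fq[s:e] <- Fq[s:e] + form_factor(g$record, qmag[s:e]) * S[, 1]
    }
    if (nrow(p$solvent_points)) {
      ph <- Q %*% t(p$solvent_points)
      Fq[s:e] <- Fq[s:e] +
        ((cos(ph) + 1i * sin(ph)) %*% p$solvent_amplitude)[, 1]
    }
  }
  Fq
}

#' Precompute a particle's 3D diffraction volume
#'
#' Evaluates `|F(q)|^2` on the cubic grid `[-q_max, q_max]^3` with `n_grid`
#' (odd) voxels per axis, by direct summation. This is a one-time cost per
#' particle state; per-shot patterns are then produced by [slice_pattern()]
#' at a rate independent of the atom count.
#'
#' The grid must oversample the particle's speckles: choose the voxel spacing
#' `2 q_max / (n_grid - 1)` at most a quarter of the Shannon spacing
#' `pi / D` for particle diameter D (see [default_n_grid()]).
#'
#' @param p A [particle].
#' @param q_max Grid half-extent per axis in Angstrom^-1.
#' @param n_grid Odd voxel count per axis (>= 9).
#' @return Object of class `diffraction_volume`: `grid` (n^3 array of
#'   electrons^2), `q_max`, `n_grid`, `axis` (voxel center coordinates),
#'   `particle_label`.
#' @export
build_volume <- function(p, q_max, n_grid) {
  stopifnot(inherits(p, "particle"), q_max > 0, n_grid >= 9, n_grid %% 2 == 1)
  ax <- seq(-q_max, q_max, length.out = n_grid)
  qpts <- as.matrix(expand.grid(qx = ax, qy = ax, qz = ax,
                                KEEP.OUT.ATTRS = FALSE))
  Fq <- structure_factor_direct(p, qpts)
  vol <- array(Re(Fq)^2 + Im(Fq)^2, dim = c(n_grid, n_grid, n_grid))
  structure(list(grid = vol, q_max = q_max, n_grid = n_grid, axis = ax,
                 particle_label = p$label),
            class = "diffraction_volume")
}

#' @export
print.diffraction_volume <- function(x, ...) {
  cat(sprintf("<diffraction_volume> %s: %d^3 voxels, q_max %.4g A^-1 (dq %.4g)\n",
              x$particle_label, x$n_grid, x$q_max, x$axis[2] - x$axis[1]))
  invisible(x)
}

#' Default grid size for a detector/particle pairing
#'
#' Smallest odd integer giving at least `oversampling`-fold sampling of the
#' particle's Shannon voxel `pi / D` across `[-q_max, q_max]`.
#'
#' @param q_max Volume half-extent (Angstrom^-1).
#' @param particle_diameter Particle diameter D in Angstrom.
#' @param oversampling Grid points per Shannon spacing (default 8, keeping
#'   trilinear interpolation error during slicing negligible).
#' @return Odd integer grid size (at least 9).
#' @export
default_n_grid <- function(q_max, particle_diameter, oversampling = 8) {
  dq <- (pi / particle_diameter) / oversampling
  n <- ceiling(2 * q_max / dq) + 1
  n <- max(9, n)
  if (n %% 2 == 0) n <- n + 1
  as.integer(n)
}

#' Cache a diffraction volume to HDF5
#' @param vol A `diffraction_volume`.
#' @param path Output path (overwritten).
#' @return `path`, invisibly.
#' @export
write_volume_h5 <- function(vol, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(vol$grid, path, "volume")
  rhdf5::h5write(vol$q_max, path, "q_max")
  rhdf5::h5write(vol$n_grid, path, "n_grid")
  rhdf5::h5write(vol$particle_label, path, "particle_label")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Load a cached diffraction volume
#' @param path HDF5 path written by [write_volume_h5()].
#' @return A `diffraction_volume`.
#' @export
read_volume_h5 <- function(path) {
  grid <- rhdf5::h5read(path, "volume")
  q_max <- as.numeric(rhdf5::h5read(path, "q_max"))
  n_grid <- as.integer(rhdf5::h5read(path, "n_grid"))
  label <- as.character(rhdf5::h5read(path, "particle_label"))
  structure(list(grid = array(grid, dim = c(n_grid, n_grid, n_grid)),
                 q_max = q_max, n_grid = n_grid,
                 axis = seq(-q_max, q_max, length.out = n_grid),
                 particle_label = label),
            class = "diffraction_volume")
}

# trilinear interpolation of a cubic volume at points (m x 3) on the axis
# grid; points outside return NA
.trilinear <- function(vol, axis, pts) {
  n <- length(axis)
  dq <- axis[2] - axis[1]
  # fractional voxel coordinates, 1-based
  fx <- (pts[, 1] - axis[1]) / dq + 1
  fy <- (pts[, 2] - axis[1]) / dq + 1
  fz <- (pts[, 3] - axis[1]) / dq + 1
  tol <- 1e-9  # voxel units: points on the boundary stay inside
  ok <- fx >= 1 - tol & fx <= n + tol & fy >= 1 - tol & fy <= n + tol &
    fz >= 1 - tol & fz <= n + tol
  out <- rep(NA_real_, nrow(pts))
  if (!any(ok)) return(out)
  clamp <- function(x) pmin(pmax(x, 1), n)
  fx <- clamp(fx[ok]); fy <- clamp(fy[ok]); fz <- clamp(fz[ok])
  i0 <- pmin(floor(fx), n - 1); j0 <- pmin(floor(fy), n - 1)
  k0 <- pmin(floor(fz), n - 1)
  tx <- fx - i0; ty <- fy - j0; tz <- fz - k0
  idx <- function(i, j, k) i + n * (j - 1) + n * n * (k - 1)
  v <- vol
  out[ok] <-
    v[idx(i0,     j0,     k0)]     * (1 - tx) * (1 - ty) * (1 - tz) +
    v[idx(i0 + 1, j0,     k0)]     * tx       * (1 - ty) * (1 - tz) +
    v[idx(i0,     j0 + 1, k0)]     * (1 - tx) * ty       * (1 - tz) +
    v[idx(i0 + 1, j0 + 1, k0)]     * tx       * ty       * (1 - tz) +
    v[idx(i0,     j0,     k0 + 1)] * (1 - tx) * (1 - ty) * tz +
    v[idx(i0 + 1, j0,     k0 + 1)] * tx       * (1 - ty) * tz +
    v[idx(i0,     j0 + 1, k0 + 1)] * (1 - tx) * ty       * tz +
    v[idx(i0 + 1, j0 + 1, k0 + 1)] * tx       * ty       * tz
  out
}

#' Slice an Ewald-sphere pattern from a diffraction volume
#'
#' Rotates the detector's pixel momentum transfers into the particle frame
#' (`q' = R q` for the orientation quaternion's rotation matrix R) and
#' interpolates the precomputed `|F|^2` volume trilinearly at those points.
#' Pixels falling outside the volume are returned as `NA` (masked, never
#' extrapolated).
#'
#' @param vol A `diffraction_volume`.
#' @param orientation Unit quaternion `(w, x, y, z)`.
#' @param maps [pixel_maps()] for the shot's wavelength.
#' @return Per-pixel `|F|^2` in electrons^2 (vector aligned with the maps);
#'   attribute `"out_of_volume"` flags masked pixels.
#' @export
slice_pattern <- function(vol, orientation, maps) {
  stopifnot(inherits(vol, "diffraction_volume"), inherits(maps, "pixel_maps"))
  R <- quat_to_matrix(orientation)
  qrot <- maps$q_vectors %*% t(R)
  out <- .trilinear(vol$grid, vol$axis, qrot)
  oov <- is.na(out)
  if (all(oov)) stop("all pixels fall outside the diffraction volume")
  attr(out, "out_of_volume") <- oov
  out
}

#' Coherent (or incoherent) multi-particle pattern
#'
#' For particle states k with orientation `R_k` and center offset `d_k`
#' (Angstrom), the coherent pattern is
#' `|sum_k exp(i q.d_k) F_k(R_k q)|^2`, evaluated by exact per-particle
#' direct summation at the pixel momentum transfers (squared-magnitude
#' volumes cannot carry the inter-particle cross terms). With
#' `coherent = FALSE` the single-particle intensities are summed instead.
#'
#' @param states List of states, each a list with `particle`, `orientation`
#'   (unit quaternion), `offset` (length-3, Angstrom).
#' @param maps [pixel_maps()] for the shot's wavelength.
#' @param coherent Sum amplitudes (TRUE, default) or intensities.
#' @return Per-pixel `|F_total|^2` in electrons^2.
#' @export
multi_particle_pattern <- function(states, maps, coherent = TRUE) {
  stopifnot(length(states) >= 1, inherits(maps, "pixel_maps"))
  Q <- maps$q_vectors
  # a state backed by a |F|^2 volume carries no phase: usable for incoherent
  # sums and for a lone particle (where the offset phase cancels)
  single <- length(states) == 1L
  total_amp <- complex(nrow(Q))
  total_int <- numeric(nrow(Q))
  for (st in states) {
    if (!is.null(st$volume)) {
      if (coherent && !single)
        stop("coherent multi-particle sums need particles (amplitudes), not |F|^2 volumes")
      I_k <- slice_pattern(st$volume, st$orientation, maps)
      if (coherent) return(I_k)
      I_k[is.na(I_k)] <- 0
      total_int <- total_int + I_k
      next
    }
    R <- quat_to_matrix(st$orientation)
    Fk <- structure_factor_direct(st$particle, Q %*% t(R))
    off <- if (is.null(st$offset)) c(0, 0, 0) else st$offset
    ph <- Q %*% off
    if (coherent) total_amp <- total_amp + exp(1i * ph[, 1]) * Fk
    else total_int <- total_int + Re(Fk)^2 + Im(Fk)^2
  }
  if (coherent) Re(total_amp)^2 + Im(total_amp)^2 else total_int
}

#' Expected photon counts for a pattern
#'
#' `lambda_p = fluence x r_e^2 x solid_angle_p x polarization_p x |F|^2_p`
#' with the classical electron radius `r_e = 2.8179403e-15 m` and fluence in
#' photons per square meter. These are the ideal intensities; Poisson
#' quantization is applied by [pattern_to_photons()].
#'
#' @param pattern Per-pixel `|F|^2` (electrons^2); `NA` treated as 0.
#' @param maps [pixel_maps()].
#' @param fluence Photons per square meter at the particle.
#' @return Expected photons per pixel.
#' @export
expected_counts <- function(pattern, maps, fluence) {
  stopifnot(inherits(maps, "pixel_maps"), fluence >= 0)
  pat <- pattern
  pat[is.na(pat)] <- 0
  if (any(pat < 0)) stop("negative pattern values")
  fluence * CLASSICAL_ELECTRON_RADIUS_M^2 * maps$solid_angle *
    maps$polarization * pat
}

#' Quantize a pattern to photon counts
#'
#' Photon counting follows a Poisson distribution: independent
#' `Poisson(lambda_p)` draws with `lambda_p` from [expected_counts()].
#'
#' @inheritParams expected_counts
#' @param seed Integer seed.
#' @return Integer photon counts per pixel.
#' @export
pattern_to_photons <- function(pattern, maps, fluence, seed = 1L) {
  lam <- expected_counts(pattern, maps, fluence)
  .with_seed(seed, stats::rpois(length(lam), lam))
}

#' Polychromatic pattern as an incoherent spectral mixture
#'
#' SASE spikes are mutually incoherent, so a polychromatic pattern is the
#' weighted sum over spectrum samples of monochromatic patterns, each sample
#' re-mapping the pixel momentum transfers for its own wavelength. A
#' monochromatic spectrum reproduces the plain single-wavelength path
#' exactly.
#'
#' @param vol A `diffraction_volume`.
#' @param orientation Unit quaternion.
#' @param geometry A `detector_geometry`.
#' @param spectrum A `spectrum` (from [monochromatic_spectrum()] or
#'   [sase_spectrum()]).
#' @param polarization Beam polarization state.
#' @return Per-pixel `|F|^2` weighted over the spectrum, with attribute
#'   `"maps"` holding the pixel maps of the central wavelength.
#' @export
polychromatic_pattern <- function(vol, orientation, geometry, spectrum,
                                  polarization = "horizontal") {
  stopifnot(inherits(spectrum, "spectrum"))
  acc <- NULL
  for (i in seq_len(nrow(spectrum))) {
    m_i <- pixel_maps(geometry, spectrum$wavelength[i], polarization)
    pat <- slice_pattern(vol, orientation, m_i)
    pat[is.na(pat)] <- 0
    acc <- if (is.null(acc)) spectrum$weight[i] * pat
           else acc + spectrum$weight[i] * pat
  }
  central <- sum(spectrum$weight * spectrum$wavelength)
  attr(acc, "maps") <- pixel_maps(geometry, central, polarization)
  acc
}
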