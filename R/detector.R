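# Detector geometry and detector-side noise: pixel-to-reciprocal-space
# mapping (Ewald construction), solid angle, polarization factor, beam
# miscentering, dark noise, static background, and auto-ranging gain.
#
# Conventions (fixed package-wide): q = k_out - k_in with |k| = 2*pi/lambda,
# resolution d = 2*pi/|q|; beam along +z; fast axis = x; pixel indices
# 0-based; even-sized arrays put the beam center between the two central
# pixels.

CLASSICAL_ELECTRON_RADIUS_M <- 2.8179403e-15

#' Monolithic square detector
#'
#' @param n_pixels Pixels per side.
#' @param pixel_size_m Pixel pitch in meters.
#' @param distance_m Sample-to-detector distance along the beam in meters.
#' @param center_offset_m Direct-beam position relative to the nominal array
#'   center, (x, y) in meters.
#' @param mask Logical live-pixel matrix (`n_pixels x n_pixels`); default all
#'   live.
#' @return Object of class `detector_geometry`.
#' @export
monolithic_detector <- function(n_pixels, pixel_size_m, distance_m,
                                center_offset_m = c(0, 0), mask = NULL) {
  stopifnot(n_pixels >= 2, pixel_size_m > 0, distance_m > 0)
  if (is.null(mask)) mask <- matrix(TRUE, n_pixels, n_pixels)
  stopifnot(all(dim(mask) == c(n_pixels, n_pixels)))
  half <- (n_pixels - 1) / 2
  panel <- list(nx = n_pixels, ny = n_pixels, pitch = pixel_size_m,
                origin = c(-half * pixel_size_m, -half * pixel_size_m, 0),
                fast = c(1, 0, 0), slow = c(0, 1, 0))
  structure(list(panels = list(panel), distance = distance_m,
                 center_offset = center_offset_m, mask = as.vector(mask),
                 dims = c(n_pixels, n_pixels), kind = "monolithic"),
            class = "detector_geometry")
}

#' Two-panel pnCCD-like detector with a central gap
#'
#' Two `n_pixels x n_pixels/2` panels separated along the slow (y) axis by a
#' physical gap, emulating the split-panel layout common at XFEL endstations.
#'
#' @inheritParams monolithic_detector
#' @param gap_m Physical gap between the panels in meters.
#' @return Object of class `detector_geometry`.
#' @export
pnccd_detector <- function(n_pixels, pixel_size_m, distance_m, gap_m,
                           center_offset_m = c(0, 0)) {
  stopifnot(n_pixels %% 2 == 0, gap_m >= 0)
  half_n <- n_pixels / 2L
  half <- (n_pixels - 1) / 2
  p_lo <- list(nx = n_pixels, ny = half_n, pitch = pixel_size_m,
               origin = c(-half * pixel_size_m,
                          -half * pixel_size_m - gap_m / 2, 0),
               fast = c(1, 0, 0), slow = c(0, 1, 0))
  p_hi <- list(nx = n_pixels, ny = half_n, pitch = pixel_size_m,
               origin = c(-half * pixel_size_m,
                          (0.5) * pixel_size_m + gap_m / 2, 0),
               fast = c(1, 0, 0), slow = c(0, 1, 0))
  structure(list(panels = list(p_lo, p_hi), distance = distance_m,
                 center_offset = center_offset_m,
                 mask = rep(TRUE, n_pixels * n_pixels),
                 dims = c(n_pixels, n_pixels), kind = "pnccd"),
            class = "detector_geometry")
}

#' Read a detector geometry from a YAML file
#'
#' Arbitrary panel layouts: a list of panels each with `nx`, `ny`,
#' `pitch_m`, `origin_m` (x, y relative offsets in the detector plane),
#' `fast`, `slow` (unit vectors), plus top-level `distance_m` and optional
#' `center_offset_m`.
#'
#' @param path YAML geometry file.
#' @return Object of class `detector_geometry`.
#' @export
read_geometry_yaml <- function(path) {
  g <- yaml::read_yaml(path)
  panels <- lapply(g$panels, function(p)
    list(nx = p$nx, ny = p$ny, pitch = p$pitch_m,
         origin = as.numeric(p$origin_m),
         fast = as.numeric(p$fast), slow = as.numeric(p$slow)))
  npix <- sum(vapply(panels, function(p) p$nx * p$ny, numeric(1)))
  structure(list(panels = panels, distance = g$distance_m,
                 center_offset = if (is.null(g$center_offset_m)) c(0, 0)
                                 else as.numeric(g$center_offset_m),
                 mask = rep(TRUE, npix), dims = NULL, kind = "custom"),
            class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  npix <- length(x$mask)
  cat(sprintf("<detector_geometry> %s, %d panel(s), %d pixels, distance %.3g m\n",
              x$kind, length(x$panels), npix, x$distance))
  invisible(x)
}

# lab-frame pixel centers (n_pix x 3, meters), origin at interaction point,
# honoring the per-shot beam-center offset
.pixel_positions <- function(geometry) {
  off <- geometry$center_offset
  do.call(rbind, lapply(geometry$panels, function(p) {
    i <- rep(seq_len(p$nx) - 1L, times = p$ny)    # fast varies fastest
    j <- rep(seq_len(p$ny) - 1L, each = p$nx)
    base <- cbind(p$origin[1] + i * p$pitch * p$fast[1] + j * p$pitch * p$slow[1],
                  p$origin[2] + i * p$pitch * p$fast[2] + j * p$pitch * p$slow[2],
                  geometry$distance +
                    if (length(p$origin) > 2) p$origin[3] else 0)
    base[, 1] <- base[, 1] - off[1]
    base[, 2] <- base[, 2] - off[2]
    base
  }))
}

#' Reciprocal-space pixel maps
#'
#' For each pixel at lab position p (interaction point at the origin), with
#' outgoing unit direction `u = p/|p|` and `k = 2 pi / lambda`, the momentum
#' transfer is `q = k (u - z_hat)` (Angstrom^-1), bounded by `|q| <= 4 pi /
#' lambda` on the Ewald sphere. The solid angle is `A cos(theta_inc) / |p|^2`
#' and the Thomson polarization factor follows the beam polarization state.
#'
#' @param geometry A `detector_geometry`.
#' @param lambda Wavelength in Angstrom.
#' @param polarization `"horizontal"` (default), `"vertical"` or
#'   `"unpolarized"`.
#' @return Object of class `pixel_maps`: `q_vectors` (n x 3, Angstrom^-1),
#'   `q_mag`, `solid_angle` (sr), `polarization` in [0, 1], `mask`, `dims`,
#'   `lambda`.
#' @export
pixel_maps <- function(geometry, lambda,
                       polarization = c("horizontal", "vertical", "unpolarized")) {
  stopifnot(inherits(geometry, "detector_geometry"), lambda > 0)
  polarization <- match.arg(polarization)
  P <- .pixel_positions(geometry)
  r <- sqrt(rowSums(P^2))
  if (any(r == 0)) stop("pixel at the interaction point")
  u <- P / r
  k <- 2 * pi / lambda
  q <- k * cbind(u[, 1], u[, 2], u[, 3] - 1)
  qmag <- sqrt(rowSums(q^2))
  pitch2 <- do.call(c, lapply(geometry$panels, function(p)
    rep(p$pitch^2, p$nx * p$ny)))
  solid <- pitch2 * u[, 3] / r^2
  pol <- switch(polarization,
                horizontal = 1 - u[, 1]^2,
                vertical = 1 - u[, 2]^2,
                unpolarized = (1 + u[, 3]^2) / 2)  # cos(2 theta) = u_z
  structure(list(q_vectors = q, q_mag = qmag, solid_angle = solid,
                 polarization = pol, mask = geometry$mask,
                 dims = geometry$dims, lambda = lambda,
                 polarization_state = polarization),
            class = "pixel_maps")
}

#' Resolution at the detector's outermost live pixel
#'
#' `d = 2 pi / q_max` over live pixels (the highest momentum transfer the
#' detector records, i.e. at the array corner for a square detector).
#'
#' @param geometry A `detector_geometry`.
#' @param lambda Wavelength in Angstrom.
#' @return Resolution in Angstrom.
#' @export
resolution_at_edge <- function(geometry, lambda) {
  m <- pixel_maps(geometry, lambda)
  2 * pi / max(m$q_mag[m$mask])
}

#' Detector distance achieving a requested resolution limit
#'
#' Inverse of [resolution_at_edge()]: the distance at which the outermost
#' live pixel reaches momentum transfer `2 pi / d`.
#'
#' @param geometry A `detector_geometry` (its distance is ignored).
#' @param lambda Wavelength in Angstrom.
#' @param d Requested resolution in Angstrom (`d > lambda / 2`).
#' @return Distance in meters.
#' @export
distance_for_resolution <- function(geometry, lambda, d) {
  stopifnot(d > lambda / 2)
  g0 <- geometry; g0$distance <- 1  # in-plane radii are distance independent
  P <- .pixel_positions(g0)
  r_max <- max(sqrt(rowSums(P[geometry$mask, 1:2, drop = FALSE]^2)))
  theta <- 2 * asin(lambda / (2 * d))  # scattering angle 2*theta
  r_max / tan(theta)
}

#' Noise configuration for the detector-side stack
#'
#' @param miscenter_sigma_m Gaussian sigma of per-axis beam miscentering in
#'   meters (length 1 or 2).
#' @param dark_frames Optional list of pedestal-subtracted dark frames (ADU
#'   arrays matching the detector); one is drawn at random per shot.
#' @param dark_sigma_adu Per-pixel Gaussian dark sigma in ADU, used when no
#'   frames are supplied (default 0 = off).
#' @param static_background Optional per-pixel expected background photons
#'   (added before Poisson quantization; >= 0).
#' @param gain_mode `"photon_counting"` (ADU = photon counts) or
#'   `"autoranging"` (pixel-wise gain switching as in ePix10k/Jungfrau).
#' @param adu_per_kev Gain levels in ADU per keV, positive and descending
#'   (finest first); default `c(10, 10/6.7, 0.1)` (relative gains 1:6.7:100).
#' @param full_well_adu Full well per range in ADU (default 16384).
#' @param switch_fraction Switch to the next range at this fraction of full
#'   well (default 0.8).
#' @return Object of class `noise_config`.
#' @export
noise_config <- function(miscenter_sigma_m = 0, dark_frames = NULL,
                         dark_sigma_adu = 0, static_background = NULL,
                         gain_mode = c("photon_counting", "autoranging"),
                         adu_per_kev = c(10, 10 / 6.7, 0.1),
                         full_well_adu = 16384, switch_fraction = 0.8) {
  gain_mode <- match.arg(gain_mode)
  miscenter_sigma_m <- rep_len(miscenter_sigma_m, 2L)
  stopifnot(all(miscenter_sigma_m >= 0), dark_sigma_adu >= 0,
            all(adu_per_kev > 0), all(diff(adu_per_kev) < 0) || length(adu_per_kev) == 1,
            switch_fraction > 0, switch_fraction <= 1)
  if (!is.null(static_background) && any(static_background < 0))
    stop("static background must be nonnegative")
  structure(list(miscenter_sigma_m = miscenter_sigma_m,
                 dark_frames = dark_frames, dark_sigma_adu = dark_sigma_adu,
                 static_background = static_background,
                 gain_mode = gain_mode, adu_per_kev = adu_per_kev,
                 full_well_adu = full_well_adu,
                 switch_fraction = switch_fraction),
            class = "noise_config")
}

#' Draw a beam-miscentering offset
#'
#' Displacements of the direct-beam position relative to the detector center
#' are independent per axis and Gaussian distributed; apply the draw with
#' [with_miscenter()] before computing pixel maps for the shot.
#'
#' @param noise A `noise_config`.
#' @param seed Integer seed.
#' @return Offset `(dx, dy)` in meters.
#' @export
sample_miscenter <- function(noise, seed = 1L) {
  stopifnot(inherits(noise, "noise_config"))
  s <- noise$miscenter_sigma_m
  if (all(s == 0)) return(c(0, 0))
  .with_seed(seed, stats::rnorm(2, 0, s))
}

#' Apply a beam-center offset to a geometry
#' @param geometry A `detector_geometry`.
#' @param offset `(dx, dy)` in meters, added to the current center offset.
#' @return Updated geometry.
#' @export
with_miscenter <- function(geometry, offset) {
  geometry$center_offset <- geometry$center_offset + offset
  geometry
}

#' Add fluctuating dark noise to an ADU image
#'
#' Adds one randomly selected supplied dark frame, or per-pixel
#' `N(0, dark_sigma^2)` ADU when no frames are supplied. Dark noise is
#' incoherent and detector-side: it is applied after photon quantization and
#' digitization, in ADU.
#'
#' @param image ADU array.
#' @param noise A `noise_config`.
#' @param seed Integer seed.
#' @return ADU array of the same shape.
#' @export
apply_dark_noise <- function(image, noise, seed = 1L) {
  stopifnot(inherits(noise, "noise_config"))
  if (!is.null(noise$dark_frames)) {
    k <- .with_seed(seed, sample.int(length(noise$dark_frames), 1))
    frame <- noise$dark_frames[[k]]
    if (length(frame) != length(image))
      stop("dark frame shape does not match the image")
    return(image + frame)
  }
  if (noise$dark_sigma_adu == 0) return(image)
  image + .with_seed(seed,
    stats::rnorm(length(image), 0, noise$dark_sigma_adu))
}

#' Add a static background to expected photon intensities
#'
#' The background (parasitic scattering, optics shadows) is added
#' incoherently to the expected diffraction intensities, before photon
#' quantization — so it is Poisson-sampled together with the signal.
#'
#' @param lambda Expected-photon array.
#' @param background Expected background photons per pixel (>= 0), same shape.
#' @return Array of summed expected photons.
#' @export
apply_static_background <- function(lambda, background) {
  if (is.null(background)) return(lambda)
  if (any(background < 0)) stop("negative background")
  if (length(background) != length(lambda)) stop("background shape mismatch")
  lambda + background
}

#' Digitize photon counts to ADU
#'
#' Photon-counting mode returns the counts as ADU. Auto-ranging mode converts
#' counts to deposited energy (keV), selects per pixel the finest gain range
#' whose switch threshold is not exceeded, and returns `ADU = energy x gain`.
#' Energy beyond the coarsest range is clamped at full well and flagged
#' saturated. ADU are kept continuous so that decoding `ADU / gain` recovers
#' the deposited energy exactly in noise-free mode.
#'
#' @param photons Nonnegative photon counts.
#' @param noise A `noise_config`.
#' @param photon_energy_ev Photon energy in eV (needed for auto-ranging).
#' @return ADU array with attributes `gain_index` (1 = finest) and
#'   `saturated` (logical).
#' @export
digitize <- function(photons, noise, photon_energy_ev = NULL) {
  stopifnot(inherits(noise, "noise_config"), all(photons >= 0))
  if (noise$gain_mode == "photon_counting") {
    out <- photons
    attr(out, "gain_index") <- rep(1L, length(photons))
    attr(out, "saturated") <- rep(FALSE, length(photons))
    return(out)
  }
  if (is.null(photon_energy_ev)) stop("auto-ranging needs the photon energy")
  e_kev <- as.numeric(photons) * photon_energy_ev / 1000
  gains <- noise$adu_per_kev
  thresh <- noise$switch_fraction * noise$full_well_adu / gains  # keV per range
  gi <- rep(length(gains), length(e_kev))
  for (r in rev(seq_along(gains))) gi[e_kev <= thresh[r]] <- r
  sat <- e_kev > thresh[length(gains)]
  adu <- pmin(e_kev * gains[gi], noise$full_well_adu)
  out <- adu
  attributes(out) <- attributes(photons)
  attr(out, "gain_index") <- gi
  attr(out, "saturated") <- sat
  out
}
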