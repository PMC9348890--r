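# X-ray pulse model: central photon energy, photon budget, focus geometry,
# spatial fluence profile, shot-to-shot jitter, and the wavelength spectrum
# (monochromatic or SASE spike trains).

HC_EV_ANGSTROM <- 12398.42  # h*c in eV * Angstrom

#' Construct a beam
#'
#' @param photon_energy_ev Central photon energy in eV (> 0).
#' @param photons_per_pulse Photons per pulse (>= 0).
#' @param focus_radius_m Focus radius in meters (circular focus) — for the
#'   uniform profile; for the Gaussian profile it sets `sigma_x = sigma_y`
#'   unless overridden.
#' @param profile `"uniform"` or `"gaussian"`.
#' @param sigma_x_m,sigma_y_m Gaussian-profile standard deviations in meters;
#'   default `focus_radius_m`.
#' @param jitter_fraction Relative standard deviation of Gaussian shot-to-shot
#'   total-fluence jitter (>= 0, default 0).
#' @param polarization `"horizontal"`, `"vertical"` or `"unpolarized"`.
#' @return Object of class `beam`.
#' @export
beam <- function(photon_energy_ev, photons_per_pulse,
                 focus_radius_m = 1e-7,
                 profile = c("uniform", "gaussian"),
                 sigma_x_m = focus_radius_m, sigma_y_m = focus_radius_m,
                 jitter_fraction = 0,
                 polarization = c("horizontal", "vertical", "unpolarized")) {
  stopifnot(photon_energy_ev > 0, photons_per_pulse >= 0,
            focus_radius_m > 0, jitter_fraction >= 0)
  structure(list(photon_energy_ev = photon_energy_ev,
                 photons_per_pulse = photons_per_pulse,
                 focus_radius_m = focus_radius_m,
                 profile = match.arg(profile),
                 sigma_x_m = sigma_x_m, sigma_y_m = sigma_y_m,
                 jitter_fraction = jitter_fraction,
                 polarization = match.arg(polarization)),
            class = "beam")
}

#' @export
print.beam <- function(x, ...) {
  cat(sprintf("<beam> %.1f eV (%.3f A), %.3g photons/pulse, %s profile, %s polarization\n",
              x$photon_energy_ev, wavelength(x), x$photons_per_pulse,
              x$profile, x$polarization))
  if (x$jitter_fraction > 0)
    cat(sprintf("  fluence jitter sigma: %.1f%%\n", 100 * x$jitter_fraction))
  invisible(x)
}

#' Central wavelength of a beam
#'
#' `lambda[A] = 12398.42 / E[eV]`.
#' @param b A [beam] or a photon energy in eV.
#' @return Wavelength in Angstrom.
#' @export
wavelength <- function(b) {
  e <- if (inherits(b, "beam")) b$photon_energy_ev else b
  HC_EV_ANGSTROM / e
}

#' Monochromatic spectrum
#'
#' @param b A [beam].
#' @return A `spectrum` data frame with a single sample of weight 1.
#' @export
monochromatic_spectrum <- function(b) {
  out <- data.frame(wavelength = wavelength(b), weight = 1)
  structure(out, class = c("spectrum", "data.frame"),
            provenance = "monochromatic")
}

#' Simulate a SASE spectrum as a Gaussian KDE over uncorrelated spikes
#'
#' Self-amplified spontaneous emission produces pulses whose energy spectrum
#' is a train of uncorrelated spikes. Spike center energies are drawn
#' independently from `N(E0, (bandwidth_fraction * E0)^2)`, spike heights
#' independently from `Uniform(0.5, 1.5)`; a Gaussian kernel density estimate
#' (bandwidth by Scott's rule over the spike centers) is evaluated on
#' `n_samples` energies spanning E0 +/- 4 sigma and returned as normalized
#' (wavelength, weight) samples. Spectrum samples are treated as mutually
#' incoherent downstream.
#'
#' @param b A [beam] (supplies the central energy E0).
#' @param n_spikes Number of spikes (>= 1).
#' @param bandwidth_fraction Relative sigma of the spike-center distribution
#'   (> 0; SASE bandwidth is typically ~1e-3).
#' @param n_samples Number of returned spectral samples (default 100).
#' @param seed Integer seed.
#' @param height_range Spike-height range for the uniform draw.
#' @return A `spectrum` data frame: columns `wavelength` (Angstrom) and
#'   `weight` (nonnegative, summing to 1).
#' @export
sase_spectrum <- function(b, n_spikes = 15L, bandwidth_fraction = 1e-3,
                          n_samples = 100L, seed = 1L,
                          height_range = c(0.5, 1.5)) {
  stopifnot(inherits(b, "beam"), n_spikes >= 1, bandwidth_fraction > 0,
            n_samples >= 1)
  e0 <- b$photon_energy_ev
  sig <- bandwidth_fraction * e0
  sm <- .with_seed(seed, {
    centers <- stats::rnorm(n_spikes, e0, sig)
    heights <- stats::runif(n_spikes, height_range[1], height_range[2])
    list(centers = centers, heights = heights)
  })
  h <- if (n_spikes >= 2) stats::bw.nrd(sm$centers) else 0.25 * sig
  if (!is.finite(h) || h <= 0) h <- max(0.25 * sig, 1e-12 * e0)
  egrid <- seq(e0 - 4 * sig, e0 + 4 * sig, length.out = n_samples)
  w <- sm$heights / sum(sm$heights)
  dens <- vapply(egrid, function(e)
    sum(w * stats::dnorm(e, sm$centers, h)), numeric(1))
  if (sum(dens) <= 0) dens <- rep(1, length(egrid))
  out <- data.frame(wavelength = HC_EV_ANGSTROM / egrid,
                    weight = dens / sum(dens))
  structure(out, class = c("spectrum", "data.frame"),
            provenance = list(type = "sase", seed = seed, n_spikes = n_spikes,
                              bandwidth_fraction = bandwidth_fraction,
                              kde_bandwidth_ev = h,
                              spike_centers_ev = sm$centers,
                              spike_heights = sm$heights))
}

#' Spectral centroid energy
#' @param s A `spectrum`.
#' @return Weight-averaged photon energy in eV.
#' @export
spectrum_centroid_ev <- function(s) {
  sum(s$weight * HC_EV_ANGSTROM / s$wavelength)
}

#' Draw the total fluence for one shot
#'
#' Shot-to-shot changes in total fluence are Gaussian: the pulse photon count
#' is scaled by `max(0, 1 + eps)` with `eps ~ N(0, jitter_fraction^2)`.
#'
#' @param b A [beam].
#' @param seed Integer seed.
#' @return Photons in this pulse (scalar, >= 0).
#' @export
shot_fluence <- function(b, seed = 1L) {
  stopifnot(inherits(b, "beam"))
  if (b$jitter_fraction == 0) return(b$photons_per_pulse)
  eps <- .with_seed(seed, stats::rnorm(1, 0, b$jitter_fraction))
  b$photons_per_pulse * max(0, 1 + eps)
}

#' Fluence at a transverse offset from the beam axis
#'
#' Uniform profile: `N / (pi r^2)` inside the focus, 0 outside. Gaussian
#' profile: a 2D Gaussian normalized so its integral over the plane equals
#' the pulse photon count.
#'
#' @param b A [beam].
#' @param offset Length-2 transverse offset (x, y) in meters, or an n x 2
#'   matrix.
#' @param photons Pulse photon count for this shot (default the beam nominal;
#'   pass a [shot_fluence()] draw to include jitter).
#' @return Fluence in photons per square meter.
#' @export
fluence_at <- function(b, offset = c(0, 0), photons = b$photons_per_pulse) {
  stopifnot(inherits(b, "beam"))
  off <- if (is.matrix(offset)) offset else matrix(offset, ncol = 2)
  if (b$profile == "uniform") {
    r2 <- rowSums(off^2)
    out <- ifelse(r2 <= b$focus_radius_m^2,
                  photons / (pi * b$focus_radius_m^2), 0)
  } else {
    out <- photons / (2 * pi * b$sigma_x_m * b$sigma_y_m) *
      exp(-off[, 1]^2 / (2 * b$sigma_x_m^2) - off[, 2]^2 / (2 * b$sigma_y_m^2))
  }
  if (!is.matrix(offset)) out[1] else out
}
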