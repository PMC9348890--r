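# Experiment orchestration: SPI, SPI-aggregate, FXS and FTH runs share one
# shot pipeline, differing only in the number, type and relative positions of
# the particles in the beam. Per shot: draw states, orientations and
# positions; spectrum -> slice/coherent sum -> static background -> Poisson
# -> digitize -> dark noise; record all ground truth.

#' Configure a CXDI experiment
#'
#' @param kind `"spi"` (one particle per shot), `"spi_aggregate"` (particles
#'   stick into one ballistic cluster), `"fxs"` (many dispersed particles) or
#'   `"fth"` (target + reference hologram).
#' @param n_shots Number of shots.
#' @param particles List of [particle] states (the state library).
#' @param beam A [beam].
#' @param geometry A `detector_geometry`.
#' @param weights Sampling weight per state (normalized internally).
#' @param noise A [noise_config()] (default: all detector noise off).
#' @param particles_per_shot Fixed particle count per shot (aggregate/FXS).
#' @param poisson_mean If set (FXS), per-shot counts are drawn
#'   `Poisson(poisson_mean)` instead of fixed.
#' @param interaction_box_m Extents (x, y, z) in meters of the box where the
#'   sample jet and beam overlap; particle positions are uniform in it.
#' @param reference Reference [particle] for FTH (e.g. [gold_reference()]).
#' @param reference_offset_A Target-to-reference separation vector (Angstrom,
#'   in the detector plane); default `2.5 * (target diameter + reference
#'   diameter)` along x.
#' @param outputs `"both"`, `"ideal"` or `"photons"`.
#' @param spectrum_type `"monochromatic"` or `"sase"`.
#' @param sase Options for [sase_spectrum()] (list: `n_spikes`,
#'   `bandwidth_fraction`, `n_samples`).
#' @param q_max Diffraction-volume half-extent; default 1.02 x the detector's
#'   maximum momentum transfer at the central wavelength.
#' @param n_grid Volume grid size; default from [default_n_grid()] with
#'   `oversampling` grid points per Shannon spacing of the largest state.
#' @param oversampling Grid points per Shannon spacing (default 8).
#' @param seed Root seed; per-shot child streams are derived with
#'   [derive_seed()] so shot i is reproducible independently of order.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(kind = c("spi", "spi_aggregate", "fxs", "fth"),
                              n_shots, particles, beam, geometry,
                              weights = NULL, noise = noise_config(),
                              particles_per_shot = NULL, poisson_mean = NULL,
                              interaction_box_m = c(1e-6, 1e-6, 1e-6),
                              reference = NULL, reference_offset_A = NULL,
                              outputs = c("both", "ideal", "photons"),
                              spectrum_type = c("monochromatic", "sase"),
                              sase = list(n_spikes = 15L,
                                          bandwidth_fraction = 1e-3,
                                          n_samples = 25L),
                              q_max = NULL, n_grid = NULL, oversampling = 8,
                              seed = 1L) {
  kind <- match.arg(kind)
  outputs <- match.arg(outputs)
  spectrum_type <- match.arg(spectrum_type)
  stopifnot(n_shots >= 1, length(particles) >= 1,
            inherits(beam, "beam"), inherits(geometry, "detector_geometry"),
            inherits(noise, "noise_config"))
  lapply(particles, function(p) stopifnot(inherits(p, "particle")))
  if (is.null(weights)) weights <- rep(1, length(particles))
  stopifnot(length(weights) == length(particles), all(weights >= 0),
            sum(weights) > 0)
  weights <- weights / sum(weights)
  if (kind == "spi") particles_per_shot <- 1L
  if (kind == "fth") {
    if (is.null(reference)) stop("fth needs a reference particle")
    if (length(particles) != 1L) stop("fth uses exactly one target source")
    particles_per_shot <- 1L
    if (is.null(reference_offset_A)) {
      d_t <- 2 * bounding_radius(particles[[1]])
      d_r <- 2 * bounding_radius(reference)
      reference_offset_A <- c(2.5 * (d_t + d_r), 0, 0)
    }
  }
  if (is.null(particles_per_shot) && is.null(poisson_mean))
    particles_per_shot <- 2L
  lam0 <- wavelength(beam)
  if (is.null(q_max)) {
    m0 <- pixel_maps(geometry, lam0, beam$polarization)
    q_max <- 1.02 * max(m0$q_mag[m0$mask])
  }
  if (is.null(n_grid)) {
    dmax <- max(vapply(particles, function(p) 2 * bounding_radius(p) +
                         ifelse(nrow(p$solvent_points) > 0, 4, 0), numeric(1)))
    dmax <- max(dmax, 2)  # lone atoms: any small grid oversamples
    n_grid <- default_n_grid(q_max, dmax, oversampling)
  }
  structure(list(kind = kind, n_shots = as.integer(n_shots),
                 particles = particles, weights = weights,
                 beam = beam, geometry = geometry, noise = noise,
                 particles_per_shot = particles_per_shot,
                 poisson_mean = poisson_mean,
                 interaction_box_m = interaction_box_m,
                 reference = reference,
                 reference_offset_A = reference_offset_A,
                 outputs = outputs, spectrum_type = spectrum_type,
                 sase = sase, q_max = q_max, n_grid = as.integer(n_grid),
                 oversampling = oversampling, seed = as.integer(seed)),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config> %s: %d shots, %d state(s), seed %d\n",
              x$kind, x$n_shots, length(x$particles), x$seed))
  cat(sprintf("  volume: %d^3 voxels to q_max %.4g A^-1; spectrum %s; outputs %s\n",
              x$n_grid, x$q_max, x$spectrum_type, x$outputs))
  invisible(x)
}

#' Precompute the per-state diffraction volumes of a configuration
#'
#' One volume per library state (the one-time cost); reused across shots by
#' [simulate_shot()] for single-particle slicing.
#'
#' @param config An `experiment_config`.
#' @return List of `diffraction_volume`, one per state.
#' @export
precompute_volumes <- function(config) {
  lapply(config$particles, build_volume, q_max = config$q_max,
         n_grid = config$n_grid)
}

# stage ids for per-shot child RNG streams
.STREAM <- c(states = 1L, orient = 2L, place = 3L, cluster = 4L,
             spectrum = 5L, fluence = 6L, miscenter = 7L, poisson = 8L,
             dark = 9L, count = 10L)

#' Simulate one shot
#'
#' Draws the shot's particle state(s), orientations (uniform over SO(3)) and
#' positions (uniform in the interaction volume), computes the coherent
#' pattern, and applies the noise stack in the fixed order: spectrum ->
#' slice/sum -> static background -> Poisson -> digitize -> dark. All
#' randomness flows through child streams of `(seed, shot_index)`.
#'
#' @param config An `experiment_config`.
#' @param shot_index Shot number (1-based).
#' @param volumes Optional [precompute_volumes()] result (computed on the
#'   fly when omitted; precomputing is much faster across shots).
#' @return A `shot_record`: list with `ideal` (expected photons per pixel,
#'   background included), `photons`, `adu` (when digitization/dark applies),
#'   `n_particles`, `state_index`, `orientations` (n x 4), `positions_m`
#'   (n x 3), `fluence_photons`, `miscenter_m`, `shot_index`.
#' @export
simulate_shot <- function(config, shot_index, volumes = NULL) {
  stopifnot(inherits(config, "experiment_config"), shot_index >= 1)
  cfg <- config
  sd_of <- function(stage) derive_seed(cfg$seed, shot_index, .STREAM[[stage]])

  # ---- how many particles, which states
  n_p <- if (cfg$kind %in% c("spi", "fth")) 1L
         else if (!is.null(cfg$poisson_mean))
           .with_seed(sd_of("count"), stats::rpois(1, cfg$poisson_mean))
         else as.integer(cfg$particles_per_shot)
  state_idx <- if (n_p > 0)
    .with_seed(sd_of("states"),
               sample.int(length(cfg$particles), n_p, replace = TRUE,
                          prob = cfg$weights))
  else integer(0)

  # ---- orientations and positions
  quats <- if (n_p > 0) .with_seed(sd_of("orient"), random_quaternions(n_p))
           else matrix(numeric(0), 0, 4)
  box <- cfg$interaction_box_m
  pos_m <- if (n_p > 0) .with_seed(sd_of("place"), {
    matrix(stats::runif(3 * n_p, -0.5, 0.5), n_p, 3, byrow = TRUE) *
      matrix(box, n_p, 3, byrow = TRUE)
  }) else matrix(numeric(0), 0, 3)

  # ---- beam for this shot
  photons <- shot_fluence(cfg$beam, sd_of("fluence"))
  fl <- fluence_at(cfg$beam, c(0, 0), photons)
  spec <- if (cfg$spectrum_type == "sase")
    sase_spectrum(cfg$beam, n_spikes = cfg$sase$n_spikes,
                  bandwidth_fraction = cfg$sase$bandwidth_fraction,
                  n_samples = cfg$sase$n_samples, seed = sd_of("spectrum"))
  else monochromatic_spectrum(cfg$beam)

  # ---- per-shot geometry (beam miscentering)
  mis <- sample_miscenter(cfg$noise, sd_of("miscenter"))
  geom <- with_miscenter(cfg$geometry, mis)

  # ---- diffraction pattern |F|^2 per pixel
  if (n_p == 0) {
    m0 <- pixel_maps(geom, wavelength(cfg$beam), cfg$beam$polarization)
    pat <- numeric(length(m0$q_mag))
    maps <- m0
  } else if (cfg$kind == "spi") {
    vol <- if (!is.null(volumes)) volumes[[state_idx[1]]]
           else build_volume(cfg$particles[[state_idx[1]]], cfg$q_max, cfg$n_grid)
    # random displacement is metadata only for single particles (recorded in
    # positions_m); the transverse phase ramp is invisible in |F|^2
    sl <- .spectral_pattern_volume(vol, quats[1, ], geom, spec,
                                   cfg$beam$polarization)
    pat <- sl$pattern; maps <- sl$maps
  } else {
    states <- .shot_states(cfg, shot_index, n_p, state_idx, quats, pos_m)
    sl <- .spectral_pattern_direct(states, geom, spec, cfg$beam$polarization)
    pat <- sl$pattern; maps <- sl$maps
    quats <- sl$quats; pos_m <- sl$pos_m; state_idx <- sl$state_idx
    n_p <- nrow(quats)
  }

  # ---- noise stack: background -> Poisson -> digitize -> dark
  lam <- expected_counts(pat, maps, fl)
  lam <- apply_static_background(lam, cfg$noise$static_background)
  counts <- .with_seed(sd_of("poisson"), stats::rpois(length(lam), lam))
  adu <- NULL
  if (cfg$noise$gain_mode != "photon_counting" ||
      cfg$noise$dark_sigma_adu > 0 || !is.null(cfg$noise$dark_frames)) {
    adu <- digitize(counts, cfg$noise, cfg$beam$photon_energy_ev)
    adu <- apply_dark_noise(adu, cfg$noise, sd_of("dark"))
  }
  structure(list(ideal = if (cfg$outputs != "photons") lam else NULL,
                 photons = if (cfg$outputs != "ideal") counts else NULL,
                 adu = adu, n_particles = n_p, state_index = state_idx,
                 orientations = quats, positions_m = pos_m,
                 fluence_photons = photons, miscenter_m = mis,
                 shot_index = shot_index),
            class = "shot_record")
}

# assemble per-particle states (orientation + Angstrom offsets) for the
# coherent multi-particle sum
.shot_states <- function(cfg, shot_index, n_p, state_idx, quats, pos_m) {
  if (cfg$kind == "fth") {
    target <- cfg$particles[[state_idx[1]]]
    states <- list(
      list(particle = target, orientation = quats[1, ], offset = c(0, 0, 0)),
      list(particle = cfg$reference,
           orientation = .with_seed(derive_seed(cfg$seed, shot_index, 11L),
                                    random_quaternions(1))[1, ],
           offset = cfg$reference_offset_A))
    # record both members
    quats <- rbind(quats[1, , drop = FALSE], states[[2]]$orientation)
    pos_m <- rbind(pos_m[1, , drop = FALSE],
                   pos_m[1, ] + cfg$reference_offset_A * 1e-10)
    state_idx <- c(state_idx[1], NA_integer_)
    return(list(states = states, quats = quats, pos_m = pos_m,
                state_idx = state_idx))
  }
  if (cfg$kind == "spi_aggregate") {
    members <- cfg$particles[state_idx]
    layout <- build_cluster(members,
                            seed = derive_seed(cfg$seed, shot_index,
                                               .STREAM[["cluster"]]))
    states <- lapply(seq_len(n_p), function(m)
      list(particle = members[[m]], orientation = layout$quaternions[m, ],
           offset = layout$centers[m, ]))
    quats <- layout$quaternions
    # cluster internal geometry (Angstrom) rides on the common shot position
    pos_m <- sweep(layout$centers * 1e-10, 2, pos_m[1, ], "+")
    return(list(states = states, quats = quats, pos_m = pos_m,
                state_idx = state_idx))
  }
  # fxs: dispersed particles; Angstrom offsets from the metered positions
  states <- lapply(seq_len(n_p), function(m)
    list(particle = cfg$particles[[state_idx[m]]], orientation = quats[m, ],
         offset = pos_m[m, ] * 1e10))
  list(states = states, quats = quats, pos_m = pos_m, state_idx = state_idx)
}

.spectral_pattern_volume <- function(vol, quat, geom, spec, polstate) {
  if (nrow(spec) == 1L) {
    maps <- pixel_maps(geom, spec$wavelength[1], polstate)
    pat <- slice_pattern(vol, quat, maps)
    pat[is.na(pat)] <- 0
  } else {
    pat <- polychromatic_pattern(vol, quat, geom, spec, polstate)
    maps <- attr(pat, "maps")
    attr(pat, "maps") <- NULL
  }
  list(pattern = as.numeric(pat), maps = maps)
}

.spectral_pattern_direct <- function(st, geom, spec, polstate) {
  acc <- NULL; maps <- NULL
  for (i in seq_len(nrow(spec))) {
    m_i <- pixel_maps(geom, spec$wavelength[i], polstate)
    pat <- multi_particle_pattern(st$states, m_i, coherent = TRUE)
    acc <- if (is.null(acc)) spec$weight[i] * pat else acc + spec$weight[i] * pat
    if (i == 1L) maps <- m_i
  }
  if (nrow(spec) > 1L) {
    central <- sum(spec$weight * spec$wavelength)
    maps <- pixel_maps(geom, central, polstate)
  }
  list(pattern = acc, maps = maps, quats = st$quats, pos_m = st$pos_m,
       state_idx = st$state_idx)
}

#' Run an experiment and write a CXI-flavored HDF5 dataset
#'
#' Streams `n_shots` records to one HDF5 file. Per-state diffraction volumes
#' are computed once and reused. Layout: `entry_1/data_1/data` (photons,
#' nx x ny x n_shots), `entry_1/data_1/ideal` (expected photons),
#' `entry_1/data_1/adu` (when digitization or dark noise is on),
#' `entry_1/sample_1/geometry/orientations` (4 x max_p x n_shots, NA-padded),
#' `.../positions` (3 x max_p x n_shots, meters),
#' `entry_1/instrument_1/detector_1/{distance, x_pixel_size, wavelength}`,
#' and a `ground_truth` group (n_particles, state_index, fluence,
#' miscenter, seed).
#'
#' @param config An `experiment_config`.
#' @param path Output `.cxi`/`.h5` path (overwritten).
#' @param quiet Suppress the per-run log line?
#' @return `path`, invisibly.
#' @export
run_experiment <- function(config, path, quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  t0 <- proc.time()[["elapsed"]]
  volumes <- if (config$kind == "spi") precompute_volumes(config) else NULL
  t_vol <- proc.time()[["elapsed"]] - t0
  shots <- lapply(seq_len(config$n_shots), function(i)
    simulate_shot(config, i, volumes))
  t_all <- proc.time()[["elapsed"]] - t0
  .write_dataset(config, shots, path)
  if (!quiet)
    message(sprintf(
      "%s: %d shots in %.1f s (volumes %.1f s, %.2f patterns/s), seed %d -> %s",
      config$kind, config$n_shots, t_all, t_vol,
      config$n_shots / max(1e-9, t_all - t_vol), config$seed, path))
  invisible(path)
}

.write_dataset <- function(config, shots, path) {
  if (file.exists(path)) unlink(path)
  dims <- config$geometry$dims
  if (is.null(dims)) dims <- c(length(config$geometry$mask), 1L)
  n <- length(shots)
  maxp <- max(1L, vapply(shots, function(s) s$n_particles, integer(1)))
  to_cube <- function(field) {
    arr <- array(NA_real_, c(dims[1], dims[2], n))
    for (i in seq_len(n)) if (!is.null(shots[[i]][[field]]))
      arr[, , i] <- array(as.numeric(shots[[i]][[field]]), dims)
    arr
  }
  rhdf5::h5createFile(path)
  for (g in c("entry_1", "entry_1/data_1", "entry_1/sample_1",
              "entry_1/sample_1/geometry", "entry_1/instrument_1",
              "entry_1/instrument_1/detector_1", "ground_truth"))
    rhdf5::h5createGroup(path, g)
  if (!is.null(shots[[1]]$photons))
    rhdf5::h5write(to_cube("photons"), path, "entry_1/data_1/data")
  if (!is.null(shots[[1]]$ideal))
    rhdf5::h5write(to_cube("ideal"), path, "entry_1/data_1/ideal")
  if (!is.null(shots[[1]]$adu))
    rhdf5::h5write(to_cube("adu"), path, "entry_1/data_1/adu")
  orient <- array(NA_real_, c(4, maxp, n))
  posn <- array(NA_real_, c(3, maxp, n))
  npart <- integer(n); flu <- numeric(n)
  misc <- matrix(0, 2, n)
  stidx <- matrix(NA_integer_, maxp, n)
  for (i in seq_len(n)) {
    s <- shots[[i]]
    npart[i] <- s$n_particles; flu[i] <- s$fluence_photons
    misc[, i] <- s$miscenter_m
    if (s$n_particles > 0) {
      orient[, seq_len(s$n_particles), i] <- t(s$orientations)
      posn[, seq_len(s$n_particles), i] <- t(s$positions_m)
      stidx[seq_len(s$n_particles), i] <- s$state_index
    }
  }
  rhdf5::h5write(orient, path, "entry_1/sample_1/geometry/orientations")
  rhdf5::h5write(posn, path, "entry_1/sample_1/geometry/positions")
  rhdf5::h5write(config$geometry$distance, path,
                 "entry_1/instrument_1/detector_1/distance")
  rhdf5::h5write(config$geometry$panels[[1]]$pitch, path,
                 "entry_1/instrument_1/detector_1/x_pixel_size")
  rhdf5::h5write(wavelength(config$beam), path,
                 "entry_1/instrument_1/detector_1/wavelength")
  rhdf5::h5write(npart, path, "ground_truth/n_particles")
  rhdf5::h5write(stidx, path, "ground_truth/state_index")
  rhdf5::h5write(flu, path, "ground_truth/fluence")
  rhdf5::h5write(misc, path, "ground_truth/miscenter")
  rhdf5::h5write(config$seed, path, "ground_truth/seed")
  rhdf5::h5write(config$kind, path, "ground_truth/kind")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a dataset written by [run_experiment()]
#'
#' @param path Dataset path.
#' @return List with `photons`, `ideal`, `adu` (any may be `NULL`),
#'   `orientations`, `positions`, `n_particles`, `state_index`, `fluence`,
#'   `miscenter`, `seed`, `kind`, `distance`, `pixel_size`, `wavelength`.
#' @export
read_experiment <- function(path) {
  ls <- rhdf5::h5ls(path)
  nm <- paste(ls$group, ls$name, sep = "/")
  get <- function(key) {
    if (any(nm == key)) rhdf5::h5read(path, key) else NULL
  }
  out <- list(photons = get("/entry_1/data_1/data"),
              ideal = get("/entry_1/data_1/ideal"),
              adu = get("/entry_1/data_1/adu"),
              orientations = get("/entry_1/sample_1/geometry/orientations"),
              positions = get("/entry_1/sample_1/geometry/positions"),
              n_particles = as.integer(get("/ground_truth/n_particles")),
              state_index = get("/ground_truth/state_index"),
              fluence = as.numeric(get("/ground_truth/fluence")),
              miscenter = get("/ground_truth/miscenter"),
              seed = as.integer(get("/ground_truth/seed")),
              kind = as.character(get("/ground_truth/kind")),
              distance = as.numeric(get("/entry_1/instrument_1/detector_1/distance")),
              pixel_size = as.numeric(get("/entry_1/instrument_1/detector_1/x_pixel_size")),
              wavelength = as.numeric(get("/entry_1/instrument_1/detector_1/wavelength")))
  rhdf5::h5closeAll()
  out
}

#' Radially averaged intensity profile
#'
#' Mean pattern value over live pixels binned by momentum-transfer magnitude;
#' the small- and wide-angle scattering profile of a shot.
#'
#' @param pattern Per-pixel values (any of ideal/photons/ADU).
#' @param maps [pixel_maps()].
#' @param n_bins Number of equal-width q bins (>= 1).
#' @return Data frame with `q` (bin centers, Angstrom^-1), `intensity`
#'   (mean; `NA` for empty bins) and `n_pixels`.
#' @export
radial_profile <- function(pattern, maps, n_bins = 100L) {
  stopifnot(inherits(maps, "pixel_maps"), n_bins >= 1)
  live <- maps$mask & !is.na(pattern)
  qm <- maps$q_mag[live]
  v <- as.numeric(pattern)[live]
  edges <- seq(0, max(qm) * (1 + 1e-12), length.out = n_bins + 1)
  bin <- findInterval(qm, edges, rightmost.closed = TRUE)
  sums <- tapply(v, factor(bin, levels = seq_len(n_bins)), sum)
  cnts <- tapply(rep(1, length(v)), factor(bin, levels = seq_len(n_bins)), sum)
  cnts[is.na(cnts)] <- 0
  data.frame(q = (edges[-1] + edges[-(n_bins + 1)]) / 2,
             intensity = as.numeric(sums) / ifelse(cnts > 0, cnts, NA),
             n_pixels = as.integer(cnts))
}
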