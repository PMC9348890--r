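# Experiment orchestration: shot pipeline, datasets, ground truth, profiles

tiny_config <- function(kind = "spi", n_shots = 2, seed = 1L, ...) {
  experiment_config(
    kind = kind, n_shots = n_shots,
    particles = list(make_fixture("two_atom")),
    beam = beam(6000, 1e12, focus_radius_m = 1e-7),
    geometry = monolithic_detector(8, 300e-6, 0.1),
    seed = seed, ...)
}

test_that("noise-free SPI shots are deterministic and reproduce the ideal path", {
  cfg <- tiny_config()
  vols <- precompute_volumes(cfg)
  a <- simulate_shot(cfg, 1, vols)
  b <- simulate_shot(cfg, 1, vols)
  expect_identical(a, b)
  # order independence: shot 2 simulated alone equals shot 2 in sequence
  s2 <- simulate_shot(cfg, 2, vols)
  invisible(simulate_shot(cfg, 1, vols))
  expect_identical(simulate_shot(cfg, 2, vols), s2)

  # with all noise off the recorded ideal equals the manual pipeline
  maps <- pixel_maps(cfg$geometry, wavelength(cfg$beam), "horizontal")
  sl <- slice_pattern(vols[[1]], a$orientations[1, ], maps)
  sl[is.na(sl)] <- 0
  lam <- expected_counts(sl, maps, fluence_at(cfg$beam))
  expect_equal(a$ideal, as.numeric(lam))
  expect_identical(a$fluence_photons, cfg$beam$photons_per_pulse)
  expect_identical(a$miscenter_m, c(0, 0))
})

test_that("different seeds and shot indices give different shots", {
  cfg <- tiny_config(seed = 1)
  cfg2 <- tiny_config(seed = 2)
  vols <- precompute_volumes(cfg)
  expect_false(identical(simulate_shot(cfg, 1, vols)$orientations,
                         simulate_shot(cfg, 2, vols)$orientations))
  expect_false(identical(simulate_shot(cfg, 1, vols)$orientations,
                         simulate_shot(cfg2, 1, vols)$orientations))
})

test_that("datasets hold every shot with complete ground truth and round-trip", {
  cfg <- tiny_config(n_shots = 10)
  f <- tempfile(fileext = ".cxi")
  run_experiment(cfg, f, quiet = TRUE)
  ds <- read_experiment(f)
  expect_equal(dim(ds$photons), c(8, 8, 10))
  expect_equal(dim(ds$ideal), c(8, 8, 10))
  expect_length(ds$n_particles, 10)
  expect_true(all(ds$n_particles == 1))
  expect_equal(dim(ds$orientations), c(4, 1, 10))
  expect_equal(dim(ds$positions), c(3, 1, 10))
  expect_length(ds$fluence, 10)
  expect_true(all(ds$photons >= 0 & ds$photons == round(ds$photons)))
  # quaternions recorded unit-norm
  expect_equal(colSums(ds$orientations[, 1, ]^2), rep(1, 10), tolerance = 1e-9)
  # rerun with the same config and seed: identical content
  f2 <- tempfile(fileext = ".cxi")
  run_experiment(cfg, f2, quiet = TRUE)
  ds2 <- read_experiment(f2)
  expect_identical(ds, ds2)
})

test_that("state libraries are sampled at their configured weights", {
  lib <- list(make_fixture("two_atom", list(d = 8)),
              make_fixture("two_atom", list(d = 12)))
  cfg <- experiment_config(
    kind = "spi", n_shots = 1, particles = lib, weights = c(0.8, 0.2),
    beam = beam(6000, 1e12), geometry = monolithic_detector(8, 300e-6, 0.1),
    seed = 3)
  draws <- vapply(1:5000, function(i)
    cxdisim:::.with_seed(derive_seed(3L, i, 1L),
                         sample.int(2, 1, prob = c(0.8, 0.2))), integer(1))
  frac <- mean(draws == 1)
  expect_lt(abs(frac - 0.8), 3 * sqrt(0.8 * 0.2 / 5000))
  # and the full pipeline draws through the same stream
  vols <- precompute_volumes(cfg)
  recs <- lapply(1:200, function(i) simulate_shot(cfg, i, vols))
  got <- vapply(recs, function(r) r$state_index[1], integer(1))
  expect_identical(got, draws[1:200])
})

test_that("FXS particle counts follow the configured Poisson mean", {
  cfg <- tiny_config(kind = "fxs", poisson_mean = 2)
  counts <- vapply(1:10000, function(i)
    cxdisim:::.with_seed(derive_seed(1L, i, 10L), stats::rpois(1, 2)),
    integer(1))
  expect_lt(abs(mean(counts) - 2), 3 * sqrt(2 / 10000))
  recs <- lapply(1:300, function(i) simulate_shot(cfg, i))
  expect_identical(vapply(recs, `[[`, integer(1), "n_particles"), counts[1:300])
  # multi-particle shots carry per-particle ground truth
  k <- which(counts[1:300] >= 2)[1]
  expect_equal(nrow(recs[[k]]$orientations), counts[k])
  expect_equal(nrow(recs[[k]]$positions_m), counts[k])
})

test_that("aggregate shots place members in contact as one cluster", {
  cfg <- tiny_config(kind = "spi_aggregate", particles_per_shot = 4)
  rec <- simulate_shot(cfg, 1)
  expect_equal(rec$n_particles, 4L)
  # members ride at Angstrom-scale separations around the shot position
  d <- stats::dist(rec$positions_m * 1e10)
  R <- bounding_radius(cfg$particles[[1]])
  expect_true(all(d >= 2 * R * (1 - 1e-6)))
  expect_true(any(d <= 2 * R * (1 + 1e-3)))
})

test_that("FTH holograms carry cross-term fringes at the reference separation", {
  d_sep <- 40
  one_c <- particle(matrix(0, 1, 3), element = "AU")
  target <- particle(matrix(0, 1, 3), element = "C")
  cfg <- experiment_config(
    kind = "fth", n_shots = 1, particles = list(target),
    reference = one_c, reference_offset_A = c(d_sep, 0, 0),
    beam = beam(6000, 1e12), geometry = monolithic_detector(64, 150e-6, 0.05),
    outputs = "ideal", seed = 5)
  rec <- simulate_shot(cfg, 1)
  maps <- pixel_maps(cfg$geometry, wavelength(cfg$beam))
  # subtract the single-scatterer intensities: the fringe term remains
  lam_t <- expected_counts(abs(structure_factor_direct(target, maps$q_vectors))^2,
                           maps, fluence_at(cfg$beam))
  lam_r <- expected_counts(abs(structure_factor_direct(one_c, maps$q_vectors))^2,
                           maps, fluence_at(cfg$beam))
  cross <- array(rec$ideal - lam_t - lam_r, c(64, 64))
  qx <- array(maps$q_vectors[, 1], c(64, 64))[, 32]
  row <- cross[, 32]
  # fringe period along the offset direction = 2 pi / separation, measured
  # from the spacing of interpolated upward zero crossings of the 1D cut
  up <- which(row[-length(row)] < 0 & row[-1] >= 0)
  zc <- qx[up] - row[up] * (qx[up + 1] - qx[up]) / (row[up + 1] - row[up])
  expect_gt(length(zc), 2)
  spacing <- mean(diff(zc))
  expect_rel_equal(spacing, 2 * pi / d_sep, 0.02)
})

test_that("the full noise stack engages and stays reproducible", {
  bg <- matrix(0.5, 8, 8)
  cfg <- tiny_config(
    n_shots = 3,
    noise = noise_config(miscenter_sigma_m = 3e-5, dark_sigma_adu = 2,
                         static_background = bg, gain_mode = "autoranging"),
    spectrum_type = "sase", sase = list(n_spikes = 6, bandwidth_fraction = 1e-3,
                                        n_samples = 7))
  cfg$beam$jitter_fraction <- 0.1
  vols <- precompute_volumes(cfg)
  a <- simulate_shot(cfg, 1, vols)
  expect_identical(simulate_shot(cfg, 1, vols), a)
  expect_false(identical(a$miscenter_m, c(0, 0)))
  expect_false(identical(a$fluence_photons, cfg$beam$photons_per_pulse))
  expect_false(is.null(a$adu))
  # background raises the expected counts by its value
  cfg0 <- tiny_config(n_shots = 3)
  base <- simulate_shot(cfg0, 1, vols)
  expect_true(all(a$ideal >= 0))
  expect_true(all(base$ideal < max(a$ideal) + 1))
})

test_that("the command-line front end runs a config and profiles the output", {
  cli <- system.file("cli", "cxdisim.R", package = "cxdisim")
  expect_true(nzchar(cli))
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c(
    "beam: {photon_energy_ev: 6000, photons_per_pulse: 1.0e12, focus_radius_m: 1.0e-7}",
    "detector: {n_pixels: 16, pixel_size_m: 3.0e-4, distance_m: 0.15}",
    "particles:",
    "  - fixture: two_atom",
    "    params: {d: 12}",
    "experiment: {kind: spi, n_shots: 3}"), cfg)
  out <- tempfile(fileext = ".cxi")
  status <- system2("Rscript", c(cli, "run", "--config", cfg, "--seed", "3",
                                 "--out", out), stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0L)
  ds <- read_experiment(out)
  expect_equal(dim(ds$photons), c(16, 16, 3))
  prof_csv <- tempfile(fileext = ".csv")
  status2 <- system2("Rscript", c(cli, "profile", "--dataset", out,
                                  "--bins", "8", "--out", prof_csv),
                     stdout = FALSE, stderr = FALSE)
  expect_equal(status2, 0L)
  expect_equal(nrow(utils::read.csv(prof_csv)), 8L)
})

test_that("radial profiles bin by momentum transfer", {
  g <- monolithic_detector(32, 200e-6, 0.1)
  maps <- pixel_maps(g, 2)
  const <- rep(3.5, 32 * 32)
  prof <- radial_profile(const, maps, 20)
  expect_true(all(prof$intensity[prof$n_pixels > 0] == 3.5))
  # pattern equal to q_mag: profile tracks the bin centers
  prof2 <- radial_profile(maps$q_mag, maps, 25)
  ok <- prof2$n_pixels > 0
  halfbin <- (prof2$q[2] - prof2$q[1]) / 2
  expect_true(all(abs(prof2$intensity[ok] - prof2$q[ok]) <= halfbin))
  expect_error(radial_profile(const, maps, 0), "n_bins")
})
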