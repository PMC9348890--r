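# Diffraction engine: direct summation, volumes, Ewald slicing, coherent
# multi-particle sums, Poisson quantization

test_that("single-atom structure factors equal the form factor and phases cancel", {
  one <- particle(matrix(0, 1, 3), element = "C")
  set.seed(1)
  q <- matrix(stats::rnorm(60, sd = 0.3), 20, 3)
  F <- structure_factor_direct(one, q)
  expect_equal(Im(F), rep(0, 20))
  expect_equal(Re(F), form_factor("C", sqrt(rowSums(q^2))))
  # translation changes only a global phase: |F|^2 invariant
  coil <- make_fixture("random_coil", list(n = 20, seed = 4))
  moved <- coil; moved$positions <- sweep(coil$positions, 2, c(30, -12, 7), "+")
  expect_equal(abs(structure_factor_direct(moved, q)),
               abs(structure_factor_direct(coil, q)), tolerance = 1e-10)
})

test_that("two-atom fringes follow 4 f^2 cos^2(q_x d / 2) with zeros at pi/d", {
  d <- 10
  p <- make_fixture("two_atom", list(d = d))
  qx <- seq(0, 1.2, length.out = 600)
  I <- abs(structure_factor_direct(p, cbind(qx, 0, 0)))^2
  f <- form_factor("C", qx)
  expect_equal(I, 4 * f^2 * cos(qx * d / 2)^2, tolerance = 1e-10)
  # zero positions at odd multiples of pi/d, located from the sampled curve
  zeros_expected <- pi / d * c(1, 3)
  for (z in zeros_expected) {
    i <- which.min(abs(qx - z))
    expect_lt(I[i] / max(I), 1e-4)
  }
})

test_that("volumes store |F|^2 with Friedel symmetry and the f(0) center", {
  three <- particle(matrix(c(0, 0, 0, 3, 0, 0, 0, 4, 0), 3, 3, byrow = TRUE),
                    element = rep("C", 3))
  v <- build_volume(three, q_max = 0.6, n_grid = 15)
  # 20 random voxels equal direct summation bitwise (same code path)
  set.seed(8)
  idx <- cbind(sample(15, 20, TRUE), sample(15, 20, TRUE), sample(15, 20, TRUE))
  qpts <- cbind(v$axis[idx[, 1]], v$axis[idx[, 2]], v$axis[idx[, 3]])
  Fd <- structure_factor_direct(three, qpts)
  expect_identical(v$grid[idx], Re(Fd)^2 + Im(Fd)^2)
  # Friedel: I(q) = I(-q) for a real scattering density
  expect_equal(v$grid, v$grid[15:1, 15:1, 15:1], tolerance = 1e-10)
  # central voxel equals (sum of f(0))^2 ~ (3 * 6)^2
  expect_equal(v$grid[8, 8, 8], total_electrons(three)^2, tolerance = 1e-9)
  expect_lt(abs(v$grid[8, 8, 8] - 324), 0.5)
})

test_that("slicing at grid nodes is exact and respects the quaternion double cover", {
  coil <- make_fixture("random_coil", list(n = 12, seed = 6))
  v <- build_volume(coil, q_max = 0.4, n_grid = 21)
  nodes <- maps_at_grid_nodes(v)
  sl <- slice_pattern(v, c(1, 0, 0, 0), nodes)
  plane <- v$grid[, , 11]
  expect_equal(as.numeric(sl), as.numeric(plane), tolerance = 1e-9)

  g <- toy_detector(24)
  maps <- pixel_maps(g, 2.5)
  set.seed(9); qt <- random_quaternions(1)[1, ]
  expect_identical(slice_pattern(v, qt, maps), slice_pattern(v, -qt, maps))
})

test_that("volume slicing reproduces direct summation within 1% at 4x oversampling", {
  coil <- make_fixture("random_coil", list(n = 60, seed = 7))
  g <- toy_detector(48)
  lam <- wavelength(6000)
  maps <- pixel_maps(g, lam)
  qmax <- 1.02 * max(maps$q_mag)
  ng <- default_n_grid(qmax, 2 * bounding_radius(coil), 4)
  v <- build_volume(coil, qmax, ng)
  set.seed(12)
  for (k in 1:3) {
    qt <- random_quaternions(1)[1, ]
    sl <- slice_pattern(v, qt, maps)
    R <- quat_to_matrix(qt)
    direct <- abs(structure_factor_direct(coil, maps$q_vectors %*% t(R)))^2
    rel_rms <- sqrt(mean((sl - direct)^2)) / sqrt(mean(direct^2))
    expect_lt(rel_rms, 0.01)
  }
})

test_that("multi-particle coherent sums reduce to and extend the single-particle path", {
  coil <- make_fixture("random_coil", list(n = 15, seed = 2))
  g <- toy_detector(32)
  maps <- pixel_maps(g, 2.5)
  set.seed(3); qt <- random_quaternions(1)[1, ]
  # one particle at offset 0, via its volume, equals slice_pattern bitwise
  v <- build_volume(coil, 1.02 * max(maps$q_mag),
                    default_n_grid(1.02 * max(maps$q_mag),
                                   2 * bounding_radius(coil)))
  one_vol <- multi_particle_pattern(
    list(list(volume = v, orientation = qt, offset = c(0, 0, 0))), maps)
  expect_identical(as.numeric(one_vol), as.numeric(slice_pattern(v, qt, maps)))

  # two single-atom "particles" separated by d equal the in-particle pair
  d <- 8
  one <- particle(matrix(0, 1, 3), element = "C")
  pair <- multi_particle_pattern(
    list(list(particle = one, orientation = c(1, 0, 0, 0), offset = c(-d / 2, 0, 0)),
         list(particle = one, orientation = c(1, 0, 0, 0), offset = c(d / 2, 0, 0))),
    maps)
  in_particle <- abs(structure_factor_direct(
    make_fixture("two_atom", list(d = d)), maps$q_vectors))^2
  expect_equal(pair, in_particle, tolerance = 1e-10)

  # coherent cross term oscillates around zero across pixels
  set.seed(5)
  states <- list(
    list(particle = coil, orientation = random_quaternions(1)[1, ],
         offset = c(0, 0, 0)),
    list(particle = coil, orientation = random_quaternions(1)[1, ],
         offset = c(800, -350, 120)))
  coh <- multi_particle_pattern(states, maps, coherent = TRUE)
  inc <- multi_particle_pattern(states, maps, coherent = FALSE)
  cross <- coh - inc
  expect_gt(stats::sd(cross), 0)
  expect_lt(abs(mean(cross)) / mean(inc), 0.05)
})

test_that("photon quantization has Poisson moments and scales with fluence", {
  g <- toy_detector(8)
  maps <- pixel_maps(g, 2)
  pat <- rep(1, 64)
  expect_true(all(pattern_to_photons(pat, maps, fluence = 0, seed = 1) == 0))
  # single-pixel lambda = 3.2 over many draws
  lam_target <- 3.2
  maps1 <- maps
  maps1$solid_angle <- rep(1, 64); maps1$polarization <- rep(1, 64)
  flu <- lam_target / cxdisim:::CLASSICAL_ELECTRON_RADIUS_M^2
  expect_equal(expected_counts(rep(1, 64), maps1, flu),
               rep(lam_target, 64), tolerance = 1e-9)
  draws <- vapply(1:1563, function(s)
    pattern_to_photons(rep(1, 64), maps1, flu, seed = s), numeric(64))
  x <- as.numeric(draws)  # 1e5 Poisson(3.2) samples
  n <- length(x)
  expect_lt(abs(mean(x) - lam_target), 3 * sqrt(lam_target / n))
  var_se <- sqrt((lam_target + 2 * lam_target^2) / n)  # var of Poisson variance est.
  expect_lt(abs(stats::var(x) - lam_target), 3 * var_se)
  # linearity of expected counts in fluence
  expect_equal(expected_counts(pat, maps, 2e20), 2 * expected_counts(pat, maps, 1e20))
})

test_that("a uniform ball reproduces the analytic sphere form factor", {
  R <- 20
  ball <- make_fixture("ball", list(R = R, voxel = 1.2))
  g <- monolithic_detector(64, 150e-6, 0.06)
  maps <- pixel_maps(g, wavelength(6000))
  pat <- abs(structure_factor_direct(ball, maps$q_vectors))^2
  prof <- radial_profile(pat, maps, 120)
  qr <- prof$q * R
  shape <- (3 * (sin(qr) - qr * cos(qr)) / qr^3)^2
  # normalized curves agree in the single-particle regime before the zero
  sel <- qr > 0.3 & qr < 4 & !is.na(prof$intensity)
  expect_gt(stats::cor(prof$intensity[sel], shape[sel]), 0.999)
  # first minimum at qR = 4.4934 (root of tan x = x) within half a radial bin
  expect_lt(abs(first_profile_minimum(prof$q, prof$intensity) * R - 4.4934),
            (qr[2] - qr[1]) / 2)
})

test_that("radial profiles of a spherically symmetric object are orientation independent", {
  ball <- make_fixture("ball", list(R = 12, voxel = 2))
  g <- toy_detector(32, distance = 0.1)
  maps <- pixel_maps(g, 2)
  qmax <- 1.02 * max(maps$q_mag)
  v <- build_volume(ball, qmax, default_n_grid(qmax, 28, 4))
  set.seed(10)
  profs <- lapply(1:3, function(k) {
    sl <- slice_pattern(v, random_quaternions(1)[1, ], maps)
    radial_profile(sl, maps, 40)$intensity
  })
  expect_equal(profs[[1]], profs[[2]], tolerance = 0.02)
  expect_equal(profs[[1]], profs[[3]], tolerance = 0.02)
})

test_that("volumes cache to HDF5 and reload bitwise", {
  p <- make_fixture("two_atom")
  v <- build_volume(p, 0.3, 11)
  f <- tempfile(fileext = ".h5")
  write_volume_h5(v, f)
  v2 <- read_volume_h5(f)
  expect_identical(v2$grid, v$grid)
  expect_identical(v2$axis, v$axis)
})
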