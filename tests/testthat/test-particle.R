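# Particle loading, form factors, hydration shell, cavity fill, gold reference

test_that("PDB reading parses elements and coordinates and is deterministic", {
  f <- tempfile(fileext = ".pdb")
  write_toy_pdb(f, matrix(c(0, 0, 0), 1, 3), "C")
  p <- load_pdb(f)
  expect_s3_class(p, "particle")
  expect_equal(nrow(p$positions), 1L)
  expect_equal(p$element, "C")
  expect_equal(unname(p$positions[1, ]), c(0, 0, 0))
  expect_identical(load_pdb(f)$positions, p$positions)

  pos <- matrix(c(1.234, -2.5, 0.001,
                  10.5, 3.25, -7.125,
                  0.125, 0.25, 0.5), 3, 3, byrow = TRUE)
  f3 <- tempfile(fileext = ".pdb")
  write_toy_pdb(f3, pos, c("C", "N", "O"))
  p3 <- load_pdb(f3)
  expect_lt(max(abs(p3$positions - pos)), 1e-3)  # PDB fixed-point precision
  expect_equal(p3$element, c("C", "N", "O"))
})

test_that("PDB reader filters water and rejects empty/unknown input", {
  f <- tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", f)
  expect_error(load_pdb(f))
  expect_error(load_pdb(tempfile()), "cannot read")
})

test_that("HDF5 particles round-trip and agree with the PDB reader", {
  # constant explicit form factors f == 1
  pos <- matrix(stats::rnorm(30), 10, 3)
  recs <- replicate(10, list(a = c(0, 0, 0, 0), b = c(1, 1, 1, 1), c = 1),
                    simplify = FALSE)
  p <- particle(pos, ff_records = recs)
  f <- tempfile(fileext = ".h5")
  write_particle_h5(p, f)
  p2 <- load_particle_h5(f)
  expect_equal(p2$positions, p$positions)
  expect_equal(form_factor(p2$ff_records[[1]], c(0, 0.5, 2)), c(1, 1, 1))

  # element-labeled HDF5 equals the equivalent PDB (positions on the PDB
  # 0.001 A lattice so both readers see identical values)
  pos3 <- round(matrix(stats::runif(9, -5, 5), 3, 3), 3)
  ele <- c("C", "N", "S")
  fp <- tempfile(fileext = ".pdb"); fh <- tempfile(fileext = ".h5")
  write_toy_pdb(fp, pos3, ele)
  write_particle_h5(particle(pos3, element = ele), fh)
  a <- load_pdb(fp); b <- load_particle_h5(fh)
  expect_identical(a$positions, b$positions)
  qprobe <- seq(0, 2, length.out = 10)
  for (i in 1:3)
    expect_equal(form_factor(a$element[i], qprobe),
                 form_factor(b$element[i], qprobe))
})

test_that("HDF5 reader rejects mismatched datasets", {
  f <- tempfile(fileext = ".h5")
  rhdf5::h5createFile(f)
  rhdf5::h5write(matrix(0, 10, 3), f, "positions")
  rhdf5::h5write(rep("C", 9), f, "elements")
  rhdf5::h5closeAll()
  expect_error(load_particle_h5(f), "does not match")
  f2 <- tempfile(fileext = ".h5")
  rhdf5::h5createFile(f2)
  rhdf5::h5write(1:3, f2, "unrelated")
  rhdf5::h5closeAll()
  expect_error(load_particle_h5(f2), "positions")
})

test_that("form factors equal electron counts at q = 0 and decay monotonically", {
  expect_lt(abs(form_factor("C", 0) - 6), 0.05)
  expect_lt(abs(form_factor("H", 0) - 1), 0.05)
  expect_lt(abs(form_factor("AU", 0) - 79), 0.2)
  for (el in c("H", "C", "N", "O", "S")) {
    f <- form_factor(el, seq(0, 2, length.out = 200))
    expect_true(all(diff(f) < 0), info = el)
  }
  expect_error(form_factor("XX", 0), "no form-factor record")
})

test_that("hydration shell electrons match the analytic shell volume", {
  one <- particle(matrix(0, 1, 3), element = "C")
  probe <- 1.7; thick <- 12; vox <- 0.8; rho <- 0.334
  h <- add_hydration_layer(one, thick, density = rho, voxel = vox,
                           probe = probe)
  v_shell <- 4 / 3 * pi * ((probe + thick)^3 - probe^3)
  expect_rel_equal(sum(h$solvent_amplitude), rho * v_shell, 0.05)
  # mask invariant: every point within (0, thickness] of the envelope surface
  d <- sqrt(rowSums(h$solvent_points^2)) - probe
  expect_true(all(d > 0 & d <= thick))
  # linearity in density
  h2 <- add_hydration_layer(one, thick, density = 2 * rho, voxel = vox,
                            probe = probe)
  expect_equal(h2$solvent_amplitude, 2 * h$solvent_amplitude)
})

test_that("hydration shell converges to the analytic volume as voxel shrinks", {
  one <- particle(matrix(0, 1, 3), element = "C")
  v_shell <- function(probe, t) 4 / 3 * pi * ((probe + t)^3 - probe^3)
  err <- vapply(c(2, 1, 0.5), function(vox) {
    h <- add_hydration_layer(one, 10, density = 1, voxel = vox, probe = 1.7)
    abs(sum(h$solvent_amplitude) - v_shell(1.7, 10)) / v_shell(1.7, 10)
  }, numeric(1))
  expect_lt(err[3], 0.02)
  expect_true(err[3] <= err[1] + 1e-9)
})

test_that("degenerate hydration shells error out", {
  one <- particle(matrix(0, 1, 3), element = "C")
  expect_error(add_hydration_layer(one, 3, voxel = 3.1, probe = 0),
               "empty hydration shell")
  expect_error(add_hydration_layer(one, -1), "thickness > 0")
})

test_that("cavity fill recovers the interior volume of a hollow shell", {
  sh <- make_fixture("shell", list(R = 18, spacing = 1.2))
  rho <- 0.334; vox <- 1.2; probe <- 1.7
  filled <- fill_cavity(sh, density = rho, voxel = vox, probe = probe)
  v_int <- 4 / 3 * pi * (18 - probe)^3
  expect_rel_equal(sum(filled$solvent_amplitude), rho * v_int, 0.05)
  # all fill points strictly inside the shell radius
  expect_true(all(rowSums(filled$solvent_points^2) < 18^2))
})

test_that("cavity fill warns and is a no-op without a void; zero density is inert", {
  solid <- make_fixture("random_coil", list(n = 5, seed = 2))
  expect_warning(out <- fill_cavity(solid, voxel = 2), "no interior void")
  expect_identical(out$positions, solid$positions)
  expect_equal(nrow(out$solvent_points), 0L)

  sh <- make_fixture("shell", list(R = 15, spacing = 1.2))
  z <- fill_cavity(sh, density = 0, voxel = 1.5)
  expect_true(all(z$solvent_amplitude == 0))
  q <- cbind(seq(0.01, 0.3, length.out = 5), 0, 0)
  expect_equal(abs(structure_factor_direct(z, q)),
               abs(structure_factor_direct(sh, q)))
})

test_that("gold reference enumerates FCC sites inside the sphere", {
  r <- 10; a <- 4.08
  au <- gold_reference(r, a)
  # independent brute-force count over a redundant index range
  cnt <- 0L
  rng <- -5:5
  for (i in rng) for (j in rng) for (k in rng)
    for (b in list(c(0, 0, 0), c(.5, .5, 0), c(.5, 0, .5), c(0, .5, .5))) {
      x <- (c(i, j, k) + b + 0.25) * a
      if (sum(x^2) <= r^2) cnt <- cnt + 1L
    }
  expect_equal(nrow(au$positions), cnt)
  expect_true(all(rowSums(au$positions^2) <= r^2 + 1e-9))
  expect_true(all(au$element == "AU"))
  expect_identical(gold_reference(r, a)$positions, au$positions)
  expect_error(gold_reference(0.5), "zero atoms|radius")
})
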