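# Validation utilities: Fourier shell correlation between density maps,
# resolution at a correlation threshold, and the deterministic toy particles
# used as fixtures throughout the test suite.

#' Fourier shell correlation between two density maps
#'
#' Per spherical shell in spatial frequency k,
#' `FSC(k) = Re(sum F1 F2*) / sqrt(sum |F1|^2 sum |F2|^2)` over the Fourier
#' voxels of the shell. The real part is taken because the raw ratio can be
#' complex for a finite shell. Frequencies are in cycles per voxel edge
#' (`k_nyquist = 0.5 / voxel_size`).
#'
#' @param map1,map2 Real cubic 3D arrays of equal shape.
#' @param n_shells Number of equal-width shells up to Nyquist (default
#'   `dim/2`).
#' @param voxel_size Voxel edge in Angstrom (default 1).
#' @return Object of class `fsc_curve`: data frame with `k` (shell centers,
#'   cycles per Angstrom), `fsc`, `n_voxels`; attributes `shell_width`,
#'   `voxel_size`.
#' @export
fsc <- function(map1, map2, n_shells = NULL, voxel_size = 1) {
  stopifnot(length(dim(map1)) == 3, identical(dim(map1), dim(map2)),
            voxel_size > 0)
  n <- dim(map1)[1]
  stopifnot(all(dim(map1) == n))
  if (is.null(n_shells)) n_shells <- n %/% 2
  stopifnot(n_shells >= 1)
  F1 <- stats::fft(map1)
  F2 <- stats::fft(map2)
  fr <- .fft_freq(n)  # cycles per voxel
  kmag <- sqrt(outer(outer(fr^2, fr^2, "+"), fr^2, "+"))
  width <- 0.5 / n_shells
  shell <- pmin(n_shells, floor(kmag / width) + 1L)
  shell[kmag > 0.5] <- NA_integer_  # beyond Nyquist corner voxels excluded
  f <- factor(shell, levels = seq_len(n_shells))
  num <- tapply(Re(F1 * Conj(F2)), f, sum)
  d1 <- tapply(abs(F1)^2, f, sum)
  d2 <- tapply(abs(F2)^2, f, sum)
  nv <- tapply(rep(1, length(shell)), f, sum)
  if (any(is.na(nv) | nv == 0)) stop("empty FSC shell; reduce n_shells")
  vals <- as.numeric(num) / sqrt(as.numeric(d1) * as.numeric(d2))
  out <- data.frame(k = (seq_len(n_shells) - 0.5) * width / voxel_size,
                    fsc = vals, n_voxels = as.integer(nv))
  structure(out, class = c("fsc_curve", "data.frame"),
            shell_width = width / voxel_size, voxel_size = voxel_size)
}

.fft_freq <- function(n) {
  # DFT sample frequencies in cycles per sample
  k <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1)
  k / n
}

#' @export
print.fsc_curve <- function(x, ...) {
  cat(sprintf("<fsc_curve> %d shells, width %.4g /A; fsc[1] = %.4f\n",
              nrow(x), attr(x, "shell_width"), x$fsc[1]))
  invisible(x)
}

#' Plot an FSC curve
#' @param x An `fsc_curve`.
#' @param threshold Horizontal guide (default 0.5).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.fsc_curve <- function(x, threshold = 0.5, ...) {
  graphics::plot(x$k, x$fsc, type = "l", xlab = "spatial frequency (1/A)",
                 ylab = "FSC", ylim = c(min(0, min(x$fsc)), 1), ...)
  graphics::abline(h = threshold, lty = 2)
  invisible(x)
}

#' Resolution at an FSC threshold
#'
#' Locates the first crossing of the curve below `threshold` by linear
#' interpolation between adjacent shells and reports `d = 1 / k_cross`
#' (real-space distance per the map's cycles-per-Angstrom convention; the
#' angular-frequency equivalent is `2 pi / q` with `q = 2 pi k`). Returns
#' `Inf` with flag `"beyond_nyquist"` when the curve never crosses.
#'
#' @param curve An `fsc_curve`.
#' @param threshold Correlation threshold in (0, 1) (default 0.5).
#' @return Resolution in Angstrom (possibly `Inf`), with attributes
#'   `k_cross` and `flag` (`"ok"`, `"beyond_nyquist"` or
#'   `"starts_below_threshold"`).
#' @export
resolution_at_threshold <- function(curve, threshold = 0.5) {
  stopifnot(inherits(curve, "fsc_curve"), threshold > 0, threshold < 1,
            nrow(curve) >= 1)
  v <- curve$fsc; k <- curve$k
  if (v[1] < threshold) {
    out <- 1 / k[1]
    attr(out, "k_cross") <- k[1]
    attr(out, "flag") <- "starts_below_threshold"
    return(out)
  }
  below <- which(v < threshold)
  if (!length(below)) {
    out <- Inf
    attr(out, "k_cross") <- NA_real_
    attr(out, "flag") <- "beyond_nyquist"
    return(out)
  }
  i <- below[1]
  # linear interpolation between shells i-1 and i
  k_cross <- k[i - 1] + (threshold - v[i - 1]) * (k[i] - k[i - 1]) /
    (v[i] - v[i - 1])
  out <- 1 / k_cross
  attr(out, "k_cross") <- k_cross
  attr(out, "flag") <- "ok"
  out
}

#' Deterministic toy particles
#'
#' Synthetic fixtures used across the test suite and examples:
#' \describe{
#'   \item{two_atom}{two unit-occupancy carbon atoms separated by `d`
#'     Angstrom along x, centered at the origin (`params$d`, default 10).}
#'   \item{shell}{hollow spherical shell of carbon pseudo-atoms of radius
#'     `params$R` (default 30) with inter-atom spacing `params$spacing`
#'     (default 1.5), quasi-uniform by Fibonacci-sphere placement.}
#'   \item{ball}{uniform solid ball of continuum-solvent points on a cubic
#'     lattice: radius `params$R` (default 20), spacing `params$voxel`
#'     (default 2), density `params$density` e/A^3 (default 0.334). Carries
#'     one zero-occupancy carbon so the scatterer set is nonempty.}
#'   \item{random_coil}{self-avoiding-free random walk of `params$n` carbon
#'     pseudo-atoms (default 50) with 3.8 A steps, seeded by `params$seed`
#'     (default 1).}
#' }
#'
#' @param name One of `"two_atom"`, `"shell"`, `"ball"`, `"random_coil"`.
#' @param params Named list of parameters (see above).
#' @return A [particle].
#' @export
make_fixture <- function(name = c("two_atom", "shell", "ball", "random_coil"),
                         params = list()) {
  name <- match.arg(name)
  gp <- function(key, default) if (!is.null(params[[key]])) params[[key]] else default
  switch(name,
    two_atom = {
      d <- gp("d", 10)
      particle(positions = rbind(c(-d / 2, 0, 0), c(d / 2, 0, 0)),
               element = c("C", "C"), label = sprintf("two_atom_d%g", d))
    },
    shell = {
      R <- gp("R", 30); spacing <- gp("spacing", 1.5)
      n <- max(12L, ceiling(4 * pi * R^2 / spacing^2))
      i <- seq_len(n) - 0.5
      phi <- acos(1 - 2 * i / n)
      theta <- pi * (1 + sqrt(5)) * i
      pos <- R * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
      particle(positions = pos, element = rep("C", n),
               label = sprintf("shell_R%g", R))
    },
    ball = {
      R <- gp("R", 20); vox <- gp("voxel", 2); rho <- gp("density", 0.334)
      ax <- seq(-R, R, by = vox)
      g <- as.matrix(expand.grid(x = ax, y = ax, z = ax,
                                 KEEP.OUT.ATTRS = FALSE))
      g <- g[rowSums(g^2) <= R^2, , drop = FALSE]
      particle(positions = matrix(0, 1, 3), element = "C",
               occupancy = 0,
               solvent_points = g,
               solvent_amplitude = rep(rho * vox^3, nrow(g)),
               label = sprintf("ball_R%g", R))
    },
    random_coil = {
      n <- gp("n", 50L); seed <- gp("seed", 1L)
      steps <- .with_seed(seed, {
        u <- matrix(stats::rnorm(3 * (n - 1)), n - 1, 3)
        u / sqrt(rowSums(u^2)) * 3.8
      })
      pos <- rbind(c(0, 0, 0), apply(steps, 2, cumsum))
      pos <- sweep(pos, 2, colMeans(pos))
      particle(positions = pos, element = rep("C", n),
               label = sprintf("coil_n%d_seed%d", n, seed))
    })
}
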