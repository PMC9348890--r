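# Shared fixture builders for the suite. All fixtures are generated in code;
# nothing is read from disk that a helper did not just write.

# minimal fixed-width PDB writer for toy particles (ATOM records only)
write_toy_pdb <- function(path, positions, elements, occupancy = NULL,
                          atom_names = NULL) {
  n <- nrow(positions)
  if (is.null(occupancy)) occupancy <- rep(1, n)
  if (is.null(atom_names)) atom_names <- elements
  lines <- vapply(seq_len(n), function(i) {
    sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, substr(atom_names[i], 1, 4), "GLY", "A", i,
            positions[i, 1], positions[i, 2], positions[i, 3],
            occupancy[i], 0, toupper(elements[i]))
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

# small detector + maps used across diffraction tests
toy_detector <- function(n = 32, pitch = 200e-6, distance = 0.2) {
  monolithic_detector(n, pitch, distance)
}

# a pixel_maps-like object whose q-vectors are exact volume grid nodes
maps_at_grid_nodes <- function(vol, k_plane = (vol$n_grid + 1) / 2) {
  ax <- vol$axis
  g <- as.matrix(expand.grid(qx = ax, qy = ax, KEEP.OUT.ATTRS = FALSE))
  q <- cbind(g, ax[k_plane])
  structure(list(q_vectors = q, q_mag = sqrt(rowSums(q^2)),
                 solid_angle = rep(1e-8, nrow(q)),
                 polarization = rep(1, nrow(q)),
                 mask = rep(TRUE, nrow(q)), dims = c(vol$n_grid, vol$n_grid),
                 lambda = 2), class = "pixel_maps")
}

expect_rel_equal <- function(object, expected, rel_tol) {
  expect_lt(abs(object - expected), rel_tol * abs(expected))
}

# first local minimum of a radial profile, refined to sub-bin precision by a
# parabola through the three bins around the discrete argmin
first_profile_minimum <- function(q, intensity) {
  n <- length(intensity)
  i <- which(vapply(2:(n - 1), function(j)
    !anyNA(intensity[(j - 1):(j + 1)]) &&
      intensity[j] < intensity[j - 1] && intensity[j] < intensity[j + 1],
    logical(1)))[1] + 1
  y <- intensity[(i - 1):(i + 1)]
  delta <- 0.5 * (y[1] - y[3]) / (y[1] - 2 * y[2] + y[3])
  q[i] + delta * (q[i + 1] - q[i])
}

# connectivity (edge BFS), contact degree and no-overlap for a cluster layout
cluster_checks <- function(lay) {
  n <- nrow(lay$centers)
  tol <- 1e-6
  deg <- tabulate(c(lay$contact_edges), nbins = n)
  if (any(deg == 0)) return(FALSE)
  seen <- rep(FALSE, n); seen[1] <- TRUE; frontier <- 1L
  while (length(frontier)) {
    nb <- unique(c(lay$contact_edges[lay$contact_edges[, 1] %in% frontier, 2],
                   lay$contact_edges[lay$contact_edges[, 2] %in% frontier, 1]))
    frontier <- nb[!seen[nb]]
    seen[frontier] <- TRUE
  }
  if (!all(seen)) return(FALSE)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((lay$centers[i, ] - lay$centers[j, ])^2))
    R <- lay$radii[i] + lay$radii[j]
    if (d < R * (1 - tol)) return(FALSE)
  }
  TRUE
}
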