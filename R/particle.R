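# Particle representation: scatterer positions + form factors, optional
# continuum-solvent sample points (hydration shell / cavity fill).

#' Construct a particle
#'
#' A particle is the scattering object of a simulated shot: point scatterers
#' (atoms or coarse-grained pseudo-atoms) with positions in Angstrom and a
#' form-factor evaluator each, plus optional continuum-solvent sample points
#' carrying fixed scattering amplitudes in electrons.
#'
#' @param positions Numeric n x 3 matrix of scatterer positions (Angstrom).
#' @param element Character vector of element symbols, one per scatterer;
#'   may be `NULL` when `ff_records` is supplied.
#' @param ff_records Optional list of per-scatterer form-factor records
#'   (each a list with `a`, `b`, `c`); overrides the element table.
#' @param occupancy Per-scatterer weights, default 1.
#' @param atom_name Optional per-scatterer atom names (kept from PDB input;
#'   used e.g. for C-alpha selection in normal-mode analysis).
#' @param solvent_points Numeric m x 3 matrix of solvent sample positions.
#' @param solvent_amplitude Nonnegative amplitude (electrons) per solvent point.
#' @param label Free-text state identifier.
#' @return Object of class `particle`.
#' @export
particle <- function(positions, element = NULL, ff_records = NULL,
                     occupancy = NULL, atom_name = NULL,
                     solvent_points = NULL, solvent_amplitude = NULL,
                     label = "particle") {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must be an n x 3 matrix")
  storage.mode(positions) <- "double"
  n <- nrow(positions)
  if (n < 1L) stop("a particle needs at least one scatterer")
  if (!all(is.finite(positions))) stop("non-finite scatterer positions")
  if (is.null(element) && is.null(ff_records))
    stop("supply 'element' or 'ff_records'")
  if (!is.null(element)) {
    element <- as.character(element)
    if (length(element) != n) stop("length(element) != number of positions")
    if (is.null(ff_records)) {
      bad <- setdiff(unique(toupper(element)), ff_elements())
      if (length(bad))
        stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
    }
  }
  if (!is.null(ff_records) && length(ff_records) != n)
    stop("length(ff_records) != number of positions")
  if (is.null(occupancy)) occupancy <- rep(1, n)
  stopifnot(length(occupancy) == n, all(is.finite(occupancy)))
  if (is.null(solvent_points)) {
    solvent_points <- matrix(numeric(0), 0L, 3L)
    solvent_amplitude <- numeric(0)
  } else {
    solvent_points <- as.matrix(solvent_points)
    stopifnot(ncol(solvent_points) == 3L,
              length(solvent_amplitude) == nrow(solvent_points),
              all(solvent_amplitude >= 0))
  }
  structure(list(positions = positions, element = element,
                 ff_records = ff_records, occupancy = as.numeric(occupancy),
                 atom_name = atom_name,
                 solvent_points = solvent_points,
                 solvent_amplitude = as.numeric(solvent_amplitude),
                 label = label),
            class = "particle")
}

#' @export
print.particle <- function(x, ...) {
  cat("<particle> ", x$label, "\n", sep = "")
  cat("  scatterers: ", nrow(x$positions),
      if (!is.null(x$element)) paste0(" (", paste(utils::head(unique(x$element), 6),
                                                  collapse = ","), ")"), "\n", sep = "")
  cat("  solvent points: ", nrow(x$solvent_points),
      sprintf(" (%.1f e total)", sum(x$solvent_amplitude)), "\n", sep = "")
  cat("  bounding radius: ", sprintf("%.2f A", bounding_radius(x)), "\n", sep = "")
  invisible(x)
}

#' Total electrons of a particle (forward-scattering amplitude)
#'
#' Sum of occupancy-weighted `f(0)` over scatterers plus all solvent
#' amplitudes; this equals `sqrt` of the central voxel of a diffraction volume.
#' @param p A `particle`.
#' @return Electron count (numeric scalar).
#' @export
total_electrons <- function(p) {
  stopifnot(inherits(p, "particle"))
  f0 <- numeric(nrow(p$positions))
  for (g in .ff_groups(p)) f0[g$indices] <- form_factor(g$record, 0)
  sum(f0 * p$occupancy) + sum(p$solvent_amplitude)
}

# centroid over scatterers only (solvent excluded: it decorates the envelope)
.centroid <- function(p) colMeans(p$positions)

#' Read a particle from a PDB file
#'
#' One scatterer per ATOM/HETATM record; the element is taken from the PDB
#' element column (columns 77-78), falling back to parsing the atom name.
#' Coordinates are in Angstrom. Parsing is delegated to [bio3d::read.pdb].
#'
#' @param path Path to a PDB-format text file.
#' @param exclude_water Drop water residues (HOH/WAT/DOD)? Default `TRUE`.
#' @param label State label; defaults to the file name.
#' @return A [particle].
#' @export
load_pdb <- function(path, exclude_water = TRUE, label = basename(path)) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (exclude_water) at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (nrow(at) == 0L) stop("zero atoms after filtering in ", path)
  elesy <- toupper(trimws(at$elesy))
  miss <- is.na(elesy) | elesy == ""
  if (any(miss)) {
    # fall back to the leading alphabetic characters of the atom name;
    # two-letter symbols only when they match a known element
    nm <- toupper(gsub("[^A-Za-z].*$", "", trimws(at$elety[miss])))
    two <- substr(nm, 1, 2)
    one <- substr(nm, 1, 1)
    elesy[miss] <- ifelse(two %in% ff_elements(), two, one)
  }
  bad <- setdiff(unique(elesy), ff_elements())
  if (length(bad))
    stop("unknown element symbol(s) in PDB: ", paste(bad, collapse = ", "))
  occ <- at$o
  occ[is.na(occ)] <- 1
  particle(positions = cbind(at$x, at$y, at$z), element = elesy,
           occupancy = occ, atom_name = trimws(at$elety), label = label)
}

#' Read a particle from an HDF5 file
#'
#' Layout: dataset `positions` (n x 3, Angstrom) plus either `elements`
#' (n strings) or explicit coarse-grained form factors `form_factors/a`
#' (n x 4), `form_factors/b` (n x 4), `form_factors/c` (n). When explicit
#' records are present they are used verbatim.
#'
#' @param path Path to the HDF5 file.
#' @param label State label; defaults to the file name.
#' @return A [particle].
#' @seealso [write_particle_h5()]
#' @export
load_particle_h5 <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("cannot read HDF5 file: ", path)
  contents <- rhdf5::h5ls(path)
  names_in <- paste0(contents$group, "/", contents$name)
  has <- function(nm) any(names_in == nm | names_in == paste0("/", nm) |
                            sub("^//", "/", names_in) == paste0("/", nm))
  if (!has("positions")) stop("missing required dataset 'positions' in ", path)
  pos <- rhdf5::h5read(path, "positions")
  pos <- as.matrix(pos)
  if (ncol(pos) != 3L && nrow(pos) == 3L) pos <- t(pos)
  n <- nrow(pos)
  elements <- NULL; records <- NULL
  if (has("form_factors/a")) {
    a <- as.matrix(rhdf5::h5read(path, "form_factors/a"))
    b <- as.matrix(rhdf5::h5read(path, "form_factors/b"))
    cc <- as.numeric(rhdf5::h5read(path, "form_factors/c"))
    if (nrow(a) != n && ncol(a) == n) { a <- t(a); b <- t(b) }
    if (nrow(a) != n || nrow(b) != n || length(cc) != n)
      stop("form-factor datasets do not match the number of positions")
    records <- lapply(seq_len(n), function(i)
      structure(list(a = a[i, ], b = b[i, ], c = cc[i]),
                class = "form_factor_record"))
    if (has("elements")) elements <- as.character(rhdf5::h5read(path, "elements"))
  } else if (has("elements")) {
    elements <- as.character(rhdf5::h5read(path, "elements"))
    if (length(elements) != n)
      stop("'elements' length (", length(elements),
           ") does not match positions (", n, ")")
  } else {
    stop("need either 'elements' or 'form_factors/*' datasets in ", path)
  }
  if (!is.null(elements) && length(elements) != n)
    stop("'elements' length does not match positions")
  particle(positions = pos, element = elements, ff_records = records,
           label = label)
}

#' Write a particle to an HDF5 file
#'
#' Inverse of [load_particle_h5()]; element labels and/or explicit
#' form-factor records are written as available.
#'
#' @param p A [particle].
#' @param path Output path (overwritten).
#' @return `path`, invisibly.
#' @export
write_particle_h5 <- function(p, path) {
  stopifnot(inherits(p, "particle"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(p$positions, path, "positions")
  if (!is.null(p$element)) rhdf5::h5write(p$element, path, "elements")
  if (!is.null(p$ff_records)) {
    rhdf5::h5createGroup(path, "form_factors")
    a <- t(vapply(p$ff_records, `[[`, numeric(4), "a"))
    b <- t(vapply(p$ff_records, `[[`, numeric(4), "b"))
    cc <- vapply(p$ff_records, `[[`, numeric(1), "c")
    rhdf5::h5write(a, path, "form_factors/a")
    rhdf5::h5write(b, path, "form_factors/b")
    rhdf5::h5write(cc, path, "form_factors/c")
  }
  rhdf5::h5closeAll()
  invisible(path)
}

# cubic lattice of spacing `voxel` covering the particle bounding box padded
# by `pad`, centered on the scatterer centroid
.solvent_lattice <- function(p, voxel, pad) {
  ctr <- .centroid(p)
  lo <- apply(p$positions, 2, min) - pad
  hi <- apply(p$positions, 2, max) + pad
  ax <- lapply(1:3, function(k) {
    nneg <- ceiling((ctr[k] - lo[k]) / voxel)
    npos <- ceiling((hi[k] - ctr[k]) / voxel)
    ctr[k] + voxel * seq(-nneg, npos)
  })
  as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                        KEEP.OUT.ATTRS = FALSE))
}

# distance from each point (m x 3) to the nearest scatterer, chunked to bound
# the m x n distance matrix
.min_dist_to_scatterers <- function(points, positions, chunk = 200000L) {
  m <- nrow(points); n <- nrow(positions)
  out <- numeric(m)
  csize <- max(1L, chunk %/% max(1L, n))
  for (s in seq(1L, m, by = csize)) {
    e <- min(m, s + csize - 1L)
    blk <- points[s:e, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), rowSums(positions^2), "+") -
      2 * blk %*% t(positions)
    out[s:e] <- sqrt(pmax(0, apply(d2, 1, min)))
  }
  out
}

#' Add a continuum hydration shell
#'
#' Decorates a particle with a layer of uniform water density that follows the
#' particle contour, as retained by aerosolized particles in vacuum. The
#' envelope is the union of spheres of radius `probe` around the scatterers;
#' solvent sample points are placed on a cubic lattice of spacing `voxel`
#' within the shell `0 < d_surface <= thickness` outside the envelope, each
#' carrying `density * voxel^3` electrons.
#'
#' @param p A [particle].
#' @param thickness Shell thickness in Angstrom (> 0).
#' @param density Solvent electron density in e / cubic Angstrom
#'   (default 0.334, bulk water).
#' @param voxel Lattice spacing in Angstrom (default 2).
#' @param probe Envelope sphere radius in Angstrom (default 1.7, a generic
#'   heavy-atom van der Waals radius).
#' @return A new [particle] with solvent points appended.
#' @export
add_hydration_layer <- function(p, thickness, density = 0.334, voxel = 2,
                                probe = 1.7) {
  stopifnot(inherits(p, "particle"), thickness > 0, density > 0, voxel > 0,
            probe >= 0)
  lat <- .solvent_lattice(p, voxel, pad = probe + thickness + voxel)
  d <- .min_dist_to_scatterers(lat, p$positions) - probe
  keep <- d > 0 & d <= thickness
  if (!any(keep))
    stop("empty hydration shell: thickness ", thickness,
         " A holds no lattice point at voxel ", voxel, " A")
  pts <- lat[keep, , drop = FALSE]
  amp <- rep(density * voxel^3, nrow(pts))
  out <- p
  out$solvent_points <- rbind(p$solvent_points, pts)
  out$solvent_amplitude <- c(p$solvent_amplitude, amp)
  out$label <- paste0(p$label, "+hydration")
  out
}

#' Fill interior cavities with uniform scattering density
#'
#' For particles with large internal voids (e.g. nucleic-acid-containing
#' capsids modeled as empty shells) this adds solvent-type points inside the
#' envelope's interior void: lattice voxels outside every scatterer sphere
#' that are not connected to the exterior. Connectivity is determined by a
#' 6-neighbor flood fill from the lattice boundary.
#'
#' @inheritParams add_hydration_layer
#' @param density Fill electron density in e / cubic Angstrom.
#' @return A new [particle]; if no interior void exists a warning is issued
#'   and an unchanged copy returned.
#' @export
fill_cavity <- function(p, density = 0.334, voxel = 2, probe = 1.7) {
  stopifnot(inherits(p, "particle"), density >= 0, voxel > 0, probe > 0)
  ctr <- .centroid(p)
  lo <- apply(p$positions, 2, min) - voxel
  hi <- apply(p$positions, 2, max) + voxel
  ax <- lapply(1:3, function(k) {
    nneg <- ceiling((ctr[k] - lo[k]) / voxel)
    npos <- ceiling((hi[k] - ctr[k]) / voxel)
    ctr[k] + voxel * seq(-nneg, npos)
  })
  dims <- vapply(ax, length, integer(1))
  lat <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                               KEEP.OUT.ATTRS = FALSE))
  open <- array(.min_dist_to_scatterers(lat, p$positions) > probe, dim = dims)
  # flood fill exterior from the box faces
  ext <- array(FALSE, dim = dims)
  queue <- which(open & .face_mask(dims))
  ext[queue] <- TRUE
  nxyz <- dims
  while (length(queue)) {
    idx <- arrayInd(queue, dims)
    nb <- rbind(idx + matrix(c(1, 0, 0), nrow(idx), 3, byrow = TRUE),
                idx - matrix(c(1, 0, 0), nrow(idx), 3, byrow = TRUE),
                idx + matrix(c(0, 1, 0), nrow(idx), 3, byrow = TRUE),
                idx - matrix(c(0, 1, 0), nrow(idx), 3, byrow = TRUE),
                idx + matrix(c(0, 0, 1), nrow(idx), 3, byrow = TRUE),
                idx - matrix(c(0, 0, 1), nrow(idx), 3, byrow = TRUE))
    ok <- nb[, 1] >= 1 & nb[, 1] <= nxyz[1] & nb[, 2] >= 1 &
      nb[, 2] <= nxyz[2] & nb[, 3] >= 1 & nb[, 3] <= nxyz[3]
    nb <- nb[ok, , drop = FALSE]
    lin <- nb[, 1] + nxyz[1] * (nb[, 2] - 1L) + nxyz[1] * nxyz[2] * (nb[, 3] - 1L)
    lin <- unique(lin[open[lin] & !ext[lin]])
    ext[lin] <- TRUE
    queue <- lin
  }
  void <- open & !ext
  if (nrow(p$solvent_points)) {
    # keep existing shell points out of the fill
    vi <- which(void)
    if (length(vi)) {
      pts <- lat[vi, , drop = FALSE]
      d <- .min_dist_to_scatterers(pts, p$solvent_points)
      void[vi[d < voxel / 2]] <- FALSE
    }
  }
  if (!any(void)) {
    warning("no interior void found; particle returned unchanged")
    return(p)
  }
  pts <- lat[which(void), , drop = FALSE]
  out <- p
  out$solvent_points <- rbind(p$solvent_points, pts)
  out$solvent_amplitude <- c(p$solvent_amplitude,
                             rep(density * voxel^3, nrow(pts)))
  out$label <- paste0(p$label, "+cavity")
  out
}

.face_mask <- function(dims) {
  m <- array(FALSE, dim = dims)
  m[c(1, dims[1]), , ] <- TRUE
  m[, c(1, dims[2]), ] <- TRUE
  m[, , c(1, dims[3])] <- TRUE
  m
}

#' Spherical gold nanoparticle reference
#'
#' Gold atoms on a face-centered-cubic lattice clipped to a sphere, centered
#' at the origin. Used as the reference scatterer in Fourier-transform
#' holography, where interference between target and reference encodes the
#' target's image.
#'
#' @param radius Sphere radius in Angstrom (> 0).
#' @param lattice_constant FCC cell edge in Angstrom (default 4.08, bulk gold).
#' @return A [particle] of Au atoms.
#' @export
gold_reference <- function(radius, lattice_constant = 4.08) {
  stopifnot(radius > 0, lattice_constant > 0)
  a <- lattice_constant
  nmax <- ceiling(radius / a) + 1L
  cells <- as.matrix(expand.grid(i = -nmax:nmax, j = -nmax:nmax, k = -nmax:nmax,
                                 KEEP.OUT.ATTRS = FALSE))
  # lattice offset by a quarter cell: the sphere center falls between sites,
  # so a radius below the nearest-site distance yields zero atoms
  basis <- matrix(c(0, 0, 0,  0.5, 0.5, 0,  0.5, 0, 0.5,  0, 0.5, 0.5),
                  4, 3, byrow = TRUE) + 0.25
  pos <- do.call(rbind, lapply(1:4, function(b)
    sweep(cells, 2, basis[b, ], "+") * a))
  keep <- sqrt(rowSums(pos^2)) <= radius
  if (!any(keep))
    stop("radius ", radius, " A smaller than one FCC cell: zero atoms")
  pos <- pos[keep, , drop = FALSE]
  particle(positions = pos, element = rep("AU", nrow(pos)),
           label = sprintf("gold_r%g", radius))
}
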