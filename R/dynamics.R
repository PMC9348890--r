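# Conformational heterogeneity via elastic-network normal modes: an
# anisotropic network model (ANM) over selected nodes, sampled to build a
# library of displaced conformers.

#' Build an anisotropic network model over a particle
#'
#' Nodes are connected by uniform springs within `cutoff`; the ANM Hessian is
#' assembled from the standard 3x3 super-element blocks
#' `-gamma (dr dr^T) / |dr|^2` and diagonalized. For a connected network the
#' six smallest eigenvalues are numerically zero (rigid-body translations and
#' rotations); internal modes follow in ascending stiffness.
#'
#' @param p A [particle].
#' @param cutoff Spring cutoff in Angstrom (default 15).
#' @param node_selection `"calpha"` (C-alpha atoms when atom names are
#'   available, otherwise falls back), `"all"`, or `"subsample"` (uniform
#'   spatial subsample capped at `max_nodes`).
#' @param max_nodes Node budget for `"subsample"`/fallback (default 500).
#' @param gamma Uniform spring constant (default 1; eigenvalues scale with it).
#' @return Object of class `normal_mode_set`: node positions and indices,
#'   ascending eigenvalues, unit-norm eigenvectors (3N x 3N, columns), the
#'   cutoff, and `num_zero_modes`.
#' @export
build_anm <- function(p, cutoff = 15, node_selection = c("calpha", "all", "subsample"),
                      max_nodes = 500L, gamma = 1) {
  stopifnot(inherits(p, "particle"), cutoff > 0, gamma > 0)
  node_selection <- match.arg(node_selection)
  n_all <- nrow(p$positions)
  idx <- seq_len(n_all)
  if (node_selection == "calpha" && !is.null(p$atom_name) &&
      any(p$atom_name == "CA")) {
    idx <- which(p$atom_name == "CA")
  }
  if (length(idx) > max_nodes || node_selection == "subsample") {
    take <- unique(round(seq(1, length(idx), length.out = min(max_nodes, length(idx)))))
    idx <- idx[take]
  }
  if (length(idx) < 3L) stop("need at least 3 network nodes")
  X <- p$positions[idx, , drop = FALSE]
  n <- nrow(X)
  d2 <- outer(rowSums(X^2), rowSums(X^2), "+") - 2 * X %*% t(X)
  within <- d2 <= cutoff^2 & d2 > 1e-12
  H <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) {
    js <- which(within[i, ])
    for (j in js[js > i]) {
      dr <- X[j, ] - X[i, ]
      blk <- -gamma * tcrossprod(dr) / sum(dr^2)
      ri <- (3 * i - 2):(3 * i); rj <- (3 * j - 2):(3 * j)
      H[ri, rj] <- blk
      H[rj, ri] <- blk
      H[ri, ri] <- H[ri, ri] - blk
      H[rj, rj] <- H[rj, rj] - blk
    }
  }
  eig <- eigen(H, symmetric = TRUE)
  ord <- order(eig$values)
  vals <- eig$values[ord]
  vecs <- eig$vectors[, ord, drop = FALSE]
  vals[vals < 0 & vals > -1e-9 * max(abs(vals))] <- 0
  nzero <- sum(vals < 1e-8 * max(vals))
  if (nzero > 6L)
    stop("elastic network is disconnected at cutoff ", cutoff,
         " A (", nzero, " near-zero modes); increase the cutoff")
  structure(list(node_positions = X, node_indices = idx,
                 eigenvalues = vals, eigenvectors = vecs,
                 hessian = H, cutoff = cutoff, gamma = gamma,
                 num_zero_modes = nzero),
            class = "normal_mode_set")
}

#' @export
print.normal_mode_set <- function(x, ...) {
  cat("<normal_mode_set> ", nrow(x$node_positions), " nodes, cutoff ",
      x$cutoff, " A\n", sep = "")
  cat("  zero modes: ", x$num_zero_modes, "; first internal eigenvalues: ",
      paste(signif(utils::head(x$eigenvalues[-seq_len(x$num_zero_modes)], 4), 3),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Sample a conformational-state library along normal modes
#'
#' Each state displaces the nodes by `sum_m c_m v_m`, with the coefficient of
#' mode m drawn as `c_m = z * amplitudes[m] * sqrt(N)` for `z ~ N(0, 1)`, so
#' that the signed per-state RMSD contribution of mode m (`c_m / sqrt(N)` over
#' N nodes) has standard deviation `amplitudes[m]` Angstrom. Scatterers that
#' are not network nodes move rigidly with their nearest node.
#'
#' @param p A [particle].
#' @param modes A `normal_mode_set` from [build_anm()].
#' @param mode_indices Indices of modes to sample (1-based over the ascending
#'   eigenvalue order); must exclude the rigid-body modes.
#' @param amplitudes Per-mode RMSD scale in Angstrom (recycled).
#' @param n_states Number of conformers to draw.
#' @param seed Integer seed.
#' @return List of [particle] objects with distinct labels; attribute
#'   `"coefficients"` holds the n_states x n_modes draw matrix (RMSD units).
#' @export
sample_conformers <- function(p, modes, mode_indices, amplitudes, n_states,
                              seed = 1L) {
  stopifnot(inherits(p, "particle"), inherits(modes, "normal_mode_set"),
            n_states >= 1)
  if (any(mode_indices <= modes$num_zero_modes))
    stop("mode_indices include rigid-body (zero) modes; internal modes start at ",
         modes$num_zero_modes + 1)
  if (any(mode_indices > length(modes$eigenvalues))) stop("mode index out of range")
  amplitudes <- rep_len(amplitudes, length(mode_indices))
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0")
  n_nodes <- nrow(modes$node_positions)
  # map every scatterer to its nearest node
  near <- .nearest_index(p$positions, modes$node_positions)
  coefs <- .with_seed(seed,
    matrix(stats::rnorm(n_states * length(mode_indices)), n_states))
  coefs <- sweep(coefs, 2, amplitudes, "*")  # RMSD units
  out <- vector("list", n_states)
  for (s in seq_len(n_states)) {
    disp_nodes <- matrix(0, n_nodes, 3)
    for (k in seq_along(mode_indices)) {
      v <- matrix(modes$eigenvectors[, mode_indices[k]], ncol = 3, byrow = TRUE)
      disp_nodes <- disp_nodes + coefs[s, k] * sqrt(n_nodes) * v
    }
    q <- p
    q$positions <- p$positions + disp_nodes[near, , drop = FALSE]
    q$label <- sprintf("%s_state%03d", p$label, s)
    out[[s]] <- q
  }
  attr(out, "coefficients") <- coefs
  attr(out, "seed") <- seed
  out
}

.nearest_index <- function(points, ref) {
  d2 <- outer(rowSums(points^2), rowSums(ref^2), "+") - 2 * points %*% t(ref)
  max.col(-d2, ties.method = "first")
}

#' Write a conformer library to disk
#'
#' One particle HDF5 file per state plus a JSON manifest mapping labels to
#' files and recording the sampling settings.
#'
#' @param states List of [particle] objects (e.g. from [sample_conformers()]).
#' @param dir Output directory (created if needed).
#' @return Path to the manifest JSON, invisibly.
#' @export
write_conformer_library <- function(states, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(states))
  for (i in seq_along(states)) {
    files[i] <- file.path(dir, sprintf("state_%03d.h5", i))
    write_particle_h5(states[[i]], files[i])
  }
  manifest <- list(
    states = lapply(seq_along(states), function(i)
      list(label = states[[i]]$label, file = basename(files[i]))),
    seed = attr(states, "seed"))
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(mf)
}
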