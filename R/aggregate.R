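# Ballistic hit-and-stick particle-cluster aggregation: clusters grow by
# successive collisions between the current cluster and one incoming particle,
# which freezes at first contact (no re-orientation, compression or
# fragmentation). Collision detection is at bounding-sphere level.

#' Bounding radius of a particle
#'
#' Radius of the smallest origin-centered sphere containing all scatterers
#' after centering at the scatterer centroid.
#'
#' @param p A [particle].
#' @return Radius in Angstrom.
#' @export
bounding_radius <- function(p) {
  stopifnot(inherits(p, "particle"))
  ctr <- .centroid(p)
  sqrt(max(rowSums(sweep(p$positions, 2, ctr)^2)))
}

#' Build a multi-particle cluster by ballistic aggregation
#'
#' The first member sits at the origin. Each subsequent member is uniformly
#' rotated, launched from a random direction outside the cluster with a random
#' transverse impact offset (uniform in the disk of the cluster's projected
#' radius), and translated along its line of flight toward the cluster center
#' of mass until its bounding sphere first touches any member's bounding
#' sphere, where it sticks.
#'
#' @param particles List of [particle] objects, one per member, in insertion
#'   order (a single particle may be repeated).
#' @param seed Integer seed.
#' @param margin Launch-distance margin in Angstrom (default 1).
#' @param max_retries Resampling budget when a trajectory misses (default 100).
#' @return Object of class `cluster_layout`: per-member quaternion and center
#'   offset (Angstrom), bounding radii, and the contact graph edge list.
#' @export
build_cluster <- function(particles, seed = 1L, margin = 1, max_retries = 100L) {
  stopifnot(length(particles) >= 1)
  lapply(particles, function(p) stopifnot(inherits(p, "particle")))
  radii <- vapply(particles, bounding_radius, numeric(1))
  n <- length(particles)
  centers <- matrix(0, n, 3)
  quats <- matrix(0, n, 4)
  edges <- matrix(integer(0), 0, 2)
  tol_rel <- 1e-6
  .with_seed(seed, {
    quats[1, ] <- random_quaternions(1)
    if (n > 1) for (m in 2:n) {
      quats[m, ] <- random_quaternions(1)
      com <- colMeans(centers[1:(m - 1), , drop = FALSE])
      ext <- max(sqrt(rowSums(sweep(centers[1:(m - 1), , drop = FALSE], 2, com)^2)) +
                   radii[1:(m - 1)])
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        # transverse offset uniform in the cluster's projected disk
        b_r <- ext * sqrt(stats::runif(1))
        b_a <- stats::runif(1, 0, 2 * pi)
        e1 <- .perp_unit(u)
        e2 <- c(u[2] * e1[3] - u[3] * e1[2],
                u[3] * e1[1] - u[1] * e1[3],
                u[1] * e1[2] - u[2] * e1[1])
        x0 <- com + (ext + radii[m] + margin) * u +
          b_r * (cos(b_a) * e1 + sin(b_a) * e2)
        # first contact along x(t) = x0 - t*u with members' spheres
        t_hit <- Inf; hit <- NA_integer_
        for (i in 1:(m - 1)) {
          dc <- x0 - centers[i, ]
          R <- radii[i] + radii[m]
          bq <- sum(dc * u)           # t at closest approach
          cq <- sum(dc^2) - R^2
          disc <- bq^2 - cq
          if (disc >= 0) {
            t1 <- bq - sqrt(disc)
            if (t1 > 0 && t1 < t_hit) { t_hit <- t1; hit <- i }
          }
        }
        if (is.finite(t_hit)) {
          centers[m, ] <- x0 - t_hit * u
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("aggregation trajectory missed the cluster ", max_retries,
             " times for member ", m)
      # contact edges at insertion
      for (i in 1:(m - 1)) {
        R <- radii[i] + radii[m]
        if (sqrt(sum((centers[m, ] - centers[i, ])^2)) <= R * (1 + tol_rel))
          edges <- rbind(edges, c(i, m))
      }
    }
  })
  structure(list(particles = particles, radii = radii,
                 quaternions = quats, centers = centers,
                 contact_edges = edges, seed = seed),
            class = "cluster_layout")
}

.perp_unit <- function(u) {
  v <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w <- v - sum(v * u) * u
  w / sqrt(sum(w^2))
}

#' @export
print.cluster_layout <- function(x, ...) {
  cat("<cluster_layout> ", nrow(x$centers), " members, ",
      nrow(x$contact_edges), " contacts (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Merge a cluster layout into a single particle
#'
#' Rotates each member (about its scatterer centroid) by its quaternion,
#' offsets it by its center, and concatenates scatterers and solvent points.
#'
#' @param layout A `cluster_layout` from [build_cluster()].
#' @return A single merged [particle].
#' @export
realize_cluster <- function(layout) {
  stopifnot(inherits(layout, "cluster_layout"))
  parts <- lapply(seq_along(layout$particles), function(m) {
    p <- layout$particles[[m]]
    R <- quat_to_matrix(layout$quaternions[m, ])
    ctr <- .centroid(p)
    off <- layout$centers[m, ]
    q <- p
    q$positions <- sweep(sweep(p$positions, 2, ctr) %*% t(R), 2, off, "+")
    if (nrow(p$solvent_points))
      q$solvent_points <- sweep(sweep(p$solvent_points, 2, ctr) %*% t(R), 2, off, "+")
    q
  })
  merged <- parts[[1]]
  merged$positions <- do.call(rbind, lapply(parts, `[[`, "positions"))
  merged$occupancy <- do.call(c, lapply(parts, `[[`, "occupancy"))
  merged$solvent_points <- do.call(rbind, lapply(parts, `[[`, "solvent_points"))
  merged$solvent_amplitude <- do.call(c, lapply(parts, `[[`, "solvent_amplitude"))
  names_ok <- all(vapply(parts, function(q) !is.null(q$atom_name), logical(1)))
  merged$atom_name <- if (names_ok) do.call(c, lapply(parts, `[[`, "atom_name")) else NULL
  if (any(vapply(parts, function(q) !is.null(q$ff_records), logical(1)))) {
    # mixed element/explicit members: promote everything to explicit records
    merged$ff_records <- do.call(c, lapply(parts, .records_or_from_elements))
    merged$element <- NULL
  } else {
    merged$ff_records <- NULL
    merged$element <- do.call(c, lapply(parts, `[[`, "element"))
  }
  merged$label <- sprintf("cluster_n%d_seed%d", length(parts), layout$seed)
  merged
}

.records_or_from_elements <- function(p) {
  if (!is.null(p$ff_records)) return(p$ff_records)
  lapply(p$element, ff_record)
}

#' Serialize a cluster layout to JSON
#'
#' Quaternions, center offsets, radii and seed; enough to reproduce the
#' geometry without re-running the aggregation.
#'
#' @param layout A `cluster_layout`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_cluster_json <- function(layout, path) {
  stopifnot(inherits(layout, "cluster_layout"))
  jsonlite::write_json(
    list(quaternions = layout$quaternions, centers = layout$centers,
         radii = layout$radii, contact_edges = layout$contact_edges,
         seed = layout$seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
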