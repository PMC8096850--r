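#' One mean-shift step on a density map
#'
#' Moves a position to the density-weighted Gaussian-kernel mean of the voxel
#' centres in its neighbourhood (kernel sigma = `bandwidth`, truncated at
#' 3 sigma). Negative densities are clamped to zero before weighting. A
#' position is a fixed point exactly when it is a stationary point of the
#' kernel-smoothed density.
#'
#' @param y numeric length-3 position in Angstrom.
#' @param map a [density_map()].
#' @param bandwidth kernel sigma in Angstrom.
#' @return The shifted position; attribute `"null_shift"` is `TRUE` when the
#'   neighbourhood carried zero total weight (position returned unchanged).
#' @export
mean_shift_step <- function(y, map, bandwidth) {
  if (bandwidth <= 0) abort("bandwidth must be > 0")
  res <- cpp_mean_shift(as.numeric(map$values), dim(map$values),
                        map$voxel_size, map$origin,
                        matrix(as.numeric(y), nrow = 1), bandwidth,
                        max_iter = 1L, tol = 0)
  out <- drop(res$points)
  if (res$null_shift[1]) out <- as.numeric(y)
  attr(out, "null_shift") <- res$null_shift[1]
  out
}

# Kernel-smoothed density (unnormalised KDE with density weights) used by the
# monotone-ascent checks.
kernel_density_at <- function(points, map, bandwidth) {
  pts <- matrix(as.numeric(points), ncol = 3)
  res <- cpp_mean_shift(as.numeric(map$values), dim(map$values),
                        map$voxel_size, map$origin, pts, bandwidth,
                        max_iter = 1L, tol = 0)
  res$density
}

#' Extract local dense points (LDPs) from a density map
#'
#' Every voxel at or above `threshold` is iterated to convergence under
#' Gaussian mean shift; converged positions within `merge_radius` of each
#' other are merged into a single density-weighted point. Strings of LDPs
#' follow ridges of the map and expose main-chain trails in well-resolved
#' regions.
#'
#' @param map a [density_map()].
#' @param threshold absolute density cutoff, or `"<k>sigma"` notation (see
#'   [resolve_threshold()]).
#' @param bandwidth kernel sigma in Angstrom; default twice the voxel size.
#' @param merge_radius merge distance in Angstrom; default one voxel.
#' @param max_iter,tol convergence controls for the iteration.
#' @return A tibble with class `ldp_set`: columns `x`, `y`, `z`,
#'   `density_at_point`, `members`.
#' @export
extract_ldps <- function(map, threshold, bandwidth = 2 * max(map$voxel_size),
                         merge_radius = max(map$voxel_size),
                         max_iter = 200, tol = 1e-3) {
  thr <- resolve_threshold(map, threshold)
  sel <- which(map$values >= thr)
  empty <- tibble(x = numeric(0), y = numeric(0), z = numeric(0),
                  density_at_point = numeric(0), members = integer(0))
  class(empty) <- c("ldp_set", class(empty))
  if (!length(sel)) return(empty)
  d <- dim(map$values)
  ii <- arrayInd(sel, d)
  starts <- cbind(map$origin[1] + (ii[, 1] - 1) * map$voxel_size[1],
                  map$origin[2] + (ii[, 2] - 1) * map$voxel_size[2],
                  map$origin[3] + (ii[, 3] - 1) * map$voxel_size[3])
  res <- cpp_mean_shift(as.numeric(map$values), d, map$voxel_size,
                        map$origin, starts, bandwidth,
                        max_iter = as.integer(max_iter), tol = tol)
  pts <- res$points
  dens <- res$density
  keep <- !res$null_shift
  pts <- pts[keep, , drop = FALSE]
  dens <- dens[keep]
  if (!nrow(pts)) return(empty)
  # greedy merge in decreasing density order
  ord <- order(-dens, pts[, 1], pts[, 2], pts[, 3])
  assigned <- rep(NA_integer_, nrow(pts))
  centers <- list()
  for (p in ord) {
    placed <- FALSE
    for (cidx in seq_along(centers)) {
      cc <- centers[[cidx]]
      if (sum((pts[p, ] - cc$pos)^2) <= merge_radius^2) {
        w <- dens[p]
        cc$pos <- (cc$pos * cc$wsum + pts[p, ] * w) / (cc$wsum + w)
        cc$wsum <- cc$wsum + w
        cc$members <- cc$members + 1L
        cc$density <- max(cc$density, dens[p])
        centers[[cidx]] <- cc
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centers[[length(centers) + 1L]] <-
        list(pos = pts[p, ], wsum = dens[p], density = dens[p], members = 1L)
    }
  }
  out <- tibble(
    x = vapply(centers, function(cc) cc$pos[1], numeric(1)),
    y = vapply(centers, function(cc) cc$pos[2], numeric(1)),
    z = vapply(centers, function(cc) cc$pos[3], numeric(1)),
    density_at_point = vapply(centers, function(cc) cc$density, numeric(1)),
    members = vapply(centers, function(cc) cc$members, integer(1))
  ) |> arrange(dplyr::desc(.data$density_at_point))
  class(out) <- c("ldp_set", class(out))
  out
}

#' Distance graph over a set of LDPs
#'
#' Undirected edges between all pairs of points closer than `cutoff`,
#' useful for visualising main-chain trails.
#'
#' @param ldps an `ldp_set` tibble from [extract_ldps()].
#' @param cutoff edge distance cutoff in Angstrom.
#' @return Tibble of edges: `from`, `to` (row indices), `distance`.
#' @export
ldp_graph <- function(ldps, cutoff) {
  if (cutoff <= 0) abort("cutoff must be > 0")
  n <- nrow(ldps)
  if (n < 2) {
    return(tibble(from = integer(0), to = integer(0), distance = numeric(0)))
  }
  dm <- as.matrix(dist(cbind(ldps$x, ldps$y, ldps$z)))
  pairs <- which(upper.tri(dm) & dm < cutoff, arr.ind = TRUE)
  tibble(from = as.integer(pairs[, 1]), to = as.integer(pairs[, 2]),
         distance = dm[pairs]) |> arrange(.data$from, .data$to)
}

#' Write LDPs as pseudo-atoms
#'
#' LDPs are written as HETATM pseudo-atom records (element X) so they can be
#' displayed alongside maps and models in standard viewers.
#'
#' @param ldps an `ldp_set` tibble.
#' @param path output PDB path.
#' @export
write_ldps_pdb <- function(ldps, path) {
  model <- atomic_model(tibble(
    chain = "L", resid = seq_len(nrow(ldps)), resname = "LDP", atom = "X",
    element = "X", x = ldps$x, y = ldps$y, z = ldps$z,
    occupancy = 1, b_factor = ldps$density_at_point
  ))
  xyz <- as.vector(t(model_xyz(model)))
  bio3d::write.pdb(pdb = NULL, file = path, xyz = xyz, type = "HETATM",
                   resno = model$resid, resid = model$resname,
                   chain = model$chain, elety = model$atom,
                   o = model$occupancy, b = model$b_factor,
                   elesy = model$element)
  invisible(NULL)
}
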