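#' Hydrated and Stokes radii of common permeant ions
#'
#' Default table used for constriction reporting and open/closed
#' classification: hydrated radii of calcium (4.12 A), chloride (3.32 A) and
#' potassium (3.31 A); the bare Stokes radius (1.21 A for chloride) is kept
#' where available.
#'
#' @return Tibble with columns `ion`, `hydrated_radius`, `stokes_radius` (A).
#' @export
ion_radii <- function() {
  tibble(
    ion = c("Ca2+", "Cl-", "K+"),
    hydrated_radius = c(4.12, 3.32, 3.31),
    stokes_radius = c(NA_real_, 1.21, NA_real_)
  )
}

#' Estimate the channel (pore) axis of a model
#'
#' For a Cn-symmetric assembly the conduction path runs along the rotational
#' symmetry axis. The axis is placed through the centre of mass; its direction
#' starts from the smallest-variance eigenvector of the chain-centroid
#' covariance (chain centroids of a ring-like assembly spread in the plane
#' perpendicular to the axis) and is refined by minimising the variance of
#' chain-centroid distances to the axis. With fewer than three chains the
#' direction falls back to the most isolated eigenvector of the atomic
#' covariance. The direction is normalised to point along +z where possible.
#'
#' @param model an [atomic_model()].
#' @return A `channel_axis` object: list with `point` and unit `direction`.
#' @export
channel_axis <- function(model) {
  xyz <- model_xyz(model)
  if (nrow(xyz) < 3) abort("degenerate axis: need at least 3 atoms")
  point <- colMeans(xyz)
  chains <- split.data.frame(xyz, model$chain)
  if (length(chains) >= 3) {
    cent <- do.call(rbind, lapply(chains, colMeans))
    ev <- eigen(stats::cov(cent), symmetric = TRUE)
    dir0 <- ev$vectors[, 3]
    dir <- refine_axis_direction(dir0, cent, point)
  } else {
    ev <- eigen(stats::cov(xyz), symmetric = TRUE)
    lam <- ev$values
    # the eigenvalue most separated from the other two marks the symmetry axis
    sep <- vapply(1:3, function(i) min(abs(lam[i] - lam[-i])), numeric(1))
    dir <- ev$vectors[, which.max(sep)]
  }
  dir <- dir / sqrt(sum(dir^2))
  flip <- if (abs(dir[3]) > 1e-8) sign(dir[3]) else {
    if (abs(dir[1]) > 1e-8) sign(dir[1]) else sign(dir[2])
  }
  dir <- dir * flip
  structure(list(point = point, direction = dir), class = "channel_axis")
}

refine_axis_direction <- function(dir0, centroids, point) {
  sph <- c(acos(max(-1, min(1, dir0[3]))), atan2(dir0[2], dir0[1]))
  obj <- function(p) {
    d <- c(sin(p[1]) * cos(p[2]), sin(p[1]) * sin(p[2]), cos(p[1]))
    rel <- sweep(centroids, 2, point)
    proj <- rel - outer(drop(rel %*% d), d)
    stats::var(sqrt(rowSums(proj^2)))
  }
  fit <- optim(sph, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 500))
  p <- fit$par
  c(sin(p[1]) * cos(p[2]), sin(p[1]) * sin(p[2]), cos(p[1]))
}

# Orthonormal frame with w along the axis; returns atoms as (u, v, w).
to_axis_frame <- function(xyz, axis) {
  d <- axis$direction
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * d) * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  rel <- sweep(xyz, 2, axis$point)
  cbind(u = drop(rel %*% e1), v = drop(rel %*% e2), w = drop(rel %*% d))
}

#' Maximal inscribed sphere radius in one plane normal to the axis
#'
#' HOLE-style profiling: at axial position `z`, the pore radius is the
#' largest sphere centred in the plane that touches no atom, i.e. the maximum
#' over in-plane centres of the minimal atom clearance
#' (distance minus van der Waals radius). Maximisation uses multi-start
#' Nelder-Mead ascent (axis point, caller-provided seed centre and a ring of
#' perturbed starts) with a seeded simulated-annealing fallback when every
#' start lands inside an atom.
#'
#' @param model an [atomic_model()].
#' @param z axial position in Angstrom (in the axis frame).
#' @param axis a [channel_axis()]; computed from the model when `NULL`.
#' @param r_cap radius cap in Angstrom; planes with no atoms within reach are
#'   flagged `"unbounded"` at this radius.
#' @param start optional in-plane `(u, v)` centre used to seed the search.
#' @param n_starts number of perturbed ring starts.
#' @param seed RNG seed for the annealing fallback.
#' @return List with `radius` (A), `center` (u, v), `lining` (row index of
#'   the contact atom in `model`, or `NA`), and `flag` (`""` or
#'   `"unbounded"`).
#' @export
max_inscribed_radius <- function(model, z, axis = NULL, r_cap = 30,
                                 start = NULL, n_starts = 8, seed = 1) {
  if (is.null(axis)) axis <- channel_axis(model)
  fr <- to_axis_frame(model_xyz(model), axis)
  slab <- abs(fr[, "w"] - z) <= r_cap + max(model$vdw)
  if (!any(slab)) {
    return(list(radius = r_cap, center = c(0, 0), lining = NA_integer_,
                flag = "unbounded"))
  }
  au <- fr[slab, "u"]; av <- fr[slab, "v"]; adz <- fr[slab, "w"] - z
  avdw <- model$vdw[slab]
  idx <- which(slab)
  clearance <- function(c_uv) {
    min(sqrt((au - c_uv[1])^2 + (av - c_uv[2])^2 + adz^2) - avdw)
  }
  starts <- rbind(c(0, 0))
  if (!is.null(start)) {
    starts <- rbind(starts, start)
    ang <- 2 * pi * (seq_len(n_starts) - 1) / n_starts
    starts <- rbind(starts,
                    cbind(start[1] + cos(ang), start[2] + sin(ang)),
                    cbind(start[1] + 2.5 * cos(ang), start[2] + 2.5 * sin(ang)))
  } else {
    ang <- 2 * pi * (seq_len(n_starts) - 1) / n_starts
    starts <- rbind(starts, cbind(2.5 * cos(ang), 2.5 * sin(ang)))
  }
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- optim(starts[s, ], function(p) -clearance(p),
                 method = "Nelder-Mead",
                 control = list(reltol = 1e-12, maxit = 2000))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (-best$value < 0) {
    # every start is buried: seeded annealing sweep, then polish
    best_sa <- withr::with_seed(seed, {
      optim(c(0, 0), function(p) -clearance(p), method = "SANN",
            control = list(maxit = 2000, temp = 5))
    })
    polish <- optim(best_sa$par, function(p) -clearance(p),
                    method = "Nelder-Mead",
                    control = list(reltol = 1e-12, maxit = 2000))
    if (polish$value < best$value) best <- polish
  }
  r <- -best$value
  flag <- ""
  if (r >= r_cap) { r <- r_cap; flag <- "unbounded" }
  if (r < 0) r <- 0
  dmin <- sqrt((au - best$par[1])^2 + (av - best$par[2])^2 + adz^2) - avdw
  # tie-break on the smallest atom index
  lining <- idx[which(dmin <= min(dmin) + 1e-9)[1]]
  list(radius = r, center = best$par, lining = lining, flag = flag)
}

#' Profile the pore radius along the channel axis
#'
#' Sweeps planes from `z_min` to `z_max` every `step` Angstrom, seeding each
#' plane's search from the previous plane's optimal centre (path continuity).
#'
#' @inheritParams max_inscribed_radius
#' @param z_min,z_max axial range in Angstrom (axis frame); defaults to the
#'   model's axial extent.
#' @param step plane spacing in Angstrom.
#' @return A tibble with class `pore_profile`: columns `z`, `radius`, `cx`,
#'   `cy`, `chain`, `resid`, `atom`, `flag`. The axis is attached as
#'   attribute `"axis"`.
#' @export
pore_profile <- function(model, axis = NULL, z_min = NULL, z_max = NULL,
                         step = 0.5, r_cap = 30, seed = 1) {
  if (is.null(axis)) axis <- channel_axis(model)
  w <- to_axis_frame(model_xyz(model), axis)[, "w"]
  if (is.null(z_min)) z_min <- min(w)
  if (is.null(z_max)) z_max <- max(w)
  if (!(z_min < z_max)) abort("z_min must be < z_max")
  if (step <= 0) abort("step must be > 0")
  zs <- seq(z_min, z_max, by = step)
  prev <- NULL
  rows <- vector("list", length(zs))
  for (i in seq_along(zs)) {
    res <- max_inscribed_radius(model, zs[i], axis, r_cap = r_cap,
                                start = prev, seed = seed)
    prev <- if (res$flag == "") res$center else NULL
    lin <- res$lining
    rows[[i]] <- tibble(
      z = zs[i], radius = res$radius, cx = res$center[1], cy = res$center[2],
      chain = if (is.na(lin)) NA_character_ else as.character(model$chain[lin]),
      resid = if (is.na(lin)) NA_integer_ else as.integer(model$resid[lin]),
      atom = if (is.na(lin)) NA_character_ else as.character(model$atom[lin]),
      flag = res$flag
    )
  }
  out <- bind_rows(rows)
  attr(out, "axis") <- axis
  class(out) <- c("pore_profile", class(out))
  out
}

# Prominence of local minima of `radius`: depth below the lower of the two
# enclosing ridges, ridges bounded by deeper minima or the profile ends.
minima_with_prominence <- function(radius) {
  n <- length(radius)
  if (n < 3) return(integer(0))
  is_min <- vapply(2:(n - 1), function(i) {
    radius[i] < radius[i - 1] && radius[i] <= radius[i + 1]
  }, logical(1))
  idx <- (2:(n - 1))[is_min]
  prom <- vapply(idx, function(i) {
    left <- radius[1:i]
    right <- radius[i:n]
    deeper_l <- which(left < radius[i])
    deeper_r <- which(right < radius[i])
    lmax <- if (length(deeper_l)) max(left[max(deeper_l):i]) else max(left)
    rmax <- if (length(deeper_r)) max(right[1:min(deeper_r)]) else max(right)
    min(lmax, rmax) - radius[i]
  }, numeric(1))
  stats::setNames(prom, idx)
}

#' Locate pore constrictions
#'
#' Constrictions are local minima of the radius profile with prominence at
#' least `prominence` Angstrom. Each is reported with its lining residue (the
#' atom realising the minimum) and the subset of ions whose hydrated radius
#' exceeds the local pore radius.
#'
#' @param profile a [pore_profile()].
#' @param model optional [atomic_model()] (unused beyond lining columns kept
#'   in the profile; accepted for call-site symmetry).
#' @param ions an [ion_radii()]-style tibble.
#' @param prominence minimum prominence in Angstrom.
#' @return Tibble: `z`, `radius`, `prominence`, `chain`, `resid`, `atom`,
#'   `excluded_ions` (comma-joined ion names).
#' @export
find_constrictions <- function(profile, model = NULL, ions = ion_radii(),
                               prominence = 0.5) {
  if (!nrow(profile)) abort("empty profile")
  prom <- minima_with_prominence(profile$radius)
  keep <- prom >= prominence
  idx <- as.integer(names(prom))[keep]
  out <- profile[idx, c("z", "radius", "chain", "resid", "atom")]
  out$prominence <- unname(prom[keep])
  out$excluded_ions <- vapply(out$radius, function(r) {
    paste(ions$ion[ions$hydrated_radius > r], collapse = ",")
  }, character(1))
  out <- out[, c("z", "radius", "prominence", "chain", "resid", "atom",
                 "excluded_ions")]
  as_tibble(out)
}

#' Classify the channel state per ion
#'
#' An ion is blocked ("closed") when the minimum pore radius is strictly
#' smaller than its hydrated radius; a minimum radius exactly equal to the
#' hydrated radius counts as open (strict-inequality convention).
#'
#' @inheritParams find_constrictions
#' @return Tibble: `ion`, `hydrated_radius`, `min_radius`, `closed`,
#'   `margin` (hydrated minus minimum radius; positive means blocked).
#' @export
classify_state <- function(profile, ions = ion_radii()) {
  if (!nrow(profile)) abort("empty profile")
  rmin <- min(profile$radius)
  ions |>
    mutate(min_radius = rmin,
           closed = rmin < .data$hydrated_radius,
           margin = .data$hydrated_radius - rmin) |>
    select("ion", "hydrated_radius", "min_radius", "closed", "margin")
}
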