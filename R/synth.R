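#' Analytic free-energy profiles
#'
#' Closed-form potentials of mean force used as ground truth by the
#' synthetic umbrella-sampling generators. Shipped forms:
#'
#' * `flat`: A = 0.
#' * `harmonic`: A = k/2 q^2.
#' * `double_well`: A = height * ((q/width)^2 - 1)^2 — a `height` kcal/mol
#'   barrier at q = 0 between minima at +/- `width` A.
#' * `multi_barrier`: a sum of Gaussian bumps; the defaults mirror a
#'   pannexin-like channel with a 5 kcal/mol intracellular-constriction peak
#'   and a 4 kcal/mol pore-funnel peak at the designated axial positions.
#' * `tabulated`: cubic-spline interpolation of supplied `(q, A)` samples.
#'
#' @param form profile form id.
#' @param height,width double-well barrier height (kcal/mol) and half-well
#'   separation (A).
#' @param k harmonic spring constant (kcal/mol/A^2).
#' @param heights,positions,widths Gaussian bump parameters for
#'   `multi_barrier` (kcal/mol, A, A).
#' @param q,A samples for `tabulated`.
#' @return An `analytic_pmf` object with [pmf_value()] / [pmf_grad()]
#'   methods.
#' @export
analytic_pmf <- function(form = c("flat", "harmonic", "double_well",
                                  "multi_barrier", "tabulated"),
                         height = 5, width = 10, k = 1,
                         heights = c(5, 4), positions = c(-15, 15),
                         widths = c(4, 4), q = NULL, A = NULL) {
  form <- match.arg(form)
  obj <- list(form = form, height = height, width = width, k = k,
              heights = heights, positions = positions, widths = widths,
              tab_q = q, tab_A = A)
  if (form == "multi_barrier" &&
      !(length(heights) == length(positions) &&
        length(heights) == length(widths))) {
    abort("heights, positions, widths must have equal length")
  }
  if (form == "tabulated") {
    if (is.null(q) || is.null(A) || length(q) != length(A) || length(q) < 4) {
      abort("tabulated form needs matching q and A samples (>= 4)")
    }
    obj$spline <- stats::splinefun(q, A, method = "natural")
  }
  structure(obj, class = "analytic_pmf")
}

#' Evaluate an analytic PMF or its gradient
#'
#' @param pmf an [analytic_pmf()].
#' @param q reaction coordinate in Angstrom (vectorised).
#' @return Energies in kcal/mol, or gradients in kcal/mol/A.
#' @export
pmf_value <- function(pmf, q) {
  switch(pmf$form,
    flat = rep(0, length(q)),
    harmonic = pmf$k / 2 * q^2,
    double_well = pmf$height * ((q / pmf$width)^2 - 1)^2,
    multi_barrier = {
      v <- rep(0, length(q))
      for (j in seq_along(pmf$heights)) {
        v <- v + pmf$heights[j] *
          exp(-0.5 * ((q - pmf$positions[j]) / pmf$widths[j])^2)
      }
      v
    },
    tabulated = pmf$spline(q)
  )
}

#' @rdname pmf_value
#' @export
pmf_grad <- function(pmf, q) {
  switch(pmf$form,
    flat = rep(0, length(q)),
    harmonic = pmf$k * q,
    double_well = 4 * pmf$height * q * (q^2 / pmf$width^2 - 1) / pmf$width^2,
    multi_barrier = {
      v <- rep(0, length(q))
      for (j in seq_along(pmf$heights)) {
        d <- q - pmf$positions[j]
        v <- v - pmf$heights[j] * d / pmf$widths[j]^2 *
          exp(-0.5 * (d / pmf$widths[j])^2)
      }
      v
    },
    tabulated = pmf$spline(q, deriv = 1)
  )
}

# Numeric encoding shared with the C++ sampler.
pmf_cpp_spec <- function(pmf, grid_n = 4001) {
  form_id <- match(pmf$form,
                   c("flat", "harmonic", "double_well", "multi_barrier",
                     "tabulated")) - 1L
  spec <- list(form_id = form_id,
               p1 = if (pmf$form == "harmonic") pmf$k else pmf$height,
               p2 = pmf$width,
               heights = as.numeric(pmf$heights),
               positions = as.numeric(pmf$positions),
               widths = as.numeric(pmf$widths),
               tab_q0 = 0, tab_dq = 1, tab_grad = 0)
  if (pmf$form == "tabulated") {
    q0 <- min(pmf$tab_q); q1 <- max(pmf$tab_q)
    qq <- seq(q0, q1, length.out = grid_n)
    spec$tab_q0 <- q0
    spec$tab_dq <- qq[2] - qq[1]
    spec$tab_grad <- pmf$spline(qq, deriv = 1)
  }
  spec
}

#' Sample one umbrella window with biased Langevin/Metropolis dynamics
#'
#' A 1-D surrogate for the biased all-atom runs: the ion coordinate diffuses
#' on `U(q) = A*(q) + c/2 (q - anchor)^2` at temperature
#' `thermo$temperature` under Metropolis-adjusted overdamped Langevin
#' dynamics (MALA), whose stationary law is exactly `exp(-beta U)` at any
#' stable step size; acceptance is near unity at the defaults. The default
#' step keeps `c * dt / damping` well below 0.1 for the stiffest shipped
#' case (c = 20 on a 5 kcal/mol barrier). At zero temperature the update
#' degenerates to gradient descent on the biased potential. All randomness
#' is drawn through R's RNG under `seed`.
#'
#' @param pmf an [analytic_pmf()].
#' @param anchor window anchor in Angstrom.
#' @param force_const bias force constant in kcal/mol/A^2.
#' @param n_samples samples to record.
#' @param dt integration step (reduced time units).
#' @param damping friction coefficient gamma.
#' @param thermo a [thermo_state()].
#' @param seed RNG seed.
#' @param stride steps between recorded samples.
#' @param burn_in discarded equilibration steps.
#' @param q0 initial coordinate; defaults to the anchor.
#' @return A [time_series()] tibble (`time_ns` in units of `dt` steps).
#' @export
sample_window <- function(pmf, anchor, force_const = 20, n_samples = 1e4,
                          dt = 0.002, damping = 1, thermo = thermo_state(),
                          seed = 1, stride = 20, burn_in = 2000,
                          q0 = anchor) {
  n_steps <- burn_in + stride * n_samples
  noise_sd <- sqrt(2 * thermo$kT * dt / damping)
  q <- withr::with_seed(seed, {
    noise <- rnorm(n_steps, sd = noise_sd)
    unif <- runif(n_steps)
    cpp_sample_window(pmf_cpp_spec(pmf), anchor, force_const, dt, damping,
                      thermo$kT, noise, unif, as.integer(burn_in),
                      as.integer(stride), as.integer(n_samples), q0)
  })
  time_series((burn_in + stride * seq_len(n_samples)) * dt, q)
}

#' Steered seeding of umbrella windows
#'
#' Pulls the coordinate with a moving harmonic anchor from `q_from` to
#' `q_to` at constant `velocity`, recording a snapshot whenever the anchor
#' crosses each window anchor. Snapshots serve as initial conditions for
#' [sample_window()].
#'
#' @inheritParams sample_window
#' @param q_from,q_to pull end points in Angstrom.
#' @param velocity anchor speed in A per reduced time unit.
#' @param anchors window anchors to snapshot; default every 1 A.
#' @return Tibble: `anchor`, `q`, `time`.
#' @export
steered_seed <- function(pmf, q_from, q_to, velocity = 5, force_const = 20,
                         thermo = thermo_state(), dt = 0.002, damping = 1,
                         seed = 1, anchors = NULL) {
  if (q_from == q_to) abort("q_from and q_to must differ")
  if (is.null(anchors)) {
    anchors <- seq(q_from, q_to, by = sign(q_to - q_from))
  }
  ord <- order(if (q_to >= q_from) anchors else -anchors)
  anchors_sorted <- anchors[ord]
  n_steps <- ceiling(abs(q_to - q_from) / (velocity * dt)) + 2
  noise_sd <- sqrt(2 * thermo$kT * dt / damping)
  res <- withr::with_seed(seed, {
    noise <- rnorm(n_steps, sd = noise_sd)
    cpp_steered(pmf_cpp_spec(pmf), q_from, q_to, velocity, force_const,
                dt, damping, noise, anchors_sorted, q_from)
  })
  out <- tibble(anchor = anchors_sorted, q = res$q, time = res$time)
  out[match(anchors, anchors_sorted), , drop = FALSE]
}

#' Generate a full synthetic window set for WHAM
#'
#' Convenience wrapper: builds the window grid with [make_windows()] and
#' samples every window with [sample_window()], pooling replicas at the same
#' anchor under distinct sub-seeds.
#'
#' @inheritParams sample_window
#' @param windows window grid from [make_windows()].
#' @return The window tibble with a `series` list-column.
#' @export
sample_windows <- function(pmf, windows, n_samples = 1e4, dt = 0.002,
                           damping = 1, thermo = thermo_state(), seed = 1,
                           stride = 20, burn_in = 2000) {
  windows$series <- purrr::map(seq_len(nrow(windows)), function(i) {
    sample_window(pmf, windows$anchor[i], windows$force_const[i],
                  n_samples = n_samples, dt = dt, damping = damping,
                  thermo = thermo, seed = (seed * 1009L + i) %% .Machine$integer.max,
                  stride = stride, burn_in = burn_in)
  })
  windows
}

#' Build a toy channel model with a known radius profile
#'
#' Stacks rings of pseudo-atoms along z: at each axial position the ring
#' radius follows `radius(z)`, atoms are spaced evenly in angle, and chains
#' partition the atoms into `symmetry` angular sectors (default C7).
#' Residue indices increase along z, so axial positions map cleanly onto
#' residues. The analytic construction makes the true pore radius
#' `radius(z) - vdw` available in closed form for validation.
#'
#' @param radius a function of z returning the ring radius in Angstrom, or a
#'   single number for a cylinder.
#' @param z_range axial extent in Angstrom.
#' @param ring_spacing spacing between rings in Angstrom.
#' @param atoms_per_ring atoms per ring (a multiple of `symmetry`).
#' @param vdw pseudo-atom van der Waals radius in Angstrom.
#' @param symmetry rotational symmetry order.
#' @return An [atomic_model()].
#' @export
build_toy_channel <- function(radius = 5, z_range = c(-20, 20),
                              ring_spacing = 2, atoms_per_ring = 14,
                              vdw = 1.5, symmetry = 7) {
  rfun <- if (is.function(radius)) radius else function(z) rep(radius, length(z))
  if (ring_spacing <= 0) abort("ring_spacing must be > 0")
  if (atoms_per_ring %% symmetry != 0) {
    abort("atoms_per_ring must be a multiple of symmetry")
  }
  zs <- seq(z_range[1], z_range[2], by = ring_spacing)
  per_chain <- atoms_per_ring / symmetry
  rows <- purrr::map(seq_along(zs), function(ri) {
    z <- zs[ri]
    r <- rfun(z)
    ang <- 2 * pi * (seq_len(atoms_per_ring) - 1) / atoms_per_ring
    sector <- rep(seq_len(symmetry), each = per_chain)
    tibble(
      chain = LETTERS[sector],
      resid = ri,
      resname = "RNG",
      atom = paste0("X", rep(seq_len(per_chain), times = symmetry)),
      element = "X",
      x = r * cos(ang), y = r * sin(ang), z = z,
      occupancy = 1, b_factor = 0, vdw = vdw
    )
  })
  atomic_model(bind_rows(rows))
}

#' Two-waist radius profile for toy channels
#'
#' An open lumen of radius `r_open` pinched by Gaussian waists at
#' `waist_z`, mirroring a channel with an intracellular and an
#' extracellular constriction.
#'
#' @param r_open open-lumen ring radius in Angstrom.
#' @param waist_radius ring radius at each waist in Angstrom.
#' @param waist_z axial waist positions in Angstrom.
#' @param waist_width Gaussian width of each waist in Angstrom.
#' @return A function of z suitable for [build_toy_channel()].
#' @export
channel_profile_two_waist <- function(r_open = 8, waist_radius = c(3.5, 4.1),
                                      waist_z = c(-10, 10),
                                      waist_width = c(3, 3)) {
  waist_width <- rep_len(waist_width, length(waist_z))
  waist_radius <- rep_len(waist_radius, length(waist_z))
  function(z) {
    r <- rep(r_open, length(z))
    for (j in seq_along(waist_z)) {
      r <- r - (r_open - waist_radius[j]) *
        exp(-0.5 * ((z - waist_z[j]) / waist_width[j])^2)
    }
    r
  }
}

#' Synthetic model-derived map with optional noise and half maps
#'
#' Blurs the model onto a grid ([model_to_map()]) and adds independent
#' Gaussian voxel noise. In `halves` mode two independent noise realizations
#' of the same signal are returned (plus their average as the full map),
#' emulating gold-standard half maps.
#'
#' @inheritParams model_to_map
#' @param noise_sd Gaussian voxel noise standard deviation (map units).
#' @param seed RNG seed.
#' @param halves return two half maps instead of one map.
#' @param voxel_size,pad grid construction when `grid` is `NULL`.
#' @return A [density_map()], or a list `half1`, `half2`, `full`.
#' @export
synth_map <- function(model, grid = NULL, blur_width = 3.15, noise_sd = 0,
                      seed = 1, halves = FALSE, voxel_size = 1, pad = 6) {
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  g <- if (is.null(grid)) grid_around_model(model, voxel_size, pad) else
    as_grid_spec(grid)
  signal <- model_to_map(model, g, blur_width)
  addnoise <- function(map, eps) {
    density_map(map$values + eps, map$voxel_size, map$origin)
  }
  if (!halves) {
    if (noise_sd == 0) return(signal)
    eps <- withr::with_seed(seed, array(rnorm(prod(g$dim), sd = noise_sd), g$dim))
    return(addnoise(signal, eps))
  }
  eps <- withr::with_seed(seed, {
    list(array(rnorm(prod(g$dim), sd = noise_sd), g$dim),
         array(rnorm(prod(g$dim), sd = noise_sd), g$dim))
  })
  list(half1 = addnoise(signal, eps[[1]]),
       half2 = addnoise(signal, eps[[2]]),
       full = addnoise(signal, (eps[[1]] + eps[[2]]) / 2))
}

coords_of <- function(x) {
  if (inherits(x, "atomic_model")) return(model_xyz(x))
  as.matrix(x)
}

match_atoms <- function(ref, mob) {
  if (inherits(ref, "atomic_model") && inherits(mob, "atomic_model")) {
    kr <- paste(ref$chain, ref$resid, ref$atom)
    km <- paste(mob$chain, mob$resid, mob$atom)
    if (!identical(sort(kr), sort(km))) {
      offenders <- c(setdiff(kr, km), setdiff(km, kr))
      abort(paste0("atom sets differ: ",
                   paste(head(offenders, 5), collapse = "; "),
                   if (length(offenders) > 5) " ..."))
    }
    mob <- mob[match(kr, km), , drop = FALSE]
  }
  list(ref = coords_of(ref), mob = coords_of(mob))
}

#' Root-mean-square deviation between coordinate sets
#'
#' Standard all-atom r.m.s.d.; with `superpose = TRUE` the mobile set is
#' first rigid-body aligned onto the reference (Kabsch fit via bio3d).
#' Atomic-model inputs are matched on `(chain, resid, atom)`; a mismatch is
#' an error listing the offending atoms.
#'
#' @param ref,coords coordinate matrices (n x 3) or [atomic_model()]s.
#' @param superpose apply optimal rigid-body alignment first.
#' @return r.m.s.d. in Angstrom.
#' @export
rmsd <- function(ref, coords, superpose = FALSE) {
  m <- match_atoms(ref, coords)
  a <- m$ref; b <- m$mob
  if (nrow(a) != nrow(b)) abort("coordinate sets differ in size")
  if (superpose) {
    inds <- seq_len(3 * nrow(a))
    b <- matrix(bio3d::fit.xyz(as.vector(t(a)), as.vector(t(b)),
                               fixed.inds = inds, mobile.inds = inds),
                ncol = 3, byrow = TRUE)
  }
  sqrt(mean(rowSums((a - b)^2)))
}

#' Per-atom root-mean-square fluctuation over a trajectory
#'
#' Each frame is optionally superposed onto the reference, then the
#' fluctuation of every atom about its trajectory-mean position is reported.
#'
#' @param traj list of coordinate matrices (frames, each n x 3).
#' @param ref reference coordinates for superposition; defaults to the first
#'   frame.
#' @param superpose apply rigid-body alignment per frame.
#' @return Numeric vector of per-atom r.m.s.f. in Angstrom.
#' @export
rmsf <- function(traj, ref = NULL, superpose = TRUE) {
  frames <- lapply(traj, coords_of)
  n <- unique(vapply(frames, nrow, integer(1)))
  if (length(n) != 1) abort("all frames must have the same atom count")
  if (is.null(ref)) ref <- frames[[1]]
  ref <- coords_of(ref)
  if (superpose) {
    inds <- seq_len(3 * nrow(ref))
    frames <- lapply(frames, function(f) {
      matrix(bio3d::fit.xyz(as.vector(t(ref)), as.vector(t(f)),
                            fixed.inds = inds, mobile.inds = inds),
             ncol = 3, byrow = TRUE)
    })
  }
  arr <- simplify2array(frames)                 # n x 3 x frames
  mean_pos <- apply(arr, c(1, 2), mean)
  sq <- apply(arr, 3, function(f) rowSums((f - mean_pos)^2))
  sqrt(rowMeans(matrix(sq, nrow = n)))
}
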