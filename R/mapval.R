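#' Grid specification helper
#'
#' Builds the grid metadata used by [model_to_map()]: either copied from a
#' template [density_map()] or constructed to cover a model's bounding box
#' with padding.
#'
#' @param dim integer length-3 grid dimensions.
#' @param voxel_size voxel edge in Angstrom (scalar or length 3).
#' @param origin grid origin in Angstrom (first voxel centre).
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(dim, voxel_size = 1, origin = c(0, 0, 0)) {
  structure(list(dim = as.integer(rep_len(dim, 3L)),
                 voxel_size = rep_len(as.numeric(voxel_size), 3L),
                 origin = rep_len(as.numeric(origin), 3L)),
            class = "grid_spec")
}

#' @param model an [atomic_model()].
#' @param pad padding in Angstrom around the model bounding box.
#' @rdname grid_spec
#' @export
grid_around_model <- function(model, voxel_size = 1, pad = 6) {
  xyz <- model_xyz(model)
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  lo <- apply(xyz, 2, min) - pad
  hi <- apply(xyz, 2, max) + pad
  d <- pmax(2L, as.integer(ceiling((hi - lo) / voxel_size)) + 1L)
  grid_spec(d, voxel_size, lo)
}

as_grid_spec <- function(grid) {
  if (inherits(grid, "grid_spec")) return(grid)
  if (inherits(grid, "density_map")) {
    return(grid_spec(dim(grid$values), grid$voxel_size, grid$origin))
  }
  abort("grid must be a grid_spec or density_map")
}

#' Synthesize a model-derived density map
#'
#' Each atom contributes an isotropic Gaussian of width `blur_width`
#' (interpreted as sigma) and unit mass, truncated at 4 sigma; the grid mass
#' therefore equals the atom count up to truncation loss. Atoms outside the
#' grid contribute only their in-grid mass (with a warning).
#'
#' @param model an [atomic_model()].
#' @param grid a [grid_spec()] or template [density_map()].
#' @param blur_width Gaussian sigma in Angstrom.
#' @return A [density_map()] on the requested grid.
#' @export
model_to_map <- function(model, grid, blur_width = 3.15) {
  if (blur_width <= 0) abort("blur_width must be > 0")
  g <- as_grid_spec(grid)
  vals <- array(0, dim = g$dim)
  sigma <- blur_width
  cut <- 4 * sigma
  xyz <- model_xyz(model)
  # density convention: sum(values) * voxel volume integrates to atom count
  norm <- 1 / ((2 * pi * sigma^2)^(3 / 2))
  ax <- lapply(1:3, function(d) g$origin[d] + (seq_len(g$dim[d]) - 1) * g$voxel_size[d])
  hi_edge <- g$origin + (g$dim - 1) * g$voxel_size
  outside <- sum(apply(xyz, 1, function(ctr) {
    any(ctr < g$origin) || any(ctr > hi_edge)
  }))
  for (a in seq_len(nrow(xyz))) {
    ctr <- xyz[a, ]
    rng <- lapply(1:3, function(d) {
      which(abs(ax[[d]] - ctr[d]) <= cut)
    })
    if (any(lengths(rng) == 0)) next
    g1 <- exp(-0.5 * ((ax[[1]][rng[[1]]] - ctr[1]) / sigma)^2)
    g2 <- exp(-0.5 * ((ax[[2]][rng[[2]]] - ctr[2]) / sigma)^2)
    g3 <- exp(-0.5 * ((ax[[3]][rng[[3]]] - ctr[3]) / sigma)^2)
    vals[rng[[1]], rng[[2]], rng[[3]]] <-
      vals[rng[[1]], rng[[2]], rng[[3]]] +
      norm * (g1 %o% g2 %o% g3)
  }
  if (outside > 0) {
    warn(sprintf("%d atom(s) outside the grid contribute only in-grid mass",
                 outside))
  }
  density_map(vals, voxel_size = g$voxel_size, origin = g$origin)
}

# Per-voxel resolution-shell index and shell metadata for a grid.
fsc_shells <- function(d, voxel_size) {
  freq_axis <- function(n, v) {
    k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)
    if (n == 1) k <- 0
    k[seq_len(n)] / (n * v)
  }
  fx <- freq_axis(d[1], voxel_size[1])
  fy <- freq_axis(d[2], voxel_size[2])
  fz <- freq_axis(d[3], voxel_size[3])
  r <- sqrt(outer(outer(fx^2, fy^2, "+"), fz^2, "+"))
  width <- max(1 / (d * voxel_size))
  shell <- as.integer(round(r / width))
  nyquist <- 1 / (2 * max(voxel_size))
  list(shell = shell, width = width, nyquist = nyquist)
}

#' Fourier shell correlation between two maps
#'
#' Per-shell normalized cross-correlation of the discrete Fourier transforms
#' of two maps on the same grid; an optional real-space mask (clamped to
#' `[0, 1]`) is applied before transforming. Shell width is one reciprocal
#' voxel; shells beyond the Nyquist frequency are dropped. Zero-power shells
#' are recorded as 0 with a flag.
#'
#' @param map_a,map_b [density_map()]s on identical grids.
#' @param mask optional [density_map()] mask.
#' @return A tibble with class `fsc_curve`: `freq` (1/A shell centre),
#'   `fsc`, `n_voxels`, `flag`.
#' @export
fsc <- function(map_a, map_b, mask = NULL) {
  if (!same_grid(map_a, map_b)) abort("maps must share one grid")
  a <- map_a$values
  b <- map_b$values
  if (!is.null(mask)) {
    if (!same_grid(map_a, mask)) abort("mask must share the map grid")
    m <- pmin(pmax(mask$values, 0), 1)
    a <- a * m
    b <- b * m
  }
  d <- dim(a)
  sh <- fsc_shells(d, map_a$voxel_size)
  fa <- fft(a)
  fb <- fft(b)
  cross <- Re(fa * Conj(fb))
  pa <- Mod(fa)^2
  pb <- Mod(fb)^2
  idx <- sh$shell + 1L
  num <- as.vector(tapply(as.vector(cross), idx, sum))
  da <- as.vector(tapply(as.vector(pa), idx, sum))
  db <- as.vector(tapply(as.vector(pb), idx, sum))
  nvox <- as.vector(tapply(rep(1L, length(idx)), idx, sum))
  s <- sort(unique(as.vector(idx))) - 1L
  freq <- s * sh$width
  keep <- freq <= sh$nyquist + 1e-12
  denom <- sqrt(da * db)
  zero <- denom <= 0
  val <- ifelse(zero, 0, num / ifelse(zero, 1, denom))
  out <- tibble(freq = freq[keep], fsc = val[keep],
                n_voxels = as.integer(nvox[keep]),
                flag = ifelse(zero[keep], "zero_power", ""))
  class(out) <- c("fsc_curve", class(out))
  out
}

#' Resolution at an FSC threshold
#'
#' Reciprocal of the first frequency at which the curve crosses below the
#' threshold (gold-standard half-map threshold 0.143; map-model threshold
#' 0.5), linearly interpolated between shells. If the curve never crosses,
#' `NA` is returned with attribute `sentinel = "better_than_nyquist"`; if the
#' threshold exceeds the whole curve, the coarsest shell's resolution is
#' returned.
#'
#' @param curve an `fsc_curve` from [fsc()].
#' @param threshold FSC threshold.
#' @return Resolution in Angstrom (possibly with a sentinel attribute).
#' @export
resolution_at <- function(curve, threshold = 0.143) {
  cv <- curve[curve$freq > 0, , drop = FALSE]
  if (!nrow(cv)) abort("empty FSC curve")
  below <- which(cv$fsc < threshold)
  if (!length(below)) {
    return(structure(NA_real_, sentinel = "better_than_nyquist"))
  }
  i <- below[1]
  if (i == 1) return(1 / cv$freq[1])
  f0 <- cv$freq[i - 1]; f1 <- cv$freq[i]
  y0 <- cv$fsc[i - 1]; y1 <- cv$fsc[i]
  fstar <- f0 + (y0 - threshold) / (y0 - y1) * (f1 - f0)
  1 / fstar
}

#' Randomly perturb atom positions
#'
#' Displaces every atom by an independent uniform random vector of norm at
#' most `max_disp` (the overfitting cross-validation protocol uses 0.5 A).
#'
#' @param model an [atomic_model()].
#' @param max_disp maximum displacement in Angstrom.
#' @param seed RNG seed for reproducibility.
#' @return The perturbed [atomic_model()].
#' @export
perturb_model <- function(model, max_disp = 0.5, seed = 1) {
  if (max_disp < 0) abort("max_disp must be >= 0")
  n <- nrow(model)
  if (max_disp == 0) return(model)
  disp <- withr::with_seed(seed, {
    dirs <- matrix(rnorm(3 * n), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    r <- max_disp * runif(n)^(1 / 3)
    dirs * r
  })
  model$x <- model$x + disp[, 1]
  model$y <- model$y + disp[, 2]
  model$z <- model$z + disp[, 3]
  model
}

#' Half-map cross-validation FSC curves
#'
#' Computes FSC of a (perturbed-and-refined) test model's synthetic map
#' against each half map, and of the final model against the full map. A
#' large gap between the two half-map curves indicates overfitting into the
#' noise of one half.
#'
#' @param model_test the test model (e.g. from [perturb_model()]).
#' @param halfmap1,halfmap2,fullmap [density_map()]s on one grid.
#' @param blur_width Gaussian sigma for [model_to_map()].
#' @param model_final the final model; defaults to `model_test`.
#' @param mask optional mask applied to every FSC.
#' @return A `crossval_fsc` list: `fsc_half1`, `fsc_half2`, `fsc_full`,
#'   `gap` (max shell gap between the two half-map curves).
#' @export
crossval_fsc <- function(model_test, halfmap1, halfmap2, fullmap,
                         blur_width = 3.15, model_final = model_test,
                         mask = NULL) {
  if (!same_grid(halfmap1, halfmap2) || !same_grid(halfmap1, fullmap)) {
    abort("half maps and full map must share one grid")
  }
  map_test <- model_to_map(model_test, halfmap1, blur_width)
  map_final <- if (identical(model_final, model_test)) map_test else
    model_to_map(model_final, fullmap, blur_width)
  f1 <- fsc(map_test, halfmap1, mask)
  f2 <- fsc(map_test, halfmap2, mask)
  ff <- fsc(map_final, fullmap, mask)
  structure(
    list(fsc_half1 = f1, fsc_half2 = f2, fsc_full = ff,
         gap = max(abs(f1$fsc - f2$fsc))),
    class = "crossval_fsc"
  )
}

#' Per-residue Z-scored local map fit
#'
#' For every residue, a Manders-style overlap between the model-derived
#' density and the experimental density over the residue's voxel footprint
#' (voxels within `footprint_radius` of any residue atom), optionally
#' averaged over a sliding window of `window` residues along each chain.
#' Scores are then Z-scored against the mean and standard deviation pooled
#' over all residues, so a poorly fitting residue stands out as a low Z.
#'
#' @param model an [atomic_model()].
#' @param map experimental [density_map()].
#' @param blur_width Gaussian sigma for the model map.
#' @param window odd sliding-window length in residues (1 = no smoothing).
#' @param footprint_radius footprint radius in Angstrom.
#' @return Tibble: `chain`, `resid`, `score`, `score_windowed`, `z`, `flag`.
#'   Residues with empty footprints get `NA` scores, are excluded from
#'   pooling, and carry flag `"empty_footprint"`; a degenerate pooled sd is
#'   flagged `"degenerate_pooling"` on every row with z set to 0.
#' @export
local_fit_z <- function(model, map, blur_width = 3.15, window = 1,
                        footprint_radius = 2.5) {
  g <- as_grid_spec(map)
  mmap <- model_to_map(model, g, blur_width)
  ax <- lapply(1:3, function(d) g$origin[d] + (seq_len(g$dim[d]) - 1) * g$voxel_size[d])
  res_tbl <- dplyr::distinct(as_tibble(model[, c("chain", "resid")]))
  score <- rep(NA_real_, nrow(res_tbl))
  for (r in seq_len(nrow(res_tbl))) {
    sel <- model$chain == res_tbl$chain[r] & model$resid == res_tbl$resid[r]
    xyz <- model_xyz(model[sel, , drop = FALSE])
    foot <- array(FALSE, dim = g$dim)
    for (a in seq_len(nrow(xyz))) {
      rng <- lapply(1:3, function(d) which(abs(ax[[d]] - xyz[a, d]) <= footprint_radius))
      if (any(lengths(rng) == 0)) next
      dx2 <- outer(outer((ax[[1]][rng[[1]]] - xyz[a, 1])^2,
                         (ax[[2]][rng[[2]]] - xyz[a, 2])^2, "+"),
                   (ax[[3]][rng[[3]]] - xyz[a, 3])^2, "+")
      foot[rng[[1]], rng[[2]], rng[[3]]] <-
        foot[rng[[1]], rng[[2]], rng[[3]]] | (dx2 <= footprint_radius^2)
    }
    if (!any(foot)) next
    mv <- mmap$values[foot]
    ev <- map$values[foot]
    den <- sqrt(sum(mv^2) * sum(ev^2))
    score[r] <- if (den > 0) sum(mv * ev) / den else NA_real_
  }
  res_tbl$score <- score
  # sliding window along residue order within each chain
  res_tbl <- res_tbl |>
    group_by(.data$chain) |>
    arrange(.data$resid, .by_group = TRUE) |>
    mutate(score_windowed = slide_mean(.data$score, window)) |>
    ungroup()
  pooled <- res_tbl$score_windowed[!is.na(res_tbl$score_windowed)]
  mu <- mean(pooled)
  sdev <- sd(pooled)
  degenerate <- !is.finite(sdev) || sdev < 1e-9
  res_tbl$z <- if (degenerate) {
    ifelse(is.na(res_tbl$score_windowed), NA_real_, 0)
  } else {
    (res_tbl$score_windowed - mu) / sdev
  }
  res_tbl$flag <- dplyr::case_when(
    is.na(res_tbl$score) ~ "empty_footprint",
    degenerate ~ "degenerate_pooling",
    TRUE ~ ""
  )
  res_tbl
}

slide_mean <- function(x, window) {
  if (window <= 1) return(x)
  half <- floor(window / 2)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    idx <- max(1, i - half):min(n, i + half)
    v <- x[idx]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
}

#' Windowed local amplitude scaling
#'
#' Simplified single-pass local amplitude scaling: the experimental map is
#' processed in overlapping cubic windows (side `window` Angstrom, stride
#' half a window, triangular blending); within each window the radial
#' Fourier amplitudes of the experimental map are rescaled to match those of
#' the reference (model-derived) map shell by shell. A zero-amplitude
#' reference shell falls back to scale 1.
#'
#' @param map_exp experimental [density_map()].
#' @param map_ref reference [density_map()] on the same grid.
#' @param window window side in Angstrom (must cover at least 2 voxels).
#' @return The locally scaled [density_map()].
#' @export
local_scale <- function(map_exp, map_ref, window = 30) {
  if (!same_grid(map_exp, map_ref)) abort("maps must share one grid")
  d <- dim(map_exp$values)
  w <- pmin(d, pmax(2L, as.integer(round(window / map_exp$voxel_size))))
  stride <- pmax(1L, w %/% 2L)
  starts <- lapply(1:3, function(k) {
    s <- unique(c(seq(1L, max(1L, d[k] - w[k] + 1L), by = stride[k]),
                  max(1L, d[k] - w[k] + 1L)))
    s
  })
  tri <- lapply(1:3, function(k) {
    x <- seq_len(w[k])
    pmax(1e-3, 1 - abs(x - (w[k] + 1) / 2) / ((w[k] + 1) / 2))
  })
  wt3 <- tri[[1]] %o% tri[[2]] %o% tri[[3]]
  acc <- array(0, dim = d)
  wacc <- array(0, dim = d)
  for (i in starts[[1]]) for (j in starts[[2]]) for (k in starts[[3]]) {
    ix <- i:(i + w[1] - 1); iy <- j:(j + w[2] - 1); iz <- k:(k + w[3] - 1)
    sub_e <- map_exp$values[ix, iy, iz, drop = FALSE]
    sub_r <- map_ref$values[ix, iy, iz, drop = FALSE]
    fe <- fft(sub_e)
    fr <- fft(sub_r)
    sh <- fsc_shells(w, map_exp$voxel_size)
    idx <- as.vector(sh$shell) + 1L
    amp_e <- sqrt(as.vector(tapply(as.vector(Mod(fe)^2), idx, sum)))
    amp_r <- sqrt(as.vector(tapply(as.vector(Mod(fr)^2), idx, sum)))
    scale <- ifelse(amp_e > 0, amp_r / amp_e, 1)
    scale[amp_r <= 0] <- 1
    shells_present <- sort(unique(idx))
    smap <- scale[match(idx, shells_present)]
    out <- Re(fft(fe * array(smap, dim = w), inverse = TRUE)) / prod(w)
    acc[ix, iy, iz] <- acc[ix, iy, iz] + out * wt3
    wacc[ix, iy, iz] <- wacc[ix, iy, iz] + wt3
  }
  density_map(acc / wacc, voxel_size = map_exp$voxel_size,
              origin = map_exp$origin)
}
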