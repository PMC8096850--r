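#' Tidy a WHAM result into its bin table
#'
#' @param x a `pmf_result` from [wham_solve()].
#' @param ... unused.
#' @return Tibble of bins: `q`, `A`, `P`, `N` (and `A_smooth` after
#'   [smooth_pmf()]).
#' @export
tidy.pmf_result <- function(x, ...) {
  as_tibble(x$bins)
}

#' One-row summary of a WHAM result
#'
#' @inheritParams tidy.pmf_result
#' @return Tibble: window/bin counts, bin width, temperature, iteration
#'   count, convergence flag, and the apparent barrier (max A over finite
#'   bins).
#' @export
glance.pmf_result <- function(x, ...) {
  A <- if ("A_smooth" %in% names(x$bins)) x$bins$A_smooth else x$bins$A
  tibble(
    n_windows = nrow(x$offsets),
    n_bins = nrow(x$bins),
    bin_width = x$bin_width,
    temperature = x$thermo$temperature,
    iterations = x$iterations,
    converged = x$converged,
    barrier = max(A[is.finite(A)]) - min(A[is.finite(A)])
  )
}

#' One-row summary of an FSC curve
#'
#' @param x an `fsc_curve` from [fsc()].
#' @param ... unused.
#' @return Tibble with the resolutions at the 0.143 and 0.5 thresholds
#'   (`NA` when the curve never crosses) and the shell count.
#' @export
glance.fsc_curve <- function(x, ...) {
  r143 <- resolution_at(x, 0.143)
  r05 <- resolution_at(x, 0.5)
  tibble(
    resolution_fsc0143 = as.numeric(r143),
    resolution_fsc05 = as.numeric(r05),
    n_shells = nrow(x)
  )
}

#' One-row summary of a pore profile
#'
#' @param x a `pore_profile` from [pore_profile()].
#' @param ... unused.
#' @return Tibble: plane count, z range, minimum radius and its position.
#' @export
glance.pore_profile <- function(x, ...) {
  i <- which.min(x$radius)
  tibble(
    n_planes = nrow(x),
    z_min = min(x$z), z_max = max(x$z),
    min_radius = x$radius[i],
    min_radius_z = x$z[i]
  )
}
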