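#' Plot a pore radius profile
#'
#' Radius against axial position, with dashed reference lines at the
#' hydrated radii of the tabulated ions.
#'
#' @param object a `pore_profile`.
#' @param ions an [ion_radii()]-style tibble (or `NULL` to omit the lines).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.pore_profile <- function(object, ions = ion_radii(), ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$z, y = .data$radius)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "axial position z (Å)",
                  y = "pore radius (Å)")
  if (!is.null(ions)) {
    p <- p + ggplot2::geom_hline(
      data = ions,
      ggplot2::aes(yintercept = .data$hydrated_radius),
      linetype = "dashed", colour = "grey40") +
      ggplot2::geom_text(
        data = ions,
        ggplot2::aes(x = -Inf, y = .data$hydrated_radius, label = .data$ion),
        hjust = -0.2, vjust = -0.4, size = 3, colour = "grey30")
  }
  p
}

#' Plot a potential of mean force
#'
#' Binned PMF (points) with the quadratic-smoothed curve when present.
#'
#' @param object a `pmf_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.pmf_result <- function(object, ...) {
  bins <- object$bins[is.finite(object$bins$A), , drop = FALSE]
  p <- ggplot2::ggplot(bins, ggplot2::aes(x = .data$q, y = .data$A)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::labs(x = "reaction coordinate q (Å)",
                  y = "A(q) (kcal/mol)")
  if ("A_smooth" %in% names(bins)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$A_smooth),
                                colour = "firebrick")
  }
  p
}

#' Plot an FSC curve
#'
#' Correlation against spatial frequency with the conventional 0.143 and
#' 0.5 thresholds marked.
#'
#' @param object an `fsc_curve`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.fsc_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object[object$freq > 0, ]),
                  ggplot2::aes(x = .data$freq, y = .data$fsc)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(0.143, 0.5), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "spatial frequency (1/Å)", y = "FSC")
}

#' Plot a set of local dense points
#'
#' Projection of the LDPs onto a coordinate plane, sized by cluster
#' membership and coloured by density.
#'
#' @param object an `ldp_set`.
#' @param plane which projection to draw.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ldp_set <- function(object, plane = c("xy", "xz", "yz"), ...) {
  plane <- match.arg(plane)
  ax <- strsplit(plane, "")[[1]]
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]],
                               size = .data$members,
                               colour = .data$density_at_point)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::labs(x = paste0(ax[1], " (Å)"), y = paste0(ax[2], " (Å)"),
                  colour = "density", size = "members")
}
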