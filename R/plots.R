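#' Plot a PMF profile
#'
#' Free energy against the pore coordinate, with a ribbon for the per-point
#' standard error when present.
#'
#' @param object A [pmf_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pmf_profile <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$xi, y = .data$G))
  if ("se" %in% names(object)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$G - .data$se, ymax = .data$G + .data$se),
      fill = "grey80"
    )
  }
  p + ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = expression(xi[p]), y = "G [kJ/mol]") +
    ggplot2::theme_minimal()
}

#' Plot fitted pore energetics
#'
#' The analysed PMF with the linear-regime fit (dashed), the nucleation
#' point, and any metastable minima marked.
#'
#' @param object A [fit_pore_energetics()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pore_energetics <- function(object, ...) {
  pmf <- object$pmf
  R0 <- pmf_R0(pmf)
  fit <- object$fit
  fitline <- tibble(
    xi = seq(object$fit_range[1], object$fit_range[2], length.out = 20)
  )
  fitline$G <- fit$intercept + fit$slope_kj_mol_nm * fitline$xi * R0
  p <- autoplot.pmf_profile(pmf) +
    ggplot2::geom_line(data = fitline, linetype = "dashed", colour = "black") +
    ggplot2::annotate("point", x = object$xi_nuc, y = object$dG_nuc,
                      shape = 21, fill = "white", size = 2)
  if (nrow(object$metastable) > 0) {
    ys <- approx(pmf$xi, pmf$G, xout = object$metastable$xi_min)$y
    p <- p + ggplot2::annotate("point", x = object$metastable$xi_min, y = ys,
                               shape = 25, fill = "red", size = 2)
  }
  p
}

#' Plot a cylindrical density map
#'
#' Raster of the per-species density (or bulk-relative ratio) over (r, z),
#' faceted by species.
#'
#' @param object A [density_map()] or [relative_density()] map.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.density_map <- function(object, ...) {
  fill <- if ("ratio" %in% names(object)) "ratio" else "density"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r_mid, y = .data$z_mid,
                                       fill = .data[[fill]])) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~species) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "r [nm]", y = "z [nm]", fill = fill) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.density_map
#' @export
autoplot.relative_density_map <- autoplot.density_map

#' Plot radial sorting profiles
#'
#' @param object A [radial_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.radial_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r_mid, y = .data$ratio,
                                       colour = .data$species)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r [nm]", y = "density / bulk", colour = "species") +
    ggplot2::theme_minimal()
}
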