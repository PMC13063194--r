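# ggplot2 conveniences for the main result types. Plots are presentation
# aids; no analysis depends on them.

#' Plot a per-residue interaction panel
#'
#' Horizontal bars of per-residue interaction energies, filled by ligand
#' region tag when available.
#'
#' @param panel Tibble from [bird_panel()] or [decompose_site()].
#' @return A ggplot object.
#' @export
plot_bird_panel <- function(panel) {
  panel <- mutate(panel,
    residue = factor(
      paste0(.data$resid, .data$resno),
      levels = rev(paste0(.data$resid, .data$resno))
    )
  )
  p <- ggplot2::ggplot(panel, ggplot2::aes(
    x = .data$energy, y = .data$residue
  ))
  if ("region_tag" %in% names(panel) && !all(is.na(panel$region_tag))) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$region_tag))
  } else {
    p <- p + ggplot2::geom_col()
  }
  p +
    ggplot2::labs(
      x = "interaction energy (kcal/mol)", y = NULL,
      fill = "ligand region"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a radius-convergence profile
#'
#' @param profile Tibble from [radius_profile()].
#' @return A ggplot object.
#' @export
plot_radius_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(
    x = .data$radius, y = .data$cumulative_energy
  )) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "binding-site radius (Å)",
      y = "cumulative interaction energy (kcal/mol)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an RMSD time series
#'
#' @param series Tibble from [rmsd_series()].
#' @return A ggplot object.
#' @export
plot_rmsd <- function(series) {
  ggplot2::ggplot(series, ggplot2::aes(x = .data$time_ns, y = .data$rmsd)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ns)", y = "RMSD (Å)") +
    ggplot2::theme_minimal()
}

#' Plot a per-residue RMSF profile
#'
#' @param profile Tibble from [rmsf()].
#' @return A ggplot object.
#' @export
plot_rmsf <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$resno, y = .data$rmsf)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = "RMSF (Å)") +
    ggplot2::theme_minimal()
}

#' Plot a clustered embedding
#'
#' @param object An `"ensemble_fit"` object.
#' @param ... Unused.
#' @return A ggplot object showing the embedding coloured by cluster.
#' @export
autoplot.ensemble_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(
    x = .data$dim1, y = .data$dim2,
    colour = factor(.data$cluster)
  )) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(colour = "cluster", x = "dim 1", y = "dim 2") +
    ggplot2::theme_minimal()
}
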