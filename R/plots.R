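# Figures for the dispersion analysis. All plots return ggplot objects
# so callers can restyle them.

#' Distribution of per-session dispersion by strain
#'
#' Histograms of the per-rat-session dispersion values, one facet per
#' trait, filled by strain — the usual first look at how strongly the
#' dispersion distributions separate (they are typically right-skewed,
#' which is why the inference works on ranks and logs).
#'
#' @param pd_tbl Dispersion table from [dispersion_table()].
#' @param bins Number of histogram bins (default 30).
#' @return A ggplot object.
#' @export
plot_pd_distribution <- function(pd_tbl, bins = 30) {
  ggplot2::ggplot(pd_tbl, ggplot2::aes(x = .data$pd, fill = .data$strain)) +
    ggplot2::geom_histogram(bins = bins, position = "identity", alpha = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$trait), scales = "free") +
    ggplot2::labs(x = "phenotypic dispersion (per rat-session)",
                  y = "rat-sessions", fill = "strain")
}

#' @describeIn compare_strains Log-scale strain means with 95% CIs,
#'   one panel per trait.
#' @param object A `strain_comparison` object.
#' @export
autoplot.strain_comparison <- function(object, ...) {
  means <- object$table |>
    dplyr::select("trait", "means") |>
    tidyr::unnest("means")
  ggplot2::ggplot(means, ggplot2::aes(x = .data$strain, y = .data$mean_log,
                                      color = .data$strain)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_log - .data$ci95_halfwidth,
      ymax = .data$mean_log + .data$ci95_halfwidth
    )) +
    ggplot2::facet_wrap(ggplot2::vars(.data$trait), scales = "free_y") +
    ggplot2::labs(y = sprintf("mean log(PD + %g) with 95%% CI",
                              object$settings$log_offset),
                  x = NULL) +
    ggplot2::guides(color = "none")
}

#' @describeIn within_sessions_model Per-strain linear slope estimates
#'   with approximate 95% intervals (beta +/- 1.96 SE).
#' @param object A `trend_fit` object.
#' @export
autoplot.trend_fit <- function(object, ...) {
  ggplot2::ggplot(object$slopes,
                  ggplot2::aes(x = .data$strain, y = .data$beta)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$beta - 1.96 * .data$se,
      ymax = .data$beta + 1.96 * .data$se
    )) +
    ggplot2::labs(
      title = sprintf("%s: %s trend", object$trait,
                      gsub("_", " ", object$scope)),
      y = sprintf("slope per unit index (%s scale)", object$slope_scale),
      x = NULL
    )
}
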