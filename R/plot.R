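#' Plot depth profiles of a profile set
#'
#' Depth-profile panels (depth increasing downward, one facet per
#' analyte) in the conventional orientation of sediment geochemistry
#' figures.
#'
#' @param ps A [profile_set()].
#' @param analytes Optional character vector to subset.
#' @return A ggplot object.
#' @export
plot_profiles <- function(ps, analytes = NULL) {
  df <- as_tibble(ps)
  if (!is.null(analytes)) df <- dplyr::filter(df, .data$analyte %in% analytes)
  df <- dplyr::mutate(df,
                      panel = paste0(.data$analyte, " [", .data$unit, "]"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$depth)) +
    ggplot2::geom_path(na.rm = TRUE) +
    ggplot2::geom_point(size = 1, na.rm = TRUE) +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~panel, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "depth (cmbsf)") +
    ggplot2::theme_bw()
}

#' Plot modelled concentration and rate profiles
#'
#' @param object A `seep_model_state`.
#' @param what `"rates"` (default) or `"concentrations"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.seep_model_state <- function(object, what = c("rates",
                                                       "concentrations"),
                                      ...) {
  what <- match.arg(what)
  if (what == "rates") {
    df <- rate_profiles(object)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$rate, y = .data$z)) +
      ggplot2::geom_path() +
      ggplot2::scale_y_reverse() +
      ggplot2::facet_wrap(~reaction, scales = "free_x") +
      ggplot2::labs(x = "rate (umol cm^-3 bulk yr^-1)",
                    y = "depth (cmbsf)") +
      ggplot2::theme_bw()
  } else {
    df <- conc_profiles(object)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$conc, y = .data$z)) +
      ggplot2::geom_path() +
      ggplot2::scale_y_reverse() +
      ggplot2::facet_wrap(~species, scales = "free_x") +
      ggplot2::labs(x = "concentration (umol cm^-3 own phase)",
                    y = "depth (cmbsf)") +
      ggplot2::theme_bw()
  }
}

#' Heat-map of a Spearman correlation matrix
#'
#' @param object A `seep_corr_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.seep_corr_matrix <- function(object, ...) {
  vars <- rownames(object$rho)
  df <- tidyr::expand_grid(var1 = vars, var2 = vars) |>
    dplyr::mutate(rho = as.vector(object$rho),
                  tier = as.vector(object$tier))
  ggplot2::ggplot(df, ggplot2::aes(.data$var1, .data$var2,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$tier), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166ac",
                                  mid = "white", high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
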