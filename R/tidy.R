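#' Tidy methods for seepaom result objects
#'
#' broom-style accessors: `tidy()` returns a long tibble of the object's
#' primary quantities, `glance()` a one-row summary.
#'
#' @param x A seepaom result object.
#' @param ... Unused.
#' @return A tibble.
#' @name seepaom-tidiers
NULL

#' @rdname seepaom-tidiers
#' @export
tidy.seep_model_state <- function(x, ...) {
  dplyr::bind_rows(
    conc_profiles(x) |>
      dplyr::transmute(quantity = "concentration", name = .data$species,
                       z = .data$z, value = .data$conc),
    rate_profiles(x) |>
      dplyr::transmute(quantity = "rate", name = .data$reaction,
                       z = .data$z, value = .data$rate))
}

#' @rdname seepaom-tidiers
#' @export
glance.seep_model_state <- function(x, ...) {
  tibble::tibble(
    n_nodes = length(x$z),
    core_length = max(x$z),
    converged = x$diagnostics$converged,
    pseudo_time = x$diagnostics$pseudo_time,
    max_residual = max(x$diagnostics$residuals),
    max_misclosure = max(x$mass_balance$relative_misclosure))
}

#' @rdname seepaom-tidiers
#' @export
tidy.seep_calibration <- function(x, ...) x$parameters

#' @rdname seepaom-tidiers
#' @export
glance.seep_calibration <- function(x, ...) {
  tibble::tibble(objective = x$objective,
                 n_starts = nrow(x$starts),
                 best_start = which.min(x$starts$objective),
                 n_analytes = nrow(x$residuals))
}

#' @rdname seepaom-tidiers
#' @export
tidy.seep_corr_matrix <- function(x, ...) x$pairs

#' @rdname seepaom-tidiers
#' @export
tidy.seep_budget <- function(x, ...) x$partition

#' @rdname seepaom-tidiers
#' @export
glance.seep_budget <- function(x, ...) {
  p <- x$partition
  tibble::tibble(
    total = sum(p$rate, na.rm = TRUE),
    saom = p$rate[p$pathway == "S-AOM"],
    feaom = p$rate[p$pathway == "Fe-AOM"],
    mnaom = p$rate[p$pathway == "Mn-AOM"],
    metal_fraction_pct = sum(p$fraction_raw[p$pathway != "S-AOM"],
                             na.rm = TRUE),
    minimum_estimate = x$minimum_estimate)
}

#' @rdname seepaom-tidiers
#' @export
tidy.seep_zones <- function(x, ...) x$zones

#' @rdname seepaom-tidiers
#' @export
tidy.seep_sensitivity <- function(x, ...) x$profiles

#' @rdname seepaom-tidiers
#' @export
tidy.seep_flux_estimate <- function(x, ...) tibble::as_tibble(unclass(x))
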