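#' Free-solution diffusion coefficients in seawater
#'
#' Tabulated infinite-dilution diffusion coefficients at seawater salinity
#' (~35 PSU), 10^-6 cm^2 s^-1, at 0 and 25 degC, following the standard
#' linear-in-temperature tabulations used in early-diagenesis modelling.
#' Intermediate temperatures are obtained by linear interpolation.
#'
#' @return Tibble with columns `species`, `D0_0C`, `D0_25C`
#'   (10^-6 cm^2 s^-1).
#' @export
diffusion_table <- function() {
  tibble::tribble(
    ~species, ~D0_0C, ~D0_25C,
    "SO4",    4.88,   10.68,
    "CH4",    8.50,   18.40,
    "DIC",    5.06,   11.94,  # as HCO3-
    "HCO3",   5.06,   11.94,
    "Ca",     3.60,    8.08,
    "Mg",     3.43,    7.03,
    "Fe2",    3.31,    7.06,
    "Mn2",    3.18,    7.06
  )
}

SECONDS_PER_YEAR <- 3.1536e7

#' Free-solution diffusion coefficient of a porewater solute
#'
#' Linear-in-temperature interpolation of the shipped seawater diffusivity
#' table ([diffusion_table()]); deterministic. The salinity argument is
#' accepted for interface completeness: the table is tabulated at ~35 PSU
#' and no further salinity correction is applied.
#'
#' @param species One of the registry species (`SO4`, `CH4`, `DIC`/`HCO3`,
#'   `Ca`, `Mg`, `Fe2`, `Mn2`).
#' @param temperature Temperature, degC, in 0-30.
#' @param salinity Salinity, PSU (unused beyond validation).
#' @return D0 in cm^2 yr^-1.
#' @export
#' @examples
#' diffusion_coefficient("SO4", 3.5)
diffusion_coefficient <- function(species, temperature, salinity = 35) {
  tab <- diffusion_table()
  i <- match(species, tab$species)
  if (is.na(i)) {
    stop("unknown species '", species, "'; known: ",
         paste(tab$species, collapse = ", "), call. = FALSE)
  }
  if (temperature < 0 || temperature > 30) {
    stop("temperature ", temperature, " degC outside supported 0-30 range",
         call. = FALSE)
  }
  d6 <- tab$D0_0C[i] + (tab$D0_25C[i] - tab$D0_0C[i]) * temperature / 25
  d6 * 1e-6 * SECONDS_PER_YEAR
}

#' Tortuosity correction of a diffusion coefficient
#'
#' Default is the Boudreau relation `Ds = D0 / (1 - ln(phi^2))`; the
#' Archie power law `Ds = D0 * phi^(m - 1)` is available as an
#' alternative.
#'
#' @param D0 Free-solution diffusion coefficient (any unit).
#' @param phi Porosity, strictly in (0, 1).
#' @param model `"boudreau"` (default) or `"archie"`.
#' @param m Archie exponent (used only for `model = "archie"`).
#' @return Ds in the unit of `D0`.
#' @export
#' @examples
#' tortuosity_correct(100, 0.7)  # 100 / (1 - 2*log(0.7))
tortuosity_correct <- function(D0, phi, model = c("boudreau", "archie"),
                               m = 2) {
  model <- match.arg(model)
  if (any(phi <= 0) || any(phi >= 1)) {
    stop("porosity must be strictly within (0, 1), got ",
         paste(phi[phi <= 0 | phi >= 1], collapse = ", "), call. = FALSE)
  }
  switch(model,
         boudreau = D0 / (1 - log(phi^2)),
         archie = D0 * phi^(m - 1))
}

#' Diffusive flux from a porewater gradient (Fick's first law)
#'
#' Estimates the concentration gradient by ordinary least squares over all
#' samples inside a depth window and returns the diffusive flux
#' `J = phi * Ds * |dC/dz|` with an explicit direction: `"upward"` when
#' concentration increases downward (the solute diffuses toward the
#' seafloor), `"downward"` otherwise. OLS over the window is used rather
#' than a two-point difference so the estimate is robust to sampling
#' resolution on a quasilinear gradient.
#'
#' @param series A [depth_series()] of a dissolved analyte.
#' @param window Numeric length-2, depth window (z1, z2) in cm.
#' @param Ds Tortuosity-corrected diffusion coefficient, cm^2 yr^-1.
#' @param phi Window-mean porosity (0-1).
#' @param minimum_estimate Flag carried into the result (set when sinks
#'   such as authigenic mineral precipitation are ignored, making the flux
#'   a lower bound on production).
#' @return A one-row tibble of class `seep_flux_estimate` with columns
#'   `J` (umol cm-2 yr-1, magnitude), `direction`, `z1`, `z2`,
#'   `gradient` (umol cm-4), `r_squared`, `n`, `minimum_estimate`.
#' @export
#' @examples
#' s <- depth_series(c(250, 350), c(0, 1000), "Mn2")  # uM
#' fick_flux(s, c(250, 350), Ds = 100, phi = 0.7)
fick_flux <- function(series, window, Ds, phi, minimum_estimate = FALSE) {
  stopifnot(inherits(series, "seep_depth_series"), length(window) == 2)
  window <- sort(window)
  keep <- series$depth >= window[1] & series$depth <= window[2] &
    !is.na(series$value)
  z <- series$depth[keep]
  c_raw <- series$value[keep]
  if (length(z) < 2) {
    stop("fewer than 2 samples inside window [", window[1], ", ",
         window[2], "] cm", call. = FALSE)
  }
  if (stats::var(z) == 0) stop("zero variance in depth", call. = FALSE)
  conc <- to_umol_cm3(c_raw, attr(series, "unit"))
  fit <- stats::lm(conc ~ z)
  slope <- unname(stats::coef(fit)[2])
  ss_tot <- sum((conc - mean(conc))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  out <- tibble::tibble(
    analyte = attr(series, "analyte"),
    J = phi * Ds * abs(slope),
    direction = if (slope > 0) "upward" else "downward",
    z1 = window[1], z2 = window[2],
    gradient = slope,
    r_squared = r2,
    n = length(z),
    minimum_estimate = minimum_estimate
  )
  class(out) <- c("seep_flux_estimate", class(out))
  out
}
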