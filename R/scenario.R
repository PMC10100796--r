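#' Construct a reaction-transport scenario
#'
#' A scenario bundles everything the steady-state solver needs: the depth
#' grid, the site (porosity/burial model, temperature), per-species
#' transport (free-solution diffusivity, tortuosity model, bubble
#' irrigation), the reaction-rate parameters, boundary conditions, and
#' solver controls.
#'
#' Boundary conditions: dissolved species have a fixed (Dirichlet)
#' concentration at the sediment-water interface and either a zero-gradient
#' or a fixed-value bottom condition; solid species receive a depositional
#' flux at the top and leave by burial at the bottom.
#'
#' @param core_length Core length, cm.
#' @param dz Grid spacing, cm (uniform vertex-centred grid from 0 to
#'   `core_length`).
#' @param site A [site_metadata()] object.
#' @param params Named list of reaction-rate parameters; see
#'   [reference_scenario()] for the full set.
#' @param top_bc Named numeric, fixed top concentrations of the dissolved
#'   species, umol cm^-3 (= mM).
#' @param bottom_bc Named list per dissolved species: either
#'   `list(kind = "zero_gradient")` or `list(kind = "fixed", value = v)`.
#' @param solid_flux Named numeric, depositional fluxes of the solid
#'   species at the seafloor, umol cm^-2 yr^-1.
#' @param alpha Bubble-irrigation exchange constant, yr^-1 (applied to all
#'   dissolved species over 0 to `L_irr`, zero below).
#' @param L_irr Irrigation depth, cm.
#' @param tortuosity `"boudreau"` or `"archie"`.
#' @param solver List of solver controls: `tol_rel` (steady-state
#'   residual, fraction of each species' scale per year), `t_max` (pseudo-
#'   time budget, yr), `atol`/`rtol` (integrator tolerances).
#' @return A list of class `seep_scenario`.
#' @export
scenario <- function(core_length = 430, dz = 1,
                     site = site_metadata(),
                     params = list(),
                     top_bc = c(SO4 = 28.5, CH4 = 0, DIC = 2.3,
                                Ca = 10.3, Mg = 53, Fe2 = 0),
                     bottom_bc = NULL,
                     solid_flux = c(FeOx = 2.4, FeCarb = 0),
                     alpha = 1, L_irr = 250,
                     tortuosity = "boudreau",
                     solver = list()) {
  stopifnot(core_length > 0, dz > 0)
  spp <- model_species()
  diss <- spp$species[spp$phase == "dissolved"]
  sol <- spp$species[spp$phase == "solid"]
  if (!all(diss %in% names(top_bc))) {
    stop("top_bc must name every dissolved species: ",
         paste(setdiff(diss, names(top_bc)), collapse = ", "), call. = FALSE)
  }
  if (!all(sol %in% names(solid_flux))) {
    stop("solid_flux must name every solid species", call. = FALSE)
  }
  if (is.null(bottom_bc)) {
    bottom_bc <- stats::setNames(
      rep(list(list(kind = "zero_gradient")), length(diss)), diss)
  }
  for (sp in diss) {
    bc <- bottom_bc[[sp]]
    if (is.null(bc) || !bc$kind %in% c("zero_gradient", "fixed")) {
      stop("bottom_bc for ", sp,
           " must be 'zero_gradient' or 'fixed'", call. = FALSE)
    }
  }
  defaults <- default_rate_params()
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) {
    stop("unknown rate parameters: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  params <- utils::modifyList(defaults, params)
  sctl <- utils::modifyList(
    list(tol_rel = 1e-5, t_max = 2e5, atol = 1e-8, rtol = 1e-6), solver)
  structure(
    list(core_length = core_length, dz = dz, site = site,
         params = params, top_bc = top_bc, bottom_bc = bottom_bc,
         solid_flux = solid_flux, alpha = alpha, L_irr = L_irr,
         tortuosity = tortuosity, solver = sctl),
    class = "seep_scenario")
}

#' Default reaction-rate parameters
#'
#' Units: rate constants of bimolecular laws in (umol cm^-3)^-1 yr^-1 on
#' their stated phase basis; `k_mb`, `k_poc` in yr^-1; concentrations and
#' thresholds in umol cm^-3; depths in cm.
#'
#' @return Named list.
#' @export
default_rate_params <- function() {
  list(
    k_saom = 0.5,         # (umol cm^-3 pw)^-1 yr^-1
    k_feaom = 2.2e-4,     # (umol cm^-3 dry)^-1 yr^-1
    K_inhib_so4 = 0.1,    # umol cm^-3; sulfate inhibition of Fe-AOM
    K_act_ch4 = 0,        # umol cm^-3; methane activation of Fe-AOM (off)
    hill_feaom = 2,       # Hill exponent of the Fe-AOM switches
    k_mb = 0.0025,        # yr^-1
    ch4_sat = 70,         # umol cm^-3 (~saturation at 1375 m, 3.5 degC)
    gas_zone = c(210, 430),
    k_poc = 0.001,        # yr^-1
    poc_0 = 250,          # umol C cm^-3 dry at surface
    z_poc = 150,          # cm
    K_so4 = 0.5,          # umol cm^-3
    k_camg = 4e-5,        # (umol cm^-3 pw)^-1 yr^-1
    k_fecarb = 0.09,      # (umol cm^-3 pw)^-1 yr^-1
    dic_threshold = 8     # umol cm^-3
  )
}

#' Reference scenario for a bubble-irrigated cold-seep core
#'
#' The shipped scenario used throughout the package: a 430-cm core with
#' the default site, irrigation restricted to the sulfate-replete upper
#' 130 cm, a free-gas zone below 210 cm feeding methane by bubble
#' dissolution, and rate constants that reproduce the synthetic profile
#' preset when solved to steady state. All parameters can be overridden.
#'
#' @param dz Grid spacing, cm.
#' @param ... Overrides passed to [scenario()] (e.g. `params`, `alpha`).
#' @return A `seep_scenario`.
#' @export
reference_scenario <- function(dz = 1, ...) {
  args <- list(...)
  base <- list(
    core_length = 430, dz = dz,
    site = site_metadata(core_id = "SYN-HM-S11"),
    alpha = 1, L_irr = 130,
    solid_flux = c(FeOx = 2.7, FeCarb = 0),
    params = list(k_saom = 0.5, k_feaom = 2.2e-4, K_inhib_so4 = 0.1,
                  k_mb = 0.0025, k_fecarb = 0.09, k_camg = 4e-5,
                  dic_threshold = 8)
  )
  if (!is.null(args$params)) {
    base$params <- utils::modifyList(base$params, args$params)
    args$params <- NULL
  }
  do.call(scenario, utils::modifyList(base, args))
}

#' @export
print.seep_scenario <- function(x, ...) {
  cat(sprintf(paste0("<scenario> %g cm core, dz = %g cm, alpha = %g yr-1 ",
                     "over 0-%g cm\n"),
              x$core_length, x$dz, x$alpha, x$L_irr))
  cat("rate parameters:\n")
  for (nm in names(x$params)) {
    cat(sprintf("  %-13s %s\n", nm,
                paste(signif(x$params[[nm]], 4), collapse = "-")))
  }
  invisible(x)
}

#' Read / write a scenario as YAML
#'
#' Serialises every scenario field (site, boundary conditions, rate
#' parameters, solver controls) to a structured YAML file and back;
#' round-trips unchanged.
#'
#' @param x A `seep_scenario`.
#' @param path File path.
#' @return `write_scenario` returns `path` invisibly; `read_scenario`
#'   returns a `seep_scenario`.
#' @export
write_scenario <- function(x, path) {
  stopifnot(inherits(x, "seep_scenario"))
  obj <- list(
    core_length = x$core_length, dz = x$dz,
    site = unclass(x$site),
    params = x$params,
    top_bc = as.list(x$top_bc),
    bottom_bc = x$bottom_bc,
    solid_flux = as.list(x$solid_flux),
    alpha = x$alpha, L_irr = x$L_irr,
    tortuosity = x$tortuosity, solver = x$solver)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  obj <- yaml::read_yaml(path)
  site <- do.call(site_metadata, obj$site)
  obj$params$gas_zone <- as.numeric(obj$params$gas_zone)
  scenario(core_length = obj$core_length, dz = obj$dz, site = site,
           params = obj$params, top_bc = unlist(obj$top_bc),
           bottom_bc = obj$bottom_bc,
           solid_flux = unlist(obj$solid_flux),
           alpha = obj$alpha, L_irr = obj$L_irr,
           tortuosity = obj$tortuosity, solver = obj$solver)
}
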