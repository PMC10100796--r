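# evaluate a parametric curve at depths z
eval_curve <- function(cv, z) {
  switch(cv$shape,
    linear = stats::approx(cv$anchors$depth, cv$anchors$value, xout = z,
                           rule = 2, ties = "ordered")$y,
    gauss = cv$peak * exp(-((z - cv$center) / cv$width)^2),
    logistic = cv$base + (cv$max - cv$base) /
      (1 + exp(-(z - cv$mid) / cv$scale)),
    const = rep(cv$value, length(z)),
    stop("unknown curve shape '", cv$shape, "'", call. = FALSE))
}

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Anchor specification for synthetic seep profiles
#'
#' Defines, per analyte, a parametric depth curve (piecewise-linear ramp,
#' logistic, Gaussian peak or constant) pinned to anchor points, plus a
#' noise model (relative or absolute Gaussian sigma) and the sampling
#' depths. With the default preset and sigma = 0 the curves pass exactly
#' through the concentration anchors of a deep-water seep core: e.g.
#' dissolved Fe2+ peaking at 148 uM at 370 cmbsf, Mn2+ at 2289 uM at
#' 340 cmbsf, CH4 falling from 781 uM at 210 cmbsf to 53 uM at 330 cmbsf,
#' and DIC rising from 10.38 mM at 250 cmbsf to 17.27 mM at 330 cmbsf.
#'
#' @param curves Named list of curve definitions; defaults to
#'   [default_anchor_curves()].
#' @param noise Named list of noise definitions
#'   (`list(sigma =, type = "rel"|"abs")`); partial overrides are merged
#'   into the defaults.
#' @param sampling_depths Depths at which to sample, cm; the default
#'   follows a 20-cm interval over the top 60 cm and 40-cm intervals
#'   below, augmented with the depths at which the anchor values are
#'   defined.
#' @param core_length Core length, cm.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list of class `seep_anchor_spec`.
#' @export
anchor_spec <- function(curves = default_anchor_curves(),
                        noise = list(),
                        sampling_depths = default_sampling_depths(),
                        core_length = 430,
                        seed = 1L) {
  for (nm in names(curves)) {
    cv <- curves[[nm]]
    ad <- switch(cv$shape,
                 linear = cv$anchors$depth,
                 gauss = cv$center,
                 logistic = cv$mid,
                 const = numeric(0))
    if (any(ad < 0 | ad > core_length)) {
      stop("anchor depth outside core [0, ", core_length, "] for '",
           nm, "'", call. = FALSE)
    }
  }
  nz <- utils::modifyList(default_noise(), noise)
  for (nm in names(nz)) {
    if (nz[[nm]]$sigma < 0) stop("negative noise sigma for ", nm,
                                 call. = FALSE)
  }
  structure(list(curves = curves, noise = nz,
                 sampling_depths = sort(unique(sampling_depths)),
                 core_length = core_length, seed = as.integer(seed)),
            class = "seep_anchor_spec")
}

#' @rdname anchor_spec
#' @export
default_sampling_depths <- function() {
  sort(unique(c(0, 10, 30, 50, seq(90, 410, by = 40), 230, 340, 430)))
}

#' Default anchor curves of the synthetic seep preset
#'
#' Porewater: near-seawater sulfate (28.5 mM) held to 130 cmbsf then
#' declining quasilinearly to depletion at ~230 cmbsf; methane low above
#' the SMTZ, 781 uM at 210 cmbsf, a 53 uM trough at 330 cmbsf and a
#' 919.57 uM maximum at depth; DIC and alkalinity ramping up through the
#' methanic zone (10.38 -> 17.27 mM and 16.01 -> 28.94 mM); Gaussian
#' Fe2+ (148 uM at 370 cmbsf, width 60 cm) and Mn2+ (2289 uM at
#' 340 cmbsf, width 80 cm) peaks; modest nutrient (PO4 <= 41.65 uM,
#' NH4 <= 56.72 uM) logistics; isotope ramps (d13C-CH4 -68.77 to
#' -64.33 permil; d13C-DIC below -42.3 permil in the methanic zone).
#' Solid phase: total Fe/Mn oxides and sequentially extracted iron pools
#' slightly enriched in the methanic zone. Peak widths and the shapes
#' between anchors are interpolation choices.
#'
#' @return Named list of curve definitions.
#' @export
default_anchor_curves <- function() {
  lin <- function(...) {
    a <- matrix(c(...), ncol = 2, byrow = TRUE)
    list(shape = "linear",
         anchors = tibble::tibble(depth = a[, 1], value = a[, 2]))
  }
  list(
    SO4 = lin(0, 28.5, 130, 28.5, 230, 0.1, 430, 0.1),
    CH4 = lin(0, 0.13, 130, 3, 170, 15.74, 210, 781, 250, 500,
              330, 53, 410, 919.57, 430, 919.57),
    DIC = lin(0, 2.3, 130, 4.5, 210, 8.5, 250, 10.38, 330, 17.27,
              430, 17.27),
    TA = lin(0, 2.5, 130, 5, 230, 16.01, 430, 28.94),
    Ca = lin(0, 10.3, 230, 8.5, 430, 6.0),
    Mg = lin(0, 53, 230, 50, 430, 46),
    Fe2 = list(shape = "gauss", peak = 148, center = 370, width = 60),
    Mn2 = list(shape = "gauss", peak = 2289, center = 340, width = 80),
    PO4 = list(shape = "logistic", base = 1, max = 41.65, mid = 220,
               scale = 50),
    NH4 = list(shape = "logistic", base = 2, max = 56.72, mid = 220,
               scale = 50),
    d13C_CH4 = lin(0, -68.77, 210, -68.77, 330, -64.33, 430, -64.33),
    d13C_DIC = lin(0, -22, 130, -32, 230, -43, 300, -52, 430, -46),
    Fe2O3T = lin(0, 3.0, 130, 2.31, 210, 3.60, 240, 3.17, 370, 3.74,
                 430, 3.4),
    MnO2T = list(shape = "logistic", base = 0.04, max = 0.06, mid = 230,
                 scale = 15),
    Fe_carb = list(shape = "logistic", base = 0.10, max = 1.16, mid = 260,
                   scale = 40),
    Fe_ox1 = list(shape = "logistic", base = 0.30, max = 1.19, mid = 250,
                  scale = 50),
    Fe_mag = list(shape = "logistic", base = 0.10, max = 0.61, mid = 250,
                  scale = 50),
    Fe_py = list(shape = "const", value = 0.30)
  )
}

# analytical-error-style noise defaults; concentrations relative, isotope
# ratios absolute (permil)
default_noise <- function() {
  rel <- function(s) list(sigma = s, type = "rel")
  abs_ <- function(s) list(sigma = s, type = "abs")
  list(SO4 = rel(0.01), CH4 = rel(0.05), DIC = rel(0.02), TA = rel(0.02),
       Ca = rel(0.05), Mg = rel(0.05), Fe2 = rel(0.05), Mn2 = rel(0.05),
       PO4 = rel(0.03), NH4 = rel(0.03),
       d13C_CH4 = abs_(0.5), d13C_DIC = abs_(0.2),
       Fe2O3T = rel(0.05), MnO2T = rel(0.05), Fe_carb = rel(0.05),
       Fe_ox1 = rel(0.05), Fe_mag = rel(0.05), Fe_py = rel(0.05))
}

#' Generate synthetic anchor-preset profiles
#'
#' Samples every curve of an [anchor_spec()] at the spec's sampling
#' depths and adds seeded Gaussian noise (relative or absolute per
#' analyte), truncating concentrations at zero. With `sigma_scale = 0`
#' the sampled values equal the parametric curves exactly, so every
#' printed anchor value is reproduced at its depth.
#'
#' @param spec An [anchor_spec()].
#' @param sigma_scale Multiplier on all noise sigmas (0 = noise-free).
#' @param metadata Site metadata for the returned set.
#' @return A [profile_set()].
#' @export
#' @examples
#' ps <- generate_anchor_profiles(anchor_spec(), sigma_scale = 0)
#' s <- ps$porewater$Fe2
#' s$value[s$depth == 370]  # 148
generate_anchor_profiles <- function(spec, sigma_scale = 1,
                                     metadata = NULL) {
  stopifnot(inherits(spec, "seep_anchor_spec"))
  if (is.null(metadata)) metadata <- site_metadata(core_id = "SYN-HM-S11")
  z <- spec$sampling_depths
  reg <- analyte_registry()
  with_seed(spec$seed, {
    porewater <- list(); solids <- list()
    for (nm in names(spec$curves)) {
      v <- eval_curve(spec$curves[[nm]], z)
      nz <- spec$noise[[nm]] %||% list(sigma = 0, type = "rel")
      sd_vec <- if (nz$type == "rel") abs(v) * nz$sigma * sigma_scale
                else rep(nz$sigma * sigma_scale, length(v))
      v <- v + stats::rnorm(length(v), 0, sd_vec)
      phase <- reg$phase[match(nm, reg$analyte)]
      if (is.na(phase)) phase <- "dissolved"
      if (phase != "isotope-ratio") v <- pmax(v, 0)
      s <- depth_series(z, v, nm)
      if (phase == "solid") solids[[nm]] <- s else porewater[[nm]] <- s
    }
    profile_set(metadata, porewater, solids)
  })
}

#' Sample a solved model as synthetic observations
#'
#' Forward-solves a scenario (or reuses a supplied solution), samples the
#' modelled dissolved species at the given depths and adds relative
#' Gaussian noise — the input for parameter-recovery experiments.
#'
#' @param scn A [scenario()].
#' @param sigma Named relative noise sigmas per species, or a single
#'   number applied to all dissolved species.
#' @param sampling_depths Depths, cm.
#' @param seed Integer seed.
#' @param ms Optional pre-computed `seep_model_state` for `scn`.
#' @return A [profile_set()] with the six dissolved species, in registry
#'   units.
#' @export
generate_from_model <- function(scn, sigma = 0.02,
                                sampling_depths = default_sampling_depths(),
                                seed = 1L, ms = NULL) {
  if (is.null(ms)) ms <- solve_steady_state(scn)
  spp <- model_species()
  diss <- spp$species[spp$phase == "dissolved"]
  if (length(sigma) == 1 && is.null(names(sigma))) {
    sigma <- stats::setNames(rep(sigma, length(diss)), diss)
  }
  reg <- analyte_registry()
  with_seed(seed, {
    porewater <- list()
    for (sp in diss) {
      v <- stats::approx(ms$z, ms$conc[, sp], xout = sampling_depths,
                         ties = "ordered")$y
      unit <- reg$unit[match(sp, reg$analyte)]
      v <- from_umol_cm3(v, unit)
      s <- sigma[[sp]] %||% 0
      v <- pmax(v + stats::rnorm(length(v), 0, abs(v) * s), 0)
      porewater[[sp]] <- depth_series(sampling_depths, v, sp)
    }
    profile_set(scn$site, porewater, list())
  })
}
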