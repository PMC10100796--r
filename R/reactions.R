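#' Species modelled by the reaction-transport model
#'
#' The model state comprises six dissolved species, carried in umol cm^-3
#' porewater (numerically equal to mM), and two solid iron phases, carried
#' in umol cm^-3 dry sediment: reactive Fe oxides (`FeOx`, as Fe) and Fe
#' carbonate (`FeCarb`, as Fe).
#'
#' @return Tibble with columns `species`, `phase`, `unit`.
#' @export
model_species <- function() {
  tibble::tribble(
    ~species, ~phase,      ~unit,
    "SO4",    "dissolved", "umol/cm3",
    "CH4",    "dissolved", "umol/cm3",
    "DIC",    "dissolved", "umol/cm3",
    "Ca",     "dissolved", "umol/cm3",
    "Mg",     "dissolved", "umol/cm3",
    "Fe2",    "dissolved", "umol/cm3",
    "FeOx",   "solid",     "umol/cm3",
    "FeCarb", "solid",     "umol/cm3"
  )
}

MODEL_DISS <- c("SO4", "CH4", "DIC", "Ca", "Mg", "Fe2")
MODEL_SOL <- c("FeOx", "FeCarb")

# Elemental composition used by the conservation check. Virtual species
# (HS, CaCO3, MgCO3, POC, CH4gas) close balances for products/reactants
# the model does not carry as state variables.
element_composition <- function() {
  rbind(
    SO4    = c(C = 0, S = 1, Fe = 0, CaMg = 0),
    CH4    = c(C = 1, S = 0, Fe = 0, CaMg = 0),
    DIC    = c(C = 1, S = 0, Fe = 0, CaMg = 0),
    Ca     = c(C = 0, S = 0, Fe = 0, CaMg = 1),
    Mg     = c(C = 0, S = 0, Fe = 0, CaMg = 1),
    Fe2    = c(C = 0, S = 0, Fe = 1, CaMg = 0),
    FeOx   = c(C = 0, S = 0, Fe = 1, CaMg = 0),
    FeCarb = c(C = 1, S = 0, Fe = 1, CaMg = 0),
    HS     = c(C = 0, S = 1, Fe = 0, CaMg = 0),
    CaCO3  = c(C = 1, S = 0, Fe = 0, CaMg = 1),
    MgCO3  = c(C = 1, S = 0, Fe = 0, CaMg = 1),
    POC    = c(C = 1, S = 0, Fe = 0, CaMg = 0),
    CH4gas = c(C = 1, S = 0, Fe = 0, CaMg = 0)
  )
}

#' Kinetic rate laws
#'
#' Elementary rate expressions of the seep diagenesis network. All
#' concentrations are in umol cm^-3 of their own phase (porewater for
#' dissolved, dry sediment for solids); the returned rates are per cm^3 of
#' that same phase per year — conversion to bulk-sediment rates (via the
#' porosity factors) happens in [net_rates()]. Negative inputs are
#' rejected; all laws are continuous and non-negative.
#'
#' @param ch4,so4,feox,fe2,ca,dic Concentrations, umol cm^-3 (own phase).
#' @param k Rate constant (see each law for units).
#' @name rate_laws
NULL

check_nonneg <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    if (any(vals[[nm]] < 0, na.rm = TRUE)) {
      stop("negative concentration for ", nm, call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @rdname rate_laws
#' @details `saom_rate`: bimolecular sulfate-driven AOM,
#'   `k * [CH4] * [SO4]`, k in (umol cm^-3)^-1 yr^-1, rate per cm^3
#'   porewater.
#' @export
saom_rate <- function(ch4, so4, k) {
  if (k < 0) stop("k_saom must be non-negative", call. = FALSE)
  check_nonneg(CH4 = ch4, SO4 = so4)
  k * ch4 * so4
}

#' @rdname rate_laws
#' @details `feaom_rate`: bimolecular iron-driven AOM,
#'   `k * [CH4] * [FeOx]` with CH4 per porewater volume and reactive Fe
#'   oxides per dry-sediment volume; k in (umol cm^-3 dry)^-1 yr^-1; rate
#'   expressed per cm^3 dry sediment (mol CH4 basis). Two optional
#'   smooth switches confine iron-driven AOM to the sediment where it is
#'   observed to operate: a sulfate-inhibition factor
#'   `K_inhib^h / (K_inhib^h + [SO4]^h)` (off in sulfate-replete
#'   sediment) and a methane activation factor
#'   `[CH4]^h / (K_act^h + [CH4]^h)` standing in for the thermodynamic
#'   drive, which makes metal-AOM favourable only at high methane
#'   activity. Either `Inf` (sulfate constant) or `0` (activation
#'   constant) disables its switch.
#' @param K_inhib Sulfate-inhibition constant, umol cm^-3 (`Inf` = no
#'   inhibition).
#' @param K_act Methane-activation constant, umol cm^-3 (`0` = no
#'   activation threshold).
#' @param hill Hill exponent of the two switches (1 = Monod).
#' @export
feaom_rate <- function(ch4, feox, k, so4 = 0, K_inhib = Inf, K_act = 0,
                       hill = 2) {
  if (k < 0) stop("k_feaom must be non-negative", call. = FALSE)
  check_nonneg(CH4 = ch4, FeOx = feox)
  inhib <- if (is.infinite(K_inhib)) 1 else
    K_inhib^hill / (K_inhib^hill + so4^hill)
  act <- if (K_act <= 0) 1 else ch4^hill / (K_act^hill + ch4^hill)
  k * ch4 * feox * inhib * act
}

#' @rdname rate_laws
#' @details `mb_dissolution_rate`: methane bubble dissolution, a
#'   saturation-relaxation source `k_mb * (CH4_sat - [CH4])` active only
#'   inside the gas zone and clamped at zero above saturation; per cm^3
#'   porewater.
#' @param z Depth, cm.
#' @param k_mb Relaxation constant, yr^-1.
#' @param ch4_sat Methane saturation concentration, umol cm^-3.
#' @param gas_zone Length-2 depth interval (cm) where free gas is present.
#' @export
mb_dissolution_rate <- function(ch4, z, k_mb, ch4_sat, gas_zone) {
  if (ch4_sat <= 0) stop("ch4_sat must be positive", call. = FALSE)
  if (k_mb < 0) stop("k_mb must be non-negative", call. = FALSE)
  check_nonneg(CH4 = ch4)
  inside <- as.numeric(z >= gas_zone[1] & z <= gas_zone[2])
  k_mb * pmax(0, ch4_sat - ch4) * inside
}

#' @rdname rate_laws
#' @details `poc_degradation_rate`: organoclastic degradation of a
#'   prescribed exponentially decaying reactive particulate organic carbon
#'   profile, routed to sulfate reduction through a Monod factor
#'   `[SO4]/([SO4]+K_SO4)`; per cm^3 dry sediment (mol C basis). The POC
#'   inventory scales with the sedimentation rate through `poc_0`.
#' @param poc_0 Reactive POC at the surface, umol C cm^-3 dry.
#' @param z_poc e-folding depth of the reactive POC profile, cm.
#' @param k_poc First-order degradation constant, yr^-1.
#' @param K_so4 Monod half-saturation for sulfate, umol cm^-3.
#' @export
poc_degradation_rate <- function(z, so4, k_poc, poc_0, z_poc, K_so4) {
  check_nonneg(SO4 = so4)
  k_poc * poc_0 * exp(-z / z_poc) * so4 / (so4 + K_so4)
}

#' @rdname rate_laws
#' @details `carbonate_precipitation_rate`: threshold precipitation of a
#'   carbonate mineral, `k * max(0, [DIC] - DIC_threshold) * [cation]`,
#'   per cm^3 porewater (mol cation basis). With `cation = Fe2` the
#'   product is the modelled solid Fe carbonate.
#' @param cation Cation concentration (Ca, Mg or Fe2), umol cm^-3.
#' @param dic_threshold DIC threshold for supersaturation, umol cm^-3.
#' @export
carbonate_precipitation_rate <- function(cation, dic, k, dic_threshold) {
  if (k < 0) stop("precipitation k must be non-negative", call. = FALSE)
  check_nonneg(cation = cation, DIC = dic)
  k * pmax(0, dic - dic_threshold) * cation
}

#' Reaction network of the seep diagenesis model
#'
#' Builds the default network: sulfate-driven AOM, iron-driven AOM
#' (1 CH4 : 8 Fe(III), the standard 8-electron balance), methane bubble
#' dissolution, Monod-gated organoclastic sulfate reduction, and threshold
#' precipitation of Ca/Mg carbonate and Fe carbonate. Elemental
#' conservation (C, S, Fe, Ca+Mg) is asserted for every reaction at load.
#'
#' @param params Named list of rate parameters (see
#'   [reference_scenario()] for the full set and defaults).
#' @return List of reaction definitions (id, stoichiometry, rate basis).
#' @export
reaction_network <- function(params) {
  rxns <- list(
    list(id = "S-AOM",
         stoich = c(CH4 = -1, SO4 = -1, DIC = 1, HS = 1),
         basis = "porewater"),
    list(id = "Fe-AOM",
         stoich = c(CH4 = -1, FeOx = -8, Fe2 = 8, DIC = 1),
         basis = "solid"),
    list(id = "MB",
         stoich = c(CH4 = 1, CH4gas = -1),
         basis = "porewater"),
    list(id = "POC-SR",
         stoich = c(POC = -1, SO4 = -0.5, DIC = 1, HS = 0.5),
         basis = "solid"),
    list(id = "CaCO3",
         stoich = c(Ca = -1, DIC = -1, CaCO3 = 1),
         basis = "porewater"),
    list(id = "MgCO3",
         stoich = c(Mg = -1, DIC = -1, MgCO3 = 1),
         basis = "porewater"),
    list(id = "FeCO3",
         stoich = c(Fe2 = -1, DIC = -1, FeCarb = 1),
         basis = "porewater")
  )
  comp <- element_composition()
  for (r in rxns) {
    bal <- colSums(comp[names(r$stoich), , drop = FALSE] * r$stoich)
    if (any(abs(bal) > 1e-12)) {
      stop("reaction ", r$id, " violates elemental conservation: ",
           paste(names(bal)[abs(bal) > 1e-12], collapse = ", "),
           call. = FALSE)
    }
  }
  rxns
}

#' Per-reaction and per-species net reaction terms
#'
#' Evaluates every rate law of the network at the given state and converts
#' each to a bulk-sediment basis: porewater-based rates are multiplied by
#' `phi`, dry-solid-based rates by `1 - phi`. The per-species net term is
#' the stoichiometry-weighted sum over reactions, also per cm^3 bulk
#' sediment per year; the transport solver divides by `phi` (dissolved) or
#' `1 - phi` (solids) to recover phase-specific tendencies.
#'
#' @param state Named list of concentration vectors (model species, umol
#'   cm^-3 own phase), all the same length as `z`.
#' @param z Depth vector, cm.
#' @param phi Porosity vector.
#' @param params Rate-parameter list (see [reference_scenario()]).
#' @param network Optional precomputed [reaction_network()] for `params`
#'   (avoids re-validating the network in tight loops).
#' @return List with `reaction_rates` (named list of bulk rate vectors,
#'   umol cm^-3 bulk yr^-1, mol basis of each reaction's extent) and
#'   `net_bulk` (named list per model species).
#' @export
net_rates <- function(state, z, phi, params, network = NULL) {
  p <- params
  rr <- list(
    "S-AOM" = phi * saom_rate(state$CH4, state$SO4, p$k_saom),
    "Fe-AOM" = (1 - phi) * feaom_rate(state$CH4, state$FeOx, p$k_feaom,
                                      so4 = state$SO4,
                                      K_inhib = p$K_inhib_so4,
                                      K_act = p$K_act_ch4,
                                      hill = p$hill_feaom),
    "MB" = phi * mb_dissolution_rate(state$CH4, z, p$k_mb, p$ch4_sat,
                                     p$gas_zone),
    "POC-SR" = (1 - phi) * poc_degradation_rate(z, state$SO4, p$k_poc,
                                                p$poc_0, p$z_poc, p$K_so4),
    "CaCO3" = phi * carbonate_precipitation_rate(state$Ca, state$DIC,
                                                 p$k_camg, p$dic_threshold),
    "MgCO3" = phi * carbonate_precipitation_rate(state$Mg, state$DIC,
                                                 p$k_camg, p$dic_threshold),
    "FeCO3" = phi * carbonate_precipitation_rate(state$Fe2, state$DIC,
                                                 p$k_fecarb, p$dic_threshold)
  )
  rxns <- network %||% reaction_network(p)
  spp <- c(MODEL_DISS, MODEL_SOL)
  net <- stats::setNames(rep(list(rep(0, length(z))), length(spp)), spp)
  for (r in rxns) {
    rate <- rr[[r$id]]
    for (sp in intersect(names(r$stoich), spp)) {
      net[[sp]] <- net[[sp]] + r$stoich[[sp]] * rate
    }
  }
  list(reaction_rates = rr, net_bulk = net)
}
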