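# shared fixtures: fast coarse scenarios and tiny profile sets

coarse_reference <- function(dz = 5, ...) reference_scenario(dz = dz, ...)

# a small porewater-only profile set with two analytes
tiny_profiles <- function() {
  profile_set(
    metadata = site_metadata(core_id = "TINY"),
    porewater = list(
      SO4 = depth_series(c(10, 50, 90), c(28, 20, 12), "SO4"),
      CH4 = depth_series(c(10, 50, 90), c(1, 200, 800), "CH4")))
}

# random profile set used by round-trip properties; values >= 0, some NAs
random_profiles <- function(n_analytes = 3, n_depths = 6) {
  reg <- analyte_registry()
  pick <- sample(nrow(reg), n_analytes)
  depth <- sort(sample(seq(0, 430, by = 5), n_depths))
  porewater <- list(); solids <- list()
  for (i in pick) {
    v <- round(stats::runif(n_depths, 0, 100), 6)
    if (stats::runif(1) < 0.3) v[sample(n_depths, 1)] <- NA
    if (reg$phase[i] == "isotope-ratio") v <- v - 50
    s <- depth_series(depth, v, reg$analyte[i])
    if (reg$phase[i] == "solid") solids[[reg$analyte[i]]] <- s
    else porewater[[reg$analyte[i]]] <- s
  }
  profile_set(site_metadata(), porewater, solids)
}

# solver scenario engineered so methane obeys pure decay-diffusion:
# effectively constant sulfate (huge reservoir), no bubbles, no burial,
# no irrigation, uniform porosity; CH4 enters at the top and decays at
# k_eff = k_saom * SO4_top
decay_oracle_scenario <- function(dz = 1, k_eff = 0.2, so4_top = 1000) {
  site <- site_metadata(phi_0 = 0.7, phi_inf = 0.7, w_inf = 1e-6)
  scenario(
    core_length = 430, dz = dz, site = site,
    params = list(k_saom = k_eff / so4_top, k_feaom = 0, k_mb = 0,
                  k_poc = 0, k_camg = 0, k_fecarb = 0),
    top_bc = c(SO4 = so4_top, CH4 = 1, DIC = 2.3, Ca = 10.3, Mg = 53,
               Fe2 = 0),
    solid_flux = c(FeOx = 0, FeCarb = 0),
    alpha = 0)
}

expect_profile_sets_equal <- function(a, b, tol = 1e-12) {
  expect_equal(sort(names(all_series_list(a))),
               sort(names(all_series_list(b))))
  for (nm in names(all_series_list(a))) {
    sa <- all_series_list(a)[[nm]]
    sb <- all_series_list(b)[[nm]]
    expect_equal(sa$depth, sb$depth, tolerance = tol)
    expect_equal(sa$value, sb$value, tolerance = tol)
    expect_identical(attr(sa, "unit"), attr(sb, "unit"))
  }
}

all_series_list <- function(ps) c(ps$porewater, ps$solids)
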