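ref_params <- function() reference_scenario()$params

test_that("every reaction conserves C, S, Fe and Ca+Mg at network load", {
  expect_silent(reaction_network(ref_params()))
  # a corrupted network is rejected (checked through the internal
  # composition table by building a bad stoichiometry directly)
  comp <- seepaom:::element_composition()
  bad <- c(CH4 = -1, DIC = 2)
  bal <- colSums(comp[names(bad), ] * bad)
  expect_gt(max(abs(bal)), 0)
})

test_that("rate laws vanish at zero concentrations except bubble
          dissolution inside the gas zone", {
  p <- ref_params()
  state0 <- list(SO4 = 0, CH4 = 0, DIC = 0, Ca = 0, Mg = 0, Fe2 = 0,
                 FeOx = 0, FeCarb = 0)
  nr <- net_rates(lapply(state0, function(x) rep(x, 2)),
                  z = c(100, 300), phi = c(0.7, 0.62), params = p)
  rr <- nr$reaction_rates
  for (id in setdiff(names(rr), "MB")) {
    if (id == "POC-SR") next  # gated by SO4 = 0, also zero here
    expect_equal(rr[[id]], c(0, 0), info = id)
  }
  expect_equal(rr[["POC-SR"]], c(0, 0))
  # bubble dissolution at CH4 = 0: k_mb * ch4_sat inside the gas zone only
  expect_equal(rr[["MB"]], c(0, 0.62 * p$k_mb * p$ch4_sat))
})

test_that("S-AOM stoichiometry is 1:1:1 (CH4:SO4:DIC) and bilinear", {
  p <- ref_params()
  st <- list(SO4 = 10, CH4 = 0.5, DIC = 2, Ca = 10, Mg = 50, Fe2 = 0,
             FeOx = 0, FeCarb = 0)
  nr <- net_rates(st, z = 150, phi = 0.65, params = p)
  r <- nr$reaction_rates[["S-AOM"]]
  expect_gt(r, 0)
  expect_equal(nr$net_bulk$CH4, -r + nr$reaction_rates[["MB"]])
  expect_equal(nr$net_bulk$SO4,
               -r - 0.5 * nr$reaction_rates[["POC-SR"]])
  # DIC gains from S-AOM and POC, loses to precipitation
  expect_equal(saom_rate(0, 10, 1), 0)
  expect_equal(saom_rate(0.5, 0, 1), 0)
  expect_equal(saom_rate(1, 2, 0.3), 0.6)
  expect_equal(saom_rate(2, 4, 0.3), 4 * saom_rate(1, 2, 0.3))
})

test_that("Fe-AOM switches behave: off without Fe oxides, suppressed by
          sulfate, activated by methane", {
  expect_equal(feaom_rate(10, 0, 1e-3), 0)
  expect_equal(feaom_rate(0, 100, 1e-3), 0)
  plain <- feaom_rate(10, 100, 1e-3)
  expect_equal(plain, 1e-3 * 10 * 100)
  expect_lt(feaom_rate(10, 100, 1e-3, so4 = 10, K_inhib = 0.1), plain / 100)
  expect_lt(feaom_rate(1, 100, 1e-3, K_act = 15), 1e-3 * 1 * 100 * 0.01)
  expect_error(feaom_rate(10, 100, -1), "non-negative")
})

test_that("bubble dissolution is a clamped relaxation to saturation", {
  expect_equal(mb_dissolution_rate(70, 300, 0.1, 70, c(210, 430)), 0)
  expect_equal(mb_dissolution_rate(80, 300, 0.1, 70, c(210, 430)), 0)
  expect_equal(mb_dissolution_rate(0, 300, 0.1, 70, c(210, 430)), 7)
  expect_equal(mb_dissolution_rate(0, 100, 0.1, 70, c(210, 430)), 0)
  expect_error(mb_dissolution_rate(0, 300, 0.1, -1, c(210, 430)),
               "positive")
})

test_that("one-box Euler integration of Fe-AOM conserves iron across
          phases", {
  # single cell, no transport: d(FeOx)/dt = -8 R_dry (per dry volume),
  # d(Fe2)/dt = +8 R_bulk / phi (per porewater volume); total Fe per bulk
  # volume (1-phi)*FeOx + phi*Fe2 must be conserved, and 8 x CH4 consumed
  # must equal Fe2 produced (both per bulk volume)
  p <- ref_params()
  p$K_act_ch4 <- 0; p$K_inhib_so4 <- Inf   # bare bimolecular law
  phi <- 0.6
  st <- list(SO4 = 0, CH4 = 5, DIC = 0, Ca = 0, Mg = 0, Fe2 = 0.01,
             FeOx = 100, FeCarb = 0)
  dt <- 0.01
  fe_tot0 <- (1 - phi) * st$FeOx + phi * st$Fe2
  ch4_0 <- phi * st$CH4
  for (i in 1:200) {
    nb <- net_rates(st, z = 300, phi = phi, params = p)$net_bulk
    # suppress every process except Fe-AOM couplings
    st$CH4 <- st$CH4 + dt * (-net_rates(st, 300, phi, p)$reaction_rates[[
      "Fe-AOM"]] + 0) / phi
    st$FeOx <- st$FeOx + dt * nb$FeOx / (1 - phi)
    st$Fe2 <- st$Fe2 + dt * nb$Fe2 / phi
  }
  fe_tot1 <- (1 - phi) * st$FeOx + phi * st$Fe2
  expect_equal(fe_tot1, fe_tot0, tolerance = 1e-10)
  d_ch4 <- ch4_0 - phi * st$CH4
  d_fe2 <- phi * st$Fe2 - 0.6 * 0.01
  expect_equal(d_fe2, 8 * d_ch4, tolerance = 1e-8)
})

test_that("unit conversion: an Fe-AOM step adds 8R/phi to porewater
          Fe2+", {
  p <- ref_params(); p$K_act_ch4 <- 0; p$K_inhib_so4 <- Inf
  phi <- 0.5
  st <- list(SO4 = 0, CH4 = 2, DIC = 0, Ca = 0, Mg = 0, Fe2 = 0,
             FeOx = 50, FeCarb = 0)
  nr <- net_rates(st, 300, phi, p)
  r_bulk <- nr$reaction_rates[["Fe-AOM"]]
  expect_equal(r_bulk, (1 - phi) * p$k_feaom * 2 * 50)
  expect_equal(nr$net_bulk$Fe2 / phi, 8 * r_bulk / phi)
})

test_that("carbonate precipitation has a sharp DIC threshold", {
  expect_equal(carbonate_precipitation_rate(10, 5, 0.1, 8), 0)
  expect_equal(carbonate_precipitation_rate(10, 9, 0.1, 8), 1)
  expect_error(carbonate_precipitation_rate(-1, 9, 0.1, 8), "negative")
})

test_that("negative concentrations are rejected by the rate laws", {
  expect_error(saom_rate(-1, 10, 0.1), "negative")
  expect_error(net_rates(list(SO4 = -1, CH4 = 0, DIC = 0, Ca = 0, Mg = 0,
                              Fe2 = 0, FeOx = 0, FeCarb = 0),
                         100, 0.6, ref_params()), "negative")
})
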