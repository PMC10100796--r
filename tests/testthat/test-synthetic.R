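test_that("the noise-free preset reproduces every printed concentration
          anchor at its depth", {
  ps <- generate_anchor_profiles(anchor_spec(), sigma_scale = 0)
  val <- function(a, z) {
    s <- if (!is.null(ps$porewater[[a]])) ps$porewater[[a]] else
      ps$solids[[a]]
    s$value[s$depth == z]
  }
  expect_equal(val("Fe2", 370), 148)
  expect_equal(val("Mn2", 340), 2289)
  expect_equal(val("CH4", 210), 781)
  expect_equal(val("CH4", 330), 53)
  expect_equal(val("CH4", 170), 15.74)
  expect_equal(val("DIC", 250), 10.38)
  expect_equal(val("DIC", 330), 17.27)
  expect_equal(val("TA", 230), 16.01)
  expect_equal(val("TA", 430), 28.94)
  expect_equal(val("SO4", 0), 28.5)
  expect_equal(val("d13C_CH4", 210), -68.77)
  expect_equal(val("d13C_CH4", 330), -64.33)
  # methanic-zone ceilings hold everywhere
  expect_lte(max(ps$porewater$PO4$value), 41.65)
  expect_lte(max(ps$porewater$NH4$value), 56.72)
  meth <- ps$porewater$d13C_DIC$depth >= 240 &
    ps$porewater$d13C_DIC$depth <= 430
  expect_true(all(ps$porewater$d13C_DIC$value[meth] <= -42.30))
})

test_that("identical seeds give bitwise-identical profile sets and the
          caller's RNG state is untouched", {
  a <- generate_anchor_profiles(anchor_spec(seed = 7))
  set.seed(123); before <- runif(1)
  set.seed(123)
  b <- generate_anchor_profiles(anchor_spec(seed = 7))
  after <- runif(1)
  expect_identical(a, b)
  expect_identical(before, after)
  c <- generate_anchor_profiles(anchor_spec(seed = 8))
  expect_false(identical(a$porewater$SO4$value, c$porewater$SO4$value))
})

test_that("the preset sulfate window is quasilinear with R^2 >= 0.98", {
  ps <- generate_anchor_profiles(anchor_spec(), sigma_scale = 0)
  s <- ps$porewater$SO4
  w <- s$depth >= 130 & s$depth <= 230
  r2 <- suppressWarnings(
    summary(stats::lm(s$value[w] ~ s$depth[w])))$r.squared
  expect_gte(r2, 0.98)
  # and survives the preset's analytical noise level
  psn <- generate_anchor_profiles(anchor_spec(seed = 42), sigma_scale = 1)
  sn <- psn$porewater$SO4
  r2n <- summary(stats::lm(sn$value[w] ~ sn$depth[w]))$r.squared
  expect_gte(r2n, 0.98)
})

test_that("the default preset zonates to the expected boundaries within
          one sampling interval", {
  ps <- generate_anchor_profiles(anchor_spec(), sigma_scale = 0)
  zn <- zonate(ps)
  interval <- 40
  expect_lte(abs(zn$z1 - 130), interval)
  expect_lte(abs(zn$z2 - 230), interval)
})

test_that("anchor curves outside the core are rejected and negative noise
          is rejected", {
  curves <- default_anchor_curves()
  curves$Fe2$center <- 600
  expect_error(anchor_spec(curves = curves), "outside core")
  expect_error(anchor_spec(noise = list(SO4 = list(sigma = -1,
                                                   type = "rel"))),
               "negative")
})

test_that("relative noise matches the half-normal mean |dx|/x over many
          draws", {
  # with sigma = 1% relative noise, E|rel deviation| = sigma*sqrt(2/pi)
  sp <- anchor_spec(noise = list(Mn2 = list(sigma = 0.01, type = "rel")))
  truth <- generate_anchor_profiles(sp, sigma_scale = 0)$porewater$Mn2
  devs <- numeric(0)
  for (seed in 1:500) {
    sp$seed <- seed
    v <- generate_anchor_profiles(sp)$porewater$Mn2$value
    keep <- truth$value > 1  # avoid division blow-up at near-zero tails
    devs <- c(devs, abs(v[keep] - truth$value[keep]) / truth$value[keep])
  }
  expect_equal(mean(devs), 0.01 * sqrt(2 / pi), tolerance = 0.05)
})

test_that("model-generated observations equal the regridded solution at
          sigma = 0 and are seed-reproducible", {
  scn <- coarse_reference(dz = 10)
  ms <- solve_steady_state(scn)
  depths <- seq(20, 420, 50)
  obs <- generate_from_model(scn, sigma = 0, sampling_depths = depths,
                             ms = ms)
  m <- approx(ms$z, ms$conc[, "SO4"], xout = depths)$y
  expect_equal(obs$porewater$SO4$value, m, tolerance = 1e-12)
  # CH4 comes back in uM
  mch4 <- approx(ms$z, ms$conc[, "CH4"], xout = depths)$y * 1e3
  expect_equal(obs$porewater$CH4$value, mch4, tolerance = 1e-12)

  o1 <- generate_from_model(scn, sigma = 0.02, sampling_depths = depths,
                            seed = 5, ms = ms)
  o2 <- generate_from_model(scn, sigma = 0.02, sampling_depths = depths,
                            seed = 5, ms = ms)
  expect_identical(o1, o2)
})
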