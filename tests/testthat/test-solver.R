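test_that("with no reactions and no transport forcing the solution is the
          constant boundary value", {
  scn <- decay_oracle_scenario(dz = 5, k_eff = 0)
  scn$top_bc[["CH4"]] <- 0.5
  ms <- solve_steady_state(scn)
  # every dissolved profile collapses to its top value (Laplace equation
  # with equal effective end conditions)
  for (sp in c("SO4", "CH4", "DIC", "Ca", "Mg")) {
    expect_equal(ms$conc[, sp], rep(scn$top_bc[[sp]], length(ms$z)),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("fixed unequal end values with constant phi*Ds give a linear
          profile", {
  scn <- decay_oracle_scenario(dz = 5, k_eff = 0)
  scn$bottom_bc$Ca <- list(kind = "fixed", value = 2)
  ms <- solve_steady_state(scn)
  z <- ms$z
  lin <- 10.3 + (2 - 10.3) * z / 430
  expect_equal(ms$conc[, "Ca"], lin, tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("steady decay-diffusion matches the closed form to < 1% at 1-cm
          resolution", {
  k_eff <- 0.2
  scn <- decay_oracle_scenario(dz = 1, k_eff = k_eff)
  ms <- solve_steady_state(scn)
  ds <- tortuosity_correct(
    diffusion_coefficient("CH4", scn$site$temperature), 0.7)
  lam <- sqrt(k_eff / ds)
  analytic <- exp(-lam * ms$z)
  keep <- analytic > 1e-4   # compare over ~9 decay lengths
  rel <- abs(ms$conc[keep, "CH4"] - analytic[keep]) / analytic[keep]
  expect_lt(max(rel), 0.01)
})

test_that("every converged run closes its per-species mass balance to
          1%", {
  ms <- solve_steady_state(coarse_reference(dz = 5))
  expect_true(all(ms$mass_balance$relative_misclosure <= 0.01))
  expect_true(ms$diagnostics$converged)
  expect_true(all(ms$conc >= 0))
})

test_that("switching off Fe-AOM kills the Fe2+ profile and its
          depth-integrated rate exactly", {
  ms <- solve_steady_state(coarse_reference(dz = 5,
                                            params = list(k_feaom = 0)))
  expect_equal(depth_integrate(ms, "Fe-AOM", c(0, 430)), 0)
  expect_lt(max(ms$conc[, "Fe2"]), 1e-6)
})

test_that("the solution is insensitive to the pseudo-time path (warm
          start reaches the same steady state)", {
  scn <- coarse_reference(dz = 10)
  cold <- solve_steady_state(scn)
  # warm-start from a perturbed state: same fixed point
  scn2 <- coarse_reference(dz = 10)
  warm <- solve_steady_state(scn2, init = cold)
  expect_equal(warm$conc, cold$conc, tolerance = 1e-4)
})

test_that("grid refinement converges: the decay oracle error shrinks with
          h and pure diffusion is grid-exact", {
  # pure diffusion at two resolutions: identical to rounding
  lin1 <- solve_steady_state(decay_oracle_scenario(dz = 10, k_eff = 0))
  lin2 <- solve_steady_state(decay_oracle_scenario(dz = 5, k_eff = 0))
  expect_equal(max(lin1$conc[, "Ca"]) - min(lin1$conc[, "Ca"]), 0,
               tolerance = 1e-6)
  expect_equal(max(lin2$conc[, "Ca"]) - min(lin2$conc[, "Ca"]), 0,
               tolerance = 1e-6)

  # decay oracle at h = 4, 2, 1 cm: error vs closed form shrinks
  k_eff <- 0.2
  ds <- tortuosity_correct(diffusion_coefficient("CH4", 3.5), 0.7)
  lam <- sqrt(k_eff / ds)
  err <- vapply(c(4, 2, 1), function(h) {
    ms <- solve_steady_state(decay_oracle_scenario(dz = h, k_eff = k_eff))
    analytic <- exp(-lam * ms$z)
    keep <- analytic > 1e-3
    max(abs(ms$conc[keep, "CH4"] - analytic[keep]) / analytic[keep])
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("refine_and_verify reports resolutions and the observed order", {
  rep <- refine_and_verify(decay_oracle_scenario(dz = 8, k_eff = 0.2),
                           factors = c(1, 2, 4),
                           functional = function(ms) {
                             depth_integrate(ms, "S-AOM", c(0, 430))
                           })
  expect_equal(rep$dz, c(8, 4, 2))
  expect_true(all(rep$change[-1] < 0.05))
  expect_gte(attr(rep, "observed_order"), 1)
})

test_that("non-convergence raises an informative error", {
  scn <- coarse_reference(dz = 10, solver = list(t_max = 5,
                                                 tol_rel = 1e-10))
  expect_error(solve_steady_state(scn), "steady state not reached")
})

test_that("tidy and glance summarise a model state", {
  ms <- solve_steady_state(coarse_reference(dz = 10))
  td <- tidy(ms)
  expect_setequal(unique(td$quantity), c("concentration", "rate"))
  expect_true(all(c("S-AOM", "Fe-AOM") %in% td$name))
  g <- glance(ms)
  expect_true(g$converged)
  expect_lte(g$max_misclosure, 0.01)
})
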