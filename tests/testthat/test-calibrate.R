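test_that("spearman_matrix handles monotone, anti-monotone and constant
          vectors", {
  x <- 1:10
  df <- data.frame(a = x, b = x^3, c = -sqrt(x), d = rep(1, 10))
  m <- spearman_matrix(df)
  expect_equal(m$rho["a", "b"], 1)
  expect_equal(m$rho["a", "c"], -1)
  expect_true(is.na(m$rho["a", "d"]))   # constant: missing, not zero
  expect_equal(diag(m$rho), rep(1, 4), ignore_attr = TRUE)
  expect_equal(m$rho, t(m$rho))
})

test_that("exact permutation p at n = 8 equals the library's exact
          Spearman test on tie-free data", {
  withr::local_seed(21)
  for (i in 1:5) {
    x <- rnorm(8); y <- rnorm(8)
    m <- spearman_matrix(data.frame(x = x, y = y))
    ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                     exact = TRUE))
    expect_equal(m$rho["x", "y"], unname(ref$estimate), tolerance = 1e-12)
    expect_equal(m$p["x", "y"], ref$p.value, tolerance = 1e-12)
  }
})

test_that("exact permutation handles ties via midranks and stays a valid
          probability", {
  x <- c(1, 2, 2, 3, 4, 5, 5, 6)
  y <- c(2, 1, 4, 4, 3, 7, 6, 8)
  m <- spearman_matrix(data.frame(x = x, y = y))
  expect_equal(m$rho["x", "y"],
               cor(x, y, method = "spearman"), tolerance = 1e-12)
  expect_gte(m$p["x", "y"], 0)
  expect_lte(m$p["x", "y"], 1)
})

test_that("spearman is invariant under strictly monotone transforms", {
  withr::local_seed(8)
  x <- rnorm(12); y <- rnorm(12)
  m1 <- spearman_matrix(data.frame(x = x, y = y))
  m2 <- spearman_matrix(data.frame(x = exp(3 * x), y = y^3))
  expect_equal(m1$rho["x", "y"], m2$rho["x", "y"], tolerance = 1e-12)
  expect_equal(m1$p["x", "y"], m2$p["x", "y"], tolerance = 1e-12)
})

test_that("large-sample p uses the t approximation and significance tiers
          follow the conventional thresholds", {
  withr::local_seed(2)
  x <- rnorm(30); y <- x + rnorm(30, sd = 0.4)
  m <- spearman_matrix(data.frame(x = x, y = y))
  rho <- m$rho["x", "y"]; n <- 30
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  expect_equal(m$p["x", "y"], 2 * pt(-abs(tstat), n - 2), tolerance = 1e-12)
  expect_identical(m$tier["x", "y"], "***")
  expect_identical(seepaom:::sig_tier(c(0.2, 0.03, 0.005, 5e-4)),
                   c("", "*", "**", "***"))
})

test_that("pairwise-complete handling and the BH column", {
  df <- data.frame(a = c(1:8, NA, NA), b = c(NA, 2:10), c = rnorm(10))
  m <- spearman_matrix(df, adjust = TRUE)
  expect_equal(m$n["a", "b"], 7)
  expect_true("p_adjusted" %in% names(m$pairs))
  expect_error(spearman_matrix(df["a"]), "at least 2")
})

test_that("sensitivity report is a no-op at factor 1", {
  scn <- coarse_reference(dz = 10)
  sens <- sensitivity_sedimentation(scn, factors = 1)
  expect_true(all(sens$profiles$max_relative_deviation == 0))
  expect_true(all(sens$rates$saom_change_pct == 0))
})

test_that("an advection-dominated scenario is sensitive to sedimentation
          (negative control)", {
  # with burial 100x faster, transport of solutes is advection-controlled
  # and doubling the sedimentation rate visibly shifts the profiles
  scn <- coarse_reference(dz = 10)
  scn$site$w_inf <- 5
  sens <- sensitivity_sedimentation(scn, factors = c(1, 2))
  dev <- sens$profiles$max_relative_deviation[sens$profiles$factor == 2]
  expect_gt(max(dev), 0.1)
})

test_that("calibration recovers a known parameter from noise-free
          self-generated observations", {
  scn <- coarse_reference(dz = 10)
  truth <- scn$params$k_saom
  obs <- generate_from_model(scn, sigma = 0,
                             sampling_depths = seq(10, 430, 30))
  start <- scn
  start$params$k_saom <- truth * 2.5
  cal <- calibrate(start, obs, free = list(k_saom = c(truth / 10,
                                                      truth * 10)),
                   n_starts = 1, maxit = 40)
  expect_lt(abs(cal$parameters$estimate - truth) / truth, 0.05)
  expect_true(all(cal$parameters$estimate >= cal$parameters$lower &
                    cal$parameters$estimate <= cal$parameters$upper))
  # the returned objective is the best over all evaluated starts
  expect_lte(cal$objective, min(cal$starts$objective))
})

test_that("calibration input validation", {
  scn <- coarse_reference(dz = 10)
  obs <- tiny_profiles()
  expect_error(calibrate(scn, obs, free = list(nope = c(1, 2))),
               "not a scenario parameter")
  expect_error(calibrate(scn, obs, free = list(k_saom = c(2, 1))),
               "bounds")
  expect_error(calibrate(scn, obs, free = list(k_saom = c(0.1, 1)),
                         weights = c(SO4 = 0, CH4 = 0)),
               "weights are zero")
})
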