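test_that("depth_series validates its invariants with actionable messages", {
  s <- depth_series(c(10, 50, 90), c(28, 20, 12), "SO4")
  expect_s3_class(s, "seep_depth_series")
  expect_identical(attr(s, "unit"), "mM")
  expect_identical(attr(s, "phase"), "dissolved")

  expect_error(depth_series(c(10, 50, 50), c(1, 2, 3), "SO4"),
               "strictly increasing")
  expect_error(depth_series(c(10, 90, 50), c(1, 2, 3), "SO4"),
               "offending rows: 3")
  expect_error(depth_series(10, 1, "SO4"), "at least 2")
  expect_error(depth_series(c(10, 50), c(-1, 2), "SO4"), "negative")
  # isotope ratios may be negative
  expect_silent(depth_series(c(10, 50), c(-68, -64), "d13C_CH4"))
})

test_that("read_profile_table parses a small table and rejects bad input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("depth_cmbsf[cm],SO4[mM]", "10,28", "50,20", "90,12"), path)
  ps <- read_profile_table(path)
  expect_length(ps$porewater, 1)
  expect_equal(ps$porewater$SO4$value, c(28, 20, 12))
  expect_identical(attr(ps$porewater$SO4, "unit"), "mM")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("depth_cmbsf[cm],SO4[mM]", "50,28", "10,20"), bad)
  expect_error(read_profile_table(bad), "strictly increasing")

  nodepth <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("SO4[mM],CH4[uM]", "28,1"), nodepth)
  expect_error(read_profile_table(nodepth), "depth column")

  nonnum <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("depth_cmbsf[cm],SO4[mM]", "10,28", "50,oops"), nonnum)
  expect_error(read_profile_table(nonnum), "rows: 2")

  # empty cells become missing values
  gaps <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("depth_cmbsf[cm],SO4[mM]", "10,28", "50,", "90,12"), gaps)
  expect_equal(read_profile_table(gaps)$porewater$SO4$value, c(28, NA, 12))
})

test_that("write/read round trip preserves values over random tables", {
  withr::local_seed(42)
  for (i in 1:100) {
    ps <- random_profiles()
    path <- tempfile(fileext = ".csv")
    write_profile_table(ps, path)
    back <- read_profile_table(path)
    expect_profile_sets_equal(ps, back)
    unlink(path)
  }
})

test_that("mixed depth grids are written as a union grid with gaps", {
  ps <- profile_set(
    porewater = list(
      SO4 = depth_series(c(0, 100), c(28, 20), "SO4"),
      CH4 = depth_series(c(50, 150), c(1, 500), "CH4")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_table(ps, path)
  back <- read_profile_table(path)
  expect_equal(back$porewater$SO4$depth, c(0, 50, 100, 150))
  expect_equal(back$porewater$SO4$value, c(28, NA, 20, NA))
  expect_equal(back$porewater$CH4$value, c(NA, 1, NA, 500))
})

test_that("solids-free profile set writes a porewater-only table", {
  ps <- tiny_profiles()
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_table(ps, path)
  hdr <- readLines(path, n = 1)
  expect_match(hdr, "SO4\\[mM\\]")
  expect_false(grepl("Fe2O3T", hdr))
})

test_that("regrid interpolates linearly, exactly at nodes, and refuses to
          extrapolate", {
  s <- depth_series(c(0, 100), c(10, 20), "SO4")
  expect_equal(regrid(s, 50)$value, 15)
  expect_equal(regrid(s, c(0, 100))$value, s$value)
  expect_error(regrid(s, 150), "extrapolate")

  # brute-force two-point interpolation oracle on a random piecewise-
  # linear series
  withr::local_seed(7)
  d <- sort(sample(0:430, 25))
  v <- runif(25, 0, 100)
  s2 <- depth_series(d, v, "Mn2")
  q <- runif(1000, min(d), max(d))
  brute <- vapply(q, function(x) {
    i <- findInterval(x, d, rightmost.closed = TRUE)
    i <- min(max(i, 1), length(d) - 1)
    v[i] + (v[i + 1] - v[i]) * (x - d[i]) / (d[i + 1] - d[i])
  }, numeric(1))
  got <- regrid(s2, q)$value
  expect_equal(got, brute[order(q)], tolerance = 1e-12)
})

test_that("regrid is idempotent and exact on affine profiles", {
  s <- depth_series(seq(0, 400, 50), 5 + 0.03 * seq(0, 400, 50), "DIC")
  once <- regrid(s, seq(0, 400, 10))
  twice <- regrid(once, seq(0, 400, 10))
  expect_equal(once$value, twice$value)
  expect_equal(once$value, 5 + 0.03 * seq(0, 400, 10))
})

test_that("porosity profile follows the compaction model and site
          invariants are enforced", {
  site <- site_metadata()
  pp <- porosity_profile(site, c(0, 100, 1e5))
  expect_equal(pp$phi[1], site$phi_0)
  expect_equal(pp$phi[3], site$phi_inf, tolerance = 1e-6)
  # solid and porewater volume fluxes are depth-invariant
  expect_equal((1 - pp$phi) * pp$w_solid,
               rep((1 - site$phi_inf) * site$w_inf, 3))
  expect_equal(pp$phi * pp$v_porewater,
               rep(site$phi_inf * site$w_inf, 3))
  expect_error(site_metadata(phi_0 = 0.5, phi_inf = 0.6), "phi_inf")
})

test_that("profile_set as_tibble gives one row per depth and analyte", {
  df <- tibble::as_tibble(tiny_profiles())
  expect_equal(nrow(df), 6)
  expect_setequal(unique(df$analyte), c("SO4", "CH4"))
  expect_setequal(unique(df$unit), c("mM", "uM"))
})
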