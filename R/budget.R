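#' Biogeochemical zonation of a core from sulfate and methane profiles
#'
#' Splits a core into sulfate reduction zone (SRZ), sulfate-methane
#' transition zone (SMTZ) and methanic zone. The SMTZ top `z1` is the
#' change point where sulfate begins its quasilinear decline, found by a
#' brute-force two-segment least-squares scan over sample depths; the SMTZ
#' base `z2` is the shallowest depth where sulfate falls below a depletion
#' threshold (linearly interpolated between samples by default). If
#' sulfate never falls below the threshold a two-zone result is returned
#' with `no_smtz = TRUE`.
#'
#' @param profiles A [profile_set()] containing an `SO4` series (and
#'   normally `CH4`).
#' @param so4_threshold Sulfate depletion threshold, mM.
#' @param interpolate_crossing Interpolate `z2` between samples
#'   (default) rather than reporting the first sampled depth below the
#'   threshold.
#' @return List of class `seep_zones` with elements `z1`, `z2`, `zones`
#'   (tibble of zone bounds) and `diagnostics` (threshold used, R^2 of
#'   the declining segment, `no_smtz` flag, sampling interval).
#' @export
zonate <- function(profiles, so4_threshold = 0.5,
                   interpolate_crossing = TRUE) {
  stopifnot(inherits(profiles, "seep_profile_set"))
  so4 <- profiles$porewater$SO4
  if (is.null(so4)) stop("profile set has no SO4 series", call. = FALSE)
  ok <- !is.na(so4$value)
  z <- so4$depth[ok]
  v_mm <- to_umol_cm3(so4$value[ok], attr(so4, "unit"))  # umol/cm3 == mM
  core_length <- max(unlist(lapply(all_series(profiles),
                                   function(s) max(s$depth))))
  below <- which(v_mm < so4_threshold)
  no_smtz <- length(below) == 0
  z2 <- NA_real_
  if (!no_smtz) {
    i <- below[1]
    if (interpolate_crossing && i > 1) {
      z2 <- z[i - 1] + (so4_threshold - v_mm[i - 1]) *
        (z[i] - z[i - 1]) / (v_mm[i] - v_mm[i - 1])
    } else {
      z2 <- z[i]
    }
  }
  # two-segment break-point scan on the profile above the depletion depth
  top <- if (no_smtz) length(z) else below[1]
  sse2 <- function(y, x) {
    if (length(y) < 2) return(0)
    sum(stats::lm.fit(cbind(1, x), y)$residuals^2)
  }
  cand <- 2:(top - 1)
  if (length(cand) < 1 || top < 4) {
    z1 <- NA_real_
    seg_r2 <- NA_real_
  } else {
    sse <- vapply(cand, function(i) {
      sse2(v_mm[1:i], z[1:i]) + sse2(v_mm[i:top], z[i:top])
    }, numeric(1))
    best <- cand[which.min(sse)]
    z1 <- z[best]
    seg <- best:top
    fit <- stats::lm.fit(cbind(1, z[seg]), v_mm[seg])
    ss_tot <- sum((v_mm[seg] - mean(v_mm[seg]))^2)
    seg_r2 <- if (ss_tot == 0) 1 else 1 - sum(fit$residuals^2) / ss_tot
  }
  zones <- if (no_smtz || is.na(z1)) {
    tibble::tibble(zone = c("srz", "deep"),
                   top = c(0, z1 %||% NA_real_),
                   bottom = c(z1 %||% core_length, core_length))
  } else {
    tibble::tibble(zone = c("srz", "smtz", "methanic"),
                   top = c(0, z1, z2), bottom = c(z1, z2, core_length))
  }
  structure(
    list(z1 = z1, z2 = z2, zones = zones,
         diagnostics = list(so4_threshold = so4_threshold,
                            segment_r_squared = seg_r2,
                            no_smtz = no_smtz,
                            sampling_interval = stats::median(diff(z)))),
    class = "seep_zones")
}

#' @export
print.seep_zones <- function(x, ...) {
  if (x$diagnostics$no_smtz) {
    cat("<zonation> sulfate never depleted (no SMTZ)\n")
  } else {
    cat(sprintf("<zonation> SRZ 0-%g, SMTZ %g-%g, methanic %g-%g cmbsf\n",
                x$z1, x$z1, x$z2, x$z2, max(x$zones$bottom)))
  }
  invisible(x)
}

#' Depth-integrate a reaction-rate profile over a zone
#'
#' Trapezoidal integral of a bulk-sediment rate profile over a depth
#' interval, with linear interpolation of the rate at the interval
#' endpoints. Rates are per cm^3 bulk sediment, so no porosity factor
#' enters the integral.
#'
#' @param x A `seep_model_state`, or a data frame with columns `z` and
#'   `rate`.
#' @param reaction Reaction id (required for a model state, e.g. `"S-AOM"`,
#'   `"Fe-AOM"`).
#' @param zone Length-2 numeric depth interval (a, b), cm.
#' @return Integral in umol cm^-2 yr^-1.
#' @export
#' @examples
#' depth_integrate(data.frame(z = c(0, 100), rate = c(0.01, 0.01)),
#'                 zone = c(0, 100))  # 1.0
depth_integrate <- function(x, reaction = NULL, zone) {
  if (inherits(x, "seep_model_state")) {
    if (is.null(reaction) || !reaction %in% colnames(x$rates)) {
      stop("reaction must be one of: ",
           paste(colnames(x$rates), collapse = ", "), call. = FALSE)
    }
    z <- x$z; r <- x$rates[, reaction]
  } else {
    z <- x$z; r <- x$rate
  }
  zone <- sort(zone)
  if (zone[1] < min(z) || zone[2] > max(z)) {
    stop("zone [", zone[1], ", ", zone[2], "] outside the rate grid [",
         min(z), ", ", max(z), "]", call. = FALSE)
  }
  zz <- sort(unique(c(zone, z[z > zone[1] & z < zone[2]])))
  rr <- stats::approx(z, r, xout = zz, ties = "ordered")$y
  sum(diff(zz) * (utils::head(rr, -1) + utils::tail(rr, -1)) / 2)
}

#' Methane consumption by Mn-AOM from a diffusive Mn2+ flux
#'
#' Converts an upward diffusive Mn2+ flux into the methane oxidation rate
#' it implies, using the 4:1 Mn(IV):CH4 stoichiometry of manganese-driven
#' AOM (four MnO2 reduced per CH4 oxidised). The result inherits the
#' `minimum_estimate` flag: a flux that ignores Mn2+ consumption by
#' authigenic minerals bounds the true Mn-AOM rate from below.
#'
#' @param flux A `seep_flux_estimate` from [fick_flux()], or a bare
#'   non-negative flux in umol Mn cm^-2 yr^-1.
#' @return One-row tibble with `J_mn`, `rate_ch4` (umol CH4 cm^-2 yr^-1)
#'   and `minimum_estimate`.
#' @export
#' @examples
#' mn_aom_from_flux(1.276)$rate_ch4  # 0.319
mn_aom_from_flux <- function(flux) {
  if (inherits(flux, "seep_flux_estimate")) {
    j <- flux$J
    minimum <- flux$minimum_estimate
  } else {
    j <- as.numeric(flux)
    minimum <- FALSE
  }
  if (any(j < 0)) stop("flux must be non-negative", call. = FALSE)
  tibble::tibble(J_mn = j, rate_ch4 = j / 4, minimum_estimate = minimum)
}

round_table1 <- function(x) {
  ifelse(is.na(x), NA_real_, ifelse(x >= 10, round(x), round(x, 1)))
}

#' Partition total methane removal among AOM pathways
#'
#' Converts depth-integrated rates of S-AOM, Fe-AOM and (optionally)
#' Mn-AOM into percentage fractions of total CH4 removal. Raw fractions
#' sum to exactly 100; the `fraction` column applies the conventional
#' mixed rounding of cross-study budget tables (integers at >= 10 %, one
#' decimal below 10 %).
#'
#' @param saom,feaom Depth-integrated rates, umol CH4 cm^-2 yr^-1.
#' @param mnaom Depth-integrated Mn-AOM rate, or `NA`/`NULL` when not
#'   available.
#' @return Tibble with `pathway`, `rate`, `fraction_raw`, `fraction`.
#' @export
#' @examples
#' partition_budget(20.05, 0.31, 0.32)
partition_budget <- function(saom, feaom, mnaom = NULL) {
  if (is.null(mnaom)) mnaom <- NA_real_
  rates <- c("S-AOM" = saom, "Fe-AOM" = feaom, "Mn-AOM" = mnaom)
  if (any(rates < 0, na.rm = TRUE)) {
    stop("rates must be non-negative", call. = FALSE)
  }
  tot <- sum(rates, na.rm = TRUE)
  if (tot == 0) stop("all rates are zero; nothing to partition",
                     call. = FALSE)
  raw <- 100 * rates / tot
  tibble::tibble(pathway = names(rates), rate = unname(rates),
                 fraction_raw = unname(raw),
                 fraction = round_table1(unname(raw)))
}

#' Full methane budget of a solved scenario
#'
#' Depth-integrates the modelled S-AOM and Fe-AOM rate profiles (whole
#' core and per zone), converts a measured Mn2+ flux to Mn-AOM, and
#' partitions total CH4 removal among the three pathways. Following the
#' usual budget convention, the partition uses the whole-core S-AOM
#' integral and the methanic-zone Fe-AOM/Mn-AOM rates.
#'
#' @param ms A `seep_model_state`.
#' @param zones A `seep_zones` from [zonate()] (or `NULL` to use the
#'   whole core for every pathway).
#' @param mn_flux A `seep_flux_estimate` for Mn2+, a bare flux (umol Mn
#'   cm^-2 yr^-1), or `NULL` when Mn-AOM is not constrained.
#' @return List of class `seep_budget` with `integrals` (per pathway x
#'   zone), `partition`, `peak_rates`, `zones`.
#' @export
budget_summary <- function(ms, zones = NULL, mn_flux = NULL) {
  stopifnot(inherits(ms, "seep_model_state"))
  zmax <- max(ms$z)
  zn <- if (is.null(zones) || is.na(zones$z2 %||% NA)) {
    tibble::tibble(zone = "whole", top = 0, bottom = zmax)
  } else {
    dplyr::bind_rows(zones$zones,
                     tibble::tibble(zone = "whole", top = 0, bottom = zmax))
  }
  paths <- c("S-AOM", "Fe-AOM")
  integrals <- purrr::map_dfr(paths, function(p) {
    purrr::map_dfr(seq_len(nrow(zn)), function(i) {
      tibble::tibble(pathway = p, zone = zn$zone[i],
                     top = zn$top[i], bottom = zn$bottom[i],
                     rate = depth_integrate(ms, p, c(zn$top[i],
                                                     zn$bottom[i])))
    })
  })
  methanic <- if ("methanic" %in% zn$zone) "methanic" else "whole"
  pick <- function(p, zone) {
    integrals$rate[integrals$pathway == p & integrals$zone == zone]
  }
  mn <- if (is.null(mn_flux)) NULL else mn_aom_from_flux(mn_flux)
  part <- partition_budget(pick("S-AOM", "whole"),
                           pick("Fe-AOM", methanic),
                           if (is.null(mn)) NA_real_ else mn$rate_ch4)
  peak <- purrr::map_dfr(paths, function(p) {
    zi <- ms$z >= (if (methanic == "whole") 0 else zn$top[zn$zone ==
                                                            methanic]) &
      ms$z <= zmax
    tibble::tibble(pathway = p,
                   peak_rate = max(ms$rates[zi, p]),
                   peak_depth = ms$z[zi][which.max(ms$rates[zi, p])])
  })
  structure(list(integrals = integrals, partition = part,
                 peak_rates = peak, zones = zn,
                 minimum_estimate = !is.null(mn) && any(mn$minimum_estimate)),
            class = "seep_budget")
}

#' @export
print.seep_budget <- function(x, ...) {
  cat("<methane budget>\n")
  print(x$partition)
  invisible(x)
}

#' One-row budget table in the cross-study layout
#'
#' @param budget A `seep_budget`.
#' @param site_name Label for the row.
#' @return One-row tibble: site, the three depth-integrated rates and the
#'   three rounded fractions.
#' @export
budget_row <- function(budget, site_name = "this study") {
  p <- budget$partition
  tibble::tibble(
    site = site_name,
    saom = p$rate[p$pathway == "S-AOM"],
    feaom = p$rate[p$pathway == "Fe-AOM"],
    mnaom = p$rate[p$pathway == "Mn-AOM"],
    f_saom = p$fraction[p$pathway == "S-AOM"],
    f_feaom = p$fraction[p$pathway == "Fe-AOM"],
    f_mnaom = p$fraction[p$pathway == "Mn-AOM"])
}
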