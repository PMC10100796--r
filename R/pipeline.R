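#' Pipeline configuration
#'
#' Bundles everything needed for a full reproducible run: the anchor
#' spec for synthetic observations (or a path to an observed profile
#' table), the scenario, the calibration setup, the Mn2+ flux window,
#' and explicit seeds for every stochastic stage.
#'
#' @param scenario A [scenario()].
#' @param anchors An [anchor_spec()], or `NULL` when `profile_table` is
#'   given.
#' @param profile_table Optional path to an observed profile table read
#'   with [read_profile_table()].
#' @param sigma_scale Noise multiplier for the synthetic stage.
#' @param calibration `NULL` to skip calibration, or a list with
#'   elements `free`, `weights`, `maxit`, `n_starts`, `dz` (grid spacing
#'   used during the search; the final solve always uses the scenario's
#'   own spacing).
#' @param mn_window Depth window (cm) for the Mn2+ Fick-flux estimate.
#' @param seeds Named list of integer seeds (`simulate`, `calibrate`);
#'   every stochastic stage must have one.
#' @return List of class `seep_pipeline_config`.
#' @export
pipeline_config <- function(scenario = reference_scenario(),
                            anchors = anchor_spec(),
                            profile_table = NULL,
                            sigma_scale = 0,
                            calibration = list(),
                            mn_window = c(250, 350),
                            seeds = list(simulate = 1L, calibrate = 1L)) {
  if (!is.null(calibration)) {
    spec <- reference_calibration_spec(scenario)
    calibration <- utils::modifyList(
      list(free = spec$free, weights = spec$weights,
           maxit = 60, n_starts = 1, dz = 5), calibration)
  }
  needed <- c("simulate", if (!is.null(calibration)) "calibrate")
  missing <- setdiff(needed, names(seeds))
  if (length(missing) > 0 || any(vapply(seeds[needed], is.null,
                                        logical(1)))) {
    stop("missing seed for stochastic stage(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(scenario = scenario, anchors = anchors,
                 profile_table = profile_table,
                 sigma_scale = sigma_scale, calibration = calibration,
                 mn_window = mn_window, seeds = seeds),
            class = "seep_pipeline_config")
}

pipeline_log <- function(verbose, stage, msg) {
  if (verbose) {
    message(format(Sys.time(), "[%H:%M:%S] "), stage, ": ", msg)
  }
}

#' Run the full seep methane-budget pipeline
#'
#' Executes the stages in dependency order — simulate (or read) profiles,
#' zonate, calibrate the scenario, solve to steady state, estimate the
#' Mn2+ diffusive flux, assemble the methane budget, sedimentation-rate
#' sensitivity, and a Spearman correlation matrix of the porewater
#' variables — writing each stage's outputs to `out_dir` before the next
#' stage starts, plus a machine-readable run manifest (config, seeds,
#' package version). Deterministic stages re-run byte-identically for
#' the same config and seeds.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @param verbose Log stage progress to standard error.
#' @return Invisibly, a list with the main stage results
#'   (`profiles`, `zones`, `calibration`, `model_state`, `mn_flux`,
#'   `budget`, `sensitivity`, `correlations`).
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "seep_pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  result <- tryCatch({
    # -- simulate / read ---------------------------------------------------
    profiles <- if (!is.null(config$profile_table)) {
      pipeline_log(verbose, stage, paste("reading", config$profile_table))
      read_profile_table(config$profile_table)
    } else {
      sp <- config$anchors
      sp$seed <- as.integer(config$seeds$simulate)
      pipeline_log(verbose, stage,
                   paste("generating synthetic profiles, seed", sp$seed))
      generate_anchor_profiles(sp, sigma_scale = config$sigma_scale)
    }
    write_profile_table(profiles, file.path(out_dir, "profiles.csv"))

    # -- zonate ------------------------------------------------------------
    stage <- "zonate"
    zones <- zonate(profiles)
    pipeline_log(verbose, stage, sprintf("z1 = %.1f, z2 = %.1f cm",
                                         zones$z1, zones$z2))
    readr::write_csv(zones$zones, file.path(out_dir, "zones.csv"))

    # -- calibrate ---------------------------------------------------------
    stage <- "calibrate"
    scn <- config$scenario
    cal <- NULL
    if (!is.null(config$calibration)) {
      cc <- config$calibration
      search_scn <- scn
      search_scn$dz <- cc$dz %||% scn$dz
      pipeline_log(verbose, stage,
                   paste("fitting", paste(names(cc$free), collapse = ", ")))
      cal <- calibrate(search_scn, profiles, free = cc$free,
                       weights = cc$weights, maxit = cc$maxit,
                       n_starts = cc$n_starts,
                       seed = as.integer(config$seeds$calibrate))
      scn <- cal$scenario
      scn$dz <- config$scenario$dz
      readr::write_csv(cal$parameters,
                       file.path(out_dir, "calibration.csv"))
    }

    # -- solve -------------------------------------------------------------
    stage <- "solve"
    ms <- solve_steady_state(scn)
    pipeline_log(verbose, stage,
                 sprintf("converged, max misclosure %.2g%%",
                         100 * max(ms$mass_balance$relative_misclosure)))
    readr::write_csv(conc_profiles(ms),
                     file.path(out_dir, "concentrations.csv"))
    readr::write_csv(rate_profiles(ms), file.path(out_dir, "rates.csv"))
    readr::write_csv(ms$mass_balance,
                     file.path(out_dir, "massbalance.csv"))

    # -- flux --------------------------------------------------------------
    stage <- "flux"
    site <- scn$site
    mn_series <- profiles$porewater$Mn2
    if (is.null(mn_series)) stop("no Mn2 series for the flux stage",
                                 call. = FALSE)
    zbar <- mean(config$mn_window)
    phi_bar <- porosity_profile(site, zbar)$phi
    ds <- tortuosity_correct(
      diffusion_coefficient("Mn2", site$temperature, site$salinity),
      phi_bar, model = scn$tortuosity)
    mn_flux <- fick_flux(mn_series, config$mn_window, Ds = ds,
                         phi = phi_bar, minimum_estimate = TRUE)
    pipeline_log(verbose, stage,
                 sprintf("J(Mn2+) = %.3f umol cm-2 yr-1 (%s)", mn_flux$J,
                         mn_flux$direction))
    readr::write_csv(tibble::as_tibble(unclass(mn_flux)),
                     file.path(out_dir, "mn_flux.csv"))

    # -- budget ------------------------------------------------------------
    stage <- "budget"
    budget <- budget_summary(ms, zones, mn_flux)
    readr::write_csv(budget$partition, file.path(out_dir, "budget.csv"))
    readr::write_csv(budget_row(budget), file.path(out_dir,
                                                   "budget_row.csv"))

    # -- sensitivity -------------------------------------------------------
    stage <- "sensitivity"
    sens_scn <- scn
    sens_scn$dz <- max(scn$dz, 5)  # coarse grid is ample for deviations
    sens <- sensitivity_sedimentation(sens_scn)
    readr::write_csv(sens$profiles, file.path(out_dir, "sensitivity.csv"))

    # -- correlate ---------------------------------------------------------
    stage <- "correlate"
    wide <- as_tibble(profiles) |>
      dplyr::filter(.data$phase != "solid") |>
      dplyr::select("depth", "analyte", "value") |>
      tidyr::pivot_wider(names_from = "analyte",
                         values_from = "value")
    corr <- spearman_matrix(wide[setdiff(names(wide), "depth")])
    readr::write_csv(corr$pairs, file.path(out_dir, "correlations.csv"))

    list(profiles = profiles, zones = zones, calibration = cal,
         model_state = ms, mn_flux = mn_flux, budget = budget,
         sensitivity = sens, correlations = corr)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("seepaom")),
    r_version = as.character(getRversion()),
    seeds = config$seeds,
    sigma_scale = config$sigma_scale,
    mn_window = config$mn_window,
    parameters = result$model_state$scenario$params,
    alpha = result$model_state$scenario$alpha,
    calibrated = !is.null(result$calibration))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(result)
}
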