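# Discretization helpers ----------------------------------------------------

# Precompute everything the RHS needs: grid, porosity, interface
# diffusivities, advective volume fluxes, irrigation mask.
build_discretization <- function(scn) {
  n <- max(round(scn$core_length / scn$dz), 2) + 1
  z <- seq(0, scn$core_length, length.out = n)
  scn$dz <- z[2] - z[1]
  site <- scn$site
  por <- porosity_profile(site, z)
  phi <- por$phi
  dz_eff <- z[2] - z[1]
  dzc <- rep(dz_eff, n); dzc[c(1, n)] <- dz_eff / 2  # cell widths
  spp <- model_species()
  diss <- spp$species[spp$phase == "dissolved"]
  sol <- spp$species[spp$phase == "solid"]
  # interface phi*Ds per dissolved species (harmonic mean of nodal values)
  phiDs <- lapply(diss, function(sp) {
    d0 <- diffusion_coefficient(sp, site$temperature, site$salinity)
    ds <- tortuosity_correct(d0, phi, model = scn$tortuosity)
    nodal <- phi * ds
    2 / (1 / nodal[-n] + 1 / nodal[-1])
  })
  names(phiDs) <- diss
  u_up <- scn$u_up %||% 0
  list(z = z, n = n, phi = phi, dzc = dzc, dz = dz_eff,
       diss = diss, sol = sol, phiDs = phiDs,
       q_pw = site$phi_inf * site$w_inf - u_up,   # porewater volume flux
       q_sol = (1 - site$phi_inf) * site$w_inf,   # solid volume flux
       alpha_z = ifelse(z <= scn$L_irr, scn$alpha, 0),
       rxns = reaction_network(scn$params))
}

# advective flux at interfaces for volume flux q (scalar, signed, positive
# downward) with first-order upwinding; conc is the nodal vector
upwind_flux <- function(q, conc) {
  if (q >= 0) q * conc[-length(conc)] else q * conc[-1]
}

# RHS of the method-of-lines system; y is the full state vector
rtm_rhs <- function(t, y, ctx) {
  d <- ctx$disc
  scn <- ctx$scn
  n <- d$n
  Y <- matrix(y, nrow = n)
  colnames(Y) <- c(d$diss, d$sol)
  Yg <- pmax(Y, 0)   # guard for rate laws
  state <- stats::setNames(lapply(seq_len(ncol(Y)), function(j) Yg[, j]),
                           colnames(Y))
  net <- net_rates(state, d$z, d$phi, scn$params, network = d$rxns)$net_bulk
  dY <- matrix(0, n, ncol(Y))
  colnames(dY) <- colnames(Y)
  for (sp in d$diss) {
    C <- Y[, sp]
    fd <- -d$phiDs[[sp]] * diff(C) / d$dz
    fa <- upwind_flux(d$q_pw, C)
    f <- fd + fa
    # boundary fluxes: top handled by Dirichlet (dC1/dt = 0); bottom
    # zero-diffusive-gradient with advective outflow unless fixed
    f_bot <- if (d$q_pw >= 0) d$q_pw * C[n] else d$q_pw * C[n]
    flux <- c(0, f, f_bot)
    dC <- (flux[-(n + 1)] - flux[-1]) / (d$phi * d$dzc) +
      d$alpha_z * (scn$top_bc[[sp]] - C) + net[[sp]] / d$phi
    dC[1] <- 0
    if (scn$bottom_bc[[sp]]$kind == "fixed") dC[n] <- 0
    dY[, sp] <- dC
  }
  for (sp in d$sol) {
    S <- Y[, sp]
    g <- upwind_flux(d$q_sol, S)
    flux <- c(scn$solid_flux[[sp]], g, d$q_sol * S[n])
    dY[, sp] <- (flux[-(n + 1)] - flux[-1]) / ((1 - d$phi) * d$dzc) +
      net[[sp]] / (1 - d$phi)
  }
  list(as.vector(dY))
}

initial_state <- function(scn, d) {
  Y <- matrix(0, d$n, length(d$diss) + length(d$sol))
  colnames(Y) <- c(d$diss, d$sol)
  for (sp in d$diss) Y[, sp] <- scn$top_bc[[sp]]
  Y[-1, "CH4"] <- 0
  for (sp in d$diss) {
    # boundary nodes are held at their conditions (dC/dt = 0 there)
    Y[1, sp] <- scn$top_bc[[sp]]
    bc <- scn$bottom_bc[[sp]]
    if (bc$kind == "fixed") Y[d$n, sp] <- bc$value
  }
  for (sp in d$sol) {
    Y[, sp] <- if (d$q_sol > 0) scn$solid_flux[[sp]] / d$q_sol else 0
  }
  Y
}

# Steady-state solve ---------------------------------------------------------

#' Solve the reaction-transport model to steady state
#'
#' Discretises the coupled advection-diffusion-irrigation-reaction
#' equations by a conservative finite-volume scheme (harmonic-mean
#' interface diffusivities, first-order upwind advection) on a uniform
#' vertex-centred grid, then marches the transient system in pseudo-time
#' with a stiff implicit integrator (`deSolve::ode`, `lsodes`) until the
#' largest scaled tendency `|dC/dt|` falls below the scenario tolerance.
#' A per-species steady-state mass balance (boundary fluxes + irrigation +
#' net reaction) is computed and must close to within 1 %.
#'
#' @param scn A [scenario()].
#' @param check_balance If `TRUE` (default), error when any species'
#'   steady-state mass balance miscloses by more than 1 %.
#' @param init Optional `seep_model_state` used as a warm start (its
#'   concentration profiles are interpolated onto the scenario grid);
#'   useful when solving many nearby parameter sets, as in calibration.
#' @return An object of class `seep_model_state`: list with `z`,
#'   `conc` (matrix, umol cm^-3 own phase), `rates` (matrix of bulk
#'   reaction rates, umol cm^-3 bulk yr^-1), `mass_balance` (tibble),
#'   `diagnostics` (convergence info) and the scenario.
#' @export
solve_steady_state <- function(scn, check_balance = TRUE, init = NULL) {
  stopifnot(inherits(scn, "seep_scenario"))
  d <- build_discretization(scn)
  ctx <- list(disc = d, scn = scn)
  Y <- initial_state(scn, d)
  if (!is.null(init) && inherits(init, "seep_model_state")) {
    for (sp in colnames(Y)) {
      Y[, sp] <- stats::approx(init$z, init$conc[, sp], xout = d$z,
                               rule = 2, ties = "ordered")$y
    }
    for (sp in d$diss) {
      Y[1, sp] <- scn$top_bc[[sp]]
      bc <- scn$bottom_bc[[sp]]
      if (bc$kind == "fixed") Y[d$n, sp] <- bc$value
    }
  }
  y <- as.vector(Y)
  tol <- scn$solver$tol_rel
  t_done <- 0
  residuals <- NULL
  steps <- 0L
  t_max <- scn$solver$t_max
  warm <- !is.null(init)
  for (round in 1:3) {
    seg <- if (warm && round == 1) c(500, 5000, t_max) else
      c(200, 1000, 5000, 25000, t_max - t_done)
    times <- unique(c(0, pmin(seg, t_max - t_done)))
    times <- times[times >= 0]
    if (length(times) < 2) break
    out <- suppressWarnings(
      deSolve::ode(y = y, times = times, func = rtm_rhs,
                   parms = ctx, method = "lsodes", maxsteps = 50000,
                   atol = scn$solver$atol, rtol = scn$solver$rtol))
    last <- max(which(stats::complete.cases(out)))
    steps <- steps + attr(out, "istate")[3]
    y <- out[last, -1]
    t_done <- t_done + out[last, 1]
    dy <- matrix(rtm_rhs(t_done, y, ctx)[[1]], nrow = d$n)
    Ym <- matrix(y, nrow = d$n)
    scale <- pmax(apply(abs(Ym), 2, max), 1e-6)
    residuals <- apply(abs(dy), 2, max) / scale
    names(residuals) <- c(d$diss, d$sol)
    if (max(residuals) < tol || t_done >= t_max) break
  }
  converged <- max(residuals) < tol
  Y <- matrix(y, nrow = d$n)
  colnames(Y) <- c(d$diss, d$sol)
  neg <- min(Y)
  if (neg < -1e-6 * max(abs(Y))) {
    bad <- which(Y == neg, arr.ind = TRUE)[1, ]
    stop("negative concentration in species ", colnames(Y)[bad[2]],
         " at depth ", d$z[bad[1]], " cm (", signif(neg, 3), ")",
         call. = FALSE)
  }
  Y[Y < 0] <- 0
  state <- stats::setNames(lapply(seq_len(ncol(Y)), function(j) Y[, j]),
                           colnames(Y))
  nr <- net_rates(state, d$z, d$phi, scn$params, network = d$rxns)
  rates <- do.call(cbind, nr$reaction_rates)
  mb <- steady_mass_balance(scn, d, Y, nr$net_bulk)
  if (!converged) {
    stop("steady state not reached within t_max = ", scn$solver$t_max,
         " yr; residuals: ",
         paste(names(residuals), signif(residuals, 2), collapse = ", "),
         call. = FALSE)
  }
  if (check_balance && any(mb$relative_misclosure > 0.01)) {
    bad <- mb$species[mb$relative_misclosure > 0.01]
    stop("steady-state mass balance misclosure > 1% for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(scenario = scn, z = d$z, conc = Y, rates = rates,
         mass_balance = mb,
         diagnostics = list(converged = converged, residuals = residuals,
                            pseudo_time = t_done, steps = steps)),
    class = "seep_model_state")
}

# Integrated steady-state balance per species: influx - outflux +
# irrigation + net reaction must vanish.
steady_mass_balance <- function(scn, d, Y, net_bulk) {
  n <- d$n
  rows <- lapply(c(d$diss, d$sol), function(sp) {
    if (sp %in% d$diss) {
      C <- Y[, sp]
      fixed_bot <- scn$bottom_bc[[sp]]$kind == "fixed"
      # balance over interior cells (held boundary nodes excluded)
      keep <- if (fixed_bot) 2:(n - 1) else 2:n
      f_top <- -d$phiDs[[sp]][1] * (C[2] - C[1]) / d$dz +
        upwind_flux(d$q_pw, C[1:2])
      f_bot <- if (fixed_bot) {
        -d$phiDs[[sp]][n - 1] * (C[n] - C[n - 1]) / d$dz +
          upwind_flux(d$q_pw, C[(n - 1):n])
      } else {
        d$q_pw * C[n]
      }
      w <- d$dzc[keep]
      irr <- sum((d$phi * d$alpha_z * (scn$top_bc[[sp]] - C))[keep] * w)
      rxn <- sum(net_bulk[[sp]][keep] * w)
      turnover <- sum(abs(net_bulk[[sp]][keep]) * w)
    } else {
      S <- Y[, sp]
      f_top <- scn$solid_flux[[sp]]
      f_bot <- d$q_sol * S[n]
      irr <- 0
      rxn <- sum(net_bulk[[sp]] * d$dzc)
      turnover <- sum(abs(net_bulk[[sp]]) * d$dzc)
    }
    terms <- c(f_top, -f_bot, irr, rxn)
    tibble::tibble(species = sp, influx_top = f_top, outflux_bottom = f_bot,
                   irrigation = irr, net_reaction = rxn,
                   misclosure = sum(terms),
                   relative_misclosure =
                     abs(sum(terms)) / max(abs(terms), turnover, 1e-12))
  })
  dplyr::bind_rows(rows)
}

#' @export
print.seep_model_state <- function(x, ...) {
  cat(sprintf(paste0("<model state> %d nodes (0-%g cm), converged: %s ",
                     "(pseudo-time %g yr)\n"),
              length(x$z), max(x$z), x$diagnostics$converged,
              x$diagnostics$pseudo_time))
  cat(sprintf("max mass-balance misclosure: %.3g%%\n",
              100 * max(x$mass_balance$relative_misclosure)))
  invisible(x)
}

#' Concentration profiles of a solved model
#'
#' @param ms A `seep_model_state`.
#' @return Long tibble with `z`, `species`, `phase`, `conc`
#'   (umol cm^-3 of the species' own phase).
#' @export
conc_profiles <- function(ms) {
  stopifnot(inherits(ms, "seep_model_state"))
  spp <- model_species()
  purrr::map_dfr(colnames(ms$conc), function(sp) {
    tibble::tibble(z = ms$z, species = sp,
                   phase = spp$phase[match(sp, spp$species)],
                   conc = ms$conc[, sp])
  })
}

#' Reaction-rate profiles of a solved model
#'
#' @param ms A `seep_model_state`.
#' @return Long tibble with `z`, `reaction`, `rate` (umol cm^-3 bulk
#'   sediment yr^-1, on each reaction's extent basis — mol CH4 for the
#'   AOM pathways).
#' @export
rate_profiles <- function(ms) {
  stopifnot(inherits(ms, "seep_model_state"))
  purrr::map_dfr(colnames(ms$rates), function(r) {
    tibble::tibble(z = ms$z, reaction = r, rate = ms$rates[, r])
  })
}

#' Grid-refinement self-verification
#'
#' Solves the same scenario at spacings `dz`, `dz/2`, `dz/4`, ... and
#' reports a scalar functional (depth-integrated S-AOM rate by default) at
#' each resolution together with the observed convergence order. With
#' first-order upwind advection the expected order is >= 1.
#'
#' @param scn A [scenario()].
#' @param factors Refinement factors relative to `scn$dz` (default
#'   `c(1, 2, 4)` meaning dz, dz/2, dz/4).
#' @param functional Function mapping a `seep_model_state` to a scalar;
#'   default integrates the S-AOM rate over the whole core.
#' @return Tibble with `dz`, `value`, `change` (relative change from the
#'   previous resolution) and an `observed_order` attribute.
#' @export
refine_and_verify <- function(scn, factors = c(1, 2, 4),
                              functional = NULL) {
  if (is.null(functional)) {
    functional <- function(ms) {
      depth_integrate(ms, "S-AOM", c(0, max(ms$z)))
    }
  }
  vals <- purrr::map_dbl(factors, function(f) {
    functional(solve_steady_state(update_dz(scn, scn$dz / f)))
  })
  out <- tibble::tibble(
    dz = scn$dz / factors, value = vals,
    change = c(NA, abs(diff(vals)) / pmax(abs(vals[-length(vals)]), 1e-12)))
  if (length(vals) >= 3) {
    e1 <- abs(vals[2] - vals[1]); e2 <- abs(vals[3] - vals[2])
    r <- factors[2] / factors[1]
    attr(out, "observed_order") <- if (e2 > 0) log(e1 / e2) / log(r) else Inf
    if (e2 > e1) attr(out, "monotone") <- FALSE else
      attr(out, "monotone") <- TRUE
  }
  out
}

update_dz <- function(scn, dz) {
  scn$dz <- dz
  scn
}
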