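#' Controlled vocabulary of analytes
#'
#' Registry of the analyte names understood by the package, together with
#' their phase and canonical unit. Porewater solutes are carried in uM or mM,
#' solid-phase pools in weight percent of dry sediment, and stable-isotope
#' ratios in permil (which may be negative).
#'
#' @return A tibble with columns `analyte`, `phase` and `unit`.
#' @export
#' @examples
#' analyte_registry()
analyte_registry <- function() {
  tibble::tribble(
    ~analyte,    ~phase,          ~unit,
    "CH4",       "dissolved",     "uM",
    "SO4",       "dissolved",     "mM",
    "DIC",       "dissolved",     "mM",
    "Ca",        "dissolved",     "mM",
    "Mg",        "dissolved",     "mM",
    "Fe2",       "dissolved",     "uM",
    "Mn2",       "dissolved",     "uM",
    "PO4",       "dissolved",     "uM",
    "NH4",       "dissolved",     "uM",
    "TA",        "dissolved",     "mM",
    "d13C_CH4",  "isotope-ratio", "permil",
    "d13C_DIC",  "isotope-ratio", "permil",
    "Fe2O3T",    "solid",         "wt%",
    "MnO2T",     "solid",         "wt%",
    "Fe_carb",   "solid",         "wt%",
    "Fe_ox1",    "solid",         "wt%",
    "Fe_mag",    "solid",         "wt%",
    "Fe_py",     "solid",         "wt%"
  )
}

#' One analyte sampled on a depth axis
#'
#' A depth series is the basic data object: one analyte measured (or
#' generated) at strictly increasing depths below the seafloor. Missing
#' values are allowed inside the series (sampling gaps); depths must be
#' finite and strictly increasing, and concentrations must be non-negative
#' (isotope ratios may be negative).
#'
#' @param depth Numeric vector, depth in cm below seafloor (cmbsf),
#'   strictly increasing, length >= 2.
#' @param value Numeric vector of the same length; `NA` allowed.
#' @param analyte Analyte name; names in [analyte_registry()] get their
#'   phase/unit filled in automatically.
#' @param unit Unit string (e.g. `"uM"`, `"mM"`, `"wt%"`, `"permil"`).
#' @param phase One of `"dissolved"`, `"solid"`, `"isotope-ratio"`.
#' @return A tibble of class `seep_depth_series` with columns `depth` and
#'   `value` and attributes `analyte`, `unit`, `phase`.
#' @export
#' @examples
#' depth_series(c(10, 50, 90), c(28, 20, 12), "SO4")
depth_series <- function(depth, value, analyte,
                         unit = NULL, phase = NULL) {
  reg <- analyte_registry()
  hit <- match(analyte, reg$analyte)
  if (is.null(unit)) {
    unit <- if (!is.na(hit)) reg$unit[hit] else "unknown"
  }
  if (is.null(phase)) {
    phase <- if (!is.na(hit)) reg$phase[hit] else "dissolved"
  }
  x <- tibble::tibble(depth = as.numeric(depth), value = as.numeric(value))
  attr(x, "analyte") <- as.character(analyte)
  attr(x, "unit") <- as.character(unit)
  attr(x, "phase") <- match.arg(phase, c("dissolved", "solid", "isotope-ratio"))
  class(x) <- c("seep_depth_series", class(x))
  validate_depth_series(x)
}

#' @export
print.seep_depth_series <- function(x, ...) {
  cat(sprintf("<depth series> %s [%s], %s phase, %d depths (%g-%g cmbsf)\n",
              attr(x, "analyte"), attr(x, "unit"), attr(x, "phase"),
              nrow(x), min(x$depth), max(x$depth)))
  NextMethod()
}

validate_depth_series <- function(x) {
  if (nrow(x) < 2) {
    stop("depth series '", attr(x, "analyte"),
         "' needs at least 2 depths, got ", nrow(x), call. = FALSE)
  }
  if (anyNA(x$depth) || any(!is.finite(x$depth))) {
    stop("depth series '", attr(x, "analyte"),
         "' has non-finite depths", call. = FALSE)
  }
  dd <- diff(x$depth)
  if (any(dd <= 0)) {
    bad <- which(dd <= 0)
    stop("depth series '", attr(x, "analyte"),
         "' depths must be strictly increasing; offending rows: ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  }
  if (attr(x, "phase") != "isotope-ratio" &&
      any(x$value < 0, na.rm = TRUE)) {
    stop("depth series '", attr(x, "analyte"),
         "' has negative concentrations", call. = FALSE)
  }
  x
}

#' Site metadata for a sediment core
#'
#' Physical setting of a core: water depth, bottom-water conditions, the
#' steady-state compaction model (porosity decays exponentially from
#' `phi_0` at the sediment surface to `phi_inf` at depth with e-folding
#' `lambda`), the burial velocity at depth, and grain/porewater densities.
#' Defaults are typical continental-slope values for a deep-water seep site.
#'
#' @param core_id Core identifier.
#' @param water_depth Water depth, m.
#' @param temperature Bottom-water temperature, degC.
#' @param salinity Salinity, PSU.
#' @param phi_0 Porosity at the sediment-water interface (0-1).
#' @param phi_inf Porosity at depth (0-1), `phi_inf <= phi_0`.
#' @param lambda Porosity e-folding depth, cm.
#' @param w_inf Burial (sedimentation) velocity at depth, cm yr-1.
#' @param rho_solid Dry solid density, g cm-3.
#' @param rho_porewater Porewater density, g cm-3.
#' @return A list of class `seep_site`.
#' @export
site_metadata <- function(core_id = "SYN-CORE",
                          water_depth = 1375,
                          temperature = 3.5,
                          salinity = 34.6,
                          phi_0 = 0.80,
                          phi_inf = 0.60,
                          lambda = 100,
                          w_inf = 0.05,
                          rho_solid = 2.65,
                          rho_porewater = 1.0) {
  stopifnot(phi_inf > 0, phi_inf <= phi_0, phi_0 < 1,
            lambda > 0, w_inf > 0, rho_solid > rho_porewater)
  structure(
    list(core_id = core_id, water_depth = water_depth,
         temperature = temperature, salinity = salinity,
         phi_0 = phi_0, phi_inf = phi_inf, lambda = lambda,
         w_inf = w_inf, rho_solid = rho_solid,
         rho_porewater = rho_porewater),
    class = "seep_site")
}

#' Porosity and burial velocities at depth
#'
#' Steady-state compaction: porosity `phi(z) = phi_inf + (phi_0 - phi_inf)
#' exp(-z / lambda)`; the solid burial velocity satisfies
#' `(1 - phi) w = (1 - phi_inf) w_inf` and the porewater burial velocity
#' `phi v = phi_inf w_inf` (no externally impressed flow).
#'
#' @param site A [site_metadata()] object.
#' @param z Depth, cm (vectorised).
#' @return A tibble with columns `z`, `phi`, `w_solid`, `v_porewater`.
#' @export
porosity_profile <- function(site, z) {
  phi <- site$phi_inf + (site$phi_0 - site$phi_inf) * exp(-z / site$lambda)
  tibble::tibble(
    z = z,
    phi = phi,
    w_solid = (1 - site$phi_inf) * site$w_inf / (1 - phi),
    v_porewater = site$phi_inf * site$w_inf / phi
  )
}

#' Bundle of porewater and solid-phase profiles for one core
#'
#' @param metadata A [site_metadata()] object.
#' @param porewater Named list of [depth_series()] (dissolved and
#'   isotope-ratio phases).
#' @param solids Named list of [depth_series()] (solid phase).
#' @return A list of class `seep_profile_set`.
#' @export
profile_set <- function(metadata = site_metadata(),
                        porewater = list(), solids = list()) {
  stopifnot(inherits(metadata, "seep_site"))
  chk <- function(lst, allowed) {
    for (nm in names(lst)) {
      s <- lst[[nm]]
      if (!inherits(s, "seep_depth_series")) {
        stop("profile '", nm, "' is not a depth_series", call. = FALSE)
      }
      validate_depth_series(s)
      if (!attr(s, "phase") %in% allowed) {
        stop("profile '", nm, "' has phase '", attr(s, "phase"),
             "', expected one of: ", paste(allowed, collapse = ", "),
             call. = FALSE)
      }
    }
  }
  chk(porewater, c("dissolved", "isotope-ratio"))
  chk(solids, "solid")
  structure(list(metadata = metadata, porewater = porewater,
                 solids = solids),
            class = "seep_profile_set")
}

#' @export
print.seep_profile_set <- function(x, ...) {
  cat(sprintf("<profile set> core %s: %d porewater, %d solid series\n",
              x$metadata$core_id, length(x$porewater), length(x$solids)))
  invisible(x)
}

all_series <- function(ps) c(ps$porewater, ps$solids)

#' Long-format view of a profile set
#'
#' @param x A `seep_profile_set`.
#' @param ... Unused.
#' @return Tibble with columns `depth`, `analyte`, `value`, `unit`, `phase`.
#' @export
as_tibble.seep_profile_set <- function(x, ...) {
  purrr::map_dfr(all_series(x), function(s) {
    tibble::tibble(depth = s$depth, analyte = attr(s, "analyte"),
                   value = s$value, unit = attr(s, "unit"),
                   phase = attr(s, "phase"))
  })
}

parse_header_unit <- function(h) {
  m <- regmatches(h, regexec("^([^][]+)\\[([^][]*)\\]$", h))[[1]]
  if (length(m) == 3) list(analyte = trimws(m[2]), unit = trimws(m[3]))
  else list(analyte = trimws(h), unit = NA_character_)
}

#' Read a delimited depth-profile table
#'
#' Reads a UTF-8 comma- or tab-delimited table (auto-detected) whose first
#' column is depth in cmbsf (named `depth_cmbsf` or `depth`) and whose
#' remaining columns are analytes, optionally with units in the header as
#' `analyte[unit]`. Unknown analytes are kept, with phase and unit taken
#' from `format_spec` when given, else defaulting to a dissolved phase.
#' Empty cells become missing values.
#'
#' @param path Path to the file.
#' @param format_spec Optional named list mapping column name to a list with
#'   elements `unit` and/or `phase`, overriding header/registry inference.
#' @param metadata A [site_metadata()] for the returned set.
#' @return A [profile_set()].
#' @export
read_profile_table <- function(path, format_spec = NULL,
                               metadata = site_metadata()) {
  first <- readLines(path, n = 1L, warn = FALSE)
  delim <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"), comment.char = "",
                          quote = "\"")
  headers <- names(df)
  dcol <- grep("^depth", trimws(vapply(headers, function(h)
    parse_header_unit(h)$analyte, character(1))), ignore.case = TRUE)
  if (length(dcol) == 0) {
    stop("no depth column found in '", path,
         "' (expected first column 'depth_cmbsf' or 'depth')", call. = FALSE)
  }
  dcol <- dcol[1]
  depth <- df[[dcol]]
  if (!is.numeric(depth)) {
    bad <- which(is.na(suppressWarnings(as.numeric(depth))) & !is.na(depth))
    stop("unparseable depth values at rows: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(diff(depth) <= 0)) {
    bad <- which(diff(depth) <= 0) + 1L
    stop("depth column not strictly increasing; offending rows: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  reg <- analyte_registry()
  porewater <- list(); solids <- list()
  for (j in setdiff(seq_along(headers), dcol)) {
    info <- parse_header_unit(headers[j])
    nm <- info$analyte
    v <- df[[j]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v) & trimws(v) != "")
      if (length(bad)) {
        stop("unparseable numeric values in column '", nm,
             "' at rows: ", paste(bad, collapse = ", "), call. = FALSE)
      }
      v <- conv
    }
    spec <- format_spec[[nm]]
    unit <- spec$unit %||% (if (!is.na(info$unit)) info$unit else NULL)
    phase <- spec$phase %||% NULL
    s <- depth_series(depth, v, nm, unit = unit, phase = phase)
    if (attr(s, "phase") == "solid") solids[[nm]] <- s
    else porewater[[nm]] <- s
  }
  profile_set(metadata, porewater, solids)
}

#' Write a profile set as a delimited table
#'
#' One row per depth of the union grid of all series, one column per
#' analyte with its unit in the header (`analyte[unit]`); depths where a
#' series was not sampled are left empty. Values are written with 15
#' significant digits so a read/write round trip preserves them to at
#' least 12 significant digits.
#'
#' @param ps A [profile_set()].
#' @param path Output path.
#' @param delim Delimiter, `","` (default) or `"\t"`.
#' @return Invisibly, `path`.
#' @export
write_profile_table <- function(ps, path, delim = ",") {
  ser <- all_series(ps)
  if (length(ser) == 0) stop("profile set has no series", call. = FALSE)
  grid <- sort(unique(unlist(lapply(ser, function(s) s$depth))))
  cols <- lapply(ser, function(s) s$value[match(grid, s$depth)])
  names(cols) <- vapply(ser, function(s)
    sprintf("%s[%s]", attr(s, "analyte"), attr(s, "unit")), character(1))
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.15g", v))
  out <- cbind(`depth_cmbsf[cm]` = fmt(grid),
               do.call(cbind, lapply(cols, fmt)))
  lines <- c(paste(colnames(out), collapse = delim),
             apply(out, 1, paste, collapse = delim))
  tryCatch(writeLines(lines, path),
           error = function(e) stop("cannot write '", path, "': ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Linearly interpolate a depth series onto a new grid
#'
#' Exact at original nodes; refuses to extrapolate outside the sampled
#' depth range. Missing values are dropped before interpolation.
#'
#' @param series A [depth_series()].
#' @param grid Numeric vector of query depths, cm.
#' @return A [depth_series()] on `grid` (sorted).
#' @export
#' @examples
#' s <- depth_series(c(0, 100), c(10, 20), "SO4")
#' regrid(s, 50)$value  # 15
regrid <- function(series, grid) {
  stopifnot(inherits(series, "seep_depth_series"))
  ok <- !is.na(series$value)
  if (sum(ok) < 2) {
    stop("need at least 2 non-missing values to regrid '",
         attr(series, "analyte"), "'", call. = FALSE)
  }
  d <- series$depth[ok]; v <- series$value[ok]
  grid <- sort(as.numeric(grid))
  if (min(grid) < min(d) || max(grid) > max(d)) {
    stop("regrid would extrapolate: grid [", min(grid), ", ", max(grid),
         "] outside sampled range [", min(d), ", ", max(d), "] of '",
         attr(series, "analyte"), "'", call. = FALSE)
  }
  out <- stats::approx(d, v, xout = grid, method = "linear", ties = "ordered")
  res <- tibble::tibble(depth = out$x, value = out$y)
  attr(res, "analyte") <- attr(series, "analyte")
  attr(res, "unit") <- attr(series, "unit")
  attr(res, "phase") <- attr(series, "phase")
  class(res) <- c("seep_depth_series", class(res))
  res  # may be a single-depth query; skip the length-2 constructor check
}

# convert a dissolved-phase value to umol cm^-3 porewater (= mM)
to_umol_cm3 <- function(value, unit) {
  switch(unit,
         "uM" = value * 1e-3,
         "mM" = value,
         "umol/cm3" = value,
         stop("cannot convert unit '", unit, "' to umol cm^-3", call. = FALSE))
}

from_umol_cm3 <- function(value, unit) {
  switch(unit,
         "uM" = value * 1e3,
         "mM" = value,
         "umol/cm3" = value,
         stop("cannot convert unit '", unit, "' from umol cm^-3",
              call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
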