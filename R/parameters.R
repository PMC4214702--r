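#' @importFrom tibble tibble as_tibble
#' @importFrom rlang abort
NULL

.fields <- c("c", "q", "M", "rho", "Rg", "beta", "T", "h", "e", "w")

.field_labels <- c(
  c = "tumor cells", q = "M-CSF", M = "MDSC", rho = "IL-35",
  Rg = "Treg", beta = "TGF-beta", T = "CD8+ T cells", h = "VEGF",
  e = "endothelial cells", w = "oxygen")

#' Read the transcribed model parameter table
#'
#' Returns the versioned parameter file shipped with the package: one row per
#' model constant with its dimensional value, unit, the scaling rule that maps
#' it to dimensionless form, and the stored dimensionless value. All code
#' paths read constants from this table; nothing is hard-coded.
#'
#' @return A tibble with columns `name`, `group`, `value`, `unit`,
#'   `nd_scale`, `description`, `nd_value`.
#' @export
parameter_table <- function() {
  path <- system.file("extdata", "parameters.csv", package = "il35sim",
                      mustWork = TRUE)
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Symbol-to-equation map
#'
#' Machine-readable audit trail: which equation and which term each named
#' constant enters.
#'
#' @return A tibble with columns `name`, `equation`, `term`.
#' @export
symbol_map <- function() {
  path <- system.file("extdata", "symbol_map.csv", package = "il35sim",
                      mustWork = TRUE)
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

scenario_table <- function() {
  path <- system.file("extdata", "scenarios.csv", package = "il35sim",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Reference scales for nondimensionalization
#'
#' One reference magnitude per field (cell densities, cytokine
#' concentrations, oxygen), a reference length (the tumor radius) and a
#' reference time (one day), plus references for the three mediators folded
#' into the MDSC terms (IL-10, IL-12, MCP-1).
#'
#' @param ... Named overrides of individual scale factors.
#' @return An object of class `il35_scaling`.
#' @export
default_scaling <- function(...) {
  s <- list(L = 0.5, tau = 1, cref = 0.4, qref = 1e-9, Mref = 1e-2,
            rhoref = 1e-10, Rref = 1e-3, betaref = 1e-10, Tref = 1e-2,
            href = 1e-9, eref = 5e-3, wref = 5e-6,
            il10ref = 1e-10, il12ref = 1e-11, mcpref = 1e-9)
  ov <- list(...)
  bad <- setdiff(names(ov), names(s))
  if (length(bad)) abort(paste0("unknown scale factor(s): ",
                                paste(bad, collapse = ", ")))
  s[names(ov)] <- ov
  if (any(vapply(s, function(x) !is.finite(x) || x <= 0, logical(1))))
    abort("all scale factors must be finite and strictly positive")
  structure(s, class = "il35_scaling")
}

#' Field reference magnitudes as a named vector
#'
#' @param s An `il35_scaling` object.
#' @return Named numeric vector over the ten fields, in field order.
#' @export
field_refs <- function(s = default_scaling()) {
  stats::setNames(
    c(s$cref, s$qref, s$Mref, s$rhoref, s$Rref, s$betaref, s$Tref, s$href,
      s$eref, s$wref), .fields)
}

#' Load a scenario parameter set
#'
#' The two presets correspond to the two tumor lines simulated by the model:
#' `"J558-IL-35"` (tumor cells transfected to secrete IL-35 at a high rate)
#' and `"J558-Ctrl"` (control line secreting very little IL-35). The presets
#' differ only in `lambda_rho_c`, the tumor IL-35 production rate. A path to
#' a YAML config file with fields `scenario` and (optionally) `overrides`
#' may be given instead of a preset name.
#'
#' @param name Scenario id (`"J558-IL-35"` or `"J558-Ctrl"`) or a file path.
#' @param overrides Named list of parameter overrides applied after the
#'   preset; every override must name a known, strictly positive parameter
#'   (except the fraction parameters, which must lie in (0, 1]).
#' @return A validated `il35_params` object (named list of constants with a
#'   `scenario` attribute).
#' @export
load_scenario <- function(name = "J558-IL-35", overrides = list()) {
  if (file.exists(name) && !name %in% scenario_table()$scenario) {
    cfg <- yaml::read_yaml(name)
    if (is.null(cfg$scenario)) abort("config file must name a `scenario`")
    ov <- c(cfg$overrides, overrides)
    return(load_scenario(cfg$scenario, overrides = ov))
  }
  scen <- scenario_table()
  if (!name %in% scen$scenario)
    abort(paste0("unknown scenario: '", name, "' (expected one of ",
                 paste(scen$scenario, collapse = ", "),
                 " or an existing config path)"))
  tab <- parameter_table()
  p <- stats::setNames(as.list(tab$value), tab$name)
  row <- scen[scen$scenario == name, ]
  p[[row$parameter]] <- row$value
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(p))
    if (length(bad)) abort(paste0("unknown parameter(s) in overrides: ",
                                  paste(bad, collapse = ", ")))
    p[names(overrides)] <- overrides
  }
  p <- structure(p, class = "il35_params", scenario = name)
  validate_params(p)
  p
}

#' @rdname load_scenario
#' @param scenario Scenario id passed through to [load_scenario()].
#' @param ... Individual parameter overrides.
#' @export
il35_params <- function(scenario = "J558-IL-35", ...) {
  load_scenario(scenario, overrides = list(...))
}

#' Validate a parameter set
#'
#' Checks strict positivity of every rate, diffusion coefficient, density and
#' threshold; the oxygen threshold ordering `0 < w_nec < w_hyp < w_normal`
#' and `0 < w_star < w_normal`; and that the baseline ratios `eps_c`, `eps_M`
#' are below 1.
#'
#' @param p An `il35_params` object or plain named list.
#' @return Invisibly `TRUE`; aborts with a message naming the offending
#'   parameter otherwise.
#' @export
validate_params <- function(p) {
  needed <- parameter_table()$name
  missing <- setdiff(needed, names(p))
  if (length(missing)) abort(paste0("missing parameter(s): ",
                                    paste(missing, collapse = ", ")))
  vals <- unlist(p[needed])
  bad <- needed[!is.finite(vals) | vals <= 0]
  if (length(bad)) abort(paste0("non-positive or non-finite parameter(s): ",
                                paste(bad, collapse = ", ")))
  if (!(p$w_nec < p$w_hyp && p$w_hyp < p$w_normal))
    abort("oxygen thresholds must satisfy 0 < w_nec < w_hyp < w_normal")
  if (!(p$w_star < p$w_normal))
    abort("w_star must lie below w_normal")
  if (p$eps_c >= 1 || p$eps_M >= 1)
    abort("baseline VEGF ratios eps_c and eps_M must be < 1")
  for (f in c("e_init_frac", "w_init_frac"))
    if (p[[f]] > 1) abort(paste0(f, " must lie in (0, 1]"))
  invisible(TRUE)
}

nd_factors <- function(s) {
  tab <- parameter_table()
  env <- list2env(unclass(s))
  stats::setNames(
    vapply(tab$nd_scale, function(e) eval(parse(text = e), envir = env),
           numeric(1)),
    tab$name)
}

#' Map a dimensional parameter set to dimensionless form
#'
#' Each constant is multiplied by the scale factor recorded for it in the
#' parameter table (a product of the reference length, time and field
#' magnitudes of `s`), yielding the constants of the dimensionless system
#' that is actually integrated.
#'
#' @param p An `il35_params` object.
#' @param s An `il35_scaling` object.
#' @return An `il35_params_nd` object (named list, same names as `p`).
#' @export
nondimensionalize <- function(p, s = default_scaling()) {
  stopifnot(inherits(s, "il35_scaling"))
  f <- nd_factors(s)
  out <- as.list(unlist(p[names(f)]) * f)
  structure(out, class = "il35_params_nd", scenario = attr(p, "scenario"))
}

#' Map a dimensionless parameter set back to dimensional form
#'
#' Exact inverse of [nondimensionalize()] under the same scaling.
#'
#' @param pn An `il35_params_nd` object.
#' @param s An `il35_scaling` object.
#' @return An `il35_params` object.
#' @export
redimensionalize <- function(pn, s = default_scaling()) {
  stopifnot(inherits(s, "il35_scaling"))
  f <- nd_factors(s)
  out <- as.list(unlist(pn[names(f)]) / f)
  structure(out, class = "il35_params", scenario = attr(pn, "scenario"))
}

#' Calibrate the IL-35-enhanced MDSC production rate
#'
#' Uses the simplified, space-free MDSC balances of the two scenarios: in the
#' control arm `dM/dt = s_M - d_M M`, in the IL-35 arm the same plus a
#' constant IL-35-attributable source `Lambda = lambda_Mrho * sat`, where
#' `sat` is the (slowly varying) IL-35 saturation. Neglecting the initial
#' MDSC density, both solutions share the factor `(1 - exp(-d_M t))`, so the
#' observed MDSC ratio at the horizon determines
#' `Lambda = (ratio_obs - 1) * s_M` independently of the horizon; the horizon
#' enters only through the neglected transient.
#'
#' @param ratio_obs Observed MDSC ratio (IL-35 arm over control) at the
#'   horizon; must be >= 1.
#' @param d_M MDSC death rate, 1/day.
#' @param horizon Observation time, day.
#' @param s_M Constant MDSC source, g/cm^3/day.
#' @param saturation IL-35 saturation factor `rho/(K_rho + rho)` in (0, 1].
#' @return Estimated `lambda_Mrho`, g/cm^3/day.
#' @export
calibrate_mdsc_production <- function(ratio_obs, d_M, horizon,
                                      s_M = 1e-4, saturation = 0.5) {
  if (!all(is.finite(c(ratio_obs, d_M, horizon, s_M, saturation))))
    abort("all inputs must be finite")
  if (ratio_obs < 1) abort("ratio_obs must be >= 1")
  if (d_M <= 0 || horizon <= 0 || s_M <= 0 || saturation <= 0 ||
      saturation > 1)
    abort("d_M, horizon, s_M must be positive and saturation in (0, 1]")
  (ratio_obs - 1) * s_M / saturation
}

#' Calibrate the tumor IL-35 production rate
#'
#' With tumor density held at a constant `c_bar` and all other IL-35 sources
#' switched off, IL-35 follows the saturating exponential
#' `rho(t) = (lambda * c_bar / d_rho) * (1 - exp(-d_rho * t))`. This inverts
#' that solution for `lambda` given a target concentration at time `t`.
#'
#' @param rho_target Target IL-35 concentration at time `t`, g/cm^3.
#' @param c_bar Constant tumor density, g/cm^3.
#' @param d_rho IL-35 decay rate, 1/day.
#' @param t Observation time, day; `Inf` gives the steady-state limit
#'   `lambda = d_rho * rho_target / c_bar`.
#' @return Estimated `lambda_rho_c`, 1/day.
#' @export
calibrate_il35_production <- function(rho_target, c_bar, d_rho, t) {
  if (!all(is.finite(c(rho_target, c_bar, d_rho))) || is.na(t))
    abort("all inputs must be finite (t may be Inf)")
  if (rho_target <= 0 || c_bar <= 0 || d_rho <= 0 || t <= 0)
    abort("all inputs must be positive")
  growth <- 1 - exp(-d_rho * t)
  if (growth <= 0)
    abort("rho_target is not attainable: no growth over the given time")
  d_rho * rho_target / (c_bar * growth)
}

#' @export
print.il35_params <- function(x, ...) {
  cat("<il35_params> scenario:", attr(x, "scenario") %||% "(custom)",
      "-", length(x), "constants\n")
  invisible(x)
}

#' @export
print.il35_scaling <- function(x, ...) {
  cat("<il35_scaling> L =", x$L, "cm, tau =", x$tau, "day\n")
  invisible(x)
}

#' Tidy a parameter set
#'
#' @param x An `il35_params` object.
#' @param ... Unused.
#' @return A tibble with one row per constant: name, value, unit, group,
#'   description.
#' @method tidy il35_params
#' @export
tidy.il35_params <- function(x, ...) {
  tab <- parameter_table()
  tibble(name = tab$name, value = unlist(x[tab$name]), unit = tab$unit,
         group = tab$group, description = tab$description)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
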