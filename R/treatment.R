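# Anti-IL-35 drug: dosing schedule in time, static spatial profile in r,
# and the sink term coupling the drug to the IL-35 field.

#' Define an anti-IL-35 dosing protocol
#'
#' Three modes: `"none"` (no drug), `"continuous"` (level `A0` throughout the
#' treatment window) and `"intermittent"` (level `2 * A0`, one week on / one
#' week off). Doubling the on-level makes the two active modes deliver the
#' same total dose whenever the window spans whole on/off cycles, which the
#' default 28-day month guarantees.
#'
#' @param mode One of `"none"`, `"continuous"`, `"intermittent"`.
#' @param A0 Dose strength (drug-concentration units), >= 0.
#' @param duration_months Length of the treatment window, months.
#' @param week_days,month_days Calendar convention (defaults 7 and 28 days;
#'   a 28-day month keeps the window a whole number of on/off cycles).
#' @return An `il35_protocol` object.
#' @export
treatment_protocol <- function(mode = c("none", "continuous", "intermittent"),
                               A0 = 1, duration_months = 2,
                               week_days = 7, month_days = 28) {
  mode <- match.arg(mode)
  if (!is.finite(A0) || A0 < 0) rlang::abort("A0 must be >= 0")
  if (mode != "none" && duration_months <= 0)
    rlang::abort("duration must be positive for active modes")
  structure(list(mode = mode, A0 = A0,
                 duration = duration_months * month_days,
                 week = week_days, month = month_days),
            class = "il35_protocol")
}

#' @export
print.il35_protocol <- function(x, ...) {
  cat("<il35_protocol>", x$mode,
      if (x$mode != "none") paste0("A0 = ", x$A0, ", ", x$duration, " days"),
      "\n")
  invisible(x)
}

#' Instantaneous dose level of a protocol
#'
#' `"none"`: 0 for all t. `"continuous"`: `A0` on \[0, duration\], 0 after.
#' `"intermittent"`: `2 * A0` during on-weeks (the first week is on, then
#' alternating), 0 during off-weeks and after the window. The time integral
#' over the window equals `A0 * duration` for both active modes (equal total
#' dose).
#'
#' @param t Time(s), day, >= 0.
#' @param proto An `il35_protocol`.
#' @return Dose level(s), same length as `t`.
#' @export
protocol_level <- function(t, proto) {
  if (!inherits(proto, "il35_protocol")) rlang::abort("invalid protocol")
  if (any(t < 0)) rlang::abort("t must be nonnegative")
  switch(proto$mode,
    none = rep(0, length(t)),
    continuous = ifelse(t <= proto$duration, proto$A0, 0),
    intermittent = ifelse(
      t < proto$duration & (floor(t / proto$week) %% 2 == 0),
      2 * proto$A0, 0))
}

#' Dose switching instants of a protocol
#'
#' Times at which the dose level is discontinuous; the integrator is
#' restarted at each so the adaptive stepper never straddles a square-wave
#' edge.
#'
#' @param proto An `il35_protocol`.
#' @return Increasing numeric vector of times, day.
#' @export
protocol_breakpoints <- function(proto) {
  switch(proto$mode,
    none = numeric(),
    continuous = proto$duration,
    intermittent = sort(unique(c(
      seq(0, proto$duration, by = proto$week), proto$duration))))
}

#' Static spatial profile of the drug
#'
#' The drug enters from the vasculature at the tumor boundary and penetrates
#' inward, so its concentration decreases from r = R toward the center:
#' `level * exp(-drug_alpha * (R - r))`. Nonnegative, nondecreasing in r,
#' maximal at the boundary.
#'
#' @param grid An `il35_grid`.
#' @param level Dose level (scales the profile), >= 0.
#' @param p An `il35_params` object (uses `drug_alpha`).
#' @return Numeric vector of drug concentrations at the cell centers.
#' @export
drug_spatial_profile <- function(grid, level, p) {
  if (!is.finite(level) || level < 0) rlang::abort("level must be >= 0")
  level * exp(-p$drug_alpha * (grid$R - grid$r))
}

#' Drug sink on the IL-35 field
#'
#' Mass-action neutralization `-mu_A * A * rho`: the only modification the
#' drug makes to the model. Zero when either the drug or IL-35 vanishes;
#' magnitude nondecreasing in both.
#'
#' @param rho IL-35 concentration(s), >= 0.
#' @param A Local drug concentration(s), >= 0.
#' @param p An `il35_params` object (uses `mu_A`).
#' @return Nonpositive rate contribution(s) to the IL-35 equation.
#' @export
il35_sink <- function(rho, A, p) {
  if (any(rho < 0) || any(A < 0)) rlang::abort("rho and A must be >= 0")
  -p$mu_A * A * rho
}
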