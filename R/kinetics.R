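# Local (non-transport) kinetics of the ten-field model. All functions are
# pure and vectorized over the state so each term is testable in isolation.

ramp01 <- function(u, smooth = 0) {
  u <- pmin(1, pmax(0, u))
  if (smooth > 0) u * u * (3 - 2 * u) else u
}

#' Oxygen dependence of tumor proliferation
#'
#' Factor in \[0, 1\]: zero through the necrotic and extremely hypoxic oxygen
#' ranges (w below `w_hyp`), rising linearly across the intermediate hypoxic
#' range and reaching 1 at the normal oxygen level `w_normal`, where the
#' proliferation rate attains its maximum `lambda_c`.
#'
#' @param w Oxygen concentration(s), g/cm^3; must be nonnegative.
#' @param p An `il35_params` object (uses `w_hyp`, `w_normal`).
#' @param smooth Corner-smoothing width; 0 (default) keeps the piecewise
#'   linear ramp, any positive value substitutes a C1 cubic ramp with the
#'   same endpoints (helps stiff adaptive steppers).
#' @return Numeric factor(s) in \[0, 1\].
#' @export
proliferation_oxygen_switch <- function(w, p, smooth = 0) {
  if (any(w < 0)) rlang::abort("oxygen must be nonnegative")
  ramp01((w - p$w_hyp) / (p$w_normal - p$w_hyp), smooth)
}

#' Oxygen dependence of tumor necrosis
#'
#' Factor in \[0, 1\]: 1 throughout the necrotic range (w below `w_nec`),
#' falling linearly across the extremely hypoxic range and vanishing for
#' oxygen at or above `w_hyp` (hence also at `w_normal`).
#'
#' @inheritParams proliferation_oxygen_switch
#' @return Numeric factor(s) in \[0, 1\].
#' @export
necrosis_oxygen_switch <- function(w, p, smooth = 0) {
  if (any(w < 0)) rlang::abort("oxygen must be nonnegative")
  ramp01((p$w_hyp - w) / (p$w_hyp - p$w_nec), smooth)
}

#' Hypoxic enhancement of VEGF production
#'
#' The factor `G(w) = (w / w_star) * exp(1 - w / w_star)`: zero at zero
#' oxygen (dying cells secrete nothing), maximal (value 1) at the mild
#' hypoxia level `w_star`, and decreasing toward normoxia, so tumor cells and
#' MDSCs secrete VEGF mostly under mild hypoxic conditions.
#'
#' @param w Oxygen concentration(s), g/cm^3; nonnegative.
#' @param p An `il35_params` object (uses `w_star`).
#' @return Nonnegative factor(s), at most 1.
#' @export
vegf_hypoxia_factor <- function(w, p) {
  if (any(w < 0)) rlang::abort("oxygen must be nonnegative")
  (w / p$w_star) * exp(1 - w / p$w_star)
}

#' VEGF dependence of endothelial-cell proliferation
#'
#' The thresholded factor `max(h - h_star, 0) / (K_h + h)`: zero at or below
#' the proliferation threshold `h_star`, positive and nondecreasing above it,
#' saturating for large VEGF.
#'
#' @param h VEGF concentration(s), g/cm^3; nonnegative.
#' @param p An `il35_params` object (uses `h_star`, `K_h`).
#' @return Nonnegative factor(s) < 1.
#' @export
ec_proliferation_switch <- function(h, p) {
  if (any(h < 0)) rlang::abort("VEGF must be nonnegative")
  pmax(h - p$h_star, 0) / (p$K_h + h)
}

#' IL-10-mediated suppression of CD8+ T-cell activation
#'
#' MDSC-derived IL-10 (concentration `k_10M * M`) suppresses CD8+ T-cell
#' activation through the factor `1 / (1 + k_10M * M / K_T1)`.
#'
#' @param M MDSC density(ies), g/cm^3; nonnegative.
#' @param p An `il35_params` object (uses `k_10M`, `K_T1`).
#' @return Factor(s) in (0, 1\].
#' @export
il10_suppression <- function(M, p) {
  if (any(M < 0)) rlang::abort("MDSC density must be nonnegative")
  1 / (1 + p$k_10M * M / p$K_T1)
}

# Vectorized kinetics over a 10 x n state matrix (rows in field order).
# A is the local drug concentration (scalar or length-n).
reaction_matrix <- function(Y, p, A = 0, smooth = 0) {
  c_ <- Y[1, ]; q <- Y[2, ]; M <- Y[3, ]; rho <- Y[4, ]; Rg <- Y[5, ]
  beta <- Y[6, ]; T_ <- Y[7, ]; h <- Y[8, ]; e <- Y[9, ]; w <- Y[10, ]
  G <- vegf_hypoxia_factor(w, p)
  out <- matrix(0, 10, ncol(Y))
  out[1, ] <- p$lambda_c * c_ * (1 - c_ / p$c_max) *
      proliferation_oxygen_switch(w, p, smooth) -
    p$d_n * c_ * necrosis_oxygen_switch(w, p, smooth) -
    p$d_c * c_ - p$eta * c_ * T_
  out[2, ] <- p$s_q * c_ - p$d_q * q
  out[3, ] <- p$s_M + p$lambda_Mrho * rho / (p$K_rho + rho) +
    p$lambda_MQ * p$M_0 * q / (p$K_q + q) - p$d_M * M
  out[4, ] <- p$lambda_rho_c * c_ + p$lambda_rho_R * Rg +
    p$lambda_rho_M * M - p$d_rho * rho + il35_sink(rho, A, p)
  out[5, ] <- p$lambda_RM * M / (p$K_M + M) +
    p$lambda_Rbeta * beta / (p$K_beta + beta) - p$d_R * Rg
  out[6, ] <- p$lambda_beta_c * c_ + p$lambda_beta_R * Rg - p$d_beta * beta
  il12 <- p$k_12M * M
  out[7, ] <- p$lambda_T12 * il12 / (p$K_T2 + il12) * il10_suppression(M, p) -
    p$d_T * T_
  out[8, ] <- p$lambda_hc * c_ * (p$eps_c + G * rho / (p$K_rho_h + rho)) +
    p$lambda_hM * M * (p$eps_M + G * q / (p$K_q_h + q)) - p$d_h * h
  out[9, ] <- p$lambda_e * e * (1 - e / p$e_max) *
    ec_proliferation_switch(h, p)
  out[10, ] <- p$lambda_w * e * (p$w_0 - w) -
    (p$k_wT * T_ + p$k_wM * M + p$k_wR * Rg + p$k_wc * c_) * w
  out
}

#' Local reaction rates at a single point
#'
#' Evaluates every non-transport term of the ten field equations at one
#' spatial point: logistic, oxygen-switched tumor growth and death; linear
#' cytokine production/decay; saturating (Michaelis-Menten) activation terms;
#' the IL-10 suppression factor; the hypoxia-enhanced VEGF sources;
#' thresholded EC proliferation; EC oxygen delivery and cellular consumption.
#' An anti-IL-35 drug at level `A` adds a sink to the IL-35 component only.
#'
#' @param state Named numeric vector with entries `c`, `q`, `M`, `rho`, `Rg`,
#'   `beta`, `T`, `h`, `e`, `w` (all finite and nonnegative), g/cm^3.
#' @param p An `il35_params` object.
#' @param A Local drug concentration, nonnegative scalar.
#' @param smooth Corner-smoothing width for the oxygen switches (see
#'   [proliferation_oxygen_switch()]).
#' @return Named numeric 10-vector of local rates, g/cm^3/day.
#' @export
reaction_rhs <- function(state, p, A = 0, smooth = 0) {
  if (!all(.fields %in% names(state)))
    rlang::abort(paste0("state must name all fields: ",
                        paste(.fields, collapse = ", ")))
  x <- as.numeric(state[.fields])
  if (any(!is.finite(x)) || any(x < 0))
    rlang::abort("state entries must be finite and nonnegative")
  if (!is.finite(A) || A < 0) rlang::abort("drug level A must be >= 0")
  stats::setNames(drop(reaction_matrix(matrix(x, 10, 1), p, A, smooth)),
                  .fields)
}
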