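# Initial fields: a tumor mass concentrated at the center plus quasi-steady
# profiles for the species it entrains.

#' Initial tumor profile
#'
#' Gaussian-in-radius profile `c_init * exp(-(r / r_init)^2)`: maximal at the
#' center r = 0 (the injected bolus), strictly decreasing in r, and
#' negligible at the domain boundary for the default decay length.
#'
#' @param grid An `il35_grid`.
#' @param p An `il35_params` object (uses `c_init`, `r_init`).
#' @return Numeric vector of tumor densities at the cell centers, g/cm^3.
#' @export
tumor_initial_profile <- function(grid, p) {
  if (!is.finite(p$c_init) || p$c_init <= 0 || p$r_init <= 0)
    rlang::abort("c_init and r_init must be positive")
  p$c_init * exp(-(grid$r / p$r_init)^2)
}

#' Quasi-steady initial state from a tumor profile
#'
#' Builds the full ten-field initial state entrained by a given tumor
#' profile `c0`:
#' * M-CSF proportional to `c0` with the steady-state constant `s_q / d_q`
#'   of its production/decay balance (uniform ratio);
#' * MDSC localized like the tumor, scaled by the steady state of its local
#'   balance at the center;
#' * TGF-beta, Treg and IL-35 from their quasi-steady local balances given
#'   `c0` and the MDSC profile;
#' * VEGF from its IL-35/M-CSF-independent baseline production;
#' * no activated CD8+ T cells (`T = 0`);
#' * EC and oxygen increasing from a central fraction of their healthy-tissue
#'   values to exactly `e_normal` and `w_0` at r = R (endothelial cells, and
#'   with them oxygen, enter from the surrounding tissue).
#'
#' @param grid An `il35_grid`.
#' @param c0 Tumor density profile (length `grid$n`).
#' @param p An `il35_params` object.
#' @return 10 x n matrix of dimensional field values (rows in field order).
#' @export
quasi_steady_initials <- function(grid, c0, p) {
  if (length(c0) != grid$n) rlang::abort("c0 length must match the grid")
  if (any(c0 < 0)) rlang::abort("c0 must be nonnegative")
  shape <- if (max(c0) > 0) c0 / max(c0) else c0
  q0 <- (p$s_q / p$d_q) * c0
  M0 <- ((p$s_M + p$lambda_MQ * p$M_0 * q0 / (p$K_q + q0)) / p$d_M) * shape
  beta0 <- p$lambda_beta_c * c0 / p$d_beta
  R0 <- (p$lambda_RM * M0 / (p$K_M + M0) +
           p$lambda_Rbeta * beta0 / (p$K_beta + beta0)) / p$d_R
  beta0 <- beta0 + p$lambda_beta_R * R0 / p$d_beta
  rho0 <- (p$lambda_rho_c * c0 + p$lambda_rho_R * R0 +
             p$lambda_rho_M * M0) / p$d_rho
  h0 <- (p$lambda_hc * c0 * p$eps_c + p$lambda_hM * M0 * p$eps_M) / p$d_h
  T0 <- numeric(grid$n)
  rr <- (grid$r / grid$R)^2
  e0 <- p$e_normal * (p$e_init_frac + (1 - p$e_init_frac) * rr)
  w0 <- p$w_0 * (p$w_init_frac + (1 - p$w_init_frac) * rr)
  # the boundary-adjacent cell carries the healthy-tissue values exactly
  e0[grid$n] <- p$e_normal
  w0[grid$n] <- p$w_0
  out <- rbind(c0, q0, M0, rho0, R0, beta0, T0, h0, e0, w0)
  rownames(out) <- .fields
  if (any(!is.finite(out)) || any(out < 0))
    rlang::abort("constructed initial state is not finite and nonnegative")
  out
}
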