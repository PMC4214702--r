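# Spatial discretization (finite volume on the sphere radius) and method-of-
# lines time integration of the full ten-field model.
#
# State layout for the solver: the 10 x n matrix of scaled fields is stacked
# column-wise (all ten fields of cell 1, then cell 2, ...), which keeps the
# Jacobian banded: reactions couple within a cell (bandwidth 9) and transport
# couples neighbouring cells of the same or an adjacent row (bandwidth <= 19).

.BAND <- 19L

#' Discrete spherical diffusion operator
#'
#' Conservative finite-volume Laplacian on the sphere radius: face fluxes
#' `area * D * df/dr` differenced over shell volumes. The r = 0 face has zero
#' area (symmetry; no ghost singularity) and the outer face flux is 0 unless
#' a boundary exchange is added separately.
#'
#' @param f Field values at cell centers.
#' @param D Diffusion coefficient.
#' @param grid An `il35_grid`.
#' @return Rates of change per cell (same length as `f`).
#' @export
diffusion_term <- function(f, D, grid) {
  n <- grid$n
  if (length(f) != n) rlang::abort("field length must match the grid")
  flux <- numeric(n + 1)
  flux[2:n] <- grid$area[2:n] * D * (f[-1] - f[-n]) / grid$dr
  (flux[-1] - flux[-(n + 1)]) / grid$vol
}

#' Discrete chemotaxis operator
#'
#' Conservative divergence of the advective flux `-chi * cells * grad(attr)`
#' with first-order upwinding of the cell density at faces. Under no-flux
#' boundaries the sphere integral of the returned rates is zero to rounding.
#'
#' @param cells Migrating cell density at cell centers.
#' @param attractant Attractant concentration at cell centers.
#' @param chi Chemotactic sensitivity (>= 0).
#' @param grid An `il35_grid`.
#' @return Rates of change per cell.
#' @export
chemotaxis_term <- function(cells, attractant, chi, grid) {
  n <- grid$n
  if (length(cells) != n || length(attractant) != n)
    rlang::abort("field lengths must match the grid")
  if (chi < 0) rlang::abort("chi must be nonnegative")
  v <- chi * (attractant[-1] - attractant[-n]) / grid$dr   # face velocity
  up <- ifelse(v > 0, cells[-n], cells[-1])                # upwind donor
  flux <- numeric(n + 1)
  flux[2:n] <- grid$area[2:n] * v * up
  -(flux[-1] - flux[-(n + 1)]) / grid$vol
}

#' Boundary exchange fluxes at r = R
#'
#' All fields obey the symmetry condition at r = 0 and no-flux at r = R,
#' except endothelial cells and oxygen, which exchange with the surrounding
#' healthy tissue through Robin conditions: flux `gamma_e * (e_normal - e)`
#' for EC (inward when the tumor rim is EC-poor) and `gamma_w * (w_0 - w)`
#' for oxygen. Returned as per-field outer-face flux densities (amount per
#' area per day, positive inward).
#'
#' @param state 10 x n matrix of dimensional field values (rows in field
#'   order c, q, M, rho, Rg, beta, T, h, e, w).
#' @param p An `il35_params` object.
#' @return Named numeric 10-vector of outer-face flux densities.
#' @export
boundary_fluxes <- function(state, p) {
  if (!is.matrix(state) || nrow(state) != 10)
    rlang::abort("state must be a 10-row matrix")
  n <- ncol(state)
  flux <- stats::setNames(numeric(10), .fields)
  flux["e"] <- p$gamma_e * (p$e_normal - state[9, n])
  flux["w"] <- p$gamma_w * (p$w_0 - state[10, n])
  flux
}

diffusion_coefs <- function(p) {
  c(p$D_c, p$D_q, p$D_M, p$D_rho, p$D_R, p$D_beta, p$D_T, p$D_h, p$D_e, p$D_w)
}

# Full model right-hand side on the scaled state vector.
model_rhs <- function(t, y, ctx) {
  g <- ctx$grid; p <- ctx$p
  Y <- matrix(y, 10, g$n) * ctx$refs
  Y[Y < 0] <- 0
  A <- if (is.null(ctx$protocol)) 0 else
    protocol_level(t, ctx$protocol) * ctx$drug_profile
  dY <- if (ctx$reactions) reaction_matrix(Y, p, A, ctx$smooth) else
    matrix(0, 10, g$n)
  Ds <- ctx$D
  for (f in 1:10) if (Ds[f] > 0)
    dY[f, ] <- dY[f, ] + diffusion_term(Y[f, ], Ds[f], g)
  if (ctx$chemotaxis) {
    dY[3, ] <- dY[3, ] + chemotaxis_term(Y[3, ], Y[2, ], p$chi_M, g)
    dY[7, ] <- dY[7, ] + chemotaxis_term(Y[7, ], p$k_MCP * Y[3, ], p$chi_T, g)
    dY[9, ] <- dY[9, ] + chemotaxis_term(Y[9, ], Y[8, ], p$chi_e, g)
  }
  if (ctx$boundary) {
    bf <- boundary_fluxes(Y, p)
    scale <- g$area[g$n + 1] / g$vol[g$n]
    dY[9, g$n] <- dY[9, g$n] + scale * bf["e"]
    dY[10, g$n] <- dY[10, g$n] + scale * bf["w"]
  }
  if (length(ctx$frozen_idx)) dY[ctx$frozen_idx, ] <- 0
  list(as.vector(dY / ctx$refs))
}

#' Simulate the ten-field tumor model
#'
#' Method-of-lines integration: finite-volume discretization in r (see
#' [build_grid()]), stiff adaptive integrator (deSolve's `lsode` with a
#' banded internally estimated Jacobian) in time. Fields are scaled by their
#' reference magnitudes inside the solver. When a treatment protocol with
#' dose discontinuities is supplied, integration is restarted at each
#' switching instant.
#'
#' @param p An `il35_params` object (see [il35_params()]).
#' @param t_out Increasing output times, day; must start at 0.
#' @param protocol A [treatment_protocol()] or `NULL` for no drug.
#' @param n_cells Grid resolution (default 200).
#' @param ic Optional 10 x n initial state matrix (dimensional); defaults to
#'   [quasi_steady_initials()] on the tumor profile of
#'   [tumor_initial_profile()].
#' @param rtol,atol Solver tolerances on the scaled fields.
#' @param reactions,chemotaxis,boundary Logical switches disabling groups of
#'   terms (used by conservation and oracle tests).
#' @param frozen Character vector of field names whose rates are pinned to 0.
#' @param smooth Oxygen-switch corner smoothing width (default 0 = exact
#'   piecewise form).
#' @param scaling An `il35_scaling` providing the field reference magnitudes.
#' @return An `il35_trajectory`: list with `times`, `states` (list of 10 x n
#'   dimensional matrices, one per output time), `grid`, `params`,
#'   `protocol`, and `diagnostics` (solver steps, clipped-negative count).
#' @export
simulate_tumor <- function(p, t_out = seq(0, p$t_final, by = 1),
                           protocol = NULL, n_cells = 200, ic = NULL,
                           rtol = 1e-6, atol = 1e-9,
                           reactions = TRUE, chemotaxis = TRUE,
                           boundary = TRUE, frozen = character(),
                           smooth = 0, scaling = default_scaling()) {
  validate_params(p)
  if (is.unsorted(t_out, strictly = TRUE))
    rlang::abort("t_out must be strictly increasing")
  if (t_out[1] != 0) rlang::abort("t_out must start at 0")
  grid <- build_grid(p$R_domain, n_cells)
  if (is.null(ic)) {
    c0 <- tumor_initial_profile(grid, p)
    ic <- quasi_steady_initials(grid, c0, p)
  }
  if (!is.matrix(ic) || nrow(ic) != 10 || ncol(ic) != grid$n)
    rlang::abort("ic must be a 10 x n_cells matrix")
  bad <- setdiff(frozen, .fields)
  if (length(bad)) rlang::abort(paste0("unknown frozen field(s): ",
                                       paste(bad, collapse = ", ")))
  refs <- field_refs(scaling)
  ctx <- list(grid = grid, p = p, refs = refs, D = diffusion_coefs(p),
              protocol = protocol,
              drug_profile = if (is.null(protocol)) NULL else
                drug_spatial_profile(grid, 1, p),
              reactions = reactions, chemotaxis = chemotaxis,
              boundary = boundary,
              frozen_idx = match(frozen, .fields), smooth = smooth)

  # integrate piecewise between dose discontinuities
  breaks <- if (is.null(protocol)) numeric() else
    protocol_breakpoints(protocol)
  tmax <- max(t_out)
  breaks <- sort(unique(breaks[breaks > 0 & breaks < tmax]))
  segs <- c(0, breaks, tmax)

  y <- as.vector(ic / refs)
  rows <- matrix(NA_real_, length(t_out), length(y))
  rows[1, ] <- y
  steps <- 0L
  for (k in seq_len(length(segs) - 1)) {
    a <- segs[k]; b <- segs[k + 1]
    inner <- t_out[t_out > a & t_out < b]
    tt <- unique(c(a, inner, b))
    sol <- deSolve::lsode(y, tt, model_rhs, ctx, jactype = "bandint",
                          bandup = .BAND, banddown = .BAND,
                          rtol = rtol, atol = atol, maxsteps = 100000)
    if (attr(sol, "istate")[1] < 0)
      rlang::abort(paste0("solver failed at t = ",
                          signif(max(sol[, 1]), 6), " day"))
    if (any(!is.finite(sol[, -1])))
      rlang::abort("non-finite state encountered during integration")
    steps <- steps + attr(sol, "istate")[3]
    keep <- match(t_out[t_out > a & t_out <= b], sol[, 1])
    rows[which(t_out > a & t_out <= b), ] <- sol[keep, -1, drop = FALSE]
    y <- sol[nrow(sol), -1]
  }

  # clip policy: undershoots within the solver's absolute-error budget are
  # clipped to zero and counted; anything larger is a genuine failure
  neg_tol <- max(1e-10, 10 * atol)
  neg_min <- min(rows)
  if (neg_min < -neg_tol)
    rlang::abort(paste0("negative undershoot below tolerance: ", neg_min))
  clipped <- sum(rows < 0)
  rows[rows < 0] <- 0

  states <- lapply(seq_along(t_out), function(i) {
    m <- matrix(rows[i, ], 10, grid$n) * refs
    rownames(m) <- .fields
    m
  })
  structure(
    list(times = t_out, states = states, grid = grid, params = p,
         protocol = protocol,
         diagnostics = list(steps = steps, clipped = clipped,
                            min_scaled = neg_min, n_cells = grid$n)),
    class = "il35_trajectory")
}

#' @export
print.il35_trajectory <- function(x, ...) {
  cat("<il35_trajectory>", length(x$times), "time points over",
      max(x$times), "days;", x$grid$n, "cells; scenario:",
      attr(x$params, "scenario") %||% "(custom)", "\n")
  invisible(x)
}

#' Trajectory as a tidy long table
#'
#' @param x An `il35_trajectory`.
#' @param ... Unused.
#' @return Tibble with columns `time` (day), `radius`, `field`, `label`,
#'   `value` (dimensional units).
#' @method as_tibble il35_trajectory
#' @export
as_tibble.il35_trajectory <- function(x, ...) {
  n <- x$grid$n
  purrr::map_dfr(seq_along(x$times), function(i) {
    tibble::tibble(
      time = x$times[i],
      radius = rep(x$grid$r, each = 10),
      field = rep(.fields, n),
      value = as.vector(x$states[[i]]))
  }) |>
    dplyr::mutate(label = .field_labels[.data$field], .after = "field")
}

#' Extract one field from a trajectory state
#'
#' @param traj An `il35_trajectory`.
#' @param field Field name (one of c, q, M, rho, Rg, beta, T, h, e, w).
#' @param t Output time (must be one of `traj$times`).
#' @return Numeric vector of cell values.
#' @export
field_at <- function(traj, field, t) {
  i <- match(t, traj$times)
  if (is.na(i)) rlang::abort(paste0("time ", t, " is not an output time"))
  f <- match.arg(field, .fields)
  traj$states[[i]][f, ]
}
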