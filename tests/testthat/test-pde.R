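test_that("discrete spherical diffusion has the right local behaviour", {
  g <- build_grid(1, 50)
  expect_equal(diffusion_term(rep(4, g$n), 0.3, g), rep(0, g$n))
  # f = r^2 has spherical Laplacian 6, exactly reproduced away from r = R
  d <- diffusion_term(g$r^2, 0.5, g)
  expect_equal(d[1:(g$n - 1)], rep(6 * 0.5, g$n - 1), tolerance = 1e-10)
  expect_error(diffusion_term(1:3, 0.5, g), "match")
})

test_that("diffusion operator equals a dense finite-volume assembly", {
  g <- build_grid(0.7, 12)
  D <- 0.2
  # operator matrix by applying the term to unit vectors
  L <- sapply(seq_len(g$n), function(j) {
    e <- numeric(g$n); e[j] <- 1
    diffusion_term(e, D, g)
  })
  # dense construction: interior face conductances area*D/dr
  A <- matrix(0, g$n, g$n)
  for (i in seq_len(g$n)) {
    if (i > 1) {
      cnd <- g$area[i] * D / g$dr / g$vol[i]
      A[i, i - 1] <- A[i, i - 1] + cnd; A[i, i] <- A[i, i] - cnd
    }
    if (i < g$n) {
      cnd <- g$area[i + 1] * D / g$dr / g$vol[i]
      A[i, i + 1] <- A[i, i + 1] + cnd; A[i, i] <- A[i, i] - cnd
    }
  }
  expect_equal(L, A, tolerance = 1e-12)
})

test_that("chemotaxis is conservative and vanishes in trivial cases", {
  g <- build_grid(0.5, 64)
  cells <- exp(-(g$r / 0.2)^2)
  expect_equal(chemotaxis_term(cells, rep(1, g$n), 5, g), rep(0, g$n))
  expect_equal(chemotaxis_term(rep(0, g$n), g$r, 5, g), rep(0, g$n))
  set.seed(3)
  for (i in 1:5) {
    a <- 1e-9 * (1 + sin(3 * g$r + stats::runif(1)))
    rate <- chemotaxis_term(cells, a, 800, g)
    scale <- sum(g$vol * abs(rate)) + 1e-300
    expect_lt(abs(sum(g$vol * rate)) / scale, 1e-12)
  }
  expect_error(chemotaxis_term(cells, g$r, -1, g), "nonnegative")
})

test_that("boundary exchange fluxes follow the Robin forms", {
  g <- build_grid(p_il35$R_domain, 16)
  st <- matrix(0, 10, g$n)
  st[9, g$n] <- p_il35$e_normal
  st[10, g$n] <- p_il35$w_0
  bf <- boundary_fluxes(st, p_il35)
  expect_equal(unname(bf), rep(0, 10))  # equilibrium with healthy tissue
  st[9, g$n] <- p_il35$e_normal / 2
  bf <- boundary_fluxes(st, p_il35)
  expect_gt(bf[["e"]], 0)               # EC-poor rim draws cells inward
  expect_equal(sum(bf[c("c", "q", "M", "rho", "Rg", "beta", "T", "h")]), 0)
  expect_error(boundary_fluxes(matrix(0, 3, 4), p_il35), "10-row")
})

test_that("single-field diffusion matches the eigenfunction series solution", {
  fx <- make_fixtures("diffusion-oracle", seed = 4)
  p <- il35_params("J558-IL-35", D_q = fx$D)
  ic <- matrix(0, 10, fx$n)
  ic[2, ] <- fx$ic
  tr <- simulate_tumor(p, t_out = c(0, fx$t_end), n_cells = fx$n, ic = ic,
                       reactions = FALSE, chemotaxis = FALSE,
                       boundary = FALSE, rtol = 1e-9, atol = 1e-12)
  got <- field_at(tr, "q", fx$t_end)
  expect_lt(max(abs(got / fx$exact - 1)), 1e-3)
})

test_that("an absent tumor stays absent while the MDSC source acts", {
  p <- p_il35
  g <- build_grid(p$R_domain, 24)
  ic <- quasi_steady_initials(g, rep(0, g$n), p)
  tr <- simulate_tumor(p, t_out = c(0, 5, 10), n_cells = 24, ic = ic)
  expect_equal(max(field_at(tr, "c", 10)), 0)
  expect_gt(min(field_at(tr, "M", 10)), 0)
})

test_that("trajectories satisfy their structural invariants", {
  tr <- simulate_tumor(p_il35, t_out = c(0, 2, 4), n_cells = 20)
  expect_identical(tr$times, c(0, 2, 4))
  ic <- quasi_steady_initials(tr$grid, tumor_initial_profile(tr$grid, p_il35),
                              p_il35)
  expect_equal(tr$states[[1]], ic, tolerance = 1e-12)
  expect_true(all(vapply(tr$states, function(s) all(s >= 0), logical(1))))
  expect_gt(tr$diagnostics$steps, 0)
  df <- as_tibble(tr)
  expect_identical(nrow(df), 3L * 10L * 20L)
  expect_error(simulate_tumor(p_il35, t_out = c(0, 2, 1), n_cells = 20),
               "increasing")
  expect_error(simulate_tumor(p_il35, t_out = c(1, 2), n_cells = 20),
               "start at 0")
  expect_error(simulate_tumor(p_il35, t_out = c(0, 1), n_cells = 20,
                              frozen = "bogus"), "unknown frozen")
})

test_that("frozen fields stay pinned to their initial values", {
  tr <- simulate_tumor(p_il35, t_out = c(0, 3), n_cells = 20, frozen = "c")
  expect_equal(field_at(tr, "c", 3), field_at(tr, "c", 0), tolerance = 1e-12)
})
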