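test_that("oxygen switches have the right endpoints and monotonicity", {
  p <- p_il35
  expect_equal(proliferation_oxygen_switch(0, p), 0)
  expect_equal(proliferation_oxygen_switch(p$w_nec / 2, p), 0)
  expect_equal(proliferation_oxygen_switch(p$w_normal, p), 1)
  expect_equal(necrosis_oxygen_switch(0, p), 1)
  expect_equal(necrosis_oxygen_switch(p$w_nec * 0.99, p), 1)
  expect_equal(necrosis_oxygen_switch(p$w_normal, p), 0)
  w <- seq(0, 2 * p$w_normal, length.out = 1000)
  for (sm in c(0, 1)) {
    fp <- proliferation_oxygen_switch(w, p, smooth = sm)
    fn <- necrosis_oxygen_switch(w, p, smooth = sm)
    expect_true(all(diff(fp) >= 0))
    expect_true(all(diff(fn) <= 0))
    expect_true(all(fp >= 0 & fp <= 1 & fn >= 0 & fn <= 1))
  }
  expect_error(proliferation_oxygen_switch(-1e-9, p), "nonnegative")
  expect_error(necrosis_oxygen_switch(-1e-9, p), "nonnegative")
})

test_that("hypoxic VEGF factor peaks at w_star and is mild-hypoxia biased", {
  p <- p_il35
  w <- seq(0, 2 * p$w_normal, length.out = 20001)
  g <- vegf_hypoxia_factor(w, p)
  expect_equal(w[which.max(g)], p$w_star, tolerance = 1e-3)
  expect_lte(vegf_hypoxia_factor(p$w_normal, p),
             vegf_hypoxia_factor(p$w_star, p))
  expect_true(all(g >= 0))
  expect_equal(vegf_hypoxia_factor(p$w_star, p), 1)
})

test_that("EC proliferation switch is thresholded and nondecreasing", {
  p <- p_il35
  expect_equal(ec_proliferation_switch(0, p), 0)
  expect_equal(ec_proliferation_switch(p$h_star, p), 0)
  h <- seq(p$h_star, 100 * p$h_star, length.out = 500)
  g <- ec_proliferation_switch(h, p)
  expect_true(all(diff(g) >= 0))
  expect_true(all(g >= 0 & g < 1))
})

test_that("reaction rates at the origin state reduce to the constant MDSC source", {
  r <- reaction_rhs(zero_state(), p_il35)
  expect_equal(unname(r["M"]), p_il35$s_M)
  expect_equal(unname(r[setdiff(names(r), "M")]), rep(0, 9))
})

test_that("tumor kill term vanishes without activated CD8 T cells", {
  st <- random_state(); st["T"] <- 0
  p_hot <- p_il35; p_hot$eta <- 1e6
  expect_equal(reaction_rhs(st, p_il35)[["c"]], reaction_rhs(st, p_hot)[["c"]])
})

test_that("M-CSF balances exactly at its production/decay steady state", {
  st <- zero_state()
  st["c"] <- p_il35$c_max
  st["q"] <- p_il35$s_q * p_il35$c_max / p_il35$d_q
  expect_equal(reaction_rhs(st, p_il35)[["q"]], 0)
})

test_that("the drug enters only the IL-35 equation, as a sink", {
  st <- random_state()
  r0 <- reaction_rhs(st, p_il35, A = 0)
  r1 <- reaction_rhs(st, p_il35, A = 2)
  expect_lt(r1[["rho"]], r0[["rho"]])
  expect_equal(r1[setdiff(names(r1), "rho")], r0[setdiff(names(r0), "rho")])
})

test_that("no field is driven negative by reactions alone", {
  set.seed(11)
  flds <- names(zero_state())
  for (i in 1:200) {
    st <- random_state()
    f <- sample(flds, 1)
    st[f] <- 0
    expect_gte(reaction_rhs(st, p_il35, A = stats::runif(1, 0, 2))[[f]], 0)
  }
})

test_that("reaction_rhs rejects malformed states", {
  st <- random_state(); st["M"] <- -1
  expect_error(reaction_rhs(st, p_il35), "nonnegative")
  st <- random_state(); st["h"] <- NaN
  expect_error(reaction_rhs(st, p_il35), "finite")
  expect_error(reaction_rhs(random_state(), p_il35, A = -1), ">= 0")
})

test_that("IL-10 suppression is a bounded decreasing factor", {
  M <- seq(0, 0.05, length.out = 200)
  s <- il10_suppression(M, p_il35)
  expect_equal(s[1], 1)
  expect_true(all(diff(s) < 0))
  expect_true(all(s > 0 & s <= 1))
})
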