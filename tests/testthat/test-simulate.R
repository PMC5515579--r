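test_that("regulatory input is the weighted sum with a switchable bcd term", {
  g <- axis_grid(10)
  p <- silent_params()
  state <- matrix(0, 4, 10)
  mat <- matrix(0, 4, 10, dimnames = list(c("bcd", "cad", "tll", "hkb"), NULL))

  # all weights and offsets zero -> u identically zero
  expect_equal(regulatory_input(state, mat, p), matrix(0, 4, 10),
               ignore_attr = TRUE)

  # single maternal weight: M[kr, bcd] = 2, bcd = 0.5, h_kr = -0.3
  p$M["kr", "bcd"] <- 2; p$h["kr"] <- -0.3
  mat["bcd", ] <- 0.5
  u_on <- regulatory_input(state, mat, p, bcd_active = TRUE)
  expect_equal(unname(u_on["kr", ]), rep(0.7, 10))
  # illumination zeroes the bcd contribution exactly
  u_off <- regulatory_input(state, mat, p, bcd_active = FALSE)
  expect_equal(unname(u_off["kr", ]), rep(-0.3, 10))

  # hb enters through its monomer/dimer forms
  p2 <- silent_params()
  p2$T["gt", "hb_m"] <- 1; p2$T["gt", "hb_d"] <- 10
  state2 <- state; state2[1, ] <- 2  # hb row
  part <- hb_partition(2, p2$K_hb)
  expect_equal(unname(regulatory_input(state2, mat * 0, p2)["gt", 1]),
               part$monomer + 10 * part$dimer)

  expect_error(regulatory_input(state[, 1:5], mat, p),
               class = "bcdecode_invalid_input")
})

test_that("pure decay matches the exponential closed form", {
  g <- axis_grid(10)
  p <- silent_params(n_genes_lam = 0.1)
  tr <- simulate_circuit(p, flat_maternal(g), grid = g, t_start = -10,
                         t_end = 0, dt = 0.01, v0 = matrix(1, 4, 10),
                         t_out = c(-10, -5, 0))
  expect_equal(max(abs(tr$states[, , 2] - exp(-0.5))) / exp(-0.5), 0,
               tolerance = 1e-8)
  expect_equal(max(abs(tr$states[, , 3] - exp(-1))) / exp(-1), 0,
               tolerance = 1e-8)
})

test_that("frozen input relaxes to the R*Phi(u)/lam fixed point", {
  g <- axis_grid(10)
  p <- silent_params(n_genes_lam = 1)
  p$R[] <- 2; p$h[] <- 1   # u = 1 everywhere, frozen (no cross terms)
  tr <- simulate_circuit(p, flat_maternal(g), grid = g, t_start = -40,
                         t_end = 0, dt = 0.01, v0 = matrix(0, 4, 10),
                         t_out = 0)
  expected <- steady_state_closed_form(p, 1, "kr")
  expect_equal(expected, 2 * circuit_sigmoid(1) / 1, tolerance = 1e-12)
  expect_equal(expected, 1.707107, tolerance = 1e-6)
  expect_lt(max(abs(end_state(tr) - expected)) / expected, 1e-6)

  # closed-form helper edge cases
  p0 <- silent_params(); p0$R[] <- 0
  expect_equal(steady_state_closed_form(p0, 3, "hb"), 0)
  q <- silent_params(0.5); q$R[] <- 1
  expect_equal(steady_state_closed_form(q, 0, "gt"), 1.0)  # R*Phi(0)/lam
  expect_error(steady_state_closed_form(p0, 1, "nope"),
               class = "bcdecode_invalid_input")
})

test_that("illumination scenarios respect causality", {
  w <- ref_world()
  sc <- illumination_scenario("3", list(c(-30, 0)))
  t_out <- c(-60, -45, -31, -15, 0)
  dark <- simulate_circuit(w$params, w$maternal, grid = w$grid, t_out = t_out)
  lit <- simulate_circuit(w$params, w$maternal, scenario = sc, grid = w$grid,
                          t_out = t_out)
  # identical before the window opens...
  for (k in 1:3)
    expect_equal(lit$states[, , k], dark$states[, , k], tolerance = 1e-12)
  # ...and different afterwards
  expect_gt(max(abs(lit$states[, , 5] - dark$states[, , 5])), 1e-3)
})

test_that("simulated concentrations stay non-negative for random circuits", {
  set.seed(7)
  g <- axis_grid(20)
  mat <- make_maternal_inputs(g)
  for (rep in 1:5) {
    p <- make_reference_circuit()
    p$T <- p$T + matrix(stats::rnorm(20, 0, 5), 4, 5)
    p$M <- p$M + matrix(stats::rnorm(16, 0, 5), 4, 4)
    p$h <- p$h + stats::rnorm(4, 0, 2)
    tr <- simulate_circuit(p, mat, grid = g, t_start = -30, t_end = 0,
                           dt = 0.05, t_out = c(-15, 0))
    expect_gte(min(tr$states), -1e-9)
  }
})

test_that("stability bound and input validation are enforced", {
  w <- ref_world()
  expect_error(simulate_circuit(w$params, w$maternal, grid = w$grid, dt = 10),
               class = "bcdecode_config_error")
  expect_error(simulate_circuit(w$params, w$maternal, grid = w$grid,
                                t_start = 0, t_end = 0),
               class = "bcdecode_invalid_input")
  expect_error(simulate_circuit(w$params, w$maternal, grid = w$grid,
                                v0 = matrix(-1, 4, 100)),
               class = "bcdecode_invalid_input")
})

test_that("halving the bin width changes the end state by under 2 percent", {
  w <- ref_world()
  coarse <- end_state(ref_dark())
  g2 <- axis_grid(200)
  m2 <- make_maternal_inputs(g2)
  fine <- end_state(simulate_circuit(w$params, m2, grid = g2))
  # compare on the coarse bin centres by linear interpolation of the fine run
  sup <- 0
  for (gene in 1:4) {
    fi <- stats::approx(g2$el, fine[gene, ], xout = w$grid$el, rule = 2)$y
    sup <- max(sup, max(abs(fi - coarse[gene, ])))
  }
  expect_lt(sup / max(coarse), 0.02)
})
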