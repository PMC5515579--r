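test_that("nuclear binning averages per 5 um step and marks empty bins", {
  # constant intensity -> constant profile
  nuc <- data.frame(position_um = runif(50, 0, 500), intensity = 7)
  p <- extract_profile(nuc)
  expect_equal(length(p$positions), 100L)  # 500 um / 5 um
  expect_true(all(p$values[is.finite(p$values)] == 7))

  # known per-bin means recomputed directly
  set.seed(3)
  nuc2 <- data.frame(position_um = runif(400, 0, 500),
                     intensity = rnorm(400, 100, 20))
  p2 <- extract_profile(nuc2)
  idx <- floor(nuc2$position_um / 5) + 1
  for (k in c(1, 25, 60, 100)) {
    inb <- idx == k
    if (any(inb)) expect_equal(p2$values[k], mean(nuc2$intensity[inb]),
                               tolerance = 1e-12)
    else expect_true(is.na(p2$values[k]))
  }

  # empty bins are NA, not zero
  nuc3 <- data.frame(position_um = c(2, 3), intensity = c(5, 7))
  p3 <- extract_profile(nuc3)
  expect_equal(p3$values[1], 6)
  expect_true(all(is.na(p3$values[-1])))

  # background subtraction for tabular input
  p4 <- extract_profile(nuc3, background = 1)
  expect_equal(p4$values[1], 5)

  expect_error(extract_profile(data.frame()), class = "bcdecode_invalid_input")
})

test_that("exponential fitting recovers a noiseless gradient exactly", {
  el <- seq(1, 99, by = 1)
  d <- (100 - el) / 100 * 500
  prof <- expression_profile(el, 1.0 * exp(-d / 80))
  fit <- fit_exponential(prof, 500)
  expect_equal(fit$length_scale, 80, tolerance = 1e-6)
  expect_equal(fit$amplitude, 1.0, tolerance = 1e-6)
  expect_equal(fit$offset, 0, tolerance = 1e-6)
  expect_lt(fit$rms_residual, 1e-8)

  # constant profile is degenerate
  expect_error(fit_exponential(expression_profile(el, rep(3, 99)), 500),
               class = "bcdecode_fit_error")

  # scale equivariance: intensities x c scale amplitude/offset, not length
  prof2 <- expression_profile(el, 5 * (exp(-d / 80) + 0.1))
  f1 <- fit_exponential(expression_profile(el, exp(-d / 80) + 0.1), 500)
  f2 <- fit_exponential(prof2, 500)
  expect_equal(f2$length_scale, f1$length_scale, tolerance = 1e-9)
  expect_equal(f2$amplitude, 5 * f1$amplitude, tolerance = 1e-6)
  expect_equal(f2$offset, 5 * f1$offset, tolerance = 1e-6)
})

test_that("length-scale recovery tolerates multiplicative noise", {
  ells <- vapply(1:20, function(s) {
    g <- make_gradient_nuclei(500, noise_sd = 0.05, seed = 1000 + s)
    fit_exponential(extract_profile(g$nuclei), 500)$length_scale
  }, numeric(1))
  expect_lt(abs(mean(ells) - 80) / 80, 0.03)
})

test_that("half-maximum boundaries interpolate as specified", {
  # step profile: posterior boundary of an anterior domain at the step
  el <- seq(0.5, 99.5, by = 1)
  step <- expression_profile(el, as.numeric(el > 50))
  expect_equal(boundary_position(step, "posterior", c(0, 100)), 50,
               tolerance = 0.51)

  # linear ramp 0 -> 1 over 40 -> 60: half-max at 50 exactly
  ramp <- expression_profile(seq(40, 60, 1), seq(0, 1, length.out = 21))
  expect_equal(boundary_position(ramp, "posterior", c(40, 60)), 50,
               tolerance = 1e-12)

  # symmetric bump spanning 45-58 at half height
  elf <- seq(20, 80, 0.5)
  bump <- 1 / (1 + exp(-(elf - 45) * 3)) / (1 + exp((elf - 58) * 3))
  bp <- expression_profile(elf, bump)
  expect_equal(boundary_position(bp, "anterior", c(30, 70)), 58,
               tolerance = 0.5)
  expect_equal(boundary_position(bp, "posterior", c(30, 70)), 45,
               tolerance = 0.5)

  # invariant to positive rescaling
  bp2 <- expression_profile(elf, 37.3 * bump)
  expect_equal(boundary_position(bp2, "anterior", c(30, 70)),
               boundary_position(bp, "anterior", c(30, 70)), tolerance = 1e-12)

  # no crossing inside the domain -> classed error
  flat <- expression_profile(el, rep(1, length(el)))
  expect_error(boundary_position(flat, "posterior", c(0, 100)),
               class = "bcdecode_domain_error")
})

test_that("raising the peak with a fixed tail moves the boundary posteriorly", {
  # posterior-high (Cad-like) profile: a posterior plateau of height k
  # meeting a FIXED anterior ramp; only the plateau (peak) changes with k
  el <- seq(0.5, 99.5, 0.5)
  ramp <- pmax((80 - el) / 10, 0)
  b <- vapply(c(1, 2, 4), function(pk) {
    prof <- expression_profile(el, pmin(ramp, pk))
    boundary_position(prof, "anterior", c(0, 100))
  }, numeric(1))
  # half-max crossings at 80 - 5k: a higher peak calls the boundary
  # further posterior (smaller %EL)
  expect_equal(b, c(75, 70, 60), tolerance = 1e-9)
  expect_true(all(diff(b) < 0))
})

test_that("profile normalisation is idempotent and respects the posterior peak", {
  el <- seq(0.5, 99.5, 1)
  vals <- exp(-(el - 20)^2 / 50) * 2 + exp(-(el - 80)^2 / 50) * 5
  p <- expression_profile(el, vals)
  n1 <- normalize_profile(p, "peak")
  expect_equal(max(n1$values), 1)
  expect_identical(normalize_profile(n1, "peak"), n1)
  n2 <- normalize_profile(p, "posterior_peak")
  # posterior-domain peak (el < 40) maps to 1; global max exceeds 1
  expect_equal(max(n2$values[n2$positions <= 40]), 1, tolerance = 1e-9)
  expect_gt(max(n2$values), 1)
})

test_that("percent input follows the 2^(adjusted - Ct) rule", {
  expect_equal(percent_input(25, 25), 100)
  expect_equal(percent_input(26, 25), 50)   # one qPCR cycle = factor 2
  expect_equal(percent_input(24, 25), 200)
  # 2% input control: adjusted input = Ct - log2(50)
  expect_equal(adjusted_input_ct(20, 2), 20 - log2(50))
  # identical light/dark -> relative % input of 1
  pi_d <- percent_input(24.3, adjusted_input_ct(21))
  expect_equal(relative_percent_input(pi_d, pi_d), 1)
  expect_error(percent_input(NA, 25), class = "bcdecode_invalid_input")
})
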