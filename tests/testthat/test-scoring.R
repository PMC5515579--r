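test_that("scenario batteries require and lead with the dark control", {
  w <- ref_world()
  g <- axis_grid(20)
  m <- make_maternal_inputs(g)
  expect_error(run_scenarios(w$params, m, default_scenarios(c("2", "3")),
                             grid = g),
               class = "bcdecode_invalid_input")
  trs <- run_scenarios(w$params, m, default_scenarios(c("3", "1")), grid = g,
                       t_start = -30, t_end = 0, t_out = 0)
  expect_named(trs, c("1", "3"))
  expect_equal(trs[["1"]]$scenario_id, "1")
})

# build a synthetic end-state with controllable kr/kni/hb/gt patterns
fake_state <- function(grid, kr = c(45, 58), kni = c(37, 45), hb_edge = 50,
                       hb_level = 1, gt_level = 1, kni_ant_level = 0.8,
                       kr_level = 1, kni_level = 1) {
  el <- grid$el
  bump <- function(lo, hi, level) level / (1 + exp(-(el - lo) * 4)) /
    (1 + exp((el - hi) * 4))
  rbind(hb = hb_level / (1 + exp(-(el - hb_edge) * 2)),
        gt = bump(60, 95, gt_level),
        kr = bump(kr[1], kr[2], kr_level),
        kni = bump(kni[1], kni[2], kni_level) + bump(88, 97, kni_ant_level))
}

test_that("criterion scoring reacts to the designed shifts and reductions", {
  g <- axis_grid(200)
  ctrl <- fake_state(g)

  # identical states meet nothing
  rep0 <- score_criteria(ctrl, ctrl, g)
  expect_equal(unname(rep0$criteria), rep(FALSE, 5))
  expect_equal(rep0$n_met, 0)

  # only the Kr anterior boundary moves anteriorly -> only (i)
  rep1 <- score_criteria(ctrl, fake_state(g, kr = c(45, 60)), g)
  expect_true(rep1$criteria[["i"]])
  expect_equal(unname(rep1$criteria[c("ii", "iii", "iv", "v")]), rep(FALSE, 4))
  expect_equal(rep1$measures[["kr_anterior"]], 2, tolerance = 0.1)

  # Kni posterior-domain anterior boundary shift -> (ii)
  rep2 <- score_criteria(ctrl, fake_state(g, kni = c(37, 48)), g)
  expect_true(rep2$criteria[["ii"]])
  expect_false(rep2$criteria[["i"]])

  # anterior Kni and Gt reductions -> (iii), (iv)
  rep3 <- score_criteria(ctrl, fake_state(g, kni_ant_level = 0.2,
                                          gt_level = 0.5), g)
  expect_true(rep3$criteria[["iii"]])
  expect_true(rep3$criteria[["iv"]])

  # criterion (v) is conjunctive: a shift without reduction fails
  rep4 <- score_criteria(ctrl, fake_state(g, hb_edge = 53), g)
  expect_gt(rep4$measures[["hb_posterior"]], 1)
  expect_false(rep4$criteria[["v"]])
  rep5 <- score_criteria(ctrl, fake_state(g, hb_edge = 53, hb_level = 0.7), g)
  expect_true(rep5$criteria[["v"]])
})

test_that("shift scoring is threshold-monotone", {
  g <- axis_grid(200)
  ctrl <- fake_state(g)
  shifts <- c(1.5, 3, 6)
  met <- vapply(shifts, function(s) {
    score_criteria(ctrl, fake_state(g, kr = c(45, 58 + s)), g)$criteria[["i"]]
  }, logical(1))
  expect_true(all(met))  # once true, increasing the shift keeps it true
})

test_that("subset selection applies the at-least-three rule", {
  # constructed 21-member score table with exactly 9 passing sets
  n_met <- c(rep(5, 3), rep(4, 3), rep(3, 3), rep(2, 6), rep(1, 3), rep(0, 3))
  scores <- data.frame(id = sprintf("set%02d", 1:21), n_met = n_met)
  sel <- select_subset(scores, 3)
  expect_length(sel, 9)
  expect_equal(sel, sprintf("set%02d", 1:9))
  expect_false("set10" %in% sel)  # exactly two criteria is excluded
  expect_length(select_subset(scores, 0), 21)

  # nesting: a stricter cutoff selects a subset of a looser one
  for (k in 0:4)
    expect_true(all(select_subset(scores, k + 1) %in% select_subset(scores, k)))

  expect_error(select_subset(scores[0, ]), class = "bcdecode_invalid_input")
})

make_param_with <- function(rkr) {
  p <- make_reference_circuit()
  p$R["kr"] <- rkr
  p
}

test_that("parameter z-scores reproduce the printed formula", {
  ens <- list(a = make_param_with(1), b = make_param_with(2),
              c = make_param_with(3))
  z <- param_zscore(ens, "c")
  zi <- z$z[z$parameter == "R[kr]"]
  # ensemble {1,2,3} (sample sd 1), subset {3}: (2 - 3)/(1/sqrt(3)) = -sqrt(3)
  expect_equal(zi, -sqrt(3), tolerance = 1e-12)
  expect_equal(zi, -1.7321, tolerance = 1e-4)
  # every other parameter is constant across the ensemble: z = 0, degenerate
  other <- z[z$parameter != "R[kr]", ]
  expect_true(all(other$z == 0))
  expect_true(all(other$degenerate))
  expect_false(z$degenerate[z$parameter == "R[kr]"])

  # subset = ensemble -> all zero
  zall <- param_zscore(ens, c("a", "b", "c"))
  expect_true(all(zall$z == 0))

  # switchable denominator: sigma/n instead of sigma/sqrt(n)
  zn <- param_zscore(ens, "c", denominator = "n")
  expect_equal(zn$z[zn$parameter == "R[kr]"], -3, tolerance = 1e-12)

  expect_error(param_zscore(ens, character(0)),
               class = "bcdecode_invalid_input")
  expect_error(param_zscore(ens, "zz"), class = "bcdecode_invalid_input")
})

test_that("z-scores are antisymmetric under subset complementation", {
  ens <- list(a = make_param_with(1), b = make_param_with(5),
              c = make_param_with(2), d = make_param_with(7))
  z1 <- param_zscore(ens, c("a", "b"))
  z2 <- param_zscore(ens, c("c", "d"))
  expect_equal(z1$z, -z2$z, tolerance = 1e-12)
})

test_that("z-score matrix reshapes interactions by regulator and target", {
  ens <- make_param_ensemble(n = 5, jitter = 0.2, seed = 3)
  z <- param_zscore(ens, c("set02", "set04"))
  m <- zscore_matrix(z)
  expect_equal(dim(m), c(9L, 4L))
  expect_equal(m["cad", "kni"], z$z[z$parameter == "M[kni,cad]"])
  expect_equal(m["hb_d", "kr"], z$z[z$parameter == "T[kr,hb_d]"])
})
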