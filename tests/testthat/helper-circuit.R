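# Shared, lazily computed reference-fixture simulations so the slow runs
# happen once per test session.
.ref_cache <- new.env(parent = emptyenv())

ref_world <- function() {
  if (is.null(.ref_cache$world)) {
    grid <- axis_grid(100)
    .ref_cache$world <- list(grid = grid,
                             maternal = make_maternal_inputs(grid),
                             params = make_reference_circuit())
  }
  .ref_cache$world
}

ref_dark <- function() {
  if (is.null(.ref_cache$dark)) {
    w <- ref_world()
    .ref_cache$dark <- simulate_circuit(w$params, w$maternal, grid = w$grid)
  }
  .ref_cache$dark
}

ref_scenario5 <- function() {
  if (is.null(.ref_cache$sc5)) {
    w <- ref_world()
    .ref_cache$sc5 <- simulate_circuit(
      w$params, w$maternal,
      scenario = illumination_scenario("5", list(c(-60, 0))), grid = w$grid)
  }
  .ref_cache$sc5
}

ref_boundary <- function(state, gene, side, domain) {
  w <- ref_world()
  boundary_position(expression_profile(w$grid$el, state[gene, ]), side, domain)
}

# a tiny flat maternal field + silent parameter set for closed-form tests
silent_params <- function(n_genes_lam = 0.1) {
  p <- make_reference_circuit()
  p$T[] <- 0; p$M[] <- 0; p$h[] <- 0
  p$R[] <- 0; p$lam[] <- n_genes_lam; p$D[] <- 0
  p
}

flat_maternal <- function(grid) maternal_field(grid, matrix(0, 4, grid$n_bins))
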