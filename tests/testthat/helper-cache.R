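# Session-wide cache for expensive fixtures (phantoms, atlas, simulations),
# shared across test files within one test run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

base_phantom <- function() cached("base_phantom", make_phantom(phantom_spec()))

stock_atlas <- function() cached("stock_atlas", {
  pop <- make_population(phantom_spec(), 30, seed = 20)
  build_atlas(lapply(pop, function(p) p$water))
})

# the stock 10-phantom experiment (5 inner, 5 outer), reference
# reconstructions included; the seed fixes the simulated study
stock_experiment <- function() cached("stock_experiment", {
  run_experiment(experiment_config(reference_recon = TRUE, seed = 20L))
})

artifact_free_sim <- function() cached("artifact_free_sim", {
  ph <- base_phantom()
  list(ph = ph, sim = simulate_case(ph, seed = 77))
})
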