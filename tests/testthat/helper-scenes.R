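# Small shared scene fixtures, built once per test run.

small_layout <- function(dead_fraction = 0) {
  orchard_layout(n_rows = 3, trees_per_row = c(6, 7, 8), row_spacing = 5,
                 plant_spacing = 4, field_length = 40, field_width = 16,
                 dead_fraction = dead_fraction)
}

.fixture_env <- new.env(parent = emptyenv())

# memoised fixture: build once, reuse across test files in one run
fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env))
    assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

small_scene <- function() {
  fixture("small_scene", function()
    simulate_scene(small_layout(dead_fraction = 0.1), gsd = 4.39, seed = 11))
}
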