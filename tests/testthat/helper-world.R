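# shared fixtures, generated in code and cached per test session

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, fn(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

tiny_config <- function(seed = 1) {
  world_config(grid_width = 24, grid_height = 24, n_states = 4,
               lgas_per_state = 2, n_clusters = 40,
               respondents_per_cluster = 15, n_covariates = 6,
               covariate_smoothness = 3, n_facilities = 8, seed = seed)
}

tiny_world <- function() cached("tiny_world", function() generate_world(tiny_config()))

default_world <- function() cached("default_world", function()
  generate_world(world_config(seed = 1)))

# the full default pipeline run is shared by acceptance + validation tests
default_run <- function() cached("default_run", function()
  suppressWarnings(run_pipeline(pipeline_config(seed = 1))))

default_margins <- function() list(
  margin_spec("urbanicity", c(urban = 0.53, rural = 0.47)),
  margin_spec("gender", c(female = 0.49, male = 0.51)),
  margin_spec("asset_owner", c(yes = 0.45, no = 0.55)))

# small deterministic raster for geometry tests
toy_grid <- function(vals = matrix(1:12, 3, 4), cs = 10) {
  raster_grid(vals + 0, cell_size = cs)
}
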