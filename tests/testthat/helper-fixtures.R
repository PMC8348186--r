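# Shared fixtures, built lazily and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, .fixture_env)) assign(name, builder(), .fixture_env)
  get(name, .fixture_env)
}

# tiny frame for I/O and geometry tests
tiny_config <- function(bands = 10L) {
  simulation_config(lines = 16, samples = 12, band_count = bands,
                    band_step_nm = (2500 - 930) / (bands - 1),
                    fruit_axes = c(6, 5), bruise_radius_px = 2, seed = 3)
}

# mid-size frame with a reduced band grid still covering the SWIR range
mid_config <- function() {
  simulation_config(band_count = 144L, band_step_nm = (2500 - 930) / 143)
}

mid_table1_dataset <- function() {
  fixture("mid_table1", function() {
    assemble_dataset(experiment_manifest("table1", seed = 1), mid_config(),
                     sound_total = 287)
  })
}

mid_factorial_dataset <- function() {
  fixture("mid_factorial", function() {
    assemble_dataset(experiment_manifest("factorial", seed = 2), mid_config(),
                     sound_total = 287)
  })
}

# full five-seed study at default settings (the expensive fixture; built
# once and reused by every block that asserts on study-level behaviour)
study_fixture <- function() {
  fixture("study5", function() run_study(seeds = 1:5))
}

# a default-scale L2 cube shared by segmentation/visualisation tests
default_l2_cube <- function() {
  fixture("default_l2", function() {
    generate_hypercube(simulation_config(), "L2", hours = 6, seed = 11,
                       n_bruises = 6)
  })
}
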