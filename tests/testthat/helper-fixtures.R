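# Shared fixtures: tiny simulated cohorts and small model configs, cached per
# test run so expensive objects are built once.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE))
    assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# a small 2-patient cohort at 32 px for fast unit tests
small_cohort <- function() fixture("small_cohort", function() {
  simulate_cohort(sim_config(n_patients = 2L, spots_per_patient = 30L,
                             patch_size_px = 32L, seed = 11L))
})

# a 64-px cohort slice for detector / morphology tests
mid_cohort <- function() fixture("mid_cohort", function() {
  simulate_cohort(sim_config(n_patients = 1L, spots_per_patient = 60L,
                             patch_size_px = 64L, seed = 21L))
})

tiny_arch <- function(markers = 6L) nn_arch(16L, n_markers = markers,
                                            noise_dim = 8L, base_width = 4L)

tiny_config <- function(markers = paste0("m", 1:6)) {
  run_config(patch_size_px = 16L, spot_size_px = 8L, noise_dim = 8L,
             batch_size = 8L, epochs = 1L, marker_names = markers,
             base_width = 4L)
}

# tiny transformed dataset matching tiny_config(), for train-loop tests
tiny_train_dataset <- function() fixture("tiny_train_dataset", function() {
  cfg <- sim_config(n_patients = 2L, spots_per_patient = 16L,
                    patch_size_px = 16L, n_markers = 6L, seed = 31L,
                    k_range = c(1L, 4L), r_range = c(0.08, 0.16))
  ds <- simulate_cohort(cfg)
  ft <- fit_transform_expression(ds$expression)
  ds$expression <- ft$transformed
  ds$transformed <- TRUE
  ds
})
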