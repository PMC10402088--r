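# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fx <- function(name, maker) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE))
    assign(name, maker(), envir = .fixture_env)
  get(name, envir = .fixture_env, inherits = FALSE)
}

cache_fixture <- function(name, value)
  assign(name, value, envir = .fixture_env)
get_fixture <- function(name)
  get(name, envir = .fixture_env, inherits = FALSE)

fx_basis <- function() fx("basis", function() build_orthonormal_basis())

fx_schedules <- function() fx("schedules",
                              function() build_study_schedule(seed = 1))

# Noiseless 4-vertex full-study simulation plus its joint fit; shared by the
# forward/inverse, averaging, and residual tests.
fx_noiseless_fit <- function() fx("noiseless_fit", function() {
  sch <- fx_schedules()
  basis <- fx_basis()
  geom <- make_vertex_geometry(4, seed = 2)
  truth <- quiet_truth(geom)
  bold <- simulate_bold(sch, truth, basis, seed = 4)
  fit <- fit_timeseries(bold, basis)
  list(bold = bold, fit = fit, geom = geom, truth = truth)
})

# Noiseless, pattern-free, drift-free truth over a given geometry.
quiet_truth <- function(geom, ...) {
  ground_truth(geom, seed = 3, pattern_sd = 0, noise_sd = 0,
               drift_amplitude = 0, ...)
}

# A hand-built minimal schedule (not from make_schedule) for covariate
# support tests: arbitrary trial frequencies at 12 s spacing, direction LMS.
toy_schedule <- function(frequencies, direction = "LMS") {
  structure(list(
    trials = data.frame(
      onset = (seq_along(frequencies) - 1) * 12,
      duration = 12,
      frequency_hz = frequencies,
      direction = direction,
      sequence_label = "A",
      stringsAsFactors = FALSE),
    attention_onsets = numeric(0),
    acquisition_duration = 336),
    class = "stimulus_schedule")
}

# True amplitude for a row of a fitted amplitude table under a ground truth
# with all-ones carry-over.
true_amplitude_of <- function(truth, geom, row) {
  neural_amplitude(truth, row$direction, row$frequency_hz,
                   geom$eccentricity_deg[row$vertex])
}
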