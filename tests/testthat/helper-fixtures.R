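# shared fixtures: small, deterministic cohorts and a noiseless spec

quiet_spec <- function(seed = 1, n_per_group = 2, ...) {
  cohort_spec(n_per_group = n_per_group, noise = quiet_noise(),
              artifact_rate = 0, seed = seed, ...)
}

flat_amplitude <- function(value = 1) {
  m <- default_effect_amplitude()
  m[] <- value
  m
}

default_band_filter <- function() {
  function(v) bandpass_filter(v)
}
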