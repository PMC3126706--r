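# Shared fixtures: a noiseless sensor model for deterministic checks and a
# short study design that keeps simulation-heavy tests fast (600 s instead
# of the full 4 h; the pipeline's structure is duration-independent).

quiet_noise <- function() {
  sensor_noise_model(timing_jitter_sd = 0, pressure_noise_sd = 0,
                     pressure_drift_amplitude = 0,
                     pump_drift_max_fraction = 0,
                     pump_load_sensitivity = 0)
}

short_design <- function(seed = 1L, duration = 600, replicates = 2,
                         us_window = c(60, 180)) {
  study_design(replicates = replicates, duration = duration,
               ultrasound_window = us_window, seed = seed)
}

# module objects reused across files (default_circuit solves the valve once)
test_circuit <- default_circuit()
test_carrier <- default_carrier()
test_waveform <- make_ica_waveform()
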