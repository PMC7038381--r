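# Small fixtures built in code: a short excitation cycle and reduced
# beverage panels keep the unit tests fast; full-size designs are
# exercised in test-acceptance.R.

tiny_excitation <- function() {
  excitation_spec(segment_frequencies = c(1, 2),
                  pulse_amplitudes = c(1, 0.6, 0.2),
                  cycle_duration = 8, sampling_rate = 40)
}

tiny_dataset <- function(classes = c("a", "b", "c"), replicates = 2,
                         concentrations = 1, seed = 1, model = electrode_model()) {
  simulate_beverage_dataset(class_names = classes,
                            concentrations = concentrations,
                            replicates = replicates,
                            excitation = tiny_excitation(),
                            model = model, seed = seed)
}

random_sensor <- function(m, d, scale = 1) {
  matrix(stats::rnorm(m * d, sd = scale), nrow = m)
}
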