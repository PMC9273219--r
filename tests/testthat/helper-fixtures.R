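# small in-code fixtures shared across test files

# deterministic multi-neuron trace set: sinusoids + constants
toy_traces <- function(n_neurons = 4, n_frames = 200, fs = 2,
                       baseline = 100) {
  t <- (seq_len(n_frames) - 1) / fs
  vals <- matrix(baseline, n_neurons, n_frames)
  for (i in seq_len(n_neurons)) {
    vals[i, ] <- baseline * (1 + 0.5 * sin(2 * pi * 0.05 * t + i))
  }
  calcium_traces(vals, fs, trial_id = "toy", condition = "test")
}

# the four-signal worked example: sin, -sin, sin, -sin
four_sinusoids <- function(n_frames = 400, fs = 2) {
  t <- (seq_len(n_frames) - 1) / fs
  s <- sin(2 * pi * 0.05 * t)
  rbind(s, -s, s, -s)
}
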