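# shared fixture builders; everything is generated in code at test time

make_recording <- function(n = 300, channels = c("O1", "F3"), rate = 90,
                           seed = 1, reference = "common") {
  set.seed(seed)
  eeg_recording(matrix(rnorm(n * length(channels)), n, length(channels)),
                rate, channels, reference = reference)
}

# one normalized full-length window simulated from a scenario
scenario_window <- function(scenario, n = 5402, seed = 1, window_s = 60) {
  rec <- simulate_var(scenario, n, seed = seed)
  sliding_windows(rec, window_s, window_s)[[1]]
}

# a tiny fully-connected 3-channel montage
tri_montage <- function(labels = c("F3", "F4", "Cz")) {
  montage(stats::setNames(lapply(seq_along(labels), function(i) labels[-i]),
                          labels))
}

# companion spectral radius of a coefficient list
.stability_radius <- function(coefs) {
  max(Mod(eigen(companion_matrix(coefs), only.values = TRUE)$values))
}

.restab <- function(m) check_stability(m$coefficients)
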