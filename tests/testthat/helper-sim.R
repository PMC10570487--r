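# Shared helpers: small simulation configurations and constructors for
# hand-built epoch sets / analytic tensors used across test files.

tiny_sim <- function(seed = 1L, n_dyads = 1L, n_trials_per_mode = 4L,
                     fs = 250, ...) {
  sim_config(n_dyads = n_dyads, fs = fs,
             n_trials_per_mode = n_trials_per_mode, seed = seed, ...)
}

# epoch_set from an explicit trials x channels x samples array
make_epochs <- function(arr, fs = 250, tmin = -1) {
  ns <- dim(arr)[3]
  structure(list(
    data = arr,
    times = tmin + (seq_len(ns) - 1L) / fs,
    fs = fs,
    labels = data.frame(trial = seq_len(dim(arr)[1]),
                        mode = NA_character_, run = NA_integer_),
    channels = paste0("ch", seq_len(dim(arr)[2]))
  ), class = "epoch_set")
}

# analytic tensor holding unit phasors of the given phase array
# (trials x channels x samples)
phase_tensor <- function(ph, fs = 1, tmin = 0, band = "theta") {
  d <- dim(ph)
  structure(list(
    values = array(exp(1i * ph), d),
    times = tmin + (seq_len(d[3]) - 1L) / fs,
    fs = fs, band = band,
    labels = data.frame(trial = seq_len(d[1])),
    channels = paste0("ch", seq_len(d[2]))
  ), class = "analytic_tensor")
}
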