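# build an eeg_epochs object directly from a channels x samples x epochs
# array, for tests that need exact control over the data
make_epochset <- function(data, labels, trial_ids = NULL, fs = 256,
                          baselines = NULL) {
  n_ch <- dim(data)[1]
  montage <- if (n_ch == 14) emotiv_montage() else
    make_montage(sprintf("CH%02d", seq_len(n_ch)),
                 rep(c("F", "C", "Te", "Pa", "O"), length.out = n_ch))
  if (is.null(trial_ids)) trial_ids <- seq_len(dim(data)[3])
  ep <- rep(1L, length(trial_ids))
  for (i in seq_along(trial_ids)) {
    ep[i] <- sum(trial_ids[seq_len(i)] == trial_ids[i])
  }
  structure(list(data = data,
                 labels = factor(labels, levels = c("fear", "joy", "neutral")),
                 trial_ids = trial_ids, epoch_ids = ep,
                 band = "broadband", fs = fs, montage = montage,
                 baselines = baselines),
            class = "eeg_epochs")
}

# generator -> broadband epochs in one step (segment, epoch; no rejection)
quick_epochs <- function(..., baseline_ms = NULL) {
  gen <- generate_recording(generator_config(...))
  ep <- epoch_trials(segment_trials(gen$recording))
  if (!is.null(baseline_ms)) ep <- baseline_correct(ep, baseline_ms)
  list(epochs = ep, truth = gen$truth, recording = gen$recording)
}

abs_cosine <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
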