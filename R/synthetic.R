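#' Configuration for the synthetic EEG generator
#'
#' Default trial counts and durations follow the study layout of the four
#' emotion-elicitation paradigms: emotional imagery (EI) and video (VI) use
#' 10 trials per state of 60 s; picture (PI) uses 45 trials of 7 s; sound
#' (SI) uses 45 trials with durations between 6 and 10 s, fixed here at the
#' 7 s midpoint so the 5 s analysis window always fits. Every trial is
#' preceded by a 5 s pre-stimulus baseline.
#'
#' Amplitudes are in microvolts. The 1/f background is scaled to
#' `background_rms` per channel (default 2 uV RMS), chosen so that a planted
#' source at snr = 10 stays below the 150 uV peak-to-peak epoch-rejection
#' threshold. `snr` is the ratio of total planted-source power to total
#' background power across channels.
#'
#' @param paradigm one of "EI", "VI", "PI", "SI".
#' @param n_channels number of channels (14 gives the Emotiv montage).
#' @param fs sampling frequency, Hz.
#' @param trials_per_state trials per emotional state; default per paradigm.
#' @param trial_duration activity duration per trial in seconds; default per
#'   paradigm.
#' @param baseline_duration pre-stimulus baseline in seconds.
#' @param band_of_effect Hz interval of the planted class-dependent sources.
#' @param snr source-to-background power ratio (>= 0; 0 plants no source).
#' @param artifact_rate per-epoch probability of an injected artifact.
#' @param background_rms background amplitude per channel, uV RMS.
#' @param pattern_jitter sd of per-subject Gaussian jitter added to the
#'   mixing patterns before renormalization (inter-subject variability).
#' @param seed integer seed; all randomness flows from it.
#' @return a `generator_config` list.
#' @export
generator_config <- function(paradigm = c("EI", "VI", "PI", "SI"),
                             n_channels = 14, fs = 256,
                             trials_per_state = NULL, trial_duration = NULL,
                             baseline_duration = 5, band_of_effect = c(8, 13),
                             snr = 1, artifact_rate = 0, background_rms = 2,
                             pattern_jitter = 0, seed = 1) {
  paradigm <- match.arg(paradigm)
  defaults <- list(EI = c(10, 60), VI = c(10, 60), PI = c(45, 7), SI = c(45, 7))
  if (is.null(trials_per_state)) trials_per_state <- defaults[[paradigm]][1]
  if (is.null(trial_duration)) trial_duration <- defaults[[paradigm]][2]
  stopifnot(n_channels >= 2, fs > 0, trials_per_state >= 1,
            trial_duration > 0, baseline_duration >= 0,
            length(band_of_effect) == 2, band_of_effect[1] > 0,
            band_of_effect[2] > band_of_effect[1],
            snr >= 0, artifact_rate >= 0, artifact_rate <= 1,
            background_rms > 0, pattern_jitter >= 0)
  if (fs <= 2 * band_of_effect[2]) {
    stop(sprintf("band_of_effect upper edge %g Hz is infeasible at fs = %g Hz (needs fs > %g)",
                 band_of_effect[2], fs, 2 * band_of_effect[2]))
  }
  structure(list(paradigm = paradigm, n_channels = n_channels, fs = fs,
                 trials_per_state = trials_per_state,
                 trial_duration = trial_duration,
                 baseline_duration = baseline_duration,
                 band_of_effect = band_of_effect, snr = snr,
                 artifact_rate = artifact_rate,
                 background_rms = background_rms,
                 pattern_jitter = pattern_jitter,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# 1/f-amplitude Gaussian noise, unit variance, via spectral shaping
one_over_f_noise <- function(n, fs) {
  w <- stats::rnorm(n)
  k <- 0:(n - 1)
  freq <- pmin(k, n - k) * fs / n
  amp <- 1 / sqrt(pmax(freq, 1))   # flat below 1 Hz to keep power finite
  x <- Re(stats::fft(stats::fft(w) * amp, inverse = TRUE)) / n
  x / stats::sd(x)
}

# deterministic sub-stream seed per trial (kept below 2^31)
trial_seed <- function(seed, trial) {
  as.integer((as.double(seed) * 48271 + 1009 * trial) %% 2147483647)
}

#' Generate a synthetic multichannel EEG recording with known ground truth
#'
#' Produces a continuous recording of `3 * trials_per_state` trials in
#' alternating state order (fear, neutral, joy, fear, ...), each trial a
#' pre-stimulus baseline followed by an activity window. The background is
#' 1/f-shaped Gaussian noise mixed through a random full-rank matrix, so its
#' spatial covariance is non-diagonal. During each activity window a
#' band-limited source (white noise band-passed to `band_of_effect`) is
#' mixed into the channels through that state's unit-norm mixing pattern at
#' the requested signal-to-noise ratio.
#'
#' @param config a [generator_config()].
#' @return list with `recording` (an `eeg_recording`) and `truth` (list with
#'   `mixing_patterns` — channels x 3 matrix, one column per state —
#'   `source_band`, and `artifact_epochs`, filled by [inject_artifacts()]).
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  N <- config$n_channels
  fs <- config$fs
  states <- c("fear", "neutral", "joy")
  n_trials <- 3L * config$trials_per_state
  trial_states <- rep(states, config$trials_per_state)
  nb <- as.integer(round(config$baseline_duration * fs))
  na <- as.integer(round(config$trial_duration * fs))
  block <- nb + na
  n <- n_trials * block

  set.seed(config$seed)
  # state mixing patterns: unit-norm, almost surely independent; redraw on
  # near-collinearity so CSP recovery is well posed
  repeat {
    P <- matrix(stats::rnorm(N * 3), N, 3)
    P <- sweep(P, 2, sqrt(colSums(P^2)), "/")
    cc <- abs(crossprod(P))
    if (max(cc[upper.tri(cc)]) < 0.9) break
  }
  if (config$pattern_jitter > 0) {
    P <- P + matrix(stats::rnorm(N * 3, sd = config$pattern_jitter), N, 3)
    P <- sweep(P, 2, sqrt(colSums(P^2)), "/")
  }
  colnames(P) <- states

  # spatially correlated 1/f background at background_rms per channel
  A <- matrix(stats::rnorm(N * N), N, N)
  S <- t(vapply(seq_len(N), function(i) one_over_f_noise(n, fs),
                numeric(n)))
  bg <- A %*% S
  bg <- sweep(bg, 1, apply(bg, 1, stats::sd) / config$background_rms, "/")
  samples <- bg

  src_filt <- butter_bandpass_sos(config$band_of_effect, fs)
  src_scale <- sqrt(config$snr * N * config$background_rms^2)
  onsets <- integer(n_trials)
  for (tr in seq_len(n_trials)) {
    onset <- (tr - 1L) * block + nb + 1L
    onsets[tr] <- onset
    if (config$snr > 0) {
      set.seed(trial_seed(config$seed, tr))
      src <- sos_filtfilt(src_filt, stats::rnorm(na))
      src <- src / stats::sd(src) * src_scale
      idx <- onset:(onset + na - 1L)
      samples[, idx] <- samples[, idx] +
        P[, trial_states[tr]] %*% matrix(src, 1)
    }
  }

  montage <- if (N == 14) emotiv_montage() else
    make_montage(sprintf("CH%02d", seq_len(N)),
                 rep(c("F", "C", "Te", "Pa", "O"), length.out = N))
  rownames(samples) <- montage$channels
  events <- data.frame(onset_sample = onsets,
                       state = trial_states,
                       paradigm = config$paradigm,
                       stringsAsFactors = FALSE)
  rec <- structure(list(samples = samples, fs = fs, montage = montage,
                        events = events, baseline_samples = nb,
                        artifacts = NULL),
                   class = "eeg_recording")
  truth <- list(mixing_patterns = P, source_band = config$band_of_effect,
                artifact_epochs = data.frame(trial = integer(0),
                                             epoch = integer(0)))
  list(recording = rec, truth = truth)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples at %g Hz (%.1f s), %d events\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs, nrow(x$events)))
  if (!is.null(x$artifacts) && nrow(x$artifacts) > 0) {
    cat(sprintf("  %d injected artifact epochs\n", nrow(x$artifacts)))
  }
  invisible(x)
}

#' Inject high-amplitude transient artifacts at epoch-aligned positions
#'
#' Adds a one-sided half-sine deflection of height `amplitude` to a random
#' channel of randomly chosen analysis-window epochs. Because the deflection
#' is one-sided, the epoch's max-min range is guaranteed to reach at least
#' `amplitude`, making every injected epoch rejectable by the 150 uV rule.
#' Injected positions are recorded in the returned recording's `artifacts`
#' field as (trial, epoch-within-analysis-window) pairs.
#'
#' @param recording an `eeg_recording` with events.
#' @param rate per-epoch injection probability in `[0, 1]`.
#' @param amplitude deflection height in uV; must exceed 150 so injected
#'   epochs are rejectable.
#' @param seed integer seed.
#' @return the recording with artifacts added and positions recorded.
#' @export
inject_artifacts <- function(recording, rate, amplitude = 200, seed = 1) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (rate < 0 || rate > 1) stop("artifact rate must be in [0, 1]")
  if (amplitude <= 150) {
    stop("artifact amplitude must exceed 150 uV peak-to-peak to be rejectable")
  }
  if (rate == 0) return(recording)
  geo <- trial_geometry(recording)
  fs <- recording$fs
  set.seed(as.integer(seed))
  hits <- list()
  pulse_len <- max(4L, round(fs / 8))
  pulse <- amplitude * sin(pi * seq_len(pulse_len) / (pulse_len + 1))
  for (tr in seq_len(nrow(geo))) {
    n_ep <- geo$n_epochs[tr]
    if (n_ep < 1) next
    hit <- which(stats::runif(n_ep) < rate)
    for (ep in hit) {
      start <- geo$win_start[tr] + (ep - 1L) * fs
      pos <- start + sample.int(fs - pulse_len, 1) - 1L
      ch <- sample.int(nrow(recording$samples), 1)
      recording$samples[ch, pos:(pos + pulse_len - 1L)] <-
        recording$samples[ch, pos:(pos + pulse_len - 1L)] + pulse
    }
    if (length(hit) > 0) {
      hits[[length(hits) + 1L]] <- data.frame(trial = tr, epoch = hit)
    }
  }
  recording$artifacts <- if (length(hits) > 0) {
    do.call(rbind, hits)
  } else {
    data.frame(trial = integer(0), epoch = integer(0))
  }
  recording
}

#' Simulate a region-level band-power table for ANOVA calibration studies
#'
#' Draws percent band-power changes directly at the (subject, state, band,
#' region) cell level: a subject random intercept plus i.i.d. Gaussian
#' noise, with an optional additive state effect confined to one
#' (band, region) cell. With `effect = 0` the design is an exact null for
#' the state factor, which is what the ANOVA calibration tests exercise.
#'
#' @param n_subjects number of subjects.
#' @param states,bands,regions factor levels of the within-subject design.
#' @param effect additive shift (percent points) applied to the first state
#'   in cell `effect_cell`.
#' @param effect_cell character length-2: (band, region) receiving the shift.
#' @param subject_sd sd of the subject random intercept.
#' @param noise_sd residual sd.
#' @param seed integer seed.
#' @return data.frame with columns subject, paradigm, state, band, region,
#'   percent_change.
#' @export
simulate_bandpower_table <- function(n_subjects = 8,
                                     states = c("fear", "joy"),
                                     bands = c("delta", "theta", "alpha",
                                               "beta", "low_gamma"),
                                     regions = c("F", "C", "Te", "Pa", "O"),
                                     effect = 0,
                                     effect_cell = c("alpha", "F"),
                                     subject_sd = 5, noise_sd = 10,
                                     seed = 1) {
  set.seed(as.integer(seed))
  tab <- expand.grid(subject = seq_len(n_subjects), state = states,
                     band = bands, region = regions,
                     stringsAsFactors = FALSE)
  intercept <- stats::rnorm(n_subjects, sd = subject_sd)
  tab$percent_change <- intercept[tab$subject] +
    stats::rnorm(nrow(tab), sd = noise_sd)
  if (effect != 0) {
    sel <- tab$state == states[1] & tab$band == effect_cell[1] &
      tab$region == effect_cell[2]
    tab$percent_change[sel] <- tab$percent_change[sel] + effect
  }
  tab$paradigm <- "EI"
  tab[, c("subject", "paradigm", "state", "band", "region", "percent_change")]
}
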