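#' Analysis-window length for a paradigm
#'
#' Long-stimulus paradigms (emotional imagery EI, video VI) are analyzed
#' over the last 55 s of each trial; short-stimulus paradigms (picture PI,
#' sound SI) over the last 5 s.
#'
#' @param paradigm one of "EI", "VI", "PI", "SI".
#' @return window length in seconds.
#' @export
analysis_window_s <- function(paradigm) {
  switch(paradigm, EI = 55, VI = 55, PI = 5, SI = 5,
         stop("unknown paradigm: ", paradigm))
}

# per-trial sample geometry: onset, activity end, analysis window, epoch count
trial_geometry <- function(recording, analysis_window = NULL) {
  ev <- recording$events[order(recording$events$onset_sample), ]
  if (nrow(ev) == 0) stop("recording has no events")
  fs <- recording$fs
  W <- if (is.null(analysis_window)) {
    analysis_window_s(ev$paradigm[1])
  } else {
    analysis_window
  }
  nb <- if (!is.null(recording$baseline_samples)) {
    recording$baseline_samples
  } else {
    ev$onset_sample[1] - 1L   # recording starts with the first baseline
  }
  n <- ncol(recording$samples)
  onset <- ev$onset_sample
  act_end <- c(onset[-1] - nb - 1L, n)
  win_len <- round(W * fs)
  win_start <- act_end - win_len + 1L
  data.frame(trial = seq_len(nrow(ev)), state = ev$state,
             onset = onset, act_end = act_end,
             base_start = pmax(1L, onset - nb), base_end = onset - 1L,
             win_start = win_start, win_end = act_end,
             n_epochs = ifelse(win_start >= onset, floor(win_len / fs), 0L))
}

#' Segment a recording into per-trial analysis windows with baselines
#'
#' For every stimulus event, extracts the paradigm's analysis window (the
#' last 55 s of EI/VI trials, the last 5 s of PI/SI trials) together with
#' the pre-stimulus baseline segment. Trials too short to contain the full
#' window are dropped with a warning.
#'
#' @param recording an `eeg_recording`.
#' @param paradigm paradigm code; defaults to the one recorded in the
#'   events table.
#' @param analysis_window optional window length in seconds, overriding the
#'   paradigm default.
#' @return an `eeg_trials` object: list of trials, each holding `data`
#'   (channels x window samples), `baseline` (channels x baseline samples),
#'   `state` and `trial_id`.
#' @export
segment_trials <- function(recording, paradigm = NULL,
                           analysis_window = NULL) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (is.null(paradigm)) paradigm <- recording$events$paradigm[1]
  if (is.null(analysis_window)) analysis_window <- analysis_window_s(paradigm)
  geo <- trial_geometry(recording, analysis_window)
  trials <- list()
  for (tr in seq_len(nrow(geo))) {
    if (geo$win_start[tr] < geo$onset[tr]) {
      warning(sprintf("trial %d shorter than the %g s analysis window; dropped",
                      tr, analysis_window))
      next
    }
    trials[[length(trials) + 1L]] <- list(
      data = recording$samples[, geo$win_start[tr]:geo$win_end[tr],
                               drop = FALSE],
      baseline = recording$samples[, geo$base_start[tr]:geo$base_end[tr],
                                   drop = FALSE],
      state = geo$state[tr], trial_id = geo$trial[tr])
  }
  structure(list(trials = trials, fs = recording$fs,
                 montage = recording$montage, paradigm = paradigm,
                 analysis_window = analysis_window),
            class = "eeg_trials")
}

#' @export
print.eeg_trials <- function(x, ...) {
  st <- vapply(x$trials, `[[`, character(1), "state")
  cat(sprintf("EEG trial set (%s): %d trials, %g s analysis windows [%s]\n",
              x$paradigm, length(x$trials), x$analysis_window,
              paste(sprintf("%s=%d", names(table(st)), table(st)),
                    collapse = " ")))
  invisible(x)
}

state_levels <- c("fear", "joy", "neutral")

#' Cut trial analysis windows into non-overlapping 1 s epochs
#'
#' Each epoch is a channels x `fs` matrix tagged with its state label,
#' trial of origin and position within the trial; trailing samples that do
#' not fill a whole second are discarded. Trial baselines are carried along
#' for later baseline correction and band-power referencing.
#'
#' @param trialset an `eeg_trials` object from [segment_trials()].
#' @param epoch_length epoch length in seconds (default 1).
#' @return an `eeg_epochs` object: `data` is a channels x samples x epochs
#'   array, with `labels`, `trial_ids`, `epoch_ids`, `band`, `fs`,
#'   `montage`, and per-trial `baselines`.
#' @export
epoch_trials <- function(trialset, epoch_length = 1) {
  stopifnot(inherits(trialset, "eeg_trials"))
  fs <- trialset$fs
  len <- round(epoch_length * fs)
  n_ch <- nrow(trialset$trials[[1]]$data)
  chunks <- list(); labels <- character(0)
  trial_ids <- integer(0); epoch_ids <- integer(0)
  baselines <- list()
  for (tr in trialset$trials) {
    n_ep <- floor(ncol(tr$data) / len)
    for (e in seq_len(n_ep)) {
      chunks[[length(chunks) + 1L]] <-
        tr$data[, ((e - 1L) * len + 1L):(e * len), drop = FALSE]
    }
    labels <- c(labels, rep(tr$state, n_ep))
    trial_ids <- c(trial_ids, rep(tr$trial_id, n_ep))
    epoch_ids <- c(epoch_ids, seq_len(n_ep))
    baselines[[as.character(tr$trial_id)]] <- tr$baseline
  }
  data <- array(unlist(chunks), dim = c(n_ch, len, length(chunks)))
  structure(list(data = data,
                 labels = factor(labels, levels = state_levels),
                 trial_ids = trial_ids, epoch_ids = epoch_ids,
                 band = "broadband", fs = fs, montage = trialset$montage,
                 baselines = baselines),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("EEG epochs (%s): %d epochs of %d channels x %d samples at %g Hz\n",
              if (is.character(x$band)) x$band else
                sprintf("%g-%g Hz", x$band[1], x$band[2]),
              d[3], d[1], d[2], x$fs))
  print(table(droplevels(x$labels)))
  invisible(x)
}

#' Number of epochs in an epoch set
#' @param epochset an `eeg_epochs` object.
#' @export
n_epochs <- function(epochset) dim(epochset$data)[3]

#' Subset an epoch set by epoch index
#' @param epochset an `eeg_epochs` object.
#' @param idx integer or logical epoch index.
#' @return an `eeg_epochs` holding the selected epochs.
#' @export
subset_epochs <- function(epochset, idx) {
  epochset$data <- epochset$data[, , idx, drop = FALSE]
  epochset$labels <- epochset$labels[idx]
  epochset$trial_ids <- epochset$trial_ids[idx]
  epochset$epoch_ids <- epochset$epoch_ids[idx]
  epochset
}

#' Reject epochs by the max-min amplitude rule
#'
#' An epoch is rejected when the peak-to-peak amplitude (max minus min) on
#' any channel exceeds `threshold` microvolts; the default 150 uV is the
#' conventional cutoff for ocular/movement artifacts. The rule is applied
#' per channel and an epoch fails if its worst channel fails.
#'
#' @param epochset an `eeg_epochs` object with data in uV.
#' @param threshold rejection threshold in uV (> 0).
#' @return list with `epochs` (the retained set) and `report`, a data.frame
#'   of rejected (trial, epoch) positions with the offending range.
#' @export
reject_epochs_maxmin <- function(epochset, threshold = 150) {
  stopifnot(inherits(epochset, "eeg_epochs"))
  if (threshold <= 0) stop("rejection threshold must be positive")
  rng <- apply(epochset$data, 3, function(X) {
    max(apply(X, 1, max) - apply(X, 1, min))
  })
  bad <- rng > threshold
  report <- data.frame(trial = epochset$trial_ids[bad],
                       epoch = epochset$epoch_ids[bad],
                       range_uv = rng[bad])
  list(epochs = subset_epochs(epochset, !bad), report = report)
}

#' Baseline-correct epochs against the immediate pre-stimulus interval
#'
#' For every trial and channel, the mean amplitude over the final
#' `interval_ms` milliseconds before stimulus onset is subtracted from all
#' of that trial's post-stimulus epochs. Trials whose stored baseline is
#' shorter than the interval are dropped with a warning.
#'
#' @param epochset an `eeg_epochs` object carrying trial baselines.
#' @param interval_ms pre-stimulus averaging interval in milliseconds
#'   (default 200).
#' @return the corrected `eeg_epochs`.
#' @export
baseline_correct <- function(epochset, interval_ms = 200) {
  stopifnot(inherits(epochset, "eeg_epochs"))
  ns <- max(1L, round(interval_ms / 1000 * epochset$fs))
  keep <- rep(TRUE, n_epochs(epochset))
  for (tid in unique(epochset$trial_ids)) {
    bl <- epochset$baselines[[as.character(tid)]]
    if (is.null(bl) || ncol(bl) < ns) {
      warning(sprintf("trial %d lacks a %g ms baseline; dropped", tid,
                      interval_ms))
      keep[epochset$trial_ids == tid] <- FALSE
      next
    }
    mu <- rowMeans(bl[, (ncol(bl) - ns + 1L):ncol(bl), drop = FALSE])
    sel <- which(epochset$trial_ids == tid)
    epochset$data[, , sel] <- epochset$data[, , sel, drop = FALSE] - mu
  }
  subset_epochs(epochset, keep)
}

#' Filter-bank specification
#'
#' The default bands are delta 1-3, theta 4-7, alpha 8-13, beta 14-30,
#' low gamma 31-50 and high gamma 51-70 Hz, filtered with a zero-phase
#' order-5 Butterworth band-pass per band.
#'
#' @param bands named list of Hz intervals.
#' @param order Butterworth prototype order.
#' @return a `filter_bank_spec` list.
#' @export
filter_bank_spec <- function(bands = list(delta = c(1, 3), theta = c(4, 7),
                                          alpha = c(8, 13), beta = c(14, 30),
                                          low_gamma = c(31, 50),
                                          high_gamma = c(51, 70)),
                             order = 5) {
  stopifnot(length(bands) > 0, !is.null(names(bands)))
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (length(b) != 2 || b[1] <= 0 || b[2] <= b[1]) {
      stop("invalid band interval for ", nm)
    }
  }
  structure(list(bands = bands, order = order), class = "filter_bank_spec")
}

# zero-phase band-pass of the whole epoch tensor (and trial baselines)
filter_epochset <- function(epochset, band, order = 5, band_name = NULL) {
  fs <- epochset$fs
  if (band[2] >= fs / 2) {
    stop(sprintf("band %s (%g-%g Hz) upper edge reaches Nyquist at fs = %g",
                 band_name %||% "", band[1], band[2], fs))
  }
  filt <- butter_bandpass_sos(band, fs, order)
  d <- dim(epochset$data)
  # rows = channel x epoch series, columns = time
  M <- matrix(aperm(epochset$data, c(1, 3, 2)), d[1] * d[3], d[2])
  M <- sos_filtfilt(filt, M)
  epochset$data <- aperm(array(M, c(d[1], d[3], d[2])), c(1, 3, 2))
  epochset$baselines <- lapply(epochset$baselines, function(bl) {
    sos_filtfilt(filt, bl)
  })
  epochset$band <- band
  epochset$band_name <- band_name
  epochset
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a Butterworth band-pass filter bank to an epoch set
#'
#' Produces one band-limited copy of the epoch set (and of its trial
#' baselines) per band in the specification. Filtering is zero-phase
#' (forward-backward), so the effective attenuation is the squared
#' magnitude response of the order-5 design.
#'
#' @param epochset an `eeg_epochs` object.
#' @param spec a [filter_bank_spec()].
#' @return named list of band-limited `eeg_epochs`, one per band.
#' @export
bandpass_filterbank <- function(epochset, spec = filter_bank_spec()) {
  stopifnot(inherits(epochset, "eeg_epochs"),
            inherits(spec, "filter_bank_spec"))
  out <- lapply(names(spec$bands), function(nm) {
    filter_epochset(epochset, spec$bands[[nm]], spec$order, nm)
  })
  names(out) <- names(spec$bands)
  out
}
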