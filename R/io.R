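#' Write a recording as delimited text (samples + events + montage)
#'
#' `path` is a stem: writes `<stem>_samples.tsv` (one row per sample,
#' columns = channels in montage order, header = channel names),
#' `<stem>_events.tsv` (onset_sample, state, paradigm) and
#' `<stem>_montage.tsv`. Values are written in full double precision so the
#' round-trip is bit-identical.
#'
#' @param recording an `eeg_recording`.
#' @param path file stem (no extension).
#' @return the stem, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  samp <- as.data.frame(t(recording$samples))
  names(samp) <- recording$montage$channels
  utils::write.table(format(samp, digits = 17, trim = TRUE, scientific = TRUE),
                     paste0(path, "_samples.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ev <- recording$events
  ev$fs <- recording$fs
  ev$baseline_samples <- recording$baseline_samples %||% NA
  utils::write.table(ev, paste0(path, "_events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_montage(recording$montage, paste0(path, "_montage.tsv"))
  invisible(path)
}

#' Read a delimited-text recording
#'
#' Reads the three files written by [write_recording()] (or equivalently
#' prepared: a samples table in microvolts with channel-name header, an
#' events sidecar, a montage map) and reassembles the recording. The
#' channel set must match the montage exactly.
#'
#' @param path file stem (no extension).
#' @param format only "delimited" is supported.
#' @return an `eeg_recording`.
#' @export
read_recording <- function(path, format = "delimited") {
  format <- match.arg(format, c("delimited", "edf"))
  if (format == "edf") {
    stop("European Data Format input is not supported by this build; ",
         "use the delimited-text representation")
  }
  sfile <- paste0(path, "_samples.tsv")
  efile <- paste0(path, "_events.tsv")
  mfile <- paste0(path, "_montage.tsv")
  for (f in c(sfile, efile, mfile)) {
    if (!file.exists(f)) stop("missing recording file: ", f)
  }
  montage <- read_montage(mfile)
  samp <- utils::read.table(sfile, header = TRUE, sep = "\t",
                            check.names = FALSE)
  missing_ch <- setdiff(montage$channels, names(samp))
  if (length(missing_ch) > 0) {
    stop("samples file lacks montage channel(s): ",
         paste(missing_ch, collapse = ", "))
  }
  ev <- utils::read.table(efile, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("onset_sample", "state", "paradigm", "fs")
  if (!all(need %in% names(ev))) {
    stop("events file must have columns: ", paste(need, collapse = ", "))
  }
  samples <- t(as.matrix(samp[, montage$channels]))
  if (any(ev$onset_sample < 1 | ev$onset_sample > ncol(samples))) {
    stop("event onset outside the recording")
  }
  structure(list(samples = samples, fs = ev$fs[1], montage = montage,
                 events = ev[, c("onset_sample", "state", "paradigm")],
                 baseline_samples = if (!is.na(ev$baseline_samples[1]))
                   ev$baseline_samples[1] else NULL,
                 artifacts = NULL),
            class = "eeg_recording")
}

#' Pipeline configuration
#'
#' Collects and validates every knob of the end-to-end analysis. With
#' `input = "synthetic"` the pipeline generates its own recordings from
#' [generator_config()] parameters; otherwise `input` is a vector of
#' recording file stems (one per subject) for [read_recording()].
#'
#' @param input "synthetic" or character vector of recording stems.
#' @param paradigm paradigm code.
#' @param n_subjects subjects to simulate (synthetic input only).
#' @param generator named list of [generator_config()] overrides.
#' @param bands named list of Hz intervals for the filter bank.
#' @param filter_order Butterworth prototype order.
#' @param m CSP filters per tail.
#' @param n_folds,n_reps cross-validation scheme.
#' @param reject_threshold max-min rejection threshold, uV.
#' @param baseline_ms baseline-correction interval, ms.
#' @param seed master seed for the run.
#' @param output_dir directory for the result bundle (NULL: nothing
#'   written).
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(input = "synthetic", paradigm = "EI",
                            n_subjects = 1, generator = list(),
                            bands = filter_bank_spec()$bands,
                            filter_order = 5, m = 3, n_folds = 10,
                            n_reps = 10, reject_threshold = 150,
                            baseline_ms = 200, seed = 1,
                            output_dir = NULL) {
  stopifnot(paradigm %in% c("EI", "VI", "PI", "SI"),
            n_subjects >= 1, m >= 1, n_folds >= 2, n_reps >= 1,
            reject_threshold > 0, baseline_ms > 0)
  spec <- filter_bank_spec(bands, filter_order)   # validates bands
  if (!identical(input, "synthetic")) {
    stopifnot(is.character(input), length(input) >= 1)
  }
  structure(list(input = input, paradigm = paradigm,
                 n_subjects = as.integer(n_subjects), generator = generator,
                 bands = spec$bands, filter_order = filter_order,
                 m = as.integer(m), n_folds = as.integer(n_folds),
                 n_reps = as.integer(n_reps),
                 reject_threshold = reject_threshold,
                 baseline_ms = baseline_ms, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

# subject-level preprocessing: recording -> band-filtered epoch sets
preprocess_recording <- function(recording, config) {
  trials <- segment_trials(recording, config$paradigm)
  epochs <- epoch_trials(trials)
  rej <- reject_epochs_maxmin(epochs, config$reject_threshold)
  epochs <- baseline_correct(rej$epochs, config$baseline_ms)
  list(by_band = bandpass_filterbank(
         epochs, filter_bank_spec(config$bands, config$filter_order)),
       rejection = rej$report,
       n_epochs_raw = n_epochs(epochs))
}

#' Run the full analysis pipeline
#'
#' Executes segment -> epoch -> max-min rejection -> baseline correction ->
#' filter bank -> per-band CSP + one-vs-rest LDA under trial-wise repeated
#' cross-validation -> band-power change statistics, per subject, then
#' (with 3+ subjects) the repeated-measures ANOVA across subjects. With an
#' `output_dir` set, writes the accuracy grid, band-power table, ANOVA
#' table, follow-up contrasts, topographic exports and a run manifest as
#' delimited text.
#'
#' @param config a [pipeline_config()].
#' @return a result bundle (list): `accuracy` (per subject), `cv` (raw
#'   `cv_result`s), `band_power`, `anova`, `contrasts`, `topo`, `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  n_subj <- if (identical(config$input, "synthetic")) {
    config$n_subjects
  } else {
    length(config$input)
  }
  cvs <- list(); bp <- list(); topo_rows <- list()
  for (si in seq_len(n_subj)) {
    if (identical(config$input, "synthetic")) {
      gargs <- utils::modifyList(
        list(paradigm = config$paradigm,
             seed = trial_seed(config$seed, 7919 + si)),
        config$generator)
      gen <- generate_recording(do.call(generator_config, gargs))
      rec <- gen$recording
    } else {
      rec <- read_recording(config$input[si])
    }
    pp <- preprocess_recording(rec, config)
    note("subject %d: %d epochs, %d rejected", si, pp$n_epochs_raw,
         nrow(pp$rejection))
    cvs[[si]] <- run_cv(pp$by_band, n_folds = config$n_folds,
                        n_reps = config$n_reps, m = config$m,
                        seed = trial_seed(config$seed, 104729 + si))
    bp[[si]] <- band_power_table(pp$by_band, subject = si,
                                 paradigm = config$paradigm)
    note("subject %d: mean three-class accuracy %.1f%%", si,
         mean(cvs[[si]]$mean_multiclass))
  }

  acc <- do.call(rbind, lapply(seq_len(n_subj), function(si) {
    g <- accuracy_grid(cvs[[si]])
    g$subject <- si
    g
  }))
  band_tab <- do.call(rbind, bp)
  region_tab <- region_average(band_tab)

  anova_tab <- NULL; contr <- NULL
  if (n_subj >= 3) {
    two_state <- region_tab[region_tab$state %in% c("fear", "joy"), ]
    anova_tab <- rm_anova(two_state, c("state", "band", "region"))
    contr <- state_contrasts(two_state)
  } else {
    note("ANOVA skipped: %d subject(s) < 3", n_subj)
  }

  montage <- if (identical(config$input, "synthetic")) {
    emotiv_montage()
  } else {
    read_montage(paste0(config$input[1], "_montage.tsv"))
  }
  topo <- lapply(c("fear", "joy"), function(s) {
    topographic_export(band_tab, montage, state = s)
  })
  names(topo) <- c("fear", "joy")

  bundle <- list(accuracy = acc, cv = cvs, band_power = band_tab,
                 region_power = region_tab, anova = anova_tab,
                 contrasts = contr, topo = topo, log = log_lines,
                 config = config)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(x, f) {
      if (!is.null(x)) {
        utils::write.table(x, file.path(config$output_dir, f), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
    }
    wt(acc, "accuracy_grid.tsv")
    wt(band_tab, "band_power.tsv")
    wt(region_tab, "region_power.tsv")
    wt(anova_tab, "anova.tsv")
    wt(contr, "contrasts.tsv")
    for (s in names(topo)) wt(topo[[s]], sprintf("topo_%s.tsv", s))
    manifest <- list(
      package = "emocsp",
      version = tryCatch(as.character(utils::packageVersion("emocsp")),
                         error = function(e) "unknown"),
      r_version = R.version.string,
      seed = config$seed,
      config = unclass(config)[setdiff(names(config), "output_dir")])
    yaml::write_yaml(manifest, file.path(config$output_dir, "manifest.yaml"))
    writeLines(log_lines, file.path(config$output_dir, "run_log.txt"))
  }
  invisible(bundle)
}
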