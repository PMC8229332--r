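#' Trial-wise repeated cross-validation of the CSP + LDA pipeline
#'
#' Runs the full one-vs-rest classification under an `n_reps` x `n_folds`
#' (default 10 x 10) cross-validation in which *trials* — not epochs — are
#' partitioned into folds, separately and evenly per state. All epochs of a
#' trial therefore live on the same side of every split, so the spatial
#' filters and the classifier never see data from a test trial (no leakage
#' through within-trial autocorrelation). Per repetition the fold
#' assignment is reshuffled; per fold, CSP and LDA are fitted on the
#' training trials only and epoch-level accuracy is measured on the
#' held-out trials. An epoch-wise partitioning mode is available for
#' comparison but inflates accuracy and is not the default.
#'
#' @param epochsets a single labeled `eeg_epochs` or a named list of them
#'   (one per frequency band, identical trial structure).
#' @param n_folds folds per repetition (reduced with a message if a state
#'   has fewer trials).
#' @param n_reps repetitions with reshuffled fold assignment.
#' @param m CSP filters per tail.
#' @param gamma CSP ridge parameter.
#' @param seed integer seed driving all fold shuffles (and the label
#'   permutation, if requested).
#' @param permute_labels if TRUE, state labels are randomly permuted across
#'   trials before the CV — a null run whose accuracy should sit at chance.
#' @param by_epoch if TRUE, partition epochs instead of trials (leaky
#'   fidelity mode).
#' @return a `cv_result`: arrays `binary_acc` (rep x fold x band x state)
#'   and `multi_acc` (rep x fold x band) in percent, plus mean tables
#'   `mean_binary` (band x state) and `mean_multiclass` (per band).
#' @export
run_cv <- function(epochsets, n_folds = 10, n_reps = 10, m = 3, gamma = 0,
                   seed = 1, permute_labels = FALSE, by_epoch = FALSE) {
  if (inherits(epochsets, "eeg_epochs")) {
    epochsets <- list(broadband = epochsets)
  }
  stopifnot(length(epochsets) >= 1, !is.null(names(epochsets)))
  bands <- names(epochsets)
  ref <- epochsets[[1]]
  for (b in bands) {
    stopifnot(identical(epochsets[[b]]$trial_ids, ref$trial_ids),
              identical(epochsets[[b]]$labels, ref$labels))
  }
  states <- levels(droplevels(ref$labels))
  labels <- as.character(ref$labels)
  trial_ids <- ref$trial_ids
  utrials <- unique(trial_ids)
  trial_state <- labels[match(utrials, trial_ids)]

  set.seed(as.integer(seed))
  if (permute_labels) {
    trial_state <- sample(trial_state)
    labels <- trial_state[match(trial_ids, utrials)]
  }

  unit_ids <- if (by_epoch) seq_along(labels) else trial_ids
  uunits <- if (by_epoch) unit_ids else utrials
  unit_state <- if (by_epoch) labels else trial_state

  min_per_state <- min(table(unit_state))
  if (min_per_state < n_folds) {
    message(sprintf("run_cv: only %d units in the smallest state; using %d folds",
                    min_per_state, min_per_state))
    n_folds <- min_per_state
  }

  moments <- lapply(epochsets, epoch_moments)

  binary_acc <- array(NA_real_, c(n_reps, n_folds, length(bands),
                                  length(states)),
                      dimnames = list(NULL, NULL, bands, states))
  multi_acc <- array(NA_real_, c(n_reps, n_folds, length(bands)),
                     dimnames = list(NULL, NULL, bands))
  test_units <- train_units <- matrix(NA_integer_, n_reps, n_folds)

  for (r in seq_len(n_reps)) {
    fold_of_unit <- integer(length(uunits))
    for (s in states) {
      su <- which(unit_state == s)
      fold_of_unit[su[sample.int(length(su))]] <-
        rep_len(seq_len(n_folds), length(su))
    }
    fold_of_epoch <- fold_of_unit[match(unit_ids, uunits)]
    for (k in seq_len(n_folds)) {
      test <- fold_of_epoch == k
      train <- !test
      test_units[r, k] <- sum(fold_of_unit == k)
      train_units[r, k] <- sum(fold_of_unit != k)
      for (bi in seq_along(bands)) {
        mom <- moments[[bi]]
        scores <- matrix(NA_real_, sum(test), length(states),
                         dimnames = list(NULL, states))
        for (s in states) {
          pos <- train & labels == s
          neg <- train & labels != s
          model <- fit_csp_cov(
            matrix(rowMeans(mom$Cflat[, pos, drop = FALSE]), mom$N, mom$N),
            matrix(rowMeans(mom$Cflat[, neg, drop = FALSE]), mom$N, mom$N),
            m = m, gamma = gamma, band = bands[bi])
          fe <- csp_features_from_moments(model, mom)
          f <- fe$features
          lda <- fit_lda(f[pos & fe$valid, , drop = FALSE],
                         f[neg & fe$valid, , drop = FALSE])
          sc <- lda_scores(lda, f[test, , drop = FALSE])
          scores[, s] <- sc
          binary_acc[r, k, bi, s] <-
            100 * mean((sc > 0) == (labels[test] == s))
        }
        pred <- ovr_classify(scores, states)
        multi_acc[r, k, bi] <- 100 * mean(as.character(pred) == labels[test])
      }
    }
  }

  structure(list(binary_acc = binary_acc, multi_acc = multi_acc,
                 mean_binary = apply(binary_acc, c(3, 4), mean),
                 mean_multiclass = apply(multi_acc, 3, mean),
                 test_units = test_units, train_units = train_units,
                 n_folds = n_folds, n_reps = n_reps, m = m, seed = seed,
                 states = states, bands = bands,
                 permuted = permute_labels, by_epoch = by_epoch),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%dx%d cross-validation (%s-wise folds%s), m = %d\n",
              x$n_reps, x$n_folds, if (x$by_epoch) "epoch" else "trial",
              if (x$permuted) ", permuted labels" else "", x$m))
  cat("mean one-vs-rest accuracy (%):\n")
  print(round(x$mean_binary, 1))
  cat("mean three-class accuracy (%):\n")
  print(round(x$mean_multiclass, 1))
  invisible(x)
}

#' Accuracy grid of a cross-validation result as a data frame
#'
#' One row per (band, target state) with the mean one-vs-rest accuracy,
#' plus one row per band for the three-class assignment — the layout of a
#' bands x states accuracy table.
#'
#' @param cv a `cv_result`.
#' @return data.frame with columns band, target, accuracy_pct, sd_pct.
#' @export
accuracy_grid <- function(cv) {
  stopifnot(inherits(cv, "cv_result"))
  rows <- list()
  for (b in cv$bands) {
    for (s in cv$states) {
      a <- cv$binary_acc[, , b, s]
      rows[[length(rows) + 1L]] <- data.frame(
        band = b, target = paste0(s, "_vs_rest"),
        accuracy_pct = mean(a), sd_pct = stats::sd(c(a)))
    }
    a <- cv$multi_acc[, , b]
    rows[[length(rows) + 1L]] <- data.frame(
      band = b, target = "three_class", accuracy_pct = mean(a),
      sd_pct = stats::sd(c(a)))
  }
  do.call(rbind, rows)
}
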