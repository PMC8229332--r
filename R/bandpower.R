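#' Band power per epoch and channel
#'
#' Mean squared amplitude of the (band-limited) signal per channel and
#' epoch, i.e. the power of the signal in the band it was filtered to.
#'
#' @param epochset an `eeg_epochs`, normally band-pass filtered.
#' @return epochs x channels matrix of power values (uV^2).
#' @export
band_power <- function(epochset) {
  stopifnot(inherits(epochset, "eeg_epochs"))
  d <- dim(epochset$data)
  t(apply(epochset$data, 3, function(X) rowMeans(X^2)))
}

#' Percent band-power change relative to a baseline
#'
#' `100 * (stimulus - baseline) / baseline`, the event-related
#' desynchronization/synchronization (ERD/ERS) convention: negative values
#' are power decreases relative to the pre-stimulus reference.
#'
#' @param stimulus_power,baseline_power numeric vectors or matrices of
#'   matching shape; `baseline_power` must be positive.
#' @return percent change, same shape.
#' @export
percent_change <- function(stimulus_power, baseline_power) {
  if (any(baseline_power <= 0)) stop("baseline power must be positive")
  100 * (stimulus_power - baseline_power) / baseline_power
}

#' Per-channel percent band-power change table for one subject
#'
#' For each band-limited epoch set: stimulus power is the mean squared
#' amplitude per (epoch, channel) averaged over the epochs of a trial;
#' the reference is the power of that trial's band-filtered pre-stimulus
#' baseline (the full baseline interval, not the 200 ms correction
#' window, so slow bands have enough cycles). The percent change is then
#' averaged over trials of the same state, giving one row per
#' (state, band, channel).
#'
#' @param epochsets_by_band named list of band-filtered `eeg_epochs` (from
#'   [bandpass_filterbank()]), with baselines attached.
#' @param subject subject identifier for the output rows.
#' @param paradigm paradigm code for the output rows.
#' @return a `band_power_table` data.frame: subject, paradigm, state, band,
#'   channel, region, percent_change.
#' @export
band_power_table <- function(epochsets_by_band, subject = 1,
                             paradigm = "EI") {
  stopifnot(is.list(epochsets_by_band), !is.null(names(epochsets_by_band)))
  rows <- list()
  for (bname in names(epochsets_by_band)) {
    es <- epochsets_by_band[[bname]]
    ch <- es$montage$channels
    reg <- es$montage$regions
    pw <- band_power(es)                      # epochs x channels
    for (tid in unique(es$trial_ids)) {
      sel <- es$trial_ids == tid
      bl <- es$baselines[[as.character(tid)]]
      if (is.null(bl)) {
        warning(sprintf("trial %d has no baseline; skipped in band power", tid))
        next
      }
      base_p <- rowMeans(bl^2)                # per channel
      if (any(base_p <= 0)) {
        warning(sprintf("trial %d has zero baseline power; skipped", tid))
        next
      }
      stim_p <- colMeans(pw[sel, , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subject, paradigm = paradigm,
        state = as.character(es$labels[sel][1]), band = bname,
        trial = tid, channel = ch, region = unname(reg[ch]),
        percent_change = percent_change(stim_p, base_p))
    }
  }
  tab <- do.call(rbind, rows)
  # average over trials of the same state
  agg <- stats::aggregate(percent_change ~ subject + paradigm + state +
                            band + channel + region, data = tab, FUN = mean)
  class(agg) <- c("band_power_table", "data.frame")
  agg
}

#' Aggregate a channel-level band-power table to scalp regions
#'
#' The region value is the unweighted mean of its member channels.
#'
#' @param table a `band_power_table` with a `channel` column.
#' @return data.frame with one row per (subject, paradigm, state, band,
#'   region).
#' @export
region_average <- function(table) {
  stats::aggregate(percent_change ~ subject + paradigm + state + band +
                     region, data = table, FUN = mean)
}

#' Repeated-measures ANOVA over within-subject factors
#'
#' Univariate repeated-measures ANOVA of percent band-power change with
#' all supplied factors treated as within-subject (fully crossed, one
#' observation per subject and cell; unbalanced subjects are removed
#' listwise with a message). Each effect is tested against its
#' subject-by-effect interaction stratum, the textbook within-subject
#' error term. No sphericity correction is applied by default, matching
#' common practice when none is reported.
#'
#' @param table region-level table (see [region_average()]) with columns
#'   `subject`, `percent_change` and the factor columns.
#' @param factors character vector of factor column names, e.g.
#'   `c("state", "band", "region")`.
#' @return an `anova_result` data.frame: effect, df1, df2, F, p.
#' @export
rm_anova <- function(table, factors = c("state", "band", "region")) {
  stopifnot(all(c("subject", "percent_change", factors) %in% names(table)))
  df <- table
  df$subject <- factor(df$subject)
  for (f in factors) df[[f]] <- factor(df[[f]])
  single <- factors[vapply(factors, function(f) nlevels(df[[f]]) < 2,
                           logical(1))]
  if (length(single) > 0) {
    message("rm_anova: dropping single-level factor(s): ",
            paste(single, collapse = ", "))
    factors <- setdiff(factors, single)
  }
  if (length(factors) == 0) stop("no factor with 2 or more levels")

  # listwise removal of subjects with incomplete cells
  n_cells <- prod(vapply(factors, function(f) nlevels(df[[f]]), integer(1)))
  cnt <- table(df$subject)
  bad <- names(cnt)[cnt != n_cells]
  if (length(bad) > 0) {
    message("rm_anova: removing incomplete subject(s): ",
            paste(bad, collapse = ", "))
    df <- df[!(df$subject %in% bad), ]
    df$subject <- droplevels(df$subject)
  }
  if (nlevels(df$subject) < 3) {
    stop("rm_anova needs at least 3 complete subjects")
  }

  fixed <- paste(factors, collapse = " * ")
  form <- stats::as.formula(sprintf(
    "percent_change ~ %s + Error(subject/(%s))", fixed, fixed))
  fit <- stats::aov(form, data = df)
  # guard for exactly-null effects: 0/0 mean-square ratios are reported as
  # F = 0, p = 1 instead of floating-point noise
  ss_tol <- 1e-12 * max(sum((df$percent_change -
                               mean(df$percent_change))^2), 1)
  out <- list()
  for (stratum in summary(fit)) {
    st <- stratum[[1]]
    terms <- rownames(st)
    for (i in seq_along(terms)) {
      nm <- trimws(terms[i])
      if (nm == "Residuals") next
      Fv <- st[i, "F value"]
      pv <- min(1, st[i, "Pr(>F)"])
      if (st[i, "Sum Sq"] < ss_tol) {
        Fv <- 0; pv <- 1
      }
      out[[length(out) + 1L]] <- data.frame(
        effect = gsub(":", " x ", nm),
        df1 = st[i, "Df"],
        df2 = st[nrow(st), "Df"],
        F = Fv, p = pv)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("anova_result", "data.frame")
  res
}

#' Cell-wise fear-vs-joy follow-up contrasts
#'
#' Paired t-tests of the two states within every (band, region) cell of a
#' region-level table, with Benjamini-Hochberg adjusted p-values across
#' the grid alongside the raw ones.
#'
#' @param table region-level table with exactly two states.
#' @param states the two state labels to contrast.
#' @return data.frame: band, region, mean_diff, t, df, p, p_bh.
#' @export
state_contrasts <- function(table, states = c("fear", "joy")) {
  stopifnot(all(states %in% table$state), length(states) == 2)
  cells <- unique(table[, c("band", "region")])
  out <- list()
  for (i in seq_len(nrow(cells))) {
    sub <- table[table$band == cells$band[i] & table$region == cells$region[i] &
                   table$state %in% states, ]
    wide <- stats::reshape(sub[, c("subject", "state", "percent_change")],
                           idvar = "subject", timevar = "state",
                           direction = "wide")
    a <- wide[[paste0("percent_change.", states[1])]]
    b <- wide[[paste0("percent_change.", states[2])]]
    tt <- stats::t.test(a, b, paired = TRUE)
    out[[i]] <- data.frame(band = cells$band[i], region = cells$region[i],
                           mean_diff = mean(a - b),
                           t = unname(tt$statistic),
                           df = unname(tt$parameter),
                           p = tt$p.value)
  }
  res <- do.call(rbind, out)
  res$p_bh <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Per-channel value map for topographic (scalp-map) rendering
#'
#' Exports a channel -> value table with the montage's 2-D layout
#' coordinates. For a CSP model the value is a column of the spatial
#' pattern matrix (default: the pattern of the top class-1 filter); for a
#' channel-level band-power table it is the mean percent change per
#' channel, optionally restricted to one state and band.
#'
#' @param x a `csp_model` or a channel-level `band_power_table`.
#' @param montage the montage supplying names and coordinates (required
#'   for CSP models).
#' @param pattern which pattern column to export (CSP models).
#' @param state,band optional filters (band-power tables).
#' @return data.frame: channel, x, y, region, value.
#' @export
topographic_export <- function(x, montage = NULL, pattern = 1,
                               state = NULL, band = NULL) {
  if (inherits(x, "csp_model")) {
    if (is.null(montage)) stop("a montage is required to export a CSP model")
    if (length(montage$channels) != nrow(x$patterns)) {
      stop("montage channel count does not match the CSP model")
    }
    val <- x$patterns[, pattern]
  } else {
    tab <- x
    if (!is.null(state)) tab <- tab[tab$state == state, ]
    if (!is.null(band)) tab <- tab[tab$band == band, ]
    agg <- stats::aggregate(percent_change ~ channel, data = tab, FUN = mean)
    if (is.null(montage)) {
      stop("a montage is required for layout coordinates")
    }
    unknown <- setdiff(agg$channel, montage$channels)
    if (length(unknown) > 0) {
      stop("channel(s) not in montage: ", paste(unknown, collapse = ", "))
    }
    val <- agg$percent_change[match(montage$channels, agg$channel)]
  }
  data.frame(channel = montage$channels,
             x = montage$xy[, "x"], y = montage$xy[, "y"],
             region = unname(montage$regions[montage$channels]),
             value = val, row.names = NULL)
}
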