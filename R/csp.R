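#' Normalized spatial covariance of one epoch
#'
#' For an epoch `X` (channels x time), returns `X X^T / tr(X X^T)`: a
#' symmetric, positive semidefinite matrix with unit trace. Trace
#' normalization makes the estimate invariant to the epoch's overall power,
#' so trials with different amplitudes contribute equally to the class
#' covariance.
#'
#' @param epoch numeric matrix, channels x time samples.
#' @return channels x channels normalized covariance matrix.
#' @export
normalized_covariance <- function(epoch) {
  stopifnot(is.matrix(epoch), all(is.finite(epoch)))
  if (ncol(epoch) <= nrow(epoch)) {
    warning("epoch has no more time samples than channels; covariance is rank deficient")
  }
  S <- tcrossprod(epoch)
  tr <- sum(diag(S))
  if (tr <= 0) stop("zero-signal epoch: covariance trace is 0")
  S / tr
}

# sufficient statistics for a whole epoch set, used by CSP fitting and
# feature extraction without re-touching the raw tensor:
#   Cflat: vectorized normalized covariance per epoch (N^2 x E)
#   M2flat: vectorized second moment X X^T / T per epoch (N^2 x E)
#   M1: per-epoch channel means (N x E)
epoch_moments <- function(epochset) {
  d <- dim(epochset$data)
  N <- d[1]; Tn <- d[2]; E <- d[3]
  M2flat <- matrix(0, N * N, E)
  M1 <- matrix(0, N, E)
  for (e in seq_len(E)) {
    X <- epochset$data[, , e]
    M2flat[, e] <- tcrossprod(X)
    M1[, e] <- rowMeans(X)
  }
  tr <- colSums(M2flat[1L + (seq_len(N) - 1L) * (N + 1L), , drop = FALSE])
  if (any(tr <= 0)) {
    stop("zero-signal epoch(s) at index: ",
         paste(which(tr <= 0), collapse = ", "))
  }
  list(Cflat = sweep(M2flat, 2, tr, "/"), M2flat = M2flat / Tn, M1 = M1,
       N = N, Tn = Tn)
}

# CSP from the two class-mean normalized covariances
fit_csp_cov <- function(C1, C2, m, gamma = 0, band = "broadband") {
  N <- nrow(C1)
  stopifnot(nrow(C2) == N, m >= 1, 2 * m <= N)
  if (gamma > 0) {
    C1 <- (1 - gamma) * C1 + gamma * (sum(diag(C1)) / N) * diag(N)
    C2 <- (1 - gamma) * C2 + gamma * (sum(diag(C2)) / N) * diag(N)
  }
  Cc <- (C1 + C2 + t(C1 + C2)) / 2
  ec <- eigen(Cc, symmetric = TRUE)
  if (min(ec$values) < 1e-10 * max(ec$values)) {
    stop("composite covariance is rank deficient; consider ridge regularization (gamma > 0)")
  }
  P <- diag(1 / sqrt(ec$values)) %*% t(ec$vectors)   # whitening: P Cc P^T = I
  S1 <- P %*% C1 %*% t(P)
  e1 <- eigen((S1 + t(S1)) / 2, symmetric = TRUE)    # descending eigenvalues
  W <- t(e1$vectors) %*% P                           # rows are spatial filters
  # sign convention: largest-magnitude coefficient of each filter positive
  for (j in seq_len(N)) {
    if (W[j, which.max(abs(W[j, ]))] < 0) W[j, ] <- -W[j, ]
  }
  lambda1 <- pmin(pmax(e1$values, 0), 1)
  structure(list(projection = W, patterns = solve(W), eigvals_class1 = lambda1,
                 m = m, selected = c(seq_len(m), (N - m + 1):N),
                 band = band, gamma = gamma),
            class = "csp_model")
}

#' Fit common spatial patterns for two epoch classes
#'
#' Averages the per-epoch normalized spatial covariances of each class and
#' computes the projection `W` (rows = spatial filters) that simultaneously
#' diagonalizes both class covariances: `W C1 W^T = diag(lambda1)` and
#' `W C2 W^T = diag(lambda2)` with `lambda1 + lambda2 = I`. Filters are
#' ordered by `lambda1` descending, so the first filters maximize class-1
#' variance and the last maximize class-2 variance; the first and last `m`
#' are flagged as the selected discriminative filters. Columns of
#' `patterns` (the inverse of `W`) are the corresponding spatial patterns,
#' i.e. the forward mixing each filter undoes.
#'
#' @param class1_epochs,class2_epochs `eeg_epochs` objects (or precomputed
#'   class covariance matrices).
#' @param m filters kept per tail (`2 m <=` channel count). Default 3.
#' @param gamma optional ridge shrinkage of each class covariance toward a
#'   scaled identity (0 = plain CSP).
#' @return a `csp_model`.
#' @export
fit_csp <- function(class1_epochs, class2_epochs, m = 3, gamma = 0) {
  as_cov <- function(x, who) {
    if (is.matrix(x)) return(x)
    stopifnot(inherits(x, "eeg_epochs"))
    if (n_epochs(x) < 2) stop(who, " needs at least 2 epochs")
    mom <- epoch_moments(x)
    matrix(rowMeans(mom$Cflat), mom$N, mom$N)
  }
  band <- if (inherits(class1_epochs, "eeg_epochs")) {
    class1_epochs$band_name %||% class1_epochs$band
  } else {
    "broadband"
  }
  fit_csp_cov(as_cov(class1_epochs, "class 1"),
              as_cov(class2_epochs, "class 2"), m, gamma, band)
}

#' @export
print.csp_model <- function(x, ...) {
  N <- nrow(x$projection)
  cat(sprintf("CSP model: %d channels, m = %d (2m = %d selected filters)\n",
              N, x$m, 2 * x$m))
  cat("lambda1 (class-1 eigenvalues):",
      paste(sprintf("%.3f", x$eigvals_class1), collapse = " "), "\n")
  invisible(x)
}

# log-variance features from precomputed moments (columns = epochs)
csp_features_from_moments <- function(model, mom) {
  Wsel <- model$projection[model$selected, , drop = FALSE]
  N <- mom$N
  # var(w' X) = w' (XX^T/T) w - (w' mean)^2, vectorized over epochs via the
  # flattened quadratic form
  Wq <- t(apply(Wsel, 1, function(w) as.vector(tcrossprod(w))))
  V <- Wq %*% mom$M2flat - (Wsel %*% mom$M1)^2
  V <- pmax(V, 0)
  tot <- colSums(V)
  f <- log(sweep(V, 2, tot, "/"))
  list(features = t(f), valid = tot > 0 & apply(is.finite(f), 2, all))
}

#' Project epochs through selected CSP filters and take log-variance features
#'
#' Each epoch is projected by the `2 m` selected spatial filters; the
#' feature vector is the log of each projected signal's variance divided by
#' the total variance over the selected filters. Features are therefore
#' all non-positive and their exponentials sum to one per epoch.
#'
#' @param model a `csp_model`.
#' @param epochset an `eeg_epochs` with the model's channel count.
#' @return a `csp_features` object: `features` (epochs x 2m matrix),
#'   `labels`, `trial_ids`, and `valid` (epochs with nonzero total
#'   variance; invalid rows are excluded downstream).
#' @export
apply_csp <- function(model, epochset) {
  stopifnot(inherits(model, "csp_model"), inherits(epochset, "eeg_epochs"))
  if (dim(epochset$data)[1] != ncol(model$projection)) {
    stop("epoch channel count does not match the CSP model")
  }
  mom <- epoch_moments(epochset)
  fe <- csp_features_from_moments(model, mom)
  structure(list(features = fe$features, labels = epochset$labels,
                 trial_ids = epochset$trial_ids, valid = fe$valid,
                 band = model$band, m = model$m),
            class = "csp_features")
}
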