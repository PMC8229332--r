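#' Fisher linear discriminant with shared covariance
#'
#' Classic two-class LDA under the equal-covariance Gaussian model: class
#' means are sample means, the covariance is the pooled within-class
#' estimate, and the weight vector is `C^-1 (mu_pos - mu_neg)`. The bias is
#' the midpoint projection `w' (mu_pos + mu_neg) / 2`, so the discriminant
#' score `w' x - b` is positive for the positive class. If the pooled
#' covariance is numerically singular it is shrunk toward a scaled identity
#' just enough to invert, and the shrinkage used is recorded.
#'
#' @param features_pos,features_neg numeric matrices (samples x features)
#'   for the positive and negative class.
#' @return an `lda_model`: `weights`, `bias`, `class_means` (2 x d),
#'   `pooled_cov`, `shrinkage`.
#' @export
fit_lda <- function(features_pos, features_neg) {
  features_pos <- as.matrix(features_pos)
  features_neg <- as.matrix(features_neg)
  stopifnot(nrow(features_pos) >= 2, nrow(features_neg) >= 2,
            ncol(features_pos) == ncol(features_neg))
  mu_p <- colMeans(features_pos)
  mu_n <- colMeans(features_neg)
  n_p <- nrow(features_pos); n_n <- nrow(features_neg)
  Sp <- stats::cov(features_pos); Sn <- stats::cov(features_neg)
  C <- ((n_p - 1) * Sp + (n_n - 1) * Sn) / (n_p + n_n - 2)
  d <- ncol(C)
  shrink <- 0
  repeat {
    Cs <- (1 - shrink) * C + shrink * (sum(diag(C)) / d) * diag(d)
    w <- tryCatch(solve(Cs, mu_p - mu_n), error = function(e) NULL)
    if (!is.null(w) && all(is.finite(w)) &&
        rcond(Cs) > .Machine$double.eps * 100) break
    shrink <- if (shrink == 0) 1e-6 else shrink * 10
    if (shrink > 1) stop("pooled covariance could not be stabilized")
  }
  if (shrink > 0) {
    message(sprintf("fit_lda: singular pooled covariance, shrinkage %g applied",
                    shrink))
  }
  structure(list(weights = w,
                 bias = sum(w * (mu_p + mu_n)) / 2,
                 class_means = rbind(pos = mu_p, neg = mu_n),
                 pooled_cov = C, shrinkage = shrink),
            class = "lda_model")
}

#' Signed discriminant scores of an LDA model
#'
#' Returns `(w' x - b)`, optionally normalized by `||w||` so scores from
#' different binary classifiers are on a comparable signed-distance scale.
#'
#' @param model an `lda_model`.
#' @param features samples x features matrix.
#' @param normalize divide by the weight norm (default TRUE).
#' @export
lda_scores <- function(model, features, normalize = TRUE) {
  s <- as.matrix(features) %*% model$weights - model$bias
  nw <- sqrt(sum(model$weights^2))
  if (normalize && nw > 0) s <- s / nw
  drop(s)
}

#' Fit the one-vs-rest CSP + LDA model stack for three emotional states
#'
#' For each target state a dedicated CSP model is fitted (target epochs vs.
#' all remaining epochs), its log-variance features extracted, and a binary
#' LDA trained with the target as positive class. The three binary
#' classifiers operate in different feature spaces because each has its own
#' spatial filters.
#'
#' @param epochset a labeled `eeg_epochs` set (training data).
#' @param m CSP filters per tail.
#' @param gamma CSP ridge parameter.
#' @return an `ovr_model`: named list of per-state `(csp, lda)` pairs.
#' @export
fit_ovr <- function(epochset, m = 3, gamma = 0) {
  states <- levels(epochset$labels)
  fits <- lapply(states, function(s) {
    pos <- subset_epochs(epochset, epochset$labels == s)
    neg <- subset_epochs(epochset, epochset$labels != s)
    csp <- fit_csp(pos, neg, m = m, gamma = gamma)
    fp <- apply_csp(csp, pos)
    fn <- apply_csp(csp, neg)
    lda <- fit_lda(fp$features[fp$valid, , drop = FALSE],
                   fn$features[fn$valid, , drop = FALSE])
    list(csp = csp, lda = lda)
  })
  names(fits) <- states
  structure(list(fits = fits, states = states, m = m), class = "ovr_model")
}

#' Assign a state to each epoch by the highest one-vs-rest score
#'
#' Scores are signed distances to each binary decision boundary (normalized
#' by the weight norm); ties are broken toward the lowest state index in
#' the fixed order fear < joy < neutral.
#'
#' @param scores epochs x states matrix of discriminant scores (columns in
#'   state order).
#' @param states state names, in tie-break order.
#' @return factor of assigned states.
#' @export
ovr_classify <- function(scores, states = colnames(scores)) {
  scores <- as.matrix(scores)
  idx <- apply(scores, 1, which.max)   # which.max takes the first on ties
  factor(states[idx], levels = states)
}

#' Predict states for new epochs with a fitted one-vs-rest stack
#'
#' @param object an `ovr_model` from [fit_ovr()].
#' @param epochset epochs to classify.
#' @param ... unused.
#' @return list with `labels` (factor of assigned states) and `scores`
#'   (epochs x states matrix).
#' @export
predict.ovr_model <- function(object, epochset, ...) {
  scores <- vapply(object$states, function(s) {
    f <- apply_csp(object$fits[[s]]$csp, epochset)
    lda_scores(object$fits[[s]]$lda, f$features)
  }, numeric(n_epochs(epochset)))
  scores <- matrix(scores, ncol = length(object$states),
                   dimnames = list(NULL, object$states))
  list(labels = ovr_classify(scores), scores = scores)
}
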