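#' Design a Butterworth band-pass filter as second-order sections
#'
#' Builds an order-`n` Butterworth band-pass prototype in zero-pole-gain
#' form (analog low-pass poles, low-pass to band-pass transform, bilinear
#' transform) and returns it as a cascade of biquad sections. The zpk/SOS
#' route keeps narrow low-frequency bands (e.g. delta, 1--3 Hz at 256 Hz)
#' numerically stable where the expanded transfer-function polynomial is
#' not: every pole is guaranteed strictly inside the unit circle.
#'
#' @param band numeric length-2, band edges in Hz (low, high).
#' @param fs sampling frequency in Hz.
#' @param order prototype low-pass order (the band-pass has `2 * order`
#'   poles). Default 5.
#' @return object of class `butter_sos`: list with `sos` (n_sections x 6
#'   matrix, columns b0 b1 b2 a0 a1 a2), `band`, `fs`, `order`.
#' @export
butter_bandpass_sos <- function(band, fs, order = 5) {
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1])
  if (band[2] >= fs / 2) {
    stop(sprintf("band upper edge %g Hz is not below the Nyquist frequency %g Hz",
                 band[2], fs / 2))
  }
  n <- as.integer(order)
  stopifnot(n >= 1)

  # analog Butterworth low-pass prototype poles (unit cutoff, gain 1)
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  if (n %% 2 == 1) p[(n + 1) / 2] <- -1 + 0i  # force the real pole exact

  # pre-warped analog band edges for the bilinear transform
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * band[1] / fs)
  w2 <- fs2 * tan(pi * band[2] / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)

  # low-pass -> band-pass in the s-plane: n poles become 2n, n zeros at s=0
  ph <- p * bw / 2
  pbp <- c(ph + sqrt(ph^2 - w0^2), ph - sqrt(ph^2 - w0^2))
  gain <- bw^n

  # bilinear transform to the z-plane; zeros: n at z=+1 (from s=0),
  # n at z=-1 (pole excess)
  pd <- (fs2 + pbp) / (fs2 - pbp)
  gain_d <- gain * Re(prod(fs2 - 0) ^ n / prod(fs2 - pbp))
  if (any(Mod(pd) >= 1)) {
    stop(sprintf("unstable Butterworth design for band %g-%g Hz at order %d",
                 band[1], band[2], n))
  }

  # pair conjugate poles into biquads; each section carries one zero at +1
  # and one at -1, i.e. numerator (1, 0, -1)
  pos <- pd[Im(pd) > 0]
  real_p <- sort(Re(pd[abs(Im(pd)) < 1e-9]))
  sections <- vector("list", n)
  si <- 1
  for (pp in pos) {
    sections[[si]] <- c(1, 0, -1, 1, -2 * Re(pp), Mod(pp)^2)
    si <- si + 1
  }
  # any residual real poles pair up (can occur for strongly detuned bands)
  while (length(real_p) >= 2) {
    a1 <- -(real_p[1] + real_p[2]); a2 <- real_p[1] * real_p[2]
    sections[[si]] <- c(1, 0, -1, 1, a1, a2)
    real_p <- real_p[-(1:2)]
    si <- si + 1
  }
  sos <- do.call(rbind, sections[seq_len(si - 1)])
  sos[1, 1:3] <- sos[1, 1:3] * gain_d

  structure(list(sos = sos, band = band, fs = fs, order = n),
            class = "butter_sos")
}

#' @export
print.butter_sos <- function(x, ...) {
  cat(sprintf("Butterworth band-pass (SOS): %g-%g Hz, order %d, fs %g Hz, %d sections\n",
              x$band[1], x$band[2], x$order, x$fs, nrow(x$sos)))
  invisible(x)
}

# steady-state DF2T state for a unit-step input (scipy lfilter_zi analogue);
# initializing with zi * x[1] removes start-up transients for near-constant edges
biquad_zi <- function(b, a) {
  z1 <- (b[2] + b[3] - (a[2] + a[3]) * b[1]) / (1 + a[2] + a[3])
  z2 <- b[3] - a[3] * (b[1] + z1)
  c(z1, z2)
}

# one biquad over the columns (time axis) of X, transposed direct-form II,
# vectorized across rows; x0 scales the steady-state initial condition
biquad_filter_mat <- function(b, a, X, x0 = NULL) {
  nt <- ncol(X)
  Y <- matrix(0, nrow(X), nt)
  if (is.null(x0)) {
    z1 <- z2 <- numeric(nrow(X))
  } else {
    zi <- biquad_zi(b, a)
    z1 <- zi[1] * x0; z2 <- zi[2] * x0
  }
  for (t in seq_len(nt)) {
    xt <- X[, t]
    yt <- b[1] * xt + z1
    z1 <- b[2] * xt - a[2] * yt + z2
    z2 <- b[3] * xt - a[3] * yt
    Y[, t] <- yt
  }
  Y
}

sos_filter_mat <- function(filt, X, steady_init = FALSE) {
  for (s in seq_len(nrow(filt$sos))) {
    sec <- filt$sos[s, ]
    x0 <- if (steady_init) X[, 1] else NULL
    X <- biquad_filter_mat(sec[1:3], sec[4:6], X, x0 = x0)
  }
  X
}

#' Zero-phase (forward-backward) filtering of one or many signals
#'
#' Applies a second-order-section filter forward and backward over the time
#' axis, giving zero phase distortion and squared magnitude response. Edge
#' transients are reduced with odd-reflection padding at both ends.
#'
#' @param filt a `butter_sos` filter.
#' @param x numeric vector, or matrix with one signal per row (time along
#'   columns).
#' @return filtered data, same shape as `x`.
#' @export
sos_filtfilt <- function(filt, x) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, nrow = 1) else x
  nt <- ncol(X)
  npad <- min(nt - 1L, 9L * nrow(filt$sos) + 3L)
  if (npad > 0) {
    left  <- 2 * X[, 1] - X[, (npad + 1):2, drop = FALSE]
    right <- 2 * X[, nt] - X[, (nt - 1):(nt - npad), drop = FALSE]
    X <- cbind(left, X, right)
  }
  Y <- sos_filter_mat(filt, X, steady_init = TRUE)
  Y <- sos_filter_mat(filt, Y[, ncol(Y):1, drop = FALSE], steady_init = TRUE)
  Y <- Y[, ncol(Y):1, drop = FALSE]
  if (npad > 0) Y <- Y[, (npad + 1):(npad + nt), drop = FALSE]
  if (vec) drop(Y) else Y
}
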