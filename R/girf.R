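## Linear time-invariant model of the gradient chain: per-axis impulse
## response kernels, their application to waveforms, the predicted
## excitation k-space, and frequency-domain estimation from input/output
## waveform pairs.

#' Construct a gradient impulse response
#'
#' @param h numeric matrix (n x 3) of per-axis causal kernel samples, or a
#'   vector reused for all axes. The kernel is in units of 1/s times `dt`
#'   (i.e. a discrete convolution kernel: an identity response is a single
#'   1 followed by zeros).
#' @param dt kernel raster, s.
#' @return An object of class `impulse_response`.
#' @export
impulse_response <- function(h, dt) {
  if (is.vector(h)) h <- matrix(h, length(h), 3)
  if (any(!is.finite(h))) stop2("kernel must be finite")
  structure(list(h = h, dt = dt), class = "impulse_response")
}

#' Identity gradient impulse response
#'
#' @param dt raster, s.
#' @return An `impulse_response` whose convolution leaves waveforms
#'   unchanged.
#' @export
girf_identity <- function(dt = 6.4e-6) impulse_response(c(1, 0), dt)

#' Synthetic delay + low-pass gradient impulse response
#'
#' A qualitative stand-in for a measured gradient-chain response: a pure
#' delay cascaded with a single-pole low-pass filter, optionally slightly
#' different per axis. Useful as a test fixture and for demonstrations;
#' it is synthetic and does not describe any physical scanner.
#'
#' @param dt raster, s.
#' @param delay_us group delay in microseconds (length 1 or 3).
#' @param bandwidth_khz -3 dB bandwidth of the low-pass pole, kHz (length 1
#'   or 3).
#' @param length_s kernel length, s.
#' @return An `impulse_response`.
#' @export
girf_synthetic <- function(dt = 6.4e-6, delay_us = c(12, 12, 16),
                           bandwidth_khz = c(22, 22, 15), length_s = 5e-4) {
  delay_us <- rep_len(delay_us, 3L)
  bandwidth_khz <- rep_len(bandwidth_khz, 3L)
  n <- max(8L, ceiling(length_s / dt))
  tt <- (seq_len(n) - 1) * dt
  h <- sapply(1:3, function(a) {
    tau <- 1 / (2 * pi * bandwidth_khz[a] * 1e3)
    td <- delay_us[a] * 1e-6
    k <- ifelse(tt >= td, exp(-(tt - td) / tau), 0)
    k / sum(k)
  })
  impulse_response(h, dt)
}

#' @export
print.impulse_response <- function(x, ...) {
  cat(sprintf("<impulse_response> %d taps @ %.1f us (%.2f ms support)\n",
              nrow(x$h), x$dt * 1e6, nrow(x$h) * x$dt * 1e3))
  invisible(x)
}

## Resample a kernel to a new raster preserving its continuous-time action.
resample_kernel <- function(H, dt_new) {
  if (abs(H$dt - dt_new) < 1e-15) return(H)
  n_old <- nrow(H$h)
  t_old <- (seq_len(n_old) - 1) * H$dt
  t_new <- seq(0, t_old[n_old], by = dt_new)
  h2 <- sapply(1:3, function(a)
    stats::approx(t_old, H$h[, a], xout = t_new, rule = 2)$y)
  h2 <- h2 * dt_new / H$dt # keep DC gain
  impulse_response(h2, dt_new)
}

#' Apply a gradient impulse response to a waveform
#'
#' Per-axis causal linear convolution with zero padding; the output is
#' truncated to the duration of the input (the decaying convolution tail
#' beyond the end of the waveform is discarded).
#'
#' @param G a `gradient_set`.
#' @param H an `impulse_response` (resampled internally if its raster
#'   differs).
#' @return A `gradient_set` with the filtered waveform.
#' @export
apply_girf <- function(G, H) {
  H <- resample_kernel(H, G$dt)
  n <- nrow(G$G)
  nh <- nrow(H$h)
  Gf <- sapply(1:3, function(a) {
    full <- stats::convolve(c(G$G[, a], rep(0, nh)), rev(H$h[, a]),
                            type = "open")
    full[seq_len(n)]
  })
  out <- G
  out$G <- Gf
  out$k <- NULL
  out
}

#' Predicted excitation k-space under a gradient impulse response
#'
#' Computes \eqn{k_H(t) = -\gamma \int_t^T (H * G)(\tau) d\tau}: the
#' excitation k-space the filtered gradients actually realize. With an
#' identity response this is the nominal trajectory; at the end of the
#' pulse it is always exactly zero.
#'
#' @param G a `gradient_set`.
#' @param H an `impulse_response`; default identity.
#' @return Matrix (n x 3) of predicted k-space samples, rad/m.
#' @export
predicted_kspace <- function(G, H = girf_identity(G$dt)) {
  kspace_of(apply_girf(G, H))
}

#' Estimate a gradient impulse response from waveform pairs
#'
#' Frequency-domain least-squares estimate per axis with Tikhonov
#' regularization toward the identity response: with input spectra
#' \eqn{I_k(f)} and measured-output spectra \eqn{M_k(f)},
#' \deqn{\hat H(f) = \frac{\sum_k \bar I_k M_k + \lambda}{\sum_k |I_k|^2 + \lambda}.}
#' Frequency bins with (almost) no input energy are therefore returned as
#' identity and flagged. The frequency resolution is the reciprocal of the
#' (common, zero-padded) waveform duration.
#'
#' @param inputs list of `gradient_set` inputs (spectrally rich, e.g.
#'   chirps).
#' @param measured list of `gradient_set` outputs, same rasters/lengths.
#' @param regularization Tikhonov weight relative to the peak input power
#'   (default 1e-6).
#' @param kernel_length_s length of the returned time-domain kernel, s.
#' @return An `impulse_response` with attributes `freq` (Hz), `H_freq`
#'   (complex matrix, per axis) and `empty_bins` (logical matrix).
#' @export
estimate_girf <- function(inputs, measured, regularization = 1e-6,
                          kernel_length_s = 5e-4) {
  if (length(inputs) != length(measured) || length(inputs) < 1)
    stop2("need matching non-empty input/measured lists")
  dt <- inputs[[1]]$dt
  nmax <- max(vapply(c(inputs, measured), function(g) nrow(g$G), 1L))
  nfft <- stats::nextn(2L * nmax, 2)
  num <- matrix(0+0i, nfft, 3)
  den <- matrix(0, nfft, 3)
  for (k in seq_along(inputs)) {
    for (a in 1:3) {
      I <- stats::fft(c(inputs[[k]]$G[, a], rep(0, nfft - nrow(inputs[[k]]$G))))
      M <- stats::fft(c(measured[[k]]$G[, a], rep(0, nfft - nrow(measured[[k]]$G))))
      num[, a] <- num[, a] + Conj(I) * M
      den[, a] <- den[, a] + Mod(I)^2
    }
  }
  lam <- regularization * apply(den, 2, max)
  Hf <- sapply(1:3, function(a) (num[, a] + lam[a]) / (den[, a] + lam[a]))
  empty <- sapply(1:3, function(a) den[, a] < 1e3 * lam[a])
  h <- Re(sapply(1:3, function(a) stats::fft(Hf[, a], inverse = TRUE))) / nfft
  nk <- min(nfft, max(8L, ceiling(kernel_length_s / dt)))
  H <- impulse_response(h[seq_len(nk), , drop = FALSE], dt)
  attr(H, "freq") <- (seq_len(nfft) - 1) / (nfft * dt)
  attr(H, "H_freq") <- Hf
  attr(H, "empty_bins") <- empty
  ## independent information is limited by the (non-quiet) test waveform
  ## duration, not by zero padding
  nsup <- max(vapply(inputs, function(g) {
    nz <- which(rowSums(abs(g$G)) > 0)
    if (length(nz)) max(nz) else nrow(g$G)
  }, 1L))
  attr(H, "freq_resolution_hz") <- 1 / (nsup * dt)
  H
}

#' Read / write an impulse response as CSV
#'
#' Plain-text interchange format: columns `t` (s), `hx`, `hy`, `hz`. A
#' synthetic fixture response (delay plus mild low-pass, see
#' [girf_synthetic()]) ships with the package as
#' `extdata/synthetic_girf.csv`.
#'
#' @param file path to a CSV file.
#' @return An `impulse_response`.
#' @examples
#' H <- read_girf_csv(system.file("extdata", "synthetic_girf.csv",
#'                                package = "cpmgpulse"))
#' @export
read_girf_csv <- function(file) {
  df <- utils::read.csv(file, comment.char = "#")
  for (col in c("t", "hx", "hy", "hz"))
    if (is.null(df[[col]])) stop2("impulse-response CSV is missing column: ",
                                  col)
  impulse_response(as.matrix(df[, c("hx", "hy", "hz")]), df$t[2] - df$t[1])
}

#' @param H an `impulse_response`.
#' @rdname read_girf_csv
#' @export
write_girf_csv <- function(H, file) {
  df <- data.frame(t = (seq_len(nrow(H$h)) - 1) * H$dt,
                   hx = H$h[, 1], hy = H$h[, 2], hz = H$h[, 3])
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Chirped test gradient waveform
#'
#' Linear frequency sweep used to probe the gradient chain over a band of
#' interest when estimating impulse responses.
#'
#' @param duration_s waveform duration, s.
#' @param f0,f1 start and end frequency of the sweep, Hz.
#' @param amplitude_mt amplitude, mT/m.
#' @param dt raster, s.
#' @param axis axis (1-3) carrying the chirp; the others are zero.
#' @return A `gradient_set`.
#' @export
chirp_waveform <- function(duration_s = 6e-3, f0 = 100, f1 = 2e4,
                           amplitude_mt = 10, dt = 6.4e-6, axis = 1) {
  tt <- seq(0, duration_s, by = dt)
  phase <- 2 * pi * (f0 * tt + (f1 - f0) * tt^2 / (2 * duration_s))
  g <- amplitude_mt * 1e-3 * sin(phase)
  G <- matrix(0, length(tt), 3)
  G[, axis] <- g
  structure(list(G = G, dt = dt, duration = duration_s),
            class = "gradient_set")
}
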