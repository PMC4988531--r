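test_that("identity and delay kernels behave as convolution dictates", {
  dtt <- 1e-5
  gs <- chirp_waveform(3e-3, 100, 5e3, 10, dtt, axis = 1)
  ## identity kernel: output equals input exactly
  out <- apply_girf(gs, girf_identity(dtt))
  expect_equal(out$G, gs$G, tolerance = 1e-12)
  ## pure delay: output is the input shifted by tau
  lag <- 7L
  h <- rep(0, 16); h[lag + 1] <- 1
  out2 <- apply_girf(gs, impulse_response(h, dtt))
  n <- nrow(gs$G)
  expect_equal(out2$G[(lag + 1):n, 1], gs$G[1:(n - lag), 1],
               tolerance = 1e-10)
})

test_that("low-pass kernel attenuates a sinusoid by |H(f)|", {
  dtt <- 1e-5
  f0 <- 3000
  n <- 2000
  tt <- (seq_len(n) - 1) * dtt
  gs <- flat_gradient(n, dtt)
  gs$G[, 2] <- 0.01 * sin(2 * pi * f0 * tt)
  H <- girf_synthetic(dtt, delay_us = 0, bandwidth_khz = 3, length_s = 2e-3)
  out <- apply_girf(gs, H)
  ## frequency-domain oracle: gain of the kernel at f0
  hf <- sum(H$h[, 2] * exp(-2i * pi * f0 * (seq_len(nrow(H$h)) - 1) * dtt))
  mid <- 500:1500 # avoid transients
  gain <- max(abs(out$G[mid, 2])) / 0.01
  expect_equal(gain, Mod(hf), tolerance = 0.02)
})

test_that("predicted k-space obeys the backward-integral convention", {
  dtt <- 1e-5
  n <- 400
  G0 <- 0.005
  gs <- flat_gradient(n, dtt, gx = G0)
  kH <- predicted_kspace(gs) # identity response
  ## k(T) = 0 always
  expect_equal(kH[n, ], c(0, 0, 0), tolerance = 1e-9)
  ## constant G: k(t) = -gamma G0 (T - t), a linear ramp
  tt <- (seq_len(n) - 1) * dtt
  Tend <- tt[n]
  expect_equal(kH[, 1], -gyromagnetic_ratio() * G0 * (Tend - tt),
               tolerance = 1e-6)
  ## identity response on a shells waveform recovers the nominal trajectory
  gs2 <- time_optimal_gradients(shells_3d(3, 150, 1.75, 3.21, 30, 220),
                                40, 200, 6.4e-6)
  expect_lt(max(abs(predicted_kspace(gs2) - kspace_of(gs2))), 1e-6)
})

test_that("predicted k-space is linear in the gradient waveform", {
  dtt <- 1e-5
  g1 <- chirp_waveform(2e-3, 100, 3e3, 8, dtt, axis = 1)
  g2 <- chirp_waveform(2e-3, 50, 7e3, 5, dtt, axis = 1)
  H <- girf_synthetic(dtt)
  gsum <- g1; gsum$G <- 2 * g1$G + 3 * g2$G
  expect_equal(predicted_kspace(gsum, H),
               2 * predicted_kspace(g1, H) + 3 * predicted_kspace(g2, H),
               tolerance = 1e-8)
})

test_that("impulse-response estimation recovers the truth from chirps", {
  dtt <- 2e-5
  ## chirps with a trailing quiet period so the filtered response decays
  ## fully inside the recorded window
  mk_chirp <- function(ax) {
    g <- chirp_waveform(6e-3, 50, 2e4, 10, dtt, axis = ax)
    g$G <- rbind(g$G, matrix(0, 100, 3))
    g$duration <- nrow(g$G) * dtt
    g
  }
  chirps <- lapply(1:3, mk_chirp)
  ## self-consistency: measured == inputs -> identity response
  Hid <- estimate_girf(chirps, chirps)
  g <- chirp_waveform(4e-3, 100, 1e4, 8, dtt, axis = 2)
  expect_equal(apply_girf(g, Hid)$G, g$G, tolerance = 1e-6)
  ## frequency resolution is set by the waveform duration (6 ms -> ~167 Hz)
  expect_equal(attr(Hid, "freq_resolution_hz"), 1 / 6e-3, tolerance = 0.05)

  ## parameter recovery: synthetic truth applied to noiseless chirps
  H0 <- girf_synthetic(dtt, delay_us = 40, bandwidth_khz = 4, length_s = 1e-3)
  measured <- lapply(chirps, apply_girf, H = H0)
  Hest <- estimate_girf(chirps, measured, regularization = 1e-10)
  freq <- attr(Hest, "freq")
  Hf_est <- attr(Hest, "H_freq")
  nfft <- length(freq)
  Hf_true <- sapply(1:3, function(a)
    fft(c(H0$h[, a], rep(0, nfft - nrow(H0$h)))))
  band <- freq > 200 & freq < 1.5e4 # inside the excited band
  relerr <- max(Mod(Hf_est[band, ] - Hf_true[band, ]) / Mod(Hf_true[band, ]))
  expect_lt(relerr, 0.01)
})

test_that("a GIRF-filtered shells waveform still ends at the k-space origin", {
  gs <- time_optimal_gradients(shells_3d(2, 100, 1.75, 3.21, 30, 220),
                               40, 200, 6.4e-6)
  kH <- predicted_kspace(gs, girf_synthetic(gs$dt))
  expect_equal(kH[nrow(kH), ], c(0, 0, 0), tolerance = 1e-9)
})

test_that("the packaged synthetic impulse response loads from CSV", {
  f <- system.file("extdata", "synthetic_girf.csv", package = "cpmgpulse")
  H <- read_girf_csv(f)
  expect_s3_class(H, "impulse_response")
  expect_equal(H$dt, 6.4e-6, tolerance = 1e-9)
  ## unit DC gain per axis and a causal decaying shape
  expect_equal(colSums(H$h), c(1, 1, 1), tolerance = 1e-6,
               ignore_attr = TRUE)
  rt <- tempfile(fileext = ".csv")
  write_girf_csv(H, rt)
  expect_equal(read_girf_csv(rt)$h, H$h, tolerance = 1e-12,
               ignore_attr = TRUE)
})
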