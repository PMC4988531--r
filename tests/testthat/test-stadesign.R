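test_that("hard-pulse limit: constant RF at k = 0 gives gamma b dt N_t", {
  maps <- tiny_uniform_maps(8)
  nt <- 50; dtt <- 1e-5
  A <- build_system_matrix(maps, matrix(0, nt, 3), dtt)
  b0 <- 1e-6 # tesla
  m <- A$A %*% rep(b0, nt)
  expect_equal(Mod(m[, 1]), rep(gyromagnetic_ratio() * b0 * dtt * nt,
                                nrow(A$A)), tolerance = 1e-10)
  ## dimension contract for multi-channel maps
  m8 <- make_phantom_maps(c(10, 10, 1), 220, 8, seed = 1)
  A8 <- build_system_matrix(m8, matrix(0, 20, 3), dtt)
  expect_equal(dim(A8$A), c(sum(m8$mask), 8L * 20L))
})

test_that("off-resonance phase is referenced to the end of the pulse", {
  maps <- tiny_uniform_maps(8)
  maps$dw[] <- 2 * pi * 100 # rad/s everywhere
  nt <- 40; dtt <- 1e-4
  A <- build_system_matrix(maps, matrix(0, nt, 3), dtt)
  ## single nonzero sample j: contribution phase advanced by dw (t_j - T)
  for (j in c(1L, 25L)) {
    b <- rep(0, nt); b[j] <- 1e-6
    m <- (A$A %*% b)[1, 1]
    tj <- (j - 0.5) * dtt; Tend <- nt * dtt
    expected_phase <- pi / 2 + 2 * pi * 100 * (tj - Tend) # i factor + dw term
    expect_equal(Arg(m), ((expected_phase + pi) %% (2 * pi)) - pi,
                 tolerance = 1e-9)
  }
})

test_that("iterative solve matches the dense normal-equations oracle", {
  ## random tiny instance: 6 voxels, 1 channel, 4 time samples
  set.seed(42)
  n_vox <- 6; nt <- 4
  A_raw <- matrix(complex(real = rnorm(n_vox * nt),
                          imaginary = rnorm(n_vox * nt)), n_vox, nt)
  m <- complex(real = rnorm(n_vox), imaginary = rnorm(n_vox))
  Aobj <- structure(list(A = A_raw, voxels = seq_len(n_vox), n_channels = 1L,
                         n_t = nt, dt = 1e-5, grid_shape = c(n_vox, 1L, 1L)),
                    class = "system_matrix")
  for (w_r in c(0, 0.25, 1)) {
    for (lam in c(0, 0.3)) {
      sol <- solve_phase_relaxed(Aobj, m, w_r = w_r, lambda = lam,
                                 tol = 1e-12, max_iter = 300)
      oracle <- dense_pr_solve(A_raw, m, w_r,
                               lam * lambda_scale(A_raw, w_r))
      expect_lt(max(Mod(sol$b - oracle)) / max(Mod(oracle)), 1e-8)
    }
  }
})

test_that("larger oracle instances agree to 1e-6 relative error", {
  set.seed(7)
  n_vox <- 40; nt <- 12; nc <- 2
  A_raw <- matrix(complex(real = rnorm(n_vox * nt * nc),
                          imaginary = rnorm(n_vox * nt * nc)), n_vox, nt * nc)
  m <- complex(real = rnorm(n_vox), imaginary = rnorm(n_vox))
  Aobj <- structure(list(A = A_raw, voxels = seq_len(n_vox), n_channels = nc,
                         n_t = nt, dt = 1e-5, grid_shape = c(n_vox, 1L, 1L)),
                    class = "system_matrix")
  sol <- solve_phase_relaxed(Aobj, m, w_r = 0.4, lambda = 0.05,
                             tol = 1e-10, max_iter = 500)
  oracle <- dense_pr_solve(A_raw, m, 0.4, 0.05 * lambda_scale(A_raw, 0.4))
  expect_lt(sqrt(mean(Mod(sol$b - oracle)^2)) / sqrt(mean(Mod(oracle)^2)),
            1e-6)
})

test_that("w_r = 1 reproduces the standard complex least-squares design", {
  set.seed(3)
  n_vox <- 12; nt <- 6
  A_raw <- matrix(complex(real = rnorm(n_vox * nt),
                          imaginary = rnorm(n_vox * nt)), n_vox, nt)
  m <- complex(real = rnorm(n_vox), imaginary = rnorm(n_vox))
  Aobj <- structure(list(A = A_raw, voxels = seq_len(n_vox), n_channels = 1L,
                         n_t = nt, dt = 1e-5, grid_shape = c(n_vox, 1L, 1L)),
                    class = "system_matrix")
  lam_abs <- 0.1 * lambda_scale(A_raw, 1)
  sol <- solve_phase_relaxed(Aobj, m, w_r = 1, lambda = 0.1, tol = 1e-12,
                             max_iter = 400)
  ## ordinary complex Tikhonov solution
  ref <- solve(Conj(t(A_raw)) %*% A_raw + lam_abs * diag(nt),
               Conj(t(A_raw)) %*% m)
  expect_lt(max(Mod(sol$b - as.vector(ref))), 1e-7 * max(Mod(ref)))
})

test_that("strong regularization drives the pulse to zero", {
  set.seed(5)
  maps <- tiny_uniform_maps(10)
  A <- build_system_matrix(maps, matrix(rnorm(30), 10, 3) * 50, 1e-5)
  tgt <- make_target(maps, "cube", size_mm = 50, apodization_fwhm_mm = 10,
                     flip_deg = 30)
  m <- Mod(as.vector(tgt$m)[A$voxels])
  sol <- solve_phase_relaxed(A, tgt, w_r = 1, lambda = 1e6)
  expect_lt(max(Mod(sol$b)), 1e-8)
  expect_equal(sol$rms_im_err, sqrt(mean(m^2)), tolerance = 1e-4)
})

test_that("l-curve is monotone in the non-CPMG weight at fixed lambda", {
  set.seed(11)
  n_vox <- 20; nt <- 8
  A_raw <- matrix(complex(real = rnorm(n_vox * nt),
                          imaginary = rnorm(n_vox * nt)), n_vox, nt)
  m <- 1i * abs(rnorm(n_vox)) # pure-imaginary target, as in CPMG designs
  Aobj <- structure(list(A = A_raw, voxels = seq_len(n_vox), n_channels = 1L,
                         n_t = nt, dt = 1e-5, grid_shape = c(n_vox, 1L, 1L)),
                    class = "system_matrix")
  wr_list <- c(1, 0.5, 0.25, 0.1, 0)
  tab <- lcurve_study(Aobj, m, wr_list, lambda_list = 0.05, tol = 1e-12,
                      max_iter = 500)
  ## decreasing w_r: CPMG error non-increasing, non-CPMG error non-decreasing
  expect_true(all(diff(tab$rms_im_err) <= 1e-10))
  expect_true(all(diff(tab$rms_re_err) >= -1e-10))
})

test_that("the unregularized solution is linear in the target", {
  set.seed(13)
  nt <- 10 # overdetermined full-rank tiny instance
  A_raw <- matrix(complex(real = rnorm(60), imaginary = rnorm(60)), 6, 10)
  A_raw <- A_raw[, 1:4]
  m <- complex(real = rnorm(6), imaginary = rnorm(6))
  Aobj <- structure(list(A = A_raw, voxels = 1:6, n_channels = 1L,
                         n_t = 4L, dt = 1e-5, grid_shape = c(6L, 1L, 1L)),
                    class = "system_matrix")
  s1 <- solve_phase_relaxed(Aobj, m, w_r = 0.3, lambda = 0, tol = 1e-12,
                            max_iter = 300)
  s2 <- solve_phase_relaxed(Aobj, 2.5 * m, w_r = 0.3, lambda = 0,
                            tol = 1e-12, max_iter = 300)
  expect_equal(s2$b, 2.5 * s1$b, tolerance = 1e-7)
})

test_that("small-tip designs agree with the Bloch simulation at 5 degrees", {
  maps <- make_phantom_maps(c(20, 20, 1), fov = 200, n_channels = 2,
                            b0_amplitude = 30, seed = 3)
  gs <- time_optimal_gradients(spiral_2d(200, 12, 2), 40, 200, 6.4e-6)
  tgt <- make_target(maps, "cube", size_mm = 70, apodization_fwhm_mm = 12,
                     flip_deg = 5)
  A <- build_system_matrix(maps, rf_sample_kspace(gs), gs$dt)
  sol <- solve_phase_relaxed(A, tgt, w_r = 1, lambda = 0.003,
                             max_iter = 600)
  pulse <- rf_pulse_set(matrix(sol$b * 1e6, A$n_t, A$n_channels), A$dt)
  fl <- equivalent_flip(bloch_simulate(pulse, gs, maps))
  rel <- sqrt(mean(Mod(fl$alpha - sol$predicted)^2)) /
    sqrt(mean(Mod(sol$predicted)^2))
  expect_lt(rel, 0.02)
})

test_that("the design loop exits early when the peak limit is satisfied", {
  maps <- make_phantom_maps(c(20, 20, 1), fov = 200, n_channels = 1,
                            uniform = TRUE)
  kc <- spiral_2d(200, 14, 2)
  des <- design_pulse(maps, kc,
                      target = list(shape = "cube", size_mm = 60,
                                    apodization_fwhm_mm = 14, flip_deg = 5),
                      w_r = 1, lambda = 0.05,
                      limits = list(peak_ut = 1e5, attenuation_ut = 8e4),
                      dt = 6.4e-6, design_res_mm = 10, time_decimation = 1L,
                      max_iter = 5L)
  expect_length(des$iterations, 1L)
  expect_true(des$compliant)
})

test_that("the re-VERSE loop reduces peak amplitude towards the limit", {
  maps <- make_phantom_maps(c(20, 20, 1), fov = 200, n_channels = 1,
                            uniform = TRUE)
  kc <- spiral_2d(200, 14, 2)
  ref <- design_pulse(maps, kc,
                      target = list(shape = "cube", size_mm = 60,
                                    apodization_fwhm_mm = 14, flip_deg = 90),
                      w_r = 1, lambda = 0.05,
                      limits = list(peak_ut = 1e9, attenuation_ut = 1e9),
                      dt = 6.4e-6, design_res_mm = 10, time_decimation = 1L,
                      max_iter = 1L)
  lim <- ref$pulse$peak * 0.7
  des <- suppressWarnings(design_pulse(
    maps, kc,
    target = list(shape = "cube", size_mm = 60,
                  apodization_fwhm_mm = 14, flip_deg = 90),
    w_r = 1, lambda = 0.05,
    limits = list(peak_ut = lim, attenuation_ut = 0.75 * lim),
    dt = 6.4e-6, design_res_mm = 10, time_decimation = 1L, max_iter = 5L))
  expect_gt(length(des$iterations), 1L)
  expect_lt(des$pulse$peak, ref$pulse$peak)
  peaks <- vapply(des$iterations, `[[`, 0, "peak_ut")
  expect_lt(min(peaks), peaks[1])
})
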