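test_that("textbook rotations and the equivalent flip angle agree", {
  maps <- tiny_uniform_maps(8)
  nt <- 200; dtt <- 1e-5
  g0 <- flat_gradient(nt, dtt)
  ## on-resonance hard pulse along +x with area pi/2 tips M onto +y
  b90 <- (pi / 2) / (gyromagnetic_ratio() * dtt * nt) * 1e6
  p <- rf_pulse_set(matrix(complex(real = b90), nt, 1), dtt)
  mg <- bloch_simulate(p, g0, maps)
  expect_equal(mg$M[1, ], c(Mx = 0, My = 1, Mz = 0), tolerance = 1e-9)
  fl <- equivalent_flip(mg)
  expect_equal(fl$alpha[1], 1i * pi / 2, tolerance = 1e-9)
  ## zero RF leaves magnetization untouched
  p0 <- rf_pulse_set(matrix(0+0i, nt, 1), dtt)
  mg0 <- bloch_simulate(p0, g0, maps)
  expect_true(all(mg0$M[, 3] == 1))
  expect_equal(equivalent_flip(mg0)$alpha, rep(0+0i, nrow(mg0$M)))
})

test_that("equivalent flip angle closed forms hold", {
  ## untouched magnetization
  expect_equal(equivalent_flip(matrix(c(0, 0, 1), 1))$alpha, 0+0i)
  ## pure CPMG 90 degrees
  expect_equal(equivalent_flip(matrix(c(0, 1, 0), 1))$alpha, 1i * pi / 2,
               tolerance = 1e-12)
  ## 10-degree non-CPMG tip
  M <- matrix(c(sin(pi / 18), 0, cos(pi / 18)), 1)
  expect_equal(equivalent_flip(M)$alpha, complex(real = pi / 18),
               tolerance = 1e-12)
  ## round trip through an ideal rotation about an arbitrary transverse axis
  for (phi in c(0, 0.7, 2.1)) {
    for (amp in c(0.2, 1.2)) {
      M <- c(sin(amp) * cos(phi), sin(amp) * sin(phi), cos(amp))
      a <- equivalent_flip(matrix(M, 1))$alpha
      expect_equal(a, amp * exp(1i * phi), tolerance = 1e-10)
    }
  }
  ## clamped |Mz| > M0 warns
  expect_warning(equivalent_flip(matrix(c(0, 0, 1 + 1e-6), 1)), "clamp")
})

test_that("one-ahead pseudo-steady-state sweeps match the product sequence", {
  sw <- pss_sweep(35, n_echoes = 100)
  expect_equal(sw$theta_deg[1], 139, tolerance = 1)
  expect_equal(sw$theta_deg[2:4], c(74, 50, 41), tolerance = 1.5)
  expect_equal(tail(sw$theta_deg, 50), rep(35, 50))
  ## convergence is monotone after the first pulse
  dev <- abs(sw$theta_deg - 35)
  expect_true(all(diff(dev) <= 1e-9))
  ## perfect refocusing is a fixed point
  sw180 <- pss_sweep(180, n_echoes = 10)
  expect_equal(sw180$theta_deg, rep(180, 10))
  ## sweeps converge to the requested asymptote in general
  for (a in c(70, 120)) {
    swa <- pss_sweep(a, n_echoes = 30)
    expect_equal(tail(swa$theta_deg, 5), rep(a, 5), tolerance = 1e-6)
    dev <- abs(swa$theta_deg - a)
    expect_true(all(diff(dev) <= 1e-9))
  }
  expect_error(pss_sweep(0), "asymptotic_angle")
})

test_that("ideal 180-degree CPMG trains refocus both excitation phases", {
  ec <- epg_fse(1i * pi / 2, rep(180, 20))
  expect_equal(Mod(ec$e), rep(1, 20), tolerance = 1e-12)
  en <- epg_fse(pi / 2 + 0i, rep(180, 20))
  expect_equal(Mod(en$e), rep(1, 20), tolerance = 1e-12)
  ## so the suppression factor is exactly 1 without relaxation
  expect_equal(as.numeric(xi_factor(epg_fse(1i * pi / 2, rep(180, 60)),
                                    epg_fse(pi / 2 + 0i, rep(180, 60)),
                                    window = 40:49)), 1)
})

test_that("EPG equals the isochromat-ensemble Bloch oracle", {
  sw <- pss_sweep(35, n_echoes = 40)$theta_deg
  cases <- list(
    list(exc = 1i * pi / 2, T1 = 3651, T2 = 1429, th = sw),     # CPMG, CSF
    list(exc = pi / 2 + 0i, T1 = 3651, T2 = 1429, th = sw),     # non-CPMG
    list(exc = 1i * pi / 2, T1 = 1543, T2 = 122, th = sw),      # GM
    list(exc = exp(1i * 0.8) * pi / 3, T1 = 907, T2 = 92,
         th = rep(120, 40)),                                    # oblique
    list(exc = 1i * pi / 2, T1 = Inf, T2 = Inf, th = rep(35, 40)))
  for (cs in cases) {
    epg <- epg_fse(cs$exc, cs$th, cs$T1, cs$T2, esp = 4)
    iso <- iso_fse(cs$exc, cs$th, cs$T1, cs$T2, esp = 4, n_iso = 512)
    expect_lt(max(abs(Mod(epg$e) - Mod(iso))), 1e-4)
  }
})

test_that("suppression factors reproduce the worked example", {
  sf <- suppression_factors(1i * pi / 2, deg2rad_c(10), xi = 17)
  expect_equal(round(sf$sigma_noncpmg), 98)
  ## equal CPMG flips give no suppression
  sf2 <- suppression_factors(1i * pi / 2, 1i * pi / 2, xi = 1)
  expect_equal(sf2$sigma_cpmg, 1)
  ## xi = 1 reduces to the plain sine ratio
  sf3 <- suppression_factors(1i * pi / 2, deg2rad_c(10), xi = 1)
  expect_equal(sf3$sigma_noncpmg, 1 / sin(pi / 18))
  ## zero outer-volume flip reports infinity
  expect_equal(suppression_factors(1i * pi / 2, 0+0i, 2)$sigma_noncpmg, Inf)
})

test_that("xi handles identity, flooring and short trains", {
  a <- epg_fse(1i * pi / 2, rep(90, 60), 1000, 100)
  expect_equal(as.numeric(xi_factor(a, a, window = 40:49)), 1)
  expect_error(xi_factor(a, a, window = 60:70), "window")
})

test_that("EPG state energy never exceeds M0^2 without relaxation", {
  for (th in list(rep(35, 25), pss_sweep(50, 25)$theta_deg, rep(137, 25))) {
    for (exc in c(1i * pi / 2, pi / 2 + 0i, exp(0.5i) * 1)) {
      et <- epg_fse(exc, th, keep_state = TRUE)
      st <- et$state
      k <- length(st$Fp)
      e_t <- Mod(st$Fp[1])^2 + sum(Mod(st$Fp[-1])^2 + Mod(st$Fm[-1])^2)
      e_z <- Mod(st$Z[1])^2 + 2 * sum(Mod(st$Z[-1])^2)
      expect_lte(e_t + e_z, 1 + 1e-9)
    }
  }
})

test_that("spatially resolved EPG reduces to the scalar simulation", {
  sw <- pss_sweep(35, 20)
  set.seed(8)
  alpha <- c(1i * pi / 2, 0.3 + 0.2i, 0.05 + 0i, 0+0i,
             complex(real = rnorm(6, 0, 0.1), imaginary = runif(6, 0, 1)))
  st <- spatial_epg(alpha, sw, T1 = 3651, T2 = 1429, esp = 4)
  expect_equal(dim(st$cpmg), c(20L, length(alpha)))
  expect_equal(sum(st$dummy), 6L)
  for (v in seq_along(alpha)) {
    ref_c <- epg_fse(1i * Im(alpha[v]), sw, 3651, 1429, 4)$e
    ref_n <- epg_fse(complex(real = Re(alpha[v])), sw, 3651, 1429, 4)$e
    expect_equal(st$cpmg[, v], ref_c, tolerance = 1e-12)
    expect_equal(st$noncpmg[, v], ref_n, tolerance = 1e-12)
  }
  ## the non-CPMG stack decays along the train while the CPMG one is stable
  big <- abs(Im(alpha)) > 0.1 | abs(Re(alpha)) > 0.1
  cp <- Mod(st$cpmg[, 1]); nc <- Mod(st$noncpmg[, 2])
  expect_gt(mean(cp[15:20]) / cp[1], 0.4)
  expect_lt(mean(nc[15:20]) / max(nc[1:3]), 0.3)
})

test_that("echo trains export as CSV", {
  et <- epg_fse(1i * pi / 2, rep(120, 10), 1000, 200)
  f <- tempfile(fileext = ".csv")
  df <- write_echo_train(et, f)
  rt <- read.csv(f)
  expect_equal(rt$magnitude, Mod(et$e), tolerance = 1e-12)
})
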