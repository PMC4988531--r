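## Time-optimal VERSE: re-time the gradient waveform along its own k-space
## path so that the peak RF amplitude is capped, preserving the ratio of RF
## to gradient amplitude as a function of arc length (the VERSE invariant,
## which leaves the on-resonance small-tip profile unchanged).

#' Time-optimal VERSE peak-RF reduction
#'
#' Traverses the identical k-space path with a new time parameterization
#' such that the maximum RF amplitude over channels does not exceed
#' `b_limit`, subject to the gradient amplitude and slew limits. At every
#' arc position the ratio of RF to traversal speed is preserved (the VERSE
#' invariant), so the on-resonance small-tip excitation profile is
#' unchanged; the local speed is additionally capped at the value that
#' brings the RF down to `b_limit`, and forward/backward acceleration
#' passes restore slew feasibility. Samples where the gradient is (near)
#' zero but RF plays — such as the terminal k-space-centre portion of a
#' spin-echo excitation — cannot be re-parameterized in arc length and are
#' instead dilated in time, scaling the RF down while preserving its
#' integral. The output never contains an out-of-limit sample.
#'
#' @param gradients a `gradient_set`.
#' @param pulse an `rf_pulse_set` on the same raster (microtesla).
#' @param b_limit peak RF limit, microtesla.
#' @param g_max gradient limit, mT/m.
#' @param s_max slew limit, T/m/s.
#' @return List of class `verse_result` with new `gradients`, `pulse`, the
#'   achieved `peak_ut` and the input peak.
#' @export
time_optimal_verse <- function(gradients, pulse, b_limit, g_max = 40,
                               s_max = 200) {
  if (b_limit <= 0) stop2("b_limit must be positive")
  if (nrow(pulse$b) != nrow(gradients$G))
    stop2("pulse and gradients must share the raster")
  peak_in <- pulse$peak
  if (peak_in <= b_limit) {
    return(structure(list(gradients = gradients, pulse = pulse,
                          peak_ut = peak_in, peak_in_ut = peak_in,
                          changed = FALSE),
                     class = "verse_result"))
  }
  gam <- GAMMA_PROTON
  dt <- gradients$dt
  n <- nrow(gradients$G)
  if (is.null(gradients$k)) gradients$k <- kspace_of(gradients)
  k <- gradients$k
  v <- gam * sqrt(rowSums(gradients$G^2)) # rad/m/s
  vref <- max(v)
  moving <- v > 1e-3 * vref
  demand <- apply(Mod(pulse$b), 1, max) # uT per time sample

  ## demanded speed: slow down exactly where RF is over the limit (the
  ## input waveform already satisfies the geometric limits and slowing
  ## down can only lower gradient amplitude)
  r <- pmin(1, 0.999 * b_limit / pmax(demand, 1e-12))
  v_des <- v * r

  ## forward/backward passes smooth the transitions into and out of
  ## slowed-down regions so the deceleration stays slew-feasible; a
  ## conservative tangential-acceleration budget leaves headroom for the
  ## curvature the input waveform already carries
  ds <- sqrt(rowSums((k[-1, , drop = FALSE] - k[-n, , drop = FALSE])^2))
  ## per-segment acceleration budget: never tighter than what the input
  ## waveform itself does (so its own ramps are untouched), with a
  ## conservative floor for ramps into newly slowed regions
  a_in <- abs(v[-1]^2 - v[-n]^2) / (2 * pmax(ds, 1e-12))
  a_seg <- pmax(a_in, 0.7 * gam * s_max)
  vf <- v_des
  for (i in 2:n) {
    lim <- sqrt(vf[i - 1]^2 + 2 * a_seg[i - 1] * ds[i - 1])
    if (vf[i] > lim) vf[i] <- lim
  }
  vb <- vf
  for (i in (n - 1):1) {
    lim <- sqrt(vb[i + 1]^2 + 2 * a_seg[i] * ds[i])
    if (vb[i] > lim) vb[i] <- lim
  }
  vnew <- pmin(vb, v) # never faster than the input

  ## per-sample stretch factor: how much slower each input sample plays
  s_fac <- ifelse(moving & vnew > 0, v / vnew,
                  pmax(1, demand / (0.999 * b_limit)))
  s_fac <- pmax(s_fac, 1)

  ## stretched centre time of each input sample (sample 1 centred at 0, as
  ## in the unstretched raster), and its deposition kernel edges: sample i
  ## deposits its RF area b_i*dt uniformly over s_i*dt around its centre
  cent <- dt * c(0, cumsum((s_fac[-n] + s_fac[-1]) / 2))
  Tend <- cent[n]
  nt <- ceiling(Tend / dt) + 1L
  tu <- seq(0, by = dt, length.out = nt)
  tu[nt] <- Tend
  cmono <- cent + seq(0, 1e-9 * max(Tend, dt), length.out = n)
  kt <- sapply(1:3, function(j) stats::approx(cmono, k[, j], xout = tu,
                                              rule = 2)$y)
  ## cumulative deposition is piecewise linear between kernel edges
  ## g_i = cent_i - s_i dt/2 (contiguous: g_{i+1} = g_i + s_i dt); each
  ## output sample integrates it over its own raster kernel. When no
  ## stretching is needed this reproduces the input samples exactly.
  edges <- c(cent - s_fac * dt / 2, cent[n] + s_fac[n] * dt / 2)
  edges <- cummax(edges + seq(0, 1e-9 * max(Tend, dt), length.out = n + 1))
  Dn <- rbind(0+0i, apply(pulse$b * dt, 2, cumsum))
  bnew <- sapply(seq_len(ncol(pulse$b)), function(cc) {
    Dre <- stats::approx(edges, Re(Dn[, cc]), xout = c(tu - dt / 2, Tend + dt / 2),
                         rule = 2)$y
    Dim <- stats::approx(edges, Im(Dn[, cc]), xout = c(tu - dt / 2, Tend + dt / 2),
                         rule = 2)$y
    complex(real = diff(Dre), imaginary = diff(Dim)) / dt
  })
  G <- matrix(0, nt, 3)
  if (nt > 2)
    G[2:(nt - 1), ] <- (kt[3:nt, , drop = FALSE] -
                        kt[1:(nt - 2), , drop = FALSE]) / (2 * gam * dt)

  ## guard against interpolation overshoot: never emit an out-of-limit sample
  dem_out <- apply(Mod(bnew), 1, max)
  over <- dem_out > b_limit
  if (any(over))
    bnew[over, ] <- bnew[over, , drop = FALSE] * (b_limit / dem_out[over])

  gs <- structure(list(G = G, dt = dt, duration = (nt - 1) * dt, k = kt,
                       g_max = g_max, s_max = s_max,
                       curve = gradients$curve),
                  class = "gradient_set")
  pl <- rf_pulse_set(bnew, dt)
  structure(list(gradients = gs, pulse = pl, peak_ut = pl$peak,
                 peak_in_ut = peak_in, changed = TRUE),
            class = "verse_result")
}

#' @export
print.verse_result <- function(x, ...) {
  cat(sprintf("<verse_result> peak %.2f -> %.2f uT | duration %.2f ms%s\n",
              x$peak_in_ut, x$peak_ut, x$gradients$duration * 1e3,
              if (x$changed) "" else " (input already compliant)"))
  invisible(x)
}
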