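## Excitation k-space curves (3D spherical shells, 2D spiral) and their
## conversion to slew- and amplitude-limited time-optimal gradient
## waveforms by forward/backward velocity passes over the arc-length
## parameterized curve.

new_k_curve <- function(points, meta = list()) {
  colnames(points) <- c("kx", "ky", "kz")
  structure(c(list(points = points), meta), class = "k_curve")
}

#' @export
print.k_curve <- function(x, ...) {
  kmax <- max(sqrt(rowSums(x$points^2)))
  cat(sprintf("<k_curve> %s | %d points | max |k| %.1f rad/m | ends at |k| = %.2g\n",
              if (is.null(x$kind)) "custom" else x$kind, nrow(x$points), kmax,
              sqrt(sum(x$points[nrow(x$points), ]^2))))
  invisible(x)
}

#' 3D spherical-shells excitation k-space curve
#'
#' Concentric spherical spirals traversed from the outermost shell inwards,
#' ending exactly at the k-space origin so that the effective centre of the
#' excitation sits at the end of the pulse (the property that makes shells
#' trajectories suitable for spin-echo excitation). Each shell is a
#' constant-polar-rate spherical spiral (Wong-Roos style); successive shells
#' are rotated about the x-axis by `inter_shell_rotation` and alternate
#' pole-to-pole direction so inter-shell jumps stay short.
#'
#' Shell radii are spaced by `radial_undersample` times the Nyquist spacing
#' \eqn{2\pi/FOV}; the within-shell turn spacing along the polar arc is
#' `angular_undersample` times the same Nyquist spacing.
#'
#' @param n_shells number of shells (>= 1).
#' @param k_max outermost shell radius, rad/m.
#' @param radial_undersample radial spacing factor relative to Nyquist (>= 1).
#' @param angular_undersample within-shell turn spacing factor (>= 1).
#' @param inter_shell_rotation rotation between successive shells about the
#'   x-axis, degrees.
#' @param fov_ref reference field of view for the Nyquist spacing, mm.
#' @param ds approximate arc-length sample spacing of the returned curve,
#'   rad/m.
#' @return A `k_curve` object.
#' @examples
#' kc <- shells_3d(6, 280, 1.75, 3.21, 30, 220)
#' max(sqrt(rowSums(kc$points^2))) # 280
#' @export
shells_3d <- function(n_shells = 6, k_max = 280, radial_undersample = 1.75,
                      angular_undersample = 3.21, inter_shell_rotation = 30,
                      fov_ref = 220, ds = 1) {
  if (k_max <= 0) stop2("k_max must be positive")
  if (n_shells < 1) stop2("n_shells must be >= 1")
  if (radial_undersample < 1 || angular_undersample < 1)
    stop2("under-sample factors must be >= 1")
  if (fov_ref <= 0) stop2("fov_ref must be positive")

  nyq <- 2 * pi / (fov_ref / 1000)            # rad/m
  dr <- radial_undersample * nyq              # shell separation
  spacing <- angular_undersample * nyq        # turn separation along polar arc
  radii <- k_max - (seq_len(n_shells) - 1) * dr
  radii <- radii[radii > 1e-9]
  if (!length(radii)) { # zero-extent limit: a single point at the origin
    return(new_k_curve(matrix(0, 2, 3),
                       list(kind = "shells_3d", n_shells = 0L, k_max = k_max,
                            radial_undersample = radial_undersample,
                            angular_undersample = angular_undersample,
                            inter_shell_rotation = inter_shell_rotation,
                            fov_ref = fov_ref)))
  }

  pts <- list()
  for (s in seq_along(radii)) {
    r <- radii[s]
    n_turns <- max(1, pi * r / spacing)
    arclen <- pi * r * sqrt(1 + (2 * n_turns * 2 / pi)^2) # rough estimate
    npt <- max(16L, ceiling(arclen / ds))
    th <- seq(0, pi, length.out = npt)
    if (s %% 2 == 0) th <- rev(th)            # alternate traversal direction
    ph <- 2 * n_turns * th
    p <- cbind(r * sin(th) * cos(ph), r * sin(th) * sin(ph), r * cos(th))
    rot <- deg2rad(inter_shell_rotation) * (s - 1)
    cr <- cos(rot); sr <- sin(rot)
    p <- cbind(p[, 1], cr * p[, 2] - sr * p[, 3], sr * p[, 2] + cr * p[, 3])
    pts[[s]] <- p
  }
  p <- do.call(rbind, pts)
  ## straight run-in to the origin from the last shell's end point
  endp <- p[nrow(p), ]
  endlen <- sqrt(sum(endp^2))
  if (endlen > 1e-9) {
    nin <- max(2L, ceiling(endlen / ds))
    frac <- seq(1, 0, length.out = nin + 1)[-1]
    p <- rbind(p, outer(frac, endp))
  }
  p[nrow(p), ] <- 0
  new_k_curve(p, list(kind = "shells_3d", n_shells = length(radii),
                      k_max = k_max, radial_undersample = radial_undersample,
                      angular_undersample = angular_undersample,
                      inter_shell_rotation = inter_shell_rotation,
                      fov_ref = fov_ref))
}

#' 2D spiral excitation k-space curve
#'
#' Archimedean spiral traversed from the edge of k-space to the centre,
#' ending exactly at the origin. `k_max` is set by the nominal resolution,
#' \eqn{k_{max} = \pi / \Delta x}; the spacing between adjacent turns is
#' `undersample` times the Nyquist spacing \eqn{2\pi/FOV}.
#'
#' The optional `variable_velocity` profile separates geometry from timing:
#' it is a function of normalized radius \eqn{|k|/k_{max}} returning a
#' factor in (0, 1] that multiplies the local speed limit during
#' time-optimal gradient generation, slowing the traversal (usually near the
#' k-space centre) to buy peak-RF headroom. The curve geometry is identical
#' with or without it.
#'
#' @param fov field of view, mm.
#' @param resolution nominal excitation resolution, mm.
#' @param undersample turn-spacing factor relative to Nyquist.
#' @param variable_velocity optional function(kfrac) -> speed factor in (0,1].
#' @param ds approximate arc-length sample spacing, rad/m.
#' @return A `k_curve` object.
#' @examples
#' kc <- spiral_2d(220, 3.4, 3.5)
#' max(sqrt(rowSums(kc$points^2))) # ~ pi / 0.0034
#' @export
spiral_2d <- function(fov = 220, resolution = 3.4, undersample = 3.5,
                      variable_velocity = NULL, ds = 1) {
  if (resolution >= fov) stop2("resolution must be smaller than fov")
  if (undersample < 1)
    warning("undersample < 1: trajectory is over-sampled relative to Nyquist")
  k_max <- pi / (resolution / 1000)
  spacing <- undersample * 2 * pi / (fov / 1000) # rad/m between turns
  a <- spacing / (2 * pi)                        # k = a * phi
  phi_max <- k_max / a
  ## uniform arc length: ds ~ a*sqrt(1+phi^2) dphi; integrate numerically
  nphi <- max(64L, ceiling(a * phi_max^2 / 2 / ds))
  phi <- sqrt(seq(phi_max^2, 0, length.out = nphi)) # denser near edge is fine
  k <- a * phi
  p <- cbind(k * cos(phi), k * sin(phi), 0)
  p[nrow(p), ] <- 0
  new_k_curve(p, list(kind = "spiral_2d", k_max = k_max, fov_ref = fov,
                      resolution = resolution, undersample = undersample,
                      variable_velocity = variable_velocity))
}

## Resample an N x 3 polyline to ~uniform arc length; returns points, s grid.
resample_arclength <- function(p, n_out) {
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  keep <- c(TRUE, seg > 1e-12)
  p <- p[keep, , drop = FALSE]; s <- s[keep]
  L <- s[length(s)]
  su <- seq(0, L, length.out = n_out)
  out <- sapply(1:3, function(j) stats::approx(s, p[, j], xout = su)$y)
  list(points = out, s = su, L = L)
}

## Curvature magnitude of an arc-length-uniform polyline (1/(rad/m)).
curvature_of <- function(p, ds) {
  n <- nrow(p)
  d2 <- (p[c(2:n, n), ] - 2 * p + p[c(1, 1:(n - 1)), ]) / ds^2
  k <- sqrt(rowSums(d2^2))
  k[1] <- k[2]; k[n] <- k[n - 1]
  ## light smoothing guards against resampling noise
  k <- (c(k[1], k[-n]) + k + c(k[-1], k[n])) / 3
  k
}

#' Time-optimal gradient waveforms for a k-space curve
#'
#' Reparameterizes the curve in time so that it is traversed in minimum
#' duration subject to the gradient amplitude limit `g_max` and slew-rate
#' limit `s_max`, using forward and backward velocity passes over the
#' arc-length parameterization: the speed (in rad/m/s) is capped by
#' \eqn{\gamma G_{max}} and by \eqn{\sqrt{\gamma S_{max}/\kappa}} where
#' \eqn{\kappa} is the local curvature, and acceleration is limited by the
#' slew rate. The waveform starts and ends at zero gradient.
#'
#' @param curve a `k_curve`.
#' @param g_max gradient amplitude limit, mT/m.
#' @param s_max slew-rate limit, T/m/s.
#' @param dt output raster time, s (default 6.4 microseconds).
#' @param n_arc number of arc-length samples used internally (default scales
#'   with curve length).
#' @return An object of class `gradient_set`: `G` (matrix n x 3, T/m), `dt`,
#'   `duration` (s), plus the realized k-space samples `k` (n x 3, rad/m).
#' @examples
#' kc <- spiral_2d(220, 8, 4)
#' gs <- time_optimal_gradients(kc, 40, 200)
#' @export
time_optimal_gradients <- function(curve, g_max = 40, s_max = 200,
                                   dt = 6.4e-6, n_arc = NULL) {
  if (g_max <= 0 || s_max <= 0 || dt <= 0) stop2("limits must be positive")
  p0 <- curve$points
  if (nrow(p0) < 2) stop2("curve must have at least 2 points")
  gam <- GAMMA_PROTON
  seg <- sqrt(rowSums((p0[-1, , drop = FALSE] - p0[-nrow(p0), , drop = FALSE])^2))
  L <- sum(seg)
  if (L <= 0) { # degenerate single-point curve
    G <- matrix(0, 2, 3)
    return(structure(list(G = G, dt = dt, duration = dt,
                          k = rbind(p0[1, ], p0[1, ]), curve = curve),
                     class = "gradient_set"))
  }
  if (is.null(n_arc)) n_arc <- min(60000L, max(4000L, ceiling(L / 0.5)))
  rs <- resample_arclength(p0, n_arc)
  p <- rs$points; s <- rs$s; ds <- s[2] - s[1]
  kap <- pmax(curvature_of(p, ds), 1e-12)

  ## small safety margins keep the discretized output strictly inside limits
  vmax_amp <- gam * g_max * 1e-3 * 0.999
  acc <- gam * s_max * 0.995                  # rad/m/s^2
  vmax <- pmin(vmax_amp, sqrt(acc / kap))
  vv <- curve$variable_velocity
  if (!is.null(vv)) {
    kfrac <- sqrt(rowSums(p^2)) / max(sqrt(rowSums(p^2)), 1e-12)
    vmax <- vmax * pmin(pmax(vv(kfrac), 1e-3), 1)
  }

  ## forward pass (from rest) and backward pass (to rest), Euler in s
  vf <- numeric(n_arc); vf[1] <- 0
  for (i in 2:n_arc) {
    v <- vf[i - 1]
    a_t <- sqrt(max(acc^2 - (kap[i - 1] * v^2)^2, 0)) # tangential headroom
    v2 <- sqrt(v^2 + 2 * a_t * ds)
    vf[i] <- min(v2, vmax[i])
  }
  vb <- numeric(n_arc); vb[n_arc] <- 0
  for (i in (n_arc - 1):1) {
    v <- vb[i + 1]
    a_t <- sqrt(max(acc^2 - (kap[i + 1] * v^2)^2, 0))
    v2 <- sqrt(v^2 + 2 * a_t * ds)
    vb[i] <- min(v2, vmax[i])
  }
  v <- pmin(vf, vb)

  ## time along the curve: dt = ds / v with midpoint speeds
  vmid <- pmax((v[-1] + v[-n_arc]) / 2, 1e-9)
  tt <- c(0, cumsum(ds / vmid))
  Tend <- tt[n_arc]
  nt <- ceiling(Tend / dt) + 1L
  tu <- seq(0, by = dt, length.out = nt)
  tu[nt] <- Tend
  si <- stats::approx(tt, s, xout = tu)$y
  kt <- sapply(1:3, function(j) stats::approx(s, p[, j], xout = si)$y)

  ## G from the k samples: k(t) = -gamma * int_t^T G  =>  dk/dt = +gamma G
  ## (central differences keep trapezoidal re-integration consistent)
  G <- matrix(0, nt, 3)
  if (nt > 2)
    G[2:(nt - 1), ] <- (kt[3:nt, , drop = FALSE] -
                        kt[1:(nt - 2), , drop = FALSE]) / (2 * gam * dt)
  structure(list(G = G, dt = dt, duration = (nt - 1) * dt, k = kt,
                 g_max = g_max, s_max = s_max, curve = curve),
            class = "gradient_set")
}

#' @export
print.gradient_set <- function(x, ...) {
  gm <- max(sqrt(rowSums(x$G^2))) * 1e3
  sl <- max_slew(x)
  cat(sprintf("<gradient_set> %d samples @ %.1f us | duration %.2f ms | max |G| %.1f mT/m | max slew %.0f T/m/s\n",
              nrow(x$G), x$dt * 1e6, x$duration * 1e3, gm, sl))
  invisible(x)
}

#' @export
plot.gradient_set <- function(x, ...) {
  t_ms <- seq(0, by = x$dt, length.out = nrow(x$G)) * 1e3
  graphics::matplot(t_ms, x$G * 1e3, type = "l", lty = 1,
                    xlab = "time (ms)", ylab = "G (mT/m)", ...)
  graphics::legend("topright", legend = c("x", "y", "z"), col = 1:3, lty = 1,
                   bty = "n")
  invisible(x)
}

## Maximum per-axis slew rate of a gradient_set, T/m/s.
max_slew <- function(gs) {
  dG <- diff(gs$G) / gs$dt
  max(abs(dG))
}

#' Excitation k-space at RF sample centres
#'
#' Excitation k-space evaluated at the effective time of each RF sample
#' under the hard-pulse discretization used by [bloch_simulate()] (each
#' sample's rotation composes its own half gradient step plus all later
#' steps):
#' \eqn{k_j = -\gamma \Delta t (G_j/2 + \sum_{l>j} G_l)}. Using these
#' samples in [build_system_matrix()] makes the linear prediction agree
#' with the Bloch simulator to discretization order.
#'
#' @param gs a `gradient_set`.
#' @return Matrix (n x 3), rad/m.
#' @export
rf_sample_kspace <- function(gs) {
  n <- nrow(gs$G)
  sapply(1:3, function(j) {
    g <- gs$G[, j]
    tailsum <- rev(cumsum(rev(g))) # S_j = sum_{l >= j} g_l
    -GAMMA_PROTON * gs$dt * (tailsum - g / 2)
  })
}

#' Excitation k-space of a gradient waveform
#'
#' Returns \eqn{k(t) = -\gamma \int_t^T G(\tau) d\tau} (rad/m), the
#' excitation k-space convention in which the trajectory always ends at the
#' origin.
#'
#' @param gs a `gradient_set`.
#' @return Matrix (n x 3) of k-space samples, rad/m.
#' @export
kspace_of <- function(gs) {
  n <- nrow(gs$G)
  tgrid <- seq(0, by = gs$dt, length.out = n)
  sapply(1:3, function(j) {
    ci <- cumtrapz1(tgrid, gs$G[, j])
    -GAMMA_PROTON * (ci[n] - ci)
  })
}
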