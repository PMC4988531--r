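# Independent oracles used across the suite.

# Brute-force isochromat-ensemble FSE simulator: N isochromats uniformly
# spread in dephasing angle (ideal crushers: one full 2*pi spread per
# half echo spacing), rotations applied explicitly to 3-vectors.
iso_fse <- function(excitation, thetas_deg, T1 = Inf, T2 = Inf, esp = 4,
                    n_iso = 512) {
  psi <- 2 * pi * (seq_len(n_iso) - 1) / n_iso
  a <- Mod(excitation); ph <- Arg(excitation)
  mxy <- sin(a) * exp(1i * ph)
  Mxy <- rep(mxy, n_iso)
  Mz <- rep(cos(a), n_iso)
  E1 <- exp(-esp / 2 / T1); E2 <- exp(-esp / 2 / T2)
  relax_dephase <- function() {
    Mxy <<- Mxy * E2 * exp(-1i * psi) # precession convention: exp(-i psi)
    Mz <<- E1 * Mz + (1 - E1)
  }
  rot_y <- function(th) {
    al <- th * pi / 180
    mx <- Re(Mxy); my <- Im(Mxy)
    mx2 <- mx * cos(al) + Mz * sin(al)
    mz2 <- -mx * sin(al) + Mz * cos(al)
    Mxy <<- complex(real = mx2, imaginary = my)
    Mz <<- mz2
  }
  echoes <- complex(length(thetas_deg))
  for (n in seq_along(thetas_deg)) {
    relax_dephase()
    rot_y(thetas_deg[n])
    relax_dephase()
    echoes[n] <- mean(Mxy)
  }
  echoes
}

# Dense direct solution of the phase-relaxed problem via the explicitly
# stacked real system and base R solve() on the normal equations.
dense_pr_solve <- function(A, m, w_r, lambda_abs, w_i = 1) {
  Ar <- Re(A); Ai <- Im(A)
  Asw <- rbind(cbind(w_i * Ai, w_i * Ar),
               cbind(w_r * Ar, -w_r * Ai))
  msw <- c(w_i * Im(m), w_r * Re(m))
  nn <- ncol(Asw)
  N <- t(Asw) %*% Asw + lambda_abs * diag(nn)
  rhs <- t(Asw) %*% msw
  ## pseudo-inverse solve so rank-deficient cases (w_r = 0, lambda = 0)
  ## give the minimum-norm solution, as conjugate gradient from zero does
  sv <- svd(N)
  keep <- sv$d > max(sv$d) * 1e-12
  xs <- sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% rhs) / sv$d[keep])
  complex(real = xs[1:(nn / 2)], imaginary = xs[(nn / 2 + 1):nn])
}

# lambda normalization used by solve_phase_relaxed, reproduced here so the
# dense oracle solves the identical system
lambda_scale <- function(A, w_r) mean(Mod(A)^2) * nrow(A) * (1 + w_r^2) / 2

# constant-gradient gradient_set helper
flat_gradient <- function(n, dt, gx = 0, gy = 0, gz = 0) {
  G <- cbind(rep(gx, n), rep(gy, n), rep(gz, n))
  structure(list(G = G, dt = dt, duration = n * dt, k = NULL),
            class = "gradient_set")
}

# small uniform single-slice maps used in several design tests
tiny_uniform_maps <- function(n = 12, fov = 100, n_channels = 1) {
  make_phantom_maps(c(n, n, 1), fov = fov, n_channels = n_channels,
                    uniform = TRUE)
}
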