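## Synthetic transmit-sensitivity / off-resonance maps, phantom masks and
## target excitation patterns. These emulate the qualitative structure of
## body-coil parallel-transmit field maps (smooth low-order spatial
## variation, per-channel azimuthal phase) without any electromagnetic
## simulation, so every design and simulation module is testable without
## scanner data.

#' Generate synthetic field maps for a spherical phantom
#'
#' Produces per-channel complex transmit sensitivities \eqn{S_c(r)}, an
#' off-resonance map \eqn{\Delta\omega(r)} and a spherical object mask on a
#' regular 3D grid. Sensitivities follow a birdcage-like model: a smooth
#' low-order harmonic magnitude profile with a per-channel azimuthal phase
#' ramp plus small seeded random harmonic perturbations. The off-resonance
#' field is a smooth low-order polynomial scaled to the requested range,
#' optionally with focal Gaussian lesions superimposed.
#'
#' @param grid_shape integer vector of length 3 (or a scalar, reused), at
#'   least 8 per axis. A third dimension of 1 gives a single-slice (2D)
#'   problem.
#' @param fov field of view in mm (length 3 or scalar).
#' @param n_channels number of transmit channels (>= 1).
#' @param b0_amplitude approximate peak off-resonance inside the object, Hz.
#' @param focal_b0 optional list (or list of lists) with elements
#'   `center_mm` (length 3), `fwhm_mm` and `amplitude_hz` describing focal
#'   off-resonance Gaussians.
#' @param uniform if `TRUE`, returns the identity configuration:
#'   \eqn{S \equiv 1 + 0i} on every channel and \eqn{\Delta\omega \equiv 0}.
#' @param drive_amplitude overall linear scaling of all sensitivities.
#' @param seed integer seed; maps are bit-identical for equal seeds.
#' @return An object of class `field_maps`: a list with `grid_shape`,
#'   `voxel_mm`, `fov_mm`, `S` (complex array `nx x ny x nz x n_channels`),
#'   `dw` (rad/s, array), `mask` (logical array).
#' @examples
#' maps <- make_phantom_maps(c(16, 16, 1), fov = 220, n_channels = 2, seed = 1)
#' @export
make_phantom_maps <- function(grid_shape, fov = 220, n_channels = 8,
                              b0_amplitude = 50, focal_b0 = NULL,
                              uniform = FALSE, drive_amplitude = 1,
                              seed = NULL) {
  grid_shape <- as.integer(rep_len(grid_shape, 3L))
  fov <- rep_len(as.numeric(fov), 3L)
  if (any(fov <= 0)) stop2("fov must be positive")
  if (any(grid_shape < 1L) || all(grid_shape < 8L))
    stop2("grid_shape must be at least 8 along the principal axes")
  if (n_channels < 1L) stop2("n_channels must be >= 1")
  voxel_mm <- fov / grid_shape

  ax <- function(n, f) if (n == 1L) 0 else (seq_len(n) - (n + 1) / 2) / n * f
  xs <- ax(grid_shape[1], fov[1]) # mm, centred on isocentre
  ys <- ax(grid_shape[2], fov[2])
  zs <- ax(grid_shape[3], fov[3])
  X <- array(rep(xs, times = grid_shape[2] * grid_shape[3]), grid_shape)
  Y <- array(rep(rep(ys, each = grid_shape[1]), times = grid_shape[3]),
             grid_shape)
  Z <- array(rep(zs, each = grid_shape[1] * grid_shape[2]), grid_shape)

  ## spherical (or, for single-slice grids, circular) phantom mask
  r_obj <- 0.45 * min(fov[grid_shape > 1L])
  R2 <- (X / r_obj)^2 + (Y / r_obj)^2 + if (grid_shape[3] > 1L)
    (Z / r_obj)^2 else 0
  mask <- R2 <= 1

  S <- array(0+0i, c(grid_shape, n_channels))
  dw <- array(0, grid_shape)

  if (uniform) {
    S[] <- 1+0i
  } else {
    Rn <- max(fov) / 2 # normalisation length, mm
    u <- X / Rn; v <- Y / Rn; w <- Z / Rn
    coef <- with_seed(seed, {
      list(mag = matrix(stats::runif(n_channels * 3, -0.15, 0.15), n_channels),
           ph  = matrix(stats::runif(n_channels * 3, -0.4, 0.4), n_channels),
           b0  = stats::runif(6, -1, 1))
    })
    for (cc in seq_len(n_channels)) {
      phi_c <- 2 * pi * (cc - 1) / n_channels
      ## radial-ish magnitude peaked towards the channel's side of the object
      along <- u * cos(phi_c) + v * sin(phi_c)
      perp  <- -u * sin(phi_c) + v * cos(phi_c)
      mag <- 1 + 0.45 * along + coef$mag[cc, 1] * perp +
        coef$mag[cc, 2] * (u^2 + v^2) + coef$mag[cc, 3] * w
      mag <- pmax(mag, 0.08)
      ph <- phi_c + 0.9 * perp + coef$ph[cc, 1] * along +
        coef$ph[cc, 2] * w + coef$ph[cc, 3] * (u^2 - v^2)
      S[, , , cc] <- drive_amplitude * mag * exp(1i * ph)
    }
    b0 <- coef$b0
    raw <- b0[1] * u + b0[2] * v + b0[3] * w + b0[4] * (u^2 + v^2 - w^2) +
      b0[5] * u * v + b0[6] * (u^2 - v^2)
    pk <- max(abs(raw[mask]), 1e-12)
    dw <- raw / pk * 2 * pi * b0_amplitude
  }

  if (!is.null(focal_b0)) {
    if (!is.null(focal_b0$center_mm)) focal_b0 <- list(focal_b0)
    for (f in focal_b0) {
      sig <- f$fwhm_mm / 2.3548
      d2 <- (X - f$center_mm[1])^2 + (Y - f$center_mm[2])^2 +
        (Z - f$center_mm[3])^2
      dw <- dw + 2 * pi * f$amplitude_hz * exp(-d2 / (2 * sig^2))
    }
  }

  structure(list(grid_shape = grid_shape, voxel_mm = voxel_mm, fov_mm = fov,
                 S = S, dw = dw, mask = mask, n_channels = n_channels),
            class = "field_maps")
}

#' @export
print.field_maps <- function(x, ...) {
  cat("<field_maps> grid", paste(x$grid_shape, collapse = "x"),
      sprintf("| voxel %.2fx%.2fx%.2f mm | %d channel(s) | %d voxels in mask\n",
              x$voxel_mm[1], x$voxel_mm[2], x$voxel_mm[3], x$n_channels,
              sum(x$mask)))
  if (any(x$mask))
    cat(sprintf("  off-resonance range %.1f .. %.1f Hz inside mask\n",
                min(x$dw[x$mask]) / 2 / pi, max(x$dw[x$mask]) / 2 / pi))
  invisible(x)
}

## Voxel-centre positions in metres, n_voxels x 3, grid (column-major) order.
field_positions <- function(maps) {
  g <- maps$grid_shape
  ax <- function(n, f) if (n == 1L) 0 else (seq_len(n) - (n + 1) / 2) / n * f
  xs <- ax(g[1], maps$fov_mm[1]) / 1000
  ys <- ax(g[2], maps$fov_mm[2]) / 1000
  zs <- ax(g[3], maps$fov_mm[3]) / 1000
  cbind(rep(xs, times = g[2] * g[3]),
        rep(rep(ys, each = g[1]), times = g[3]),
        rep(zs, each = g[1] * g[2]))
}

#' Decimate field maps to a coarser design mesh
#'
#' Pulse design matrices scale with the number of voxels, so design is
#' usually carried out on a coarse mesh (about 5.5 mm in the reference
#' experiments) even when maps are stored finer. Decimation is by
#' subsampling (nearest voxel), which cannot introduce values absent from
#' the input maps.
#'
#' @param maps a `field_maps` object.
#' @param res_mm requested design resolution in mm.
#' @return A `field_maps` object on the coarser grid.
#' @export
decimate_maps <- function(maps, res_mm) {
  step <- pmax(1L, as.integer(round(res_mm / maps$voxel_mm)))
  idx <- lapply(1:3, function(a) {
    n <- maps$grid_shape[a]
    s <- min(step[a], n)
    seq.int(from = (s + 1L) %/% 2L, to = n, by = s)
  })
  g2 <- lengths(idx)
  out <- maps
  out$grid_shape <- as.integer(g2)
  out$voxel_mm <- maps$voxel_mm * step
  out$S <- maps$S[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE]
  out$dw <- maps$dw[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  out$mask <- maps$mask[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  out
}

## Separable Gaussian blur of a 3D array, FWHM in mm per axis.
gaussian_blur3 <- function(a, fwhm_mm, voxel_mm) {
  fwhm_mm <- rep_len(fwhm_mm, 3L)
  d <- dim(a)
  for (axis in 1:3) {
    if (fwhm_mm[axis] <= 0 || d[axis] == 1L) next
    sig <- fwhm_mm[axis] / 2.3548 / voxel_mm[axis] # voxels
    hw <- max(1L, ceiling(3 * sig))
    k <- exp(-((-hw:hw)^2) / (2 * sig^2))
    k <- k / sum(k)
    a <- apply(a, setdiff(1:3, axis), function(v) {
      nv <- length(v)
      vp <- c(rep(0, hw), v, rep(0, hw)) # zero-padded: support cannot grow sign
      stats::filter(vp, k, sides = 2)[(hw + 1):(hw + nv)]
    })
    ## apply() collapses the filtered axis to the first dim; restore order
    a <- aperm(array(a, c(d[axis], d[setdiff(1:3, axis)])),
               order(c(axis, setdiff(1:3, axis))))
  }
  a
}

#' Build a target excitation pattern
#'
#' The target flip-angle map is pure imaginary inside the region of interest
#' (the CPMG component lies along the refocusing axis, y by convention) and
#' exactly zero outside, apodized with an isotropic Gaussian kernel
#' parameterized by its FWHM.
#'
#' @param maps `field_maps` defining the grid.
#' @param shape one of `"cube"`, `"heart"` (2D heart extruded along z), or
#'   `"point"` (single voxel).
#' @param size_mm edge length (cube), maximum width (heart); ignored for
#'   `"point"`.
#' @param center_mm offset of the shape centre from isocentre, mm.
#' @param apodization_fwhm_mm Gaussian apodization kernel FWHM in mm (0 for
#'   none).
#' @param flip_deg target flip angle in degrees (stored in radians).
#' @return An object of class `target_pattern` with complex array `m`
#'   (radians), logical `roi` and the apodization used.
#' @examples
#' maps <- make_phantom_maps(c(24, 24, 1), 220, 1, uniform = TRUE)
#' tgt <- make_target(maps, "cube", size_mm = 60, apodization_fwhm_mm = 6)
#' @export
make_target <- function(maps, shape = c("cube", "heart", "point"),
                        size_mm = 60, center_mm = c(0, 0, 0),
                        apodization_fwhm_mm = 6, flip_deg = 90) {
  shape <- match.arg(shape)
  g <- maps$grid_shape
  center_mm <- rep_len(center_mm, 3L)
  pos <- field_positions(maps) * 1000 # mm
  px <- pos[, 1] - center_mm[1]
  py <- pos[, 2] - center_mm[2]
  pz <- pos[, 3] - center_mm[3]

  half_fov <- maps$fov_mm / 2
  if (shape != "point" &&
      any(abs(center_mm[1:2]) + size_mm / 2 > half_fov[1:2]))
    stop2("target shape does not fit inside the field of view")

  roi <- switch(shape,
    cube = {
      h <- size_mm / 2
      ok <- abs(px) <= h & abs(py) <= h
      if (g[3] > 1L) ok <- ok & abs(pz) <= h
      ok
    },
    heart = {
      ## classic implicit heart curve (x^2 + y^2 - 1)^3 - x^2 y^3 <= 0,
      ## scaled so the maximum width equals size_mm; 2D, extruded along z
      sc <- size_mm / 2 / 1.139 # curve half-width in its own units
      hx <- px / sc; hy <- py / sc + 0.25
      (hx^2 + hy^2 - 1)^3 - hx^2 * hy^3 <= 0
    },
    point = {
      i0 <- which.min(px^2 + py^2 + pz^2)
      out <- rep(FALSE, nrow(pos)); out[i0] <- TRUE; out
    })
  roi <- array(roi, g)

  amp <- array(as.numeric(roi), g)
  if (apodization_fwhm_mm > 0 && shape != "point")
    amp <- gaussian_blur3(amp, apodization_fwhm_mm, maps$voxel_mm)
  amp <- pmin(pmax(amp, 0), 1)

  m <- array(1i * deg2rad(flip_deg) * amp, g)
  structure(list(m = m, roi = roi, flip_deg = flip_deg,
                 apodization_fwhm_mm = apodization_fwhm_mm, shape = shape,
                 grid_shape = g),
            class = "target_pattern")
}

#' @export
print.target_pattern <- function(x, ...) {
  cat(sprintf("<target_pattern> %s | flip %.1f deg | apodization %.1f mm | %d ROI voxels\n",
              x$shape, x$flip_deg, x$apodization_fwhm_mm, sum(x$roi)))
  invisible(x)
}

#' Write field maps to NIfTI files
#'
#' Writes four NIfTI volumes: `<prefix>_smag.nii.gz` and
#' `<prefix>_sphase.nii.gz` (4D, one volume per channel),
#' `<prefix>_b0.nii.gz` (off-resonance, Hz) and `<prefix>_mask.nii.gz`.
#'
#' @param maps a `field_maps` object.
#' @param prefix path prefix for the output files.
#' @return Invisibly, the vector of file names written.
#' @export
write_field_maps <- function(maps, prefix) {
  pd <- maps$voxel_mm
  wr <- function(a, suffix) {
    f <- paste0(prefix, "_", suffix, ".nii.gz")
    img <- RNifti::asNifti(a)
    RNifti::pixdim(img) <- rep_len(pd, length(dim(a)))
    RNifti::writeNifti(img, f)
    f
  }
  files <- c(wr(Mod(maps$S), "smag"), wr(Arg(maps$S), "sphase"),
             wr(maps$dw / (2 * pi), "b0"), wr(maps$mask + 0, "mask"))
  invisible(files)
}

#' Read field maps written by [write_field_maps()]
#'
#' @param prefix path prefix used when writing.
#' @return A `field_maps` object.
#' @export
read_field_maps <- function(prefix) {
  rd <- function(suffix) {
    f <- paste0(prefix, "_", suffix, ".nii.gz")
    if (!file.exists(f)) stop2("missing field-map file: ", f)
    RNifti::readNifti(f)
  }
  smag <- rd("smag"); sphase <- rd("sphase")
  b0 <- rd("b0"); msk <- rd("mask")
  voxel_mm <- RNifti::pixdim(smag)[1:3]
  d <- dim(smag)
  if (length(d) == 3L) d <- c(d, 1L)
  g <- d[1:3]
  S <- array(as.vector(smag) * exp(1i * as.vector(sphase)), d)
  structure(list(grid_shape = as.integer(g), voxel_mm = voxel_mm,
                 fov_mm = voxel_mm * g,
                 S = S, dw = array(as.vector(b0) * 2 * pi, g),
                 mask = array(as.vector(msk) > 0.5, g),
                 n_channels = d[4]),
            class = "field_maps")
}
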