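## Trajectory evaluation: point-spread-function surrogates (design a pulse
## for a point target and measure the predicted excitation), random
## candidate-trajectory scanning, and image-domain suppression-ratio
## quantification.

#' Point-spread-function surrogate for a trajectory
#'
#' Designs a pulse for a single-voxel target at (or nearest to) the
#' requested location, predicts the excitation with the forward model
#' \eqn{\hat m = A b}, and measures the full width at half maximum of
#' \eqn{|\hat m|} along each grid axis through the peak (linear
#' interpolation at half max) and the peak-to-sidelobe ratio (main-lobe
#' peak over the largest local maximum outside twice the FWHM around the
#' peak, searched over the whole mask). The PSF of a tailored pulse is
#' spatially variable; this evaluates it at one location as a guide.
#'
#' @param maps `field_maps` (already at design resolution).
#' @param curve a `k_curve`.
#' @param dt raster, s.
#' @param eval_point_mm location of the point target, mm (default
#'   isocentre).
#' @param lambda regularization for the point design.
#' @param w_r non-CPMG weight (default 1: standard design).
#' @param g_max,s_max gradient limits for the timing.
#' @param girf optional `impulse_response`.
#' @return List with `fwhm_mm` (length 3, `NA` on singleton axes), `psr`
#'   (`Inf` with a flag when no sidelobe exists), `duration_ms` and the
#'   predicted excitation magnitude image.
#' @export
psf_surrogate <- function(maps, curve, dt = 6.4e-6,
                          eval_point_mm = c(0, 0, 0), lambda = 1e-3,
                          w_r = 1, g_max = 40, s_max = 200, girf = NULL) {
  gs <- time_optimal_gradients(curve, g_max, s_max, dt)
  kH <- if (is.null(girf)) rf_sample_kspace(gs) else
    rf_sample_kspace(apply_girf(gs, girf))
  td <- max(1L, nrow(kH) %/% 512L)
  idx <- unique(c(seq(1L, nrow(kH), by = td), nrow(kH)))
  A <- build_system_matrix(maps, kH[idx, , drop = FALSE], gs$dt * td)
  tgt <- make_target(maps, "point", center_mm = eval_point_mm,
                     apodization_fwhm_mm = 0)
  sol <- solve_phase_relaxed(A, tgt, w_r = w_r, lambda = lambda)
  img <- array(0, maps$grid_shape)
  img[A$voxels] <- Mod(sol$predicted)

  peak_idx <- which.max(img)
  pk <- arrayInd(peak_idx, maps$grid_shape)
  pval <- img[peak_idx]

  fwhm <- rep(NA_real_, 3)
  for (axis in 1:3) {
    if (maps$grid_shape[axis] == 1L) next
    prof <- switch(axis,
                   img[, pk[2], pk[3]], img[pk[1], , pk[3]],
                   img[pk[1], pk[2], ])
    fwhm[axis] <- profile_fwhm(prof, maps$voxel_mm[axis], pk[axis])
  }

  ## main lobe: voxels within 2x FWHM of the peak (per axis)
  g <- maps$grid_shape
  ai <- arrayInd(seq_len(prod(g)), g)
  r_vox <- fwhm / maps$voxel_mm
  r_vox[is.na(r_vox)] <- 1
  inlobe <- rowSums(((ai - matrix(pk, prod(g), 3, byrow = TRUE)) /
                       matrix(pmax(r_vox, 1), prod(g), 3, byrow = TRUE))^2) <= 4
  side <- img
  side[inlobe] <- 0
  smax <- max(side)
  psr <- if (smax <= 0) structure(Inf, flag = "no sidelobe found") else
    pval / smax
  list(fwhm_mm = fwhm, psr = psr, duration_ms = gs$duration * 1e3,
       image = img, peak_index = pk)
}

## FWHM of a 1D profile (linear interpolation at half max), in mm.
profile_fwhm <- function(prof, voxel_mm, peak_pos = which.max(prof)) {
  half <- prof[peak_pos] / 2
  n <- length(prof)
  left <- NA_real_
  for (i in seq(peak_pos, 2)) {
    if (prof[i - 1] < half) {
      left <- (i - 1) + (half - prof[i - 1]) / (prof[i] - prof[i - 1])
      break
    }
  }
  right <- NA_real_
  if (peak_pos < n) {
    for (i in seq(peak_pos, n - 1)) {
      if (prof[i + 1] < half) {
        right <- i + (prof[i] - half) / (prof[i] - prof[i + 1])
        break
      }
    }
  }
  if (is.na(left) || is.na(right)) return(NA_real_)
  (right - left) * voxel_mm
}

#' Scan random candidate shell trajectories
#'
#' Generates `n_candidates` random 3D-shells trajectories within the given
#' parameter ranges, produces time-optimal gradients for each and scores
#' them with the point-target PSF surrogate. No automatic winner is
#' declared; the table is meant for manual inspection.
#'
#' @param maps design-resolution `field_maps`.
#' @param n_candidates number of candidates.
#' @param ranges list of `c(min, max)` ranges for `n_shells`, `k_max`,
#'   `radial_undersample`, `angular_undersample`, `inter_shell_rotation`.
#' @param seed RNG seed (results are reproducible for equal seeds).
#' @param dt raster, s.
#' @param ... passed to [psf_surrogate()].
#' @return Data frame, one row per candidate: parameters, `fwhm_x/y/z_mm`,
#'   `psr`, `duration_ms`, and `ok` (FALSE when the candidate failed).
#' @export
scan_trajectories <- function(maps, n_candidates = 10,
                              ranges = list(n_shells = c(4, 8),
                                            k_max = c(150, 350),
                                            radial_undersample = c(1, 2.5),
                                            angular_undersample = c(2, 4),
                                            inter_shell_rotation = c(0, 45)),
                              seed = 1, dt = 6.4e-6, ...) {
  draw <- function(r) stats::runif(1, r[1], r[2])
  rows <- with_seed(seed, {
    lapply(seq_len(n_candidates), function(i) {
      par <- list(n_shells = round(draw(ranges$n_shells)),
                  k_max = draw(ranges$k_max),
                  radial_undersample = draw(ranges$radial_undersample),
                  angular_undersample = draw(ranges$angular_undersample),
                  inter_shell_rotation = draw(ranges$inter_shell_rotation))
      res <- tryCatch({
        kc <- do.call(shells_3d, c(par, list(fov_ref = max(maps$fov_mm))))
        psf_surrogate(maps, kc, dt = dt, ...)
      }, error = function(e) {
        message(sprintf("candidate %d skipped: %s", i, conditionMessage(e)))
        NULL
      })
      data.frame(candidate = i, as.data.frame(par),
                 fwhm_x_mm = if (is.null(res)) NA else res$fwhm_mm[1],
                 fwhm_y_mm = if (is.null(res)) NA else res$fwhm_mm[2],
                 fwhm_z_mm = if (is.null(res)) NA else res$fwhm_mm[3],
                 psr = if (is.null(res)) NA else as.numeric(res$psr),
                 duration_ms = if (is.null(res)) NA else res$duration_ms,
                 ok = !is.null(res))
    })
  })
  do.call(rbind, rows)
}

#' Image-domain suppression ratio
#'
#' Compares the mean signal inside a small inner-volume region with the
#' outer-volume signal: the outer region is everything inside the object
#' mask but outside a buffer cube (aliasing-safe margin), optionally eroded
#' by one voxel at the object edge. Both the mean ratio and the ratio to
#' the 99th centile of the outer signal are reported. The measure is
#' invariant to global image scaling.
#'
#' @param image 3D numeric array.
#' @param maps `field_maps` providing geometry and object mask.
#' @param inner_center_mm centre of the inner sampling volume, mm.
#' @param inner_size_mm edge of the cubic inner sampling volume, mm
#'   (default 10 mm, i.e. 1 cm^3).
#' @param buffer_mm edge of the exclusion cube around the excited volume
#'   (default 100 mm).
#' @param erode_edge erode the object mask by one voxel before defining the
#'   outer region.
#' @return List with `mean_ratio`, `p99_ratio` and voxel counts.
#' @export
suppression_ratio <- function(image, maps, inner_center_mm = c(0, 0, 0),
                              inner_size_mm = 10, buffer_mm = 100,
                              erode_edge = TRUE) {
  g <- maps$grid_shape
  pos <- field_positions(maps) * 1000
  ic <- rep_len(inner_center_mm, 3L)
  off <- sweep(pos, 2, ic)
  inner <- apply(abs(off) <= inner_size_mm / 2, 1, all)
  inner <- inner & as.vector(maps$mask)
  if (!any(inner)) { # coarse grids: fall back to the nearest masked voxel
    cand <- which(as.vector(maps$mask))
    inner <- rep(FALSE, nrow(pos))
    inner[cand[which.min(rowSums(off[cand, , drop = FALSE]^2))]] <- TRUE
  }
  buffer <- apply(abs(pos) <= buffer_mm / 2, 1, all)
  obj <- maps$mask
  if (erode_edge) obj <- erode1(obj)
  outer <- as.vector(obj) & !buffer
  if (!any(outer)) stop2("outer region is empty")
  iv <- as.vector(image)
  mo <- mean(iv[outer])
  mi <- mean(iv[inner])
  list(mean_ratio = if (mo == 0) Inf else mi / mo,
       p99_ratio = {
         q <- stats::quantile(iv[outer], 0.99, names = FALSE)
         if (q == 0) Inf else mi / q
       },
       n_inner = sum(inner), n_outer = sum(outer))
}

## One-voxel 6-neighbour erosion of a logical 3D array.
erode1 <- function(mask) {
  d <- dim(mask)
  out <- mask
  shift <- function(a, axis, by) {
    idx <- lapply(d, seq_len)
    idx[[axis]] <- pmin(pmax(idx[[axis]] + by, 1L), d[axis])
    a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  for (axis in 1:3) {
    if (d[axis] == 1L) next
    out <- out & shift(mask, axis, 1L) & shift(mask, axis, -1L)
  }
  out
}
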