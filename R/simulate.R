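# Separable Gaussian blur of a 3-D array; sigma given per axis in voxels.
# Kernel sampled at integer offsets out to 4 sigma and normalized, so total
# intensity is conserved for sources away from the grid edges (zero padding).
.gaussian_blur3d <- function(arr, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(4 * s))
    k <- stats::dnorm(-r:r, sd = s)
    k <- k / sum(k)
    arr <- .conv_axis(arr, k, ax)
  }
  arr
}

# Convolve along axis `ax` with kernel k (odd length), zero padding.
.conv_axis <- function(arr, k, ax) {
  d <- dim(arr)
  perm <- c(ax, setdiff(1:3, ax))
  a <- aperm(arr, perm)
  n <- d[ax]
  m <- matrix(a, nrow = n)
  r <- (length(k) - 1L) / 2L
  # band matrix K[i, j] = k[i - j + r + 1]
  K <- matrix(0, n, n)
  for (off in -r:r) {
    idx <- seq_len(n - abs(off))
    if (off >= 0) K[cbind(idx + off, idx)] <- k[off + r + 1L]
    else K[cbind(idx, idx - off)] <- k[-off + r + 1L]
  }
  out <- K %*% m
  a <- array(out, dim = d[perm])
  aperm(a, order(perm))
}

#' Simulate a reconstructed PET image
#'
#' Applies the combined resolution blur (Gaussian with
#' `FWHM = sqrt(psf_fwhm^2 + positron_blur^2)`) to a true activity
#' concentration map, optionally followed by Poisson count noise (applied in
#' count space at the model's sensitivity, then rescaled back to Bq/mL). The
#' simulation targets the calibrated reconstructed-image level; sinogram
#' physics, attenuation and scatter are out of scope.
#'
#' @param activity_map a Bq/mL [voxel_image] (e.g. from
#'   [rasterize_phantom()]).
#' @param acq an [acquisition_model].
#' @param duration_s frame duration in seconds (Poisson model only).
#' @param seed integer RNG seed (Poisson model only); the output is
#'   reproducible given the seed.
#' @return A Bq/mL [voxel_image] on the same grid.
#' @export
simulate_pet <- function(activity_map, acq = acquisition_model(),
                         duration_s = 2400, seed = 1L) {
  stopifnot(activity_map$units == "Bq_per_mL")
  fwhm <- sqrt(acq$psf_fwhm_mm^2 + acq$positron_blur_mm^2)
  sigma_mm <- fwhm / (2 * sqrt(2 * log(2)))
  out <- activity_map$data
  if (sigma_mm > 0)
    out <- .gaussian_blur3d(out, sigma_mm / activity_map$spacing)
  if (acq$pet_noise == "poisson") {
    vol_mL <- voxel_volume(activity_map, "mL")
    # Bq/mL -> kBq in voxel -> expected counts over the frame
    scale <- vol_mL / 1000 * acq$sensitivity * duration_s
    out <- withr::with_seed(seed, {
      counts <- stats::rpois(length(out), lambda = pmax(out * scale, 0))
      counts / scale
    })
    out <- array(out, dim(activity_map$data))
  }
  voxel_image(out, activity_map$spacing, activity_map$origin, "Bq_per_mL")
}

#' Simulate a contrast-enhanced CT image
#'
#' Maps material labels to a unitless contrast index (air 0.0, water 0.1,
#' contrast agent 1.0) and adds Gaussian noise of standard deviation
#' `acq$ct_noise_sd`. Deterministic given the seed.
#'
#' @param material_map a label [voxel_image] (0 = air, 1 = water,
#'   2 = contrast).
#' @param acq an [acquisition_model].
#' @param seed integer RNG seed.
#' @return A contrast-index [voxel_image] on the CT grid.
#' @export
simulate_ct <- function(material_map, acq = acquisition_model(), seed = 1L) {
  stopifnot(material_map$units == "label")
  levels <- c(0, 0.1, 1.0)                  # air, water, contrast
  out <- array(levels[material_map$data + 1L], dim(material_map$data))
  if (acq$ct_noise_sd > 0) {
    out <- out + withr::with_seed(
      seed, stats::rnorm(length(out), sd = acq$ct_noise_sd))
    out <- array(out, dim(material_map$data))
  }
  voxel_image(out, material_map$spacing, material_map$origin,
              "contrast_index")
}
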