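#' Digital thyroid phantom specification
#'
#' A water-filled cylinder holding pairs of contrast/activity-filled spheres
#' on either side of an air tube that mimics the trachea. The cylinder axis
#' runs along z through (x, y) = (0, 0), base at z = 0. Sphere geometry is
#' defined by the inner diameter; the analytic inner volume `pi/6 * d^3` is
#' treated as ground truth.
#'
#' @param cylinder_diameter_mm cylinder diameter, mm.
#' @param cylinder_height_mm cylinder height, mm.
#' @param spheres data.frame with columns `cx`, `cy`, `cz` (center, mm),
#'   `inner_diameter_mm`, `activity_kBq` (>= 0), `contrast` (logical).
#' @param trachea list with `cx`, `cy` (axis position, mm) and `diameter_mm`;
#'   the air tube spans the full cylinder height. `NULL` for no tube.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(cylinder_diameter_mm = 30,
                         cylinder_height_mm = 80,
                         spheres,
                         trachea = list(cx = 0, cy = 0, diameter_mm = 3)) {
  stopifnot(is.data.frame(spheres),
            all(c("cx", "cy", "cz", "inner_diameter_mm", "activity_kBq",
                  "contrast") %in% names(spheres)))
  if (any(spheres$activity_kBq < 0)) stop("sphere activities must be >= 0")
  if (any(spheres$inner_diameter_mm <= 0)) stop("sphere diameters must be > 0")
  R <- cylinder_diameter_mm / 2
  r <- spheres$inner_diameter_mm / 2
  # every sphere fully inside the cylinder
  rad <- sqrt(spheres$cx^2 + spheres$cy^2)
  if (any(rad + r > R) ||
      any(spheres$cz - r < 0) || any(spheres$cz + r > cylinder_height_mm))
    stop("spheres must lie fully inside the cylinder")
  # no sphere-sphere overlap
  n <- nrow(spheres)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
      d <- sqrt(sum((unlist(spheres[i, c("cx", "cy", "cz")]) -
                     unlist(spheres[j, c("cx", "cy", "cz")]))^2))
      if (d < r[i] + r[j]) stop("spheres overlap")
    }
  }
  # no sphere-trachea overlap
  if (!is.null(trachea)) {
    dt <- sqrt((spheres$cx - trachea$cx)^2 + (spheres$cy - trachea$cy)^2)
    if (any(dt < r + trachea$diameter_mm / 2))
      stop("spheres overlap the trachea tube")
  }
  structure(list(cylinder_diameter_mm = cylinder_diameter_mm,
                 cylinder_height_mm = cylinder_height_mm,
                 spheres = spheres, trachea = trachea),
            class = "phantom_spec")
}

#' Default validation phantom
#'
#' Three same-size pairs of spheres (inner diameters 3.95, 6.23 and 7.86 mm;
#' activities 140, 198 and 1765 kBq per sphere set member) at x = +/-8 mm of
#' the central air tube, one pair per axial level, inside a 30 x 80 mm water
#' cylinder.
#'
#' @return A [phantom_spec].
#' @export
default_phantom_spec <- function() {
  d <- c(3.95, 6.23, 7.86)
  act <- c(140, 198, 1765)
  spheres <- data.frame(
    cx = rep(c(-8, 8), 3),
    cy = 0,
    cz = rep(c(20, 40, 60), each = 2),
    inner_diameter_mm = rep(d, each = 2),
    activity_kBq = rep(act, each = 2),
    contrast = TRUE
  )
  phantom_spec(spheres = spheres)
}

#' Acquisition model for simulated PET and CT
#'
#' Grid geometry, resolution blur and noise settings of the simulated
#' scanners. PET defaults follow a reconstructed small-animal grid of
#' 0.87 x 0.87 x 0.79 mm voxels; CT defaults follow 0.091 mm isotropic
#' voxels. Because the CT grid is very fine, the CT field of view defaults to
#' a tight bounding box around the contrast objects rather than the whole
#' phantom (`ct_fov = NULL`).
#'
#' @param pet_voxel_mm numeric(3) PET voxel size.
#' @param psf_fwhm_mm scanner point-spread FWHM, mm (>= 0).
#' @param positron_blur_mm extra blur FWHM from positron range, mm (>= 0).
#'   Total image blur FWHM is `sqrt(psf^2 + positron^2)`.
#' @param pet_noise `"none"` or `"poisson"`.
#' @param sensitivity counts per kBq.s for the Poisson model.
#' @param ct_voxel_mm numeric(3) CT voxel size.
#' @param ct_noise_sd Gaussian CT noise standard deviation (contrast-index
#'   units).
#' @param ct_fov optional list `(origin, size)` in mm fixing the CT field of
#'   view; `NULL` means a tight box around contrast/air structures.
#' @param supersampling integer >= 1 sub-division factor per axis used when
#'   rasterizing curved boundaries.
#' @param margin_mm margin added around the phantom for the PET grid; wide
#'   enough by default for a lateral background band beside an off-center
#'   20-pixel enclosing region.
#' @return An object of class `acquisition_model`.
#' @export
acquisition_model <- function(pet_voxel_mm = c(0.87, 0.87, 0.79),
                              psf_fwhm_mm = 1.7,
                              positron_blur_mm = 2.0,
                              pet_noise = c("none", "poisson"),
                              sensitivity = 5,
                              ct_voxel_mm = c(0.091, 0.091, 0.091),
                              ct_noise_sd = 0,
                              ct_fov = NULL,
                              supersampling = 4L,
                              margin_mm = 10) {
  pet_noise <- match.arg(pet_noise)
  stopifnot(psf_fwhm_mm >= 0, positron_blur_mm >= 0, supersampling >= 1)
  structure(list(pet_voxel_mm = pet_voxel_mm,
                 psf_fwhm_mm = psf_fwhm_mm,
                 positron_blur_mm = positron_blur_mm,
                 pet_noise = pet_noise,
                 sensitivity = sensitivity,
                 ct_voxel_mm = ct_voxel_mm,
                 ct_noise_sd = ct_noise_sd,
                 ct_fov = ct_fov,
                 supersampling = as.integer(supersampling),
                 margin_mm = margin_mm),
            class = "acquisition_model")
}

# Fractional sphere occupancy of each voxel of a grid.
# Voxels fully inside/outside (center distance vs radius -/+ half-diagonal)
# are decided analytically; boundary-shell voxels are supersampled ss^3.
.sphere_occupancy <- function(xc, yc, zc, center, radius, spacing, ss) {
  dx2 <- (xc - center[1])^2
  dy2 <- (yc - center[2])^2
  dz2 <- (zc - center[3])^2
  d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  hd <- sqrt(sum((spacing / 2)^2))
  occ <- array(0, dim(d2))
  occ[d2 <= (radius - hd)^2] <- 1
  shell <- which(d2 > max(radius - hd, 0)^2 & d2 < (radius + hd)^2)
  if (length(shell)) {
    idx <- arrayInd(shell, dim(d2))
    sx <- xc[idx[, 1]]; sy <- yc[idx[, 2]]; sz <- zc[idx[, 3]]
    off <- (seq_len(ss) - 0.5) / ss - 0.5
    hits <- numeric(length(shell))
    for (ox in off) for (oy in off) for (oz in off) {
      hits <- hits + as.numeric(
        (sx + ox * spacing[1] - center[1])^2 +
        (sy + oy * spacing[2] - center[2])^2 +
        (sz + oz * spacing[3] - center[3])^2 <= radius^2)
    }
    occ[shell] <- hits / ss^3
  }
  occ
}

# Binary center-test mask for an axis-aligned z cylinder.
.cylinder_mask <- function(xc, yc, zc, cx, cy, radius, z0, z1) {
  r2 <- outer((xc - cx)^2, (yc - cy)^2, `+`)
  inplane <- r2 <= radius^2
  inz <- zc >= z0 & zc <= z1
  outer(inplane, inz, `&`)
}

#' Rasterize a phantom onto PET and CT grids
#'
#' Produces the ground-truth activity concentration map on the PET grid
#' (Bq/mL; each sphere's concentration is its activity divided by the
#' analytic inner volume) and a material label map on the CT grid
#' (0 = air, 1 = water, 2 = contrast). Curved boundaries are handled by
#' fractional-occupancy supersampling so that the total activity on the grid
#' matches the sum of sphere activities to well under 0.5% at
#' `supersampling >= 4`.
#'
#' @param spec a [phantom_spec].
#' @param acq an [acquisition_model].
#' @return List with elements `activity_map` (Bq/mL [voxel_image]) and
#'   `material_map` (label [voxel_image]).
#' @export
rasterize_phantom <- function(spec, acq = acquisition_model()) {
  R <- spec$cylinder_diameter_mm / 2
  H <- spec$cylinder_height_mm
  m <- acq$margin_mm
  ss <- acq$supersampling

  ## --- PET activity map -----------------------------------------------
  ext_lo <- c(-R - m, -R - m, -m)
  ext_hi <- c(R + m, R + m, H + m)
  dims <- pmax(1L, ceiling((ext_hi - ext_lo) / acq$pet_voxel_mm))
  origin <- ext_lo
  act <- array(0, dims)
  img0 <- voxel_image(act, acq$pet_voxel_mm, origin, "Bq_per_mL")
  xc <- voxel_centers(img0, 1); yc <- voxel_centers(img0, 2)
  zc <- voxel_centers(img0, 3)
  for (i in seq_len(nrow(spec$spheres))) {
    s <- spec$spheres[i, ]
    if (s$activity_kBq == 0) next
    r <- s$inner_diameter_mm / 2
    vol_uL <- pi / 6 * s$inner_diameter_mm^3        # analytic inner volume
    conc_Bq_mL <- s$activity_kBq / vol_uL * 1e6     # kBq/uL -> Bq/mL
    occ <- .sphere_occupancy(xc, yc, zc, c(s$cx, s$cy, s$cz), r,
                             acq$pet_voxel_mm, ss)
    act <- act + conc_Bq_mL * occ
  }
  activity_map <- voxel_image(act, acq$pet_voxel_mm, origin, "Bq_per_mL")

  ## --- CT material map -------------------------------------------------
  if (is.null(acq$ct_fov)) {
    rr <- spec$spheres$inner_diameter_mm / 2
    lo <- c(min(spec$spheres$cx - rr), min(spec$spheres$cy - rr),
            min(spec$spheres$cz - rr)) - 1.5
    hi <- c(max(spec$spheres$cx + rr), max(spec$spheres$cy + rr),
            max(spec$spheres$cz + rr)) + 1.5
    if (!is.null(spec$trachea)) {
      tr <- spec$trachea$diameter_mm / 2
      lo[1:2] <- pmin(lo[1:2], c(spec$trachea$cx - tr, spec$trachea$cy - tr) - 1.5)
      hi[1:2] <- pmax(hi[1:2], c(spec$trachea$cx + tr, spec$trachea$cy + tr) + 1.5)
    }
  } else {
    lo <- acq$ct_fov$origin
    hi <- lo + acq$ct_fov$size
  }
  cdims <- pmax(1L, ceiling((hi - lo) / acq$ct_voxel_mm))
  mat <- array(0L, cdims)                           # air everywhere
  mimg0 <- voxel_image(mat, acq$ct_voxel_mm, lo, "label")
  cx <- voxel_centers(mimg0, 1); cy <- voxel_centers(mimg0, 2)
  cz <- voxel_centers(mimg0, 3)
  mat[.cylinder_mask(cx, cy, cz, 0, 0, R, 0, H)] <- 1L     # water
  for (i in seq_len(nrow(spec$spheres))) {
    s <- spec$spheres[i, ]
    if (!isTRUE(s$contrast)) next
    occ <- .sphere_occupancy(cx, cy, cz, c(s$cx, s$cy, s$cz),
                             s$inner_diameter_mm / 2, acq$ct_voxel_mm,
                             max(2L, ss %/% 2L))
    mat[occ >= 0.5] <- 2L
  }
  if (!is.null(spec$trachea))
    mat[.cylinder_mask(cx, cy, cz, spec$trachea$cx, spec$trachea$cy,
                       spec$trachea$diameter_mm / 2, 0, H)] <- 0L
  material_map <- voxel_image(mat, acq$ct_voxel_mm, lo, "label")

  list(activity_map = activity_map, material_map = material_map)
}
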