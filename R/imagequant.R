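# Global Otsu threshold over a numeric array (256-bin histogram).
.otsu_threshold <- function(x, nbins = 256L) {
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  br <- seq(r[1], r[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  valid <- w0 > 0 & w0 < 1
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!valid] <- -Inf
  # threshold at the upper edge of the last lower-class bin, so that all
  # values inside that bin stay below it
  br[which.max(between) + 1L]
}

# 3-D connected-component labels (6-connectivity) of a logical array,
# computed on a block-coarsened grid for speed: occupied blocks of
# `block`^3 voxels are labeled by BFS, then every foreground voxel takes
# its block's label. Components closer than ~2 blocks may merge; callers
# work with structures separated by more than that.
.label_components <- function(mask, block = 4L) {
  d <- dim(mask)
  cd <- as.integer(ceiling(d / block))
  padded <- array(FALSE, cd * block)
  padded[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- mask
  occ <- array(padded, dim = c(block, cd[1], block, cd[2], block, cd[3]))
  coarse <- apply(occ, c(2, 4, 6), any)
  lin <- which(coarse)
  if (!length(lin)) return(array(0L, d))
  lab_coarse <- array(0L, cd)
  nb <- rbind(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L),
              c(0L, 1L, 0L), c(0L, 0L, -1L), c(0L, 0L, 1L))
  cur <- 0L
  queue <- matrix(0L, nrow = length(lin), ncol = 3L)
  for (start in lin) {
    if (lab_coarse[start]) next
    cur <- cur + 1L
    qi <- arrayInd(start, cd)
    queue[1L, ] <- qi
    head <- 1L; tail <- 1L
    lab_coarse[start] <- cur
    while (head <= tail) {
      v <- queue[head, ]; head <- head + 1L
      for (k in 1:6) {
        w <- v + nb[k, ]
        if (any(w < 1L) || any(w > cd)) next
        if (coarse[w[1], w[2], w[3]] && lab_coarse[w[1], w[2], w[3]] == 0L) {
          lab_coarse[w[1], w[2], w[3]] <- cur
          tail <- tail + 1L
          queue[tail, ] <- w
        }
      }
    }
  }
  # broadcast block labels back to voxels
  bx <- (seq_len(d[1]) - 1L) %/% block + 1L
  by <- (seq_len(d[2]) - 1L) %/% block + 1L
  bz <- (seq_len(d[3]) - 1L) %/% block + 1L
  full <- lab_coarse[bx, by, bz, drop = FALSE]
  full <- array(full, d)
  full[!mask] <- 0L
  full
}

#' Measure the volume of a voxel mask
#'
#' Exact arithmetic: voxel count times voxel volume; 1 mm^3 = 1 uL.
#'
#' @param mask logical (or 0/1) array.
#' @param spacing_mm numeric(3) voxel spacing, mm (> 0).
#' @return Volume in uL.
#' @export
measure_volume <- function(mask, spacing_mm) {
  if (any(spacing_mm <= 0)) stop("'spacing_mm' must be positive")
  sum(mask != 0) * prod(spacing_mm)
}

#' Segment the thyroid (contrast-filled structure) on CT
#'
#' Thresholds the contrast-index image (global Otsu by default, or a fixed
#' value), removes connected components smaller than
#' `min_component_voxels`, and keeps up to the two largest remaining
#' components (the two lobes). The air tube falls below any sensible
#' threshold by construction.
#'
#' @param ct a contrast-index [voxel_image].
#' @param policy `"otsu"` or a single numeric fixed threshold.
#' @param min_component_voxels components with fewer voxels are discarded.
#' @return List of class `segmentation_result` with `mask` (logical array on
#'   the CT grid), `volume_uL`, `n_components`, `threshold`, `empty` flag,
#'   and `component_labels` (integer array; 0 outside).
#' @export
segment_thyroid_ct <- function(ct, policy = "otsu",
                               min_component_voxels = 200L) {
  stopifnot(ct$units == "contrast_index")
  thr <- if (identical(policy, "otsu")) .otsu_threshold(ct$data)
         else if (is.numeric(policy) && length(policy) == 1L) policy
         else stop("'policy' must be \"otsu\" or a single numeric threshold")
  mask <- ct$data > thr
  if (!any(mask)) {
    return(structure(list(mask = mask, volume_uL = 0, n_components = 0L,
                          threshold = thr, empty = TRUE,
                          component_labels = array(0L, dim(ct$data))),
                     class = "segmentation_result"))
  }
  labels <- .label_components(mask)
  sizes <- tabulate(labels[labels > 0L])
  keep <- which(sizes >= min_component_voxels)
  if (length(keep) > 2L) keep <- keep[order(sizes[keep], decreasing = TRUE)][1:2]
  mask <- array(labels %in% keep, dim(ct$data))
  labels[!mask] <- 0L
  structure(list(mask = mask,
                 volume_uL = measure_volume(mask, ct$spacing),
                 n_components = length(keep),
                 threshold = thr,
                 empty = !any(mask),
                 component_labels = labels),
            class = "segmentation_result")
}

#' Map a CT-grid mask to the PET grid
#'
#' A PET voxel belongs to the output mask iff the majority of its footprint
#' (supersampled `ss`^3) maps inside the CT mask under the given rigid
#' transform (PET point -> CT point). Identity by default, appropriate for
#' synthetic data simulated in a common frame.
#'
#' @param mask logical array on the CT grid.
#' @param ct the CT [voxel_image] that carries the mask's geometry.
#' @param pet the target PET [voxel_image].
#' @param transform list with rotation `R` (3x3, `|det| = 1`) and
#'   translation `t` (mm), or `NULL` for identity.
#' @param ss supersampling factor per axis.
#' @return Logical array on the PET grid.
#' @export
map_roi_to_pet <- function(mask, ct, pet, transform = NULL, ss = 4L) {
  if (is.null(transform)) transform <- list(R = diag(3), t = c(0, 0, 0))
  if (abs(abs(det(transform$R)) - 1) > 1e-6)
    stop("degenerate transform: |det(R)| must be 1")
  out <- array(FALSE, dim(pet$data))
  if (!any(mask)) return(out)
  ct_idx <- which(mask)
  ct_dim <- dim(ct$data)
  # CT-space bounding box of the mask, mapped back to PET index ranges
  idx3 <- arrayInd(ct_idx, ct_dim)
  lo_ct <- ct$origin + (apply(idx3, 2, min) - 1) * ct$spacing
  hi_ct <- ct$origin + apply(idx3, 2, max) * ct$spacing
  Rinv <- solve(transform$R)
  corners <- as.matrix(expand.grid(c(lo_ct[1], hi_ct[1]),
                                   c(lo_ct[2], hi_ct[2]),
                                   c(lo_ct[3], hi_ct[3])))
  pet_pts <- t(Rinv %*% (t(corners) - transform$t))
  lo_p <- pmax(1L, floor((apply(pet_pts, 2, min) - pet$origin) /
                           pet$spacing) + 1L - 1L)
  hi_p <- pmin(dim(pet$data), ceiling((apply(pet_pts, 2, max) - pet$origin) /
                                        pet$spacing) + 1L)
  lo_p <- pmax(lo_p, 1L)
  if (any(hi_p < lo_p)) return(out)
  ix <- lo_p[1]:hi_p[1]; iy <- lo_p[2]:hi_p[2]; iz <- lo_p[3]:hi_p[3]
  grid <- as.matrix(expand.grid(ix = ix, iy = iy, iz = iz))
  centers <- t(t(grid - 0.5) * pet$spacing + pet$origin)
  off <- (seq_len(ss) - 0.5) / ss - 0.5
  hits <- numeric(nrow(grid))
  for (ox in off) for (oy in off) for (oz in off) {
    p <- centers + rep(c(ox, oy, oz) * pet$spacing, each = nrow(centers))
    q <- t(transform$R %*% t(p) + transform$t)
    ci <- floor(sweep(q, 2, ct$origin) / rep(ct$spacing, each = nrow(q))) + 1
    ok <- ci[, 1] >= 1 & ci[, 1] <= ct_dim[1] &
          ci[, 2] >= 1 & ci[, 2] <= ct_dim[2] &
          ci[, 3] >= 1 & ci[, 3] <= ct_dim[3]
    inmask <- logical(nrow(q))
    if (any(ok))
      inmask[ok] <- mask[cbind(ci[ok, 1], ci[ok, 2], ci[ok, 3])]
    hits <- hits + inmask
  }
  sel <- hits > ss^3 / 2
  if (any(sel))
    out[grid[sel, , drop = FALSE]] <- TRUE
  out
}

#' Build the X/Y/Z region-of-interest set around a thyroid mask
#'
#' ROI X is a rectangle of fixed width `x_width` pixels (x direction) per
#' coronal (fixed-y) plane, centered on the mask's x extent, whose z height
#' is the mask's z extent plus `margin` on each side and at least
#' `x_width`; it is applied to every plane from `margin` planes before the
#' mask's first plane to `margin` planes after its last, so that counts
#' displaced along y by the finite resolution stay enclosed. ROI Y is a
#' band `y_width` pixels wide placed laterally adjacent to ROI X (separated
#' by `gap`) on the side away from the image x center (away from the
#' trachea), sharing X's z range and planes; ROI Z is the mask itself.
#'
#' @param thyroid_mask_pet logical array on the PET grid.
#' @param pet the PET [voxel_image] (for bounds only).
#' @param x_width ROI X width in pixels.
#' @param y_width ROI Y width in pixels.
#' @param gap pixels between ROI X and ROI Y.
#' @param margin pixels added beyond the mask extent in z and in coronal
#'   planes (y).
#' @return List of class `roi_set` with logical arrays `roi_x`, `roi_y`,
#'   `roi_z` and counts `n_x`, `n_y`, `n_z`.
#' @export
build_roi_set <- function(thyroid_mask_pet, pet, x_width = 20L, y_width = 7L,
                          gap = 1L, margin = 5L) {
  if (!any(thyroid_mask_pet)) stop("thyroid mask is empty")
  d <- dim(thyroid_mask_pet)
  roi_x <- array(FALSE, d); roi_y <- array(FALSE, d)
  idx <- arrayInd(which(thyroid_mask_pet), d)
  xs <- range(idx[, 1]); ys <- range(idx[, 2]); zs <- range(idx[, 3])
  if (diff(xs) + 1L > x_width)
    stop("thyroid wider than ROI X width")
  planes <- max(1L, ys[1] - margin):min(d[2], ys[2] + margin)
  cx <- mean(xs)
  x0 <- as.integer(floor(cx - x_width / 2) + 1L)
  x1 <- x0 + x_width - 1L
  zh <- max(diff(zs) + 1L + 2L * margin, x_width)
  cz <- mean(zs)
  z0 <- as.integer(floor(cz - zh / 2) + 1L)
  z1 <- z0 + zh - 1L
  if (x0 < 1L || x1 > d[1] || z0 < 1L || z1 > d[3])
    stop("ROI X exceeds image bounds")
  # ROI Y on the side of X away from the image x center
  right <- cx >= (d[1] + 1) / 2
  if (right) { y0 <- x1 + gap + 1L; y1 <- y0 + y_width - 1L }
  else       { y1 <- x0 - gap - 1L; y0 <- y1 - y_width + 1L }
  if (y0 < 1L || y1 > d[1]) {             # flip side if out of bounds
    if (right) { y1 <- x0 - gap - 1L; y0 <- y1 - y_width + 1L }
    else       { y0 <- x1 + gap + 1L; y1 <- y0 + y_width - 1L }
  }
  if (y0 < 1L || y1 > d[1])
    stop("ROI Y exceeds image bounds")
  roi_x[x0:x1, planes, z0:z1] <- TRUE
  roi_y[y0:y1, planes, z0:z1] <- TRUE
  roi_z <- thyroid_mask_pet
  if (!all(roi_x[roi_z])) stop("ROI Z not contained in ROI X")
  if (any(roi_x & roi_y)) stop("ROI X and ROI Y overlap")
  structure(list(roi_x = roi_x, roi_y = roi_y, roi_z = roi_z,
                 n_x = sum(roi_x), n_y = sum(roi_y), n_z = sum(roi_z)),
            class = "roi_set")
}

#' Spillover/background-compensated thyroid activity
#'
#' Computes `A_thyr = A_x - A_y / n_y * (n_x - n_z)`: the activity in the
#' enclosing region X minus the mean per-pixel background (estimated from
#' the adjacent region Y) over the pixels of X that lie outside the
#' CT-derived outline Z. This keeps counts displaced outside Z by the finite
#' PET resolution while subtracting ambient background. Activities are sums
#' of voxel value x voxel volume, accumulated in index order, reported in
#' kBq. A negative compensated activity is clamped to zero and flagged.
#'
#' @param pet a Bq/mL [voxel_image].
#' @param rois a [build_roi_set()] result.
#' @return List of class `roi_quant` with `A_x_kBq`, `A_y_kBq`,
#'   `A_thyr_kBq`, `n_x`, `n_y`, `n_z`, `clamped`.
#' @export
quantify_thyroid_activity <- function(pet, rois) {
  stopifnot(pet$units == "Bq_per_mL")
  if (!all(rois$roi_x[rois$roi_z]) || any(rois$roi_x & rois$roi_y) ||
      rois$n_y <= 0 || rois$n_x <= rois$n_z)
    stop("ROI set violates its invariants")
  vml <- voxel_volume(pet, "mL")
  A_x <- sum(pet$data[which(rois$roi_x)]) * vml / 1000   # Bq -> kBq
  A_y <- sum(pet$data[which(rois$roi_y)]) * vml / 1000
  A_thyr <- A_x - A_y / rois$n_y * (rois$n_x - rois$n_z)
  clamped <- A_thyr < 0
  if (clamped) {
    warning("compensated activity was negative; clamped to 0")
    A_thyr <- 0
  }
  structure(list(A_x_kBq = A_x, A_y_kBq = A_y, A_thyr_kBq = A_thyr,
                 n_x = rois$n_x, n_y = rois$n_y, n_z = rois$n_z,
                 clamped = clamped),
            class = "roi_quant")
}
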