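# Shared fixtures: small single-structure phantoms that keep CT grids tiny.

# A phantom holding one sphere (no trachea), for focused rasterization tests.
single_sphere_spec <- function(diameter_mm = 6.23, activity_kBq = 198,
                               center = c(0, 0, 15)) {
  phantom_spec(
    cylinder_diameter_mm = 30, cylinder_height_mm = 30,
    spheres = data.frame(cx = center[1], cy = center[2], cz = center[3],
                         inner_diameter_mm = diameter_mm,
                         activity_kBq = activity_kBq, contrast = TRUE),
    trachea = NULL)
}

# Acquisition with a CT field of view just covering that sphere.
tight_acq <- function(spec, ct_voxel = 0.091, supersampling = 4L, ...) {
  s <- spec$spheres[1, ]
  r <- s$inner_diameter_mm / 2
  acquisition_model(
    ct_voxel_mm = rep(ct_voxel, 3),
    ct_fov = list(origin = c(s$cx, s$cy, s$cz) - r - 1.2,
                  size = rep(2 * r + 2.4, 3)),
    supersampling = supersampling, ...)
}

# Noiseless two-phase physical curve sampled on a schedule.
noiseless_tac <- function(C, k_u, k_b, lambda_p, t) {
  data.frame(t_h = t,
             activity_MBq = C * (1 - exp(-k_u * t)) * exp(-(k_b + lambda_p) * t))
}
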