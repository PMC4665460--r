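#' Pipeline run configuration
#'
#' Bundles the seed, acquisition model and analysis options into a single
#' serializable object so a run is reproducible from (config, seed) alone.
#'
#' @param seed integer master seed; every stochastic stage derives its
#'   stream from it.
#' @param acquisition an [acquisition_model].
#' @param phantom a [phantom_spec] (phantom runs).
#' @param tac_model `"smooth"` or `"piecewise"`.
#' @param lookup `"nearest"` or `"loglog_interp"`.
#' @param segmentation `"otsu"` or a numeric fixed threshold.
#' @param noise_cv TAC measurement noise CV (cohort runs).
#' @param out_dir optional output directory; `NULL` disables file output.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       acquisition = acquisition_model(),
                       phantom = default_phantom_spec(),
                       tac_model = c("smooth", "piecewise"),
                       lookup = c("nearest", "loglog_interp"),
                       segmentation = "otsu",
                       noise_cv = 0,
                       out_dir = NULL) {
  structure(list(seed = as.integer(seed), acquisition = acquisition,
                 phantom = phantom, tac_model = match.arg(tac_model),
                 lookup = match.arg(lookup), segmentation = segmentation,
                 noise_cv = noise_cv, out_dir = out_dir),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Reads the blocks `seed`, `acquisition`, `nuclide`, `tac_model`,
#' `lookup`, `segmentation`, `noise_cv`, `out_dir`; fields omitted from the
#' file keep their defaults. The `nuclide` block is returned alongside the
#' config for stages that need it.
#'
#' @param path YAML file path.
#' @return List with `config` (a [run_config]) and `nuclide`
#'   (a [radionuclide]).
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  acq_args <- y$acquisition %||% list()
  acq <- do.call(acquisition_model, acq_args)
  cfg <- run_config(
    seed = y$seed %||% 1L,
    acquisition = acq,
    tac_model = y$tac_model %||% "smooth",
    lookup = y$lookup %||% "nearest",
    segmentation = y$segmentation %||% "otsu",
    noise_cv = y$noise_cv %||% 0,
    out_dir = y$out_dir)
  list(config = cfg, nuclide = nuclide_from_config(y$nuclide %||% list()))
}

.strip_classes <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), .strip_classes))
  x
}

# Stable hash of a configuration: md5 of its canonical JSON serialization.
config_hash <- function(config) {
  js <- jsonlite::toJSON(.strip_classes(config),
                         auto_unbox = TRUE, digits = 12, null = "null")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(js), f)
  unname(tools::md5sum(f))
}

#' Phantom validation run
#'
#' Simulates the sphere phantom end to end (rasterize, PET blur/noise, CT
#' per sphere pair), then recovers each sphere's activity through the
#' X/Y/Z-ROI compensation and its volume through CT segmentation, and
#' reports truth vs measured with relative errors. Noiseless runs are
#' checked against 2% tolerances on both activity and volume.
#'
#' @param config a [run_config].
#' @return List of class `phantom_validation` with `results` (one row per
#'   sphere: truth and measured activity and volume plus relative errors and
#'   pass flags), `tolerance`, `config_hash`, `seed`.
#' @export
run_phantom_validation <- function(config = run_config()) {
  spec <- config$phantom
  acq <- config$acquisition
  maps <- rasterize_phantom(spec, acq)
  pet <- simulate_pet(maps$activity_map, acq, seed = config$seed)
  rows <- list()
  for (i in seq_len(nrow(spec$spheres))) {
    s <- spec$spheres[i, ]
    r <- s$inner_diameter_mm / 2
    # tight CT field of view around this sphere
    acq_i <- acq
    acq_i$ct_fov <- list(origin = c(s$cx, s$cy, s$cz) - r - 1.5,
                         size = rep(2 * r + 3, 3))
    mm <- rasterize_phantom(
      phantom_spec(spec$cylinder_diameter_mm, spec$cylinder_height_mm,
                   s, trachea = NULL), acq_i)$material_map
    ct <- simulate_ct(mm, acq_i, seed = config$seed + i)
    seg <- segment_thyroid_ct(ct, config$segmentation)
    vol_true <- pi / 6 * s$inner_diameter_mm^3
    mask_pet <- map_roi_to_pet(seg$mask, ct, pet)
    quant <- if (any(mask_pet)) {
      rois <- build_roi_set(mask_pet, pet)
      quantify_thyroid_activity(pet, rois)
    } else list(A_thyr_kBq = 0)
    rows[[i]] <- data.frame(
      sphere = i,
      inner_diameter_mm = s$inner_diameter_mm,
      truth_activity_kBq = s$activity_kBq,
      measured_activity_kBq = quant$A_thyr_kBq,
      truth_volume_uL = vol_true,
      measured_volume_uL = seg$volume_uL
    )
  }
  res <- do.call(rbind, rows)
  res$activity_rel_err <- with(res, ifelse(truth_activity_kBq > 0,
    (measured_activity_kBq - truth_activity_kBq) / truth_activity_kBq, 0))
  res$volume_rel_err <-
    with(res, (measured_volume_uL - truth_volume_uL) / truth_volume_uL)
  tol <- 0.02
  res$activity_pass <- abs(res$activity_rel_err) < tol
  res$volume_pass <- abs(res$volume_rel_err) < tol
  out <- structure(list(results = res, tolerance = tol,
                        config_hash = config_hash(config),
                        seed = config$seed),
                   class = "phantom_validation")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- file.path(config$out_dir, "phantom_validation.csv")
    .write_report_csv(res, p, out$config_hash, config$seed)
  }
  out
}

#' Cohort dosimetry run
#'
#' Generates (or accepts) a subject cohort of time-activity samples, fits
#' each subject's curve, integrates to cumulated activity, selects S-values
#' from the table by CT volume and emits the per-subject dose report,
#' together with decay-corrected fractional-uptake curves.
#'
#' With `a_tilde_override` the kinetics stage is bypassed and the given
#' cumulated activities are used directly ("parity mode", for exercising
#' the dosimetry stage against externally stated values).
#'
#' @param config a [run_config].
#' @param cohort a [default_cohort()]-shaped list, or `NULL` to generate
#'   one from `config$seed` and `config$noise_cv`.
#' @param svalues an [svalue_table].
#' @param a_tilde_override optional data.frame (`subject_id`,
#'   `a_tilde_MBqs`) replacing the fitted cumulated activities.
#' @return List of class `cohort_dosimetry` with `report` (dose report
#'   data.frame), `fits` (per-subject [fit_tac()] objects or `NULL` in
#'   parity mode), `uptake` (fractional-uptake samples), `config_hash`,
#'   `seed`.
#' @export
run_cohort_dosimetry <- function(config = run_config(), cohort = NULL,
                                 svalues = default_svalue_table(),
                                 a_tilde_override = NULL) {
  nuc <- iodine124()
  if (is.null(cohort))
    cohort <- default_cohort(seed = config$seed, noise_cv = config$noise_cv)
  subjects <- cohort$subjects
  fits <- NULL
  uptake <- NULL
  if (is.null(a_tilde_override)) {
    ids <- subjects$subject_id
    fits <- lapply(ids, function(id) {
      tac <- cohort$tacs[cohort$tacs$subject_id == id, ]
      fit_tac(tac, method = config$tac_model, nuclide = nuc)
    })
    names(fits) <- ids
    a_tilde <- data.frame(
      subject_id = ids,
      a_tilde_MBqs = vapply(fits, function(f)
        cumulated_activity(f)$a_tilde_MBqs, numeric(1)))
    uptake <- do.call(rbind, lapply(ids, function(id) {
      tac <- cohort$tacs[cohort$tacs$subject_id == id, ]
      fu <- fractional_uptake(tac, subjects$administered_MBq[
        subjects$subject_id == id], nuc)
      fu$subject_id <- id
      fu
    }))
  } else {
    a_tilde <- a_tilde_override
  }
  mode <- if (config$lookup == "nearest") "nearest" else "loglog_interp"
  report <- build_dose_report(
    subjects[, intersect(c("subject_id", "weight_g", "administered_MBq",
                           "ct_volume_uL"), names(subjects))],
    a_tilde, table = svalues, mode = mode)
  out <- structure(list(report = report, fits = fits, uptake = uptake,
                        config_hash = config_hash(config),
                        seed = config$seed),
                   class = "cohort_dosimetry")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    .write_report_csv(report, file.path(config$out_dir, "dose_report.csv"),
                      out$config_hash, config$seed)
    jsonlite::write_json(
      report, file.path(config$out_dir, "dose_report.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  out
}

# CSV with provenance header comments (config hash + seed).
.write_report_csv <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  writeLines(sprintf("# seed: %d", seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
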