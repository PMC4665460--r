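#' Thyroid self-dose S-value table
#'
#' Pairs of (Monte Carlo thyroid volume, S-value) for thyroid<-thyroid
#' self-dose, with the tissue density used to derive them. Volumes must be
#' positive and unique and the S-value strictly decreasing in volume
#' (self-dose falls as the mass grows).
#'
#' @param mc_volume_uL tabulated volumes, uL.
#' @param s_value_mGy_per_MBqs S-values, mGy/(MBq.s).
#' @param density_g_per_cm3 assumed tissue density.
#' @return An object of class `svalue_table` with a data.frame `entries`
#'   (sorted by volume) and `density`.
#' @export
svalue_table <- function(mc_volume_uL, s_value_mGy_per_MBqs,
                         density_g_per_cm3 = 1.04) {
  stopifnot(length(mc_volume_uL) == length(s_value_mGy_per_MBqs),
            length(mc_volume_uL) > 0)
  if (any(mc_volume_uL <= 0)) stop("volumes must be positive")
  if (anyDuplicated(mc_volume_uL)) stop("volumes must be unique")
  o <- order(mc_volume_uL)
  v <- mc_volume_uL[o]; s <- s_value_mGy_per_MBqs[o]
  if (any(diff(s) >= 0))
    stop("S-values must be strictly decreasing in volume")
  structure(list(entries = data.frame(mc_volume_uL = v,
                                      s_value_mGy_per_MBqs = s),
                 density_g_per_cm3 = density_g_per_cm3),
            class = "svalue_table")
}

#' Packaged rat-thyroid S-value table
#'
#' The tabulated (volume, S-value) pairs used for the seven-rat study
#' (EGS4/MOBY-derived, density 1.04 g/cm^3), deduplicated to the five
#' distinct volumes: 33.2, 43.4, 47.3, 51.3 and 69.8 uL.
#'
#' @return An [svalue_table].
#' @export
default_svalue_table <- function() {
  svalue_table(mc_volume_uL = c(33.2, 43.4, 47.3, 51.3, 69.8),
               s_value_mGy_per_MBqs = c(0.70, 0.57, 0.54, 0.51, 0.40),
               density_g_per_cm3 = 1.04)
}

#' Read an S-value table from CSV
#'
#' Expects columns `mc_volume_uL` and `s_value_mGy_per_MBqs`.
#'
#' @param path CSV path.
#' @param density_g_per_cm3 assumed density.
#' @return An [svalue_table].
#' @export
read_svalue_table <- function(path, density_g_per_cm3 = 1.04) {
  df <- utils::read.csv(path)
  svalue_table(df$mc_volume_uL, df$s_value_mGy_per_MBqs, density_g_per_cm3)
}

#' Select an S-value for a measured thyroid volume
#'
#' `"nearest"` (default) picks the tabulated entry whose volume is closest
#' to the CT-based volume, breaking exact ties toward the smaller volume
#' (the larger, more conservative S-value). `"loglog_interp"` interpolates
#' log S linearly in log V, clamped at the table ends.
#'
#' @param ct_volume_uL measured thyroid volume, uL (> 0).
#' @param table an [svalue_table].
#' @param mode `"nearest"` or `"loglog_interp"`.
#' @return List with `mc_volume_uL` (the matched tabulated volume, NA for
#'   interpolation) and `s_value_mGy_per_MBqs`.
#' @export
lookup_svalue <- function(ct_volume_uL, table = default_svalue_table(),
                          mode = c("nearest", "loglog_interp")) {
  mode <- match.arg(mode)
  if (!is.numeric(ct_volume_uL) || ct_volume_uL <= 0)
    stop("'ct_volume_uL' must be > 0")
  e <- table$entries
  if (mode == "nearest") {
    d <- abs(e$mc_volume_uL - ct_volume_uL)
    i <- which(d == min(d))[1]     # entries sorted ascending: tie -> smaller V
    list(mc_volume_uL = e$mc_volume_uL[i],
         s_value_mGy_per_MBqs = e$s_value_mGy_per_MBqs[i])
  } else {
    v <- min(max(ct_volume_uL, min(e$mc_volume_uL)), max(e$mc_volume_uL))
    ls <- stats::approx(log(e$mc_volume_uL), log(e$s_value_mGy_per_MBqs),
                        xout = log(v))$y
    list(mc_volume_uL = NA_real_, s_value_mGy_per_MBqs = exp(ls))
  }
}

#' Local-deposition S-value estimate
#'
#' Analytic sanity bound assuming the full non-penetrating (electron +
#' positron) energy per decay is absorbed locally in the source volume,
#' ignoring positron escape and photon self-dose:
#' `S = E_np[MeV] * 1.60218e-13 [J/MeV] * 1e6 [decays/MBq.s] / mass[kg]`,
#' returned in mGy/(MBq.s). Tabulated Monte Carlo S-values fall below this
#' estimate because part of the positron energy escapes small volumes.
#'
#' @param volume_uL source volume, uL (> 0).
#' @param density_g_per_cm3 density (> 0).
#' @param nuclide a [radionuclide].
#' @return S-value estimate, mGy/(MBq.s).
#' @export
estimate_svalue_local <- function(volume_uL, density_g_per_cm3 = 1.04,
                                  nuclide = iodine124()) {
  if (any(volume_uL <= 0) || density_g_per_cm3 <= 0)
    stop("volume and density must be > 0")
  mass_kg <- density_g_per_cm3 * volume_uL * 1e-6      # uL -> cm^3 -> kg
  gy_per_decay <- nuclide$mean_np_energy_MeV * 1.60218e-13 / mass_kg
  gy_per_decay * 1e6 * 1000                            # -> mGy/(MBq.s)
}

#' Mean absorbed dose from cumulated activity
#'
#' `D[Gy] = A_tilde[MBq.s] * S[mGy/(MBq.s)] / 1000`.
#'
#' @param a_tilde_MBqs cumulated activity, MBq.s (>= 0).
#' @param s_value_mGy_per_MBqs S-value (>= 0).
#' @return Absorbed dose, Gy.
#' @export
absorbed_dose <- function(a_tilde_MBqs, s_value_mGy_per_MBqs) {
  if (any(a_tilde_MBqs < 0) || any(s_value_mGy_per_MBqs < 0))
    stop("inputs must be non-negative")
  a_tilde_MBqs * s_value_mGy_per_MBqs / 1000
}

#' Dose per unit administered activity
#'
#' `1000 * dose[Gy] / administered[MBq]` in mGy/MBq, optionally rounded to
#' the nearest 100 for report parity with conventional tabulation.
#'
#' @param dose_Gy absorbed dose, Gy.
#' @param administered_MBq administered activity, MBq (> 0).
#' @param rounding `"nearest_100"` or `"none"`.
#' @return mGy/MBq.
#' @export
dose_per_admin <- function(dose_Gy, administered_MBq,
                           rounding = c("nearest_100", "none")) {
  rounding <- match.arg(rounding)
  if (any(administered_MBq <= 0)) stop("'administered_MBq' must be > 0")
  x <- 1000 * dose_Gy / administered_MBq
  if (rounding == "nearest_100") round(x / 100) * 100 else x
}

#' Build a per-subject dose report
#'
#' Joins subject records with their cumulated activities, selects an
#' S-value per subject from the table, and computes absorbed dose and dose
#' per administered activity (raw and rounded).
#'
#' @param subjects data.frame with `subject_id`, `administered_MBq`,
#'   `ct_volume_uL` (and optionally `weight_g`).
#' @param a_tilde data.frame with `subject_id`, `a_tilde_MBqs`.
#' @param table an [svalue_table].
#' @param mode lookup mode, see [lookup_svalue()].
#' @return data.frame with one row per subject: `subject_id`,
#'   `administered_MBq`, `ct_volume_uL`, `mc_volume_uL`,
#'   `s_value_mGy_per_MBqs`, `a_tilde_MBqs`, `dose_Gy`,
#'   `dose_per_admin_mGy_per_MBq` (raw) and
#'   `dose_per_admin_rounded` (nearest 100).
#' @export
build_dose_report <- function(subjects, a_tilde,
                              table = default_svalue_table(),
                              mode = "nearest") {
  missing_ids <- setdiff(subjects$subject_id, a_tilde$subject_id)
  extra_ids <- setdiff(a_tilde$subject_id, subjects$subject_id)
  if (length(missing_ids) || length(extra_ids))
    stop("unmatched subject ids: ",
         paste(c(missing_ids, extra_ids), collapse = ", "))
  df <- merge(subjects, a_tilde, by = "subject_id")
  df <- df[order(df$subject_id), ]
  sel <- lapply(df$ct_volume_uL, lookup_svalue, table = table, mode = mode)
  df$mc_volume_uL <- vapply(sel, `[[`, numeric(1), "mc_volume_uL")
  df$s_value_mGy_per_MBqs <-
    vapply(sel, `[[`, numeric(1), "s_value_mGy_per_MBqs")
  df$dose_Gy <- absorbed_dose(df$a_tilde_MBqs, df$s_value_mGy_per_MBqs)
  df$dose_per_admin_mGy_per_MBq <-
    dose_per_admin(df$dose_Gy, df$administered_MBq, "none")
  df$dose_per_admin_rounded <-
    dose_per_admin(df$dose_Gy, df$administered_MBq, "nearest_100")
  rownames(df) <- NULL
  df
}

#' Reference study dose table
#'
#' Published per-subject absorbed doses and doses per administered activity
#' for the seven-rat reference study, for arithmetic parity checks and the
#' parity pipeline mode.
#'
#' @return data.frame with `subject_id`, `dose_Gy`,
#'   `dose_per_admin_mGy_per_MBq`.
#' @export
rat_study_doses <- function() {
  data.frame(
    subject_id = paste0("Rat", 1:7),
    dose_Gy = c(225.7, 82.6, 115.7, 44.7, 38.0, 39.7, 5.2),
    dose_per_admin_mGy_per_MBq = c(10500, 4500, 5600, 4800, 7000, 7400, 7700)
  )
}
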