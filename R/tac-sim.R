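#' Two-phase kinetic parameters
#'
#' Parameters of the biological (decay-corrected) thyroid uptake curve
#' `B(t) = C * (1 - exp(-k_u * t)) * exp(-k_b * t)`: a saturating uptake
#' phase at rate `k_u` riding on mono-exponential biological clearance at
#' rate `k_b`. The curve is unimodal with its maximum at
#' `t = log(1 + k_u / k_b) / k_u`.
#'
#' @param peak_fraction peak fractional uptake, percent of administered
#'   activity (0 < x < 100).
#' @param k_u uptake rate, 1/h.
#' @param k_b biological clearance rate, 1/h; must satisfy
#'   `k_u > k_b > 0`.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(peak_fraction, k_u, k_b) {
  if (!(k_u > k_b && k_b > 0)) stop("require k_u > k_b > 0")
  if (!(peak_fraction > 0 && peak_fraction < 100))
    stop("'peak_fraction' must be in (0, 100)")
  structure(list(peak_fraction = peak_fraction, k_u = k_u, k_b = k_b),
            class = "kinetic_params")
}

#' Biological peak time of a two-phase curve
#'
#' @param k_u uptake rate, 1/h.
#' @param k_b clearance rate, 1/h (> 0).
#' @return Peak time in hours, `log(1 + k_u/k_b) / k_u`.
#' @export
tac_peak_time <- function(k_u, k_b) log(1 + k_u / k_b) / k_u

#' Simulate a subject time-activity curve
#'
#' The noiseless biological curve is scaled so its maximum equals
#' `peak_fraction/100 * administered_MBq`; the measured (physical) activity
#' at each scheduled time is the biological value times the physical decay
#' factor, with optional multiplicative log-normal noise of coefficient of
#' variation `noise_cv`.
#'
#' @param params a [kinetic_params].
#' @param administered_MBq administered activity, MBq.
#' @param schedule_h increasing, non-negative sampling times, hours.
#' @param nuclide a [radionuclide].
#' @param noise_cv fractional coefficient of variation (>= 0) of the
#'   multiplicative noise; 0 means noiseless.
#' @param seed integer RNG seed; sampling is reproducible given the seed.
#' @return data.frame with columns `t_h`, `activity_MBq` (physical, at
#'   measurement time) and `true_MBq` (noiseless physical value).
#' @export
generate_subject_tac <- function(params, administered_MBq, schedule_h,
                                 nuclide = iodine124(), noise_cv = 0,
                                 seed = 1L) {
  if (length(schedule_h) == 0) stop("'schedule_h' must be non-empty")
  if (is.unsorted(schedule_h, strictly = TRUE) || any(schedule_h < 0))
    stop("'schedule_h' must be increasing and non-negative")
  if (noise_cv < 0) stop("'noise_cv' must be >= 0")
  tp <- tac_peak_time(params$k_u, params$k_b)
  bmax <- (1 - exp(-params$k_u * tp)) * exp(-params$k_b * tp)
  C <- params$peak_fraction / 100 * administered_MBq / bmax
  B <- C * (1 - exp(-params$k_u * schedule_h)) * exp(-params$k_b * schedule_h)
  A <- B * decay_factor(schedule_h, nuclide)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    mult <- withr::with_seed(
      seed, stats::rlnorm(length(A), meanlog = -sdlog^2 / 2, sdlog = sdlog))
    obs <- A * mult
  } else obs <- A
  data.frame(t_h = schedule_h, activity_MBq = obs, true_MBq = A)
}

#' Reference study subjects
#'
#' The seven-rat study roster: body weights, administered I-124 activities
#' and CT-measured thyroid volumes.
#'
#' @return data.frame with columns `subject_id`, `weight_g`,
#'   `administered_MBq`, `ct_volume_uL`.
#' @export
rat_study_subjects <- function() {
  data.frame(
    subject_id = paste0("Rat", 1:7),
    weight_g = c(360, 372, 354, 394, 389, 533, 501),
    administered_MBq = c(21.50, 18.20, 20.70, 9.30, 5.50, 5.40, 0.70),
    ct_volume_uL = c(49.3, 41.9, 47.8, 70.6, 45.8, 34.3, 51.6)
  )
}

#' Generate the default synthetic cohort
#'
#' Seven subjects with the reference-study weights and administered
#' activities, each given per-subject kinetics drawn as: peak fractional
#' uptake uniform in 4.0-6.2%, uptake rate `k_u` uniform in 0.10-0.20 /h,
#' biological peak time uniform in 22-26 h with `k_b` solved accordingly
#' (`k_b = k_u / (exp(k_u * t_peak) - 1)`). Activities are sampled at
#' 3, 24, 48 and 72 h post injection.
#'
#' @param seed integer RNG seed.
#' @param noise_cv measurement noise CV passed to [generate_subject_tac()].
#' @param schedule_h sampling schedule, hours.
#' @param nuclide a [radionuclide].
#' @return List with `subjects` (data.frame: roster plus the drawn
#'   `peak_fraction`, `k_u`, `k_b`) and `tacs` (data.frame: `subject_id`,
#'   `t_h`, `activity_MBq`, `true_MBq`, `administered_MBq`).
#' @export
default_cohort <- function(seed = 1L, noise_cv = 0,
                           schedule_h = c(3, 24, 48, 72),
                           nuclide = iodine124()) {
  subjects <- rat_study_subjects()
  n <- nrow(subjects)
  draws <- withr::with_seed(seed, {
    list(pf = stats::runif(n, 4.0, 6.2),
         ku = stats::runif(n, 0.10, 0.20),
         tp = stats::runif(n, 22, 26),
         sub_seeds = sample.int(.Machine$integer.max, n))
  })
  kb <- draws$ku / (exp(draws$ku * draws$tp) - 1)
  subjects$peak_fraction <- draws$pf
  subjects$k_u <- draws$ku
  subjects$k_b <- kb
  tacs <- do.call(rbind, lapply(seq_len(n), function(i) {
    tac <- generate_subject_tac(
      kinetic_params(draws$pf[i], draws$ku[i], kb[i]),
      subjects$administered_MBq[i], schedule_h, nuclide,
      noise_cv = noise_cv, seed = draws$sub_seeds[i])
    tac$subject_id <- subjects$subject_id[i]
    tac$administered_MBq <- subjects$administered_MBq[i]
    tac
  }))
  list(subjects = subjects, tacs = tacs)
}

#' Write / read a cohort TAC table as CSV
#'
#' @param cohort the list returned by [default_cohort()].
#' @param path CSV file path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns a data.frame of TAC samples with subject metadata columns.
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- merge(cohort$tacs,
              cohort$subjects[, c("subject_id", "weight_g", "ct_volume_uL")],
              by = "subject_id")
  df <- df[order(df$subject_id, df$t_h), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
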