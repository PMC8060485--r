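# Seeded synthetic cohorts: per-patient vessel TACs plus clinical covariates
# with the statistical structure the analysis assumes, and ground truth for
# recovery tests. Defaults emulate a two-group cohort (36 symptomatic, 22
# asymptomatic) with group-specific affected-side venous delays, per-vein
# absence probabilities, and probabilistic links from early-to-peak delay to
# collateral status and from ipsilateral CVF- count to 3-month outcome.

vein_names <- c("SMCV", "VOT", "VOL")

#' Configuration of a synthetic dynamic-CTA cohort
#'
#' All knobs of the generator in one validated object. Defaults target the
#' cohort-level anchors of the study population this package models: group
#' sizes 36/22; onset-delay medians 2.0 s (symptomatic) and 1.8 s
#' (asymptomatic); early-to-peak widening medians 1.9 s and 0.1 s (drawn from
#' shifted log-normals so that negative values occur); per-vein absence
#' probabilities that imply ipsilateral CVF- proportions of about 53% and
#' 18%; and link probabilities that associate fast early-to-peak filling with
#' poor collaterals and a higher ipsilateral CVF- count with poor 3-month
#' outcome.
#'
#' @param n_symptomatic,n_asymptomatic Group sizes.
#' @param n_volumes,grid_spacing,grid_start Acquisition grid specification
#'   (see [acquisition_grid()]).
#' @param arterial_t0_mean,arterial_t0_sd Normal parameters of the arterial
#'   bolus-arrival time (s).
#' @param arterial_alpha,arterial_beta Gamma-variate shape/time-scale of the
#'   arterial curves.
#' @param arterial_peak_enh Range (HU) of arterial peak enhancement.
#' @param venous_delay Arterial-to-venous transit time tau_v (s).
#' @param venous_alpha,venous_beta Gamma-variate shape/time-scale of the
#'   venous curves.
#' @param vein_peak_enh,sss_peak_enh Ranges (HU) of cortical-vein and
#'   superior-sagittal-sinus peak enhancement.
#' @param vein_t0_jitter_sd Per-vein anatomical jitter (s) applied to both
#'   hemispheres of the same vein.
#' @param baseline_range Range (HU) of pre-contrast attenuation.
#' @param onset_delay Per-group log-normal parameters (`meanlog`, `sdlog`) of
#'   the affected-side onset delay delta1 (s, >= 0).
#' @param peak_widening Per-group shifted log-normal parameters (`shift`,
#'   `meanlog`, `sdlog`) of the additional early-to-peak widening delta21
#'   (s, may be negative).
#' @param absence_prob Per-group, per-hemisphere named probabilities of each
#'   vein being absent (CVF-).
#' @param noise_sd Measurement noise (HU).
#' @param visibility_threshold Enhancement threshold (HU) used downstream.
#' @param fast_delta21_cutoff Injected delta21 at or below which a patient
#'   counts as truly fast (s).
#' @param collateral_poor_prob Named probabilities `c(fast=, slow=)` of poor
#'   collateral status for symptomatic patients.
#' @param collateral_poor_prob_asymptomatic Flat probability of poor
#'   collaterals in the asymptomatic group.
#' @param antegrade_preserved_prob Per-group probability of preserved
#'   antegrade flow.
#' @param outcome_poor_prob Probability of poor 3-month outcome (mRS > 2)
#'   given the true ipsilateral CVF- count 0..3.
#' @param nihss_base,nihss_lambda NIHSS at admission is
#'   `nihss_base + Poisson(lambda)` with outcome-specific lambda.
#' @param seed Integer seed; all randomness flows from it.
#' @return An object of class `"cohort_config"`.
#' @export
cohort_config <- function(
  n_symptomatic = 36,
  n_asymptomatic = 22,
  n_volumes = 19,
  grid_spacing = 2,
  grid_start = 8,
  arterial_t0_mean = 7,
  arterial_t0_sd = 1,
  arterial_alpha = 3,
  arterial_beta = 1.5,
  arterial_peak_enh = c(250, 350),
  venous_delay = 4,
  venous_alpha = 3,
  venous_beta = 2.5,
  vein_peak_enh = c(150, 300),
  sss_peak_enh = c(350, 450),
  vein_t0_jitter_sd = 0.3,
  baseline_range = c(35, 45),
  onset_delay = list(
    symptomatic = list(meanlog = log(2.0), sdlog = 0.5),
    asymptomatic = list(meanlog = log(1.8), sdlog = 0.5)
  ),
  peak_widening = list(
    symptomatic = list(shift = -2.0, meanlog = log(3.9), sdlog = 0.6),
    asymptomatic = list(shift = -0.4, meanlog = log(0.5), sdlog = 0.5)
  ),
  absence_prob = list(
    symptomatic = list(
      affected = c(SMCV = 0.19, VOT = 0.25, VOL = 0.28),
      contralateral = c(SMCV = 0, VOT = 0, VOL = 0.06)
    ),
    asymptomatic = list(
      affected = c(SMCV = 0.05, VOT = 0.09, VOL = 0.05),
      contralateral = c(SMCV = 0.05, VOT = 0, VOL = 0.18)
    )
  ),
  noise_sd = 5,
  visibility_threshold = 50,
  fast_delta21_cutoff = 1.9,
  collateral_poor_prob = c(fast = 0.58, slow = 0.18),
  collateral_poor_prob_asymptomatic = 0.23,
  antegrade_preserved_prob = c(symptomatic = 0.42, asymptomatic = 0.45),
  outcome_poor_prob = c(`0` = 0.12, `1` = 0.25, `2` = 0.86, `3` = 0.86),
  nihss_base = 2,
  nihss_lambda = c(good = 1.5, poor = 3.5),
  seed = 42
) {
  cfg <- as.list(environment())
  probs <- c(
    unlist(cfg$absence_prob, use.names = FALSE),
    cfg$collateral_poor_prob, cfg$collateral_poor_prob_asymptomatic,
    cfg$antegrade_preserved_prob, cfg$outcome_poor_prob
  )
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$n_symptomatic < 0 || cfg$n_asymptomatic < 0) {
    stop("group sizes must be non-negative")
  }
  if (cfg$noise_sd < 0) stop("'noise_sd' must be non-negative")
  if (cfg$venous_delay <= 0) stop("'venous_delay' must be positive")
  for (g in c("symptomatic", "asymptomatic")) {
    if (is.null(cfg$onset_delay[[g]]) || is.null(cfg$peak_widening[[g]]) ||
        is.null(cfg$absence_prob[[g]])) {
      stop("per-group settings must cover 'symptomatic' and 'asymptomatic'")
    }
    if (!all(vein_names %in% names(cfg$absence_prob[[g]]$affected)) ||
        !all(vein_names %in% names(cfg$absence_prob[[g]]$contralateral))) {
      stop("absence probabilities must name SMCV, VOT and VOL per hemisphere")
    }
  }
  if (is.null(cfg$seed) || !is.finite(cfg$seed)) stop("'seed' is mandatory")
  # acquisition_grid() validates the grid spec
  acquisition_grid(cfg$n_volumes, cfg$grid_spacing, cfg$grid_start)
  structure(cfg, class = "cohort_config")
}

#' Read a cohort configuration from a YAML file
#'
#' Fields not present in the file keep their [cohort_config()] defaults; the
#' seed is mandatory (in the file or via `seed`).
#'
#' @param path Path to a YAML file of [cohort_config()] fields.
#' @param seed Optional seed overriding the file.
#' @return A `"cohort_config"` object.
#' @export
read_cohort_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(seed)) raw$seed <- seed
  do.call(cohort_config, raw)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config> %d symptomatic + %d asymptomatic, %d volumes @ %.1f s, noise %.1f HU, seed %s\n",
    x$n_symptomatic, x$n_asymptomatic, x$n_volumes, x$grid_spacing,
    x$noise_sd, format(x$seed)
  ))
  invisible(x)
}

runif_range <- function(r) stats::runif(1, r[1], r[2])

# Scaled visibility crossing of a peak-normalized gamma-variate: the first
# time enhancement reaches `ratio` (threshold / peak amplitude) is beta * u
# with u the root of (u/alpha)^alpha * exp(alpha - u) = ratio on (0, alpha).
# Both the analytic onset (t0 + beta*u) and the early-to-peak interval
# (beta*(alpha - u)) are linear in beta, which lets the generator inject the
# observable delays exactly (see generate_patient).
crossing_scale <- function(alpha, ratio) {
  if (ratio <= 0 || ratio >= 1) stop("'ratio' must be in (0, 1)")
  stats::uniroot(function(u) (u / alpha)^alpha * exp(alpha - u) - ratio,
                 c(1e-9, alpha * (1 - 1e-9)), tol = 1e-10)$root
}

noise_tac <- function(times, baseline, noise_sd) {
  vals <- rep(baseline, length(times))
  if (noise_sd > 0) vals <- vals + stats::rnorm(length(times), 0, noise_sd)
  tac(times, vals, baseline = baseline)
}

#' Generate one synthetic patient
#'
#' Draws one patient's vessel TACs, clinical record and ground truth from the
#' current RNG state (call inside a seeded context; [generate_cohort()] does
#' this). Contralateral veins are gamma-variate curves with venous arrival
#' `arterial t0 + venous_delay`; affected veins are delayed and widened so
#' that, analytically, their visibility onset comes delta1 later and their
#' early-to-peak interval is delta21 wider than the contralateral vein's
#' (the injected delays live on the same observable scale as the scored
#' rCVF1/rCVF21); each vein is independently absent (pure-noise curve) with
#' its group/side-specific probability.
#'
#' @param config A [cohort_config()].
#' @param group `"symptomatic"` or `"asymptomatic"`.
#' @param id Patient identifier.
#' @return List with `tacs` (long data frame), `clinical` (one-row data
#'   frame) and `truth` (one-row data frame).
#' @export
generate_patient <- function(config, group = c("symptomatic", "asymptomatic"),
                             id = "P001") {
  stopifnot(inherits(config, "cohort_config"))
  group <- match.arg(group)
  times <- acquisition_grid(config$n_volumes, config$grid_spacing,
                            config$grid_start)
  baseline <- runif_range(config$baseline_range)
  t0_a <- max(2, stats::rnorm(1, config$arterial_t0_mean,
                              config$arterial_t0_sd))

  # affected-side delays: delta1 delays the visibility onset, delta21 widens
  # the early-to-peak interval (both on the observable scale)
  od <- config$onset_delay[[group]]
  delta1 <- min(8, stats::rlnorm(1, od$meanlog, od$sdlog))
  pw <- config$peak_widening[[group]]
  delta21 <- pw$shift + stats::rlnorm(1, pw$meanlog, pw$sdlog)

  # antegrade flow: label first, then a ratio consistent with it
  preserved <- stats::runif(1) < config$antegrade_preserved_prob[[group]]
  filling_ratio <- if (preserved) {
    stats::runif(1, 2 / 3 + 0.01, 1)
  } else {
    stats::runif(1, 0.2, 2 / 3)
  }

  # vessel TACs -----------------------------------------------------------
  rows <- list()
  add_tac <- function(structure_name, hemisphere, tc) {
    rows[[length(rows) + 1L]] <<- data.frame(
      patient_id = id, group = group, hemisphere = hemisphere,
      structure = structure_name, time_s = tc$times,
      attenuation_hu = tc$values
    )
  }
  amp_mca <- runif_range(config$arterial_peak_enh)
  mca_con <- sample_tac(
    gv_from_peak(t0_a, config$arterial_alpha, config$arterial_beta,
                 amp_mca, baseline),
    times, config$noise_sd
  )
  mca_aff <- sample_tac(
    gv_from_peak(t0_a, config$arterial_alpha, config$arterial_beta,
                 amp_mca * max(0.3, filling_ratio), baseline),
    times, config$noise_sd
  )
  add_tac("MCA", "affected", mca_aff)
  add_tac("MCA", "contralateral", mca_con)

  t0_v <- t0_a + config$venous_delay
  sss <- sample_tac(
    gv_from_peak(t0_v, config$venous_alpha, config$venous_beta,
                 runif_range(config$sss_peak_enh), baseline),
    times, config$noise_sd
  )
  add_tac("SSS", "affected", sss)

  ap <- config$absence_prob[[group]]
  absent <- list(
    affected = stats::runif(3) < ap$affected[vein_names],
    contralateral = stats::runif(3) < ap$contralateral[vein_names]
  )
  for (side in c("affected", "contralateral")) {
    names(absent[[side]]) <- vein_names
  }
  for (j in seq_along(vein_names)) {
    vjit <- stats::rnorm(1, 0, config$vein_t0_jitter_sd)
    amp <- runif_range(config$vein_peak_enh)
    # calibrate the affected curve so that, analytically, its visibility
    # crossing sits delta1 after the contralateral crossing and its
    # early-to-peak interval is delta21 wider: with u the crossing scale,
    # onset = t0 + beta*u and interval = beta*(alpha - u), both linear in
    # beta, so widen beta by delta21/(alpha - u) and pull t0 back by the
    # induced crossing shift
    u <- crossing_scale(config$venous_alpha,
                        config$visibility_threshold / amp)
    beta_aff <- max(0.3,
                    config$venous_beta + delta21 / (config$venous_alpha - u))
    t0_aff <- t0_v + vjit + delta1 - (beta_aff - config$venous_beta) * u
    for (side in c("affected", "contralateral")) {
      tc <- if (absent[[side]][j]) {
        noise_tac(times, baseline, config$noise_sd)
      } else if (side == "affected") {
        sample_tac(
          gv_from_peak(t0_aff, config$venous_alpha, beta_aff, amp, baseline),
          times, config$noise_sd
        )
      } else {
        sample_tac(
          gv_from_peak(t0_v + vjit, config$venous_alpha, config$venous_beta,
                       amp, baseline),
          times, config$noise_sd
        )
      }
      add_tac(vein_names[j], side, tc)
    }
  }

  # clinical covariates ----------------------------------------------------
  sym <- group == "symptomatic"
  fast_true <- delta21 <= config$fast_delta21_cutoff
  p_poor_coll <- if (sym) {
    config$collateral_poor_prob[[if (fast_true) "fast" else "slow"]]
  } else {
    config$collateral_poor_prob_asymptomatic
  }
  collateral_status <- if (stats::runif(1) < p_poor_coll) "poor" else "good"
  if (collateral_status == "good") {
    grade_v <- "complete"
    grade_a <- sample(c("peripheral", "complete"), 1)
  } else {
    grade_a <- sample(c("none", "peripheral"), 1)
    grade_v <- sample(c("none", "peripheral"), 1)
  }

  n_ips_true <- sum(absent$affected & !absent$contralateral)
  if (sym) {
    p_poor_out <- config$outcome_poor_prob[[as.character(min(n_ips_true, 3))]]
    outcome <- if (stats::runif(1) < p_poor_out) "poor" else "good"
    mrs <- if (outcome == "poor") {
      sample(3:6, 1, prob = c(0.5, 0.3, 0.15, 0.05))
    } else {
      sample(0:2, 1, prob = c(0.3, 0.4, 0.3))
    }
    nihss <- config$nihss_base + stats::rpois(1, config$nihss_lambda[[outcome]])
    angioplasty <- stats::runif(1) < 0.11
  } else {
    outcome <- NA_character_
    mrs <- NA_integer_
    nihss <- NA_integer_
    angioplasty <- FALSE
  }

  clinical <- data.frame(
    patient_id = id, group = group,
    age = round(stats::rnorm(1, if (sym) 58.3 else 61.3,
                             if (sym) 9.2 else 11.0)),
    sex = sample(c("female", "male"), 1,
                 prob = if (sym) c(0.25, 0.75) else c(0.27, 0.73)),
    hypertension = stats::runif(1) < (if (sym) 0.44 else 0.55),
    diabetes = stats::runif(1) < (if (sym) 0.33 else 0.32),
    smoking = stats::runif(1) < (if (sym) 0.64 else 0.46),
    drinking = stats::runif(1) < (if (sym) 0.25 else 0.36),
    lipid_disorder = stats::runif(1) < (if (sym) 0.72 else 0.71),
    stenosis_class = sample(c("70-99%", "occlusion"), 1,
                            prob = if (sym) c(0.67, 0.33) else c(0.59, 0.41)),
    nihss = nihss, mrs_3mo = mrs, angioplasty = angioplasty,
    antegrade_filling_ratio = filling_ratio,
    antegrade_label = classify_antegrade(filling_ratio),
    collateral_grade_atac = grade_a,
    collateral_grade_vtac = grade_v,
    collateral_status = classify_collateral(grade_a, grade_v)
  )

  truth <- data.frame(
    patient_id = id, group = group,
    delta1 = delta1, delta21 = delta21, fast_true = fast_true,
    absent_smcv_aff = absent$affected["SMCV"],
    absent_vot_aff = absent$affected["VOT"],
    absent_vol_aff = absent$affected["VOL"],
    absent_smcv_contra = absent$contralateral["SMCV"],
    absent_vot_contra = absent$contralateral["VOT"],
    absent_vol_contra = absent$contralateral["VOL"],
    n_ipsilateral_true = n_ips_true,
    collateral_status = collateral_status,
    outcome = outcome,
    row.names = NULL
  )

  list(tacs = do.call(rbind, rows), clinical = clinical, truth = truth)
}

#' Generate a seeded synthetic cohort
#'
#' Draws `n_symptomatic + n_asymptomatic` patients from the configuration.
#' The same configuration (including its seed) always reproduces the
#' identical cohort.
#'
#' @param config A [cohort_config()].
#' @return An object of class `"cvf_cohort"`: list with `tacs` (long TAC data
#'   frame), `clinical`, `truth` and the `config`.
#' @seealso [write_cohort()] to persist the CSV/manifest bundle,
#'   [score_cohort()] to score it, [recovery_report()] to compare scores with
#'   ground truth.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_symptomatic + config$n_asymptomatic
  groups <- rep(c("symptomatic", "asymptomatic"),
                c(config$n_symptomatic, config$n_asymptomatic))
  ids <- sprintf("P%03d", seq_len(n))
  pts <- mapply(function(g, id) generate_patient(config, g, id),
                groups, ids, SIMPLIFY = FALSE)
  out <- list(
    tacs = do.call(rbind, c(lapply(pts, `[[`, "tacs"),
                            list(make.row.names = FALSE))),
    clinical = do.call(rbind, c(lapply(pts, `[[`, "clinical"),
                                list(make.row.names = FALSE))),
    truth = do.call(rbind, c(lapply(pts, `[[`, "truth"),
                             list(make.row.names = FALSE))),
    config = config
  )
  class(out) <- "cvf_cohort"
  out
}

#' @export
print.cvf_cohort <- function(x, ...) {
  cat(sprintf(
    "<cvf_cohort> %d patients (%d symptomatic, %d asymptomatic), %d TAC rows, seed %s\n",
    nrow(x$clinical), sum(x$clinical$group == "symptomatic"),
    sum(x$clinical$group == "asymptomatic"), nrow(x$tacs),
    format(x$config$seed)
  ))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits `tacs.csv`, `clinical.csv`, `ground_truth.csv` and `manifest.json`
#' (config echo, seed, file list) into `dir`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cvf_cohort"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create output directory: ", dir)
  }
  files <- c(
    tacs = file.path(dir, "tacs.csv"),
    clinical = file.path(dir, "clinical.csv"),
    ground_truth = file.path(dir, "ground_truth.csv"),
    manifest = file.path(dir, "manifest.json")
  )
  utils::write.csv(cohort$tacs, files["tacs"], row.names = FALSE)
  utils::write.csv(cohort$clinical, files["clinical"], row.names = FALSE)
  utils::write.csv(cohort$truth, files["ground_truth"], row.names = FALSE)
  manifest <- list(
    seed = cohort$config$seed,
    config = unclass(cohort$config),
    files = as.list(files[1:3])
  )
  jsonlite::write_json(manifest, files["manifest"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(files)
}

#' Recovery of injected parameters from scored results
#'
#' Compares scored per-patient quantities with the generator's ground truth:
#' bias and RMSE of the recovered onset delay (rCVF1 vs delta1) and
#' early-to-peak widening (rCVF21 vs delta21), and confusion matrices of
#' vein presence and, when `clinical` is supplied, of collateral status and
#' outcome class.
#'
#' @param truth Ground-truth data frame from [generate_cohort()].
#' @param scores Scores data frame from [score_cohort()].
#' @param clinical Optional clinical data frame for the class confusions.
#' @return An object of class `"recovery_report"`.
#' @export
recovery_report <- function(truth, scores, clinical = NULL) {
  if (!setequal(truth$patient_id, scores$patient_id)) {
    stop("patient ids of ground truth and scores do not match")
  }
  m <- merge(truth, scores, by = "patient_id", suffixes = c(".true", ""))
  err_stats <- function(err) {
    err <- err[!is.na(err)]
    c(bias = mean(err), rmse = sqrt(mean(err^2)), n = length(err))
  }
  pres_truth <- !as.matrix(m[, c(
    "absent_smcv_aff", "absent_vot_aff", "absent_vol_aff",
    "absent_smcv_contra", "absent_vot_contra", "absent_vol_contra"
  )])
  pres_scored <- as.matrix(m[, c(
    "smcv_aff", "vot_aff", "vol_aff",
    "smcv_contra", "vot_contra", "vol_contra"
  )]) == "present"
  presence_confusion <- table(
    truth = ifelse(pres_truth, "present", "absent"),
    scored = ifelse(pres_scored, "present", "absent")
  )
  out <- list(
    delta1 = err_stats(m$rcvf1 - m$delta1),
    delta21 = err_stats(m$rcvf21 - m$delta21),
    presence_confusion = presence_confusion,
    presence_misclassification_rate =
      mean(pres_truth != pres_scored, na.rm = TRUE)
  )
  if (!is.null(clinical)) {
    mc <- merge(truth, clinical, by = "patient_id", suffixes = c(".true", ""))
    out$collateral_confusion <- table(truth = mc$collateral_status.true,
                                      derived = mc$collateral_status)
    sym <- mc[!is.na(mc$mrs_3mo), ]
    if (nrow(sym)) {
      out$outcome_confusion <- table(
        truth = sym$outcome,
        derived = ifelse(sym$mrs_3mo > 2, "poor", "good")
      )
    }
  }
  class(out) <- "recovery_report"
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  cat(sprintf("  onset delay:   bias %+.3f s, RMSE %.3f s (n = %d)\n",
              x$delta1["bias"], x$delta1["rmse"], x$delta1["n"]))
  cat(sprintf("  peak widening: bias %+.3f s, RMSE %.3f s (n = %d)\n",
              x$delta21["bias"], x$delta21["rmse"], x$delta21["n"]))
  cat(sprintf("  presence misclassification rate: %.4f\n",
              x$presence_misclassification_rate))
  print(x$presence_confusion)
  invisible(x)
}
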