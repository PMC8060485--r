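# Per-patient and per-cohort scoring: phase selection, presence, hemispheric
# CVF times, relative scores, and the ipsilateral CVF- count, from a
# long-format TAC table.

tac_from_rows <- function(df, structure_name, hemisphere) {
  rows <- df[df$structure == structure_name & df$hemisphere == hemisphere, ,
             drop = FALSE]
  if (nrow(rows) == 0L) return(NULL)
  rows <- rows[order(rows$time_s), , drop = FALSE]
  tac(rows$time_s, rows$attenuation_hu)
}

#' Score one patient's TACs
#'
#' Runs the full scoring chain on one patient's long-format TAC rows:
#' arterial/venous phase selection ([select_phases()]), per-vein presence
#' over the venous phase ([assess_presence()]), hemispheric CVF timing
#' ([score_hemisphere()]), relative scores ([relative_cvf()]) and the
#' ipsilateral CVF- count ([ipsilateral_absence()]).
#'
#' The venous window for presence starts one grid interval before the
#' hemisphere's CVF1 and runs to the last volume; when the hemisphere's
#' timing is censored the window falls back to two grid intervals before
#' V-TAC. Because CVF1 is itself defined over present veins, presence is
#' first assessed on the fallback window and then confirmed on the
#' CVF1-anchored window (the two agree except in pathological cases).
#'
#' @param df Data frame with columns `patient_id`, `group`, `hemisphere`
#'   (`affected`/`contralateral`), `structure` (`MCA`, `SSS`, `SMCV`, `VOT`,
#'   `VOL`), `time_s`, `attenuation_hu`, for a single patient. The midline
#'   SSS may appear under either (or both) hemisphere labels; the
#'   affected-side copy is used when both are present.
#' @param visibility_threshold Enhancement threshold in HU (default 50).
#' @param peak_tolerance,majority_fraction Passed to [detect_cvf2()].
#' @return A one-row data frame of scores (see [score_cohort()]).
#' @export
score_patient <- function(df, visibility_threshold = 50,
                          peak_tolerance = 0.05, majority_fraction = 0.5) {
  pid <- unique(df$patient_id)
  if (length(pid) != 1L) stop("'df' must contain exactly one patient")
  grp <- unique(df$group)[1]

  mca_aff <- tac_from_rows(df, "MCA", "affected")
  mca_con <- tac_from_rows(df, "MCA", "contralateral")
  sss <- tac_from_rows(df, "SSS", "affected") %||%
    tac_from_rows(df, "SSS", "contralateral")
  if (is.null(mca_aff) || is.null(mca_con) || is.null(sss)) {
    stop("patient ", pid, ": MCA (both hemispheres) and SSS TACs are required")
  }
  phases <- select_phases(mca_aff, mca_con, sss)
  times <- sss$times
  spacing <- stats::median(diff(times))
  grid_end <- max(times)
  fallback_window <- c(phases$v_tac - 2 * spacing, grid_end)

  hemi <- lapply(c(affected = "affected", contralateral = "contralateral"),
                 function(side) {
    veins <- lapply(vein_names, function(v) tac_from_rows(df, v, side))
    names(veins) <- vein_names
    if (any(vapply(veins, is.null, logical(1)))) {
      stop("patient ", pid, ": missing ", side, " vein TACs")
    }
    presence <- vapply(
      veins, assess_presence, character(1),
      visibility_threshold = visibility_threshold,
      venous_window = fallback_window
    )
    present <- presence == "present"
    if (!any(present)) {
      return(list(
        times = structure(list(cvf1 = NA_real_, cvf2 = NA_real_,
                               cvf3 = NA_real_, cvf21 = NA_real_,
                               cvf31 = NA_real_,
                               censored = c(onset = TRUE, clearance = FALSE)),
                          class = "hemisphere_cvf"),
        presence = presence, no_present_vein = TRUE
      ))
    }
    ht <- score_hemisphere(veins, present, visibility_threshold,
                           peak_tolerance, majority_fraction)
    if (!is.na(ht$cvf1)) {
      presence <- vapply(
        veins, assess_presence, character(1),
        visibility_threshold = visibility_threshold,
        venous_window = c(ht$cvf1 - spacing, grid_end)
      )
    }
    list(times = ht, presence = presence, no_present_vein = FALSE)
  })

  rel <- relative_cvf(hemi$affected$times, hemi$contralateral$times)
  ext <- ipsilateral_absence(hemi$affected$presence,
                             hemi$contralateral$presence)

  data.frame(
    patient_id = pid, group = grp,
    a_tac = phases$a_tac, v_tac = phases$v_tac,
    cvf1_aff = hemi$affected$times$cvf1,
    cvf2_aff = hemi$affected$times$cvf2,
    cvf3_aff = hemi$affected$times$cvf3,
    cvf21_aff = hemi$affected$times$cvf21,
    cvf31_aff = hemi$affected$times$cvf31,
    cvf1_contra = hemi$contralateral$times$cvf1,
    cvf2_contra = hemi$contralateral$times$cvf2,
    cvf3_contra = hemi$contralateral$times$cvf3,
    cvf21_contra = hemi$contralateral$times$cvf21,
    cvf31_contra = hemi$contralateral$times$cvf31,
    rcvf1 = unname(rel["rcvf1"]), rcvf2 = unname(rel["rcvf2"]),
    rcvf3 = unname(rel["rcvf3"]), rcvf21 = unname(rel["rcvf21"]),
    rcvf31 = unname(rel["rcvf31"]),
    smcv_aff = unname(hemi$affected$presence["SMCV"]),
    vot_aff = unname(hemi$affected$presence["VOT"]),
    vol_aff = unname(hemi$affected$presence["VOL"]),
    smcv_contra = unname(hemi$contralateral$presence["SMCV"]),
    vot_contra = unname(hemi$contralateral$presence["VOT"]),
    vol_contra = unname(hemi$contralateral$presence["VOL"]),
    ipsilateral_cvf_minus_n = ext$n_ipsilateral_absent,
    ipsilateral_cvf_minus = paste(ext$ipsilateral_absent, collapse = ";"),
    censored_onset_aff = unname(hemi$affected$times$censored["onset"]),
    censored_clearance_aff =
      unname(hemi$affected$times$censored["clearance"]),
    censored_onset_contra =
      unname(hemi$contralateral$times$censored["onset"]),
    censored_clearance_contra =
      unname(hemi$contralateral$times$censored["clearance"]),
    stringsAsFactors = FALSE
  )
}

#' Score a cohort of TACs
#'
#' Applies [score_patient()] to every patient in a long-format TAC table
#' (one produced by [generate_cohort()], [read_tac_csv()], or assembled by
#' the caller).
#'
#' @param tacs Long-format TAC data frame (see [score_patient()]); may also
#'   be a `"cvf_cohort"` object.
#' @inheritParams score_patient
#' @return Data frame with one row per patient: phase times, hemispheric CVF
#'   times and intervals, rCVF scores, per-vein presence, the ipsilateral
#'   CVF- count, and censoring flags.
#' @export
score_cohort <- function(tacs, visibility_threshold = 50,
                         peak_tolerance = 0.05, majority_fraction = 0.5) {
  if (inherits(tacs, "cvf_cohort")) tacs <- tacs$tacs
  needed <- c("patient_id", "group", "hemisphere", "structure", "time_s",
              "attenuation_hu")
  missing <- setdiff(needed, names(tacs))
  if (length(missing)) {
    stop("TAC table lacks columns: ", paste(missing, collapse = ", "))
  }
  split_df <- split(tacs, tacs$patient_id)
  rows <- lapply(split_df, score_patient,
                 visibility_threshold = visibility_threshold,
                 peak_tolerance = peak_tolerance,
                 majority_fraction = majority_fraction)
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$patient_id), , drop = FALSE]
}
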