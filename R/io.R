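# File contracts: long-format TAC CSV and the per-patient clinical CSV.

tac_structures <- c("MCA", "SSS", "SMCV", "VOT", "VOL")

#' Read a long-format TAC CSV
#'
#' Expected header: `patient_id`, `group` (`symptomatic`/`asymptomatic`),
#' `hemisphere` (`affected`/`contralateral`), `structure` (`MCA`, `SSS`,
#' `SMCV`, `VOT`, `VOL`), `time_s`, `attenuation_hu`. One SSS row-set per
#' patient (a midline copy under each hemisphere is accepted).
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_tac_csv <- function(path) {
  if (!file.exists(path)) stop("TAC CSV not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("patient_id", "group", "hemisphere", "structure", "time_s",
              "attenuation_hu")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("TAC CSV lacks columns: ", paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(df$structure), tac_structures)
  if (length(bad)) {
    stop("unknown structures in TAC CSV: ", paste(bad, collapse = ", "))
  }
  if (!all(df$hemisphere %in% c("affected", "contralateral"))) {
    stop("'hemisphere' must be 'affected' or 'contralateral'")
  }
  if (!is.numeric(df$time_s) || !is.numeric(df$attenuation_hu)) {
    stop("'time_s' and 'attenuation_hu' must be numeric")
  }
  df
}

#' Read a per-patient clinical CSV
#'
#' Mandatory columns: `patient_id`, `group`. Recognized optional columns
#' include risk factors, `nihss`, `mrs_3mo`, `angioplasty`,
#' `antegrade_filling_ratio`, `antegrade_label`, `collateral_grade_atac`,
#' `collateral_grade_vtac`, `collateral_status`. The antegrade label is
#' derived from the filling ratio and the collateral status from the
#' phase-wise grades whenever the inputs are present and the derived column
#' is not.
#'
#' @param path CSV path.
#' @return Validated data frame with derived label columns filled in.
#' @export
read_clinical_csv <- function(path) {
  if (!file.exists(path)) stop("clinical CSV not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("patient_id", "group"), names(df))
  if (length(missing)) {
    stop("clinical CSV lacks columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$patient_id)) {
    stop("clinical CSV has duplicated patient ids")
  }
  if (is.null(df$antegrade_label) &&
      !is.null(df$antegrade_filling_ratio)) {
    df$antegrade_label <- classify_antegrade(df$antegrade_filling_ratio)
  }
  if (is.null(df$collateral_status) &&
      !is.null(df$collateral_grade_atac) &&
      !is.null(df$collateral_grade_vtac)) {
    df$collateral_status <- classify_collateral(df$collateral_grade_atac,
                                                df$collateral_grade_vtac)
  }
  df
}
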