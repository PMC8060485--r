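# Antegrade-flow and collateral-status decision rules. The visual readings
# that produce the filling ratio and the three-level collateral grades are
# inputs (simulated or transcribed from a reader); only the decision rules
# live here.

#' Classify antegrade flow across the stenotic MCA
#'
#' Antegrade flow is preserved when contrast filling of the affected MCA and
#' its distal branches at A-TAC exceeds two-thirds of the contralateral
#' hemisphere, and compromised otherwise. "More than two-thirds" is strict:
#' a ratio of exactly 2/3 is compromised.
#'
#' @param filling_ratio Fraction of the contralateral MCA territory filled by
#'   the affected side at A-TAC, in `[0, 1]`. Vectorized.
#' @return `"preserved"` or `"compromised"` per element.
#' @export
#' @examples
#' classify_antegrade(c(0.9, 2/3, 0))
classify_antegrade <- function(filling_ratio) {
  if (!is.numeric(filling_ratio) || anyNA(filling_ratio) ||
      any(filling_ratio < 0 | filling_ratio > 1)) {
    stop("'filling_ratio' must be within [0, 1]")
  }
  ifelse(filling_ratio > 2 / 3, "preserved", "compromised")
}

collateral_grades <- c("none", "peripheral", "complete")

#' Classify collateral status from phase-wise grades
#'
#' Collateral status is good if the collaterals show complete contrast
#' enhancement at either the arterial (A-TAC) or the venous (V-TAC) phase,
#' and poor when only peripheral or no enhancement is seen at both.
#'
#' @param grade_at_a,grade_at_v Collateral grades at A-TAC and V-TAC: each
#'   `"none"`, `"peripheral"`, or `"complete"`. Vectorized (recycled
#'   pairwise).
#' @return `"good"` or `"poor"` per element.
#' @export
#' @examples
#' classify_collateral("peripheral", "complete")  # good
classify_collateral <- function(grade_at_a, grade_at_v) {
  check <- function(g, nm) {
    if (!all(g %in% collateral_grades)) {
      stop("'", nm, "' must be one of: ",
           paste(collateral_grades, collapse = ", "))
    }
  }
  check(grade_at_a, "grade_at_a")
  check(grade_at_v, "grade_at_v")
  ifelse(grade_at_a == "complete" | grade_at_v == "complete", "good", "poor")
}
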