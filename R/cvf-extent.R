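# Extent of cortical venous filling: per-vein presence (CVF+) / absence
# (CVF-) over the venous phase, and the ipsilateral CVF- set and count.

#' Assess presence (CVF+) or absence (CVF-) of one cortical vein
#'
#' A vein is present (CVF+) if its baseline-corrected enhancement reaches the
#' visibility threshold at any grid time within the venous window, and absent
#' (CVF-) if it never does over the whole venous phase. A value exactly at the
#' threshold counts as present.
#'
#' @param vein_tac A [tac()] for one vein.
#' @param visibility_threshold Enhancement threshold in HU above baseline
#'   (default 50, shared with the timing detectors).
#' @param venous_window Numeric `c(start, end)` in seconds delimiting the
#'   venous phase; default spans the whole grid. Must intersect the grid.
#' @return `"present"` or `"absent"`.
#' @export
assess_presence <- function(vein_tac, visibility_threshold = 50,
                            venous_window = range(vein_tac$times)) {
  stopifnot(inherits(vein_tac, "tac"))
  if (length(venous_window) != 2L || venous_window[1] > venous_window[2]) {
    stop("'venous_window' must be c(start, end) with start <= end")
  }
  sel <- vein_tac$times >= venous_window[1] & vein_tac$times <= venous_window[2]
  if (!any(sel)) {
    stop("the venous window does not intersect the acquisition grid")
  }
  if (max(enhancement(vein_tac)[sel]) >= visibility_threshold) {
    "present"
  } else {
    "absent"
  }
}

#' Ipsilateral CVF-: absent on the affected side, present contralaterally
#'
#' A vein counts as ipsilateral CVF- only when it is absent in the affected
#' hemisphere *and* present in the contralateral hemisphere; bilateral absence
#' is attributed to anatomical variation and excluded.
#'
#' @param affected,contralateral Per-vein presence for each hemisphere: named
#'   character vectors of `"present"`/`"absent"` (or named logicals, `TRUE` =
#'   present), with matching vein names (typically `SMCV`, `VOT`, `VOL`).
#' @return An object of class `"extent_result"`: list with
#'   `ipsilateral_absent` (character vector of vein names),
#'   `n_ipsilateral_absent` (0..3) and `category`
#'   (`"none"`, `"CVF-=1"`, `"CVF-=2"`, `"CVF-=3"`).
#' @export
#' @examples
#' aff <- c(SMCV = "absent", VOT = "present", VOL = "present")
#' con <- c(SMCV = "present", VOT = "present", VOL = "absent")
#' ipsilateral_absence(aff, con)  # SMCV only; VOL is bilateral anatomy, n = 1
ipsilateral_absence <- function(affected, contralateral) {
  as_present <- function(x, side) {
    if (is.character(x)) {
      if (!all(x %in% c("present", "absent"))) {
        stop("presence flags must be 'present' or 'absent' (", side, ")")
      }
      x <- x == "present"
    }
    if (!is.logical(x) || is.null(names(x)) || anyNA(x)) {
      stop("presence flags must be a named character or logical vector (",
           side, ")")
    }
    x
  }
  aff <- as_present(affected, "affected")
  con <- as_present(contralateral, "contralateral")
  if (!setequal(names(aff), names(con))) {
    stop("affected and contralateral hemispheres must score the same veins")
  }
  con <- con[names(aff)]
  ips <- names(aff)[!aff & con]
  n <- length(ips)
  structure(
    list(
      ipsilateral_absent = ips,
      n_ipsilateral_absent = n,
      category = c("none", "CVF-=1", "CVF-=2", "CVF-=3")[n + 1L]
    ),
    class = "extent_result"
  )
}

#' @export
print.extent_result <- function(x, ...) {
  veins <- if (x$n_ipsilateral_absent) {
    paste(x$ipsilateral_absent, collapse = ", ")
  } else {
    "none"
  }
  cat(sprintf("<extent_result> ipsilateral CVF-: %s (%s)\n", veins, x$category))
  invisible(x)
}
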