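# Venous-phase timing: CVF1 (first appearance of any cortical vein), CVF2
# (most veins at maximum opacification), CVF3 (all veins cleared), the derived
# intervals CVF21/CVF31, affected-minus-contralateral relative scores (rCVF),
# and the cohort-median fast/slow velocity split.

# Normalize the veins argument: a single tac or a list of tacs, subset to the
# present ones, all sharing one grid. Returns list(times, enh) with enh an
# n_times x n_veins matrix.
prepare_veins <- function(veins, present = NULL) {
  if (inherits(veins, "tac")) veins <- list(veins)
  if (!length(veins) || !all(vapply(veins, inherits, logical(1), "tac"))) {
    stop("'veins' must be a tac or a list of tac objects")
  }
  if (is.null(present)) present <- rep(TRUE, length(veins))
  if (length(present) != length(veins)) {
    stop("'present' must have one flag per vein")
  }
  veins <- veins[present]
  if (length(veins) == 0L) {
    stop("at least one present (CVF+) vein is required for timing")
  }
  times <- veins[[1]]$times
  for (v in veins) {
    if (!isTRUE(all.equal(v$times, times))) {
      stop("all vein TACs must share one acquisition grid")
    }
  }
  enh <- vapply(veins, enhancement, numeric(length(times)))
  list(times = times, enh = matrix(enh, nrow = length(times)))
}

#' Detect CVF1: first appearance of any cortical vein
#'
#' The earliest grid time at which any present (CVF+) vein's baseline-corrected
#' enhancement reaches the visibility threshold. Absent (CVF-) veins are
#' excluded from timing.
#'
#' @param veins A [tac()] or list of vein TACs for one hemisphere.
#' @param present Logical vector of CVF+ flags, one per vein (default: all).
#' @param visibility_threshold Enhancement (HU above baseline) at which a vein
#'   counts as visible; default 50 HU, shared with [detect_cvf3()] and
#'   [assess_presence()].
#' @return Onset time in seconds (a grid time).
#' @section Errors: if no present vein ever reaches the threshold a
#'   condition of class `"cvf_censored_onset"` is signalled; this is distinct
#'   from the absent-vein (CVF-) state.
#' @export
detect_cvf1 <- function(veins, present = NULL, visibility_threshold = 50) {
  pv <- prepare_veins(veins, present)
  hit <- which(rowSums(pv$enh >= visibility_threshold) > 0)
  if (length(hit) == 0L) {
    cvf_stop("cvf_censored_onset",
             "no present vein reaches the visibility threshold within the scan")
  }
  pv$times[hit[1]]
}

#' Detect CVF2: most cortical veins at maximum opacification
#'
#' The earliest grid time at which at least `ceiling(majority_fraction * m)` of
#' the `m` present veins are within `peak_tolerance` of their own maximum
#' enhancement. With one vein and zero tolerance this is the vein's argmax.
#' If no grid time satisfies the majority rule (possible for three or more
#' veins with disjoint near-peak windows), the earliest time maximizing the
#' near-peak count is returned.
#'
#' @inheritParams detect_cvf1
#' @param peak_tolerance Fraction of each vein's own peak enhancement within
#'   which it counts as "at maximum" (default 0.05).
#' @param majority_fraction Fraction of present veins required (default 0.5).
#' @return Peak-phase time in seconds (a grid time).
#' @export
detect_cvf2 <- function(veins, present = NULL, peak_tolerance = 0.05,
                        majority_fraction = 0.5) {
  if (peak_tolerance < 0 || peak_tolerance >= 1) {
    stop("'peak_tolerance' must be in [0, 1)")
  }
  if (majority_fraction <= 0 || majority_fraction > 1) {
    stop("'majority_fraction' must be in (0, 1]")
  }
  pv <- prepare_veins(veins, present)
  m <- ncol(pv$enh)
  peak <- apply(pv$enh, 2, max)
  near <- sweep(pv$enh, 2, (1 - peak_tolerance) * peak, `>=`)
  count <- rowSums(near)
  need <- ceiling(majority_fraction * m)
  ok <- which(count >= need)
  idx <- if (length(ok)) ok[1] else which.max(count)
  pv$times[idx]
}

#' Detect CVF3: first clearance of all cortical veins
#'
#' The earliest grid time strictly after `after` (the hemisphere's CVF2) at
#' which every present vein's enhancement has dropped below the visibility
#' threshold.
#'
#' @inheritParams detect_cvf1
#' @param after Time in seconds after which clearance is sought (the
#'   hemisphere's CVF2).
#' @return Clearance time in seconds (a grid time).
#' @section Errors: if the veins never clear within the scan a condition of
#'   class `"cvf_censored_clearance"` is signalled.
#' @export
detect_cvf3 <- function(veins, present = NULL, visibility_threshold = 50,
                        after) {
  pv <- prepare_veins(veins, present)
  clear <- which(pv$times > after &
                   rowSums(pv$enh >= visibility_threshold) == 0)
  if (length(clear) == 0L) {
    cvf_stop("cvf_censored_clearance",
             "cortical veins remain opacified at the last acquired volume")
  }
  pv$times[clear[1]]
}

#' Derive the venous-phase intervals CVF21 and CVF31
#'
#' CVF21 = CVF2 - CVF1 is the early-to-peak venous phase; CVF31 = CVF3 - CVF1
#' spans the whole venous phase.
#'
#' @param cvf1,cvf2,cvf3 Times in seconds with `cvf1 <= cvf2 <= cvf3`.
#' @return Named numeric vector `c(cvf21, cvf31)`.
#' @export
#' @examples
#' derive_intervals(20.9, 24.8, 37.7)  # 3.9, 16.8
derive_intervals <- function(cvf1, cvf2, cvf3) {
  eps <- 1e-9
  if (cvf1 > cvf2 + eps || cvf2 > cvf3 + eps) {
    stop("CVF times must be ordered cvf1 <= cvf2 <= cvf3")
  }
  c(cvf21 = cvf2 - cvf1, cvf31 = cvf3 - cvf1)
}

#' Hemispheric CVF times
#'
#' Bundles the three venous-phase time points and the derived intervals for
#' one hemisphere.
#'
#' @inheritParams derive_intervals
#' @return An object of class `"hemisphere_cvf"` with elements `cvf1`, `cvf2`,
#'   `cvf3`, `cvf21`, `cvf31`.
#' @export
#' @examples
#' hemisphere_cvf(19.0, 24.8, 32.7)
hemisphere_cvf <- function(cvf1, cvf2, cvf3) {
  iv <- derive_intervals(cvf1, cvf2, cvf3)
  structure(
    list(cvf1 = cvf1, cvf2 = cvf2, cvf3 = cvf3,
         cvf21 = unname(iv["cvf21"]), cvf31 = unname(iv["cvf31"])),
    class = "hemisphere_cvf"
  )
}

#' @export
print.hemisphere_cvf <- function(x, ...) {
  cat(sprintf(
    "<hemisphere_cvf> CVF1 %.1f s, CVF2 %.1f s, CVF3 %.1f s (CVF21 %.1f s, CVF31 %.1f s)\n",
    x$cvf1, x$cvf2, x$cvf3, x$cvf21, x$cvf31
  ))
  invisible(x)
}

#' Score all CVF time points for one hemisphere
#'
#' Runs [detect_cvf1()], [detect_cvf2()] and [detect_cvf3()] on the present
#' veins of one hemisphere and derives the intervals. Censored detections
#' yield `NA` for the affected quantities and are flagged rather than raised.
#'
#' @inheritParams detect_cvf1
#' @inheritParams detect_cvf2
#' @return A `"hemisphere_cvf"` object with an additional `censored` element,
#'   a named logical vector with entries `onset` and `clearance`.
#' @export
score_hemisphere <- function(veins, present = NULL, visibility_threshold = 50,
                             peak_tolerance = 0.05, majority_fraction = 0.5) {
  censored <- c(onset = FALSE, clearance = FALSE)
  cvf1 <- tryCatch(
    detect_cvf1(veins, present, visibility_threshold),
    cvf_censored_onset = function(e) {
      censored["onset"] <<- TRUE
      NA_real_
    }
  )
  if (is.na(cvf1)) {
    out <- structure(
      list(cvf1 = NA_real_, cvf2 = NA_real_, cvf3 = NA_real_,
           cvf21 = NA_real_, cvf31 = NA_real_),
      class = "hemisphere_cvf"
    )
    out$censored <- censored
    return(out)
  }
  cvf2 <- detect_cvf2(veins, present, peak_tolerance, majority_fraction)
  cvf3 <- tryCatch(
    detect_cvf3(veins, present, visibility_threshold, after = cvf2),
    cvf_censored_clearance = function(e) {
      censored["clearance"] <<- TRUE
      NA_real_
    }
  )
  cvf21 <- if (cvf2 >= cvf1) cvf2 - cvf1 else NA_real_
  cvf31 <- if (!is.na(cvf3)) cvf3 - cvf1 else NA_real_
  out <- structure(
    list(cvf1 = cvf1, cvf2 = cvf2, cvf3 = cvf3, cvf21 = cvf21, cvf31 = cvf31),
    class = "hemisphere_cvf"
  )
  out$censored <- censored
  out
}

#' Relative CVF: affected minus contralateral
#'
#' Each component is the affected-hemisphere value minus the contralateral
#' value for the corresponding index; positive values mean delayed filling on
#' the affected side. Swapping hemispheres negates every component.
#'
#' @param affected,contralateral `"hemisphere_cvf"` objects (or numeric
#'   vectors `c(cvf1, cvf2, cvf3, cvf21, cvf31)`).
#' @return An object of class `"relative_cvf"`: named numeric vector with
#'   components `rcvf1`, `rcvf2`, `rcvf3`, `rcvf21`, `rcvf31` (seconds,
#'   signed).
#' @export
#' @examples
#' aff <- hemisphere_cvf(20.9, 24.8, 37.7)
#' con <- hemisphere_cvf(19.0, 24.8, 32.7)
#' relative_cvf(aff, con)  # 1.9, 0, 5.0, -1.9, 3.1
relative_cvf <- function(affected, contralateral) {
  as_vec <- function(h) {
    if (inherits(h, "hemisphere_cvf")) {
      c(h$cvf1, h$cvf2, h$cvf3, h$cvf21, h$cvf31)
    } else if (is.numeric(h) && length(h) == 5L) {
      as.numeric(h)
    } else {
      stop("hemispheres must be 'hemisphere_cvf' objects or length-5 numerics")
    }
  }
  d <- as_vec(affected) - as_vec(contralateral)
  structure(
    stats::setNames(d, c("rcvf1", "rcvf2", "rcvf3", "rcvf21", "rcvf31")),
    class = "relative_cvf"
  )
}

#' @export
print.relative_cvf <- function(x, ...) {
  cat("<relative_cvf> affected - contralateral (s)\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Classify CVF velocity by the cohort-median rule
#'
#' Fast CVF is a relative time less than or equal to the cohort median of
#' that rCVF index; slow is the opposite. The threshold is the sample median
#' of the analysis cohort (mean of the two central order statistics for even
#' n), so at least half the cohort is always labelled fast.
#'
#' @param cohort_values Numeric vector of one rCVF index across the analysis
#'   cohort (`NA`s allowed; they stay `NA`).
#' @param threshold Optional externally supplied threshold in seconds;
#'   default: the median of `cohort_values`.
#' @return An object of class `"velocity_classification"`: list with
#'   `threshold` (seconds) and `label` (character, `"fast"`/`"slow"`, parallel
#'   to the input).
#' @export
#' @examples
#' classify_velocity(c(1, 2, 3))  # threshold 2: fast, fast, slow
classify_velocity <- function(cohort_values, threshold = NULL) {
  if (length(cohort_values) == 0L || all(is.na(cohort_values))) {
    stop("at least one finite rCVF value is required")
  }
  threshold <- threshold %||% stats::median(cohort_values, na.rm = TRUE)
  label <- ifelse(cohort_values <= threshold, "fast", "slow")
  structure(
    list(threshold = threshold, label = label, values = cohort_values),
    class = "velocity_classification"
  )
}

#' @export
print.velocity_classification <- function(x, ...) {
  cat(sprintf(
    "<velocity_classification> threshold %.2f s: %d fast, %d slow, %d NA\n",
    x$threshold, sum(x$label == "fast", na.rm = TRUE),
    sum(x$label == "slow", na.rm = TRUE), sum(is.na(x$label))
  ))
  invisible(x)
}
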