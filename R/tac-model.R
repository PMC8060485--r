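# Time-attenuation curves (TACs), the gamma-variate bolus model, the discrete
# multi-volume acquisition grid, and arterial/venous phase selection.

#' Acquisition time grid for dynamic CTA
#'
#' Dynamic CTA acquires a fixed number of whole-brain volumes (19 in the
#' protocol this package models), each stamped with its acquisition time.
#' All CVF times are reported on this grid; no sub-sample interpolation is
#' performed.
#'
#' @param n_volumes Number of volumes (default 19).
#' @param spacing Inter-volume interval in seconds (default 2).
#' @param start Time of the first volume in seconds (default 8).
#' @return Numeric vector of acquisition times in seconds.
#' @export
#' @examples
#' acquisition_grid()          # 8, 10, ..., 44 s
#' acquisition_grid(10, 1.5, 5)
acquisition_grid <- function(n_volumes = 19, spacing = 2, start = 8) {
  if (n_volumes < 3) stop("an acquisition grid needs at least 3 volumes")
  if (spacing <= 0) stop("'spacing' must be positive")
  if (start <= 0) stop("'start' must be positive")
  validate_grid(start + spacing * (seq_len(n_volumes) - 1))
}

validate_grid <- function(times) {
  if (!is.numeric(times) || length(times) < 3) {
    stop("an acquisition grid needs at least 3 time points")
  }
  if (any(!is.finite(times)) || any(times <= 0)) {
    stop("grid times must be finite and positive")
  }
  if (any(diff(times) <= 0)) {
    stop("grid times must be strictly increasing")
  }
  as.numeric(times)
}

#' Gamma-variate bolus parameters
#'
#' The gamma-variate function is the standard parametric model of a contrast
#' bolus passing through a vessel:
#' \deqn{a(t) = baseline + K (t - t_0)^\alpha e^{-(t - t_0)/\beta}, \quad t > t_0,}
#' and \eqn{a(t) = baseline} before bolus arrival. The curve is unimodal with
#' its peak at \eqn{t_0 + \alpha\beta}.
#'
#' @param t0 Bolus arrival time in seconds.
#' @param alpha Shape parameter (dimensionless, > 0).
#' @param beta Time-scale parameter in seconds (> 0).
#' @param K Amplitude scale in HU (> 0); note its units absorb the
#'   \eqn{s^{\alpha}} factor.
#' @param baseline Pre-contrast attenuation in HU (default 40).
#' @return An object of class `"gamma_variate"`.
#' @seealso [gv_from_peak()] to parameterize by peak enhancement,
#'   [eval_gamma_variate()], [sample_tac()].
#' @export
gamma_variate_params <- function(t0, alpha, beta, K, baseline = 40) {
  if (!is.finite(t0)) stop("'t0' must be finite")
  if (alpha <= 0) stop("'alpha' must be positive")
  if (beta <= 0) stop("'beta' must be positive")
  if (K <= 0) stop("'K' must be positive")
  structure(
    list(t0 = t0, alpha = alpha, beta = beta, K = K, baseline = baseline),
    class = "gamma_variate"
  )
}

#' @rdname gamma_variate_params
#' @param peak_enhancement Peak enhancement above baseline in HU; converted to
#'   the amplitude scale `K` via the analytic peak value
#'   \eqn{K (\alpha\beta)^\alpha e^{-\alpha}}.
#' @export
gv_from_peak <- function(t0, alpha, beta, peak_enhancement, baseline = 40) {
  if (peak_enhancement <= 0) stop("'peak_enhancement' must be positive")
  K <- peak_enhancement / ((alpha * beta)^alpha * exp(-alpha))
  gamma_variate_params(t0, alpha, beta, K, baseline)
}

#' @rdname gamma_variate_params
#' @param params A `"gamma_variate"` object.
#' @export
gv_peak_time <- function(params) {
  stopifnot(inherits(params, "gamma_variate"))
  params$t0 + params$alpha * params$beta
}

#' Evaluate a gamma-variate curve
#'
#' @param params A [gamma_variate_params()] object.
#' @param t Numeric vector of times in seconds.
#' @return Attenuation in HU at each time; equal to the baseline at and before
#'   bolus arrival, continuous at `t0` for `alpha > 0`.
#' @export
#' @examples
#' p <- gamma_variate_params(t0 = 10, alpha = 3, beta = 2, K = 1, baseline = 40)
#' eval_gamma_variate(p, c(10, 16))  # baseline, then 40 + 216 * exp(-3)
eval_gamma_variate <- function(params, t) {
  stopifnot(inherits(params, "gamma_variate"))
  if (any(!is.finite(t))) stop("'t' must be finite")
  dt <- t - params$t0
  out <- rep(params$baseline, length(t))
  up <- dt > 0
  out[up] <- params$baseline +
    params$K * dt[up]^params$alpha * exp(-dt[up] / params$beta)
  out
}

#' Time-attenuation curve (TAC)
#'
#' One vessel's attenuation samples on the acquisition grid. Enhancement is
#' attenuation minus the pre-contrast baseline; unless supplied, the baseline
#' is taken from the first sample because the pre-contrast volume is acquired
#' first.
#'
#' @param times Acquisition times in seconds (strictly increasing, length >= 3).
#' @param values Attenuation in HU, one per time point.
#' @param baseline Pre-contrast attenuation in HU (default: first sample).
#' @return An object of class `"tac"`.
#' @export
tac <- function(times, values, baseline = values[1]) {
  times <- validate_grid(times)
  if (length(values) != length(times)) {
    stop("'values' must have one sample per grid time")
  }
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop("'values' must be finite attenuations in HU")
  }
  structure(
    list(times = times, values = as.numeric(values), baseline = baseline),
    class = "tac"
  )
}

#' @rdname tac
#' @param x A `"tac"` object.
#' @param ... Unused.
#' @return `enhancement()` returns baseline-corrected attenuation in HU.
#' @export
enhancement <- function(x, ...) UseMethod("enhancement")

#' @export
enhancement.tac <- function(x, ...) x$values - x$baseline

#' @export
print.tac <- function(x, ...) {
  cat(sprintf(
    "<tac> %d volumes, %.1f-%.1f s, baseline %.1f HU, peak enhancement %.1f HU at %.1f s\n",
    length(x$times), min(x$times), max(x$times), x$baseline,
    max(enhancement(x)), x$times[which.max(enhancement(x))]
  ))
  invisible(x)
}

#' @export
plot.tac <- function(x, ..., xlab = "time (s)", ylab = "attenuation (HU)",
                     type = "b") {
  graphics::plot(x$times, x$values, type = type, xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = x$baseline, lty = 3)
  invisible(x)
}

#' Sample a noisy TAC from a gamma-variate model
#'
#' Evaluates the bolus model on the acquisition grid and adds independent
#' Gaussian measurement noise. With a `seed` the draw is reproducible and the
#' caller's RNG stream is left untouched.
#'
#' @param params A [gamma_variate_params()] object.
#' @param times Acquisition grid (see [acquisition_grid()]).
#' @param noise_sd Noise standard deviation in HU (>= 0; 0 gives the noiseless
#'   curve and consumes no random numbers).
#' @param seed Optional integer seed for a self-contained draw.
#' @return A [tac()] whose baseline is the model baseline.
#' @export
sample_tac <- function(params, times, noise_sd = 0, seed = NULL) {
  times <- validate_grid(times)
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  mu <- eval_gamma_variate(params, times)
  draw <- function() {
    if (noise_sd > 0) mu + stats::rnorm(length(times), 0, noise_sd) else mu
  }
  values <- if (is.null(seed)) draw() else with_seed(seed, draw())
  tac(times, values, baseline = params$baseline)
}

#' Select the arterial and venous phases from reference TACs
#'
#' The venous phase (V-TAC) is the grid time of maximum enhancement of the
#' superior sagittal sinus TAC. The arterial phase (A-TAC) is the grid time,
#' restricted to times strictly before V-TAC so that the reading is least
#' affected by cortical veins and sinuses, that maximizes the *minimum* of the
#' two baseline-corrected MCA enhancements (the best bilateral opacification).
#' Ties are broken toward the earlier time.
#'
#' @param mca_affected,mca_contralateral MCA TACs of the two hemispheres.
#' @param sss Superior-sagittal-sinus TAC.
#' @return An object of class `"phase_selection"` with elements `a_tac` and
#'   `v_tac` (seconds, both on the grid, `a_tac < v_tac`).
#' @export
select_phases <- function(mca_affected, mca_contralateral, sss) {
  stopifnot(inherits(mca_affected, "tac"), inherits(mca_contralateral, "tac"),
            inherits(sss, "tac"))
  if (!isTRUE(all.equal(mca_affected$times, sss$times)) ||
      !isTRUE(all.equal(mca_contralateral$times, sss$times))) {
    stop("all three TACs must share one acquisition grid")
  }
  times <- sss$times
  v_idx <- which.max(enhancement(sss)) # first maximum -> earlier tie-break
  v_tac <- times[v_idx]
  pre <- which(times < v_tac)
  if (length(pre) == 0L) {
    cvf_stop("cvf_phase_selection_error",
             "no grid time precedes the venous peak; cannot select A-TAC")
  }
  bilateral <- pmin(enhancement(mca_affected), enhancement(mca_contralateral))
  a_tac <- times[pre[which.max(bilateral[pre])]]
  structure(list(a_tac = a_tac, v_tac = v_tac), class = "phase_selection")
}

#' @export
print.phase_selection <- function(x, ...) {
  cat(sprintf("<phase_selection> A-TAC %.1f s, V-TAC %.1f s\n", x$a_tac, x$v_tac))
  invisible(x)
}
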