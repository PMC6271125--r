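#' Kinetic parameters of the second-order flavor-release model
#'
#' Bundles the four parameters of the bi-exponential HS-SPME extraction
#' model: the net amount of an analyte on the fiber is the difference of
#' two parallel first-order processes,
#' \deqn{C(t) = k_1 (1 - e^{-t/\tau_1}) - k_2 (1 - e^{-t/\tau_2}),}
#' adsorption onto the fiber (amplitude `k1`, time constant `tau1`) and
#' release back into the headspace (`k2`, `tau2`). Adsorption is the
#' faster process (`tau1 < tau2`) and the plateau `k1 - k2` is positive.
#'
#' @param k1,k2 equilibrium constants (amplitudes) of the adsorption and
#'   release processes, in the units of the data being fitted (GC peak
#'   area, possibly normalized). Both must be positive with `k1 > k2`.
#' @param tau1,tau2 time constants in minutes; both positive, and `tau2`
#'   must exceed `tau1 * (1 + min_tau_separation)`.
#' @param min_tau_separation minimum relative separation delta enforced
#'   between the time constants, guarding the `tau2 -> tau1` degeneracy
#'   of the peak-time formula. Default `1e-4`.
#' @return An object of class `kinetic_params`.
#' @examples
#' p <- kinetic_params(k1 = 2, k2 = 1, tau1 = 10, tau2 = 20)
#' equilibrium_conc(p)
#' peak_time(p)
#' @export
kinetic_params <- function(k1, k2, tau1, tau2, min_tau_separation = 1e-4) {
  vals <- c(k1 = k1, k2 = k2, tau1 = tau1, tau2 = tau2)
  if (any(!is.finite(vals))) {
    stop("kinetic parameters must be finite numbers")
  }
  if (any(vals <= 0)) {
    stop("kinetic parameters must all be strictly positive")
  }
  if (k1 <= k2) {
    stop("k1 must exceed k2 (positive equilibrium level k1 - k2)")
  }
  if (tau2 < tau1 * (1 + min_tau_separation)) {
    stop(sprintf(
      "tau2 must be at least tau1 * (1 + %g); got tau1 = %g, tau2 = %g",
      min_tau_separation, tau1, tau2
    ))
  }
  structure(
    list(k1 = k1, k2 = k2, tau1 = tau1, tau2 = tau2),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "kinetic_params: k1 = %.6g, k2 = %.6g, tau1 = %.6g min, tau2 = %.6g min\n",
    x$k1, x$k2, x$tau1, x$tau2
  ))
  cat(sprintf("  plateau C_inf = %.6g", equilibrium_conc(x)))
  if (has_overshoot(x)) {
    cat(sprintf(", t_max = %.6g min, C_max = %.6g\n", peak_time(x), peak_conc(x)))
  } else {
    cat(" (monotone profile, no interior peak)\n")
  }
  invisible(x)
}

check_times <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop("extraction times must be finite numbers")
  }
  if (any(t < 0)) {
    stop("extraction time must be nonnegative (minutes)")
  }
  t
}

#' Adsorption, release, and net concentration curves
#'
#' `adsorption_conc()` evaluates the first-order adsorption component
#' `k1 * (1 - exp(-t / tau1))`, `release_conc()` the release component
#' `k2 * (1 - exp(-t / tau2))`, and `net_conc()` their difference, the
#' actual amount of analyte on the fiber at extraction time `t`.
#'
#' @param params a [kinetic_params()] object.
#' @param t vector of extraction times in minutes, all `>= 0`.
#' @return Numeric vector of concentrations (peak-area units) of the same
#'   length as `t`.
#' @export
adsorption_conc <- function(params, t) {
  t <- check_times(t)
  params$k1 * (1 - exp(-t / params$tau1))
}

#' @rdname adsorption_conc
#' @export
release_conc <- function(params, t) {
  t <- check_times(t)
  params$k2 * (1 - exp(-t / params$tau2))
}

#' @rdname adsorption_conc
#' @export
net_conc <- function(params, t) {
  adsorption_conc(params, t) - release_conc(params, t)
}

#' Equilibrium concentration of the net curve
#'
#' The long-time plateau of the net curve, `k1 - k2`; strictly positive
#' under the parameter invariants.
#'
#' @inheritParams adsorption_conc
#' @return Scalar plateau concentration.
#' @export
equilibrium_conc <- function(params) {
  params$k1 - params$k2
}

#' Does the profile overshoot its plateau?
#'
#' The net curve rises past the plateau and then declines exactly when
#' the initial slope is positive, `k1 / tau1 > k2 / tau2`, together with
#' the model ordering `tau1 < tau2`. When this fails the curve is
#' monotone and has no interior maximum.
#'
#' @inheritParams adsorption_conc
#' @return `TRUE` if an interior maximum exists.
#' @export
has_overshoot <- function(params) {
  (params$k1 / params$tau1 > params$k2 / params$tau2) &&
    (params$tau1 < params$tau2)
}

#' Time and height of the overshoot peak
#'
#' Setting the derivative of the net curve to zero gives the closed form
#' \deqn{t_{max} = \frac{\tau_1 \tau_2}{\tau_2 - \tau_1}
#'       \ln\!\frac{k_1 \tau_2}{k_2 \tau_1},}
#' valid when an interior maximum exists (see [has_overshoot()]);
#' `peak_conc()` is the net curve evaluated there and always lies at or
#' above the plateau [equilibrium_conc()].
#'
#' @inheritParams adsorption_conc
#' @return `peak_time()`: the peak time in minutes; `peak_conc()`: the
#'   concentration at the peak.
#' @export
peak_time <- function(params) {
  if (!has_overshoot(params)) {
    stop(
      "monotone profile: no interior maximum ",
      "(requires k1/tau1 > k2/tau2 and tau1 < tau2)"
    )
  }
  with(params, (tau1 * tau2 / (tau2 - tau1)) * log((k1 * tau2) / (k2 * tau1)))
}

#' @rdname peak_time
#' @export
peak_conc <- function(params) {
  net_conc(params, peak_time(params))
}
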