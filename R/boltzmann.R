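#' Boltzmann sigmoid survival model
#'
#' Four-parameter logistic-in-time curve used throughout the package, both to
#' generate synthetic per-strain survival and to fit reconstructed survival
#' curves:
#' \deqn{V(t) = bottom + \frac{top - bottom}{1 + \exp((t - t_{50})/\tau)}}
#' The curve decreases from `top` towards `bottom` as `t` grows; `t50` is the
#' midpoint day and `tau` the slope width in days.
#'
#' @param t Numeric vector of days.
#' @param top,bottom Upper and lower asymptotes (percent survival).
#' @param t50 Midpoint day of the transition.
#' @param tau Slope width in days; must be positive.
#' @return Numeric vector of curve values at `t`.
#' @examples
#' boltzmann(9, top = 100, bottom = 0, t50 = 9, tau = 2) # 50
#' @export
boltzmann <- function(t, top, bottom, t50, tau) {
  if (tau <= 0) abort("`tau` must be positive")
  bottom + (top - bottom) / (1 + exp((t - t50) / tau))
}

#' Survival fraction normalized to a reference day
#'
#' Evaluates the (top = 1, bottom = 0) Boltzmann sigmoid and rescales it so
#' the value at `reference_day` equals 1. This is the planted survival model
#' of the synthetic screen generator: the same functional form the survival
#' module fits, which makes parameter recovery exact in the noiseless limit.
#'
#' @param t Numeric vector of days.
#' @param t50 Midpoint day.
#' @param tau Slope width in days.
#' @param reference_day Day at which survival is defined as 1 (100%).
#' @return Survival fractions, equal to 1 at `reference_day`.
#' @export
boltzmann_survival <- function(t, t50, tau, reference_day) {
  boltzmann(t, 1, 0, t50, tau) / boltzmann(reference_day, 1, 0, t50, tau)
}
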