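#' Ventricular activation waveform
#'
#' Piecewise-cosine activation: a cosine rise over `[0, ts1]`, a cosine fall
#' over `[ts1, ts2]` and zero for the rest of the beat.  The systolic
#' duration follows a Bazett-type rate correction, shrinking with the square
#' root of the instantaneous beat period rather than proportionally to it:
#' `ts2 = ts2_frac * sqrt(rr * rr_ref)` (capped at 90% of the beat), with
#' `ts1` keeping its proportion of `ts2`.  At `rr = rr_ref` the fractions
#' hold exactly.  The waveform is continuously differentiable and bounded in
#' `[0, 1]`, peaking at `t = ts1`.
#'
#' @param t time since beat onset (s), vectorized.
#' @param rr current beat period (s).
#' @param ts1_frac,ts2_frac systolic timing fractions at the reference
#'   period.
#' @param rr_ref reference beat period (s) anchoring the rate correction.
#' @return activation value(s) in `[0, 1]`.
#' @export
activation_ventricle <- function(t, rr, ts1_frac = 0.3, ts2_frac = 0.45,
                                 rr_ref = 60 / 70) {
  stopifnot(rr > 0, all(t >= 0))
  ts2 <- min(ts2_frac * sqrt(rr * rr_ref), 0.9 * rr)
  ts1 <- ts1_frac / ts2_frac * ts2
  e <- numeric(length(t))
  i1 <- t < ts1
  i2 <- !i1 & t < ts2
  e[i1] <- 0.5 * (1 - cos(pi * t[i1] / ts1))
  e[i2] <- 0.5 * (1 + cos(pi * (t[i2] - ts1) / (ts2 - ts1)))
  e
}

#' Atrial activation waveform
#'
#' A single cosine bump of width `tpww` starting at `tpwb` (fractions of the
#' beat period), wrapping past the beat boundary, so that atrial systole
#' immediately precedes the next ventricular contraction.
#'
#' @inheritParams activation_ventricle
#' @param tpwb_frac,tpww_frac bump onset and width as fractions of `rr`.
#' @return activation value(s) in `[0, 1]`.
#' @export
activation_atrium <- function(t, rr, tpwb_frac = 0.92, tpww_frac = 0.09) {
  stopifnot(rr > 0, all(t >= 0))
  u <- (t - tpwb_frac * rr) %% rr
  ifelse(u < tpww_frac * rr, 0.5 * (1 - cos(2 * pi * u / (tpww_frac * rr))),
         0)
}

#' Time-varying chamber elastance
#'
#' `E(t) = E_min + (E_max - E_min) e(t)` with the ventricular or atrial
#' activation `e`.  A passive chamber (atria during fibrillation) keeps
#' `E = E_min` for the whole beat, so its pressure-volume relation is the
#' straight line `P = E_min (V - V_un)`.
#'
#' @param t time since beat onset (s), in `[0, rr)`.
#' @param rr beat period (s).
#' @param E_min,E_max elastance bounds (mmHg/ml).
#' @param chamber `"ventricle"` or `"atrium"` (selects the waveform).
#' @param passive if `TRUE`, return `E_min` identically.
#' @param timing named list of timing fractions (defaults as in
#'   [cardio_params()]).
#' @return elastance (mmHg/ml), vectorized over `t`.
#' @export
#' @examples
#' chamber_elastance(0.1, 0.857, 0.15, 0.25, "atrium", passive = TRUE)
chamber_elastance <- function(t, rr, E_min, E_max,
                              chamber = c("ventricle", "atrium"),
                              passive = FALSE,
                              timing = list(ts1_frac = 0.3, ts2_frac = 0.45,
                                            tpwb_frac = 0.92,
                                            tpww_frac = 0.09)) {
  chamber <- match.arg(chamber)
  if (rr <= 0 || any(t < 0) || any(t >= rr))
    stop("require 0 <= t < rr and rr > 0")
  if (passive) return(rep(E_min, length(t)))
  if (is.null(timing$rr_ref)) timing$rr_ref <- 60 / 70
  e <- if (chamber == "ventricle")
    activation_ventricle(t, rr, timing$ts1_frac, timing$ts2_frac,
                         timing$rr_ref)
  else
    activation_atrium(t, rr, timing$tpwb_frac, timing$tpww_frac)
  E_min + (E_max - E_min) * e
}
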