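#' Exercise (MET) parameter overrides
#'
#' Eight cardiovascular parameters are retuned at each exercise intensity to
#' reproduce the physiological response to graded exertion: ventricular
#' maximum elastances rise (inotropy), systemic arterial and venous
#' compliances fall (vasoconstriction, venous tone), and systemic arteriolar,
#' systemic capillary and pulmonary capillary resistances fall (muscular
#' vasodilation, capillary recruitment).
#'
#' @return A data.frame with one row per parameter and one column per MET
#'   level (`met1`, `met4`, `met6`, `met8`).
#' @export
exercise_overrides <- function() {
  data.frame(
    parameter = c("E_lv_max", "E_rv_max", "C_sas", "C_sat",
                  "R_sar", "R_scp", "C_svn", "R_pcp"),
    met1 = c(2.5, 1.15, 0.064, 1.28, 0.44, 0.4576, 20.5, 0.0385),
    met4 = c(6, 2.3, 0.0576, 1.152, 0.2948, 0.3066, 14, 0.0258),
    met6 = c(8, 3, 0.0512, 1.024, 0.2332, 0.2425, 9.5, 0.0204),
    met8 = c(10, 3.5, 0.0448, 0.896, 0.1936, 0.2013, 5, 0.0181),
    stringsAsFactors = FALSE
  )
}

#' Apply a MET level to a baseline parameter set
#'
#' Replaces exactly the eight exercise-tuned parameters with their values at
#' the requested intensity; every other parameter is left untouched.  At
#' 1 MET the baseline is returned unchanged.
#'
#' @param baseline a [cardio_params()] object.
#' @param met MET level, one of 1, 4, 6, 8.
#' @param scale optional named numeric vector of multiplicative perturbations
#'   applied to the overridden values after replacement (used by the
#'   sensitivity scan), e.g. `c(R_sar = 1.05)`.
#' @return A `cardio_params` object.
#' @export
#' @examples
#' p8 <- apply_exercise(cardio_params(), 8)
#' p8$C_svn  # 5 ml/mmHg
apply_exercise <- function(baseline, met, scale = NULL) {
  validate_params(baseline)
  if (!length(met) == 1 || !met %in% c(1, 4, 6, 8))
    stop("met must be one of 1, 4, 6, 8")
  ov <- exercise_overrides()
  col <- paste0("met", met)
  out <- baseline
  out[ov$parameter] <- as.list(ov[[col]])
  if (!is.null(scale)) {
    bad <- setdiff(names(scale), names(out))
    if (length(bad))
      stop("unknown parameter(s) in scale: ", paste(bad, collapse = ", "))
    for (nm in names(scale)) out[[nm]] <- out[[nm]] * scale[[nm]]
  }
  out
}

#' Scheduled heart rate for a simulation arm at a MET level
#'
#' The sinus-rhythm validation (SR) and the slower-resting-HR AF arm (SHR)
#' share one chronotropic schedule; the higher-resting-HR AF arm (HHR) starts
#' 30 bpm higher at every grade.
#'
#' @param arm one of `"SR"`, `"SHR"`, `"HHR"`.
#' @param met MET level, one of 1, 4, 6, 8.
#' @return Heart rate in bpm.
#' @export
#' @examples
#' hr_for("SHR", 8)  # 130
#' hr_for("HHR", 4)  # 120
hr_for <- function(arm, met) {
  arm <- match.arg(arm, c("SR", "SHR", "HHR"))
  if (!length(met) == 1 || !met %in% c(1, 4, 6, 8))
    stop("met must be one of 1, 4, 6, 8")
  base <- c(`1` = 70, `4` = 90, `6` = 110, `8` = 130)
  hr <- unname(base[as.character(met)])
  if (arm == "HHR") hr <- hr + 30
  hr
}
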