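#' Variation comparative index
#'
#' Ratio of the absolute exercise-minus-rest variation of a hemodynamic
#' variable in the slower-resting-HR (SHR) arm to the corresponding absolute
#' variation in the higher-resting-HR (HHR) arm:
#' `VCI = |q_ex - q_res|_SHR / |q_ex - q_res|_HHR`.
#' Values above 1 mean the variable changes more upon exertion when the
#' resting heart rate is slower; the magnitudes are compared regardless of
#' the direction of change in each arm.  The index is invariant to affine
#' changes of the variable's units.
#'
#' @param q_ex_shr,q_res_shr exercise and resting means in the SHR arm.
#' @param q_ex_hhr,q_res_hhr exercise and resting means in the HHR arm.
#' @param absolute if `FALSE`, return the signed ratio of the raw
#'   differences instead (exposes opposite-direction changes as negative
#'   values).
#' @return VCI value; `NaN` with a warning when the HHR variation is zero
#'   (undefined index, flagged rather than dropped).
#' @export
#' @examples
#' vci(126.17, 92.26, 124.24, 102.52)  # 1.56 (mean systemic pressure, 8 METs)
vci <- function(q_ex_shr, q_res_shr, q_ex_hhr, q_res_hhr, absolute = TRUE) {
  den <- q_ex_hhr - q_res_hhr
  num <- q_ex_shr - q_res_shr
  out <- if (absolute) abs(num) / abs(den) else num / den
  if (any(den == 0)) {
    warning("undefined VCI: zero HHR variation")
    out[den == 0] <- NaN
  }
  out
}

#' Relevance classification of a VCI value
#'
#' A variation is considered relevant when it exceeds the +/-15% band
#' attributed to measurement variability: `VCI >= 1.15` (greater change in
#' the SHR arm) or `VCI <= 0.85` (greater change in the HHR arm), both
#' thresholds inclusive.
#'
#' @param x VCI value(s).
#' @return character vector: `"relevant-SHR"`, `"relevant-HHR"` or
#'   `"not-relevant"` (`NA` for non-finite input).
#' @export
#' @examples
#' classify_vci(c(1.15, 1.0, 0.85))
classify_vci <- function(x) {
  out <- rep(NA_character_, length(x))
  f <- is.finite(x)
  out[f & x >= 1.15] <- "relevant-SHR"
  out[f & x <= 0.85] <- "relevant-HHR"
  out[f & x > 0.85 & x < 1.15] <- "not-relevant"
  out
}

#' VCI table from per-arm aggregate statistics
#'
#' Computes the VCI of every hemodynamic variable at each exercise grade
#' from the per-MET mean values of the two arms, with relevance flags.
#'
#' @param shr,hhr named lists of `beat_stats` (or data.frames with
#'   `variable`/`mean` columns) keyed `"met1"`, `"met4"`, `"met6"`, `"met8"`.
#' @param variables variables to tabulate (default: the 16 reported ones).
#' @return object of class `vci_table`: data.frame with `variable`,
#'   `VCI_4`, `VCI_6`, `VCI_8` and `relevant` (TRUE when at least one VCI is
#'   relevant).
#' @export
vci_table <- function(shr, hhr, variables = report_variables()) {
  get_mean <- function(stats, v) stats$mean[match(v, stats$variable)]
  res <- data.frame(variable = variables, stringsAsFactors = FALSE)
  for (met in c(4, 6, 8)) {
    col <- paste0("met", met)
    res[[paste0("VCI_", met)]] <- vci(
      get_mean(shr[[col]], variables), get_mean(shr$met1, variables),
      get_mean(hhr[[col]], variables), get_mean(hhr$met1, variables))
  }
  v <- as.matrix(res[paste0("VCI_", c(4, 6, 8))])
  res$relevant <- apply(v, 1, function(x)
    any(is.finite(x) & (x >= 1.15 | x <= 0.85)))
  structure(res, class = c("vci_table", "data.frame"))
}

#' @export
print.vci_table <- function(x, ...) {
  df <- x
  for (col in paste0("VCI_", c(4, 6, 8))) df[[col]] <- round(df[[col]], 2)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

## the 16 variables reported in the AF result tables, in table order
report_variables <- function() {
  c("P_laed", "P_lved", "V_laed", "V_lved",
    "P_sas", "P_sas_dias", "P_sas_syst",
    "P_pas", "P_pas_dias", "P_pas_syst", "P_pvn",
    "SV", "EF", "CO", "TTI_min", "SW_min")
}

#' Parameter sensitivity scan
#'
#' Perturbs each exercise-tuned parameter one at a time by a relative
#' `delta` in both directions, at the resting and vigorous-exercise grades
#' of the SHR arm, and reports the relative change of selected output means
#' against the unperturbed run.  All runs at a given MET share the same RR
#' realization (matched seed), isolating the parameter effect from
#' sampling noise.
#'
#' @param baseline a [cardio_params()] object.
#' @param mets MET levels scanned (default 1 and 8).
#' @param parameters parameters scanned (default: the eight exercise-tuned
#'   ones).
#' @param delta relative perturbation (default 0.05).
#' @param outputs output variables reported.
#' @param n_beats,discard beats simulated / discarded per run.
#' @param seed RNG seed for the shared RR realizations.
#' @param arm simulation arm providing the HR schedule.
#' @return object of class `sensitivity_scan`: data.frame with columns
#'   `parameter`, `direction`, `met`, one column per output (signed relative
#'   change, %).
#' @export
sensitivity_scan <- function(baseline = cardio_params(), mets = c(1, 8),
                             parameters = exercise_overrides()$parameter,
                             delta = 0.05,
                             outputs = c("P_sas", "P_pvn", "P_pas_dias",
                                         "SV"),
                             n_beats = 1000, discard = 200, seed = 1L,
                             arm = "SHR") {
  rows <- list()
  for (met in mets) {
    hr <- hr_for(arm, met)
    rr <- generate_rr(rr_spec(hr, n_beats = n_beats + discard, seed = seed))
    ref_sim <- simulate_cardio(apply_exercise(baseline, met), rr,
                               atria_passive = TRUE)
    ref <- aggregate_beats(ref_sim$beats, discard = discard)
    for (par in parameters) {
      for (dir in c(1, -1)) {
        sc <- stats::setNames(1 + dir * delta, par)
        sim <- tryCatch(
          simulate_cardio(apply_exercise(baseline, met, scale = sc), rr,
                          atria_passive = TRUE),
          error = function(e) stop("sensitivity run failed for ", par,
                                   " (", ifelse(dir > 0, "+", "-"),
                                   100 * delta, "%, ", met, " MET): ",
                                   conditionMessage(e)))
        st <- aggregate_beats(sim$beats, discard = discard)
        chg <- 100 * (st$mean[match(outputs, st$variable)] -
                        ref$mean[match(outputs, ref$variable)]) /
          ref$mean[match(outputs, ref$variable)]
        rows[[length(rows) + 1L]] <- data.frame(
          parameter = par, direction = ifelse(dir > 0, "+", "-"),
          met = met, t(stats::setNames(chg, outputs)),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(do.call(rbind, rows), class = c("sensitivity_scan",
                                            "data.frame"))
}

#' @export
print.sensitivity_scan <- function(x, ...) {
  num <- vapply(x, is.numeric, logical(1)) & names(x) != "met"
  df <- x
  df[num] <- round(df[num], 3)
  print.data.frame(df, row.names = FALSE)
  cat(sprintf("max |relative change| = %.3f%%\n",
              max(abs(as.matrix(x[vapply(x, is.numeric, logical(1)) &
                                    names(x) != "met"])))))
  invisible(x)
}

#' Robustness of the results to reduced atrial compliance
#'
#' Atrial compliance is reduced in fibrillating atria; the model keeps it at
#' its baseline value, which is justified by checking that stiffening both
#' atria (raising their minimum elastance by `reduction`) changes the
#' standard output means by well under 1%.  Runs share the RR realization.
#'
#' @param baseline a [cardio_params()] object.
#' @param reduction relative atrial compliance reduction (default 0.10).
#' @param met MET level of the check.
#' @param n_beats,discard,seed as in [sensitivity_scan()].
#' @param outputs output variables compared.
#' @return maximum absolute relative change (%) over the outputs, with the
#'   per-output changes as attribute `changes`.
#' @export
atrial_compliance_check <- function(baseline = cardio_params(),
                                    reduction = 0.10, met = 1,
                                    n_beats = 1000, discard = 200,
                                    seed = 1L,
                                    outputs = c("P_sas", "P_pvn",
                                                "P_pas_dias", "SV")) {
  hr <- hr_for("SHR", met)
  rr <- generate_rr(rr_spec(hr, n_beats = n_beats + discard, seed = seed))
  p0 <- apply_exercise(baseline, met)
  ## compliance is 1/E for a passive chamber: a 10% compliance reduction is
  ## a 1/(1 - r) increase of the minimum elastance
  p1 <- p0
  p1$E_la_min <- p0$E_la_min / (1 - reduction)
  p1$E_ra_min <- p0$E_ra_min / (1 - reduction)
  s0 <- aggregate_beats(simulate_cardio(p0, rr, atria_passive = TRUE)$beats,
                        discard = discard)
  s1 <- aggregate_beats(simulate_cardio(p1, rr, atria_passive = TRUE)$beats,
                        discard = discard)
  chg <- 100 * (s1$mean[match(outputs, s1$variable)] -
                  s0$mean[match(outputs, s0$variable)]) /
    s0$mean[match(outputs, s0$variable)]
  structure(max(abs(chg)), changes = stats::setNames(chg, outputs))
}
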