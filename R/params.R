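#' Baseline (resting, 1 MET) cardiovascular model parameters
#'
#' Returns the full parameter set of the closed-loop lumped model: per-chamber
#' elastance bounds and unstressed volumes, per-valve flow and leaflet-dynamics
#' coefficients, and the RCL elements of the systemic and pulmonary circuits.
#' Values follow the Korakianitis-Shi four-chamber formulation, with the eight
#' exercise-tuned symbols (`E_lv_max`, `E_rv_max`, `C_sas`, `C_sat`, `R_sar`,
#' `R_scp`, `C_svn`, `R_pcp`) at their resting values.
#'
#' Units: elastances E mmHg/ml, volumes V ml, compliances C ml/mmHg,
#' resistances R mmHg s/ml, inertances L mmHg s^2/ml, valve flow coefficients
#' CQ ml/(s mmHg^0.5), valve angles rad.  Activation timing parameters are
#' fractions of the instantaneous beat period.
#'
#' @param ... named overrides of individual parameters.
#' @return An object of class `cardio_params` (named list).
#' @export
#' @examples
#' p <- cardio_params()
#' p$E_lv_max
cardio_params <- function(...) {
  p <- list(
    ## heart chambers: minimum/maximum elastance, unstressed volume
    E_la_min = 0.15, E_la_max = 0.35, V_la_un = 4,
    E_lv_min = 0.08, E_lv_max = 2.5,  V_lv_un = 5,
    E_ra_min = 0.15, E_ra_max = 0.35, V_ra_un = 4,
    E_rv_min = 0.08, E_rv_max = 1.15, V_rv_un = 10,
    ## valves: orifice flow coefficient, leaflet dynamics (pressure,
    ## friction, blood-velocity, vortex), maximum opening angle
    CQ_mi = 240, Kp_mi = 5500, Kf_mi = 50, Kb_mi = 2, Kv_mi = 3.5,
    theta_max_mi = 75 * pi / 180,
    CQ_ao = 350, Kp_ao = 5500, Kf_ao = 50, Kb_ao = 2, Kv_ao = 3.5,
    theta_max_ao = 75 * pi / 180,
    CQ_ti = 400, Kp_ti = 5500, Kf_ti = 50, Kb_ti = 2, Kv_ti = 3.5,
    theta_max_ti = 75 * pi / 180,
    CQ_po = 350, Kp_po = 5500, Kf_po = 50, Kb_po = 2, Kv_po = 3.5,
    theta_max_po = 75 * pi / 180,
    ## systemic circulation: aortic sinus, artery, arterioles, capillaries,
    ## vein
    C_sas = 0.064, R_sas = 0.003, L_sas = 6.2e-5,
    C_sat = 1.28,  R_sat = 0.05,  L_sat = 1.7e-3,
    R_sar = 0.44,  R_scp = 0.4576,
    C_svn = 20.5,  R_svn = 0.075,
    ## pulmonary circulation
    C_pas = 0.18, R_pas = 0.002, L_pas = 5.2e-5,
    C_pat = 3.8,  R_pat = 0.01,  L_pat = 1.7e-3,
    R_par = 0.025, R_pcp = 0.0385,
    C_pvn = 20.5, R_pvn = 0.006,
    ## activation timing: systolic durations scale with sqrt(RR) (Bazett),
    ## anchored at the resting period rr_ref; atrial bump scales with RR
    ts1_frac = 0.3, ts2_frac = 0.45, tpwb_frac = 0.92, tpww_frac = 0.09,
    rr_ref = 60 / 70
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  structure(p, class = "cardio_params")
}

#' @export
print.cardio_params <- function(x, ...) {
  cat("Lumped cardiovascular model parameters (", length(x), " values)\n",
      sep = "")
  cat(sprintf("  E_lv,max %.3g  E_rv,max %.3g mmHg/ml; C_svn %.3g ml/mmHg\n",
              x$E_lv_max, x$E_rv_max, x$C_svn))
  cat(sprintf("  R_sar %.4g  R_scp %.4g  R_pcp %.4g mmHg s/ml\n",
              x$R_sar, x$R_scp, x$R_pcp))
  invisible(x)
}

validate_params <- function(p) {
  stopifnot(inherits(p, "cardio_params"))
  pos <- c("C_sas", "C_sat", "C_svn", "C_pas", "C_pat", "C_pvn",
           "R_sas", "R_sat", "R_sar", "R_scp", "R_svn",
           "R_pas", "R_pat", "R_par", "R_pcp", "R_pvn",
           "L_sas", "L_sat", "L_pas", "L_pat",
           "CQ_mi", "CQ_ao", "CQ_ti", "CQ_po")
  for (nm in pos)
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop("parameter ", nm, " must be strictly positive")
  for (ch in c("la", "lv", "ra", "rv")) {
    emin <- p[[paste0("E_", ch, "_min")]]
    emax <- p[[paste0("E_", ch, "_max")]]
    if (!(emax >= emin && emin > 0))
      stop("chamber ", ch, ": need E_max >= E_min > 0")
  }
  invisible(p)
}

## fixed packing order shared with src/cardio.c
pack_order <- function() {
  c("E_la_min", "E_la_max", "V_la_un",
    "E_lv_min", "E_lv_max", "V_lv_un",
    "E_ra_min", "E_ra_max", "V_ra_un",
    "E_rv_min", "E_rv_max", "V_rv_un",
    "CQ_mi", "Kp_mi", "Kf_mi", "Kb_mi", "Kv_mi", "theta_max_mi",
    "CQ_ao", "Kp_ao", "Kf_ao", "Kb_ao", "Kv_ao", "theta_max_ao",
    "CQ_ti", "Kp_ti", "Kf_ti", "Kb_ti", "Kv_ti", "theta_max_ti",
    "CQ_po", "Kp_po", "Kf_po", "Kb_po", "Kv_po", "theta_max_po",
    "C_sas", "R_sas", "L_sas", "C_sat", "R_sat", "L_sat",
    "R_sar", "R_scp", "C_svn", "R_svn",
    "C_pas", "R_pas", "L_pas", "C_pat", "R_pat", "L_pat",
    "R_par", "R_pcp", "C_pvn", "R_pvn",
    "ts1_frac", "ts2_frac", "tpwb_frac", "tpww_frac", "rr_ref")
}

MAXBEATS_CHUNK <- 400L

## parameter vector for the compiled rhs: model params, passive-atria flag,
## beat count and chunk-local beat boundary times, zero-padded to the fixed
## length expected by the DLL
pack_parms <- function(p, beat_t0, atria_passive) {
  head <- c(unlist(p[pack_order()], use.names = FALSE),
            as.numeric(atria_passive),
            length(beat_t0) - 1L, beat_t0)
  n <- 63L + MAXBEATS_CHUNK + 1L
  c(head, numeric(n - length(head)))
}

#' Write / read a parameter set as a flat key-value YAML file
#'
#' One key per model symbol, values in the units documented in
#' [cardio_params()].  Files written by [write_params()] restore to an
#' identical parameter object.
#'
#' @param params a [cardio_params()] object.
#' @param file path to a YAML file.
#' @return `read_params` returns a `cardio_params` object.
#' @export
write_params <- function(params, file) {
  validate_params(params)
  yaml::write_yaml(lapply(unclass(params), unname), file, precision = 15)
  invisible(file)
}

#' @rdname write_params
#' @export
read_params <- function(file) {
  vals <- yaml::read_yaml(file)
  do.call(cardio_params, vals)
}
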