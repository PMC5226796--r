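## State layout shared with src/cardio.c
state_names <- function() {
  c("V_la", "V_lv", "V_ra", "V_rv",
    "theta_mi", "omega_mi", "theta_ao", "omega_ao",
    "theta_ti", "omega_ti", "theta_po", "omega_po",
    "P_sas", "Q_sas", "P_sat", "Q_sat", "P_svn",
    "P_pas", "Q_pas", "P_pat", "Q_pat", "P_pvn")
}

aux_names <- function() {
  c("P_la", "P_lv", "P_ra", "P_rv", "Q_mi", "Q_ao", "Q_ti", "Q_po",
    "e_v", "e_a")
}

#' Default initial state
#'
#' A physiologic end-diastolic-like starting point (valves closed, chambers
#' filled, venous reservoirs charged).  Steady-state statistics of the closed
#' loop depend on the initial state only through the total stressed volume it
#' implies; this default is calibrated so that the resting sinus-rhythm run
#' reproduces normal resting hemodynamics (cardiac output near 5.2 l/min,
#' mean systemic arterial pressure near 97 mmHg).
#'
#' @return named numeric state vector of length 22.
#' @export
default_state <- function() {
  structure(
    c(V_la = 60, V_lv = 130, V_ra = 60, V_rv = 130,
      theta_mi = 0, omega_mi = 0, theta_ao = 0, omega_ao = 0,
      theta_ti = 0, omega_ti = 0, theta_po = 0, omega_po = 0,
      P_sas = 80, Q_sas = 0, P_sat = 78, Q_sat = 0, P_svn = 12.8,
      P_pas = 13, Q_pas = 0, P_pat = 12, Q_pat = 0, P_pvn = 10),
    names = state_names())
}

#' Initial state with conserved blood volume
#'
#' Builds the starting state for a simulation under arbitrary parameters,
#' holding total stressed blood volume at the calibrated resting value: the
#' circulating volume does not change with exercise, so when parameter
#' overrides alter compliances (venoconstriction shrinks `C_svn` four-fold
#' at vigorous exercise) the systemic venous pressure of the initial state
#' is adjusted to carry the same volume.  Without this correction an
#' exercise run would silently start hypovolemic.
#'
#' @param params a [cardio_params()] object.
#' @param total_stressed target stressed volume (ml); default: the volume
#'   implied by [default_state()] under baseline parameters.
#' @return named state vector of length 22.
#' @export
initial_state <- function(params,
                          total_stressed =
                            total_stressed_volume(default_state(),
                                                  cardio_params())) {
  y <- default_state()
  v <- total_stressed_volume(y, params)
  y[["P_svn"]] <- y[["P_svn"]] + (total_stressed - v) / params$C_svn
  if (y[["P_svn"]] <= 0)
    stop("target stressed volume infeasible for these compliances")
  y
}

#' Total stressed blood volume of a state
#'
#' Sum of chamber volumes above their unstressed volumes plus the volume
#' stored in every compliant segment (`C x P`).  The model conserves this
#' quantity exactly at the equation level, so its numerical drift measures
#' integration error.
#'
#' @param state named state vector (or matrix with state columns).
#' @param params a [cardio_params()] object.
#' @return stressed volume (ml).
#' @export
total_stressed_volume <- function(state, params) {
  g <- function(nm) if (is.matrix(state)) state[, nm] else state[[nm]]
  (g("V_la") - params$V_la_un) + (g("V_lv") - params$V_lv_un) +
    (g("V_ra") - params$V_ra_un) + (g("V_rv") - params$V_rv_un) +
    params$C_sas * g("P_sas") + params$C_sat * g("P_sat") +
    params$C_svn * g("P_svn") + params$C_pas * g("P_pas") +
    params$C_pat * g("P_pat") + params$C_pvn * g("P_pvn")
}

#' Model right-hand side (reference R implementation)
#'
#' Time derivative of the 22-dimensional state: elastance chambers
#' (`P = E(t) (V - V_un)`), orifice valve flows, second-order leaflet
#' dynamics with hard stops, and the systemic/pulmonary RCL segments
#' (`C dP/dt = Q_in - Q_out`, `L dQ/dt = dP - R Q`).  This readable version
#' is numerically identical to the compiled rhs used by [simulate_cardio()]
#' and serves as its cross-check.
#'
#' @param t_in_beat time since beat onset (s).
#' @param state named numeric state vector.
#' @param params a [cardio_params()] object.
#' @param rr current beat period (s).
#' @param atria_passive if `TRUE` atrial elastance stays at its minimum.
#' @return list: `deriv` (named derivative vector) and `aux` (instantaneous
#'   chamber pressures, valve flows and activations).
#' @export
cardio_rhs <- function(t_in_beat, state, params, rr, atria_passive = FALSE) {
  if (!all(is.finite(state)))
    stop("non-finite state component: ",
         paste(state_names()[!is.finite(state)], collapse = ", "))
  s <- as.list(state)
  names(s) <- state_names()
  p <- params

  ev <- activation_ventricle(t_in_beat, rr, p$ts1_frac, p$ts2_frac,
                             p$rr_ref)
  ea <- if (atria_passive) 0
        else activation_atrium(t_in_beat, rr, p$tpwb_frac, p$tpww_frac)

  P_la <- (p$E_la_min + ea * (p$E_la_max - p$E_la_min)) * (s$V_la - p$V_la_un)
  P_lv <- (p$E_lv_min + ev * (p$E_lv_max - p$E_lv_min)) * (s$V_lv - p$V_lv_un)
  P_ra <- (p$E_ra_min + ea * (p$E_ra_max - p$E_ra_min)) * (s$V_ra - p$V_ra_un)
  P_rv <- (p$E_rv_min + ev * (p$E_rv_max - p$E_rv_min)) * (s$V_rv - p$V_rv_un)

  Q_mi <- valve_flow(P_la - P_lv, s$theta_mi, p$CQ_mi, p$theta_max_mi)
  Q_ao <- valve_flow(P_lv - s$P_sas, s$theta_ao, p$CQ_ao, p$theta_max_ao)
  Q_ti <- valve_flow(P_ra - P_rv, s$theta_ti, p$CQ_ti, p$theta_max_ti)
  Q_po <- valve_flow(P_rv - s$P_pas, s$theta_po, p$CQ_po, p$theta_max_po)

  Q_svn <- (s$P_svn - P_ra) / p$R_svn
  Q_pvn <- (s$P_pvn - P_la) / p$R_pvn

  K <- function(v) list(Kp = p[[paste0("Kp_", v)]], Kf = p[[paste0("Kf_", v)]],
                        Kb = p[[paste0("Kb_", v)]], Kv = p[[paste0("Kv_", v)]])
  vmi <- valve_dyn_clamped(s$theta_mi, s$omega_mi, P_la - P_lv, Q_mi,
                           K("mi"), p$theta_max_mi)
  vao <- valve_dyn_clamped(s$theta_ao, s$omega_ao, P_lv - s$P_sas, Q_ao,
                           K("ao"), p$theta_max_ao)
  vti <- valve_dyn_clamped(s$theta_ti, s$omega_ti, P_ra - P_rv, Q_ti,
                           K("ti"), p$theta_max_ti)
  vpo <- valve_dyn_clamped(s$theta_po, s$omega_po, P_rv - s$P_pas, Q_po,
                           K("po"), p$theta_max_po)

  deriv <- c(
    V_la = Q_pvn - Q_mi,
    V_lv = Q_mi - Q_ao,
    V_ra = Q_svn - Q_ti,
    V_rv = Q_ti - Q_po,
    theta_mi = vmi[1], omega_mi = vmi[2],
    theta_ao = vao[1], omega_ao = vao[2],
    theta_ti = vti[1], omega_ti = vti[2],
    theta_po = vpo[1], omega_po = vpo[2],
    P_sas = (Q_ao - s$Q_sas) / p$C_sas,
    Q_sas = (s$P_sas - s$P_sat - p$R_sas * s$Q_sas) / p$L_sas,
    P_sat = (s$Q_sas - s$Q_sat) / p$C_sat,
    Q_sat = (s$P_sat - s$P_svn - (p$R_sat + p$R_sar + p$R_scp) * s$Q_sat) /
      p$L_sat,
    P_svn = (s$Q_sat - Q_svn) / p$C_svn,
    P_pas = (Q_po - s$Q_pas) / p$C_pas,
    Q_pas = (s$P_pas - s$P_pat - p$R_pas * s$Q_pas) / p$L_pas,
    P_pat = (s$Q_pas - s$Q_pat) / p$C_pat,
    Q_pat = (s$P_pat - s$P_pvn - (p$R_pat + p$R_par + p$R_pcp) * s$Q_pat) /
      p$L_pat,
    P_pvn = (s$Q_pat - Q_pvn) / p$C_pvn)

  list(deriv = deriv,
       aux = c(P_la = P_la, P_lv = P_lv, P_ra = P_ra, P_rv = P_rv,
               Q_mi = Q_mi, Q_ao = Q_ao, Q_ti = Q_ti, Q_po = Q_po,
               e_v = ev, e_a = ea))
}
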