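## falling crossing of x below thr: first index k with x[k] >= thr,
## x[k+1] < thr; returns interpolation weight too
first_falling_crossing <- function(x, thr) {
  k <- which(x[-length(x)] >= thr & x[-1] < thr)
  if (!length(k)) return(NULL)
  k <- k[1]
  w <- (x[k] - thr) / (x[k] - x[k + 1])
  list(k = k, w = w)
}

#' Detect end-diastole and end-systole per beat
#'
#' End-diastole is the instant of mitral valve closure and end-systole the
#' instant of aortic valve closure, located as the first downward crossing of
#' the leaflet angle below 1% of its fully-open value within each beat.
#' Beats in which either valve never closes (e.g. a valve that never opened)
#' are flagged and excluded from statistics.
#'
#' @param traj a `cardio_traj` trajectory (see [simulate_cardio()]).
#' @return data.frame with columns `beat`, `t_ed`, `t_es`, `ok`.
#' @export
detect_beat_events <- function(traj) {
  stopifnot(inherits(traj, "cardio_traj"))
  nb <- length(traj$rr)
  idx <- c(traj$index, nrow(traj$mat) + 1L)
  th_mi <- traj$mat[, "theta_mi"]
  th_ao <- traj$mat[, "theta_ao"]
  time <- traj$time
  thr_mi <- 0.01 * traj$params$theta_max_mi
  thr_ao <- 0.01 * traj$params$theta_max_ao
  t_ed <- t_es <- rep(NA_real_, nb)
  ok <- logical(nb)
  for (b in seq_len(nb)) {
    r <- idx[b]:(idx[b + 1] - 1L)
    ed <- first_falling_crossing(th_mi[r], thr_mi)
    es <- first_falling_crossing(th_ao[r], thr_ao)
    if (!is.null(ed) && !is.null(es)) {
      t_ed[b] <- time[r[ed$k]] + ed$w * (time[r[ed$k + 1]] - time[r[ed$k]])
      t_es[b] <- time[r[es$k]] + es$w * (time[r[es$k + 1]] - time[r[es$k]])
      ok[b] <- TRUE
    }
  }
  data.frame(beat = traj$beat_offset + seq_len(nb), t_ed = t_ed,
             t_es = t_es, ok = ok)
}

## linear interpolation of column `col` at crossing cr within beat rows r
interp_at <- function(mat, col, r, cr) {
  x <- mat[r, col]
  x[cr$k] + cr$w * (x[cr$k + 1] - x[cr$k])
}

#' Per-beat hemodynamic metrics
#'
#' For every beat of a trajectory: end-diastolic left atrial and ventricular
#' pressures and volumes (at mitral closure), end-systolic LV volume (at
#' aortic closure), stroke volume `SV = V_lved - V_lves`, ejection fraction
#' `EF = SV / V_lved x 100`, per-beat cardiac output `SV / RR` rescaled to
#' l/min, stroke work (shoelace area of the closed LV pressure-volume loop,
#' 1 mmHg ml = 1.33322e-4 J) per minute, tension-time index per minute
#' (time-mean LV pressure x 60), and systolic/diastolic/mean systemic and
#' pulmonary arterial pressures plus mean pulmonary venous pressure over the
#' beat window.
#'
#' @param traj a `cardio_traj` trajectory.
#' @param events optional result of [detect_beat_events()] (recomputed if
#'   missing).
#' @return data.frame with one row per beat; beats without valid valve
#'   events carry `NA` metrics and `ok = FALSE`.
#' @export
beat_metrics <- function(traj, events = detect_beat_events(traj)) {
  stopifnot(inherits(traj, "cardio_traj"))
  nb <- length(traj$rr)
  idx <- c(traj$index, nrow(traj$mat) + 1L)
  mat <- traj$mat
  thr_mi <- 0.01 * traj$params$theta_max_mi
  thr_ao <- 0.01 * traj$params$theta_max_ao

  out <- matrix(NA_real_, nb, 18)
  colnames(out) <- c("P_laed", "P_lved", "V_laed", "V_lved", "V_lves",
                     "SV", "EF", "CO", "SW_min", "TTI_min",
                     "P_sas_syst", "P_sas_dias", "P_sas",
                     "P_pas_syst", "P_pas_dias", "P_pas", "P_pvn", "RR")
  for (b in seq_len(nb)) {
    r <- idx[b]:(idx[b + 1] - 1L)
    rr <- traj$rr[b]
    out[b, "RR"] <- rr
    psas <- mat[r, "P_sas"]
    ppas <- mat[r, "P_pas"]
    out[b, c("P_sas_syst", "P_sas_dias", "P_sas")] <-
      c(max(psas), min(psas), mean(psas))
    out[b, c("P_pas_syst", "P_pas_dias", "P_pas")] <-
      c(max(ppas), min(ppas), mean(ppas))
    out[b, "P_pvn"] <- mean(mat[r, "P_pvn"])
    out[b, "TTI_min"] <- mean(mat[r, "P_lv"]) * 60

    if (!events$ok[b]) next
    ed <- first_falling_crossing(mat[r, "theta_mi"], thr_mi)
    es <- first_falling_crossing(mat[r, "theta_ao"], thr_ao)
    v_lved <- interp_at(mat, "V_lv", r, ed)
    v_lves <- interp_at(mat, "V_lv", r, es)
    sv <- v_lved - v_lves
    out[b, "P_laed"] <- interp_at(mat, "P_la", r, ed)
    out[b, "P_lved"] <- interp_at(mat, "P_lv", r, ed)
    out[b, "V_laed"] <- interp_at(mat, "V_la", r, ed)
    out[b, "V_lved"] <- v_lved
    out[b, "V_lves"] <- v_lves
    out[b, "SV"] <- sv
    out[b, "EF"] <- 100 * sv / v_lved
    out[b, "CO"] <- sv / rr * 60 / 1000
    sw_mmhg_ml <- pv_loop_area(mat[r, "V_lv"], mat[r, "P_lv"])
    out[b, "SW_min"] <- sw_mmhg_ml * 1.33322e-4 / rr * 60
  }
  df <- data.frame(beat = traj$beat_offset + seq_len(nb), out,
                   ok = events$ok)
  df
}

#' Signed area of a closed pressure-volume loop
#'
#' Shoelace polygon area of the cycle traced in the (V, P) plane, closing
#' the polygon between last and first sample.  The physiologic LV loop is
#' traversed counter-clockwise (filling at low pressure, ejection at high
#' pressure), giving a positive area.
#'
#' @param v,p volume and pressure samples over one beat.
#' @return area in the units of `v * p` (mmHg ml for an LV loop).
#' @export
pv_loop_area <- function(v, p) {
  stopifnot(length(v) == length(p), length(v) >= 3)
  j <- c(seq_along(v)[-1], 1L)
  0.5 * sum(v * p[j] - v[j] * p)
}

#' Aggregate per-beat metrics
#'
#' Mean and population standard deviation of every metric over the included
#' beats, after discarding an initial transient and any flagged beats, plus
#' a stationarity diagnostic (relative difference between first-half and
#' second-half means).
#'
#' @param beats data.frame from [beat_metrics()] (or `cardio_sim$beats`).
#' @param discard number of initial beats to drop.
#' @return object of class `beat_stats`: data.frame with columns `variable`,
#'   `mean`, `sd`, plus attributes `n_beats`, `n_excluded`,
#'   `stationarity` (named vector of half-sample relative differences).
#' @export
aggregate_beats <- function(beats, discard = 0) {
  stopifnot(is.data.frame(beats))
  keep <- beats[beats$beat > min(beats$beat) - 1 + discard & beats$ok, ,
                drop = FALSE]
  if (!nrow(keep)) stop("no beats left after discard/exclusion")
  vars <- setdiff(names(keep), c("beat", "ok"))
  m <- vapply(keep[vars], mean, numeric(1))
  sdev <- vapply(keep[vars], function(x) {
    mu <- mean(x); sqrt(mean((x - mu)^2))
  }, numeric(1))
  h <- nrow(keep) %/% 2
  stat <- vapply(vars, function(v) {
    m1 <- mean(keep[[v]][seq_len(h)])
    m2 <- mean(keep[[v]][(h + 1):nrow(keep)])
    abs(m2 - m1) / max(abs(m[[v]]), .Machine$double.eps)
  }, numeric(1))
  structure(data.frame(variable = vars, mean = unname(m), sd = unname(sdev),
                       stringsAsFactors = FALSE),
            n_beats = nrow(keep),
            n_excluded = sum(!beats$ok),
            stationarity = stat,
            class = c("beat_stats", "data.frame"))
}

#' @export
print.beat_stats <- function(x, ...) {
  cat("Beat-wise hemodynamic statistics over", attr(x, "n_beats"),
      "beats (", attr(x, "n_excluded"), "excluded )\n")
  print.data.frame(cbind(x["variable"],
                         round(x[c("mean", "sd")], 3)), row.names = FALSE)
  invisible(x)
}
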