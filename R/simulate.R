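#' Simulate the closed-loop model over a prescribed RR series
#'
#' Integrates the 22-state lumped cardiovascular model beat by beat: the
#' activation clock restarts at every beat boundary and the elastance
#' schedule is rescaled to that beat's RR interval.  The stiff ODE system is
#' solved with an adaptive variable-order multistep scheme (deSolve's Adams
#' or BDF families) running the
#' compiled model code, in chunks of beats to bound memory; per-beat
#' hemodynamic metrics are extracted on the fly.
#'
#' @param params a [cardio_params()] object.
#' @param rr numeric vector of beat durations in seconds (all positive), or
#'   an `rr_series` object from [generate_rr()].
#' @param init initial state; by default [initial_state()] under
#'   `params`, preserving the calibrated total stressed blood volume.
#' @param atria_passive if `TRUE`, both atria stay at minimum elastance for
#'   the whole beat (atrial fibrillation).
#' @param rtol,atol solver tolerances.
#' @param method adaptive multistep solver: `"adams"` (variable-order
#'   Adams, default) or `"bdf"` (stiff backward differentiation, slower but
#'   robust to much stiffer parameter regimes).
#' @param n_out output samples per beat used for metric extraction.
#' @param keep_trajectory if `TRUE`, the full sampled trajectory is retained
#'   (memory grows with beats); otherwise only per-beat metrics are kept.
#' @param chunk_beats beats per solver call (internal batching).
#' @return An object of class `cardio_sim`: list with `beats` (data.frame of
#'   per-beat metrics, see [beat_metrics()]), `rr`, `final_state`, solver
#'   diagnostics, and optionally `trajectory` (a `cardio_traj`).
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_cardio(cardio_params(), rep(60 / 70, 30))
#' summary(sim, discard = 20)
#' }
simulate_cardio <- function(params, rr, init = initial_state(params),
                            atria_passive = FALSE,
                            rtol = 1e-6, atol = 1e-8, n_out = 100,
                            keep_trajectory = FALSE, chunk_beats = 200,
                            method = c("adams", "bdf")) {
  validate_params(params)
  method <- match.arg(method)
  if (inherits(rr, "rr_series")) rr <- rr$rr
  rr <- as.numeric(rr)
  if (!length(rr) || any(!is.finite(rr)) || any(rr <= 0))
    stop("rr must be a non-empty vector of positive beat durations")
  stopifnot(length(init) == 22L, chunk_beats >= 1, n_out >= 8)
  chunk_beats <- min(chunk_beats, MAXBEATS_CHUNK)

  n_beats <- length(rr)
  state <- unname(as.numeric(init))
  starts <- seq(1L, n_beats, by = chunk_beats)
  beats_list <- vector("list", length(starts))
  traj_list <- if (keep_trajectory) vector("list", length(starts))
  steps <- 0; t_offset <- 0

  for (ci in seq_along(starts)) {
    b0 <- starts[ci]
    b1 <- min(b0 + chunk_beats - 1L, n_beats)
    rr_c <- rr[b0:b1]
    t0 <- c(0, cumsum(rr_c))
    times <- unlist(lapply(seq_along(rr_c), function(i)
      t0[i] + rr_c[i] * (0:(n_out - 1)) / n_out), use.names = FALSE)
    times <- c(times, t0[length(t0)])

    out <- deSolve::ode(
      y = state, times = times, func = "cardio_derivs",
      parms = pack_parms(params, t0, atria_passive),
      dllname = "afcirc", initfunc = "cardio_initmod",
      nout = 10L, outnames = aux_names(), method = method,
      rtol = rtol, atol = atol, maxsteps = 50000)

    if (nrow(out) < length(times) || any(!is.finite(out)))
      stop("solver failed near beat ",
           b0 + max(0L, (nrow(out) - 1L) %/% n_out))
    ist <- attributes(out)$istate
    if (length(ist) >= 3) steps <- steps + ist[3]

    mat <- out[seq_len(nrow(out) - 1L), -1L, drop = FALSE]
    colnames(mat) <- c(state_names(), aux_names())
    if (any(mat[, c("V_la", "V_lv", "V_ra", "V_rv")] < 0))
      stop("negative chamber volume near beat ", b0)

    traj <- new_cardio_traj(
      time = t_offset + out[seq_len(nrow(out) - 1L), 1L],
      mat = mat,
      index = seq(1L, length(rr_c) * n_out, by = n_out),
      rr = rr_c, beat_offset = b0 - 1L, params = params,
      atria_passive = atria_passive)

    beats_list[[ci]] <- beat_metrics(traj)
    if (keep_trajectory) traj_list[[ci]] <- traj

    state <- unname(out[nrow(out), 1L + seq_len(22L)])
    t_offset <- t_offset + t0[length(t0)]
  }

  beats <- do.call(rbind, beats_list)
  trajectory <- if (keep_trajectory) bind_traj(traj_list)
  structure(list(beats = beats, rr = rr, params = params,
                 atria_passive = atria_passive,
                 final_state = structure(state, names = state_names()),
                 trajectory = trajectory,
                 solver = list(rtol = rtol, atol = atol, n_out = n_out,
                               steps = unname(steps))),
            class = "cardio_sim")
}

new_cardio_traj <- function(time, mat, index, rr, beat_offset, params,
                            atria_passive) {
  structure(list(time = time, mat = mat, index = index, rr = rr,
                 beat_offset = beat_offset, params = params,
                 atria_passive = atria_passive),
            class = "cardio_traj")
}

bind_traj <- function(traj_list) {
  n_prev <- cumsum(c(0L, vapply(traj_list, function(x) nrow(x$mat),
                                integer(1))))
  idx <- unlist(lapply(seq_along(traj_list), function(i)
    traj_list[[i]]$index + n_prev[i]), use.names = FALSE)
  t1 <- traj_list[[1]]
  new_cardio_traj(
    time = unlist(lapply(traj_list, `[[`, "time"), use.names = FALSE),
    mat = do.call(rbind, lapply(traj_list, `[[`, "mat")),
    index = idx,
    rr = unlist(lapply(traj_list, `[[`, "rr"), use.names = FALSE),
    beat_offset = t1$beat_offset, params = t1$params,
    atria_passive = t1$atria_passive)
}

#' @export
print.cardio_sim <- function(x, ...) {
  cat("Lumped cardiovascular simulation:",
      nrow(x$beats), "beats,",
      if (x$atria_passive) "passive atria (AF)" else "sinus rhythm", "\n")
  cat(sprintf("  mean RR %.4f s (HR %.1f bpm), solver steps %d\n",
              mean(x$rr), 60 / mean(x$rr), x$solver$steps))
  invisible(x)
}

#' @export
summary.cardio_sim <- function(object, discard = 0, ...) {
  aggregate_beats(object$beats, discard = discard)
}

#' @export
plot.cardio_sim <- function(x, beats = NULL, ...) {
  if (is.null(x$trajectory))
    stop("simulation was run with keep_trajectory = FALSE")
  tr <- x$trajectory
  nb <- length(tr$rr)
  if (is.null(beats)) beats <- max(1, nb - 4):nb
  idx <- c(tr$index, nrow(tr$mat) + 1L)
  rows <- unlist(lapply(beats, function(b) idx[b]:(idx[b + 1] - 1L)))
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  graphics::plot(tr$mat[rows, "V_lv"], tr$mat[rows, "P_lv"], type = "l",
                 xlab = "LV volume [ml]", ylab = "LV pressure [mmHg]",
                 main = "PV loop")
  graphics::plot(tr$time[rows], tr$mat[rows, "P_sas"], type = "l",
                 xlab = "time [s]", ylab = "P_sas [mmHg]",
                 main = "Systemic arterial pressure")
  invisible(x)
}

#' Export a sampled trajectory as a data.frame / CSV
#'
#' @param traj a `cardio_traj` (from [simulate_cardio()] with
#'   `keep_trajectory = TRUE`).
#' @param file optional path; when given, the table is written as CSV.
#' @return data.frame with time, state and derived-pressure columns.
#' @export
trajectory_table <- function(traj, file = NULL) {
  stopifnot(inherits(traj, "cardio_traj"))
  df <- data.frame(time = traj$time, traj$mat, check.names = FALSE)
  if (!is.null(file)) utils::write.csv(df, file, row.names = FALSE)
  df
}
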