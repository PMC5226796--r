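# Shared fixtures: small synthetic trajectories and cached short simulations.

# Synthetic trajectory with prescribed signals; every unspecified column is
# zero.  `signals` is a named list of length-n vectors.
make_traj <- function(n_per_beat, rr, signals, params = cardio_params(),
                      atria_passive = FALSE) {
  nb <- length(rr)
  n <- nb * n_per_beat
  t0 <- c(0, cumsum(rr))
  time <- unlist(lapply(seq_len(nb), function(i)
    t0[i] + rr[i] * (0:(n_per_beat - 1)) / n_per_beat))
  mat <- matrix(0, n, length(afcirc:::state_names()) +
                  length(afcirc:::aux_names()),
                dimnames = list(NULL, c(afcirc:::state_names(),
                                        afcirc:::aux_names())))
  for (nm in names(signals)) mat[, nm] <- signals[[nm]]
  afcirc:::new_cardio_traj(time = time, mat = mat,
                           index = seq(1L, n, by = n_per_beat), rr = rr,
                           beat_offset = 0L, params = params,
                           atria_passive = atria_passive)
}

# One short resting sinus-rhythm simulation reused across test files.
sim_cache <- new.env(parent = emptyenv())

rest_sim <- function() {
  if (is.null(sim_cache$rest))
    sim_cache$rest <- simulate_cardio(cardio_params(), rep(60 / 70, 60),
                                      keep_trajectory = TRUE)
  sim_cache$rest
}
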