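test_that("valve-closure events are located at prescribed switch times", {
  th_max <- cardio_params()$theta_max_mi
  n <- 100
  t <- (0:(n - 1)) / n
  traj <- make_traj(n, rr = 1, signals = list(
    theta_mi = ifelse(t < 0.05, th_max, 0),
    theta_ao = ifelse(t >= 0.10 & t < 0.45, th_max, 0)))
  ev <- detect_beat_events(traj)
  expect_true(ev$ok)
  expect_equal(ev$t_ed, 0.05, tolerance = 5e-3)
  expect_equal(ev$t_es, 0.45, tolerance = 5e-3)
})

test_that("a beat whose aortic valve never opens is flagged and excluded", {
  th_max <- cardio_params()$theta_max_mi
  n <- 50
  t <- (0:(n - 1)) / n
  traj <- make_traj(n, rr = 1, signals = list(
    theta_mi = ifelse(t < 0.05, th_max, 0),
    theta_ao = 0 * t))
  ev <- detect_beat_events(traj)
  expect_false(ev$ok)
  bm <- beat_metrics(traj)
  expect_true(is.na(bm$SV))
  expect_false(bm$ok)
  expect_error(aggregate_beats(bm), "no beats left")
})

test_that("beat metrics follow their defining formulas on a constructed
          trajectory", {
  th_max <- cardio_params()$theta_max_mi
  n <- 200
  t <- (0:(n - 1)) / n
  traj <- make_traj(n, rr = 1, signals = list(
    theta_mi = ifelse(t < 0.05, th_max, 0),
    theta_ao = ifelse(t >= 0.10 & t < 0.45, th_max, 0),
    V_lv = 130 - 80 * t,
    P_lv = rep(50, n),
    P_sas = 90 + 20 * sin(2 * pi * t)))
  bm <- beat_metrics(traj)
  expect_equal(bm$V_lved, 130 - 80 * 0.05, tolerance = 0.1)
  expect_equal(bm$SV, 80 * 0.40, tolerance = 0.1)
  expect_equal(bm$EF, 100 * bm$SV / bm$V_lved)
  expect_equal(bm$CO, bm$SV / 1 * 60 / 1000)
  expect_equal(bm$TTI_min, 50 * 60, tolerance = 1e-6)
  expect_equal(bm$SW_min, 0, tolerance = 1e-6)  # flat P: zero loop area
  expect_equal(bm$P_sas_syst, 110, tolerance = 0.01)
  expect_equal(bm$P_sas_dias, 70, tolerance = 0.01)
  expect_equal(bm$P_sas, 90, tolerance = 0.01)
})

test_that("PV-loop area matches the shoelace oracle on a rectangle", {
  # 50 ml x 80 mmHg rectangle, counter-clockwise as a physiologic LV loop
  v <- c(seq(60, 110, length.out = 26)[-26],
         rep(110, 25),
         seq(110, 60, length.out = 26)[-26],
         rep(60, 25))
  p <- c(rep(5, 25),
         seq(5, 85, length.out = 26)[-26],
         rep(85, 25),
         seq(85, 5, length.out = 26)[-26])
  a <- pv_loop_area(v, p)
  expect_equal(a, 4000)
  expect_equal(a * 1.33322e-4, 0.533, tolerance = 1e-3)  # joules
  # reversing orientation flips the sign
  expect_equal(pv_loop_area(rev(v), rev(p)), -4000)
})

test_that("stroke work equals the trapezoid line integral on refined
          output grids", {
  sim <- simulate_cardio(cardio_params(), rep(60 / 70, 25), n_out = 400)
  b <- sim$beats[sim$beats$beat > 20 & sim$beats$ok, ]
  # recompute via trapezoid integral of P dV on the same grid
  tr <- simulate_cardio(cardio_params(), rep(60 / 70, 25), n_out = 400,
                        keep_trajectory = TRUE)$trajectory
  idx <- c(tr$index, nrow(tr$mat) + 1L)
  for (beat in b$beat) {
    r <- idx[beat]:(idx[beat + 1] - 1L)
    vv <- c(tr$mat[r, "V_lv"], tr$mat[r[1], "V_lv"])
    pp <- c(tr$mat[r, "P_lv"], tr$mat[r[1], "P_lv"])
    trap <- sum(0.5 * (pp[-1] + pp[-length(pp)]) * diff(vv))
    sw_trap <- trap * 1.33322e-4 / tr$rr[beat] * 60
    expect_equal(b$SW_min[b$beat == beat], abs(sw_trap),
                 tolerance = 5e-3)
  }
})

test_that("per-beat cardiac output equals SV x HR under constant RR", {
  sim <- rest_sim()
  b <- sim$beats[sim$beats$ok, ]
  expect_equal(b$CO, b$SV * (60 / b$RR) / 1000)
})

test_that("aggregated pressures preserve systolic >= mean >= diastolic", {
  s <- summary(rest_sim(), discard = 20)
  g <- function(v) s$mean[s$variable == v]
  expect_gt(g("P_sas_syst"), g("P_sas"))
  expect_gt(g("P_sas"), g("P_sas_dias"))
  expect_gt(g("P_pas_syst"), g("P_pas"))
  expect_gt(g("P_pas"), g("P_pas_dias"))
})

test_that("aggregation computes mean, population SD and the stationarity
          diagnostic", {
  beats <- data.frame(beat = 1:3, x = c(2, 4, 6), ok = TRUE)
  s <- aggregate_beats(beats)
  expect_equal(s$mean[s$variable == "x"], 4)
  expect_equal(s$sd[s$variable == "x"], sqrt(8 / 3))
  expect_equal(attr(s, "n_beats"), 3L)

  same <- data.frame(beat = 1:5, x = rep(3.3, 5), ok = TRUE)
  ss <- aggregate_beats(same)
  expect_equal(ss$sd, 0)
  expect_equal(unname(attr(ss, "stationarity")["x"]), 0)

  # discard drops leading beats
  sd2 <- aggregate_beats(beats, discard = 2)
  expect_equal(sd2$mean[sd2$variable == "x"], 6)
  expect_error(aggregate_beats(beats, discard = 5), "no beats left")
})
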