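random_state <- function() {
  s <- default_state()
  s[c("V_la", "V_lv", "V_ra", "V_rv")] <-
    stats::runif(4, 20, 150)
  s[c("theta_mi", "theta_ao", "theta_ti", "theta_po")] <-
    stats::runif(4, 0, 75 * pi / 180)
  s[c("omega_mi", "omega_ao", "omega_ti", "omega_po")] <-
    stats::runif(4, -20, 20)
  s[c("P_sas", "P_sat", "P_svn", "P_pas", "P_pat", "P_pvn")] <-
    stats::runif(6, 5, 120)
  s[c("Q_sas", "Q_sat", "Q_pas", "Q_pat")] <- stats::runif(4, -50, 400)
  s
}

test_that("rhs conserves total stressed volume analytically", {
  p <- cardio_params()
  set.seed(42)
  for (i in 1:25) {
    s <- random_state()
    rr <- stats::runif(1, 0.35, 1.1)
    r <- cardio_rhs(stats::runif(1, 0, rr * 0.999), s, p, rr,
                    atria_passive = i %% 2 == 0)
    d <- r$deriv
    dv_tot <- sum(d[c("V_la", "V_lv", "V_ra", "V_rv")]) +
      p$C_sas * d[["P_sas"]] + p$C_sat * d[["P_sat"]] +
      p$C_svn * d[["P_svn"]] + p$C_pas * d[["P_pas"]] +
      p$C_pat * d[["P_pat"]] + p$C_pvn * d[["P_pvn"]]
    expect_lt(abs(dv_tot), 1e-9)
  }
})

test_that("circuit laws are wired correctly", {
  p <- cardio_params()
  set.seed(7)
  s <- random_state()
  r <- cardio_rhs(0.2, s, p, 0.8)
  d <- r$deriv; a <- r$aux
  expect_equal(p$C_sas * d[["P_sas"]], a[["Q_ao"]] - s[["Q_sas"]])
  expect_equal(p$L_sat * d[["Q_sat"]],
               s[["P_sat"]] - s[["P_svn"]] -
                 (p$R_sat + p$R_sar + p$R_scp) * s[["Q_sat"]])
  expect_equal(p$C_pvn * d[["P_pvn"]],
               s[["Q_pat"]] - (s[["P_pvn"]] - a[["P_la"]]) / p$R_pvn)
  expect_equal(d[["V_lv"]], a[["Q_mi"]] - a[["Q_ao"]])
})

test_that("with all valves shut the ventricular volume is frozen", {
  p <- cardio_params()
  s <- default_state()  # all theta = 0
  r <- cardio_rhs(0.1, s, p, 0.8)
  expect_equal(r$deriv[["V_lv"]], 0)
  expect_equal(r$deriv[["V_rv"]], 0)
  expect_equal(r$aux[["Q_ao"]], 0)
})

test_that("non-finite state is rejected with the offending component named", {
  s <- default_state()
  s[["V_lv"]] <- NaN
  expect_error(cardio_rhs(0.1, s, cardio_params(), 0.8), "V_lv")
})

test_that("compiled rhs integrates to the same trajectory as the R
          reference rhs", {
  p <- cardio_params()
  rr <- 60 / 75
  n_beats <- 3
  sim <- simulate_cardio(p, rep(rr, n_beats), keep_trajectory = TRUE)

  rhs_r <- function(t, y, parms) {
    tb <- t %% rr
    names(y) <- afcirc:::state_names()
    list(unname(cardio_rhs(tb, y, p, rr)$deriv))
  }
  times <- sim$trajectory$time
  out <- deSolve::ode(unname(initial_state(p)), c(times, n_beats * rr),
                      rhs_r, NULL, method = "adams",
                      rtol = 1e-6, atol = 1e-8, maxsteps = 50000)
  ref <- out[seq_along(times), -1, drop = FALSE]
  got <- sim$trajectory$mat[, seq_len(22)]
  scale <- pmax(abs(ref), 1)
  expect_lt(max(abs(got - ref) / scale), 2e-3)
})
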