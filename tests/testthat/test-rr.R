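test_that("gamma follows the fitted linear relation at all tabulated heart
          rates", {
  cfg <- ref_rr_configs()
  expect_equal(round(gamma_from_hr(cfg$hr), 4), cfg$gamma)
  # root of the relation is rejected
  expect_error(gamma_from_hr(60 / (14.6 / 9.2)), "non-positive gamma")
  expect_error(gamma_from_hr(-10))
})

test_that("moment matching splits the EMG into its two components", {
  cmp <- emg_components(0.8571, 0.24, 6.7143)
  expect_equal(cmp$mu_g, 0.8571 - 1 / 6.7143, tolerance = 1e-6)
  expect_equal(round(cmp$mu_g, 4), 0.7082)
  expect_equal(round(cmp$sigma_g, 4), 0.1419)
  # component moments sum back to the target moments
  expect_equal(cmp$mu_g + 1 / cmp$gamma, 0.8571)
  expect_equal(cmp$sigma_g^2 + 1 / cmp$gamma^2, (0.24 * 0.8571)^2)

  # marginal feasibility at the fastest tabulated rate
  cmp2 <- emg_components(0.3750, 0.24, 11.15)
  expect_equal(round(cmp2$sigma_g, 4), 0.0075)

  # exponential component vanishing leaves the Gaussian moments
  cmp3 <- emg_components(0.8, 0.24, 1e6)
  expect_equal(cmp3$mu_g, 0.8, tolerance = 1e-5)
  expect_equal(cmp3$sigma_g, 0.24 * 0.8, tolerance = 1e-5)
})

test_that("infeasible specs are rejected at the feasibility boundary", {
  expect_error(emg_components(0.8, 0.1, 1 / 0.09), "infeasible")
  # property: (cv mu) gamma <= 1 is always rejected
  set.seed(1)
  for (i in 1:20) {
    mu <- stats::runif(1, 0.3, 1)
    cv <- stats::runif(1, 0.05, 0.3)
    g <- stats::runif(1, 0.2, 1) / (cv * mu)  # (cv mu) g in (0.2, 1]
    expect_error(emg_components(mu, cv, g), "infeasible")
  }
})

test_that("pink noise has the requested moments, determinism and 1/f
          spectrum", {
  x <- pink_gaussian(10000, 0.7, 0.14, seed = 3)
  expect_equal(mean(x), 0.7, tolerance = 1e-6)
  expect_equal(stats::sd(x), 0.14, tolerance = 1e-6)
  expect_identical(x, pink_gaussian(10000, 0.7, 0.14, seed = 3))
  expect_equal(pink_gaussian(50, 0.7, 0, seed = 1), rep(0.7, 50))

  # log-log periodogram slope over low-mid frequencies close to -1
  z <- x - mean(x)
  s <- Mod(stats::fft(z))^2 / length(z)
  k <- 2:500
  fit <- stats::lm(log(s[k + 1]) ~ log(k))
  expect_gt(stats::coef(fit)[2], -1.3)
  expect_lt(stats::coef(fit)[2], -0.7)
})

test_that("generated RR series match the target moments and shape", {
  spec <- rr_spec(70, n_beats = 5000, seed = 11)
  rr <- generate_rr(spec)$rr
  expect_length(rr, 5000)
  expect_lt(abs(mean(rr) / spec$mu - 1), 0.02)
  expect_lt(abs(stats::sd(rr) / mean(rr) - 0.24), 0.02)
  expect_true(all(rr >= 0.25))
  # positive skew from the exponential right tail
  expect_gt(mean(((rr - mean(rr)) / stats::sd(rr))^3), 0.3)
  # determinism
  expect_identical(rr, generate_rr(spec)$rr)

  # moment identities against the component decomposition, within 3 SE
  cmp <- emg_components(spec$mu, spec$cv, spec$gamma)
  se_mean <- spec$sigma / sqrt(5000)
  expect_lt(abs(mean(rr) - (cmp$mu_g + 1 / cmp$gamma)), 3 * se_mean)
  se_var <- stats::var(rr) * sqrt(2 / 4999)
  expect_lt(abs(stats::var(rr) - (cmp$sigma_g^2 + 1 / cmp$gamma^2)),
            3 * se_var)

  # faster schedule: mean ~ 0.6 s at 100 bpm
  rr100 <- generate_rr(rr_spec(100, n_beats = 5000, seed = 12))$rr
  expect_lt(abs(mean(rr100) - 0.6), 0.02 * 0.6)
})

test_that("near-degenerate spec collapses to a constant series", {
  rr <- generate_rr(rr_spec(70, n_beats = 200, cv = 0.01,
                            gamma = 1000, seed = 2))$rr
  expect_lt(stats::sd(rr), 0.02)
  expect_equal(mean(rr), 60 / 70, tolerance = 0.05)
})

test_that("RR series round-trip through single-column CSV", {
  rr <- generate_rr(rr_spec(90, n_beats = 50, seed = 4))
  f <- withr::local_tempfile(fileext = ".csv")
  write_rr(rr, f)
  expect_equal(read_rr(f), rr$rr, tolerance = 1e-12)
})

test_that("spectral tail estimator recovers gamma", {
  # analytic flat-spectrum oracle: for white noise of variance v the
  # normalized periodogram level is v, so the estimate is v^(-1/2)
  set.seed(8)
  v <- 0.04
  w <- stats::rnorm(20000, 0, sqrt(v))
  expect_lt(abs(estimate_gamma(w) / v^(-0.5) - 1), 0.1)

  # scaling law: scaling the series by c divides the estimate by c
  expect_equal(estimate_gamma(3 * w), estimate_gamma(w) / 3)

  # generator/estimator closed loop at 100 bpm
  spec <- rr_spec(100, n_beats = 10000, seed = 21)
  g_hat <- estimate_gamma(generate_rr(spec))
  expect_lt(abs(g_hat / spec$gamma - 1), 0.15)

  expect_error(estimate_gamma(stats::rnorm(500)), "at least 1000")
})

test_that("generator/estimator loop closes for every tabulated
          configuration", {
  cfg <- ref_rr_configs()
  for (i in seq_len(nrow(cfg))) {
    spec <- rr_spec(cfg$hr[i], n_beats = 10000, seed = 100 + i)
    g_hat <- estimate_gamma(generate_rr(spec))
    expect_lt(abs(g_hat / cfg$gamma[i] - 1), 0.15,
              label = paste0("gamma recovery at ", cfg$hr[i], " bpm"))
  }
})

test_that("least-squares fit recovers the gamma vs RR relation", {
  # exactly collinear points
  rrv <- c(0.4, 0.6, 0.8, 1.0)
  fit <- suppressWarnings(  # lm flags the numerically perfect fit
    fit_gamma_relation(data.frame(rr = rrv, gamma = -9.2 * rrv + 14.6)))
  expect_equal(fit$slope, -9.2)
  expect_equal(fit$intercept, 14.6)
  expect_equal(fit$r_squared, 1)

  # noisy synthetic recovery
  set.seed(9)
  rrn <- stats::runif(52, 0.35, 1.0)
  fitn <- fit_gamma_relation(
    data.frame(rr = rrn, gamma = -9.2 * rrn + 14.6 + stats::rnorm(52, 0, 0.2)))
  expect_equal(fitn$slope, -9.2, tolerance = 0.05)
  expect_equal(fitn$intercept, 14.6, tolerance = 0.05)

  expect_error(fit_gamma_relation(data.frame(rr = rep(0.5, 5),
                                             gamma = 1:5)), "degenerate")
  expect_error(fit_gamma_relation(data.frame(rr = c(0.5, 0.6),
                                             gamma = c(1, 2))))
})

test_that("the spectral calibration pipeline runs end-to-end over emulated
          recordings", {
  # 26 synthetic recordings x 2 windows -> 52 (mean RR, gamma) points
  set.seed(123)
  pts <- do.call(rbind, lapply(1:26, function(i) {
    hr <- 60 / stats::runif(1, 0.45, 1.0)
    s1 <- generate_rr(rr_spec(hr, n_beats = 2000, seed = 2000 + 2 * i))
    s2 <- generate_rr(rr_spec(hr, n_beats = 2000, seed = 2001 + 2 * i))
    data.frame(rr = c(mean(s1$rr), mean(s2$rr)),
               gamma = c(estimate_gamma(s1), estimate_gamma(s2)))
  }))
  expect_equal(nrow(pts), 52)
  fit <- fit_gamma_relation(pts)
  expect_lt(fit$slope, 0)  # faster rates carry larger exponential rates
})
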