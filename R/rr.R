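#' Rate parameter of the exponential RR component from heart rate
#'
#' Linear relation between the exponential rate parameter of the
#' exponentially modified Gaussian RR distribution and the mean RR interval,
#' fitted on long-term AF recordings: `gamma = -9.2 RR + 14.6` with RR in
#' seconds and gamma in Hz.
#'
#' @param hr heart rate in bpm.
#' @return gamma (Hz).
#' @export
#' @examples
#' gamma_from_hr(70)   # 6.7143
#' gamma_from_hr(160)  # 11.15
gamma_from_hr <- function(hr) {
  stopifnot(is.numeric(hr), all(hr > 0))
  g <- -9.2 * (60 / hr) + 14.6
  if (any(g <= 0))
    stop("non-positive gamma: mean RR must be below 14.6/9.2 s")
  g
}

#' Specification of a synthetic AF RR series
#'
#' Captures the target marginal moments of the beat-interval distribution:
#' mean `mu = 60/HR`, standard deviation `sigma = cv * mu` with the AF
#' coefficient of variation `cv = 0.24` by default, and the exponential rate
#' `gamma` taken from [gamma_from_hr()] unless overridden.
#'
#' @param hr heart rate (bpm).
#' @param n_beats number of beats to generate.
#' @param cv coefficient of variation of the RR distribution.
#' @param gamma exponential rate (Hz); default from the fitted relation.
#' @param seed integer seed making the realization reproducible.
#' @return object of class `rr_spec`.
#' @export
rr_spec <- function(hr, n_beats = 5000, cv = 0.24,
                    gamma = gamma_from_hr(hr), seed = 1L) {
  mu <- 60 / hr
  spec <- structure(list(hr = hr, mu = mu, cv = cv, sigma = cv * mu,
                         gamma = gamma, n_beats = as.integer(n_beats),
                         seed = as.integer(seed)),
                    class = "rr_spec")
  emg_components(mu, cv, gamma)  # validates feasibility
  spec
}

#' Moment-matched components of the EMG RR distribution
#'
#' The RR interval is the sum of two independent times: a correlated
#' (pink-noise) Gaussian component and an uncorrelated exponential component
#' of rate `gamma` (mean and SD `1/gamma`).  Matching first and second
#' moments, the Gaussian takes mean `mu - 1/gamma` and variance
#' `sigma^2 - 1/gamma^2`, which requires `(cv mu) gamma > 1`.
#'
#' @param mu target mean RR (s).
#' @param cv coefficient of variation.
#' @param gamma exponential rate (Hz).
#' @return list with `mu_g`, `sigma_g`, `gamma`.
#' @export
#' @examples
#' emg_components(0.8571, 0.24, 6.7143)  # mu_g ~ 0.708, sigma_g ~ 0.142
emg_components <- function(mu, cv, gamma) {
  stopifnot(mu > 0, cv >= 0, gamma > 0)
  sigma2 <- (cv * mu)^2
  if (sigma2 <= 1 / gamma^2)
    stop("infeasible RR spec: requires (cv*mu)^2 > 1/gamma^2, got (",
         signif(sigma2, 4), ") <= (", signif(1 / gamma^2, 4), ")")
  mu_g <- mu - 1 / gamma
  if (mu_g <= 0)
    stop("infeasible RR spec: requires mu > 1/gamma")
  list(mu_g = mu_g, sigma_g = sqrt(sigma2 - 1 / gamma^2), gamma = gamma)
}

#' Correlated pink (1/f) Gaussian series
#'
#' Frequency-domain synthesis: white complex Gaussian spectral amplitudes
#' are shaped by `f^(-1/2)` (power spectral density proportional to `1/f`),
#' transformed back, and affinely rescaled to the requested mean and
#' standard deviation.  The realization is fully determined by the seed.
#'
#' @param n series length (>= 2).
#' @param mu_g,sigma_g target sample mean and SD.
#' @param seed integer seed.
#' @return numeric vector of length `n`.
#' @export
pink_gaussian <- function(n, mu_g, sigma_g, seed = 1L) {
  stopifnot(n >= 2, sigma_g >= 0)
  if (sigma_g == 0) return(rep(mu_g, n))
  set.seed(seed)
  m <- n %/% 2
  ## Hermitian spectrum of a real series: bins 1..m get 1/sqrt(f) amplitudes
  amp <- (seq_len(m))^(-0.5)
  z <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m)) * amp
  spec <- complex(length.out = n)
  spec[2:(m + 1)] <- z
  spec[n:(n - m + 1)] <- Conj(z)
  x <- Re(stats::fft(spec, inverse = TRUE))
  x <- (x - mean(x)) / stats::sd(x)
  mu_g + sigma_g * x
}

#' Generate a synthetic AF RR-interval series
#'
#' Element-wise sum of the correlated pink Gaussian component and i.i.d.
#' exponential draws of rate `gamma`, giving an exponentially modified
#' Gaussian marginal with the spec's mean and coefficient of variation and a
#' `1/f`-correlated structure.  Beats shorter than `floor` (physiological
#' refractoriness) have their exponential component redrawn; in the rare
#' case redrawing fails repeatedly the beat is clamped at the floor.
#'
#' @param spec an [rr_spec()].
#' @param floor minimum admissible beat duration (s).
#' @return object of class `rr_series`: list with `rr` (numeric vector) and
#'   `spec`.
#' @export
#' @examples
#' rr <- generate_rr(rr_spec(70, n_beats = 1000, seed = 42))
#' mean(rr$rr)  # ~ 60/70
generate_rr <- function(spec, floor = 0.25) {
  stopifnot(inherits(spec, "rr_spec"))
  cmp <- emg_components(spec$mu, spec$cv, spec$gamma)
  n <- spec$n_beats
  g <- pink_gaussian(n, cmp$mu_g, cmp$sigma_g, seed = spec$seed)
  set.seed(spec$seed + 1L)
  e <- stats::rexp(n, rate = cmp$gamma)
  rr <- g + e
  for (i in 1:100) {
    low <- which(rr < floor)
    if (!length(low)) break
    e[low] <- stats::rexp(length(low), rate = cmp$gamma)
    rr[low] <- g[low] + e[low]
  }
  rr[rr < floor] <- floor
  structure(list(rr = rr, spec = spec), class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf(
    "AF RR series: %d beats, target HR %g bpm (mu %.4f s, cv %.2f, gamma %.4f Hz)\n",
    length(x$rr), x$spec$hr, x$spec$mu, x$spec$cv, x$spec$gamma))
  cat(sprintf("  sample mean %.4f s, sample cv %.4f, seed %d\n",
              mean(x$rr), stats::sd(x$rr) / mean(x$rr), x$spec$seed))
  invisible(x)
}

#' Write / read an RR series as single-column CSV
#'
#' @param x an `rr_series` or numeric vector (seconds).
#' @param file path.
#' @return `read_rr` returns a numeric vector of beat durations.
#' @export
write_rr <- function(x, file) {
  rr <- if (inherits(x, "rr_series")) x$rr else as.numeric(x)
  utils::write.csv(data.frame(rr_s = rr), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_rr
#' @export
read_rr <- function(file) {
  df <- utils::read.csv(file)
  as.numeric(df[[1]])
}

#' Estimate the exponential rate parameter from an RR series
#'
#' The power spectral density of the beat-indexed RR sequence flattens at
#' the highest frequencies, where the uncorrelated exponential component
#' dominates; its level equals that component's variance `1/gamma^2`.  The
#' estimator averages the periodogram (normalized so that a white series of
#' variance v has flat level v: `S_k = |FFT(x - mean)|^2 / n`) over the 100
#' highest-frequency bins and returns `gamma = S_inf^(-1/2)`.
#'
#' @param rr an `rr_series` or numeric vector of beat durations (length >=
#'   1000).
#' @param n_tail number of highest-frequency bins averaged.
#' @return estimated gamma (Hz).
#' @export
estimate_gamma <- function(rr, n_tail = 100) {
  if (inherits(rr, "rr_series")) rr <- rr$rr
  n <- length(rr)
  if (n < 1000)
    stop("need at least 1000 beats for a meaningful spectral tail")
  x <- rr - mean(rr)
  s <- Mod(stats::fft(x))^2 / n
  half <- n %/% 2
  tail_bins <- (half - n_tail + 1):half + 1L  # +1: fft index offset
  s_inf <- mean(s[tail_bins])
  s_inf^(-1 / 2)
}

#' Least-squares fit of the gamma vs mean-RR relation
#'
#' Ordinary least squares of the spectral rate estimates on the window mean
#' RR, as used to calibrate the linear relation adopted by
#' [gamma_from_hr()].
#'
#' @param points data.frame (or list) with columns/elements `rr` (mean RR,
#'   s) and `gamma` (Hz); at least 3 points.
#' @return list with `slope`, `intercept`, `r_squared` and the underlying
#'   `lm` fit.
#' @export
fit_gamma_relation <- function(points) {
  df <- as.data.frame(points)
  stopifnot(all(c("rr", "gamma") %in% names(df)), nrow(df) >= 3)
  if (stats::sd(df$rr) == 0) stop("degenerate abscissae: all mean RR equal")
  fit <- stats::lm(gamma ~ rr, data = df)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       fit = fit)
}
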