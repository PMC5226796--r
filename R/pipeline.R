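#' Study configuration
#'
#' Bundles every tunable of the experiment suites: beats per AF run,
#' transient discards, sinus-rhythm run length, solver tolerances, master
#' seed and optional output directory.  Per-run seeds are derived
#' deterministically from the master seed so that runs are reproducible yet
#' use independent RR realizations.
#'
#' @param n_beats AF beats retained per run (after discard).
#' @param discard_af transient beats discarded in AF runs.
#' @param n_beats_sr,discard_sr beats simulated / discarded in constant-RR
#'   sinus-rhythm runs.
#' @param seed master integer seed.
#' @param rtol,atol solver tolerances.
#' @param out_dir optional directory for CSV outputs.
#' @return list of class `study_config`.
#' @export
study_config <- function(n_beats = 5000, discard_af = 200,
                         n_beats_sr = 60, discard_sr = 20,
                         seed = 1L, rtol = 1e-6, atol = 1e-8,
                         out_dir = NULL) {
  structure(list(n_beats = n_beats, discard_af = discard_af,
                 n_beats_sr = n_beats_sr, discard_sr = discard_sr,
                 seed = as.integer(seed), rtol = rtol, atol = atol,
                 out_dir = out_dir),
            class = "study_config")
}

## deterministic per-run seed derivation, kept well below 2^31
run_seed <- function(config, arm, met) {
  offs <- c(SR = 0L, SHR = 100L, HHR = 200L)
  (config$seed * 1000L + offs[[arm]] + as.integer(met)) %% 2147483647L
}

write_stats_csv <- function(stats_by_met, file) {
  df <- NULL
  for (met in names(stats_by_met)) {
    s <- stats_by_met[[met]]
    add <- data.frame(variable = s$variable)
    add[[paste0(met, "_mean")]] <- s$mean
    add[[paste0(met, "_sd")]] <- s$sd
    df <- if (is.null(df)) add else merge(df, add, by = "variable",
                                          sort = FALSE)
  }
  utils::write.csv(df, file, row.names = FALSE)
}

#' Sinus-rhythm validation suite
#'
#' Constant-RR runs at the four exercise grades with the MET parameter
#' overrides and active atria; reports steady-state values of all tabulated
#' variables plus the three rest-to-vigorous tuning deltas (relative change
#' of systolic and diastolic systemic pressure and of cardiac output from
#' 1 to 8 METs).
#'
#' @param config a [study_config()].
#' @param baseline baseline parameters.
#' @return list of class `sr_validation`: `table` (variable x MET means),
#'   `deltas` (named percentages), `stats` (per-MET `beat_stats`).
#' @export
run_sr_validation <- function(config = study_config(),
                              baseline = cardio_params()) {
  stats <- list()
  for (met in c(1, 4, 6, 8)) {
    hr <- hr_for("SR", met)
    rr <- rep(60 / hr, config$n_beats_sr)
    sim <- simulate_cardio(apply_exercise(baseline, met), rr,
                           rtol = config$rtol, atol = config$atol)
    stats[[paste0("met", met)]] <-
      aggregate_beats(sim$beats, discard = config$discard_sr)
  }
  tab <- data.frame(variable = report_variables(),
                    stringsAsFactors = FALSE)
  for (met in c(1, 4, 6, 8)) {
    s <- stats[[paste0("met", met)]]
    tab[[paste0("met", met)]] <- s$mean[match(tab$variable, s$variable)]
  }
  g <- function(v, met) tab[[paste0("met", met)]][tab$variable == v]
  deltas <- c(
    P_sas_syst = 100 * (g("P_sas_syst", 8) / g("P_sas_syst", 1) - 1),
    P_sas_dias = 100 * (g("P_sas_dias", 8) / g("P_sas_dias", 1) - 1),
    CO = 100 * (g("CO", 8) / g("CO", 1) - 1))
  out <- structure(list(table = tab, deltas = deltas, stats = stats,
                        config = config), class = "sr_validation")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(config$out_dir, "sr_validation.csv"),
                     row.names = FALSE)
  }
  out
}

#' @export
print.sr_validation <- function(x, ...) {
  cat("Sinus-rhythm validation (constant RR, active atria)\n")
  tab <- x$table
  tab[-1] <- round(tab[-1], 2)
  print.data.frame(tab, row.names = FALSE)
  cat(sprintf(
    "1 -> 8 METs: P_sas_syst %+.1f%%, P_sas_dias %+.1f%%, CO %+.1f%%\n",
    x$deltas[["P_sas_syst"]], x$deltas[["P_sas_dias"]], x$deltas[["CO"]]))
  invisible(x)
}

#' AF simulation arm
#'
#' Four AF runs (one per exercise grade) for one resting-HR arm: passive
#' atria driven by synthetic EMG RR series at the arm's heart-rate schedule,
#' aggregated as mean and SD per variable over the retained beats.
#'
#' @param arm `"SHR"` or `"HHR"`.
#' @param config a [study_config()].
#' @param baseline baseline parameters.
#' @param mets MET levels to run (default all four).
#' @return list of class `af_arm`: `stats` (per-MET `beat_stats`), `table`
#'   (means and SDs), `arm`, `config`.
#' @export
run_af_arm <- function(arm, config = study_config(),
                       baseline = cardio_params(), mets = c(1, 4, 6, 8)) {
  arm <- match.arg(arm, c("SHR", "HHR"))
  stats <- list()
  for (met in mets) {
    hr <- hr_for(arm, met)
    spec <- rr_spec(hr, n_beats = config$n_beats + config$discard_af,
                    seed = run_seed(config, arm, met))
    sim <- simulate_cardio(apply_exercise(baseline, met),
                           generate_rr(spec), atria_passive = TRUE,
                           rtol = config$rtol, atol = config$atol)
    stats[[paste0("met", met)]] <-
      aggregate_beats(sim$beats, discard = config$discard_af)
  }
  out <- structure(list(arm = arm, stats = stats, config = config),
                   class = "af_arm")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_stats_csv(stats, file.path(config$out_dir,
                                     paste0("af_", tolower(arm), ".csv")))
  }
  out
}

#' @export
print.af_arm <- function(x, ...) {
  cat("AF arm", x$arm, "- mean +/- SD over",
      attr(x$stats[[1]], "n_beats"), "beats\n")
  for (met in names(x$stats)) {
    s <- x$stats[[met]]
    i <- match(c("SV", "EF", "CO", "P_sas", "P_pvn"), s$variable)
    cat(sprintf(
      " %s: SV %.1f+/-%.1f ml, EF %.1f%%, CO %.2f l/min, P_sas %.1f, P_pvn %.2f mmHg\n",
      met, s$mean[i[1]], s$sd[i[1]], s$mean[i[2]], s$mean[i[3]],
      s$mean[i[4]], s$mean[i[5]]))
  }
  invisible(x)
}

#' Run the full computational study
#'
#' Executes the sinus-rhythm validation, both AF arms, the VCI computation
#' and (optionally) the sensitivity scan from one configuration, writing CSV
#' tables and a JSON-like manifest when an output directory is set.
#'
#' @param config a [study_config()].
#' @param baseline baseline parameters.
#' @param sensitivity if `TRUE`, include the +/-5% sensitivity scan (at
#'   `sens_beats` beats per run) and the atrial-compliance robustness check.
#' @param sens_beats beats per sensitivity run.
#' @return list of class `full_study` with elements `sr`, `shr`, `hhr`,
#'   `vci`, and optionally `sensitivity`, `atrial_check`.
#' @export
run_full_study <- function(config = study_config(),
                           baseline = cardio_params(),
                           sensitivity = FALSE, sens_beats = 1000) {
  sr <- run_sr_validation(config, baseline)
  shr <- run_af_arm("SHR", config, baseline)
  hhr <- run_af_arm("HHR", config, baseline)
  v <- vci_table(shr$stats, hhr$stats)
  out <- list(sr = sr, shr = shr, hhr = hhr, vci = v, config = config)
  if (sensitivity) {
    out$sensitivity <- sensitivity_scan(
      baseline, n_beats = sens_beats, discard = config$discard_af,
      seed = run_seed(config, "SHR", 1))
    out$atrial_check <- atrial_compliance_check(
      baseline, n_beats = sens_beats, discard = config$discard_af,
      seed = run_seed(config, "SHR", 1))
  }
  if (!is.null(config$out_dir)) {
    utils::write.csv(v, file.path(config$out_dir, "vci.csv"),
                     row.names = FALSE)
    manifest <- c(
      sprintf("seed: %d", config$seed),
      sprintf("n_beats: %d", config$n_beats),
      sprintf("discard_af: %d", config$discard_af),
      sprintf("rtol: %g / atol: %g", config$rtol, config$atol))
    writeLines(manifest, file.path(config$out_dir, "manifest.txt"))
  }
  structure(out, class = "full_study")
}

#' @export
print.full_study <- function(x, ...) {
  print(x$sr)
  cat("\n")
  print(x$vci)
  invisible(x)
}
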