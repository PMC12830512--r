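# Instrument qualification suite: background, linearity, repeatability,
# limit of quantification, working range, positional accuracy, and the
# Bland-Altman method comparison. Each test returns a result object carrying
# its measured value and a pass/fail against the printed acceptance
# criterion; run_qualification() assembles the consolidated report.

offset_seed <- function(seed, k) {
  if (is.null(seed)) NULL else as.integer(seed + k)
}

#' Background assessment
#'
#' Average background count rate from replicate blank acquisitions
#' (triplicate 5-minute scans in the standard protocol). Each record's rate is
#' its total counts over its total acquisition time; the mean and sample
#' standard deviation across records are reported.
#'
#' @param records List of [chromatogram()]s (or `acquisition_record`s) of
#'   equal duration; at least two.
#' @return A list of class `background_result`: `mean_cps`, `sd_cps`,
#'   `rates_cps`, `n`.
#' @export
background_assessment <- function(records) {
  chroms <- lapply(records, function(r) {
    if (inherits(r, "acquisition_record")) r$chromatogram else r
  })
  if (length(chroms) < 2L ||
      !all(vapply(chroms, inherits, logical(1), "chromatogram"))) {
    rtlc_stop("need at least 2 chromatograms", "rtlc_invalid_input")
  }
  durations <- vapply(chroms, function(ch) ch$dwell_s * length(ch$counts),
                      numeric(1))
  if (max(durations) - min(durations) > 1e-9) {
    rtlc_stop("records have mismatched acquisition durations",
              "rtlc_invalid_input")
  }
  rates <- vapply(chroms, function(ch) sum(ch$counts), numeric(1)) / durations
  structure(list(mean_cps = mean(rates), sd_cps = sd(rates),
                 rates_cps = rates, n = length(rates)),
            class = "background_result")
}

#' Linearity of detector response
#'
#' A single high-activity spot is scanned repeatedly as it decays; the
#' background-subtracted net count rate of the peak region is regressed
#' (Pearson, raw scale) against the decay-corrected calculated activity.
#'
#' @param records List of [chromatogram()]s / `acquisition_record`s, one per
#'   time point (at least 3).
#' @param elapsed_h Elapsed time of each scan since the activity reference,
#'   hours.
#' @param a0_MBq Activity at the reference time, MBq.
#' @param half_life_h Isotope half-life, hours.
#' @param regions A [region_set()] with the peak and background regions used
#'   for the net-rate measurement.
#' @return A list of class `linearity_result`: `points` (data frame of
#'   calculated activity and net count rate), `pearson_r`, `pass`
#'   (`pearson_r >= 0.99`).
#' @export
linearity_test <- function(records, elapsed_h, a0_MBq, half_life_h, regions) {
  if (length(records) < 3L || length(elapsed_h) != length(records)) {
    rtlc_stop("need >= 3 records with matching elapsed times",
              "rtlc_invalid_input")
  }
  x <- decay_activity(a0_MBq, elapsed_h, half_life_h)
  if (max(x) - min(x) <= 0) {
    rtlc_stop("all calculated activities identical: correlation undefined",
              "rtlc_undefined_correlation")
  }
  y <- vapply(records, function(r) {
    chrom <- if (inherits(r, "acquisition_record")) r$chromatogram else r
    bl <- baseline_stats(chrom, regions)
    peaks <- regions[regions$kind == "peak", , drop = FALSE]
    net <- vapply(seq_len(nrow(peaks)), function(i) {
      integrate_region(chrom, peaks[i, ], bl)
    }, numeric(1))
    # main peak's net rate; negative fluctuations near blank level are kept
    # as-is so the regression stays unbiased
    max(net) / (chrom$dwell_s * length(chrom$counts))
  }, numeric(1))
  r <- cor(x, y)
  structure(list(points = data.frame(calculated_activity_MBq = x,
                                     net_count_rate_cps = y),
                 pearson_r = r, pass = r >= 0.99),
            class = "linearity_result")
}

#' Repeatability (precision) of the impurity measurement
#'
#' Coefficient of variation of the impurity percentages obtained from
#' consecutive scans of the same strip.
#'
#' @param impurity_percents Numeric vector (six values in the standard
#'   protocol; at least two), percent.
#' @return A list of class `repeatability_result`: `impurity_percents`,
#'   `cv_percent` (100 * sample sd / mean), `pass` (`cv <= 5`).
#' @export
repeatability_test <- function(impurity_percents) {
  if (length(impurity_percents) < 2L || any(impurity_percents < 0)) {
    rtlc_stop("need >= 2 non-negative impurity values", "rtlc_invalid_input")
  }
  m <- mean(impurity_percents)
  if (m == 0) {
    rtlc_stop("mean impurity is zero: CV undefined", "rtlc_undefined_cv")
  }
  cv <- 100 * sd(impurity_percents) / m
  structure(list(impurity_percents = impurity_percents, cv_percent = cv,
                 pass = cv <= 5),
            class = "repeatability_result")
}

default_loq_regions <- function() {
  region_set(c("peak", "background"), c(45, 85), c(75, 115),
             c("peak", "background"))
}

#' Limit-of-quantification search
#'
#' The LOQ is the lowest activity concentration whose peak reaches a
#' signal-to-noise ratio of at least 10 (pharmacopoeial 2H/h convention).
#' Each candidate concentration is converted to a spot activity through the
#' sample volume, simulated and analyzed `replicates` times, and judged on
#' its median SNR.
#'
#' With `stochastic = FALSE` the search runs in the deterministic limit: the
#' net peak height is computed analytically
#' (`efficiency * activity * w_peak * dwell`) and divided by the supplied
#' `noise_pp` — useful as a closed-form cross-check of the stochastic search.
#'
#' @param config A [scan_config()] describing the instrument (its `seed`
#'   seeds the replicate simulations).
#' @param concentrations_MBq_per_ml Candidate concentrations, sorted
#'   descending, MBq/ml.
#' @param sample_volume_ul Spotted sample volume, microlitres (default 5).
#' @param replicates Simulated scans per concentration (default 3).
#' @param regions Integration regions; default: peak 45-75 mm, background
#'   85-115 mm around the scenario's centred spot.
#' @param stochastic Simulate Poisson scans (default) or use the analytic
#'   deterministic limit.
#' @param noise_pp Peak-to-peak baseline noise assumed in the deterministic
#'   limit (counts); required when `stochastic = FALSE`.
#' @return A list of class `loq_result`: `loq_MBq_per_ml`, `snr_at_loq`,
#'   `sample_volume_ul`, `found`, and the per-concentration `table`. When no
#'   concentration qualifies, `found` is `FALSE` and `loq_MBq_per_ml` is `NA`
#'   (the table then serves as the diagnostic).
#' @export
loq_search <- function(config, concentrations_MBq_per_ml, sample_volume_ul = 5,
                       replicates = 3, regions = default_loq_regions(),
                       stochastic = TRUE, noise_pp = NULL) {
  stopifnot(inherits(config, "scan_config"))
  conc <- concentrations_MBq_per_ml
  if (length(conc) < 1L || any(conc <= 0) || is.unsorted(rev(conc), strictly = TRUE)) {
    rtlc_stop("concentrations must be positive and sorted descending",
              "rtlc_invalid_input")
  }
  if (replicates < 1L) {
    rtlc_stop("replicates must be >= 1", "rtlc_invalid_input")
  }
  activities <- conc * sample_volume_ul * 1e-3  # MBq/ml * ml

  med_snr <- numeric(length(conc))
  if (stochastic) {
    for (i in seq_along(conc)) {
      snrs <- numeric(replicates)
      for (r in seq_len(replicates)) {
        scen <- make_scenario("loq", activity_MBq = activities[i],
                              seed = offset_seed(config$seed,
                                                 (i - 1L) * replicates + r))
        cfg <- config
        cfg$seed <- scen$config$seed
        ch <- simulate_scan(scen$model, cfg)
        rep_ <- suppressWarnings(analyze_strip(ch, regions))
        snrs[r] <- rep_$peaks$snr[1]
      }
      med_snr[i] <- stats::median(snrs)
    }
  } else {
    assert_scalar_number(noise_pp, "noise_pp", min = 0, strict_min = TRUE)
    dwell <- config$total_time_s / floor(config$scan_range_mm / config$step_mm)
    w_peak <- line_spread_weight(0, config$response_sigma_mm, config$step_mm)
    heights <- config$efficiency_cps_per_MBq * activities * w_peak * dwell
    med_snr <- 2 * heights / noise_pp
  }

  ok <- which(med_snr >= 10)
  tab <- data.frame(concentration_MBq_per_ml = conc, median_snr = med_snr)
  if (length(ok) == 0) {
    return(structure(list(loq_MBq_per_ml = NA_real_, snr_at_loq = NA_real_,
                          sample_volume_ul = sample_volume_ul, found = FALSE,
                          table = tab),
                     class = "loq_result"))
  }
  best <- max(ok)  # concentrations are descending: max index = lowest value
  structure(list(loq_MBq_per_ml = conc[best], snr_at_loq = med_snr[best],
                 sample_volume_ul = sample_volume_ul, found = TRUE,
                 table = tab),
            class = "loq_result")
}

#' Working range of the method
#'
#' The qualified range runs from 200 times the LOQ (so that an impurity of
#' 0.5% of the lower limit is still quantifiable) up to the highest
#' concentration verified in the linearity test.
#'
#' @param loq_MBq_per_ml Limit of quantification, MBq/ml.
#' @param max_verified_MBq_per_ml Highest verified concentration, MBq/ml.
#' @return A list of class `working_range`: `lower_MBq_per_ml` (= 200 * LOQ)
#'   and `upper_MBq_per_ml`.
#' @examples
#' working_range(0.5, 3700)  # 100 - 3700 MBq/ml
#' @export
working_range <- function(loq_MBq_per_ml, max_verified_MBq_per_ml) {
  assert_scalar_number(loq_MBq_per_ml, "loq_MBq_per_ml", min = 0, strict_min = TRUE)
  assert_scalar_number(max_verified_MBq_per_ml, "max_verified_MBq_per_ml",
                       min = 0, strict_min = TRUE)
  lower <- 200 * loq_MBq_per_ml
  if (lower >= max_verified_MBq_per_ml) {
    rtlc_stop(sprintf(
      "lower limit 200*LOQ = %g MBq/ml is not below the upper limit %g MBq/ml",
      lower, max_verified_MBq_per_ml), "rtlc_invalid_range")
  }
  structure(list(lower_MBq_per_ml = lower,
                 upper_MBq_per_ml = max_verified_MBq_per_ml),
            class = "working_range")
}

#' Positional accuracy of the detector carriage
#'
#' Spots at known positions are located in the recorded chromatogram (maximum
#' counts within a window around each expected position; ties toward lower
#' position) and their observed retention factors compared with the
#' calculated ones.
#'
#' @param record A [chromatogram()] or `acquisition_record`.
#' @param expected_positions_mm Sorted expected spot positions, mm.
#' @param origin_mm,front_mm Solvent marks defining the Rf frame.
#' @param window_mm Half-width of the search window around each expected
#'   position (default 5 mm; windows are half-open and must not overlap).
#' @return A list of class `position_accuracy_result`: `expected_rf`,
#'   `observed_rf`, `observed_positions_mm`, `max_deviation_percent`
#'   (largest relative Rf deviation, percent), `pass` (`<= 10`).
#' @export
position_accuracy_test <- function(record, expected_positions_mm,
                                   origin_mm, front_mm, window_mm = 5) {
  chrom <- if (inherits(record, "acquisition_record")) {
    record$chromatogram
  } else {
    record
  }
  stopifnot(inherits(chrom, "chromatogram"))
  ep <- expected_positions_mm
  if (length(ep) < 1L || is.unsorted(ep, strictly = TRUE)) {
    rtlc_stop("expected positions must be strictly increasing",
              "rtlc_invalid_input")
  }
  if (length(ep) > 1 && min(diff(ep)) < 2 * window_mm) {
    rtlc_stop("expected positions closer than 2*window_mm: windows overlap",
              "rtlc_invalid_input")
  }
  obs <- vapply(ep, function(e) {
    idx <- which(chrom$positions_mm >= e - window_mm &
                   chrom$positions_mm < e + window_mm)
    if (length(idx) == 0) {
      rtlc_stop(sprintf("no channels in the window around %g mm", e),
                "rtlc_peak_matching_error")
    }
    chrom$positions_mm[idx][which.max(chrom$counts[idx])]
  }, numeric(1))
  expected_rf <- retention_factor(ep, origin_mm, front_mm)
  observed_rf <- retention_factor(obs, origin_mm, front_mm)
  if (any(expected_rf <= 0)) {
    rtlc_stop("expected Rf must be positive for a relative deviation",
              "rtlc_invalid_input")
  }
  dev <- 100 * abs(observed_rf - expected_rf) / expected_rf
  structure(list(expected_rf = expected_rf, observed_rf = observed_rf,
                 observed_positions_mm = obs,
                 max_deviation_percent = max(dev), pass = max(dev) <= 10),
            class = "position_accuracy_result")
}

#' Method comparison: correlation, bias and limits of agreement
#'
#' Bland-Altman agreement analysis between the device under test and a
#' reference instrument on paired RCP measurements: mean difference (bias),
#' limits of agreement at bias +/- 1.96 standard deviations of the
#' differences, Pearson correlation of the pairs (target r >= 0.95), and a
#' Shapiro-Wilk normality check of the differences (alpha = 0.05).
#'
#' @param pairs A data frame with columns `rcp_test` and `rcp_reference`
#'   (percent), or a two-column matrix/data frame in that order; at least 3
#'   pairs.
#' @return A list of class `method_comparison`: `pairs`, `pearson_r`, `bias`,
#'   `sd_diff`, `loa_low`, `loa_high`, `shapiro_w`, `shapiro_p`, `pass_r`
#'   (`r >= 0.95`), `normality_ok` (`p > 0.05`).
#' @export
compare_methods <- function(pairs) {
  if (is.matrix(pairs)) pairs <- as.data.frame(pairs)
  if (!all(c("rcp_test", "rcp_reference") %in% names(pairs))) {
    if (ncol(pairs) == 2L) {
      names(pairs) <- c("rcp_test", "rcp_reference")
    } else {
      rtlc_stop("pairs must have columns rcp_test and rcp_reference",
                "rtlc_invalid_input")
    }
  }
  if (nrow(pairs) < 3L) {
    rtlc_stop("need at least 3 pairs", "rtlc_invalid_input")
  }
  x <- pairs$rcp_test
  y <- pairs$rcp_reference
  if (sd(x) == 0 || sd(y) == 0) {
    rtlc_stop("zero variance in one series: correlation undefined",
              "rtlc_undefined_correlation")
  }
  d <- x - y
  bias <- mean(d)
  sd_diff <- sd(d)
  r <- cor(x, y)
  if (sd_diff > 0) {
    sw <- shapiro.test(d)
    shapiro_w <- unname(sw$statistic)
    shapiro_p <- sw$p.value
  } else {
    shapiro_w <- NA_real_
    shapiro_p <- NA_real_
  }
  structure(list(pairs = pairs, pearson_r = r, bias = bias, sd_diff = sd_diff,
                 loa_low = bias - 1.96 * sd_diff,
                 loa_high = bias + 1.96 * sd_diff,
                 shapiro_w = shapiro_w, shapiro_p = shapiro_p,
                 pass_r = r >= 0.95,
                 normality_ok = if (is.na(shapiro_p)) NA else shapiro_p > 0.05),
            class = "method_comparison")
}

#' Simulate a paired method-comparison study
#'
#' Emulates parallel RCP testing on two virtual instruments: for each pair a
#' strip with a randomly drawn impurity fraction is simulated once on the
#' device under test and once on a reference scanner with ten times its
#' efficiency, and both chromatograms are analyzed with the same regions.
#'
#' @param n_pairs Number of paired measurements (default 100, as in a typical
#'   comparison campaign).
#' @param seed Random seed for the impurity draws and scan simulations.
#' @param impurity_range Range (percent) from which true impurities are drawn
#'   uniformly; default 0.5-8%, covering typical kit acceptance windows.
#' @return A data frame with columns `true_impurity_percent`, `rcp_test`,
#'   `rcp_reference`.
#' @export
simulate_comparison <- function(n_pairs = 100, seed = NULL,
                                impurity_range = c(0.5, 8)) {
  if (n_pairs < 3L) rtlc_stop("need n_pairs >= 3", "rtlc_invalid_input")
  imps <- with_seed(seed, runif(n_pairs, impurity_range[1], impurity_range[2]))
  regions <- region_set(c("main", "impurity", "bg"),
                        c(15, 80, 55), c(50, 115, 78),
                        c("peak", "peak", "background"))
  rcp_t <- numeric(n_pairs)
  rcp_r <- numeric(n_pairs)
  for (i in seq_len(n_pairs)) {
    scen <- make_scenario("comparison_pair", impurity_percent = imps[i],
                          seed = offset_seed(seed, 2L * i))
    ch_t <- simulate_scan(scen$model, scen$config)
    ch_r <- simulate_scan(scen$model, scen$config_reference)
    rcp_t[i] <- suppressWarnings(
      analyze_strip(ch_t, regions, main_label = "main"))$rcp_percent
    rcp_r[i] <- suppressWarnings(
      analyze_strip(ch_r, regions, main_label = "main"))$rcp_percent
  }
  data.frame(true_impurity_percent = imps, rcp_test = rcp_t,
             rcp_reference = rcp_r)
}

default_repeatability_regions <- function() {
  region_set(c("main", "impurity", "bg"), c(5, 85, 50), c(45, 115, 80),
             c("peak", "peak", "background"))
}

default_linearity_regions <- function() {
  region_set(c("peak", "background"), c(45, 85), c(75, 115),
             c("peak", "background"))
}

#' Run the full qualification suite
#'
#' Executes every scenario end to end (simulate, serialize implicit, analyze,
#' score) and assembles the consolidated report: one row per qualification
#' parameter with its acceptance criterion, measured result and pass/fail.
#'
#' @param seed Master seed; every stochastic sub-test derives its own seed
#'   from it, and the report records it.
#' @param loq_concentrations Candidate LOQ grid, MBq/ml, descending.
#' @param loq_replicates Replicates per LOQ concentration.
#' @return An object of class `qualification_report`: a data frame with
#'   columns `parameter`, `criterion`, `result`, `pass`, with the underlying
#'   result objects in `attr(, "details")` and the master seed in
#'   `attr(, "seed")`.
#' @export
run_qualification <- function(seed = 1,
                              loq_concentrations = c(16, 8, 4, 2, 1, 0.5, 0.25),
                              loq_replicates = 3) {
  base <- as.integer(seed) * 1000L

  # Background: triplicate 5-min blanks
  bg_scen <- make_scenario("background")
  bg_records <- lapply(1:3, function(k) {
    cfg <- bg_scen$config
    cfg$seed <- base + k
    simulate_scan(bg_scen$model, cfg)
  })
  bg <- background_assessment(bg_records)

  # Linearity: nine scans over the decay series
  lin_scen <- make_scenario("linearity")
  lin_records <- lapply(seq_along(lin_scen$start_offsets_h), function(k) {
    cfg <- lin_scen$config
    cfg$seed <- base + 100L + k
    cfg$start_offset_h <- lin_scen$start_offsets_h[k]
    simulate_scan(lin_scen$model, cfg)
  })
  lin <- linearity_test(lin_records, lin_scen$start_offsets_h,
                        a0_MBq = lin_scen$a0_MBq,
                        half_life_h = lin_scen$config$half_life_h,
                        regions = default_linearity_regions())

  # Repeatability: six consecutive 2-min scans of the 7.4 + 0.4 MBq strip
  rep_scen <- make_scenario("repeatability")
  rep_regions <- default_repeatability_regions()
  imp <- vapply(1:6, function(k) {
    cfg <- rep_scen$config
    cfg$seed <- base + 200L + k
    ch <- simulate_scan(rep_scen$model, cfg)
    100 - analyze_strip(ch, rep_regions, main_label = "main")$rcp_percent
  }, numeric(1))
  rep_res <- repeatability_test(imp)

  # Limit of quantification and derived working range
  loq_cfg <- scan_config(total_time_s = 300, seed = base + 300L)
  loq <- loq_search(loq_cfg, loq_concentrations, sample_volume_ul = 5,
                    replicates = loq_replicates)
  rng <- if (loq$found) {
    # upper limit: highest linearity sample, 18.5 MBq in 5 ul = 3700 MBq/ml
    tryCatch(working_range(loq$loq_MBq_per_ml, 3700),
             rtlc_invalid_range = function(e) NULL)
  } else {
    NULL
  }

  # Positional accuracy: nine spots at 10 mm spacing
  pos_scen <- make_scenario("position_accuracy")
  pos_cfg <- pos_scen$config
  pos_cfg$seed <- base + 401L
  pos_ch <- simulate_scan(pos_scen$model, pos_cfg)
  pos <- position_accuracy_test(pos_ch, pos_scen$expected_positions_mm,
                                origin_mm = pos_scen$model$origin_mm,
                                front_mm = pos_scen$model$front_mm)

  report <- data.frame(
    parameter = c("Background", "Linearity", "Repeatability",
                  "Limit of quantification", "Range", "Position accuracy"),
    criterion = c("-", "R > 0.99", "CV < 5%", "SNR >= 10", "-",
                  "Deviation from calculated RF <= 10%"),
    result = c(
      sprintf("%.2f +/- %.2f cps", bg$mean_cps, bg$sd_cps),
      sprintf("R = %.4f", lin$pearson_r),
      sprintf("CV = %.1f%%", rep_res$cv_percent),
      if (loq$found) {
        sprintf("%.3g MBq/ml (SNR = %.1f)", loq$loq_MBq_per_ml, loq$snr_at_loq)
      } else {
        "not reached on tested grid"
      },
      if (!is.null(rng)) {
        sprintf("%.4g-%.4g MBq/ml", rng$upper_MBq_per_ml, rng$lower_MBq_per_ml)
      } else {
        "undefined"
      },
      sprintf("max deviation = %.1f%%", pos$max_deviation_percent)),
    pass = c(TRUE, lin$pass, rep_res$pass, loq$found, !is.null(rng), pos$pass),
    stringsAsFactors = FALSE)
  structure(report,
            class = c("qualification_report", "data.frame"),
            details = list(background = bg, linearity = lin,
                           repeatability = rep_res, loq = loq, range = rng,
                           position_accuracy = pos),
            seed = seed)
}

#' @export
print.qualification_report <- function(x, ...) {
  cat(sprintf("Qualification report (seed %s)\n", attr(x, "seed")))
  print.data.frame(x, row.names = FALSE, right = FALSE)
  invisible(x)
}
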