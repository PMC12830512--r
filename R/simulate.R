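# Scan simulator: a collimated scintillation detector stepping along a TLC
# strip bearing radioactive spots. The physical truth is a strip_model (spot
# positions, activities, deposit widths, solvent marks); the instrument is a
# scan_config (geometry, timing, efficiency, background, response width,
# half-life). simulate_scan() combines the two into a Poisson-counted
# chromatogram.

#' Describe one radioactive spot deposited on a strip
#'
#' @param position_mm Spot centre, in mm from the scan start.
#' @param activity_MBq Activity at the reference time (time zero), MBq.
#' @param deposit_sigma_mm Physical spread of the applied drop, expressed as a
#'   Gaussian standard deviation in mm. The default 0 models a point-like
#'   deposit, so the recorded peak width is set by the detector response alone.
#' @return An object of class `spot_deposit`.
#' @examples
#' spot_deposit(60, 18.5)
#' @export
spot_deposit <- function(position_mm, activity_MBq, deposit_sigma_mm = 0) {
  assert_scalar_number(position_mm, "position_mm", min = 0)
  assert_scalar_number(activity_MBq, "activity_MBq", min = 0)
  assert_scalar_number(deposit_sigma_mm, "deposit_sigma_mm", min = 0)
  structure(list(position_mm = position_mm,
                 activity_MBq = activity_MBq,
                 deposit_sigma_mm = deposit_sigma_mm),
            class = "spot_deposit")
}

#' Describe a chromatographic strip
#'
#' A strip is the physical object placed on the scanner: its length, the
#' radioactive spots it bears and the solvent origin/front marks that define
#' the retention-factor reference frame.
#'
#' @param length_mm Strip length in mm.
#' @param spots A list of [spot_deposit()] objects; may be empty (blank strip).
#' @param origin_mm,front_mm Solvent origin and front marks in mm;
#'   `0 <= origin_mm < front_mm <= length_mm`.
#' @return An object of class `strip_model`.
#' @examples
#' strip_model(120, list(spot_deposit(60, 18.5)), origin_mm = 10, front_mm = 110)
#' @export
strip_model <- function(length_mm, spots = list(), origin_mm, front_mm) {
  assert_scalar_number(length_mm, "length_mm", min = 0, strict_min = TRUE)
  assert_scalar_number(origin_mm, "origin_mm", min = 0)
  assert_scalar_number(front_mm, "front_mm", min = 0)
  if (!(origin_mm < front_mm && front_mm <= length_mm)) {
    rtlc_stop("marks must satisfy 0 <= origin_mm < front_mm <= length_mm",
              "rtlc_invalid_parameter")
  }
  if (!is.list(spots) || !all(vapply(spots, inherits, logical(1), "spot_deposit"))) {
    rtlc_stop("'spots' must be a list of spot_deposit objects",
              "rtlc_invalid_parameter")
  }
  for (s in spots) {
    if (s$position_mm > length_mm) {
      rtlc_stop(sprintf("spot at %g mm lies beyond the %g mm strip",
                        s$position_mm, length_mm), "rtlc_invalid_parameter")
    }
  }
  structure(list(length_mm = length_mm, spots = spots,
                 origin_mm = origin_mm, front_mm = front_mm),
            class = "strip_model")
}

#' Instrument configuration for one acquisition
#'
#' @param scan_range_mm Scanned length in mm. The firmware caps the travel at
#'   120 mm, so values above 120 are rejected.
#' @param step_mm Channel pitch in mm (detector step size); default 0.5.
#' @param total_time_s Total acquisition time for the full scan, seconds. It is
#'   divided evenly over the channels (dwell time per channel).
#' @param efficiency_cps_per_MBq Whole-spot detection efficiency: the count
#'   rate summed over all channels produced by 1 MBq well inside the scan
#'   range. Default 5000 cps/MBq.
#' @param background_cps Background count rate per channel dwell, cps.
#'   Default 0.31 cps.
#' @param response_sigma_mm Detector line-spread standard deviation in mm. The
#'   default 1.486 mm gives a point-source FWHM of about 3.5 mm.
#' @param half_life_h Isotope half-life in hours; default 6.0067 h
#'   (technetium-99m).
#' @param start_offset_h Elapsed time between the activity reference time and
#'   the start of the scan, hours.
#' @param seed Optional random seed; identical (model, config, seed) gives a
#'   byte-identical chromatogram.
#' @return An object of class `scan_config`.
#' @examples
#' scan_config(total_time_s = 120, seed = 1)
#' @export
scan_config <- function(scan_range_mm = 120, step_mm = 0.5, total_time_s = 120,
                        efficiency_cps_per_MBq = 5000, background_cps = 0.31,
                        response_sigma_mm = 1.486, half_life_h = 6.0067,
                        start_offset_h = 0, seed = NULL) {
  assert_scalar_number(scan_range_mm, "scan_range_mm", min = 0, strict_min = TRUE)
  if (scan_range_mm > 120) {
    rtlc_stop("scan_range_mm exceeds the 120 mm software safety limit",
              "rtlc_invalid_parameter")
  }
  assert_scalar_number(step_mm, "step_mm", min = 0, strict_min = TRUE)
  assert_scalar_number(total_time_s, "total_time_s", min = 0, strict_min = TRUE)
  assert_scalar_number(efficiency_cps_per_MBq, "efficiency_cps_per_MBq", min = 0)
  assert_scalar_number(background_cps, "background_cps", min = 0)
  assert_scalar_number(response_sigma_mm, "response_sigma_mm", min = 0)
  assert_scalar_number(half_life_h, "half_life_h", min = 0, strict_min = TRUE)
  assert_scalar_number(start_offset_h, "start_offset_h", min = 0)
  assert_scalar_number(seed, "seed", allow_null = TRUE)
  structure(list(scan_range_mm = scan_range_mm, step_mm = step_mm,
                 total_time_s = total_time_s,
                 efficiency_cps_per_MBq = efficiency_cps_per_MBq,
                 background_cps = background_cps,
                 response_sigma_mm = response_sigma_mm,
                 half_life_h = half_life_h, start_offset_h = start_offset_h,
                 seed = seed),
            class = "scan_config")
}

#' Metadata block of an acquisition record
#'
#' @param batch_number,operator Free-text identification fields.
#' @param scan_range_mm,acquisition_time_s Scan geometry and total time.
#' @param origin_mm,front_mm Solvent origin and front marks (must satisfy
#'   `origin_mm < front_mm`).
#' @param timestamp ISO-8601 text. Defaults to a fixed epoch string so that
#'   simulated records are reproducible from (model, config, seed) alone; pass
#'   a real timestamp for live acquisitions.
#' @return An object of class `acquisition_metadata`.
#' @export
acquisition_metadata <- function(batch_number, operator, scan_range_mm,
                                 acquisition_time_s, origin_mm, front_mm,
                                 timestamp = "1970-01-01T00:00:00Z") {
  assert_scalar_number(scan_range_mm, "scan_range_mm", min = 0, strict_min = TRUE)
  assert_scalar_number(acquisition_time_s, "acquisition_time_s",
                       min = 0, strict_min = TRUE)
  assert_scalar_number(origin_mm, "origin_mm")
  assert_scalar_number(front_mm, "front_mm")
  if (!(origin_mm < front_mm)) {
    rtlc_stop("origin_mm must be smaller than front_mm", "rtlc_invalid_parameter")
  }
  structure(list(batch_number = as.character(batch_number)[1],
                 operator = as.character(operator)[1],
                 scan_range_mm = scan_range_mm,
                 acquisition_time_s = acquisition_time_s,
                 origin_mm = origin_mm, front_mm = front_mm,
                 timestamp = as.character(timestamp)[1]),
            class = "acquisition_metadata")
}

#' Construct a chromatogram
#'
#' One acquisition: ordered channel centres at constant pitch, non-negative
#' integer counts, the dwell time per channel, the acquisition metadata and an
#' integrity status carried from the record the data came from.
#'
#' @param positions_mm Strictly increasing channel centres at constant pitch, mm.
#' @param counts Non-negative integer counts, one per channel.
#' @param dwell_s Counting time per channel, seconds.
#' @param metadata An [acquisition_metadata()] object.
#' @param integrity One of `"verified"`, `"failed"`, `"unhashed"`.
#' @return An object of class `chromatogram`.
#' @export
chromatogram <- function(positions_mm, counts, dwell_s, metadata,
                         integrity = "unhashed") {
  if (length(positions_mm) != length(counts)) {
    rtlc_stop("positions and counts must have equal length",
              "rtlc_invalid_parameter")
  }
  if (length(positions_mm) < 1L) {
    rtlc_stop("a chromatogram needs at least one channel",
              "rtlc_invalid_parameter")
  }
  if (length(positions_mm) > 1L) {
    d <- diff(positions_mm)
    if (any(d <= 0) || max(abs(d - d[1])) > 1e-9) {
      rtlc_stop("positions must be strictly increasing at constant pitch",
                "rtlc_invalid_parameter")
    }
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    rtlc_stop("counts must be non-negative integers", "rtlc_invalid_parameter")
  }
  assert_scalar_number(dwell_s, "dwell_s", min = 0, strict_min = TRUE)
  if (!inherits(metadata, "acquisition_metadata")) {
    rtlc_stop("'metadata' must be an acquisition_metadata object",
              "rtlc_invalid_parameter")
  }
  integrity <- match.arg(integrity, c("verified", "failed", "unhashed"))
  structure(list(positions_mm = as.numeric(positions_mm),
                 counts = as.integer(round(counts)),
                 dwell_s = dwell_s, metadata = metadata,
                 integrity = integrity),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf(
    "<chromatogram> %d channels, pitch %.3g mm, dwell %.4g s, total %d counts\n",
    length(x$counts),
    if (length(x$positions_mm) > 1) diff(x$positions_mm[1:2]) else NA_real_,
    x$dwell_s, sum(x$counts)))
  cat(sprintf("  batch %s / operator %s / integrity %s\n",
              x$metadata$batch_number, x$metadata$operator, x$integrity))
  invisible(x)
}

#' Exponential radioactive decay
#'
#' @param a0_MBq Activity at the reference time, MBq.
#' @param elapsed_h Elapsed time in hours (>= 0).
#' @param half_life_h Half-life in hours (> 0).
#' @return Activity after `elapsed_h` hours: `a0 * 2^(-elapsed/half_life)`.
#' @examples
#' decay_activity(18.5, 6.0067, 6.0067)  # one half-life -> 9.25 MBq
#' @export
decay_activity <- function(a0_MBq, elapsed_h, half_life_h) {
  assert_scalar_number(half_life_h, "half_life_h", min = 0, strict_min = TRUE)
  if (!is.numeric(a0_MBq) || any(a0_MBq < 0)) {
    rtlc_stop("'a0_MBq' must be non-negative", "rtlc_invalid_parameter")
  }
  if (!is.numeric(elapsed_h) || any(elapsed_h < 0)) {
    rtlc_stop("'elapsed_h' must be non-negative", "rtlc_invalid_parameter")
  }
  a0_MBq * 2^(-elapsed_h / half_life_h)
}

#' Channel centre positions for a scan configuration
#'
#' The detector homes against a limit switch and then steps along the strip;
#' channel i (0-based) counts while centred at `(i + 1/2) * step_mm`. A 120 mm
#' range at the default 0.5 mm pitch gives 240 channels.
#'
#' @param config A [scan_config()].
#' @return Numeric vector of channel centres in mm.
#' @examples
#' length(channel_positions(scan_config()))  # 240
#' @export
channel_positions <- function(config) {
  stopifnot(inherits(config, "scan_config"))
  n <- floor(config$scan_range_mm / config$step_mm)
  if (n < 1L) {
    rtlc_stop("step_mm exceeds scan_range_mm: no channels",
              "rtlc_invalid_parameter")
  }
  (seq_len(n) - 0.5) * config$step_mm
}

#' Gaussian line-spread weight of a channel
#'
#' The collimator slit and crystal response are modelled as a Gaussian
#' line-spread: a channel at distance `d` from a point source receives the
#' fraction `step_mm * dnorm(d, 0, sigma)` of the source's whole-strip count
#' rate. Summed over a channel grid wide enough to cover the response, the
#' weights add to 1, so the configured efficiency is a whole-spot quantity.
#'
#' @param distance_mm Distance(s) between channel centre and source, mm.
#' @param response_sigma_mm Line-spread standard deviation, mm. A value of 0
#'   selects the delta-function convention: weight 1 for the nearest channel
#'   (|d| <= step/2), 0 elsewhere.
#' @param step_mm Channel pitch, mm.
#' @return Dimensionless weight(s), same length as `distance_mm`.
#' @export
line_spread_weight <- function(distance_mm, response_sigma_mm, step_mm) {
  assert_scalar_number(response_sigma_mm, "response_sigma_mm", min = 0)
  assert_scalar_number(step_mm, "step_mm", min = 0, strict_min = TRUE)
  if (response_sigma_mm == 0) {
    return(as.numeric(abs(distance_mm) <= step_mm / 2))
  }
  step_mm * dnorm(distance_mm, mean = 0, sd = response_sigma_mm)
}

#' Expected count rate at a detector position
#'
#' Composes decay, whole-spot efficiency and the line-spread response:
#' `rate = background + sum_k eff * A_k(elapsed) * w(position - mu_k)`, where
#' the effective spread of spot k combines detector response and deposit
#' width in quadrature, `sigma_eff^2 = sigma_r^2 + deposit_sigma^2`.
#'
#' @param model A [strip_model()].
#' @param config A [scan_config()].
#' @param position_mm Detector position(s), mm.
#' @param elapsed_h Time since the activity reference, hours.
#' @return Expected rate(s) in counts per second; never below the background.
#' @export
expected_rate <- function(model, config, position_mm, elapsed_h = 0) {
  stopifnot(inherits(model, "strip_model"), inherits(config, "scan_config"))
  rate <- rep(config$background_cps, length(position_mm))
  for (s in model$spots) {
    a <- decay_activity(s$activity_MBq, elapsed_h, config$half_life_h)
    sigma_eff <- sqrt(config$response_sigma_mm^2 + s$deposit_sigma_mm^2)
    rate <- rate + config$efficiency_cps_per_MBq * a *
      line_spread_weight(position_mm - s$position_mm, sigma_eff, config$step_mm)
  }
  rate
}

#' Simulate one acquisition
#'
#' Splits the total acquisition time evenly over the channels and draws each
#' channel's counts from a Poisson distribution with mean
#' `dwell * expected_rate`, evaluating the decay at that channel's own dwell
#' start time (`start_offset_h + i * dwell / 3600`), so decay during the scan
#' is modelled. With a non-NULL seed in the configuration the output is
#' reproducible bit for bit; the caller's random stream is left untouched.
#'
#' @param model A [strip_model()].
#' @param config A [scan_config()].
#' @param batch_number,operator,timestamp Metadata fields recorded with the
#'   acquisition; the default timestamp is a fixed epoch string so simulated
#'   records are fully reproducible.
#' @return A [chromatogram()] with integrity `"unhashed"` (the footprint is
#'   added when the record is serialized).
#' @examples
#' m <- strip_model(120, list(spot_deposit(60, 1)), origin_mm = 10, front_mm = 110)
#' simulate_scan(m, scan_config(seed = 1))
#' @export
simulate_scan <- function(model, config, batch_number = "SIM",
                          operator = "simulator",
                          timestamp = "1970-01-01T00:00:00Z") {
  stopifnot(inherits(model, "strip_model"), inherits(config, "scan_config"))
  pos <- channel_positions(config)
  n <- length(pos)
  dwell <- config$total_time_s / n
  elapsed <- config$start_offset_h + (seq_len(n) - 1L) * dwell / 3600
  mu <- numeric(n)
  for (i in seq_len(n)) {
    mu[i] <- dwell * expected_rate(model, config, pos[i], elapsed[i])
  }
  counts <- with_seed(config$seed, rpois(n, mu))
  md <- acquisition_metadata(batch_number = batch_number, operator = operator,
                             scan_range_mm = config$scan_range_mm,
                             acquisition_time_s = config$total_time_s,
                             origin_mm = model$origin_mm,
                             front_mm = model$front_mm,
                             timestamp = timestamp)
  chromatogram(pos, counts, dwell, md, integrity = "unhashed")
}

# Time for an activity a0 to decay to `target` (hours).
decay_time_to <- function(a0_MBq, target_MBq, half_life_h) {
  log2(a0_MBq / target_MBq) * half_life_h
}

#' Ready-made qualification scenarios
#'
#' Factory for the strip/instrument pairs used by the qualification suite:
#'
#' * `"background"`: blank 120 mm strip, one 300 s (5 min) acquisition.
#' * `"linearity"`: a single 18.5 MBq spot at the strip centre, scanned for
#'   2 min at nine elapsed times spaced evenly from 0 to the time at which the
#'   sample has decayed to 2.5 kBq (about 77.2 h for technetium-99m); the
#'   offsets are returned in `$start_offsets_h`.
#' * `"repeatability"`: 7.4 MBq and 0.4 MBq spots near opposite ends of a
#'   120 mm strip (a designed impurity of 0.4/7.8 = 5.1%), 2 min acquisition.
#' * `"loq"`: a single spot of activity `activity_MBq` at the centre, 300 s
#'   acquisition (low-activity samples need the longer dwell).
#' * `"position_accuracy"`: nine equal 1 MBq spots at 10, 20, ..., 90 mm on a
#'   100 mm strip with origin 0 and front 100 mm, 2 min acquisition.
#' * `"comparison_pair"`: one main + impurity strip (impurity fraction
#'   `impurity_percent`) plus configurations for two virtual instruments — the
#'   device under test and a reference scanner with ten times its efficiency.
#'
#' @param name Scenario name (see above).
#' @param seed Seed stored in the returned configuration(s).
#' @param activity_MBq Spot activity for the `"loq"` scenario, MBq.
#' @param impurity_percent Designed impurity for `"comparison_pair"`, percent.
#' @return A list with elements `model` and `config`, plus scenario-specific
#'   extras (`start_offsets_h`, `expected_positions_mm`, `config_reference`, ...).
#' @export
make_scenario <- function(name, seed = NULL, activity_MBq = 0.0025,
                          impurity_percent = 5) {
  valid <- c("background", "linearity", "repeatability", "loq",
             "position_accuracy", "comparison_pair")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid)) {
    rtlc_stop(sprintf("unknown scenario '%s'; valid scenarios: %s",
                      paste(name, collapse = ","),
                      paste(valid, collapse = ", ")),
              "rtlc_invalid_parameter")
  }
  switch(name,
    background = list(
      model = strip_model(120, list(), origin_mm = 10, front_mm = 110),
      config = scan_config(total_time_s = 300, seed = seed)),
    linearity = {
      cfg <- scan_config(total_time_s = 120, seed = seed)
      t_end <- decay_time_to(18.5, 0.0025, cfg$half_life_h)
      list(
        model = strip_model(120, list(spot_deposit(60, 18.5)),
                            origin_mm = 10, front_mm = 110),
        config = cfg,
        a0_MBq = 18.5,
        start_offsets_h = seq(0, t_end, length.out = 9))
    },
    repeatability = list(
      model = strip_model(120,
                          list(spot_deposit(20, 7.4), spot_deposit(100, 0.4)),
                          origin_mm = 10, front_mm = 110),
      config = scan_config(total_time_s = 120, seed = seed)),
    loq = list(
      model = strip_model(120, list(spot_deposit(60, activity_MBq)),
                          origin_mm = 10, front_mm = 110),
      config = scan_config(total_time_s = 300, seed = seed)),
    position_accuracy = list(
      model = strip_model(100,
                          lapply(seq(10, 90, by = 10), spot_deposit,
                                 activity_MBq = 1),
                          origin_mm = 0, front_mm = 100),
      config = scan_config(scan_range_mm = 100, total_time_s = 120, seed = seed),
      expected_positions_mm = seq(10, 90, by = 10)),
    comparison_pair = {
      main <- 100 - impurity_percent
      list(
        model = strip_model(120,
                            list(spot_deposit(30, 7.4 * main / 100),
                                 spot_deposit(95, 7.4 * impurity_percent / 100)),
                            origin_mm = 10, front_mm = 110),
        config = scan_config(total_time_s = 120, seed = seed),
        config_reference = scan_config(total_time_s = 120,
                                       efficiency_cps_per_MBq = 50000,
                                       seed = if (is.null(seed)) NULL else seed + 1L))
    })
}
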