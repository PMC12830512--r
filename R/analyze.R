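# Chromatogram analytics, mirroring the integration spreadsheet: the user
# supplies named integration regions (peaks plus exactly one background
# region); the package computes background-subtracted areas, relative
# percentages, retention factors, pharmacopoeial SNR (2H/h), FWHM and the
# strip's radiochemical purity.

#' Build an integration region set
#'
#' @param label Character vector of region names.
#' @param start_mm,end_mm Region bounds in strip coordinates (mm);
#'   `start_mm < end_mm` per region. A channel belongs to a region when its
#'   centre lies in `[start_mm, end_mm)`.
#' @param kind `"peak"` or `"background"`; exactly one background region is
#'   required per analysis and peak regions must not overlap.
#' @return A `data.frame` of class `region_set`.
#' @examples
#' region_set(c("main", "impurity", "bg"), c(10, 90, 45), c(35, 115, 70),
#'            c("peak", "peak", "background"))
#' @export
region_set <- function(label, start_mm, end_mm, kind) {
  if (length(label) == 0) {
    rtlc_stop("region set must contain at least one region",
              "rtlc_invalid_parameter")
  }
  if (!all(lengths(list(start_mm, end_mm, kind)) == length(label))) {
    rtlc_stop("label, start_mm, end_mm and kind must have equal length",
              "rtlc_invalid_parameter")
  }
  kind <- match.arg(kind, c("peak", "background"), several.ok = TRUE)
  if (any(start_mm >= end_mm)) {
    rtlc_stop("every region needs start_mm < end_mm", "rtlc_invalid_parameter")
  }
  if (sum(kind == "background") != 1L) {
    rtlc_stop("exactly one background region is required",
              "rtlc_invalid_parameter")
  }
  pk <- which(kind == "peak")
  if (length(pk) >= 2) {
    o <- pk[order(start_mm[pk])]
    if (any(end_mm[o][-length(o)] > start_mm[o][-1])) {
      rtlc_stop("peak regions must not overlap", "rtlc_invalid_parameter")
    }
  }
  structure(data.frame(label = as.character(label), start_mm = start_mm,
                       end_mm = end_mm, kind = kind,
                       stringsAsFactors = FALSE),
            class = c("region_set", "data.frame"))
}

#' Read / write region sets as CSV
#'
#' The on-disk form is a plain CSV with columns `label,start_mm,end_mm,kind`.
#'
#' @param path File path.
#' @return `read_regions()` returns a [region_set()]; `write_regions()`
#'   returns `path` invisibly.
#' @export
read_regions <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "start_mm", "end_mm", "kind")
  if (!all(need %in% names(df))) {
    rtlc_stop("region file must have columns label,start_mm,end_mm,kind",
              "rtlc_parse_error")
  }
  region_set(df$label, df$start_mm, df$end_mm, df$kind)
}

#' @rdname read_regions
#' @param regions A [region_set()].
#' @export
write_regions <- function(regions, path) {
  write.csv(as.data.frame(regions), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Indices of channels whose centre falls inside [start, end).
region_channels <- function(chrom, start_mm, end_mm) {
  which(chrom$positions_mm >= start_mm & chrom$positions_mm < end_mm)
}

check_region_bounds <- function(chrom, region) {
  span <- range(chrom$positions_mm)
  pitch <- if (length(chrom$positions_mm) > 1) {
    diff(chrom$positions_mm[1:2])
  } else {
    Inf
  }
  if (region$start_mm < span[1] - pitch / 2 || region$end_mm > span[2] + pitch / 2) {
    rtlc_stop(sprintf("region '%s' [%g, %g) lies outside the scanned range",
                      region$label, region$start_mm, region$end_mm),
              "rtlc_bounds_error")
  }
}

#' Baseline level and noise of a background region
#'
#' The baseline level is the flat arithmetic mean of the counts in the
#' background region; the noise is the peak-to-peak amplitude (max - min),
#' the pharmacopoeial convention used by the 2H/h signal-to-noise ratio.
#'
#' @param chrom A [chromatogram()].
#' @param background_region One row of a [region_set()] with
#'   `kind == "background"`, or a full region set (its background row is used).
#' @return A list of class `baseline_stats` with `mean_counts_per_channel`
#'   and `noise_pp_counts`.
#' @export
baseline_stats <- function(chrom, background_region) {
  stopifnot(inherits(chrom, "chromatogram"))
  if (inherits(background_region, "region_set")) {
    background_region <- background_region[background_region$kind == "background", ]
  }
  if (nrow(background_region) != 1L) {
    rtlc_stop("exactly one background region is required",
              "rtlc_invalid_parameter")
  }
  check_region_bounds(chrom, background_region)
  idx <- region_channels(chrom, background_region$start_mm,
                         background_region$end_mm)
  if (length(idx) < 2L) {
    rtlc_stop("background region covers fewer than 2 channels",
              "rtlc_insufficient_baseline")
  }
  v <- chrom$counts[idx]
  structure(list(mean_counts_per_channel = mean(v),
                 noise_pp_counts = max(v) - min(v)),
            class = "baseline_stats")
}

#' Net (background-subtracted) area of a region
#'
#' Subtracts the flat baseline level from every channel in the region and
#' sums: `net = sum(counts - baseline_mean)`. The result can be negative for
#' blank regions (Poisson fluctuation); percentage normalization clamps such
#' areas to zero, see [relative_percentages()].
#'
#' @param chrom A [chromatogram()].
#' @param region One row of a [region_set()].
#' @param baseline A [baseline_stats()].
#' @return Net area in counts.
#' @export
integrate_region <- function(chrom, region, baseline) {
  stopifnot(inherits(chrom, "chromatogram"), inherits(baseline, "baseline_stats"))
  check_region_bounds(chrom, region)
  idx <- region_channels(chrom, region$start_mm, region$end_mm)
  sum(chrom$counts[idx] - baseline$mean_counts_per_channel)
}

#' Relative percentages of net peak areas
#'
#' Negative net areas (possible on blank regions through Poisson fluctuation)
#' are clamped to zero with a warning before normalization, so percentages
#' always lie in \[0, 100\] and sum to 100.
#'
#' @param net_areas Numeric vector of net areas, one per peak region.
#' @return Percentages summing to 100.
#' @examples
#' relative_percentages(c(7.4, 0.4))  # 94.87, 5.13
#' @export
relative_percentages <- function(net_areas) {
  if (length(net_areas) < 1L) {
    rtlc_stop("at least one peak region is required", "rtlc_invalid_parameter")
  }
  if (any(net_areas < 0)) {
    rtlc_warn("negative net area(s) clamped to 0 before normalization",
              "rtlc_negative_area")
    net_areas <- pmax(net_areas, 0)
  }
  total <- sum(net_areas)
  if (total <= 0) {
    rtlc_stop("total net peak area is not positive: percentages undefined",
              "rtlc_undefined_percentage")
  }
  100 * net_areas / total
}

#' Retention factor
#'
#' Distance travelled by the solute over distance travelled by the solvent
#' front, both measured from the application origin.
#'
#' @param peak_position_mm Peak position, mm.
#' @param origin_mm,front_mm Solvent origin and front marks, mm
#'   (`origin_mm < front_mm`).
#' @return Rf, dimensionless. Values outside \[-0.05, 1.05\] trigger an
#'   out-of-strip warning but are returned unchanged.
#' @export
retention_factor <- function(peak_position_mm, origin_mm, front_mm) {
  if (!(front_mm > origin_mm)) {
    rtlc_stop("solvent front must lie beyond the origin", "rtlc_invalid_marks")
  }
  rf <- (peak_position_mm - origin_mm) / (front_mm - origin_mm)
  if (any(rf < -0.05 | rf > 1.05)) {
    rtlc_warn("retention factor outside [-0.05, 1.05]: peak off the strip?",
              "rtlc_out_of_strip")
  }
  rf
}

#' Pharmacopoeial signal-to-noise ratio
#'
#' `SNR = 2 * H / h`: twice the background-subtracted peak height over the
#' peak-to-peak baseline noise. A peak whose net height is five times the
#' baseline noise therefore has SNR = 10, the limit-of-quantification
#' threshold.
#'
#' @param peak_height_net Background-subtracted peak maximum, counts.
#' @param noise_pp Peak-to-peak baseline noise, counts.
#' @return The ratio; `Inf` with a warning when the baseline noise is zero
#'   (idealized noiseless input).
#' @export
snr <- function(peak_height_net, noise_pp) {
  assert_scalar_number(peak_height_net, "peak_height_net")
  assert_scalar_number(noise_pp, "noise_pp", min = 0)
  if (noise_pp == 0) {
    rtlc_warn("baseline noise is zero: SNR is infinite (noiseless input)",
              "rtlc_zero_noise")
    return(Inf)
  }
  2 * peak_height_net / noise_pp
}

#' Full width at half maximum of a peak
#'
#' Works on the background-subtracted profile inside the region: finds the
#' maximum (ties broken toward lower position) and locates the two
#' half-maximum crossings by linear interpolation between adjacent channels.
#' For a Gaussian peak of standard deviation `sigma` this returns
#' `2.3548 * sigma` to within one channel pitch.
#'
#' @param chrom A [chromatogram()].
#' @param region One row of a [region_set()].
#' @param baseline A [baseline_stats()].
#' @return Width in mm.
#' @export
fwhm <- function(chrom, region, baseline) {
  stopifnot(inherits(chrom, "chromatogram"), inherits(baseline, "baseline_stats"))
  check_region_bounds(chrom, region)
  idx <- region_channels(chrom, region$start_mm, region$end_mm)
  if (length(idx) < 3L) {
    rtlc_stop("region too narrow for a width estimate", "rtlc_undefined_fwhm")
  }
  net <- chrom$counts[idx] - baseline$mean_counts_per_channel
  pos <- chrom$positions_mm[idx]
  imax <- which.max(net)  # which.max takes the first (lowest-position) tie
  hmax <- net[imax]
  if (hmax <= 0) {
    rtlc_stop("peak does not rise above the baseline: FWHM undefined",
              "rtlc_undefined_fwhm")
  }
  half <- hmax / 2

  cross <- function(i_lo, i_hi) {
    # linear interpolation of the half-maximum crossing between two channels
    pos[i_lo] + (half - net[i_lo]) / (net[i_hi] - net[i_lo]) *
      (pos[i_hi] - pos[i_lo])
  }
  left <- NA_real_
  if (imax > 1L) {
    for (i in seq(imax, 2L)) {
      if (net[i - 1L] < half && net[i] >= half) {
        left <- cross(i - 1L, i)
        break
      }
    }
  }
  right <- NA_real_
  if (imax < length(net)) {
    for (i in seq(imax, length(net) - 1L)) {
      if (net[i] >= half && net[i + 1L] < half) {
        right <- cross(i + 1L, i)
        break
      }
    }
  }
  if (is.na(left) || is.na(right)) {
    rtlc_stop("half-maximum crossing falls outside the region: FWHM undefined",
              "rtlc_undefined_fwhm")
  }
  right - left
}

#' Analyze a strip: per-region metrics and radiochemical purity
#'
#' Assembles the full spreadsheet calculation: baseline statistics from the
#' background region, then for each peak region the net area, relative
#' percentage, peak position (channel of maximum net counts, ties toward
#' lower position), retention factor (using the origin/front marks from the
#' record metadata), SNR and FWHM. The strip's radiochemical purity is the
#' relative percentage of the main-species region.
#'
#' Records whose integrity footprint failed verification are refused: results
#' from tampered raw data must not enter a quality-control decision.
#'
#' @param record An `acquisition_record` from [read_record()]/[parse_record()],
#'   or a bare [chromatogram()] (treated as unhashed).
#' @param regions A [region_set()] with at least one peak region.
#' @param main_label Label of the peak region holding the desired chemical
#'   species. Default: the peak with the largest net area.
#' @return An object of class `analysis_report`: list with `peaks` (one row
#'   per peak region: label, net_area_counts, percent, rf, snr, fwhm_mm,
#'   peak_position_mm, peak_height_counts), `baseline`, `rcp_percent`,
#'   `main_label` and `integrity`. FWHM that is undefined for a region (peak
#'   not above baseline, crossing outside bounds) is reported as `NA`.
#' @export
analyze_strip <- function(record, regions, main_label = NULL) {
  chrom <- if (inherits(record, "acquisition_record")) {
    record$chromatogram
  } else if (inherits(record, "chromatogram")) {
    record
  } else {
    rtlc_stop("'record' must be an acquisition_record or chromatogram",
              "rtlc_invalid_parameter")
  }
  if (chrom$integrity == "failed") {
    rtlc_stop("record failed integrity verification: refusing to analyze",
              "rtlc_integrity_error")
  }
  if (!inherits(regions, "region_set")) {
    rtlc_stop("'regions' must be a region_set", "rtlc_invalid_parameter")
  }
  bl <- baseline_stats(chrom, regions)
  peaks <- regions[regions$kind == "peak", , drop = FALSE]
  if (nrow(peaks) == 0) {
    rtlc_stop("region set contains no peak regions", "rtlc_invalid_parameter")
  }

  n <- nrow(peaks)
  net <- numeric(n)
  pos_pk <- numeric(n)
  height <- numeric(n)
  width <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    rg <- peaks[i, ]
    net[i] <- integrate_region(chrom, rg, bl)
    idx <- region_channels(chrom, rg$start_mm, rg$end_mm)
    net_prof <- chrom$counts[idx] - bl$mean_counts_per_channel
    j <- which.max(net_prof)
    pos_pk[i] <- chrom$positions_mm[idx][j]
    height[i] <- net_prof[j]
    width[i] <- tryCatch(fwhm(chrom, rg, bl),
                         rtlc_undefined_fwhm = function(e) NA_real_)
  }
  pct <- relative_percentages(net)
  rf <- retention_factor(pos_pk, chrom$metadata$origin_mm,
                         chrom$metadata$front_mm)
  snr_v <- vapply(height, function(h) {
    if (bl$noise_pp_counts == 0) Inf else 2 * h / bl$noise_pp_counts
  }, numeric(1))

  if (is.null(main_label)) {
    main_label <- peaks$label[which.max(net)]
  }
  if (!(main_label %in% peaks$label)) {
    rtlc_stop(sprintf("main_label '%s' is not a peak region", main_label),
              "rtlc_invalid_parameter")
  }
  rcp <- pct[match(main_label, peaks$label)]

  structure(list(
    peaks = data.frame(label = peaks$label, net_area_counts = net,
                       percent = pct, rf = rf, snr = snr_v, fwhm_mm = width,
                       peak_position_mm = pos_pk, peak_height_counts = height,
                       stringsAsFactors = FALSE),
    baseline = bl,
    rcp_percent = rcp,
    main_label = main_label,
    integrity = chrom$integrity),
    class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> RCP = %.2f%% (main region '%s', integrity %s)\n",
              x$rcp_percent, x$main_label, x$integrity))
  df <- x$peaks
  df$net_area_counts <- round(df$net_area_counts, 1)
  df$percent <- round(df$percent, 2)
  df$rf <- round(df$rf, 3)
  df$snr <- round(df$snr, 1)
  df$fwhm_mm <- round(df$fwhm_mm, 2)
  print(df, row.names = FALSE)
  cat(sprintf("baseline: mean %.3f counts/channel, noise (p-p) %g counts\n",
              x$baseline$mean_counts_per_channel, x$baseline$noise_pp_counts))
  invisible(x)
}

#' Overall purity of a dual-strip assay
#'
#' Dual-strip kit monographs quantify one impurity per strip (in two solvent
#' systems); the overall radiochemical purity is
#' `100 - impurity_1 - impurity_2`, floored at zero.
#'
#' @param report_strip1,report_strip2 [analyze_strip()] reports; each strip's
#'   impurity is `100 - rcp_percent` of that strip.
#' @return Overall RCP in percent.
#' @export
rcp_dual_strip <- function(report_strip1, report_strip2) {
  stopifnot(inherits(report_strip1, "analysis_report"),
            inherits(report_strip2, "analysis_report"))
  imp1 <- 100 - report_strip1$rcp_percent
  imp2 <- 100 - report_strip2$rcp_percent
  rcp <- 100 - imp1 - imp2
  if (rcp < 0) {
    rtlc_warn("impurities exceed 100%: overall RCP clamped to 0",
              "rtlc_rcp_clamped")
    rcp <- 0
  }
  rcp
}
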