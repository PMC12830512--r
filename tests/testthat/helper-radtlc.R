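# Fixture builders shared across the suite. Everything is generated in code;
# no stored data files.

test_metadata <- function(scan_range_mm = 120, acquisition_time_s = 120,
                          origin_mm = 10, front_mm = 110) {
  acquisition_metadata(batch_number = "TST-001", operator = "tester",
                       scan_range_mm = scan_range_mm,
                       acquisition_time_s = acquisition_time_s,
                       origin_mm = origin_mm, front_mm = front_mm)
}

# Chromatogram with explicit counts on the default half-offset grid.
test_chrom <- function(counts, step = 0.5, dwell = 0.5,
                       origin_mm = 0, front_mm = NULL) {
  n <- length(counts)
  pos <- (seq_len(n) - 0.5) * step
  if (is.null(front_mm)) front_mm <- max(pos)
  chromatogram(pos, counts, dwell,
               test_metadata(scan_range_mm = n * step,
                             acquisition_time_s = dwell * n,
                             origin_mm = origin_mm, front_mm = front_mm))
}

# Noiseless Gaussian peak on a flat integer baseline: amplitude is the peak
# counts at the centre channel.
gaussian_chrom <- function(sigma_mm, centre_mm = 60, amplitude = 1e6,
                           range_mm = 120, step = 0.5, baseline = 0) {
  pos <- (seq_len(floor(range_mm / step)) - 0.5) * step
  profile <- exp(-(pos - centre_mm)^2 / (2 * sigma_mm^2))
  counts <- round(baseline + amplitude * profile)
  chromatogram(pos, counts, 0.5,
               test_metadata(scan_range_mm = range_mm,
                             acquisition_time_s = 0.5 * length(pos),
                             origin_mm = 0, front_mm = range_mm))
}

# Random but valid chromatogram for round-trip property tests.
random_chrom <- function() {
  n <- sample(5:60, 1)
  step <- sample(c(0.25, 0.5, 1, 2), 1)
  counts <- rpois(n, lambda = sample(c(0.2, 3, 50, 4000), 1))
  dwell <- runif(1, 0.1, 5)
  pos <- (seq_len(n) - 0.5) * step
  md <- acquisition_metadata(
    batch_number = paste0("B", sample(1e5, 1)),
    operator = sample(c("alice", "bob", "qc-2"), 1),
    scan_range_mm = n * step,
    acquisition_time_s = dwell * n,
    origin_mm = 0.05 * n * step,
    front_mm = 0.9 * n * step,
    timestamp = "2026-01-02T03:04:05Z")
  chromatogram(pos, counts, dwell, md)
}

two_peak_regions <- function() {
  region_set(c("main", "impurity", "bg"), c(5, 85, 50), c(45, 115, 80),
             c("peak", "peak", "background"))
}
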