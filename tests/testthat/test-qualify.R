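test_that("background_assessment averages per-record count rates", {
  zeros <- lapply(1:3, function(i) test_chrom(rep(0L, 60), dwell = 5))
  bg0 <- background_assessment(zeros)
  expect_equal(bg0$mean_cps, 0)
  expect_equal(bg0$sd_cps, 0)

  # totals 90, 93, 96 counts over 300 s each -> mean 0.31 cps
  mk_total <- function(total) {
    counts <- rep(total %/% 60L, 60)
    counts[1] <- counts[1] + total %% 60L
    test_chrom(as.integer(counts), dwell = 5)
  }
  bg <- background_assessment(lapply(c(90L, 93L, 96L), mk_total))
  expect_equal(bg$mean_cps, 0.31)
  expect_equal(bg$sd_cps, sd(c(90, 93, 96) / 300))

  short <- test_chrom(rep(0L, 60), dwell = 1)
  expect_error(background_assessment(list(zeros[[1]], short)),
               class = "rtlc_invalid_input")
  expect_error(background_assessment(zeros[1]), class = "rtlc_invalid_input")
})

test_that("background rate is recovered unbiased from simulated blanks", {
  scen <- make_scenario("background")
  cfg <- scan_config(scan_range_mm = 20, total_time_s = 30,
                     background_cps = 0.31)
  model <- strip_model(20, list(), origin_mm = 2, front_mm = 18)
  n_rep <- 200
  records <- lapply(seq_len(n_rep), function(k) {
    cfg$seed <- 40000 + k
    simulate_scan(model, cfg)
  })
  est <- background_assessment(records)
  # SE of the mean rate: sqrt(b / (T * n)) for Poisson counting
  se <- sqrt(0.31 / (30 * n_rep))
  expect_lt(abs(est$mean_cps - 0.31), 4 * se)
})

test_that("linearity_test is exact in the noiseless limit and errors on flat x", {
  regions <- region_set(c("peak", "background"), c(45, 85), c(75, 115),
                        c("peak", "background"))
  m <- strip_model(120, list(spot_deposit(60, 18.5)), origin_mm = 10,
                   front_mm = 110)
  cfg <- scan_config(total_time_s = 120)
  pos <- channel_positions(cfg)
  offs <- seq(0, 40, length.out = 5)
  noiseless <- lapply(offs, function(t0) {
    mu <- 0.5 * expected_rate(m, cfg, pos, elapsed_h = t0)
    test_chrom(as.integer(round(mu)))
  })
  res <- linearity_test(noiseless, offs, 18.5, 6.0067, regions)
  expect_gt(res$pearson_r, 0.999999)
  expect_true(res$pass)
  expect_equal(nrow(res$points), 5)

  expect_error(linearity_test(noiseless, rep(0, 5), 18.5, 6.0067, regions),
               class = "rtlc_undefined_correlation")
  expect_error(linearity_test(noiseless[1:2], offs[1:2], 18.5, 6.0067, regions),
               class = "rtlc_invalid_input")
})

test_that("repeatability_test computes the CV of impurity values", {
  expect_equal(repeatability_test(rep(5, 6))$cv_percent, 0)

  # frozen oracle: mean 5.0, sample sd sqrt(0.1/5) -> CV 2.8284%
  res <- repeatability_test(c(5.0, 5.1, 4.9, 5.2, 4.8, 5.0))
  expect_equal(res$cv_percent, 100 * sqrt(0.02) / 5, tolerance = 1e-12)
  expect_equal(res$cv_percent, 2.8284, tolerance = 1e-4)
  expect_true(res$pass)
  expect_false(repeatability_test(c(1, 2, 3, 10))$pass)

  # CV is invariant under rescaling
  set.seed(5)
  v <- runif(6, 4, 6)
  expect_equal(repeatability_test(3.7 * v)$cv_percent,
               repeatability_test(v)$cv_percent)

  expect_error(repeatability_test(c(0, 0, 0)), class = "rtlc_undefined_cv")
  expect_error(repeatability_test(5), class = "rtlc_invalid_input")
})

test_that("loq_search matches the closed-form deterministic oracle", {
  cfg <- scan_config(total_time_s = 300)
  grid <- c(16, 8, 4, 2, 1, 0.5, 0.25)
  noise_pp <- 3

  res <- loq_search(cfg, grid, sample_volume_ul = 5, stochastic = FALSE,
                    noise_pp = noise_pp)

  # independent oracle: smallest grid value with 2*eff*A*w_peak*dwell/h >= 10
  dwell <- 300 / 240
  w_peak <- 0.5 * dnorm(0, 0, 1.486)
  snr_oracle <- 2 * 5000 * (grid * 5e-3) * w_peak * dwell / noise_pp
  expect_equal(res$table$median_snr, snr_oracle)
  expect_equal(res$loq_MBq_per_ml, min(grid[snr_oracle >= 10]))
  expect_gte(res$snr_at_loq, 10)
  expect_true(res$found)

  # deterministic SNR is monotone non-decreasing in concentration
  expect_true(all(diff(rev(res$table$median_snr)) >= 0))

  none <- loq_search(cfg, grid, stochastic = FALSE, noise_pp = 1e9)
  expect_false(none$found)
  expect_true(is.na(none$loq_MBq_per_ml))
  expect_equal(nrow(none$table), length(grid))

  expect_error(loq_search(cfg, rev(grid), stochastic = FALSE, noise_pp = 3),
               class = "rtlc_invalid_input")
})

test_that("stochastic loq_search finds a qualifying concentration", {
  cfg <- scan_config(total_time_s = 300, seed = 88)
  res <- loq_search(cfg, c(32, 16, 8, 4), replicates = 3)
  expect_true(res$found)
  expect_gte(res$snr_at_loq, 10)
  # the reported LOQ is the lowest passing grid point
  passing <- res$table$concentration_MBq_per_ml[res$table$median_snr >= 10]
  expect_equal(res$loq_MBq_per_ml, min(passing))
})

test_that("working_range applies the 200x rule", {
  wr <- working_range(0.5, 3700)
  expect_equal(wr$lower_MBq_per_ml, 100)
  expect_equal(wr$upper_MBq_per_ml, 3700)
  # 0.5% of the lower limit equals the LOQ exactly
  expect_equal(0.005 * wr$lower_MBq_per_ml, 0.5)

  expect_error(working_range(1, 150), class = "rtlc_invalid_range")
  expect_error(working_range(0, 100), class = "rtlc_invalid_parameter")
})

test_that("position accuracy is exact for noiseless spots on the grid", {
  scen <- make_scenario("position_accuracy")
  cfg <- scen$config
  pos <- channel_positions(cfg)
  dwell <- cfg$total_time_s / length(pos)
  mu <- dwell * expected_rate(scen$model, cfg, pos)
  noiseless <- chromatogram(pos, round(mu * 100), dwell,
                            test_metadata(scan_range_mm = 100,
                                          acquisition_time_s = 120,
                                          origin_mm = 0, front_mm = 100))
  res <- position_accuracy_test(noiseless, scen$expected_positions_mm, 0, 100)
  # exact grid placement: the maximum sits within one channel of each spot
  expect_true(all(abs(res$observed_positions_mm -
                        scen$expected_positions_mm) <= 0.25 + 1e-9))
  expect_lt(res$max_deviation_percent, 100 * 0.25 / 10 + 1e-9)
  expect_true(res$pass)
  expect_equal(res$expected_rf, seq(0.1, 0.9, 0.1))

  expect_error(position_accuracy_test(noiseless, c(10, 12), 0, 100),
               class = "rtlc_invalid_input")
  expect_error(position_accuracy_test(noiseless, c(10, 50, 99.9), 0, 100,
                                      window_mm = 0.01),
               class = "rtlc_peak_matching_error")
})

test_that("compare_methods reproduces the Bland-Altman arithmetic", {
  # frozen oracle: d = (-0.30, 0.00, -0.06) -> bias -0.12, sd 0.1587451,
  # LOA -0.12 -/+ 1.96*sd = (-0.4311404, 0.1911404), computed by hand
  ref <- c(95, 96, 97)
  pairs <- data.frame(rcp_test = ref + c(-0.30, 0.00, -0.06),
                      rcp_reference = ref)
  cmp <- compare_methods(pairs)
  expect_equal(cmp$bias, -0.12)
  expect_equal(cmp$sd_diff, 0.1587451, tolerance = 1e-6)
  expect_equal(cmp$loa_low, -0.4311404, tolerance = 1e-6)
  expect_equal(cmp$loa_high, 0.1911404, tolerance = 1e-6)

  # pairs on an exact line y = x with spread: r = 1, bias 0, LOA (0, 0)
  line <- data.frame(rcp_test = c(90, 94, 99), rcp_reference = c(90, 94, 99))
  cl <- compare_methods(line)
  expect_equal(cl$pearson_r, 1)
  expect_equal(cl$bias, 0)
  expect_equal(c(cl$loa_low, cl$loa_high), c(0, 0))

  flat <- data.frame(rcp_test = c(95, 95, 95), rcp_reference = c(94, 95, 96))
  expect_error(compare_methods(flat), class = "rtlc_undefined_correlation")
  expect_error(compare_methods(pairs[1:2, ]), class = "rtlc_invalid_input")
})

test_that("Bland-Altman invariants hold on random pairings", {
  set.seed(31)
  for (k in 1:20) {
    n <- sample(5:40, 1)
    refv <- runif(n, 90, 100)
    testv <- refv + rnorm(n, sd = 0.4)
    cmp <- compare_methods(data.frame(rcp_test = testv, rcp_reference = refv))
    # exact LOA width identity
    expect_equal(cmp$loa_high - cmp$loa_low, 3.92 * cmp$sd_diff)
    expect_true(cmp$loa_low <= cmp$bias && cmp$bias <= cmp$loa_high)
    # translation equivariance: shifting the test series shifts only the bias
    shifted <- compare_methods(data.frame(rcp_test = testv + 2,
                                          rcp_reference = refv))
    expect_equal(shifted$bias, cmp$bias + 2)
    expect_equal(shifted$sd_diff, cmp$sd_diff)
    expect_equal(shifted$pearson_r, cmp$pearson_r)
  }
})

test_that("simulated paired instruments agree strongly", {
  pairs <- simulate_comparison(n_pairs = 30, seed = 60)
  cmp <- compare_methods(pairs[, c("rcp_test", "rcp_reference")])
  expect_gte(cmp$pearson_r, 0.95)
  expect_true(cmp$pass_r)
  expect_lt(abs(cmp$bias), 0.5)
  # both instruments track the designed truth
  expect_lt(max(abs(pairs$rcp_test - (100 - pairs$true_impurity_percent))), 2)
})

test_that("run_qualification assembles the six-row report in order", {
  qr <- run_qualification(seed = 1)
  expect_s3_class(qr, "qualification_report")
  expect_equal(qr$parameter,
               c("Background", "Linearity", "Repeatability",
                 "Limit of quantification", "Range", "Position accuracy"))
  expect_true(all(qr$pass))
  details <- attr(qr, "details")
  expect_gte(details$linearity$pearson_r, 0.99)
  expect_lte(details$repeatability$cv_percent, 5)
  expect_lte(details$position_accuracy$max_deviation_percent, 10)
  # seeded: rerunning reproduces the report exactly
  qr2 <- run_qualification(seed = 1)
  expect_identical(as.data.frame(qr), as.data.frame(qr2))
})

test_that("a 100x less efficient detector fails repeatability", {
  scen <- make_scenario("repeatability")
  imp <- vapply(1:6, function(k) {
    cfg <- scan_config(total_time_s = 120, efficiency_cps_per_MBq = 50,
                       seed = 70000 + k)
    ch <- simulate_scan(scen$model, cfg)
    100 - analyze_strip(ch, two_peak_regions(),
                        main_label = "main")$rcp_percent
  }, numeric(1))
  res <- repeatability_test(imp)
  expect_gt(res$cv_percent, 5)
  expect_false(res$pass)
})
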