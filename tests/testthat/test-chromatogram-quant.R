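single_peak_chrom <- function(area = 100, rt = 10, sigma = 0.05,
                              noise_sd = 0, baseline = 0, seed = 1) {
  render_chromatogram(
    chromatogram_spec(tibble::tibble(peak = "p1", rt = rt, sigma = sigma,
                                     area = area),
                      baseline_level = baseline, noise_sd = noise_sd),
    seed = seed
  )
}

test_that("chromatogram reading handles delimiters, headers and bad rows", {
  expect_equal(read_chromatogram(c("0,0", "1,5"))$intensity, c(0, 5))
  with_header <- read_chromatogram(c("time,fluorescence", "0,1", "0.5,2",
                                     "1,1"))
  expect_equal(with_header$time, c(0, 0.5, 1))
  tabs <- read_chromatogram(c("0\t1", "1\t2"))
  expect_equal(tabs$intensity, c(1, 2))
  expect_warning(bad <- read_chromatogram(c("0,1", "x,y", "1,2", "2,3")),
                 "line\\(s\\): 2")
  expect_equal(nrow(bad), 3)
  expect_error(read_chromatogram(c("1.0,1", "0.5,2")), "row 2")
  expect_error(read_chromatogram(c("0,1")), "fewer than 2")
})

test_that("rendered chromatograms conserve configured mass", {
  ch <- single_peak_chrom(area = 100)
  integral <- sum(diff(ch$time) *
                    (head(ch$intensity, -1) + tail(ch$intensity, -1)) / 2)
  expect_equal(integral, 100, tolerance = 0.005)
  flat <- render_chromatogram(
    chromatogram_spec(tibble::tibble(peak = character(), rt = numeric(),
                                     sigma = numeric(), area = numeric()),
                      baseline_level = 5, time_range = c(0, 1))
  )
  expect_true(all(flat$intensity == 5))
})

test_that("feature detection finds constructed peaks and applies thresholds", {
  peaks <- tibble::tibble(peak = c("a", "b", "c"), rt = c(10, 12, 14),
                          sigma = 0.05, area = c(100, 50, 20))
  ch <- render_chromatogram(chromatogram_spec(peaks))
  det <- detect_features(ch)
  expect_equal(nrow(det), 3)
  expect_equal(sort(det$expected_rt), peaks$rt,
               tolerance = sampling_int <- median(diff(ch$time)))
  expect_equal(det$width, rep(0.05, 3), tolerance = 0.02)
  # relative threshold of 0.5 suppresses the small peaks
  det_hi <- detect_features(ch, min_intensity = 0.5)
  expect_equal(nrow(det_hi), 1)
  # flat trace: empty result with a warning
  flat <- new_ch <- tibble::tibble(time = seq(0, 1, 0.01), intensity = 0)
  expect_warning(none <- detect_features(structure(flat, class = class(ch))),
                 "flat")
  expect_equal(nrow(none), 0)
})

test_that("detected maxima match a brute-force scan of the smoothed trace", {
  set.seed(81)
  tt <- seq(0, 10, 0.01)
  y <- 50 * exp(-(tt - 3)^2 / (2 * 0.1^2)) +
    30 * exp(-(tt - 7)^2 / (2 * 0.1^2)) + rnorm(length(tt), 0, 0.5)
  ch <- structure(tibble::tibble(time = tt, intensity = y),
                  class = c("fuco_chromatogram", class(tibble::tibble())))
  det <- detect_features(ch, min_intensity = 0.05, smoothing_window = 5)
  # brute-force scan of the same moving-average trace
  k <- stats::filter(c(rep(y[1], 2), y, rep(y[length(y)], 2)),
                     rep(1 / 5, 5), sides = 2)
  s <- as.numeric(k)[3:(length(tt) + 2)]
  s <- s - min(s)
  i <- 2:(length(s) - 1)
  idx <- i[s[i] > s[i - 1] & s[i] >= s[i + 1] & s[i] >= 0.05 * max(s)]
  expect_equal(nrow(det), length(idx))
})

test_that("sigma-edge quantification matches the closed-form Gaussian area", {
  ch <- single_peak_chrom(area = 100)
  q <- quantify_peak(ch, tibble::tibble(peak = "p1", expected_rt = 10,
                                        width = 0.2))
  closed_form <- (2 * pnorm(2) - 1) * 100
  expect_equal(q$area, closed_form, tolerance = 0.002)
  expect_equal(q$fitted_sigma, 0.05, tolerance = 0.001)
  expect_equal(q$gpq, 1, tolerance = 1e-6)
  expect_true(q$fit_ok)
  # model-based area agrees even more closely on a pure Gaussian
  expect_equal(q$model_area, closed_form, tolerance = 1e-6)
})

test_that("area scales linearly with intensity and grows with sigma_edge", {
  ch <- single_peak_chrom(area = 80)
  ch_scaled <- ch
  ch_scaled$intensity <- ch$intensity * 3.7
  feat <- tibble::tibble(peak = "p1", expected_rt = 10, width = 0.2)
  q1 <- quantify_peak(ch, feat)
  q2 <- quantify_peak(ch_scaled, feat)
  expect_equal(q2$area / q1$area, 3.7, tolerance = 1e-6)
  areas <- vapply(c(1, 1.5, 2, 3, 4),
                  function(k) quantify_peak(ch, feat, sigma_edge = k)$area,
                  numeric(1))
  expect_true(all(diff(areas) > 0))
  # converges to the full integral
  expect_equal(areas[5], 80, tolerance = 0.002)
})

test_that("zero or noise-dominated signal fails quantification gracefully", {
  flat <- structure(tibble::tibble(time = seq(9, 11, 0.004), intensity = 0),
                    class = c("fuco_chromatogram", class(tibble::tibble())))
  q <- quantify_peak(flat, tibble::tibble(peak = "px", expected_rt = 10,
                                          width = 0.2))
  expect_equal(q$area, 0)
  expect_false(q$passed_qc)
  expect_false(q$fit_ok)
})

test_that("signal-to-noise reflects constructed height over noise", {
  ch <- single_peak_chrom(area = 90 * 0.05 * sqrt(2 * pi), noise_sd = 10,
                          seed = 5)
  q <- quantify_peak(ch, tibble::tibble(peak = "p1", expected_rt = 10,
                                        width = 0.2))
  expect_true(q$fit_ok)
  expect_equal(q$sn, 9, tolerance = 0.5)
})

test_that("GPQ is the squared correlation, clamped and guarded", {
  tt <- seq(-1, 1, 0.01)
  g <- exp(-tt^2 / 0.1)
  expect_equal(compute_gpq(g, g), 1)
  set.seed(91)
  noisy <- g + rnorm(length(g), 0, 0.05)
  # independent oracle: explicit correlation formula
  r2 <- (sum((noisy - mean(noisy)) * (g - mean(g))) /
           sqrt(sum((noisy - mean(noisy))^2) * sum((g - mean(g))^2)))^2
  expect_equal(compute_gpq(noisy, g), r2, tolerance = 1e-12)
  pure_noise <- rnorm(1000)
  expect_lt(compute_gpq(pure_noise, exp(-seq(-2, 2, length.out = 1000)^2)),
            0.05)
  expect_equal(compute_gpq(rep(1, 10), g[1:10]), 0)
  expect_error(compute_gpq(1:3, 1:3), ">= 5")
})

test_that("analyte gating applies inclusive thresholds without removal", {
  quants <- tibble::tibble(
    peak = c("a", "b", "c"),
    gpq = c(0.8, 0.79, 0.99), sn = c(9, 100, 8.99),
    fit_ok = TRUE, passed_qc = NA
  )
  gated <- gate_analytes(quants)
  expect_equal(gated$passed_qc, c(TRUE, FALSE, FALSE))
  expect_equal(gated$peak, quants$peak)
  expect_equal(nrow(gate_analytes(quants[0, ])), 0)
})

test_that("retention-time calibration recovers shifts and refuses underdetermined fits", {
  layout <- default_peak_layout()
  cal <- layout[layout$is_calibrant, ]
  peaks <- tibble::tibble(peak = cal$peak, rt = cal$rt, sigma = 0.05,
                          area = 50)
  aligned <- render_chromatogram(chromatogram_spec(peaks,
                                                   time_range = c(8, 66)))
  cal_feats <- dplyr::mutate(cal, expected_rt = rt)
  recal <- calibrate_rt(aligned, cal_feats)
  expect_true(attr(recal, "calibrated"))
  # identity map within numerical tolerance
  expect_equal(recal$time, aligned$time, tolerance = 1e-6)
  # uniform shift
  shifted <- render_chromatogram(
    chromatogram_spec(peaks, time_range = c(8, 66), time_warp = c(0.5, 1)))
  fixed <- calibrate_rt(shifted, cal_feats)
  det <- detect_features(fixed)
  errs <- vapply(cal$rt, function(rt) min(abs(det$expected_rt - rt)),
                 numeric(1))
  expect_true(all(errs < median(diff(fixed$time))))
  # fewer than 2 matched calibrants: refused, flagged uncalibrated
  lone <- render_chromatogram(
    chromatogram_spec(peaks[1, ], time_range = c(8, 16)))
  expect_warning(refused <- calibrate_rt(lone, cal_feats), "refused")
  expect_false(attr(refused, "calibrated"))
})

test_that("calibrating an already-calibrated trace is idempotent", {
  layout <- default_peak_layout()
  cal <- layout[layout$is_calibrant, ]
  peaks <- tibble::tibble(peak = cal$peak, rt = cal$rt, sigma = 0.05,
                          area = 50)
  warped <- render_chromatogram(
    chromatogram_spec(peaks, time_range = c(8, 67),
                      time_warp = c(0.1, 1, 2e-4)))
  cal_feats <- dplyr::mutate(cal, expected_rt = rt)
  once <- calibrate_rt(warped, cal_feats)
  twice <- calibrate_rt(once, cal_feats)
  d1 <- detect_features(once)
  d2 <- detect_features(twice)
  for (rt in cal$rt) {
    a1 <- d1$expected_rt[which.min(abs(d1$expected_rt - rt))]
    a2 <- d2$expected_rt[which.min(abs(d2$expected_rt - rt))]
    expect_lt(abs(a1 - a2), median(diff(once$time)))
  }
})

test_that("quantification recovers configured areas on rendered traces", {
  set.seed(101)
  layout <- default_peak_layout()[10:14, ]
  areas <- runif(5, 30, 150)
  ch <- render_chromatogram(
    chromatogram_spec(tibble::tibble(peak = layout$peak, rt = layout$rt,
                                     sigma = layout$sigma, area = areas)))
  feats <- tibble::tibble(peak = layout$peak, expected_rt = layout$rt,
                          width = layout$width)
  q <- quantify_chromatogram(ch, feats)
  frac <- 2 * pnorm(2) - 1
  expect_equal(q$area, areas * frac, tolerance = 0.01)
  expect_equal(q$fitted_sigma, rep(0.05, 5), tolerance = 0.02)
  expect_true(all(q$gpq > 0.999))
})
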