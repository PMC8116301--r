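erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

moving_average <- function(y, window) {
  if (window <= 1) return(y)
  window <- as.integer(window)
  if (window %% 2 == 0) window <- window + 1L
  half <- window %/% 2
  ypad <- c(rep(y[1], half), y, rep(y[length(y)], half))
  as.numeric(stats::filter(ypad, rep(1 / window, window), sides = 2))[
    (half + 1):(half + length(y))]
}

# Trapezoidal integral of (time, signal) restricted to [lo, hi], with the
# boundary ordinates obtained by linear interpolation.
trapz_between <- function(time, signal, lo, hi) {
  lo <- max(lo, time[1])
  hi <- min(hi, time[length(time)])
  if (hi <= lo) return(0)
  inside <- time > lo & time < hi
  tt <- c(lo, time[inside], hi)
  yy <- c(approx(time, signal, lo)$y, signal[inside],
          approx(time, signal, hi)$y)
  sum(diff(tt) * (head(yy, -1) + tail(yy, -1)) / 2)
}

#' Detect peaks in a chromatogram
#'
#' Automated peak detection: the trace is smoothed with a moving average,
#' shifted to a zero floor, and local maxima above `min_intensity` times the
#' global maximum are reported as features. Apex positions are refined by
#' three-point parabolic interpolation; widths are estimated as the
#' half-height width divided by 2.355 (the Gaussian FWHM/sigma ratio).
#'
#' @param chrom Chromatogram tibble.
#' @param min_intensity Detection threshold as a fraction of the global
#'   maximum of the smoothed trace (default 0.001).
#' @param smoothing_window Moving-average window in points (default 5).
#' @return Tibble with columns `peak`, `expected_rt`, `width`, `height`,
#'   `is_calibrant` (all `FALSE`), ready for use as a feature list. Empty
#'   (with a warning) if no maximum clears the threshold.
#' @export
detect_features <- function(chrom, min_intensity = 0.001,
                            smoothing_window = 5) {
  if (min_intensity <= 0 || min_intensity >= 1) {
    abort("min_intensity must be in (0, 1)")
  }
  s <- moving_average(chrom$intensity, smoothing_window)
  s <- s - min(s)
  thr <- min_intensity * max(s)
  n <- length(s)
  empty <- tibble::tibble(peak = character(), expected_rt = numeric(),
                          width = numeric(), height = numeric(),
                          is_calibrant = logical())
  if (max(s) <= 0) {
    warn("flat trace: no features detected")
    return(empty)
  }
  i <- 2:(n - 1)
  # ties between equal-height adjacent samples break to the earlier time
  is_max <- s[i] > s[i - 1] & s[i] >= s[i + 1] & s[i] >= thr
  idx <- i[is_max]
  if (!length(idx)) {
    warn("no features above the detection threshold")
    return(empty)
  }
  dt <- sampling_interval_of(chrom)
  feats <- purrr::map(idx, function(k) {
    denom <- s[k - 1] - 2 * s[k] + s[k + 1]
    delta <- if (denom < 0) 0.5 * (s[k - 1] - s[k + 1]) / denom else 0
    apex_t <- chrom$time[k] + delta * dt
    half <- s[k] / 2
    l <- k
    while (l > 1 && s[l] > half) l <- l - 1
    r <- k
    while (r < n && s[r] > half) r <- r + 1
    t_left <- if (s[l] <= half && l < k) {
      approx(s[l:(l + 1)], chrom$time[l:(l + 1)], half)$y
    } else {
      NA_real_
    }
    t_right <- if (s[r] <= half && r > k) {
      approx(s[(r - 1):r], chrom$time[(r - 1):r], half)$y
    } else {
      NA_real_
    }
    width <- if (is.na(t_left) || is.na(t_right)) {
      NA_real_
    } else {
      (t_right - t_left) / 2.355
    }
    tibble::tibble(expected_rt = apex_t, width = width, height = s[k])
  })
  out <- dplyr::bind_rows(feats)
  out <- dplyr::mutate(out, peak = sprintf("f%d", dplyr::row_number()),
                       is_calibrant = FALSE, .before = 1)
  out
}

#' Calibrate the retention-time axis against reference features
#'
#' Matches each calibrant feature to the nearest detected apex within its
#' matching window and remaps the time axis by a least-squares polynomial
#' fitted to the observed-apex vs expected-retention-time pairs (degree 2
#' when at least 3 calibrants match, else degree 1). If fewer than 2
#' calibrants match, calibration is refused: the chromatogram is returned
#' unchanged, flagged uncalibrated.
#'
#' @param chrom Chromatogram tibble.
#' @param calibrants Feature tibble (rows with `expected_rt`; rows with
#'   `is_calibrant = FALSE` are dropped if the column is present).
#' @param match_window Half-width (minutes) of the apex matching window
#'   around each expected retention time.
#' @param min_intensity,smoothing_window Passed to [detect_features()].
#' @return The chromatogram with a remapped time axis; attribute
#'   `calibrated` is `TRUE` on success, `FALSE` when refused, and attribute
#'   `rt_map` carries the fitted polynomial coefficients.
#' @export
calibrate_rt <- function(chrom, calibrants, match_window = 1,
                         min_intensity = 0.001, smoothing_window = 5) {
  if ("is_calibrant" %in% names(calibrants)) {
    calibrants <- calibrants[calibrants$is_calibrant, ]
  }
  det <- detect_features(chrom, min_intensity, smoothing_window)
  matched <- purrr::map(calibrants$expected_rt, function(ert) {
    if (!nrow(det)) return(NULL)
    d <- abs(det$expected_rt - ert)
    k <- which.min(d)
    if (d[k] <= match_window) c(observed = det$expected_rt[k], expected = ert)
    else NULL
  })
  matched <- dplyr::bind_rows(purrr::compact(
    purrr::map(matched, function(m) if (is.null(m)) NULL else as.list(m))))
  if (nrow(matched) < 2) {
    warn(sprintf("only %d calibrant(s) matched: calibration refused",
                 nrow(matched)))
    attr(chrom, "calibrated") <- FALSE
    return(chrom)
  }
  degree <- if (nrow(matched) >= 3) 2 else 1
  fit <- lm(expected ~ poly(observed, degree, raw = TRUE), data = matched)
  new_time <- as.numeric(predict(fit, tibble::tibble(observed = chrom$time)))
  if (any(diff(new_time) <= 0)) {
    warn("fitted retention-time map is non-monotone: calibration refused")
    attr(chrom, "calibrated") <- FALSE
    return(chrom)
  }
  out <- new_chromatogram(new_time, chrom$intensity)
  attr(out, "calibrated") <- TRUE
  attr(out, "rt_map") <- coef(fit)
  out
}

# Background and noise from the flanking windows of a feature: within each
# flank, contiguous runs of half the flank's length are scanned and the run
# with the lowest mean supplies background (its mean) and noise (its sd).
estimate_background <- function(chrom, lo, hi, width) {
  flank <- (chrom$time >= lo - width & chrom$time < lo) |
    (chrom$time > hi & chrom$time <= hi + width)
  left <- chrom$intensity[chrom$time >= lo - width & chrom$time < lo]
  right <- chrom$intensity[chrom$time > hi & chrom$time <= hi + width]
  best <- NULL
  for (side in list(left, right)) {
    m <- length(side)
    if (m < 2) next
    h <- ceiling(m / 2)
    means <- vapply(seq_len(m - h + 1),
                    function(j) mean(side[j:(j + h - 1)]), numeric(1))
    j <- which.min(means)
    run <- side[j:(j + h - 1)]
    if (is.null(best) || mean(run) < best$bg) {
      best <- list(bg = mean(run), noise = sd(run))
    }
  }
  if (is.null(best)) {
    all_f <- chrom$intensity[flank]
    if (!length(all_f)) return(list(bg = 0, noise = 0))
    return(list(bg = mean(all_f), noise = if (length(all_f) > 1) sd(all_f) else 0))
  }
  best
}

#' Gaussian peak quality: goodness of the Gaussian model fit
#'
#' The squared Pearson correlation between the observed background-subtracted
#' signal in the feature window and the fitted Gaussian evaluated at the same
#' points, clamped to `[0, 1]`. A zero-variance observed signal yields 0.
#'
#' @param observed,fitted Numeric vectors of equal length (>= 5 points).
#' @return GPQ in `[0, 1]`.
#' @export
compute_gpq <- function(observed, fitted) {
  if (length(observed) < 5 || length(observed) != length(fitted)) {
    abort("need >= 5 paired points to compute GPQ")
  }
  if (sd(observed) == 0 || sd(fitted) == 0) return(0)
  r <- cor(observed, fitted)
  min(max(r^2, 0), 1)
}

failed_quant <- function(label, apex_rt, bg, noise) {
  tibble::tibble(peak = label, apex_rt = apex_rt, fitted_mu = NA_real_,
                 fitted_sigma = NA_real_, fitted_height = NA_real_,
                 background = bg, noise = noise, area = 0,
                 model_area = NA_real_, sn = NA_real_, gpq = 0,
                 fit_ok = FALSE, passed_qc = FALSE)
}

#' Quantify one peak by Gaussian fitting with sigma-edge integration
#'
#' Within the feature window `expected_rt +/- width`: background and noise
#' are estimated from flanking windows (one feature width on each side); a
#' Gaussian is least-squares fitted (Levenberg-Marquardt) to the
#' background-subtracted signal; the reported area is the trapezoidal
#' integral of the background-subtracted raw signal between
#' `mu +/- sigma_edge * sigma` of the fit (the sigma-edge bounds); the
#' closed-form fitted-model area is exposed as `model_area` for diagnostics.
#' Signal-to-noise is the fitted height over the flank noise, and GPQ is the
#' squared correlation between signal and fit. Failed fits (non-finite
#' parameters, sigma wider than the window) are flagged, never raised.
#'
#' @param chrom Chromatogram tibble (calibrated).
#' @param feature One-row feature tibble (`peak`, `expected_rt`, `width`).
#' @param sigma_edge Integration boundary in fitted sigmas (default 2.0).
#' @return One-row tibble of the quantification fields.
#' @export
quantify_peak <- function(chrom, feature, sigma_edge = 2.0) {
  lo <- feature$expected_rt - feature$width
  hi <- feature$expected_rt + feature$width
  in_win <- chrom$time >= lo & chrom$time <= hi
  tt <- chrom$time[in_win]
  bgn <- estimate_background(chrom, lo, hi, 2 * feature$width)
  if (sum(in_win) < 5) {
    return(failed_quant(feature$peak, NA_real_, bgn$bg, bgn$noise))
  }
  yy <- chrom$intensity[in_win] - bgn$bg
  apex_rt <- tt[which.max(yy)]
  if (max(yy) <= 0 || sd(yy) == 0) {
    return(failed_quant(feature$peak, apex_rt, bgn$bg, bgn$noise))
  }
  start <- list(h = max(yy), mu = apex_rt,
                s = max(feature$width / 4, sampling_interval_of(chrom)))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yy ~ h * exp(-(tt - mu)^2 / (2 * s^2)),
      start = start,
      lower = c(h = 0, mu = lo, s = 1e-6),
      upper = c(h = Inf, mu = hi, s = 10 * feature$width),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(failed_quant(feature$peak, apex_rt, bgn$bg, bgn$noise))
  }
  p <- coef(fit)
  if (!all(is.finite(p)) || p[["s"]] <= 0 || p[["s"]] > (hi - lo)) {
    return(failed_quant(feature$peak, apex_rt, bgn$bg, bgn$noise))
  }
  fitted_vals <- p[["h"]] * exp(-(tt - p[["mu"]])^2 / (2 * p[["s"]]^2))
  gpq <- compute_gpq(yy, fitted_vals)
  area <- trapz_between(chrom$time, chrom$intensity - bgn$bg,
                        p[["mu"]] - sigma_edge * p[["s"]],
                        p[["mu"]] + sigma_edge * p[["s"]])
  clamped <- area < 0
  area <- max(area, 0)
  sn <- if (bgn$noise > 0) p[["h"]] / bgn$noise else Inf
  tibble::tibble(
    peak = feature$peak, apex_rt = apex_rt, fitted_mu = p[["mu"]],
    fitted_sigma = p[["s"]], fitted_height = p[["h"]],
    background = bgn$bg, noise = bgn$noise, area = area,
    model_area = p[["h"]] * p[["s"]] * sqrt(2 * pi) * erf(sigma_edge / sqrt(2)),
    sn = sn, gpq = gpq, fit_ok = TRUE,
    passed_qc = !clamped
  )
}

#' Quantify all features of a chromatogram
#'
#' Runs [quantify_peak()] for every row of the feature list and applies the
#' analyte QC gate. One failing peak never aborts the batch.
#'
#' @param chrom Chromatogram tibble.
#' @param features Feature tibble (`peak`, `expected_rt`, `width`).
#' @param sigma_edge Integration boundary in fitted sigmas.
#' @param gpq_min,sn_min QC gates, see [gate_analytes()].
#' @return Tibble of quantifications, one row per feature, gated.
#' @export
quantify_chromatogram <- function(chrom, features, sigma_edge = 2.0,
                                  gpq_min = 0.8, sn_min = 9) {
  quants <- purrr::map(seq_len(nrow(features)), function(i) {
    quantify_peak(chrom, features[i, ], sigma_edge)
  })
  gate_analytes(dplyr::bind_rows(quants), gpq_min, sn_min)
}

#' Gate analytes on Gaussian peak quality and signal-to-noise
#'
#' Flags each quantification: `passed_qc` is true iff the fit succeeded and
#' `gpq >= gpq_min` and `sn >= sn_min` (both thresholds inclusive). Nothing
#' is removed; order is preserved.
#'
#' @param quants Quantification tibble from [quantify_peak()].
#' @param gpq_min Minimum Gaussian peak quality (default 0.8).
#' @param sn_min Minimum signal-to-noise (default 9).
#' @return The tibble with `passed_qc` updated.
#' @export
gate_analytes <- function(quants, gpq_min = 0.8, sn_min = 9) {
  if (!nrow(quants)) return(quants)
  dplyr::mutate(
    quants,
    passed_qc = .data$fit_ok &
      !is.na(.data$gpq) & .data$gpq >= gpq_min &
      !is.na(.data$sn) & .data$sn >= sn_min
  )
}
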