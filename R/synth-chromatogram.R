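#' Specify a synthetic fluorescence chromatogram
#'
#' Describes a HILIC-UHPLC fluorescence trace as a sum of Gaussian peaks on a
#' linear baseline with white detector noise, sampled on a regular
#' retention-time grid. An optional polynomial time warp displaces the peak
#' positions, emulating run-to-run retention drift that the calibration stage
#' must correct.
#'
#' @param peaks Tibble with columns `peak` (label), `rt` (minutes), `sigma`
#'   (minutes, > 0) and `area` (arbitrary units x minutes, >= 0).
#' @param baseline_level Constant baseline (arbitrary units).
#' @param baseline_drift Linear drift (arbitrary units per minute).
#' @param noise_sd White-noise standard deviation (arbitrary units).
#' @param sampling_interval Sampling step (minutes).
#' @param time_range Length-2 numeric, start/end of the run (minutes).
#' @param time_warp Polynomial coefficients `c(a0, a1, a2, ...)`; a peak with
#'   nominal retention time t appears at `a0 + a1 t + a2 t^2 + ...`. The
#'   default `c(0, 1)` is the identity.
#' @return An object of class `chromatogram_spec`.
#' @export
#' @examples
#' spec <- chromatogram_spec(
#'   peaks = tibble::tibble(peak = "p1", rt = 10, sigma = 0.05, area = 100)
#' )
#' chrom <- render_chromatogram(spec, seed = 1)
chromatogram_spec <- function(peaks,
                              baseline_level = 0, baseline_drift = 0,
                              noise_sd = 0, sampling_interval = 0.004,
                              time_range = NULL, time_warp = c(0, 1)) {
  if (nrow(peaks)) {
    if (any(duplicated(peaks$peak))) abort("duplicate peak labels")
    if (any(peaks$sigma <= 0)) abort("peak sigma must be positive")
    if (any(peaks$area < 0)) abort("peak areas must be non-negative")
    if (is.unsorted(peaks$rt, strictly = TRUE)) {
      abort("peak retention times must be strictly increasing")
    }
  }
  if (sampling_interval <= 0) abort("sampling_interval must be positive")
  if (is.null(time_range)) {
    time_range <- if (nrow(peaks)) {
      c(max(0, min(peaks$rt) - 2), max(peaks$rt) + 2)
    } else {
      c(0, 70)
    }
  }
  structure(
    list(peaks = peaks, baseline_level = baseline_level,
         baseline_drift = baseline_drift, noise_sd = noise_sd,
         sampling_interval = sampling_interval, time_range = time_range,
         time_warp = time_warp),
    class = "chromatogram_spec"
  )
}

eval_poly <- function(coefs, x) {
  out <- numeric(length(x))
  for (i in seq_along(coefs)) out <- out + coefs[i] * x^(i - 1)
  out
}

#' Render a synthetic chromatogram
#'
#' Samples the trace `sum of Gaussians + baseline + drift * t + noise` on the
#' spec's time grid, with the time warp applied to the peak positions. With
#' zero noise and zero baseline the numeric integral of the trace equals the
#' configured total area up to truncation of the Gaussian tails.
#'
#' @param spec A [chromatogram_spec()].
#' @param seed Integer seed for the noise draws.
#' @return A tibble with columns `time` (minutes) and `intensity` (arbitrary
#'   units), of class `fuco_chromatogram`.
#' @export
render_chromatogram <- function(spec, seed = 1L) {
  tt <- seq(spec$time_range[1], spec$time_range[2],
            by = spec$sampling_interval)
  intensity <- spec$baseline_level + spec$baseline_drift * tt
  if (nrow(spec$peaks)) {
    mu <- eval_poly(spec$time_warp, spec$peaks$rt)
    for (i in seq_len(nrow(spec$peaks))) {
      h <- spec$peaks$area[i] / (spec$peaks$sigma[i] * sqrt(2 * pi))
      intensity <- intensity +
        h * exp(-(tt - mu[i])^2 / (2 * spec$peaks$sigma[i]^2))
    }
  }
  if (spec$noise_sd > 0) {
    withr::with_seed(seed, {
      intensity <- intensity + rnorm(length(tt), 0, spec$noise_sd)
    })
  }
  new_chromatogram(tt, intensity)
}

#' Render chromatograms for every sample of a peak table
#'
#' Turns each row of a (relative-area) peak table into a chromatogram spec
#' using a peak layout for retention times and widths, scaling relative areas
#' to absolute units.
#'
#' @param peak_table Tibble `sample_id` + peak columns (relative areas).
#' @param layout Peak layout tibble, see [default_peak_layout()].
#' @param total_area Absolute area corresponding to a row total of 1.
#' @param noise_sd,baseline_level,baseline_drift,time_warp,sampling_interval
#'   Passed to [chromatogram_spec()].
#' @param seed Integer seed; sample i uses `seed + i`.
#' @return Named list of chromatogram tibbles, one per sample.
#' @export
render_sample_chromatograms <- function(peak_table,
                                        layout = default_peak_layout(),
                                        total_area = 1000, noise_sd = 0,
                                        baseline_level = 0,
                                        baseline_drift = 0,
                                        time_warp = c(0, 1),
                                        sampling_interval = 0.004,
                                        seed = 1L) {
  peaks_present <- intersect(layout$peak, names(peak_table))
  lay <- layout[match(peaks_present, layout$peak), ]
  out <- purrr::map(seq_len(nrow(peak_table)), function(i) {
    areas <- unlist(peak_table[i, peaks_present]) * total_area
    spec <- chromatogram_spec(
      peaks = tibble::tibble(peak = peaks_present, rt = lay$rt,
                             sigma = lay$sigma, area = unname(areas)),
      baseline_level = baseline_level, baseline_drift = baseline_drift,
      noise_sd = noise_sd, sampling_interval = sampling_interval,
      time_warp = time_warp
    )
    render_chromatogram(spec, seed = seed + i)
  })
  names(out) <- peak_table$sample_id
  out
}
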