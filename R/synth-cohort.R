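# Truncated-to-[0,1] normal: sampling and quantile function. The bounded
# support matches fucosylation indexes, which are fractions by construction.
rtruncnorm01 <- function(n, mean, sd) {
  lo <- pnorm(0, mean, sd)
  hi <- pnorm(1, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

qtruncnorm01 <- function(p, mean, sd) {
  lo <- pnorm(0, mean, sd)
  hi <- pnorm(1, mean, sd)
  qnorm(lo + p * (hi - lo), mean, sd)
}

# Lognormal meanlog/sdlog from an arithmetic mean and sd.
lnorm_params <- function(m, s) {
  sdlog2 <- log(1 + (s / m)^2)
  c(meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

# Mean-one multiplicative lognormal noise factors with coefficient of
# variation cv.
ln_noise_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, 0, sdlog) - sdlog^2 / 2)
}

#' Specify a synthetic HNF1A-MODY study cohort
#'
#' Defines the group sizes, per-group true fucosylation-index distributions,
#' and the CRP coupling used by [generate_cohort()]. Defaults mirror the study
#' design: 18 (likely) damaging, 5 VUS and 8 (likely) benign HNF1A variant
#' carriers plus 289 diabetes cases without a rare HNF1A variant, with
#' antennary fucosylation lowered in the damaging group and a positive rank
#' correlation between the traits and high-sensitivity CRP.
#'
#' @param n_damaging,n_vus,n_benign,n_none Group sizes (non-negative counts).
#' @param group_index_means Tibble `trait, damaging, vus, benign, none` of true
#'   index means (fractions in `[0, 1]`).
#' @param group_index_sd Same shape, standard deviations (> 0).
#' @param crp_trait_rho Target Spearman rank correlation between each trait and
#'   CRP, in `[-1, 1]`; coupled through a Gaussian copula.
#' @param crp_mean,crp_sd Named vectors (by group) of arithmetic CRP moments
#'   (mg/L) for the log-normal CRP marginal.
#' @param seed Integer seed; the cohort is a pure function of the spec.
#' @return An object of class `cohort_spec`.
#' @export
#' @examples
#' spec <- cohort_spec(seed = 1)
#' nrow(generate_cohort(spec))
cohort_spec <- function(n_damaging = 18, n_vus = 5, n_benign = 8, n_none = 289,
                        group_index_means = default_group_traits()$means,
                        group_index_sd = default_group_traits()$sds,
                        crp_trait_rho = 0.3,
                        crp_mean = c(damaging = 0.80, vus = 4.01,
                                     benign = 5.21, none = 3.79),
                        crp_sd = c(damaging = 1.32, vus = 6.30,
                                   benign = 5.75, none = 6.97),
                        seed = 1L) {
  spec <- structure(
    list(n_damaging = n_damaging, n_vus = n_vus, n_benign = n_benign,
         n_none = n_none, group_index_means = group_index_means,
         group_index_sd = group_index_sd, crp_trait_rho = crp_trait_rho,
         crp_mean = crp_mean, crp_sd = crp_sd, seed = as.integer(seed)),
    class = "cohort_spec"
  )
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  counts <- c(spec$n_damaging, spec$n_vus, spec$n_benign, spec$n_none)
  if (any(counts < 0)) abort("group sizes must be non-negative")
  groups <- c("damaging", "vus", "benign", "none")
  if (!all(groups %in% names(spec$group_index_means)) ||
      !all(groups %in% names(spec$group_index_sd))) {
    abort("group_index_means/group_index_sd need columns damaging, vus, benign, none")
  }
  m <- as.matrix(spec$group_index_means[groups])
  s <- as.matrix(spec$group_index_sd[groups])
  if (any(m < 0 | m > 1)) abort("trait means must lie in [0, 1]")
  if (any(s <= 0)) abort("trait standard deviations must be positive")
  if (abs(spec$crp_trait_rho) > 1) abort("crp_trait_rho must lie in [-1, 1]")
  invisible(spec)
}

group_levels <- function() c("damaging", "vus", "benign", "none")

#' Generate a synthetic cohort with true fucosylation indexes
#'
#' Draws one record per subject: mutation group, sex, age, CRP and the true
#' (noise-free) fucosylation index for every trait in the spec. Trait values
#' follow a per-group truncated-to-`[0, 1]` normal; CRP has a per-group
#' log-normal marginal and is tied to the traits through a Gaussian copula so
#' that each trait's rank correlation with CRP approaches `crp_trait_rho`.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `sample_id`, `group`, `sex`, `age`, `crp` and
#'   one column per trait holding the true index.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  validate_cohort_spec(spec)
  withr::with_seed(spec$seed, {
    groups <- group_levels()
    n_per <- c(damaging = spec$n_damaging, vus = spec$n_vus,
               benign = spec$n_benign, none = spec$n_none)
    male_frac <- c(damaging = 0.28, vus = 0.40, benign = 0.50, none = 0.52)
    age_mean <- c(damaging = 39.7, vus = 54.2, benign = 48.1, none = 45.6)
    age_sd <- c(damaging = 17.4, vus = 14.2, benign = 11.2, none = 9.7)
    traits <- spec$group_index_means$trait
    # latent correlation reproducing the target Spearman rho under the copula
    rho <- 2 * sin(pi * spec$crp_trait_rho / 6)

    recs <- purrr::map(groups, function(g) {
      n <- n_per[[g]]
      if (n == 0) return(NULL)
      z_crp <- rnorm(n)
      lp <- lnorm_params(spec$crp_mean[[g]], spec$crp_sd[[g]])
      vals <- purrr::map(traits, function(tr) {
        mu <- spec$group_index_means[[g]][spec$group_index_means$trait == tr]
        sdv <- spec$group_index_sd[[g]][spec$group_index_sd$trait == tr]
        z <- rho * z_crp + sqrt(1 - rho^2) * rnorm(n)
        qtruncnorm01(pnorm(z), mu, sdv)
      })
      names(vals) <- traits
      tibble::tibble(
        group = g,
        sex = ifelse(runif(n) < male_frac[[g]], "male", "female"),
        age = pmax(18, rnorm(n, age_mean[[g]], age_sd[[g]])),
        crp = qlnorm(pnorm(z_crp), lp[["meanlog"]], lp[["sdlog"]]),
        !!!vals
      )
    })
    out <- dplyr::bind_rows(recs)
    out <- dplyr::mutate(
      out,
      sample_id = sprintf("S%03d", dplyr::row_number()),
      group = factor(.data$group, levels = groups),
      .before = 1
    )
    out
  })
}

#' Trait columns of a cohort or trait table
#'
#' @param x A cohort or trait tibble.
#' @return Character vector of trait column names.
#' @export
trait_names <- function(x) {
  setdiff(names(x), c("sample_id", "group", "sex", "age", "crp", "derived",
                      "plate", "replicate"))
}

#' Expand a cohort into raw (unnormalized) peak areas
#'
#' Inverts the trait construction: each trait's fucosylated/non-fucosylated
#' pair receives the pair's combined template abundance split as
#' `(index, 1 - index)` according to the sample's true index, filler peaks
#' keep their template abundance, and every cell is multiplied by mean-one
#' log-normal noise with coefficient of variation `noise_cv`. Areas are in
#' arbitrary units (`total_area` per unit of template abundance), i.e. not yet
#' normalized; pipe through [normalize_peak_table()] or use
#' [cohort_to_peak_table()].
#'
#' @param cohort Tibble from [generate_cohort()].
#' @param template Named vector of baseline peak abundances,
#'   see [default_peak_template()].
#' @param pairings Trait pairing tibble, see [default_trait_pairings()].
#' @param noise_cv Multiplicative measurement noise CV (fraction; 0 = exact).
#' @param seed Integer seed for the noise draws.
#' @param total_area Total area scale (arbitrary units x minutes).
#' @return Tibble `sample_id` + one column per template peak with raw areas.
#' @export
cohort_to_raw_areas <- function(cohort, template = default_peak_template(),
                                pairings = default_trait_pairings(),
                                noise_cv = 0, seed = 1L, total_area = 100) {
  traits <- intersect(pairings$trait, names(cohort))
  pairings <- pairings[pairings$trait %in% traits, ]
  needed <- c(unlist(pairings$fucosylated), unlist(pairings$nonfucosylated))
  missing <- setdiff(needed, names(template))
  if (length(missing)) {
    abort(paste0("template is missing paired peak(s): ",
                 paste(missing, collapse = ", ")))
  }
  n <- nrow(cohort)
  areas <- matrix(rep(template, each = n), nrow = n,
                  dimnames = list(NULL, names(template)))
  for (i in seq_len(nrow(pairings))) {
    tr <- pairings$trait[i]
    fuc <- pairings$fucosylated[[i]]
    nonfuc <- pairings$nonfucosylated[[i]]
    pair_total <- sum(template[c(fuc, nonfuc)])
    idx <- cohort[[tr]]
    areas[, fuc] <- pair_total * idx / length(fuc)
    areas[, nonfuc] <- pair_total * (1 - idx) / length(nonfuc)
  }
  areas <- areas * total_area
  if (noise_cv > 0) {
    withr::with_seed(seed, {
      areas <- areas * matrix(ln_noise_factor(length(areas), noise_cv),
                              nrow = n)
    })
  }
  dplyr::bind_cols(tibble::tibble(sample_id = cohort$sample_id),
                   tibble::as_tibble(areas))
}

#' Expand a cohort into a normalized peak table
#'
#' Convenience wrapper: [cohort_to_raw_areas()] followed by
#' [normalize_peak_table()] over the analysis peaks, so each row's analysis
#' peaks sum to 1. With `noise_cv = 0`, [compute_traits()] on the result
#' reproduces the cohort's true indexes exactly.
#'
#' @inheritParams cohort_to_raw_areas
#' @param analysis Peaks defining the normalization total,
#'   default [analysis_peaks()] of `pairings`.
#' @return A normalized peak table tibble (`sample_id` + peak columns).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(seed = 7))
#' pt <- cohort_to_peak_table(cohort, seed = 7)
cohort_to_peak_table <- function(cohort, template = default_peak_template(),
                                 pairings = default_trait_pairings(),
                                 noise_cv = 0, seed = 1L,
                                 analysis = analysis_peaks(pairings)) {
  raw <- cohort_to_raw_areas(cohort, template, pairings, noise_cv, seed)
  normalize_peak_table(raw, analysis)
}

#' Simulate pooled-plasma standard triplicates across plates
#'
#' Each 96-well plate carries a pooled human plasma standard in triplicate to
#' monitor repeatability. Replicate rows are the standard's peak values under
#' two multiplicative log-normal noise layers: a per-plate offset (CV
#' `inter_cv`) shared by a plate's replicates, and independent within-plate
#' noise (CV `intra_cv`).
#'
#' @param standard_row One-row tibble (or named vector) of per-peak values for
#'   the pooled standard.
#' @param n_plates Number of plates (0 gives an empty table).
#' @param intra_cv,inter_cv Within-plate and between-plate CVs (fractions,
#'   >= 0).
#' @param n_replicates Replicates per plate (default 3).
#' @param seed Integer seed.
#' @return Tibble with `plate`, `replicate`, `sample_id` and peak columns.
#' @export
generate_triplicates <- function(standard_row, n_plates, intra_cv = 0.05,
                                 inter_cv = 0.07, n_replicates = 3,
                                 seed = 1L) {
  if (intra_cv < 0 || inter_cv < 0) abort("CVs must be non-negative")
  if (is.data.frame(standard_row)) {
    standard_row <- unlist(standard_row[1, setdiff(names(standard_row),
                                                   "sample_id")])
  }
  peaks <- names(standard_row)
  if (n_plates == 0) {
    return(tibble::tibble(plate = integer(), replicate = integer(),
                          sample_id = character(),
                          !!!setNames(rep(list(numeric()), length(peaks)),
                                      peaks)))
  }
  withr::with_seed(seed, {
    rows <- purrr::map(seq_len(n_plates), function(pl) {
      plate_f <- ln_noise_factor(length(peaks), inter_cv)
      purrr::map(seq_len(n_replicates), function(rep_i) {
        rep_f <- ln_noise_factor(length(peaks), intra_cv)
        vals <- standard_row * plate_f * rep_f
        tibble::tibble(plate = pl, replicate = rep_i,
                       sample_id = sprintf("STD_P%02d_R%d", pl, rep_i),
                       !!!as.list(vals))
      })
    })
    dplyr::bind_rows(purrr::flatten(rows))
  })
}

#' Simulate a second laboratory's measurements of the same traits
#'
#' Applies a strictly monotone transform to each first-laboratory trait column
#' (emulating a different trait representation, e.g. percent relative
#' abundance instead of a fucosylation index) and adds Gaussian noise whose
#' standard deviation is `noise_sd` times the spread of the transformed
#' values. With `noise_sd = 0` the Spearman correlation with the input is
#' exactly +/-1 for any monotone transform.
#'
#' @param traits Trait table tibble (`sample_id` + trait columns).
#' @param transform A strictly monotone function, applied elementwise.
#' @param noise_sd Noise level as a fraction of the per-trait standard
#'   deviation of the transformed values.
#' @param seed Integer seed.
#' @return Tibble of the same shape with second-laboratory values.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(seed = 2))
#' traits <- cohort[c("sample_id", trait_names(cohort))]
#' lab2 <- generate_second_lab(traits, transform = function(x) 100 * x,
#'                             noise_sd = 0.3, seed = 2)
generate_second_lab <- function(traits, transform = function(x) 100 * x,
                                noise_sd = 0, seed = 1L) {
  cols <- trait_names(traits)
  probe <- transform(c(0.25, 0.75))
  if (diff(probe) == 0) abort("transform must be strictly monotone")
  withr::with_seed(seed, {
    out <- traits
    for (cl in cols) {
      y <- transform(traits[[cl]])
      s <- sd(y)
      if (noise_sd > 0 && s > 0) y <- y + rnorm(length(y), 0, noise_sd * s)
      out[[cl]] <- y
    }
    out
  })
}

#' Calibrate second-laboratory noise to a target Spearman correlation
#'
#' Monte-Carlo bisection: finds the `noise_sd` for [generate_second_lab()]
#' under which the Spearman correlation between first- and second-laboratory
#' values of a trait vector matches a target, averaged over seeded replicate
#' noise draws.
#'
#' @param x Numeric vector of first-laboratory trait values.
#' @param target_rho Target Spearman correlation in (0, 1).
#' @param transform Monotone transform passed to the noise model.
#' @param n_reps Inner Monte-Carlo replicates per candidate noise level.
#' @param seed Integer seed.
#' @param iter Bisection iterations.
#' @return The calibrated `noise_sd` (fraction of transformed-signal sd).
#' @export
calibrate_interlab_noise <- function(x, target_rho, transform = identity,
                                     n_reps = 25, seed = 1L, iter = 14) {
  if (target_rho <= 0 || target_rho >= 1) abort("target_rho must be in (0, 1)")
  y0 <- transform(x)
  s <- sd(y0)
  mean_rho <- function(nsd) {
    withr::with_seed(seed, {
      mean(purrr::map_dbl(seq_len(n_reps), function(i) {
        cor(y0, y0 + rnorm(length(y0), 0, nsd * s), method = "spearman")
      }))
    })
  }
  lo <- 0
  hi <- 1
  while (mean_rho(hi) > target_rho && hi < 64) hi <- hi * 2
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (mean_rho(mid) > target_rho) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
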