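#' Evaluate fucosylation traits as HNF1A-MODY classifiers
#'
#' For every trait x group-comparison: flags outliers by the 1.5 x IQR rule
#' per trait within each patient group, runs the two-sided
#' Wilcoxon-Mann-Whitney test on the outlier-filtered values, fits the ROC
#' curve with the Youden-optimal cutpoint, and applies a Bonferroni
#' correction across the whole trait x comparison grid. Samples in the VUS
#' group (variants of unknown significance) are scored against each cutoff
#' and reported as classified-pathogenic or not — the triage readout the
#' biomarker exists for.
#'
#' @param traits Tibble `sample_id` + trait columns (e.g. from
#'   [compute_traits()]).
#' @param metadata Tibble with `sample_id` and `group`
#'   (damaging/vus/benign/none).
#' @param comparisons List of length-2 character vectors `c(case_group,
#'   control_group)`.
#' @param test_traits Trait columns to evaluate (default: all).
#' @param iqr_k Outlier fence multiplier.
#' @param direction ROC direction, `"auto"` by default (the biology implies
#'   lower indexes in pathogenic cases).
#' @param bonferroni_m Family size for the correction (default: number of
#'   tests in the grid).
#' @return Object of class `fuco_eval` with elements `results` (one row per
#'   trait x comparison), `vus` (per VUS sample x trait x comparison
#'   classification), `outlier_flags` (per sample x trait) and `n_tests`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(seed = 3))
#' traits <- compute_traits(cohort_to_peak_table(cohort, seed = 3))
#' ev <- evaluate_biomarkers(traits, cohort)
#' tidy(ev)
evaluate_biomarkers <- function(traits, metadata,
                                comparisons = list(c("damaging", "none"),
                                                   c("damaging", "benign")),
                                test_traits = NULL, iqr_k = 1.5,
                                direction = "auto", bonferroni_m = NULL) {
  data <- dplyr::inner_join(traits, metadata[c("sample_id", "group")],
                            by = "sample_id")
  if (is.null(test_traits)) {
    test_traits <- c(trait_names(traits),
                     intersect("derived", names(traits)))
  }
  groups_needed <- unique(unlist(comparisons))
  missing_g <- setdiff(groups_needed, as.character(unique(data$group)))
  if (length(missing_g)) {
    abort(paste0("group(s) absent from metadata: ",
                 paste(missing_g, collapse = ", ")))
  }

  # outliers: per trait within each patient group, over the whole cohort
  flags <- purrr::map_dfr(test_traits, function(tr) {
    dplyr::mutate(
      dplyr::group_by(data[c("sample_id", "group", tr)], .data$group),
      trait = tr,
      outlier = flag_outliers_iqr(.data[[tr]], k = iqr_k),
      .keep = "unused"
    )
  })
  flags <- dplyr::ungroup(flags)[c("sample_id", "group", "trait", "outlier")]

  grid <- tidyr::expand_grid(
    trait = test_traits,
    comparison = purrr::map_chr(comparisons, paste, collapse = "_vs_")
  )
  comp_of <- setNames(comparisons,
                      purrr::map_chr(comparisons, paste, collapse = "_vs_"))

  rows <- purrr::pmap(grid, function(trait, comparison) {
    cmp <- comp_of[[comparison]]
    fl <- flags[flags$trait == trait, ]
    d <- dplyr::left_join(data[c("sample_id", "group", trait)],
                          fl[c("sample_id", "outlier")], by = "sample_id")
    d <- d[!is.na(d[[trait]]), ]
    n_out <- sum(d$outlier & d$group %in% cmp)
    d <- d[!d$outlier, ]
    case_v <- d[[trait]][d$group == cmp[1]]
    ctrl_v <- d[[trait]][d$group == cmp[2]]
    if (!length(case_v) || !length(ctrl_v)) {
      abort(sprintf("comparison %s for %s: a group is empty after outlier removal",
                    comparison, trait))
    }
    mw <- mann_whitney(case_v, ctrl_v)
    rc <- roc_curve(c(case_v, ctrl_v),
                    rep(c(TRUE, FALSE), c(length(case_v), length(ctrl_v))),
                    direction = direction)
    cp <- optimal_cutpoint(rc)
    tibble::tibble(
      trait = trait, comparison = comparison,
      n_case = length(case_v), n_control = length(ctrl_v),
      n_outliers_removed = n_out,
      u = mw$statistic, p_raw = mw$p.value,
      auc = rc$auc, direction = rc$direction,
      cutoff = cp$cutoff, sensitivity = cp$sensitivity,
      specificity = cp$specificity, roc = list(rc)
    )
  })
  results <- dplyr::bind_rows(rows)
  m <- bonferroni_m %||% nrow(results)
  results$p_bonferroni <- bonferroni(results$p_raw, m)
  results <- dplyr::relocate(results, "p_bonferroni", .after = "p_raw")
  results <- dplyr::relocate(results, "roc", .after = dplyr::last_col())

  vus_data <- data[data$group == "vus", ]
  vus <- purrr::pmap_dfr(
    results[c("trait", "comparison", "cutoff", "direction")],
    function(trait, comparison, cutoff, direction) {
      v <- vus_data[[trait]]
      classified <- if (direction == "lower_indicates_case") {
        v <= cutoff
      } else {
        v >= cutoff
      }
      tibble::tibble(sample_id = vus_data$sample_id, trait = trait,
                     comparison = comparison, value = v,
                     classified_pathogenic = classified)
    })

  structure(list(results = results, vus = vus, outlier_flags = flags,
                 n_tests = m),
            class = "fuco_eval")
}

#' @export
print.fuco_eval <- function(x, ...) {
  cat(sprintf("Biomarker evaluation: %d trait x comparison tests (Bonferroni m = %d)\n",
              nrow(x$results), x$n_tests))
  print(dplyr::select(x$results, -"roc"), n = Inf)
  invisible(x)
}

#' @export
tidy.fuco_eval <- function(x, ...) dplyr::select(x$results, -"roc")

#' @export
glance.fuco_eval <- function(x, ...) {
  tibble::tibble(
    n_tests = x$n_tests,
    n_significant = sum(x$results$p_bonferroni <= 0.05),
    best_auc = max(x$results$auc),
    best_trait = x$results$trait[which.max(x$results$auc)],
    n_vus_flagged = if (nrow(x$vus)) {
      length(unique(x$vus$sample_id[x$vus$classified_pathogenic]))
    } else {
      0L
    }
  )
}

#' @export
autoplot.fuco_eval <- function(object, ...) {
  res <- dplyr::select(object$results, -"roc")
  ggplot2::ggplot(res, ggplot2::aes(x = .data$trait, y = .data$auc,
                                    fill = .data$comparison)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "AUC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Dot plot of trait values by patient group
#'
#' The standard presentation of antennary fucosylation levels across HNF1A
#' mutation groups.
#'
#' @param traits Trait tibble (`sample_id` + trait columns).
#' @param metadata Tibble with `sample_id` and `group`.
#' @return A ggplot object.
#' @export
plot_trait_distributions <- function(traits, metadata) {
  long <- tidyr::pivot_longer(
    dplyr::inner_join(traits, metadata[c("sample_id", "group")],
                      by = "sample_id"),
    cols = -c("sample_id", "group"),
    names_to = "trait", values_to = "index"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$index)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::stat_summary(fun = median, geom = "crossbar", width = 0.5,
                          linewidth = 0.3, colour = "red") +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Fucosylation index") +
    ggplot2::theme_minimal()
}

#' Descriptive sex and age associations per trait
#'
#' Exposes simple per-trait covariate checks: Spearman correlation with age
#' and a Wilcoxon-Mann-Whitney comparison between sexes. These are
#' descriptive only; no covariate adjustment enters the biomarker
#' evaluation.
#'
#' @param traits Trait tibble.
#' @param metadata Tibble with `sample_id`, `sex`, `age`.
#' @return Tibble `trait`, `age_spearman_r`, `sex_p`.
#' @export
descriptive_covariates <- function(traits, metadata) {
  data <- dplyr::inner_join(traits, metadata[c("sample_id", "sex", "age")],
                            by = "sample_id")
  trs <- c(trait_names(traits), intersect("derived", names(traits)))
  purrr::map_dfr(trs, function(tr) {
    ok <- !is.na(data[[tr]])
    tibble::tibble(
      trait = tr,
      age_spearman_r = spearman_cor(data[[tr]][ok], data$age[ok]),
      sex_p = mann_whitney(data[[tr]][ok & data$sex == "male"],
                           data[[tr]][ok & data$sex == "female"])$p.value
    )
  })
}
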