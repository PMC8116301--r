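#' Flag outliers by the 1.5 x IQR rule
#'
#' Tukey fences with quartiles by linear interpolation between order
#' statistics: a value is an outlier iff it lies below `Q1 - k * IQR` or above
#' `Q3 + k * IQR`. Applied per trait within each patient group before ROC
#' analysis. Groups smaller than 4 are never flagged (a warning is issued):
#' quartile fences are meaningless at those sizes.
#'
#' @param values Numeric vector (one group's values for one trait).
#' @param k Fence multiplier (default 1.5).
#' @return Logical vector of flags, `FALSE` for `NA` values.
#' @export
#' @examples
#' flag_outliers_iqr(c(1, 2, 3, 4, 100))
flag_outliers_iqr <- function(values, k = 1.5) {
  flags <- rep(FALSE, length(values))
  ok <- !is.na(values)
  if (sum(ok) < 4) {
    if (sum(ok) > 0) warn("fewer than 4 values: no outlier flagging")
    return(flags)
  }
  q <- quantile(values[ok], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  flags[ok] <- values[ok] < q[1] - k * iqr | values[ok] > q[2] + k * iqr
  flags
}

# Exact null distribution of the Mann-Whitney U for sample sizes (m, n),
# by the standard count recurrence c(u; m, n) = c(u - n; m - 1, n) +
# c(u; m, n - 1); returns counts over u = 0..m*n.
mw_exact_counts <- function(m, n) {
  umax <- m * n
  a <- matrix(0, nrow = m + 1, ncol = umax + 1)
  a[, 1] <- 1  # n' = 0: U is necessarily 0
  if (n >= 1) {
    for (j in seq_len(n)) {
      for (i in seq_len(m)) {
        shifted <- c(rep(0, min(j, umax + 1)),
                     a[i, seq_len(max(umax + 1 - j, 0))])
        a[i + 1, ] <- a[i + 1, ] + shifted
      }
    }
  }
  a[m + 1, ]
}

#' Wilcoxon-Mann-Whitney test
#'
#' Two-sided rank-sum test. The U statistic counts pairs where `a > b` plus
#' half of the tied pairs. The p-value is exact (full enumeration of the
#' permutation null via the count recurrence) when the smaller group has at
#' most 8 observations and there are no ties; otherwise a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @param mode `"auto"` (default), `"exact"` or `"normal"`.
#' @return One-row tibble: `statistic` (U of `a` vs `b`), `p.value`,
#'   `method`, `n1`, `n2`.
#' @export
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # exact two-sided p = 1/3
mann_whitney <- function(a, b, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  n1 <- length(a)
  n2 <- length(b)
  if (n1 == 0 || n2 == 0) abort("both groups must be non-empty")
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(a, b))
  has_ties <- any(ties > 1)
  use_exact <- switch(mode,
                      exact = TRUE,
                      normal = FALSE,
                      auto = min(n1, n2) <= 8 && !has_ties)
  if (use_exact && has_ties) {
    abort("exact mode requires tie-free data")
  }
  if (use_exact) {
    m <- min(n1, n2)
    n <- max(n1, n2)
    counts <- mw_exact_counts(m, n)
    total <- sum(counts)
    # U of the smaller group; the distribution is symmetric so U of `a`
    # and U of `b` give identical two-sided p-values
    us <- if (n1 <= n2) u else n1 * n2 - u
    pl <- sum(counts[seq_len(us + 1)]) / total
    pu <- sum(counts[(us + 1):(m * n + 1)]) / total
    p <- min(1, 2 * min(pl, pu))
    method <- "exact"
  } else {
    nn <- n1 + n2
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      cc <- 0.5 * sign(u - mu)
      z <- (u - mu - cc) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal"
  }
  tibble::tibble(statistic = u, p.value = p, method = method,
                 n1 = n1, n2 = n2)
}

#' Bonferroni correction
#'
#' `min(1, p * m)` elementwise. The family size `m` is explicit because the
#' test family is a design choice, not a property of the vector at hand.
#'
#' @param pvals P-values in `[0, 1]`.
#' @param m Family size (default `length(pvals)`).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  pmin(1, pvals * m)
}

#' ROC curve and AUC for a trait against a binary outcome
#'
#' Builds the ROC point sequence over all distinct thresholds and computes
#' the area under the curve by the trapezoid rule, which equals the
#' tie-corrected Mann-Whitney `U / (n1 * n2)`. The direction is auto-detected
#' on the input so that AUC >= 0.5 (pathogenic HNF1A variants lower the
#' fucosylation indexes, so `lower_indicates_case` is the biological
#' default), and can be forced.
#'
#' @param scores Numeric trait values.
#' @param labels Logical (or two-level) vector; `TRUE` / `case_level` marks
#'   cases.
#' @param direction `"auto"`, `"lower_indicates_case"` or
#'   `"higher_indicates_case"`.
#' @param case_level For non-logical labels, the level regarded as case.
#' @return Object of class `fuco_roc`: list with `points` (tibble `threshold`,
#'   `fpr`, `tpr`), `auc`, `direction`, `n_case`, `n_control` and the input
#'   data (for cutpoint selection).
#' @export
#' @examples
#' r <- roc_curve(c(1, 2, 2, 3), c(TRUE, TRUE, FALSE, FALSE),
#'                direction = "higher_indicates_case")
#' r$auc
roc_curve <- function(scores, labels,
                      direction = c("auto", "lower_indicates_case",
                                    "higher_indicates_case"),
                      case_level = NULL) {
  direction <- match.arg(direction)
  if (!is.logical(labels)) {
    if (is.null(case_level)) abort("case_level required for non-logical labels")
    labels <- labels == case_level
  }
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  n_case <- sum(labels)
  n_control <- sum(!labels)
  if (n_case == 0 || n_control == 0) {
    abort("both classes must be present for ROC analysis")
  }
  auc_of <- function(s) {
    ord <- order(s, decreasing = TRUE)
    lab <- labels[ord]
    sv <- s[ord]
    grp <- cumsum(!duplicated(sv))  # runs of tied scores
    tp <- as.numeric(tapply(lab, grp, sum))
    fp <- as.numeric(tapply(!lab, grp, sum))
    tpr <- c(0, cumsum(tp)) / n_case
    fpr <- c(0, cumsum(fp)) / n_control
    list(auc = sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2),
         tpr = tpr, fpr = fpr,
         thresholds = c(Inf, sv[!duplicated(sv)]))
  }
  if (direction == "auto") {
    direction <- if (auc_of(scores)$auc >= 0.5) "higher_indicates_case"
                 else "lower_indicates_case"
  }
  s_eff <- if (direction == "lower_indicates_case") -scores else scores
  res <- auc_of(s_eff)
  thresholds <- res$thresholds
  if (direction == "lower_indicates_case") thresholds <- -thresholds
  structure(
    list(points = tibble::tibble(threshold = thresholds, fpr = res$fpr,
                                 tpr = res$tpr),
         auc = res$auc, direction = direction,
         n_case = n_case, n_control = n_control,
         scores = scores, labels = labels),
    class = "fuco_roc"
  )
}

#' @export
print.fuco_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%s; %d cases vs %d controls)\n",
              x$auc, x$direction, x$n_case, x$n_control))
  invisible(x)
}

#' @export
tidy.fuco_roc <- function(x, ...) x$points

#' @export
glance.fuco_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, direction = x$direction,
                 n_case = x$n_case, n_control = x$n_control)
}

#' @export
autoplot.fuco_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Youden-optimal cutpoint of a ROC curve
#'
#' Scans all candidate cutoffs (midpoints between adjacent distinct score
#' values, plus one beyond each extreme) and returns the one maximizing
#' sensitivity + specificity (the Youden criterion). Ties break toward
#' higher specificity — fewer false positives in a screening setting — and
#' the reported cutoff is the midpoint itself.
#'
#' @param roc A `fuco_roc` object.
#' @return One-row tibble: `cutoff`, `sensitivity`, `specificity`, `youden`.
#' @export
optimal_cutpoint <- function(roc) {
  s <- sort(unique(roc$scores))
  gap <- if (length(s) > 1) median(diff(s)) / 2 else 0.5
  cands <- c(s[1] - gap,
             if (length(s) > 1) (head(s, -1) + tail(s, -1)) / 2,
             s[length(s)] + gap)
  lower <- roc$direction == "lower_indicates_case"
  stats_at <- function(cut) {
    pos <- if (lower) roc$scores <= cut else roc$scores >= cut
    c(sens = sum(pos & roc$labels) / roc$n_case,
      spec = sum(!pos & !roc$labels) / roc$n_control)
  }
  grid <- t(vapply(cands, stats_at, numeric(2)))
  j <- grid[, "sens"] + grid[, "spec"] - 1
  ord <- order(-j, -grid[, "spec"], cands)
  best <- ord[1]
  tibble::tibble(cutoff = cands[best],
                 sensitivity = unname(grid[best, "sens"]),
                 specificity = unname(grid[best, "spec"]),
                 youden = unname(j[best]))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties), on
#' pairwise-complete observations.
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs).
#' @return The correlation coefficient.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) abort("need at least 3 complete pairs")
  cor(x[ok], y[ok], method = "spearman")
}

#' Interlaboratory concordance of trait measurements
#'
#' Joins two laboratories' per-sample measurements and reports the Spearman
#' correlation per trait. A negative coefficient is flagged as a direction
#' inversion (the second laboratory's representation runs opposite to the
#' first's).
#'
#' @param lab1,lab2 Tibbles `sample_id` + trait columns.
#' @param traits Trait columns to compare (default: common trait columns).
#' @return Tibble `trait`, `n`, `spearman_r`, `direction_inverted`.
#' @export
interlab_concordance <- function(lab1, lab2,
                                 traits = intersect(trait_names(lab1),
                                                    trait_names(lab2))) {
  joined <- dplyr::inner_join(lab1[c("sample_id", traits)],
                              lab2[c("sample_id", traits)],
                              by = "sample_id", suffix = c("_1", "_2"))
  purrr::map_dfr(traits, function(tr) {
    r <- spearman_cor(joined[[paste0(tr, "_1")]], joined[[paste0(tr, "_2")]])
    tibble::tibble(trait = tr, n = nrow(joined), spearman_r = r,
                   direction_inverted = r < 0)
  })
}

#' Repeatability QC from pooled-standard triplicates
#'
#' Per peak: the intra-plate CV is the mean over plates of the within-plate
#' sd/mean; the inter-plate CV is the sd/mean of the plate means; both in
#' percent. The summary averages are restricted to peaks whose mean relative
#' intensity exceeds `ri_min` percent — low-abundance peaks have unstable
#' CVs and are excluded from the headline repeatability figures.
#'
#' @param triplicates Tibble with a `plate` column and peak columns
#'   (replicate rows within plates).
#' @param ri_min Relative-intensity threshold (percent) for the summary.
#' @return Object of class `fuco_qc`: `per_peak` tibble (`peak`, `mean_ri`,
#'   `intra_cv`, `inter_cv`) and `summary` one-row tibble.
#' @export
qc_cv <- function(triplicates, ri_min = 1) {
  peaks <- peak_columns(triplicates)
  if (!"plate" %in% names(triplicates)) abort("need a 'plate' column")
  vals <- as.matrix(triplicates[peaks])
  ri <- 100 * colMeans(vals / rowSums(vals))
  plates <- split(seq_len(nrow(vals)), triplicates$plate)
  per_peak <- purrr::map_dfr(seq_along(peaks), function(j) {
    within <- purrr::map_dbl(plates, function(rows) {
      x <- vals[rows, j]
      if (length(x) < 2) return(NA_real_)
      sd(x) / mean(x)
    })
    plate_means <- purrr::map_dbl(plates, function(rows) mean(vals[rows, j]))
    inter <- if (length(plate_means) >= 2) {
      sd(plate_means) / mean(plate_means)
    } else {
      NA_real_
    }
    tibble::tibble(peak = peaks[j], mean_ri = ri[j],
                   intra_cv = 100 * mean(within, na.rm = TRUE),
                   inter_cv = 100 * inter)
  })
  keep <- per_peak$mean_ri > ri_min
  summary <- tibble::tibble(
    n_peaks = length(peaks), n_peaks_ri = sum(keep),
    mean_intra_cv = mean(per_peak$intra_cv[keep], na.rm = TRUE),
    mean_inter_cv = mean(per_peak$inter_cv[keep], na.rm = TRUE)
  )
  structure(list(per_peak = per_peak, summary = summary), class = "fuco_qc")
}

#' @export
print.fuco_qc <- function(x, ...) {
  cat(sprintf(
    "Repeatability QC: %d/%d peaks with RI > threshold; mean intra-plate CV %.1f%%, inter-plate CV %.1f%%\n",
    x$summary$n_peaks_ri, x$summary$n_peaks,
    x$summary$mean_intra_cv, x$summary$mean_inter_cv))
  invisible(x)
}

#' @export
tidy.fuco_qc <- function(x, ...) x$per_peak

#' @export
glance.fuco_qc <- function(x, ...) x$summary
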