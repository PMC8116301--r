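# Independent brute-force oracles used to cross-check the package's
# statistics. Kept deliberately naive and separate from the implementation.

# Quartile by linear interpolation between order statistics, written out
# directly from the h = (n - 1) p formula.
quartile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p
  lo <- floor(h) + 1
  if (lo >= n) return(x[n])
  x[lo] + (h - floor(h)) * (x[lo + 1] - x[lo])
}

iqr_flags_oracle <- function(x, k = 1.5) {
  q1 <- quartile_oracle(x, 0.25)
  q3 <- quartile_oracle(x, 0.75)
  x < q1 - k * (q3 - q1) | x > q3 + k * (q3 - q1)
}

# U statistic by direct pairwise comparison (half credit for ties).
u_pairwise <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

# Two-sided Mann-Whitney p by scanning every labeling of the pooled values.
mw_scan_oracle <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a)
  u_obs <- u_pairwise(a, b)
  labelings <- utils::combn(length(pool), n1)
  us <- apply(labelings, 2, function(idx) {
    u_pairwise(pool[idx], pool[-idx])
  })
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# AUC as the probability a random case outscores a random control.
auc_pairwise_oracle <- function(case, control) {
  mean(outer(case, control, ">") + 0.5 * outer(case, control, "=="))
}

# Small two-group cohort spec with a single trait, for calibration studies.
two_group_spec <- function(mean_case, mean_control, sdv, seed,
                           n_case = 18, n_control = 289) {
  cohort_spec(
    n_damaging = n_case, n_vus = 0, n_benign = 0, n_none = n_control,
    group_index_means = tibble::tibble(trait = "T1", damaging = mean_case,
                                       vus = mean_control,
                                       benign = mean_control,
                                       none = mean_control),
    group_index_sd = tibble::tibble(trait = "T1", damaging = sdv, vus = sdv,
                                    benign = sdv, none = sdv),
    seed = seed
  )
}
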