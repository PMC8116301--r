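peak_columns <- function(table) {
  setdiff(names(table)[vapply(table, is.numeric, logical(1))],
          c("plate", "replicate", "valid"))
}

#' Normalize a raw peak-area table to analysis-peak relative areas
#'
#' Divides each sample's areas by the sum over the analysis peaks (the peaks
#' used for statistical analysis), so those columns express relative areas
#' summing to 1 per row. Rows whose analysis-peak total is zero are flagged
#' invalid (`valid = FALSE`), left undivided, and excluded from downstream
#' statistics.
#'
#' @param raw_areas Tibble `sample_id` + peak columns of raw areas (>= 0).
#' @param analysis Character vector of analysis peak labels (default: every
#'   peak column).
#' @return The table with normalized values and a `valid` flag column.
#' @export
#' @examples
#' raw <- tibble::tibble(sample_id = "a", p1 = 2, p2 = 2)
#' normalize_peak_table(raw)
normalize_peak_table <- function(raw_areas, analysis = NULL) {
  peaks <- peak_columns(raw_areas)
  if (is.null(analysis)) analysis <- peaks
  missing <- setdiff(analysis, peaks)
  if (length(missing)) {
    abort(paste0("missing analysis peak column(s): ",
                 paste(missing, collapse = ", ")))
  }
  vals <- as.matrix(raw_areas[peaks])
  if (any(vals < 0, na.rm = TRUE)) abort("raw areas must be non-negative")
  totals <- rowSums(as.matrix(raw_areas[analysis]))
  valid <- totals > 0
  vals[valid, ] <- vals[valid, , drop = FALSE] / totals[valid]
  out <- raw_areas
  out[peaks] <- tibble::as_tibble(vals)
  out$valid <- valid
  out
}

#' Fucosylation index of a fucosylated/non-fucosylated peak pair
#'
#' The fraction of a glycan structure carrying the antennary fucose:
#' `fuc / (fuc + nonfuc)`, bounded in `[0, 1]`. When both areas are zero the
#' index is undefined and `NA` is returned.
#'
#' @param fuc_area,nonfuc_area Non-negative areas (vectorized).
#' @return Index values in `[0, 1]`, `NA` where both areas are zero.
#' @export
#' @examples
#' fucosylation_index(0.02, 0.06)  # 0.25
fucosylation_index <- function(fuc_area, nonfuc_area) {
  if (any(fuc_area < 0 | nonfuc_area < 0, na.rm = TRUE)) {
    abort("areas must be non-negative")
  }
  total <- fuc_area + nonfuc_area
  ifelse(total > 0, fuc_area / total, NA_real_)
}

#' Compute direct fucosylation traits and the derived trait
#'
#' For each trait pairing, the single trait is the fucosylation index of the
#' summed fucosylated peaks against the summed non-fucosylated counterpart
#' peaks. The derived antennary fucosylation trait is the arithmetic mean of
#' the configured member traits; a sample missing any member gets a missing
#' derived value (the derived trait's definition never varies across
#' samples).
#'
#' @param table Normalized peak table from [normalize_peak_table()].
#' @param pairings Trait pairing tibble, see [default_trait_pairings()].
#' @param derived_members Trait names averaged into the derived trait;
#'   `NULL` suppresses the derived column.
#' @return Tibble `sample_id` + one column per trait (+ `derived`).
#' @export
compute_traits <- function(table, pairings = default_trait_pairings(),
                           derived_members = default_derived_members()) {
  peaks <- peak_columns(table)
  referenced <- c(unlist(pairings$fucosylated), unlist(pairings$nonfucosylated))
  unknown <- setdiff(referenced, peaks)
  if (length(unknown)) {
    abort(paste0("pairing references unknown peak(s): ",
                 paste(unknown, collapse = ", ")))
  }
  valid <- if ("valid" %in% names(table)) table$valid else rep(TRUE, nrow(table))
  out <- tibble::tibble(sample_id = table$sample_id)
  for (i in seq_len(nrow(pairings))) {
    fuc <- rowSums(as.matrix(table[pairings$fucosylated[[i]]]))
    nonfuc <- rowSums(as.matrix(table[pairings$nonfucosylated[[i]]]))
    idx <- fucosylation_index(fuc, nonfuc)
    idx[!valid] <- NA_real_
    out[[pairings$trait[i]]] <- idx
  }
  if (!is.null(derived_members)) {
    bad <- setdiff(derived_members, pairings$trait)
    if (length(bad)) {
      abort(paste0("derived member(s) not among pairings: ",
                   paste(bad, collapse = ", ")))
    }
    m <- as.matrix(out[derived_members])
    out$derived <- rowMeans(m)  # any missing member poisons the mean
  }
  out
}

#' Relative abundance of one peak, percent scale
#'
#' The normalized column of a peak expressed as a percentage of the summed
#' analysis-peak areas — the representation used by the earlier
#' interlaboratory study, exposed for concordance analyses.
#'
#' @param table Normalized peak table.
#' @param peak Peak label.
#' @return Tibble `sample_id`, `relative_abundance` (percent).
#' @export
relative_abundance <- function(table, peak) {
  if (!peak %in% names(table)) {
    abort(paste0("peak not present in table: ", peak))
  }
  tibble::tibble(sample_id = table$sample_id,
                 relative_abundance = 100 * table[[peak]])
}

#' Read a trait-pairing configuration file
#'
#' YAML layout:
#' ```yaml
#' traits:
#'   A3FG3S2: {fucosylated: [p35], nonfucosylated: [p32]}
#' derived: [A3FG3S2, ...]
#' ```
#'
#' @param path Path to the YAML file.
#' @return List with elements `pairings` (tibble) and `derived_members`.
#' @export
read_trait_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$traits)) abort("pairing config needs a 'traits' section")
  pairings <- tibble::tibble(
    trait = names(cfg$traits),
    fucosylated = purrr::map(cfg$traits, function(x) unlist(x$fucosylated)),
    nonfucosylated = purrr::map(cfg$traits,
                                function(x) unlist(x$nonfucosylated))
  )
  for (i in seq_len(nrow(pairings))) {
    f <- pairings$fucosylated[[i]]
    nf <- pairings$nonfucosylated[[i]]
    if (!length(f) || !length(nf) || length(intersect(f, nf))) {
      abort(sprintf("trait %s: peak lists must be non-empty and disjoint",
                    pairings$trait[i]))
    }
  }
  list(pairings = pairings,
       derived_members = unlist(cfg$derived) %||% default_derived_members())
}
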