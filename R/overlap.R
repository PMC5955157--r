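# Five overlap indices between a baseline sub-volume I and a recurrence
# sub-volume R on a shared grid:
#   Dice      D   = 2|I n R| / (|I| + |R|)
#   Jaccard   J   = |I n R| / |I u R|
#   Overlap fraction OF = |I n R| / min(|I|, |R|)
#   VcI = |I n R| / |I|   (common volume over the baseline volume)
#   VcR = |I n R| / |R|   (common volume over the recurrence volume)
# All are computed on voxel counts of same-grid masks, equivalent to
# volumes; no sub-voxel surface estimation.

mask_of <- function(x) {
  if (inherits(x, "metabolic_subvolume")) x$mask
  else if (inherits(x, "binary_mask")) x
  else abort("expected a binary_mask or metabolic_subvolume")
}

label_of <- function(x, default) {
  if (inherits(x, "metabolic_subvolume")) x$label else default
}

#' Overlap indices between two sub-volume masks
#'
#' @param a The baseline sub-volume (plays I): a `binary_mask` or
#'   `metabolic_subvolume`. Must be nonempty.
#' @param b The recurrence sub-volume (plays R); same grid, nonempty.
#' @param i_label,r_label Labels recorded in the output (taken from
#'   `metabolic_subvolume` inputs when available).
#' @return A one-row tibble: `i_label`, `r_label`, voxel counts `n_i`,
#'   `n_r`, `n_intersection`, `intersection_cc`, and the five indices
#'   `dice`, `jaccard`, `of`, `vci`, `vcr` (all in `[0, 1]`).
#' @export
overlap_indices <- function(a, b, i_label = NULL, r_label = NULL) {
  i_label <- i_label %||% label_of(a, "I")
  r_label <- r_label %||% label_of(b, "R")
  ma <- mask_of(a); mb <- mask_of(b)
  if (!same_grid(ma$grid, mb$grid)) abort("masks must share one grid")
  na <- sum(ma$membership); nb <- sum(mb$membership)
  if (na == 0 || nb == 0)
    abort("overlap indices are undefined for an empty mask")
  ni <- sum(ma$membership & mb$membership)
  nu <- na + nb - ni
  tibble::tibble(
    i_label = i_label, r_label = r_label,
    n_i = na, n_r = nb, n_intersection = ni,
    intersection_cc = ni * voxel_volume_cc(ma$grid),
    dice = 2 * ni / (na + nb),
    jaccard = ni / nu,
    of = ni / min(na, nb),
    vci = ni / na,
    vcr = ni / nb
  )
}

#' Classify an overlap value on the Cohen-kappa-style concordance scale
#'
#' Half-open bins making the scale a total, ordered classification of
#' `[0, 1]`: `[0, 0.2]` very low, `(0.2, 0.4]` low, `(0.4, 0.6]` moderate,
#' `(0.6, 0.8]` good, `(0.8, 1]` very good.
#'
#' @param value Numeric vector of overlap values in `[0, 1]`.
#' @return An ordered factor with levels `very_low < low < moderate <
#'   good < very_good`.
#' @export
classify_concordance <- function(value) {
  if (any(!is.finite(value)) || any(value < 0 | value > 1))
    abort("concordance values must lie in [0, 1]")
  cut(value, breaks = c(0, 0.2, 0.4, 0.6, 0.8, 1),
      labels = c("very_low", "low", "moderate", "good", "very_good"),
      include.lowest = TRUE, right = TRUE, ordered_result = TRUE)
}

#' Per-patient overlap table for one baseline/recurrence sub-volume set
#'
#' Convenience wrapper computing [overlap_indices()] between every baseline
#' sub-volume and one recurrence sub-volume.
#'
#' @param baseline_series A [delineate_series()] result (list of
#'   `metabolic_subvolume`s).
#' @param recurrence A recurrence `metabolic_subvolume` (e.g. R40 or R90).
#' @return A tibble with one row per baseline sub-volume.
#' @export
patient_overlaps <- function(baseline_series, recurrence) {
  purrr::map_dfr(baseline_series, overlap_indices, b = recurrence)
}

check_overlap_cols <- function(overlaps) {
  need <- c("i_label", "r_label", "dice", "jaccard", "of", "vci", "vcr",
            "n_intersection")
  miss <- setdiff(need, names(overlaps))
  if (length(miss))
    abort(sprintf("overlap table is missing columns: %s",
                  paste(miss, collapse = ", ")))
  if (nrow(overlaps) == 0) abort("empty cohort")
}

#' Cohort mean and SD of the overlap indices per baseline threshold
#'
#' Aggregates a per-patient overlap table into the histogram-style summary
#' (one mean and SD per baseline threshold and index). Patients with zero
#' overlap are included with value 0; the `zero_overlap_included` attribute
#' records that choice.
#'
#' @param overlaps A tibble of per-patient [overlap_indices()] rows (e.g.
#'   bound rows of [patient_overlaps()]), one set per patient.
#' @param r_label Which recurrence sub-volume to summarize against
#'   (`"R40"` or `"R90"`).
#' @return A long-format tibble: `i_label`, `index`, `mean`, `sd`, `n`.
#' @export
cohort_overlap_table <- function(overlaps, r_label = "R40") {
  check_overlap_cols(overlaps)
  out <- overlaps |>
    dplyr::filter(.data$r_label == !!r_label) |>
    tidyr::pivot_longer(cols = c("dice", "jaccard", "of", "vci", "vcr"),
                        names_to = "index", values_to = "value") |>
    dplyr::group_by(.data$i_label, .data$index) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = if (dplyr::n() > 1) sd(.data$value) else 0,
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$i_label, .data$index)
  attr(out, "zero_overlap_included") <- TRUE
  out
}

#' Count patients with any baseline/recurrence overlap per threshold
#'
#' For each baseline threshold, the number (and integer-rounded percentage)
#' of patients whose sub-volume shares at least `min_voxels` voxels with
#' the recurrence sub-volume.
#'
#' @inheritParams cohort_overlap_table
#' @param r_label Recurrence sub-volume label (default `"R90"`).
#' @param min_voxels Minimum shared voxel count that counts as "overlap
#'   present" (default 1).
#' @return A tibble: `i_label`, `n_overlap`, `n`, `percent`, and a
#'   formatted `label` column like `"14 (37%)"`.
#' @export
overlap_presence_counts <- function(overlaps, r_label = "R90", min_voxels = 1) {
  check_overlap_cols(overlaps)
  overlaps |>
    dplyr::filter(.data$r_label == !!r_label) |>
    dplyr::group_by(.data$i_label) |>
    dplyr::summarise(
      n_overlap = sum(.data$n_intersection >= min_voxels),
      n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(percent = as.integer(round(100 * .data$n_overlap / .data$n)),
                  label = sprintf("%d (%d%%)", .data$n_overlap, .data$percent)) |>
    dplyr::arrange(.data$i_label)
}
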