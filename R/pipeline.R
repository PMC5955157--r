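# End-to-end orchestration: simulate (or accept) a cohort, register each
# follow-up scan pair onto its baseline, delineate the baseline threshold
# series and the follow-up R40/R90 sub-volumes on the shared grid, compute
# the five overlap indices, and assemble the cohort report tables
# (per-threshold volume summary, R90 presence counts, overlap-index
# summary, and the group comparisons of I40 MTV, TLG and SUVmax).

#' Configure a full pipeline run
#'
#' @param n_cr,n_lrrd Cohort composition (defaults 35 complete responders
#'   and 38 recurrence/residual patients).
#' @param cohort A [cohort_config()].
#' @param registration If `FALSE`, scans are treated as pre-aligned and the
#'   identity transform is used (the `--skip-registration` path).
#' @param reg_bins,reg_levels,reg_max_iter Options passed to
#'   [register_rigid()].
#' @param region_fraction,region_margin_mm [derive_region()] parameters for
#'   the registration region (defaults 0.30 and 40 mm).
#' @param fractions_baseline Baseline threshold fractions (default 0.30 to
#'   0.90 by 0.10).
#' @param fractions_followup Follow-up threshold fractions (default 0.40
#'   and 0.90).
#' @param voi_fraction,voi_margin_mm The operator-VOI stand-in: the lesion
#'   VOI is the bounding box of voxels above `voi_fraction` of the global
#'   SUVmax, padded by `voi_margin_mm`.
#' @param seed Master seed; every source of randomness derives from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_cr = 35, n_lrrd = 38, cohort = cohort_config(),
                            registration = TRUE, reg_bins = 32,
                            reg_levels = c(3, 1), reg_max_iter = 1000,
                            region_fraction = 0.30, region_margin_mm = 40,
                            fractions_baseline = seq(0.3, 0.9, by = 0.1),
                            fractions_followup = c(0.4, 0.9),
                            voi_fraction = 0.5, voi_margin_mm = 16,
                            seed = 1) {
  stopifnot(all(fractions_baseline > 0 & fractions_baseline <= 1),
            all(fractions_followup > 0 & fractions_followup <= 1))
  structure(list(n_cr = n_cr, n_lrrd = n_lrrd, cohort = cohort,
                 registration = registration, reg_bins = reg_bins,
                 reg_levels = reg_levels, reg_max_iter = reg_max_iter,
                 region_fraction = region_fraction,
                 region_margin_mm = region_margin_mm,
                 fractions_baseline = fractions_baseline,
                 fractions_followup = fractions_followup,
                 voi_fraction = voi_fraction, voi_margin_mm = voi_margin_mm,
                 seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys are [pipeline_config()] arguments; a `cohort` mapping is
#' passed to [cohort_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$cohort)) y$cohort <- do.call(cohort_config, y$cohort)
  do.call(pipeline_config, y)
}

#' Analyze one patient's scan pair
#'
#' Runs the per-patient stages (registration region, rigid registration,
#' follow-up resampling, baseline series delineation, R40/R90 delineation,
#' overlap indices) on a generated or loaded `patient_phantom`-shaped
#' object.
#'
#' @param phantom A `patient_phantom` (or any list with the same fields).
#' @param config A [pipeline_config()].
#' @param keep_masks Keep the delineated masks in the result (memory-heavy
#'   for large cohorts; default `FALSE`).
#' @return A list: `record` (one-row tibble of per-patient scalars),
#'   `subvolumes` (tibble, one row per sub-volume), `overlaps` (tibble of
#'   overlap indices, `NULL` for CR), and optionally `baseline_series`,
#'   `r_masks`.
#' @export
analyze_patient <- function(phantom, config = pipeline_config(),
                            keep_masks = FALSE) {
  base_pet <- phantom$baseline_pet
  grid <- base_pet$grid

  region <- derive_region(base_pet, config$region_fraction,
                          config$region_margin_mm)
  if (config$registration) {
    reg <- register_rigid(phantom$baseline_anat, phantom$followup_anat,
                          region, bins = config$reg_bins,
                          levels = config$reg_levels,
                          max_iter = config$reg_max_iter)
    tf <- reg$transform
    reg_converged <- reg$converged
    reg_mi <- reg$mi
  } else {
    tf <- rigid_transform(center = as.vector(colMeans(grid_extent(grid))))
    reg_converged <- NA
    reg_mi <- NA_real_
  }
  fu_pet <- apply_rigid(phantom$followup_pet, tf, grid,
                        interpolation = "trilinear")

  voi_b <- as_voi(derive_region(base_pet, config$voi_fraction, 0),
                  margin_mm = config$voi_margin_mm)
  series <- delineate_series(base_pet, voi_b,
                             fractions = config$fractions_baseline,
                             prefix = "I")
  i40 <- series[[sprintf("I%.0f", 40)]]
  tlg40 <- if (!is.null(i40)) i40$tlg else NA_real_

  overlaps <- NULL
  r_masks <- NULL
  sub_tbl <- subvolume_table(series) |>
    dplyr::mutate(scan = "baseline", .before = 1)
  if (phantom$group == "LRRD") {
    voi_f <- as_voi(derive_region(fu_pet, config$voi_fraction, 0),
                    margin_mm = config$voi_margin_mm)
    r_masks <- delineate_series(fu_pet, voi_f,
                                fractions = config$fractions_followup,
                                prefix = "R")
    overlaps <- purrr::map_dfr(r_masks, function(r) patient_overlaps(series, r))
    sub_tbl <- dplyr::bind_rows(
      sub_tbl,
      subvolume_table(r_masks) |> dplyr::mutate(scan = "followup", .before = 1))
  }

  record <- tibble::tibble(
    group = phantom$group,
    suvmax = if (!is.null(i40)) i40$suvmax else max(base_pet$values),
    i40_cc = if (!is.null(i40)) i40$mtv_cc else NA_real_,
    tlg = tlg40,
    reg_converged = reg_converged,
    reg_mi = reg_mi,
    tx = tf$translation[1], ty = tf$translation[2], tz = tf$translation[3],
    rx = tf$rotation[1], ry = tf$rotation[2], rz = tf$rotation[3]
  )
  out <- list(record = record, subvolumes = sub_tbl, overlaps = overlaps)
  if (keep_masks) {
    out$baseline_series <- series
    out$r_masks <- r_masks
    out$resampled_followup_pet <- fu_pet
    out$transform <- tf
  }
  out
}

#' Run the full cohort analysis
#'
#' Simulates the configured cohort (one patient at a time, from per-patient
#' seeds derived from the master seed), analyzes every patient with
#' [analyze_patient()], and assembles the report. A per-patient stage
#' failure is recorded with its reason rather than silently dropping the
#' patient; non-converged registrations are flagged in the patient table.
#' Recurrence/residual patients contribute to the overlap tables; all
#' patients contribute to the group statistics.
#'
#' @param config A [pipeline_config()].
#' @param progress Print per-patient progress lines (default `FALSE`).
#' @return An object of class `petsubvol_report`: tibbles `patients`,
#'   `subvolumes`, `overlaps`, `volume_summary` (per-threshold mean and SD
#'   MTV for the recurrence group, baseline and follow-up),
#'   `presence_counts` (R90, per threshold), `overlap_summary` (R40,
#'   long format), `comparisons` (I40 MTV, TLG, SUVmax between groups),
#'   `failures`, and a `provenance` list (seed, config hash, package
#'   version).
#' @export
run_pipeline <- function(config = pipeline_config(), progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  draws <- draw_cohort_configs(config$n_cr, config$n_lrrd, config$cohort,
                               seed = config$seed)
  records <- list(); subvols <- list(); overlaps <- list()
  failures <- list()
  for (i in seq_len(nrow(draws))) {
    pid <- draws$patient_id[i]
    t0 <- Sys.time()
    res <- tryCatch(
      analyze_patient(generate_patient(draws$config[[i]]), config),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <-
        tibble::tibble(patient_id = pid, reason = conditionMessage(res))
      next
    }
    records[[i]] <- dplyr::mutate(res$record, patient_id = pid, .before = 1)
    subvols[[i]] <- dplyr::mutate(res$subvolumes, patient_id = pid, .before = 1)
    if (!is.null(res$overlaps))
      overlaps[[i]] <- dplyr::mutate(res$overlaps, patient_id = pid, .before = 1)
    if (progress)
      message(sprintf("%s (%s): %.1f s", pid, draws$group[i],
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  patients <- dplyr::bind_rows(records)
  subvolumes <- dplyr::bind_rows(subvols)
  overlap_tbl <- dplyr::bind_rows(overlaps)
  failures <- if (length(failures)) dplyr::bind_rows(failures)
              else tibble::tibble(patient_id = character(), reason = character())

  volume_summary <- subvolumes |>
    dplyr::filter(.data$patient_id %in% patients$patient_id[patients$group == "LRRD"]) |>
    dplyr::group_by(.data$scan, .data$label, .data$fraction) |>
    dplyr::summarise(mean_cc = mean(.data$mtv_cc),
                     sd_cc = if (dplyr::n() > 1) sd(.data$mtv_cc) else 0,
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$scan, .data$fraction)

  presence_counts <- if (nrow(overlap_tbl))
    overlap_presence_counts(overlap_tbl, r_label = "R90") else NULL
  overlap_summary <- if (nrow(overlap_tbl))
    cohort_overlap_table(overlap_tbl, r_label = "R40") else NULL
  comparisons <- if (dplyr::n_distinct(patients$group) == 2)
    compare_groups(patients, vars = c("i40_cc", "tlg", "suvmax")) else NULL

  structure(list(
    patients = patients, subvolumes = subvolumes, overlaps = overlap_tbl,
    volume_summary = volume_summary, presence_counts = presence_counts,
    overlap_summary = overlap_summary, comparisons = comparisons,
    failures = failures,
    provenance = list(seed = config$seed,
                      config_hash = rlang::hash(unclass(config)),
                      package_version = as.character(utils::packageVersion("petsubvol")),
                      n_cr = config$n_cr, n_lrrd = config$n_lrrd)
  ), class = "petsubvol_report")
}

#' @export
print.petsubvol_report <- function(x, ...) {
  cat(sprintf("<petsubvol_report> %d patients (%d CR, %d LRRD), seed %s\n",
              nrow(x$patients), sum(x$patients$group == "CR"),
              sum(x$patients$group == "LRRD"), x$provenance$seed))
  if (nrow(x$failures)) cat(sprintf("  %d patient(s) failed\n", nrow(x$failures)))
  if (!is.null(x$comparisons)) {
    cmp <- x$comparisons
    cat(sprintf("  I40 MTV %s vs %s: median %.1f vs %.1f cc, p = %.2g\n",
                cmp$group_a[1], cmp$group_b[1],
                cmp$median_a[cmp$variable == "i40_cc"],
                cmp$median_b[cmp$variable == "i40_cc"],
                cmp$p_value[cmp$variable == "i40_cc"]))
  }
  invisible(x)
}

#' Glance at a cohort report
#'
#' @param x A [run_pipeline()] report.
#' @param ... Unused.
#' @return A one-row tibble of headline quantities: cohort sizes, median
#'   I40 per group, the I40/TLG/SUVmax p-values, and the mean OF between
#'   R40 and I40.
#' @export
glance.petsubvol_report <- function(x, ...) {
  p <- function(v) {
    if (is.null(x$comparisons)) return(NA_real_)
    x$comparisons$p_value[x$comparisons$variable == v]
  }
  med <- function(g) median(x$patients$i40_cc[x$patients$group == g])
  of_i40 <- if (!is.null(x$overlap_summary)) {
    s <- x$overlap_summary
    s$mean[s$i_label == "I40" & s$index == "of"]
  } else NA_real_
  tibble::tibble(
    n_cr = sum(x$patients$group == "CR"),
    n_lrrd = sum(x$patients$group == "LRRD"),
    median_i40_cr_cc = med("CR"),
    median_i40_lrrd_cc = med("LRRD"),
    p_i40 = p("i40_cc"), p_tlg = p("tlg"), p_suvmax = p("suvmax"),
    mean_of_r40_i40 = of_i40,
    n_failed = nrow(x$failures)
  )
}

#' Tidy a cohort report
#'
#' @param x A [run_pipeline()] report.
#' @param ... Unused.
#' @return The long-format overlap summary tibble (threshold, index, mean,
#'   sd), the Figure-style data.
#' @export
tidy.petsubvol_report <- function(x, ...) {
  if (is.null(x$overlap_summary))
    abort("report contains no overlap results (no LRRD patients)")
  x$overlap_summary
}

#' Write the report tables to a directory
#'
#' Emits deterministic CSVs (`patients.csv`, `subvolumes.csv`,
#' `overlaps.csv`, `volume_summary.csv`, `presence_counts.csv`,
#' `overlap_summary.csv`, `comparisons.csv`, `failures.csv`) plus a
#' consolidated `report.json` with the provenance block.
#'
#' @param report A `petsubvol_report`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    if (!is.null(x) && is.data.frame(x))
      readr::write_csv(x, file.path(dir, paste0(name, ".csv")))
  }
  wr(report$patients, "patients")
  wr(report$subvolumes, "subvolumes")
  wr(report$overlaps, "overlaps")
  wr(report$volume_summary, "volume_summary")
  wr(report$presence_counts, "presence_counts")
  wr(report$overlap_summary, "overlap_summary")
  wr(report$comparisons, "comparisons")
  wr(report$failures, "failures")
  jsonlite::write_json(
    list(provenance = report$provenance,
         glance = as.list(glance(report))),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
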