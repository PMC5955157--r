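# Seeded synthetic PET/CT phantoms. Each patient is a continuous scene
# defined in baseline world coordinates: a soft-edged body ellipsoid with
# high-intensity anatomical landmarks (registration anchors) near the tumor,
# plus a heterogeneous tumor built from a handful of anisotropic Gaussian
# uptake kernels confined to an ellipsoid, rescaled so the noise-free
# maximum hits a target SUVmax. The follow-up scan observes the same scene
# (with the tumor replaced by a residual/recurrence lesion, or by background
# for complete responders) through the inverse of a true patient
# repositioning transform, giving exact ground truth for registration and
# overlap recovery. Additive Gaussian noise comes last.

# Reference sub-volume sizes of the unit (size = 1) tumor and recurrence
# templates, measured once on the noise-free template by running the
# package's own delineation; patient size factors are derived from target
# volumes through exact c^3 scaling of all spatial parameters.
REF_I40_CC <- 12.800
REF_R40_CC <- 27.136

ellipsoid_q <- function(pts, center, semi_axes) {
  sqrt(((pts[, 1] - center[1]) / semi_axes[1])^2 +
       ((pts[, 2] - center[2]) / semi_axes[2])^2 +
       ((pts[, 3] - center[3]) / semi_axes[3])^2)
}

# sum of anisotropic Gaussian kernels; centers: k x 3, sigmas: k x 3, amps: k
gaussian_kernel_sum <- function(pts, centers, sigmas, amps) {
  out <- numeric(nrow(pts))
  for (k in seq_len(nrow(centers))) {
    e <- ((pts[, 1] - centers[k, 1]) / sigmas[k, 1])^2 +
         ((pts[, 2] - centers[k, 2]) / sigmas[k, 2])^2 +
         ((pts[, 3] - centers[k, 3]) / sigmas[k, 3])^2
    out <- out + amps[k] * exp(-e / 2)
  }
  out
}

# unit-size lesion templates; every length scales with the size factor
tumor_template <- function() {
  list(semi_axes = c(26, 24, 22),
       kernel_offsets = rbind(c(0, 0, 0), c(9, -7, 5), c(-8, 6, -7),
                              c(2, -1, 1)),
       kernel_sigmas = rbind(c(12, 10.5, 9.5), c(7, 6, 6), c(6, 5, 5),
                             c(4.5, 4.5, 4.5)),
       kernel_amps = c(1, 0.45, 0.35, 0.3))
}

recurrence_template <- function() {
  list(semi_axes = c(32, 29, 27),
       kernel_offsets = rbind(c(0, 0, 0), c(3, -2, 2)),
       kernel_sigmas = rbind(c(16, 14.5, 13.5), c(4.5, 4.5, 4.5)),
       kernel_amps = c(1, 0.4))
}

scale_template <- function(tpl, size) {
  list(semi_axes = tpl$semi_axes * size,
       kernel_offsets = tpl$kernel_offsets * size,
       kernel_sigmas = tpl$kernel_sigmas * size,
       kernel_amps = tpl$kernel_amps)
}

#' Configure a single synthetic patient phantom
#'
#' Unspecified stochastic elements (target SUVmax, the true repositioning
#' transform, the recurrence centroid offset) are drawn at generation time
#' from the cohort-level defaults; pass explicit values for fully
#' deterministic scenes. All tumor lengths scale with `size` (so every
#' threshold sub-volume scales with `size^3` exactly); `size = 1`
#' corresponds to a baseline I40 of about `r REF_I40_CC` cc.
#'
#' @param group `"LRRD"` (local recurrence / residual disease; the phantom
#'   carries a recurrence lesion) or `"CR"` (complete response; no lesion on
#'   follow-up).
#' @param size Tumor size factor (> 0).
#' @param recurrence_size Recurrence lesion size factor (> 0); ignored for CR.
#' @param target_suvmax Baseline tumor SUVmax; `NULL` draws from
#'   N(14.3, 4.5^2) truncated above 5.
#' @param recurrence_suvmax Follow-up lesion SUVmax; `NULL` draws from the
#'   same distribution.
#' @param recurrence_offset mm triple from the baseline tumor centroid;
#'   `NULL` draws an edge-weighted offset (lesions sit near the baseline
#'   tumor boundary, the regime the cohort emulates).
#' @param translation,rotation True repositioning transform (mm, degrees,
#'   Z-Y-X Euler); `NULL` draws N(0, 4^2) mm clipped to +/-10 and
#'   N(0, 1.5^2) degrees clipped to +/-5.
#' @param noise_sd PET additive Gaussian noise SD, SUV (default 0.1).
#' @param anat_noise_sd Anatomical image noise SD (default 1).
#' @param shape,spacing Grid: voxels per axis and spacing in mm (defaults
#'   64^3 at 4 mm; the grid is centered on the world origin).
#' @param background_suv Body background SUV (default 1.5).
#' @param tumor_centroid World position of the tumor, mm.
#' @param seed Integer seed; identical seeds give bit-identical phantoms.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(group = c("LRRD", "CR"), size = 1,
                           recurrence_size = 1,
                           target_suvmax = NULL, recurrence_suvmax = NULL,
                           recurrence_offset = NULL,
                           translation = NULL, rotation = NULL,
                           noise_sd = 0.1, anat_noise_sd = 1,
                           shape = c(64, 64, 64), spacing = c(4, 4, 4),
                           background_suv = 1.5,
                           tumor_centroid = c(20, 0, 10), seed = NULL) {
  group <- match.arg(group)
  stopifnot(size > 0, recurrence_size > 0, noise_sd >= 0, background_suv > 0)
  if (!is.null(target_suvmax) && target_suvmax <= background_suv)
    abort("target SUVmax must exceed the background level")
  cfg <- list(group = group, size = size, recurrence_size = recurrence_size,
              target_suvmax = target_suvmax,
              recurrence_suvmax = recurrence_suvmax,
              recurrence_offset = recurrence_offset,
              translation = translation, rotation = rotation,
              noise_sd = noise_sd, anat_noise_sd = anat_noise_sd,
              shape = as.integer(shape), spacing = as.numeric(spacing),
              background_suv = background_suv,
              tumor_centroid = as.numeric(tumor_centroid), seed = seed)
  structure(cfg, class = "phantom_config")
}

draw_truncnorm <- function(n, mean, sd, lower) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  x <- rnorm(n, mean, sd)
  while (any(bad <- x <= lower)) x[bad] <- rnorm(sum(bad), mean[bad], sd[bad])
  x
}

draw_edge_offset <- function(semi_axes) {
  u <- rnorm(3)
  u <- u / sqrt(sum(u^2))
  rb <- 1 / sqrt(sum((u / semi_axes)^2))   # boundary radius along u
  u * rb * runif(1, 0.7, 1.1)
}

soft_step <- function(x, width) stats::plogis(x / width)

#' Generate one synthetic patient (baseline + follow-up PET/CT pair)
#'
#' @param config A [phantom_config()].
#' @return An object of class `patient_phantom`: baseline and follow-up
#'   `suv_image`s (`baseline_pet`, `baseline_anat`, `followup_pet`,
#'   `followup_anat`), the true repositioning [rigid_transform()]
#'   (`true_transform`, mapping baseline world coordinates into the
#'   follow-up frame, i.e. the transform [apply_rigid()] needs to pull the
#'   follow-up scan onto the baseline grid), ground-truth `tumor_mask` and
#'   `recurrence_mask` (native grids; `recurrence_mask` is `NULL` for CR),
#'   the group label, and the fully resolved `draws`.
#' @export
generate_patient <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  tum <- scale_template(tumor_template(), config$size)
  suvmax <- config$target_suvmax %||% draw_truncnorm(1, 14.3, 4.5, 5)
  translation <- config$translation %||%
    pmax(pmin(rnorm(3, 0, 4), 10), -10)
  rotation <- config$rotation %||%
    pmax(pmin(rnorm(3, 0, 1.5), 5), -5)

  rec <- NULL
  if (config$group == "LRRD") {
    rec <- scale_template(recurrence_template(), config$recurrence_size)
    rec$suvmax <- config$recurrence_suvmax %||% draw_truncnorm(1, 14.3, 4.5, 5)
    rec$offset <- config$recurrence_offset %||% draw_edge_offset(tum$semi_axes)
    rec$centroid <- config$tumor_centroid + rec$offset
  }

  grid <- volume_grid(config$shape,
                      spacing = config$spacing,
                      origin = -config$spacing * (config$shape - 1L) / 2)
  ext <- grid_extent(grid)
  ctr <- config$tumor_centroid
  if (any(ctr - tum$semi_axes - 10 < ext["lo", ]) ||
      any(ctr + tum$semi_axes + 10 > ext["hi", ]))
    abort("tumor extends beyond the grid")

  body_center <- c(0, 0, 0)
  body_semi <- c(105, 105, 118)
  softness <- 2
  if (!is.null(rec) &&
      ellipsoid_q(matrix(rec$centroid, 1), body_center, body_semi) >= 1)
    abort("recurrence lesion falls outside the body")

  landmark_offsets <- rbind(c(34, 12, -22), c(-30, 26, 18),
                            c(8, -34, -14), c(22, 30, 26))
  landmark_radius <- 8
  # broader organ-like soft-tissue structures give the registration an
  # extended intensity gradient field around the sharp bony landmarks
  organ_offsets <- rbind(c(42, 22, -8), c(-36, -26, 14), c(4, 36, 32))
  organ_semi <- rbind(c(30, 24, 22), c(26, 28, 20), c(24, 22, 26))

  scene_anat <- function(pts) {
    qb <- ellipsoid_q(pts, body_center, body_semi)
    v <- 40 * soft_step(1 - qb, softness / mean(body_semi))
    for (o in seq_len(nrow(organ_offsets))) {
      qo <- ellipsoid_q(pts, ctr + organ_offsets[o, ], organ_semi[o, ])
      v <- v + 45 * soft_step(1 - qo, 3 / mean(organ_semi[o, ]))
    }
    for (l in seq_len(nrow(landmark_offsets))) {
      d <- sqrt(rowSums(sweep(pts, 2, ctr + landmark_offsets[l, ], "-")^2))
      v <- v + 220 * soft_step(landmark_radius - d, softness)
    }
    v
  }

  lesion_field <- function(pts, centroid, tpl, amp_scale) {
    inside <- ellipsoid_q(pts, centroid, tpl$semi_axes) <= 1
    v <- numeric(nrow(pts))
    if (any(inside)) {
      centers <- sweep(tpl$kernel_offsets, 2, centroid, "+")
      v[inside] <- amp_scale * gaussian_kernel_sum(pts[inside, , drop = FALSE],
                                                   centers, tpl$kernel_sigmas,
                                                   tpl$kernel_amps)
    }
    v
  }

  pts <- grid_coords(grid)
  body_soft <- soft_step(1 - ellipsoid_q(pts, body_center, body_semi),
                         softness / mean(body_semi))

  # rescale so the noise-free baseline maximum equals the target SUVmax
  raw_tum <- lesion_field(pts, ctr, tum, 1)
  amp_tum <- (suvmax - config$background_suv) / max(raw_tum)
  pet_base <- config$background_suv * body_soft + amp_tum * raw_tum
  anat_base <- scene_anat(pts)

  true_tf <- rigid_transform(translation, rotation,
                             center = as.vector(colMeans(ext)))
  # follow-up voxel w observes baseline scene point T^{-1}(w)
  pts_f <- transform_points(invert_transform(true_tf), pts)
  body_soft_f <- soft_step(1 - ellipsoid_q(pts_f, body_center, body_semi),
                           softness / mean(body_semi))
  pet_fu <- config$background_suv * body_soft_f
  rec_mask <- NULL
  if (!is.null(rec)) {
    raw_rec_base <- lesion_field(pts, rec$centroid, rec, 1)
    amp_rec <- (rec$suvmax - config$background_suv) / max(raw_rec_base)
    pet_fu <- pet_fu + lesion_field(pts_f, rec$centroid, rec, amp_rec)
    rec_mask <- binary_mask(array(ellipsoid_q(pts_f, rec$centroid,
                                              rec$semi_axes) <= 1,
                                  dim = grid$shape), grid)
  }
  anat_fu <- scene_anat(pts_f)

  n <- prod(grid$shape)
  add_noise <- function(v, sd_, clamp0) {
    if (sd_ > 0) v <- v + rnorm(n, 0, sd_)
    if (clamp0) v <- pmax(v, 0)
    v
  }
  pet_base <- add_noise(pet_base, config$noise_sd, TRUE)
  pet_fu <- add_noise(pet_fu, config$noise_sd, TRUE)
  anat_base <- add_noise(anat_base, config$anat_noise_sd, FALSE)
  anat_fu <- add_noise(anat_fu, config$anat_noise_sd, FALSE)

  as_img <- function(v, modality) suv_image(array(v, dim = grid$shape), grid, modality)
  tumor_mask <- binary_mask(array(ellipsoid_q(pts, ctr, tum$semi_axes) <= 1,
                                  dim = grid$shape), grid)

  structure(list(
    baseline_pet = as_img(pet_base, "PET"),
    baseline_anat = as_img(anat_base, "ANAT"),
    followup_pet = as_img(pet_fu, "PET"),
    followup_anat = as_img(anat_fu, "ANAT"),
    true_transform = true_tf,
    tumor_mask = tumor_mask,
    recurrence_mask = rec_mask,
    group = config$group,
    draws = list(target_suvmax = suvmax,
                 recurrence_suvmax = if (is.null(rec)) NA_real_ else rec$suvmax,
                 recurrence_offset = if (is.null(rec)) NULL else rec$offset,
                 translation = translation, rotation = rotation),
    config = config
  ), class = "patient_phantom")
}

#' @export
print.patient_phantom <- function(x, ...) {
  cat(sprintf("<patient_phantom> group %s, baseline SUVmax target %.2f\n",
              x$group, x$draws$target_suvmax))
  invisible(x)
}

#' Cohort-level phantom parameters
#'
#' Defaults emulate the statistical structure of a head-and-neck
#' radio-chemotherapy cohort: baseline I40 volumes lognormal with medians
#' 23.5 cc (LRRD) and 8.9 cc (CR) — a median ratio of about 2.6 — and
#' sdlog 0.45; group SUVmax N(16.1, 5.2^2) for LRRD and N(13.2, 3.1^2) for
#' CR, truncated above 5; recurrence R40 volumes lognormal with median
#' 25.4 cc; repositioning translations N(0, 4^2) mm clipped to +/-10 and
#' rotations N(0, 1.5^2) degrees clipped to +/-5.
#'
#' @param median_i40_lrrd,median_i40_cr Median baseline I40 volume (cc) per
#'   group; their ratio is the cohort effect size.
#' @param sdlog_i40 Log-scale SD of the I40 volume distributions.
#' @param median_r40 Median recurrence R40 volume (cc).
#' @param sdlog_r40 Log-scale SD of the R40 distribution.
#' @param suvmax_mean,suvmax_sd Named (`CR`, `LRRD`) SUVmax distribution
#'   parameters.
#' @param noise_sd PET noise SD, SUV.
#' @param shape,spacing Grid specification passed to every patient.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(median_i40_lrrd = 23.5, median_i40_cr = 8.9,
                          sdlog_i40 = 0.45,
                          median_r40 = 25.4, sdlog_r40 = 0.45,
                          suvmax_mean = c(CR = 13.2, LRRD = 16.1),
                          suvmax_sd = c(CR = 3.1, LRRD = 5.2),
                          noise_sd = 0.1,
                          shape = c(64, 64, 64), spacing = c(4, 4, 4)) {
  structure(list(median_i40_lrrd = median_i40_lrrd,
                 median_i40_cr = median_i40_cr, sdlog_i40 = sdlog_i40,
                 median_r40 = median_r40, sdlog_r40 = sdlog_r40,
                 suvmax_mean = suvmax_mean, suvmax_sd = suvmax_sd,
                 noise_sd = noise_sd, shape = as.integer(shape),
                 spacing = as.numeric(spacing)),
            class = "cohort_config")
}

#' Draw per-patient phantom configurations for a cohort
#'
#' Per-patient target volumes, SUVmax values, repositioning transforms and
#' seeds are all derived from `seed`, so a cohort is reproducible
#' independently of how many patients are later generated.
#'
#' @param n_cr,n_lrrd Number of complete-response and recurrence/residual
#'   patients (>= 0).
#' @param params A [cohort_config()].
#' @param seed Integer master seed.
#' @return A tibble with one row per patient: `patient_id`, `group`,
#'   `target_i40_cc`, `target_suvmax`, `size`, `recurrence_size`, `seed`,
#'   and a `config` list-column of [phantom_config()] objects.
#' @export
draw_cohort_configs <- function(n_cr, n_lrrd, params = cohort_config(), seed = 1) {
  stopifnot(n_cr >= 0, n_lrrd >= 0)
  n <- n_cr + n_lrrd
  if (n == 0) {
    return(tibble::tibble(patient_id = character(), group = character(),
                          target_i40_cc = numeric(), target_suvmax = numeric(),
                          size = numeric(), recurrence_size = numeric(),
                          seed = integer(), config = list()))
  }
  set.seed(seed)
  group <- c(rep("CR", n_cr), rep("LRRD", n_lrrd))
  med <- ifelse(group == "LRRD", params$median_i40_lrrd, params$median_i40_cr)
  target_i40 <- exp(rnorm(n, log(med), params$sdlog_i40))
  suvmax <- draw_truncnorm(n, params$suvmax_mean[group], params$suvmax_sd[group], 5)
  target_r40 <- exp(rnorm(n, log(params$median_r40), params$sdlog_r40))
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  size <- (target_i40 / REF_I40_CC)^(1 / 3)
  rec_size <- (target_r40 / REF_R40_CC)^(1 / 3)
  cfgs <- lapply(seq_len(n), function(i) {
    phantom_config(group = group[i], size = size[i],
                   recurrence_size = rec_size[i],
                   target_suvmax = suvmax[i],
                   noise_sd = params$noise_sd,
                   shape = params$shape, spacing = params$spacing,
                   seed = seeds[i])
  })
  tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    group = group,
    target_i40_cc = target_i40,
    target_suvmax = suvmax,
    size = size,
    recurrence_size = ifelse(group == "LRRD", rec_size, NA_real_),
    seed = seeds,
    config = cfgs
  )
}

#' Generate a whole synthetic cohort
#'
#' @inheritParams draw_cohort_configs
#' @return A list of [generate_patient()] results (`patient_phantom`
#'   objects), in patient order, with the draw table attached as attribute
#'   `"draws"`.
#' @export
generate_cohort <- function(n_cr, n_lrrd, params = cohort_config(), seed = 1) {
  draws <- draw_cohort_configs(n_cr, n_lrrd, params, seed)
  phantoms <- lapply(draws$config, generate_patient)
  attr(phantoms, "draws") <- draws[setdiff(names(draws), "config")]
  phantoms
}

`%||%` <- function(a, b) if (is.null(a)) b else a
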