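# Fixed-percentage-of-SUVmax delineation of metabolic tumor sub-volumes.
#
# A sub-volume at fraction f is the 26-connected component, containing the
# SUVmax voxel, of all voxels inside the operator VOI with SUV >= f * SUVmax
# (ties at exactly the threshold are included). Seeding at the SUVmax voxel
# makes the threshold series provably nested and excludes remote
# physiologic uptake islands. Volumes are voxel-count times voxel-volume.

#' Define a lesion volume of interest (VOI)
#'
#' An axis-aligned box in world mm, standing in for the operator's lesion
#' bounding box. The SUVmax search and delineation are restricted to it.
#'
#' @param lo,hi Numeric mm triples, lower and upper box corners.
#' @return An object of class `voi`.
#' @export
voi_box <- function(lo, hi) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  stopifnot(length(lo) == 3, length(hi) == 3)
  if (any(hi < lo)) abort("voi upper corner must be >= lower corner")
  structure(list(box = rbind(lo = lo, hi = hi)), class = "voi")
}

#' VOI covering the whole image domain
#'
#' @param image An `suv_image`.
#' @return A [voi_box()].
#' @export
voi_whole_image <- function(image) {
  ext <- grid_extent(image$grid)
  voi_box(ext["lo", ], ext["hi", ])
}

#' VOI from a registration region or binary mask
#'
#' @param x A `registration_region` or `binary_mask`.
#' @param margin_mm Margin added on every side, mm.
#' @return A [voi_box()].
#' @export
as_voi <- function(x, margin_mm = 0) {
  if (inherits(x, "voi")) return(x)
  if (inherits(x, "registration_region"))
    return(voi_box(x$box["lo", ] - margin_mm, x$box["hi", ] + margin_mm))
  if (inherits(x, "binary_mask")) {
    hits <- which(x$membership)
    if (!length(hits)) abort("cannot build a VOI from an empty mask")
    ijk <- arrayInd(hits, x$grid$shape) - 1L
    lo <- index_to_world(x$grid, matrix(apply(ijk, 2, min), 1)) - margin_mm
    hi <- index_to_world(x$grid, matrix(apply(ijk, 2, max), 1)) + margin_mm
    return(voi_box(as.vector(lo), as.vector(hi)))
  }
  abort("cannot convert this object to a VOI")
}

voi_index_ranges <- function(grid, voi) {
  rng <- lapply(1:3, function(d) {
    lo <- ceiling((voi$box["lo", d] - grid$origin[d]) / grid$spacing[d] - 1e-9)
    hi <- floor((voi$box["hi", d] - grid$origin[d]) / grid$spacing[d] + 1e-9)
    lo <- max(0L, as.integer(lo)); hi <- min(grid$shape[d] - 1L, as.integer(hi))
    if (hi < lo) abort("VOI contains no voxel")
    lo:hi
  })
  rng
}

#' Locate the SUVmax voxel inside a VOI
#'
#' Ties are broken by the smallest linear (column-major, x-fastest) index.
#'
#' @param image An `suv_image`.
#' @param voi A [voi_box()] containing at least one voxel.
#' @return A list with `suvmax` and `index` (0-based voxel triple).
#' @export
find_suvmax <- function(image, voi = voi_whole_image(image)) {
  rng <- voi_index_ranges(image$grid, as_voi(voi))
  sub <- image$values[rng[[1]] + 1L, rng[[2]] + 1L, rng[[3]] + 1L, drop = FALSE]
  lin <- which.max(sub)   # first maximum in column-major order
  loc <- arrayInd(lin, dim(sub))
  idx <- c(rng[[1]][loc[1]], rng[[2]][loc[2]], rng[[3]][loc[3]])
  list(suvmax = sub[lin], index = idx)
}

# 26-connected component of `cand` containing `seed` (both logical arrays /
# index triple are in the sub-array frame), by iterative mask dilation
flood_fill_26 <- function(cand, seed) {
  d <- dim(cand)
  comp <- array(FALSE, dim = d)
  comp[seed[1], seed[2], seed[3]] <- TRUE
  pad <- function(a) {
    p <- array(FALSE, dim = d + 2L)
    p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- a
    p
  }
  repeat {
    p <- pad(comp)
    grown <- array(FALSE, dim = d)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      grown <- grown | p[(2:(d[1] + 1)) + dx, (2:(d[2] + 1)) + dy,
                         (2:(d[3] + 1)) + dz]
    }
    new_comp <- grown & cand
    if (sum(new_comp) == sum(comp)) break
    comp <- new_comp
  }
  comp
}

#' Delineate a metabolic sub-volume at a fraction of SUVmax
#'
#' @param image An `suv_image` (PET).
#' @param voi A [voi_box()]; the SUVmax reference and the mask are both
#'   restricted to it.
#' @param fraction Threshold as a proportion of SUVmax, in (0, 1].
#' @param label Sub-volume label (e.g. `"I40"`, `"R90"`).
#' @return An object of class `metabolic_subvolume`: the `binary_mask`, the
#'   `label` and `fraction`, the reference `suvmax`, and the derived scalars
#'   `n_voxels`, `mtv_cc`, `suv_mean`, and `tlg` (MTV x SUVmean, populated
#'   only for 40% masks, `NA` otherwise).
#' @export
delineate <- function(image, voi, fraction, label = sprintf("M%.0f", fraction * 100)) {
  if (!(fraction > 0 && fraction <= 1)) abort("fraction must be in (0, 1]")
  voi <- as_voi(voi)
  peak <- find_suvmax(image, voi)
  rng <- voi_index_ranges(image$grid, voi)
  sub <- image$values[rng[[1]] + 1L, rng[[2]] + 1L, rng[[3]] + 1L, drop = FALSE]
  cand <- sub >= fraction * peak$suvmax
  seed <- c(match(peak$index[1], rng[[1]]), match(peak$index[2], rng[[2]]),
            match(peak$index[3], rng[[3]]))
  comp <- flood_fill_26(cand, seed)
  full <- array(FALSE, dim = image$grid$shape)
  full[rng[[1]] + 1L, rng[[2]] + 1L, rng[[3]] + 1L] <- comp
  mask <- binary_mask(full, image$grid)
  n_vox <- sum(comp)
  suv_mean <- mean(sub[comp])
  mtv <- n_vox * voxel_volume_cc(image$grid)
  structure(list(mask = mask, label = label, fraction = fraction,
                 suvmax = peak$suvmax, suvmax_index = peak$index,
                 n_voxels = n_vox, mtv_cc = mtv, suv_mean = suv_mean,
                 tlg = if (abs(fraction - 0.40) < 1e-9) mtv * suv_mean else NA_real_),
            class = "metabolic_subvolume")
}

#' @export
print.metabolic_subvolume <- function(x, ...) {
  cat(sprintf("<metabolic_subvolume> %s (%.0f%% of SUVmax %.2f): %d voxels, MTV %.3f cc, SUVmean %.2f\n",
              x$label, x$fraction * 100, x$suvmax, x$n_voxels, x$mtv_cc,
              x$suv_mean))
  invisible(x)
}

#' Delineate the full baseline threshold series
#'
#' Applies [delineate()] at every fraction (default 30% to 90% in steps of
#' 10%), sharing one SUVmax reference; the resulting masks are nested
#' (higher fractions are subsets of lower ones).
#'
#' @inheritParams delineate
#' @param fractions Threshold fractions (default `seq(0.3, 0.9, 0.1)`).
#' @param prefix Label prefix: `"I"` for baseline, `"R"` for follow-up.
#' @return A named list of `metabolic_subvolume`s (e.g. `I30` ... `I90`).
#' @export
delineate_series <- function(image, voi, fractions = seq(0.3, 0.9, by = 0.1),
                             prefix = "I") {
  labels <- sprintf("%s%.0f", prefix, fractions * 100)
  out <- lapply(seq_along(fractions), function(i) {
    delineate(image, voi, fractions[i], labels[i])
  })
  setNames(out, labels)
}

#' Total lesion glycolysis of a 40% sub-volume
#'
#' TLG is the metabolic tumor volume at 40% of SUVmax multiplied by the
#' SUVmean over that same volume.
#'
#' @param image The `suv_image` the sub-volume was delineated on.
#' @param mask40 A `metabolic_subvolume` with fraction 0.40.
#' @return TLG in SUV times cm^3 (0 for an empty mask).
#' @export
tlg <- function(image, mask40) {
  stopifnot(inherits(mask40, "metabolic_subvolume"))
  if (abs(mask40$fraction - 0.40) > 1e-9)
    abort("TLG is defined on the 40% sub-volume")
  if (mask40$n_voxels == 0) return(0)
  vals <- image$values[mask40$mask$membership]
  mask40$mtv_cc * mean(vals)
}

#' Tabulate a set of metabolic sub-volumes
#'
#' @param subvolumes A list of `metabolic_subvolume`s (e.g. a
#'   [delineate_series()] result).
#' @return A tibble with one row per sub-volume: `label`, `fraction`,
#'   `suvmax`, `n_voxels`, `mtv_cc`, `suv_mean`, `tlg`.
#' @export
subvolume_table <- function(subvolumes) {
  purrr::map_dfr(subvolumes, function(s) {
    tibble::tibble(label = s$label, fraction = s$fraction, suvmax = s$suvmax,
                   n_voxels = s$n_voxels, mtv_cc = s$mtv_cc,
                   suv_mean = s$suv_mean, tlg = s$tlg)
  })
}
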