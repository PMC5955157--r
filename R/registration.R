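# Longitudinal rigid registration: the follow-up scan pair is aligned onto
# the baseline pair by maximizing the mutual information of the two
# anatomical volumes inside a region of interest derived from the baseline
# PET (high-uptake region plus a margin), and the estimated transform is
# then applied to the follow-up PET. The baseline scan is always the
# reference image.

#' Derive the anatomical registration region from a baseline PET
#'
#' The axis-aligned bounding box of all voxels with SUV at or above
#' `fraction` times the global SUVmax, expanded by `margin_mm` on every side
#' and clipped to the image domain. A `fraction` of 0 yields the whole
#' domain.
#'
#' @param baseline_pet An `suv_image` (PET) with at least one positive voxel.
#' @param fraction Proportion of global SUVmax defining "high uptake"
#'   (default 0.30).
#' @param margin_mm Margin added to the box on each side, mm (default 40).
#' @return An object of class `registration_region` holding a 2 x 3 `box`
#'   matrix (rows `lo`, `hi`) in world mm.
#' @export
derive_region <- function(baseline_pet, fraction = 0.30, margin_mm = 40) {
  stopifnot(inherits(baseline_pet, "suv_image"))
  if (max(baseline_pet$values) <= 0)
    abort("PET image must have a voxel > 0")
  ext <- grid_extent(baseline_pet$grid)
  if (fraction <= 0) {
    box <- ext
  } else {
    thr <- fraction * max(baseline_pet$values)
    hits <- which(baseline_pet$values >= thr)
    if (!length(hits)) abort("no voxels at or above the threshold")
    ijk <- arrayInd(hits, baseline_pet$grid$shape) - 1L
    w_lo <- index_to_world(baseline_pet$grid, matrix(apply(ijk, 2, min), 1))
    w_hi <- index_to_world(baseline_pet$grid, matrix(apply(ijk, 2, max), 1))
    box <- rbind(lo = pmax(as.vector(w_lo) - margin_mm, ext["lo", ]),
                 hi = pmin(as.vector(w_hi) + margin_mm, ext["hi", ]))
  }
  structure(list(box = box), class = "registration_region")
}

#' @export
print.registration_region <- function(x, ...) {
  cat(sprintf("<registration_region> x [%g, %g], y [%g, %g], z [%g, %g] mm\n",
              x$box[1, 1], x$box[2, 1], x$box[1, 2], x$box[2, 2],
              x$box[1, 3], x$box[2, 3]))
  invisible(x)
}

# 0-based index ranges (list of three integer vectors) of voxel centers
# inside the region, optionally strided
region_index_ranges <- function(grid, region, stride = 1L) {
  lapply(1:3, function(d) {
    lo <- ceiling((region$box["lo", d] - grid$origin[d]) / grid$spacing[d] - 1e-9)
    hi <- floor((region$box["hi", d] - grid$origin[d]) / grid$spacing[d] + 1e-9)
    lo <- max(0L, as.integer(lo)); hi <- min(grid$shape[d] - 1L, as.integer(hi))
    if (hi < lo) abort("region does not intersect the image domain")
    seq(lo, hi, by = stride)
  })
}

region_points <- function(grid, region, stride = 1L) {
  rng <- region_index_ranges(grid, region, stride)
  n1 <- length(rng[[1]]); n2 <- length(rng[[2]]); n3 <- length(rng[[3]])
  idx <- cbind(rep(rng[[1]], times = n2 * n3),
               rep(rep(rng[[2]], each = n1), times = n3),
               rep(rng[[3]], each = n1 * n2))
  index_to_world(grid, idx)
}

mi_from_joint <- function(h) {
  n <- sum(h)
  if (n == 0) return(0)
  p <- h / n
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  outer_p <- outer(px, py)
  sum(p[nz] * log(p[nz] / outer_p[nz]))
}

# binning range: percentile-clipped per image (standard windowed MI binning)
mi_range <- function(v, probs = c(0.01, 0.99)) {
  r <- as.numeric(quantile(v, probs, names = FALSE, type = 7))
  if (r[2] <= r[1]) r <- range(v)
  r
}

#' Mutual information of two images inside a region
#'
#' Shannon mutual information in nats, estimated from a `bins x bins` joint
#' histogram of paired voxel values inside the region. The histogram range
#' is clipped to each image's 1st-99th percentile (within the region) and
#' values are clamped into range.
#'
#' @param fixed,moving `suv_image`s sampled on the same grid.
#' @param region A [derive_region()] result, or `NULL` for the whole domain.
#' @param bins Number of histogram bins per image (default 32, >= 2).
#' @return Mutual information in nats (>= 0).
#' @export
mutual_information <- function(fixed, moving, region = NULL, bins = 32) {
  stopifnot(inherits(fixed, "suv_image"), inherits(moving, "suv_image"))
  if (!same_grid(fixed$grid, moving$grid))
    abort("fixed and moving must be sampled on the same grid")
  if (bins < 2) abort("bins must be >= 2")
  if (is.null(region)) region <- structure(list(box = grid_extent(fixed$grid)),
                                           class = "registration_region")
  rng <- region_index_ranges(fixed$grid, region)
  a <- as.numeric(fixed$values[rng[[1]] + 1L, rng[[2]] + 1L, rng[[3]] + 1L])
  b <- as.numeric(moving$values[rng[[1]] + 1L, rng[[2]] + 1L, rng[[3]] + 1L])
  if (length(a) < bins^2 / 4)
    warn(sprintf("region has %d voxels; MI estimate with %d^2 bins is unstable",
                 length(a), bins))
  ra <- mi_range(a); rb <- mi_range(b)
  if (ra[2] <= ra[1] || rb[2] <= rb[1]) return(0)  # constant image: zero entropy
  h <- c_joint_hist(a, b, as.integer(bins), ra[1], ra[2], rb[1], rb[2])
  max(0, mi_from_joint(h))
}

# negative MI cost over fixed sample points; binning ranges are frozen
# across optimizer iterations so the cost surface stays coherent
make_mi_cost <- function(fixed_vals, pts, moving, bins, center, ra, rb,
                         lock_rotation = FALSE) {
  mvals <- as.numeric(moving$values)
  mshape <- moving$grid$shape
  force(pts); force(fixed_vals)
  function(par) {
    tf <- if (lock_rotation) rigid_transform(par[1:3], c(0, 0, 0), center)
          else rigid_transform(par[1:3], par[4:6], center)
    idx <- world_to_index(moving$grid, transform_points(tf, pts))
    b <- c_sample_trilinear(mvals, mshape, idx, NA_real_)
    inside <- !is.na(b)
    if (mean(inside) < 0.5) return(10)  # severe misoverlap penalty
    h <- c_joint_hist(fixed_vals[inside], b[inside], as.integer(bins),
                      ra[1], ra[2], rb[1], rb[2])
    -mi_from_joint(h)
  }
}

#' Estimate the rigid transform aligning a follow-up scan onto a baseline
#'
#' Maximizes the mutual information of the two anatomical volumes over the
#' six rigid parameters (translations in mm, Z-Y-X Euler rotations in
#' degrees about the fixed-image center), restricted to a PET-derived
#' region of the baseline scan. Optimization is multi-resolution
#' (strided subsampling, then full resolution) with derivative-free
#' Nelder-Mead at each level, initialized from center-of-mass alignment.
#' Deterministic given its inputs.
#'
#' @param fixed_anat Baseline anatomical `suv_image` (the reference).
#' @param moving_anat Follow-up anatomical `suv_image`.
#' @param region A [derive_region()] box on the baseline scan; `NULL` for
#'   the whole domain.
#' @param bins Histogram bins for the MI estimate (default 32).
#' @param levels Resolution levels: strides used per level
#'   (default `c(3, 1)`).
#' @param max_iter Nelder-Mead iteration cap per level (default 1000).
#' @param lock_rotation If `TRUE`, optimize translation only.
#' @param init Optional `rigid_transform` initial guess; default is
#'   center-of-mass translation alignment.
#' @return A list of class `rigid_registration` with elements `transform`
#'   (the estimated [rigid_transform()]), `mi` (final mutual information,
#'   nats), `converged` (logical; non-convergence is flagged, not an
#'   error), and `evaluations`.
#' @export
register_rigid <- function(fixed_anat, moving_anat, region = NULL, bins = 32,
                           levels = c(3, 1), max_iter = 1000,
                           lock_rotation = FALSE, init = NULL) {
  stopifnot(inherits(fixed_anat, "suv_image"), inherits(moving_anat, "suv_image"))
  center <- as.vector(colMeans(grid_extent(fixed_anat$grid)))
  if (is.null(region))
    region <- structure(list(box = grid_extent(fixed_anat$grid)),
                        class = "registration_region")

  com <- function(img) {
    w <- pmax(img$values - min(img$values), 0)
    pts <- grid_coords(img$grid)
    as.vector(colSums(pts * as.numeric(w)) / sum(w))
  }
  t0 <- if (is.null(init)) com(moving_anat) - com(fixed_anat) else init$translation
  r0 <- if (is.null(init)) c(0, 0, 0) else init$rotation

  # frozen binning ranges: fixed from region values, moving from whole image
  rng <- region_index_ranges(fixed_anat$grid, region)
  fvals_full <- as.numeric(fixed_anat$values[rng[[1]] + 1L, rng[[2]] + 1L, rng[[3]] + 1L])
  ra <- mi_range(fvals_full)
  rb <- mi_range(as.numeric(moving_anat$values))

  par <- if (lock_rotation) t0 else c(t0, r0)
  converged <- TRUE
  evals <- 0L
  for (li in seq_along(levels)) {
    stride <- levels[li]
    pts <- region_points(fixed_anat$grid, region, stride = stride)
    rngl <- region_index_ranges(fixed_anat$grid, region, stride = stride)
    fv <- as.numeric(fixed_anat$values[rngl[[1]] + 1L, rngl[[2]] + 1L, rngl[[3]] + 1L])
    cost <- make_mi_cost(fv, pts, moving_anat, bins, center, ra, rb, lock_rotation)
    scale <- if (lock_rotation) rep(1, 3) else c(1, 1, 1, 0.5, 0.5, 0.5)
    # final level: restart Nelder-Mead with a shrinking simplex for precision
    nstart <- if (li == length(levels)) 2L else 1L
    step <- if (li == 1) 2 else 0.5
    for (s in seq_len(nstart)) {
      fit <- optim(par, cost, method = "Nelder-Mead",
                   control = list(maxit = max_iter, reltol = 1e-8,
                                  parscale = scale * step))
      par <- fit$par
      evals <- evals + fit$counts[["function"]]
      if (fit$convergence != 0) converged <- FALSE
      step <- step / 5
    }
  }
  tf <- if (lock_rotation) rigid_transform(par, c(0, 0, 0), center)
        else rigid_transform(par[1:3], par[4:6], center)
  final_cost <- make_mi_cost(fvals_full, region_points(fixed_anat$grid, region),
                             moving_anat, bins, center, ra, rb, lock_rotation)
  structure(list(transform = tf, mi = -final_cost(if (lock_rotation) par else par),
                 converged = converged, evaluations = evals),
            class = "rigid_registration")
}

#' @export
print.rigid_registration <- function(x, ...) {
  cat(sprintf("<rigid_registration> MI = %.4f nats, %s (%d cost evaluations)\n",
              x$mi, if (x$converged) "converged" else "NOT converged",
              x$evaluations))
  print(x$transform)
  invisible(x)
}
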