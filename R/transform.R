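# Rigid (translation + rotation) transforms between scan coordinate frames.
#
# Convention, used everywhere in the package: a transform maps points from
# the *fixed* (reference/baseline) world frame into the *moving* (follow-up)
# world frame, so that resampling pulls moving-image values onto the fixed
# grid. Rotations are intrinsic Euler angles in degrees applied in Z-Y-X
# order about a fixed rotation center: T(p) = R (p - c) + c + t with
# R = Rz(rz) Ry(ry) Rx(rx).

euler_zyx_matrix <- function(rotation_deg) {
  r <- rotation_deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  rz %*% ry %*% rx
}

# inverse of euler_zyx_matrix: recover (rx, ry, rz) in degrees
euler_zyx_angles <- function(R) {
  # R = Rz Ry Rx => R[3,1] = -sin(ry)
  sy <- -R[3, 1]
  sy <- max(-1, min(1, sy))
  ry <- asin(sy)
  if (abs(sy) < 1 - 1e-10) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {
    # gimbal lock: fold everything into rx
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  }
  c(rx, ry, rz) * 180 / pi
}

#' Create a rigid transform
#'
#' Maps points from the fixed (baseline) frame to the moving (follow-up)
#' frame: `T(p) = R (p - center) + center + translation`, with `R` built from
#' intrinsic Z-Y-X Euler angles in degrees.
#'
#' @param translation Numeric triple, mm.
#' @param rotation Numeric triple `(rx, ry, rz)`, degrees.
#' @param center Numeric triple, rotation center in mm (conventionally the
#'   center of the fixed image).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  translation <- as.numeric(translation)
  rotation <- as.numeric(rotation)
  center <- as.numeric(center)
  stopifnot(length(translation) == 3, length(rotation) == 3, length(center) == 3)
  if (any(!is.finite(c(translation, rotation, center))))
    abort("transform parameters must be finite")
  structure(list(translation = translation, rotation = rotation,
                 center = center, convention = "euler_zyx_deg"),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> t = (%.3f, %.3f, %.3f) mm, r = (%.3f, %.3f, %.3f) deg, center (%g, %g, %g) mm\n",
              x$translation[1], x$translation[2], x$translation[3],
              x$rotation[1], x$rotation[2], x$rotation[3],
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' Is a transform (numerically) the identity?
#'
#' @param transform A [rigid_transform()].
#' @param tol_mm,tol_deg Tolerances on translation (mm) and rotation (deg).
#' @return Logical.
#' @export
is_identity_transform <- function(transform, tol_mm = 1e-9, tol_deg = 1e-9) {
  all(abs(transform$translation) <= tol_mm) &&
    all(abs(transform$rotation) <= tol_deg)
}

transform_matrix <- function(transform) {
  R <- euler_zyx_matrix(transform$rotation)
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- transform$center + transform$translation - R %*% transform$center
  m
}

matrix_to_transform <- function(m, center) {
  R <- m[1:3, 1:3]
  rotation <- euler_zyx_angles(R)
  translation <- m[1:3, 4] - center + as.vector(R %*% center)
  rigid_transform(translation, rotation, center)
}

#' Apply a rigid transform to points
#'
#' @param transform A [rigid_transform()].
#' @param pts An `n x 3` matrix of world coordinates (mm).
#' @return An `n x 3` matrix of transformed coordinates.
#' @export
transform_points <- function(transform, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  R <- euler_zyx_matrix(transform$rotation)
  offset <- transform$center + transform$translation -
    as.vector(R %*% transform$center)
  sweep(pts %*% t(R), 2, offset, "+")
}

#' Invert a rigid transform
#'
#' The inverse keeps the same rotation center; composing a transform with
#' its inverse yields the identity to machine precision.
#'
#' @param transform A [rigid_transform()].
#' @return A `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  matrix_to_transform(solve(transform_matrix(transform)), transform$center)
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `second` after `first`:
#' `T(p) = second(first(p))`. The result keeps `first`'s rotation center.
#'
#' @param first,second [rigid_transform()] objects.
#' @return A `rigid_transform`.
#' @export
compose_transforms <- function(first, second) {
  matrix_to_transform(transform_matrix(second) %*% transform_matrix(first),
                      first$center)
}

#' Serialize a rigid transform to JSON
#'
#' @param transform A [rigid_transform()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(
    list(translation_mm = transform$translation,
         rotation_deg = transform$rotation,
         center_mm = transform$center,
         convention = transform$convention),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a rigid transform from JSON
#'
#' @param path Path to a transform JSON written by [write_transform()].
#' @return A `rigid_transform`.
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$convention, "euler_zyx_deg"))
    abort(sprintf("unsupported transform convention: %s", x$convention))
  rigid_transform(x$translation_mm, x$rotation_deg, x$center_mm)
}

#' Resample an image or mask through a rigid transform
#'
#' Pull-resampling: for each voxel center `p` of `target_grid`, the output
#' takes the value of `image` at `transform(p)`. SUV images should use
#' trilinear interpolation (output bounded by the input range); masks use
#' nearest-neighbor to stay binary. Out-of-domain voxels are filled with 0.
#'
#' @param image An `suv_image` or `binary_mask`.
#' @param transform A [rigid_transform()] mapping target (fixed) world
#'   coordinates into the image's (moving) world frame.
#' @param target_grid The [volume_grid()] to sample onto.
#' @param interpolation `"trilinear"` or `"nearest"` (masks are always
#'   nearest).
#' @return The resampled `suv_image` or `binary_mask` on `target_grid`.
#' @export
apply_rigid <- function(image, transform, target_grid,
                        interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  is_mask <- inherits(image, "binary_mask")
  if (is_mask) interpolation <- "nearest"
  src_grid <- image$grid
  vals <- if (is_mask) array(as.numeric(image$membership), dim = src_grid$shape)
          else image$values
  pts <- grid_coords(target_grid)
  idx <- world_to_index(src_grid, transform_points(transform, pts))
  out <- if (interpolation == "trilinear") {
    c_sample_trilinear(as.numeric(vals), src_grid$shape, idx, 0)
  } else {
    c_sample_nearest(as.numeric(vals), src_grid$shape, idx, 0)
  }
  arr <- array(out, dim = target_grid$shape)
  if (is_mask) {
    binary_mask(arr > 0.5, target_grid)
  } else {
    suv_image(arr, target_grid, modality = image$modality)
  }
}
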