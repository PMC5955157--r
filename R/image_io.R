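#' @useDynLib petsubvol, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom rlang abort warn .data
#' @importFrom stats median optim pchisq pnorm pwilcox quantile rnorm runif sd setNames
#' @importFrom utils head
NULL

# ---- metric grid -----------------------------------------------------------

#' Define a metric voxel grid
#'
#' A `volume_grid` fixes the geometry every image, mask and transform in the
#' package refers to: the number of voxels per axis, the voxel spacing in mm,
#' and the world position (mm) of the *center* of voxel index `(0, 0, 0)`.
#' Voxel indexing is 0-based and the axis order is a fixed right-handed
#' (x, y, z) with x varying fastest, matching R's column-major array layout.
#'
#' @param shape Integer triple, voxels per axis (each >= 1).
#' @param spacing Numeric triple, voxel spacing in mm (each > 0).
#' @param origin Numeric triple, world coordinate (mm) of the center of voxel
#'   `(0, 0, 0)`.
#' @return An object of class `volume_grid`.
#' @examples
#' g <- volume_grid(c(64, 64, 64), spacing = c(4, 4, 4), origin = c(-126, -126, -126))
#' voxel_volume_cc(g) # 0.064 cc per 4 mm isotropic voxel
#' @export
volume_grid <- function(shape, spacing = c(4, 4, 4), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || length(spacing) != 3L || length(origin) != 3L)
    abort("shape, spacing and origin must all have length 3")
  if (any(shape < 1L)) abort("all shape entries must be >= 1")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    abort("all spacings must be strictly positive")
  if (any(!is.finite(origin))) abort("origin must be finite")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %d x %d x %d voxels, spacing %g x %g x %g mm, origin (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Voxel volume of a grid
#'
#' @param grid A [volume_grid()].
#' @return Volume of one voxel in cm^3 (`voxel_volume_cc`) or mm^3
#'   (`voxel_volume_mm3`).
#' @export
voxel_volume_cc <- function(grid) prod(grid$spacing) / 1000

#' @rdname voxel_volume_cc
#' @export
voxel_volume_mm3 <- function(grid) prod(grid$spacing)

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

# world <-> continuous 0-based voxel index; pts is an n x 3 matrix
world_to_index <- function(grid, pts) {
  sweep(sweep(pts, 2, grid$origin, "-"), 2, grid$spacing, "/")
}

index_to_world <- function(grid, idx) {
  sweep(sweep(idx, 2, grid$spacing, "*"), 2, grid$origin, "+")
}

# world coordinates of every voxel center, as an n x 3 matrix in array order
grid_coords <- function(grid, stride = 1L) {
  ax <- lapply(1:3, function(d) {
    grid$origin[d] + grid$spacing[d] * seq(0L, grid$shape[d] - 1L, by = stride)
  })
  n1 <- length(ax[[1]]); n2 <- length(ax[[2]]); n3 <- length(ax[[3]])
  cbind(rep(ax[[1]], times = n2 * n3),
        rep(rep(ax[[2]], each = n1), times = n3),
        rep(ax[[3]], each = n1 * n2))
}

# extent of voxel centers per axis: 2 x 3 matrix (lo; hi)
grid_extent <- function(grid) {
  hi <- grid$origin + grid$spacing * (grid$shape - 1L)
  rbind(lo = grid$origin, hi = hi)
}

# ---- images and masks ------------------------------------------------------

#' Construct an SUV (or anatomical) image on a metric grid
#'
#' @param values 3-D numeric array whose dimensions equal `grid$shape`. PET
#'   images hold standardized uptake values (unitless, body-weight
#'   normalized); anatomical images hold CT-like arbitrary units.
#' @param grid A [volume_grid()].
#' @param modality `"PET"` or `"ANAT"`. PET values must be finite and >= 0;
#'   anatomical values must be finite.
#' @return An object of class `suv_image`.
#' @export
suv_image <- function(values, grid, modality = c("PET", "ANAT")) {
  modality <- match.arg(modality)
  if (!is.array(values) || length(dim(values)) != 3L)
    abort("values must be a 3-D array")
  if (!identical(as.integer(dim(values)), grid$shape))
    abort("value array shape must equal grid shape")
  bad <- which(!is.finite(values))
  if (length(bad)) {
    idx <- arrayInd(bad[1], dim(values)) - 1L
    abort(sprintf("non-finite voxel at 0-based index (%d, %d, %d)",
                  idx[1], idx[2], idx[3]))
  }
  if (modality == "PET" && any(values < 0))
    abort("PET values must be >= 0")
  structure(list(values = values, grid = grid, modality = modality),
            class = "suv_image")
}

#' @export
print.suv_image <- function(x, ...) {
  cat(sprintf("<suv_image> %s, range [%.3g, %.3g]\n", x$modality,
              min(x$values), max(x$values)))
  print(x$grid)
  invisible(x)
}

#' Construct a binary voxel mask on a metric grid
#'
#' @param membership Logical (or 0/1 numeric) 3-D array matching `grid$shape`.
#' @param grid A [volume_grid()].
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(membership, grid) {
  if (!is.array(membership) || length(dim(membership)) != 3L)
    abort("membership must be a 3-D array")
  if (!identical(as.integer(dim(membership)), grid$shape))
    abort("mask shape must equal grid shape")
  membership <- array(as.logical(membership), dim = dim(membership))
  if (any(is.na(membership))) abort("mask membership must not contain NA")
  structure(list(membership = membership, grid = grid), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d voxels, %.3f cc\n", sum(x$membership),
              mask_volume_cc(x)))
  invisible(x)
}

#' Volume of a binary mask in cm^3
#'
#' Voxel-count times voxel-volume; no partial-volume surface correction.
#'
#' @param mask A [binary_mask()].
#' @return Volume in cm^3.
#' @export
mask_volume_cc <- function(mask) sum(mask$membership) * voxel_volume_cc(mask$grid)

# ---- NIfTI I/O -------------------------------------------------------------

grid_affine <- function(grid) {
  aff <- diag(c(grid$spacing, 1))
  aff[1:3, 4] <- grid$origin
  aff
}

#' Read an SUV volume or mask from a NIfTI-1 file
#'
#' Only 3-D scalar volumes on axis-aligned grids (diagonal affine with
#' positive spacings) are supported; the grid spacing and origin are taken
#' from the NIfTI qform/sform affine. DICOM ingestion and SUV computation
#' from injected dose are out of scope: PET inputs are expected to be
#' SUV-valued already.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param modality `"PET"` or `"ANAT"` (see [suv_image()]).
#' @return An `suv_image`.
#' @export
read_volume <- function(path, modality = c("PET", "ANAT")) {
  modality <- match.arg(modality)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    abort(sprintf("expected a 3-D volume, got %d dimensions", length(dim(arr))))
  aff <- RNifti::xform(img)
  rot <- aff[1:3, 1:3]
  if (max(abs(rot - diag(diag(rot)))) > 1e-4)
    abort("only axis-aligned (diagonal-affine) NIfTI volumes are supported")
  spacing <- diag(rot)
  if (any(spacing <= 0))
    abort("only positive-spacing (RAS-aligned) NIfTI volumes are supported")
  grid <- volume_grid(dim(arr), spacing, aff[1:3, 4])
  suv_image(array(as.numeric(arr), dim = dim(arr)), grid, modality)
}

#' Read a binary mask from a NIfTI-1 file
#'
#' Voxels with value > 0.5 become members.
#'
#' @inheritParams read_volume
#' @return A `binary_mask`.
#' @export
read_mask <- function(path) {
  img <- read_volume(path, modality = "ANAT")
  binary_mask(img$values > 0.5, img$grid)
}

#' Write an SUV volume or binary mask to a NIfTI-1 file
#'
#' Images are stored as float32 with the grid encoded in the qform/sform
#' affine; masks are stored as 0/1 unsigned bytes.
#'
#' @param x An `suv_image` or `binary_mask`.
#' @param path Output path (`.nii` or `.nii.gz`); the parent directory must
#'   exist.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(x, path) {
  if (!dir.exists(dirname(path)))
    abort(sprintf("parent directory does not exist: %s", dirname(path)))
  if (inherits(x, "binary_mask")) {
    arr <- array(as.integer(x$membership), dim = dim(x$membership))
    grid <- x$grid
    dtype <- "uint8"
  } else if (inherits(x, "suv_image")) {
    arr <- x$values
    grid <- x$grid
    dtype <- "float"
  } else {
    abort("x must be an suv_image or binary_mask")
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- grid$spacing
  RNifti::qform(img) <- structure(grid_affine(grid), code = 2L)
  RNifti::sform(img) <- structure(grid_affine(grid), code = 2L)
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}
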