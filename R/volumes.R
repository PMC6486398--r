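#' Parametric volume container
#'
#' A `parametric_volume` holds one co-registered 3D scalar map (ADC, rCBV,
#' the diffusion-tensor p or q component, or any other modality) together
#' with its voxel dimensions in mm and the voxel-to-world affine.
#'
#' @param data 3D numeric array.
#' @param voxel_dims Numeric length-3 vector of voxel edge lengths in mm,
#'   all strictly positive.
#' @param modality One of `"ADC"`, `"rCBV"`, `"p"`, `"q"`, `"other"`.
#' @param affine 4x4 voxel-to-world matrix. Defaults to a diagonal scaling
#'   by `voxel_dims`.
#' @return An object of class `parametric_volume` with fields `data`,
#'   `voxel_dims`, `modality`, `affine`.
#' @export
parametric_volume <- function(data, voxel_dims = c(1, 1, 1),
                              modality = c("other", "ADC", "rCBV", "p", "q"),
                              affine = NULL) {
  modality <- match.arg(modality)
  if (length(dim(data)) != 3L) {
    stop("`data` must be a 3D array, got ", length(dim(data)), " dimensions.",
         call. = FALSE)
  }
  voxel_dims <- as.numeric(voxel_dims)
  if (length(voxel_dims) != 3L || any(!is.finite(voxel_dims)) ||
      any(voxel_dims <= 0)) {
    stop("`voxel_dims` must be 3 strictly positive finite numbers.",
         call. = FALSE)
  }
  if (is.null(affine)) {
    affine <- diag(c(voxel_dims, 1))
  }
  structure(
    list(data = array(as.double(data), dim(data)),
         voxel_dims = voxel_dims, modality = modality, affine = affine),
    class = "parametric_volume"
  )
}

#' @export
print.parametric_volume <- function(x, ...) {
  cat("<parametric_volume> modality:", x$modality,
      " dim:", paste(dim(x$data), collapse = "x"),
      " voxel (mm):", paste(signif(x$voxel_dims, 4), collapse = "x"), "\n")
  invisible(x)
}

#' Binary region-of-interest mask
#'
#' A `roi_mask` is a binary mask on the same voxel grid as its companion
#' parametric volumes. Labels follow the habitat vocabulary: the
#' contrast-enhancing ROI (`CE`), FLAIR hyperintensity (`FLAIR`),
#' normal-appearing white matter (`NAWM`), the quartile masks
#' (`rCBV_L`, `ADC_L`, `ADC_H`), the two compartments
#' (`ADC_L-rCBV_L`, `ADC_H-rCBV_L`) and the contrast-enhancing control
#' (`CEC`).
#'
#' @param data 3D array coercible to logical (values 0/1 or TRUE/FALSE).
#' @param label Mask label string.
#' @param voxel_dims Voxel edge lengths in mm.
#' @param affine Optional 4x4 voxel-to-world matrix.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(data, label = "other", voxel_dims = c(1, 1, 1),
                     affine = NULL) {
  if (length(dim(data)) != 3L) {
    stop("`data` must be a 3D array.", call. = FALSE)
  }
  vals <- as.vector(data)
  if (!is.logical(vals) && !all(vals %in% c(0, 1))) {
    stop("Mask values must be exactly 0/1 (or logical).", call. = FALSE)
  }
  voxel_dims <- as.numeric(voxel_dims)
  if (length(voxel_dims) != 3L || any(voxel_dims <= 0)) {
    stop("`voxel_dims` must be 3 strictly positive numbers.", call. = FALSE)
  }
  if (is.null(affine)) affine <- diag(c(voxel_dims, 1))
  structure(
    list(data = array(as.logical(data), dim(data)),
         label = label, voxel_dims = voxel_dims, affine = affine),
    class = "roi_mask"
  )
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("<roi_mask>", x$label, " dim:", paste(dim(x$data), collapse = "x"),
      " voxels:", sum(x$data), "\n")
  invisible(x)
}

grid_of <- function(x) {
  list(shape = dim(x$data), voxel_dims = x$voxel_dims)
}

#' Read a parametric volume from NIfTI
#'
#' Reads a NIfTI-1/2 file into a [parametric_volume]. Voxel dimensions come
#' from the header `pixdim` and the world affine from the sform/qform.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param modality Modality tag to attach.
#' @return A [parametric_volume].
#' @export
read_volume <- function(path, modality = "other") {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) {
    stop("Expected a 3D image, got ", length(dim(img)), "D: ", path,
         call. = FALSE)
  }
  aff <- unclass(RNifti::xform(img))
  code <- attr(aff, "code")
  vd <- if (!is.null(code) && code > 0) {
    sqrt(colSums(aff[1:3, 1:3]^2))     # voxel size from the world affine
  } else {
    abs(RNifti::pixdim(img))[1:3]
  }
  parametric_volume(as.array(img), voxel_dims = vd, modality = modality,
                    affine = aff)
}

#' Write a parametric volume to NIfTI
#'
#' @param vol A [parametric_volume] or [roi_mask]. Masks are written as
#'   unsigned 8-bit, parametric maps as 32-bit float.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  is_mask <- inherits(vol, "roi_mask")
  dat <- if (is_mask) array(as.integer(vol$data), dim(vol$data)) else vol$data
  img <- RNifti::asNifti(dat, datatype = if (is_mask) "uint8" else "float")
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary ROI mask from NIfTI
#'
#' Any strictly positive voxel is treated as inside the mask.
#'
#' @inheritParams read_volume
#' @param label Mask label to attach.
#' @return A [roi_mask].
#' @export
read_mask <- function(path, label = "other") {
  vol <- read_volume(path)
  roi_mask(vol$data > 0, label = label, voxel_dims = vol$voxel_dims,
           affine = vol$affine)
}

#' Check that volumes and masks share one voxel grid
#'
#' The pipeline assumes all inputs were co-registered upstream; it refuses
#' mixed grids rather than resampling. Shapes must be identical and voxel
#' dimensions must agree within `tol` mm.
#'
#' @param volumes List of [parametric_volume] / [roi_mask] objects.
#' @param tol Voxel-dimension tolerance in mm.
#' @return `TRUE` if all grids match, else `FALSE`.
#' @export
check_grid_compatibility <- function(volumes, tol = 1e-6) {
  stopifnot(length(volumes) >= 1L)
  ref <- grid_of(volumes[[1L]])
  for (v in volumes[-1L]) {
    g <- grid_of(v)
    if (length(g$shape) != length(ref$shape) ||
        any(g$shape != ref$shape)) return(FALSE)
    if (any(abs(g$voxel_dims - ref$voxel_dims) > tol)) return(FALSE)
  }
  TRUE
}

#' Normalize a parametric map by its NAWM mean
#'
#' Divides every voxel by the arithmetic mean of the map over the
#' normal-appearing white matter mask, yielding a dimensionless map whose
#' NAWM mean is exactly 1. ADC and rCBV maps are normalized this way before
#' any thresholding.
#'
#' @param map A [parametric_volume].
#' @param nawm A non-empty [roi_mask] on the same grid.
#' @return A [parametric_volume] with `modality` preserved and an attribute
#'   `nawm_mean` recording the divisor.
#' @export
normalize_by_nawm <- function(map, nawm) {
  if (!check_grid_compatibility(list(map, nawm))) {
    stop("`map` and `nawm` are not on the same voxel grid.", call. = FALSE)
  }
  if (!any(nawm$data)) stop("NAWM mask is empty.", call. = FALSE)
  vals <- map$data[nawm$data]
  if (any(!is.finite(vals))) {
    stop("Non-finite map values inside the NAWM mask.", call. = FALSE)
  }
  m <- mean(vals)
  if (m <= 0) stop("NAWM mean must be strictly positive, got ", m,
                   call. = FALSE)
  out <- parametric_volume(map$data / m, voxel_dims = map$voxel_dims,
                           modality = map$modality, affine = map$affine)
  attr(out, "nawm_mean") <- m
  attr(out, "normalized") <- TRUE
  out
}

#' Dice similarity coefficient of two masks
#'
#' `2|A intersect B| / (|A| + |B|)`; used for interrater mask agreement and
#' for phantom-recovery checks. Two empty masks are defined to agree
#' perfectly (score `empty_value`, default 1).
#'
#' @param a,b [roi_mask] objects on the same grid.
#' @param empty_value Score returned when both masks are empty.
#' @return Dice score in `[0, 1]`.
#' @export
dice <- function(a, b, empty_value = 1) {
  if (!check_grid_compatibility(list(a, b))) {
    stop("Masks are not on the same voxel grid.", call. = FALSE)
  }
  na <- sum(a$data); nb <- sum(b$data)
  if (na + nb == 0L) return(empty_value)
  2 * sum(a$data & b$data) / (na + nb)
}
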