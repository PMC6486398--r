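#' Isotropic (p) and anisotropic (q) diffusion-tensor components
#'
#' Decomposes the diffusion tensor voxelwise from its eigenvalues: with
#' mean diffusivity `MD = (l1 + l2 + l3) / 3`,
#' `p = sqrt(3) * MD` and
#' `q = sqrt((l1 - MD)^2 + (l2 - MD)^2 + (l3 - MD)^2)`.
#' Both carry the eigenvalue units (mm^2/s). `q` is zero exactly where the
#' tensor is isotropic and is invariant to eigenvalue permutation.
#'
#' Negative eigenvalues (noise) are clamped to 0 with a warning; non-finite
#' eigenvalues yield `NA` in both maps and are counted in attribute
#' `n_nonfinite`.
#'
#' @param l1,l2,l3 [parametric_volume]s (or plain 3D arrays) of the three
#'   principal diffusivities, any order.
#' @return List of two [parametric_volume]s `p` and `q`, with attributes
#'   `n_clamped` and `n_nonfinite`.
#' @export
compute_pq <- function(l1, l2, l3) {
  as_arr <- function(x) if (inherits(x, "parametric_volume")) x$data else x
  vd <- if (inherits(l1, "parametric_volume")) l1$voxel_dims else c(1, 1, 1)
  af <- if (inherits(l1, "parametric_volume")) l1$affine else NULL
  a1 <- as_arr(l1); a2 <- as_arr(l2); a3 <- as_arr(l3)
  stopifnot(all(dim(a1) == dim(a2)), all(dim(a1) == dim(a3)))

  bad <- !is.finite(a1) | !is.finite(a2) | !is.finite(a3)
  n_bad <- sum(bad)
  if (n_bad > 0) {
    a1[bad] <- NA_real_; a2[bad] <- NA_real_; a3[bad] <- NA_real_
  }
  n_clamped <- sum(a1 < 0, na.rm = TRUE) + sum(a2 < 0, na.rm = TRUE) +
    sum(a3 < 0, na.rm = TRUE)
  if (n_clamped > 0) {
    warning(n_clamped, " negative eigenvalues clamped to 0.", call. = FALSE)
    a1 <- pmax(a1, 0); a2 <- pmax(a2, 0); a3 <- pmax(a3, 0)
  }
  md <- (a1 + a2 + a3) / 3
  p <- sqrt(3) * md
  q <- sqrt((a1 - md)^2 + (a2 - md)^2 + (a3 - md)^2)
  out <- list(
    p = parametric_volume(p, voxel_dims = vd, modality = "p", affine = af),
    q = parametric_volume(q, voxel_dims = vd, modality = "q", affine = af)
  )
  attr(out, "n_clamped") <- n_clamped
  attr(out, "n_nonfinite") <- n_bad
  out
}

#' Derive p/q abnormality masks from a z-score rule
#'
#' Voxels whose map value exceeds the NAWM mean by more than `z` NAWM
#' standard deviations are flagged abnormal. This is a configurable
#' stand-in for externally supplied abnormality masks, which take
#' precedence when available.
#'
#' @param map A [parametric_volume] (p or q).
#' @param nawm NAWM [roi_mask].
#' @param z Z-score threshold (default 2).
#' @param within Optional [roi_mask] restricting where abnormality may be
#'   called (typically the FLAIR envelope plus CE); without it, the
#'   expected ~2% of normal voxels exceeding the z threshold by chance
#'   would dominate a maximum-distance margin.
#' @return A [roi_mask].
#' @export
abnormality_mask <- function(map, nawm, z = 2, within = NULL) {
  if (!any(nawm$data)) stop("NAWM mask is empty.", call. = FALSE)
  vals <- map$data[nawm$data]
  mu <- mean(vals); sdv <- stats::sd(vals)
  abn <- !is.na(map$data) & map$data > mu + z * sdv
  if (!is.null(within)) abn <- abn & within$data
  roi_mask(abn, label = paste0(map$modality, "_abnormal"),
           voxel_dims = map$voxel_dims, affine = map$affine)
}

# max distance (mm) from voxels of `mask` outside `ce` to the CE surface;
# brute force against CE boundary voxels, chunked to bound memory
max_margin_mm <- function(mask, ce, voxel_dims) {
  outside <- which(mask$data & !ce$data)
  if (length(outside) == 0L) return(0)
  d <- dim(ce$data)
  # CE boundary: CE voxels with at least one 6-neighbour outside CE
  cearr <- ce$data
  shift <- function(a, ax, by) {
    idx <- rep(list(quote(expr = )), 3)
    n <- dim(a)[ax]
    src <- if (by > 0) c(1L, 1:(n - 1L)) else c(2:n, n)
    idx[[ax]] <- src
    do.call(`[`, c(list(a), idx))
  }
  interior <- cearr
  for (ax in 1:3) {
    interior <- interior & shift(cearr, ax, 1L) & shift(cearr, ax, -1L)
  }
  boundary <- which(cearr & !interior)
  if (length(boundary) == 0L) boundary <- which(cearr)
  to_mm <- function(ind) {
    ijk <- arrayInd(ind, d)
    sweep(ijk, 2, voxel_dims, `*`)
  }
  b <- to_mm(boundary)
  o <- to_mm(outside)
  max_min <- 0
  chunk <- max(1L, floor(5e6 / nrow(b)))
  for (s in seq(1L, nrow(o), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(o))
    oc <- o[s:e, , drop = FALSE]
    # squared distances outside-chunk x boundary
    d2 <- outer(rowSums(oc^2), rowSums(b^2), `+`) - 2 * tcrossprod(oc, b)
    rowmin <- d2[cbind(seq_len(nrow(d2)), max.col(-d2, "first"))]
    max_min <- max(max_min, sqrt(pmax(rowmin, 0)))
  }
  max_min
}

#' Maximal extent of p/q abnormality beyond the CE boundary
#'
#' For each abnormality mask, the maximum Euclidean distance (mm) from an
#' abnormal voxel outside CE to the CE surface; 0 when the abnormality is
#' contained in CE.
#'
#' @param p_abnormal,q_abnormal Abnormality [roi_mask]s.
#' @param ce Non-empty CE [roi_mask] on the same grid.
#' @param voxel_dims Voxel dimensions in mm; defaults to the CE mask's.
#' @return A one-row tibble with `p_margin_mm`, `q_margin_mm`.
#' @export
abnormality_margins <- function(p_abnormal, q_abnormal, ce,
                                voxel_dims = ce$voxel_dims) {
  if (!check_grid_compatibility(list(p_abnormal, q_abnormal, ce))) {
    stop("Masks are not on one voxel grid.", call. = FALSE)
  }
  if (!any(ce$data)) stop("CE mask is empty.", call. = FALSE)
  tibble::tibble(
    p_margin_mm = max_margin_mm(p_abnormal, ce, voxel_dims),
    q_margin_mm = max_margin_mm(q_abnormal, ce, voxel_dims)
  )
}

#' Classify the DTI invasive phenotype
#'
#' Three phenotypes are distinguished from how far the isotropic (p) and
#' anisotropic (q) abnormalities extend beyond the contrast-enhancing
#' boundary: *minimal* when both margins stay below `t_min`; *diffuse*
#' when the p abnormality outruns the q abnormality by more than `t_diff`
#' (isotropic spread without matching anisotropic change); *localized*
#' otherwise. The defaults are provisional package defaults — the original
#' classification criteria live in prior work and externally assigned
#' labels should be preferred when available (pass them through the cohort
#' table instead).
#'
#' @param p_margin,q_margin Margins in mm (see [abnormality_margins()]).
#' @param t_min Margin below which invasion is called minimal (mm).
#' @param t_diff Excess of p over q margin that defines diffuse invasion
#'   (mm).
#' @return A one-row tibble with `phenotype` (factor: minimal, localized,
#'   diffuse), `p_margin_mm`, `q_margin_mm`.
#' @export
classify_phenotype <- function(p_margin, q_margin, t_min = 10, t_diff = 10) {
  stopifnot(p_margin >= 0, q_margin >= 0)
  label <- if (p_margin < t_min && q_margin < t_min) {
    "minimal"
  } else if (p_margin - q_margin > t_diff) {
    "diffuse"
  } else {
    "localized"
  }
  tibble::tibble(
    phenotype = factor(label, levels = c("minimal", "localized", "diffuse")),
    p_margin_mm = p_margin, q_margin_mm = q_margin
  )
}
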