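#' Pooled quartile thresholds within an ROI
#'
#' Pools the voxel values of a (normalized) map inside an ROI — in the
#' habitat pipeline, the contrast-enhancing (CE) region — and returns the
#' 25th and 75th percentiles. The linear-interpolation quantile definition
#' (`stats::quantile` type 7) is used by default.
#'
#' @param map A [parametric_volume] (normalized to NAWM upstream).
#' @param roi Non-empty [roi_mask] on the same grid.
#' @param type Quantile definition passed to [stats::quantile()].
#' @return A one-row tibble with columns `source`, `q1`, `q3`, `n_voxels`.
#' @export
pooled_quartiles <- function(map, roi, type = 7) {
  if (!check_grid_compatibility(list(map, roi))) {
    stop("`map` and `roi` are not on the same voxel grid.", call. = FALSE)
  }
  if (!any(roi$data)) stop("ROI is empty; cannot pool quartiles.",
                           call. = FALSE)
  vals <- map$data[roi$data]
  if (any(!is.finite(vals))) {
    stop("Non-finite map values inside the ROI.", call. = FALSE)
  }
  q <- stats::quantile(vals, probs = c(0.25, 0.75), type = type,
                       names = FALSE)
  tibble::tibble(source = map$modality, q1 = q[1], q3 = q[2],
                 n_voxels = length(vals))
}

quartile_mask <- function(map, roi, threshold, op, label) {
  keep <- roi$data & op(map$data, threshold)
  ties <- sum(roi$data & (map$data == threshold))
  out <- roi_mask(keep, label = label, voxel_dims = roi$voxel_dims,
                  affine = roi$affine)
  attr(out, "n_ties") <- ties
  out
}

#' Lowest-quartile mask of a map within an ROI
#'
#' Voxels of the ROI whose value is at or below the 25th percentile
#' (`q1`). Applied to the normalized rCBV map this yields the low-perfusion
#' region `rCBV_L`; on ADC it yields the restricted-diffusivity `ADC_L`.
#' Threshold voxels (ties at `q1`) are included; the tie count is recorded
#' in attribute `n_ties`.
#'
#' @inheritParams pooled_quartiles
#' @param thresholds Tibble from [pooled_quartiles()] computed on the same
#'   map and ROI.
#' @param label Label for the resulting mask.
#' @return A [roi_mask] subset of `roi`.
#' @export
lowest_quartile_mask <- function(map, roi, thresholds, label = "low") {
  quartile_mask(map, roi, thresholds$q1, `<=`, label)
}

#' Highest-quartile mask of a map within an ROI
#'
#' Voxels of the ROI whose value is at or above the 75th percentile
#' (`q3`); on ADC this yields the elevated-diffusivity `ADC_H`.
#'
#' @inheritParams lowest_quartile_mask
#' @return A [roi_mask] subset of `roi`.
#' @export
highest_quartile_mask <- function(map, roi, thresholds, label = "high") {
  quartile_mask(map, roi, thresholds$q3, `>=`, label)
}

#' Intersect quartile masks into habitat compartments
#'
#' Builds the two low-perfusion compartments and the contrast-enhancing
#' control: `ADC_L-rCBV_L = ADC_L` ∩ `rCBV_L`, `ADC_H-rCBV_L = ADC_H` ∩
#' `rCBV_L`, and `CEC` = CE voxels in neither compartment. The three masks
#' partition CE exactly.
#'
#' @param rcbv_l,adc_l,adc_h Quartile [roi_mask]s, all subsets of `ce`.
#' @param ce The contrast-enhancing [roi_mask].
#' @return Named list of [roi_mask]s: `rCBV_L`, `ADC_L`, `ADC_H`,
#'   `ADC_L-rCBV_L`, `ADC_H-rCBV_L`, `CEC`.
#' @export
intersect_compartments <- function(rcbv_l, adc_l, adc_h, ce) {
  if (!check_grid_compatibility(list(rcbv_l, adc_l, adc_h, ce))) {
    stop("Masks are not on one voxel grid.", call. = FALSE)
  }
  for (m in list(rcbv_l, adc_l, adc_h)) {
    if (any(m$data & !ce$data)) {
      stop("Mask '", m$label, "' extends outside the CE ROI.", call. = FALSE)
    }
  }
  mk <- function(d, lab) roi_mask(d, label = lab,
                                  voxel_dims = ce$voxel_dims,
                                  affine = ce$affine)
  low  <- adc_l$data & rcbv_l$data
  high <- adc_h$data & rcbv_l$data
  cec  <- ce$data & !(low | high)
  list(
    "rCBV_L" = rcbv_l, "ADC_L" = adc_l, "ADC_H" = adc_h,
    "ADC_L-rCBV_L" = mk(low, "ADC_L-rCBV_L"),
    "ADC_H-rCBV_L" = mk(high, "ADC_H-rCBV_L"),
    "CEC" = mk(cec, "CEC")
  )
}

#' Absolute volume of a mask in cm^3
#'
#' @param mask A [roi_mask].
#' @param voxel_dims Optional voxel dimensions (mm); defaults to the mask's.
#' @return Volume in cm^3.
#' @export
mask_volume <- function(mask, voxel_dims = mask$voxel_dims) {
  sum(mask$data) * prod(voxel_dims) / 1000
}

#' Proportional volume of a compartment within CE
#'
#' `100 * |compartment| / |CE|`, in percent.
#'
#' @param compartment [roi_mask], subset of `ce`.
#' @param ce Non-empty contrast-enhancing [roi_mask].
#' @return Percentage in `[0, 100]`.
#' @export
proportional_volume <- function(compartment, ce) {
  if (!any(ce$data)) stop("CE mask is empty.", call. = FALSE)
  if (any(compartment$data & !ce$data)) {
    stop("Compartment extends outside CE.", call. = FALSE)
  }
  100 * sum(compartment$data) / sum(ce$data)
}

#' Segment the two low-perfusion habitat compartments
#'
#' Runs the full habitat pipeline for one subject: normalize ADC and rCBV
#' to the NAWM mean, pool values within CE, threshold at the pooled
#' quartiles (lowest rCBV quartile = low perfusion; lowest / highest ADC
#' quartiles = restricted / elevated diffusivity), intersect, and measure
#' absolute (cm^3) and proportional (% of CE) volumes.
#'
#' @param adc,rcbv [parametric_volume]s (raw; normalized internally).
#' @param ce,nawm [roi_mask]s on the same grid.
#' @param quantile_type Quantile definition (see [stats::quantile()]).
#' @param min_ce_voxels CE masks smaller than this are flagged (volumes are
#'   still computed).
#' @return An object of class `habitat_result`: list with `masks` (see
#'   [intersect_compartments()]), `thresholds` (tibble), `volumes` (tidy
#'   tibble of absolute and proportional volumes), `flags`.
#' @export
segment_habitats <- function(adc, rcbv, ce, nawm, quantile_type = 7,
                             min_ce_voxels = 64) {
  if (!check_grid_compatibility(list(adc, rcbv, ce, nawm))) {
    stop("Inputs are not on one voxel grid; the pipeline does not resample.",
         call. = FALSE)
  }
  if (!any(ce$data)) stop("CE mask is empty.", call. = FALSE)
  flags <- character(0)
  if (sum(ce$data) < min_ce_voxels) {
    flags <- c(flags, sprintf("CE has %d voxels (< %d)", sum(ce$data),
                              min_ce_voxels))
  }
  adc_n  <- normalize_by_nawm(adc, nawm)
  rcbv_n <- normalize_by_nawm(rcbv, nawm)

  th_rcbv <- pooled_quartiles(rcbv_n, ce, type = quantile_type)
  th_adc  <- pooled_quartiles(adc_n, ce, type = quantile_type)

  rcbv_l <- lowest_quartile_mask(rcbv_n, ce, th_rcbv, label = "rCBV_L")
  adc_l  <- lowest_quartile_mask(adc_n, ce, th_adc, label = "ADC_L")
  adc_h  <- highest_quartile_mask(adc_n, ce, th_adc, label = "ADC_H")

  masks <- intersect_compartments(rcbv_l, adc_l, adc_h, ce)
  masks$CE <- ce

  vol_rows <- purrr::map(names(masks), function(nm) {
    tibble::tibble(
      roi = nm,
      n_voxels = sum(masks[[nm]]$data),
      abs_volume_cm3 = mask_volume(masks[[nm]]),
      prop_of_ce_pct = proportional_volume(masks[[nm]], ce)
    )
  })
  thresholds <- dplyr::bind_rows(th_rcbv, th_adc)
  thresholds$n_ties_low <- c(attr(rcbv_l, "n_ties"), attr(adc_l, "n_ties"))
  thresholds$n_ties_high <- c(NA_integer_, attr(adc_h, "n_ties"))

  structure(
    list(masks = masks, thresholds = thresholds,
         volumes = dplyr::bind_rows(vol_rows), flags = flags),
    class = "habitat_result"
  )
}

#' @export
print.habitat_result <- function(x, ...) {
  cat("<habitat_result>\n")
  print(x$volumes)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.habitat_result <- function(x, ...) x$volumes

#' @export
glance.habitat_result <- function(x, ...) {
  v <- x$volumes
  pick <- function(r, col) v[[col]][v$roi == r]
  tibble::tibble(
    ce_volume_cm3 = pick("CE", "abs_volume_cm3"),
    adcl_rcbvl_cm3 = pick("ADC_L-rCBV_L", "abs_volume_cm3"),
    adch_rcbvl_cm3 = pick("ADC_H-rCBV_L", "abs_volume_cm3"),
    adcl_rcbvl_pct = pick("ADC_L-rCBV_L", "prop_of_ce_pct"),
    adch_rcbvl_pct = pick("ADC_H-rCBV_L", "prop_of_ce_pct"),
    n_flags = length(x$flags)
  )
}

#' Plot one axial slice of a habitat segmentation
#'
#' Colors the two compartments and the contrast-enhancing control on a
#' chosen axial slice.
#'
#' @param object A `habitat_result`.
#' @param slice Axial slice index; defaults to the CE center of mass.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.habitat_result <- function(object, slice = NULL, ...) {
  ce <- object$masks$CE$data
  if (is.null(slice)) {
    zs <- which(apply(ce, 3, any))
    slice <- zs[ceiling(length(zs) / 2)]
  }
  lab <- array(NA_character_, dim(ce)[1:2])
  lab[object$masks$CEC$data[, , slice]] <- "CEC"
  lab[object$masks$`ADC_H-rCBV_L`$data[, , slice]] <- "ADC_H-rCBV_L"
  lab[object$masks$`ADC_L-rCBV_L`$data[, , slice]] <- "ADC_L-rCBV_L"
  df <- tidyr::expand_grid(x = seq_len(nrow(lab)), y = seq_len(ncol(lab)))
  df$region <- as.vector(lab)
  df <- df[!is.na(df$region), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$region)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_manual(values = c("ADC_L-rCBV_L" = "#E8C51D",
                                          "ADC_H-rCBV_L" = "#2166AC",
                                          "CEC" = "grey35")) +
    ggplot2::labs(title = paste("Habitat compartments, slice", slice),
                  fill = NULL) +
    ggplot2::theme_minimal()
}
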