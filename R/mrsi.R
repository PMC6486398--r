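#' MR spectroscopic imaging grid
#'
#' Represents a coarse 2D-MRSI lattice mapped onto the image grid. Each
#' spectroscopic voxel covers an axis-aligned block of image voxels
#' (typically ~10x coarser in-plane, one slice thick) and carries metabolite
#' ratios to creatine (Lac/Cr, ML9/Cr) plus a spectral-quality indicator.
#'
#' @param voxels A data frame with one row per spectroscopic voxel and
#'   columns `row`, `col` (lattice indices), `x0`, `y0`, `z0` (1-based image
#'   voxel origin of the block), `nx`, `ny`, `nz` (block extent in image
#'   voxels), `lac_cr`, `ml9_cr`, and either a logical `quality_pass` or a
#'   numeric `rel_sd` (Cramer-Rao-style relative SD in percent, filtered at
#'   `max_rel_sd`).
#' @param image_dim Integer length-3 image grid dimensions the blocks refer
#'   to.
#' @param max_rel_sd Quality threshold (%) applied when `rel_sd` is supplied
#'   instead of `quality_pass`.
#' @return An object of class `mrsi_grid`: a tibble of voxels with
#'   attributes `image_dim` and `max_rel_sd`.
#' @export
mrsi_grid <- function(voxels, image_dim, max_rel_sd = 20) {
  voxels <- tibble::as_tibble(voxels)
  need <- c("row", "col", "x0", "y0", "z0", "nx", "ny", "nz",
            "lac_cr", "ml9_cr")
  miss <- setdiff(need, names(voxels))
  if (length(miss)) stop("MRSI table is missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!"quality_pass" %in% names(voxels)) {
    if (!"rel_sd" %in% names(voxels)) {
      stop("Provide either `quality_pass` or `rel_sd`.", call. = FALSE)
    }
    voxels$quality_pass <- voxels$rel_sd <= max_rel_sd
  }
  image_dim <- as.integer(image_dim)
  stopifnot(length(image_dim) == 3L)
  if (any(voxels$x0 < 1 | voxels$y0 < 1 | voxels$z0 < 1 |
          voxels$x0 + voxels$nx - 1 > image_dim[1] |
          voxels$y0 + voxels$ny - 1 > image_dim[2] |
          voxels$z0 + voxels$nz - 1 > image_dim[3])) {
    stop("Spectroscopic voxel blocks extend outside the image grid.",
         call. = FALSE)
  }
  # non-overlap: every image voxel belongs to at most one block
  occ <- array(0L, image_dim)
  for (i in seq_len(nrow(voxels))) {
    xs <- voxels$x0[i]:(voxels$x0[i] + voxels$nx[i] - 1L)
    ys <- voxels$y0[i]:(voxels$y0[i] + voxels$ny[i] - 1L)
    zs <- voxels$z0[i]:(voxels$z0[i] + voxels$nz[i] - 1L)
    occ[xs, ys, zs] <- occ[xs, ys, zs] + 1L
  }
  if (any(occ > 1L)) stop("Spectroscopic voxel blocks overlap.",
                          call. = FALSE)
  voxels$voxel_id <- seq_len(nrow(voxels))
  structure(voxels, class = c("mrsi_grid", class(voxels)),
            image_dim = image_dim, max_rel_sd = max_rel_sd)
}

#' Build a regular MRSI slab over one slice
#'
#' Convenience constructor for the usual acquisition geometry: a regular
#' in-plane lattice of `block[1] x block[2]` image-voxel blocks, one slice
#' thick, covering the whole in-plane field of view.
#'
#' @param image_dim Image grid dimensions.
#' @param block In-plane block size in image voxels.
#' @param slice Image slice carrying the slab.
#' @param lac_cr,ml9_cr Per-voxel ratio vectors (lattice row-major,
#'   recycled).
#' @param quality_pass Logical vector, recycled.
#' @return An `mrsi_grid`.
#' @export
mrsi_grid_regular <- function(image_dim, block = c(10, 10), slice = 1,
                              lac_cr = 0, ml9_cr = 0, quality_pass = TRUE) {
  image_dim <- as.integer(image_dim)
  if (image_dim[1] %% block[1] != 0 || image_dim[2] %% block[2] != 0) {
    stop("Block size must divide the in-plane extent.", call. = FALSE)
  }
  nr <- image_dim[1] %/% block[1]
  nc <- image_dim[2] %/% block[2]
  g <- tidyr::expand_grid(row = seq_len(nr), col = seq_len(nc))
  g$x0 <- (g$row - 1L) * block[1] + 1L
  g$y0 <- (g$col - 1L) * block[2] + 1L
  g$z0 <- as.integer(slice)
  g$nx <- as.integer(block[1]); g$ny <- as.integer(block[2]); g$nz <- 1L
  g$lac_cr <- rep_len(lac_cr, nrow(g))
  g$ml9_cr <- rep_len(ml9_cr, nrow(g))
  g$quality_pass <- rep_len(quality_pass, nrow(g))
  mrsi_grid(g, image_dim)
}

block_indices <- function(grid, i) {
  list(x = grid$x0[i]:(grid$x0[i] + grid$nx[i] - 1L),
       y = grid$y0[i]:(grid$y0[i] + grid$ny[i] - 1L),
       z = grid$z0[i]:(grid$z0[i] + grid$nz[i] - 1L))
}

#' Coverage fraction of a mask in each spectroscopic voxel
#'
#' For every spectroscopic voxel, the fraction of its image-voxel block
#' lying inside `mask` — the raw ingredient of the MRSI weights.
#'
#' @param mask [roi_mask] on the image grid the MRSI geometry refers to.
#' @param grid An [mrsi_grid].
#' @return Tibble with `voxel_id`, `coverage` in `[0, 1]`.
#' @export
coverage_fractions <- function(mask, grid) {
  if (any(dim(mask$data) != attr(grid, "image_dim"))) {
    stop("Mask grid does not match the MRSI geometry's image grid.",
         call. = FALSE)
  }
  cov <- vapply(seq_len(nrow(grid)), function(i) {
    b <- block_indices(grid, i)
    mean(mask$data[b$x, b$y, b$z])
  }, numeric(1))
  tibble::tibble(voxel_id = grid$voxel_id, coverage = cov)
}

#' Tumor-containment filter for spectroscopic voxels
#'
#' A spectroscopic voxel is eligible only if its whole image-voxel block
#' lies inside the delineated tumor and its spectral quality passes.
#'
#' @param tumor Tumor [roi_mask] (usually the CE ROI).
#' @param grid An [mrsi_grid].
#' @return Tibble with `voxel_id`, `contained`, `quality_pass`, `included`.
#' @export
tumor_containment_filter <- function(tumor, grid) {
  cov <- coverage_fractions(tumor, grid)
  tibble::tibble(
    voxel_id = cov$voxel_id,
    contained = cov$coverage == 1,
    quality_pass = grid$quality_pass,
    included = cov$coverage == 1 & grid$quality_pass
  )
}

#' Coverage-weighted metabolite value of a compartment
#'
#' Aggregates a metabolite ratio over the spectroscopic voxels that (a) lie
#' completely within the tumor, (b) pass spectral quality, and (c) overlap
#' the compartment. Each eligible voxel is weighted by the fraction of its
#' block covered by the compartment, weights are renormalized to sum to 1,
#' and the value is the weighted mean of the ratios.
#'
#' @param mask Compartment [roi_mask] on the image grid.
#' @param grid An [mrsi_grid].
#' @param tumor Tumor [roi_mask] used for the containment filter.
#' @param metabolite `"lac_cr"` or `"ml9_cr"`.
#' @return A one-row tibble with `metabolite`, `value`, `n_voxels`, and a
#'   list-column `weights` (tibble of `voxel_id`, `coverage`, `weight`,
#'   `ratio`). With no eligible voxel, `value` is `NA` and `n_voxels` 0 —
#'   an explicit missing-value record, the subject drops out of metabolite
#'   analyses.
#' @export
weighted_metabolite <- function(mask, grid, tumor,
                                metabolite = c("lac_cr", "ml9_cr")) {
  metabolite <- match.arg(metabolite)
  incl <- tumor_containment_filter(tumor, grid)
  cov <- coverage_fractions(mask, grid)
  elig <- incl$included & cov$coverage > 0
  if (!any(elig)) {
    return(tibble::tibble(metabolite = metabolite, value = NA_real_,
                          n_voxels = 0L,
                          weights = list(tibble::tibble(
                            voxel_id = integer(), coverage = numeric(),
                            weight = numeric(), ratio = numeric()))))
  }
  cvg <- cov$coverage[elig]
  w <- cvg / sum(cvg)
  ratio <- grid[[metabolite]][elig]
  tibble::tibble(
    metabolite = metabolite,
    value = sum(w * ratio),
    n_voxels = sum(elig),
    weights = list(tibble::tibble(voxel_id = cov$voxel_id[elig],
                                  coverage = cvg, weight = w, ratio = ratio))
  )
}

#' Metabolite table for all habitat compartments
#'
#' Applies [weighted_metabolite()] to the two compartments, the
#' contrast-enhancing control and (optionally) NAWM, for both Lac/Cr and
#' ML9/Cr. For NAWM the containment filter uses the NAWM mask itself.
#'
#' @param habitat A `habitat_result` from [segment_habitats()].
#' @param grid An [mrsi_grid].
#' @param nawm Optional NAWM [roi_mask].
#' @return Tidy tibble: `compartment`, `metabolite`, `value`, `n_voxels`.
#' @export
compartment_metabolites <- function(habitat, grid, nawm = NULL) {
  ce <- habitat$masks$CE
  comps <- list("ADC_L-rCBV_L" = habitat$masks$`ADC_L-rCBV_L`,
                "ADC_H-rCBV_L" = habitat$masks$`ADC_H-rCBV_L`,
                "CEC" = habitat$masks$CEC)
  rows <- purrr::map(names(comps), function(nm) {
    purrr::map(c("lac_cr", "ml9_cr"), function(met) {
      r <- weighted_metabolite(comps[[nm]], grid, ce, met)
      tibble::tibble(compartment = nm, metabolite = met,
                     value = r$value, n_voxels = r$n_voxels)
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  if (!is.null(nawm)) {
    # NAWM is a reference region, not tumor: the tumor-containment filter
    # does not apply, so containment is trivially satisfied everywhere
    everywhere <- roi_mask(array(TRUE, dim(nawm$data)), "all",
                           nawm$voxel_dims)
    nw <- purrr::map(c("lac_cr", "ml9_cr"), function(met) {
      r <- weighted_metabolite(nawm, grid, everywhere, met)
      tibble::tibble(compartment = "NAWM", metabolite = met,
                     value = r$value, n_voxels = r$n_voxels)
    })
    out <- dplyr::bind_rows(out, dplyr::bind_rows(nw))
  }
  out
}

#' Read / write the MRSI table
#'
#' The on-disk schema is a delimited text file with the columns documented
#' in [mrsi_grid()]; grid dimensions travel in a header comment line
#' `# image_dim: X Y Z`.
#'
#' @param path File path.
#' @param grid An [mrsi_grid] (for writing).
#' @return [read_mrsi()] returns an `mrsi_grid`; [write_mrsi()] returns
#'   `path` invisibly.
#' @export
read_mrsi <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  hdr <- readLines(path, n = 1L)
  if (!grepl("^# image_dim:", hdr)) {
    stop("Missing '# image_dim: X Y Z' header line in ", path, call. = FALSE)
  }
  image_dim <- as.integer(strsplit(sub("^# image_dim:\\s*", "", hdr),
                                   "\\s+")[[1]])
  voxels <- utils::read.csv(path, comment.char = "#")
  mrsi_grid(voxels, image_dim)
}

#' @rdname read_mrsi
#' @export
write_mrsi <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# image_dim:",
                   paste(attr(grid, "image_dim"), collapse = " ")), con)
  utils::write.csv(as.data.frame(grid)[, setdiff(names(grid), "voxel_id")],
                   con, row.names = FALSE)
  invisible(path)
}
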