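# run expr with a private RNG stream seeded by `seed`, restoring global state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  stats::qnorm(stats::runif(n, stats::pnorm(lo, mean, sd),
                            stats::pnorm(hi, mean, sd)), mean, sd)
}

#' Phantom specification
#'
#' Describes a synthetic rim-enhancing lesion used to exercise the whole
#' habitat pipeline with known ground truth: an ellipsoidal
#' contrast-enhancing (CE) lesion whose innermost `core_fraction` of
#' voxels forms a low-perfusion core, split into a restricted-diffusivity
#' and an elevated-diffusivity subregion; a surrounding FLAIR envelope; a
#' contralateral 10 mm NAWM sphere; a one-slice 2D-MRSI slab ~10x coarser
#' in-plane; and per-region intensity distributions.
#'
#' In the default `"separated"` mode the region intensity distributions
#' are truncated to disjoint supports — core rCBV strictly below rim rCBV,
#' restricted-core ADC below rim ADC below elevated-core ADC — so the
#' planted core is exactly the lowest pooled rCBV quartile when
#' `core_fraction = 0.25` and the quartile pipeline must recover it.
#' `"overlapping"` drops the truncation to test graceful degradation.
#'
#' @param dim Image grid dimensions (in-plane extent must be divisible by
#'   `mrsi_block`).
#' @param voxel_dims Voxel size, mm.
#' @param center Lesion center (voxels); default left-of-midline.
#' @param radii_mm CE ellipsoid radii, mm.
#' @param flair_extra_mm FLAIR envelope margin beyond CE, mm.
#' @param core_fraction Fraction of CE voxels in the low-perfusion core.
#' @param split_fraction Fraction of core voxels with restricted
#'   diffusivity (the ADC_L side).
#' @param mode `"separated"` or `"overlapping"` intensity supports.
#' @param rcbv,adc Per-region `(mean, sd)` rows: list with `rim`, `core`
#'   (rCBV) / `rim`, `core_restricted`, `core_elevated` (ADC), `nawm`.
#'   ADC in 1e-3 mm^2/s.
#' @param mrsi_block In-plane MRSI block size, image voxels.
#' @param metabolites Per-region mean Lac/Cr and ML9/Cr used to build the
#'   spectroscopic voxel expectations.
#' @param mrsi_sd Gaussian noise SD added to each spectroscopic ratio.
#' @param quality_fail_rate Fraction of spectroscopic voxels flagged as
#'   failing spectral quality.
#' @param seed Integer seed; all phantom randomness flows from it.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(dim = c(70, 70, 48), voxel_dims = c(1, 1, 1),
                         center = NULL, radii_mm = c(16, 14, 12),
                         flair_extra_mm = 6,
                         core_fraction = 0.25, split_fraction = 0.35,
                         mode = c("separated", "overlapping"),
                         rcbv = list(rim = c(2.0, 0.25), core = c(0.55, 0.10),
                                     nawm = c(1.0, 0.05)),
                         adc = list(rim = c(1.15, 0.08),
                                    core_restricted = c(0.65, 0.05),
                                    core_elevated = c(1.62, 0.08),
                                    nawm = c(0.80, 0.03)),
                         mrsi_block = c(10, 10),
                         metabolites = list(
                           lac_cr = c(core_restricted = 1.2,
                                      core_elevated = 0.9,
                                      cec = 0.5, outside = 0.25),
                           ml9_cr = c(core_restricted = 0.9,
                                      core_elevated = 1.0,
                                      cec = 0.6, outside = 0.30)),
                         mrsi_sd = 0.05, quality_fail_rate = 0.05,
                         seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(core_fraction > 0, core_fraction < 1,
            split_fraction > 0, split_fraction < 1)
  if (dim[1] %% mrsi_block[1] != 0 || dim[2] %% mrsi_block[2] != 0) {
    stop("`mrsi_block` must divide the in-plane extent.", call. = FALSE)
  }
  if (is.null(center)) center <- c(round(dim[1] * 0.38), dim[2] / 2,
                                   dim[3] / 2)
  r_vox <- radii_mm / voxel_dims
  if (any(center - r_vox < 2) || any(center + r_vox > dim - 1)) {
    stop("Lesion does not fit inside the grid.", call. = FALSE)
  }
  structure(
    list(dim = as.integer(dim), voxel_dims = voxel_dims, center = center,
         radii_mm = radii_mm, flair_extra_mm = flair_extra_mm,
         core_fraction = core_fraction, split_fraction = split_fraction,
         mode = mode, rcbv = rcbv, adc = adc, mrsi_block = mrsi_block,
         metabolites = metabolites, mrsi_sd = mrsi_sd,
         quality_fail_rate = quality_fail_rate, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

ellipsoid_r2 <- function(dim, center, radii_vox) {
  x <- (seq_len(dim[1]) - center[1]) / radii_vox[1]
  y <- (seq_len(dim[2]) - center[2]) / radii_vox[2]
  z <- (seq_len(dim[3]) - center[3]) / radii_vox[3]
  outer(outer(x^2, y^2, `+`), z^2, `+`)
}

region_draw <- function(n, ms, mode, lo, hi) {
  if (mode == "separated") rtruncnorm(n, ms[1], ms[2], lo, hi)
  else stats::rnorm(n, ms[1], ms[2])
}

#' Generate a synthetic subject bundle
#'
#' Builds all per-subject inputs of the habitat pipeline from a
#' [phantom_spec], plus the planted ground truth.
#'
#' @param spec A [phantom_spec].
#' @return A list of class `phantom_bundle`: parametric volumes `adc`,
#'   `rcbv`, eigenvalue volumes `l1`, `l2`, `l3`; masks `ce`, `flair`,
#'   `nawm`; `mrsi` (an [mrsi_grid]); and `truth` with the planted `core`,
#'   `core_restricted` / `core_elevated` masks, the per-spectroscopic-voxel
#'   noise-free expected ratios, and the spec.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    d <- spec$dim; vd <- spec$voxel_dims
    r_vox <- spec$radii_mm / vd
    r2_ce <- ellipsoid_r2(d, spec$center, r_vox)
    ce_arr <- r2_ce <= 1
    flair_arr <- ellipsoid_r2(d, spec$center,
                              (spec$radii_mm + spec$flair_extra_mm) / vd) <= 1
    # contralateral NAWM sphere, 10 mm diameter, farthest from the lesion
    nawm_center <- c(d[1] - ceiling(5 / vd[1]) - 2, spec$center[2],
                     spec$center[3])
    nawm_arr <- ellipsoid_r2(d, nawm_center, rep(5, 3) / vd) <= 1
    nawm_arr <- nawm_arr & !flair_arr
    if (!any(nawm_arr)) stop("NAWM region overlaps the lesion; enlarge ",
                             "the grid or shrink the lesion.", call. = FALSE)

    ce_idx <- which(ce_arr)
    n_ce <- length(ce_idx)
    n_core <- round(spec$core_fraction * n_ce)
    ord <- order(r2_ce[ce_idx])            # innermost first, ties by index
    core_idx <- ce_idx[ord[seq_len(n_core)]]
    core_arr <- array(FALSE, d); core_arr[core_idx] <- TRUE

    # split the core along y: restricted-diffusivity side first
    n_res <- round(spec$split_fraction * n_core)
    yy <- arrayInd(core_idx, d)[, 2]
    res_idx <- core_idx[order(yy, core_idx)[seq_len(n_res)]]
    res_arr <- array(FALSE, d); res_arr[res_idx] <- TRUE
    ele_arr <- core_arr & !res_arr

    rim_arr <- ce_arr & !core_arr
    edema_arr <- flair_arr & !ce_arr

    # rCBV: core support strictly below rim support (separated mode)
    rcbv <- array(stats::rnorm(prod(d), spec$rcbv$nawm[1],
                               spec$rcbv$nawm[2]), d)
    rcbv[rim_arr] <- region_draw(sum(rim_arr), spec$rcbv$rim, spec$mode,
                                 lo = 1.3, hi = 2.7)
    rcbv[core_arr] <- region_draw(sum(core_arr), spec$rcbv$core, spec$mode,
                                  lo = 0.25, hi = 0.85)

    # ADC (1e-3 mm^2/s): restricted < rim < elevated supports
    adc <- array(stats::rnorm(prod(d), spec$adc$nawm[1], spec$adc$nawm[2]), d)
    adc[edema_arr] <- stats::rnorm(sum(edema_arr), 1.30, 0.08)
    adc[rim_arr] <- region_draw(sum(rim_arr), spec$adc$rim, spec$mode,
                                lo = 0.95, hi = 1.35)
    adc[res_arr] <- region_draw(sum(res_arr), spec$adc$core_restricted,
                                spec$mode, lo = 0.50, hi = 0.88)
    adc[ele_arr] <- region_draw(sum(ele_arr), spec$adc$core_elevated,
                                spec$mode, lo = 1.45, hi = 1.85)
    adc <- adc * 1e-3

    # diffusion tensor eigenvalues: anisotropic white matter, near-isotropic
    # tumor and edema (elevated mean diffusivity -> elevated p in FLAIR)
    frac <- array(0.30, d)
    frac[flair_arr] <- 0.05
    md <- adc
    l1 <- md * (1 + 2 * frac)
    l2 <- md * (1 - frac)
    l3 <- l2

    mk_vol <- function(a, modality) parametric_volume(a, voxel_dims = vd,
                                                      modality = modality)
    ce <- roi_mask(ce_arr, "CE", vd)
    flair <- roi_mask(flair_arr, "FLAIR", vd)
    nawm <- roi_mask(nawm_arr, "NAWM", vd)

    # MRSI slab on the mid-lesion slice: expected ratio per spectroscopic
    # voxel is the coverage-weighted mixture of region means
    slab <- round(spec$center[3])
    grid0 <- mrsi_grid_regular(d, spec$mrsi_block, slab)
    regions <- list(core_restricted = res_arr, core_elevated = ele_arr,
                    cec = rim_arr)
    cover <- lapply(regions, function(a)
      coverage_fractions(roi_mask(a, "r", vd), grid0)$coverage)
    out_frac <- 1 - Reduce(`+`, cover)
    expected <- lapply(spec$metabolites, function(mu) {
      cover$core_restricted * mu[["core_restricted"]] +
        cover$core_elevated * mu[["core_elevated"]] +
        cover$cec * mu[["cec"]] + out_frac * mu[["outside"]]
    })
    nv <- nrow(grid0)
    lac <- expected$lac_cr + stats::rnorm(nv, 0, spec$mrsi_sd)
    ml9 <- expected$ml9_cr + stats::rnorm(nv, 0, spec$mrsi_sd)
    qpass <- stats::runif(nv) >= spec$quality_fail_rate
    gdf <- tibble::as_tibble(grid0)
    gdf$lac_cr <- lac; gdf$ml9_cr <- ml9; gdf$quality_pass <- qpass
    grid <- mrsi_grid(gdf[, setdiff(names(gdf), "voxel_id")], d)

    structure(
      list(adc = mk_vol(adc, "ADC"), rcbv = mk_vol(rcbv, "rCBV"),
           l1 = mk_vol(l1, "other"), l2 = mk_vol(l2, "other"),
           l3 = mk_vol(l3, "other"),
           ce = ce, flair = flair, nawm = nawm, mrsi = grid,
           truth = list(
             core = roi_mask(core_arr, "rCBV_L", vd),
             core_restricted = roi_mask(res_arr, "ADC_L-rCBV_L", vd),
             core_elevated = roi_mask(ele_arr, "ADC_H-rCBV_L", vd),
             mrsi_expected = tibble::tibble(
               voxel_id = grid0$voxel_id,
               lac_cr = expected$lac_cr, ml9_cr = expected$ml9_cr),
             mrsi_sd = spec$mrsi_sd,
             spec = spec)),
      class = "phantom_bundle"
    )
  })
}

#' Cohort specification
#'
#' Describes a synthetic clinical cohort with planted covariate effects on
#' survival. Covariates are drawn from `covariates` (named list of
#' functions of `n`); survival times are exponential with hazard
#' `baseline_hazard * exp(sum(beta_j * x_j))`, where each named `beta`
#' refers to a numeric column (factors contribute through the 0/1 columns
#' listed in `betas`). Censoring is independent exponential calibrated so
#' the expected censored fraction equals `censoring_rate`.
#'
#' Defaults mirror a glioblastoma cohort treated per the Stupp protocol:
#' n = 80 with survival data, age ~ 59 +- 10 years, 75% male, 67% complete
#' resection, 44% MGMT-methylated (with a few missing), 6% IDH-1 mutant,
#' log-normal lesion volumes, median OS around 455 days and PFS around
#' 265 days, ~30% censoring.
#'
#' @param n Number of subjects.
#' @param baseline_hazard_os,baseline_hazard_pfs Exponential baseline
#'   rates, per day.
#' @param betas Named numeric vector of planted log-hazard-ratios.
#' @param censoring_rate Expected fraction censored, in `[0, 1)`.
#' @param covariates Named list of generator functions `n -> vector`;
#'   `NULL` uses the default clinical set.
#' @param mgmt_missing_rate,mrs_missing_rate,phenotype_missing_rate
#'   Missingness rates for the optional fields.
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n = 80,
                        baseline_hazard_os = log(2) / 455,
                        baseline_hazard_pfs = log(2) / 265,
                        betas = c(ce_vol = 0.012, eor_partial = 0.7,
                                  mgmt_methylated = -0.5,
                                  lac_cr_adcl = 0.4),
                        censoring_rate = 0.3,
                        covariates = NULL,
                        mgmt_missing_rate = 0.04,
                        mrs_missing_rate = 0.28,
                        phenotype_missing_rate = 0.2,
                        seed = 1L) {
  stopifnot(n >= 1, censoring_rate >= 0, censoring_rate < 1)
  structure(
    list(n = as.integer(n), baseline_hazard_os = baseline_hazard_os,
         baseline_hazard_pfs = baseline_hazard_pfs, betas = betas,
         censoring_rate = censoring_rate, covariates = covariates,
         mgmt_missing_rate = mgmt_missing_rate,
         mrs_missing_rate = mrs_missing_rate,
         phenotype_missing_rate = phenotype_missing_rate,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

rlnorm_ms <- function(n, mean, sd) {
  cv2 <- (sd / mean)^2
  sdlog <- sqrt(log(1 + cv2))
  stats::rlnorm(n, log(mean) - sdlog^2 / 2, sdlog)
}

default_cohort_covariates <- function(n) {
  ce_vol <- rlnorm_ms(n, 53, 33)
  adcl <- rlnorm_ms(n, 2.3, 2.2)
  adch <- rlnorm_ms(n, 5.7, 4.6)
  tibble::tibble(
    age = pmin(pmax(round(stats::rnorm(n, 59, 10)), 22), 76),
    sex = factor(ifelse(stats::runif(n) < 0.75, "M", "F"),
                 levels = c("F", "M")),
    eor = factor(sample(c("complete", "partial", "biopsy"), n, TRUE,
                        prob = c(0.65, 0.30, 0.05)),
                 levels = c("complete", "partial", "biopsy")),
    mgmt = factor(ifelse(stats::runif(n) < 0.44, "methylated",
                         "unmethylated"),
                  levels = c("unmethylated", "methylated")),
    idh1 = factor(ifelse(stats::runif(n) < 0.06, "mutant", "wildtype"),
                  levels = c("wildtype", "mutant")),
    ce_vol = ce_vol,
    flair_vol = rlnorm_ms(n, 113, 61),
    adcl_rcbvl_vol = pmin(adcl, 0.45 * ce_vol),
    adch_rcbvl_vol = pmin(adch, 0.45 * ce_vol),
    lac_cr_adcl = stats::rnorm(n, 1.2, 0.3),
    lac_cr_adch = stats::rnorm(n, 0.9, 0.25),
    lac_cr_cec = stats::rnorm(n, 0.5, 0.2),
    ml9_cr_adcl = stats::rnorm(n, 0.9, 0.25),
    ml9_cr_adch = stats::rnorm(n, 1.0, 0.25),
    phenotype = factor(sample(c("minimal", "localized", "diffuse"), n, TRUE,
                              prob = c(0.3, 0.4, 0.3)),
                       levels = c("minimal", "localized", "diffuse"))
  )
}

# numeric design column for a planted beta name
beta_column <- function(df, nm) {
  if (nm %in% names(df)) {
    v <- df[[nm]]
    if (is.numeric(v)) return(v)
    if (is.logical(v)) return(as.numeric(v))
    stop("Planted beta on non-numeric column '", nm,
         "'; name a dummy like 'eor_partial'.", call. = FALSE)
  }
  # dummy form <column>_<level>
  for (cand in names(df)) {
    pre <- paste0(cand, "_")
    if (startsWith(nm, pre)) {
      lev <- substring(nm, nchar(pre) + 1)
      return(as.numeric(df[[cand]] == lev))
    }
  }
  stop("Unknown covariate in betas: ", nm, call. = FALSE)
}

#' Generate a synthetic cohort table
#'
#' @param spec A [cohort_spec].
#' @return A tibble (one row per subject) with the clinical covariates,
#'   imaging volumes, metabolite ratios, phenotype, and censored
#'   `pfs_days`/`os_days` with 0/1 event flags. Attribute `truth` carries
#'   the planted parameters.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n
    df <- if (is.null(spec$covariates)) {
      default_cohort_covariates(n)
    } else {
      tibble::as_tibble(lapply(spec$covariates, function(f) f(n)))
    }
    lp <- rep(0, n)
    for (nm in names(spec$betas)) {
      lp <- lp + spec$betas[[nm]] * beta_column(df, nm)
    }
    draw_surv <- function(h0) {
      h <- h0 * exp(lp)
      t_event <- stats::rexp(n, rate = h)
      if (spec$censoring_rate > 0) {
        c_ratio <- spec$censoring_rate / (1 - spec$censoring_rate)
        t_cens <- stats::rexp(n, rate = h * c_ratio)
      } else {
        t_cens <- rep(Inf, n)
      }
      list(time = pmax(ceiling(pmin(t_event, t_cens)), 1),
           event = as.integer(t_event <= t_cens))
    }
    os <- draw_surv(spec$baseline_hazard_os)
    pfs <- draw_surv(spec$baseline_hazard_pfs)
    df$pfs_days <- pmin(pfs$time, os$time)
    df$pfs_event <- ifelse(pfs$time <= os$time, pfs$event, os$event)
    df$os_days <- os$time
    df$os_event <- os$event

    # planted missingness
    if ("mgmt" %in% names(df) && spec$mgmt_missing_rate > 0) {
      df$mgmt[stats::runif(n) < spec$mgmt_missing_rate] <- NA
    }
    mrs_cols <- grep("^(lac|ml9)_cr_", names(df), value = TRUE)
    if (length(mrs_cols) && spec$mrs_missing_rate > 0) {
      no_mrs <- stats::runif(n) < spec$mrs_missing_rate
      for (cc in mrs_cols) df[[cc]][no_mrs] <- NA
    }
    if ("phenotype" %in% names(df) && spec$phenotype_missing_rate > 0) {
      df$phenotype[stats::runif(n) < spec$phenotype_missing_rate] <- NA
    }
    attr(df, "truth") <- list(betas = spec$betas,
                              baseline_hazard_os = spec$baseline_hazard_os,
                              baseline_hazard_pfs = spec$baseline_hazard_pfs,
                              censoring_rate = spec$censoring_rate,
                              linear_predictor = lp, seed = spec$seed)
    df
  })
}
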