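#' Run the per-subject habitat pipeline
#'
#' Orchestrates one subject end-to-end: grid checks, NAWM normalization,
#' quartile habitat segmentation, volumetrics, coverage-weighted MRSI
#' metabolite values, and (when diffusion inputs are given) p/q maps,
#' abnormality margins and the invasive phenotype. Outputs are
#' deterministic for fixed inputs and configuration; the report records
#' the package version, a configuration hash and quartile tie counts so
#' threshold behavior is auditable.
#'
#' @param adc,rcbv [parametric_volume]s (raw ADC / rCBV maps).
#' @param ce,nawm [roi_mask]s.
#' @param mrsi Optional [mrsi_grid]; when absent, metabolite fields are
#'   marked missing and volumetrics still run.
#' @param flair Optional FLAIR [roi_mask]; when given, derived p/q
#'   abnormality is restricted to FLAIR plus CE.
#' @param eigenvalues Optional list of three eigenvalue
#'   [parametric_volume]s (`l1`, `l2`, `l3`).
#' @param p_abnormal,q_abnormal Optional abnormality [roi_mask]s; when
#'   absent and eigenvalues are given they are derived with the z-score
#'   rule of [abnormality_mask()].
#' @param phenotype_override Optional externally assigned phenotype label
#'   (takes precedence over the margin rule).
#' @param quantile_type,min_ce_voxels Passed to [segment_habitats()].
#' @param z_abnormal,t_min,t_diff Diffusion-rule parameters (see
#'   [abnormality_mask()], [classify_phenotype()]).
#' @return An object of class `subject_report`: list with `thresholds`,
#'   `volumes`, `metabolites`, `phenotype`, `flags`, `habitat` (the full
#'   [segment_habitats()] result), `meta` (version + config hash).
#' @export
run_subject <- function(adc, rcbv, ce, nawm, mrsi = NULL, flair = NULL,
                        eigenvalues = NULL, p_abnormal = NULL,
                        q_abnormal = NULL, phenotype_override = NULL,
                        quantile_type = 7, min_ce_voxels = 64,
                        z_abnormal = 2, t_min = 10, t_diff = 10) {
  vols <- list(adc, rcbv, ce, nawm)
  if (!check_grid_compatibility(vols)) {
    stop("[grid] inputs are not on one voxel grid.", call. = FALSE)
  }
  config <- list(quantile_type = quantile_type,
                 min_ce_voxels = min_ce_voxels, z_abnormal = z_abnormal,
                 t_min = t_min, t_diff = t_diff)
  habitat <- tryCatch(
    segment_habitats(adc, rcbv, ce, nawm, quantile_type = quantile_type,
                     min_ce_voxels = min_ce_voxels),
    error = function(e) stop("[habitat] ", conditionMessage(e),
                             call. = FALSE))
  flags <- habitat$flags

  metabolites <- NULL
  if (!is.null(mrsi)) {
    metabolites <- tryCatch(
      compartment_metabolites(habitat, mrsi, nawm = nawm),
      error = function(e) stop("[mrsi] ", conditionMessage(e),
                               call. = FALSE))
  } else {
    flags <- c(flags, "no MRSI input; metabolite values missing")
  }

  phenotype <- NULL
  if (!is.null(phenotype_override)) {
    phenotype <- tibble::tibble(
      phenotype = factor(phenotype_override,
                         levels = c("minimal", "localized", "diffuse")),
      p_margin_mm = NA_real_, q_margin_mm = NA_real_)
  } else if (!is.null(eigenvalues) || (!is.null(p_abnormal) &&
                                       !is.null(q_abnormal))) {
    phenotype <- tryCatch({
      if (is.null(p_abnormal) || is.null(q_abnormal)) {
        pq <- compute_pq(eigenvalues[[1]], eigenvalues[[2]],
                         eigenvalues[[3]])
        within <- if (!is.null(flair)) {
          roi_mask(flair$data | ce$data, "FLAIR+CE", ce$voxel_dims)
        }
        if (is.null(p_abnormal)) {
          p_abnormal <- abnormality_mask(pq$p, nawm, z = z_abnormal,
                                         within = within)
        }
        if (is.null(q_abnormal)) {
          q_abnormal <- abnormality_mask(pq$q, nawm, z = z_abnormal,
                                         within = within)
        }
      }
      m <- abnormality_margins(p_abnormal, q_abnormal, ce)
      classify_phenotype(m$p_margin_mm, m$q_margin_mm,
                         t_min = t_min, t_diff = t_diff)
    }, error = function(e) stop("[dti] ", conditionMessage(e),
                                call. = FALSE))
  }

  structure(
    list(thresholds = habitat$thresholds, volumes = habitat$volumes,
         metabolites = metabolites, phenotype = phenotype, flags = flags,
         habitat = habitat,
         meta = list(package_version =
                       as.character(utils::packageVersion("habitatr")),
                     config = config, config_hash = rlang::hash(config))),
    class = "subject_report"
  )
}

#' @export
print.subject_report <- function(x, ...) {
  cat("<subject_report> config", substr(x$meta$config_hash, 1, 8), "\n")
  print(x$volumes)
  if (!is.null(x$phenotype)) print(x$phenotype)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Run the pipeline on a synthetic subject bundle
#'
#' @param bundle A `phantom_bundle` from [make_phantom()].
#' @param ... Passed to [run_subject()].
#' @return A `subject_report`.
#' @export
run_subject_bundle <- function(bundle, ...) {
  run_subject(bundle$adc, bundle$rcbv, bundle$ce, bundle$nawm,
              mrsi = bundle$mrsi, flair = bundle$flair,
              eigenvalues = list(bundle$l1, bundle$l2, bundle$l3), ...)
}

#' Serialize a subject report to JSON
#'
#' Timestamps are deliberately excluded so reruns on identical inputs are
#' byte-identical.
#'
#' @param report A `subject_report`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_json <- function(report, path = NULL) {
  payload <- list(
    meta = report$meta,
    thresholds = report$thresholds,
    volumes = report$volumes,
    metabolites = report$metabolites,
    phenotype = if (!is.null(report$phenotype)) {
      p <- report$phenotype
      p$phenotype <- as.character(p$phenotype)
      p
    },
    flags = report$flags
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = 10,
                         null = "null", na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Run the cohort-level analyses
#'
#' Produces the cohort deliverables from a per-subject table: a
#' descriptive comparison of ROI volumes across clinical subgroups with
#' Benjamini-Hochberg adjustment, Spearman correlations of compartment
#' volumes against CE and FLAIR volumes, maximally-selected cutpoint
#' dichotomization with Kaplan-Meier log-rank tests for the imaging and
#' metabolite variables, and multivariate plus forward/backward stepwise
#' AIC Cox models for each outcome. Cohorts below `min_n` subjects skip
#' the survival stages with a warning.
#'
#' @param cohort Data frame (one row per subject; see [make_cohort()] for
#'   the column conventions).
#' @param outcomes Named list mapping an outcome label to
#'   `c(time_col, event_col)`.
#' @param cox_covariates Candidate covariates for the Cox models.
#' @param cutpoint_vars Continuous variables to dichotomize.
#' @param group_vars Clinical grouping columns for the descriptive table.
#' @param volume_vars Volume columns compared in the descriptive table.
#' @param minprop Minimum group fraction for [surv_cutpoint()].
#' @param log_volumes Passed to [cox_fit()] / [stepwise_cox()].
#' @param min_n Minimum cohort size for the survival stages.
#' @return An object of class `cohort_report`: list with `descriptive`,
#'   `correlations`, `cutpoints`, `km`, `cox`, `stepwise`, `meta`.
#' @export
run_cohort <- function(cohort,
                       outcomes = list(pfs = c("pfs_days", "pfs_event"),
                                       os = c("os_days", "os_event")),
                       cox_covariates = c("age", "sex", "eor", "mgmt",
                                          "idh1", "ce_vol"),
                       cutpoint_vars = c("ce_vol", "flair_vol",
                                         "adcl_rcbvl_vol",
                                         "adch_rcbvl_vol"),
                       group_vars = c("sex", "eor", "mgmt", "idh1"),
                       volume_vars = c("ce_vol", "flair_vol",
                                       "adcl_rcbvl_vol", "adch_rcbvl_vol"),
                       minprop = 0.1, log_volumes = NULL, min_n = 10) {
  cohort <- tibble::as_tibble(cohort)
  group_vars <- intersect(group_vars, names(cohort))
  volume_vars <- intersect(volume_vars, names(cohort))
  cutpoint_vars <- intersect(cutpoint_vars, names(cohort))
  cox_covariates <- intersect(cox_covariates, names(cohort))

  # Descriptive table: rank tests of each volume across each subgroup,
  # BH-adjusted within each volume family
  descriptive <- NULL
  if (length(group_vars) && length(volume_vars)) {
    rows <- purrr::map(group_vars, function(gv) {
      lev <- unique(stats::na.omit(cohort[[gv]]))
      if (length(lev) < 2) return(NULL)
      method <- if (length(lev) == 2) "wilcoxon" else "kruskal"
      purrr::map(volume_vars, function(vv) {
        gc <- group_compare(cohort, vv, gv, method = method)
        tibble::tibble(group = gv, variable = vv, method = gc$method,
                       statistic = gc$statistic, p_value = gc$p_value)
      })
    })
    descriptive <- dplyr::bind_rows(purrr::flatten(purrr::compact(rows)))
    if (nrow(descriptive)) {
      descriptive <- dplyr::mutate(
        dplyr::group_by(descriptive, .data$group),
        p_adjusted = bh_adjust(.data$p_value))
      descriptive <- dplyr::ungroup(descriptive)
    }
  }

  # Spearman correlations: compartment volumes vs CE / FLAIR volumes
  comp_vars <- intersect(c("adcl_rcbvl_vol", "adch_rcbvl_vol"),
                         names(cohort))
  ref_vars <- intersect(c("ce_vol", "flair_vol"), names(cohort))
  correlations <- NULL
  if (length(comp_vars) && length(ref_vars)) {
    correlations <- dplyr::bind_rows(purrr::flatten(purrr::map(
      comp_vars, function(cv) purrr::map(ref_vars, function(rv) {
        sc <- spearman_cor(cohort[[cv]], cohort[[rv]])
        tibble::tibble(x = cv, y = rv, rho = sc$rho,
                       p_value = sc$p_value, n = sc$n)
      }))))
  }

  cutpoints <- list(); km <- list(); cox <- list(); stepwise <- list()
  if (nrow(cohort) < min_n) {
    warning("Cohort has ", nrow(cohort), " subjects (< ", min_n,
            "); survival stages skipped.", call. = FALSE)
  } else {
    for (oc in names(outcomes)) {
      tcol <- outcomes[[oc]][1]; ecol <- outcomes[[oc]][2]
      cutpoints[[oc]] <- purrr::map(
        rlang::set_names(cutpoint_vars), function(v) {
          tryCatch(surv_cutpoint(cohort, tcol, ecol, v,
                                 minprop = minprop),
                   error = function(e) NULL)
        })
      km[[oc]] <- purrr::map(
        rlang::set_names(cutpoint_vars), function(v) {
          cp <- cutpoints[[oc]][[v]]
          if (is.null(cp)) return(NULL)
          dd <- cohort[stats::complete.cases(cohort[, c(tcol, ecol, v)]), ]
          dd$.group <- cp$groups
          km_logrank(dd, tcol, ecol, ".group")
        })
      cox[[oc]] <- tryCatch(
        cox_fit(cohort, tcol, ecol, cox_covariates,
                log_volumes = log_volumes),
        error = function(e) {
          warning("Cox fit (", oc, ") failed: ", conditionMessage(e),
                  call. = FALSE)
          NULL
        })
      stepwise[[oc]] <- purrr::map(
        rlang::set_names(c("forward", "backward")), function(dir) {
          tryCatch(stepwise_cox(cohort, tcol, ecol, cox_covariates,
                                direction = dir,
                                log_volumes = log_volumes),
                   error = function(e) NULL)
        })
    }
  }

  config <- list(outcomes = outcomes, cox_covariates = cox_covariates,
                 cutpoint_vars = cutpoint_vars, minprop = minprop,
                 log_volumes = log_volumes, min_n = min_n)
  structure(
    list(descriptive = descriptive, correlations = correlations,
         cutpoints = cutpoints, km = km, cox = cox, stepwise = stepwise,
         meta = list(n = nrow(cohort),
                     package_version =
                       as.character(utils::packageVersion("habitatr")),
                     config_hash = rlang::hash(config))),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report> n =", x$meta$n, "\n")
  if (!is.null(x$descriptive)) {
    cat("descriptive comparisons:", nrow(x$descriptive), "tests\n")
  }
  for (oc in names(x$stepwise)) {
    for (dir in names(x$stepwise[[oc]])) {
      sw <- x$stepwise[[oc]][[dir]]
      if (!is.null(sw)) {
        cat(sprintf("  %s %s stepwise: %s (AIC %.2f)\n", oc, dir,
                    if (length(sw$selected))
                      paste(sw$selected, collapse = ", ")
                    else "(none)", sw$aic))
      }
    }
  }
  invisible(x)
}
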