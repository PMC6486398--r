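# habitatr

Habitat imaging of rim-enhancing brain tumors from multiparametric MRI.

Glioblastomas are spatially heterogeneous: within the contrast-enhancing
(CE) lesion, poorly perfused regions can develop an acidic,
treatment-resistant microenvironment. `habitatr` delineates and
characterizes two such *low-perfusion compartments* per subject and
carries them into cohort-level survival analysis. It is aimed at imaging
researchers working with co-registered parametric maps (ADC, rCBV,
diffusion-tensor eigenvalues), ROI masks, 2D-MRSI metabolite ratios and a
clinical outcomes table.

## The method

Per subject, with all maps normalized to the contralateral
normal-appearing white matter (NAWM) mean:

1. Pool ADC and rCBV voxel values within the CE ROI and take per-subject
   quartiles (linear-interpolation definition).
2. Threshold: `rCBV_L` = lowest rCBV quartile (low perfusion); `ADC_L` /
   `ADC_H` = lowest / highest ADC quartile (restricted / elevated
   diffusivity).
3. Intersect: `ADC_L-rCBV_L = ADC_L ∩ rCBV_L` and
   `ADC_H-rCBV_L = ADC_H ∩ rCBV_L`; remaining CE voxels form the
   contrast-enhancing control (CEC). The three regions partition CE
   exactly. Absolute volumes (cm³) and proportional volumes (% of CE) are
   reported.
4. MRSI: spectroscopic voxels completely inside the tumor and passing
   spectral quality are weighted by the fraction of their block covered by
   a compartment; the compartment's metabolite value (Lac/Cr, ML9/Cr) is
   the weight-renormalized mean `Σ wᵢ rᵢ`.
5. DTI: the tensor decomposes into `p = √3·MD` and
   `q = √(Σ(λᵢ − MD)²)`; the maximal extent of p/q abnormality beyond the
   CE surface classifies the invasive phenotype (minimal / localized /
   diffuse).
6. Cohort: rank tests with Benjamini–Hochberg control, Spearman
   correlations, maximally-selected log-rank cutpoints, Kaplan–Meier /
   log-rank, and multivariate plus forward/backward stepwise-AIC Cox
   models for PFS and OS.

A synthetic phantom and cohort generator with planted ground truth makes
the whole pipeline testable end to end without any patient data. See the
methods vignette (`vignettes/habitat-imaging.Rmd`) for assumptions,
parameter defaults and design decisions.

## Worked example

```r
library(habitatr)

b <- make_phantom(phantom_spec(seed = 1))   # synthetic subject bundle
report <- run_subject_bundle(b)
report$volumes
#> # A tibble: 7 × 4
#>   roi          n_voxels abs_volume_cm3 prop_of_ce_pct
#>   <chr>           <int>          <dbl>          <dbl>
#> 1 rCBV_L           2805          2.80           25.0
#> 2 ADC_L            2805          2.80           25.0
#> 3 ADC_H            2805          2.80           25.0
#> 4 ADC_L-rCBV_L      981          0.981           8.75
#> 5 ADC_H-rCBV_L     1823          1.82           16.3
#> 6 CEC              8413          8.41           75.0
#> 7 CE              11217         11.2           100
```

Each quartile mask holds 25% of the 11217 CE voxels; the two compartments
(8.75% and 16.3% of CE) plus the control partition CE exactly. The
recovered low-perfusion core matches the planted one:

```r
dice(report$habitat$masks$rCBV_L, b$truth$core)
#> [1] 0.9998217
```

Metabolite values are coverage-weighted means over eligible spectroscopic
voxels (both compartments sit on mixed blocks here, hence similar values;
NAWM reflects the planted baseline):

```r
dplyr::filter(report$metabolites, metabolite == "lac_cr")
#> # A tibble: 4 × 4
#>   compartment  metabolite value n_voxels
#> 1 ADC_L-rCBV_L lac_cr     0.899        2
#> 2 ADC_H-rCBV_L lac_cr     0.898        2
#> 3 CEC          lac_cr     0.801        1
#> 4 NAWM         lac_cr     0.305        3

report$phenotype
#>   phenotype p_margin_mm q_margin_mm
#> 1 minimal          6.40           0
```

Cohort analysis on a simulated 80-subject cohort with planted effects on
lesion volume, resection extent and MGMT status:

```r
co <- make_cohort(cohort_spec(seed = 1))
tidy(surv_cutpoint(co, "os_days", "os_event", "ce_vol"))
#> # A tibble: 1 × 8
#>   covariate threshold cutpoint_value statistic n_low n_high p_logrank ...
#> 1 ce_vol         85.1           84.4      2.44    71      9 0.0000984

sw <- stepwise_cox(co, "os_days", "os_event",
                   c("age", "sex", "eor", "mgmt", "idh1", "ce_vol"),
                   direction = "backward")
sw
#> <stepwise_cox> backward  selected: eor, ce_vol  AIC = 375.844
```

The backward AIC search keeps the two covariates with planted hazard
effects strong enough to be detectable at n = 80. `tidy()` and `glance()`
return hazard ratios with 95% confidence intervals and model summaries;
`autoplot()` draws compartment overlays and Kaplan–Meier curves.

A command-line front end over the same functions ships in
`inst/cli/habitatseg.R` (subcommands `simulate`, `normalize`, `habitats`,
`survival`).

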