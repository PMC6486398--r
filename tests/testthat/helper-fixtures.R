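# small in-code fixtures and independent oracles used across the suite

# mask with given linear indices set
mk_mask <- function(dims, idx = integer(), label = "other", vd = c(1, 1, 1)) {
  a <- array(FALSE, dims)
  a[idx] <- TRUE
  roi_mask(a, label = label, voxel_dims = vd)
}

mk_vol <- function(values, dims = dim(values), vd = c(1, 1, 1),
                   modality = "other") {
  parametric_volume(array(values, dims), voxel_dims = vd,
                    modality = modality)
}

# compact phantom used wherever many phantoms are generated
mini_spec <- function(seed, ...) {
  phantom_spec(dim = c(40, 40, 24), radii_mm = c(10, 9, 7),
               mrsi_block = c(8, 8), seed = seed, ...)
}

# hand implementation of the Benjamini-Hochberg step-up rule
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(n / (n:1) * p[o]))
  adj[ro]
}

# per-image-voxel accumulation oracle for the coverage-weighted metabolite
oracle_weighted_metabolite <- function(mask, grid, tumor, metabolite) {
  dims <- attr(grid, "image_dim")
  owner <- array(0L, dims)
  bsize <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    xs <- grid$x0[i]:(grid$x0[i] + grid$nx[i] - 1L)
    ys <- grid$y0[i]:(grid$y0[i] + grid$ny[i] - 1L)
    zs <- grid$z0[i]:(grid$z0[i] + grid$nz[i] - 1L)
    owner[xs, ys, zs] <- i
    bsize[i] <- length(xs) * length(ys) * length(zs)
  }
  in_mask <- tabulate(owner[mask$data & owner > 0], nbins = nrow(grid))
  in_tumor <- tabulate(owner[tumor$data & owner > 0], nbins = nrow(grid))
  contained <- in_tumor == bsize
  cov <- in_mask / bsize
  elig <- contained & grid$quality_pass & cov > 0
  if (!any(elig)) return(NA_real_)
  w <- cov[elig] / sum(cov[elig])
  sum(w * grid[[metabolite]][elig])
}

# scalar-by-scalar p/q oracle built on mean/deviation identities
oracle_pq <- function(l) {
  md <- mean(l)
  c(p = sqrt(3) * md, q = sqrt(sum((l - md)^2)))
}

# exhaustive maximally-selected log-rank oracle; scores from survfit's
# Nelson-Aalen cumulative hazard
oracle_cutpoint <- function(time, event, x, minprop = 0.1) {
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, ctype = 1)
  ch <- stats::stepfun(sf$time, c(0, sf$cumhaz))(time)
  a <- event - ch
  n <- length(a)
  abar <- mean(a)
  ss <- sum((a - abar)^2)
  ux <- sort(unique(x))
  out <- NULL
  for (c0 in ux[-length(ux)]) {
    m <- sum(x <= c0)
    if (m / n < minprop || (n - m) / n < minprop) next
    std <- abs(sum(a[x <= c0]) - m * abar) /
      sqrt(m * (n - m) / (n * (n - 1)) * ss)
    out <- rbind(out, c(cut = c0, std = std))
  }
  if (is.null(out)) return(NULL)
  as.data.frame(out)
}

# exhaustive best-AIC subset search over candidate covariates
oracle_best_subset <- function(data, time, event, candidates) {
  df <- data[stats::complete.cases(data[, c(time, event, candidates)]), ]
  y <- survival::Surv(df[[time]], df[[event]])
  subsets <- unlist(lapply(0:length(candidates), function(k)
    utils::combn(candidates, k, simplify = FALSE)), recursive = FALSE)
  aics <- vapply(subsets, function(s) {
    if (length(s) == 0) {
      f <- survival::coxph(y ~ 1, data = df)
      return(-2 * f$loglik[1])
    }
    f <- survival::coxph(stats::reformulate(s, response = "y"), data = df,
                         ties = "efron")
    -2 * f$loglik[2] + 2 * length(stats::coef(f))
  }, numeric(1))
  list(set = subsets[[which.min(aics)]], aic = min(aics))
}

# simulated two-arm exponential survival data
sim_surv_cohort <- function(n, beta = 0, censor_ratio = 0, h0 = 0.002,
                            x = NULL) {
  if (is.null(x)) x <- stats::rbinom(n, 1, 0.5)
  h <- h0 * exp(beta * x)
  t_ev <- stats::rexp(n, h)
  t_cn <- if (censor_ratio > 0) stats::rexp(n, h * censor_ratio)
          else rep(Inf, n)
  data.frame(x = x, time = pmin(t_ev, t_cn),
             event = as.integer(t_ev <= t_cn))
}
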