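#' Compare a continuous variable between groups
#'
#' Thin tidy wrappers over the standard tests used for cohort tables:
#' Welch's two-sample t-test for approximately normal continuous
#' variables, Wilcoxon's rank-sum test for two skewed groups (volumes,
#' metabolite ratios), and Kruskal-Wallis for three or more groups.
#'
#' @param data A data frame.
#' @param value Name of the continuous column.
#' @param group Name of the grouping column.
#' @param method `"welch"`, `"wilcoxon"` or `"kruskal"`.
#' @return A one-row tibble: `method`, `statistic`, `p_value`, `n_groups`.
#' @export
group_compare <- function(data, value, group,
                          method = c("welch", "wilcoxon", "kruskal")) {
  method <- match.arg(method)
  df <- data[!is.na(data[[value]]) & !is.na(data[[group]]), ]
  g <- factor(df[[group]])
  v <- df[[value]]
  sizes <- table(g)
  if (any(sizes == 0) || length(sizes) < 2) {
    stop("Need at least two non-empty groups.", call. = FALSE)
  }
  if (method %in% c("welch", "wilcoxon") && length(sizes) != 2) {
    stop("`", method, "` requires exactly two groups, got ", length(sizes),
         call. = FALSE)
  }
  res <- switch(method,
    welch = {
      if (any(sizes < 2)) stop("Welch t-test needs n >= 2 per group.",
                               call. = FALSE)
      t <- stats::t.test(v ~ g)               # Welch is the default
      c(statistic = unname(t$statistic), p = t$p.value)
    },
    wilcoxon = {
      w <- suppressWarnings(stats::wilcox.test(v ~ g, exact = FALSE,
                                               correct = TRUE))
      c(statistic = unname(w$statistic), p = w$p.value)
    },
    kruskal = {
      k <- stats::kruskal.test(v ~ g)
      c(statistic = unname(k$statistic), p = k$p.value)
    }
  )
  tibble::tibble(method = method, statistic = res[["statistic"]],
                 p_value = res[["p"]], n_groups = length(sizes))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values, monotone in rank order and capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed,
#'   propagated).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p-values must lie in [0, 1].", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Spearman rank correlation
#'
#' @param x,y Paired numeric vectors (pairs with `NA` dropped), `n >= 3`.
#' @return A one-row tibble: `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("Need at least 3 complete pairs.", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Spearman correlation is undefined for a constant vector.",
         call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x))
}

# log-rank (Nelson-Aalen) scores a_i = event_i - cumhaz(t_i)
logrank_scores <- function(time, event) {
  dt <- sort(unique(time[event == 1]))
  if (length(dt) == 0) return(rep(0, length(time)))
  haz <- vapply(dt, function(s) sum(time == s & event == 1) / sum(time >= s),
                numeric(1))
  ch <- cumsum(haz)
  idx <- findInterval(time, dt)      # number of distinct event times <= t_i
  event - ifelse(idx == 0, 0, ch[pmax(idx, 1L)])
}

#' Maximally selected log-rank cutpoint
#'
#' Dichotomizes a continuous covariate at the value maximizing the
#' standardized two-sample log-rank statistic over all admissible splits
#' (each side keeps at least a `minprop` fraction of subjects) — the same
#' construction as `survminer::surv_cutpoint`. Subjects with covariate at
#' or below the cutpoint form the `"low"` group. The reported `threshold`
#' is the midpoint between the optimal split value and the next distinct
#' covariate value; `cutpoint_value` is the split value itself.
#'
#' The naive p-value from the log-rank test after dichotomization is
#' anti-conservative because the split maximizes the statistic; an
#' optional permutation-corrected p-value (`n_perm > 0`) permutes the
#' covariate and re-maximizes.
#'
#' @param data Data frame.
#' @param time,event,covariate Column names (times > 0; event 0/1).
#' @param minprop Minimum fraction of subjects on each side of the split.
#' @param n_perm Number of permutations for the corrected p-value
#'   (0 = skip).
#' @return An object of class `cutpoint_result`: list with `threshold`,
#'   `cutpoint_value`, `statistic` (standardized log-rank at the optimum),
#'   `groups` (factor low/high per subject of the complete cases),
#'   `n_low`, `n_high`, `p_logrank` (naive), `p_permutation` (or `NA`),
#'   `candidates` (tibble of all admissible splits and their statistics).
#' @export
surv_cutpoint <- function(data, time, event, covariate, minprop = 0.1,
                          n_perm = 0) {
  df <- data[stats::complete.cases(data[, c(time, event, covariate)]), ]
  tt <- df[[time]]; ee <- df[[event]]; xx <- df[[covariate]]
  n <- length(tt)
  if (n < 10) stop("Need at least 10 complete cases.", call. = FALSE)
  if (length(unique(xx)) < 2) {
    stop("Covariate is constant; no split exists.", call. = FALSE)
  }
  a <- logrank_scores(tt, ee)
  abar <- mean(a)
  ss <- sum((a - abar)^2)

  ox <- order(xx)
  xs <- xx[ox]; as_ <- a[ox]
  cum_a <- cumsum(as_)
  ux <- unique(xs)
  m_at <- cumsum(table(factor(xs, levels = ux)))   # m for split "x <= ux"
  cand_m <- as.integer(m_at[-length(m_at)])
  cand_x <- ux[-length(ux)]
  next_x <- ux[-1]
  keep <- (cand_m / n >= minprop) & ((n - cand_m) / n >= minprop)
  if (!any(keep)) stop("No admissible split for minprop = ", minprop,
                       call. = FALSE)
  cand_m <- cand_m[keep]; cand_x <- cand_x[keep]; next_x <- next_x[keep]
  S <- cum_a[cand_m]
  E <- cand_m * abar
  V <- cand_m * (n - cand_m) / (n * (n - 1)) * ss
  std <- abs(S - E) / sqrt(V)
  best <- which.max(std)

  groups <- factor(ifelse(xx <= cand_x[best], "low", "high"),
                   levels = c("low", "high"))
  sd_fit <- survival::survdiff(survival::Surv(tt, ee) ~ groups)
  p_naive <- stats::pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE)

  p_perm <- NA_real_
  if (n_perm > 0) {
    maxstd <- function(xp) {
      oxp <- order(xp); ap <- a[oxp]; xsp <- xp[oxp]
      cum <- cumsum(ap)
      uxp <- unique(xsp)
      mm <- as.integer(cumsum(table(factor(xsp, levels = uxp))))
      mm <- mm[-length(mm)]
      kp <- (mm / n >= minprop) & ((n - mm) / n >= minprop)
      if (!any(kp)) return(0)
      mm <- mm[kp]
      max(abs(cum[mm] - mm * abar) /
            sqrt(mm * (n - mm) / (n * (n - 1)) * ss))
    }
    obs <- std[best]
    exceed <- vapply(seq_len(n_perm),
                     function(i) maxstd(sample(xx)) >= obs, logical(1))
    p_perm <- (sum(exceed) + 1) / (n_perm + 1)
  }

  structure(
    list(threshold = (cand_x[best] + next_x[best]) / 2,
         cutpoint_value = cand_x[best],
         statistic = std[best],
         groups = groups,
         n_low = sum(groups == "low"), n_high = sum(groups == "high"),
         p_logrank = p_naive, p_permutation = p_perm,
         candidates = tibble::tibble(cutpoint_value = cand_x,
                                     n_low = cand_m, statistic = std),
         covariate = covariate, minprop = minprop, n = n),
    class = "cutpoint_result"
  )
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat("<cutpoint_result>", x$covariate, "\n")
  cat(sprintf("  threshold %.4g (split value %.4g), |standardized log-rank| %.3f\n",
              x$threshold, x$cutpoint_value, x$statistic))
  cat(sprintf("  groups: %d low / %d high; naive log-rank p = %.3g\n",
              x$n_low, x$n_high, x$p_logrank))
  invisible(x)
}

#' @export
tidy.cutpoint_result <- function(x, ...) {
  tibble::tibble(covariate = x$covariate, threshold = x$threshold,
                 cutpoint_value = x$cutpoint_value, statistic = x$statistic,
                 n_low = x$n_low, n_high = x$n_high,
                 p_logrank = x$p_logrank, p_permutation = x$p_permutation)
}

#' Kaplan-Meier curves and log-rank test
#'
#' @param data Data frame.
#' @param time,event,group Column names.
#' @return An object of class `km_result`: list with `chisq`, `df`,
#'   `p_value`, the `survfit` object (`fit`) and group sizes.
#' @export
km_logrank <- function(data, time, event, group) {
  df <- data[stats::complete.cases(data[, c(time, event, group)]), ]
  g <- factor(df[[group]])
  if (nlevels(g) < 2) stop("Need at least two groups.", call. = FALSE)
  y <- survival::Surv(df[[time]], df[[event]])
  fit <- survival::survfit(y ~ g)
  if (sum(df[[event]]) == 0) {          # no events: nothing to compare
    chisq <- 0; kdf <- nlevels(g) - 1; nn <- as.vector(table(g))
  } else {
    sd_fit <- survival::survdiff(y ~ g)
    chisq <- sd_fit$chisq; kdf <- length(sd_fit$n) - 1
    nn <- as.vector(sd_fit$n)
  }
  structure(
    list(chisq = chisq, df = kdf,
         p_value = stats::pchisq(chisq, kdf, lower.tail = FALSE),
         fit = fit, n = nn, group = group),
    class = "km_result"
  )
}

#' @export
print.km_result <- function(x, ...) {
  cat("<km_result> log-rank chisq =", signif(x$chisq, 4), "df =", x$df,
      "p =", signif(x$p_value, 3), "\n")
  invisible(x)
}

#' @export
glance.km_result <- function(x, ...) {
  tibble::tibble(statistic = x$chisq, df = x$df, p_value = x$p_value,
                 n = sum(x$n))
}

#' @export
autoplot.km_result <- function(object, ...) {
  s <- summary(object$fit, censored = TRUE)
  df <- tibble::tibble(time = s$time, surv = s$surv,
                       strata = as.character(s$strata),
                       censored = s$n.censor > 0 & s$n.event == 0)
  # prepend t = 0, S = 1 per stratum
  start <- dplyr::distinct(df, .data$strata)
  start$time <- 0; start$surv <- 1; start$censored <- FALSE
  df <- dplyr::arrange(dplyr::bind_rows(start, df), .data$strata,
                       .data$time)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$surv,
                                   colour = .data$strata)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = df[df$censored, ], shape = 3) +
    ggplot2::labs(x = "Time (days)", y = "Survival probability",
                  colour = NULL,
                  subtitle = sprintf("log-rank p = %.3g", object$p_value)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Efron tie handling. Hazard ratios are
#' `exp(coef)` with Wald 95% confidence intervals; model AIC is
#' `-2 logPL + 2k`.
#'
#' @param data Data frame.
#' @param time,event Column names.
#' @param covariates Character vector of covariate column names.
#' @param log_volumes Optional character vector of (volume) covariates to
#'   log-transform (`log(x + 1e-3)`) before fitting.
#' @return An object of class `habitat_cox` wrapping the `coxph` fit, with
#'   `n`, `n_events`, `aic`, `dropped` (complete-case count removed).
#' @export
cox_fit <- function(data, time, event, covariates, log_volumes = NULL) {
  stopifnot(length(covariates) >= 1)
  cols <- c(time, event, covariates)
  df <- data[stats::complete.cases(data[, cols]), cols]
  dropped <- nrow(data) - nrow(df)
  for (v in intersect(log_volumes, covariates)) {
    df[[v]] <- log(df[[v]] + 1e-3)
  }
  for (v in covariates) {
    vv <- df[[v]]
    if ((is.numeric(vv) && stats::sd(vv) == 0) ||
        (!is.numeric(vv) && length(unique(vv)) < 2)) {
      stop("Covariate '", v, "' is constant in the complete cases.",
           call. = FALSE)
    }
  }
  n_events <- sum(df[[event]])
  if (n_events < length(covariates) + 1) {
    stop("Too few events (", n_events, ") for ", length(covariates),
         " covariates.", call. = FALSE)
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time, ", ", event, ") ~ ",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  if (any(is.na(stats::coef(fit)))) {
    warning("Collinear covariates: ",
            paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                  collapse = ", "), call. = FALSE)
  }
  if (!is.null(fit$info) && grepl("infinite", paste(fit$info, collapse = " "))) {
    warning("Possible separation in the Cox fit.", call. = FALSE)
  }
  k <- sum(!is.na(stats::coef(fit)))
  structure(
    list(fit = fit, time = time, event = event, covariates = covariates,
         n = nrow(df), n_events = n_events,
         aic = -2 * fit$loglik[2] + 2 * k, dropped = dropped),
    class = "habitat_cox"
  )
}

#' @export
print.habitat_cox <- function(x, ...) {
  cat("<habitat_cox> n =", x$n, " events =", x$n_events,
      " AIC =", signif(x$aic, 6), "\n")
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.habitat_cox <- function(x, conf_level = 0.95, ...) {
  s <- summary(x$fit, conf.int = conf_level)
  co <- s$coefficients
  ci <- s$conf.int
  tibble::tibble(
    term = rownames(co),
    estimate = co[, "coef"],
    hr = co[, "exp(coef)"],
    conf_low = ci[, 3],
    conf_high = ci[, 4],
    std_error = co[, "se(coef)"],
    p_value = co[, "Pr(>|z|)"]
  )
}

#' @export
glance.habitat_cox <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, aic = x$aic,
                 log_partial_lik = x$fit$loglik[2],
                 concordance = unname(x$fit$concordance["concordance"]),
                 n_dropped = x$dropped)
}

null_cox_aic <- function(df, time, event) {
  fit0 <- survival::coxph(stats::as.formula(
    paste0("survival::Surv(", time, ", ", event, ") ~ 1")), data = df)
  -2 * fit0$loglik[1]
}

#' Stepwise AIC Cox model selection
#'
#' Greedy covariate selection by the Akaike Information Criterion. The
#' forward procedure starts from the null model and repeatedly adds the
#' single covariate giving the largest AIC decrease; the backward
#' procedure starts from the model with all candidates and repeatedly
#' drops the covariate giving the largest decrease. Either stops when no
#' step lowers the AIC. Complete cases over all candidates are used
#' throughout so AICs are comparable across visited models.
#'
#' @param data Data frame.
#' @param time,event Column names.
#' @param candidates Character vector of candidate covariates.
#' @param direction `"forward"` or `"backward"`.
#' @param log_volumes Passed to [cox_fit()].
#' @return An object of class `stepwise_cox`: list with `selected`
#'   (character), `fit` (a `habitat_cox`, or `NULL` when the final model
#'   is empty), `aic`, `trace` (tibble of every step: action, covariate,
#'   AIC), `direction`.
#' @export
stepwise_cox <- function(data, time, event, candidates,
                         direction = c("forward", "backward"),
                         log_volumes = NULL) {
  direction <- match.arg(direction)
  cols <- c(time, event, candidates)
  df <- data[stats::complete.cases(data[, cols]), cols]
  aic_of <- function(set) {
    if (length(set) == 0) null_cox_aic(df, time, event)
    else cox_fit(df, time, event, set, log_volumes = log_volumes)$aic
  }
  current <- if (direction == "forward") character(0) else candidates
  cur_aic <- aic_of(current)
  trace <- list(tibble::tibble(step = 0L, action = "start",
                               covariate = NA_character_, aic = cur_aic))
  step <- 0L
  repeat {
    moves <- if (direction == "forward") setdiff(candidates, current)
             else current
    if (length(moves) == 0) break
    aics <- vapply(moves, function(v) {
      set <- if (direction == "forward") c(current, v) else setdiff(current, v)
      aic_of(set)
    }, numeric(1))
    best <- which.min(aics)
    if (aics[best] >= cur_aic) break
    step <- step + 1L
    current <- if (direction == "forward") c(current, moves[best])
               else setdiff(current, moves[best])
    cur_aic <- aics[best]
    trace[[length(trace) + 1L]] <- tibble::tibble(
      step = step,
      action = if (direction == "forward") "add" else "drop",
      covariate = moves[best], aic = cur_aic)
  }
  final <- if (length(current)) {
    cox_fit(df, time, event, current, log_volumes = log_volumes)
  } else NULL
  structure(
    list(selected = current, fit = final, aic = cur_aic,
         trace = dplyr::bind_rows(trace), direction = direction),
    class = "stepwise_cox"
  )
}

#' @export
print.stepwise_cox <- function(x, ...) {
  cat("<stepwise_cox>", x$direction, " selected:",
      if (length(x$selected)) paste(x$selected, collapse = ", ") else "(none)",
      " AIC =", signif(x$aic, 6), "\n")
  invisible(x)
}

#' @export
tidy.stepwise_cox <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(term = character(), estimate = numeric(),
                          hr = numeric(), conf_low = numeric(),
                          conf_high = numeric(), std_error = numeric(),
                          p_value = numeric()))
  }
  tidy(x$fit)
}

#' @export
glance.stepwise_cox <- function(x, ...) {
  tibble::tibble(direction = x$direction, aic = x$aic,
                 n_selected = length(x$selected),
                 n_steps = max(x$trace$step))
}
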