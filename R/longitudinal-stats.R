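# Longitudinal endpoint statistics.
#
# Time courses are summarized per series as adjusted AUCs (trapezoidal AUC
# divided by the spanned time interval, i.e. the time-average of the
# interpolated curve), then analysed with a repeated-measures model: both
# treatments are applied to cultures of each donor, so the two AUCs of one
# donor are correlated. Compound symmetry is assumed (equal variance, equal
# within-donor correlation); fixed factors are donor status (group),
# treatment, and their interaction. Treatment contrasts within each group are
# tested one-sided on within-subject degrees of freedom, without multiplicity
# adjustment.

#' Adjusted area under the curve
#'
#' Trapezoidal AUC over the day grid divided by the length of the considered
#' time interval (`last - first` day), i.e. the time-average of the
#' piecewise-linear interpolated curve. With `log_transform = TRUE` the
#' natural logarithm is applied to the adjusted AUC value itself (not
#' pointwise to the series).
#'
#' @param days strictly increasing numeric vector (>= 2 time points).
#' @param values endpoint values, one per day.
#' @param log_transform apply `log()` to the adjusted AUC.
#' @return an object of class `"adjusted_auc"`: list with `value`,
#'   `span_days`, `log_transformed`.
#' @export
adjusted_auc <- function(days, values, log_transform = FALSE) {
  stop_if(length(days) < 2L, "adjusted AUC needs at least two time points")
  stop_if(length(days) != length(values), "'days' and 'values' lengths differ")
  stop_if(any(diff(days) <= 0), "'days' must be strictly increasing")
  stop_if(!all(is.finite(days)) || !all(is.finite(values)),
          "'days' and 'values' must be finite")
  check_flag(log_transform, "log_transform")
  span <- days[length(days)] - days[1]
  val <- pracma::trapz(days, values) / span
  if (log_transform) {
    stop_if(val <= 0, "adjusted AUC must be positive for log transformation")
    val <- log(val)
  }
  structure(list(value = val, span_days = span, log_transformed = log_transform),
            class = "adjusted_auc")
}

#' @export
print.adjusted_auc <- function(x, ...) {
  cat(sprintf("adjusted %sAUC over %g days: %.6g\n",
              if (x$log_transformed) "log " else "", x$span_days, x$value))
  invisible(x)
}

#' Collapse a tidy longitudinal table to per-series adjusted AUCs
#'
#' @param data data.frame with columns `subject`, `group`, `treatment`,
#'   `endpoint`, `day`, `value` (one endpoint or several).
#' @param log_transform `TRUE`/`FALSE`, or a named logical vector per
#'   endpoint.
#' @return data.frame with one row per (subject, group, treatment, endpoint)
#'   and column `auc`.
#' @export
adjusted_auc_table <- function(data, log_transform = FALSE) {
  need <- c("subject", "group", "treatment", "endpoint", "day", "value")
  stop_if(!all(need %in% names(data)),
          paste("'data' must have columns", paste(need, collapse = ", ")))
  key <- interaction(data$subject, data$group, data$treatment, data$endpoint,
                     drop = TRUE)
  pieces <- lapply(split(data, key), function(d) {
    d <- d[order(d$day), ]
    lt <- if (length(log_transform) == 1L && is.null(names(log_transform)))
      log_transform else isTRUE(log_transform[[as.character(d$endpoint[1])]])
    data.frame(subject = d$subject[1], group = d$group[1],
               treatment = d$treatment[1], endpoint = d$endpoint[1],
               auc = adjusted_auc(d$day, d$value, lt)$value,
               log_transformed = lt)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$endpoint, out$group, out$subject, out$treatment), ]
}

#' Fold change from comparative-Ct adjusted AUCs
#'
#' qPCR delta-Ct values (`Ct_target - Ct_control`) decrease when expression
#' increases, so the fold change between two adjusted-AUC delta-Ct summaries
#' is `2^|auc_air - auc_smoke|`, an *increase* when the smoke AUC is the
#' lower one.
#'
#' @param auc_air,auc_smoke adjusted AUCs of the delta-Ct series under air
#'   control and smoke exposure.
#' @return list with `fold` (>= 1) and `direction` (`"increase"`,
#'   `"decrease"` or `"no change"`).
#' @export
fold_change_from_auc <- function(auc_air, auc_smoke) {
  check_number(auc_air, "auc_air"); check_number(auc_smoke, "auc_smoke")
  fold <- 2^abs(auc_air - auc_smoke)
  direction <- if (auc_smoke < auc_air) "increase"
               else if (auc_smoke > auc_air) "decrease" else "no change"
  list(fold = fold, direction = direction)
}

#' One-sided hypothesis registry for smoke-exposure endpoints
#'
#' Expected direction of the smoke-vs-air contrast (`mu_CS - mu_Air`) per
#' endpoint, together with whether the endpoint's adjusted AUC is analysed on
#' the log scale. A *decrease* is expected under smoke for the (log) AUC of
#' active-cilia area, the AUC of CBF, the log AUC of TEER and the delta-Ct
#' AUCs of KRT5, KRT14 and MUC5AC (lower delta-Ct = induction of these
#' markers); an *increase* is expected for the delta-Ct AUCs of SCGB1A1 and
#' FOXJ1 (their expression drops).
#'
#' @return data.frame with columns `endpoint`, `direction`, `log_transform`.
#' @export
default_direction_registry <- function() {
  data.frame(
    endpoint = c("active_area", "cbf", "teer",
                 "KRT5_dCt", "KRT14_dCt", "MUC5AC_dCt",
                 "SCGB1A1_dCt", "FOXJ1_dCt"),
    direction = c("lower", "lower", "lower", "lower", "lower", "lower",
                  "upper", "upper"),
    log_transform = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
}

#' Fit the compound-symmetry repeated-measures model to adjusted AUCs
#'
#' One adjusted-AUC value per (subject, treatment), subjects nested in
#' groups, both treatments observed on every subject (no imputation). The
#' model has fixed cell means `mu[group, treatment]` and a compound-symmetry
#' covariance within subject (variance `sigma2`, correlation `rho`). For
#' this balanced paired two-treatment design the REML solution coincides
#' with closed-form moment estimators, which are used here: the
#' within-subject variance component is estimated from the per-subject
#' treatment differences, the between-subject component from the per-subject
#' means. Residual degrees of freedom are partitioned into between-subject
#' (`N - G`, used by the group effect) and within-subject (`N - G`, used by
#' treatment and interaction effects), `N` subjects in `G` groups.
#'
#' @param data data.frame with columns `subject`, `group`, `treatment` and
#'   the response column `value_col`.
#' @param value_col name of the response column (default `"auc"`).
#' @param exposed,control treatment labels; the reported contrast is
#'   `exposed - control` (default `CS - Air`).
#' @return an object of class `"rm_fit"` with cell means, variance
#'   components, the degree-of-freedom partition and per-group contrasts.
#' @export
fit_repeated_measures <- function(data, value_col = "auc",
                                  exposed = "CS", control = "Air") {
  need <- c("subject", "group", "treatment", value_col)
  stop_if(!all(need %in% names(data)),
          paste("'data' must have columns", paste(need, collapse = ", ")))
  data$subject <- as.character(data$subject)
  data$group <- as.character(data$group)
  data$treatment <- as.character(data$treatment)
  trts <- sort(unique(data$treatment))
  stop_if(!setequal(trts, c(exposed, control)),
          sprintf("treatments must be exactly {'%s', '%s'}, got {%s}",
                  exposed, control, paste(trts, collapse = ", ")))
  y <- data[[value_col]]
  stop_if(!is.numeric(y) || !all(is.finite(y)),
          sprintf("'%s' must be finite numeric", value_col))

  # paired-design validation: each subject has exactly one row per treatment
  tab <- table(data$subject, data$treatment)
  bad <- rownames(tab)[rowSums(tab == 1) != 2L | rowSums(tab) != 2L]
  stop_if(length(bad) > 0,
          paste("each subject needs exactly one observation per treatment;",
                "offending subject(s):", paste(bad, collapse = ", ")))
  grp_of <- tapply(data$group, data$subject, function(g) {
    stop_if(length(unique(g)) != 1, "a subject appears in more than one group")
    g[1]
  })
  groups <- sort(unique(data$group))
  G <- length(groups); N <- length(grp_of)
  stop_if(N <= G, "need more subjects than groups to estimate variances")

  y_exp <- setNames(y[data$treatment == exposed], data$subject[data$treatment == exposed])
  y_ctl <- setNames(y[data$treatment == control], data$subject[data$treatment == control])
  subj <- names(grp_of)
  d <- y_exp[subj] - y_ctl[subj]               # within-subject differences
  msub <- (y_exp[subj] + y_ctl[subj]) / 2      # subject means

  cell_means <- matrix(NA_real_, G, 2, dimnames = list(groups, c(control, exposed)))
  for (g in groups) {
    sg <- subj[grp_of == g]
    cell_means[g, control] <- mean(y_ctl[sg])
    cell_means[g, exposed] <- mean(y_exp[sg])
  }

  center <- function(v) v - ave(v, grp_of[names(v)])
  ss_d <- sum(center(d)^2)                     # within-subject sums of squares
  ss_m <- sum(center(msub)^2)
  df_within <- N - G
  df_between <- N - G
  var_d <- ss_d / df_within                    # = 2 * sigma2 * (1 - rho)
  var_m <- ss_m / df_between                   # = sigma2 * (1 + rho) / 2
  sigma2 <- (var_d / 2 + 2 * var_m) / 2
  rho <- if (sigma2 > 0) (2 * var_m - var_d / 2) / (2 * sigma2) else NA_real_

  n_g <- table(grp_of)[groups]
  contrasts <- data.frame(
    group = groups,
    estimate = cell_means[, exposed] - cell_means[, control],
    se = sqrt(var_d / as.numeric(n_g)),
    df = df_within, row.names = NULL)

  structure(list(cell_means = cell_means, sigma2 = sigma2, rho = rho,
                 df_between = df_between, df_within = df_within,
                 contrasts = contrasts, exposed = exposed, control = control,
                 n_subjects = as.numeric(n_g), groups = groups,
                 differences = d, value_col = value_col),
            class = "rm_fit")
}

#' @export
print.rm_fit <- function(x, ...) {
  cat("Compound-symmetry repeated-measures fit (paired treatments)\n")
  cat(sprintf("  %d subjects in %d group(s); response '%s'\n",
              sum(x$n_subjects), length(x$groups), x$value_col))
  cat("  cell means:\n")
  print(round(x$cell_means, 4))
  cat(sprintf("  sigma^2 = %.4g, rho = %.3f; df between/within = %d/%d\n",
              x$sigma2, x$rho, x$df_between, x$df_within))
  invisible(x)
}

#' @export
coef.rm_fit <- function(object, ...) {
  cm <- object$cell_means
  setNames(as.vector(cm),
           as.vector(outer(rownames(cm), colnames(cm), paste, sep = ":")))
}

#' @export
summary.rm_fit <- function(object, ...) {
  ct <- object$contrasts
  ct$t <- ifelse(ct$se > 0, ct$estimate / ct$se,
                 ifelse(ct$estimate == 0, NaN, sign(ct$estimate) * Inf))
  ct$p_two_sided <- 2 * pt(-abs(ct$t), ct$df)
  structure(list(fit = object, contrast_table = ct), class = "summary.rm_fit")
}

#' @export
print.summary.rm_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  treatment contrasts (%s - %s), two-sided:\n",
              x$fit$exposed, x$fit$control))
  print(x$contrast_table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' One-sided treatment contrast from a repeated-measures fit
#'
#' Tests `mu[group, exposed] - mu[group, control]` against zero in the
#' direction registered for the endpoint (`"lower"`: H1 is a decrease under
#' exposure; `"upper"`: an increase), using a t distribution on the
#' within-subject degrees of freedom. P-values are not adjusted for
#' multiplicity.
#'
#' @param fit an `"rm_fit"`.
#' @param group group whose contrast is tested.
#' @param direction `"lower"` or `"upper"`; if omitted, looked up by
#'   `endpoint` in `registry`.
#' @param endpoint endpoint name for the registry lookup.
#' @param registry direction registry, see [default_direction_registry()].
#' @return an object of class `"contrast_result"`: list with `estimate`,
#'   `se`, `df`, `t`, `p_one_sided`, `direction`, `group`. With zero
#'   estimated variance the t statistic is `+-Inf` (p of 0 or 1) for a
#'   non-zero estimate and undefined (`NA`) for a zero estimate.
#' @export
test_one_sided <- function(fit, group, direction = NULL, endpoint = NULL,
                           registry = default_direction_registry()) {
  stop_if(!inherits(fit, "rm_fit"), "'fit' must come from fit_repeated_measures()")
  stop_if(!group %in% fit$groups,
          sprintf("group '%s' not in the fit (has: %s)", group,
                  paste(fit$groups, collapse = ", ")))
  if (is.null(direction)) {
    stop_if(is.null(endpoint), "provide 'direction' or a registered 'endpoint'")
    hit <- registry$direction[registry$endpoint == endpoint]
    stop_if(length(hit) != 1,
            sprintf("endpoint '%s' is not in the direction registry", endpoint))
    direction <- hit
  }
  stop_if(!direction %in% c("lower", "upper"),
          "'direction' must be 'lower' or 'upper'")
  row <- fit$contrasts[fit$contrasts$group == group, ]
  t_stat <- if (row$se > 0) row$estimate / row$se
            else if (row$estimate == 0) NA_real_
            else sign(row$estimate) * Inf
  p <- if (is.na(t_stat)) NA_real_
       else if (direction == "lower") pt(t_stat, row$df)
       else pt(t_stat, row$df, lower.tail = FALSE)
  structure(list(estimate = row$estimate, se = row$se, df = row$df,
                 t = t_stat, p_one_sided = p, direction = direction,
                 group = group, exposed = fit$exposed, control = fit$control),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("%s: %s - %s = %.4g (SE %.4g, df %d)\n", x$group, x$exposed,
              x$control, x$estimate, x$se, x$df))
  cat(sprintf("  one-sided (%s) t = %.4g, p = %.4g\n", x$direction, x$t,
              x$p_one_sided))
  invisible(x)
}
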