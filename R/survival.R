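#' Kaplan-Meier survival curves per pseudotime group
#'
#' Product-limit estimate of the survival function for each group;
#' censored subjects leave the risk set without contributing an event
#' step, and at tied times events are processed before censorings.
#'
#' @param data Data frame with one row per patient.
#' @param time,event,group Unquoted column names for the follow-up time
#'   (>= 0), the 0/1 event flag, and (optionally) the grouping; omit
#'   `group` for a single pooled curve.
#' @return A `km_fit` tibble with `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `estimate`, carrying the underlying
#'   [survival::survfit()] object as attribute `survfit`.
#' @export
#' @examples
#' d <- data.frame(t = c(1, 2, 3), e = c(1, 1, 0))
#' km_fit(d, t, e)
km_fit <- function(data, time, event, group = NULL) {
  t <- dplyr::pull(data, {{ time }})
  e <- dplyr::pull(data, {{ event }})
  g_quo <- enquo(group)
  g <- if (quo_is_null(g_quo)) factor(rep("all", length(t)))
       else factor(dplyr::pull(data, !!g_quo))
  if (any(t < 0, na.rm = TRUE)) abort("Negative survival times.")
  keep <- !is.na(t) & !is.na(e) & !is.na(g)
  t <- t[keep]; e <- e[keep]; g <- droplevels(g[keep])
  if (!length(t)) abort("No complete survival records.")
  sf <- survival::survfit(survival::Surv(t, e) ~ g)
  grp <- if (is.null(sf$strata)) {
    rep(levels(g)[1], length(sf$time))
  } else {
    rep(sub("^g=", "", names(sf$strata)), sf$strata)
  }
  out <- tibble(
    group = grp,
    time = sf$time,
    n_risk = sf$n.risk,
    n_event = sf$n.event,
    n_censor = sf$n.censor,
    estimate = sf$surv
  )
  structure(out, class = c("km_fit", class(out)), survfit = sf)
}

#' Log-rank test across pseudotime groups
#'
#' k-group Mantel-Haenszel log-rank test; the statistic is referred to a
#' chi-square distribution with `k - 1` degrees of freedom.
#'
#' @inheritParams km_fit
#' @return One-row tibble with `statistic`, `df`, `p_value`, `n`.
#' @export
logrank_test <- function(data, time, event, group) {
  t <- dplyr::pull(data, {{ time }})
  e <- dplyr::pull(data, {{ event }})
  g <- factor(dplyr::pull(data, {{ group }}))
  keep <- !is.na(t) & !is.na(e) & !is.na(g)
  t <- t[keep]; e <- e[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2) abort("Log-rank needs at least 2 groups.")
  if (any(t < 0)) abort("Negative survival times.")
  sd <- survival::survdiff(survival::Surv(t, e) ~ g)
  df <- nlevels(g) - 1
  tibble(
    statistic = unname(sd$chisq),
    df = df,
    p_value = pchisq(sd$chisq, df, lower.tail = FALSE),
    n = length(t)
  )
}

#' Multivariate Cox model over pseudotime group, COO and IPI
#'
#' Cox proportional-hazards regression of the chosen endpoint on the
#' pseudotime group plus optional cell-of-origin and IPI risk class, with
#' Efron handling of tied event times. Categorical covariates are
#' dummy-coded against the conventional references: `low` pseudotime,
#' `GCB`, `low` IPI. Used to check that the pseudotime grouping retains
#' prognostic value alongside the established covariates.
#'
#' @param data Data frame with one row per patient.
#' @param time,event,group Unquoted columns as in [km_fit()]; `group` is
#'   required here.
#' @param coo,ipi Optional unquoted columns with the COO class and IPI
#'   risk class.
#' @return A `cox_fit` object wrapping the [survival::coxph()] fit;
#'   `tidy()` gives per-level hazard ratios with 95% confidence intervals
#'   and Wald p-values, `glance()` the model-level summary.
#' @export
cox_multivariate <- function(data, time, event, group, coo = NULL, ipi = NULL) {
  df <- tibble(
    .time = dplyr::pull(data, {{ time }}),
    .event = dplyr::pull(data, {{ event }}),
    group = dplyr::pull(data, {{ group }})
  )
  df$group <- relevel_if_present(factor(df$group), "low")
  coo_quo <- enquo(coo); ipi_quo <- enquo(ipi)
  if (!quo_is_null(coo_quo)) {
    df$coo <- relevel_if_present(factor(dplyr::pull(data, !!coo_quo)), "GCB")
  }
  if (!quo_is_null(ipi_quo)) {
    df$ipi <- relevel_if_present(factor(dplyr::pull(data, !!ipi_quo)), "low")
  }
  df <- df[stats::complete.cases(df), ]
  if (any(df$.time < 0)) abort("Negative survival times.")
  if (sum(df$.event) == 0) abort("No events in the data.")
  covars <- setdiff(names(df), c(".time", ".event"))
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~", paste(covars, collapse = " + ")
  ))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  n_coef <- length(stats::coef(fit))
  if (nrow(df) < 10 * n_coef) {
    warn(paste0("Only ", nrow(df), " complete cases for ", n_coef,
                " coefficients; estimates may be unstable."))
  }
  if (any(is.na(stats::coef(fit)))) {
    abort("Cox model did not converge (singular or separated covariate).")
  }
  structure(list(fit = fit, data = df), class = "cox_fit")
}

relevel_if_present <- function(f, ref) {
  if (ref %in% levels(f)) stats::relevel(f, ref = ref) else f
}

#' @export
print.cox_fit <- function(x, ...) {
  print(tidy(x))
  invisible(x)
}

#' Per-level hazard ratios of a Cox fit
#'
#' @param x A `cox_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate` (log hazard ratio), `hr`,
#'   `conf_low`, `conf_high` (95% interval on the HR scale), `p_value`.
#' @export
tidy.cox_fit <- function(x, ...) {
  s <- summary(x$fit)
  co <- s$coefficients
  ci <- s$conf.int
  tibble(
    term = rownames(co),
    estimate = co[, "coef"],
    hr = co[, "exp(coef)"],
    conf_low = ci[, "lower .95"],
    conf_high = ci[, "upper .95"],
    p_value = co[, "Pr(>|z|)"]
  )
}

#' Model-level summary of a Cox fit
#'
#' @param x A `cox_fit`.
#' @param ... Unused.
#' @return One-row tibble with `n`, `n_event`, `logrank_p` (score test),
#'   `wald_p`, `concordance`.
#' @export
glance.cox_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    n = s$n,
    n_event = s$nevent,
    logrank_p = unname(s$sctest["pvalue"]),
    wald_p = unname(s$waldtest["pvalue"]),
    concordance = unname(s$concordance["C"])
  )
}

#' Proportional-hazards diagnostic (scaled Schoenfeld residuals)
#'
#' Score test for a zero slope of the scaled Schoenfeld residuals against
#' transformed event time, per covariate and globally — the conventional
#' `cox.zph` check run before interpreting log-rank / Cox results.
#'
#' @param fit A [cox_multivariate()] result.
#' @param time_transform `"km-rank"` (default; Kaplan-Meier transform of
#'   time, `cox.zph`'s `"km"`), `"identity"`, or `"log"`.
#' @return Tibble with `term` (including `GLOBAL`), `chisq`, `df`,
#'   `p_value`.
#' @export
ph_check <- function(fit, time_transform = c("km-rank", "identity", "log")) {
  stopifnot(inherits(fit, "cox_fit"))
  time_transform <- match.arg(time_transform)
  tr <- c(`km-rank` = "km", identity = "identity", log = "log")[time_transform]
  zp <- survival::cox.zph(fit$fit, transform = unname(tr))
  tab <- zp$table
  tibble(
    term = rownames(tab),
    chisq = tab[, "chisq"],
    df = tab[, "df"],
    p_value = tab[, "p"]
  )
}
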