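#' Kaplan-Meier curves per patient group
#'
#' Product-limit survival estimates for each group of a patient
#' stratification (e.g. pattern-high vs pattern-low), with median
#' survival. The median is the earliest time at which the survival
#' function drops to 0.5 or below; when the curve never reaches 0.5 it
#' is undefined (`NA`), never the last observed time.
#'
#' @param records Survival records (tibble with `patient_id`,
#'   `os_months`, `os_event`; see [read_clinical()]).
#' @param groups Named character/factor vector mapping `patient_id` to a
#'   group label, or an unnamed vector aligned with `records` rows.
#' @return A `km_curves` tibble: `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`; attribute `medians` is a tibble of
#'   per-group `n`, `events` and `median_months`.
#' @export
km_curves <- function(records, groups) {
  grp <- align_groups(records, groups)
  if (any(table(grp) < 1) || anyNA(grp)) {
    stop("every record needs a nonempty group label")
  }
  df <- data.frame(time = records$os_months, event = as.integer(records$os_event),
                   group = as.factor(grp))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sm <- summary(fit, censored = TRUE)
  strata <- if (is.null(sm$strata)) rep(levels(df$group)[1], length(sm$time)) else
    sub("^group=", "", as.character(sm$strata))
  curves <- tibble::tibble(
    group = strata, time = sm$time, n_risk = sm$n.risk,
    n_event = sm$n.event, n_censor = sm$n.censor, survival = sm$surv
  )
  tab <- summary(fit)$table
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = 1, dimnames = list(levels(df$group)[1], names(tab)))
  medians <- tibble::tibble(
    group = sub("^group=", "", rownames(tab)),
    n = tab[, "records"], events = tab[, "events"],
    median_months = unname(tab[, "median"])
  )
  structure(curves, class = c("km_curves", class(curves)), medians = medians)
}

#' Per-group KM medians
#'
#' @param curves A `km_curves` object.
#' @return The medians tibble stored on the curves.
#' @export
km_medians <- function(curves) attr(curves, "medians")

#' Step plot of Kaplan-Meier curves
#'
#' @param object A `km_curves` object.
#' @param ... Unused.
#' @return A ggplot of the per-group survival step functions.
#' @method autoplot km_curves
#' @export
autoplot.km_curves <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(group = unique(object$group), time = 0, survival = 1),
    tibble::as_tibble(object)[c("group", "time", "survival")]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months", y = "overall survival") +
    ggplot2::theme_minimal()
}

#' Two-group log-rank test
#'
#' Standard two-sided log-rank chi-square test (1 degree of freedom) for
#' a difference in survival between two patient groups. Symmetric under
#' relabeling the groups.
#'
#' @inheritParams km_curves
#' @return A one-row tibble: `statistic`, `p_value`, `n1`, `n2`,
#'   `events`. `p_value` is `NA` when no events occurred.
#' @export
logrank <- function(records, groups) {
  grp <- align_groups(records, groups)
  labs <- unique(grp)
  if (length(labs) != 2) stop("logrank needs exactly two groups; got ", length(labs))
  events <- sum(records$os_event)
  if (events == 0) {
    return(tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                          n1 = sum(grp == labs[1]), n2 = sum(grp == labs[2]),
                          events = 0L))
  }
  df <- data.frame(time = records$os_months, event = as.integer(records$os_event),
                   group = grp)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  tibble::tibble(
    statistic = sd$chisq,
    p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
    n1 = sum(grp == labs[1]), n2 = sum(grp == labs[2]),
    events = as.integer(events)
  )
}

#' Cox proportional-hazards fit with concordance
#'
#' Univariate (pattern-high indicator) or bivariate (adding tumor stage,
#' encoded ordinally I-IV as 1-4) Cox model with Efron handling of tied
#' event times, reporting hazard ratios, 95% confidence intervals and
#' Harrell's concordance index.
#'
#' @param records Survival records; must contain `stage` when it is used.
#' @param pattern_high Pattern-carrier status (logical/0-1) or a numeric
#'   risk score, aligned with records or named by `patient_id`.
#' @param with_stage Also include ordinal stage as a covariate.
#' @return A `cox_fit` object wrapping the `survival::coxph` fit.
#' @export
cox_fit <- function(records, pattern_high, with_stage = FALSE) {
  ph <- align_groups(records, pattern_high)
  ph <- as.numeric(ph)
  if (length(unique(ph)) < 2) stop("`pattern_high` is constant; cannot fit")
  df <- data.frame(time = records$os_months, event = as.integer(records$os_event),
                   pattern_high = ph)
  form <- survival::Surv(time, event) ~ pattern_high
  if (with_stage) {
    df$stage <- as.numeric(records$stage)
    if (anyNA(df$stage)) {
      keep <- !is.na(df$stage)
      df <- df[keep, , drop = FALSE]
    }
    if (length(unique(df$stage)) < 2) stop("`stage` is constant; cannot fit")
    form <- survival::Surv(time, event) ~ pattern_high + stage
  }
  if (sum(df$event) < length(all.vars(form)) - 1) {
    stop("too few events (", sum(df$event), ") for the model")
  }
  fit <- survival::coxph(form, data = df, ties = "efron")
  if (!fit$iter || any(!is.finite(fit$coefficients))) {
    stop("Cox fit failed to converge (possible separation)")
  }
  structure(list(fit = fit, n = nrow(df), events = sum(df$event)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("<cox_fit> n = ", x$n, ", events = ", x$events, "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Hazard ratios of a Cox fit
#'
#' @param x A `cox_fit`.
#' @param ... Unused.
#' @return A tibble per covariate: `term`, `hazard_ratio`, `conf_low`,
#'   `conf_high` (95%), `p_value`.
#' @method tidy cox_fit
#' @export
tidy.cox_fit <- function(x, ...) {
  sm <- summary(x$fit)
  ci <- exp(stats::confint(x$fit))
  tibble::tibble(
    term = rownames(sm$coefficients),
    hazard_ratio = unname(exp(sm$coefficients[, "coef"])),
    conf_low = unname(ci[, 1]),
    conf_high = unname(ci[, 2]),
    p_value = unname(sm$coefficients[, "Pr(>|z|)"])
  )
}

#' Model-level summary of a Cox fit
#'
#' @param x A `cox_fit`.
#' @param ... Unused.
#' @return One-row tibble: `n`, `events`, `concordance`,
#'   `likelihood_ratio_p`.
#' @method glance cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(
    n = x$n, events = x$events,
    concordance = unname(sm$concordance["C"]),
    likelihood_ratio_p = unname(sm$logtest["pvalue"])
  )
}

#' Restrict records to patients with sufficient progression-free survival
#'
#' Keeps records whose recorded `pfs_months` is at least the threshold;
#' records lacking PFS are excluded. Thresholds nest: the subset at a
#' larger threshold is contained in the subset at a smaller one.
#'
#' @param records Survival records.
#' @param min_pfs_months Nonnegative threshold in months.
#' @return The filtered records tibble.
#' @export
pfs_subset <- function(records, min_pfs_months = 0) {
  stopifnot(min_pfs_months >= 0)
  dplyr::filter(records, !is.na(.data$pfs_months),
                .data$pfs_months >= min_pfs_months)
}

# Accept groups either aligned with the records rows or named by patient id
align_groups <- function(records, groups) {
  if (!is.null(names(groups)) && all(records$patient_id %in% names(groups))) {
    return(unname(groups[records$patient_id]))
  }
  if (length(groups) != nrow(records)) {
    stop("`groups` must be named by patient_id or aligned with records (",
         nrow(records), " rows)")
  }
  groups
}
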