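# Clinicopathological association, methylation-expression correlation, and
# survival stratification by methylation call.
#
# Contingency analysis uses the uncorrected Pearson chi-squared statistic
# (the convention of SPSS-style clinical tables); Yates continuity
# correction is available behind a flag.  Survival uses the product-limit
# estimator and the 1-df log-rank test, with ties handled by the standard
# simultaneous-death convention.

#' Pearson chi-squared test on a contingency table
#'
#' Classical Pearson statistic against the independence expecteds,
#' `sum((o - e)^2 / e)`, with `df = (rows - 1)(cols - 1)` and a chi-square
#' p-value.  Empty rows/columns are dropped with a warning; a table that
#' collapses below 2x2 is an error.
#'
#' @param table matrix of nonnegative counts (at least 2x2 after dropping
#'   empty margins).
#' @param correct apply Yates continuity correction (2x2 only); default
#'   `FALSE`.
#' @return A list of class `contingency_result`: `statistic`, `df`,
#'   `p_value`, `dims`.
#' @export
contingency_test <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be >= 0")
  keep_r <- rowSums(table) > 0
  keep_c <- colSums(table) > 0
  if (!all(keep_r) || !all(keep_c))
    warning("dropping ", sum(!keep_r), " empty row(s) and ",
            sum(!keep_c), " empty column(s)")
  table <- table[keep_r, keep_c, drop = FALSE]
  if (nrow(table) < 2 || ncol(table) < 2)
    stop("table collapses below 2x2 after dropping empty margins")
  ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
  structure(list(statistic = unname(ht$statistic),
                 df = as.integer(unname(ht$parameter)),
                 p_value = unname(ht$p.value),
                 dims = dim(table)),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("Pearson X^2 = %.4g, df = %d, p = %.4g (%dx%d table)\n",
              x$statistic, x$df, x$p_value, x$dims[1], x$dims[2]))
  invisible(x)
}

# Table-1-style stratifications of the clinical vocabulary
CLINICAL_PARAMETERS <- c("age", "sex", "tumor_type", "stage", "t_size",
                         "n_status", "m_status", "grade", "location", "msi")

clinical_stratum <- function(clinical, parameter) {
  switch(parameter,
    age = ifelse(clinical$age < 65, "<65", ">=65"),
    sex = clinical$sex,
    tumor_type = clinical$tumor_type,
    stage = ifelse(clinical$stage %in% c("0", "I"), "0 and I",
                   "II, III, and IV"),
    t_size = ifelse(clinical$t_size <= 1, "T0-T1", "T2-T4"),
    n_status = ifelse(clinical$n_status == 0, "N = 0", "N >= 1"),
    m_status = ifelse(clinical$m_status == 0, "M = 0", "M >= 1"),
    grade = clinical$grade,
    location = clinical$location,
    msi = clinical$msi,
    stop("unknown clinical parameter: ", parameter)
  )
}

#' Break down calls by a clinical parameter
#'
#' Joins per-patient fold-ratio calls to the clinical table, stratifies by
#' one parameter (age is dichotomized at 65, stage at 0-I vs II-IV, tumor
#' size at T1, nodal and distant status at 0), and reports per-stratum
#' class counts and percentages plus the Pearson chi-squared association.
#' Patients missing that parameter are excluded from this breakdown only.
#'
#' @param calls a `pair_call` data.frame (patient_id + call).
#' @param clinical a [clinical_table()].
#' @param parameter one of `"age"`, `"sex"`, `"tumor_type"`, `"stage"`,
#'   `"t_size"`, `"n_status"`, `"m_status"`, `"grade"`, `"location"`,
#'   `"msi"`.
#' @return A list of class `clinical_breakdown`: `parameter`, `rows`
#'   (data.frame: stratum, n, one count and one percent column per class),
#'   `test` (a `contingency_result`, or `NULL` when the table is
#'   degenerate), `n_missing`.
#' @export
clinical_breakdown <- function(calls, clinical, parameter) {
  parameter <- match.arg(parameter, CLINICAL_PARAMETERS)
  idx <- match(calls$patient_id, clinical$patient_id)
  if (anyNA(idx))
    stop("calls include patients absent from the clinical table")
  strat <- clinical_stratum(clinical[idx, , drop = FALSE], parameter)
  keep <- !is.na(strat)
  n_missing <- sum(!keep)
  strat <- strat[keep]
  call <- calls$call[keep]
  if (length(strat) == 0) stop("no patient has data for ", parameter)
  tab <- table(stratum = strat, call = call)
  # drop call classes absent from the whole cohort but keep strata order
  classes <- colnames(tab)
  rows <- data.frame(stratum = rownames(tab),
                     n = as.integer(rowSums(tab)),
                     stringsAsFactors = FALSE)
  for (cl in classes) {
    rows[[paste0("n_", cl)]] <- as.integer(tab[, cl])
    rows[[paste0("pct_", cl)]] <- 100 * tab[, cl] / rowSums(tab)
  }
  tab_used <- tab[, colSums(tab) > 0, drop = FALSE]
  test <- tryCatch(contingency_test(unclass(tab_used)),
                   error = function(e) NULL)
  structure(list(parameter = parameter, rows = rows, test = test,
                 n_missing = n_missing),
            class = "clinical_breakdown")
}

#' Methylation-expression correlation
#'
#' Pearson and Spearman correlation with two-sided p-values between
#' per-patient methylation (e.g. beta at one probe) and relative
#' expression.  Pairs with a missing member are dropped; a constant vector
#' leaves the coefficients undefined (flagged, not zeroed).
#'
#' @param methylation,expression paired numeric vectors.
#' @return A list of class `correlation_result`: `r`, `rho`, `p_pearson`,
#'   `p_spearman`, `n`, `undefined` (logical).
#' @export
methylation_expression_correlation <- function(methylation, expression) {
  if (length(methylation) != length(expression))
    stop("methylation and expression must be paired (equal length)")
  ok <- !is.na(methylation) & !is.na(expression)
  x <- methylation[ok]; y <- expression[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(list(r = NA_real_, rho = NA_real_,
                          p_pearson = NA_real_, p_spearman = NA_real_,
                          n = length(x), undefined = TRUE),
                     class = "correlation_result"))
  }
  pe <- stats::cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  structure(list(r = unname(pe$estimate), rho = unname(sp$estimate),
                 p_pearson = pe$p.value, p_spearman = sp$p.value,
                 n = length(x), undefined = FALSE),
            class = "correlation_result")
}

#' Product-limit (Kaplan-Meier) survival estimate
#'
#' Censored subjects leave the risk set without a step.  Returns the step
#' function at the observed event/censoring times, starting from S(0) = 1.
#'
#' @param times nonnegative follow-up times (months).
#' @param events logical, `TRUE` = event (death), `FALSE` = censored.
#' @return A list of class `survival_curve`: `time`, `survival`
#'   (nonincreasing, in \[0,1\]), `at_risk`, `n_events` (all per time
#'   point), `n`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) != length(events))
    stop("times and events must have equal length")
  if (any(times < 0)) stop("negative follow-up time")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(time = fit$time, survival = fit$surv,
                 at_risk = fit$n.risk, n_events = fit$n.event,
                 n = length(times)),
            class = "survival_curve")
}

#' Survival probability at given times
#'
#' Right-continuous step-function evaluation of a [km_estimate()] curve.
#'
#' @param curve a `survival_curve`.
#' @param at times to evaluate.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(curve, at) {
  vapply(at, function(t) {
    idx <- which(curve$time <= t)
    if (length(idx) == 0) 1 else curve$survival[max(idx)]
  }, numeric(1))
}

#' Log-rank test between two survival groups
#'
#' Standard 1-df log-rank statistic with a chi-square p-value.  When no
#' event occurs in either group the statistic is undefined and flagged.
#'
#' @param times_a,events_a follow-up and event indicator, group A.
#' @param times_b,events_b follow-up and event indicator, group B.
#' @return A list of class `logrank_result`: `statistic`, `p_value`,
#'   `n_a`, `n_b`, `defined`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0 || length(times_b) == 0)
    stop("both groups must be nonempty")
  if (any(c(times_a, times_b) < 0)) stop("negative follow-up time")
  time <- c(times_a, times_b)
  event <- c(events_a, events_b)
  group <- rep(c("A", "B"), c(length(times_a), length(times_b)))
  if (sum(event) == 0) {
    return(structure(list(statistic = NA_real_, p_value = NA_real_,
                          n_a = length(times_a), n_b = length(times_b),
                          defined = FALSE),
                     class = "logrank_result"))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  structure(list(statistic = unname(sd$chisq),
                 p_value = stats::pchisq(sd$chisq, df = 1,
                                         lower.tail = FALSE),
                 n_a = length(times_a), n_b = length(times_b),
                 defined = TRUE),
            class = "logrank_result")
}

#' Survival stratified by methylation call
#'
#' Dichotomizes patients into hypomethylated vs non-hypomethylated from
#' their fold-ratio call and compares overall survival, optionally within
#' a clinical subgroup.
#'
#' @param calls a `pair_call` data.frame (patient_id + call).
#' @param clinical a [clinical_table()] with `followup_months` and
#'   `death_event`.
#' @param subgroup optional subgroup filter: one of `"age_gt65"`,
#'   `"male"`, `"stage_iii_iv"`, or `NULL` for all patients.
#' @return A list of class `survival_stratification`: `curve_hypo`,
#'   `curve_other` ([km_estimate()] curves), `logrank`
#'   ([logrank_test()] result), `subgroup`, `n_excluded` (patients with
#'   missing follow-up or subgroup data).
#' @export
survival_by_call <- function(calls, clinical, subgroup = NULL) {
  idx <- match(calls$patient_id, clinical$patient_id)
  if (anyNA(idx))
    stop("calls include patients absent from the clinical table")
  cl <- clinical[idx, , drop = FALSE]
  keep <- !is.na(cl$followup_months) & !is.na(cl$death_event)
  if (!is.null(subgroup)) {
    subgroup <- match.arg(subgroup, c("age_gt65", "male", "stage_iii_iv"))
    sel <- switch(subgroup,
      age_gt65 = cl$age > 65,
      male = cl$sex == "male",
      stage_iii_iv = cl$stage %in% c("III", "IV"))
    keep <- keep & !is.na(sel) & sel
  }
  n_excluded <- sum(!keep)
  cl <- cl[keep, , drop = FALSE]
  is_hypo <- calls$call[keep] %in% c("hypo", "low")
  if (sum(is_hypo) == 0 || sum(!is_hypo) == 0)
    stop("need patients in both the hypo and non-hypo groups")
  structure(list(
    curve_hypo = km_estimate(cl$followup_months[is_hypo],
                             cl$death_event[is_hypo]),
    curve_other = km_estimate(cl$followup_months[!is_hypo],
                              cl$death_event[!is_hypo]),
    logrank = logrank_test(cl$followup_months[is_hypo],
                           cl$death_event[is_hypo],
                           cl$followup_months[!is_hypo],
                           cl$death_event[!is_hypo]),
    subgroup = if (is.null(subgroup)) "all" else subgroup,
    n_excluded = n_excluded
  ), class = "survival_stratification")
}
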