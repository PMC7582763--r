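# Plasma ccfDNA hypomethylation calling and diagnostic evaluation.
#
# "Positive" throughout means a hypomethylation call (the disease-indicating
# state): a relative methylated level strictly below the cutoff.  Disease =
# CRC.  So sensitivity = TP/(TP+FN) counts CRC subjects called
# hypomethylated, and PPV = TP/(TP+FP).

#' Plasma call configuration
#'
#' @param cutoff absolute relative-level cutoff; a level strictly below it
#'   is called positive (hypomethylated).  Default 0.5.
#' @param healthy_reference_mean informational only: the typical healthy
#'   relative level the cutoff is judged against (default 25.37); it plays
#'   no role in the call.
#' @return A list of class `plasma_call_config`.
#' @export
plasma_call_config <- function(cutoff = 0.5, healthy_reference_mean = 25.37) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  structure(list(cutoff = cutoff,
                 healthy_reference_mean = healthy_reference_mean),
            class = "plasma_call_config")
}

#' Call plasma hypomethylation
#'
#' Positive iff `relative_level < cutoff` (strict: a level exactly at the
#' cutoff is negative).
#'
#' @param relative_level nonnegative relative level(s).
#' @param config a [plasma_call_config()] (or a bare numeric cutoff).
#' @return Logical vector, `TRUE` = positive (hypomethylated).
#' @export
call_plasma <- function(relative_level, config = plasma_call_config()) {
  if (is.numeric(config)) config <- plasma_call_config(cutoff = config)
  if (any(!is.finite(relative_level)) || any(relative_level < 0))
    stop("relative_level must be finite and >= 0")
  relative_level < config$cutoff
}

#' Confusion table from calls and disease labels
#'
#' @param group character vector, `"healthy"` or `"CRC"` per subject.
#' @param positive logical vector of hypomethylation calls.
#' @return A list of class `confusion_table` with integer fields `tp`,
#'   `fp`, `fn`, `tn`.
#' @export
confusion_from_calls <- function(group, positive) {
  if (length(group) != length(positive))
    stop("group and positive must have equal length")
  bad <- setdiff(unique(group), c("healthy", "CRC"))
  if (length(bad)) stop("unknown group label: ", paste(bad, collapse = ", "))
  confusion_table(tp = sum(group == "CRC" & positive),
                  fp = sum(group == "healthy" & positive),
                  fn = sum(group == "CRC" & !positive),
                  tn = sum(group == "healthy" & !positive))
}

#' @rdname confusion_from_calls
#' @param tp,fp,fn,tn nonnegative integer cell counts (positive call =
#'   hypomethylation; disease = CRC).
#' @export
confusion_table <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("confusion cells must be nonnegative integers")
  structure(as.list(as.integer(cells)), names = names(cells),
            class = "confusion_table")
}

#' Diagnostic performance summary of a confusion table
#'
#' Sensitivity = tp/(tp+fn), specificity = tn/(tn+fp), PPV = tp/(tp+fp),
#' NPV = tn/(tn+fn).  A metric with a zero denominator is `NA` and named in
#' the `undefined` field, never reported as 0.  `exact_test_p` is the
#' two-sided Fisher exact test on the 2x2 table.
#'
#' @param tab a [confusion_table()].
#' @return A list of class `diagnostic_summary`: the four metrics,
#'   `exact_test_p`, `n`, and `undefined` (character vector of metrics with
#'   empty denominators).
#' @export
diagnostic_summary <- function(tab) {
  stopifnot(inherits(tab, "confusion_table"))
  n <- tab$tp + tab$fp + tab$fn + tab$tn
  if (n == 0) stop("empty confusion table")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- safe_div(tab$tp, tab$tp + tab$fn)
  spec <- safe_div(tab$tn, tab$tn + tab$fp)
  ppv <- safe_div(tab$tp, tab$tp + tab$fp)
  npv <- safe_div(tab$tn, tab$tn + tab$fn)
  m <- matrix(c(tab$tp, tab$fn, tab$fp, tab$tn), 2, 2,
              dimnames = list(call = c("positive", "negative"),
                              group = c("CRC", "healthy")))
  p <- stats::fisher.test(m)$p.value
  metrics <- c(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv)
  structure(list(sensitivity = sens, specificity = spec, ppv = ppv,
                 npv = npv, exact_test_p = p, n = as.integer(n),
                 undefined = names(metrics)[is.na(metrics)]),
            class = "diagnostic_summary")
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", 100 * v)
  cat(sprintf(
    "n = %d: sensitivity %s, specificity %s, PPV %s, NPV %s (Fisher p = %.3g)\n",
    x$n, fmt(x$sensitivity), fmt(x$specificity), fmt(x$ppv), fmt(x$npv),
    x$exact_test_p))
  invisible(x)
}

#' Group comparison of plasma levels
#'
#' Welch two-sample t-test on log-transformed relative levels (zero levels
#' are floored at half the smallest positive level before the log).
#'
#' @param plasma a [plasma_table()].
#' @return `htest` object from [stats::t.test()].
#' @export
compare_plasma_levels <- function(plasma) {
  lv <- plasma$relative_level
  if (any(lv == 0)) {
    floor_lv <- min(lv[lv > 0]) / 2
    lv[lv == 0] <- floor_lv
  }
  stats::t.test(log(lv) ~ factor(plasma$group, levels = c("CRC", "healthy")))
}

#' Evaluate plasma diagnostics at one cutoff
#'
#' Convenience wrapper: call, tabulate, summarize.
#'
#' @param plasma a [plasma_table()].
#' @param config a [plasma_call_config()] or numeric cutoff.
#' @return A [diagnostic_summary()].
#' @export
plasma_diagnostics <- function(plasma, config = plasma_call_config()) {
  pos <- call_plasma(plasma$relative_level, config)
  diagnostic_summary(confusion_from_calls(plasma$group, pos))
}

#' Sweep the call cutoff over a grid
#'
#' One row per cutoff, each evaluated exactly like
#' [plasma_diagnostics()].  As the cutoff rises, more subjects are called
#' positive, so sensitivity is nondecreasing and specificity nonincreasing
#' in cutoff.
#'
#' @param plasma a [plasma_table()] with at least one subject per group.
#' @param cutoffs ascending numeric vector of cutoffs (> 0).
#' @return data.frame: `cutoff`, `sensitivity`, `specificity`, `ppv`
#'   (`NA` where undefined).
#' @export
threshold_sweep <- function(plasma, cutoffs) {
  if (length(cutoffs) == 0) stop("cutoffs must be nonempty")
  if (any(cutoffs <= 0)) stop("cutoffs must be > 0")
  if (is.unsorted(cutoffs, strictly = TRUE))
    stop("cutoffs must be strictly ascending")
  if (!all(c("healthy", "CRC") %in% plasma$group))
    stop("need at least one subject per group")
  rows <- lapply(cutoffs, function(ct) {
    s <- plasma_diagnostics(plasma, plasma_call_config(cutoff = ct))
    data.frame(cutoff = ct, sensitivity = s$sensitivity,
               specificity = s$specificity, ppv = s$ppv)
  })
  do.call(rbind, rows)
}
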