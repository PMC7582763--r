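# Delta-delta-Ct relative quantification and three-class fold-ratio calls.
#
# Relative level of a target assay against a reference assay in one sample:
#   level = base^-(Ct_target - Ct_reference)
# Paired tumor/normal fold ratio:
#   ratio = level_tumor / level_normal = base^-(ddCt),
#   ddCt  = (Ct_T,target - Ct_T,ref) - (Ct_N,target - Ct_N,ref)
# Classes (strict boundaries; a ratio of exactly 0.5 or 2 is the middle
# class): ratio < 0.5 -> hypo/low, ratio > 2 -> hyper/high, else
# equal/moderate.

call_levels <- function(mode = c("methylation", "expression")) {
  mode <- match.arg(mode)
  if (mode == "methylation") c("hypo", "equal", "hyper")
  else c("low", "moderate", "high")
}

#' Relative level from target and reference Ct
#'
#' Computes `base^-(ct_target - ct_reference)`, the methylation or expression
#' level of the target assay normalized to the reference gene under an
#' assumed amplification factor per cycle (`base = 2` means 100% efficiency).
#'
#' @param ct_target,ct_reference quantification cycles, strictly positive.
#'   Vectorized.
#' @param base amplification factor per PCR cycle (default 2).
#' @return Numeric vector of dimensionless relative levels (always > 0).
#' @examples
#' relative_level(28, 25)       # 2^-3 = 0.125
#' relative_level(25, 25)       # 1
#' @export
relative_level <- function(ct_target, ct_reference, base = 2) {
  if (any(!is.finite(ct_target)) || any(ct_target <= 0) ||
      any(!is.finite(ct_reference)) || any(ct_reference <= 0))
    stop("Ct values must be positive and finite")
  if (base <= 1) stop("amplification base must be > 1")
  base^(-(ct_target - ct_reference))
}

#' Per-sample relative levels from a Ct table
#'
#' Aggregates technical replicates by the arithmetic mean of Ct, then forms
#' the target-vs-reference relative level for every sample.  A sample with a
#' target assay but no reference assay (or vice versa) is an error: the
#' normalization is undefined.
#'
#' @param ct a [ct_table()].
#' @param base amplification factor per cycle.
#' @return data.frame with columns `sample_id`, `ct_target`, `ct_reference`,
#'   `level`.
#' @export
ct_relative_levels <- function(ct, base = 2) {
  m <- replicate_means(ct)
  tgt <- m[m$assay == "target", ]
  ref <- m[m$assay == "reference", ]
  ids <- unique(m$sample_id)
  miss_ref <- setdiff(tgt$sample_id, ref$sample_id)
  miss_tgt <- setdiff(ref$sample_id, tgt$sample_id)
  if (length(miss_ref))
    stop("missing reference assay for sample(s): ",
         paste(utils::head(miss_ref, 5), collapse = ", "))
  if (length(miss_tgt))
    stop("missing target assay for sample(s): ",
         paste(utils::head(miss_tgt, 5), collapse = ", "))
  ct_t <- tgt$ct[match(ids, tgt$sample_id)]
  ct_r <- ref$ct[match(ids, ref$sample_id)]
  data.frame(sample_id = ids, ct_target = ct_t, ct_reference = ct_r,
             level = relative_level(ct_t, ct_r, base = base),
             stringsAsFactors = FALSE)
}

#' Paired tumor/normal fold-ratio call
#'
#' Forms the tumor-to-normal ratio of relative levels and classifies it:
#' ratio < 0.5 is hypomethylation (methylation mode) or low expression
#' (expression mode); ratio > 2 is hypermethylation / high expression;
#' anything else (boundaries included) is equal / moderate.
#'
#' Zero levels are degenerate, never silently perturbed: both levels zero
#' gives the middle class with an undefined ratio; a zero normal level with
#' a positive tumor level gives the high class with an undefined ratio.
#'
#' @param tumor_level,normal_level nonnegative relative levels (vectorized).
#' @param patient_id optional patient identifiers.
#' @param mode `"methylation"` or `"expression"` (chooses the class labels).
#' @return data.frame of class `pair_call` with columns `patient_id`,
#'   `ratio`, `call` (factor, levels low-to-high), `ratio_defined`, `mode`.
#' @export
pair_ratio <- function(tumor_level, normal_level,
                       patient_id = seq_along(tumor_level),
                       mode = c("methylation", "expression")) {
  mode <- match.arg(mode)
  if (any(tumor_level < 0, na.rm = TRUE) ||
      any(normal_level < 0, na.rm = TRUE))
    stop("relative levels must be >= 0")
  lv <- call_levels(mode)
  n <- length(tumor_level)
  ratio <- rep(NA_real_, n)
  call <- character(n)
  defined <- normal_level > 0
  ratio[defined] <- tumor_level[defined] / normal_level[defined]
  call[defined] <- ifelse(ratio[defined] < 0.5, lv[1],
                          ifelse(ratio[defined] > 2, lv[3], lv[2]))
  both_zero <- !defined & tumor_level == 0
  call[both_zero] <- lv[2]
  call[!defined & tumor_level > 0] <- lv[3]
  out <- data.frame(patient_id = as.character(patient_id), ratio = ratio,
                    call = factor(call, levels = lv),
                    ratio_defined = defined, mode = mode,
                    stringsAsFactors = FALSE)
  class(out) <- c("pair_call", "data.frame")
  out
}

#' Paired calls from a Ct table and sample sheet
#'
#' Runs the full delta-delta-Ct pipeline: replicate means, per-sample
#' relative levels, tumor/normal pairing via the sample sheet, fold ratio
#' and class per patient.
#'
#' @param ct a [ct_table()] covering both members of each pair.
#' @param sheet a [sample_sheet()] defining the tumor/normal pairing.
#' @param base amplification factor per cycle.
#' @inheritParams pair_ratio
#' @return A `pair_call` data.frame, one row per paired patient.
#' @export
qmsp_pair_calls <- function(ct, sheet, base = 2,
                            mode = c("methylation", "expression")) {
  mode <- match.arg(mode)
  levels <- ct_relative_levels(ct, base = base)
  pairs <- paired_samples(sheet)
  if (nrow(pairs) == 0) stop("no paired patients in sample sheet")
  t_lv <- levels$level[match(pairs$tumor_sample, levels$sample_id)]
  n_lv <- levels$level[match(pairs$normal_sample, levels$sample_id)]
  keep <- !is.na(t_lv) & !is.na(n_lv)
  if (!any(keep)) stop("no patient has Ct data for both pair members")
  res <- pair_ratio(t_lv[keep], n_lv[keep],
                    patient_id = pairs$patient_id[keep], mode = mode)
  attr(res, "n_skipped") <- sum(!keep)
  res
}

#' Paired calls from array beta values at one probe
#'
#' Applies the same < 0.5 / > 2 fold-ratio rule to array beta values: for
#' each paired patient, ratio = tumor beta / normal beta at the given probe.
#' Patients with a missing beta in either member are skipped; the skip count
#' is attached as attribute `n_skipped`.
#'
#' @param bmat a [beta_matrix()].
#' @param sheet a [sample_sheet()].
#' @param probe_id single probe identifier present in `bmat`.
#' @inheritParams pair_ratio
#' @return A `pair_call` data.frame.
#' @export
beta_pair_calls <- function(bmat, sheet, probe_id,
                            mode = c("methylation", "expression")) {
  mode <- match.arg(mode)
  if (!probe_id %in% rownames(bmat))
    stop("probe '", probe_id, "' not in beta matrix")
  pairs <- paired_samples(sheet)
  if (nrow(pairs) == 0) stop("no paired patients in sample sheet")
  t_b <- bmat[probe_id, pairs$tumor_sample]
  n_b <- bmat[probe_id, pairs$normal_sample]
  keep <- !is.na(t_b) & !is.na(n_b)
  if (!any(keep)) stop("no patient has beta values for both pair members")
  res <- pair_ratio(t_b[keep], n_b[keep],
                    patient_id = pairs$patient_id[keep], mode = mode)
  attr(res, "n_skipped") <- sum(!keep)
  res
}

#' Cohort class rates
#'
#' Counts and percentages per fold-ratio class.  Percentages are computed at
#' full precision from the counts; `percent_label` rounds the display to one
#' decimal.
#'
#' @param calls a `pair_call` data.frame (or factor of calls).
#' @return A list of class `cohort_rates`: `n_total`, `counts` (named),
#'   `fraction`, `percent`, `percent_label`.
#' @examples
#' calls <- pair_ratio(c(0.3, 0.4, 1.2), c(1, 1, 1))
#' cohort_rates(calls)
#' @export
cohort_rates <- function(calls) {
  f <- if (is.data.frame(calls)) calls$call else calls
  if (!is.factor(f)) stop("calls must be a pair_call table or factor")
  if (length(f) == 0) stop("no calls to summarize")
  counts <- table(f)
  n <- length(f)
  fraction <- as.numeric(counts) / n
  out <- list(
    n_total = n,
    counts = stats::setNames(as.integer(counts), names(counts)),
    fraction = stats::setNames(fraction, names(counts)),
    percent = stats::setNames(100 * fraction, names(counts)),
    percent_label = stats::setNames(sprintf("%.1f", 100 * fraction),
                                    names(counts))
  )
  class(out) <- "cohort_rates"
  out
}

#' @export
print.cohort_rates <- function(x, ...) {
  cat(sprintf("cohort of %d pairs:\n", x$n_total))
  for (cl in names(x$counts))
    cat(sprintf("  %-9s %4d/%d (%s%%)\n", cl, x$counts[[cl]], x$n_total,
                x$percent_label[[cl]]))
  invisible(x)
}
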