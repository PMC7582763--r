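# Differential-hypomethylation discovery on beta matrices.
#
# Per-probe summaries (Avg_beta in normal and tumor, their difference, a
# paired p-value), three strict filtering criteria, and a two-cohort
# intersection with deterministic candidate ranking.

#' Discovery filtering criteria
#'
#' Three strict predicates applied to a per-probe summary:
#' `delta < delta_max` (tumor minus normal beta difference),
#' `avg_n > normal_min` (well-methylated in normal tissue), and
#' `avg_t < tumor_max` (lowly methylated in tumor tissue).
#'
#' @param delta_max maximum (negative) tumor-minus-normal mean-beta
#'   difference; default -0.25.
#' @param normal_min minimum normal-tissue mean beta; default 0.5.
#' @param tumor_max maximum tumor-tissue mean beta; default 0.2.
#' @return A validated list of class `discovery_criteria`.
#' @export
discovery_criteria <- function(delta_max = -0.25, normal_min = 0.5,
                               tumor_max = 0.2) {
  if (delta_max >= 0) stop("delta_max must be negative")
  if (!(tumor_max > 0 && tumor_max < normal_min && normal_min < 1))
    stop("need 0 < tumor_max < normal_min < 1")
  structure(list(delta_max = delta_max, normal_min = normal_min,
                 tumor_max = tumor_max), class = "discovery_criteria")
}

#' Per-probe differential-methylation summary
#'
#' Means are taken over non-missing values (pairwise-complete pairs when
#' `paired = TRUE`).  The paired p-value comes from the Wilcoxon signed-rank
#' test (exact null for n <= 25 usable pairs, normal approximation above);
#' a paired t-test p-value is reported alongside.  A degenerate case with
#' no nonzero differences yields p = 1.
#'
#' @param normals,tumors numeric beta vectors; equal length when paired.
#' @param paired logical; `TRUE` treats positions as patient pairs.
#' @param probe_id optional identifier carried into the result.
#' @return A one-row data.frame of class `probe_summary`: `probe_id`,
#'   `avg_n`, `avg_t`, `delta` (= avg_t - avg_n), `p_value` (Wilcoxon),
#'   `p_t_test`, `n_pairs`, `n_missing`.
#' @export
summarize_probe <- function(normals, tumors, paired = TRUE,
                            probe_id = NA_character_) {
  if (paired && length(normals) != length(tumors))
    stop("paired summaries need equal-length normal and tumor vectors")
  if (paired) {
    ok <- !is.na(normals) & !is.na(tumors)
    n_usable <- sum(ok)
    n_missing <- length(normals) - n_usable
    nv <- normals[ok]; tv <- tumors[ok]
  } else {
    nv <- normals[!is.na(normals)]; tv <- tumors[!is.na(tumors)]
    n_usable <- min(length(nv), length(tv))
    n_missing <- (length(normals) - length(nv)) +
      (length(tumors) - length(tv))
  }
  if (n_usable < 2)
    stop("fewer than 2 usable pairs for probe ", probe_id)
  avg_n <- mean(nv); avg_t <- mean(tv)
  if (paired) {
    d <- tv - nv
    if (all(d == 0)) {
      p_w <- 1; p_t <- 1
    } else {
      p_w <- suppressWarnings(
        stats::wilcox.test(tv, nv, paired = TRUE,
                           exact = n_usable <= 25,
                           correct = n_usable > 25)$p.value)
      # a (numerically) constant nonzero shift leaves the t-test degenerate
      p_t <- if (stats::sd(d) <= 1e-10 * mean(abs(d))) 0
      else stats::t.test(tv, nv, paired = TRUE)$p.value
    }
  } else {
    if (stats::sd(c(nv, tv)) == 0) {
      p_w <- 1; p_t <- 1
    } else {
      p_w <- tryCatch(stats::wilcox.test(tv, nv, exact = FALSE)$p.value,
                      error = function(e) NA_real_)
      p_t <- tryCatch(stats::t.test(tv, nv)$p.value,
                      error = function(e) NA_real_)
    }
  }
  out <- data.frame(probe_id = probe_id, avg_n = avg_n, avg_t = avg_t,
                    delta = avg_t - avg_n, p_value = p_w, p_t_test = p_t,
                    n_pairs = n_usable, n_missing = n_missing,
                    stringsAsFactors = FALSE)
  class(out) <- c("probe_summary", "data.frame")
  out
}

#' Summarize every probe of a cohort
#'
#' Applies [summarize_probe()] to each probe of a beta matrix using the
#' sample sheet's tumor/normal pairing, and appends Benjamini-Hochberg
#' adjusted p-values.  Probes with fewer than 2 usable pairs are dropped
#' with a warning.
#'
#' @param bmat a [beta_matrix()].
#' @param sheet a [sample_sheet()].
#' @return A `probe_summary` data.frame, one row per summarizable probe,
#'   with columns `p_adjusted` (BH on the Wilcoxon p-values) added.
#' @export
summarize_cohort <- function(bmat, sheet) {
  pairs <- paired_samples(sheet)
  if (nrow(pairs) == 0) stop("no paired patients in sample sheet")
  nm <- unclass(bmat)[, pairs$normal_sample, drop = FALSE]
  tm <- unclass(bmat)[, pairs$tumor_sample, drop = FALSE]
  rows <- vector("list", nrow(bmat))
  dropped <- character(0)
  for (i in seq_len(nrow(bmat))) {
    rows[[i]] <- tryCatch(
      summarize_probe(nm[i, ], tm[i, ], paired = TRUE,
                      probe_id = rownames(bmat)[i]),
      error = function(e) NULL)
    if (is.null(rows[[i]])) dropped <- c(dropped, rownames(bmat)[i])
  }
  if (length(dropped))
    warning("dropped ", length(dropped),
            " probe(s) with < 2 usable pairs: ",
            paste(utils::head(dropped, 5), collapse = ", "))
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no probe could be summarized")
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  class(out) <- c("probe_summary", "data.frame")
  out
}

#' Apply discovery criteria to probe summaries
#'
#' All three predicates are strict inequalities; p-values play no role in
#' the filter (they are reported, not selected on).
#'
#' @param summary a `probe_summary` data.frame (one or more rows).
#' @param criteria a [discovery_criteria()].
#' @return `summary` with logical columns `pass_delta`, `pass_normal`,
#'   `pass_tumor` and overall `pass` appended.
#' @export
apply_criteria <- function(summary, criteria = discovery_criteria()) {
  stopifnot(inherits(criteria, "discovery_criteria"))
  summary$pass_delta <- summary$delta < criteria$delta_max
  summary$pass_normal <- summary$avg_n > criteria$normal_min
  summary$pass_tumor <- summary$avg_t < criteria$tumor_max
  summary$pass <- summary$pass_delta & summary$pass_normal &
    summary$pass_tumor
  summary
}

#' Select candidate genes across one or two cohorts
#'
#' A gene is selected when at least one of its probes passes all criteria
#' in cohort A and, when a second cohort is provided, at least one probe
#' (not necessarily the same one) passes in cohort B.  Probes with more
#' than `max_missing_fraction` of pairs missing are excluded from
#' selection.  Ranking is ascending by the minimum tumor mean beta across
#' the gene's passing probes (cohort A), ties broken by descending normal
#' mean beta, then lexicographic gene symbol.  The reported `best_probe` is
#' the probe attaining that minimum, preferring probes that pass in every
#' contributing cohort.
#'
#' @param cohort_a a `probe_summary` data.frame for the primary cohort.
#' @param cohort_b optional `probe_summary` for the confirmation cohort;
#'   `NULL` runs single-cohort selection.
#' @param annotation a [probe_annotation()] covering all summarized probes.
#' @param criteria a [discovery_criteria()].
#' @param max_missing_fraction probes whose missing-pair fraction exceeds
#'   this are ignored (default 0.2).
#' @return data.frame of class `candidate_genes`: `gene_symbol`,
#'   `best_probe`, `avg_t_best`, `avg_n_best`, `rank`, ordered by rank.
#'   Empty (zero rows) when nothing passes.
#' @export
select_candidates <- function(cohort_a, cohort_b = NULL, annotation,
                              criteria = discovery_criteria(),
                              max_missing_fraction = 0.2) {
  prep <- function(summ) {
    missing_gene <- setdiff(summ$probe_id, annotation$probe_id)
    if (length(missing_gene))
      stop("no annotation for probe(s): ",
           paste(utils::head(missing_gene, 5), collapse = ", "))
    summ$gene_symbol <- annotation$gene_symbol[match(summ$probe_id,
                                                     annotation$probe_id)]
    frac_missing <- summ$n_missing / (summ$n_pairs + summ$n_missing)
    summ <- summ[frac_missing <= max_missing_fraction, , drop = FALSE]
    apply_criteria(summ, criteria)
  }
  a <- prep(cohort_a)
  pass_a <- a[a$pass, , drop = FALSE]
  genes <- unique(pass_a$gene_symbol)
  if (!is.null(cohort_b)) {
    b <- prep(cohort_b)
    genes_b <- unique(b$gene_symbol[b$pass])
    genes <- intersect(genes, genes_b)
  }
  empty <- data.frame(gene_symbol = character(0), best_probe = character(0),
                      avg_t_best = numeric(0), avg_n_best = numeric(0),
                      rank = integer(0), stringsAsFactors = FALSE)
  class(empty) <- c("candidate_genes", "data.frame")
  if (length(genes) == 0) return(empty)

  rows <- lapply(genes, function(g) {
    pg <- pass_a[pass_a$gene_symbol == g, , drop = FALSE]
    if (!is.null(cohort_b)) {
      both <- pg$probe_id %in% b$probe_id[b$pass]
      if (any(both)) pg <- pg[both, , drop = FALSE]
    }
    best <- pg[order(pg$avg_t, -pg$avg_n, pg$probe_id), ][1, ]
    data.frame(gene_symbol = g, best_probe = best$probe_id,
               avg_t_best = best$avg_t, avg_n_best = best$avg_n,
               min_avg_t = min(pg$avg_t), max_avg_n_at_min =
                 max(pg$avg_n[pg$avg_t == min(pg$avg_t)]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$min_avg_t, -out$max_avg_n_at_min, out$gene_symbol), ,
             drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out <- out[, c("gene_symbol", "best_probe", "avg_t_best", "avg_n_best",
                 "rank")]
  rownames(out) <- NULL
  class(out) <- c("candidate_genes", "data.frame")
  out
}
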