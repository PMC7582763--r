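# Independent oracles used to cross-check the implementation.  These are
# deliberately naive re-derivations (hand formulas, brute-force predicate
# evaluation) and never call the functions they check.

# Pearson chi-squared by the textbook formula sum((o - e)^2 / e)
oracle_pearson_chisq <- function(tab) {
  tab <- as.matrix(tab)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# brute-force gene selection: evaluate the three predicates probe by probe,
# then take genes with a passing probe in each provided cohort
oracle_select_genes <- function(summ_a, summ_b = NULL, annotation,
                                delta_max = -0.25, normal_min = 0.5,
                                tumor_max = 0.2) {
  passing_genes <- function(summ) {
    genes <- character(0)
    for (i in seq_len(nrow(summ))) {
      ok <- summ$delta[i] < delta_max &&
        summ$avg_n[i] > normal_min &&
        summ$avg_t[i] < tumor_max
      if (ok) {
        g <- annotation$gene_symbol[annotation$probe_id == summ$probe_id[i]]
        genes <- union(genes, g)
      }
    }
    genes
  }
  out <- passing_genes(summ_a)
  if (!is.null(summ_b)) out <- intersect(out, passing_genes(summ_b))
  sort(out)
}

# product-limit estimator computed step by step from first principles
oracle_km <- function(times, events) {
  ord <- order(times)
  times <- times[ord]; events <- events[ord]
  ev_times <- sort(unique(times[events]))
  s <- 1
  surv <- numeric(length(ev_times))
  for (k in seq_along(ev_times)) {
    t <- ev_times[k]
    at_risk <- sum(times >= t)
    d <- sum(times == t & events)
    s <- s * (1 - d / at_risk)
    surv[k] <- s
  }
  list(time = ev_times, survival = surv)
}

# log-rank statistic by direct enumeration of risk sets at each event time
oracle_logrank <- function(times_a, events_a, times_b, events_b) {
  time <- c(times_a, times_b)
  event <- c(events_a, events_b)
  grp <- rep(c(1, 2), c(length(times_a), length(times_b)))
  ev_times <- sort(unique(time[event]))
  o1 <- 0; e1 <- 0; v <- 0
  for (t in ev_times) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & grp == 1)
    d <- sum(time == t & event)
    d1 <- sum(time == t & event & grp == 1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v
}

# one-row probe summary constructed directly (for hand-built cohorts)
make_summary <- function(probe_id, avg_n, avg_t, n_pairs = 10,
                         n_missing = 0) {
  out <- data.frame(probe_id = probe_id, avg_n = avg_n, avg_t = avg_t,
                    delta = avg_t - avg_n, p_value = 0.01, p_t_test = 0.01,
                    n_pairs = n_pairs, n_missing = n_missing,
                    stringsAsFactors = FALSE)
  class(out) <- c("probe_summary", "data.frame")
  out
}

# tiny two-pair beta cohort used across data-model tests
tiny_beta_fixture <- function() {
  ann <- probe_annotation(c("cg01", "cg02", "cg03"),
                          c("GA", "GA", "GB"),
                          c(-525L, 12535L, -94L))
  sheet <- sample_sheet(c("p1_N", "p2_N", "p1_T", "p2_T"),
                        c("p1", "p2", "p1", "p2"),
                        c("normal", "normal", "tumor", "tumor"))
  values <- matrix(c(0.524, 0.60, NA,
                     0.524, 0.55, 0.30,
                     0.119, 0.20, 0.25,
                     0.119, 0.15, 0.35),
                   nrow = 3,
                   dimnames = list(c("cg01", "cg02", "cg03"),
                                   c("p1_N", "p2_N", "p1_T", "p2_T")))
  list(ann = ann, sheet = sheet,
       beta = beta_matrix(values, annotation = ann, sheet = sheet))
}
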