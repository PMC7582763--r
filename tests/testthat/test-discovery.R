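# Per-probe summaries, criteria filtering, candidate selection and ranking.

test_that("summarize_probe computes exact means and differences", {
  s <- summarize_probe(rep(0.524, 6), rep(0.119, 6), probe_id = "cg24")
  expect_equal(s$avg_n, 0.524)
  expect_equal(s$avg_t, 0.119)
  expect_equal(s$delta, -0.405)

  s2 <- summarize_probe(c(0.6, 0.5), c(0.2, 0.1))
  expect_equal(s2$avg_n, 0.55)
  expect_equal(s2$avg_t, 0.15)
  expect_equal(s2$delta, -0.40)

  ident <- summarize_probe(c(0.3, 0.4, 0.5), c(0.3, 0.4, 0.5))
  expect_equal(ident$delta, 0)
  expect_equal(ident$p_value, 1)

  expect_error(summarize_probe(c(0.5, NA), c(0.2, 0.3)), "fewer than 2")
  expect_error(summarize_probe(c(0.5, 0.6, 0.7), c(0.2, 0.3)),
               "equal-length")
})

test_that("missing pairs are excluded from the means, not imputed", {
  s <- summarize_probe(c(0.6, NA, 0.5), c(0.2, 0.9, 0.1))
  expect_equal(s$avg_n, 0.55)
  expect_equal(s$avg_t, 0.15)
  expect_equal(s$n_pairs, 2L)
  expect_equal(s$n_missing, 1L)
})

test_that("criteria are strict and flag the failing predicate", {
  crit <- discovery_criteria()
  a <- apply_criteria(make_summary("p1", 0.63, 0.11), crit)
  expect_true(a$pass)
  b <- apply_criteria(make_summary("p2", 0.6, 0.6), crit)
  expect_false(b$pass)
  expect_false(b$pass_delta)
  c_ <- apply_criteria(make_summary("p3", 0.52, 0.12), crit)
  expect_true(c_$pass)
  # boundary values fail strict inequalities
  d <- apply_criteria(make_summary("p4", 0.5, 0.2), crit)
  expect_false(d$pass_normal)
  expect_false(d$pass_tumor)
  expect_error(discovery_criteria(delta_max = 0.1), "negative")
  expect_error(discovery_criteria(normal_min = 0.1, tumor_max = 0.2),
               "tumor_max < normal_min")
})

test_that("selection intersects cohorts, ranks by tumor beta with the
           normal-beta tie break, and errors on unannotated probes", {
  ann <- probe_annotation(c("p1", "p2", "p3"), c("GA", "GB", "GC"),
                         c(-100L, -100L, -100L))
  none <- make_summary("p1", 0.4, 0.3)
  expect_identical(nrow(select_candidates(none, NULL, ann)), 0L)

  # two genes tie on min tumor beta 0.12; normal beta 0.52 vs 0.51 decides
  a <- rbind(make_summary("p1", 0.52, 0.12),
             make_summary("p2", 0.51, 0.12),
             make_summary("p3", 0.60, 0.35))
  class(a) <- c("probe_summary", "data.frame")
  sel <- select_candidates(a, NULL, ann)
  expect_identical(sel$gene_symbol, c("GA", "GB"))
  expect_identical(sel$rank, 1:2)

  # second cohort restricts to the intersection
  b <- make_summary("p2", 0.55, 0.10)
  class(b) <- c("probe_summary", "data.frame")
  sel_ab <- select_candidates(a, b, ann)
  expect_identical(sel_ab$gene_symbol, "GB")

  bad_ann <- probe_annotation("p1", "GA", -100L)
  expect_error(select_candidates(a, NULL, bad_ann), "no annotation")
})

test_that("selection is monotone under criteria relaxation and
           two-cohort selection is contained in single-cohort", {
  set.seed(42)
  ann <- probe_annotation(sprintf("p%02d", 1:20),
                          rep(sprintf("G%d", 1:10), each = 2),
                          rep(c(-200L, 500L), 10))
  for (rep_i in 1:10) {
    avg_n <- runif(20, 0.3, 0.9)
    avg_t <- pmax(0.01, avg_n + runif(20, -0.6, 0.1))
    summ <- do.call(rbind, lapply(1:20, function(i)
      make_summary(sprintf("p%02d", i), avg_n[i], avg_t[i])))
    class(summ) <- c("probe_summary", "data.frame")
    avg_n2 <- runif(20, 0.3, 0.9)
    avg_t2 <- pmax(0.01, avg_n2 + runif(20, -0.6, 0.1))
    summ_b <- do.call(rbind, lapply(1:20, function(i)
      make_summary(sprintf("p%02d", i), avg_n2[i], avg_t2[i])))
    class(summ_b) <- c("probe_summary", "data.frame")

    tight <- discovery_criteria(-0.25, 0.5, 0.2)
    loose <- discovery_criteria(-0.15, 0.4, 0.3)
    g_tight <- select_candidates(summ, NULL, ann, tight)$gene_symbol
    g_loose <- select_candidates(summ, NULL, ann, loose)$gene_symbol
    expect_true(all(g_tight %in% g_loose))

    g_both <- select_candidates(summ, summ_b, ann, tight)$gene_symbol
    expect_true(all(g_both %in% g_tight))
  }
})

test_that("probes with too many missing pairs are excluded from selection", {
  ann <- probe_annotation(c("p1", "p2"), c("GA", "GB"), c(-1L, -1L))
  summ <- rbind(make_summary("p1", 0.6, 0.1, n_pairs = 5, n_missing = 5),
                make_summary("p2", 0.6, 0.1, n_pairs = 10, n_missing = 0))
  class(summ) <- c("probe_summary", "data.frame")
  sel <- select_candidates(summ, NULL, ann, max_missing_fraction = 0.2)
  expect_identical(sel$gene_symbol, "GB")
})

test_that("cohort summaries add BH-adjusted p-values and drop
           unsummarizable probes with a warning", {
  sim <- generate_methylation_cohort(
    methylation_sim_config(n_pairs = 10, n_genes = 4, seed = 8,
                           missing_rate = 0))
  summ <- summarize_cohort(sim$beta, sim$sheet)
  expect_identical(nrow(summ), 20L)
  expect_true(all(summ$p_adjusted >= summ$p_value - 1e-12))
  # knock out a probe almost entirely
  b <- unclass(sim$beta)
  b[1, 2:20] <- NA
  crippled <- beta_matrix(b)
  expect_warning(s2 <- summarize_cohort(crippled, sim$sheet),
                 "dropped 1 probe")
  expect_identical(nrow(s2), 19L)
})
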