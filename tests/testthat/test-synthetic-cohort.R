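# Generators: determinism, planted-truth structure, config validation.

test_that("methylation generator is seed-deterministic and respects the
           configured means", {
  cfg <- methylation_sim_config(n_pairs = 50, n_genes = 10, seed = 11,
                                missing_rate = 0)
  a <- generate_methylation_cohort(cfg)
  b <- generate_methylation_cohort(cfg)
  expect_identical(a, b)
  expect_false(anyNA(a$beta))

  # per-probe means of the planted gene sit near the configured centers
  planted_probes <- a$annotation$probe_id[a$annotation$gene_symbol == "G001"]
  pairs <- paired_samples(a$sheet)
  for (p in planted_probes) {
    expect_lt(abs(mean(a$beta[p, pairs$tumor_sample]) - 0.12), 0.05)
    expect_lt(abs(mean(a$beta[p, pairs$normal_sample]) - 0.55), 0.05)
  }
})

test_that("methylation generator masks cells at the missing rate and
           validates its config", {
  cfg <- methylation_sim_config(n_pairs = 40, n_genes = 10,
                                missing_rate = 0.1, seed = 3)
  sim <- generate_methylation_cohort(cfg)
  frac <- mean(is.na(sim$beta))
  expect_lt(abs(frac - 0.1), 0.02)
  expect_error(methylation_sim_config(planted_hypo_genes = "NOPE"),
               "not in universe")
  expect_error(methylation_sim_config(n_pairs = 1), "n_pairs")
  expect_error(methylation_sim_config(normal_beta_mean = 1.2), "\\(0, 1\\)")
})

test_that("zero-noise QMSP cohorts are classified exactly as planted", {
  cfg <- qmsp_sim_config(n_pairs = 40, fraction_hypo = 1,
                         fraction_equal = 0, fraction_hyper = 0,
                         noise_sd = 0, seed = 5)
  sim <- generate_qmsp_cohort(cfg)
  calls <- qmsp_pair_calls(sim$ct, sim$sheet)
  expect_true(all(calls$call == "hypo"))

  # mixed classes, still zero noise: every patient recovers its truth
  cfg2 <- qmsp_sim_config(n_pairs = 60, fraction_hypo = 0.5,
                          fraction_equal = 0.3, fraction_hyper = 0.2,
                          noise_sd = 0, seed = 6)
  sim2 <- generate_qmsp_cohort(cfg2)
  calls2 <- qmsp_pair_calls(sim2$ct, sim2$sheet)
  expect_identical(as.character(calls2$call[match(sim2$truth$patient_id,
                                                  calls2$patient_id)]),
                   sim2$truth$class)
})

test_that("QMSP config validation rejects bad fractions and sizes", {
  expect_error(qmsp_sim_config(n_pairs = 0), "n_pairs")
  expect_error(qmsp_sim_config(fraction_hypo = 0.5, fraction_equal = 0.1,
                               fraction_hyper = 0.1), "sum to 1")
  expect_error(qmsp_sim_config(fraction_hypo = 1.2, fraction_equal = -0.2,
                               fraction_hyper = 0), ">= 0")
})

test_that("study-sized QMSP cohort lands near the configured hypo rate", {
  sim <- generate_qmsp_cohort(qmsp_sim_config(n_pairs = 548, seed = 1))
  calls <- qmsp_pair_calls(sim$ct, sim$sheet)
  rates <- cohort_rates(calls)
  expect_lt(abs(rates$percent[["hypo"]] - 91.4), 2)
})

test_that("plasma generator separates groups as configured", {
  cfg <- plasma_sim_config(crc_positive_fraction = 1,
                           healthy_positive_fraction = 0, seed = 2)
  sim <- generate_plasma_cohort(cfg)
  expect_identical(sim$plasma, generate_plasma_cohort(cfg)$plasma)
  s <- plasma_diagnostics(sim$plasma)
  expect_equal(s$sensitivity, 1)
  expect_equal(s$ppv, 1)
  # healthy negatives sit around the configured mean level
  healthy <- sim$plasma$relative_level[sim$plasma$group == "healthy"]
  expect_gt(mean(healthy), 15)
  expect_lt(mean(healthy), 40)
})

test_that("plasma sensitivity averages near the configured positive
           fraction over many seeds", {
  sens <- vapply(1:150, function(s) {
    sim <- generate_plasma_cohort(plasma_sim_config(
      n_crc = 15, n_healthy = 15, crc_positive_fraction = 0.87, seed = s))
    plasma_diagnostics(sim$plasma)$sensitivity
  }, numeric(1))
  expect_lt(abs(mean(sens) - 0.866), 0.04)
})

test_that("survival generator censors as configured and carries the
           planted hazard effect", {
  all_cens <- generate_clinical_survival(
    survival_sim_config(n_patients = 50, censor_rate = 1, seed = 4))
  expect_true(all(!all_cens$clinical$death_event))

  no_cens <- generate_clinical_survival(
    survival_sim_config(n_patients = 50, censor_rate = 0, seed = 4))
  expect_true(all(no_cens$clinical$death_event))

  # power: a hazard ratio of 3 at n = 300 is detected in most replicates
  rejections <- vapply(1:100, function(s) {
    sim <- generate_clinical_survival(survival_sim_config(
      n_patients = 300, hypo_fraction = 0.5, hazard_ratio_hypo = 3,
      censor_rate = 0.3, seed = s))
    survival_by_call(sim$calls, sim$clinical)$logrank$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.8)
})

test_that("generators restore the caller's RNG state", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_qmsp_cohort(qmsp_sim_config(n_pairs = 5, seed = 1)))
  expect_identical(.Random.seed, before)
})
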