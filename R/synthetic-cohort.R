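# Synthetic cohorts with planted truth.
#
# Each generator takes a validated config (with its own seed) and emulates
# one data modality of a paired tumor/normal methylation study:
#   * 450K-style beta matrices with planted hypomethylated genes,
#   * QMSP Ct tables built as an exact inverse of the delta-delta-Ct
#     pipeline,
#   * plasma relative-level tables separating healthy from CRC subjects,
#   * clinical covariates with exponential survival and a group hazard
#     ratio between methylation calls.
# All randomness goes through R's default Mersenne-Twister stream, seeded
# locally per call: the caller's RNG state is saved and restored, so equal
# configs give identical outputs regardless of surrounding code.

with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# beta draws parameterized by mean and concentration (phi):
# shape1 = m * phi, shape2 = (1 - m) * phi, so E = m, Var shrinks as phi grows
rbeta_mean <- function(n, mean, concentration) {
  stats::rbeta(n, shape1 = mean * concentration,
               shape2 = (1 - mean) * concentration)
}

#' Configuration for the methylation-array cohort generator
#'
#' Defaults mirror the discovery setting the package targets: 26
#' tumor/normal pairs, planted hypomethylated genes with normal-tissue mean
#' beta 0.55 and tumor mean beta 0.12, the rest of the gene universe
#' methylated identically in both tissues at gene-specific baselines.
#'
#' @param n_pairs number of tumor/normal pairs (>= 2).
#' @param n_genes number of genes in the simulated universe.
#' @param probes_per_gene probes (CpG sites) per gene.
#' @param planted_hypo_genes gene symbols planted as hypomethylated in
#'   tumors; must be a subset of the generated universe `G001..G<n_genes>`.
#' @param normal_beta_mean mean beta of planted genes in normal tissue.
#' @param tumor_beta_mean_planted mean beta of planted genes in tumor tissue.
#' @param beta_dispersion concentration of the beta distribution
#'   (larger = tighter around the mean; variance = m(1-m)/(1+phi)).
#' @param missing_rate per-cell probability of a missing beta value.
#' @param seed integer seed.
#' @return A validated config list of class `methylation_sim_config`.
#' @export
methylation_sim_config <- function(n_pairs = 26, n_genes = 20,
                                   probes_per_gene = 5,
                                   planted_hypo_genes = "G001",
                                   normal_beta_mean = 0.55,
                                   tumor_beta_mean_planted = 0.12,
                                   beta_dispersion = 60,
                                   missing_rate = 0.02, seed = 1) {
  if (n_pairs < 2) stop("n_pairs must be >= 2")
  if (n_genes < 1 || probes_per_gene < 1)
    stop("n_genes and probes_per_gene must be >= 1")
  if (normal_beta_mean <= 0 || normal_beta_mean >= 1 ||
      tumor_beta_mean_planted <= 0 || tumor_beta_mean_planted >= 1)
    stop("beta means must lie strictly in (0, 1)")
  if (beta_dispersion <= 0) stop("beta_dispersion must be > 0")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  universe <- sprintf("G%03d", seq_len(n_genes))
  bad <- setdiff(planted_hypo_genes, universe)
  if (length(bad))
    stop("planted gene(s) not in universe: ", paste(bad, collapse = ", "))
  structure(list(
    n_pairs = as.integer(n_pairs), n_genes = as.integer(n_genes),
    probes_per_gene = as.integer(probes_per_gene),
    planted_hypo_genes = as.character(planted_hypo_genes),
    normal_beta_mean = normal_beta_mean,
    tumor_beta_mean_planted = tumor_beta_mean_planted,
    beta_dispersion = beta_dispersion, missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "methylation_sim_config")
}

# plausible TSS offsets cycled over probes within a gene: five promoter
# sites upstream, five gene-body sites downstream
PROBE_OFFSETS <- c(-1133L, -525L, -413L, -122L, -94L,
                   12535L, 927L, 11421L, 1331L, 2511L)

#' Generate a paired tumor/normal methylation-array cohort
#'
#' Beta values are drawn from beta distributions parameterized by mean and
#' concentration (guaranteeing \[0,1\] support).  Planted genes get
#' `normal_beta_mean` in normals and `tumor_beta_mean_planted` in tumors;
#' every other gene gets a gene-specific baseline mean (uniform on
#' \[0.15, 0.85\]) shared by both tissues, so only planted genes carry a
#' tumor-normal difference.  Missing cells are masked independently at
#' `missing_rate`.
#'
#' @param config a [methylation_sim_config()].
#' @param cohort cohort label written into the sample sheet.
#' @return A list: `beta` ([beta_matrix()]), `sheet` ([sample_sheet()]),
#'   `annotation` ([probe_annotation()]), and `truth` (data.frame of gene
#'   symbol, planted flag, and the tissue means used).
#' @export
generate_methylation_cohort <- function(config, cohort = "cohortA") {
  stopifnot(inherits(config, "methylation_sim_config"))
  with_local_seed(config$seed, {
    genes <- sprintf("G%03d", seq_len(config$n_genes))
    n_probes <- config$n_genes * config$probes_per_gene
    probe_gene <- rep(genes, each = config$probes_per_gene)
    probes <- sprintf("cg%08d", seq_len(n_probes))
    offsets <- PROBE_OFFSETS[(seq_len(config$probes_per_gene) - 1L) %%
                               length(PROBE_OFFSETS) + 1L]
    ann <- probe_annotation(probes, probe_gene,
                            rep(offsets, times = config$n_genes))

    planted <- genes %in% config$planted_hypo_genes
    base_mean <- stats::runif(config$n_genes, 0.15, 0.85)
    mean_n <- ifelse(planted, config$normal_beta_mean, base_mean)
    mean_t <- ifelse(planted, config$tumor_beta_mean_planted, base_mean)

    patients <- sprintf("P%03d", seq_len(config$n_pairs))
    normal_ids <- paste0(patients, "_N")
    tumor_ids <- paste0(patients, "_T")
    sheet <- sample_sheet(c(normal_ids, tumor_ids),
                          c(patients, patients),
                          rep(c("normal", "tumor"), each = config$n_pairs),
                          cohort = cohort)

    draw <- function(means) {
      m <- matrix(NA_real_, n_probes, config$n_pairs)
      for (g in seq_len(config$n_genes)) {
        rows <- which(probe_gene == genes[g])
        m[rows, ] <- rbeta_mean(length(rows) * config$n_pairs, means[g],
                                config$beta_dispersion)
      }
      m
    }
    values <- cbind(draw(mean_n), draw(mean_t))
    rownames(values) <- probes
    colnames(values) <- c(normal_ids, tumor_ids)
    if (config$missing_rate > 0) {
      mask <- stats::runif(length(values)) < config$missing_rate
      values[mask] <- NA_real_
    }
    list(
      beta = beta_matrix(values, annotation = ann, sheet = sheet),
      sheet = sheet,
      annotation = ann,
      truth = data.frame(gene_symbol = genes, planted = planted,
                         normal_mean = mean_n, tumor_mean = mean_t,
                         stringsAsFactors = FALSE)
    )
  })
}

#' Configuration for the QMSP Ct-table generator
#'
#' Default class fractions follow a cohort in which 91.4% of pairs are
#' hypomethylated, 3.6% unchanged and 5.0% hypermethylated.
#'
#' @param n_pairs number of tumor/normal pairs (>= 1).
#' @param fraction_hypo,fraction_equal,fraction_hyper class probabilities,
#'   nonnegative and summing to 1.
#' @param reference_ct_mean mean Ct of the reference assay (cycles).
#' @param noise_sd per-replicate Ct noise (cycles); 0 gives exact recovery
#'   of the planted class by the delta-delta-Ct pipeline.
#' @param n_replicates technical replicates per sample and assay.
#' @param seed integer seed.
#' @return A validated config list of class `qmsp_sim_config`.
#' @export
qmsp_sim_config <- function(n_pairs = 548, fraction_hypo = 0.914,
                            fraction_equal = 0.036, fraction_hyper = 0.05,
                            reference_ct_mean = 25, noise_sd = 0.15,
                            n_replicates = 3, seed = 1) {
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  fr <- c(fraction_hypo, fraction_equal, fraction_hyper)
  if (any(fr < 0)) stop("class fractions must be >= 0")
  if (abs(sum(fr) - 1) > 1e-8)
    stop("class fractions must sum to 1 (got ", sum(fr), ")")
  if (reference_ct_mean <= 0) stop("reference_ct_mean must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(
    n_pairs = as.integer(n_pairs), fraction_hypo = fraction_hypo,
    fraction_equal = fraction_equal, fraction_hyper = fraction_hyper,
    reference_ct_mean = reference_ct_mean, noise_sd = noise_sd,
    n_replicates = as.integer(n_replicates), seed = as.integer(seed)
  ), class = "qmsp_sim_config")
}

#' Generate a QMSP Ct table with planted pair classes
#'
#' Each patient is assigned a truth class (hypo/equal/hyper) at the
#' configured fractions, then a tumor/normal fold ratio drawn safely inside
#' that class's band (log2 ratio uniform on \[-5.5, -1.2\], \[-0.6, 0.6\] or
#' \[1.2, 3\]).  Ct values are constructed as the exact inverse of the
#' delta-delta-Ct transform: the reference assay sits at
#' `reference_ct_mean`, and the target assay at reference + the delta-Ct
#' implied by the desired relative level, with independent
#' `Normal(0, noise_sd)` noise per replicate.  With `noise_sd = 0` the
#' quantification pipeline reproduces the truth class for every patient.
#'
#' @param config a [qmsp_sim_config()].
#' @param cohort cohort label for the sample sheet.
#' @return A list: `ct` ([ct_table()]), `sheet` ([sample_sheet()]), `truth`
#'   (data.frame of patient, class and planted ratio).
#' @export
generate_qmsp_cohort <- function(config, cohort = "qmsp") {
  stopifnot(inherits(config, "qmsp_sim_config"))
  with_local_seed(config$seed, {
    n <- config$n_pairs
    cls <- sample(c("hypo", "equal", "hyper"), n, replace = TRUE,
                  prob = c(config$fraction_hypo, config$fraction_equal,
                           config$fraction_hyper))
    log2_ratio <- numeric(n)
    log2_ratio[cls == "hypo"] <- stats::runif(sum(cls == "hypo"), -5.5, -1.2)
    log2_ratio[cls == "equal"] <- stats::runif(sum(cls == "equal"), -0.6, 0.6)
    log2_ratio[cls == "hyper"] <- stats::runif(sum(cls == "hyper"), 1.2, 3)
    # normal-tissue relative level varies across patients on its own
    log2_level_n <- stats::runif(n, -2, 2)
    log2_level_t <- log2_level_n + log2_ratio

    patients <- sprintf("P%03d", seq_len(n))
    normal_ids <- paste0(patients, "_N")
    tumor_ids <- paste0(patients, "_T")
    sheet <- sample_sheet(c(normal_ids, tumor_ids), c(patients, patients),
                          rep(c("normal", "tumor"), each = n),
                          cohort = cohort)

    k <- config$n_replicates
    mk_rows <- function(sample_ids, log2_level) {
      # delta-Ct implied by the level: level = 2^-(dCt) -> dCt = -log2(level)
      dct <- -log2_level
      ns <- length(sample_ids)
      sample_col <- rep(sample_ids, each = 2 * k)
      assay_col <- rep(rep(c("reference", "target"), each = k), times = ns)
      mean_ct <- config$reference_ct_mean +
        ifelse(assay_col == "target", dct[match(sample_col, sample_ids)], 0)
      data.frame(
        sample_id = sample_col,
        assay = assay_col,
        replicate = rep(rep(seq_len(k), 2), times = ns),
        ct = mean_ct + stats::rnorm(2 * k * ns, 0, config$noise_sd),
        stringsAsFactors = FALSE
      )
    }
    rows <- rbind(mk_rows(normal_ids, log2_level_n),
                  mk_rows(tumor_ids, log2_level_t))
    ct <- ct_table(rows$sample_id, rows$assay, rows$ct, rows$replicate)
    list(ct = ct, sheet = sheet,
         truth = data.frame(patient_id = patients, class = cls,
                            ratio = 2^log2_ratio, stringsAsFactors = FALSE))
  })
}

#' Configuration for the plasma ccfDNA cohort generator
#'
#' Defaults size the cohort like a small plasma pilot: 15 healthy and 15
#' CRC subjects, a healthy mean relative level of 25.37, and CRC positives
#' drawn strictly below the 0.5 hypomethylation cutoff.
#'
#' @param n_healthy,n_crc subject counts (>= 1).
#' @param healthy_mean_level mean relative level of negative healthy
#'   subjects (log-normal, sdlog 0.35).
#' @param crc_positive_fraction probability that a CRC subject is a true
#'   hypomethylation positive (level below the bound).
#' @param healthy_positive_fraction probability that a healthy subject is a
#'   false positive; 0 keeps all healthy levels around `healthy_mean_level`.
#' @param positive_level_upper_bound positives are drawn strictly below
#'   this level (default 0.5).
#' @param seed integer seed.
#' @return A validated config list of class `plasma_sim_config`.
#' @export
plasma_sim_config <- function(n_healthy = 15, n_crc = 15,
                              healthy_mean_level = 25.37,
                              crc_positive_fraction = 0.87,
                              healthy_positive_fraction = 0,
                              positive_level_upper_bound = 0.5, seed = 1) {
  if (n_healthy < 1 || n_crc < 1) stop("subject counts must be >= 1")
  if (healthy_mean_level <= 0) stop("healthy_mean_level must be > 0")
  if (positive_level_upper_bound <= 0)
    stop("positive_level_upper_bound must be > 0")
  if (crc_positive_fraction < 0 || crc_positive_fraction > 1 ||
      healthy_positive_fraction < 0 || healthy_positive_fraction > 1)
    stop("positive fractions must be in [0, 1]")
  structure(list(
    n_healthy = as.integer(n_healthy), n_crc = as.integer(n_crc),
    healthy_mean_level = healthy_mean_level,
    crc_positive_fraction = crc_positive_fraction,
    healthy_positive_fraction = healthy_positive_fraction,
    positive_level_upper_bound = positive_level_upper_bound,
    seed = as.integer(seed)
  ), class = "plasma_sim_config")
}

#' Generate a plasma ccfDNA relative-level cohort
#'
#' Positives (hypomethylated) get levels uniform on (0, bound); negatives
#' get log-normal levels centered at `healthy_mean_level` (healthy) or
#' uniform on log scale between 2x the bound and the healthy mean (CRC
#' negatives, which sit above the cutoff but below typical healthy levels).
#'
#' @param config a [plasma_sim_config()].
#' @return A list: `plasma` ([plasma_table()]) and `truth` (data.frame with
#'   the planted positive flag per subject).
#' @export
generate_plasma_cohort <- function(config) {
  stopifnot(inherits(config, "plasma_sim_config"))
  with_local_seed(config$seed, {
    ub <- config$positive_level_upper_bound
    m <- config$healthy_mean_level
    sdlog <- 0.35
    draw_group <- function(n, pos_fraction, prefix) {
      pos <- stats::runif(n) < pos_fraction
      level <- numeric(n)
      level[pos] <- stats::runif(sum(pos), ub * 0.01, ub * 0.98)
      n_neg <- sum(!pos)
      if (prefix == "H") {
        level[!pos] <- stats::rlnorm(n_neg, log(m) - sdlog^2 / 2, sdlog)
      } else {
        level[!pos] <- exp(stats::runif(n_neg, log(2 * ub), log(m)))
      }
      list(id = sprintf("%s%03d", prefix, seq_len(n)), level = level,
           pos = pos)
    }
    h <- draw_group(config$n_healthy, config$healthy_positive_fraction, "H")
    c_ <- draw_group(config$n_crc, config$crc_positive_fraction, "C")
    plasma <- plasma_table(c(h$id, c_$id),
                           rep(c("healthy", "CRC"),
                               c(config$n_healthy, config$n_crc)),
                           c(h$level, c_$level))
    list(plasma = plasma,
         truth = data.frame(subject_id = plasma$subject_id,
                            planted_positive = c(h$pos, c_$pos),
                            stringsAsFactors = FALSE))
  })
}

#' Configuration for the clinical/survival cohort generator
#'
#' Event times are exponential with a proportional-hazards effect of the
#' hypomethylation call; censoring is independent exponential calibrated so
#' that roughly `censor_rate` of the baseline group is censored.  Covariate
#' frequencies default to a cohort that is 54% over age 65, 59% male and
#' 55% stage III-IV.
#'
#' @param n_patients cohort size (>= 2).
#' @param hypo_fraction fraction of patients with a hypomethylation call.
#' @param baseline_hazard events per month in the non-hypo group.
#' @param hazard_ratio_hypo hazard ratio of the hypo group vs non-hypo.
#' @param censor_rate target censoring fraction in \[0, 1\].
#' @param covariate_frequencies named numeric vector with elements
#'   `age_gt65`, `male`, `stage_iii_iv` in \[0, 1\].
#' @param seed integer seed.
#' @return A validated config list of class `survival_sim_config`.
#' @export
survival_sim_config <- function(n_patients = 548, hypo_fraction = 0.914,
                                baseline_hazard = 0.01,
                                hazard_ratio_hypo = 2, censor_rate = 0.3,
                                covariate_frequencies = c(age_gt65 = 0.54,
                                                          male = 0.59,
                                                          stage_iii_iv = 0.55),
                                seed = 1) {
  if (n_patients < 2) stop("n_patients must be >= 2")
  if (baseline_hazard <= 0 || hazard_ratio_hypo <= 0)
    stop("hazards must be > 0")
  if (hypo_fraction < 0 || hypo_fraction > 1 ||
      censor_rate < 0 || censor_rate > 1)
    stop("fractions must be in [0, 1]")
  req <- c("age_gt65", "male", "stage_iii_iv")
  if (!all(req %in% names(covariate_frequencies)))
    stop("covariate_frequencies must name: ", paste(req, collapse = ", "))
  if (any(covariate_frequencies < 0) || any(covariate_frequencies > 1))
    stop("covariate frequencies must be in [0, 1]")
  structure(list(
    n_patients = as.integer(n_patients), hypo_fraction = hypo_fraction,
    baseline_hazard = baseline_hazard,
    hazard_ratio_hypo = hazard_ratio_hypo, censor_rate = censor_rate,
    covariate_frequencies = covariate_frequencies, seed = as.integer(seed)
  ), class = "survival_sim_config")
}

#' Generate a clinical covariate and survival cohort
#'
#' @param config a [survival_sim_config()].
#' @return A list: `clinical` ([clinical_table()]) and `calls` (data.frame
#'   with `patient_id` and a `call` factor, `hypo` vs `equal`).
#' @export
generate_clinical_survival <- function(config) {
  stopifnot(inherits(config, "survival_sim_config"))
  with_local_seed(config$seed, {
    n <- config$n_patients
    fr <- config$covariate_frequencies
    patients <- sprintf("P%03d", seq_len(n))
    hypo <- stats::runif(n) < config$hypo_fraction
    over65 <- stats::runif(n) < fr[["age_gt65"]]
    age <- ifelse(over65, stats::runif(n, 66, 90), stats::runif(n, 35, 64))
    sex <- ifelse(stats::runif(n) < fr[["male"]], "male", "female")
    late <- stats::runif(n) < fr[["stage_iii_iv"]]
    stage <- ifelse(late,
                    sample(c("III", "IV"), n, replace = TRUE,
                           prob = c(0.7, 0.3)),
                    sample(c("0", "I", "II"), n, replace = TRUE,
                           prob = c(0.05, 0.25, 0.7)))
    tumor_type <- ifelse(stats::runif(n) < 0.9, "adeno", "mucinous")
    grade <- ifelse(stats::runif(n) < 0.93, "well_moderate",
                    "poor_undifferentiated")
    location <- sample(c("cecum_appendix", "ascending_colon",
                         "transverse_colon", "descending_colon",
                         "sigmoid_colon", "rectum"), n, replace = TRUE,
                       prob = c(0.09, 0.18, 0.04, 0.10, 0.32, 0.27))
    msi <- sample(MSI_LEVELS, n, replace = TRUE, prob = c(0.77, 0.09, 0.14))

    rate <- config$baseline_hazard *
      ifelse(hypo, config$hazard_ratio_hypo, 1)
    event_time <- stats::rexp(n, rate)
    if (config$censor_rate == 0) {
      time <- event_time; event <- rep(TRUE, n)
    } else if (config$censor_rate == 1) {
      time <- stats::rexp(n, config$baseline_hazard)
      event <- rep(FALSE, n)
    } else {
      cr <- config$censor_rate
      censor_time <- stats::rexp(n, config$baseline_hazard * cr / (1 - cr))
      time <- pmin(event_time, censor_time)
      event <- event_time <= censor_time
    }
    clinical <- clinical_table(
      patients, age = age, sex = sex, tumor_type = tumor_type,
      stage = stage,
      t_size = ifelse(late, sample(2:4, n, replace = TRUE),
                      sample(0:2, n, replace = TRUE)),
      n_status = as.integer(late & stats::runif(n) < 0.8),
      m_status = as.integer(stage == "IV"),
      grade = grade, location = location, msi = msi,
      followup_months = time, death_event = event
    )
    calls <- data.frame(
      patient_id = patients,
      call = factor(ifelse(hypo, "hypo", "equal"),
                    levels = c("hypo", "equal", "hyper")),
      stringsAsFactors = FALSE
    )
    list(clinical = clinical, calls = calls)
  })
}
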