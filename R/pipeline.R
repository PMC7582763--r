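# End-to-end orchestration: simulate (or load) each data modality, run
# discovery, quantification, plasma diagnostics, clinical association and
# survival stratification, and emit a report bundle with a run log.
#
# Every stage takes exactly one input source: either file paths to the
# tabular formats of the data model, or a simulation config.  All
# thresholds are surfaced in the config; nothing downstream hard-codes the
# 0.5 / 2 / -0.25 / 0.2 boundaries.

#' Assemble a pipeline configuration
#'
#' Each stage block is either `NULL` (stage skipped), a list of file
#' `paths`, or a simulation config (a `sim` entry).  Defaults run the
#' all-synthetic study-sized pipeline: two 26-pair discovery cohorts, a
#' 548-pair QMSP cohort, a 15 + 15 plasma cohort and a 548-patient
#' survival cohort, with per-stage seeds derived from `seed`.
#'
#' @param seed master integer seed; stage configs built here use
#'   `seed + 1 .. seed + 5`.
#' @param discovery list: `sim_a`, `sim_b` ([methylation_sim_config()]s) or
#'   `paths` (named: `beta_a`, `sheet_a`, `annotation`, optionally
#'   `beta_b`, `sheet_b`); plus `criteria` ([discovery_criteria()]).
#' @param quantification list: `sim` ([qmsp_sim_config()]) or `paths`
#'   (named: `ct`, `sheet`); plus `base` (amplification factor).
#' @param plasma list: `sim` ([plasma_sim_config()]) or `paths` (named:
#'   `plasma`); plus `cutoff` and optional `sweep` (cutoff grid).
#' @param clinical list: `sim` ([survival_sim_config()]) or `paths`
#'   (named: `clinical`, `calls`); plus `parameters` (clinical parameters
#'   to break down) and `subgroups` (survival subgroup filters).
#' @param out_dir optional output directory; when given, every table of
#'   the report bundle is written there as CSV plus a `run_log.txt`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            discovery = NULL,
                            quantification = NULL,
                            plasma = NULL,
                            clinical = NULL,
                            out_dir = NULL) {
  if (is.null(discovery))
    discovery <- list(sim_a = methylation_sim_config(seed = seed + 1),
                      sim_b = methylation_sim_config(seed = seed + 2),
                      criteria = discovery_criteria())
  if (is.null(discovery$criteria)) discovery$criteria <- discovery_criteria()
  if (is.null(quantification))
    quantification <- list(sim = qmsp_sim_config(seed = seed + 3))
  if (is.null(quantification$base)) quantification$base <- 2
  if (is.null(plasma))
    plasma <- list(sim = plasma_sim_config(seed = seed + 4))
  if (is.null(plasma$cutoff)) plasma$cutoff <- 0.5
  if (is.null(clinical))
    clinical <- list(sim = survival_sim_config(seed = seed + 5))
  if (is.null(clinical$parameters))
    clinical$parameters <- c("age", "sex", "stage")
  if (is.null(clinical$subgroups))
    clinical$subgroups <- c("age_gt65", "male", "stage_iii_iv")
  for (nm in c("discovery", "quantification", "plasma", "clinical")) {
    st <- get(nm)
    has_sim <- !is.null(st$sim) || !is.null(st$sim_a)
    has_paths <- !is.null(st$paths)
    if (!is.logical(st$enabled)) st$enabled <- TRUE
    if (st$enabled && has_sim && has_paths)
      stop(nm, ": give either simulation config(s) or paths, not both")
    if (st$enabled && !has_sim && !has_paths)
      stop(nm, ": needs a simulation config or paths (or enabled = FALSE)")
    assign(nm, st)
  }
  structure(list(seed = as.integer(seed), discovery = discovery,
                 quantification = quantification, plasma = plasma,
                 clinical = clinical, out_dir = out_dir),
            class = "pipeline_config")
}

# stable short checksum of the deparsed config, for run provenance
config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "\n")
  bytes <- as.integer(charToRaw(txt))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()]: top-level `seed`, `out_dir`, and
#' one block per stage holding either a `paths` map or the fields of the
#' stage's simulation config (under `sim`, or `sim_a`/`sim_b` for
#' discovery), plus the stage's analysis settings (`criteria`, `base`,
#' `cutoff`, `sweep`, `parameters`, `subgroups`).
#'
#' @param path YAML file.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- if (is.null(y$seed)) 1L else as.integer(y$seed)
  build <- function(block, ctor, sim_names = "sim") {
    if (is.null(block)) return(NULL)
    for (s in sim_names)
      if (!is.null(block[[s]])) block[[s]] <- do.call(ctor, block[[s]])
    if (!is.null(block$criteria))
      block$criteria <- do.call(discovery_criteria, block$criteria)
    block
  }
  disc <- build(y$discovery, methylation_sim_config, c("sim_a", "sim_b"))
  quant <- build(y$quantification, qmsp_sim_config)
  plas <- build(y$plasma, plasma_sim_config)
  clin <- build(y$clinical, survival_sim_config)
  args <- list(seed = seed, out_dir = y$out_dir)
  if (!is.null(disc)) args$discovery <- disc
  if (!is.null(quant)) args$quantification <- quant
  if (!is.null(plas)) args$plasma <- plas
  if (!is.null(clin)) args$clinical <- clin
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order (discovery, quantification, plasma
#' diagnostics, clinical association + survival), collecting every result
#' table into a report bundle.  Deterministic given the config (all
#' randomness flows through the per-stage seeds).  Any stage error aborts
#' with the stage name prefixed.
#'
#' @param config a [pipeline_config()] or the path to a YAML file for
#'   [read_pipeline_config()].
#' @return A list of class `pipeline_report`: `candidates`, `qmsp_calls`,
#'   `qmsp_rates`, `plasma_summary`, `plasma_sweep`, `breakdowns` (one per
#'   clinical parameter), `survival` (one per subgroup, plus `all`),
#'   `log` (character), `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  log <- c(sprintf("pipeline start (seed %d, config %s)", config$seed,
                   config_hash(config)))
  note <- function(...) log <<- c(log, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  report <- list(config_hash = config_hash(config))

  dc <- config$discovery
  if (isTRUE(dc$enabled)) report$candidates <- stage("discovery", {
    if (!is.null(dc$paths)) {
      ann <- read_probe_annotation(dc$paths$annotation)
      sheet_a <- read_sample_sheet(dc$paths$sheet_a)
      beta_a <- read_beta_matrix(dc$paths$beta_a, ann, sheet_a)
      summ_a <- summarize_cohort(beta_a, sheet_a)
      summ_b <- NULL
      if (!is.null(dc$paths$beta_b)) {
        sheet_b <- read_sample_sheet(dc$paths$sheet_b)
        beta_b <- read_beta_matrix(dc$paths$beta_b, ann, sheet_b)
        summ_b <- summarize_cohort(beta_b, sheet_b)
      }
    } else {
      coh_a <- generate_methylation_cohort(dc$sim_a, cohort = "cohortA")
      ann <- coh_a$annotation
      summ_a <- summarize_cohort(coh_a$beta, coh_a$sheet)
      summ_b <- NULL
      if (!is.null(dc$sim_b)) {
        coh_b <- generate_methylation_cohort(dc$sim_b, cohort = "cohortB")
        summ_b <- summarize_cohort(coh_b$beta, coh_b$sheet)
      }
    }
    cand <- select_candidates(summ_a, summ_b, ann, dc$criteria)
    note("discovery: %d probes in cohort A, %d candidate gene(s)",
         nrow(summ_a), nrow(cand))
    cand
  })

  qc <- config$quantification
  if (isTRUE(qc$enabled)) {
    res <- stage("quantification", {
      if (!is.null(qc$paths)) {
        ct <- read_ct_table(qc$paths$ct)
        sheet <- read_sample_sheet(qc$paths$sheet)
      } else {
        sim <- generate_qmsp_cohort(qc$sim)
        ct <- sim$ct; sheet <- sim$sheet
      }
      calls <- qmsp_pair_calls(ct, sheet, base = qc$base)
      note("quantification: %d paired patients called (%d skipped)",
           nrow(calls), attr(calls, "n_skipped"))
      list(calls = calls, rates = cohort_rates(calls))
    })
    report$qmsp_calls <- res$calls
    report$qmsp_rates <- res$rates
  }

  pc <- config$plasma
  if (isTRUE(pc$enabled)) {
    res <- stage("plasma", {
      plasma <- if (!is.null(pc$paths)) read_plasma_table(pc$paths$plasma)
      else generate_plasma_cohort(pc$sim)$plasma
      summ <- plasma_diagnostics(plasma, plasma_call_config(pc$cutoff))
      sweep <- if (!is.null(pc$sweep)) threshold_sweep(plasma, pc$sweep)
      note("plasma: %d subjects, sensitivity %.3f", summ$n,
           summ$sensitivity)
      list(summary = summ, sweep = sweep)
    })
    report$plasma_summary <- res$summary
    report$plasma_sweep <- res$sweep
  }

  cc <- config$clinical
  if (isTRUE(cc$enabled)) {
    res <- stage("clinical", {
      if (!is.null(cc$paths)) {
        clinical <- read_clinical_table(cc$paths$clinical)
        calls_df <- utils::read.csv(cc$paths$calls,
                                    stringsAsFactors = FALSE)
        calls_df$call <- factor(calls_df$call,
                                levels = call_levels("methylation"))
      } else {
        sim <- generate_clinical_survival(cc$sim)
        clinical <- sim$clinical
        calls_df <- sim$calls
      }
      breakdowns <- lapply(cc$parameters, function(p)
        clinical_breakdown(calls_df, clinical, p))
      names(breakdowns) <- cc$parameters
      surv <- list(all = survival_by_call(calls_df, clinical))
      for (sg in cc$subgroups)
        surv[[sg]] <- survival_by_call(calls_df, clinical, subgroup = sg)
      note("clinical: %d patients, %d parameter breakdown(s), %d survival strata",
           nrow(clinical), length(breakdowns), length(surv))
      list(breakdowns = breakdowns, survival = surv)
    })
    report$breakdowns <- res$breakdowns
    report$survival <- res$survival
  }

  note("pipeline done")
  report$log <- log
  class(report) <- "pipeline_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write a pipeline report bundle to CSV files
#'
#' @param report a `pipeline_report` from [run_pipeline()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, name)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  if (!is.null(report$candidates)) w(report$candidates, "candidates.csv")
  if (!is.null(report$qmsp_calls)) w(report$qmsp_calls, "qmsp_calls.csv")
  if (!is.null(report$qmsp_rates)) {
    r <- report$qmsp_rates
    w(data.frame(class = names(r$counts), count = r$counts,
                 percent = r$percent), "qmsp_rates.csv")
  }
  if (!is.null(report$plasma_summary)) {
    s <- report$plasma_summary
    w(data.frame(metric = c("sensitivity", "specificity", "ppv", "npv",
                            "exact_test_p", "n"),
                 value = c(s$sensitivity, s$specificity, s$ppv, s$npv,
                           s$exact_test_p, s$n)), "plasma_summary.csv")
  }
  if (!is.null(report$plasma_sweep)) w(report$plasma_sweep,
                                       "plasma_sweep.csv")
  for (p in names(report$breakdowns))
    w(report$breakdowns[[p]]$rows, paste0("breakdown_", p, ".csv"))
  for (sg in names(report$survival)) {
    s <- report$survival[[sg]]
    curve_df <- function(curve, grp)
      data.frame(group = grp, time = curve$time, survival = curve$survival,
                 at_risk = curve$at_risk, n_events = curve$n_events)
    w(rbind(curve_df(s$curve_hypo, "hypo"),
            curve_df(s$curve_other, "non_hypo")),
      paste0("survival_", sg, ".csv"))
  }
  writeLines(c(report$log, paste("config", report$config_hash)),
             file.path(dir, "run_log.txt"))
  invisible(dir)
}
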