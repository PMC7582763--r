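# Domain types and tabular I/O for methylation-biomarker analyses.
#
# All on-disk formats are plain text: TSV for beta matrices (probes x
# samples), CSV for sample sheets, Ct tables, clinical tables and plasma
# tables.  Missing beta values are written as the literal "NA"; missing
# clinical fields as the empty string.  Decimal separator is ".".

TISSUE_TYPES <- c("normal", "tumor", "polyp")
ASSAY_TYPES  <- c("target", "reference")
MSI_LEVELS   <- c("MSS", "MSI-L", "MSI-H")
STAGE_LEVELS <- c("0", "I", "II", "III", "IV")

#' Create a probe annotation table
#'
#' A probe annotation maps array probe identifiers (cg-style) to gene symbols
#' and a signed base-pair offset relative to the transcription start site.
#' The region class is derived from the offset: negative offsets (upstream of
#' the TSS) are `promoter`, nonnegative offsets are `gene_body`.
#'
#' @param probe_id character vector of unique probe identifiers.
#' @param gene_symbol character vector of gene symbols, one per probe.
#' @param offset_bp integer vector of signed offsets from the TSS (1-based
#'   distance; the sign encodes the side, negative = upstream).
#' @return A `data.frame` of class `probe_annotation` with columns
#'   `probe_id`, `gene_symbol`, `offset_bp`, `region_class`.
#' @examples
#' probe_annotation(c("cg0001", "cg0002"), c("GENE1", "GENE1"), c(-525L, 12535L))
#' @export
probe_annotation <- function(probe_id, gene_symbol, offset_bp) {
  probe_id <- as.character(probe_id)
  gene_symbol <- as.character(gene_symbol)
  offset_bp <- as.integer(offset_bp)
  if (length(probe_id) != length(gene_symbol) ||
      length(probe_id) != length(offset_bp))
    stop("probe_id, gene_symbol and offset_bp must have equal length")
  if (anyDuplicated(probe_id))
    stop("duplicate probe_id: ",
         paste(unique(probe_id[duplicated(probe_id)]), collapse = ", "))
  if (any(!is.finite(offset_bp)))
    stop("offset_bp must be finite")
  ann <- data.frame(
    probe_id = probe_id,
    gene_symbol = gene_symbol,
    offset_bp = offset_bp,
    region_class = ifelse(offset_bp < 0L, "promoter", "gene_body"),
    stringsAsFactors = FALSE
  )
  class(ann) <- c("probe_annotation", "data.frame")
  ann
}

#' @rdname probe_annotation
#' @param x a `probe_annotation`.
#' @param path file path (CSV).
#' @export
write_probe_annotation <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, c("probe_id", "gene_symbol",
                                        "offset_bp")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname probe_annotation
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("probe_id", "gene_symbol", "offset_bp")
  if (!all(req %in% names(df)))
    stop("probe annotation must have columns: ", paste(req, collapse = ", "))
  probe_annotation(df$probe_id, df$gene_symbol, df$offset_bp)
}

#' Create a sample sheet
#'
#' Links array/assay samples to patients, tissue types and cohorts.  A
#' "paired" patient is one with exactly one normal and one tumor sample;
#' polyp samples carry no pairing requirement and form their own stratum.
#'
#' @param sample_id unique sample identifiers.
#' @param patient_id patient identifiers (repeated across a patient's samples).
#' @param tissue_type one of `"normal"`, `"tumor"`, `"polyp"` per sample.
#' @param cohort cohort label (recycled if scalar).
#' @return A `data.frame` of class `sample_sheet`.
#' @export
sample_sheet <- function(sample_id, patient_id, tissue_type,
                         cohort = "cohort1") {
  sample_id <- as.character(sample_id)
  patient_id <- as.character(patient_id)
  tissue_type <- as.character(tissue_type)
  n <- length(sample_id)
  if (length(patient_id) != n || length(tissue_type) != n)
    stop("sample_id, patient_id and tissue_type must have equal length")
  cohort <- rep_len(as.character(cohort), n)
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  bad <- setdiff(unique(tissue_type), TISSUE_TYPES)
  if (length(bad))
    stop("unknown tissue_type: ", paste(bad, collapse = ", "))
  sheet <- data.frame(
    sample_id = sample_id, patient_id = patient_id,
    tissue_type = tissue_type, cohort = cohort,
    stringsAsFactors = FALSE
  )
  class(sheet) <- c("sample_sheet", "data.frame")
  sheet
}

#' Construct a validated beta-value matrix
#'
#' A beta matrix holds per-probe, per-sample methylation fractions
#' (beta values, 0 = unmethylated to 1 = fully methylated).  Missing values
#' are allowed; every non-missing entry must lie in \[0, 1\].
#'
#' @param values numeric matrix with probe ids as rownames and sample ids as
#'   colnames.
#' @param annotation optional `probe_annotation`; when given, every row of
#'   `values` must be annotated.
#' @param sheet optional `sample_sheet`; when given, every column of `values`
#'   must appear in the sheet.
#' @return `values`, classed as `beta_matrix`, after validation.
#' @export
beta_matrix <- function(values, annotation = NULL, sheet = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have probe rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe id: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id in beta matrix")
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf(
      "beta value out of [0,1] at probe '%s', sample '%s' (value %g)",
      rownames(values)[i], colnames(values)[j], values[i, j]))
  }
  if (!is.null(annotation)) {
    missing_probes <- setdiff(rownames(values), annotation$probe_id)
    if (length(missing_probes))
      stop("probes absent from annotation: ",
           paste(utils::head(missing_probes, 5), collapse = ", "))
  }
  if (!is.null(sheet)) {
    missing_samples <- setdiff(colnames(values), sheet$sample_id)
    if (length(missing_samples))
      stop("samples absent from sample sheet: ",
           paste(utils::head(missing_samples, 5), collapse = ", "))
  }
  structure(values, class = c("beta_matrix", "matrix", "array"))
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d probes x %d samples (%d missing cells)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

#' Write a beta matrix to TSV
#'
#' Probes are rows (first column `probe_id`), samples are columns.  Missing
#' values are written as `NA`.
#'
#' @param x a `beta_matrix` (or numeric matrix with dimnames).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(x, path) {
  df <- data.frame(probe_id = rownames(x),
                   as.data.frame(unclass(x), check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a beta matrix from TSV
#'
#' Inverse of [write_beta_matrix()].  The file must have probe ids in the
#' first column (header `probe_id`) and sample ids as the remaining headers.
#' Validation rejects duplicate probes, values outside \[0, 1\] (naming the
#' offending cell), probes absent from `annotation` and samples absent from
#' `sheet`.
#'
#' @param path TSV file path.
#' @inheritParams beta_matrix
#' @return A validated `beta_matrix`.
#' @export
read_beta_matrix <- function(path, annotation = NULL, sheet = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = NA,
                          stringsAsFactors = FALSE, na.strings = "NA",
                          fileEncoding = "UTF-8")
  if (ncol(df) < 2 || names(df)[1] != "probe_id")
    stop("malformed beta matrix header: first column must be 'probe_id'")
  values <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(values))
    stop("non-numeric beta values in ", path)
  rownames(values) <- df$probe_id
  beta_matrix(values, annotation = annotation, sheet = sheet)
}

#' Write / read a sample sheet (CSV)
#'
#' @param x a `sample_sheet`.
#' @param path file path.
#' @return `path` (writer, invisibly) or a validated `sample_sheet` (reader).
#' @export
write_sample_sheet <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        colClasses = "character")
  req <- c("sample_id", "patient_id", "tissue_type", "cohort")
  if (!all(req %in% names(df)))
    stop("sample sheet must have columns: ", paste(req, collapse = ", "))
  sample_sheet(df$sample_id, df$patient_id, df$tissue_type, df$cohort)
}

#' Create a Ct measurement table
#'
#' One row per technical replicate of a qPCR assay (target or reference) on
#' a sample.  Replicates are aggregated downstream by the arithmetic mean of
#' Ct, see [replicate_means()].
#'
#' @param sample_id sample identifiers.
#' @param assay `"target"` or `"reference"` per row.
#' @param ct quantification cycle, strictly positive.
#' @param replicate replicate index, integer >= 1.
#' @return A `data.frame` of class `ct_table`.
#' @export
ct_table <- function(sample_id, assay, ct, replicate = 1L) {
  sample_id <- as.character(sample_id)
  assay <- as.character(assay)
  ct <- as.numeric(ct)
  n <- length(sample_id)
  replicate <- rep_len(as.integer(replicate), n)
  if (length(assay) != n || length(ct) != n)
    stop("sample_id, assay and ct must have equal length")
  bad <- setdiff(unique(assay), ASSAY_TYPES)
  if (length(bad))
    stop("unknown assay label: ", paste(bad, collapse = ", "))
  if (any(!is.finite(ct)) || any(ct <= 0))
    stop("ct must be positive and finite (offending sample: ",
         paste(utils::head(sample_id[!is.finite(ct) | ct <= 0], 3),
               collapse = ", "), ")")
  if (any(replicate < 1L))
    stop("replicate index must be >= 1")
  df <- data.frame(sample_id = sample_id, assay = assay,
                   replicate = replicate, ct = ct,
                   stringsAsFactors = FALSE)
  class(df) <- c("ct_table", "data.frame")
  df
}

#' @rdname ct_table
#' @param x a `ct_table`.
#' @param path file path.
#' @export
write_ct_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname ct_table
#' @export
read_ct_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "assay", "replicate", "ct")
  if (!all(req %in% names(df)))
    stop("ct table must have columns: ", paste(req, collapse = ", "))
  ct_table(df$sample_id, df$assay, df$ct, df$replicate)
}

#' Mean Ct per sample and assay
#'
#' Aggregates technical replicates by the arithmetic mean of Ct.
#'
#' @param ct a `ct_table`.
#' @return data.frame with columns `sample_id`, `assay`, `ct` (replicate
#'   mean), `n_replicates`.
#' @export
replicate_means <- function(ct) {
  agg <- stats::aggregate(ct ~ sample_id + assay, data = as.data.frame(ct),
                          FUN = mean)
  cnt <- stats::aggregate(ct ~ sample_id + assay, data = as.data.frame(ct),
                          FUN = length)
  agg$n_replicates <- cnt$ct[match(paste(agg$sample_id, agg$assay),
                                   paste(cnt$sample_id, cnt$assay))]
  agg[order(agg$sample_id, agg$assay), , drop = FALSE]
}

#' Create a clinical record table
#'
#' Per-patient clinicopathological covariates and overall-survival follow-up.
#' Any covariate may be missing (`NA`); categorical fields are validated
#' against their vocabularies.
#'
#' @param patient_id patient identifiers (unique).
#' @param age age in years.
#' @param sex `"male"` or `"female"`.
#' @param tumor_type `"adeno"` or `"mucinous"`.
#' @param stage ordinal tumor stage: one of `"0"`, `"I"`, ..., `"IV"`.
#' @param t_size,n_status,m_status ordinal TNM components (integers).
#' @param grade `"well_moderate"` or `"poor_undifferentiated"`.
#' @param location anatomical site label.
#' @param msi `"MSS"`, `"MSI-L"` or `"MSI-H"`.
#' @param followup_months nonnegative follow-up time in months.
#' @param death_event logical, `TRUE` = death observed, `FALSE` = censored.
#' @return A `data.frame` of class `clinical_table`.
#' @export
clinical_table <- function(patient_id, age = NA, sex = NA, tumor_type = NA,
                           stage = NA, t_size = NA, n_status = NA,
                           m_status = NA, grade = NA, location = NA,
                           msi = NA, followup_months = NA,
                           death_event = NA) {
  patient_id <- as.character(patient_id)
  n <- length(patient_id)
  if (anyDuplicated(patient_id))
    stop("duplicate patient_id in clinical table")
  rec <- function(x) rep_len(x, n)
  df <- data.frame(
    patient_id = patient_id,
    age = rec(as.numeric(age)),
    sex = rec(as.character(sex)),
    tumor_type = rec(as.character(tumor_type)),
    stage = rec(as.character(stage)),
    t_size = rec(as.integer(t_size)),
    n_status = rec(as.integer(n_status)),
    m_status = rec(as.integer(m_status)),
    grade = rec(as.character(grade)),
    location = rec(as.character(location)),
    msi = rec(as.character(msi)),
    followup_months = rec(as.numeric(followup_months)),
    death_event = rec(as.logical(death_event)),
    stringsAsFactors = FALSE
  )
  chk <- function(col, levels) {
    bad <- setdiff(unique(stats::na.omit(df[[col]])), levels)
    if (length(bad))
      stop("invalid ", col, ": ", paste(bad, collapse = ", "))
  }
  chk("sex", c("male", "female"))
  chk("tumor_type", c("adeno", "mucinous"))
  chk("stage", STAGE_LEVELS)
  chk("grade", c("well_moderate", "poor_undifferentiated"))
  chk("msi", MSI_LEVELS)
  if (any(df$followup_months < 0, na.rm = TRUE))
    stop("followup_months must be >= 0")
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' @rdname clinical_table
#' @param x a `clinical_table`.
#' @param path file path.
#' @export
write_clinical_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname clinical_table
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  if (!"patient_id" %in% names(df))
    stop("clinical table must have a patient_id column")
  clinical_table(
    df$patient_id, age = df$age, sex = df$sex, tumor_type = df$tumor_type,
    stage = as.character(df$stage), t_size = df$t_size,
    n_status = df$n_status, m_status = df$m_status, grade = df$grade,
    location = df$location, msi = df$msi,
    followup_months = df$followup_months, death_event = df$death_event
  )
}

#' Create a plasma record table
#'
#' Per-subject relative methylated level of circulating cell-free DNA
#' (target assay normalized to the reference gene) with a disease label.
#'
#' @param subject_id subject identifiers (unique).
#' @param group `"healthy"` or `"CRC"` per subject.
#' @param relative_level nonnegative dimensionless relative level.
#' @return A `data.frame` of class `plasma_table`.
#' @export
plasma_table <- function(subject_id, group, relative_level) {
  subject_id <- as.character(subject_id)
  group <- as.character(group)
  relative_level <- as.numeric(relative_level)
  if (anyDuplicated(subject_id))
    stop("duplicate subject_id in plasma table")
  bad <- setdiff(unique(group), c("healthy", "CRC"))
  if (length(bad))
    stop("unknown plasma group: ", paste(bad, collapse = ", "))
  if (any(!is.finite(relative_level)) || any(relative_level < 0))
    stop("relative_level must be finite and >= 0")
  df <- data.frame(subject_id = subject_id, group = group,
                   relative_level = relative_level, stringsAsFactors = FALSE)
  class(df) <- c("plasma_table", "data.frame")
  df
}

#' @rdname plasma_table
#' @param x a `plasma_table`.
#' @param path file path.
#' @export
write_plasma_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname plasma_table
#' @export
read_plasma_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "group", "relative_level")
  if (!all(req %in% names(df)))
    stop("plasma table must have columns: ", paste(req, collapse = ", "))
  plasma_table(df$subject_id, df$group, df$relative_level)
}

#' Identify paired patients in a sample sheet
#'
#' A patient is "paired" when it has exactly one normal and one tumor sample.
#' Polyp-only subjects are excluded from pairing (they form a separate
#' stratum); patients missing either member are dropped.  A duplicated
#' non-polyp tissue type for a patient is an error.
#'
#' @param sheet a `sample_sheet`.
#' @return Character vector of paired patient ids, in sheet order.
#' @export
validate_pairing <- function(sheet) {
  s <- as.data.frame(sheet)
  s <- s[s$tissue_type %in% c("normal", "tumor"), , drop = FALSE]
  if (nrow(s) == 0) return(character(0))
  tab <- table(s$patient_id, s$tissue_type)
  dup <- rownames(tab)[apply(tab, 1, max) > 1]
  if (length(dup))
    stop("duplicate tissue type for patient(s): ",
         paste(dup, collapse = ", "))
  have_n <- if ("normal" %in% colnames(tab)) tab[, "normal"] else 0
  have_t <- if ("tumor" %in% colnames(tab)) tab[, "tumor"] else 0
  paired <- rownames(tab)[have_n == 1 & have_t == 1]
  # preserve first-appearance order from the sheet
  ord <- unique(s$patient_id)
  ord[ord %in% paired]
}

#' Sample ids of the paired tumor/normal members for a set of patients
#'
#' @param sheet a `sample_sheet`.
#' @param patients patient ids (defaults to all paired patients).
#' @return data.frame with columns `patient_id`, `normal_sample`,
#'   `tumor_sample`.
#' @export
paired_samples <- function(sheet, patients = validate_pairing(sheet)) {
  s <- as.data.frame(sheet)
  data.frame(
    patient_id = patients,
    normal_sample = s$sample_id[match(paste(patients, "normal"),
                                      paste(s$patient_id, s$tissue_type))],
    tumor_sample = s$sample_id[match(paste(patients, "tumor"),
                                     paste(s$patient_id, s$tissue_type))],
    stringsAsFactors = FALSE
  )
}
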