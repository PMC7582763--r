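# Domain types, validation and round-trip I/O.

test_that("beta matrix TSV round-trips losslessly, including NA and the
           reference 0.524/0.119 pair", {
  fx <- tiny_beta_fixture()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_beta_matrix(fx$beta, path)
  back <- read_beta_matrix(path, annotation = fx$ann, sheet = fx$sheet)
  expect_identical(unclass(back), unclass(fx$beta))
  expect_identical(back["cg01", "p1_N"], 0.524)
  expect_identical(back["cg01", "p1_T"], 0.119)
  expect_true(is.na(back["cg03", "p1_N"]))
})

test_that("beta validation rejects out-of-range cells naming the cell,
           duplicate probes, and unannotated probes", {
  vals <- matrix(c(0.2, 1.2), 1, 2,
                 dimnames = list("cgX", c("s1", "s2")))
  expect_error(beta_matrix(vals), "cgX.*s2|s2.*cgX")
  dup <- matrix(0.5, 2, 1, dimnames = list(c("cgA", "cgA"), "s1"))
  expect_error(beta_matrix(dup), "duplicate probe")
  fx <- tiny_beta_fixture()
  stray <- matrix(0.5, 1, 1, dimnames = list("cg99", "p1_N"))
  expect_error(beta_matrix(stray, annotation = fx$ann), "absent from annotation")
})

test_that("probe annotation derives region class from the TSS offset sign", {
  ann <- probe_annotation(c("a", "b", "c"), c("G", "G", "G"),
                          c(-1133L, -94L, 927L))
  expect_identical(ann$region_class, c("promoter", "promoter", "gene_body"))
  expect_error(probe_annotation(c("a", "a"), c("G", "G"), c(1L, 2L)),
               "duplicate probe_id")
  path <- withr::local_tempfile(fileext = ".csv")
  write_probe_annotation(ann, path)
  expect_identical(read_probe_annotation(path), ann)
})

test_that("ct tables round-trip, reject nonpositive Ct, and aggregate
           replicates by the arithmetic mean", {
  ct <- ct_table(rep(c("s1", "s2"), each = 4),
                 rep(c("target", "target", "reference", "reference"), 2),
                 c(24.9, 25.1, 20, 20.2, 30, 30.4, 21, 21.2),
                 replicate = rep(1:2, 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ct_table(ct, path)
  expect_identical(read_ct_table(path), ct)
  expect_error(ct_table("s1", "target", -1), "positive")
  expect_error(ct_table("s1", "smad3", 25), "unknown assay")
  m <- replicate_means(ct)
  expect_equal(m$ct[m$sample_id == "s1" & m$assay == "target"], 25.0)
  expect_equal(m$n_replicates, rep(2L, 4))
})

test_that("sample sheet, clinical and plasma tables round-trip with their
           missing-value sentinels", {
  sheet <- sample_sheet(c("a", "b", "c"), c("p1", "p1", "p2"),
                        c("normal", "tumor", "polyp"), "tw")
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_sample_sheet(sheet, p1)
  expect_identical(read_sample_sheet(p1), sheet)

  clin <- clinical_table(c("p1", "p2"), age = c(70, NA),
                         sex = c("male", NA), stage = c("III", "I"),
                         msi = c("MSI-H", NA),
                         followup_months = c(24.5, 3),
                         death_event = c(TRUE, FALSE))
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_clinical_table(clin, p2)
  expect_identical(read_clinical_table(p2), clin)
  expect_error(clinical_table("p", sex = "other"), "invalid sex")
  expect_error(clinical_table("p", followup_months = -1), ">= 0")

  pl <- plasma_table(c("h1", "c1"), c("healthy", "CRC"), c(25.37, 0.3))
  p3 <- withr::local_tempfile(fileext = ".csv")
  write_plasma_table(pl, p3)
  expect_identical(read_plasma_table(p3), pl)
  expect_error(plasma_table("x", "healthy", -0.1), ">= 0")
})

test_that("pairing validation returns complete pairs only and flags
           duplicated tissue types", {
  sheet <- sample_sheet(c("a", "b", "c", "d", "e"),
                        c("p1", "p1", "p2", "p2", "p3"),
                        c("normal", "tumor", "normal", "tumor", "tumor"))
  expect_identical(validate_pairing(sheet), c("p1", "p2"))
  empty <- sample_sheet(character(0), character(0), character(0))
  expect_identical(validate_pairing(empty), character(0))
  dup <- sample_sheet(c("a", "b", "c"), c("p1", "p1", "p1"),
                      c("tumor", "tumor", "normal"))
  expect_error(validate_pairing(dup), "p1")
  # polyp-only subjects never pair
  pol <- sample_sheet(c("a", "b", "c"), c("p1", "p1", "p9"),
                      c("normal", "tumor", "polyp"))
  expect_identical(validate_pairing(pol), "p1")
})

test_that("a study-sized generated sheet yields one pair per patient", {
  n <- 548
  sheet <- sample_sheet(c(sprintf("P%03d_N", 1:n), sprintf("P%03d_T", 1:n)),
                        rep(sprintf("P%03d", 1:n), 2),
                        rep(c("normal", "tumor"), each = n))
  expect_length(validate_pairing(sheet), 548)
})
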