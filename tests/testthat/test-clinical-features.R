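# Deterministic clinical codings: remission index, ketoacidosis grading,
# HLA risk groups, antibody cutoffs, additive genotype coding.

test_that("IDAA1c is the insulin-dose-adjusted HbA1c and is exactly linear", {
  expect_equal(compute_idaa1c(7.0, 0.5), 9.0)
  expect_equal(compute_idaa1c(6.0, 0.0), 6.0)
  # cohort means: HbA1c 9.3 and IDAA1c 11.0 at one month imply a mean
  # dose of (11.0 - 9.3)/4 by linearity
  expect_equal(compute_idaa1c(9.3, 0.425), 11.0)
  h <- 8.1; d1 <- 0.37; d2 <- 0.21
  expect_equal(compute_idaa1c(h, d1 + d2) - compute_idaa1c(h, d1), 4 * d2)
  expect_error(compute_idaa1c(7.0, -0.1), "non-negative")
  expect_error(compute_idaa1c(0, 0.5), "positive")
})

test_that("partial remission is IDAA1c <= 9 with an inclusive boundary", {
  expect_true(is_partial_remission(9.0))
  expect_false(is_partial_remission(9.01))
  expect_false(is_partial_remission(11.0))
  expect_true(is_partial_remission(compute_idaa1c(7.0, 0.5)))
})

test_that("DKA grading uses inclusive bicarbonate thresholds 15 and 5 mmol/L", {
  expect_equal(as.character(classify_dka(15.0)), "dka")
  expect_equal(as.character(classify_dka(5.0)), "severe_dka")
  expect_equal(as.character(classify_dka(20.0)), "none")
  expect_equal(as.character(classify_dka(15.001)), "none")
  # severity is monotone non-increasing in bicarbonate
  grades <- classify_dka(c(26, 18, 15, 10, 5, 2))
  expect_true(all(diff(as.integer(grades)) >= 0))
  # severe implies the plain DKA flag in the block encoding
  fl <- dka_flags(c(4, 12, 22))
  expect_equal(fl$dka, c(TRUE, TRUE, FALSE))
  expect_equal(fl$severe_dka, c(TRUE, FALSE, FALSE))
  expect_error(classify_dka(0), "positive")
})

test_that("HLA-DQB1 pairs map to the documented risk groups", {
  expect_equal(as.character(classify_hla_risk("0302", "02")), "very_high")
  expect_equal(as.character(classify_hla_risk("02", "0302")), "very_high")
  expect_equal(as.character(classify_hla_risk("0302", "0302")), "high")
  expect_equal(as.character(classify_hla_risk("0302", "0304")), "high")  # 0304 is X
  expect_equal(as.character(classify_hla_risk("02", "0604")), "high")
  expect_equal(as.character(classify_hla_risk("0302", "0301")), "moderate")
  expect_equal(as.character(classify_hla_risk("02", "0603")), "moderate")
  expect_equal(as.character(classify_hla_risk("0304", "0604")), "moderate")  # X/X
  expect_equal(as.character(classify_hla_risk("0302", "0602")), "low")
  expect_equal(as.character(classify_hla_risk("0301", "0604")), "low")
  # three-level collapse for modelling
  expect_equal(as.character(classify_hla_risk("0302", "0301", collapse = TRUE)),
               "moderate_low")
  expect_equal(levels(classify_hla_risk("0302", "02", collapse = TRUE)),
               c("very_high", "high", "moderate_low"))
  expect_error(classify_hla_risk("0302", "9999"), "unknown DQB1 allele")
})

test_that("antibody positivity uses inclusive assay cutoffs", {
  cuts <- antibody_cutoffs()
  expect_equal(unname(cuts[c("ICA", "IAA", "GADA", "IA2A")]),
               c(2.5, 2.80, 5.36, 0.43))
  expect_equal(unname(cuts[c("ZnT8Arg", "ZnT8Trp", "ZnT8Gln", "ZnT8Triple")]),
               c(60, 58, 65, 58))
  expect_true(antibody_positive("ZnT8Arg", 60))
  expect_true(antibody_positive("GADA", 5.36))
  expect_false(antibody_positive("IAA", 2.79))
  for (a in names(cuts)) {
    expect_true(antibody_positive(a, cuts[[a]]))
    expect_false(antibody_positive(a, cuts[[a]] * (1 - 1e-9)))
  }
  expect_error(antibody_positive("XYZ", 1), "unknown analyte")
})

test_that("additive genotype coding counts risk alleles and keeps NA", {
  expect_equal(encode_genotype("A", "A", risk_allele = "A"), 2)
  expect_equal(encode_genotype("A", "G", risk_allele = "A"), 1)
  expect_equal(encode_genotype("G", "G", risk_allele = "A"), 0)
  expect_true(is.na(encode_genotype(NA, "A", risk_allele = "A")))
  expect_error(encode_genotype("T", "G", risk_allele = "A", alleles = c("A", "G")),
               "not in declared set")
  geno <- data.frame(rs1_a1 = c("A", "G", NA), rs1_a2 = c("A", "A", "G"),
                     rs2 = c(0, 1, 2))
  enc <- encode_genotype_table(geno, c(rs1 = "A", rs2 = "C"))
  expect_equal(enc$rs1, c(2L, 1L, NA))
  expect_equal(enc$rs2, c(0L, 1L, 2L))
})

test_that("age groups use half-open bins", {
  expect_equal(as.character(age_group(c(4.99, 5, 9.99, 10, 0))),
               c("<5", "5-<10", "5-<10", ">=10", "<5"))
})

test_that("derive_baseline_features adds the coded modelling variables", {
  b <- data.frame(
    subject_id = c("s1", "s2"),
    age_years = c(3.5, 12),
    hba1c_pct = c(9.3, 7.0),
    insulin_dose_u_per_kg = c(0.425, 0.5),
    hco3_mmol_per_l = c(4, 22),
    dqb1_allele1 = c("0302", "0301"),
    dqb1_allele2 = c("02", "0604")
  )
  d <- derive_baseline_features(b)
  expect_equal(d$idaa1c, c(11.0, 9.0))
  expect_equal(d$partial_remission, c(FALSE, TRUE))
  expect_equal(d$dka, c(TRUE, FALSE))
  expect_equal(d$severe_dka, c(TRUE, FALSE))
  expect_equal(d$hla_risk, c("very_high", "moderate_low"))
  expect_equal(as.character(d$age_grp), c("<5", ">=10"))
})
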