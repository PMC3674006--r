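#' Insulin-dose-adjusted HbA1c (IDAA1c)
#'
#' IDAA1c combines glycaemic control and exogenous insulin need into a
#' single remission index: HbA1c (percent) + 4 x daily insulin dose
#' (units per kg per 24 h).
#'
#' @param hba1c_pct HbA1c in percent; must be positive.
#' @param insulin_dose_u_per_kg Daily insulin dose in U/kg/24h; must be
#'   non-negative.
#' @return Numeric IDAA1c value(s).
#' @examples
#' compute_idaa1c(7.0, 0.5)  # 9.0, on the partial-remission boundary
#' @export
compute_idaa1c <- function(hba1c_pct, insulin_dose_u_per_kg) {
  if (any(!is.finite(hba1c_pct)) || any(hba1c_pct <= 0)) {
    stop("hba1c_pct must be positive")
  }
  if (any(!is.finite(insulin_dose_u_per_kg)) || any(insulin_dose_u_per_kg < 0)) {
    stop("insulin dose must be non-negative")
  }
  hba1c_pct + 4 * insulin_dose_u_per_kg
}

#' Partial remission status
#'
#' Partial remission of type 1 diabetes is defined as IDAA1c at or below 9
#' (the boundary value 9 counts as remission).
#'
#' @param idaa1c IDAA1c value(s), positive.
#' @return Logical vector.
#' @export
is_partial_remission <- function(idaa1c) {
  if (any(!is.finite(idaa1c)) || any(idaa1c <= 0)) stop("idaa1c must be positive")
  idaa1c <= 9
}

#' Diabetic ketoacidosis grade from standard bicarbonate
#'
#' DKA at diagnosis is graded from venous standard bicarbonate:
#' HCO3- <= 15 mmol/L is DKA, <= 5 mmol/L is severe DKA (both boundaries
#' inclusive).  Severe DKA implies DKA, so the two-flag block encoding
#' returned by [dka_flags()] sets both indicators for severe cases.
#'
#' @param hco3_mmol_per_l Standard bicarbonate in mmol/L; positive.
#' @return Factor with levels `none`, `dka`, `severe_dka`.
#' @export
classify_dka <- function(hco3_mmol_per_l) {
  if (any(!is.finite(hco3_mmol_per_l)) || any(hco3_mmol_per_l <= 0)) {
    stop("hco3 must be positive")
  }
  out <- ifelse(hco3_mmol_per_l <= 5, "severe_dka",
                ifelse(hco3_mmol_per_l <= 15, "dka", "none"))
  factor(out, levels = c("none", "dka", "severe_dka"))
}

#' @rdname classify_dka
#' @return `dka_flags()`: data.frame with logical columns `dka` and
#'   `severe_dka` (severe cases are flagged in both).
#' @export
dka_flags <- function(hco3_mmol_per_l) {
  g <- classify_dka(hco3_mmol_per_l)
  data.frame(dka = g %in% c("dka", "severe_dka"),
             severe_dka = g == "severe_dka")
}

.dqb1_alleles <- c("02", "0301", "0302", "0304", "0602", "0603", "0604", "X")

# Alleles other than the named risk/protective set collapse to "X".
normalize_dqb1 <- function(allele) {
  allele <- sub("^DQB1\\*", "", as.character(allele))
  if (!allele %in% .dqb1_alleles) stop("unknown DQB1 allele label: ", allele)
  if (allele %in% c("0304", "0604")) "X" else allele
}

#' HLA-DQB1 diabetes risk group
#'
#' Maps an unordered DQB1 allele pair onto the four-level susceptibility
#' grouping used for newly diagnosed type 1 diabetes: very high risk is
#' the 0302/02 heterozygote only; high risk covers 0302/0302, 0302/X,
#' 02/02 and 02/X; moderate risk covers 0302/0301, 0302/0603, 02/0301,
#' 02/0603 and X/X; low risk covers 0302/0602, 02/0602, 0301/X and
#' 0603/X, where X stands for any other typed allele.  Rules are applied
#' in that priority order, so a pair matching several templates takes the
#' highest-risk label.
#'
#' @param allele1,allele2 DQB1 allele labels from
#'   `{02, 0301, 0302, 0304, 0602, 0603, 0604, X}` (a `DQB1*` prefix is
#'   tolerated); order is irrelevant.
#' @param collapse If TRUE, return the three-level modelling variable
#'   (`very_high`, `high`, `moderate_low`).
#' @return Factor, four levels (or three when `collapse = TRUE`).
#' @export
classify_hla_risk <- function(allele1, allele2, collapse = FALSE) {
  a <- sort(c(normalize_dqb1(allele1), normalize_dqb1(allele2)))
  pair_in <- function(templates) {
    any(vapply(templates, function(tt) identical(sort(tt), a), logical(1)))
  }
  # 0602 is dominantly protective: any 0602 pair present in the rules is low.
  grp <-
    if (pair_in(list(c("0302", "02")))) "very_high"
    else if (pair_in(list(c("0302", "0602"), c("02", "0602"), c("0602", "0602"),
                          c("0602", "0301"), c("0602", "0603"), c("0602", "X")))) "low"
    else if (pair_in(list(c("0302", "0302"), c("0302", "X"),
                          c("02", "02"), c("02", "X")))) "high"
    else if (pair_in(list(c("0302", "0301"), c("0302", "0603"),
                          c("02", "0301"), c("02", "0603"), c("X", "X")))) "moderate"
    else if (pair_in(list(c("0301", "X"), c("0603", "X"), c("0301", "0301"),
                          c("0603", "0603"), c("0301", "0603")))) "low"
    else stop("unmapped DQB1 pair: ", paste(a, collapse = "/"))
  if (collapse) {
    grp <- if (grp %in% c("moderate", "low")) "moderate_low" else grp
    factor(grp, levels = c("very_high", "high", "moderate_low"))
  } else {
    factor(grp, levels = c("very_high", "high", "moderate", "low"))
  }
}

.antibody_cutoffs <- c(
  ICA = 2.5,       # Juvenile Diabetes Foundation units
  IAA = 2.80,      # relative units
  GADA = 5.36,     # relative units
  IA2A = 0.43,     # relative units
  ZnT8Arg = 60,    # U/ml
  ZnT8Trp = 58,    # U/ml
  ZnT8Gln = 65,    # U/ml
  ZnT8Triple = 58  # U/ml
)

#' Islet autoantibody positivity
#'
#' Dichotomizes an autoantibody titer at the assay cutoff: ICA 2.5 JDFU,
#' IAA 2.80 RU, GADA 5.36 RU, IA-2A 0.43 RU, ZnT8 variant assays 60
#' (Arg), 58 (Trp), 65 (Gln) and 58 (triple mix) U/ml.  All cutoffs are
#' inclusive (titer >= cutoff is positive).
#'
#' @param analyte One of ICA, IAA, GADA, IA2A, ZnT8Arg, ZnT8Trp, ZnT8Gln,
#'   ZnT8Triple.
#' @param titer Non-negative titer in the analyte's assay units.
#' @return Logical.
#' @export
antibody_positive <- function(analyte, titer) {
  analyte <- as.character(analyte)
  if (!analyte %in% names(.antibody_cutoffs)) {
    stop("unknown analyte: ", analyte)
  }
  if (any(!is.finite(titer)) || any(titer < 0)) stop("titer must be non-negative")
  titer >= .antibody_cutoffs[[analyte]]
}

#' @rdname antibody_positive
#' @return `antibody_cutoffs()`: named numeric vector of the positivity
#'   cutoffs in assay units.
#' @export
antibody_cutoffs <- function() .antibody_cutoffs

#' Additive (risk-allele count) genotype coding
#'
#' Counts copies of the declared risk allele in a biallelic genotype,
#' giving the standard additive 0/1/2 coding for SNP association
#' modelling.  Missing genotypes (NA alleles) propagate as NA so they can
#' be masked in the gene block.
#'
#' @param allele1,allele2 Character alleles; NA for missing.
#' @param risk_allele The SNP's risk allele.
#' @param alleles Optional declared allele set for validation.
#' @return Integer 0, 1 or 2, or NA for a missing genotype.
#' @export
encode_genotype <- function(allele1, allele2, risk_allele, alleles = NULL) {
  if (is.na(allele1) || is.na(allele2)) return(NA_integer_)
  obs <- c(as.character(allele1), as.character(allele2))
  if (!is.null(alleles) && !all(obs %in% alleles)) {
    stop("allele not in declared set: ", paste(setdiff(obs, alleles), collapse = ","))
  }
  sum(obs == as.character(risk_allele))
}

#' Age group at onset
#'
#' Half-open age bins `[0,5)`, `[5,10)`, `[10,Inf)` years.
#' @param age_years Non-negative age in years.
#' @return Factor with levels `<5`, `5-<10`, `>=10`.
#' @export
age_group <- function(age_years) {
  if (any(!is.finite(age_years)) || any(age_years < 0)) stop("age must be >= 0")
  cut(age_years, breaks = c(0, 5, 10, Inf), right = FALSE,
      labels = c("<5", "5-<10", ">=10"))
}

#' Derive modelling variables from a raw baseline table
#'
#' Adds the deterministic clinical codings used in the baseline block to a
#' one-row-per-subject table: `idaa1c` and `partial_remission` (when
#' `hba1c_pct` and `insulin_dose_u_per_kg` are present), `dka` and
#' `severe_dka` indicators (from `hco3_mmol_per_l`), the three-level
#' `hla_risk` group (from `dqb1_allele1`/`dqb1_allele2`) and `age_grp`
#' (from `age_years`).  Columns whose inputs are absent are skipped.
#'
#' @param baseline data.frame, one row per subject.
#' @return The table with derived columns appended.
#' @export
derive_baseline_features <- function(baseline) {
  stopifnot(is.data.frame(baseline))
  b <- baseline
  if (all(c("hba1c_pct", "insulin_dose_u_per_kg") %in% names(b))) {
    b$idaa1c <- compute_idaa1c(b$hba1c_pct, b$insulin_dose_u_per_kg)
    b$partial_remission <- is_partial_remission(b$idaa1c)
  }
  if ("hco3_mmol_per_l" %in% names(b)) {
    fl <- dka_flags(b$hco3_mmol_per_l)
    b$dka <- fl$dka
    b$severe_dka <- fl$severe_dka
  }
  if (all(c("dqb1_allele1", "dqb1_allele2") %in% names(b))) {
    b$hla_risk <- vapply(seq_len(nrow(b)), function(i) {
      as.character(classify_hla_risk(b$dqb1_allele1[i], b$dqb1_allele2[i],
                                     collapse = TRUE))
    }, character(1))
  }
  if ("age_years" %in% names(b)) b$age_grp <- age_group(b$age_years)
  b
}

#' Encode a wide genotype table additively
#'
#' Converts a table with per-SNP allele-pair columns (`<snp>_a1`,
#' `<snp>_a2`) into risk-allele counts using a named risk-allele map.
#' Numeric columns already coded 0/1/2 pass through unchanged.
#'
#' @param genotypes data.frame, one row per subject.
#' @param risk_alleles Named character vector, SNP name -> risk allele.
#' @return data.frame of integer counts (NA where genotype missing).
#' @export
encode_genotype_table <- function(genotypes, risk_alleles) {
  out <- list()
  for (snp in names(risk_alleles)) {
    a1 <- paste0(snp, "_a1"); a2 <- paste0(snp, "_a2")
    if (all(c(a1, a2) %in% names(genotypes))) {
      out[[snp]] <- vapply(seq_len(nrow(genotypes)), function(i) {
        g <- encode_genotype(genotypes[[a1]][i], genotypes[[a2]][i],
                             risk_alleles[[snp]])
        if (is.na(g)) NA_integer_ else as.integer(g)
      }, integer(1))
    } else if (snp %in% names(genotypes)) {
      v <- genotypes[[snp]]
      if (!all(is.na(v) | v %in% 0:2)) stop("genotype counts must be 0/1/2: ", snp)
      out[[snp]] <- as.integer(v)
    } else {
      stop("no genotype columns for SNP ", snp)
    }
  }
  as.data.frame(out, check.names = FALSE)
}
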