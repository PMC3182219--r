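#' Read study-level meta-analysis records
#'
#' Tab-separated, one row per study-by-variant, with either allele-level
#' 2x2 counts (`case_risk_alleles`, `case_total_alleles`,
#' `control_risk_alleles`, `control_total_alleles`) or precomputed
#' `log_or` and `se`, plus `study_id`, `variant_id` and optionally
#' `ethnicity`.
#'
#' @param path Path to the TSV file.
#' @return Data frame of study records.
#' @export
read_study_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("study_id", "variant_id")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("study table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  has_counts <- all(c("case_risk_alleles", "case_total_alleles",
                      "control_risk_alleles", "control_total_alleles")
                    %in% names(tab))
  has_effect <- all(c("log_or", "se") %in% names(tab))
  if (!has_counts && !has_effect) {
    stop("study table needs 2x2 allele counts or (log_or, se)")
  }
  tab
}

#' Read a variant specification table
#'
#' Tab-separated with columns `variant_id`, `gene`, `type` (`"snp"` or
#' `"hla"`), `or` (per-allele odds ratio) and `raf` (risk/coded allele
#' frequency); extra columns are kept.
#'
#' @param path Path to the TSV file.
#' @return Data frame of variants.
#' @export
read_variant_spec <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "type", "or", "raf")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("variant spec lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  stopifnot(all(tab$type %in% c("snp", "hla")))
  tab
}

#' Build a simulation scenario from a variant specification
#'
#' @param variants Data frame from [read_variant_spec()].
#' @param ... Passed to [scenario_spec()] (`blocks`, `prevalence`,
#'   `calibration`, ...).
#' @return A [scenario_spec()].
#' @export
scenario_from_variants <- function(variants, ...) {
  snp <- variants[variants$type == "snp", , drop = FALSE]
  hla <- variants[variants$type == "hla", , drop = FALSE]
  scenario_spec(
    snps = if (nrow(snp)) data.frame(variant_id = snp$variant_id,
                                     or = snp$or, raf = snp$raf),
    hla = if (nrow(hla)) data.frame(allele = hla$variant_id,
                                    or = hla$or, freq = hla$raf),
    ...
  )
}

#' Path to the bundled synthetic base-variant table
#'
#' A stand-in variant table for the 6 HLA-DRB1 alleles and 14 SNPs of
#' the base risk model: odds ratios from the published univariate
#' association analysis, allele frequencies synthetic (chosen once as
#' plausible Japanese-population values; the study's own frequency
#' table is supplementary material that is not redistributed here).
#'
#' @return File path.
#' @export
synthetic_base_variants_path <- function() {
  system.file("extdata", "synthetic_base_variants.tsv",
              package = "rasysgen", mustWork = TRUE)
}
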