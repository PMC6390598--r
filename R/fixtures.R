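#' Path to a bundled data file
#'
#' @param file File name under the package's `extdata` directory.
#' @return Absolute path.
#' @keywords internal
mbs_extdata <- function(file) {
  path <- system.file("extdata", file, package = "mbscall", mustWork = TRUE)
  path
}

read_fixture <- function(file) {
  readr::read_tsv(mbs_extdata(file), show_col_types = FALSE,
                  progress = FALSE)
}

#' Bundled clinical-cohort characteristic counts
#'
#' Per-characteristic level counts of the 64-patient EGFR-mutant lung
#' adenocarcinoma cohort, split by single versus compound mutation status:
#' sex, smoking habit, common-mutation genotype and pathological stage.
#'
#' @return A tibble with columns parameter, level, single, compound.
#' @export
cohort_characteristics <- function() read_fixture("cohort_characteristics.tsv")

#' Bundled cohort group summaries (mean +/- SD rows)
#'
#' Age (years) and tumour size (mm) summaries of the single- and
#' compound-mutation groups, as (n, mean, sd).
#'
#' @return A tibble with columns parameter, group, n, mean, sd.
#' @export
cohort_group_summaries <- function() read_fixture("cohort_group_summaries.tsv")

#' Bundled compound-mutation allele-frequency table
#'
#' Per-patient allele frequencies (percent) of the common and uncommon
#' EGFR mutation in each compound-mutant tumour, with the reported
#' absolute difference.
#'
#' @return A tibble with columns patient, common_label, common_af,
#'   uncommon_label, uncommon_af, difference.
#' @export
egfr_af_table <- function() read_fixture("egfr_af_table.tsv")

#' Bundled TCGA-validation compound-mutation counts
#'
#' Compound/single patient counts per common-mutation genotype in the
#' independent lung-adenocarcinoma validation cohort.
#'
#' @return A tibble with columns genotype, compound, single.
#' @export
tcga_compound_counts <- function() read_fixture("tcga_compound_counts.tsv")

#' Bundled replicate matched/orphan counts
#'
#' Matched and orphan call counts for technical replicate library pairs,
#' by arm (`raw` = without molecular barcoding, `mbs` = with).
#'
#' @return A tibble with columns sample_id, arm, matched, orphan.
#' @export
replicate_counts <- function() {
  x <- read_fixture("replicate_counts.tsv")
  x$sample_id <- as.character(x$sample_id)
  x
}

#' Synthetic 28-sample per-sample call counts
#'
#' A synthetic stand-in for per-sample call counts of a 28-sample
#' with/without-barcoding comparison; the per-sample values are constructed
#' to be consistent with the reported cohort summaries (mean 2.4 calls with
#' MBS in range 1-4, mean 3.3 without in range 1-8, 17 of 28 samples
#' reduced).
#'
#' @return A tibble with columns sample_id, mbs_calls, raw_calls.
#' @export
call_count_cohort <- function() read_fixture("cohort28_call_counts_synthetic.tsv")

#' Expand characteristic counts into per-patient records
#'
#' Turns a (genotype, compound, single) count table into one record per
#' patient, suitable for [build_compound_table()].
#'
#' @param counts A tibble with columns `genotype`, `compound`, `single`.
#' @return A tibble with columns genotype, status.
#' @export
compound_records_from_counts <- function(counts) {
  tibble::tibble(
    genotype = rep(counts$genotype, times = counts$compound + counts$single),
    status = unlist(purrr::map2(counts$compound, counts$single, function(co, si) {
      c(rep("compound", co), rep("single", si))
    }))
  )
}

#' Main-cohort genotype-by-status records
#'
#' Per-patient genotype/status records of the 64-patient cohort, derived
#' from the bundled characteristic counts.
#'
#' @return A tibble with columns genotype, status (64 rows).
#' @export
main_cohort_records <- function() {
  gt <- dplyr::filter(cohort_characteristics(), .data$parameter == "genotype")
  compound_records_from_counts(
    tibble::tibble(genotype = gt$level, compound = gt$compound,
                   single = gt$single)
  )
}
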