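# CSV readers/writers for the pipeline's file dialects. All files are
# UTF-8, comma-separated, '.' decimal, header required.

check_cols <- function(df, need, what) {
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stopf("%s is missing column(s): %s", what, paste(miss, collapse = ", "))
  }
  df
}

#' Read an oxygen-trace CSV
#'
#' Expected columns: `vial_id`, `time_s`, `o2_mg_per_l`, `temp_c`,
#' `volume_ul`, `is_blank`, `embryo_id`.
#'
#' @param path file path.
#' @return data.frame in the trace dialect.
#' @export
read_traces_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d <- check_cols(d, c("vial_id", "time_s", "o2_mg_per_l", "temp_c",
                       "volume_ul", "is_blank", "embryo_id"),
                  "trace CSV")
  d$is_blank <- as.logical(d$is_blank)
  d
}

#' Read a cohort CSV
#'
#' Expected columns: `embryo_id`, `stage`, `phase`, `egg_ww_mg`,
#' `embryo_ww_mg`.
#'
#' @param path file path.
#' @return data.frame in the cohort dialect.
#' @export
read_cohort_csv <- function(path) {
  check_cols(utils::read.csv(path, stringsAsFactors = FALSE),
             c("embryo_id", "stage", "phase", "egg_ww_mg", "embryo_ww_mg"),
             "cohort CSV")
}

#' Read a biomarker CSV
#'
#' Expected columns: `sample_id`, `tissue`, `stage`, `analyte`, `value`,
#' `unit`, `protein_mg`.
#'
#' @param path file path.
#' @return data.frame in the biomarker dialect.
#' @export
read_biomarkers_csv <- function(path) {
  check_cols(utils::read.csv(path, stringsAsFactors = FALSE),
             c("sample_id", "tissue", "stage", "analyte", "value", "unit",
               "protein_mg"), "biomarker CSV")
}

#' Read a qPCR dilution-series CSV
#'
#' Expected columns: `gene`, `log10_input`, `rep`, `cq`.
#'
#' @param path file path.
#' @return data.frame in the dilution dialect.
#' @export
read_dilution_csv <- function(path) {
  check_cols(utils::read.csv(path, stringsAsFactors = FALSE),
             c("gene", "log10_input", "rep", "cq"), "dilution CSV")
}

#' Read a qPCR Cq CSV
#'
#' Expected columns: `sample_id`, `stage`, `phase`, `gene`, `rep`, `cq`,
#' `is_reference`.
#'
#' @param path file path.
#' @return data.frame in the Cq dialect.
#' @export
read_cq_csv <- function(path) {
  d <- check_cols(utils::read.csv(path, stringsAsFactors = FALSE),
                  c("sample_id", "stage", "phase", "gene", "rep", "cq",
                    "is_reference"), "Cq CSV")
  d$is_reference <- as.logical(d$is_reference)
  d
}
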