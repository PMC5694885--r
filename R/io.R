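# TSV interfaces: the peptide report (the shape of a Scaffold-style export),
# gel-model and reference-stoichiometry tables, and tabular result writers.

#' Read a peptide identification report
#'
#' Expected columns: `protein_id`, `peptide`, `start_res`, `end_res`,
#' `spectral_count`, `slice_index`, `peptide_prob`, and optionally
#' `protein_prob`. Extra columns are preserved.
#'
#' @param path TSV file path.
#' @return Peptide report tibble.
#' @export
read_peptide_report <- function(path) {
  rep <- readr::read_tsv(path, col_types = readr::cols(
    protein_id = readr::col_character(),
    peptide = readr::col_character(),
    start_res = readr::col_integer(),
    end_res = readr::col_integer(),
    spectral_count = readr::col_integer(),
    slice_index = readr::col_integer(),
    peptide_prob = readr::col_double(),
    .default = readr::col_guess()
  ))
  need <- c("protein_id", "peptide", "start_res", "end_res",
            "spectral_count")
  miss <- setdiff(need, names(rep))
  if (length(miss) > 0) {
    stop("peptide report ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  rep
}

#' @rdname read_peptide_report
#' @param report Peptide report tibble.
#' @export
write_peptide_report <- function(report, path) {
  readr::write_tsv(report, path)
  invisible(path)
}

#' Read a gel model TSV (`slice`, `lo_kda`, `hi_kda`)
#'
#' @param path TSV file path.
#' @return A [gel_model()] tibble.
#' @export
read_gel_model <- function(path) {
  g <- readr::read_tsv(path, col_types = readr::cols(
    slice = readr::col_integer(),
    lo_kda = readr::col_double(),
    hi_kda = readr::col_double()
  ))
  gel_model(g$slice, g$lo_kda, g$hi_kda)
}

#' Read a reference-stoichiometry TSV (`protein_id`, `known_copies`)
#'
#' @param path TSV file path.
#' @return Tibble with `protein_id`, `known_copies`.
#' @export
read_refs <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    protein_id = readr::col_character(),
    known_copies = readr::col_double()
  ))
}
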