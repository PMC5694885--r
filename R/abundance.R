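#' Quality-filter configuration
#'
#' The standard protein-identification report filters: minimum peptide
#' identification probability 0.95, minimum protein identification
#' probability 0.999, and at least 3 distinct peptides per protein.
#'
#' @param min_peptide_prob Minimum peptide probability (in `[0, 1]`).
#' @param min_protein_prob Minimum protein probability (in `[0, 1]`).
#' @param min_peptides Minimum number of distinct peptides per protein.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_peptide_prob = 0.95, min_protein_prob = 0.999,
                          min_peptides = 3L) {
  stopifnot(min_peptide_prob >= 0, min_peptide_prob <= 1,
            min_protein_prob >= 0, min_protein_prob <= 1, min_peptides >= 1)
  structure(list(min_peptide_prob = min_peptide_prob,
                 min_protein_prob = min_protein_prob,
                 min_peptides = as.integer(min_peptides)),
            class = "filter_config")
}

#' Apply identification-quality filters to a peptide report
#'
#' Drops peptide rows below the peptide-probability threshold, then drops
#' whole proteins below the protein-probability threshold or supported by
#' fewer than `min_peptides` distinct peptide sequences. Missing probability
#' columns are treated as passing, with a warning.
#'
#' @param report Peptide report tibble.
#' @param cfg A [filter_config()].
#' @return The filtered report.
#' @export
apply_filters <- function(report, cfg = filter_config()) {
  if (nrow(report) == 0) {
    warning("empty peptide report", call. = FALSE)
    return(report)
  }
  if ("peptide_prob" %in% names(report)) {
    report <- report[is.na(report$peptide_prob) |
                       report$peptide_prob >= cfg$min_peptide_prob, ,
                     drop = FALSE]
  } else {
    warning("no peptide_prob column; peptide filter not applied",
            call. = FALSE)
  }
  if ("protein_prob" %in% names(report)) {
    keep_prob <- report |>
      dplyr::group_by(.data$protein_id) |>
      dplyr::summarise(p = max(.data$protein_prob), .groups = "drop")
    ok <- keep_prob$protein_id[keep_prob$p >= cfg$min_protein_prob]
    report <- report[report$protein_id %in% ok, , drop = FALSE]
  } else {
    warning("no protein_prob column; protein filter not applied",
            call. = FALSE)
  }
  n_pep <- report |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(n = dplyr::n_distinct(.data$peptide), .groups = "drop")
  ok <- n_pep$protein_id[n_pep$n >= cfg$min_peptides]
  report[report$protein_id %in% ok, , drop = FALSE]
}

#' Mass-normalized spectral count (SC/M)
#'
#' The relative-abundance statistic: a protein's total spectral count divided
#' by its molecular mass in kDa. Proteins with similar SC/M are present in
#' similar copy numbers; SC/M <= 1 indicates at most a few copies per
#' particle. When a protein is proteolytically processed, dividing by the
#' processed (mature) mass gives the abundance of the mature species.
#'
#' @param total_sc Total spectral count (non-negative).
#' @param mass_kda Molecular mass in kDa (> 0).
#' @return The exact quotient (spectra/kDa). Vectorised.
#' @export
scm <- function(total_sc, mass_kda) {
  if (any(mass_kda <= 0)) stop("mass must be positive", call. = FALSE)
  total_sc / mass_kda
}

#' @rdname scm
#' @details `scm_report()` rounds half-up to 2 decimals, the precision used
#'   in published virion-abundance tables.
#' @export
scm_report <- function(total_sc, mass_kda) {
  round_half_up(scm(total_sc, mass_kda), 2)
}

#' Gel model: ordered slice mass windows
#'
#' @param slice Integer slice indices; slice 1 is the lowest-mass region of
#'   the gel.
#' @param lo_kda,hi_kda Mass window of each slice in kDa; windows must
#'   ascend with the index.
#' @return Tibble with columns `slice`, `lo_kda`, `hi_kda`.
#' @export
gel_model <- function(slice, lo_kda, hi_kda) {
  ord <- order(slice)
  slice <- as.integer(slice[ord]); lo_kda <- lo_kda[ord]; hi_kda <- hi_kda[ord]
  stopifnot(all(hi_kda > lo_kda))
  if (length(slice) > 1 && any(diff(lo_kda) < 0)) {
    stop("slice windows must ascend with slice index", call. = FALSE)
  }
  tibble::tibble(slice = slice, lo_kda = lo_kda, hi_kda = hi_kda)
}

#' Peak gel slice of a spectral-count profile
#'
#' @param profile Named numeric vector (names = slice indices) or tibble
#'   with `slice` and `sc` columns.
#' @return A list with `slice` (argmax; lowest index on ties; `NA` for an
#'   all-zero profile), `tie` and `all_zero` flags.
#' @export
peak_slice <- function(profile) {
  if (is.data.frame(profile)) {
    sc <- profile$sc
    idx <- profile$slice
  } else {
    sc <- as.numeric(profile)
    idx <- as.integer(names(profile))
  }
  if (length(sc) == 0) stop("empty slice profile", call. = FALSE)
  if (all(sc == 0)) {
    return(list(slice = NA_integer_, tie = FALSE, all_zero = TRUE))
  }
  best <- which(sc == max(sc))
  list(slice = as.integer(min(idx[best])), tie = length(best) > 1,
       all_zero = FALSE)
}

#' Consistency of a mature mass with gel migration
#'
#' @param mass_kda Mature (or precursor) mass in kDa.
#' @param peak Peak slice index (see [peak_slice()]).
#' @param gel A [gel_model()].
#' @param tolerance Fractional widening of the slice window (migration on a
#'   gel is only accurate to tens of percent).
#' @return `"consistent"`, `"inconsistent"`, or `"untestable"` (peak slice
#'   absent from the model or `NA`).
#' @export
gel_consistency <- function(mass_kda, peak, gel, tolerance = 0.15) {
  if (is.na(peak) || !(peak %in% gel$slice)) return("untestable")
  w <- gel[gel$slice == peak, ]
  lo <- w$lo_kda * (1 - tolerance)
  hi <- w$hi_kda * (1 + tolerance)
  if (mass_kda >= lo && mass_kda <= hi) "consistent" else "inconsistent"
}

#' Calibrate copy-number estimates against reference stoichiometry
#'
#' Virion proteins of known copy number (major capsid, tail sheath, portal)
#' anchor the SC/M scale: the calibration constant is the median over
#' references of known_copies / SC/M, robust to individual references that
#' are under-detected (the portal's 12 copies typically yield SC/M near 1).
#' Estimates are order-of-magnitude, not absolute quantification.
#'
#' @param records Tibble with `protein_id` and an SC/M column named `scm`
#'   (use the processed-mass SC/M where a mature form exists).
#' @param references Tibble with `protein_id` and `known_copies`.
#' @return A list with `k` (the calibration constant), `estimates` (the
#'   input with a `copy_estimate` column), and `residuals` (per-reference
#'   observed vs fitted copies).
#' @export
calibrate_copies <- function(records, references) {
  refs <- dplyr::inner_join(records, references, by = "protein_id")
  if (nrow(refs) == 0) {
    stop("no reference protein with both SC/M and known copies",
         call. = FALSE)
  }
  k <- stats::median(refs$known_copies / refs$scm)
  records$copy_estimate <- k * records$scm
  residuals <- tibble::tibble(
    protein_id = refs$protein_id,
    known_copies = refs$known_copies,
    fitted_copies = k * refs$scm,
    residual = refs$known_copies - k * refs$scm
  )
  list(k = k, estimates = records, residuals = residuals)
}

#' Assemble a per-protein abundance table
#'
#' Summarises a filtered, classified peptide report into the per-protein
#' abundance statistics of a virion-proteomics report: total spectral count,
#' precursor and processed mass, SC/M on both bases, peak gel slice,
#' abundance tier and (when references are given) calibrated copy estimates.
#'
#' Tiers: `high` when SC/M (processed basis where available) is at or above
#' the anchor reference's SC/M (by default the lowest-SC/M reference protein
#' with > 100 known copies, i.e. a stoichiometric anchor like the tail
#' sheath), `trace` when SC/M <= `trace_max`, else `mid_low`.
#'
#' @param observations Filtered, classified peptide report.
#' @param proteins Protein-record tibble.
#' @param mature_forms Optional tibble with `protein_id`, `start_res`,
#'   `end_res`, `mass_kda`, `status` of accepted mature forms.
#' @param references Optional tibble with `protein_id`, `known_copies`.
#' @param trace_max SC/M at or below which a protein is `trace`.
#' @return Tibble with one row per protein, ordered by decreasing SC/M
#'   (processed basis where available).
#' @export
abundance_table <- function(observations, proteins, mature_forms = NULL,
                            references = NULL, trace_max = 1) {
  base <- observations |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(total_sc = sum(.data$spectral_count),
                     n_peptides = dplyr::n_distinct(.data$peptide),
                     .groups = "drop")
  prec <- tibble::tibble(
    protein_id = proteins$id,
    precursor_mass_kda = average_mass(proteins$sequence) / 1000
  )
  out <- dplyr::inner_join(base, prec, by = "protein_id")
  out$scm <- scm(out$total_sc, out$precursor_mass_kda)

  if (!is.null(mature_forms) && nrow(mature_forms) > 0) {
    mf <- mature_forms[, c("protein_id", "mass_kda", "status")]
    names(mf) <- c("protein_id", "processed_mass_kda", "form_status")
    out <- dplyr::left_join(out, mf, by = "protein_id")
  } else {
    out$processed_mass_kda <- NA_real_
    out$form_status <- NA_character_
  }
  out$scm_basis <- ifelse(
    is.na(out$processed_mass_kda), "precursor",
    ifelse(out$form_status == "inferred", "inferred-basis", "processed"))
  out$scm_processed <- ifelse(is.na(out$processed_mass_kda), NA_real_,
                              out$total_sc / out$processed_mass_kda)
  out$scm_best <- ifelse(is.na(out$scm_processed), out$scm,
                         out$scm_processed)

  # per-slice profile -> peak slice
  if ("slice_index" %in% names(observations)) {
    peaks <- observations |>
      dplyr::group_by(.data$protein_id, .data$slice_index) |>
      dplyr::summarise(sc = sum(.data$spectral_count), .groups = "drop_last") |>
      dplyr::summarise(
        peak_slice = {
          p <- peak_slice(stats::setNames(.data$sc, .data$slice_index))
          p$slice
        },
        peak_tie = {
          p <- peak_slice(stats::setNames(.data$sc, .data$slice_index))
          p$tie
        },
        .groups = "drop")
    out <- dplyr::left_join(out, peaks, by = "protein_id")
  } else {
    out$peak_slice <- NA_integer_
    out$peak_tie <- FALSE
  }

  anchor_scm <- NA_real_
  if (!is.null(references) && nrow(references) > 0) {
    refs_in <- dplyr::inner_join(
      out[, c("protein_id", "scm_best")], references, by = "protein_id")
    anchors <- refs_in[refs_in$known_copies > 100, , drop = FALSE]
    if (nrow(anchors) > 0) anchor_scm <- min(anchors$scm_best)
    calib <- calibrate_copies(
      dplyr::rename(out[, c("protein_id", "scm_best")], scm = "scm_best"),
      references)
    out$copy_estimate <- calib$estimates$copy_estimate
  } else {
    out$copy_estimate <- NA_real_
  }
  out$abundance_tier <- ifelse(
    out$scm_best <= trace_max, "trace",
    ifelse(!is.na(anchor_scm) & out$scm_best >= anchor_scm,
           "high", "mid_low"))
  dplyr::arrange(out, dplyr::desc(.data$scm_best))
}

#' Compare two virion proteomes by presence/absence
#'
#' Set difference of protein identifiers between a reference proteome (e.g.
#' wild type) and a sample proteome (e.g. an amber mutant grown under
#' non-permissive conditions): which proteins disappeared, which appeared.
#' Both lists should already be quality-filtered. Ordering is by gene-product
#' number when identifiers contain one.
#'
#' @param reference,sample Character vectors of protein identifiers (or
#'   tibbles with a `protein_id` column).
#' @return A list with `missing` (in reference, not sample) and `gained`
#'   (in sample, not reference).
#' @export
compare_proteomes <- function(reference, sample) {
  as_ids <- function(x) {
    if (is.data.frame(x)) x <- x$protein_id
    unique(as.character(x))
  }
  reference <- as_ids(reference)
  sample <- as_ids(sample)
  by_gp <- function(ids) {
    num <- suppressWarnings(as.integer(gsub("\\D", "", ids)))
    ids[order(num, ids, na.last = TRUE)]
  }
  list(missing = by_gp(setdiff(reference, sample)),
       gained = by_gp(setdiff(sample, reference)))
}
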