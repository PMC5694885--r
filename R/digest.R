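#' Tryptic cleavage positions of a sequence
#'
#' Positions `i` such that trypsin cuts after residue `i`: residue `i` is K
#' or R and, under the proline rule (on by default, the classic trypsin
#' convention), residue `i + 1` is not P. The C-terminal residue is never a
#' cut position (the chain simply ends there).
#'
#' @param sequence Amino-acid string.
#' @param proline_rule Suppress cuts before proline.
#' @return Increasing integer vector of cut positions (possibly empty).
#' @export
tryptic_sites <- function(sequence, proline_rule = TRUE) {
  n <- nchar(sequence)
  if (n < 2) return(integer(0))
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  i <- which(aa[-n] %in% c("K", "R"))
  if (proline_rule) i <- i[aa[i + 1L] != "P"]
  i
}

#' In-silico tryptic digest
#'
#' Enumerates all peptide spans delimited by consecutive tryptic cut
#' positions (and the protein termini) containing at most `max_missed`
#' internal cut positions.
#'
#' @param sequence Amino-acid string.
#' @param max_missed Maximum missed cleavages (>= 0).
#' @param proline_rule Passed to [tryptic_sites()].
#' @param min_length Drop peptides shorter than this many residues.
#' @return Tibble with columns `start_res`, `end_res`, `peptide`,
#'   `n_missed`, sorted by start then end.
#' @export
digest <- function(sequence, max_missed = 0L, proline_rule = TRUE,
                   min_length = 1L) {
  stopifnot(max_missed >= 0)
  cuts <- tryptic_sites(sequence, proline_rule = proline_rule)
  bounds <- c(0L, cuts, nchar(sequence))
  n_seg <- length(bounds) - 1L
  out <- list()
  for (a in seq_len(n_seg)) {
    for (b in a:min(n_seg, a + max_missed)) {
      out[[length(out) + 1L]] <- c(bounds[a] + 1L, bounds[b + 1L], b - a)
    }
  }
  m <- do.call(rbind, out)
  res <- tibble::tibble(
    start_res = as.integer(m[, 1]), end_res = as.integer(m[, 2]),
    n_missed = as.integer(m[, 3])
  )
  res <- res[res$end_res - res$start_res + 1L >= min_length, ]
  res$peptide <- substring(sequence, res$start_res, res$end_res)
  dplyr::arrange(res[, c("start_res", "end_res", "peptide", "n_missed")],
                 .data$start_res, .data$end_res)
}

#' Classify the termini of an observed peptide
#'
#' Labels each terminus of an identified peptide against its protein context:
#' `tryptic` (consistent with trypsin specificity), `protein_terminus`
#' (the peptide reaches the protein's own end), or `nonspecific` (the
#' signature of an in-vivo proteolytic event). A peptide starting at residue
#' 2 of a Met-initiated protein is a protein terminus with an `nme` flag
#' (N-terminal Met excision by the host aminopeptidase), not a protease
#' candidate. The `overall` class combines the two termini; a protein
#' terminus counts as specific, so e.g. an N-terminal peptide ending in K is
#' `fully_tryptic`.
#'
#' @param start_res,end_res 1-based inclusive peptide coordinates.
#' @param protein_sequence The protein's full sequence.
#' @param peptide Optional peptide string; validated against the coordinates
#'   when supplied.
#' @param proline_rule Apply the proline rule when judging tryptic termini.
#' @return A list with `n_term`, `c_term`, `overall`, and logical `nme`.
#' @export
classify_termini <- function(start_res, end_res, protein_sequence,
                             peptide = NULL, proline_rule = TRUE) {
  n <- nchar(protein_sequence)
  if (start_res < 1 || end_res > n || start_res > end_res) {
    stop("peptide coordinates out of range for protein", call. = FALSE)
  }
  if (!is.null(peptide) &&
      substr(protein_sequence, start_res, end_res) != peptide) {
    stop("peptide sequence does not match protein at the given coordinates",
         call. = FALSE)
  }
  res <- function(i) substr(protein_sequence, i, i)
  nme <- FALSE

  if (start_res == 1L) {
    n_term <- "protein_terminus"
  } else if (start_res == 2L && res(1L) == "M") {
    n_term <- "protein_terminus"
    nme <- TRUE
  } else if (res(start_res - 1L) %in% c("K", "R") &&
             (!proline_rule || res(start_res) != "P")) {
    n_term <- "tryptic"
  } else {
    n_term <- "nonspecific"
  }

  if (end_res == n) {
    c_term <- "protein_terminus"
  } else if (res(end_res) %in% c("K", "R") &&
             (!proline_rule || res(end_res + 1L) != "P")) {
    c_term <- "tryptic"
  } else {
    c_term <- "nonspecific"
  }

  n_ok <- n_term != "nonspecific"
  c_ok <- c_term != "nonspecific"
  overall <- if (n_ok && c_ok) "fully_tryptic"
  else if (!n_ok && c_ok) "semi_tryptic_N"
  else if (n_ok && !c_ok) "semi_tryptic_C"
  else "non_tryptic"

  list(n_term = n_term, c_term = c_term, overall = overall, nme = nme)
}

#' Classify every observation in a peptide report
#'
#' Applies [classify_termini()] row-wise to a peptide report joined against
#' its proteins, adding `n_term`, `c_term`, `term_class` and `nme` columns.
#' Terminus classification depends only on coordinates and sequence context,
#' never on spectral counts or gel slice.
#'
#' @param observations Peptide report tibble (see [read_peptide_report()]).
#' @param proteins Protein-record tibble.
#' @param proline_rule Apply the proline rule.
#' @return The input tibble with classification columns appended.
#' @export
classify_report <- function(observations, proteins, proline_rule = TRUE) {
  seqs <- stats::setNames(proteins$sequence, proteins$id)
  missing <- setdiff(unique(observations$protein_id), names(seqs))
  if (length(missing) > 0) {
    stop("observations reference unknown protein(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cls <- Map(function(pid, s, e, pep) {
    classify_termini(s, e, seqs[[pid]], peptide = pep,
                     proline_rule = proline_rule)
  }, observations$protein_id, observations$start_res, observations$end_res,
     observations$peptide)
  observations$n_term <- vapply(cls, `[[`, character(1), "n_term")
  observations$c_term <- vapply(cls, `[[`, character(1), "c_term")
  observations$term_class <- vapply(cls, `[[`, character(1), "overall")
  observations$nme <- vapply(cls, `[[`, logical(1), "nme")
  observations
}

#' Per-residue spectral coverage of a protein
#'
#' @param observations Peptide report rows for one protein.
#' @param protein_length Protein length in residues.
#' @return Integer vector of length `protein_length`: summed spectral counts
#'   covering each residue.
#' @export
residue_coverage <- function(observations, protein_length) {
  cov <- integer(protein_length)
  if (nrow(observations) == 0) return(cov)
  for (k in seq_len(nrow(observations))) {
    idx <- observations$start_res[k]:observations$end_res[k]
    cov[idx] <- cov[idx] + observations$spectral_count[k]
  }
  cov
}
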