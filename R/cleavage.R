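#' Protease cleavage-motif models
#'
#' A motif model describes the three residues N-terminal to a cleavage point
#' (P3, P2, P1; cleavage occurs after P1). The prohead proteases of
#' phiKZ-like phages and of T4 all cleave C-terminal to a glutamate, and
#' differ in which residues they accept at P3. Presets:
#' \describe{
#'   \item{`spn3us`}{A-X-E (X = any residue)}
#'   \item{`phikz`}{S/A/G-X-E}
#'   \item{`201phi2-1`}{S/A/G/T-X-E}
#'   \item{`t4`}{I/L/A/S/T-X-E (the looser E-anchored family motif)}
#' }
#'
#' @param p3_allowed Residue set accepted at P3.
#' @param p2_allowed Residue set accepted at P2 (default: all 20, "X").
#' @param p1_residue The P1 residue (glutamate throughout this protease
#'   family).
#' @param name Model name.
#' @return A `motif_model` list.
#' @export
motif_model <- function(p3_allowed = "A", p2_allowed = names(.AA_AVERAGE),
                        p1_residue = "E", name = "custom") {
  structure(list(p3_allowed = unique(toupper(p3_allowed)),
                 p2_allowed = unique(toupper(p2_allowed)),
                 p1_residue = toupper(p1_residue), name = name),
            class = "motif_model")
}

#' @rdname motif_model
#' @param preset Preset name (`"spn3us"`, `"phikz"`, `"201phi2-1"`, `"t4"`).
#' @export
motif_preset <- function(preset = c("spn3us", "phikz", "201phi2-1", "t4")) {
  preset <- match.arg(preset)
  p3 <- switch(preset,
    "spn3us" = "A",
    "phikz" = c("S", "A", "G"),
    "201phi2-1" = c("S", "A", "G", "T"),
    "t4" = c("I", "L", "A", "S", "T"))
  motif_model(p3_allowed = p3, name = preset)
}

#' Match one position against a cleavage-motif model
#'
#' Tests whether cleavage after residue `p1_pos` conforms to the motif:
#' residue `p1_pos` must be the P1 residue (glutamate), `p1_pos - 1` in the
#' P2 set and `p1_pos - 2` in the P3 set.
#'
#' @param protein_sequence Protein sequence.
#' @param p1_pos Residue index of the putative P1 (cleavage occurs after it).
#' @param model A [motif_model()].
#' @param allow_short Permit `p1_pos < 3` (P3/P2 then unchecked).
#' @return The P3-P2-P1 motif string (e.g. `"ATE"`) on a match, `NA` on
#'   no-match.
#' @export
match_motif <- function(protein_sequence, p1_pos, model = motif_preset(),
                        allow_short = FALSE) {
  n <- nchar(protein_sequence)
  if (p1_pos < 1 || p1_pos > n) {
    stop("p1_pos ", p1_pos, " out of range 1..", n, call. = FALSE)
  }
  if (p1_pos < 3 && !allow_short) {
    stop("p1_pos < 3: no P3 residue exists (set allow_short = TRUE)",
         call. = FALSE)
  }
  r <- function(i) if (i >= 1) substr(protein_sequence, i, i) else ""
  if (r(p1_pos) != model$p1_residue) return(NA_character_)
  if (p1_pos >= 2 && !(r(p1_pos - 1L) %in% model$p2_allowed)) {
    return(NA_character_)
  }
  if (p1_pos >= 3 && !(r(p1_pos - 2L) %in% model$p3_allowed)) {
    return(NA_character_)
  }
  paste0(r(p1_pos - 2L), r(p1_pos - 1L), r(p1_pos))
}

#' Scan a protein for all motif-conforming positions
#'
#' @param protein_sequence Protein sequence.
#' @param model A [motif_model()].
#' @return Increasing integer vector of P1 positions (possibly empty); every
#'   observed motif-conforming cleavage site is a member of this set.
#' @export
scan_motif <- function(protein_sequence, model = motif_preset()) {
  n <- nchar(protein_sequence)
  if (n < 3) return(integer(0))
  hits <- integer(0)
  for (p in 3:n) {
    if (!is.na(match_motif(protein_sequence, p, model))) hits <- c(hits, p)
  }
  hits
}

#' Aggregate semi-tryptic termini into candidate cleavage boundaries
#'
#' Formalizes the manual inspection of semi-tryptic search results: each
#' semi-tryptic N-terminus at residue `start_res` is evidence of a cut after
#' residue `start_res - 1`; each semi-tryptic C-terminus is evidence of a cut
#' after `end_res`. NME-flagged starts and protein-terminus boundaries are
#' excluded (they are not protease events). Evidence is aggregated per
#' (protein, boundary): `support_spectra` sums spectral counts and
#' `support_peptides` counts distinct peptide forms.
#'
#' @param observations Classified peptide report (see [classify_report()]),
#'   normally already quality-filtered with [apply_filters()].
#' @return Tibble with columns `protein_id`, `p1_pos`, `support_spectra`,
#'   `support_peptides`.
#' @export
candidate_sites <- function(observations) {
  empty <- tibble::tibble(protein_id = character(0), p1_pos = integer(0),
                          support_spectra = integer(0),
                          support_peptides = integer(0))
  if (nrow(observations) == 0) return(empty)
  n_ev <- observations[observations$n_term == "nonspecific" &
                         !observations$nme, , drop = FALSE]
  c_ev <- observations[observations$c_term == "nonspecific", , drop = FALSE]
  ev <- dplyr::bind_rows(
    tibble::tibble(protein_id = n_ev$protein_id,
                   p1_pos = n_ev$start_res - 1L,
                   spectral_count = n_ev$spectral_count,
                   peptide = n_ev$peptide),
    tibble::tibble(protein_id = c_ev$protein_id,
                   p1_pos = c_ev$end_res,
                   spectral_count = c_ev$spectral_count,
                   peptide = c_ev$peptide)
  )
  ev <- ev[ev$p1_pos >= 1L, , drop = FALSE]
  if (nrow(ev) == 0) return(empty)
  ev |>
    dplyr::group_by(.data$protein_id, .data$p1_pos) |>
    dplyr::summarise(support_spectra = sum(.data$spectral_count),
                     support_peptides = dplyr::n_distinct(.data$peptide),
                     .groups = "drop") |>
    dplyr::arrange(.data$protein_id, .data$p1_pos)
}

#' Accept candidate boundaries as observed cleavage sites
#'
#' Applies a conservative acceptance rule to candidate boundaries: a
#' candidate is accepted if it matches the motif model and has at least
#' `min_spectra_motif` supporting spectra, or, without a motif match, if at
#' least `min_peptides_nonmotif` distinct semi-tryptic peptides support it.
#' Boundaries supported by a single spectrum with no motif match are kept in
#' a `low_confidence` tier rather than dropped — ragged in-source
#' fragmentation and genuine non-canonical cuts cannot be distinguished at
#' this level.
#'
#' Side assignment: a cut at or before `n_side_fraction` of the protein
#' length is taken as an N-side (propeptide) cut, otherwise C-side.
#'
#' @param candidates Output of [candidate_sites()].
#' @param proteins Protein-record tibble.
#' @param model A [motif_model()], or `NULL` to disable motif enforcement.
#' @param min_spectra_motif Minimum spectra for motif-matching sites.
#' @param min_peptides_nonmotif Minimum distinct peptides for non-motif
#'   sites.
#' @param n_side_fraction Fraction of protein length at or below which a cut
#'   is N-side.
#' @return Tibble of cleavage sites: `protein_id`, `p1_pos`, `motif`,
#'   `support_spectra`, `support_peptides`, `side`, `status`
#'   (`"observed"`), `tier` (`"accepted"` or `"low_confidence"`).
#' @export
accept_sites <- function(candidates, proteins, model = motif_preset(),
                         min_spectra_motif = 1L, min_peptides_nonmotif = 2L,
                         n_side_fraction = 0.5) {
  seqs <- stats::setNames(proteins$sequence, proteins$id)
  if (nrow(candidates) == 0) {
    return(tibble::tibble(protein_id = character(0), p1_pos = integer(0),
                          motif = character(0), support_spectra = integer(0),
                          support_peptides = integer(0), side = character(0),
                          status = character(0), tier = character(0)))
  }
  motif <- vapply(seq_len(nrow(candidates)), function(k) {
    s <- seqs[[candidates$protein_id[k]]]
    p <- candidates$p1_pos[k]
    if (is.null(model) || p > nchar(s)) return(NA_character_)
    match_motif(s, p, model, allow_short = TRUE)
  }, character(1))
  out <- candidates
  out$motif <- motif
  has_motif <- !is.na(motif)
  accepted <- (has_motif & out$support_spectra >= min_spectra_motif) |
    (!has_motif & out$support_peptides >= min_peptides_nonmotif)
  out$tier <- ifelse(accepted, "accepted", "low_confidence")
  len <- unname(nchar(seqs[out$protein_id]))
  out$side <- ifelse(out$p1_pos <= n_side_fraction * len,
                     "N_propeptide", "C_propeptide")
  out$status <- "observed"
  out[, c("protein_id", "p1_pos", "motif", "support_spectra",
          "support_peptides", "side", "status", "tier")]
}

#' Infer an unobserved maturation cleavage from coverage and gel migration
#'
#' When MS coverage of a protein only begins at residue `r > 1`, the
#' maturation cut most likely lies just upstream of `r` at a motif-conforming
#' position that was not itself captured by a semi-tryptic peptide. Among
#' motif positions in the interval (last observed upstream cut, `r - 1`],
#' this picks the one closest to the coverage start (i.e. the most
#' C-terminal, the longest propeptide consistent with coverage). When a gel
#' mass window for the protein's peak slice is supplied, candidates whose
#' mature mass falls inside the window are preferred over proximity.
#'
#' @param protein_sequence Protein sequence.
#' @param coverage Per-residue coverage vector (see [residue_coverage()]).
#' @param model A [motif_model()].
#' @param observed_sites Integer vector of already-observed P1 positions for
#'   this protein (may be empty).
#' @param gel_window Optional `c(lo, hi)` mass window in kDa for the
#'   protein's peak gel slice.
#' @return A one-row tibble (`p1_pos`, `motif`, `status = "inferred"`,
#'   `mature_mass_kda`) or `NULL` when no propeptide is indicated or no motif
#'   position qualifies.
#' @export
infer_maturation_site <- function(protein_sequence, coverage,
                                  model = motif_preset(),
                                  observed_sites = integer(0),
                                  gel_window = NULL) {
  covered <- which(coverage > 0)
  if (length(covered) == 0) return(NULL)
  r <- covered[1]
  if (r == 1L) return(NULL)
  upstream <- if (length(observed_sites) > 0) {
    max(c(0L, observed_sites[observed_sites < r]))
  } else 0L
  cand <- scan_motif(protein_sequence, model)
  cand <- cand[cand > upstream & cand <= r - 1L]
  if (length(cand) == 0) return(NULL)
  pick <- max(cand)
  if (!is.null(gel_window)) {
    mm <- vapply(cand, function(p) {
      average_mass(substr(protein_sequence, p + 1L, nchar(protein_sequence)))
    }, numeric(1)) / 1000
    in_win <- cand[mm >= gel_window[1] & mm <= gel_window[2]]
    if (length(in_win) > 0) pick <- max(in_win)
  }
  tibble::tibble(
    p1_pos = as.integer(pick),
    motif = match_motif(protein_sequence, pick, model, allow_short = TRUE),
    status = "inferred",
    mature_mass_kda = mass_kda(average_mass(
      substr(protein_sequence, pick + 1L, nchar(protein_sequence))))
  )
}

#' Mature form of a processed protein
#'
#' Given the accepted cleavage sites of one protein, the retained (mature)
#' span runs from just after the most C-terminal N-side cut to the most
#' N-terminal C-side cut (or the protein ends where no cut exists on that
#' side). Additional sub-cuts inside the removed propeptides are recorded in
#' `removed_segments` but do not change the mature span.
#'
#' @param protein_sequence Protein sequence.
#' @param sites Tibble of accepted sites for this protein with `p1_pos` and
#'   `side` columns (may be empty: full-length form).
#' @return A list with `start_res`, `end_res`, `mass_da`, `mass_kda`, and
#'   `removed_segments` (list of `c(start, end)` spans with a side
#'   attribute).
#' @export
mature_form <- function(protein_sequence, sites = NULL) {
  n <- nchar(protein_sequence)
  n_cuts <- integer(0)
  c_cuts <- integer(0)
  if (!is.null(sites) && nrow(sites) > 0) {
    n_cuts <- sites$p1_pos[sites$side == "N_propeptide"]
    c_cuts <- sites$p1_pos[sites$side == "C_propeptide"]
  }
  start_res <- if (length(n_cuts) > 0) max(n_cuts) + 1L else 1L
  end_res <- if (length(c_cuts) > 0) min(c_cuts) else n
  if (start_res > end_res) {
    stop("crossing cuts: N-side boundary beyond C-side boundary",
         call. = FALSE)
  }
  removed <- list()
  if (start_res > 1L) {
    removed <- c(removed, list(structure(c(1L, start_res - 1L),
                                         side = "N_propeptide")))
  }
  if (end_res < n) {
    removed <- c(removed, list(structure(c(end_res + 1L, n),
                                         side = "C_propeptide")))
  }
  mass <- average_mass(substr(protein_sequence, start_res, end_res))
  list(start_res = start_res, end_res = end_res,
       mass_da = mass, mass_kda = mass_kda(mass),
       removed_segments = removed)
}

#' Position frequency matrix around cleavage sites
#'
#' Builds a residue frequency matrix over a window spanning P5..P2' (five
#' residues N-terminal through two residues C-terminal of each cut), the
#' input to a cleavage-site sequence logo. Window positions that fall outside
#' a protein are skipped for that site, and each column is renormalized over
#' the sites that contribute to it, so every column sums to 1. For a
#' motif-conforming site set the P1 column is pure glutamate.
#'
#' @param sites Tibble with `protein_id` and `p1_pos` (>= 1 row).
#' @param proteins Protein-record tibble.
#' @param upstream,downstream Window extent: residues P\{upstream\}..P1 and
#'   P1'..P\{downstream\}'.
#' @return A list with `pfm` (20 x window matrix of column-stochastic
#'   frequencies, columns named `P5`..`P1`, `P1'`, `P2'`), `counts` (raw
#'   counts), and `information` (per-column information content in bits).
#' @export
build_pfm <- function(sites, proteins, upstream = 5L, downstream = 2L) {
  if (is.null(sites) || nrow(sites) == 0) {
    stop("cannot build a frequency matrix from an empty site list",
         call. = FALSE)
  }
  seqs <- stats::setNames(proteins$sequence, proteins$id)
  offsets <- seq.int(-(upstream - 1L), downstream)
  colnames_out <- c(paste0("P", upstream:1),
                    paste0("P", seq_len(downstream), "'"))
  counts <- matrix(0L, nrow = 20, ncol = length(offsets),
                   dimnames = list(names(.AA_AVERAGE), colnames_out))
  for (k in seq_len(nrow(sites))) {
    s <- seqs[[sites$protein_id[k]]]
    pos <- sites$p1_pos[k] + offsets
    keep <- pos >= 1 & pos <= nchar(s)
    aa <- substring(s, pos[keep], pos[keep])
    for (j in seq_along(aa)) {
      if (aa[j] %in% rownames(counts)) {
        counts[aa[j], which(keep)[j]] <- counts[aa[j], which(keep)[j]] + 1L
      }
    }
  }
  col_n <- colSums(counts)
  pfm <- sweep(counts, 2, pmax(col_n, 1L), "/")
  info <- apply(pfm, 2, function(p) {
    p <- p[p > 0]
    log2(20) + sum(p * log2(p))
  })
  info[col_n == 0] <- NA_real_
  list(pfm = pfm, counts = counts, information = info)
}
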