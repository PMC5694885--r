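#' Run configuration
#'
#' Collects the inputs and thresholds of a full analysis run. Any argument
#' may also be supplied through a YAML file (see [read_run_config()]) whose
#' keys mirror the argument names.
#'
#' @param proteins Path to the protein FASTA.
#' @param peptides Path to the peptide report TSV.
#' @param genome Optional genome FASTA path (start-site reassignment).
#' @param cds Optional GFF-lite TSV path with CDS coordinates.
#' @param peptides2 Optional second-sample peptide report TSV (enables the
#'   wild-type-vs-mutant presence/absence comparison; the first report is
#'   the reference).
#' @param motif Motif preset name (`"spn3us"`, `"phikz"`, `"201phi2-1"`,
#'   `"t4"`) or a [motif_model()].
#' @param gel Optional gel-model TSV path.
#' @param refs Optional reference-stoichiometry TSV path.
#' @param out Output directory.
#' @param filters A [filter_config()].
#' @param proline_rule Trypsin proline rule.
#' @param seed Seed (recorded in the log; only simulation consumes it).
#' @return A `run_config` list.
#' @export
run_config <- function(proteins, peptides, genome = NULL, cds = NULL,
                       peptides2 = NULL, motif = "spn3us", gel = NULL,
                       refs = NULL, out = "phagehead_out",
                       filters = filter_config(), proline_rule = TRUE,
                       seed = 1L) {
  if (is.character(motif)) motif <- motif_preset(motif)
  structure(list(proteins = proteins, peptides = peptides, genome = genome,
                 cds = cds, peptides2 = peptides2, motif = motif, gel = gel,
                 refs = refs, out = out, filters = filters,
                 proline_rule = proline_rule, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; `filters` may be a mapping
#' with `min_peptide_prob`, `min_protein_prob`, `min_peptides`.
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$filters)) y$filters <- do.call(filter_config, y$filters)
  do.call(run_config, y)
}

.check_path <- function(path, what) {
  if (!is.null(path) && !file.exists(path)) {
    stop("missing ", what, " file: ", path, call. = FALSE)
  }
  path
}

#' Run the full cleavage-site and abundance pipeline
#'
#' Reads the inputs named in a [run_config()], applies identification-quality
#' filters, classifies peptide termini against an in-silico tryptic digest,
#' aggregates semi-tryptic termini into candidate cleavage sites, accepts
#' sites under the motif model, infers unobserved maturation cuts from
#' coverage (and gel migration when a gel model is given), derives mature
#' forms and masses, builds the cleavage-site frequency matrix, assembles the
#' abundance table, and (when a second sample is given) the presence/absence
#' comparison. All results are written as TSVs under the output directory,
#' along with a run log recording the configuration and every decision flag
#' fired.
#'
#' @param cfg A [run_config()] or a path to a YAML config.
#' @return Invisibly, a list with all result tables (`observations`,
#'   `sites`, `mature_forms`, `pfm`, `abundance`, `comparison`).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  .check_path(cfg$proteins, "protein FASTA")
  .check_path(cfg$peptides, "peptide report")
  for (f in c("genome", "cds", "peptides2", "gel", "refs")) {
    .check_path(cfg[[f]], f)
  }
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("phagehead run, seed %d", cfg$seed),
                 sprintf("motif model: %s (P3 in {%s}, P1 = %s)",
                         cfg$motif$name,
                         paste(cfg$motif$p3_allowed, collapse = ","),
                         cfg$motif$p1_residue))

  proteins <- read_protein_fasta(cfg$proteins)
  report <- read_peptide_report(cfg$peptides)
  gel <- if (!is.null(cfg$gel)) read_gel_model(cfg$gel) else NULL
  refs <- if (!is.null(cfg$refs)) read_refs(cfg$refs) else NULL

  filt <- suppressWarnings(apply_filters(report, cfg$filters))
  log_lines <- c(log_lines,
                 sprintf("filters: %d/%d peptide rows retained",
                         nrow(filt), nrow(report)))
  cls <- classify_report(filt, proteins, proline_rule = cfg$proline_rule)
  if (any(cls$nme)) {
    log_lines <- c(log_lines, sprintf(
      "NME: start-at-residue-2 peptides for %s treated as host Met excision",
      paste(unique(cls$protein_id[cls$nme]), collapse = ", ")))
  }

  cand <- candidate_sites(cls)
  sites <- accept_sites(cand, proteins, model = cfg$motif)
  n_low <- sum(sites$tier == "low_confidence")
  if (n_low > 0) {
    log_lines <- c(log_lines, sprintf(
      "%d boundary(ies) reported in the low-confidence tier", n_low))
  }

  # coverage-based inference of unobserved maturation cuts
  inferred <- list()
  acc <- sites[sites$tier == "accepted", ]
  for (pid in unique(cls$protein_id)) {
    pseq <- proteins$sequence[proteins$id == pid]
    pobs <- cls[cls$protein_id == pid, ]
    cov <- residue_coverage(pobs, nchar(pseq))
    obs_p1 <- acc$p1_pos[acc$protein_id == pid]
    window <- NULL
    if (!is.null(gel)) {
      pk <- peak_slice(stats::setNames(
        tapply(pobs$spectral_count, pobs$slice_index, sum),
        names(tapply(pobs$spectral_count, pobs$slice_index, sum))))
      if (!is.na(pk$slice) && pk$slice %in% gel$slice) {
        w <- gel[gel$slice == pk$slice, ]
        window <- c(w$lo_kda, w$hi_kda)
      }
    }
    inf <- infer_maturation_site(pseq, cov, model = cfg$motif,
                                 observed_sites = obs_p1,
                                 gel_window = window)
    if (!is.null(inf)) {
      inferred[[length(inferred) + 1L]] <- tibble::tibble(
        protein_id = pid, p1_pos = inf$p1_pos, motif = inf$motif,
        support_spectra = 0L, support_peptides = 0L,
        side = "N_propeptide", status = "inferred", tier = "accepted")
    }
  }
  if (length(inferred) > 0) {
    sites <- dplyr::bind_rows(sites, dplyr::bind_rows(inferred))
    log_lines <- c(log_lines, sprintf("%d maturation site(s) inferred",
                                      length(inferred)))
  }

  acc <- sites[sites$tier == "accepted", ]
  forms <- NULL
  if (nrow(acc) > 0) {
    forms <- acc |>
      dplyr::group_by(.data$protein_id) |>
      dplyr::group_modify(function(d, g) {
        pseq <- proteins$sequence[proteins$id == g$protein_id]
        f <- mature_form(pseq, d)
        tibble::tibble(start_res = f$start_res, end_res = f$end_res,
                       mass_kda = f$mass_da / 1000,
                       status = if (any(d$status == "inferred")) {
                         "inferred"
                       } else {
                         "observed"
                       })
      }) |>
      dplyr::ungroup()
  }

  pfm <- NULL
  motif_sites <- acc[!is.na(acc$motif), ]
  if (nrow(motif_sites) > 0) pfm <- build_pfm(motif_sites, proteins)

  tab <- abundance_table(cls, proteins, mature_forms = forms,
                         references = refs)
  if (!is.null(gel) && !is.null(forms)) {
    gc <- vapply(seq_len(nrow(forms)), function(k) {
      pk <- tab$peak_slice[tab$protein_id == forms$protein_id[k]]
      if (length(pk) == 0) return("untestable")
      gel_consistency(forms$mass_kda[k], pk, gel)
    }, character(1))
    forms$gel_consistency <- gc
  }

  comparison <- NULL
  if (!is.null(cfg$peptides2)) {
    rep2 <- read_peptide_report(cfg$peptides2)
    filt2 <- suppressWarnings(apply_filters(rep2, cfg$filters))
    comparison <- compare_proteomes(unique(filt$protein_id),
                                    unique(filt2$protein_id))
  }

  readr::write_tsv(cls, file.path(cfg$out, "observations_filtered.tsv"))
  readr::write_tsv(sites, file.path(cfg$out, "cleavage_sites.tsv"))
  if (!is.null(forms)) {
    readr::write_tsv(forms, file.path(cfg$out, "mature_forms.tsv"))
  }
  if (!is.null(pfm)) {
    pfm_df <- tibble::as_tibble(pfm$pfm, rownames = "residue")
    readr::write_tsv(pfm_df, file.path(cfg$out, "cleavage_pfm.tsv"))
  }
  readr::write_tsv(tab, file.path(cfg$out, "abundance.tsv"))
  if (!is.null(comparison)) {
    comp_df <- dplyr::bind_rows(
      tibble::tibble(protein_id = comparison$missing, change = "missing"),
      tibble::tibble(protein_id = comparison$gained, change = "gained"))
    readr::write_tsv(comp_df, file.path(cfg$out, "comparison.tsv"))
  }
  writeLines(c(log_lines, paste("finished", format(Sys.time()))),
             file.path(cfg$out, "run.log"))

  invisible(list(observations = cls, sites = sites, mature_forms = forms,
                 pfm = pfm, abundance = tab, comparison = comparison))
}
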