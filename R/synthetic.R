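# Seeded generator of a virion proteome with planted maturation events and
# GeLC-MS/MS-style peptide observations, giving every pipeline stage a known
# ground truth.

# background residue frequencies (Robinson & Robinson order-0 composition)
.AA_FREQ <- c(
  A = 0.078, R = 0.051, N = 0.045, D = 0.054, C = 0.019, Q = 0.043,
  E = 0.063, G = 0.073, H = 0.022, I = 0.053, L = 0.091, K = 0.059,
  M = 0.022, F = 0.039, P = 0.052, S = 0.068, T = 0.059, W = 0.014,
  Y = 0.032, V = 0.066
)

#' Simulation configuration
#'
#' Defaults emulate the composition of a giant-phage virion proteome: about
#' 100 detected proteins with lognormal lengths (median ~350 residues), copy
#' numbers spanning 1 to 1600 with a designated major-capsid-like protein at
#' 1560 copies plus sheath-like (264) and portal-like (12) stoichiometric
#' references, roughly one protein in six carrying a planted prohead-protease
#' cleavage site at the configured motif (N-terminal propeptides of 20-260
#' residues, occasional C-terminal events), Poisson spectral counts with
#' expected totals proportional to copies x mature mass, and mass-ordered
#' gel-slice assignment with multiplicative migration noise.
#'
#' @param n_proteins Number of proteins.
#' @param length_meanlog,length_sdlog Lognormal length distribution (aa).
#' @param copy_range Log-uniform copy-number range for ordinary proteins.
#' @param mcp_copies Copies of the designated most-abundant protein.
#' @param ref_copies Copies of the two additional reference proteins.
#' @param fraction_processed Fraction of proteins carrying a planted
#'   maturation site.
#' @param motif A [motif_model()] used for planting.
#' @param propeptide_range N-side propeptide length range (residues).
#' @param c_side_rate Probability that a processed protein also carries a
#'   C-terminal cleavage.
#' @param sc_rate Spectral-count rate constant `c`: expected total SC per
#'   protein is `c * copies * mature mass (kDa)`.
#' @param semi_peptide_rate Rate of semi-tryptic boundary peptides at planted
#'   cuts, as a fraction of the per-peptide expected count.
#' @param propeptide_detect Detection rate of released propeptide fragments
#'   relative to the mature species.
#' @param n_slices Number of gel slices (10 emulates a wild-type lane, 6 a
#'   mutant lane).
#' @param slice_mass_range Mass range (kDa) spanned by the gel.
#' @param migration_sigma Fractional standard deviation of gel migration
#'   noise.
#' @param max_missed Maximum missed cleavages in simulated peptides.
#' @param missed_weight Relative detectability of each additional missed
#'   cleavage.
#' @param low_prob_rate Fraction of peptide rows given sub-threshold
#'   identification probabilities (to exercise quality filters).
#' @param seed Mandatory random seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_proteins = 100L, length_meanlog = log(350),
                       length_sdlog = 0.45, copy_range = c(1, 600),
                       mcp_copies = 1560L, ref_copies = c(264L, 12L),
                       fraction_processed = 0.16,
                       motif = motif_preset("spn3us"),
                       propeptide_range = c(20L, 260L), c_side_rate = 0.15,
                       sc_rate = 0.05, semi_peptide_rate = 0.9,
                       propeptide_detect = 0.3, n_slices = 10L,
                       slice_mass_range = c(7, 260), migration_sigma = 0.08,
                       max_missed = 2L, missed_weight = 0.3,
                       low_prob_rate = 0.05, seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(fraction_processed >= 0, fraction_processed <= 1,
            sc_rate >= 0, semi_peptide_rate >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Gel model implied by a simulation configuration
#'
#' Log-spaced mass windows over `slice_mass_range`, slice 1 lowest.
#'
#' @param cfg A [sim_config()].
#' @return A [gel_model()] tibble.
#' @export
sim_gel_model <- function(cfg) {
  br <- exp(seq(log(cfg$slice_mass_range[1]), log(cfg$slice_mass_range[2]),
                length.out = cfg$n_slices + 1))
  gel_model(seq_len(cfg$n_slices), br[-length(br)], br[-1])
}

.sample_sequence <- function(n) {
  paste(c("M", sample(names(.AA_FREQ), n - 1L, replace = TRUE,
                      prob = .AA_FREQ)), collapse = "")
}

.plant_motif <- function(sequence, p1_pos, model) {
  p3 <- sample(model$p3_allowed, 1)
  p2 <- sample(model$p2_allowed, 1)
  substr(sequence, p1_pos - 2L, p1_pos) <- paste0(p3, p2, model$p1_residue)
  sequence
}

#' Generate a synthetic proteome with planted cleavage sites
#'
#' Deterministic under the configuration's seed. Sequences are drawn from
#' background residue frequencies; processed proteins get a motif trimer
#' written at the planted P3..P1 positions. The first protein is the
#' major-capsid-like reference; proteins 2 and 3 carry the sheath-like and
#' portal-like reference copy numbers.
#'
#' @param cfg A [sim_config()].
#' @return A list with `proteins` (protein-record tibble; reference proteins
#'   carry `known_copies`) and `truth` (list with `copies`, `sites`,
#'   `mature_forms` tibbles).
#' @export
generate_proteome <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_proteins
  ids <- sprintf("sp%03d", seq_len(n))
  lens <- pmin(pmax(round(stats::rlnorm(n, cfg$length_meanlog,
                                        cfg$length_sdlog)), 80L), 2500L)
  seqs <- vapply(lens, .sample_sequence, character(1))

  copies <- round(exp(stats::runif(n, log(cfg$copy_range[1]),
                                   log(cfg$copy_range[2]))))
  copies[1] <- cfg$mcp_copies
  copies[2] <- cfg$ref_copies[1]
  copies[3] <- cfg$ref_copies[2]
  known <- rep(NA_integer_, n)
  known[1:3] <- c(cfg$mcp_copies, cfg$ref_copies)

  n_proc <- round(cfg$fraction_processed * n)
  eligible <- which(lens >= 2L * cfg$propeptide_range[1] + 40L)
  proc_idx <- sort(sample(eligible, min(n_proc, length(eligible))))

  site_rows <- list()
  form_rows <- list()
  for (i in seq_len(n)) {
    s <- seqs[i]
    n_cut <- NA_integer_
    c_cut <- NA_integer_
    if (i %in% proc_idx) {
      lmax <- min(cfg$propeptide_range[2], floor(lens[i] / 2) - 10L)
      L <- sample(cfg$propeptide_range[1]:max(cfg$propeptide_range[1], lmax), 1)
      s <- .plant_motif(s, L, cfg$motif)
      n_cut <- L
      site_rows[[length(site_rows) + 1L]] <- tibble::tibble(
        protein_id = ids[i], p1_pos = L, side = "N_propeptide")
      if (stats::runif(1) < cfg$c_side_rate) {
        Lc <- sample(20:60, 1)
        p1c <- lens[i] - Lc
        if (p1c > L + 30L) {
          s <- .plant_motif(s, p1c, cfg$motif)
          c_cut <- p1c
          site_rows[[length(site_rows) + 1L]] <- tibble::tibble(
            protein_id = ids[i], p1_pos = p1c, side = "C_propeptide")
        }
      }
    }
    start_res <- if (is.na(n_cut)) 1L else n_cut + 1L
    end_res <- if (is.na(c_cut)) lens[i] else c_cut
    seqs[i] <- s
    form_rows[[i]] <- tibble::tibble(
      protein_id = ids[i], start_res = start_res, end_res = end_res,
      mature_mass_kda = average_mass(substr(s, start_res, end_res)) / 1000)
  }
  sites <- if (length(site_rows) > 0) {
    dplyr::bind_rows(site_rows)
  } else {
    tibble::tibble(protein_id = character(0), p1_pos = integer(0),
                   side = character(0))
  }
  if (nrow(sites) > 0) {
    sites$motif <- vapply(seq_len(nrow(sites)), function(k) {
      match_motif(seqs[match(sites$protein_id[k], ids)], sites$p1_pos[k],
                  cfg$motif)
    }, character(1))
  } else {
    sites$motif <- character(0)
  }
  forms <- dplyr::bind_rows(form_rows)
  gel <- sim_gel_model(cfg)
  forms$true_slice <- vapply(forms$mature_mass_kda, function(m) {
    w <- which(gel$lo_kda <= m & m < gel$hi_kda)
    if (length(w) == 0) {
      if (m < gel$lo_kda[1]) 1L else cfg$n_slices
    } else {
      w[1]
    }
  }, integer(1))

  proteins <- protein_records(id = ids, sequence = seqs,
                              known_copies = known)
  list(proteins = proteins,
       truth = list(copies = tibble::tibble(protein_id = ids,
                                            copies = copies),
                    sites = sites, mature_forms = forms))
}

#' Simulate a GeLC-MS/MS peptide report from a synthetic proteome
#'
#' For each protein the mature span is digested with missed cleavages;
#' expected spectral counts are distributed over peptides (each missed
#' cleavage multiplies detectability by `missed_weight`) so that the
#' protein's expected total is `sc_rate * copies * mature mass`. Counts are
#' Poisson. At each planted cut a semi-tryptic boundary peptide is emitted at
#' `semi_peptide_rate` times the per-peptide rate. Released propeptide
#' fragments are observed at a reduced rate in the gel slice matching the
#' propeptide's own mass. Peptides are assigned the slice whose mass window
#' contains the carrier species' mass after multiplicative migration noise.
#' Identification probabilities are drawn to exercise [apply_filters()].
#'
#' @param proteins,truth Output of [generate_proteome()].
#' @param cfg The same [sim_config()].
#' @return A peptide report tibble (see [read_peptide_report()]).
#' @export
simulate_observations <- function(proteins, truth, cfg) {
  set.seed(cfg$seed + 1L)
  gel <- sim_gel_model(cfg)
  copies <- stats::setNames(truth$copies$copies, truth$copies$protein_id)
  rows <- list()

  noisy_slice <- function(mass_kda) {
    m <- mass_kda * (1 + stats::rnorm(1, 0, cfg$migration_sigma))
    w <- which(gel$lo_kda <= m & m < gel$hi_kda)
    if (length(w) == 0) {
      if (m < gel$lo_kda[1]) 1L else cfg$n_slices
    } else {
      w[1]
    }
  }

  emit <- function(protein_id, peps, lambda, slice) {
    sc <- stats::rpois(nrow(peps), lambda)
    keep <- sc > 0
    if (!any(keep)) return(NULL)
    tibble::tibble(
      protein_id = protein_id,
      peptide = peps$peptide[keep],
      start_res = peps$start_res[keep],
      end_res = peps$end_res[keep],
      spectral_count = sc[keep],
      slice_index = slice)
  }

  for (i in seq_len(nrow(proteins))) {
    pid <- proteins$id[i]
    cp <- copies[[pid]]
    if (cp < 1) next
    s <- proteins$sequence[i]
    form <- truth$mature_forms[truth$mature_forms$protein_id == pid, ]
    mat_seq <- substr(s, form$start_res, form$end_res)
    total <- cfg$sc_rate * cp * average_mass(mat_seq) / 1000

    peps <- digest(mat_seq, max_missed = cfg$max_missed, min_length = 6L)
    peps <- peps[nchar(peps$peptide) <= 45, , drop = FALSE]
    if (nrow(peps) == 0) next
    off <- form$start_res - 1L
    peps$start_res <- peps$start_res + off
    peps$end_res <- peps$end_res + off
    # peptides touching a cleavage boundary are the semi-tryptic evidence;
    # they are emitted separately at semi_peptide_rate, not here
    if (form$start_res > 1L) {
      peps <- peps[peps$start_res > form$start_res, , drop = FALSE]
    }
    if (form$end_res < nchar(s)) {
      peps <- peps[peps$end_res < form$end_res, , drop = FALSE]
    }
    if (nrow(peps) == 0) next
    w <- cfg$missed_weight^peps$n_missed
    lambda <- total * w / sum(w)
    slice <- noisy_slice(form$mature_mass_kda)
    rows[[length(rows) + 1L]] <- emit(pid, peps, lambda, slice)

    lambda_bar <- total / sum(w)
    tsites <- tryptic_sites(s)
    psites <- truth$sites[truth$sites$protein_id == pid, ]
    for (k in seq_len(nrow(psites))) {
      p1 <- psites$p1_pos[k]
      if (psites$side[k] == "N_propeptide") {
        nxt <- tsites[tsites > p1]
        semi_end <- if (length(nxt) > 0) min(nxt) else nchar(s)
        semi <- tibble::tibble(
          peptide = substr(s, p1 + 1L, semi_end),
          start_res = p1 + 1L, end_res = semi_end)
      } else {
        prv <- tsites[tsites < p1 - 1L]
        semi_start <- if (length(prv) > 0) max(prv) + 1L else 1L
        semi <- tibble::tibble(
          peptide = substr(s, semi_start, p1),
          start_res = semi_start, end_res = p1)
      }
      if (nchar(semi$peptide) < 4) next
      rows[[length(rows) + 1L]] <-
        emit(pid, semi, cfg$semi_peptide_rate * lambda_bar, slice)
    }

    # released N-terminal propeptide, partially retained/detected
    if (form$start_res > 1L && cfg$propeptide_detect > 0) {
      pro_seq <- substr(s, 1L, form$start_res - 1L)
      pro_peps <- digest(pro_seq, max_missed = cfg$max_missed,
                         min_length = 6L)
      pro_peps <- pro_peps[nchar(pro_peps$peptide) <= 45, , drop = FALSE]
      if (nrow(pro_peps) > 0) {
        pro_slice <- noisy_slice(average_mass(pro_seq) / 1000)
        lam <- cfg$propeptide_detect * lambda_bar *
          cfg$missed_weight^pro_peps$n_missed
        # the propeptide's own C-terminus is the cleavage boundary: its
        # observability scales with semi_peptide_rate like all cut evidence
        at_cut <- pro_peps$end_res == nchar(pro_seq)
        lam[at_cut] <- lam[at_cut] * cfg$semi_peptide_rate
        rows[[length(rows) + 1L]] <- emit(pid, pro_peps, lam, pro_slice)
      }
    }
  }

  rep <- dplyr::bind_rows(rows)
  if (nrow(rep) == 0) {
    rep <- tibble::tibble(protein_id = character(0), peptide = character(0),
                          start_res = integer(0), end_res = integer(0),
                          spectral_count = integer(0),
                          slice_index = integer(0))
  }
  n <- nrow(rep)
  low <- stats::runif(n) < cfg$low_prob_rate
  rep$peptide_prob <- ifelse(low, stats::runif(n, 0.3, 0.94),
                             stats::runif(n, 0.96, 1))
  prot_low <- stats::setNames(
    stats::runif(nrow(proteins)) < 0.02, proteins$id)
  rep$protein_prob <- ifelse(prot_low[rep$protein_id], 0.5, 0.9999)
  rep
}

#' Run the full pipeline on simulated data and score against truth
#'
#' Generates a proteome and observations under `cfg`, runs quality
#' filtering, terminus classification, site aggregation/acceptance and
#' abundance estimation, and scores the result against the planted truth.
#' Recall is measured over detectable planted sites — those supported by at
#' least `min_detect_spectra` semi-tryptic spectra in the raw report — since
#' no evidence-based method can recover a site that produced no evidence.
#'
#' @param cfg A [sim_config()].
#' @param filters A [filter_config()].
#' @param min_detect_spectra Spectra required for a planted site to count as
#'   detectable.
#' @return A list with `precision`, `recall`, `n_detectable`,
#'   `spearman_copies`, `pfm_distance` (mean absolute difference between
#'   recovered and planted site frequency matrices), plus the intermediate
#'   `sites`, `table`, `truth` objects.
#' @export
end_to_end_recovery <- function(cfg, filters = filter_config(),
                                min_detect_spectra = 3L) {
  gen <- generate_proteome(cfg)
  rep <- simulate_observations(gen$proteins, gen$truth, cfg)

  filt <- suppressWarnings(apply_filters(rep, filters))
  cls <- classify_report(filt, gen$proteins)
  cand <- candidate_sites(cls)
  sites <- accept_sites(cand, gen$proteins, model = cfg$motif)
  obs_sites <- sites[sites$tier == "accepted", ]

  truth_key <- paste(gen$truth$sites$protein_id, gen$truth$sites$p1_pos)
  found_key <- paste(obs_sites$protein_id, obs_sites$p1_pos)
  precision <- if (length(found_key) == 0) {
    NA_real_
  } else {
    mean(found_key %in% truth_key)
  }

  cand_all <- candidate_sites(classify_report(rep, gen$proteins))
  cand_key <- paste(cand_all$protein_id, cand_all$p1_pos)
  detectable <- truth_key[truth_key %in%
    cand_key[cand_all$support_spectra >= min_detect_spectra]]
  recall <- if (length(detectable) == 0) {
    NA_real_
  } else {
    mean(detectable %in% found_key)
  }

  forms <- obs_sites |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::group_modify(function(d, g) {
      seq <- gen$proteins$sequence[gen$proteins$id == g$protein_id]
      f <- mature_form(seq, d)
      tibble::tibble(start_res = f$start_res, end_res = f$end_res,
                     mass_kda = f$mass_da / 1000, status = "observed")
    }) |>
    dplyr::ungroup()

  refs <- gen$proteins[!is.na(gen$proteins$known_copies),
                       c("id", "known_copies")]
  names(refs)[1] <- "protein_id"
  tab <- abundance_table(cls, gen$proteins, mature_forms = forms,
                         references = refs)
  joined <- dplyr::inner_join(tab, gen$truth$copies, by = "protein_id")
  spearman <- stats::cor(joined$copy_estimate, joined$copies,
                         method = "spearman")

  pfm_distance <- NA_real_
  motif_found <- obs_sites[!is.na(obs_sites$motif), ]
  if (nrow(motif_found) > 0 && nrow(gen$truth$sites) > 0) {
    pfm_rec <- build_pfm(motif_found, gen$proteins)$pfm
    pfm_true <- build_pfm(gen$truth$sites, gen$proteins)$pfm
    pfm_distance <- mean(abs(pfm_rec - pfm_true))
  }

  list(precision = precision, recall = recall,
       n_detectable = length(detectable), spearman_copies = spearman,
       pfm_distance = pfm_distance, sites = sites, table = tab,
       truth = gen$truth, proteins = gen$proteins, report = rep)
}
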