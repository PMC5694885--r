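test_that("motif matching recognises the A-X-E family", {
  s75 <- gp75_synthetic()
  expect_equal(match_motif(s75, 130), "ATE")
  expect_true(is.na(match_motif(s75, 131)))          # not a glutamate
  expect_error(match_motif(s75, 9999), "out of range")

  # the shared N-terminus of the two head-ejection paralogs reads as a
  # cleavage site under A-X-E at position 12 and under S/A/G-X-E at 15
  nterm <- "MANFVKSKLARESVE"
  expect_equal(match_motif(nterm, 12), "ARE")
  expect_true(is.na(match_motif(nterm, 15)))
  expect_equal(match_motif(nterm, 15, motif_preset("phikz")), "SVE")
  expect_equal(match_motif(nterm, 15, motif_preset("201phi2-1")), "SVE")
})

test_that("motif scanning matches a brute-force substring oracle", {
  expect_equal(scan_motif("MGGSTGGSTGG"), integer(0))  # no glutamate at all
  s245 <- gp245_synthetic()
  expect_equal(scan_motif(s245), c(203L, 234L, 246L))

  set.seed(41)
  for (k in 1:5) {
    s <- random_protein(500)
    model <- motif_preset("phikz")
    expect_equal(scan_motif(s, model),
                 brute_scan(s, model$p3_allowed))
  }
})

test_that("semi-tryptic termini aggregate into supported candidate boundaries", {
  s <- gp75_synthetic()
  prot <- protein_records("gp75s", s)

  # fully tryptic input yields nothing
  d <- digest(s, 0, min_length = 6)
  full <- obs_row("gp75s", d$peptide[2:4], d$start_res[2:4], d$end_res[2:4])
  expect_equal(nrow(candidate_sites(classify_report(full, prot))), 0)

  # three semi-tryptic peptide forms sharing the boundary after residue 130
  semi <- dplyr::bind_rows(
    obs_row("gp75s", substr(s, 131, 136), 131, 136, spectral_count = 2),
    obs_row("gp75s", substr(s, 131, 144), 131, 144, spectral_count = 1),
    obs_row("gp75s", substr(s, 131, 152), 131, 152, spectral_count = 4))
  cand <- candidate_sites(classify_report(semi, prot))
  expect_equal(nrow(cand), 1)
  expect_equal(cand$p1_pos, 130L)
  expect_equal(cand$support_spectra, 7L)
  expect_equal(cand$support_peptides, 3L)

  # NME starts and protein termini are not protease evidence
  nme <- obs_row("gp75s", substr(s, 2, 8), 2, 8)
  expect_equal(nrow(candidate_sites(classify_report(nme, prot))), 0)

  # a semi-tryptic C-terminus contributes a cut after its last residue
  semi_c <- obs_row("gp75s", substr(s, 201, 210), 201, 210)
  cand_c <- candidate_sites(classify_report(semi_c, prot))
  expect_equal(cand_c$p1_pos, 210L)
})

test_that("site acceptance separates motif, multi-peptide and low-confidence evidence", {
  s <- gp75_synthetic()
  prot <- protein_records("gp75s", s)
  obs <- dplyr::bind_rows(
    obs_row("gp75s", substr(s, 131, 136), 131, 136, spectral_count = 1),
    obs_row("gp75s", substr(s, 201, 210), 201, 210, spectral_count = 1))
  sites <- accept_sites(candidate_sites(classify_report(obs, prot)), prot)
  s130 <- sites[sites$p1_pos == 130, ]
  s210 <- sites[sites$p1_pos == 210, ]
  expect_equal(s130$tier, "accepted")       # motif + 1 spectrum suffices
  expect_equal(s130$motif, "ATE")
  expect_equal(s130$side, "N_propeptide")
  expect_equal(s210$tier, "low_confidence") # no motif, single peptide
  expect_true(is.na(s210$motif))

  # observed motif-conforming sites are always inside the scan superset
  expect_true(all(s130$p1_pos %in% scan_motif(s)))
})

test_that("maturation cuts are inferred from missing N-terminal coverage", {
  s47 <- gp47_synthetic()
  # no sequence coverage until residue 119; observed propeptide cut at 79
  cov <- integer(nchar(s47))
  cov[119:300] <- 5L
  inf <- infer_maturation_site(s47, cov, observed_sites = 79L)
  expect_equal(inf$p1_pos, 111L)
  expect_equal(inf$motif, "ALE")
  expect_equal(inf$status, "inferred")

  # full coverage from residue 1: no propeptide, nothing to infer
  expect_null(infer_maturation_site(s47, rep(1L, nchar(s47))))

  # no motif-conforming position in the gap: nothing to infer
  plain <- filler_protein(200)
  cov2 <- integer(200); cov2[50:200] <- 1L
  expect_null(infer_maturation_site(plain, cov2))
})

test_that("gel mass windows arbitrate between inferred maturation candidates", {
  s81 <- plant_trimer(gp81_synthetic(), 200L, "AQE")
  cov <- integer(nchar(s81))
  cov[255:900] <- 3L
  m254 <- average_mass(substr(s81, 255, nchar(s81))) / 1000
  m200 <- average_mass(substr(s81, 201, nchar(s81))) / 1000

  # without a window: the candidate closest to the coverage start wins
  inf <- infer_maturation_site(s81, cov, observed_sites = 161L)
  expect_equal(inf$p1_pos, 254L)

  # a window bracketing only the shorter mature form keeps 254
  inf_in <- infer_maturation_site(s81, cov, observed_sites = 161L,
                                  gel_window = c(m254 - 2, m254 + 2))
  expect_equal(inf_in$p1_pos, 254L)

  # a window bracketing only the longer mature form overrides proximity
  inf_up <- infer_maturation_site(s81, cov, observed_sites = 161L,
                                  gel_window = c(m200 - 1, m200 + 1))
  expect_equal(inf_up$p1_pos, 200L)
})

test_that("mature forms trim accepted cuts and never gain mass", {
  s75 <- gp75_synthetic()
  none <- mature_form(s75)
  expect_equal(none$start_res, 1L)
  expect_equal(none$end_res, nchar(s75))
  expect_equal(none$mass_da, average_mass(s75))

  one <- mature_form(s75, tibble::tibble(p1_pos = 130L,
                                         side = "N_propeptide"))
  expect_equal(one$start_res, 131L)
  expect_equal(one$mass_da,
               average_mass(substr(s75, 131, nchar(s75))))
  expect_lt(one$mass_da, none$mass_da)
  expect_equal(length(one$removed_segments), 1L)

  # dual-end trimming, as in the T4 ADP-ribosyltransferase Alt
  alt <- filler_protein(669)
  dual <- mature_form(alt, tibble::tibble(
    p1_pos = c(6L, 619L), side = c("N_propeptide", "C_propeptide")))
  expect_equal(c(dual$start_res, dual$end_res), c(7L, 619L))
  expect_equal(length(dual$removed_segments), 2L)

  expect_error(
    mature_form(alt, tibble::tibble(p1_pos = c(400L, 300L),
                                    side = c("N_propeptide",
                                             "C_propeptide"))),
    "crossing")
})

test_that("cleavage-site frequency matrices are column-stochastic with pure P1", {
  prots <- protein_records(
    c("a", "b", "c"),
    c(gp75_synthetic(), gp245_synthetic(), gp47_synthetic()))
  sites <- tibble::tibble(
    protein_id = c("a", "b", "b", "b", "c", "c"),
    p1_pos = c(130L, 203L, 234L, 246L, 79L, 111L))
  pfm <- build_pfm(sites, prots)
  expect_equal(unname(colSums(pfm$pfm)), rep(1, 7), tolerance = 1e-9)
  expect_equal(unname(pfm$pfm["E", "P1"]), 1)
  expect_equal(unname(pfm$pfm["A", "P3"]), 1)
  expect_true(all(pfm$information >= 0, na.rm = TRUE))

  one <- build_pfm(sites[1, ], prots)
  expect_true(all(apply(one$counts, 2, max) == 1))

  expect_error(build_pfm(sites[0, ], prots), "empty")
})

test_that("planted uniform P2 residues recover a near-uniform P2 column", {
  set.seed(53)
  n_sites <- 50
  ids <- sprintf("u%02d", seq_len(n_sites))
  aa20 <- rownames(build_pfm(tibble::tibble(protein_id = "x", p1_pos = 50L),
                             protein_records("x", filler_protein(100)))$pfm)
  p2 <- sample(aa20, n_sites, replace = TRUE)
  seqs <- vapply(seq_len(n_sites), function(i) {
    plant_trimer(filler_protein(120), 60L, paste0("A", p2[i], "E"))
  }, character(1))
  prots <- protein_records(ids, seqs)
  pfm <- build_pfm(tibble::tibble(protein_id = ids, p1_pos = 60L), prots)
  # frequency-count oracle
  expect_equal(as.integer(pfm$counts[, "P2"]),
               as.integer(table(factor(p2, levels = aa20))))
  expect_lte(max(pfm$pfm[, "P2"]), 0.25)
})
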