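test_that("identification-quality filters drop weak peptides and proteins", {
  expect_warning(out <- apply_filters(obs_row("x", "PEPK", 1, 4)[0, ]),
                 "empty")
  expect_equal(nrow(out), 0)

  # a protein with only two distinct peptides is removed at the default
  # minimum of three
  rep2 <- dplyr::bind_rows(
    obs_row("two", c("AAAK", "CCCK"), c(1, 10), c(4, 13)),
    obs_row("three", c("DDDK", "FFFK", "GGGK"), c(1, 10, 20),
            c(4, 13, 23)))
  kept <- apply_filters(rep2)
  expect_equal(unique(kept$protein_id), "three")

  # hand-enumerated survivor set over planted sub-threshold entries
  planted <- dplyr::bind_rows(
    obs_row("ok", c("AK", "CK", "DK"), c(1, 5, 9), c(2, 6, 10)),
    obs_row("lowpep", c("EK", "FK", "GK"), c(1, 5, 9), c(2, 6, 10),
            peptide_prob = c(0.5, 0.99, 0.99)),
    obs_row("lowprot", c("HK", "IK", "LK"), c(1, 5, 9), c(2, 6, 10),
            protein_prob = 0.9))
  surv <- apply_filters(planted)
  expect_setequal(unique(surv$protein_id), "ok")
  expect_equal(nrow(surv), 3)
})

test_that("tightening any filter threshold never adds a protein", {
  set.seed(61)
  rep <- obs_row(sample(sprintf("p%d", 1:8), 60, replace = TRUE),
                 sprintf("PEP%02dK", 1:60), 1:60, 5:64,
                 peptide_prob = runif(60, 0.5, 1),
                 protein_prob = rep(runif(8, 0.9, 1),
                                    length.out = 60)[order(runif(60))])
  rep$protein_prob <- ave(rep$peptide_prob, rep$protein_id, FUN = max)
  base <- filter_config(0.8, 0.9, 2)
  loose <- suppressWarnings(apply_filters(rep, base))
  for (cfg in list(filter_config(0.95, 0.9, 2),
                   filter_config(0.8, 0.99, 2),
                   filter_config(0.8, 0.9, 4))) {
    tight <- suppressWarnings(apply_filters(rep, cfg))
    expect_true(all(unique(tight$protein_id) %in%
                      unique(loose$protein_id)))
    expect_lte(nrow(tight), nrow(loose))
  }
})

test_that("SC/M is the exact mass-normalized quotient with 2-decimal reporting", {
  expect_equal(scm_report(1592, 83.9), 18.97)
  expect_equal(scm_report(1592, 70.4), 22.61)
  expect_equal(scm_report(662, 31.5), 21.02)
  expect_equal(scm_report(643, 31.9), 20.16)
  expect_equal(scm(0, 55.5), 0)
  expect_equal(scm(100, 50), 2)
  expect_error(scm(10, 0), "positive")
})

test_that("peak slice is the argmax with deterministic tie handling", {
  expect_equal(peak_slice(c(`4` = 12))$slice, 4L)
  p <- peak_slice(c(`3` = 10, `5` = 10, `4` = 2))
  expect_equal(p$slice, 3L)
  expect_true(p$tie)
  z <- peak_slice(c(`1` = 0, `2` = 0))
  expect_true(is.na(z$slice))
  expect_true(z$all_zero)
  expect_error(peak_slice(numeric(0)), "empty")
})

test_that("gel consistency is mass-window membership with tolerance", {
  gel <- gel_model(1:3, c(10, 30, 60), c(30, 60, 100))
  expect_equal(gel_consistency(45, 2L, gel), "consistent")
  expect_equal(gel_consistency(20, 3L, gel), "inconsistent")
  expect_equal(gel_consistency(72.3, 3L, gel), "consistent")
  expect_equal(gel_consistency(50, 9L, gel), "untestable")
  # tolerance widens the window fractionally
  expect_equal(gel_consistency(63, 2L, gel, tolerance = 0.05), "consistent")
  expect_equal(gel_consistency(63, 2L, gel, tolerance = 0), "inconsistent")
})

test_that("copy calibration uses the median reference ratio", {
  recs <- tibble::tibble(protein_id = c("r1", "r2", "q"),
                         scm = c(10, 1, 2))
  refs <- tibble::tibble(protein_id = c("r1", "r2"),
                         known_copies = c(1000, 100))
  cal <- calibrate_copies(recs, refs)
  expect_equal(cal$k, 100)
  expect_equal(cal$estimates$copy_estimate[3], 200)

  # single reference: a query with the same SC/M lands exactly on the
  # reference copy number
  one <- calibrate_copies(
    tibble::tibble(protein_id = c("mcp", "q"), scm = c(22.61, 22.61)),
    tibble::tibble(protein_id = "mcp", known_copies = 1560))
  expect_equal(one$estimates$copy_estimate[2], 1560)

  # head-ejection protein calibrated on the major capsid protein: the
  # estimate clears the conservative lower bound of 600 copies
  mcp_scm <- 1592 / 70.4
  gp53_scm <- 662 / 31.5
  est <- calibrate_copies(
    tibble::tibble(protein_id = c("gp75", "gp53"),
                   scm = c(mcp_scm, gp53_scm)),
    tibble::tibble(protein_id = "gp75", known_copies = 1560))
  expect_equal(est$estimates$copy_estimate[2], 1450, tolerance = 0.01)
  expect_gt(est$estimates$copy_estimate[2], 600)

  expect_error(calibrate_copies(recs[3, ], refs), "no reference")
})

test_that("presence/absence comparison is an ordered set difference", {
  expect_equal(compare_proteomes(c("gp1", "gp2"), c("gp2", "gp1")),
               list(missing = character(0), gained = character(0)))
  ref <- sprintf("gp%d", c(1, 5, 10, 42, 218))
  cmp <- compare_proteomes(ref, setdiff(ref, c("gp42", "gp5", "gp218")))
  expect_equal(cmp$missing, c("gp5", "gp42", "gp218"))
  expect_equal(cmp$gained, character(0))
  cmp2 <- compare_proteomes(ref, c(ref, "gp99"))
  expect_equal(cmp2$gained, "gp99")
})

test_that("processed-mass SC/M never falls below precursor SC/M", {
  s <- gp75_synthetic()
  prot <- protein_records("gp75s", s)
  obs <- dplyr::bind_rows(
    obs_row("gp75s", substr(s, 131, 136), 131, 136, spectral_count = 5),
    obs_row("gp75s", substr(s, 137, 144), 137, 144, spectral_count = 3),
    obs_row("gp75s", substr(s, 145, 152), 145, 152, spectral_count = 2))
  cls <- classify_report(obs, prot)
  forms <- tibble::tibble(protein_id = "gp75s", start_res = 131L,
                          end_res = nchar(s),
                          mass_kda = average_mass(substr(s, 131,
                                                         nchar(s))) / 1000,
                          status = "observed")
  tab <- abundance_table(cls, prot, mature_forms = forms)
  expect_gte(tab$scm_processed, tab$scm)
  expect_equal(tab$scm_basis, "processed")
  expect_equal(tab$total_sc, 10L)
})
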