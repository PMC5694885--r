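# Deterministic stand-in proteins built from a filler alphabet that contains
# neither A nor E, so the only cleavage-motif occurrences are the ones we
# plant. The trailing K of each filler unit provides regular tryptic sites.
# Stand-ins mimic the coordinates of published processing events (their
# residue content, and hence their masses, are synthetic).

filler_protein <- function(n, unit = "GSTLNVQK") {
  s <- strrep(unit, ceiling(n / nchar(unit)))
  s <- substr(s, 1, n)
  substr(s, 1, 1) <- "M"
  s
}

plant_trimer <- function(seq, p1, trimer) {
  stopifnot(nchar(trimer) == 3, p1 >= 3, p1 <= nchar(seq))
  substr(seq, p1 - 2L, p1) <- trimer
  seq
}

# major-capsid-like stand-in: maturation cut ATE-130
gp75_synthetic <- function() plant_trimer(filler_protein(754), 130L, "ATE")

# protease-like stand-in: C-terminal autocleavage candidates
# AQE-203, ATE-234, AQE-246 in a 263-residue chain
gp245_synthetic <- function() {
  s <- filler_protein(263)
  s <- plant_trimer(s, 203L, "AQE")
  s <- plant_trimer(s, 234L, "ATE")
  plant_trimer(s, 246L, "AQE")
}

# ejection-protein-like stand-in: observed cut AVE-79, motif-conforming
# maturation candidate ALE-111, coverage beginning at residue 119
gp47_synthetic <- function() {
  s <- filler_protein(565)
  s <- plant_trimer(s, 79L, "AVE")
  plant_trimer(s, 111L, "ALE")
}

# portal-like stand-in: observed propeptide sub-cut ATE-161, inferred
# maturation cut AQE-254
gp81_synthetic <- function() {
  s <- filler_protein(905)
  s <- plant_trimer(s, 161L, "ATE")
  plant_trimer(s, 254L, "AQE")
}

random_protein <- function(n) {
  paste(c("M", sample(c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N",
                        "D", "Q", "K", "E", "M", "H", "F", "R", "Y", "W"),
                      n - 1L, replace = TRUE)), collapse = "")
}

# independent digest oracle: test every substring (i, j) directly against
# regex-located cut positions
brute_digest <- function(sequence, max_missed, proline_rule = TRUE) {
  n <- nchar(sequence)
  pat <- if (proline_rule) "[KR](?!P)" else "[KR]"
  cuts <- gregexpr(pat, sequence, perl = TRUE)[[1]]
  cuts <- as.integer(cuts[cuts > 0 & cuts < n])
  is_cut <- rep(FALSE, n)
  is_cut[cuts] <- TRUE
  cum <- cumsum(is_cut)
  grid <- expand.grid(i = seq_len(n), j = seq_len(n))
  grid <- grid[grid$i <= grid$j, ]
  left_ok <- grid$i == 1L | is_cut[pmax(grid$i - 1L, 1L)]
  right_ok <- grid$j == n | is_cut[grid$j]
  upto_j <- cum[pmax(grid$j - 1L, 1L)]
  upto_j[grid$j == 1L] <- 0L
  before_i <- cum[pmax(grid$i - 1L, 1L)]
  before_i[grid$i == 1L] <- 0L
  internal <- upto_j - before_i
  internal[grid$j == grid$i] <- 0L
  keep <- left_ok & right_ok & internal <= max_missed
  out <- grid[keep, ]
  out <- out[order(out$i, out$j), ]
  tibble::tibble(start_res = out$i, end_res = out$j,
                 peptide = substring(sequence, out$i, out$j))
}

# independent motif-scan oracle: direct position-by-position substring check
brute_scan <- function(sequence, p3_set, p1 = "E") {
  hits <- integer(0)
  for (p in 3:nchar(sequence)) {
    if (substr(sequence, p, p) == p1 &&
        substr(sequence, p - 2, p - 2) %in% p3_set) {
      hits <- c(hits, p)
    }
  }
  hits
}

# minimal peptide-report row constructor
obs_row <- function(protein_id, peptide, start_res, end_res,
                    spectral_count = 1L, slice_index = 1L,
                    peptide_prob = 0.99, protein_prob = 0.9999) {
  tibble::tibble(protein_id = protein_id, peptide = peptide,
                 start_res = as.integer(start_res),
                 end_res = as.integer(end_res),
                 spectral_count = as.integer(spectral_count),
                 slice_index = as.integer(slice_index),
                 peptide_prob = peptide_prob, protein_prob = protein_prob)
}
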