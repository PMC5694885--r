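test_that("protein records validate the residue alphabet", {
  expect_error(protein_records("p1", "MABZ"), "p1")
  recs <- protein_records(c("a", "b"), c("MKLV", "MGGR"))
  expect_equal(nrow(recs), 2)
  expect_warning(
    protein_records("p1", "MKLV", gene_start = 1L, gene_end = 12L,
                    strand = "+"),
    "CDS span")
  expect_silent(protein_records("p1", "MKLV", gene_start = 1L,
                                gene_end = 15L, strand = "+"))
})

test_that("FASTA round-trips through protein records", {
  path <- withr::local_tempfile(fileext = ".fasta")
  recs <- protein_records(c("gpA", "gpB"), c("MKLVNNR", "MGGRSTV"))
  write_protein_fasta(recs, path)
  back <- read_protein_fasta(path)
  expect_equal(back$id, recs$id)
  expect_equal(back$sequence, recs$sequence)
})

test_that("CDS translation strips the stop and flags internal stops", {
  g <- genome_record("g", "ATGGCTTAA")
  expect_equal(translate_cds(g, 1, 9, "+"), "MA")
  expect_error(translate_cds(g, 1, 8, "+"), "divisible by 3")
  g2 <- genome_record("g2", "ATGTAAGCTTAA")
  expect_error(translate_cds(g2, 1, 12, "+"), "codon index 2")
})

test_that("minus-strand translation equals plus-strand translation of the mirrored span", {
  set.seed(11)
  bases <- c("A", "C", "G", "T")
  n_checked <- 0
  for (k in 1:40) {
    L <- 90L
    nt <- paste(sample(bases, L, replace = TRUE), collapse = "")
    s <- sample(seq(1, L - 30, by = 1), 1)
    e <- s + 3L * sample(4:9, 1) - 1L
    if (e > L) next
    g <- genome_record("g", nt)
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(nt)))
    g_rc <- genome_record("grc", rc)
    minus <- tryCatch(translate_cds(g, s, e, "-"), error = function(e) NULL)
    plus <- tryCatch(translate_cds(g_rc, L - e + 1L, L - s + 1L, "+"),
                     error = function(e) NULL)
    if (is.null(minus) || is.null(plus)) next  # internal stop drawn
    expect_equal(minus, plus)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 5)
})

test_that("upstream-mapping peptides reassign the start to an in-frame ATG", {
  # gene with a planted in-frame ATG six codons upstream of the annotated
  # start; a peptide spanning the old start must move it back 18 nt
  up6 <- "ATGAAATTTGGGCCCAAA"            # M K F G P K
  cds <- "ATGTCTCTGGTTAACAAA"            # M S L V N K
  genome <- genome_record("g", paste0("GGGGG", up6, cds, "TAAGG"))
  prot <- protein_records("p", "MSLVNK", gene_start = 24L, gene_end = 44L,
                          strand = "+")

  inside <- reassign_start(genome, prot, "SLVNK")
  expect_equal(inside$status, "unchanged")

  r <- reassign_start(genome, prot, "KFGPKMSLVNK", max_extension_codons = 10L)
  expect_equal(r$status, "reassigned")
  expect_equal(r$gene_start, 24L - 18L)
  # brute-force oracle: the chosen start is the nearest in-frame ATG at or
  # upstream of the peptide's first codon
  expect_equal((24L - r$gene_start) %% 3L, 0L)
  expect_equal(substr(genome$sequence, r$gene_start, r$gene_start + 2L),
               "ATG")

  # N-terminal Met excision: peptide begins at codon 2 of the extended ORF
  nme <- reassign_start(genome, prot, "KFGPKMSLVNK")
  expect_equal(nme$extension_codons, 6L)
})

test_that("start reassignment reports unreachable or broken frames", {
  genome <- genome_record("g", paste0("CCCCCCCCCCCCCCCCCC",
                                      "ATGTCTCTGGTTAACAAA", "TAA"))
  prot <- protein_records("p", "MSLVNK", gene_start = 19L, gene_end = 39L,
                          strand = "+")
  none <- reassign_start(genome, prot, "PPPMSLVNK",
                         max_extension_codons = 5L)
  expect_equal(none$status, "no-start-found")

  # extension contains an in-frame stop between the candidate ATG and the
  # annotated start
  genome2 <- genome_record("g", paste0("ATGAAATAAGGGCCCAAA",
                                       "ATGTCTCTGGTTAACAAA", "TAA"))
  prot2 <- protein_records("p", "MSLVNK", gene_start = 19L, gene_end = 39L,
                           strand = "+")
  r2 <- reassign_start(genome2, prot2, "KXGPKMSLVNK")
  expect_true(r2$status %in% c("no-start-found", "broken-frame"))
  r3 <- reassign_start(genome2, prot2, "GPKMSLVNK")
  expect_equal(r3$status, "broken-frame")
})
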