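#' Construct a table of protein records
#'
#' The central sequence container of the package: one row per protein, with
#' optional genomic provenance (CDS coordinates on a source genome) and known
#' per-virion stoichiometry for calibration references. Residue coordinates
#' used throughout the package are 1-based and inclusive, so a site label
#' like "ATE-130" means the motif ends at residue 130 and cleavage occurs
#' after it. Genomic coordinates are 1-based inclusive as in GenBank.
#'
#' @param id Character vector of protein identifiers (e.g. `"gp75"`).
#' @param sequence Amino-acid sequences (20 standard one-letter codes;
#'   `X` tolerated when `tolerate_x = TRUE`).
#' @param gene_start,gene_end Optional genomic CDS coordinates (1-based,
#'   inclusive, including the stop codon).
#' @param strand Optional `"+"`/`"-"` per protein.
#' @param known_copies Optional known copies per virion (calibration refs).
#' @param annotation Optional free-text tag (e.g. `"MCP"`, `"portal"`).
#' @param tolerate_x Allow `X` in sequences.
#' @return A tibble with one row per protein.
#' @export
protein_records <- function(id, sequence, gene_start = NA_integer_,
                            gene_end = NA_integer_, strand = NA_character_,
                            known_copies = NA_integer_,
                            annotation = NA_character_, tolerate_x = FALSE) {
  stopifnot(length(id) == length(sequence))
  sequence <- toupper(sequence)
  alphabet <- paste0("^[", paste(names(.AA_AVERAGE), collapse = ""),
                     if (tolerate_x) "X", "]+$")
  ok <- grepl(alphabet, sequence)
  if (!all(ok)) {
    stop("invalid residues in sequence(s): ",
         paste(id[!ok], collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    id = as.character(id), sequence = sequence,
    gene_start = as.integer(gene_start), gene_end = as.integer(gene_end),
    strand = as.character(strand), known_copies = as.integer(known_copies),
    annotation = as.character(annotation)
  )
  has_coord <- !is.na(out$gene_start) & !is.na(out$gene_end)
  span <- out$gene_end[has_coord] - out$gene_start[has_coord] + 1L
  bad <- span != 3L * (nchar(out$sequence[has_coord]) + 1L)
  if (any(bad)) {
    warning("CDS span does not equal 3*(protein length + 1) for: ",
            paste(out$id[has_coord][bad], collapse = ", "), call. = FALSE)
  }
  out
}

#' Construct a genome record
#'
#' @param id Genome identifier.
#' @param sequence Nucleotide sequence (alphabet `ACGTN`).
#' @return A list with elements `id` and `sequence`.
#' @export
genome_record <- function(id, sequence) {
  sequence <- toupper(sequence)
  if (!grepl("^[ACGTN]*$", sequence)) {
    stop("genome sequence contains characters outside ACGTN", call. = FALSE)
  }
  list(id = as.character(id), sequence = sequence)
}

#' Read and write protein FASTA
#'
#' Thin wrappers over [Biostrings::readAAStringSet()] and
#' [Biostrings::writeXStringSet()] that move between FASTA files and the
#' package's protein-record tibble. The FASTA identifier is the first
#' whitespace-delimited token of the header.
#'
#' @param path File path.
#' @param tolerate_x Allow `X` residues.
#' @return `read_protein_fasta()` returns a protein-record tibble.
#' @export
read_protein_fasta <- function(path, tolerate_x = FALSE) {
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  protein_records(id = ids, sequence = unname(as.character(set)),
                  tolerate_x = tolerate_x)
}

#' @rdname read_protein_fasta
#' @param proteins Protein-record tibble.
#' @export
write_protein_fasta <- function(proteins, path) {
  set <- Biostrings::AAStringSet(stats::setNames(proteins$sequence,
                                                 proteins$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a genome FASTA (first record)
#'
#' @param path File path.
#' @return A genome record (see [genome_record()]).
#' @export
read_genome_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  genome_record(id = sub("\\s.*$", "", names(set)[1]),
                sequence = as.character(set[[1]]))
}

#' Read GFF-lite CDS coordinates
#'
#' A four-column TSV (`id`, `start`, `end`, `strand`) giving CDS spans on the
#' source genome; enough provenance for translation and start-site
#' reassignment without a full GFF3 parser.
#'
#' @param path File path.
#' @return Tibble with columns `id`, `start`, `end`, `strand`.
#' @export
read_gff_lite <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(), start = readr::col_integer(),
    end = readr::col_integer(), strand = readr::col_character()
  ))
}

#' Translate a CDS span of a genome
#'
#' Standard-code translation of a genomic span. The terminal stop codon, if
#' present, is stripped; an internal stop is an error naming the offending
#' codon index. A non-ATG initiator is translated as Met only when
#' `alt_start = TRUE`.
#'
#' @param genome A genome record (see [genome_record()]).
#' @param start,end 1-based inclusive nucleotide positions; span length must
#'   be divisible by 3.
#' @param strand `"+"` or `"-"`. For `"-"`, the span is reverse-complemented
#'   before translation (coordinates still refer to the `+` strand).
#' @param alt_start Translate a non-ATG first codon as `M`.
#' @return Amino-acid string.
#' @export
translate_cds <- function(genome, start, end, strand = "+",
                          alt_start = FALSE) {
  stopifnot(start >= 1, end <= nchar(genome$sequence), start <= end)
  if ((end - start + 1L) %% 3L != 0L) {
    stop("CDS span length not divisible by 3", call. = FALSE)
  }
  nt <- substr(genome$sequence, start, end)
  if (strand == "-") {
    nt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                           if.fuzzy.codon = "X"))
  if (alt_start && substr(aa, 1, 1) != "M") {
    substr(aa, 1, 1) <- "M"
  }
  # strip one terminal stop; any remaining stop is internal
  aa <- sub("\\*$", "", aa)
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0) {
    stop("internal stop codon at codon index ", stop_at, call. = FALSE)
  }
  aa
}

#' Reassign a gene start from an upstream-mapping peptide
#'
#' A peptide whose residues translate in-frame upstream of a gene's annotated
#' start codon is proteogenomic evidence that the true start lies further 5'.
#' This operation scans in-frame codons upstream of the annotated start
#' (up to `max_extension_codons`), finds where the peptide translates exactly,
#' and proposes the nearest in-frame ATG at or immediately upstream of the
#' peptide's first residue. The peptide may begin at codon 2 of the proposed
#' ORF, accounting for N-terminal Met excision by the host methionine
#' aminopeptidase.
#'
#' @param genome Genome record.
#' @param protein One protein record row with `gene_start`, `gene_end`,
#'   `strand` set.
#' @param peptide Observed peptide sequence (string), or a peptide
#'   observation row with a `peptide` column.
#' @param max_extension_codons Search bound upstream of the annotated start.
#' @return A list with `status` (`"reassigned"`, `"unchanged"`,
#'   `"no-start-found"`, or `"broken-frame"`), the proposed `gene_start` and
#'   `gene_end`, and `extension_codons` (0 when unchanged).
#' @export
reassign_start <- function(genome, protein, peptide,
                           max_extension_codons = 30L) {
  if (is.list(peptide) && !is.null(peptide$peptide)) peptide <- peptide$peptide
  stopifnot(is.character(peptide), length(peptide) == 1)
  s0 <- protein$gene_start
  e0 <- protein$gene_end
  strand <- protein$strand
  if (is.na(s0) || is.na(e0) || is.na(strand)) {
    stop("protein record lacks genomic coordinates", call. = FALSE)
  }
  unchanged <- list(status = "unchanged", gene_start = s0, gene_end = e0,
                    extension_codons = 0L)
  if (grepl(peptide, protein$sequence, fixed = TRUE)) {
    return(unchanged)
  }

  # translate up to max_extension_codons in-frame codons upstream of the
  # annotated start (protein 5' direction); index 1 = furthest upstream
  n_ext <- max_extension_codons
  ext_aa <- character(0)
  for (k in n_ext:1) {
    if (strand == "+") {
      a <- s0 - 3L * k
      if (a < 1) next
      codon <- substr(genome$sequence, a, a + 2L)
    } else {
      b <- e0 + 3L * k
      if (b > nchar(genome$sequence)) next
      codon <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(substr(genome$sequence, b - 2L, b))))
    }
    ext_aa <- c(ext_aa, as.character(
      Biostrings::translate(Biostrings::DNAString(codon),
                            no.init.codon = TRUE, if.fuzzy.codon = "X")))
  }
  n_ext <- length(ext_aa)
  full <- paste0(paste(ext_aa, collapse = ""), protein$sequence)

  hits <- gregexpr(peptide, full, fixed = TRUE)[[1]]
  hits <- hits[hits > 0 & hits <= n_ext]
  if (length(hits) == 0) {
    return(list(status = "no-start-found", gene_start = s0, gene_end = e0,
                extension_codons = NA_integer_))
  }
  i <- max(hits)  # nearest occurrence to the annotated start
  j <- NA_integer_
  for (cand in i:1) {
    if (ext_aa[cand] == "M") { j <- cand; break }
  }
  if (is.na(j)) {
    return(list(status = "no-start-found", gene_start = s0, gene_end = e0,
                extension_codons = NA_integer_))
  }
  if (any(ext_aa[j:n_ext] == "*")) {
    return(list(status = "broken-frame", gene_start = s0, gene_end = e0,
                extension_codons = NA_integer_))
  }
  ext <- n_ext - j + 1L
  if (strand == "+") {
    list(status = "reassigned", gene_start = s0 - 3L * ext, gene_end = e0,
         extension_codons = ext)
  } else {
    list(status = "reassigned", gene_start = s0, gene_end = e0 + 3L * ext,
         extension_codons = ext)
  }
}
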