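# Six-frame ORF extraction with coordinate bookkeeping between peptide space
# and forward-strand DNA coordinates (0-based, half-open).

#' Six-frame ORF extraction
#'
#' ORFs are stop-to-stop peptide segments (no start-codon requirement;
#' sequence ends act as boundaries) in all six frames; segments shorter than
#' `config$min_peptide_len` are dropped.  Coordinates are always reported on
#' the forward strand.
#'
#' @param dna DNA string over ACGTN, or a one-row tibble from [read_fasta()].
#' @param code An `fh_genetic_code`.
#' @param config An `fh_config` (uses `min_peptide_len`, `both_strands`).
#' @param target_id Id recorded on the ORFs (taken from the tibble if given).
#' @return A tibble with columns `target_id`, `strand`, `frame`, `dna_start`,
#'   `dna_end`, `peptide`; `(dna_end - dna_start) == 3 * nchar(peptide)`.
#' @export
six_frame_orfs <- function(dna, code = genetic_code(1),
                           config = search_config(), target_id = "target") {
  if (is.data.frame(dna)) {
    target_id <- dna$id[1]
    dna <- dna$seq[1]
  }
  six_frame_orfs_batch(setNames(dna, target_id), code, config)
}

#' Six-frame ORF extraction for many targets at once
#'
#' @param seqs Named character vector of DNA strings (names become
#'   `target_id`s).
#' @inheritParams six_frame_orfs
#' @return As [six_frame_orfs()], rows over all targets.
#' @export
six_frame_orfs_batch <- function(seqs, code = genetic_code(1),
                                 config = search_config()) {
  aa64 <- paste(c("*", AA_ALPHABET)[codon_aa_indices(code) + 1L],
                collapse = "")
  res <- cpp_six_frame_orfs(unname(toupper(seqs)), config$min_peptide_len,
                            aa64, config$both_strands)
  tibble(target_id = names(seqs)[res$seq_index],
         strand = res$strand, frame = res$frame,
         dna_start = res$dna_start, dna_end = res$dna_end,
         peptide = res$peptide)
}

#' Map a peptide sub-span of an ORF back to DNA coordinates
#'
#' @param orf One ORF (a one-row tibble/list with `strand`, `dna_start`,
#'   `dna_end`, `peptide`).
#' @param aa_from,aa_to 0-based half-open amino-acid span within the peptide.
#' @return `c(nt_from, nt_to)`: forward-strand, 0-based half-open.
#' @export
peptide_span_to_dna <- function(orf, aa_from, aa_to) {
  np <- nchar(orf$peptide)
  if (!(aa_from >= 0 && aa_from < aa_to && aa_to <= np)) {
    stop("peptide_span_to_dna: aa span out of range")
  }
  if (orf$strand == "+") {
    c(orf$dna_start + 3 * aa_from, orf$dna_start + 3 * aa_to)
  } else {
    c(orf$dna_end - 3 * aa_to, orf$dna_end - 3 * aa_from)
  }
}
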