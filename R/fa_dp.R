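# R-level interface to the dynamic-programming engines: protein-space
# MSV/Viterbi/Forward and the frameshift-aware codon-space engines.

dp_pack_protein <- function(profile) {
  M <- profile$M
  bg <- profile$background
  lme <- log(profile$match_emissions) - matrix(log(bg), M, 20, byrow = TRUE)
  lie <- log(profile$insert_emissions) - matrix(log(bg), M, 20, byrow = TRUE)
  ltr <- log(profile$transitions)
  k <- seq_len(M)
  lentry <- log(2 * (M - k + 1) / (M * (M + 1)))
  list(M = M, lme = lme, lie = lie, ltr = ltr, lentry = lentry)
}

dp_pack_codon <- function(cp) {
  if (!is.null(cp$pack)) return(cp$pack)
  p <- cp$parent
  M <- p$M
  k <- seq_len(M)
  pen <- cp$penalties
  qsets <- quasi_candidate_sets(cp$code)
  qcand <- list(); qcand_off <- list()
  for (L in c("1", "2", "4", "5")) {
    sets <- qsets[[L]]
    qcand[[L]] <- as.integer(unlist(sets))
    qcand_off[[L]] <- as.integer(c(0, cumsum(lengths(sets))))
  }
  stop_sets <- lapply(cp$stop_codons, stop_neighbor_aas, code = cp$code)
  list(M = M, S = length(cp$stop_codons),
       ltr = log(p$transitions),
       lentry = log(2 * (M - k + 1) / (M * (M + 1))),
       lbg = log(cp$dna_background),
       lsense_m = cp$match$lsense, lstop_m = cp$match$lstop,
       lq1_m = cp$match$lquasi[["1"]], lq2_m = cp$match$lquasi[["2"]],
       lq4_m = cp$match$lquasi[["4"]], lq5_m = cp$match$lquasi[["5"]],
       lsense_i = cp$insert$lsense, lstop_i = cp$insert$lstop,
       aa_of_codon = cp$aa_of_codon, stop_index = cp$stop_index,
       me = p$match_emissions, ie = p$insert_emissions,
       lnsyn = log(cp$n_syn),
       lZq_m = cp$match$lZ, lZq_i = cp$insert$lZ,
       lnorm = log(pen$norm), lpstop = log(pen$p_stop),
       lpen = log(c(pen$p1, pen$p2, pen$p4, pen$p5)),
       qcand = unname(qcand), qcand_off = unname(qcand_off),
       stop_cand = as.integer(unlist(stop_sets)),
       stop_cand_off = as.integer(c(0, cumsum(lengths(stop_sets)))))
}

encode_peptides <- function(peptides) {
  chars <- strsplit(toupper(peptides), "", fixed = TRUE)
  idx <- lapply(chars, function(ch) {
    v <- match(ch, AA_ALPHABET) - 1L
    v[is.na(v)] <- -1L  # X and other ambiguity: neutral
    v
  })
  list(concat = as.integer(unlist(idx)),
       offsets = as.integer(c(0, cumsum(lengths(idx)))))
}

# subset an encoded peptide set by indices
subset_enc <- function(enc, idx) {
  lens <- diff(enc$offsets)
  pieces <- lapply(idx, function(i) {
    if (lens[i] == 0) integer(0)
    else enc$concat[(enc$offsets[i] + 1):enc$offsets[i + 1]]
  })
  list(concat = as.integer(unlist(pieces)),
       offsets = as.integer(c(0, cumsum(lens[idx]))))
}

protein_scores_enc <- function(profile, enc, algo) {
  cpp_protein_scores(dp_pack_protein(profile), enc$concat, enc$offsets, algo)
}

encode_window <- function(window) {
  v <- encode_dna(window)
  v[is.na(v)] <- -1L
  as.integer(v)
}

#' MSV filter score
#'
#' Multiple-ungapped-segment score of peptides against a profile: match
#' emissions only, uniform local entry, free exit, multihit specials.
#'
#' @param profile An `fh_profile`.
#' @param peptides Character vector of peptides.
#' @return Bit scores (one per peptide; `-Inf` for empty peptides).
#' @export
msv_score <- function(profile, peptides) {
  enc <- encode_peptides(peptides)
  cpp_protein_scores(dp_pack_protein(profile), enc$concat, enc$offsets, 0L)
}

#' Gapped Viterbi score (protein space)
#'
#' @inheritParams msv_score
#' @return Bit scores of the maximum-probability local multihit alignment.
#' @export
viterbi_score_protein <- function(profile, peptides) {
  enc <- encode_peptides(peptides)
  cpp_protein_scores(dp_pack_protein(profile), enc$concat, enc$offsets, 1L)
}

#' Forward score (protein space)
#'
#' @inheritParams msv_score
#' @return Bit scores summing over all local multihit alignments.
#' @export
forward_protein <- function(profile, peptides) {
  enc <- encode_peptides(peptides)
  cpp_protein_scores(dp_pack_protein(profile), enc$concat, enc$offsets, 2L)
}

# forward/backward/posterior decode of one peptide
protein_decode <- function(profile, peptide) {
  enc <- encode_peptides(peptide)[["concat"]]
  cpp_protein_engine(dp_pack_protein(profile), enc)
}

# Viterbi alignment path of one peptide; returns list(bits, path tibble)
protein_viterbi_path <- function(profile, peptide) {
  enc <- encode_peptides(peptide)[["concat"]]
  res <- cpp_protein_viterbi_path(dp_pack_protein(profile), enc)
  path <- as_tibble(as.data.frame(res$path))
  path$kind <- c("M", "I", "D")[path$kind + 1]
  list(bits = res$vit_bits, path = path)
}

#' Build the emission cache for a window
#'
#' Decodes every (end position, consumed length) chunk of a DNA window once:
#' for length-3 chunks the encoded amino acid (or stop codon) and for
#' quasi-codon lengths the completion candidate set, together with the
#' background log-probability of the consumed nucleotides.  The frameshift-
#' aware engines rebuild exactly this table internally and reuse it across
#' Forward, Backward, posterior decoding, and Viterbi.
#'
#' @param window_dna DNA string over ACGTN.
#' @param codon_profile An `fh_codon_profile`.
#' @return A tibble with one row per (j, len) chunk: `j` (1-based end), `len`,
#'   `class` (`sense`, `stop`, `quasi`, `neutral`), `aa` (encoded amino acid
#'   for sense codons), `stop` (stop codon string), `candidates` (list column
#'   of completion amino acids), `lbg` (background log-probability).
#' @export
build_emission_cache <- function(window_dna, codon_profile) {
  v <- encode_window(window_dna)
  n <- length(v)
  code <- codon_profile$code
  qsets <- quasi_candidate_sets(code)
  lbg_nt <- log(codon_profile$dna_background)
  rows <- list()
  for (j in seq_len(n)) {
    for (len in 1:5) {
      if (len > j) next
      chunk <- v[(j - len + 1):j]
      if (any(chunk < 0)) {
        rows[[length(rows) + 1]] <- list(j = j, len = len, class = "neutral",
                                         aa = NA_character_, stop = NA_character_,
                                         candidates = list(character()), lbg = 0)
        next
      }
      lbg <- sum(lbg_nt[chunk + 1])
      if (len == 3) {
        ci <- chunk[1] * 16L + chunk[2] * 4L + chunk[3] + 1L
        aa <- codon_profile$aa_of_codon[ci]
        if (aa == 0) {
          rows[[length(rows) + 1]] <- list(j = j, len = len, class = "stop",
                                           aa = NA_character_,
                                           stop = paste(NT_ALPHABET[chunk + 1], collapse = ""),
                                           candidates = list(character()), lbg = lbg)
        } else {
          rows[[length(rows) + 1]] <- list(j = j, len = len, class = "sense",
                                           aa = AA_ALPHABET[aa], stop = NA_character_,
                                           candidates = list(character()), lbg = lbg)
        }
      } else {
        qidx <- sum(chunk * 4^((len - 1):0)) + 1L
        cand <- qsets[[as.character(len)]][[qidx]]
        rows[[length(rows) + 1]] <- list(j = j, len = len, class = "quasi",
                                         aa = NA_character_, stop = NA_character_,
                                         candidates = list(AA_ALPHABET[cand]), lbg = lbg)
      }
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    tibble(j = r$j, len = r$len, class = r$class, aa = r$aa, stop = r$stop,
           candidates = r$candidates, lbg = r$lbg)
  }))
  out
}

#' Frameshift-aware Forward score
#'
#' Forward algorithm over the codon profile: match states consume 1-5 nt
#' (codon, stop codon, or quasi-codon), inserts exactly 3, deletes none;
#' N/C/J flank states consume single nucleotides at null frequency.  The
#' score is log-odds in bits against an i.i.d. nucleotide background with
#' geometric length correction.
#'
#' @param codon_profile An `fh_codon_profile`.
#' @param window DNA string over ACGTN (strand-oriented).
#' @param use_cache Use the per-window emission memoization (the default);
#'   `FALSE` recomputes every emission per DP cell (bit-identical, slower).
#' @return Bit score, with attribute `n_decodes` counting chunk decodes.
#' @export
fa_forward <- function(codon_profile, window, use_cache = TRUE) {
  res <- cpp_fa_engine(dp_pack_codon(codon_profile), encode_window(window),
                       use_cache, FALSE, FALSE, FALSE)
  structure(res$fwd_bits, n_decodes = res$n_decodes)
}

#' Frameshift-aware Backward score
#'
#' @inheritParams fa_forward
#' @return Bit score; equals [fa_forward()] to numerical tolerance.
#' @export
fa_backward <- function(codon_profile, window, use_cache = TRUE) {
  res <- cpp_fa_engine(dp_pack_codon(codon_profile), encode_window(window),
                       use_cache, TRUE, FALSE, FALSE)
  res$bwd_bits
}

#' Frameshift-aware posterior decoding
#'
#' @inheritParams fa_forward
#' @return A list with `core` (per-nucleotide posterior probability of being
#'   consumed by a match/insert state) and `flank` (N/C/J states); the two
#'   sum to 1 per position.
#' @export
fa_posterior <- function(codon_profile, window, use_cache = TRUE) {
  res <- cpp_fa_engine(dp_pack_codon(codon_profile), encode_window(window),
                       use_cache, TRUE, TRUE, FALSE)
  list(core = res$post_core, flank = res$post_flank,
       fwd_bits = res$fwd_bits, bwd_bits = res$bwd_bits)
}

#' Reference scores by exhaustive path enumeration
#'
#' Walks every legal state path of the frameshift-aware model explicitly
#' (no dynamic programming) and returns the exact Forward (log-sum over
#' paths) and Viterbi (max over paths) bit scores.  Exponential cost: only
#' usable on tiny models and windows; intended for validating the DP
#' engines.
#'
#' @inheritParams fa_forward
#' @param path_limit Abort (with `overflow = TRUE`) beyond this many paths.
#' @return List with `forward_bits`, `viterbi_bits`, `n_paths`, `overflow`.
#' @export
fa_reference_scores <- function(codon_profile, window, path_limit = 1e8) {
  cpp_fa_reference(dp_pack_codon(codon_profile), encode_window(window),
                   path_limit)
}

FA_CLS_LABELS <- c("sense", "stop", "quasi1", "quasi2", "quasi4", "quasi5",
                   "gap", "flank", "neutral")

#' Frameshift-aware Viterbi alignment
#'
#' @inheritParams fa_forward
#' @return A list: `bits` (Viterbi score), `path` (tibble of steps with
#'   `kind` M/I/D/N/C/J, `state`, `from`/`to` 0-based half-open window nt
#'   span, `class`), `frameshift_count` (quasi-codon steps), `stop_count`
#'   (stop-codon match steps).
#' @export
fa_viterbi_path <- function(codon_profile, window, use_cache = TRUE) {
  res <- cpp_fa_engine(dp_pack_codon(codon_profile), encode_window(window),
                       use_cache, FALSE, FALSE, TRUE)
  path <- as_tibble(as.data.frame(res$path))
  path$kind <- c("M", "I", "D", "N", "C", "J")[path$kind + 1]
  path$class <- FA_CLS_LABELS[path$cls + 1]
  path$cls <- NULL
  list(bits = res$vit_bits, path = path,
       frameshift_count = sum(path$kind == "M" &
                                path$class %in% c("quasi1", "quasi2", "quasi4", "quasi5")),
       stop_count = sum(path$kind == "M" & path$class == "stop"))
}
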