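# Alphabets, background frequencies, and BLOSUM62-derived conditionals.
# Amino acids are kept in fixed alphabetical order; ties in argmax operations
# resolve to the earlier letter.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

NT_ALPHABET <- c("A", "C", "G", "T")

# Swissprot-derived amino-acid background (the distribution HMMER-style null
# models use), renormalized to sum to 1.
AA_BACKGROUND_RAW <- c(
  A = 0.0787945, C = 0.0151600, D = 0.0535222, E = 0.0668298,
  F = 0.0397062, G = 0.0695071, H = 0.0229198, I = 0.0590092,
  K = 0.0594422, L = 0.0963728, M = 0.0237718, N = 0.0414386,
  P = 0.0482904, Q = 0.0395639, R = 0.0540978, S = 0.0683364,
  T = 0.0540687, V = 0.0673417, W = 0.0114135, Y = 0.0304133)

aa_background <- function() {
  bg <- AA_BACKGROUND_RAW[AA_ALPHABET]
  bg / sum(bg)
}

dna_background <- function() {
  setNames(rep(0.25, 4), NT_ALPHABET)
}

aa_index <- function(chars) {
  idx <- match(chars, AA_ALPHABET)
  idx
}

#' Encode a protein string as 1-based indices into the amino-acid alphabet
#' @noRd
encode_protein <- function(x) {
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  match(ch, AA_ALPHABET)
}

#' Encode DNA as 0-based indices A=0,C=1,G=2,T=3; N and other ambiguity = NA
#' @noRd
encode_dna <- function(x) {
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  match(ch, NT_ALPHABET) - 1L
}

revcomp <- function(x) {
  chartr("ACGTNacgtn", "TGCANtgcan",
         paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
}

# BLOSUM62 conditional substitution distributions P(a | b), reconstructed
# from the integer half-bit score matrix: s(a,b) = 2*log2(p(a,b)/(f_a f_b))
# implies P(a|b) proportional to f_a * 2^(s(a,b)/2).
blosum62_conditionals <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  S <- env$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
  bg <- aa_background()
  P <- matrix(0, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  for (b in seq_len(20)) {
    w <- bg * 2^(S[, b] / 2)
    P[, b] <- w / sum(w)
  }
  # column b gives the emission distribution for a model position whose
  # underlying residue is b
  P
}
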