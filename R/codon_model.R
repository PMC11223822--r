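# Genetic-code machinery and the frameshift-aware codon profile: per-state
# emission scores for sense codons, stop codons, and quasi-codons of length
# 1, 2, 4, and 5.

#' Frameshift and stop-codon penalties
#'
#' The penalty for a quasi-codon acts as an implicit within-state transition
#' probability: 0.01 for length 2 or 4 quasi-codons, 0.005 for length 1 or
#' 5, and 0.01 for stop codons.  All sense-codon emissions are scaled by
#' `norm = 1 - (p_stop + p1 + p2 + p4 + p5)` (0.96 at the defaults).
#'
#' @param p1,p2,p4,p5 Quasi-codon penalties by length.
#' @param p_stop Stop-codon penalty.
#' @return A list of class `fh_penalties` with the derived `norm`.
#' @export
frameshift_penalties <- function(p1 = 0.005, p2 = 0.01, p4 = 0.01,
                                 p5 = 0.005, p_stop = 0.01) {
  stopifnot(p1 >= 0, p1 < 1, p2 >= 0, p2 < 1, p4 >= 0, p4 < 1, p5 >= 0,
            p5 < 1, p_stop >= 0, p_stop < 1)
  norm <- 1 - (p_stop + p1 + p2 + p4 + p5)
  if (norm <= 0) stop("penalties sum to >= 1")
  structure(list(p1 = p1, p2 = p2, p4 = p4, p5 = p5, p_stop = p_stop,
                 norm = norm), class = "fh_penalties")
}

#' NCBI genetic code table
#'
#' @param table_id NCBI translation table id (1, 4, and 11 are guaranteed;
#'   any id known to Biostrings works).
#' @return A list of class `fh_genetic_code` with `table_id`, `codon_to_aa`
#'   (named character over the 64 DNA triplets, `*` for stop), and
#'   `stop_codons`.
#' @export
genetic_code <- function(table_id = 1) {
  tab <- tryCatch(Biostrings::getGeneticCode(as.character(table_id)),
                  error = function(e) stop("genetic_code: unknown table id ",
                                           table_id))
  codons <- names(tab)
  stopifnot(length(tab) == 64)
  structure(list(table_id = table_id,
                 codon_to_aa = setNames(unname(tab), codons),
                 stop_codons = codons[tab == "*"]),
            class = "fh_genetic_code")
}

# codon index 0..63 as 16*a + 4*b + c with A=0,C=1,G=2,T=3
codon_index <- function(codons) {
  m <- do.call(rbind, strsplit(codons, "", fixed = TRUE))
  v <- matrix(match(m, NT_ALPHABET) - 1L, nrow = nrow(m))
  as.integer(v[, 1] * 16L + v[, 2] * 4L + v[, 3])
}

all_codons <- function() {
  g <- expand.grid(c3 = NT_ALPHABET, c2 = NT_ALPHABET, c1 = NT_ALPHABET,
                   stringsAsFactors = FALSE)
  paste0(g$c1, g$c2, g$c3)  # ordered by codon_index
}

# aa index (1..20) per codon index+1; 0 = stop
codon_aa_indices <- function(code) {
  key <- paste0("aaidx_", code$table_id)
  if (!is.null(.fh_cache[[key]])) return(.fh_cache[[key]])
  codons <- all_codons()
  aa <- code$codon_to_aa[codons]
  idx <- match(aa, AA_ALPHABET)
  idx[aa == "*"] <- 0L
  if (anyNA(idx)) stop("genetic code contains unsupported amino acid")
  .fh_cache[[key]] <- as.integer(idx)
  .fh_cache[[key]]
}

#' Completion set of a quasi-codon
#'
#' The set of amino acids encoded by any codon reachable from `q` by adding
#' (length < 3) or removing (length > 3) the nucleotides needed to reach
#' length 3, i.e. all sense codons having `q` as a subsequence (or being a
#' subsequence of `q`).  Stop codons are excluded.
#'
#' @param q Quasi-codon string over ACGT, length 1, 2, 4, or 5.
#' @param code An `fh_genetic_code`.
#' @return Character vector of amino acids, in alphabet order (possibly
#'   empty if every completion is a stop).
#' @export
completion_set <- function(q, code = genetic_code(1)) {
  q <- toupper(q)
  L <- nchar(q)
  if (L == 3) stop("completion_set: length-3 strings are codons, not quasi-codons")
  stopifnot(L %in% c(1, 2, 4, 5), grepl("^[ACGT]+$", q))
  codons <- all_codons()
  qc <- strsplit(q, "", fixed = TRUE)[[1]]
  keep <- vapply(codons, function(cd) {
    cc <- strsplit(cd, "", fixed = TRUE)[[1]]
    if (L < 3) is_subsequence(qc, cc) else is_subsequence(cc, qc)
  }, logical(1))
  aa <- unique(code$codon_to_aa[codons[keep]])
  aa <- aa[aa != "*"]
  sort(aa)
}

is_subsequence <- function(sub, full) {
  i <- 1
  for (ch in full) {
    if (i <= length(sub) && ch == sub[i]) i <- i + 1
  }
  i > length(sub)
}

#' Stop-codon neighbor score
#'
#' The emission probability of stop codon `s` at a state with amino-acid
#' emission vector `emissions`: the stop-codon penalty times the emission of
#' the best amino acid encoded by a sense codon at Hamming distance <= 1
#' from `s`.
#'
#' @param s Stop codon string.
#' @param emissions Length-20 emission probability vector.
#' @param penalties An `fh_penalties`.
#' @param code An `fh_genetic_code`.
#' @return A probability.
#' @export
stop_neighbor_score <- function(s, emissions, penalties = frameshift_penalties(),
                                code = genetic_code(1)) {
  s <- toupper(s)
  stopifnot(s %in% code$stop_codons, length(emissions) == 20)
  cand <- stop_neighbor_aas(s, code)
  if (length(cand) == 0) return(0)
  penalties$p_stop * max(emissions[cand])
}

# aa indices of sense codons within Hamming distance 1 of stop codon s
stop_neighbor_aas <- function(s, code) {
  sc <- strsplit(s, "", fixed = TRUE)[[1]]
  neigh <- character(0)
  for (pos in 1:3) {
    for (nt in NT_ALPHABET) {
      cc <- sc
      cc[pos] <- nt
      neigh <- c(neigh, paste(cc, collapse = ""))
    }
  }
  neigh <- unique(neigh)  # includes s itself; it is a stop, filtered below
  aa <- code$codon_to_aa[neigh]
  sort(unique(match(aa[aa != "*"], AA_ALPHABET)))
}

# --- quasi-codon enumeration tables (cached per genetic code) -------------

.fh_cache <- new.env(parent = emptyenv())

quasi_lengths <- c(1L, 2L, 4L, 5L)

# For each quasi length, a list over the 4^len strings (in base-4 order,
# A=0..T=3) of integer aa-index candidate sets.
quasi_candidate_sets <- function(code) {
  key <- paste0("quasi_", code$table_id)
  if (!is.null(.fh_cache[[key]])) return(.fh_cache[[key]])
  codons <- all_codons()
  codon_chars <- strsplit(codons, "", fixed = TRUE)
  aa_idx <- codon_aa_indices(code)
  out <- list()
  for (L in quasi_lengths) {
    grid <- as.matrix(expand.grid(rep(list(0:3), L)))[, L:1, drop = FALSE]
    # rows ordered so that row r corresponds to base-4 value r-1
    sets <- vector("list", 4^L)
    for (r in seq_len(4^L)) {
      qc <- NT_ALPHABET[grid[r, ] + 1]
      keep <- vapply(seq_along(codons), function(ci) {
        cc <- codon_chars[[ci]]
        if (L < 3) is_subsequence(qc, cc) else is_subsequence(cc, qc)
      }, logical(1))
      aas <- sort(unique(aa_idx[keep & aa_idx > 0]))
      sets[[r]] <- as.integer(aas)
    }
    out[[as.character(L)]] <- sets
  }
  .fh_cache[[key]] <- out
  out
}

#' Derive the frameshift-aware codon profile from a protein profile
#'
#' Per state i and sense codon c, the emission score is
#' `norm * match_emissions[i, aa(c)]`; per stop codon it is the
#' [stop_neighbor_score()]; per quasi-codon q it is `penalty(|q|)` times the
#' best emission among the completion set of q.  Insert-state emission
#' vectors receive the same construction.
#'
#' @param profile An `fh_profile`.
#' @param penalties An `fh_penalties`.
#' @param code An `fh_genetic_code`.
#' @param dna_bg Nucleotide background probabilities (length 4).
#' @return An object of class `fh_codon_profile` carrying per-state log-score
#'   tables for sense codons, stop codons, and each quasi-codon length.
#' @export
make_codon_profile <- function(profile, penalties = frameshift_penalties(),
                               code = genetic_code(1), dna_bg = dna_background()) {
  stopifnot(inherits(profile, "fh_profile"))
  M <- profile$M
  qsets <- quasi_candidate_sets(code)
  aa_idx <- codon_aa_indices(code)
  stops <- code$stop_codons
  stop_cands <- lapply(stops, stop_neighbor_aas, code = code)
  pen_of_len <- c(`1` = penalties$p1, `2` = penalties$p2,
                  `4` = penalties$p4, `5` = penalties$p5)

  # synonymous-codon counts per amino acid: the emission mass of an amino
  # acid is divided equally among its codons so the codon distribution is
  # properly normalized (random coding DNA then scores near 0 against the
  # nucleotide null instead of drifting positive with length)
  n_syn <- tabulate(aa_idx[aa_idx > 0], nbins = 20)
  lnsyn <- log(n_syn)

  build_tables <- function(em) {
    lsense <- (log(penalties$norm) + log(em)) -
      matrix(lnsyn, M, 20, byrow = TRUE)           # M x 20, by aa index
    lstop <- matrix(-Inf, M, length(stops))
    for (si in seq_along(stops)) {
      cand <- stop_cands[[si]]
      if (length(cand)) {
        lstop[, si] <- log(penalties$p_stop) +
          log(apply(em[, cand, drop = FALSE], 1, max))
      }
    }
    # Quasi-codon class: the penalty is the probability of entering the
    # quasi-codon sub-state of that length; within the class, emission mass
    # is distributed over the 4^len strings proportionally to the best
    # completion emission (normalized by Z so the class sums to the penalty).
    lquasi <- list()
    lZ <- matrix(NA_real_, M, 4,
                 dimnames = list(NULL, as.character(quasi_lengths)))
    for (L in quasi_lengths) {
      sets <- qsets[[as.character(L)]]
      maxem <- matrix(0, M, length(sets))
      for (r in seq_along(sets)) {
        cand <- sets[[r]]
        if (length(cand)) {
          maxem[, r] <- apply(em[, cand, drop = FALSE], 1, max)
        }
      }
      Z <- rowSums(maxem)
      lp <- log(pen_of_len[[as.character(L)]])
      tabm <- (lp + log(maxem)) - matrix(log(Z), M, ncol(maxem))
      lquasi[[as.character(L)]] <- tabm
      lZ[, as.character(L)] <- log(Z)
    }
    list(lsense = lsense, lstop = lstop, lquasi = lquasi, lZ = lZ)
  }

  mt <- build_tables(profile$match_emissions)
  it <- build_tables(profile$insert_emissions)
  structure(list(parent = profile, penalties = penalties, code = code,
                 dna_background = dna_bg,
                 n_syn = n_syn,                 # synonymous codons per aa
                 aa_of_codon = aa_idx,          # 0 = stop, by codon index+1
                 stop_codons = stops,
                 stop_index = {                 # 1..n_stops by codon index+1
                   v <- integer(64)
                   v[codon_index(stops) + 1L] <- seq_along(stops)
                   v
                 },
                 match = mt, insert = it),
            class = "fh_codon_profile")
}

#' @export
print.fh_codon_profile <- function(x, ...) {
  cat(sprintf("<fh_codon_profile '%s': M=%d, table %s, norm=%.4f>\n",
              x$parent$name, x$parent$M, x$code$table_id, x$penalties$norm))
  invisible(x)
}

#' Emission score of a (quasi-)codon at one state
#'
#' Linear-probability accessor into the codon profile tables, mainly for
#' inspection and testing.
#'
#' @param cp An `fh_codon_profile`.
#' @param state State index (1..M).
#' @param chunk Nucleotide string of length 1-5.
#' @param type `"match"` or `"insert"`.
#' @return Emission probability of the chunk at the state.
#' @export
codon_score <- function(cp, state, chunk, type = c("match", "insert")) {
  type <- match.arg(type)
  tabs <- cp[[type]]
  chunk <- toupper(chunk)
  L <- nchar(chunk)
  v <- encode_dna(chunk)
  stopifnot(!anyNA(v), L %in% c(1:5))
  if (L == 3) {
    ci <- v[1] * 16L + v[2] * 4L + v[3] + 1L
    aa <- cp$aa_of_codon[ci]
    if (aa == 0) return(exp(tabs$lstop[state, cp$stop_index[ci]]))
    return(exp(tabs$lsense[state, aa]))
  }
  r <- sum(v * 4^((L - 1):0)) + 1L
  exp(tabs$lquasi[[as.character(L)]][state, r])
}

#' Reverse-translate a protein into DNA
#'
#' Each amino acid is encoded by a uniformly chosen synonymous sense codon,
#' so the result is stop-free in frame 0 and translates back to the input.
#' Uses the R random number generator; seed with `set.seed()`.
#'
#' @param protein Protein string (20 standard amino acids).
#' @param code An `fh_genetic_code`.
#' @return A DNA string of length `3 * nchar(protein)`.
#' @export
reverse_translate <- function(protein, code = genetic_code(1)) {
  reverse_translate_batch(protein, code)[1]
}

#' @rdname reverse_translate
#' @param proteins Character vector of protein strings.
#' @export
reverse_translate_batch <- function(proteins, code = genetic_code(1)) {
  key <- paste0("aa2codon_tab_", code$table_id)
  if (is.null(.fh_cache[[key]])) {
    codons <- all_codons()
    aa <- code$codon_to_aa[codons]
    sp <- split(codons, aa)
    sp <- sp[names(sp) != "*"]
    nmax <- max(lengths(sp))
    tabm <- matrix(NA_character_, 20, nmax,
                   dimnames = list(AA_ALPHABET, NULL))
    for (a in names(sp)) tabm[a, seq_along(sp[[a]])] <- sp[[a]]
    .fh_cache[[key]] <- list(tab = tabm, nsyn = lengths(sp)[AA_ALPHABET])
  }
  tabm <- .fh_cache[[key]]$tab
  nsyn <- .fh_cache[[key]]$nsyn
  chars <- strsplit(toupper(proteins), "", fixed = TRUE)
  lens <- lengths(chars)
  all <- unlist(chars, use.names = FALSE)
  ai <- match(all, AA_ALPHABET)
  if (anyNA(ai)) stop("reverse_translate: unsupported residue '",
                      all[which(is.na(ai))[1]], "'")
  pick <- floor(runif(length(ai)) * nsyn[ai]) + 1L
  cods <- tabm[cbind(ai, pick)]
  grp <- rep.int(seq_along(lens), lens)
  unname(vapply(split(cods, grp), paste, character(1), collapse = ""))
}

#' Translate DNA in a given frame
#'
#' @param dna DNA string over ACGTN.
#' @param code An `fh_genetic_code`.
#' @param frame 0, 1, or 2 (offset on the chosen strand).
#' @param strand `"+"` or `"-"` (minus translates the reverse complement).
#' @return Protein string with `*` for stops and `X` for codons containing N;
#'   trailing 1-2 nt are dropped.
#' @export
translate_dna <- function(dna, code = genetic_code(1), frame = 0, strand = "+") {
  dna <- toupper(dna)
  if (grepl("[^ACGTN]", dna)) {
    stop("translate_dna: non-ACGTN character in input")
  }
  stopifnot(frame %in% 0:2, strand %in% c("+", "-"))
  if (strand == "-") dna <- revcomp(dna)
  v <- encode_dna(dna)
  translate_codon_indices(v, frame, code)
}

# v: 0-based nt indices with NA for N; returns the translated string
translate_codon_indices <- function(v, frame, code) {
  n <- length(v)
  start <- frame + 1
  ncod <- (n - frame) %/% 3
  if (ncod <= 0) return("")
  i1 <- v[seq(start, by = 3, length.out = ncod)]
  i2 <- v[seq(start + 1, by = 3, length.out = ncod)]
  i3 <- v[seq(start + 2, by = 3, length.out = ncod)]
  ci <- i1 * 16L + i2 * 4L + i3 + 1L
  aa_chr <- c("*", AA_ALPHABET)[codon_aa_indices(code) + 1L]
  out <- aa_chr[ci]
  out[is.na(out)] <- "X"
  paste(out, collapse = "")
}
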