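# Building protein profile HMMs from alignments or single sequences, plus
# consensus extraction, model sampling, and the emitted-length distribution
# that defines the genomic window size L.

# Emission prior: single-component Dirichlet with concentration 20 spread as
# 20 * background.  Transition prior counts favour match-to-match.
EMISSION_PRIOR_CONC <- 20
TRANS_PRIOR_M <- c(MM = 6.0, MI = 0.2, MD = 0.2)
TRANS_PRIOR_I <- c(IM = 0.6, II = 0.4)
TRANS_PRIOR_D <- c(DM = 0.6, DD = 0.4)

#' Build a profile HMM from a multiple sequence alignment
#'
#' Columns with gap fraction < 0.5 become match states.  Sequences are
#' weighted by Henikoff position-based weighting (normalized so the total
#' weight equals the number of distinct rows, which makes the build invariant
#' to duplicated rows), emission counts are blended with a
#' `20 * background` Dirichlet prior, and transition counts with fixed prior
#' counts.
#'
#' @param msa An `fh_msa` (protein alphabet).
#' @param config An `fh_config`; unused fields are ignored.
#' @return An `fh_profile`.
#' @export
build_from_msa <- function(msa, config = search_config()) {
  stopifnot(inherits(msa, "fh_msa"))
  rows <- toupper(msa$rows)
  nseq <- length(rows)
  ncol_aln <- nchar(rows[1])
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  is_gap <- mat == "-"
  gap_frac <- colMeans(is_gap)
  match_cols <- which(gap_frac < 0.5)
  if (length(match_cols) == 0) stop("build_from_msa: alignment has no match columns")
  M <- length(match_cols)
  w <- henikoff_weights(mat, is_gap)
  w <- w / sum(w) * length(unique(rows))
  bg <- aa_background()
  alpha <- EMISSION_PRIOR_CONC * bg

  me <- matrix(rep(alpha, each = M), M, 20)
  ie <- matrix(rep(alpha, each = M), M, 20)
  # transition counts: classify each row position as M (residue in match
  # col), D (gap in match col), I (residue in insert col)
  trc <- matrix(0, M, 7, dimnames = list(NULL, TRANS_NAMES))
  col_state <- rep("I", ncol_aln)
  col_state[match_cols] <- "M"
  node_of_col <- integer(ncol_aln)
  node_of_col[match_cols] <- seq_len(M)
  # insert columns belong to the preceding match node
  node_of_col[col_state == "I"] <-
    findInterval(which(col_state == "I"), match_cols)

  for (s in seq_len(nseq)) {
    prev_state <- NULL  # state at current node position
    prev_node <- 0
    for (j in seq_len(ncol_aln)) {
      if (col_state[j] == "M") {
        k <- node_of_col[j]
        st <- if (is_gap[s, j]) "D" else "M"
        if (st == "M") {
          a <- match(mat[s, j], AA_ALPHABET)
          if (!is.na(a)) me[k, a] <- me[k, a] + w[s]
        }
        if (!is.null(prev_state) && prev_node >= 1) {
          tc <- paste0(prev_state, st)
          if (tc %in% colnames(trc)) {
            trc[prev_node, tc] <- trc[prev_node, tc] + w[s]
          }
        }
        prev_state <- st
        prev_node <- k
      } else if (!is_gap[s, j] && prev_node >= 1 && prev_node < M) {
        # insert residue between match nodes
        a <- match(mat[s, j], AA_ALPHABET)
        if (!is.na(a)) ie[prev_node, a] <- ie[prev_node, a] + w[s]
        if (!is.null(prev_state)) {
          tc <- paste0(prev_state, "I")
          if (tc %in% colnames(trc)) {
            trc[prev_node, tc] <- trc[prev_node, tc] + w[s]
          }
          prev_state <- "I"
        }
      }
    }
  }
  # fold in priors and normalize
  tr <- matrix(0, M, 7, dimnames = list(NULL, TRANS_NAMES))
  for (k in seq_len(M)) {
    m3 <- trc[k, 1:3] + TRANS_PRIOR_M
    i2 <- trc[k, 4:5] + TRANS_PRIOR_I
    d2 <- trc[k, 6:7] + TRANS_PRIOR_D
    tr[k, 1:3] <- m3 / sum(m3)
    tr[k, 4:5] <- i2 / sum(i2)
    tr[k, 6:7] <- d2 / sum(d2)
  }
  me <- me / rowSums(me)
  ie <- ie / rowSums(ie)
  new_profile(msa$name, me, ie, tr, background = bg)
}

# Henikoff position-based weights: each column contributes 1/(r*s) to each
# sequence, where r is the number of distinct residues in the column and s
# the multiplicity of the sequence's residue.  Gap cells contribute nothing.
henikoff_weights <- function(mat, is_gap) {
  nseq <- nrow(mat)
  w <- numeric(nseq)
  for (j in seq_len(ncol(mat))) {
    res <- mat[, j]
    ok <- !is_gap[, j]
    if (!any(ok)) next
    tab <- table(res[ok])
    r <- length(tab)
    contrib <- 1 / (r * as.numeric(tab[res[ok]]))
    w[ok] <- w[ok] + contrib
  }
  if (all(w == 0)) w[] <- 1
  w
}

#' Build a profile HMM from a single protein sequence
#'
#' Match emissions at position i are the BLOSUM62 conditional distribution
#' P(a | seq[i]); an `X` residue yields background emissions.  All nodes
#' share one gap-cost-derived transition set (insert/delete open 0.02,
#' extend 0.4).
#'
#' @param seq A protein string, or a one-row tibble as from [read_fasta()].
#' @param config An `fh_config`.
#' @param name Model name.
#' @return An `fh_profile`.
#' @export
build_from_sequence <- function(seq, config = search_config(), name = NULL) {
  if (is.data.frame(seq)) {
    if (is.null(name)) name <- seq$id[1]
    seq <- seq$seq[1]
  }
  if (is.null(name)) name <- "query"
  seq <- toupper(seq)
  stopifnot(nchar(seq) >= 1)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bg <- aa_background()
  cond <- blosum62_conditionals()
  M <- length(chars)
  me <- matrix(0, M, 20)
  for (i in seq_len(M)) {
    me[i, ] <- if (chars[i] == "X") bg else cond[, chars[i]]
  }
  ie <- matrix(rep(bg, each = M), M, 20)
  open <- 0.02; extend <- 0.4
  tr <- matrix(rep(c(1 - 2 * open, open, open,
                     1 - extend, extend, 1 - extend, extend), each = M),
               M, 7, dimnames = list(NULL, TRANS_NAMES))
  new_profile(name, me, ie, tr, background = bg)
}

#' Consensus sequence of a profile
#'
#' Residue i is the argmax of the match emissions at state i; ties break to
#' the alphabetically earlier amino acid.
#'
#' @param profile An `fh_profile`.
#' @return A one-row tibble with columns `id`, `desc`, `seq`.
#' @export
consensus_sequence <- function(profile) {
  idx <- apply(profile$match_emissions, 1, which.max)
  tibble(id = paste0(profile$name, "-consensus"), desc = "",
         seq = paste(AA_ALPHABET[idx], collapse = ""))
}

#' Emitted-length distribution tail of the core model
#'
#' Computes, by dynamic programming over the core model (entered at node 1 in
#' the match state), the exact distribution of the number of residues emitted,
#' and returns the smallest L such that P(length > L) <= `tail_mass`.  The
#' result is also stored in `profile$max_len_aa`.
#'
#' @param profile An `fh_profile`.
#' @param tail_mass Tail probability (default 1e-7).
#' @param cap Maximum length considered; exceeding it is an error.
#' @return The profile with `max_len_aa` set; the selected L is
#'   `profile$max_len_aa`, and the full distribution is in
#'   `attr(profile, "length_distribution")`.
#' @export
emitted_length_tail <- function(profile, tail_mass = 1e-7,
                                cap = 100 * profile$M) {
  stopifnot(tail_mass > 0, tail_mass < 1)
  dist <- core_length_distribution(profile, cap)
  cum <- cumsum(dist)
  tail <- 1 - cum
  ok <- which(tail <= tail_mass)
  if (length(ok) == 0) {
    stop("emitted_length_tail: cap ", cap,
         " reached before tail mass fell below ", tail_mass,
         "; increase cap")
  }
  L <- ok[1] - 1L  # dist[1] is P(length = 0)
  L <- max(L, 1L)
  profile$max_len_aa <- as.integer(L)
  attr(profile, "length_distribution") <- dist
  profile
}

# P(emitted length = n) for n in 0..cap, as a vector of length cap+1.
# The core model is entered at M1 (which emits one residue); insert runs are
# geometric; deletes emit nothing.  Probability mass escaping past the cap is
# simply missing from the vector.
core_length_distribution <- function(profile, cap) {
  M <- profile$M
  tr <- profile$transitions
  a <- numeric(cap + 1)  # P(just emitted at M_i, total n); index n+1
  d <- numeric(cap + 1)
  a[2] <- 1  # M1 emits 1 residue
  for (i in seq_len(M)) {
    if (i == M) break
    MM <- tr[i, "MM"]; MI <- tr[i, "MI"]; MD <- tr[i, "MD"]
    IM <- tr[i, "IM"]; II <- tr[i, "II"]
    DM <- tr[i, "DM"]; DD <- tr[i, "DD"]
    # insert-run contribution: from a[n], emit j >= 1 inserts then move on:
    # g[n] = MI * sum_j II^(j-1) IM a[n - j]  -> recursive filter
    src <- MI * IM * a
    g <- as.numeric(stats::filter(c(0, src[1:cap]), II, method = "recursive"))
    from_md <- MM * a + DM * d
    a_new <- numeric(cap + 1)
    a_new[2:(cap + 1)] <- from_md[1:cap] + g[1:cap]  # M_{i+1} emits 1
    d_new <- MD * a + DD * d
    a <- a_new
    d <- d_new
  }
  a + d
}

#' Sample a sequence from the core model
#'
#' Walks the core model from node 1 (match state) to node M following the
#' transition probabilities, emitting match and insert residues from the
#' profile's emission distributions.
#'
#' @param profile An `fh_profile`.
#' @param n Number of sequences to sample.
#' @return A character vector of protein strings.  Use `set.seed()` for
#'   reproducibility.
#' @export
sample_sequence <- function(profile, n = 1) {
  M <- profile$M
  tr <- profile$transitions
  out <- character(n)
  for (s in seq_len(n)) {
    res <- character(0)
    state <- "M"
    for (i in seq_len(M)) {
      if (state == "M") {
        res <- c(res, AA_ALPHABET[sample.int(20, 1, prob = profile$match_emissions[i, ])])
      }
      if (i == M) break
      if (state == "M") {
        nxt <- sample(c("M", "I", "D"), 1, prob = tr[i, 1:3])
        while (nxt == "I") {
          res <- c(res, AA_ALPHABET[sample.int(20, 1, prob = profile$insert_emissions[i, ])])
          nxt <- sample(c("M", "I"), 1, prob = tr[i, 4:5])
        }
        state <- if (nxt == "D") "D" else "M"
      } else {  # D
        state <- sample(c("M", "D"), 1, prob = tr[i, 6:7])
      }
    }
    out[s] <- paste(res, collapse = "")
  }
  out
}
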