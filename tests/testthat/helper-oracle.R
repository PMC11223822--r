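# Brute-force path-enumeration oracle for the DP engines.  Enumerates every
# legal state path through the local multihit model explicitly (no dynamic
# programming, no memoization), accumulating log path weights; the Forward
# score is the log-sum over paths and the Viterbi score the max.  Usable for
# both the protein model (match/insert consume 1 residue) and the
# frameshift-aware codon model (match consumes 1-5 nt, insert exactly 3).

oracle_lse <- function(v) {
  v <- v[is.finite(v)]
  if (length(v) == 0) return(-Inf)
  m <- max(v)
  m + log(sum(exp(v - m)))
}

# emfun(k, j0, l): log-odds of match state k consuming positions
#   (j0, j0+l] (0-based start); -Inf if not allowed
# eifun(k, j0): insert state k consuming its fixed-length chunk
# lens: allowed match chunk lengths; ilen: insert chunk length
oracle_scores <- function(M, ltr, lentry, emfun, eifun, n, lens, ilen) {
  nn <- n
  nloop <- log(nn / (nn + 3)); nmove <- log(3 / (nn + 3))
  jloop <- nloop; jmove <- nmove; cloop <- nloop; cmove <- nmove
  ej <- log(0.5); ec <- log(0.5)
  nullsc <- nn * log(nn / (nn + 1)) + log(1 / (nn + 1))

  acc <- new.env()
  acc$v <- numeric(0)

  # all (end position, weight) completions of a core pass currently in
  # state (kind, k) having consumed up to j, with accumulated weight w
  exits <- function(kind, k, j, w) {
    if (kind == "M" || kind == "D") {
      acc_pass$v[[length(acc_pass$v) + 1]] <<- c(j, w)  # free exit to E
    }
    if (k >= M && kind != "I") return(invisible())
    if (kind == "M") {
      if (k < M) {
        for (l in lens) {
          if (j + l <= n) {
            e <- emfun(k + 1, j, l)
            if (is.finite(e)) exits("M", k + 1, j + l, w + ltr[k, "MM"] + e)
          }
        }
        if (j + ilen <= n) {
          e <- eifun(k, j)
          if (is.finite(e)) exits("I", k, j + ilen, w + ltr[k, "MI"] + e)
        }
        exits("D", k + 1, j, w + ltr[k, "MD"])
      }
    } else if (kind == "I") {
      for (l in lens) {
        if (j + l <= n) {
          e <- emfun(k + 1, j, l)
          if (is.finite(e)) exits("M", k + 1, j + l, w + ltr[k, "IM"] + e)
        }
      }
      if (j + ilen <= n) {
        e <- eifun(k, j)
        if (is.finite(e)) exits("I", k, j + ilen, w + ltr[k, "II"] + e)
      }
    } else {  # D
      if (k < M) {
        for (l in lens) {
          if (j + l <= n) {
            e <- emfun(k + 1, j, l)
            if (is.finite(e)) exits("M", k + 1, j + l, w + ltr[k, "DM"] + e)
          }
        }
        exits("D", k + 1, j, w + ltr[k, "DD"])
      }
    }
    invisible()
  }

  acc_pass <- new.env()
  pass_completions <- function(jB) {
    acc_pass$v <- list()
    for (k in seq_len(M)) {
      for (l in lens) {
        if (jB + l <= n) {
          e <- emfun(k, jB, l)
          if (is.finite(e)) exits("M", k, jB + l, lentry[k] + e)
        }
      }
    }
    acc_pass$v
  }

  # cache pass completions per start position (pure function of jB)
  pass_cache <- vector("list", n + 1)
  get_passes <- function(jB) {
    if (is.null(pass_cache[[jB + 1]])) pass_cache[[jB + 1]] <<- pass_completions(jB)
    pass_cache[[jB + 1]]
  }

  walk_tail <- function(jB, w) {
    for (pe in get_passes(jB)) {
      jend <- pe[1]; wpass <- pe[2]
      # finish through C
      acc$v[length(acc$v) + 1] <- w + wpass + ec + (n - jend) * cloop + cmove
      # or loop through J into another pass
      if (jend < n || TRUE) {
        for (g in 0:(n - jend)) {
          walk_tail(jend + g, w + wpass + ej + g * jloop + jmove)
        }
      }
    }
  }
  for (a in 0:n) walk_tail(a, a * nloop + nmove)

  list(forward_bits = (oracle_lse(acc$v) - nullsc) / log(2),
       viterbi_bits = (max(c(-Inf, acc$v)) - nullsc) / log(2),
       n_paths = length(acc$v))
}

# oracle for the protein model
oracle_protein <- function(profile, peptide) {
  pep <- match(strsplit(toupper(peptide), "")[[1]], framehmm:::AA_ALPHABET)
  M <- profile$M
  bg <- profile$background
  lme <- log(profile$match_emissions) - matrix(log(bg), M, 20, byrow = TRUE)
  lie <- log(profile$insert_emissions) - matrix(log(bg), M, 20, byrow = TRUE)
  ltr <- log(profile$transitions)
  k <- seq_len(M)
  lentry <- log(2 * (M - k + 1) / (M * (M + 1)))
  emfun <- function(k, j0, l) {
    a <- pep[j0 + 1]
    if (is.na(a)) 0 else lme[k, a]
  }
  eifun <- function(k, j0) {
    a <- pep[j0 + 1]
    if (is.na(a)) 0 else lie[k, a]
  }
  oracle_scores(M, ltr, lentry, emfun, eifun, length(pep), lens = 1, ilen = 1)
}

# oracle for the frameshift-aware codon model; emissions looked up from the
# codon-profile tables (which are unit-tested against brute-force completion
# enumeration separately)
oracle_fa <- function(cp, window) {
  p <- cp$parent
  M <- p$M
  win <- framehmm:::encode_dna(window)
  win[is.na(win)] <- -1L
  n <- length(win)
  ltr <- log(p$transitions)
  k <- seq_len(M)
  lentry <- log(2 * (M - k + 1) / (M * (M + 1)))
  lbg <- log(cp$dna_background)
  chunk_em <- function(tabs, k, j0, l) {
    chunk <- win[(j0 + 1):(j0 + l)]
    if (any(chunk < 0)) return(0)
    bgl <- sum(lbg[chunk + 1])
    if (l == 3) {
      ci <- chunk[1] * 16L + chunk[2] * 4L + chunk[3] + 1L
      aa <- cp$aa_of_codon[ci]
      if (aa == 0) return(tabs$lstop[k, cp$stop_index[ci]] - bgl)
      return(tabs$lsense[k, aa] - bgl)
    }
    qidx <- sum(chunk * 4^((l - 1):0)) + 1L
    tabs$lquasi[[as.character(l)]][k, qidx] - bgl
  }
  emfun <- function(k, j0, l) chunk_em(cp$match, k, j0, l)
  eifun <- function(k, j0) chunk_em(cp$insert, k, j0, 3)
  oracle_scores(M, ltr, lentry, emfun, eifun, n, lens = 1:5, ilen = 3)
}
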