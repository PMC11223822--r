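# The staged search pipeline: six-frame ORFs -> MSV filter -> Viterbi filter
# -> genomic window -> dual Forward scores (standard F0, frameshift-aware F1)
# -> gate -> arbitration -> envelope definition, rescoring, E-values.

#' Select the genomic window around a surviving ORF hit
#'
#' The window length is `3 * max_len_aa + 2 * pad` nucleotides (L chosen so
#' that only `window_tail_mass` of model emissions exceed it), centered on
#' the seed span and clipped at the sequence ends.
#'
#' @param target_len Target sequence length (nt).
#' @param seed_start,seed_end Forward-strand 0-based half-open seed span.
#' @param profile An `fh_profile` with `max_len_aa` set.
#' @param pad Extra nucleotides on each side (default 15).
#' @return `c(start, end)`, 0-based half-open, containing the seed span.
#' @export
select_window <- function(target_len, seed_start, seed_end, profile, pad = 15) {
  if (is.null(profile$max_len_aa)) stop("profile has no max_len_aa; run emitted_length_tail()")
  W <- 3 * profile$max_len_aa + 2 * pad
  mid <- (seed_start + seed_end) / 2
  s <- floor(mid - W / 2)
  e <- s + W
  if (s < 0) { e <- e - s; s <- 0 }
  if (e > target_len) { s <- s - (e - target_len); e <- target_len }
  s <- max(0, s)
  # the window length stays capped at W: a seed longer than the window (a
  # long multihit chain) is covered around its center, not extended to
  c(as.integer(s), as.integer(e))
}

#' Define the alignment envelope from a posterior vector
#'
#' The smallest contiguous span outside which the core-model posterior is
#' below `threshold` everywhere: from the first to the last position with
#' posterior at or above it.
#'
#' @param posterior Numeric vector of per-position core posteriors.
#' @param threshold Posterior threshold (default 0.5).
#' @return `c(from, to)` 0-based half-open, or `NULL` if no position reaches
#'   the threshold (the hit is dropped).
#' @export
define_envelope <- function(posterior, threshold = 0.5) {
  idx <- which(posterior >= threshold)
  if (length(idx) == 0) return(NULL)
  c(idx[1] - 1L, idx[length(idx)])
}

# normalize query input to a list of calibrated profiles with codon profiles
prepare_queries <- function(queries, config) {
  if (inherits(queries, "fh_profile")) queries <- list(queries)
  if (inherits(queries, "fh_msa")) queries <- list(build_from_msa(queries, config))
  stopifnot(is.list(queries), length(queries) >= 1)
  pen <- frameshift_penalties()
  if (!is.null(config$fs_prob)) {
    pen <- frameshift_penalties(p1 = config$fs_prob / 2, p2 = config$fs_prob,
                                p4 = config$fs_prob, p5 = config$fs_prob / 2,
                                p_stop = if (is.null(config$stop_prob)) 0.01 else config$stop_prob)
  } else if (!is.null(config$stop_prob)) {
    pen <- frameshift_penalties(p_stop = config$stop_prob)
  }
  code <- genetic_code(config$genetic_code_id)
  lapply(seq_along(queries), function(i) {
    p <- queries[[i]]
    if (inherits(p, "fh_msa")) p <- build_from_msa(p, config)
    if (is.null(p$max_len_aa)) p <- emitted_length_tail(p, config$window_tail_mass)
    cp <- make_codon_profile(p, pen, code)
    if (is.null(p$calibration) || is.na(p$calibration$ffwd_tau) ||
        is.null(p$calibration$ffwd_env_tau)) {
      p <- calibrate(p, cp, n = config$calibrate_n, seed = config$seed + i)
      cp$parent <- p
    }
    cp$pack <- dp_pack_codon(cp)
    list(profile = p, cp = cp)
  })
}

# Stage 1-7 for one query against a precomputed ORF table: returns gated
# candidates with window coordinates and both Forward P-values.
search_candidates <- function(q, orfs, targets_len, config, enc = NULL) {
  profile <- q$profile; cp <- q$cp
  cal <- profile$calibration
  if (nrow(orfs) == 0) return(NULL)
  if (is.null(enc)) enc <- encode_peptides(orfs$peptide)
  msv_p <- gumbel_pvalue(protein_scores_enc(profile, enc, 0L),
                         cal$msv_mu, cal$msv_lambda)
  surv <- which(msv_p <= config$msv_pthresh)
  n_msv <- length(surv)
  if (length(surv) == 0) return(NULL)
  vit_p <- gumbel_pvalue(protein_scores_enc(profile, subset_enc(enc, surv), 1L),
                         cal$vit_mu, cal$vit_lambda)
  surv <- surv[vit_p <= config$vit_pthresh]
  n_vit <- length(surv)
  if (length(surv) == 0) return(NULL)

  cand <- orfs[surv, ]
  # seed on the Viterbi alignment span within the ORF, not the whole ORF
  seed_span <- t(vapply(seq_len(nrow(cand)), function(i) {
    vp <- protein_viterbi_path(profile, cand$peptide[i])
    core <- vp$path[vp$path$kind %in% c("M", "I"), ]
    if (nrow(core) == 0) {
      return(c(cand$dna_start[i], cand$dna_end[i]))
    }
    peptide_span_to_dna(cand[i, ], min(core$from), max(core$to))
  }, numeric(2)))
  win <- t(vapply(seq_len(nrow(cand)), function(i) {
    select_window(targets_len[[cand$target_id[i]]],
                  seed_span[i, 1], seed_span[i, 2], profile)
  }, numeric(2)))
  cand$win_start <- win[, 1]; cand$win_end <- win[, 2]
  # deduplicate identical windows (same target/strand), keeping the first
  key <- paste(cand$target_id, cand$strand, cand$win_start, cand$win_end)
  cand <- cand[!duplicated(key), ]

  # clip each peptide to the part inside its window, so the standard-path
  # statistic is bounded by the same window length as the FA statistic (and
  # as the calibration simulations)
  clip <- t(vapply(seq_len(nrow(cand)), function(i) {
    ov_s <- max(cand$win_start[i], cand$dna_start[i])
    ov_e <- min(cand$win_end[i], cand$dna_end[i])
    if (cand$strand[i] == "+") {
      aa_from <- ceiling((ov_s - cand$dna_start[i]) / 3)
      aa_to <- floor((ov_e - cand$dna_start[i]) / 3)
    } else {
      aa_from <- ceiling((cand$dna_end[i] - ov_e) / 3)
      aa_to <- floor((cand$dna_end[i] - ov_s) / 3)
    }
    np <- nchar(cand$peptide[i])
    aa_from <- max(0, min(aa_from, np - 1))
    aa_to <- max(aa_from + 1, min(aa_to, np))
    c(aa_from, aa_to)
  }, numeric(2)))
  cand$clip_aa_off <- as.integer(clip[, 1])
  cand$pep_clip <- substr(cand$peptide, clip[, 1] + 1, clip[, 2])

  f0_bits <- forward_protein(profile, cand$pep_clip)
  cand$F0 <- exp_pvalue(f0_bits, cal$fwd_tau, cal$fwd_lambda)
  wseq <- character(nrow(cand))
  f1_bits <- numeric(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ws <- substr(attr(orfs, "target_seqs")[[cand$target_id[i]]],
                 cand$win_start[i] + 1, cand$win_end[i])
    if (cand$strand[i] == "-") ws <- revcomp(ws)
    wseq[i] <- ws
    f1_bits[i] <- as.numeric(fa_forward(cp, ws))
  }
  cand$window_seq <- wseq
  cand$F1 <- exp_pvalue(f1_bits, cal$ffwd_tau, cal$ffwd_lambda)
  gate <- !(cand$F0 > config$fwd_pthresh & cand$F1 > config$fwd_pthresh)
  n_windows <- nrow(cand)
  cand <- cand[gate, ]
  if (isTRUE(config$verbose)) {
    message(sprintf(
      "[%s] orfs %d | msv pass %d | viterbi pass %d | windows %d | gate pass %d",
      profile$name, nrow(orfs), n_msv, n_vit, n_windows, nrow(cand)))
  }
  if (nrow(cand) == 0) return(NULL)
  cand
}

# Steps 8-9 for gated candidates of one query under a given mode.
postprocess_candidates <- function(q, cand, db_nt, config) {
  profile <- q$profile; cp <- q$cp
  cal <- profile$calibration
  L_nt <- 3 * profile$max_len_aa
  hits <- list()
  for (i in seq_len(nrow(cand))) {
    row <- cand[i, ]
    use_std <- switch(config$mode,
                      nofs = TRUE, fsonly = FALSE,
                      default = row$F0 <= row$F1)
    if (use_std) {
      dec <- protein_decode(profile, row$pep_clip)
      env <- define_envelope(dec$post_core)
      if (is.null(env)) next
      sub_pep <- substr(row$pep_clip, env[1] + 1, env[2])
      S <- forward_protein(profile, sub_pep)
      P <- exp_pvalue(S, cal$fwd_env_tau, cal$fwd_env_lambda)
      env_abs <- env + row$clip_aa_off
      span <- peptide_span_to_dna(row, env_abs[1], env_abs[2])
      vp <- protein_viterbi_path(profile, sub_pep)
      aln <- list(type = "standard", path = vp$path, seq = sub_pep,
                  orf = row[, c("strand", "frame", "dna_start", "dna_end")],
                  env_aa = env_abs)
      fs <- 0L; stp <- 0L
    } else {
      po <- fa_posterior(cp, row$window_seq)
      env <- define_envelope(po$core)
      if (is.null(env)) next
      sub_win <- substr(row$window_seq, env[1] + 1, env[2])
      S <- as.numeric(fa_forward(cp, sub_win))
      P <- exp_pvalue(S, cal$ffwd_env_tau, cal$ffwd_env_lambda)
      if (row$strand == "+") {
        span <- c(row$win_start + env[1], row$win_start + env[2])
      } else {
        span <- c(row$win_end - env[2], row$win_end - env[1])
      }
      vp <- fa_viterbi_path(cp, sub_win)
      aln <- list(type = "fa", path = vp$path, seq = sub_win,
                  env_nt = env)
      fs <- vp$frameshift_count; stp <- vp$stop_count
    }
    E <- evalue(P, db_nt, L_nt, config$both_strands)
    if (E > config$report_evalue_max) next
    hits[[length(hits) + 1]] <- tibble(
      query = profile$name, target = row$target_id, strand = row$strand,
      dna_start = as.integer(span[1]), dna_end = as.integer(span[2]),
      score = S, pvalue = P, evalue = E,
      path_used = if (use_std) "standard" else "frameshift_aware",
      F0 = row$F0, F1 = row$F1,
      frameshift_count = as.integer(fs), stop_count = as.integer(stp),
      alignment = list(aln))
  }
  if (length(hits) == 0) return(NULL)
  do.call(rbind, hits)
}

# overlap deduplication: same query + target, >50% overlap of the shorter
# span -> keep the better E-value
dedup_hits <- function(hits) {
  if (is.null(hits) || nrow(hits) <= 1) return(hits)
  hits <- hits[order(hits$evalue), ]
  grp <- paste(hits$query, hits$target)
  keep <- rep(TRUE, nrow(hits))
  for (idx in split(seq_len(nrow(hits)), grp)) {
    if (length(idx) <= 1) next
    for (a in seq_along(idx)) {
      i <- idx[a]
      if (!keep[i]) next
      for (b in seq_along(idx)) {
        if (b <= a) next
        j <- idx[b]
        if (!keep[j]) next
        ov <- min(hits$dna_end[i], hits$dna_end[j]) -
          max(hits$dna_start[i], hits$dna_start[j])
        if (ov <= 0) next
        shorter <- min(hits$dna_end[i] - hits$dna_start[i],
                       hits$dna_end[j] - hits$dna_start[j])
        if (ov / shorter > 0.5) keep[j] <- FALSE
      }
    }
  }
  hits[keep, ]
}

#' Run the translated search pipeline
#'
#' Executes the staged pipeline: (1) six-frame ORF extraction; (2) MSV
#' filter; (3) Viterbi filter; (4) genomic window selection; (5) standard
#' Forward P-value F0 on the surviving peptide; (6) frameshift-aware Forward
#' P-value F1 on the window; (7) discard when both exceed the gate
#' threshold; (8) arbitration (standard path iff F0 <= F1, overridable via
#' `config$mode`); (9) envelope definition, rescoring, E-values, overlap
#' deduplication.
#'
#' @param queries An `fh_profile`, `fh_msa`, or list of them.  Uncalibrated
#'   profiles are calibrated automatically.
#' @param targets A tibble from [read_fasta()] (columns `id`, `seq`) or a
#'   named character vector of DNA strings.
#' @param config An `fh_config`.
#' @param chunk_size Targets are processed in chunks of this many sequences.
#' @return A tibble of hits sorted by E-value: coordinates are 0-based
#'   half-open on the forward strand; `path_used` records the arbitration;
#'   `alignment` is a list column for [render_alignment()].
#' @export
run_search <- function(queries, targets, config = search_config(),
                       chunk_size = 2000) {
  if (is.character(targets)) {
    targets <- tibble(id = names(targets), seq = unname(targets))
  }
  qs <- prepare_queries(queries, config)
  if (nrow(targets) == 0) return(empty_hits())
  db_nt <- sum(nchar(targets$seq))
  code <- genetic_code(config$genetic_code_id)
  all_hits <- vector("list", 0)
  starts <- seq(1, nrow(targets), by = chunk_size)
  for (cs in starts) {
    chunk <- targets[cs:min(cs + chunk_size - 1, nrow(targets)), ]
    orfs <- six_frame_orfs_batch(setNames(chunk$seq, chunk$id), code, config)
    if (nrow(orfs) == 0) next
    attr(orfs, "target_seqs") <- setNames(as.list(chunk$seq), chunk$id)
    tlen <- setNames(as.list(nchar(chunk$seq)), chunk$id)
    enc <- encode_peptides(orfs$peptide)
    for (q in qs) {
      cand <- search_candidates(q, orfs, tlen, config, enc)
      if (is.null(cand)) next
      h <- postprocess_candidates(q, cand, db_nt, config)
      if (!is.null(h)) all_hits[[length(all_hits) + 1]] <- h
    }
  }
  if (length(all_hits) == 0) return(empty_hits())
  hits <- do.call(rbind, all_hits)
  hits <- dedup_hits(hits)
  hits[order(hits$evalue), ]
}

empty_hits <- function() {
  tibble(query = character(), target = character(), strand = character(),
         dna_start = integer(), dna_end = integer(), score = numeric(),
         pvalue = numeric(), evalue = numeric(), path_used = character(),
         F0 = numeric(), F1 = numeric(), frameshift_count = integer(),
         stop_count = integer(), alignment = list())
}

#' Rescore a hit envelope
#'
#' Reruns the chosen Forward variant on the envelope subsequence only and
#' recomputes P and E (the effective test count stays fixed by the full
#' target length).  This is the step 9 computation exposed for inspection;
#' [run_search()] already applies it.
#'
#' @param q A prepared query (list with `profile`, `cp`).
#' @param hit One hit row from [run_search()].
#' @param db_nt Total searched DNA length.
#' @param config An `fh_config`.
#' @return List with `score`, `pvalue`, `evalue`.
#' @export
rescore_envelope <- function(q, hit, db_nt, config = search_config()) {
  cal <- q$profile$calibration
  aln <- hit$alignment[[1]]
  if (aln$type == "standard") {
    S <- forward_protein(q$profile, aln$seq)
    P <- exp_pvalue(S, cal$fwd_env_tau, cal$fwd_env_lambda)
  } else {
    S <- as.numeric(fa_forward(q$cp, aln$seq))
    P <- exp_pvalue(S, cal$ffwd_env_tau, cal$ffwd_env_lambda)
  }
  list(score = S, pvalue = P,
       evalue = evalue(P, db_nt, 3 * q$profile$max_len_aa, config$both_strands))
}
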