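# Synthetic benchmark generation and evaluation: background pseudochromosome
# HMM, reverse-translated decoys, indel injection, embedding with ground
# truth, TP/FP classification, ROC and recall-0, coverage, overextension,
# and the E-value accuracy experiment.

#' Background genome HMM
#'
#' A K-state HMM over nucleotides emulating compositional heterogeneity of
#' real genomes: states have GC contents spread over \[0.25, 0.75\] and
#' sticky transitions, so sampled sequence shows long-range GC
#' autocorrelation.  This preset stands in for an HMM trained on real
#' genomic sequence.
#'
#' @param K Number of states (default 15).
#' @param stay Self-transition probability.
#' @param gc_range GC content range spanned by the states.
#' @return A list of class `fh_bg_hmm` with `K`, `trans` (K x K), `emis`
#'   (K x 4 over A,C,G,T).
#' @export
background_hmm <- function(K = 15, stay = 0.995, gc_range = c(0.25, 0.75)) {
  gc <- seq(gc_range[1], gc_range[2], length.out = K)
  emis <- cbind((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  colnames(emis) <- NT_ALPHABET
  trans <- matrix((1 - stay) / (K - 1), K, K)
  diag(trans) <- stay
  if (K == 1) trans <- matrix(1, 1, 1)
  structure(list(K = K, trans = trans, emis = emis), class = "fh_bg_hmm")
}

#' Sample DNA from a background HMM
#'
#' @param hmm An `fh_bg_hmm`.
#' @param length Number of nucleotides.
#' @return A DNA string.  Seed the RNG with `set.seed()` for reproducibility.
#' @export
sample_background <- function(hmm, length) {
  K <- hmm$K
  out <- character(0)
  pos <- 0
  state <- sample.int(K, 1)
  while (pos < length) {
    stay <- hmm$trans[state, state]
    run <- if (stay >= 1) length - pos else min(1 + stats::rgeom(1, 1 - stay), length - pos)
    out <- c(out, paste(sample(NT_ALPHABET, run, replace = TRUE,
                               prob = hmm$emis[state, ]), collapse = ""))
    pos <- pos + run
    if (K > 1) {
      p <- hmm$trans[state, ]
      p[state] <- 0
      state <- sample.int(K, 1, prob = p)
    }
  }
  paste(out, collapse = "")
}

#' Make a decoy coding sequence
#'
#' Shuffles the amino acids of a protein (destroying homology while keeping
#' composition) and reverse-translates it with uniformly chosen synonymous
#' codons, yielding a stop-free ORF in frame 0.
#'
#' @param protein Protein string.
#' @param code An `fh_genetic_code`.
#' @return A DNA string of length `3 * nchar(protein)`.
#' @export
make_decoy <- function(protein, code = genetic_code(1)) {
  chars <- strsplit(toupper(protein), "", fixed = TRUE)[[1]]
  reverse_translate(paste(sample(chars), collapse = ""), code)
}

#' Inject indels into a DNA sequence
#'
#' Each position independently starts an indel with probability `rate`;
#' insertions and deletions are equally likely and lengths are
#' 1 + Geometric(0.5) (an initiated indel extends with 50% probability), so
#' about 6/7 of indel lengths are not a multiple of 3.
#'
#' @param dna DNA string.
#' @param rate Per-nucleotide indel initiation probability.
#' @param ext Extension (continuation) probability.
#' @return List with `dna` (mutated sequence) and `events` (tibble with
#'   `position` in pre-mutation 0-based coordinates, `kind`, `length`).
#' @export
inject_indels <- function(dna, rate, ext = 0.5) {
  n <- nchar(dna)
  if (rate == 0 || n == 0) {
    return(list(dna = dna, events = tibble(position = integer(),
                                           kind = character(),
                                           length = integer())))
  }
  pos <- which(runif(n) < rate)
  if (length(pos) == 0) {
    return(list(dna = dna, events = tibble(position = integer(),
                                           kind = character(),
                                           length = integer())))
  }
  kind <- ifelse(runif(length(pos)) < 0.5, "insertion", "deletion")
  len <- 1L + stats::rgeom(length(pos), 1 - ext)
  events <- tibble(position = pos - 1L, kind = kind, length = as.integer(len))
  # apply right-to-left so earlier positions keep pre-mutation coordinates
  chars <- strsplit(dna, "", fixed = TRUE)[[1]]
  pieces <- list()
  prev <- n
  for (i in rev(seq_along(pos))) {
    p <- pos[i]  # 1-based position where the indel starts
    if (kind[i] == "insertion") {
      ins <- paste(sample(NT_ALPHABET, len[i], replace = TRUE), collapse = "")
      pieces[[length(pieces) + 1]] <- paste0(
        ins, paste(chars[p:prev][seq_len(prev - p + 1)], collapse = ""))
      prev <- p - 1
    } else {
      from <- min(p + len[i], prev + 1)
      if (from <= prev) {
        pieces[[length(pieces) + 1]] <- paste(chars[from:prev], collapse = "")
      } else {
        pieces[[length(pieces) + 1]] <- ""
      }
      prev <- p - 1
    }
  }
  if (prev >= 1) pieces[[length(pieces) + 1]] <- paste(chars[1:prev], collapse = "")
  list(dna = paste(rev(unlist(pieces)), collapse = ""), events = events)
}

#' Embed sequences into a background chromosome
#'
#' Insert positions are chosen uniformly (without overlap, since each insert
#' occupies its own point of the background and displaces the rest); each
#' insert lands on a random strand.
#'
#' @param background Background DNA string.
#' @param inserts Tibble with columns `seq`, `label`
#'   (`"family_instance"`/`"decoy"`), `family` (NA for decoys).
#' @return List with `chromosome` (DNA string) and `truth` (tibble with
#'   final 0-based half-open `start`/`end`, `label`, `family`, `strand`).
#' @export
embed_sequences <- function(background, inserts) {
  nb <- nchar(background)
  k <- nrow(inserts)
  if (k == 0) {
    return(list(chromosome = background,
                truth = tibble(start = integer(), end = integer(),
                               label = character(), family = character(),
                               strand = character())))
  }
  anchor <- sort(sample.int(nb + 1, k, replace = TRUE) - 1L)
  strand <- ifelse(runif(k) < 0.5, "+", "-")
  seqs <- ifelse(strand == "+", inserts$seq,
                 vapply(inserts$seq, revcomp, character(1)))
  lens <- nchar(seqs)
  starts <- anchor + c(0, cumsum(lens))[seq_len(k)]
  pieces <- character(2 * k + 1)
  prev <- 0
  for (i in seq_len(k)) {
    pieces[2 * i - 1] <- substr(background, prev + 1, anchor[i])
    pieces[2 * i] <- seqs[i]
    prev <- anchor[i]
  }
  pieces[2 * k + 1] <- substr(background, prev + 1, nb)
  list(chromosome = paste(pieces, collapse = ""),
       truth = tibble(start = as.integer(starts),
                      end = as.integer(starts + lens),
                      label = inserts$label, family = inserts$family,
                      strand = strand))
}

#' Sample a random protein family profile
#'
#' Each match state prefers one random amino acid (emission mass `peak` on
#' it, the remainder spread as background), with match-dominated
#' transitions.  Used to make synthetic query families without any external
#' alignment data.
#'
#' @param M Model length.
#' @param name Model name.
#' @param peak Emission probability of the preferred residue.
#' @return An `fh_profile`.
#' @export
sample_family_profile <- function(M, name = "family", peak = 0.6) {
  bg <- aa_background()
  pref <- sample.int(20, M, replace = TRUE, prob = bg)
  me <- matrix(rep((1 - peak) * bg, each = M), M, 20)
  me[cbind(seq_len(M), pref)] <- me[cbind(seq_len(M), pref)] + peak
  ie <- matrix(rep(bg, each = M), M, 20)
  tr <- matrix(rep(c(0.94, 0.03, 0.03, 0.65, 0.35, 0.65, 0.35), each = M),
               M, 7)
  new_profile(name, me, ie, tr)
}

#' Generate a synthetic translated-search benchmark
#'
#' Families are random profiles; test instances are sequences emitted from
#' each family model, reverse-translated, optionally trimmed to their middle
#' 50% (the overextension construction), mutated with indels, and embedded
#' together with shuffled reverse-translated decoys into background
#' pseudochromosomes.
#'
#' @param n_families,instances_per_family Family structure.
#' @param n_decoys Number of decoy ORFs.
#' @param indel_rate Per-nucleotide indel initiation rate (0 for none).
#' @param n_chrom,chrom_len Pseudochromosome count and background length.
#' @param mid50 Embed only the middle 50% of each instance.
#' @param M_range Family model lengths are drawn uniformly from this range.
#' @param seed Integer seed.
#' @return List with `queries` (list of calibrated-ready `fh_profile`s),
#'   `chromosomes` (tibble `id`, `seq`), `truth` (tibble with `chrom`,
#'   `start`, `end`, `label`, `family`, `strand`, plus per-instance indel
#'   counts).
#' @export
generate_benchmark <- function(n_families = 20, instances_per_family = 10,
                               n_decoys = 100, indel_rate = 0.02,
                               n_chrom = 10, chrom_len = 20000,
                               mid50 = FALSE, M_range = c(60, 90),
                               seed = 1) {
  set.seed(seed)
  code <- genetic_code(1)
  queries <- lapply(seq_len(n_families), function(f) {
    M <- sample(M_range[1]:M_range[2], 1)
    sample_family_profile(M, name = sprintf("fam%02d", f))
  })
  inserts <- list()
  for (f in seq_len(n_families)) {
    prof <- queries[[f]]
    for (i in seq_len(instances_per_family)) {
      prot <- sample_sequence(prof)
      dna <- reverse_translate(prot, code)
      if (mid50) {
        n <- nchar(dna)
        q1 <- floor(n / 4); q3 <- floor(3 * n / 4)
        dna <- substr(dna, q1 + 1, q3)
      }
      mut <- inject_indels(dna, indel_rate)
      inserts[[length(inserts) + 1]] <-
        tibble(seq = mut$dna, label = "family_instance",
               family = prof$name, n_indels = nrow(mut$events),
               n_frameshifts = sum(mut$events$length %% 3 != 0))
    }
  }
  aa_lens <- round(runif(n_decoys, 80, 200))
  for (d in seq_len(n_decoys)) {
    prot <- sample_background_peptides(1, aa_lens[d])
    inserts[[length(inserts) + 1]] <-
      tibble(seq = make_decoy(prot, code), label = "decoy",
             family = NA_character_, n_indels = 0L, n_frameshifts = 0L)
  }
  inserts <- do.call(rbind, inserts)
  inserts <- inserts[sample.int(nrow(inserts)), ]
  # deal inserts round-robin over chromosomes
  chrom_of <- rep_len(seq_len(n_chrom), nrow(inserts))
  hmm <- background_hmm()
  chroms <- character(n_chrom)
  truth <- list()
  for (c_i in seq_len(n_chrom)) {
    bgdna <- sample_background(hmm, chrom_len)
    emb <- embed_sequences(bgdna, inserts[chrom_of == c_i, ])
    chroms[c_i] <- emb$chromosome
    tr <- emb$truth
    tr$chrom <- sprintf("chr%02d", c_i)
    tr$n_indels <- inserts$n_indels[chrom_of == c_i]
    tr$n_frameshifts <- inserts$n_frameshifts[chrom_of == c_i]
    truth[[c_i]] <- tr
  }
  list(queries = queries,
       chromosomes = tibble(id = sprintf("chr%02d", seq_len(n_chrom)),
                            seq = chroms),
       truth = do.call(rbind, truth))
}

#' Write / read benchmark truth as BED6
#'
#' Columns: chrom, start, end, `label:family`, score 0, strand.
#' @param truth Truth tibble from [generate_benchmark()].
#' @param path File path.
#' @export
write_truth_bed <- function(truth, path) {
  name <- ifelse(is.na(truth$family), truth$label,
                 paste(truth$label, truth$family, sep = ":"))
  writeLines(paste(truth$chrom, truth$start, truth$end, name, 0, truth$strand,
                   sep = "\t"), path)
  invisible(path)
}

#' @rdname write_truth_bed
#' @export
read_truth_bed <- function(path) {
  m <- do.call(rbind, strsplit(readLines(path, warn = FALSE), "\t"))
  parts <- strsplit(m[, 4], ":", fixed = TRUE)
  tibble(chrom = m[, 1], start = as.integer(m[, 2]), end = as.integer(m[, 3]),
         label = vapply(parts, `[`, character(1), 1),
         family = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, character(1)),
         strand = m[, 6])
}

#' Classify hits against benchmark truth
#'
#' A hit is a true positive when it covers more than half of a same-family
#' embedded instance; a false positive when more than half of its alignment
#' lies in decoy or background sequence; ignored when more than half of its
#' alignment lies in an instance of a different family (homology cannot be
#' ruled out); remaining hits (e.g. small same-family fragments) are labeled
#' `partial` and excluded from both counts.
#'
#' @param hits Hit tibble (needs `query`, `target`, `dna_start`, `dna_end`,
#'   `evalue`).
#' @param truth Truth tibble from [generate_benchmark()].
#' @return The hits with columns `class` (`TP`/`FP`/`ignored`/`partial`) and
#'   `instance` (truth row index of the covered instance for TPs).
#' @export
classify_hits <- function(hits, truth) {
  n <- nrow(hits)
  cls <- character(n)
  inst <- rep(NA_integer_, n)
  truth_i <- seq_len(nrow(truth))
  for (i in seq_len(n)) {
    hs <- hits$dna_start[i]; he <- hits$dna_end[i]
    hlen <- he - hs
    tt <- truth[truth$chrom == hits$target[i], ]
    ti <- truth_i[truth$chrom == hits$target[i]]
    ov <- pmax(0, pmin(he, tt$end) - pmax(hs, tt$start))
    same_fam <- tt$label == "family_instance" & !is.na(tt$family) &
      tt$family == hits$query[i]
    # rule 1: covers >50% of a same-family instance
    cover <- ov / (tt$end - tt$start)
    if (any(same_fam & cover > 0.5)) {
      cls[i] <- "TP"
      best <- which(same_fam & cover > 0.5)
      inst[i] <- ti[best[which.max(ov[best])]]
      next
    }
    # rule 2: >50% of the alignment in decoy or background
    decoy_nt <- sum(ov[tt$label == "decoy"])
    bg_nt <- hlen - sum(ov)
    if ((decoy_nt + bg_nt) / hlen > 0.5) { cls[i] <- "FP"; next }
    # rule 3: >50% of the alignment in a different family's instance
    other_nt <- sum(ov[tt$label == "family_instance" & !same_fam])
    if (other_nt / hlen > 0.5) { cls[i] <- "ignored"; next }
    cls[i] <- "partial"
  }
  hits$class <- cls
  hits$instance <- inst
  hits
}

#' ROC table and recall before first false positive
#'
#' @param labeled Classified hits from [classify_hits()].
#' @param truth Truth tibble.
#' @return List with `roc` (tibble: cumulative `fp` count vs `recall`
#'   fraction of embedded instances, in E-value order) and `recall0`
#'   (tibble per family: recall at thresholds strictly better than that
#'   family's first FP; with no FP, overall recall).
#' @export
roc_and_recall0 <- function(labeled, truth) {
  inst <- truth[truth$label == "family_instance", ]
  n_inst <- nrow(inst)
  h <- labeled[order(labeled$evalue), ]
  is_tp_new <- h$class == "TP" & !duplicated(h$instance)
  roc <- tibble(evalue = h$evalue,
                fp = cumsum(h$class == "FP"),
                recall = cumsum(is_tp_new) / n_inst)
  fams <- unique(inst$family)
  recall0 <- do.call(rbind, lapply(fams, function(f) {
    hf <- h[h$query == f, ]
    n_f <- sum(inst$family == f)
    first_fp <- which(hf$class == "FP")[1]
    cutoff <- if (is.na(first_fp)) Inf else hf$evalue[first_fp]
    tp <- hf$class == "TP" & !duplicated(hf$instance) & hf$evalue < cutoff
    tibble(family = f, recall0 = sum(tp) / n_f)
  }))
  list(roc = roc, recall0 = recall0)
}

#' Per-instance alignment coverage
#'
#' For each embedded instance, the fraction of its nucleotides included in
#' at least one true-positive alignment (counted once), among hits with
#' E-value at or below `evalue_cut`.
#'
#' @param labeled Classified hits.
#' @param truth Truth tibble.
#' @param evalue_cut E-value threshold.
#' @return List with `per_instance` tibble (`instance`, `coverage`,
#'   `n_alignments`), `mean_coverage` (over covered instances), and
#'   `mean_alignments`.
#' @export
coverage_metrics <- function(labeled, truth, evalue_cut = 1e-5) {
  tps <- labeled[labeled$class == "TP" & labeled$evalue <= evalue_cut, ]
  inst_ids <- sort(unique(tps$instance))
  rows <- lapply(inst_ids, function(ii) {
    tr <- truth[ii, ]
    hh <- tps[tps$instance == ii, ]
    cov <- logical(tr$end - tr$start)
    for (r in seq_len(nrow(hh))) {
      a <- max(hh$dna_start[r], tr$start) - tr$start + 1
      b <- min(hh$dna_end[r], tr$end) - tr$start
      if (b >= a) cov[a:b] <- TRUE
    }
    tibble(instance = ii, coverage = mean(cov), n_alignments = nrow(hh))
  })
  per_instance <- if (length(rows)) do.call(rbind, rows) else
    tibble(instance = integer(), coverage = numeric(), n_alignments = integer())
  list(per_instance = per_instance,
       mean_coverage = if (nrow(per_instance)) mean(per_instance$coverage) else 0,
       mean_alignments = if (nrow(per_instance)) mean(per_instance$n_alignments) else 0)
}

#' Overextension metrics
#'
#' For each true-positive alignment, the number of aligned nucleotides
#' outside the truth span; alignments with `min_nt` or more are flagged as
#' overextended.
#'
#' @param labeled Classified hits.
#' @param truth Truth tibble.
#' @param min_nt Flagging threshold (4 = more than one codon... more than
#'   three nucleotides).
#' @param evalue_cut E-value threshold.
#' @return List with `per_alignment` tibble, `frac_overextended`, and
#'   `mean_overextension` (mean length among flagged alignments).
#' @export
overextension_metrics <- function(labeled, truth, min_nt = 4,
                                  evalue_cut = 1e-5) {
  tps <- labeled[labeled$class == "TP" & labeled$evalue <= evalue_cut, ]
  if (nrow(tps) == 0) {
    return(list(per_alignment = tibble(), frac_overextended = 0,
                mean_overextension = 0))
  }
  tr <- truth[tps$instance, ]
  left <- pmax(0, tr$start - tps$dna_start)
  right <- pmax(0, tps$dna_end - tr$end)
  ext <- left + right
  per <- tibble(instance = tps$instance, overextension = ext,
                flagged = ext >= min_nt)
  list(per_alignment = per,
       frac_overextended = mean(per$flagged),
       mean_overextension = if (any(per$flagged)) mean(per$overextension[per$flagged]) else 0)
}

#' E-value accuracy experiment
#'
#' Generates random amino-acid sequences of length `aa_len`, reverse-
#' translates them (guaranteeing a full-length frame-0 ORF), and searches
#' them with calibrated profiles in all three arbitration modes.  If
#' E-values are accurate, the number of hits with E <= x is about
#' `(number of queries) * x` regardless of target set size.
#'
#' @param profiles List of `fh_profile`s (calibrated automatically).
#' @param n_targets Number of random targets.
#' @param aa_len Protein length per target (DNA length is 3x).
#' @param xs E-value thresholds to tabulate.
#' @param config Base `fh_config` (mode is overridden internally).
#' @param seed Integer seed.
#' @param chunk_size Targets per processing chunk.
#' @return Tibble with `mode`, `x`, `expected`, `actual`.
#' @export
evalue_experiment <- function(profiles, n_targets = 1e5, aa_len = 400,
                              xs = c(0.1, 1, 10), config = search_config(
                                report_evalue_max = 100),
                              seed = 7, chunk_size = 2000) {
  set.seed(seed)
  qs <- prepare_queries(profiles, config)
  code <- genetic_code(config$genetic_code_id)
  db_nt <- n_targets * 3 * aa_len
  modes <- c("default", "nofs", "fsonly")
  counts <- matrix(0, length(modes), length(xs),
                   dimnames = list(modes, as.character(xs)))
  done <- 0
  while (done < n_targets) {
    nb <- min(chunk_size, n_targets - done)
    prots <- sample_background_peptides(nb, aa_len)
    seqs <- reverse_translate_batch(prots, code)
    ids <- sprintf("rt%07d", done + seq_len(nb))
    orfs <- six_frame_orfs_batch(setNames(seqs, ids), code, config)
    attr(orfs, "target_seqs") <- setNames(as.list(seqs), ids)
    tlen <- setNames(as.list(nchar(seqs)), ids)
    enc <- encode_peptides(orfs$peptide)
    for (q in qs) {
      cand <- search_candidates(q, orfs, tlen, config, enc)
      if (is.null(cand)) next
      for (m in modes) {
        cfg <- config
        cfg$mode <- m
        h <- postprocess_candidates(q, cand, db_nt, cfg)
        if (is.null(h)) next
        h <- dedup_hits(h)
        for (xi in seq_along(xs)) {
          counts[m, xi] <- counts[m, xi] + sum(h$evalue <= xs[xi])
        }
      }
    }
    done <- done + nb
  }
  out <- list()
  for (m in modes) for (xi in seq_along(xs)) {
    out[[length(out) + 1]] <- tibble(mode = m, x = xs[xi],
                                     expected = length(qs) * xs[xi],
                                     actual = counts[m, xi])
  }
  do.call(rbind, out)
}
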