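# Dynamic-programming engines: protein MSV/Viterbi/Forward and the
# frameshift-aware codon-space Forward/Backward/posterior/Viterbi, checked
# against explicit path enumeration.

test_that("MSV single-residue score matches hand arithmetic on a 1-state model", {
  prof <- fixture_rough_profile(1, seed = 31)
  a <- which.max(prof$match_emissions[1, ])
  pep <- framehmm:::AA_ALPHABET[a]
  # one path: N -> B -> M1 -> E -> C -> T with n = 1
  nmove <- log(3 / 4); ec <- log(0.5); cmove <- nmove
  entry <- log(2 * 1 / (1 * 2))
  em <- log(unname(prof$match_emissions[1, a]) / unname(prof$background[a]))
  nullsc <- 1 * log(1 / 2) + log(1 / 2)
  expected <- (nmove + entry + em + ec + cmove - nullsc) / log(2)
  expect_equal(msv_score(prof, pep), expected, tolerance = 1e-12)
  # and MSV = Viterbi = Forward on a single-path instance
  expect_equal(viterbi_score_protein(prof, pep), expected, tolerance = 1e-12)
  expect_equal(forward_protein(prof, pep), expected, tolerance = 1e-12)
})

test_that("consensus of a peaked profile scores positive under MSV", {
  prof <- fixture_peaked_profile("MKVAWLYEHD")
  expect_gt(msv_score(prof, "MKVAWLYEHD"), 0)
  expect_equal(msv_score(prof, ""), -Inf)
})

test_that("protein Viterbi and Forward match exhaustive path enumeration", {
  set.seed(32)
  for (trial in 1:6) {
    M <- sample(1:2, 1)
    n <- sample(1:4, 1)
    prof <- fixture_rough_profile(M, seed = 320 + trial)
    pep <- paste(sample(framehmm:::AA_ALPHABET, n, replace = TRUE),
                 collapse = "")
    o <- oracle_protein(prof, pep)
    expect_equal(forward_protein(prof, pep), o$forward_bits, tolerance = 1e-9)
    expect_equal(viterbi_score_protein(prof, pep), o$viterbi_bits,
                 tolerance = 1e-9)
  }
})

test_that("Viterbi never exceeds Forward", {
  set.seed(33)
  prof <- fixture_rough_profile(15, seed = 33)
  for (i in 1:10) {
    pep <- paste(sample(framehmm:::AA_ALPHABET, sample(5:60, 1),
                        replace = TRUE), collapse = "")
    expect_lte(viterbi_score_protein(prof, pep), forward_protein(prof, pep))
  }
})

test_that("MSV null scores match the calibrated Gumbel near the operating tail", {
  # the Gumbel is anchored at the filter operating point, so accuracy is
  # asserted on tail probabilities around it rather than bulk uniformity
  prof <- fixture_profile(30, seed = 34)
  prof <- calibrate(prof, n = 2000, seed = 35)
  cal <- prof$calibration
  set.seed(36)
  peps <- framehmm:::sample_background_peptides(2000, 60)
  p <- gumbel_pvalue(msv_score(prof, peps), cal$msv_mu, cal$msv_lambda)
  for (thr in c(0.05, 0.02, 0.01)) {
    tol <- 3 * sqrt(thr * (1 - thr) / 2000 + (thr / sqrt(thr * 2000))^2)
    expect_lt(abs(mean(p <= thr) - thr), tol)
  }
})

test_that("emission cache records chunk classes and completion candidates", {
  prof <- fixture_rough_profile(3, seed = 37)
  cp <- make_codon_profile(prof)
  cache <- build_emission_cache("ATG", cp)
  row <- cache[cache$j == 3 & cache$len == 3, ]
  expect_equal(row$class, "sense")
  expect_equal(row$aa, "M")
  cache2 <- build_emission_cache("TGA", cp)
  row2 <- cache2[cache2$j == 3 & cache2$len == 3, ]
  expect_equal(row2$class, "stop")
  expect_equal(row2$stop, "TGA")
  # the cached candidate set for the "CA" prefix equals the completion set
  cache3 <- build_emission_cache("CAG", cp)
  row3 <- cache3[cache3$j == 2 & cache3$len == 2, ]
  expect_equal(row3$candidates[[1]], completion_set("ca"))
  # N-containing chunks are neutral
  cache4 <- build_emission_cache("ANG", cp)
  expect_true(all(cache4$class[cache4$j == 2] == "neutral"))
})

test_that("FA Forward/Backward/Viterbi agree with enumeration on small instances", {
  set.seed(38)
  for (trial in 1:8) {
    M <- sample(1:2, 1)
    n <- sample(2:6, 1)
    prof <- fixture_rough_profile(M, seed = 380 + trial)
    cp <- make_codon_profile(prof)
    win <- paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
                        prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
    o_r <- oracle_fa(cp, win)
    o_c <- fa_reference_scores(cp, win)
    expect_equal(o_c$forward_bits, o_r$forward_bits, tolerance = 1e-9)
    expect_equal(o_c$n_paths, o_r$n_paths)
    expect_equal(as.numeric(fa_forward(cp, win)), o_r$forward_bits,
                 tolerance = 1e-9)
    expect_equal(fa_backward(cp, win), o_r$forward_bits, tolerance = 1e-6)
    expect_equal(fa_viterbi_path(cp, win)$bits, o_r$viterbi_bits,
                 tolerance = 1e-9)
  }
})

test_that("memoized and naive FA engines are bit-identical", {
  set.seed(39)
  prof <- fixture_rough_profile(12, seed = 39)
  cp <- make_codon_profile(prof)
  for (i in 1:5) {
    win <- paste(sample(c("A", "C", "G", "T", "N"), sample(20:80, 1),
                        replace = TRUE, prob = c(rep(0.245, 4), 0.02)),
                 collapse = "")
    fc <- fa_forward(cp, win, use_cache = TRUE)
    fn <- fa_forward(cp, win, use_cache = FALSE)
    expect_identical(as.numeric(fc), as.numeric(fn))
    # the cache decodes each chunk once; the naive engine once per state
    expect_lt(attr(fc, "n_decodes"), attr(fn, "n_decodes"))
  }
})

test_that("FA Forward equals Backward and posteriors normalize", {
  set.seed(40)
  prof <- fixture_rough_profile(8, seed = 40)
  cp <- make_codon_profile(prof)
  for (i in 1:4) {
    win <- paste(sample(c("A", "C", "G", "T"), sample(15:60, 1),
                        replace = TRUE), collapse = "")
    po <- fa_posterior(cp, win)
    expect_equal(po$fwd_bits, po$bwd_bits, tolerance = 1e-6)
    expect_true(all(abs(po$core + po$flank - 1) < 1e-6))
    expect_true(all(po$core >= -1e-9 & po$core <= 1 + 1e-9))
  }
})

test_that("posterior decoding separates a strong hit from pure background", {
  set.seed(41)
  prof <- fixture_profile(40, seed = 41, peak = 0.8)
  cp <- make_codon_profile(prof)
  code <- genetic_code(1)
  inst <- reverse_translate(sample_sequence(prof), code)
  flank1 <- paste(sample(c("A", "C", "G", "T"), 45, replace = TRUE), collapse = "")
  flank2 <- paste(sample(c("A", "C", "G", "T"), 45, replace = TRUE), collapse = "")
  win <- paste0(flank1, inst, flank2)
  po <- fa_posterior(cp, win)
  mid <- (45 + 10):(45 + nchar(inst) - 10)
  expect_gt(mean(po$core[mid] > 0.9), 0.9)
  bg_win <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE), collapse = "")
  po_bg <- fa_posterior(cp, bg_win)
  # pure background: posterior mostly below the envelope threshold (weak
  # local fluctuations keep the mean above the idealized <0.1-everywhere)
  expect_lt(mean(po_bg$core > 0.5), 0.2)
  expect_lt(mean(po_bg$core), 0.35)
  expect_gt(mean(po$core[mid]), mean(po_bg$core) + 0.5)
})

test_that("FA Viterbi path structure: in-frame, frameshift recovery, tiling", {
  set.seed(42)
  prof <- fixture_peaked_profile(
    paste(sample(framehmm:::AA_ALPHABET, 30, replace = TRUE), collapse = ""),
    peak = 0.95)
  cp <- make_codon_profile(prof)
  code <- genetic_code(1)
  inst <- reverse_translate(consensus_sequence(prof)$seq, code)

  vp <- fa_viterbi_path(cp, inst)
  expect_equal(vp$frameshift_count, 0)

  # delete one nucleotide mid-instance: exactly one quasi-codon step near it
  del_at <- 46
  mut <- paste0(substr(inst, 1, del_at - 1), substr(inst, del_at + 1, nchar(inst)))
  vp2 <- fa_viterbi_path(cp, mut)
  expect_equal(vp2$frameshift_count, 1)
  qstep <- vp2$path[vp2$path$class == "quasi2", ]
  expect_equal(nrow(qstep), 1)
  expect_lte(abs(qstep$from - (del_at - 1)), 6)  # within +-2 codons

  # consumed spans tile the window
  core <- vp2$path
  core <- core[order(core$from), ]
  expect_true(all(core$from <= core$to))
  emitting <- core[core$kind != "D", ]
  expect_equal(sum(emitting$to - emitting$from), nchar(mut))
  expect_true(all(emitting$from[-1] == head(emitting$to, -1)))
})

test_that("in-frame FA and protein scores agree after composition accounting", {
  set.seed(43)
  prof <- fixture_profile(25, seed = 43, peak = 0.9)
  cp <- make_codon_profile(prof)
  code <- genetic_code(1)
  pep <- sample_sequence(prof)
  dna <- reverse_translate(pep, code)
  dv <- fa_viterbi_path(cp, dna)$bits - viterbi_score_protein(prof, pep)
  ai <- match(strsplit(pep, "")[[1]], framehmm:::AA_ALPHABET)
  comp <- sum(log2(0.96 * 64 * prof$background[ai] / cp$n_syn[ai]))
  # the per-residue decomposition holds up to flank/length-model differences
  expect_lt(abs(dv - comp), 2.5)
})

test_that("lowering the length-2 penalty lowers frameshifted alignments only", {
  set.seed(44)
  prof <- fixture_profile(30, seed = 44, peak = 0.8)
  code <- genetic_code(1)
  inst <- reverse_translate(sample_sequence(prof), code)
  mut <- paste0(substr(inst, 1, 40), substr(inst, 42, nchar(inst)))
  cp_hi <- make_codon_profile(prof, frameshift_penalties())
  cp_lo <- make_codon_profile(prof, frameshift_penalties(p2 = 0.001))
  v_hi <- fa_viterbi_path(cp_hi, mut)
  v_lo <- fa_viterbi_path(cp_lo, mut)
  if (v_hi$frameshift_count > 0 && v_lo$frameshift_count > 0) {
    expect_lt(v_lo$bits, v_hi$bits)
  }
  # in-frame alignments are barely affected (only via the norm scale)
  v0_hi <- fa_viterbi_path(cp_hi, inst)$bits
  v0_lo <- fa_viterbi_path(cp_lo, inst)$bits
  expect_lt(abs(v0_hi - v0_lo), 1)
})
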