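# Genetic code machinery, quasi-codon completion sets, stop-codon neighbor
# scores, penalties, and the derived codon profile.

test_that("genetic_code returns standard and alternative tables", {
  g1 <- genetic_code(1)
  expect_length(g1$codon_to_aa, 64)
  expect_equal(unname(g1$codon_to_aa["ATG"]), "M")
  expect_equal(sort(g1$stop_codons), c("TAA", "TAG", "TGA"))
  g4 <- genetic_code(4)
  expect_equal(unname(g4$codon_to_aa["TGA"]), "W")
  g11 <- genetic_code(11)
  expect_length(g11$stop_codons, 3)
  expect_error(genetic_code(99999), "unknown")
})

test_that("completion_set matches the worked quasi-codon example and edge cases", {
  expect_equal(completion_set("ca"), c("A", "H", "L", "P", "Q", "R", "S", "T"))
  expect_equal(completion_set("aaaa"), "K")
  # length-1 set: union over all codons containing the base, minus stops
  t_set <- completion_set("t")
  expect_true(all(c("F", "L", "S", "Y", "C", "W") %in% t_set))
  expect_false("*" %in% t_set)
  expect_error(completion_set("cat"), "codons, not quasi")
})

test_that("completion_set agrees with explicit insertion/deletion enumeration", {
  code <- genetic_code(1)
  nts <- c("A", "C", "G", "T")
  brute <- function(q) {
    qc <- strsplit(q, "")[[1]]
    L <- length(qc)
    grow <- function(strs) {
      # insert one nucleotide at every position into every string
      unique(unlist(lapply(strs, function(s) {
        sc <- strsplit(s, "")[[1]]
        unlist(lapply(0:length(sc), function(pos) {
          paste0(paste(head(sc, pos), collapse = ""), nts,
                 paste(tail(sc, length(sc) - pos), collapse = ""))
        }))
      })))
    }
    shrink <- function(strs) {
      unique(unlist(lapply(strs, function(s) {
        sc <- strsplit(s, "")[[1]]
        vapply(seq_along(sc), function(pos)
          paste(sc[-pos], collapse = ""), character(1))
      })))
    }
    cods <- toupper(q)
    while (nchar(cods[1]) < 3) cods <- toupper(grow(cods))
    while (nchar(cods[1]) > 3) cods <- shrink(cods)
    aa <- unique(code$codon_to_aa[cods])
    sort(aa[aa != "*"])
  }
  # exhaustive over every quasi-codon up to length 5
  for (L in c(1, 2, 4, 5)) {
    qs <- apply(expand.grid(rep(list(nts), L)), 1, paste, collapse = "")
    for (q in qs) {
      expect_equal(completion_set(q, code), brute(q), info = q)
    }
  }
})

test_that("stop_neighbor_score follows the Hamming-1 rule", {
  pen <- frameshift_penalties()
  unif <- rep(1 / 20, 20)
  expect_equal(stop_neighbor_score("TGA", unif, pen), pen$p_stop / 20)

  peakW <- setNames(rep(1e-4, 20), framehmm:::AA_ALPHABET)
  peakW["W"] <- 1 - 19e-4
  # TGG (W) is one substitution from TGA
  expect_equal(stop_neighbor_score("TGA", peakW, pen),
               pen$p_stop * peakW[["W"]])

  # a residue two substitutions away cannot be selected: peak on M (ATG),
  # which is Hamming distance 2 from TAA
  peakM <- setNames(rep(1e-4, 20), framehmm:::AA_ALPHABET)
  peakM["M"] <- 1 - 19e-4
  code <- genetic_code(1)
  neigh <- framehmm:::stop_neighbor_aas("TAA", code)
  expect_false(match("M", framehmm:::AA_ALPHABET) %in% neigh)
  best <- max(peakM[neigh])
  expect_equal(stop_neighbor_score("TAA", unname(peakM), pen), pen$p_stop * best)
})

test_that("default penalties give norm exactly 0.96", {
  pen <- frameshift_penalties()
  expect_equal(pen$norm, 0.96, tolerance = 1e-12)
  expect_equal(pen$norm, 1 - (0.01 + 0.01 + 0.01 + 0.005 + 0.005))
})

test_that("codon profile scores: sense scaling, penalty bounds, normalization", {
  prof <- fixture_rough_profile(4, seed = 7)
  pen <- frameshift_penalties()
  code <- genetic_code(1)
  cp <- make_codon_profile(prof, pen, code)

  # sense codon score = norm * em(aa) / n_synonyms(aa), exactly
  aa_idx <- framehmm:::codon_aa_indices(code)
  for (cod in c("ATG", "AAA", "CTG", "TGG")) {
    ci <- framehmm:::codon_index(cod) + 1L
    aa <- aa_idx[ci]
    expect_equal(codon_score(cp, 2, cod),
                 pen$norm * prof$match_emissions[2, aa] / cp$n_syn[aa],
                 tolerance = 1e-12, info = cod)
  }
  # summed over all sense codons, each state's sense mass is exactly norm
  sense_sum <- sum(vapply(framehmm:::all_codons()[aa_idx > 0],
                          function(cod) codon_score(cp, 3, cod), numeric(1)))
  expect_equal(sense_sum, pen$norm, tolerance = 1e-9)

  # every quasi-codon class sums to its penalty and no single quasi-codon
  # or stop codon exceeds its penalty
  for (L in c(1, 2, 4, 5)) {
    qs <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), L)), 1,
                paste, collapse = "")
    v <- vapply(qs, function(q) codon_score(cp, 1, q), numeric(1))
    pL <- switch(as.character(L), `1` = pen$p1, `2` = pen$p2,
                 `4` = pen$p4, `5` = pen$p5)
    expect_equal(sum(v), pL, tolerance = 1e-9)
    expect_lte(max(v), pL)
  }
  stops <- vapply(code$stop_codons, function(s) codon_score(cp, 1, s), numeric(1))
  expect_lte(max(stops), pen$p_stop)

  # quasi scores at a state peaked on Q track the completion-set maximum
  pq <- fixture_peaked_profile("Q")
  cpq <- make_codon_profile(pq, pen, code)
  v_ca <- codon_score(cpq, 1, "CA")
  v_gg <- codon_score(cpq, 1, "GG")   # completion set of GG excludes Q
  expect_gt(v_ca, v_gg)

  # zero penalty for length-2 quasi-codons kills them and raises norm
  pen0 <- frameshift_penalties(p2 = 0)
  expect_equal(pen0$norm, 0.97, tolerance = 1e-12)
  cp0 <- make_codon_profile(prof, pen0, code)
  expect_equal(codon_score(cp0, 1, "CA"), 0)
  expect_equal(codon_score(cp0, 1, "ATG"),
               codon_score(cp, 1, "ATG") * 0.97 / 0.96, tolerance = 1e-12)
})

test_that("make_codon_profile is a pure function of its inputs", {
  prof <- fixture_rough_profile(3, seed = 8)
  a <- make_codon_profile(prof)
  b <- make_codon_profile(prof)
  expect_identical(a$match$lsense, b$match$lsense)
  expect_identical(a$match$lquasi, b$match$lquasi)
  expect_identical(a$match$lstop, b$match$lstop)
})

test_that("translate_dna handles frames, strands, N, and bad input", {
  expect_equal(translate_dna("ATGAAATAG", frame = 0), "MK*")
  expect_equal(translate_dna("ATGAAATAG", frame = 1), "*N")  # TGA AAT ag
  expect_equal(translate_dna("CAT", strand = "-"), "M")      # revcomp ATG
  expect_equal(translate_dna("ATGNNATAG", frame = 0), "MX*")
  expect_error(translate_dna("ATGR"), "non-ACGTN")
  g4 <- genetic_code(4)
  expect_equal(translate_dna("TGA", g4), "W")
})

test_that("reverse translation inverts translation and is stop-free", {
  set.seed(5)
  code <- genetic_code(1)
  prots <- framehmm:::sample_background_peptides(20, 30)
  dna <- reverse_translate_batch(prots, code)
  expect_true(all(nchar(dna) == 90))
  for (i in seq_along(prots)) {
    expect_equal(translate_dna(dna[i], code), prots[i])
  }
})
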