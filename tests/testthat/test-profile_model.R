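# Profile construction from alignments and sequences, consensus, the
# emitted-length distribution, and model sampling.

msa_of <- function(rows, ids = sprintf("s%d", seq_along(rows))) {
  framehmm:::new_msa("test", ids, rows)
}

test_that("build_from_msa: match columns, argmax, duplicate-row idempotence", {
  p <- build_from_msa(msa_of("ACD"))
  expect_equal(p$M, 3)
  expect_equal(which.max(p$match_emissions[1, ]), c(A = 1))
  # the 20-count background prior outweighs rare residues in a 1-row MSA, so
  # the consensus is checked on the single-sequence builder instead
  expect_equal(consensus_sequence(build_from_sequence("ACD"))$seq, "ACD")

  p2 <- build_from_msa(msa_of(c("ACD", "ACD")))
  expect_equal(p2$match_emissions, p$match_emissions, tolerance = 1e-12)
  expect_equal(p2$transitions, p$transitions, tolerance = 1e-12)

  # a column with gap fraction >= 0.5 is not a match state
  rows <- c("AC-D", "AC-D", "ACWD", "A-CD")  # col 3: gaps 2/4 = 0.5 -> insert
  p3 <- build_from_msa(msa_of(rows))
  expect_equal(p3$M, 3)

  expect_error(build_from_msa(msa_of(c("--", "--"))), "no match columns")
})

test_that("build_from_msa is invariant to row order", {
  rows <- c("ACDEF", "AC-EF", "GCDEF", "ACDEY")
  p1 <- build_from_msa(msa_of(rows))
  p2 <- build_from_msa(msa_of(rev(rows), ids = sprintf("s%d", 4:1)))
  expect_equal(p1$match_emissions, p2$match_emissions, tolerance = 1e-12)
  expect_equal(p1$transitions, p2$transitions, tolerance = 1e-12)
})

test_that("build_from_sequence uses BLOSUM62 conditionals", {
  p <- build_from_sequence("W", name = "w")
  expect_equal(p$M, 1)
  expect_equal(which.max(p$match_emissions[1, ]), c(W = 19))

  p2 <- build_from_sequence("AA")
  expect_equal(p2$match_emissions[1, ], p2$match_emissions[2, ])
  expect_true(all(abs(rowSums(p2$match_emissions) - 1) < 1e-9))

  # X residue falls back to background emissions
  p3 <- build_from_sequence("XK")
  expect_equal(unname(p3$match_emissions[1, ]),
               unname(framehmm:::aa_background()), tolerance = 1e-12)
})

test_that("consensus breaks ties toward the alphabetically first residue", {
  me <- matrix(1 / 20, 1, 20)
  ie <- me
  tr <- matrix(c(1, 0, 0, 1, 0, 1, 0), 1, 7)
  p <- new_profile("u", me, ie, tr)
  expect_equal(consensus_sequence(p)$seq, "A")
})

test_that("emitted_length_tail: degenerate and geometric-insert cases", {
  # all-MM profile: emitted length is exactly M
  p <- fixture_peaked_profile("MKVAW")
  p$transitions[, ] <- matrix(rep(c(1, 0, 0, 1, 0, 1, 0), each = 5), 5, 7)
  p <- emitted_length_tail(p, 1e-7)
  expect_equal(p$max_len_aa, 5L)
  dist <- attr(p, "length_distribution")
  expect_equal(dist[6], 1, tolerance = 1e-12)   # P(len = 5) = 1

  # single insert loop: closed-form geometric tail
  # M = 2; node 1: MI = 0.3, II = 0.5 -> P(len > L) = MI * II^(L-2), L >= 2
  q <- fixture_peaked_profile("MK")
  q$transitions[1, ] <- c(0.7, 0.3, 0, 0.5, 0.5, 1, 0)
  closed_form_L <- function(tm) {
    L <- 2
    while (0.3 * 0.5^(L - 2) > tm) L <- L + 1
    L
  }
  for (tm in c(1e-3, 1e-5, 1e-7)) {
    qq <- emitted_length_tail(q, tm)
    expect_equal(qq$max_len_aa, closed_form_L(tm),
                 info = paste("tail mass", tm))
    dist <- attr(qq, "length_distribution")
    expect_lte(1 - sum(dist[seq_len(qq$max_len_aa + 1)]), tm)
    expect_gte(sum(dist), 1 - tm)
  }

  # smaller tail mass can only increase L
  r <- fixture_rough_profile(8, seed = 5)
  L3 <- emitted_length_tail(r, 1e-3)$max_len_aa
  L7 <- emitted_length_tail(r, 1e-7)$max_len_aa
  expect_gte(L7, L3)

  expect_error(emitted_length_tail(q, 1e-7, cap = 4), "cap")
})

test_that("sample_sequence is reproducible and respects the model", {
  p <- fixture_peaked_profile("MKV")
  p$transitions[, ] <- matrix(rep(c(1, 0, 0, 1, 0, 1, 0), each = 3), 3, 7)
  set.seed(11)
  s <- sample_sequence(p, 200)
  expect_true(all(nchar(s) == 3))           # insert-free: length = M
  expect_gte(mean(s == "MKV"), 0.99)        # (0.999)^3 per sequence

  set.seed(42); a <- sample_sequence(fixture_rough_profile(6, 2), 5)
  set.seed(42); b <- sample_sequence(fixture_rough_profile(6, 2), 5)
  expect_identical(a, b)
})
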