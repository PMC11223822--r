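# The staged search pipeline end to end on planted synthetic instances.

make_planted <- function(seed, M = 60, flank = 1500, delete_at = NULL,
                         strand = "+") {
  set.seed(seed)
  prof <- sample_family_profile(M, name = "fam")
  code <- genetic_code(1)
  inst <- reverse_translate(sample_sequence(prof), code)
  if (!is.null(delete_at)) {
    inst <- paste0(substr(inst, 1, delete_at - 1),
                   substr(inst, delete_at + 1, nchar(inst)))
  }
  hmm <- background_hmm()
  bg1 <- sample_background(hmm, flank)
  bg2 <- sample_background(hmm, flank)
  target <- paste0(bg1, if (strand == "+") inst else framehmm:::revcomp(inst), bg2)
  list(profile = prof, target = target, inst_start = flank,
       inst_end = flank + nchar(inst))
}

test_that("select_window sizes, clips, and always contains the seed", {
  prof <- fixture_profile(40, seed = 60)
  prof$max_len_aa <- 50L
  w <- select_window(10000, 5000, 5100, prof)
  expect_equal(w[2] - w[1], 3 * 50 + 30)
  expect_true(w[1] <= 5000 && w[2] >= 5100)
  w2 <- select_window(10000, 5, 95, prof)
  expect_equal(w2[1], 0)
  w3 <- select_window(130, 10, 120, prof)
  expect_true(w3[1] <= 10 && w3[2] >= 120 && w3[2] <= 130)
})

test_that("define_envelope finds the high-posterior span", {
  post <- rep(0.01, 120)
  post[31:90] <- 0.99
  expect_equal(define_envelope(post), c(30L, 90L))
  expect_null(define_envelope(rep(0.4, 50)))
  # lowering the threshold can only widen the envelope
  post2 <- c(rep(0.3, 10), rep(0.7, 20), rep(0.3, 10))
  e5 <- define_envelope(post2, 0.5)
  e2 <- define_envelope(post2, 0.25)
  expect_true(e2[1] <= e5[1] && e2[2] >= e5[2])
})

test_that("a clean planted instance is found via the standard path", {
  pl <- make_planted(61)
  cfg <- search_config(seed = 601)
  hits <- run_search(pl$profile, c(chr = pl$target), cfg)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$path_used, "standard")
  expect_equal(hits$frameshift_count, 0L)
  expect_lt(hits$evalue, 1e-6)
  # reported span covers most of the instance and stays near it
  ov <- min(hits$dna_end, pl$inst_end) - max(hits$dna_start, pl$inst_start)
  expect_gt(ov / (pl$inst_end - pl$inst_start), 0.8)
  # step-7 gate and arbitration invariants
  expect_false(hits$F0 > cfg$fwd_pthresh && hits$F1 > cfg$fwd_pthresh)
  expect_true(xor(hits$F0 <= hits$F1, hits$path_used == "frameshift_aware"))
})

test_that("a frameshifted instance yields one frameshift-aware hit", {
  pl <- make_planted(62, delete_at = 80)
  hits <- run_search(pl$profile, c(chr = pl$target), search_config(seed = 602))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$path_used, "frameshift_aware")
  expect_gte(hits$frameshift_count, 1L)
  # the alignment spans material on both sides of the deletion
  expect_lt(hits$dna_start, pl$inst_start + 60)
  expect_gt(hits$dna_end, pl$inst_start + 100)
})

test_that("minus-strand instances are reported in forward coordinates", {
  pl <- make_planted(63, strand = "-")
  hits <- run_search(pl$profile, c(chr = pl$target), search_config(seed = 603))
  expect_gte(nrow(hits), 1)
  expect_equal(hits$strand[1], "-")
  ov <- min(hits$dna_end[1], pl$inst_end) - max(hits$dna_start[1], pl$inst_start)
  expect_gt(ov / (pl$inst_end - pl$inst_start), 0.7)
})

test_that("empty inputs give empty results", {
  prof <- fixture_profile(20, seed = 64)
  hits <- run_search(prof, tibble::tibble(id = character(), seq = character()),
                     search_config(seed = 604))
  expect_equal(nrow(hits), 0)
})

test_that("nofs and default agree on indel-free instances up to P-value noise", {
  pl <- make_planted(65)
  h_def <- run_search(pl$profile, c(chr = pl$target),
                      search_config(mode = "default", seed = 605))
  h_nofs <- run_search(pl$profile, c(chr = pl$target),
                       search_config(mode = "nofs", seed = 605))
  # same hit either way: one significant match over the planted instance;
  # the arbitration may land on either path (F0 vs F1 is a coin flip on
  # clean data) but never calls frameshifts there
  expect_equal(nrow(h_def), nrow(h_nofs))
  expect_equal(h_def$frameshift_count[1], 0L)
  ov <- min(h_def$dna_end[1], h_nofs$dna_end[1]) -
    max(h_def$dna_start[1], h_nofs$dna_start[1])
  expect_gt(ov / (h_nofs$dna_end[1] - h_nofs$dna_start[1]), 0.7)
  expect_lt(abs(log10(h_def$evalue[1]) - log10(h_nofs$evalue[1])), 6)
})

test_that("fsonly forces the frameshift-aware path", {
  pl <- make_planted(66)
  h <- run_search(pl$profile, c(chr = pl$target),
                  search_config(mode = "fsonly", seed = 606))
  expect_gte(nrow(h), 1)
  expect_true(all(h$path_used == "frameshift_aware"))
})

test_that("rescore_envelope reproduces the reported score", {
  pl <- make_planted(67)
  cfg <- search_config(seed = 607)
  qs <- framehmm:::prepare_queries(pl$profile, cfg)
  hits <- run_search(qs[[1]]$profile, c(chr = pl$target), cfg)
  rs <- rescore_envelope(qs[[1]], hits[1, ], nchar(pl$target), cfg)
  expect_equal(rs$score, hits$score[1], tolerance = 1e-9)
  expect_equal(rs$evalue, hits$evalue[1], tolerance = 1e-9)
  expect_true(is.finite(rs$score))
})

test_that("render_alignment produces the four-row block", {
  pl <- make_planted(68, delete_at = 75)
  hits <- run_search(pl$profile, c(chr = pl$target),
                     search_config(mode = "fsonly", seed = 608))
  expect_equal(hits$path_used[1], "frameshift_aware")
  txt <- render_alignment(hits[1, ], pl$profile, pl$target)
  rows <- strsplit(txt, "\n")[[1]]
  rows <- rows[nzchar(rows)]
  expect_equal(length(rows) %% 4, 0)
  # identity columns show the residue; the quasi-codon is lowercase in row 4
  expect_match(txt, "[a-z]")
  # a standard-path hit renders too (needs the target sequence for codons)
  pl2 <- make_planted(69)
  hits2 <- run_search(pl2$profile, c(chr = pl2$target),
                      search_config(mode = "nofs", seed = 609))
  expect_equal(hits2$path_used[1], "standard")
  txt2 <- render_alignment(hits2[1, ], pl2$profile, pl2$target)
  expect_gt(nchar(txt2), 100)
  rows2 <- strsplit(txt2, "\n")[[1]]
  # match row marks identities with the residue letter
  expect_true(any(grepl("[A-Z]", rows2[seq(2, length(rows2), by = 5)])))
})
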