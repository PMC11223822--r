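# Benchmark generation (background HMM, decoys, indels, embedding) and
# evaluation (classification, ROC/recall-0, coverage, overextension).

test_that("background sampling: composition, determinism, GC autocorrelation", {
  h1 <- background_hmm(K = 1, gc_range = c(0.5, 0.5))
  set.seed(70)
  s <- sample_background(h1, 100000)
  tab <- table(strsplit(s, "")[[1]]) / 100000
  expect_true(all(abs(tab - 0.25) < 0.01))

  set.seed(71); a <- sample_background(background_hmm(), 5000)
  set.seed(71); b <- sample_background(background_hmm(), 5000)
  expect_identical(a, b)

  # two sticky states with different GC -> positive long-range correlation
  h2 <- background_hmm(K = 2, stay = 0.99, gc_range = c(0.3, 0.7))
  set.seed(72)
  s2 <- sample_background(h2, 50000)
  gc <- strsplit(s2, "")[[1]] %in% c("G", "C")
  lag <- 50
  expect_gt(stats::cor(gc[1:(50000 - lag)], gc[(lag + 1):50000]), 0.02)
})

test_that("decoys preserve composition and translate back to a shuffle", {
  set.seed(73)
  prot <- framehmm:::sample_background_peptides(1, 100)
  d <- make_decoy(prot)
  expect_equal(nchar(d), 300)
  back <- translate_dna(d)
  expect_false(grepl("\\*", back))                       # stop-free frame 0
  expect_equal(sort(strsplit(back, "")[[1]]),
               sort(strsplit(prot, "")[[1]]))            # anagram
})

test_that("indel injection: identity at rate 0 and correct event statistics", {
  set.seed(74)
  dna <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE), collapse = "")
  r0 <- inject_indels(dna, 0)
  expect_identical(r0$dna, dna)
  expect_equal(nrow(r0$events), 0)

  n <- 1e6
  big <- strrep("ACGT", n / 4)
  set.seed(75)
  r <- inject_indels(big, 0.02)
  ev <- r$events
  # initiation count: Binomial(1e6, .02), 3 sigma
  expect_lt(abs(nrow(ev) - 20000), 3 * sqrt(1e6 * 0.02 * 0.98))
  # kinds balanced
  expect_lt(abs(mean(ev$kind == "insertion") - 0.5), 3 * sqrt(0.25 / nrow(ev)))
  # lengths are 1 + Geometric(0.5)
  expect_lt(abs(mean(ev$length) - 2), 3 * sqrt(2) / sqrt(nrow(ev)))
  expect_lt(abs(mean(ev$length == 1) - 0.5), 3 * sqrt(0.25 / nrow(ev)))
  # mutated length shifts by insertions - deletions (deletions may truncate
  # at overlaps, so only a loose check)
  expect_lt(abs(nchar(r$dna) - n) / n, 0.01)
})

test_that("sequence reconstruction around indels is locally correct", {
  # deterministic check on a tiny sequence with forced events
  set.seed(76)
  dna <- "AAAACCCCGGGGTTTT"
  found_ins <- FALSE; found_del <- FALSE
  for (i in 1:200) {
    r <- inject_indels(dna, 0.08)
    ev <- r$events
    if (nrow(ev) == 1 && ev$kind == "deletion" &&
        ev$position + ev$length <= nchar(dna)) {
      expect_equal(r$dna, paste0(substr(dna, 1, ev$position),
                                 substr(dna, ev$position + ev$length + 1,
                                        nchar(dna))))
      found_del <- TRUE
    }
    if (nrow(ev) == 1 && ev$kind == "insertion") {
      expect_equal(nchar(r$dna), nchar(dna) + ev$length)
      expect_equal(substr(r$dna, 1, ev$position), substr(dna, 1, ev$position))
      found_ins <- TRUE
    }
    if (found_ins && found_del) break
  }
  expect_true(found_ins && found_del)
})

test_that("embedding records exact coordinates and conserves length", {
  set.seed(77)
  bg <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE), collapse = "")
  ins <- tibble::tibble(seq = c(strrep("ACGTT", 20), strrep("GATTA", 30)),
                        label = c("family_instance", "decoy"),
                        family = c("famX", NA))
  emb <- embed_sequences(bg, ins)
  expect_equal(nchar(emb$chromosome), 10000 + 100 + 150)
  tr <- emb$truth
  for (i in 1:2) {
    sub <- substr(emb$chromosome, tr$start[i] + 1, tr$end[i])
    planted <- if (tr$strand[i] == "+") ins$seq[i] else framehmm:::revcomp(ins$seq[i])
    expect_equal(sub, planted)
  }
  expect_true(tr$end[1] <= tr$start[2] || tr$end[2] <= tr$start[1])
})

test_that("classification implements the three >50% rules", {
  truth <- tibble::tibble(chrom = "c1",
                          start = c(1000L, 3000L, 5000L),
                          end = c(1300L, 3300L, 5300L),
                          label = c("family_instance", "family_instance", "decoy"),
                          family = c("famA", "famB", NA),
                          strand = "+")
  hits <- tibble::tibble(
    query = c("famA", "famA", "famA", "famA"),
    target = "c1",
    dna_start = c(1040L, 7000L, 3010L, 1200L),
    dna_end = c(1290L, 7200L, 3250L, 1340L),
    evalue = c(1e-10, 1e-4, 1e-6, 1e-3),
    frameshift_count = 0L)
  lab <- classify_hits(hits, truth)
  expect_equal(lab$class, c("TP",       # covers 250/300 of same-family famA
                            "FP",       # entirely background
                            "ignored",  # mostly inside famB's instance
                            "partial")) # same family but covers < 50%
  expect_equal(lab$instance[1], 1L)
  # 80% inside a decoy is a false positive
  h2 <- tibble::tibble(query = "famA", target = "c1", dna_start = 5050L,
                       dna_end = 5350L, evalue = 1e-5, frameshift_count = 0L)
  expect_equal(classify_hits(h2, truth)$class, "FP")
})

test_that("ROC and recall-0 behave at the boundaries", {
  truth <- tibble::tibble(chrom = "c1", start = c(0L, 1000L), end = c(300L, 1300L),
                          label = "family_instance", family = "famA",
                          strand = "+")
  mk <- function(starts, ends, evalues, classes) {
    h <- tibble::tibble(query = "famA", target = "c1",
                        dna_start = starts, dna_end = ends,
                        evalue = evalues, frameshift_count = 0L)
    lab <- classify_hits(h, truth)
    stopifnot(identical(lab$class, classes))
    lab
  }
  # no FPs: recall-0 equals overall recall
  lab <- mk(c(10L, 1010L), c(290L, 1290L), c(1e-9, 1e-8), c("TP", "TP"))
  rr <- roc_and_recall0(lab, truth)
  expect_equal(rr$recall0$recall0, 1)
  expect_true(all(diff(rr$roc$fp) >= 0) && all(diff(rr$roc$recall) >= 0))
  # first hit is an FP: recall-0 is 0
  lab2 <- mk(c(6000L, 10L, 1010L), c(6300L, 290L, 1290L),
             c(1e-12, 1e-9, 1e-8), c("FP", "TP", "TP"))
  rr2 <- roc_and_recall0(lab2, truth)
  expect_equal(rr2$recall0$recall0, 0)
})

test_that("coverage counts each nucleotide once", {
  truth <- tibble::tibble(chrom = "c1", start = 1000L, end = 1300L,
                          label = "family_instance", family = "famA",
                          strand = "+")
  base <- tibble::tibble(query = "famA", target = "c1", evalue = 1e-9,
                         frameshift_count = 0L)
  exact <- cbind(base, dna_start = 1000L, dna_end = 1300L)
  lab <- classify_hits(exact, truth)
  cov <- coverage_metrics(lab, truth)
  expect_equal(cov$mean_coverage, 1)
  expect_equal(cov$per_instance$n_alignments, 1L)

  halves <- rbind(cbind(base, dna_start = 1000L, dna_end = 1180L),
                  cbind(base, dna_start = 1120L, dna_end = 1300L))
  lab2 <- classify_hits(halves, truth)
  cov2 <- coverage_metrics(lab2, truth)
  expect_equal(cov2$mean_coverage, 1)          # overlap counted once
  expect_equal(cov2$per_instance$n_alignments, 2L)
})

test_that("overextension flags at four or more nucleotides", {
  truth <- tibble::tibble(chrom = "c1", start = 1000L, end = 1300L,
                          label = "family_instance", family = "famA",
                          strand = "+")
  base <- tibble::tibble(query = "famA", target = "c1", evalue = 1e-9,
                         frameshift_count = 0L)
  h <- rbind(cbind(base, dna_start = 1000L, dna_end = 1300L),  # exact
             cbind(base, dna_start = 997L, dna_end = 1300L),   # 3 nt: not flagged
             cbind(base, dna_start = 996L, dna_end = 1300L))   # 4 nt: flagged
  lab <- classify_hits(h, truth)
  ov <- overextension_metrics(lab, truth)
  expect_equal(ov$per_alignment$flagged, c(FALSE, FALSE, TRUE))
  expect_equal(ov$frac_overextended, 1 / 3)
  expect_equal(ov$mean_overextension, 4)
})

test_that("generate_benchmark produces a consistent world", {
  bench <- generate_benchmark(n_families = 3, instances_per_family = 2,
                              n_decoys = 5, indel_rate = 0.02,
                              n_chrom = 2, chrom_len = 5000, seed = 12)
  expect_length(bench$queries, 3)
  expect_equal(nrow(bench$chromosomes), 2)
  tr <- bench$truth
  expect_equal(sum(tr$label == "family_instance"), 6)
  expect_equal(sum(tr$label == "decoy"), 5)
  # truth coordinates point at the right chromosome content
  for (i in seq_len(nrow(tr))) {
    chrom <- bench$chromosomes$seq[bench$chromosomes$id == tr$chrom[i]]
    expect_equal(nchar(substr(chrom, tr$start[i] + 1, tr$end[i])),
                 tr$end[i] - tr$start[i])
  }
  # BED round trip
  f <- withr::local_tempfile()
  write_truth_bed(tr, f)
  back <- read_truth_bed(f)
  expect_equal(back$start, tr$start)
  expect_equal(back$family, tr$family)

  # mid50 halves the embedded instances
  b2 <- generate_benchmark(n_families = 2, instances_per_family = 2,
                           n_decoys = 0, indel_rate = 0, n_chrom = 1,
                           chrom_len = 4000, mid50 = TRUE, seed = 13)
  inst_len <- with(b2$truth[b2$truth$label == "family_instance", ], end - start)
  Ms <- vapply(b2$queries, function(q) q$M, numeric(1))
  expect_true(all(inst_len < 3 * max(Ms) * 0.7))
})
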