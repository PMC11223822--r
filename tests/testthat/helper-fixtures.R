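# Shared fixture builders.  Everything is generated in code; the only stored
# fixtures are the tiny Stockholm alignment and its hmmbuild-produced
# HMMER3 ASCII profile under inst/extdata.

fixture_path <- function(name) {
  system.file("extdata", name, package = "framehmm")
}

# a reproducible random profile with given size (wraps the benchmark module's
# family sampler under a local seed so tests do not disturb the RNG stream)
fixture_profile <- function(M, seed = 1, peak = 0.6, name = "fix") {
  withr::with_seed(seed, sample_family_profile(M, name = name, peak = peak))
}

# a fully random (non-peaked) profile: rough emission/transition draws
fixture_rough_profile <- function(M, seed = 1, name = "rough") {
  withr::with_seed(seed, {
    me <- t(sapply(seq_len(M), function(i) { x <- stats::rexp(20)^2; x / sum(x) }))
    ie <- t(sapply(seq_len(M), function(i) { x <- stats::rexp(20); x / sum(x) }))
    tr <- t(sapply(seq_len(M), function(i) {
      m3 <- c(0.85, 0.08, 0.07) + stats::runif(3, 0, 0.05)
      c(m3 / sum(m3), 0.6, 0.4, 0.7, 0.3)
    }))
    new_profile(name, me, ie, tr)
  })
}

# a profile that deterministically emits a fixed consensus (near-degenerate)
fixture_peaked_profile <- function(consensus, peak = 0.999, name = "peaked") {
  chars <- strsplit(consensus, "")[[1]]
  M <- length(chars)
  bg <- framehmm:::aa_background()
  me <- matrix(rep((1 - peak) * bg, each = M), M, 20)
  idx <- match(chars, framehmm:::AA_ALPHABET)
  me[cbind(seq_len(M), idx)] <- me[cbind(seq_len(M), idx)] + peak
  ie <- matrix(rep(bg, each = M), M, 20)
  tr <- matrix(rep(c(0.998, 0.001, 0.001, 0.9, 0.1, 0.9, 0.1), each = M), M, 7)
  new_profile(name, me, ie, tr)
}
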