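# Score statistics: Gumbel and exponential-tail P-values, calibration of a
# profile by simulation against random sequences, and E-values.

#' Gumbel P-value
#'
#' `P = 1 - exp(-exp(-lambda * (score - mu)))`; used for the MSV and Viterbi
#' filter scores.
#'
#' @param score Bit score(s).
#' @param mu,lambda Gumbel location and slope.
#' @return P-value(s) in \[0, 1\].
#' @export
gumbel_pvalue <- function(score, mu, lambda) {
  p <- -expm1(-exp(-lambda * (score - mu)))
  pmin(pmax(p, 0), 1)
}

#' Exponential-tail P-value
#'
#' `P = min(1, exp(-lambda * (score - tau)))`; used for Forward scores.
#'
#' @param score Bit score(s).
#' @param tau,lambda Exponential location and rate.
#' @return P-value(s) in \[0, 1\].
#' @export
exp_pvalue <- function(score, tau, lambda) {
  pmin(exp(-lambda * (score - tau)), 1)
}

# Gumbel fit anchored at a filter's operating point.  The empirical score
# distributions deviate from a single Gumbel across their whole range, so a
# bulk ML fit misplaces the thin operating tail; instead the slope is taken
# from two tail quantiles bracketing the operating region and the location
# is anchored so the fitted P-value is exact at the `p_anchor` empirical
# quantile.
fit_gumbel_filter <- function(scores, p_anchor, p_hi, p_lo) {
  x <- sort(scores[is.finite(scores)])
  n <- length(x)
  q <- function(p) x[ceiling((1 - p) * n)]
  g <- function(p) -log(-log1p(-p))  # Gumbel quantile transform
  d <- q(p_lo) - q(p_hi)
  lam <- if (d > 0) (g(p_lo) - g(p_hi)) / d else log(2)
  mu <- q(p_anchor) - g(p_anchor) / lam
  list(mu = mu, lambda = lam)
}

# Exponential upper-tail fit with the slope fixed at ln 2 (the asymptotic
# Forward-tail slope in bit units; the empirical slope steepens toward it
# with depth, so a fitted shallow slope would badly mis-extrapolate).  The
# location anchors the model at a deep empirical quantile:
# P(S > s) = tailp * exp(-lambda (s - s0)) = exp(-lambda (s - tau)).
# -Inf scores (e.g. windows without an envelope) stay in the sample: they
# are part of the statistic's distribution and deflate the tail.
fit_exp_tail <- function(scores, tailp = 0.02, lambda = log(2)) {
  n <- length(scores)
  ss <- sort(scores)
  s0 <- ss[ceiling((1 - tailp) * n)]
  if (!is.finite(s0)) {
    fin <- ss[is.finite(ss)]
    if (length(fin) == 0) return(list(tau = -Inf, lambda = lambda))
    s0 <- fin[1]
    tailp <- length(fin) / n
  }
  list(tau = s0 + log(tailp) / lambda, lambda = lambda)
}

# i.i.d. background peptides
sample_background_peptides <- function(n, len, bg = aa_background()) {
  vapply(seq_len(n), function(i) {
    paste(sample(AA_ALPHABET, len, replace = TRUE, prob = bg), collapse = "")
  }, character(1))
}

#' Calibrate score statistics of a profile by simulation
#'
#' Scores `n` random i.i.d. background sequences: peptides of length `2M`
#' with the MSV and Viterbi engines, window-length best-span clips with the
#' Forward protein engine, and (if a codon profile is given)
#' reverse-translated random-peptide DNA of the pipeline's window length
#' with the frameshift-aware Forward engine.  MSV and Viterbi Gumbels are
#' anchored at their filter operating points with locally estimated slopes;
#' the Forward variants get exponential upper-tail fits with the slope fixed
#' at ln 2 and the location anchored at the empirical 98th percentile.  The
#' envelope-rescored final statistics (`fwd_env_*`, `ffwd_env_*`) are
#' calibrated by running the same posterior-envelope-rescore computation the
#' pipeline reports.
#'
#' @param profile An `fh_profile`.
#' @param codon_profile Optional `fh_codon_profile` derived from `profile`.
#' @param n Number of simulated sequences (a warning is logged below 50).
#' @param seed Integer seed; calibration is reproducible given the seed.
#' @return The profile with `$calibration` set (and the same calibration
#'   installed on the codon profile's parent if one was supplied).
#' @export
calibrate <- function(profile, codon_profile = NULL, n = 500, seed = 42) {
  if (n < 50) warning("calibrate: n = ", n, " is small; estimates will be noisy")
  M <- profile$M
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  peps <- sample_background_peptides(n, 2 * M, profile$background)
  msv <- msv_score(profile, peps)
  vit <- viterbi_score_protein(profile, peps)
  # Forward statistics are calibrated on peptides of the pipeline's window
  # length (the search clips candidate peptides to the window), so the
  # simulated statistic matches the reported one in length as well as form
  win_len_aa <- if (!is.null(profile$max_len_aa))
    ceiling((3 * profile$max_len_aa + 30) / 3) else 2 * M
  # The pipeline centers a window-length clip on the best Viterbi span of a
  # surviving ORF, so the null statistic is a best-span-centered clip of a
  # longer random peptide, not a randomly placed one.  Simulate exactly
  # that: sample a 3x-window peptide, locate the Viterbi span, clip, then
  # compute the first-pass Forward and the envelope-rescored Forward.
  sim_len <- 3 * win_len_aa
  fpeps <- sample_background_peptides(n, sim_len, profile$background)
  fwd <- numeric(n)
  fwd_env <- vapply(seq_len(n), function(i) {
    vp <- protein_viterbi_path(profile, fpeps[i])
    core <- vp$path[vp$path$kind %in% c("M", "I"), ]
    mid <- if (nrow(core)) (min(core$from) + max(core$to)) / 2 else sim_len / 2
    a <- max(0, min(round(mid - win_len_aa / 2), sim_len - win_len_aa))
    clip <- substr(fpeps[i], a + 1, a + win_len_aa)
    dec <- protein_decode(profile, clip)
    fwd[i] <<- dec$fwd_bits
    env <- define_envelope(dec$post_core)
    if (is.null(env)) return(-Inf)
    forward_protein(profile, substr(clip, env[1] + 1, env[2]))
  }, numeric(1))
  ffwd_fit <- list(tau = NA_real_, lambda = NA_real_)
  ffwd_env_fit <- list(tau = NA_real_, lambda = NA_real_)
  if (!is.null(codon_profile)) {
    code <- codon_profile$code
    n_fa <- n
    dna <- reverse_translate_batch(
      sample_background_peptides(n_fa, win_len_aa, profile$background), code)
    ffwd <- numeric(n_fa)
    ffwd_env <- vapply(seq_len(n_fa), function(i) {
      po <- fa_posterior(codon_profile, dna[i])
      ffwd[i] <<- po$fwd_bits
      env <- define_envelope(po$core)
      if (is.null(env)) return(-Inf)
      as.numeric(fa_forward(codon_profile, substr(dna[i], env[1] + 1, env[2])))
    }, numeric(1))
    ffwd_fit <- fit_exp_tail(ffwd)
    ffwd_env_fit <- fit_exp_tail(ffwd_env)
  }
  msv_fit <- fit_gumbel_filter(msv, 0.02, 0.05, 0.01)
  vit_fit <- fit_gumbel_filter(vit, 0.002, 0.01, 0.002)
  fwd_fit <- fit_exp_tail(fwd)
  fwd_env_fit <- fit_exp_tail(fwd_env)
  profile$calibration <- list(
    msv_mu = msv_fit$mu, msv_lambda = msv_fit$lambda,
    vit_mu = vit_fit$mu, vit_lambda = vit_fit$lambda,
    fwd_tau = fwd_fit$tau, fwd_lambda = fwd_fit$lambda,
    ffwd_tau = ffwd_fit$tau, ffwd_lambda = ffwd_fit$lambda,
    fwd_env_tau = fwd_env_fit$tau, fwd_env_lambda = fwd_env_fit$lambda,
    ffwd_env_tau = ffwd_env_fit$tau, ffwd_env_lambda = ffwd_env_fit$lambda,
    seed = as.integer(seed), n = as.integer(n))
  profile
}

#' E-value from a P-value
#'
#' Bonferroni-style correction: the effective number of tests is the target
#' length (times 2 when both strands are searched) divided by the query's
#' window length L in nucleotides, floored at 1.
#'
#' @param pvalue P-value(s).
#' @param target_nt_len Total searched DNA length (nt).
#' @param L_nt Window length L in nucleotides (`3 * max_len_aa`).
#' @param both_strands Whether both strands were searched.
#' @return E-value(s).
#' @export
evalue <- function(pvalue, target_nt_len, L_nt, both_strands = TRUE) {
  stopifnot(L_nt >= 1)
  n_eff <- max(1, target_nt_len * (if (both_strands) 2 else 1) / L_nt)
  pvalue * n_eff
}
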