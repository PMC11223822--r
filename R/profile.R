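# The protein profile HMM object: per-position match/insert emission
# distributions over the 20 amino acids and per-node transition
# probabilities, plus optional score calibration parameters and the
# window-length parameter derived from the emitted-length distribution.

TRANS_NAMES <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")

#' Construct a protein profile HMM
#'
#' Core model with `M` nodes.  Row `i` of `transitions` holds the
#' probabilities out of node `i` (`MM, MI, MD, IM, II, DM, DD`); row `M`
#' leads to the end state, so `MM` there is the match-to-end probability and
#' `MI`/`MD` must be 0.
#'
#' @param name Model name.
#' @param match_emissions `M x 20` matrix, rows sum to 1.
#' @param insert_emissions `M x 20` matrix, rows sum to 1.
#' @param transitions `M x 7` matrix, groups `(MM,MI,MD)`, `(IM,II)`,
#'   `(DM,DD)` each summing to 1 per row.
#' @param background Length-20 amino-acid background distribution.
#' @param calibration Optional list of calibration parameters
#'   (see [calibrate()]).
#' @param max_len_aa Optional window length parameter L
#'   (see [emitted_length_tail()]).
#' @return An object of class `fh_profile`.
#' @export
new_profile <- function(name, match_emissions, insert_emissions, transitions,
                        background = aa_background(), calibration = NULL,
                        max_len_aa = NULL) {
  M <- nrow(match_emissions)
  stopifnot(M >= 1, ncol(match_emissions) == 20,
            all(dim(insert_emissions) == c(M, 20)),
            all(dim(transitions) == c(M, 7)),
            length(background) == 20)
  # renormalize within tolerance, fail beyond it
  renorm <- function(m, groups) {
    for (g in groups) {
      s <- rowSums(m[, g, drop = FALSE])
      if (any(abs(s - 1) > 1e-4)) {
        stop("profile probabilities do not sum to 1 (off by ",
             max(abs(s - 1)), ")")
      }
      m[, g] <- m[, g, drop = FALSE] / s
    }
    m
  }
  match_emissions <- renorm(match_emissions, list(1:20))
  insert_emissions <- renorm(insert_emissions, list(1:20))
  transitions[M, 2] <- 0; transitions[M, 3] <- 0
  transitions[M, 1] <- 1
  transitions <- renorm(transitions, list(1:3, 4:5, 6:7))
  colnames(transitions) <- TRANS_NAMES
  colnames(match_emissions) <- AA_ALPHABET
  colnames(insert_emissions) <- AA_ALPHABET
  structure(list(name = name, M = M,
                 match_emissions = match_emissions,
                 insert_emissions = insert_emissions,
                 transitions = transitions,
                 background = background / sum(background),
                 calibration = calibration,
                 max_len_aa = max_len_aa),
            class = "fh_profile")
}

#' @export
print.fh_profile <- function(x, ...) {
  cat(sprintf("<fh_profile '%s': M=%d%s%s>\n", x$name, x$M,
              if (!is.null(x$max_len_aa)) sprintf(", L=%d aa", x$max_len_aa) else "",
              if (!is.null(x$calibration)) ", calibrated" else ""))
  invisible(x)
}

#' Search configuration
#'
#' Collects the tunable thresholds of the search pipeline.  Defaults follow
#' the staged-filter design: peptides of at least 20 residues enter the
#' pipeline, the MSV filter keeps P <= .02, the Viterbi filter P <= .001, and
#' a candidate survives the dual-Forward gate when either Forward P-value is
#' at most 1e-5.
#'
#' @param msv_pthresh,vit_pthresh,fwd_pthresh Stage P-value thresholds.
#' @param min_peptide_len Minimum translated ORF length (aa).
#' @param window_tail_mass Tail mass defining the window length L.
#' @param report_evalue_max Maximum E-value reported.
#' @param genetic_code_id NCBI translation table id.
#' @param both_strands Search both strands of the target.
#' @param mode One of `"default"`, `"nofs"` (force the standard path),
#'   `"fsonly"` (force the frameshift-aware path).
#' @param fs_prob,stop_prob Optional overrides for the frameshift/stop-codon
#'   penalties: `fs_prob` sets the length-2/4 quasi-codon penalty (the
#'   length-1/5 penalty is half of it), `stop_prob` the stop-codon penalty.
#' @param seed Integer seed used wherever the pipeline needs randomness
#'   (calibration).
#' @param calibrate_n Simulation sample size used when profiles must be
#'   calibrated on the fly.
#' @param verbose Log per-stage survivor tallies (MSV, Viterbi, window,
#'   Forward gate) per query.
#' @return A list of class `fh_config`.
#' @export
search_config <- function(msv_pthresh = 0.02, vit_pthresh = 0.001,
                          fwd_pthresh = 1e-5, min_peptide_len = 20,
                          window_tail_mass = 1e-7, report_evalue_max = 10,
                          genetic_code_id = 1, both_strands = TRUE,
                          mode = c("default", "nofs", "fsonly"),
                          fs_prob = NULL, stop_prob = NULL, seed = 42,
                          calibrate_n = 500, verbose = FALSE) {
  mode <- match.arg(mode)
  stopifnot(msv_pthresh > 0, msv_pthresh < 1, vit_pthresh > 0, vit_pthresh < 1,
            fwd_pthresh > 0, fwd_pthresh < 1, min_peptide_len >= 1,
            window_tail_mass > 0, window_tail_mass < 1)
  structure(list(msv_pthresh = msv_pthresh, vit_pthresh = vit_pthresh,
                 fwd_pthresh = fwd_pthresh, min_peptide_len = min_peptide_len,
                 window_tail_mass = window_tail_mass,
                 report_evalue_max = report_evalue_max,
                 genetic_code_id = genetic_code_id,
                 both_strands = both_strands, mode = mode,
                 fs_prob = fs_prob, stop_prob = stop_prob, seed = seed,
                 calibrate_n = calibrate_n, verbose = verbose),
            class = "fh_config")
}
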