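# framehmm

Frameshift-aware translated homology search of DNA against protein profile
hidden Markov models, with a synthetic benchmark generator and evaluator.

## The problem

Protein-coding DNA accumulates nucleotide insertions and deletions —
through sequencing error or pseudogenization — and any indel whose length
is not a multiple of 3 shifts the reading frame.  Conventional translated
search (six-frame translation followed by protein–protein comparison)
fragments such regions at every frameshift and at every in-frame stop
codon, so hits shrink, scores drop, and marginal homologs are lost
entirely.  `framehmm` searches DNA with a protein profile HMM whose match
states emit, besides ordinary codons, *stop codons* and *quasi-codons* of
1, 2, 4, or 5 nucleotides, so a single alignment can pass through
frameshifts and degenerate stops while paying an explicit probabilistic
penalty for each.

## The model

A query is a profile HMM with per-position match/insert emission
distributions over the 20 amino acids and `MM, MI, MD, IM, II, DM, DD`
transitions.  From it the codon-space model is derived:

* a **sense codon** `c` is emitted by match state `i` with probability
  `0.96 × e_i(aa(c)) / n_syn(aa(c))` (the amino-acid emission shared
  equally among its synonymous codons);
* a **stop codon** `s` with probability `0.01 × e_i(c*)`, where `c*` is the
  best sense codon within one substitution of `s`;
* a **quasi-codon** `q` of length 1, 2, 4, or 5 with probability
  `p_len × e_i(c*_q) / Z_len`, where `c*_q` maximizes the emission over the
  *completion set* of `q` (all codons reachable by adding or removing the
  nucleotides needed to reach length 3; e.g. `ca` completes to
  `{A,H,L,P,Q,R,S,T}`), `p_len` is 0.01 for lengths 2/4 and 0.005 for
  lengths 1/5, and `Z_len` normalizes the class;
* `0.96 = 1 − (0.01 + 0.01 + 0.01 + 0.005 + 0.005)` keeps each state's
  emission a probability distribution.

The search pipeline mirrors a staged translated-search design: six-frame
stop-to-stop ORFs (≥ 20 aa) → MSV filter (P ≤ .02) → Viterbi filter
(P ≤ .001) → genomic window of length `3L + 30` around the seed (L chosen
so only 1e-7 of model emissions exceed it) → standard Forward P-value `F0`
and frameshift-aware Forward P-value `F1` → a candidate survives when
either is ≤ 1e-5 → the less extreme path is discarded (standard iff
`F0 ≤ F1`) → posterior-decoded envelope, rescoring, and an E-value
`P × 2·(target length)/3L`.  Score statistics are calibrated per profile by
simulation (Gumbel fits for the filters, exponential tails with slope ln 2
for both Forward variants).

## Worked example

Plant a sampled family instance, delete one nucleotide in its middle, and
search:

```r
library(framehmm)
set.seed(10)
prof <- sample_family_profile(80, "famA")            # random 80-state family
inst <- reverse_translate(sample_sequence(prof))     # one instance as DNA
inst <- paste0(substr(inst, 1, 120), substr(inst, 122, nchar(inst)))  # -1 nt
target <- paste0(sample_background(background_hmm(), 3000), inst,
                 sample_background(background_hmm(), 3000))
hits <- run_search(prof, c(chr1 = target), search_config())
hits[, c("query","strand","dna_start","dna_end","score","evalue",
         "path_used","frameshift_count")]
#> # A tibble: 1 x 8
#>   query strand dna_start dna_end score   evalue path_used        frameshift_count
#> 1 famA  +           2963    3221  82.8 1.38e-18 frameshift_aware                1
```

One hit: the frameshift-aware path was chosen (its `F1` beat the standard
`F0`), the alignment crosses the deleted nucleotide with exactly one
quasi-codon step (`frameshift_count = 1`), and the reported span covers the
planted instance across both reading frames.  On the same target *without*
the deletion the pipeline reports the standard path with
`frameshift_count = 0`.

`render_alignment(hits[1, ], prof, target)` prints the four-row alignment
(query consensus, match line, translated codons, target nucleotides with
quasi-codons in lowercase).

Shell front ends in `exec/` wrap the same functions:
`framehmm build/convert/search` and `framehmm-bench generate/evaluate`.

## Acceptance script

`scripts/acceptance.R` recomputes, from scratch against the installed
package: the fraction of 20 000 random background peptides removed by the
calibrated MSV filter at P ≤ .02 and by the Viterbi filter at P ≤ .001
(for a freshly sampled, freshly calibrated 100-state profile), and the
maximum emitted-length tail mass beyond the automatically selected window
length L over 20 random profiles.  Run it from the repository root:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
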