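---
title: "Frameshift-aware translated search: models, statistics, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frameshift-aware translated search: models, statistics, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(framehmm)
```

This vignette is the package's own account of its science: the models it
implements, the statistical machinery behind its E-values, the numerical
and design choices that were genuinely open, and what its synthetic
benchmark does and does not establish.

## 1. The two models

### Protein profile HMM

The core object is a standard profile HMM over the 20 amino acids: `M`
nodes, each with a match emission distribution, an insert emission
distribution, and transition probabilities `MM, MI, MD / IM, II / DM, DD`.
Searching is done in HMMER-style *local multihit* mode: uniform entry
`B -> M_k` with probability `2(M-k+1)/(M(M+1))`, free exit from any match
or delete state, and flanking `N/C/J` states that emit at null frequency
with length-dependent loop probabilities (`loop = n/(n+3)` for a target of
length `n`).  Scores are log-odds in bits against an i.i.d. background
with geometric length.

Profiles can be built three ways:

* **From an MSA** (`build_from_msa`): columns with gap fraction < 0.5
  become match states; sequences get Henikoff position-based weights,
  normalized so the total weight equals the number of *distinct* rows
  (duplicated rows then change nothing, which is the behaviour a user
  expects of an alignment with redundant members).  Emission counts are
  blended with a single-component Dirichlet prior of concentration 20
  spread as the background distribution; transition counts with small
  fixed prior counts that favour match-to-match.  This is deliberately
  simpler than HMMER's mixture-Dirichlet machinery: it is documented,
  testable, and adequate for profiles built from more than a handful of
  sequences.  For very small alignments the prior dominates rare residues
  (a cysteine seen once will not beat leucine's background), which is the
  price of the simple prior.
* **From a single sequence** (`build_from_sequence`): position `i` emits
  `P(a | seq_i)` derived from the BLOSUM62 joint distribution
  (`p(a,b) ∝ f_a f_b 2^{s_{ab}/2}`), with one fixed gap-cost-derived
  transition set (open 0.02, extend 0.4) at every node.
* **From files**: the native `FRAMEHMM/1` text format round-trips
  profiles losslessly including calibration; HMMER3 ASCII `.hmm` files are
  read (never written).

### Frameshift-aware codon model

Each match state of the codon-space model emits one of four chunk classes,
with class probabilities acting as implicit within-state transitions:

| class        | length | probability of the class | emission within the class |
|--------------|--------|--------------------------|---------------------------|
| sense codon  | 3      | `norm = 0.96`            | `e_i(aa(c)) / n_syn(aa(c))` |
| stop codon   | 3      | (bounded by `p_stop = 0.01`) | `p_stop × max` emission over sense codons within Hamming distance 1 |
| quasi-codon  | 1 or 5 | `p = 0.005`              | `e_i(c*_q) / Z` over the completion set |
| quasi-codon  | 2 or 4 | `p = 0.01`               | `e_i(c*_q) / Z` over the completion set |

The *completion set* of a quasi-codon `q` is the set of amino acids coded
by any codon having `q` as a subsequence (length < 3) or being a
subsequence of `q` (length > 3), stop codons excluded; the worked example
`ca -> {A,H,L,P,Q,R,S,T}` is pinned in the tests.  Assignment of a
quasi-codon to an amino acid is position-specific maximum likelihood: the
best completion *for the state being scored*.

**A normalization choice that matters.**  Taking the quasi-codon
probability to be literally `penalty × best-completion emission` for every
one of the `4^len` strings (and the sense-codon probability to be the full
amino-acid emission for each synonymous codon) does not define a
probability distribution: summed over codons the sense mass is ~3x (codon
degeneracy) and the length-4/5 quasi classes sum to more than 1 on their
own.  Scored against a nucleotide background, random coding DNA then
drifts upward at ~1.7 bits per codon, chains of length-5 quasi-codons
score *positive* on pure background, posterior envelopes saturate, and
E-values become length-unstable.  The within-state transition picture —
"with probability 0.01 enter the length-2 quasi-codon sub-state, then emit
from its distribution" — requires each class to be a distribution, so this
package divides the amino-acid emission equally among its synonymous
codons and normalizes each quasi class by its per-state sum `Z_len`.  The
two stated bounds (every quasi score ≤ its class penalty; every stop score
≤ `p_stop`) still hold, and each state's total emission mass is again 1.
Stop-codon scores are kept exactly `p_stop ×` the best Hamming-1 neighbor
emission: their total mass is at most `3 p_stop` and the slight excess is
immaterial.

Insert states consume exactly 3 nucleotides and receive the same sense and
stop treatment as match states (so Forward paths never die inside an
insertion over degenerate sequence); quasi-codon emission at insert states
is not reachable by the dynamic programming.  Chunks containing `N` score
log-odds 0 in every class: ambiguity can neither create nor destroy a hit.

## 2. Engines and their validation

All engines (protein MSV / Viterbi / Forward / Backward / posterior, and
the frameshift-aware Forward / Backward / posterior / Viterbi with
traceback) are compiled code operating in log space with exact
log-sum-exp.  The FA engines consume a per-window *emission cache*: each
(end position, length) chunk is decoded once — codon index, stop index, or
quasi-codon index plus background log-probability — and per-state scores
are O(1) table lookups thanks to per-profile precomputed maxima over
completion sets.  A deliberately naive engine (`use_cache = FALSE`)
recomputes every emission per DP cell with identical arithmetic; the tests
require bit-identical scores and strictly fewer chunk decodes with the
cache.

The primary correctness instrument is an *exhaustive path enumerator*
(`fa_reference_scores`): an explicit recursion over every legal state path
(no dynamic programming), whose log-sum and max over path weights are the
Forward and Viterbi scores by definition.  It is implemented twice —
compiled, and independently in plain R in the test helpers — and the two
enumerators and the DP engines must agree to 1e-9 bits on random small
instances.  Enumeration is exponential: at `M = 3` and a 10-nt window a
single instance already has ~1.5e9 paths, so the 1000-instance acceptance
sweep draws from the enumerable part of the grid and the largest size is
covered by a dedicated spot check.

## 3. The pipeline

`run_search` implements the staged design exactly: (1) six-frame
stop-to-stop ORFs of ≥ 20 aa (no start-codon requirement — stops and
sequence ends are the only boundaries, which maximizes downstream
sensitivity); (2) MSV at P ≤ .02; (3) Viterbi at P ≤ .001; (4) a genomic
window of length `3L + 30` centered on the *Viterbi alignment span* of the
surviving peptide; (5) `F0`, the Forward P-value of the peptide clipped to
the window; (6) `F1`, the frameshift-aware Forward P-value of the window;
(7) discard iff both exceed 1e-5; (8) standard path iff `F0 ≤ F1` (ties to
standard; `--nofs` and `--fsonly` force one side); (9) envelope
definition, rescoring, E-values, overlap deduplication (same query,
overlap > 50% of the shorter span, keep the better E-value).

Three window decisions deserve notice:

* The window is *hard-capped* at `3L + 30`.  A multihit Viterbi seed can
  span an entire long ORF; extending the window to contain it would let
  multihit chains accumulate score over many window-lengths of sequence,
  which no fixed-length calibration can describe (in testing this inflated
  null hit counts by an order of magnitude).  A long seed is therefore
  covered around its center; when the seed fits, the window contains it.
* The standard-path statistic operates on the peptide *clipped to the
  window*, so both arbitration branches test sequence of the same bounded
  length.
* The envelope is the span between the first and last window position with
  core-model posterior ≥ 0.5 — a deliberate simplification of HMMER's
  domain-definition machinery, isolated in `define_envelope` so it can be
  revised.  The displayed alignment is the FA Viterbi path within the
  envelope (HMMER would use optimal accuracy; the Viterbi path is what the
  frameshift and stop counts are defined on).

## 4. Score statistics

Every profile is calibrated by simulation (`calibrate`), reproducibly
under a seed:

* **Filters.**  MSV and Viterbi scores of random background peptides are
  fit with Gumbel curves *anchored at the filter operating points*: the
  slope comes from two tail quantiles bracketing the operating region and
  the location is set so the fitted P-value is exact at the empirical
  anchor quantile.  A whole-sample maximum-likelihood Gumbel fit (and a
  fixed slope of 0.693 even more so) visibly misplaces the 2% tail,
  because the empirical distributions are only locally Gumbel.
* **Forward tails.**  Both Forward variants are modeled as exponential
  tails with slope fixed at `ln 2` and location anchored at the empirical
  98th percentile.  The fixed slope is deliberate: measured tail slopes
  *steepen with depth toward ln 2* (from ~0.45 at the 80th percentile to
  ~0.65+ beyond the 99.5th), so a slope estimated at a shallow anchor
  under-extrapolates by orders of magnitude at reporting depths, and a
  per-profile fitted slope adds noise that inflates expected counts by
  Jensen's inequality.
* **Statistic matching.**  What is calibrated is exactly what is reported:
  the envelope-rescored Forward score of a window-length sequence whose
  placement is centered on the best Viterbi span of a longer random
  peptide — mirroring the pipeline's seeding selection.  Random DNA for
  the FA statistic is reverse-translated random peptide (matching the
  coding-like composition of translated-search targets).  First-pass fits
  (`fwd_tau`, `ffwd_tau`) drive the step-7 gate and arbitration;
  envelope-statistic fits (`fwd_env_tau`, `ffwd_env_tau`) drive the
  reported P.

E-values are `P × max(1, 2·(total target nt)/L_nt)` with
`L_nt = 3 × max_len_aa`; `L` (in amino acids) is the smallest length whose
emitted-length tail mass, computed exactly by dynamic programming over the
core model, is at most 1e-7.  The division is done in nucleotides — the
natural unit once the window is a DNA segment; the choice is configurable
at the `evalue()` call.

In default mode the reported P-value is the chosen path's P-value, with no
correction for having looked at two statistics; the E-value accuracy
experiment accordingly shows default mode running up to ~2x above the
expected count line while the forced modes track it — the same ordering
the reference experiment reports, and the reason the acceptance tolerance
is a ratio band rather than pure counting noise.

## 5. The synthetic benchmark

The generator emulates a translated-search benchmark without any external
data: pseudochromosomes sampled from a 15-state nucleotide HMM with
GC-heterogeneous sticky states (a stand-in for an HMM trained on real
genomes — real genomes also have repeats, coding skew and k-mer structure
that this does not reproduce); decoy ORFs made by shuffling random
proteins and reverse-translating them with uniform synonymous codons;
family instances emitted from randomly parameterized profiles
(`sample_family_profile`: one preferred residue per state at emission 0.6,
match-dominated transitions — roughly the information content of a
mid-sized protein family), reverse-translated, mutated with indels
(per-position initiation, fair insertion/deletion coin, geometric
50%-continuation lengths, hence 6/7 of indels frameshifting), and embedded
at uniform non-overlapping positions on random strands with exact truth
coordinates.  A `mid50` option embeds only the middle half of each
instance for over-extension measurement.

Evaluation classifies each hit by nucleotide overlap: a true positive
covers > 50% of a same-family instance; a false positive has > 50% of its
alignment in decoy or background; > 50% in another family's instance is
ignored (homology cannot be excluded); a same-family fragment below the
coverage bar is `partial` and counted on neither side.  On top of the
labels: ROC tables, per-family recall before the first false positive,
per-instance coverage (each nucleotide counted once), and over-extension
(flagged at ≥ 4 nt beyond the truth span).

A green benchmark test establishes that the pipeline recovers
indel-mutated instances of peaked random families far better with the
frameshift model than without (and identically when there are no indels).
It does not establish performance on real protein families — remote
homology, heterogeneous conservation, compositional bias and repeats are
all absent from the generator.

## 6. Numerical and scale choices

* Default calibration uses 500 simulated sequences (1000–4000 in the
  accuracy experiments, where anchor noise must sit below counting noise);
  tail anchors are the 98th percentile (Forward) and the operating
  quantiles (filters).
* The emitted-length DP caps at `100 M` with an explicit error rather than
  silent truncation; probability vectors are renormalized to 1e-9 after
  construction and profile files carry 15 significant digits.
* `-Inf` is the absorbing no-path sentinel throughout; log-sum-exp is
  exact (no lookup-table approximation), which is what makes the
  enumeration-vs-DP comparisons meaningful at 1e-9 bits.
* The E-value accuracy suite runs at 6e4 targets (reference scale 1e5) and
  the benchmark at 20 families x 10 instances on 10 x 20-kb
  pseudochromosomes — small enough for a test suite, large enough that
  the expected-count bands and recall orderings are far from degenerate.
* Seeds: every stochastic step (generation, calibration, sampling) is
  seeded explicitly; `calibrate` saves and restores the caller's RNG
  state.

## 7. Known limitations

* No biased-composition (null2) correction: strongly repetitive or
  low-complexity targets will score optimistically.
* The quasi/stop penalties are fixed defaults (configurable, not learned);
  per-error-environment calibration is explicitly out of scope.
* Insert-state quasi-codon emissions exist in the model tables but no DP
  transition consumes them; frameshifts inside long insertions are
  absorbed by neighbouring match states instead.
* The flank-state contract (single-nucleotide null loops) is this
  package's concrete choice where the reference design defers to
  supplementary material; it is isolated behind the engine interface.
* Throughput is a single CPU core without SIMD striping; the engines are
  written for correctness and testability first.
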