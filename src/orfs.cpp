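// Batch six-frame ORF extraction.  Stop-to-stop peptide segments (sequence
// ends act as boundaries, no start-codon requirement) in all six frames,
// with forward-strand 0-based half-open coordinates.

#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_six_frame_orfs(CharacterVector seqs, int min_len,
                        std::string aa64, bool both_strands) {
  std::vector<int> out_seq, out_frame, out_start, out_end;
  std::vector<char> out_strand;
  std::vector<std::string> out_pep;

  for (int si = 0; si < seqs.size(); ++si) {
    const char* s = CHAR(STRING_ELT(seqs, si));
    int n = LENGTH(STRING_ELT(seqs, si));
    std::vector<int> fwd(n);
    for (int i = 0; i < n; ++i) {
      switch (s[i]) {
      case 'A': case 'a': fwd[i] = 0; break;
      case 'C': case 'c': fwd[i] = 1; break;
      case 'G': case 'g': fwd[i] = 2; break;
      case 'T': case 't': fwd[i] = 3; break;
      default: fwd[i] = -1;
      }
    }
    for (int st = 0; st < (both_strands ? 2 : 1); ++st) {
      std::vector<int> v;
      if (st == 0) v = fwd;
      else {
        v.resize(n);
        for (int i = 0; i < n; ++i) {
          int x = fwd[n - 1 - i];
          v[i] = x < 0 ? -1 : 3 - x;
        }
      }
      for (int frame = 0; frame < 3; ++frame) {
        int ncod = (n - frame) / 3;
        if (ncod <= 0) continue;
        std::string pep(ncod, 'X');
        for (int c = 0; c < ncod; ++c) {
          int a = v[frame + 3 * c], b = v[frame + 3 * c + 1],
              d = v[frame + 3 * c + 2];
          pep[c] = (a < 0 || b < 0 || d < 0) ? 'X'
            : aa64[(size_t)(a * 16 + b * 4 + d)];
        }
        // split at '*'
        int seg_start = 0;
        for (int c = 0; c <= ncod; ++c) {
          if (c == ncod || pep[c] == '*') {
            int seg_len = c - seg_start;
            if (seg_len >= min_len) {
              // aa span [seg_start, c) -> strand-local nt
              int s_nt = frame + 3 * seg_start;
              int e_nt = frame + 3 * c;
              int ds, de;
              if (st == 0) { ds = s_nt; de = e_nt; }
              else { ds = n - e_nt; de = n - s_nt; }
              out_seq.push_back(si + 1);
              out_strand.push_back(st == 0 ? '+' : '-');
              out_frame.push_back(frame);
              out_start.push_back(ds);
              out_end.push_back(de);
              out_pep.push_back(pep.substr(seg_start, seg_len));
            }
            seg_start = c + 1;
          }
        }
      }
    }
  }
  int m = out_seq.size();
  IntegerVector rseq(m), rframe(m), rstart(m), rend(m);
  CharacterVector rstrand(m), rpep(m);
  for (int i = 0; i < m; ++i) {
    rseq[i] = out_seq[i]; rframe[i] = out_frame[i];
    rstart[i] = out_start[i]; rend[i] = out_end[i];
    rstrand[i] = std::string(1, out_strand[i]);
    rpep[i] = out_pep[i];
  }
  return List::create(_["seq_index"] = rseq, _["strand"] = rstrand,
                      _["frame"] = rframe, _["dna_start"] = rstart,
                      _["dna_end"] = rend, _["peptide"] = rpep);
}
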